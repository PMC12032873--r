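test_that("phase converts to displacement linearly with the encoding strength", {
  series <- list(phase_x = array(pi, c(2, 2, 1)),
                 phase_y = array(0, c(2, 2, 1)),
                 frame_times = 0, masks = array(TRUE, c(2, 2, 1)),
                 acq = list(ke = 0.1))
  eu <- phase_to_eulerian(series)
  expect_equal(eu$ux[1, 1, 1], 5)        # pi / (2 pi 0.1) = 5 mm
  expect_true(eu$wrapped)
  # linearity before wrapping
  series$phase_x <- series$phase_x / 2
  expect_equal(phase_to_eulerian(series)$ux[1, 1, 1], 2.5)
  # a full period wraps back to zero displacement
  series$phase_x <- array(wrap_phase(2 * pi), c(2, 2, 1))
  expect_equal(phase_to_eulerian(series)$ux[1, 1, 1], 0)
})

make_field <- function(ux, uy = ux * 0, masks = NULL, ke = 0.1,
                       times = seq_len(dim(ux)[3]) * 30) {
  if (is.null(masks)) masks <- array(TRUE, dim = dim(ux))
  structure(list(ux = ux, uy = uy, frame_times = times, masks = masks,
                 ke = ke, wrapped = TRUE),
            class = "dense_eulerian")
}

test_that("unwrapping recovers a wrapped ramp and respects gauge freedom", {
  n <- 24
  ramp <- matrix(rep(seq(0, 8, length.out = n), each = n), n, n)
  m <- matrix(TRUE, n, n)
  wrapped <- wrap_period(ramp, 10)
  fld <- make_field(array(wrapped, c(n, n, 1)), masks = array(m, c(n, n, 1)))
  un <- unwrap_series(fld)
  # equal to the truth up to a global period constant
  d <- un$ux[, , 1] - ramp
  off <- stats::median(d)
  expect_equal(off, round(off / 10) * 10, tolerance = 1e-9)
  expect_lt(sqrt(mean((d - off)^2)), 0.1)
  # input without wraps is returned unchanged
  small <- make_field(array(ramp / 4, c(n, n, 1)),
                      masks = array(m, c(n, n, 1)))
  un2 <- unwrap_series(small)
  expect_equal(un2$ux[, , 1], ramp / 4, tolerance = 1e-9)
  # adding one full period everywhere shifts the output by one period
  shifted <- make_field(array(wrap_period(ramp + 10, 10), c(n, n, 1)),
                        masks = array(m, c(n, n, 1)))
  un3 <- unwrap_series(shifted)
  expect_lt(sqrt(mean((un3$ux[, , 1] - un$ux[, , 1] -
                         round(mean(un3$ux[, , 1] - un$ux[, , 1]) / 10) * 10)^2)),
            0.1)
})

test_that("temporal unwrapping follows motion across several periods", {
  n <- 16; nt <- 12
  m <- array(TRUE, c(n, n, nt))
  truth <- array(0, c(n, n, nt))
  for (f in seq_len(nt)) truth[, , f] <- (f - 1) * 2.2   # 0 .. 24.2 mm
  fld <- make_field(wrap_period(truth, 10), masks = m)
  un <- unwrap_series(fld)
  expect_lt(max(abs(un$ux - truth)), 1e-9)
})

test_that("the regularized grid fit interpolates at k -> 0 and flattens at k -> 1", {
  set.seed(4)
  nr <- 12; nc <- 12
  idx <- seq_len(nr * nc)
  vals <- rnorm(nr * nc)
  # noise-free samples on every node, negligible smoothing: interpolation
  sol <- densesim:::gridfit_solve(idx, vals, nr, nc, k = 1e-12)
  expect_lt(max(abs(sol[, 1] - vals)), 1e-8)
  # k -> 1 on noisy constant data approaches the constant
  sol1 <- densesim:::gridfit_solve(idx, 5 + rnorm(nr * nc, sd = 0.5),
                                   nr, nc, k = 1 - 1e-9)
  expect_lt(stats::sd(sol1[, 1]), 0.5)
  expect_equal(mean(sol1[, 1]), 5, tolerance = 0.2)
  # k = 0 with unconstrained nodes warns and falls back to a ridge
  expect_warning(
    densesim:::gridfit_solve(idx[1:100], vals[1:100], nr, nc, k = 0),
    "ridge")
})

test_that("sparse solution equals a dense direct solve and is a strict optimum", {
  set.seed(8)
  nr <- 10; nc <- 10
  m <- matrix(FALSE, nr, nc); m[3:8, 2:9] <- TRUE
  idx <- which(m)
  vals <- rnorm(length(idx))
  k <- 0.7; ls <- 0.1
  sol <- densesim:::gridfit_solve(idx, vals, nr, nc, k, lambda_scale = ls)
  # dense reference solve of the same quadratic objective
  A <- matrix(0, length(idx), nr * nc)
  A[cbind(seq_along(idx), idx)] <- 1
  L <- as.matrix(densesim:::grid_laplacian(nr, nc))
  lambda <- k / (1 - k) * ls
  Md <- crossprod(A) + lambda * crossprod(L)
  Md <- Md + (1e-10 * max(diag(Md)) + 1e-12) * diag(nr * nc)
  dense <- solve(Md, crossprod(A, vals))
  expect_lt(max(abs(sol[, 1] - dense)), 1e-6)
  # perturbing the solution increases the objective
  obj <- function(x) sum((A %*% x - vals)^2) + lambda * sum((L %*% x)^2)
  o0 <- obj(dense)
  set.seed(9)
  for (r in 1:10) {
    d <- rnorm(length(dense)); d <- d / sqrt(sum(d^2)) * 1e-3
    expect_gt(obj(dense + d), o0)
  }
})

test_that("temporal polynomial fitting reproduces polynomials and denoises", {
  nt <- 40
  times <- seq(22.5, by = 30, length.out = nt)
  tt <- (times - mean(times)) / 500
  poly_traj <- 3 + 0.5 * tt - 2 * tt^3 + tt^7
  traj <- array(0, c(2, 2, nt))
  traj[1, 1, ] <- poly_traj
  traj[2, 1, ] <- 1
  sm <- temporal_fit(traj, times, order = 10)
  expect_lt(max(abs(sm[1, 1, ] - poly_traj)), 1e-9)
  expect_lt(max(abs(sm[2, 1, ] - 1)), 1e-9)
  # white-noise perturbed sinusoid: residual variance shrinks
  set.seed(2)
  clean <- sin(2 * pi * times / max(times))
  noisy <- clean + rnorm(nt, sd = 0.2)
  traj[1, 2, ] <- noisy
  sm <- temporal_fit(traj, times, order = 10)
  expect_lt(mean((sm[1, 2, ] - clean)^2), mean((noisy - clean)^2))
  # too few frames: order reduced with a warning
  expect_warning(temporal_fit(traj[, , 1:8, drop = FALSE], times[1:8],
                              order = 10),
                 "reduced")
})

test_that("strain from trajectories shares the ground-truth operator", {
  fx <- fixture_annulus()
  lmap <- fx$labelmap; g <- fx$geometry
  n_img <- 64; fov <- 192
  xs <- pixel_centers(n_img, fov / n_img)
  X <- matrix(xs, n_img, n_img, byrow = TRUE)
  Y <- matrix(xs, n_img, n_img)
  lab <- densesim:::bilinear_nearest_label(lmap, cbind(as.vector(X), as.vector(Y)))
  pix <- which(matrix(lab == 1, n_img, n_img))
  ref <- cbind(as.vector(X)[pix], as.vector(Y)[pix])
  # uniform scaling trajectory: closed-form strain
  traj <- array(0, c(nrow(ref), 2, 2))
  traj[, , 2] <- sweep(ref, 2, g$center) * (0.8 - 1)
  st <- strain_from_trajectories(traj, ref, pix, c(0, 300), g, n_img, fov)
  expect_lt(max(abs(st$err[[2]] - (-0.18)), na.rm = TRUE), 1e-9)
  expect_lt(max(abs(st$ecc[[2]] - (-0.18)), na.rm = TRUE), 1e-9)
  # ground-truth trajectories give identically zero signed error
  p <- motion_params(rr_interval = 900, peak_rotation = 0.2)
  for (f in 1:2) {
    t <- c(0, 300)[f]
    traj[, , f] <- densesim:::deform_positions(ref, t, p, g) - ref
  }
  st <- strain_from_trajectories(traj, ref, pix, c(0, 300), g, n_img, fov)
  fld <- generate_displacement_field(lmap, g, p, c(0, 300))
  truth <- green_strain(fld, geometry = g)
  pe <- pixel_signed_errors(truth, st, 2, 2)
  gl <- pe$segment == "global"
  # same operator on the same motion; residual is only the resolution gap
  expect_lt(max(abs(pe$ase[gl])), 0.02)
})

test_that("noise-free pipeline recovers end-systolic strain within tight bounds", {
  fx <- fixture_cartesian_series(seed = 3, Nf = 90, rot = 0.2)
  truth <- green_strain(
    generate_displacement_field(fx$labelmap, fx$geometry, fx$params,
                                fx$series$frame_times),
    geometry = fx$geometry)
  est <- evaluate_strain(fx$series, fx$labelmap, fx$geometry, k = 0.1)
  es <- fx$series$es_index
  pe <- pixel_signed_errors(truth, est, es, es)
  ecc_g <- pe$component == "ecc" & pe$segment == "global"
  expect_lt(abs(pe$ase[ecc_g]), 0.02)
  err_g <- pe$component == "err" & pe$segment == "global"
  expect_lt(abs(pe$ase[err_g]), 0.03)
})

test_that("estimated transmural Ecc profile matches the truth on noise-free data", {
  fx <- fixture_cartesian_series(seed = 3, Nf = 90, rot = 0.2)
  truth <- green_strain(
    generate_displacement_field(fx$labelmap, fx$geometry, fx$params,
                                fx$series$frame_times),
    geometry = fx$geometry)
  est <- evaluate_strain(fx$series, fx$labelmap, fx$geometry, k = 0.1)
  es <- fx$series$es_index
  for (tert in 1:3) {
    lo <- (tert - 1) / 3; hi <- tert / 3
    tv <- truth$ecc[[es]][!is.na(truth$transmural) &
                            truth$transmural >= lo & truth$transmural < hi]
    ev <- est$ecc[[es]][!is.na(est$transmural) &
                          est$transmural >= lo & est$transmural < hi]
    expect_lt(abs(mean(tv, na.rm = TRUE) - mean(ev, na.rm = TRUE)), 0.02)
  }
})
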