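test_that("sampled motion parameters respect their configured ranges", {
  set.seed(11)
  for (i in 1:25) {
    p <- sample_motion_parameters()
    expect_gte(p$rr_interval, 825); expect_lte(p$rr_interval, 1200)
    expect_gte(p$peak_rotation, -0.5); expect_lte(p$peak_rotation, 0.5)
    expect_gt(p$es_fraction, 0); expect_lt(p$es_fraction, 1)
  }
  # collapsed ranges reproduce exact values
  degen <- lapply(default_motion_ranges(), function(r) rep(mean(r), 2))
  p <- sample_motion_parameters(degen)
  expect_equal(p$rr_interval, mean(c(825, 1200)))
  expect_equal(p$peak_rotation, 0)
  # inverted range rejected
  expect_error(
    sample_motion_parameters(list(rr_interval = c(1200, 825))),
    class = "densesim_config_error")
})

test_that("temporal activation anchors ED and ES and is systole-weighted", {
  p <- motion_params(rr_interval = 1000, es_fraction = 0.35)
  t_es <- 350
  expect_equal(temporal_activation(0, p), 0)
  expect_equal(temporal_activation(t_es, p), 1)
  # strictly increasing over systole, decreasing after
  ts <- seq(0, t_es, by = 5)
  expect_true(all(diff(temporal_activation(ts, p)) > 0))
  td <- seq(t_es, 1000, by = 5)
  expect_true(all(diff(temporal_activation(td, p)) < 0))
  # early-systolic rate exceeds late-systolic rate (finite differences)
  h <- 0.5
  d1 <- diff(temporal_activation(0.25 * t_es + c(0, h), p)) / h
  d2 <- diff(temporal_activation(0.75 * t_es + c(0, h), p)) / h
  expect_gt(d1, d2)
  expect_error(temporal_activation(-1, p), class = "densesim_domain_error")
  expect_error(temporal_activation(1001, p), class = "densesim_domain_error")
})

test_that("zero-amplitude deformation is the identity and pure rotation an isometry", {
  fx <- fixture_annulus()
  p0 <- motion_params(peak_err_scale = 0, peak_ecc_scale = 0,
                      peak_rotation = 0, transmural_err_gradient = 0)
  fld <- generate_displacement_field(fx$labelmap, fx$geometry, p0,
                                     c(0, 200, 500))
  expect_equal(max(abs(fld$displacements)), 0)

  prot <- motion_params(peak_err_scale = 0, peak_ecc_scale = 0,
                        peak_rotation = 0.4, transmural_err_gradient = 0)
  fld <- generate_displacement_field(fx$labelmap, fx$geometry, prot,
                                     c(0, 350))
  ref <- fld$ref_positions
  def <- ref + fld$displacements[, , 2]
  r0 <- sqrt(rowSums(sweep(ref, 2, fx$geometry$center)^2))
  r1 <- sqrt(rowSums(sweep(def, 2, fx$geometry$center)^2))
  expect_lt(max(abs(r1 - r0)), 1e-9)
})

test_that("displacements vanish exactly at t = 0 and the map never folds", {
  fx <- fixture_annulus()
  p <- motion_params(rr_interval = 1000, peak_rotation = 0.5)
  fld <- generate_displacement_field(fx$labelmap, fx$geometry, p,
                                     c(0, 100, 350, 700))
  expect_identical(max(abs(fld$displacements[, , 1])), 0)
  for (f in 2:4) {
    def <- fld$ref_positions + fld$displacements[, , f]
    expect_true(all(is.finite(def)))
  }
  # folding parameterization rejected at runtime (constructor bypassed:
  # its range checks make the polynomial family fold-free)
  pbad <- motion_params(peak_err_scale = 0.45)
  pbad$transmural_err_gradient <- 3
  suppressWarnings(expect_error(
    generate_displacement_field(fx$labelmap, fx$geometry, pbad, c(0, 350)),
    class = "densesim_parameter_error"))
})

test_that("incompressible parameterization keeps the Jacobian at unity", {
  fx <- fixture_annulus()
  p <- motion_params(peak_ecc_scale = -0.18, incompressible = TRUE)
  fld <- generate_displacement_field(fx$labelmap, fx$geometry, p, c(0, 350))
  # finite-difference Jacobian at ES over a probe grid
  h <- 1e-4
  probe <- fld$ref_positions[seq(1, nrow(fld$ref_positions), by = 23), ]
  J <- vapply(seq_len(nrow(probe)), function(i) {
    x <- probe[i, ]
    fx_ <- function(q) deform_positions(matrix(q, 1), 350, p, fx$geometry)
    d1 <- (fx_(x + c(h, 0)) - fx_(x - c(h, 0))) / (2 * h)
    d2 <- (fx_(x + c(0, h)) - fx_(x - c(0, h))) / (2 * h)
    d1[1] * d2[2] - d1[2] * d2[1]
  }, numeric(1))
  expect_true(all(abs(J - 1) < 0.02))
})

test_that("green strain reproduces closed forms: scaling, rotation, incompressible annulus", {
  fx <- fixture_annulus()
  p0 <- motion_params(peak_err_scale = 0, peak_ecc_scale = 0,
                      transmural_err_gradient = 0)
  fld <- generate_displacement_field(fx$labelmap, fx$geometry, p0, c(0, 350))
  # uniform scaling by 0.8 about the center
  fld$displacements[, , 2] <-
    sweep(fld$ref_positions, 2, fx$geometry$center) * (0.8 - 1)
  st <- green_strain(fld)
  expect_lt(max(abs(st$err[[2]] - (-0.18)), na.rm = TRUE), 1e-9)
  expect_lt(max(abs(st$ecc[[2]] - (-0.18)), na.rm = TRUE), 1e-9)

  # rigid rotation by 0.4 rad leaves Green strain at zero
  th <- 0.4
  rel <- sweep(fld$ref_positions, 2, fx$geometry$center)
  rot <- cbind(rel[, 1] * cos(th) - rel[, 2] * sin(th),
               rel[, 1] * sin(th) + rel[, 2] * cos(th))
  fld$displacements[, , 2] <- rot - rel
  st <- green_strain(fld)
  expect_lt(max(abs(st$err[[2]]), na.rm = TRUE), 1e-9)
  expect_lt(max(abs(st$ecc[[2]]), na.rm = TRUE), 1e-9)

  # strain at t = 0 is zero to machine precision
  expect_lt(max(abs(st$err[[1]]), na.rm = TRUE), 1e-12)

  # incompressible annulus closed form at the endocardium
  orc <- incompressible_oracle()
  lm <- oracle_annulus(0.75)
  g <- polar_geometry(lm)
  fld <- generate_displacement_field(lm, g, orc$params, c(0, 350))
  st <- green_strain(fld, geometry = g)
  n <- nrow(lm$labels)
  xs <- pixel_centers(n, 0.75)
  r <- sqrt(outer(xs^2, xs^2, "+"))
  ring <- st$valid[[2]] & r > 30 + 0.8 & r < 31.5
  expect_gt(sum(ring), 50)
  expect_lt(max(abs(st$err[[2]][ring] - orc$err(r[ring])) / orc$err(r[ring])),
            0.01)
  expect_lt(max(abs(st$ecc[[2]][ring] - orc$ecc(r[ring]))), 0.01 * 0.28125)
  expect_equal(orc$ecc(30), -0.18)
  expect_equal(orc$err(30), 0.28125)
})

test_that("projected strains match the analytic polar deformation gradient under twist", {
  lm <- oracle_annulus(0.75)
  g <- polar_geometry(lm)
  p <- motion_params(peak_rotation = 0.4, twist_falloff = 0.5,
                     peak_err_scale = 0.3, peak_ecc_scale = -0.15,
                     transmural_err_gradient = 0.6)
  fld <- generate_displacement_field(lm, g, p, c(0, 350))
  st <- green_strain(fld, geometry = g)
  # analytic strain: F = [[lam_r, 0], [r' phi', lam_c]] in the polar frame
  a <- temporal_activation(350, p)
  pr <- densesim:::radial_profile(p, g)
  n <- nrow(lm$labels)
  xs <- pixel_centers(n, lm$pixel_size)
  r <- sqrt(outer(xs^2, xs^2, "+"))
  rho <- r - pr$r_endo
  f <- pr$c0 + pr$c1 * rho + pr$c2 * rho^2
  lam_r <- 1 - a * (pr$c1 + 2 * pr$c2 * rho)
  r_new <- r - a * f
  lam_c <- r_new / r
  w <- g$r_epi - g$r_endo
  phi_p <- a * p$peak_rotation * (-p$twist_falloff / w)
  err_an <- (lam_r^2 + (r_new * phi_p)^2 - 1) / 2
  ecc_an <- (lam_c^2 - 1) / 2
  ring <- st$valid[[2]] & r > g$r_endo + 1 & r < g$r_epi - 1
  expect_lt(max(abs(st$err[[2]][ring] - err_an[ring])), 0.005)
  expect_lt(max(abs(st$ecc[[2]][ring] - ecc_an[ring])), 0.005)
})
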