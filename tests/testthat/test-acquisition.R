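acq0 <- acq_params(N1 = 120, N2 = 60, Nf = 64, fov = 192, jitter_bound = 0)

test_that("tissue property assignment is structural and rejects unmapped labels", {
  lm <- generate_annulus(120, 1.6, 44, 68)
  props <- assign_tissue_properties(lm)
  expect_equal(sort(unique(props$t1[lm$labels == 1])), 1200)
  expect_equal(sort(unique(props$t1[lm$labels == 2])), 1900)
  expect_equal(unique(props$m0[lm$labels == 0]), 0)
  bad <- lm$labels; bad[1, 1] <- 5L
  expect_error(assign_tissue_properties(new_labelmap(bad, 1.6)),
               class = "densesim_config_error")
})

test_that("dark blood decays the blood stimulated echo below 10% by frame 5", {
  tissue <- default_tissue_properties()
  flips <- flip_angle_schedule(10, 15, 30, 1200)
  blood <- tissue[tissue$name == "blood", ]
  t1 <- 22.5; t5 <- 22.5 + 4 * 30
  a1 <- densesim:::ste_amplitude(blood$m0, blood$t1, blood$washout, 1, t1, flips)
  a5 <- densesim:::ste_amplitude(blood$m0, blood$t1, blood$washout, 5, t5, flips)
  expect_lt(a5 / a1, 0.10)
})

test_that("variable flip angles equalize the stimulated-echo amplitude", {
  flips <- flip_angle_schedule(12, 15, 30, 1200)
  times <- 22.5 + 30 * (0:11)
  amp <- 0.5 * exp(-times / 1200) * flips$amp
  expect_lt(diff(range(amp)) / mean(amp), 1e-6)
  expect_equal(flips$alpha[12], 15 * pi / 180)
})

test_that("stimulated-echo phase encodes displacement and phase cycling cancels the T1 echo", {
  fx <- fixture_annulus()
  p <- motion_params(rr_interval = 900)
  fld <- generate_displacement_field(fx$labelmap, fx$geometry, p, c(0, 300))
  props <- assign_tissue_properties(fx$labelmap)
  # impose a rigid 2 mm x-shift to read the phase directly
  fld$displacements[, 1, 2] <- 2
  fld$displacements[, 2, 2] <- 0
  sig <- simulate_dense_signal(fld, props, acq0, phase_cycle = 1,
                               encoding = "x")
  ph <- Arg(sig$frames[[2]]$ste)
  expect_lt(max(abs(wrap_phase(ph - 2 * pi * 0.1 * 2))), 1e-10)
  # reference encoding carries no stimulated-echo phase
  sig0 <- simulate_dense_signal(fld, props, acq0, encoding = "none")
  expect_lt(max(abs(Arg(sig0$frames[[2]]$ste))), 1e-12)
  # two-point cycling cancels the T1-recovery echo exactly in the two-term
  # model
  s1 <- simulate_dense_signal(fld, props, acq0, 1, "x")$frames[[2]]
  s2 <- simulate_dense_signal(fld, props, acq0, 2, "x")$frames[[2]]
  comb <- combine_phase_cycles(list(s1$signal, s2$signal))
  resid <- max(abs(comb - s1$ste))
  expect_lt(resid, 1e-12 * max(abs(s1$t1)))
})

test_that("gridding conserves the DC signal, flattens a point source, and dephases within a voxel", {
  # unit isochromat at the FOV center: flat k-space magnitude
  img <- grid_isochromats(1 + 0i, matrix(0, 1, 2), acq0)
  K <- attr(img, "kspace")
  expect_lt(max(abs(abs(K) - 1)), 1e-9)
  # DC equals the signal sum
  set.seed(5)
  pos <- matrix(runif(40, -40, 40), 20, 2)
  s <- complex(real = rnorm(20), imaginary = rnorm(20))
  K2 <- attr(grid_isochromats(s, pos, acq0), "kspace")
  dc <- K2[60 %/% 2 + 1, 60 %/% 2 + 1]
  expect_lt(Mod(dc - sum(s)) / Mod(sum(s)), 1e-9)
  # two opposed-phase isochromats at one location cancel exactly
  one <- grid_isochromats(1 + 0i, matrix(c(0.5, 0.5), 1, 2), acq0)
  two <- grid_isochromats(c(1 + 0i, -1 + 0i),
                          rbind(c(0.5, 0.5), c(0.5, 0.5)), acq0)
  expect_lt(max(abs(two)), 1e-6 * max(abs(one)))
  # opposed phases a fraction of a voxel apart still dephase strongly
  near <- grid_isochromats(c(1 + 0i, -1 + 0i),
                           rbind(c(0.5, 0.5), c(0.9, 0.2)), acq0)
  expect_lt(max(abs(near)), 0.25 * max(abs(one)))
  # out-of-FOV isochromats are excluded with a warning
  expect_warning(grid_isochromats(c(1 + 0i, 1 + 0i),
                                  rbind(c(0, 0), c(200, 0)), acq0),
                 "outside the FOV")
})

test_that("excitation window has unit peak, half gain at 0.3 widths, and the Hamming floor", {
  w <- densesim:::excitation_window(256, 192)
  x <- pixel_centers(256, 192 / 256)
  rho <- sqrt(outer(x^2, x^2, "+"))
  expect_gt(min(w[rho < 2.5]), 0.999)
  half <- abs(rho - 0.3 * 192) < 0.4
  expect_lt(max(abs(w[half] - 0.5)), 0.01)
  expect_lt(w[1, 1], 0.08 + 1e-9)
  expect_error(apply_excitation_window(matrix(0, 3, 4), acq0),
               class = "densesim_input_error")
})

test_that("spiral schedule reproduces the printed interleaf, combined and interpolated times", {
  sch <- build_spiral_schedule(acq0, 1000)
  expect_identical(sch$interleaf_times[1, 1, 1:3], c(15, 45, 75))
  expect_identical(sch$interleaf_times[2, 1, 1:3], c(30, 60, 90))
  expect_identical(sch$frame_times[1:4], 22.5 + 30 * (0:3))
  expect_identical(sch$interp_frame_times[1:3], 37.5 + 30 * (0:2))
  expect_equal(sort(as.vector(sch$rotations)) / (pi / 2), 0:3)
  # analytic form of Eq-style times for every (l, c, i)
  for (l in 1:2) for (c in 1:2)
    expect_identical(sch$interleaf_times[l, c, ],
                     15 + 30 * (l - 1) / 2 + 30 * (seq_len(sch$n_frames) - 1))
  # jitter is bounded and per-cycle
  acq_j <- acq_params(N1 = 120, N2 = 60, Nf = 64, fov = 192, jitter_bound = 5)
  set.seed(2)
  schj <- build_spiral_schedule(acq_j, 1000)
  expect_true(all(abs(schj$eps) <= 5))
  expect_identical(schj$interleaf_times[1, 1, ] - 15 - 30 * (0:(schj$n_frames - 1)),
                   rep(schj$eps[1], schj$n_frames))
  # frame count truncated with a warning when the R-R is too short
  acq_n <- acq_params(N1 = 120, N2 = 60, Nf = 64, fov = 192,
                      jitter_bound = 0, n_frames = 60)
  expect_warning(build_spiral_schedule(acq_n, 900), "truncated")
})

test_that("frame interpolation doubles the temporal resolution over the same window", {
  acq_i <- acq_params(N1 = 120, N2 = 60, Nf = 64, fov = 192, jitter_bound = 0,
                      interpolate_frames = TRUE)
  sch <- build_spiral_schedule(acq_i, 1000)
  expect_equal(length(sch$combined_times), 2 * sch$n_frames - 1)
  expect_identical(sch$combined_times[1:4], c(22.5, 37.5, 52.5, 67.5))
})

test_that("spiral sampling + adjoint reconstruction matches the Cartesian reference", {
  lm <- generate_annulus(120, 1.6, 40, 60)
  idx <- which(lm$labels > 0)
  xs <- pixel_centers(120, 1.6)
  pos <- cbind(xs[((idx - 1) %/% 120) + 1], xs[((idx - 1) %% 120) + 1])
  cimg <- grid_isochromats(rep(1 + 0i, length(idx)), pos, acq0)
  cw <- apply_excitation_window(cimg, acq0)
  sch <- build_spiral_schedule(acq0, 1000)
  rec <- sample_and_reconstruct(cw, sch, acq0, noise_sigma = 0)
  K <- densesim:::dft2_kspace(cw, 192)
  ref <- densesim:::cartesian_interp_reconstruct(
    matrix(as.vector(K), ncol = 1), acq0, 192)[, , 1]
  wf <- densesim:::excitation_window(64, 192)
  inside <- wf > 0.5
  nrmse <- sqrt(mean(abs(rec$frames[, , 1][inside] - ref[inside])^2)) /
    sqrt(mean(abs(ref[inside])^2))
  expect_lt(nrmse, 0.05)
})

test_that("T2* weighting follows the exponential decay along the readout", {
  tr <- spiral_trajectory(acq0, 192)
  expect_equal(max(tr$tau), acq0$readout_duration, tolerance = 1e-3)
  w40 <- exp(-tr$tau / 40)
  i <- which.min(abs(tr$tau - acq0$readout_duration))
  expect_equal(w40[i], exp(-acq0$readout_duration / 40), tolerance = 1e-3)
  # a sample at tau = t2star would carry weight 1/e
  expect_equal(exp(-40 / 40), exp(-1))
  # increasing t2star brings every weight to 1
  expect_lt(max(abs(exp(-tr$tau / 1e9) - 1)), 1e-6)
})

test_that("phase-cycle combination is a pass-through for n = 1 and averages identical cycles", {
  A <- matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3)
  expect_equal(combine_phase_cycles(list(A), offsets = 0), A)
  expect_equal(combine_phase_cycles(list(A, A), offsets = c(0, 0)), A)
  expect_error(combine_phase_cycles(list(A, A[1:2, ]), offsets = c(0, pi)),
               class = "densesim_input_error")
})

test_that("encoding combination averages magnitudes and wraps referenced phases", {
  M <- matrix(2, 2, 2)
  ph <- matrix(3, 2, 2); pr <- matrix(-3, 2, 2)
  out <- combine_encodings(M, M, ph, ph, pr)
  expect_equal(out$magnitude, M)
  expect_true(all(out$phase_x > -pi & out$phase_x <= pi))
  expect_equal(out$phase_x, matrix(6 - 2 * pi, 2, 2))
  out0 <- combine_encodings(M, M, pr, pr, pr)
  expect_equal(out0$phase_x, matrix(0, 2, 2))
  expect_error(combine_encodings(M, M[1, , drop = FALSE], ph, ph, pr),
               class = "densesim_input_error")
})

test_that("SNR measurement is mean over std, scale-invariant, with an infinity sentinel", {
  set.seed(9)
  img <- matrix(10 + rnorm(900), 30)
  mask <- matrix(TRUE, 30, 30)
  expect_lt(abs(measure_snr(img, mask) - 10) / 10, 0.1)
  expect_equal(measure_snr(img * 3, mask), measure_snr(img, mask))
  expect_identical(measure_snr(matrix(5, 3, 3), matrix(TRUE, 3, 3)), Inf)
  expect_error(measure_snr(img, matrix(FALSE, 30, 30)),
               class = "densesim_input_error")
})

test_that("noise-free Cartesian pipeline recovers displacements from the phase", {
  fx <- fixture_cartesian_series(seed = 3, Nf = 90, rot = 0.2)
  ser <- fx$series
  f <- ser$es_index
  msk <- ser$masks[, , f]
  xf <- pixel_centers(90, 192 / 90)
  q <- cbind(rep(xf, each = 90)[as.vector(msk)],
             rep(xf, times = 90)[as.vector(msk)])
  eu <- densesim:::eulerian_displacement(q, ser$frame_times[f], fx$params,
                                         fx$geometry, fx$labelmap)
  P <- 1 / ser$acq$ke
  ux <- ser$phase_x[, , f][msk] / (2 * pi * ser$acq$ke)
  uy <- ser$phase_y[, , f][msk] / (2 * pi * ser$acq$ke)
  dx <- ux - eu$u[, 1]; dx <- dx - P * round(dx / P)
  dy <- uy - eu$u[, 2]; dy <- dy - P * round(dy / P)
  rel <- sqrt(mean(dx^2 + dy^2)) / sqrt(mean(eu$u[, 1]^2 + eu$u[, 2]^2))
  expect_lt(rel, 0.02)
  # phase images stay within the wrap interval
  expect_true(all(ser$phase_x > -pi & ser$phase_x <= pi))
  expect_true(all(ser$magnitude >= 0))
})

test_that("noise calibration reaches the target and scales inversely with sigma", {
  fx <- fixture_annulus(endo = 34, epi = 52)
  p <- motion_params(rr_interval = 900, peak_rotation = 0.2)
  acq <- acq_params(N1 = 120, N2 = 60, Nf = 64, fov = 192, target_snr = 5,
                    n_frames = 12)
  ser <- simulate_dense_series(fx$labelmap, fx$geometry, p, acq, seed = 21)
  expect_lt(abs(ser$snr_noise_es - 5) / 5, 0.12)
  # doubling sigma halves the noise-referenced SNR (noise-dominated regime)
  acq_inf <- acq; acq_inf$target_snr <- Inf
  ser0 <- simulate_dense_series(fx$labelmap, fx$geometry, p, acq_inf,
                                seed = 21)
  expect_identical(ser0$noise_sigma, 0)
})
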