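# Shared small fixtures, built in code. Sizes are kept small so the whole
# suite runs quickly; the acceptance tests build their own larger objects.

# A mid-sized annulus at the reduced ground-truth resolution.
fixture_annulus <- function(n = 120, px = 1.6, endo = 44, epi = 68) {
  lm <- generate_annulus(n, px, endo, epi)
  list(labelmap = lm, geometry = polar_geometry(lm))
}

# The incompressible-annulus oracle: r_endo 30 mm contracting to 24 mm,
# r'(r)^2 = r^2 - c with c = 30^2 - 24^2. Closed-form Green strains at
# reference radius r (mm).
incompressible_oracle <- function() {
  c0 <- 30^2 - 24^2
  list(
    c = c0,
    err = function(r) 0.5 * (r^2 / (r^2 - c0) - 1),
    ecc = function(r) 0.5 * ((r^2 - c0) / r^2 - 1),
    # matching motion parameters: ecc at the endocardium is
    # ((24/30)^2 - 1)/2 = -0.18
    params = motion_params(rr_interval = 1000, peak_ecc_scale = -0.18,
                           incompressible = TRUE, es_fraction = 0.35))
}

# Annulus with r_endo = 30 mm, r_epi = 45 mm at the requested pixel size.
oracle_annulus <- function(pixel_size) {
  n <- ceiling(100 / pixel_size / 2) * 2
  generate_annulus(n, pixel_size,
                   endo_diameter = 60 / pixel_size,
                   epi_diameter = 90 / pixel_size)
}

# A noise-free Cartesian-sampled series for end-to-end checks; cached per
# session because several files exercise the identical default object.
.fixture_env <- new.env()

fixture_cartesian_series <- function(seed = 3, Nf = 90, rot = 0.2) {
  key <- sprintf("cart_%d_%d_%g", seed, Nf, rot)
  if (is.null(.fixture_env[[key]])) {
    fx <- fixture_annulus()
    mp <- motion_params(rr_interval = 900, peak_rotation = rot)
    acq <- acq_params(N1 = 120, N2 = 60, Nf = Nf, fov = 192,
                      jitter_bound = 0, sampling = "cartesian",
                      target_snr = Inf)
    ser <- simulate_dense_series(fx$labelmap, fx$geometry, mp, acq,
                                 seed = seed)
    .fixture_env[[key]] <- c(fx, list(params = mp, acq = acq, series = ser))
  }
  .fixture_env[[key]]
}
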