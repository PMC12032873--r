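# Motion module: smooth contractile 2D deformations of the myocardium with a
# configurable transmural radial-strain gradient, 2D twist and
# systole-weighted temporal dynamics, plus the ground-truth Green-Lagrange
# strain computed by central differences on the deformed pixel positions.
#
# The deformation is defined in polar coordinates around the LV center:
#   r'(r, t)     = r - a(t) * f(r)         (radial contraction)
#   theta'(r, t) = theta + a(t) * rot * g(r)   (twist)
# with a(t) the temporal activation in [0, 1] and f a polynomial of order <= 2
# in the transmural offset rho = r - r_endo. f is parameterized by the peak
# endocardial radial strain, the peak endocardial circumferential strain and
# a transmural gradient knob (0 = transmurally constant radial strain,
# > 0 = endocardium-weighted, approximately linear across the wall). An exact
# incompressible variant r'^2 = r^2 - c(t) is also available.

#' Motion model parameters
#'
#' @param rr_interval cardiac cycle length, ms
#' @param peak_rotation peak-systolic rotation (2D twist), rad
#' @param transmural_err_gradient 0 gives transmurally constant radial
#'   strain; positive values weight the radial strain toward the
#'   endocardium approximately linearly (1 means zero radial strain at the
#'   epicardium)
#' @param peak_err_scale peak (end-systolic) endocardial radial Green strain
#' @param peak_ecc_scale peak endocardial circumferential Green strain
#'   (negative in systole)
#' @param es_fraction fraction of the R-R interval at end-systole
#' @param coverage_start prospective-trigger offset, ms: ground-truth frames
#'   are only generated from this time on
#' @param activation_skew exponent (< 1) skewing the activation curve so the
#'   early-systolic strain rate exceeds the late-systolic rate
#' @param twist_falloff linear transmural falloff of the twist profile
#'   (0 = solid rotation)
#' @param incompressible if TRUE use the exact area-preserving radial map
#'   r'^2 = r^2 - c(t) (Jacobian 1) instead of the polynomial profile
#' @return an object of class `dense_motion_params`
#' @export
motion_params <- function(rr_interval = 1000,
                          peak_rotation = 0,
                          transmural_err_gradient = 0.5,
                          peak_err_scale = 0.35,
                          peak_ecc_scale = -0.18,
                          es_fraction = 0.35,
                          coverage_start = 0,
                          activation_skew = 0.8,
                          twist_falloff = 0,
                          incompressible = FALSE) {
  if (rr_interval <= 0) err_config("rr_interval must be positive")
  if (es_fraction <= 0 || es_fraction >= 1)
    err_config("es_fraction must lie strictly inside (0, 1)")
  if (1 + 2 * peak_ecc_scale <= 0 || 1 + 2 * peak_err_scale <= 0 ||
      1 + 2 * peak_err_scale * (1 - transmural_err_gradient) <= 0)
    err_config("strain amplitudes must keep 1 + 2E positive")
  structure(
    list(rr_interval = rr_interval, peak_rotation = peak_rotation,
         transmural_err_gradient = transmural_err_gradient,
         peak_err_scale = peak_err_scale, peak_ecc_scale = peak_ecc_scale,
         es_fraction = es_fraction, coverage_start = coverage_start,
         activation_skew = activation_skew, twist_falloff = twist_falloff,
         incompressible = incompressible),
    class = "dense_motion_params")
}

#' Default cohort sampling ranges for the motion and acquisition parameters
#'
#' Each entry is a (min, max) interval sampled uniformly per case. The R-R
#' interval and peak rotation ranges are the study conditions (50-70 bpm,
#' twist up to half a radian); strain amplitudes and the transmural gradient
#' cover the span of healthy left-ventricular deformation.
#'
#' @return named list of ranges
#' @export
default_motion_ranges <- function() {
  list(rr_interval = c(825, 1200),
       peak_rotation = c(-0.5, 0.5),
       transmural_err_gradient = c(0, 0.8),
       peak_err_scale = c(0.25, 0.45),
       peak_ecc_scale = c(-0.22, -0.14),
       es_fraction = c(0.32, 0.38))
}

#' Sample motion parameters from configured ranges
#'
#' Draws each parameter independently and uniformly from its configured
#' (min, max) range; zero-width ranges yield exactly that value. Uses the
#' current RNG state, so results are reproducible under `set.seed()`.
#'
#' @param ranges named list of (min, max) ranges as in
#'   [default_motion_ranges()]; missing entries fall back to the defaults
#' @param ... fixed parameter overrides passed to [motion_params()]
#' @return a [motion_params()] object
#' @export
sample_motion_parameters <- function(ranges = default_motion_ranges(), ...) {
  defaults <- default_motion_ranges()
  ranges <- utils::modifyList(defaults, ranges)
  draw <- function(rg, name) {
    if (length(rg) != 2 || rg[1] > rg[2])
      err_config(sprintf("range for %s must be (min, max) with min <= max", name))
    if (rg[1] == rg[2]) rg[1] else stats::runif(1, rg[1], rg[2])
  }
  vals <- mapply(draw, ranges, names(ranges), SIMPLIFY = FALSE)
  do.call(motion_params, utils::modifyList(vals, list(...)))
}

#' Temporal activation curve
#'
#' Dimensionless activation in [0, 1]: 0 at end-diastole (t = 0), 1 at
#' end-systole, strictly increasing over systole and decreasing back over
#' diastole. The systolic branch is a raised cosine in the skewed phase
#' (t / t_ES)^q with q = `activation_skew` < 1, which makes the
#' early-systolic rate exceed the late-systolic rate, as observed in vivo.
#'
#' @param t time since the ECG R-wave, ms (vectorized)
#' @param params a [motion_params()] object
#' @return activation values in [0, 1]
#' @export
temporal_activation <- function(t, params) {
  rr <- params$rr_interval
  if (any(t < 0 | t > rr)) err_domain("t must lie within [0, rr_interval]")
  t_es <- params$es_fraction * rr
  q <- params$activation_skew
  a <- numeric(length(t))
  sys <- t <= t_es
  s <- t[sys] / t_es
  a[sys] <- 0.5 * (1 - cos(pi * s^q))
  u <- (t[!sys] - t_es) / (rr - t_es)
  a[!sys] <- 0.5 * (1 + cos(pi * u))
  a
}

# Radial contraction profile f(rho) (mm), its derivative, and twist profile.
radial_profile <- function(params, geometry) {
  r_endo <- geometry$r_endo
  w <- geometry$r_epi - geometry$r_endo
  lam_endo <- sqrt(1 + 2 * params$peak_err_scale)
  lam_epi <- sqrt(1 + 2 * params$peak_err_scale *
                    (1 - params$transmural_err_gradient))
  c0 <- r_endo * (1 - sqrt(1 + 2 * params$peak_ecc_scale))
  c1 <- 1 - lam_endo
  c2 <- (lam_endo - lam_epi) / (2 * w)
  list(c0 = c0, c1 = c1, c2 = c2, r_endo = r_endo, w = w)
}

# Map reference positions (mm, columns x/y) at time t. Returns deformed
# positions; core of the analytic motion model, shared by the ground-truth
# strain path and the acquisition module (which samples arbitrary jittered
# times).
deform_positions <- function(ref, t, params, geometry) {
  a <- temporal_activation(t, params)
  if (a == 0) return(ref)   # exact identity at end-diastole
  dx <- ref[, 1] - geometry$center[1]
  dy <- ref[, 2] - geometry$center[2]
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  if (params$incompressible) {
    c_max <- -2 * params$peak_ecc_scale * geometry$r_endo^2
    r2 <- r^2 - a * c_max
    # radii inside the deformed cavity (possible for off-myocardium query
    # points) are clamped; folding on the myocardium itself is guarded by
    # the Jacobian check in generate_displacement_field()
    r_new <- sqrt(pmax(r2, (1e-3 * geometry$r_endo)^2))
  } else {
    p <- radial_profile(params, geometry)
    rho <- r - p$r_endo
    f <- p$c0 + p$c1 * rho + p$c2 * rho^2
    r_new <- pmax(r - a * f, 1e-3 * geometry$r_endo)
  }
  w <- geometry$r_epi - geometry$r_endo
  g <- 1 - params$twist_falloff * (r - geometry$r_endo) / w
  theta_new <- theta + a * params$peak_rotation * g
  cbind(geometry$center[1] + r_new * cos(theta_new),
        geometry$center[2] + r_new * sin(theta_new))
}

# Analytic Jacobian determinant of the deformation map at reference radii r
# (twist with transmural falloff is a simple shear and does not change it).
deformation_jacobian <- function(r, t, params, geometry) {
  a <- temporal_activation(t, params)
  if (params$incompressible) return(rep(1, length(r)))
  p <- radial_profile(params, geometry)
  rho <- r - p$r_endo
  f <- p$c0 + p$c1 * rho + p$c2 * rho^2
  lam_r <- 1 - a * (p$c1 + 2 * p$c2 * rho)
  lam_c <- (r - a * f) / r
  lam_r * lam_c
}

#' Generate Lagrangian pixel trajectories for the myocardium
#'
#' Evaluates the analytic deformation at each requested frame time for every
#' myocardial pixel center of the label map. Displacements at t = 0 are
#' exactly zero; the map is checked for folding (positive Jacobian) at every
#' frame.
#'
#' @param labelmap a [new_labelmap()] object
#' @param geometry the matching [polar_geometry()] object
#' @param params a [motion_params()] object
#' @param frame_times frame times in ms, within `[coverage_start, rr_interval]`
#' @return an object of class `dense_motion` with fields `ref_positions`
#'   (n x 2, mm), `pixel_idx` (linear raster indices), `frame_times`,
#'   `displacements` (n x 2 x T, mm)
#' @export
generate_displacement_field <- function(labelmap, geometry, params,
                                        frame_times) {
  rr <- params$rr_interval
  if (any(frame_times < 0 | frame_times > rr))
    err_domain("frame_times must lie within [0, rr_interval]")
  if (any(frame_times < params$coverage_start))
    err_domain("frame_times must not precede coverage_start")
  if (is.unsorted(frame_times, strictly = TRUE))
    err_input("frame_times must be strictly increasing")
  n <- nrow(labelmap$labels)
  idx <- mask_indices(labelmap$labels == LABEL_MYOCARDIUM)
  xs <- pixel_centers(n, labelmap$pixel_size, labelmap$origin[1])
  ys <- pixel_centers(n, labelmap$pixel_size, labelmap$origin[2])
  col_i <- ((idx - 1) %/% n) + 1
  row_i <- ((idx - 1) %% n) + 1
  ref <- cbind(xs[col_i], ys[row_i])
  r <- sqrt((ref[, 1] - geometry$center[1])^2 +
              (ref[, 2] - geometry$center[2])^2)
  disp <- array(0, dim = c(length(idx), 2, length(frame_times)))
  for (f in seq_along(frame_times)) {
    t <- frame_times[f]
    jac <- deformation_jacobian(r, t, params, geometry)
    if (any(!is.finite(jac)) || min(jac) <= 0)
      err_parameter(sprintf("deformation folds (Jacobian <= 0) at t = %g ms", t))
    disp[, , f] <- deform_positions(ref, t, params, geometry) - ref
  }
  structure(
    list(ref_positions = ref, pixel_idx = idx, frame_times = frame_times,
         displacements = disp, params = params, geometry = geometry,
         n = n, pixel_size = labelmap$pixel_size, origin = labelmap$origin),
    class = "dense_motion")
}

#' @export
print.dense_motion <- function(x, ...) {
  cat(sprintf("<dense_motion> %d myocardial pixels, %d frames (%.1f..%.1f ms)\n",
              nrow(x$ref_positions), length(x$frame_times),
              min(x$frame_times), max(x$frame_times)))
  invisible(x)
}

# Shared central-difference Green-strain core. def_x/def_y are rasters of
# deformed x/y positions (NA outside the region), `valid` marks pixels
# carrying displacements. The deformation gradient F is estimated by central
# differences where both neighbors exist, one-sided at region edges; pixels
# with no valid neighbor along either axis are flagged invalid.
strain_from_deformed_rasters <- function(def_x, def_y, valid, spacing,
                                         geometry) {
  n_row <- nrow(def_x); n_col <- ncol(def_x)
  shift <- function(m, di, dj) {
    out <- matrix(NA_real_, n_row, n_col)
    ri <- seq_len(n_row); rj <- seq_len(n_col)
    si <- ri - di; sj <- rj - dj
    ok_i <- si >= 1 & si <= n_row; ok_j <- sj >= 1 & sj <= n_col
    out[ri[ok_i], rj[ok_j]] <- m[si[ok_i], sj[ok_j]]
    out
  }
  vnum <- valid * 1
  deriv <- function(m, axis) {
    if (axis == "x") { p <- shift(m, 0, -1); q <- shift(m, 0, 1)
      vp <- shift(vnum, 0, -1); vq <- shift(vnum, 0, 1)
    } else { p <- shift(m, -1, 0); q <- shift(m, 1, 0)
      vp <- shift(vnum, -1, 0); vq <- shift(vnum, 1, 0)
    }
    vp[is.na(vp)] <- 0; vq[is.na(vq)] <- 0
    both <- vp == 1 & vq == 1
    fwd <- vp == 1 & vq == 0
    bwd <- vq == 1 & vp == 0
    d <- matrix(NA_real_, n_row, n_col)
    d[both] <- (p[both] - q[both]) / (2 * spacing)
    d[fwd] <- (p[fwd] - m[fwd]) / spacing
    d[bwd] <- (m[bwd] - q[bwd]) / spacing
    list(d = d, ok = both | fwd | bwd)
  }
  gxx <- deriv(def_x, "x"); gxy <- deriv(def_x, "y")
  gyx <- deriv(def_y, "x"); gyy <- deriv(def_y, "y")
  ok <- valid & gxx$ok & gxy$ok & gyx$ok & gyy$ok
  Fxx <- gxx$d; Fxy <- gxy$d; Fyx <- gyx$d; Fyy <- gyy$d
  # E = (F^T F - I) / 2
  Exx <- (Fxx^2 + Fyx^2 - 1) / 2
  Eyy <- (Fxy^2 + Fyy^2 - 1) / 2
  Exy <- (Fxx * Fxy + Fyx * Fyy) / 2
  rx <- geometry$radial_x; ry <- geometry$radial_y
  cx <- geometry$circ_x; cy <- geometry$circ_y
  err <- rx^2 * Exx + 2 * rx * ry * Exy + ry^2 * Eyy
  ecc <- cx^2 * Exx + 2 * cx * cy * Exy + cy^2 * Eyy
  err[!ok] <- NA_real_; ecc[!ok] <- NA_real_
  Exx[!ok] <- NA_real_; Eyy[!ok] <- NA_real_; Exy[!ok] <- NA_real_
  list(err = err, ecc = ecc, Exx = Exx, Eyy = Eyy, Exy = Exy, valid = ok)
}

#' Ground-truth Green-Lagrange strain of a motion field
#'
#' Builds rasters of deformed pixel positions per frame, estimates the
#' deformation gradient by central differences (one-sided at myocardial
#' edges), forms E = (F'F - I)/2 and projects it onto the radial and
#' circumferential unit vectors at the end-diastolic pixel locations.
#'
#' @param field a [generate_displacement_field()] object
#' @param spacing raster spacing in mm (defaults to the field's pixel size)
#' @param geometry the [polar_geometry()] of the reference label map
#' @return an object of class `dense_strain`: lists of `err` / `ecc` rasters
#'   per frame, valid mask, frame times, transmural raster
#' @export
green_strain <- function(field, spacing = field$pixel_size,
                         geometry = field$geometry) {
  n <- field$n
  xs <- pixel_centers(n, field$pixel_size, field$origin[1])
  ys <- pixel_centers(n, field$pixel_size, field$origin[2])
  col_i <- ((field$pixel_idx - 1) %/% n) + 1
  row_i <- ((field$pixel_idx - 1) %% n) + 1
  valid <- matrix(FALSE, n, n); valid[field$pixel_idx] <- TRUE
  nt <- length(field$frame_times)
  err <- ecc <- vector("list", nt)
  valid_out <- vector("list", nt)
  for (f in seq_len(nt)) {
    def_x <- def_y <- matrix(NA_real_, n, n)
    def_x[field$pixel_idx] <- field$ref_positions[, 1] +
      field$displacements[, 1, f]
    def_y[field$pixel_idx] <- field$ref_positions[, 2] +
      field$displacements[, 2, f]
    st <- strain_from_deformed_rasters(def_x, def_y, valid, spacing, geometry)
    err[[f]] <- st$err; ecc[[f]] <- st$ecc; valid_out[[f]] <- st$valid
  }
  structure(
    list(err = err, ecc = ecc, valid = valid_out,
         frame_times = field$frame_times,
         transmural = geometry$transmural,
         pixel_size = field$pixel_size, n = n, origin = field$origin,
         geometry = geometry),
    class = "dense_strain")
}

#' @export
print.dense_strain <- function(x, ...) {
  cat(sprintf("<dense_strain> %d frames on %d x %d raster @ %.3g mm\n",
              length(x$frame_times), x$n, x$n, x$pixel_size))
  invisible(x)
}

# Eulerian (image-frame) displacement of the motion model at query positions:
# solves X + u(X, t) = x by fixed-point iteration on the analytic forward
# map. Returns the displacement u at each query position, and whether the
# material point ended inside the myocardium.
eulerian_displacement <- function(query, t, params, geometry, labelmap,
                                  iters = 12) {
  X <- query
  for (i in seq_len(iters)) {
    u <- deform_positions(X, t, params, geometry) - X
    X_new <- query - u
    if (max(abs(X_new - X)) < 1e-9) { X <- X_new; break }
    X <- X_new
  }
  u <- query - X
  lab <- bilinear_nearest_label(labelmap, X)
  list(u = u, ref = X, in_myo = lab == LABEL_MYOCARDIUM)
}

# Nearest-pixel label lookup at physical positions.
bilinear_nearest_label <- function(labelmap, pos) {
  n <- nrow(labelmap$labels)
  px <- labelmap$pixel_size
  i <- round((pos[, 2] - labelmap$origin[2]) / px + 0.5 + n / 2)
  j <- round((pos[, 1] - labelmap$origin[1]) / px + 0.5 + n / 2)
  ok <- i >= 1 & i <= n & j >= 1 & j <= n
  out <- rep(LABEL_BACKGROUND, nrow(pos))
  out[ok] <- labelmap$labels[cbind(i[ok], j[ok])]
  out
}

# Eulerian myocardial masks on an n_img grid at the given times.
eulerian_masks <- function(labelmap, geometry, params, times, n_img, fov) {
  px_img <- fov / n_img
  xs <- pixel_centers(n_img, px_img)
  query <- cbind(rep(xs, each = n_img), rep(xs, times = n_img))
  masks <- array(FALSE, dim = c(n_img, n_img, length(times)))
  for (f in seq_along(times)) {
    eu <- eulerian_displacement(query, times[f], params, geometry, labelmap)
    masks[, , f] <- matrix(eu$in_myo, n_img, n_img)
  }
  masks
}
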