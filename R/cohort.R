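# Cohort module: seeded virtual cohorts of annulus-based DENSE cases across
# SNR strata, and the evaluation statistics comparing recovered strain to
# the ground truth: pooled pixel signed errors (ASE +/- std) by
# regularization level, SNR stratum and transmural segment; transmural
# quadratic profiles; Bland-Altman analysis of global peak strain.

#' Cohort configuration
#'
#' Defaults emulate the published virtual-cohort conditions at a reduced
#' problem size: annulus-only anatomies with epicardial diameter 0.4-0.6 of
#' the matrix and endocardial diameter 0.5-0.8 of the epicardial, R-R
#' 825-1200 ms, peak rotation within +/-0.5 rad, and three end-systolic SNR
#' strata ([3.9, 6.1], [8.3, 11.5], [13.9, 17.7]) with equal case counts.
#'
#' @param n_cases number of cases (divisible by the number of strata)
#' @param snr_strata list of (low, high) target-SNR ranges
#' @param k_grid regularization levels evaluated downstream
#' @param N1,N2,Nf,pixel_size acquisition geometry (ground-truth raster,
#'   gridding raster, reconstruction raster, ground-truth pixel size mm)
#' @param epi_range_frac epicardial diameter range as a fraction of N1
#' @param endo_frac_range endocardial/epicardial diameter ratio range
#' @param motion_ranges parameter ranges as [default_motion_ranges()]
#' @param interpolate_frames acquisition frame interpolation flag
#' @param master_seed master RNG seed; each case derives a child seed
#' @return an object of class `dense_cohort_config`
#' @export
cohort_config <- function(n_cases = 24,
                          snr_strata = list(c(3.9, 6.1), c(8.3, 11.5),
                                            c(13.9, 17.7)),
                          k_grid = c(0.1, 0.3, 0.6, 0.9),
                          N1 = 120, N2 = 60, Nf = 64, pixel_size = 1.6,
                          epi_range_frac = c(0.4, 0.6),
                          endo_frac_range = c(0.5, 0.8),
                          motion_ranges = default_motion_ranges(),
                          interpolate_frames = FALSE,
                          master_seed = 1L) {
  if (n_cases %% length(snr_strata) != 0)
    err_config("n_cases must be divisible by the number of SNR strata")
  structure(
    list(n_cases = as.integer(n_cases), snr_strata = snr_strata,
         k_grid = k_grid, N1 = as.integer(N1), N2 = as.integer(N2),
         Nf = as.integer(Nf), pixel_size = pixel_size,
         epi_range_frac = epi_range_frac, endo_frac_range = endo_frac_range,
         motion_ranges = motion_ranges,
         interpolate_frames = interpolate_frames,
         master_seed = as.integer(master_seed)),
    class = "dense_cohort_config")
}

#' Generate a seeded virtual cohort
#'
#' For each case: a child seed is derived deterministically from the master
#' seed; annulus geometry, motion parameters and the SNR target are drawn;
#' the anatomy, motion, ground-truth strain (at the reconstructed frame
#' times) and the DENSE series are generated. Failed cases are flagged and
#' skipped with a warning.
#'
#' @param config a [cohort_config()]
#' @param progress print one line per case
#' @return list of cases, each with `labelmap`, `geometry`, `params`,
#'   `series`, `truth` (ground-truth `dense_strain`), `stratum`,
#'   `target_snr`, `seed`
#' @export
generate_cohort <- function(config = cohort_config(), progress = FALSE) {
  n_strata <- length(config$snr_strata)
  per_stratum <- config$n_cases / n_strata
  stratum_of <- rep(seq_len(n_strata), each = per_stratum)
  set.seed(config$master_seed)
  child_seeds <- sample.int(.Machine$integer.max - 1, config$n_cases)
  cases <- vector("list", config$n_cases)
  for (ci in seq_len(config$n_cases)) {
    cases[[ci]] <- tryCatch(
      simulate_cohort_case(config, stratum_of[ci], child_seeds[ci]),
      error = function(e) {
        warning(sprintf("case %d failed and was skipped: %s", ci,
                        conditionMessage(e)))
        list(failed = TRUE, message = conditionMessage(e))
      })
    cases[[ci]]$index <- ci
    if (progress)
      message(sprintf("case %d/%d (stratum %d) done", ci, config$n_cases,
                      stratum_of[ci]))
  }
  structure(list(cases = cases, config = config), class = "dense_cohort")
}

simulate_cohort_case <- function(config, stratum, seed) {
  set.seed(seed)
  epi <- round(stats::runif(1, config$epi_range_frac[1] * config$N1,
                            config$epi_range_frac[2] * config$N1))
  endo <- round(epi * stats::runif(1, config$endo_frac_range[1],
                                   config$endo_frac_range[2]))
  labelmap <- generate_annulus(config$N1, config$pixel_size, endo, epi)
  geometry <- polar_geometry(labelmap)
  params <- sample_motion_parameters(config$motion_ranges)
  rg <- config$snr_strata[[stratum]]
  target <- stats::runif(1, rg[1], rg[2])
  acq <- acq_params(N1 = config$N1, N2 = config$N2, Nf = config$Nf,
                    fov = config$N1 * config$pixel_size,
                    target_snr = target,
                    interpolate_frames = config$interpolate_frames)
  series <- simulate_dense_series(labelmap, geometry, params, acq)
  field <- generate_displacement_field(labelmap, geometry, params,
                                       series$frame_times)
  truth <- green_strain(field, geometry = geometry)
  list(labelmap = labelmap, geometry = geometry, params = params,
       series = series, truth = truth, stratum = stratum,
       target_snr = target, seed = seed, failed = FALSE)
}

#' @export
print.dense_cohort <- function(x, ...) {
  ok <- sum(!vapply(x$cases, function(cs) isTRUE(cs$failed), logical(1)))
  cat(sprintf("<dense_cohort> %d/%d cases simulated, %d SNR strata\n",
              ok, x$config$n_cases, length(x$config$snr_strata)))
  invisible(x)
}

# Resample a ground-truth strain raster (N1 resolution) at the estimated
# material positions (bilinear over the valid myocardium).
resample_truth <- function(truth_raster, truth, positions) {
  z <- truth_raster
  bilinear_sample(z, truth$pixel_size, positions[, 1], positions[, 2],
                  origin = truth$origin)
}

#' Pixel signed errors between ground-truth and estimated strain
#'
#' Errors are ground truth minus estimate per pixel (positive radial-strain
#' errors therefore mean underestimation); mean (ASE) and standard
#' deviation are reported globally and per transmural tertile
#' (subendocardial, mid-myocardial, subepicardial).
#'
#' @param truth ground-truth `dense_strain` (high-resolution raster)
#' @param est estimated `dense_strain` (image-resolution raster)
#' @param frame_truth,frame_est frame indices to compare (end-systole)
#' @return data.frame with columns component, segment, ase, std, n
#' @export
pixel_signed_errors <- function(truth, est,
                                frame_truth = length(truth$frame_times),
                                frame_est = frame_truth) {
  n <- est$n
  idx <- which(est$valid[[frame_est]])
  if (length(idx) == 0) err_input("no valid estimated pixels")
  xs <- pixel_centers(n, est$pixel_size, est$origin[1])
  pos <- cbind(xs[((idx - 1) %/% n) + 1], xs[((idx - 1) %% n) + 1])
  trans <- est$transmural[idx]
  out <- list()
  for (comp in c("err", "ecc")) {
    tv <- resample_truth(truth[[comp]][[frame_truth]], truth, pos)
    ev <- est[[comp]][[frame_est]][idx]
    ok <- !is.na(tv) & !is.na(ev)
    if (!any(ok)) err_input("no overlapping valid pixels")
    d <- tv[ok] - ev[ok]
    tr <- trans[ok]
    seg <- cut(tr, breaks = c(-Inf, 1 / 3, 2 / 3, Inf),
               labels = c("subendo", "mid", "subepi"))
    for (s in c("subendo", "mid", "subepi")) {
      sel <- seg == s
      out[[length(out) + 1]] <- data.frame(
        component = comp, segment = s,
        ase = mean(d[sel]), std = stats::sd(d[sel]), n = sum(sel))
    }
    out[[length(out) + 1]] <- data.frame(
      component = comp, segment = "global",
      ase = mean(d), std = stats::sd(d), n = length(d))
  }
  do.call(rbind, out)
}

#' Transmural strain profile with quadratic regression
#'
#' Bins the strain of one frame against the normalized transmural
#' coordinate and fits an ordinary least-squares polynomial of order 2.
#'
#' @param strain a `dense_strain` object
#' @param frame frame index
#' @param component "err" or "ecc"
#' @param n_bins number of transmural bins
#' @return list with `bins` (data.frame: mid, mean, sd, n) and
#'   `coefficients` (intercept, linear, quadratic)
#' @export
transmural_profile <- function(strain, frame = length(strain$frame_times),
                               component = "err", n_bins = 10) {
  v <- strain[[component]][[frame]]
  ok <- !is.na(v) & !is.na(strain$transmural)
  d <- strain$transmural[ok]; y <- v[ok]
  if (length(unique(round(d, 8))) < 3)
    err_input("need at least 3 distinct transmural values")
  deg <- 2
  if (length(unique(round(d, 8))) < deg + 1) {
    warning("degenerate transmural abscissa; reducing polynomial order")
    deg <- length(unique(round(d, 8))) - 1
  }
  fit <- stats::lm(y ~ stats::poly(d, deg, raw = TRUE))
  co <- stats::coef(fit)
  co <- c(co, rep(0, 3 - length(co)))
  edges <- seq(0, 1, length.out = n_bins + 1)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  bin <- cut(d, breaks = edges, include.lowest = TRUE)
  bins <- data.frame(
    mid = mid,
    mean = as.numeric(tapply(y, bin, mean)),
    sd = as.numeric(tapply(y, bin, stats::sd)),
    n = as.numeric(table(bin)))
  list(bins = bins, coefficients = stats::setNames(
    as.numeric(co[1:3]), c("intercept", "linear", "quadratic")))
}

#' Bland-Altman analysis of paired global peak strain
#'
#' Differences are ground truth minus estimate; the bias is their mean and
#' the limits of agreement are bias +/- 1.96 standard deviations.
#'
#' @param true_peaks,est_peaks paired numeric vectors (n >= 2)
#' @return list with `bias`, `loa_low`, `loa_high`, `sd`, `n`
#' @export
bland_altman <- function(true_peaks, est_peaks) {
  if (length(true_peaks) != length(est_peaks) || length(true_peaks) < 2)
    err_input("paired series of length >= 2 required")
  d <- true_peaks - est_peaks
  b <- mean(d); s <- stats::sd(d)
  list(bias = b, loa_low = b - 1.96 * s, loa_high = b + 1.96 * s,
       sd = s, n = length(d))
}

#' Global peak strain of a strain series
#'
#' Spatial mean over the myocardium per frame, then the extremum over
#' frames: maximum for radial strain, minimum (most negative) for
#' circumferential strain.
#'
#' @param strain a `dense_strain` object
#' @param component "err" or "ecc"
#' @return peak global strain
#' @export
global_peak_strain <- function(strain, component = "err") {
  gm <- vapply(seq_along(strain$frame_times), function(f) {
    v <- strain[[component]][[f]]
    mean(v[!is.na(v)])
  }, numeric(1))
  if (component == "err") max(gm) else min(gm)
}

#' Evaluate a cohort at each regularization level
#'
#' Runs the strain-evaluation chain on every case at every smoothness level
#' in the k grid and assembles the error report: pooled pixel signed errors
#' at end-systole per (component, k, stratum, segment), per-case means, and
#' Bland-Altman bias/limits of global peak strain per (component, k).
#'
#' @param cohort a [generate_cohort()] result
#' @param k_grid regularization levels (defaults to the cohort config)
#' @param progress print one line per case
#' @return an object of class `dense_error_report`: `table` (data.frame),
#'   `bland_altman` (data.frame), `pixels` (pooled per-pixel errors),
#'   `peaks` (per-case peak strain pairs)
#' @export
evaluation_table <- function(cohort, k_grid = cohort$config$k_grid,
                             progress = FALSE, lambda_scale = 0.1) {
  pix <- list(); peaks <- list()
  for (cs in cohort$cases) {
    if (isTRUE(cs$failed)) next
    es <- cs$series$es_index
    unw <- unwrap_series(phase_to_eulerian(cs$series))
    for (k in k_grid) {
      est <- evaluate_strain(cs$series, cs$labelmap, cs$geometry, k = k,
                             unwrapped = unw, lambda_scale = lambda_scale)
      pe <- pixel_errors_raw(cs$truth, est, es, es)
      pe$k <- k; pe$stratum <- cs$stratum; pe$case <- cs$index
      pix[[length(pix) + 1]] <- pe
      peaks[[length(peaks) + 1]] <- data.frame(
        case = cs$index, stratum = cs$stratum, k = k,
        true_err = global_peak_strain(cs$truth, "err"),
        est_err = global_peak_strain(est, "err"),
        true_ecc = global_peak_strain(cs$truth, "ecc"),
        est_ecc = global_peak_strain(est, "ecc"))
    }
    if (progress) message(sprintf("case %d evaluated", cs$index))
  }
  if (length(pix) == 0) err_input("no successfully evaluated cases")
  pix <- do.call(rbind, pix)
  peaks <- do.call(rbind, peaks)
  segs <- c("subendo", "mid", "subepi", "global")
  rows <- list()
  for (comp in c("err", "ecc")) for (k in k_grid)
    for (st in c(seq_along(cohort$config$snr_strata), "global"))
      for (seg in segs) {
        sel <- pix$component == comp & pix$k == k &
          (st == "global" | pix$stratum == st) &
          (if (seg == "global") TRUE else pix$segment == seg)
        d <- pix$error[sel]
        if (length(d) == 0) next
        pc <- tapply(pix$error[sel], pix$case[sel], mean)
        rows[[length(rows) + 1]] <- data.frame(
          component = comp, k = k, stratum = as.character(st), segment = seg,
          ase = mean(d), std = stats::sd(d), n = length(d),
          case_mean_ase = mean(pc))
      }
  tab <- do.call(rbind, rows)
  ba <- list()
  for (comp in c("err", "ecc")) for (k in k_grid) {
    pk <- peaks[peaks$k == k, ]
    r <- bland_altman(pk[[paste0("true_", comp)]], pk[[paste0("est_", comp)]])
    ba[[length(ba) + 1]] <- data.frame(
      component = comp, k = k, bias = r$bias, loa_low = r$loa_low,
      loa_high = r$loa_high, sd = r$sd, n = r$n)
  }
  structure(list(table = tab, bland_altman = do.call(rbind, ba),
                 pixels = pix, peaks = peaks),
            class = "dense_error_report")
}

# Per-pixel signed errors (long format) at one frame.
pixel_errors_raw <- function(truth, est, frame_truth, frame_est) {
  n <- est$n
  idx <- which(est$valid[[frame_est]])
  xs <- pixel_centers(n, est$pixel_size, est$origin[1])
  pos <- cbind(xs[((idx - 1) %/% n) + 1], xs[((idx - 1) %% n) + 1])
  trans <- est$transmural[idx]
  out <- list()
  for (comp in c("err", "ecc")) {
    tv <- resample_truth(truth[[comp]][[frame_truth]], truth, pos)
    ev <- est[[comp]][[frame_est]][idx]
    ok <- !is.na(tv) & !is.na(ev)
    seg <- cut(trans[ok], breaks = c(-Inf, 1 / 3, 2 / 3, Inf),
               labels = c("subendo", "mid", "subepi"))
    out[[length(out) + 1]] <- data.frame(
      component = comp, segment = as.character(seg),
      transmural = trans[ok], error = tv[ok] - ev[ok])
  }
  do.call(rbind, out)
}

#' @export
print.dense_error_report <- function(x, ...) {
  cat("<dense_error_report>\n")
  g <- x$table[x$table$stratum == "global" & x$table$segment == "global", ]
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %s k=%.1f: ASE %+.3f +/- %.3f (n=%d)\n",
                g$component[i], g$k[i], g$ase[i], g$std[i], g$n[i]))
  invisible(x)
}

#' Write an error report to CSV files
#'
#' @param report a [evaluation_table()] result
#' @param dir output directory (created if missing)
#' @return the directory, invisibly
#' @export
write_error_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$table, file.path(dir, "pixel_errors.csv"),
                   row.names = FALSE)
  utils::write.csv(report$bland_altman, file.path(dir, "bland_altman.csv"),
                   row.names = FALSE)
  utils::write.csv(report$peaks, file.path(dir, "global_peaks.csv"),
                   row.names = FALSE)
  invisible(dir)
}
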