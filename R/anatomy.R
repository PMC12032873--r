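# Anatomy module: end-diastolic label maps (myocardium / blood pool /
# background) from a parametric annulus or an imported binary mask, and
# per-pixel polar geometry (transmural coordinate, radial/circumferential
# unit vectors) used for strain projection and transmural binning.

LABEL_BACKGROUND <- 0L
LABEL_MYOCARDIUM <- 1L
LABEL_BLOODPOOL  <- 2L

#' Construct a label map
#'
#' A label map is a square integer raster at the ground-truth resolution with
#' a physical pixel size. Label codes: 0 background, 1 myocardium, 2 blood
#' pool, >= 3 other tissues. Rows index the physical y axis (increasing with
#' row index), columns the x axis; pixel centers sit at
#' (index + 0.5) * pixel_size with the raster center at `origin`.
#'
#' @param labels square integer matrix of label codes
#' @param pixel_size pixel edge length in mm (> 0)
#' @param origin physical (x, y) coordinate of the raster center, mm
#' @return an object of class `dense_labelmap`
#' @export
new_labelmap <- function(labels, pixel_size, origin = c(0, 0)) {
  if (!is.matrix(labels) || nrow(labels) != ncol(labels))
    err_input("`labels` must be a square matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    err_input("`pixel_size` must be a positive scalar (mm)")
  structure(
    list(labels = matrix(as.integer(labels), nrow(labels)),
         pixel_size = as.numeric(pixel_size),
         origin = as.numeric(origin)),
    class = "dense_labelmap")
}

#' @export
print.dense_labelmap <- function(x, ...) {
  n <- nrow(x$labels)
  cat(sprintf("<dense_labelmap> %d x %d @ %.3g mm/px\n", n, n, x$pixel_size))
  tb <- table(x$labels)
  cat("  labels:", paste(sprintf("%s:%d", names(tb), tb), collapse = "  "), "\n")
  invisible(x)
}

#' Generate an annular left-ventricular phantom
#'
#' Creates an end-diastolic label map of a centered annulus: pixels whose
#' center radius lies in (endo/2, epi/2] are myocardium, radius <= endo/2 is
#' blood pool, the remainder background. Diameters are expressed in pixels of
#' the requested raster.
#'
#' @param matrix_size raster size in pixels (square)
#' @param pixel_size pixel size in mm (default 0.8, the usual ground-truth
#'   resolution)
#' @param endo_diameter endocardial diameter in pixels
#' @param epi_diameter epicardial diameter in pixels
#' @return a [new_labelmap()] object
#' @export
generate_annulus <- function(matrix_size, pixel_size = 0.8,
                             endo_diameter, epi_diameter) {
  if (endo_diameter >= epi_diameter)
    err_geometry("endocardial diameter must be strictly smaller than epicardial diameter")
  if (endo_diameter <= 0 || epi_diameter > matrix_size)
    err_geometry("diameters must satisfy 0 < endo < epi <= matrix_size")
  n <- as.integer(matrix_size)
  u <- seq_len(n) - 0.5 - n / 2        # pixel-center offsets, pixel units
  r <- sqrt(outer(u^2, u^2, "+"))      # rows = y, cols = x
  labels <- matrix(LABEL_BACKGROUND, n, n)
  labels[r <= endo_diameter / 2] <- LABEL_BLOODPOOL
  labels[r > endo_diameter / 2 & r <= epi_diameter / 2] <- LABEL_MYOCARDIUM
  new_labelmap(labels, pixel_size)
}

#' Upsample, binarize and dilate an imported myocardial mask
#'
#' Emulates the preparation of manually-segmented myocardial masks: the
#' binary mask is smoothed with a Gaussian filter (sigma in input pixels) to
#' suppress staircase edges, spline-interpolated to the target resolution,
#' binarized at an intensity threshold of 0.5 and optionally dilated
#' morphologically (disc element, radius in output pixels). The blood pool is
#' inferred by hole-filling the myocardial annulus, so imported masks need
#' only contain myocardium.
#'
#' @param mask binary matrix (nonzero = myocardium)
#' @param target_size output raster size in pixels
#' @param dilation dilation radius in output pixels (0 to 6)
#' @param pixel_size output pixel size in mm
#' @param sigma Gaussian smoothing width in input pixels
#' @return a [new_labelmap()] object
#' @export
upsample_and_dilate_mask <- function(mask, target_size, dilation = 0,
                                     pixel_size = 0.8, sigma = 1) {
  if (!is.matrix(mask)) err_input("`mask` must be a matrix")
  m <- (mask != 0) * 1
  if (sum(m) == 0) err_input("mask is empty")
  if (dilation < 0 || dilation > 6)
    err_input("`dilation` must be between 0 and 6 pixels")
  sm <- EBImage::gblur(m, sigma = sigma)
  # separable cubic-spline interpolation onto the target pixel centers,
  # matching field-of-view between input and output rasters
  n_in <- nrow(m); n_out <- as.integer(target_size)
  u_in  <- (seq_len(n_in) - 0.5) / n_in
  u_out <- (seq_len(n_out) - 0.5) / n_out
  tmp <- apply(sm, 2, function(col)
    stats::spline(u_in, col, xout = u_out, method = "natural")$y)
  up <- t(apply(tmp, 1, function(row)
    stats::spline(u_in, row, xout = u_out, method = "natural")$y))
  myo <- up >= 0.5
  if (dilation > 0) {
    brush <- EBImage::makeBrush(2 * as.integer(dilation) + 1, shape = "disc")
    myo <- EBImage::dilate(myo * 1, brush) > 0
  }
  filled <- EBImage::fillHull(myo * 1) > 0
  labels <- matrix(LABEL_BACKGROUND, n_out, n_out)
  labels[filled & !myo] <- LABEL_BLOODPOOL
  labels[myo] <- LABEL_MYOCARDIUM
  new_labelmap(labels, pixel_size)
}

#' Per-pixel polar geometry of a label map
#'
#' Computes the left-ventricular center (centroid of blood pool plus
#' myocardium), the normalized transmural coordinate (0 at the endocardial
#' border, 1 at the epicardial border, from the ratio of Euclidean distance
#' transforms), and per-pixel orthonormal radial / circumferential unit
#' vectors taken along the outward ray from the center.
#'
#' @param labelmap a [new_labelmap()] object satisfying its invariants
#' @return an object of class `dense_polar` with fields `center` (mm),
#'   `transmural` (raster, NA outside myocardium), `radial_x`, `radial_y`,
#'   `circ_x`, `circ_y` (unit-vector rasters), and endo/epi radius estimates
#' @export
polar_geometry <- function(labelmap) {
  lab <- labelmap$labels
  px <- labelmap$pixel_size
  n <- nrow(lab)
  myo <- lab == LABEL_MYOCARDIUM
  blood <- lab == LABEL_BLOODPOOL
  if (!any(myo)) err_geometry("label map contains no myocardium")
  if (!any(blood)) err_geometry("label map contains no blood pool")
  ncomp <- max(EBImage::bwlabel(myo * 1))
  if (ncomp != 1)
    err_geometry("myocardium must form a single connected annular component")
  filled <- EBImage::fillHull(myo * 1) > 0
  if (any(blood & !filled))
    err_geometry("blood pool must be enclosed by the myocardial annulus")

  xs <- pixel_centers(n, px, labelmap$origin[1])
  ys <- pixel_centers(n, px, labelmap$origin[2])
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(ys, n, n)
  inner <- myo | blood
  center <- c(mean(X[inner]), mean(Y[inner]))

  # transmural coordinate from endo/epi Euclidean distance transforms;
  # the half-pixel shifts place 0/1 exactly on border pixel centers
  d_endo <- as.matrix(EBImage::distmap(1 - blood * 1))
  d_epi  <- as.matrix(EBImage::distmap(inner * 1))
  trans_full <- (d_endo - 0.5) / pmax(d_endo + d_epi - 1, .Machine$double.eps)
  trans_full <- pmin(pmax(trans_full, 0), 1)
  trans_full[blood] <- 0
  trans_full[!inner & !myo] <- 1
  trans <- trans_full
  trans[!myo] <- NA_real_

  dx <- X - center[1]
  dy <- Y - center[2]
  r <- sqrt(dx^2 + dy^2)
  r[r == 0] <- NA_real_
  ux <- dx / r; uy <- dy / r

  r_myo <- r[myo]
  r_blood <- r[blood]
  r_endo <- (max(r_blood, na.rm = TRUE) + min(r_myo)) / 2
  r_epi <- max(r_myo) + (min(r_myo) - r_endo)

  structure(
    list(center = center,
         transmural = trans,
         transmural_full = trans_full,
         radial_x = ux, radial_y = uy,
         circ_x = -uy, circ_y = ux,
         r_endo = r_endo, r_epi = r_epi,
         pixel_size = px, n = n, origin = labelmap$origin),
    class = "dense_polar")
}

#' @export
print.dense_polar <- function(x, ...) {
  cat(sprintf("<dense_polar> center (%.2f, %.2f) mm, r_endo %.2f mm, r_epi %.2f mm\n",
              x$center[1], x$center[2], x$r_endo, x$r_epi))
  invisible(x)
}

#' Import a binary myocardial mask from PNG or NIfTI
#'
#' Nonzero pixels are interpreted as myocardium.
#'
#' @param path file path ending in .png, .nii or .nii.gz
#' @return binary matrix
#' @export
read_mask <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    return(img > 0)
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) > 2) arr <- arr[, , 1]
    return(arr > 0)
  }
  err_input("unsupported mask format (use .png, .nii or .nii.gz)")
}

#' Export a label map as integer NIfTI
#'
#' @param labelmap a [new_labelmap()] object
#' @param path output path (.nii or .nii.gz)
#' @return the path, invisibly
#' @export
write_labelmap_nifti <- function(labelmap, path) {
  img <- RNifti::asNifti(labelmap$labels,
                         pixdim = rep(labelmap$pixel_size, 2))
  RNifti::writeNifti(img, path)
  invisible(path)
}
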