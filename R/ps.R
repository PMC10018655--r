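#' Extract non-overlapping central ROIs from a slice
#'
#' Tiles the centred `central_size x central_size` window of a slice
#' with non-overlapping `roi_size x roi_size` ROIs. With the defaults
#' (64 within 128) this yields exactly four ROIs, one per quadrant of
#' the central window.
#'
#' @param slice_image 2D HU matrix, at least `central_size` on each
#'   side.
#' @param roi_size ROI side in pixels.
#' @param central_size Central window side in pixels; must be a
#'   multiple of `roi_size`.
#' @return List of `roi_size x roi_size` matrices, row-major over the
#'   tiling.
#' @export
extract_central_rois <- function(slice_image, roi_size = 64, central_size = 128) {
  stopifnot(is.matrix(slice_image))
  if (central_size %% roi_size != 0)
    stopf("`central_size` (%d) must be divisible by `roi_size` (%d)",
          central_size, roi_size)
  nr <- nrow(slice_image); nc <- ncol(slice_image)
  if (nr < central_size || nc < central_size)
    stopf("image (%d x %d) smaller than the central window (%d)",
          nr, nc, central_size)
  r0 <- floor((nr - central_size) / 2)
  c0 <- floor((nc - central_size) / 2)
  k <- central_size %/% roi_size
  rois <- vector("list", k * k)
  i <- 1L
  for (br in seq_len(k)) for (bc in seq_len(k)) {
    rows <- r0 + (br - 1L) * roi_size + seq_len(roi_size)
    cols <- c0 + (bc - 1L) * roi_size + seq_len(roi_size)
    rois[[i]] <- slice_image[rows, cols]
    i <- i + 1L
  }
  rois
}

#' Mirror an ROI into an even-symmetric block
#'
#' Reflects a square N x N ROI about its right and bottom edges,
#' producing a 2N x 2N block that is invariant under left-right and
#' up-down flips. Mirroring before the Fourier transform suppresses
#' the edge (leakage) artefacts that arise when spectra are estimated
#' on patches of strongly correlated images; the DFT of the mirrored
#' block is real (cosine-only).
#'
#' @param roi Square numeric matrix.
#' @return A `2N x 2N` matrix.
#' @export
#' @examples
#' mirror_roi(matrix(1:4, 2, 2, byrow = TRUE))
mirror_roi <- function(roi) {
  stopifnot(is.matrix(roi), nrow(roi) == ncol(roi))
  top <- cbind(roi, roi[, rev(seq_len(ncol(roi))), drop = FALSE])
  rbind(top, top[rev(seq_len(nrow(top))), , drop = FALSE])
}

#' Power spectrum of a single block
#'
#' Subtracts the block mean, applies the 2D DFT and returns
#' `(pixel_spacing^2 / n_pixels) * |DFT|^2` on the unshifted frequency
#' grid. The DC bin is zero after mean subtraction. Units are
#' HU^2 mm^2; the grid's frequency spacing is
#' `1 / (side * pixel_spacing)` mm^-1. Summing the spectrum times the
#' frequency-bin area returns the block's pixel variance (population
#' divisor) exactly -- Parseval's identity.
#'
#' @param block Square numeric matrix (typically a mirrored ROI).
#' @param pixel_spacing mm per pixel.
#' @return An object of class `ps2d`: list with `values` (matrix,
#'   unshifted), `freq_spacing`, `pixel_spacing`, `n_rois_averaged`,
#'   `n_slices_averaged`.
#' @export
roi_power_spectrum <- function(block, pixel_spacing) {
  stopifnot(is.matrix(block), nrow(block) == ncol(block), nrow(block) > 0)
  check_scalar_num(pixel_spacing, "pixel_spacing", positive = TRUE)
  n <- nrow(block)
  ft <- stats::fft(block - mean(block))
  vals <- (pixel_spacing^2 / (n * n)) * (Mod(ft))^2
  new_ps2d(vals, pixel_spacing, n_rois = 1L, n_slices = 1L)
}

new_ps2d <- function(values, pixel_spacing, n_rois, n_slices) {
  structure(
    list(values = values, freq_spacing = 1 / (nrow(values) * pixel_spacing),
         pixel_spacing = pixel_spacing,
         n_rois_averaged = n_rois, n_slices_averaged = n_slices),
    class = "ps2d")
}

#' @export
print.ps2d <- function(x, ...) {
  cat(sprintf("<ps2d> %d x %d grid, freq spacing %.5f mm^-1, %d ROI(s) over %d slice(s)\n",
              nrow(x$values), ncol(x$values), x$freq_spacing,
              x$n_rois_averaged, x$n_slices_averaged))
  invisible(x)
}

#' Per-examination 2D power spectrum
#'
#' The examination spectrum is the mean, over every ROI of every
#' slice, of the block power spectrum of the mirrored ROI. ROIs are
#' taken from the centred `central_size` window of each slice
#' ([extract_central_rois()]). The result does not depend on slice or
#' ROI order.
#'
#' @param stack A [ct_stack()].
#' @inheritParams extract_central_rois
#' @return A `ps2d` with averaging counts filled in.
#' @export
examination_ps <- function(stack, roi_size = 64, central_size = 128) {
  stopifnot(inherits(stack, "ct_stack"))
  ns <- n_slices(stack)
  if (ns < 1) stopf("empty stack")
  acc <- NULL
  n_rois <- 0L
  for (k in seq_len(ns)) {
    for (roi in extract_central_rois(get_slice(stack, k), roi_size, central_size)) {
      ps <- roi_power_spectrum(mirror_roi(roi), stack$pixel_spacing)
      acc <- if (is.null(acc)) ps$values else acc + ps$values
      n_rois <- n_rois + 1L
    }
  }
  new_ps2d(acc / n_rois, stack$pixel_spacing, n_rois = n_rois, n_slices = ns)
}

#' Radially average a 2D power spectrum
#'
#' Bins the 2D spectrum by radial frequency `|f|` into bins one
#' frequency-grid step wide. Each output value is the unweighted mean
#' of the grid samples whose `|f|` falls in the bin; the DC sample is
#' excluded and empty bins are dropped. The bin abscissa is the mean
#' `|f|` of the contributing samples.
#'
#' @param ps2d A `ps2d`.
#' @return A `ps_curve`: data frame with columns `freq` (mm^-1,
#'   ascending) and `ps` (HU^2 mm^2).
#' @export
radial_average <- function(ps2d) {
  stopifnot(inherits(ps2d, "ps2d"))
  n <- nrow(ps2d$values)
  f1 <- fft_freq(n, ps2d$pixel_spacing)
  fr <- sqrt(outer(f1^2, f1^2, "+"))
  keep <- fr > 0  # exclude DC
  bin <- floor(fr[keep] / ps2d$freq_spacing) + 1L
  v <- ps2d$values[keep]
  ps <- tapply(v, bin, mean)
  freq <- tapply(fr[keep], bin, mean)
  ord <- order(freq)
  new_ps_curve(data.frame(freq = as.numeric(freq)[ord],
                          ps = as.numeric(ps)[ord]))
}

new_ps_curve <- function(df, n_patients = NA_integer_) {
  structure(df, class = c("ps_curve", "data.frame"), n_patients = n_patients)
}

#' Cohort-average 1D power spectrum
#'
#' Averages per-examination radial curves across patients and attaches
#' the relative standard error of each data point,
#' `100 * (SD across patients / sqrt(n)) / mean`, as the measure of
#' between-patient uncertainty.
#'
#' @param curves List of `ps_curve` objects on identical frequency
#'   bins (same ROI size and pixel spacing).
#' @return A `ps_curve` with columns `freq`, `ps`, `relative_se`
#'   (percent) and attribute `n_patients`.
#' @export
cohort_ps <- function(curves) {
  stopifnot(length(curves) >= 1)
  f0 <- curves[[1]]$freq
  for (cu in curves)
    if (length(cu$freq) != length(f0) || any(abs(cu$freq - f0) > 1e-9))
      stopf("all curves must share identical frequency bins")
  m <- sapply(curves, function(cu) cu$ps)  # bins x patients
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  n <- ncol(m)
  mu <- rowMeans(m)
  if (n >= 2) {
    sdv <- apply(m, 1, stats::sd)
    rse <- 100 * (sdv / sqrt(n)) / mu
    rse[mu == 0 & sdv == 0] <- 0  # structural zeros (mirrored-block Nyquist corner)
  } else {
    rse <- rep(NA_real_, length(mu))
  }
  new_ps_curve(data.frame(freq = f0, ps = mu, relative_se = rse),
               n_patients = n)
}

#' @export
plot.ps_curve <- function(x, ..., log = "y", xlab = "spatial frequency (mm^-1)",
                          ylab = "PS (HU^2 mm^2)") {
  graphics::plot(x$freq, x$ps, type = "l", log = log, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
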