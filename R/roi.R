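#' Circular-ROI specification
#'
#' A circular region of interest given in mm slice coordinates (see
#' [ct_stack()] for the coordinate convention).
#'
#' @param center Length-2 numeric `(x, y)` in mm.
#' @param diameter ROI diameter in mm (default 15, the standard size
#'   for aorta/fat CNR measurements).
#' @param slice_index 1-based slice index.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(center, diameter = 15, slice_index = 1L) {
  stopifnot(length(center) == 2, is.numeric(center))
  check_scalar_num(diameter, "diameter", positive = TRUE)
  check_scalar_num(slice_index, "slice_index", positive = TRUE)
  structure(list(center = as.numeric(center), diameter = diameter,
                 slice_index = as.integer(slice_index)),
            class = "roi_spec")
}

#' ROI mean and standard deviation
#'
#' A pixel belongs to the ROI iff its centre lies within
#' `diameter / 2` of the ROI centre (centre-in-circle rule, which is
#' orientation-independent and reproducible). The SD uses the `n - 1`
#' divisor. The ROI must lie fully inside the image.
#'
#' @param slice_image 2D HU matrix.
#' @param spec A [roi_spec()] (its `slice_index` is ignored here).
#' @param pixel_spacing mm per pixel.
#' @return List with `mean_hu`, `sd_hu`, `n_pixels`.
#' @export
roi_stats <- function(slice_image, spec, pixel_spacing) {
  stopifnot(is.matrix(slice_image), inherits(spec, "roi_spec"))
  check_scalar_num(pixel_spacing, "pixel_spacing", positive = TRUE)
  r <- spec$diameter / 2
  cx <- spec$center[1]; cy <- spec$center[2]
  w <- ncol(slice_image) * pixel_spacing
  h <- nrow(slice_image) * pixel_spacing
  if (cx - r < 0 || cy - r < 0 || cx + r > w || cy + r > h)
    stopf("ROI (centre %.1f, %.1f mm, diameter %.1f mm) extends outside the image",
          cx, cy, spec$diameter)
  # candidate pixel window
  cols <- max(1L, floor((cx - r) / pixel_spacing)) :
    min(ncol(slice_image), ceiling((cx + r) / pixel_spacing) + 1L)
  rows <- max(1L, floor((cy - r) / pixel_spacing)) :
    min(nrow(slice_image), ceiling((cy + r) / pixel_spacing) + 1L)
  pcx <- (cols - 0.5) * pixel_spacing
  pcy <- (rows - 0.5) * pixel_spacing
  inside <- outer((pcy - cy)^2, (pcx - cx)^2, "+") <= r^2
  vals <- slice_image[rows, cols, drop = FALSE][inside]
  if (!length(vals)) stopf("ROI contains no pixel centres")
  list(mean_hu = mean(vals),
       sd_hu = if (length(vals) > 1) stats::sd(vals) else 0,
       n_pixels = length(vals))
}

#' Contrast-to-noise ratio between two ROIs
#'
#' `CNR = (mean1 - mean2) / sqrt(sd1^2 + sd2^2)`. By convention ROI1
#' is the ascending aorta and ROI2 the mediastinal fat anterior to it,
#' so positive CNR means the aorta is brighter. The CNR is invariant
#' under a global HU offset and under positive rescaling of the image.
#'
#' @param roi1,roi2 ROI statistics as returned by [roi_stats()].
#' @return Unitless CNR.
#' @export
#' @examples
#' cnr(list(mean_hu = 40, sd_hu = 6), list(mean_hu = -60, sd_hu = 8))  # 10
cnr <- function(roi1, roi2) {
  denom <- sqrt(roi1$sd_hu^2 + roi2$sd_hu^2)
  if (denom == 0) stopf("both ROI SDs are zero; CNR undefined")
  (roi1$mean_hu - roi2$mean_hu) / denom
}

#' Paired comparison of per-patient CNR between two reconstructions
#'
#' Computes the per-patient differences `cnr_a - cnr_b`, their mean
#' and standard error of the mean, and a two-sided paired Student
#' t-test (df = n - 1). Differences with zero variance are flagged
#' degenerate (the t statistic is 0 with p = 1 when the mean is also
#' zero, otherwise infinite with p = 0).
#'
#' @param cnr_a,cnr_b Equal-length numeric vectors of per-patient CNR,
#'   paired by patient.
#' @param alpha Significance threshold (default 0.05).
#' @return An object of class `cnr_comparison`: list with
#'   `per_patient_diffs`, `mean_diff`, `sem`, `t_statistic`,
#'   `p_value`, `df`, `significant`, `degenerate`.
#' @export
cnr_difference_analysis <- function(cnr_a, cnr_b, alpha = 0.05) {
  if (length(cnr_a) != length(cnr_b))
    stopf("paired CNR vectors differ in length (%d vs %d)",
          length(cnr_a), length(cnr_b))
  n <- length(cnr_a)
  if (n < 2) stopf("need at least 2 patients for paired inference")
  d <- cnr_a - cnr_b
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    res <- list(per_patient_diffs = d, mean_diff = m, sem = 0,
                t_statistic = if (m == 0) 0 else sign(m) * Inf,
                p_value = if (m == 0) 1 else 0,
                df = n - 1L, degenerate = TRUE)
  } else {
    tt <- stats::t.test(cnr_a, cnr_b, paired = TRUE)
    res <- list(per_patient_diffs = d, mean_diff = m, sem = s / sqrt(n),
                t_statistic = unname(tt$statistic), p_value = tt$p.value,
                df = n - 1L, degenerate = FALSE)
  }
  res$significant <- res$p_value < alpha
  structure(res, class = "cnr_comparison")
}

#' @export
print.cnr_comparison <- function(x, ...) {
  cat(sprintf("<cnr_comparison> n = %d patients\n", length(x$per_patient_diffs)))
  cat(sprintf("  mean CNR difference %.3f (SEM %.3f), t(%d) = %.3f, p = %.4g%s%s\n",
              x$mean_diff, x$sem, x$df, x$t_statistic, x$p_value,
              if (x$significant) " *" else "",
              if (x$degenerate) " [degenerate: zero-variance differences]" else ""))
  invisible(x)
}

#' Line profile through a slice
#'
#' Samples HU values along the segment from `p0` to `p1` (mm
#' coordinates) at uniform steps, by bilinear interpolation between
#' the four neighbouring pixel centres (`method = "bilinear"`) or by
#' nearest pixel (`method = "nearest"`). The requested step is
#' adjusted to the nearest value that divides the segment length
#' evenly, so both endpoints are always sampled. Typical use: a short
#' profile perpendicular over a small vessel, with identical
#' endpoints across the reconstructions being compared.
#'
#' @param slice_image 2D HU matrix.
#' @param p0,p1 Length-2 numeric endpoints (x, y) in mm, inside the
#'   image.
#' @param sample_step Requested step in mm (default half the pixel
#'   spacing).
#' @param pixel_spacing mm per pixel.
#' @param method Interpolation method.
#' @return A `line_profile`: data frame with columns `position` (mm
#'   from `p0`) and `value` (HU); attributes `p0`, `p1`.
#' @export
line_profile <- function(slice_image, p0, p1, pixel_spacing,
                         sample_step = pixel_spacing / 2,
                         method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(is.matrix(slice_image), length(p0) == 2, length(p1) == 2)
  check_scalar_num(pixel_spacing, "pixel_spacing", positive = TRUE)
  check_scalar_num(sample_step, "sample_step", positive = TRUE)
  w <- ncol(slice_image) * pixel_spacing
  h <- nrow(slice_image) * pixel_spacing
  for (p in list(p0, p1))
    if (p[1] < 0 || p[1] > w || p[2] < 0 || p[2] > h)
      stopf("profile endpoint (%.1f, %.1f) mm outside the image", p[1], p[2])
  len <- sqrt(sum((p1 - p0)^2))
  nseg <- max(1L, round(len / sample_step))
  t <- seq(0, 1, length.out = nseg + 1L)
  xs <- p0[1] + t * (p1[1] - p0[1])
  ys <- p0[2] + t * (p1[2] - p0[2])
  vals <- interp_image(slice_image, xs, ys, pixel_spacing, method)
  structure(data.frame(position = t * len, value = vals),
            class = c("line_profile", "data.frame"), p0 = p0, p1 = p1)
}

interp_image <- function(img, xs, ys, spacing, method) {
  # continuous pixel coordinates: pixel c has centre at x = (c - 0.5) * spacing
  px <- xs / spacing + 0.5
  py <- ys / spacing + 0.5
  nx <- ncol(img); ny <- nrow(img)
  if (method == "nearest") {
    cc <- pmin(pmax(round(px), 1), nx)
    rr <- pmin(pmax(round(py), 1), ny)
    return(img[cbind(rr, cc)])
  }
  c0 <- pmin(pmax(floor(px), 1), nx); c1 <- pmin(c0 + 1, nx)
  r0 <- pmin(pmax(floor(py), 1), ny); r1 <- pmin(r0 + 1, ny)
  wx <- pmin(pmax(px - c0, 0), 1)
  wy <- pmin(pmax(py - r0, 0), 1)
  v00 <- img[cbind(r0, c0)]; v01 <- img[cbind(r0, c1)]
  v10 <- img[cbind(r1, c0)]; v11 <- img[cbind(r1, c1)]
  (1 - wy) * ((1 - wx) * v00 + wx * v01) + wy * ((1 - wx) * v10 + wx * v11)
}

#' @export
plot.line_profile <- function(x, ..., xlab = "position (mm)", ylab = "HU") {
  graphics::plot(x$position, x$value, type = "l", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
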