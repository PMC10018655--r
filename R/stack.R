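#' CT image stack
#'
#' A multi-slice CT image in Hounsfield units (HU) with its in-plane
#' pixel spacing and slice thickness. The voxel array is ordered
#' `[row, column, slice]`; in mm coordinates the centre of pixel
#' `(r, c)` is at `x = (c - 0.5) * pixel_spacing`,
#' `y = (r - 0.5) * pixel_spacing`, with the origin at the top-left
#' image corner.
#'
#' @param voxels Numeric 3D array `[row, col, slice]` (a matrix is
#'   promoted to a single-slice stack) of HU values.
#' @param pixel_spacing In-plane pixel spacing in mm (isotropic).
#' @param slice_thickness Reconstructed slice thickness in mm.
#' @param labels Named list of free-form identifiers (patient,
#'   protocol, reconstruction, ...).
#' @return An object of class `ct_stack`.
#' @export
ct_stack <- function(voxels, pixel_spacing, slice_thickness = 0.625,
                     labels = list()) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stopf("`voxels` must be a [row, col, slice] array")
  check_scalar_num(pixel_spacing, "pixel_spacing", positive = TRUE)
  check_scalar_num(slice_thickness, "slice_thickness", positive = TRUE)
  stopifnot(is.list(labels))
  structure(
    list(voxels = voxels, pixel_spacing = pixel_spacing,
         slice_thickness = slice_thickness, labels = labels),
    class = "ct_stack")
}

#' @export
print.ct_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_stack> %d x %d pixels, %d slice(s), %.4g mm/px, %.4g mm thick\n",
              d[1], d[2], d[3], x$pixel_spacing, x$slice_thickness))
  if (length(x$labels))
    cat("  labels:", paste(names(x$labels), unlist(x$labels),
                           sep = "=", collapse = ", "), "\n")
  rng <- range(x$voxels)
  cat(sprintf("  HU range: [%.1f, %.1f]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.ct_stack <- function(x) dim(x$voxels)

n_slices <- function(stack) dim(stack$voxels)[3]

get_slice <- function(stack, i) stack$voxels[, , i]
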