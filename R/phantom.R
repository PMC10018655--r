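#' Phantom configuration
#'
#' Describes a deterministic chest-like software phantom: an elliptical
#' body on an air background, with disk/ellipse structures (lungs,
#' aorta, mediastinal fat, small vessels) painted in HU. Rasterisation
#' is by pixel centre, so the phantom is a pure function of its
#' configuration -- no randomness is involved.
#'
#' @param image_size Pixels per side (square image), >= 128.
#' @param pixel_spacing In-plane pixel spacing in mm.
#' @param n_slices Number of identical slices in the stack.
#' @param slice_thickness Slice thickness in mm.
#' @param body_axes Length-2 numeric, semi-axes (x, y) of the body
#'   ellipse in mm. The body is centred in the image.
#' @param body_hu HU value inside the body ellipse (soft tissue ~ 35).
#' @param structures List of structures, each a list with fields
#'   `shape` ("disk" or "ellipse"), `center` (x, y in mm), `size`
#'   (radius in mm for disks, semi-axes (x, y) for ellipses) and `hu`.
#'   Structures are painted in order, later ones on top.
#' @return An object of class `phantom_config`.
#' @seealso [generate_phantom_stack()], [default_phantom_config()]
#' @export
phantom_config <- function(image_size = 512, pixel_spacing = 0.75,
                           n_slices = 20, slice_thickness = 0.625,
                           body_axes = c(150, 100), body_hu = 35,
                           structures = list()) {
  check_scalar_num(image_size, "image_size")
  if (image_size < 128) stopf("`image_size` must be >= 128")
  check_scalar_num(pixel_spacing, "pixel_spacing", positive = TRUE)
  check_scalar_num(n_slices, "n_slices", positive = TRUE)
  stopifnot(length(body_axes) == 2, all(body_axes > 0))
  extent <- image_size * pixel_spacing
  centre <- c(extent, extent) / 2
  for (s in structures) validate_structure(s, centre, body_axes)
  structure(
    list(image_size = as.integer(image_size), pixel_spacing = pixel_spacing,
         n_slices = as.integer(n_slices), slice_thickness = slice_thickness,
         body_axes = body_axes, body_hu = body_hu, structures = structures),
    class = "phantom_config")
}

validate_structure <- function(s, body_centre, body_axes) {
  if (!is.list(s) || is.null(s$shape) || is.null(s$center) || is.null(s$hu))
    stopf("each structure needs `shape`, `center`, `size`, `hu`")
  if (!s$shape %in% c("disk", "ellipse"))
    stopf("unknown structure shape '%s'", s$shape)
  sext <- if (s$shape == "disk") rep(s$size[1], 2) else s$size
  if (any(sext <= 0)) stopf("structure size must be > 0")
  # conservative containment: shrink the body ellipse by the structure extent
  a <- body_axes[1] - sext[1]; b <- body_axes[2] - sext[2]
  if (a <= 0 || b <= 0 ||
      ((s$center[1] - body_centre[1]) / a)^2 +
      ((s$center[2] - body_centre[2]) / b)^2 > 1)
    stopf("structure at (%.1f, %.1f) mm extends outside the body ellipse",
          s$center[1], s$center[2])
  invisible(TRUE)
}

#' Default chest phantom
#'
#' A chest-like arrangement: two low-attenuation lung fields
#' (-850 HU), an ascending-aorta disk (45 HU) and an anterior
#' mediastinal-fat disk (-100 HU) near the image centre, and a set of
#' small pulmonary vessels (1--4 mm disks, 50 HU) whose in-lung
#' placement can be jittered per patient via `vessel_shift` to emulate
#' between-patient anatomical variation.
#'
#' @param vessel_shift Length-2 numeric (mm) added to every vessel
#'   centre; keep within a few mm so vessels stay inside the lung.
#' @inheritParams phantom_config
#' @return A `phantom_config`.
#' @export
default_phantom_config <- function(image_size = 512, pixel_spacing = 0.75,
                                   n_slices = 20, vessel_shift = c(0, 0)) {
  extent <- image_size * pixel_spacing
  cx <- extent / 2; cy <- extent / 2
  vs <- function(p) list(shape = "disk",
                         center = p[1:2] + vessel_shift, size = p[3], hu = 50)
  structures <- c(
    list(
      list(shape = "ellipse", center = c(cx - 62, cy), size = c(52, 68), hu = -850),
      list(shape = "ellipse", center = c(cx + 62, cy), size = c(52, 68), hu = -850),
      list(shape = "disk", center = c(cx, cy + 12), size = 15, hu = 45),
      list(shape = "disk", center = c(cx, cy - 24), size = 12, hu = -100)
    ),
    lapply(list(c(cx - 70, cy - 25, 1.0), c(cx - 55, cy + 20, 2.0),
                c(cx - 80, cy + 10, 1.5), c(cx + 70, cy - 20, 1.0),
                c(cx + 58, cy + 25, 2.0), c(cx + 82, cy + 5, 1.0)),
           vs))
  phantom_config(image_size = image_size, pixel_spacing = pixel_spacing,
                 n_slices = n_slices, structures = structures)
}

#' Generate a noiseless phantom stack
#'
#' Rasterises a [phantom_config()] into a noiseless HU stack. A pixel
#' takes a structure's HU value iff its centre lies inside the
#' structure; pixels inside the body ellipse but in no structure take
#' `body_hu`; pixels outside the body are air (-1000 HU). All slices
#' share the same anatomy. The generator is deterministic: identical
#' configurations yield bit-identical stacks.
#'
#' @param config A `phantom_config`.
#' @return A [ct_stack()] with labels `kind = "phantom"`.
#' @export
#' @examples
#' cfg <- default_phantom_config(image_size = 128, n_slices = 2)
#' stk <- generate_phantom_stack(cfg)
generate_phantom_stack <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$image_size
  d <- config$pixel_spacing
  xs <- ((1:n) - 0.5) * d
  X <- matrix(xs, n, n, byrow = TRUE)   # x along columns
  Y <- matrix(xs, n, n)                 # y along rows
  extent <- n * d
  cx <- extent / 2; cy <- extent / 2
  img <- matrix(-1000, n, n)
  inside_body <- ((X - cx) / config$body_axes[1])^2 +
    ((Y - cy) / config$body_axes[2])^2 <= 1
  img[inside_body] <- config$body_hu
  for (s in config$structures) {
    ax <- if (s$shape == "disk") rep(s$size[1], 2) else s$size
    mask <- ((X - s$center[1]) / ax[1])^2 + ((Y - s$center[2]) / ax[2])^2 <= 1
    img[mask] <- s$hu
  }
  vox <- array(img, dim = c(n, n, config$n_slices))
  ct_stack(vox, pixel_spacing = d, slice_thickness = config$slice_thickness,
           labels = list(kind = "phantom"))
}
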