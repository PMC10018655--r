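#' Write / read an image stack as a raw container
#'
#' The canonical on-disk format for synthetic stacks: a directory with
#' `voxels.raw` (little-endian IEEE doubles, column-major
#' `[row, col, slice]`) and a JSON sidecar `meta.json` carrying the
#' array dimensions, pixel spacing (mm), slice thickness (mm) and
#' labels. The round trip is bit-exact.
#'
#' @param stack A [ct_stack()].
#' @param path Directory to create/write into.
#' @return `write_stack` returns `path` invisibly; `read_stack`
#'   returns a `ct_stack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ct_stack"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(dim = dim(stack$voxels),
               pixel_spacing_mm = stack$pixel_spacing,
               slice_thickness_mm = stack$slice_thickness,
               labels = stack$labels)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, "voxels.raw"), "wb")
  on.exit(close(con))
  writeBin(as.vector(stack$voxels), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  mpath <- file.path(path, "meta.json")
  vpath <- file.path(path, "voxels.raw")
  if (!file.exists(mpath) || !file.exists(vpath))
    stopf("'%s' is not a stack container (missing meta.json or voxels.raw)", path)
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  if (length(d) != 3) stopf("invalid dimensions in %s", mpath)
  con <- file(vpath, "rb")
  on.exit(close(con))
  vox <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
  if (length(vox) != prod(d)) stopf("voxel data truncated in %s", vpath)
  dim(vox) <- d
  ct_stack(vox, pixel_spacing = meta$pixel_spacing_mm,
           slice_thickness = meta$slice_thickness_mm,
           labels = as.list(meta$labels))
}

#' Write / read a rating set as CSV
#'
#' Header: `case_id,reader_id,question_id,condition,rating,scale_size`
#' plus a `coding` column recording the rating orientation
#' (`higher_better` or `questionnaire`). Files without the `coding`
#' column are read as questionnaire-coded (the convention of reading
#' forms, where 1 is the best answer). Reading re-validates ranges,
#' duplicates and pairing, with row-numbered errors.
#'
#' @param ratings A `rating_set`.
#' @param path CSV file path.
#' @return `write_ratings` returns `path` invisibly; `read_ratings` a
#'   `rating_set`.
#' @export
write_ratings <- function(ratings, path) {
  stopifnot(inherits(ratings, "rating_set"))
  df <- as.data.frame(ratings)
  df$coding <- attr(ratings, "coding")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  coding <- if ("coding" %in% names(df)) {
    cd <- unique(df$coding)
    if (length(cd) != 1) stopf("mixed `coding` values in %s", path)
    df$coding <- NULL
    cd
  } else "questionnaire"
  as_rating_set(df, coding = coding)
}

#' Write / read a 1D power-spectrum curve as CSV
#'
#' Columns: `freq_mm^-1`, `ps_hu2mm2` and, for cohort curves,
#' `relative_se_pct`.
#'
#' @param curve A `ps_curve`.
#' @param path CSV file path.
#' @return `write_ps_curve` returns `path` invisibly; `read_ps_curve`
#'   a `ps_curve`.
#' @export
write_ps_curve <- function(curve, path) {
  df <- data.frame(`freq_mm^-1` = curve$freq, ps_hu2mm2 = curve$ps,
                   check.names = FALSE)
  if (!is.null(curve$relative_se)) df$relative_se_pct <- curve$relative_se
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ps_curve
#' @export
read_ps_curve <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  out <- data.frame(freq = df[["freq_mm^-1"]], ps = df[["ps_hu2mm2"]])
  if ("relative_se_pct" %in% names(df)) out$relative_se <- df$relative_se_pct
  new_ps_curve(out)
}

#' Read dose records from CSV
#'
#' Expects columns `patient_id`, `protocol`, `ctdi_vol_mgy`,
#' `dlp_mgycm`; effective dose is computed from DLP on read.
#'
#' @param path CSV file path.
#' @param k_factor DLP-to-effective-dose coefficient.
#' @return A [dose_records()] data frame.
#' @export
read_dose_records <- function(path, k_factor = 0.015) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "protocol", "ctdi_vol_mgy", "dlp_mgycm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing columns in %s: %s", path,
                          paste(miss, collapse = ", "))
  dose_records(df$patient_id, df$protocol, df$ctdi_vol_mgy, df$dlp_mgycm,
               k_factor = k_factor)
}

#' @rdname read_dose_records
#' @param records A [dose_records()] data frame.
#' @export
write_dose_records <- function(records, path) {
  df <- data.frame(patient_id = records$patient_id,
                   protocol = records$protocol,
                   ctdi_vol_mgy = records$ctdi_vol,
                   dlp_mgycm = records$dlp)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
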