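#' Effective dose from DLP
#'
#' Effective dose in mSv estimated as `k_factor * dlp`, with the
#' standard adult chest conversion coefficient 0.015 mSv/(mGy cm) as
#' the default. The coefficient is configurable because published
#' values vary with tube voltage and anatomy.
#'
#' @param dlp Dose-length product in mGy cm (>= 0, vectorised).
#' @param k_factor Conversion coefficient in mSv/(mGy cm).
#' @return Effective dose in mSv.
#' @export
#' @examples
#' effective_dose(100)         # 1.5 mSv
#' effective_dose(166.7)       # ~2.5 mSv, a typical full-dose chest CT
effective_dose <- function(dlp, k_factor = 0.015) {
  if (any(dlp < 0)) stopf("`dlp` must be >= 0")
  check_scalar_num(k_factor, "k_factor", nonneg = TRUE)
  k_factor * dlp
}

#' Build a dose-record table
#'
#' @param patient_id Vector of patient identifiers.
#' @param protocol Protocol label per record (e.g. `"full_dose"`,
#'   `"uld"`).
#' @param ctdi_vol CTDIvol in mGy.
#' @param dlp DLP in mGy cm.
#' @param k_factor Conversion coefficient for [effective_dose()].
#' @return Data frame of class `dose_records` with columns
#'   `patient_id`, `protocol`, `ctdi_vol`, `dlp`, `effective_dose`,
#'   `k_factor`.
#' @export
dose_records <- function(patient_id, protocol, ctdi_vol, dlp, k_factor = 0.015) {
  n <- length(patient_id)
  if (length(protocol) != n || length(ctdi_vol) != n || length(dlp) != n)
    stopf("all dose-record columns must have equal length")
  if (any(ctdi_vol < 0) || any(dlp < 0)) stopf("dose quantities must be >= 0")
  structure(
    data.frame(patient_id = patient_id, protocol = protocol,
               ctdi_vol = ctdi_vol, dlp = dlp,
               effective_dose = effective_dose(dlp, k_factor),
               k_factor = k_factor),
    class = c("dose_records", "data.frame"))
}

#' Per-protocol dose summary
#'
#' Mean, minimum and maximum of CTDIvol, DLP and effective dose per
#' protocol, plus the ratio of protocol mean effective doses as a
#' percentage when exactly two protocols are present (smaller mean
#' over larger mean, e.g. an ultra-low-dose protocol at 2% of the
#' full-dose protocol).
#'
#' @param records A [dose_records()] data frame.
#' @return List with `per_protocol` (data frame: protocol, n, and
#'   mean/min/max of each quantity) and `dose_ratio_pct` (numeric or
#'   `NA` unless exactly two protocols).
#' @export
protocol_summary <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  agg <- function(f, nm) {
    a <- stats::aggregate(records[c("ctdi_vol", "dlp", "effective_dose")],
                   by = list(protocol = records$protocol), FUN = f)
    names(a)[-1] <- paste0(nm, "_", names(a)[-1])
    a
  }
  per <- Reduce(function(x, y) merge(x, y, by = "protocol"),
                list(agg(mean, "mean"), agg(min, "min"), agg(max, "max")))
  per$n <- as.vector(table(records$protocol)[per$protocol])
  ratio <- NA_real_
  if (nrow(per) == 2) {
    m <- sort(per$mean_effective_dose)
    ratio <- 100 * m[1] / m[2]
  }
  list(per_protocol = per, dose_ratio_pct = ratio)
}
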