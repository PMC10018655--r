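#' @keywords internal
"_PACKAGE"

## Internal validation helpers ------------------------------------------------

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (positive && x <= 0) stopf("`%s` must be > 0", name)
  if (nonneg && x < 0) stopf("`%s` must be >= 0", name)
  invisible(x)
}

#' Derive a stage seed from a global seed
#'
#' Maps a global integer seed and a stage label to a reproducible
#' 32-bit stage seed, so that every stochastic stage of a study draws
#' from its own stream and adding a stage never perturbs the streams of
#' existing stages.
#'
#' @param seed Global integer seed.
#' @param stage Character stage label (e.g. `"noise/full/asirv"`).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "ratings/full")
derive_seed <- function(seed, stage) {
  check_scalar_num(seed, "seed")
  stopifnot(is.character(stage), length(stage) == 1L)
  m <- 2147483647  # 2^31 - 1, Mersenne prime; Horner hash stays in double range
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% m
  as.integer(h %% (m - 1) + 1)
}

## Frequency axis of an unshifted DFT grid (cycles/mm)
fft_freq <- function(n, spacing) {
  c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1) / (n * spacing)
}
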