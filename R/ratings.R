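#' Observer-study design
#'
#' The factorial layout of a paired visual-grading study: every reader
#' rates every case on every question under both conditions.
#'
#' @param n_cases Number of cases (patients), >= 1.
#' @param n_readers Number of readers (observers), >= 1.
#' @param questions Data frame with columns `question_id` and
#'   `scale_size` (3 or 5), or `NULL` for the default battery of six
#'   five-step criterion questions (Q1--Q6) and four three-step
#'   acceptability questions (Q7--Q10).
#' @param conditions Character vector of length 2: `(reference, test)`.
#' @return An object of class `rating_design`.
#' @export
rating_design <- function(n_cases = 25, n_readers = 5, questions = NULL,
                          conditions = c("reference", "test")) {
  check_scalar_num(n_cases, "n_cases", positive = TRUE)
  check_scalar_num(n_readers, "n_readers", positive = TRUE)
  if (length(conditions) != 2 || anyDuplicated(conditions))
    stopf("`conditions` must be two distinct labels (reference, test)")
  if (is.null(questions))
    questions <- data.frame(
      question_id = paste0("Q", 1:10),
      scale_size = c(rep(5L, 6), rep(3L, 4)))
  stopifnot(is.data.frame(questions),
            all(c("question_id", "scale_size") %in% names(questions)))
  if (!all(questions$scale_size %in% c(3L, 5L)))
    stopf("scale_size must be 3 or 5")
  structure(
    list(n_cases = as.integer(n_cases), n_readers = as.integer(n_readers),
         questions = questions, conditions = conditions),
    class = "rating_design")
}

#' Latent threshold model for ordinal ratings
#'
#' A cumulative-threshold (ordered-categories) model for paired
#' ratings. For reader r, case i, question q and condition c the
#' latent value is
#' `z = mu_c + a_i + b_r + e`, with `mu_ref = 0`, `mu_test = delta`,
#' case effect `a_i ~ N(0, sigma_case^2)` and reader effect
#' `b_r ~ N(0, sigma_reader^2)` shared between the two conditions
#' (which is what makes the design paired), and independent residual
#' `e ~ N(0, sigma_noise^2)`. The ordinal category is
#' `1 + #\{thresholds below z\}`.
#'
#' With zero case and reader effects the population AUC comparing the
#' two conditions has the closed form `pnorm(delta / (sigma_noise *
#' sqrt(2)))`, which parameter-recovery tests exploit.
#'
#' @param delta Latent mean shift of the test condition.
#' @param sigma_case,sigma_reader Between-case / between-reader SDs
#'   (>= 0).
#' @param sigma_noise Residual SD (> 0).
#' @param thresholds Named list with elements `"3"` and `"5"`: strictly
#'   ascending cut-points (length `scale_size - 1`) on the latent axis.
#' @return An object of class `latent_rating_model`.
#' @export
latent_rating_model <- function(delta = 0, sigma_case = 0.5,
                                sigma_reader = 0.3, sigma_noise = 1,
                                thresholds = list(`3` = c(-1, 1),
                                                  `5` = c(-1.5, -0.5, 0.5, 1.5))) {
  check_scalar_num(delta, "delta")
  check_scalar_num(sigma_case, "sigma_case", nonneg = TRUE)
  check_scalar_num(sigma_reader, "sigma_reader", nonneg = TRUE)
  check_scalar_num(sigma_noise, "sigma_noise", positive = TRUE)
  for (nm in names(thresholds)) {
    th <- thresholds[[nm]]
    if (length(th) != as.integer(nm) - 1L || is.unsorted(th, strictly = TRUE))
      stopf("thresholds[['%s']] must be %d strictly ascending cut-points",
            nm, as.integer(nm) - 1L)
  }
  structure(
    list(delta = delta, sigma_case = sigma_case, sigma_reader = sigma_reader,
         sigma_noise = sigma_noise, thresholds = thresholds),
    class = "latent_rating_model")
}

#' Simulate a paired multi-reader rating set
#'
#' Draws ratings from the latent threshold model for every
#' (case, reader, question, condition) cell of the design. Case and
#' reader effects are drawn once per (case, question) and
#' (reader, question) and shared between conditions, preserving the
#' paired structure. Ratings are emitted in `"higher_better"` coding
#' (the ordinal category itself: a latent value below all thresholds
#' maps to 1, above all thresholds to `scale_size`); see
#' [orient_ratings()] for the questionnaire coding used by reading
#' forms in which 1 denotes the best answer.
#'
#' @param design A [rating_design()].
#' @param model A [latent_rating_model()].
#' @param seed Integer seed.
#' @return A `rating_set`: a data frame with columns `case_id`,
#'   `reader_id`, `question_id`, `condition`, `rating`, `scale_size`
#'   and attribute `coding = "higher_better"`.
#' @export
generate_ratings <- function(design, model, seed) {
  stopifnot(inherits(design, "rating_design"),
            inherits(model, "latent_rating_model"))
  check_scalar_num(seed, "seed")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  nc <- design$n_cases; nr <- design$n_readers
  out <- vector("list", nrow(design$questions))
  for (qi in seq_len(nrow(design$questions))) {
    q <- design$questions$question_id[qi]
    k <- design$questions$scale_size[qi]
    th <- model$thresholds[[as.character(k)]]
    if (is.null(th)) stopf("no thresholds for scale size %d", k)
    a <- stats::rnorm(nc, 0, model$sigma_case)
    b <- stats::rnorm(nr, 0, model$sigma_reader)
    grid <- expand.grid(case = seq_len(nc), reader = seq_len(nr),
                        cond = 1:2, KEEP.OUT.ATTRS = FALSE)
    mu <- ifelse(grid$cond == 2L, model$delta, 0)
    z <- mu + a[grid$case] + b[grid$reader] +
      stats::rnorm(nrow(grid), 0, model$sigma_noise)
    rating <- 1L + rowSums(outer(z, th, ">"))
    out[[qi]] <- data.frame(
      case_id = grid$case, reader_id = grid$reader, question_id = q,
      condition = design$conditions[grid$cond],
      rating = as.integer(rating), scale_size = k)
  }
  as_rating_set(do.call(rbind, out), coding = "higher_better")
}

#' Rating-set container
#'
#' Validates and classes a data frame of paired ordinal ratings. The
#' paired design requires both conditions for every
#' (case, reader, question) triple, ratings in `1..scale_size`, and no
#' duplicated cells.
#'
#' @param df Data frame with columns `case_id`, `reader_id`,
#'   `question_id`, `condition`, `rating`, `scale_size`.
#' @param coding `"higher_better"` (rating increases with quality) or
#'   `"questionnaire"` (1 is the best answer, as on the reading form).
#' @return The validated data frame with class `rating_set` and
#'   attribute `coding`.
#' @export
as_rating_set <- function(df, coding = c("higher_better", "questionnaire")) {
  coding <- match.arg(coding)
  need <- c("case_id", "reader_id", "question_id", "condition",
            "rating", "scale_size")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  bad <- which(df$rating < 1 | df$rating > df$scale_size |
                 df$rating != round(df$rating))
  if (length(bad))
    stopf("rating out of 1..scale_size range at row(s) %s",
          paste(utils::head(bad, 5), collapse = ", "))
  key <- paste(df$case_id, df$reader_id, df$question_id, df$condition)
  if (anyDuplicated(key))
    stopf("duplicated (case, reader, question, condition) at row %d",
          which(duplicated(key))[1])
  conds <- sort(unique(as.character(df$condition)))
  if (length(conds) != 2)
    stopf("a rating set must contain exactly two conditions (found %d)",
          length(conds))
  pair_key <- paste(df$case_id, df$reader_id, df$question_id)
  tab <- table(pair_key)
  if (any(tab != 2)) {
    off <- names(tab)[tab != 2][1]
    stopf("unpaired ratings: (case reader question) = (%s) lacks one condition", off)
  }
  structure(df, class = c("rating_set", "data.frame"), coding = coding)
}

#' @export
print.rating_set <- function(x, ...) {
  cat(sprintf("<rating_set> %d records, %d case(s) x %d reader(s) x %d question(s), coding '%s'\n",
              nrow(x), length(unique(x$case_id)), length(unique(x$reader_id)),
              length(unique(x$question_id)), attr(x, "coding")))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}
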