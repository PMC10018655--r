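#' Orient paired ratings so that larger means better
#'
#' Extracts one question from a [as_rating_set()] and maps ratings to
#' a common orientation in which larger oriented values always mean
#' better image quality. For sets in `"questionnaire"` coding (1 is
#' the best answer on the reading form: "confident that the criterion
#' is fulfilled" on five-step criterion scales, "fully acceptable" on
#' three-step acceptability scales) the scale is reversed:
#' `oriented = scale_size + 1 - rating`, so raw 1 maps to 5 on a
#' five-step scale and raw "fully acceptable" (1) maps to 3 on a
#' three-step scale. Sets in `"higher_better"` coding (the synthetic
#' generator's output) pass through unchanged.
#'
#' @param ratings A `rating_set`.
#' @param question_id The question to extract.
#' @param conditions Optional length-2 character `(reference, test)`;
#'   defaults to the sorted condition labels with the first as
#'   reference.
#' @return An object of class `oriented_ratings`: list with `test`,
#'   `reference` (equal-length integer vectors, pairing shared),
#'   `scale_size`, `case`, `reader`.
#' @export
orient_ratings <- function(ratings, question_id, conditions = NULL) {
  stopifnot(inherits(ratings, "rating_set"))
  coding <- attr(ratings, "coding")
  if (is.null(coding)) coding <- "questionnaire"
  df <- as.data.frame(ratings)
  df <- df[df$question_id == question_id, , drop = FALSE]
  if (!nrow(df)) stopf("no ratings for question '%s'", question_id)
  if (is.null(conditions)) conditions <- sort(unique(as.character(df$condition)))
  if (length(conditions) != 2) stopf("need exactly two conditions")
  k <- unique(df$scale_size)
  if (length(k) != 1) stopf("mixed scale sizes within question '%s'", question_id)
  oriented <- if (coding == "questionnaire") k + 1L - df$rating else df$rating
  key <- paste(df$case_id, df$reader_id)
  ref <- df$condition == conditions[1]
  tst <- df$condition == conditions[2]
  kr <- key[ref]; kt <- key[tst]
  if (length(kr) != length(kt) || !setequal(kr, kt)) {
    off <- c(setdiff(kr, kt), setdiff(kt, kr))[1]
    stopf("unpaired ratings for (case reader) = (%s) on question '%s'",
          off, question_id)
  }
  ord <- match(kr, kt)
  structure(
    list(test = as.integer(oriented[tst][ord]),
         reference = as.integer(oriented[ref]),
         scale_size = as.integer(k),
         case = df$case_id[ref], reader = df$reader_id[ref],
         conditions = conditions),
    class = "oriented_ratings")
}

#' VGC curve of paired oriented ratings
#'
#' For each threshold `t` from `scale_size` down to 1 plots the
#' fraction of reference ratings `>= t` (x) against the fraction of
#' test ratings `>= t` (y); the endpoints (0,0) and (1,1) complete the
#' curve. Both coordinates are non-decreasing along the curve. A curve
#' on the diagonal indicates identically distributed ratings.
#'
#' @param oriented An [orient_ratings()] result.
#' @return Data frame with columns `x` (reference cumulative
#'   fraction) and `y` (test cumulative fraction), ascending.
#' @export
vgc_curve <- function(oriented) {
  stopifnot(inherits(oriented, "oriented_ratings"))
  k <- oriented$scale_size
  nt <- length(oriented$test); nr <- length(oriented$reference)
  xs <- vapply(k:1, function(t) mean(oriented$reference >= t), 0)
  ys <- vapply(k:1, function(t) mean(oriented$test >= t), 0)
  df <- data.frame(x = c(0, xs), y = c(0, ys))
  df[nrow(df), ] <- c(1, 1)  # threshold 1 always includes everything
  df
}

#' Trapezoidal AUC under the VGC curve
#'
#' Area under the [vgc_curve()] by the trapezoidal rule. This equals,
#' identically, the tie-corrected pairwise exceedance statistic
#' `P(test > ref) + 0.5 * P(test = ref)` over all test x reference
#' rating pairs pooled across readers and cases. 0.5 indicates
#' similar ratings in the two conditions; values above 0.5 indicate
#' higher ratings for the test condition. The statistic is invariant
#' under any strictly monotone relabelling of the ordinal categories.
#'
#' @param oriented An [orient_ratings()] result.
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoidal <- function(oriented) {
  stopifnot(inherits(oriented, "oriented_ratings"))
  # computed through the rank-sum form of the pairwise statistic, which is
  # algebraically the trapezoid area under vgc_curve() but exact in floating
  # point (no accumulation of fractional trapezoids)
  pairwise_auc(oriented$test, oriented$reference)
}

## Fast tie-corrected pairwise AUC from two rating vectors (identical to the
## trapezoidal area; used in bootstrap loops where speed matters).
pairwise_auc <- function(test, reference) {
  nt <- length(test); nr <- length(reference)
  r <- rank(c(test, reference))
  (sum(r[seq_len(nt)]) - nt * (nt + 1) / 2) / (nt * nr)
}

## Same, from per-category counts (ct, cr of equal length = scale size)
counts_auc <- function(ct, cr) {
  below <- cumsum(cr) - cr  # reference strictly below each category
  sum(ct * (below + cr / 2)) / (sum(ct) * sum(cr))
}

#' Binormal AUC by maximum likelihood
#'
#' Fits a latent-normal (binormal) model to the two ordinal samples:
#' shared cut-points, reference latent N(0, 1), test latent
#' N(mu, sigma^2), by maximising the multinomial likelihood of the
#' observed category counts. The fitted AUC is
#' `pnorm(mu / sqrt(1 + sigma^2))` (equivalently
#' `pnorm(a / sqrt(1 + b^2))` with the conventional binormal
#' parameters `a = mu / sigma`, `b = 1 / sigma`).
#'
#' @param oriented An [orient_ratings()] result.
#' @return List with `auc`, `mu`, `sigma`, `cutpoints`,
#'   `convergence` (0 = converged).
#' @export
auc_binormal <- function(oriented) {
  stopifnot(inherits(oriented, "oriented_ratings"))
  k <- oriented$scale_size
  ct <- tabulate(oriented$test, nbins = k)
  cr <- tabulate(oriented$reference, nbins = k)
  pooled <- ct + cr
  used <- which(pooled > 0)
  if (length(used) < 2)
    stopf("all ratings fall in one category; binormal fit is degenerate")
  # collapse unused categories; cut-points only needed between used ones
  m <- length(used)
  ctu <- ct[used]; cru <- cr[used]
  pool_cum <- cumsum(ctu + cru) / sum(pooled)
  c_init <- stats::qnorm(pmin(pmax(pool_cum[-m], 1e-3), 1 - 1e-3))
  mu0 <- (sum(ctu * seq_len(m)) / sum(ctu) - sum(cru * seq_len(m)) / sum(cru))
  par0 <- c(mu0, 0, c_init[1], if (m > 2) log(pmax(diff(c_init), 1e-3)))
  nll <- function(p) {
    mu <- p[1]; sg <- exp(p[2])
    cp <- p[3]
    if (m > 2) cp <- c(cp, cp + cumsum(exp(p[4:(m + 1)])))
    pr_r <- diff(c(0, stats::pnorm(cp), 1))
    pr_t <- diff(c(0, stats::pnorm((cp - mu) / sg), 1))
    -sum(cru * log(pmax(pr_r, 1e-300))) - sum(ctu * log(pmax(pr_t, 1e-300)))
  }
  fit <- stats::optim(par0, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  mu <- fit$par[1]; sg <- exp(fit$par[2])
  cp <- fit$par[3]
  if (m > 2) cp <- c(cp, cp + cumsum(exp(fit$par[4:(m + 1)])))
  list(auc = stats::pnorm(mu / sqrt(1 + sg^2)), mu = mu, sigma = sg,
       cutpoints = cp, convergence = fit$convergence)
}

#' Bootstrap AUC_VGC with fixed- or random-reader resampling
#'
#' Computes the point AUC (trapezoidal by default, binormal on
#' request) for one question and a percentile bootstrap confidence
#' interval from trapezoidal replicate AUCs.
#'
#' In the *fixed-reader* analysis, cases are resampled with
#' replacement and every original reader's paired ratings for each
#' drawn case are kept, so conclusions apply to the participating
#' readers only. In the *random-reader* analysis readers are first
#' resampled with replacement and cases are then resampled, so
#' conclusions generalise to a population of readers (at the price of
#' wider intervals). Pairing is preserved throughout: a drawn case
#' contributes both its test and its reference ratings.
#'
#' @param ratings A `rating_set`.
#' @param question_id Question to analyse.
#' @param mode `"fixed_reader"` or `"random_reader"`.
#' @param n_boot Number of bootstrap replicates (>= 100 recommended
#'   for CI use; default 2000).
#' @param seed Integer seed (mandatory, for reproducibility).
#' @param estimator Point estimator, `"trapezoidal"` or `"binormal"`.
#' @param conditions Passed to [orient_ratings()].
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `vgc_result`: list with `auc`, `ci_low`,
#'   `ci_high`, `mode`, `estimator`, `n_boot`, `seed`, `significant`
#'   (CI excludes 0.5), `boot_auc` (replicates), `per_reader_auc`
#'   (diagnostic), `question_id`.
#' @export
bootstrap_vgc <- function(ratings, question_id,
                          mode = c("fixed_reader", "random_reader"),
                          n_boot = 2000, seed,
                          estimator = c("trapezoidal", "binormal"),
                          conditions = NULL, conf_level = 0.95) {
  mode <- match.arg(mode)
  estimator <- match.arg(estimator)
  check_scalar_num(n_boot, "n_boot", positive = TRUE)
  check_scalar_num(seed, "seed")
  oriented <- orient_ratings(ratings, question_id, conditions)
  cases <- unique(oriented$case)
  readers <- unique(oriented$reader)
  ncase <- length(cases); nread <- length(readers)
  if (ncase < 2) stopf("need at least 2 cases to bootstrap")
  # case x reader matrices of oriented ratings
  ci <- match(oriented$case, cases)
  ri <- match(oriented$reader, readers)
  Mt <- matrix(NA_integer_, ncase, nread)
  Mr <- matrix(NA_integer_, ncase, nread)
  Mt[cbind(ci, ri)] <- oriented$test
  Mr[cbind(ci, ri)] <- oriented$reference
  point <- if (estimator == "trapezoidal") auc_trapezoidal(oriented)
           else auc_binormal(oriented)$auc
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  boot <- vapply(seq_len(n_boot), function(b) {
    rs <- if (mode == "random_reader") sample.int(nread, replace = TRUE)
          else seq_len(nread)
    cs <- sample.int(ncase, replace = TRUE)
    pairwise_auc(as.vector(Mt[cs, rs]), as.vector(Mr[cs, rs]))
  }, 0)
  qs <- stats::quantile(boot, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                        names = FALSE)
  per_reader <- vapply(seq_len(nread), function(r)
    pairwise_auc(Mt[, r], Mr[, r]), 0)
  names(per_reader) <- as.character(readers)
  structure(
    list(auc = point, ci_low = qs[1], ci_high = qs[2], mode = mode,
         estimator = estimator, n_boot = as.integer(n_boot),
         seed = as.integer(seed),
         significant = qs[1] > 0.5 || qs[2] < 0.5,
         boot_auc = boot, per_reader_auc = per_reader,
         question_id = question_id, conf_level = conf_level),
    class = "vgc_result")
}

#' @export
print.vgc_result <- function(x, ...) {
  cat(sprintf("<vgc_result> %s: AUC_VGC = %.3f, %d%% CI [%.3f, %.3f] (%s, %s, %d reps)%s\n",
              x$question_id, x$auc, round(100 * x$conf_level), x$ci_low,
              x$ci_high, sub("_", " ", x$mode), x$estimator, x$n_boot,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' @export
plot.vgc_result <- function(x, ratings = NULL, ...) {
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3,
                 xlab = "reference cumulative fraction",
                 ylab = "test cumulative fraction", ...)
  invisible(x)
}

#' Per-question VGC table
#'
#' Runs [bootstrap_vgc()] for every question in a rating set and
#' returns one row per question.
#'
#' @inheritParams bootstrap_vgc
#' @param question_ids Questions to analyse (default: all, in order of
#'   first appearance).
#' @return Data frame with columns `question`, `estimator`, `mode`,
#'   `auc`, `ci_low`, `ci_high`, `significant`.
#' @export
vgc_table <- function(ratings, question_ids = NULL,
                      mode = "fixed_reader", n_boot = 2000, seed = 1,
                      estimator = "trapezoidal", conditions = NULL) {
  if (is.null(question_ids)) question_ids <- unique(ratings$question_id)
  rows <- lapply(seq_along(question_ids), function(i) {
    v <- bootstrap_vgc(ratings, question_ids[i], mode = mode, n_boot = n_boot,
                       seed = derive_seed(seed, paste0("vgc/", question_ids[i])),
                       estimator = estimator, conditions = conditions)
    data.frame(question = question_ids[i], estimator = v$estimator,
               mode = v$mode, auc = v$auc, ci_low = v$ci_low,
               ci_high = v$ci_high, significant = v$significant)
  })
  do.call(rbind, rows)
}

#' Answer-proportion table
#'
#' For each question and condition, the proportion of ratings in each
#' answer category, pooled over readers and cases (in the set's own
#' rating coding). Proportions in each (question, condition) cell sum
#' to 1.
#'
#' @param ratings A `rating_set`.
#' @param question_ids Questions to tabulate (default all).
#' @return Data frame with columns `question`, `condition`, `rating`,
#'   `proportion`.
#' @export
proportion_table <- function(ratings, question_ids = NULL) {
  stopifnot(inherits(ratings, "rating_set"))
  df <- as.data.frame(ratings)
  if (!is.null(question_ids)) df <- df[df$question_id %in% question_ids, ]
  if (!nrow(df)) stopf("no ratings selected")
  out <- do.call(rbind, lapply(split(df, df[c("question_id", "condition")],
                                     drop = TRUE), function(g) {
    k <- g$scale_size[1]
    counts <- tabulate(g$rating, nbins = k)
    data.frame(question = g$question_id[1], condition = g$condition[1],
               rating = seq_len(k), proportion = counts / sum(counts))
  }))
  rownames(out) <- NULL
  out[order(out$question, out$condition, out$rating), ]
}
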