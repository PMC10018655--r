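# Shared fixtures and independent oracles, built in code at test time.

# flat (zero) stack for pure-noise experiments
flat_stack <- function(side = 256, n_slices = 20, spacing = 0.75) {
  ct_stack(array(0, c(side, side, n_slices)), pixel_spacing = spacing)
}

# oriented_ratings straight from two rating vectors (pairing irrelevant for
# the pooled statistics; fabricated ids keep the object valid)
make_oriented <- function(test, reference, scale_size = 5) {
  structure(
    list(test = as.integer(test), reference = as.integer(reference),
         scale_size = as.integer(scale_size),
         case = seq_along(test), reader = rep(1L, length(test)),
         conditions = c("ref", "test")),
    class = "oriented_ratings")
}

# exhaustive pairwise AUC oracle: wins + half ties over all test x ref pairs
auc_oracle <- function(test, reference) {
  cmp <- outer(test, reference, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# a small paired rating set built by hand (2 cases x 2 readers x 1 question)
tiny_rating_set <- function(ratings_test = c(4, 5, 3, 4),
                            ratings_ref = c(2, 3, 2, 1),
                            coding = "higher_better") {
  grid <- expand.grid(case_id = 1:2, reader_id = 1:2)
  as_rating_set(rbind(
    data.frame(grid, question_id = "Q1", condition = "test",
               rating = ratings_test, scale_size = 5L),
    data.frame(grid, question_id = "Q1", condition = "ref",
               rating = ratings_ref, scale_size = 5L)),
    coding = coding)
}

# recovery-experiment thresholds: cut-points centred between the condition
# means (delta/2), equally spaced over +/- 1
centered_thresholds <- function(delta) {
  list(`3` = delta / 2 + c(-0.6, 0.6),
       `5` = delta / 2 + c(-1, -1 / 3, 1 / 3, 1))
}
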