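test_that("questionnaire scales are reversed so larger means better", {
  rs <- tiny_rating_set(ratings_test = c(1, 1, 2, 1),
                        ratings_ref = c(5, 4, 5, 5),
                        coding = "questionnaire")
  o <- orient_ratings(rs, "Q1")
  # raw 1 ("confident fulfilled") -> oriented 5
  expect_equal(sort(o$test), c(4, 5, 5, 5))
  expect_equal(sort(o$reference), c(1, 1, 1, 2))
  # higher_better sets pass through unchanged
  rs2 <- tiny_rating_set(coding = "higher_better")
  o2 <- orient_ratings(rs2, "Q1", conditions = c("ref", "test"))
  expect_equal(sort(o2$test), c(3, 4, 4, 5))
})

test_that("three-step acceptability maps fully acceptable to oriented 3", {
  grid <- expand.grid(case_id = 1:2, reader_id = 1)
  df <- rbind(
    data.frame(grid, question_id = "Q7", condition = "test",
               rating = c(1L, 2L), scale_size = 3L),   # fully, probably
    data.frame(grid, question_id = "Q7", condition = "ref",
               rating = c(3L, 3L), scale_size = 3L))   # unacceptable
  rs <- as_rating_set(df, coding = "questionnaire")
  o <- orient_ratings(rs, "Q7")
  expect_equal(sort(o$test), c(2, 3))
  expect_equal(o$reference, c(1, 1))
})

test_that("missing pair members are reported with the offending cell", {
  rs <- tiny_rating_set()
  df <- as.data.frame(rs)
  expect_error(as_rating_set(df[-3, ]), "1 2")
})

test_that("the VGC curve matches brute-force threshold enumeration", {
  o <- make_oriented(test = c(3, 3, 4), reference = c(1, 2, 3))
  cv <- vgc_curve(o)
  # thresholds 5,4,3,2,1 -> (x, y) by direct counting
  expect_equal(cv$x, c(0, 0, 0, 1/3, 2/3, 1))
  expect_equal(cv$y, c(0, 0, 1/3, 1, 1, 1))
  # identical arms sit on the diagonal
  oid <- make_oriented(c(1, 3, 5, 2), c(1, 3, 5, 2))
  cvid <- vgc_curve(oid)
  expect_equal(cvid$x, cvid$y)
  # perfect separation passes through (0, 1)
  osep <- make_oriented(c(5, 5), c(1, 1))
  expect_true(any(vgc_curve(osep)$x == 0 & vgc_curve(osep)$y == 1))
})

test_that("trapezoidal AUC equals the tie-splitting pairwise statistic", {
  o <- make_oriented(c(3, 3, 4), c(1, 2, 3))
  expect_equal(auc_trapezoidal(o), 8 / 9, tolerance = 1e-12)  # (7 + 2/2)/9
  # identical multisets -> exactly 0.5
  o2 <- make_oriented(c(1, 2, 3, 4, 5, 3), c(3, 1, 4, 2, 5, 3))
  expect_identical(auc_trapezoidal(o2), 0.5)
  # complementarity AUC(t, r) + AUC(r, t) = 1
  set.seed(40)
  for (i in 1:20) {
    t <- sample(1:5, 17, replace = TRUE)
    r <- sample(1:5, 11, replace = TRUE)
    expect_equal(auc_trapezoidal(make_oriented(t, r)) +
                   auc_trapezoidal(make_oriented(r, t)), 1, tolerance = 1e-12)
  }
})

test_that("trapezoidal AUC equals the exhaustive oracle on random instances", {
  set.seed(41)
  for (i in 1:200) {
    k <- sample(c(3, 5), 1)
    nt <- sample(1:50, 1); nr <- sample(1:50, 1)
    t <- sample(seq_len(k), nt, replace = TRUE)
    r <- sample(seq_len(k), nr, replace = TRUE)
    expect_equal(auc_trapezoidal(make_oriented(t, r, k)), auc_oracle(t, r),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone relabelling", {
  set.seed(42)
  relabel <- c(1, 3, 4, 8, 9)  # strictly increasing map of 1..5
  for (i in 1:25) {
    t <- sample(1:5, 20, replace = TRUE)
    r <- sample(1:5, 20, replace = TRUE)
    a1 <- auc_trapezoidal(make_oriented(t, r))
    a2 <- auc_oracle(relabel[t], relabel[r])
    expect_equal(a1, a2, tolerance = 1e-12)
  }
})

test_that("binormal fit recovers the generative AUC and rejects degeneracy", {
  o <- make_oriented(rep(1:5, 40), rep(1:5, 40))
  expect_equal(auc_binormal(o)$auc, 0.5, tolerance = 0.01)
  des <- rating_design(n_cases = 3000, n_readers = 1,
                       questions = data.frame(question_id = "Q1",
                                              scale_size = 5L))
  mdl <- latent_rating_model(delta = 1, sigma_case = 0, sigma_reader = 0)
  rs <- generate_ratings(des, mdl, seed = 3)
  fit <- auc_binormal(orient_ratings(rs, "Q1"))
  expect_equal(fit$convergence, 0)
  expect_equal(fit$auc, pnorm(1 / sqrt(2)), tolerance = 0.03)
  expect_equal(fit$mu, 1, tolerance = 0.1)
  expect_error(auc_binormal(make_oriented(c(2, 2), c(2, 2))), "one category")
})

test_that("bootstrap CIs are deterministic and collapse under separation", {
  rs <- generate_ratings(rating_design(n_cases = 10, n_readers = 3),
                         latent_rating_model(delta = 0.8), seed = 12)
  b1 <- bootstrap_vgc(rs, "Q1", n_boot = 300, seed = 5)
  b2 <- bootstrap_vgc(rs, "Q1", n_boot = 300, seed = 5)
  expect_identical(b1$boot_auc, b2$boot_auc)
  expect_identical(c(b1$ci_low, b1$ci_high), c(b2$ci_low, b2$ci_high))
  # every test rating strictly above every reference rating -> CI [1, 1]
  sep <- tiny_rating_set(ratings_test = c(5, 5, 4, 4),
                         ratings_ref = c(2, 1, 2, 1))
  bs <- bootstrap_vgc(sep, "Q1", n_boot = 100, seed = 6,
                      conditions = c("ref", "test"))
  expect_equal(bs$auc, 1)
  expect_equal(c(bs$ci_low, bs$ci_high), c(1, 1))
  expect_true(bs$significant)
})

test_that("random-reader intervals are wider than fixed-reader on average", {
  widths <- sapply(1:8, function(s) {
    rs <- generate_ratings(rating_design(n_cases = 25, n_readers = 5),
                           latent_rating_model(delta = 0.5, sigma_reader = 0.5),
                           seed = s)
    bf <- bootstrap_vgc(rs, "Q1", mode = "fixed_reader", n_boot = 400,
                        seed = 100 + s)
    br <- bootstrap_vgc(rs, "Q1", mode = "random_reader", n_boot = 400,
                        seed = 200 + s)
    c(bf$ci_high - bf$ci_low, br$ci_high - br$ci_low)
  })
  expect_gt(mean(widths[2, ]), mean(widths[1, ]))
})

test_that("answer proportions match a direct tally and sum to one", {
  rs <- tiny_rating_set(ratings_test = c(4, 4, 4, 4), ratings_ref = c(2, 2, 3, 5))
  pt <- proportion_table(rs)
  test_rows <- pt[pt$condition == "test", ]
  expect_equal(test_rows$proportion[test_rows$rating == 4], 1)
  ref_rows <- pt[pt$condition == "ref", ]
  expect_equal(ref_rows$proportion[ref_rows$rating == 2], 0.5)
  agg <- aggregate(proportion ~ question + condition, pt, sum)
  expect_true(all(abs(agg$proportion - 1) < 1e-12))
  # generated set: counts match a hand tally for one cell
  rs2 <- generate_ratings(rating_design(n_cases = 25, n_readers = 5),
                          latent_rating_model(delta = 1), seed = 9)
  pt2 <- proportion_table(rs2, "Q3")
  cell <- rs2$rating[rs2$question_id == "Q3" & rs2$condition == "test"]
  expect_equal(pt2$proportion[pt2$condition == "test"],
               as.numeric(table(factor(cell, levels = 1:5))) / length(cell))
})

test_that("the rank form of the AUC equals the trapezoid area under the curve", {
  set.seed(43)
  for (i in 1:30) {
    k <- sample(c(3, 5), 1)
    o <- make_oriented(sample(seq_len(k), 15, replace = TRUE),
                       sample(seq_len(k), 12, replace = TRUE), k)
    cv <- vgc_curve(o)
    trap <- sum(diff(cv$x) * (head(cv$y, -1) + tail(cv$y, -1)) / 2)
    expect_equal(auc_trapezoidal(o), trap, tolerance = 1e-12)
  }
})
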