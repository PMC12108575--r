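test_that("ANOVA F matches hand calculations and degenerate conventions", {
  expect_equal(anova_f_score(c(1, 2, 3, 1, 2, 3),
                             rep(c("a", "b"), each = 3)), 0)
  expect_identical(anova_f_score(c(0, 0, 1, 1), c("a", "a", "b", "b")), Inf)
  # groups {1,2} vs {3,4}: between MS 4 at 1 df, within MS 0.5 at 2 df
  expect_equal(anova_f_score(c(1, 2, 3, 4), c("a", "a", "b", "b")), 8.0)
  # both groups constant and equal -> 0 by convention
  expect_equal(anova_f_score(c(2, 2, 2, 2), c("a", "a", "b", "b")), 0)
})

test_that("ANOVA F equals the squared pooled-variance t on random instances", {
  set.seed(401)
  for (i in 1:200) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    a <- round(rnorm(na, sample(0:3, 1)), 3)
    b <- round(rnorm(nb, sample(0:3, 1)), 3)
    f <- anova_f_score(c(a, b), rep(c("x", "y"), c(na, nb)))
    expect_equal(f, t_pooled(a, b)^2, tolerance = 1e-10)
  }
})

test_that("RFE keeps a perfectly separating feature among noise", {
  set.seed(7)
  n <- 20
  y <- rep(c("case", "control"), each = n / 2)
  x <- matrix(rnorm(n * 21), n, 21,
              dimnames = list(NULL, sprintf("f%02d", 1:21)))
  x[, "f11"] <- ifelse(y == "case", 3, -3) + rnorm(n, sd = 0.1)
  res <- select_rfe(x, y, n_select = 1)
  expect_identical(res$feature_id, "f11")
})

test_that("RFE returns everything when nothing must be eliminated and breaks ties by ID", {
  set.seed(8)
  x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, c("fa", "fb", "fc", "fd")))
  y <- rep(c("case", "control"), 5)
  res <- select_rfe(x, y, n_select = 4)
  expect_setequal(res$feature_id, colnames(x))
  expect_error(select_rfe(x, y, n_select = 0), "n_select")

  # duplicated informative column: exactly one of the twins survives,
  # and the tie-break keeps the lexicographically smaller ID
  x2 <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("dupA", "dupB", "noise")))
  x2[, "dupA"] <- ifelse(y == "case", 2, -2)
  x2[, "dupB"] <- x2[, "dupA"]
  res2 <- select_rfe(x2, y, n_select = 1)
  expect_identical(res2$feature_id, "dupA")
})

test_that("random-forest importance recovers planted features and is seeded", {
  co <- small_planted(seed = 42)
  d <- transformed_xy(co)
  res <- select_rf_importance(d$x, d$y, n_select = 10, seed = 99)
  expect_gte(length(intersect(res$feature_id, co$truth_informative)), 8)
  res2 <- select_rf_importance(d$x, d$y, n_select = 10, seed = 99)
  expect_identical(res$feature_id, res2$feature_id)

  # single feature: selected with the whole importance mass
  x1 <- d$x[, 1, drop = FALSE]
  r1 <- select_rf_importance(x1, d$y, n_select = 1, seed = 1)
  expect_identical(r1$feature_id, colnames(x1))
  expect_equal(r1$score / sum(r1$score), 1.0)
})

test_that("pure-noise importances spread over features and differ across seeds", {
  co <- null_cohort(synthetic_spec(n_features = 80, seed = 31))
  d <- transformed_xy(co)
  a <- select_rf_importance(d$x, d$y, n_select = 10, seed = 1)
  b <- select_rf_importance(d$x, d$y, n_select = 10, seed = 2)
  expect_true(all(a$score >= 0))
  expect_false(identical(a$feature_id, b$feature_id))
})

test_that("LASSO support shrinks with the penalty and covers planted features", {
  co <- small_planted(seed = 43)
  d <- transformed_xy(co)
  expect_identical(nrow(select_lasso(d$x, d$y, l1_strength = 1e3)), 0L)
  weak <- select_lasso(d$x, d$y, l1_strength = 1e-4)
  # the strongest planted features (largest univariate F) must be in
  # the near-unpenalised support
  f <- vapply(co$truth_informative,
              function(id) anova_f_score(d$x[, id], d$y$label), numeric(1))
  strong <- names(sort(f, decreasing = TRUE))[1:3]
  expect_true(all(strong %in% weak$feature_id))
  expect_error(select_lasso(d$x, d$y, l1_strength = 0), "l1_strength")
})

test_that("duplicated informative columns keep a joint LASSO footprint", {
  set.seed(12)
  y <- rep(c("case", "control"), each = 15)
  x <- matrix(rnorm(30 * 5), 30, 5,
              dimnames = list(NULL, c("dupA", "dupB", "n1", "n2", "n3")))
  x[, "dupA"] <- ifelse(y == "case", 1.5, -1.5) + rnorm(30, sd = 0.2)
  x[, "dupB"] <- x[, "dupA"]
  res <- select_lasso(scale(x), y, l1_strength = 0.05)
  expect_gte(length(intersect(res$feature_id, c("dupA", "dupB"))), 1)
})

test_that("k-best ranks by F with a lexicographic tie-break", {
  x <- matrix(c(1, 2, 3, 4,
                4, 3, 2.5, 2), 4, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- c("a", "a", "b", "b")
  res <- select_kbest(x, y, k = 1)
  f1 <- anova_f_score(x[, 1], y)
  f2 <- anova_f_score(x[, 2], y)
  expect_identical(res$feature_id, colnames(x)[which.max(c(f1, f2))])

  expect_setequal(select_kbest(x, y, k = 2)$feature_id, colnames(x))
  expect_error(select_kbest(x, y, k = 0), "k must")
  expect_error(select_kbest(x, y, k = 3), "exceeds")

  # identical columns tie exactly -> smaller ID first
  xt <- cbind(zB = x[, 1], zA = x[, 1])
  res_tie <- select_kbest(xt, y, k = 2)
  expect_identical(res_tie$feature_id, c("zA", "zB"))
})

test_that("consensus voting matches exhaustive counting on the worked example", {
  sets <- list(c("a", "b", "c"), c("b", "c"), c("c", "d"), "c")
  cv <- consensus_vote(sets, min_votes = 3)
  expect_identical(cv$features, "c")
  tally <- stats::setNames(cv$tally$votes, cv$tally$feature_id)
  expect_identical(tally[c("a", "b", "c", "d")],
                   c(a = 1L, b = 2L, c = 4L, d = 1L))

  expect_setequal(consensus_vote(sets, min_votes = 1)$features,
                  c("a", "b", "c", "d"))
  same <- replicate(4, c("x", "y"), simplify = FALSE)
  expect_setequal(consensus_vote(same, min_votes = 4)$features, c("x", "y"))
  expect_error(consensus_vote(sets, min_votes = 5), "exceed")
})

test_that("signature accumulation matches fold-hit counting and orders output", {
  folds <- list(c("a", "b"), "a", c("a", "c"))
  fm <- accumulate_fminimal(folds, min_folds = 3)
  expect_identical(fm$feature_id, "a")
  expect_identical(fm$fold_hits, 3L)

  all_f <- accumulate_fminimal(folds, min_folds = 1)
  expect_identical(all_f$feature_id, c("a", "b", "c"))  # desc hits, then ID
  expect_identical(all_f$fold_hits, c(3L, 1L, 1L))

  empty <- accumulate_fminimal(list(character(0), character(0), character(0)), 3)
  expect_identical(nrow(empty), 0L)
})

test_that("consensus and accumulation shrink weakly as thresholds rise", {
  set.seed(77)
  for (i in 1:50) {
    sets <- replicate(4, sample(letters[1:8], sample(1:6, 1)), simplify = FALSE)
    sizes <- vapply(1:4, function(v) length(consensus_vote(sets, v)$features),
                    integer(1))
    expect_true(all(diff(sizes) <= 0))
    folds <- replicate(5, sample(letters[1:8], sample(0:5, 1)), simplify = FALSE)
    fsizes <- vapply(1:5, function(v) nrow(accumulate_fminimal(folds, v)),
                     integer(1))
    expect_true(all(diff(fsizes) <= 0))
  }
})

test_that("selectors are deterministic on fixed input and seed", {
  co <- small_planted(seed = 44, n_features = 40)
  d <- transformed_xy(co)
  expect_identical(select_rfe(d$x, d$y, 5), select_rfe(d$x, d$y, 5))
  expect_identical(select_kbest(d$x, d$y, 5), select_kbest(d$x, d$y, 5))
  expect_identical(select_lasso(d$x, d$y, 0.01), select_lasso(d$x, d$y, 0.01))
  expect_identical(select_rf_importance(d$x, d$y, 5, seed = 3),
                   select_rf_importance(d$x, d$y, 5, seed = 3))
})
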