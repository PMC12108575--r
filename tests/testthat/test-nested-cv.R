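make_lab <- function(n_case, n_control) {
  sample_labels(sprintf("s%03d", seq_len(n_case + n_control)),
                rep(c("case", "control"), c(n_case, n_control)))
}

test_that("the study-shape fold plan is 10 folds of 54 train / 6 validation", {
  plan <- make_outer_folds(60, 0.10, make_lab(31, 29), seed = 1)
  expect_length(plan$outer, 10)
  expect_true(all(vapply(plan$outer, function(f) length(f$train), integer(1)) == 54))
  expect_true(all(vapply(plan$outer, function(f) length(f$validation), integer(1)) == 6))
})

test_that("fold sizing handles the leave-one-out limit and remainders", {
  plan1 <- make_outer_folds(10, 0.10, make_lab(5, 5), seed = 2)
  expect_length(plan1$outer, 10)
  expect_true(all(lengths(lapply(plan1$outer, `[[`, "validation")) == 1))

  plan2 <- make_outer_folds(61, 0.10, make_lab(31, 30), seed = 3)
  sizes <- sort(lengths(lapply(plan2$outer, `[[`, "validation")), decreasing = TRUE)
  expect_identical(as.integer(sizes), c(7L, rep(6L, 9)))

  expect_error(make_outer_folds(60, 0, make_lab(31, 29)), "fraction")
  expect_error(make_outer_folds(60, 1.2, make_lab(31, 29)), "fraction")
})

test_that("inner folds stratify within one sample per class of the parent mix", {
  lab <- make_lab(31, 29)
  plan <- make_outer_folds(60, 0.10, lab, seed = 4)
  ti <- plan$outer[[1]]$train
  inner <- make_inner_folds(ti, lab, k = 5, seed = 5)
  expect_length(inner, 5)
  val_union <- sort(unlist(lapply(inner, `[[`, "validation")))
  expect_identical(val_union, sort(ti))
  # |T_i| = 54 at k = 5: every inner training set has 43 or 44 samples (~80%)
  tsizes <- lengths(lapply(inner, `[[`, "train"))
  expect_true(all(tsizes %in% c(43L, 44L)))

  parent_frac <- mean(lab$label[ti] == "case")
  for (f in inner) {
    n_val <- length(f$validation)
    expect_lte(abs(sum(lab$label[f$validation] == "case") - parent_frac * n_val), 1)
  }
})

test_that("two-fold splits of a balanced quartet are exact halves", {
  lab <- make_lab(2, 2)
  inner <- make_inner_folds(1:4, lab, k = 2, seed = 1)
  for (f in inner) {
    expect_length(f$validation, 2)
    expect_identical(sort(as.vector(table(lab$label[f$validation]))), c(1L, 1L))
  }
})

test_that("a class smaller than k is rejected", {
  lab <- make_lab(3, 51)
  expect_error(make_inner_folds(1:54, lab, k = 5, seed = 1), "at least 5")
  expect_error(make_inner_folds(1:54, lab, k = 1, seed = 1), "k must be")
})

test_that("fold-plan invariants hold over 1000 random draws", {
  set.seed(900)
  for (i in 1:1000) {
    n_case <- sample(5:40, 1)
    n_control <- sample(5:40, 1)
    n <- n_case + n_control
    fraction <- runif(1, 1.5 / n, 0.4)
    lab <- make_lab(n_case, n_control)
    plan <- make_outer_folds(n, fraction, lab, seed = i)
    val_all <- unlist(lapply(plan$outer, `[[`, "validation"))
    stopifnot(
      !anyDuplicated(val_all),                      # disjoint validation sets
      setequal(val_all, seq_len(n)),                # coverage
      all(vapply(plan$outer, function(f) {
        setequal(union(f$train, f$validation), seq_len(n)) &&
          length(intersect(f$train, f$validation)) == 0
      }, logical(1))),
      diff(range(lengths(lapply(plan$outer, `[[`, "validation")))) <= 1
    )
    # stratification: per-fold class count within 1 of the proportional share
    frac_case <- n_case / n
    ok <- vapply(plan$outer, function(f) {
      v <- f$validation
      abs(sum(lab$label[v] == "case") - frac_case * length(v)) <= 1
    }, logical(1))
    stopifnot(all(ok))
  }
  expect_true(TRUE)  # reached only if every draw satisfied the invariants
})

test_that("the leakage guard trips on corrupted fold plans", {
  lab <- make_lab(16, 14)
  plan <- make_outer_folds(30, 0.2, lab, seed = 6)
  expect_silent(check_fold_plan(plan, 30))

  overlap <- plan
  overlap$outer[[1]]$validation <- overlap$outer[[2]]$validation
  expect_error(check_fold_plan(overlap, 30), "Leakage")

  leaky <- plan
  leaky$outer[[1]]$train <- c(leaky$outer[[1]]$train,
                              leaky$outer[[1]]$validation[1])
  expect_error(check_fold_plan(leaky, 30), "Leakage")

  co <- simulate_cohort(synthetic_spec(n_case = 16, n_control = 14,
                                       n_features = 30, seed = 7))
  expect_error(
    run_pipeline(co$matrix, co$labels,
                 pipeline_config(outer_fraction = 0.2, random_seed = 1),
                 fold_plan = leaky),
    "Leakage"
  )
})

test_that("the inner loop selects informative consensus sets and picks winners", {
  co <- simulate_cohort(synthetic_spec(n_case = 16, n_control = 14,
                                       n_features = 60, log2_fold_change = 2.5,
                                       seed = 21))
  cfg <- pipeline_config(inner_k = 2, n_select = 5, random_seed = 3)
  res <- run_inner_loop(co$matrix, co$labels, train_indices = 1:30, config = cfg)
  expect_length(res$folds, 2)
  for (cons in res$consensus_sets) {
    expect_gt(length(intersect(cons, co$truth_informative)), 0)
  }
  expect_true(all(res$winners %in% classifier_roster()))
  # the per-fold winner dominates its fold on the configured rule
  for (f in res$folds) {
    expect_equal(max(f$evaluations$mean_metric),
                 f$evaluations$mean_metric[f$evaluations$model == f$winner])
  }
})

test_that("best-model selection follows frequency, then AUC, then roster order", {
  fake <- function(winners, auc_by_model) {
    evals <- tibble::tibble(
      model = rep(names(auc_by_model), 2),
      auc = rep(unname(auc_by_model), 2),
      mean_metric = rep(unname(auc_by_model), 2)
    )
    list(evaluations = evals, winners = winners)
  }
  r <- fake(c("logistic_regression", "logistic_regression", "svm",
              "logistic_regression", "random_forest"),
            c(logistic_regression = 0.9, svm = 0.95, random_forest = 0.8))
  expect_identical(select_best_model(r, "frequency"), "logistic_regression")

  tie <- fake(c("logistic_regression", "svm", "logistic_regression", "svm"),
              c(logistic_regression = 0.85, svm = 0.95))
  expect_identical(select_best_model(tie, "frequency"), "svm")

  tie2 <- fake(c("logistic_regression", "svm"),
               c(logistic_regression = 0.9, svm = 0.9))
  expect_identical(select_best_model(tie2, "frequency"), "logistic_regression")

  single <- fake("adaboost", c(adaboost = 0.7))
  expect_identical(select_best_model(single, "frequency"), "adaboost")

  expect_identical(select_best_model(tie, "mean_performance"), "svm")
})

test_that("the full pipeline recovers planted signal at unit scale", {
  co <- simulate_cohort(synthetic_spec(n_features = 120, seed = 3))
  rep1 <- run_pipeline(co$matrix, co$labels, pipeline_config(random_seed = 11))
  expect_identical(rep1$n_outer_folds, 10L)
  expect_gte(sum(co$truth_informative %in% rep1$f_minimal$feature_id), 8)
  expect_gt(rep1$aggregate$mean[rep1$aggregate$metric == "auc"], 0.9)
  # config echo is exact
  expect_identical(rep1$config, unclass(pipeline_config(random_seed = 11)))
  # per-fold table recomputes to the aggregate
  core <- c("accuracy", "sensitivity", "specificity", "f1", "auc")
  re_agg <- aggregate_metrics(rep1$outer_metrics[, c("fold", core)])
  expect_equal(rep1$aggregate, re_agg)
})

test_that("pipeline runs are deterministic and scope/mode switches work", {
  co <- simulate_cohort(synthetic_spec(n_features = 80, seed = 13))
  cfg <- pipeline_config(random_seed = 7)
  a <- run_pipeline(co$matrix, co$labels, cfg)
  b <- run_pipeline(co$matrix, co$labels, cfg)
  expect_identical(a$f_minimal, b$f_minimal)
  expect_equal(a$outer_metrics, b$outer_metrics)

  per_fold <- run_pipeline(co$matrix, co$labels,
                           pipeline_config(random_seed = 7,
                                           fminimal_scope = "per_outer_fold"))
  expect_gt(nrow(per_fold$f_minimal), 0)
  algo_only <- run_pipeline(co$matrix, co$labels,
                            pipeline_config(random_seed = 7,
                                            consensus_mode = "algorithms_only"))
  # dropping the fold threshold can only widen the signature
  expect_true(all(a$f_minimal$feature_id %in% algo_only$f_minimal$feature_id))
})
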