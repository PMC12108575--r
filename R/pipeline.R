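#' Pipeline configuration
#'
#' All tunables of the nested ensemble-selection pipeline with their
#' defaults: a 10% outer validation fraction (10 folds at N = 60),
#' 5 stratified inner folds (an 80/20 inner split), a 10-feature
#' budget per selector, within-fold consensus at 3 of 4 selectors,
#' and signature accumulation at 3 supporting inner folds.
#'
#' @param outer_fraction Outer validation fraction in (0, 1).
#' @param inner_k Inner stratified folds (>= 2).
#' @param n_select Features each of RFE / RF-importance / k-best
#'   returns per inner fold (LASSO support is data-driven).
#' @param l1_strength LASSO penalty.
#' @param ridge_lambda Ridge penalty of the RFE base classifier.
#' @param consensus_min_votes Selectors that must back a feature
#'   within one inner fold (<= 4).
#' @param fminimal_min_folds Inner folds whose consensus set must
#'   contain a feature before it enters the minimal signature.
#' @param consensus_mode `"both"` applies the selector-vote threshold
#'   within folds and the fold threshold across folds;
#'   `"algorithms_only"` applies only the selector votes;
#'   `"folds_only"` applies only the fold threshold (fold sets are
#'   selector unions).
#' @param fminimal_scope `"global"` accumulates the signature over
#'   every inner fold of every outer fold (the single returned
#'   signature then informs each outer validation — the estimate is
#'   labeled accordingly); `"per_outer_fold"` accumulates separately
#'   inside each outer fold.
#' @param classifiers Classifier roster (subset of
#'   [classifier_roster()]).
#' @param model_selection_rule `"frequency"` (most frequent inner-fold
#'   winner) or `"mean_performance"`.
#' @param transform Feature transform (see
#'   [fit_feature_transform()]).
#' @param stratify_outer Stratify outer folds by class.
#' @param positive_class Positive label (`NULL` = label conventions).
#' @param random_seed Integer master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outer_fraction = 0.10, inner_k = 5, n_select = 10,
                            l1_strength = 0.01, ridge_lambda = 1,
                            consensus_min_votes = 3, fminimal_min_folds = 3,
                            consensus_mode = c("both", "algorithms_only", "folds_only"),
                            fminimal_scope = c("global", "per_outer_fold"),
                            classifiers = classifier_roster(),
                            model_selection_rule = c("frequency", "mean_performance"),
                            transform = c("log2p1_zscore", "none"),
                            stratify_outer = TRUE, positive_class = NULL,
                            random_seed = 1L) {
  cfg <- list(
    outer_fraction = outer_fraction, inner_k = as.integer(inner_k),
    n_select = as.integer(n_select), l1_strength = l1_strength,
    ridge_lambda = ridge_lambda,
    consensus_min_votes = as.integer(consensus_min_votes),
    fminimal_min_folds = as.integer(fminimal_min_folds),
    consensus_mode = match.arg(consensus_mode),
    fminimal_scope = match.arg(fminimal_scope),
    classifiers = match.arg(classifiers, classifier_roster(), several.ok = TRUE),
    model_selection_rule = match.arg(model_selection_rule),
    transform = match.arg(transform),
    stratify_outer = isTRUE(stratify_outer),
    positive_class = positive_class,
    random_seed = as.integer(random_seed)
  )
  if (cfg$outer_fraction <= 0 || cfg$outer_fraction >= 1) {
    abort("outer_fraction must lie in (0, 1).")
  }
  if (cfg$inner_k < 2) abort("inner_k must be >= 2.")
  if (cfg$n_select < 1) abort("n_select must be >= 1.")
  if (cfg$consensus_min_votes < 1 || cfg$consensus_min_votes > 4) {
    abort("consensus_min_votes must lie in 1..4 (there are 4 selectors).")
  }
  if (cfg$fminimal_min_folds < 1) abort("fminimal_min_folds must be >= 1.")
  structure(cfg, class = "pipeline_config")
}

## deterministic sub-seed derivation, kept well under 2^31
derive_seed <- function(seed, ...) {
  parts <- c(seed %% 100000L, ...)
  s <- 0
  for (p in parts) s <- (s * 131 + as.integer(p) + 7) %% 2147483629L
  as.integer(s) + 1L
}

run_selectors <- function(x_t, y_t, config, seed) {
  list(
    rfe = select_rfe(x_t, y_t, n_select = config$n_select,
                     ridge_lambda = config$ridge_lambda),
    rf_importance = select_rf_importance(x_t, y_t, n_select = config$n_select,
                                         seed = seed),
    lasso = select_lasso(x_t, y_t, l1_strength = config$l1_strength),
    kbest = select_kbest(x_t, y_t, k = min(config$n_select, ncol(x_t)))
  )
}

#' Run the inner selection/benchmark loop on one outer training set
#'
#' For each of `inner_k` stratified inner folds: the transform is
#' fitted on the inner-train samples only; the four selectors run on
#' the transformed inner-train matrix; a fold-level consensus feature
#' set is formed; the five classifiers are trained on the inner-train
#' samples restricted to that consensus set and evaluated on the
#' inner-test fold; the fold winner is the model with the best mean
#' of the five metrics (ties: higher AUC, then roster order). An
#' empty consensus falls back to progressively lower vote thresholds
#' (logged).
#'
#' @param x An [expr_matrix()].
#' @param labels A [sample_labels()].
#' @param train_indices Outer training-set indices `T_i`.
#' @param config A [pipeline_config()].
#' @param seed Integer seed for this loop.
#' @return A list with `folds` (per-inner-fold results: selections,
#'   consensus set, evaluation tibble, winner), `evaluations` (bound
#'   tibble), `consensus_sets`, and `warnings`.
#' @export
run_inner_loop <- function(x, labels, train_indices, config = pipeline_config(),
                           seed = config$random_seed) {
  warnings <- character(0)
  inner <- make_inner_folds(train_indices, labels, k = config$inner_k,
                            seed = derive_seed(seed, 1L))
  min_votes <- if (config$consensus_mode == "folds_only") 1L else config$consensus_min_votes
  folds <- lapply(inner, function(fold) {
    assert_subset_of_train(c(fold$train, fold$validation), train_indices,
                           sprintf("inner fold %d", fold$fold))
    x_t <- t(unclass(x)[, fold$train, drop = FALSE])
    x_v <- t(unclass(x)[, fold$validation, drop = FALSE])
    tr <- transform_features(x_t, x_v, mode = config$transform)
    y_t <- labels$label[fold$train]
    y_v <- labels$label[fold$validation]
    pos <- config$positive_class %||% positive_class(labels)

    sel_seed <- derive_seed(seed, 2L, fold$fold)
    selections <- run_selectors(tr$train, sample_labels_like(y_t, pos), config, sel_seed)
    mv <- min_votes
    cons <- consensus_vote(selections, min_votes = mv)
    while (length(cons$features) == 0 && mv > 1) {
      mv <- mv - 1L
      cons <- consensus_vote(selections, min_votes = mv)
      warnings <<- c(warnings, sprintf(
        "inner fold %d: empty consensus; relaxed selector votes to %d", fold$fold, mv))
    }
    feats <- cons$features

    evals <- purrr::map_dfr(config$classifiers, function(name) {
      model <- train_classifier(name, tr$train[, feats, drop = FALSE],
                                sample_labels_like(y_t, pos),
                                seed = derive_seed(seed, 3L, fold$fold, match(name, classifier_roster())))
      pr <- predict(model, tr$applied[, feats, drop = FALSE])
      cc <- confusion_counts(y_v, pr$class, pos)
      ms <- metric_set(cc, scores = pr$score, y_true = y_v, positive_class = pos)
      dplyr::mutate(ms, model = name, .before = 1)
    })
    core <- c("accuracy", "sensitivity", "specificity", "f1", "auc")
    evals$mean_metric <- rowMeans(evals[, core])
    winner <- evals$model[order(-evals$mean_metric, -evals$auc,
                                match(evals$model, classifier_roster()))][1]
    list(fold = fold$fold, selections = selections, consensus = feats,
         tally = cons$tally, evaluations = evals, winner = winner)
  })
  evaluations <- purrr::map_dfr(folds, function(f) {
    dplyr::mutate(f$evaluations, inner_fold = f$fold, .before = 1)
  })
  list(folds = folds, evaluations = evaluations,
       consensus_sets = lapply(folds, `[[`, "consensus"),
       winners = vapply(folds, `[[`, character(1), "winner"),
       warnings = warnings)
}

## labels vector -> minimal sample_labels-like object for binary_y
sample_labels_like <- function(labels, positive) {
  out <- tibble::tibble(sample_id = as.character(seq_along(labels)), label = labels)
  class(out) <- c("sample_labels", class(out))
  attr(out, "positive_class") <- positive
  out
}

#' Choose the best model from inner-loop results
#'
#' Under `"frequency"` (the default) the most frequent per-fold
#' winner is chosen; under `"mean_performance"` the model with the
#' highest mean of the five metrics averaged over the inner folds.
#' Ties are broken by mean AUC, then roster order.
#'
#' @param inner_results The value of [run_inner_loop()] (or a list of
#'   them, pooled).
#' @param rule Selection rule.
#' @return A classifier name.
#' @export
select_best_model <- function(inner_results,
                              rule = c("frequency", "mean_performance")) {
  rule <- match.arg(rule)
  if (!is.null(inner_results$evaluations)) inner_results <- list(inner_results)
  evals <- purrr::map_dfr(inner_results, "evaluations")
  winners <- unlist(lapply(inner_results, `[[`, "winners"))
  if (length(winners) == 0) abort("At least one inner result is required.")
  stats_by_model <- evals |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(mean_auc = mean(.data$auc),
                     mean_metric = mean(.data$mean_metric), .groups = "drop")
  cand <- tibble::tibble(model = stats_by_model$model) |>
    dplyr::left_join(stats_by_model, by = "model") |>
    dplyr::mutate(
      wins = as.integer(table(factor(winners, levels = .data$model))[.data$model]),
      roster = match(.data$model, classifier_roster())
    )
  key <- if (rule == "frequency") cand$wins else cand$mean_metric
  cand$model[order(-key, -cand$mean_auc, cand$roster)][1]
}

#' Run the full nested ensemble-selection pipeline
#'
#' Orchestration of the whole method: build the outer fold plan
#' (validated by the leakage guard); run the inner
#' selection/benchmark loop on every outer training set; accumulate
#' the minimal signature from the fold-level consensus sets (globally
#' across all inner folds by default, or per outer fold); then, for
#' each outer fold, retrain that fold's best model on the full outer
#' training set restricted to the signature (transform refitted on
#' the training portion) and evaluate it on the held-out validation
#' fold. If no feature reaches the fold threshold, the threshold is
#' relaxed one step at a time until the signature is nonempty, and
#' the relaxation is recorded in the report warnings.
#'
#' @param x An [expr_matrix()].
#' @param labels A [sample_labels()] aligned with `x`.
#' @param config A [pipeline_config()].
#' @param seed Master seed (defaults to `config$random_seed`).
#' @param fold_plan Optional pre-built outer [make_outer_folds()]
#'   plan; it is validated before use.
#' @return An `efscv_report` object; see [tidy.efscv_report()],
#'   [glance.efscv_report()], [autoplot.efscv_report()],
#'   [write_report()].
#' @export
run_pipeline <- function(x, labels, config = pipeline_config(),
                         seed = config$random_seed, fold_plan = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!inherits(labels, "sample_labels")) abort("`labels` must be sample_labels.")
  if (!identical(labels$sample_id, sample_ids(x))) {
    abort("Labels are not aligned with the matrix sample order.")
  }
  n <- ncol(x)
  pos <- config$positive_class %||% positive_class(labels)
  warnings <- character(0)

  if (is.null(fold_plan)) {
    fold_plan <- make_outer_folds(n, fraction = config$outer_fraction,
                                  labels = labels, seed = derive_seed(seed, 0L),
                                  stratified = config$stratify_outer)
  }
  check_fold_plan(fold_plan, n)

  inner_runs <- lapply(fold_plan$outer, function(of) {
    run_inner_loop(x, labels, of$train, config = config,
                   seed = derive_seed(seed, 10L, of$fold))
  })
  for (i in seq_along(inner_runs)) {
    if (length(inner_runs[[i]]$warnings) > 0) {
      warnings <- c(warnings, paste0("outer fold ", i, ": ", inner_runs[[i]]$warnings))
    }
  }

  min_folds <- if (config$consensus_mode == "algorithms_only") 1L else config$fminimal_min_folds
  accumulate_with_fallback <- function(sets, min_folds, label) {
    mf <- min(min_folds, length(sets))
    fm <- accumulate_fminimal(sets, mf)
    while (nrow(fm) == 0 && mf > 1) {
      mf <- mf - 1L
      fm <- accumulate_fminimal(sets, mf)
      warnings <<- c(warnings, sprintf(
        "%s: empty minimal set; relaxed fold threshold to %d", label, mf))
    }
    fm
  }

  if (config$fminimal_scope == "global") {
    all_sets <- unlist(lapply(inner_runs, `[[`, "consensus_sets"), recursive = FALSE)
    f_minimal <- accumulate_with_fallback(all_sets, min_folds, "global accumulation")
    fm_by_fold <- NULL
  } else {
    fm_by_fold <- lapply(seq_along(inner_runs), function(i) {
      accumulate_with_fallback(inner_runs[[i]]$consensus_sets, min_folds,
                               sprintf("outer fold %d", i))
    })
    hits <- purrr::map_dfr(fm_by_fold, ~.x)
    f_minimal <- hits |>
      dplyr::group_by(.data$feature_id) |>
      dplyr::summarise(fold_hits = sum(.data$fold_hits), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$fold_hits), .data$feature_id)
  }

  outer_metrics <- purrr::map_dfr(seq_along(fold_plan$outer), function(i) {
    of <- fold_plan$outer[[i]]
    feats <- if (config$fminimal_scope == "global") f_minimal$feature_id
             else fm_by_fold[[i]]$feature_id
    m_star <- select_best_model(inner_runs[[i]], rule = config$model_selection_rule)
    x_t <- t(unclass(x)[, of$train, drop = FALSE])
    x_v <- t(unclass(x)[, of$validation, drop = FALSE])
    tr <- transform_features(x_t, x_v, mode = config$transform)
    model <- train_classifier(m_star, tr$train[, feats, drop = FALSE],
                              sample_labels_like(labels$label[of$train], pos),
                              seed = derive_seed(seed, 20L, i))
    pr <- predict(model, tr$applied[, feats, drop = FALSE])
    y_v <- labels$label[of$validation]
    cc <- confusion_counts(y_v, pr$class, pos)
    ms <- metric_set(cc, scores = pr$score, y_true = y_v, positive_class = pos)
    dplyr::mutate(ms, fold = i, model = m_star,
                  n_validation = length(of$validation), .before = 1)
  })
  degen <- outer_metrics$fold[outer_metrics$degenerate != ""]
  if (length(degen) > 0) {
    warnings <- c(warnings, sprintf(
      "outer fold %d: zero-denominator metric(s) reported as 0", degen))
  }

  core <- c("accuracy", "sensitivity", "specificity", "f1", "auc")
  aggregate <- aggregate_metrics(outer_metrics[, c("fold", core)])
  best_model <- select_best_model(inner_runs, rule = config$model_selection_rule)

  inner_summary <- purrr::map_dfr(seq_along(inner_runs), function(i) {
    tibble::tibble(
      outer_fold = i,
      inner_fold = vapply(inner_runs[[i]]$folds, `[[`, integer(1), "fold"),
      winner = inner_runs[[i]]$winners,
      consensus_size = lengths(inner_runs[[i]]$consensus_sets)
    )
  })

  feature_stats <- purrr::map_dfr(inner_runs, function(run) {
    purrr::map_dfr(run$folds, function(f) {
      purrr::map_dfr(f$selections, ~.x[, c("feature_id", "score")])
    })
  }) |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(selector_votes = dplyr::n(),
                     mean_score = mean(.data$score), .groups = "drop")
  all_sets <- unlist(lapply(inner_runs, `[[`, "consensus_sets"), recursive = FALSE)
  hit_tab <- table(unlist(lapply(all_sets, unique)))
  feature_stats$fold_hits <- as.integer(hit_tab[feature_stats$feature_id])
  feature_stats$fold_hits[is.na(feature_stats$fold_hits)] <- 0L
  feature_stats <- dplyr::arrange(feature_stats, dplyr::desc(.data$fold_hits),
                                  dplyr::desc(.data$selector_votes), .data$feature_id)

  structure(list(
    f_minimal = f_minimal,
    best_model = best_model,
    outer_metrics = outer_metrics,
    aggregate = aggregate,
    inner_summary = inner_summary,
    feature_stats = feature_stats,
    config = unclass(config),
    seed = as.integer(seed),
    positive_class = pos,
    n_samples = n,
    n_features = nrow(x),
    n_outer_folds = length(fold_plan$outer),
    warnings = warnings,
    notes = c(
      "sensitivity is TP/(TP+FN) (recall / true positive rate)",
      if (config$fminimal_scope == "global")
        "signature accumulated globally across outer folds; outer validation estimates share it"
    )
  ), class = "efscv_report")
}
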