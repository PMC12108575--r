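## Selector ensemble: four families (RFE wrapper, random-forest
## embedded importance, L1-penalised logistic regression, ANOVA-F
## k-best filter) plus the consensus-vote / F_minimal accumulation
## logic. Every selector returns a `selection_result` tibble ordered
## by descending score with ties broken by ascending feature ID, so
## selector output is a total order and runs are reproducible.

binary_y <- function(y, positive = NULL) {
  if (inherits(y, "sample_labels")) {
    positive <- positive %||% positive_class(y)
    y <- y$label
  }
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2) {
    abort(sprintf("Binary labels required, found %d class(es).", length(classes)))
  }
  if (is.null(positive)) {
    positive <- if ("case" %in% classes) "case" else {
      counts <- table(y)
      names(counts)[order(counts, names(counts))][1]
    }
  }
  list(labels = y, y01 = as.integer(y == positive), positive = positive,
       negative = setdiff(classes, positive))
}

selection_result <- function(selector, feature_ids, scores) {
  ord <- order(-scores, feature_ids)
  out <- tibble::tibble(
    selector = selector,
    rank = seq_along(feature_ids),
    feature_id = feature_ids[ord],
    score = unname(scores[ord])
  )
  class(out) <- c("selection_result", class(out))
  out
}

selected_set <- function(x) {
  if (inherits(x, "selection_result") || is.data.frame(x)) x$feature_id
  else as.character(x)
}

## L2-penalised least-squares classifier on +/-1 labels, solved in the
## dual (n x n system) so refitting after each elimination is cheap
## even with hundreds of features.
ridge_weights <- function(x, ypm, lambda) {
  n <- nrow(x)
  k <- tcrossprod(x)
  alpha <- solve(k + lambda * diag(n), ypm)
  as.vector(crossprod(x, alpha))
}

#' Recursive feature elimination with a linear-model ranking
#'
#' Wrapper selection: fit an L2-penalised linear classifier on the
#' full feature set, rank features by absolute coefficient, drop the
#' lowest-ranked one, refit, and repeat until `n_select` features
#' remain. One feature is eliminated per step by default. Coefficient
#' ties are broken by eliminating the lexicographically larger
#' feature ID, so the surviving set is deterministic.
#'
#' @param x Transformed samples-by-features numeric matrix with
#'   feature IDs as column names.
#' @param y Class labels (a [sample_labels()] or a vector aligned with
#'   the rows of `x`).
#' @param n_select Number of features to retain (>= 1).
#' @param ridge_lambda Ridge penalty of the base classifier.
#' @param step Features eliminated per refit (default 1).
#' @return A `selection_result` tibble: `selector`, `rank`,
#'   `feature_id`, `score` (absolute coefficient in the final refit).
#' @export
select_rfe <- function(x, y, n_select, ridge_lambda = 1, step = 1L) {
  if (n_select <= 0) abort("n_select must be >= 1.")
  x <- as.matrix(x)
  if (is.null(colnames(x))) abort("`x` needs feature IDs as column names.")
  by <- binary_y(y)
  ypm <- 2 * by$y01 - 1
  remaining <- colnames(x)
  while (length(remaining) > n_select) {
    w <- abs(ridge_weights(x[, remaining, drop = FALSE], ypm, ridge_lambda))
    drop_n <- min(step, length(remaining) - n_select)
    victims <- remaining[order(w, -xtfrm(remaining))][seq_len(drop_n)]
    remaining <- setdiff(remaining, victims)
  }
  w <- abs(ridge_weights(x[, remaining, drop = FALSE], ypm, ridge_lambda))
  selection_result("rfe", remaining, w)
}

#' Random-forest impurity-importance selection
#'
#' Embedded selection: a random forest is grown on the training
#' samples and features are ranked by mean decrease in Gini impurity;
#' the top `n_select` are returned. The forest is seeded so the
#' selection is reproducible.
#'
#' @inheritParams select_rfe
#' @param n_trees Number of trees (the library default, 500).
#' @param seed Integer seed for the forest.
#' @return A `selection_result` tibble with importance scores.
#' @export
select_rf_importance <- function(x, y, n_select, n_trees = 500, seed = 1L) {
  if (n_select <= 0) abort("n_select must be >= 1.")
  x <- as.matrix(x)
  by <- binary_y(y)
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = factor(by$labels), ntree = n_trees)
  imp <- rf$importance[, "MeanDecreaseGini"]
  ord <- order(-imp, colnames(x))
  keep <- ord[seq_len(min(n_select, ncol(x)))]
  selection_result("rf_importance", colnames(x)[keep], imp[keep])
}

#' L1-penalised logistic (LASSO) selection
#'
#' Embedded selection through sparsity: features with a nonzero
#' coefficient in an L1-penalised logistic regression at the given
#' penalty are selected; scores are absolute coefficients. The number
#' selected is data-driven (possibly zero at strong penalties). `x`
#' is expected to be standardized already (the pipeline transform
#' contract), so no internal re-standardization is applied.
#'
#' @inheritParams select_rfe
#' @param l1_strength Penalty (glmnet `lambda`); must be > 0.
#' @return A `selection_result` tibble over the nonzero-support
#'   features.
#' @export
select_lasso <- function(x, y, l1_strength = 0.01) {
  if (l1_strength <= 0) abort("l1_strength must be > 0.")
  x <- as.matrix(x)
  by <- binary_y(y)
  xfit <- x
  if (ncol(xfit) < 2) {  # glmnet needs >= 2 columns; pad with a dead one
    xfit <- cbind(xfit, `..pad..` = 0)
  }
  ## glmnet warns about class counts < 8 on small inner folds; the
  ## sparse support is still well-defined there, so silence the nag
  fit <- withCallingHandlers(
    glmnet::glmnet(xfit, by$y01, family = "binomial", alpha = 1,
                   lambda = l1_strength, standardize = FALSE),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- as.matrix(coef(fit))[-1, 1]
  beta <- beta[names(beta) %in% colnames(x)]
  nz <- which(beta != 0)
  selection_result("lasso", names(beta)[nz], abs(beta[nz]))
}

#' One-way ANOVA F statistic for a two-group comparison
#'
#' F = between-group mean square / within-group mean square. For two
#' groups this equals the squared pooled-variance two-sample t
#' statistic. Degenerate inputs follow a documented convention: zero
#' within-group variance with equal group means gives 0; zero
#' within-group variance with unequal means gives `Inf` (a perfect
#' separator).
#'
#' @param values Numeric vector, one value per sample.
#' @param y Binary class labels aligned with `values`.
#' @return The F statistic (nonnegative, possibly `Inf`).
#' @export
#' @examples
#' anova_f_score(c(1, 2, 3, 4), c("a", "a", "b", "b"))
anova_f_score <- function(values, y) {
  by <- binary_y(y)
  as.vector(anova_f_scores(matrix(values, ncol = 1), by$y01))
}

## vectorized over the columns of a samples-by-features matrix
anova_f_scores <- function(x, y01) {
  g1 <- y01 == 1
  n1 <- sum(g1); n0 <- sum(!g1); n <- n1 + n0
  if (n1 == 0 || n0 == 0) abort("Both groups must be non-empty.")
  m1 <- colMeans(x[g1, , drop = FALSE])
  m0 <- colMeans(x[!g1, , drop = FALSE])
  grand <- (n1 * m1 + n0 * m0) / n
  ss_between <- n1 * (m1 - grand)^2 + n0 * (m0 - grand)^2
  ss_within <- colSums(sweep(x[g1, , drop = FALSE], 2, m1)^2) +
    colSums(sweep(x[!g1, , drop = FALSE], 2, m0)^2)
  f <- ifelse(ss_within > 0,
              (ss_between / 1) / (ss_within / (n - 2)),
              ifelse(ss_between > 0, Inf, 0))
  unname(f)
}

#' ANOVA-F k-best selection
#'
#' Filter selection: every feature is scored with the one-way ANOVA F
#' statistic between the two classes and the `k` highest-scoring
#' features are kept (ties broken by ascending feature ID).
#'
#' @inheritParams select_rfe
#' @param k Number of features to keep (>= 1, <= ncol(x)).
#' @return A `selection_result` tibble with F-statistic scores.
#' @export
select_kbest <- function(x, y, k) {
  if (k <= 0) abort("k must be >= 1.")
  x <- as.matrix(x)
  if (k > ncol(x)) abort("k exceeds the number of features.")
  by <- binary_y(y)
  f <- anova_f_scores(x, by$y01)
  ord <- order(-f, colnames(x))[seq_len(k)]
  selection_result("kbest", colnames(x)[ord], f[ord])
}

#' Consensus vote over selector results
#'
#' Counts, for each feature, how many selectors chose it, and keeps
#' the features backed by at least `min_votes` selectors — the
#' "appearing in at least three algorithms" rule at the default
#' threshold of 3 out of 4 selectors.
#'
#' @param results List of `selection_result` objects (or plain
#'   character vectors of feature IDs).
#' @param min_votes Minimum number of supporting selectors.
#' @return A list: `features` (consensus feature IDs, ordered by
#'   descending votes then ID) and `tally` (tibble `feature_id`,
#'   `votes` over every feature any selector chose).
#' @export
consensus_vote <- function(results, min_votes = 3) {
  if (length(results) < 1) abort("At least one selection result is required.")
  if (min_votes > length(results)) {
    abort("min_votes cannot exceed the number of selectors.")
  }
  sets <- lapply(results, function(r) unique(selected_set(r)))
  votes <- table(unlist(sets))
  tally <- tibble::tibble(
    feature_id = as.character(names(votes) %||% character(0)),
    votes = as.integer(votes)
  ) |> dplyr::arrange(dplyr::desc(.data$votes), .data$feature_id)
  list(features = tally$feature_id[tally$votes >= min_votes], tally = tally)
}

#' Accumulate the minimal feature set across folds
#'
#' Counts, for each feature, the number of fold-level consensus sets
#' containing it and keeps features hitting at least `min_folds`
#' folds — the "selected in >= 3 inner folds" accumulation rule that
#' builds the minimal signature.
#'
#' @param per_fold_consensus List of character vectors, one consensus
#'   feature set per fold.
#' @param min_folds Minimum number of supporting folds.
#' @return A tibble (`feature_id`, `fold_hits`) restricted to
#'   features with `fold_hits >= min_folds`, ordered by descending
#'   `fold_hits` then ascending `feature_id`.
#' @export
accumulate_fminimal <- function(per_fold_consensus, min_folds = 3) {
  if (min_folds > length(per_fold_consensus)) {
    abort("min_folds cannot exceed the number of folds.")
  }
  sets <- lapply(per_fold_consensus, function(s) unique(as.character(s)))
  hits <- table(unlist(sets))
  out <- tibble::tibble(
    feature_id = as.character(names(hits) %||% character(0)),
    fold_hits = as.integer(hits)
  ) |>
    dplyr::filter(.data$fold_hits >= min_folds) |>
    dplyr::arrange(dplyr::desc(.data$fold_hits), .data$feature_id)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
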