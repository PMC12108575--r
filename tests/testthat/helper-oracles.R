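# Independent oracles and small fixtures used across the suite.

# AUC by brute-force pairwise concordance: P(random positive outscores
# a random negative), ties counted one half.
auc_brute <- function(scores, y01) {
  pos <- scores[y01 == 1]
  neg <- scores[y01 == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Pooled-variance two-sample t statistic, computed from the textbook
# formula (independent of the package's ANOVA-F path).
t_pooled <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Exhaustive membership counting for set systems.
count_memberships <- function(sets) {
  u <- sort(unique(unlist(sets)))
  vapply(u, function(f) sum(vapply(sets, function(s) f %in% s, logical(1))),
         integer(1)) |> stats::setNames(u)
}

# A tiny deterministic expression fixture: 3 features x 4 samples.
tiny_matrix <- function() {
  expr_matrix(
    matrix(c(1, 2, 3, 4,
             10, 20, 30, 40,
             5, 5, 5, 5), nrow = 3, byrow = TRUE),
    feature_ids = c("fA", "fB", "fC"),
    sample_ids = c("s1", "s2", "s3", "s4")
  )
}

tiny_labels <- function() {
  sample_labels(c("s1", "s2", "s3", "s4"),
                c("case", "case", "control", "control"))
}

# A small planted cohort for selector unit tests: strong effect so
# recovery assertions are stable at desk scale.
small_planted <- function(seed = 42, n_features = 100, fc = 3) {
  simulate_cohort(synthetic_spec(
    n_case = 20, n_control = 20, n_features = n_features,
    n_informative = 10, log2_fold_change = fc, seed = seed
  ))
}

transformed_xy <- function(cohort) {
  x <- t(unclass(cohort$matrix))
  list(x = transform_features(x)$train, y = cohort$labels)
}
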