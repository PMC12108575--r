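#' Specification for a synthetic two-class count cohort
#'
#' Defines the generative model for a labeled miRNA-style count
#' cohort: negative-binomial (Gamma–Poisson) counts with
#' feature-specific base means drawn log-uniformly, a shared
#' dispersion, and a small planted subset of class-informative
#' features whose case-class mean is shifted on the log2 scale. The
#' defaults emulate a NanoString-scale cohort: 798 features, 31 case
#' and 29 control samples, 10 informative features at a log2 fold
#' change of 2.
#'
#' @param n_case,n_control Samples per class.
#' @param n_features Number of count features.
#' @param n_informative Number of planted class-informative features.
#' @param log2_fold_change Absolute log2 shift of the case-class mean
#'   for informative features (>= 0).
#' @param base_mean_log_range Length-2 range (log2 scale) the base
#'   means are drawn from, log-uniformly.
#' @param nb_dispersion Negative-binomial dispersion (the `size`
#'   parameter is `1/nb_dispersion`); must be > 0.
#' @param direction_mix Fraction of informative features shifted UP in
#'   the case class; the rest shift down. Rounded to a whole count.
#' @param seed Integer seed; generation is deterministic given it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_case = 31, n_control = 29, n_features = 798,
                           n_informative = 10, log2_fold_change = 2.0,
                           base_mean_log_range = c(4, 10), nb_dispersion = 0.3,
                           direction_mix = 0.5, seed = 1L) {
  spec <- list(
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    n_features = as.integer(n_features), n_informative = as.integer(n_informative),
    log2_fold_change = as.numeric(log2_fold_change),
    base_mean_log_range = as.numeric(base_mean_log_range),
    nb_dispersion = as.numeric(nb_dispersion),
    direction_mix = as.numeric(direction_mix),
    seed = as.integer(seed)
  )
  if (spec$n_case < 1 || spec$n_control < 1) abort("Both classes need >= 1 sample.")
  if (spec$n_features < 1) abort("n_features must be >= 1.")
  if (spec$n_informative < 0 || spec$n_informative > spec$n_features) {
    abort("n_informative must lie in [0, n_features].")
  }
  if (spec$log2_fold_change < 0) abort("log2_fold_change must be >= 0.")
  if (length(spec$base_mean_log_range) != 2 ||
      diff(spec$base_mean_log_range) < 0) {
    abort("base_mean_log_range must be an increasing length-2 range.")
  }
  if (spec$nb_dispersion <= 0) abort("nb_dispersion must be > 0.")
  if (spec$direction_mix < 0 || spec$direction_mix > 1) {
    abort("direction_mix must lie in [0, 1].")
  }
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic labeled count cohort
#'
#' Counts for feature f in class g are drawn i.i.d. from
#' NB(mu = mu_gf, size = 1/dispersion). Control means equal the base
#' mean; for informative features the case mean is the base mean times
#' `2^(+/- log2_fold_change)`, with the up/down sign assigned per
#' `direction_mix`. Non-informative features have identical group
#' means by construction, so the planted truth set is exactly the set
#' of features whose group means differ.
#'
#' @param spec A [synthetic_spec()].
#' @return A `synthetic_cohort` list: `matrix` (an [expr_matrix()]),
#'   `labels` (a [sample_labels()]), `truth_informative` (character
#'   vector of planted feature IDs), `true_means` (tibble of
#'   per-feature case/control means), and the `spec`.
#' @export
#' @examples
#' cohort <- simulate_cohort(synthetic_spec(n_features = 40, seed = 7))
#' dim(cohort$matrix)
simulate_cohort <- function(spec = synthetic_spec()) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  set.seed(spec$seed)
  f <- spec$n_features
  n <- spec$n_case + spec$n_control
  width <- max(4, nchar(as.character(f)))
  fids <- sprintf("miR-sim-%0*d", width, seq_len(f))
  sids <- sprintf("S%03d", seq_len(n))
  labels <- c(rep("case", spec$n_case), rep("control", spec$n_control))

  base_mean <- 2^runif(f, spec$base_mean_log_range[1], spec$base_mean_log_range[2])
  informative <- sort(sample.int(f, spec$n_informative))
  n_up <- round(spec$n_informative * spec$direction_mix)
  sign <- rep(0, f)
  if (spec$n_informative > 0) {
    sign[informative] <- c(rep(1, n_up), rep(-1, spec$n_informative - n_up))
  }
  mean_control <- base_mean
  mean_case <- base_mean * 2^(sign * spec$log2_fold_change)

  size <- 1 / spec$nb_dispersion
  counts <- matrix(0, nrow = f, ncol = n)
  counts[, seq_len(spec$n_case)] <-
    rnbinom(f * spec$n_case, mu = rep(mean_case, spec$n_case), size = size)
  counts[, spec$n_case + seq_len(spec$n_control)] <-
    rnbinom(f * spec$n_control, mu = rep(mean_control, spec$n_control), size = size)

  structure(list(
    matrix = expr_matrix(counts, feature_ids = fids, sample_ids = sids),
    labels = sample_labels(sids, labels, positive_class = "case"),
    truth_informative = fids[informative],
    true_means = tibble::tibble(
      feature_id = fids, mean_case = mean_case, mean_control = mean_control,
      informative = sign != 0, direction = c("down", "none", "up")[sign + 2]
    ),
    spec = spec
  ), class = "synthetic_cohort")
}

#' Generate a null cohort (no informative features)
#'
#' Convenience wrapper over [simulate_cohort()] with
#' `n_informative = 0`: labels carry no information about any feature,
#' so any pipeline run on it should perform at chance.
#'
#' @param spec A [synthetic_spec()]; its `n_informative` is forced to 0.
#' @return A `synthetic_cohort` with an empty `truth_informative`.
#' @export
null_cohort <- function(spec = synthetic_spec()) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  spec$n_informative <- 0L
  simulate_cohort(spec)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d features x %d samples, %d planted informative\n",
              nrow(x$matrix), ncol(x$matrix), length(x$truth_informative)))
  invisible(x)
}
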