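#' Fit a per-feature transform on training samples
#'
#' The default preprocessing for count-scale expression data is
#' `log2(x + 1)` followed by a per-feature z-score. The mean and
#' standard deviation are estimated on the training samples only and
#' reused verbatim on any matrix the fit is later applied to, so no
#' information can leak from held-out samples into the scaling.
#' Zero-variance (constant) training features map to 0 after
#' centering.
#'
#' @param x Numeric matrix, samples in rows, features in columns (the
#'   model-facing orientation).
#' @param mode `"log2p1_zscore"` (default) or `"none"`.
#' @return A `feature_transform` object holding the fitted per-feature
#'   parameters.
#' @seealso [apply_feature_transform()], [transform_features()]
#' @export
fit_feature_transform <- function(x, mode = c("log2p1_zscore", "none")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (mode == "none") {
    fit <- list(mode = mode, feature_ids = colnames(x))
  } else {
    lx <- log2(x + 1)
    mu <- colMeans(lx)
    sigma <- apply(lx, 2, sd)
    fit <- list(mode = mode, feature_ids = colnames(x), mean = mu, sd = sigma)
  }
  structure(fit, class = "feature_transform")
}

#' Apply a fitted feature transform
#'
#' @param fit A [fit_feature_transform()] object.
#' @param x Samples-by-features matrix with the same feature columns
#'   the fit was trained on.
#' @return The transformed matrix (same shape as `x`).
#' @export
apply_feature_transform <- function(fit, x) {
  stopifnot(inherits(fit, "feature_transform"))
  x <- as.matrix(x)
  if (fit$mode == "none") return(x)
  if (!is.null(fit$feature_ids) && !is.null(colnames(x))) {
    if (!identical(colnames(x), fit$feature_ids)) {
      if (!all(fit$feature_ids %in% colnames(x))) {
        abort("Matrix lacks feature(s) the transform was fitted on.")
      }
      x <- x[, fit$feature_ids, drop = FALSE]
    }
  }
  z <- sweep(log2(x + 1), 2, fit$mean, "-")
  s <- fit$sd
  s[s == 0] <- Inf  # constant training feature -> centred value / Inf = 0
  sweep(z, 2, s, "/")
}

#' Transform train and apply-to matrices without leakage
#'
#' Convenience wrapper: fits the transform on `train` and applies the
#' fitted parameters to both `train` and `apply_to`.
#'
#' @param train Samples-by-features training matrix (parameters are
#'   estimated here and nowhere else).
#' @param apply_to Matrix to transform with the train-fitted
#'   parameters; defaults to `train`.
#' @param mode See [fit_feature_transform()].
#' @return A list with elements `train`, `applied` (transformed
#'   matrices) and `fit` (the fitted parameters).
#' @export
transform_features <- function(train, apply_to = train,
                               mode = c("log2p1_zscore", "none")) {
  fit <- fit_feature_transform(train, mode = mode)
  list(
    train = apply_feature_transform(fit, train),
    applied = apply_feature_transform(fit, apply_to),
    fit = fit
  )
}
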