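## Fold planning for the nested scheme: the outer loop partitions all
## samples into non-overlapping validation folds of ~`fraction` of the
## cohort (p-fold style, NOT combinatorial leave-p-out); the inner
## loop splits each outer training set into k stratified folds.

## Deal class members (already shuffled within class) into folds with
## fixed target sizes by largest-remainder apportionment against the
## remaining fold capacities. Each fold receives floor or ceiling of
## its proportional share of every class, so per-fold class counts
## stay within one sample of the stratified ideal while fold sizes
## are met exactly.
deal_stratified <- function(class_members, sizes) {
  n_folds <- length(sizes)
  capacity <- sizes
  folds <- vector("list", n_folds)
  for (members in class_members) {
    nc <- length(members)
    if (nc == 0) next
    quota <- nc * capacity / sum(capacity)
    alloc <- floor(quota)
    rem <- nc - sum(alloc)
    if (rem > 0) {
      for (f in order(-(quota - alloc), seq_len(n_folds))) {
        if (rem == 0) break
        if (alloc[f] < capacity[f]) {
          alloc[f] <- alloc[f] + 1
          rem <- rem - 1
        }
      }
    }
    pos <- 1
    for (f in seq_len(n_folds)) {
      if (alloc[f] > 0) {
        folds[[f]] <- c(folds[[f]], members[pos:(pos + alloc[f] - 1)])
        pos <- pos + alloc[f]
      }
    }
    capacity <- capacity - alloc
  }
  folds
}

#' Build the outer fold plan
#'
#' Partitions `n_samples` into non-overlapping validation folds. The
#' base validation-fold size is `p = floor(n_samples * fraction)`;
#' there are `floor(n_samples / p)` folds and the remainder
#' (`n_samples mod p`) is spread one sample per fold over the first
#' folds, so fold sizes never differ by more than one. With N = 60
#' and fraction 0.10 this yields 10 folds of 6 validation samples
#' against 54 training samples each. Folds are stratified by class by
#' default so no validation set can be single-class.
#'
#' @param n_samples Number of samples.
#' @param fraction Validation fraction in (0, 1); default 0.10.
#' @param labels A [sample_labels()] (required when `stratified`).
#' @param seed Integer seed for the shuffle.
#' @param stratified Stratify folds by class (default `TRUE`).
#' @return A `fold_plan` object: list with `outer`, a list of
#'   `list(fold, train, validation)` index vectors, plus the plan
#'   parameters.
#' @export
make_outer_folds <- function(n_samples, fraction = 0.10, labels = NULL,
                             seed = 1L, stratified = TRUE) {
  if (fraction <= 0 || fraction >= 1) abort("fraction must lie in (0, 1).")
  p <- floor(n_samples * fraction)
  if (p < 1) abort("fraction too small: validation folds would be empty.")
  n_folds <- floor(n_samples / p)
  sizes <- rep(floor(n_samples / n_folds), n_folds)
  extra <- n_samples - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  set.seed(seed)
  if (stratified) {
    if (is.null(labels)) abort("`labels` are required for stratified folds.")
    if (nrow(labels) != n_samples) abort("labels/sample-count mismatch.")
    classes <- sort(unique(labels$label))
    members <- lapply(classes, function(cl) sample(which(labels$label == cl)))
    val_sets <- deal_stratified(members, sizes)
  } else {
    shuffled <- sample.int(n_samples)
    val_sets <- split(shuffled, rep(seq_len(n_folds), times = sizes))
  }
  outer <- lapply(seq_len(n_folds), function(i) {
    v <- sort(val_sets[[i]])
    list(fold = i, train = setdiff(seq_len(n_samples), v), validation = v)
  })
  structure(list(outer = outer, n_samples = n_samples, fraction = fraction,
                 fold_size = p, seed = seed, stratified = stratified),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  sizes <- vapply(x$outer, function(f) length(f$validation), integer(1))
  cat(sprintf("<fold_plan> %d outer folds over %d samples (validation sizes: %s)\n",
              length(x$outer), x$n_samples,
              paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Build stratified inner folds inside one outer training set
#'
#' Splits `train_indices` into `k` stratified folds; each pair uses
#' one fold for inner testing (`validation`) and the remaining k-1
#' folds for inner training (`train`, about (k-1)/k of the outer
#' training set — 80% at the default k = 5). Every class must have at
#' least `k` members.
#'
#' @param train_indices Sample indices of the outer training set.
#' @param labels A [sample_labels()] over ALL samples (subset
#'   internally).
#' @param k Number of inner folds (>= 2).
#' @param seed Integer seed.
#' @return List of `list(fold, train, validation)` index pairs; the
#'   validation parts partition `train_indices`.
#' @export
make_inner_folds <- function(train_indices, labels, k = 5, seed = 1L) {
  if (k < 2) abort("k must be >= 2.")
  lab <- labels$label[train_indices]
  counts <- table(lab)
  if (any(counts < k)) {
    small <- names(counts)[which.min(counts)]
    abort(sprintf("Class '%s' has %d sample(s) in this training set; %d folds need at least %d.",
                  small, min(counts), k, k))
  }
  n <- length(train_indices)
  sizes <- rep(floor(n / k), k)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  set.seed(seed)
  classes <- sort(unique(lab))
  members <- lapply(classes, function(cl) sample(train_indices[lab == cl]))
  val_sets <- deal_stratified(members, sizes)
  lapply(seq_len(k), function(j) {
    v <- sort(val_sets[[j]])
    list(fold = j, train = setdiff(train_indices, v), validation = v)
  })
}

#' Validate a fold plan against the sample space
#'
#' The leakage guard: asserts that the outer validation folds are
#' pairwise disjoint and cover all samples, and that every fold's
#' train set is exactly the complement of its validation set. Any
#' violation aborts — a corrupted plan must never reach model fitting.
#'
#' @param plan A `fold_plan`.
#' @param n_samples Expected number of samples.
#' @return `plan`, invisibly, if valid.
#' @export
check_fold_plan <- function(plan, n_samples) {
  if (!inherits(plan, "fold_plan")) abort("Not a fold_plan.")
  if (plan$n_samples != n_samples) abort("Fold plan built for a different cohort size.")
  all_idx <- seq_len(n_samples)
  val_all <- unlist(lapply(plan$outer, `[[`, "validation"))
  if (anyDuplicated(val_all)) {
    abort("Leakage: outer validation folds overlap.")
  }
  if (!setequal(val_all, all_idx)) {
    abort("Leakage: outer validation folds do not cover all samples.")
  }
  for (f in plan$outer) {
    if (length(intersect(f$train, f$validation)) > 0) {
      abort(sprintf("Leakage: fold %d train and validation sets overlap.", f$fold))
    }
    if (!setequal(union(f$train, f$validation), all_idx)) {
      abort(sprintf("Fold %d does not partition the sample space.", f$fold))
    }
  }
  invisible(plan)
}

## inner-loop guard: every index used for fitting must come from T_i
assert_subset_of_train <- function(idx, train_indices, what) {
  if (!all(idx %in% train_indices)) {
    abort(sprintf("Leakage: %s touches indices outside the outer training set.", what))
  }
  invisible(idx)
}
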