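#' Labeled expression-matrix container
#'
#' An `expr_matrix` holds a feature-by-sample block of nonnegative,
#' finite expression values (normalized counts) together with unique
#' feature and sample identifiers. It is the container every pipeline
#' stage consumes; files on disk may be oriented either way, but the
#' in-memory representation is always feature-major (features in rows).
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#' @param feature_ids Character vector of unique feature identifiers,
#'   one per row of `values`. Defaults to `rownames(values)`.
#' @param sample_ids Character vector of unique sample identifiers,
#'   one per column of `values`. Defaults to `colnames(values)`.
#'
#' @return An object of class `expr_matrix`: a numeric matrix with
#'   feature IDs as rownames and sample IDs as colnames.
#' @export
#' @examples
#' m <- expr_matrix(matrix(1:6, 3, 2), paste0("f", 1:3), c("s1", "s2"))
#' dim(m)
expr_matrix <- function(values, feature_ids = rownames(values),
                        sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids) || is.null(sample_ids)) {
    abort("`feature_ids` and `sample_ids` are required when `values` has no dimnames.")
  }
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values)) {
    abort(sprintf("%d feature IDs for %d rows.", length(feature_ids), nrow(values)))
  }
  if (length(sample_ids) != ncol(values)) {
    abort(sprintf("%d sample IDs for %d columns.", length(sample_ids), ncol(values)))
  }
  dup_f <- feature_ids[duplicated(feature_ids)]
  if (length(dup_f) > 0) {
    abort(sprintf("Duplicate feature ID(s): %s", paste(unique(dup_f), collapse = ", ")))
  }
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s) > 0) {
    abort(sprintf("Duplicate sample ID(s): %s", paste(unique(dup_s), collapse = ", ")))
  }
  bad <- which(!is.finite(values))
  if (length(bad) > 0) {
    i <- arrayInd(bad[1], dim(values))
    abort(sprintf("Non-finite value at feature '%s', sample '%s'.",
                  feature_ids[i[1]], sample_ids[i[2]]))
  }
  neg <- which(values < 0)
  if (length(neg) > 0) {
    i <- arrayInd(neg[1], dim(values))
    abort(sprintf("Negative value (%g) at feature '%s', sample '%s'.",
                  values[neg[1]], feature_ids[i[1]], sample_ids[i[2]]))
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(values, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d features x %d samples\n", nrow(x), ncol(x)))
  cat("features:", paste(utils::head(rownames(x), 3), collapse = ", "),
      if (nrow(x) > 3) "..." else "", "\n")
  cat("samples: ", paste(utils::head(colnames(x), 3), collapse = ", "),
      if (ncol(x) > 3) "..." else "", "\n")
  invisible(x)
}

feature_ids <- function(x) rownames(x)
sample_ids <- function(x) colnames(x)

#' Convert an expression matrix to a long tibble
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `feature_id`, `sample_id`, `value`.
#' @method as_tibble expr_matrix
#' @export
as_tibble.expr_matrix <- function(x, ...) {
  tibble::tibble(
    feature_id = rep(rownames(x), times = ncol(x)),
    sample_id = rep(colnames(x), each = nrow(x)),
    value = as.vector(unclass(x))
  )
}

#' Read a delimited expression matrix
#'
#' Reads a TSV/CSV expression table with an ID header row and an ID
#' first column. Orientation is explicit — files are never
#' auto-transposed, because silently guessing the orientation is the
#' classic failure mode with near-square expression tables.
#'
#' @param path Path to a delimited text file. The delimiter is taken
#'   from the extension (`.csv` is comma, anything else tab) unless
#'   `sep` is given.
#' @param orientation `"features_in_rows"` (the transcriptomics file
#'   convention, default) or `"samples_in_rows"`.
#' @param sep Field separator override.
#' @return An [expr_matrix()] (always features in rows internally).
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("features_in_rows", "samples_in_rows"),
                                   sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  widths <- count.fields(path, sep = sep, quote = "\"")
  if (length(unique(widths)) > 1) {
    bad_row <- which(widths != widths[1])[1]
    abort(sprintf("Ragged file: row %d has %d fields, expected %d.",
                  bad_row, widths[bad_row], widths[1]))
  }
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2) abort("Expected an ID column plus at least one value column.")
  row_ids <- df[[1]]
  body <- df[, -1, drop = FALSE]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1) num <- matrix(num, nrow = 1, dimnames = list(NULL, colnames(body)))
  bad <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("Non-numeric cell '%s' at row '%s', column '%s'.",
                  as.matrix(body)[bad[1, 1], bad[1, 2]],
                  row_ids[bad[1, 1]], colnames(body)[bad[1, 2]]))
  }
  if (orientation == "features_in_rows") {
    expr_matrix(num, feature_ids = row_ids, sample_ids = colnames(body))
  } else {
    expr_matrix(t(num), feature_ids = colnames(body), sample_ids = row_ids)
  }
}

#' Write an expression matrix to delimited text
#'
#' Values are written at 12 significant digits so that a write/read
#' round trip reproduces the matrix exactly within text formatting.
#'
#' @param x An [expr_matrix()].
#' @param path Output path; `.csv` writes comma-separated, else TSV.
#' @param orientation Layout on disk (see [read_expression_matrix()]).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path,
                                    orientation = c("features_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  m <- unclass(x)
  if (orientation == "samples_in_rows") m <- t(m)
  id_col <- if (orientation == "features_in_rows") "feature_id" else "sample_id"
  out <- data.frame(rownames(m), signif(m, 12), check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out) <- c(id_col, colnames(m))
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-class sample labels
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param labels Character vector (or factor) of class labels, one per
#'   sample; exactly two distinct labels, both present.
#' @param positive_class The label treated as the positive (case)
#'   class in every metric. Defaults to `"case"` when present,
#'   otherwise the rarer class (ties broken lexicographically).
#' @return A `sample_labels` tibble with columns `sample_id`, `label`
#'   and a `positive_class` attribute.
#' @export
sample_labels <- function(sample_ids, labels, positive_class = NULL) {
  sample_ids <- as.character(sample_ids)
  labels <- as.character(labels)
  if (length(sample_ids) != length(labels)) {
    abort("One label per sample is required.")
  }
  if (anyDuplicated(sample_ids)) {
    abort(sprintf("Duplicate sample ID(s): %s",
                  paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  }
  if (anyNA(labels)) abort("Missing label value(s).")
  classes <- sort(unique(labels))
  if (length(classes) != 2) {
    abort(sprintf("Binary task requires exactly 2 classes, found %d (%s).",
                  length(classes), paste(classes, collapse = ", ")))
  }
  if (is.null(positive_class)) {
    positive_class <- if ("case" %in% classes) {
      "case"
    } else {
      counts <- table(labels)
      names(counts)[order(counts, names(counts))][1]
    }
  }
  if (!positive_class %in% classes) {
    abort(sprintf("positive_class '%s' is not a label (labels: %s).",
                  positive_class, paste(classes, collapse = ", ")))
  }
  out <- tibble::tibble(sample_id = sample_ids, label = labels)
  class(out) <- c("sample_labels", class(out))
  attr(out, "positive_class") <- positive_class
  out
}

#' @export
print.sample_labels <- function(x, ...) {
  counts <- table(x$label)
  cat(sprintf("<sample_labels> %d samples (%s); positive class: %s\n",
              nrow(x),
              paste(sprintf("%s: %d", names(counts), counts), collapse = ", "),
              positive_class(x)))
  invisible(x)
}

#' Positive class of a label set
#' @param x A `sample_labels` object.
#' @return The positive class label (length-1 character).
#' @export
positive_class <- function(x) attr(x, "positive_class")

#' Read sample labels and align them to a matrix
#'
#' @param path Two-column delimited file (`sample_id`, `label`).
#' @param matrix An [expr_matrix()] whose sample order the labels are
#'   reordered to. Coverage must be exact: every matrix sample
#'   labeled, no extra samples in the file.
#' @param header Does the file carry a header row? Default `TRUE`.
#' @param positive_class See [sample_labels()].
#' @param sep Field separator override (extension-based default).
#' @return A [sample_labels()] tibble in matrix sample order.
#' @export
read_labels <- function(path, matrix, header = TRUE, positive_class = NULL,
                        sep = NULL) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = header, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) abort("Label file needs two columns: sample_id, label.")
  ids <- df[[1]]
  labs <- df[[2]]
  unknown <- setdiff(ids, sample_ids(matrix))
  if (length(unknown) > 0) {
    abort(sprintf("Label file has unknown sample ID(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(sample_ids(matrix), ids)
  if (length(missing) > 0) {
    abort(sprintf("Sample(s) without a label: %s", paste(missing, collapse = ", ")))
  }
  ord <- match(sample_ids(matrix), ids)
  sample_labels(ids[ord], labs[ord], positive_class = positive_class)
}

#' Write labels to a two-column TSV
#' @param labels A [sample_labels()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  write.table(labels[, c("sample_id", "label")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
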