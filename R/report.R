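#' @export
print.efscv_report <- function(x, ...) {
  cat(sprintf("<efscv_report> %d features x %d samples, %d outer folds\n",
              x$n_features, x$n_samples, x$n_outer_folds))
  cat(sprintf("minimal signature: %d feature(s); best model: %s\n",
              nrow(x$f_minimal), x$best_model))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-12s %.3f +/- %.3f  (95%% CI %.3f-%.3f)\n",
                agg$metric[i], agg$mean[i], agg$sd[i], agg$ci_lo[i], agg$ci_hi[i]))
  }
  if (length(x$warnings) > 0) {
    cat(sprintf("warnings: %d (see $warnings)\n", length(x$warnings)))
  }
  invisible(x)
}

#' Tidy per-fold validation metrics of a pipeline report
#'
#' @param x An `efscv_report`.
#' @param ... Unused.
#' @return A long tibble: `fold`, `model`, `metric`, `value`.
#' @method tidy efscv_report
#' @export
tidy.efscv_report <- function(x, ...) {
  core <- c("accuracy", "sensitivity", "specificity", "f1", "auc")
  x$outer_metrics |>
    dplyr::select("fold", "model", dplyr::all_of(core)) |>
    tidyr::pivot_longer(dplyr::all_of(core), names_to = "metric",
                        values_to = "value")
}

#' One-row summary of a pipeline report
#'
#' @param x An `efscv_report`.
#' @param ... Unused.
#' @return A one-row tibble: best model, signature size, fold counts,
#'   and the mean of each validation metric.
#' @method glance efscv_report
#' @export
glance.efscv_report <- function(x, ...) {
  means <- stats::setNames(x$aggregate$mean, paste0("mean_", x$aggregate$metric))
  tibble::tibble(
    best_model = x$best_model,
    n_signature = nrow(x$f_minimal),
    n_outer_folds = x$n_outer_folds,
    n_samples = x$n_samples,
    n_features = x$n_features,
    !!!as.list(means),
    n_warnings = length(x$warnings)
  )
}

#' Plot per-fold validation metrics
#'
#' Per-fold metric values (points) with the aggregate mean and its
#' 95% confidence interval overlaid per metric.
#'
#' @param object An `efscv_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot efscv_report
#' @export
autoplot.efscv_report <- function(object, ...) {
  per_fold <- tidy(object)
  ggplot2::ggplot(per_fold, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.6,
                         ggplot2::aes(colour = .data$model)) +
    ggplot2::geom_pointrange(
      data = object$aggregate,
      ggplot2::aes(x = .data$metric, y = .data$mean,
                   ymin = .data$ci_lo, ymax = .data$ci_hi),
      inherit.aes = FALSE, shape = 18, size = 0.8
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "outer validation value", colour = "model",
                  title = "Outer-fold validation metrics",
                  subtitle = sprintf("best model: %s; signature size: %d",
                                     object$best_model, nrow(object$f_minimal))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

report_to_list <- function(report) {
  list(
    package_version = as.character(utils::packageVersion("efscv")),
    seed = report$seed,
    positive_class = report$positive_class,
    n_samples = report$n_samples,
    n_features = report$n_features,
    n_outer_folds = report$n_outer_folds,
    best_model = report$best_model,
    f_minimal = as.list(report$f_minimal),
    outer_metrics = as.list(report$outer_metrics),
    aggregate = as.list(report$aggregate),
    inner_summary = as.list(report$inner_summary),
    config = report$config,
    warnings = as.list(report$warnings),
    notes = as.list(report$notes)
  )
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (the full machine-readable report — no
#' timestamps, so identical runs are byte-identical), `fminimal.tsv`
#' (the signature with fold hits, selector votes, and mean scores),
#' `metrics_per_fold.csv`, and `metrics_aggregate.csv`.
#'
#' @param report An `efscv_report`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "efscv_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_to_list(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  fm <- dplyr::left_join(report$f_minimal,
                         report$feature_stats[, c("feature_id", "selector_votes", "mean_score")],
                         by = "feature_id")
  write.table(fm, file.path(dir, "fminimal.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  utils::write.csv(report$outer_metrics, file.path(dir, "metrics_per_fold.csv"),
                   row.names = FALSE)
  utils::write.csv(report$aggregate, file.path(dir, "metrics_aggregate.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Render a report as a fixed-width text table
#'
#' Deterministic plain-text rendering of the aggregate validation
#' metrics (`mean +/- sd (95% CI)` per metric) plus the signature —
#' the layout mirrors the usual benchmarking tables of this
#' literature.
#'
#' @param report An `efscv_report` or a path to a `report.json`.
#' @return Character vector of lines, invisibly; also printed.
#' @export
render_report <- function(report) {
  if (is.character(report)) {
    if (!file.exists(report)) abort(sprintf("No such report: %s", report))
    r <- jsonlite::read_json(report, simplifyVector = TRUE)
    if (is.null(r$aggregate) || is.null(r$best_model)) {
      abort("Malformed report: missing aggregate metrics or best model.")
    }
    agg <- tibble::as_tibble(r$aggregate)
    fm <- tibble::as_tibble(r$f_minimal)
    best <- r$best_model
    notes <- unlist(r$notes)
  } else {
    stopifnot(inherits(report, "efscv_report"))
    agg <- report$aggregate
    fm <- report$f_minimal
    best <- report$best_model
    notes <- report$notes
  }
  lines <- c(
    sprintf("Best model: %s", best),
    sprintf("Minimal signature (%d features): %s", nrow(fm),
            paste(fm$feature_id, collapse = ", ")),
    "",
    sprintf("%-12s %-16s %s", "metric", "mean +/- sd", "95% CI"),
    vapply(seq_len(nrow(agg)), function(i) {
      sprintf("%-12s %.3f +/- %.3f   (%.3f, %.3f)", agg$metric[i], agg$mean[i],
              agg$sd[i], agg$ci_lo[i], agg$ci_hi[i])
    }, character(1))
  )
  if (length(notes) > 0) lines <- c(lines, "", paste("note:", notes))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: package version,
#' config echo, input-file MD5 digests, seed, timestamps, and
#' warnings. Timestamps live here (not in `report.json`) so the
#' report itself stays byte-reproducible.
#'
#' @param dir Output directory.
#' @param config A [pipeline_config()] (or any list echoed as-is).
#' @param seed Integer seed.
#' @param inputs Named character vector of input file paths.
#' @param warnings Character vector of run warnings.
#' @param started,finished POSIXct timestamps.
#' @return Path to `manifest.json`, invisibly.
#' @export
write_manifest <- function(dir, config, seed, inputs = character(0),
                           warnings = character(0), started = Sys.time(),
                           finished = Sys.time()) {
  digests <- if (length(inputs) > 0) {
    as.list(stats::setNames(unname(tools::md5sum(inputs)), names(inputs)))
  } else list()
  manifest <- list(
    tool = "efscv",
    version = as.character(utils::packageVersion("efscv")),
    seed = as.integer(seed),
    config = if (inherits(config, "pipeline_config")) unclass(config) else config,
    input_digests = digests,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
    warnings = as.list(warnings)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
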