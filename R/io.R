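#' Write a feature table to CSV plus a metadata sidecar
#'
#' The CSV holds the numeric matrix with `channel.band.type` header names;
#' the sidecar (`<path>.meta.json`) holds the per-sample metadata and the
#' normalized flag. Values round-trip through [read_feature_table()] to
#' better than 1e-12.
#'
#' @param table A [feature_table].
#' @param path CSV output path; the sidecar lands next to it.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- tibble::as_tibble(table$values)
  readr::write_csv(df, path)
  sidecar <- paste0(path, ".meta.json")
  jsonlite::write_json(
    list(normalized = table$normalized,
         sample_meta = table$sample_meta),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' Rebuilds the values, the per-column provenance (parsed from the
#' `channel.band.type` header) and the sample metadata. Errors name any
#' malformed header column; a missing sidecar or an empty file is an error,
#' not an empty table.
#'
#' @param path CSV path (sidecar expected at `<path>.meta.json`).
#' @return A [feature_table].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  sidecar <- paste0(path, ".meta.json")
  if (!file.exists(sidecar)) {
    stop("Missing metadata sidecar: ", sidecar, call. = FALSE)
  }
  df <- suppressMessages(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
  if (nrow(df) == 0 || ncol(df) == 0) {
    stop("Feature CSV is empty: ", path, call. = FALSE)
  }
  columns <- parse_feature_column_names(names(df))
  if (!all(columns$type %in% c("DE", "PSD"))) {
    bad <- names(df)[!columns$type %in% c("DE", "PSD")]
    stop("Malformed feature column name(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  meta_json <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  sample_meta <- tibble::as_tibble(meta_json$sample_meta)
  if (nrow(sample_meta) != nrow(df)) {
    stop("Sidecar metadata has ", nrow(sample_meta), " rows but the CSV has ",
         nrow(df), ".", call. = FALSE)
  }
  feature_table(as.matrix(df), columns, sample_meta,
                normalized = isTRUE(meta_json$normalized))
}

#' Write an evaluation report to a directory
#'
#' Writes `per_fold.csv` (per held-out-domain accuracies), `summary.csv`
#' (one row per method/axis with the mean accuracy to 3 decimals plus a
#' full-precision companion column) and `manifest.json` (full config echo,
#' seed, package version).
#'
#' @param report A `brada_eval` report (or list of them).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  if (inherits(report, "brada_eval")) report <- list(report)
  stopifnot(all(vapply(report, inherits, TRUE, "brada_eval")))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  per_fold <- purrr::map_dfr(report, function(r)
    dplyr::mutate(r$per_fold, method = r$config$method,
                  label_axis = r$config$label_axis, protocol = r$protocol))
  readr::write_csv(per_fold, file.path(dir, "per_fold.csv"))
  summary <- purrr::map_dfr(report, function(r)
    tibble::tibble(method = r$config$method,
                   label_axis = r$config$label_axis,
                   protocol = r$protocol,
                   mean_accuracy = round(r$mean_accuracy, 3),
                   mean_accuracy_full = r$mean_accuracy,
                   pooled_accuracy = round(r$pooled_accuracy, 3),
                   n_folds = nrow(r$per_fold),
                   h = r$chosen_h))
  readr::write_csv(summary, file.path(dir, "summary.csv"))
  manifest <- run_manifest(
    config = lapply(report, function(r) config_to_list(r$config)),
    outputs = c("per_fold.csv", "summary.csv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

config_to_list <- function(cfg) {
  out <- unclass(cfg)
  if (!is.null(out$kernel)) out$kernel <- unclass(out$kernel)
  out
}

#' Assemble a run manifest
#'
#' A serializable record sufficient to re-run an experiment: the full
#' configuration, seed, package version, input-file digests and output
#' list.
#'
#' @param config Configuration echo (list).
#' @param inputs Character vector of input file paths (digested with MD5).
#' @param outputs Character vector of output file names.
#' @param seed Seed used, if any.
#' @param wall_time Elapsed seconds, if measured.
#' @return A named list.
#' @export
run_manifest <- function(config = list(), inputs = character(),
                         outputs = character(), seed = NULL,
                         wall_time = NULL) {
  digests <- if (length(inputs)) {
    as.list(tools::md5sum(inputs))
  } else list()
  list(
    package = "brada",
    version = as.character(utils::packageVersion("brada")),
    seed = seed,
    config = config,
    input_digests = digests,
    outputs = as.list(outputs),
    wall_time_sec = wall_time
  )
}

#' Read a flat dotted-key YAML configuration
#'
#' Keys like `adapt.kernel.degree: 3` override [brada_config()] defaults;
#' recognised keys are `method`, `h`, `mu`, `label_axis`,
#' `binarize_threshold`, `normalize`, `transductive`, `seed`,
#' `kernel.kind`, `kernel.degree`, `kernel.coef0`, `kernel.gamma_scale`,
#' `svm.kernel`, `svm.cost`.
#'
#' @param path YAML file path.
#' @param overrides Named list applied on top of the file values (CLI flags
#'   win over file values).
#' @return A [brada_config].
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  vals[names(overrides)] <- overrides
  kernel_keys <- grep("^kernel\\.", names(vals), value = TRUE)
  kernel <- NULL
  if (length(kernel_keys)) {
    kl <- stats::setNames(vals[kernel_keys],
                          sub("^kernel\\.", "", kernel_keys))
    kernel <- kernel_spec(kind = kl$kind %||% "polynomial",
                          degree = kl$degree %||% 2,
                          coef0 = kl$coef0 %||% 1,
                          gamma_scale = kl$gamma_scale)
  }
  svm <- list(kernel = vals[["svm.kernel"]] %||% "linear",
              cost = vals[["svm.cost"]] %||% 1)
  brada_config(
    method = vals$method %||% "brada",
    h = vals$h %||% 40,
    mu = vals$mu %||% 1,
    kernel = kernel,
    label_axis = vals$label_axis %||% "valence",
    binarize_threshold = vals$binarize_threshold %||% 5,
    svm = svm,
    normalize = vals$normalize %||% TRUE,
    transductive = vals$transductive %||% TRUE,
    seed = vals$seed %||% 0L
  )
}
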