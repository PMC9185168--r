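#' Construct a feature table
#'
#' The central tabular container: an n x m numeric matrix of per-trial
#' features, per-column provenance (which channel, frequency band and feature
#' type each column came from) and per-row sample metadata (subject, database,
#' valence/arousal ratings). Column names are `channel.band.type`.
#'
#' @param values Numeric matrix, samples x features; no missing values.
#' @param columns Data frame with columns `channel`, `band`,
#'   `type` (`"DE"` or `"PSD"`), one row per feature column.
#' @param sample_meta Data frame with one row per sample; must contain
#'   `subject_id` and `database_id`; typically also `valence`, `arousal`.
#' @param normalized Logical flag: has joint min-max scaling been applied?
#' @return A `feature_table` object.
#' @export
feature_table <- function(values, columns, sample_meta, normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  columns <- tibble::as_tibble(columns)
  sample_meta <- tibble::as_tibble(sample_meta)
  if (!all(c("channel", "band", "type") %in% names(columns))) {
    stop("`columns` must have channel, band and type columns.", call. = FALSE)
  }
  if (nrow(columns) != ncol(values)) {
    stop("Provenance has ", nrow(columns), " rows but `values` has ",
         ncol(values), " columns.", call. = FALSE)
  }
  if (nrow(sample_meta) != nrow(values)) {
    stop("`sample_meta` has ", nrow(sample_meta), " rows but `values` has ",
         nrow(values), " samples.", call. = FALSE)
  }
  if (!all(c("subject_id", "database_id") %in% names(sample_meta))) {
    stop("`sample_meta` must contain subject_id and database_id.",
         call. = FALSE)
  }
  if (anyNA(values) || !all(is.finite(values))) {
    stop("Feature values must be finite with no missing entries.",
         call. = FALSE)
  }
  if (!all(columns$type %in% c("DE", "PSD"))) {
    stop("Feature type must be DE or PSD.", call. = FALSE)
  }
  colnames(values) <- feature_column_names(columns)
  structure(
    list(values = values, columns = columns, sample_meta = sample_meta,
         normalized = isTRUE(normalized)),
    class = "feature_table"
  )
}

feature_column_names <- function(columns) {
  paste(columns$channel, columns$band, columns$type, sep = ".")
}

parse_feature_column_names <- function(names) {
  parts <- strsplit(names, ".", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 3L)
  if (length(bad)) {
    stop("Malformed feature column name(s): ",
         paste(names[bad], collapse = ", "),
         " (expected channel.band.type).", call. = FALSE)
  }
  tibble::tibble(
    channel = vapply(parts, `[`, "", 1L),
    band = vapply(parts, `[`, "", 2L),
    type = vapply(parts, `[`, "", 3L)
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw"))
  cat("  subjects:", length(unique(x$sample_meta$subject_id)),
      " databases:", paste(unique(x$sample_meta$database_id), collapse = ", "),
      " channels:", length(unique(x$columns$channel)), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Coerce a feature table to a tibble
#'
#' Sample metadata columns first, then one column per feature.
#'
#' @param x A [feature_table].
#' @param ... Unused.
#' @return A tibble with `nrow(x)` rows.
#' @method as_tibble feature_table
#' @export
as_tibble.feature_table <- function(x, ...) {
  dplyr::bind_cols(x$sample_meta, tibble::as_tibble(x$values))
}

#' Tidy a feature table into long form
#'
#' One row per (sample, feature) with provenance unpacked — convenient for
#' ggplot summaries of per-band or per-channel feature distributions.
#'
#' @param x A [feature_table].
#' @param ... Unused.
#' @return A tibble with columns `sample`, `subject_id`, `database_id`,
#'   `channel`, `band`, `type`, `value`.
#' @method tidy feature_table
#' @export
tidy.feature_table <- function(x, ...) {
  long <- tibble::tibble(
    sample = rep(seq_len(nrow(x$values)), times = ncol(x$values)),
    subject_id = rep(x$sample_meta$subject_id, times = ncol(x$values)),
    database_id = rep(x$sample_meta$database_id, times = ncol(x$values)),
    channel = rep(x$columns$channel, each = nrow(x$values)),
    band = rep(x$columns$band, each = nrow(x$values)),
    type = rep(x$columns$type, each = nrow(x$values)),
    value = as.vector(x$values)
  )
  long
}

#' Subset the feature columns of a table by channel set
#'
#' Keeps only the columns whose channel belongs to `channels`, ordered
#' channel-major following the channel-set order (band, then feature type
#' within channel). Sample metadata is unchanged.
#'
#' @param table A [feature_table].
#' @param channels A [channel_set] or character vector of channel names.
#' @return A `feature_table` restricted to the requested channels.
#' @export
select_feature_channels <- function(table, channels) {
  stopifnot(inherits(table, "feature_table"))
  wanted <- canonical_channels(as.character(channels))
  missing <- setdiff(wanted, unique(table$columns$channel))
  if (length(missing)) {
    stop("Channel(s) absent from the feature table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  idx <- unlist(lapply(wanted, function(ch) which(table$columns$channel == ch)))
  feature_table(table$values[, idx, drop = FALSE],
                table$columns[idx, , drop = FALSE],
                table$sample_meta, normalized = table$normalized)
}

#' Row-bind two feature tables with identical schemas
#'
#' Used by the cross-database protocol to pool two databases before joint
#' normalization and subspace learning. Errors name any differing columns.
#'
#' @param a,b [feature_table] objects with identical column provenance.
#' @return A combined `feature_table`.
#' @export
bind_feature_tables <- function(a, b) {
  stopifnot(inherits(a, "feature_table"), inherits(b, "feature_table"))
  na <- feature_column_names(a$columns)
  nb <- feature_column_names(b$columns)
  if (!identical(na, nb)) {
    diff <- union(setdiff(na, nb), setdiff(nb, na))
    if (!length(diff)) diff <- "column order differs"
    stop("Feature schemas differ between tables: ",
         paste(utils::head(diff, 10), collapse = ", "), call. = FALSE)
  }
  if (a$normalized != b$normalized) {
    stop("Cannot bind a normalized table to a raw one.", call. = FALSE)
  }
  meta <- dplyr::bind_rows(a$sample_meta, b$sample_meta)
  feature_table(rbind(a$values, b$values), a$columns, meta,
                normalized = a$normalized)
}
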