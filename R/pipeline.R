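#' Pipeline configuration
#'
#' Bundles every tunable of the evaluation pipeline. `method` selects the
#' feature transformation applied before the SVM:
#' * `baseline` — normalized features of the selected channels, no
#'   adaptation;
#' * `tca`, `sa`, `mida` — the corresponding transfer method on the
#'   full-montage features (linear kernel);
#' * `brada_tca`, `brada_sa`, `brada_mida` — the same solvers applied per
#'   brain region with the projections concatenated;
#' * `brada` — region-wise maximum-independence adaptation with the
#'   polynomial kernel (the method's flagship configuration).
#'
#' @param method One of the methods above.
#' @param h Subspace dimension per region (default 40).
#' @param mu Variance/independence trade-off (default 1).
#' @param kernel Optional [kernel_spec] overriding the method default
#'   (polynomial degree 2 for `brada`, linear otherwise).
#' @param label_axis `"valence"` or `"arousal"`.
#' @param binarize_threshold Ratings strictly above this are the high class
#'   (default 5).
#' @param svm List with `kernel` and `cost` for the classifier (defaults:
#'   linear, C = 1).
#' @param normalize Apply joint min-max scaling before adaptation?
#' @param transductive Should unlabeled evaluation samples enter subspace
#'   learning (default `TRUE`, matching the method's unsupervised design)?
#' @param regions Character vector of regions used by the `brada_*` methods.
#' @param h_grid Candidate dimensions for [search_h()].
#' @param seed Integer seed controlling any pipeline randomness.
#' @return A `brada_config` list.
#' @export
brada_config <- function(method = c("brada", "baseline", "tca", "sa", "mida",
                                    "brada_tca", "brada_sa", "brada_mida"),
                         h = 40, mu = 1, kernel = NULL,
                         label_axis = c("valence", "arousal"),
                         binarize_threshold = 5,
                         svm = list(kernel = "linear", cost = 1),
                         normalize = TRUE, transductive = TRUE,
                         regions = c("auditory", "visual"),
                         h_grid = seq(10, 100, by = 10),
                         seed = 0L) {
  method <- match.arg(method)
  label_axis <- match.arg(label_axis)
  if (mu <= 0) stop("mu must be positive.", call. = FALSE)
  if (!is.null(kernel)) stopifnot(inherits(kernel, "kernel_spec"))
  structure(
    list(method = method, h = h, mu = mu, kernel = kernel,
         label_axis = label_axis, binarize_threshold = binarize_threshold,
         svm = svm, normalize = normalize, transductive = transductive,
         regions = regions, h_grid = h_grid, seed = as.integer(seed)),
    class = "brada_config"
  )
}

method_kernel <- function(cfg) {
  if (!is.null(cfg$kernel)) return(cfg$kernel)
  if (cfg$method == "brada") kernel_spec("polynomial", degree = 2, coef0 = 1)
  else kernel_spec("linear")
}

#' Binarize 1-9 affective ratings
#'
#' `high` iff the rating strictly exceeds the threshold; ratings exactly at
#' the threshold go to the low class.
#'
#' @param ratings Numeric vector of ratings on the 1-9 scale.
#' @param threshold Cut point (default 5).
#' @return Factor with levels `low`, `high`.
#' @export
binarize_labels <- function(ratings, threshold = 5) {
  if (any(!is.finite(ratings)) || any(ratings < 1 | ratings > 9)) {
    stop("Ratings must lie within the 1-9 scale.", call. = FALSE)
  }
  factor(ifelse(ratings > threshold, "high", "low"),
         levels = c("low", "high"))
}

#' SVM classification of projected features
#'
#' Thin wrapper over [e1071::svm] with the pipeline defaults (linear
#' kernel, C = 1, no internal rescaling — features are already processed).
#'
#' @param Z_train,Z_test Numeric matrices, samples x dimensions.
#' @param y_train Factor of training labels (needs both classes).
#' @param y_test Optional test labels; when given, accuracy is computed.
#' @param svm List with `kernel` and `cost`.
#' @return List with `predictions` (factor) and `accuracy` (or `NA`).
#' @export
svm_classify <- function(Z_train, y_train, Z_test, y_test = NULL,
                         svm = list(kernel = "linear", cost = 1)) {
  y_train <- droplevels(as.factor(y_train))
  if (nlevels(y_train) < 2) {
    stop("SVM training requires at least two classes.", call. = FALSE)
  }
  Z_train <- as.matrix(Z_train)
  Z_test <- as.matrix(Z_test)
  # center and globally rescale with training-set statistics (applied
  # unchanged to the test rows): keeps the solver well-conditioned whatever
  # the projection scale while preserving the relative weighting of the
  # subspace components
  mu <- colMeans(Z_train)
  scale <- stats::sd(as.vector(sweep(Z_train, 2, mu)))
  if (!is.finite(scale) || scale == 0) scale <- 1
  Z_train <- sweep(Z_train, 2, mu) / scale
  Z_test <- sweep(Z_test, 2, mu) / scale
  fit <- e1071::svm(x = Z_train, y = y_train,
                    kernel = svm$kernel %||% "linear",
                    cost = svm$cost %||% 1, scale = FALSE)
  pred <- stats::predict(fit, Z_test)
  acc <- if (is.null(y_test)) NA_real_ else mean(pred == y_test)
  list(predictions = pred, accuracy = acc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rescale one region's projection block (samples x dims) to unit average
# variance. Kernel magnitudes grow with the region's feature count, so
# without this the concatenated embedding would be dominated by the larger
# region; rescaling lets both regions contribute comparably.
scale_block <- function(Z) {
  s <- stats::sd(as.vector(sweep(Z, 2, colMeans(Z))))
  if (!is.finite(s) || s == 0) return(Z)
  Z / s
}

# Resolve the transformed design matrix Z (samples x dims) for one
# train/test split. Kernel methods on augmented features are transductive
# by default: the subspace is learned from every sample (labels unused), so
# the embedding does not depend on the split and callers may hoist it.
compute_embedding <- function(table, cfg, design, split = NULL) {
  method <- cfg$method
  if (method == "baseline") {
    return(list(Z = table$values, models = list(), h_used = ncol(table$values)))
  }
  region_tables <- if (startsWith(method, "brada_") || method == "brada") {
    stats::setNames(
      lapply(cfg$regions, function(r)
        select_feature_channels(table, region_channels(r))),
      cfg$regions)
  } else {
    list(all = table)
  }
  solver <- sub("^brada_?", "", method)
  if (solver == "") solver <- "mida"
  if (method == "brada") solver <- "mida"
  kernel <- method_kernel(cfg)
  models <- list()
  blocks <- list()
  h_used <- integer(0)
  n <- nrow(table$values)
  for (nm in names(region_tables)) {
    X <- t(region_tables[[nm]]$values) # m x n, samples in columns
    if (solver == "mida") {
      eff_h <- min(cfg$h, n)
      X_bar <- augment_features(X, design)
      if (isTRUE(cfg$transductive) || is.null(split)) {
        model <- fit_mida(X_bar, design, h = eff_h, mu = cfg$mu,
                          kernel = kernel)
        Z <- t(stats::predict(model))
      } else {
        tr <- split$train
        sub_design <- domain_onehot(table$sample_meta[tr, , drop = FALSE])
        model <- fit_mida(X_bar[, tr, drop = FALSE], sub_design,
                          h = min(eff_h, length(tr)), mu = cfg$mu,
                          kernel = kernel)
        Z <- t(stats::predict(model, X_bar))
      }
    } else if (solver == "tca") {
      if (is.null(split)) {
        stop("TCA needs a source/target split.", call. = FALSE)
      }
      eff_h <- min(cfg$h, n)
      model <- fit_tca(X, split$train, split$test, h = eff_h, mu = cfg$mu,
                       kernel = kernel)
      Z <- t(stats::predict(model))
    } else if (solver == "sa") {
      if (is.null(split)) {
        stop("SA needs a source/target split.", call. = FALSE)
      }
      Xr <- region_tables[[nm]]$values # samples x m
      eff_h <- min(cfg$h, ncol(Xr), length(split$train), length(split$test))
      model <- fit_sa(Xr[split$train, , drop = FALSE],
                      Xr[split$test, , drop = FALSE], h = eff_h)
      Z <- matrix(NA_real_, n, eff_h)
      Z[split$train, ] <- stats::predict(model, Xr[split$train, , drop = FALSE],
                                         domain = "source")
      Z[split$test, ] <- stats::predict(model, Xr[split$test, , drop = FALSE],
                                        domain = "target")
    } else {
      stop("Unknown method: ", method, call. = FALSE)
    }
    models[[nm]] <- model
    blocks[[nm]] <- scale_block(Z)
    h_used <- c(h_used, ncol(Z))
  }
  list(Z = do.call(cbind, blocks), models = models, h_used = sum(h_used))
}

prepare_table <- function(table, cfg) {
  if (cfg$normalize && !table$normalized) minmax_normalize(table) else table
}

new_eval_report <- function(per_fold, cfg, chosen_h, folds,
                            protocol, pooled_accuracy,
                            embedding_dim = NA_integer_) {
  structure(
    list(per_fold = per_fold,
         mean_accuracy = mean(per_fold$accuracy),
         pooled_accuracy = pooled_accuracy,
         chosen_h = chosen_h,
         embedding_dim = embedding_dim,
         protocol = protocol,
         folds = folds,
         config = cfg),
    class = "brada_eval"
  )
}

#' Leave-one-subject-out cross-validation
#'
#' Each (database, subject) pair is held out once: its samples form the test
#' set, every other subject's samples train the SVM. With the default
#' transductive setting the subspace is learned from all samples jointly
#' (no labels are used in subspace learning, so nothing leaks); set
#' `transductive = FALSE` in the config for strict out-of-sample projection
#' of the held-out subject.
#'
#' @param table A [feature_table] (raw or normalized).
#' @param cfg A [brada_config].
#' @return A `brada_eval` report: per-fold accuracies, their unweighted
#'   mean, the pooled per-sample accuracy, and the fold index sets.
#' @export
loso_cv <- function(table, cfg = brada_config()) {
  stopifnot(inherits(table, "feature_table"), inherits(cfg, "brada_config"))
  set.seed(cfg$seed)
  meta <- table$sample_meta
  key <- paste(meta$database_id, meta$subject_id, sep = "\r")
  subjects <- unique(key)
  if (length(subjects) < 3) {
    stop("Leave-one-subject-out needs at least 3 subjects.", call. = FALSE)
  }
  y <- binarize_labels(meta[[cfg$label_axis]], cfg$binarize_threshold)
  norm <- prepare_table(table, cfg)
  design <- domain_onehot(meta)
  transductive_methods <- c("baseline", "brada", "brada_mida", "mida")
  shared <- if (cfg$method %in% transductive_methods && cfg$transductive) {
    compute_embedding(norm, cfg, design, split = NULL)
  } else NULL
  folds <- list()
  rows <- vector("list", length(subjects))
  correct <- 0L
  for (i in seq_along(subjects)) {
    test_idx <- which(key == subjects[i])
    train_idx <- setdiff(seq_len(nrow(norm$values)), test_idx)
    emb <- shared %||%
      compute_embedding(norm, cfg, design,
                        split = list(train = train_idx, test = test_idx))
    res <- svm_classify(emb$Z[train_idx, , drop = FALSE], y[train_idx],
                        emb$Z[test_idx, , drop = FALSE], y[test_idx],
                        svm = cfg$svm)
    folds[[i]] <- list(train = train_idx, test = test_idx)
    correct <- correct + sum(res$predictions == y[test_idx])
    rows[[i]] <- tibble::tibble(
      fold = i,
      database_id = meta$database_id[test_idx[1]],
      subject_id = meta$subject_id[test_idx[1]],
      n_test = length(test_idx),
      accuracy = res$accuracy
    )
  }
  per_fold <- dplyr::bind_rows(rows)
  chosen_h <- if (cfg$method == "baseline") NA_integer_ else as.integer(cfg$h)
  new_eval_report(per_fold, cfg, chosen_h, folds, "loso",
                  correct / nrow(norm$values),
                  embedding_dim = as.integer(ncol(emb$Z)))
}

#' Cross-database evaluation
#'
#' Pools both databases, normalizes jointly, learns one subspace per region
#' from all samples (each (database, subject) pair is a domain), then trains
#' the SVM on the source database's rows and tests on the target database's
#' rows. Per-fold accuracies are reported per target subject.
#'
#' @param table_a,table_b [feature_table]s with identical feature schemas.
#' @param direction `"a_to_b"` (train on `table_a`) or `"b_to_a"`.
#' @param cfg A [brada_config].
#' @return A `brada_eval` report.
#' @export
cross_database_eval <- function(table_a, table_b,
                                direction = c("a_to_b", "b_to_a"),
                                cfg = brada_config()) {
  direction <- match.arg(direction)
  set.seed(cfg$seed)
  pooled <- bind_feature_tables(table_a, table_b)
  n_a <- nrow(table_a$values)
  idx_a <- seq_len(n_a)
  idx_b <- n_a + seq_len(nrow(table_b$values))
  src <- if (direction == "a_to_b") idx_a else idx_b
  tgt <- if (direction == "a_to_b") idx_b else idx_a
  meta <- pooled$sample_meta
  y <- binarize_labels(meta[[cfg$label_axis]], cfg$binarize_threshold)
  norm <- prepare_table(pooled, cfg)
  design <- domain_onehot(meta)
  emb <- compute_embedding(norm, cfg, design,
                           split = list(train = src, test = tgt))
  res <- svm_classify(emb$Z[src, , drop = FALSE], y[src],
                      emb$Z[tgt, , drop = FALSE], y[tgt], svm = cfg$svm)
  tgt_key <- paste(meta$database_id[tgt], meta$subject_id[tgt], sep = "\r")
  rows <- lapply(seq_along(unique(tgt_key)), function(i) {
    sel <- tgt_key == unique(tgt_key)[i]
    tibble::tibble(
      fold = i,
      database_id = meta$database_id[tgt][sel][1],
      subject_id = meta$subject_id[tgt][sel][1],
      n_test = sum(sel),
      accuracy = mean(res$predictions[sel] == y[tgt][sel])
    )
  })
  chosen_h <- if (cfg$method == "baseline") NA_integer_ else as.integer(cfg$h)
  new_eval_report(dplyr::bind_rows(rows), cfg, chosen_h,
                  list(list(train = src, test = tgt)),
                  paste0("cross_database_", direction), res$accuracy,
                  embedding_dim = as.integer(ncol(emb$Z)))
}

#' Search the subspace dimension
#'
#' Evaluates the configured protocol at every `h` in the grid and returns
#' the full accuracy curve plus the best dimension (ties broken toward the
#' smallest `h`). This sweeps the evaluation protocol itself — an
#' oracle-style selection mirroring how such curves are usually reported;
#' treat the curve, not the argmax, as the honest output.
#'
#' @param table A [feature_table].
#' @param cfg A [brada_config]; `cfg$h_grid` supplies the grid.
#' @param grid Optional override of the grid.
#' @return A `brada_h_search`: list with `curve` (tibble of `h`,
#'   `mean_accuracy`) and `best_h`.
#' @export
search_h <- function(table, cfg = brada_config(), grid = NULL) {
  grid <- grid %||% cfg$h_grid
  stopifnot(length(grid) >= 1)
  curve <- purrr::map_dfr(grid, function(h) {
    cfg_h <- cfg
    cfg_h$h <- h
    rep <- loso_cv(table, cfg_h)
    tibble::tibble(h = h, mean_accuracy = rep$mean_accuracy)
  })
  best_h <- curve$h[which.max(curve$mean_accuracy)]
  structure(list(curve = curve, best_h = best_h, config = cfg),
            class = "brada_h_search")
}

#' Detect a rise-then-plateau shape in an accuracy curve
#'
#' A curve plateaus when, once it first comes within `tol` of its maximum,
#' it never falls more than `tol` below that maximum again, and it is
#' non-decreasing (within `tol`) before that point. This is the qualitative
#' signature of a subspace dimension exceeding the data's intrinsic
#' dimension.
#'
#' @param accuracy Numeric vector of accuracies, ordered by increasing `h`.
#' @param tol Tolerance on the accuracy scale (default 0.05).
#' @return A list with `plateau` (logical) and `onset` (index where the
#'   plateau starts).
#' @export
detect_plateau <- function(accuracy, tol = 0.05) {
  stopifnot(length(accuracy) >= 2)
  top <- max(accuracy)
  onset <- which(accuracy >= top - tol)[1]
  flat_after <- all(accuracy[onset:length(accuracy)] >= top - tol)
  rising_before <- onset == 1 ||
    all(diff(accuracy[1:onset]) >= -tol)
  list(plateau = flat_after && rising_before, onset = onset)
}

#' @export
print.brada_h_search <- function(x, ...) {
  cat("<brada_h_search> best h =", x$best_h, "\n")
  print(x$curve)
  invisible(x)
}

#' Paired significance test between two evaluation reports
#'
#' Two-sided paired t-test over per-fold accuracies (folds matched by
#' held-out domain). Identical reports (all differences zero) return
#' statistic 0 and p = 1.
#'
#' @param report_a,report_b `brada_eval` reports with matching folds.
#' @return A tibble with `statistic`, `p_value`, `mean_difference`,
#'   `n_folds`.
#' @export
significance_test <- function(report_a, report_b) {
  a <- report_a$per_fold$accuracy
  b <- report_b$per_fold$accuracy
  if (length(a) != length(b)) {
    stop("Reports have different fold counts (", length(a), " vs ",
         length(b), ").", call. = FALSE)
  }
  d <- a - b
  if (all(abs(d - mean(d)) < 1e-15)) {
    stat <- if (abs(mean(d)) < 1e-15) 0 else sign(mean(d)) * Inf
    p <- if (abs(mean(d)) < 1e-15) 1 else 0
  } else {
    tt <- stats::t.test(a, b, paired = TRUE)
    stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  tibble::tibble(statistic = stat, p_value = p,
                 mean_difference = mean(d), n_folds = length(d))
}

#' Ablation suite
#'
#' Re-runs the configured protocol while varying one design axis at a time:
#' brain-region selection (auditory only, visual only, both), feature
#' normalization (on/off), and kernel family (gaussian, linear,
#' polynomial). Returns a tidy table with one row per variant.
#'
#' @param table A [feature_table].
#' @param cfg The base [brada_config] (method should be a `brada` variant).
#' @return A tibble with columns `family`, `variant`, `label_axis`,
#'   `mean_accuracy`, `n_folds` and a `report` list-column.
#' @export
ablation_suite <- function(table, cfg = brada_config()) {
  run <- function(cfg2) loso_cv(table, cfg2)
  variants <- list()
  for (reg in list(c("auditory"), c("visual"), c("auditory", "visual"))) {
    cfg2 <- cfg
    cfg2$regions <- reg
    variants[[length(variants) + 1]] <- list(
      family = "region",
      variant = paste(reg, collapse = "+"),
      report = run(cfg2))
  }
  for (nz in c(TRUE, FALSE)) {
    cfg2 <- cfg
    cfg2$normalize <- nz
    variants[[length(variants) + 1]] <- list(
      family = "normalization",
      variant = if (nz) "with" else "without",
      report = run(cfg2))
  }
  for (kk in c("gaussian", "linear", "polynomial")) {
    cfg2 <- cfg
    cfg2$kernel <- kernel_spec(kk)
    variants[[length(variants) + 1]] <- list(
      family = "kernel",
      variant = kk,
      report = run(cfg2))
  }
  purrr::map_dfr(variants, function(v) {
    tibble::tibble(
      family = v$family,
      variant = v$variant,
      label_axis = cfg$label_axis,
      mean_accuracy = v$report$mean_accuracy,
      n_folds = nrow(v$report$per_fold),
      report = list(v$report)
    )
  })
}

#' Region-wise adaptation and concatenation
#'
#' The method's core transform as a standalone operation: fits the
#' configured solver independently on the auditory-region and visual-region
#' tables (identical `h`, `mu` and kernel), projects every sample, and
#' concatenates the two projections into a `2h`-dimensional embedding.
#'
#' @param table_a Auditory-region [feature_table] (normalized).
#' @param table_v Visual-region [feature_table] (same sample order).
#' @param design The shared [domain_onehot()] design.
#' @param cfg A [brada_config].
#' @return A `brada_embedding`: list with `Z` (samples x 2h matrix, columns
#'   `A1..Ah, V1..Vh`), `sample_meta`, and the per-region models.
#' @export
brada_transform <- function(table_a, table_v, design, cfg = brada_config()) {
  stopifnot(inherits(table_a, "feature_table"),
            inherits(table_v, "feature_table"))
  if (!identical(dim(table_a$values)[1], dim(table_v$values)[1]) ||
      !identical(table_a$sample_meta$subject_id,
                 table_v$sample_meta$subject_id) ||
      !identical(table_a$sample_meta$database_id,
                 table_v$sample_meta$database_id)) {
    stop("Region tables disagree on sample order or metadata.",
         call. = FALSE)
  }
  kernel <- method_kernel(cfg)
  n <- nrow(table_a$values)
  eff_h <- min(cfg$h, n)
  fit_block <- function(tbl) {
    X_bar <- augment_features(t(tbl$values), design)
    model <- fit_mida(X_bar, design, h = eff_h, mu = cfg$mu, kernel = kernel)
    list(model = model, Z = t(stats::predict(model)))
  }
  ba <- fit_block(table_a)
  bv <- fit_block(table_v)
  Z <- cbind(scale_block(ba$Z), scale_block(bv$Z))
  colnames(Z) <- c(paste0("A", seq_len(eff_h)), paste0("V", seq_len(eff_h)))
  structure(list(Z = Z, sample_meta = table_a$sample_meta,
                 models = list(auditory = ba$model, visual = bv$model),
                 h = eff_h),
            class = "brada_embedding")
}

#' @export
print.brada_embedding <- function(x, ...) {
  cat(sprintf("<brada_embedding> %d samples x %d dims (h = %d per region)\n",
              nrow(x$Z), ncol(x$Z), x$h))
  invisible(x)
}

#' @export
print.brada_eval <- function(x, ...) {
  cat(sprintf("<brada_eval> %s | method = %s | axis = %s\n",
              x$protocol, x$config$method, x$config$label_axis))
  cat(sprintf("  mean accuracy %.3f over %d folds (pooled %.3f)\n",
              x$mean_accuracy, nrow(x$per_fold), x$pooled_accuracy))
  invisible(x)
}

#' Per-fold accuracies of an evaluation report
#'
#' @param x A `brada_eval` report.
#' @param ... Unused.
#' @return The per-fold tibble.
#' @method tidy brada_eval
#' @export
tidy.brada_eval <- function(x, ...) x$per_fold

#' One-row summary of an evaluation report
#'
#' @param x A `brada_eval` report.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance brada_eval
#' @export
glance.brada_eval <- function(x, ...) {
  tibble::tibble(
    protocol = x$protocol,
    method = x$config$method,
    label_axis = x$config$label_axis,
    mean_accuracy = x$mean_accuracy,
    pooled_accuracy = x$pooled_accuracy,
    n_folds = nrow(x$per_fold),
    h = x$chosen_h
  )
}
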