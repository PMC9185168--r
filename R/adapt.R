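#' One-hot domain design from sample metadata
#'
#' Each distinct (database, subject) pair is one domain; the design matrix
#' `D` is `m_d x n` with a single 1 per column marking the sample's domain.
#' The same subject label appearing in two databases yields two distinct
#' domain rows, so cross-database runs are multi-source multi-target.
#'
#' @param sample_meta Data frame with `database_id` and `subject_id`
#'   columns, one row per sample.
#' @return A `domain_design`: list with `D` (m_d x n one-hot matrix) and
#'   `encoding` (tibble mapping database/subject to row index).
#' @export
domain_onehot <- function(sample_meta) {
  sample_meta <- tibble::as_tibble(sample_meta)
  stopifnot(nrow(sample_meta) >= 1)
  key <- paste(sample_meta$database_id, sample_meta$subject_id, sep = "\r")
  levels <- unique(key)
  idx <- match(key, levels)
  m_d <- length(levels)
  n <- length(idx)
  D <- matrix(0, nrow = m_d, ncol = n)
  D[cbind(idx, seq_len(n))] <- 1
  first <- match(levels, key)
  encoding <- tibble::tibble(
    database_id = sample_meta$database_id[first],
    subject_id = sample_meta$subject_id[first],
    row = seq_len(m_d)
  )
  structure(list(D = D, encoding = encoding, m_d = m_d),
            class = "domain_design")
}

#' @export
print.domain_design <- function(x, ...) {
  cat(sprintf("<domain_design> %d domains x %d samples\n",
              x$m_d, ncol(x$D)))
  invisible(x)
}

#' Augment region features with domain features
#'
#' Stacks the one-hot domain rows under the (normalized) feature rows:
#' `rbind(X_region, D)`. No scaling is applied to the domain rows. The
#' augmented columns let the learned projection express per-domain offsets,
#' which is how subject- and database-specific shifts get cancelled.
#'
#' @param X_region Numeric matrix, features x samples.
#' @param design A [domain_onehot()] design (or `NULL` for no augmentation).
#' @return Matrix of shape `(m_region + m_d) x n`.
#' @export
augment_features <- function(X_region, design = NULL) {
  X_region <- as.matrix(X_region)
  if (is.null(design) || (inherits(design, "domain_design") && design$m_d == 0)) {
    return(X_region)
  }
  stopifnot(inherits(design, "domain_design"))
  if (ncol(X_region) != ncol(design$D)) {
    stop("Feature matrix has ", ncol(X_region), " samples but the domain ",
         "design has ", ncol(design$D), ".", call. = FALSE)
  }
  rbind(X_region, design$D)
}

#' Kernel specification
#'
#' @param kind `"linear"`, `"polynomial"` or `"gaussian"`.
#' @param degree Polynomial degree (default 2, the lowest strictly
#'   nonlinear choice).
#' @param coef0 Polynomial offset (default 1).
#' @param gamma_scale Gaussian width multiplier; `NULL` means
#'   `1 / (p * var(X))` resolved from the data at fit time.
#' @return A `kernel_spec` object.
#' @export
kernel_spec <- function(kind = c("polynomial", "linear", "gaussian"),
                        degree = 2, coef0 = 1, gamma_scale = NULL) {
  kind <- match.arg(kind)
  if (degree < 1) stop("Polynomial degree must be >= 1.", call. = FALSE)
  if (!is.null(gamma_scale) && gamma_scale <= 0) {
    stop("gamma_scale must be positive.", call. = FALSE)
  }
  structure(list(kind = kind, degree = degree, coef0 = coef0,
                 gamma_scale = gamma_scale),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  extra <- switch(x$kind,
    polynomial = sprintf(" (degree %g, coef0 %g)", x$degree, x$coef0),
    gaussian = sprintf(" (gamma_scale %s)",
                       if (is.null(x$gamma_scale)) "auto" else x$gamma_scale),
    "")
  cat("<kernel_spec> ", x$kind, extra, "\n", sep = "")
  invisible(x)
}

# Resolve the gaussian width against concrete data (columns = samples).
resolve_kernel <- function(spec, X) {
  if (spec$kind == "gaussian" && is.null(spec$gamma_scale)) {
    spec$gamma_scale <- 1 / (nrow(X) * stats::var(as.vector(X)))
  }
  spec
}

#' Gram matrix of sample columns under a kernel
#'
#' Columns of `X` (and `Y`) are samples. Linear: `x'y`; polynomial:
#' `(x'y + coef0)^degree`; gaussian: `exp(-gamma_scale * ||x - y||^2)`.
#'
#' @param X Numeric matrix, variables x samples.
#' @param spec A [kernel_spec].
#' @param Y Optional second matrix (same row count) for cross-kernels;
#'   defaults to `X`.
#' @return `ncol(X) x ncol(Y)` kernel matrix.
#' @export
kernel_matrix <- function(X, spec = kernel_spec(), Y = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("Non-finite entries in kernel input.",
                               call. = FALSE)
  same <- is.null(Y)
  Y <- if (same) X else as.matrix(Y)
  if (!all(is.finite(Y))) stop("Non-finite entries in kernel input.",
                               call. = FALSE)
  if (nrow(X) != nrow(Y)) {
    stop("Kernel inputs have different variable counts (", nrow(X), " vs ",
         nrow(Y), ").", call. = FALSE)
  }
  spec <- resolve_kernel(spec, X)
  G <- crossprod(X, Y)
  K <- switch(spec$kind,
    linear = G,
    polynomial = (G + spec$coef0)^spec$degree,
    gaussian = {
      sx <- colSums(X^2)
      sy <- colSums(Y^2)
      d2 <- outer(sx, sy, "+") - 2 * G
      d2[d2 < 0] <- 0
      exp(-spec$gamma_scale * d2)
    })
  if (same) K <- (K + t(K)) / 2
  K
}

#' Centering matrix
#'
#' `H = I - (1/n) 11'`; idempotent and annihilates constant vectors.
#'
#' @param n Number of samples.
#' @return `n x n` centering matrix.
#' @export
centering_matrix <- function(n) {
  stopifnot(n >= 1)
  diag(n) - matrix(1 / n, n, n)
}

#' Empirical Hilbert-Schmidt independence criterion
#'
#' The biased estimator `(n - 1)^-2 * tr(K_Z H K_D H)` of the dependence
#' between two kernelized views of the same samples. Non-negative when both
#' kernels are positive semi-definite; zero when either kernel is constant.
#'
#' @param K_Z,K_D `n x n` symmetric kernel matrices over the same samples.
#' @return The HSIC estimate (scalar).
#' @export
hsic <- function(K_Z, K_D) {
  K_Z <- as.matrix(K_Z); K_D <- as.matrix(K_D)
  n <- nrow(K_Z)
  if (n != ncol(K_Z) || !all(dim(K_D) == n)) {
    stop("Kernel matrices must both be n x n over the same samples.",
         call. = FALSE)
  }
  if (n < 2) stop("HSIC estimator undefined for a single sample.",
                  call. = FALSE)
  H <- centering_matrix(n)
  sum(diag(K_Z %*% H %*% K_D %*% H)) / (n - 1)^2
}

# Fix eigenvector signs so the largest-magnitude entry is positive;
# reproducible across platforms.
fix_signs <- function(W) {
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  W
}

new_adaptation_model <- function(method, W, eigenvalues, kernel, h, mu,
                                 X_bar_train, extra = list()) {
  structure(
    c(list(method = method, W = W, eigenvalues = eigenvalues,
           kernel = kernel, h = h, mu = mu, X_bar_train = X_bar_train),
      extra),
    class = "brada_adaptation"
  )
}

#' Maximum-independence subspace learning (MIDA)
#'
#' Learns a kernel subspace that maximizes the variance of the projected
#' samples while minimizing their HSIC dependence on the domain design. With
#' `K` the kernel matrix of the augmented features, `K_D = D'D` and `H` the
#' centering matrix, the projection coefficients `W` are the top-`h`
#' eigenvectors of `M = K (-H K_D H + mu H) K` (symmetrized); the achieved
#' objective `tr(W' M W)` equals the sum of the retained eigenvalues.
#'
#' @param X_bar Augmented feature matrix, `(m + m_d) x n` (see
#'   [augment_features()]).
#' @param design The [domain_onehot()] design used for augmentation; may be
#'   `NULL` for a single implicit domain.
#' @param h Subspace dimension, `h <= n`.
#' @param mu Trade-off between variance and domain independence (default 1).
#' @param kernel A [kernel_spec]; the method's default is polynomial
#'   degree 2.
#' @param ridge Optional diagonal ridge multiplier added to the kernel
#'   (scaled by `mean(diag(K))`); 0 disables it.
#' @return A `brada_adaptation` model holding `W` (n x h, orthonormal),
#'   the eigenvalue spectrum, the kernel spec and the stored training
#'   matrix for out-of-sample projection.
#' @export
fit_mida <- function(X_bar, design = NULL, h, mu = 1,
                     kernel = kernel_spec("polynomial"), ridge = 0) {
  X_bar <- as.matrix(X_bar)
  n <- ncol(X_bar)
  if (h > n) stop("Subspace dimension h = ", h, " exceeds the ", n,
                  " available samples.", call. = FALSE)
  if (mu <= 0) stop("mu must be positive.", call. = FALSE)
  kernel <- resolve_kernel(kernel, X_bar)
  K <- kernel_matrix(X_bar, kernel)
  if (ridge > 0) K <- K + diag(ridge * mean(diag(K)), n)
  if (is.null(design)) {
    K_D <- matrix(1, n, n) # single domain: centered away entirely
  } else {
    K_D <- crossprod(design$D)
  }
  H <- centering_matrix(n)
  M <- K %*% (-H %*% K_D %*% H + mu * H) %*% K
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  W <- fix_signs(eig$vectors[, seq_len(h), drop = FALSE])
  new_adaptation_model("mida", W, eig$values, kernel, h, mu, X_bar,
                       extra = list(objective = sum(eig$values[seq_len(h)])))
}

#' Transfer component analysis (TCA) baseline
#'
#' Classical TCA: minimizes the maximum mean discrepancy between a source
#' and a target sample group in a kernel subspace. Solves the generalized
#' eigenproblem of `(K L K + mu I)^-1 K H K` where `L` is the MMD matrix,
#' and keeps the top-`h` eigenvectors.
#'
#' @param X_bar Feature matrix, variables x samples.
#' @param source_idx,target_idx Disjoint, non-empty sample index vectors.
#' @inheritParams fit_mida
#' @return A `brada_adaptation` model (`method = "tca"`).
#' @export
fit_tca <- function(X_bar, source_idx, target_idx, h, mu = 1,
                    kernel = kernel_spec("linear")) {
  X_bar <- as.matrix(X_bar)
  n <- ncol(X_bar)
  if (!length(source_idx) || !length(target_idx)) {
    stop("Source and target groups must both be non-empty.", call. = FALSE)
  }
  if (h > n) stop("h exceeds sample count.", call. = FALSE)
  kernel <- resolve_kernel(kernel, X_bar)
  K <- kernel_matrix(X_bar, kernel)
  L <- mmd_matrix(n, source_idx, target_idx)
  H <- centering_matrix(n)
  A <- K %*% L %*% K + mu * diag(n)
  B <- K %*% H %*% K
  eig <- eigen(solve(A, B))
  ord <- order(Re(eig$values), decreasing = TRUE)
  W <- Re(eig$vectors[, ord[seq_len(h)], drop = FALSE])
  W <- apply(W, 2, function(w) w / sqrt(sum(w^2)))
  W <- fix_signs(as.matrix(W))
  new_adaptation_model("tca", W, Re(eig$values[ord]), kernel, h, mu, X_bar,
                       extra = list(source_idx = source_idx,
                                    target_idx = target_idx))
}

#' MMD coefficient matrix for two sample groups
#'
#' `L[i, j]` is `1/ns^2` within source, `1/nt^2` within target and
#' `-1/(ns * nt)` across; rows sum to zero.
#'
#' @param n Total sample count.
#' @param source_idx,target_idx Index vectors partitioning (a subset of)
#'   `1:n`.
#' @return `n x n` matrix.
#' @export
mmd_matrix <- function(n, source_idx, target_idx) {
  e <- numeric(n)
  e[source_idx] <- 1 / length(source_idx)
  e[target_idx] <- -1 / length(target_idx)
  outer(e, e)
}

#' Subspace alignment (SA) baseline
#'
#' PCA bases `V_s`, `V_t` (top `h` components) are computed per domain;
#' source features map through `V_s (V_s' V_t)` and target features through
#' `V_t`, aligning the source subspace onto the target one.
#'
#' @param X_source,X_target Numeric matrices, samples x features (same
#'   feature count).
#' @param h Subspace dimension, at most `min(m, n_s, n_t)`.
#' @return A `brada_sa` alignment map with `$project(X, domain)`.
#' @export
fit_sa <- function(X_source, X_target, h) {
  X_source <- as.matrix(X_source); X_target <- as.matrix(X_target)
  if (ncol(X_source) != ncol(X_target)) {
    stop("Source and target feature counts differ.", call. = FALSE)
  }
  limit <- min(ncol(X_source), nrow(X_source), nrow(X_target))
  if (h > limit) {
    stop("h = ", h, " exceeds the admissible subspace dimension ", limit,
         ".", call. = FALSE)
  }
  pca_basis <- function(X) {
    mu <- colMeans(X)
    sv <- svd(sweep(X, 2, mu), nu = 0, nv = h)
    fix_signs(sv$v)
  }
  V_s <- pca_basis(X_source)
  V_t <- pca_basis(X_target)
  M <- crossprod(V_s, V_t)
  mu_s <- colMeans(X_source); mu_t <- colMeans(X_target)
  structure(list(V_s = V_s, V_t = V_t, M = M, mu_s = mu_s, mu_t = mu_t,
                 h = h),
            class = "brada_sa")
}

#' Project samples through a subspace-alignment map
#'
#' @param object A [fit_sa()] map.
#' @param X Samples x features matrix.
#' @param domain `"source"` (maps through the aligned source basis) or
#'   `"target"`.
#' @param ... Unused.
#' @return Samples x h matrix of aligned coordinates.
#' @export
predict.brada_sa <- function(object, X, domain = c("source", "target"), ...) {
  domain <- match.arg(domain)
  X <- as.matrix(X)
  if (domain == "source") {
    sweep(X, 2, object$mu_s) %*% (object$V_s %*% object$M)
  } else {
    sweep(X, 2, object$mu_t) %*% object$V_t
  }
}

#' Project (new) samples through a fitted kernel adaptation model
#'
#' Computes `Z = W' K_cross` where `K_cross[i, j]` is the kernel between
#' stored training sample `i` and new sample `j`. Transforming the training
#' matrix itself reproduces the training-time projection exactly.
#'
#' @param object A `brada_adaptation` model from [fit_mida()] or
#'   [fit_tca()].
#' @param X_bar_new Augmented matrix of new samples, same row count as the
#'   stored training matrix.
#' @param ... Unused.
#' @return `h x n_new` matrix of projected coordinates.
#' @export
predict.brada_adaptation <- function(object, X_bar_new = NULL, ...) {
  if (is.null(X_bar_new)) X_bar_new <- object$X_bar_train
  X_bar_new <- as.matrix(X_bar_new)
  if (nrow(X_bar_new) != nrow(object$X_bar_train)) {
    stop("New samples have ", nrow(X_bar_new), " rows but the model was ",
         "fit with ", nrow(object$X_bar_train), ".", call. = FALSE)
  }
  K_cross <- kernel_matrix(object$X_bar_train, object$kernel, X_bar_new)
  t(object$W) %*% K_cross
}

#' @export
print.brada_adaptation <- function(x, ...) {
  cat(sprintf("<brada_adaptation> %s: h = %d, mu = %g, kernel = %s, n = %d\n",
              x$method, x$h, x$mu, x$kernel$kind, ncol(x$X_bar_train)))
  invisible(x)
}

#' Tidy the eigen-spectrum of an adaptation model
#'
#' @param x A `brada_adaptation` model.
#' @param ... Unused.
#' @return A tibble with `component`, `eigenvalue`, `retained`.
#' @method tidy brada_adaptation
#' @export
tidy.brada_adaptation <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    retained = seq_along(x$eigenvalues) <= x$h
  )
}

#' One-row summary of an adaptation model
#'
#' @param x A `brada_adaptation` model.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance brada_adaptation
#' @export
glance.brada_adaptation <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    h = x$h,
    mu = x$mu,
    kernel = x$kernel$kind,
    n_train = ncol(x$X_bar_train),
    objective = sum(x$eigenvalues[seq_len(x$h)])
  )
}

#' Serialize an adaptation model to a portable list
#'
#' Everything needed to re-instantiate the model (projection, spectrum,
#' kernel spec, stored training matrix) as plain numeric vectors, suitable
#' for JSON round-trips.
#'
#' @param model A `brada_adaptation` model.
#' @return A plain list.
#' @export
adaptation_to_list <- function(model) {
  list(
    method = model$method,
    h = model$h,
    mu = model$mu,
    kernel = unclass(model$kernel),
    W = list(dim = dim(model$W), data = as.vector(model$W)),
    eigenvalues = model$eigenvalues,
    X_bar_train = list(dim = dim(model$X_bar_train),
                       data = as.vector(model$X_bar_train))
  )
}

#' @rdname adaptation_to_list
#' @param x A list from [adaptation_to_list()].
#' @export
adaptation_from_list <- function(x) {
  gs <- x$kernel$gamma_scale
  if (!length(gs)) gs <- NULL # JSON null round-trips as an empty list
  kernel <- kernel_spec(kind = x$kernel$kind, degree = x$kernel$degree,
                        coef0 = x$kernel$coef0, gamma_scale = gs)
  new_adaptation_model(
    x$method,
    matrix(x$W$data, x$W$dim[1], x$W$dim[2]),
    as.numeric(x$eigenvalues),
    kernel, x$h, x$mu,
    matrix(x$X_bar_train$data, x$X_bar_train$dim[1], x$X_bar_train$dim[2])
  )
}
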