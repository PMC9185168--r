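test_that("domain one-hot encoding marks each sample's (database, subject)", {
  meta <- tibble::tibble(subject_id = c("s1", "s1", "s2"),
                         database_id = "db")
  d <- domain_onehot(meta)
  expect_equal(d$D, rbind(c(1, 1, 0), c(0, 0, 1)))
  expect_equal(colSums(d$D), rep(1, 3))
  # same subject label in two databases -> two distinct domains
  meta2 <- tibble::tibble(subject_id = c("s1", "s1"),
                          database_id = c("dbA", "dbB"))
  d2 <- domain_onehot(meta2)
  expect_equal(d2$m_d, 2)
  expect_equal(nrow(d2$encoding), 2)
})

test_that("augmentation stacks domain rows under the feature rows", {
  set.seed(3)
  meta <- tibble::tibble(subject_id = rep(c("a", "b", "c"), each = 4),
                         database_id = "db")
  design <- domain_onehot(meta)
  X120 <- matrix(rnorm(120 * 12), 120, 12)
  X50 <- matrix(rnorm(50 * 12), 50, 12)
  expect_equal(dim(augment_features(X120, design)), c(120 + 3, 12))
  expect_equal(dim(augment_features(X50, design)), c(50 + 3, 12))
  expect_equal(augment_features(X50, design)[1:50, ], X50)
  expect_identical(augment_features(X50, NULL), X50)
  bad <- domain_onehot(meta[1:8, ])
  expect_error(augment_features(X50, bad), "samples")
})

test_that("kernel matrices follow their closed forms", {
  expect_equal(kernel_matrix(diag(2), kernel_spec("linear")), diag(2))
  ab <- cbind(c(1, 0), c(0, 1))
  expect_equal(kernel_matrix(ab, kernel_spec("polynomial", degree = 2,
                                             coef0 = 1)),
               rbind(c(4, 1), c(1, 4)))
  set.seed(4)
  X <- matrix(rnorm(30), 5, 6)
  Kg <- kernel_matrix(X, kernel_spec("gaussian", gamma_scale = 0.7))
  expect_equal(diag(Kg), rep(1, 6))
  expect_true(isSymmetric(Kg))
  expect_error(kernel_matrix(matrix(c(1, NA), 1, 2)), "Non-finite")
})

test_that("the centering matrix is an idempotent mean-remover", {
  expect_equal(centering_matrix(2), rbind(c(0.5, -0.5), c(-0.5, 0.5)))
  H <- centering_matrix(7)
  expect_equal(H %*% H, H, tolerance = 1e-12)
  expect_equal(as.numeric(H %*% rep(1, 7)), rep(0, 7), tolerance = 1e-12)
})

test_that("the HSIC estimator agrees with a dense brute-force oracle", {
  # scalar expansion of tr(K H L H):
  # sum(K*L) - (2/n) 1'KL1 + (1/n^2)(1'K1)(1'L1)
  hsic_oracle <- function(K, L) {
    n <- nrow(K)
    term1 <- sum(K * L)
    term2 <- sum(colSums(K) * colSums(L)) * 2 / n
    term3 <- sum(K) * sum(L) / n^2
    (term1 - term2 + term3) / (n - 1)^2
  }
  set.seed(5)
  for (rep in 1:50) {
    K <- random_psd(10)
    L <- random_psd(10)
    expect_equal(hsic(K, L), hsic_oracle(K, L), tolerance = 1e-10)
    expect_gte(hsic(K, L), -1e-12)
  }
  # constant kernel is annihilated by centering
  expect_equal(hsic(matrix(3, 8, 8), random_psd(8)), 0, tolerance = 1e-12)
  # identity kernels at n = 3: (1/4) tr(H) = 0.5
  expect_equal(hsic(diag(3), diag(3)), 0.5)
  expect_error(hsic(matrix(1, 1, 1), matrix(1, 1, 1)), "single sample")
  # clustered structure in both views -> strictly positive dependence
  z <- c(rep(0, 3), rep(5, 3))
  Kc <- kernel_matrix(rbind(z), kernel_spec("gaussian", gamma_scale = 1))
  expect_gt(hsic(Kc, Kc), 0.01)
})

test_that("the subspace solver attains the Rayleigh-trace optimum", {
  fx <- make_mean_shift(n_per = 10, m = 6)
  h <- 3
  model <- fit_mida(fx$X_bar, fx$design, h = h,
                    kernel = kernel_spec("polynomial"))
  n <- ncol(fx$X_bar)
  expect_equal(crossprod(model$W), diag(h), tolerance = 1e-8)
  expect_true(all(diff(model$eigenvalues) <= 1e-8))
  # rebuild M densely and compare the objective with the spectrum
  K <- kernel_matrix(fx$X_bar, model$kernel)
  K_D <- crossprod(fx$design$D)
  H <- centering_matrix(n)
  M <- K %*% (-H %*% K_D %*% H + 1 * H) %*% K
  M <- (M + t(M)) / 2
  obj <- function(W) sum(diag(t(W) %*% M %*% W))
  expect_equal(obj(model$W), sum(model$eigenvalues[1:h]), tolerance = 1e-6)
  set.seed(6)
  for (r in 1:200) {
    W0 <- random_orthonormal(n, h)
    expect_lte(obj(W0), obj(model$W) + 1e-6)
  }
  # retaining every component recovers the full trace
  full <- fit_mida(fx$X_bar, fx$design, h = n)
  expect_equal(sum(full$eigenvalues), sum(diag(M)), tolerance = 1e-6)
})

test_that("projection reduces dependence on the domain design", {
  fx <- make_mean_shift(n_per = 12, m = 8, delta = 4, seed = 9)
  model <- fit_mida(fx$X_bar, fx$design, h = 4)
  Z <- predict(model)
  K_D <- crossprod(fx$design$D)
  before <- hsic(kernel_matrix(fx$X_bar, model$kernel), K_D)
  after <- hsic(kernel_matrix(Z, kernel_spec("linear")), K_D)
  expect_lt(after, before)
})

test_that("a single-domain design degenerates to pure variance maximization", {
  set.seed(10)
  X <- matrix(rnorm(5 * 8), 5, 8)
  meta <- tibble::tibble(subject_id = "s1", database_id = "db",
                         .rows = 8)
  design <- domain_onehot(meta)
  X_bar <- augment_features(X, design)
  model <- fit_mida(X_bar, design, h = 8, mu = 1,
                    kernel = kernel_spec("linear"))
  K <- kernel_matrix(X_bar, model$kernel)
  H <- centering_matrix(8)
  # -H K_D H vanishes, leaving mu K H K: spectrum sums to tr(K H K)
  expect_equal(sum(model$eigenvalues), sum(diag(K %*% H %*% K)),
               tolerance = 1e-8)
  # and the centered projection's total energy matches the dense oracle
  Z <- predict(model)
  expect_equal(sum((Z %*% H)^2), sum(diag(K %*% H %*% H %*% K)),
               tolerance = 1e-6)
})

test_that("out-of-sample projection is consistent with training", {
  fx <- make_mean_shift()
  model <- fit_mida(fx$X_bar, fx$design, h = 3)
  Z_train <- predict(model)
  expect_equal(dim(Z_train), c(3, ncol(fx$X_bar)))
  expect_equal(predict(model, fx$X_bar), Z_train)
  # permuting input columns permutes output columns
  perm <- sample(ncol(fx$X_bar))
  expect_equal(predict(model, fx$X_bar[, perm]), Z_train[, perm])
  # single-column call equals the batched column
  expect_equal(predict(model, fx$X_bar[, 5, drop = FALSE]),
               Z_train[, 5, drop = FALSE], tolerance = 1e-12)
  expect_error(predict(model, fx$X_bar[-1, ]), "rows")
})

test_that("TCA reduces the empirical mean discrepancy on a mean shift", {
  fx <- make_mean_shift(n_per = 12, m = 6, delta = 3, seed = 15)
  src <- 1:12; tgt <- 13:24
  L <- mmd_matrix(24, src, tgt)
  expect_equal(as.numeric(L %*% rep(1, 24)), rep(0, 24), tolerance = 1e-12)
  model <- fit_tca(fx$X, src, tgt, h = 3, kernel = kernel_spec("linear"))
  Z <- predict(model)
  mmd <- function(M) sum((rowMeans(M[, src, drop = FALSE]) -
                            rowMeans(M[, tgt, drop = FALSE]))^2)
  # compare on a common scale: unit-normalized coordinates
  scale_rows <- function(M) M / sqrt(mean(M^2))
  expect_lt(mmd(scale_rows(Z)), mmd(scale_rows(fx$X)))
})

test_that("one-component TCA matches a dense generalized eigensolve", {
  fx <- make_mean_shift(n_per = 6, m = 4, seed = 21)
  src <- 1:6; tgt <- 7:12
  kern <- kernel_spec("linear")
  model <- fit_tca(fx$X, src, tgt, h = 1, mu = 1, kernel = kern)
  K <- kernel_matrix(fx$X, kern)
  L <- mmd_matrix(12, src, tgt)
  H <- centering_matrix(12)
  A <- K %*% L %*% K + diag(12)
  B <- K %*% H %*% K
  dense <- eigen(solve(A, B))
  lam1 <- max(Re(dense$values))
  w <- model$W[, 1]
  rayleigh <- as.numeric((t(w) %*% B %*% w) / (t(w) %*% A %*% w))
  expect_equal(rayleigh, lam1, tolerance = 1e-8)
})

test_that("subspace alignment maps a domain onto itself exactly", {
  set.seed(30)
  X <- matrix(rnorm(40 * 6), 40, 6)
  map <- fit_sa(X, X, h = 3)
  aligned <- predict(map, X, "source")
  target <- predict(map, X, "target")
  expect_equal(abs(aligned), abs(target), tolerance = 1e-8)
  # alignment matrix is a product of orthonormal bases
  expect_lte(max(svd(map$M)$d), 1 + 1e-10)
  expect_error(fit_sa(X, X, h = 50), "admissible")
})

test_that("feature-space rotations leave aligned distances unchanged", {
  set.seed(31)
  Xs <- matrix(rnorm(30 * 5), 30, 5)
  Xt <- matrix(rnorm(25 * 5), 25, 5)
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  # rotating the target features does not move the target's own aligned
  # coordinates (its PCA basis co-rotates, up to component signs)
  m1 <- fit_sa(Xs, Xt, h = 3)
  m2 <- fit_sa(Xs, Xt %*% Q, h = 3)
  expect_equal(as.numeric(dist(predict(m1, Xt, "target"))),
               as.numeric(dist(predict(m2, Xt %*% Q, "target"))),
               tolerance = 1e-8)
  # a common rotation of both domains leaves the aligned source geometry
  # intact as well
  m3 <- fit_sa(Xs %*% Q, Xt %*% Q, h = 3)
  expect_equal(as.numeric(dist(predict(m1, Xs, "source"))),
               as.numeric(dist(predict(m3, Xs %*% Q, "source"))),
               tolerance = 1e-8)
})

test_that("adaptation models survive a serialization round trip", {
  fx <- make_mean_shift()
  model <- fit_mida(fx$X_bar, fx$design, h = 2)
  li <- adaptation_to_list(model)
  back <- adaptation_from_list(li)
  expect_equal(back$W, model$W)
  expect_equal(predict(back), predict(model))
  # via JSON text for bit-stability of the archive format
  json <- jsonlite::toJSON(li, auto_unbox = TRUE, digits = NA)
  back2 <- adaptation_from_list(jsonlite::fromJSON(json))
  expect_equal(predict(back2), predict(model), tolerance = 1e-12)
})
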