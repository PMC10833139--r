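test_that("normalized Laplacian matches closed-form spectra", {
  # single edge on two nodes
  L2 <- normalized_laplacian(matrix(c(0, 1, 1, 0), 2))
  expect_equal(L2, matrix(c(1, -1, -1, 1), 2))
  expect_equal(sort(eigen(L2)$values), c(0, 2))
  # triangle K3
  K3 <- matrix(1, 3, 3); diag(K3) <- 0
  L3 <- normalized_laplacian(K3)
  expect_equal(L3[upper.tri(L3)], rep(-0.5, 3))
  expect_equal(sort(eigen(L3)$values), c(0, 1.5, 1.5), tolerance = 1e-12)
  # empty graph -> zero matrix; isolated rows stay zero
  expect_equal(normalized_laplacian(matrix(0, 4, 4)), matrix(0, 4, 4))
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1
  expect_equal(normalized_laplacian(A)[3, ], rep(0, 3))

  expect_error(normalized_laplacian(matrix(c(0, 1, 0, 0), 2)), "symmetric")
  expect_error(normalized_laplacian(matrix(c(0, -1, -1, 0), 2)), "nonnegative")
})

test_that("Laplacian eigenvalues lie in [0, 2] for random graphs", {
  set.seed(1)
  for (i in 1:20) {
    p <- sample(3:12, 1)
    A <- matrix(rbinom(p * p, 1, 0.3) * runif(p * p), p)
    A <- (A + t(A)) / 2; diag(A) <- 0
    ev <- eigen(normalized_laplacian(A), symmetric = TRUE)$values
    expect_true(all(ev >= -1e-10 & ev <= 2 + 1e-10))
  }
})

test_that("class scatter matrices follow their definitions", {
  set.seed(2)
  # identical class means -> S_b ~ 0
  X <- scale(matrix(rnorm(40), 20, 2), scale = FALSE)
  lab <- rep(c(1, 2), 10)
  Xs <- X
  for (k in 1:2) {
    idx <- lab == k
    Xs[idx, ] <- sweep(X[idx, ], 2, colMeans(X[idx, , drop = FALSE]), "-")
  }
  expect_lt(max(abs(class_scatter(Xs, lab)$S_b)), 1e-10)

  # 1-D, means +/-1, equal sizes -> S_b = 1
  x1 <- matrix(c(rep(-1, 10), rep(1, 10)), ncol = 1)
  expect_equal(class_scatter(x1, rep(c("a", "b"), each = 10))$S_b,
               matrix(1, 1, 1))

  # rank(S_b) <= K - 1 on random instances
  for (i in 1:10) {
    K <- sample(2:4, 1); p <- sample(3:8, 1)
    Xr <- scale(matrix(rnorm(20 * K * p), 20 * K, p), scale = FALSE)
    lr <- rep(seq_len(K), each = 20)
    sb <- class_scatter(Xr, lr)$S_b
    expect_lte(sum(eigen(sb, symmetric = TRUE, only.values = TRUE)$values > 1e-10),
               K - 1)
  }
  expect_error(class_scatter(x1, rep("a", 20)), "2 classes")
})

test_that("cvSIDA separates well-separated classes and selects true features", {
  gen <- generate_sida_data(n_per_class = 60, K = 2, D = 2, p = 30, s = 8,
                            delta = 4, psi = 1, sigma2 = 1, seed = 31)
  m <- fit_sida(gen$data, folds = 3, seed = 5)
  expect_lte(m$train_error, 0.05)
  expect_true(m$train_correlation >= 0 && m$train_correlation <= 1)
  test <- generate_sida_data(n_per_class = 250, K = 2, D = 2, p = 30, s = 8,
                             delta = 4, psi = 1, sigma2 = 1, seed = 77)
  pred <- classify_sida(m, test$data)
  expect_lte(mean(pred$labels != as.character(test$data$outcome$values)), 0.1)
  sel <- which(rowSums(m$hatalpha[[1]] != 0) > 0)
  expect_gte(length(intersect(sel, gen$truth$supports[[1]])), 6)
  # unit-norm nonzero loading columns
  expect_equal(sum(m$hatalpha[[1]][, 1]^2), 1, tolerance = 1e-8)
})

test_that("three classes yield q = 2 discriminant vectors and sane errors", {
  gen <- generate_sida_data(n_per_class = 50, K = 3, D = 2, p = 20, s = 6,
                            delta = 4, psi = 1, sigma2 = 1, seed = 41)
  m <- fit_sida(gen$data, folds = 3, seed = 2)
  expect_equal(m$q, 2)
  expect_equal(ncol(m$hatalpha[[1]]), 2)
  expect_lte(m$train_error, 0.1)
})

test_that("balance = 1 with identical views reduces to sparse LDA", {
  set.seed(3)
  gen <- generate_sida_data(n_per_class = 50, K = 2, D = 2, p = 15, s = 5,
                            delta = 3, psi = 0.5, sigma2 = 1, seed = 51)
  X <- gen$data$views[[1]]
  d <- multiview_data(list(A = X, B = X),
                      outcome = gen$data$outcome)
  m <- fit_sida(d, lambda_grid = list(1e-8, 1e-8), folds = 3, balance = 1,
                seed = 4)
  Xc <- scale(X, scale = FALSE)
  sb_top <- eigen(class_scatter(Xc, gen$data$outcome$values)$S_b,
                  symmetric = TRUE)$vectors[, 1]
  cosine <- abs(sum(m$hatalpha[[1]][, 1] * sb_top))
  expect_gt(cosine, 0.99)
})

test_that("SIDANet with kappa = 0 or empty networks reproduces SIDA bit-for-bit", {
  gen <- generate_sida_data(n_per_class = 40, K = 2, D = 2, p = 20, s = 6,
                            delta = 3, psi = 1, sigma2 = 1, seed = 61)
  m0 <- fit_sida(gen$data, folds = 3, seed = 9)
  empty <- list(variable_network(matrix(0, 20, 20)),
                variable_network(matrix(0, 20, 20)))
  m1 <- fit_sidanet(gen$data, networks = empty, kappa = 1, folds = 3, seed = 9)
  m2 <- fit_sidanet(gen$data, networks = NULL, kappa = 0, folds = 3, seed = 9)
  expect_identical(m0$hatalpha, m1$hatalpha)
  expect_identical(m0$hatalpha, m2$hatalpha)
  expect_identical(m0$optLambda, m1$optLambda)

  # dimension mismatch is caught
  bad <- list(variable_network(matrix(0, 5, 5)), NULL)
  expect_error(fit_sidanet(gen$data, networks = bad, folds = 3, seed = 9),
               "dimension")
})

test_that("network structure does not hurt support recovery on modular truth", {
  f1s <- matrix(NA_real_, 3, 2)
  for (i in 1:3) {
    gen <- generate_sida_data(n_per_class = 60, K = 2, D = 2, p = 30, s = 8,
                              delta = 3, psi = 1, sigma2 = 1, seed = 70 + i)
    nets <- lapply(1:2, function(d) {
      generate_network_for_support(30, gen$truth$supports[[d]], seed = 80 + d)
    })
    ms <- fit_sida(gen$data, folds = 3, seed = 5)
    mn <- fit_sidanet(gen$data, networks = nets, kappa = 1, folds = 3, seed = 5)
    f1s[i, ] <- c(
      f1_support(which(rowSums(ms$hatalpha[[1]] != 0) > 0), gen$truth$supports[[1]]),
      f1_support(which(rowSums(mn$hatalpha[[1]] != 0) > 0), gen$truth$supports[[1]]))
  }
  expect_gte(mean(f1s[, 2]), mean(f1s[, 1]) - 0.05)
})

test_that("classification contracts hold", {
  gen <- generate_sida_data(n_per_class = 40, K = 2, D = 2, p = 20, s = 6,
                            delta = 4, psi = 1, sigma2 = 1, seed = 91)
  m <- fit_sida(gen$data, folds = 3, seed = 1)

  # classifying samples at the training centroids recovers each class
  centroid_views <- lapply(1:2, function(d) {
    # build one synthetic sample per class whose scores equal the centroid:
    # use the pseudo-inverse of the loadings on the centered scale
    G <- m$hatalpha[[d]]
    X <- m$centroids[[d]] %*% MASS_ginv(G)
    sweep(X, 2, m$preprocessing$means[[d]], "+")
  })
  pred <- classify_sida(m, centroid_views)
  expect_equal(pred$labels, m$class_labels)

  # wrong number of views
  expect_error(classify_sida(m, gen$data$views[1]), "2 view")

  # shifts on zero-loading features never change predictions
  zero_feat <- which(rowSums(m$hatalpha[[1]] != 0) == 0)[1]
  shifted <- gen$data$views
  shifted[[1]][, zero_feat] <- shifted[[1]][, zero_feat] + 100
  expect_identical(classify_sida(m, shifted)$labels,
                   classify_sida(m, gen$data$views)$labels)
})

test_that("permuted labels give chance-level behavior", {
  # permuted labels on signalled data: CV error indistinguishable from 0.5
  gen <- generate_sida_data(n_per_class = 200, K = 2, D = 2, p = 20, s = 6,
                            delta = 3, psi = 1, sigma2 = 1, seed = 101)
  perm <- gen$data
  perm$outcome$values <- with_seed_local(5, sample(perm$outcome$values))
  m <- fit_sida(perm, folds = 5, seed = 3)
  se3 <- 3 * sqrt(0.25 / 400)
  expect_lt(abs(m$cv_error - 0.5), se3 + 0.05)

  # independent pure-noise views (no class means, no shared latent):
  # the reported training correlation stays low on average
  tc <- vapply(1:3, function(s) {
    noise <- generate_sida_data(n_per_class = 200, K = 2, D = 2, p = 10, s = 3,
                                delta = 0, psi = 0, sigma2 = 1, seed = 102 + s)
    pn <- noise$data
    pn$outcome$values <- with_seed_local(6 + s, sample(pn$outcome$values))
    mn <- fit_sida(pn, folds = 5, seed = 4)
    expect_true(mn$train_correlation >= 0 && mn$train_correlation <= 1)
    mn$train_correlation
  }, 0)
  expect_lt(mean(tc), 0.3)
})
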