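test_that("preprocess centers, scales and log2-transforms as documented", {
  X <- cbind(a = c(1, 2, 3), b = c(0, 1, 3))
  expect_equal(preprocess(X, center = TRUE)$matrix[, "a"], c(-1, 0, 1))
  expect_equal(preprocess(X, log2 = TRUE)$matrix[, "b"], c(0, 1, 2))
  expect_error(preprocess(cbind(x = c(-2, 1)), log2 = TRUE), "> -1")

  # normalize == center + scale
  set.seed(1)
  Y <- matrix(rnorm(60, 5, 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  n1 <- preprocess(Y, normalize = TRUE)$matrix
  n2 <- preprocess(Y, center = TRUE, scale = TRUE)$matrix
  expect_equal(n1, n2)
  expect_true(all(abs(colMeans(n1)) < 1e-8))
  expect_true(all(abs(apply(n1, 2, var) - 1) < 1e-8))
})

test_that("training transforms are replayed on test data without re-estimation", {
  set.seed(2)
  tr <- matrix(rnorm(40, 10), 20, 2, dimnames = list(NULL, c("a", "b")))
  te <- matrix(rnorm(10, 3), 5, 2, dimnames = list(NULL, c("a", "b")))
  pp <- preprocess(tr, normalize = TRUE)
  out <- preprocess(te, train_params = pp$params)
  # training means were used, so test means are generally nonzero
  expect_gt(max(abs(colMeans(out$matrix))), 0.5)
  expect_equal(out$matrix, sweep(sweep(te, 2, pp$params$means, "-"), 2,
                                 pp$params$sds, "/"))
})

test_that("zero-variance columns error or drop under scaling", {
  X <- cbind(a = c(1, 1, 1), b = c(1, 2, 3))
  expect_error(preprocess(X, scale = TRUE), "zero-variance.*a")
  expect_warning(pp <- preprocess(X, scale = TRUE, zero_var = "drop"), "dropping")
  expect_equal(colnames(pp$matrix), "b")
  # the drop is recorded and replayed on new data
  out <- preprocess(X, train_params = pp$params)
  expect_equal(colnames(out$matrix), "b")
})

test_that("BH adjustment matches the hand-computed step-up and p.adjust", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
  expect_equal(adjust_pvalues(0.5, "BH"), 0.5)
  expect_equal(adjust_pvalues(0.5, "bonferroni"), 0.5)
  # order-equivariance
  p <- c(0.04, 0.02, 0.01)
  expect_equal(adjust_pvalues(p, "BH"), c(0.04, 0.03, 0.03))
  # against the stats oracle on random vectors
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    expect_equal(adjust_pvalues(p, "BH"), p.adjust(p, "BH"))
    expect_equal(adjust_pvalues(p, "bonferroni"), p.adjust(p, "bonferroni"))
  }
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("supervised filtering flags signal and ignores constants", {
  set.seed(4)
  n <- 40
  y_bin <- mv_outcome(rep(c(0, 1), each = n / 2), kind = "binary")
  X <- cbind(const = rep(1, n), signal = rep(c(0, 3), each = n / 2) + rnorm(n, sd = 0.3),
             noise = rnorm(n))
  fr <- supervised_filter(X, y_bin, method = "ttest", padjust = TRUE)
  tb <- fr$table
  expect_equal(tb$p_value[tb$name == "const"], 1)
  expect_false(tb$keep[tb$name == "const"])
  expect_true(tb$keep[tb$name == "signal"])
  # effect = group2 - group1 mean difference
  expect_equal(tb$effect[tb$name == "signal"],
               mean(X[21:40, "signal"]) - mean(X[1:20, "signal"]))
  expect_true(all(tb$p_adjusted >= tb$p_value, na.rm = TRUE))

  # linear: a feature equal to the outcome is kept with p ~ 0
  y_cont <- mv_outcome(rnorm(n), kind = "continuous")
  Xl <- cbind(self = y_cont$values, noise = rnorm(n))
  # lm warns about the essentially perfect fit; that is the point of the case
  frl <- suppressWarnings(supervised_filter(Xl, y_cont, method = "linear"))
  expect_lt(frl$table$p_value[1], 1e-12)
  expect_true(frl$table$keep[1])
})

test_that("perfectly separating features are excluded from the logistic screen", {
  set.seed(5)
  n <- 30
  y <- mv_outcome(rep(c(0, 1), each = n / 2), kind = "binary")
  X <- cbind(sep = rep(c(-5, 5), each = n / 2), ok = rnorm(n))
  expect_warning(fr <- supervised_filter(X, y, method = "logistic"), "separat")
  expect_true(is.na(fr$table$p_value[fr$table$name == "sep"]))
  expect_false(fr$table$keep[fr$table$name == "sep"])
})

test_that("ttest and kw rank strongly-signalled features similarly", {
  set.seed(6)
  n <- 60; p <- 30
  grp <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  X[grp == 1, 1:10] <- X[grp == 1, 1:10] + rep(seq(2, 0.5, length.out = 10), each = n / 2)
  y <- mv_outcome(grp, kind = "binary")
  pt <- supervised_filter(X, y, method = "ttest")$table$p_value
  pk <- supervised_filter(X, y, method = "kw")$table$p_value
  expect_gt(cor(-log(pt), -log(pk), method = "spearman"), 0.8)
})

test_that("unsupervised filtering ranks by variance/IQR with stable ties", {
  X <- cbind(f1 = c(0, 1, 0, 1), f2 = c(0, 2, 0, 2), f3 = c(0, 3, 0, 3))
  fr <- unsupervised_filter(X, "variance", keep_fraction = 1 / 3)
  expect_equal(kept_features(fr), "f3")
  expect_equal(kept_features(unsupervised_filter(X, "variance", 1)),
               c("f1", "f2", "f3"))

  # IQR ranking matches a brute-force type-7 quantile oracle
  set.seed(7)
  Y <- matrix(rnorm(50 * 20), 50, 20, dimnames = list(NULL, paste0("g", 1:20)))
  fr2 <- unsupervised_filter(Y, "iqr", keep_fraction = 0.25)
  oracle <- apply(Y, 2, function(x) {
    q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE); q[2] - q[1]
  })
  # kept set = top-k by the brute-force oracle (kept_features preserves the
  # original column order, so compare as sets)
  expect_setequal(kept_features(fr2),
                  colnames(Y)[order(-oracle)][1:ceiling(0.25 * 20)])
  expect_equal(fr2$table$statistic, unname(oracle))

  # ties broken by original column order
  Z <- cbind(t1 = c(0, 1), t2 = c(0, 1), t3 = c(0, 2))
  fr3 <- unsupervised_filter(Z, "variance", keep_fraction = 2 / 3)
  expect_equal(kept_features(fr3), c("t1", "t3"))
})

test_that("apply_filter restricts test data to kept training features", {
  set.seed(8)
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  fr <- unsupervised_filter(X, "variance", keep_fraction = 0.5)
  kept <- kept_features(fr)
  te <- matrix(rnorm(50), 10, 5,
               dimnames = list(NULL, c(paste0("f", 1:4), "extra")))
  out <- apply_filter(te, fr)
  expect_equal(colnames(out), kept) # extras dropped silently, kept-order
  te_missing <- te[, setdiff(colnames(te), kept[1]), drop = FALSE]
  expect_error(apply_filter(te_missing, fr), kept[1])

  # keep_fraction = 1 then apply is the identity on feature sets
  fr_all <- unsupervised_filter(X, "variance", keep_fraction = 1)
  expect_setequal(colnames(apply_filter(X, fr_all)), colnames(X))
})
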