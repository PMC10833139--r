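# Sparse canonical correlation analysis. The nonsparse initializer takes the
# leading singular triplets of the cross-covariance S12 = X1'X2/(n-1)
# (within-view covariances treated as identity, the high-dimension-friendly
# convention for n << p). Each canonical direction is sparsified by the SELP
# subproblem — minimize ||u||_1 subject to ||c - rho u||_inf <= tau — whose
# solution with this diagonal constraint is coordinate-wise soft-thresholding.
# Components beyond the first are obtained by Hotelling deflation of S12 with
# the nonsparse triplet.

# ---- nonsparse initializer ---------------------------------------------------

#' Nonsparse CCA initializer via the cross-covariance SVD
#'
#' Computes the leading `K` singular triplets of `S12 = t(X1) %*% X2 / (n-1)`.
#' Columns are unit-norm; the sign of each left vector is fixed so its
#' largest-magnitude entry is positive (the right vector is flipped in step).
#'
#' @param X1,X2 Column-centered numeric matrices with the same number of rows.
#' @param K Number of components; must not exceed the rank of `S12`.
#' @return List with `atilde` (p1 x K), `btilde` (p2 x K), `d` (K singular
#'   values).
#' @export
initial_cca <- function(X1, X2, K = 1) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  stopifnot(nrow(X1) == nrow(X2), K >= 1)
  n <- nrow(X1)
  S12 <- crossprod(X1, X2) / (n - 1)
  svd_triplets(S12, K)
}

svd_triplets <- function(S12, K) {
  sv <- svd(S12)
  rank <- sum(sv$d > max(dim(S12)) * .Machine$double.eps * sv$d[1])
  if (K > rank) stop("K = ", K, " exceeds the rank of the cross-covariance (", rank, ")")
  atilde <- sv$u[, seq_len(K), drop = FALSE]
  btilde <- sv$v[, seq_len(K), drop = FALSE]
  for (k in seq_len(K)) {
    j <- which.max(abs(atilde[, k]))
    if (atilde[j, k] < 0) {
      atilde[, k] <- -atilde[, k]
      btilde[, k] <- -btilde[, k]
    }
  }
  rownames(atilde) <- rownames(S12)
  rownames(btilde) <- colnames(S12)
  list(atilde = atilde, btilde = btilde, d = sv$d[seq_len(K)])
}

# ---- SELP subproblem ---------------------------------------------------------

#' Sparsify a direction by the SELP subproblem
#'
#' Solves `minimize ||u||_1 subject to ||c - rho * u||_inf <= tau`. With this
#' separable constraint the exact solution is coordinate-wise
#' soft-thresholding, `u_j = sign(c_j) * max(0, |c_j| - tau) / rho`, after
#' which the vector is rescaled to unit Euclidean norm (unless `normalize =
#' FALSE`). `tau = 0` reproduces the nonsparse direction `c / rho`; `tau >=
#' max(|c|)` thresholds everything, and the all-zero vector is returned as the
#' "no variables selected" signal for the caller to handle.
#'
#' @param c Numeric vector (e.g. `S12 %*% btilde` for the view-1 update).
#' @param rho Positive scalar, the current singular value.
#' @param tau Nonnegative threshold.
#' @param normalize Rescale a nonzero solution to unit norm? Default `TRUE`;
#'   `FALSE` returns the raw solution, which satisfies the infinity-norm
#'   constraint exactly.
#' @return Numeric vector of the same length as `c`.
#' @export
selp_sparsify <- function(c, rho, tau, normalize = TRUE) {
  stopifnot(rho > 0, tau >= 0)
  u <- sign(c) * pmax(0, abs(c) - tau) / rho
  nrm <- sqrt(sum(u^2))
  if (normalize && nrm > 0) u <- u / nrm
  u
}

log_spaced <- function(lo, hi, length_out) {
  exp(seq(log(lo), log(hi), length.out = length_out))
}

auto_tau_grid <- function(cvec, length_out = 10) {
  m <- max(abs(cvec))
  log_spaced(0.05 * m, 0.95 * m, length_out)
}

# alternating SELP updates on a fixed (deflated) cross-covariance.
# returns NULL if either support empties.
selp_alternate <- function(S12, a0, b0, d, tau1, tau2,
                           tol = 1e-6, max_iter = 50, warn_cap = FALSE) {
  a <- a0; b <- b0
  for (it in seq_len(max_iter)) {
    a_new <- selp_sparsify(drop(S12 %*% b), d, tau1)
    if (all(a_new == 0)) return(NULL)
    b_new <- selp_sparsify(drop(crossprod(S12, a_new)), d, tau2)
    if (all(b_new == 0)) return(NULL)
    delta <- max(max(abs(a_new - a)), max(abs(b_new - b)))
    a <- a_new; b <- b_new
    if (delta < tol) return(list(a = a, b = b, iterations = it, converged = TRUE))
  }
  if (warn_cap) warning("alternating SELP updates hit the iteration cap (", max_iter, ")")
  list(a = a, b = b, iterations = max_iter, converged = FALSE)
}

abs_cor <- function(u, v) {
  if (stats::sd(u) == 0 || stats::sd(v) == 0) return(0)
  abs(stats::cor(u, v))
}

get_two_views <- function(data) {
  stopifnot(inherits(data, "mvdata"))
  if (length(data$views) != 2) stop("SELPCCA requires exactly 2 views")
  data$views
}

# ---- fixed-tau fit -----------------------------------------------------------

#' Fit SELPCCA at fixed tuning values
#'
#' Fits `ncancorr` sparse canonical components with the per-view thresholds
#' fixed (no cross-validation). `tau = c(0, 0)` yields the nonsparse CCA
#' solution. Views are centered internally; the training means are stored on
#' the model and replayed by [transform_scores()].
#'
#' @param data An `mvdata` with exactly two views.
#' @param tau Length-2 vector (view-1, view-2 thresholds), or a 2 x K matrix
#'   for per-component values.
#' @param ncancorr Number of canonical components K (default 1).
#' @return A `selpcca_model`; see [cv_selpcca()] for the fields.
#' @export
selpcca <- function(data, tau = c(0, 0), ncancorr = 1) {
  views <- get_two_views(data)
  if (is.matrix(tau)) stopifnot(nrow(tau) == 2, ncol(tau) == ncancorr)
  else tau <- matrix(rep(tau, ncancorr), nrow = 2)
  fit_selpcca_engine(views[[1]], views[[2]], K = ncancorr,
                     tau_fixed = tau, view_names = data$view_names)
}

#' Cross-validated SELPCCA
#'
#' For each canonical component, selects the per-view threshold pair by
#' `folds`-fold cross-validation, maximizing the mean held-out absolute
#' correlation of the two views' scores; ties are broken toward larger
#' thresholds (sparser loadings). The model is then refit on the full
#' training data at the selected pair, the cross-covariance is deflated with
#' the component's nonsparse singular triplet, and the next component is
#' tuned the same way.
#'
#' @param data An `mvdata` with exactly two views.
#' @param ncancorr Number of canonical components K (default 1).
#' @param tau_grid Optional list of two numeric vectors (per-view candidate
#'   thresholds); by default 10 log-spaced values per view from 5% to 95% of
#'   the largest entry of the view's update vector.
#' @param folds Number of CV folds (default 5); every fold needs >= 2 samples.
#' @param seed Integer seed for the fold assignment.
#' @return A `selpcca_model`: list with `hatalpha`, `hatbeta` (p_d x K sparse
#'   loadings, unit-norm nonzero columns), `optTau` (2 x K), `maxcorr`
#'   (K absolute training canonical correlations), `train_scores` (`U`, `V`),
#'   `nonzero` (2 x K counts), `cv_correlation` (mean held-out |cor| at the
#'   optimum, per component), `preprocessing` (per-view training means),
#'   `feature_names`, `view_names`, `K`.
#' @export
cv_selpcca <- function(data, ncancorr = 1, tau_grid = NULL, folds = 5,
                       seed = 1234) {
  views <- get_two_views(data)
  n <- nrow(views[[1]])
  if (n < 2 * folds) stop("need n >= 2 * folds samples for ", folds, "-fold CV")
  fit_selpcca_engine(views[[1]], views[[2]], K = ncancorr, tau_grid = tau_grid,
                     folds = folds, seed = seed, view_names = data$view_names)
}

fit_selpcca_engine <- function(X1, X2, K, tau_fixed = NULL, tau_grid = NULL,
                               folds = 5, seed = 1234, view_names = c("View1", "View2")) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  n <- nrow(X1)
  if (is.null(colnames(X1))) colnames(X1) <- paste0("x1_", seq_len(ncol(X1)))
  if (is.null(colnames(X2))) colnames(X2) <- paste0("x2_", seq_len(ncol(X2)))
  mu1 <- colMeans(X1); mu2 <- colMeans(X2)
  X1c <- sweep(X1, 2, mu1, "-")
  X2c <- sweep(X2, 2, mu2, "-")
  S12 <- crossprod(X1c, X2c) / (n - 1)

  do_cv <- is.null(tau_fixed)
  if (do_cv) {
    foldid <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
    if (min(table(foldid)) < 2) stop("a CV fold has fewer than 2 samples")
    fold_pre <- lapply(seq_len(folds), function(f) {
      tr <- foldid != f
      m1 <- colMeans(X1[tr, , drop = FALSE]); m2 <- colMeans(X2[tr, , drop = FALSE])
      A <- sweep(X1[tr, , drop = FALSE], 2, m1, "-")
      B <- sweep(X2[tr, , drop = FALSE], 2, m2, "-")
      list(S12 = crossprod(A, B) / (sum(tr) - 1),
           X1te = sweep(X1[!tr, , drop = FALSE], 2, m1, "-"),
           X2te = sweep(X2[!tr, , drop = FALSE], 2, m2, "-"))
    })
  }

  p1 <- ncol(X1); p2 <- ncol(X2)
  hatalpha <- matrix(0, p1, K, dimnames = list(colnames(X1), NULL))
  hatbeta <- matrix(0, p2, K, dimnames = list(colnames(X2), NULL))
  optTau <- matrix(NA_real_, 2, K, dimnames = list(view_names, NULL))
  maxcorr <- cv_corr <- numeric(K)
  S12_def <- S12
  triplets <- vector("list", K)

  for (k in seq_len(K)) {
    tri <- svd_triplets(S12_def, 1)
    atil <- drop(tri$atilde); btil <- drop(tri$btilde); dk <- tri$d[1]
    triplets[[k]] <- list(a = atil, b = btil, d = dk)

    if (do_cv) {
      c1 <- drop(S12_def %*% btil); c2 <- drop(crossprod(S12_def, atil))
      grid1 <- if (is.null(tau_grid)) auto_tau_grid(c1) else sort(tau_grid[[1]])
      grid2 <- if (is.null(tau_grid)) auto_tau_grid(c2) else sort(tau_grid[[2]])
      fold_scores <- array(NA_real_, c(length(grid1), length(grid2), folds))
      valid <- matrix(TRUE, length(grid1), length(grid2))
      for (f in seq_len(folds)) {
        fp <- fold_pre[[f]]
        S12f <- fp$S12
        for (j in seq_len(k - 1)) {
          tj <- triplets[[j]]
          S12f <- S12f - tj$d * tcrossprod(tj$a, tj$b)
        }
        trif <- svd_triplets(S12f, 1)
        af <- drop(trif$atilde); bf <- drop(trif$btilde); df <- trif$d[1]
        for (i1 in seq_along(grid1)) for (i2 in seq_along(grid2)) {
          fit <- selp_alternate(S12f, af, bf, df, grid1[i1], grid2[i2])
          if (is.null(fit)) { valid[i1, i2] <- FALSE; next }
          fold_scores[i1, i2, f] <-
            abs_cor(drop(fp$X1te %*% fit$a), drop(fp$X2te %*% fit$b))
        }
      }
      score <- apply(fold_scores, c(1, 2), mean)
      score[!valid] <- -Inf
      if (all(!is.finite(score))) {
        stop("no threshold pair retained variables in every fold (component ", k, ")")
      }
      # one-standard-error rule: CV estimates are noisy, so "ties go to the
      # sparser model" means the sparsest pair within 1 SE of the maximum
      top <- which(score == max(score), arr.ind = TRUE)[1, ]
      se <- stats::sd(fold_scores[top[1], top[2], ]) / sqrt(folds)
      best <- which(score >= max(score) - se, arr.ind = TRUE)
      best <- best[order(-(best[, 1] + best[, 2]), -best[, 1]), , drop = FALSE][1, ]
      tau_k <- c(grid1[best[1]], grid2[best[2]])
      cv_corr[k] <- score[best[1], best[2]]
    } else {
      tau_k <- tau_fixed[, k]
    }

    fit <- selp_alternate(S12_def, atil, btil, dk, tau_k[1], tau_k[2],
                          warn_cap = TRUE)
    if (is.null(fit)) {
      stop("no variables selected at tau = (", tau_k[1], ", ", tau_k[2],
           ") for component ", k, "; shrink tau")
    }
    hatalpha[, k] <- fit$a
    hatbeta[, k] <- fit$b
    optTau[, k] <- tau_k
    maxcorr[k] <- abs_cor(drop(X1c %*% fit$a), drop(X2c %*% fit$b))
    S12_def <- S12_def - dk * tcrossprod(atil, btil)
  }

  model <- list(
    hatalpha = hatalpha, hatbeta = hatbeta, optTau = optTau,
    maxcorr = maxcorr, cv_correlation = if (do_cv) cv_corr else NULL,
    train_scores = list(U = X1c %*% hatalpha, V = X2c %*% hatbeta),
    nonzero = rbind(colSums(hatalpha != 0), colSums(hatbeta != 0)),
    preprocessing = list(means = list(mu1, mu2)),
    feature_names = list(colnames(X1), colnames(X2)),
    view_names = view_names, K = K
  )
  rownames(model$nonzero) <- view_names
  rownames(model$train_scores$U) <- rownames(X1)
  rownames(model$train_scores$V) <- rownames(X2)
  class(model) <- "selpcca_model"
  model
}

#' @export
print.selpcca_model <- function(x, ...) {
  cat(sprintf("<selpcca_model> %d component(s), views %s / %s\n",
              x$K, x$view_names[1], x$view_names[2]))
  for (k in seq_len(x$K)) {
    cat(sprintf("  comp %d: |cor| = %.3f, nonzero = %d + %d, tau = (%.4g, %.4g)\n",
                k, x$maxcorr[k], x$nonzero[1, k], x$nonzero[2, k],
                x$optTau[1, k], x$optTau[2, k]))
  }
  invisible(x)
}

#' Canonical scores for new data
#'
#' Applies the model's training centering and projects both views onto the
#' fitted canonical loadings. On the training data this reproduces
#' `model$train_scores` exactly.
#'
#' @param model A `selpcca_model`.
#' @param X1new,X2new Matrices whose columns match the model's feature sets
#'   (extra columns are an error).
#' @return List with `U` (`X1` scores, n x K) and `V` (`X2` scores).
#' @export
transform_scores <- function(model, X1new, X2new) {
  stopifnot(inherits(model, "selpcca_model"))
  X1new <- as.matrix(X1new); X2new <- as.matrix(X2new)
  for (i in 1:2) {
    Xn <- if (i == 1) X1new else X2new
    want <- model$feature_names[[i]]
    if (is.null(colnames(Xn))) {
      if (ncol(Xn) != length(want)) {
        stop("view ", i, " has ", ncol(Xn), " unnamed columns; expected ",
             length(want))
      }
      colnames(Xn) <- want
      if (i == 1) X1new <- Xn else X2new <- Xn
    }
    have <- colnames(Xn)
    if (!identical(sort(have), sort(want))) {
      stop("view ", i, " feature mismatch; missing: ",
           paste(utils::head(setdiff(want, have), 5), collapse = ", "),
           "; unexpected: ",
           paste(utils::head(setdiff(have, want), 5), collapse = ", "))
    }
  }
  X1new <- X1new[, model$feature_names[[1]], drop = FALSE]
  X2new <- X2new[, model$feature_names[[2]], drop = FALSE]
  X1c <- sweep(X1new, 2, model$preprocessing$means[[1]], "-")
  X2c <- sweep(X2new, 2, model$preprocessing$means[[2]], "-")
  list(U = X1c %*% model$hatalpha, V = X2c %*% model$hatbeta)
}
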