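# Sparse integrative discriminant analysis: for each view d the working
# matrix A_d = c * S_b^d + (1-c)/(D-1) * sum_{j != d} M_dj G_j G_j' M_dj'
# blends within-view class separation (between-class scatter S_b) with
# cross-view association (projected cross-covariances M_dj = X_d'X_j/(n-1)).
# Discriminant vectors are the top eigenvectors of A_d, sparsified by the
# SELP soft-thresholding step; the Laplacian-structured variant replaces the
# eigenproblem with the generalized problem A_d g = eta (I + kappa L_d) g.

# ---- graph utilities ---------------------------------------------------------

#' Normalized graph Laplacian
#'
#' `L = I - D^(-1/2) A D^(-1/2)` with `D` the degree diagonal. Rows and
#' columns of isolated nodes (zero degree) are set to zero, so an empty graph
#' maps to the zero matrix. Eigenvalues of a valid normalized Laplacian lie
#' in \[0, 2\].
#'
#' @param adjacency Square symmetric nonnegative matrix with zero diagonal.
#' @return The normalized Laplacian matrix.
#' @export
normalized_laplacian <- function(adjacency) {
  A <- as.matrix(adjacency)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (any(A < 0)) stop("adjacency must be nonnegative")
  if (max(abs(A - t(A))) > 1e-8) stop("adjacency must be symmetric")
  if (any(diag(A) != 0)) stop("adjacency must have a zero diagonal")
  p <- nrow(A)
  deg <- rowSums(A)
  L <- matrix(0, p, p, dimnames = dimnames(A))
  nz <- deg > 0
  if (any(nz)) {
    dinv <- 1 / sqrt(deg[nz])
    L[nz, nz] <- diag(sum(nz)) - (dinv * A[nz, nz]) %*% diag(dinv, sum(nz))
    L[nz, nz] <- (L[nz, nz] + t(L[nz, nz])) / 2
  }
  L
}

#' Construct a per-view variable network
#'
#' Wraps a variable-variable adjacency (square matrix, or a 3-column edge
#' list `i, j, weight` with indices or names) together with its normalized
#' Laplacian, for use with [fit_sidanet()].
#'
#' @param adjacency Square symmetric nonnegative matrix, or a 3-column
#'   edge-list data.frame/matrix.
#' @param p Number of variables (required for an edge list with integer ids).
#' @param feature_names Optional names for the variables.
#' @param view_name Label.
#' @return A `variable_network` with fields `adjacency`,
#'   `normalized_laplacian`, `view_name`.
#' @export
variable_network <- function(adjacency, p = NULL, feature_names = NULL,
                             view_name = "view") {
  if ((is.data.frame(adjacency) || is.matrix(adjacency)) &&
      ncol(adjacency) == 3 && (is.data.frame(adjacency) ||
                               nrow(adjacency) != ncol(adjacency))) {
    el <- as.data.frame(adjacency)
    if (is.null(p)) p <- length(feature_names)
    if (is.null(p) || p == 0) stop("edge-list input requires `p` or `feature_names`")
    A <- matrix(0, p, p)
    i <- if (is.numeric(el[[1]])) el[[1]] else match(el[[1]], feature_names)
    j <- if (is.numeric(el[[2]])) el[[2]] else match(el[[2]], feature_names)
    w <- as.numeric(el[[3]])
    if (anyNA(i) || anyNA(j)) stop("edge list refers to unknown variables")
    for (e in seq_along(i)) {
      A[i[e], j[e]] <- w[e]
      A[j[e], i[e]] <- w[e]
    }
    diag(A) <- 0
  } else {
    A <- as.matrix(adjacency)
  }
  if (!is.null(feature_names)) dimnames(A) <- list(feature_names, feature_names)
  out <- list(view_name = view_name, adjacency = A,
              normalized_laplacian = normalized_laplacian(A))
  class(out) <- "variable_network"
  out
}

# ---- scatter matrices --------------------------------------------------------

#' Between-class and total scatter of a centered view
#'
#' `S_t = X'X/(n-1)`; `S_b = sum_k (n_k/n) m_k m_k'` with `m_k` the class-k
#' mean of the centered data. Both are symmetric positive semidefinite and
#' `rank(S_b) <= K - 1`.
#'
#' @param X Column-centered numeric matrix.
#' @param labels Class labels, at least two classes.
#' @return List with `S_b` and `S_t`.
#' @export
class_scatter <- function(X, labels) {
  X <- as.matrix(X)
  cls <- factor(labels)
  if (nlevels(cls) < 2) stop("need at least 2 classes")
  n <- nrow(X)
  S_t <- crossprod(X) / (n - 1)
  S_b <- matrix(0, ncol(X), ncol(X))
  for (k in levels(cls)) {
    idx <- cls == k
    m_k <- colMeans(X[idx, , drop = FALSE])
    S_b <- S_b + (sum(idx) / n) * tcrossprod(m_k)
  }
  dimnames(S_b) <- dimnames(S_t)
  list(S_b = S_b, S_t = S_t)
}

# ---- engine ------------------------------------------------------------------

# precompute per-dataset quantities reused across lambda candidates
sida_precompute <- function(Xc, cls, q) {
  D <- length(Xc)
  n <- nrow(Xc[[1]])
  S_b <- lapply(Xc, function(X) class_scatter(X, cls)$S_b)
  M <- vector("list", D)
  for (d in seq_len(D)) {
    M[[d]] <- vector("list", D)
    for (j in seq_len(D)) if (j != d) {
      M[[d]][[j]] <- crossprod(Xc[[d]], Xc[[j]]) / (n - 1)
    }
  }
  init <- lapply(S_b, function(S) {
    eg <- eigen(S, symmetric = TRUE)
    G <- eg$vectors[, seq_len(q), drop = FALSE]
    sign_fix_cols(G)
  })
  list(S_b = S_b, M = M, init = init, D = D, q = q)
}

sign_fix_cols <- function(G) {
  for (l in seq_len(ncol(G))) {
    j <- which.max(abs(G[, l]))
    if (G[j, l] < 0) G[, l] <- -G[, l]
  }
  G
}

# alternating SIDA updates; Binvhalf[[d]] is NULL for the plain eigenproblem.
# penalize[d] = FALSE keeps the nonsparse eigenvectors (covariate views).
# returns NULL if any penalized view's support empties.
sida_core <- function(pre, c_weight, lambda, Binvhalf, penalize,
                      max_iter = 20, tol = 1e-4, warn_cap = FALSE) {
  D <- pre$D; q <- pre$q
  Gamma <- pre$init
  obj_prev <- -Inf
  assoc_w <- if (D > 1) (1 - c_weight) / (D - 1) else 0
  for (it in seq_len(max_iter)) {
    obj <- 0
    for (d in seq_len(D)) {
      A <- c_weight * pre$S_b[[d]]
      for (j in seq_len(D)) if (j != d) {
        MG <- pre$M[[d]][[j]] %*% Gamma[[j]]
        A <- A + assoc_w * tcrossprod(MG)
      }
      A <- (A + t(A)) / 2
      if (is.null(Binvhalf[[d]])) {
        eg <- eigen(A, symmetric = TRUE)
        vecs <- eg$vectors[, seq_len(q), drop = FALSE]
        vals <- eg$values[seq_len(q)]
      } else {
        At <- Binvhalf[[d]] %*% A %*% Binvhalf[[d]]
        eg <- eigen((At + t(At)) / 2, symmetric = TRUE)
        vecs <- Binvhalf[[d]] %*% eg$vectors[, seq_len(q), drop = FALSE]
        vecs <- sweep(vecs, 2, sqrt(colSums(vecs^2)), "/")
        vals <- eg$values[seq_len(q)]
      }
      vecs <- sign_fix_cols(vecs)
      if (penalize[d]) {
        G <- matrix(0, nrow(vecs), q)
        for (l in seq_len(q)) {
          rho <- max(vals[l], .Machine$double.eps)
          G[, l] <- selp_sparsify(drop(A %*% vecs[, l]), rho, lambda[d])
        }
        # a view whose support empties entirely invalidates the candidate;
        # individual zero columns are allowed (between-class scatter can have
        # rank < q when class means are collinear)
        if (all(G == 0)) return(NULL)
        Gamma[[d]] <- G
      } else {
        Gamma[[d]] <- vecs
      }
      obj <- obj + sum(diag(crossprod(Gamma[[d]], A %*% Gamma[[d]])))
    }
    if (abs(obj - obj_prev) < tol * max(1, abs(obj_prev))) {
      return(list(Gamma = Gamma, iterations = it, converged = TRUE, objective = obj))
    }
    obj_prev <- obj
  }
  if (warn_cap) warning("SIDA alternating updates hit the iteration cap (", max_iter, ")")
  list(Gamma = Gamma, iterations = max_iter, converged = FALSE, objective = obj_prev)
}

sida_centroids <- function(Xc, Gamma, cls) {
  lev <- levels(cls)
  lapply(seq_along(Xc), function(d) {
    sc <- Xc[[d]] %*% Gamma[[d]]
    cen <- do.call(rbind, lapply(lev, function(k) {
      colMeans(sc[cls == k, , drop = FALSE])
    }))
    rownames(cen) <- lev
    cen
  })
}

nearest_centroid <- function(scores, centroids, lev) {
  n <- nrow(scores[[1]])
  K <- length(lev)
  dist2 <- matrix(0, n, K)
  for (d in seq_along(scores)) {
    for (k in seq_len(K)) {
      dist2[, k] <- dist2[, k] +
        rowSums(sweep(scores[[d]], 2, centroids[[d]][k, ], "-")^2)
    }
  }
  lev[apply(dist2, 1, which.min)] # which.min ties -> first (lowest label)
}

auto_lambda_grid <- function(pre, c_weight, d, length_out = 8) {
  # scale of the first component's update vector at the initial Gamma
  A <- c_weight * pre$S_b[[d]]
  assoc_w <- if (pre$D > 1) (1 - c_weight) / (pre$D - 1) else 0
  for (j in seq_len(pre$D)) if (j != d) {
    MG <- pre$M[[d]][[j]] %*% pre$init[[j]]
    A <- A + assoc_w * tcrossprod(MG)
  }
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  cmax <- max(abs(A %*% eg$vectors[, 1]))
  log_spaced(0.05 * cmax, 0.95 * cmax, length_out)
}

stratified_folds <- function(cls, folds, seed) {
  with_seed(seed, {
    foldid <- integer(length(cls))
    for (k in levels(cls)) {
      idx <- which(cls == k)
      foldid[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
    foldid
  })
}

# ---- user-facing fitters -----------------------------------------------------

#' Cross-validated sparse integrative discriminant analysis
#'
#' Jointly maximizes cross-view association and within-view class separation
#' over two or more views, with sparse per-view discriminant loadings
#' (`q = K - 1` vectors for `K` classes). The per-view threshold `lambda` is
#' chosen by class-stratified `folds`-fold cross-validation minimizing the
#' held-out nearest-centroid misclassification rate; ties are broken toward
#' larger thresholds (sparser). With two views every pair from the two grids
#' is scored; with three or more views a single shared threshold is tuned on
#' one grid (documented in the methods vignette). Covariates, when requested,
#' join as an extra unpenalized view that is always retained.
#'
#' @param data An `mvdata` with >= 2 views and a binary/multiclass outcome.
#' @param lambda_grid Optional list of per-view candidate threshold vectors;
#'   auto grids (8 log-spaced values from 5% to 95% of the initial update
#'   vector's largest entry) by default.
#' @param folds CV folds (default 5).
#' @param balance Association/separation balance weight `c` in (0, 1\];
#'   `c = 1` is sparse LDA per view, smaller values weight cross-view
#'   association more. Default 0.5.
#' @param with_covariates Include `data$covariates` as an extra unpenalized
#'   view? Default `FALSE`.
#' @param seed Integer seed for fold assignment.
#' @return A `sida_model`: list with `hatalpha` (per-view p_d x q sparse
#'   loadings), `optLambda`, `balance`, `train_scores`, `centroids` (per-view
#'   K x q), `train_correlation` (mean pairwise absolute correlation of the
#'   first score columns), `train_error`, `cv_error`, `class_labels`,
#'   `preprocessing` (per-view training means), `feature_names`,
#'   `view_names`, `q`, convergence diagnostics.
#' @export
fit_sida <- function(data, lambda_grid = NULL, folds = 5, balance = 0.5,
                     with_covariates = FALSE, seed = 1234) {
  fit_sida_impl(data, networks = NULL, kappa = 0, lambda_grid = lambda_grid,
                folds = folds, balance = balance,
                with_covariates = with_covariates, seed = seed)
}

#' Cross-validated SIDA with prior network structure
#'
#' Identical to [fit_sida()] except that each view's nonsparse update solves
#' the generalized eigenproblem `A_d g = eta (I + kappa * L_d) g`, with `L_d`
#' the normalized Laplacian of the view's variable-variable network. This
#' shrinks directions that vary across connected variables, encouraging the
#' selection of connected, similarly-behaving predictors. `kappa = 0` or
#' empty networks reproduce [fit_sida()] exactly.
#'
#' @inheritParams fit_sida
#' @param networks List of [variable_network()] objects (or `NULL` entries),
#'   one per view, with dimensions matching each view's feature count.
#' @param kappa Nonnegative Laplacian weight (default 1).
#' @export
fit_sidanet <- function(data, networks, kappa = 1, lambda_grid = NULL,
                        folds = 5, balance = 0.5, with_covariates = FALSE,
                        seed = 1234) {
  fit_sida_impl(data, networks = networks, kappa = kappa,
                lambda_grid = lambda_grid, folds = folds, balance = balance,
                with_covariates = with_covariates, seed = seed)
}

fit_sida_impl <- function(data, networks, kappa, lambda_grid, folds, balance,
                          with_covariates, seed) {
  stopifnot(inherits(data, "mvdata"), balance > 0, balance <= 1)
  D <- length(data$views)
  if (D < 2) stop("SIDA requires at least 2 views")
  if (is.null(data$outcome) || !data$outcome$kind %in% c("binary", "multiclass")) {
    stop("SIDA requires a binary or multiclass outcome")
  }
  cls <- factor(outcome_classes(data$outcome))
  K <- nlevels(cls)
  q <- max(K - 1L, 1L)
  n <- n_samples(data)
  if (n < 2 * folds) stop("need n >= 2 * folds samples for ", folds, "-fold CV")

  Xlist <- data$views
  view_names <- data$view_names
  penalize <- rep(TRUE, D)
  if (with_covariates) {
    if (is.null(data$covariates)) stop("with_covariates = TRUE but data has no covariates")
    Xlist <- c(Xlist, list(data$covariates))
    view_names <- c(view_names, "covariates")
    penalize <- c(penalize, FALSE)
  }
  Dall <- length(Xlist)

  # Laplacian transforms (NULL when kappa * L is identically zero, so the
  # plain-eigen code path is taken and kappa = 0 reproduces fit_sida exactly)
  Binvhalf <- vector("list", Dall)
  if (!is.null(networks) && kappa > 0) {
    for (d in seq_len(D)) {
      nw <- networks[[d]]
      if (is.null(nw)) next
      stopifnot(inherits(nw, "variable_network"))
      L <- nw$normalized_laplacian
      if (nrow(L) != ncol(Xlist[[d]])) {
        stop("network for view '", view_names[d], "' has dimension ",
             nrow(L), ", expected ", ncol(Xlist[[d]]))
      }
      if (all(L == 0)) next
      eg <- eigen(diag(nrow(L)) + kappa * L, symmetric = TRUE)
      Binvhalf[[d]] <- eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
    }
  }

  means <- lapply(Xlist, colMeans)
  Xc <- mapply(function(X, m) sweep(X, 2, m, "-"), Xlist, means, SIMPLIFY = FALSE)

  # --- cross-validation over lambda -------------------------------------------
  foldid <- stratified_folds(cls, folds, seed)
  pre_full <- sida_precompute(Xc, cls, q)
  grids <- lapply(seq_len(Dall), function(d) {
    if (!penalize[d]) return(0)
    if (!is.null(lambda_grid)) sort(lambda_grid[[min(d, length(lambda_grid))]])
    else auto_lambda_grid(pre_full, balance, d)
  })
  pen_idx <- which(penalize)
  candidates <- if (length(pen_idx) == 2) {
    expand.grid(grids[[pen_idx[1]]], grids[[pen_idx[2]]])
  } else {
    # shared threshold across penalized views
    data.frame(matrix(rep(grids[[pen_idx[1]]], length(pen_idx)),
                      ncol = length(pen_idx)))
  }

  fold_pre <- lapply(seq_len(folds), function(f) {
    tr <- foldid != f
    m <- lapply(Xlist, function(X) colMeans(X[tr, , drop = FALSE]))
    Xtr <- mapply(function(X, mm) sweep(X[tr, , drop = FALSE], 2, mm, "-"),
                  Xlist, m, SIMPLIFY = FALSE)
    Xte <- mapply(function(X, mm) sweep(X[!tr, , drop = FALSE], 2, mm, "-"),
                  Xlist, m, SIMPLIFY = FALSE)
    list(pre = sida_precompute(Xtr, droplevels(cls[tr]), q),
         Xtr = Xtr, Xte = Xte, cls_tr = cls[tr], cls_te = cls[!tr])
  })

  cv_err <- rep(Inf, nrow(candidates))
  cv_se <- rep(NA_real_, nrow(candidates))
  for (ci in seq_len(nrow(candidates))) {
    lam <- numeric(Dall)
    lam[pen_idx] <- as.numeric(candidates[ci, ])
    errs <- numeric(folds)
    bad <- FALSE
    for (f in seq_len(folds)) {
      fp <- fold_pre[[f]]
      fit <- sida_core(fp$pre, balance, lam, Binvhalf, penalize)
      if (is.null(fit)) { bad <- TRUE; break }
      cen <- sida_centroids(fp$Xtr, fit$Gamma, fp$cls_tr)
      sc_te <- lapply(seq_len(Dall), function(d) fp$Xte[[d]] %*% fit$Gamma[[d]])
      pred <- nearest_centroid(sc_te, cen, levels(cls))
      errs[f] <- mean(pred != as.character(fp$cls_te))
    }
    if (!bad) {
      cv_err[ci] <- mean(errs)
      cv_se[ci] <- stats::sd(errs) / sqrt(folds)
    }
  }
  if (all(!is.finite(cv_err))) {
    stop("every candidate threshold emptied a view's support; supply a smaller lambda_grid")
  }
  # one-standard-error rule: among thresholds within 1 SE of the smallest CV
  # error, prefer the sparsest (largest total threshold); if the winner
  # empties a support on the full-data refit, fall back to the next candidate
  in_band <- which(cv_err <= min(cv_err) + cv_se[which.min(cv_err)])
  in_band <- in_band[order(rowSums(candidates[in_band, , drop = FALSE]),
                           decreasing = TRUE)]
  rest <- setdiff(which(is.finite(cv_err)), in_band)
  rest <- rest[order(cv_err[rest],
                     -rowSums(candidates[rest, , drop = FALSE]))]
  fit <- NULL
  optLambda <- numeric(Dall)
  for (ci in c(in_band, rest)) {
    optLambda[pen_idx] <- as.numeric(candidates[ci, ])
    fit <- sida_core(pre_full, balance, optLambda, Binvhalf, penalize,
                     warn_cap = TRUE)
    if (!is.null(fit)) { best <- ci; break }
  }
  if (is.null(fit)) stop("every candidate threshold emptied a support on the full data")
  for (d in seq_len(Dall)) rownames(fit$Gamma[[d]]) <- colnames(Xlist[[d]])
  scores <- lapply(seq_len(Dall), function(d) {
    s <- Xc[[d]] %*% fit$Gamma[[d]]
    rownames(s) <- data$sample_ids
    s
  })
  centroids <- sida_centroids(Xc, fit$Gamma, cls)
  pred_train <- nearest_centroid(scores, centroids, levels(cls))
  train_error <- mean(pred_train != as.character(cls))
  pairs <- utils::combn(seq_len(Dall), 2)
  train_correlation <- mean(apply(pairs, 2, function(pr) {
    abs_cor(scores[[pr[1]]][, 1], scores[[pr[2]]][, 1])
  }))

  model <- list(
    hatalpha = stats::setNames(fit$Gamma, view_names),
    optLambda = stats::setNames(optLambda, view_names),
    balance = balance, kappa = kappa,
    train_scores = stats::setNames(scores, view_names),
    centroids = stats::setNames(centroids, view_names),
    train_correlation = train_correlation, train_error = train_error,
    cv_error = min(cv_err),
    class_labels = levels(cls),
    nonzero = vapply(fit$Gamma, function(G) sum(rowSums(G != 0) > 0), 0L),
    preprocessing = list(means = means),
    feature_names = lapply(Xlist, colnames),
    view_names = view_names, q = q, D = Dall,
    with_covariates = with_covariates,
    convergence = list(iterations = fit$iterations, converged = fit$converged,
                       objective = fit$objective)
  )
  class(model) <- "sida_model"
  model
}

#' @export
print.sida_model <- function(x, ...) {
  cat(sprintf("<sida_model> %d views, %d classes, q = %d\n",
              x$D, length(x$class_labels), x$q))
  cat(sprintf("  train error = %.3f, train correlation = %.3f\n",
              x$train_error, x$train_correlation))
  cat("  nonzero variables:",
      paste(sprintf("%s = %d", x$view_names, x$nonzero), collapse = ", "), "\n")
  invisible(x)
}

#' Classify new samples with a fitted SIDA model
#'
#' Centers each new view with the training means, projects onto the
#' discriminant loadings, and assigns each sample to the class whose training
#' centroid is nearest in the summed squared distance across views. Ties go
#' to the lowest class label.
#'
#' @param model A `sida_model`.
#' @param new_views List of matrices (one per view, in model order) or an
#'   `mvdata`; feature sets must match the training views.
#' @param covariates Covariate matrix, required when the model was fitted
#'   `with_covariates` and `new_views` is a plain list.
#' @return List with `labels` (predicted classes) and `scores` (per-view
#'   discriminant score matrices).
#' @export
classify_sida <- function(model, new_views, covariates = NULL) {
  stopifnot(inherits(model, "sida_model"))
  if (inherits(new_views, "mvdata")) {
    covariates <- covariates %||% new_views$covariates
    new_views <- new_views$views
  }
  if (model$with_covariates) {
    if (is.null(covariates)) stop("model was fitted with covariates; supply them")
    new_views <- c(new_views, list(covariates))
  }
  if (length(new_views) != model$D) {
    stop("model has ", model$D, " view(s); got ", length(new_views))
  }
  scores <- lapply(seq_len(model$D), function(d) {
    X <- as.matrix(new_views[[d]])
    want <- model$feature_names[[d]]
    if (!is.null(colnames(X))) {
      missing <- setdiff(want, colnames(X))
      if (length(missing) > 0) {
        stop("view ", d, " lacks feature(s): ",
             paste(utils::head(missing, 5), collapse = ", "))
      }
      X <- X[, want, drop = FALSE]
    } else if (ncol(X) != length(want)) {
      stop("view ", d, " has ", ncol(X), " columns; expected ", length(want))
    }
    sweep(X, 2, model$preprocessing$means[[d]], "-") %*% model$hatalpha[[d]]
  })
  labels <- nearest_centroid(scores, model$centroids, model$class_labels)
  list(labels = labels, scores = stats::setNames(scores, model$view_names))
}
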