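# Synthetic multiview generators with analytically known ground truth. The
# two-view generator is a rank-1 latent-factor model whose population first
# canonical correlation is 1/(1 + sigma2); the multiclass generator plants
# class-mean separation and a shared latent factor along the same sparse
# per-view direction, giving a closed-form per-view Bayes error for two
# classes. These stand in for bundled example fixtures: they emulate sparse
# association/discrimination structure, not omics marginals.

#' Two-view latent-factor data with sparse canonical directions
#'
#' Draws a latent factor `Z ~ N(0, 1)` per sample and sets
#' `X_d = Z w_d' + E_d`, where `w_d` is the unit vector with equal weights
#' `1/sqrt(s_d)` on the first `s_d` features and `E_d` has independent
#' `N(0, sigma2)` entries. The population first canonical correlation is
#' `rho* = 1/(1 + sigma2)` and the true supports are the first `s_d` feature
#' indices of each view. A binary outcome `1(Z + noise > 0)` is attached for
#' downstream prediction tests.
#'
#' @param n Number of samples.
#' @param p1,p2 Features per view.
#' @param s1,s2 Support sizes (`s_d <= p_d`).
#' @param sigma2 Noise variance (> 0). Default 0.25, giving `rho* = 0.8`.
#' @param seed Integer seed; the output is a pure function of the arguments.
#' @param random_weights Use random (still unit-norm, support-restricted)
#'   weights instead of equal weights? Default `FALSE`.
#' @return List with `data` (an `mvdata` with views `X1`, `X2` and a binary
#'   outcome) and `truth` (list: `support1`, `support2`, `rho_star`, `w1`,
#'   `w2`, `sigma2`, `seed`).
#' @export
generate_selp_data <- function(n = 500, p1 = 100, p2 = 100, s1 = 10, s2 = 10,
                               sigma2 = 0.25, seed = 1234,
                               random_weights = FALSE) {
  stopifnot(s1 <= p1, s2 <= p2, s1 >= 1, s2 >= 1, sigma2 > 0, n >= 2)
  with_seed(seed, {
    w1 <- numeric(p1); w2 <- numeric(p2)
    if (random_weights) {
      w1[seq_len(s1)] <- stats::rnorm(s1)
      w2[seq_len(s2)] <- stats::rnorm(s2)
      w1 <- w1 / sqrt(sum(w1^2)); w2 <- w2 / sqrt(sum(w2^2))
    } else {
      w1[seq_len(s1)] <- 1 / sqrt(s1)
      w2[seq_len(s2)] <- 1 / sqrt(s2)
    }
    Z <- stats::rnorm(n)
    X1 <- tcrossprod(Z, w1) + matrix(stats::rnorm(n * p1, sd = sqrt(sigma2)), n, p1)
    X2 <- tcrossprod(Z, w2) + matrix(stats::rnorm(n * p2, sd = sqrt(sigma2)), n, p2)
    ids <- sprintf("s%04d", seq_len(n))
    dimnames(X1) <- list(ids, sprintf("x1_%03d", seq_len(p1)))
    dimnames(X2) <- list(ids, sprintf("x2_%03d", seq_len(p2)))
    y <- as.integer(Z + stats::rnorm(n, sd = sqrt(sigma2)) > 0)
    data <- multiview_data(list(X1 = X1, X2 = X2),
                           outcome = mv_outcome(y, kind = "binary"))
    truth <- list(support1 = seq_len(s1), support2 = seq_len(s2),
                  rho_star = 1 / (1 + sigma2), w1 = w1, w2 = w2,
                  sigma2 = sigma2, seed = seed)
    list(data = data, truth = truth)
  })
}

#' Multiclass multiview data with sparse discriminant directions
#'
#' For `D` views and `K` classes, the class-`k` mean in view `d` is
#' `delta_k u_d` with `u_d` the equal-weight unit vector on the first `s_d`
#' features and `delta_k = (k - (K+1)/2) * delta`. A shared per-sample latent
#' factor `Z ~ N(0, 1)` adds `psi * Z * u_d'` to every view (the cross-view
#' association), and independent `N(0, sigma2)` noise is added throughout.
#' For `K = 2` the per-view Bayes error along `u_d` is
#' `pnorm(-delta / (2 * sqrt(psi^2 + sigma2)))`, and the population
#' correlation between two views' projections on their `u_d` is
#' `psi^2 / (psi^2 + sigma2)` (within class).
#'
#' @param n_per_class Samples per class.
#' @param K Number of classes (>= 2).
#' @param D Number of views.
#' @param p,s Integer vectors (recycled to length `D`): features and support
#'   sizes per view.
#' @param delta Class-mean separation step.
#' @param psi Shared-latent strength (association signal).
#' @param sigma2 Noise variance.
#' @param seed Integer seed.
#' @return List with `data` (an `mvdata` with a binary or multiclass outcome)
#'   and `truth` (supports, `delta`, `psi`, `sigma2`, per-view two-class
#'   `bayes_error`, `seed`).
#' @export
generate_sida_data <- function(n_per_class = 100, K = 2, D = 2, p = 50,
                               s = 10, delta = 2, psi = 1, sigma2 = 1,
                               seed = 1234) {
  stopifnot(K >= 2, D >= 2, sigma2 > 0)
  p <- rep_len(p, D); s <- rep_len(s, D)
  stopifnot(all(s <= p), all(s >= 1))
  n <- n_per_class * K
  with_seed(seed, {
    cls <- rep(seq_len(K), each = n_per_class)
    deltas <- (seq_len(K) - (K + 1) / 2) * delta
    Z <- stats::rnorm(n)
    ids <- sprintf("s%04d", seq_len(n))
    views <- vector("list", D)
    supports <- vector("list", D)
    for (d in seq_len(D)) {
      u <- numeric(p[d])
      u[seq_len(s[d])] <- 1 / sqrt(s[d])
      supports[[d]] <- seq_len(s[d])
      X <- tcrossprod(deltas[cls] + psi * Z, u) +
        matrix(stats::rnorm(n * p[d], sd = sqrt(sigma2)), n, p[d])
      dimnames(X) <- list(ids, sprintf("v%d_%03d", d, seq_len(p[d])))
      views[[d]] <- X
    }
    names(views) <- paste0("View", seq_len(D))
    outcome <- mv_outcome(cls, kind = if (K == 2) "binary" else "multiclass")
    data <- multiview_data(views, outcome = outcome)
    truth <- list(supports = supports, delta = delta, psi = psi,
                  sigma2 = sigma2,
                  bayes_error = if (K == 2)
                    stats::pnorm(-delta / (2 * sqrt(psi^2 + sigma2))) else NA_real_,
                  assoc_correlation = psi^2 / (psi^2 + sigma2),
                  seed = seed)
    list(data = data, truth = truth)
  })
}

#' Random variable network covering a given support
#'
#' Builds a connected subgraph (a path backbone plus random chords) on the
#' support indices, plus `extra_edges` random edges among the remaining
#' variables — a fixture for the network-structured discriminant fit.
#'
#' @param p Number of variables.
#' @param support Integer indices of the true support.
#' @param extra_edges Random edges among non-support variables (default 0).
#' @param chords Random extra edges within the support (default
#'   `length(support)`).
#' @param seed Integer seed.
#' @param feature_names,view_name Passed to [variable_network()].
#' @return A `variable_network`.
#' @export
generate_network_for_support <- function(p, support, extra_edges = 0,
                                         chords = length(support), seed = 1234,
                                         feature_names = NULL,
                                         view_name = "view") {
  stopifnot(all(support >= 1), all(support <= p))
  with_seed(seed, {
    A <- matrix(0, p, p)
    s <- length(support)
    if (s >= 2) {
      for (i in seq_len(s - 1)) { # path backbone
        A[support[i], support[i + 1]] <- A[support[i + 1], support[i]] <- 1
      }
      for (e in seq_len(chords)) {
        pick <- sample(support, 2)
        A[pick[1], pick[2]] <- A[pick[2], pick[1]] <- 1
      }
    }
    rest <- setdiff(seq_len(p), support)
    if (extra_edges > 0 && length(rest) >= 2) {
      for (e in seq_len(extra_edges)) {
        pick <- sample(rest, 2)
        A[pick[1], pick[2]] <- A[pick[2], pick[1]] <- 1
      }
    }
    diag(A) <- 0
    variable_network(A, feature_names = feature_names, view_name = view_name)
  })
}

#' Survival outcome generated from linear scores
#'
#' Event times are exponential with rate `exp(scores %*% beta)`; independent
#' exponential censoring is calibrated so the expected censored fraction is
#' approximately `censor_rate` (the censoring rate is tuned numerically on
#' the realized linear predictors).
#'
#' @param scores Numeric matrix (or vector) of predictors.
#' @param beta Coefficient vector.
#' @param censor_rate Target fraction censored, in \[0, 1).
#' @param seed Integer seed.
#' @return An [mv_outcome()] of kind `"survival"`.
#' @export
generate_survival_from_scores <- function(scores, beta, censor_rate = 0.2,
                                          seed = 1234) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == length(beta), censor_rate >= 0, censor_rate < 1)
  with_seed(seed, {
    rate <- exp(drop(scores %*% beta))
    n <- length(rate)
    t_event <- stats::rexp(n, rate = rate)
    if (censor_rate == 0) {
      return(mv_outcome(kind = "survival", time = t_event, event = rep(1, n)))
    }
    # P(censored) = E[ c / (c + rate) ] for censoring rate c; solve for c
    f <- function(cr) mean(cr / (cr + rate)) - censor_rate
    cr <- stats::uniroot(f, c(1e-8, 1e8))$root
    t_cens <- stats::rexp(n, rate = cr)
    mv_outcome(kind = "survival",
               time = pmin(t_event, t_cens),
               event = as.numeric(t_event <= t_cens))
  })
}
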