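# Per-view preprocessing and feature filtering. Transforms and filter
# statistics are always estimated on training data; `apply_filter()` carries
# them to new data without re-estimation.

# ---- preprocessing -----------------------------------------------------------

#' Preprocess a view
#'
#' Optional log2 transform (as `log2(x + 1)`, tolerating zeros in count-like
#' data), centering to mean zero, scaling to unit variance, or normalization
#' (centering + scaling). When `train_params` is supplied the stored training
#' means/variances are applied verbatim — nothing is re-estimated — so test
#' columns generally have nonzero means after the mapping; that is the
#' contract, not a bug.
#'
#' @param view Numeric matrix, samples x features.
#' @param log2 Apply `log2(x + 1)`? Requires all values > -1.
#' @param center Subtract column means (training means when `train_params`
#'   given).
#' @param scale Divide by column standard deviations.
#' @param normalize Shorthand for `center = TRUE, scale = TRUE`.
#' @param zero_var One of `"error"` (default) or `"drop"`: what to do with
#'   zero-variance columns when scaling.
#' @param train_params Transform record from a previous call, to apply a
#'   training mapping to new data.
#' @return A list with `matrix` (transformed data) and `params` (the transform
#'   record: flags plus the means/sds used).
#' @export
preprocess <- function(view, log2 = FALSE, center = FALSE, scale = FALSE,
                       normalize = FALSE, zero_var = c("error", "drop"),
                       train_params = NULL) {
  zero_var <- match.arg(zero_var)
  view <- as.matrix(view)
  if (!is.null(train_params)) {
    p <- train_params
    if (p$log2) {
      if (any(view <= -1)) stop("log2 transform requires all values > -1")
      view <- base::log2(view + 1)
    }
    keep <- colnames(view)
    if (!is.null(p$kept_features)) {
      missing <- setdiff(p$kept_features, colnames(view))
      if (length(missing) > 0) {
        stop("new data lacks feature(s): ", paste(missing, collapse = ", "))
      }
      view <- view[, p$kept_features, drop = FALSE]
    }
    if (p$center) view <- sweep(view, 2, p$means, "-")
    if (p$scale) view <- sweep(view, 2, p$sds, "/")
    return(list(matrix = view, params = p))
  }
  if (normalize) center <- scale <- TRUE
  if (log2) {
    if (any(view <= -1)) stop("log2 transform requires all values > -1")
    view <- base::log2(view + 1)
  }
  params <- list(log2 = log2, center = center, scale = scale,
                 means = NULL, sds = NULL, kept_features = NULL)
  if (scale) {
    sds <- apply(view, 2, stats::sd)
    zv <- which(sds == 0 | !is.finite(sds))
    if (length(zv) > 0) {
      if (zero_var == "error") {
        stop("zero-variance column(s) under scaling: ",
             paste(colnames(view)[zv], collapse = ", "))
      }
      warning("dropping ", length(zv), " zero-variance column(s)")
      view <- view[, -zv, drop = FALSE]
      sds <- sds[-zv]
      params$kept_features <- colnames(view)
    }
    params$sds <- sds
  }
  if (center) {
    params$means <- colMeans(view)
    view <- sweep(view, 2, params$means, "-")
  }
  if (scale) view <- sweep(view, 2, params$sds, "/")
  list(matrix = view, params = params)
}

# ---- p-value adjustment ------------------------------------------------------

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up (`"BH"`), Bonferroni, or no adjustment. BH is
#' computed directly: on sorted p-values, `q_(i) = min_(j >= i)
#' min(1, m p_(j) / j)`, mapped back to the original order.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs pass through).
#' @param method `"BH"`, `"bonferroni"`, or `"none"`.
#' @return Vector of adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni", "none")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  if (method == "none") return(p)
  m <- sum(ok)
  out <- p
  if (method == "bonferroni") {
    out[ok] <- pmin(1, m * p[ok])
    return(out)
  }
  ord <- order(p[ok])
  ps <- p[ok][ord]
  q <- rev(cummin(rev(pmin(1, m * ps / seq_len(m)))))
  adj <- numeric(m)
  adj[ord] <- q
  out[ok] <- adj
  out
}

# ---- supervised filtering ----------------------------------------------------

welch_row <- function(x, g1, g2) {
  x1 <- x[g1]; x2 <- x[g2]
  v1 <- stats::var(x1); v2 <- stats::var(x2)
  se2 <- v1 / length(x1) + v2 / length(x2)
  if (se2 == 0) return(c(stat = 0, p = 1))
  tt <- tryCatch(stats::t.test(x1, x2), error = function(e) NULL)
  if (is.null(tt)) return(c(stat = 0, p = 1))
  c(stat = unname(tt$statistic), p = tt$p.value)
}

#' Supervised (outcome-associated) feature filtering
#'
#' Tests each feature individually against the outcome: `"linear"` — slope
#' test in a simple linear regression of the outcome on the feature
#' (continuous outcomes); `"logistic"` — Wald z-test of the feature's
#' log-odds coefficient in a single-predictor logistic regression (binary);
#' `"ttest"` — Welch two-sample t (binary); `"kw"` — Kruskal-Wallis rank test
#' (two or more groups). The effect column holds the regression coefficient
#' (linear/logistic) or the group2 - group1 mean difference (ttest/kw; equal
#' to the log2 fold change when the matrix is on the log2 scale). Features are
#' kept when their (adjusted) p-value is at most `alpha`.
#'
#' A logistic fit that fails to converge (e.g. perfect separation) flags the
#' feature, records a missing p-value and excludes it from the kept set, with
#' a warning.
#'
#' @param view Numeric matrix, samples x features (training data).
#' @param outcome An [mv_outcome()] compatible with `method`.
#' @param method One of `"linear"`, `"logistic"`, `"ttest"`, `"kw"`.
#' @param padjust Adjust p-values before thresholding? Default `TRUE`.
#' @param adjmethod Adjustment method, see [adjust_pvalues()]; default `"BH"`.
#' @param alpha Significance threshold, default `0.05`.
#' @param view_name Label stored in the result.
#' @param transform_record Optional preprocessing record to carry along (so
#'   [apply_filter()] can replay the training transform).
#' @return A `filter_result`: a list with `table` (data.frame: name,
#'   statistic, effect, p_value, p_adjusted, keep), plus the method, alpha and
#'   transform record.
#' @export
supervised_filter <- function(view, outcome,
                              method = c("linear", "logistic", "ttest", "kw"),
                              padjust = TRUE, adjmethod = "BH", alpha = 0.05,
                              view_name = "view", transform_record = NULL) {
  method <- match.arg(method)
  view <- as.matrix(view)
  p <- ncol(view)
  if (is.null(colnames(view))) colnames(view) <- paste0("f", seq_len(p))
  stopifnot(inherits(outcome, "mv_outcome"))
  kinds_ok <- switch(method,
    linear = "continuous", logistic = "binary",
    ttest = "binary", kw = c("binary", "multiclass"))
  if (!outcome$kind %in% kinds_ok) {
    stop("method '", method, "' requires a ", paste(kinds_ok, collapse = "/"),
         " outcome, got ", outcome$kind)
  }
  stat <- effect <- pval <- rep(NA_real_, p)
  failed <- logical(p)
  if (method == "linear") {
    y <- as.numeric(outcome$values)
    for (j in seq_len(p)) {
      x <- view[, j]
      if (stats::var(x) == 0) { stat[j] <- 0; effect[j] <- 0; pval[j] <- 1; next }
      fit <- stats::lm(y ~ x)
      co <- summary(fit)$coefficients
      if (nrow(co) < 2) { stat[j] <- 0; effect[j] <- 0; pval[j] <- 1; next }
      stat[j] <- co[2, 3]; effect[j] <- co[2, 1]; pval[j] <- co[2, 4]
    }
  } else if (method == "logistic") {
    y <- as.integer(factor(outcome$values)) - 1L
    for (j in seq_len(p)) {
      x <- view[, j]
      if (stats::var(x) == 0) { stat[j] <- 0; effect[j] <- 0; pval[j] <- 1; next }
      # perfect separation: the two classes occupy disjoint feature ranges,
      # so the log-odds coefficient diverges (glm converges silently)
      if (max(x[y == 0]) < min(x[y == 1]) || max(x[y == 1]) < min(x[y == 0])) {
        failed[j] <- TRUE; next
      }
      sep <- FALSE
      fit <- withCallingHandlers(
        stats::glm(y ~ x, family = stats::binomial(), control = list(maxit = 100)),
        warning = function(w) {
          # glm signals quasi-separation as fitted probabilities of 0/1
          if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
            sep <<- TRUE
          }
          invokeRestart("muffleWarning")
        })
      sep <- sep || !fit$converged
      if (sep) { failed[j] <- TRUE; next }
      co <- summary(fit)$coefficients
      stat[j] <- co[2, 3]; effect[j] <- co[2, 1]; pval[j] <- co[2, 4]
    }
    if (any(failed)) {
      warning(sum(failed), " feature(s) with non-converged/separated logistic ",
              "fit excluded: ",
              paste(utils::head(colnames(view)[failed], 5), collapse = ", "))
    }
  } else {
    cls <- factor(outcome_classes(outcome))
    lev <- levels(cls)
    if (method == "ttest") {
      if (length(lev) != 2) stop("ttest requires exactly 2 groups")
      if (min(table(cls)) < 3) stop("ttest requires >= 3 samples per group")
      g1 <- cls == lev[1]; g2 <- cls == lev[2]
      for (j in seq_len(p)) {
        r <- welch_row(view[, j], g1, g2)
        stat[j] <- r["stat"]; pval[j] <- r["p"]
        effect[j] <- mean(view[g2, j]) - mean(view[g1, j])
      }
    } else { # kw
      for (j in seq_len(p)) {
        x <- view[, j]
        if (stats::var(x) == 0) { stat[j] <- 0; pval[j] <- 1 } else {
          kt <- stats::kruskal.test(x, cls)
          stat[j] <- unname(kt$statistic); pval[j] <- kt$p.value
        }
        effect[j] <- if (length(lev) == 2) {
          mean(x[cls == lev[2]]) - mean(x[cls == lev[1]])
        } else NA_real_
      }
    }
  }
  padj <- if (padjust) adjust_pvalues(pval, adjmethod) else rep(NA_real_, p)
  crit <- if (padjust) padj else pval
  keep <- !is.na(crit) & crit <= alpha & !failed
  res <- list(
    view_name = view_name, method = method,
    table = data.frame(name = colnames(view), statistic = stat,
                       effect = effect, p_value = pval, p_adjusted = padj,
                       keep = keep, stringsAsFactors = FALSE),
    padjust = padjust, adjmethod = if (padjust) adjmethod else "none",
    alpha = alpha, transform_record = transform_record
  )
  class(res) <- "filter_result"
  res
}

# ---- unsupervised filtering --------------------------------------------------

#' Unsupervised (variance / IQR) feature filtering
#'
#' Ranks features by sample variance or interquartile range (descending; IQR
#' uses linear-interpolation type-7 quartiles) and keeps the top
#' `ceiling(keep_fraction * p)`. Ties are broken by original column order.
#'
#' @inheritParams supervised_filter
#' @param method `"variance"` or `"iqr"`.
#' @param keep_fraction Fraction of features to keep, in (0, 1\].
#' @return A `filter_result` (statistic column holds the ranking criterion;
#'   effect and p-value columns are NA).
#' @export
unsupervised_filter <- function(view, method = c("variance", "iqr"),
                                keep_fraction = 0.5, view_name = "view",
                                transform_record = NULL) {
  method <- match.arg(method)
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  view <- as.matrix(view)
  p <- ncol(view)
  if (is.null(colnames(view))) colnames(view) <- paste0("f", seq_len(p))
  stat <- if (method == "variance") {
    apply(view, 2, stats::var)
  } else {
    apply(view, 2, function(x) {
      q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
      q[2] - q[1]
    })
  }
  if (all(stat == 0)) warning("all features are constant; keeping leading columns")
  n_keep <- ceiling(keep_fraction * p)
  ord <- order(-stat, seq_len(p)) # descending, ties by column order
  keep <- logical(p)
  keep[ord[seq_len(n_keep)]] <- TRUE
  res <- list(
    view_name = view_name, method = method,
    table = data.frame(name = colnames(view), statistic = stat,
                       effect = NA_real_, p_value = NA_real_,
                       p_adjusted = NA_real_, keep = keep,
                       stringsAsFactors = FALSE),
    padjust = FALSE, adjmethod = "none", keep_fraction = keep_fraction,
    transform_record = transform_record
  )
  class(res) <- "filter_result"
  res
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter_result> view '%s', method %s: %d / %d features kept\n",
              x$view_name, x$method, sum(x$table$keep), nrow(x$table)))
  invisible(x)
}

#' Kept feature names of a filter result
#' @param result A `filter_result`.
#' @return Character vector, in training kept-order.
#' @export
kept_features <- function(result) {
  stopifnot(inherits(result, "filter_result"))
  result$table$name[result$table$keep]
}

#' Apply a training filter (and transform) to new data
#'
#' Restricts a test matrix to the features kept on the training data, in the
#' training kept-order, and replays the training transform record (if any).
#' Extra test features are dropped silently; a missing kept feature is an
#' error.
#'
#' @param test_view Numeric matrix, samples x features.
#' @param result A `filter_result` from training data.
#' @return The filtered (and transformed) test matrix.
#' @export
apply_filter <- function(test_view, result) {
  stopifnot(inherits(result, "filter_result"))
  test_view <- as.matrix(test_view)
  if (!is.null(result$transform_record)) {
    test_view <- preprocess(test_view, train_params = result$transform_record)$matrix
  }
  kept <- kept_features(result)
  missing <- setdiff(kept, colnames(test_view))
  if (length(missing) > 0) {
    stop("test data lacks kept feature(s): ", paste(missing, collapse = ", "))
  }
  test_view[, kept, drop = FALSE]
}
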