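# Outcome prediction from canonical variates: a GLM with the canonical link
# (gaussian/binomial/poisson) or a Cox proportional-hazards model (survival),
# fit on the scores U_1..U_K, V_1..V_K plus optional unpenalized covariates.

score_frame <- function(scores, covariates = NULL) {
  if (inherits(scores, "selpcca_model")) scores <- scores$train_scores
  if (is.matrix(scores) || is.numeric(scores)) scores <- list(U = scores)
  U <- as.matrix(scores$U)
  df <- data.frame(U)
  colnames(df) <- paste0("U", seq_len(ncol(U)))
  if (!is.null(scores$V)) {
    V <- as.matrix(scores$V)
    df <- cbind(df, stats::setNames(data.frame(V), paste0("V", seq_len(ncol(V)))))
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    }
    df <- cbind(df, as.data.frame(covariates))
  }
  df
}

#' Fit an outcome model on canonical variates
#'
#' Regresses the outcome on the canonical scores of both views (and optional
#' covariates, entered unpenalized): a maximum-likelihood GLM with the
#' canonical link for `family` `"gaussian"` (identity), `"binomial"` (logit)
#' or `"poisson"` (log), or a Cox proportional-hazards model (Efron tie
#' handling, no intercept) for `"survival"`.
#'
#' @param scores A list with matrices `U` and `V` (n x K each) as returned by
#'   [transform_scores()], or a fitted `selpcca_model` (its training scores
#'   are used).
#' @param outcome An [mv_outcome()] compatible with the family.
#' @param family `"gaussian"`, `"binomial"`, `"poisson"` or `"survival"`.
#' @param covariates Optional numeric matrix of covariates.
#' @return An `outcome_model`: list with `family`, `coefficients` (data.frame:
#'   term, estimate, std_error, statistic, p_value), the underlying `fit`, and
#'   the term names.
#' @export
fit_outcome_model <- function(scores, outcome,
                              family = c("gaussian", "binomial", "poisson", "survival"),
                              covariates = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(outcome, "mv_outcome"))
  ok <- switch(family,
    gaussian = outcome$kind == "continuous",
    binomial = outcome$kind == "binary",
    poisson = outcome$kind %in% c("count", "continuous"),
    survival = outcome$kind == "survival")
  if (!ok) stop("family '", family, "' is incompatible with a ", outcome$kind, " outcome")
  df <- score_frame(scores, covariates)
  if (nrow(df) <= ncol(df) + (family != "survival")) {
    stop("need more samples than model terms")
  }
  terms <- colnames(df)
  if (family == "survival") {
    df$.time <- outcome$time
    df$.event <- outcome$event
    fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                   paste(terms, collapse = " + ")))
    fit <- survival::coxph(fml, data = df, ties = "efron")
    co <- summary(fit)$coefficients
    coef_table <- data.frame(term = rownames(co), estimate = co[, "coef"],
                             std_error = co[, "se(coef)"], statistic = co[, "z"],
                             p_value = co[, "Pr(>|z|)"], row.names = NULL,
                             stringsAsFactors = FALSE)
  } else {
    y <- if (family == "binomial") as.integer(factor(outcome$values)) - 1L
         else as.numeric(outcome$values)
    df$.y <- y
    fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
    fit <- stats::glm(fml, data = df, family = switch(family,
      gaussian = stats::gaussian(), binomial = stats::binomial(),
      poisson = stats::poisson()))
    if (family != "gaussian" && !fit$converged) {
      warning("GLM did not converge (possible separation); ",
              "coefficients returned as-is")
    }
    co <- summary(fit)$coefficients
    coef_table <- data.frame(term = rownames(co), estimate = co[, 1],
                             std_error = co[, 2], statistic = co[, 3],
                             p_value = co[, 4], row.names = NULL,
                             stringsAsFactors = FALSE)
  }
  model <- list(family = family, coefficients = coef_table, fit = fit,
                terms = terms,
                class_labels = if (family == "binomial")
                  levels(factor(outcome$values)) else NULL)
  class(model) <- "outcome_model"
  model
}

#' @export
print.outcome_model <- function(x, ...) {
  cat(sprintf("<outcome_model> family %s\n", x$family))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Predict from a fitted outcome model
#'
#' Returns the natural-scale prediction for each family: the linear predictor
#' for gaussian, the event probability (inverse logit) for binomial, the
#' expected count for poisson, and the linear predictor (relative log-risk)
#' for survival.
#'
#' @param model An `outcome_model`.
#' @param new_scores List with `U` and `V` matrices (e.g. from
#'   [transform_scores()]).
#' @param covariates Optional covariate matrix matching the fitted terms.
#' @return Numeric vector of predictions.
#' @export
predict_outcome <- function(model, new_scores, covariates = NULL) {
  stopifnot(inherits(model, "outcome_model"))
  df <- score_frame(new_scores, covariates)
  missing <- setdiff(model$terms, colnames(df))
  if (length(missing) > 0) {
    stop("new data lacks model term(s): ", paste(missing, collapse = ", "))
  }
  if (model$family == "survival") {
    unname(stats::predict(model$fit, newdata = df, type = "lp"))
  } else {
    unname(stats::predict(model$fit, newdata = df, type = "response"))
  }
}

#' Prediction performance metrics
#'
#' For `family = "binomial"`, labels are thresholded at probability 0.5 and
#' the report contains accuracy, sensitivity, specificity, precision,
#' negative predictive value, F1 (0 when precision and sensitivity are both
#' 0) and AUC by the rank (Mann-Whitney) formula with ties averaged. For
#' `"gaussian"`: MSE, RMSE, MAE, R-squared (1 - SSE/SST) and the Pearson
#' correlation.
#'
#' @param predicted Predicted probabilities (binomial) or values (gaussian).
#' @param truth True 0/1 labels (binomial) or numeric values (gaussian).
#' @param family `"binomial"` or `"gaussian"`.
#' @return A `performance_report` (named list of metrics).
#' @export
performance_metrics <- function(predicted, truth, family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  stopifnot(length(predicted) == length(truth))
  if (family == "gaussian") {
    err <- truth - predicted
    mse <- mean(err^2)
    sst <- sum((truth - mean(truth))^2)
    rep <- list(family = "gaussian", mse = mse, rmse = sqrt(mse),
                mae = mean(abs(err)),
                r_squared = if (sst > 0) 1 - sum(err^2) / sst else NA_real_,
                correlation = if (stats::sd(predicted) > 0 && stats::sd(truth) > 0)
                  stats::cor(predicted, truth) else NA_real_)
  } else {
    if (!all(truth %in% c(0, 1))) stop("binomial truth must be 0/1")
    lab <- as.integer(predicted >= 0.5)
    tp <- sum(lab == 1 & truth == 1); fp <- sum(lab == 1 & truth == 0)
    fn <- sum(lab == 0 & truth == 1); tn <- sum(lab == 0 & truth == 0)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
    f1 <- if (isTRUE(prec + sens > 0)) 2 * prec * sens / (prec + sens) else 0
    auc <- if (length(unique(truth)) < 2) {
      warning("AUC undefined: truth has a single class")
      NA_real_
    } else {
      r <- rank(predicted) # midranks average ties
      n1 <- sum(truth == 1); n0 <- sum(truth == 0)
      (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
    rep <- list(family = "binomial",
                accuracy = (tp + tn) / length(truth),
                sensitivity = sens, specificity = spec, precision = prec,
                npv = npv, f1 = f1, auc = auc,
                confusion = c(tp = tp, fp = fp, fn = fn, tn = tn))
  }
  class(rep) <- "performance_report"
  rep
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance_report> family %s\n", x$family))
  for (nm in setdiff(names(x), c("family", "confusion"))) {
    cat(sprintf("  %-12s %.4f\n", nm, x[[nm]]))
  }
  invisible(x)
}
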