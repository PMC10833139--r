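# ---- internal helpers --------------------------------------------------------

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- Outcome -----------------------------------------------------------------

#' Construct an outcome for a multiview dataset
#'
#' An outcome is a typed response measured on the same samples as the views.
#' Supported kinds are `"binary"`, `"multiclass"`, `"continuous"`, `"count"`
#' and `"survival"` (the last given as positive times plus a 0/1 event
#' indicator).
#'
#' @param values Length-n vector of labels or values (ignored for survival).
#' @param kind One of `"binary"`, `"multiclass"`, `"continuous"`, `"count"`,
#'   `"survival"`, or `"auto"` to guess from `values`: two distinct values are
#'   binary, up to ten distinct non-numeric or integer-valued entries are
#'   multiclass, anything else continuous.
#' @param time,event Survival time (positive) and event indicator (0/1),
#'   required when `kind = "survival"`.
#' @return An object of class `mv_outcome`.
#' @export
mv_outcome <- function(values = NULL, kind = "auto", time = NULL, event = NULL) {
  if (identical(kind, "survival") || (!is.null(time) && is.null(values))) {
    kind <- "survival"
    if (is.null(time) || is.null(event)) {
      stop("survival outcome requires `time` and `event`")
    }
    time <- as.numeric(time)
    event <- as.numeric(event)
    if (length(time) != length(event)) stop("time and event lengths differ")
    if (any(!is.finite(time)) || any(time <= 0)) {
      stop("survival times must be positive and finite")
    }
    if (!all(event %in% c(0, 1))) stop("event indicator must be 0/1")
    out <- list(kind = "survival", time = time, event = event, values = NULL)
    class(out) <- "mv_outcome"
    return(out)
  }
  if (is.null(values)) stop("`values` required for non-survival outcomes")
  if (identical(kind, "auto")) {
    u <- unique(values[!is.na(values)])
    kind <- if (length(u) == 2) {
      "binary"
    } else if (!is.numeric(values) || (length(u) <= 10 && all(values == round(values)))) {
      "multiclass"
    } else if (is.numeric(values) && all(values >= 0) && all(values == round(values))) {
      "count"
    } else {
      "continuous"
    }
  }
  if (anyNA(values)) stop("outcome contains missing values")
  nlev <- length(unique(values))
  switch(kind,
    binary = if (nlev != 2) stop("binary outcome must have exactly 2 distinct labels"),
    multiclass = if (nlev < 2) stop("multiclass outcome must have >= 2 classes"),
    continuous = if (!is.numeric(values)) stop("continuous outcome must be numeric"),
    count = {
      if (!is.numeric(values) || any(values < 0) || any(values != round(values))) {
        stop("count outcome must be non-negative integers")
      }
    },
    stop("unknown outcome kind: ", kind)
  )
  out <- list(kind = kind, values = values, time = NULL, event = NULL)
  class(out) <- "mv_outcome"
  out
}

#' @export
print.mv_outcome <- function(x, ...) {
  if (x$kind == "survival") {
    cat(sprintf("<mv_outcome> survival, n = %d, events = %d\n",
                length(x$time), sum(x$event)))
  } else {
    cat(sprintf("<mv_outcome> %s, n = %d\n", x$kind, length(x$values)))
  }
  invisible(x)
}

outcome_length <- function(outcome) {
  if (outcome$kind == "survival") length(outcome$time) else length(outcome$values)
}

# subset an outcome by sample index
outcome_subset <- function(outcome, idx) {
  if (is.null(outcome)) return(NULL)
  if (outcome$kind == "survival") {
    mv_outcome(kind = "survival", time = outcome$time[idx], event = outcome$event[idx])
  } else {
    # bypass the binary/multiclass level checks: a subset may lose a class
    out <- outcome
    out$values <- outcome$values[idx]
    out
  }
}

# class labels used for stratification / classification
outcome_classes <- function(outcome) {
  stopifnot(outcome$kind %in% c("binary", "multiclass"))
  as.character(outcome$values)
}

# ---- MultiViewData -----------------------------------------------------------

#' Assemble a multiview dataset
#'
#' Bundles two or more numeric feature matrices (samples in rows, features in
#' columns) measured on the same samples, with an optional outcome and
#' covariate matrix. Views are aligned by the intersection of their sample
#' identifiers (row names), reordered to match the first view; dropped samples
#' are reported with a warning.
#'
#' @param views List of numeric matrices (or a single matrix), each with row
#'   names (sample identifiers) and unique column names (feature names).
#' @param view_names Optional character vector naming the views; defaults to
#'   the list names or `View1`, `View2`, ...
#' @param outcome Optional [mv_outcome()]; its entries must follow the order of
#'   the first view's samples (or carry matching names).
#' @param covariates Optional numeric matrix (samples x covariates) with row
#'   names, aligned like a view.
#' @param na_action `"error"` (default) aborts on missing values; `"impute"`
#'   replaces each NA with its feature's mean.
#' @return An object of class `mvdata` with fields `views`, `view_names`,
#'   `sample_ids`, `outcome`, `covariates`.
#' @export
multiview_data <- function(views, view_names = NULL, outcome = NULL,
                           covariates = NULL, na_action = c("error", "impute")) {
  na_action <- match.arg(na_action)
  if (is.matrix(views)) views <- list(views)
  views <- lapply(views, function(v) {
    v <- as.matrix(v)
    storage.mode(v) <- "double"
    v
  })
  if (is.null(view_names)) {
    view_names <- names(views) %||% paste0("View", seq_along(views))
    if (any(view_names == "")) view_names <- paste0("View", seq_along(views))
  }
  names(views) <- view_names
  for (d in seq_along(views)) {
    v <- views[[d]]
    if (is.null(rownames(v))) stop("view '", view_names[d], "' lacks sample identifiers (row names)")
    if (is.null(colnames(v))) colnames(v) <- paste0(view_names[d], "_f", seq_len(ncol(v)))
    if (anyDuplicated(colnames(v))) {
      stop("duplicate feature names in view '", view_names[d], "': ",
           paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", "))
    }
    if (anyDuplicated(rownames(v))) stop("duplicate sample identifiers in view '", view_names[d], "'")
    views[[d]] <- v
  }
  ids <- rownames(views[[1]])
  for (d in seq_along(views)[-1]) ids <- intersect(ids, rownames(views[[d]]))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    if (is.null(rownames(covariates))) stop("covariates lack sample identifiers (row names)")
    ids <- intersect(ids, rownames(covariates))
  }
  if (length(ids) == 0) stop("no samples shared across all views (empty intersection)")
  all_ids <- unique(unlist(lapply(views, rownames)))
  dropped <- setdiff(all_ids, ids)
  if (length(dropped) > 0) {
    warning("dropped ", length(dropped), " sample(s) absent from some view: ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ..." else "")
  }
  views <- lapply(views, function(v) v[ids, , drop = FALSE])
  if (!is.null(covariates)) covariates <- covariates[ids, , drop = FALSE]

  for (d in seq_along(views)) {
    v <- views[[d]]
    if (anyNA(v) || any(!is.finite(v))) {
      if (na_action == "error") {
        bad <- which(!is.finite(v), arr.ind = TRUE)[1, ]
        stop("non-finite value in view '", view_names[d], "' at sample '",
             rownames(v)[bad[1]], "', feature '", colnames(v)[bad[2]],
             "' (use na_action = \"impute\" to mean-impute)")
      }
      for (j in seq_len(ncol(v))) {
        miss <- !is.finite(v[, j])
        if (any(miss)) v[miss, j] <- mean(v[!miss, j])
      }
      views[[d]] <- v
    }
  }
  if (!is.null(outcome)) {
    stopifnot(inherits(outcome, "mv_outcome"))
    if (outcome_length(outcome) != length(ids)) {
      stop("outcome length (", outcome_length(outcome),
           ") does not match number of aligned samples (", length(ids), ")")
    }
  }
  out <- list(views = views, view_names = view_names, sample_ids = ids,
              outcome = outcome, covariates = covariates)
  class(out) <- "mvdata"
  out
}

#' @export
print.mvdata <- function(x, ...) {
  cat(sprintf("<mvdata> %d view(s), n = %d samples\n",
              length(x$views), length(x$sample_ids)))
  for (d in seq_along(x$views)) {
    cat(sprintf("  %s: %d features\n", x$view_names[d], ncol(x$views[[d]])))
  }
  if (!is.null(x$outcome)) cat("  outcome:", x$outcome$kind, "\n")
  if (!is.null(x$covariates)) cat("  covariates:", ncol(x$covariates), "\n")
  invisible(x)
}

n_samples <- function(data) length(data$sample_ids)

# subset an mvdata by sample ids or indices
mvdata_subset <- function(data, idx) {
  if (is.character(idx)) idx <- match(idx, data$sample_ids)
  views <- lapply(data$views, function(v) v[idx, , drop = FALSE])
  multiview_data(views, view_names = data$view_names,
                 outcome = outcome_subset(data$outcome, idx),
                 covariates = if (is.null(data$covariates)) NULL else
                   data$covariates[idx, , drop = FALSE])
}

# ---- delimited-table I/O -----------------------------------------------------

read_numeric_table <- function(path, delimiter) {
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          row.names = NULL)
  if (ncol(df) < 2) stop("file '", path, "' has no feature columns")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) &
                   !is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop("non-numeric cell in '", path, "' at row ", bad[1, 1] + 1L,
           " (sample '", ids[bad[1, 1]], "'), column '",
           colnames(m)[bad[1, 2]], "'")
    }
    storage.mode(m) <- "double"
  }
  rownames(m) <- ids
  m
}

#' Load views (and optional outcome/covariates) from delimited files
#'
#' Each file is a delimited table with a header row of feature names and a
#' first column of sample identifiers. Samples are intersected across all
#' files and reordered to the first view's order; dropped samples are warned
#' about.
#'
#' @param paths Character vector of view file paths.
#' @param outcome_path Optional path to an outcome table: one value column, or
#'   `time` + `event` columns for survival outcomes.
#' @param covariate_path Optional path to a numeric covariate table.
#' @param delimiter Field delimiter (default `","`; use `"\t"` for TSV).
#' @param outcome_kind Outcome kind passed to [mv_outcome()] (default
#'   `"auto"`).
#' @param view_names Optional names for the views; defaults to file base names.
#' @param na_action Passed to [multiview_data()].
#' @return An `mvdata` object.
#' @export
load_views <- function(paths, outcome_path = NULL, covariate_path = NULL,
                       delimiter = ",", outcome_kind = "auto",
                       view_names = NULL, na_action = "error") {
  views <- lapply(paths, read_numeric_table, delimiter = delimiter)
  if (is.null(view_names)) {
    view_names <- vapply(paths, function(p) sub("\\.[^.]*$", "", basename(p)), "")
  }
  names(views) <- view_names
  covariates <- NULL
  if (!is.null(covariate_path)) {
    covariates <- read_numeric_table(covariate_path, delimiter)
  }
  data <- multiview_data(views, view_names = view_names,
                         covariates = covariates, na_action = na_action)
  if (!is.null(outcome_path)) {
    df <- utils::read.table(outcome_path, header = TRUE, sep = delimiter,
                            check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    keep <- match(data$sample_ids, ids)
    if (anyNA(keep)) {
      stop("outcome file lacks sample(s): ",
           paste(utils::head(data$sample_ids[is.na(keep)], 10), collapse = ", "))
    }
    df <- df[keep, -1, drop = FALSE]
    lc <- tolower(colnames(df))
    outcome <- if (all(c("time", "event") %in% lc)) {
      mv_outcome(kind = "survival", time = df[[which(lc == "time")]],
                 event = df[[which(lc == "event")]])
    } else {
      mv_outcome(df[[1]], kind = outcome_kind)
    }
    data$outcome <- outcome
  }
  data
}

# ---- train/test splitting ----------------------------------------------------

#' Split a multiview dataset into training and test sets
#'
#' With `stratify = TRUE` (requires a binary or multiclass outcome) each
#' class contributes `round(pct_train * n_k)` training samples (rounding half
#' away from zero); any deficit or excess relative to the overall target is
#' absorbed by the largest class, and every class keeps at least one test
#' sample when it has more than one member. The same `seed` always yields the
#' same partition.
#'
#' @param data An `mvdata` object.
#' @param pct_train Fraction of samples assigned to training, in (0, 1).
#' @param stratify Stratify by outcome class? Default `TRUE` when a
#'   binary/multiclass outcome is present.
#' @param seed Integer seed governing the random assignment.
#' @return A list with elements `train` and `test`, both `mvdata`.
#' @export
split_train_test <- function(data, pct_train = 0.8, stratify = NULL, seed = 1234) {
  stopifnot(inherits(data, "mvdata"), pct_train > 0, pct_train < 1)
  n <- n_samples(data)
  if (is.null(stratify)) {
    stratify <- !is.null(data$outcome) &&
      data$outcome$kind %in% c("binary", "multiclass")
  }
  if (stratify && (is.null(data$outcome) ||
                   !data$outcome$kind %in% c("binary", "multiclass"))) {
    stop("stratified split requires a binary or multiclass outcome")
  }
  train_idx <- with_seed(seed, {
    if (!stratify) {
      sort(sample.int(n, max(1, min(n - 1, round_half_away(pct_train * n)))))
    } else {
      cls <- outcome_classes(data$outcome)
      tab <- sort(table(cls), decreasing = TRUE)
      n_train <- vapply(names(tab), function(k) {
        round_half_away(pct_train * tab[[k]])
      }, 0)
      # each multi-member class keeps >= 1 sample on each side
      n_train <- pmin(pmax(n_train, 1), pmax(tab - 1, 1))
      singletons <- names(tab)[tab == 1]
      if (length(singletons) > 0) {
        warning("class(es) with a single sample assigned to training: ",
                paste(singletons, collapse = ", "))
      }
      # absorb rounding deficit/excess into the largest class
      target <- round_half_away(pct_train * n)
      diff <- target - sum(n_train)
      big <- names(tab)[1]
      n_train[big] <- min(max(n_train[big] + diff, 1), max(tab[[big]] - 1, 1))
      idx <- unlist(lapply(names(tab), function(k) {
        members <- which(cls == k)
        members[sample.int(length(members), n_train[k])]
      }))
      sort(idx)
    }
  })
  list(train = mvdata_subset(data, train_idx),
       test = mvdata_subset(data, setdiff(seq_len(n), train_idx)))
}

# ---- model serialization -----------------------------------------------------

MODEL_FORMAT <- "mvintegrate-model"
MODEL_FORMAT_VERSION <- 1L

#' Save / load a fitted model
#'
#' Models are stored as a self-describing archive: a manifest (format tag,
#' format version, package version, model class, creation time) alongside the
#' model object, serialized with R's native format so every numeric field
#' round-trips bit-exactly.
#'
#' @param model A fitted `selpcca_model`, `sida_model` or `outcome_model`.
#' @param path File path to write to / read from.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("selpcca_model", "sida_model", "outcome_model")))
  archive <- list(
    manifest = list(
      format = MODEL_FORMAT,
      format_version = MODEL_FORMAT_VERSION,
      package_version = as.character(utils::packageVersion("mvintegrate")),
      model_class = class(model)[1],
      created = format(Sys.time(), tz = "UTC")
    ),
    model = model
  )
  saveRDS(archive, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  archive <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot deserialize '", path, "': ", conditionMessage(e))
  })
  if (!is.list(archive) || !identical(archive$manifest$format, MODEL_FORMAT)) {
    stop("'", path, "' is not an mvintegrate model archive")
  }
  if (archive$manifest$format_version > MODEL_FORMAT_VERSION) {
    stop("model archive version ", archive$manifest$format_version,
         " is newer than supported version ", MODEL_FORMAT_VERSION)
  }
  archive$model
}
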