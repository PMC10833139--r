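# Every plot family is computed as a testable table first; rendering is a
# thin base-graphics layer over the tables and carries no logic of its own.

new_plot_table <- function(df, kind, ...) {
  attr(df, "kind") <- kind
  hints <- list(...)
  for (nm in names(hints)) attr(df, nm) <- hints[[nm]]
  class(df) <- c("mv_plot_table", "data.frame")
  df
}

#' @export
print.mv_plot_table <- function(x, ...) {
  cat(sprintf("<mv_plot_table> kind '%s', %d rows\n", attr(x, "kind"), nrow(x)))
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

# ---- volcano -----------------------------------------------------------------

#' Volcano-plot table from a supervised filter result
#'
#' Columns: `name`, `effect`, `neg_log10_adj_p` (`-log10` of the adjusted
#' p-value, capped at 300 with a `capped` flag), `significant` (the filter's
#' keep decision).
#'
#' @param result A supervised `filter_result` with adjusted p-values.
#' @return An `mv_plot_table` of kind `"volcano"`.
#' @export
volcano_table <- function(result) {
  stopifnot(inherits(result, "filter_result"))
  if (result$method %in% c("variance", "iqr") || !result$padjust) {
    stop("volcano plots need a supervised filter result with adjusted p-values")
  }
  tb <- result$table
  y <- -log10(tb$p_adjusted)
  capped <- !is.na(y) & y > 300
  y[capped] <- 300
  new_plot_table(
    data.frame(name = tb$name, effect = tb$effect, neg_log10_adj_p = y,
               capped = capped, significant = tb$keep,
               stringsAsFactors = FALSE),
    kind = "volcano", alpha = result$alpha, view_name = result$view_name)
}

# ---- umap --------------------------------------------------------------------

#' UMAP embedding table
#'
#' Two-dimensional UMAP embedding of a matrix (or of all views of an `mvdata`
#' concatenated column-wise), delegated to the uwot implementation. The same
#' seed always yields the same embedding (single-threaded exact mode).
#'
#' @param data Numeric matrix (samples x features) or an `mvdata`.
#' @param labels Optional per-sample labels (defaults to the outcome classes
#'   when `data` is an `mvdata` with a class outcome).
#' @param seed Integer seed.
#' @param n_neighbors UMAP neighborhood size (default 15, reduced for tiny n).
#' @return An `mv_plot_table` of kind `"umap"` with columns `sample_id`,
#'   `dim1`, `dim2`, `label`.
#' @export
umap_table <- function(data, labels = NULL, seed = 1234, n_neighbors = 15) {
  if (inherits(data, "mvdata")) {
    if (is.null(labels) && !is.null(data$outcome) &&
        data$outcome$kind %in% c("binary", "multiclass")) {
      labels <- outcome_classes(data$outcome)
    }
    X <- do.call(cbind, data$views)
    rownames(X) <- data$sample_ids
  } else {
    X <- as.matrix(data)
  }
  n <- nrow(X)
  if (n < 10) stop("UMAP needs at least 10 samples")
  ids <- rownames(X) %||% sprintf("s%04d", seq_len(n))
  emb <- with_seed(seed, {
    uwot::umap(X, n_neighbors = min(n_neighbors, n - 1), n_threads = 1,
               n_sgd_threads = 1, batch = TRUE)
  })
  new_plot_table(
    data.frame(sample_id = ids, dim1 = emb[, 1], dim2 = emb[, 2],
               label = if (is.null(labels)) NA_character_ else as.character(labels),
               stringsAsFactors = FALSE),
    kind = "umap", seed = seed)
}

# ---- importance --------------------------------------------------------------

model_loadings <- function(model, view) {
  if (inherits(model, "selpcca_model")) {
    stopifnot(view %in% c(1, 2))
    if (view == 1) model$hatalpha else model$hatbeta
  } else if (inherits(model, "sida_model")) {
    stopifnot(view >= 1, view <= model$D)
    model$hatalpha[[view]]
  } else {
    stop("model must be a selpcca_model or sida_model")
  }
}

#' Variable-importance table
#'
#' The `top_n` variables with largest absolute loading on one component of
#' one view, in descending order (ties broken by name). Since nonzero loading
#' columns are unit-norm, a larger absolute weight means a larger
#' contribution to the association (and, for discriminant models, the class
#' separation).
#'
#' @param model A `selpcca_model` or `sida_model`.
#' @param view View index.
#' @param component Component index (default 1).
#' @param top_n Number of variables (default 20); zero-loading variables are
#'   never included.
#' @return An `mv_plot_table` of kind `"importance"` with columns `name`,
#'   `loading`, `abs_loading`.
#' @export
importance_table <- function(model, view = 1, component = 1, top_n = 20) {
  W <- model_loadings(model, view)
  if (component < 1 || component > ncol(W)) {
    stop("component ", component, " out of range (model has ", ncol(W), ")")
  }
  w <- W[, component]
  nz <- which(w != 0)
  if (length(nz) == 0) {
    warning("all loadings are zero for this component")
    return(new_plot_table(
      data.frame(name = character(), loading = numeric(),
                 abs_loading = numeric(), stringsAsFactors = FALSE),
      kind = "importance", view = view, component = component))
  }
  ord <- nz[order(-abs(w[nz]), names(w)[nz] %||% as.character(nz))]
  ord <- utils::head(ord, top_n)
  nms <- rownames(W) %||% as.character(seq_len(nrow(W)))
  new_plot_table(
    data.frame(name = nms[ord], loading = w[ord], abs_loading = abs(w[ord]),
               stringsAsFactors = FALSE),
    kind = "importance", view = view, component = component)
}

# ---- model scores helper -----------------------------------------------------

# per-view score matrices for either model class; new data optional
view_scores <- function(model, views = NULL, covariates = NULL) {
  if (inherits(model, "selpcca_model")) {
    sc <- if (is.null(views)) model$train_scores
          else transform_scores(model, views[[1]], views[[2]])
    list(scores = list(sc$U, sc$V), names = model$view_names)
  } else if (inherits(model, "sida_model")) {
    sc <- if (is.null(views)) model$train_scores
          else classify_sida(model, views, covariates)$scores
    list(scores = sc, names = model$view_names)
  } else {
    stop("model must be a selpcca_model or sida_model")
  }
}

# ---- discriminant ------------------------------------------------------------

#' Discriminant-plot table
#'
#' Per view, the first one or two discriminant/canonical score columns for
#' each sample alongside its class — per-class densities over `score_1` when
#' only one component exists, a scatter of the first two otherwise.
#'
#' @param model A `sida_model` or `selpcca_model`.
#' @param views Optional list of new view matrices (training scores by
#'   default).
#' @param labels Class labels (required for new data; training labels cannot
#'   be recovered from a `selpcca_model`, so pass them explicitly there).
#' @return An `mv_plot_table` of kind `"discriminant"` with columns `view`,
#'   `sample_id`, `score_1` (`score_2` when available), `class`.
#' @export
discriminant_table <- function(model, views = NULL, labels = NULL) {
  vs <- view_scores(model, views)
  if (is.null(labels)) {
    if (inherits(model, "sida_model") && is.null(views)) {
      labels <- classify_sida_train_labels(model)
    }
    if (is.null(labels)) stop("class labels are required")
  }
  q <- ncol(vs$scores[[1]])
  rows <- lapply(seq_along(vs$scores), function(d) {
    sc <- vs$scores[[d]]
    df <- data.frame(view = vs$names[d],
                     sample_id = rownames(sc) %||% sprintf("s%04d", seq_len(nrow(sc))),
                     score_1 = unname(sc[, 1]), row.names = NULL,
                     stringsAsFactors = FALSE)
    if (q >= 2) df$score_2 <- unname(sc[, 2])
    df$class <- as.character(labels)
    df
  })
  new_plot_table(do.call(rbind, rows), kind = "discriminant", q = min(q, 2))
}

# training labels reconstructed from the stored centroids are not available;
# sida models carry the classes, so recover labels from stored train scores
classify_sida_train_labels <- function(model) {
  nearest_centroid(model$train_scores, model$centroids, model$class_labels)
}

# ---- correlation -------------------------------------------------------------

#' Correlation-plot table
#'
#' For every pair of views, the first score components of the two views per
#' sample with the class label; each pair is annotated with the Pearson
#' correlation of the two plotted columns (attribute `"correlations"`).
#'
#' @inheritParams discriminant_table
#' @return An `mv_plot_table` of kind `"correlation"` with columns `pair`,
#'   `sample_id`, `score_1`, `score_2`, `class`.
#' @export
correlation_table <- function(model, views = NULL, labels = NULL) {
  vs <- view_scores(model, views)
  if (is.null(labels) && inherits(model, "sida_model") && is.null(views)) {
    labels <- classify_sida_train_labels(model)
  }
  D <- length(vs$scores)
  prs <- utils::combn(D, 2)
  cors <- numeric(ncol(prs))
  rows <- vector("list", ncol(prs))
  for (i in seq_len(ncol(prs))) {
    d <- prs[1, i]; j <- prs[2, i]
    s1 <- vs$scores[[d]][, 1]; s2 <- vs$scores[[j]][, 1]
    cors[i] <- stats::cor(s1, s2)
    rows[[i]] <- data.frame(
      pair = paste(vs$names[d], vs$names[j], sep = " vs "),
      sample_id = rownames(vs$scores[[d]]) %||% sprintf("s%04d", seq_along(s1)),
      score_1 = unname(s1), score_2 = unname(s2),
      class = if (is.null(labels)) NA_character_ else as.character(labels),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  names(cors) <- vapply(rows, function(r) r$pair[1], "")
  new_plot_table(do.call(rbind, rows), kind = "correlation", correlations = cors)
}

# ---- relevance network -------------------------------------------------------

#' Bipartite relevance network between two views
#'
#' Nodes are the model-selected variables (nonzero loadings) of each view;
#' an edge joins a view-1 and a view-2 variable when the absolute Pearson
#' correlation of their training columns reaches `cutoff`. Positive edges are
#' tagged solid, negative dashed; view-1 nodes are circles, view-2 nodes
#' rectangles; isolated nodes are dropped.
#'
#' @param model A fitted `selpcca_model` or `sida_model`.
#' @param X1,X2 Training data for the two views (samples x features).
#' @param cutoff Absolute-correlation threshold in \[0, 1\] (default 0.5).
#' @return A `relevance_graph`: list with `nodes` (data.frame: view, name,
#'   shape), `edges` (node1, node2, weight, sign) and `cutoff`.
#' @export
relevance_network <- function(model, X1, X2, cutoff = 0.5) {
  if (cutoff < 0 || cutoff > 1) stop("cutoff must lie in [0, 1]")
  sel1 <- which(rowSums(model_loadings(model, 1) != 0) > 0)
  sel2 <- which(rowSums(model_loadings(model, 2) != 0) > 0)
  if (length(sel1) == 0 || length(sel2) == 0) {
    stop("model selected no variables in one of the views")
  }
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  n1 <- rownames(model_loadings(model, 1)) %||% paste0("x1_", seq_len(ncol(X1)))
  n2 <- rownames(model_loadings(model, 2)) %||% paste0("x2_", seq_len(ncol(X2)))
  C <- stats::cor(X1[, sel1, drop = FALSE], X2[, sel2, drop = FALSE])
  hits <- which(abs(C) >= cutoff, arr.ind = TRUE)
  edges <- data.frame(
    node1 = n1[sel1][hits[, 1]], node2 = n2[sel2][hits[, 2]],
    weight = C[hits], sign = ifelse(C[hits] >= 0, "solid", "dashed"),
    stringsAsFactors = FALSE)
  used <- unique(c(edges$node1, edges$node2))
  nodes <- rbind(
    data.frame(view = 1L, name = n1[sel1], shape = "circle",
               stringsAsFactors = FALSE),
    data.frame(view = 2L, name = n2[sel2], shape = "rectangle",
               stringsAsFactors = FALSE))
  nodes <- nodes[nodes$name %in% used, , drop = FALSE]
  rownames(nodes) <- NULL
  out <- list(nodes = nodes, edges = edges, cutoff = cutoff)
  class(out) <- "relevance_graph"
  out
}

#' @export
print.relevance_graph <- function(x, ...) {
  cat(sprintf("<relevance_graph> %d nodes, %d edges, |cor| cutoff %.2f\n",
              nrow(x$nodes), nrow(x$edges), x$cutoff))
  invisible(x)
}

# ---- loadings ----------------------------------------------------------------

#' Loadings-plane table for one view
#'
#' The first two loading components for every variable with a nonzero
#' loading; variables close together in this plane have similar loading
#' profiles. Unit-norm columns keep all points inside the unit disk.
#'
#' @inheritParams importance_table
#' @return An `mv_plot_table` of kind `"loadings"` with columns `name`,
#'   `loading_comp1`, `loading_comp2`.
#' @export
loadings_table <- function(model, view = 1) {
  W <- model_loadings(model, view)
  if (ncol(W) < 2) stop("loadings plot needs at least 2 components")
  nz <- which(rowSums(W[, 1:2, drop = FALSE] != 0) > 0)
  nms <- rownames(W) %||% as.character(seq_len(nrow(W)))
  new_plot_table(
    data.frame(name = nms[nz], loading_comp1 = W[nz, 1],
               loading_comp2 = W[nz, 2], stringsAsFactors = FALSE),
    kind = "loadings", view = view)
}

# ---- biplots -----------------------------------------------------------------

arrow_layer <- function(X, s1, s2, candidates, top_n) {
  a1 <- suppressWarnings(apply(X[, candidates, drop = FALSE], 2, stats::cor, s1))
  a2 <- suppressWarnings(apply(X[, candidates, drop = FALSE], 2, stats::cor, s2))
  a1[is.na(a1)] <- 0; a2[is.na(a2)] <- 0
  len <- sqrt(a1^2 + a2^2)
  keep <- utils::head(order(-len), top_n)
  data.frame(name = colnames(X)[candidates][keep], a1 = a1[keep], a2 = a2[keep],
             stringsAsFactors = FALSE)
}

#' Within-view biplot table
#'
#' Sample layer: the view's first two score components with class labels.
#' Arrow layer: for the `top_n` selected variables (by arrow length), the
#' Pearson correlations of the variable's column with the two plotted scores
#' (correlation-biplot convention, so arrows live inside the unit disk).
#'
#' @param model A fitted model with >= 2 components.
#' @param view_data The view's training data matrix.
#' @param labels Class labels for the sample layer.
#' @param view View index (default 1).
#' @param top_n Maximum number of arrows (default 10).
#' @return An `mv_plot_table` of kind `"biplot_within"` (the sample layer)
#'   with the arrow layer in attribute `"arrows"`.
#' @export
biplot_within <- function(model, view_data, labels = NULL, view = 1, top_n = 10) {
  W <- model_loadings(model, view)
  if (ncol(W) < 2) stop("biplot needs at least 2 components")
  X <- as.matrix(view_data)
  Xc <- sweep(X, 2, model$preprocessing$means[[view]], "-")
  sc <- Xc %*% W
  sel <- which(rowSums(W != 0) > 0)
  arrows <- arrow_layer(X, sc[, 1], sc[, 2], sel, top_n)
  df <- data.frame(
    sample_id = rownames(X) %||% sprintf("s%04d", seq_len(nrow(X))),
    score_1 = sc[, 1], score_2 = sc[, 2],
    class = if (is.null(labels)) NA_character_ else as.character(labels),
    stringsAsFactors = FALSE)
  new_plot_table(df, kind = "biplot_within", arrows = arrows, view = view)
}

#' Between-view biplot table
#'
#' Projects samples onto the first two view-1 score components and overlays
#' arrows for the selected variables of both views — correlations of each
#' variable's column with those axes. View-1 arrows carry style `"solid"`,
#' view-2 arrows `"dashed"`; set `axes_view = 2` for the symmetric
#' alternative.
#'
#' @param model A fitted model with >= 2 components.
#' @param X1,X2 Training data for the two views.
#' @param labels Class labels for the sample layer.
#' @param top_n Maximum arrows per view (default 10).
#' @param axes_view Which view supplies the score axes (default 1).
#' @return An `mv_plot_table` of kind `"biplot_between"` with attribute
#'   `"arrows"` (columns name, a1, a2, view, style).
#' @export
biplot_between <- function(model, X1, X2, labels = NULL, top_n = 10,
                           axes_view = 1) {
  W_axes <- model_loadings(model, axes_view)
  if (ncol(W_axes) < 2) stop("biplot needs at least 2 components")
  Xa <- as.matrix(if (axes_view == 1) X1 else X2)
  Xac <- sweep(Xa, 2, model$preprocessing$means[[axes_view]], "-")
  sc <- Xac %*% W_axes
  arrows <- do.call(rbind, lapply(1:2, function(v) {
    X <- as.matrix(if (v == 1) X1 else X2)
    sel <- which(rowSums(model_loadings(model, v) != 0) > 0)
    ar <- arrow_layer(X, sc[, 1], sc[, 2], sel, top_n)
    ar$view <- v
    ar$style <- if (v == 1) "solid" else "dashed"
    ar
  }))
  df <- data.frame(
    sample_id = rownames(Xa) %||% sprintf("s%04d", seq_len(nrow(Xa))),
    score_1 = sc[, 1], score_2 = sc[, 2],
    class = if (is.null(labels)) NA_character_ else as.character(labels),
    stringsAsFactors = FALSE)
  new_plot_table(df, kind = "biplot_between", arrows = arrows,
                 axes_view = axes_view)
}

# ---- rendering ---------------------------------------------------------------

#' Render a plot table to a graphics device
#'
#' A thin base-graphics layer: every mark is a pure function of the computed
#' table. When `file` is given a PNG device is opened and closed around the
#' drawing.
#'
#' @param x An `mv_plot_table` or `relevance_graph`.
#' @param file Optional PNG path.
#' @param ... Unused.
#' @return The input, invisibly.
#' @export
render_plot <- function(x, file = NULL, ...) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700, res = 110)
    on.exit(grDevices::dev.off())
  }
  if (inherits(x, "relevance_graph")) {
    render_network(x)
    return(invisible(x))
  }
  kind <- attr(x, "kind")
  cls <- if ("class" %in% names(x)) factor(x$class) else factor(rep(1, nrow(x)))
  pal <- grDevices::hcl.colors(max(2, nlevels(cls)), "Dark 2")
  col <- pal[as.integer(cls)]
  switch(kind,
    volcano = {
      plot(x$effect, x$neg_log10_adj_p, pch = 20,
           col = ifelse(x$significant, "firebrick", "grey50"),
           xlab = "effect", ylab = "-log10 adjusted p", main = "Volcano")
      graphics::abline(h = -log10(attr(x, "alpha")), lty = 2)
    },
    umap = {
      plot(x$dim1, x$dim2, col = pal[as.integer(factor(x$label))], pch = 20,
           xlab = "UMAP 1", ylab = "UMAP 2", main = "UMAP")
    },
    importance = {
      graphics::barplot(rev(x$abs_loading), names.arg = rev(x$name),
                        horiz = TRUE, las = 1, cex.names = 0.6,
                        xlab = "|loading|", main = "Variable importance")
    },
    discriminant = {
      views <- unique(x$view)
      graphics::par(mfrow = c(1, length(views)))
      for (v in views) {
        xv <- x[x$view == v, ]
        if (attr(x, "q") >= 2) {
          plot(xv$score_1, xv$score_2, col = pal[as.integer(factor(xv$class))],
               pch = 20, xlab = "score 1", ylab = "score 2", main = v)
        } else {
          dens <- tapply(xv$score_1, xv$class, stats::density)
          plot(NULL, xlim = range(xv$score_1),
               ylim = c(0, max(vapply(dens, function(d) max(d$y), 0))),
               xlab = "score 1", ylab = "density", main = v)
          for (i in seq_along(dens)) graphics::lines(dens[[i]], col = pal[i])
        }
      }
    },
    correlation = {
      prs <- unique(x$pair)
      graphics::par(mfrow = c(1, length(prs)))
      for (pr in prs) {
        xp <- x[x$pair == pr, ]
        plot(xp$score_1, xp$score_2, col = pal[as.integer(factor(xp$class))],
             pch = 20, main = sprintf("%s (r = %.2f)", pr,
                                      attr(x, "correlations")[[pr]]),
             xlab = "score (first view)", ylab = "score (second view)")
      }
    },
    loadings = {
      plot(x$loading_comp1, x$loading_comp2, pch = 20, xlim = c(-1, 1),
           ylim = c(-1, 1), xlab = "component 1", ylab = "component 2",
           main = "Loadings")
      graphics::text(x$loading_comp1, x$loading_comp2, x$name, pos = 3, cex = 0.6)
      graphics::abline(h = 0, v = 0, lty = 3)
    },
    {
      # biplots
      plot(x$score_1, x$score_2, col = col, pch = 20,
           xlab = "score 1", ylab = "score 2", main = kind)
      ar <- attr(x, "arrows")
      sc <- max(abs(c(x$score_1, x$score_2)))
      lty <- if (!is.null(ar$style)) ifelse(ar$style == "solid", 1, 2) else 1
      graphics::arrows(0, 0, ar$a1 * sc, ar$a2 * sc, length = 0.08, lty = lty,
                       col = if (!is.null(ar$view)) c("black", "red")[ar$view]
                             else "black")
      graphics::text(ar$a1 * sc, ar$a2 * sc, ar$name, pos = 3, cex = 0.6)
    }
  )
  invisible(x)
}

render_network <- function(g) {
  # circular layout: view-1 nodes on the left arc, view-2 on the right
  nodes <- g$nodes
  n <- nrow(nodes)
  if (n == 0) {
    plot(NULL, xlim = c(-1, 1), ylim = c(-1, 1), main = "Relevance network",
         xlab = "", ylab = "")
    return(invisible(g))
  }
  th <- numeric(n)
  v1 <- nodes$view == 1
  th[v1] <- seq(pi / 2, 3 * pi / 2, length.out = sum(v1) + 2)[-c(1, sum(v1) + 2)]
  th[!v1] <- seq(-pi / 2, pi / 2, length.out = sum(!v1) + 2)[-c(1, sum(!v1) + 2)]
  xy <- cbind(cos(th), sin(th))
  rownames(xy) <- nodes$name
  plot(NULL, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), axes = FALSE,
       xlab = "", ylab = "", main = sprintf("Relevance network (|r| >= %.2f)",
                                            g$cutoff))
  for (i in seq_len(nrow(g$edges))) {
    e <- g$edges[i, ]
    graphics::segments(xy[e$node1, 1], xy[e$node1, 2],
                       xy[e$node2, 1], xy[e$node2, 2],
                       lty = if (e$sign == "solid") 1 else 2,
                       col = if (e$sign == "solid") "steelblue" else "tomato")
  }
  graphics::points(xy, pch = ifelse(nodes$view == 1, 21, 22), bg = "white",
                   cex = 1.4)
  graphics::text(xy[, 1] * 1.15, xy[, 2] * 1.15, nodes$name, cex = 0.6)
  invisible(g)
}
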