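#' PCA reduction with a fixed sign convention
#'
#' Reduces a dense cells-by-features matrix to `n_components` principal
#' component scores (centered, unscaled PCA). The sign of each component is
#' fixed so that the loading with the largest absolute value is positive,
#' making scores deterministic across runs and linear algebra backends.
#'
#' @param M dense cells-by-features matrix
#' @param n_components number of components, at most `min(cells, features)`
#' @return cells-by-components score matrix; the rotation is attached as
#'   attribute `"rotation"`
#' @export
reduce <- function(M, n_components = 50L) {
  M <- as.matrix(M)
  if (n_components > min(dim(M))) {
    stop("`n_components` exceeds min(cells, features)")
  }
  p <- stats::prcomp(M, center = TRUE, scale. = FALSE, rank. = n_components)
  rot <- p$rotation
  scores <- p$x
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  attr(scores, "rotation") <- rot
  attr(scores, "sdev") <- p$sdev[seq_len(n_components)]
  scores
}

#' Leave-one-out k-nearest-neighbor class prediction
#'
#' For each cell, predicts its class from the majority vote of its `k`
#' Euclidean nearest neighbors among the remaining \eqn{n-1} cells. Vote
#' ties are broken by the smallest class label (alphabetical); neighbor
#' distance ties by the smallest cell index. Distances are computed in
#' blocks, so memory stays at one block-by-n slab.
#'
#' @param E cells-by-components embedding matrix
#' @param labels per-cell class labels
#' @param k number of neighbors (default 15), `0 < k < n_cells`
#' @param block_size rows per distance block (default 512)
#' @return character vector of per-cell predicted labels
#' @export
knn_loo_predict <- function(E, labels, k = 15L, block_size = 512L) {
  E <- as.matrix(E)
  n <- nrow(E)
  labels <- as.character(labels)
  stopifnot(length(labels) == n)
  if (k <= 0) stop("`k` must be positive")
  if (k >= n) stop("`k` must be smaller than the number of cells")
  if (length(unique(labels)) < 2) stop("need at least 2 classes")
  classes <- sort(unique(labels))
  lab_idx <- match(labels, classes)
  sq <- rowSums(E^2)
  pred <- character(n)
  for (start in seq(1, n, by = block_size)) {
    rows <- start:min(start + block_size - 1, n)
    # squared Euclidean distances of the block against all cells
    D <- outer(sq[rows], sq, "+") - 2 * E[rows, , drop = FALSE] %*% t(E)
    for (r in seq_along(rows)) {
      i <- rows[r]
      d <- D[r, ]
      d[i] <- Inf                      # exclude the cell itself
      nb <- order(d, seq_len(n))[seq_len(k)]
      votes <- tabulate(lab_idx[nb], nbins = length(classes))
      pred[i] <- classes[which.max(votes)]   # ties -> smallest label
    }
  }
  pred
}

#' Macro-averaged F1 score
#'
#' Per-class F1 is the harmonic mean of precision and recall
#' (\eqn{2PR/(P+R)}, 0 when \eqn{P+R=0}); the macro F1 is the unweighted
#' mean over the classes present in the true labels, so a rare class
#' contributes as much as a large one — unlike overall accuracy.
#'
#' @param true_labels ground truth class labels
#' @param predicted_labels predictions, same length
#' @return scalar macro F1 in `[0, 1]`; the per-class table (precision,
#'   recall, F1, support) is attached as attribute `"per_class"`, overall
#'   accuracy as attribute `"accuracy"`
#' @export
macro_f1 <- function(true_labels, predicted_labels) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) == 0) stop("empty input")
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must have equal length")
  }
  classes <- sort(unique(true_labels))
  per <- data.frame(class = classes, precision = NA_real_, recall = NA_real_,
                    f1 = NA_real_, support = NA_integer_)
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    tp <- sum(true_labels == cl & predicted_labels == cl)
    fp <- sum(true_labels != cl & predicted_labels == cl)
    fn <- sum(true_labels == cl & predicted_labels != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    per[ci, 2:5] <- c(prec, rec, f1, tp + fn)
  }
  out <- mean(per$f1)
  attr(out, "per_class") <- per
  attr(out, "accuracy") <- mean(true_labels == predicted_labels)
  out
}

#' Registered data transformations for the benchmark
#' @return character vector of transform names accepted by
#'   [apply_transform()]
#' @export
benchmark_transforms <- function() {
  c("pearson", "deviance", "sqrt_cpmedian", "log_cpmedian",
    "log_cpmedian_std", "log_cpm")
}

#' Apply a registered transformation to a count matrix
#'
#' @param X a [count_matrix()]
#' @param transform one of [benchmark_transforms()]: clipped Pearson
#'   residuals (`theta`), deviance residuals, sqrt of counts-per-median,
#'   log1p of counts-per-median (optionally standardized), or log1p of CPM
#' @param theta overdispersion for the residual transforms (default 100)
#' @return dense cells-by-genes matrix
#' @export
apply_transform <- function(X, transform, theta = 100) {
  switch(transform,
    pearson = pearson_residuals(X, theta = theta, clip = "sqrt_n")$values,
    deviance = deviance_residuals(X, theta = theta)$values,
    sqrt_cpmedian = sqrt_family(depth_normalize(X, "median"), "sqrt"),
    log_cpmedian = log_family(depth_normalize(X, "median"), 1),
    log_cpmedian_std = standardize(log_family(depth_normalize(X, "median"), 1)),
    log_cpm = log_family(depth_normalize(X, "million"), 1),
    stop("unknown transform: ", transform)
  )
}

#' Pipeline specification for the benchmark grid
#'
#' @param hvg_method one of [hvg_methods()] or `"none"`
#' @param transform one of [benchmark_transforms()]
#' @param n_hvgs number of genes to select (default 2000)
#' @param n_components PCA dimensionality (default 50)
#' @param theta overdispersion used by residual-based steps (default 100)
#' @return object of class `PipelineSpec`
#' @export
pipeline_spec <- function(hvg_method = "pearson_var", transform = "pearson",
                          n_hvgs = 2000L, n_components = 50L, theta = 100) {
  if (!hvg_method %in% c(hvg_methods(), "none")) {
    stop("unknown HVG method: ", hvg_method)
  }
  if (!transform %in% benchmark_transforms()) {
    stop("unknown transform: ", transform)
  }
  structure(
    list(hvg_method = hvg_method, transform = transform,
         n_hvgs = as.integer(n_hvgs), n_components = as.integer(n_components),
         theta = theta,
         id = paste0(hvg_method, "+", transform)),
    class = "PipelineSpec"
  )
}

#' The default in-scope pipeline grid
#'
#' All registered transforms crossed with all HVG criteria plus no
#' selection: `6 x (5 + 1) = 36` pipelines.
#'
#' @inheritParams pipeline_spec
#' @return list of [pipeline_spec()] objects
#' @export
default_grid <- function(n_hvgs = 2000L, n_components = 50L, theta = 100) {
  grid <- list()
  for (h in c(hvg_methods(), "none")) {
    for (tr in benchmark_transforms()) {
      grid[[length(grid) + 1]] <- pipeline_spec(h, tr, n_hvgs, n_components,
                                                theta)
    }
  }
  grid
}

#' Run one pipeline on a labeled dataset
#'
#' HVG selection (when requested) precedes the transform; the transform is
#' then applied to the subset matrix, so sequencing depths are recomputed
#' over the selected genes only. PCA reduces to `n_components`, and
#' leave-one-out kNN classification with `k` neighbors is scored by macro
#' F1.
#'
#' @param dataset a `LabeledDataset` from [make_benchmark()]
#' @param pipeline a [pipeline_spec()]
#' @param k kNN neighbors (default 15)
#' @return list with `macro_f1`, `accuracy`, `per_class` (data.frame),
#'   `predictions`, `selected_genes`, `elapsed`
#' @export
run_pipeline <- function(dataset, pipeline, k = 15L) {
  stopifnot(inherits(dataset, "LabeledDataset"),
            inherits(pipeline, "PipelineSpec"))
  t0 <- proc.time()[["elapsed"]]
  X <- dataset$counts
  selected <- X$gene_ids
  if (pipeline$hvg_method != "none") {
    scores <- score_genes(X, pipeline$hvg_method, theta = pipeline$theta)
    kk <- min(pipeline$n_hvgs, length(scores))
    idx <- select_top_k(scores, kk)
    X <- X[, idx]
    selected <- X$gene_ids
  }
  M <- apply_transform(X, pipeline$transform, theta = pipeline$theta)
  E <- reduce(M, pipeline$n_components)
  pred <- knn_loo_predict(E, dataset$labels, k = k)
  f1 <- macro_f1(dataset$labels, pred)
  list(macro_f1 = as.numeric(f1),
       accuracy = attr(f1, "accuracy"),
       per_class = attr(f1, "per_class"),
       predictions = pred,
       selected_genes = selected,
       elapsed = proc.time()[["elapsed"]] - t0)
}

#' Run a grid of pipelines
#'
#' Evaluates each pipeline with [run_pipeline()]; a failing pipeline is
#' recorded with `NA` metrics and its error message, and the grid
#' continues.
#'
#' @param dataset a `LabeledDataset`
#' @param pipelines list of [pipeline_spec()] objects (default
#'   [default_grid()])
#' @param k kNN neighbors
#' @param verbose print one line per pipeline with its wall time
#' @return data.frame with one row per pipeline: `pipeline`, `hvg_method`,
#'   `transform`, `macro_f1`, `accuracy`, per-class F1 columns, `elapsed`,
#'   `error`
#' @export
run_grid <- function(dataset, pipelines = default_grid(), k = 15L,
                     verbose = FALSE) {
  classes <- sort(unique(dataset$labels))
  rows <- vector("list", length(pipelines))
  for (i in seq_along(pipelines)) {
    pl <- pipelines[[i]]
    res <- tryCatch(run_pipeline(dataset, pl, k = k),
                    error = function(e) e)
    if (inherits(res, "error")) {
      row <- data.frame(pipeline = pl$id, hvg_method = pl$hvg_method,
                        transform = pl$transform, macro_f1 = NA_real_,
                        accuracy = NA_real_, elapsed = NA_real_,
                        error = conditionMessage(res))
      for (cl in classes) row[[paste0("f1_", cl)]] <- NA_real_
    } else {
      row <- data.frame(pipeline = pl$id, hvg_method = pl$hvg_method,
                        transform = pl$transform, macro_f1 = res$macro_f1,
                        accuracy = res$accuracy, elapsed = res$elapsed,
                        error = NA_character_)
      for (cl in classes) {
        row[[paste0("f1_", cl)]] <- res$per_class$f1[res$per_class$class == cl]
      }
      if (verbose) {
        message(sprintf("%-28s macro F1 = %.3f (%.1f s)", pl$id,
                        res$macro_f1, res$elapsed))
      }
    }
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}
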