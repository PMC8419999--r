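#' Remove genes detected in too few cells
#'
#' Drops genes with non-zero counts in fewer than `min_cells` cells, the
#' standard pre-filter before residual computation and regression
#' diagnostics (default 5 detecting cells).
#'
#' @param X a [count_matrix()]
#' @param min_cells minimum number of cells with count > 0 (default 5);
#'   0 is the identity
#' @return filtered `CountMatrix`; the number of removed genes is attached
#'   as attribute `"n_removed"` and reported via `message()`
#' @export
filter_min_cells <- function(X, min_cells = 5L) {
  stopifnot(inherits(X, "CountMatrix"), min_cells >= 0)
  detected <- Matrix::colSums(X$counts > 0)
  keep <- detected >= min_cells
  if (!any(keep)) stop("filter_min_cells would remove all genes")
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    message(sprintf("filter_min_cells: removed %d of %d genes (min_cells = %d)",
                    n_removed, length(keep), min_cells))
  }
  out <- X[, which(keep)]
  attr(out, "n_removed") <- n_removed
  out
}

#' Registered highly-variable-gene scoring methods
#' @return character vector of method names accepted by [score_genes()]
#' @export
hvg_methods <- function() {
  c("pearson_var", "deviance_var", "sqrt_var", "log_var", "fano")
}

#' Score genes for variability
#'
#' Computes a per-gene scalar score under one of the registered criteria;
#' genes whose variation exceeds the technical expectation score highest.
#'
#' \describe{
#'   \item{`pearson_var`}{variance of analytic Pearson residuals
#'     ([residual_variance()]); clipped by default, which avoids spuriously
#'     large scores for genes expressed in a handful of cells.}
#'   \item{`deviance_var`}{variance of (unclipped) deviance residuals.}
#'   \item{`sqrt_var`}{variance after median depth normalization and square
#'     root transform.}
#'   \item{`log_var`}{variance after median depth normalization and
#'     \eqn{\log(1+x)} transform.}
#'   \item{`fano`}{Fano factor of median-normalized counts.}
#' }
#'
#' @param X a (filtered) [count_matrix()]
#' @param method one of [hvg_methods()]
#' @param theta overdispersion for the residual criteria (default 100)
#' @param clip clip spec for `pearson_var` (default `"sqrt_n"`)
#' @return numeric score vector named by gene id
#' @export
score_genes <- function(X, method = "pearson_var", theta = 100,
                        clip = "sqrt_n") {
  stopifnot(inherits(X, "CountMatrix"))
  if (!method %in% hvg_methods()) {
    stop("unknown HVG method: ", method,
         " (known: ", paste(hvg_methods(), collapse = ", "), ")")
  }
  scores <- switch(method,
    pearson_var = residual_variance(X, "pearson", theta = theta, clip = clip),
    deviance_var = residual_variance(X, "deviance", theta = theta, clip = "none"),
    sqrt_var = {
      Y <- sqrt_family(depth_normalize(X, "median"), "sqrt")
      colMeans(Y^2) - colMeans(Y)^2
    },
    log_var = {
      Y <- log_family(depth_normalize(X, "median"), 1)
      colMeans(Y^2) - colMeans(Y)^2
    },
    fano = as.numeric(fano_factor(X))
  )
  names(scores) <- X$gene_ids
  scores
}

#' Select the top-k scoring genes
#'
#' Returns the indices of the `k` largest scores. Ties are broken by
#' ascending gene index, so selection is deterministic and invariant to
#' reordering up to that documented rule.
#'
#' @param scores numeric score vector
#' @param k number of genes to select, `1 <= k <= length(scores)`
#' @return integer vector of selected gene indices, in ascending index order
#' @export
select_top_k <- function(scores, k) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0) stop("`k` must be positive")
  if (k > length(scores)) stop("`k` exceeds the number of genes")
  ord <- order(-scores, seq_along(scores))
  sort(ord[seq_len(k)])
}

#' Score table for HVG selection
#'
#' Convenience wrapper producing the on-disk score table: gene id, mean
#' expression, score, and a selected flag for the top `k` genes. Selection
#' is reproducible from the table plus `k` alone.
#'
#' @inheritParams score_genes
#' @param k number of genes to flag as selected
#' @return data.frame with columns `gene_id`, `mean_expression`, `score`,
#'   `selected`
#' @export
hvg_table <- function(X, method = "pearson_var", k = 2000L, theta = 100,
                      clip = "sqrt_n") {
  k <- min(k, ncol(X$counts))
  scores <- score_genes(X, method, theta = theta, clip = clip)
  sel <- select_top_k(scores, k)
  data.frame(
    gene_id = X$gene_ids,
    mean_expression = as.numeric(Matrix::colSums(X$counts)) / nrow(X$counts),
    score = as.numeric(scores),
    selected = seq_along(scores) %in% sel
  )
}
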