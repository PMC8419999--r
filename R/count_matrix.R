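#' Sparse UMI count matrix with cell and gene identifiers
#'
#' A `CountMatrix` stores unique molecular identifier (UMI) counts as a
#' sparse cells-by-genes matrix together with cell barcodes and gene
#' identifiers. Cells are always rows and genes are always columns; readers
#' for the 10x genes-as-rows Matrix Market dialect transpose on load (see
#' [read_counts()]).
#'
#' @param counts a matrix or `Matrix::sparseMatrix` of non-negative integer
#'   counts, cells in rows, genes in columns. Dense input is converted to
#'   sparse storage; zeros are never materialized.
#' @param cell_ids character vector of cell identifiers, one per row.
#'   Defaults to existing rownames or `cell_1..cell_n`.
#' @param gene_ids character vector of gene identifiers, one per column.
#'   Defaults to existing colnames or `gene_1..gene_m`.
#'
#' @return an object of class `CountMatrix` with fields `counts`
#'   (a `dgCMatrix`), `cell_ids` and `gene_ids`.
#' @examples
#' X <- count_matrix(matrix(c(1, 2, 3, 4), nrow = 2, byrow = TRUE))
#' sequencing_depths(X)
#' @export
count_matrix <- function(counts, cell_ids = NULL, gene_ids = NULL) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!methods::is(counts, "Matrix") && !is.matrix(counts)) {
    stop("`counts` must be a matrix or sparse Matrix")
  }
  vals <- if (methods::is(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  if (anyNA(vals)) stop("counts contain missing values")
  if (any(vals < 0)) stop("counts must be non-negative")
  if (any(abs(vals - round(vals)) > 1e-8)) stop("counts must be integral")
  if (is.null(cell_ids)) cell_ids <- rownames(counts)
  if (is.null(gene_ids)) gene_ids <- colnames(counts)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(counts)))
  if (length(cell_ids) != nrow(counts)) stop("length(cell_ids) must equal nrow(counts)")
  if (length(gene_ids) != ncol(counts)) stop("length(gene_ids) must equal ncol(counts)")
  m <- Matrix::Matrix(counts, sparse = TRUE)
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  m <- Matrix::drop0(m * 1)
  dimnames(m) <- NULL
  structure(
    list(counts = m, cell_ids = as.character(cell_ids),
         gene_ids = as.character(gene_ids)),
    class = "CountMatrix"
  )
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
print.CountMatrix <- function(x, ...) {
  nz <- length(x$counts@x)
  cat(sprintf("CountMatrix: %d cells x %d genes, %d non-zero entries (%.1f%% dense)\n",
              nrow(x$counts), ncol(x$counts), nz,
              100 * nz / max(1, prod(dim(x$counts)))))
  invisible(x)
}

#' Subset a CountMatrix by cells and/or genes
#'
#' @param x a `CountMatrix`
#' @param i cell (row) index vector
#' @param j gene (column) index vector
#' @param ... ignored
#' @export
`[.CountMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  count_matrix(x$counts[i, j, drop = FALSE],
               cell_ids = x$cell_ids[i], gene_ids = x$gene_ids[j])
}

#' Per-cell sequencing depths
#'
#' The sequencing depth of a cell is its total UMI count,
#' \eqn{n_c = \sum_g X_{cg}}. Under the null model all cross-cell variation
#' of a gene is attributed to depth.
#'
#' @param X a `CountMatrix`
#' @return numeric vector of length `n_cells` with the per-cell row sums
#' @export
sequencing_depths <- function(X) {
  stopifnot(inherits(X, "CountMatrix"))
  as.numeric(Matrix::rowSums(X$counts))
}

# internal: validate a theta argument; Inf is the Poisson sentinel
check_theta <- function(theta) {
  if (length(theta) != 1 || is.na(theta) || theta <= 0) {
    stop("`theta` must be a single positive number or Inf (Poisson)")
  }
  theta
}

#' Poisson sentinel for the overdispersion parameter
#'
#' `theta = poisson_theta()` (infinity) marks the Poisson model wherever an
#' overdispersion parameter is accepted; arithmetic branches on the sentinel
#' rather than evaluating `mu^2 / Inf`.
#'
#' @return `Inf`
#' @export
poisson_theta <- function() Inf

#' @rdname poisson_theta
#' @param theta overdispersion value to test
#' @export
is_poisson_theta <- function(theta) is.infinite(theta)
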