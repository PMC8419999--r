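#' Sequencing depth normalization with median / CPM scaling
#'
#' Divides each cell by its sequencing depth and rescales by a common
#' factor: the median depth across cells ("counts per median", the
#' conservative default), one million ("counts per million"), or a given
#' constant. Large scale factors combined with small pseudocounts in a
#' subsequent log transform are known to introduce spurious variation, which
#' is why the median is the default.
#'
#' @param X a [count_matrix()]; every cell must have depth > 0
#' @param scale `"median"`, `"million"`, or a positive number
#' @return sparse cells-by-genes real matrix (zeros preserved exactly),
#'   with the scale factor as attribute `"scale_factor"`
#' @export
depth_normalize <- function(X, scale = "median") {
  stopifnot(inherits(X, "CountMatrix"))
  depths <- sequencing_depths(X)
  if (any(depths == 0)) {
    stop("cell(s) with zero sequencing depth: ",
         paste(utils::head(X$cell_ids[depths == 0], 5), collapse = ", "))
  }
  s <- if (identical(scale, "median")) {
    median_depth(depths)
  } else if (identical(scale, "million")) {
    1e6
  } else if (is.numeric(scale) && length(scale) == 1 && scale > 0) {
    scale
  } else {
    stop("`scale` must be \"median\", \"million\", or a positive number")
  }
  Y <- Matrix::Diagonal(x = s / depths) %*% X$counts
  Y <- methods::as(Y, "CsparseMatrix")
  attr(Y, "scale_factor") <- s
  Y
}

# lower median for even counts: deterministic across implementations
median_depth <- function(depths) {
  sorted <- sort(depths)
  sorted[ceiling(length(sorted) / 2)]
}

#' Square-root family of variance-stabilizing transformations
#'
#' Elementwise \eqn{\sqrt y} (`"sqrt"`), the Anscombe transformation
#' \eqn{2\sqrt{y + 3/8}} (`"anscombe"`), or the Freeman-Tukey
#' transformation \eqn{\sqrt y + \sqrt{y+1}} (`"freeman_tukey"`). For
#' Poisson data all three are approximately variance-stabilizing at high
#' means (variance \eqn{\approx 1/4} for plain sqrt), but none stabilizes
#' low-expression genes, whose variance collapses toward zero.
#'
#' @param Y non-negative matrix (dense or sparse), e.g. from
#'   [depth_normalize()]
#' @param variant `"sqrt"`, `"anscombe"`, or `"freeman_tukey"`
#' @return transformed matrix, dense
#' @export
sqrt_family <- function(Y, variant = c("sqrt", "anscombe", "freeman_tukey")) {
  variant <- match.arg(variant)
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop("input to sqrt_family must be non-negative")
  switch(variant,
    sqrt = sqrt(Y),
    anscombe = 2 * sqrt(Y + 3 / 8),
    freeman_tukey = sqrt(Y) + sqrt(Y + 1)
  )
}

#' Shifted log transformation
#'
#' Elementwise \eqn{\ln(y + \varepsilon)} with pseudocount
#' \eqn{\varepsilon = 1} by default, so zeros map to zero.
#'
#' @param Y non-negative matrix
#' @param pseudocount positive pseudocount \eqn{\varepsilon}
#' @return transformed dense matrix
#' @export
log_family <- function(Y, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0) {
    stop("`pseudocount` must be a positive number")
  }
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop("input to log_family must be non-negative")
  log(Y + pseudocount)
}

#' Per-gene standardization
#'
#' Centers each gene (column) at mean zero and scales it to unit variance.
#' The population variance (divide by \eqn{n}) is used, matching the
#' unit-variance convention of Pearson residuals. Zero-variance genes are
#' mapped to 0 and flagged in attribute `"zero_variance_genes"`.
#'
#' @param M dense cells-by-genes matrix
#' @return standardized matrix with per-column mean 0 and variance 1
#' @export
standardize <- function(M) {
  M <- as.matrix(M)
  mu <- colMeans(M)
  v <- colMeans(M^2) - mu^2
  zero <- v <= 0
  sdv <- sqrt(ifelse(zero, 1, v))
  out <- sweep(sweep(M, 2, mu), 2, sdv, "/")
  out[, zero] <- 0
  attr(out, "zero_variance_genes") <- zero
  out
}

#' Fano factor of median-normalized counts
#'
#' Per-gene variance/mean ratio after sequencing depth normalization and
#' median scaling. Equals 1 for Poisson counts at equal depths, and is
#' closely related to the variance of unclipped Poisson Pearson residuals.
#' Zero-mean genes get the value 0 and are flagged in attribute
#' `"zero_genes"`.
#'
#' @param X a [count_matrix()]; depths must be positive
#' @return numeric vector of per-gene Fano factors
#' @export
fano_factor <- function(X) {
  Y <- depth_normalize(X, scale = "median")
  mu <- as.numeric(Matrix::colMeans(Y))
  ex2 <- as.numeric(Matrix::colMeans(Y^2))
  v <- ex2 - mu^2
  zero <- mu == 0
  out <- ifelse(zero, 0, v / ifelse(zero, 1, mu))
  attr(out, "zero_genes") <- zero
  out
}
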