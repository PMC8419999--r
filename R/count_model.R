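#' Fit the rank-one null model to a UMI count matrix
#'
#' The null model assumes each gene takes a fixed fraction \eqn{p_g} of the
#' total UMI count \eqn{n_c} of each cell, so counts are Poisson (or negative
#' binomial with shared overdispersion \eqn{\theta}) with mean
#' \eqn{\mu_{cg} = n_c p_g}. Under the Poisson model the maximum likelihood
#' estimates are closed-form margins:
#' \eqn{\hat n_c = \sum_g X_{cg}},
#' \eqn{\hat p_g = \sum_c X_{cg} / \sum_c \hat n_c}, and hence
#' \eqn{\hat\mu_{cg} = (\mathrm{row\ sum}_c \times \mathrm{col\ sum}_g)/
#' \mathrm{grand\ total}}. For the negative binomial model this holds
#' approximately and becomes exact as \eqn{\theta \to \infty}.
#'
#' @param X a [count_matrix()] with at least one non-zero entry
#' @param theta shared overdispersion parameter, a positive number or `Inf`
#'   for the Poisson model. Default 100, a value consistent with the
#'   technical noise of negative-control UMI datasets.
#' @return an object of class `NullFit` with fields `depths` (\eqn{\hat n_c}),
#'   `fractions` (\eqn{\hat p_g}, summing to 1), `theta`, and `total`
#'   (grand sum of counts).
#' @seealso [pearson_residuals()], [predict_mu()]
#' @export
fit_null <- function(X, theta = 100) {
  stopifnot(inherits(X, "CountMatrix"))
  check_theta(theta)
  depths <- sequencing_depths(X)
  total <- sum(depths)
  if (total == 0) stop("cannot fit the null model to an all-zero count matrix")
  fractions <- as.numeric(Matrix::colSums(X$counts)) / total
  structure(
    list(depths = depths, fractions = fractions, theta = theta, total = total,
         cell_ids = X$cell_ids, gene_ids = X$gene_ids),
    class = "NullFit"
  )
}

#' @export
print.NullFit <- function(x, ...) {
  cat(sprintf("NullFit: %d cells, %d genes, theta = %s, total counts = %g\n",
              length(x$depths), length(x$fractions),
              if (is_poisson_theta(x$theta)) "Inf (Poisson)" else format(x$theta),
              x$total))
  invisible(x)
}

#' Evaluate the fitted null means
#'
#' Lazily evaluates \eqn{\hat\mu_{cg} = \hat n_c \hat p_g} for the requested
#' cells and genes without ever storing the full dense matrix unless asked
#' for all of it.
#'
#' @param fit a `NullFit`
#' @param cells row indices (default all)
#' @param genes column indices (default all)
#' @return dense matrix of fitted means for the requested block
#' @export
predict_mu <- function(fit, cells = NULL, genes = NULL) {
  stopifnot(inherits(fit, "NullFit"))
  if (is.null(cells)) cells <- seq_along(fit$depths)
  if (is.null(genes)) genes <- seq_along(fit$fractions)
  outer(fit$depths[cells], fit$fractions[genes])
}

# internal: resolve a clip spec to a numeric bound (or NULL for no clipping)
resolve_clip <- function(clip, n_cells) {
  if (is.null(clip) || (is.character(clip) && identical(clip, "none"))) return(NULL)
  if (is.character(clip)) {
    if (!identical(clip, "sqrt_n")) stop("unknown clip spec: ", clip)
    return(sqrt(n_cells))
  }
  if (!is.numeric(clip) || length(clip) != 1 || clip < 0) {
    stop("`clip` must be \"sqrt_n\", \"none\"/NULL, or a non-negative number")
  }
  clip
}

# internal: residuals for one gene column given dense counts x and means mu.
# Zero-count genes (mu identically 0) get residual 0 by convention.
residual_column <- function(x, mu, kind, theta) {
  if (all(mu == 0)) return(numeric(length(x)))
  if (kind == "pearson") {
    sd <- if (is_poisson_theta(theta)) sqrt(mu) else sqrt(mu + mu^2 / theta)
    z <- (x - mu) / pmax(sd, 1e-300)
  } else {
    # deviance residuals; x*log(x/mu) with the x = 0 branch explicit
    xlx <- ifelse(x > 0, x * log(x / pmax(mu, 1e-300)), 0)
    if (is_poisson_theta(theta)) {
      dev <- 2 * (xlx - (x - mu))
    } else {
      dev <- 2 * (xlx - (x + theta) * log((x + theta) / (mu + theta)))
    }
    z <- sign(x - mu) * sqrt(pmax(dev, 0))
  }
  z
}

#' Analytic Pearson residuals
#'
#' Computes \eqn{Z_{cg} = (X_{cg} - \hat\mu_{cg}) /
#' \sqrt{\hat\mu_{cg} + \hat\mu_{cg}^2/\theta}} with \eqn{\hat\mu} the
#' closed-form null fit ([fit_null()]). \eqn{\theta = \infty} gives the
#' Poisson denominator \eqn{\sqrt{\hat\mu_{cg}}}. Residuals of genes that are
#' expressed in only a handful of cells can be arbitrarily large; clipping to
#' \eqn{\pm\sqrt{n}} (the default) bounds their influence.
#'
#' @param X a [count_matrix()]
#' @param theta shared overdispersion, positive or `Inf`; default 100
#' @param clip `"sqrt_n"` (default; bound \eqn{\sqrt{n_{cells}}}),
#'   `"none"`/`NULL`, or a non-negative numeric bound
#' @return a `ResidualMatrix`: fields `values` (dense cells-by-genes matrix),
#'   `kind`, `theta`, `clip_bound` (`NULL` if unclipped), `zero_genes`
#'   (logical flag per gene: all-zero genes whose residuals are 0 by
#'   convention), `cell_ids`, `gene_ids`.
#' @examples
#' X <- count_matrix(matrix(c(1, 2, 3, 4), 2, byrow = TRUE))
#' pearson_residuals(X, theta = Inf, clip = "none")$values
#' @export
pearson_residuals <- function(X, theta = 100, clip = "sqrt_n") {
  residual_matrix(X, kind = "pearson", theta = theta, clip = clip)
}

#' Deviance residuals
#'
#' Signed square roots of the per-entry deviance terms of the null model, so
#' that the sum of squared residuals equals the model deviance (twice the
#' log-likelihood gap to the saturated model). For the Poisson model
#' \eqn{Z_{cg} = \mathrm{sign}(X-\hat\mu)\sqrt{2[X\ln(X/\hat\mu) -
#' (X-\hat\mu)]}} with the \eqn{x\ln x} term taken as 0 at \eqn{X = 0};
#' the negative binomial form with fixed \eqn{\theta} reduces to it as
#' \eqn{\theta\to\infty}.
#'
#' @inheritParams pearson_residuals
#' @param clip default `"none"`: deviance residuals are bounded enough in
#'   practice that the field does not clip them
#' @return a `ResidualMatrix` (see [pearson_residuals()])
#' @export
deviance_residuals <- function(X, theta = Inf, clip = "none") {
  residual_matrix(X, kind = "deviance", theta = theta, clip = clip)
}

# shared dense-path residual computation
residual_matrix <- function(X, kind = c("pearson", "deviance"), theta = 100,
                            clip = "sqrt_n") {
  stopifnot(inherits(X, "CountMatrix"))
  kind <- match.arg(kind)
  check_theta(theta)
  fit <- fit_null(X, theta)
  n <- nrow(X$counts)
  bound <- resolve_clip(clip, n)
  dense <- as.matrix(X$counts)
  Z <- matrix(0, n, ncol(dense))
  for (g in seq_len(ncol(dense))) {
    Z[, g] <- residual_column(dense[, g], fit$depths * fit$fractions[g],
                              kind, theta)
  }
  if (!is.null(bound)) Z <- pmin(pmax(Z, -bound), bound)
  structure(
    list(values = Z, kind = kind, theta = theta, clip_bound = bound,
         zero_genes = fit$fractions == 0,
         cell_ids = X$cell_ids, gene_ids = X$gene_ids),
    class = "ResidualMatrix"
  )
}

#' @export
print.ResidualMatrix <- function(x, ...) {
  cat(sprintf("ResidualMatrix (%s): %d cells x %d genes, theta = %s, clip = %s\n",
              x$kind, nrow(x$values), ncol(x$values),
              if (is_poisson_theta(x$theta)) "Inf" else format(x$theta),
              if (is.null(x$clip_bound)) "none" else format(x$clip_bound)))
  invisible(x)
}

#' Per-gene residual variance, computed gene by gene
#'
#' Streams over gene columns so that peak additional memory is one dense
#' column, never the full residual matrix. Under the null model the variance
#' of Pearson residuals is close to 1 for every gene; excess variance flags
#' genes whose variation exceeds the technical expectation, which is the
#' basis of highly-variable-gene selection.
#'
#' Variances are population variances (divide by \eqn{n}), matching the
#' unit-variance convention of standardized residuals.
#'
#' @inheritParams pearson_residuals
#' @param kind `"pearson"` or `"deviance"`
#' @return numeric vector of per-gene residual variances
#' @export
residual_variance <- function(X, kind = c("pearson", "deviance"),
                              theta = 100, clip = "sqrt_n") {
  stopifnot(inherits(X, "CountMatrix"))
  kind <- match.arg(kind)
  check_theta(theta)
  fit <- fit_null(X, theta)
  n <- nrow(X$counts)
  bound <- resolve_clip(clip, n)
  m <- ncol(X$counts)
  out <- numeric(m)
  cp <- X$counts@p
  ci <- X$counts@i
  cx <- X$counts@x
  x <- numeric(n)
  for (g in seq_len(m)) {
    idx <- if (cp[g + 1] > cp[g]) (cp[g] + 1):cp[g + 1] else integer(0)
    x[] <- 0
    if (length(idx)) x[ci[idx] + 1L] <- cx[idx]
    z <- residual_column(x, fit$depths * fit$fractions[g], kind, theta)
    if (!is.null(bound)) z <- pmin(pmax(z, -bound), bound)
    out[g] <- mean(z^2) - mean(z)^2
  }
  out
}

#' Analytic intercepts of the offset regression model
#'
#' In the offset parametrization \eqn{\ln\mu_{cg} = \beta_{0g} + \ln n_c}
#' the slope on log-depth is fixed to 1 and the single free parameter has
#' the closed form \eqn{\hat\beta_{0g} = \ln(\sum_c X_{cg} / \sum_c n_c)},
#' i.e. log mean expression minus log mean depth. This is also the intercept
#' of the rank-one intercept-only Poisson GLM-PCA.
#'
#' @param X a [count_matrix()]; every cell must have depth > 0
#' @return numeric vector \eqn{\hat\beta_{0g}}; genes with zero total count
#'   give `-Inf` and are flagged in the `"zero_genes"` attribute
#' @export
offset_intercepts <- function(X) {
  stopifnot(inherits(X, "CountMatrix"))
  depths <- sequencing_depths(X)
  if (any(depths == 0)) stop("every cell must have sequencing depth > 0")
  totals <- as.numeric(Matrix::colSums(X$counts))
  b0 <- log(totals / sum(depths))
  attr(b0, "zero_genes") <- totals == 0
  b0
}

#' Poisson log-likelihood of the rank-one model (up to a constant)
#'
#' \eqn{\mathcal{L} = \sum_{cg} [X_{cg}\ln(n_c p_g) - n_c p_g]}. Serves as
#' the objective surface whose maximizer is the closed-form null fit; used
#' by the test suite as an oracle for [fit_null()].
#'
#' @param X a [count_matrix()]
#' @param depths per-cell positive reals \eqn{n_c}
#' @param fractions per-gene reals \eqn{p_g}, positive wherever the gene has
#'   counts
#' @return scalar log-likelihood up to an additive constant
#' @export
poisson_loglik <- function(X, depths, fractions) {
  stopifnot(inherits(X, "CountMatrix"))
  tm <- methods::as(X$counts, "TsparseMatrix")
  i <- tm@i + 1L
  j <- tm@j + 1L
  x <- tm@x
  mu_nz <- depths[i] * fractions[j]
  if (any(mu_nz <= 0)) stop("fractions must be positive wherever the gene has counts")
  sum(x * log(mu_nz)) - sum(depths) * sum(fractions)
}

#' Negative binomial log-likelihood of the rank-one model (up to a constant)
#'
#' For fixed \eqn{\theta}:
#' \eqn{\mathcal{L} = \sum_{cg} [X_{cg}\ln(n_c p_g) -
#' (X_{cg}+\theta)\ln(n_c p_g + \theta)]}. Unlike the Poisson case this has
#' no closed-form maximizer, but for large \eqn{\theta} the Poisson solution
#' is an approximate maximizer. Evaluates the dense mean matrix, so intended
#' for small diagnostic inputs.
#'
#' @inheritParams poisson_loglik
#' @param theta positive overdispersion (finite)
#' @return scalar log-likelihood up to an additive constant
#' @export
nb_loglik <- function(X, depths, fractions, theta) {
  stopifnot(inherits(X, "CountMatrix"))
  if (!is.finite(theta) || theta <= 0) stop("`theta` must be a finite positive number")
  mu <- outer(depths, fractions)
  xd <- as.matrix(X$counts)
  if (any(mu[xd > 0] <= 0)) stop("fractions must be positive wherever the gene has counts")
  lognp <- ifelse(xd > 0, log(pmax(mu, 1e-300)), 0)
  sum(xd * lognp - (xd + theta) * log(mu + theta))
}

#' Negative binomial density used by the shared-theta model
#'
#' Thin wrapper around [stats::dnbinom()] in the \eqn{(\mu, \theta)}
#' parametrization with variance \eqn{\mu + \mu^2/\theta}; `theta = Inf`
#' falls back to the Poisson density.
#'
#' @param x non-negative integer quantiles
#' @param mu mean
#' @param theta overdispersion, positive or `Inf`
#' @param log return log density?
#' @export
dnb <- function(x, mu, theta, log = FALSE) {
  check_theta(theta)
  if (is_poisson_theta(theta)) return(stats::dpois(x, mu, log = log))
  stats::dnbinom(x, size = theta, mu = mu, log = log)
}

#' Expected Pearson residual of a rare-population marker gene
#'
#' For a dataset of `n` cells with equal depths containing a rare population
#' of `m` cells in which a marker gene is Poisson(`lambda`) and zero
#' elsewhere, the expected residual of the marker in the population cells is
#' \eqn{(n-m)\sqrt{\lambda/(nm)} \approx \sqrt{\lambda n/m}}. Comparing this
#' to the clip bound \eqn{\sqrt n} shows that clipping engages exactly when
#' \eqn{\lambda > m}: a population of `m` cells with within-population mean
#' above `m` UMIs is represented as if its mean were `m` UMIs.
#'
#' @param lambda within-population mean expression (UMIs)
#' @param m number of cells in the rare population
#' @param n total number of cells
#' @return the expected Pearson residual \eqn{(n-m)\sqrt{\lambda/(nm)}}
#' @seealso [clip_implied_mean()]
#' @export
expected_marker_residual <- function(lambda, m, n) {
  stopifnot(lambda >= 0, m > 0, n > m)
  (n - m) * sqrt(lambda / (n * m))
}

#' Within-population mean implied by sqrt(n) clipping
#'
#' Solves \eqn{\sqrt{\lambda n / m} = \sqrt{n}} for \eqn{\lambda}: the
#' largest within-population mean expression that a rare population of `m`
#' cells can exhibit before its marker residuals are truncated by the
#' \eqn{\pm\sqrt n} clip. The root is found numerically on the approximate
#' expected-residual curve; analytically it equals `m`.
#'
#' @param m number of cells in the rare population
#' @param n total number of cells
#' @return the implied within-population mean (in UMIs)
#' @export
clip_implied_mean <- function(m, n) {
  stopifnot(m > 0, n > m)
  f <- function(lambda) sqrt(lambda * n / m) - sqrt(n)
  stats::uniroot(f, lower = 1e-9, upper = n, tol = 1e-12)$root
}
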