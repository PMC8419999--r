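#' Specification of a synthetic UMI dataset
#'
#' Bundles the parameters of the null count model used by all generators:
#' number of cells and genes, the sequencing depth distribution, the gene
#' expression fraction distribution, the shared overdispersion, and the
#' seed. All generators are pure functions of the spec (including its
#' seed): identical specs give bit-identical output.
#'
#' Depth models: `list(type = "lognormal", mean_depth, sdlog)` draws
#' integer depths from a lognormal with the given arithmetic mean
#' (default 2000 UMIs, a typical droplet experiment) and log-sd
#' (default 0.5); `list(type = "empirical", depths = ...)` uses a given
#' depth vector. Fraction models: `list(type = "power_law", exponent)`
#' sets \eqn{p_g \propto g^{-exponent}} (default exponent 1, the Zipf-like
#' decay of transcriptome fractions, spanning several decades of mean
#' expression); `list(type = "dirichlet", alpha)` draws fractions from a
#' symmetric Dirichlet; `list(type = "explicit", fractions = ...)` uses a
#' given vector (renormalized).
#'
#' @param n_cells number of cells
#' @param n_genes number of genes
#' @param depth_model see Details
#' @param fraction_model see Details
#' @param theta shared overdispersion; `Inf` (default) simulates Poisson
#' @param seed integer seed recorded in all outputs
#' @return object of class `SimulationSpec`
#' @export
simulation_spec <- function(n_cells = 2000L, n_genes = 1000L,
                            depth_model = list(type = "lognormal",
                                               mean_depth = 2000, sdlog = 0.5),
                            fraction_model = list(type = "power_law",
                                                  exponent = 1),
                            theta = Inf, seed = 1L) {
  if (n_cells < 1 || n_genes < 1) stop("degenerate spec: need >= 1 cell and gene")
  check_theta(theta)
  stopifnot(is.list(depth_model), !is.null(depth_model$type),
            is.list(fraction_model), !is.null(fraction_model$type))
  structure(
    list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
         depth_model = depth_model, fraction_model = fraction_model,
         theta = theta, seed = as.integer(seed)),
    class = "SimulationSpec"
  )
}

# draw per-cell integer depths according to the spec (uses the RNG stream)
sample_depths <- function(spec) {
  dm <- spec$depth_model
  d <- switch(dm$type,
    lognormal = {
      sdlog <- if (is.null(dm$sdlog)) 0.5 else dm$sdlog
      meanlog <- log(dm$mean_depth) - sdlog^2 / 2
      round(stats::rlnorm(spec$n_cells, meanlog, sdlog))
    },
    empirical = {
      if (length(dm$depths) != spec$n_cells) {
        stop("empirical depth model must supply n_cells depths")
      }
      round(dm$depths)
    },
    stop("unknown depth model: ", dm$type)
  )
  pmax(d, 1)
}

# per-gene expression fractions summing to 1 (may use the RNG stream)
sample_fractions <- function(spec) {
  fm <- spec$fraction_model
  p <- switch(fm$type,
    power_law = {
      ex <- if (is.null(fm$exponent)) 1 else fm$exponent
      seq_len(spec$n_genes)^(-ex)
    },
    dirichlet = {
      a <- if (is.null(fm$alpha)) 1 else fm$alpha
      stats::rgamma(spec$n_genes, shape = a)
    },
    explicit = {
      if (length(fm$fractions) != spec$n_genes) {
        stop("explicit fraction model must supply n_genes fractions")
      }
      fm$fractions
    },
    stop("unknown fraction model: ", fm$type)
  )
  if (any(p < 0)) stop("fractions must be non-negative")
  p / sum(p)
}

#' Draw the null model parameters of a simulation spec
#'
#' Draws depths and fractions only (no counts), so replicate count matrices
#' can be generated conditional on fixed parameters.
#'
#' @param spec a [simulation_spec()]
#' @return list with `depths` and `fractions`
#' @export
null_model_params <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)
  list(depths = sample_depths(spec), fractions = sample_fractions(spec))
}

# sparse column-wise count sampler: X[, g] ~ Poisson(depths * p_g) or NB
sample_count_columns <- function(depths, fractions, theta) {
  n <- length(depths)
  ii <- list(); jj <- list(); xx <- list()
  for (g in seq_along(fractions)) {
    mu <- depths * fractions[g]
    x <- if (is_poisson_theta(theta)) {
      stats::rpois(n, mu)
    } else {
      stats::rnbinom(n, size = theta, mu = mu)
    }
    nz <- which(x > 0)
    if (length(nz)) {
      ii[[g]] <- nz; jj[[g]] <- rep.int(g, length(nz)); xx[[g]] <- x[nz]
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, length(fractions)))
}

#' Simulate a null UMI count matrix
#'
#' Draws \eqn{X_{cg} \sim Poisson(n_c p_g)} (or NB with the spec's
#' \eqn{\theta}) after sampling depths and fractions from the spec. The
#' realized per-cell totals differ from the target depths by sampling
#' noise. Under this generator every gene's variation is purely technical,
#' so Pearson residual variances concentrate near 1.
#'
#' @param spec a [simulation_spec()]
#' @param params optional pre-drawn `list(depths, fractions)` from
#'   [null_model_params()]; when supplied, only counts are drawn (the seed
#'   still initializes the RNG)
#' @return a [count_matrix()]; the spec is attached as attribute `"spec"`
#' @export
simulate_null <- function(spec, params = NULL) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)
  if (is.null(params)) {
    params <- list(depths = sample_depths(spec),
                   fractions = sample_fractions(spec))
  }
  counts <- sample_count_columns(params$depths, params$fractions, spec$theta)
  X <- count_matrix(counts)
  attr(X, "spec") <- spec
  attr(X, "params") <- params
  X
}

#' Simulate a negative-control grid over overdispersion values
#'
#' Emulates negative control experiments (droplets of homogeneous RNA, no
#' biological variability) at several known overdispersion values: one null
#' dataset per \eqn{\theta} in the grid, all sharing the same depths and
#' fractions so that only the noise model differs. The canonical grid is
#' \eqn{\theta \in \{10, 100, 1000, \infty\}}.
#'
#' @param spec a [simulation_spec()] (its own `theta` is ignored)
#' @param theta_grid numeric vector of overdispersion values; `Inf` = Poisson
#' @return named list of [count_matrix()] objects, one per grid value
#' @export
simulate_negative_control <- function(spec,
                                      theta_grid = c(10, 100, 1000, Inf)) {
  stopifnot(inherits(spec, "SimulationSpec"), length(theta_grid) >= 1)
  params <- null_model_params(spec)
  out <- vector("list", length(theta_grid))
  for (k in seq_along(theta_grid)) {
    check_theta(theta_grid[k])
    set.seed(spec$seed + k)
    counts <- sample_count_columns(params$depths, params$fractions,
                                   theta_grid[k])
    X <- count_matrix(counts)
    attr(X, "spec") <- spec
    attr(X, "theta") <- theta_grid[k]
    out[[k]] <- X
  }
  names(out) <- ifelse(is.infinite(theta_grid), "Inf",
                       format(theta_grid, trim = TRUE))
  out
}

#' Simulate a labeled multi-type benchmark with an injected rare population
#'
#' Builds a dataset emulating a FACS-sorted multi-type mixture: `n_types`
#' populations of 400-600 cells each, with distinct expression fraction
#' profiles, plus a ninth, artificial, rare type created by taking
#' `rare_cells` cells of the first (donor) type and appending
#' `n_pseudo_genes` pseudo marker genes that are Poisson(\eqn{n_i p}) in
#' those cells (with \eqn{p} = `p_pseudo`, default 0.001) and exactly zero
#' elsewhere. Between-type differences use a synthetic stand-in (real
#' mixtures come from sorted cells): each type up-regulates its own
#' disjoint block of `n_marker_genes` genes by `marker_fold`.
#'
#' @param spec a [simulation_spec()] providing `n_genes`, the depth model,
#'   the base fraction model and the noise model; `spec$n_cells` is ignored
#'   in favor of the per-type sizes
#' @param n_types number of base cell types (default 8)
#' @param cells_per_type integer range from which each type's size is drawn
#'   uniformly (default `c(400, 600)`)
#' @param rare_cells size of the injected rare population (default 50)
#' @param n_pseudo_genes number of appended pseudo marker genes (default 10)
#' @param p_pseudo expression fraction of each pseudo gene in rare cells
#'   (default 0.001, i.e. 5 expected UMIs at depth 5000)
#' @param n_marker_genes genes up-regulated per type (default 30)
#' @param marker_fold fold change of the up-regulated block (default 4)
#' @param seed integer seed; overrides `spec$seed` when given
#' @return a `LabeledDataset`: `counts` (a [count_matrix()]), `labels`
#'   (per-cell type, rare cells labeled `"rare"`), and `truth` (generating
#'   parameters: per-type fractions, rare cell indices, pseudo gene ids,
#'   seed)
#' @export
make_benchmark <- function(spec, n_types = 8L, cells_per_type = c(400L, 600L),
                           rare_cells = 50L, n_pseudo_genes = 10L,
                           p_pseudo = 0.001, n_marker_genes = 30L,
                           marker_fold = 4, seed = NULL) {
  stopifnot(inherits(spec, "SimulationSpec"), n_types >= 1)
  if (p_pseudo <= 0) stop("`p_pseudo` must be positive")
  if (n_types * n_marker_genes > spec$n_genes) {
    stop("not enough genes for disjoint marker blocks")
  }
  if (is.null(seed)) seed <- spec$seed
  set.seed(seed)
  sizes <- sample(seq(cells_per_type[1], cells_per_type[2]), n_types,
                  replace = TRUE)
  if (rare_cells > sizes[1]) {
    stop("`rare_cells` exceeds the size of the donor type")
  }
  n <- sum(sizes)
  type_of <- rep(seq_len(n_types), sizes)
  depths <- sample_depths(
    simulation_spec(n, spec$n_genes, spec$depth_model, spec$fraction_model,
                    spec$theta, seed)
  )
  base_p <- sample_fractions(spec)
  # per-type fraction profiles: disjoint up-regulated marker blocks
  type_p <- matrix(rep(base_p, n_types), nrow = n_types, byrow = TRUE)
  marker_blocks <- vector("list", n_types)
  for (t in seq_len(n_types)) {
    block <- ((t - 1) * n_marker_genes + 1):(t * n_marker_genes)
    marker_blocks[[t]] <- block
    type_p[t, block] <- type_p[t, block] * marker_fold
    type_p[t, ] <- type_p[t, ] / sum(type_p[t, ])
  }
  # draw counts gene by gene with type-specific fractions
  ii <- list(); jj <- list(); xx <- list()
  for (g in seq_len(spec$n_genes)) {
    mu <- depths * type_p[cbind(type_of, g)]
    x <- if (is_poisson_theta(spec$theta)) {
      stats::rpois(n, mu)
    } else {
      stats::rnbinom(n, size = spec$theta, mu = mu)
    }
    nz <- which(x > 0)
    if (length(nz)) {
      ii[[g]] <- nz; jj[[g]] <- rep.int(g, length(nz)); xx[[g]] <- x[nz]
    }
  }
  # rare type: rare_cells cells of the donor (first) type get pseudo genes
  donor_cells <- which(type_of == 1L)
  rare_idx <- sort(sample(donor_cells, rare_cells))
  g0 <- spec$n_genes
  for (k in seq_len(n_pseudo_genes)) {
    x <- stats::rpois(rare_cells, depths[rare_idx] * p_pseudo)
    nz <- which(x > 0)
    if (length(nz)) {
      ii[[g0 + k]] <- rare_idx[nz]
      jj[[g0 + k]] <- rep.int(g0 + k, length(nz))
      xx[[g0 + k]] <- x[nz]
    }
  }
  counts <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                 x = unlist(xx),
                                 dims = c(n, g0 + n_pseudo_genes))
  gene_ids <- c(paste0("gene_", seq_len(g0)),
                paste0("pseudo_", seq_len(n_pseudo_genes)))
  labels <- paste0("type_", type_of)
  labels[rare_idx] <- "rare"
  X <- count_matrix(counts, gene_ids = gene_ids)
  structure(
    list(counts = X, labels = labels,
         truth = list(type_fractions = type_p, marker_blocks = marker_blocks,
                      rare_cells = rare_idx,
                      pseudo_gene_ids = paste0("pseudo_",
                                               seq_len(n_pseudo_genes)),
                      p_pseudo = p_pseudo, depths = depths, seed = seed)),
    class = "LabeledDataset"
  )
}

#' @export
print.LabeledDataset <- function(x, ...) {
  cat(sprintf("LabeledDataset: %d cells x %d genes, %d classes (%s)\n",
              nrow(x$counts$counts), ncol(x$counts$counts),
              length(unique(x$labels)),
              paste(names(sort(table(x$labels))), collapse = ", ")))
  invisible(x)
}
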