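# small fixture builders shared across test files

toy22 <- function() count_matrix(matrix(c(1, 2, 3, 4), 2, byrow = TRUE))

# exactly rank-one integer matrix: X_cg = a_c * b_g
rank_one_matrix <- function(a = c(1, 2, 3), b = c(2, 1, 4)) {
  count_matrix(outer(a, b))
}

# random small count matrix with no all-zero rows or columns
random_counts <- function(n, m, lambda = 1.3, max_entry = Inf) {
  repeat {
    x <- matrix(stats::rpois(n * m, lambda), n, m)
    x <- pmin(x, max_entry)
    if (all(rowSums(x) > 0) && all(colSums(x) > 0)) return(count_matrix(x))
  }
}

# deterministic two-fold-change construction: gene A has exactly mu UMIs in
# half the cells and 2*mu in the other half; gene B fills depths to equal
twofold_matrix <- function(mu = 40, n = 100, depth = 200) {
  a <- rep(c(mu, 2 * mu), each = n / 2)
  count_matrix(cbind(a, depth - a))
}

small_benchmark <- function(seed = 20) {
  spec <- simulation_spec(n_genes = 800, seed = seed)
  suppressMessages(
    make_benchmark(spec, n_types = 4, cells_per_type = c(150, 200),
                   rare_cells = 30, n_marker_genes = 30, seed = seed)
  )
}
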