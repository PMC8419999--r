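test_that("generators are pure functions of spec and seed", {
  spec <- simulation_spec(n_cells = 100, n_genes = 50, seed = 5)
  X1 <- simulate_null(spec)
  X2 <- simulate_null(spec)
  expect_identical(as.matrix(X1$counts), as.matrix(X2$counts))
  X3 <- simulate_null(simulation_spec(n_cells = 100, n_genes = 50, seed = 6))
  expect_false(identical(as.matrix(X1$counts), as.matrix(X3$counts)))
  ds1 <- make_benchmark(spec, n_types = 3, cells_per_type = c(50, 60),
                        rare_cells = 10, n_marker_genes = 10)
  ds2 <- make_benchmark(spec, n_types = 3, cells_per_type = c(50, 60),
                        rare_cells = 10, n_marker_genes = 10)
  expect_identical(as.matrix(ds1$counts$counts), as.matrix(ds2$counts$counts))
  expect_identical(ds1$labels, ds2$labels)
})

test_that("spec validation rejects degenerate input", {
  expect_error(simulation_spec(n_cells = 0), "degenerate")
  expect_error(simulation_spec(theta = -1), "theta")
  expect_error(simulate_null(
    simulation_spec(10, 5, fraction_model = list(type = "explicit",
                                                 fractions = c(1, 1)))),
    "n_genes")
})

test_that("simulated counts have the requested marginal means", {
  spec <- simulation_spec(
    n_cells = 50, n_genes = 20,
    depth_model = list(type = "lognormal", mean_depth = 1000, sdlog = 0.5),
    seed = 71)
  params <- null_model_params(spec)
  acc <- matrix(0, 50, 20)
  for (r in 1:200) {
    rep_spec <- spec
    rep_spec$seed <- 71000 + r
    Xr <- simulate_null(rep_spec, params = params)
    acc <- acc + as.matrix(Xr$counts)
  }
  expected_gene_means <- mean(params$depths) * params$fractions
  observed_gene_means <- colMeans(acc / 200)
  expect_lt(max(abs(observed_gene_means / expected_gene_means - 1)), 0.02)
})

test_that("NB simulation matches the mu + mu^2/theta variance law", {
  n <- 20000
  spec <- simulation_spec(
    n_cells = n, n_genes = 5,
    depth_model = list(type = "empirical", depths = rep(100, n)),
    fraction_model = list(type = "explicit", fractions = rep(0.2, 5)),
    theta = 10, seed = 81)
  X <- simulate_null(spec)
  for (g in 1:5) {
    x <- as.numeric(X$counts[, g])
    expect_equal(stats::var(x), 20 + 400 / 10, tolerance = 0.1)
  }
  # theta = 10 null: unclipped Poisson-Pearson variance tracks 1 + mean/10
  spec2 <- simulation_spec(n_cells = 2000, n_genes = 100, theta = 10, seed = 82)
  X2 <- simulate_null(spec2)
  v <- residual_variance(X2, "pearson", theta = Inf, clip = "none")
  mu_bar <- as.numeric(Matrix::colSums(X2$counts)) / 2000
  expect_lt(abs(stats::median(v / (1 + mu_bar / 10)) - 1), 0.15)
  expect_gt(stats::cor(v, 1 + mu_bar / 10), 0.9)
})

test_that("negative control grid shares parameters and recovers theta ordering", {
  spec <- simulation_spec(n_cells = 500, n_genes = 200, seed = 31)
  grid <- simulate_negative_control(spec, c(10, 100, 1000, Inf))
  expect_named(grid, c("10", "100", "1000", "Inf"))
  # same depths and fractions: only the noise differs, so column sums are close
  cs <- sapply(grid, function(X) sum(X$counts))
  expect_lt(max(abs(cs / cs[1] - 1)), 0.1)
  ests <- sapply(grid, function(X) fit_theta_shared(X)$theta_hat)
  expect_identical(unname(ests[4]), Inf)        # Poisson hits the guard
  expect_true(all(diff(ests[1:3]) > 0))         # ordering recovered
  expect_lt(abs(ests[1] - 10) / 10, 0.5)
  expect_lt(abs(log10(ests[2] / 100)), 0.5)
  # per-gene estimates for high-mean genes on the theta = 100 dataset
  X <- grid[["100"]]
  me <- as.numeric(Matrix::colSums(X$counts)) / nrow(X$counts)
  hi <- which(me >= 50)
  f <- fit_null(X, Inf)
  ths <- vapply(hi, function(g) {
    fit_theta_mle(as.numeric(X$counts[, g]), predict_mu(f, genes = g)[, 1],
                  max_iter = 100)$theta_hat
  }, 0)
  expect_lt(abs(log10(stats::median(ths) / 100)), log10(2))
})

test_that("benchmark construction injects the rare type as documented", {
  spec <- simulation_spec(n_genes = 300, seed = 91)
  ds <- make_benchmark(spec, n_types = 3, cells_per_type = c(100, 150),
                       rare_cells = 20, n_pseudo_genes = 10,
                       n_marker_genes = 20, seed = 91)
  n <- nrow(ds$counts$counts)
  expect_equal(length(ds$labels), n)
  expect_equal(sum(ds$labels == "rare"), 20)
  expect_equal(ncol(ds$counts$counts), 310)
  # pseudo genes are exactly zero outside the rare cells
  pseudo_cols <- which(ds$counts$gene_ids %in% ds$truth$pseudo_gene_ids)
  sub <- as.matrix(ds$counts$counts[-ds$truth$rare_cells, pseudo_cols])
  expect_equal(sum(sub), 0)
  # expected pseudo count scales as depth * p (5000 * 0.001 = 5)
  expect_equal(5000 * ds$truth$p_pseudo, 5)
  expect_error(make_benchmark(spec, p_pseudo = 0), "p_pseudo")
  expect_error(make_benchmark(spec, n_types = 2, cells_per_type = c(30, 40),
                              rare_cells = 100, n_marker_genes = 10),
               "donor")
})

test_that("pseudo gene counts follow Poisson(depth * p) on average", {
  set.seed(92)
  n_reps <- 200
  tot <- 0
  spec <- simulation_spec(
    n_genes = 100,
    depth_model = list(type = "lognormal", mean_depth = 5000, sdlog = 0.3),
    seed = 92)
  for (r in 1:n_reps) {
    ds <- make_benchmark(spec, n_types = 2, cells_per_type = c(60, 80),
                         rare_cells = 30, n_pseudo_genes = 2,
                         n_marker_genes = 10, seed = 92000 + r)
    pseudo_cols <- which(ds$counts$gene_ids %in% ds$truth$pseudo_gene_ids)
    obs <- sum(ds$counts$counts[ds$truth$rare_cells, pseudo_cols])
    exp_count <- 2 * sum(ds$truth$depths[ds$truth$rare_cells]) * 0.001
    tot <- tot + obs / exp_count
  }
  expect_equal(tot / n_reps, 1, tolerance = 0.05)
})

test_that("null simulation yields unit Pearson residual variance", {
  X <- simulate_null(simulation_spec(n_cells = 1000, n_genes = 300, seed = 14))
  v <- residual_variance(X, "pearson", theta = Inf, clip = "sqrt_n")
  expect_lt(abs(stats::median(v) - 1), 0.1)
  expect_gt(mean(abs(v - 1) < 0.3), 0.9)   # most genes near 1
})
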