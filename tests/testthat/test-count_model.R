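test_that("sequencing_depths are row sums", {
  expect_equal(sequencing_depths(toy22()), c(3, 7))
  expect_equal(sequencing_depths(count_matrix(matrix(0, 2, 3))), c(0, 0))
  expect_equal(sequencing_depths(count_matrix(matrix(c(0, 0, 5, 0), 2))), c(5, 0))
})

test_that("count_matrix validates its input", {
  expect_error(count_matrix(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  expect_error(count_matrix(matrix(c(1.5, 2, 3, 4), 2)), "integral")
  expect_error(count_matrix(matrix(1, 2, 2), cell_ids = "only_one"), "cell_ids")
})

test_that("fit_null reproduces the closed-form solution", {
  # uniform matrix: mu = 2*2/4 = 1 everywhere
  expect_equal(predict_mu(fit_null(count_matrix(matrix(1, 2, 2)))),
               matrix(1, 2, 2))
  # direct evaluation of row*col/total
  expect_equal(predict_mu(fit_null(toy22())),
               matrix(c(1.2, 2.8, 1.8, 4.2), 2))
  # exactly rank-one input is reproduced by its margins
  X <- rank_one_matrix()
  expect_equal(predict_mu(fit_null(X)), as.matrix(X$counts))
  # fractions sum to one
  expect_equal(sum(fit_null(toy22())$fractions), 1, tolerance = 1e-12)
  expect_error(fit_null(count_matrix(matrix(0, 2, 2))), "all-zero")
  expect_error(fit_null(toy22(), theta = -1), "theta")
})

test_that("margins of the fitted means are preserved exactly", {
  set.seed(101)
  for (rep in 1:10) {
    X <- random_counts(sample(3:8, 1), sample(3:8, 1))
    mu <- predict_mu(fit_null(X))
    expect_equal(rowSums(mu), sequencing_depths(X), tolerance = 1e-12)
    expect_equal(colSums(mu), as.numeric(Matrix::colSums(X$counts)),
                 tolerance = 1e-12)
    # hence residual numerators sum to zero per gene and per cell
    delta <- as.matrix(X$counts) - mu
    expect_lt(max(abs(colSums(delta))), 1e-10)
    expect_lt(max(abs(rowSums(delta))), 1e-10)
  }
})

test_that("analytic solution maximizes the Poisson likelihood (optim oracle)", {
  set.seed(9)
  for (rep in 1:15) {
    X <- random_counts(4, 4, lambda = 1.3, max_entry = 5)
    fit <- fit_null(X, Inf)
    l_analytic <- poisson_loglik(X, fit$depths, fit$fractions)
    obj <- function(par) -poisson_loglik(X, exp(par[1:4]), exp(par[5:8]))
    par0 <- c(log(fit$depths * stats::runif(4, 0.5, 2)),
              log(fit$fractions * stats::runif(4, 0.5, 2)))
    best <- stats::optim(par0, obj, method = "BFGS",
                         control = list(maxit = 500, reltol = 1e-14))$value
    expect_lte(-best, l_analytic + 1e-6)
    expect_gte(l_analytic, -best - 1e-6)
  }
})

test_that("poisson_loglik evaluates the closed form", {
  X1 <- count_matrix(matrix(1))
  expect_equal(poisson_loglik(X1, 1, 1), -1)
  expect_error(poisson_loglik(toy22(), c(3, 7), c(0, 1)), "positive")
})

test_that("pearson residuals match hand evaluation and vanish on rank-one input", {
  Z <- pearson_residuals(toy22(), theta = Inf, clip = "none")$values
  expect_equal(Z[1, 1], (1 - 1.2) / sqrt(1.2), tolerance = 1e-12)
  expect_equal(Z, matrix(c(-0.2 / sqrt(1.2), 0.2 / sqrt(2.8),
                           0.2 / sqrt(1.8), -0.2 / sqrt(4.2)), 2),
               tolerance = 1e-12)
  X <- rank_one_matrix()
  expect_equal(pearson_residuals(X, clip = "none")$values,
               matrix(0, 3, 3))
})

test_that("zero-count genes give residual 0 and are flagged", {
  X <- count_matrix(matrix(c(1, 2, 0, 0, 3, 1), 2))
  R <- pearson_residuals(X, clip = "none")
  expect_equal(R$values[, 2], c(0, 0))
  expect_equal(R$zero_genes, c(FALSE, TRUE, FALSE))
  b0 <- offset_intercepts(X)
  expect_equal(b0[2], -Inf)
  expect_equal(attr(b0, "zero_genes"), c(FALSE, TRUE, FALSE))
})

test_that("deviance residuals satisfy their closed forms and the deviance identity", {
  # rank-one input: saturated and fitted model coincide
  expect_equal(deviance_residuals(rank_one_matrix())$values, matrix(0, 3, 3))
  # zero count, mean m: Z = -sqrt(2m)
  X <- count_matrix(matrix(c(0, 2, 4, 2), 2))
  mu <- predict_mu(fit_null(X))
  Z <- deviance_residuals(X, theta = Inf)$values
  expect_equal(Z[1, 1], -sqrt(2 * mu[1, 1]), tolerance = 1e-12)
  # sum of squared residuals equals the deviance
  set.seed(33)
  X <- random_counts(10, 6, lambda = 2)
  mu <- predict_mu(fit_null(X))
  xd <- as.matrix(X$counts)
  dev <- 2 * sum(ifelse(xd > 0, xd * log(xd / mu), 0) - (xd - mu))
  Z <- deviance_residuals(X, theta = Inf)$values
  expect_equal(sum(Z^2), dev, tolerance = 1e-10)
})

test_that("NB residuals converge monotonically to the Poisson limit", {
  set.seed(44)
  X <- random_counts(6, 5, lambda = 3)
  for (kind in c("pearson", "deviance")) {
    fn <- if (kind == "pearson") pearson_residuals else deviance_residuals
    Zp <- fn(X, theta = Inf, clip = "none")$values
    Zbig <- fn(X, theta = 1e8, clip = "none")$values
    expect_equal(Zbig, Zp, tolerance = 1e-3)
    prev <- abs(fn(X, theta = 1, clip = "none")$values)
    for (th in c(10, 100, 1000)) {
      cur <- abs(fn(X, theta = th, clip = "none")$values)
      expect_true(all(cur >= prev - 1e-12))
      expect_true(all(cur <= abs(Zp) + 1e-12))
      prev <- cur
    }
  }
})

test_that("nb_loglik approaches the Poisson surface for large theta", {
  set.seed(55)
  X <- random_counts(3, 3, lambda = 2)
  fit <- fit_null(X, Inf)
  # argmax over fractions at theta = 1e8 is within 1e-4 of the analytic one
  obj <- function(lp) {
    p <- exp(lp) / sum(exp(lp))
    -nb_loglik(X, fit$depths, p, theta = 1e8)
  }
  o <- stats::optim(log(fit$fractions), obj, method = "BFGS",
                    control = list(reltol = 1e-14))
  p_hat <- exp(o$par) / sum(exp(o$par))
  expect_lt(max(abs(p_hat - fit$fractions)), 1e-4)
  # finite-difference gradient in (depths, fractions) vanishes at the
  # analytic solution as theta grows
  num_grad <- function(theta) {
    h <- 1e-6
    g <- numeric(3)
    for (j in 1:3) {
      p1 <- fit$fractions; p1[j] <- p1[j] + h
      p2 <- fit$fractions; p2[j] <- p2[j] - h
      g[j] <- (nb_loglik(X, fit$depths, p1, theta) -
                 nb_loglik(X, fit$depths, p2, theta)) / (2 * h)
    }
    g
  }
  expect_lt(max(abs(num_grad(1e8))), 1e-3)
  expect_error(nb_loglik(X, fit$depths, fit$fractions, theta = -2), "theta")
})

test_that("NB density is a proper distribution", {
  expect_equal(sum(dnb(0:2000, mu = 2, theta = 5)), 1, tolerance = 1e-12)
  expect_equal(dnb(0:50, mu = 3, theta = Inf), stats::dpois(0:50, 3))
})

test_that("offset intercepts are log mean expression minus log mean depth", {
  X <- count_matrix(matrix(1, 2, 4))
  expect_equal(as.numeric(offset_intercepts(X)), rep(log(1 / 4), 4))
  expect_equal(as.numeric(offset_intercepts(toy22())), log(c(0.4, 0.6)))
  set.seed(66)
  X <- random_counts(20, 8, lambda = 2)
  b0 <- as.numeric(offset_intercepts(X))
  mean_expr <- as.numeric(Matrix::colSums(X$counts)) / 20
  mean_depth <- mean(sequencing_depths(X))
  # exact straight line of slope 1 against log mean expression
  expect_equal(b0, log(mean_expr) - log(mean_depth), tolerance = 1e-12)
})

test_that("offset model equals iterative rank-one GLM-PCA fit", {
  set.seed(8)
  X <- random_counts(100, 10, lambda = 2)
  d <- sequencing_depths(X)
  b0 <- offset_intercepts(X)
  dense <- as.matrix(X$counts)
  for (g in seq_len(10)) {
    fit <- umiresid:::irls_poisson_loglinear(dense[, g], t_c = log(d),
                                             offset = log(d), tol = 1e-12,
                                             max_iter = 50)
    expect_equal(fit$beta0, b0[g], tolerance = 1e-8)
  }
})

test_that("clipping truncates at sqrt(n) exactly", {
  set.seed(77)
  n <- 64
  x <- c(stats::rpois(n - 3, 1), 50, 80, 120)  # a few extreme cells
  X <- count_matrix(cbind(x, pmax(200 - x, 0)))
  R <- pearson_residuals(X, theta = Inf, clip = "sqrt_n")
  expect_equal(R$clip_bound, sqrt(n))
  expect_lte(max(abs(R$values)), sqrt(n))
  Rn <- pearson_residuals(X, theta = Inf, clip = "none")
  expect_gt(max(abs(Rn$values)), sqrt(n))
  expect_equal(pearson_residuals(X, clip = 2.5)$clip_bound, 2.5)
})

test_that("residual variance streaming path equals the dense path", {
  set.seed(88)
  X <- random_counts(50, 20, lambda = 2)
  for (kind in c("pearson", "deviance")) {
    for (clip in list("sqrt_n", "none")) {
      v_stream <- residual_variance(X, kind, theta = 100, clip = clip)
      Z <- umiresid:::residual_matrix(X, kind, theta = 100, clip = clip)$values
      v_dense <- colMeans(Z^2) - colMeans(Z)^2
      expect_equal(v_stream, v_dense, tolerance = 1e-12)
    }
  }
  expect_equal(residual_variance(rank_one_matrix()), rep(0, 3))
})

test_that("two-fold change gives residuals 0.5*mu/sqrt(1.5*mu) without noise", {
  for (mu in c(10, 40, 100)) {
    X <- twofold_matrix(mu = mu, n = 100, depth = 4 * mu)
    Z <- pearson_residuals(X, theta = Inf, clip = "none")$values[, 1]
    expect_equal(sort(unique(round(Z, 9))),
                 round(c(-0.5 * mu, 0.5 * mu) / sqrt(1.5 * mu), 9))
    expect_equal(abs(Z[1]) / sqrt(mu), 0.5 / sqrt(1.5), tolerance = 1e-12)
  }
})

test_that("clipping worked example: implied within-population mean equals m", {
  expect_equal(clip_implied_mean(10, 1000), 10, tolerance = 1e-8)
  expect_equal(clip_implied_mean(25, 5000), 25, tolerance = 1e-8)
  expect_equal(expected_marker_residual(20, 10, 1000),
               (1000 - 10) * sqrt(20 / (1000 * 10)))
})
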