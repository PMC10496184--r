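test_that("initialization follows the jitter-ladder rules", {
  sim <- quick_sim(n = 40, J = 8, seed = 23)
  g <- zinb_global_fit(sim$X, sim$B)
  # K = 3: beta ladder is beta_tilde * (1, 1.01, 1.02)
  ini <- zinbmix_init(sim$X, sim$B, 3, g)
  pr <- ini$params
  expect_equal(pr$p, rep(1 / 3, 3))
  expect_equal(pr$beta[, 2], g$beta_star * 1.01)
  expect_equal(pr$beta[, 3], g$beta_star * 1.02)
  expect_equal(pr$beta_star, g$beta_star)
  # K = 1 keeps the global means exactly
  ini1 <- zinbmix_init(sim$X, sim$B, 1, g)
  expect_equal(ini1$params$beta[, 1], g$beta_star)
  # pi ladder is clipped at 0.999
  g2 <- g; g2$pi_tilde[] <- 0.999
  ini2 <- zinbmix_init(sim$X, sim$B, 3, g2)
  expect_true(all(ini2$params$pi <= 0.999))
  expect_error(zinbmix_init(sim$X, sim$B, 100, g), "exceed")
})

test_that("E-step is an exact Bayes rule and respects symmetry", {
  dat <- toy_data(n = 4, J = 2, seed = 3)
  pr <- toy_params(J = 2, K = 2, S = 2, seed = 4)
  z <- e_step(dat$X, dat$B, pr)
  expect_equal(rowSums(z), rep(1, 4), tolerance = 1e-12)
  # direct Bayes-rule oracle through plain probability products
  for (i in 1:4) {
    s <- which(dat$B[i, ] == 1)
    lik <- vapply(1:2, function(k) {
      mu <- exp(pr$beta[, k] + pr$gamma[s])
      prod(oracle_zinb_pmf(dat$X[i, ], pmin(pmax(pr$pi[, k], 1e-6), 1 - 1e-6),
                           mu, pr$phi))
    }, 0)
    post <- pr$p * lik / sum(pr$p * lik)
    expect_equal(z[i, ], post, tolerance = 1e-12)
  }
  # identical clusters give uniform responsibilities
  pr_sym <- pr
  pr_sym$p <- c(0.5, 0.5)
  pr_sym$pi[, 2] <- pr_sym$pi[, 1]
  pr_sym$beta[, 2] <- pr_sym$beta[, 1]
  z_sym <- e_step(dat$X, dat$B, pr_sym)
  expect_equal(as.vector(z_sym), rep(0.5, 8), tolerance = 1e-12)
  # K = 1 gives all ones
  pr1 <- toy_params(J = 2, K = 1, S = 2, seed = 4)
  expect_equal(as.vector(e_step(dat$X, dat$B, pr1)), rep(1, 4))
})

test_that("mixing-proportion update is the responsibility column mean", {
  z <- matrix(c(0.2, 0.7, 0.4, 0.8, 0.3, 0.6), 3, 2)
  expect_equal(update_p(z), c(mean(z[, 1]), mean(z[, 2])))
  z1 <- matrix(c(1, 1, 1, 0, 0, 0), 3, 2)
  expect_equal(update_p(z1), c(1, 0))
  zu <- matrix(1 / 2, 3, 2)
  expect_equal(update_p(zu), c(0.5, 0.5))
})

test_that("dropout posterior follows the printed scalar formula", {
  pr <- zinbmix_params(p = 1, pi = matrix(0.3), beta = matrix(log(5)),
                       phi = 2, gamma = 0, beta_star = log(5))
  X <- matrix(c(0, 4), 2, 1)
  B <- matrix(1, 2, 1)
  m <- update_m(X, B, pr)
  marr <- as.array(m)
  expect_equal(marr[1, 1, 1], 0.3 / (0.3 + 0.7 * (2 / 7)^2), tolerance = 1e-12)
  expect_identical(marr[2, 1, 1], 0)   # positive counts are never dropouts
  # pi = 1 makes every zero a certain dropout
  pr1 <- pr; pr1$pi[] <- 1
  expect_equal(as.array(update_m(X, B, pr1))[1, 1, 1], 1)
})

test_that("dropout-probability update is the weighted posterior mean", {
  pr <- zinbmix_params(p = c(0.5, 0.5), pi = matrix(0.4, 1, 2),
                       beta = matrix(log(3), 1, 2), phi = 1.5, gamma = 0,
                       beta_star = log(3))
  X <- matrix(c(0, 0, 2), 3, 1)
  B <- matrix(1, 3, 1)
  z <- matrix(c(0.8, 0.3, 0.5, 0.2, 0.7, 0.5), 3, 2)
  m <- update_m(X, B, pr)
  pi_new <- update_pi(z, m, pr$pi)
  m0 <- m$m0[[1]][1, ]  # same posterior for both zero cells (same batch)
  for (k in 1:2) {
    expect_equal(pi_new[1, k],
                 (z[1, k] * m0[k] + z[2, k] * m0[k]) / sum(z[, k]),
                 tolerance = 1e-12)
  }
  # m identically zero gives pi = 0; all-dropout zeros give pi = 1
  pr0 <- pr; pr0$pi[] <- 0
  expect_equal(unique(as.vector(update_pi(z, update_m(X, B, pr0), pr0$pi))), 0)
  X0 <- matrix(0, 3, 1)
  pr1 <- pr; pr1$pi[] <- 1
  expect_equal(unique(as.vector(update_pi(z, update_m(X0, B, pr1), pr1$pi))), 1)
  # empty cluster holds its previous value and is flagged
  z_empty <- cbind(rep(1, 3), rep(0, 3))
  pi_held <- update_pi(z_empty, m, pr$pi)
  expect_equal(pi_held[, 2], pr$pi[, 2])
  expect_equal(attr(pi_held, "empty"), 2L)
})

test_that("dispersion update matches a 1-D grid-search oracle", {
  set.seed(31)
  n <- 150
  x <- rnbinom(n, size = 2.2, mu = 9)
  X <- matrix(x, n, 1)
  B <- matrix(1, n, 1)
  pr <- zinbmix_params(p = 1, pi = matrix(1e-6), beta = matrix(log(9)),
                       phi = 1, gamma = 0, beta_star = log(9))
  z <- matrix(1, n, 1)
  m <- update_m(X, B, pr)
  phi_hat <- update_phi(X, B, pr, z, m)
  # independent grid search over log phi of the plain NB likelihood
  grid <- seq(log(0.2), log(30), length.out = 4000)
  ll <- vapply(grid, function(lp) {
    sum((1 - as.array(m)[, 1, 1]) * oracle_nb_logpmf(x, 9, exp(lp)))
  }, 0)
  expect_equal(log(phi_hat), grid[which.max(ll)], tolerance = 5e-3)
})

test_that("dispersion sampling distribution concentrates near truth", {
  set.seed(77)
  hits <- 0L
  reps <- 40L
  for (r in seq_len(reps)) {
    n <- 500
    x <- rnbinom(n, size = 2, mu = 10)
    X <- matrix(x, n, 1); B <- matrix(1, n, 1)
    pr <- zinbmix_params(p = 1, pi = matrix(1e-6), beta = matrix(log(mean(x))),
                         phi = 2, gamma = 0, beta_star = log(mean(x)))
    phi_hat <- update_phi(X, B, pr, matrix(1, n, 1), update_m(X, B, pr))
    if (phi_hat > 1.5 && phi_hat < 2.7) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.9)
})

test_that("a Poisson-like gene is pushed to a large dispersion", {
  set.seed(5)
  x <- rpois(200, 6)
  X <- matrix(x, 200, 1); B <- matrix(1, 200, 1)
  pr <- zinbmix_params(p = 1, pi = matrix(1e-6), beta = matrix(log(6)),
                       phi = 5, gamma = 0, beta_star = log(6))
  phi_hat <- update_phi(X, B, pr, matrix(1, 200, 1), update_m(X, B, pr))
  expect_gt(phi_hat, 50)
})

test_that("batch-coefficient update recovers contrasts and scaling", {
  set.seed(41)
  n <- 240; J <- 60
  sidx <- rep(1:2, each = n / 2)
  B <- batch_design(sidx)
  beta_true <- rnorm(J, 1.3, 0.4)
  X <- count_matrix(sapply(seq_len(J), function(j) {
    rnbinom(n, size = 3, mu = exp(beta_true[j] + c(0.1, 0.4)[sidx]))
  }))
  pr <- zinbmix_params(p = 1, pi = matrix(1e-6, J, 1),
                       beta = matrix(beta_true + 0.1, J, 1), phi = rep(3, J),
                       gamma = c(0, 0), beta_star = beta_true)
  z <- matrix(1, n, 1)
  m <- update_m(X, B, pr)
  gam <- update_gamma(X, B, pr, z, m)
  expect_identical(gam[1], 0)  # reference batch fixed
  expect_equal(gam[2], 0.3, tolerance = 0.07)
  # doubling batch-2 counts raises the contrast by about log 2
  X2 <- X; X2[sidx == 2, ] <- X2[sidx == 2, ] * 2
  gam2 <- update_gamma(count_matrix(X2), B, pr, z, update_m(count_matrix(X2), B, pr))
  expect_equal(gam2[2] - gam[2], log(2), tolerance = 0.1)
  # S = 1 stays at the reference zero
  B1 <- matrix(1, n, 1)
  pr1 <- pr; pr1$gamma <- 0; pr1$S <- 1L
  expect_identical(update_gamma(X, B1, pr1, z, update_m(X, B1, pr1)), 0)
})

test_that("full fits ascend, are deterministic, and respect penalty extremes", {
  # generalized-EM ascent on a batch of small random fits
  set.seed(9)
  for (r in 1:6) {
    sim <- quick_sim(n = 40, J = 15, seed = 100 + r,
                     dropout = sample(c("low", "medium"), 1))
    lam <- runif(1, 0, 5)
    fit <- zinbmix_fit(sim$X, sim$B, 2, lambda = lam, max_iter = 40)
    expect_true(all(diff(fit$objective_trace) > -1e-4),
                label = sprintf("ascent seed %d", 100 + r))
  }
  sim <- quick_sim(n = 50, J = 20, seed = 55)
  f1 <- zinbmix_fit(sim$X, sim$B, 2, lambda = 1, max_iter = 60)
  f2 <- zinbmix_fit(sim$X, sim$B, 2, lambda = 1, max_iter = 60)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$params$beta, f2$params$beta)
  expect_identical(f1$selected_genes, f2$selected_genes)
  # total shrinkage under a huge penalty
  fbig <- zinbmix_fit(sim$X, sim$B, 2, lambda = 1e4, max_iter = 60)
  expect_identical(fbig$selected_genes, character(0))
  expect_true(all(fbig$params$beta == fbig$params$beta_star))
  # K = 1 with a single batch: the mixture likelihood coincides with the
  # global fit, so any positive penalty pins beta at the global means
  B1 <- matrix(1, nrow(sim$X), 1)
  f1k <- zinbmix_fit(sim$X, B1, 1, lambda = 1, max_iter = 40)
  expect_true(all(f1k$labels == 1))
  expect_identical(f1k$selected_genes, character(0))
})

test_that("well-separated clusters are recovered across seeds", {
  aris <- vapply(1:8, function(r) {
    sim <- quick_sim(n = 120, J = 60, seed = 300 + r, Delta = 1.6)
    fit <- zinbmix_fit(sim$X, sim$B, 2, lambda = 1, max_iter = 100)
    ari(sim$labels, fit$labels)
  }, 0)
  expect_gte(sum(aris == 1), 4L)
  expect_true(all(aris >= 0.8))
})

test_that("selected genes track informative structure in a strong design", {
  sim <- quick_sim(n = 80, J = 40, seed = 404, Delta = 1.6)
  fit <- select_lambda(sim$X, sim$B, 2,
                       selection_config(lambda_min = 0.01, lambda_max = 20, M = 5))$fit
  prf <- selection_prf(sim$informative, selected_genes(fit),
                       universe = colnames(sim$X))
  expect_gte(prf$recall, 0.5)
  expect_gt(prf$f1, 0.3)
})

test_that("overspecified K never produces non-finite parameters", {
  sim <- quick_sim(n = 60, J = 20, seed = 61, Delta = 1.6)
  fit <- zinbmix_fit(sim$X, sim$B, 4, lambda = 2, max_iter = 60)
  expect_true(all(is.finite(fit$params$beta)))
  expect_true(all(is.finite(fit$params$pi)))
  expect_true(all(is.finite(fit$params$phi)))
  expect_true(all(is.finite(fit$params$p)))
  expect_true(all(is.finite(fit$resp$z_hat)))
})

test_that("fits are equivalent under permuted initial cluster ordering", {
  sim <- quick_sim(n = 60, J = 25, seed = 71, Delta = 1.6)
  g <- zinb_global_fit(sim$X, sim$B)
  ini <- zinbmix_init(sim$X, sim$B, 2, g)
  pr <- ini$params
  prp <- pr
  prp$pi <- pr$pi[, 2:1]; prp$beta <- pr$beta[, 2:1]
  f1 <- zinbmix_fit(sim$X, sim$B, 2, lambda = 1, init = pr, global = g,
                    max_iter = 60)
  f2 <- zinbmix_fit(sim$X, sim$B, 2, lambda = 1, init = prp, global = g,
                    max_iter = 60)
  expect_equal(ari(sim$labels, f1$labels), ari(sim$labels, f2$labels))
})

test_that("tidy, glance and autoplot expose the fit", {
  sim <- quick_sim(n = 40, J = 10, seed = 81)
  fit <- zinbmix_fit(sim$X, sim$B, 2, lambda = 1, max_iter = 30)
  td <- generics::tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 20L)
  expect_setequal(td$gene[td$selected], fit$selected_genes)
  gl <- generics::glance(fit)
  expect_equal(gl$bic, zinbmix_bic(fit)$bic)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
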