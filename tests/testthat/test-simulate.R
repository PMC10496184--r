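test_that("baseline fixture is deterministic and respects truncation", {
  b1 <- baseline_fixture(500, seed = 4)
  b2 <- baseline_fixture(500, seed = 4)
  expect_identical(b1, b2)
  expect_true(all(b1$mu_base >= 0.1 & b1$mu_base <= 500))
  expect_true(all(b1$phi_base >= 0.05 & b1$phi_base <= 50))
  # law of large numbers on the stated sampler
  big <- baseline_fixture(10000, seed = 5)
  expect_equal(mean(log(big$mu_base)), 1.0, tolerance = 0.05)
  # user-supplied pool
  tmp <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(mu = c(2, 8), phi = c(1, 3)), tmp,
                     row.names = FALSE, sep = "\t")
  bu <- baseline_fixture(50, seed = 1, file = tmp)
  expect_true(all(bu$mu_base %in% c(2, 8)))
  expect_identical(bu$source, "user")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("not a table at all", bad)
  expect_error(baseline_fixture(10, seed = 1, file = bad), "mu")
})

test_that("simulated datasets are exactly reproducible from config and seed", {
  cfg <- sim_config(n = 40, J = 30, seed = 77, dropout_level = "medium")
  s1 <- simulate_main(cfg); s2 <- simulate_main(cfg)
  expect_identical(s1$X, s2$X)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$dropout_indicators, s2$dropout_indicators)
})

test_that("dropout indicators force zeros and realized fractions track the ranges", {
  cfg <- sim_config(n = 150, J = 400, seed = 3, dropout_level = "medium")
  sim <- simulate_main(cfg)
  expect_true(all(sim$X[sim$dropout_indicators == 1] == 0))
  # E[pi] = 0.45 for the medium range; binomial noise at n*J = 60000 is tiny
  expect_equal(sim$realized_dropout, 0.45, tolerance = 0.02)
  simh <- simulate_main(sim_config(n = 150, J = 400, seed = 3,
                                   dropout_level = "high"))
  expect_equal(simh$realized_dropout, 0.75, tolerance = 0.02)
  # cluster-specific dropout draws are distinct within genes
  expect_true(all(apply(sim$gen_params$pi, 1, function(r) !anyDuplicated(r))))
})

test_that("Delta = 0 removes all mean signal from informative genes", {
  cfg <- sim_config(n = 30, J = 50, seed = 5, Delta = 0)
  sim <- simulate_main(cfg)
  expect_true(all(sim$gen_params$beta == log(baseline_fixture(50, seed = 5)$mu_base)))
})

test_that("odd cell counts split batches ceiling/floor with a warning", {
  cfg <- sim_config(n = 31, J = 10, seed = 2)
  expect_warning(sim <- simulate_main(cfg), "odd")
  expect_equal(unname(colSums(sim$B)), c(16, 15))
})

test_that("NB-mixture design has no structural zeros and matches the zero-mass oracle", {
  cfg <- sim_config(n = 400, J = 150, seed = 9, Delta = 1.2)
  sim <- simulate_nb_mixture(cfg)
  expect_true(all(sim$dropout_indicators == 0))
  expect_identical(unique(sim$gen_params$gamma), 0)
  # analytic expected zero fraction: mean over entries of NB(0; mu_jk, phi_j)
  gp <- sim$gen_params
  MU <- exp(t(gp$beta)[sim$labels, ])
  P0 <- (gp$phi / (t(MU) + gp$phi))^gp$phi  # J x n by recycling
  expect_equal(mean(sim$X == 0), mean(P0), tolerance = 0.01)
})

test_that("cluster-independent dropout shares pi across clusters", {
  cfg <- sim_config(n = 40, J = 30, seed = 11, dropout_level = "low",
                    frac_informative = 0.1)
  sim <- simulate_noninformative_dropout(cfg)
  expect_true(all(sim$gen_params$pi[, 1] == sim$gen_params$pi[, 2]))
  expect_true(all(sim$gen_params$pi[, 1] >= 0.2 & sim$gen_params$pi[, 1] <= 0.4))
  simm <- simulate_noninformative_dropout(
    sim_config(n = 200, J = 300, seed = 11, dropout_level = "medium",
               frac_informative = 0.1))
  expect_equal(simm$realized_dropout, 0.5, tolerance = 0.02)
})

test_that("zero-inflated Poisson designs expose their stated structure", {
  cfg <- sim_config(n = 60, J = 80, seed = 13)
  rz <- simulate_zip_rzimm(cfg)
  k_star <- rz$gen_params$elevated_cluster
  others <- setdiff(seq_len(cfg$K), k_star)
  inf <- rz$informative
  # exactly one cluster's informative means elevated, by log(fold)
  expect_true(all(rz$gen_params$beta[inf, k_star] -
                    rz$gen_params$beta[inf, others[1]] > 0))
  expect_equal(rz$gen_params$beta[inf, k_star] -
                 rz$gen_params$beta[inf, others[1]],
               rep(log(2), sum(inf)), tolerance = 1e-12)
  expect_true(all(rz$gen_params$beta[!inf, 1] == rz$gen_params$beta[!inf, 2]))

  cd <- simulate_zip_cidr(sim_config(n = 500, J = 120, seed = 14))
  # dropout probability decreases with expression
  gp <- cd$gen_params
  MU <- exp(t(gp$beta)[cd$labels, ])
  pd <- 1 / (1 + exp(gp$slope * (log(MU) - gp$midpoint)))
  expect_true(all(diff(pd[order(MU[1, ])][c(1, ncol(MU))]) <= 0) ||
                pd[which.max(MU[1, ])] < pd[which.min(MU[1, ])])
  # empirical dropout rate tracks the configured logistic within binomial error
  bins <- cut(log(MU), breaks = quantile(log(MU), seq(0, 1, 0.25)),
              include.lowest = TRUE)
  emp <- tapply(as.vector(cd$dropout_indicators), bins, mean)
  thr <- tapply(as.vector(pd), bins, mean)
  expect_true(all(abs(emp - thr) < 0.03))
  expect_true(all(diff(thr) < 0))
})

test_that("the informative-gene pattern catalogs match the printed designs", {
  expect_equal(zinbmix:::.delta_catalog(3),
               list(c(-1, 0, 1), c(1, 1, 0), c(0, 1, 1)))
  expect_equal(zinbmix:::.delta_catalog(4),
               list(c(-1, 1, 0, 1), c(1, -1, 1, 0), c(1, 1, -1, -1)))
  expect_equal(zinbmix:::.delta_catalog(5),
               list(c(-1, -1, 1, 0, 1), c(-1, 1, 1, 1, 0), c(0, 1, -1, -1, -1)))
  expect_equal(zinbmix:::.delta_catalog(6),
               list(c(1, 1, -1, -1, 0, 0), c(-1, 0, 1, -1, 1, 1),
                    c(1, 0, 1, -1, -1, 0), c(0, 0, -1, -1, -1, -1)))
  expect_equal(zinbmix:::.delta_catalog(8),
               list(c(1, 1, 1, -1, -1, -1, 0, 0), c(-1, -1, 0, 1, 1, -1, 1, 1),
                    c(1, -1, 0, 1, 1, -1, -1, 0), c(0, 1, 0, -1, 0, -1, -1, -1)))
  expect_equal(zinbmix:::.delta_catalog(10),
               list(c(-1, 1, 1, 0, -1, -1, -1, 0, 0, 1),
                    c(-1, 1, -1, 1, 0, 1, 1, 0, 0, 1),
                    c(-1, -1, 0, 1, 1, -1, -1, 1, -1, -1),
                    c(-1, -1, 0, 1, 1, 1, 0, 1, 1, 1)))
  expect_error(zinbmix:::.delta_catalog(7), "catalog")
})

test_that("non-dropout entries match the configured NB moments", {
  # single cluster/batch corner: large-n moment check per the generator
  cfg <- sim_config(n = 5000, J = 4, K = 3, seed = 21, dropout_level = "medium",
                    frac_informative = 0.25)
  sim <- simulate_main(cfg)
  gp <- sim$gen_params
  checked <- 0L
  for (j in 1:4) {
    k <- 1
    rows <- which(sim$labels == k & sim$dropout_indicators[, j] == 0 &
                    zinbmix:::.batch_index(sim$B) == 1)
    if (length(rows) < 300) next
    checked <- checked + 1L
    mu <- exp(gp$beta[j, k] + gp$gamma[1])
    v <- mu + mu^2 / gp$phi[j]
    expect_equal(mean(sim$X[rows, j]), mu,
                 tolerance = (0.15 * mu + 4 * sqrt(v / length(rows))) / mu)
  }
  expect_gt(checked, 0L)
})
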