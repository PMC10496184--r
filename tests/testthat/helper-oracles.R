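# Independent oracles used across the suite. These deliberately avoid the
# package's internal code paths: explicit Gamma-function arithmetic, direct
# probability sums, and brute-force 1-D grid searches.

# NB log-pmf written out with lgamma, independent of stats::dnbinom
oracle_nb_logpmf <- function(x, mu, phi) {
  lgamma(x + phi) - lgamma(x + 1) - lgamma(phi) +
    x * (log(mu) - log(mu + phi)) + phi * (log(phi) - log(mu + phi))
}

oracle_zinb_pmf <- function(x, pi, mu, phi) {
  pi * (x == 0) + (1 - pi) * exp(oracle_nb_logpmf(x, mu, phi))
}

# direct mixture likelihood of a full dataset by plain products and sums
oracle_mixture_loglik <- function(X, B, params) {
  n <- nrow(X)
  total <- 0
  for (i in seq_len(n)) {
    s <- which(B[i, ] == 1)
    cellp <- 0
    for (k in seq_len(params$K)) {
      mu <- exp(params$beta[, k] + params$gamma[s])
      cellp <- cellp + params$p[k] *
        prod(oracle_zinb_pmf(X[i, ], params$pi[, k], mu, params$phi))
    }
    total <- total + log(cellp)
  }
  total
}

# exact penalized objective of a scalar beta subproblem, for grid search
oracle_beta_objective <- function(beta, sub) {
  mu <- exp(beta + sub$offset)
  sum(sub$w * oracle_nb_logpmf(sub$x, mu, sub$phi)) -
    sub$lambda * abs(beta - sub$beta_star)
}

# fine grid + golden-section refinement of the penalized scalar problem;
# the kink at beta_star is included as an explicit candidate
oracle_beta_solve <- function(sub, lo = sub$beta_star - 8, hi = sub$beta_star + 8) {
  grid <- sort(c(seq(lo, hi, length.out = 2001), sub$beta_star))
  vals <- vapply(grid, oracle_beta_objective, 0, sub = sub)
  i <- which.max(vals)
  h <- (hi - lo) / 2000
  opt <- stats::optimize(oracle_beta_objective, c(grid[i] - h, grid[i] + h),
                         sub = sub, maximum = TRUE, tol = 1e-10)
  if (oracle_beta_objective(sub$beta_star, sub) >= opt$objective - 1e-12) {
    return(sub$beta_star)
  }
  opt$maximum
}

# contingency-table ARI (Hubert-Arabie via sums of binomial coefficients),
# used as the second route next to mclust::adjustedRandIndex
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) sum(x * (x - 1) / 2)
  sij <- ch2(tab); si <- ch2(rowSums(tab)); sj <- ch2(colSums(tab))
  n2 <- ch2(length(a))
  if (n2 == 0) return(NA_real_)
  expected <- si * sj / n2
  mx <- (si + sj) / 2
  if (mx == expected) return(ifelse(sij == mx, 1, 0))
  (sij - expected) / (mx - expected)
}

# small ZINB dataset builder with known parameters (not via the generators)
toy_params <- function(J = 3, K = 2, S = 2, seed = 1) {
  set.seed(seed)
  zinbmix_params(
    p = as.vector(prop.table(runif(K) + 0.5)),
    pi = matrix(runif(J * K, 0.05, 0.4), J, K),
    beta = matrix(rnorm(J * K, 1.5, 0.5), J, K),
    phi = runif(J, 0.5, 5),
    gamma = c(0, rnorm(S - 1, 0, 0.3)),
    beta_star = rnorm(J, 1.5, 0.5)
  )
}

toy_data <- function(n = 5, J = 3, S = 2, seed = 2, max_count = 12) {
  set.seed(seed)
  X <- matrix(rpois(n * J, 3), n, J)
  X[sample(length(X), length(X) %/% 4)] <- 0
  B <- matrix(0, n, S)
  B[cbind(seq_len(n), rep_len(seq_len(S), n))] <- 1
  list(X = count_matrix(X), B = B)
}

# quick simulated two-cluster dataset for fit-level tests
quick_sim <- function(n = 80, J = 40, K = 2, Delta = 1.6, seed = 1,
                      dropout = "low", gamma = c(0.1, 0.2)) {
  cfg <- sim_config(n = n, J = J, K = K, frac_informative = 0.2,
                    dropout_level = dropout, gamma = gamma, Delta = Delta,
                    seed = seed,
                    delta_patterns = if (K == 2) list(c(-1, 1), c(1, 0)) else NULL)
  simulate_main(cfg)
}

# randomized penalized scalar subproblem shared by unit and acceptance tests
random_subproblem <- function(seed) {
  set.seed(seed)
  n <- 30L
  phi <- runif(1, 0.3, 8)
  beta_true <- rnorm(1, 1.2, 0.8)
  offset <- rnorm(n, 0, 0.3)
  x <- rnbinom(n, size = phi, mu = exp(beta_true + offset))
  beta_subproblem(
    x_col = x,
    w = runif(n, 0.2, 1),
    offset = offset,
    phi_j = phi,
    lambda = runif(1, 0, 8),
    beta_star_j = beta_true + rnorm(1, 0, 0.6),
    beta_init = beta_true + rnorm(1, 0, 0.2)
  )
}

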