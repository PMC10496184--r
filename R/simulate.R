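# Synthetic-data generators: the main ZINB design with cluster-specific
# dropout, batch shifts and informative-gene fold-change patterns; a variant
# with cluster-independent dropout; and three misspecification designs
# (NB mixture without dropout, and two zero-inflated Poisson models).

# catalog of informative-gene fold-change sign patterns delta_jk by K
.delta_catalog <- function(K) {
  switch(as.character(K),
    "2" = list(c(-1, 1), c(1, 0), c(0, 1)),   # minimal two-cluster analogue
    "3" = list(c(-1, 0, 1), c(1, 1, 0), c(0, 1, 1)),
    "4" = list(c(-1, 1, 0, 1), c(1, -1, 1, 0), c(1, 1, -1, -1)),
    "5" = list(c(-1, -1, 1, 0, 1), c(-1, 1, 1, 1, 0), c(0, 1, -1, -1, -1)),
    "6" = list(c(1, 1, -1, -1, 0, 0), c(-1, 0, 1, -1, 1, 1),
               c(1, 0, 1, -1, -1, 0), c(0, 0, -1, -1, -1, -1)),
    "8" = list(c(1, 1, 1, -1, -1, -1, 0, 0), c(-1, -1, 0, 1, 1, -1, 1, 1),
               c(1, -1, 0, 1, 1, -1, -1, 0), c(0, 1, 0, -1, 0, -1, -1, -1)),
    "10" = list(c(-1, 1, 1, 0, -1, -1, -1, 0, 0, 1),
                c(-1, 1, -1, 1, 0, 1, 1, 0, 0, 1),
                c(-1, -1, 0, 1, 1, -1, -1, 1, -1, -1),
                c(-1, -1, 0, 1, 1, 1, 0, 1, 1, 1)),
    stop(sprintf("no built-in informative-gene pattern catalog for K = %s; supply delta_patterns", K),
         call. = FALSE)
  )
}

.dropout_range <- function(level, noninformative = FALSE) {
  if (is.numeric(level) && length(level) == 2L) return(level)
  if (noninformative) {
    switch(match.arg(level, c("low", "medium", "high")),
           low = c(0.2, 0.4), medium = c(0.4, 0.6), high = c(0.6, 0.8))
  } else {
    switch(match.arg(level, c("low", "medium", "high")),
           low = c(0.0, 0.3), medium = c(0.3, 0.6), high = c(0.6, 0.9))
  }
}

#' Simulation configuration
#'
#' Study conditions for the generators. Defaults follow the main design:
#' 300 cells, 1000 genes, 3 clusters, 5% informative genes, batch effects
#' `gamma = (0.1, 0.2)` over two equally sized batches, balanced mixing, and
#' fold-change magnitude `Delta = 1.2` (informative-gene log-means are
#' `log(mu_j * 2^(Delta * delta_jk))`).
#'
#' @param n,J,K Cells, genes, clusters.
#' @param frac_informative Fraction of genes given a nonzero pattern.
#' @param dropout_level `"low"`, `"medium"`, `"high"` (uniform ranges
#'   U(0, 0.3) / U(0.3, 0.6) / U(0.6, 0.9) for cluster-specific dropout;
#'   U(0.2, 0.4) / U(0.4, 0.6) / U(0.6, 0.8) in the cluster-independent
#'   design), or a numeric `c(lo, hi)`.
#' @param gamma Batch effects (length S); cells are split into S contiguous
#'   equally sized batches.
#' @param mixing `"balanced"`, `"imbalanced"` (1/2, 1/3, 1/6 for K = 3) or a
#'   numeric probability vector.
#' @param Delta Fold-change magnitude on the log2 scale.
#' @param delta_patterns Optional list of length-K sign patterns; defaults to
#'   the built-in catalog for K in (2, 3, 4, 5, 6, 8, 10).
#' @param cluster_specific_dropout Draw K distinct dropout probabilities per
#'   gene (redrawn on exact collision).
#' @param rzimm_fold Mean-elevation fold of the zero-inflated Poisson design
#'   with one elevated cluster.
#' @param cidr_midpoint,cidr_slope Midpoint and slope of the decreasing
#'   logistic linking dropout probability to the log-mean in the
#'   expression-dependent dropout design (midpoint defaults to the mean
#'   log baseline mean).
#' @param seed Integer RNG seed; every generated dataset is exactly
#'   reproducible from the configuration and seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 300L, J = 1000L, K = 3L, frac_informative = 0.05,
                       dropout_level = "low", gamma = c(0.1, 0.2),
                       mixing = "balanced", Delta = 1.2,
                       delta_patterns = NULL, cluster_specific_dropout = TRUE,
                       rzimm_fold = 2, cidr_midpoint = NULL, cidr_slope = 1,
                       seed = 1L) {
  if (frac_informative <= 0 || frac_informative >= 1) {
    stop("frac_informative must lie in (0, 1)", call. = FALSE)
  }
  if (is.character(mixing)) {
    mixing <- switch(match.arg(mixing, c("balanced", "imbalanced")),
                     balanced = rep(1 / K, K),
                     imbalanced = {
                       w <- 1 / 2^(seq_len(K) - 1)
                       if (K == 3L) c(1 / 2, 1 / 3, 1 / 6) else w / sum(w)
                     })
  }
  if (abs(sum(mixing) - 1) > 1e-8) stop("mixing proportions must sum to 1", call. = FALSE)
  if (length(mixing) != K) stop("mixing must have K entries", call. = FALSE)
  structure(list(n = as.integer(n), J = as.integer(J), K = as.integer(K),
                 frac_informative = frac_informative,
                 dropout_level = dropout_level, gamma = gamma, mixing = mixing,
                 Delta = Delta, delta_patterns = delta_patterns,
                 cluster_specific_dropout = isTRUE(cluster_specific_dropout),
                 rzimm_fold = rzimm_fold, cidr_midpoint = cidr_midpoint,
                 cidr_slope = cidr_slope, seed = as.integer(seed)),
            class = "sim_config")
}

#' Baseline gene-level means and dispersions
#'
#' Synthetic stand-in for an empirical pool of gene-wise ZINB maximum
#' likelihood estimates from a reference cortex dataset: baseline means are
#' drawn from a log-normal (log-mean 1.0, log-sd 1.2) truncated to
#' \[0.1, 500\] and dispersions from a log-normal (log-mean 0.5, log-sd 0.8)
#' truncated to \[0.05, 50\]. A user-supplied two-column file
#' (`mu`, `phi`; TSV/CSV with header) replaces the synthetic pool.
#'
#' @param J Number of genes to draw.
#' @param seed Integer seed.
#' @param file Optional path to a two-column table of empirical estimates,
#'   sampled from with replacement.
#' @return A list of class `baseline_params` with `mu_base`, `phi_base`,
#'   `source`.
#' @export
baseline_fixture <- function(J, seed = 1L, file = NULL) {
  if (J < 1L) stop("J must be at least 1", call. = FALSE)
  set.seed(seed)
  if (!is.null(file)) {
    tb <- tryCatch(utils::read.table(file, header = TRUE, sep = ""),
                   error = function(e) stop("malformed baseline file", call. = FALSE))
    if (ncol(tb) < 2L || !all(c("mu", "phi") %in% names(tb))) {
      stop("baseline file needs columns 'mu' and 'phi'", call. = FALSE)
    }
    if (any(!is.finite(tb$mu)) || any(tb$mu <= 0) || any(tb$phi <= 0)) {
      stop("baseline file values must be positive and finite", call. = FALSE)
    }
    idx <- sample.int(nrow(tb), J, replace = TRUE)
    return(structure(list(mu_base = tb$mu[idx], phi_base = tb$phi[idx],
                          source = "user"), class = "baseline_params"))
  }
  rlnorm_trunc <- function(J, ml, sl, lo, hi) {
    u <- stats::runif(J, stats::plnorm(lo, ml, sl), stats::plnorm(hi, ml, sl))
    stats::qlnorm(u, ml, sl)
  }
  structure(list(
    mu_base = rlnorm_trunc(J, 1.0, 1.2, 0.1, 500),
    phi_base = rlnorm_trunc(J, 0.5, 0.8, 0.05, 50),
    source = "fixture"
  ), class = "baseline_params")
}

# contiguous, as-equal-as-possible batch assignment (half/half for S = 2)
.batch_blocks <- function(n, S) {
  if (S == 2L && n %% 2L == 1L) {
    warning("odd number of cells: batches split ceiling(n/2) / floor(n/2)", call. = FALSE)
  }
  sizes <- rep(n %/% S, S)
  if (n %% S) sizes[seq_len(n %% S)] <- sizes[seq_len(n %% S)] + 1L
  rep(seq_len(S), times = sizes)
}

# shared scaffolding: labels, batches, informative flags, delta matrix
.sim_frame <- function(cfg) {
  n <- cfg$n; J <- cfg$J; K <- cfg$K
  labels <- sample.int(K, n, replace = TRUE, prob = cfg$mixing)
  S <- length(cfg$gamma)
  sidx <- .batch_blocks(n, S)
  B <- matrix(0, n, S); B[cbind(seq_len(n), sidx)] <- 1
  n_inf <- max(1L, round(cfg$frac_informative * J))
  informative <- logical(J)
  informative[sample.int(J, n_inf)] <- TRUE
  patterns <- cfg$delta_patterns
  if (is.null(patterns)) patterns <- .delta_catalog(K)
  stopifnot(all(vapply(patterns, length, 0L) == K))
  delta <- matrix(0, J, K)
  pick <- sample.int(length(patterns), n_inf, replace = TRUE)
  delta[informative, ] <- do.call(rbind, patterns[pick])
  list(labels = labels, B = B, sidx = sidx, informative = informative, delta = delta)
}

# draw pi_jk from U(lo, hi); K distinct values per gene when cluster-specific
.draw_pi <- function(J, K, range, cluster_specific) {
  if (!cluster_specific) {
    return(matrix(stats::runif(J, range[1], range[2]), J, K))
  }
  pi <- matrix(stats::runif(J * K, range[1], range[2]), J, K)
  for (j in seq_len(J)) {
    while (anyDuplicated(pi[j, ])) {
      pi[j, ] <- stats::runif(K, range[1], range[2])
    }
  }
  pi
}

.assemble_sim <- function(cfg, frame, X, D, gen_params, extra = list()) {
  X <- count_matrix(X)
  out <- c(list(X = X, B = frame$B, labels = frame$labels,
                informative = frame$informative,
                dropout_indicators = D,
                gen_params = gen_params,
                realized_dropout = mean(D),
                config = cfg), extra)
  structure(out, class = "zinbmix_sim")
}

#' Main ZINB simulation design
#'
#' Cell types are multinomial with the configured mixing proportions; cells
#' split into contiguous equally sized batches; per gene and cluster the
#' dropout probability is drawn from the configured uniform range (distinct
#' across clusters); informative genes receive a random catalog pattern so
#' their cluster log-means are `log(mu_j * 2^(Delta * delta_jk))`; every entry
#' is a Bernoulli dropout (recorded) or an NB draw with mean
#' `exp(beta_jk + B_i' gamma)` and dispersion `phi_j`.
#'
#' @param cfg A [sim_config()].
#' @param base Optional [baseline_fixture()]; drawn with `cfg$seed` otherwise.
#' @return A list of class `zinbmix_sim`: `X`, `B`, `labels`, `informative`,
#'   `dropout_indicators`, `gen_params`, `realized_dropout`, `config`.
#' @export
simulate_main <- function(cfg = sim_config(), base = NULL) {
  set.seed(cfg$seed)
  if (is.null(base)) base <- baseline_fixture(cfg$J, seed = cfg$seed)
  stopifnot(length(base$mu_base) == cfg$J)
  frame <- .sim_frame(cfg)
  rng <- .dropout_range(cfg$dropout_level)
  pi <- .draw_pi(cfg$J, cfg$K, rng, cfg$cluster_specific_dropout)
  beta <- log(base$mu_base * 2^(cfg$Delta * frame$delta))
  .draw_zinb(cfg, frame, pi, beta, base$phi_base, cfg$gamma)
}

.draw_zinb <- function(cfg, frame, pi, beta, phi, gamma) {
  n <- cfg$n; J <- cfg$J
  MU <- exp(t(beta)[frame$labels, , drop = FALSE] + gamma[frame$sidx])
  PI <- t(pi)[frame$labels, , drop = FALSE]
  D <- matrix(stats::rbinom(n * J, 1L, PI), n, J)
  X <- matrix(0, n, J)
  nb <- stats::rnbinom(n * J, size = rep(phi, each = n), mu = MU)
  X[D == 0] <- nb[D == 0]
  .assemble_sim(cfg, frame, X, D,
                gen_params = list(p = cfg$mixing, pi = pi, beta = beta,
                                  phi = phi, gamma = gamma))
}

#' Simulation with cluster-independent dropout
#'
#' As [simulate_main()] but with a single dropout probability per gene shared
#' by all clusters (`pi_j1 = ... = pi_jK`), drawn from U(0.2, 0.4),
#' U(0.4, 0.6) or U(0.6, 0.8) for the low/medium/high levels, so dropout
#' carries no clustering information.
#'
#' @inheritParams simulate_main
#' @export
simulate_noninformative_dropout <- function(cfg = sim_config(frac_informative = 0.1),
                                            base = NULL) {
  set.seed(cfg$seed)
  if (is.null(base)) base <- baseline_fixture(cfg$J, seed = cfg$seed)
  frame <- .sim_frame(cfg)
  rng <- .dropout_range(cfg$dropout_level, noninformative = TRUE)
  pi <- .draw_pi(cfg$J, cfg$K, rng, cluster_specific = FALSE)
  beta <- log(base$mu_base * 2^(cfg$Delta * frame$delta))
  .draw_zinb(cfg, frame, pi, beta, base$phi_base, cfg$gamma)
}

#' Negative binomial mixture design (no dropout, no batch effects)
#'
#' The main design with all dropout probabilities set to zero and no batch
#' shift: every zero is an NB zero.
#'
#' @inheritParams simulate_main
#' @export
simulate_nb_mixture <- function(cfg = sim_config(), base = NULL) {
  set.seed(cfg$seed)
  if (is.null(base)) base <- baseline_fixture(cfg$J, seed = cfg$seed)
  frame <- .sim_frame(cfg)
  pi <- matrix(0, cfg$J, cfg$K)
  beta <- log(base$mu_base * 2^(cfg$Delta * frame$delta))
  gamma0 <- rep(0, length(cfg$gamma))
  .draw_zinb(cfg, frame, pi, beta, base$phi_base, gamma0)
}

#' Zero-inflated Poisson design with one elevated cluster
#'
#' Poisson counts in which one randomly chosen cluster has the means of the
#' informative genes multiplied by `rzimm_fold`; dropout probabilities are
#' drawn as configured and batch shifts apply on the log-mean.
#'
#' @inheritParams simulate_main
#' @export
simulate_zip_rzimm <- function(cfg = sim_config(), base = NULL) {
  set.seed(cfg$seed)
  if (is.null(base)) base <- baseline_fixture(cfg$J, seed = cfg$seed)
  frame <- .sim_frame(cfg)
  rng <- .dropout_range(cfg$dropout_level)
  pi <- .draw_pi(cfg$J, cfg$K, rng, cfg$cluster_specific_dropout)
  k_star <- sample.int(cfg$K, 1L)
  beta <- matrix(log(base$mu_base), cfg$J, cfg$K)
  beta[frame$informative, k_star] <- beta[frame$informative, k_star] + log(cfg$rzimm_fold)
  n <- cfg$n; J <- cfg$J
  MU <- exp(t(beta)[frame$labels, , drop = FALSE] + cfg$gamma[frame$sidx])
  PI <- t(pi)[frame$labels, , drop = FALSE]
  D <- matrix(stats::rbinom(n * J, 1L, PI), n, J)
  X <- matrix(0, n, J)
  pois <- stats::rpois(n * J, MU)
  X[D == 0] <- pois[D == 0]
  .assemble_sim(cfg, frame, X, D,
                gen_params = list(p = cfg$mixing, pi = pi, beta = beta,
                                  gamma = cfg$gamma, elevated_cluster = k_star,
                                  fold = cfg$rzimm_fold))
}

#' Zero-inflated Poisson design with expression-dependent dropout
#'
#' Poisson counts whose entry-wise dropout probability decreases with the
#' expression level through a logistic curve:
#' `P(dropout) = 1 / (1 + exp(slope * (log mu - midpoint)))`, so highly
#' expressed genes drop out rarely. Cluster structure comes from the usual
#' fold-change patterns; no batch shift.
#'
#' @inheritParams simulate_main
#' @export
simulate_zip_cidr <- function(cfg = sim_config(), base = NULL) {
  set.seed(cfg$seed)
  if (is.null(base)) base <- baseline_fixture(cfg$J, seed = cfg$seed)
  frame <- .sim_frame(cfg)
  beta <- log(base$mu_base * 2^(cfg$Delta * frame$delta))
  midpoint <- if (is.null(cfg$cidr_midpoint)) mean(log(base$mu_base)) else cfg$cidr_midpoint
  n <- cfg$n; J <- cfg$J
  MU <- exp(t(beta)[frame$labels, , drop = FALSE])
  PDROP <- 1 / (1 + exp(cfg$cidr_slope * (log(MU) - midpoint)))
  D <- matrix(stats::rbinom(n * J, 1L, PDROP), n, J)
  X <- matrix(0, n, J)
  pois <- stats::rpois(n * J, MU)
  X[D == 0] <- pois[D == 0]
  .assemble_sim(cfg, frame, X, D,
                gen_params = list(p = cfg$mixing, beta = beta,
                                  midpoint = midpoint, slope = cfg$cidr_slope))
}

#' @export
print.zinbmix_sim <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d cells x %d genes, K = %d, %d informative gene(s)\n",
              nrow(x$X), ncol(x$X), x$config$K, sum(x$informative)))
  cat(sprintf("  realized dropout-event fraction: %.1f%%; overall zero fraction: %.1f%%\n",
              100 * x$realized_dropout, 100 * mean(x$X == 0)))
  invisible(x)
}
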