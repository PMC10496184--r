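# Likelihood kernels for the ZINB mixture with batch effects.
#
# The log-mean decomposes as log(mu_ijk) = beta_jk + B_i' gamma with a one-hot
# batch design, so mu takes at most S distinct values per (gene, cluster).
# All heavy computations therefore collapse onto per-batch quantities:
#   c1[s][j,k] = log(mu / (mu + phi))          (coefficient of x)
#   c2[s][j,k] = phi * log(phi / (mu + phi))   (the NB zero-mass log-prob)
# and the per-entry log-gamma terms, which do not depend on (k, gamma, beta),
# are accumulated once per call. This keeps the EM engine at BLAS speed
# without compiled code.

.MU_MIN <- 1e-10
.MU_MAX <- 1e12

# clamp exp(beta + gamma_s), optionally recording the number of clamped values
.clamped_mu <- function(eta, counter = NULL) {
  mu <- exp(eta)
  n_bad <- sum(mu < .MU_MIN | mu > .MU_MAX)
  if (n_bad > 0) {
    if (is.environment(counter)) {
      counter$n <- counter$n + n_bad
    } else {
      warning(sprintf("clamped %d extreme NB mean value(s) to [%g, %g]",
                      n_bad, .MU_MIN, .MU_MAX), call. = FALSE)
    }
    mu <- pmin(pmax(mu, .MU_MIN), .MU_MAX)
  }
  mu
}

.clip_pi <- function(pi) pmin(pmax(pi, 1e-6), 1 - 1e-6)

# per-batch c1/c2 (each a J x K matrix), phi recycled down columns
.batch_c1c2 <- function(beta, gamma, phi, counter = NULL) {
  lapply(seq_along(gamma), function(s) {
    mu <- .clamped_mu(beta + gamma[s], counter)
    list(c1 = log(mu) - log(mu + phi), c2 = phi * (log(phi) - log(mu + phi)))
  })
}

# run ends of a non-decreasing integer group vector: list(ids, ends)
.run_ends <- function(g) {
  if (!length(g)) return(list(ids = integer(0), ends = integer(0)))
  ends <- c(which(diff(g) != 0), length(g))
  list(ids = g[ends], ends = ends)
}

# group sums of v over contiguous runs, scattered into a length-m vector
.run_sum <- function(v, runs, m) {
  out <- numeric(m)
  if (!length(v)) return(out)
  cs <- cumsum(v)[runs$ends]
  out[runs$ids] <- diff(c(0, cs))
  out
}

# dataset-level precomputations shared across EM iterations
.precompute <- function(X, B) {
  sidx <- .batch_index(B)
  S <- ncol(B)
  pos <- which(X > 0, arr.ind = TRUE)
  pos_i <- pos[, 1L]; pos_j <- pos[, 2L]
  pos_x <- X[pos]
  Zpos <- (X > 0) + 0
  # per-gene tables of unique positive counts (for the dispersion objective)
  ut <- lapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]; v <- v[v > 0]
    if (!length(v)) return(NULL)
    tb <- table(v)
    cbind(j, as.numeric(names(tb)), as.numeric(tb))
  })
  ut <- do.call(rbind, ut)
  if (is.null(ut)) ut <- matrix(numeric(0), 0, 3)
  # fixed-pattern group sums via cumsum over contiguous runs: ut rows are
  # already contiguous per gene; positive entries are re-ordered by cell once
  ut_j <- ut[, 1L]
  ut_runs <- .run_ends(ut_j)
  # contiguous ut and positive-entry ranges per gene (pos_j is sorted because
  # which() scans column-major), for subsetted evaluation and caching
  ut_len <- tabulate(ut_j, nbins = ncol(X))
  ut_end <- cumsum(ut_len)
  pos_len <- tabulate(pos_j, nbins = ncol(X))
  pos_end <- cumsum(pos_len)
  pos_perm <- order(pos_i)
  pos_runs <- .run_ends(pos_i[pos_perm])
  list(
    ut_runs = ut_runs, pos_perm = pos_perm, pos_runs = pos_runs,
    ut_len = ut_len, ut_start = ut_end - ut_len + 1L, ut_end = ut_end,
    pos_len = pos_len, pos_start = pos_end - pos_len + 1L, pos_end = pos_end,
    n = nrow(X), J = ncol(X), S = S,
    sidx = sidx,
    batch_rows = split(seq_len(nrow(X)), sidx),
    pos_i = pos_i, pos_j = pos_j, pos_x = pos_x,
    lg_xp1 = lgamma(pos_x + 1),
    Zpos = Zpos, Zneg = 1 - Zpos,
    npos_gene = colSums(Zpos),
    ut_j = ut[, 1L], ut_v = ut[, 2L], ut_c = ut[, 3L],
    const_lgx = -sum(lgamma(pos_x + 1)),  # constant part of the phi objective
    lg_cache = new.env(parent = emptyenv())
  )
}

# indices of the positive entries / ut rows belonging to a set of genes
.range_unlist <- function(start, end, idx) {
  idx <- idx[end[idx] >= start[idx]]
  if (!length(idx)) return(integer(0))
  unlist(lapply(idx, function(j) start[j]:end[j]), use.names = FALSE)
}

# n x K matrix of per-cell, per-cluster ZINB log-likelihood sums over genes
.cell_loglik_matrix <- function(X, params, pc, counter = NULL) {
  phi <- params$phi
  piM <- .clip_pi(params$pi)
  cc <- .batch_c1c2(params$beta, params$gamma, phi, counter)
  # k-invariant log-gamma part, accumulated per cell over positive entries;
  # per-entry lgamma terms are cached and refreshed only for genes whose
  # dispersion changed since the previous call
  ce <- pc$lg_cache
  if (is.null(ce$phi)) {
    ce$lg <- lgamma(pc$pos_x + phi[pc$pos_j]) - pc$lg_xp1 - lgamma(phi)[pc$pos_j]
    ce$phi <- phi
  } else if (!identical(ce$phi, phi)) {
    changed <- which(ce$phi != phi)
    rows <- .range_unlist(pc$pos_start, pc$pos_end, changed)
    if (length(rows)) {
      ce$lg[rows] <- lgamma(pc$pos_x[rows] + phi[pc$pos_j[rows]]) -
        pc$lg_xp1[rows] - lgamma(phi)[pc$pos_j[rows]]
    }
    ce$phi <- phi
  }
  G <- .run_sum(ce$lg[pc$pos_perm], pc$pos_runs, pc$n)
  out <- matrix(0, pc$n, params$K)
  l1mpi <- log1p(-piM)
  lpi <- log(piM)
  for (s in seq_len(pc$S)) {
    rows <- pc$batch_rows[[s]]
    c1 <- cc[[s]]$c1; c2 <- cc[[s]]$c2
    z0 <- .logsumexp2(lpi, l1mpi + c2)          # log f_ZINB at x = 0
    # sum_j [x>0](M1) + [x=0](z0) = colSums(z0) + Zpos (M1 - z0)
    out[rows, ] <- out[rows, , drop = FALSE] +
      X[rows, , drop = FALSE] %*% c1 +
      pc$Zpos[rows, , drop = FALSE] %*% (l1mpi + c2 - z0) +
      matrix(colSums(z0), length(rows), params$K, byrow = TRUE)
  }
  out + G
}

#' Log-likelihood of one cell under one cluster
#'
#' Sums the ZINB log-pmf over genes for a single cell row, with the cluster's
#' dropout probabilities and log-means and the cell's batch shift:
#' `sum_j log f_ZINB(x_j; pi_jk, exp(beta_jk + B_i' gamma), phi_j)`.
#'
#' @param x_row Integer vector of J counts for one cell.
#' @param params A [zinbmix_params()] object.
#' @param b_row Binary batch indicator vector of length S for the cell.
#' @param k Cluster index.
#' @return Scalar log-likelihood.
#' @export
cell_cluster_loglik <- function(x_row, params, b_row, k) {
  stopifnot(length(x_row) == params$J, length(b_row) == params$S)
  s <- which(b_row == 1)
  if (length(s) != 1L) stop("b_row must be a one-hot indicator", call. = FALSE)
  mu <- .clamped_mu(params$beta[, k] + params$gamma[s])
  sum(zinb_logpmf(x_row, .clip_pi(params$pi[, k]), mu, params$phi))
}

#' Observed-data log-likelihood of the ZINB mixture
#'
#' `sum_i log sum_k p_k prod_j f_ZINB(...)`, computed with all per-gene terms
#' in log space and the mixture combined by log-sum-exp.
#'
#' @param X Cells-by-genes count matrix (see [count_matrix()]).
#' @param B Batch design matrix (see [batch_design()]).
#' @param params A [zinbmix_params()] object.
#' @return Scalar log-likelihood.
#' @export
observed_loglik <- function(X, B, params) {
  if (params$K < 1L || nrow(X) < 1L) stop("empty data or no clusters", call. = FALSE)
  .validate_batch(B, nrow(X))
  pc <- .precompute(X, B)
  L <- .cell_loglik_matrix(X, params, pc)
  sum(.logsumexp_rows(L + matrix(log(params$p + 1e-300), nrow(L), ncol(L), byrow = TRUE)))
}

#' Penalized objective of the model
#'
#' The observed log-likelihood minus an L1 penalty pulling each cluster-specific
#' log-mean toward the gene's global mean:
#' `l(theta) - lambda * sum_jk |beta_jk - beta*_j|`.
#'
#' @inheritParams observed_loglik
#' @param lambda Non-negative penalty.
#' @return Scalar objective value (always `<=` the log-likelihood).
#' @export
penalized_objective <- function(X, B, params, lambda) {
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  observed_loglik(X, B, params) -
    lambda * sum(abs(params$beta - params$beta_star))
}
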