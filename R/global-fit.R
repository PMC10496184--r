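# Global (single-component) ZINB fits, one gene at a time. These provide the
# shrinkage targets beta*_j and the starting values for the mixture EM.

# weighted NB log-likelihood and gradient for one gene, aggregated by batch:
# par = c(beta, gamma[2..S], log phi); gamma_1 = 0 (reference batch).
# agg: list(n0 = zeros per batch, wz = zero weights per batch (posterior
# "not dropout"), u/cu/su = unique positive counts, their multiplicities and
# batch of each row, Apos = sum of positive counts per batch,
# npos = positive entries per batch)
# parameters are box-bounded by the caller, so exp() needs no clamping here
.gene_nb_obj <- function(par, agg, S) {
  beta <- par[1L]
  gamma <- c(0, par[seq_len(S - 1L) + 1L])[seq_len(S)]
  phi <- exp(par[length(par)])
  mu <- exp(beta + gamma)
  lmp <- log(mu + phi)
  c2 <- phi * (log(phi) - lmp)
  c1 <- beta + gamma - lmp
  ll <- sum(agg$wz * c2) +
    sum(agg$cu * lgamma(agg$u + phi)) - agg$lgu_const -
    sum(agg$npos) * lgamma(phi) +
    sum(agg$Apos * c1 + agg$npos * c2)
  -ll
}

.gene_nb_grad <- function(par, agg, S) {
  beta <- par[1L]
  gamma <- c(0, par[seq_len(S - 1L) + 1L])[seq_len(S)]
  phi <- exp(par[length(par)])
  mu <- exp(beta + gamma)
  mp <- mu + phi
  W <- agg$wz + agg$npos                       # NB weights per batch
  sc_s <- phi / mp * (agg$Apos - mu * W)       # d/d eta_s
  g_beta <- sum(sc_s)
  g_gamma <- if (S > 1L) sc_s[-1L] else numeric(0)
  g_phi <- sum(agg$cu * digamma(agg$u + phi)) - sum(agg$cu) * digamma(phi) +
    sum(W * (log(phi / mp) + mu / mp)) -
    sum(agg$Apos / mp)
  -c(g_beta, g_gamma, phi * g_phi)
}

#' Global single-cluster ZINB fit for one gene
#'
#' Maximizes the homogeneous (no-cluster) zero-inflated negative binomial
#' likelihood for a single gene with a batch shift on the log-mean, via an
#' inner EM over dropout indicators with a quasi-Newton update of
#' `(beta, gamma, log phi)`. The batch coefficients use a reference-batch
#' constraint (`gamma[1] = 0`) so the intercept is carried by `beta`.
#'
#' An all-zero gene cannot identify the parameters; it returns the documented
#' fallback (`pi = 0.99`, `beta = log(0.01)`, `phi = 10`, `gamma = 0`) with
#' `degenerate = TRUE`.
#'
#' @param x_col Integer vector of counts for one gene across cells.
#' @param B Batch design matrix.
#' @param max_em,tol Inner EM iteration cap and parameter tolerance.
#' @return A list with `beta_star`, `pi_tilde`, `phi_tilde`, `gamma_tilde`
#'   (length S, first entry 0) and a `degenerate` flag.
#' @export
fit_global_gene <- function(x_col, B, max_em = 20L, tol = 1e-4) {
  .validate_batch(B, length(x_col))
  S <- ncol(B)
  sidx <- .batch_index(B)
  if (all(x_col == 0)) {
    return(list(beta_star = log(0.01), pi_tilde = 0.99, phi_tilde = 10,
                gamma_tilde = rep(0, S), degenerate = TRUE))
  }
  n <- length(x_col)
  n0 <- vapply(seq_len(S), function(s) sum(x_col[sidx == s] == 0), 0)
  npos <- vapply(seq_len(S), function(s) sum(x_col[sidx == s] > 0), 0)
  Apos <- vapply(seq_len(S), function(s) sum(x_col[sidx == s]), 0)
  pos_tab <- do.call(rbind, lapply(seq_len(S), function(s) {
    v <- x_col[sidx == s]; v <- v[v > 0]
    if (!length(v)) return(NULL)
    tb <- table(v)
    cbind(s, as.numeric(names(tb)), as.numeric(tb))
  }))
  agg <- list(n0 = n0, npos = npos, Apos = Apos,
              u = pos_tab[, 2L], cu = pos_tab[, 3L],
              lgu_const = sum(pos_tab[, 3L] * lgamma(pos_tab[, 2L] + 1)))
  .fit_global_agg(agg, x_col, S, max_em, tol)
}

# inner EM over dropout indicators for one gene, given batch aggregates
.fit_global_agg <- function(agg, x_col, S, max_em = 20L, tol = 1e-4) {
  n <- length(x_col)
  zfrac <- sum(agg$n0) / n
  m <- mean(x_col); v <- stats::var(x_col)
  pi_t <- min(0.5 * zfrac, 0.95)
  beta_t <- log(max(mean(x_col[x_col > 0]), 0.02))
  phi_t <- min(max(m^2 / max(v - m, 1e-3), 0.05), 100)
  # box bounds keep the quasi-Newton search off the degenerate ridges
  # (phi -> 0 or infinity with compensating beta/gamma excursions)
  lo <- c(-30, rep(-20, S - 1L), log(1e-4))
  hi <- c(30, rep(20, S - 1L), log(1e6))
  par <- pmin(pmax(c(beta_t, rep(0, S - 1L), log(phi_t)), lo), hi)

  for (it in seq_len(max_em)) {
    beta <- par[1L]
    gamma <- c(0, par[seq_len(S - 1L) + 1L])[seq_len(S)]
    phi <- exp(par[length(par)])
    mu <- exp(beta + gamma)
    nb0 <- (phi / (mu + phi))^phi
    drop_s <- if (pi_t <= 0) rep(0, S) else pi_t / (pi_t + (1 - pi_t) * nb0)
    pi_new <- sum(agg$n0 * drop_s) / n
    agg$wz <- agg$n0 * (1 - drop_s)
    opt <- tryCatch(
      stats::optim(par, .gene_nb_obj, .gene_nb_grad,
                   agg = agg, S = S, method = "L-BFGS-B",
                   lower = lo, upper = hi,
                   control = list(maxit = if (it == 1L) 60L else 20L)),
      error = function(e) NULL)
    par_new <- if (is.null(opt) || !is.finite(opt$value) ||
                   opt$value > .gene_nb_obj(par, agg, S) + 1e-8) {
      par
    } else {
      opt$par
    }
    delta <- max(abs(c(par_new - par, pi_new - pi_t)))
    par <- par_new; pi_t <- pi_new
    if (delta < tol) break
  }
  list(beta_star = par[1L],
       pi_tilde = min(max(pi_t, 0), 1),
       phi_tilde = exp(par[length(par)]),
       gamma_tilde = c(0, par[seq_len(S - 1L) + 1L])[seq_len(S)],
       degenerate = FALSE)
}

#' Global ZINB fits for all genes
#'
#' Applies [fit_global_gene()] to every gene, returning the per-gene global
#' log-means, dropout probabilities, dispersions and batch coefficients used to
#' initialize the mixture EM and as the shrinkage targets of the penalty.
#'
#' @param X Cells-by-genes count matrix.
#' @param B Batch design matrix.
#' @return A list of class `zinbmix_global` with vectors `beta_star`,
#'   `pi_tilde`, `phi_tilde`, a J x S matrix `gamma_tilde`, and a logical
#'   `degenerate` flag per gene.
#' @export
zinb_global_fit <- function(X, B) {
  .validate_batch(B, nrow(X))
  S <- ncol(B)
  sidx <- .batch_index(B)
  J <- ncol(X)
  # batch-level sufficient statistics for all genes in three products
  Zpos <- (X > 0) + 0
  n0_all <- crossprod(1 - Zpos, B)      # J x S zeros per batch
  npos_all <- crossprod(Zpos, B)
  Apos_all <- crossprod(X, B)
  # per-gene, per-batch tables of unique positive counts, built once
  tabs <- vector("list", J)
  for (s in seq_len(S)) {
    rows <- which(sidx == s)
    for (j in seq_len(J)) {
      v <- X[rows, j]; v <- v[v > 0]
      if (!length(v)) next
      tb <- table(v)
      tabs[[j]] <- rbind(tabs[[j]],
                         cbind(as.numeric(names(tb)), as.numeric(tb)))
    }
  }
  fits <- lapply(seq_len(J), function(j) {
    x <- X[, j]
    if (all(x == 0)) {
      return(list(beta_star = log(0.01), pi_tilde = 0.99, phi_tilde = 10,
                  gamma_tilde = rep(0, S), degenerate = TRUE))
    }
    tb <- tabs[[j]]
    agg <- list(n0 = n0_all[j, ], npos = npos_all[j, ], Apos = Apos_all[j, ],
                u = tb[, 1L], cu = tb[, 2L],
                lgu_const = sum(tb[, 2L] * lgamma(tb[, 1L] + 1)))
    .fit_global_agg(agg, x, S)
  })
  structure(list(
    beta_star = vapply(fits, `[[`, 0, "beta_star"),
    pi_tilde = vapply(fits, `[[`, 0, "pi_tilde"),
    phi_tilde = vapply(fits, `[[`, 0, "phi_tilde"),
    gamma_tilde = do.call(rbind, lapply(fits, `[[`, "gamma_tilde")),
    degenerate = vapply(fits, `[[`, TRUE, "degenerate")
  ), class = "zinbmix_global")
}
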