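#' Negative binomial log-pmf in mean/dispersion form
#'
#' The negative binomial is parameterized by its mean `mu` and dispersion
#' `phi`, so that `Var = mu + mu^2 / phi`:
#' \deqn{f(x; \mu, \phi) = \frac{\Gamma(x+\phi)}{x!\,\Gamma(\phi)}
#'   \left(\frac{\mu}{\mu+\phi}\right)^x \left(\frac{\phi}{\mu+\phi}\right)^\phi.}
#' As `phi` grows the distribution approaches a Poisson with mean `mu`.
#'
#' @param x Non-negative integer count(s).
#' @param mu Positive mean(s).
#' @param phi Positive dispersion(s).
#' @return Log-probability, vectorized over arguments.
#' @export
nb_logpmf <- function(x, mu, phi) {
  if (any(!is.finite(x)) || any(!is.finite(mu)) || any(!is.finite(phi))) {
    stop("non-finite arguments to nb_logpmf", call. = FALSE)
  }
  if (any(x < 0) || any(abs(x - round(x)) > 1e-8)) {
    stop("x must be a non-negative integer", call. = FALSE)
  }
  if (any(mu <= 0) || any(phi <= 0)) stop("mu and phi must be positive", call. = FALSE)
  stats::dnbinom(round(x), size = phi, mu = mu, log = TRUE)
}

#' Zero-inflated negative binomial log-pmf
#'
#' Mixture of a point mass at zero with probability `pi` (the dropout
#' component) and a negative binomial with mean `mu` and dispersion `phi`:
#' `pi * I(x = 0) + (1 - pi) * NB(x; mu, phi)`. The `x = 0` branch is computed
#' with a log-sum-exp of the two components for numerical stability.
#'
#' @inheritParams nb_logpmf
#' @param pi Dropout probability in \[0, 1\], vectorized.
#' @return Log-probability, vectorized over arguments.
#' @export
zinb_logpmf <- function(x, pi, mu, phi) {
  if (any(pi < 0 | pi > 1) || any(!is.finite(pi))) {
    stop("pi must lie in [0, 1]", call. = FALSE)
  }
  nb <- nb_logpmf(x, mu, phi)
  out <- log1p(-pi) + nb
  zero <- (x == 0) & rep_len(TRUE, length(out))
  if (any(zero)) {
    piz <- rep_len(pi, length(out))[zero]
    out[zero] <- .logsumexp2(log(piz), log1p(-piz) + nb[zero])
  }
  # pure point mass: pi = 1 gives 0 at x = 0 and -Inf elsewhere
  one <- rep_len(pi, length(out)) == 1
  if (any(one)) out[one] <- ifelse(rep_len(x, length(out))[one] == 0, 0, -Inf)
  out
}

# elementwise log(exp(a) + exp(b)) robust to -Inf
.logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  r <- m + log(exp(a - m) + exp(b - m))
  r[!is.finite(m)] <- m[!is.finite(m)]
  r
}

# row-wise log-sum-exp of a matrix
.logsumexp_rows <- function(L) {
  m <- L[, 1L]
  if (ncol(L) > 1L) for (k in 2:ncol(L)) m <- pmax(m, L[, k])
  ok <- is.finite(m)
  out <- m
  if (any(ok)) out[ok] <- m[ok] + log(rowSums(exp(L[ok, , drop = FALSE] - m[ok])))
  out
}
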