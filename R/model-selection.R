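# Penalty-grid construction, BIC with the effective parameter count, and
# selection of the penalty and of the number of clusters.

#' Selection configuration
#'
#' Defaults: an equally spaced penalty grid of `M = 10` values from 0.01 to
#' 20, and candidate cluster numbers 2 to 20.
#'
#' @param lambda_min,lambda_max Endpoints of the penalty grid.
#' @param M Grid size (`>= 2`).
#' @param K_candidates Integer vector of candidate cluster numbers.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(lambda_min = 0.01, lambda_max = 20, M = 10L,
                             K_candidates = 2:20) {
  if (!(lambda_min < lambda_max)) stop("lambda_min must be below lambda_max", call. = FALSE)
  if (M < 2L) stop("the grid needs at least two values", call. = FALSE)
  structure(list(lambda_min = lambda_min, lambda_max = lambda_max, M = as.integer(M),
                 K_candidates = as.integer(K_candidates)),
            class = "selection_config")
}

#' Equally spaced penalty grid
#'
#' `lambda^(i) = lambda^(1) + (lambda^(M) - lambda^(1)) (i - 1) / (M - 1)`,
#' so the endpoints are exactly `lambda_min` and `lambda_max`.
#'
#' @param cfg A [selection_config()].
#' @return Numeric vector of M penalties.
#' @export
lambda_grid <- function(cfg = selection_config()) {
  cfg$lambda_min + (cfg$lambda_max - cfg$lambda_min) *
    (seq_len(cfg$M) - 1) / (cfg$M - 1)
}

#' BIC of a fitted model with the effective parameter count
#'
#' `BIC = -2 l(theta_hat) + log(n) d` where `l` is the *unpenalized* observed
#' log-likelihood and `d = (K - 1) + J + S + 2KJ - q` counts effective
#' parameters, with `q` the number of cluster log-means shrunk exactly to the
#' global mean.
#'
#' @param fit A `zinbmix_fit`.
#' @param tol Shrinkage-detection tolerance.
#' @return A one-row tibble: `lambda`, `K`, `loglik`, `q`, `d`, `bic`.
#' @export
.effective_d <- function(K, J, S, q) (K - 1) + J + S + 2 * K * J - q

zinbmix_bic <- function(fit, tol = 1e-6) {
  q <- sum(abs(fit$params$beta - fit$params$beta_star) <= tol)
  d <- .effective_d(fit$K, fit$J, fit$S, q)
  tibble::tibble(lambda = fit$lambda, K = fit$K, loglik = fit$loglik,
                 q = q, d = d, bic = -2 * fit$loglik + log(fit$n) * d)
}

#' Select the penalty by BIC along the grid
#'
#' Fits the model at every grid penalty (small to large, warm-starting each
#' fit from the previous solution) and returns the fit with the lowest BIC;
#' ties break toward the larger penalty, i.e. the sparser model.
#'
#' @inheritParams zinbmix_fit
#' @param cfg A [selection_config()].
#' @param warm_start Reuse the previous penalty's solution as the next start.
#' @param path_max_iter EM iteration cap for the grid fits: the path is
#'   explored glmnet-style with warm starts and moderately converged fits to
#'   rank the penalties, and the winner is then refit to full convergence.
#' @param refit Refit the selected penalty with the full iteration budget,
#'   warm-started from its path solution.
#' @param ... Passed to [zinbmix_fit()].
#' @return A list with `lambda`, `fit` (the argmin-BIC fit) and `records`
#'   (tibble of per-penalty BIC rows).
#' @export
select_lambda <- function(X, B, K, cfg = selection_config(), warm_start = TRUE,
                          global = NULL, path_max_iter = 30L, refit = TRUE,
                          max_iter = 200L, ...) {
  X <- count_matrix(X)
  if (!is.matrix(B)) B <- batch_design(B)
  if (is.null(global)) global <- zinb_global_fit(X, B)
  grid <- lambda_grid(cfg)
  fits <- vector("list", length(grid))
  init <- NULL
  ok <- logical(length(grid))
  for (i in seq_along(grid)) {
    fits[[i]] <- tryCatch(
      zinbmix_fit(X, B, K, lambda = grid[i], global = global, init = init,
                  max_iter = min(path_max_iter, max_iter), ...),
      error = function(e) e)
    ok[i] <- inherits(fits[[i]], "zinbmix_fit")
    if (ok[i] && warm_start) init <- fits[[i]]$params
  }
  if (!any(ok)) stop("all penalty-grid fits failed", call. = FALSE)
  records <- do.call(rbind, lapply(fits[ok], zinbmix_bic))
  # argmin BIC; ties toward larger lambda (sparser model)
  cand <- which(records$bic <= min(records$bic) + 1e-9)
  best <- cand[which.max(records$lambda[cand])]
  best_fit <- fits[ok][[best]]
  if (refit && !best_fit$converged && max_iter > path_max_iter) {
    best_fit <- zinbmix_fit(X, B, K, lambda = records$lambda[best],
                            global = global, init = best_fit$params,
                            max_iter = max_iter, ...)
    records[best, ] <- zinbmix_bic(best_fit)
  }
  list(lambda = records$lambda[best], fit = best_fit, records = records)
}

#' Select the number of clusters by BIC
#'
#' For every candidate `K`, selects the penalty by [select_lambda()] and
#' compares the resulting BIC values across `K`.
#'
#' @inheritParams select_lambda
#' @return A list with `K` (the argmin), `fit`, `records` (one BIC row per
#'   candidate, at that candidate's selected penalty) and `per_K` (the full
#'   [select_lambda()] results).
#' @export
select_K <- function(X, B, cfg = selection_config(), global = NULL, ...) {
  if (!length(cfg$K_candidates)) stop("no candidate K values", call. = FALSE)
  X <- count_matrix(X)
  if (!is.matrix(B)) B <- batch_design(B)
  if (is.null(global)) global <- zinb_global_fit(X, B)
  per_K <- lapply(cfg$K_candidates, function(K) {
    tryCatch(select_lambda(X, B, K, cfg = cfg, global = global, ...),
             error = function(e) NULL)
  })
  ok <- !vapply(per_K, is.null, TRUE)
  if (!any(ok)) stop("all fits failed across candidate K", call. = FALSE)
  records <- do.call(rbind, lapply(per_K[ok], function(r) zinbmix_bic(r$fit)))
  best <- which.min(records$bic)
  list(K = records$K[best], fit = per_K[ok][[best]]$fit,
       records = records, per_K = per_K[ok])
}
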