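#' Rasch endorsement probability
#'
#' Probability that a person of ability `beta` endorses an item of
#' difficulty `delta` under the dichotomous Rasch model,
#' `exp(beta - delta) / (1 + exp(beta - delta))`.  Vectorised and
#' numerically stable for large `|beta - delta|`.
#'
#' @param beta Person ability, logits.
#' @param delta Item difficulty, logits.
#' @return Probability in (0, 1).
#' @examples
#' item_prob(0, 0)   # 0.5
#' item_prob(0, 2)   # ~0.119: an item 2 logits above the person
#' @export
item_prob <- function(beta, delta) {
  if (any(!is.finite(beta)) || any(!is.finite(delta))) {
    stop("item_prob: beta and delta must be finite")
  }
  stats::plogis(beta - delta)
}

rasch_loglik <- function(X, beta, delta) {
  eta <- outer(beta, delta, "-")
  ll <- X * eta - log1p(exp(pmin(eta, 700)))
  sum(ll[!is.na(X)])
}

#' Joint maximum likelihood calibration of the dichotomous Rasch model
#'
#' Alternates damped Newton updates of person abilities (given item
#' difficulties) and item difficulties (given abilities) until the largest
#' absolute parameter change falls below `tol`.  Item difficulties are
#' re-centered to mean zero each cycle — the conventional gauge fix, so the
#' latent scale origin is the mean item difficulty.  Requires data already
#' screened of extreme (all-0 / all-1) persons and items; see
#' [screen_extremes()].
#'
#' Missing cells are treated as not administered and excluded from all
#' sums.  The raw score is the sufficient statistic: with complete data,
#' persons with equal raw scores receive identical abilities.
#'
#' @param data A [response_matrix()] with no extreme rows/columns.
#' @param max_iter Maximum alternation cycles.
#' @param tol Convergence tolerance on the maximum absolute parameter
#'   change, logits.
#' @param bias_correction If `TRUE`, multiply the final difficulties by
#'   `(L-1)/L` (L = number of items), the usual first-order correction for
#'   the outward bias of joint maximum likelihood. Default off.
#' @return Object of class `rasch_fit`: `beta`, `delta`, `se_beta`,
#'   `se_delta` (named numeric vectors, logits), `converged`, `n_iter`,
#'   `loglik`.
#' @export
estimate_jml <- function(data, max_iter = 100, tol = 1e-6,
                         bias_correction = FALSE) {
  X <- data$X
  n <- nrow(X); L <- ncol(X)
  obs <- !is.na(X)
  if (any(rowSums(obs) == 0) || any(colSums(obs) == 0)) {
    stop("degenerate data: person or item with no observed responses")
  }
  r <- rowSums(X, na.rm = TRUE)
  s <- colSums(X, na.rm = TRUE)
  n_obs_p <- rowSums(obs)
  n_obs_i <- colSums(obs)
  if (any(r == 0) || any(r == n_obs_p) || any(s == 0) || any(s == n_obs_i)) {
    stop("extreme persons or items present; run screen_extremes() first")
  }
  beta <- stats::qlogis((r + 0.5) / (n_obs_p + 1))
  delta <- stats::qlogis((n_obs_i - s) / n_obs_i)
  delta <- delta - mean(delta)

  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    P <- stats::plogis(outer(beta, delta, "-"))
    W <- P * (1 - P); W[!obs] <- 0; P[!obs] <- 0
    step_b <- (r - rowSums(P)) / rowSums(W)
    step_b <- pmax(pmin(step_b, 1), -1)
    beta_new <- beta + step_b

    P <- stats::plogis(outer(beta_new, delta, "-"))
    W <- P * (1 - P); W[!obs] <- 0; P[!obs] <- 0
    step_d <- (colSums(P) - s) / colSums(W)
    step_d <- pmax(pmin(step_d, 1), -1)
    delta_new <- delta + step_d
    delta_new <- delta_new - mean(delta_new)

    dmax <- max(abs(beta_new - beta), abs(delta_new - delta))
    beta <- beta_new; delta <- delta_new
    if (dmax < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("JML did not converge in ", max_iter, " cycles (last max change above tol)")
  }
  if (bias_correction) {
    delta <- delta * (L - 1) / L
    delta <- delta - mean(delta)
  }
  names(beta) <- rownames(X); names(delta) <- colnames(X)
  fit <- structure(list(beta = beta, delta = delta,
                        se_beta = NULL, se_delta = NULL,
                        converged = converged, n_iter = it,
                        loglik = rasch_loglik(X, beta, delta)),
                   class = "rasch_fit")
  standard_errors(fit, data)
}

#' Standard errors of Rasch measures
#'
#' Observed-information standard errors: for item i,
#' `1 / sqrt(sum_p P_pi (1 - P_pi))` over the persons who answered it, and
#' symmetrically for persons.  Entities with an empty information sum get
#' `NA` with a warning.
#'
#' @param fit A `rasch_fit`.
#' @param data The `response_matrix` it was fitted to.
#' @return The fit with `se_beta` and `se_delta` filled.
#' @export
standard_errors <- function(fit, data) {
  X <- data$X
  obs <- !is.na(X)
  P <- stats::plogis(outer(fit$beta, fit$delta, "-"))
  W <- P * (1 - P); W[!obs] <- 0
  info_p <- rowSums(W); info_i <- colSums(W)
  se_b <- ifelse(info_p > 0, 1 / sqrt(info_p), NA_real_)
  se_d <- ifelse(info_i > 0, 1 / sqrt(info_i), NA_real_)
  if (anyNA(se_b) || anyNA(se_d)) warning("empty information sum; se flagged missing")
  names(se_b) <- names(fit$beta); names(se_d) <- names(fit$delta)
  fit$se_beta <- se_b; fit$se_delta <- se_d
  fit
}

#' @export
print.rasch_fit <- function(x, ...) {
  cat("<rasch_fit> ", length(x$beta), " persons, ", length(x$delta), " items; ",
      if (x$converged) "converged" else "NOT converged", " in ", x$n_iter,
      " cycles; loglik ", format(x$loglik, digits = 8), "\n", sep = "")
  cat("  item difficulty range: [",
      format(min(x$delta), digits = 3), ", ",
      format(max(x$delta), digits = 3), "] logits (mean 0)\n", sep = "")
  invisible(x)
}

#' Export measures to CSV
#'
#' One row per entity with columns `entity_type` (person|item), `id`,
#' `measure`, `se`, `raw_score`, `count`.
#'
#' @param fit A `rasch_fit`.
#' @param data The fitted `response_matrix`.
#' @param path Output CSV path.
#' @return Invisibly, the exported data.frame.
#' @export
export_fit <- function(fit, data, path) {
  obs <- !is.na(data$X)
  out <- rbind(
    data.frame(entity_type = "person", id = names(fit$beta),
               measure = unname(fit$beta), se = unname(fit$se_beta),
               raw_score = rowSums(data$X, na.rm = TRUE),
               count = rowSums(obs), stringsAsFactors = FALSE),
    data.frame(entity_type = "item", id = names(fit$delta),
               measure = unname(fit$delta), se = unname(fit$se_delta),
               raw_score = colSums(data$X, na.rm = TRUE),
               count = colSums(obs), stringsAsFactors = FALSE)
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
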