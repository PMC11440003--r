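#' Build the dummy-coded DIF design
#'
#' Dummy-codes the person covariates with named reference levels so that a
#' reference person (by default female / high-school age / severe
#' symptoms) has an all-zero covariate row.  One column per non-reference
#' level: `gender` (male indicator), `infant`, `kindergarten`, `primary`,
#' `junior_high`, `non_autism`, `mild_moderate` — 7 columns.
#'
#' @param covariates data.frame with columns `gender`, `age_group`,
#'   `symptom_level` (and optionally `person_id`), levels as in
#'   [read_responses()].
#' @param references Named list of reference levels per factor.
#' @return Object of class `dif_design`: `X` (persons x q 0/1 matrix),
#'   `coding_map` (column -> factor/level), `references`.
#' @export
build_design <- function(covariates,
                         references = list(gender = "female",
                                           age_group = "high",
                                           symptom_level = "severe")) {
  cov <- as.data.frame(covariates, stringsAsFactors = FALSE)
  cols <- list()
  map <- list()
  for (v in names(covariate_levels)) {
    if (is.null(cov[[v]])) stop("covariates lack column '", v, "'")
    vals <- as.character(cov[[v]])
    bad <- setdiff(unique(vals), covariate_levels[[v]])
    if (length(bad)) stop("unknown ", v, " level(s): ", paste(bad, collapse = ", "))
    ref <- references[[v]]
    if (!(ref %in% covariate_levels[[v]])) {
      stop("reference level '", ref, "' is not a level of ", v)
    }
    for (lev in setdiff(covariate_levels[[v]], ref)) {
      nm <- if (v == "gender") "gender" else lev
      cols[[nm]] <- as.integer(vals == lev)
      map[[nm]] <- list(factor = v, level = lev)
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- if (!is.null(cov$person_id)) as.character(cov$person_id) else NULL
  structure(list(X = X, coding_map = map, references = references),
            class = "dif_design")
}

#' Log-odds of endorsement under the DIF model
#'
#' `alpha_i * (theta - (diff_i + x . gamma_i))`: the effective difficulty
#' of item i for a person with dummy row `x` is `diff_i + x . gamma_i`, so
#' a negative coefficient makes the item easier (more readily endorsed)
#' for that group at equal latent trait.
#'
#' @param theta Latent trait, logits.
#' @param item Item index.
#' @param person_covariates Dummy-coded covariate row (length q).
#' @param model A `dif_model`.
#' @return Log-odds (numeric).
#' @export
item_response_logodds <- function(theta, item, person_covariates, model) {
  drift <- sum(person_covariates * model$gamma[item, ])
  model$alpha[item] * (theta - (model$diff[item] + drift))
}

# Gauss-Hermite nodes/weights for a standard-normal latent trait.
gh_rule <- function(nodes) {
  gh <- pracma::gaussHermite(nodes)
  list(theta = sqrt(2) * gh$x, logw = log(gh$w) - 0.5 * log(pi))
}

# Expand per-pattern quantities to flattened (pattern, node) rows.
dif_workspace <- function(X, D, rule) {
  pat_key <- apply(D, 1, paste, collapse = "")
  pat_levels <- unique(pat_key)
  pat <- match(pat_key, pat_levels)
  Dg <- D[match(pat_levels, pat_key), , drop = FALSE]
  G <- nrow(Dg); Q <- length(rule$theta)
  obs <- !is.na(X)
  X0 <- X; X0[!obs] <- 0L
  list(X0 = X0, obs = obs + 0, pat = pat, Dg = Dg, G = G, Q = Q,
       theta_rows = rep(rule$theta, times = G),       # length G*Q
       Drow = Dg[rep(seq_len(G), each = Q), , drop = FALSE],
       logw = rule$logw)
}

# eta for all (pattern, node) rows x items
dif_eta <- function(ws, alpha, diff, gamma) {
  drift <- ws$Dg %*% t(gamma)                         # G x L
  shift <- drift[rep(seq_len(ws$G), each = ws$Q), , drop = FALSE]
  outer(ws$theta_rows, alpha) -
    (matrix(alpha * diff, nrow(shift), ncol(shift), byrow = TRUE) +
       shift * matrix(alpha, nrow(shift), ncol(shift), byrow = TRUE))
}

# E-step: posterior node weights and marginal loglik
dif_estep <- function(ws, alpha, diff, gamma) {
  eta <- dif_eta(ws, alpha, diff, gamma)
  logP <- -log1p(exp(-eta))
  log1mP <- logP - eta
  n <- nrow(ws$X0); Q <- ws$Q
  W <- matrix(0, n, Q)
  ll <- 0
  for (g in seq_len(ws$G)) {
    rows <- which(ws$pat == g)
    blk <- ((g - 1) * Q + 1):(g * Q)
    lp <- ws$X0[rows, , drop = FALSE] %*% t(logP[blk, , drop = FALSE]) +
      (ws$obs[rows, , drop = FALSE] - ws$X0[rows, , drop = FALSE]) %*%
        t(log1mP[blk, , drop = FALSE])
    lp <- sweep(lp, 2, ws$logw, "+")
    m <- lp[cbind(seq_len(nrow(lp)), max.col(lp))]
    pw <- exp(lp - m)
    rs <- rowSums(pw)
    W[rows, ] <- pw / rs
    ll <- ll + sum(m + log(rs))
  }
  list(W = W, loglik = ll)
}

# Aggregate expected successes/failures per (pattern, node) row
dif_counts <- function(ws, W) {
  L <- ncol(ws$X0); Q <- ws$Q
  S <- matrix(0, ws$G * Q, L); Fm <- matrix(0, ws$G * Q, L)
  for (g in seq_len(ws$G)) {
    rows <- which(ws$pat == g)
    blk <- ((g - 1) * Q + 1):(g * Q)
    Wg <- W[rows, , drop = FALSE]
    S[blk, ] <- t(Wg) %*% ws$X0[rows, , drop = FALSE]
    Fm[blk, ] <- t(Wg) %*% (ws$obs[rows, , drop = FALSE] -
                              ws$X0[rows, , drop = FALSE])
  }
  list(S = S, Fm = Fm)
}

# Penalized M-step for one item: damped Newton on (alpha, diff) then
# coordinate soft-threshold updates of gamma.
dif_mstep_item <- function(s, f, ws, a, d, g_row, lambda, rasch_constrained,
                           inner = 3) {
  th <- ws$theta_rows
  Xc <- ws$Drow
  n_gq <- s + f
  clamp <- function(x, lim) max(min(x, lim), -lim)
  # expected complete-data log-likelihood for this item (stable in eta)
  bern_ll <- function(a_, d_, drift_) {
    eta <- a_ * (th - d_ - drift_)
    sum(s * eta - n_gq * (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  }
  pen <- function(g_) if (is.finite(lambda)) lambda * sum(abs(g_)) else 0
  drift <- as.vector(Xc %*% g_row)
  obj <- bern_ll(a, d, drift) - pen(g_row)
  for (sweep_i in seq_len(inner)) {
    P <- 1 / (1 + exp(-a * (th - d - drift)))
    u <- th - d - drift
    resid <- s - n_gq * P
    wgt <- n_gq * P * (1 - P)
    if (rasch_constrained) {
      da <- 0
      dd <- clamp(-a * sum(resid) / max(a^2 * sum(wgt), 1e-10), 1)
    } else {
      ga <- sum(resid * u)
      gd <- -a * sum(resid)
      haa <- sum(wgt * u^2)
      hdd <- a^2 * sum(wgt)
      had <- -a * sum(wgt * u)
      Hdet <- haa * hdd - had^2
      if (Hdet > 1e-12) {
        da <- (hdd * ga - had * gd) / Hdet
        dd <- (haa * gd - had * ga) / Hdet
      } else {
        da <- ga / max(haa, 1e-10); dd <- gd / max(hdd, 1e-10)
      }
      da <- clamp(da, 0.5); dd <- clamp(dd, 1)
    }
    # backtracking line search keeps the M-step an ascent step
    step <- 1
    for (half in 1:12) {
      a_try <- if (rasch_constrained) a else max(a + step * da, 0.02)
      d_try <- d + step * dd
      o_try <- bern_ll(a_try, d_try, drift) - pen(g_row)
      if (o_try >= obj - 1e-12) { a <- a_try; d <- d_try; obj <- o_try; break }
      step <- step / 2
    }
    # gamma coordinates: quadratic-approximation soft-threshold updates,
    # each accepted only if the penalized objective does not decrease
    for (k in seq_len(ncol(Xc))) {
      xk <- Xc[, k]
      P <- 1 / (1 + exp(-a * (th - d - drift)))
      grad <- -a * sum((s - n_gq * P) * xk)
      hess <- a^2 * sum(n_gq * P * (1 - P) * xk)   # xk is 0/1 so xk^2 = xk
      if (hess < 1e-10) next
      z <- hess * g_row[k] + grad
      g_new <- sign(z) * max(abs(z) - lambda, 0) / hess
      g_new <- max(min(g_new, g_row[k] + 1), g_row[k] - 1)
      if (g_new == g_row[k]) next
      step <- 1
      for (half in 1:12) {
        g_try <- g_row[k] + step * (g_new - g_row[k])
        drift_try <- drift + (g_try - g_row[k]) * xk
        g_vec <- g_row; g_vec[k] <- g_try
        o_try <- bern_ll(a, d, drift_try) - pen(g_vec)
        if (o_try >= obj - 1e-12) {
          drift <- drift_try; g_row[k] <- g_try; obj <- o_try; break
        }
        step <- step / 2
      }
    }
  }
  list(a = a, d = d, g = g_row)
}

dif_em <- function(ws, lambda, start, rasch_constrained, max_iter, tol) {
  alpha <- start$alpha; diff <- start$diff; gamma <- start$gamma
  pen_ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    es <- dif_estep(ws, alpha, diff, gamma)
    cnt <- dif_counts(ws, es$W)
    old <- c(alpha, diff, gamma)
    for (i in seq_along(alpha)) {
      up <- dif_mstep_item(cnt$S[, i], cnt$Fm[, i], ws, alpha[i], diff[i],
                           gamma[i, ], lambda, rasch_constrained)
      alpha[i] <- up$a; diff[i] <- up$d; gamma[i, ] <- up$g
    }
    dmax <- max(abs(c(alpha, diff, gamma) - old))
    pen_ll <- es$loglik -
      (if (is.finite(lambda)) lambda * sum(abs(gamma)) else 0)
    # stop on parameter stability or a stalled penalized objective
    if (dmax < tol ||
        abs(pen_ll - pen_ll_old) < 1e-9 * (1 + abs(pen_ll))) {
      converged <- TRUE
      break
    }
    pen_ll_old <- pen_ll
  }
  es <- dif_estep(ws, alpha, diff, gamma)
  list(alpha = alpha, diff = diff, gamma = gamma, loglik = es$loglik,
       converged = converged, n_iter = it)
}

# Smallest lambda with all gamma zero: max |score| of the penalized
# coordinates at the null (gamma = 0) optimum.
dif_lambda_max <- function(ws, null_fit) {
  es <- dif_estep(ws, null_fit$alpha, null_fit$diff, null_fit$gamma)
  cnt <- dif_counts(ws, es$W)
  eta <- dif_eta(ws, null_fit$alpha, null_fit$diff, null_fit$gamma)
  P <- stats::plogis(eta)
  gmax <- 0
  for (i in seq_along(null_fit$alpha)) {
    resid <- cnt$S[, i] - (cnt$S[, i] + cnt$Fm[, i]) * P[, i]
    sc <- abs(as.vector(t(ws$Drow) %*% resid) * null_fit$alpha[i])
    gmax <- max(gmax, sc)
  }
  gmax
}

new_dif_model <- function(fit, lambda, n_persons, q_names, item_names,
                          rasch_constrained, zero_threshold) {
  gamma <- fit$gamma
  gamma[abs(gamma) < zero_threshold] <- 0
  dimnames(gamma) <- list(item_names, q_names)
  L <- length(fit$alpha)
  df <- (if (rasch_constrained) L else 2L * L) + sum(gamma != 0)
  structure(list(alpha = stats::setNames(fit$alpha, item_names),
                 diff = stats::setNames(fit$diff, item_names),
                 gamma = gamma,
                 theta_scale = list(mean = 0, sd = 1),
                 lambda = lambda, loglik = fit$loglik,
                 bic = -2 * fit$loglik + log(n_persons) * df,
                 df = df, converged = fit$converged,
                 n_iter = fit$n_iter,
                 rasch_constrained = rasch_constrained,
                 zero_threshold = zero_threshold),
            class = "dif_model")
}

#' Fit the lasso-penalized uniform-DIF model over a penalty path
#'
#' Marginal maximum likelihood for the two-parameter logistic model with
#' uniform group shifts: log-odds for person p, item i is
#' `alpha_i (theta_p - diff_i - x_p . gamma_i)` with a standard-normal
#' latent trait integrated by Gauss-Hermite quadrature, maximized minus an
#' L1 penalty `lambda * sum |gamma|` by an EM algorithm whose M-step
#' combines damped Newton updates of the item parameters with coordinate
#' soft-threshold updates of the DIF coefficients.  The path runs from
#' `lambda_max` (the smallest penalty with all gamma exactly zero,
#' computed from the score equations at the no-DIF fit) down to
#' `lambda_max * lambda_min_ratio` on a log-spaced grid, warm-starting
#' each model from the previous one.  Per-model
#' `BIC = -2 loglik + log(n_persons) * df` with `df` counting item
#' parameters plus non-zero DIF coefficients.
#'
#' @param data A screened `response_matrix`.
#' @param design A [build_design()] aligned to the persons of `data`.
#' @param n_lambda Number of penalty values on the path.
#' @param quadrature_nodes Gauss-Hermite nodes for the trait integral.
#' @param lambda_min_ratio Smallest penalty as a fraction of `lambda_max`.
#' @param rasch_constrained If `TRUE`, all discriminations are fixed at 1
#'   (Rasch-constrained variant); default `FALSE` fits the 2PL.
#' @param zero_threshold Coefficients below this magnitude are reported as
#'   zero and excluded from `df`.
#' @param max_em_iter,tol EM iteration cap and parameter-change tolerance.
#' @return Object of class `dif_path`: `models` (list of `dif_model` over
#'   decreasing lambda), `lambda`, `bic`, `selected_index`.
#' @export
fit_dif_path <- function(data, design, n_lambda = 50, quadrature_nodes = 21,
                         lambda_min_ratio = 1e-3, rasch_constrained = FALSE,
                         zero_threshold = 1e-4, max_em_iter = 200,
                         tol = 1e-4) {
  X <- data$X
  D <- design$X
  if (nrow(D) != nrow(X)) stop("design has ", nrow(D), " rows but data has ",
                               nrow(X), " persons")
  ws <- dif_workspace(X, D, gh_rule(quadrature_nodes))
  L <- ncol(X); q <- ncol(D)
  p_hat <- colMeans(X, na.rm = TRUE)
  start <- list(alpha = rep(1, L),
                diff = stats::qlogis(1 - pmin(pmax(p_hat, 0.02), 0.98)),
                gamma = matrix(0, L, q))
  null_fit <- dif_em(ws, lambda = Inf, start, rasch_constrained,
                     max_iter = max_em_iter, tol = tol)
  lam_max <- max(dif_lambda_max(ws, null_fit), 1e-6)  # guard: zero design
  lambdas <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                     length.out = n_lambda))
  models <- vector("list", n_lambda)
  warm <- null_fit
  any_ok <- FALSE
  for (j in seq_len(n_lambda)) {
    fit <- dif_em(ws, lambdas[j], warm, rasch_constrained,
                  max_iter = max_em_iter, tol = tol)
    if (!fit$converged) {
      warning("DIF EM not converged at lambda = ", signif(lambdas[j], 4),
              "; model flagged, path continues")
    } else any_ok <- TRUE
    warm <- fit
    models[[j]] <- new_dif_model(fit, lambdas[j], nrow(X), colnames(D),
                                 colnames(X), rasch_constrained,
                                 zero_threshold)
  }
  if (!any_ok) stop("no DIF model on the path converged")
  bic <- vapply(models, function(m) m$bic, numeric(1))
  structure(list(models = models, lambda = lambdas, bic = bic,
                 selected_index = which.min(bic)),
            class = "dif_path")
}

#' @export
print.dif_path <- function(x, ...) {
  sel <- x$models[[x$selected_index]]
  cat("<dif_path> ", length(x$models), " models, lambda ",
      signif(max(x$lambda), 4), " .. ", signif(min(x$lambda), 4),
      "\n  BIC-selected: lambda ", signif(sel$lambda, 4), ", ",
      sum(sel$gamma != 0), " non-zero DIF coefficient(s)\n", sep = "")
  invisible(x)
}

#' @export
print.dif_model <- function(x, ...) {
  cat("<dif_model> ", length(x$alpha), " items, lambda ",
      signif(x$lambda, 4), ", loglik ", format(x$loglik, digits = 8),
      ", BIC ", format(x$bic, digits = 8), ", df ", x$df, "\n  ",
      sum(x$gamma != 0), " non-zero DIF coefficient(s) on ",
      sum(rowSums(x$gamma != 0) > 0), " item(s)\n", sep = "")
  invisible(x)
}

#' Select the BIC-optimal model on a path
#'
#' Minimizes BIC; ties break toward larger lambda (the sparser model).
#'
#' @param path A `dif_path`.
#' @return The selected `dif_model`.
#' @export
select_bic <- function(path) {
  if (!length(path$models)) stop("empty path")
  path$models[[which.min(path$bic)]]  # lambdas decrease, so first min = largest lambda
}

#' Tabulate DIF coefficients of a selected model
#'
#' One row per item, one column per dummy-coded covariate (gender, the
#' four non-reference age groups, the two non-reference symptom levels);
#' coefficients below the model's zero threshold print as 0.  A non-zero
#' entry is uniform DIF for that group on that item.
#'
#' @param model A `dif_model`.
#' @param design The `dif_design` it was fitted with.
#' @return data.frame with column `item` then the covariate columns.
#' @export
dif_table <- function(model, design) {
  gamma <- model$gamma
  gamma[abs(gamma) < model$zero_threshold] <- 0
  out <- data.frame(item = rownames(gamma), gamma, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}
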