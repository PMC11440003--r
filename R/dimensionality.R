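#' Principal component analysis of standardized residuals
#'
#' Unidimensionality check: after the Rasch dimension is removed, the
#' standardized residuals should be unstructured noise.  The item x item
#' correlation matrix of standardized residuals (pairwise-complete) is
#' eigendecomposed; its eigenvalues are the "contrast" sizes in item units
#' (they sum to the number of items).  A first contrast with eigenvalue
#' >= 2 — more residual structure than two items' worth of noise — signals
#' a secondary dimension.
#'
#' The variance explained by the Rasch measures is computed from the
#' observation-variance split: in standardized-residual units each observed
#' cell contributes unit noise variance (L per person in total, L = number
#' of items), while the model-explained part is
#' `V = sum_i mean_p [ P_pi (1-P_pi) (beta_p - delta_i)^2 ]`, so
#' `percent explained = 100 V / (V + L)`.  The descriptive measure-to-
#' contrast ratios `V / eigenvalue` are reported but do not enter the
#' unidimensionality flag.
#'
#' @param fit A converged `rasch_fit`.
#' @param data The fitted `response_matrix` (>= 3 items).
#' @param min_overlap Minimum persons jointly answering an item pair;
#'   pairs below it are flagged in `sparse_pairs`.
#' @return Object of class `contrast_result`: `variance_explained_by_measure`
#'   (percent), `measure_eigen_equivalent` (V, item units),
#'   `contrast_eigenvalues`, `contrast_percents`, `measure_contrast_ratios`,
#'   `loadings` (items x contrasts, sign-fixed so the largest-loading item
#'   of each contrast is positive), `unidimensional`, `sparse_pairs`.
#' @export
residual_pca <- function(fit, data, min_overlap = 30) {
  X <- data$X
  L <- ncol(X)
  if (L < 3) stop("residual PCA needs at least 3 items")
  Z <- standardized_residuals(fit, data)
  obs <- !is.na(Z)
  overlap <- crossprod(obs + 0)
  sparse <- which(overlap < min_overlap & upper.tri(overlap), arr.ind = TRUE)
  sparse_pairs <- if (nrow(sparse)) {
    data.frame(item_a = colnames(X)[sparse[, 1]],
               item_b = colnames(X)[sparse[, 2]],
               overlap = overlap[sparse], stringsAsFactors = FALSE)
  } else NULL
  R <- suppressWarnings(stats::cor(Z, use = "pairwise.complete.obs"))
  if (anyNA(R)) {
    bad <- colnames(R)[apply(R, 2, anyNA)]
    stop("residual correlation undefined for item(s) ",
         paste(bad, collapse = ", "), " (constant or disjoint residuals)")
  }
  eg <- eigen(R, symmetric = TRUE)
  ev <- eg$values
  if (min(ev) < -1e-6) warning("residual correlation matrix not PSD; check collinear items")
  loadings <- eg$vectors * rep(sqrt(pmax(ev, 0)), each = L)
  # sign convention: largest-|loading| item positive per contrast
  for (k in seq_len(ncol(loadings))) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) loadings[, k] <- -loadings[, k]
  }
  dimnames(loadings) <- list(colnames(X), paste0("contrast_", seq_len(L)))

  P <- stats::plogis(outer(fit$beta, fit$delta, "-"))
  W <- P * (1 - P); W[!obs] <- 0
  M2 <- W * outer(fit$beta, fit$delta, "-")^2
  V_measure <- sum(colSums(M2) / colSums(obs))  # item units
  pct <- 100 * V_measure / (V_measure + L)

  structure(list(
    variance_explained_by_measure = pct,
    measure_eigen_equivalent = V_measure,
    contrast_eigenvalues = ev,
    contrast_percents = 100 * ev / (V_measure + L),
    measure_contrast_ratios = V_measure / ev,
    loadings = loadings,
    unidimensional = (pct >= 40) && (ev[1] < 2.0),
    sparse_pairs = sparse_pairs), class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat("<contrast_result> variance explained by measures: ",
      format(x$variance_explained_by_measure, digits = 3),
      "%\n  first contrast eigenvalue: ",
      format(x$contrast_eigenvalues[1], digits = 3),
      " (", format(x$contrast_percents[1], digits = 2), "% of total)\n",
      "  unidimensional: ", x$unidimensional, "\n", sep = "")
  invisible(x)
}

#' Items loading on residual contrasts
#'
#' Lists, per contrast, the items whose absolute loading meets the
#' threshold (default 0.4, the conventional cut for a meaningful loading),
#' ordered by decreasing absolute loading.
#'
#' @param result A `contrast_result`.
#' @param threshold Minimum absolute loading for inclusion.
#' @param n_contrasts How many leading contrasts to tabulate.
#' @return Named list of data.frames (`item`, `loading`).
#' @export
contrast_loadings <- function(result, threshold = 0.4, n_contrasts = 3) {
  Ld <- result$loadings
  n_contrasts <- min(n_contrasts, ncol(Ld))
  out <- lapply(seq_len(n_contrasts), function(k) {
    sel <- which(abs(Ld[, k]) >= threshold)
    sel <- sel[order(-abs(Ld[sel, k]))]
    data.frame(item = rownames(Ld)[sel], loading = unname(Ld[sel, k]),
               stringsAsFactors = FALSE)
  })
  names(out) <- colnames(Ld)[seq_len(n_contrasts)]
  out
}
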