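#' Standardized response residuals
#'
#' `z_pi = (x_pi - P_pi) / sqrt(P_pi (1 - P_pi))` for observed cells;
#' missing cells stay missing.  Under the model each z has mean 0 and
#' variance 1, which is what makes the mean-square fit statistics and the
#' residual PCA interpretable.
#'
#' @param fit A converged `rasch_fit`.
#' @param data The fitted `response_matrix`.
#' @return Numeric persons x items matrix.
#' @export
standardized_residuals <- function(fit, data) {
  X <- data$X
  P <- stats::plogis(outer(fit$beta, fit$delta, "-"))
  if (any(P[!is.na(X)] <= 0 | P[!is.na(X)] >= 1)) {
    stop("degenerate probability 0 or 1 encountered; screen extremes first")
  }
  Z <- (X - P) / sqrt(P * (1 - P))
  dimnames(Z) <- dimnames(X)
  Z
}

# Wilson-Hilferty cube-root standardization of a mean-square with model
# variance q2; reported values clamped to +/-9.9 as fit tables conventionally
# print them.
wh_zstd <- function(mnsq, q2, clamp = 9.9) {
  q <- sqrt(pmax(q2, .Machine$double.eps))
  z <- (mnsq^(1 / 3) - 1) * (3 / q) + q / 3
  pmax(pmin(z, clamp), -clamp)
}

#' Fit report: infit/outfit statistics, correlations, summary indices
#'
#' Outfit MNSQ is the unweighted mean of squared standardized residuals;
#' infit MNSQ is the information-weighted mean,
#' `sum(W z^2) / sum(W)` with `W = P(1-P)`.  Both have expectation ~1 under
#' the model.  Zstd is the Wilson-Hilferty cube-root standardization using
#' the statistic's model variance (for a Bernoulli cell, `var(z^2) = 1/W - 4`
#' and `var((x-P)^2) = W - 4W^2`), clamped to +/-9.9 for reporting.
#' Point-measure correlations and model-based separation/reliability
#' summaries are included.
#'
#' @param fit A converged `rasch_fit`.
#' @param data The fitted `response_matrix`.
#' @return Object of class `fit_report`: `per_item` and `per_person`
#'   data.frames and a `summary` list with person/item separation and
#'   reliability.
#' @export
rasch_fit_report <- function(fit, data) {
  X <- data$X
  obs <- !is.na(X)
  P <- stats::plogis(outer(fit$beta, fit$delta, "-"))
  W <- P * (1 - P)
  Z2 <- ((X - P)^2) / W
  Z2[!obs] <- 0
  Wm <- W; Wm[!obs] <- 0
  SqRes <- (X - P)^2; SqRes[!obs] <- 0

  stat_block <- function(margin) {
    msum <- function(M) if (margin == 2) colSums(M) else rowSums(M)
    n_obs <- msum(obs + 0)
    outfit <- msum(Z2) / n_obs
    q2_out <- msum((1 / Wm - 4) * obs) / n_obs^2
    infit <- msum(SqRes) / msum(Wm)
    q2_in <- msum(Wm - 4 * Wm^2) / msum(Wm)^2
    few <- n_obs < 2
    out <- data.frame(
      count = n_obs,
      outfit_mnsq = ifelse(few, NA_real_, outfit),
      outfit_zstd = ifelse(few, NA_real_, wh_zstd(outfit, q2_out)),
      infit_mnsq = ifelse(few, NA_real_, infit),
      infit_zstd = ifelse(few, NA_real_, wh_zstd(infit, q2_in)))
    out
  }

  ib <- stat_block(2)
  pb <- stat_block(1)
  per_item <- data.frame(
    id = names(fit$delta),
    total_score = colSums(X, na.rm = TRUE),
    count = ib$count,
    measure = unname(fit$delta),
    se = unname(fit$se_delta),
    infit_mnsq = ib$infit_mnsq, infit_zstd = ib$infit_zstd,
    outfit_mnsq = ib$outfit_mnsq, outfit_zstd = ib$outfit_zstd,
    point_measure_corr = point_measure_corr(data, fit),
    stringsAsFactors = FALSE, row.names = NULL)
  per_person <- data.frame(
    id = names(fit$beta),
    total_score = rowSums(X, na.rm = TRUE),
    count = pb$count,
    measure = unname(fit$beta),
    se = unname(fit$se_beta),
    infit_mnsq = pb$infit_mnsq, infit_zstd = pb$infit_zstd,
    outfit_mnsq = pb$outfit_mnsq, outfit_zstd = pb$outfit_zstd,
    stringsAsFactors = FALSE, row.names = NULL)

  ps <- separation_reliability(fit$beta, fit$se_beta)
  is <- separation_reliability(fit$delta, fit$se_delta)
  structure(list(per_item = per_item, per_person = per_person,
                 summary = list(person_separation = ps$separation,
                                person_reliability = ps$reliability,
                                item_separation = is$separation,
                                item_reliability = is$reliability)),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  s <- x$summary
  cat("<fit_report> ", nrow(x$per_person), " persons, ", nrow(x$per_item),
      " items\n  person separation ", format(s$person_separation, digits = 3),
      " (reliability ", format(s$person_reliability, digits = 3),
      "); item separation ", format(s$item_separation, digits = 3),
      " (reliability ", format(s$item_reliability, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Flag misfitting items
#'
#' Applies acceptance windows to the infit columns: an item is flagged when
#' its infit MNSQ falls outside `mnsq_range` or its infit Zstd outside
#' `zstd_range`.  Defaults are the conventional 0.75-1.33 and -2 to 2
#' windows; other conventions (e.g. 0.5-1.5) are one argument away.
#'
#' @param report A `fit_report`, or any data.frame with columns `id` (or
#'   `item`), `infit_mnsq`, `infit_zstd` (e.g. a published fit table being
#'   re-screened).
#' @param mnsq_range,zstd_range Length-2 numeric acceptance intervals.
#' @return List: `flags` (data.frame with `id`, `mnsq_violation`,
#'   `zstd_violation`, `any`, `both`), `n_any`, `n_both`.
#' @export
flag_misfit <- function(report, mnsq_range = c(0.75, 1.33),
                        zstd_range = c(-2, 2)) {
  tab <- if (inherits(report, "fit_report")) report$per_item else as.data.frame(report)
  if (is.null(tab$id) && !is.null(tab$item)) tab$id <- tab$item
  stopifnot(all(c("id", "infit_mnsq", "infit_zstd") %in% names(tab)))
  mv <- tab$infit_mnsq < mnsq_range[1] | tab$infit_mnsq > mnsq_range[2]
  zv <- tab$infit_zstd < zstd_range[1] | tab$infit_zstd > zstd_range[2]
  flags <- data.frame(id = tab$id, mnsq_violation = mv, zstd_violation = zv,
                      any = mv | zv, both = mv & zv, stringsAsFactors = FALSE)
  list(flags = flags, n_any = sum(flags$any, na.rm = TRUE),
       n_both = sum(flags$both, na.rm = TRUE))
}

#' Separation and reliability indices
#'
#' Signal-to-noise summaries of a set of measures: error variance is the
#' mean squared standard error, true variance the observed variance of the
#' measures minus error (floored at 0), separation
#' `G = sqrt(true / error)` and reliability `R = true / observed`, so
#' `R = G^2 / (1 + G^2)` identically.
#'
#' @param measures,ses Numeric vectors of measures and their standard
#'   errors, logits; at least 2 entities.
#' @return List with `separation` and `reliability`.
#' @export
separation_reliability <- function(measures, ses) {
  ok <- is.finite(measures) & is.finite(ses)
  measures <- measures[ok]; ses <- ses[ok]
  if (length(measures) < 2) stop("need at least 2 entities with measures and ses")
  err_var <- mean(ses^2)
  obs_var <- stats::var(measures)
  true_var <- max(obs_var - err_var, 0)
  if (obs_var <= 0) return(list(separation = 0, reliability = 0))
  G <- sqrt(true_var / err_var)
  list(separation = G, reliability = true_var / obs_var)
}

#' Point-measure correlation per item
#'
#' Pearson correlation between the item's responses and the person
#' measures, over the persons who answered it.  A constant item column
#' yields `NA` with a warning.
#'
#' @param data A `response_matrix`.
#' @param fit A `rasch_fit`.
#' @return Named numeric vector, one value per item.
#' @export
point_measure_corr <- function(data, fit) {
  X <- data$X
  out <- vapply(seq_len(ncol(X)), function(i) {
    x <- X[, i]; ok <- !is.na(x)
    if (stats::sd(x[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], fit$beta[ok])
  }, numeric(1))
  if (anyNA(out)) warning("constant item column(s); correlation flagged missing")
  names(out) <- colnames(X)
  out
}
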