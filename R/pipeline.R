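#' Default analysis configuration
#'
#' All decision thresholds of the pipeline in one block: infit acceptance
#' windows (0.75-1.33 MNSQ, -2..2 Zstd), the unidimensionality rules
#' (>= 40% variance explained, first contrast eigenvalue < 2), the 0.4
#' loading cut, and the DIF path settings (see [fit_dif_path()]).
#'
#' @return Nested list of defaults; override fields and pass to
#'   [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    jml = list(max_iter = 100, tol = 1e-6, bias_correction = FALSE),
    misfit = list(mnsq_range = c(0.75, 1.33), zstd_range = c(-2, 2)),
    dimensionality = list(variance_pct_min = 40, eigen_max = 2,
                          loading_threshold = 0.4, min_overlap = 30),
    dif = list(n_lambda = 50, quadrature_nodes = 21, zero_threshold = 1e-4,
               rasch_constrained = FALSE, lambda_min_ratio = 1e-3,
               references = list(gender = "female", age_group = "high",
                                 symptom_level = "severe")))
}

read_pipeline_config <- function(path) {
  cfg <- default_pipeline_config()
  if (is.null(path)) return(cfg)
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else jsonlite::fromJSON(path, simplifyVector = TRUE)
  utils::modifyList(cfg, user)
}

#' Text Wright map (person-item map)
#'
#' Joint histogram of person abilities (left) and item difficulties
#' (right) on the shared logit scale, mean item difficulty at 0.  Each
#' `#` stands for a stated number of persons (ceiling of n over the
#' number of rows); a `.` marks a bin holding fewer persons than one
#' glyph's worth.
#'
#' @param fit A `rasch_fit`.
#' @param bins Number of vertical bins.
#' @return Character vector of lines (class `wright_map`); printed by
#'   `cat`-ing one per line.
#' @export
wright_map <- function(fit, bins = 30) {
  beta <- fit$beta; delta <- fit$delta
  rng <- range(c(beta, delta))
  edges <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = bins + 1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  per_glyph <- max(1L, as.integer(ceiling(length(beta) / bins)))
  pc <- tabulate(findInterval(beta, edges, all.inside = TRUE), nbins = bins)
  ib <- findInterval(delta, edges, all.inside = TRUE)
  lines <- character(bins)
  for (b in seq_len(bins)) {
    glyphs <- strrep("#", pc[b] %/% per_glyph)
    if (pc[b] %% per_glyph > 0) glyphs <- paste0(glyphs, ".")
    items <- paste(names(delta)[ib == b], collapse = " ")
    lines[b] <- sprintf("%6.2f %20s | %s", mids[b],
                        formatC(glyphs, width = 20), items)
  }
  out <- c("person ability (left) | item difficulty (right), logits",
           sprintf("each '#' = %d persons; '.' = 1-%d persons",
                   per_glyph, max(per_glyph - 1, 1)),
           rev(lines))
  class(out) <- "wright_map"
  out
}

#' @export
print.wright_map <- function(x, ...) {
  cat(x, sep = "\n")
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Executes the analysis stages in order: read and validate, screen
#' extremes, joint maximum likelihood calibration, fit diagnostics,
#' residual PCA, DIF design and lasso path, BIC selection.  Any stage
#' error aborts with the stage named.  When `out_dir` is given, all
#' exports (measures, fit report, contrasts, loadings, DIF path and
#' table, Wright map, run log) and a provenance record (input hashes,
#' config snapshot, timestamps) are written there; on failure a FAILED
#' marker file names the stage.
#'
#' @param responses_path,covariates_path Input CSV paths (see
#'   [read_responses()]).
#' @param instrument_path Optional instrument JSON; when supplied and the
#'   responses are weighted scores, they are dichotomized first.
#' @param config_path Optional JSON/YAML configuration overriding
#'   [default_pipeline_config()].
#' @param out_dir Optional export directory.
#' @return Object of class `analysis_bundle`: `fit`, `fit_report`,
#'   `misfit`, `contrasts`, `dif_path`, `dif_model`, `dif_table`,
#'   `screening`, `provenance`.
#' @export
run_pipeline <- function(responses_path, covariates_path,
                         instrument_path = NULL, config_path = NULL,
                         out_dir = NULL) {
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    note("stage ", name, " start")
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        writeLines(c(paste("FAILED at stage:", name), conditionMessage(e),
                     log_lines), file.path(out_dir, "FAILED"))
      }
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cfg <- stage("config", read_pipeline_config(config_path))
  data <- stage("data_io", {
    d <- read_responses(responses_path, covariates_path)
    if (!is.null(instrument_path)) {
      inst <- load_instrument(instrument_path)
      if (any(d$X > 1, na.rm = TRUE)) {
        d <- response_matrix(dichotomize(d$X, inst), d$covariates)
      }
    }
    d
  })
  scr <- stage("screen_extremes", screen_extremes(data))
  note("screened: ", length(scr$extreme_persons), " persons, ",
       length(scr$extreme_items), " items removed")
  kept <- scr$kept
  fit <- stage("rasch_calibration",
               estimate_jml(kept, max_iter = cfg$jml$max_iter,
                            tol = cfg$jml$tol,
                            bias_correction = cfg$jml$bias_correction))
  note("JML ", if (fit$converged) "converged" else "NOT converged",
       " in ", fit$n_iter, " cycles, loglik ", format(fit$loglik, digits = 8))
  report <- stage("fit_diagnostics", rasch_fit_report(fit, kept))
  misfit <- stage("flag_misfit",
                  flag_misfit(report, cfg$misfit$mnsq_range,
                              cfg$misfit$zstd_range))
  contrasts <- stage("dimensionality",
                     residual_pca(fit, kept,
                                  min_overlap = cfg$dimensionality$min_overlap))
  if (is.null(kept$covariates)) stage("dif_design", stop("no covariates supplied"))
  design <- stage("dif_design",
                  build_design(kept$covariates, cfg$dif$references))
  path <- stage("dif_lasso",
                fit_dif_path(kept, design,
                             n_lambda = cfg$dif$n_lambda,
                             quadrature_nodes = cfg$dif$quadrature_nodes,
                             lambda_min_ratio = cfg$dif$lambda_min_ratio,
                             rasch_constrained = cfg$dif$rasch_constrained,
                             zero_threshold = cfg$dif$zero_threshold))
  sel <- select_bic(path)
  dtab <- dif_table(sel, design)
  note("DIF: BIC selected lambda ", signif(sel$lambda, 4), " with ",
       sum(sel$gamma != 0), " non-zero coefficient(s)")

  inputs <- c(responses = responses_path, covariates = covariates_path)
  if (!is.null(instrument_path)) inputs["instrument"] <- instrument_path
  provenance <- list(inputs = as.list(tools::md5sum(inputs)),
                     config = cfg,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                     package_version = as.character(utils::packageVersion("raschdif")))
  bundle <- structure(list(fit = fit, fit_report = report, misfit = misfit,
                           contrasts = contrasts, dif_path = path,
                           dif_model = sel, dif_table = dtab,
                           screening = scr[c("extreme_persons", "extreme_items")],
                           provenance = provenance),
                      class = "analysis_bundle")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    export_fit(fit, kept, file.path(out_dir, "measures.csv"))
    utils::write.csv(report$per_item, file.path(out_dir, "fit_report_items.csv"),
                     row.names = FALSE)
    utils::write.csv(report$per_person, file.path(out_dir, "fit_report_persons.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(contrast = seq_along(contrasts$contrast_eigenvalues),
                                eigenvalue = contrasts$contrast_eigenvalues,
                                percent = contrasts$contrast_percents),
                     file.path(out_dir, "contrasts.csv"), row.names = FALSE)
    utils::write.csv(data.frame(lambda = path$lambda,
                                loglik = vapply(path$models, `[[`, 0, "loglik"),
                                df = vapply(path$models, `[[`, 0L, "df"),
                                bic = path$bic,
                                n_nonzero_gamma = vapply(path$models, function(m)
                                  sum(m$gamma != 0), 0L)),
                     file.path(out_dir, "dif_path.csv"), row.names = FALSE)
    utils::write.csv(dtab, file.path(out_dir, "dif_table.csv"), row.names = FALSE)
    writeLines(unclass(wright_map(fit)), file.path(out_dir, "wright_map.txt"))
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  bundle
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat("<analysis_bundle>\n")
  print(x$fit)
  print(x$fit_report)
  cat("  misfitting items (infit windows): ", x$misfit$n_any, "\n", sep = "")
  print(x$contrasts)
  print(x$dif_path)
  invisible(x)
}
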