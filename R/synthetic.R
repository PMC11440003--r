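#' Simulation configuration emulating the ABC validation sample
#'
#' Default configuration matching the structure of the calibration study
#' sample this package is designed around: 3,319 persons; 57 items with
#' difficulties equally spaced on [-2, 2] logits plus two outliers near
#' -4.2 (the two near-universal behaviors) and one near +1.1 (the rarest),
#' discriminations 1; standard-normal trait; demographic margins gender
#' male 0.7969, age groups (infant 0.4260, kindergarten 0.4528, primary
#' 0.1145, junior_high 0.006, high 0.0007), symptom levels (non-autism
#' 0.3420, mild-to-moderate 0.4357, severe 0.2223); no DIF (`gamma = 0`)
#' and no trait impact by default.
#'
#' @return Object of class `sim_config` (a validated list); see
#'   [sim_config()] for the fields.
#' @export
default_abc_config <- function() {
  d <- seq(-2, 2, length.out = 57)
  d[10] <- -4.22; d[38] <- -4.27; d[19] <- 1.1
  sim_config(
    n_persons = 3319,
    item_difficulties = d,
    item_discriminations = rep(1, 57),
    theta_dist = list(mean = 0, sd = 1),
    group_proportions = list(
      gender = c(male = 0.7969, female = 0.2031),
      age_group = c(infant = 0.4260, kindergarten = 0.4528, primary = 0.1145,
                    junior_high = 0.006, high = 0.0007),
      symptom_level = c(non_autism = 0.3420, mild_moderate = 0.4357,
                        severe = 0.2223)),
    gamma = NULL,
    theta_shift_by_group = NULL,
    missing_rate = 0,
    seed = 20240916)
}

#' Construct and validate a simulation configuration
#'
#' @param n_persons Number of persons.
#' @param item_difficulties Numeric vector of difficulties, logits.
#' @param item_discriminations Positive numeric vector, same length.
#' @param theta_dist List `{mean, sd}` of the latent-trait normal.
#' @param group_proportions Named list (gender, age_group, symptom_level)
#'   of named probability vectors; each must sum to 1.
#' @param gamma Items x dummy-columns matrix of uniform-DIF coefficients
#'   (columns as in [build_design()]), or `NULL` for no DIF.
#' @param theta_shift_by_group Named numeric vector of trait-mean shifts
#'   per dummy column (impact, distinct from DIF), or `NULL`.
#' @param missing_rate MCAR missingness probability per cell.
#' @param seed Integer seed; identical seeds give identical output.
#' @return `sim_config` object.
#' @export
sim_config <- function(n_persons, item_difficulties, item_discriminations,
                       theta_dist = list(mean = 0, sd = 1),
                       group_proportions, gamma = NULL,
                       theta_shift_by_group = NULL, missing_rate = 0,
                       seed = 1L) {
  L <- length(item_difficulties)
  if (length(item_discriminations) != L) {
    stop("difficulties and discriminations disagree in length")
  }
  if (any(item_discriminations <= 0)) stop("discriminations must be positive")
  for (v in names(covariate_levels)) {
    p <- group_proportions[[v]]
    if (is.null(p)) stop("group_proportions lacks '", v, "'")
    if (!all(names(p) %in% covariate_levels[[v]])) {
      stop("unknown level in group_proportions$", v)
    }
    if (abs(sum(p) - 1) > 1e-9) stop("proportions for ", v, " must sum to 1")
  }
  q_names <- dummy_column_names()
  if (!is.null(gamma)) {
    gamma <- as.matrix(gamma)
    if (nrow(gamma) != L || ncol(gamma) != length(q_names)) {
      stop("gamma must be ", L, " x ", length(q_names),
           " (columns: ", paste(q_names, collapse = ", "), ")")
    }
    colnames(gamma) <- q_names
  } else gamma <- matrix(0, L, length(q_names), dimnames = list(NULL, q_names))
  shift <- stats::setNames(rep(0, length(q_names)), q_names)
  if (!is.null(theta_shift_by_group)) {
    bad <- setdiff(names(theta_shift_by_group), q_names)
    if (length(bad)) stop("unknown shift column(s): ", paste(bad, collapse = ", "))
    shift[names(theta_shift_by_group)] <- theta_shift_by_group
  }
  structure(list(n_persons = as.integer(n_persons),
                 item_difficulties = item_difficulties,
                 item_discriminations = item_discriminations,
                 theta_dist = theta_dist,
                 group_proportions = group_proportions,
                 gamma = gamma, theta_shift_by_group = shift,
                 missing_rate = missing_rate,
                 seed = as.integer(seed),
                 rng = "Mersenne-Twister"),
            class = "sim_config")
}

dummy_column_names <- function() {
  c("gender", "infant", "kindergarten", "primary", "junior_high",
    "non_autism", "mild_moderate")
}

#' Simulate dichotomous responses with covariates, impact, and DIF
#'
#' Draws covariates from the configured categorical margins (independently
#' across factors), latent traits from the configured normal plus any
#' per-group mean shifts (impact), and responses
#' `x_pi ~ Bernoulli(plogis(alpha_i (theta_p - diff_i - x_p . gamma_i)))`.
#' Sub-draws use one generator seeded from the config, in fixed order
#' (covariates by factor, theta, responses, missingness), so identical
#' seeds give identical output.
#'
#' @param config A [sim_config()].
#' @return List: `data` (a [response_matrix()] with covariates) and
#'   `truth` (theta, covariate dummy matrix, and all generating
#'   parameters).
#' @export
simulate_responses <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  n <- config$n_persons
  cov <- data.frame(person_id = sprintf("P%05d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (v in names(covariate_levels)) {
    p <- config$group_proportions[[v]]
    cov[[v]] <- sample(names(p), n, replace = TRUE, prob = p)
  }
  D <- build_design(cov)$X
  mu <- config$theta_dist$mean + as.vector(D %*% config$theta_shift_by_group)
  theta <- stats::rnorm(n, mean = mu, sd = config$theta_dist$sd)
  L <- length(config$item_difficulties)
  drift <- D %*% t(config$gamma)                     # n x L
  eta <- sweep(outer(theta, rep(1, L)) - drift, 2,
               config$item_difficulties, "-")
  eta <- sweep(eta, 2, config$item_discriminations, "*")
  P <- stats::plogis(eta)
  X <- matrix(as.integer(stats::runif(n * L) < P), n, L)
  if (config$missing_rate > 0) {
    X[stats::runif(n * L) < config$missing_rate] <- NA_integer_
  }
  rownames(X) <- cov$person_id
  colnames(X) <- paste0("item_", seq_len(L))
  list(data = response_matrix(X, cov),
       truth = list(theta = stats::setNames(theta, cov$person_id),
                    design = D, config = config))
}

#' Write a simulated dataset to the CSV pair the reader consumes
#'
#' @param sim Result of [simulate_responses()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths (responses, covariates,
#'   truth JSON).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rp <- file.path(dir, "responses.csv")
  cp <- file.path(dir, "covariates.csv")
  tp <- file.path(dir, "truth.json")
  write_responses(sim$data, rp, cp)
  cfg <- sim$truth$config
  jsonlite::write_json(
    list(seed = cfg$seed, rng = cfg$rng, n_persons = cfg$n_persons,
         item_difficulties = cfg$item_difficulties,
         item_discriminations = cfg$item_discriminations,
         theta_dist = cfg$theta_dist,
         group_proportions = cfg$group_proportions,
         gamma = cfg$gamma, theta_shift_by_group = cfg$theta_shift_by_group,
         missing_rate = cfg$missing_rate,
         theta = unname(sim$truth$theta)),
    tp, auto_unbox = TRUE, digits = NA)
  invisible(c(responses = rp, covariates = cp, truth = tp))
}
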