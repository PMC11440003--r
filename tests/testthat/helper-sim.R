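# Shared fixture builders; everything is generated in code.

# Bernoulli Rasch responses for given abilities/difficulties.
sim_rasch_matrix <- function(theta, delta, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  P <- plogis(outer(theta, delta, "-"))
  X <- matrix(rbinom(length(P), 1, P), nrow(P), ncol(P))
  rownames(X) <- paste0("P", seq_along(theta))
  colnames(X) <- paste0("item_", seq_along(delta))
  X
}

# Screen + JML in one step; returns list(fit, data).
quick_fit <- function(X, ...) {
  scr <- screen_extremes(response_matrix(X))
  list(fit = estimate_jml(scr$kept, ...), data = scr$kept, screen = scr)
}

# Two independent traits each driving one item cluster.
sim_two_trait_matrix <- function(n, items_per_cluster = 10, seed = 1) {
  set.seed(seed)
  th1 <- rnorm(n); th2 <- rnorm(n)
  delta <- seq(-1.5, 1.5, length.out = items_per_cluster)
  X <- cbind(sim_rasch_matrix(th1, delta), sim_rasch_matrix(th2, delta))
  colnames(X) <- paste0("item_", seq_len(2 * items_per_cluster))
  rownames(X) <- paste0("P", seq_len(n))
  X
}

# A hand-built rasch_fit (for closed-form diagnostics checks).
manual_fit <- function(beta, delta) {
  structure(list(beta = setNames(beta, paste0("P", seq_along(beta))),
                 delta = setNames(delta, paste0("item_", seq_along(delta))),
                 se_beta = rep(NA_real_, length(beta)),
                 se_delta = rep(NA_real_, length(delta)),
                 converged = TRUE, n_iter = 0L, loglik = NA_real_),
            class = "rasch_fit")
}

# Write a small instrument JSON; weights recycled over items.
write_test_instrument <- function(weights, cutoff = 68,
                                  subscales = NULL, ids = seq_along(weights)) {
  n <- length(weights)
  if (is.null(subscales)) subscales <- rep("sensory", n)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(name = "test instrument", cutoff_score = cutoff,
         items = data.frame(id = ids, text = "", subscale = subscales,
                            weight = weights)),
    path, auto_unbox = TRUE)
  path
}

# Balanced covariate margins for DIF simulations.
balanced_props <- function() {
  list(gender = c(male = 0.5, female = 0.5),
       age_group = c(infant = 0.25, kindergarten = 0.25, primary = 0.2,
                     junior_high = 0.15, high = 0.15),
       symptom_level = c(non_autism = 1/3, mild_moderate = 1/3, severe = 1/3))
}

dif_sim_config <- function(n = 800, L = 15, gamma = NULL, shift = NULL,
                           seed = 1) {
  sim_config(n_persons = n,
             item_difficulties = seq(-2, 2, length.out = L),
             item_discriminations = rep(1, L),
             group_proportions = balanced_props(),
             gamma = gamma, theta_shift_by_group = shift, seed = seed)
}

published_fit_table <- function() {
  read.csv(system.file("extdata", "abc_published_fit_statistics.csv",
                       package = "raschdif"), stringsAsFactors = FALSE)
}

published_dif_table <- function() {
  read.csv(system.file("extdata", "abc_published_dif_coefficients.csv",
                       package = "raschdif"), stringsAsFactors = FALSE)
}
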