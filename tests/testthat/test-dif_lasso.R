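test_that("dummy coding maps covariates with the stated references", {
  cov <- data.frame(
    person_id = c("a", "b", "c"),
    gender = c("male", "female", "female"),
    age_group = c("infant", "high", "primary"),
    symptom_level = c("non_autism", "severe", "mild_moderate"),
    stringsAsFactors = FALSE)
  des <- build_design(cov)
  expect_equal(dim(des$X), c(3L, 7L))
  expect_equal(colnames(des$X),
               c("gender", "infant", "kindergarten", "primary", "junior_high",
                 "non_autism", "mild_moderate"))
  expect_equal(unname(des$X["a", ]), c(1L, 1L, 0L, 0L, 0L, 1L, 0L))
  expect_equal(unname(des$X["b", ]), rep(0L, 7))  # reference person
  expect_equal(unname(des$X["c", ]), c(0L, 0L, 0L, 1L, 0L, 0L, 1L))
  expect_error(build_design(transform(cov, gender = "other")), "unknown gender")
})

test_that("log-odds reduce correctly and respect the sign convention", {
  gam <- matrix(0, 3, 7, dimnames = list(NULL, raschdif:::dummy_column_names()))
  gam[2, "gender"] <- -0.087
  model <- structure(list(alpha = c(1, 1.3, 0.8), diff = c(-0.5, 0.2, 1),
                          gamma = gam, zero_threshold = 1e-4,
                          theta_scale = list(mean = 0, sd = 1)),
                     class = "dif_model")
  x0 <- rep(0, 7)
  # no DIF: plain 2PL log-odds
  expect_equal(item_response_logodds(0.7, 1, x0, model), 1 * (0.7 - (-0.5)))
  # a boy (gender dummy 1) sees effective difficulty diff - 0.087
  boy <- replace(x0, 1, 1)
  expect_equal(item_response_logodds(0.5, 2, boy, model),
               1.3 * (0.5 - (0.2 - 0.087)))
  # endorsement is 50:50 exactly at the effective difficulty
  expect_equal(plogis(item_response_logodds(0.2 - 0.087, 2, boy, model)), 0.5)
  # negative gamma lowers effective difficulty, raising endorsement
  expect_gt(item_response_logodds(0, 2, boy, model),
            item_response_logodds(0, 2, x0, model))
})

test_that("BIC selection takes the minimum, ties to larger lambda", {
  fake <- function(bics, lambdas) {
    structure(list(models = lapply(seq_along(bics), function(i)
      list(bic = bics[i], lambda = lambdas[i])),
      lambda = lambdas, bic = bics, selected_index = which.min(bics)),
      class = "dif_path")
  }
  expect_equal(select_bic(fake(c(100, 90, 95), c(2, 1, 0.5)))$lambda, 1)
  expect_equal(select_bic(fake(c(90, 90), c(1, 0.5)))$lambda, 1)
  expect_equal(select_bic(fake(42, 3))$bic, 42)
  expect_error(select_bic(structure(list(models = list()), class = "dif_path")),
               "empty")
})

test_that("the largest path penalty yields an all-zero DIF matrix", {
  gam <- matrix(0, 8, 7); gam[3, 1] <- 1.2
  sim <- simulate_responses(dif_sim_config(n = 300, L = 8, gamma = gam, seed = 5))
  scr <- screen_extremes(sim$data)
  des <- build_design(scr$kept$covariates)
  path <- fit_dif_path(scr$kept, des, n_lambda = 8, quadrature_nodes = 15)
  expect_true(all(path$models[[1]]$gamma == 0))
  expect_true(all(diff(path$lambda) < 0))
  expect_true(all(is.finite(path$bic)))
  # just below lambda_max the penalized optimum moves off zero
  ws <- raschdif:::dif_workspace(scr$kept$X, des$X, raschdif:::gh_rule(15))
  start <- list(alpha = path$models[[1]]$alpha,
                diff = path$models[[1]]$diff,
                gamma = path$models[[1]]$gamma * 0)
  sub <- raschdif:::dif_em(ws, 0.9 * path$lambda[1], start,
                           rasch_constrained = FALSE, max_iter = 200,
                           tol = 1e-5)
  expect_gt(max(abs(sub$gamma)), 0)
  # non-zero count does not shrink as the penalty relaxes (thresholded)
  nnz <- vapply(path$models, function(m) sum(m$gamma != 0), 0L)
  expect_true(all(diff(nnz) >= 0))
})

test_that("with an all-zero design the fit collapses to the plain marginal 2PL", {
  sim <- simulate_responses(sim_config(300, seq(-1, 1, length.out = 6),
                                       rep(1, 6),
                                       group_proportions = balanced_props(),
                                       seed = 15))
  scr <- screen_extremes(sim$data)
  X <- scr$kept$X
  des0 <- structure(list(X = matrix(0L, nrow(X), 2,
                                    dimnames = list(NULL, c("g1", "g2"))),
                         coding_map = list(), references = list()),
                    class = "dif_design")
  path <- fit_dif_path(scr$kept, des0, n_lambda = 2, quadrature_nodes = 21,
                       rasch_constrained = TRUE, tol = 1e-8,
                       max_em_iter = 2000)
  expect_true(all(vapply(path$models, function(m) all(m$gamma == 0), TRUE)))
  # independent route: direct numerical maximization of the marginal
  # Rasch likelihood with the same Gauss-Hermite rule
  gh <- pracma::gaussHermite(21)
  nodes <- sqrt(2) * gh$x; logw <- log(gh$w) - 0.5 * log(pi)
  L <- ncol(X)
  nll <- function(d) {
    eta <- outer(nodes, rep(1, L)) - t(outer(d, rep(1, 21)))
    lp <- -log1p(exp(-eta)); l1p <- lp - eta
    ll_nq <- X %*% t(lp) + (1 - X) %*% t(l1p)
    ll_nq <- sweep(ll_nq, 2, logw, "+")
    m <- apply(ll_nq, 1, max)
    -sum(m + log(rowSums(exp(ll_nq - m))))
  }
  m1 <- path$models[[1]]
  expect_true(all(m1$alpha == 1))
  expect_equal(m1$df, L)   # no discriminations counted, no non-zero gammas
  opt <- optim(unname(m1$diff), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_lt(abs(m1$loglik - (-opt$value)), 1e-4)
})

test_that("planted gender DIF is detected with the correct sign", {
  gam <- matrix(0, 10, 7); gam[4, 1] <- 1.0
  sim <- simulate_responses(dif_sim_config(n = 600, L = 10, gamma = gam, seed = 33))
  scr <- screen_extremes(sim$data)
  des <- build_design(scr$kept$covariates)
  path <- fit_dif_path(scr$kept, des, n_lambda = 10, quadrature_nodes = 15)
  sel <- select_bic(path)
  expect_gt(sel$gamma[4, "gender"], 0)
  expect_equal(sel$df, 2 * ncol(scr$kept$X) + sum(sel$gamma != 0))
  expect_true(all(sel$alpha > 0))
  # tabulation prints sub-threshold coefficients as zero
  tab <- dif_table(sel, des)
  expect_equal(names(tab), c("item", colnames(des$X)))
  expect_true(all(tab[, -1] == 0 | abs(tab[, -1]) >= sel$zero_threshold))
})

test_that("published DIF coefficients re-tabulate to the reported counts", {
  tab <- published_dif_table()
  nz_any <- rowSums(tab[, -1] != 0) > 0
  expect_equal(sum(nz_any), 38)                       # items with any DIF
  expect_equal(57 - sum(tab$gender != 0), 54)         # gender-invariant items
  expect_setequal(tab$item[tab$gender != 0], c(25, 31, 54))
  expect_equal(sum(tab$infant < 0), 16)               # easier for infants
})
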