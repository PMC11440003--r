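test_that("endorsement probability follows the logistic closed form", {
  expect_equal(item_prob(0, 0), 0.5)
  expect_equal(item_prob(0, 2), plogis(-2))
  expect_equal(item_prob(2, 0), plogis(2))
  # an item 2 logits above the person is endorsed ~12% of the time; 2
  # logits below, ~88%; the pair spans ~76% of the frequency range
  expect_equal(round(100 * item_prob(0, 2)), 12)
  expect_equal(round(100 * item_prob(2, 0)), 88)
  # extreme gaps stay finite and ordered (no overflow to NaN)
  expect_true(is.finite(item_prob(700, 0)) && item_prob(-700, 0) > 0)
  expect_true(item_prob(700, 0) > item_prob(36, 0) || item_prob(700, 0) == 1)
  expect_error(item_prob(NaN, 0), "finite")
})

test_that("JML respects symmetry and the centering gauge", {
  fit <- quick_fit(rbind(c(1, 0), c(0, 1)))$fit
  expect_equal(unname(fit$delta), c(0, 0), tolerance = 1e-6)
  set.seed(42)
  X <- sim_rasch_matrix(rnorm(200), seq(-1.5, 1.5, length.out = 12))
  fit2 <- quick_fit(X)$fit
  expect_true(fit2$converged)
  expect_lt(abs(mean(fit2$delta)), 1e-8)
  expect_true(all(fit2$se_delta > 0) && all(fit2$se_beta > 0))
})

test_that("JML optimum matches direct likelihood maximization on a 5x4 matrix", {
  X <- rbind(c(1, 0, 1, 0), c(1, 1, 0, 0), c(0, 1, 1, 0),
             c(1, 1, 0, 1), c(0, 0, 1, 1))
  qf <- quick_fit(X, tol = 1e-10, max_iter = 500)
  # independent route: numerical maximization of the same joint likelihood
  # with the sum-zero difficulty constraint absorbed into the last item
  nll <- function(par) {
    beta <- par[1:5]; delta <- c(par[6:8], -sum(par[6:8]))
    eta <- outer(beta, delta, "-")
    -sum(X * eta - log1p(exp(eta)))
  }
  opt <- optim(c(qf$fit$beta * 0, rep(0, 3)), nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  delta_opt <- c(opt$par[6:8], -sum(opt$par[6:8]))
  expect_lt(max(abs(unname(qf$fit$delta) - delta_opt)), 1e-3)
  expect_lt(max(abs(unname(qf$fit$beta) - opt$par[1:5])), 1e-3)
  expect_equal(qf$fit$loglik, -opt$value, tolerance = 1e-6)
})

test_that("raw score is sufficient: equal scores give equal abilities", {
  set.seed(7)
  X <- sim_rasch_matrix(rnorm(150), seq(-1, 1, length.out = 10))
  qf <- quick_fit(X)
  r <- rowSums(qf$data$X)
  for (score in unique(r)) {
    b <- qf$fit$beta[r == score]
    expect_lt(diff(range(b)), 1e-6)
  }
  # and beta is strictly increasing in the raw score
  b_by_score <- tapply(qf$fit$beta, r, mean)
  expect_true(all(diff(b_by_score[order(as.numeric(names(b_by_score)))]) > 0))
})

test_that("adding a correct response increases the person's ability", {
  set.seed(11)
  X <- sim_rasch_matrix(rnorm(100), seq(-1, 1, length.out = 10))
  qf <- quick_fit(X)
  p <- which(rowSums(qf$data$X) == 5)[1]
  X2 <- qf$data$X
  j <- which(X2[p, ] == 0)[1]
  X2[p, j] <- 1L
  fit2 <- quick_fit(X2)$fit
  expect_gt(fit2$beta[rownames(X2)[p]], qf$fit$beta[rownames(X2)[p]])
})

test_that("simulated difficulties are recovered", {
  set.seed(123)
  delta <- seq(-2, 2, length.out = 20)
  X <- sim_rasch_matrix(rnorm(500), delta)
  qf <- quick_fit(X)
  keep <- match(colnames(qf$data$X), colnames(X))
  expect_gte(cor(unname(qf$fit$delta), delta[keep]), 0.95)
})

test_that("standard errors follow the information closed form", {
  # item answered by n persons all at P = 0.5 has se = 2/sqrt(n)
  n <- 64
  fit <- manual_fit(rep(0, n), c(0, 0))
  d <- response_matrix(sim_rasch_matrix(rep(0, n), c(0, 0), seed = 5))
  se <- standard_errors(fit, d)$se_delta
  expect_equal(unname(se), rep(2 / sqrt(n), 2))
  # 3319 persons at P = 0.5: se ~ 0.035, the order of printed model S.E.
  expect_equal(2 / sqrt(3319), 0.0347, tolerance = 1e-2)
  # fewer observations -> larger se
  Xm <- sim_rasch_matrix(rep(0, n), c(0, 0), seed = 6)
  Xm[1:30, 2] <- NA
  dm <- response_matrix(Xm)
  sem <- standard_errors(manual_fit(rep(0, n), c(0, 0)), dm)$se_delta
  expect_gt(sem[2], sem[1])
})

test_that("bias correction shrinks difficulties by (L-1)/L", {
  set.seed(9)
  X <- sim_rasch_matrix(rnorm(120), seq(-1, 1, length.out = 8))
  scr <- screen_extremes(response_matrix(X))
  f0 <- estimate_jml(scr$kept)
  f1 <- estimate_jml(scr$kept, bias_correction = TRUE)
  L <- ncol(scr$kept$X)
  expect_equal(unname(f1$delta), unname(f0$delta) * (L - 1) / L,
               tolerance = 1e-8)
})

test_that("measure export mirrors the person/item table layout", {
  set.seed(10)
  qf <- quick_fit(sim_rasch_matrix(rnorm(60), seq(-1, 1, length.out = 6)))
  path <- tempfile(fileext = ".csv")
  out <- export_fit(qf$fit, qf$data, path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  expect_named(tab, c("entity_type", "id", "measure", "se", "raw_score", "count"))
  expect_equal(sum(tab$entity_type == "item"), ncol(qf$data$X))
  expect_equal(sum(tab$entity_type == "person"), nrow(qf$data$X))
})
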