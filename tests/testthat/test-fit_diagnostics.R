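test_that("standardized residuals match the closed form", {
  fit <- manual_fit(c(0, 0), c(0, 0))
  d <- response_matrix(rbind(P1 = c(1L, 0L), P2 = c(0L, 1L)))
  colnames(d$X) <- names(fit$delta); rownames(d$X) <- names(fit$beta)
  Z <- standardized_residuals(fit, d)
  expect_equal(unname(Z[1, ]), c(1, -1))   # x=1,P=.5 -> +1; x=0,P=.5 -> -1
  fit9 <- manual_fit(c(qlogis(0.9), 0), c(0, 0))
  Z9 <- standardized_residuals(fit9, d)
  expect_equal(Z9[1, 1], 1 / 3, tolerance = 1e-12)  # x=1, P=.9
  dm <- response_matrix(rbind(P1 = c(1L, NA), P2 = c(0L, 1L)))
  expect_true(is.na(standardized_residuals(fit, dm)[1, 2]))
})

test_that("a Guttman-deterministic person overfits (infit < 1)", {
  delta <- seq(-2, 2, length.out = 12)
  set.seed(21)
  X <- sim_rasch_matrix(rnorm(80), delta)
  # person endorsing exactly the items below their ability
  X <- rbind(X, guttman = as.integer(delta < 0.3))
  scr <- screen_extremes(response_matrix(X))
  fit <- estimate_jml(scr$kept)
  rep_ <- rasch_fit_report(fit, scr$kept)
  expect_lt(rep_$per_person$infit_mnsq[rep_$per_person$id == "guttman"], 1)
})

test_that("fit report is internally consistent and Zstd is clamped", {
  set.seed(31)
  X <- sim_rasch_matrix(rnorm(300), seq(-1.5, 1.5, length.out = 15))
  qf <- quick_fit(X)
  rep_ <- rasch_fit_report(qf$fit, qf$data)
  expect_true(all(rep_$per_item$infit_mnsq >= 0))
  expect_true(all(rep_$per_item$outfit_mnsq >= 0))
  expect_true(all(abs(rep_$per_item$infit_zstd) <= 9.9))
  expect_true(all(abs(rep_$per_person$outfit_zstd) <= 9.9))
  # the clamp itself
  expect_equal(raschdif:::wh_zstd(50, 1e-4), 9.9)
  expect_equal(raschdif:::wh_zstd(0.01, 1e-4), -9.9)
  # complete data: item and person outfit partition the same z^2 pool
  z2_items <- sum(rep_$per_item$outfit_mnsq * rep_$per_item$count)
  z2_persons <- sum(rep_$per_person$outfit_mnsq * rep_$per_person$count)
  expect_equal(z2_items, z2_persons, tolerance = 1e-9)
  # summary indices satisfy R = G^2/(1+G^2)
  s <- rep_$summary
  expect_equal(s$person_reliability,
               s$person_separation^2 / (1 + s$person_separation^2),
               tolerance = 1e-9)
  expect_equal(s$item_reliability,
               s$item_separation^2 / (1 + s$item_separation^2),
               tolerance = 1e-9)
})

test_that("misfit flags honour the windows and are monotone in them", {
  tab <- data.frame(id = 1:4,
                    infit_mnsq = c(1.0, 1.34, 0.74, 1.2),
                    infit_zstd = c(0, 9.9, -1.5, -2.5))
  fl <- flag_misfit(tab)
  expect_equal(fl$flags$any, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(fl$flags$both, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(fl$n_any, 3)
  # widening either window never adds a flag
  wide <- flag_misfit(tab, mnsq_range = c(0.5, 1.5), zstd_range = c(-3, 3))
  expect_true(all(fl$flags$any | !wide$flags$any))
  expect_lte(wide$n_any, fl$n_any)
})

test_that("separation and reliability follow the variance decomposition", {
  # measures built so observed var = 1 + G^2 exactly with unit error
  g1 <- separation_reliability(c(-sqrt(2), 0, sqrt(2)), rep(1, 3))
  expect_equal(g1$separation, 1, tolerance = 1e-12)
  expect_equal(g1$reliability, 0.5, tolerance = 1e-12)
  g0 <- separation_reliability(c(0.01, -0.01, 0), rep(1, 3))
  expect_equal(g0$separation, 0)
  expect_equal(g0$reliability, 0)
  set.seed(3)
  for (i in 1:5) {
    m <- rnorm(20, sd = runif(1, 0.5, 3)); s <- runif(20, 0.1, 0.5)
    r <- separation_reliability(m, s)
    expect_equal(r$reliability, r$separation^2 / (1 + r$separation^2),
                 tolerance = 1e-9)
    expect_gte(r$reliability, 0); expect_lte(r$reliability, 1)
  }
  expect_error(separation_reliability(1, 0.1), "at least 2")
})

test_that("point-measure correlation tracks item-measure agreement", {
  set.seed(41)
  beta <- sort(rnorm(200))
  fit <- manual_fit(beta, c(0, 0, 0))
  ordered <- as.integer(beta > 0)            # follows the measure order
  anti <- 1L - ordered
  coin <- rbinom(200, 1, 0.5)
  X <- cbind(item_1 = ordered, item_2 = anti, item_3 = coin)
  rownames(X) <- names(fit$beta)
  d <- response_matrix(X)
  pmc <- point_measure_corr(d, fit)
  expect_gt(pmc[1], 0.7)
  expect_lt(pmc[2], -0.7)
  expect_lt(abs(pmc[3]), 0.2)
  Xc <- X; Xc[, 3] <- 1L; Xc[1, 3] <- 1L
  expect_warning(point_measure_corr(response_matrix(Xc), fit), "constant")
})
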