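test_that("the exact signed-rank test matches enumeration and references", {
  set.seed(21)
  for (n in c(4, 6, 8, 10)) {
    for (rep in 1:5) {
      x <- rnorm(n)
      y <- rnorm(n)
      got <- wilcoxon_signed_rank(x, y)
      expect_equal(got$p_value, enumerate_signed_rank_p(x, y),
                   tolerance = 1e-12)
    }
    # ties and zeros handled: duplicate differences, one exact zero
    x <- c(rnorm(n - 2), 1.5, 2)
    y <- c(rnorm(n - 2), 1.5 - 0.3, 2 - 0.3)
    got <- wilcoxon_signed_rank(x, y)
    expect_equal(got$p_value, enumerate_signed_rank_p(x, y), tolerance = 1e-12)
  }
  # agreement with stats::wilcox.test in the tie-free exact regime
  set.seed(8)
  x <- rnorm(9); y <- rnorm(9)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
  # all 17 differences of one sign: p = 2 / 2^17
  off <- 1:17
  on <- off - runif(17, 0.5, 1.5)
  expect_equal(paired_onoff_test(off, on)$p_value, 2 / 2^17, tolerance = 1e-15)
})

test_that("type-I error of the paired test is nominal under a symmetric null", {
  set.seed(99)
  hits <- mean(replicate(2000, {
    d <- rnorm(17)
    wilcoxon_signed_rank(d, rep(0, 17))$p_value < 0.05
  }))
  expect_lt(abs(hits - 0.05), 0.02)
})

test_that("study simulation follows the generating model", {
  eff0 <- study_effects(beta = c(GPi_efferent = 0), random_intercept_sd = 0,
                        residual_sd = 0, n_hemispheres = 4)
  d0 <- simulate_study(eff0, seed = 1)
  expect_true(all(d0$response == 0))

  effb <- study_effects(beta = c(GPi_efferent = -1e-5, GPe_STN = 4e-6),
                        random_intercept_sd = 0, residual_sd = 0,
                        n_hemispheres = 4)
  db <- simulate_study(effb, seed = 1)
  manual <- -1e-5 * db$GPi_efferent + 4e-6 * db$GPe_STN
  expect_equal(db$response, manual, tolerance = 1e-12)

  # GPi-efferent activation reduces the response under the default effects
  expect_lt(study_effects()$beta[["GPi_efferent"]], 0)

  expect_identical(simulate_study(study_effects(), seed = 3),
                   simulate_study(study_effects(), seed = 3))
})

test_that("the mixed model recovers known coefficients", {
  # zero-noise data: coefficients recovered essentially exactly
  beta <- c(GPi_efferent = -2e-5, GPe_GPi_STN = 1e-5, GPe_STN = 5e-6,
            Put_GPe = -8e-6, Put_GPe_GPi = 3e-6)
  eff <- study_effects(beta = beta, random_intercept_sd = 0, residual_sd = 0,
                       n_hemispheres = 8)
  dat <- simulate_study(eff, seed = 2)
  fit <- fit_linkage(dat)
  expect_equal(coef(fit)[names(beta)], beta, tolerance = 1e-6)
  expect_true(fit$singular)
  # singular fit reduces to ordinary least squares
  ols <- lm(response ~ GPi_efferent + GPe_GPi_STN + GPe_STN + Put_GPe +
              Put_GPe_GPi, data = dat)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-6)

  # location equivariance: shifting responses moves only the intercept
  dat2 <- dat
  dat2$response <- dat$response + 5
  fit2 <- fit_linkage(dat2)
  expect_equal(coef(fit2)[-1], coef(fit)[-1], tolerance = 1e-6)
  expect_equal(unname(coef(fit2)[1] - coef(fit)[1]), 5, tolerance = 1e-6)

  # collinear predictors are named in the error
  dat3 <- dat
  dat3$Put_GPe_GPi <- 2 * dat3$GPi_efferent
  expect_error(fit_linkage(dat3), "collinear")

  # recovery with noise: mean estimate within one s.e. of truth (REML)
  eff_n <- study_effects(beta = beta, random_intercept_sd = 5e-4,
                         residual_sd = 8e-4, n_hemispheres = 17)
  ests <- t(vapply(1:200, function(r) {
    f <- fit_linkage(simulate_study(eff_n, seed = 100 + r))
    coef(f)[names(beta)]
  }, numeric(5)))
  se_mean <- apply(ests, 2, sd) / sqrt(nrow(ests))
  expect_true(all(abs(colMeans(ests) - beta) <= pmax(se_mean, 1e-12) * 3))
})

test_that("model predictions correlate by Kendall tau with exact small-n law", {
  x <- c(1, 2, 3, 4)
  expect_equal(kendall_correlation(x, x * 2 + 1)$tau, 1)
  expect_equal(kendall_correlation(x, -x)$tau, -1)

  # n = 4 with one discordant pair: tau = 2/3 and the exact permutation p
  y <- c(1, 2, 4, 3)
  got <- kendall_correlation(x, y)
  expect_equal(got$tau, 2 / 3, tolerance = 1e-12)
  perms <- matrix(unlist(perms_of(4)), ncol = 4, byrow = TRUE)
  taus <- apply(perms, 1, function(p) cor(x, y[p], method = "kendall"))
  p_exact <- mean(abs(taus) >= abs(got$tau) - 1e-12)
  expect_equal(got$p_value, p_exact, tolerance = 1e-12)

  # fitted-vs-measured wrapper returns a usable correlation
  eff <- study_effects(n_hemispheres = 6)
  dat <- simulate_study(eff, seed = 4)
  fit <- fit_linkage(dat)
  pc <- predict_and_correlate(fit)
  expect_equal(length(pc$predicted), nrow(dat))
  expect_gt(pc$tau, 0)
})

test_that("the efferent-difference model identifies single-pathway truth", {
  # truth: response depends only on the GPi-efferent count, negatively
  beta <- c(GPi_efferent = -2e-5)
  eff <- study_effects(beta = beta, random_intercept_sd = 0, residual_sd = 0,
                       n_hemispheres = 8)
  dat <- simulate_study(eff, seed = 6)
  out <- efferent_difference_analysis(dat)
  # more GPe-relative activation means less rigidity reduction: positive slope
  expect_gt(out$slope, 0)

  # zero-noise single-predictor truth is recovered exactly
  dat$response <- 3e-5 * ((dat$GPe_STN + dat$GPe_GPi_STN) - dat$GPi_efferent)
  out2 <- efferent_difference_analysis(dat)
  expect_equal(out2$slope, 3e-5, tolerance = 1e-8)

  # model selection: on single-predictor truth the one-term model usually
  # beats the five-term model by BIC
  eff_n <- study_effects(beta = beta, random_intercept_sd = 2e-4,
                         residual_sd = 5e-4, n_hemispheres = 17)
  wins <- mean(vapply(1:30, function(r) {
    d <- simulate_study(eff_n, seed = 300 + r)
    diffp <- (d$GPe_STN + d$GPe_GPi_STN) - d$GPi_efferent
    d$response <- 3e-5 * diffp + rnorm(nrow(d), 0, 5e-4)
    efferent_difference_analysis(d)$BIC < fit_linkage(d)$BIC
  }, logical(1)))
  expect_gt(wins, 0.5)
})

test_that("activation summaries reshape into the linkage design", {
  pathways <- c("GPi_efferent", "GPe_GPi_STN", "GPe_STN", "Put_GPe",
                "Put_GPe_GPi")
  summ <- expand.grid(hemisphere = 1:2, setting = c("clinical", "dorsal"),
                      pathway = pathways, stringsAsFactors = FALSE)
  summ$n_activated <- seq_len(nrow(summ))
  wide <- linkage_dataset_from_summaries(summ)
  expect_equal(nrow(wide), 4)
  expect_true(all(pathways %in% names(wide)))
  row1 <- summ[summ$hemisphere == 1 & summ$setting == "clinical" &
                 summ$pathway == "GPe_STN", "n_activated"]
  expect_equal(wide$GPe_STN[wide$hemisphere == 1 & wide$setting == "clinical"],
               row1)
})
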