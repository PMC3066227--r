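test_that("reporting probabilities exponentiate estimates and Wald bounds", {
  r <- reporting_probability(0, 0)
  expect_equal(r$point, 1)
  expect_equal(r$ci_low, 1)
  expect_equal(r$ci_high, 1)

  r2 <- reporting_probability(-0.33, 0.11)
  expect_equal(r2$point, exp(-0.33))
  expect_equal(r2$ci_low, exp(-0.33 - 1.96 * 0.11))
  expect_equal(r2$ci_high, exp(-0.33 + 1.96 * 0.11))
  expect_true(r2$ci_low < r2$point & r2$point < r2$ci_high)

  expect_error(reporting_probability(0, -1), "nonnegative")
})

test_that("the early-replication contrast uses the covariance of the pair", {
  ## var(diff) = v1 + v2 - 2 c12
  ct <- reporting_contrast(-0.11, -0.43, se1 = 0.17, se2 = 0.17,
                           cov12 = 0.0191)
  expect_equal(ct$estimate, 0.32)
  expect_equal(ct$std.error, sqrt(0.17^2 + 0.17^2 - 2 * 0.0191))
  expect_equal(ct$point, exp(-0.32))
  expect_true(ct$ci_low <= ct$point && ct$point <= ct$ci_high)
})

test_that("model comparison differences against the unbiased baseline", {
  corpus <- small_sim_corpus(seed = 121, n_markers = 20)
  fits <- fit_models(corpus, c("unbiased", "model1"), exclude = TRUE)
  tbl <- model_table(fits)

  base <- tbl[tbl$model == "unbiased", ]
  expect_equal(base$delta_L, 0)
  expect_equal(base$delta_AIC, 0)

  m1 <- tbl[tbl$model == "model1", ]
  ## dAIC = 2 dk - 2 dL, with one extra weight parameter
  expect_equal(m1$delta_AIC, 2 * 1 - 2 * m1$delta_L)
  expect_equal(m1$n_weight_params, 1L)
  expect_equal(sum(tbl$best), 1L)

  ## mismatched corpora are refused
  other <- fit_selection_model(small_sim_corpus(seed = 122, n_markers = 5),
                               build_model("model1"))
  expect_error(model_table(list(unbiased = fits$unbiased, model1 = other)),
               "identical corpus")
})

test_that("equal-complexity models differ in AIC only through likelihood", {
  corpus <- small_sim_corpus(seed = 131, n_markers = 20, model = "model2",
                             log_weights = c(log_w_I = -0.8, log_w_S = -0.2))
  fits <- fit_models(corpus, c("unbiased", "model3", "proteus"),
                     exclude = TRUE)
  tbl <- model_table(fits)
  a3 <- tbl[tbl$model == "model3", ]
  ap <- tbl[tbl$model == "proteus", ]
  expect_equal(ap$delta_AIC - a3$delta_AIC,
               -2 * (ap$delta_L - a3$delta_L))
})

test_that("fitted reporting probabilities expose the sign-agreement contrast", {
  corpus <- small_sim_corpus(seed = 141, n_markers = 25, model = "proteus",
                             log_weights = c(log_w_I = -0.8, log_w_E1 = -0.1,
                                             log_w_E2 = -0.5, log_w_S = -0.2))
  prot <- exclusion_protocol(corpus, "proteus")
  fit <- prot$fits$proteus
  rp <- derive_reporting_probability(fit)
  expect_equal(nrow(rp), 5L)  # 4 weights + contrast
  expect_true(all(rp$ci_low <= rp$point & rp$point <= rp$ci_high))
  ## the contrast row equals the closed form from the covariance matrix
  V <- vcov(fit)
  e <- setNames(fit$weights$estimate, fit$weights$term)
  se_d <- sqrt(V["log_w_E1", "log_w_E1"] + V["log_w_E2", "log_w_E2"] -
                 2 * V["log_w_E1", "log_w_E2"])
  expect_equal(rp$point[5], exp(-(e["log_w_E1"] - e["log_w_E2"])),
               ignore_attr = TRUE)
  d <- e["log_w_E1"] - e["log_w_E2"]
  expect_equal(rp$ci_low[5], exp(-d - 1.96 * se_d), ignore_attr = TRUE)

  expect_error(derive_reporting_probability(fit, parameters = "log_w_zzz"),
               "no weight parameter")
})

test_that("corrected and uncorrected estimates coincide without selection", {
  corpus <- small_sim_corpus(seed = 151, n_markers = 25, model = "unbiased",
                             log_weights = NULL)
  fits <- fit_models(corpus, c("unbiased", "model1"), exclude = TRUE)
  cmp <- corrected_estimates(fits$model1, fits$unbiased)
  ## with no true selection the fitted weight is within sampling error of
  ## zero, so corrections stay small
  expect_lt(max(abs(cmp$delta_corrected - cmp$delta_uncorrected)), 0.06)
  s <- attr(cmp, "summary")
  expect_lt(abs(s$abs_delta_shrinkage), 0.03)

  other <- fit_selection_model(small_sim_corpus(seed = 152, n_markers = 5),
                               build_model("unbiased"))
  expect_error(corrected_estimates(fits$model1, other), "identical corpus")
})

test_that("selection-model correction shrinks effects and heterogeneity", {
  corpus <- small_sim_corpus(
    seed = 161, n_markers = 40, model = "proteus",
    log_weights = c(log_w_I = -1.2, log_w_E1 = -0.3, log_w_E2 = -0.9,
                    log_w_S = -0.5),
    studies = c(4, 20)
  )
  fits <- fit_models(corpus, c("unbiased", "proteus"), exclude = TRUE)
  cmp <- corrected_estimates(fits$proteus, fits$unbiased)
  s <- attr(cmp, "summary")
  expect_lte(s$mean_abs_delta_corrected, s$mean_abs_delta_uncorrected + 1e-6)
  expect_lte(s$mean_tau2_corrected, s$mean_tau2_uncorrected + 1e-6)
})
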