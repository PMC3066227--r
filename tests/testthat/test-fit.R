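test_that("the fixed-effect unbiased fit equals the inverse-variance mean", {
  corpus <- tibble::tibble(
    marker_id = "m", pub_id = c("a", "b"), year = c(2000, 2001),
    log_or = c(0.2, 0.5), se = c(0.2, 0.3)
  )
  fit <- fit_selection_model(corpus, build_model("unbiased", "fixed"))
  ivm <- sum(corpus$log_or / corpus$se^2) / sum(1 / corpus$se^2)
  expect_equal(fit$markers$delta, ivm, tolerance = 1e-7)
  expect_true(fit$converged)
  ## the closed-form SE of the inverse-variance mean
  expect_equal(fit$markers$se_delta, sqrt(1 / sum(1 / corpus$se^2)),
               tolerance = 1e-4)
})

test_that("AIC is consistent with the likelihood and parameter count", {
  corpus <- small_sim_corpus(seed = 61, n_markers = 10)
  fit <- fit_selection_model(corpus, build_model("model1"))
  expect_equal(fit$n_params, count_parameters(build_model("model1"), corpus))
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik)
})

test_that("unbiased-corpus effects are recovered within 3 SE almost always", {
  sim <- simulate_corpus(sim_config(n_markers = 100, model = "unbiased",
                                    seed = 71))
  truth <- attr(sim, "truth")
  fit <- fit_selection_model(categorize_studies(sim), build_model("unbiased"))
  m <- dplyr::inner_join(fit$markers, truth, by = "marker_id",
                         suffix = c("", "_true"))
  ok <- abs(m$delta - m$delta_true) <= 3 * m$se_delta
  expect_gte(mean(ok, na.rm = TRUE), 0.95)
})

test_that("rescaling one marker's effects rescales its estimates, not the weights", {
  corpus <- small_sim_corpus(seed = 81, n_markers = 15)
  fit1 <- fit_selection_model(corpus, build_model("model1"))
  target <- fit1$markers$marker_id[which(fit1$markers$converged)[1]]
  c_ <- 3
  scaled <- corpus |>
    dplyr::mutate(
      log_or = ifelse(marker_id == target, log_or * c_, log_or),
      se = ifelse(marker_id == target, se * c_, se)
    )
  fit2 <- fit_selection_model(scaled, build_model("model1"))
  expect_equal(fit2$weights$estimate, fit1$weights$estimate, tolerance = 1e-3)
  i1 <- match(target, fit1$markers$marker_id)
  expect_equal(fit2$markers$delta[i1], c_ * fit1$markers$delta[i1],
               tolerance = 1e-3)
  expect_equal(sqrt(fit2$markers$tau2[i1]), c_ * sqrt(fit1$markers$tau2[i1]),
               tolerance = 1e-2)
})

test_that("degenerate markers are flagged and excluded across all models", {
  corpus <- small_sim_corpus(seed = 91, n_markers = 12)
  degenerate <- tibble::tibble(
    marker_id = "DEGEN", pub_id = paste0("d", 1:6),
    year = c(2000, 2000, 2001, 2001, 2002, 2003),
    log_or = rep(0.25, 6), se = rep(0.2, 6)
  )
  poisoned <- categorize_studies(dplyr::bind_rows(corpus, degenerate))
  fit <- fit_selection_model(poisoned, build_model("unbiased"))
  expect_true("DEGEN" %in% fit$nonconverged_markers)
  expect_false(fit$converged)

  prot <- exclusion_protocol(poisoned, c("unbiased", "model1"))
  expect_true("DEGEN" %in% prot$excluded$marker_id)
  ## a marker failing under any model is absent from the shared corpus
  expect_false("DEGEN" %in% prot$corpus$marker_id)
  ## the final fits are on the shared surviving corpus
  expect_equal(prot$fits$unbiased$n_markers, prot$fits$model1$n_markers)
})

test_that("a clean corpus passes the exclusion protocol unchanged", {
  corpus <- small_sim_corpus(seed = 95, n_markers = 8, studies = c(8, 15))
  prot <- exclusion_protocol(corpus, "unbiased")
  if (prot$n_excluded == 0) {
    expect_identical(as.data.frame(prot$corpus), as.data.frame(corpus))
  } else {
    expect_true(all(prot$excluded$marker_id %in% corpus$marker_id))
  }
})

test_that("the variance floor keeps between-study variances nonnegative", {
  corpus <- small_sim_corpus(seed = 99, n_markers = 10)
  fit <- fit_selection_model(corpus, build_model("model1"),
                             control = list(variance_floor = TRUE))
  expect_true(all(fit$markers$tau2 >= 0))
})
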