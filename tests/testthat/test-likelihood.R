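test_that("interval probabilities match symmetry, totality and quadrature", {
  expect_equal(interval_probs(0, 0, 1, 0), c(0.5, 0.5))
  expect_equal(interval_probs(0, 0, 1), 1.0)

  ## quadrature oracle: mass of N(delta, sigma^2 + tau2) over the z-intervals
  delta <- 0.3; tau2 <- 0.04; s <- 0.2; b <- c(-1.64, 1.64)
  dens <- function(x) dnorm(x, delta, sqrt(s^2 + tau2))
  cuts <- c(-Inf, b * s, Inf)
  oracle <- vapply(1:3, function(j) {
    integrate(dens, cuts[j], cuts[j + 1], rel.tol = 1e-12)$value
  }, numeric(1))
  expect_equal(interval_probs(delta, tau2, s, b), oracle, tolerance = 1e-8)

  expect_error(interval_probs(0, -1, 0.5, 0), "positive")
})

test_that("interval probabilities are nonnegative and sum to one", {
  set.seed(7)
  for (i in 1:50) {
    delta <- rnorm(1, 0, 0.6)
    tau2 <- runif(1, 0, 0.2)
    s <- runif(1, 0.05, 0.5)
    b <- sort(rnorm(sample(1:6, 1), 0, 2))
    p <- interval_probs(delta, tau2, s, b)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("weighted density reduces to the normal and normalizes to one", {
  x <- c(-0.4, 0, 0.37); s <- 0.25; delta <- 0.1; tau2 <- 0.03
  wf1 <- weight_function(c(-1.64, 1.64), c(0, 0, 0))
  expect_equal(
    weighted_logdensity(x, s, delta, tau2, wf1),
    dnorm(x, delta, sqrt(s^2 + tau2), log = TRUE)
  )

  set.seed(11)
  for (i in 1:20) {
    wf <- random_wf()
    mass <- quadrature_mass(wf, rnorm(1, 0, 0.4), runif(1, 0, 0.1),
                            runif(1, 0.08, 0.4))
    expect_lt(abs(mass - 1), 1e-6)
  }
})

test_that("halving a mid-interval weight lowers mid-interval density relatively", {
  s <- 0.2; delta <- 0; tau2 <- 0
  wf_hi <- weight_function(c(-1.64, 1.64), c(0, log(0.8), 0),
                           c(FALSE, TRUE, FALSE))
  wf_lo <- weight_function(c(-1.64, 1.64), c(0, log(0.4), 0),
                           c(FALSE, TRUE, FALSE))
  x_mid <- 0.1          # |z| = 0.5, mid interval
  x_out <- 0.5          # |z| = 2.5, outer interval
  rel_hi <- weighted_logdensity(x_mid, s, delta, tau2, wf_hi) -
    weighted_logdensity(x_out, s, delta, tau2, wf_hi)
  rel_lo <- weighted_logdensity(x_mid, s, delta, tau2, wf_lo) -
    weighted_logdensity(x_out, s, delta, tau2, wf_lo)
  expect_lt(rel_lo, rel_hi)
})

test_that("marker log likelihood composes weight, density and normalization", {
  ## single study at its mode under no selection: the normal density maximum
  st <- tibble::tibble(marker_id = "m", pub_id = "p", year = 2000,
                       log_or = 0.3, se = 0.21)
  expect_equal(
    marker_loglik(st, delta = 0.3, tau2 = 0, model = build_model("unbiased")),
    log(1 / (0.21 * sqrt(2 * pi)))
  )

  ## compositional oracle: evaluate_weight + dnorm + interval_probs
  corpus <- categorize_studies(tiny_corpus())
  mA <- dplyr::filter(corpus, marker_id == "mA")
  model <- build_model("model3")
  lw <- c(log_w_I = -0.6, log_w_E1 = -0.2, log_w_E2 = -0.9, log_w_S = -0.4)
  delta <- 0.12; tau2 <- 0.02
  oracle <- sum(vapply(seq_len(nrow(mA)), function(i) {
    wf <- select_weight_function(model, mA$category[i],
                                 initial_sign = mA$initial_sign[i],
                                 log_weights = lw)
    x <- mA$log_or[i]; s <- mA$se[i]
    B <- interval_probs(delta, tau2, s, wf$boundaries)
    log(evaluate_weight(wf, x / s)) +
      dnorm(x, delta, sqrt(s^2 + tau2), log = TRUE) -
      log(sum(exp(wf$log_weights) * B))
  }, numeric(1)))
  expect_equal(marker_loglik(mA, delta, tau2, model, lw), oracle,
               tolerance = 1e-10)

  ## permutation invariance
  perm <- mA[c(3, 1, 5, 2, 4), ]
  expect_equal(marker_loglik(perm, delta, tau2, model, lw),
               marker_loglik(mA, delta, tau2, model, lw))

  expect_error(marker_loglik(mA[0, ], 0, 0), "empty")
})

test_that("the combined log likelihood is additive and reduces correctly", {
  corpus <- categorize_studies(tiny_corpus())
  pars <- tibble::tibble(marker_id = c("mA", "mB"), delta = c(0.1, -0.2),
                         tau2 = c(0.02, 0.01))
  model <- build_model("model2")
  lw <- c(log_w_I = -0.7, log_w_S = -0.2)

  mA <- dplyr::filter(corpus, marker_id == "mA")
  mB <- dplyr::filter(corpus, marker_id == "mB")
  expect_equal(
    combined_loglik(mA, pars[1, ], model, lw),
    marker_loglik(mA, 0.1, 0.02, model, lw)
  )
  expect_equal(
    combined_loglik(corpus, pars, model, lw),
    combined_loglik(mA, pars[1, ], model, lw) +
      combined_loglik(mB, pars[2, ], model, lw)
  )

  ## with all weights one this is the plain random-effects normal likelihood
  expect_equal(
    combined_loglik(corpus, pars, build_model("unbiased")),
    re_normal_loglik(mA$log_or, mA$se, 0.1, 0.02) +
      re_normal_loglik(mB$log_or, mB$se, -0.2, 0.01)
  )

  ## relabeling markers leaves the value unchanged
  relab <- dplyr::mutate(corpus, marker_id = paste0("x_", marker_id))
  pars2 <- dplyr::mutate(pars, marker_id = paste0("x_", marker_id))
  expect_equal(combined_loglik(relab, pars2, model, lw),
               combined_loglik(corpus, pars, model, lw))

  expect_error(combined_loglik(corpus, pars[1, ], model, lw), "mB")
})

test_that("two independent finite-difference stencils agree on the gradient", {
  corpus <- small_sim_corpus(seed = 55, n_markers = 8, studies = c(4, 8))
  model <- build_model("model2")
  pars <- corpus |>
    dplyr::distinct(marker_id) |>
    dplyr::mutate(delta = 0.05, tau2 = 0.02)
  lw0 <- c(log_w_I = -0.4, log_w_S = -0.15)

  f <- function(v) combined_loglik(corpus, pars, model,
                                   setNames(v, names(lw0)))
  for (i in 1:2) {
    h1 <- 1e-5; h2 <- 2.5e-4
    e <- c(0, 0); e[i] <- 1
    g1 <- (f(lw0 + h1 * e) - f(lw0 - h1 * e)) / (2 * h1)
    ## 4-point stencil with a different, larger step
    g2 <- (8 * (f(lw0 + h2 * e) - f(lw0 - h2 * e)) -
             (f(lw0 + 2 * h2 * e) - f(lw0 - 2 * h2 * e))) / (12 * h2)
    expect_equal(g1, g2, tolerance = 1e-4)
  }
})
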