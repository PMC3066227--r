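test_that("per-allele log OR agrees with the collapsed Woolf estimator", {
  ## identical case/control genotype distributions: exactly no effect
  t0 <- tibble::tibble(case_hom = 10, case_het = 20, case_wt = 20,
                       ctrl_hom = 10, ctrl_het = 20, ctrl_wt = 20)
  r0 <- per_allele_log_or(t0)
  expect_equal(r0$log_or, 0, tolerance = 1e-8)
  expect_gt(r0$se, 0)

  ## Woolf estimator on the collapsed allele table bounds the discrepancy;
  ## the dose-model coefficient itself is checked against an independent
  ## maximization of the grouped binomial likelihood
  t1 <- tibble::tibble(case_hom = 4, case_het = 12, case_wt = 34,
                       ctrl_hom = 2, ctrl_het = 10, ctrl_wt = 38)
  a <- 2 * 4 + 12; b <- 2 * 34 + 12; cc <- 2 * 2 + 10; d <- 2 * 38 + 10
  woolf <- log((a * d) / (b * cc))
  r1 <- per_allele_log_or(t1)
  expect_equal(a, 20)
  expect_equal(cc, 14)
  expect_lt(abs(r1$log_or - woolf), 0.1)
  expect_false(r1$corrected)

  ## independent oracle: direct Nelder-Mead maximization of the per-subject
  ## dose likelihood sum_g w_g * [y_g * eta_g - log(1 + exp(eta_g))]
  dose <- c(2, 1, 0, 2, 1, 0); y <- c(1, 1, 1, 0, 0, 0)
  wts <- c(4, 12, 34, 2, 10, 38)
  nll <- function(p) -sum(wts * (y * (p[1] + p[2] * dose) -
                                   log1p(exp(p[1] + p[2] * dose))))
  oracle <- optim(c(0, 0), nll, method = "Nelder-Mead",
                  control = list(reltol = 1e-12))$par[2]
  expect_equal(r1$log_or, oracle, tolerance = 1e-4)

  ## swapping cases and controls negates the estimate exactly
  t1s <- tibble::tibble(case_hom = 2, case_het = 10, case_wt = 38,
                        ctrl_hom = 4, ctrl_het = 12, ctrl_wt = 34)
  expect_equal(per_allele_log_or(t1s)$log_or, -r1$log_or, tolerance = 1e-8)

  ## scaling all counts leaves the Woolf-form estimate invariant
  t1x <- dplyr::mutate(t1, dplyr::across(dplyr::everything(), ~ .x * 3))
  expect_equal(per_allele_log_or(t1x)$log_or, r1$log_or, tolerance = 1e-3)

  ## zero cell: continuity-corrected fallback, flagged
  tz <- tibble::tibble(case_hom = 0, case_het = 0, case_wt = 40,
                       ctrl_hom = 3, ctrl_het = 10, ctrl_wt = 30)
  rz <- per_allele_log_or(tz)
  expect_true(rz$corrected)
  expect_true(is.finite(rz$log_or) && is.finite(rz$se))

  expect_error(per_allele_log_or(dplyr::select(t1, -case_hom)), "missing")
})

test_that("temporal categories follow the first-publication-year rules", {
  corpus <- tibble::tibble(
    marker_id = "m",
    pub_id = paste0("p", 1:5),
    year = c(2000, 2000, 2002, 2004, 2005),
    log_or = c(0.9, -0.1, 0.3, 0.2, -0.2),
    se = rep(0.3, 5)
  )
  out <- categorize_studies(corpus)
  expect_equal(out$category, c("initial", "initial", "early", "late", "late"))

  ## single study is initial
  one <- categorize_studies(corpus[1, ])
  expect_equal(one$category, "initial")

  ## several initial studies: the most extreme result sets the sign
  two <- tibble::tibble(
    marker_id = "m", pub_id = c("p1", "p2"), year = c(2000, 2000),
    log_or = c(-0.5, 2.1), se = c(1, 1)
  )
  expect_equal(unique(categorize_studies(two)$initial_sign), 1)
  two$log_or <- c(-2.5, 2.1)
  expect_equal(unique(categorize_studies(two)$initial_sign), -1)

  ## row order does not matter
  shuf <- categorize_studies(out[c(4, 1, 5, 3, 2), 1:5])
  merged <- dplyr::left_join(out, shuf, by = "pub_id")
  expect_equal(merged$category.x, merged$category.y)
  expect_equal(merged$initial_sign.x, merged$initial_sign.y)

  ## early studies carry the sign-agreement flag, others NA
  expect_identical(is.na(out$sign_agrees), out$category != "early")
  expect_equal(out$sign_agrees[3], TRUE)  # z = 1 > 0, initial sign positive
})

test_that("the inclusion filter requires four independent publications", {
  corpus <- tibble::tibble(
    marker_id = rep(c("few", "dup", "ok"), c(3, 4, 4)),
    pub_id = c(paste0("f", 1:3), c("d1", "d1", "d2", "d3"), paste0("k", 1:4)),
    year = 2000, log_or = 0.1, se = 0.2
  )
  kept <- filter_min_publications(corpus)
  expect_equal(sort(unique(kept$marker_id)), "ok")
  expect_equal(nrow(filter_min_publications(corpus[0, ])), 0L)
})

test_that("raw genotype input and precomputed effects give identical analyses", {
  set.seed(21)
  n <- 8
  tabs <- tibble::tibble(
    marker_id = rep(c("g1", "g2"), each = 4),
    pub_id = paste0("p", 1:n),
    year = rep(c(2000, 2000, 2001, 2003), 2),
    case_hom = rpois(n, 6) + 1, case_het = rpois(n, 20) + 1,
    case_wt = rpois(n, 30) + 1,
    ctrl_hom = rpois(n, 5) + 1, ctrl_het = rpois(n, 18) + 1,
    ctrl_wt = rpois(n, 33) + 1
  )
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tabs, fb)
  pre <- per_allele_log_or(tabs)[, c("marker_id", "pub_id", "year",
                                     "log_or", "se")]
  readr::write_csv(pre, fa)

  ca <- categorize_studies(read_corpus(fa))
  cb <- categorize_studies(read_corpus(fb, dialect = "genotypes"))
  pars <- tibble::tibble(marker_id = c("g1", "g2"), delta = c(0.05, -0.1),
                         tau2 = c(0.01, 0.02))
  lw <- c(log_w_I = -0.5, log_w_S = -0.2)
  expect_equal(
    combined_loglik(ca, pars, build_model("model2"), lw),
    combined_loglik(cb, pars, build_model("model2"), lw),
    tolerance = 1e-10
  )
})
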