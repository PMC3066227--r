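## Derived quantities: the exclusion protocol, relative reporting
## probabilities with 95% CIs, the model-comparison table, and corrected
## versus uncorrected per-marker estimates.

#' Convergence-exclusion protocol across models
#'
#' Fits every requested model and collects the markers flagged non-converged
#' under *any* of them.  To keep model comparisons meaningful, a marker that
#' fails under one model is excluded from all of them; the surviving corpus
#' is what every reported fit should use.
#'
#' @param corpus Study-level data frame (categorized).
#' @param models Character vector of model names (see [build_model()]).
#' @param effects `"random"` or `"fixed"`.
#' @param control Optimizer control passed to [fit_selection_model()].
#' @param max_rounds Exclusion is iterated (a refit on the reduced corpus can
#'   expose further boundary-chasing markers) until no model flags a marker
#'   or this many rounds have run.
#' @return A list with `corpus` (the surviving studies), `excluded` (a tibble
#'   of excluded markers, the models they failed under and the exclusion
#'   round), `n_excluded`, and `fits` (the final round's fits, which are on
#'   the surviving corpus).
#' @export
exclusion_protocol <- function(corpus,
                               models = c("unbiased", "model1", "model2",
                                          "model3", "proteus"),
                               effects = "random", control = list(),
                               max_rounds = 5) {
  excluded <- tibble::tibble(marker_id = character(0), models = character(0),
                             round = integer(0))
  fits <- NULL
  for (round in seq_len(max_rounds)) {
    fits <- purrr::map(models, function(nm) {
      fit_selection_model(corpus, build_model(nm, effects), control)
    })
    names(fits) <- models
    failures <- purrr::map(fits, "nonconverged_markers")
    new_excl <- tibble::tibble(
      marker_id = unlist(failures, use.names = FALSE),
      model = rep(models, lengths(failures))
    ) |>
      dplyr::group_by(.data$marker_id) |>
      dplyr::summarise(
        models = paste(sort(unique(.data$model)), collapse = ";"),
        .groups = "drop"
      ) |>
      dplyr::mutate(round = round)
    if (nrow(new_excl) == 0L) break
    excluded <- dplyr::bind_rows(excluded, new_excl)
    corpus <- dplyr::filter(corpus, !.data$marker_id %in% new_excl$marker_id)
    if (nrow(corpus) == 0L) {
      abort("the exclusion protocol removed every marker; no stable fit exists.")
    }
    fits <- NULL
  }
  if (is.null(fits)) {
    fits <- purrr::map(models, function(nm) {
      fit_selection_model(corpus, build_model(nm, effects), control)
    })
    names(fits) <- models
  }
  list(
    corpus = corpus,
    excluded = excluded,
    n_excluded = nrow(excluded),
    fits = fits
  )
}

#' Fit several models on a shared post-exclusion corpus
#'
#' Convenience wrapper: applies [exclusion_protocol()] (optionally), then fits
#' every requested model on the identical surviving corpus.
#'
#' @inheritParams exclusion_protocol
#' @param exclude Apply the convergence-exclusion protocol first?
#' @return A named list of `selection_fit`s with attributes `excluded` and
#'   `corpus`.
#' @export
fit_models <- function(corpus,
                       models = c("unbiased", "model1", "model2",
                                  "model3", "proteus"),
                       effects = "random", exclude = TRUE, control = list()) {
  excluded <- tibble::tibble(marker_id = character(0), models = character(0))
  if (exclude) {
    prot <- exclusion_protocol(corpus, models, effects, control)
    corpus <- prot$corpus
    excluded <- prot$excluded
    fits <- prot$fits
  } else {
    fits <- purrr::map(models, function(nm) {
      fit_selection_model(corpus, build_model(nm, effects), control)
    })
    names(fits) <- models
  }
  attr(fits, "excluded") <- excluded
  attr(fits, "corpus") <- corpus
  class(fits) <- "selection_fit_list"
  fits
}

#' Relative reporting probability from a log-weight estimate
#'
#' Exponentiates a log-weight estimate and its Wald 95% CI:
#' `point = exp(est)`, `CI = exp(est +/- 1.96 * se)`.  The result is the
#' probability of a result in that interval being reported, relative to
#' results in the outer (weight one) intervals.
#'
#' @param estimate Log-weight estimate(s).
#' @param se Standard error(s).
#' @param label Optional term label(s).
#' @return Tibble with `term`, `point`, `ci_low`, `ci_high`.
#' @examples
#' reporting_probability(-0.33, 0.11)  # about 72% (58%, 89%)
#' @export
reporting_probability <- function(estimate, se, label = NULL) {
  if (any(se < 0, na.rm = TRUE)) abort("`se` must be nonnegative.")
  tibble::tibble(
    term = label %||% paste0("exp(", format(estimate, digits = 3), ")"),
    point = exp(estimate),
    ci_low = exp(estimate - 1.96 * se),
    ci_high = exp(estimate + 1.96 * se)
  )
}

#' Relative reporting probability of a contrast of two log-weights
#'
#' For the early-replication contrast the quantity of interest is
#' `exp(-(est1 - est2))`: the probability of a confirming non-significant
#' result being published relative to an opposing one.  The two estimates
#' share the outer-interval reference, so their errors are correlated; the
#' contrast SE is `sqrt(var1 + var2 - 2 * cov12)`.
#'
#' @param est1,est2 The two log-weight estimates (e.g. `log w_E1`, `log w_E2`).
#' @param se1,se2 Their standard errors.
#' @param cov12 Their estimated covariance.
#' @param label Term label.
#' @return Tibble with `term`, `estimate` (`est1 - est2`), `std.error`,
#'   `point`, `ci_low`, `ci_high`, where `point = exp(-(est1 - est2))`.
#' @examples
#' # difference 0.32 with contrast SE 0.14 -> 73% (55%, 96%)
#' reporting_contrast(-0.11, -0.43, se1 = 0.17, se2 = 0.17, cov12 = 0.0191)
#' @export
reporting_contrast <- function(est1, est2, se1, se2, cov12,
                               label = "E2 vs E1") {
  diff <- est1 - est2
  se <- sqrt(se1^2 + se2^2 - 2 * cov12)
  if (!is.finite(se)) abort("contrast variance is not positive.")
  tibble::tibble(
    term = label,
    estimate = diff,
    std.error = se,
    point = exp(-diff),
    ci_low = exp(-diff - 1.96 * se),
    ci_high = exp(-diff + 1.96 * se)
  )
}

#' Derived reporting probabilities from a fitted model
#'
#' For each free weight parameter, the relative reporting probability and its
#' 95% CI; with `contrast = TRUE` (models with early-replication weights) the
#' sign-agreement contrast `exp(-(log w_E1 - log w_E2))` is appended, its SE
#' computed from the estimated covariance of the two parameters.
#'
#' @param fit A `selection_fit`.
#' @param parameters Which weight parameters to report (default all).
#' @param contrast Append the `log w_E1 - log w_E2` contrast when available?
#' @return Tibble with one row per derived effect.
#' @export
derive_reporting_probability <- function(fit, parameters = NULL,
                                         contrast = TRUE) {
  stopifnot(inherits(fit, "selection_fit"))
  w <- fit$weights
  parameters <- parameters %||% w$term
  bad <- setdiff(parameters, w$term)
  if (length(bad)) {
    abort(paste0("fit has no weight parameter(s): ", toString(bad)))
  }
  w <- w[match(parameters, w$term), ]
  out <- reporting_probability(w$estimate, w$std.error, label = w$term)
  has_contrast <- all(c("log_w_E1", "log_w_E2") %in% fit$weights$term)
  if (contrast && has_contrast) {
    V <- fit$vcov_weights
    if (is.null(V) || !all(c("log_w_E1", "log_w_E2") %in% rownames(V))) {
      abort("fit lacks the covariance entries needed for the contrast.")
    }
    e <- fit$weights
    e1 <- e$estimate[e$term == "log_w_E1"]
    e2 <- e$estimate[e$term == "log_w_E2"]
    ct <- reporting_contrast(
      e1, e2,
      se1 = sqrt(V["log_w_E1", "log_w_E1"]),
      se2 = sqrt(V["log_w_E2", "log_w_E2"]),
      cov12 = V["log_w_E1", "log_w_E2"],
      label = if (fit$model$sign_dependent) {
        "confirming vs opposing (exp(-(log_w_E1 - log_w_E2)))"
      } else {
        "upper vs lower early interval (exp(-(log_w_E1 - log_w_E2)))"
      }
    )
    out <- dplyr::bind_rows(out, ct[, c("term", "point", "ci_low", "ci_high")])
  }
  out
}

#' Model-comparison table against an unbiased baseline
#'
#' One row per fitted model: weight estimates with standard errors, the
#' log-likelihood gain over the baseline, the number of free weight
#' parameters, and `delta_AIC = 2 * delta_k - 2 * delta_L` (per-marker
#' parameter counts cancel between models fitted on the same corpus).  The
#' lowest-AIC model is flagged.
#'
#' @param fits A list of `selection_fit`s (e.g. from [fit_models()]).
#' @param baseline The unbiased fit to difference against; defaults to the
#'   element of `fits` named `"unbiased"`.
#' @return A tibble with columns `model`, the four canonical weight estimates
#'   and SEs where present, `delta_L`, `n_weight_params`, `delta_AIC`, `best`.
#' @export
model_table <- function(fits, baseline = NULL) {
  if (inherits(fits, "selection_fit")) fits <- list(fits)
  baseline <- baseline %||% fits[["unbiased"]]
  if (is.null(baseline)) {
    abort("no baseline: supply an unbiased fit or include one in `fits`.")
  }
  fp <- vapply(fits, function(f) f$corpus_fingerprint, character(1))
  if (length(unique(c(fp, baseline$corpus_fingerprint))) != 1L) {
    abort("all fits (and the baseline) must use the identical corpus.")
  }
  canon <- c("log_w_I", "log_w_E1", "log_w_E2", "log_w_S")
  rows <- purrr::imap(fits, function(f, nm) {
    row <- tibble::tibble(
      model = if (is.null(names(fits)) || nm == "") f$model_name else nm
    )
    for (p in canon) {
      i <- match(p, f$weights$term)
      row[[p]] <- if (is.na(i)) NA_real_ else f$weights$estimate[i]
      row[[paste0("se_", p)]] <- if (is.na(i)) NA_real_ else f$weights$std.error[i]
    }
    row$loglik <- f$loglik
    row$delta_L <- f$loglik - baseline$loglik
    row$n_weight_params <- f$model$n_free_weights
    row$delta_AIC <- 2 * (f$model$n_free_weights -
                          baseline$model$n_free_weights) - 2 * row$delta_L
    row$converged <- f$converged
    row
  })
  out <- purrr::list_rbind(rows)
  out$best <- out$delta_AIC == min(out$delta_AIC)
  out
}

#' Corrected versus uncorrected per-marker estimates
#'
#' Compares each marker's estimated mean log odds ratio and between-study
#' variance under a selection model (corrected for selective reporting) with
#' the unbiased model's estimates (uncorrected), and summarises the shrinkage
#' direction.
#'
#' @param fit_selection A `selection_fit` under a selection model.
#' @param fit_unbiased The unbiased-model fit on the same corpus.
#' @return A tibble with per-marker uncorrected and corrected `delta`, `se`,
#'   `tau2`, and attribute `summary` (mean |delta| and mean tau2 under each
#'   model, with the shrinkage differences).
#' @export
corrected_estimates <- function(fit_selection, fit_unbiased) {
  stopifnot(inherits(fit_selection, "selection_fit"),
            inherits(fit_unbiased, "selection_fit"))
  if (fit_selection$corpus_fingerprint != fit_unbiased$corpus_fingerprint) {
    abort("the two fits must use the identical corpus.")
  }
  un <- fit_unbiased$markers
  co <- fit_selection$markers
  out <- tibble::tibble(
    marker_id = un$marker_id,
    n_studies = un$n_studies,
    delta_uncorrected = un$delta,
    se_uncorrected = un$se_delta,
    tau2_uncorrected = un$tau2,
    delta_corrected = co$delta[match(un$marker_id, co$marker_id)],
    se_corrected = co$se_delta[match(un$marker_id, co$marker_id)],
    tau2_corrected = co$tau2[match(un$marker_id, co$marker_id)]
  )
  attr(out, "summary") <- tibble::tibble(
    mean_abs_delta_uncorrected = mean(abs(out$delta_uncorrected)),
    mean_abs_delta_corrected = mean(abs(out$delta_corrected)),
    mean_tau2_uncorrected = mean(out$tau2_uncorrected),
    mean_tau2_corrected = mean(out$tau2_corrected),
    abs_delta_shrinkage = mean(abs(out$delta_uncorrected)) -
      mean(abs(out$delta_corrected)),
    tau2_shrinkage = mean(out$tau2_uncorrected) - mean(out$tau2_corrected)
  )
  out
}

#' Serialize a fit to JSON
#'
#' Writes estimates, standard errors, the weight-parameter covariance and the
#' optimizer diagnostics; everything the reporting layer prints is
#' reproducible from this file.
#'
#' @param fit A `selection_fit`.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  x <- list(
    model = fit$model_name,
    effects = fit$effects,
    loglik = fit$loglik,
    n_params = fit$n_params,
    aic = fit$aic,
    converged = fit$converged,
    weights = fit$weights,
    vcov_weights = fit$vcov_weights,
    markers = fit$markers,
    nonconverged_markers = fit$nonconverged_markers,
    diagnostics = fit$diagnostics[c("optim_convergence", "grad_max_norm",
                                    "info_pd", "polished", "restarts")]
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
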