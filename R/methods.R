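## broom-style accessors and plotting.

#' Tidy a selection-model fit
#'
#' @param x A `selection_fit`.
#' @param pars `"weights"` (default) for the shared log-weight parameters or
#'   `"markers"` for the per-marker mean effects and between-study variances.
#' @param ... Unused.
#' @return A tibble; for weights: `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high` (Wald 95%).
#' @method tidy selection_fit
#' @export
tidy.selection_fit <- function(x, pars = c("weights", "markers"), ...) {
  pars <- match.arg(pars)
  if (pars == "markers") {
    return(x$markers |>
      tidyr::pivot_longer(c("delta", "tau2"),
        names_to = "term", values_to = "estimate"
      ) |>
      dplyr::mutate(
        std.error = dplyr::if_else(.data$term == "delta",
                                   .data$se_delta, .data$se_tau2)
      ) |>
      dplyr::select("marker_id", "term", "estimate", "std.error", "converged"))
  }
  x$weights |>
    dplyr::mutate(
      conf.low = .data$estimate - 1.96 * .data$std.error,
      conf.high = .data$estimate + 1.96 * .data$std.error
    )
}

#' One-row summary of a selection-model fit
#'
#' @param x A `selection_fit`.
#' @param ... Unused.
#' @method glance selection_fit
#' @export
glance.selection_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model_name,
    effects = x$effects,
    logLik = x$loglik,
    AIC = x$aic,
    n_params = x$n_params,
    n_weight_params = x$model$n_free_weights,
    n_markers = x$n_markers,
    n_studies = x$n_studies,
    converged = x$converged,
    n_nonconverged_markers = length(x$nonconverged_markers)
  )
}

## fitted weight functions as a step-plot table (one row per interval per
## weight function)
weight_steps <- function(fit, z_range = c(-4, 4)) {
  model <- fit$model
  est <- setNames(fit$weights$estimate, fit$weights$term)
  se <- setNames(fit$weights$std.error, fit$weights$term)
  purrr::imap(model$wfs, function(tmpl, nm) {
    b <- tmpl$boundaries
    lo <- c(z_range[1], b)
    hi <- c(b, z_range[2])
    par <- ifelse(tmpl$assign == 0L, NA_character_,
                  model$params[pmax(tmpl$assign, 1L)])
    tibble::tibble(
      weight_function = nm,
      z_low = lo, z_high = hi,
      term = par,
      log_weight = ifelse(is.na(par), 0, est[par]),
      se = ifelse(is.na(par), 0, se[par])
    )
  }) |>
    purrr::list_rbind()
}

#' Plot the fitted weight function(s)
#'
#' Step plot of the estimated relative publication probability against the
#' standardized effect z, one panel per weight function, with pointwise
#' +/- 1 SE bars on the estimated (free) intervals.
#'
#' @param object A `selection_fit`.
#' @param z_range Plotted z-range.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot selection_fit
#' @export
autoplot.selection_fit <- function(object, z_range = c(-4, 4), ...) {
  df <- weight_steps(object, z_range) |>
    dplyr::mutate(
      weight = exp(.data$log_weight),
      w_low = exp(.data$log_weight - .data$se),
      w_high = exp(.data$log_weight + .data$se),
      z_mid = (.data$z_low + .data$z_high) / 2
    )
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$z_low, xend = .data$z_high,
                   y = .data$weight, yend = .data$weight),
      linewidth = 0.8
    ) +
    ggplot2::geom_errorbar(
      data = dplyr::filter(df, !is.na(.data$term)),
      ggplot2::aes(x = .data$z_mid, ymin = .data$w_low, ymax = .data$w_high),
      width = 0.08, alpha = 0.6
    ) +
    ggplot2::facet_wrap(~weight_function) +
    ggplot2::labs(
      x = "standardized effect z",
      y = "relative publication probability",
      title = paste0("Fitted weight function: ", object$model_name)
    ) +
    ggplot2::theme_minimal()
}

#' Step-plot of corrected vs uncorrected per-marker estimates
#'
#' @param comparison Output of [corrected_estimates()].
#' @return A ggplot of corrected against uncorrected mean log odds ratios.
#' @export
plot_correction <- function(comparison) {
  ggplot2::ggplot(
    comparison,
    ggplot2::aes(x = .data$delta_uncorrected, y = .data$delta_corrected)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "uncorrected log OR (unbiased model)",
      y = "corrected log OR (selection model)"
    ) +
    ggplot2::theme_minimal()
}
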