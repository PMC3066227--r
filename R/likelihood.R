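## Weighted-density likelihood layer.
##
## Published results x_i are modelled as draws from N(delta, sigma_i^2 + tau2)
## that survive selection with relative probability omega(z_i), the stepwise
## weight function.  The observed-data density is then
##
##   f(x_i) = omega(x_i / sigma_i) * phi(x_i; delta, sigma_i^2 + tau2) / A_i,
##   A_i    = sum_j w_j * B_ij,
##
## where B_ij is the probability that an unselected result falls in weight
## interval j.  Everything below is vectorized over studies; the per-study
## interval probabilities use complementary CDFs in the right tail to avoid
## cancellation.

## B_ij matrix for n studies sharing one boundary set.
## delta, v (= sigma_i^2 + tau2) and s are per-study vectors.
interval_probs_matrix <- function(delta, v, s, boundaries) {
  n <- length(s)
  k <- length(boundaries) + 1L
  if (k == 1L) return(matrix(1, n, 1L))
  sd <- sqrt(v)
  ## standardized boundary arguments a_ij, n x (k-1)
  A <- (outer(s, boundaries) - delta) / sd
  P <- pnorm(A)                       # lower-tail
  Q <- pnorm(A, lower.tail = FALSE)   # upper-tail
  B <- matrix(0, n, k)
  B[, 1L] <- P[, 1L]
  B[, k] <- Q[, k - 1L]
  if (k > 2L) {
    for (j in 2:(k - 1L)) {
      ## difference in whichever tail keeps both operands well-conditioned
      Bj <- Q[, j - 1L] - Q[, j]
      low <- A[, j] <= 0
      if (any(low)) Bj[low] <- P[low, j] - P[low, j - 1L]
      B[, j] <- Bj
    }
  }
  B[B < 0] <- 0
  B
}

#' Interval probabilities of an unselected study result
#'
#' Probability that a result from `N(delta, sigma^2 + tau2)` falls into each
#' z-interval of a stepwise weight function with the given boundaries, for a
#' study with within-study standard error `sigma`.  The j-th entry is
#' `pnorm((z_j*sigma - delta)/s) - pnorm((z_{j-1}*sigma - delta)/s)` with
#' `s = sqrt(sigma^2 + tau2)`, `z_0 = -Inf` and `z_k = +Inf`.
#'
#' @param delta Mean effect (log-OR scale).
#' @param tau2 Between-study variance (may be negative as long as
#'   `sigma^2 + tau2 > 0`).
#' @param sigma Within-study standard error (> 0).
#' @param boundaries Strictly increasing z-scale boundaries (may be empty).
#' @return Probability vector of length `length(boundaries) + 1` summing to 1.
#' @examples
#' interval_probs(0, 0, 1, 0)              # (0.5, 0.5)
#' interval_probs(0.3, 0.04, 0.2, c(-1.64, 1.64))
#' @export
interval_probs <- function(delta, tau2, sigma, boundaries = numeric(0)) {
  stopifnot(length(delta) == 1L, length(tau2) == 1L, length(sigma) == 1L)
  if (!is.finite(sigma) || sigma <= 0) abort("`sigma` must be positive.")
  v <- sigma^2 + tau2
  if (!is.finite(v) || v <= 0) {
    abort("total variance sigma^2 + tau2 must be positive.")
  }
  if (length(boundaries) > 1 && any(diff(boundaries) <= 0)) {
    abort("`boundaries` must be strictly increasing.")
  }
  drop(interval_probs_matrix(delta, v, sigma, boundaries))
}

#' Log density of a published result under selection
#'
#' Evaluates the weighted (selection-model) log density
#' `log omega(x/sigma) + log phi(x; delta, sigma^2 + tau2) - log sum_j w_j B_j`
#' for one parameter configuration.  With all weights equal to one this
#' reduces exactly to the unweighted normal log density.
#'
#' @param x Observed effect(s) (log odds ratio), vectorized.
#' @param sigma Within-study standard error(s), recycled against `x`.
#' @param delta Mean effect.
#' @param tau2 Between-study variance.
#' @param wf A [weight_function()] governing these studies.
#' @return Numeric vector of log densities.
#' @export
weighted_logdensity <- function(x, sigma, delta, tau2, wf) {
  stopifnot(inherits(wf, "weight_function"))
  n <- max(length(x), length(sigma))
  x <- rep_len(x, n)
  sigma <- rep_len(sigma, n)
  if (any(!is.finite(x)) || any(!is.finite(sigma)) || any(sigma <= 0)) {
    abort("`x` must be finite and `sigma` positive.")
  }
  v <- sigma^2 + tau2
  if (any(v <= 0)) abort("total variance sigma^2 + tau2 must be positive.")
  z <- x / sigma
  lw <- wf$log_weights[interval_index(z, wf$boundaries)]
  B <- interval_probs_matrix(rep_len(delta, n), v, sigma, wf$boundaries)
  denom <- drop(B %*% exp(wf$log_weights))
  if (any(!is.finite(denom)) || any(denom <= 0)) {
    abort("weight-function normalization sum_j w_j B_ij underflowed to <= 0.")
  }
  lw + dnorm(x, delta, sqrt(v), log = TRUE) - log(denom)
}

## ---- corpus preparation ----------------------------------------------------

## Validate a study-level data frame and attach the per-study weight-function
## assignment for one model.  Returns a list of parallel vectors plus one
## index-group per distinct weight function (so likelihood evaluation can be
## vectorized within groups).
prepare_loglik_data <- function(corpus, model) {
  stopifnot(inherits(model, "selectmeta_model"))
  need <- c("marker_id", "log_or", "se")
  missing_cols <- setdiff(need, names(corpus))
  if (length(missing_cols)) {
    abort(paste0("`corpus` is missing column(s): ", toString(missing_cols)))
  }
  if (nrow(corpus) == 0L) abort("`corpus` has no studies.")
  if (any(!is.finite(corpus$log_or))) abort("`log_or` must be finite.")
  if (any(!is.finite(corpus$se)) || any(corpus$se <= 0)) {
    abort("`se` must be finite and positive.")
  }
  multi_cat <- !model$name %in% c("unbiased", "high_resolution", "model1")
  if (multi_cat && !"category" %in% names(corpus)) {
    abort(paste0(
      "model `", model$name, "` needs a `category` column; ",
      "run categorize_studies() first."
    ))
  }
  if (model$sign_dependent && !"initial_sign" %in% names(corpus)) {
    abort(paste0(
      "the Proteus model needs an `initial_sign` column; ",
      "run categorize_studies() first."
    ))
  }

  marker <- factor(corpus$marker_id, levels = unique(corpus$marker_id))
  wf_names <- names(model$wfs)
  if (length(wf_names) == 1L) {
    g <- rep(1L, nrow(corpus))
  } else {
    nm <- vapply(seq_len(nrow(corpus)), function(i) {
      wf_name_for(model, corpus$category[i], corpus$initial_sign[i])
    }, character(1))
    g <- match(nm, wf_names)
  }

  list(
    x = corpus$log_or,
    s = corpus$se,
    z = corpus$log_or / corpus$se,
    im = as.integer(marker),
    markers = levels(marker),
    n_markers = nlevels(marker),
    groups = lapply(seq_along(wf_names), function(j) which(g == j)),
    wfs = model$wfs,
    model = model
  )
}

## Per-marker log-likelihood contributions for one parameter configuration.
## theta_w: numeric vector over model$params (possibly length 0);
## delta, tau2: per-marker vectors aligned with dat$markers.
## Returns list(ok, per_marker, total); ok = FALSE when any total variance is
## nonpositive or the normalization degenerates (the optimizer backtracks).
eval_loglik <- function(dat, theta_w, delta, tau2) {
  v <- dat$s^2 + tau2[dat$im]
  if (any(!is.finite(v)) || any(v <= 0)) {
    return(list(ok = FALSE, bad = unique(dat$im[!is.finite(v) | v <= 0])))
  }
  mu <- delta[dat$im]
  ll <- dnorm(dat$x, mu, sqrt(v), log = TRUE)
  for (j in seq_along(dat$groups)) {
    rows <- dat$groups[[j]]
    if (length(rows) == 0L) next
    tmpl <- dat$wfs[[j]]
    lw <- ifelse(tmpl$assign == 0L, 0, theta_w[pmax(tmpl$assign, 1L)])
    if (length(tmpl$boundaries) > 0L) {
      idx <- interval_index(dat$z[rows], tmpl$boundaries)
      ll[rows] <- ll[rows] + lw[idx]
      B <- interval_probs_matrix(mu[rows], v[rows], dat$s[rows], tmpl$boundaries)
      denom <- drop(B %*% exp(lw))
      if (any(!is.finite(denom)) || any(denom <= 0)) {
        return(list(ok = FALSE, bad = unique(dat$im[rows][!is.finite(denom) | denom <= 0])))
      }
      ll[rows] <- ll[rows] - log(denom)
    }
    ## single-interval weight functions: lw is a scalar and the normalization
    ## equals w, so numerator and denominator cancel exactly
  }
  per_marker <- as.numeric(rowsum(ll, dat$im, reorder = TRUE))
  list(ok = TRUE, per_marker = per_marker, total = sum(per_marker))
}

## ---- exported likelihood API ----------------------------------------------

check_marker_params <- function(dat, marker_params) {
  need <- c("marker_id", "delta")
  missing_cols <- setdiff(need, names(marker_params))
  if (length(missing_cols)) {
    abort(paste0("`marker_params` is missing column(s): ", toString(missing_cols)))
  }
  idx <- match(dat$markers, marker_params$marker_id)
  if (anyNA(idx)) {
    abort(paste0(
      "no parameters supplied for marker(s): ",
      toString(dat$markers[is.na(idx)])
    ))
  }
  tau2 <- if (is.null(marker_params$tau2)) rep(0, length(idx)) else
    marker_params$tau2[idx]
  list(delta = marker_params$delta[idx], tau2 = tau2)
}

#' Log likelihood of one marker's studies
#'
#' Sum of the weighted log densities of a single marker's published results,
#' each with its category-selected weight function.
#'
#' @param studies Data frame of the marker's studies (columns `marker_id`,
#'   `log_or`, `se`, plus `category` / `initial_sign` for multi-category
#'   models).
#' @param delta,tau2 The marker's mean effect and between-study variance.
#' @param model A [build_model()] specification.
#' @param log_weights Named numeric vector of weight-parameter values
#'   (defaults to all zero, the unbiased configuration).
#' @return Scalar log likelihood.
#' @export
marker_loglik <- function(studies, delta, tau2 = 0, model = build_model("unbiased"),
                          log_weights = NULL) {
  if (nrow(studies) == 0L) abort("`studies` is empty.")
  if (dplyr::n_distinct(studies$marker_id) != 1L) {
    abort("`studies` must contain exactly one marker.")
  }
  dat <- prepare_loglik_data(studies, model)
  res <- eval_loglik(dat, fill_weights(model, log_weights), delta, tau2)
  if (!res$ok) {
    abort(paste0(
      "nonpositive total variance or degenerate normalization for marker ",
      dat$markers[res$bad[1]]
    ))
  }
  res$total
}

#' Combined log likelihood over all markers
#'
#' The multi-dataset log likelihood: markers have their own mean effect and
#' between-study variance, but the weight-function parameters are shared by
#' all of them.
#'
#' @param corpus Study-level data frame (all markers).
#' @param marker_params Data frame with columns `marker_id`, `delta` and
#'   (for random-effects models) `tau2`.
#' @param model A [build_model()] specification.
#' @param log_weights Named numeric vector over the model's weight parameters.
#' @return Scalar log likelihood.
#' @examples
#' corpus <- tibble::tibble(
#'   marker_id = "m1", pub_id = c("a", "b"), year = c(2000, 2001),
#'   log_or = c(0.2, 0.4), se = c(0.2, 0.25)
#' )
#' pars <- tibble::tibble(marker_id = "m1", delta = 0.3, tau2 = 0.01)
#' combined_loglik(corpus, pars, build_model("model1"),
#'                 log_weights = c(log_w_S = -0.3))
#' @export
combined_loglik <- function(corpus, marker_params, model = build_model("unbiased"),
                            log_weights = NULL) {
  dat <- prepare_loglik_data(corpus, model)
  mp <- check_marker_params(dat, marker_params)
  res <- eval_loglik(dat, fill_weights(model, log_weights), mp$delta, mp$tau2)
  if (!res$ok) {
    abort(paste0(
      "nonpositive total variance or degenerate normalization for marker ",
      dat$markers[res$bad[1]]
    ))
  }
  res$total
}
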