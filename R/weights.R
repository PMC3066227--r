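#' Stepwise-constant publication weight functions
#'
#' A weight function gives the relative probability that a study result is
#' published as a function of its standardized effect `z = x / sigma`.  It is
#' stepwise constant: `k - 1` ordered boundaries on the z-scale partition the
#' real line into `k` intervals, each carrying one weight `w_j = exp(log_w_j)`.
#' Intervals are left-open / right-closed, so a `z` exactly on a boundary
#' belongs to the lower interval.  Weights are parameterized on the log scale;
#' entries with `free = FALSE` are pinned at `log w = 0` (weight one) — by
#' convention the outer intervals, so all estimated weights are relative to
#' results beyond the outermost boundaries.
#'
#' @param boundaries Strictly increasing numeric vector of interval boundaries
#'   on the z-scale (may be empty for a single-interval, constant function).
#' @param log_weights Numeric vector of `length(boundaries) + 1` log-weights.
#' @param free Logical vector marking which log-weights are free parameters;
#'   fixed entries must be exactly 0.  Defaults to all-fixed.
#'
#' @return An object of class `weight_function`.
#' @examples
#' wf <- weight_function(c(-1.64, 1.64), c(0, -0.33, 0), c(FALSE, TRUE, FALSE))
#' evaluate_weight(wf, c(-2, 0, 2))
#' @export
weight_function <- function(boundaries, log_weights,
                            free = rep(FALSE, length(log_weights))) {
  boundaries <- as.numeric(boundaries)
  log_weights <- as.numeric(log_weights)
  free <- as.logical(free)
  if (anyNA(boundaries) || any(!is.finite(boundaries))) {
    abort("`boundaries` must be finite and non-missing.")
  }
  if (length(boundaries) > 1 && any(diff(boundaries) <= 0)) {
    abort("`boundaries` must be strictly increasing.")
  }
  if (length(log_weights) != length(boundaries) + 1L) {
    abort(sprintf(
      "`log_weights` must have length(boundaries) + 1 = %d entries, got %d.",
      length(boundaries) + 1L, length(log_weights)
    ))
  }
  if (any(!is.finite(log_weights))) abort("`log_weights` must be finite.")
  if (length(free) != length(log_weights)) {
    abort("`free` must match `log_weights` in length.")
  }
  if (any(log_weights[!free] != 0)) {
    abort("fixed (non-free) log-weights must be exactly 0.")
  }
  structure(
    list(boundaries = boundaries, log_weights = log_weights, free = free),
    class = "weight_function"
  )
}

#' @export
print.weight_function <- function(x, ...) {
  k <- length(x$log_weights)
  cat("<weight_function> ", k, " interval", if (k > 1) "s", "\n", sep = "")
  lo <- c(-Inf, x$boundaries)
  hi <- c(x$boundaries, Inf)
  for (j in seq_len(k)) {
    cat(sprintf(
      "  (%6s, %6s]  log w = %8.4f  %s\n",
      formatC(lo[j], digits = 3), formatC(hi[j], digits = 3),
      x$log_weights[j], if (x$free[j]) "free" else "fixed"
    ))
  }
  invisible(x)
}

## interval index of z under the left-open/right-closed convention;
## returns values in 1..k.  Shared by evaluation and the B_ij integrals.
interval_index <- function(z, boundaries) {
  if (length(boundaries) == 0L) return(rep(1L, length(z)))
  findInterval(z, boundaries, left.open = TRUE) + 1L
}

#' Evaluate a weight function at standardized effects
#'
#' Returns `exp(log_w_j)` for the interval containing each `z`; boundary
#' values belong to the lower interval.
#'
#' @param wf A [weight_function()].
#' @param z Numeric vector of standardized effects (must be finite).
#' @return Numeric vector of positive weights, one per `z`.
#' @export
evaluate_weight <- function(wf, z) {
  stopifnot(inherits(wf, "weight_function"))
  if (length(z) == 0L) return(numeric(0))
  if (anyNA(z) || any(!is.finite(z))) {
    abort("`z` must be finite and non-missing.")
  }
  exp(wf$log_weights[interval_index(z, wf$boundaries)])
}

#' Select the weight function governing one study
#'
#' Under a multi-category model the weight function applied to a study depends
#' on its temporal category (initial finding, early replication, late
#' replication) and — for the Proteus model only — on the sign of the marker's
#' initial result, which decides how the two early-replication weights are
#' arranged around z = 0.
#'
#' @param model A [build_model()] specification.
#' @param category One of `"initial"`, `"early"`, `"late"`.
#' @param initial_sign `+1` or `-1`; required only when `model` is the Proteus
#'   model and `category` is `"early"`.
#' @param log_weights Named numeric vector of values for the model's free
#'   weight parameters (defaults to all zero).
#' @return A [weight_function()] with the parameter values filled in.
#' @export
select_weight_function <- function(model, category,
                                   initial_sign = NULL,
                                   log_weights = NULL) {
  stopifnot(inherits(model, "selectmeta_model"))
  category <- match.arg(category, c("initial", "early", "late"))
  wf_name <- wf_name_for(model, category, initial_sign)
  realize_wf(model, wf_name, fill_weights(model, log_weights))
}

## map (category, initial_sign) -> the model's weight-function name
wf_name_for <- function(model, category, initial_sign = NULL) {
  switch(model$name,
    unbiased = ,
    high_resolution = ,
    model1 = "all",
    model2 = if (category == "initial") "initial" else "subsequent",
    model3 = category,
    proteus = {
      if (category != "early") return(category)
      if (is.null(initial_sign) || is.na(initial_sign)) {
        abort(paste0(
          "the Proteus model needs the initial study's sign to pick the ",
          "early-replication weight function."
        ))
      }
      if (initial_sign > 0) "early_pos" else "early_neg"
    }
  )
}

## build a numeric weight_function from a model template + parameter values
realize_wf <- function(model, wf_name, theta_w) {
  tmpl <- model$wfs[[wf_name]]
  lw <- ifelse(tmpl$assign == 0L, 0, theta_w[pmax(tmpl$assign, 1L)])
  weight_function(tmpl$boundaries, lw, free = tmpl$assign != 0L)
}

fill_weights <- function(model, log_weights) {
  theta <- setNames(rep(0, length(model$params)), model$params)
  if (!is.null(log_weights)) {
    bad <- setdiff(names(log_weights), model$params)
    if (length(bad)) {
      abort(paste0("unknown weight parameter(s): ", toString(bad)))
    }
    theta[names(log_weights)] <- log_weights
  }
  theta
}

## sign convention used throughout: z > 0 is positive, z <= 0 negative
z_sign <- function(z) ifelse(z > 0, 1, -1)
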