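## The six model specifications.
##
## Every model pins the weight of the outer intervals at one, so all estimated
## weights are relative publication probabilities against results beyond the
## outermost boundaries (|z| > 2.58 for the high-resolution model, |z| > 1.64
## for the reduced models).  A weight-function template stores its boundaries
## plus an `assign` vector mapping each interval to the index of a free
## parameter (0 = pinned at log w = 0).

HIGH_RES_BOUNDARIES <- c(
  -2.58, -1.96, -1.64, -1.28, -1.04, -0.67, -0.25, 0,
  0.25, 0.67, 1.04, 1.28, 1.64, 1.96, 2.58
)
MID_BOUNDARIES <- c(-1.64, 1.64)
EARLY_BOUNDARIES <- c(-1.64, 0, 1.64)

MODEL_NAMES <- c(
  "unbiased", "high_resolution", "model1", "model2", "model3", "proteus"
)

#' Build one of the six selection-model specifications
#'
#' The models differ in how many weight functions they use and which studies
#' each one governs:
#'
#' * `unbiased` — weight identically one; no selection (0 weight parameters).
#' * `high_resolution` — one weight function for all studies with 16 z-intervals
#'   (boundaries from -2.58 to 2.58); the 14 inner intervals each carry an
#'   independent free log-weight, the outer two are pinned at one.
#' * `model1` — one weight function, boundaries (-1.64, 1.64); a single free
#'   weight `w_S` for the non-significant mid interval.
#' * `model2` — as `model1` but with separate mid-interval weights for the
#'   initial study (`w_I`) and all subsequent studies (`w_S`); 2 parameters.
#' * `model3` — three categories.  Initial studies: `w_I`; early replications:
#'   `w_E1` for z in (-1.64, 0], `w_E2` for z in (0, 1.64]; late replications:
#'   `w_S`; 4 parameters.
#' * `proteus` — as `model3`, but the early-replication weights are arranged by
#'   agreement with the initial study's sign: a non-significant early result
#'   *opposing* the initial sign gets `w_E1`, one *confirming* it gets `w_E2`;
#'   4 parameters.
#'
#' @param name Model name, one of
#'   `c("unbiased", "high_resolution", "model1", "model2", "model3", "proteus")`.
#' @param effects `"random"` (per-marker between-study variance estimated,
#'   unrestricted) or `"fixed"` (between-study variances pinned at zero).
#' @return A `selectmeta_model` object.
#' @examples
#' build_model("proteus")
#' build_model("model1", effects = "fixed")
#' @export
build_model <- function(name, effects = c("random", "fixed")) {
  if (length(name) != 1L || !name %in% MODEL_NAMES) {
    abort(paste0(
      "unknown model `", paste(name, collapse = ","),
      "`; valid names are: ", toString(MODEL_NAMES)
    ))
  }
  effects <- match.arg(effects)

  mid <- function(par_idx) {
    list(boundaries = MID_BOUNDARIES, assign = c(0L, par_idx, 0L))
  }
  spec <- switch(name,
    unbiased = list(
      params = character(0),
      wfs = list(all = list(boundaries = numeric(0), assign = 0L))
    ),
    high_resolution = list(
      params = sprintf("log_w_%02d", 1:14),
      wfs = list(all = list(
        boundaries = HIGH_RES_BOUNDARIES,
        assign = c(0L, 1:14, 0L)
      ))
    ),
    model1 = list(
      params = "log_w_S",
      wfs = list(all = mid(1L))
    ),
    model2 = list(
      params = c("log_w_I", "log_w_S"),
      wfs = list(initial = mid(1L), subsequent = mid(2L))
    ),
    model3 = list(
      params = c("log_w_I", "log_w_E1", "log_w_E2", "log_w_S"),
      wfs = list(
        initial = mid(1L),
        early = list(boundaries = EARLY_BOUNDARIES, assign = c(0L, 2L, 3L, 0L)),
        late = mid(4L)
      )
    ),
    proteus = list(
      params = c("log_w_I", "log_w_E1", "log_w_E2", "log_w_S"),
      wfs = list(
        initial = mid(1L),
        early_pos = list(
          boundaries = EARLY_BOUNDARIES, assign = c(0L, 2L, 3L, 0L)
        ),
        early_neg = list(
          boundaries = EARLY_BOUNDARIES, assign = c(0L, 3L, 2L, 0L)
        ),
        late = mid(4L)
      )
    )
  )

  structure(
    list(
      name = name,
      effects = effects,
      params = spec$params,
      n_free_weights = length(spec$params),
      wfs = spec$wfs,
      sign_dependent = identical(name, "proteus")
    ),
    class = "selectmeta_model"
  )
}

#' @export
print.selectmeta_model <- function(x, ...) {
  cat(sprintf(
    "<selectmeta_model> %s (%s effects), %d free weight parameter%s\n",
    x$name, x$effects, x$n_free_weights, if (x$n_free_weights == 1) "" else "s"
  ))
  if (x$n_free_weights > 0) cat("  weights:", toString(x$params), "\n")
  invisible(x)
}

#' Count free parameters of a model on a corpus
#'
#' Total parameter count `k` entering `AIC = 2k - 2L`: the model's free
#' weight parameters plus one mean effect per marker and, under random
#' effects, one between-study variance per marker.  When models are compared
#' on the same corpus the per-marker counts cancel, so AIC differences depend
#' only on the weight-parameter counts and the log-likelihood difference.
#'
#' @param model A [build_model()] specification.
#' @param corpus A study-level data frame with a `marker_id` column.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model, corpus) {
  stopifnot(inherits(model, "selectmeta_model"))
  if (!"marker_id" %in% names(corpus) || nrow(corpus) == 0L) {
    abort("`corpus` must be a nonempty data frame with a `marker_id` column.")
  }
  m <- dplyr::n_distinct(corpus$marker_id)
  per_marker <- if (model$effects == "random") 2L else 1L
  model$n_free_weights + per_marker * m
}
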