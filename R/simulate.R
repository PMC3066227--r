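## Simulator of selectively reported study corpora.
##
## Candidate studies are generated in temporal order from the random-effects
## normal model and each is published with probability omega(z) / max(omega),
## using the category- (and, for the Proteus model, sign-) appropriate weight
## function.  Only published studies are emitted, so fitting the generating
## model to the output is a parameter-recovery experiment.

#' Configuration for a simulated study corpus
#'
#' The defaults emulate a large gene-disease association corpus: about 100
#' markers with 4 to 30 published case-control results each, a small fraction
#' of markers with a real effect, per-study standard errors typical of
#' moderately sized case-control studies, and year-stamped studies arriving
#' over a few calendar years.
#'
#' @param n_markers Number of markers.
#' @param studies Integer range `c(min, max)` of published studies per marker
#'   (drawn uniformly).
#' @param prob_nonnull Fraction of markers with a true association.
#' @param effect_size Range of |log OR| for non-null markers (sign random).
#' @param tau2 Range of the true between-study variance (uniform).
#' @param sigma Range of within-study standard errors (uniform per study).
#' @param start_year Range of the calendar year of a marker's first candidate
#'   study.
#' @param year_gap_probs Probabilities of a 0/1/2-year gap between successive
#'   candidate studies on a marker.
#' @param model Name of the generating model (see [build_model()]).
#' @param log_weights Named numeric vector of true log-weights for the
#'   generating model's free parameters (defaults to all zero = no selection).
#' @param max_candidates_factor Abort a marker after this many candidates per
#'   published study (guards against near-zero acceptance rates).
#' @param seed Integer seed; mandatory so corpora are reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_markers = 100,
                       studies = c(4, 30),
                       prob_nonnull = 0.10,
                       effect_size = c(0.1, 0.5),
                       tau2 = c(0, 0.05),
                       sigma = c(0.08, 0.4),
                       start_year = c(1995, 2005),
                       year_gap_probs = c(0.5, 0.35, 0.15),
                       model = "unbiased",
                       log_weights = NULL,
                       max_candidates_factor = 50,
                       seed) {
  if (missing(seed) || !is.finite(seed)) abort("`seed` is mandatory.")
  if (prob_nonnull < 0 || prob_nonnull > 1) {
    abort("`prob_nonnull` must be a probability.")
  }
  if (any(year_gap_probs < 0) || sum(year_gap_probs) <= 0) {
    abort("`year_gap_probs` must be nonnegative with positive sum.")
  }
  spec <- build_model(model)  # validates name and weight names
  fill_weights(spec, log_weights)
  structure(
    list(
      n_markers = as.integer(n_markers), studies = as.integer(studies),
      prob_nonnull = prob_nonnull, effect_size = effect_size, tau2 = tau2,
      sigma = sigma, start_year = as.integer(start_year),
      year_gap_probs = year_gap_probs / sum(year_gap_probs),
      model = model, log_weights = log_weights,
      max_candidates_factor = max_candidates_factor, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Read a simulator configuration from JSON or YAML
#'
#' @param path File whose extension selects the parser (`.json`, `.yml`,
#'   `.yaml`).
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML configs requires the `yaml` package.")
    }
    yaml::read_yaml(path)
  } else {
    abort("config must be .json, .yml or .yaml")
  }
  if (!is.null(raw$log_weights)) raw$log_weights <- unlist(raw$log_weights)
  do.call(sim_config, raw)
}

## uniform integer draw on a closed range, safe when min == max
sample_range <- function(range, n) {
  range[1] + sample.int(range[2] - range[1] + 1L, n, replace = TRUE) - 1L
}

## Simulate one marker; returns a tibble of its published studies.
simulate_marker <- function(cfg, spec, marker_id, delta, tau2, n_target) {
  sample_gap <- function(n) {
    sample.int(length(cfg$year_gap_probs), n, replace = TRUE,
               prob = cfg$year_gap_probs) - 1L
  }
  theta_w <- fill_weights(spec, cfg$log_weights)
  wf_cache <- lapply(names(spec$wfs), function(nm) {
    tmpl <- spec$wfs[[nm]]
    lw <- ifelse(tmpl$assign == 0L, 0, theta_w[pmax(tmpl$assign, 1L)])
    list(boundaries = tmpl$boundaries, log_w = lw, max_w = max(exp(lw)))
  })
  names(wf_cache) <- names(spec$wfs)

  accept_prob <- function(wf, z) {
    exp(wf$log_w[interval_index(z, wf$boundaries)]) / wf$max_w
  }

  year0 <- sample_range(cfg$start_year, 1L)
  cap <- cfg$max_candidates_factor * n_target
  pub <- list()
  n_pub <- 0L
  n_cand <- 0L
  year <- year0
  first_year <- NA_integer_
  initial_sign <- NA_real_

  ## phase 1: one-at-a-time until the first publication fixes the time origin
  ## and (for the Proteus model) the initial sign
  while (n_pub == 0L) {
    if (n_cand >= cap) {
      abort(paste0(
        "candidate cap reached for marker ", marker_id,
        " before any publication; weaken the selection or raise ",
        "`max_candidates_factor`."
      ))
    }
    n_cand <- n_cand + 1L
    s <- runif(1, cfg$sigma[1], cfg$sigma[2])
    x <- rnorm(1, delta, sqrt(s^2 + tau2))
    z <- x / s
    ## before anything is published every candidate counts as an initial study
    wf <- wf_cache[[wf_name_for(spec, "initial")]]
    if (runif(1) < accept_prob(wf, z)) {
      n_pub <- 1L
      first_year <- year
      initial_sign <- z_sign(z)
      pub[[1L]] <- c(x = x, se = s, year = year)
    }
    year <- year + sample_gap(1L)
  }

  ## phase 2: batched candidates with known category structure
  while (n_pub < n_target) {
    n_batch <- min(max(2L * (n_target - n_pub), 16L), cap - n_cand)
    if (n_batch <= 0L) {
      abort(paste0(
        "candidate cap reached for marker ", marker_id,
        "; weaken the selection or raise `max_candidates_factor`."
      ))
    }
    n_cand <- n_cand + n_batch
    years <- year + cumsum(c(0L, sample_gap(n_batch)))[seq_len(n_batch)]
    year <- years[n_batch] + sample_gap(1L)
    s <- runif(n_batch, cfg$sigma[1], cfg$sigma[2])
    x <- rnorm(n_batch, delta, sqrt(s^2 + tau2))
    z <- x / s
    cat_b <- ifelse(years == first_year, "initial",
             ifelse(years <= first_year + 2L, "early", "late"))
    p <- vapply(seq_len(n_batch), function(i) {
      wf <- wf_cache[[wf_name_for(spec, cat_b[i], initial_sign)]]
      accept_prob(wf, z[i])
    }, numeric(1))
    keep <- which(runif(n_batch) < p)
    keep <- head(keep, n_target - n_pub)
    if (length(keep) == n_target - n_pub && length(keep) > 0L) {
      ## the process stops at the target-reaching candidate; trailing batch
      ## candidates never happen
      n_cand <- n_cand - (n_batch - keep[length(keep)])
    }
    for (i in keep) {
      n_pub <- n_pub + 1L
      pub[[n_pub]] <- c(x = x[i], se = s[i], year = years[i])
    }
  }

  mat <- do.call(rbind, pub)
  list(
    studies = tibble::tibble(
      marker_id = marker_id,
      pub_id = sprintf("%s_P%03d", marker_id, seq_len(n_pub)),
      year = as.integer(mat[, "year"]),
      log_or = mat[, "x"],
      se = mat[, "se"]
    ),
    n_candidates = n_cand
  )
}

#' Simulate a selectively reported study corpus
#'
#' For each marker, draws a true mean effect and between-study variance,
#' generates candidate studies in temporal order, and publishes each with
#' probability `omega(z) / max(omega)` under the generating model's weight
#' function for the candidate's category (initial studies before the first
#' publication; thereafter the year-based rules).  The Proteus model's sign
#' context is taken from the first *published* study.  Generation continues
#' until the target published count is reached.
#'
#' @param cfg A [sim_config()].
#' @return A study-level tibble (CSV dialect `"effects"` columns) with
#'   attributes `truth` (per-marker true `delta`, `tau2`, candidate counts)
#'   and `config`.
#' @examples
#' corpus <- simulate_corpus(sim_config(
#'   n_markers = 5, studies = c(4, 8), model = "model1",
#'   log_weights = c(log_w_S = -0.5), seed = 1
#' ))
#' @export
simulate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  spec <- build_model(cfg$model)
  withr::with_seed(cfg$seed, {
    ids <- sprintf("M%03d", seq_len(cfg$n_markers))
    nonnull <- runif(cfg$n_markers) < cfg$prob_nonnull
    delta <- ifelse(
      nonnull,
      sample(c(-1, 1), cfg$n_markers, replace = TRUE) *
        runif(cfg$n_markers, cfg$effect_size[1], cfg$effect_size[2]),
      0
    )
    tau2 <- runif(cfg$n_markers, cfg$tau2[1], cfg$tau2[2])
    n_target <- sample_range(cfg$studies, cfg$n_markers)
    res <- purrr::pmap(
      list(ids, delta, tau2, n_target),
      function(id, d, t2, nt) simulate_marker(cfg, spec, id, d, t2, nt)
    )
    out <- purrr::list_rbind(purrr::map(res, "studies"))
    attr(out, "truth") <- tibble::tibble(
      marker_id = ids, delta = delta, tau2 = tau2, n_published = n_target,
      n_candidates = purrr::map_int(res, "n_candidates")
    )
    attr(out, "config") <- cfg
    out
  })
}

#' Closed-form interval fractions of published studies
#'
#' For one configuration `(delta, tau2, sigma)` and one weight function, the
#' probability that a *published* study's z falls in each weight interval is
#' `w_j B_j / sum_j w_j B_j`.  This is the analytic oracle the simulator is
#' validated against.
#'
#' @inheritParams interval_probs
#' @param wf A [weight_function()].
#' @return Probability vector over the weight function's intervals.
#' @export
expected_interval_fractions <- function(delta, tau2, sigma, wf) {
  stopifnot(inherits(wf, "weight_function"))
  B <- interval_probs(delta, tau2, sigma, wf$boundaries)
  wB <- exp(wf$log_weights) * B
  wB / sum(wB)
}
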