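## End-to-end analysis and simulation-recovery pipelines.

#' Run the full selection-model analysis on a corpus
#'
#' Reads (or accepts) a study corpus, derives per-allele effects if raw
#' genotype tables were supplied, assigns temporal categories, applies the
#' minimum-publication inclusion filter and the convergence-exclusion
#' protocol, fits the requested models on the shared surviving corpus, and
#' assembles the comparison table, derived reporting probabilities and
#' per-marker corrected estimates.  With `out_dir` set, everything is also
#' written to disk (CSV + JSON + a plain-text summary).
#'
#' @param input A file path (CSV; see [read_corpus()]) or a study-level data
#'   frame.
#' @param dialect CSV dialect for file input (`"auto"`, `"effects"`,
#'   `"genotypes"`).
#' @param models Model names to fit.
#' @param effects `"random"` or `"fixed"`.
#' @param min_publications Inclusion threshold on distinct publications.
#' @param exclude Apply the convergence-exclusion protocol?
#' @param control Optimizer control, see [fit_selection_model()].
#' @param out_dir Optional output directory.
#' @param verbose Log progress and exclusions to the console?
#' @return A `selectmeta_report` list: `corpus`, `fits`, `table`,
#'   `reporting`, `corrected`, `excluded`.
#' @export
run_analysis <- function(input,
                         dialect = "auto",
                         models = c("unbiased", "model1", "model2",
                                    "model3", "proteus"),
                         effects = "random",
                         min_publications = 4,
                         exclude = TRUE,
                         control = list(),
                         out_dir = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) inform(sprintf(...))
  corpus <- if (is.character(input)) read_corpus(input, dialect) else
    tibble::as_tibble(input)
  say("corpus: %d studies on %d markers", nrow(corpus),
      dplyr::n_distinct(corpus$marker_id))

  corpus <- filter_min_publications(corpus, min_publications)
  say("after inclusion filter (>= %d publications): %d studies on %d markers",
      min_publications, nrow(corpus), dplyr::n_distinct(corpus$marker_id))
  if (nrow(corpus) == 0L) abort("no markers survive the inclusion filter.")
  if (!"category" %in% names(corpus)) corpus <- categorize_studies(corpus)

  fits <- fit_models(corpus, models, effects, exclude = exclude,
                     control = control)
  excluded <- attr(fits, "excluded")
  if (nrow(excluded) > 0) {
    say("excluded %d marker(s) by the convergence protocol: %s",
        nrow(excluded),
        paste0(excluded$marker_id, " (", excluded$models, ")",
               collapse = ", "))
  } else {
    say("no markers excluded by the convergence protocol")
  }
  for (nm in names(fits)) {
    say("fitted %-16s log L = %10.3f  converged = %s",
        nm, fits[[nm]]$loglik, fits[[nm]]$converged)
  }

  tbl <- if ("unbiased" %in% names(fits)) model_table(fits) else NULL
  best_sel <- setdiff(names(fits), "unbiased")
  reporting <- purrr::map(fits[best_sel], derive_reporting_probability) |>
    purrr::list_rbind(names_to = "model")
  corrected <- NULL
  if ("unbiased" %in% names(fits) && length(best_sel)) {
    pick <- if (!is.null(tbl)) {
      cand <- tbl$model[tbl$best]
      if (any(cand != "unbiased")) setdiff(cand, "unbiased")[1] else best_sel[length(best_sel)]
    } else best_sel[length(best_sel)]
    corrected <- corrected_estimates(fits[[pick]], fits[["unbiased"]])
    attr(corrected, "selection_model") <- pick
  }

  report <- structure(
    list(corpus = attr(fits, "corpus"), fits = fits, table = tbl,
         reporting = reporting, corrected = corrected, excluded = excluded),
    class = "selectmeta_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$table)) {
    readr::write_csv(report$table, file.path(out_dir, "model_table.csv"))
  }
  if (!is.null(report$reporting) && nrow(report$reporting)) {
    readr::write_csv(report$reporting,
                     file.path(out_dir, "reporting_probabilities.csv"))
  }
  if (!is.null(report$corrected)) {
    readr::write_csv(report$corrected,
                     file.path(out_dir, "corrected_estimates.csv"))
  }
  readr::write_csv(report$excluded, file.path(out_dir, "excluded_markers.csv"))
  for (nm in names(report$fits)) {
    write_fit_json(report$fits[[nm]],
                   file.path(out_dir, paste0("fit_", nm, ".json")))
  }
  summary_path <- file.path(out_dir, "summary.txt")
  withr::with_output_sink(summary_path, print(report))
  invisible(out_dir)
}

#' @export
print.selectmeta_report <- function(x, ...) {
  cat("<selectmeta_report>\n")
  cat(sprintf("  corpus: %d studies on %d markers (%d excluded)\n",
              nrow(x$corpus), dplyr::n_distinct(x$corpus$marker_id),
              nrow(x$excluded)))
  if (!is.null(x$table)) {
    cat("  model comparison (differences to the unbiased model):\n")
    tb <- x$table
    for (i in seq_len(nrow(tb))) {
      cat(sprintf("    %-16s dL = %8.3f  k_w = %d  dAIC = %8.3f%s\n",
                  tb$model[i], tb$delta_L[i], tb$n_weight_params[i],
                  tb$delta_AIC[i], if (tb$best[i]) "  <- best" else ""))
    }
  }
  if (!is.null(x$reporting) && nrow(x$reporting)) {
    cat("  derived reporting probabilities:\n")
    r <- x$reporting
    for (i in seq_len(nrow(r))) {
      cat(sprintf("    %-10s %-45s %5.1f%% (%5.1f%%, %5.1f%%)\n",
                  r$model[i], r$term[i], 100 * r$point[i],
                  100 * r$ci_low[i], 100 * r$ci_high[i]))
    }
  }
  invisible(x)
}

#' Simulation-recovery study
#'
#' Simulates `n_replicates` corpora under a generating configuration, fits
#' the generating model to each, and reports truth versus estimate for every
#' free weight parameter with a 2-SE coverage flag per replicate.
#'
#' @param cfg A [sim_config()] (its `seed` seeds replicate 1; replicate r
#'   uses `seed + r - 1`).
#' @param n_replicates Number of simulated corpora.
#' @param fit_model Model to fit (defaults to the generating model).
#' @param effects `"random"` or `"fixed"`.
#' @param control Optimizer control.
#' @param verbose Log per-replicate progress?
#' @return A tibble with one row per replicate and weight parameter:
#'   `replicate`, `term`, `truth`, `estimate`, `std.error`, `covered`
#'   (|estimate - truth| <= 2 SE), `converged`.
#' @export
run_simulation <- function(cfg, n_replicates = 25, fit_model = NULL,
                           effects = "random", control = list(),
                           verbose = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  fit_model <- fit_model %||% cfg$model
  build_model(fit_model, effects)  # validate early
  truth <- fill_weights(build_model(cfg$model), cfg$log_weights)
  rows <- purrr::map(seq_len(n_replicates), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r - 1L
    corpus <- simulate_corpus(cfg_r) |> categorize_studies()
    prot <- exclusion_protocol(corpus, fit_model, effects, control)
    fit <- prot$fits[[fit_model]]
    if (verbose) {
      inform(sprintf("replicate %d: log L = %.2f, converged = %s",
                     r, fit$loglik, fit$converged))
    }
    w <- fit$weights
    tr <- ifelse(w$term %in% names(truth), truth[w$term], NA_real_)
    tibble::tibble(
      replicate = r,
      term = w$term,
      truth = tr,
      estimate = w$estimate,
      std.error = w$std.error,
      covered = abs(w$estimate - tr) <= 2 * w$std.error,
      converged = fit$converged
    )
  })
  purrr::list_rbind(rows)
}
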