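## Per-allele effects from genotype tables, temporal categories, inclusion.

#' Per-allele log odds ratios from 2x3 genotype tables
#'
#' Derives, for each row, the per-allele log odds ratio and its standard error
#' by logistic regression of case/control status on allele dose (0, 1 or 2
#' copies of the variant allele; one observation per subject, expanded from
#' the genotype counts).  When the collapsed 2x2 allele table has a zero cell
#' — or the regression separates — the Woolf estimator on the allele table
#' with the Haldane 0.5 continuity correction is used instead and the row is
#' flagged.  The variant-allele column of the input defines the risk-allele
#' orientation; no re-orientation by frequency is performed.
#'
#' @param tables Data frame with columns `case_hom`, `case_het`, `case_wt`,
#'   `ctrl_hom`, `ctrl_het`, `ctrl_wt` (nonnegative integer counts; `hom` =
#'   homozygous variant, `wt` = wildtype) and any identifier columns, which
#'   are carried through.
#' @return The input tibble with columns `log_or`, `se` and
#'   `corrected` (logical; `TRUE` where the continuity-corrected Woolf
#'   fallback was used) appended.
#' @examples
#' t <- tibble::tibble(
#'   marker_id = "m1", pub_id = "p1", year = 2000,
#'   case_hom = 4, case_het = 12, case_wt = 34,
#'   ctrl_hom = 2, ctrl_het = 10, ctrl_wt = 38
#' )
#' per_allele_log_or(t)
#' @export
per_allele_log_or <- function(tables) {
  need <- c("case_hom", "case_het", "case_wt", "ctrl_hom", "ctrl_het", "ctrl_wt")
  missing_cols <- setdiff(need, names(tables))
  if (length(missing_cols)) {
    abort(paste0("`tables` is missing column(s): ", toString(missing_cols)))
  }
  counts <- as.matrix(tables[need])
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("genotype counts must be nonnegative integers.")
  }
  if (any(rowSums(counts[, 1:3, drop = FALSE]) == 0) ||
      any(rowSums(counts[, 4:6, drop = FALSE]) == 0)) {
    abort("each study needs at least one case and one control subject.")
  }

  one <- function(ch, che, cw, th, the, tw) {
    ## collapsed allele-count 2x2 table
    a <- 2 * ch + che   # case variant alleles
    b <- 2 * cw + che   # case reference alleles
    cc <- 2 * th + the  # control variant alleles
    d <- 2 * tw + the   # control reference alleles
    woolf <- function(a, b, cc, d) {
      c(log((a * d) / (b * cc)), sqrt(1 / a + 1 / b + 1 / cc + 1 / d))
    }
    if (min(a, b, cc, d) == 0) {
      est <- woolf(a + 0.5, b + 0.5, cc + 0.5, d + 0.5)
      return(c(est, 1))
    }
    df <- data.frame(
      case = rep(c(1, 1, 1, 0, 0, 0)),
      dose = rep(c(2, 1, 0, 2, 1, 0)),
      w = c(ch, che, cw, th, the, tw)
    )
    df <- df[df$w > 0, ]
    fit <- tryCatch(
      suppressWarnings(glm(case ~ dose, family = binomial(), data = df,
                           weights = df$w)),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged ||
        !is.finite(coef(fit)[["dose"]]) || abs(coef(fit)[["dose"]]) > 15) {
      est <- woolf(a + 0.5, b + 0.5, cc + 0.5, d + 0.5)
      return(c(est, 1))
    }
    sm <- summary(fit)$coefficients
    c(sm["dose", 1], sm["dose", 2], 0)
  }

  res <- t(mapply(
    one,
    counts[, 1], counts[, 2], counts[, 3],
    counts[, 4], counts[, 5], counts[, 6]
  ))
  out <- tibble::as_tibble(tables)
  out$log_or <- unname(res[, 1])
  out$se <- unname(res[, 2])
  out$corrected <- unname(res[, 3] > 0)
  out
}

#' Assign temporal categories and sign context to studies
#'
#' For each marker: studies published in the same year as the marker's first
#' study are `initial`; studies in the following two calendar years are
#' `early` replications; all later studies are `late`.  The marker's
#' `initial_sign` is the sign of z of its initial study, taking the most
#' extreme result (largest |z|) when several studies are initial; each early
#' study gets `sign_agrees = TRUE` when its own sign matches the initial sign.
#' A z of exactly 0 counts as negative, and a tie in extremeness between the
#' two signs resolves to positive, so the output is invariant to row order.
#'
#' @param corpus Study-level data frame with `marker_id`, `year`, `log_or`,
#'   `se` columns.
#' @return The corpus with `category`, `initial_sign` and `sign_agrees`
#'   columns appended (`sign_agrees` is `NA` outside the early category).
#' @export
categorize_studies <- function(corpus) {
  need <- c("marker_id", "year", "log_or", "se")
  missing_cols <- setdiff(need, names(corpus))
  if (length(missing_cols)) {
    abort(paste0("`corpus` is missing column(s): ", toString(missing_cols)))
  }
  if (nrow(corpus) == 0L) abort("`corpus` has no studies.")
  if (any(!is.finite(corpus$year)) || any(corpus$year != round(corpus$year))) {
    abort("`year` must be an integer publication year.")
  }

  corpus |>
    tibble::as_tibble() |>
    dplyr::mutate(.z = .data$log_or / .data$se) |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::mutate(
      .y0 = min(.data$year),
      category = dplyr::case_when(
        .data$year == .data$.y0 ~ "initial",
        .data$year <= .data$.y0 + 2 ~ "early",
        TRUE ~ "late"
      ),
      initial_sign = {
        zi <- .data$.z[.data$category == "initial"]
        ext <- zi[abs(zi) == max(abs(zi))]
        if (any(ext > 0)) 1 else -1
      },
      sign_agrees = dplyr::if_else(
        .data$category == "early",
        z_sign(.data$.z) == .data$initial_sign,
        NA
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".z", -".y0")
}

#' Keep only markers with enough independent publications
#'
#' Retains markers whose studies come from at least `min_publications`
#' distinct publications.  No filtering on Hardy-Weinberg equilibrium or on
#' effect magnitude is applied.
#'
#' @param corpus Study-level data frame with `marker_id` and `pub_id` columns.
#' @param min_publications Minimum number of distinct `pub_id`s (default 4).
#' @return The filtered corpus.
#' @export
filter_min_publications <- function(corpus, min_publications = 4) {
  if (!"pub_id" %in% names(corpus)) abort("`corpus` must have a `pub_id` column.")
  corpus |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::filter(dplyr::n_distinct(.data$pub_id) >= min_publications) |>
    dplyr::ungroup()
}

#' Read a study corpus from CSV
#'
#' Two dialects are supported.  `"effects"`: columns `marker_id`, `pub_id`,
#' `year`, `log_or`, `se` (precomputed per-allele log odds ratios).
#' `"genotypes"`: columns `marker_id`, `pub_id`, `year`, `case_hom`,
#' `case_het`, `case_wt`, `ctrl_hom`, `ctrl_het`, `ctrl_wt` (raw 2x3 genotype
#' count tables), from which effects are derived via [per_allele_log_or()].
#' With `dialect = "auto"` the column names decide.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param dialect `"auto"`, `"effects"` or `"genotypes"`.
#' @return A study-level tibble with `log_or` and `se` columns.
#' @export
read_corpus <- function(path, dialect = c("auto", "effects", "genotypes")) {
  dialect <- match.arg(dialect)
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (dialect == "auto") {
    dialect <- if (all(c("log_or", "se") %in% names(df))) "effects"
      else if ("case_hom" %in% names(df)) "genotypes"
      else abort(paste0(
        "cannot determine dialect of ", path,
        ": need either log_or/se or case_*/ctrl_* columns."
      ))
  }
  need <- c("marker_id", "pub_id", "year")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0(path, " is missing column(s): ", toString(missing_cols)))
  }
  if (dialect == "genotypes") df <- per_allele_log_or(df)
  if (!all(c("log_or", "se") %in% names(df))) {
    abort(paste0(path, " is missing log_or/se columns."))
  }
  tibble::as_tibble(df)
}
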