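## Shared oracles and fixture builders (everything is generated in code).

## numeric integral of the weighted density over the real line, split at the
## weight-function discontinuities so adaptive quadrature sees smooth pieces
quadrature_mass <- function(wf, delta, tau2, sigma, rel.tol = 1e-10) {
  f <- function(x) exp(weighted_logdensity(x, sigma, delta, tau2, wf))
  cuts <- c(-Inf, wf$boundaries * sigma, Inf)
  sum(vapply(seq_len(length(cuts) - 1), function(j) {
    integrate(f, cuts[j], cuts[j + 1], rel.tol = rel.tol)$value
  }, numeric(1)))
}

## a small deterministic corpus (no randomness; values chosen by hand)
tiny_corpus <- function() {
  tibble::tibble(
    marker_id = rep(c("mA", "mB"), c(5, 4)),
    pub_id = c(paste0("a", 1:5), paste0("b", 1:4)),
    year = c(2000, 2000, 2001, 2003, 2004, 1998, 1999, 2000, 2002),
    log_or = c(0.55, -0.12, 0.31, 0.05, 0.42, -0.38, -0.10, 0.22, -0.55),
    se = c(0.25, 0.30, 0.22, 0.28, 0.35, 0.20, 0.24, 0.30, 0.26)
  )
}

## random-effects normal log likelihood of one marker (no selection),
## closed form used as the unweighted oracle
re_normal_loglik <- function(x, se, delta, tau2) {
  sum(dnorm(x, delta, sqrt(se^2 + tau2), log = TRUE))
}

## random valid weight function on the model-3 boundary set
random_wf <- function() {
  weight_function(
    c(-1.64, 0, 1.64),
    c(0, rnorm(1, 0, 0.7), rnorm(1, 0, 0.7), 0),
    c(FALSE, TRUE, TRUE, FALSE)
  )
}

## small simulated corpus used by several fitting tests
small_sim_corpus <- function(seed = 101, n_markers = 30, model = "model1",
                             log_weights = c(log_w_S = -0.5),
                             studies = c(4, 15)) {
  categorize_studies(simulate_corpus(sim_config(
    n_markers = n_markers, studies = studies, model = model,
    log_weights = log_weights, seed = seed
  )))
}
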