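## Small in-code fixtures shared across test files.

## complete single-group panel: N subjects, constant mean mu, precision phi
const_panel <- function(N, Tn, mu, phi, seed, times = seq(0, 4 * (Tn - 1), by = 4)) {
  y <- matrix(rbeta_mp(N * Tn, mu, phi, seed = seed), ncol = Tn)
  panel_data(y, times = times)
}

## random valid mixture model for a given spec (moderate parameter ranges)
random_model <- function(spec, seed, tscale = c(0, 1)) {
  with_seed_local(seed, {
    groups <- lapply(seq_len(spec$J), function(j) {
      list(beta = stats::rnorm(spec$orders[j] + 1L, 0, 0.8),
           log_phi = stats::runif(1, log(1), log(10)),
           delta = if (spec$dropout)
             stats::rnorm(1L + spec$dropout_lags, -1, 0.5) else NULL)
    })
    gamma <- stats::rnorm(spec$J - 1L, 0, 0.7)
    mixture_model(spec, groups, gamma, tscale = tscale)
  })
}

## evaluate under a fixed seed without disturbing the test RNG state
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

## three-group scenario with a genuinely cubic low group and quadratic others
cubic_truth_config <- function(n_subjects = 400) {
  synth_config(
    n_subjects = n_subjects, times = seq(0, 48, by = 4),
    weights = c(0.3, 0.4, 0.3),
    coefs = list(c(-2, 3, -9, 6), c(0.8, -3, 1.5), c(2.5, -1.5, 1.0)),
    phi = c(8, 8, 8), link = "logit")
}

## overlapping groups with strongly outcome-dependent dropout in the top group
informative_dropout_config <- function(n_subjects = 400) {
  synth_config(
    n_subjects = n_subjects, times = seq(0, 48, by = 4),
    weights = c(0.3, 0.35, 0.35),
    coefs = list(c(-2), c(0.2), c(1.4)), phi = c(4, 4, 4),
    delta = list(c(-6, 0), c(-6, 0), c(-4.5, 4.5)), link = "logit")
}
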