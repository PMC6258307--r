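## Mean-precision parameterization of the beta distribution.
##
## y ~ Beta(mu, phi) with E(y) = mu in (0,1) and precision phi > 0;
## Var(y) = mu (1 - mu) / (1 + phi).  The usual shape parameters are
## a = mu * phi and b = (1 - mu) * phi.  Larger phi means smaller variance
## at a fixed mean; phi < 1 gives densities unbounded at one or both
## boundaries (J- and U-shapes), which is why likelihood code works in log
## space throughout.

check_mp <- function(mu, phi) {
  if (any(!is.finite(mu)) || any(mu <= 0) || any(mu >= 1))
    stopf("'mu' must lie strictly inside (0, 1)")
  if (any(!is.finite(phi)) || any(phi <= 0))
    stopf("'phi' (precision) must be strictly positive")
  invisible(TRUE)
}

#' Beta parameters in the mean-precision parameterization
#'
#' Bundles a mean `mu` in (0,1) and a precision `phi > 0`. Validation happens
#' here, at construction, so downstream density code does not recheck inside
#' hot likelihood loops.
#'
#' @param mu Mean, strictly inside (0, 1). Vectorized.
#' @param phi Precision, strictly positive. Vectorized (recycled against `mu`).
#' @return An object of class `"beta_params"`: a list with elements `mu` and
#'   `phi`.
#' @examples
#' p <- beta_params(0.42, 0.77)
#' beta_moments(p$mu, p$phi)
#' @export
beta_params <- function(mu, phi) {
  check_mp(mu, phi)
  n <- max(length(mu), length(phi))
  structure(list(mu = rep_len(mu, n), phi = rep_len(phi, n)),
            class = "beta_params")
}

#' @export
print.beta_params <- function(x, ...) {
  cat("Beta(mean-precision): mu =", format(x$mu), " phi =", format(x$phi), "\n")
  invisible(x)
}

#' Beta density in the mean-precision parameterization
#'
#' Density (or log-density) of the beta distribution indexed by mean `mu` and
#' precision `phi`, i.e. shapes `a = mu*phi`, `b = (1-mu)*phi`:
#' \deqn{\log f(y) = \log\Gamma(\phi) - \log\Gamma(\mu\phi) -
#'   \log\Gamma((1-\mu)\phi) + (\mu\phi - 1)\log y + ((1-\mu)\phi - 1)\log(1-y).}
#'
#' The support is the open interval (0, 1): exact 0/1 observations must be
#' mapped inward first (see [boundary_adjust()]).
#'
#' @param y Numeric vector of values strictly inside (0, 1).
#' @param mu Mean(s) in (0, 1).
#' @param phi Precision(s), positive.
#' @param log If `TRUE`, return the log-density.
#' @return Numeric vector of (log-)density values.
#' @examples
#' dbeta_mp(0.3, mu = 0.5, phi = 2)        # uniform special case: density 1
#' dbeta_mp(0.5, mu = 0.5, phi = 4)        # Beta(2,2) at its mode: 1.5
#' @seealso [boundary_adjust()] for handling exact 0/1 data.
#' @export
dbeta_mp <- function(y, mu, phi, log = FALSE) {
  check_mp(mu, phi)
  if (any(!is.finite(y)) || any(y <= 0) || any(y >= 1))
    stopf(paste("'y' must lie strictly inside (0, 1); exact 0/1 observations",
                "must be moved off the boundary first with boundary_adjust()"))
  ll <- beta_logpdf_raw(y, mu, phi)
  if (log) ll else exp(ll)
}

## unchecked core used by likelihood code (validation done at construction)
beta_logpdf_raw <- function(y, mu, phi) {
  a <- mu * phi
  b <- (1 - mu) * phi
  lgamma(phi) - lgamma(a) - lgamma(b) + (a - 1) * log(y) + (b - 1) * log1p(-y)
}

#' Moments of the mean-precision beta distribution
#'
#' @inheritParams dbeta_mp
#' @return A list with components `mean` (= `mu`) and `variance`
#'   (= `mu*(1-mu)/(1+phi)`).
#' @examples
#' beta_moments(0.5, 1)   # mean 0.5, variance 0.125
#' @export
beta_moments <- function(mu, phi) {
  check_mp(mu, phi)
  list(mean = mu, variance = mu * (1 - mu) / (1 + phi))
}

#' Draw beta variates in the mean-precision parameterization
#'
#' Delegates to [stats::rbeta()] after shape conversion. With a `seed`, the
#' draw is reproducible and the caller's RNG state is left untouched.
#'
#' @param n Number of draws (at least 1).
#' @param mu,phi Mean and precision (vectors are recycled over draws).
#' @param seed Optional integer seed; if `NULL`, the current RNG stream is
#'   used (and advanced).
#' @return Numeric vector of `n` draws strictly inside (0, 1).
#' @examples
#' x <- rbeta_mp(1000, mu = 0.9, phi = 20, seed = 1)
#' mean(x)
#' @export
rbeta_mp <- function(n, mu, phi, seed = NULL) {
  check_mp(mu, phi)
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stopf("'n' must be a single count >= 1")
  draw <- function() stats::rbeta(n, shape1 = mu * phi, shape2 = (1 - mu) * phi)
  x <- if (is.null(seed)) draw() else with_seed(seed, draw())
  ## extreme shapes can underflow to exact 0/1; nudge only those draws so the
  ## open-interval support holds without distorting the distribution
  x[x <= 0] <- .Machine$double.xmin
  x[x >= 1] <- 1 - 2^-53
  x
}

#' Convert between mean-precision and shape parameterizations
#'
#' `mp_to_shapes()` maps `(mu, phi)` to the standard shapes
#' `(shape1, shape2) = (mu*phi, (1-mu)*phi)`; `shapes_to_mp()` is its exact
#' inverse `mu = a/(a+b)`, `phi = a+b`.
#'
#' @inheritParams dbeta_mp
#' @return A list with components `shape1`/`shape2` (or `mu`/`phi`).
#' @examples
#' mp_to_shapes(0.5, 2)                 # Beta(1, 1), the uniform
#' shapes_to_mp(2, 2)                   # mu 0.5, phi 4
#' @export
mp_to_shapes <- function(mu, phi) {
  check_mp(mu, phi)
  list(shape1 = mu * phi, shape2 = (1 - mu) * phi)
}

#' @rdname mp_to_shapes
#' @param shape1,shape2 Standard beta shape parameters, both positive.
#' @export
shapes_to_mp <- function(shape1, shape2) {
  if (any(!is.finite(shape1)) || any(shape1 <= 0) ||
      any(!is.finite(shape2)) || any(shape2 <= 0))
    stopf("shape parameters must be strictly positive")
  list(mu = shape1 / (shape1 + shape2), phi = shape1 + shape2)
}
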