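## Model structure: J latent groups, each with a polynomial mean trajectory on
## a link scale and its own precision; multinomial-logit mixing proportions;
## optional per-group logistic dropout sub-model.  A trajectory_spec fixes the
## structure; a mixture_model attaches numeric parameters; pack()/unpack()
## bridge to the flat vector the optimizer sees.

#' Specify the structure of a beta trajectory mixture
#'
#' @param groups Number of latent trajectory groups `J >= 1`.
#' @param order Polynomial order(s) of the group mean trajectories on the link
#'   scale; a single value is recycled to all groups, or give one per group.
#' @param link Link for the mean trajectory: `"logit"` (default; guarantees
#'   means inside (0,1) for any coefficients) or `"identity"` (the raw
#'   polynomial; evaluation outside (0,1) is an error, never a silent clamp).
#' @param dropout If `TRUE`, each group carries a logistic dropout hazard with
#'   covariates (intercept, lagged outcome, ...); see `dropout_lags`.
#' @param dropout_lags Number of lagged outcomes in the dropout hazard (1 or 2).
#' @param max_order Maximum admissible polynomial order (guard rail for
#'   selection routines).
#' @return An object of class `"trajectory_spec"`.
#' @examples
#' trajectory_spec(groups = 3, order = c(3, 2, 2))
#' @export
trajectory_spec <- function(groups, order = 2, link = c("logit", "identity"),
                            dropout = FALSE, dropout_lags = 1L, max_order = 4L) {
  link <- match.arg(link)
  if (length(groups) != 1L || !is.finite(groups) || groups < 1 ||
      groups != round(groups))
    stopf("'groups' must be a single integer >= 1")
  J <- as.integer(groups)
  if (any(!is.finite(order)) || any(order < 0) || any(order != round(order)))
    stopf("'order' must be non-negative integers")
  orders <- as.integer(rep_len(order, J))
  if (any(orders > max_order))
    stopf("polynomial order exceeds max_order = %d", max_order)
  if (!dropout_lags %in% c(1L, 2L))
    stopf("'dropout_lags' must be 1 or 2")
  structure(list(J = J, orders = orders, link = link,
                 dropout = isTRUE(dropout),
                 dropout_lags = as.integer(dropout_lags),
                 max_order = as.integer(max_order)),
            class = "trajectory_spec")
}

#' @export
print.trajectory_spec <- function(x, ...) {
  cat(sprintf("Beta GBTM structure: %d group(s), polynomial order(s) %s, %s link%s\n",
              x$J, paste(x$orders, collapse = "/"), x$link,
              if (x$dropout) sprintf(", dropout hazard (%d lag%s)",
                                     x$dropout_lags,
                                     if (x$dropout_lags > 1) "s" else "")
              else ""))
  invisible(x)
}

## number of free parameters implied by a spec
n_params_spec <- function(spec) {
  sum(spec$orders + 1L) + spec$J +
    (if (spec$dropout) spec$J * (1L + spec$dropout_lags) else 0L) +
    (spec$J - 1L)
}

#' Bundle parameters with a trajectory structure
#'
#' @param spec A [trajectory_spec()].
#' @param groups A list of length `J`; element j is a list with `beta`
#'   (link-scale polynomial coefficients, length `orders[j] + 1`), `log_phi`
#'   (log precision), and — when the spec has dropout — `delta` (hazard
#'   coefficients: intercept then lag coefficients).
#' @param gamma Mixing-logit coefficients, length `J - 1` (last group is the
#'   reference).
#' @param tscale Affine time coding `c(origin, scale)`: polynomials are
#'   evaluated at `(t - origin)/scale`. Defaults to raw time.
#' @return An object of class `"mixture_model"`.
#' @examples
#' sp <- trajectory_spec(2, order = 1)
#' m <- mixture_model(sp,
#'   groups = list(list(beta = c(-2, 0.5), log_phi = log(4)),
#'                 list(beta = c(1, -0.5), log_phi = log(8))),
#'   gamma = 0.2)
#' mixing_probs(m$gamma)
#' @export
mixture_model <- function(spec, groups, gamma = numeric(0),
                          tscale = c(0, 1)) {
  stopifnot(inherits(spec, "trajectory_spec"))
  if (length(groups) != spec$J)
    stopf("'groups' must have one element per latent group (J = %d)", spec$J)
  for (j in seq_len(spec$J)) {
    g <- groups[[j]]
    if (length(g$beta) != spec$orders[j] + 1L)
      stopf("group %d: 'beta' must have length order + 1 = %d",
            j, spec$orders[j] + 1L)
    if (length(g$log_phi) != 1L || !is.finite(g$log_phi))
      stopf("group %d: 'log_phi' must be a single finite value", j)
    if (spec$dropout) {
      if (length(g$delta) != 1L + spec$dropout_lags)
        stopf("group %d: 'delta' must have length %d (intercept + lags)",
              j, 1L + spec$dropout_lags)
    } else if (!is.null(g$delta)) {
      stopf("group %d supplies dropout coefficients but the spec has dropout = FALSE", j)
    }
  }
  if (length(gamma) != spec$J - 1L)
    stopf("'gamma' must have length J - 1 = %d", spec$J - 1L)
  if (length(gamma) && any(!is.finite(gamma)))
    stopf("'gamma' must be finite")
  if (length(tscale) != 2L || tscale[2] == 0)
    stopf("'tscale' must be c(origin, scale) with nonzero scale")
  structure(list(spec = spec, groups = groups, gamma = as.numeric(gamma),
                 tscale = as.numeric(tscale)),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  print(x$spec)
  pi <- mixing_probs(x$gamma)
  for (j in seq_len(x$spec$J)) {
    g <- x$groups[[j]]
    cat(sprintf("  group %d: pi = %.3f, beta = (%s), phi = %.3f%s\n",
                j, pi[j], paste(format(g$beta, digits = 4), collapse = ", "),
                exp(g$log_phi),
                if (!is.null(g$delta))
                  sprintf(", delta = (%s)",
                          paste(format(g$delta, digits = 4), collapse = ", "))
                else ""))
  }
  invisible(x)
}

#' Polynomial mean trajectory through a link
#'
#' Evaluates `mu(t) = linkinv(beta[1] + beta[2] t + beta[3] t^2 + ...)`.
#' Under the logit link the result is always strictly inside (0, 1); under the
#' identity link any value outside (0, 1) raises an error naming the offending
#' time.
#'
#' @param beta Polynomial coefficients on the link scale (ascending powers).
#' @param times Numeric vector of (finite) time values.
#' @param link `"logit"` or `"identity"`.
#' @return Vector of group means, one per time.
#' @examples
#' mean_curve(c(0, 0), 0:5)                      # flat at 0.5
#' mean_curve(c(0.3, 0.01), 10, link = "identity")  # 0.4
#' @export
mean_curve <- function(beta, times, link = c("logit", "identity")) {
  link <- match.arg(link)
  if (any(!is.finite(times))) stopf("'times' must be finite")
  eta <- drop(poly_basis(times, length(beta) - 1L) %*% beta)
  ## clamp away from 0/1: plogis saturates in floating point beyond |eta| ~ 37
  if (link == "logit")
    return(pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12))
  bad <- eta <= 0 | eta >= 1
  if (any(bad))
    stopf("identity-link mean outside (0,1) at time %s (value %.4g)",
          format(times[which(bad)[1]]), eta[which(bad)[1]])
  eta
}

## T x (order+1) matrix of raw polynomial powers
poly_basis <- function(times, order) {
  outer(as.numeric(times), 0:order, `^`)
}

## group mean curve of a mixture_model at raw times (applies tscale)
model_mean_curve <- function(model, j, times) {
  s <- (times - model$tscale[1]) / model$tscale[2]
  mean_curve(model$groups[[j]]$beta, s, model$spec$link)
}

#' Mixing proportions from multinomial-logit coefficients
#'
#' `pi_j = exp(gamma_j) / (1 + sum_k exp(gamma_k))` for `j < J`, with the last
#' group as reference (`pi_J = 1 / (1 + sum_k exp(gamma_k))`).
#'
#' @param gamma Numeric vector of length `J - 1` (may be empty for `J = 1`).
#' @return Probability vector of length `J` (positive, sums to 1).
#' @examples
#' mixing_probs(c(0, 0))        # three equal groups
#' mixing_probs(log(2))         # (2/3, 1/3)
#' @export
mixing_probs <- function(gamma) {
  if (length(gamma) && any(!is.finite(gamma))) stopf("'gamma' must be finite")
  z <- c(gamma, 0)
  w <- exp(z - max(z))
  w / sum(w)
}

#' @rdname mixing_probs
#' @param pi Probability vector (positive, sums to 1).
#' @return `probs_to_logits()` returns the `gamma` vector reproducing `pi`.
#' @export
probs_to_logits <- function(pi) {
  if (any(pi <= 0) || abs(sum(pi) - 1) > 1e-8)
    stopf("'pi' must be strictly positive and sum to 1")
  J <- length(pi)
  log(pi[-J] / pi[J])
}

#' Flatten model parameters for the optimizer
#'
#' The layout is group-major and stable: for each group its `beta`
#' coefficients, then `log_phi`, then (if the spec has dropout) `delta`;
#' after all groups the `J - 1` mixing logits `gamma`.
#'
#' @param model A [mixture_model()].
#' @return `pack_params()`: a named numeric vector. `unpack_params()`: the
#'   [mixture_model()] it encodes.
#' @examples
#' sp <- trajectory_spec(1, order = 0)
#' m <- mixture_model(sp, list(list(beta = 0.2, log_phi = 1)))
#' pack_params(m)       # length 2: b0, log_phi
#' @export
pack_params <- function(model) {
  stopifnot(inherits(model, "mixture_model"))
  spec <- model$spec
  out <- numeric(0)
  for (j in seq_len(spec$J)) {
    g <- model$groups[[j]]
    v <- c(g$beta, g$log_phi, if (spec$dropout) g$delta)
    names(v) <- c(paste0("g", j, ".b", 0:spec$orders[j]),
                  paste0("g", j, ".logphi"),
                  if (spec$dropout) paste0("g", j, ".d", 0:spec$dropout_lags))
    out <- c(out, v)
  }
  if (spec$J > 1L) {
    g <- model$gamma
    names(g) <- paste0("gamma", seq_len(spec$J - 1L))
    out <- c(out, g)
  }
  out
}

#' @rdname pack_params
#' @param theta Flat parameter vector laid out as produced by `pack_params()`.
#' @param spec The [trajectory_spec()] fixing the layout.
#' @param tscale Time coding to attach to the rebuilt model.
#' @export
unpack_params <- function(theta, spec, tscale = c(0, 1)) {
  stopifnot(inherits(spec, "trajectory_spec"))
  need <- n_params_spec(spec)
  if (length(theta) != need)
    stopf("parameter vector has length %d but the structure needs %d",
          length(theta), need)
  pos <- 0L
  take <- function(k) {
    v <- theta[pos + seq_len(k)]
    pos <<- pos + k
    as.numeric(v)
  }
  groups <- vector("list", spec$J)
  for (j in seq_len(spec$J)) {
    beta <- take(spec$orders[j] + 1L)
    log_phi <- take(1L)
    delta <- if (spec$dropout) take(1L + spec$dropout_lags) else NULL
    groups[[j]] <- list(beta = beta, log_phi = log_phi, delta = delta)
  }
  gamma <- take(spec$J - 1L)
  mixture_model(spec, groups, gamma, tscale = tscale)
}

#' Rebase polynomial coefficients under an affine time recoding
#'
#' Given coefficients `coef` for a polynomial in `s = (t - origin)/scale`,
#' returns the coefficients of the identical polynomial in raw time `t`.
#' Used to report trajectory coefficients on the original time axis while the
#' optimizer works on times rescaled to `[0, 1]`.
#'
#' @param coef Coefficients in ascending powers of `s`.
#' @param origin,scale The affine coding.
#' @return Coefficients in ascending powers of `t`, same length.
#' @examples
#' poly_rebase(c(1, 2), origin = 10, scale = 2)  # 1 + 2(t-10)/2 = -9 + t
#' @export
poly_rebase <- function(coef, origin, scale) {
  p <- length(coef) - 1L
  out <- numeric(p + 1L)
  for (k in 0:p) {
    ck <- coef[k + 1L] / scale^k
    for (m in 0:k)
      out[m + 1L] <- out[m + 1L] + ck * choose(k, m) * (-origin)^(k - m)
  }
  out
}
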