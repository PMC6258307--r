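## Mixture log-likelihood.
##
## For subject i with observed occasions O_i, the group-j conditional
## log-likelihood is the sum over t in O_i of the beta log-density at
## (mu_jt, phi_j) — serial observations are conditionally independent given
## the group.  The subject log-likelihood is log sum_j pi_j exp(ll_ij),
## always assembled with log-sum-exp (per-group conditional terms reach large
## negative values at T ~ 13).  Intermittent missing values are ignored (MAR).
## With the dropout sub-model enabled, each group's conditional likelihood is
## multiplied (inside the mixture) by a discrete-time logistic hazard
## likelihood: at each occasion t >= 2 at which the subject is still under
## observation and the lagged outcome(s) are observed, the hazard
## h = plogis(delta_0 + delta_1 * y_{t-1} [+ delta_2 * y_{t-2}]) contributes
## log(1 - h) if the subject continues and log(h) at the dropout occasion.
## The first occasion carries no hazard term.

#' Group-conditional log-likelihood of one subject
#'
#' Sum of beta log-densities over the observed occasions of a single subject
#' under one group's trajectory, plus (optionally) that group's dropout-hazard
#' terms.
#'
#' @param y Outcome vector over the time grid (NA = unobserved).
#' @param times Time grid (same length as `y`).
#' @param beta Link-scale polynomial coefficients of the group mean curve.
#' @param phi Group precision (> 0).
#' @param link `"logit"` or `"identity"`.
#' @param delta Optional dropout-hazard coefficients (intercept then lag
#'   coefficient(s)); requires `dropout_occasion`.
#' @param dropout_occasion First occasion after the subject's last
#'   observation (`length(y) + 1` if followed to the end); only used with
#'   `delta`.
#' @return The scalar log-likelihood contribution.
#' @examples
#' group_conditional_loglik(c(0.5, NA), times = c(0, 1),
#'                          beta = c(0, 0), phi = 2)  # uniform: 0
#' @export
group_conditional_loglik <- function(y, times, beta, phi,
                                     link = c("logit", "identity"),
                                     delta = NULL, dropout_occasion = NULL) {
  link <- match.arg(link)
  obs <- which(is.finite(y))
  if (!length(obs)) stopf("subject has no observed occasions")
  mu <- mean_curve(beta, times[obs], link)
  ll <- sum(beta_logpdf_raw(y[obs], mu, phi))
  if (!is.null(delta)) {
    if (is.null(dropout_occasion))
      stopf("'dropout_occasion' is required when dropout coefficients are supplied")
    ll <- ll + dropout_loglik_terms(y, dropout_occasion, delta)
  }
  ll
}

#' Dropout-hazard log-likelihood terms for one subject
#'
#' Discrete-time logistic hazard on the occasion index: at each occasion
#' `t >= 2` with the subject still under observation and the lag(s) observed,
#' the hazard `plogis(delta[1] + delta[2]*y[t-1] [+ delta[3]*y[t-2]])`
#' contributes `log(1 - h)` for continuation and `log(h)` at the dropout
#' occasion. Occasions with a missing lag contribute nothing.
#'
#' @inheritParams group_conditional_loglik
#' @param delta Hazard coefficients: intercept followed by 1 or 2 lag
#'   coefficients.
#' @return Scalar sum of hazard log-terms (0 if no occasion qualifies).
#' @examples
#' # hazard 1/2 everywhere; dropout at occasion 2 of 3 -> log(0.5)
#' dropout_loglik_terms(c(0.4, NA, NA), dropout_occasion = 2, delta = c(0, 0))
#' @export
dropout_loglik_terms <- function(y, dropout_occasion, delta) {
  nlag <- length(delta) - 1L
  if (!nlag %in% c(1L, 2L)) stopf("'delta' must be (intercept, 1 or 2 lag coefficients)")
  Tn <- length(y)
  if (length(dropout_occasion) != 1L || dropout_occasion < 1 ||
      dropout_occasion > Tn + 1L)
    stopf("'dropout_occasion' must lie in 1..T+1")
  ll <- 0
  for (t in seq.int(1L + nlag, Tn)) {
    if (t > dropout_occasion) break
    lags <- y[t - seq_len(nlag)]
    if (any(!is.finite(lags))) next
    lin <- delta[1] + sum(delta[-1] * lags)
    ll <- ll + if (t == dropout_occasion)
      stats::plogis(lin, log.p = TRUE)
    else
      stats::plogis(-lin, log.p = TRUE)
  }
  ll
}

#' Subject-level mixture log-likelihood
#'
#' `log sum_j pi_j exp(ll_ij)` over the model's groups, computed with
#' log-sum-exp stabilization.
#'
#' @inheritParams group_conditional_loglik
#' @param model A [mixture_model()] (its `tscale` is applied to `times`).
#' @return Scalar log-likelihood of the subject.
#' @export
subject_loglik <- function(y, times, model, dropout_occasion = NULL) {
  stopifnot(inherits(model, "mixture_model"))
  spec <- model$spec
  if (spec$dropout && is.null(dropout_occasion))
    stopf("'dropout_occasion' is required for a model with dropout")
  s <- (times - model$tscale[1]) / model$tscale[2]
  lp <- log(mixing_probs(model$gamma))
  a <- vapply(seq_len(spec$J), function(j) {
    g <- model$groups[[j]]
    lp[j] + group_conditional_loglik(
      y, s, g$beta, exp(g$log_phi), spec$link,
      delta = if (spec$dropout) g$delta else NULL,
      dropout_occasion = dropout_occasion)
  }, numeric(1))
  logsumexp(a)
}

#' Panel log-likelihood
#'
#' Sum of [subject_loglik()] over the independent subjects of a panel.
#'
#' @param panel A [panel_data()] object.
#' @param model A [mixture_model()].
#' @return Scalar total log-likelihood (0, with a warning, for an empty
#'   panel).
#' @export
total_loglik <- function(panel, model) {
  stopifnot(inherits(panel, "gbtm_panel"))
  if (panel$N == 0L) {
    warnf("empty panel: log-likelihood is 0")
    return(0)
  }
  pm <- panel_matrices(panel, model$spec, tscale = model$tscale)
  sum(row_logsumexp(loglik_matrix_raw(pm, model) +
                      rep(log(mixing_probs(model$gamma)), each = panel$N)))
}

## ---------------------------------------------------------------------------
## Vectorized engine used by the optimizer.  panel_matrices() precomputes all
## data-dependent quantities once; loglik_matrix_raw() returns the N x J
## matrix of conditional log-likelihoods; make_objective() closes over the
## matrices and returns mean negative log-likelihood and its analytic
## gradient.

panel_matrices <- function(panel, spec, tscale = NULL) {
  Y <- panel$y
  M <- is.finite(Y) * 1
  Y0 <- ifelse(M == 1, Y, 0.5)             # placeholder; masked out below
  LY <- log(Y0) * M
  L1Y <- log1p(-Y0) * M
  if (is.null(tscale)) {
    rng <- range(panel$times)
    tscale <- if (diff(rng) > 0) c(rng[1], diff(rng)) else c(rng[1], 1)
  }
  s <- (panel$times - tscale[1]) / tscale[2]
  P <- poly_basis(s, max(spec$orders))
  dropcells <- NULL
  if (spec$dropout) {
    nlag <- spec$dropout_lags
    Tn <- panel$T
    if (Tn < nlag + 1L)
      stopf("dropout model needs at least %d occasions", nlag + 1L)
    cells <- list()
    for (t in seq.int(1L + nlag, Tn)) {
      atrisk <- panel$dropout_occasion >= t
      lag_ok <- M[, t - 1L] == 1
      if (nlag == 2L) lag_ok <- lag_ok & M[, t - 2L] == 1
      keep <- which(atrisk & lag_ok)
      if (!length(keep)) next
      cells[[length(cells) + 1L]] <- data.frame(
        i = keep,
        d = as.numeric(panel$dropout_occasion[keep] == t),
        y1 = Y[keep, t - 1L],
        y2 = if (nlag == 2L) Y[keep, t - 2L] else NA_real_)
    }
    dropcells <- if (length(cells)) do.call(rbind, cells) else
      data.frame(i = integer(0), d = numeric(0), y1 = numeric(0),
                 y2 = numeric(0))
  }
  list(Y = Y, M = M, LY = LY, L1Y = L1Y, s = s, P = P, tscale = tscale,
       N = panel$N, T = panel$T, dropcells = dropcells,
       n_obs = rowSums(M))
}

## hazard design matrix for the flattened risk cells
drop_design <- function(pm, nlag) {
  dc <- pm$dropcells
  if (nlag == 2L) cbind(1, dc$y1, dc$y2) else cbind(1, dc$y1)
}

## N x J matrix of conditional log-likelihoods (observation + dropout terms);
## returns NULL if an identity-link mean leaves (0,1).
loglik_matrix_raw <- function(pm, model) {
  spec <- model$spec
  N <- pm$N
  ll <- matrix(0, N, spec$J)
  X <- if (spec$dropout) drop_design(pm, spec$dropout_lags)
  for (j in seq_len(spec$J)) {
    g <- model$groups[[j]]
    eta <- drop(pm$P[, seq_len(spec$orders[j] + 1L), drop = FALSE] %*% g$beta)
    if (spec$link == "logit") {
      mu <- stats::plogis(eta)
      mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    } else {
      if (any(eta <= 0 | eta >= 1)) return(NULL)
      mu <- eta
    }
    phi <- exp(g$log_phi)
    a <- mu * phi
    b <- (1 - mu) * phi
    const <- lgamma(phi) - lgamma(a) - lgamma(b)
    ll[, j] <- drop(pm$M %*% const + pm$LY %*% (a - 1) + pm$L1Y %*% (b - 1))
    if (spec$dropout) {
      dc <- pm$dropcells
      if (nrow(dc)) {
        lin <- drop(X %*% g$delta)
        contrib <- ifelse(dc$d == 1,
                          stats::plogis(lin, log.p = TRUE),
                          stats::plogis(-lin, log.p = TRUE))
        agg <- rowsum(contrib, dc$i)
        ll[as.integer(rownames(agg)), j] <-
          ll[as.integer(rownames(agg)), j] + agg[, 1]
      }
    }
  }
  ll
}

## Objective closure: fn = -mean subject loglik, gr = analytic gradient,
## posterior(theta) = N x J posterior matrix, ll(theta) = total loglik.
make_objective <- function(panel, spec, tscale = NULL) {
  pm <- panel_matrices(panel, spec, tscale)
  N <- pm$N
  X <- if (spec$dropout) drop_design(pm, spec$dropout_lags)
  big <- 1e8

  eval_parts <- function(theta) {
    model <- unpack_params(theta, spec, tscale = pm$tscale)
    llm <- loglik_matrix_raw(pm, model)
    if (is.null(llm)) return(NULL)
    lpi <- log(mixing_probs(model$gamma))
    A <- llm + rep(lpi, each = N)
    si <- row_logsumexp(A)
    W <- exp(A - si)                       # posterior weights
    list(model = model, total = sum(si), W = W)
  }

  fn <- function(theta) {
    p <- eval_parts(theta)
    if (is.null(p) || !is.finite(p$total)) return(big)
    -p$total / N
  }

  gr <- function(theta) {
    p <- eval_parts(theta)
    if (is.null(p) || !is.finite(p$total)) return(rep(0, length(theta)))
    model <- p$model
    W <- p$W
    g <- numeric(length(theta))
    pos <- 0L
    for (j in seq_len(spec$J)) {
      gp <- model$groups[[j]]
      ord <- spec$orders[j]
      Pj <- pm$P[, seq_len(ord + 1L), drop = FALSE]
      eta <- drop(Pj %*% gp$beta)
      if (spec$link == "logit") {
        mu <- stats::plogis(eta)
        mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
        dmu <- mu * (1 - mu)
      } else {
        mu <- eta
        dmu <- rep(1, length(eta))
      }
      phi <- exp(gp$log_phi)
      a <- mu * phi
      b <- (1 - mu) * phi
      wj <- W[, j]
      ## per-occasion weighted sufficient statistics
      wM <- drop(crossprod(pm$M, wj))      # sum_i w_ij M_it
      wLY <- drop(crossprod(pm$LY, wj))
      wL1Y <- drop(crossprod(pm$L1Y, wj))
      Amu <- digamma(a) - digamma(b)
      ## d/d beta
      u <- phi * (wLY - wL1Y - Amu * wM) * dmu
      g[pos + seq_len(ord + 1L)] <- drop(crossprod(Pj, u))
      pos <- pos + ord + 1L
      ## d/d log phi
      cphi <- digamma(phi) - mu * digamma(a) - (1 - mu) * digamma(b)
      g[pos + 1L] <- phi * sum(cphi * wM + mu * wLY + (1 - mu) * wL1Y)
      pos <- pos + 1L
      if (spec$dropout) {
        dc <- pm$dropcells
        nd <- 1L + spec$dropout_lags
        if (nrow(dc)) {
          lin <- drop(X %*% gp$delta)
          h <- stats::plogis(lin)
          r <- wj[dc$i] * (dc$d - h)
          g[pos + seq_len(nd)] <- drop(crossprod(X, r))
        }
        pos <- pos + nd
      }
    }
    if (spec$J > 1L) {
      pi <- mixing_probs(model$gamma)
      cs <- colSums(W)
      g[pos + seq_len(spec$J - 1L)] <- cs[-spec$J] - N * pi[-spec$J]
    }
    -g / N
  }

  posterior <- function(theta) {
    p <- eval_parts(theta)
    if (is.null(p)) stopf("identity-link mean left (0,1) at the supplied parameters")
    p$W
  }

  ll <- function(theta) {
    p <- eval_parts(theta)
    if (is.null(p)) return(-Inf)
    p$total
  }

  list(fn = fn, gr = gr, posterior = posterior, ll = ll, pm = pm,
       tscale = pm$tscale, N = N)
}
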