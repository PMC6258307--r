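## Maximum-likelihood fitting: multi-start quasi-Newton (BFGS) on the mixture
## log-likelihood with an analytic gradient, canonical relabeling of groups,
## and standard errors from the inverse observed information matrix.

default_control <- function(control) {
  utils::modifyList(list(maxit = 500L, reltol = 1e-10, grad_tol = 1e-4,
                         replicate_tol = 1e-4), control)
}

## Deterministic start: slice subjects into J blocks by time-averaged outcome,
## fit crude per-block curves/precisions by least squares and moments.
init_deterministic <- function(panel, pm, spec) {
  N <- pm$N
  J <- spec$J
  ybar <- rowSums(pm$M * ifelse(pm$M == 1, panel$y, 0)) / pm$n_obs
  blocks <- if (J == 1L) rep(1L, N)
            else as.integer(cut(rank(ybar, ties.method = "first"),
                                breaks = J, labels = FALSE))
  groups <- vector("list", J)
  for (j in seq_len(J)) {
    idx <- which(blocks == j)
    Mj <- pm$M[idx, , drop = FALSE]
    Yj <- ifelse(Mj == 1, panel$y[idx, , drop = FALSE], 0)
    cnt <- colSums(Mj)
    mt <- ifelse(cnt > 0, colSums(Yj) / pmax(cnt, 1), mean(ybar[idx]))
    mt <- pmin(pmax(mt, 0.02), 0.98)
    eta <- if (spec$link == "logit") stats::qlogis(mt) else mt
    Pj <- pm$P[, seq_len(spec$orders[j] + 1L), drop = FALSE]
    w <- sqrt(pmax(cnt, 0))
    beta <- tryCatch(qr.solve(Pj * w, eta * w),
                     error = function(e) c(mean(eta),
                                           rep(0, spec$orders[j])))
    if (any(!is.finite(beta))) beta <- c(mean(eta), rep(0, spec$orders[j]))
    ## moment estimate of the precision: phi = m(1-m)/v - 1 per occasion
    vt <- vapply(seq_len(pm$T), function(t) {
      yo <- panel$y[idx, t][Mj[, t] == 1]
      if (length(yo) > 2) stats::var(yo) else NA_real_
    }, numeric(1))
    phit <- mt * (1 - mt) / vt - 1
    phit <- phit[is.finite(phit) & phit > 0]
    phi <- if (length(phit)) stats::median(phit) else 5
    phi <- min(max(phi, 0.3), 200)
    delta <- NULL
    if (spec$dropout) {
      docc <- panel$dropout_occasion[idx]
      rate <- sum(docc <= pm$T) / max(1, sum(pmin(docc, pm$T + 1) - 1))
      rate <- min(max(rate, 0.01), 0.5)
      delta <- c(stats::qlogis(rate), rep(0, spec$dropout_lags))
    }
    groups[[j]] <- list(beta = as.numeric(beta), log_phi = log(phi),
                        delta = delta)
  }
  gamma <- if (J > 1L) probs_to_logits(pmax(tabulate(blocks, J), 1) /
                                         sum(pmax(tabulate(blocks, J), 1)))
           else numeric(0)
  pack_params(mixture_model(spec, groups, gamma, tscale = pm$tscale))
}

jitter_start <- function(theta0, spec, seed) {
  with_seed(seed, {
    sd <- rep(0.4, length(theta0))
    nm <- names(theta0)
    sd[grepl("logphi", nm)] <- 0.3
    sd[grepl("^gamma", nm)] <- 0.3
    sd[grepl("\\.d[0-9]$", nm)] <- 0.3
    theta0 + stats::rnorm(length(theta0), 0, sd)
  })
}

## symmetric central-difference Jacobian of a gradient function -> Hessian
fd_jacobian <- function(g, x) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  for (k in seq_len(p)) {
    h <- 6e-6 * max(1, abs(x[k]))
    e <- numeric(p); e[k] <- h
    H[, k] <- (g(x + e) - g(x - e)) / (2 * h)
  }
  (H + t(H)) / 2
}

## permutation that orders groups by ascending time-averaged fitted mean
canonical_order <- function(model, s_grid) {
  avg <- vapply(seq_len(model$spec$J), function(j)
    mean(mean_curve(model$groups[[j]]$beta, s_grid, model$spec$link)),
    numeric(1))
  order(avg)
}

relabel_model <- function(model, perm) {
  pi <- mixing_probs(model$gamma)[perm]
  mixture_model(model$spec, model$groups[perm],
                if (model$spec$J > 1L) probs_to_logits(pi) else numeric(0),
                tscale = model$tscale)
}

#' Fit a beta group-based trajectory model to a panel
#'
#' Maximizes the mixture log-likelihood by multi-start BFGS with an analytic
#' gradient. Starts combine a deterministic one (subjects quantile-sliced by
#' time-averaged outcome into blocks, per-block least-squares curves and
#' moment precisions) with randomized perturbations of it. Groups in the
#' returned fit are relabeled in increasing order of time-averaged fitted
#' mean, so group 1 is always the lowest trajectory. Standard errors come
#' from the inverse observed information (negative Hessian by central finite
#' differences of the analytic gradient).
#'
#' @param panel A [panel_data()] object.
#' @param spec A [trajectory_spec()]; needs `T >= max(order) + 1` occasions.
#' @param n_starts Number of optimizer starts (>= 1).
#' @param seed Integer seed governing the randomized starts.
#' @param control List: `maxit`, `reltol` (BFGS), `grad_tol` (max abs
#'   per-subject gradient at the reported optimum), `replicate_tol` (relative
#'   log-likelihood tolerance for calling two starts replicates).
#' @param se Compute standard errors (set `FALSE` to skip the Hessian).
#' @return An object of class `"betagbtm"`; see [summary.betagbtm()].
#'   Key fields: `model` (internal, time rescaled to `[0,1]`), `coefficients`
#'   (per-group curve coefficients on the original time axis), `se`, `vcov`,
#'   `loglik`, `aic`, `bic`, `pi`, `posterior`, `converged`, `replicated`,
#'   `start_logliks`, `gradient_norm`.
#' @examples
#' cfg <- cohort_preset(n_subjects = 120, dropout = FALSE)
#' sim <- generate_panel(cfg, seed = 1)
#' fit <- fit_gbtm(sim$panel, trajectory_spec(3, order = 1),
#'                 n_starts = 2, seed = 1)
#' fit$pi
#' @export
fit_gbtm <- function(panel, spec, n_starts = 5L, seed = 1L,
                     control = list(), se = TRUE) {
  stopifnot(inherits(panel, "gbtm_panel"), inherits(spec, "trajectory_spec"))
  if (panel$T < max(spec$orders) + 1L)
    stopf("panel has %d occasions but the highest polynomial order needs %d",
          panel$T, max(spec$orders) + 1L)
  if (n_starts < 1L) stopf("'n_starts' must be >= 1")
  ctrl <- default_control(control)
  obj <- make_objective(panel, spec)
  theta0 <- init_deterministic(panel, obj$pm, spec)

  starts <- vector("list", n_starts)
  starts[[1L]] <- theta0
  if (n_starts > 1L)
    for (k in 2:n_starts)
      starts[[k]] <- jitter_start(theta0, spec, derive_seed(seed, k))

  runs <- lapply(starts, function(st) {
    tryCatch(stats::optim(st, obj$fn, obj$gr, method = "BFGS",
                          control = list(maxit = ctrl$maxit,
                                         reltol = ctrl$reltol)),
             error = function(e) list(error = conditionMessage(e)))
  })
  ok <- vapply(runs, function(r) is.null(r$error) && is.finite(r$value),
               logical(1))
  if (!any(ok)) {
    msgs <- vapply(runs, function(r) r$error %||% "non-finite objective",
                   character(1))
    stopf("all %d optimizer starts failed: %s", n_starts,
          paste(unique(msgs), collapse = "; "))
  }
  vals <- ifelse(ok, vapply(runs, function(r) r$value %||% Inf, numeric(1)),
                 Inf)
  best <- which.min(vals)
  theta <- runs[[best]]$par
  loglik <- obj$ll(theta)
  start_logliks <- ifelse(is.finite(vals), -vals * obj$N, NA_real_)
  replicated <- if (sum(ok) > 1L)
    any(abs(start_logliks[-best] - loglik) <
          ctrl$replicate_tol * max(1, abs(loglik)), na.rm = TRUE)
  else NA

  ## canonical relabeling: ascending time-averaged fitted mean
  model <- unpack_params(theta, spec, tscale = obj$tscale)
  perm <- canonical_order(model, obj$pm$s)
  model <- relabel_model(model, perm)
  theta <- pack_params(model)

  grad_norm <- max(abs(obj$gr(theta)))
  converged <- runs[[best]]$convergence == 0 && grad_norm < ctrl$grad_tol
  n_params <- length(theta)
  pi_hat <- mixing_probs(model$gamma)
  W <- obj$posterior(theta)
  ic <- information_criteria(loglik, n_params, panel$N)

  se_vec <- rep(NA_real_, n_params)
  vcov <- NULL
  if (se) {
    info <- obj$N * fd_jacobian(obj$gr, theta)   # observed information
    vcov <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(vcov)) {
      warnf("observed information matrix is singular; standard errors unavailable")
    } else {
      d <- diag(vcov)
      bad <- !is.finite(d) | d <= 0
      if (any(bad))
        warnf("observed information is not positive definite; %d standard error(s) unavailable",
              sum(bad))
      se_vec[!bad] <- sqrt(d[!bad])
      dimnames(vcov) <- list(names(theta), names(theta))
    }
  }
  names(se_vec) <- names(theta)

  ## report curve coefficients on the original time axis as well
  coef_orig <- lapply(model$groups, function(g)
    poly_rebase(g$beta, obj$tscale[1], obj$tscale[2]))

  structure(list(
    call = match.call(), spec = spec, panel = panel, model = model,
    theta = theta, coefficients = coef_orig, se = se_vec, vcov = vcov,
    loglik = loglik, n_params = n_params, n_subjects = panel$N,
    n_obs = sum(panel$n_obs), aic = ic[["aic"]], bic = ic[["bic"]],
    pi = pi_hat, posterior = W, converged = converged,
    replicated = replicated, n_starts_used = sum(ok),
    start_logliks = start_logliks, gradient_norm = grad_norm,
    tscale = obj$tscale, seed = seed), class = "betagbtm")
}

#' Standard errors from the observed information matrix
#'
#' Square roots of the diagonal of the inverse negative Hessian of the panel
#' log-likelihood at the supplied parameters (Hessian by central finite
#' differences of the analytic gradient, step scaled per parameter).
#'
#' @param panel A [panel_data()] object.
#' @param model A [mixture_model()] at (or near) an interior optimum.
#' @return Named vector of standard errors, `NA` where the information matrix
#'   is not positive definite (with a warning).
#' @export
standard_errors <- function(panel, model) {
  obj <- make_objective(panel, model$spec, tscale = model$tscale)
  theta <- pack_params(model)
  info <- obj$N * fd_jacobian(obj$gr, theta)
  se <- rep(NA_real_, length(theta))
  names(se) <- names(theta)
  vc <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(vc)) {
    warnf("observed information matrix is singular; standard errors unavailable")
    return(se)
  }
  d <- diag(vc)
  ok <- is.finite(d) & d > 0
  if (!all(ok))
    warnf("observed information not positive definite for %d parameter(s)",
          sum(!ok))
  se[ok] <- sqrt(d[ok])
  se
}

#' Posterior group-membership probabilities
#'
#' Bayes-rule posteriors `pi_j exp(ll_ij) / sum_k pi_k exp(ll_ik)` computed in
#' log space; each row sums to 1.
#'
#' @inheritParams standard_errors
#' @return `N x J` matrix of posterior probabilities.
#' @export
posterior_probs <- function(panel, model) {
  obj <- make_objective(panel, model$spec, tscale = model$tscale)
  obj$posterior(pack_params(model))
}
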