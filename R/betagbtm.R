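## User front end and S3 methods for the fitted model object.

#' Beta group-based trajectory model
#'
#' Fits a finite mixture of latent trajectory groups to a bounded continuous
#' longitudinal outcome. Each group j follows a polynomial mean trajectory on
#' the link scale with its own precision `phi_j`; observations are beta
#' distributed around the group mean, serially independent given group
#' membership; mixing proportions follow a multinomial logit. Exact 0/1
#' outcomes are moved off the boundary by `0.5 / N` before fitting. With
#' `dropout = TRUE`, a group-specific logistic hazard on the lagged outcome
#' accounts for non-random end of follow-up.
#'
#' @param data A long-format data frame (columns named by `id`, `time`,
#'   `value`; one row per subject-occasion, outcome in [0, 1]) or a
#'   [panel_data()] object.
#' @param groups Number of latent trajectory groups.
#' @param order Polynomial order(s) of the group mean trajectories.
#' @param link `"logit"` (default) or `"identity"`.
#' @param dropout Fit the dropout sub-model.
#' @param dropout_lags Lagged outcomes in the dropout hazard (1 or 2).
#' @param id,time,value Column names when `data` is a data frame.
#' @param n_starts,seed,control,se Passed to [fit_gbtm()].
#' @return An object of class `"betagbtm"`; see [fit_gbtm()] for fields and
#'   the `print`, `summary`, `coef`, `predict`, `plot`, `simulate`,
#'   `residuals` and `logLik` methods.
#' @examples
#' sim <- generate_panel(cohort_preset(n_subjects = 150, dropout = FALSE),
#'                       seed = 3)
#' fit <- betagbtm(sim$panel, groups = 3, order = 1, n_starts = 2, seed = 3)
#' fit
#' @export
betagbtm <- function(data, groups = 2L, order = 2L, link = "logit",
                     dropout = FALSE, dropout_lags = 1L,
                     id = "id", time = "time", value = "value",
                     n_starts = 5L, seed = 1L, control = list(), se = TRUE) {
  panel <- if (inherits(data, "gbtm_panel")) data
           else long_to_panel(as.data.frame(data), id = id, time = time,
                              value = value)
  spec <- trajectory_spec(groups, order = order, link = link,
                          dropout = dropout, dropout_lags = dropout_lags,
                          max_order = max(4L, max(order)))
  fit <- fit_gbtm(panel, spec, n_starts = n_starts, seed = seed,
                  control = control, se = se)
  fit$call <- match.call()
  fit
}

#' @export
print.betagbtm <- function(x, digits = 4, ...) {
  cat("Beta group-based trajectory model\n")
  cat(sprintf("  %d group(s), order(s) %s, %s link%s; N = %d subjects, %d observations\n",
              x$spec$J, paste(x$spec$orders, collapse = "/"), x$spec$link,
              if (x$spec$dropout) ", dropout sub-model" else "",
              x$n_subjects, x$n_obs))
  cat(sprintf("  logLik %.3f on %d parameters; AIC %.1f, BIC %.1f%s\n",
              x$loglik, x$n_params, x$aic, x$bic,
              if (!x$converged) "  [did not converge]" else ""))
  cat("  estimated group shares (%):",
      paste(format(100 * x$pi, digits = digits), collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a fitted beta trajectory mixture
#'
#' @param object A `"betagbtm"` fit.
#' @param ... Unused.
#' @return An object of class `"summary.betagbtm"` carrying a coefficient
#'   table (estimate, standard error, Wald z, p-value on the internal
#'   unit-time scale), mixing shares, precisions, classification quality
#'   (APP/OCC) and fit statistics.
#' @export
summary.betagbtm <- function(object, ...) {
  est <- object$theta
  se <- object$se
  z <- est / se
  ctab <- cbind(Estimate = est, `Std. Error` = se, `z value` = z,
                `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(fit = object, coef_table = ctab,
                 cq = classification_quality(object$posterior, object$pi)),
            class = "summary.betagbtm")
}

#' @export
print.summary.betagbtm <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f)
  cat("\nCoefficients (link scale, time rescaled to [0,1]):\n")
  stats::printCoefmat(x$coef_table, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE, na.print = "NA")
  cat(sprintf("\ntime coding: s = (t - %g) / %g; group precisions phi: %s\n",
              f$tscale[1], f$tscale[2],
              paste(format(vapply(f$model$groups,
                                  function(g) exp(g$log_phi), numeric(1)),
                           digits = digits), collapse = ", ")))
  cat("\nClassification quality:\n")
  print(x$cq, row.names = FALSE, digits = digits)
  invisible(x)
}

#' Extract trajectory coefficients
#'
#' @param object A `"betagbtm"` fit.
#' @param scale `"time"` for coefficients against raw time (default) or
#'   `"internal"` for the unit-rescaled basis the optimizer used.
#' @param ... Unused.
#' @return A list of per-group link-scale polynomial coefficient vectors.
#' @export
coef.betagbtm <- function(object, scale = c("time", "internal"), ...) {
  scale <- match.arg(scale)
  if (scale == "time") object$coefficients
  else lapply(object$model$groups, `[[`, "beta")
}

#' @export
logLik.betagbtm <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_subjects,
            class = "logLik")
}

#' @export
nobs.betagbtm <- function(object, ...) object$n_subjects

#' @export
vcov.betagbtm <- function(object, ...) object$vcov

#' Predicted group mean trajectories
#'
#' @param object A `"betagbtm"` fit.
#' @param times Times at which to evaluate (default: the panel grid).
#' @param type `"response"` for means in (0,1) or `"link"` for the linear
#'   predictor.
#' @param ... Unused.
#' @return A `length(times) x J` matrix of group means.
#' @export
predict.betagbtm <- function(object, times = NULL,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  times <- times %||% object$panel$times
  s <- (times - object$tscale[1]) / object$tscale[2]
  out <- vapply(seq_len(object$spec$J), function(j) {
    beta <- object$model$groups[[j]]$beta
    eta <- drop(poly_basis(s, length(beta) - 1L) %*% beta)
    if (type == "link" || object$spec$link == "identity") eta
    else stats::plogis(eta)
  }, numeric(length(times)))
  out <- matrix(out, nrow = length(times))
  dimnames(out) <- list(NULL, paste0("group", seq_len(object$spec$J)))
  out
}

#' @export
fitted.betagbtm <- function(object, ...) {
  ## posterior-weighted expected outcome per subject-occasion
  mu <- predict(object)                       # T x J
  object$posterior %*% t(mu)
}

#' Randomized quantile residuals
#'
#' For each observed cell, the mixture CDF
#' `F(y_it) = sum_j w_ij pbeta(y_it; mu_jt, phi_j)` (weighted by the subject's
#' posterior) is mapped through the standard normal quantile. Under a correct
#' model these are approximately standard normal.
#'
#' @param object A `"betagbtm"` fit.
#' @param ... Unused.
#' @return An `N x T` matrix of residuals (`NA` where unobserved).
#' @export
residuals.betagbtm <- function(object, ...) {
  panel <- object$panel
  J <- object$spec$J
  mu <- predict(object)                       # T x J
  phi <- vapply(object$model$groups, function(g) exp(g$log_phi), numeric(1))
  r <- matrix(NA_real_, panel$N, panel$T)
  for (t in seq_len(panel$T)) {
    obs <- which(is.finite(panel$y[, t]))
    if (!length(obs)) next
    Fm <- matrix(0, length(obs), J)
    for (j in seq_len(J))
      Fm[, j] <- stats::pbeta(panel$y[obs, t], mu[t, j] * phi[j],
                              (1 - mu[t, j]) * phi[j])
    u <- rowSums(object$posterior[obs, , drop = FALSE] * Fm)
    r[obs, t] <- stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
  }
  r
}

#' Simulate panels from a fitted model
#'
#' Draws new panels from the fitted mixture (and, if fitted, the dropout
#' sub-model) at the original time grid and cohort size.
#'
#' @param object A `"betagbtm"` fit.
#' @param nsim Number of panels.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `nsim` results from [generate_panel()].
#' @export
simulate.betagbtm <- function(object, nsim = 1, seed = 1L, ...) {
  cfg <- synth_config(
    n_subjects = object$n_subjects, times = object$panel$times,
    weights = object$pi,
    coefs = lapply(object$model$groups, `[[`, "beta"),
    phi = vapply(object$model$groups, function(g) exp(g$log_phi), numeric(1)),
    delta = if (object$spec$dropout)
      lapply(object$model$groups, `[[`, "delta") else NULL,
    link = object$spec$link, seed = seed)
  lapply(seq_len(nsim), function(k) generate_panel(cfg, derive_seed(seed, k)))
}

#' Plot a fitted beta trajectory mixture
#'
#' `type = "trajectories"` draws the fitted group mean curves with pointwise
#' confidence bands; `type = "density"` draws the observed-vs-predicted
#' density overlay of [density_overlay()] for one group and occasion.
#'
#' @param x A `"betagbtm"` fit.
#' @param type `"trajectories"` or `"density"`.
#' @param occasion,group For `type = "density"`.
#' @param ... Passed to the underlying plotting calls.
#' @return `x`, invisibly.
#' @export
plot.betagbtm <- function(x, type = c("trajectories", "density"),
                          occasion = 1L, group = 1L, ...) {
  type <- match.arg(type)
  if (type == "trajectories") {
    tt <- trajectory_table(x, times = seq(min(x$panel$times),
                                          max(x$panel$times),
                                          length.out = 101))
    graphics::plot(NULL, xlim = range(tt$time), ylim = c(0, 1),
                   xlab = "time", ylab = "group mean outcome", ...)
    for (j in seq_len(x$spec$J)) {
      d <- tt[tt$group == j, ]
      if (all(is.finite(d$lower)))
        graphics::polygon(c(d$time, rev(d$time)), c(d$lower, rev(d$upper)),
                          col = grDevices::adjustcolor(j, 0.2), border = NA)
      graphics::lines(d$time, d$mean, col = j, lwd = 2)
    }
    graphics::legend("topright",
                     legend = sprintf("group %d (%.1f%%)", seq_len(x$spec$J),
                                      100 * x$pi),
                     col = seq_len(x$spec$J), lwd = 2, bty = "n")
  } else {
    ov <- density_overlay(x, occasion, group)
    mids <- (ov$breaks[-1] + ov$breaks[-length(ov$breaks)]) / 2
    graphics::plot(mids, ov$density, type = "h", lwd = 8, col = "grey70",
                   lend = 1, xlab = "outcome",
                   ylab = "relative frequency density",
                   ylim = c(0, max(ov$density,
                                   ov$curve_y[is.finite(ov$curve_y)])), ...)
    graphics::lines(ov$curve_x, ov$curve_y, col = 2, lwd = 2)
    graphics::legend("topright",
                     legend = c("observed", sprintf("Beta(%.2f, %.2f)",
                                                    ov$mu, ov$phi)),
                     col = c("grey70", 2), lwd = c(8, 2), bty = "n")
  }
  invisible(x)
}
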