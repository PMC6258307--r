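## Model selection: information criteria across candidate numbers of groups,
## and backward pruning of polynomial orders by Wald significance of the
## highest-order term.

#' Information criteria for a fitted mixture
#'
#' `AIC = 2k - 2*loglik`; `BIC = k*log(N) - 2*loglik` with `N` the number of
#' subjects — subjects, not observations, are the independent units of the
#' mixture likelihood (a different `N` can be supplied).
#'
#' @param loglik Maximized log-likelihood.
#' @param n_params Number of free parameters `k >= 1`.
#' @param n_subjects Sample size `N >= 1` used in the BIC penalty.
#' @return Named vector `c(aic = , bic = )`.
#' @examples
#' information_criteria(-100, 5, 50)
#' @export
information_criteria <- function(loglik, n_params, n_subjects) {
  if (n_params < 1) stopf("'n_params' must be >= 1")
  if (n_subjects < 1) stopf("'n_subjects' must be >= 1")
  c(aic = 2 * n_params - 2 * loglik,
    bic = n_params * log(n_subjects) - 2 * loglik)
}

#' Sweep over candidate numbers of trajectory groups
#'
#' Fits one model per candidate `J` and tabulates log-likelihood, parameter
#' count, AIC and BIC. Both criteria's choices are reported; disagreement is
#' flagged, never silently resolved. A fit whose best-of-starts log-likelihood
#' is not replicated by any other start is marked unstable.
#'
#' @param panel A [panel_data()] object.
#' @param j_range Integer vector of candidate group numbers.
#' @param order Polynomial order used for every group during the sweep.
#' @param link,dropout,dropout_lags Passed to [trajectory_spec()].
#' @param n_starts,seed,control Passed to [fit_gbtm()].
#' @return An object of class `"gbtm_sweep"`: list with `table` (one row per
#'   candidate), `selected_bic`, `selected_aic`, `agree`, and `fits` (the
#'   fitted objects, named by J).
#' @examples
#' cfg <- cohort_preset(n_subjects = 100, dropout = FALSE)
#' sim <- generate_panel(cfg, seed = 2)
#' sw <- sweep_groups(sim$panel, j_range = 1:2, order = 1,
#'                    n_starts = 2, seed = 2)
#' sw$selected_bic
#' @export
sweep_groups <- function(panel, j_range, order = 2, link = "logit",
                         dropout = FALSE, dropout_lags = 1L,
                         n_starts = 3L, seed = 1L, control = list()) {
  if (!length(j_range)) stopf("'j_range' must be nonempty")
  j_range <- sort(unique(as.integer(j_range)))
  fits <- list()
  rows <- list()
  for (J in j_range) {
    key <- as.character(J)
    res <- tryCatch(
      fit_gbtm(panel, trajectory_spec(J, order = order, link = link,
                                      dropout = dropout,
                                      dropout_lags = dropout_lags),
               n_starts = n_starts, seed = derive_seed(seed, J),
               control = control, se = FALSE),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[key]] <- data.frame(J = J, loglik = NA_real_, k = NA_integer_,
                                aic = NA_real_, bic = NA_real_,
                                converged = FALSE, unstable = NA,
                                error = conditionMessage(res))
      next
    }
    fits[[key]] <- res
    rows[[key]] <- data.frame(J = J, loglik = res$loglik, k = res$n_params,
                              aic = res$aic, bic = res$bic,
                              converged = res$converged,
                              unstable = isFALSE(res$replicated),
                              error = NA_character_)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  sel_bic <- if (any(is.finite(tab$bic))) tab$J[which.min(tab$bic)] else NA
  sel_aic <- if (any(is.finite(tab$aic))) tab$J[which.min(tab$aic)] else NA
  structure(list(table = tab, selected_bic = sel_bic, selected_aic = sel_aic,
                 agree = isTRUE(sel_bic == sel_aic), fits = fits),
            class = "gbtm_sweep")
}

#' @export
print.gbtm_sweep <- function(x, ...) {
  cat("Group-number sweep\n")
  print(x$table[, c("J", "loglik", "k", "aic", "bic", "converged", "unstable")],
        row.names = FALSE)
  cat(sprintf("selected: BIC -> J = %s, AIC -> J = %s%s\n",
              x$selected_bic, x$selected_aic,
              if (!x$agree) "  (criteria disagree)" else ""))
  invisible(x)
}

#' Backward pruning of polynomial orders
#'
#' All groups start at `max_order`. At each step the fitted model's
#' highest-order coefficient is Wald-tested (z = estimate/se against the
#' standard normal) in every group; the group with the largest p-value above
#' `alpha` has its order reduced by one and the model is refitted. Pruning
#' stops when every group's top coefficient is significant or has reached
#' order 0. One order is removed per refit because removing a term changes
#' the remaining coefficients' significance.
#'
#' @param panel A [panel_data()] object.
#' @param J Number of trajectory groups.
#' @param max_order Starting polynomial order for every group.
#' @param alpha Significance level for the Wald test (default 0.05).
#' @param link,dropout,dropout_lags Passed to [trajectory_spec()].
#' @param n_starts,seed,control Passed to [fit_gbtm()].
#' @return An object of class `"gbtm_prune"`: list with `orders` (final
#'   per-group orders), `fit` (final [fit_gbtm()] object), and `path`
#'   (data frame logging each pruning step: the group pruned, the order
#'   removed, its Wald p-value and the log-likelihood before removal).
#' @export
prune_polynomials <- function(panel, J, max_order = 3L, alpha = 0.05,
                              link = "logit", dropout = FALSE,
                              dropout_lags = 1L, n_starts = 3L, seed = 1L,
                              control = list()) {
  if (alpha <= 0 || alpha >= 1) stopf("'alpha' must lie in (0, 1)")
  orders <- rep(as.integer(max_order), J)
  path <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    spec <- trajectory_spec(J, order = orders, link = link, dropout = dropout,
                            dropout_lags = dropout_lags,
                            max_order = max_order)
    fit <- fit_gbtm(panel, spec, n_starts = n_starts,
                    seed = derive_seed(seed, step), control = control)
    pvals <- rep(NA_real_, J)
    for (j in seq_len(J)) {
      if (orders[j] == 0L) next                  # never prune the intercept
      nm <- sprintf("g%d.b%d", j, orders[j])
      est <- fit$theta[[nm]]
      s <- fit$se[[nm]]
      if (!is.finite(s) || s <= 0)
        stopf("standard error unavailable for %s; pruning halted (see fit diagnostics)", nm)
      pvals[j] <- 2 * stats::pnorm(-abs(est / s))
    }
    cand <- which(is.finite(pvals) & pvals > alpha)
    if (!length(cand)) {
      pathdf <- if (length(path)) do.call(rbind, path) else
        data.frame(step = integer(0), group = integer(0),
                   order_removed = integer(0), p_value = numeric(0),
                   loglik = numeric(0))
      return(structure(list(orders = orders, fit = fit, path = pathdf,
                            alpha = alpha),
                       class = "gbtm_prune"))
    }
    g <- cand[which.max(pvals[cand])]
    path[[step]] <- data.frame(step = step, group = g,
                               order_removed = orders[g],
                               p_value = pvals[g], loglik = fit$loglik)
    orders[g] <- orders[g] - 1L
  }
}

#' @export
print.gbtm_prune <- function(x, ...) {
  cat(sprintf("Polynomial pruning (alpha = %.3g): final orders (%s)\n",
              x$alpha, paste(x$orders, collapse = ", ")))
  if (nrow(x$path)) {
    cat("pruning path:\n")
    print(x$path, row.names = FALSE)
  } else cat("no terms pruned\n")
  invisible(x)
}
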