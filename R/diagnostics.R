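## Fit-adequacy diagnostics: observed-vs-predicted density overlays at a
## measurement occasion, fitted trajectory tables with delta-method bands,
## and posterior-classification quality (APP / OCC).

#' Observed-vs-predicted density overlay for one group at one occasion
#'
#' Builds a relative-frequency density histogram of the outcomes observed at
#' one occasion, weighting each subject by its posterior probability of the
#' group (soft assignment; `assignment = "modal"` uses hard classification),
#' normalized so that sum(height * width) = 1, and pairs it with the fitted
#' beta density at that occasion's group mean and the group precision. Both
#' are returned as plain numeric vectors so any plotting backend can draw
#' them.
#'
#' @param fit A [fit_gbtm()] / [betagbtm()] object.
#' @param occasion Occasion index (column of the panel's time grid).
#' @param group Group index in `1..J`.
#' @param n_bins Number of equal-width histogram bins on [0, 1].
#' @param assignment `"posterior"` (soft weights, default) or `"modal"`.
#' @return List with `breaks` (length `n_bins + 1`), `density` (bin heights),
#'   `curve_x`, `curve_y` (fitted beta density on a fine grid), `mu`, `phi`,
#'   `time`, and `weight_total`.
#' @export
density_overlay <- function(fit, occasion, group, n_bins = 20L,
                            assignment = c("posterior", "modal")) {
  stopifnot(inherits(fit, "betagbtm"))
  assignment <- match.arg(assignment)
  panel <- fit$panel
  if (occasion < 1 || occasion > panel$T)
    stopf("'occasion' must index the time grid (1..%d)", panel$T)
  if (group < 1 || group > fit$spec$J)
    stopf("'group' must lie in 1..%d", fit$spec$J)
  y <- panel$y[, occasion]
  obs <- which(is.finite(y))
  if (!length(obs)) stopf("no observed data at occasion %d", occasion)
  w <- if (assignment == "posterior") fit$posterior[obs, group]
       else as.numeric(max.col(fit$posterior[obs, , drop = FALSE],
                               ties.method = "first") == group)
  if (sum(w) <= 0)
    stopf("no subjects carry weight for group %d at occasion %d", group, occasion)
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  width <- 1 / n_bins
  bin <- pmin(pmax(ceiling(y[obs] / width), 1L), n_bins)
  height <- numeric(n_bins)
  agg <- rowsum(w, bin)
  height[as.integer(rownames(agg))] <- agg[, 1]
  height <- height / (sum(w) * width)       # sum(height * width) = 1
  mu <- model_mean_curve(fit$model, group, panel$times[occasion])
  phi <- exp(fit$model$groups[[group]]$log_phi)
  curve_x <- seq(width / 20, 1 - width / 20, length.out = 400L)
  list(breaks = breaks, density = height,
       curve_x = curve_x, curve_y = dbeta_mp(curve_x, mu, phi),
       mu = mu, phi = phi, time = panel$times[occasion],
       weight_total = sum(w))
}

#' Fitted trajectory table with confidence bands
#'
#' Per-group fitted mean curves at requested times, with pointwise delta
#' method bands (normal interval on the link scale mapped through the inverse
#' link) and estimated membership percentages `100 * pi_hat`.
#'
#' @param fit A fitted `"betagbtm"` object.
#' @param times Times at which to evaluate the curves (default: the panel
#'   grid).
#' @param level Confidence level for the bands.
#' @return Data frame with columns `group`, `time`, `mean`, `lower`, `upper`
#'   and `share_pct`; bands are `NA` (with a warning) when the covariance
#'   matrix is unavailable.
#' @export
trajectory_table <- function(fit, times = NULL, level = 0.95) {
  stopifnot(inherits(fit, "betagbtm"))
  times <- times %||% fit$panel$times
  s <- (times - fit$tscale[1]) / fit$tscale[2]
  z <- stats::qnorm(1 - (1 - level) / 2)
  have_vcov <- !is.null(fit$vcov)
  if (!have_vcov) warnf("covariance matrix unavailable; bands omitted")
  out <- list()
  for (j in seq_len(fit$spec$J)) {
    beta <- fit$model$groups[[j]]$beta
    Pj <- poly_basis(s, length(beta) - 1L)
    eta <- drop(Pj %*% beta)
    lo <- hi <- rep(NA_real_, length(eta))
    if (have_vcov) {
      nm <- paste0("g", j, ".b", seq_along(beta) - 1L)
      V <- fit$vcov[nm, nm, drop = FALSE]
      se_eta <- sqrt(pmax(rowSums((Pj %*% V) * Pj), 0))
      lo <- eta - z * se_eta
      hi <- eta + z * se_eta
    }
    if (fit$spec$link == "logit") {
      mean_j <- stats::plogis(eta); lo <- stats::plogis(lo); hi <- stats::plogis(hi)
    } else {
      mean_j <- eta
    }
    out[[j]] <- data.frame(group = j, time = times, mean = mean_j,
                           lower = lo, upper = hi,
                           share_pct = 100 * fit$pi[j])
  }
  do.call(rbind, out)
}

#' Posterior-classification quality (APP and OCC)
#'
#' Average posterior probability of assignment: `APP_j` is the mean of the
#' row-maximum posterior probability among subjects modally assigned to group
#' j. Odds of correct classification:
#' `OCC_j = [APP_j / (1 - APP_j)] / [pi_j / (1 - pi_j)]`; values well above 1
#' (conventionally above 5) indicate that the posterior sharpens assignment
#' far beyond the marginal shares.
#'
#' @param posterior `N x J` posterior-probability matrix (rows sum to 1).
#' @param pi Estimated mixing proportions (length J).
#' @return Data frame with columns `group`, `n_assigned`, `app`, `occ`,
#'   `pi`; groups with no assigned subjects get `NA` metrics and a warning.
#' @examples
#' post <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.95, 0.05))
#' classification_quality(post, pi = c(0.6, 0.4))
#' @export
classification_quality <- function(posterior, pi) {
  posterior <- as.matrix(posterior)
  J <- ncol(posterior)
  if (length(pi) != J) stopf("'pi' must have one entry per posterior column")
  if (any(abs(rowSums(posterior) - 1) > 1e-6))
    stopf("posterior rows must sum to 1")
  assigned <- max.col(posterior, ties.method = "first")
  pmax_i <- posterior[cbind(seq_len(nrow(posterior)), assigned)]
  app <- occ <- rep(NA_real_, J)
  n_assigned <- tabulate(assigned, J)
  for (j in seq_len(J)) {
    if (n_assigned[j] == 0L) next
    app[j] <- mean(pmax_i[assigned == j])
    occ[j] <- (app[j] / (1 - app[j])) / (pi[j] / (1 - pi[j]))
  }
  if (any(n_assigned == 0L))
    warnf("group(s) %s have no modally assigned subjects; APP/OCC undefined",
          paste(which(n_assigned == 0L), collapse = ", "))
  data.frame(group = seq_len(J), n_assigned = n_assigned, app = app,
             occ = occ, pi = pi)
}
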