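test_that("analytic gradient matches central finite differences", {
  cfg <- cohort_preset(n_subjects = 60, dropout = TRUE)
  sim <- generate_panel(cfg, seed = 14)
  for (spec in list(trajectory_spec(3, order = c(2, 1, 0), dropout = TRUE),
                    trajectory_spec(2, order = 2),
                    trajectory_spec(1, order = 1))) {
    obj <- betagbtm:::make_objective(sim$panel, spec)
    theta <- pack_params(random_model(spec, 15, tscale = obj$tscale))
    g <- obj$gr(theta)
    gn <- vapply(seq_along(theta), function(k) {
      h <- 1e-6 * max(1, abs(theta[k]))
      e <- replace(numeric(length(theta)), k, h)
      (obj$fn(theta + e) - obj$fn(theta - e)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - gn)), 1e-6)
  }
})

test_that("a single-group constant model recovers its mean and precision", {
  p <- const_panel(200, 10, mu = 0.7, phi = 10, seed = 16)
  f <- fit_gbtm(p, trajectory_spec(1, order = 0), n_starts = 2, seed = 1)
  expect_true(f$converged)
  expect_equal(plogis(f$theta[["g1.b0"]]), 0.7, tolerance = 0.02)
  expect_equal(exp(f$theta[["g1.logphi"]]), 10, tolerance = 0.15 * 10)
})

test_that("refitting from the generating truth cannot beat the optimum", {
  cfg <- cohort_preset(n_subjects = 200, dropout = FALSE)
  sim <- generate_panel(cfg, seed = 17)
  spec <- trajectory_spec(3, order = 1)
  f <- fit_gbtm(sim$panel, spec, n_starts = 3, seed = 2, se = FALSE)
  ## truth model on the internal unit-time basis (orders padded to the spec)
  truth <- mixture_model(spec, list(
    list(beta = c(cfg$coefs[[1]], 0), log_phi = log(cfg$phi[1])),
    list(beta = cfg$coefs[[2]], log_phi = log(cfg$phi[2])),
    list(beta = c(cfg$coefs[[3]], 0), log_phi = log(cfg$phi[3]))),
    gamma = probs_to_logits(cfg$weights), tscale = f$tscale)
  ll_truth <- total_loglik(sim$panel, truth)
  expect_gte(f$loglik, ll_truth - 1e-6)
  ## and the optimum dominates every recorded start's final value
  expect_true(all(f$start_logliks <= f$loglik + 1e-6, na.rm = TRUE))
})

test_that("groups come back in canonical order regardless of start labeling", {
  cfg <- cohort_preset(n_subjects = 150, dropout = FALSE)
  sim <- generate_panel(cfg, seed = 18)
  f1 <- fit_gbtm(sim$panel, trajectory_spec(3, order = 1), n_starts = 2,
                 seed = 5, se = FALSE)
  f2 <- fit_gbtm(sim$panel, trajectory_spec(3, order = 1), n_starts = 4,
                 seed = 99, se = FALSE)
  avg1 <- colMeans(predict(f1))
  expect_true(all(diff(avg1) > 0))                 # ascending mean trajectories
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-5)
  expect_equal(f1$pi, f2$pi, tolerance = 1e-3)
})

test_that("posterior probabilities are proper and sharpen with separation", {
  cfg <- cohort_preset(n_subjects = 150, dropout = FALSE)
  sim <- generate_panel(cfg, seed = 19)
  f <- fit_gbtm(sim$panel, trajectory_spec(3, order = 1), n_starts = 2,
                seed = 6, se = FALSE)
  expect_lt(max(abs(rowSums(f$posterior) - 1)), 1e-10)
  expect_gt(mean(apply(f$posterior, 1, max)), 0.9)  # well-separated preset
  ## J = 1: all ones
  f1 <- fit_gbtm(sim$panel, trajectory_spec(1, order = 1), n_starts = 1,
                 seed = 1, se = FALSE)
  expect_equal(unname(f1$posterior), matrix(1, sim$panel$N, 1))
  ## equidistant subject under equal mixing: uniform posterior row
  spec2 <- trajectory_spec(2, order = 0)
  m2 <- mixture_model(spec2, list(list(beta = qlogis(0.3), log_phi = log(4)),
                                  list(beta = qlogis(0.7), log_phi = log(4))),
                      gamma = 0)
  peq <- panel_data(matrix(0.5, 1, 3), times = 0:2, adjust = FALSE)
  expect_equal(drop(posterior_probs(peq, m2)), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("standard errors are permutation-invariant and track information", {
  p <- const_panel(150, 6, mu = 0.6, phi = 8, seed = 20)
  f <- fit_gbtm(p, trajectory_spec(1, order = 0), n_starts = 1, seed = 1)
  perm <- sample(p$N)
  p2 <- panel_data(p$y[perm, ], p$times, adjust = FALSE)
  f2 <- fit_gbtm(p2, trajectory_spec(1, order = 0), n_starts = 1, seed = 1)
  expect_equal(f$se, f2$se, tolerance = 1e-6)
  ## flatter likelihood (small phi) gives wider precision standard errors
  pflat <- const_panel(150, 6, mu = 0.6, phi = 0.8, seed = 21)
  fflat <- fit_gbtm(pflat, trajectory_spec(1, order = 0), n_starts = 1, seed = 1)
  expect_gt(fflat$se[["g1.b0"]], f$se[["g1.b0"]])
})

test_that("estimates are invariant to affine recoding of the time axis", {
  cfg <- cohort_preset(n_subjects = 120, dropout = FALSE)
  sim <- generate_panel(cfg, seed = 22)
  f1 <- fit_gbtm(sim$panel, trajectory_spec(3, order = 1), n_starts = 2,
                 seed = 7, se = FALSE)
  p2 <- panel_data(sim$panel$y, 2 * sim$panel$times + 5, adjust = FALSE)
  f2 <- fit_gbtm(p2, trajectory_spec(3, order = 1), n_starts = 2,
                 seed = 7, se = FALSE)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-5)
  expect_equal(f1$pi, f2$pi, tolerance = 1e-4)
  ## curves agree at matched raw times after back-transforming coefficients
  t1 <- seq(0, 48, length.out = 7)
  mu1 <- vapply(1:3, function(j)
    plogis(drop(outer(t1, 0:1, `^`) %*% coef(f1)[[j]])), numeric(7))
  mu2 <- vapply(1:3, function(j)
    plogis(drop(outer(2 * t1 + 5, 0:1, `^`) %*% coef(f2)[[j]])), numeric(7))
  expect_equal(mu1, mu2, tolerance = 1e-3)
})

test_that("aic and bic follow their defining formulas", {
  p <- const_panel(80, 5, mu = 0.5, phi = 5, seed = 23)
  f <- fit_gbtm(p, trajectory_spec(1, order = 1), n_starts = 1, seed = 1,
                se = FALSE)
  expect_equal(f$aic, 2 * f$n_params - 2 * f$loglik)
  expect_equal(f$bic, f$n_params * log(f$n_subjects) - 2 * f$loglik)
  expect_equal(AIC(f), f$aic)
  expect_equal(BIC(f), f$bic)
})
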