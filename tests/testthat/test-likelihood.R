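test_that("group-conditional log-likelihood sums beta log-densities over observed occasions", {
  ## uniform case: one observed occasion contributes exactly 0
  expect_equal(group_conditional_loglik(c(0.37, NA), c(0, 1),
                                        beta = c(0, 0), phi = 2), 0)
  ## additivity and brute-force agreement
  set.seed(8)
  times <- seq(0, 1, length.out = 6)
  beta <- c(-0.5, 1.2, -0.6)
  phi <- 3.5
  y <- runif(6, 0.05, 0.95)
  y[4] <- NA
  ll <- group_conditional_loglik(y, times, beta, phi)
  brute <- sum(vapply(which(is.finite(y)), function(t)
    dbeta_mp(y[t], mean_curve(beta, times[t]), phi, log = TRUE), numeric(1)))
  expect_equal(ll, brute, tolerance = 1e-12)
  ## two-occasion additivity
  one <- function(t) group_conditional_loglik(replace(rep(NA_real_, 6), t, y[t]),
                                              times, beta, phi)
  expect_equal(one(1) + one(2),
               group_conditional_loglik(replace(y, 3:6, NA), times, beta, phi),
               tolerance = 1e-12)
  expect_error(group_conditional_loglik(rep(NA_real_, 3), 0:2, c(0), 1),
               "no observed")
})

test_that("subject likelihood is the stabilized mixture of group likelihoods", {
  times <- seq(0, 1, length.out = 5)
  sp1 <- trajectory_spec(1, order = 1)
  m1 <- random_model(sp1, 2)
  y <- rbeta_mp(5, 0.5, 3, seed = 2)
  expect_equal(subject_loglik(y, times, m1),
               group_conditional_loglik(y, times, m1$groups[[1]]$beta,
                                        exp(m1$groups[[1]]$log_phi)))
  ## epsilon-mixture limit: pi -> (1, 0) recovers group 1
  sp2 <- trajectory_spec(2, order = 1)
  m2 <- random_model(sp2, 3)
  m2eps <- mixture_model(sp2, m2$groups, gamma = 40)
  expect_equal(subject_loglik(y, times, m2eps),
               group_conditional_loglik(y, times, m2$groups[[1]]$beta,
                                        exp(m2$groups[[1]]$log_phi)),
               tolerance = 1e-10)
  ## direct (unstabilized) mixture sum as oracle, randomized
  sp3 <- trajectory_spec(3, order = c(2, 1, 1))
  for (seed in 1:20) {
    m3 <- random_model(sp3, seed)
    yy <- rbeta_mp(5, 0.4, 2, seed = seed)
    pi <- mixing_probs(m3$gamma)
    direct <- log(sum(vapply(1:3, function(j) {
      mu_j <- mean_curve(m3$groups[[j]]$beta, times)
      phi_j <- exp(m3$groups[[j]]$log_phi)
      pi[j] * prod(dbeta(yy, mu_j * phi_j, (1 - mu_j) * phi_j))
    }, numeric(1))))
    expect_equal(subject_loglik(yy, times, m3), direct, tolerance = 1e-10)
  }
})

test_that("panel likelihood is exchangeable over subjects and label permutations", {
  cfg <- cohort_preset(n_subjects = 40, dropout = FALSE)
  sim <- generate_panel(cfg, seed = 9)
  spec <- trajectory_spec(3, order = 1)
  m <- random_model(spec, 4)
  ## keep shapes > 1 so densities vanish at the boundaries (direction check below)
  m$groups <- lapply(m$groups, function(g) { g$log_phi <- log(8); g })
  ll <- total_loglik(sim$panel, m)
  expect_true(is.finite(ll))
  ## subject permutation
  perm <- sample(sim$panel$N)
  p2 <- panel_data(sim$panel$y[perm, ], sim$panel$times, adjust = FALSE)
  expect_equal(total_loglik(p2, m), ll, tolerance = 1e-12)
  ## label-switching symmetry: permute groups and remap gamma
  pi <- mixing_probs(m$gamma)
  for (gperm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    mp <- mixture_model(spec, m$groups[gperm], probs_to_logits(pi[gperm]))
    expect_equal(total_loglik(sim$panel, mp), ll, tolerance = 1e-10)
  }
  ## moving an observation away from all group means lowers the likelihood
  mu_occ1 <- vapply(1:3, function(j)
    mean_curve(m$groups[[j]]$beta, sim$panel$times[1] / 48), numeric(1))
  y3 <- sim$panel$y
  far <- if (mean(mu_occ1) > 0.5) 0.01 else 0.99
  y3[1, 1] <- far
  p3 <- panel_data(y3, sim$panel$times, adjust = FALSE)
  expect_lt(total_loglik(p3, m), ll)
})

test_that("dropout hazard terms follow the discrete-time logistic model", {
  ## hazard 1/2 at every occasion; dropout at occasion 2 of 3
  expect_equal(dropout_loglik_terms(c(0.4, NA, NA), 2, delta = c(0, 0)),
               log(0.5))
  ## no-dropout limit: strongly negative intercept gives vanishing terms
  expect_equal(dropout_loglik_terms(c(0.4, 0.5, 0.6), 4, delta = c(-40, 0)),
               0, tolerance = 1e-12)
  ## survival + event decomposition with an outcome-dependent hazard
  y <- c(0.2, 0.8, NA, NA)
  d <- c(-1, 2)
  manual <- plogis(-(d[1] + d[2] * 0.2), log.p = TRUE) +    # survives occ 2
    plogis(d[1] + d[2] * 0.8, log.p = TRUE)                 # drops at occ 3
  expect_equal(dropout_loglik_terms(y, 3, d), manual, tolerance = 1e-12)
  ## missing lag at occasion 3 contributes no hazard term; the dropout event
  ## at occasion 4 uses the occasion-3 lag
  y2 <- c(0.2, NA, 0.4, NA)
  expect_equal(dropout_loglik_terms(y2, 4, d),
               plogis(-(d[1] + d[2] * 0.2), log.p = TRUE) +
                 plogis(d[1] + d[2] * 0.4, log.p = TRUE))
  expect_error(dropout_loglik_terms(y, 9, d), "1..T")
})

test_that("disabling dropout recovers the MAR likelihood exactly", {
  ## complete panel: with no dropout events, a vanishing hazard contributes 0
  cfg <- cohort_preset(n_subjects = 60, dropout = FALSE)
  sim <- generate_panel(cfg, seed = 10)
  spec_mar <- trajectory_spec(3, order = 1)
  spec_dr <- trajectory_spec(3, order = 1, dropout = TRUE)
  m_mar <- random_model(spec_mar, 5)
  groups_dr <- lapply(m_mar$groups, function(g) {
    g$delta <- c(-30, 0)          # hazard ~ 0: dropout terms vanish
    g
  })
  m_dr <- mixture_model(spec_dr, groups_dr, m_mar$gamma)
  expect_equal(total_loglik(sim$panel, m_dr), total_loglik(sim$panel, m_mar),
               tolerance = 1e-8)
  ## structural error: dropout terms on a group without dropout parameters
  expect_error(subject_loglik(sim$panel$y[1, ], sim$panel$times, m_dr),
               "dropout_occasion")
})

test_that("vectorized engine and per-subject reference agree, dropout included", {
  cfg <- cohort_preset(n_subjects = 50, dropout = TRUE)
  sim <- generate_panel(cfg, seed = 12)
  spec <- trajectory_spec(3, order = c(2, 1, 0), dropout = TRUE)
  obj <- betagbtm:::make_objective(sim$panel, spec)
  m <- random_model(spec, 6, tscale = obj$tscale)
  theta <- pack_params(m)
  engine <- obj$ll(theta)
  reference <- sum(vapply(seq_len(sim$panel$N), function(i)
    subject_loglik(sim$panel$y[i, ], sim$panel$times, m,
                   dropout_occasion = sim$panel$dropout_occasion[i]),
    numeric(1)))
  expect_equal(engine, reference, tolerance = 1e-10)
  expect_equal(total_loglik(sim$panel, m), engine, tolerance = 1e-10)
})
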