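fit_small <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      sim <- generate_panel(cohort_preset(n_subjects = 150, dropout = FALSE),
                            seed = 27)
      memo <<- fit_gbtm(sim$panel, trajectory_spec(3, order = 1),
                        n_starts = 2, seed = 8)
    }
    memo
  }
})

test_that("density overlays are normalized relative-frequency histograms", {
  f <- fit_small()
  for (g in 1:3) {
    ov <- density_overlay(f, occasion = 4, group = g)
    w <- diff(ov$breaks)
    expect_equal(sum(ov$density * w), 1, tolerance = 1e-9)
    expect_true(all(ov$curve_y >= 0))
  }
  ## hard assignment variant also normalizes exactly
  ov2 <- density_overlay(f, occasion = 4, group = 2, assignment = "modal")
  expect_equal(sum(ov2$density * diff(ov2$breaks)), 1, tolerance = 1e-9)
  expect_error(density_overlay(f, occasion = 99, group = 1), "occasion")
  expect_error(density_overlay(f, occasion = 1, group = 9), "group")
})

test_that("a single subject yields one bin of mass, still exactly normalized", {
  p <- panel_data(matrix(0.42, 1, 2), times = 0:1, adjust = FALSE)
  f1 <- fit_gbtm(p, trajectory_spec(1, order = 0), n_starts = 1, seed = 1,
                 se = FALSE)
  ov <- density_overlay(f1, occasion = 1, group = 1)
  expect_equal(sum(ov$density > 0), 1L)
  expect_equal(sum(ov$density * diff(ov$breaks)), 1, tolerance = 1e-12)
})

test_that("overlay discrepancy is small and shrinks with the cohort size", {
  ## integrated absolute difference between the posterior-weighted histogram
  ## measure and the predicted beta bin masses
  iad_fit <- function(f, occ) {
    max(vapply(seq_len(f$spec$J), function(g) {
      ov <- density_overlay(f, occasion = occ, group = g)
      sh <- mp_to_shapes(ov$mu, ov$phi)
      predicted <- diff(pbeta(ov$breaks, sh$shape1, sh$shape2))
      sum(abs(ov$density * diff(ov$breaks) - predicted))
    }, numeric(1)))
  }
  iad <- vapply(c(400, 4000), function(N) {
    sim <- generate_panel(cohort_preset(n_subjects = N, dropout = FALSE),
                          seed = 31)
    f <- fit_gbtm(sim$panel, trajectory_spec(3, order = 1), n_starts = 1,
                  seed = 9, se = FALSE)
    iad_fit(f, occ = 4)
  }, numeric(1))
  ## 20-bin histograms of ~130 subjects per group carry sampling noise of
  ## ~0.2 total variation even under the true parameters, so the bound at
  ## N = 400 reflects that floor; the discrepancy must shrink with N
  expect_lt(iad[1], 0.35)
  expect_lt(iad[2], 0.15)
  expect_lt(iad[2], iad[1])
})

test_that("trajectory tables carry shares that are exactly the mixing logit", {
  f <- fit_small()
  tt <- trajectory_table(f)
  expect_equal(sum(unique(tt$share_pct)), 100, tolerance = 1e-8)
  expect_equal(unique(tt$share_pct), 100 * mixing_probs(f$model$gamma))
  expect_true(all(tt$lower <= tt$mean & tt$mean <= tt$upper, na.rm = TRUE))
  ## J = 1 fit: a single 100% group
  p <- const_panel(40, 4, 0.5, 5, seed = 28)
  f1 <- fit_gbtm(p, trajectory_spec(1, order = 0), n_starts = 1, seed = 1)
  expect_equal(unique(trajectory_table(f1)$share_pct), 100)
})

test_that("confidence bands narrow as the cohort grows", {
  width <- vapply(c(100, 400), function(N) {
    p <- const_panel(N, 5, 0.6, 6, seed = 29)
    f <- fit_gbtm(p, trajectory_spec(1, order = 1), n_starts = 1, seed = 1)
    tt <- trajectory_table(f)
    mean(tt$upper - tt$lower)
  }, numeric(1))
  expect_lt(width[2], width[1])
})

test_that("classification quality has the textbook limiting cases", {
  onehot <- diag(3)[c(1, 2, 3, 1, 2), ]
  cq <- classification_quality(onehot, pi = c(0.4, 0.4, 0.2))
  expect_equal(cq$app, rep(1, 3))
  ## (near-)uniform posteriors with each group assigned in turn: no information
  eps <- 1e-9
  uni <- do.call(rbind, lapply(rep(1:3, 3), function(j)
    replace(rep((1 - eps) / 3, 3), j, (1 - eps) / 3 + eps)))
  cq2 <- classification_quality(uni, pi = rep(1 / 3, 3))
  expect_equal(cq2$app, rep(1 / 3, 3), tolerance = 1e-6)
  expect_equal(cq2$occ, rep(1, 3), tolerance = 1e-6)
  expect_warning(
    cq3 <- classification_quality(rbind(c(0.9, 0.1), c(0.8, 0.2)),
                                  pi = c(0.9, 0.1)),
    "no modally assigned")
  expect_true(is.na(cq3$app[2]))
  expect_error(classification_quality(matrix(0.4, 2, 2), pi = c(0.5, 0.5)),
               "sum to 1")
})
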