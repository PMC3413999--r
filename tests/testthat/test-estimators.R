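# estimators module: the three OLS fits, the nested F-test, pooling.

test_that("noiseless lines are recovered exactly by all three fits", {
  t <- seq(0, 100, 10)

  dr <- fit_drift_linear(make_summary(t, 100 - 0.35 * t, 1))
  expect_equal(dr$v, -0.35, tolerance = 1e-12)
  expect_equal(dr$intercept, 100, tolerance = 1e-10)
  expect_equal(fit_drift_linear(make_summary(t, rep(42, length(t)), 1))$v, 0)

  pd <- fit_pure_diffusion(make_summary(t, 1, 1000 + 83.6 * t))
  expect_equal(pd$D, 41.8, tolerance = 1e-12)
  expect_equal(fit_pure_diffusion(make_summary(t, 1, rep(7, length(t))))$D, 0)

  # quadratic MSD built from the pooled away-from-wound coefficients
  dd <- fit_drift_diffusion(make_summary(t, 10 + t, 16 * t + 0.0676 * t^2))
  expect_equal(dd$v, 0.26, tolerance = 1e-9)
  expect_equal(dd$D, 8, tolerance = 1e-9)
  # decreasing mean distance flips the sign of v, not its magnitude
  dd_neg <- fit_drift_diffusion(make_summary(t, 10 - t, 16 * t + 0.0676 * t^2))
  expect_equal(dd_neg$v, -0.26, tolerance = 1e-9)
})

test_that("lm-based fits equal the hand-coded normal-equation oracle", {
  set.seed(501)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    t <- sort(runif(n, 0, 960))
    m <- 50 + 0.3 * t + rnorm(n, sd = 20)
    s <- 2000 + 30 * t + 0.05 * t^2 + rnorm(n, sd = 4000)
    ps <- make_summary(t, m, s)

    o_lin <- ols_oracle(cbind(1, t), s)
    pd <- fit_pure_diffusion(ps)
    expect_equal(pd$D, o_lin$beta[2] / 2, tolerance = 1e-8)
    expect_equal(pd$D_se, o_lin$se[2] / 2, tolerance = 1e-8)
    expect_equal(pd$rss, o_lin$rss, tolerance = 1e-8)

    o_quad <- ols_oracle(cbind(1, t, t^2), s)
    dd <- fit_drift_diffusion(ps)
    expect_equal(dd$D, o_quad$beta[2] / 2, tolerance = 1e-8)
    expect_equal(abs(dd$v), sqrt(max(o_quad$beta[3], 0)), tolerance = 1e-8)
    expect_equal(dd$rss, o_quad$rss, tolerance = 1e-8)

    o_dr <- ols_oracle(cbind(1, t), m)
    dr <- fit_drift_linear(ps)
    expect_equal(dr$v, o_dr$beta[2], tolerance = 1e-8)
    expect_equal(dr$v_se, o_dr$se[2], tolerance = 1e-8)
  }
})

test_that("the F statistic follows the stated arithmetic and guards", {
  t <- seq(0, 220, 10)                      # 23 timepoints
  set.seed(502)
  ps <- make_summary(t, 50 + t, 100 + 20 * t + rnorm(23, sd = 50))
  pd <- fit_pure_diffusion(ps)
  dd <- fit_drift_diffusion(ps)

  # rss_pure = rss_dd  ->  F = 0
  pd0 <- pd; pd0$rss <- dd$rss
  f0 <- f_test(pd0, dd)
  expect_equal(f0$F, 0)
  expect_false(f0$prefer_drift)

  # rss_pure = 2 rss_dd, n = 23  ->  F = (n - 3) = 20
  pd2 <- pd; pd2$rss <- 2 * dd$rss
  f2 <- f_test(pd2, dd)
  expect_equal(f2$F, 20, tolerance = 1e-12)
  expect_true(f2$prefer_drift)
  expect_equal(f2$df2, 20L)

  # mismatched n and tiny n are refused
  pd_bad <- pd; pd_bad$n <- 10L
  expect_error(f_test(pd_bad, dd), "same summary",
               class = "woundwalk_domain_error")
  t4 <- c(0, 10, 20, 30)
  ps4 <- make_summary(t4[1:3], c(1, 2, 3), c(1, 4, 9))
  expect_error(fit_drift_diffusion(ps4), "at least 4",
               class = "woundwalk_domain_error")
  expect_error(fit_drift_linear(ps4[1:2, ]), "at least 3",
               class = "woundwalk_domain_error")
  expect_error(fit_drift_linear(make_summary(c(5, 5, 5), 1:3, 1)),
               "identical", class = "woundwalk_domain_error")
})

test_that("quadratic OLS nests linear OLS: rss_dd <= rss_pure always", {
  set.seed(503)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    t <- sort(runif(n, 0, 960))
    s <- runif(1, 0, 5000) + runif(1, -20, 60) * t +
      runif(1, -0.05, 0.08) * t^2 + rnorm(n, sd = runif(1, 1, 5000))
    ps <- make_summary(t, 1 + 0.1 * t, s)
    expect_lte(fit_drift_diffusion(ps)$rss,
               fit_pure_diffusion(ps)$rss + 1e-8)
  }
})

test_that("F-test is calibrated in its own regime (iid errors, true line)", {
  # With independent homoscedastic noise around a straight MSD line the
  # partial F for the quadratic term is exactly F(1, n - 3); the decision
  # threshold 5 then has tail probability pf(5, 1, n - 3, lower = FALSE).
  set.seed(504)
  n <- 20L
  t <- seq(0, 950, length.out = n)
  n_reps <- 500
  hits <- 0L
  for (r in seq_len(n_reps)) {
    s <- 500 + 40 * t + rnorm(n, sd = 2000)
    ps <- make_summary(t, 1 + 0.01 * t, s)
    ft <- f_test(fit_pure_diffusion(ps), fit_drift_diffusion(ps))
    hits <- hits + (ft$F > 5)
  }
  p_hat <- hits / n_reps
  p_true <- pf(5, 1, n - 3, lower.tail = FALSE)
  ci <- p_hat + c(-1.96, 1.96) * sqrt(p_hat * (1 - p_hat) / n_reps)
  expect_gte(p_true, ci[1])
  expect_lte(p_true, ci[2])
})

test_that("sign convention: toward-wound drift estimates are negative", {
  # Curvature must dominate sampling noise for the quadratic term to be
  # resolved, hence the long window and large cohort.
  p_in <- simulation_params(v = -0.4, D = 5, n_cells = 2000,
                            times = seq(0, 480, 20),
                            init = init_uniform(800, lo = 400), seed = 505)
  f_in <- fit_replicate(p_in)
  expect_lt(f_in$dr$v, 0)
  expect_lt(f_in$dd$v, 0)

  p_out <- simulation_params(v = 0.4, D = 5, n_cells = 2000,
                             times = seq(0, 480, 20),
                             init = init_point(0), seed = 506)
  f_out <- fit_replicate(p_out)
  expect_gt(f_out$dr$v, 0)
  expect_gt(f_out$dd$v, 0)
})

test_that("under pure-diffusion truth the drift estimate shrinks to zero", {
  # |v-hat| = sqrt(max(b2-hat, 0)) is non-negative, so under the null it
  # converges to 0 from above at rate n_cells^(-1/4): a 16-fold larger
  # cohort should roughly halve it.  (Near the reflecting boundary the
  # mean distance grows even with v = 0, so the SIGN attached to v-hat is
  # legitimately positive here; only the magnitude is at issue.)
  run <- function(n_cells, seeds) {
    vapply(seeds, function(s) {
      p <- simulation_params(v = 0, D = 15, n_cells = n_cells,
                             times = seq(0, 480, 20), seed = s)
      abs(fit_replicate(p)$dd$v)
    }, numeric(1))
  }
  set.seed(507)
  seeds <- sample.int(2^31 - 2, 40)
  v_small_n <- run(200, seeds[1:20])
  v_big_n <- run(3200, seeds[21:40])
  expect_gt(mean(v_small_n) / mean(v_big_n), 1.4)   # ~2 expected
  expect_lt(mean(v_big_n), 0.05)  # far below any reported drift scale
})

test_that("pool_subjects pools cells, namespaces ids and aligns grids", {
  ds <- data.frame(cell_id = c("a", "b"), time_min = 0,
                   distance_um = c(10, 30))
  pooled_self <- pool_subjects(list(ds, ds))
  ps_self <- population_summary(pooled_self)
  expect_equal(ps_self$n_cells, 4L)
  expect_equal(ps_self$mean_dist, 20)

  one_a <- data.frame(cell_id = "a", time_min = 0, distance_um = 10)
  one_b <- data.frame(cell_id = "a", time_min = 0.2, distance_um = 30)
  ps_two <- population_summary(pool_subjects(list(one_a, one_b),
                                             tolerance = 0.5))
  expect_equal(ps_two$mean_dist, 20)   # snapped onto one grid

  expect_error(pool_subjects(list(one_a, transform(one_b, time_min = 7))),
               "tolerance", class = "woundwalk_domain_error")

  # concatenate-then-summarise oracle on synthetic subjects
  p <- simulation_params(v = 0.1, D = 6, n_cells = 50,
                         times = seq(0, 60, 20), seed = 508)
  reps <- simulate_ensemble(p, 3)
  series <- lapply(reps, compute_distances, wound = simulation_wound())
  ps_pool <- population_summary(pool_subjects(series))
  all_d <- do.call(rbind, lapply(series, as.data.frame))
  for (t in unique(all_d$time_min)) {
    expect_equal(ps_pool$mean_dist[ps_pool$time_min == t],
                 mean(all_d$distance_um[all_d$time_min == t]))
  }
  expect_equal(ps_pool$n_cells, rep(150L, 4))
})
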