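test_that("stimulation is the difference of relative variations in points", {
  t <- c(0, 48)
  same <- series_df(t, c(2e6, 2.6e6))
  expect_equal(stimulation(same, same), 0)

  v <- series_df(t, c(1e6, 2e6))    # doubles: +100%
  vf <- series_df(t, c(1e6, 3e6))   # triples: +200%
  expect_equal(stimulation(vf, v), 100)

  v2 <- series_df(t, c(2.0e6, 2.6e6))
  vfa <- series_df(t, c(1.9e6, 3.1e6))
  expect_equal(stimulation(vfa, v2),
               100 * ((3.1 - 1.9) / 1.9 - 0.6 / 2.0), tolerance = 1e-12)
  expect_equal(round(stimulation(vfa, v2), 1), 33.2)
})

test_that("stimulation is antisymmetric and scale invariant", {
  t <- c(0, 96)
  a <- series_df(t, c(1.2e6, 3.3e6))
  b <- series_df(t, c(2.1e6, 2.9e6))
  expect_equal(stimulation(a, b, 0, 96), -stimulation(b, a, 0, 96))
  for (k in c(0.01, 3, 1e4)) {
    a_k <- series_df(t, k * a$value)
    expect_equal(stimulation(a_k, b, 0, 96), stimulation(a, b, 0, 96),
                 tolerance = 1e-9)
  }
})

test_that("stimulation rejects windows starting at zero abundance", {
  t <- c(0, 48)
  expect_error(stimulation(series_df(t, c(0, 1e6)), series_df(t, c(1, 2))),
               "zero value")
  expect_error(stimulation(series_df(c(0, 24), c(1, 2)),
                           series_df(t, c(1, 2)), t_end = 48),
               "lacks a value")
})

test_that("one-way ANOVA matches the sum-of-squares oracle", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8))
  res <- one_way_anova(groups)
  expect_equal(res$statistic, anova_F_oracle(groups), tolerance = 1e-12)
  expect_true(res$significant)
  expect_equal(res$n, 9)
})

test_that("identical groups give F = 0 and p = 1", {
  res <- one_way_anova(list(c(2, 2, 2), c(2, 2, 2), c(2, 2, 2)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
  expect_null(res$lsd)
})

test_that("with two groups F equals the squared pooled-variance t", {
  x <- c(1.2, 1.9, 2.4, 1.7); y <- c(2.8, 3.3, 2.9)
  res <- one_way_anova(list(x = x, y = y))
  t2 <- stats::t.test(x, y, var.equal = TRUE)$statistic^2
  expect_equal(res$statistic, unname(t2), tolerance = 1e-12)
})

test_that("Fisher LSD comparisons appear only when the omnibus F is significant", {
  sig <- one_way_anova(list(a = c(1, 1.1, 0.9), b = c(1, 1.2, 1.1),
                            c = c(5, 5.1, 4.9)))
  expect_true(sig$significant)
  expect_s3_class(sig$lsd, "data.frame")
  expect_equal(nrow(sig$lsd), 3)
  # the distant group differs from both others; the close pair does not
  ab <- sig$lsd[sig$lsd$group1 == "a" & sig$lsd$group2 == "b", ]
  expect_false(ab$significant)
  expect_true(all(sig$lsd$significant[sig$lsd$group2 == "c" |
                                        sig$lsd$group1 == "c"]))

  ns <- one_way_anova(list(a = c(1, 2, 3), b = c(1.1, 2.1, 3.1)))
  expect_false(ns$significant)
  expect_null(ns$lsd)
})

test_that("paired t matches the direct difference formula", {
  x <- c(1, 2, 3, 4); y <- c(2, 2, 4, 5)
  res <- paired_t(x, y)
  d <- x - y
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(res$p_value,
               2 * pt(-abs(t_oracle), length(d) - 1), tolerance = 1e-12)
})

test_that("paired t handles zero-variance differences explicitly", {
  res0 <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_warning(res1 <- paired_t(c(2, 3, 4), c(1, 2, 3)), "degenerate")
  expect_true(res1$degenerate)
  expect_true(is.na(res1$p_value))
  expect_error(paired_t(1:3, 1:4), "lengths differ")
})

test_that("stimulation_table recovers a constructed uniform stimulation", {
  # deterministic bundles tuned to +30 points in the 0-48 h window
  p <- params_for_stimulation(
    sim_params(mu_b = 0.5, delta_v = 0.2, graze = 0.1, cv_noise = 0),
    30, "VF", 0, 48)
  bundles <- lapply(c("LA1", "LA2", "LB1", "LB2"), function(lab)
    simulate_experiment(p, label = lab, treatments = c("V", "VF"),
                        seed = 1))
  summ <- summarize_stimulation(bundles, windows = list(c(0, 48)))
  expect_equal(summ$cells$mean_stimulation_pct, rep(30, 4),
               tolerance = 1e-6)
  # identical dynamics in every experiment: contrasts cannot be significant
  expect_false(isTRUE(summ$season_contrast$significant))
})

test_that("identical treatments give zero stimulation everywhere", {
  s <- expand.grid(replicate = 1:3, time_h = c(0, 48, 96))
  counts <- do.call(rbind, lapply(c("V", "VF", "VFA"), function(tr)
    data.frame(experiment = "E", treatment = tr, replicate = s$replicate,
               variable = "bacteria", time_h = s$time_h,
               value = 1e6 * exp(0.4 * s$time_h / 24))))
  st <- stimulation_table(counts)
  expect_equal(st$stimulation_pct, rep(0, nrow(st)), tolerance = 1e-12)
})

test_that("stochastic bundles recover the planted stimulation on average", {
  p <- params_for_stimulation(
    sim_params(mu_b = 0.5, delta_v = 0.2, graze = 0.1, cv_noise = 0.05),
    25, "VF", 0, 48)
  means <- vapply(1:30, function(s) {
    b <- simulate_experiment(p, treatments = c("V", "VF"), seed = s,
                             assay_days = integer(0))
    mean(stimulation_table(b, windows = list(c(0, 48)))$stimulation_pct)
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 25), 2 * se + 1)
})
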