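test_that("zero-rate parameters give a constant bacterial series", {
  p <- sim_params(mu_b = 0, delta_v = 0, graze = 0, cv_noise = 0,
                  bacteria = 1e6, decay_v = 0)
  tr <- microcosm_trajectory(p, "V", c(0, 24, 48, 96))
  expect_equal(unname(tr[, "bacteria"]), rep(1e6, 4), tolerance = 1e-12)
})

test_that("pure exponential growth matches the closed form", {
  p <- sim_params(mu_b = 0.5, delta_v = 0, graze = 0, cv_noise = 0,
                  bacteria = 1e6, decay_v = 0)
  tr <- microcosm_trajectory(p, "V", c(0, 48, 96))
  expect_equal(unname(tr[2, "bacteria"]), 1e6 * exp(0.5 * 2), tolerance = 1e-9)
  expect_equal(unname(tr[3, "bacteria"]), 1e6 * exp(0.5 * 4), tolerance = 1e-9)
})

test_that("viruses gained equal burst size times bacteria lysed", {
  # analytic oracle: B(t) = B0 e^{rt}, lysed = delta_v * B0 (e^{rt}-1)/r
  p <- sim_params(mu_b = 0.5, delta_v = 0.4, graze = 0, cv_noise = 0,
                  bacteria = 1e6, viruses = 5e7, decay_v = 0,
                  burst_size = 27)
  tr <- microcosm_trajectory(p, "V", c(0, 96))
  r <- 0.5 - 0.4
  lysed <- 0.4 * 1e6 * (exp(r * 4) - 1) / r
  gained <- tr[2, "viruses"] - 5e7
  expect_lt(abs(gained - 27 * lysed) / (27 * lysed), 1e-3)
})

test_that("increasing grazing strictly decreases bacteria at 96 h", {
  b96 <- vapply(c(0, 0.1, 0.2, 0.4), function(g) {
    p <- sim_params(mu_b = 0.5, delta_v = 0.1, graze = g, cv_noise = 0)
    microcosm_trajectory(p, "VF", c(0, 96))[2, "bacteria"]
  }, numeric(1))
  expect_true(all(diff(b96) < 0))
})

test_that("identical seeds give identical bundles", {
  p <- microcosm_preset("LB2")
  b1 <- simulate_experiment(p, label = "LB2", seed = 42)
  b2 <- simulate_experiment(p, label = "LB2", seed = 42)
  expect_identical(b1$counts, b2$counts)
  expect_identical(b1$dilution_assays, b2$dilution_assays)
  expect_identical(b1$leucine, b2$leucine)
})

test_that("V treatment carries no flagellates and a small residual of picocyanobacteria", {
  p <- microcosm_preset("LA1", cv_noise = 0)
  tr <- microcosm_trajectory(p, "V", c(0, 96))
  expect_equal(unname(tr[1, "hnf"]), 0)
  expect_equal(unname(tr[1, "pnf"]), 0)
  expect_lte(tr[1, "picocyano"] / p$init[["picocyano"]], 0.05)
})

test_that("parameter validation rejects bad inputs", {
  expect_error(sim_params(mu_b = -0.1), "non-negative")
  expect_error(sim_params(cv_noise = 1), "cv_noise")
  expect_error(sim_params(burst_size = 0), "burst_size")
  p <- sim_params()
  expect_error(microcosm_trajectory(p, "V", c(48, 0)), "increasing")
  expect_error(microcosm_trajectory(p, "V", c(24, 48)), "start at 0")
})

test_that("dilution assay generator has the closed-form mean slope", {
  p <- sim_params(delta_v = 0, cv_noise = 0)
  a0 <- simulate_dilution_assay(p, c(bacteria = 3e6, viruses = 6e7))
  expect_equal(a0$true_slope, 0)
  expect_equal(stats::sd(a0$viral_counts), 0)

  p1 <- sim_params(delta_v = 0.4, burst_size = 27, cv_noise = 0)
  a1 <- simulate_dilution_assay(p1, c(bacteria = 3e6, viruses = 6e7),
                                dilution_factor = 1 / 3)
  expect_equal(a1$b, 1e6)
  expect_equal(a1$true_slope, 27 * 0.4 * 1e6 / 24)  # 4.5e5 per hour
  expect_equal(ols_slope(a1$times, a1$viral_counts), a1$true_slope,
               tolerance = 1e-12)
  expect_error(simulate_dilution_assay(p1, c(bacteria = 1, viruses = 1),
                                       dilution_factor = 1.2),
               "dilution_factor")
})

test_that("noisy dilution-assay slopes are unbiased (Monte-Carlo oracle)", {
  p <- sim_params(delta_v = 0.4, burst_size = 27, cv_noise = 0.05)
  state <- c(bacteria = 3e6, viruses = 6e7)
  slopes <- vapply(1:100, function(s) {
    set.seed(s)
    a <- simulate_dilution_assay(p, state)
    ols_slope(a$times, a$viral_counts)
  }, numeric(1))
  truth <- 27 * 0.4 * 1e6 / 24
  se <- stats::sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - truth), 2 * se)
})

test_that("gel simulation respects the detection floor and lane identity", {
  prof <- rbind(a = c(0.5, 0.3, 0.199, 0.001),
                b = c(0.5, 0.3, 0.199, 0.001))
  g <- simulate_gel(prof, detection_floor = 0.004, position_jitter = 0)
  expect_identical(g[g$lane == "a", -1], g[g$lane == "b", -1],
                   ignore_attr = TRUE)
  expect_equal(sum(g$lane == "a"), 3)  # the 0.001 phylotype left no band
  expect_error(simulate_gel(rbind(c(0.5, 0.4))), "sum to 1")
})

test_that("commonality from a simulated gel matches the generator's truth", {
  set.seed(7)
  n_phy <- 20
  prof <- t(replicate(3, {
    p <- rexp(n_phy) + 0.02
    p / sum(p)
  }))
  rownames(prof) <- c("V", "VF", "VFA")
  g <- simulate_gel(prof, detection_floor = 0.004, position_jitter = 0)
  truth <- attr(g, "truth")
  bm <- match_bands(g, tolerance = 5)
  ct <- commonality_table(bm, setNames(rownames(prof), rownames(prof)))
  expect_equal(ct$total, sum(apply(truth, 2, any)))
  expect_equal(unname(ct$counts[["common_all"]]),
               sum(colSums(truth) == 3))
  expect_equal(unname(ct$counts[["specific_V"]]),
               sum(truth["V", ] & colSums(truth) == 1))
})

test_that("noise-free bundles let kinetics recover the composite net rates", {
  p <- microcosm_preset("LB1", cv_noise = 0)
  b <- simulate_experiment(p, label = "LB1", seed = 3)
  rt <- rate_table(b)
  for (tr in c("V", "VF", "VFA")) {
    truth <- net_growth_rate(p, tr)
    est <- rt$growth_rate[rt$treatment == tr & rt$horizon_h == 96]
    expect_lt(abs(est - truth) / abs(truth), 1e-9)
  }
})

test_that("tuned enrichment yields the requested deterministic stimulation", {
  p <- sim_params(mu_b = 0.5, delta_v = 0.2, graze = 0.1, cv_noise = 0)
  for (target in c(10, 25, 40)) {
    pt <- params_for_stimulation(p, target, "VF", 0, 48)
    trt <- microcosm_trajectory(pt, "VF", c(0, 48))
    ref <- microcosm_trajectory(pt, "V", c(0, 48))
    stim <- stimulation(series_df(c(0, 48), trt[, "bacteria"]),
                        series_df(c(0, 48), ref[, "bacteria"]))
    expect_equal(stim, target, tolerance = 1e-6)
  }
})
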