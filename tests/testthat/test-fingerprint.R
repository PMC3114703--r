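test_that("relative intensity normalizes peak surfaces", {
  expect_equal(relative_intensity(c(2, 3, 5)), c(0.2, 0.3, 0.5))
  expect_equal(relative_intensity(rep(7, 4)), rep(0.25, 4))
  expect_equal(relative_intensity(c(1, 0, 7, 2)), c(0.1, 0, 0.7, 0.2))
  expect_error(relative_intensity(c(0, 0)), "no bands")
  expect_error(relative_intensity(c(-1, 2)), ">= 0")
})

test_that("band matching merges positions within tolerance", {
  raw <- data.frame(lane = c("a", "b"), position_px = c(100, 104),
                    surface = c(1, 2))
  bm <- match_bands(raw, tolerance = 5)
  expect_equal(length(bm$positions), 1)
  expect_equal(bm$positions, 102)
  expect_equal(unname(bm$intensity[, 1]), c(1, 2))

  # identical lanes match band-for-band
  raw2 <- data.frame(lane = rep(c("a", "b"), each = 3),
                     position_px = rep(c(50, 120, 200), 2),
                     surface = rep(c(1, 2, 3), 2))
  bm2 <- match_bands(raw2, tolerance = 5)
  expect_equal(length(bm2$positions), 3)
  expect_equal(bm2$rel_intensity["a", ], bm2$rel_intensity["b", ])
})

test_that("band matching recovers jittered bands from a simulated gel", {
  set.seed(21)
  prof <- t(replicate(3, {
    p <- runif(12, 0.5, 1.5); p / sum(p)
  }))
  rownames(prof) <- c("l1", "l2", "l3")
  g <- simulate_gel(prof, positions = 30 * seq_len(12),
                    detection_floor = 0, position_jitter = 1)
  bm <- match_bands(g, tolerance = 5)
  expect_equal(length(bm$positions), 12)
  expect_true(all(rowSums(bm$intensity > 0) == 12))
})

test_that("band matching is idempotent and flags same-lane conflicts", {
  set.seed(22)
  prof <- t(replicate(4, { p <- runif(8, 0.5, 1.5); p / sum(p) }))
  rownames(prof) <- paste0("l", 1:4)
  g <- simulate_gel(prof, positions = 40 * seq_len(8), position_jitter = 0.8)
  bm <- match_bands(g, tolerance = 5)
  long <- data.frame(
    lane = rep(rownames(bm$intensity), times = ncol(bm$intensity)),
    position_px = rep(bm$positions, each = nrow(bm$intensity)),
    surface = as.vector(bm$intensity))
  long <- long[long$surface > 0, ]
  bm2 <- match_bands(long, tolerance = 5)
  expect_equal(bm2$positions, bm$positions, tolerance = 1e-12)
  expect_equal(bm2$intensity, bm$intensity)

  conflict <- data.frame(lane = c("a", "a"), position_px = c(100, 103),
                         surface = c(1, 1))
  expect_error(match_bands(conflict, tolerance = 5), "two bands")
})

test_that("commonality partition counts always sum to the total", {
  set.seed(23)
  for (i in 1:10) {
    pres <- matrix(runif(3 * 15) > 0.4, nrow = 3,
                   dimnames = list(c("V", "VF", "VFA"), NULL))
    pres <- pres[, colSums(pres) > 0, drop = FALSE]
    pres["V", 1] <- TRUE; pres["VF", 2] <- TRUE; pres["VFA", 3] <- TRUE
    bm <- band_matrix(10 * seq_len(ncol(pres)), pres * 1)
    ct <- commonality_table(bm, setNames(c("V", "VF", "VFA"),
                                         c("V", "VF", "VFA")))
    expect_equal(sum(ct$counts), ct$total)
  }
})

test_that("identical lanes are 100% common with no specific bands", {
  bm <- band_matrix(c(10, 20, 30),
                    matrix(1, 3, 3, dimnames = list(c("V", "VF", "VFA"),
                                                    NULL)))
  ct <- commonality_table(bm, setNames(c("V", "VF", "VFA"),
                                       c("V", "VF", "VFA")))
  expect_equal(unname(ct$percent[["common_all"]]), 100)
  expect_equal(sum(ct$counts[-1]), 0)
})

test_that("commonality errors on unmapped lanes or missing treatments", {
  bm <- band_matrix(c(10, 20), matrix(1, 2, 2,
                                      dimnames = list(c("V", "VF"), NULL)))
  expect_error(commonality_table(bm, c(V = "V")), "unmapped")
  expect_error(commonality_table(bm, c(V = "V", VF = "VF")),
               "three treatments")
})

test_that("Bray-Curtis similarity matches hand values and its bounds", {
  expect_equal(bray_curtis_similarity(c(0.5, 0.5, 0), c(0.5, 0.5, 0)), 1)
  expect_equal(bray_curtis_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(bray_curtis_similarity(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5)),
               0.5)
  set.seed(31)
  for (i in 1:20) {
    p <- runif(8); q <- runif(8)
    s <- bray_curtis_similarity(p, q)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s, bray_curtis_similarity(q, p))
  }
  expect_error(bray_curtis_similarity(c(0, 0), c(0, 0)), "undefined")
})

test_that("Bray-Curtis agrees with vegan on random profiles", {
  skip_if_not_installed("vegan")
  set.seed(32)
  x <- matrix(runif(2 * 10), nrow = 2)
  d <- as.numeric(vegan::vegdist(x, method = "bray"))
  expect_equal(bray_curtis_similarity(x[1, ], x[2, ]), 1 - d,
               tolerance = 1e-12)
})

test_that("UPGMA joins the identical pair first", {
  pres <- rbind(A = c(1, 1, 0, 0), B = c(1, 1, 0, 0), C = c(0, 0, 1, 1))
  bm <- band_matrix(c(10, 20, 30, 40), pres)
  tree <- cluster_lanes(bm)
  first <- tree$hclust$merge[1, ]
  expect_true(all(first < 0))
  expect_setequal(tree$hclust$labels[-first], c("A", "B"))
  expect_equal(tree$hclust$height[1], 0)
})

test_that("cophenetic distances equal the brute-force UPGMA oracle", {
  set.seed(33)
  for (i in 1:5) {
    pres <- matrix(runif(4 * 10), nrow = 4,
                   dimnames = list(paste0("L", 1:4), NULL))
    bm <- band_matrix(10 * seq_len(10), pres)
    tree <- cluster_lanes(bm)
    coph <- as.matrix(stats::cophenetic(tree$hclust))
    oracle <- upgma_cophenetic_oracle(1 - similarity_matrix(bm))
    expect_equal(coph[rownames(oracle), colnames(oracle)], oracle,
                 tolerance = 1e-12)
  }
})

test_that("clustering recovers two planted lane groups", {
  set.seed(34)
  base1 <- runif(12, 0.5, 1.5); base2 <- runif(12, 0.5, 1.5)
  base2[1:6] <- 0.01  # group 2 nearly lacks the first six phylotypes
  mk <- function(base) { p <- base * exp(rnorm(12, 0, 0.1)); p / sum(p) }
  prof <- rbind(g1a = mk(base1), g1b = mk(base1), g1c = mk(base1),
                g2a = mk(base2), g2b = mk(base2))
  g <- simulate_gel(prof, positions = 30 * seq_len(12), position_jitter = 0)
  bm <- match_bands(g, tolerance = 5)
  tree <- cluster_lanes(bm)
  cut <- stats::cutree(tree$hclust, k = 2)
  expect_equal(length(unique(cut[c("g1a", "g1b", "g1c")])), 1)
  expect_equal(length(unique(cut[c("g2a", "g2b")])), 1)
  expect_false(cut[["g1a"]] == cut[["g2a"]])
})

test_that("the published band tallies reproduce the consistent printed cells", {
  fixtures <- band_fixtures_from_partitions()
  lane_map <- setNames(c("V", "VF", "VFA"), c("V", "VF", "VFA"))
  ct_la2 <- commonality_table(fixtures$LA2, lane_map)
  expect_equal(unname(ct_la2$percent[["common_all"]]), 42)
  ct_lb2 <- commonality_table(fixtures$LB2, lane_map)
  expect_equal(unname(ct_lb2$percent[["pair_VFA_VF"]]), 23)
  ct_lb1 <- commonality_table(fixtures$LB1, lane_map)
  expect_equal(unname(ct_lb1$percent[["specific_V"]]), 9)
  # totals match the published band counts
  expect_equal(vapply(fixtures, function(f) length(f$positions), numeric(1)),
               c(LA1 = 37, LA2 = 31, LB1 = 34, LB2 = 31))
})
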