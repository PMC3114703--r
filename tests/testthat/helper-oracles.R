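# Independent oracles used across test files. These deliberately avoid
# the package's own code paths.

# Ordinary least-squares slope via the normal equations.
ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# One-way ANOVA F statistic from a raw sum-of-squares decomposition.
anova_F_oracle <- function(groups) {
  values <- unlist(groups)
  grand <- mean(values)
  ss_between <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - grand)^2, numeric(1)))
  ss_within <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), numeric(1)))
  k <- length(groups); N <- length(values)
  (ss_between / (k - 1)) / (ss_within / (N - k))
}

# Brute-force UPGMA: returns the full cophenetic distance matrix.
# Average linkage over all cross-cluster pairs (size-weighted), merging
# the closest pair at each step; ties broken by the smaller indices.
upgma_cophenetic_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  labs <- rownames(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  active <- rep(TRUE, length(clusters))
  cross_dist <- function(a, b) mean(d[a, b, drop = FALSE])
  while (sum(active) > 1) {
    idx <- which(active)
    best <- NULL; best_d <- Inf
    for (i in idx) for (j in idx) if (i < j) {
      dij <- cross_dist(clusters[[i]], clusters[[j]])
      if (dij < best_d - 1e-15) { best_d <- dij; best <- c(i, j) }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_d; coph[b, a] <- best_d
    clusters[[best[1]]] <- c(a, b)
    active[best[2]] <- FALSE
  }
  coph
}

# Simple two-column series data frame.
series_df <- function(times, values) data.frame(time_h = times, value = values)

# Leucine unit-chain oracle: pmol -> mol -> g leucine -> g protein
# carbon -> ug, written as one explicit chain.
leucine_oracle <- function(pmol) {
  mol <- pmol * 1e-12
  g_leu <- mol * 131.2
  g_protein <- g_leu / 0.073
  g_carbon <- g_protein * 0.86 * 1
  g_carbon * 1e6
}
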