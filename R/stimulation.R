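#' Predator-stimulation of a measured quantity
#'
#' The stimulation of a quantity in a predator treatment (VF or VFA)
#' relative to the predator-free V treatment is the difference between
#' the two treatments' relative variations over a time window, in
#' percentage points:
#' \deqn{100 \left[ \frac{X_T(t_1) - X_T(t_0)}{X_T(t_0)}
#'              - \frac{X_V(t_1) - X_V(t_0)}{X_V(t_0)} \right]}
#' Positive values mean the quantity increased more (or decreased less)
#' with predators present. `mode = "absolute"` instead returns the
#' difference of absolute changes scaled by the reference's starting
#' value, for sensitivity analysis.
#'
#' @param treated Data frame with `time_h` and `value` for the VF or
#'   VFA series.
#' @param reference Same quantity in the V treatment.
#' @param t_start,t_end Window bounds in hours.
#' @param mode `"relative"` (default) or `"absolute"`.
#' @return Stimulation in percentage points.
#' @export
stimulation <- function(treated, reference, t_start = 0, t_end = 48,
                        mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  val <- function(df, t) {
    v <- df$value[match(t, df$time_h)]
    if (is.na(v)) stop(sprintf("series lacks a value at %g h", t),
                       call. = FALSE)
    v
  }
  x0 <- val(treated, t_start); x1 <- val(treated, t_end)
  v0 <- val(reference, t_start); v1 <- val(reference, t_end)
  if (mode == "relative") {
    if (x0 == 0 || v0 == 0)
      stop("zero value at window start; relative variation undefined",
           call. = FALSE)
    100 * ((x1 - x0) / x0 - (v1 - v0) / v0)
  } else {
    if (v0 == 0) stop("zero reference value at window start", call. = FALSE)
    100 * ((x1 - x0) - (v1 - v0)) / v0
  }
}

#' One-way ANOVA with Fisher's protected LSD
#'
#' Standard fixed-effects one-way analysis of variance across groups of
#' replicate values, followed by Fisher's protected least significant
#' difference pairwise comparisons — computed only when the omnibus F
#' test is significant at `alpha` (the "protection").
#'
#' @param groups Named (or unnamed) list of numeric vectors, each of
#'   length >= 2; at least 2 groups.
#' @param alpha Significance threshold (default 0.05).
#' @return A `comparison_result` list: `statistic` (F), `df`, `p_value`,
#'   `n`, `significant`, and `lsd` (pairwise data frame or NULL).
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2))
    stop("each group needs at least 2 values", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  k <- length(groups); N <- length(values)

  if (stats::var(values) == 0) {
    # every observation identical: no variance to partition
    return(structure(list(statistic = 0, df = c(k - 1, N - k), p_value = 1,
                          n = N, significant = FALSE, lsd = NULL),
                     class = "comparison_result"))
  }
  fit <- stats::aov(values ~ fac)
  tab <- summary(fit)[[1]]
  F_stat <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  mse <- tab[["Mean Sq"]][2]
  df_err <- tab[["Df"]][2]

  lsd <- NULL
  if (p < alpha && mse > 0) {
    pairs <- utils::combn(names(groups), 2)
    lsd <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      na <- length(groups[[a]]); nb <- length(groups[[b]])
      se <- sqrt(mse * (1 / na + 1 / nb))
      t_stat <- (mean(groups[[a]]) - mean(groups[[b]])) / se
      p_ab <- 2 * stats::pt(-abs(t_stat), df_err)
      data.frame(group1 = a, group2 = b, diff = mean(groups[[a]]) - mean(groups[[b]]),
                 t = t_stat, p_value = p_ab, significant = p_ab < alpha,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(statistic = F_stat, df = c(k - 1, df_err), p_value = p,
                 n = N, significant = p < alpha, lsd = lsd),
            class = "comparison_result")
}

#' Paired t test
#'
#' Classical two-sided paired t on the within-pair differences. If the
#' differences have zero variance the test is degenerate: identical
#' vectors give t = 0, p = 1; a constant non-zero difference is flagged
#' (`degenerate = TRUE`, p = NA) rather than reported as infinitely
#' significant.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @param alpha Significance threshold (default 0.05).
#' @return A `comparison_result` list: `statistic` (t), `df`, `p_value`,
#'   `n`, `significant`, `degenerate`.
#' @export
paired_t <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (mean(d) == 0)
      return(structure(list(statistic = 0, df = n - 1, p_value = 1, n = n,
                            significant = FALSE, degenerate = FALSE),
                       class = "comparison_result"))
    warning("constant non-zero paired difference; t test degenerate",
            call. = FALSE)
    return(structure(list(statistic = Inf, df = n - 1, p_value = NA_real_,
                          n = n, significant = NA, degenerate = TRUE),
                     class = "comparison_result"))
  }
  t_stat <- mean(d) / (sd_d / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), n - 1)
  structure(list(statistic = t_stat, df = n - 1, p_value = p, n = n,
                 significant = p < alpha, degenerate = FALSE),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  lab <- if (length(x$df) == 2) sprintf("F(%g, %g)", x$df[1], x$df[2])
         else sprintf("t(%g)", x$df)
  cat(sprintf("%s = %.4g, p = %.4g, n = %d%s\n", lab, x$statistic,
              x$p_value, x$n,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Per-replicate stimulation table for count data
#'
#' For each experiment, predator treatment (VF/VFA) and window, computes
#' the stimulation of a count variable per replicate, using the
#' replicate-mean V trajectory as the reference (bottles across
#' treatments are unpaired).
#'
#' @param counts Long count data frame or `experiment_bundle`.
#' @param variable Variable to analyse (default "bacteria").
#' @param windows List of `c(t_start, t_end)` pairs in hours; default
#'   the 0-48, 48-96 and 0-96 h windows.
#' @param mode Passed to [stimulation()].
#' @return Data frame with per-replicate `stimulation_pct` plus group
#'   mean and sd columns.
#' @export
stimulation_table <- function(counts, variable = "bacteria",
                              windows = list(c(0, 48), c(48, 96), c(0, 96)),
                              mode = "relative") {
  if (inherits(counts, "experiment_bundle")) counts <- counts$counts
  counts <- counts[counts$variable == variable, , drop = FALSE]
  out <- list()
  for (exp_i in unique(counts$experiment)) {
    ce <- counts[counts$experiment == exp_i, , drop = FALSE]
    cv <- ce[ce$treatment == "V", , drop = FALSE]
    if (nrow(cv) == 0)
      stop("experiment ", exp_i, ": V treatment missing", call. = FALSE)
    ref <- stats::aggregate(value ~ time_h, data = cv, FUN = mean)
    for (tr in intersect(c("VF", "VFA"), unique(ce$treatment))) {
      ct <- ce[ce$treatment == tr, , drop = FALSE]
      for (w in windows) {
        stim <- vapply(sort(unique(ct$replicate)), function(rep_i)
          stimulation(ct[ct$replicate == rep_i, ], ref,
                      t_start = w[1], t_end = w[2], mode = mode),
          numeric(1))
        out[[length(out) + 1L]] <- data.frame(
          experiment = exp_i, treatment = tr,
          t_start = w[1], t_end = w[2],
          replicate = sort(unique(ct$replicate)),
          stimulation_pct = stim,
          mean_pct = mean(stim), sd_pct = stats::sd(stim),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize stimulation across experiments by lake and season
#'
#' Aggregates per-replicate stimulation over a set of experiment bundles
#' labelled in the `LA1`/`LA2`/`LB1`/`LB2` convention (first two letters
#' = lake, final digit = season: 1 early spring, 2 summer) and runs the
#' lake-vs-lake and season-vs-season paired t comparisons on the
#' replicate-level values (paired by treatment x window x replicate).
#'
#' @param bundles List of `experiment_bundle` objects (or a named list
#'   of long count data frames).
#' @param variable Count variable to analyse.
#' @param windows Windows as in [stimulation_table()].
#' @param mode Passed to [stimulation()].
#' @return List with `cells` (mean stimulation per lake x season),
#'   `lake_contrast` and `season_contrast` (`comparison_result`s), and
#'   the underlying `replicates` table.
#' @export
summarize_stimulation <- function(bundles, variable = "bacteria",
                                  windows = list(c(0, 48), c(48, 96)),
                                  mode = "relative") {
  tabs <- lapply(bundles, stimulation_table, variable = variable,
                 windows = windows, mode = mode)
  tab <- do.call(rbind, tabs)
  tab$lake <- substr(tab$experiment, 1, 2)
  tab$season <- ifelse(grepl("1$", tab$experiment), "spring", "summer")

  cells <- stats::aggregate(stimulation_pct ~ lake + season, data = tab,
                            FUN = mean)
  names(cells)[3] <- "mean_stimulation_pct"

  # pair by everything except the contrasted factor
  pair_contrast <- function(col, lev, key_cols) {
    a <- tab[tab[[col]] == lev[1], ]
    b <- tab[tab[[col]] == lev[2], ]
    key <- function(d) do.call(paste, d[key_cols])
    a <- a[order(key(a)), ]; b <- b[order(key(b)), ]
    if (nrow(a) != nrow(b) || nrow(a) < 2 || !all(key(a) == key(b)))
      return(NULL)
    paired_t(a$stimulation_pct, b$stimulation_pct)
  }
  lakes <- sort(unique(tab$lake))
  lake_c <- if (length(lakes) == 2)
    pair_contrast("lake", lakes,
                  c("season", "treatment", "t_start", "t_end", "replicate"))
  else NULL
  season_c <- pair_contrast("season", c("spring", "summer"),
                            c("lake", "treatment", "t_start", "t_end",
                              "replicate"))

  list(cells = cells, lake_contrast = lake_c, season_contrast = season_c,
       replicates = tab)
}
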