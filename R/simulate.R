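#' @keywords internal
#' Initial state vector for one treatment.
#'
#' V (< 1.6 um) excludes flagellates entirely and lets only a small
#' residual of the picocyanobacterial community through; VF/VFA (< 5 um)
#' keep both at their (slightly reduced) in situ level.
.initial_state <- function(params, treatment) {
  init <- params$init
  if (treatment == "V") {
    init[["hnf"]] <- 0
    init[["pnf"]] <- 0
    init[["picocyano"]] <- params$residual_frac * init[["picocyano"]]
  }
  init
}

# Derivative closure in per-hour units over the unnamed state vector
# (bacteria, viruses, hnf, pnf, picocyano); all rate constants are
# resolved once so the RK4 loop stays cheap.
.make_deriv <- function(params, treatment) {
  flag <- treatment != "V"
  net_b <- net_growth_rate(params, treatment) / 24
  prod_v <- params$burst_size * params$delta_v / 24
  decay_v <- params$decay_v / 24
  r_h <- if (flag) params$flag_growth / 24 else 0
  r_p <- if (flag) 0.7 * params$flag_growth / 24 else 0
  Kh <- params$flag_K_mult * max(params$init[["hnf"]], 1)
  Kp <- params$flag_K_mult * max(params$init[["pnf"]], 1)
  Kc <- 2 * max(params$init[["picocyano"]], 1)
  vfa <- treatment == "VFA"
  r_c <- if (vfa) params$pcy_growth / 24 else 0
  d_c <- if (vfa) 0 else params$pcy_decay / 24
  function(s) {
    c(net_b * s[1],
      prod_v * s[1] - decay_v * s[2],
      r_h * s[3] * (1 - s[3] / Kh),
      r_p * s[4] * (1 - s[4] / Kp),
      r_c * s[5] * (1 - s[5] / Kc) - d_c * s[5])
  }
}

#' Deterministic mean trajectory of a microcosm treatment
#'
#' Integrates the within-bottle dynamics with a fixed-step fourth-order
#' Runge-Kutta scheme (step 0.05 h) and returns the state at the
#' requested times. No observation noise is applied.
#'
#' @param params A [sim_params()] object.
#' @param treatment "V", "VF" or "VFA".
#' @param times Sorted vector of sampling times in hours, starting at 0.
#' @param step RK4 step in hours (must be <= 0.1).
#' @return A matrix with one row per time and columns `bacteria`,
#'   `viruses`, `hnf`, `pnf`, `picocyano`, plus a `time_h` attribute-free
#'   first column `time_h`.
#' @export
microcosm_trajectory <- function(params, treatment, times = c(0, 48, 96),
                                 step = 0.1) {
  stopifnot(inherits(params, "sim_params"))
  treatment <- match.arg(treatment, c("V", "VF", "VFA"))
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (times[1] != 0) stop("times must start at 0", call. = FALSE)
  if (step > 0.1) stop("RK4 step must be <= 0.1 h", call. = FALSE)

  init <- .initial_state(params, treatment)
  deriv <- .make_deriv(params, treatment)
  state <- unname(init)
  out <- matrix(NA_real_, nrow = length(times), ncol = 5,
                dimnames = list(NULL, names(init)))
  out[1, ] <- state
  t_now <- 0
  for (i in seq_along(times)[-1]) {
    t_target <- times[i]
    while (t_now < t_target - 1e-12) {
      h <- min(step, t_target - t_now)
      k1 <- deriv(state)
      k2 <- deriv(state + h / 2 * k1)
      k3 <- deriv(state + h / 2 * k2)
      k4 <- deriv(state + h * k3)
      state <- pmax(state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
      t_now <- t_now + h
    }
    out[i, ] <- state
  }
  cbind(time_h = times, out)
}

# Mean-one lognormal factors with coefficient of variation cv.
.lognorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Simulate observed count series for one microcosm treatment
#'
#' Runs [microcosm_trajectory()] and multiplies every count by a
#' mean-one lognormal observation-noise factor (CV = `cv_noise`), so
#' simulated counts stay positive. Uses the current RNG state; seed it
#' (or set `params$seed`) for reproducibility.
#'
#' @inheritParams microcosm_trajectory
#' @param replicate Replicate index recorded in the output.
#' @param experiment Experiment label recorded in the output.
#' @return Long-format data frame with columns `experiment`, `treatment`,
#'   `replicate`, `variable`, `time_h`, `value`. Variables with zero
#'   initial abundance (flagellates in V) are reported as 0 without noise.
#' @export
simulate_microcosm <- function(params, treatment, times = c(0, 48, 96),
                               replicate = 1L, experiment = "SIM") {
  traj <- microcosm_trajectory(params, treatment, times)
  .observe_trajectory(traj, params, treatment, replicate, experiment)
}

# Apply observation noise to a precomputed trajectory (shared by
# simulate_microcosm and simulate_experiment so replicates of one
# treatment reuse one ODE solve).
.observe_trajectory <- function(traj, params, treatment, replicate,
                                experiment) {
  times <- traj[, "time_h"]
  vars <- colnames(traj)[-1]
  df <- data.frame(
    experiment = experiment, treatment = treatment,
    replicate = as.integer(replicate),
    variable = rep(vars, each = length(times)),
    time_h = rep(times, times = length(vars)),
    value = as.vector(traj[, -1]),
    stringsAsFactors = FALSE)
  # absent populations (flagellates in V) are dropped rather than kept
  # as zero rows: count series are strictly positive by contract
  df <- df[df$value > 0, , drop = FALSE]
  rownames(df) <- NULL
  df$value <- df$value * .lognorm_noise(nrow(df), params$cv_noise)
  df
}

#' Simulate a 24-h viral-production dilution assay
#'
#' Emulates dilution of a subsample into virus-free water (the 50:150
#' design gives a dilution factor of 1/3): bacterial hosts are reduced
#' from `B` to `b = dilution_factor * B`, and mean viral counts rise
#' linearly at the generator's true production rate
#' `burst_size * delta_v * b / 24` per hour, with lognormal observation
#' noise on each count.
#'
#' @param params A [sim_params()] object (supplies `delta_v`,
#'   `burst_size` and `cv_noise`).
#' @param state Named vector with `bacteria` and `viruses`: undiluted
#'   abundances at assay start (per ml).
#' @param dilution_factor Fraction of the original community retained
#'   (strictly between 0 and 1; default 1/3).
#' @param times Sampling times in hours within [0, 24].
#' @param experiment,treatment,replicate Labels carried in the output.
#' @return A `dilution_assay` object: list with `times`, `viral_counts`,
#'   `b`, `B`, labels and the ground-truth `true_slope`
#'   (virus ml^-1 h^-1).
#' @export
simulate_dilution_assay <- function(params, state,
                                    dilution_factor = 1 / 3,
                                    times = c(0, 3, 6, 12, 18, 24),
                                    experiment = "SIM", treatment = "V",
                                    replicate = 1L) {
  stopifnot(inherits(params, "sim_params"))
  if (dilution_factor <= 0 || dilution_factor >= 1)
    stop("dilution_factor must be strictly between 0 and 1", call. = FALSE)
  if (min(times) < 0 || max(times) > 24)
    stop("assay times must lie within [0, 24] h", call. = FALSE)
  B <- state[["bacteria"]]
  b <- dilution_factor * B
  v0 <- dilution_factor * state[["viruses"]]
  slope <- params$burst_size * params$delta_v * b / 24
  counts <- (v0 + slope * times) * .lognorm_noise(length(times), params$cv_noise)
  dilution_assay(times = times, viral_counts = counts, b = b, B = B,
                 experiment = experiment, treatment = treatment,
                 replicate = replicate, true_slope = slope)
}

#' Construct a dilution-assay record
#'
#' @param times Sampling times (hours, within [0, 24], >= 3 points).
#' @param viral_counts Viral abundance (per ml) at each time.
#' @param b Bacterial concentration after dilution (per ml).
#' @param B Bacterial concentration before dilution (per ml).
#' @param experiment,treatment,replicate Labels.
#' @param true_slope Optional ground-truth slope (simulated assays only).
#' @return A `dilution_assay` object.
#' @export
dilution_assay <- function(times, viral_counts, b, B,
                           experiment = NA_character_,
                           treatment = NA_character_, replicate = NA_integer_,
                           true_slope = NA_real_) {
  if (length(times) != length(viral_counts))
    stop("times and viral_counts lengths differ", call. = FALSE)
  if (length(times) < 3)
    stop("a dilution assay needs at least 3 time points", call. = FALSE)
  if (min(times) < 0 || max(times) > 24)
    stop("assay times must lie within [0, 24] h", call. = FALSE)
  if (!(b > 0 && b <= B))
    stop("need 0 < b <= B", call. = FALSE)
  structure(list(times = as.numeric(times),
                 viral_counts = as.numeric(viral_counts),
                 b = b, B = B, experiment = experiment,
                 treatment = treatment, replicate = replicate,
                 true_slope = true_slope),
            class = "dilution_assay")
}

#' Simulate a DGGE gel from known phylotype profiles
#'
#' Each lane is a community profile (relative abundances over a common
#' phylotype pool). Phylotypes below the detection floor leave no band;
#' detected phylotypes produce a band at their canonical gel position
#' (plus optional Gaussian position jitter) with surface proportional to
#' relative abundance.
#'
#' @param profiles Numeric matrix, lanes x phylotypes; each row must sum
#'   to 1 (tolerance 1e-8). Row names label lanes.
#' @param positions Canonical band positions in pixels, one per
#'   phylotype (default evenly spaced 50 px apart).
#' @param detection_floor Minimum relative abundance yielding a band
#'   (default 0.004, the sensitivity usually quoted for DGGE: populations
#'   above roughly 0.3-0.4% of total counts).
#' @param position_jitter Standard deviation (pixels) of band-position
#'   jitter.
#' @return Data frame with columns `lane`, `position_px`, `surface`, and
#'   attribute `truth`: the logical lanes x phylotypes detection matrix.
#' @export
simulate_gel <- function(profiles, positions = NULL,
                         detection_floor = 0.004, position_jitter = 0) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("lane", seq_len(nrow(profiles)))
  if (any(abs(rowSums(profiles) - 1) > 1e-8))
    stop("each lane profile must sum to 1", call. = FALSE)
  if (any(profiles < 0)) stop("relative abundances must be >= 0", call. = FALSE)
  if (is.null(positions)) positions <- 50 * seq_len(ncol(profiles))
  detected <- profiles >= detection_floor & profiles > 0
  rows <- which(detected, arr.ind = TRUE)
  n <- nrow(rows)
  jit <- if (position_jitter > 0) stats::rnorm(n, 0, position_jitter) else numeric(n)
  out <- data.frame(
    lane = rownames(profiles)[rows[, 1]],
    position_px = positions[rows[, 2]] + jit,
    surface = profiles[detected],
    stringsAsFactors = FALSE)
  out <- out[order(out$lane, out$position_px), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "truth") <- detected
  out
}

#' Simulate a complete fractionation experiment bundle
#'
#' Generates, with known ground truth, everything one experiment
#' produces: count time series for all treatments and replicates,
#' dilution assays for viral production at day 0/2/4, leucine-uptake
#' assays for bacterial production, and (optionally) a DGGE band list.
#'
#' The true bacterial carbon production underlying the leucine assays is
#' `mu_b_eff * B(t) * cell_carbon`, converted to a leucine incorporation
#' rate by the inverse of the standard leucine-to-carbon factor.
#'
#' @param params A [sim_params()] object.
#' @param label Experiment label.
#' @param treatments Character subset of c("V","VF","VFA").
#' @param replicates Replicates per treatment (default 3, triplicates).
#' @param times Sampling times in hours (default 0, 48, 96).
#' @param assay_days Days at which dilution assays are run (default 0, 2, 4).
#' @param cell_carbon Carbon content per bacterial cell (ug C; default
#'   2e-8, i.e. 20 fg C per cell).
#' @param with_gel Simulate a pooled-replicate DGGE band list?
#' @param seed Optional integer seed (overrides `params$seed`).
#' @return An `experiment_bundle`: list with `label`, `counts`,
#'   `dilution_assays`, `leucine`, `bands` (or NULL) and `truth`.
#' @export
simulate_experiment <- function(params, label = "SIM",
                                treatments = c("V", "VF", "VFA"),
                                replicates = 3, times = c(0, 48, 96),
                                assay_days = c(0, 2, 4),
                                cell_carbon = 2e-8,
                                with_gel = FALSE, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  seed <- if (!is.null(seed)) seed else params$seed
  if (!is.null(seed)) set.seed(seed)
  treatments <- match.arg(treatments, c("V", "VF", "VFA"), several.ok = TRUE)

  counts <- list(); assays <- list(); leu <- list()
  for (tr in treatments) {
    traj <- microcosm_trajectory(params, tr, times)
    for (rep_i in seq_len(replicates)) {
      counts[[length(counts) + 1L]] <-
        .observe_trajectory(traj, params, tr, replicate = rep_i,
                            experiment = label)
      for (day in assay_days) {
        t_h <- day * 24
        idx <- match(t_h, times)
        if (is.na(idx)) next
        state <- traj[idx, c("bacteria", "viruses")]
        assays[[paste(tr, day, rep_i, sep = "_")]] <-
          simulate_dilution_assay(params, state, experiment = label,
                                  treatment = tr, replicate = rep_i)
      }
      # leucine assays: 3 live tubes + 2 killed controls per sampling time
      net <- net_growth_rate(params, tr)
      boost <- (net + params$delta_v + if (tr != "V") params$graze else 0)
      for (idx in seq_along(times)) {
        bp_true <- boost * traj[idx, "bacteria"] * cell_carbon * 1000 / 24
        leu_true <- bp_true / leucine_carbon_factor()
        ctrl_true <- 0.02 * leu_true
        live <- (leu_true + ctrl_true) * .lognorm_noise(3, params$cv_noise)
        ctrl <- ctrl_true * .lognorm_noise(2, params$cv_noise)
        leu[[length(leu) + 1L]] <- data.frame(
          experiment = label, treatment = tr, replicate = rep_i,
          time_h = times[idx],
          role = c(rep("live", 3), rep("control", 2)),
          leucine_pmol = c(live, ctrl), stringsAsFactors = FALSE)
      }
    }
  }

  bands <- NULL
  if (with_gel) {
    lanes <- c("V_0", "V_final",
               if ("VF" %in% treatments) c("VF_0", "VF_final"),
               if ("VFA" %in% treatments) "VFA_final")
    n_phy <- 20
    base <- stats::rexp(n_phy) + 0.05
    profs <- t(vapply(lanes, function(l) {
      p <- base * exp(stats::rnorm(n_phy, 0, 0.6))
      p / sum(p)
    }, numeric(n_phy)))
    rownames(profs) <- lanes
    bands <- simulate_gel(profs, position_jitter = 1)
  }

  structure(list(label = label,
                 counts = do.call(rbind, counts),
                 dilution_assays = assays,
                 leucine = do.call(rbind, leu),
                 bands = bands,
                 truth = params),
            class = "experiment_bundle")
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat("Experiment bundle", x$label, "\n")
  cat(sprintf("  counts: %d rows; dilution assays: %d; leucine rows: %d; gel: %s\n",
              nrow(x$counts), length(x$dilution_assays),
              if (is.null(x$leucine)) 0L else nrow(x$leucine),
              if (is.null(x$bands)) "absent" else "present"))
  invisible(x)
}

#' Tune the enrichment boost to a target stimulation
#'
#' Solves for the `enrich` parameter so that the deterministic relative
#' change of bacterial abundance in the flagellate treatment exceeds the
#' V treatment's by exactly `target_pct` percentage points over the
#' window `[t_start, t_end]` — i.e. the true stimulation equals
#' `target_pct`.
#'
#' @param params Baseline [sim_params()] (its `enrich` is replaced).
#' @param target_pct Target stimulation in percentage points.
#' @param treatment "VF" or "VFA" (the treatment being tuned).
#' @param t_start,t_end Window in hours.
#' @return A `sim_params` object with `enrich` set (for "VFA" the
#'   autotroph boost is kept and enrich absorbs the remainder).
#' @export
params_for_stimulation <- function(params, target_pct, treatment = "VF",
                                   t_start = 0, t_end = 48) {
  stopifnot(inherits(params, "sim_params"))
  treatment <- match.arg(treatment, c("VF", "VFA"))
  T_d <- (t_end - t_start) / 24
  r_v <- params$mu_b - params$delta_v
  growth_target <- exp(r_v * T_d) + target_pct / 100
  if (growth_target <= 0)
    stop("target stimulation is unattainably negative", call. = FALSE)
  r_t <- log(growth_target) / T_d
  boost_total <- (r_t + params$delta_v + params$graze) / params$mu_b - 1
  enrich <- boost_total - if (treatment == "VFA") params$autotroph_boost else 0
  if (enrich < 0)
    stop("required enrich is negative; lower autotroph_boost or graze",
         call. = FALSE)
  out <- unclass(params)
  out$enrich <- enrich
  class(out) <- "sim_params"
  out
}
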