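#' Relative band intensities within a lane
#'
#' The relative intensity of band i is the ratio between the surface of
#' its peak (n_i) and the sum of the surfaces of all peaks in the
#' profile (N). Absent bands (surface 0) stay 0.
#'
#' @param lane_intensities Numeric vector of peak surfaces (>= 0, at
#'   least one positive).
#' @return Vector of P_i summing to 1 over present bands.
#' @export
relative_intensity <- function(lane_intensities) {
  if (any(lane_intensities < 0))
    stop("peak surfaces must be >= 0", call. = FALSE)
  total <- sum(lane_intensities)
  if (total == 0)
    stop("lane has no bands (all surfaces zero)", call. = FALSE)
  lane_intensities / total
}

#' Match raw gel bands across lanes into a band matrix
#'
#' Greedy nearest-position clustering: bands are processed in increasing
#' position order; a band joins the nearest existing canonical band
#' within `tolerance` pixels (ties broken toward the lower canonical
#' position), otherwise it founds a new one. The canonical position is
#' the running mean of member positions. Two bands of the same lane
#' mapping to one canonical band is a quantification conflict and an
#' error.
#'
#' @param raw_lanes Data frame with columns `lane`, `position_px`,
#'   `surface`.
#' @param tolerance Matching tolerance in pixels (> 0; default 5).
#' @return A `band_matrix`: list with `positions` (sorted canonical
#'   positions), `intensity` (lanes x bands surface matrix, 0 = absent)
#'   and `rel_intensity` (per-lane P_i, rows summing to 1).
#' @export
match_bands <- function(raw_lanes, tolerance = 5) {
  stopifnot(is.data.frame(raw_lanes),
            all(c("lane", "position_px", "surface") %in% names(raw_lanes)))
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  ord <- order(raw_lanes$position_px, raw_lanes$lane)
  pos <- raw_lanes$position_px[ord]
  lane <- as.character(raw_lanes$lane[ord])
  surf <- raw_lanes$surface[ord]

  canon_pos <- numeric(0)     # running mean positions
  members <- list()           # indices into sorted input
  for (i in seq_along(pos)) {
    assigned <- FALSE
    if (length(canon_pos)) {
      d <- abs(canon_pos - pos[i])
      ok <- which(d <= tolerance)
      if (length(ok)) {
        # nearest; ties toward the lower canonical position
        best <- ok[order(d[ok], canon_pos[ok])][1]
        mem <- members[[best]]
        if (lane[i] %in% lane[mem])
          stop(sprintf(
            "lane %s has two bands matching one canonical band near %.1f px",
            lane[i], canon_pos[best]), call. = FALSE)
        members[[best]] <- c(mem, i)
        canon_pos[best] <- mean(pos[members[[best]]])
        assigned <- TRUE
      }
    }
    if (!assigned) {
      canon_pos <- c(canon_pos, pos[i])
      members[[length(members) + 1L]] <- i
    }
  }

  band_order <- order(canon_pos)
  lanes <- sort(unique(lane))
  intensity <- matrix(0, nrow = length(lanes), ncol = length(band_order),
                      dimnames = list(lanes, NULL))
  for (j in seq_along(band_order)) {
    mem <- members[[band_order[j]]]
    intensity[cbind(match(lane[mem], lanes), j)] <- surf[mem]
  }
  band_matrix(positions = canon_pos[band_order], intensity = intensity)
}

#' Construct a band matrix
#'
#' @param positions Strictly increasing canonical band positions (px).
#' @param intensity Lanes x bands matrix of peak surfaces (0 = absent),
#'   with lane row names.
#' @return A `band_matrix` object with per-lane relative intensities.
#' @export
band_matrix <- function(positions, intensity) {
  intensity <- as.matrix(intensity)
  if (length(positions) != ncol(intensity))
    stop("positions length must equal the number of band columns",
         call. = FALSE)
  if (is.unsorted(positions, strictly = TRUE))
    stop("canonical positions must be strictly increasing", call. = FALSE)
  if (any(intensity < 0)) stop("surfaces must be >= 0", call. = FALSE)
  if (is.null(rownames(intensity)))
    rownames(intensity) <- paste0("lane", seq_len(nrow(intensity)))
  tot <- rowSums(intensity)
  if (any(tot == 0))
    stop("lane(s) with no bands: ",
         paste(rownames(intensity)[tot == 0], collapse = ", "), call. = FALSE)
  rel <- sweep(intensity, 1, tot, "/")
  structure(list(positions = positions, intensity = intensity,
                 rel_intensity = rel),
            class = "band_matrix")
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf("Band matrix: %d lanes x %d bands (positions %.0f-%.0f px)\n",
              nrow(x$intensity), length(x$positions),
              min(x$positions), max(x$positions)))
  invisible(x)
}

#' Commonality and specificity of bands across treatments
#'
#' A band is counted as present in a treatment if its relative intensity
#' exceeds `floor` in any lane of that treatment (e.g. the t0 and tfinal
#' lanes). The table partitions the bands into: common to all three
#' treatments, specific to exactly one, and shared by exactly two — with
#' the VFA+VF pair (bands resisting or profiting from grazers) reported
#' explicitly. Percentages are rounded to the nearest integer.
#'
#' @param matrix A `band_matrix`.
#' @param lane_to_treatment Named character vector mapping every lane to
#'   "V", "VF" or "VFA".
#' @param floor Detection floor on relative intensity (default 0; set
#'   0.004 to emulate the usual DGGE sensitivity).
#' @return A `commonality_table` list of counts and percentages.
#' @export
commonality_table <- function(matrix, lane_to_treatment, floor = 0) {
  stopifnot(inherits(matrix, "band_matrix"))
  lanes <- rownames(matrix$intensity)
  if (!all(lanes %in% names(lane_to_treatment)))
    stop("unmapped lanes: ",
         paste(setdiff(lanes, names(lane_to_treatment)), collapse = ", "),
         call. = FALSE)
  trts <- c("V", "VF", "VFA")
  if (!all(trts %in% lane_to_treatment[lanes]))
    stop("all three treatments must be represented", call. = FALSE)

  present <- vapply(trts, function(tr) {
    sub <- matrix$rel_intensity[lane_to_treatment[lanes] == tr, ,
                                drop = FALSE]
    apply(sub > floor, 2, any)
  }, logical(length(matrix$positions)))
  if (is.null(dim(present))) present <- matrix(present, nrow = 1,
                                               dimnames = list(NULL, trts))
  total <- sum(apply(present, 1, any))
  n_in <- rowSums(present)
  count <- function(sel) sum(sel)
  counts <- c(
    common_all = count(n_in == 3),
    specific_V = count(present[, "V"] & n_in == 1),
    specific_VF = count(present[, "VF"] & n_in == 1),
    specific_VFA = count(present[, "VFA"] & n_in == 1),
    pair_VFA_VF = count(present[, "VFA"] & present[, "VF"] & !present[, "V"]),
    pair_V_VF = count(present[, "V"] & present[, "VF"] & !present[, "VFA"]),
    pair_V_VFA = count(present[, "V"] & present[, "VFA"] & !present[, "VF"]))
  structure(list(total = total,
                 per_treatment = colSums(present),
                 counts = counts,
                 percent = round(100 * counts / total)),
            class = "commonality_table")
}

#' @export
print.commonality_table <- function(x, ...) {
  cat("Total distinct bands:", x$total, "\n")
  cat("Per treatment:", paste(names(x$per_treatment), x$per_treatment,
                              sep = "=", collapse = "  "), "\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-13s %2d (%d%%)\n", nm, x$counts[[nm]], x$percent[[nm]]))
  invisible(x)
}

#' Bray-Curtis similarity between two band profiles
#'
#' `1 - sum(|p_i - q_i|) / sum(p_i + q_i)` on a shared matched band set.
#' Identical profiles give 1, profiles with disjoint band sets give 0.
#'
#' @param p,q Numeric vectors (relative intensities) on the same matched
#'   band set.
#' @return Similarity in [0, 1].
#' @export
bray_curtis_similarity <- function(p, q) {
  if (length(p) != length(q)) stop("profile lengths differ", call. = FALSE)
  if (any(p < 0) || any(q < 0)) stop("intensities must be >= 0", call. = FALSE)
  denom <- sum(p + q)
  if (denom == 0)
    stop("both profiles are all-zero; similarity undefined", call. = FALSE)
  1 - sum(abs(p - q)) / denom
}

#' Pairwise Bray-Curtis similarity matrix of gel lanes
#'
#' @param matrix A `band_matrix`.
#' @return Symmetric lanes x lanes similarity matrix with unit diagonal.
#' @export
similarity_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "band_matrix"))
  rel <- matrix$rel_intensity
  n <- nrow(rel)
  sim <- diag(1, n)
  dimnames(sim) <- list(rownames(rel), rownames(rel))
  if (n > 1)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      sim[i, j] <- sim[j, i] <- bray_curtis_similarity(rel[i, ], rel[j, ])
  sim
}

#' UPGMA clustering of gel lanes by Bray-Curtis dissimilarity
#'
#' Average-linkage (UPGMA) agglomeration on `1 - similarity`. The
#' dendrogram is deterministic; lanes are ordered by label before
#' clustering so ties resolve by label order.
#'
#' @param matrix A `band_matrix` with >= 2 lanes.
#' @return List with `hclust` (the stats::hclust tree), `phylo` (ape
#'   tree with branch lengths = half the cophenetic distance) and
#'   `newick` (serialized phylo).
#' @export
cluster_lanes <- function(matrix) {
  stopifnot(inherits(matrix, "band_matrix"))
  if (nrow(matrix$intensity) < 2)
    stop("need at least 2 lanes to cluster", call. = FALSE)
  sim <- similarity_matrix(matrix)
  ord <- order(rownames(sim))
  d <- stats::as.dist(1 - sim[ord, ord])
  hc <- stats::hclust(d, method = "average")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, phylo = phy, newick = ape::write.tree(phy))
}

#' Synthetic band matrix with a prescribed commonality partition
#'
#' Builds a lanes x bands matrix whose treatment-level presence pattern
#' has exactly the requested numbers of bands common to all three
#' treatments, specific to each single treatment, and shared by each
#' pair. Useful for encoding published band tallies as a concrete
#' fixture (the resulting gel is synthetic; only the partition is real).
#'
#' @param common_all,specific_v,specific_vf,specific_vfa Counts.
#' @param pair_vfa_vf,pair_v_vf,pair_v_vfa Counts for two-treatment
#'   bands.
#' @return A `band_matrix` with one lane per treatment (lanes named
#'   `V`, `VF`, `VFA`) and unit surfaces.
#' @export
band_partition_fixture <- function(common_all, specific_v = 0,
                                   specific_vf = 0, specific_vfa = 0,
                                   pair_vfa_vf = 0, pair_v_vf = 0,
                                   pair_v_vfa = 0) {
  blocks <- list(
    c(TRUE, TRUE, TRUE),   # common to all
    c(TRUE, FALSE, FALSE), # V only
    c(FALSE, TRUE, FALSE), # VF only
    c(FALSE, FALSE, TRUE), # VFA only
    c(FALSE, TRUE, TRUE),  # VF + VFA
    c(TRUE, TRUE, FALSE),  # V + VF
    c(TRUE, FALSE, TRUE))  # V + VFA
  n <- c(common_all, specific_v, specific_vf, specific_vfa,
         pair_vfa_vf, pair_v_vf, pair_v_vfa)
  pres <- do.call(rbind, rep(blocks, times = n))
  total <- nrow(pres)
  intensity <- t(pres) * 1
  rownames(intensity) <- c("V", "VF", "VFA")
  band_matrix(positions = 10 * seq_len(total), intensity = intensity)
}
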