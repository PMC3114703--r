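#!/usr/bin/env Rscript
# DGGE fingerprint analytics: band matching, commonality/specificity
# tallies (simulated gels and the published tallies), Bray-Curtis
# similarity and UPGMA dendrograms.

suppressPackageStartupMessages(library(microloop))

labels <- c("LA1", "LA2", "LB1", "LB2")
for (lab in labels) {
  b <- read_bundle(file.path("results", "sim", lab))
  if (is.null(b$bands)) next
  bm <- match_bands(b$bands, tolerance = 5)
  lanes <- rownames(bm$intensity)
  lane_map <- setNames(sub("_.*$", "", lanes), lanes)
  sim <- similarity_matrix(bm)
  write.csv(sim, file.path("results", paste0("similarity_", lab, ".csv")))
  tree <- cluster_lanes(bm)
  writeLines(tree$newick, file.path("results", paste0("tree_", lab, ".nwk")))
  cat(sprintf("%s: %d matched bands across %d lanes; min similarity %.2f\n",
              lab, length(bm$positions), nrow(sim), min(sim)))
}

cat("\nPublished band tallies, recomputed through the commonality table:\n")
fx <- band_fixtures_from_partitions()
lane_map <- setNames(c("V", "VF", "VFA"), c("V", "VF", "VFA"))
tab <- do.call(rbind, lapply(names(fx), function(lab) {
  ct <- commonality_table(fx[[lab]], lane_map)
  data.frame(experiment = lab, total = ct$total,
             common_pct = ct$percent[["common_all"]],
             v_specific_pct = ct$percent[["specific_V"]],
             vfa_vf_pct = ct$percent[["pair_VFA_VF"]])
}))
print(tab, row.names = FALSE)
write.csv(tab, file.path("results", "commonality_observed.csv"),
          row.names = FALSE)
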