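#!/usr/bin/env Rscript
# Viral production from the 0-24 h dilution assays, converted to lysed
# cells (burst size 27) and per-capita lysis mortality.

suppressPackageStartupMessages(library(microloop))

labels <- c("LA1", "LA2", "LB1", "LB2")
lysis <- do.call(rbind, lapply(labels, function(lab) {
  b <- read_bundle(file.path("results", "sim", lab))
  viral_activity_table(b$dilution_assays, burst_size = 27)
}))
write.csv(lysis, file.path("results", "lysis.csv"), row.names = FALSE)

summ <- aggregate(cbind(vp, mortality) ~ experiment + treatment, lysis, mean)
summ <- summ[order(summ$experiment, summ$treatment), ]
cat("Mean viral production (virus ml^-1 h^-1) and lysis mortality (d^-1):\n")
print(data.frame(summ[c("experiment", "treatment")],
                 vp = signif(summ$vp, 3),
                 mortality = round(summ$mortality, 2)), row.names = FALSE)

pos <- 0L
for (lab in labels) {
  s <- summ[summ$experiment == lab, ]
  v <- s$vp[s$treatment == "V"]
  rel <- 100 * (s$vp[s$treatment %in% c("VF", "VFA")] - v) / v
  pos <- pos + sum(rel > 0)
  cat(sprintf("%s: VP in VF %+.0f%%, VFA %+.0f%% relative to V\n", lab,
              100 * (s$vp[s$treatment == "VF"] - v) / v,
              100 * (s$vp[s$treatment == "VFA"] - v) / v))
}
cat(sprintf("Viral production exceeds the V treatment in %d of %d grazer cells.\n",
            pos, 2L * length(labels)))
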