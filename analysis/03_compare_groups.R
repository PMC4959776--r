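#!/usr/bin/env Rscript
# Compare proliferation indices across genotypes with unpaired two-sided
# Student's t tests against the two reference conditions (driver-only
# control and apoptosis-inhibited baseline), annotate significance stars,
# and draw the group bar plot.

suppressPackageStartupMessages(library(wingquant))

res <- read.csv("results/quantification.csv")

cmp <- compare_all(res, reference_groups = c("driver>GFP", "driver>P35"))
write.csv(as.data.frame(cmp), "results/comparisons.csv", row.names = FALSE)

cat("Group comparisons (no multiple-testing correction, as is conventional",
    "for this assay):\n")
print(cbind(cmp[, c("group_a", "reference", "n_a", "n_b")],
            round(cmp[, c("mean_a", "mean_b", "t_stat", "p_value")], 4),
            stars = cmp$stars))

png("results/index_barplot.png", width = 900, height = 700, res = 120)
op <- par(mar = c(11, 5, 2, 1))
plot_group_indices(res, cmp)
par(op)
invisible(dev.off())
cat("Wrote results/comparisons.csv and results/index_barplot.png\n")
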