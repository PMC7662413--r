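#!/usr/bin/env Rscript
# Stage 5: deprivation-assignment sensitivity. The surveillance world is
# refitted with a perturbed decile vintage (a fraction of areas moved one
# decile, emulating a re-based deprivation index) and the two detection
# surfaces are compared cell by cell.

library(stmort)

outdir <- "results/analysis"

data <- read_mortality_table(file.path(outdir, "surveillance.csv"),
                             "female")
graph <- read_region_graph(file.path(outdir, "surveillance_graph.txt"))
s_a <- fit(data, graph,
           model_config(chains = 2, burnin = 1500, iter = 750, seed = 311))

# alternative decile vintage: move ~20% of areas one decile (clamped)
set.seed(321)
data_b <- data
shift_areas <- sample(length(data$area_ids),
                      round(0.2 * length(data$area_ids)))
dec_b <- data$decile
dec_b[shift_areas] <- pmin(10L, pmax(1L, dec_b[shift_areas] +
                                       sample(c(-1L, 1L), length(shift_areas),
                                              replace = TRUE)))
data_b$decile <- dec_b
s_b <- fit(data_b, graph,
           model_config(chains = 2, burnin = 1500, iter = 750, seed = 311))

cmp <- sensitivity_compare(s_a, s_b, threshold = 0.95, window = 2012:2018)
write_table(cmp$table, file.path(outdir, "sensitivity_table.csv"))
write_table(cmp$summary, file.path(outdir, "sensitivity_summary.csv"))

cat(sprintf("areas re-allocated to a neighbouring decile: %d of %d\n",
            length(shift_areas), length(data$area_ids)))
print(cmp$summary)
moved_ids <- data$area_ids[shift_areas]
only_b <- cmp$table[cmp$table$class == "only-B", ]
cat(sprintf("flags unique to the perturbed vintage: %d, of which %d belong to re-allocated areas\n",
            nrow(only_b), sum(only_b$area %in% moved_ids)))
cat("finding: when decile effects and decile-time trends are strong, a\n",
    "changed vintage shifts every area's decile-trend reference, so the\n",
    "space-time term absorbs the mismatch and detection becomes vintage-\n",
    "sensitive; the discrepancy table quantifies exactly which area-years\n",
    "move in or out of the flagged set\n")
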