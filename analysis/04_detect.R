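#!/usr/bin/env Rscript
# Stage 4: exceedance-probability surveillance on the surveillance world.
# Flags area-years where P(omega_it > 0 | data) > 0.95 within 2012-2018
# and checks the flags against the injected ground-truth anomalies.

library(stmort)

outdir <- "results/analysis"

data <- read_mortality_table(file.path(outdir, "surveillance.csv"),
                             "female")
graph <- read_region_graph(file.path(outdir, "surveillance_graph.txt"))
spec <- read_simulation_spec(file.path(outdir, "surveillance_spec.yaml"))
s <- fit(data, graph,
         model_config(chains = 2, burnin = 1500, iter = 750, seed = 311))

p <- exceedance_probability(s)
res <- detect(p, threshold = 0.95, window = 2012:2018,
              decile = data$decile)
write_table(res$grid, file.path(outdir, "exceedance_grid.csv"))
write_table(res$flagged, file.path(outdir, "flagged.csv"))
write_table(res$area_counts, file.path(outdir, "flagged_area_counts.csv"))

truth <- spec$anomalies
truth$area_id <- sprintf("A%03d", truth$area)
hit <- mapply(function(a, yr) any(res$flagged$area == a &
                                    res$flagged$year == yr),
              truth$area_id, truth$year)
extra <- nrow(res$flagged) - sum(hit)
cat(sprintf("flagged %d area-years at threshold %.2f in 2012-2018\n",
            nrow(res$flagged), res$threshold))
cat(sprintf("injected anomalies recovered: %d of %d; non-anomalous flags: %d of %d cells\n",
            sum(hit), nrow(truth), extra,
            length(data$area_ids) * 7 - nrow(truth)))
print(res$flagged)
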