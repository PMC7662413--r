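#!/usr/bin/env Rscript
# Stage 1: build the synthetic study worlds.
#
# Two datasets are generated per sex-like arm:
#   - a surveillance world at the desk-scale defaults (10x10 lattice,
#     10 age groups, 2009-2018) with four injected area-year anomalies of
#     +0.3 on the log scale, used for detection;
#   - a life-expectancy world on the full 20-group age grid with a flat
#     1/80 hazard and modest decile/year effects, used for the life-table
#     and gap analyses.
# Everything is written in the package's plain-text formats under
# results/analysis/.

library(stmort)

outdir <- "results/analysis"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

anomalies <- data.frame(area = c(5, 23, 57, 88),
                        year = c(2013, 2015, 2016, 2018), shift = 0.3)
spec_surv <- simulation_spec(seed = 301, anomalies = anomalies)
sim_surv <- simulate_dataset(spec_surv)
write_mortality_table(sim_surv$data, file.path(outdir, "surveillance.csv"))
write_region_graph(sim_surv$graph, file.path(outdir, "surveillance_graph.txt"))
write_simulation_spec(spec_surv, file.path(outdir, "surveillance_spec.yaml"))

spec_e0 <- simulation_spec(
  J = 20, a0 = log(1 / 80),
  tau = c(alpha = 1e12, gamma = 100, zeta = 400, phi = 400, omega = 1e4,
          delta = 400, kappa = 1e12, nu = 1e12),
  seed = 302)
sim_e0 <- simulate_dataset(spec_e0)
write_mortality_table(sim_e0$data, file.path(outdir, "lifeexp.csv"))
write_region_graph(sim_e0$graph, file.path(outdir, "lifeexp_graph.txt"))
write_simulation_spec(spec_e0, file.path(outdir, "lifeexp_spec.yaml"))

cat(sprintf(
  "surveillance world: %d areas, %d age groups, years %d-%d, %d anomalies injected\n",
  length(sim_surv$data$area_ids), length(sim_surv$data$age_groups),
  min(sim_surv$data$years), max(sim_surv$data$years), nrow(anomalies)))
cat(sprintf(
  "life-expectancy world: %d age groups, crude rate %.4f (flat hazard 1/80)\n",
  length(sim_e0$data$age_groups),
  sum(sim_e0$data$deaths) / sum(sim_e0$data$population)))
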