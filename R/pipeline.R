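#' Run the full analysis pipeline from a config file
#'
#' Executes simulate (or load) -> fit -> life tables -> detect -> report
#' from a single YAML config, writing every stage's outputs and a run
#' manifest (config snapshot, seeds, file digests, per-stage status) to the
#' output directory. Stages fail with a stage-labelled error; outputs of
#' completed stages are retained.
#'
#' The config has top-level keys:
#' \describe{
#'   \item{simulation}{keys of [simulation_spec()], used when no `data`
#'     key is present;}
#'   \item{data}{optional `csv` and `graph` paths for pre-existing inputs
#'     plus `sex`;}
#'   \item{model}{keys of [model_config()];}
#'   \item{detection}{`threshold` and `window` (two-element year range);}
#'   \item{gap}{`period_a`, `period_b` year vectors.}
#' }
#'
#' @param config_path path to the YAML config.
#' @param outdir output directory (created if needed).
#' @return the run manifest, invisibly (also written as `manifest.json`
#'   when jsonlite is installed, else `manifest.yaml`).
#' @export
run_pipeline <- function(config_path, outdir = "results") {
  cfg <- yaml::read_yaml(config_path)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg,
                   package_version =
                     as.character(utils::packageVersion("stmort")),
                   started = as.character(Sys.time()),
                   stages = list(), outputs = list())
  out <- function(name) file.path(outdir, name)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- "ok"
    res
  }

  sim <- NULL
  if (!is.null(cfg$data)) {
    data <- stage("load", read_mortality_table(cfg$data$csv,
                                               cfg$data$sex %||% "female"))
    graph <- stage("load_graph", read_region_graph(cfg$data$graph))
  } else {
    spec <- stage("simulate", do.call(simulation_spec, cfg$simulation))
    sim <- stage("simulate", simulate_dataset(spec))
    data <- sim$data
    graph <- sim$graph
    write_mortality_table(data, out("dataset.csv"))
    write_region_graph(graph, out("graph.txt"))
    truth_flat <- data.frame(component = "a0", index = "1",
                             value = sim$truth$a0)
    for (k in c("alpha", "gamma", "zeta", "phi", "omega", "delta",
                "kappa", "nu")) {
      v <- sim$truth[[k]]
      truth_flat <- rbind(truth_flat, data.frame(
        component = k, index = as.character(seq_along(v)),
        value = as.vector(v)))
    }
    write_table(truth_flat, out("ground_truth.csv"))
  }

  mc <- do.call(model_config, cfg$model %||% list())
  samples <- stage("fit", fit(data, graph, mc))
  if (mc$chains >= 2) {
    diag <- stage("fit", convergence_report(samples))
    write_table(diag, out("convergence.csv"))
  }

  ltc <- lifetable_config(data$age_groups)
  e0_area_arr <- stage("lifetable", e0_posterior(samples, data, ltc, "area"))
  e0_dec_arr <- stage("lifetable", e0_posterior(samples, data, ltc, "decile"))
  write_table(summarize_e0(e0_area_arr, data$sex, "area"),
              out("e0_area_year.csv"))
  write_table(summarize_e0(e0_dec_arr, data$sex, "decile"),
              out("e0_decile_year.csv"))
  gap_cfg <- cfg$gap %||% list(period_a = c(2012, 2013),
                               period_b = c(2017, 2018))
  years <- data$years
  if (all(unlist(gap_cfg) %in% years)) {
    gap <- stage("lifetable",
                 e0_gap(e0_dec_arr, unlist(gap_cfg$period_a),
                        unlist(gap_cfg$period_b)))
    write_table(gap, out("e0_gap_decile.csv"))
  }

  det_cfg <- cfg$detection %||% list()
  threshold <- det_cfg$threshold %||% 0.95
  window <- if (!is.null(det_cfg$window))
    seq(det_cfg$window[[1]], det_cfg$window[[2]]) else 2012:2018
  if (!any(window %in% years))
    stop("[stage detect] detection window outside dataset years",
         call. = FALSE)
  p <- stage("detect", exceedance_probability(samples))
  res <- stage("detect", detect(p, threshold, window, data$decile))
  write_table(res$grid, out("exceedance_grid.csv"))
  write_table(res$flagged, out("flagged.csv"))
  write_table(res$area_counts, out("flagged_area_counts.csv"))

  files <- list.files(outdir, pattern = "\\.(csv|txt)$", full.names = TRUE)
  manifest$outputs <- as.list(tools::md5sum(files))
  manifest$finished <- as.character(Sys.time())
  manifest$seed <- mc$seed
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)
  } else {
    yaml::write_yaml(manifest, out("manifest.yaml"))
  }
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the canonical small test fixtures
#'
#' Deterministic, byte-identical on every call: a tiny long-format
#' mortality CSV (2 areas x 3 age groups x 2 years, both sexes), the
#' matching 2-node region graph, and a degenerate posterior omega-draw
#' table with S = 4 draws whose exceedance probabilities are computable by
#' hand.
#'
#' @param out_dir writable directory (created if needed).
#' @return character vector of paths written, invisibly.
#' @export
make_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ages <- c("0-0", "1-4", "5+")
  grid <- expand.grid(area = c("A1", "A2"), age_group = ages,
                      year = 2017:2018, sex = c("female", "male"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # deterministic counts: a simple function of the row's indices
  grid$population <- 1000 + 100 * match(grid$age_group, ages) +
    10 * (grid$year - 2017) + ifelse(grid$area == "A2", 5, 0)
  grid$deaths <- (match(grid$age_group, ages) +
                    (grid$year - 2017) + ifelse(grid$sex == "male", 1, 0))
  grid$decile <- ifelse(grid$area == "A1", 1L, 10L)
  csv <- file.path(out_dir, "tiny_mortality.csv")
  utils::write.csv(grid[, c("area", "age_group", "year", "sex", "deaths",
                            "population", "decile")],
                   csv, row.names = FALSE, quote = FALSE)

  gpath <- file.path(out_dir, "tiny_graph.txt")
  writeLines(c("2", "1 1 2", "2 1 1"), gpath)

  # 4 draws x 2 areas x 2 years omega fixture; exceedance by hand:
  # A1/2017: {1,1,1,1} -> 1; A1/2018: {-1,1,-1,1} -> 0.5
  # A2/2017: {-2,-1,0,1} -> 0.25; A2/2018: {-1,-1,-1,-1} -> 0
  om <- expand.grid(draw = 1:4, area = c("A1", "A2"), year = 2017:2018,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  om$omega <- c(1, 1, 1, 1, -2, -1, 0, 1, -1, 1, -1, 1, -1, -1, -1, -1)
  opath <- file.path(out_dir, "tiny_omega_draws.csv")
  utils::write.csv(om, opath, row.names = FALSE, quote = FALSE)
  invisible(c(csv, gpath, opath))
}

#' Load the omega-draw fixture as an S x I x T array
#'
#' @param path CSV written by [make_fixtures()] (long format with columns
#'   draw, area, year, omega).
#' @return S x I x T array with dimnames.
#' @export
read_omega_draws <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  draws <- sort(unique(df$draw))
  areas <- unique(df$area)
  years <- sort(unique(df$year))
  arr <- array(NA_real_, dim = c(length(draws), length(areas),
                                 length(years)),
               dimnames = list(NULL, areas, years))
  for (r in seq_len(nrow(df)))
    arr[match(df$draw[r], draws), df$area[r], as.character(df$year[r])] <-
      df$omega[r]
  if (any(is.na(arr))) stop("incomplete omega draw table", call. = FALSE)
  arr
}
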