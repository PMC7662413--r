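#' Posterior exceedance probabilities of the space-time interaction
#'
#' p_it = fraction of posterior draws with omega_it strictly above zero.
#' A draw exactly at zero counts as non-exceeding.
#'
#' @param omega an S x I x T array of omega draws (e.g. [omega_draws()]),
#'   or a `posterior_samples` object.
#' @return I x T matrix of probabilities with the array's dimnames.
#' @export
exceedance_probability <- function(omega) {
  if (inherits(omega, "posterior_samples")) omega <- omega_draws(omega)
  if (length(dim(omega)) != 3 || dim(omega)[1] < 1)
    stop("need an S x I x T array with S >= 1", call. = FALSE)
  apply(omega > 0, c(2, 3), mean)
}

#' Flag area-years with unexplained excess mortality
#'
#' Flags exactly the (area, year) pairs whose exceedance probability is
#' strictly above the threshold and whose calendar year lies in the
#' detection window. Reports the full grid, the flagged pairs with their
#' deciles, and per-area counts of flagged years.
#'
#' @param p I x T exceedance-probability matrix (areas x years, with year
#'   dimnames as calendar labels).
#' @param threshold detection threshold in (0, 1); default 0.95, strict
#'   inequality.
#' @param window calendar years to restrict detection to; default
#'   2012-2018.
#' @param decile optional named decile vector per area for reporting.
#' @return object of class `detection_result` with fields `grid` (long
#'   data.frame: area, year, exceedance_probability, flagged), `flagged`
#'   (area, decile, year, probability), `area_counts`, `threshold`,
#'   `window`.
#' @export
detect <- function(p, threshold = 0.95, window = 2012:2018, decile = NULL) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  if (length(window) == 0) stop("empty detection window", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("probabilities outside [0, 1]", call. = FALSE)
  areas <- rownames(p)
  if (is.null(areas)) areas <- as.character(seq_len(nrow(p)))
  years <- suppressWarnings(as.integer(colnames(p)))
  if (any(is.na(years))) years <- seq_len(ncol(p))
  grid <- expand.grid(area = areas, year = years, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$exceedance_probability <- as.vector(p)
  grid$flagged <- grid$exceedance_probability > threshold &
    grid$year %in% window
  fl <- grid[grid$flagged, c("area", "year", "exceedance_probability")]
  names(fl)[3] <- "probability"
  fl$decile <- if (!is.null(decile)) unname(decile[fl$area]) else
    rep(NA_integer_, nrow(fl))
  fl <- fl[order(fl$decile, fl$area, fl$year),
           c("area", "decile", "year", "probability")]
  rownames(fl) <- NULL
  counts <- if (nrow(fl) > 0) {
    cnt <- as.data.frame(table(area = fl$area), stringsAsFactors = FALSE)
    names(cnt)[2] <- "n_years_flagged"
    cnt$decile <- if (!is.null(decile)) unname(decile[cnt$area]) else
      NA_integer_
    cnt[order(-cnt$n_years_flagged, cnt$area), ]
  } else {
    data.frame(area = character(0), n_years_flagged = integer(0),
               decile = integer(0))
  }
  rownames(counts) <- NULL
  structure(list(grid = grid, flagged = fl, area_counts = counts,
                 threshold = threshold, window = window),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("detection_result: %d flagged area-year(s) at threshold %g in window %d-%d\n",
              nrow(x$flagged), x$threshold, min(x$window), max(x$window)))
  if (nrow(x$flagged) > 0) print(utils::head(x$flagged, 20))
  invisible(x)
}

#' Compare detections under two deprivation-decile assignments
#'
#' Both fits must cover the same areas and years; typically they differ
#' only in the decile vintage used (e.g. two editions of a deprivation
#' index). Every area-year is classified as flagged by both fits, only the
#' first, only the second, or neither.
#'
#' @param samples_a,samples_b `posterior_samples` from two fits of the same
#'   data.
#' @param threshold,window as in [detect()].
#' @return list with `table` (area, year, p_a, p_b, flag_a, flag_b,
#'   class) and `summary` (count per discrepancy class plus unique areas
#'   detected by each fit only).
#' @export
sensitivity_compare <- function(samples_a, samples_b, threshold = 0.95,
                                window = 2012:2018) {
  if (!identical(samples_a$meta$area_ids, samples_b$meta$area_ids) ||
      !identical(samples_a$meta$years, samples_b$meta$years))
    stop("fits cover different areas or years", call. = FALSE)
  pa <- exceedance_probability(samples_a)
  pb <- exceedance_probability(samples_b)
  da <- detect(pa, threshold, window, samples_a$meta$decile)
  db <- detect(pb, threshold, window, samples_b$meta$decile)
  tab <- da$grid[, c("area", "year")]
  tab$p_a <- da$grid$exceedance_probability
  tab$p_b <- db$grid$exceedance_probability
  tab$flag_a <- da$grid$flagged
  tab$flag_b <- db$grid$flagged
  tab$class <- ifelse(tab$flag_a & tab$flag_b, "both",
               ifelse(tab$flag_a, "only-A",
               ifelse(tab$flag_b, "only-B", "neither")))
  summary <- data.frame(
    class = c("both", "only-A", "only-B", "neither"),
    n_area_years = vapply(c("both", "only-A", "only-B", "neither"),
                          function(k) sum(tab$class == k), integer(1)))
  summary$n_unique_areas <- vapply(summary$class, function(k)
    length(unique(tab$area[tab$class == k])), integer(1))
  list(table = tab, summary = summary)
}
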