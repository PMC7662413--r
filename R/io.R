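#' Parse age-group labels into intervals
#'
#' Labels follow the national-statistics convention: `"0-0"` is the infant
#' group `[0, 1)`, `"a-b"` covers whole years `a` to `b` (interval
#' `[a, b + 1)`), and a trailing `"x+"` label is the open-ended last group.
#'
#' @param labels character vector of age-group labels.
#' @return data.frame with columns `label`, `lower`, `upper` (NA for the
#'   open-ended group) and `width` (Inf for the open-ended group), ordered
#'   as given.
#' @keywords internal
parse_age_groups <- function(labels) {
  lower <- upper <- numeric(length(labels))
  for (k in seq_along(labels)) {
    lab <- labels[k]
    if (grepl("^[0-9]+\\+$", lab)) {
      lower[k] <- as.numeric(sub("\\+$", "", lab))
      upper[k] <- NA_real_
    } else if (grepl("^[0-9]+-[0-9]+$", lab)) {
      parts <- as.numeric(strsplit(lab, "-", fixed = TRUE)[[1]])
      lower[k] <- parts[1]
      upper[k] <- parts[2] + 1
    } else {
      stop("unparseable age-group label: '", lab, "'", call. = FALSE)
    }
  }
  data.frame(label = labels, lower = lower, upper = upper,
             width = ifelse(is.na(upper), Inf, upper - lower),
             stringsAsFactors = FALSE)
}

#' Construct and validate a mortality dataset
#'
#' Bundles death counts and person-years of exposure on a dense
#' area x age-group x year grid for one sex, together with the deprivation
#' decile of each area. This is the container every downstream stage
#' (model fitting, life tables, detection) consumes.
#'
#' @param area_ids character vector of unique area identifiers (length I).
#' @param age_groups character vector of age-group labels, ordered,
#'   contiguous, starting at `"0-0"` and ending with an open-ended group
#'   such as `"90+"` (length J).
#' @param years integer vector of consecutive calendar years (length T).
#' @param sex `"female"` or `"male"`.
#' @param deaths integer array of dimension I x J x T.
#' @param population non-negative numeric array of dimension I x J x T
#'   (person-years at risk).
#' @param decile named integer vector (names = `area_ids`) of deprivation
#'   deciles in 1..10, 1 = most deprived.
#' @return An object of class `mortality_dataset`.
#' @export
mortality_dataset <- function(area_ids, age_groups, years, sex,
                              deaths, population, decile) {
  dn <- list(as.character(area_ids), as.character(age_groups),
             as.character(years))
  if (length(dim(deaths)) == 3) dimnames(deaths) <- dn
  if (length(dim(population)) == 3) dimnames(population) <- dn
  x <- structure(
    list(area_ids = as.character(area_ids),
         age_groups = as.character(age_groups),
         age_table = parse_age_groups(as.character(age_groups)),
         years = as.integer(years),
         sex = match.arg(sex, c("female", "male")),
         deaths = deaths, population = population,
         decile = decile[as.character(area_ids)]),
    class = "mortality_dataset")
  validate_mortality_dataset(x)
}

#' Validate a mortality dataset
#'
#' Checks the structural invariants: dense tensors of matching shape,
#' non-negative integer deaths, non-negative population, no deaths where
#' exposure is zero, consecutive years, contiguous age intervals beginning
#' at `[0,1)` and ending open-ended, and a decile in 1..10 for every area.
#'
#' @param x a `mortality_dataset`.
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_mortality_dataset <- function(x) {
  I <- length(x$area_ids); J <- length(x$age_groups); T <- length(x$years)
  if (anyDuplicated(x$area_ids)) stop("duplicate area ids", call. = FALSE)
  if (!identical(dim(x$deaths), c(I, J, T)) ||
      !identical(dim(x$population), c(I, J, T)))
    stop("deaths/population tensors must be I x J x T", call. = FALSE)
  if (any(is.na(x$deaths)) || any(x$deaths < 0) ||
      any(x$deaths != round(x$deaths)))
    stop("deaths must be non-negative integers", call. = FALSE)
  if (any(is.na(x$population)) || any(x$population < 0))
    stop("population must be non-negative", call. = FALSE)
  bad <- which(x$population == 0 & x$deaths > 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("deaths > 0 with zero population at (area %s, age %s, year %s)",
                 x$area_ids[bad[1, 1]], x$age_groups[bad[1, 2]],
                 x$years[bad[1, 3]]), call. = FALSE)
  if (T > 1 && any(diff(x$years) != 1L))
    stop("years must be consecutive", call. = FALSE)
  at <- x$age_table
  if (at$lower[1] != 0 || is.na(at$upper[1]) || at$upper[1] != 1)
    stop("first age group must be [0,1), labelled '0-0'", call. = FALSE)
  if (!is.na(at$upper[J]))
    stop("last age group must be open-ended ('x+')", call. = FALSE)
  if (J > 1 && any(at$lower[-1] != at$upper[-J], na.rm = TRUE))
    stop("age groups must be contiguous and ordered", call. = FALSE)
  dec <- x$decile
  if (length(dec) != I || any(is.na(dec)) || any(dec < 1 | dec > 10) ||
      any(dec != round(dec)))
    stop("every area needs one decile in 1..10", call. = FALSE)
  invisible(x)
}

#' @export
print.mortality_dataset <- function(x, ...) {
  cat(sprintf("mortality_dataset: %d areas x %d age groups x %d years (%s)\n",
              length(x$area_ids), length(x$age_groups), length(x$years),
              x$sex))
  cat(sprintf("  years %d-%d; %d deaths; %.3g person-years\n",
              min(x$years), max(x$years), sum(x$deaths), sum(x$population)))
  invisible(x)
}

#' Read a long-format mortality table
#'
#' Reads a CSV with columns `area, age_group, year, sex, deaths, population,
#' decile` (one row per area x age group x year x sex) and returns the dense
#' validated dataset for one sex. Every combination of area, age group and
#' year must be present: a missing cell is an error, never a silent zero.
#'
#' @param path path to the CSV file.
#' @param sex which sex to extract, `"female"` or `"male"`.
#' @return a [mortality_dataset()].
#' @export
read_mortality_table <- function(path, sex = c("female", "male")) {
  sex <- match.arg(sex)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("area", "age_group", "year", "sex", "deaths", "population", "decile")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  df <- df[df$sex == sex, , drop = FALSE]
  if (nrow(df) == 0) stop("no rows for sex '", sex, "'", call. = FALSE)

  area_ids <- unique(df$area)
  age_labels <- unique(df$age_group)
  # order age groups by lower bound, not file order
  at <- parse_age_groups(age_labels)
  age_labels <- age_labels[order(at$lower)]
  years <- sort(unique(as.integer(df$year)))

  key <- paste(df$area, df$age_group, df$year, sep = "\r")
  if (anyDuplicated(key)) {
    k <- key[duplicated(key)][1]
    stop("duplicate row for (", gsub("\r", ", ", k, fixed = TRUE), ")",
         call. = FALSE)
  }
  I <- length(area_ids); J <- length(age_labels); T <- length(years)
  full <- expand.grid(area = area_ids, age_group = age_labels, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fkey <- paste(full$area, full$age_group, full$year, sep = "\r")
  absent <- setdiff(fkey, key)
  if (length(absent) > 0)
    stop("missing cell for (", gsub("\r", ", ", absent[1], fixed = TRUE),
         ")", call. = FALSE)

  idx <- match(fkey, key)
  deaths <- array(as.numeric(df$deaths[idx]), dim = c(I, J, T),
                  dimnames = list(area_ids, age_labels, years))
  population <- array(as.numeric(df$population[idx]), dim = c(I, J, T),
                      dimnames = list(area_ids, age_labels, years))

  dec_by_area <- tapply(df$decile, df$area, function(v) unique(v))
  if (any(lengths(dec_by_area) != 1))
    stop("area with inconsistent decile assignment", call. = FALSE)
  decile <- vapply(dec_by_area, as.integer, integer(1))[area_ids]
  names(decile) <- area_ids

  mortality_dataset(area_ids, age_labels, years, sex, deaths, population,
                    decile)
}

#' Construct a region adjacency graph
#'
#' @param nb list of integer vectors; `nb[[i]]` are the (1-based) neighbours
#'   of node i. Must be symmetric, without self-loops.
#' @param ids optional character node labels.
#' @return object of class `region_graph` with elements `n`, `nb`, `ids`.
#' @export
region_graph <- function(nb, ids = NULL) {
  n <- length(nb)
  nb <- lapply(nb, function(v) sort(as.integer(v)))
  for (i in seq_len(n)) {
    v <- nb[[i]]
    if (anyDuplicated(v)) stop("duplicate neighbour for node ", i, call. = FALSE)
    if (any(v < 1 | v > n)) stop("neighbour index out of range at node ", i,
                                 call. = FALSE)
    if (any(v == i)) stop("self-loop at node ", i, call. = FALSE)
    for (j in v) if (!(i %in% nb[[j]]))
      stop("asymmetric adjacency: ", i, " lists ", j,
           " but not vice versa", call. = FALSE)
  }
  if (is.null(ids)) ids <- as.character(seq_len(n))
  structure(list(n = n, nb = nb, ids = as.character(ids)),
            class = "region_graph")
}

#' @export
print.region_graph <- function(x, ...) {
  cat(sprintf("region_graph: %d nodes, %d edges, %d component(s)\n",
              x$n, sum(lengths(x$nb)) / 2, n_components(x)))
  invisible(x)
}

#' Connected components of a region graph
#'
#' @param graph a `region_graph`.
#' @return integer vector of component labels (1-based) per node.
#' @export
graph_components <- function(graph) {
  n <- graph$n
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in graph$nb[[v]]) if (comp[w] == 0L) {
        comp[w] <- cur
        queue <- c(queue, w)
      }
    }
  }
  comp
}

#' @rdname graph_components
#' @export
n_components <- function(graph) max(graph_components(graph))

#' Read a plain-text region graph
#'
#' The file follows the common disease-mapping region-graph convention:
#' the first line is the number of nodes N; each subsequent line is
#' `node-index degree neighbour-indices...` with 1-based indices. The
#' adjacency must be symmetric.
#'
#' @param path path to the graph file.
#' @return a [region_graph()].
#' @export
read_region_graph <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || n < 1) stop("invalid node count line", call. = FALSE)
  if (length(lines) != n + 1)
    stop("expected ", n, " node lines, found ", length(lines) - 1,
         call. = FALSE)
  nb <- vector("list", n)
  seen <- logical(n)
  for (k in seq_len(n)) {
    f <- as.integer(strsplit(trimws(lines[k + 1]), "[[:space:]]+")[[1]])
    if (any(is.na(f)) || length(f) < 2)
      stop("malformed node line: '", lines[k + 1], "'", call. = FALSE)
    node <- f[1]; deg <- f[2]; nbrs <- f[-(1:2)]
    if (node < 1 || node > n) stop("node index out of range: ", node,
                                   call. = FALSE)
    if (seen[node]) stop("duplicate line for node ", node, call. = FALSE)
    seen[node] <- TRUE
    if (length(nbrs) != deg)
      stop("degree mismatch at node ", node, ": declared ", deg,
           ", listed ", length(nbrs), call. = FALSE)
    nb[[node]] <- nbrs
  }
  region_graph(nb)
}

#' Write a region graph in the plain-text dialect
#'
#' @param graph a `region_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_graph <- function(graph, path) {
  lines <- c(as.character(graph$n),
             vapply(seq_len(graph$n), function(i) {
               paste(c(i, length(graph$nb[[i]]), graph$nb[[i]]),
                     collapse = " ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a tabular result to CSV
#'
#' All downstream outputs (life-table summaries, detection tables,
#' diagnostics) are persisted as headered CSV. Numeric columns are written
#' at full double precision so that re-reading reproduces the values.
#'
#' @param records a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  rec <- records
  for (k in seq_along(rec)) {
    if (is.double(rec[[k]])) rec[[k]] <- sprintf("%.17g", rec[[k]])
  }
  utils::write.csv(rec, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read back a tabular result written by [write_table()]
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Flatten a mortality dataset to the long CSV layout
#'
#' Inverse of [read_mortality_table()]: one row per
#' area x age group x year, with the dataset's sex and decile columns.
#'
#' @param data a `mortality_dataset`.
#' @return data.frame with columns area, age_group, year, sex, deaths,
#'   population, decile.
#' @export
dataset_to_long <- function(data) {
  grid <- expand.grid(area = data$area_ids, age_group = data$age_groups,
                      year = data$years, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$sex <- data$sex
  grid$deaths <- as.vector(data$deaths)
  grid$population <- as.vector(data$population)
  grid$decile <- data$decile[grid$area]
  grid
}

#' Write a mortality dataset as a long CSV
#'
#' @param data a `mortality_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mortality_table <- function(data, path) {
  write_table(dataset_to_long(data), path)
}
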