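#' Rook-adjacency lattice graph
#'
#' A rows x cols lattice with horizontal and vertical adjacency, used as a
#' stand-in for administrative contiguity in simulations. Node i sits at
#' (row, col) with column-major numbering.
#'
#' @param rows,cols positive lattice dimensions with `rows * cols >= 2`.
#' @return a [region_graph()] that is always connected.
#' @export
make_lattice_graph <- function(rows, cols) {
  if (rows < 1 || cols < 1 || rows * cols < 2)
    stop("lattice needs positive dimensions and at least 2 nodes",
         call. = FALSE)
  id <- function(r, c) (c - 1L) * rows + r
  nb <- vector("list", rows * cols)
  for (c in seq_len(cols)) for (r in seq_len(rows)) {
    v <- integer(0)
    if (r > 1) v <- c(v, id(r - 1L, c))
    if (r < rows) v <- c(v, id(r + 1L, c))
    if (c > 1) v <- c(v, id(r, c - 1L))
    if (c < cols) v <- c(v, id(r, c + 1L))
    nb[[id(r, c)]] <- v
  }
  region_graph(nb)
}

#' Draw from a first-order random-walk (RW1) prior
#'
#' Increments x[k+1] - x[k] are independent Gaussian with mean 0 and
#' variance 1/tau; the draw is re-centred to sum to zero, matching the
#' identifiability constraint imposed during model fitting.
#'
#' @param n length, at least 2.
#' @param tau positive precision of the increments.
#' @return numeric vector of length n summing to zero.
#' @export
sample_rw1 <- function(n, tau) {
  if (n < 2) stop("RW1 needs length >= 2", call. = FALSE)
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  x <- cumsum(c(0, stats::rnorm(n - 1, 0, 1 / sqrt(tau))))
  x - mean(x)
}

#' Draw from an intrinsic CAR (ICAR) prior on a connected graph
#'
#' Samples from the improper Gaussian Markov random field with density
#' proportional to exp(-(tau/2) * sum over edges (x_i - x_j)^2), restricted
#' to the sum-to-zero subspace. The draw is exact: the graph Laplacian is
#' eigendecomposed and independent Gaussians with variance 1/(tau * lambda_k)
#' are placed on the non-null eigenvectors.
#'
#' @param graph a connected [region_graph()].
#' @param tau positive precision.
#' @return numeric vector of length `graph$n` summing to zero.
#' @export
sample_icar <- function(graph, tau) {
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  if (n_components(graph) != 1)
    stop("ICAR sampling requires a connected graph; sample per component",
         call. = FALSE)
  L <- as.matrix(icar_structure(graph))
  eig <- eigen(L, symmetric = TRUE)
  pos <- eig$values > 1e-10 * max(eig$values)
  lam <- eig$values[pos]
  z <- stats::rnorm(length(lam), 0, 1 / sqrt(tau * lam))
  x <- drop(eig$vectors[, pos, drop = FALSE] %*% z)
  x - mean(x)
}

#' Assign spatially smooth deprivation deciles
#'
#' Areas are ranked by a sampled ICAR surface and cut into D groups whose
#' sizes differ by at most one, so neighbouring areas tend to share a
#' decile, emulating the spatial clustering of real deprivation. Decile 1
#' is by convention the most deprived.
#'
#' @param graph a connected [region_graph()] with I nodes.
#' @param D number of deciles, `D <= I` (default 10).
#' @return named integer vector of deciles in 1..D per node.
#' @export
assign_deciles <- function(graph, D = 10) {
  I <- graph$n
  if (D > I) stop("more deciles than areas", call. = FALSE)
  surface <- sample_icar(graph, tau = 1)
  sizes <- rep(I %/% D, D)
  extra <- I %% D
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  dec <- integer(I)
  dec[order(surface)] <- rep(seq_len(D), times = sizes)
  names(dec) <- graph$ids
  dec
}

#' Simulation specification
#'
#' Defines the generative conditions for a synthetic mortality dataset:
#' lattice dimensions, grid sizes, the baseline log rate, one precision per
#' model component, the population scale, and any injected area-year
#' anomalies. The defaults are the package's desk-scale study conditions: a
#' 10 x 10 lattice, 10 age groups, 10 years ending in 2018, 10 deciles,
#' crude baseline rate 1% and roughly 1e4 person-years per area-age cell.
#' The default space-time precision is large (1e4) so that non-anomalous
#' area-years carry no unexplained space-time signal: under the
#' surveillance premise, genuine anomalies are the injected shifts, and a
#' flag anywhere else is a false alarm.
#'
#' @param rows,cols lattice dimensions (I = rows * cols areas).
#' @param J number of age groups (>= 2); labels are built on the 5-year
#'   national-statistics grid truncated to J groups.
#' @param T_years number of consecutive calendar years.
#' @param D number of deprivation deciles.
#' @param a0 baseline log mortality rate (per person-year).
#' @param tau named precisions for alpha (age), gamma (space), zeta (year),
#'   phi (decile), omega (space-time), delta (space-age), kappa (age-time),
#'   nu (decile-time).
#' @param pop_scale average person-years per area-age cell.
#' @param anomalies data.frame with columns `area` (index), `year`
#'   (calendar year) and `shift` (added to omega after centring), or NULL.
#' @param last_year calendar label of the final year.
#' @param sex sex label attached to the simulated dataset.
#' @param seed integer seed; the whole simulation is a deterministic
#'   function of the spec including this seed.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(rows = 10, cols = 10, J = 10, T_years = 10,
                            D = 10, a0 = log(0.01),
                            tau = c(alpha = 2, gamma = 25, zeta = 100,
                                    phi = 25, omega = 1e4, delta = 100,
                                    kappa = 200, nu = 200),
                            pop_scale = 1e4, anomalies = NULL,
                            last_year = 2018, sex = "female", seed = 1) {
  need <- c("alpha", "gamma", "zeta", "phi", "omega", "delta", "kappa", "nu")
  if (!all(need %in% names(tau)))
    stop("tau must name all of: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(tau <= 0)) stop("all precisions must be positive", call. = FALSE)
  I <- rows * cols
  if (I < 4) stop("need at least 4 areas (rows * cols >= 4)", call. = FALSE)
  if (D > I) stop("D must not exceed the number of areas", call. = FALSE)
  if (!is.null(anomalies)) {
    stopifnot(is.data.frame(anomalies),
              all(c("area", "year", "shift") %in% names(anomalies)))
    if (any(!is.finite(anomalies$shift)))
      stop("anomaly shifts must be finite", call. = FALSE)
  }
  structure(list(rows = rows, cols = cols, J = J, T_years = T_years, D = D,
                 a0 = a0, tau = tau[need], pop_scale = pop_scale,
                 anomalies = anomalies, last_year = as.integer(last_year),
                 sex = sex, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Age-group labels on the 5-year grid
#'
#' First group `"0-0"` ([0,1)), then `"1-4"`, then 5-year groups, the last
#' open-ended, truncated to J groups (J = 20 reproduces the standard
#' 0, 1-4, 5-9, ..., 85-89, 90+ abridged grid).
#'
#' @param J number of groups, >= 2.
#' @return character vector of labels.
#' @export
standard_age_groups <- function(J = 20) {
  if (J < 2) stop("need at least 2 age groups", call. = FALSE)
  lowers <- c(0, 1, seq(5, by = 5, length.out = max(0, J - 2)))
  lowers <- lowers[seq_len(J)]
  labs <- character(J)
  for (k in seq_len(J - 1)) {
    labs[k] <- paste0(lowers[k], "-", lowers[k + 1] - 1)
  }
  labs[J] <- paste0(lowers[J], "+")
  labs
}

# Deterministic peaked age-weight vector for the synthetic population
# pyramid: rises to a peak around the fourth decile of the age range, then
# decays, so old-age cells carry less exposure, as in real populations.
age_pyramid_weights <- function(J) {
  j <- seq_len(J)
  peak <- 0.35 * J
  w <- exp(-((j - peak) / (0.45 * J))^2)
  w / sum(w)
}

#' Simulate a mortality dataset from the generative model
#'
#' Draws every component of the hierarchical model from its prior (RW1 for
#' the age, year and decile main effects and for the age-time and
#' decile-time interactions over time; ICAR for the spatial effect;
#' doubly centred exchangeable Gaussians for the space-age and space-time
#' interactions), builds the linear predictor, generates populations from a
#' peaked age pyramid with per-area +/-20% jitter, and draws Poisson death
#' counts. Anomaly shifts are added to the space-time interaction after
#' centring, so injected signal lives exactly where the detection rule
#' looks.
#'
#' @param spec a [simulation_spec()].
#' @return list with elements `data` (a [mortality_dataset()]), `truth`
#'   (realised components, decile map and anomaly list) and `graph`
#'   (the lattice [region_graph()]).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  I <- spec$rows * spec$cols
  J <- spec$J; T <- spec$T_years; D <- spec$D
  years <- seq(spec$last_year - T + 1L, spec$last_year)
  graph <- make_lattice_graph(spec$rows, spec$cols)
  decile <- assign_deciles(graph, D)

  tau <- spec$tau
  alpha <- sample_rw1(J, tau["alpha"])
  zeta  <- sample_rw1(T, tau["zeta"])
  phi   <- sample_rw1(D, tau["phi"])
  gamma <- sample_icar(graph, tau["gamma"])

  double_center <- function(m) {
    m - outer(rowMeans(m), rep(1, ncol(m))) -
      outer(rep(1, nrow(m)), colMeans(m)) + mean(m)
  }
  omega <- double_center(
    matrix(stats::rnorm(I * T, 0, 1 / sqrt(tau["omega"])), I, T))
  delta <- double_center(
    matrix(stats::rnorm(I * J, 0, 1 / sqrt(tau["delta"])), I, J))
  # RW1 rows over time already sum to zero over t; removing the per-year
  # column means then yields the doubly centred constraint set the model
  # imposes (rows over t, columns over j resp. d per t)
  kappa <- t(vapply(seq_len(J), function(j) sample_rw1(T, tau["kappa"]),
                    numeric(T)))                 # J x T
  kappa <- sweep(kappa, 2, colMeans(kappa))
  nu <- t(vapply(seq_len(D), function(d) sample_rw1(T, tau["nu"]),
                 numeric(T)))                    # D x T
  nu <- sweep(nu, 2, colMeans(nu))

  if (!is.null(spec$anomalies)) {
    for (r in seq_len(nrow(spec$anomalies))) {
      i <- spec$anomalies$area[r]
      t <- match(spec$anomalies$year[r], years)
      if (is.na(t) || i < 1 || i > I)
        stop("anomaly references out-of-range area or year", call. = FALSE)
      omega[i, t] <- omega[i, t] + spec$anomalies$shift[r]
    }
  }

  w <- age_pyramid_weights(J)
  area_scale <- spec$pop_scale * stats::runif(I, 0.8, 1.2)
  population <- array(0, dim = c(I, J, T))
  for (j in seq_len(J)) population[, j, ] <- area_scale * w[j] * J

  eta <- array(0, dim = c(I, J, T))
  for (t in seq_len(T)) for (j in seq_len(J)) {
    eta[, j, t] <- spec$a0 + alpha[j] + gamma + zeta[t] + phi[decile] +
      omega[, t] + delta[, j] + kappa[j, t] + nu[decile, t]
  }
  mu <- exp(eta) * population
  deaths <- array(stats::rpois(length(mu), mu), dim = dim(mu))

  area_ids <- sprintf("A%03d", seq_len(I))
  names(decile) <- area_ids
  graph$ids <- area_ids
  data <- mortality_dataset(area_ids, standard_age_groups(J), years,
                            spec$sex, deaths, population, decile)
  truth <- list(a0 = spec$a0, alpha = alpha, gamma = gamma, zeta = zeta,
                phi = phi, omega = omega, delta = delta, kappa = kappa,
                nu = nu, decile = decile, anomalies = spec$anomalies,
                eta = eta, years = years)
  list(data = data, truth = truth, graph = graph)
}

#' Round-trip a simulation spec through a flat YAML config
#'
#' @param spec a [simulation_spec()].
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_simulation_spec <- function(spec, path) {
  x <- unclass(spec)
  x$tau <- as.list(x$tau)
  if (!is.null(x$anomalies)) x$anomalies <- lapply(
    seq_len(nrow(x$anomalies)),
    function(r) as.list(x$anomalies[r, c("area", "year", "shift")]))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_simulation_spec
#' @param path path to a YAML file written by [write_simulation_spec()]
#'   (or hand-written with the same keys).
#' @return for `read_simulation_spec`, a [simulation_spec()].
#' @export
read_simulation_spec <- function(path) {
  x <- yaml::read_yaml(path)
  anom <- NULL
  if (!is.null(x$anomalies) && length(x$anomalies) > 0)
    anom <- do.call(rbind, lapply(x$anomalies, as.data.frame))
  simulation_spec(rows = x$rows, cols = x$cols, J = x$J,
                  T_years = x$T_years, D = x$D, a0 = x$a0,
                  tau = unlist(x$tau), pop_scale = x$pop_scale,
                  anomalies = anom, last_year = x$last_year, sex = x$sex,
                  seed = x$seed)
}
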