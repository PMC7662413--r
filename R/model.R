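#' MCMC configuration for the hierarchical Poisson model
#'
#' @param chains number of chains (>= 1; diagnostics need >= 2).
#' @param burnin burn-in iterations per chain (adaptation happens only
#'   here).
#' @param iter kept iterations per chain after burn-in and thinning
#'   (>= 100).
#' @param thin thinning interval.
#' @param tau_shape,tau_rate Gamma hyperprior on every component precision;
#'   the default Gamma(1, 0.01) is the weakly informative conjugate choice
#'   common in disease mapping.
#' @param a0_var variance of the vague normal prior on the intercept.
#' @param target_accept adaptation target for the scalar Metropolis steps.
#' @param constraint_tol tolerance for the sum-to-zero checks on stored
#'   samples.
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @return object of class `model_config`.
#' @export
model_config <- function(chains = 2, burnin = 1000, iter = 1000, thin = 1,
                         tau_shape = 1, tau_rate = 0.01, a0_var = 1e6,
                         target_accept = 0.44, constraint_tol = 1e-6,
                         seed = 1) {
  if (iter < 100) stop("need at least 100 kept iterations per chain",
                       call. = FALSE)
  if (tau_shape <= 0 || tau_rate <= 0 || a0_var <= 0)
    stop("hyperprior parameters must be positive", call. = FALSE)
  structure(list(chains = as.integer(chains), burnin = as.integer(burnin),
                 iter = as.integer(iter), thin = as.integer(thin),
                 tau_shape = tau_shape, tau_rate = tau_rate,
                 a0_var = a0_var, target_accept = target_accept,
                 constraint_tol = constraint_tol, seed = as.integer(seed)),
            class = "model_config")
}

#' Evaluate the linear predictor for one posterior draw
#'
#' log(lambda_ijt) = a0 + alpha_j + gamma_i + zeta_t + phi_d(i) + omega_it
#' + delta_ij + kappa_jt + nu_d(i),t, where d(i) is the deprivation decile
#' of area i. Arguments `i`, `j`, `t` are indices (recycled to a common
#' length).
#'
#' @param draw list with elements a0 (scalar), alpha (J), gamma (I),
#'   zeta (T), phi (D), omega (I x T), delta (I x J), kappa (J x T),
#'   nu (D x T).
#' @param decile integer vector: decile per area index.
#' @param i,j,t area, age-group and year indices.
#' @return numeric vector of log rates.
#' @export
linear_predictor <- function(draw, decile, i, j, t) {
  n <- max(length(i), length(j), length(t))
  i <- rep_len(as.integer(i), n); j <- rep_len(as.integer(j), n)
  t <- rep_len(as.integer(t), n)
  I <- length(draw$gamma); J <- length(draw$alpha); T <- length(draw$zeta)
  if (any(i < 1 | i > I) || any(j < 1 | j > J) || any(t < 1 | t > T))
    stop("index out of range", call. = FALSE)
  d <- decile[i]
  draw$a0 + draw$alpha[j] + draw$gamma[i] + draw$zeta[t] + draw$phi[d] +
    draw$omega[cbind(i, t)] + draw$delta[cbind(i, j)] +
    draw$kappa[cbind(j, t)] + draw$nu[cbind(d, t)]
}

#' Linear predictor over the full I x J x T grid
#'
#' @inheritParams linear_predictor
#' @return I x J x T array of log rates.
#' @export
linear_predictor_array <- function(draw, decile) {
  I <- length(draw$gamma); J <- length(draw$alpha); T <- length(draw$zeta)
  eta <- array(0, dim = c(I, J, T))
  for (t in seq_len(T)) {
    base_t <- draw$gamma + draw$phi[decile] + draw$omega[, t] +
      draw$nu[decile, t] + draw$zeta[t] + draw$a0
    for (j in seq_len(J)) {
      eta[, j, t] <- base_t + draw$alpha[j] + draw$delta[, j] +
        draw$kappa[j, t]
    }
  }
  eta
}

#' Poisson log likelihood of one draw
#'
#' Sum over all cells with positive exposure of the Poisson log pmf of the
#' observed deaths with mean exp(eta) x population; zero-exposure cells
#' contribute exactly zero.
#'
#' @param draw a component list as in [linear_predictor()].
#' @param data a [mortality_dataset()].
#' @return scalar log likelihood.
#' @export
log_likelihood <- function(draw, data) {
  dec <- unname(data$decile)
  eta <- linear_predictor_array(draw, dec)
  if (any(!is.finite(eta))) stop("non-finite linear predictor", call. = FALSE)
  mu <- exp(eta) * data$population
  keep <- data$population > 0
  sum(stats::dpois(data$deaths[keep], mu[keep], log = TRUE))
}

#' Fit the hierarchical spatio-temporal Poisson model by MCMC
#'
#' Metropolis-within-Gibbs sampling: adaptive scalar random-walk
#' Metropolis updates for the intercept and every element of the Gaussian
#' fields against the Poisson likelihood, conjugate Gamma Gibbs updates for
#' the eight component precisions, and sum-to-zero re-centring (with the
#' removed means transferred into the intercept and main effects, so the
#' fitted rates are untouched) after every sweep. Step sizes adapt toward
#' the target acceptance rate during burn-in only.
#'
#' @param data a [mortality_dataset()].
#' @param graph a connected [region_graph()] on the same areas.
#' @param config a [model_config()].
#' @return object of class `posterior_samples`: per-component draw arrays
#'   with the chain index of every draw, acceptance-rate log and metadata.
#' @export
fit <- function(data, graph, config = model_config()) {
  validate_mortality_dataset(data)
  I <- length(data$area_ids); J <- length(data$age_groups)
  T <- length(data$years)
  if (I < 2) stop("spatial prior undefined on a single area", call. = FALSE)
  if (graph$n != I) stop("graph/data area count mismatch", call. = FALSE)
  if (n_components(graph) != 1) stop("graph must be connected", call. = FALSE)

  dec <- unname(as.integer(data$decile))
  D <- max(dec)
  y <- as.numeric(data$deaths)
  E <- as.numeric(data$population)
  nb0 <- lapply(graph$nb, function(v) as.integer(v - 1L))

  comp_names <- c("a0", "alpha", "gamma", "zeta", "phi", "omega", "delta",
                  "kappa", "nu")
  tau_names <- comp_names[-1]

  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed(config$seed + ch - 1L)
    res <- stm_sampler(y, E, I, J, T, D, dec - 1L, nb0,
                       config$burnin, config$iter, config$thin,
                       config$tau_shape, config$tau_rate, config$a0_var,
                       config$target_accept)
    if (!all(is.finite(res$a0)))
      stop("divergent chain: non-finite posterior draws", call. = FALSE)
    if (all(res$accept < 1e-12))
      stop("divergent chain: all proposals rejected", call. = FALSE)
    chains[[ch]] <- res
  }

  S <- config$iter
  bindmat <- function(name) do.call(rbind, lapply(chains, `[[`, name))
  draws <- list(
    a0 = unlist(lapply(chains, `[[`, "a0")),
    alpha = bindmat("alpha"), gamma = bindmat("gamma"),
    zeta = bindmat("zeta"), phi = bindmat("phi"),
    omega = array(t(bindmat("omega")), c(I, T, S * config$chains)),
    delta = array(t(bindmat("delta")), c(I, J, S * config$chains)),
    kappa = array(t(bindmat("kappa")), c(J, T, S * config$chains)),
    nu = array(t(bindmat("nu")), c(D, T, S * config$chains)),
    tau = bindmat("tau"))
  colnames(draws$tau) <- tau_names
  # omega etc. stored unit-slowest: permute to S x ... for ergonomic access
  draws$omega <- aperm(draws$omega, c(3, 1, 2))
  draws$delta <- aperm(draws$delta, c(3, 1, 2))
  draws$kappa <- aperm(draws$kappa, c(3, 1, 2))
  draws$nu <- aperm(draws$nu, c(3, 1, 2))

  accept <- do.call(rbind, lapply(chains, `[[`, "accept"))
  colnames(accept) <- comp_names

  structure(list(
    draws = draws,
    chain = rep(seq_len(config$chains), each = S),
    accept = accept,
    meta = list(area_ids = data$area_ids, age_groups = data$age_groups,
                years = data$years, decile = data$decile, sex = data$sex,
                config = config)),
    class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  S <- length(x$draws$a0)
  cat(sprintf("posterior_samples: %d draws (%d chain(s)) over %d areas x %d ages x %d years\n",
              S, max(x$chain), length(x$meta$area_ids),
              length(x$meta$age_groups), length(x$meta$years)))
  cat(sprintf("  a0: mean %.4f, 95%% CI [%.4f, %.4f]\n",
              mean(x$draws$a0),
              stats::quantile(x$draws$a0, 0.025),
              stats::quantile(x$draws$a0, 0.975)))
  invisible(x)
}

#' Number of stored draws
#' @param samples a `posterior_samples` object.
#' @return integer.
#' @export
n_draws <- function(samples) length(samples$draws$a0)

#' Extract one posterior draw as a component list
#'
#' @param samples a `posterior_samples` object.
#' @param s draw index.
#' @return list usable with [linear_predictor()] / [log_likelihood()].
#' @export
get_draw <- function(samples, s) {
  d <- samples$draws
  list(a0 = d$a0[s], alpha = d$alpha[s, ], gamma = d$gamma[s, ],
       zeta = d$zeta[s, ], phi = d$phi[s, ],
       omega = d$omega[s, , ], delta = d$delta[s, , ],
       kappa = d$kappa[s, , ], nu = d$nu[s, , ])
}

#' Posterior draws of the space-time interaction
#'
#' @param samples a `posterior_samples` object.
#' @return S x I x T array of omega draws with area and year dimnames.
#' @export
omega_draws <- function(samples) {
  om <- samples$draws$omega
  dimnames(om) <- list(NULL, samples$meta$area_ids, samples$meta$years)
  om
}
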