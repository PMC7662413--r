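#' Split-chain potential scale reduction (Rhat)
#'
#' Each chain is split in half and the standard between/within variance
#' ratio is computed over the resulting 2m half-chains. A series with
#' (numerically) zero variance returns exactly 1.
#'
#' @param x numeric vector of draws.
#' @param chain integer chain label per draw.
#' @return scalar Rhat.
#' @export
split_rhat <- function(x, chain) {
  halves <- list()
  for (ch in unique(chain)) {
    v <- x[chain == ch]
    n2 <- floor(length(v) / 2)
    halves <- c(halves, list(v[seq_len(n2)], v[seq_len(n2) + n2]))
  }
  n <- min(lengths(halves))
  halves <- lapply(halves, function(v) v[seq_len(n)])
  m <- length(halves)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W < 1e-300) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size from pooled autocorrelations
#'
#' Standard estimator: S / (1 + 2 * sum of autocorrelations), with the sum
#' truncated by Geyer's initial-positive-sequence rule on pairs of lags,
#' autocovariances averaged over chains around the per-chain means.
#'
#' @inheritParams split_rhat
#' @return scalar effective sample size.
#' @export
ess <- function(x, chain) {
  chains <- lapply(unique(chain), function(ch) x[chain == ch])
  n <- min(lengths(chains))
  chains <- lapply(chains, function(v) v[seq_len(n)])
  S <- n * length(chains)
  if (stats::var(x) < 1e-300 || n < 4) return(S)
  # average autocovariance over chains (demeaned per chain)
  acov <- function(v, lag) {
    v <- v - mean(v)
    sum(v[seq_len(n - lag)] * v[seq_len(n - lag) + lag]) / n
  }
  maxlag <- min(n - 2, 500)
  g0 <- mean(vapply(chains, acov, numeric(1), lag = 0))
  rho <- numeric(maxlag)
  for (l in seq_len(maxlag))
    rho[l] <- mean(vapply(chains, acov, numeric(1), lag = l)) / g0
  # Geyer initial positive sequence on paired lags
  s <- 0
  l <- 1
  while (l + 1 <= maxlag) {
    pair <- rho[l] + rho[l + 1]
    if (pair <= 0) break
    s <- s + pair
    l <- l + 2
  }
  max(1, min(S, S / (1 + 2 * s)))
}

#' Convergence diagnostics for a fitted model
#'
#' Split-chain scale reduction and effective sample size for every scalar
#' summary: the intercept, each precision, and the per-draw mean of each
#' field (identically zero for centred components, reported for
#' completeness). Requires at least two chains.
#'
#' @param samples a `posterior_samples` object from [fit()].
#' @return data.frame with columns `parameter`, `rhat`, `ess`, `flagged`
#'   (TRUE where rhat > 1.1).
#' @export
convergence_report <- function(samples) {
  if (max(samples$chain) < 2)
    stop("convergence diagnostics need at least 2 chains", call. = FALSE)
  d <- samples$draws
  scalars <- list(a0 = d$a0)
  for (k in colnames(d$tau)) scalars[[paste0("tau_", k)]] <- d$tau[, k]
  for (k in c("alpha", "gamma", "zeta", "phi"))
    scalars[[paste0("mean_", k)]] <- rowMeans(d[[k]])
  for (k in c("omega", "delta", "kappa", "nu"))
    scalars[[paste0("mean_", k)]] <- apply(d[[k]], 1, mean)
  rhat <- vapply(scalars, split_rhat, numeric(1), chain = samples$chain)
  essv <- vapply(scalars, ess, numeric(1), chain = samples$chain)
  data.frame(parameter = names(scalars), rhat = unname(rhat),
             ess = unname(essv), flagged = unname(rhat > 1.1),
             stringsAsFactors = FALSE)
}
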