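#' Abridged life-table configuration
#'
#' Holds the age-interval widths and the average fraction of the interval
#' lived by those dying in it (the Chiang a values). Defaults follow the
#' standard national-statistics abridged construction: a = 0.5 in closed
#' intervals, a = 0.1 for the infant group when it spans a single year, and
#' the open-ended last interval closed as L = l / m.
#'
#' @param age_groups character age-group labels (see
#'   [standard_age_groups()]); widths and the open last interval are
#'   derived from them.
#' @param a optional numeric vector of fractions per closed interval; by
#'   default 0.5 everywhere with 0.1 for a one-year infant group.
#' @param rate_floor rates are floored at this value before the life-table
#'   arithmetic, guarding the open-interval division.
#' @return object of class `lifetable_config` with fields `width`, `a`,
#'   `rate_floor`.
#' @export
lifetable_config <- function(age_groups, a = NULL, rate_floor = 1e-10) {
  at <- parse_age_groups(age_groups)
  J <- nrow(at)
  width <- at$width
  if (is.null(a)) {
    a <- rep(0.5, J)
    if (width[1] == 1) a[1] <- 0.1
  }
  if (length(a) != J) stop("a must have one entry per age group",
                           call. = FALSE)
  if (any(a[-J] <= 0 | a[-J] >= 1))
    stop("a must lie in (0,1) for closed intervals", call. = FALSE)
  structure(list(labels = age_groups, width = width, a = a,
                 rate_floor = rate_floor),
            class = "lifetable_config")
}

#' Life expectancy at birth from age-specific rates
#'
#' Chiang-style abridged period life table. For closed intervals the death
#' probability is q = n m / (1 + n (1 - a) m) (capped at 1); the last,
#' open-ended interval has q = 1 and person-years L = l / m. e0 is total
#' person-years lived per birth.
#'
#' Vectorised: `m` may be a matrix with one schedule per row.
#'
#' @param m positive age-specific mortality rates per person-year, length-J
#'   vector or (units x J) matrix.
#' @param config a [lifetable_config()].
#' @return life expectancy at birth in years (scalar or vector per row).
#' @export
e0_from_rates <- function(m, config) {
  single <- is.null(dim(m))
  m <- unname(rbind(m))
  J <- length(config$width)
  if (ncol(m) != J) stop("rate schedule length mismatch", call. = FALSE)
  if (any(!is.finite(m)) || any(m < 0))
    stop("rates must be finite and non-negative", call. = FALSE)
  m <- pmax(m, config$rate_floor)
  n <- config$width
  a <- config$a
  l <- rep(1, nrow(m))
  e0 <- numeric(nrow(m))
  for (j in seq_len(J)) {
    if (j < J) {
      q_raw <- n[j] * m[, j] / (1 + n[j] * (1 - a[j]) * m[, j])
      q <- pmin(1, q_raw)
      d <- l * q
      lnext <- l - d
      L <- n[j] * (lnext + a[j] * d)
      # when the whole cohort dies in the interval the tabular L is
      # replaced by the exposure-consistent person-years d / m
      cap <- q_raw >= 1
      L[cap] <- (d / m[, j])[cap]
      e0 <- e0 + L
      l <- lnext
    } else {
      e0 <- e0 + l / m[, j]
    }
  }
  if (single) e0[1] else e0
}

#' Per-draw life expectancy surfaces from posterior samples
#'
#' For each posterior draw, the age-specific rate schedule
#' m_j = exp(linear predictor) is built per unit (area or deprivation
#' decile, the latter via population-weighted pooling of member-area rates)
#' and year, and converted to life expectancy at birth.
#'
#' @param samples a `posterior_samples` object from [fit()].
#' @param data the [mortality_dataset()] the model was fitted to.
#' @param config a [lifetable_config()]; defaults to the dataset's age
#'   grid.
#' @param by `"area"` or `"decile"`.
#' @return S x units x years array of e0 draws with dimnames.
#' @export
e0_posterior <- function(samples, data, config = NULL,
                         by = c("area", "decile")) {
  by <- match.arg(by)
  if (is.null(config)) config <- lifetable_config(data$age_groups)
  dec <- unname(data$decile)
  I <- length(data$area_ids); J <- length(data$age_groups)
  T <- length(data$years)
  S <- n_draws(samples)
  if (by == "area") {
    units <- data$area_ids
  } else {
    units <- sort(unique(dec))
    if (any(tabulate(dec) == 0 & seq_len(max(dec)) %in% units))
      stop("empty decile", call. = FALSE)
  }
  U <- length(units)
  out <- array(NA_real_, dim = c(S, U, T),
               dimnames = list(NULL, as.character(units), data$years))
  pop <- data$population
  for (s in seq_len(S)) {
    lam <- exp(linear_predictor_array(get_draw(samples, s), dec))
    for (t in seq_len(T)) {
      if (by == "area") {
        out[s, , t] <- e0_from_rates(lam[, , t], config)
      } else {
        mjd <- matrix(NA_real_, U, J)
        for (u in seq_len(U)) {
          members <- which(dec == units[u])
          if (length(members) == 0) stop("empty decile", call. = FALSE)
          w <- pop[members, , t, drop = FALSE][, , 1, drop = FALSE]
          dim(w) <- c(length(members), J)
          lm <- lam[members, , t, drop = FALSE]
          dim(lm) <- c(length(members), J)
          ws <- colSums(w)
          mjd[u, ] <- ifelse(ws > 0, colSums(lm * w) / ws, colMeans(lm))
        }
        out[s, , t] <- e0_from_rates(mjd, config)
      }
    }
  }
  out
}

#' Summarise an e0 draw array as mean and 95% credible interval
#'
#' @param e0_arr S x units x years array from [e0_posterior()].
#' @param sex sex label carried into the output.
#' @param unit_name name for the unit column (`"area"` or `"decile"`).
#' @return data.frame with one row per unit-year.
#' @export
summarize_e0 <- function(e0_arr, sex, unit_name) {
  S <- dim(e0_arr)[1]
  units <- dimnames(e0_arr)[[2]]
  years <- as.integer(dimnames(e0_arr)[[3]])
  grid <- expand.grid(unit = units, year = years, stringsAsFactors = FALSE)
  res <- data.frame(unit = grid$unit, sex = sex, year = grid$year,
                    e0_mean = NA_real_, e0_low = NA_real_,
                    e0_high = NA_real_, n_draws = S,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(res))) {
    v <- e0_arr[, res$unit[r], as.character(res$year[r])]
    res$e0_mean[r] <- mean(v)
    res$e0_low[r] <- unname(stats::quantile(v, 0.025, type = 7))
    res$e0_high[r] <- unname(stats::quantile(v, 0.975, type = 7))
  }
  names(res)[1] <- unit_name
  res
}

#' Life-expectancy summaries per area-year
#'
#' Posterior mean and central 95% credible interval of life expectancy at
#' birth for every area and year.
#'
#' @inheritParams e0_posterior
#' @return data.frame with columns area, sex, year, e0_mean, e0_low,
#'   e0_high, n_draws.
#' @export
area_year_e0 <- function(samples, data, config = NULL) {
  summarize_e0(e0_posterior(samples, data, config, by = "area"),
               data$sex, "area")
}

#' Life-expectancy summaries per deprivation decile and year
#'
#' As [area_year_e0()], with member-area rates pooled by population weight
#' within each decile before the life-table conversion.
#'
#' @inheritParams e0_posterior
#' @return data.frame with columns decile, sex, year, e0_mean, e0_low,
#'   e0_high, n_draws.
#' @export
decile_year_e0 <- function(samples, data, config = NULL) {
  summarize_e0(e0_posterior(samples, data, config, by = "decile"),
               data$sex, "decile")
}

#' Life-expectancy gap between two periods, in days
#'
#' For each posterior draw and unit, the gap is the mean e0 over
#' `period_b` minus the mean over `period_a`, converted to days with the
#' calendar-neutral factor 365.25; the per-draw gaps are then summarised
#' as posterior mean and central 95% interval. Differencing happens within
#' draws so the interval reflects the correlation between the two periods.
#'
#' @param e0_arr an S x units x years array from [e0_posterior()].
#' @param period_a,period_b non-empty calendar-year vectors contained in
#'   the array's years.
#' @return data.frame with columns unit, gap_days, gap_low, gap_high.
#' @export
e0_gap <- function(e0_arr, period_a, period_b) {
  years <- as.integer(dimnames(e0_arr)[[3]])
  if (length(period_a) == 0 || length(period_b) == 0)
    stop("empty period", call. = FALSE)
  ia <- match(period_a, years); ib <- match(period_b, years)
  if (any(is.na(ia)) || any(is.na(ib)))
    stop("period outside the series years", call. = FALSE)
  units <- dimnames(e0_arr)[[2]]
  out <- data.frame(unit = units, gap_days = NA_real_, gap_low = NA_real_,
                    gap_high = NA_real_, stringsAsFactors = FALSE)
  for (u in seq_along(units)) {
    ma <- e0_arr[, u, ia, drop = FALSE]
    mb <- e0_arr[, u, ib, drop = FALSE]
    gap <- (apply(mb, 1, mean) - apply(ma, 1, mean)) * 365.25
    out$gap_days[u] <- mean(gap)
    out$gap_low[u] <- unname(stats::quantile(gap, 0.025, type = 7))
    out$gap_high[u] <- unname(stats::quantile(gap, 0.975, type = 7))
  }
  out
}
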