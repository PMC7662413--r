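lt20 <- lifetable_config(standard_age_groups(20))

test_that("constant-hazard schedules reproduce the exponential life expectancy", {
  # continuous-time oracle: constant hazard m gives e0 = 1/m exactly,
  # including the open interval
  m <- rep(0.0125, 20)
  expect_lt(abs(e0_from_rates(m, lt20) - 80) / 80, 0.02)
  m2 <- rep(1 / 40, 20)
  expect_lt(abs(e0_from_rates(m2, lt20) - 40) / 40, 0.02)
})

test_that("extreme mortality collapses e0 and halving rates raises it", {
  expect_lt(e0_from_rates(rep(1e6, 20), lt20), 0.01)
  set.seed(1)
  m <- exp(log(3e-5) + 0.09 * c(0.5, 3, seq(7.5, 92.5, by = 5)))
  e_full <- e0_from_rates(m, lt20)
  expect_gt(e0_from_rates(m / 2, lt20), e_full)
  # strict monotonicity in every coordinate
  for (j in c(1, 7, 20)) {
    m_up <- m
    m_up[j] <- m_up[j] * 1.2
    expect_lt(e0_from_rates(m_up, lt20), e_full)
  }
})

test_that("abridged e0 tracks a single-year-of-age oracle on Gompertz schedules", {
  # fine-grid oracle: 1-year intervals to age 120 with the same Chiang
  # arithmetic, open interval at 120+; returns e0 plus the l/L columns so
  # the abridged inputs can be built as occurrence/exposure rates
  fine_lifetable <- function(mx) {
    n_age <- length(mx)
    l <- numeric(n_age + 1); l[1] <- 1
    L <- d <- numeric(n_age)
    for (x in seq_len(n_age)) {
      if (x < n_age) {
        q <- min(1, mx[x] / (1 + 0.5 * mx[x]))
        d[x] <- l[x] * q
        l[x + 1] <- l[x] - d[x]
        L[x] <- l[x + 1] + 0.5 * d[x]
      } else {
        d[x] <- l[x]
        L[x] <- l[x] / mx[x]
      }
    }
    list(e0 = sum(L), d = d, L = L)
  }
  for (b in c(0.085, 0.1, 0.11)) {
    gomp <- function(x) 3e-5 * exp(b * x)
    mx_fine <- gomp(0:120 + 0.5)
    ft <- fine_lifetable(mx_fine)
    # grouped occurrence/exposure rates, as observed abridged data would be
    bounds <- c(0, 1, seq(5, 90, by = 5), 121)  # ages covered by group
    m_abr <- vapply(seq_len(20), function(j) {
      idx <- (bounds[j] + 1):bounds[j + 1]
      sum(ft$d[idx]) / sum(ft$L[idx])
    }, numeric(1))
    expect_lt(abs(e0_from_rates(m_abr, lt20) - ft$e0) / ft$e0, 0.02)
  }
})

test_that("degenerate single-draw samples reduce to the plain life table", {
  sim <- small_sim()
  data <- sim$data
  I <- length(data$area_ids); J <- length(data$age_groups)
  T <- length(data$years); D <- max(data$decile)
  m <- 0.015
  fake <- structure(list(
    draws = list(a0 = log(m),
                 alpha = matrix(0, 1, J), gamma = matrix(0, 1, I),
                 zeta = matrix(0, 1, T), phi = matrix(0, 1, D),
                 omega = array(0, c(1, I, T)), delta = array(0, c(1, I, J)),
                 kappa = array(0, c(1, J, T)), nu = array(0, c(1, D, T)),
                 tau = matrix(1, 1, 8)),
    chain = 1L,
    meta = list(area_ids = data$area_ids, age_groups = data$age_groups,
                years = data$years, decile = data$decile, sex = data$sex)),
    class = "posterior_samples")
  cfg <- lifetable_config(data$age_groups)
  res <- area_year_e0(fake, data, cfg)
  e_expect <- e0_from_rates(rep(m, J), cfg)
  expect_equal(unique(round(res$e0_mean, 10)), round(e_expect, 10))
  expect_equal(res$e0_low, res$e0_mean)   # zero-width interval at S = 1
  expect_equal(res$e0_high, res$e0_mean)

  # identical areas give identical summaries; decile pooling of identical
  # rates returns the common schedule
  resd <- decile_year_e0(fake, data, cfg)
  expect_equal(unique(round(resd$e0_mean, 10)), round(e_expect, 10))
})

test_that("posterior e0 summaries are invariant to draw order and ordered correctly", {
  s <- small_fit()
  sim <- small_sim()
  arr <- e0_posterior(s, sim$data)
  res <- area_year_e0(s, sim$data)
  expect_true(all(res$e0_low <= res$e0_mean + 1e-12))
  expect_true(all(res$e0_mean <= res$e0_high + 1e-12))
  expect_true(all(res$e0_mean > 0))

  perm <- sample(dim(arr)[1])
  arr_perm <- arr[perm, , , drop = FALSE]
  expect_equal(apply(arr_perm, c(2, 3), mean), apply(arr, c(2, 3), mean))
  expect_equal(apply(arr_perm, c(2, 3), quantile, 0.025),
               apply(arr, c(2, 3), quantile, 0.025))
})

test_that("decile pooling is a population-weighted convex combination", {
  s <- small_fit()
  sim <- small_sim()
  data <- sim$data
  dec <- unname(data$decile)
  dr <- get_draw(s, 1)
  lam <- exp(linear_predictor_array(dr, dec))
  d <- dec[1]
  members <- which(dec == d)
  for (t in c(1, dim(lam)[3])) {
    w <- data$population[members, , t]
    pooled <- colSums(lam[members, , t] * w) / colSums(w)
    lo <- apply(lam[members, , t, drop = FALSE], 2, min)
    hi <- apply(lam[members, , t, drop = FALSE], 2, max)
    expect_true(all(pooled >= lo - 1e-12 & pooled <= hi + 1e-12))
  }
})

test_that("gap computation does the period arithmetic in days", {
  # deterministic series: +0.1 year per year
  years <- 2010:2018
  e0 <- array(rep(70 + 0.1 * (years - 2010), each = 1), c(1, 1, 9),
              dimnames = list(NULL, "A1", years))
  gap <- e0_gap(e0, c(2012, 2013), c(2017, 2018))
  expect_equal(gap$gap_days, 0.5 * 365.25)
  expect_equal(gap$gap_low, gap$gap_days)

  # identical periods: zero gap; swapping flips the sign
  expect_equal(e0_gap(e0, c(2012, 2013), c(2012, 2013))$gap_days, 0)
  expect_equal(e0_gap(e0, c(2017, 2018), c(2012, 2013))$gap_days,
               -gap$gap_days)
  expect_error(e0_gap(e0, integer(0), 2018), "empty period")
  expect_error(e0_gap(e0, 1999, 2018), "outside")
})
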