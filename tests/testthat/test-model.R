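test_that("linear predictor assembles every term exactly once", {
  I <- 3; J <- 2; T <- 2; D <- 2
  dec <- c(1L, 2L, 1L)
  z <- zero_draw(I, J, T, D, a0 = -4)
  expect_equal(linear_predictor(z, dec, 1, 1, 1), -4)

  # distinct powers of ten per term: the digits of the sum identify each
  d <- zero_draw(I, J, T, D, a0 = 1)
  d$alpha[2] <- 10; d$gamma[3] <- 100; d$zeta[2] <- 1000
  d$phi[1] <- 1e4; d$omega[3, 2] <- 1e5; d$delta[3, 2] <- 1e6
  d$kappa[2, 2] <- 1e7; d$nu[1, 2] <- 1e8
  expect_equal(linear_predictor(d, dec, i = 3, j = 2, t = 2), 111111111)

  expect_error(linear_predictor(d, dec, 4, 1, 1), "out of range")
})

test_that("linear predictor agrees with term-by-term summation on random draws", {
  set.seed(1)
  I <- 6; J <- 4; T <- 5; D <- 3
  dec <- sample(1:D, I, replace = TRUE)
  for (rep in 1:5) {
    dr <- random_draw(I, J, T, D)
    i <- sample(I, 1); j <- sample(J, 1); t <- sample(T, 1)
    manual <- dr$a0 + dr$alpha[j] + dr$gamma[i] + dr$zeta[t] +
      dr$phi[dec[i]] + dr$omega[i, t] + dr$delta[i, j] + dr$kappa[j, t] +
      dr$nu[dec[i], t]
    expect_equal(linear_predictor(dr, dec, i, j, t), manual,
                 tolerance = 1e-12)
    eta <- linear_predictor_array(dr, dec)
    expect_equal(eta[i, j, t], manual, tolerance = 1e-12)
  }
})

test_that("single-cell Poisson log pmf values are reproduced", {
  d <- mortality_dataset("A1", c("0-0", "1+"), 2018L, "female",
                         deaths = array(c(0, 0), c(1, 2, 1)),
                         population = array(c(100, 0), c(1, 2, 1)),
                         decile = c(A1 = 1L))
  z <- zero_draw(1, 2, 1, 1, a0 = log(0.01))
  # y = 0, mean 1 -> log pmf = -1; the zero-population cell contributes 0
  expect_equal(log_likelihood(z, d), -1, tolerance = 1e-12)

  d2 <- mortality_dataset("A1", c("0-0", "1+"), 2018L, "female",
                          deaths = array(c(2, 0), c(1, 2, 1)),
                          population = array(c(100, 0), c(1, 2, 1)),
                          decile = c(A1 = 1L))
  z2 <- zero_draw(1, 2, 1, 1, a0 = log(0.02))
  expect_equal(log_likelihood(z2, d2), 2 * log(2) - 2 - log(2),
               tolerance = 1e-12)
})

test_that("log likelihood matches the brute-force oracle on a synthetic dataset", {
  sim <- small_sim()
  set.seed(3)
  I <- length(sim$data$area_ids); J <- length(sim$data$age_groups)
  T <- length(sim$data$years); D <- max(sim$data$decile)
  for (rep in 1:3) {
    dr <- random_draw(I, J, T, D, sd = 0.2)
    expect_equal(log_likelihood(dr, sim$data),
                 brute_force_loglik(dr, sim$data), tolerance = 1e-8)
  }
})

test_that("fitting is deterministic under the seed and refuses degenerate inputs", {
  sim <- small_sim()
  cfg <- model_config(chains = 1, burnin = 150, iter = 100, seed = 5)
  s1 <- fit(sim$data, sim$graph, cfg)
  s2 <- fit(sim$data, sim$graph, cfg)
  expect_identical(s1$draws$a0, s2$draws$a0)
  expect_identical(s1$draws$omega, s2$draws$omega)

  # single-area dataset: spatial prior undefined
  d1 <- mortality_dataset("A1", c("0-0", "1+"), 2018L, "female",
                          deaths = array(c(1, 2), c(1, 2, 1)),
                          population = array(c(100, 100), c(1, 2, 1)),
                          decile = c(A1 = 1L))
  expect_error(fit(d1, region_graph(list(integer(0))), cfg), "single area")

  disconnected <- region_graph(rep(list(integer(0)), sim$graph$n))
  expect_error(fit(sim$data, disconnected, cfg), "connected")
})

test_that("kept samples satisfy the sum-to-zero constraints and have positive precisions", {
  s <- small_fit()
  tol <- s$meta$config$constraint_tol
  d <- s$draws
  expect_lt(max(abs(rowSums(d$alpha))), tol)
  expect_lt(max(abs(rowSums(d$gamma))), tol)
  expect_lt(max(abs(rowSums(d$zeta))), tol)
  expect_lt(max(abs(rowSums(d$phi))), tol)
  for (s_i in c(1, n_draws(s))) {
    dr <- get_draw(s, s_i)
    for (m in list(dr$omega, dr$delta, dr$kappa, dr$nu)) {
      expect_lt(max(abs(rowSums(m))), tol)
      expect_lt(max(abs(colSums(m))), tol)
    }
  }
  expect_true(all(d$tau > 0))
})

test_that("a strong isolated anomaly dominates the posterior space-time surface", {
  tau_hi <- c(alpha = 1e12, gamma = 1e12, zeta = 1e12, phi = 1e12,
              omega = 200, delta = 1e12, kappa = 1e12, nu = 1e12)
  spec <- simulation_spec(rows = 3, cols = 3, J = 4, T_years = 5, D = 3,
                          a0 = log(0.02), tau = tau_hi, pop_scale = 5e3,
                          anomalies = data.frame(area = 4, year = 2016,
                                                 shift = 0.6),
                          seed = 21)
  sim <- simulate_dataset(spec)
  s <- fit(sim$data, sim$graph,
           model_config(chains = 1, burnin = 500, iter = 300, seed = 22))
  om_mean <- apply(s$draws$omega, c(2, 3), mean)
  t_idx <- match(2016, sim$data$years)
  expect_gt(om_mean[4, t_idx], 0)
  expect_true(all(om_mean[4, t_idx] > om_mean[4, -t_idx]))
})

test_that("posterior uncertainty on the intercept contracts with population size", {
  sds <- vapply(c(500, 2000, 8000), function(ps) {
    spec <- simulation_spec(rows = 3, cols = 3, J = 4, T_years = 4, D = 3,
                            pop_scale = ps, seed = 31)
    sim <- simulate_dataset(spec)
    s <- fit(sim$data, sim$graph,
             model_config(chains = 1, burnin = 400, iter = 250, seed = 32))
    sd(s$draws$a0)
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
})
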