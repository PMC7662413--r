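test_that("lattice graphs have the expected rook structure", {
  g <- make_lattice_graph(2, 2)
  expect_equal(g$n, 4)
  expect_equal(sum(lengths(g$nb)) / 2, 4)  # 4 edges on a 2x2

  path <- make_lattice_graph(1, 5)
  expect_equal(sort(lengths(path$nb)), c(1, 1, 2, 2, 2))

  g3 <- make_lattice_graph(3, 3)
  expect_equal(lengths(g3$nb)[5], 4)       # centre node
  expect_equal(n_components(g3), 1)
  expect_error(make_lattice_graph(0, 3), "positive")
})

test_that("RW1 draws are centred, degenerate at huge precision, and need n >= 2", {
  set.seed(1)
  for (n in c(2, 5, 40)) expect_lt(abs(sum(sample_rw1(n, 0.5))), 1e-10)
  expect_lt(max(abs(sample_rw1(10, 1e12))), 1e-4)
  expect_error(sample_rw1(1, 1), "length")
  expect_error(sample_rw1(5, -1), "positive")
})

test_that("ICAR draws are centred and refuse disconnected graphs", {
  g <- make_lattice_graph(3, 4)
  set.seed(2)
  expect_lt(abs(sum(sample_icar(g, 2))), 1e-10)
  disconnected <- region_graph(list(2L, 1L, 4L, 3L))
  expect_error(sample_icar(disconnected, 1), "connected")
})

test_that("RW1 and ICAR prior samples match their closed-form variances", {
  # quick-look calibration at modest replicate counts; the full 20k-replicate
  # check lives in the acceptance suite
  set.seed(3)
  incr <- replicate(4000, {x <- sample_rw1(5, 1); x[2] - x[1]})
  expect_lt(abs(var(incr) - 1), 0.1)

  pairg <- region_graph(list(2L, 1L))
  d12 <- replicate(4000, {x <- sample_icar(pairg, 1); x[1] - x[2]})
  expect_lt(abs(var(d12) - 1), 0.1)
})

test_that("decile assignment is balanced and spatially coherent", {
  g <- make_lattice_graph(10, 10)
  set.seed(4)
  dec <- assign_deciles(g, 10)
  expect_equal(unname(table(dec)), rep(10L, 10), ignore_attr = TRUE)

  set.seed(5)
  perm <- assign_deciles(make_lattice_graph(2, 5), 10)
  expect_setequal(perm, 1:10)

  set.seed(6)
  expect_true(all(assign_deciles(make_lattice_graph(2, 3), 1) == 1))
  expect_error(assign_deciles(make_lattice_graph(2, 2), 5), "deciles")

  # smoothness: neighbours agree clearly more often than under a random
  # relabelling of the same balanced decile sizes
  set.seed(7)
  dec <- assign_deciles(g, 10)
  agree <- function(d) mean(unlist(lapply(seq_len(g$n), function(i)
    d[g$nb[[i]]] == d[i])))
  baseline <- mean(replicate(50, agree(sample(dec))))
  expect_gt(agree(dec), 1.5 * baseline)
})

test_that("simulated cell rates match the generative rate at degenerate precisions", {
  tau_hi <- c(alpha = 1e12, gamma = 1e12, zeta = 1e12, phi = 1e12,
              omega = 1e12, delta = 1e12, kappa = 1e12, nu = 1e12)
  spec <- simulation_spec(rows = 5, cols = 5, J = 5, T_years = 4, D = 5,
                          a0 = log(0.01), tau = tau_hi, pop_scale = 1e5,
                          seed = 8)
  sim <- simulate_dataset(spec)
  rate <- sum(sim$data$deaths) / sum(sim$data$population)
  expect_lt(abs(rate - 0.01) / 0.01, 0.02)
  # components collapse to zero
  expect_lt(max(abs(sim$truth$alpha)), 1e-4)
  expect_lt(max(abs(sim$truth$omega)), 1e-4)
})

test_that("simulation is a deterministic function of the spec", {
  spec <- simulation_spec(rows = 4, cols = 4, J = 4, T_years = 5, D = 4,
                          seed = 9)
  a <- simulate_dataset(spec)
  b <- simulate_dataset(spec)
  expect_identical(a$data$deaths, b$data$deaths)
  expect_identical(a$truth, b$truth)
})

test_that("anomaly shifts are added to omega after centring", {
  base <- simulation_spec(rows = 4, cols = 4, J = 4, T_years = 5, D = 4,
                          seed = 10)
  anom <- simulation_spec(rows = 4, cols = 4, J = 4, T_years = 5, D = 4,
                          seed = 10,
                          anomalies = data.frame(area = 3, year = 2017,
                                                 shift = 0.5))
  a <- simulate_dataset(base)
  b <- simulate_dataset(anom)
  t_idx <- match(2017, a$truth$years)
  expect_equal(b$truth$omega[3, t_idx], a$truth$omega[3, t_idx] + 0.5)
  expect_equal(b$truth$omega[-3, ], a$truth$omega[-3, ])

  bad <- simulation_spec(rows = 4, cols = 4, J = 4, T_years = 5, D = 4,
                         anomalies = data.frame(area = 99, year = 2017,
                                                shift = 0.5))
  expect_error(simulate_dataset(bad), "out-of-range")
})

test_that("ground-truth components satisfy their sum-to-zero constraints", {
  sim <- small_sim()
  tr <- sim$truth
  for (v in list(tr$alpha, tr$gamma, tr$zeta, tr$phi))
    expect_lt(abs(sum(v)), 1e-8)
  expect_lt(max(abs(rowSums(tr$omega))), 1e-8)
  expect_lt(max(abs(colSums(tr$omega))), 1e-8)
  expect_lt(max(abs(rowSums(tr$delta))), 1e-8)
  expect_lt(max(abs(colSums(tr$delta))), 1e-8)
  expect_lt(max(abs(rowSums(tr$kappa))), 1e-8)
  expect_lt(max(abs(colSums(tr$kappa))), 1e-8)
  expect_lt(max(abs(rowSums(tr$nu))), 1e-8)
  expect_lt(max(abs(colSums(tr$nu))), 1e-8)
})

test_that("simulation specs round-trip through YAML", {
  spec <- simulation_spec(rows = 3, cols = 4, J = 6, T_years = 7, D = 5,
                          seed = 77,
                          anomalies = data.frame(area = 2, year = 2015,
                                                 shift = 0.4))
  p <- tempfile(fileext = ".yaml")
  write_simulation_spec(spec, p)
  spec2 <- read_simulation_spec(p)
  expect_equal(spec2$tau, spec$tau)
  expect_equal(spec2$seed, spec$seed)
  expect_equal(spec2$anomalies$shift, spec$anomalies$shift)
  expect_identical(simulate_dataset(spec)$data$deaths,
                   simulate_dataset(spec2)$data$deaths)
})
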