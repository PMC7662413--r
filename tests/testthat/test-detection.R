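test_that("exceedance probabilities are exact draw fractions with strict inequality", {
  om <- array(0, c(4, 2, 2), dimnames = list(NULL, c("A1", "A2"),
                                             2017:2018))
  om[, 1, 1] <- c(1, 1, 1, 1)
  om[, 1, 2] <- c(-1, 1, -1, 1)
  om[, 2, 1] <- c(-2, -1, 0, 1)   # zero does not count as exceeding
  om[, 2, 2] <- c(-1, -1, -1, -1)
  p <- exceedance_probability(om)
  expect_equal(p["A1", "2017"], 1)
  expect_equal(p["A1", "2018"], 0.5)
  expect_equal(p["A2", "2017"], 0.25)
  expect_equal(p["A2", "2018"], 0)
  expect_error(exceedance_probability(array(0, c(0, 2, 2))), "S >= 1")
})

test_that("exceedance equals brute-force counting on random draw grids", {
  set.seed(1)
  om <- array(rnorm(200 * 5 * 4), c(200, 5, 4))
  p <- exceedance_probability(om)
  for (i in 1:5) for (t in 1:4)
    expect_equal(p[i, t], sum(om[, i, t] > 0) / 200)
})

test_that("flagging respects threshold strictness and the detection window", {
  p <- matrix(0.5, 2, 4, dimnames = list(c("A1", "A2"), 2015:2018))
  expect_equal(nrow(detect(p, 0.95, 2015:2018)$flagged), 0)

  p["A1", "2016"] <- 0.96   # inside window
  p["A2", "2015"] <- 0.99   # outside window
  res <- detect(p, 0.95, window = 2016:2018)
  expect_equal(nrow(res$flagged), 1)
  expect_equal(res$flagged$area, "A1")
  expect_equal(res$flagged$year, 2016)

  # a probability exactly at the threshold is NOT flagged
  p2 <- matrix(c(0.95, 0.950000001), 1, 2,
               dimnames = list("A1", 2017:2018))
  res2 <- detect(p2, 0.95, 2017:2018)
  expect_equal(nrow(res2$flagged), 1)
  expect_equal(res2$flagged$year, 2018)

  expect_error(detect(p2, 0.95, integer(0)), "empty")
  expect_error(detect(p2, 1.2, 2017), "threshold")
})

test_that("raising the threshold never enlarges the flagged set", {
  set.seed(2)
  p <- matrix(runif(40), 8, 5, dimnames = list(paste0("A", 1:8),
                                               2014:2018))
  flags <- lapply(c(0.8, 0.9, 0.95, 0.99), function(th) {
    f <- detect(p, th, 2014:2018)$flagged
    paste(f$area, f$year)
  })
  for (k in 2:4) expect_true(all(flags[[k]] %in% flags[[k - 1]]))
})

test_that("per-area counts and deciles mirror the flagged table", {
  p <- matrix(0.1, 3, 3, dimnames = list(c("A1", "A2", "A3"), 2016:2018))
  p["A2", ] <- c(0.97, 0.99, 0.2)
  p["A3", "2018"] <- 0.96
  dec <- c(A1 = 1L, A2 = 3L, A3 = 7L)
  res <- detect(p, 0.95, 2016:2018, dec)
  expect_equal(res$area_counts$area[1], "A2")
  expect_equal(res$area_counts$n_years_flagged,
               c(2L, 1L))
  expect_equal(res$flagged$decile[res$flagged$area == "A3"], 7L)
})

test_that("sensitivity comparison classifies discrepancies symmetrically", {
  sim <- small_sim()
  s <- small_fit()
  cmp <- sensitivity_compare(s, s, threshold = 0.95,
                             window = 2013:2018)
  expect_true(all(cmp$table$class %in% c("both", "neither")))
  expect_equal(cmp$summary$n_area_years[cmp$summary$class == "only-A"], 0L)
  expect_equal(cmp$summary$n_area_years[cmp$summary$class == "only-B"], 0L)

  # push one cell of B over the threshold
  s_b <- s
  i <- 1; t_idx <- match(2016, s$meta$years)
  s_b$draws$omega[, i, t_idx] <- abs(s_b$draws$omega[, i, t_idx]) + 0.01
  cmp2 <- sensitivity_compare(s, s_b, threshold = 0.95,
                              window = 2013:2018)
  only_b <- cmp2$table[cmp2$table$class == "only-B", ]
  expect_equal(nrow(only_b), 1)
  expect_equal(only_b$year, 2016)

  cmp3 <- sensitivity_compare(s_b, s, threshold = 0.95,
                              window = 2013:2018)
  expect_equal(sum(cmp3$table$class == "only-A"),
               sum(cmp2$table$class == "only-B"))

  s_bad <- s
  s_bad$meta$years <- s$meta$years + 1L
  expect_error(sensitivity_compare(s, s_bad), "different areas or years")
})
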