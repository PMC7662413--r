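# Shared fixtures, built in code.

# tiny complete long-format table: 2 areas x 3 age groups x 2 years
tiny_long <- function(sex = "female") {
  grid <- expand.grid(area = c("A1", "A2"), age_group = c("0-0", "1-4", "5+"),
                      year = 2017:2018, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$sex <- sex
  grid$population <- 100 + seq_len(nrow(grid))
  grid$deaths <- seq_len(nrow(grid)) %% 4
  grid$decile <- ifelse(grid$area == "A1", 2L, 9L)
  grid
}

write_tiny_csv <- function(df = tiny_long()) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# small simulated world + fitted model, computed once and reused
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- simulation_spec(rows = 4, cols = 4, J = 5, T_years = 6,
                              D = 4, pop_scale = 2000, seed = 42)
      cache <<- simulate_dataset(spec)
    }
    cache
  }
})

small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_sim()
      cache <<- fit(sim$data, sim$graph,
                    model_config(chains = 2, burnin = 400, iter = 200,
                                 seed = 11))
    }
    cache
  }
})

# hand-rolled Poisson log-pmf sum, independent of the package internals
brute_force_loglik <- function(draw, data) {
  dec <- unname(data$decile)
  total <- 0
  I <- length(data$area_ids); J <- length(data$age_groups)
  T <- length(data$years)
  for (i in seq_len(I)) for (j in seq_len(J)) for (t in seq_len(T)) {
    pop <- data$population[i, j, t]
    if (pop <= 0) next
    eta <- draw$a0 + draw$alpha[j] + draw$gamma[i] + draw$zeta[t] +
      draw$phi[dec[i]] + draw$omega[i, t] + draw$delta[i, j] +
      draw$kappa[j, t] + draw$nu[dec[i], t]
    mu <- exp(eta) * pop
    y <- data$deaths[i, j, t]
    total <- total + y * log(mu) - mu - lgamma(y + 1)
  }
  total
}

# random component draw of the right shapes
random_draw <- function(I, J, T, D, sd = 0.3) {
  list(a0 = rnorm(1, -4, 0.5),
       alpha = rnorm(J, 0, sd), gamma = rnorm(I, 0, sd),
       zeta = rnorm(T, 0, sd), phi = rnorm(D, 0, sd),
       omega = matrix(rnorm(I * T, 0, sd), I, T),
       delta = matrix(rnorm(I * J, 0, sd), I, J),
       kappa = matrix(rnorm(J * T, 0, sd), J, T),
       nu = matrix(rnorm(D * T, 0, sd), D, T))
}

# zero components at given dimensions
zero_draw <- function(I, J, T, D, a0 = 0) {
  list(a0 = a0, alpha = numeric(J), gamma = numeric(I), zeta = numeric(T),
       phi = numeric(D), omega = matrix(0, I, T), delta = matrix(0, I, J),
       kappa = matrix(0, J, T), nu = matrix(0, D, T))
}
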