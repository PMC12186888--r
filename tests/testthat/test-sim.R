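# Stochastic drift simulator: phenotype rule, division sampling,
# scheduling and population-level invariants.

test_that("phenotype follows the strict-threshold rule with grande ties", {
  expect_equal(cell_phenotype(9, 11, 0.5), "petite")
  expect_equal(cell_phenotype(20, 0, 0.5), "grande")
  expect_equal(cell_phenotype(10, 10, 0.5), "grande")  # tie -> grande
  expect_equal(cell_phenotype(10, 10, 0.5, ties = "petite"), "petite")
  expect_equal(cell_phenotype(0, 20, 0.5), "petite")
  # vectorised, and thresholds with inexact binary representation
  expect_equal(cell_phenotype(c(12, 11), c(8, 9), threshold = 0.4),
               c("grande", "petite"))
  expect_error(cell_phenotype(0, 0), "rho0")
})

test_that("daughters always carry exactly n molecules and errors are raised", {
  set.seed(42)
  for (mode in c("independent_binomial", "partition_hypergeometric")) {
    for (i in 1:50) {
      n <- sample(c(2L, 10L, 20L, 50L), 1)
      m <- sample(0:n, 1)
      f <- stats::runif(1, 0, 4)
      d <- daughter_counts(n - m, m, f, n, mode = mode)
      expect_equal(unname(rowSums(d)), c(n, n))
      expect_true(all(d >= 0))
    }
  }
  expect_error(daughter_counts(5, 5, 1, n_copies = 11), "must equal")
  expect_error(daughter_counts(5, 5, -1), "fitness")
})

test_that("homoplasmic parents only produce homoplasmic daughters", {
  set.seed(7)
  for (mode in c("independent_binomial", "partition_hypergeometric")) {
    d_mut <- daughter_counts(0, 20, 0.7, mode = mode)
    expect_equal(unname(d_mut[, "mut"]), c(20, 20))
    d_wt <- daughter_counts(20, 0, 1.5, mode = mode)
    expect_equal(unname(d_wt[, "mut"]), c(0, 0))
  }
})

test_that("n = 2 daughter distribution matches the enumerated distribution", {
  # amplified pool at w = m = 1, f = 1: sampling with replacement gives
  # Binomial(2, 1/2) = (1/4, 1/2, 1/4); partitioning the 4-molecule pool
  # without replacement gives the hypergeometric (1/6, 4/6, 1/6)
  emp_b <- daughter_mut_distribution(1, 1, 1, 2, "independent_binomial",
                                     1e5, seed = 11)
  expect_lt(0.5 * sum(abs(emp_b - c(0.25, 0.5, 0.25))), 0.01)
  emp_h <- daughter_mut_distribution(1, 1, 1, 2, "partition_hypergeometric",
                                     1e5, seed = 12)
  expect_lt(0.5 * sum(abs(emp_h - c(1, 4, 1) / 6)), 0.01)
})

test_that("division probability reflects the amplified mutant share", {
  # w = 10, m = 10, f = 1.5 -> p = 0.6, mean daughter mut count 12
  n_draws <- 2e4
  emp <- daughter_mut_distribution(10, 10, 1.5, 20,
                                   "independent_binomial", n_draws,
                                   seed = 13)
  mean_mut <- sum((0:20) * emp)
  se <- sqrt(20 * 0.6 * 0.4 / n_draws)
  expect_lt(abs(mean_mut - 12), 3 * se)
})

test_that("deterministic initialisation gives identical cells with random ages", {
  p <- sim_params(h0 = 0.25, n_cells_init = 100, seed = 5)
  set.seed(p$seed)
  st <- init_population(p)
  expect_length(st$wt, 100)
  expect_true(all(st$mut == 5L))
  expect_true(all(st$wt == 15L))
  ages <- -st$born_at
  expect_true(all(ages >= 0 & ages < p$t_grande_min))
  expect_gt(stats::sd(ages), 0)

  p0 <- sim_params(h0 = 0, n_cells_init = 50, seed = 5)
  set.seed(5); st0 <- init_population(p0)
  expect_true(all(st0$mut == 0L))
  p1 <- sim_params(h0 = 1, n_cells_init = 50, seed = 5)
  set.seed(5); st1 <- init_population(p1)
  expect_true(all(st1$mut == 20L))
  # petite founders get ages below the petite doubling time
  ages1 <- -st1$born_at
  expect_true(all(ages1 >= 0 & ages1 < p1$t_petite_min))
})

test_that("division fires at the phenotype's doubling time", {
  p <- sim_params(n_cells_init = 1, h0 = 0, seed = 1)
  # one grande cell aged 139.5: divides on the next 1-min tick
  st <- structure(list(wt = 20L, mut = 0L, born_at = -139.5,
                       next_div = 1, t_now = 0),
                  class = "population_state")
  st2 <- step_population(st, p)
  expect_length(st2$wt, 2)
  expect_equal(st2$born_at, c(1, 1))

  # one petite cell aged 139.5 does not divide until 210 min
  pp <- sim_params(n_cells_init = 1, h0 = 1, seed = 1)
  stp <- structure(list(wt = 0L, mut = 20L, born_at = -139.5,
                        next_div = 71, t_now = 0),
                   class = "population_state")
  stp2 <- step_population(stp, pp)
  expect_length(stp2$wt, 1)
  expect_equal(stp2$t_now - stp2$born_at, 140.5)
})

test_that("population size never decreases and copy number is conserved", {
  p <- sim_params(n_cells_init = 30, h0 = 0.5, fitness = 1.2,
                  t_total_min = 600, seed = 9)
  set.seed(p$seed)
  st <- init_population(p)
  size <- length(st$wt)
  for (i in 1:300) {
    st <- step_population(st, p)
    expect_gte(length(st$wt), size)
    size <- length(st$wt)
    expect_true(all(st$wt + st$mut == 20L))
  }
  expect_gt(size, 30)
})

test_that("run_simulation is deterministic for a fixed seed", {
  p <- small_template(h0 = 0.6, fitness = 1.3, seed = 77)
  r1 <- run_simulation(p, keep_state = FALSE)
  r2 <- run_simulation(p, keep_state = FALSE)
  expect_identical(r1$suppressivity, r2$suppressivity)
  expect_identical(r1$n_cells_final, r2$n_cells_final)
  r3 <- run_simulation(small_template(h0 = 0.6, fitness = 1.3, seed = 78),
                       keep_state = FALSE)
  expect_false(identical(r1$suppressivity, r3$suppressivity))
})

test_that("homoplasmic starts stay absorbed and fractions sum to one", {
  for (f in c(0.5, 1, 2)) {
    r0 <- run_simulation(small_template(h0 = 0, fitness = f, seed = 3),
                         keep_state = FALSE)
    expect_identical(r0$suppressivity, 0)
    expect_identical(r0$wt_fixed_fraction, 1)
    r1 <- run_simulation(small_template(h0 = 1, fitness = f, seed = 3),
                         keep_state = FALSE)
    expect_identical(r1$suppressivity, 1)
  }
  r <- run_simulation(small_template(h0 = 0.5, seed = 4))
  expect_equal(r$suppressivity + r$wt_fixed_fraction + r$het_fraction, 1)
})

test_that("summaries report the three fractions and the mean mutant frequency", {
  st <- list(wt = c(0L, 20L, 10L), mut = c(20L, 0L, 10L))
  s <- summarize_population(st)
  expect_equal(s$suppressivity, 1 / 3)
  expect_equal(s$wt_fixed_fraction, 1 / 3)
  expect_equal(s$het_fraction, 1 / 3)
  expect_equal(s$mean_mut_freq, mean(c(1, 0, 0.5)))
  s2 <- summarize_population(list(wt = c(0L, 0L), mut = c(20L, 20L)))
  expect_equal(s2$mean_mut_freq, 1)
  expect_error(summarize_population(list(wt = integer(0),
                                         mut = integer(0))),
               "empty")
})

test_that("results are insensitive to halving the scheduler tick", {
  res <- sapply(1:4, function(s) {
    c(run_simulation(small_template(h0 = 0.7, seed = s, dt_min = 1),
                     keep_state = FALSE)$suppressivity,
      run_simulation(small_template(h0 = 0.7, seed = s, dt_min = 0.5),
                     keep_state = FALSE)$suppressivity)
  })
  expect_lt(abs(mean(res[1, ]) - mean(res[2, ])), 0.05)
})

test_that("trajectory recording returns the fractions over time", {
  r <- run_simulation(small_template(h0 = 0.8, seed = 6,
                                     t_total_min = 600),
                      record_every_min = 120, keep_state = FALSE)
  expect_s3_class(r$trajectory, "tbl_df")
  expect_equal(r$trajectory$time_min, seq(0, 600, by = 120))
  expect_true(all(r$trajectory$n_cells == cummax(r$trajectory$n_cells)))
  sums <- r$trajectory$supp + r$trajectory$wt_fixed + r$trajectory$het
  expect_equal(sums, rep(1, nrow(r$trajectory)))
})

test_that("suppressivity accumulates once fixation starts under equal doubling times", {
  # homoplasmy is absorbing: with no growth-rate penalty and f >= 1 the
  # mutant-fixed fraction can only accumulate (small Monte-Carlo dips
  # allowed)
  r <- run_simulation(small_template(h0 = 0.7, fitness = 1.3,
                                     t_petite_min = 140, seed = 23),
                      record_every_min = 120, keep_state = FALSE)
  supp <- r$trajectory$supp
  after <- supp[r$trajectory$time_min >= 210]
  expect_true(all(diff(after) >= -0.02))
  expect_gt(supp[length(supp)], supp[1])
})

test_that("parameter validation rejects out-of-model settings", {
  expect_error(sim_params(h0 = 1.2), "h0")
  expect_error(sim_params(fitness = -0.1), "fitness")
  expect_error(sim_params(threshold = 1.5), "threshold")
  expect_error(sim_params(t_total_min = 100), "division")
  expect_error(sim_params(n_copies = 2.5), "n_copies")
})
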