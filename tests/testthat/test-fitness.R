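# Suppressivity grid construction and kNN fitness inference.

test_that("grid boundaries are exact and the grid is deterministic", {
  tpl <- sim_params(n_cells_init = 50)
  g <- build_suppressivity_grid(c(0, 0.5, 1), c(0.5, 1), reps = 2,
                                template = tpl, master_seed = 31)
  p0 <- g$points[g$points$h0 == 0, ]
  expect_true(all(p0$suppressivity_mean == 0))
  p1 <- g$points[g$points$h0 == 1, ]
  expect_true(all(p1$suppressivity_mean == 1))
  expect_true(all(g$points$n_reps == 2))
  expect_false(any(duplicated(g$points[c("h0", "fitness")])))

  g2 <- build_suppressivity_grid(c(0, 0.5, 1), c(0.5, 1), reps = 2,
                                 template = tpl, master_seed = 31)
  expect_identical(g$replicates$suppressivity, g2$replicates$suppressivity)
})

test_that("grid results are invariant to the ordering of the value lists", {
  tpl <- sim_params(n_cells_init = 50)
  g_fwd <- build_suppressivity_grid(c(0.3, 0.7), c(0.8, 1.4), reps = 2,
                                    template = tpl, master_seed = 9)
  g_rev <- build_suppressivity_grid(c(0.7, 0.3), c(1.4, 0.8), reps = 2,
                                    template = tpl, master_seed = 9)
  expect_identical(g_fwd$replicates, g_rev$replicates)
  expect_identical(g_fwd$points, g_rev$points)
})

test_that("grid rejects empty or out-of-range inputs", {
  tpl <- sim_params(n_cells_init = 50)
  expect_error(build_suppressivity_grid(numeric(0), 1, template = tpl),
               "non-empty")
  expect_error(build_suppressivity_grid(1.5, 1, template = tpl), "0, 1")
  expect_error(build_suppressivity_grid(0.5, -1, template = tpl), ">= 0")
})

test_that("the neutral curve is the fitness-1 slice, anchored and monotone", {
  g <- inference_grid()
  nc <- neutral_curve(g)
  expect_equal(nc$h0, seq(0, 1, by = 0.1))
  expect_equal(nc$suppressivity[1], 0)
  expect_equal(nc$suppressivity[nrow(nc)], 1)
  # non-decreasing within replicate noise
  expect_true(all(diff(nc$suppressivity) > -0.03))

  tpl <- sim_params(n_cells_init = 50)
  g_no1 <- build_suppressivity_grid(c(0, 1), c(0.5, 1.5), reps = 1,
                                    template = tpl)
  expect_error(neutral_curve(g_no1), "no fitness = 1")
})

test_that("kNN averages its neighbours and honours the fitness window", {
  # toy grid of exactly 6 eligible points, all at fitness 1.2
  toy <- structure(list(
    replicates = tibble::tibble(
      h0 = rep(0.5, 8), fitness = c(rep(1.2, 6), 3, 4),
      rep = 1:8, seed = 1:8,
      suppressivity = c(seq(0.1, 0.6, by = 0.1), 0.5, 0.5)),
    points = NULL, template = NULL, fitness_range = c(1.2, 4)),
    class = "suppressivity_grid")
  e <- knn_fitness(list(strain_id = "t", h0 = 0.5, suppressivity = 0.3),
                   toy, k = 6)
  expect_equal(e$fitness_hat, 1.2)  # window (0,2) excludes fitness 3, 4
  expect_error(
    knn_fitness(list(h0 = 0.5, suppressivity = 0.3), toy, k = 7),
    "fitness window")
  expect_error(
    knn_fitness(list(h0 = 2, suppressivity = 0.3), toy, k = 6),
    "\\[0, 1\\]")
})

test_that("kNN distance ties break towards lower fitness then lower h0", {
  tied <- structure(list(
    replicates = tibble::tibble(
      h0 = c(0.4, 0.6, 0.5, 0.5), fitness = c(2, 0.5, 1.5, 1),
      rep = 1:4, seed = 1:4, suppressivity = c(0.5, 0.5, 0.6, 0.4)),
    points = NULL, template = NULL, fitness_range = c(0.5, 2)),
    class = "suppressivity_grid")
  # all four points are at distance 0.1 from (0.5, 0.5)
  e <- knn_fitness(list(h0 = 0.5, suppressivity = 0.5), tied, k = 2)
  expect_equal(sort(e$neighbor_fitness), c(0.5, 1))
})

test_that("kNN estimates stay inside the hull of neighbour fitness values", {
  g <- inference_grid()
  set.seed(14)
  for (i in 1:20) {
    e <- knn_fitness(list(h0 = stats::runif(1), suppressivity = stats::runif(1)),
                     g, k = 6)
    expect_gte(e$fitness_hat, min(e$neighbor_fitness))
    expect_lte(e$fitness_hat, max(e$neighbor_fitness))
  }
})

test_that("points on the neutral curve are estimated near fitness one", {
  g <- inference_grid()
  nc <- neutral_curve(g)
  mid <- nc[nc$h0 >= 0.5 & nc$h0 <= 0.9, ]
  ests <- vapply(seq_len(nrow(mid)), function(i) {
    knn_fitness(list(h0 = mid$h0[i], suppressivity = mid$suppressivity[i]),
                g, k = 6)$fitness_hat
  }, numeric(1))
  expect_true(all(abs(ests - 1) <= 0.15))
})

test_that("panel summaries report the signed-rank test or mark it unavailable", {
  g <- inference_grid()
  obs <- data.frame(strain_id = c("a", "b", "c"),
                    h0 = c(0.7, 0.8, 0.9),
                    suppressivity = c(0.5, 0.7, 0.9))
  pan <- estimate_panel(obs, g)
  expect_equal(nrow(pan$estimates), 3)
  expect_true(is.numeric(pan$summary$p_value))
  single <- estimate_panel(obs[1, ], g)
  expect_true(is.na(single$summary$p_value))
  expect_equal(single$summary$n, 1)
  expect_error(estimate_panel(obs[0, ], g), "empty")
})

test_that("zygote heteroplasmy is the mutant share of the combined pool", {
  expect_equal(zygote_heteroplasmy(60, 20), 0.75)
  expect_equal(zygote_heteroplasmy(0, 20), 0)
  expect_equal(zygote_heteroplasmy(20, 20), 0.5)
  expect_equal(zygote_heteroplasmy(c(60, 20), 20), c(0.75, 0.5))
  expect_error(zygote_heteroplasmy(0, 0), "positive")
  expect_error(zygote_heteroplasmy(-1, 5), "non-negative")
})
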