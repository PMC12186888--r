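## Simulation-grid construction and k-nearest-neighbour estimation of the
## intracellular fitness of deletion-bearing mtDNA.

## Internal: deterministic per-run seed from a master seed and the grid
## coordinates. A Lehmer-style mix of the rounded coordinate values makes
## the seed a function of the values themselves, so grid results are
## invariant to the ordering of the value lists.
.seed_hash <- function(master, h, f, rep) {
  v <- abs(as.double(master)) %% 2147483647
  for (x in c(round(h * 1e6), round(f * 1e6), rep)) {
    v <- (v * 48271 + x + 1) %% 2147483647
  }
  as.integer(v)
}

#' Build a suppressivity grid over (heteroplasmy, fitness)
#'
#' Runs the stochastic drift simulation for every combination of initial
#' heteroplasmy `h_values` and intracellular fitness `f_values`,
#' `reps` times each with distinct deterministic seeds, and collects the
#' resulting suppressivity values. The grid is the lookup space for
#' [knn_fitness()]: an observed (heteroplasmy, suppressivity) pair is
#' matched against simulated pairs of known fitness.
#'
#' The per-run seed is a deterministic function of `master_seed` and the
#' (h, f, rep) values, so results do not depend on the ordering of the
#' value lists.
#'
#' @param h_values Initial heteroplasmy values in `[0, 1]`.
#' @param f_values Intracellular fitness values (>= 0).
#' @param reps Independent replicate runs per grid point (default 10).
#' @param template A [sim_params()] object supplying every other model
#'   constant; its `h0`, `fitness` and `seed` fields are overridden.
#' @param master_seed Master seed; defaults to `template$seed`.
#' @return An object of class `suppressivity_grid`: a list with
#'   `replicates` (tibble: `h0`, `fitness`, `rep`, `seed`,
#'   `suppressivity`), `points` (tibble of per-point `suppressivity_mean`,
#'   `suppressivity_sd`, `n_reps`), `template` and `fitness_range`.
#' @export
#' @examples
#' g <- build_suppressivity_grid(c(0, 1), c(1), reps = 2,
#'                               template = sim_params(n_cells_init = 50))
#' g$points
build_suppressivity_grid <- function(h_values, f_values, reps = 10,
                                     template = sim_params(),
                                     master_seed = template$seed) {
  stopifnot(inherits(template, "sim_params"))
  if (length(h_values) == 0 || length(f_values) == 0)
    stop("h_values and f_values must be non-empty")
  if (any(h_values < 0 | h_values > 1)) stop("h_values must lie in [0, 1]")
  if (any(f_values < 0)) stop("f_values must be >= 0")
  if (reps < 1) stop("reps must be >= 1")

  combos <- expand.grid(rep = seq_len(reps), fitness = f_values,
                        h0 = h_values, KEEP.OUT.ATTRS = FALSE)
  seeds <- mapply(.seed_hash, MoreArgs = list(master = master_seed),
                  h = combos$h0, f = combos$fitness, rep = combos$rep)
  supp <- vapply(seq_len(nrow(combos)), function(i) {
    p <- template
    p$h0 <- combos$h0[i]
    p$fitness <- combos$fitness[i]
    p$seed <- seeds[i]
    run_simulation(p, keep_state = FALSE)$suppressivity
  }, numeric(1))

  replicates <- tibble::tibble(
    h0 = combos$h0, fitness = combos$fitness, rep = combos$rep,
    seed = seeds, suppressivity = supp
  )
  replicates <- replicates[order(replicates$h0, replicates$fitness,
                                 replicates$rep), ]
  # "|" separator: the default "." collides with decimal points
  key <- paste(replicates$h0, replicates$fitness, sep = "|")
  agg <- lapply(split(replicates, key), function(d) {
    tibble::tibble(h0 = d$h0[1], fitness = d$fitness[1],
                   suppressivity_mean = mean(d$suppressivity),
                   suppressivity_sd = stats::sd(d$suppressivity),
                   n_reps = nrow(d))
  })
  points <- do.call(rbind, agg)
  points <- points[order(points$h0, points$fitness), ]

  structure(
    list(replicates = replicates, points = points, template = template,
         fitness_range = range(f_values), master_seed = master_seed),
    class = "suppressivity_grid"
  )
}

#' @export
print.suppressivity_grid <- function(x, ...) {
  cat(sprintf(
    "suppressivity grid: %d points (%d h0 x %d fitness values), %d replicate runs\n",
    nrow(x$points), length(unique(x$points$h0)),
    length(unique(x$points$fitness)), nrow(x$replicates)))
  cat(sprintf("  fitness range [%g, %g], master seed %s\n",
              x$fitness_range[1], x$fitness_range[2],
              format(x$master_seed)))
  invisible(x)
}

#' Neutral suppressivity curve
#'
#' Extracts the fitness = 1 slice of a suppressivity grid: the expected
#' relationship between zygote heteroplasmy and suppressivity when the
#' mutant mtDNA has no replication advantage. Strains lying above this
#' curve indicate intracellular fitness greater than one.
#'
#' @param grid A [build_suppressivity_grid()] result.
#' @return Tibble with columns `h0` and `suppressivity`
#'   (per-point replicate means), ordered by `h0`.
#' @export
neutral_curve <- function(grid) {
  stopifnot(inherits(grid, "suppressivity_grid"))
  sl <- grid$points[abs(grid$points$fitness - 1) < 1e-9, ]
  if (nrow(sl) == 0)
    stop("grid contains no fitness = 1 points; rebuild with fitness 1 included")
  sl <- sl[order(sl$h0), ]
  tibble::tibble(h0 = sl$h0, suppressivity = sl$suppressivity_mean)
}

#' Estimate intracellular fitness of one strain by k-nearest neighbours
#'
#' Places the strain's observed (heteroplasmy, suppressivity) point in the
#' plane of simulated grid points and averages the intracellular fitness
#' of its `k` nearest neighbours (plain Euclidean distance; both
#' coordinates are already fractions in `[0, 1]`). Only grid points whose
#' fitness lies inside `fitness_window` are eligible, mirroring the
#' restriction of the inference to fitness 0-2 where suppressivity still
#' discriminates between fitness values.
#'
#' @param obs A list or one-row data frame with `strain_id`,
#'   `suppressivity` (fraction in `[0, 1]`) and `h0` (zygote heteroplasmy
#'   in `[0, 1]`, see [zygote_heteroplasmy()]).
#' @param grid A [build_suppressivity_grid()] result.
#' @param k Number of neighbours (default 6).
#' @param fitness_window Inclusive fitness bounds for eligible grid points
#'   (default `c(0, 2)`).
#' @param use_replicates Search individual replicate runs (default,
#'   richer neighbour set) or per-point replicate means (`FALSE`).
#' @return An object of class `fitness_estimate`: list with `strain_id`,
#'   `fitness_hat`, `neighbor_fitness`, `neighbor_index` (row indices
#'   into the searched table), `k`.
#' @export
knn_fitness <- function(obs, grid, k = 6, fitness_window = c(0, 2),
                        use_replicates = TRUE) {
  stopifnot(inherits(grid, "suppressivity_grid"))
  h <- obs$h0
  s <- obs$suppressivity
  if (is.null(h) || is.null(s) || is.na(h) || is.na(s))
    stop("observation must carry h0 and suppressivity")
  if (h < 0 || h > 1 || s < 0 || s > 1)
    stop("h0 and suppressivity must be fractions in [0, 1]")

  tab <- if (use_replicates) {
    data.frame(h0 = grid$replicates$h0, fitness = grid$replicates$fitness,
               supp = grid$replicates$suppressivity)
  } else {
    data.frame(h0 = grid$points$h0, fitness = grid$points$fitness,
               supp = grid$points$suppressivity_mean)
  }
  eligible <- which(tab$fitness >= fitness_window[1] - 1e-12 &
                    tab$fitness <= fitness_window[2] + 1e-12)
  if (length(eligible) < k)
    stop(sprintf("grid has only %d points inside the fitness window, need k = %d",
                 length(eligible), k))
  d <- sqrt((tab$h0[eligible] - h)^2 + (tab$supp[eligible] - s)^2)
  # ties broken by lower fitness, then lower h0
  ord <- order(d, tab$fitness[eligible], tab$h0[eligible])
  take <- eligible[ord[seq_len(k)]]
  structure(
    list(strain_id = if (!is.null(obs$strain_id)) as.character(obs$strain_id)
                     else NA_character_,
         fitness_hat = mean(tab$fitness[take]),
         neighbor_fitness = tab$fitness[take],
         neighbor_index = take,
         k = as.integer(k)),
    class = "fitness_estimate"
  )
}

#' @export
print.fitness_estimate <- function(x, ...) {
  cat(sprintf("strain %s: intracellular fitness %.3f (mean of k = %d neighbours, range %.2f-%.2f)\n",
              x$strain_id, x$fitness_hat, x$k,
              min(x$neighbor_fitness), max(x$neighbor_fitness)))
  invisible(x)
}

#' Estimate intracellular fitness for a panel of strains
#'
#' Applies [knn_fitness()] independently to each strain and summarises the
#' panel: mean and median fitness, and a Wilcoxon signed-rank test of the
#' hypothesis that the distribution is centred at 1 (the neutral
#' expectation of no intracellular replication advantage).
#'
#' @param observations Data frame with columns `strain_id`,
#'   `suppressivity` (fraction) and `h0`, one row per strain; see
#'   [read_strain_table()].
#' @param grid A [build_suppressivity_grid()] result.
#' @param k,fitness_window,use_replicates Passed to [knn_fitness()].
#' @param exact Passed to [stats::wilcox.test()]; the default `NULL` lets
#'   R pick an exact test for small panels and the normal approximation
#'   with continuity correction otherwise.
#' @return An object of class `fitness_panel`: list with `estimates`
#'   (tibble: `strain_id`, `h0`, `suppressivity`, `fitness_hat`) and
#'   `summary` (list: `n`, `mean_fitness`, `median_fitness`, `p_value`
#'   of the signed-rank test vs 1, `NA` when fewer than two non-tied
#'   values are available).
#' @export
estimate_panel <- function(observations, grid, k = 6,
                           fitness_window = c(0, 2), use_replicates = TRUE,
                           exact = NULL) {
  observations <- as.data.frame(observations)
  if (nrow(observations) == 0) stop("empty strain panel")
  fits <- vapply(seq_len(nrow(observations)), function(i) {
    knn_fitness(observations[i, ], grid, k = k,
                fitness_window = fitness_window,
                use_replicates = use_replicates)$fitness_hat
  }, numeric(1))
  estimates <- tibble::tibble(
    strain_id = as.character(observations$strain_id),
    h0 = observations$h0,
    suppressivity = observations$suppressivity,
    fitness_hat = fits
  )
  nontied <- fits[fits != 1]
  p_value <- if (length(fits) >= 2 && length(unique(nontied)) >= 1 &&
                 length(nontied) >= 2) {
    tryCatch(
      # kNN averages tie frequently; fall back to the normal
      # approximation with continuity correction silently
      suppressWarnings(
        stats::wilcox.test(fits, mu = 1, exact = exact,
                           correct = TRUE)$p.value),
      error = function(e) NA_real_
    )
  } else NA_real_
  structure(
    list(estimates = estimates,
         summary = list(n = length(fits), mean_fitness = mean(fits),
                        median_fitness = stats::median(fits),
                        p_value = p_value)),
    class = "fitness_panel"
  )
}

#' @export
print.fitness_panel <- function(x, ...) {
  s <- x$summary
  cat(sprintf("fitness panel: %d strains, mean %.3f, median %.3f\n",
              s$n, s$mean_fitness, s$median_fitness))
  if (is.na(s$p_value)) {
    cat("  signed-rank test vs 1: unavailable (too few non-tied values)\n")
  } else {
    cat(sprintf("  Wilcoxon signed-rank vs 1: p = %.3g\n", s$p_value))
  }
  invisible(x)
}

#' Zygote heteroplasmy from parental copy numbers
#'
#' When a rho- haploid (carrying `cn_mut` mutant mtDNA copies per nuclear
#' genome) mates with a rho+ haploid (`cn_wt` wild-type copies), the
#' zygote's initial mutant-molecule fraction is the mutant share of the
#' combined pool.
#'
#' @param cn_mut,cn_wt Non-negative copy numbers (vectorised).
#' @return `cn_mut / (cn_mut + cn_wt)`, in `[0, 1]`.
#' @export
#' @examples
#' zygote_heteroplasmy(60, 20)  # 0.75
zygote_heteroplasmy <- function(cn_mut, cn_wt) {
  if (any(cn_mut < 0) || any(cn_wt < 0))
    stop("copy numbers must be non-negative")
  tot <- cn_mut + cn_wt
  if (any(tot <= 0))
    stop("cn_mut + cn_wt must be positive")
  cn_mut / tot
}
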