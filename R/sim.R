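#' Simulation parameters for the heteroplasmic-cell drift model
#'
#' Bundles and validates every constant of the stochastic model of mtDNA
#' drift and two-level selection in a growing population of heteroplasmic
#' yeast cells. Each cell carries a fixed number `n_copies` of mtDNA
#' segregating units, split between wild-type (rho+) and deletion-bearing
#' mutant (rho-) molecules. Cells whose mutant fraction exceeds the
#' pathogenicity threshold express the slow-growing petite phenotype;
#' all others are grande. At division the mtDNA pool is amplified
#' (wild-type doubled, mutant multiplied by `2 * fitness`) and daughters
#' sample their `n_copies` molecules from the amplified pool.
#'
#' @param n_copies Number of mtDNA segregating units per cell (default 20).
#' @param fitness Intracellular fitness of the mutant mtDNA: the relative
#'   per-division increase in frequency of rho- vs rho+ molecules within a
#'   heteroplasmic cell. 1 is neutral; must be >= 0.
#' @param threshold Pathogenicity threshold: a cell is petite iff its
#'   mutant-molecule fraction strictly exceeds this value (default 0.5;
#'   see `phenotype_ties`).
#' @param t_grande_min,t_petite_min Doubling times in minutes of grande
#'   and petite cells (defaults 140 and 210).
#' @param n_cells_init Initial population size (default 1000).
#' @param t_total_min Simulated horizon in minutes (default 1440).
#' @param dt_min Scheduler tick in minutes (default 1). A cell divides on
#'   the first tick at which its age reaches its phenotype's doubling time.
#' @param h0 Initial heteroplasmy: fraction of mutant molecules in every
#'   founding cell, in `[0, 1]`.
#' @param seed Integer seed recorded with every run.
#' @param division_mode `"independent_binomial"` (default): each daughter's
#'   mutant count is an independent Binomial(n, p) draw with
#'   `p = f*m / (f*m + w)`. `"partition_hypergeometric"`: the amplified pool
#'   (2w wild-type, stochastically rounded 2*f*m mutant) is partitioned;
#'   daughter one draws without replacement, daughter two draws from the
#'   depleted pool (or a fresh amplified pool when fewer than `n_copies`
#'   molecules remain).
#' @param init_mode `"deterministic"` (default): every founding cell gets
#'   exactly `round(h0 * n_copies)` mutant molecules. `"binomial"`:
#'   per-cell Binomial(n_copies, h0) mutant counts.
#' @param phenotype_ties Phenotype assigned when the mutant fraction equals
#'   the threshold exactly: `"grande"` (default) or `"petite"`.
#'
#' @return An object of class `sim_params` (a validated list).
#' @seealso [run_simulation()], [cell_phenotype()], [daughter_counts()]
#' @export
#' @examples
#' p <- sim_params(h0 = 0.5, fitness = 1.3, seed = 42)
#' p$t_grande_min
sim_params <- function(n_copies = 20L,
                       fitness = 1,
                       threshold = 0.5,
                       t_grande_min = 140,
                       t_petite_min = 210,
                       n_cells_init = 1000L,
                       t_total_min = 1440,
                       dt_min = 1,
                       h0 = 0.5,
                       seed = 1L,
                       division_mode = c("independent_binomial",
                                         "partition_hypergeometric"),
                       init_mode = c("deterministic", "binomial"),
                       phenotype_ties = c("grande", "petite")) {
  division_mode <- match.arg(division_mode)
  init_mode <- match.arg(init_mode)
  phenotype_ties <- match.arg(phenotype_ties)

  stopifnot(
    "n_copies must be a single positive integer" =
      is.numeric(n_copies) && length(n_copies) == 1 && n_copies >= 1 &&
      n_copies == as.integer(n_copies),
    "fitness must be a single non-negative number" =
      is.numeric(fitness) && length(fitness) == 1 && fitness >= 0,
    "threshold must be in [0, 1]" =
      is.numeric(threshold) && length(threshold) == 1 &&
      threshold >= 0 && threshold <= 1,
    "doubling times must be positive" =
      t_grande_min > 0 && t_petite_min > 0,
    "n_cells_init must be a positive integer" =
      n_cells_init >= 1 && n_cells_init == as.integer(n_cells_init),
    "t_total_min must allow at least one division" =
      t_total_min >= t_grande_min,
    "dt_min must be positive" = dt_min > 0,
    "h0 must be in [0, 1]" = h0 >= 0 && h0 <= 1,
    "seed must be a single finite number" =
      is.numeric(seed) && length(seed) == 1 && is.finite(seed)
  )

  structure(
    list(n_copies = as.integer(n_copies), fitness = fitness,
         threshold = threshold, t_grande_min = t_grande_min,
         t_petite_min = t_petite_min,
         n_cells_init = as.integer(n_cells_init),
         t_total_min = t_total_min, dt_min = dt_min, h0 = h0,
         seed = as.integer(seed), division_mode = division_mode,
         init_mode = init_mode, phenotype_ties = phenotype_ties),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("mtDNA drift simulation parameters\n")
  cat(sprintf("  n_copies: %d   fitness: %g   threshold: %g\n",
              x$n_copies, x$fitness, x$threshold))
  cat(sprintf("  doubling (grande/petite): %g / %g min   tick: %g min\n",
              x$t_grande_min, x$t_petite_min, x$dt_min))
  cat(sprintf("  init: %d cells at h0 = %g (%s)   horizon: %g min\n",
              x$n_cells_init, x$h0, x$init_mode, x$t_total_min))
  cat(sprintf("  division: %s   seed: %d\n", x$division_mode, x$seed))
  invisible(x)
}

#' Phenotype of a heteroplasmic cell
#'
#' A cell expresses the petite (slow-growth, respiration-deficient)
#' phenotype when its fraction of mutant molecules strictly exceeds the
#' pathogenicity threshold; otherwise it is grande. A cell whose mutant
#' fraction equals the threshold exactly is grande by default.
#'
#' @param wt_count,mut_count Non-negative integer molecule counts
#'   (vectorised; recycled to common length).
#' @param threshold Pathogenicity threshold in `[0, 1]`.
#' @param ties Phenotype at a mutant fraction exactly equal to the
#'   threshold: `"grande"` (default) or `"petite"`.
#' @return Character vector of `"grande"` / `"petite"`.
#' @export
#' @examples
#' cell_phenotype(9, 11)   # petite
#' cell_phenotype(10, 10)  # grande: tie goes to grande
cell_phenotype <- function(wt_count, mut_count, threshold = 0.5,
                           ties = c("grande", "petite")) {
  ties <- match.arg(ties)
  k <- max(length(wt_count), length(mut_count))
  wt_count <- rep_len(wt_count, k)
  mut_count <- rep_len(mut_count, k)
  if (any(wt_count < 0 | mut_count < 0))
    stop("molecule counts must be non-negative")
  tot <- wt_count + mut_count
  if (any(tot == 0))
    stop("cell with zero mtDNA molecules (rho0) is outside the model")
  frac <- mut_count / tot
  petite <- if (ties == "grande") frac > threshold + 1e-12
            else frac >= threshold - 1e-12
  ifelse(petite, "petite", "grande")
}

## Internal: TRUE where (wt, mut) is petite. Integer counts, tolerance
## guards against threshold * n floating fuzz.
.is_petite <- function(mut, n, threshold, ties = "grande") {
  if (ties == "grande") mut > threshold * n + 1e-9
  else mut >= threshold * n - 1e-9
}

## Internal: one daughter's mutant counts in the hypergeometric mode,
## drawn from a fresh amplified pool (2w wild-type, ~2*f*m mutant,
## stochastic rounding). Falls back to a binomial draw on the amplified
## ratio when the pool holds fewer than n molecules.
.draw_from_fresh_pool <- function(w, m, f, n) {
  k <- length(w)
  W <- 2 * w
  M_real <- 2 * f * m
  M <- floor(M_real) + stats::rbinom(k, 1L, M_real - floor(M_real))
  pool <- W + M
  out <- integer(k)
  ok <- pool >= n
  if (any(ok))
    out[ok] <- stats::rhyper(sum(ok), M[ok], W[ok], n)
  if (any(!ok)) {
    p <- ifelse(pool[!ok] > 0, M[!ok] / pool[!ok], as.numeric(m[!ok] > 0))
    out[!ok] <- stats::rbinom(sum(!ok), n, p)
  }
  out
}

## Internal vectorised division: mutant counts of the two daughters of
## each (w, m) parent. Returns list(m1, m2) of integer vectors.
.divide_counts <- function(w, m, f, n, mode) {
  k <- length(w)
  if (mode == "independent_binomial") {
    denom <- f * m + w
    p <- ifelse(m == 0, 0, ifelse(denom > 0, f * m / denom, 1))
    list(stats::rbinom(k, n, p), stats::rbinom(k, n, p))
  } else {
    W <- 2 * w
    M_real <- 2 * f * m
    M <- floor(M_real) + stats::rbinom(k, 1L, M_real - floor(M_real))
    pool <- W + M
    m1 <- integer(k)
    ok <- pool >= n
    if (any(ok))
      m1[ok] <- stats::rhyper(sum(ok), M[ok], W[ok], n)
    if (any(!ok)) {
      p <- ifelse(pool[!ok] > 0, M[!ok] / pool[!ok], as.numeric(m[!ok] > 0))
      m1[!ok] <- stats::rbinom(sum(!ok), n, p)
    }
    # daughter two: depleted pool where it still holds >= n molecules,
    # otherwise an independent fresh amplified pool
    M2 <- M - m1
    W2 <- W - (n - m1)
    ok2 <- ok & M2 >= 0 & W2 >= 0 & (M2 + W2) >= n
    m2 <- integer(k)
    if (any(ok2))
      m2[ok2] <- stats::rhyper(sum(ok2), M2[ok2], W2[ok2], n)
    if (any(!ok2))
      m2[!ok2] <- .draw_from_fresh_pool(w[!ok2], m[!ok2], f, n)
    list(m1, m2)
  }
}

#' Molecule counts of the two daughters of one dividing cell
#'
#' Implements the amplification-then-sampling division rule: before
#' sampling, the wild-type pool is doubled and the mutant pool multiplied
#' by `2 * fitness`; each daughter then receives exactly `n_copies`
#' molecules. In the default `independent_binomial` mode each daughter's
#' mutant count is an independent Binomial(`n_copies`, p) draw with
#' `p = f*m / (f*m + w)`; in `partition_hypergeometric` mode the amplified
#' pool is partitioned without replacement.
#'
#' @param wt_count,mut_count Parent's molecule counts; must sum to
#'   `n_copies`.
#' @param fitness Intracellular fitness of the mutant mtDNA (>= 0).
#' @param n_copies Per-cell copy number; defaults to `wt_count + mut_count`.
#' @param mode Division sampling mode, see [sim_params()].
#' @return Integer matrix with rows `daughter1`, `daughter2` and columns
#'   `wt`, `mut`.
#' @export
#' @examples
#' set.seed(1)
#' daughter_counts(10, 10, fitness = 1.5)
daughter_counts <- function(wt_count, mut_count, fitness = 1,
                            n_copies = wt_count + mut_count,
                            mode = c("independent_binomial",
                                     "partition_hypergeometric")) {
  mode <- match.arg(mode)
  stopifnot(
    "counts must be single non-negative integers" =
      length(wt_count) == 1 && length(mut_count) == 1 &&
      wt_count >= 0 && mut_count >= 0,
    "fitness must be >= 0" = length(fitness) == 1 && fitness >= 0
  )
  if (wt_count + mut_count != n_copies)
    stop("wt_count + mut_count must equal n_copies")
  d <- .divide_counts(wt_count, mut_count, fitness, n_copies, mode)
  m <- c(d[[1]], d[[2]])
  matrix(as.integer(c(n_copies - m, m)), nrow = 2,
         dimnames = list(c("daughter1", "daughter2"), c("wt", "mut")))
}

#' Initialise the founding cell population
#'
#' Creates `n_cells_init` cells. With the default deterministic
#' initialisation every cell carries `round(h0 * n_copies)` mutant
#' molecules; with `init_mode = "binomial"` each cell's mutant count is an
#' independent Binomial(`n_copies`, `h0`) draw. The time since last
#' division is assigned uniformly at random on `[0, T)` where `T` is the
#' doubling time of the cell's initial phenotype, which desynchronises
#' divisions at the start of the run.
#'
#' Uses the current RNG state; seed externally (or via [run_simulation()],
#' which seeds from `params$seed`).
#'
#' @param params A [sim_params()] object.
#' @return An object of class `population_state`: a list with integer
#'   vectors `wt`, `mut`, numeric vectors `born_at` (negative of initial
#'   age) and `next_div` (absolute tick time of next division), and scalar
#'   `t_now`.
#' @export
init_population <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_copies
  N0 <- params$n_cells_init
  mut <- if (params$init_mode == "deterministic")
    rep.int(as.integer(round(params$h0 * n)), N0)
  else
    stats::rbinom(N0, n, params$h0)
  wt <- n - mut
  petite <- .is_petite(mut, n, params$threshold, params$phenotype_ties)
  tdouble <- ifelse(petite, params$t_petite_min, params$t_grande_min)
  age0 <- stats::runif(N0, 0, tdouble)
  dt <- params$dt_min
  next_div <- dt * ceiling((tdouble - age0) / dt)
  structure(
    list(wt = wt, mut = as.integer(mut), born_at = -age0,
         next_div = next_div, t_now = 0),
    class = "population_state"
  )
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("population of %d cells at t = %g min\n",
              length(x$wt), x$t_now))
  s <- summarize_population(x)
  cat(sprintf("  suppressivity %.3f | wt-fixed %.3f | heteroplasmic %.3f | mean mut freq %.3f\n",
              s$suppressivity, s$wt_fixed_fraction, s$het_fraction,
              s$mean_mut_freq))
  invisible(x)
}

#' Advance the population by one scheduler tick
#'
#' Moves time forward by `dt_min`. Every cell whose age has reached its
#' phenotype's doubling time divides: it is replaced in place by daughter
#' one and daughter two is appended, both with age reset to zero and
#' phenotype re-evaluated from their post-division molecule counts. No
#' cell ever dies, so the population size is non-decreasing.
#'
#' @param state A `population_state`.
#' @param params The [sim_params()] used to create it.
#' @return The updated `population_state`.
#' @export
step_population <- function(state, params) {
  stopifnot(inherits(state, "population_state"),
            inherits(params, "sim_params"))
  dt <- params$dt_min
  t_new <- state$t_now + dt
  idx <- which(state$next_div <= t_new + 1e-9)
  if (length(idx)) {
    n <- params$n_copies
    d <- .divide_counts(state$wt[idx], state$mut[idx], params$fitness, n,
                        params$division_mode)
    m1 <- d[[1]]; m2 <- d[[2]]
    tick_T_g <- dt * ceiling(params$t_grande_min / dt)
    tick_T_p <- dt * ceiling(params$t_petite_min / dt)
    nd1 <- t_new + ifelse(
      .is_petite(m1, n, params$threshold, params$phenotype_ties),
      tick_T_p, tick_T_g)
    nd2 <- t_new + ifelse(
      .is_petite(m2, n, params$threshold, params$phenotype_ties),
      tick_T_p, tick_T_g)
    state$wt[idx] <- n - m1
    state$mut[idx] <- as.integer(m1)
    state$born_at[idx] <- t_new
    state$next_div[idx] <- nd1
    state$wt <- c(state$wt, n - m2)
    state$mut <- c(state$mut, as.integer(m2))
    state$born_at <- c(state$born_at, rep.int(t_new, length(idx)))
    state$next_div <- c(state$next_div, nd2)
  }
  state$t_now <- t_new
  state
}

#' Summarise a cell population
#'
#' @param state A `population_state` (or any list with integer vectors
#'   `wt` and `mut`).
#' @return A list with `suppressivity` (fraction of cells devoid of
#'   wild-type mtDNA), `wt_fixed_fraction` (fraction homoplasmic for
#'   wild-type), `het_fraction` (still heteroplasmic; the three sum to 1),
#'   `mean_mut_freq` (population mean of the per-cell mutant-molecule
#'   fraction) and `n_cells`.
#' @export
summarize_population <- function(state) {
  wt <- state$wt; mut <- state$mut
  if (length(wt) == 0) stop("empty population")
  n_cells <- length(wt)
  supp <- sum(wt == 0L) / n_cells
  fixed <- sum(mut == 0L) / n_cells
  list(suppressivity = supp,
       wt_fixed_fraction = fixed,
       het_fraction = 1 - supp - fixed,
       mean_mut_freq = mean(mut / (wt + mut)),
       n_cells = n_cells)
}

#' Run one stochastic simulation of mtDNA drift and selection
#'
#' Simulates a growing population of heteroplasmic cells for
#' `t_total_min` minutes under the amplification-then-sampling division
#' rule, with the petite/grande phenotype (and hence doubling time) set by
#' the pathogenicity threshold. Deterministic for a fixed
#' `params$seed`. The scheduler processes only division events, so runs
#' with millions of cells complete in seconds.
#'
#' @param params A [sim_params()] object.
#' @param record_every_min Optional interval in minutes at which to record
#'   the population fractions; `NULL` (default) records no trajectory.
#' @param keep_state Keep the final `population_state` in the result
#'   (default `TRUE`; set `FALSE` to save memory in large sweeps).
#' @return An object of class `simulation_result`: a list with the final
#'   summary fields of [summarize_population()], plus `seed`, `params`,
#'   optional `trajectory` (a tibble with columns `time_min`, `supp`,
#'   `wt_fixed`, `het`, `mean_mut_freq`, `n_cells`) and optional
#'   `final_state`. `suppressivity` is the fraction of cells devoid of
#'   wild-type mtDNA at the end of the run.
#' @export
#' @examples
#' r <- run_simulation(sim_params(h0 = 0.5, fitness = 1.3,
#'                                n_cells_init = 100, seed = 7))
#' r$suppressivity
run_simulation <- function(params, record_every_min = NULL,
                           keep_state = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  dt <- params$dt_min
  n <- params$n_copies
  f <- params$fitness
  tick_T_g <- dt * ceiling(params$t_grande_min / dt)
  tick_T_p <- dt * ceiling(params$t_petite_min / dt)

  st <- init_population(params)
  wt <- st$wt; mut <- st$mut; born <- st$born_at; nd <- st$next_div
  len <- length(wt)
  cap <- len * 4L
  wt <- c(wt, integer(cap - len)); mut <- c(mut, integer(cap - len))
  born <- c(born, numeric(cap - len)); nd <- c(nd, rep(Inf, cap - len))

  n_ticks <- floor(params$t_total_min / dt + 1e-9)
  traj <- if (!is.null(record_every_min)) {
    s0 <- summarize_population(list(wt = wt[seq_len(len)],
                                    mut = mut[seq_len(len)]))
    list(c(time_min = 0, supp = s0$suppressivity,
           wt_fixed = s0$wt_fixed_fraction, het = s0$het_fraction,
           mean_mut_freq = s0$mean_mut_freq, n_cells = s0$n_cells))
  } else NULL

  # Division events are bucketed by tick: a dividing cell's daughters are
  # rescheduled a fixed number of ticks ahead (one offset per phenotype),
  # so each tick touches only the cells actually dividing then.
  k_g <- as.integer(ceiling(params$t_grande_min / dt))
  k_p <- as.integer(ceiling(params$t_petite_min / dt))
  sched <- vector("list", n_ticks)
  k_init <- pmax(1L, as.integer(round(nd[seq_len(len)] / dt)))
  in_horizon <- k_init <= n_ticks
  if (any(in_horizon)) {
    by_tick <- split(which(in_horizon), k_init[in_horizon])
    for (nm in names(by_tick)) sched[[as.integer(nm)]] <- by_tick[[nm]]
  }

  t_now <- 0
  for (k in seq_len(n_ticks)) {
    t_now <- k * dt
    idx <- sched[[k]]
    n_div <- length(idx)
    if (n_div) {
      d <- .divide_counts(wt[idx], mut[idx], f, n, params$division_mode)
      m1 <- d[[1]]; m2 <- d[[2]]
      petite1 <- .is_petite(m1, n, params$threshold, params$phenotype_ties)
      petite2 <- .is_petite(m2, n, params$threshold, params$phenotype_ties)
      if (len + n_div > cap) {
        cap <- max(cap * 2L, len + n_div)
        wt <- c(wt, integer(cap - length(wt)))
        mut <- c(mut, integer(cap - length(mut)))
        born <- c(born, numeric(cap - length(born)))
        nd <- c(nd, rep(Inf, cap - length(nd)))
      }
      wt[idx] <- n - m1
      mut[idx] <- as.integer(m1)
      born[idx] <- t_now
      nd[idx] <- t_now + ifelse(petite1, tick_T_p, tick_T_g)
      new_idx <- len + seq_len(n_div)
      wt[new_idx] <- n - m2
      mut[new_idx] <- as.integer(m2)
      born[new_idx] <- t_now
      nd[new_idx] <- t_now + ifelse(petite2, tick_T_p, tick_T_g)
      len <- len + n_div
      kg_next <- k + k_g
      kp_next <- k + k_p
      if (kg_next <= n_ticks) {
        grande_kids <- c(idx[!petite1], new_idx[!petite2])
        if (length(grande_kids))
          sched[[kg_next]] <- c(sched[[kg_next]], grande_kids)
      }
      if (kp_next <= n_ticks) {
        petite_kids <- c(idx[petite1], new_idx[petite2])
        if (length(petite_kids))
          sched[[kp_next]] <- c(sched[[kp_next]], petite_kids)
      }
    }
    if (!is.null(record_every_min) &&
        abs(t_now %% record_every_min) < 1e-9) {
      s <- summarize_population(list(wt = wt[seq_len(len)],
                                     mut = mut[seq_len(len)]))
      traj[[length(traj) + 1L]] <-
        c(time_min = t_now, supp = s$suppressivity,
          wt_fixed = s$wt_fixed_fraction, het = s$het_fraction,
          mean_mut_freq = s$mean_mut_freq, n_cells = s$n_cells)
    }
  }

  final <- structure(
    list(wt = wt[seq_len(len)], mut = mut[seq_len(len)],
         born_at = born[seq_len(len)], next_div = nd[seq_len(len)],
         t_now = t_now),
    class = "population_state"
  )
  s <- summarize_population(final)
  res <- list(
    suppressivity = s$suppressivity,
    wt_fixed_fraction = s$wt_fixed_fraction,
    het_fraction = s$het_fraction,
    mean_mut_freq = s$mean_mut_freq,
    n_cells_final = s$n_cells,
    seed = params$seed,
    params = params,
    trajectory = if (!is.null(traj))
      tibble::as_tibble(do.call(rbind, traj)) else NULL,
    final_state = if (keep_state) final else NULL
  )
  class(res) <- "simulation_result"
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("mtDNA drift simulation result\n")
  cat(sprintf("  h0 = %g, fitness = %g, seed = %d -> %d cells after %g min\n",
              x$params$h0, x$params$fitness, x$seed, x$n_cells_final,
              x$params$t_total_min))
  cat(sprintf("  suppressivity %.4f | wt-fixed %.4f | heteroplasmic %.4f | mean mut freq %.4f\n",
              x$suppressivity, x$wt_fixed_fraction, x$het_fraction,
              x$mean_mut_freq))
  invisible(x)
}
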