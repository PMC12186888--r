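## Synthetic-data generators emulating the statistical structure of the
## study's inputs: depth profiles with deletions and AT-region dropout,
## plate-reader growth curves, and strain panels with known true
## intracellular fitness.

#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the generators with defaults matching the study
#' system: an 85,779-bp mitochondrial reference whose GC-rich window
#' (positions 14,000-20,000) is sequenced uniformly while the AT-rich
#' remainder suffers an approximately three-fold read-depth dropout, a
#' wild-type parental copy number taken from the coverage-based estimate
#' of the wild-type control, and a 22-strain panel whose mutant copy
#' numbers exceed the wild-type value.
#'
#' @param seed Integer master seed; every generator is bit-reproducible
#'   given `(seed, config)`.
#' @param mt_genome_length Mitochondrial reference length (default 85779,
#'   the S288C mitochondrial genome).
#' @param nuc_genome_length Length of the simulated pooled nuclear depth
#'   profile (default 20000; a representative sample, not the full
#'   nuclear genome).
#' @param base_nuclear_depth Mean nuclear read depth (default 50).
#' @param true_ratio True mtDNA/nDNA copy-number ratio (default 20).
#' @param deletions List of 1-based inclusive `c(start, end)` intervals
#'   with zero mtDNA depth.
#' @param at_dropout_factor Depth divisor applied outside the GC window
#'   (default 3, inside the observed 2.3-3.4x range).
#' @param noise_dispersion Negative-binomial dispersion of per-position
#'   depth (variance `mu + d * mu^2`); 0 gives noiseless rounded-mean
#'   depths (default 0.2).
#' @param gc_window GC-rich window `c(start, end)` (default
#'   `c(14000, 20000)`).
#' @param assay_colonies Colonies counted per suppressivity assay
#'   (default 100); `Inf` gives noise-free assays.
#' @param panel_fitness True intracellular fitness per panel strain
#'   (default 22 values spread over 0.8-1.6).
#' @param panel_copy_numbers Mutant mtDNA copy number per panel strain
#'   (default 22 values spread over 25-150, all exceeding the wild-type
#'   parental copy number as observed for deletion-bearing strains).
#' @param wt_parent_copy_number Wild-type parental copy number
#'   (default 15.5).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         mt_genome_length = 85779L,
                         nuc_genome_length = 20000L,
                         base_nuclear_depth = 50,
                         true_ratio = 20,
                         deletions = list(),
                         at_dropout_factor = 3,
                         noise_dispersion = 0.2,
                         gc_window = c(14000, 20000),
                         assay_colonies = 100,
                         panel_fitness = seq(0.8, 1.6, length.out = 22),
                         panel_copy_numbers = seq(25, 150, length.out = 22),
                         wt_parent_copy_number = 15.5) {
  stopifnot(
    "mt_genome_length must be positive" = mt_genome_length >= 1,
    "base_nuclear_depth must be positive" = base_nuclear_depth > 0,
    "true_ratio must be positive" = true_ratio > 0,
    "at_dropout_factor must be >= 1" = at_dropout_factor >= 1,
    "noise_dispersion must be >= 0" = noise_dispersion >= 0,
    "assay_colonies must be positive" = assay_colonies > 0,
    "panel lists must have equal length" =
      length(panel_fitness) == length(panel_copy_numbers),
    "wt_parent_copy_number must be positive" = wt_parent_copy_number > 0
  )
  for (d in deletions) {
    if (length(d) != 2 || d[1] < 1 || d[2] < d[1] ||
        d[2] > mt_genome_length)
      stop("each deletion must be c(start, end) inside the mt genome")
  }
  structure(
    list(seed = as.integer(seed),
         mt_genome_length = as.integer(mt_genome_length),
         nuc_genome_length = as.integer(nuc_genome_length),
         base_nuclear_depth = base_nuclear_depth,
         true_ratio = true_ratio, deletions = deletions,
         at_dropout_factor = at_dropout_factor,
         noise_dispersion = noise_dispersion,
         gc_window = gc_window,
         assay_colonies = assay_colonies,
         panel_fitness = panel_fitness,
         panel_copy_numbers = panel_copy_numbers,
         wt_parent_copy_number = wt_parent_copy_number),
    class = "synth_config"
  )
}

## Internal: NB (or noiseless) per-position depths with mean vector mu.
.depth_noise <- function(mu, dispersion) {
  if (dispersion == 0) return(round(mu))
  out <- numeric(length(mu))
  pos <- mu > 0
  out[pos] <- stats::rnbinom(sum(pos), mu = mu[pos], size = 1 / dispersion)
  out
}

#' Generate synthetic mitochondrial and nuclear depth profiles
#'
#' Nuclear depth is negative-binomial around `base_nuclear_depth`.
#' Mitochondrial depth has mean
#' `base_nuclear_depth * true_ratio / dropout(pos)`, where `dropout(pos)`
#' equals `at_dropout_factor` outside the GC window and 1 inside it, and
#' is exactly zero inside every deletion. With `noise_dispersion = 0`
#' depths are the rounded means.
#'
#' @param cfg A [synth_config()].
#' @return List with `mt` and `nuc` [depth_profile()]s and `truth` (list:
#'   `true_ratio`, `deletions`, `at_dropout_factor`, `base_nuclear_depth`).
#' @export
#' @examples
#' p <- gen_depth_profiles(synth_config(noise_dispersion = 0,
#'                                      at_dropout_factor = 1))
#' mean(p$mt$depth) / mean(p$nuc$depth)  # the true ratio, 20
gen_depth_profiles <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  nuc_depth <- .depth_noise(rep(cfg$base_nuclear_depth,
                                cfg$nuc_genome_length),
                            cfg$noise_dispersion)
  pos <- seq_len(cfg$mt_genome_length)
  dropout <- ifelse(pos >= cfg$gc_window[1] & pos <= cfg$gc_window[2],
                    1, cfg$at_dropout_factor)
  mu <- cfg$base_nuclear_depth * cfg$true_ratio / dropout
  for (d in cfg$deletions) mu[d[1]:d[2]] <- 0
  mt_depth <- .depth_noise(mu, cfg$noise_dispersion)
  list(
    mt = depth_profile(mt_depth, "chrM_synthetic"),
    nuc = depth_profile(nuc_depth, "nuclear_synthetic"),
    truth = list(true_ratio = cfg$true_ratio, deletions = cfg$deletions,
                 at_dropout_factor = cfg$at_dropout_factor,
                 base_nuclear_depth = cfg$base_nuclear_depth)
  )
}

#' Generate a synthetic plate-reader growth curve
#'
#' Logistic optical-density trajectory
#' `od(t) = K * od0 * exp(mu t) / (K + od0 * (exp(mu t) - 1))` with
#' multiplicative log-normal noise. `K = Inf` gives a pure exponential.
#'
#' @param mu Intrinsic specific growth rate (1/min), >= 0.
#' @param od0 Initial OD (> 0, default 0.05).
#' @param K Carrying capacity in OD units (> od0; default 2; may be
#'   `Inf`).
#' @param noise_sd Standard deviation of log-normal multiplicative noise
#'   (default 0).
#' @param n_points Number of samples (default 216, i.e. 18 h at 5-min
#'   intervals).
#' @param dt_min Sampling interval in minutes (default 5).
#' @param seed Integer seed.
#' @param well_id Well label.
#' @return A [growth_curve()].
#' @export
gen_growth_curve <- function(mu, od0 = 0.05, K = 2, noise_sd = 0,
                             n_points = 216, dt_min = 5, seed = 1L,
                             well_id = "synthetic") {
  if (mu < 0) stop("mu must be >= 0")
  if (od0 <= 0) stop("od0 must be positive")
  if (K <= od0) stop("K must exceed od0")
  if (n_points < 2) stop("need at least two points")
  set.seed(seed)
  tm <- (seq_len(n_points) - 1) * dt_min
  e <- exp(mu * tm)
  od <- if (is.infinite(K)) od0 * e else K * od0 * e / (K + od0 * (e - 1))
  if (noise_sd > 0) od <- od * exp(stats::rnorm(n_points, 0, noise_sd))
  growth_curve(tm, od, well_id)
}

#' Generate a synthetic strain panel with known intracellular fitness
#'
#' Emulates the experimental strain panel: each strain has a mutant copy
#' number (giving its zygote heteroplasmy against the wild-type parental
#' copy number) and a true intracellular fitness; its true suppressivity
#' is obtained by running the stochastic simulation at that
#' (heteroplasmy, fitness), and the observed suppressivity adds binomial
#' colony-sampling noise with `assay_colonies` colonies.
#'
#' @param cfg A [synth_config()]; `panel_fitness`, `panel_copy_numbers`,
#'   `wt_parent_copy_number`, `assay_colonies` and `seed` are used.
#' @param sim_template A [sim_params()] supplying the simulation
#'   constants (its `h0`, `fitness`, `seed` are overridden per strain).
#' @return Tibble with columns `strain_id`, `true_fitness`, `cn_mut`,
#'   `h0`, `true_suppressivity` (fraction), `suppressivity_pct`
#'   (observed, percent).
#' @export
gen_strain_panel <- function(cfg, sim_template = sim_params()) {
  stopifnot(inherits(cfg, "synth_config"),
            inherits(sim_template, "sim_params"))
  n_strain <- length(cfg$panel_fitness)
  if (n_strain == 0) stop("empty panel configuration")
  h0 <- zygote_heteroplasmy(cfg$panel_copy_numbers,
                            cfg$wt_parent_copy_number)
  true_supp <- vapply(seq_len(n_strain), function(i) {
    p <- sim_template
    p$h0 <- h0[i]
    p$fitness <- cfg$panel_fitness[i]
    p$seed <- .seed_hash(cfg$seed, h0[i], cfg$panel_fitness[i], i)
    run_simulation(p, keep_state = FALSE)$suppressivity
  }, numeric(1))
  set.seed(.seed_hash(cfg$seed, 0, 0, n_strain + 1L))
  observed <- if (is.infinite(cfg$assay_colonies)) {
    true_supp
  } else {
    stats::rbinom(n_strain, cfg$assay_colonies, true_supp) /
      cfg$assay_colonies
  }
  tibble::tibble(
    strain_id = sprintf("synth%02d", seq_len(n_strain)),
    true_fitness = cfg$panel_fitness,
    cn_mut = cfg$panel_copy_numbers,
    h0 = h0,
    true_suppressivity = true_supp,
    suppressivity_pct = 100 * observed
  )
}
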