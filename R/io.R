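## Readers and writers for the tabular formats the package consumes:
## samtools-depth-style TSV, headered strain/assay TSV, growth-curve CSV,
## grid TSV, BED export and flat key = value configuration files.

#' Read per-base depth profiles from a samtools-depth-style TSV
#'
#' Expects three tab-separated columns without a header: reference name,
#' 1-based position, depth. Positions absent from the file are treated as
#' depth 0 (samtools depth omits zero rows unless asked), up to the
#' largest observed position per reference or a declared length.
#'
#' @param path Path to the TSV.
#' @param ref_lengths Optional named vector of reference lengths to pad
#'   profiles to.
#' @return Named list of [depth_profile()]s, one per reference name.
#' @export
read_depth_tsv <- function(path, ref_lengths = NULL) {
  if (!file.exists(path)) stop(sprintf("depth file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop(sprintf("empty depth file: %s", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop(sprintf("line %d of %s: expected 3 tab-separated columns",
                 bad[1], path))
  refs <- vapply(parts, `[[`, character(1), 1)
  pos <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2)))
  dep <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3)))
  if (anyNA(pos) || any(pos != floor(pos)) || any(pos < 1))
    stop(sprintf("line %d of %s: position is not a positive integer",
                 which(is.na(pos) | pos != floor(pos) | pos < 1)[1], path))
  if (anyNA(dep) || any(dep < 0))
    stop(sprintf("line %d of %s: depth is not a non-negative number",
                 which(is.na(dep) | dep < 0)[1], path))
  out <- list()
  for (ref in unique(refs)) {
    sel <- refs == ref
    len <- if (!is.null(ref_lengths) && ref %in% names(ref_lengths))
      ref_lengths[[ref]] else max(pos[sel])
    depth <- numeric(len)
    depth[pos[sel]] <- dep[sel]
    out[[ref]] <- depth_profile(depth, ref)
  }
  out
}

#' Write a depth profile as samtools-depth-style TSV
#'
#' @param profile A [depth_profile()].
#' @param path Output path.
#' @param keep_zeros Write rows for zero-depth positions (default `TRUE`,
#'   so the round trip is exact even without a declared length).
#' @export
write_depth_tsv <- function(profile, path, keep_zeros = TRUE) {
  stopifnot(inherits(profile, "depth_profile"))
  pos <- seq_along(profile$depth)
  keep <- if (keep_zeros) rep(TRUE, length(pos)) else profile$depth > 0
  utils::write.table(
    data.frame(profile$ref_name, pos[keep], profile$depth[keep]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a strain table for fitness inference
#'
#' Expects a headered TSV with columns `strain_id`, `suppressivity_pct`
#' (in `[0, 100]`), `cn_mut` and `cn_wt_parent` (non-negative copy
#' numbers). Computes each strain's zygote heteroplasmy and converts
#' suppressivity to a fraction.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `strain_id`, `suppressivity` (fraction)
#'   and `h0`, ready for [estimate_panel()].
#' @export
read_strain_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("strain table not found: %s", path))
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  req <- c("strain_id", "suppressivity_pct", "cn_mut", "cn_wt_parent")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop(sprintf("strain table %s lacks column(s): %s", path,
                 paste(miss, collapse = ", ")))
  if (nrow(d) == 0) stop(sprintf("strain table is empty: %s", path))
  if (any(d$suppressivity_pct < 0 | d$suppressivity_pct > 100))
    stop("suppressivity_pct must lie in [0, 100]")
  if (any(d$cn_mut < 0) || any(d$cn_wt_parent < 0))
    stop("copy numbers must be non-negative")
  tibble::tibble(
    strain_id = as.character(d$strain_id),
    suppressivity = d$suppressivity_pct / 100,
    h0 = zygote_heteroplasmy(d$cn_mut, d$cn_wt_parent)
  )
}

#' Read a suppressivity assay / drift table
#'
#' Expects a headered TSV with columns `strain_id`, `assessment_index`
#' and either colony counts (`petite`, `grande`) or directly
#' `suppressivity_pct`. Colony counts, when present, are converted with
#' [suppressivity_from_counts()].
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `strain_id`, `assessment_index`,
#'   `suppressivity_pct`, ready for [drift_comparison()].
#' @export
read_assay_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("assay table not found: %s", path))
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("strain_id", "assessment_index") %in% names(d)))
    stop(sprintf("assay table %s needs strain_id and assessment_index", path))
  if (nrow(d) == 0) stop(sprintf("assay table is empty: %s", path))
  supp <- if ("suppressivity_pct" %in% names(d)) {
    if (any(d$suppressivity_pct < 0 | d$suppressivity_pct > 100))
      stop("suppressivity_pct must lie in [0, 100]")
    d$suppressivity_pct
  } else if (all(c("petite", "grande") %in% names(d))) {
    suppressivity_from_counts(d$petite, d$grande)
  } else {
    stop(sprintf("assay table %s needs petite/grande or suppressivity_pct",
                 path))
  }
  tibble::tibble(strain_id = as.character(d$strain_id),
                 assessment_index = as.integer(d$assessment_index),
                 suppressivity_pct = supp)
}

#' Read long-format growth curves from CSV
#'
#' Expects a headered CSV with columns `well_id`, `time_min`, `od`.
#'
#' @param path Path to the CSV.
#' @return Named list of [growth_curve()]s, one per well.
#' @export
read_growth_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("growth CSV not found: %s", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("well_id", "time_min", "od")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop(sprintf("growth CSV %s lacks column(s): %s", path,
                 paste(miss, collapse = ", ")))
  lapply(split(d, d$well_id), function(w) {
    w <- w[order(w$time_min), ]
    growth_curve(w$time_min, w$od, w$well_id[1])
  })
}

#' Write / read a suppressivity grid as TSV
#'
#' The replicate-level table (`h0`, `fitness`, `rep`, `seed`,
#' `suppressivity`) is written with a header; reading reconstructs the
#' per-point means so the grid can be reused without re-simulation.
#'
#' @param grid A [build_suppressivity_grid()] result.
#' @param path TSV path.
#' @return `write_grid_tsv` returns `path` invisibly; `read_grid_tsv`
#'   returns a `suppressivity_grid` (with a `NULL` template).
#' @export
write_grid_tsv <- function(grid, path) {
  stopifnot(inherits(grid, "suppressivity_grid"))
  utils::write.table(as.data.frame(grid$replicates), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_tsv
#' @export
read_grid_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("grid file not found: %s", path))
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  req <- c("h0", "fitness", "rep", "seed", "suppressivity")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop(sprintf("grid file %s lacks column(s): %s", path,
                 paste(miss, collapse = ", ")))
  replicates <- tibble::as_tibble(d[req])
  key <- paste(replicates$h0, replicates$fitness, sep = "|")
  agg <- lapply(split(replicates, key), function(g) {
    tibble::tibble(h0 = g$h0[1], fitness = g$fitness[1],
                   suppressivity_mean = mean(g$suppressivity),
                   suppressivity_sd = stats::sd(g$suppressivity),
                   n_reps = nrow(g))
  })
  points <- do.call(rbind, agg)
  points <- points[order(points$h0, points$fitness), ]
  structure(
    list(replicates = replicates, points = points, template = NULL,
         fitness_range = range(replicates$fitness), master_seed = NA),
    class = "suppressivity_grid"
  )
}

#' Write retained segments as BED
#'
#' Converts the 1-based inclusive segment table of
#' [detect_retained_segments()] to 0-based half-open BED.
#'
#' @param segments Tibble with `start`, `end` (1-based inclusive).
#' @param path Output path.
#' @param chrom Chromosome name for the BED records.
#' @export
write_bed <- function(segments, path, chrom = "chrM") {
  if (nrow(segments) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  utils::write.table(
    data.frame(chrom, segments$start - 1L, segments$end),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file as region specifications
#'
#' Converts 0-based half-open BED intervals to the package's 1-based
#' inclusive [region_spec()]s.
#'
#' @param path BED path (at least 3 columns; a 4th column provides the
#'   region id).
#' @return List of [region_spec()]s.
#' @export
read_bed_regions <- function(path) {
  if (!file.exists(path)) stop(sprintf("BED file not found: %s", path))
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 3) stop(sprintf("BED file %s needs at least 3 columns", path))
  lapply(seq_len(nrow(d)), function(i) {
    id <- if (ncol(d) >= 4) as.character(d[i, 4])
          else sprintf("%s_%d_%d", d[i, 1], d[i, 2], d[i, 3])
    region_spec(id, as.integer(d[i, 2]) + 1L, as.integer(d[i, 3]))
  })
}

#' Read a flat key = value configuration file
#'
#' Parses a minimal TOML-style flat configuration: one `key = value` pair
#' per line, `#` comments, quoted strings, booleans `true`/`false`,
#' numbers, and bracketed numeric arrays `[1, 2, 3]`.
#'
#' @param path Configuration file path.
#' @return Named list of parsed values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3)
      stop(sprintf("config line not of the form key = value: '%s'", ln))
    key <- m[2]; val <- trimws(m[3])
    out[[key]] <-
      if (grepl('^".*"$', val)) {
        substr(val, 2, nchar(val) - 1)
      } else if (val %in% c("true", "false")) {
        val == "true"
      } else if (grepl("^\\[.*\\]$", val)) {
        inner <- trimws(substr(val, 2, nchar(val) - 1))
        if (!nzchar(inner)) numeric(0)
        else as.numeric(strsplit(inner, ",")[[1]])
      } else {
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num)) val else num
      }
  }
  out
}

#' Build simulation parameters from a configuration list
#'
#' Maps a flat configuration (see [read_config()]) one-to-one onto
#' [sim_params()]; unknown keys are rejected.
#'
#' @param config Named list, e.g. from [read_config()].
#' @return A [sim_params()] object.
#' @export
config_to_sim_params <- function(config) {
  allowed <- names(formals(sim_params))
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop(sprintf("unknown simulation config key(s): %s",
                 paste(unknown, collapse = ", ")))
  do.call(sim_params, config)
}

#' Serialise a simulation result to JSON
#'
#' Writes the scalar fields of a [run_simulation()] result (without the
#' raw cells) plus the parameters and package version as a provenance
#' record.
#'
#' @param result A `simulation_result`.
#' @param path Output path, or `NULL` to return the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_result_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "simulation_result"))
  payload <- list(
    suppressivity = result$suppressivity,
    wt_fixed_fraction = result$wt_fixed_fraction,
    het_fraction = result$het_fraction,
    mean_mut_freq = result$mean_mut_freq,
    n_cells_final = result$n_cells_final,
    seed = result$seed,
    params = unclass(result$params),
    package_version = as.character(utils::packageVersion("rhodrift"))
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
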