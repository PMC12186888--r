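## mtDNA/nDNA copy-number estimation from per-base read-depth profiles.

#' Per-base read-depth profile
#'
#' A light container for the read depth over one reference sequence at
#' contiguous 1-based positions `1..length(depth)`.
#'
#' @param depth Non-negative numeric vector of per-position depths.
#' @param ref_name Reference sequence name.
#' @return An object of class `depth_profile`.
#' @export
depth_profile <- function(depth, ref_name = "ref") {
  if (length(depth) == 0) stop("empty depth profile")
  if (any(is.na(depth)) || any(depth < 0))
    stop("depths must be non-negative and non-missing")
  structure(list(ref_name = as.character(ref_name),
                 depth = as.numeric(depth)),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("depth profile '%s': %d positions, mean depth %.1f\n",
              x$ref_name, length(x$depth), mean(x$depth)))
  invisible(x)
}

#' @export
length.depth_profile <- function(x) length(x$depth)

#' Region specification (1-based, inclusive)
#'
#' @param region_id Region label.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(region_id, start, end) {
  if (start < 1 || end < start)
    stop("need 1 <= start <= end")
  structure(list(region_id = as.character(region_id),
                 start = as.integer(start), end = as.integer(end)),
            class = "region_spec")
}

#' Built-in mtDNA quantification regions
#'
#' The three short regions of the S288C mitochondrial reference used for
#' copy-number quantification, chosen so that every deletion-bearing
#' strain retains at least one of them, plus the GC-rich window
#' (14,000-20,000) where read depth is uniform but which some strains
#' have lost. Coordinates are 1-based inclusive on the 85,779-bp
#' mitochondrial reference.
#'
#' @param include_gc_window Also return the GC-rich window (default
#'   `FALSE`).
#' @return A list of [region_spec()] objects.
#' @export
mt_quant_regions <- function(include_gc_window = FALSE) {
  regions <- list(region_spec("region1", 8002, 8153),
                  region_spec("region2", 31222, 31305),
                  region_spec("region3", 48195, 48296))
  if (include_gc_window)
    regions <- c(regions, list(region_spec("gc_window", 14000, 20000)))
  regions
}

#' Quantile-trimmed mean nuclear depth
#'
#' Mean read depth over positions whose depth lies within the
#' `[lo_q, hi_q]` empirical quantiles of the per-position depth
#' distribution. Trimming discards the extreme-coverage positions (rRNA
#' repeats, telomeres) that would otherwise inflate or deflate the
#' nuclear baseline.
#'
#' @param profile A [depth_profile()] of the (pooled) nuclear genome.
#' @param lo_q,hi_q Quantile bounds, `0 <= lo_q < hi_q <= 1`
#'   (default 0.025 and 0.975).
#' @return Trimmed mean depth (scalar).
#' @export
nuclear_mean_depth <- function(profile, lo_q = 0.025, hi_q = 0.975) {
  stopifnot(inherits(profile, "depth_profile"))
  if (!(lo_q >= 0 && hi_q <= 1 && lo_q < hi_q))
    stop("need 0 <= lo_q < hi_q <= 1")
  q <- stats::quantile(profile$depth, c(lo_q, hi_q), names = FALSE)
  keep <- profile$depth >= q[1] & profile$depth <= q[2]
  if (!any(keep)) stop("quantile trimming removed every position")
  mean(profile$depth[keep])
}

#' Mean depth over one region
#'
#' @param profile A [depth_profile()].
#' @param region A [region_spec()] (1-based inclusive).
#' @return Arithmetic mean depth over `start..end`.
#' @export
region_mean_depth <- function(profile, region) {
  stopifnot(inherits(profile, "depth_profile"),
            inherits(region, "region_spec"))
  if (region$start > length(profile$depth))
    stop(sprintf("region '%s' (%d-%d) lies outside the profile (length %d)",
                 region$region_id, region$start, region$end,
                 length(profile$depth)))
  end <- min(region$end, length(profile$depth))
  mean(profile$depth[region$start:end])
}

#' mtDNA/nDNA copy-number ratio from depth profiles
#'
#' Computes, for each quantification region, the ratio of the region's
#' mean mitochondrial depth to the quantile-trimmed mean nuclear depth,
#' and reports the maximum across regions as the copy-number estimate.
#' The maximum is used because deletion-bearing strains retain a random
#' subset of the reference, so only regions actually present carry
#' signal; taking the maximum reads the estimate from a retained region.
#'
#' @param mt_profile Mitochondrial [depth_profile()].
#' @param nuc_profile Nuclear [depth_profile()] (all contigs pooled).
#' @param regions List of [region_spec()]s
#'   (default the three built-in quantification regions).
#' @param trim Nuclear quantile trim bounds (default `c(0.025, 0.975)`).
#' @param retention_floor A region counts as retained when its ratio
#'   exceeds this value (default 0.5 mtDNA copies per nuclear genome).
#' @return An object of class `copy_number_estimate`: list with
#'   `per_region_ratio` (named numeric), `ratio` (the maximum),
#'   `nuclear_mean`, `regions_retained` (character), and `rho0_like`
#'   (`TRUE` when no region retains any signal).
#' @export
mtdna_ratio <- function(mt_profile, nuc_profile,
                        regions = mt_quant_regions(),
                        trim = c(0.025, 0.975), retention_floor = 0.5) {
  if (length(regions) == 0) stop("need at least one quantification region")
  if (inherits(regions, "region_spec")) regions <- list(regions)
  nuc_mean <- nuclear_mean_depth(nuc_profile, trim[1], trim[2])
  if (nuc_mean <= 0) stop("trimmed nuclear mean depth is zero")
  per_region <- vapply(regions, function(r)
    region_mean_depth(mt_profile, r) / nuc_mean, numeric(1))
  names(per_region) <- vapply(regions, `[[`, character(1), "region_id")
  retained <- names(per_region)[per_region > retention_floor]
  structure(
    list(per_region_ratio = per_region,
         ratio = max(per_region),
         nuclear_mean = nuc_mean,
         regions_retained = retained,
         rho0_like = length(retained) == 0),
    class = "copy_number_estimate"
  )
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf("mtDNA/nDNA ratio: %.2f (max over %d regions; nuclear mean %.1f)\n",
              x$ratio, length(x$per_region_ratio), x$nuclear_mean))
  for (r in names(x$per_region_ratio))
    cat(sprintf("  %s: %.2f%s\n", r, x$per_region_ratio[[r]],
                if (r %in% x$regions_retained) " [retained]" else ""))
  if (x$rho0_like)
    cat("  no region retained: rho0-like input\n")
  invisible(x)
}

#' Detect retained mtDNA segments from a depth profile
#'
#' Reports maximal runs of positions whose depth reaches
#' `floor_frac * nuclear_mean`, merging runs separated by gaps shorter
#' than `merge_gap` base pairs. This summarises which parts of the
#' mitochondrial reference a deletion-bearing strain still carries.
#'
#' @param mt_profile Mitochondrial [depth_profile()].
#' @param nuclear_mean Trimmed mean nuclear depth
#'   (see [nuclear_mean_depth()]); must be positive.
#' @param floor_frac Depth floor as a fraction of `nuclear_mean`
#'   (default 0.5).
#' @param merge_gap Gaps shorter than this many bp are bridged
#'   (default 100).
#' @return Tibble with columns `start` and `end` (1-based inclusive);
#'   zero rows when nothing is retained.
#' @export
detect_retained_segments <- function(mt_profile, nuclear_mean,
                                     floor_frac = 0.5, merge_gap = 100) {
  stopifnot(inherits(mt_profile, "depth_profile"))
  if (nuclear_mean <= 0) stop("nuclear_mean must be positive")
  above <- mt_profile$depth >= floor_frac * nuclear_mean
  if (!any(above))
    return(tibble::tibble(start = integer(0), end = integer(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ir <- IRanges::IRanges(start = starts[r$values], end = ends[r$values])
  # reduce() merges at gap <= min.gapwidth; we merge gaps strictly
  # shorter than merge_gap
  merged <- IRanges::reduce(ir, min.gapwidth = max(1L, merge_gap - 1L))
  tibble::tibble(start = IRanges::start(merged),
                 end = IRanges::end(merged))
}
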