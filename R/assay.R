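## Suppressivity assay arithmetic and the first-vs-subsequent drift test.

#' Suppressivity from colony counts
#'
#' Suppressivity is the percentage of petite colonies among the diploid
#' progeny of a rho- x rho+ cross.
#'
#' @param petite,grande Non-negative colony counts (vectorised); their sum
#'   must be positive.
#' @return `100 * petite / (petite + grande)`, a percentage.
#' @export
#' @examples
#' suppressivity_from_counts(40, 10)  # 80
suppressivity_from_counts <- function(petite, grande) {
  k <- max(length(petite), length(grande))
  petite <- rep_len(petite, k); grande <- rep_len(grande, k)
  if (any(petite < 0) || any(grande < 0))
    stop("colony counts must be non-negative")
  tot <- petite + grande
  if (any(tot == 0))
    stop("petite + grande must be positive")
  100 * petite / tot
}

#' First-vs-subsequent suppressivity drift
#'
#' Tests whether suppressivity measured immediately after a narrow
#' genetic bottleneck (the first assessment of a freshly isolated rho-
#' strain) differs systematically from later assessments of the same
#' strain. Per strain the paired difference is
#' `mean(subsequent) - first` (or one difference per subsequent
#' assessment with `pairing = "per_assessment"`), and the differences are
#' submitted to a Wilcoxon signed-rank test with continuity correction.
#'
#' @param assessments Data frame with columns `strain_id`,
#'   `assessment_index` (1 = first assessment, larger = subsequent) and
#'   `suppressivity_pct` in `[0, 100]`. Strains lacking either a first or
#'   a subsequent assessment are dropped with a warning.
#' @param pairing `"mean"` (default): average the subsequent assessments
#'   per strain before differencing; `"per_assessment"`: one paired
#'   difference per subsequent assessment.
#' @param exact Passed to [stats::wilcox.test()]; default `NULL` uses an
#'   exact test for small samples without ties, otherwise the normal
#'   approximation with continuity correction.
#' @return List with `diffs` (tibble: `strain_id`, `first`, `subsequent`,
#'   `diff`), `mean_diff`, `sd_diff`, `p_value` (`NA` when fewer than two
#'   non-zero differences exist; 1 when all differences are exactly
#'   zero), `n`.
#' @export
drift_comparison <- function(assessments, pairing = c("mean",
                                                      "per_assessment"),
                             exact = NULL) {
  pairing <- match.arg(pairing)
  assessments <- as.data.frame(assessments)
  req <- c("strain_id", "assessment_index", "suppressivity_pct")
  if (!all(req %in% names(assessments)))
    stop("assessments must have columns strain_id, assessment_index, suppressivity_pct")
  if (nrow(assessments) == 0) stop("empty assessment table")
  if (any(assessments$suppressivity_pct < 0 |
          assessments$suppressivity_pct > 100))
    stop("suppressivity_pct must lie in [0, 100]")

  rows <- lapply(split(assessments, assessments$strain_id), function(d) {
    first <- d$suppressivity_pct[d$assessment_index == 1]
    subs <- d$suppressivity_pct[d$assessment_index > 1]
    if (length(first) != 1 || length(subs) == 0) return(NULL)
    if (pairing == "mean") {
      tibble::tibble(strain_id = d$strain_id[1], first = first,
                     subsequent = mean(subs), diff = mean(subs) - first)
    } else {
      tibble::tibble(strain_id = d$strain_id[1], first = first,
                     subsequent = subs, diff = subs - first)
    }
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warning(sprintf("%d strain(s) without a usable first/subsequent pair dropped",
                    dropped))
  diffs <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(diffs) || nrow(diffs) == 0)
    stop("no strain has both a first and a subsequent assessment")

  d <- diffs$diff
  p_value <- if (all(d == 0)) {
    1
  } else if (sum(d != 0) < 2) {
    NA_real_
  } else {
    suppressWarnings(
      stats::wilcox.test(d, mu = 0, exact = exact, correct = TRUE)$p.value)
  }
  list(diffs = diffs, mean_diff = mean(d), sd_diff = stats::sd(d),
       p_value = p_value, n = nrow(diffs))
}
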