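# TF-pair co-occupancy: proximal-BS percentages, HM-difference ratios,
# intra- vs inter-family testing, and cross-condition BS overlap
# partitioning.

#' Percentage of TF A's BSs proximal to TF B
#'
#' BSs of A that overlap a BS of B (>= 1 bp) are discarded first (shared
#' motif occurrences would trivially co-occur); B's ChIP peaks are extended
#' by `extend` bp on each flank; the result is the percentage of A's BSs
#' (denominator: before discarding) that lie inside an extended peak.
#' Asymmetric in (A, B), and invariant under duplicating a B peak.
#'
#' @param bs_a Site `GRanges` of TF A.
#' @param peaks_b ChIP peak `GRanges` of TF B (the peaks containing B's
#'   BSs).
#' @param bs_b Site `GRanges` of TF B (for the overlap-discard rule).
#' @param extend Flank extension in bp; default 300.
#' @return Percentage in `[0, 100]`.
#' @export
proximal_percentage <- function(bs_a, peaks_b, bs_b, extend = 300L) {
  if (length(bs_a) == 0L) stop("bs_a is empty")
  n0 <- length(bs_a)
  if (length(bs_b) > 0L) {
    keep <- countOverlaps(bs_a, bs_b, ignore.strand = TRUE) == 0L
    bs_a <- bs_a[keep]
  }
  if (length(bs_a) == 0L || length(peaks_b) == 0L) return(0)
  ext <- GRanges(seqnames(peaks_b),
                 IRanges(pmax(1L, start(peaks_b) - extend),
                         end(peaks_b) + extend))
  inside <- countOverlaps(bs_a, ext, type = "within",
                          ignore.strand = TRUE) > 0L
  100 * sum(inside) / n0
}

#' Symmetric HM difference ratio between two TFs, in percent
#'
#' `100 * |a - b| / ((a + b) / 2)` by default: the difference of the two
#' TFs' average H3K4me3 levels around their BSs relative to the pair mean
#' (symmetric and scale-free). Alternative denominators are selectable.
#'
#' @param mean_a,mean_b Average HM level (RPM) over the BS environments of
#'   the two TFs; both must be positive.
#' @param method Denominator: `"symmetric"` (pair mean, default), `"max"`,
#'   or `"first"` (`mean_a`).
#' @return Percent difference ratio.
#' @export
hm_difference_ratio <- function(mean_a, mean_b,
                                method = c("symmetric", "max", "first")) {
  method <- match.arg(method)
  if (mean_a <= 0 || mean_b <= 0) stop("means must be positive")
  den <- switch(method,
                symmetric = (mean_a + mean_b) / 2,
                max = max(mean_a, mean_b),
                first = mean_a)
  100 * abs(mean_a - mean_b) / den
}

#' Co-occupancy of every ordered TF pair
#'
#' @param sites Named list of site `GRanges`, one per TF.
#' @param peaks Named list of peak `GRanges`, one per TF (same names).
#' @param families Named character vector TF -> family.
#' @param h3k4me3 Optional [signal_track()]: when supplied, the pairwise
#'   H3K4me3 difference ratio of the BS environments is added.
#' @param extend Peak flank extension; default 300 bp.
#' @param flank Window half-width for the H3K4me3 averages; default 1000.
#' @return Data frame with one row per ordered pair: `tf_a`, `tf_b`,
#'   `pct_proximal` (A's BSs proximal to B), `same_family`, and
#'   `delta_h3k4me3_pct` when a track was given.
#' @export
cooccupancy_pairs <- function(sites, peaks, families, h3k4me3 = NULL,
                              extend = 300L, flank = 1000L) {
  tfs <- names(sites)
  stopifnot(!is.null(tfs), all(tfs %in% names(peaks)),
            all(tfs %in% names(families)))
  hm_mean <- NULL
  if (!is.null(h3k4me3)) {
    hm_mean <- vapply(tfs, function(tf) {
      mean(average_signal(h3k4me3, sites[[tf]], flank))
    }, numeric(1))
  }
  rows <- list()
  for (a in tfs) for (b in setdiff(tfs, a)) {
    row <- data.frame(
      tf_a = a, tf_b = b,
      pct_proximal = proximal_percentage(sites[[a]], peaks[[b]],
                                         sites[[b]], extend),
      same_family = unname(families[a] == families[b]))
    if (!is.null(hm_mean)) {
      row$delta_h3k4me3_pct <- hm_difference_ratio(hm_mean[[a]], hm_mean[[b]])
    }
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}

#' Test whether intra-family TF pairs co-occupy more than inter-family
#'
#' One-sided Wilcoxon rank-sum test of the proximal-BS percentages,
#' H1: intra-family > inter-family.
#'
#' @param results Data frame from [cooccupancy_pairs()] (needs
#'   `pct_proximal` and `same_family`).
#' @return The p-value.
#' @export
family_cooccupancy_test <- function(results) {
  intra <- results$pct_proximal[results$same_family]
  inter <- results$pct_proximal[!results$same_family]
  if (length(intra) < 2L || length(inter) < 2L) {
    stop("need at least 2 intra- and 2 inter-family pairs")
  }
  suppressWarnings(
    wilcox.test(intra, inter, alternative = "greater")$p.value)
}

#' Partition one TF's BSs between two conditions
#'
#' Sites of `x` sharing >= 1 bp with a site of `y` are "shared"; the rest
#' are condition-x-only, and conversely for `y`. Strand is ignored.
#'
#' @param sites_x,sites_y Site `GRanges` of the same TF in two conditions
#'   (e.g. two cell lines).
#' @return List with `x_only`, `shared`, `y_only` counts and `pct_overlap`
#'   (shared as a percentage of `|x|`).
#' @export
site_overlap_partition <- function(sites_x, sites_y) {
  sx <- countOverlaps(sites_x, sites_y, ignore.strand = TRUE) > 0L
  sy <- countOverlaps(sites_y, sites_x, ignore.strand = TRUE) > 0L
  list(x_only = sum(!sx), shared = sum(sx), y_only = sum(!sy),
       pct_overlap = if (length(sites_x)) 100 * sum(sx) / length(sites_x)
                     else NA_real_)
}
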