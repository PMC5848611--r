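# Per-base meta-profiles around sites, the signed differential-HM statistic
# Delta[-log10(q)] from one-sided Wilcoxon signed-rank tests with Bonferroni
# correction, its label-shuffle null, grouped paired t-tests, and the
# nucleosome-occupancy shift test.

#' Per-base meta-profile around a set of sites
#'
#' Extracts the RPM signal over `[start - flank, end + flank]` for every
#' site, oriented on the motif strand (minus-strand windows are reversed),
#' and returns the per-position mean and standard error. All sites must
#' share one motif length. Sites whose window runs off the chromosome are
#' skipped with a warning.
#'
#' @param track A [signal_track()] (raw tracks are RPM-normalized first) or
#'   list of replicate tracks (averaged after normalization).
#' @param sites Site `GRanges` (>= 2 usable sites; the standard error is
#'   undefined below that).
#' @param flank Window half-width in bp; default 1000.
#' @return A `MetaProfile`: `positions` (bp relative to the motif start,
#'   `-flank ... motif ... +flank`), `mean`, `stderr`, `n_sites`.
#' @export
meta_profile <- function(track, sites, flank = 1000L) {
  if (is.list(track) && !inherits(track, "SignalTrack")) {
    track <- lapply(track, normalize_rpm)
  } else {
    track <- normalize_rpm(track)
  }
  L <- unique(width(sites))
  if (length(L) != 1L) stop("sites must share one motif length")
  get_vals <- function(tr, ch, s, e) tr$values[[ch]][s:e]
  chrs <- as.character(seqnames(sites))
  lens <- vapply(
    unique(chrs),
    function(ch) {
      v <- (if (inherits(track, "SignalTrack")) track else track[[1L]])$values[[ch]]
      if (is.null(v)) stop("track has no chromosome ", ch)
      length(v)
    }, numeric(1))
  s <- start(sites) - flank; e <- end(sites) + flank
  ok <- s >= 1L & e <= lens[chrs]
  if (!all(ok)) {
    warning(sum(!ok), " site(s) skipped: window off chromosome edge")
    sites <- sites[ok]; s <- s[ok]; e <- e[ok]; chrs <- chrs[ok]
  }
  n <- length(sites)
  if (n < 2L) stop("meta_profile needs at least 2 usable sites")
  wlen <- 2L * flank + L
  mat <- matrix(NA_real_, nrow = n, ncol = wlen)
  for (i in seq_len(n)) {
    v <- if (inherits(track, "SignalTrack")) {
      get_vals(track, chrs[i], s[i], e[i])
    } else {
      Reduce(`+`, lapply(track, get_vals, chrs[i], s[i], e[i])) / length(track)
    }
    if (as.character(strand(sites))[i] == "-") v <- rev(v)
    mat[i, ] <- v
  }
  structure(list(positions = seq(-flank, flank + L - 1L),
                 mean = colMeans(mat),
                 stderr = apply(mat, 2L, sd) / sqrt(n),
                 n_sites = n),
            class = "MetaProfile")
}

#' @export
print.MetaProfile <- function(x, ...) {
  cat("MetaProfile over", x$n_sites, "sites,",
      length(x$positions), "positions\n")
  invisible(x)
}

# One-sided Wilcoxon signed-rank p-value for paired samples; exact for
# n <= 25 pairs (after dropping zero differences), normal approximation
# with continuity correction above. Base wilcox.test implements both.
signed_rank_p <- function(x, y, alternative) {
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0L) return(1)
  suppressWarnings(
    wilcox.test(d, alternative = alternative, mu = 0,
                exact = length(d) <= 25L, correct = TRUE)$p.value)
}

#' Signed differential-HM statistic Delta[-log10(q)]
#'
#' For one HM mark, compares the paired per-site window-average levels of
#' the BSs and their matched non-BSs with both one-sided Wilcoxon
#' signed-rank tests. Each one-sided p-value is Bonferroni-corrected by the
#' family size `2 * n_marks_corrected` (two directions for each of the
#' marks tested per TF) and capped at 1, and the statistic is
#' `delta = (-log10 q_greater) - (-log10 q_less)`: positive when HM levels
#' around BSs significantly exceed those around non-BSs, negative in the
#' opposite direction, and exactly antisymmetric under swapping the two
#' inputs.
#'
#' @param bs_values,nonbs_values Equal-length paired vectors of per-site
#'   window-average HM levels (RPM), in matched order (see
#'   [average_signal()] on a [matched_collection()]).
#' @param n_marks_corrected Number of marks in the Bonferroni family;
#'   default 10.
#' @return A `DeltaQResult`: `q_greater`, `q_less` (corrected q-values),
#'   `p_greater`, `p_less` (uncorrected), `delta`.
#' @export
delta_log_q <- function(bs_values, nonbs_values, n_marks_corrected = 10L) {
  if (length(bs_values) != length(nonbs_values)) {
    stop("paired value vectors must have equal length")
  }
  m <- 2L * n_marks_corrected
  if (all(bs_values == nonbs_values)) {
    return(structure(list(q_greater = 1, q_less = 1,
                          p_greater = 1, p_less = 1, delta = 0),
                     class = "DeltaQResult"))
  }
  p_g <- signed_rank_p(bs_values, nonbs_values, "greater")
  p_l <- signed_rank_p(bs_values, nonbs_values, "less")
  q_g <- min(1, m * p_g)
  q_l <- min(1, m * p_l)
  structure(list(q_greater = q_g, q_less = q_l,
                 p_greater = p_g, p_less = p_l,
                 delta = -log10(q_g) + log10(q_l)),
            class = "DeltaQResult")
}

#' @export
print.DeltaQResult <- function(x, ...) {
  cat(sprintf("Delta[-log10(q)] = %.3f  (q_greater = %.3g, q_less = %.3g)\n",
              x$delta, x$q_greater, x$q_less))
  invisible(x)
}

#' Delta[-log10(q)] for every HM mark of a matched collection
#'
#' @param collection A paired [matched_collection()].
#' @param hm_tracks Named list of HM [signal_track()]s (or replicate lists).
#' @param flank Window half-width (bp) for the per-site averages; default
#'   1000.
#' @param n_marks_corrected Bonferroni family size; defaults to the number
#'   of tracks supplied.
#' @return Data frame with one row per mark: `mark`, `delta`, `q_greater`,
#'   `q_less`.
#' @export
delta_log_q_all <- function(collection, hm_tracks, flank = 1000L,
                            n_marks_corrected = length(hm_tracks)) {
  stopifnot(inherits(collection, "MatchedSiteCollection"))
  if (!collection$paired) stop("delta_log_q_all needs a paired collection")
  rows <- lapply(names(hm_tracks), function(m) {
    bs_v <- average_signal(hm_tracks[[m]], collection$bs, flank)
    non_v <- average_signal(hm_tracks[[m]], collection$nonbs, flank)
    r <- delta_log_q(bs_v, non_v, n_marks_corrected)
    data.frame(mark = m, delta = r$delta, q_greater = r$q_greater,
               q_less = r$q_less)
  })
  do.call(rbind, rows)
}

#' Label-shuffle null for |delta|
#'
#' Permutes the BS / non-BS labels within each matched pair (each pair
#' swapped independently with probability 1/2), recomputes the statistic,
#' and returns the null sample of `|delta|`. With no real signal the
#' observed `|delta|` falls inside this null envelope.
#'
#' @inheritParams delta_log_q
#' @param n_shuffles Number of label shuffles; default 100.
#' @param seed Seed; the same seed reproduces the null sample.
#' @return Numeric vector of `n_shuffles` null `|delta|` values.
#' @export
shuffle_control <- function(bs_values, nonbs_values, n_shuffles = 100L,
                            seed = 1L, n_marks_corrected = 10L) {
  stopifnot(n_shuffles >= 1L)
  n <- length(bs_values)
  with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      swap <- runif(n) < 0.5
      b <- ifelse(swap, nonbs_values, bs_values)
      nb <- ifelse(swap, bs_values, nonbs_values)
      abs(delta_log_q(b, nb, n_marks_corrected)$delta)
    }, numeric(1))
  })
}

#' One-sided paired t-test between two conditions
#'
#' Compares a site group's HM levels between two conditions (e.g. cell
#' lines) with the standard paired t statistic.
#'
#' @param values_condition1,values_condition2 Equal-length paired vectors
#'   (n >= 3).
#' @param alternative `"greater"` or `"less"` (for condition1 relative to
#'   condition2).
#' @return The p-value.
#' @export
grouped_paired_ttest <- function(values_condition1, values_condition2,
                                 alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(values_condition1) != length(values_condition2)) {
    stop("paired vectors must have equal length")
  }
  if (length(values_condition1) < 3L) stop("need at least 3 pairs")
  d <- values_condition1 - values_condition2
  if (sd(d) == 0) {
    # a noise-free constant shift has t = +/- Inf; only the all-zero case
    # leaves t undefined
    if (mean(d) == 0) stop("all differences are zero; t undefined")
    up <- mean(d) > 0
    return(if ((up && alternative == "greater") ||
               (!up && alternative == "less")) 0 else 1)
  }
  t.test(values_condition1, values_condition2, paired = TRUE,
         alternative = alternative)$p.value
}

#' Two-sided shift test between per-site occupancy distributions
#'
#' Two-sided Wilcoxon rank-sum (unpaired) test on per-site window-average
#' values, used to ask whether nucleosome occupancy (or accessibility)
#' distributions around BSs and non-BSs are shifted.
#'
#' @param bs_means,nonbs_means Per-site window-average values of the two
#'   groups (need not be equal length).
#' @return The p-value.
#' @export
occupancy_shift_test <- function(bs_means, nonbs_means) {
  if (length(bs_means) == 0L || length(nonbs_means) == 0L) {
    stop("both samples must be nonempty")
  }
  suppressWarnings(
    wilcox.test(bs_means, nonbs_means, alternative = "two.sided")$p.value)
}
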