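# Turns each site into the model's feature vector: one-hot flanking
# sequence, four pentamer-derived DNA shape features per flank position,
# one window-average RPM value per HM mark, and optionally the average
# nucleosome occupancy.

#' One-hot encode a pair of flanking sequences
#'
#' Per-position 4-bit indicators with A = 1000, T = 0100, G = 0010,
#' C = 0001, concatenated 5' flank then 3' flank (both on the motif strand).
#'
#' @param flank5,flank3 Flanking sequences of equal length, motif-strand
#'   orientation.
#' @return Named numeric vector of length `8 * nchar(flank5)`. Errors on
#'   `N` (such sites are excluded upstream).
#' @examples
#' encode_sequence("A", "C")  # 1 0 0 0 0 0 0 1
#' @export
encode_sequence <- function(flank5, flank3) {
  f <- nchar(flank5)
  if (nchar(flank3) != f) stop("flanks must have equal length")
  seq <- paste0(flank5, flank3)
  chars <- strsplit(seq, "")[[1L]]
  onehot_bases <- c("A", "T", "G", "C")  # bit order of the encoding
  if (!all(chars %in% onehot_bases)) stop("flank contains a non-ACGT base")
  pos_label <- c(paste0("m", f:1), paste0("p", 1:f))
  out <- as.numeric(t(outer(chars, onehot_bases, "==")))
  names(out) <- as.vector(t(outer(pos_label, onehot_bases,
                                  function(p, b) paste0("seq.", p, ".", b))))
  out
}

#' Average signal in a site's motif environment, in RPM
#'
#' Mean per-base coverage over the window `[start - flank, end + flank]`
#' (i.e. `2 * flank` + motif length bases), scaled to reads per million by
#' `1e6 / total_signal`. A list of tracks is treated as experimental
#' replicates: each is normalized first, then the RPM values are averaged.
#' Windows extending past a chromosome edge are truncated with a warning.
#'
#' @param track A [signal_track()] or list of replicate tracks.
#' @param sites Site `GRanges`.
#' @param flank Window half-width in bp; default 1000.
#' @return Numeric vector, one RPM value per site.
#' @export
average_signal <- function(track, sites, flank = 1000L) {
  if (is.list(track) && !inherits(track, "SignalTrack")) {
    reps <- lapply(track, average_signal, sites = sites, flank = flank)
    return(Reduce(`+`, reps) / length(reps))
  }
  stopifnot(inherits(track, "SignalTrack"))
  raw_mean <- window_raw_means(track, sites, flank)
  if (track$normalized) return(raw_mean)
  if (track$total_signal <= 0) stop("track has total_signal = 0; cannot normalize")
  raw_mean * 1e6 / track$total_signal
}

#' Build the sites-by-features matrix
#'
#' Rows are the BSs of the collection followed by its non-BSs (labels 1 and
#' 0). Sequence and shape features are computed on the motif strand; shape
#' prediction uses 2 bp of genomic context at each flank end (the innermost
#' core bases serve as context for the innermost flank positions), so each
#' flank position gets 4 sequence bits and 4 shape values:
#' `8 * 2 * flank_len_seq` sequence+shape columns in total (80/160/240 for
#' flanks of 5/10/15 bp). Each HM mark contributes one window-average RPM
#' column, nucleosome occupancy one more. Sites whose flanks contain `N` or
#' fall off the chromosome are dropped -- pairwise in a paired collection,
#' preserving the matching.
#'
#' @param collection A [matched_collection()].
#' @param genome [read_genome()] result.
#' @param tracks List with elements `hm` (named list of [signal_track()]s
#'   or replicate lists, one per mark) and optionally `nucleosome`; either
#'   may be `NULL` to omit those feature categories.
#' @param flank_len_seq Flank length (bp per side) for sequence/shape
#'   features; one of 5, 10, 15. Default 10.
#' @param flank_len_hm Window half-width (bp) for HM and nucleosome
#'   averages, in `[10, 2000]`. Default 1000.
#' @param shape_table Pentamer shape table; default [toy_shape_table()].
#' @return A `FeatureMatrix`: list with `x` (numeric matrix), `label`
#'   (1 = BS, 0 = nonBS), `category` (per-column tag: `seq`, `MGW`, `ProT`,
#'   `Roll`, `HelT`, one tag per HM mark, `nuc`), `site_id`, and the two
#'   flank lengths.
#' @export
build_feature_matrix <- function(collection, genome, tracks = NULL,
                                 flank_len_seq = 10L, flank_len_hm = 1000L,
                                 shape_table = toy_shape_table()) {
  stopifnot(inherits(collection, "MatchedSiteCollection"))
  if (!flank_len_seq %in% c(5L, 10L, 15L)) {
    stop("flank_len_seq must be 5, 10, or 15")
  }
  if (flank_len_hm < 10L || flank_len_hm > 2000L) {
    stop("flank_len_hm must be in [10, 2000]")
  }
  f <- as.integer(flank_len_seq)
  bs <- collection$bs; nonbs <- collection$nonbs
  n_bs <- length(bs); n_non <- length(nonbs)
  sites <- c(granges_strand(bs), granges_strand(nonbs))
  label <- c(rep(1L, n_bs), rep(0L, n_non))

  # flank + context windows, strand-aware so extraction is motif-oriented
  s <- start(sites); e <- end(sites)
  neg <- as.character(strand(sites)) == "-"
  win <- function(plus_s, plus_e, minus_s, minus_e) {
    GRanges(seqnames(sites),
            IRanges(ifelse(neg, minus_s, plus_s),
                    ifelse(neg, minus_e, plus_e)),
            strand = ifelse(neg, "-", "+"))
  }
  f5 <- win(s - f, s - 1L, e + 1L, e + f)
  f3 <- win(e + 1L, e + f, s - f, s - 1L)
  f5c <- win(s - f - 2L, s + 1L, e - 1L, e + f + 2L)
  f3c <- win(e - 1L, e + f + 2L, s - f - 2L, s + 1L)

  chrom_len <- setNames(Biostrings::width(genome), names(genome))
  lo <- pmin(start(f5c), start(f3c)); hi <- pmax(end(f5c), end(f3c))
  inb <- lo >= 1L & hi <= chrom_len[as.character(seqnames(sites))]
  ok <- inb
  ok[inb] <- !grepl("N", paste0(extract_seqs(genome, f5c[inb]),
                                extract_seqs(genome, f3c[inb])), fixed = TRUE)
  keep <- site_filter(ok, n_bs, n_non, collection$paired)
  if (!all(keep)) {
    warning(sum(!keep), " site(s) dropped (N in flanks or chromosome edge)")
    sites <- sites[keep]; label <- label[keep]
    f5 <- f5[keep]; f3 <- f3[keep]; f5c <- f5c[keep]; f3c <- f3c[keep]
  }
  n <- length(sites)
  if (n == 0L) stop("no sites survived feature encoding")

  f5_seq <- extract_seqs(genome, f5); f3_seq <- extract_seqs(genome, f3)
  f5c_seq <- extract_seqs(genome, f5c); f3c_seq <- extract_seqs(genome, f3c)

  seq_block <- t(vapply(seq_len(n),
                        function(i) encode_sequence(f5_seq[i], f3_seq[i]),
                        numeric(8L * f)))
  shape_block <- t(vapply(seq_len(n), function(i) {
    m5 <- predict_shape(f5c_seq[i], shape_table)
    m3 <- predict_shape(f3c_seq[i], shape_table)
    c(rbind(m5, m3))  # columns MGW, ProT, Roll, HelT stacked
  }, numeric(8L * f)))
  pos_label <- c(paste0("m", f:1), paste0("p", 1:f))
  colnames(shape_block) <- as.vector(
    outer(pos_label, SHAPE_FEATURES, function(p, ft) paste0(ft, ".", p)))
  shape_cat <- rep(SHAPE_FEATURES, each = 2L * f)

  x <- cbind(seq_block, shape_block)
  category <- c(rep("seq", ncol(seq_block)), shape_cat)

  if (!is.null(tracks$hm)) {
    hm_block <- vapply(names(tracks$hm), function(m) {
      average_signal(tracks$hm[[m]], sites, flank_len_hm)
    }, numeric(n))
    if (n == 1L) hm_block <- matrix(hm_block, nrow = 1L,
                                    dimnames = list(NULL, names(tracks$hm)))
    x <- cbind(x, hm_block)
    category <- c(category, names(tracks$hm))
  }
  if (!is.null(tracks$nucleosome)) {
    x <- cbind(x, nuc = average_signal(tracks$nucleosome, sites, flank_len_hm))
    category <- c(category, "nuc")
  }
  if (anyNA(x)) stop("feature matrix contains missing values")

  structure(list(x = x, label = label, category = category,
                 site_id = paste0(ifelse(label == 1L, "BS_", "nonBS_"),
                                  seq_len(n)),
                 flank_len_seq = f, flank_len_hm = as.integer(flank_len_hm)),
            class = "FeatureMatrix")
}

granges_strand <- function(gr) {
  out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                 strand = strand(gr))
  out
}

# Pairwise drop logic: in a paired collection a failing site removes its
# partner too, keeping |bs| == |nonbs| and the pairing aligned.
site_filter <- function(ok, n_bs, n_non, paired) {
  if (!paired || n_bs != n_non) return(ok)
  pair_ok <- ok[seq_len(n_bs)] & ok[n_bs + seq_len(n_non)]
  c(pair_ok, pair_ok)
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat("FeatureMatrix:", nrow(x$x), "sites x", ncol(x$x), "features (",
      sum(x$label == 1L), "BS /", sum(x$label == 0L), "non-BS )\n")
  cat("  categories:", paste(unique(x$category), collapse = ", "), "\n")
  invisible(x)
}

# Column selector by category tags.
fm_columns <- function(fm, categories) {
  miss <- setdiff(categories, fm$category)
  if (length(miss)) {
    stop("feature category absent from matrix: ", paste(miss, collapse = ", "))
  }
  fm$category %in% categories
}
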