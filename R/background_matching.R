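# Construction of the non-BS background: exact-motif copies in accessible
# chromatin, at distinct loci, accessibility-matched one-to-one to the BSs.

#' Matched BS / non-BS collection
#'
#' Container pairing each binding site with one accessibility-matched
#' unbound exact copy of its core motif. Row `i` of `bs` is paired with row
#' `i` of `nonbs`; the pairing is the one used by the paired signed-rank
#' statistics downstream.
#'
#' @param bs,nonbs Site `GRanges` of equal length with a `core_seq`
#'   metadata column; `bs[i]` and `nonbs[i]` must have string-equal cores.
#' @param flank Accessibility-window half-width (bp) used for the matching;
#'   kept as metadata. Default 1000.
#' @param paired Logical; `FALSE` after bootstrap resampling breaks the 1:1
#'   pairing.
#' @return A `MatchedSiteCollection`.
#' @export
matched_collection <- function(bs, nonbs, flank = 1000L, paired = TRUE) {
  if (paired) {
    if (length(bs) != length(nonbs)) stop("|bs| != |nonbs| in paired collection")
    if (!all(mcols(bs)$core_seq == mcols(nonbs)$core_seq)) {
      stop("paired sites must have exactly matched core motifs")
    }
  }
  both <- c(granges_clean(bs), granges_clean(nonbs))
  if (length(unique(both)) != length(both)) {
    stop("bs and nonbs intervals must be pairwise distinct")
  }
  mcols(bs)$label <- "BS"
  mcols(nonbs)$label <- "nonBS"
  structure(list(bs = bs, nonbs = nonbs,
                 flank_len_accessibility = as.integer(flank),
                 paired = paired),
            class = "MatchedSiteCollection")
}

granges_clean <- function(gr) {
  GRanges(seqnames(gr), IRanges(start(gr), end(gr)))
}

#' @export
print.MatchedSiteCollection <- function(x, ...) {
  cat("MatchedSiteCollection:", length(x$bs), "BS /", length(x$nonbs),
      "non-BS", if (x$paired) "(paired)" else "(unpaired)", "\n")
  invisible(x)
}

#' Find exact occurrences of a core motif in accessible regions
#'
#' Scans both strands of every accessible region for exact copies of
#' `core_seq`. Occurrences overlapping `exclude` (typically the TF's BSs)
#' are removed, and at most one occurrence is retained per accessible
#' region -- the first in scan order (leftmost position; `+` strand on a
#' palindromic tie).
#'
#' @param core_seq Core motif string (motif-strand orientation).
#' @param accessible `GRanges` of accessible regions.
#' @param genome [read_genome()] result.
#' @param exclude `GRanges` of intervals any occurrence may not overlap.
#' @return `GRanges` of matches (possibly empty) with `core_seq` metadata.
#' @export
find_exact_matches <- function(core_seq, accessible, genome,
                               exclude = GRanges()) {
  res <- find_exact_matches_multi(core_seq, accessible, genome, exclude)
  res[[core_seq]]
}

# Vectorized worker: scans many cores against one accessible-region set,
# building the region DNAStringSet once. Returns a named list
# core_seq -> GRanges of retained matches.
find_exact_matches_multi <- function(cores, accessible, genome,
                                     exclude = GRanges()) {
  cores <- unique(cores)
  empty <- GRanges(core_seq = character(0))
  if (length(accessible) == 0L) {
    return(setNames(rep(list(empty), length(cores)), cores))
  }
  subject <- Biostrings::DNAStringSet(
    extract_seqs(genome, accessible, oriented = FALSE))
  out <- vector("list", length(cores))
  names(out) <- cores
  for (core in cores) {
    w <- nchar(core)
    f_off <- Biostrings::startIndex(Biostrings::vmatchPattern(core, subject))
    r_off <- Biostrings::startIndex(Biostrings::vmatchPattern(revcomp(core),
                                                              subject))
    f_n <- lengths(f_off); r_n <- lengths(r_off)
    regs <- c(rep(seq_along(subject), f_n), rep(seq_along(subject), r_n))
    offs <- c(unlist(f_off), unlist(r_off))
    strands <- rep(c("+", "-"), c(sum(f_n), sum(r_n)))
    if (length(offs) == 0L) {
      out[[core]] <- empty
      next
    }
    gr <- GRanges(as.character(seqnames(accessible))[regs],
                  IRanges(start = start(accessible)[regs] + offs - 1L,
                          width = w),
                  strand = strands)
    if (length(exclude) > 0L) {
      ok <- countOverlaps(gr, exclude, ignore.strand = TRUE) == 0L
      gr <- gr[ok]; regs <- regs[ok]; offs <- offs[ok]; strands <- strands[ok]
    }
    if (length(gr) == 0L) {
      out[[core]] <- empty
      next
    }
    # first in scan order per region ("+" sorts before "-" on a palindromic
    # tie); overlapping accessible regions can surface the same occurrence
    # twice, so deduplicate on the genomic interval afterwards
    ord <- order(regs, offs, strands)
    first <- !duplicated(regs[ord])
    gr <- gr[ord][first]
    gr <- gr[!duplicated(granges_clean(gr))]
    mcols(gr)$core_seq <- core
    out[[core]] <- gr
  }
  out
}

#' Select accessibility-matched non-BSs for a set of BSs
#'
#' Greedy one-per-BS assignment without replacement, in order of BS genomic
#' coordinate: each BS receives the unused exact-match candidate whose mean
#' accessibility over the site `+/- flank` window is closest to the BS's own
#' window mean (ties broken by smallest genomic coordinate). BSs left
#' without a candidate are dropped from both sets, keeping the collection
#' balanced.
#'
#' @param bs Site `GRanges` with `core_seq` metadata (e.g. from
#'   [align_binding_sites()]).
#' @param candidates Named list mapping a core sequence to a `GRanges` of
#'   exact-match candidate loci ([find_exact_matches()]), or a single
#'   `GRanges` with a `core_seq` column.
#' @param accessibility Accessibility [signal_track()] (DNase).
#' @param flank Window half-width in bp; default 1000 (window = motif
#'   `+/- flank`, mirroring the HM window convention).
#' @return A [matched_collection()].
#' @export
select_matched_nonbs <- function(bs, candidates, accessibility,
                                 flank = 1000L) {
  if (inherits(candidates, "GRanges")) {
    candidates <- split_candidates(candidates)
  }
  n_cand <- sum(vapply(candidates, length, numeric(1)))
  if (n_cand == 0L) stop("no exact-match candidates for any BS")
  # flatten candidates to parallel vectors with a used flag
  cand_gr <- unlist(GenomicRanges::GRangesList(lapply(candidates, granges_clean)),
                    use.names = FALSE)
  cand_strand <- unlist(lapply(candidates, function(g) as.character(strand(g))))
  cand_core <- rep(names(candidates), vapply(candidates, length, numeric(1)))
  cand_acc <- window_raw_means(accessibility, cand_gr, flank)
  used <- logical(length(cand_gr))
  # key collapsing entries that point at the same genomic interval (e.g.
  # mutually reverse-complementary cores), so no locus is assigned twice
  cand_key <- paste0(as.character(seqnames(cand_gr)), ":", start(cand_gr),
                     "-", end(cand_gr))

  ord <- order(as.character(seqnames(bs)), start(bs))
  bs_acc <- window_raw_means(accessibility, bs, flank)
  pick <- rep(NA_integer_, length(bs))
  for (i in ord) {
    avail <- which(!used & cand_core == mcols(bs)$core_seq[i])
    if (length(avail) == 0L) next
    d <- abs(cand_acc[avail] - bs_acc[i])
    best <- avail[order(d, start(cand_gr)[avail])][1L]
    pick[i] <- best
    used[cand_key == cand_key[best]] <- TRUE
  }
  keep <- !is.na(pick)
  if (!any(keep)) stop("no BS could be assigned a matched non-BS")
  if (any(!keep)) {
    warning(sum(!keep), " BS(s) dropped: no remaining exact-match candidate")
  }
  bs_kept <- bs[keep]
  sel <- pick[keep]
  nonbs <- GRanges(seqnames(cand_gr)[sel],
                   IRanges(start(cand_gr)[sel], end(cand_gr)[sel]),
                   strand = cand_strand[sel],
                   core_seq = cand_core[sel])
  matched_collection(bs_kept, nonbs, flank = flank)
}

split_candidates <- function(gr) {
  if (is.null(mcols(gr)$core_seq)) stop("candidates need a core_seq column")
  lapply(split(seq_along(gr), mcols(gr)$core_seq), function(ix) gr[ix])
}

#' Bootstrap an imbalanced non-BS set
#'
#' Resamples the non-BS list with replacement to `factor` times the BS count
#' (the BS list is unchanged), producing the imbalanced training variant.
#' The result is no longer 1:1 paired.
#'
#' @param collection A [matched_collection()].
#' @param factor Imbalance factor; default 5.
#' @param seed Integer seed; the same seed reproduces the same resample.
#' @return A `MatchedSiteCollection` with `paired = FALSE`.
#' @export
bootstrap_imbalanced <- function(collection, factor = 5L, seed = 1L) {
  stopifnot(inherits(collection, "MatchedSiteCollection"), factor >= 1L)
  n_bs <- length(collection$bs)
  if (n_bs == 0L || length(collection$nonbs) == 0L) stop("empty collection")
  idx <- with_seed(seed, sample.int(length(collection$nonbs),
                                    factor * n_bs, replace = TRUE))
  out <- collection
  out$nonbs <- collection$nonbs[idx]
  out$paired <- FALSE
  out
}
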