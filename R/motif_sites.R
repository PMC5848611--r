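# PWM construction, best-hit scanning of peak sequences, and the dataset
# filters that decide whether a TF enters the analysis.

#' Build a motif model from a position frequency matrix
#'
#' Converts a 4 x L count matrix (rows A, C, G, T) into a log2-odds position
#' weight matrix with a background-split pseudocount:
#' `pwm[b, j] = log2(((pfm[b, j] + pc * bg[b]) / (colsum[j] + pc)) / bg[b])`.
#'
#' @param pfm 4 x L non-negative matrix; rownames `A,C,G,T` (added if absent).
#' @param background Base frequencies (A, C, G, T); default uniform.
#' @param pseudocount Total pseudocount split by background; default 0.8
#'   (JASPAR convention).
#' @return A `MotifModel` list with elements `pfm`, `pwm`, `background`,
#'   `pseudocount`, `length`, `consensus`.
#' @export
motif_model <- function(pfm, background = rep(0.25, 4), pseudocount = 0.8) {
  pfm <- as.matrix(pfm)
  if (nrow(pfm) != 4L) stop("PFM must have 4 rows (A, C, G, T)")
  if (any(pfm < 0)) stop("PFM counts must be non-negative")
  rownames(pfm) <- DNA_BASES
  if (length(background) != 4L || any(background <= 0)) {
    stop("background must be 4 positive frequencies")
  }
  background <- background / sum(background)
  colsums <- colSums(pfm)
  if (any(colsums <= 0)) stop("PFM has an empty column")
  prob <- sweep(pfm + pseudocount * background, 2L, colsums + pseudocount, "/")
  pwm <- log2(prob / background)
  consensus <- paste0(DNA_BASES[apply(pwm, 2L, which.max)], collapse = "")
  structure(list(pfm = pfm, pwm = pwm, background = background,
                 pseudocount = pseudocount, length = ncol(pfm),
                 consensus = consensus),
            class = "MotifModel")
}

#' @export
print.MotifModel <- function(x, ...) {
  cat("MotifModel: length", x$length, "consensus", x$consensus, "\n")
  invisible(x)
}

#' Read a JASPAR-style PFM text file
#'
#' Accepts the common JASPAR layouts: an optional `>` header line, then four
#' rows of counts, optionally prefixed by the base letter and wrapped in
#' brackets, e.g. `A [ 10  2  0 ]`.
#'
#' @param path Path to the PFM text file.
#' @inheritParams motif_model
#' @return A [motif_model()].
#' @export
read_jaspar_pfm <- function(path, background = rep(0.25, 4), pseudocount = 0.8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^>", lines)]
  if (length(lines) != 4L) stop("expected 4 count rows in ", path)
  rows <- lapply(lines, function(ln) {
    ln <- gsub("^[ \t]*[ACGTacgt][ \t]*", "", ln)
    ln <- gsub("[][]", " ", ln)
    as.numeric(strsplit(trimws(ln), "[ \t]+")[[1L]])
  })
  if (length(unique(lengths(rows))) != 1L) {
    stop("PFM rows have unequal lengths in ", path)
  }
  motif_model(do.call(rbind, rows), background = background,
              pseudocount = pseudocount)
}

#' Default log-odds score threshold for motif hits
#'
#' With a uniform background, a hit's log2-odds score exceeds
#' `log2(p) + 2 * L` exactly when its probability under the motif model
#' exceeds `p`; the default `p = 1e-4` mirrors the usual motif-scanner match
#' threshold.
#'
#' @param motif A [motif_model()].
#' @param p Per-site match probability cutoff.
#' @return Scalar score threshold.
#' @export
default_score_threshold <- function(motif, p = 1e-4) {
  log2(p) + 2 * motif$length
}

# Integer-code a DNA string: A=1, C=2, G=3, T=4, anything else NA.
seq_codes <- function(seq) {
  code <- rep(NA_integer_, 256L)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  code[utf8ToInt(seq)]
}

# Log-odds scores of the motif at every offset of a coded sequence (one
# strand). NA where any base in the window is N.
scan_scores <- function(codes, pwm) {
  L <- ncol(pwm)
  n <- length(codes) - L + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(L)) {
    sc <- sc + pwm[cbind(codes[j:(j + n - 1L)], j)]
  }
  sc
}

#' Best motif hit in a sequence over both strands
#'
#' Scans all offsets on both strands and returns the maximum log-odds hit;
#' under a fixed background the maximal score is the minimal match p-value,
#' so the best-scoring hit stands in for the "lowest p-value" rule used when
#' a motif occurs more than once in a peak. Ties are broken by lowest offset,
#' then by the `+` strand.
#'
#' @param seq DNA string (uppercase ACGTN).
#' @param motif A [motif_model()].
#' @return `NULL` when the sequence is shorter than the motif or no window is
#'   free of `N`; otherwise a list with `offset` (1-based start of the hit in
#'   `seq`), `strand` (`+`/`-`), and `score`.
#' @export
scan_best_site <- function(seq, motif) {
  L <- motif$length
  if (nchar(seq) < L) return(NULL)
  fwd <- scan_scores(seq_codes(seq), motif$pwm)
  rev <- scan_scores(seq_codes(revcomp(seq)), motif$pwm)
  # a reverse-strand hit at reverse-offset k covers forward positions
  # (n - L + 2 - k) .. ; map back to forward offsets
  n_off <- length(fwd)
  rev_fwd <- rev[n_off:1]  # reverse hit aligned to forward offset
  if (all(is.na(fwd)) && all(is.na(rev_fwd))) return(NULL)
  best_f <- suppressWarnings(max(fwd, na.rm = TRUE))
  best_r <- suppressWarnings(max(rev_fwd, na.rm = TRUE))
  m <- max(best_f, best_r)
  off_f <- if (is.finite(best_f) && best_f == m) which(fwd == m)[1L] else Inf
  off_r <- if (is.finite(best_r) && best_r == m) which(rev_fwd == m)[1L] else Inf
  if (off_f <= off_r) {
    list(offset = off_f, strand = "+", score = m)
  } else {
    list(offset = off_r, strand = "-", score = m)
  }
}

#' Align ChIP-seq peaks against a motif to define binding sites
#'
#' Takes the single best motif hit per peak (both strands), keeps hits at or
#' above `score_threshold`, and then applies the study's dataset filters:
#' the TF is rejected when fewer than `min_sites` sites survive (so the
#' sample size cannot drop below the model's feature count) or when the mode
#' of the motif-center offsets from the peak centers lies outside
#' `summit_tol` (motif distribution must coincide with the peak summit).
#' Sites whose core contains `N` are dropped.
#'
#' @param peaks `GRanges` of ChIP-seq peaks.
#' @param genome [read_genome()] result.
#' @param motif A [motif_model()].
#' @param min_sites Minimum number of aligned BSs; default 132.
#' @param score_threshold Log-odds cutoff; default
#'   [default_score_threshold()].
#' @param summit_tol Tolerance (bp) for the mode of motif-center minus
#'   peak-center offsets; default 25.
#' @return A `GRanges` of sites (core motif span; metadata `core_seq` on the
#'   motif strand, `score`, `peak` index, `label = "BS"`), or an
#'   [is_rejected()] object with the reason.
#' @export
align_binding_sites <- function(peaks, genome, motif, min_sites = 132L,
                                score_threshold = NULL, summit_tol = 25L) {
  if (length(peaks) == 0L) return(new_rejection("no peaks"))
  score_threshold <- score_threshold %||% default_score_threshold(motif)
  seqs <- extract_seqs(genome, peaks, oriented = FALSE)
  L <- motif$length
  hit_list <- lapply(seqs, scan_best_site, motif = motif)
  keep <- !vapply(hit_list, is.null, logical(1))
  scores <- vapply(hit_list[keep], `[[`, numeric(1), "score")
  pass <- scores >= score_threshold
  idx <- which(keep)[pass]
  if (length(idx) == 0L) {
    return(new_rejection("no peaks with a motif hit above the score threshold"))
  }
  offs <- vapply(hit_list[idx], `[[`, numeric(1), "offset")
  strands <- vapply(hit_list[idx], `[[`, character(1), "strand")
  starts <- start(peaks)[idx] + offs - 1L
  gr <- GRanges(seqnames = seqnames(peaks)[idx],
                ranges = IRanges(start = starts, width = L),
                strand = strands)
  core <- extract_seqs(genome, gr, oriented = TRUE)
  ok <- !grepl("N", core, fixed = TRUE)
  if (!all(ok)) {
    warning(sum(!ok), " site(s) dropped for N in core motif")
    gr <- gr[ok]; idx <- idx[ok]; core <- core[ok]
  }
  if (length(gr) < min_sites) {
    return(new_rejection(sprintf("fewer than %d aligned BSs (%d)",
                                 min_sites, length(gr))))
  }
  motif_center <- (start(gr) + end(gr)) / 2
  peak_center <- (start(peaks)[idx] + end(peaks)[idx]) / 2
  d <- round(motif_center - peak_center)
  mode_off <- as.integer(names(sort(table(d), decreasing = TRUE))[1L])
  if (abs(mode_off) > summit_tol) {
    return(new_rejection(sprintf(
      "motif distribution peak (offset %d bp) does not coincide with the peak summit",
      mode_off)))
  }
  mcols(gr)$core_seq <- core
  mcols(gr)$score <- vapply(hit_list[idx], `[[`, numeric(1), "score")
  mcols(gr)$peak <- idx
  mcols(gr)$label <- "BS"
  gr
}
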