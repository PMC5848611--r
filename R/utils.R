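# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All seeded operations in the package go
# through this so that a user's session RNG is never disturbed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Dataset-level rejection object (e.g. fewer than `min_sites` aligned BSs).
new_rejection <- function(reason) {
  structure(list(reason = reason), class = "hmtf_rejection")
}

#' Test whether a pipeline stage rejected its dataset
#'
#' Stage functions such as [align_binding_sites()] return a rejection object
#' (rather than throwing) when a dataset fails the study's inclusion filters,
#' so that a multi-TF pipeline can continue with the remaining TFs.
#'
#' @param x Any object.
#' @return `TRUE` if `x` is a dataset rejection.
#' @export
is_rejected <- function(x) inherits(x, "hmtf_rejection")

#' @export
print.hmtf_rejection <- function(x, ...) {
  cat("<dataset rejected> ", x$reason, "\n", sep = "")
  invisible(x)
}

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Extract (possibly strand-oriented) sequences for a GRanges from a
# DNAStringSet genome. Returns a character vector; minus-strand ranges are
# reverse-complemented when oriented = TRUE.
extract_seqs <- function(genome, gr, oriented = TRUE) {
  out <- character(length(gr))
  chrs <- as.character(seqnames(gr))
  for (ch in unique(chrs)) {
    if (!ch %in% names(genome)) stop("unknown chromosome: ", ch)
    idx <- which(chrs == ch)
    chrom_str <- as.character(genome[[ch]])
    s <- start(gr)[idx]; e <- end(gr)[idx]
    if (any(s < 1L) || any(e > nchar(chrom_str))) {
      stop("interval out of bounds on ", ch)
    }
    out[idx] <- substring(chrom_str, s, e)
  }
  if (oriented) {
    neg <- as.character(strand(gr)) == "-"
    if (any(neg)) out[neg] <- revcomp(out[neg])
  }
  out
}

stopifnot_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number")
  }
}
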