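# Pentamer -> DNA shape lookup tables. A sliding pentamer table maps every
# 5-mer to the predicted minor groove width (MGW, Angstrom), propeller twist
# (ProT, degrees), roll and helix twist (Roll/HelT, degrees) at/around its
# center position.

SHAPE_FEATURES <- c("MGW", "ProT", "Roll", "HelT")

all_pentamers <- function() {
  g <- expand.grid(p5 = DNA_BASES, p4 = DNA_BASES, p3 = DNA_BASES,
                   p2 = DNA_BASES, p1 = DNA_BASES,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3, g$p4, g$p5)
}

#' Synthetic pentamer shape table
#'
#' A deterministic, in-code stand-in for a query table of pentamer DNA shape
#' values, for testing and synthetic studies. Values are smooth trigonometric
#' functions of the pentamer's base identities, mapped into physically
#' plausible ranges, and obey the strand symmetry a real table has: MGW,
#' ProT, and HelT are identical for a pentamer and its reverse complement,
#' while Roll is antisymmetric (sign flips under reverse complement). The
#' values themselves are synthetic -- they carry no experimental content; a
#' real table can be supplied via [read_shape_table()].
#'
#' @return 1024 x 4 numeric matrix, rownames = pentamers, columns
#'   `MGW`, `ProT`, `Roll`, `HelT`.
#' @export
toy_shape_table <- function() {
  pents <- all_pentamers()
  digit <- function(p, i) match(substring(p, i, i), DNA_BASES)
  D <- vapply(1:5, function(i) digit(pents, i), numeric(length(pents)))
  raw_for <- function(k) {
    # deterministic per-feature coefficients, no RNG involved
    co <- outer(1:5, 1:4, function(i, b) sin(7 * i + 13 * b + 29 * k))
    rowSums(vapply(1:5, function(i) co[cbind(i, D[, i])],
                   numeric(length(pents))))
  }
  rc <- revcomp(pents)
  rc_idx <- match(rc, pents)
  sym <- function(x) (x + x[rc_idx]) / 2
  anti <- function(x) (x - x[rc_idx]) / 2
  m <- cbind(
    MGW = 5.0 + 0.65 * sym(raw_for(1)) / 2,
    ProT = -8.0 + 3.5 * sym(raw_for(2)) / 2,
    Roll = 4.0 * anti(raw_for(3)) / 2,
    HelT = 34.5 + 1.6 * sym(raw_for(4)) / 2
  )
  rownames(m) <- pents
  m
}

#' Read a pentamer shape table from TSV
#'
#' Expects columns `pentamer`, `MGW`, `ProT`, `Roll`, `HelT` (with header).
#' Missing pentamers are completed from their reverse complement (MGW, ProT,
#' HelT copied; Roll negated); pentamers missing in both orientations are an
#' error.
#'
#' @param path Path to the TSV file.
#' @return 1024 x 4 numeric matrix as in [toy_shape_table()].
#' @export
read_shape_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("pentamer", SHAPE_FEATURES)
  if (!all(need %in% names(df))) {
    stop("shape table must have columns: ", paste(need, collapse = ", "))
  }
  pents <- all_pentamers()
  m <- matrix(NA_real_, nrow = length(pents), ncol = 4L,
              dimnames = list(pents, SHAPE_FEATURES))
  m[df$pentamer, ] <- as.matrix(df[, SHAPE_FEATURES])
  missing <- which(is.na(m[, 1L]))
  if (length(missing)) {
    rc <- revcomp(pents[missing])
    src <- m[rc, , drop = FALSE]
    if (anyNA(src[, 1L])) {
      stop("pentamer(s) absent in both orientations, e.g. ",
           pents[missing[which(is.na(src[, 1L]))[1L]]])
    }
    src[, "Roll"] <- -src[, "Roll"]
    m[missing, ] <- src
  }
  m
}

#' Predict DNA shape along a sequence by sliding pentamer lookup
#'
#' The input must include 2 bp of genomic context at each end, so that every
#' payload position is the center of some pentamer: an input of length `n`
#' yields `n - 4` values per shape feature, value `i` describing payload
#' position `i`. All four features (MGW, ProT, Roll, HelT) are emitted per
#' position, the step parameters being attributed to the centered pentamer's
#' position.
#'
#' @param seq DNA string over ACGT, `nchar(seq) >= 5`.
#' @param table Shape table ([toy_shape_table()] or [read_shape_table()]).
#' @return `(nchar(seq) - 4) x 4` numeric matrix, columns `MGW`, `ProT`,
#'   `Roll`, `HelT`. Errors on a pentamer absent from the table (e.g.
#'   containing `N`).
#' @export
predict_shape <- function(seq, table = toy_shape_table()) {
  n <- nchar(seq)
  if (n < 5L) stop("sequence must be at least 5 bp (2 bp context each side)")
  starts <- seq_len(n - 4L)
  pents <- substring(seq, starts, starts + 4L)
  idx <- match(pents, rownames(table))
  if (anyNA(idx)) {
    stop("pentamer not in shape table: ", pents[which(is.na(idx))[1L]])
  }
  out <- table[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
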