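# Readers/writers for the plain-text genomics formats the pipeline touches,
# and the SignalTrack container for per-base coverage.

#' Read a genome from FASTA
#'
#' Sequences are uppercased and any IUPAC ambiguity code is masked to `N`, so
#' downstream code only ever sees the alphabet `{A,C,G,T,N}`.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome (text after the
#'   first whitespace in each header is dropped).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acRt"), fa)
#' as.character(read_genome(fa))  # "ACNT"
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) == 0L) stop("empty FASTA: ", path)
  names(dss) <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(names(dss))) {
    stop("duplicate chromosome names in ", path)
  }
  dss <- Biostrings::DNAStringSet(toupper(as.character(dss)))
  Biostrings::replaceAmbiguities(dss, new = "N")
}

#' Write a genome to FASTA
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Read genomic intervals from BED
#'
#' Accepts BED3 through BED6. BED's 0-based half-open coordinates are
#' converted to the 1-based closed convention of [GenomicRanges::GRanges].
#' Strand defaults to `+` when absent or `.`. Records with `start >= end`
#' violate the interval invariant and are dropped with a warning.
#'
#' @param path Path to a BED file.
#' @return A `GRanges`; columns 4 and 5, when present, populate the `name`
#'   and `score` metadata columns.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  empty <- GRanges()
  if (file.size(path) == 0L) return(empty)
  df <- read.table(path, sep = "\t", header = FALSE, quote = "",
                   comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED requires at least 3 columns: ", path)
  starts <- as.numeric(df[[2L]]); ends <- as.numeric(df[[3L]])
  bad <- !is.finite(starts) | !is.finite(ends) | starts < 0 | starts >= ends
  if (any(bad)) {
    warning(sum(bad), " BED record(s) rejected (start >= end or malformed) in ",
            path)
    df <- df[!bad, , drop = FALSE]
    starts <- starts[!bad]; ends <- ends[!bad]
  }
  if (nrow(df) == 0L) return(empty)
  strand <- if (ncol(df) >= 6L) {
    s <- as.character(df[[6L]])
    s[!s %in% c("+", "-")] <- "+"
    s
  } else "+"
  gr <- GRanges(seqnames = as.character(df[[1L]]),
                ranges = IRanges(start = starts + 1L, end = ends),
                strand = strand)
  if (ncol(df) >= 4L) mcols(gr)$name <- as.character(df[[4L]])
  if (ncol(df) >= 5L) mcols(gr)$score <- suppressWarnings(as.numeric(df[[5L]]))
  gr
}

#' Write genomic intervals to BED6
#'
#' @param gr A `GRanges`; `name` and `score` metadata columns are used when
#'   present.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  n <- length(gr)
  name <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else rep(".", n)
  score <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else rep(0, n)
  strand <- as.character(strand(gr))
  strand[strand == "*"] <- "+"
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = format(start(gr) - 1L, scientific = FALSE, trim = TRUE),
                   end = format(end(gr), scientific = FALSE, trim = TRUE),
                   name = name, score = score, strand = strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# SignalTrack

#' Construct a per-base signal track
#'
#' A SignalTrack holds one non-negative numeric vector per chromosome (one
#' value per base) together with the genome-wide raw total used for
#' reads-per-million (RPM) normalization.
#'
#' @param values Named list of non-negative numeric vectors, one per
#'   chromosome, each as long as the chromosome.
#' @param normalized Logical; `TRUE` once values are on the RPM scale.
#' @param total_signal Genome-wide sum of raw per-base coverage. Defaults to
#'   the sum of `values` (only correct when `normalized = FALSE`).
#' @return An object of class `SignalTrack`.
#' @export
signal_track <- function(values, normalized = FALSE, total_signal = NULL) {
  stopifnot(is.list(values), !is.null(names(values)))
  for (ch in names(values)) {
    v <- values[[ch]]
    if (!is.numeric(v)) stop("track values must be numeric (", ch, ")")
    if (any(v < 0)) stop("negative coverage on ", ch)
  }
  total <- total_signal %||% sum(vapply(values, sum, numeric(1)))
  structure(list(values = values, total_signal = total,
                 normalized = normalized),
            class = "SignalTrack")
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat("SignalTrack:", length(x$values), "chromosome(s),",
      "total_signal =", format(x$total_signal),
      if (x$normalized) "(RPM)" else "(raw)", "\n")
  invisible(x)
}

#' Scale a raw track to reads per million
#'
#' @param track A [signal_track()].
#' @return The track with values multiplied by `1e6 / total_signal` and
#'   `normalized = TRUE`. Errors if `total_signal` is 0.
#' @export
normalize_rpm <- function(track) {
  stopifnot(inherits(track, "SignalTrack"))
  if (track$normalized) return(track)
  if (track$total_signal <= 0) stop("cannot RPM-normalize a track with total_signal = 0")
  f <- 1e6 / track$total_signal
  track$values <- lapply(track$values, function(v) v * f)
  track$normalized <- TRUE
  track
}

#' Read a per-base signal track
#'
#' Understands bedGraph (4 columns, 0-based half-open), fixed-step wiggle
#' (1-based; converted on read), and — when the `rtracklayer` package is
#' installed — bigWig (`.bw`/`.bigWig` extension). Bases not covered by any
#' record are 0. Overlapping bedGraph records are summed with a warning
#' (coverage semantics).
#'
#' @param path Path to the track file.
#' @param genome Genome as returned by [read_genome()]; provides chromosome
#'   lengths and the set of legal chromosome names.
#' @return A raw (`normalized = FALSE`) [signal_track()].
#' @export
read_signal_track <- function(path, genome) {
  if (!file.exists(path)) stop("no such file: ", path)
  lens <- setNames(Biostrings::width(genome), names(genome))
  values <- lapply(lens, numeric)
  add <- function(ch, from1, to1, val) {
    # 1-based closed coordinates
    if (!ch %in% names(values)) stop("unknown chromosome in track: ", ch)
    if (from1 < 1L || to1 > lens[[ch]]) stop("track record out of bounds on ", ch)
    values[[ch]][from1:to1] <<- values[[ch]][from1:to1] + val
  }
  if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("bigWig input requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path)
    for (i in seq_along(gr)) {
      add(as.character(seqnames(gr))[i], start(gr)[i], end(gr)[i],
          mcols(gr)$score[i])
    }
    return(signal_track(values))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|#)", lines)]
  if (length(lines) == 0L) return(signal_track(values))
  overlapped <- FALSE
  if (any(grepl("^fixedStep", lines))) {
    ch <- NULL; pos <- NA_integer_; step <- 1L; span <- 1L
    for (ln in lines) {
      if (grepl("^fixedStep", ln)) {
        get_field <- function(key, default = NULL) {
          m <- regmatches(ln, regexpr(paste0(key, "=[^ \t]+"), ln))
          if (length(m) == 0L) return(default)
          sub(paste0(key, "="), "", m)
        }
        ch <- get_field("chrom")
        if (is.null(ch)) stop("fixedStep header without chrom= in ", path)
        pos <- as.integer(get_field("start"))  # wiggle is 1-based
        step <- as.integer(get_field("step", "1"))
        span <- as.integer(get_field("span", "1"))
      } else {
        v <- as.numeric(ln)
        add(ch, pos, pos + span - 1L, v)
        pos <- pos + step
      }
    }
  } else {
    con <- textConnection(lines)
    df <- read.table(con, sep = "", header = FALSE, stringsAsFactors = FALSE)
    close(con)
    if (ncol(df) < 4L) stop("bedGraph requires 4 columns: ", path)
    covered <- lapply(lens, numeric)
    for (i in seq_len(nrow(df))) {
      ch <- as.character(df[[1L]][i])
      from1 <- as.integer(df[[2L]][i]) + 1L  # bedGraph is 0-based half-open
      to1 <- as.integer(df[[3L]][i])
      add(ch, from1, to1, as.numeric(df[[4L]][i]))
      if (!overlapped && ch %in% names(covered)) {
        cv <- covered[[ch]]
        if (any(cv[from1:to1] > 0)) overlapped <- TRUE
        cv[from1:to1] <- cv[from1:to1] + 1
        covered[[ch]] <- cv
      }
    }
    if (overlapped) {
      warning("overlapping bedGraph records summed (coverage semantics) in ",
              path)
    }
  }
  signal_track(values)
}

#' Write a signal track as bedGraph
#'
#' Runs of equal value are merged; zero runs are omitted. Output coordinates
#' are 0-based half-open as the format requires.
#'
#' @param track A [signal_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "SignalTrack"))
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$values)) {
    r <- rle(track$values[[ch]])
    ends <- cumsum(r$lengths)
    starts0 <- ends - r$lengths  # 0-based starts
    keep <- r$values != 0
    if (!any(keep)) next
    df <- data.frame(ch, format(starts0[keep], scientific = FALSE, trim = TRUE),
                     format(ends[keep], scientific = FALSE, trim = TRUE),
                     format(r$values[keep], scientific = FALSE, trim = TRUE))
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

# Mean of per-base values over [center windows] defined by sites +/- flank,
# computed with cumulative sums; windows are truncated at chromosome edges
# with a warning. Returns raw means (no RPM scaling).
window_raw_means <- function(track, gr, flank) {
  chrs <- as.character(seqnames(gr))
  out <- numeric(length(gr))
  truncated <- FALSE
  for (ch in unique(chrs)) {
    v <- track$values[[ch]]
    if (is.null(v)) stop("track has no chromosome ", ch)
    cs <- c(0, cumsum(v))
    idx <- which(chrs == ch)
    s <- start(gr)[idx] - flank
    e <- end(gr)[idx] + flank
    if (any(s < 1L) || any(e > length(v))) truncated <- TRUE
    s <- pmax(s, 1L); e <- pmin(e, length(v))
    out[idx] <- (cs[e + 1L] - cs[s]) / (e - s + 1L)
  }
  if (truncated) warning("window(s) truncated at chromosome edge")
  out
}
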