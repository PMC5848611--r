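# Seeded synthetic-study generator. Emulates the data structure the analysis
# assumes -- a genome with implanted motif instances, ChIP peaks around true
# BSs, unbound exact-motif decoys in accessible chromatin, accessibility
# tracks matched between the classes, HM tracks with per-mark BS enrichment,
# and a nucleosome track optionally depleted at BSs -- and records ground
# truth for parameter-recovery tests.

#' Specification of one synthetic TF
#'
#' @param name TF identifier.
#' @param family Protein-family label; TFs sharing a family share their HM
#'   effect vector (up to jitter) and, in family panels, part of their BS
#'   placement.
#' @param pfm 4 x L count matrix (rows A, C, G, T) the BS cores are sampled
#'   from; default [default_pfm()].
#' @param n_bs Number of true binding sites implanted (each wrapped in a
#'   ChIP peak). The study's inclusion filter requires at least 132.
#' @param n_decoys Number of unbound exact copies of BS core sequences
#'   implanted at distinct accessible loci (no peak). When
#'   `n_decoys >= n_bs`, every BS is guaranteed at least one exact-copy
#'   decoy.
#' @param hm_effect Numeric vector, one value per HM mark (log2 units):
#'   the HM bump at a BS is scaled by `2^hm_effect[m]` relative to the
#'   unscaled bump at a decoy. 0 = no differential signal.
#' @param hm_bump_halfwidth Standard deviation (bp) of the Gaussian bump
#'   added to signal tracks at each site; default 150.
#' @param noise_sd SD of the lognormal site-to-site bump-amplitude jitter;
#'   default 0.3.
#' @param flank_bias In `[0, 1]`: strength of a GC-rich composition bias
#'   written into the 15 bp flanks of true BSs (decoy flanks stay at genome
#'   background), so that flanking sequence/shape can carry class signal.
#'   0 (default) = flanks are background for both classes.
#' @return A `SyntheticTFSpec` list.
#' @export
synth_tf <- function(name, family = "famA", pfm = default_pfm(),
                     n_bs = 200L, n_decoys = max(250L, n_bs),
                     hm_effect = rep(0, length(HM_MARKS)),
                     hm_bump_halfwidth = 150L, noise_sd = 0.3,
                     flank_bias = 0) {
  stopifnot(n_bs >= 1L, n_decoys >= 1L,
            flank_bias >= 0, flank_bias <= 1)
  structure(list(name = name, family = family, pfm = as.matrix(pfm),
                 n_bs = as.integer(n_bs), n_decoys = as.integer(n_decoys),
                 hm_effect = hm_effect,
                 hm_bump_halfwidth = as.integer(hm_bump_halfwidth),
                 noise_sd = noise_sd, flank_bias = flank_bias),
            class = "SyntheticTFSpec")
}

#' A default 10-bp position frequency matrix
#'
#' Information-rich (dominant base count 60 of 63 per position), so sampled
#' cores are strong motif instances -- mostly consensus with occasional
#' single mismatches -- yet not all identical. At this sharpness the
#' implanted instance is, with rare chance exceptions, the best PWM hit in
#' its peak and scores above the default scan threshold.
#'
#' @return 4 x 10 count matrix.
#' @export
default_pfm <- function() {
  cons <- c("G", "A", "T", "T", "A", "C", "A", "G", "T", "C")
  pfm <- matrix(1, nrow = 4, ncol = length(cons),
                dimnames = list(DNA_BASES, NULL))
  for (j in seq_along(cons)) pfm[cons[j], j] <- 60
  pfm
}

#' Configuration of a synthetic study
#'
#' @param tfs List of [synth_tf()] specs.
#' @param genome_length Genome size in bp; must leave each implanted site a
#'   slot at least `2 * accessible_flank + 100` bp wide.
#' @param gc_fraction Genome GC content; default 0.41 (human-like).
#' @param seed Integer; together with the config it fully determines every
#'   output.
#' @param hm_marks Names of the HM tracks; default the study's 10 marks
#'   ([hm_marks()]).
#' @param accessibility_background Mean of the exponential per-base
#'   background noise in every track; default 1.
#' @param nucleosome_depletion_at_bs Depletion of the nucleosome-occupancy
#'   bump at BSs, log2 units (bump scaled by `2^-depletion`); default 1.
#' @param peak_width Width (bp) of the ChIP peak written around each BS
#'   (summit = motif center by construction); default 200.
#' @param bump_amplitude Peak height of the per-site Gaussian signal bump,
#'   in background units; default 10.
#' @param accessible_flank Half-width (bp) of the accessible region emitted
#'   around every site, and of the windows used for accessibility matching;
#'   default 1000.
#' @param sharing_fraction Fraction of each TF's BSs placed within 300 bp of
#'   a previously placed BS of a same-family partner (co-occupancy
#'   structure); default 0.
#' @param family_jitter SD of per-TF noise added to the family-shared
#'   `hm_effect` (0 = identical within family); default 0.
#' @return A `SyntheticStudyConfig` list.
#' @export
synth_config <- function(tfs, genome_length = 1e6, gc_fraction = 0.41,
                         seed = 1L, hm_marks = HM_MARKS,
                         accessibility_background = 1,
                         nucleosome_depletion_at_bs = 1,
                         peak_width = 200L, bump_amplitude = 10,
                         accessible_flank = 1000L,
                         sharing_fraction = 0, family_jitter = 0) {
  if (inherits(tfs, "SyntheticTFSpec")) tfs <- list(tfs)
  stopifnot(length(tfs) >= 1L, gc_fraction >= 0, gc_fraction <= 1)
  for (tf in tfs) {
    if (length(tf$hm_effect) != length(hm_marks)) {
      stop("hm_effect of ", tf$name, " must have one value per HM mark")
    }
  }
  names(tfs) <- vapply(tfs, `[[`, character(1), "name")
  structure(list(tfs = tfs, genome_length = as.numeric(genome_length),
                 gc_fraction = gc_fraction, seed = as.integer(seed),
                 hm_marks = hm_marks,
                 accessibility_background = accessibility_background,
                 nucleosome_depletion_at_bs = nucleosome_depletion_at_bs,
                 peak_width = as.integer(peak_width),
                 bump_amplitude = bump_amplitude,
                 accessible_flank = as.integer(accessible_flank),
                 sharing_fraction = sharing_fraction,
                 family_jitter = family_jitter),
            class = "SyntheticStudyConfig")
}

#' Generate an i.i.d. random genome
#'
#' @param length Genome length in bp.
#' @param gc GC fraction: `P(G) = P(C) = gc / 2`.
#' @param seed Integer seed; the same `(length, gc, seed)` always yields the
#'   same sequence.
#' @return A single-chromosome (`chr1`) [Biostrings::DNAStringSet].
#' @export
generate_genome <- function(length, gc = 0.41, seed = 1L) {
  stopifnot(length > 0)
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  with_seed(seed, {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    chars <- sample(DNA_BASES, length, replace = TRUE, prob = p)
    dss <- Biostrings::DNAStringSet(paste0(chars, collapse = ""))
    names(dss) <- "chr1"
    dss
  })
}

# Sample n core sequences (character) from a PFM, one base per column.
sample_cores <- function(pfm, n) {
  L <- ncol(pfm)
  probs <- sweep(pfm, 2L, colSums(pfm), "/")
  mat <- matrix("", nrow = n, ncol = L)
  for (j in seq_len(L)) {
    mat[, j] <- sample(DNA_BASES, n, replace = TRUE, prob = probs[, j])
  }
  apply(mat, 1L, paste0, collapse = "")
}

#' Generate a complete synthetic study
#'
#' Implants, for each TF in the config: `n_bs` motif instances at random
#' non-overlapping loci (each wrapped in a fixed-width ChIP peak whose summit
#' is the motif center) and `n_decoys` exact copies of sampled BS cores at
#' distinct loci without peaks. Strands are Bernoulli(1/2), with the reverse
#' complement inserted on `-`. Signal tracks are exponential background noise
#' plus a Gaussian bump at every site: the accessibility bump is identically
#' distributed for BSs and decoys (so accessibility matching is possible),
#' each HM bump is scaled by `2^hm_effect[m]` at BSs only, and the
#' nucleosome bump is scaled by `2^-nucleosome_depletion_at_bs` at BSs.
#' When `sharing_fraction > 0`, that fraction of a TF's BSs is placed within
#' 300 bp of a same-family partner BS.
#'
#' @param config A [synth_config()].
#' @param tracks Logical; set `FALSE` to skip signal-track simulation when
#'   only coordinates and sequence are needed (e.g. co-occupancy studies).
#' @return An `hmtf_study` list: `genome`, `peaks` (named list of `GRanges`
#'   per TF), `tracks` (`accessibility`, `nucleosome`, and `hm` -- a named
#'   list of [signal_track()]s), `accessible` (`GRanges` of accessible
#'   regions), `truth` (per-TF `bs`/`decoys` site `GRanges` with core
#'   sequences and pairing hints, the realized `hm_effect` matrix, family
#'   labels), and `config`.
#' @export
generate_study <- function(config, tracks = TRUE) {
  stopifnot(inherits(config, "SyntheticStudyConfig"))
  with_seed(config$seed, .generate_study_impl(config, tracks))
}

.generate_study_impl <- function(config, make_tracks) {
  tfs <- config$tfs
  glen <- as.integer(config$genome_length)
  aflank <- config$accessible_flank
  n_sites_tot <- sum(vapply(tfs, function(tf) tf$n_bs + tf$n_decoys, numeric(1)))
  slot_w <- glen %/% n_sites_tot
  max_L <- max(vapply(tfs, function(tf) ncol(tf$pfm), numeric(1)))
  min_slot <- 1200L + max_L
  if (slot_w < min_slot) {
    stop(sprintf(
      "genome too small: %d sites need slots of >= %d bp but only %d bp are available per site",
      n_sites_tot, min_slot, slot_w))
  }
  margin <- aflank + 320L

  # genome as a char vector we can write into (kept local so subassignment
  # stays in place; no closures touch it)
  p <- c((1 - config$gc_fraction) / 2, config$gc_fraction / 2,
         config$gc_fraction / 2, (1 - config$gc_fraction) / 2)
  chars <- sample(DNA_BASES, glen, replace = TRUE, prob = p)

  # slot-grid placement: shuffled disjoint slots with jittered centers keep
  # slot-placed cores >= min_slot apart, so only the family-shared
  # placements (deliberately within 300 bp of a partner) need clash checks.
  slot_centers <- as.integer(seq_len(n_sites_tot) * slot_w - slot_w / 2)
  jitter_max <- max(0L, (slot_w - min_slot) %/% 2L)
  slot_order <- sample.int(n_sites_tot)
  slot_i <- 0L
  man_s <- integer(0); man_e <- integer(0)  # manually placed (shared) cores

  family_pool <- list()  # family -> integer vector of placed BS centers
  truth <- list()
  hm_eff <- matrix(0, nrow = length(tfs), ncol = length(config$hm_marks),
                   dimnames = list(names(tfs), config$hm_marks))

  for (tf in tfs) {
    L <- ncol(tf$pfm)
    cores <- sample_cores(tf$pfm, tf$n_bs)
    eff <- tf$hm_effect
    if (config$family_jitter > 0) {
      eff <- eff + rnorm(length(eff), 0, config$family_jitter)
    }
    hm_eff[tf$name, ] <- eff

    n_shared <- round(config$sharing_fraction * tf$n_bs)
    pool <- family_pool[[tf$family]] %||% integer(0)
    if (length(pool) == 0L) n_shared <- 0L

    n_place <- tf$n_bs + tf$n_decoys
    src <- if (tf$n_decoys >= tf$n_bs) {
      # every BS gets >= 1 exact-copy decoy
      c(sample.int(tf$n_bs), sample.int(tf$n_bs, tf$n_decoys - tf$n_bs,
                                        replace = TRUE))
    } else {
      sample.int(tf$n_bs, tf$n_decoys)
    }
    place_core <- c(cores, cores[src])  # BSs first, then decoys
    p_start <- integer(n_place); p_end <- integer(n_place)
    p_strand <- character(n_place)
    for (i in seq_len(n_place)) {
      s <- NA_integer_
      if (i <= n_shared) {
        for (try in seq_len(30L)) {  # near a family partner, within 300 bp
          partner <- pool[sample.int(length(pool), 1L)]
          off <- sample(c(-1L, 1L), 1L) * sample(seq(L + 20L, 280L), 1L)
          ctr <- partner + off
          if (ctr < margin || ctr > glen - margin) next
          cs <- ctr - L %/% 2L; ce <- cs + L - 1L
          if (any(man_e >= cs - 15L & man_s <= ce + 15L)) next
          s <- cs
          man_s <- c(man_s, cs); man_e <- c(man_e, ce)
          break
        }
      }
      if (is.na(s)) {
        slot_i <- slot_i + 1L
        if (slot_i > n_sites_tot) stop("site placement capacity exhausted")
        ctr <- slot_centers[slot_order[slot_i]] +
          sample.int(2L * jitter_max + 1L, 1L) - jitter_max - 1L
        ctr <- min(max(ctr, margin), glen - margin)
        s <- ctr - L %/% 2L
      }
      e <- s + L - 1L
      std <- if (runif(1) < 0.5) "+" else "-"
      ins <- if (std == "+") place_core[i] else revcomp(place_core[i])
      chars[s:e] <- strsplit(ins, "")[[1L]]
      p_start[i] <- s; p_end[i] <- e; p_strand[i] <- std
    }
    bs_start <- p_start[seq_len(tf$n_bs)]
    bs_end <- p_end[seq_len(tf$n_bs)]
    bs_strand <- p_strand[seq_len(tf$n_bs)]
    dc_idx <- tf$n_bs + seq_len(tf$n_decoys)
    dc_start <- p_start[dc_idx]; dc_end <- p_end[dc_idx]
    dc_strand <- p_strand[dc_idx]
    family_pool[[tf$family]] <- c(pool, as.integer((bs_start + bs_end) %/% 2L))

    # flank composition bias at BSs only (slot isolation keeps these 15-bp
    # rewrites clear of every other implanted core)
    if (tf$flank_bias > 0) {
      b <- tf$flank_bias
      pf <- c((1 - b) / 4, (1 + b) / 4, (1 + b) / 4, (1 - b) / 4)  # GC-rich
      for (i in seq_len(tf$n_bs)) {
        pos <- c((bs_start[i] - 15L):(bs_start[i] - 1L),
                 (bs_end[i] + 1L):(bs_end[i] + 15L))
        pos <- pos[pos >= 1L & pos <= glen]
        chars[pos] <- sample(DNA_BASES, length(pos), replace = TRUE, prob = pf)
      }
    }

    bs <- GRanges("chr1", IRanges(bs_start, bs_end), strand = bs_strand,
                  core_seq = cores, label = "BS", tf = tf$name,
                  family = tf$family)
    dc <- GRanges("chr1", IRanges(dc_start, dc_end), strand = dc_strand,
                  core_seq = cores[src], label = "nonBS", tf = tf$name,
                  family = tf$family, source_bs = src)
    truth[[tf$name]] <- list(bs = bs, decoys = dc, family = tf$family,
                             hm_effect = setNames(eff, config$hm_marks))
  }

  genome <- Biostrings::DNAStringSet(paste0(chars, collapse = ""))
  names(genome) <- "chr1"

  # peaks: fixed width centered on the motif (summit coincides by construction)
  half_pk <- config$peak_width %/% 2L
  peaks <- lapply(truth, function(tr) {
    ctr <- (start(tr$bs) + end(tr$bs)) %/% 2L
    GRanges("chr1", IRanges(pmax(1L, ctr - half_pk),
                            pmin(glen, ctr + half_pk - 1L)))
  })

  all_sites <- unlist(GenomicRanges::GRangesList(lapply(truth, function(tr) {
    c(tr$bs, tr$decoys)
  })), use.names = FALSE)
  ctrs <- (start(all_sites) + end(all_sites)) %/% 2L
  accessible <- GRanges("chr1", IRanges(pmax(1L, ctrs - aflank),
                                        pmin(glen, ctrs + aflank)))

  track_set <- NULL
  if (make_tracks) {
    bg <- config$accessibility_background
    amp0 <- config$bump_amplitude
    new_track <- function() rexp(glen, rate = 1 / bg)

    mk_track <- function(scale_bs_log2_by_tf) {
      v <- new_track()
      for (tf in tfs) {
        tr <- truth[[tf$name]]
        hw <- tf$hm_bump_halfwidth
        offs <- -(3L * hw):(3L * hw)
        kern <- exp(-(offs^2) / (2 * hw^2))
        sc <- 2^scale_bs_log2_by_tf[[tf$name]]
        ctrs <- c((start(tr$bs) + end(tr$bs)) %/% 2L,
                  (start(tr$decoys) + end(tr$decoys)) %/% 2L)
        amps <- amp0 * exp(rnorm(length(ctrs), 0, tf$noise_sd))
        amps[seq_len(tf$n_bs)] <- amps[seq_len(tf$n_bs)] * sc
        for (i in seq_along(ctrs)) {
          pos <- ctrs[i] + offs
          inb <- pos >= 1L & pos <= glen
          p <- pos[inb]
          v[p] <- v[p] + amps[i] * kern[inb]  # in place: v is local, refcount 1
        }
      }
      signal_track(list(chr1 = v))
    }

    zero <- setNames(as.list(rep(0, length(tfs))), names(tfs))
    acc <- mk_track(zero)  # identically distributed bumps in both classes
    nuc <- mk_track(setNames(as.list(rep(-config$nucleosome_depletion_at_bs,
                                         length(tfs))), names(tfs)))
    hm <- list()
    for (m in seq_along(config$hm_marks)) {
      eff_m <- setNames(as.list(hm_eff[, m]), names(tfs))
      hm[[config$hm_marks[m]]] <- mk_track(eff_m)
    }
    track_set <- list(accessibility = acc, nucleosome = nuc, hm = hm)
  }

  structure(list(genome = genome, peaks = peaks, tracks = track_set,
                 accessible = accessible, truth = truth, config = config),
            class = "hmtf_study")
}

#' @export
print.hmtf_study <- function(x, ...) {
  cat("hmtf_study:", length(x$truth), "TF(s), genome",
      format(x$config$genome_length, big.mark = ","), "bp, seed",
      x$config$seed, "\n")
  invisible(x)
}

#' Configure a panel of TF families with shared HM preferences
#'
#' Builds a [synth_config()] with `n_families * tfs_per_family` TFs. Each
#' family shares an HM effect vector (two marks at `+effect`, one at
#' `-0.75 * effect`, distinct marks per family) and, via
#' `sharing_fraction`, spatially correlated BS placement, so both the
#' family-level differential-HM structure and the co-occupancy structure
#' are recoverable.
#'
#' @param n_families Number of families (>= 2).
#' @param tfs_per_family TFs per family.
#' @param sharing_fraction Fraction of a TF's BSs placed within 300 bp of a
#'   same-family partner BS.
#' @param effect Magnitude (log2) of the family HM preference; default 2.
#' @param n_bs,n_decoys Per-TF site counts; defaults 140 / 150.
#' @param seed Study seed.
#' @param ... Passed on to [synth_config()] (e.g. `genome_length`).
#' @return A `SyntheticStudyConfig`.
#' @export
generate_family_panel <- function(n_families = 3L, tfs_per_family = 3L,
                                  sharing_fraction = 0.5, effect = 2,
                                  n_bs = 140L, n_decoys = 150L, seed = 1L,
                                  ...) {
  stopifnot(n_families >= 2L, tfs_per_family >= 1L)
  n_marks <- length(HM_MARKS)
  tfs <- list()
  for (f in seq_len(n_families)) {
    eff <- rep(0, n_marks)
    up <- ((2 * (f - 1)) %% n_marks) + c(1L, 2L)
    dn <- n_marks - ((f - 1L) %% n_marks)
    eff[up] <- effect
    eff[dn] <- -0.75 * effect
    for (t in seq_len(tfs_per_family)) {
      nm <- sprintf("TF_f%d_%d", f, t)
      tfs[[nm]] <- synth_tf(nm, family = sprintf("fam%d", f),
                            n_bs = n_bs, n_decoys = n_decoys,
                            hm_effect = eff)
    }
  }
  args <- list(...)
  if (is.null(args$genome_length)) {
    n_tot <- sum(vapply(tfs, function(tf) tf$n_bs + tf$n_decoys, numeric(1)))
    args$genome_length <- n_tot * 1500
    args$accessible_flank <- args$accessible_flank %||% 500L
  }
  do.call(synth_config,
          c(list(tfs = tfs, seed = seed, sharing_fraction = sharing_fraction),
            args))
}

#' Ground-truth matched collection of a synthetic TF
#'
#' Pairs every true BS with one of its exact-copy decoys (first decoy per BS
#' in decoy order), bypassing the scanning and matching stages. Useful for
#' testing the statistics and models under known conditions.
#'
#' @param study A [generate_study()] result.
#' @param tf TF name; default the first TF.
#' @return A [matched_collection()].
#' @export
truth_collection <- function(study, tf = NULL) {
  tf <- tf %||% names(study$truth)[1L]
  tr <- study$truth[[tf]]
  if (is.null(tr)) stop("no such TF in study: ", tf)
  first_decoy <- !duplicated(mcols(tr$decoys)$source_bs)
  dc <- tr$decoys[first_decoy]
  src <- mcols(dc)$source_bs
  keep_bs <- sort(src)
  dc <- dc[order(src)]
  matched_collection(tr$bs[keep_bs], dc,
                     flank = study$config$accessible_flank)
}

#' Write a synthetic study to disk
#'
#' Emits `genome.fa`, `accessible.bed`, one `<tf>_peaks.bed` per TF,
#' `accessibility.bedGraph`, `nucleosome.bedGraph`, one
#' `<mark>.bedGraph` per HM track, and `truth.json`. Output is
#' byte-deterministic given the study (values are rounded to 4 decimals for
#' the tracks).
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(study$genome, file.path(dir, "genome.fa"))
  write_bed(study$accessible, file.path(dir, "accessible.bed"))
  for (tf in names(study$peaks)) {
    write_bed(study$peaks[[tf]], file.path(dir, paste0(tf, "_peaks.bed")))
  }
  round_track <- function(tr) {
    tr$values <- lapply(tr$values, round, digits = 4L)
    tr
  }
  if (!is.null(study$tracks)) {
    write_bedgraph(round_track(study$tracks$accessibility),
                   file.path(dir, "accessibility.bedGraph"))
    write_bedgraph(round_track(study$tracks$nucleosome),
                   file.path(dir, "nucleosome.bedGraph"))
    for (m in names(study$tracks$hm)) {
      write_bedgraph(round_track(study$tracks$hm[[m]]),
                     file.path(dir, paste0(m, ".bedGraph")))
    }
  }
  truth_json <- lapply(study$truth, function(tr) {
    site_df <- function(gr) {
      data.frame(chrom = as.character(seqnames(gr)), start0 = start(gr) - 1L,
                 end = end(gr), strand = as.character(strand(gr)),
                 core_seq = mcols(gr)$core_seq)
    }
    list(family = tr$family, hm_effect = as.list(tr$hm_effect),
         bs = site_df(tr$bs), decoys = site_df(tr$decoys))
  })
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
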