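# Shared fixtures and independent oracles. Studies used by several test
# files are generated once and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

make_genome <- function(seqs) {
  g <- Biostrings::DNAStringSet(unlist(seqs))
  names(g) <- names(seqs)
  g
}

flat_track <- function(lens, value = 1) {
  signal_track(lapply(lens, function(n) rep(value, n)))
}

# A sharp 5-bp test motif (counts strongly favor the consensus TGCAT).
toy_pfm5 <- function() {
  cons <- c("T", "G", "C", "A", "T")
  pfm <- matrix(1, nrow = 4, ncol = 5, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(cons)) pfm[cons[j], j] <- 20
  pfm
}

# --- independent oracles -----------------------------------------------------

# Brute-force best PWM hit: per-window score summed base by base via
# substring, over both strands, ties by lowest offset then + strand.
oracle_scan <- function(seq, motif) {
  L <- motif$length
  n <- nchar(seq)
  if (n < L) return(NULL)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  score_at <- function(s, off) {
    tot <- 0
    for (j in seq_len(L)) {
      b <- substring(s, off + j - 1L, off + j - 1L)
      if (!b %in% rownames(motif$pwm)) return(NA_real_)
      tot <- tot + unname(motif$pwm[b, j])
    }
    tot
  }
  best <- NULL
  for (off in seq_len(n - L + 1L)) {
    for (std in c("+", "-")) {
      sc <- if (std == "+") score_at(seq, off)
            else score_at(rc, n - L + 1L - off + 1L)
      if (is.na(sc)) next
      if (is.null(best) || sc > best$score) {
        best <- list(offset = off, strand = std, score = sc)
      }
    }
  }
  best
}

# Exact one-sided signed-rank p by enumerating all 2^n sign assignments of
# the (nonzero, tie-free) differences.
oracle_signed_rank_p <- function(d, alternative) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_null <- as.numeric(signs %*% r)
  if (alternative == "greater") mean(v_null >= v_obs) else mean(v_null <= v_obs)
}

# Exact two-sided rank-sum p by enumerating all label assignments.
oracle_ranksum_p2 <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  w_null <- apply(combos, 2L, function(ix) sum(r[ix])) - n * (n + 1) / 2
  p <- 2 * min(mean(w_null <= w_obs), mean(w_null >= w_obs))
  min(1, p)
}

# --- cached study fixtures ---------------------------------------------------

# Parameter-recovery conditions: 200 BSs, one mark (H3K4me3) at +2 log2
# units ("hm"), or a GC-biased flank with no HM signal ("flank").
recovery_config <- function(seed, type = c("hm", "flank")) {
  type <- match.arg(type)
  eff <- rep(0, 10)
  bias <- 0
  if (type == "hm") eff[which(hm_marks() == "H3K4me3")] <- 2
  if (type == "flank") bias <- 0.8
  synth_config(synth_tf("TF1", n_bs = 200, n_decoys = 250, hm_effect = eff,
                        flank_bias = bias),
               genome_length = 1e6, seed = seed)
}

recovery_study <- function(seed, type = "hm") {
  cached(paste0("recovery_", type, "_", seed),
         generate_study(recovery_config(seed, type)))
}

# Small null-calibration conditions: no signal anywhere, 150 pairs,
# 500-bp windows.
null_config <- function(seed) {
  synth_config(synth_tf("TF1", n_bs = 150, n_decoys = 160),
               genome_length = 310 * 1300, accessible_flank = 500,
               seed = seed)
}

# A small study for unit tests of the scan/match stages.
unit_study <- function() {
  cached("unit_study", generate_study(
    synth_config(synth_tf("TFu", n_bs = 140, n_decoys = 150),
                 genome_length = 290 * 1300, accessible_flank = 500,
                 seed = 42)))
}

# Feature matrix of the seed-1 "hm" recovery study (truth pairing).
recovery_fm <- function(type = "hm", flank_len_seq = 10) {
  cached(paste0("recovery_fm_", type, "_", flank_len_seq), {
    study <- recovery_study(1, type)
    coll <- truth_collection(study)
    build_feature_matrix(coll, study$genome,
                         tracks = list(hm = study$tracks$hm,
                                       nucleosome = study$tracks$nucleosome),
                         flank_len_seq = flank_len_seq, flank_len_hm = 1000)
  })
}
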