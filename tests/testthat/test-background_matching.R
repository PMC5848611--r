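test_that("exact-match search honors strand, exclusion, and first-per-region", {
  g <- make_genome(list(c1 = "AAGATTACAAA"))
  acc <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 11))
  hits <- find_exact_matches("GATTACA", acc, g)
  expect_length(hits, 1L)
  expect_equal(start(hits), 3L)
  expect_equal(end(hits), 9L)
  expect_equal(as.character(strand(hits)), "+")

  # only the reverse complement present -> one minus-strand match
  g2 <- make_genome(list(c1 = paste0("AAA", "TGTAATC", "AAA")))
  acc2 <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 13))
  hits2 <- find_exact_matches("GATTACA", acc2, g2)
  expect_length(hits2, 1L)
  expect_equal(as.character(strand(hits2)), "-")
  expect_equal(start(hits2), 4L)

  # two copies in one region -> only the leftmost kept
  g3 <- make_genome(list(c1 = paste0("AA", "GATTACA", "TT", "GATTACA", "AA")))
  acc3 <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 20))
  hits3 <- find_exact_matches("GATTACA", acc3, g3)
  expect_length(hits3, 1L)
  expect_equal(start(hits3), 3L)

  # exclusion removes overlapping occurrences
  excl <- GenomicRanges::GRanges("c1", IRanges::IRanges(3, 9))
  hits4 <- find_exact_matches("GATTACA", acc3, g3, exclude = excl)
  expect_equal(start(hits4), 12L)
})

test_that("accessibility matching is greedy argmin in BS coordinate order", {
  # one BS, one candidate
  g <- make_genome(list(c1 = strrep("A", 400)))
  mk_site <- function(s, core = "AAAAA") {
    GenomicRanges::GRanges("c1", IRanges::IRanges(s, s + 4), strand = "+",
                           core_seq = core)
  }
  acc_vals <- rep(0, 400)
  # windows are site +/- 10 here
  acc_vals[96:120] <- 1     # candidate A window mean ~ high
  track <- signal_track(list(c1 = acc_vals))
  bs <- mk_site(101)
  cand <- list(AAAAA = mk_site(301))
  coll <- select_matched_nonbs(bs, cand, track, flank = 10)
  expect_equal(start(coll$nonbs), 301L)

  # candidates with accessibility deltas {0.5, 0.1, 0.3} -> the 0.1 one wins
  vals <- rep(0, 1000)
  win_mean <- function(center, m) vals[(center - 12):(center + 12)] <<- m
  win_mean(101, 1.0)   # the BS
  win_mean(301, 0.5)   # candidates at means 0.5, 0.9, 0.7
  win_mean(501, 0.9)
  win_mean(701, 0.7)
  track2 <- signal_track(list(c1 = vals))
  bs2 <- mk_site(99)   # window inside the plateau
  cand2 <- list(AAAAA = c(mk_site(299), mk_site(499), mk_site(699)))
  coll2 <- select_matched_nonbs(bs2, cand2, track2, flank = 10)
  expect_equal(start(coll2$nonbs), 499L)
})

test_that("matching equals a hand-run greedy oracle on a shared candidate pool", {
  # 3 BSs (coordinate order) with window means 10, 20, 30; 5 shared
  # candidates with means 19, 29, 11, 100, 200. Greedy without replacement:
  # BS1 -> 11, BS2 -> 19, BS3 -> 29.
  vals <- rep(0, 3000)
  put <- function(center, m) vals[(center - 12):(center + 12)] <<- m
  bs_centers <- c(101, 301, 501)
  put(101, 10); put(301, 20); put(501, 30)
  cand_centers <- c(1001, 1201, 1401, 1601, 1801)
  cand_means <- c(19, 29, 11, 100, 200)
  for (i in seq_along(cand_centers)) put(cand_centers[i], cand_means[i])
  track <- signal_track(list(c1 = vals))
  mk <- function(s) GenomicRanges::GRanges("c1", IRanges::IRanges(s, s + 4),
                                           strand = "+", core_seq = "AAAAA")
  bs <- do.call(c, lapply(bs_centers - 2, mk))
  cand <- list(AAAAA = do.call(c, lapply(cand_centers - 2, mk)))
  coll <- select_matched_nonbs(bs, cand, track, flank = 10)
  expect_equal(start(coll$nonbs), c(1401L, 1001L, 1201L) - 2L)
})

test_that("pair invariants hold on a full synthetic matching run", {
  study <- unit_study()
  motif <- motif_model(study$config$tfs$TFu$pfm)
  sites <- align_binding_sites(study$peaks$TFu, study$genome, motif)
  cand <- hmtf:::find_exact_matches_multi(
    mcols(sites)$core_seq, study$accessible, study$genome,
    exclude = hmtf:::granges_clean(sites))
  coll <- select_matched_nonbs(sites, cand, study$tracks$accessibility,
                               flank = 500)
  expect_equal(length(coll$bs), length(coll$nonbs))
  expect_identical(mcols(coll$bs)$core_seq, mcols(coll$nonbs)$core_seq)
  # the genome really contains the non-BS cores (oriented)
  expect_identical(hmtf:::extract_seqs(study$genome, coll$nonbs),
                   mcols(coll$nonbs)$core_seq)
  # no interval appears twice across bs and nonbs
  all_iv <- c(hmtf:::granges_clean(coll$bs), hmtf:::granges_clean(coll$nonbs))
  expect_equal(length(unique(all_iv)), length(all_iv))
})

test_that("bootstrap resampling produces a seeded imbalanced collection", {
  study <- unit_study()
  coll <- truth_collection(study)
  n <- length(coll$bs)
  boot <- bootstrap_imbalanced(coll, factor = 5, seed = 3)
  expect_equal(length(boot$bs), n)
  expect_equal(length(boot$nonbs), 5L * n)
  expect_false(boot$paired)
  boot2 <- bootstrap_imbalanced(coll, factor = 5, seed = 3)
  expect_identical(start(boot$nonbs), start(boot2$nonbs))
  b1 <- bootstrap_imbalanced(coll, factor = 1, seed = 9)
  expect_equal(length(b1$nonbs), n)
})

test_that("degenerate matching inputs raise errors", {
  g <- make_genome(list(c1 = strrep("A", 100)))
  track <- signal_track(list(c1 = rep(1, 100)))
  bs <- GenomicRanges::GRanges("c1", IRanges::IRanges(51, 55), strand = "+",
                               core_seq = "CCCCC")
  expect_error(select_matched_nonbs(bs, list(), track, flank = 10),
               "no exact-match candidates")
})
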