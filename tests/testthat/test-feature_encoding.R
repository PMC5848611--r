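test_that("sequence one-hot encoding follows the A/T/G/C bit convention", {
  expect_equal(unname(encode_sequence("A", "C")), c(1, 0, 0, 0, 0, 0, 0, 1))
  expect_equal(unname(encode_sequence("T", "G")), c(0, 1, 0, 0, 0, 0, 1, 0))
  for (f in c(5, 10, 15)) {
    fl <- strrep("A", f)
    expect_length(encode_sequence(fl, fl), 8 * f)
  }
  expect_error(encode_sequence("AN", "AC"), "non-ACGT")
})

test_that("shape prediction equals window-by-window table lookup", {
  tab <- toy_shape_table()
  # homopolymer: constant lookup
  mono <- predict_shape(strrep("A", 9), tab)
  expect_equal(nrow(mono), 5L)
  expect_equal(mono[, "MGW"], rep(tab["AAAAA", "MGW"], 5))

  # payload of length 10 (14 with context) gives 10 values per feature
  expect_equal(nrow(predict_shape(strrep("AC", 7), tab)), 10L)

  set.seed(5)
  seq <- paste0(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
                collapse = "")
  got <- predict_shape(seq, tab)
  for (i in seq_len(nchar(seq) - 4)) {
    pent <- substr(seq, i, i + 4)
    expect_equal(unname(got[i, ]), unname(tab[pent, ]), info = pent)
  }
  expect_error(predict_shape("ACGNA", tab), "pentamer")
})

test_that("the bundled table covers all pentamers with proper strand symmetry", {
  tab <- toy_shape_table()
  expect_equal(nrow(tab), 1024L)
  rc <- hmtf:::revcomp(rownames(tab))
  expect_equal(unname(tab[, "MGW"]), unname(tab[rc, "MGW"]))
  expect_equal(unname(tab[, "ProT"]), unname(tab[rc, "ProT"]))
  expect_equal(unname(tab[, "HelT"]), unname(tab[rc, "HelT"]))
  expect_equal(unname(tab[, "Roll"]), unname(-tab[rc, "Roll"]))
  # plausible physical ranges
  expect_true(all(tab[, "MGW"] > 2 & tab[, "MGW"] < 8))
  expect_true(all(tab[, "HelT"] > 30 & tab[, "HelT"] < 40))
})

test_that("a shape table read from TSV completes missing reverse complements", {
  tab <- toy_shape_table()
  f <- withr::local_tempfile(fileext = ".tsv")
  keep <- rownames(tab)[!duplicated(pmin(rownames(tab),
                                         hmtf:::revcomp(rownames(tab))))]
  df <- data.frame(pentamer = keep, tab[keep, , drop = FALSE])
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_shape_table(f)
  expect_equal(back, tab[rownames(back), ])
})

test_that("average_signal applies the window and RPM definitions", {
  # constant coverage c with total T -> c * 1e6 / T for any window
  tr <- signal_track(list(c1 = rep(2, 5000)))
  site <- GenomicRanges::GRanges("c1", IRanges::IRanges(2001, 2007),
                                 strand = "+", core_seq = "AAAAAAA")
  expect_equal(average_signal(tr, site, flank = 1000), 2 * 1e6 / 10000)

  # window length: motif length 7 + 2 * 1000 = 2007 bases
  vals <- rep(0, 5000); vals[1001:3007] <- 1  # exactly the window
  tr2 <- signal_track(list(c1 = vals))
  expect_equal(average_signal(tr2, site, flank = 1000),
               1 * 1e6 / sum(vals))

  # replicates are averaged after normalization
  tr_a <- signal_track(list(c1 = rep(1, 5000)))
  tr_b <- signal_track(list(c1 = rep(3, 5000)))
  expect_equal(average_signal(list(tr_a, tr_b), site, flank = 1000),
               (1e6 / 5000 + 1e6 / 5000) / 2 * 1)
  expect_error(average_signal(signal_track(list(c1 = rep(0, 100))),
                              GenomicRanges::GRanges("c1", IRanges::IRanges(50, 55)),
                              flank = 10),
               "total_signal")
})

test_that("feature matrix has the documented column structure", {
  fm5 <- {
    study <- recovery_study(1, "hm")
    coll <- truth_collection(study)
    build_feature_matrix(coll, study$genome,
                         tracks = list(hm = study$tracks$hm,
                                       nucleosome = study$tracks$nucleosome),
                         flank_len_seq = 5, flank_len_hm = 1000)
  }
  expect_equal(sum(fm5$category %in% c("seq", "MGW", "ProT", "Roll", "HelT")),
               80L)
  fm10 <- recovery_fm("hm", 10)
  expect_equal(sum(fm10$category %in% c("seq", "MGW", "ProT", "Roll", "HelT")),
               160L)
  expect_equal(sum(fm10$category %in% hm_marks()), 10L)
  expect_equal(sum(fm10$category == "nuc"), 1L)
  expect_equal(ncol(fm10$x), 171L)
  expect_false(anyNA(fm10$x))
  expect_equal(fm10$label, rep(c(1L, 0L), each = length(fm10$label) / 2))
  expect_error(build_feature_matrix(truth_collection(recovery_study(1, "hm")),
                                    recovery_study(1, "hm")$genome,
                                    flank_len_seq = 7),
               "flank_len_seq")
})

test_that("features are invariant under reverse-complementing the genome", {
  study <- cached("rc_study", generate_study(
    synth_config(synth_tf("T", n_bs = 8, n_decoys = 10),
                 genome_length = 3e4, accessible_flank = 300, seed = 11)))
  coll <- truth_collection(study)
  fm <- build_feature_matrix(coll, study$genome, tracks = NULL,
                             flank_len_seq = 5)
  # flip the genome and all coordinates; strands flip too
  glen <- Biostrings::width(study$genome)[[1]]
  rc_genome <- Biostrings::reverseComplement(study$genome)
  names(rc_genome) <- names(study$genome)
  flip <- function(gr) {
    GenomicRanges::GRanges(
      seqnames(gr),
      IRanges::IRanges(glen - end(gr) + 1L, glen - start(gr) + 1L),
      strand = ifelse(as.character(strand(gr)) == "+", "-", "+"),
      core_seq = mcols(gr)$core_seq)
  }
  coll_rc <- matched_collection(flip(coll$bs), flip(coll$nonbs),
                                flank = coll$flank_len_accessibility)
  fm_rc <- build_feature_matrix(coll_rc, rc_genome, tracks = NULL,
                                flank_len_seq = 5)
  expect_equal(fm_rc$x, fm$x)
})

test_that("HM features are invariant to rescaling raw coverage", {
  study <- recovery_study(1, "hm")
  coll <- truth_collection(study)
  tr <- study$tracks$hm[["H3K4me3"]]
  scaled <- signal_track(lapply(tr$values, `*`, 7))
  expect_equal(average_signal(scaled, coll$bs, 1000),
               average_signal(tr, coll$bs, 1000))
})
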