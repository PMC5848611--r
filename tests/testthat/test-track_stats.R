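test_that("meta-profiles report per-position mean and stderr on RPM scale", {
  tr <- signal_track(list(c1 = rep(4, 2000)))
  sites <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(501, 1201), width = 5),
                                  strand = "+")
  mp <- meta_profile(tr, sites, flank = 100)
  expect_length(mp$mean, 205L)
  expect_equal(mp$positions, seq(-100, 104))
  expect_equal(unique(mp$mean), 4 * 1e6 / 8000)
  expect_equal(unique(mp$stderr), 0)
  expect_error(meta_profile(tr, sites[1], flank = 100), "at least 2")
})

test_that("meta-profiles peak at the implanted bump and orient minus strands", {
  study <- recovery_study(1, "hm")
  tr <- study$truth$TF1
  mp <- meta_profile(study$tracks$hm[["H3K4me3"]], tr$bs, flank = 1000)
  peak_pos <- mp$positions[which.max(mp$mean)]
  expect_lt(abs(peak_pos - 4), 150)  # motif center ~ position 4, halfwidth 150

  # strand orientation: an asymmetric track is mirrored for - sites
  vals <- rep(0, 400); vals[211:260] <- 1  # right of a site at [201,205]
  tr2 <- signal_track(list(c1 = vals))
  plus <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(201, 201), width = 5),
                                 strand = "+")
  minus <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(201, 201), width = 5),
                                  strand = "-")
  mp_p <- meta_profile(tr2, plus, flank = 100)
  mp_m <- meta_profile(tr2, minus, flank = 100)
  expect_equal(mp_m$mean, rev(mp_p$mean))
})

test_that("delta is zero without signal and exactly antisymmetric", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.4, 2.9)
  expect_equal(delta_log_q(x, x)$delta, 0)
  set.seed(2)
  for (i in 1:10) {
    a <- rexp(30); b <- rexp(30)
    d1 <- delta_log_q(a, b, n_marks_corrected = 10)
    d2 <- delta_log_q(b, a, n_marks_corrected = 10)
    expect_equal(d1$delta, -d2$delta)
    expect_equal(d1$q_greater, d2$q_less)
  }
})

test_that("one-sided signed-rank p matches exhaustive sign enumeration at n = 8", {
  set.seed(7)
  for (i in 1:5) {
    a <- round(rexp(8), 3); b <- round(rexp(8), 3)
    while (any(a == b) || any(duplicated(abs(a - b)))) {
      a <- round(rexp(8), 3); b <- round(rexp(8), 3)
    }
    r <- delta_log_q(a, b, n_marks_corrected = 10)
    expect_equal(r$p_greater, oracle_signed_rank_p(a - b, "greater"))
    expect_equal(r$p_less, oracle_signed_rank_p(a - b, "less"))
  }
})

test_that("Bonferroni correction caps at 1 and is monotone in family size", {
  a <- c(5, 6, 7, 8, 9, 10, 11, 12)
  b <- a - 1
  qs <- vapply(c(1L, 5L, 10L, 50L),
               function(m) delta_log_q(a, b, m)$q_greater, numeric(1))
  expect_true(all(diff(qs) >= 0))
  expect_true(all(qs <= 1))
})

test_that("label shuffling gives a calibrated null for |delta|", {
  study_null <- cached("null_seed1", generate_study(null_config(1)))
  coll <- truth_collection(study_null)
  mark <- study_null$tracks$hm[[1]]
  bs_v <- average_signal(mark, coll$bs, 500)
  nb_v <- average_signal(mark, coll$nonbs, 500)
  obs <- abs(delta_log_q(bs_v, nb_v)$delta)
  null_d <- shuffle_control(bs_v, nb_v, n_shuffles = 50, seed = 4)
  expect_length(null_d, 50L)
  expect_lte(obs, max(null_d) + 1e-9)  # no signal: inside the null envelope

  # a spiked mark escapes the shuffle null entirely
  study_hm <- recovery_study(1, "hm")
  coll_hm <- truth_collection(study_hm)
  spike <- study_hm$tracks$hm[["H3K4me3"]]
  bs_s <- average_signal(spike, coll_hm$bs, 1000)
  nb_s <- average_signal(spike, coll_hm$nonbs, 1000)
  obs_s <- abs(delta_log_q(bs_s, nb_s)$delta)
  null_s <- shuffle_control(bs_s, nb_s, n_shuffles = 100, seed = 4)
  expect_gt(obs_s, max(null_s))
  expect_identical(shuffle_control(bs_s, nb_s, 10, seed = 9),
                   shuffle_control(bs_s, nb_s, 10, seed = 9))
})

test_that("paired t-test matches the closed-form textbook computation", {
  x <- c(3.1, 4.5, 2.2, 5.0, 3.7)
  y <- c(2.5, 4.0, 2.6, 4.1, 3.0)
  d <- x - y
  t_stat <- mean(d) / (sd(d) / sqrt(length(d)))
  p_hand <- 1 - pt(t_stat, df = length(d) - 1)
  expect_equal(grouped_paired_ttest(x, y, "greater"), p_hand)
  expect_equal(grouped_paired_ttest(x, y, "less"), pt(t_stat, length(d) - 1))
  # noise-free shift -> p = 0 for the "less" alternative of condition1
  expect_equal(grouped_paired_ttest(y, y + 1, "less"), 0)
  expect_equal(grouped_paired_ttest(y, y + 1, "greater"), 1)
  expect_error(grouped_paired_ttest(c(1, 2, 3), c(1, 2, 3), "less"),
               "zero")
})

test_that("two-sided rank-sum shift test matches exact enumeration at 6 vs 6", {
  set.seed(11)
  for (i in 1:3) {
    x <- round(runif(6), 3); y <- round(runif(6) + 0.2, 3)
    while (anyDuplicated(c(x, y))) {
      x <- round(runif(6), 3); y <- round(runif(6) + 0.2, 3)
    }
    expect_equal(occupancy_shift_test(x, y), oracle_ranksum_p2(x, y))
  }
  expect_error(occupancy_shift_test(numeric(0), 1:3), "nonempty")
  # disjoint supports attain the minimal p for the sizes
  expect_equal(occupancy_shift_test(1:6, 101:106),
               oracle_ranksum_p2(1:6, 101:106))
})
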