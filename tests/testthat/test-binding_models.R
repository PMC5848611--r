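# A small dense classification fixture: two informative continuous
# features, several noise features, balanced labels.
toy_fm <- function(n_per_class = 60, seed = 1, informative = TRUE) {
  set.seed(seed)
  y <- rep(c(1L, 0L), each = n_per_class)
  n <- length(y)
  x <- cbind(f1 = rnorm(n) + if (informative) 1.5 * y else 0,
             f2 = rnorm(n) + if (informative) -1.0 * y else 0,
             n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  list(x = x, y = y)
}

test_that("AUPRC matches hand-enumerated precision-recall points", {
  # perfectly separating scores
  expect_equal(auprc(c(9, 8, 2, 1), c(1, 1, 0, 0)), 1)
  # all scores equal -> one PR point at the prevalence
  expect_equal(auprc(rep(1, 10), rep(c(1, 0), 5)), 0.5)
  expect_equal(auprc(rep(1, 8), c(1, 1, 0, 0, 0, 0, 0, 0)), 0.25)
  # alternating case: positives at ranks 1 and 3
  expect_equal(auprc(c(.9, .8, .7, .6), c(1, 0, 1, 0)), (1 + 2 / 3) / 2)
  # tie block containing a positive and a negative: both positives take the
  # precision at their block's end (ranks 1 and 3)
  expect_equal(auprc(c(.9, .5, .5, .1), c(1, 1, 0, 0)), (1 + 2 / 3) / 2)
  expect_error(auprc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUPRC is invariant under strictly monotone score transforms", {
  set.seed(3)
  s <- rnorm(100); y <- rbinom(100, 1, 0.4)
  a0 <- auprc(s, y)
  expect_equal(auprc(2 * s + 5, y), a0)
  expect_equal(auprc(exp(s), y), a0)
  expect_equal(auprc(rank(s), y), a0)
})

test_that("ridge at lambda ~ 0 reproduces the least-squares oracle (20 x 5)", {
  set.seed(4)
  x <- matrix(rnorm(100), 20, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  y <- rnorm(20)
  path <- hmtf:::ridge_path(x, y, lambdas = 0, category = rep("seq", 5))
  # category "seq" -> centered only, so coefficients equal lm()'s slopes
  fit_lm <- lm(y ~ x)
  expect_equal(as.numeric(path$coefs), unname(coef(fit_lm)[-1]),
               tolerance = 1e-8)
  expect_equal(as.numeric(hmtf:::ridge_predict(path, x)),
               unname(fitted(fit_lm)), tolerance = 1e-8)
})

test_that("ridge shrinks to the mean as lambda grows", {
  d <- toy_fm()
  path <- hmtf:::ridge_path(d$x, d$y, lambdas = 1e9,
                            category = rep("cont", ncol(d$x)))
  expect_lt(max(abs(path$coefs)), 1e-6)
  pred <- hmtf:::ridge_predict(path, d$x)
  expect_equal(as.numeric(pred), rep(mean(d$y), nrow(d$x)), tolerance = 1e-5)
})

test_that("embedded CV selects lambda from the grid and the fit separates", {
  d <- toy_fm()
  fit <- fit_l2_mlr(d$x, d$y, category = rep("cont", ncol(d$x)))
  expect_true(fit$lambda %in% default_lambda_grid())
  expect_length(fit$cv_auprc, length(default_lambda_grid()))
  expect_gt(auprc(predict(fit, d$x), d$y), 0.9)
  expect_error(fit_l2_mlr(d$x, rep(1, nrow(d$x))), "single-class")
})

test_that("prediction scores are insensitive to feature column order", {
  d <- toy_fm()
  fit1 <- fit_l2_mlr(d$x, d$y, category = rep("cont", 5))
  perm <- c(3, 1, 5, 2, 4)
  fit2 <- fit_l2_mlr(d$x[, perm], d$y, category = rep("cont", 5))
  expect_equal(predict(fit2, d$x[, perm]), predict(fit1, d$x),
               tolerance = 1e-8)
})

test_that("variant evaluation uses the category structure of the matrix", {
  fm <- recovery_fm("hm", 10)
  a_ss <- evaluate_variant(fm, "seq_shape", cv_seed = 1)
  a_hm <- evaluate_variant(fm, "hm_only", cv_seed = 1)
  a_full <- evaluate_variant(fm, "seq_shape_hm", cv_seed = 1)
  # HM-only signal: HM variant beats sequence+shape, which is near chance
  expect_gt(a_hm, a_ss + 0.2)
  expect_gt(a_full, a_ss + 0.2)
  expect_lt(abs(a_ss - 0.5), 0.15)
  a_nuc <- evaluate_variant(fm, "seq_shape_nuc", cv_seed = 1)
  expect_gt(a_nuc, a_ss)  # nucleosome depletion at BSs is informative
  expect_error(evaluate_variant(fm, "nonsense"), "unknown model variant")
  fm_nohm <- local({
    study <- recovery_study(1, "hm")
    build_feature_matrix(truth_collection(study), study$genome,
                         tracks = NULL, flank_len_seq = 5)
  })
  expect_error(evaluate_variant(fm_nohm, "seq_shape_nuc"), "absent")
})

test_that("label permutation drives AUPRC to chance at balance", {
  fm <- recovery_fm("hm", 10)
  set.seed(8)
  fm_perm <- fm
  fm_perm$label <- sample(fm$label)
  a <- evaluate_variant(fm_perm, "seq_shape_hm", cv_seed = 1)
  expect_lt(abs(a - 0.5), 0.1)
})

test_that("binding-mode quadrants follow the 5%/15% thresholds", {
  expect_equal(classify_binding_mode(10, 5)$mode, "HM_specific")
  expect_equal(classify_binding_mode(2, 20)$mode, "seq_shape_specific")
  expect_equal(classify_binding_mode(2, 5)$mode, "other")
  expect_equal(classify_binding_mode(10, 20)$mode, "both")
  # boundary values are inclusive
  expect_equal(classify_binding_mode(5, 14.99)$mode, "HM_specific")
  expect_equal(classify_binding_mode(4.99, 15)$mode, "seq_shape_specific")
})

test_that("percent gain is the relative AUPRC improvement", {
  expect_equal(percent_gain(0.81, 0.71), 100 * 0.10 / 0.71)
  expect_equal(percent_gain(0.5, 0.5), 0)
})

test_that("leave-one-feature-out returns 15 groups and spares inert features", {
  fm <- recovery_fm("hm", 10)
  lofo <- leave_one_feature_out(fm, cv_seed = 1)
  expect_equal(nrow(lofo), 15L)
  expect_setequal(lofo$feature,
                  c("sequence", "MGW", "ProT", "Roll", "HelT", hm_marks()))
  # the spiked mark dominates the importance ranking
  expect_equal(lofo$feature[which.max(lofo$pct_decrease)], "H3K4me3")
  # uninformative marks cost little
  inert <- lofo$pct_decrease[lofo$feature %in% c("H3K27me3", "H3K9me3")]
  expect_true(all(abs(inert) < 2))
})
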