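# End-to-end orchestration: simulate (or load) -> scan -> match -> encode ->
# differential HM -> models -> LOFO -> mode -> co-occupancy -> nucleosome
# profiles, from one configuration, with per-TF rejection handling and a
# JSON manifest.

#' Default study thresholds
#'
#' The analysis constants used throughout: minimum aligned BSs per TF
#' (132), peak flank extension for proximal BSs (300 bp), binding-mode
#' importance thresholds (5% HM / 15% sequence+shape), summit-coincidence
#' tolerance (25 bp), HM window half-width (1000 bp), sequence/shape flank
#' length (10 bp), Bonferroni family (2 directions x 10 marks).
#'
#' @return Named list of defaults.
#' @export
study_defaults <- function() {
  list(min_sites = 132L, proximity_extend = 300L,
       hm_gain_threshold = 5, ss_gain_threshold = 15,
       summit_tol = 25L, flank_len_hm = 1000L, flank_len_seq = 10L,
       n_marks_corrected = 10L, cv_folds = 10L, cv_seed = 1L,
       bootstrap_factor = 5L)
}

#' Run the full study pipeline on a synthetic configuration
#'
#' Executes, for every TF of the study: peak alignment against the TF's
#' PFM with the best-hit rule and dataset filters; exact-match background
#' search in the accessible regions; accessibility matching; feature
#' encoding; the per-mark Delta\[-log10(q)\] statistic; the model-variant
#' AUPRC comparison and binding-mode call; and optionally the
#' leave-one-feature-out deconvolution. TFs rejected by a filter are
#' recorded with their reason and the pipeline continues. Afterwards,
#' cross-TF co-occupancy (when >= 2 TFs survive) and the per-TF
#' nucleosome-occupancy shift test are computed. All randomness derives
#' from the config seed; rerunning with the same config reproduces every
#' number.
#'
#' @param config A [synth_config()] (or path to a YAML/JSON file with the
#'   equivalent fields; see Details).
#' @param out_dir Optional directory: when given, per-stage TSVs and a
#'   `manifest.json` are written.
#' @param run_lofo Logical; run the 15-way leave-one-feature-out analysis
#'   per TF (the most expensive stage). Default `FALSE`.
#' @param settings Overrides for [study_defaults()].
#'
#' @details A configuration file must contain a `tfs` list (each entry:
#' `name`, and optionally `family`, `n_bs`, `n_decoys`, `hm_effect`,
#' `flank_bias`, `pfm` as a 4-row count matrix) plus any of the
#' [synth_config()] scalar fields. YAML and JSON are both accepted.
#'
#' @return An `hmtf_study_result` list: `tf` (per-TF results: sites
#'   aligned, delta table, AUPRCs, gains, mode, optional LOFO, nucleosome
#'   shift p), `rejections`, `cooccupancy` (pair table and family test p,
#'   when applicable), `manifest`.
#' @export
run_study <- function(config, out_dir = NULL, run_lofo = FALSE,
                      settings = list()) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "SyntheticStudyConfig"))
  st <- modifyList(study_defaults(), settings)
  st$n_marks_corrected <- length(config$hm_marks)

  study <- generate_study(config)
  genome <- study$genome
  tracks <- study$tracks

  tf_results <- list()
  rejections <- list()
  sites_by_tf <- list()

  for (tf in config$tfs) {
    nm <- tf$name
    motif <- motif_model(tf$pfm)
    sites <- align_binding_sites(study$peaks[[nm]], genome, motif,
                                 min_sites = st$min_sites,
                                 summit_tol = st$summit_tol)
    if (is_rejected(sites)) {
      rejections[[nm]] <- sites$reason
      next
    }
    cand <- find_exact_matches_multi(mcols(sites)$core_seq,
                                     study$accessible, genome,
                                     exclude = granges_clean(sites))
    coll <- select_matched_nonbs(sites, cand, tracks$accessibility,
                                 flank = config$accessible_flank)
    fm <- build_feature_matrix(coll, genome,
                               tracks = list(hm = tracks$hm,
                                             nucleosome = tracks$nucleosome),
                               flank_len_seq = st$flank_len_seq,
                               flank_len_hm = st$flank_len_hm)
    delta <- delta_log_q_all(coll, tracks$hm, flank = st$flank_len_hm,
                             n_marks_corrected = st$n_marks_corrected)
    mode <- binding_mode_call(fm, cv_folds = st$cv_folds,
                              cv_seed = st$cv_seed)
    nuc_bs <- average_signal(tracks$nucleosome, coll$bs, st$flank_len_hm)
    nuc_non <- average_signal(tracks$nucleosome, coll$nonbs, st$flank_len_hm)
    res <- list(
      tf = nm, family = tf$family,
      n_peaks = length(study$peaks[[nm]]),
      n_sites = length(sites), n_pairs = length(coll$bs),
      delta = delta,
      auprc = mode$auprc,
      gain_hm = mode$gain_hm, gain_ss = mode$gain_ss, mode = mode$mode,
      nucleosome_shift_p = occupancy_shift_test(nuc_bs, nuc_non),
      nucleosome_bs_mean = mean(nuc_bs), nucleosome_nonbs_mean = mean(nuc_non))
    if (run_lofo) {
      res$lofo <- leave_one_feature_out(fm, cv_folds = st$cv_folds,
                                        cv_seed = st$cv_seed)
    }
    tf_results[[nm]] <- res
    sites_by_tf[[nm]] <- sites
  }

  cooc <- NULL
  if (length(sites_by_tf) >= 2L) {
    fams <- vapply(tf_results, `[[`, character(1), "family")
    pairs <- cooccupancy_pairs(sites_by_tf,
                               study$peaks[names(sites_by_tf)],
                               fams,
                               h3k4me3 = tracks$hm[["H3K4me3"]],
                               extend = st$proximity_extend,
                               flank = st$flank_len_hm)
    fam_p <- if (sum(pairs$same_family) >= 2L &&
                 sum(!pairs$same_family) >= 2L) {
      family_cooccupancy_test(pairs)
    } else NA_real_
    cooc <- list(pairs = pairs, family_test_p = fam_p)
  }

  manifest <- list(
    package = "hmtf",
    version = as.character(utils::packageVersion("hmtf")),
    seed = config$seed,
    n_tfs = length(config$tfs),
    n_analyzed = length(tf_results),
    n_rejected = length(rejections),
    settings = st[c("min_sites", "proximity_extend", "hm_gain_threshold",
                    "ss_gain_threshold", "summit_tol", "flank_len_hm",
                    "flank_len_seq", "n_marks_corrected", "cv_folds")],
    decisions = list(
      shape_attribution = "per flank position, all four features (step parameters attributed to the centered pentamer)",
      delta_definition = "(-log10 q_greater) - (-log10 q_less), Bonferroni family 2 x n_marks",
      matching_order = "greedy without replacement in BS coordinate order",
      hm_ratio_denominator = "symmetric pair mean"),
    stages = c("simulate", "scan", "match", "encode", "diff", "model",
               if (run_lofo) "lofo", "mode", "cooccupy", "nucleosome"))

  out <- structure(list(tf = tf_results, rejections = rejections,
                        cooccupancy = cooc, manifest = manifest,
                        config = config),
                   class = "hmtf_study_result")
  if (!is.null(out_dir)) write_study_result(out, out_dir)
  out
}

#' @export
print.hmtf_study_result <- function(x, ...) {
  cat("hmtf study:", length(x$tf), "TF(s) analyzed,",
      length(x$rejections), "rejected\n")
  for (r in x$tf) {
    cat(sprintf("  %s [%s]: %d sites, AUPRC ss=%.3f ss+hm=%.3f, mode %s\n",
                r$tf, r$family, r$n_sites, r$auprc[["seq_shape"]],
                r$auprc[["seq_shape_hm"]], r$mode))
  }
  invisible(x)
}

# Serialize a study result: one TSV per table + manifest.json.
write_study_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (length(result$tf)) {
    summary_df <- do.call(rbind, lapply(result$tf, function(r) {
      data.frame(tf = r$tf, family = r$family, n_sites = r$n_sites,
                 n_pairs = r$n_pairs,
                 auprc_seq_shape = r$auprc[["seq_shape"]],
                 auprc_hm_only = r$auprc[["hm_only"]],
                 auprc_seq_shape_hm = r$auprc[["seq_shape_hm"]],
                 gain_hm_pct = r$gain_hm, gain_ss_pct = r$gain_ss,
                 mode = r$mode, nucleosome_shift_p = r$nucleosome_shift_p)
    }))
    tsv(summary_df, "tf_summary.tsv")
    delta_df <- do.call(rbind, lapply(result$tf, function(r) {
      cbind(tf = r$tf, r$delta)
    }))
    tsv(delta_df, "delta.tsv")
    lofo_list <- Filter(Negate(is.null), lapply(result$tf, `[[`, "lofo"))
    if (length(lofo_list)) {
      lofo_df <- do.call(rbind, lapply(names(lofo_list), function(nm) {
        cbind(tf = nm, lofo_list[[nm]])
      }))
      tsv(lofo_df, "lofo.tsv")
    }
  }
  if (length(result$rejections)) {
    tsv(data.frame(tf = names(result$rejections),
                   reason = unlist(result$rejections)), "rejections.tsv")
  }
  if (!is.null(result$cooccupancy)) {
    tsv(result$cooccupancy$pairs, "cooccupancy.tsv")
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# Read a study configuration from YAML (or JSON) into a synth_config().
read_study_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$tfs)) stop("config must define a `tfs` list")
  tfs <- lapply(cfg$tfs, function(tf) {
    if (is.null(tf$name)) stop("each TF needs a `name`")
    args <- tf[intersect(names(tf),
                         names(formals(synth_tf)))]
    if (!is.null(tf$pfm)) args$pfm <- do.call(rbind, tf$pfm)
    do.call(synth_tf, args)
  })
  scalars <- intersect(names(cfg), setdiff(names(formals(synth_config)),
                                           "tfs"))
  do.call(synth_config, c(list(tfs = tfs), cfg[scalars]))
}
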