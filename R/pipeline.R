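# 32-bit FNV-1a hash of a canonical text rendering; used to fingerprint
# configurations in output provenance.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x, control = "all"),
                                      collapse = "\n")))
  mul32 <- function(a, b) {  # (a * b) mod 2^32 without losing precision
    lo <- a %% 65536; hi <- a %/% 65536
    (lo * b + ((hi * b) %% 65536) * 65536) %% 4294967296
  }
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- mul32(h, 16777619)
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis in one validated
#' object: the volume-ratio positivity threshold (5x), the roundness
#' cutoff (L/W 2), the relative margins of the per-subject TTP/WiR rules
#' (0.2), the arrival-detection threshold (3 pre-bolus sds), the
#' excluded-frame quality gate (0.4), the wash-in-rate source, the
#' confidence level (0.95) and the seed. Unknown keys are rejected by
#' the function signature itself; the object serialises losslessly via
#' its list representation.
#'
#' @param ratio_threshold volume-ratio positivity threshold.
#' @param shape_cutoff roundness cutoff on the length/width ratio.
#' @param rel_margin relative margin for the TTP and WiR score rules.
#' @param k_sd arrival-detection threshold in pre-bolus sds.
#' @param max_excluded_fraction CEUS quality gate.
#' @param wir_source `"fitted"` or `"raw"`.
#' @param confidence confidence level for exact intervals.
#' @param seed integer seed for any stochastic stage.
#' @return An object of class `pipeline_config` with a `config_hash`
#'   attribute.
#' @export
pipeline_config <- function(ratio_threshold = 5, shape_cutoff = 2,
                            rel_margin = 0.2, k_sd = 3,
                            max_excluded_fraction = 0.4,
                            wir_source = c("fitted", "raw"),
                            confidence = 0.95, seed = 1L) {
  wir_source <- match.arg(wir_source)
  if (ratio_threshold <= 0 || shape_cutoff <= 1 || rel_margin < 0 ||
      k_sd <= 0 || max_excluded_fraction < 0 || max_excluded_fraction > 1 ||
      confidence <= 0 || confidence >= 1)
    abort_invalid("invalid pipeline configuration values")
  cfg <- list(ratio_threshold = ratio_threshold, shape_cutoff = shape_cutoff,
              rel_margin = rel_margin, k_sd = k_sd,
              max_excluded_fraction = max_excluded_fraction,
              wir_source = wir_source, confidence = confidence,
              seed = as.integer(seed))
  structure(cfg, class = "pipeline_config", config_hash = fnv1a32(cfg))
}

#' Run the full analysis pipeline on a cohort
#'
#' Orchestrates the stages in order: morphometry of every contour stack,
#' perfusion analysis of every TIC, per-subject score cards from the
#' paired left/right records, cohort-level paired t-tests (volume, L/W
#' ratio, TTP, WiR; left vs right), and diagnostic evaluation of the left
#' (tumor-draining) nodes against pathology. Deterministic given the
#' cohort and configuration.
#'
#' @param cohort a cohort from [generate_cohort()] or [load_cohort()].
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, all tables are written
#'   as CSV together with a `provenance.dcf` carrying the package
#'   version, timestamp and config hash.
#' @return list with `morphometry` (data.frame per node), `perfusion`
#'   (data.frame per node), `scorecards` (data.frame per subject, plus
#'   list in attribute `"cards"`), `group_tests`, `performance`
#'   (see [report_performance()]), `config` and `config_hash`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(cohort) == 0L) abort_empty_eval("empty cohort")

  morpho <- list(); perf <- list(); cards <- list()
  for (subj in cohort) {
    recs <- list()
    for (side in c("left", "right")) {
      node <- subj[[side]]
      m <- measure_stack(node$contours)
      morpho[[length(morpho) + 1L]] <- data.frame(
        subject_id = subj$subject_id, side = side, node_id = node$node_id,
        volume_mm3 = m$volume_mm3, length_mm = m$length_mm,
        width_mm = m$width_mm, lw_ratio = m$lw_ratio, is_round = m$is_round,
        stringsAsFactors = FALSE)
      p <- NULL
      if (!is.null(node$tic)) {
        p <- analyze_tic(node$tic, k_sd = config$k_sd,
                         max_excluded_fraction = config$max_excluded_fraction,
                         wir_source = config$wir_source)
        perf[[length(perf) + 1L]] <- data.frame(
          subject_id = subj$subject_id, side = side, node_id = node$node_id,
          t_arrival_s = p$t_arrival_s, ttp_s = p$ttp_s,
          wir_au_per_s = p$wir_au_per_s,
          peak_enhancement_au = p$peak_enhancement_au,
          fit_rmse = p$fit_rmse, usable = p$usable,
          excluded_fraction = p$excluded_fraction,
          stringsAsFactors = FALSE)
      }
      recs[[side]] <- ln_record(node$node_id, subj$subject_id, side,
                                m, p, node$hilum_visible)
    }
    cards[[subj$subject_id]] <- build_scorecard(
      recs$left, recs$right, ratio_threshold = config$ratio_threshold,
      shape_cutoff = config$shape_cutoff, rel_margin = config$rel_margin)
  }
  morpho <- do.call(rbind, morpho)
  perf <- if (length(perf)) do.call(rbind, perf) else NULL

  card_df <- do.call(rbind, lapply(cards, function(cc) data.frame(
    subject_id = cc$subject_id,
    volume = cc$scores["volume"], shape = cc$scores["shape"],
    hilum = cc$scores["hilum"], ttp = cc$scores["ttp"],
    wir = cc$scores["wir"], available = cc$available_count,
    sum_score = cc$sum_score, sum_percent = cc$sum_percent_display,
    stringsAsFactors = FALSE, row.names = NULL)))
  attr(card_df, "cards") <- cards

  paired <- function(metric, tab) {
    ids <- unique(tab$subject_id)
    l <- tab[[metric]][match(paste(ids, "left"), paste(tab$subject_id, tab$side))]
    r <- tab[[metric]][match(paste(ids, "right"), paste(tab$subject_id, tab$side))]
    tryCatch(group_paired_ttest(l, r), lnscore_error = function(e) NULL)
  }
  group_tests <- list(
    volume = paired("volume_mm3", morpho),
    lw_ratio = paired("lw_ratio", morpho),
    ttp = if (!is.null(perf)) paired("ttp_s", perf[perf$usable, ]) else NULL,
    wir = if (!is.null(perf)) paired("wir_au_per_s", perf[perf$usable, ]) else NULL)

  pathology <- vapply(cohort, function(s) s$pathology_positive_left, logical(1))
  names(pathology) <- vapply(cohort, function(s) s$subject_id, character(1))
  performance <- report_performance(cards, pathology,
                                    confidence = config$confidence)

  out <- list(morphometry = morpho, perfusion = perf, scorecards = card_df,
              group_tests = group_tests, performance = performance,
              config = config, config_hash = attr(config, "config_hash"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(morpho, file.path(out_dir, "morphometry.csv"),
                     row.names = FALSE)
    if (!is.null(perf))
      utils::write.csv(perf, file.path(out_dir, "perfusion.csv"),
                       row.names = FALSE)
    utils::write.csv(card_df, file.path(out_dir, "scorecards.csv"),
                     row.names = FALSE)
    utils::write.csv(performance, file.path(out_dir, "performance.csv"),
                     row.names = FALSE)
    write.dcf(data.frame(
      package = "lnscore",
      version = as.character(utils::packageVersion("lnscore")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config_hash = out$config_hash), file.path(out_dir, "provenance.dcf"))
  }
  out
}
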