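#' Paired lymph-node record
#'
#' Bundles one node's measurements: morphometry, perfusion parameters
#' (possibly absent or unusable) and the observed hilum-visibility flag.
#'
#' @param node_id,subject_id identifiers.
#' @param side `"left"` (tumor-draining) or `"right"` (control).
#' @param morphometry an `ln_morphometry` (see [measure_stack()]).
#' @param perfusion a `perfusion_params` (see [analyze_tic()]) or `NULL`
#'   when no CEUS acquisition exists.
#' @param hilum_visible logical: was an echogenic hilum detected.
#' @return An object of class `ln_record`.
#' @export
ln_record <- function(node_id, subject_id, side = c("left", "right"),
                      morphometry, perfusion = NULL, hilum_visible = TRUE) {
  side <- match.arg(side)
  stopifnot(inherits(morphometry, "ln_morphometry"))
  if (!is.null(perfusion)) stopifnot(inherits(perfusion, "perfusion_params"))
  structure(
    list(node_id = node_id, subject_id = subject_id, side = side,
         morphometry = morphometry, perfusion = perfusion,
         hilum_visible = isTRUE(hilum_visible)),
    class = "ln_record"
  )
}

#' Binary volume score
#'
#' A left node at least `ratio_threshold` times (default 5x, inclusive)
#' larger than its paired right control scores 1.
#'
#' @param left_vol,right_vol node volumes (mm^3), positive.
#' @param ratio_threshold positivity threshold on the left/right ratio.
#' @return 0 or 1.
#' @export
score_volume <- function(left_vol, right_vol, ratio_threshold = 5) {
  as.integer(volume_ratio(left_vol, right_vol) >= ratio_threshold)
}

#' Binary shape score
#'
#' A round node (length/width ratio strictly below 2) scores 1;
#' elongated nodes (ratio >= 2) score 0.
#'
#' @param lw_ratio length/width ratio (>= 1).
#' @param cutoff roundness cutoff (default 2).
#' @return 0 or 1.
#' @export
score_shape <- function(lw_ratio, cutoff = 2) {
  if (!is.finite(lw_ratio) || lw_ratio < 1)
    abort_invalid("`lw_ratio` must be finite and >= 1")
  as.integer(lw_ratio < cutoff)
}

#' Binary hilum score
#'
#' Loss of the echogenic hilum scores 1; a detected hilum scores 0.
#'
#' @param hilum_visible logical.
#' @return 0 or 1.
#' @export
score_hilum <- function(hilum_visible) {
  as.integer(!isTRUE(hilum_visible))
}

#' Binary time-to-peak score
#'
#' A left-node TTP exceeding the right-node TTP by more than the relative
#' margin (default 20%) scores 1. With a single measurement per node a
#' within-animal significance test is impossible; the margin rule is the
#' package's operational stand-in for "significantly increased", with the
#' group-level paired t-test reported separately
#' (see [group_paired_ttest()]).
#'
#' @param left_ttp,right_ttp TTP values (s), or `NA` when unusable.
#' @param rel_margin relative margin (default 0.2).
#' @return 0, 1, or `NA` (unavailable) when either side is unusable.
#' @export
score_ttp <- function(left_ttp, right_ttp, rel_margin = 0.2) {
  if (is.na(left_ttp) || is.na(right_ttp)) return(NA_integer_)
  as.integer(left_ttp > right_ttp * (1 + rel_margin))
}

#' Binary wash-in-rate score
#'
#' A left-node WiR below the right-node WiR by more than the relative
#' margin (default 20%) scores 1 (hypoperfusion of the involved node);
#' see [score_ttp()] for the rationale of the margin rule.
#'
#' @param left_wir,right_wir WiR values (a.u./s), or `NA` when unusable.
#' @param rel_margin relative margin (default 0.2).
#' @return 0, 1, or `NA` (unavailable).
#' @export
score_wir <- function(left_wir, right_wir, rel_margin = 0.2) {
  if (is.na(left_wir) || is.na(right_wir)) return(NA_integer_)
  as.integer(left_wir < right_wir * (1 - rel_margin))
}

#' Score card from five parameter scores
#'
#' Assembles the five 0/1 parameter scores (with `NA` for unavailable
#' perfusion parameters) into a sum score. Unavailable parameters shrink
#' the denominator rather than imputing 0, so a subject with only the
#' three morphometric parameters evaluable can still reach 3/3 = 100%.
#'
#' @param subject_id identifier.
#' @param volume,shape,hilum,ttp,wir each 0, 1 or `NA`.
#' @return An object of class `score_card`: list with `subject_id`,
#'   `scores` (named integer vector with `NA` = unavailable),
#'   `available_count`, `sum_score`, `sum_percent` (exact), and
#'   `sum_percent_display` (rounded to nearest integer, half away from
#'   zero).
#' @export
scorecard_from_scores <- function(subject_id, volume, shape, hilum, ttp, wir) {
  scores <- c(volume = unname(volume), shape = unname(shape),
              hilum = unname(hilum), ttp = unname(ttp), wir = unname(wir))
  scores <- vapply(scores, function(s) {
    if (is.na(s)) return(NA_integer_)
    if (!s %in% c(0L, 1L, 0, 1)) abort_invalid("scores must be 0, 1 or NA")
    as.integer(s)
  }, integer(1))
  if (is.na(scores["ttp"]) != is.na(scores["wir"]))
    abort_invalid("ttp and wir must be unavailable together (one CEUS analysis per node pair)")
  avail <- sum(!is.na(scores))
  if (avail < 1L) abort_invalid("at least one parameter must be available")
  s <- sum(scores, na.rm = TRUE)
  pct <- 100 * s / avail
  structure(
    list(subject_id = subject_id, scores = scores,
         available_count = avail, sum_score = s, sum_percent = pct,
         sum_percent_display = round_half_up(pct)),
    class = "score_card"
  )
}

#' @export
print.score_card <- function(x, ...) {
  sc <- ifelse(is.na(x$scores), "N/A", x$scores)
  cat(sprintf("<score_card> %s: [%s] sum %d/%d (%g%%)\n", x$subject_id,
              paste(names(x$scores), sc, sep = "=", collapse = " "),
              x$sum_score, x$available_count, x$sum_percent_display))
  invisible(x)
}

#' Build the score card for one subject
#'
#' Applies the five binary scoring rules to a subject's paired left/right
#' records: volume ratio >= 5x, left-node roundness (L/W < 2), hilum loss,
#' lengthened TTP and reduced WiR relative to the control node. TTP and
#' WiR are marked unavailable together whenever either side's perfusion
#' analysis is missing or unusable.
#'
#' @param left,right [ln_record()]s for the same subject.
#' @param ratio_threshold volume-ratio positivity threshold (default 5).
#' @param shape_cutoff roundness cutoff (default 2).
#' @param rel_margin relative margin for the TTP and WiR rules
#'   (default 0.2).
#' @return A `score_card` (see [scorecard_from_scores()]).
#' @export
build_scorecard <- function(left, right, ratio_threshold = 5,
                            shape_cutoff = 2, rel_margin = 0.2) {
  stopifnot(inherits(left, "ln_record"), inherits(right, "ln_record"))
  if (left$side != "left" || right$side != "right" ||
      !identical(left$subject_id, right$subject_id))
    abort_pairing("need a left and a right record of the same subject")
  usable <- function(p) !is.null(p) && isTRUE(p$usable)
  perf_ok <- usable(left$perfusion) && usable(right$perfusion)
  scorecard_from_scores(
    left$subject_id,
    volume = score_volume(left$morphometry$volume_mm3,
                          right$morphometry$volume_mm3, ratio_threshold),
    shape = score_shape(left$morphometry$lw_ratio, shape_cutoff),
    hilum = score_hilum(left$hilum_visible),
    ttp = if (perf_ok)
      score_ttp(left$perfusion$ttp_s, right$perfusion$ttp_s, rel_margin)
      else NA_integer_,
    wir = if (perf_ok)
      score_wir(left$perfusion$wir_au_per_s, right$perfusion$wir_au_per_s,
                rel_margin)
      else NA_integer_
  )
}

#' Group-level paired t-test
#'
#' Two-sided paired t-test comparing left (tumor-draining) against right
#' (control) node values across subjects, reported alongside the
#' per-subject scores at cohort level; it does not gate any individual
#' score.
#'
#' @param left_values,right_values equal-length paired numeric vectors
#'   (n >= 2, pairs with `NA` on either side are dropped).
#' @return list with `t_statistic`, `p_value`, `df`, `mean_difference`.
#' @export
group_paired_ttest <- function(left_values, right_values) {
  if (length(left_values) != length(right_values))
    abort_invalid("paired samples must have equal length")
  keep <- !is.na(left_values) & !is.na(right_values)
  l <- left_values[keep]; r <- right_values[keep]
  if (length(l) < 2L) abort_invalid("need at least 2 complete pairs")
  if (stats::sd(l - r) == 0)
    abort_degenerate_test("differences have zero variance; paired t-test undefined")
  ht <- stats::t.test(l, r, paired = TRUE)
  list(t_statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), mean_difference = unname(ht$estimate))
}
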