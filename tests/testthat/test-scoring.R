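test_that("volume score uses an inclusive 5x ratio threshold", {
  expect_equal(score_volume(12.0, 1.4), 1L)
  expect_equal(score_volume(2.5, 2.5), 0L)
  expect_equal(score_volume(5.0, 1.0), 1L)        # boundary: >= is inclusive
  expect_equal(score_volume(4.999, 1.0), 0L)
  expect_error(score_volume(-1, 1), class = "lnscore_invalid_input")
})

test_that("shape score uses a strict roundness cutoff at L/W = 2", {
  expect_equal(score_shape(1.621), 1L)
  expect_equal(score_shape(2.432), 0L)
  expect_equal(score_shape(1.901), 1L)
  expect_equal(score_shape(2), 0L)                # exactly 2 is non-round
  expect_error(score_shape(0.5), class = "lnscore_invalid_input")
})

test_that("hilum score marks hilum loss as positive", {
  expect_equal(score_hilum(TRUE), 0L)
  expect_equal(score_hilum(FALSE), 1L)
})

test_that("TTP and WiR scores apply the relative-margin rule with NA propagation", {
  expect_equal(score_ttp(4.01, 1.93), 1L)
  expect_equal(score_ttp(2.0, 2.0), 0L)
  expect_equal(score_ttp(2.4, 2.0), 0L)           # exactly at the 20% margin
  expect_equal(score_ttp(2.41, 2.0), 1L)
  expect_true(is.na(score_ttp(4.0, NA)))

  expect_equal(score_wir(0.5, 2.0), 1L)
  expect_equal(score_wir(3.0, 2.0), 0L)           # more perfused left node
  expect_equal(score_wir(2.0, 2.0), 0L)
  expect_equal(score_wir(1.6, 2.0), 0L)           # exactly at the margin
  expect_true(is.na(score_wir(NA, 2.0)))
})

test_that("score cards sum available parameters with a shrinking denominator", {
  full <- scorecard_from_scores("s", 1, 1, 1, 1, 1)
  expect_equal(full$sum_score, 5L)
  expect_equal(full$sum_percent, 100)

  four <- scorecard_from_scores("s", 1, 1, 1, 1, 0)
  expect_equal(four$sum_percent, 80)

  three <- scorecard_from_scores("s", 1, 1, 1, NA, NA)
  expect_equal(three$available_count, 3L)
  expect_equal(three$sum_score, 3L)
  expect_equal(three$sum_percent, 100)

  one_third <- scorecard_from_scores("s", 1, 0, 0, NA, NA)
  expect_equal(one_third$sum_percent, 100 / 3)
  expect_equal(one_third$sum_percent_display, 33)

  expect_error(scorecard_from_scores("s", 1, 1, 1, NA, 0),
               class = "lnscore_invalid_input")   # ttp/wir NA only together
  expect_error(scorecard_from_scores("s", 2, 1, 1, 1, 1),
               class = "lnscore_invalid_input")
})

test_that("sum percent takes the expected values and is monotone in single-score flips", {
  pcts5 <- sapply(0:31, function(mask) {
    bits <- as.integer(intToBits(mask)[1:5])
    scorecard_from_scores("s", bits[1], bits[2], bits[3], bits[4],
                          bits[5])$sum_percent
  })
  expect_true(all(pcts5 %in% c(0, 20, 40, 60, 80, 100)))

  set.seed(42)
  for (rep in 1:25) {
    bits <- sample(0:1, 5, replace = TRUE)
    zeros <- which(bits == 0)
    if (length(zeros) == 0) next
    base <- scorecard_from_scores("s", bits[1], bits[2], bits[3], bits[4],
                                  bits[5])$sum_percent
    i <- zeros[sample.int(length(zeros), 1)]
    flipped <- bits; flipped[i] <- 1
    up <- scorecard_from_scores("s", flipped[1], flipped[2], flipped[3],
                                flipped[4], flipped[5])$sum_percent
    expect_gte(up, base)
  }
})

test_that("build_scorecard wires paired records through all five rules", {
  morph <- function(vol, lw) structure(
    list(node_id = "n", volume_mm3 = vol, length_mm = lw, width_mm = 1,
         lw_ratio = lw, is_round = lw < 2, length_slice_index = 0L),
    class = "ln_morphometry")
  perf <- function(ttp, wir, usable = TRUE) structure(
    list(node_id = "n", t_arrival_s = 5, t_peak_s = 5 + ttp, ttp_s = ttp,
         wir_au_per_s = wir, peak_enhancement_au = 3, baseline_au = 1,
         fit_rmse = 0, usable = usable, excluded_fraction = 0),
    class = "perfusion_params")

  left <- ln_record("L", "m", "left", morph(12, 1.6), perf(4.0, 0.5), FALSE)
  right <- ln_record("R", "m", "right", morph(1.4, 2.4), perf(1.9, 2.0), TRUE)
  card <- build_scorecard(left, right)
  expect_equal(unname(card$scores), c(1L, 1L, 1L, 1L, 1L))
  expect_equal(card$sum_percent, 100)

  # unusable right-node perfusion makes both CEUS scores unavailable
  right_bad <- ln_record("R", "m", "right", morph(1.4, 2.4),
                         perf(NA, NA, usable = FALSE), TRUE)
  card3 <- build_scorecard(left, right_bad)
  expect_true(all(is.na(card3$scores[c("ttp", "wir")])))
  expect_equal(card3$available_count, 3L)
  expect_equal(card3$sum_percent, 100)

  # absent perfusion record behaves like unusable
  card_np <- build_scorecard(
    ln_record("L", "m", "left", morph(12, 1.6), NULL, FALSE), right)
  expect_equal(card_np$available_count, 3L)

  expect_error(build_scorecard(left, left), class = "lnscore_pairing_error")
  wrong_subj <- ln_record("R", "other", "right", morph(1.4, 2.4), NULL, TRUE)
  expect_error(build_scorecard(left, wrong_subj),
               class = "lnscore_pairing_error")
})

test_that("the paired t-test matches the closed form and rejects degenerate input", {
  l <- c(5.1, 6.3, 4.8, 7.2, 5.9)
  r <- c(4.2, 5.1, 4.9, 6.0, 5.2)
  d <- l - r
  res <- group_paired_ttest(l, r)
  expect_equal(res$t_statistic, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(res$p_value,
               2 * pt(-abs(mean(d) / (sd(d) / sqrt(5))), df = 4),
               tolerance = 1e-12)
  expect_error(group_paired_ttest(l, l), class = "lnscore_degenerate_test")
  expect_error(group_paired_ttest(1, 2), class = "lnscore_invalid_input")
})

test_that("the paired t-test holds its nominal type-I error under the null", {
  set.seed(99)
  reps <- 2000
  p <- vapply(seq_len(reps), function(i) {
    l <- rnorm(12); r <- l + rnorm(12)   # paired, no shift
    group_paired_ttest(l, r)$p_value
  }, numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.015)
})
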