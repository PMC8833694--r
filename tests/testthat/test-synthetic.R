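test_that("ellipsoid contour generation is deterministic under the seed", {
  a <- generate_ellipsoid_contours(c(2.0, 1.0, 0.8), 0.038, seed = 7)
  b <- generate_ellipsoid_contours(c(2.0, 1.0, 0.8), 0.038, seed = 7)
  expect_identical(a, b)
  c <- generate_ellipsoid_contours(c(2.0, 1.0, 0.8), 0.038, seed = 8)
  expect_false(identical(a, c))
})

test_that("ellipsoid generator validates its inputs", {
  expect_error(generate_ellipsoid_contours(c(1, 1, 0.05), 0.038, seed = 1),
               class = "lnscore_invalid_spec")      # spacing >= smallest axis
  expect_error(generate_ellipsoid_contours(c(1, 1, 1), 0.8, seed = 1),
               class = "lnscore_invalid_spec")      # < 3 slices
  expect_error(generate_ellipsoid_contours(c(1, 1, 1), 0.038, n_vertices = 4,
                                           seed = 1),
               class = "lnscore_invalid_spec")
})

test_that("hilum indent removes area but keeps slices simple and measurable", {
  plain <- generate_ellipsoid_contours(c(1.5, 1.0, 0.8), 0.05, seed = 9,
                                       jitter_sd = 0)
  dented <- generate_ellipsoid_contours(c(1.5, 1.0, 0.8), 0.05, seed = 9,
                                        jitter_sd = 0, hilum_indent = TRUE)
  expect_lt(volume_from_stack(dented), volume_from_stack(plain))
  expect_s3_class(measure_stack(dented), "ln_morphometry")
})

test_that("synthetic TIC has its argmax at the lognormal mode and honours amplitude 0", {
  tic <- generate_tic(5, 0, 0.5, 10, 1, 20, 1000, noise_sd = 0,
                      excluded_fraction = 0, seed = 1)
  t_mode <- tic$time_s[which.max(tic$intensity)]
  expect_lt(abs(t_mode - (5 + exp(0 - 0.25))), 1 / 20 + 1e-9)

  flat <- generate_tic(5, 0, 0.5, 0, 2.5, 20, 200, noise_sd = 0,
                       excluded_fraction = 0, seed = 1)
  expect_true(all(flat$intensity == 2.5))
})

test_that("fitted TTP recovers the analytic lognormal mode from a generated curve", {
  tic <- generate_tic(5, 0, 0.5, 10, 1, 20, 1000, noise_sd = 0,
                      excluded_fraction = 0, seed = 1)
  p <- analyze_tic(tic)
  expect_true(p$usable)
  expect_lt(abs(p$ttp_s - exp(0 - 0.25)) / exp(0 - 0.25), 0.05)
  # dense numerical argmax of the model as an independent check
  tt <- seq(5, 15, by = 1e-4)
  dense_mode <- tt[which.max(dlnorm(tt - 5, 0, 0.5))] - 5
  expect_equal(exp(0 - 0.25), dense_mode, tolerance = 1e-3)
})

test_that("the default cohort has the study composition with one unusable CEUS node", {
  coh <- generate_cohort(small_spec(seed = 3))
  expect_length(coh, 8L)
  nodes <- unlist(lapply(coh, function(s) list(s$left, s$right)),
                  recursive = FALSE)
  expect_length(nodes, 16L)
  excl <- vapply(nodes, function(n) mean(n$tic$excluded), numeric(1))
  expect_equal(sum(excl > 0.4), 1L)
  # groups: 5 tumor-injected (incl. the two archetypes), 3 control-injected
  grp <- vapply(coh, function(s) s$group, character(1))
  expect_equal(sum(grp == "tumor_injected"), 5L)
  expect_equal(sum(grp == "control_injected"), 3L)
  # pathology: positive only in non-archetype tumor lefts and X5
  path <- vapply(coh, function(s) s$pathology_positive_left, logical(1))
  names(path) <- vapply(coh, function(s) s$subject_id, character(1))
  expect_false(path[["X4"]])
  expect_true(path[["X5"]])
  expect_false(any(vapply(coh, function(s) s$pathology_positive_right,
                          logical(1))))
})

test_that("cohort generation is deterministic and empty specs give empty cohorts", {
  s <- small_spec(seed = 21)
  expect_identical(generate_cohort(s), generate_cohort(s))
  expect_false(identical(generate_cohort(s),
                         generate_cohort(small_spec(seed = 22))))
  empty <- cohort_spec(n_tumor_subjects = 0L, n_control_subjects = 0L,
                       include_missing_ceus_subject = FALSE,
                       include_imaging_pos_path_neg_subject = FALSE)
  expect_length(generate_cohort(empty), 0L)
})

test_that("mean left/right volume ratio of involved nodes tracks the target", {
  s <- small_spec(n_tumor_subjects = 20L, n_control_subjects = 0L,
                  include_missing_ceus_subject = FALSE,
                  include_imaging_pos_path_neg_subject = FALSE,
                  seed = 14)
  coh <- generate_cohort(s)
  ratios <- vapply(coh, function(su)
    su$left$truth$volume_mm3 / su$right$truth$volume_mm3, numeric(1))
  expect_lt(abs(mean(ratios) - s$volume_ratio_involved) /
              s$volume_ratio_involved, 0.15)
})

test_that("generated stacks re-measured by the morphometry module recover the latent truth", {
  s <- small_spec(n_tumor_subjects = 2L, n_control_subjects = 1L,
                  contour_vertices = 96L, slice_spacing_mm = 0.038,
                  seed = 5)
  coh <- generate_cohort(s)
  for (su in coh) {
    for (side in c("left", "right")) {
      node <- su[[side]]
      m <- measure_stack(node$contours)
      if (node$hilum_visible) {
        # the hilar indent removes a little volume and narrows the width,
        # so the measured values sit near but not on the latent ellipsoid
        expect_lt(abs(m$volume_mm3 - node$truth$volume_mm3) /
                    node$truth$volume_mm3, 0.05)
        expect_gt(m$lw_ratio, 0.98 * node$truth$lw_ratio)
        expect_lt(m$lw_ratio, 1.15 * node$truth$lw_ratio)
      } else {
        expect_lt(abs(m$volume_mm3 - node$truth$volume_mm3) /
                    node$truth$volume_mm3, 0.01)
        expect_lt(abs(m$lw_ratio - node$truth$lw_ratio) /
                    node$truth$lw_ratio, 0.02)
      }
    }
  }
})

test_that("cohort spec validation rejects impossible designs", {
  expect_error(cohort_spec(n_tumor_subjects = -1), class = "lnscore_invalid_spec")
  expect_error(cohort_spec(hilum_loss_prob_involved = 1.5),
               class = "lnscore_invalid_spec")
  expect_error(cohort_spec(slice_spacing_mm = 0), class = "lnscore_invalid_spec")
  expect_error(generate_cohort(cohort_spec(n_tumor_subjects = 1L)),
               class = "lnscore_invalid_spec")  # 2 archetypes need 2 slots
})
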