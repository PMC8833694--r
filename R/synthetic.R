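# Evaluate `expr` under a fixed RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic paired-design cohort
#'
#' Collects the study-design parameters of the synthetic cohort: group
#' sizes, target effect sizes for involved vs control nodes, acquisition
#' settings and the master seed. Defaults are the endpoint group-level
#' values of the mouse study the generator emulates: involved left nodes
#' on average 9.92 times larger than their paired right controls, round
#' (length/width 1.621 +/- 0.181) against elongated controls
#' (2.432 +/- 0.166), hilum lost, time-to-peak 4.01 +/- 1.26 s against
#' 1.93 +/- 0.77 s, and a reduced wash-in rate; slices every 0.038 mm and
#' 1000-frame cine loops.
#'
#' @param n_tumor_subjects,n_control_subjects group sizes.
#' @param volume_ratio_involved target mean left/right volume ratio for
#'   involved nodes.
#' @param shape_ratio_involved,shape_ratio_control mean length/width ratios.
#' @param hilum_loss_prob_involved probability an involved node loses its
#'   sonographic hilum.
#' @param ttp_involved_s,ttp_control_s mean time-to-peak (s).
#' @param ttp_sd_involved_s,ttp_sd_control_s between-animal TTP sds (s).
#' @param wir_involved,wir_control mean wash-in rates (a.u./s).
#' @param noise_sd additive Gaussian intensity noise sd (a.u.).
#' @param slice_spacing_mm elevational motor step (mm).
#' @param frame_rate_hz,n_frames CEUS cine-loop sampling.
#' @param right_volume_mm3 mean control (right) node volume (mm^3).
#' @param volume_sdlog,ratio_sdlog lognormal sds of node volume and of the
#'   left/right ratio around its target.
#' @param shape_sd_involved,shape_sd_control between-animal L/W-ratio sds.
#' @param wir_sdlog lognormal sd of per-node wash-in rate.
#' @param sigma_bolus lognormal bolus width parameter (dimensionless).
#' @param baseline_au pre-bolus baseline intensity (a.u.).
#' @param routine_excluded_fraction fraction of frames lost to motion in a
#'   normal acquisition.
#' @param unusable_excluded_fraction excluded fraction for the
#'   missing-CEUS analogue node (above the 0.4 quality gate).
#' @param contour_vertices polygon vertices per slice.
#' @param include_missing_ceus_subject append a tumor subject whose control
#'   node's CEUS is unusable (perfusion scores unavailable).
#' @param include_imaging_pos_path_neg_subject append a subject with the
#'   full imaging-involved phenotype except a raised wash-in rate, and
#'   negative pathology.
#' @param seed master integer seed; the entire cohort is a deterministic
#'   function of the spec including this seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_tumor_subjects = 5L,
                        n_control_subjects = 3L,
                        volume_ratio_involved = 9.92,
                        shape_ratio_involved = 1.621,
                        shape_ratio_control = 2.432,
                        hilum_loss_prob_involved = 1.0,
                        ttp_involved_s = 4.01,
                        ttp_control_s = 1.93,
                        ttp_sd_involved_s = 1.26,
                        ttp_sd_control_s = 0.77,
                        wir_involved = 0.5,
                        wir_control = 2.0,
                        noise_sd = 0.05,
                        slice_spacing_mm = 0.038,
                        frame_rate_hz = 20,
                        n_frames = 1000L,
                        right_volume_mm3 = 1.44,
                        volume_sdlog = 0.25,
                        ratio_sdlog = 0.15,
                        shape_sd_involved = 0.181,
                        shape_sd_control = 0.166,
                        wir_sdlog = 0.3,
                        sigma_bolus = 0.5,
                        baseline_au = 1.0,
                        routine_excluded_fraction = 0.05,
                        unusable_excluded_fraction = 0.6,
                        contour_vertices = 96L,
                        include_missing_ceus_subject = TRUE,
                        include_imaging_pos_path_neg_subject = TRUE,
                        seed = 1L) {
  spec <- as.list(environment())
  counts <- c(spec$n_tumor_subjects, spec$n_control_subjects,
              spec$n_frames, spec$contour_vertices)
  if (any(counts < 0) || any(counts != floor(counts)))
    abort_spec("counts must be non-negative integers")
  probs <- c(spec$hilum_loss_prob_involved, spec$routine_excluded_fraction,
             spec$unusable_excluded_fraction)
  if (any(probs < 0 | probs > 1))
    abort_spec("probabilities must lie in [0, 1]")
  pos <- c(spec$volume_ratio_involved, spec$shape_ratio_involved,
           spec$shape_ratio_control, spec$ttp_involved_s, spec$ttp_control_s,
           spec$wir_involved, spec$wir_control, spec$slice_spacing_mm,
           spec$frame_rate_hz, spec$right_volume_mm3, spec$sigma_bolus)
  if (any(pos <= 0))
    abort_spec("effect sizes, spacing, rates and volumes must be positive")
  if (spec$noise_sd < 0) abort_spec("noise_sd must be non-negative")
  structure(spec, class = "cohort_spec")
}

#' Ellipsoid contour stack
#'
#' Slices an axis-aligned ellipsoid perpendicular to its third semiaxis
#' (the elevational/probe-translation axis) at a uniform step, producing
#' one simple closed polygon per slice at the slab midplane. A small
#' seeded multiplicative radial jitter mimics manual ROI tracing; when
#' `hilum_indent` is set, a wedge-shaped concavity is carved into one
#' side of the central slices to model the hilar depression.
#'
#' @param semiaxes_mm positive numeric triple (a, b, c) in mm; c is the
#'   slicing axis.
#' @param spacing_mm slice spacing (mm), smaller than the smallest
#'   semiaxis and fine enough to yield at least 3 slices.
#' @param n_vertices vertices per slice polygon (>= 8).
#' @param hilum_indent carve a hilar indent into the central slices.
#' @param seed integer seed for the tracing jitter.
#' @param jitter_sd multiplicative radial jitter sd (0 disables).
#' @param node_id identifier for the resulting stack.
#' @return A [contour_stack()].
#' @export
generate_ellipsoid_contours <- function(semiaxes_mm, spacing_mm,
                                        n_vertices = 96L,
                                        hilum_indent = FALSE, seed = 1L,
                                        jitter_sd = 0.002,
                                        node_id = "ellipsoid") {
  if (length(semiaxes_mm) != 3L || any(semiaxes_mm <= 0))
    abort_spec("`semiaxes_mm` must be three positive numbers")
  if (n_vertices < 8L) abort_spec("`n_vertices` must be at least 8")
  if (spacing_mm >= min(semiaxes_mm))
    abort_spec("`spacing_mm` must be smaller than the smallest semiaxis")
  a <- semiaxes_mm[1]; b <- semiaxes_mm[2]; c <- semiaxes_mm[3]
  n_slices <- floor(2 * c / spacing_mm)
  if (n_slices < 3L)
    abort_spec("spacing too coarse: fewer than 3 slices through the ellipsoid")
  theta <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  z <- -c + (seq_len(n_slices) - 0.5) * spacing_mm
  with_seed(seed, {
    slices <- lapply(seq_len(n_slices), function(k) {
      s <- sqrt(pmax(1 - (z[k] / c)^2, 0))
      r <- rep(1, n_vertices)
      if (jitter_sd > 0) r <- r * exp(stats::rnorm(n_vertices, 0, jitter_sd))
      if (hilum_indent) {
        # indent centred on theta = pi/2 (one long side of the node, the
        # usual hilar position), deepest at the equatorial slices
        central <- pmax(1 - abs(z[k]) / (c / 2), 0)
        ang <- abs(theta - pi / 2)
        wedge <- pmax(1 - ang / 0.6, 0)         # ~34 degree half-width
        r <- r * (1 - 0.35 * central * wedge)
      }
      cbind(a * s * r * cos(theta), b * s * r * sin(theta))
    })
    contour_stack(slices, spacing_mm = spacing_mm, node_id = node_id)
  })
}

#' Synthetic bolus time-intensity curve
#'
#' Generates `intensity(t) = baseline + amplitude * dlnorm(t - t_arrival;
#' mu, sigma)` sampled at `frame_rate_hz` for `n_frames` frames, with
#' additive iid Gaussian noise and a uniformly random set of frames
#' flagged as motion-excluded.
#'
#' @param t_arrival_s contrast arrival time (s).
#' @param mu,sigma lognormal bolus parameters (mode at
#'   `exp(mu - sigma^2)` s after arrival).
#' @param amplitude bolus scale (a.u. x s; peak enhancement is
#'   `amplitude * dlnorm(mode)`).
#' @param baseline pre-bolus intensity (a.u.).
#' @param frame_rate_hz,n_frames sampling grid (`n_frames >= 50`).
#' @param noise_sd additive Gaussian noise sd (a.u.).
#' @param excluded_fraction fraction of frames flagged excluded.
#' @param seed integer seed.
#' @param node_id identifier.
#' @return A [time_intensity_curve()].
#' @export
generate_tic <- function(t_arrival_s, mu, sigma, amplitude, baseline,
                         frame_rate_hz, n_frames, noise_sd = 0,
                         excluded_fraction = 0, seed = 1L,
                         node_id = "tic") {
  if (n_frames < 50L) abort_spec("`n_frames` must be at least 50")
  if (sigma <= 0 || amplitude < 0 || baseline < 0 || t_arrival_s < 0 ||
      frame_rate_hz <= 0 || noise_sd < 0 ||
      excluded_fraction < 0 || excluded_fraction > 1)
    abort_spec("invalid TIC generator parameters")
  t <- (seq_len(n_frames) - 1L) / frame_rate_hz
  clean <- baseline + amplitude * .dlnorm_shift(t, t_arrival_s, mu, sigma)
  with_seed(seed, {
    y <- clean + if (noise_sd > 0) stats::rnorm(n_frames, 0, noise_sd) else 0
    excl <- rep(FALSE, n_frames)
    n_excl <- round(excluded_fraction * n_frames)
    if (n_excl > 0) excl[sample.int(n_frames, n_excl)] <- TRUE
    time_intensity_curve(t, y, excl, node_id = node_id)
  })
}

# Amplitude that yields a target wash-in rate (OLS slope over the wash-in
# window on the frame grid); the slope is linear in the amplitude.
.amplitude_for_wir <- function(wir_target, ttp_s, sigma, frame_rate_hz) {
  mu <- log(ttp_s) + sigma^2
  tt <- seq(0, ttp_s, by = 1 / frame_rate_hz)
  if (length(tt) < 3L) tt <- seq(0, ttp_s, length.out = 5L)
  g <- stats::dlnorm(tt, meanlog = mu, sdlog = sigma)
  slope_g <- stats::cov(tt, g) / stats::var(tt)
  wir_target / slope_g
}

# One synthetic node: geometry from (volume, L/W ratio), TIC from
# (ttp, wir); `exact` suppresses tracing jitter is not needed -- jitter is
# negligible for scoring either way.
.make_node <- function(spec, node_id, volume_mm3, lw_ratio, hilum_visible,
                       ttp_s, wir, t_arrival_s, excluded_fraction,
                       seed_geom, seed_tic) {
  # semiaxes a = q*b, c = 0.8*b chosen so the in-plane equatorial slice
  # carries the length (2a) and width (2b)
  b <- (volume_mm3 / ((4 / 3) * pi * 0.8 * lw_ratio))^(1 / 3)
  stack <- generate_ellipsoid_contours(
    c(lw_ratio * b, b, 0.8 * b), spacing_mm = spec$slice_spacing_mm,
    n_vertices = spec$contour_vertices, hilum_indent = hilum_visible,
    seed = seed_geom, node_id = node_id)
  mu <- log(ttp_s) + spec$sigma_bolus^2
  amp <- .amplitude_for_wir(wir, ttp_s, spec$sigma_bolus, spec$frame_rate_hz)
  tic <- generate_tic(
    t_arrival_s, mu, spec$sigma_bolus, amp, spec$baseline_au,
    spec$frame_rate_hz, spec$n_frames, noise_sd = spec$noise_sd,
    excluded_fraction = excluded_fraction, seed = seed_tic,
    node_id = node_id)
  list(node_id = node_id, contours = stack, tic = tic,
       hilum_visible = hilum_visible,
       truth = list(volume_mm3 = volume_mm3, lw_ratio = lw_ratio,
                    ttp_s = ttp_s, wir_au_per_s = wir,
                    t_arrival_s = t_arrival_s))
}

rtrunc_norm <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  pmax(x, lower)
}

#' Generate a synthetic paired-design cohort
#'
#' Emulates the paired study design: each subject contributes a left
#' (tumor-draining) and a right (internal control) inguinal node.
#' Tumor-injected subjects get involved left nodes --- inflated volume at
#' the target left/right ratio, round shape, hilum lost with the stated
#' probability, and a long-TTP / low-WiR bolus --- while all right nodes
#' and control-group left nodes are uninvolved. Two optional archetype
#' subjects occupy the last tumor-group slots at exact group-mean effect
#' sizes (they emulate specific observed phenotypes, not random draws):
#' `X4`, with the full imaging-involved phenotype except a raised wash-in
#' rate and negative pathology, and `X5`, whose control-node CEUS is
#' unusable (perfusion scores unavailable, morphometric denominator of
#' 3). With both flags on, `n_tumor_subjects` must be at least 2.
#'
#' All randomness flows from `spec$seed`: latent per-subject parameters
#' and per-node sub-seeds are drawn in subject order (left node before
#' right) from one seeded stream, so identical specs give identical
#' cohorts.
#'
#' @param spec a [cohort_spec()].
#' @return A list of subjects (class `synthetic_cohort`); each subject is
#'   a list with `subject_id`, `group`, `left`, `right` (nodes with
#'   `contours`, `tic`, `hilum_visible`, latent `truth`),
#'   `pathology_positive_left`, `pathology_positive_right`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- list()
  with_seed(spec$seed, {
    sub_seed <- function() sample.int(.Machine$integer.max - 1L, 1L)
    add_tumor <- function(id, exact = FALSE, path_pos = TRUE,
                          wir_left_mult = 1, right_excl = NULL) {
      if (exact) {
        v_r <- spec$right_volume_mm3
        v_l <- v_r * spec$volume_ratio_involved
        q_l <- spec$shape_ratio_involved; q_r <- spec$shape_ratio_control
        hil_l <- !(spec$hilum_loss_prob_involved > 0)
        ttp_l <- spec$ttp_involved_s; ttp_r <- spec$ttp_control_s
        wir_l <- spec$wir_involved * wir_left_mult
        wir_r <- spec$wir_control
      } else {
        v_r <- spec$right_volume_mm3 * exp(stats::rnorm(1, 0, spec$volume_sdlog))
        v_l <- v_r * spec$volume_ratio_involved *
          exp(stats::rnorm(1, 0, spec$ratio_sdlog))
        q_l <- rtrunc_norm(1, spec$shape_ratio_involved,
                           spec$shape_sd_involved, 1.05)
        q_r <- rtrunc_norm(1, spec$shape_ratio_control,
                           spec$shape_sd_control, 1.05)
        hil_l <- stats::runif(1) > spec$hilum_loss_prob_involved
        ttp_l <- rtrunc_norm(1, spec$ttp_involved_s, spec$ttp_sd_involved_s, 0.5)
        ttp_r <- rtrunc_norm(1, spec$ttp_control_s, spec$ttp_sd_control_s, 0.5)
        wir_l <- spec$wir_involved * wir_left_mult *
          exp(stats::rnorm(1, 0, spec$wir_sdlog))
        wir_r <- spec$wir_control * exp(stats::rnorm(1, 0, spec$wir_sdlog))
      }
      arr_l <- stats::runif(1, 4, 6); arr_r <- stats::runif(1, 4, 6)
      left <- .make_node(spec, paste0(id, "_L"), v_l, q_l, hil_l,
                         ttp_l, wir_l, arr_l, spec$routine_excluded_fraction,
                         sub_seed(), sub_seed())
      right <- .make_node(spec, paste0(id, "_R"), v_r, q_r, TRUE,
                          ttp_r, wir_r, arr_r,
                          if (is.null(right_excl))
                            spec$routine_excluded_fraction else right_excl,
                          sub_seed(), sub_seed())
      list(subject_id = id, group = "tumor_injected",
           left = left, right = right,
           pathology_positive_left = path_pos,
           pathology_positive_right = FALSE)
    }
    add_control <- function(id) {
      v_l <- spec$right_volume_mm3 * exp(stats::rnorm(1, 0, spec$volume_sdlog))
      v_r <- spec$right_volume_mm3 * exp(stats::rnorm(1, 0, spec$volume_sdlog))
      q_l <- rtrunc_norm(1, spec$shape_ratio_control, spec$shape_sd_control, 1.05)
      q_r <- rtrunc_norm(1, spec$shape_ratio_control, spec$shape_sd_control, 1.05)
      ttp_l <- rtrunc_norm(1, spec$ttp_control_s, spec$ttp_sd_control_s, 0.5)
      ttp_r <- rtrunc_norm(1, spec$ttp_control_s, spec$ttp_sd_control_s, 0.5)
      wir_l <- spec$wir_control * exp(stats::rnorm(1, 0, spec$wir_sdlog))
      wir_r <- spec$wir_control * exp(stats::rnorm(1, 0, spec$wir_sdlog))
      arr_l <- stats::runif(1, 4, 6); arr_r <- stats::runif(1, 4, 6)
      left <- .make_node(spec, paste0(id, "_L"), v_l, q_l, TRUE,
                         ttp_l, wir_l, arr_l, spec$routine_excluded_fraction,
                         sub_seed(), sub_seed())
      right <- .make_node(spec, paste0(id, "_R"), v_r, q_r, TRUE,
                          ttp_r, wir_r, arr_r, spec$routine_excluded_fraction,
                          sub_seed(), sub_seed())
      list(subject_id = id, group = "control_injected",
           left = left, right = right,
           pathology_positive_left = FALSE, pathology_positive_right = FALSE)
    }
    n_special <- spec$include_imaging_pos_path_neg_subject +
      spec$include_missing_ceus_subject
    if (spec$n_tumor_subjects < n_special)
      abort_spec("n_tumor_subjects is too small for the enabled archetype subjects")
    for (i in seq_len(spec$n_tumor_subjects - n_special))
      subjects[[length(subjects) + 1L]] <- add_tumor(sprintf("T%d", i))
    for (i in seq_len(spec$n_control_subjects))
      subjects[[length(subjects) + 1L]] <- add_control(sprintf("C%d", i))
    if (spec$include_imaging_pos_path_neg_subject)
      subjects[[length(subjects) + 1L]] <-
        add_tumor("X4", exact = TRUE, path_pos = FALSE,
                  wir_left_mult = 2 * spec$wir_control / spec$wir_involved)
    if (spec$include_missing_ceus_subject)
      subjects[[length(subjects) + 1L]] <-
        add_tumor("X5", exact = TRUE, path_pos = TRUE,
                  right_excl = spec$unusable_excluded_fraction)
  })
  structure(subjects, class = "synthetic_cohort", spec = spec)
}
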