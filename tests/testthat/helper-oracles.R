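# Independent geometric and statistical oracles used across tests.

# regular n-gon of given circumradius, optionally rotated/translated
regular_polygon <- function(n, r = 1, phase = 0, center = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n + phase
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

ellipse_polygon <- function(a, b, n = 256, phase = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n + phase
  cbind(a * cos(th), b * sin(th))
}

# exhaustive maximum vertex-pair chord (oracle for rotating calipers)
brute_diameter <- function(pts) max(stats::dist(pts))

# brute-force Clopper-Pearson by root-finding on the binomial CDF
brute_cp <- function(x, n, conf = 0.95) {
  a <- 1 - conf
  lower <- if (x == 0) 0 else
    stats::uniroot(function(p) 1 - stats::pbinom(x - 1, n, p) - a / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-13)$root
  upper <- if (x == n) 1 else
    stats::uniroot(function(p) stats::pbinom(x, n, p) - a / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-13)$root
  c(lower, upper)
}

# clean (noise-free) bolus curve on a frame grid; independent of the
# package's internal model evaluation
clean_bolus <- function(t, t0, mu, sigma, amplitude, baseline) {
  y <- rep(baseline, length(t))
  pos <- t > t0
  y[pos] <- baseline + amplitude * dlnorm(t[pos] - t0, mu, sigma)
  y
}

# OLS slope, closed form
ols_slope <- function(x, y) cov(x, y) / var(x)

# a small fast cohort spec for structural tests; overrides win
small_spec <- function(...) {
  args <- list(n_frames = 400L, contour_vertices = 24L,
               slice_spacing_mm = 0.08)
  user <- list(...)
  args[names(user)] <- user
  do.call(cohort_spec, args)
}
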