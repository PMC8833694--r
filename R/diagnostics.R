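#' Confusion-matrix counts
#'
#' Standard 2x2 tally of binary predictions against pathology truth.
#' Entries with unavailable (`NA`) predictions must be removed upstream;
#' they are rejected here.
#'
#' @param predictions logical (or 0/1) vector of predicted positivity.
#' @param truths logical vector of pathology positivity, same length.
#' @return list with counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(predictions, truths) {
  if (length(predictions) != length(truths))
    abort_invalid("`predictions` and `truths` must have equal length")
  if (length(predictions) == 0L)
    abort_empty_eval("nothing to evaluate: no predictions")
  if (any(is.na(predictions)) || any(is.na(truths)))
    abort_invalid("remove unavailable predictions before tallying")
  p <- as.logical(predictions); t <- as.logical(truths)
  list(tp = sum(p & t), fp = sum(p & !t),
       tn = sum(!p & !t), fn = sum(!p & t))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion in beta-quantile
#' form: lower endpoint `qbeta(alpha/2, x, n - x + 1)` (0 when x = 0),
#' upper endpoint `qbeta(1 - alpha/2, x + 1, n - x)` (1 when x = n).
#'
#' @param successes,trials counts with `0 <= successes <= trials`,
#'   `trials >= 1`.
#' @param confidence two-sided confidence level (default 0.95).
#' @return numeric `c(lower, upper)` in \[0, 1\].
#' @examples
#' clopper_pearson(4, 4)   # lower ~0.3976
#' clopper_pearson(7, 8)   # ~ (0.4735, 0.9968)
#' @export
clopper_pearson <- function(successes, trials, confidence = 0.95) {
  if (!is.finite(successes) || !is.finite(trials) ||
      successes != floor(successes) || trials != floor(trials) ||
      trials < 1 || successes < 0 || successes > trials)
    abort_invalid("need integer counts with 0 <= successes <= trials, trials >= 1")
  if (confidence <= 0 || confidence >= 1)
    abort_invalid("`confidence` must be in (0, 1)")
  a <- 1 - confidence
  lower <- if (successes == 0) 0 else
    stats::qbeta(a / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else
    stats::qbeta(1 - a / 2, successes + 1, trials - successes)
  c(lower = lower, upper = upper)
}

# one metric as (estimate, lower, upper) or NAs when undefined (0 denominator)
.metric_ci <- function(num, den, confidence) {
  if (den == 0)
    return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                successes = num, trials = den))
  ci <- clopper_pearson(num, den, confidence)
  list(estimate = num / den, lower = unname(ci[1]), upper = unname(ci[2]),
       successes = num, trials = den)
}

.diagnostic_result <- function(cm, confidence) {
  n <- cm$tp + cm$fp + cm$tn + cm$fn
  structure(
    list(tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn, n_evaluated = n,
         sensitivity = .metric_ci(cm$tp, cm$tp + cm$fn, confidence),
         specificity = .metric_ci(cm$tn, cm$tn + cm$fp, confidence),
         ppv = .metric_ci(cm$tp, cm$tp + cm$fp, confidence),
         npv = .metric_ci(cm$tn, cm$tn + cm$fn, confidence),
         accuracy = .metric_ci(cm$tp + cm$tn, n, confidence)),
    class = "diagnostic_result"
  )
}

#' @export
print.diagnostic_result <- function(x, ...) {
  cat(sprintf("<diagnostic_result> n=%d  tp=%d fp=%d tn=%d fn=%d\n",
              x$n_evaluated, x$tp, x$fp, x$tn, x$fn))
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy"))
    cat(sprintf("  %-11s %s\n", m, format_pct_ci(x[[m]])))
  invisible(x)
}

#' Percent string with exact confidence bracket
#'
#' Formats a metric as `"point [lower-upper]"` in percent, rounded to the
#' nearest integer (half away from zero) at report time only; `"--"` for
#' undefined metrics.
#'
#' @param metric a metric element of a [evaluate_parameter()] result.
#' @return character scalar.
#' @export
format_pct_ci <- function(metric) {
  if (is.na(metric$estimate)) return("--")
  sprintf("%d [%d-%d]", round_half_up(100 * metric$estimate),
          round_half_up(100 * metric$lower),
          round_half_up(100 * metric$upper))
}

.pathology_lookup <- function(scorecards, pathology) {
  ids <- vapply(scorecards, function(s) s$subject_id, character(1))
  if (is.null(names(pathology)))
    abort_invalid("`pathology` must be a named logical vector keyed by subject_id")
  missing <- setdiff(ids, names(pathology))
  if (length(missing) > 0)
    abort_invalid(paste("no pathology label for subject(s):",
                        paste(missing, collapse = ", ")))
  as.logical(pathology[ids])
}

#' Diagnostic performance of one imaging parameter
#'
#' Confusion matrix and the five performance metrics (sensitivity,
#' specificity, PPV, NPV, diagnostic accuracy) with exact 95% confidence
#' intervals, for a single binary parameter evaluated against pathology.
#' Subjects whose parameter is unavailable (e.g. perfusion scores when
#' one side's CEUS failed the quality gate) are excluded from that
#' parameter's evaluation. Metrics with a zero denominator are reported
#' as undefined (`NA`), never as 0.
#'
#' @param scorecards list of `score_card`s (left nodes of each subject).
#' @param pathology named logical vector of pathology positivity, keyed
#'   by subject_id.
#' @param parameter one of `"volume"`, `"shape"`, `"hilum"`, `"ttp"`,
#'   `"wir"`.
#' @param confidence confidence level (default 0.95).
#' @return A `diagnostic_result`.
#' @export
evaluate_parameter <- function(scorecards, pathology, parameter,
                               confidence = 0.95) {
  parameter <- match.arg(parameter, c("volume", "shape", "hilum", "ttp", "wir"))
  truth <- .pathology_lookup(scorecards, pathology)
  pred <- vapply(scorecards, function(s) s$scores[[parameter]], integer(1))
  keep <- !is.na(pred)
  if (!any(keep))
    abort_empty_eval(sprintf("no evaluable subject for parameter '%s'", parameter))
  .diagnostic_result(confusion(pred[keep] == 1L, truth[keep]), confidence)
}

#' Diagnostic performance of a sum-score threshold
#'
#' A subject is predicted positive when its sum percent is at least the
#' threshold and strictly greater than zero (so at threshold 0 a subject
#' with no positive parameter is still predicted negative). All subjects
#' are evaluable: the sum percent is always defined over the available
#' parameters.
#'
#' @param scorecards list of `score_card`s.
#' @param pathology named logical vector keyed by subject_id.
#' @param threshold_percent positivity threshold in \[0, 100\].
#' @param confidence confidence level (default 0.95).
#' @return A `diagnostic_result`.
#' @export
evaluate_sum_threshold <- function(scorecards, pathology, threshold_percent,
                                   confidence = 0.95) {
  if (!is.finite(threshold_percent) || threshold_percent < 0 ||
      threshold_percent > 100)
    abort_invalid("`threshold_percent` must be in [0, 100]")
  if (length(scorecards) == 0L)
    abort_empty_eval("empty cohort: no score cards to evaluate")
  truth <- .pathology_lookup(scorecards, pathology)
  pct <- vapply(scorecards, function(s) s$sum_percent, numeric(1))
  pred <- pct >= threshold_percent & pct > 0
  .diagnostic_result(confusion(pred, truth), confidence)
}

#' Full diagnostic-performance report
#'
#' Evaluates the five individual parameters and a sweep of sum-score
#' thresholds against pathology, rendered as percent strings with exact
#' 95% confidence brackets (individual parameters first, then the
#' threshold sweep), plus the underlying `diagnostic_result` objects.
#'
#' @param scorecards list of `score_card`s.
#' @param pathology named logical vector keyed by subject_id.
#' @param thresholds sum-score thresholds to sweep
#'   (default `seq(0, 100, by = 20)`).
#' @param confidence confidence level (default 0.95).
#' @return data.frame with columns `variable`, `n`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy` (formatted strings); the raw
#'   results are attached as attribute `"results"` (a named list of
#'   `diagnostic_result`s).
#' @export
report_performance <- function(scorecards, pathology,
                               thresholds = seq(0, 100, by = 20),
                               confidence = 0.95) {
  if (length(scorecards) == 0L)
    abort_empty_eval("empty cohort: no score cards to evaluate")
  params <- c("volume", "shape", "hilum", "ttp", "wir")
  results <- list()
  for (p in params)
    results[[p]] <- evaluate_parameter(scorecards, pathology, p, confidence)
  for (th in thresholds)
    results[[paste0("sum_", th)]] <-
      evaluate_sum_threshold(scorecards, pathology, th, confidence)
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(variable = nm, n = r$n_evaluated,
               sensitivity = format_pct_ci(r$sensitivity),
               specificity = format_pct_ci(r$specificity),
               ppv = format_pct_ci(r$ppv),
               npv = format_pct_ci(r$npv),
               accuracy = format_pct_ci(r$accuracy),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "results") <- results
  out
}
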