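# Median dichotomization and 2x2 diagnostic statistics.

#' Median dichotomization of a scar index
#'
#' The cut-off is the sample median; patients strictly above it form the
#' positive (large-scar) group and patients at or below it the negative
#' group, matching the clinical "> cut-off" vs "<= cut-off" convention.
#' With even n and tied central values the `<=` rule keeps ties in the
#' negative group, deterministically.
#'
#' @param values numeric per-patient index values (n >= 2).
#' @return list with `cutoff`, logical `positive`, and group sizes
#'   `n_positive` / `n_negative`. When all values are identical one group
#'   is empty and a warning flags the degenerate split.
#' @export
dichotomize_median <- function(values) {
  if (length(values) < 2L) .stop_scarq("need at least 2 values", "scarq_range_error")
  cutoff <- median(values)
  positive <- values > cutoff
  if (!any(positive) && length(unique(values)) == 1L) {
    warning("all values identical: positive group is empty", call. = FALSE)
  }
  list(cutoff = cutoff, positive = positive,
       n_positive = sum(positive), n_negative = sum(!positive))
}

#' Build a 2x2 contingency table from labels
#'
#' Condition-positive is the clinical endpoint (appropriate ICD therapy);
#' test-positive is the dichotomized scar index.
#'
#' @param test_positive,event logical/0-1 vectors of equal length.
#' @return list of counts `tp`, `fp`, `fn`, `tn` (class `two_by_two`).
#' @export
two_by_two <- function(test_positive, event) {
  test_positive <- as.logical(test_positive); event <- as.logical(event)
  stopifnot(length(test_positive) == length(event))
  structure(
    list(
      tp = sum(test_positive & event), fp = sum(test_positive & !event),
      fn = sum(!test_positive & event), tn = sum(!test_positive & !event)
    ),
    class = "two_by_two"
  )
}

#' @noRd
.as_counts <- function(tp, fp = NULL, fn = NULL, tn = NULL) {
  if (inherits(tp, "two_by_two")) return(tp)
  counts <- c(tp, fp, fn, tn)
  if (length(counts) != 4L || any(is.na(counts)) || any(counts < 0) ||
      any(counts != floor(counts))) {
    .stop_scarq("counts tp, fp, fn, tn must be nonnegative integers",
                "scarq_range_error")
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn), class = "two_by_two")
}

#' Diagnostic statistics of a 2x2 table
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), positive predictive
#' value tp/(tp+fp) and negative predictive value tn/(tn+fn). Raw
#' fractions are retained; percentages are rounded half-up to integers as
#' printed clinically. A statistic with a zero denominator is missing
#' (NA), not 0.
#'
#' @param tp a `two_by_two` object, or the true-positive count.
#' @param fp,fn,tn remaining counts when `tp` is a count.
#' @return An object of class `diagnostic_stats`: list with `raw` and
#'   `percent` (both named over sensitivity/specificity/ppv/npv) and the
#'   `counts`.
#' @examples
#' diagnostic_stats(11, 19, 3, 33)  # sens 79%, spec 63%, npv 92%
#' @export
diagnostic_stats <- function(tp, fp = NULL, fn = NULL, tn = NULL) {
  ct <- .as_counts(tp, fp, fn, tn)
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  raw <- c(
    sensitivity = frac(ct$tp, ct$tp + ct$fn),
    specificity = frac(ct$tn, ct$tn + ct$fp),
    ppv = frac(ct$tp, ct$tp + ct$fp),
    npv = frac(ct$tn, ct$tn + ct$fn)
  )
  structure(
    list(counts = ct, raw = raw, percent = .round_half_up(100 * raw)),
    class = "diagnostic_stats"
  )
}

#' @export
print.diagnostic_stats <- function(x, ...) {
  ct <- x$counts
  cat(sprintf("<diagnostic_stats> tp=%d fp=%d fn=%d tn=%d\n", ct$tp, ct$fp, ct$fn, ct$tn))
  for (nm in names(x$raw)) {
    cat(sprintf("  %-11s %s\n", nm,
                if (is.na(x$raw[nm])) "missing (zero denominator)"
                else sprintf("%d%% (%.4f)", as.integer(x$percent[nm]), x$raw[nm])))
  }
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value of the conditional exact test: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed the observed table's.
#'
#' @inheritParams diagnostic_stats
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact <- function(tp, fp = NULL, fn = NULL, tn = NULL) {
  ct <- .as_counts(tp, fp, fn, tn)
  total <- ct$tp + ct$fp + ct$fn + ct$tn
  if (total > 1e4) {
    .stop_scarq("table total too large for exact enumeration", "scarq_range_error")
  }
  m <- matrix(c(ct$tp, ct$fn, ct$fp, ct$tn), 2L)
  fisher.test(m, alternative = "two.sided")$p.value
}

#' Dichotomize a cohort and evaluate the split
#'
#' Convenience wrapper: median split of an index, 2x2 table against the
#' endpoint, diagnostic statistics and Fisher's exact p.
#'
#' @param values per-patient index values.
#' @param event per-patient endpoint (0/1 or logical).
#' @param fisher compute Fisher's exact p (exact enumeration; disable for
#'   cohorts beyond its table-size limit).
#' @return list with `cutoff`, `table`, `stats`, `fisher_p` (NA when
#'   `fisher = FALSE`).
#' @export
evaluate_median_split <- function(values, event, fisher = TRUE) {
  split <- dichotomize_median(values)
  tab <- two_by_two(split$positive, event)
  list(cutoff = split$cutoff, table = tab, stats = diagnostic_stats(tab),
       fisher_p = if (fisher) fisher_exact(tab) else NA_real_)
}
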