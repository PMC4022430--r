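#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The lower bound solves the upper-tail beta relation at `alpha/2`
#' (`qbeta(alpha/2, s, n - s + 1)`), the upper bound the lower tail
#' (`qbeta(1 - alpha/2, s + 1, n - s)`); at `s = 0` the lower bound is
#' exactly 0 and at `s = n` the upper bound exactly 1. Wilson score
#' intervals are available via `method`.
#'
#' @param successes,trials Integer counts, `0 <= successes <= trials`,
#'   `trials >= 1`.
#' @param alpha Two-sided error rate (default 0.05).
#' @param method `"clopper-pearson"` (default) or `"wilson"`.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' exact_binomial_ci(48, 50)  # lower ~0.8629
#' @export
exact_binomial_ci <- function(successes, trials, alpha = 0.05,
                              method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  if (length(successes) != 1 || length(trials) != 1 ||
      is.na(successes) || is.na(trials) ||
      trials < 1 || successes < 0 || successes > trials) {
    stopf("invalid counts: need 0 <= successes <= trials, trials >= 1")
  }
  s <- successes; n <- trials
  if (method == "clopper-pearson") {
    lower <- if (s == 0) 0 else stats::qbeta(alpha / 2, s, n - s + 1)
    upper <- if (s == n) 1 else stats::qbeta(1 - alpha / 2, s + 1, n - s)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    ph <- s / n
    den <- 1 + z^2 / n
    centre <- (ph + z^2 / (2 * n)) / den
    half <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
    lower <- max(0, centre - half)
    upper <- min(1, centre + half)
  }
  c(lower = lower, upper = upper)
}

#' Confusion-matrix statistics with exact confidence intervals
#'
#' Computes TP/FP/TN/FN counts against the positive label `"case"` and
#' the four standard proportions — PPV `tp/(tp+fp)`, NPV `tn/(tn+fn)`,
#' sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)` — each with a
#' Clopper-Pearson interval on its own numerator/denominator. A
#' statistic with a zero denominator is reported as `NA` (undefined);
#' the others are still computed.
#'
#' @param predicted,truth Aligned character vectors with values `"case"`
#'   / `"control"`.
#' @param alpha Two-sided error rate for the intervals.
#' @param ci_method Passed to [exact_binomial_ci()].
#' @return List of class `confusion_stats`: `tp`, `fp`, `tn`, `fn`, `n`,
#'   and for each of `ppv`, `npv`, `sensitivity`, `specificity` a list
#'   `estimate`, `lower`, `upper`, `successes`, `trials`.
#' @export
confusion_stats <- function(predicted, truth, alpha = 0.05,
                            ci_method = "clopper-pearson") {
  if (length(predicted) != length(truth)) stopf("label vectors must be aligned")
  ok <- c("case", "control")
  if (any(!predicted %in% ok) || any(!truth %in% ok)) {
    stopf("labels must be 'case' or 'control'")
  }
  tp <- sum(predicted == "case" & truth == "case")
  fp <- sum(predicted == "case" & truth == "control")
  tn <- sum(predicted == "control" & truth == "control")
  fn <- sum(predicted == "control" & truth == "case")
  stat <- function(s, n) {
    if (n == 0) {
      return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                  successes = s, trials = n))
    }
    ci <- exact_binomial_ci(s, n, alpha, ci_method)
    list(estimate = s / n, lower = unname(ci["lower"]), upper = unname(ci["upper"]),
         successes = s, trials = n)
  }
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn, n = tp + fp + tn + fn,
    ppv = stat(tp, tp + fp), npv = stat(tn, tn + fn),
    sensitivity = stat(tp, tp + fn), specificity = stat(tn, tn + fp),
    alpha = alpha
  ), class = "confusion_stats")
}

#' @export
print.confusion_stats <- function(x, ...) {
  cat(sprintf("Confusion: TP %d  FP %d  TN %d  FN %d (n = %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$n))
  for (nm in c("ppv", "npv", "sensitivity", "specificity")) {
    s <- x[[nm]]
    if (is.na(s$estimate)) {
      cat(sprintf("  %-12s undefined (0 denominator)\n", toupper(nm)))
    } else {
      cat(sprintf("  %-12s %5.1f%% (%d/%d; %d%% CI %.1f-%.1f%%)\n",
                  toupper(nm), 100 * s$estimate, s$successes, s$trials,
                  round(100 * (1 - x$alpha)), 100 * s$lower, 100 * s$upper))
    }
  }
  invisible(x)
}

#' Proportional stratified sample for manual chart review
#'
#' Draws a without-replacement sample of size `n`, allocated across the
#' strata formed by `strata_vars` proportionally to stratum size using
#' largest-remainder rounding, then sampled uniformly within each
#' stratum. Strata requested but empty are skipped with a warning.
#'
#' @param cohort data.frame; must contain `patient_id` and the
#'   stratification columns.
#' @param strata_vars Character vector of column names.
#' @param n Total sample size, at most `nrow(cohort)`.
#' @param seed Global seed (substream `"review"`).
#' @return data.frame: the sampled rows of `cohort` plus a `stratum`
#'   label column.
#' @export
sample_for_review <- function(cohort, strata_vars, n, seed) {
  stopifnot(n <= nrow(cohort), n >= 0)
  for (v in strata_vars) {
    if (!v %in% names(cohort)) stopf("unknown stratification variable '%s'", v)
  }
  stratum <- if (length(strata_vars) > 0) {
    do.call(paste, c(lapply(strata_vars, function(v) as.character(cohort[[v]])),
                     sep = "|"))
  } else rep("all", nrow(cohort))
  sizes <- table(stratum)
  if (any(sizes == 0)) warning("empty stratum skipped")
  labels <- names(sizes)
  exact <- n * as.numeric(sizes) / nrow(cohort)
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  alloc <- stats::setNames(pmin(base, as.numeric(sizes)), labels)
  rows <- with_substream(seed, "review", {
    unlist(lapply(labels, function(l) {
      idx <- which(stratum == l)
      idx[sample.int(length(idx), alloc[[l]])]
    }))
  })
  out <- cohort[sort(rows), , drop = FALSE]
  out$stratum <- stratum[sort(rows)]
  rownames(out) <- NULL
  out
}
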