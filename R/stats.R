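#' Shapiro-Wilk normality p-value
#'
#' Gate for choosing between the paired t-test and the Wilcoxon signed-rank
#' test, applied to the per-participant paired differences.
#'
#' @param x Numeric sample (3 <= n <= 5000, not all equal).
#' @return p-value.
#' @export
test_normality <- function(x) {
  if (length(x) < 3L || length(x) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (diff(range(x)) == 0) stop("constant sample: normality test undefined")
  stats::shapiro.test(x)$p.value
}

#' Normality-gated paired comparison
#'
#' Tests per-participant paired differences for normality (Shapiro-Wilk at
#' `alpha`); if normal, a two-sided paired t-test, otherwise a two-sided
#' Wilcoxon signed-rank test (exact distribution for n <= 25, normal
#' approximation with continuity correction above). Degenerate all-zero
#' difference vectors return p = 1 with a flag.
#'
#' @param baseline,feedback Paired per-participant values (equal length,
#'   n >= 2, no missing pairs).
#' @param outcome Label carried into the result.
#' @param alpha Significance level of the normality gate (default 0.05).
#' @return Object of class `paired_test_result`: list with `outcome`,
#'   `test` (`"paired_t"` / `"wilcoxon"` / `"degenerate"`), `statistic`,
#'   `p`, `normality_p`, `mean_diff`, `sd_diff`, `n`, `degenerate`.
#' @export
paired_compare <- function(baseline, feedback, outcome = "outcome",
                           alpha = 0.05) {
  if (length(baseline) != length(feedback))
    stop("baseline and feedback must be paired (equal length)")
  if (anyNA(baseline) || anyNA(feedback)) stop("missing members of a pair")
  n <- length(baseline)
  if (n < 2L) stop("need n >= 2 pairs")
  d <- feedback - baseline
  out <- list(outcome = outcome, n = n,
              mean_diff = mean(d), sd_diff = stats::sd(d),
              p_adj = NA_real_, degenerate = FALSE)
  if (all(d == 0)) {
    out$test <- "degenerate"; out$statistic <- NA_real_
    out$p <- 1; out$normality_p <- NA_real_; out$degenerate <- TRUE
    class(out) <- "paired_test_result"
    return(out)
  }
  if (diff(range(d)) == 0) {
    # nonzero constant differences: t statistic undefined (sd = 0)
    out$test <- "degenerate"; out$statistic <- NA_real_
    out$p <- NA_real_; out$normality_p <- NA_real_; out$degenerate <- TRUE
    class(out) <- "paired_test_result"
    return(out)
  }
  # the normality gate needs n >= 3; with two pairs default to the t-test
  out$normality_p <- if (n >= 3) test_normality(d) else NA_real_
  if (is.na(out$normality_p) || out$normality_p >= alpha) {
    tt <- stats::t.test(d, alternative = "two.sided")
    out$test <- "paired_t"
    out$statistic <- unname(tt$statistic)
    out$p <- tt$p.value
  } else {
    wt <- stats::wilcox.test(d, alternative = "two.sided",
                             exact = n <= 25, correct = TRUE)
    out$test <- "wilcoxon"
    out$statistic <- unname(wt$statistic)
    out$p <- wt$p.value
  }
  class(out) <- "paired_test_result"
  out
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("%s: %s, mean diff %.3g +/- %.3g (n=%d), p=%.4g\n",
              x$outcome, x$test, x$mean_diff, x$sd_diff, x$n, x$p))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate control for the exploratory outcome family:
#' `p_adj_(i) = min_{j >= i} ( m * p_(j) / j )`, capped at 1, returned in
#' the original order.
#'
#' @param pvals Raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE) || anyNA(pvals))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  if (m == 0L) return(numeric(0))
  o <- order(pvals)
  ranked <- pvals[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Power of a two-sided paired t-test (noncentral t)
#'
#' @param n Number of pairs (>= 2).
#' @param mean_diff,sd_diff Mean and SD of the paired differences.
#' @param alpha Significance level.
#' @return Power in `[0, 1]`.
#' @export
paired_t_power <- function(n, mean_diff, sd_diff, alpha = 0.05) {
  ncp <- abs(mean_diff) / (sd_diff / sqrt(n))
  tc <- stats::qt(1 - alpha / 2, df = n - 1)
  1 - stats::pt(tc, df = n - 1, ncp = ncp) +
    stats::pt(-tc, df = n - 1, ncp = ncp)
}

#' Sample size for a paired t-test
#'
#' Solves the continuous noncentral-t sample-size equation (as R's
#' `power.t.test` does) and converts to a whole number of participants.
#' `rounding = "nearest"` (default) reports the nearest integer to the
#' continuous solution, the convention under which a 0.38 +/- 0.39 BW
#' effect at power 0.9 and alpha 0.05 yields 13 participants;
#' `rounding = "ceiling"` returns the smallest integer n whose power
#' reaches the target (14 for that same effect), which is the mode that
#' satisfies the bracket `power(n) >= power target > power(n - 1)`.
#'
#' @param mean_diff Expected mean of the paired differences.
#' @param sd_diff Expected SD of the paired differences (> 0).
#' @param power Target power in (0, 1).
#' @param alpha Significance level in (0, 1).
#' @param two_sided Two-sided test (only `TRUE` is supported).
#' @param rounding `"nearest"` or `"ceiling"`.
#' @return Integer number of participants (pairs), at least 2.
#' @export
paired_power_n <- function(mean_diff, sd_diff, power = 0.9, alpha = 0.05,
                           two_sided = TRUE, rounding = c("nearest", "ceiling")) {
  rounding <- match.arg(rounding)
  if (!isTRUE(two_sided)) stop("only the two-sided test is implemented")
  if (sd_diff <= 0) stop("`sd_diff` must be > 0")
  if (power <= 0 || power >= 1) stop("`power` must lie in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  if (mean_diff == 0) stop("`mean_diff` must be nonzero")
  pw <- function(n) paired_t_power(n, mean_diff, sd_diff, alpha)
  if (pw(2) >= power) return(2L)
  hi <- 4
  while (pw(hi) < power && hi < 1e7) hi <- hi * 2
  n_cont <- stats::uniroot(function(n) pw(n) - power, c(2, hi),
                           tol = 1e-8)$root
  n_int <- if (rounding == "nearest") max(2L, as.integer(round(n_cont)))
           else max(2L, as.integer(ceiling(n_cont - 1e-9)))
  n_int
}

#' Cohort descriptive summary and responder counts
#'
#' @param changes data.frame of per-participant outcome changes
#'   (feedback minus baseline), one column per outcome.
#' @param responder_sign Named vector giving, per outcome, the sign of a
#'   "response" (-1 = a reduction responds, +1 = an increase). Defaults to
#'   -1 for every outcome.
#' @return data.frame with columns `outcome`, `mean`, `sd`, `n`,
#'   `responders`, `responder_fraction`.
#' @export
cohort_summary <- function(changes,
                           responder_sign = NULL) {
  stopifnot(is.data.frame(changes), nrow(changes) >= 1L)
  outs <- names(changes)
  if (is.null(responder_sign)) responder_sign <- stats::setNames(rep(-1, length(outs)), outs)
  res <- lapply(outs, function(nm) {
    x <- changes[[nm]]
    sgn <- if (nm %in% names(responder_sign)) responder_sign[[nm]] else -1
    data.frame(outcome = nm, mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
               n = length(x),
               responders = sum(sign(x) == sgn),
               responder_fraction = mean(sign(x) == sgn))
  })
  do.call(rbind, res)
}
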