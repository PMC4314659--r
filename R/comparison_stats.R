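#' Paired differences between backtransformed and direct ages
#'
#' For sharks aged by both routes, the per-shark difference
#' (backtransformed age minus direct vertebral age) with its mean and range,
#' all on unrounded values.
#'
#' @param age_bt Backtransformed ages at recapture, years.
#' @param age_direct Direct vertebral ages, years (same length, paired).
#' @return A list with `diffs`, `mean`, `min`, `max`, `n`.
#' @examples
#' paired_differences(c(19.8, 16.4, 17.0, 22.8), c(18.5, 15.5, 14.5, 20.5))
#' @export
paired_differences <- function(age_bt, age_direct) {
  if (length(age_bt) != length(age_direct)) stop("ages are paired: lengths must match")
  keep <- !is.na(age_bt) & !is.na(age_direct)
  d <- age_bt[keep] - age_direct[keep]
  if (length(d) == 0L) stop("no complete pairs")
  list(diffs = d, mean = mean(d), min = min(d), max = max(d), n = length(d))
}

#' Two-sided tail probability of Student's t
#'
#' P(|T| >= |t|) for T ~ Student's t with `df` degrees of freedom, computed
#' from the regularized incomplete beta function:
#' \deqn{P = I_{df/(df + t^2)}(df/2, 1/2).}
#' At `df = 1` this reduces to the standard Cauchy two-sided tail
#' \eqn{2(1/2 - \arctan(t)/\pi)}, which serves as a closed-form check.
#'
#' @param t t statistic (vectorised).
#' @param df Degrees of freedom, positive.
#' @return Two-sided p value in `[0, 1]`.
#' @export
student_t_two_sided <- function(t, df) {
  if (!is.numeric(df) || length(df) != 1L || df <= 0) stop("'df' must be positive")
  stats::pbeta(df / (df + t^2), df / 2, 0.5)
}

#' Paired t-test of backtransformed vs direct ages
#'
#' Two-sided paired t-test built from its defining formulas: with per-pair
#' differences \eqn{d_i} (backtransformed minus direct),
#' \deqn{t = \frac{\bar d}{s_d / \sqrt{n}}, \quad s_d \text{ the sample SD
#' (divisor } n-1\text{)}, \quad df = n - 1,}
#' and the two-sided p value from [student_t_two_sided()]. The test is
#' two-sided because the hypothesis is a difference between the two ageing
#' routes, not a direction.
#'
#' @param age_bt Backtransformed ages at recapture, years.
#' @param age_direct Direct vertebral ages, years (paired).
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return Object of class `paired_t_test`: a list with `t`, `df`, `p`,
#'   `mean_diff`, `sd_diff`, `n`, `alpha`, `significant`.
#' @examples
#' paired_t_test(c(19.8, 16.4, 17.0, 22.8), c(18.5, 15.5, 14.5, 20.5))
#' @export
paired_t_test <- function(age_bt, age_direct, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)")
  pd <- paired_differences(age_bt, age_direct)
  n <- pd$n
  if (n < 2L) stop("paired t-test needs at least 2 complete pairs")
  sd_d <- stats::sd(pd$diffs)
  if (sd_d == 0) stop("zero variance of paired differences: t undefined")
  t_stat <- pd$mean / (sd_d / sqrt(n))
  df <- n - 1L
  p <- student_t_two_sided(t_stat, df)
  structure(
    list(t = t_stat, df = df, p = p, mean_diff = pd$mean, sd_diff = sd_d,
         n = n, alpha = alpha, significant = p < alpha),
    class = "paired_t_test"
  )
}

#' @export
print.paired_t_test <- function(x, ...) {
  cat("Paired t-test: backtransformed vs direct age\n")
  cat(sprintf("  n = %d pairs, mean difference = %.3f yr (sd %.3f)\n",
              x$n, x$mean_diff, x$sd_diff))
  cat(sprintf("  t = %.3f, df = %d, two-sided p = %.4f (%ssignificant at alpha = %g)\n",
              x$t, x$df, x$p, if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Compare ageing routes over a set of liberty records
#'
#' Selects records carrying both a backtransformed age at recapture and a
#' direct vertebral age, and runs [paired_differences()] and
#' [paired_t_test()] on them.
#'
#' @param records Liberty records from [build_liberty_records()].
#' @param alpha Significance level for the t-test.
#' @return A list with `pairs` (data frame: `tag_id`, `age_bt`, `age_direct`,
#'   `diff`), `differences`, and `t_test` (or `NULL` when fewer than 2 pairs).
#' @export
compare_age_estimates <- function(records, alpha = 0.05) {
  stopifnot(is.data.frame(records))
  keep <- !is.na(records$age_recap_bt) & !is.na(records$age_direct)
  sub <- records[keep, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no records with both age estimates")
  pairs <- data.frame(tag_id = sub$tag_id,
                      age_bt = sub$age_recap_bt,
                      age_direct = sub$age_direct,
                      diff = sub$age_recap_bt - sub$age_direct,
                      stringsAsFactors = FALSE)
  list(pairs = pairs,
       differences = paired_differences(pairs$age_bt, pairs$age_direct),
       t_test = if (nrow(pairs) >= 2L)
         paired_t_test(pairs$age_bt, pairs$age_direct, alpha) else NULL)
}
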