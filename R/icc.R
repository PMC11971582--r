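#' Intraclass correlation for inter-rater reliability
#'
#' Single-rater intraclass correlation from a two-way mixed-effects
#' ANOVA (subjects random, raters fixed), the standard summary of rater
#' consistency for ordinal note scores. The default `"consistency"`
#' form is
#' \deqn{ICC = (MS_S - MS_E) / (MS_S + (k - 1) MS_E)}
#' where \eqn{MS_S} and \eqn{MS_E} are the between-subject and residual
#' mean squares and k the number of raters; the `"agreement"` variant
#' additionally penalizes rater mean differences. The 95% confidence
#' interval uses the F-distribution bounds on \eqn{MS_S / MS_E}.
#'
#' @param ratings Numeric matrix: rows = subjects (notes), columns =
#'   raters; must be complete (no missing cells), with at least 2
#'   subjects and 2 raters.
#' @param type `"consistency"` (default) or `"agreement"`.
#' @param conf Confidence level (default 0.95).
#' @return A list of class `cr_icc` with `estimate`, `ci_low`,
#'   `ci_high`, `type`, `n_subjects`, `n_raters`.
#' @export
icc_consistency <- function(ratings, type = c("consistency", "agreement"),
                            conf = 0.95) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings matrix must be complete", call. = FALSE)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L)
    stop("need at least 2 subjects and 2 raters", call. = FALSE)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr <= .Machine$double.eps^0.5 * max(1, abs(grand)))
    stop("ICC undefined: no between-subject variance", call. = FALSE)
  alpha <- 1 - conf
  if (type == "consistency") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse <= .Machine$double.eps * max(1, msr)) {
      lo <- hi <- 1
    } else {
      fobs <- msr / mse
      fl <- fobs / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      fu <- fobs * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      lo <- (fl - 1) / (fl + k - 1)
      hi <- (fu - 1) / (fu + k - 1)
    }
  } else {
    est <- (msr - mse) /
      (msr + (k - 1) * mse + (k / n) * (msc - mse))
    if (mse <= .Machine$double.eps * max(1, msr) &&
        msc <= .Machine$double.eps * max(1, msr)) {
      lo <- hi <- 1
    } else {
      # Shrout-Fleiss approximate bounds for ICC(2,1)
      a <- (k * est) / (n * (1 - est))
      b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      f1 <- qf(1 - alpha / 2, n - 1, v)
      f2 <- qf(1 - alpha / 2, v, n - 1)
      lo <- n * (msr - f1 * mse) /
        (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
      hi <- n * (f2 * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f2 * msr)
    }
  }
  structure(list(estimate = est, ci_low = lo, ci_high = hi, type = type,
                 n_subjects = n, n_raters = k),
            class = "cr_icc")
}

#' @export
print.cr_icc <- function(x, ...) {
  cat(sprintf("ICC(%s, single rater) = %.3f [%.3f, %.3f], %d subjects x %d raters\n",
              x$type, x$estimate, x$ci_low, x$ci_high,
              x$n_subjects, x$n_raters))
  invisible(x)
}

#' Build a rating matrix from long-format ratings
#'
#' @param df A `data.frame` with columns `subject_id`, `rater_id`,
#'   `score`.
#' @return A complete numeric matrix, subjects x raters.
#' @export
rating_matrix <- function(df) {
  subj <- unique(df$subject_id); raters <- unique(df$rater_id)
  m <- matrix(NA_real_, length(subj), length(raters),
              dimnames = list(subj, raters))
  m[cbind(match(df$subject_id, subj), match(df$rater_id, raters))] <-
    df$score
  if (anyNA(m))
    stop("incomplete rating matrix: every subject needs every rater",
         call. = FALSE)
  m
}
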