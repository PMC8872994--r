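#' Repeated-measures correlation
#'
#' The common within-subject association of two repeatedly measured
#' variables: an analysis of covariance of y on x with subject as a
#' categorical factor and a shared slope. Because the subject factor absorbs
#' all between-subject intercept differences, the fit reduces to the
#' correlation of the within-subject centered values,
#' \deqn{r = \sum x_c y_c / \sqrt{\sum x_c^2 \sum y_c^2},}
#' equal to sign(slope) * sqrt(SS_x / (SS_x + SS_error)) of the ANCOVA.
#' Degrees of freedom are N_obs - N_subjects - 1 and the p-value is
#' two-sided from the t distribution. Robust to unequal group sizes and
#' missing visits: subjects contribute whatever complete pairs they have.
#'
#' @param data data.frame in long format.
#' @param x,y column names of the two variables.
#' @param subject column identifying subjects (default `"subject_id"`).
#' @return list of class `rmcorr_result`: `r`, `df`, `p`, `n_obs`,
#'   `n_subjects`, `slope`.
#' @examples
#' d <- data.frame(subject_id = rep(1:4, each = 3),
#'                 x = rep(1:3, 4), c = rep(c(0, 5, 9, 2), each = 3))
#' d$y <- d$x + d$c
#' rmcorr(d, "x", "y")$r  # 1: perfect within-subject line
#' @export
rmcorr <- function(data, x, y, subject = "subject_id") {
  miss <- setdiff(c(x, y, subject), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  d <- data[complete.cases(data[[x]], data[[y]]), c(subject, x, y)]
  cnt <- table(d[[subject]])
  d <- d[d[[subject]] %in% names(cnt)[cnt >= 2], ]
  k <- length(unique(d[[subject]]))
  n <- nrow(d)
  if (k < 2) stop("need >= 2 subjects with >= 2 complete pairs",
                  call. = FALSE)
  df <- n - k - 1
  if (df < 1) stop("insufficient data: df = N_obs - N_subjects - 1 < 1",
                   call. = FALSE)
  xc <- d[[x]] - ave(d[[x]], d[[subject]])
  yc <- d[[y]] - ave(d[[y]], d[[subject]])
  sxx <- sum(xc^2); syy <- sum(yc^2); sxy <- sum(xc * yc)
  if (sxx <= 0) stop("undefined correlation: x has no within-subject ",
                     "variance", call. = FALSE)
  if (syy <= 0) stop("undefined correlation: y has no within-subject ",
                     "variance", call. = FALSE)
  r <- sxy / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  t_stat <- if (abs(r) < 1) r * sqrt(df / (1 - r^2)) else sign(r) * Inf
  p <- 2 * pt(-abs(t_stat), df)
  structure(list(r = r, df = df, p = p, n_obs = n, n_subjects = k,
                 slope = sxy / sxx),
            class = "rmcorr_result")
}

#' @export
print.rmcorr_result <- function(x, ...) {
  cat(sprintf("Repeated-measures correlation: r = %.3f, df = %d, p = %.4g\n",
              x$r, x$df, x$p))
  if (!is.null(x$ci_low)) {
    cat(sprintf("  bootstrap %d%% CI [%.3f, %.3f] (%d resamples)\n",
                round(100 * (1 - x$ci_alpha)), x$ci_low, x$ci_high,
                x$n_boot))
  }
  invisible(x)
}

#' Subject-bootstrapped repeated-measures correlation
#'
#' Resamples subjects (clusters) with replacement, keeping each resampled
#' subject's complete visit set and treating duplicates as distinct
#' subjects, recomputes the repeated-measures correlation per replicate and
#' reports a percentile confidence interval. Cluster resampling preserves
#' the within-subject structure and relaxes distributional assumptions on
#' the markers. Replicates with insufficient degrees of freedom are redrawn
#' (up to 10 attempts) and otherwise dropped with a count.
#'
#' @inheritParams rmcorr
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed; the same seed reproduces the identical CI.
#' @param ci_alpha two-sided CI level complement (default 0.05 for a 95% CI).
#' @return `rmcorr_result` augmented with `ci_low`, `ci_high`, `n_boot`,
#'   `n_dropped`, `seed`, `r_boot` (the replicate estimates).
#' @export
bootstrap_rmcorr <- function(data, x, y, subject = "subject_id",
                             n_boot = 1000, seed = 1, ci_alpha = 0.05) {
  point <- rmcorr(data, x, y, subject)
  d <- data[complete.cases(data[[x]], data[[y]]), c(subject, x, y)]
  cnt <- table(d[[subject]])
  d <- d[d[[subject]] %in% names(cnt)[cnt >= 2], ]
  xc <- d[[x]] - ave(d[[x]], d[[subject]])
  yc <- d[[y]] - ave(d[[y]], d[[subject]])
  sid <- factor(d[[subject]])
  # per-subject sufficient statistics: centering is per subject, so a
  # duplicated subject contributes its own sums again
  sxx_i <- tapply(xc^2, sid, sum)
  syy_i <- tapply(yc^2, sid, sum)
  sxy_i <- tapply(xc * yc, sid, sum)
  n_i <- tabulate(sid)
  k <- nlevels(sid)

  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  r_boot <- rep(NA_real_, n_boot)
  n_dropped <- 0L
  for (b in seq_len(n_boot)) {
    for (try in seq_len(10L)) {
      idx <- sample.int(k, k, replace = TRUE)
      sxx <- sum(sxx_i[idx]); syy <- sum(syy_i[idx])
      df_b <- sum(n_i[idx]) - k - 1
      if (sxx > 0 && syy > 0 && df_b >= 1) {
        r_boot[b] <- sum(sxy_i[idx]) / sqrt(sxx * syy)
        break
      }
    }
    if (is.na(r_boot[b])) n_dropped <- n_dropped + 1L
  }
  rb <- r_boot[!is.na(r_boot)]
  ci <- quantile(rb, c(ci_alpha / 2, 1 - ci_alpha / 2), names = FALSE)
  out <- c(unclass(point),
           list(ci_low = ci[1], ci_high = ci[2], ci_alpha = ci_alpha,
                n_boot = n_boot, n_dropped = n_dropped, seed = seed,
                r_boot = r_boot))
  class(out) <- "rmcorr_result"
  out
}
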