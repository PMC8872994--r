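#' Distributional diagnostics for a grouped variable
#'
#' The screening battery run before choosing non-parametric tests: QQ plot
#' data against the normal, a Shapiro-Wilk normality p-value, Bartlett's,
#' Levene's (median-centered) and Fligner-Killeen's homogeneity-of-variance
#' tests across groups, and a Box-Cox suitability flag — TRUE when the
#' profile-likelihood optimal lambda transforms the variable to one that
#' passes Shapiro-Wilk at 0.05. Groups with fewer than 3 observations mark
#' the variance tests as not computable without failing the rest.
#'
#' @param values numeric measurements (positive values required for the
#'   Box-Cox profile; non-positive data skip that step).
#' @param groups group labels.
#' @return list of class `distribution_diagnostics`: `qq` (data.frame of
#'   theoretical and sample quantiles), `shapiro_p`, `bartlett`, `levene`,
#'   `fligner` (each a list with `statistic`, `p`, or NA when not
#'   computable), `boxcox_lambda`, `boxcox_suitable`.
#' @export
distribution_diagnostics <- function(values, groups) {
  keep <- complete.cases(values, groups)
  values <- values[keep]; groups <- factor(groups[keep])
  qq <- qqnorm(values, plot.it = FALSE)
  qq <- data.frame(theoretical = sort(qq$x), sample = sort(qq$y))
  shapiro_p <- if (length(values) >= 3 && length(values) <= 5000 &&
                   length(unique(values)) > 1) {
    shapiro.test(values)$p.value
  } else NA_real_

  enough <- all(table(groups) >= 3) && nlevels(groups) >= 2
  grab <- function(fn) {
    if (!enough) return(list(statistic = NA_real_, p = NA_real_))
    ht <- fn()
    list(statistic = unname(ht$statistic), p = ht$p.value)
  }
  bartlett <- grab(function() bartlett.test(values, groups))
  levene <- if (!enough) list(statistic = NA_real_, p = NA_real_) else {
    lt <- car::leveneTest(values, groups, center = median)
    list(statistic = lt[1, "F value"], p = lt[1, "Pr(>F)"])
  }
  fligner <- grab(function() fligner.test(values, groups))

  boxcox_lambda <- NA_real_
  boxcox_suitable <- FALSE
  if (all(values > 0) && length(values) >= 10 &&
      length(unique(values)) > 2) {
    bc <- MASS::boxcox(values ~ 1, lambda = seq(-3, 3, 0.05),
                       plotit = FALSE)
    boxcox_lambda <- bc$x[which.max(bc$y)]
    tv <- if (abs(boxcox_lambda) < 1e-8) log(values) else
      (values^boxcox_lambda - 1) / boxcox_lambda
    pv <- tryCatch(shapiro.test(tv)$p.value, error = function(e) 0)
    boxcox_suitable <- is.finite(pv) && pv > 0.05
  }
  structure(list(qq = qq, shapiro_p = shapiro_p, bartlett = bartlett,
                 levene = levene, fligner = fligner,
                 boxcox_lambda = boxcox_lambda,
                 boxcox_suitable = boxcox_suitable),
            class = "distribution_diagnostics")
}

#' @export
print.distribution_diagnostics <- function(x, ...) {
  cat(sprintf(
    "Shapiro p = %.3g | Bartlett p = %.3g | Levene p = %.3g | Fligner p = %.3g\n",
    x$shapiro_p, x$bartlett$p, x$levene$p, x$fligner$p))
  cat(sprintf("Box-Cox lambda = %.2f, suitable = %s\n", x$boxcox_lambda,
              x$boxcox_suitable))
  invisible(x)
}
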