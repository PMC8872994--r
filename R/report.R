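#' Longitudinal cohort report
#'
#' Runs the full longitudinal analysis over a long-format cohort table:
#' per-variable medians by timepoint, Kruskal-Wallis across timepoints with
#' Dunn's adjusted post hoc (the baseline vs. 2-month and baseline vs.
#' 12-month pairs highlighted), and subject-bootstrapped repeated-measures
#' correlations for the requested variable pairs. Marker variables enter the
#' correlation analysis on the log scale by default, matching their
#' right-skewed, strictly positive distributions.
#'
#' @param table cohort data.frame with at least `subject_id`, `timepoint`
#'   and the analysed variables.
#' @param variables columns to test across timepoints; defaults to every
#'   numeric column except identifiers.
#' @param pairs list of `c(x, y)` character pairs for repeated-measures
#'   correlation (or strings `"x:y"`).
#' @param alpha significance level (default 0.05).
#' @param adjust Dunn adjustment, `"sidak"` (default) or `"bh"`.
#' @param n_boot bootstrap resamples per pair; 0 skips the bootstrap and
#'   reports the plain fit.
#' @param log_markers log-transform strictly positive non-clinical variables
#'   before correlation (default TRUE; weight and BMI stay raw).
#' @param seed integer seed for the bootstrap.
#' @return list of class `mif_report`: `medians`, `kw`, `dunn`, `rmcorr`,
#'   `alpha`.
#' @export
run_longitudinal_report <- function(table, variables = NULL, pairs = list(),
                                    alpha = 0.05,
                                    adjust = c("sidak", "bh"),
                                    n_boot = 0, log_markers = TRUE,
                                    seed = 1) {
  adjust <- match.arg(adjust)
  required <- c("subject_id", "timepoint")
  miss <- setdiff(required, names(table))
  if (length(miss)) {
    stop("cohort table lacks required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(variables)) {
    variables <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                         c("timepoint"))
  }
  miss <- setdiff(variables, names(table))
  if (length(miss)) {
    stop("cohort table lacks variable columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tps <- sort(unique(table$timepoint))
  base_tp <- tps[1]

  med <- do.call(rbind, lapply(variables, function(v) {
    m <- tapply(table[[v]], table$timepoint, median, na.rm = TRUE)
    cbind(data.frame(variable = v, stringsAsFactors = FALSE),
          as.data.frame(as.list(m), check.names = FALSE))
  }))
  names(med)[-1] <- paste0("t", tps)

  kw <- do.call(rbind, lapply(variables, function(v) {
    res <- kruskal_wallis(table[[v]], table$timepoint)
    data.frame(variable = v, H = res$H, df = res$df, p = res$p,
               significant = res$p < alpha, stringsAsFactors = FALSE)
  }))

  dunn <- do.call(rbind, lapply(variables, function(v) {
    d <- dunn_posthoc(table[[v]], table$timepoint, adjust = adjust)
    d$variable <- v
    d$baseline_pair <- d$group1 == as.character(base_tp) |
      d$group2 == as.character(base_tp)
    d$significant <- d$p_adj < alpha
    d[, c("variable", "group1", "group2", "z", "p_raw", "p_adj",
          "baseline_pair", "significant")]
  }))

  parse_pair <- function(p) {
    if (length(p) == 1 && grepl(":", p)) strsplit(p, ":")[[1]] else p
  }
  rm_rows <- lapply(seq_along(pairs), function(i) {
    pr <- parse_pair(pairs[[i]])
    d <- table
    for (v in pr) {
      if (!v %in% names(d)) {
        stop("rmcorr pair refers to missing column: ", v, call. = FALSE)
      }
      if (log_markers && !v %in% c("weight", "bmi") && all(d[[v]] > 0,
                                                           na.rm = TRUE)) {
        d[[v]] <- log(d[[v]])
      }
    }
    res <- if (n_boot > 0) {
      bootstrap_rmcorr(d, pr[1], pr[2], n_boot = n_boot,
                       seed = seed + i)
    } else {
      rmcorr(d, pr[1], pr[2])
    }
    data.frame(x = pr[1], y = pr[2], r = res$r, df = res$df, p = res$p,
               ci_low = if (is.null(res$ci_low)) NA_real_ else res$ci_low,
               ci_high = if (is.null(res$ci_high)) NA_real_ else res$ci_high,
               significant = res$p < alpha, stringsAsFactors = FALSE)
  })
  rm_tab <- if (length(rm_rows)) do.call(rbind, rm_rows) else NULL

  structure(list(medians = med, kw = kw, dunn = dunn, rmcorr = rm_tab,
                 alpha = alpha, adjust = adjust),
            class = "mif_report")
}

#' @export
print.mif_report <- function(x, ...) {
  cat("== Medians by timepoint ==\n")
  print(x$medians, row.names = FALSE, digits = 4)
  cat("\n== Kruskal-Wallis across timepoints ==\n")
  print(x$kw, row.names = FALSE, digits = 4)
  cat(sprintf("\n== Dunn post hoc (%s-adjusted), baseline pairs ==\n",
              x$adjust))
  print(x$dunn[x$dunn$baseline_pair, ], row.names = FALSE, digits = 4)
  if (!is.null(x$rmcorr)) {
    cat("\n== Repeated-measures correlations ==\n")
    print(x$rmcorr, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
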