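#' Kruskal-Wallis test across groups
#'
#' Tie-corrected Kruskal-Wallis rank test (via [stats::kruskal.test()]) with
#' input validation suited to longitudinal marker tables: at least two
#' non-empty groups and three observations in total. All-identical values
#' give H = 0, p = 1 rather than an error.
#'
#' @param values numeric measurements.
#' @param groups group labels (e.g. timepoints), same length.
#' @param exact compute the p-value by exhaustive enumeration of group
#'   assignments instead of the chi-square approximation, which is
#'   inaccurate at very small N. Default: exact when N <= 10, asymptotic
#'   otherwise. The H statistic is identical either way.
#' @return list of class `kw_result`: `H`, `df`, `p`, `group_n`, `exact`.
#' @export
kruskal_wallis <- function(values, groups, exact = NULL) {
  keep <- complete.cases(values, groups)
  values <- values[keep]; groups <- factor(groups[keep])
  n_g <- table(groups)
  if (length(n_g) < 2 || any(n_g == 0)) {
    stop("need >= 2 non-empty groups", call. = FALSE)
  }
  if (length(values) < 3) stop("need >= 3 observations in total",
                               call. = FALSE)
  if (is.null(exact)) exact <- length(values) <= 10
  if (length(unique(values)) == 1) {
    res <- list(H = 0, df = length(n_g) - 1L, p = 1,
                group_n = as.integer(n_g), exact = FALSE)
  } else if (exact) {
    kt <- kruskal.test(values, groups)
    H_obs <- unname(kt$statistic)
    Hs <- .kw_permutation_stats(values, as.integer(n_g))
    res <- list(H = H_obs, df = unname(kt$parameter),
                p = mean(Hs >= H_obs - 1e-12),
                group_n = as.integer(n_g), exact = TRUE)
  } else {
    kt <- kruskal.test(values, groups)
    res <- list(H = unname(kt$statistic), df = unname(kt$parameter),
                p = kt$p.value, group_n = as.integer(n_g), exact = FALSE)
  }
  names(res$group_n) <- names(n_g)
  class(res) <- "kw_result"
  res
}

# H statistic for every distinct assignment of the pooled values into
# groups of the given sizes (multiset enumeration via nested combinations)
.kw_permutation_stats <- function(values, sizes) {
  idx_all <- seq_along(values)
  out <- numeric(0)
  recurse <- function(remaining, assigned) {
    gi <- length(assigned) + 1L
    if (gi == length(sizes)) {
      grp <- integer(length(values))
      for (j in seq_along(assigned)) grp[assigned[[j]]] <- j
      grp[remaining] <- gi
      out[[length(out) + 1L]] <<- unname(
        kruskal.test(values, factor(grp))$statistic)
      return(invisible())
    }
    cmb <- utils::combn(remaining, sizes[gi])
    for (c_ in seq_len(ncol(cmb))) {
      pick <- cmb[, c_]
      recurse(setdiff(remaining, pick), c(assigned, list(pick)))
    }
  }
  recurse(idx_all, list())
  unlist(out)
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g (n = %s)\n",
              x$H, x$df, x$p, paste(x$group_n, collapse = "/")))
  invisible(x)
}

#' Dunn's post hoc pairwise comparisons
#'
#' For every pair of groups following a Kruskal-Wallis test, computes the
#' pooled-rank z statistic
#' \deqn{z = (\bar R_i - \bar R_j) / \sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum(t^3 - t)}{12(N-1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)}}
#' with a tie correction, a two-sided normal p-value, and a family-wise
#' adjustment over the m = k(k-1)/2 pairs: Sidak
#' \eqn{1 - (1 - p)^m} (default) or Benjamini-Hochberg step-up.
#'
#' @param values numeric measurements.
#' @param groups group labels.
#' @param adjust `"sidak"` or `"bh"`.
#' @return data.frame of class `dunn_result`: `group1, group2, z, p_raw,
#'   p_adj` plus attribute `method`.
#' @export
dunn_posthoc <- function(values, groups, adjust = c("sidak", "bh")) {
  adjust <- match.arg(adjust)
  keep <- complete.cases(values, groups)
  values <- values[keep]; groups <- factor(groups[keep])
  n_g <- table(groups)
  if (any(n_g == 0) || length(n_g) < 2) {
    stop("need >= 2 non-empty groups", call. = FALSE)
  }
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  g <- names(n_g)
  pairs <- utils::combn(g, 2)
  m <- ncol(pairs)
  z <- p_raw <- numeric(m)
  for (k in seq_len(m)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(var_base * (1 / n_g[[i]] + 1 / n_g[[j]]))
    z[k] <- (rbar[[i]] - rbar[[j]]) / se
    p_raw[k] <- 2 * pnorm(-abs(z[k]))
  }
  p_adj <- if (adjust == "sidak") {
    pmin(1, 1 - (1 - p_raw)^m)
  } else {
    p.adjust(p_raw, method = "BH")
  }
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
                    p_raw = p_raw, p_adj = p_adj, stringsAsFactors = FALSE)
  attr(out, "method") <- adjust
  class(out) <- c("dunn_result", "data.frame")
  out
}
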