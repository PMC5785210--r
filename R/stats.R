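#' Group summaries: mean +/- SEM and boxplot statistics
#'
#' Per group: n, mean, SEM (`sd/sqrt(n)`, sample SD), and the boxplot
#' convention used throughout this analysis: central line at the median,
#' box at the 25th/75th percentiles, whiskers to the furthest points within
#' 1.5 x IQR of the box, points beyond as outliers, and the 95% notch-style
#' confidence interval of the median (`median +/- 1.57 * IQR / sqrt(n)`).
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length as `values`; alternatively pass
#'   a named list of numeric vectors as `values`.
#' @return A `group_summary` data.frame, one row per group, with an
#'   `outliers` attribute (named list).
#' @export
summarize_groups <- function(values, groups = NULL) {
  gl <- if (is.list(values)) values else split(values, groups)
  if (length(gl) == 0L || any(vapply(gl, length, 0L) == 0L))
    stop("every group must contain at least one observation")
  out_list <- list()
  rows <- lapply(names(gl), function(g) {
    x <- gl[[g]]
    n <- length(x)
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3L] - q[1L]
    lo_fence <- q[1L] - 1.5 * iqr
    hi_fence <- q[3L] + 1.5 * iqr
    inside <- x >= lo_fence & x <= hi_fence
    out_list[[g]] <<- x[!inside]
    data.frame(group = g, n = n, mean = mean(x),
               sem = if (n > 1L) sd(x) / sqrt(n) else 0,
               median = q[2L], q25 = q[1L], q75 = q[3L],
               whisker_lo = min(x[inside]), whisker_hi = max(x[inside]),
               ci95_lo = q[2L] - 1.57 * iqr / sqrt(n),
               ci95_hi = q[2L] + 1.57 * iqr / sqrt(n),
               n_outliers = sum(!inside))
  })
  out <- do.call(rbind, rows)
  attr(out, "outliers") <- out_list
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Two-tailed Student's t test
#'
#' Equal-variance (Student's) two-sample t test, two-tailed — the form
#' stated in the statistics conventions; Welch's correction is available
#' behind `var_equal = FALSE`.
#'
#' @param group_a,group_b numeric vectors (n >= 2 each).
#' @param var_equal pool the variances (Student's test) when `TRUE`.
#' @return A `test_result`: `test`, `statistic` (t), `df`, `p_value`.
#' @export
two_tailed_t <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 observations")
  if (var(group_a) == 0 && var(group_b) == 0)
    stop("zero pooled variance; t statistic undefined")
  ht <- t.test(group_a, group_b, var.equal = var_equal)
  structure(list(test = if (var_equal) "Student t (two-tailed)" else
                   "Welch t (two-tailed)",
                 statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, pairwise = NULL),
            class = "test_result")
}

#' One-way ANOVA with Bonferroni post hoc comparisons
#'
#' Classical one-way ANOVA F test across groups, followed by all pairwise
#' equal-variance t tests with Bonferroni adjustment (raw p multiplied by
#' the number of pairs, capped at 1).
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param post_hoc run the pairwise comparisons (default TRUE when > 2
#'   groups).
#' @return A `test_result` with `statistic` (F), `df` (between, within),
#'   `p_value`, and `pairwise` (data.frame `group_a`, `group_b`, `p_raw`,
#'   `p_adjusted`).
#' @export
one_way_anova <- function(groups, post_hoc = length(groups) > 2L) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  if (length(groups) < 2L) stop("need at least 2 groups")
  ns <- vapply(groups, length, 0L)
  if (any(ns < 2L)) stop("every group needs at least 2 observations")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), ns), levels = names(groups))
  ht <- oneway.test(x ~ g, var.equal = TRUE)
  pw <- NULL
  if (post_hoc) {
    pairs <- combn(names(groups), 2L)
    n_pairs <- ncol(pairs)
    pw <- do.call(rbind, lapply(seq_len(n_pairs), function(k) {
      a <- pairs[1L, k]
      b <- pairs[2L, k]
      p <- t.test(groups[[a]], groups[[b]], var.equal = TRUE)$p.value
      data.frame(group_a = a, group_b = b, p_raw = p,
                 p_adjusted = min(1, p * n_pairs))
    }))
  }
  structure(list(test = "one-way ANOVA (Bonferroni post hoc)",
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value,
                 pairwise = pw),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, p = %.4g %s\n", x$test,
              x$statistic, x$p_value, significance_stars(x$p_value)))
  if (!is.null(x$pairwise)) {
    cat("pairwise (Bonferroni-adjusted):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Significance stars at the conventional cutoffs
#'
#' `*` p < 0.05, `**` p < 0.005, `***` p < 0.0005.
#'
#' @param p p value(s).
#' @return character vector of star labels (`"ns"` when not significant).
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.0005) "***" else if (pi < 0.005) "**" else if (pi < 0.05) "*"
    else "ns"
  }, "")
}
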