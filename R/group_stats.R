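# Group-summary statistics computable from printed means/SDs/ns as well as
# from raw vectors: standardization, Welch's t from summaries, pooled-SD
# Cohen's d.

#' Scale and center a numeric vector
#'
#' Subtracts the mean and divides by the sample SD of the non-missing
#' values; missing values pass through unchanged.
#'
#' @param x Numeric vector with at least 2 non-missing values.
#' @param name Column name used in error messages.
#' @return Standardized vector (mean 0, sample SD 1 over non-missing
#'   entries).
#' @export
standardize <- function(x, name = deparse(substitute(x))) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) {
    stop_validation(sprintf("`%s` needs >= 2 non-missing values to standardize",
                            name))
  }
  s <- stats::sd(x[ok])
  if (s == 0) {
    stop_validation(sprintf("`%s` is constant and cannot be standardized", name))
  }
  (x - mean(x[ok])) / s
}

#' Welch's two-sample t-test from group summaries
#'
#' Computes the Welch statistic and Welch-Satterthwaite degrees of freedom
#' directly from per-group mean, SD and n (the quantities papers print),
#' with a two-sided p-value.
#'
#' @param mean1,sd1,n1 First group's summary.
#' @param mean2,sd2,n2 Second group's summary.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  for (nm in c("n1", "n2")) assert_number(get(nm), nm, lower = 2)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pooled-SD Cohen's d from group summaries
#'
#' `d = (mean1 - mean2) / s_p` with
#' `s_p = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @inheritParams welch_t
#' @return Cohen's d.
#' @export
cohens_d_pooled <- function(mean1, sd1, n1, mean2, sd2, n2) {
  for (nm in c("n1", "n2")) assert_number(get(nm), nm, lower = 2)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) stop_validation("both group SDs are zero: d undefined")
  (mean1 - mean2) / sp
}

#' Per-group mean/SD/n summary of a measure
#'
#' @param values Numeric vector.
#' @param group Factor-like vector with exactly two levels.
#' @return `data.frame` with one row per group: `group`, `mean`, `sd`, `n`.
#' @export
group_summary <- function(values, group) {
  g <- factor(group)
  if (nlevels(g) != 2L) stop_validation("group must have exactly two levels")
  ok <- !is.na(values)
  out <- do.call(rbind, lapply(levels(g), function(l) {
    v <- values[ok & g == l]
    data.frame(group = l, mean = mean(v), sd = stats::sd(v), n = length(v),
               stringsAsFactors = FALSE)
  }))
  if (any(out$n < 2L)) stop_validation("each group needs >= 2 observations")
  out
}
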