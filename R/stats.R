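# Nonparametric statistics connecting engraftment outputs to covariates.
# Both wrappers delegate to the stats package and standardise the reported
# conventions: Spearman rho with a two-sided p-value, and the rank-sum test
# reported both as the Mann-Whitney U of each group ordering and as the raw
# rank sum, since "W" means different things in different software.

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks, with a two-sided p-value (exact
#' permutation null for `n <= 9` without ties, t approximation otherwise).
#' Pairs with missing values are dropped. A constant input leaves rho
#' undefined (`defined = FALSE`).
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs for a
#'   p-value).
#' @return List: `rho`, `p_value`, `n`, `defined`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n, defined = FALSE))
  }
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = (n <= 9L && !ties)))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n, defined = TRUE)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test of `a` vs `b` with mid-ranks for ties. Uses the
#' exact null when `n1 * n2 <= 400` and there are no ties, and the normal
#' approximation with continuity correction otherwise. `U` is the
#' Mann-Whitney statistic of the first group (the rank sum minus its minimum
#' possible value — what R's `wilcox.test` calls `W`); `U_other = n1 n2 - U`
#' is the complementary statistic, and `rank_sum` the raw rank sum of `a`.
#'
#' @param a,b Non-empty numeric vectors.
#' @return List: `U`, `U_other`, `rank_sum`, `p_value`, `n1`, `n2`.
#' @export
rank_sum_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0L
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = (n1 * n2 <= 400L && !ties),
                       correct = TRUE))
  u <- unname(wt$statistic)
  list(U = u, U_other = n1 * n2 - u, rank_sum = u + n1 * (n1 + 1) / 2,
       p_value = wt$p.value, n1 = n1, n2 = n2)
}

#' Cohort-level engraftment summary
#'
#' Aggregates per-triad engraftment rates (triads with undefined rates are
#' excluded and counted separately) and provenance abundance fractions, and
#' tests the pre- vs post-FMT shift of the recipient-derived and
#' always-shared fractions with rank-sum tests, in both group orderings.
#'
#' @param results List of [engraftment_rate()] results.
#' @param partitions data.frame of stacked [provenance_fractions()] rows
#'   (both stages).
#' @return List of class `cohort_summary`: `rates` (mean/median/min/max,
#'   `n_defined`, `n_undefined`), `mean_fractions` (per stage and class), and
#'   `tests` (rank-sum results for recipient-derived and always-shared
#'   fractions, pre vs post and post vs pre).
#' @export
summarize_cohort <- function(results, partitions) {
  rates <- vapply(results, `[[`, numeric(1), "rate_percent")
  defined <- vapply(results, `[[`, logical(1), "defined")
  if (!any(defined)) stop("all engraftment rates are undefined", call. = FALSE)
  r <- rates[defined]

  classes <- c("fraction_always_shared", "fraction_donor_derived",
               "fraction_recipient_derived", "fraction_environmental")
  mean_frac <- function(stage) {
    rows <- partitions[partitions$stage == stage, classes, drop = FALSE]
    colMeans(rows)
  }
  pre <- partitions[partitions$stage == "preFMT", , drop = FALSE]
  post <- partitions[partitions$stage == "postFMT", , drop = FALSE]

  shift_test <- function(col) {
    list(pre_vs_post = rank_sum_test(pre[[col]], post[[col]]),
         post_vs_pre = rank_sum_test(post[[col]], pre[[col]]))
  }

  structure(list(
    rates = list(mean = mean(r), median = stats::median(r),
                 min = min(r), max = max(r),
                 n_defined = sum(defined), n_undefined = sum(!defined)),
    mean_fractions = list(preFMT = mean_frac("preFMT"),
                          postFMT = mean_frac("postFMT")),
    tests = list(
      recipient_derived = shift_test("fraction_recipient_derived"),
      always_shared = shift_test("fraction_always_shared"))),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort engraftment summary\n")
  cat(sprintf("  rates (%% of eligible donor ASVs), %d triads (%d undefined):\n",
              x$rates$n_defined + x$rates$n_undefined, x$rates$n_undefined))
  cat(sprintf("    mean %.2f | median %.2f | range %.2f-%.2f\n",
              x$rates$mean, x$rates$median, x$rates$min, x$rates$max))
  fmt_frac <- function(v) paste(sprintf("%s %.1f%%",
                                        sub("fraction_", "", names(v)),
                                        100 * v), collapse = ", ")
  cat("  mean abundance fractions pre-FMT: ",
      fmt_frac(x$mean_fractions$preFMT), "\n", sep = "")
  cat("  mean abundance fractions post-FMT: ",
      fmt_frac(x$mean_fractions$postFMT), "\n", sep = "")
  t1 <- x$tests$recipient_derived$pre_vs_post
  t2 <- x$tests$always_shared$pre_vs_post
  cat(sprintf("  recipient-derived fraction pre vs post: U = %.0f, p = %.3g\n",
              t1$U, t1$p_value))
  cat(sprintf("  always-shared fraction pre vs post:     U = %.0f, p = %.3g\n",
              t2$U, t2$p_value))
  invisible(x)
}
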