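# Nonparametric group comparisons: two-sample Kolmogorov-Smirnov for
# cumulative distributions, Kruskal-Wallis for three or more groups with
# Dunn's multiple-comparison post-test (Bonferroni-adjusted).

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' @param sample_a,sample_b Numeric samples (each n >= 5).
#' @return An object of class `group_comparison` with the KS statistic D and
#'   p-value; no post-hoc table.
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  sample_a <- sample_a[is.finite(sample_a)]
  sample_b <- sample_b[is.finite(sample_b)]
  if (length(sample_a) < 5 || length(sample_b) < 5) {
    abort("each sample needs at least 5 finite values")
  }
  ht <- suppressWarnings(ks.test(sample_a, sample_b))
  structure(
    list(
      test = "Two-sample Kolmogorov-Smirnov",
      statistic = unname(ht$statistic),
      p_value = ht$p.value,
      n = c(length(sample_a), length(sample_b)),
      posthoc = NULL
    ),
    class = "group_comparison"
  )
}

# Dunn's z statistics from pooled ranks with tie correction
dunn_posthoc <- function(values, groups, p_adjust_method) {
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_ranks <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  gl <- names(mean_ranks)
  pairs <- utils::combn(gl, 2)
  z <- apply(pairs, 2, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) *
                 (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    (mean_ranks[[pr[1]]] - mean_ranks[[pr[2]]]) / se
  })
  p_raw <- 2 * pnorm(-abs(z))
  tibble(
    group_1 = pairs[1, ], group_2 = pairs[2, ], z = as.numeric(z),
    p_value = p_raw,
    p_adjusted = p.adjust(p_raw, method = p_adjust_method)
  )
}

#' Kruskal-Wallis test with Dunn's post-test
#'
#' Compares the medians of three or more groups with the Kruskal-Wallis rank
#' test; pairwise Dunn z statistics (pooled ranks, tie-corrected) follow,
#' with Bonferroni family correction by default.
#'
#' @param data Data frame in long format.
#' @param value,group Columns holding the measurements and group labels
#'   (tidy-eval).
#' @param p_adjust_method Multiplicity adjustment for the post-hoc p-values
#'   (any method of [stats::p.adjust()]).
#' @return An object of class `group_comparison` with the H statistic,
#'   p-value, and the pairwise post-hoc tibble.
#' @export
#' @examples
#' d <- data.frame(y = c(rnorm(20), rnorm(20), rnorm(20, 2)),
#'                 g = rep(c("a", "b", "c"), each = 20))
#' kruskal_dunn(d, y, g)
kruskal_dunn <- function(data, value, group, p_adjust_method = "bonferroni") {
  values <- dplyr::pull(data, {{ value }})
  groups <- as.factor(dplyr::pull(data, {{ group }}))
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(groups[keep])
  if (nlevels(groups) < 3) abort("need at least 3 groups")
  if (any(table(groups) < 2)) abort("every group needs at least 2 observations")
  ht <- kruskal.test(values, groups)
  structure(
    list(
      test = "Kruskal-Wallis with Dunn's post-test",
      statistic = unname(ht$statistic),
      p_value = ht$p.value,
      n = as.integer(table(groups)),
      posthoc = dunn_posthoc(values, groups, p_adjust_method)
    ),
    class = "group_comparison"
  )
}

#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, p_value = x$p_value,
         n_total = sum(x$n))
}

#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  if (is.null(x$posthoc)) {
    tibble(statistic = x$statistic, p_value = x$p_value)
  } else {
    x$posthoc
  }
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n",
              x$test, x$statistic, x$p_value, paste(x$n, collapse = ", ")))
  if (!is.null(x$posthoc)) {
    cat("Post-hoc pairwise comparisons:\n")
    print(x$posthoc, ...)
  }
  invisible(x)
}
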