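#' One-tailed pooled-variance two-sample t-test
#'
#' Tests H1: mean(a) > mean(b) with the classic pooled-variance Student
#' statistic at `|a| + |b| - 2` degrees of freedom. Welch's unequal
#' variance form is available via `var_equal = FALSE`.
#'
#' @param a,b numeric samples (each of size >= 2 with nonzero variance).
#' @param var_equal pooled variance (default) or Welch.
#' @return list with `statistic`, `p`, `df`, `mean_a`, `mean_b`, `n_a`,
#'   `n_b`.
#' @export
t_test_one_tailed <- function(a, b, var_equal = TRUE) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stopf("both samples need at least 2 values")
  va <- var(a); vb <- var(b)
  if (va <= 0 || vb <= 0) stopf("degenerate sample (zero variance)")
  if (var_equal) {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tt <- (mean(a) - mean(b)) / se
  list(statistic = tt, p = pt(tt, df, lower.tail = FALSE), df = df,
       mean_a = mean(a), mean_b = mean(b), n_a = na, n_b = nb)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, p * family_size)`. The family size may exceed the
#' number of p-values supplied (tests belonging to a larger family).
#'
#' @param p_values numeric vector of raw p-values.
#' @param family_size number of tests in the family (>= length(p_values)).
#' @return adjusted p-values, same length as the input.
#' @export
bonferroni_adjust <- function(p_values, family_size = length(p_values)) {
  if (family_size < 1) stopf("`family_size` must be >= 1")
  if (family_size < length(p_values))
    stopf("`family_size` must be at least the number of tests")
  pmin(1, p_values * family_size)
}

#' One-sided permutation test for a gyral-sulcal mean difference
#'
#' The observed statistic is `mean(values[gyral]) - mean(values[sulcal])`.
#' The null distribution is built by randomly relabeling the values with
#' the same group sizes `n_perm` times; the one-sided p-value uses the
#' add-one estimator `(1 + #(null >= observed)) / (n_perm + 1)`, so it is
#' never exactly zero. Deterministic given `seed`.
#'
#' @param values numeric accuracy values.
#' @param labels logical or `"gyri"`/`"sulci"` labels (TRUE / `"gyri"` =
#'   gyral), same length as `values`; both groups must be present.
#' @param n_perm number of relabelings (>= 1, default 1000).
#' @param seed integer seed.
#' @return list with `observed_diff`, `p`, `n_perm`, `n_gyri`, `n_sulci`.
#' @export
permutation_mean_diff <- function(values, labels, n_perm = 1000, seed = 1) {
  if (is.character(labels) || is.factor(labels)) labels <- labels == "gyri"
  labels <- as.logical(labels)
  if (length(values) != length(labels)) stopf("length mismatch")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stopf("both labels must be present")
  if (n_perm < 1) stopf("`n_perm` must be >= 1")
  observed <- mean(values[labels]) - mean(values[!labels])
  tot <- sum(values); n <- length(values)
  withr::with_seed(as.integer(seed), {
    count <- 0L
    for (i in seq_len(n_perm)) {
      g <- sum(values[sample.int(n, n1)])
      null_diff <- g / n1 - (tot - g) / n0
      if (null_diff >= observed - 1e-12) count <- count + 1L
    }
    list(observed_diff = observed, p = (1 + count) / (n_perm + 1),
         n_perm = as.integer(n_perm), n_gyri = n1, n_sulci = n0)
  })
}

#' Pearson correlation with a two-sided t-based p-value
#'
#' `r` from [stats::cor()] and `p` from the exact-null transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` at `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, nonzero variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 3) stopf("need equal-length samples of size >= 3")
  if (pop_sd(x) < 1e-12 || pop_sd(y) < 1e-12)
    stopf("zero variance; correlation undefined")
  r <- cor(x, y)
  p <- if (abs(r) >= 1) .Machine$double.xmin
       else max(2 * pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2),
                .Machine$double.xmin)
  list(r = r, p = p, n = n)
}

#' Proportion of subjects with a significant gyral/sulcal difference
#'
#' Aggregates per-subject, per-network significance flags (already
#' multiple-comparison adjusted) into the per-network proportion of
#' significant subjects.
#'
#' @param results data.frame with columns `subject`, `network_id` and
#'   logical `significant`.
#' @return data.frame with `network_id`, `n_subjects`, `n_significant`,
#'   `proportion`.
#' @export
subject_proportion <- function(results) {
  stopifnot(all(c("subject", "network_id", "significant") %in% names(results)))
  if (nrow(results) < 1) stopf("need at least one subject")
  nets <- unique(results$network_id)
  do.call(rbind, lapply(nets, function(nid) {
    sub <- results[results$network_id == nid, ]
    data.frame(network_id = nid,
               n_subjects = length(unique(sub$subject)),
               n_significant = sum(sub$significant),
               proportion = sum(sub$significant) / length(unique(sub$subject)))
  }))
}
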