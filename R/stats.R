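#' Comparison result container
#'
#' Every group comparison in the package (`student_t()`,
#' `wilcoxon_signed_rank()`, `compare_networks()`, `compare_assays()`,
#' `compare_profile_maps()`) returns a `comparison_result`: the test name, the
#' statistic, its degrees of freedom (or effective sample size for rank
#' tests), the two-tailed p-value, per-group summaries and any degeneracy
#' flags. Use [generics::tidy()] / [generics::glance()] to get tibbles.
#'
#' @param test character scalar naming the test.
#' @param statistic numeric test statistic.
#' @param df degrees of freedom (`NA` for rank tests).
#' @param n_effective effective sample size after dropping zero differences
#'   (`NA` for t tests).
#' @param p_value two-tailed p-value in `[0, 1]`.
#' @param groups tibble of per-group summaries (`group`, `n`, `mean`, `se`).
#' @param flags character vector of degeneracy flags (possibly empty), e.g.
#'   `"zero-variance"`, `"degenerate"`, `"small-sample-exact"`.
#' @return An object of class `comparison_result`.
#' @keywords internal
new_comparison_result <- function(test, statistic, df = NA_real_,
                                  n_effective = NA_integer_, p_value,
                                  groups = NULL, flags = character()) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(
    list(
      test = test,
      statistic = statistic,
      df = df,
      n_effective = n_effective,
      p_value = min(1, p_value),
      groups = groups,
      flags = flags
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(x$test, "\n")
  cat(sprintf("  statistic = %.6g", x$statistic))
  if (!is.na(x$df)) cat(sprintf(", df = %g", x$df))
  if (!is.na(x$n_effective)) cat(sprintf(", n_effective = %d", x$n_effective))
  cat(sprintf(", two-tailed p = %.5g\n", x$p_value))
  if (!is.null(x$groups)) {
    print(x$groups)
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a comparison result
#'
#' @param x a `comparison_result`.
#' @param ... unused.
#' @return A one-row tibble with `test`, `statistic`, `df`, `n_effective`,
#'   `p_value` and a comma-separated `flags` column.
#' @exportS3Method generics::tidy
tidy.comparison_result <- function(x, ...) {
  tibble::tibble(
    test = x$test,
    statistic = x$statistic,
    df = x$df,
    n_effective = x$n_effective,
    p_value = x$p_value,
    flags = paste(x$flags, collapse = ",")
  )
}

#' @rdname tidy.comparison_result
#' @exportS3Method generics::glance
glance.comparison_result <- function(x, ...) {
  out <- tidy.comparison_result(x)
  if (!is.null(x$groups) && nrow(x$groups) == 2) {
    out$mean_a <- x$groups$mean[1]
    out$mean_b <- x$groups$mean[2]
  }
  out
}

group_summary_tbl <- function(a, b, labels = c("A", "B")) {
  tibble::tibble(
    group = labels,
    n = c(length(a), length(b)),
    mean = c(mean(a), mean(b)),
    se = c(stats::sd(a) / sqrt(length(a)), stats::sd(b) / sqrt(length(b)))
  )
}

#' Two-tailed Student's t-test (pooled variance)
#'
#' Classical Student's t: pooled-variance two-sample t for unpaired data, or a
#' one-sample t on the paired differences. The pooled form (not Welch) is the
#' default because the package targets the equal-variance test convention of
#' its application area; set `welch = TRUE` for the Welch-Satterthwaite
#' variant.
#'
#' Degenerate inputs are flagged rather than erroring: when every observation
#' is identical across both groups (zero pooled variance, equal means) the
#' result carries `p = 1` and a `"zero-variance"` flag; zero variance with
#' unequal means yields an infinite statistic, `p = 0` and a `"degenerate"`
#' flag.
#'
#' @param group_a,group_b numeric vectors of observations (for `paired = TRUE`
#'   they must have equal length and are differenced elementwise).
#' @param paired logical; paired test on `group_a - group_b`.
#' @param welch logical; use Welch's unequal-variance t instead of the pooled
#'   form (unpaired only).
#' @return A [comparison result][new_comparison_result].
#' @examples
#' student_t(c(1, 2, 3), c(4, 5, 6))
#' @export
student_t <- function(group_a, group_b, paired = FALSE, welch = FALSE) {
  group_a <- as.numeric(group_a)
  group_b <- as.numeric(group_b)
  if (paired) {
    if (length(group_a) != length(group_b)) {
      stop("paired test requires equal-length groups", call. = FALSE)
    }
    if (length(group_a) < 2) stop("paired test requires n >= 2", call. = FALSE)
    d <- group_a - group_b
    n <- length(d)
    sd_d <- stats::sd(d)
    groups <- group_summary_tbl(group_a, group_b)
    if (sd_d == 0) {
      if (mean(d) == 0) {
        return(new_comparison_result("paired Student's t", 0, df = n - 1,
                                     p_value = 1, groups = groups,
                                     flags = "zero-variance"))
      }
      return(new_comparison_result("paired Student's t",
                                   sign(mean(d)) * Inf, df = n - 1,
                                   p_value = 0, groups = groups,
                                   flags = "degenerate"))
    }
    t_stat <- mean(d) / (sd_d / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
    return(new_comparison_result("paired Student's t", t_stat, df = n - 1,
                                 p_value = p, groups = groups))
  }

  n_a <- length(group_a)
  n_b <- length(group_b)
  if (n_a < 2 || n_b < 2) {
    stop("each group requires n >= 2 observations", call. = FALSE)
  }
  groups <- group_summary_tbl(group_a, group_b)
  v_a <- stats::var(group_a)
  v_b <- stats::var(group_b)
  delta <- mean(group_a) - mean(group_b)
  if (welch) {
    se2 <- v_a / n_a + v_b / n_b
    if (se2 == 0) {
      if (delta == 0) {
        return(new_comparison_result("Welch's t", 0, df = n_a + n_b - 2,
                                     p_value = 1, groups = groups,
                                     flags = "zero-variance"))
      }
      return(new_comparison_result("Welch's t", sign(delta) * Inf,
                                   df = n_a + n_b - 2, p_value = 0,
                                   groups = groups, flags = "degenerate"))
    }
    df <- se2^2 / ((v_a / n_a)^2 / (n_a - 1) + (v_b / n_b)^2 / (n_b - 1))
    t_stat <- delta / sqrt(se2)
    p <- 2 * stats::pt(-abs(t_stat), df = df)
    return(new_comparison_result("Welch's t", t_stat, df = df, p_value = p,
                                 groups = groups))
  }
  sp2 <- ((n_a - 1) * v_a + (n_b - 1) * v_b) / (n_a + n_b - 2)
  df <- n_a + n_b - 2
  if (sp2 == 0) {
    if (delta == 0) {
      return(new_comparison_result("unpaired Student's t (pooled)", 0,
                                   df = df, p_value = 1, groups = groups,
                                   flags = "zero-variance"))
    }
    return(new_comparison_result("unpaired Student's t (pooled)",
                                 sign(delta) * Inf, df = df, p_value = 0,
                                 groups = groups, flags = "degenerate"))
  }
  t_stat <- delta / sqrt(sp2 * (1 / n_a + 1 / n_b))
  p <- 2 * stats::pt(-abs(t_stat), df = df)
  new_comparison_result("unpaired Student's t (pooled)", t_stat, df = df,
                        p_value = p, groups = groups)
}

# Exact null distribution of the signed-rank sum W+ under independent sign
# flips, as a probability vector over 2*W (doubled so midranks stay integral).
# Returned vector p has p[k+1] = P(2*W+ = k), k = 0..sum(2*ranks).
signed_rank_null <- function(ranks2) {
  total <- sum(ranks2)
  p <- numeric(total + 1)
  p[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), p[seq_len(total + 1 - r)])
    p <- (p + shifted) / 2
  }
  p
}

#' Wilcoxon signed-rank test with exact tie-aware null
#'
#' Two-tailed Wilcoxon signed-rank on a vector of paired differences. Zero
#' differences are dropped (the classic Wilcoxon convention); absolute values
#' are ranked with midranks for ties. For `n_effective <=` `exact_limit` the
#' two-tailed p-value is computed from the exact null distribution of the
#' positive-rank sum under all sign flips (a tie-aware dynamic program,
#' identical to full enumeration); for larger n a normal approximation with
#' continuity correction and tie-corrected variance is used.
#'
#' The two-tailed p is `P(|W - mu| >= |w - mu|)` under the (symmetric) null,
#' where `mu = n(n+1)/4`; for the exact branch this equals the sign-flip
#' enumeration probability.
#'
#' @param differences numeric vector of paired differences.
#' @param exact_limit use the exact distribution when the number of nonzero
#'   differences is at most this (default 25).
#' @return A [comparison result][new_comparison_result] with `statistic` = W+
#'   (sum of ranks of positive differences), `n_effective`, and flags
#'   `"small-sample-exact"` or `"zero-variance"` where applicable.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6))   # exact p = 2/64
#' @export
wilcoxon_signed_rank <- function(differences, exact_limit = 25) {
  d <- as.numeric(differences)
  d <- d[!is.na(d)]
  nonzero <- d[d != 0]
  n <- length(nonzero)
  if (n == 0) {
    return(new_comparison_result("Wilcoxon signed-rank", statistic = 0,
                                 n_effective = 0L, p_value = 1,
                                 flags = "zero-variance"))
  }
  r <- rank(abs(nonzero))           # midranks for ties
  w_pos <- sum(r[nonzero > 0])
  mu <- n * (n + 1) / 4

  if (n <= exact_limit) {
    ranks2 <- as.integer(round(2 * r))
    null <- signed_rank_null(ranks2)
    w2 <- round(2 * w_pos)
    mu2 <- sum(ranks2) / 2
    dev <- abs(w2 - mu2)
    support <- seq_along(null) - 1
    p <- sum(null[abs(support - mu2) >= dev - 1e-9])
    return(new_comparison_result("Wilcoxon signed-rank (exact)",
                                 statistic = w_pos, n_effective = as.integer(n),
                                 p_value = p, flags = "small-sample-exact"))
  }

  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) {
    return(new_comparison_result("Wilcoxon signed-rank (normal approx.)",
                                 statistic = w_pos, n_effective = as.integer(n),
                                 p_value = 1, flags = "zero-variance"))
  }
  dev <- abs(w_pos - mu)
  z <- (dev - 0.5) / sqrt(sigma2)   # continuity correction
  p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  new_comparison_result("Wilcoxon signed-rank (normal approx.)",
                        statistic = w_pos, n_effective = as.integer(n),
                        p_value = p)
}
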