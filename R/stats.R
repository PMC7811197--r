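#' Exact Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Computes the exact two-sided p-value from the null permutation
#' distribution of the rank-sum statistic, with mid-ranks for ties: every
#' assignment of the pooled (tied) ranks to the smaller group is
#' enumerated, and p is the null probability of a rank-sum deviation from
#' its mean at least as large as the one observed. The null distribution
#' is symmetric, so this equals doubling the smaller tail. With samples of
#' 3 and 23 in complete separation this yields 2/choose(26, 3) = 2/2600,
#' printed as 0.0008.
#'
#' Exact enumeration is used when the smaller sample has at most
#' `exact_max` observations (and the number of assignments is manageable);
#' larger designs fall back to the tie-corrected normal approximation with
#' continuity correction, flagged in the output.
#'
#' @param x,y numeric samples (no missing values).
#' @param exact_max largest size of the smaller sample for which the exact
#'   distribution is enumerated.
#' @return An `rm_test_result` tibble (one row): `method`, `statistic`
#'   (Mann-Whitney U of `x`), `p_two_tailed`, `exact`, `n1`, `n2`.
#' @examples
#' exact_mann_whitney(c(10, 11, 12), rnorm(23))  # complete separation
#' @export
exact_mann_whitney <- function(x, y, exact_max = 10) {
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed", call. = FALSE)
  n1 <- length(x); n2 <- length(y); n_tot <- n1 + n2
  r <- rank(c(x, y))
  w_x <- sum(r[seq_len(n1)])
  u_x <- w_x - n1 * (n1 + 1) / 2
  n_small <- min(n1, n2)
  w_small <- if (n1 <= n2) w_x else sum(r[n1 + seq_len(n2)])
  mu <- n_small * (n_tot + 1) / 2
  feasible <- n_small <= exact_max && choose(n_tot, n_small) <= 5e5
  if (feasible) {
    sums <- utils::combn(r, n_small, FUN = sum)
    p <- mean(abs(sums - mu) >= abs(w_small - mu) - 1e-9)
    method <- "exact_mann_whitney"
  } else {
    u_small <- w_small - n_small * (n_small + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 *
      (n_tot + 1 - sum(ties^3 - ties) / (n_tot * (n_tot - 1)))
    z <- (abs(u_small - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "mann_whitney_normal_approx"
  }
  new_test_result(method, statistic = u_x, p = p, exact = feasible,
                  n1 = n1, n2 = n2)
}

#' Exact one-sample Wilcoxon signed-rank test
#'
#' Tests the sample median against `mu0`. Zero differences are dropped
#' (documented convention); the remaining absolute differences are
#' mid-ranked and the exact two-sided p is computed from the distribution
#' of the signed-rank sum over all 2^n sign patterns, evaluated by a
#' generating-function convolution (ranks are doubled so mid-ranks stay
#' integral). Above `exact_max` retained observations the tie-corrected
#' normal approximation is used, flagged.
#'
#' @param x numeric sample.
#' @param mu0 hypothesised location.
#' @param exact_max largest n for which the exact distribution is built.
#' @return An `rm_test_result` tibble; when every value equals `mu0` the
#'   test is degenerate and p is reported as 1.
#' @examples
#' one_sample_wilcoxon(c(2, 3, 4, 5, 6, 7), mu0 = 1)  # p = 2/64
#' @export
one_sample_wilcoxon <- function(x, mu0, exact_max = 25) {
  if (!length(x)) stop("empty sample", call. = FALSE)
  if (anyNA(x)) stop("missing values are not allowed", call. = FALSE)
  d <- x - mu0
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    res <- new_test_result("one_sample_wilcoxon_degenerate", statistic = 0,
                           p = 1, exact = TRUE, n1 = length(x), n2 = NA_integer_)
    res$degenerate <- TRUE
    return(res)
  }
  r2 <- as.integer(round(2 * rank(abs(d))))  # mid-ranks doubled -> integers
  v2 <- sum(r2[d > 0])
  mu <- sum(r2) / 2
  if (n <= exact_max) {
    # counts[k + 1] = number of sign patterns with doubled rank sum k
    counts <- numeric(sum(r2) + 1)
    counts[1] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), counts[seq_len(length(counts) - rk)])
      counts <- counts + shifted
    }
    k <- seq_along(counts) - 1
    p <- sum(counts[abs(k - mu) >= abs(v2 - mu) - 1e-9]) / 2^n
    method <- "exact_one_sample_wilcoxon"
    exact <- TRUE
  } else {
    ties <- table(r2)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    # v2 is on the doubled scale; match moments on that scale
    z <- (abs(v2 / 2 - mu / 2) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "one_sample_wilcoxon_normal_approx"
    exact <- FALSE
  }
  new_test_result(method, statistic = v2 / 2, p = p, exact = exact,
                  n1 = length(x), n2 = NA_integer_)
}

new_test_result <- function(method, statistic, p, exact, n1, n2,
                            adjusted = FALSE, adjust_method = NA_character_) {
  out <- tibble::tibble(
    method = method,
    statistic = as.numeric(statistic),
    p_two_tailed = as.numeric(p),
    exact = exact,
    n1 = as.integer(n1),
    n2 = as.integer(n2),
    adjusted = adjusted,
    adjust_method = adjust_method
  )
  class(out) <- c("rm_test_result", class(out))
  out
}

#' Gated group comparison protocol
#'
#' Implements the dispatching comparison protocol used for tomogram
#' measurement groups: each group is first checked for normality
#' (Shapiro-Wilk at `alpha_normality`; possible only for n >= 3 -- smaller
#' groups force the nonparametric path) and for homoscedasticity (ratio
#' of largest to smallest group SD above `sd_ratio_threshold` counts as
#' unequal SDs). Two groups: Student t (normal, equal SDs), Welch t
#' (normal, unequal SDs) or the exact Mann-Whitney test. Three or more:
#' one-way ANOVA with Tukey's multiple-comparison post hoc, or
#' Kruskal-Wallis with Dunn's multiple-comparison post hoc
#' (Bonferroni-adjusted).
#'
#' @param data a data frame.
#' @param value,group column names (tidy-eval) holding the measurements
#'   and the grouping variable.
#' @param alpha_normality per-group Shapiro-Wilk significance level.
#' @param sd_ratio_threshold SD ratio above which Welch's correction (or
#'   the nonparametric k-sample path) is used.
#' @return A `group_comparison` list: `result` (an `rm_test_result`),
#'   `posthoc` (tibble of pairwise adjusted p-values, or `NULL`), `path`
#'   (the chosen test family) and `gates` (per-group n, Shapiro p, SD).
#' @examples
#' df <- data.frame(v = c(rnorm(10), rnorm(10, 2)),
#'                  g = rep(c("a", "b"), each = 10))
#' compare_groups(df, v, g)$path
#' @export
compare_groups <- function(data, value, group, alpha_normality = 0.05,
                           sd_ratio_threshold = 2) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- as.factor(rlang::eval_tidy(rlang::enquo(group), data))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  groups <- split(v, g)
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  ns <- vapply(groups, length, integer(1))
  small <- names(ns)[ns < 2]
  if (length(small)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  gates <- tibble::tibble(
    group = names(groups),
    n = ns,
    shapiro_p = vapply(groups, function(x) {
      if (length(x) >= 3 && stats::sd(x) > 0)
        stats::shapiro.test(x)$p.value else NA_real_
    }, numeric(1)),
    sd = vapply(groups, stats::sd, numeric(1))
  )
  all_normal <- all(!is.na(gates$shapiro_p)) &&
    all(gates$shapiro_p > alpha_normality)
  sds <- gates$sd
  equal_sd <- all(sds > 0) && max(sds) / min(sds) <= sd_ratio_threshold
  k <- length(groups)
  posthoc <- NULL
  if (k == 2) {
    if (all_normal) {
      ht <- stats::t.test(groups[[1]], groups[[2]], var.equal = equal_sd)
      path <- if (equal_sd) "student_t" else "welch_t"
      result <- new_test_result(path, ht$statistic, ht$p.value,
                                exact = FALSE, n1 = ns[1], n2 = ns[2])
    } else {
      path <- "mann_whitney"
      result <- exact_mann_whitney(groups[[1]], groups[[2]])
    }
  } else {
    if (all_normal && equal_sd) {
      path <- "anova_tukey"
      fit <- stats::aov(v ~ g)
      an <- summary(fit)[[1]]
      result <- new_test_result("anova", an$`F value`[1], an$`Pr(>F)`[1],
                                exact = FALSE, n1 = length(v), n2 = k)
      tk <- stats::TukeyHSD(fit)$g
      posthoc <- tibble::tibble(
        comparison = rownames(tk),
        estimate = tk[, "diff"],
        p_adjusted = tk[, "p adj"],
        adjust_method = "tukey"
      )
    } else {
      path <- "kruskal_dunn"
      kw <- stats::kruskal.test(v, g)
      result <- new_test_result("kruskal_wallis", kw$statistic, kw$p.value,
                                exact = FALSE, n1 = length(v), n2 = k)
      posthoc <- dunn_posthoc(v, g)
    }
  }
  structure(
    list(result = result, posthoc = posthoc, path = path, gates = gates),
    class = "group_comparison"
  )
}

# Dunn's multiple-comparison test on Kruskal-Wallis ranks with tie
# correction and Bonferroni adjustment.
dunn_posthoc <- function(v, g) {
  r <- rank(v)
  n_tot <- length(v)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  means <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  m <- ncol(pairs)
  z <- p_raw <- numeric(m)
  for (j in seq_len(m)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_term) * (1 / ns[a] + 1 / ns[b]))
    z[j] <- (means[a] - means[b]) / se
    p_raw[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  tibble::tibble(
    comparison = paste(pairs[1, ], pairs[2, ], sep = "-"),
    estimate = z,
    p_adjusted = pmin(1, p_raw * m),
    adjust_method = "bonferroni"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> path:", x$path, "\n")
  cat(sprintf("  %s: statistic %.4g, two-tailed p %.4g\n",
              x$result$method, x$result$statistic, x$result$p_two_tailed))
  if (!is.null(x$posthoc)) {
    cat("  post hoc (", x$posthoc$adjust_method[1], "-adjusted):\n", sep = "")
    print(as.data.frame(x$posthoc), row.names = FALSE)
  }
  invisible(x)
}

#' Tidy and glance methods for comparison results
#'
#' `tidy()` on a `group_comparison` returns the pairwise post-hoc table
#' when one exists (adjusted p-values are always >= the unadjusted ones by
#' construction of the adjustment), otherwise the main test row.
#' `glance()` returns the main test row.
#'
#' @param x a `group_comparison`.
#' @param ... unused.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  if (!is.null(x$posthoc)) x$posthoc else tibble::as_tibble(x$result)
}

#' @rdname tidy.group_comparison
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) tibble::as_tibble(x$result)
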