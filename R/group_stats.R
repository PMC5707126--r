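# Self-contained implementations of the statistical procedures used across
# the pipeline: Z-test of one case against a control set, Bonferroni and
# Benjamini-Hochberg multiplicity corrections, Mann-Whitney U, two-tailed
# Fisher exact for 2x2 tables, Yates-corrected chi-square, one-way ANOVA and
# Tukey HSD. Each returns a `hervex_test` record so callers can carry the
# method label and group sizes alongside the p-value.

new_test_result <- function(statistic, p_value, method, n_per_group,
                            correction = "none", degenerate = FALSE,
                            extra = list()) {
  structure(
    c(list(statistic = unname(statistic), p_value = unname(p_value),
           method = method, n_per_group = n_per_group,
           correction = correction, degenerate = degenerate), extra),
    class = "hervex_test")
}

#' @export
print.hervex_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g%s\n", x$method,
              x$statistic %||% NA_real_, x$p_value,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Z-test of a single case value against a set of control values
#'
#' Computes `z = (x - mean(controls)) / sd(controls)` with the sample (n-1)
#' standard deviation and a two-sided normal p-value. Used by the viral
#' hit-rate screen, where each case specimen is compared against the control
#' group for one taxon.
#'
#' When the control standard deviation is zero the test is degenerate: if the
#' case equals the control mean the result is p = 1; otherwise the p-value is
#' `NA` and the `degenerate` flag is set so callers can retain the comparison
#' for manual review.
#'
#' @param x single case value.
#' @param controls numeric vector of control values (length >= 2).
#' @return a `hervex_test` with fields `statistic` (z) and `p_value`.
#' @export
z_test_case_vs_controls <- function(x, controls) {
  stopifnot(length(x) == 1L, length(controls) >= 2L)
  m <- mean(controls)
  s <- stats::sd(controls)
  if (s == 0) {
    if (x == m) {
      return(new_test_result(0, 1, "z-test", c(1L, length(controls))))
    }
    return(new_test_result(NA_real_, NA_real_, "z-test",
                           c(1L, length(controls)), degenerate = TRUE))
  }
  z <- (x - m) / s
  new_test_result(z, 2 * stats::pnorm(-abs(z)), "z-test",
                  c(1L, length(controls)))
}

#' Bonferroni correction
#'
#' @param p raw p-value(s).
#' @param m family size.
#' @return `min(1, p * m)`, vectorized over `p`.
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, p * m)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Computes `q_(i) = min_{j >= i} p_(j) * m / j` over the sorted p-values and
#' restores the input order. Values are capped at 1. Quantification reports
#' apply this within each retroviral domain type separately.
#'
#' @param p numeric vector of p-values.
#' @return q-values in the order of `p`.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test with midranks for ties. For combined sample sizes of at most
#' `exact_max` the null distribution of U is obtained by full enumeration of
#' the label permutations (so ties are handled exactly); above that the
#' normal approximation with tie correction and a 0.5 continuity correction
#' is used. The two-sided p sums both symmetric tails of the permutation
#' distribution.
#'
#' @param x,y numeric vectors for the two groups.
#' @param exact_max largest `length(x) + length(y)` for which the exact
#'   permutation distribution is enumerated (default 16).
#' @return a `hervex_test`; `statistic` is U for group `x`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 16L) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 1L, ny >= 1L)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  nm <- nx * ny
  ul <- min(u, nm - u); uh <- nm - ul
  if (nx + ny <= exact_max) {
    idx <- utils::combn(nx + ny, nx)
    us <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
    eps <- 1e-9
    p <- mean(us <= ul + eps | us >= uh - eps)
    p <- min(1, p)
    method <- "mann-whitney-exact"
  } else {
    mu <- nm / 2
    n <- nx + ny
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nm / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      return(new_test_result(u, 1, "mann-whitney-normal", c(nx, ny)))
    }
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "mann-whitney-normal"
  }
  new_test_result(u, p, method, c(nx, ny))
}

#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Exact p-value by summation of hypergeometric probabilities over all tables
#' with the observed margins whose probability does not exceed that of the
#' observed table (with relative tolerance 1e-7, matching the common
#' "probability mass" two-sided convention).
#'
#' @param tab 2x2 integer matrix (or something coercible to one).
#' @return a `hervex_test`; `statistic` is the sample odds ratio
#'   (`ad/bc`, `Inf`/`NaN` for degenerate margins).
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)) || identical(dim(tab), c(2, 2)))
  stopifnot(all(tab >= 0), all(tab == round(tab)))
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p <- min(1, p)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  new_test_result(or, p, "fisher-exact-2x2", c(r1, r2))
}

#' Chi-square test with Yates continuity correction (2x2)
#'
#' `chisq = N * (max(|ad - bc| - N/2, 0))^2 / (r1 r2 c1 c2)` on 1 degree of
#' freedom, upper-tail p. Used for discrete demographics (sex).
#'
#' @param tab 2x2 matrix of counts.
#' @return a `hervex_test` with the corrected chi-square statistic.
#' @export
chi_square_yates <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  n <- sum(tab)
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    return(new_test_result(0, 1, "chi-square-yates", c(r1, r2),
                           degenerate = TRUE))
  }
  num <- max(abs(a * d - b * cc) - n / 2, 0)
  stat <- n * num^2 / (r1 * r2 * c1 * c2)
  new_test_result(stat, stats::pchisq(stat, df = 1, lower.tail = FALSE),
                  "chi-square-yates", c(r1, r2))
}

#' One-way (unweighted) analysis of variance
#'
#' @param groups list of numeric vectors, one per group.
#' @return a `hervex_test`; `statistic` is F, with `extra` fields `df1`,
#'   `df2`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, as.numeric)
  ns <- lengths(groups)
  stopifnot(all(ns >= 1L))
  k <- length(groups)
  n <- sum(ns)
  gm <- mean(unlist(groups))
  means <- vapply(groups, mean, 0)
  ss_between <- sum(ns * (means - gm)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1; df2 <- n - k
  if (df2 <= 0) stop("one-way ANOVA needs more observations than groups")
  ms_between <- ss_between / df1
  ms_within <- ss_within / df2
  if (ms_within == 0) {
    f <- if (ms_between == 0) 0 else Inf
    p <- if (ms_between == 0) 1 else 0
  } else {
    f <- ms_between / ms_within
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  new_test_result(f, p, "anova-oneway", ns,
                  extra = list(df1 = df1, df2 = df2))
}

#' Tukey honestly-significant-difference pairwise comparisons
#'
#' Studentized-range statistic per group pair with the pooled within-group
#' variance; p-values from the studentized range distribution.
#'
#' @param groups named list of numeric vectors (length >= 2 each).
#' @return data.frame with one row per pair: `group1`, `group2`, `diff`,
#'   `q_statistic`, `p_value`.
#' @export
tukey_hsd <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  ns <- lengths(groups)
  stopifnot(all(ns >= 2L))
  k <- length(groups)
  df <- sum(ns) - k
  s2 <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) / df
  means <- vapply(groups, mean, 0)
  pairs <- utils::combn(k, 2)
  out <- data.frame(
    group1 = names(groups)[pairs[1, ]],
    group2 = names(groups)[pairs[2, ]],
    diff = means[pairs[2, ]] - means[pairs[1, ]],
    q_statistic = NA_real_, p_value = NA_real_,
    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    n1 <- ns[pairs[1, i]]; n2 <- ns[pairs[2, i]]
    se <- sqrt(s2 / 2 * (1 / n1 + 1 / n2))
    if (se == 0) {
      out$q_statistic[i] <- if (out$diff[i] == 0) 0 else Inf
      out$p_value[i] <- if (out$diff[i] == 0) 1 else 0
      next
    }
    q <- abs(out$diff[i]) / se
    out$q_statistic[i] <- q
    out$p_value[i] <- stats::ptukey(q, nmeans = k, df = df,
                                    lower.tail = FALSE)
  }
  rownames(out) <- NULL
  out
}
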