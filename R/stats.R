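# Cohort statistics: rank-transform mixed-effects comparison for the matched
# design, Mann-Whitney U for ordinal grades, Spearman correlation and group
# summaries.

#' Midrank transform
#'
#' Ranks 1..n over the non-missing entries with ties assigned midranks;
#' missing values stay missing.
#'
#' @param values Numeric vector, `NA` allowed.
#' @return Numeric vector of midranks with `NA` preserved.
#' @export
rank_transform <- function(values) {
  if (all(is.na(values))) stop("empty input: all values missing")
  if (sum(!is.na(values)) < 2L) stop("need at least 2 non-missing values")
  rank(values, na.last = "keep", ties.method = "average")
}

comparison_result <- function(variable, test, statistic, p_value, n,
                              group_means = NULL, group_sds = NULL,
                              method = NA_character_, fallback = FALSE) {
  structure(list(variable = variable, test = test, statistic = statistic,
                 p_value = p_value, n = n, group_means = group_means,
                 group_sds = group_sds, method = method, fallback = fallback),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %s, statistic %.4g, p = %.4g (n = %s)%s\n",
              x$variable %||% "comparison", x$test, x$statistic, x$p_value,
              paste(x$n, collapse = "/"),
              if (isTRUE(x$fallback)) " [fallback]" else ""))
  invisible(x)
}

#' Matched-cohort comparison by rank-transform mixed-effects model
#'
#' Two-step procedure for small matched samples: the pooled values of both
#' groups are midrank-transformed, then a linear mixed model with a fixed
#' group effect and a random intercept per matched pair is fitted by REML
#' (variance components constrained non-negative) and the group effect tested
#' by a two-sided Wald t-test. The t reference distribution uses
#' (complete pairs - 1) degrees of freedom, so that in the balanced paired
#' design the test coincides with the paired t-test on within-pair rank
#' differences. If the fit fails, that paired t-test is used directly and the
#' result flagged as a fallback.
#'
#' @param records Data frame with columns `group` (two levels), `pair_id` and
#'   the variable.
#' @param variable Name of the column to compare.
#' @return A `comparison_result`.
#' @export
paired_rank_lmm_test <- function(records, variable) {
  d <- records[!is.na(records[[variable]]),
               c("group", "pair_id", variable)]
  d$group <- factor(d$group)
  if (nlevels(d$group) != 2L) stop("exactly two groups required")
  if (any(table(d$group, d$pair_id) > 1L))
    stop("each pair may contribute at most one record per group")
  tab <- table(d$pair_id)
  complete <- names(tab)[tab == 2L]
  if (length(complete) < 3L) stop("need at least 3 complete pairs")
  d$r <- rank_transform(d[[variable]])
  gm <- tapply(d[[variable]], d$group, mean)
  gs <- tapply(d[[variable]], d$group, stats::sd)
  nn <- as.vector(table(d$group))

  dc <- d[d$pair_id %in% complete, ]
  dc <- dc[order(dc$pair_id, dc$group), ]
  diffs <- dc$r[dc$group == levels(d$group)[2L]] -
    dc$r[dc$group == levels(d$group)[1L]]
  if (all(diffs == 0))
    return(comparison_result(variable, "rank-transform LMM", 0, 1, nn,
                             gm, gs, method = "degenerate (no within-pair variation)"))
  df <- length(complete) - 1L
  fit <- tryCatch({
    m <- suppressMessages(suppressWarnings(
      lme4::lmer(r ~ group + (1 | pair_id), data = d, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))))
    cf <- summary(m)$coefficients
    list(est = cf[2L, 1L], se = cf[2L, 2L])
  }, error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$se) || fit$se <= 0) {
    tt <- stats::t.test(diffs)
    return(comparison_result(variable,
                             "paired t-test on within-pair rank differences",
                             unname(tt$statistic), tt$p.value, nn, gm, gs,
                             method = "fallback", fallback = TRUE))
  }
  tstat <- fit$est / fit$se
  p <- 2 * stats::pt(-abs(tstat), df = df)
  comparison_result(variable, "rank-transform LMM (random intercept per pair)",
                    tstat, p, nn, gm, gs,
                    method = sprintf("Wald t, df = %d", df))
}

# Exact conditional null distribution of the rank sum under ties: dynamic
# programming over doubled midrank scores (integers), counting the subsets of
# each size by achievable score sum. Independent of assignment enumeration.
rank_sum_exact_p <- function(r, na) {
  s <- as.integer(round(2 * r))
  N <- length(s)
  smax <- sum(s)
  counts <- matrix(0, nrow = na + 1L, ncol = smax + 1L)  # [k+1, sum+1]
  counts[1L, 1L] <- 1
  for (x in s) {
    kmax <- min(na, N)
    for (k in kmax:1L) {
      shifted <- c(rep(0, x), counts[k, seq_len(smax + 1L - x)])
      counts[k + 1L, ] <- counts[k + 1L, ] + shifted
    }
  }
  dist <- counts[na + 1L, ]
  s_obs <- sum(s[seq_len(na)])
  total <- sum(dist)
  lo <- sum(dist[seq_len(s_obs + 1L)]) / total           # P(S <= s_obs)
  hi <- sum(dist[(s_obs + 1L):(smax + 1L)]) / total      # P(S >= s_obs)
  min(1, 2 * min(lo, hi))
}

#' Mann-Whitney U test with midrank ties
#'
#' The U statistic is computed from pooled midranks. The two-sided p-value is
#' exact when the pooled sample size is at most 12: via the standard Wilcoxon
#' null distribution when tie-free, and via the exact conditional distribution
#' of the tie-adjusted rank sum (count recursion) when ties are present.
#' Larger samples use the normal approximation with tie and continuity
#' corrections.
#'
#' @param group_a,group_b Numeric vectors (`NA` dropped).
#' @param variable Optional variable name for the report.
#' @return A `comparison_result` with the U statistic of the first group.
#' @export
mann_whitney_u <- function(group_a, group_b, variable = NULL) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  if (!length(a) || !length(b)) stop("empty input: both groups need values")
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (N <= 12L && !ties) {
    p <- 2 * min(stats::pwilcox(U, na, nb), 1 - stats::pwilcox(U - 1, na, nb))
    method <- "exact"
  } else if (N <= 12L) {
    p <- rank_sum_exact_p(r, na)
    method <- "exact (tie-conditional)"
  } else {
    t_counts <- table(pooled)
    sigma2 <- na * nb / 12 *
      ((N + 1) - sum(t_counts^3 - t_counts) / (N * (N - 1)))
    mu <- na * nb / 2
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - 0.5 * sign(U - mu)) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation with tie and continuity correction"
  }
  comparison_result(variable, "Mann-Whitney U", U, min(p, 1), c(na, nb),
                    group_means = c(mean(a), mean(b)),
                    group_sds = c(stats::sd(a), stats::sd(b)),
                    method = method)
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of midranks; the two-sided p-value uses the
#' t approximation with n - 2 degrees of freedom.
#'
#' @param x,y Paired numeric vectors (pairs with missing values dropped).
#' @param variable Optional name for the report.
#' @return A `comparison_result` with `statistic` = rho.
#' @export
spearman_correlation <- function(x, y, variable = NULL) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("undefined correlation: zero variance in a rank vector")
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  comparison_result(variable, "Spearman rank correlation", rho, p, n,
                    method = "t approximation, df = n - 2")
}

#' Per-group summary statistic
#'
#' @param records Data frame with a `group` column.
#' @param variable Column to summarise; missing entries are excluded and
#'   counted.
#' @param statistic `"mean"` or `"median"`.
#' @return Data frame with columns `group`, `value`, `n`.
#' @export
group_summary <- function(records, variable, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  f <- if (statistic == "mean") mean else stats::median
  v <- records[[variable]]
  g <- records$group
  groups <- unique(g)
  out <- data.frame(group = groups,
                    value = NA_real_, n = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(groups)) {
    vi <- v[g == groups[i] & !is.na(v)]
    if (!length(vi)) stop(sprintf("empty input: group '%s' has no values for %s",
                                  groups[i], variable))
    out$value[i] <- f(vi)
    out$n[i] <- length(vi)
  }
  out
}
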