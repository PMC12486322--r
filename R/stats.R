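#' Printed group summary (mean, SEM, n)
#'
#' Published tables report groups as mean ± SEM with a group size; this
#' container carries exactly those three numbers so that t tests and
#' one-way ANOVAs can be recomputed from print. The group SD is
#' reconstructed as `SEM * sqrt(n)`.
#'
#' @param mean group mean.
#' @param sem standard error of the mean, >= 0.
#' @param n group size, >= 2.
#' @return An object of class `summary_stats`.
#' @export
summary_stats <- function(mean, sem, n) {
  if (n < 2) stop("`n` must be >= 2")
  if (sem < 0) stop("`sem` must be >= 0")
  structure(list(mean = as.numeric(mean), sem = as.numeric(sem),
                 n = as.integer(n)),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("summary_stats: ", x$mean, " +/- ", x$sem, " (SEM), n = ", x$n,
      "\n", sep = "")
  invisible(x)
}

# (mean, sd, n) from either a raw sample or a summary_stats object
group_moments <- function(g) {
  if (inherits(g, "summary_stats"))
    list(mean = g$mean, sd = g$sem * sqrt(g$n), n = g$n)
  else {
    g <- as.numeric(g)
    if (length(g) < 2) stop("each raw sample needs n >= 2")
    list(mean = mean(g), sd = stats::sd(g), n = length(g))
  }
}

test_result <- function(statistic, df, p.value, method, estimate = NULL) {
  structure(list(statistic = statistic, df = df, p.value = p.value,
                 method = method, estimate = estimate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  lbl <- switch(x$method,
                student = sprintf("t(%g) = %.4g", x$df, x$statistic),
                welch = sprintf("Welch t(%.4g) = %.4g", x$df, x$statistic),
                anova = sprintf("F(%g, %g) = %.4g", x$df[1], x$df[2],
                                x$statistic),
                fisher = "Fisher's exact test",
                sprintf("%s = %.4g", x$method, x$statistic))
  cat(lbl, ", p = ", format.pval(x$p.value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Two-sample t test from raw samples or printed summaries
#'
#' Student's two-tailed unpaired t test, with Welch's correction for
#' unequal variances on request. Each group may be a raw numeric vector
#' or a [summary_stats] (mean, SEM, n) triple — the two paths agree
#' exactly when the summaries are computed from the raw samples. The
#' default is the pooled-variance test with `n1 + n2 - 2` degrees of
#' freedom; `welch = "auto"` applies Welch's correction when an F test
#' of the two variances rejects equality at the 0.05 level.
#'
#' @param x,y raw samples (numeric vectors) or [summary_stats].
#' @param welch "off" (pooled, default), "on", or "auto".
#' @return A `test_result` with statistic, df, two-tailed p-value and
#'   the mean difference `x - y` as estimate.
#' @export
group_t_test <- function(x, y, welch = c("off", "on", "auto")) {
  welch <- match.arg(welch)
  a <- group_moments(x); b <- group_moments(y)
  if (welch == "auto") {
    f <- (a$sd^2) / (b$sd^2)
    pf2 <- 2 * min(stats::pf(f, a$n - 1, b$n - 1),
                   stats::pf(f, a$n - 1, b$n - 1, lower.tail = FALSE))
    welch <- if (pf2 < 0.05) "on" else "off"
  }
  d <- a$mean - b$mean
  if (welch == "on") {
    v1 <- a$sd^2 / a$n; v2 <- b$sd^2 / b$n
    t <- d / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (a$n - 1) + v2^2 / (b$n - 1))
    method <- "welch"
  } else {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    t <- d / sqrt(sp2 * (1 / a$n + 1 / b$n))
    method <- "student"
  }
  p <- 2 * stats::pt(-abs(t), df)
  test_result(t, df, p, method, estimate = d)
}

#' One-way ANOVA from raw samples or printed summaries
#'
#' `F = MS_between / MS_within` over k groups given either raw samples
#' or (mean, SEM, n) summaries; on the summary path the within-group sum
#' of squares is reconstructed from the per-group variances
#' `(SEM * sqrt(n))^2`. Degrees of freedom are `(k - 1, N - k)`.
#'
#' @param groups list of raw numeric vectors and/or [summary_stats].
#' @return A `test_result` (method "anova").
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop("at least two groups are required")
  ms <- lapply(groups, group_moments)
  n <- vapply(ms, `[[`, numeric(1), "n")
  m <- vapply(ms, `[[`, numeric(1), "mean")
  s2 <- vapply(ms, `[[`, numeric(1), "sd")^2
  N <- sum(n); k <- length(ms)
  gm <- sum(n * m) / N
  ss_b <- sum(n * (m - gm)^2)
  ss_w <- sum((n - 1) * s2)
  f <- (ss_b / (k - 1)) / (ss_w / (N - k))
  p <- stats::pf(f, k - 1, N - k, lower.tail = FALSE)
  test_result(f, c(k - 1, N - k), p, "anova")
}

#' 2x2 contingency table
#'
#' @param counts 2x2 matrix of non-negative integer counts; dimnames are
#'   kept as row/column labels.
#' @return An object of class `contingency_table` (the validated matrix).
#' @export
contingency_table <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("`counts` must be 2x2")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("table must have at least one positive margin")
  storage.mode(counts) <- "integer"
  structure(counts, class = c("contingency_table", "matrix", "array"))
}

#' Two-sided Fisher's exact test
#'
#' Exact two-sided test for a 2x2 table with fixed margins, using the
#' point-probability rule: the p-value is the sum of the hypergeometric
#' probabilities of all admissible tables no more probable than the
#' observed one (a relative slack of 1e-7 guards against floating-point
#' ties). This is the convention of common statistical software;
#' mid-p and tail-doubling variants differ and are not provided.
#'
#' @param table a [contingency_table] or plain 2x2 count matrix.
#' @return A `test_result` (method "fisher") with the sample odds ratio
#'   as estimate; the statistic slot holds the observed table
#'   probability.
#' @export
fisher_exact <- function(table) {
  tab <- contingency_table(table)
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p <- min(1, p)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  test_result(p_obs, NA_real_, p, "fisher", estimate = or)
}

#' Pairwise post hoc comparisons after one-way ANOVA
#'
#' Tukey's honestly-significant-difference test (studentized-range q on
#' the pooled within-group mean square) or Bonferroni-adjusted pairwise
#' pooled t tests (p multiplied by the number of comparisons, capped at
#' 1). Groups may be raw samples or [summary_stats].
#'
#' @param groups named list of >= 2 groups (>= 3 for Tukey).
#' @param method "tukey" or "bonferroni".
#' @return data.frame with one row per pair: statistic, df and adjusted
#'   p-value.
#' @export
pairwise_posthoc <- function(groups, method = c("tukey", "bonferroni")) {
  method <- match.arg(method)
  k <- length(groups)
  if (k < 2L || (method == "tukey" && k < 3L))
    stop("need >= 2 groups (>= 3 for tukey)")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_len(k))
  ms <- lapply(groups, group_moments)
  n <- vapply(ms, `[[`, numeric(1), "n")
  m <- vapply(ms, `[[`, numeric(1), "mean")
  s2 <- vapply(ms, `[[`, numeric(1), "sd")^2
  N <- sum(n)
  msw <- sum((n - 1) * s2) / (N - k)
  pairs <- utils::combn(k, 2)
  ncmp <- ncol(pairs)
  rows <- lapply(seq_len(ncmp), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    if (method == "tukey") {
      q <- abs(m[i1] - m[i2]) / sqrt(msw / 2 * (1 / n[i1] + 1 / n[i2]))
      p <- stats::ptukey(q, k, N - k, lower.tail = FALSE)
      data.frame(pair = paste(names(groups)[c(i1, i2)], collapse = " - "),
                 statistic = q, df = N - k, p.adj = p)
    } else {
      r <- group_t_test(groups[[i1]], groups[[i2]])
      data.frame(pair = paste(names(groups)[c(i1, i2)], collapse = " - "),
                 statistic = r$statistic, df = r$df,
                 p.adj = min(1, r$p.value * ncmp))
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "method") <- method
  out
}
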