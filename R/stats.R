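# Nonparametric statistics used by the figure-style summaries: one-sided
# Mann-Whitney U with exact small-sample enumeration, boxplot five-number
# summaries, and the standard error of the mean.

#' One-sided Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties.  The p-value is
#' exact (full enumeration of the permutation distribution of U) whenever
#' n1 + n2 <= 12 and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction is used.  The returned U
#' counts pairs (x_i, y_j) with x_i > y_j (ties count one half), so
#' `alternative = "greater"` tests whether x is stochastically larger
#' than y.
#'
#' @param x,y numeric samples.
#' @param alternative `"greater"` (x tends larger) or `"less"`.
#' @return list with `U`, `p_value` (one-sided), `n1`, `n2`,
#'   `alternative`, `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_one_sided <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("empty sample")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)                       # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L
  if (!has_ties && n1 + n2 <= 12L) {
    dist <- u_exact_distribution(n1, n2)
    p <- if (alternative == "greater") sum(dist$prob[dist$u >= U - 1e-9])
         else sum(dist$prob[dist$u <= U + 1e-9])
    method <- "exact"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1                              # fully degenerate pooled sample
    } else {
      zc <- if (alternative == "greater") (U - mu - 0.5) else (U - mu + 0.5)
      z <- zc / sqrt(sigma2)
      p <- if (alternative == "greater") stats::pnorm(z, lower.tail = FALSE)
           else stats::pnorm(z)
    }
    method <- "normal"
  }
  list(U = U, p_value = min(max(p, .Machine$double.xmin), 1),
       n1 = n1, n2 = n2, alternative = alternative, method = method)
}

# Exact null distribution of U for tie-free samples: enumerate every
# C(n1+n2, n1) assignment of ranks to the first sample.
u_exact_distribution <- function(n1, n2) {
  combs <- utils::combn(n1 + n2, n1)
  u <- colSums(combs) - n1 * (n1 + 1) / 2
  tab <- table(u)
  list(u = as.numeric(names(tab)), prob = as.numeric(tab) / ncol(combs))
}

#' Boxplot five-number summary
#'
#' Median, first/third quartiles (hinges) and the 5th/95th percentiles
#' (whiskers), all by the linear-interpolation quantile convention
#' (`type = 7`); the convention is recorded in the result.
#'
#' @param values numeric vector, n >= 1.
#' @return list with `n`, `median`, `q1`, `q3`, `p5`, `p95`,
#'   `quantile_type`.
#' @export
summarize_values <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("empty input")
  q <- stats::quantile(values, c(0.05, 0.25, 0.5, 0.75, 0.95),
                       type = 7, names = FALSE)
  list(n = length(values), median = q[3], q1 = q[2], q3 = q[4],
       p5 = q[1], p95 = q[5], quantile_type = 7L)
}

#' Standard error of the mean
#'
#' Sample standard deviation (n - 1 denominator) divided by sqrt(n).
#' @param values numeric vector, n >= 2.
#' @export
sem <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("sem requires n >= 2")
  stats::sd(values) / sqrt(length(values))
}
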