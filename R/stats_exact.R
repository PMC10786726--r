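#' Exact small-sample nonparametric tests
#'
#' Exact Mann-Whitney, Wilcoxon signed-rank and Fisher tests computed by
#' dynamic programming / enumeration; their p-values are rational numbers
#' whose numerator and denominator are exposed (denominator
#' `choose(n1+n2, n1)` for Mann-Whitney, `2^n` for the signed-rank test).
#' Ties fall back to mid-rank normal approximations with tie correction and
#' are reported with `exact = FALSE`.
#'
#' @name stats-exact
NULL

test_result <- function(statistic, p_value, method, alternative, exact,
                        ...) {
  structure(c(list(statistic = statistic, p_value = p_value, method = method,
                   alternative = alternative, exact = exact), list(...)),
            class = "apobecsig_test")
}

#' @export
print.apobecsig_test <- function(x, ...) {
  cat(x$method, "\n statistic =", x$statistic,
      "\n p-value =", format(x$p_value, digits = 6),
      paste0("(", x$alternative, if (x$exact) ", exact" else ", approximate",
             ")"), "\n")
  invisible(x)
}

#' Null distribution of the Mann-Whitney U statistic
#'
#' Counts, for every u in 0..n1*n2, the number of group labelings yielding
#' U = u, by the standard restricted-partition dynamic program.
#'
#' @param n1,n2 group sizes.
#' @return Numeric vector `counts` of length n1*n2+1 (index u+1) summing to
#'   `choose(n1+n2, n1)`.
#' @export
mwu_count_distribution <- function(n1, n2) {
  # walk the pooled order statistics smallest to largest; assigning position
  # i+1 to group 1 adds the number of group-2 values already placed to U
  maxu <- n1 * n2
  dp <- matrix(0, nrow = n1 + 1, ncol = maxu + 1)  # [k+1, u+1]
  dp[1, 1] <- 1
  for (i in 0:(n1 + n2 - 1)) {
    ndp <- matrix(0, nrow = n1 + 1, ncol = maxu + 1)
    for (k in 0:min(i, n1)) {
      row <- dp[k + 1, ]
      if (all(row == 0)) next
      n_y <- i - k
      if (k < n1) {                       # next element goes to group 1
        shift <- n_y
        ndp[k + 2, (1 + shift):(maxu + 1)] <-
          ndp[k + 2, (1 + shift):(maxu + 1)] + row[1:(maxu + 1 - shift)]
      }
      if (n_y < n2) {                     # next element goes to group 2
        ndp[k + 1, ] <- ndp[k + 1, ] + row
      }
    }
    dp <- ndp
  }
  dp[n1 + 1, ]
}

#' Exact Mann-Whitney U test
#'
#' The U null distribution is computed by dynamic programming; the two-sided
#' p-value doubles the smaller tail: `p = min(1, 2 * P(U <= min(u, n1*n2-u)))`.
#' With ties the mid-rank normal approximation with tie correction is used
#' (`exact = FALSE`).
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (of x relative
#'   to y).
#' @return An `apobecsig_test` with fields `statistic` (U for x: number of
#'   (x, y) pairs with x > y), `p_value`, and for the exact path the rational
#'   `p_numerator` / `p_denominator`.
#' @export
mann_whitney_exact <- function(x, y,
                               alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("empty group")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # pairs with x > y (+ ties/2)
  ties <- any(duplicated(c(x, y)))
  if (!ties) {
    counts <- mwu_count_distribution(n1, n2)
    denom <- choose(n1 + n2, n1)
    cum <- cumsum(counts)
    lower <- function(uu) cum[uu + 1]            # P(U <= uu) * denom
    num <- switch(alternative,
      less = lower(u),
      greater = lower(n1 * n2 - u),
      two.sided = min(denom, 2 * lower(min(u, n1 * n2 - u)))
    )
    return(test_result(u, num / denom, "Exact Mann-Whitney U test",
                       alternative, TRUE,
                       p_numerator = num, p_denominator = denom))
  }
  # mid-rank normal approximation with tie correction
  N <- n1 + n2
  tie_tab <- table(c(x, y))
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  mu <- n1 * n2 / 2
  sigma <- sqrt(n1 * n2 / 12 * (N + 1 - tie_term))
  z <- (u - mu)
  correct <- switch(alternative, two.sided = sign(z) * 0.5,
                    greater = 0.5, less = -0.5)
  z <- (z - correct) / sigma
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  test_result(u, min(1, p), "Mann-Whitney U test (normal approximation, ties)",
              alternative, FALSE)
}

#' Exact Wilcoxon signed-rank test
#'
#' Zero differences are dropped (Wilcoxon's original policy; `zero_policy =
#' "pratt"` keeps them for ranking then drops their ranks). For n <= 25
#' without tied absolute differences the full 2^n sign-pattern distribution
#' is computed by dynamic programming; otherwise the normal approximation
#' with tie correction is used.
#'
#' @param d paired differences (or use `x`, `y`).
#' @param x,y optional paired samples; `d = x - y`.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (location of d
#'   relative to zero).
#' @param zero_policy `"drop"` (default) or `"pratt"`.
#' @return An `apobecsig_test`; `statistic` is W+ (sum of ranks of positive
#'   differences); exact path exposes `p_numerator` / `p_denominator = 2^n`.
#' @export
wilcoxon_signed_rank_exact <- function(d = NULL, x = NULL, y = NULL,
                                       alternative = c("two.sided", "less",
                                                       "greater"),
                                       zero_policy = c("drop", "pratt")) {
  alternative <- match.arg(alternative)
  zero_policy <- match.arg(zero_policy)
  if (is.null(d)) d <- x - y
  if (zero_policy == "drop") {
    d <- d[d != 0]
    if (length(d) == 0) stop("all differences zero")
    r <- rank(abs(d))
  } else {
    if (all(d == 0)) stop("all differences zero")
    r_all <- rank(abs(d))
    r <- r_all[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  w_pos <- sum(r[d > 0])
  tied <- any(duplicated(r)) || any(r != round(r))
  if (!tied && n <= 25 && zero_policy == "drop") {
    maxw <- n * (n + 1) / 2
    dp <- numeric(maxw + 1)
    dp[1] <- 1
    for (k in seq_len(n)) {
      shifted <- c(numeric(k), dp[seq_len(maxw + 1 - k)])
      dp <- dp + shifted
    }
    denom <- 2^n
    cum <- cumsum(dp)
    lower <- function(w) cum[w + 1]  # P(W+ <= w) * denom
    num <- switch(alternative,
      less = lower(w_pos),
      greater = denom - (if (w_pos >= 1) lower(w_pos - 1) else 0),
      two.sided = min(denom,
                      2 * min(lower(w_pos),
                              denom - (if (w_pos >= 1) lower(w_pos - 1) else 0)))
    )
    return(test_result(w_pos, num / denom,
                       "Exact Wilcoxon signed-rank test", alternative, TRUE,
                       p_numerator = num, p_denominator = denom, n = n))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                  sum(tie_tab^3 - tie_tab) / 48)
  z <- w_pos - mu
  correct <- switch(alternative, two.sided = sign(z) * 0.5,
                    greater = 0.5, less = -0.5)
  z <- (z - correct) / sigma
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  test_result(w_pos, min(1, p),
              "Wilcoxon signed-rank test (normal approximation)",
              alternative, FALSE, n = n)
}

#' Exact Fisher test on a 2x2 table
#'
#' Full hypergeometric enumeration; the two-sided p-value sums the
#' probabilities of all tables (with the observed margins) no more probable
#' than the observed one.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (association of
#'   the \[1,1\] cell).
#' @return An `apobecsig_test`; `statistic` is the sample odds ratio.
#' @export
fisher_exact_2x2 <- function(tab,
                             alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table entries must be nonnegative integers")
  }
  a <- tab[1, 1]
  m <- sum(tab[1, ])   # row 1 total (white balls)
  n <- sum(tab[2, ])   # row 2 total
  k <- sum(tab[, 1])   # column 1 total (draws)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- switch(alternative,
    less = sum(probs[support <= a]),
    greater = sum(probs[support >= a]),
    two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)])
  )
  orr <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  test_result(orr, min(1, p), "Exact Fisher test (2x2)", alternative, TRUE)
}

#' Spearman rank correlation, with optional bootstrap
#'
#' Mid-rank Spearman correlation with a t-approximation p-value; optionally a
#' pairs bootstrap reporting the mean replicate R and a 95% percentile CI
#' (the bootstrap p-value derivation is not standardized, so only the plain
#' approximate p is reported and flagged approximate).
#'
#' @param x,y numeric vectors (n >= 3, y non-constant).
#' @param bootstrap NULL, or a list with `B` (replicates, default 1000) and
#'   `seed`.
#' @param alternative sidedness of the t-approximate p-value.
#' @return An `apobecsig_test` with `statistic` = R; when bootstrapping, also
#'   `boot_mean_r` and `boot_ci` (2.5% and 97.5% percentiles).
#' @export
spearman_test <- function(x, y, bootstrap = NULL,
                          alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("x and y lengths differ")
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (length(unique(y)) < 2 || length(unique(x)) < 2) {
    stop("constant input: correlation undefined")
  }
  rho <- stats::cor(rank(x), rank(y))
  tstat <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(tstat), n - 2),
              greater = stats::pt(tstat, n - 2, lower.tail = FALSE),
              less = stats::pt(tstat, n - 2))
  res <- test_result(rho, min(1, p),
                     "Spearman rank correlation (t approximation)",
                     alternative, FALSE, n = n)
  if (!is.null(bootstrap)) {
    B <- bootstrap$B %||% 1000
    seed <- bootstrap$seed %||% 17
    old <- local_rng(seed)
    on.exit(restore_rng(old))
    reps <- vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(x[idx])) < 2 || length(unique(y[idx])) < 2) {
        return(NA_real_)
      }
      stats::cor(rank(x[idx]), rank(y[idx]))
    }, numeric(1))
    reps <- reps[!is.na(reps)]
    res$boot_mean_r <- mean(reps)
    res$boot_ci <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
    res$boot_B <- B
  }
  res
}

#' Cohen's d effect size
#'
#' Difference of group means divided by the pooled standard deviation with
#' (n-1)-weighted pooling.
#'
#' @param a,b numeric groups, each of size >= 2.
#' @return Numeric effect size; positive when `mean(a) > mean(b)`.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs n >= 2")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop("zero pooled standard deviation")
  (mean(a) - mean(b)) / sqrt(sp2)
}

# seed-scoped RNG helpers: set a local seed, then restore the caller's state
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
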