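mk_htest <- function(statistic, p_value, method, data_name, counts) {
  out <- list(p.value = p_value, method = method, data.name = data_name,
              counts = counts)
  if (!is.null(statistic)) out$statistic <- statistic
  structure(out, class = "htest")
}

two_sided_binom <- function(a, n, prob) {
  # doubling method: twice the smaller exact tail, capped at 1
  lower <- stats::pbinom(a, n, prob)
  upper <- stats::pbinom(a - 1, n, prob, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Exact binomial test of an equiprobable dichotomy
#'
#' Tests whether a split (a, b) is compatible with the equiprobable null
#' a ~ Binomial(a + b, 1/2). The two-sided p-value uses the doubling
#' method: twice the smaller exact tail probability, capped at 1.
#'
#' @param a,b non-negative counts, `a + b >= 1`.
#' @param alternative `"two_sided"` (default) or `"greater"` (upper tail
#'   for `a`).
#' @return an object of class `htest`.
#' @export
binom_equal_test <- function(a, b, alternative = c("two_sided", "greater")) {
  alternative <- match.arg(alternative)
  a <- as.integer(a); b <- as.integer(b)
  if (a < 0 || b < 0 || a + b < 1) stop("need non-negative counts with a + b >= 1")
  n <- a + b
  p <- switch(alternative,
              two_sided = two_sided_binom(a, n, 0.5),
              greater = stats::pbinom(a - 1, n, 0.5, lower.tail = FALSE))
  mk_htest(NULL, p,
           sprintf("exact equiprobable binomial test (%s, doubling method)",
                   alternative),
           sprintf("%d vs %d of %d", a, b, n), c(a = a, b = b))
}

#' Exact binomial test against the 4:1 neutral-drift null
#'
#' Tests the dichotomy of affinity-increasing (`n_over`) versus
#' affinity-decreasing (`n_under`) variants against the genome-wide
#' neutral-drift expectation that site-damaging SNPs outnumber
#' site-improving SNPs 4:1, i.e. n_over ~ Binomial(n, 1/5). Two-sided by
#' the doubling method.
#'
#' @param n_over count of affinity-increasing (site-improving) variants.
#' @param n_under count of affinity-decreasing (site-damaging) variants.
#' @param ratio damaging:improving ratio of the null (default 4).
#' @return an object of class `htest`.
#' @export
binom_neutral_test <- function(n_over, n_under, ratio = 4) {
  n_over <- as.integer(n_over); n_under <- as.integer(n_under)
  if (n_over < 0 || n_under < 0 || n_over + n_under < 1)
    stop("need non-negative counts with n_over + n_under >= 1")
  stopifnot(ratio > 0)
  n <- n_over + n_under
  prob <- 1 / (1 + ratio)
  mk_htest(NULL, two_sided_binom(n_over, n, prob),
           sprintf("exact binomial test against %g:1 neutral-drift null (doubling method)",
                   ratio),
           sprintf("%d improving vs %d damaging of %d", n_over, n_under, n),
           c(n_over = n_over, n_under = n_under))
}

#' Chi-squared goodness-of-fit test of an equal split
#'
#' chi2 = (a - n/2)^2 / (n/2) + (b - n/2)^2 / (n/2) with n = a + b, without
#' continuity correction, referred to the chi-squared distribution with one
#' degree of freedom.
#'
#' @param a,b non-negative counts, `a + b >= 1`.
#' @return an object of class `htest` with the chi-squared `statistic`.
#' @export
chi2_equal_split <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (a < 0 || b < 0 || a + b < 1) stop("need non-negative counts with a + b >= 1")
  n <- a + b
  e <- n / 2
  stat <- (a - e)^2 / e + (b - e)^2 / e
  mk_htest(c("X-squared" = stat),
           stats::pchisq(stat, df = 1, lower.tail = FALSE),
           "chi-squared equal-split test (1 df, no continuity correction)",
           sprintf("%g vs %g of %g", a, b, n), c(a = a, b = b))
}

#' Probability that all concordance checks succeed by chance
#'
#' For n independent predictions each checked against independent evidence,
#' the one-sided probability that all n agree under a coin-flip null is
#' 0.5^n. Used to quantify the significance of an all-concordant validation
#' set.
#'
#' @param n_matches number of (all successful) concordance checks, >= 1.
#' @return an object of class `htest`.
#' @export
concordance_prob <- function(n_matches) {
  n_matches <- as.integer(n_matches)
  if (n_matches < 1) stop("need at least one concordance check")
  mk_htest(NULL, 0.5^n_matches,
           "probability of full concordance under an equiprobable null",
           sprintf("%d of %d predictions concordant", n_matches, n_matches),
           c(n = n_matches))
}
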