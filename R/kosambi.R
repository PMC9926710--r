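#' Kosambi map function
#'
#' Convert a recombination fraction to a genetic distance in centimorgans
#' under the Kosambi map function, d = 25 * ln((1 + 2r) / (1 - 2r)), which
#' accounts for partial crossover interference.
#'
#' @param r recombination fraction(s) in [0, 0.5).
#' @return genetic distance(s) in cM.
#' @examples
#' kosambi(0.1)           # 10.14 cM
#' kosambiInverse(10.14)  # ~0.1
#' @export
kosambi <- function(r) {
  if (any(r < 0 | r >= 0.5, na.rm = TRUE))
    stop("recombination fraction must be in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @param d genetic distance(s) in cM, d >= 0.
#' @export
kosambiInverse <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("distance must be >= 0")
  0.5 * tanh(d / 50)
}

## chi-square goodness of fit against 1:1 segregation, df = 1, no continuity
## correction. Returns c(chi2, p).
chisq11 <- function(a, b) {
  n <- a + b
  if (n == 0) return(c(chi2 = NA_real_, p = NA_real_))
  chi2 <- (a - b)^2 / n
  c(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Sex-ratio goodness-of-fit test
#'
#' Chi-square goodness of fit of observed male:female counts against a 1:1
#' ratio (df = 1, no continuity correction).
#'
#' @param nMale,nFemale observed counts.
#' @return list with \code{chi2} and \code{p}.
#' @examples
#' sexRatioTest(40, 47)  # chi2 = 0.563, p = 0.453
#' @export
sexRatioTest <- function(nMale, nFemale) {
  stopifnot(nMale + nFemale > 0)
  ct <- stats::chisq.test(c(nMale, nFemale), p = c(0.5, 0.5), correct = FALSE)
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value))
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided signed-rank test on paired observations. Zero differences are
#' dropped; the exact null distribution is used for n <= 25 untied
#' differences, and the normal approximation with tie correction otherwise.
#'
#' @param x,y equal-length paired numeric vectors.
#' @return two-sided p-value (1 if all differences are zero).
#' @export
wilcoxonSignedRank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  ties <- any(duplicated(abs(d)))
  if (n <= 25 && !ties) {
    res <- suppressWarnings(stats::wilcox.test(d, exact = TRUE))
    return(min(1, res$p.value))
  }
  if (n <= 15) {
    ## ties break the signrank distribution: enumerate the 2^n sign
    ## assignments of the average ranks exactly
    rk <- rank(abs(d))
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    W <- as.vector(signs %*% rk)
    w <- sum(rk[d > 0])
    return(min(1, 2 * min(mean(W <= w), mean(W >= w))))
  }
  res <- suppressWarnings(stats::wilcox.test(d, exact = FALSE, correct = TRUE))
  min(1, res$p.value)
}
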