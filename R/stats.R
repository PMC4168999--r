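# Exact statistics: two-sided Fisher tests on 2x2 ultrastructure counts,
# percentage -> count reconstruction for published tables, and rare-allele
# exclusion power.

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Conditional on both margins, sums the hypergeometric probabilities of
#' every table whose probability does not exceed that of the observed table
#' (the minimum-likelihood two-sided convention of mainstream statistical
#' software).
#'
#' @param a Either a 2x2 matrix of non-negative counts, or the top-left
#'   count (rows = group, columns = outcome, e.g. dynein arm visible / not).
#' @param b,c,d Remaining counts when \code{a} is scalar.
#' @return Two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(61, 2, 8, 118)   # dynein-arm counts: p well below 1e-4
#' fisher_exact_2x2(1, 1, 1, 1)      # identical proportions: p = 1
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    counts <- as.vector(t(a))
  } else {
    counts <- c(a, b, c, d)
  }
  if (length(counts) != 4L || anyNA(counts)) stop("need four counts")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  counts <- as.integer(round(counts))
  if (sum(counts) == 0L) stop("all-zero table")
  a <- counts[1L]; b <- counts[2L]; c <- counts[3L]; d <- counts[4L]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  k <- lo:hi
  probs <- dhyper(k, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  # relative tolerance guards against ties lost to floating-point noise
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Reconstruct an integer count from a printed percentage
#'
#' Published tables often print percentages over a stated denominator; the
#' underlying count is the nearest integer (round half away from zero).
#' The consistency flag records whether that count reprints to the given
#' percentage at its printed precision -- a printed value that no integer
#' count reproduces is thereby surfaced rather than silently accepted.
#'
#' @param pct Percentage in [0, 100].  Pass a character string (e.g.
#'   \code{"91.50"}) to take the printed precision from its decimals;
#'   numeric input uses \code{digits}.
#' @param n Denominator.
#' @param digits Printed decimal places of \code{pct} (inferred from a
#'   character \code{pct}; default 0 for bare numerics without decimals).
#' @return List: \code{count}, \code{consistent}, \code{reprinted} (the
#'   percentage the count actually reprints to).
#' @examples
#' counts_from_percent("97", 63)      # 61 (96.8% reprints as 97%)
#' counts_from_percent("91.50", 63)   # 58, consistent = FALSE
#' @export
counts_from_percent <- function(pct, n, digits = NULL) {
  if (is.character(pct)) {
    if (is.null(digits)) {
      digits <- if (grepl(".", pct, fixed = TRUE)) {
        nchar(sub("^[^.]*\\.", "", pct))
      } else 0L
    }
    pct <- as.numeric(pct)
  } else if (is.null(digits)) {
    digits <- if (pct == round(pct)) 0L else 2L
  }
  if (is.na(pct) || pct < 0 || pct > 100) stop("pct must be in [0, 100]")
  n <- as.integer(n)
  if (n < 0L) stop("n must be non-negative")
  x <- pct * n / 100
  count <- as.integer(floor(x + 0.5))  # round half away from zero (x >= 0)
  reprinted <- if (n > 0L) round(100 * count / n, digits) else 0
  list(count = count,
       consistent = isTRUE(all.equal(reprinted, round(pct, digits))),
       reprinted = reprinted)
}

#' Power to exclude a rare allele
#'
#' Probability of observing an allele at least once among \code{n_chr}
#' genotyped chromosomes if its true frequency is \code{q}:
#' \code{1 - (1 - q)^n_chr}.  Failing to observe it therefore excludes
#' frequency \code{q} with this power.
#'
#' @param q Allele frequency in [0, 1].
#' @param n_chr Number of genotyped control chromosomes (>= 0).
#' @return Power in [0, 1].
#' @examples
#' exclusion_power(0.001, 13358)  # > 0.95
#' @export
exclusion_power <- function(q, n_chr) {
  if (!is.numeric(q) || is.na(q) || q < 0 || q > 1) stop("q must be in [0, 1]")
  n_chr <- as.integer(n_chr)
  if (is.na(n_chr) || n_chr < 0L) stop("n_chr must be a non-negative integer")
  1 - (1 - q)^n_chr
}
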