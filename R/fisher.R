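#' Fisher exact test on a 2x2 contingency table
#'
#' Exact hypergeometric test with both margins fixed. The table is read as
#' `a` = regulated and high, `b` = regulated and not high, `c` = not
#' regulated and high, `d` = neither. `sided = "greater"` is the
#' enrichment tail P(X >= a); `sided = "two_sided"` sums the point
#' probabilities of every table (same margins) whose probability does not
#' exceed that of the observed table, the usual small-sample two-sided
#' convention.
#'
#' @param a,b,c,d Non-negative integer cell counts; `a` may also be a
#'   2x2 matrix or a length-4 vector, in which case `b`, `c`, `d` are
#'   ignored. Matrix layout is row-major `rbind(c(a, b), c(c, d))`.
#' @param sided `"greater"` or `"two_sided"`.
#' @return The p-value, a number in \[0, 1\].
#' @examples
#' fisher_exact(5, 0, 0, 5, sided = "greater")  # 1 / choose(10, 5)
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL,
                         sided = c("greater", "two_sided")) {
  sided <- match.arg(sided)
  if (is.matrix(a) || length(a) == 4) {
    cells <- if (is.matrix(a)) as.vector(t(a)) else as.vector(a)
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  }
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    abort("contingency table cells must be non-negative integers")
  }
  n <- sum(cells)
  if (n == 0) abort("empty contingency table")
  m1 <- a + b   # regulated margin
  m2 <- c + d
  k <- a + c    # high margin
  if (sided == "greater") {
    return(phyper(a - 1, m1, m2, k, lower.tail = FALSE))
  }
  support <- max(0, k - m2):min(k, m1)
  probs <- dhyper(support, m1, m2, k)
  p_obs <- dhyper(a, m1, m2, k)
  # relative tolerance guards against ties lost to floating point
  min(1, sum(probs[probs <= p_obs * (1 + 1e-07)]))
}
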