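# Exact Poisson-binomial recurrence probabilities.
#
# K = sum of independent Bernoulli(p_j) over donors; the recurrence test
# asks P(K >= k). The full probability mass function is built by the exact
# dynamic-programming convolution over donors (O(n^2)); the upper tail is
# accumulated smallest-term-first for numerical stability.

#' Exact Poisson-binomial distribution
#'
#' Probability mass function of the number of successes among independent
#' Bernoulli trials with heterogeneous success probabilities, by the exact
#' convolution recursion.
#'
#' @param probs numeric vector of success probabilities in \[0, 1\].
#' @return numeric vector of length `length(probs) + 1`: `P(K = 0..n)`.
#' @export
poisson_binomial_pmf <- function(probs) {
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  f <- 1
  for (p in probs) {
    f <- c(f, 0) * (1 - p) + c(0, f) * p
  }
  f
}

#' Exact Poisson-binomial upper-tail probability
#'
#' `P(K >= k)` for the number of donors mutated in a window, where donor `j`
#' contributes an independent Bernoulli trial with its own window mutation
#' probability. Exact (no normal or Poisson approximation); reduces to the
#' binomial tail when all probabilities are equal.
#'
#' @param probs numeric vector of per-donor probabilities in \[0, 1\].
#' @param k integer; `k <= 0` gives 1, `k > length(probs)` gives 0.
#' @return tail probability in \[0, 1\].
#' @export
poisson_binomial_tail <- function(probs, k) {
  n <- length(probs)
  if (k <= 0) return(1)
  if (k > n) return(0)
  f <- poisson_binomial_pmf(probs)
  tail <- sum(rev(f[(k + 1L):(n + 1L)]))  # smallest terms first
  min(max(tail, 0), 1)
}
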