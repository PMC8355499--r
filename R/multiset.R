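# Exact multi-set intersection test.
#
# Model: m sets of fixed sizes s_1, ..., s_m are drawn independently and
# uniformly at random (without replacement) from a background of n elements.
# The distribution of the m-wise intersection size follows from a chain of
# hypergeometric mixtures: conditioning on the running intersection of the
# first j - 1 sets having size t, the overlap of set j with it is
# Hypergeometric(n, t, s_j), independently of how t arose. For m = 2 this
# reduces to the ordinary hypergeometric distribution. The test suite checks
# the full distribution against an independent multinomial cell-count
# enumeration on all small configurations.

#' Exact distribution of a multi-set intersection size
#'
#' @param background_n Background population size.
#' @param set_sizes Integer vector of set sizes (length >= 1), each
#'   `<= background_n`.
#' @return Numeric vector of probabilities for intersection sizes
#'   `0, 1, ..., min(set_sizes)`.
#' @export
multiset_intersection_pmf <- function(background_n, set_sizes) {
  n <- as.integer(background_n)
  sizes <- as.integer(set_sizes)
  stopifnot(n >= 1, length(sizes) >= 1, all(sizes >= 0), all(sizes <= n))
  kmax <- min(sizes)
  # distribution over the running intersection size, starting from set 1
  dist <- rep(0, n + 1)
  dist[sizes[1] + 1L] <- 1
  for (j in seq_along(sizes)[-1]) {
    new <- rep(0, n + 1)
    for (t in which(dist > 0) - 1L) {
      ks <- 0:min(t, sizes[j])
      new[ks + 1L] <- new[ks + 1L] +
        dist[t + 1L] * stats::dhyper(ks, t, n - t, sizes[j])
    }
    dist <- new
  }
  dist[seq_len(kmax + 1L)]
}

#' Exact multi-set intersection test
#'
#' Probability of observing an intersection at least as large as `observed_k`
#' among `m >= 2` sets drawn independently and uniformly from a common
#' background -- the null used to judge whether cross-study sharing of
#' differentially abundant TE families exceeds chance. All sets are treated
#' as random (none is conditioned on as fixed).
#'
#' @param background_n Background population size.
#' @param set_sizes Integer vector of m >= 2 set sizes.
#' @param observed_k Observed intersection size, `<= min(set_sizes)`.
#' @return One-row tibble with `p.value` = P(intersection >= observed_k) and
#'   `estimate` = expected intersection size under the null.
#' @examples
#' multiset_intersection_test(6, c(3, 3), 3) # p = 1/20
#' @export
multiset_intersection_test <- function(background_n, set_sizes, observed_k) {
  sizes <- as.integer(set_sizes)
  if (length(sizes) < 2) abort("need at least two sets")
  k <- as.integer(observed_k)
  if (k < 0 || k > min(sizes)) {
    abort("observed_k must be between 0 and the smallest set size")
  }
  pmf <- multiset_intersection_pmf(background_n, sizes)
  p <- sum(pmf[(k + 1L):length(pmf)])
  expected <- sum((seq_along(pmf) - 1L) * pmf)
  test_row("exact multi-set intersection test",
           p.value = min(1, p), estimate = expected)
}
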