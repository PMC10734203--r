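#' Hartigan's dip statistic
#'
#' The dip of a sample is the smallest sup-norm distance between its
#' empirical cdf and any unimodal cdf. It is bounded below by `1/(2n)` —
#' attained e.g. by equally spaced points — rises towards 0.25 for balanced
#' well-separated bimodal samples, and is invariant under strictly monotone
#' transformations of the data.
#'
#' The implementation narrows a candidate modal interval while charging the
#' convexification/concavification deviations of the flanks (the classical
#' greatest-convex-minorant / least-concave-majorant scheme); it was checked
#' exactly against a linear-programming formulation of the unimodal-fit
#' problem on small samples.
#'
#' @param x Numeric vector.
#' @return The dip statistic (scalar).
#' @export
dip_statistic <- function(x) {
  x <- x[is.finite(x)]
  .dip_stat(as.numeric(x))
}

#' Dip test of unimodality
#'
#' Monte-Carlo p-value for Hartigan's dip, simulated under the uniform null
#' distribution (the asymptotically least favourable unimodal null): the
#' p-value is the fraction of `n_boot` uniform samples of the same size whose
#' dip is at least as large as the observed one.
#'
#' @param x Numeric sample (at least 10 values).
#' @param n_boot Number of null replicates.
#' @param seed Integer seed for the null simulation.
#' @return List with `statistic`, `p_value`, `n`, `n_boot`.
#' @export
dip_test <- function(x, n_boot = 500, seed = 0L) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 10) stop("dip test requires at least 10 values (got ", n, ")")
  stat <- .dip_stat(as.numeric(x))
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) .dip_stat(stats::runif(n)), numeric(1))
  })
  p <- (1 + sum(null >= stat)) / (n_boot + 1)
  list(statistic = stat, p_value = p, n = n, n_boot = n_boot)
}

#' Gate the novel-pattern search on multimodality of likelihood scores
#'
#' Applies the dip test to the likelihood scores of the predicted genes; a
#' multimodal score distribution (p < alpha) is the evidence that some
#' predicted genes resemble no known pattern.
#'
#' @param scores Numeric likelihood scores (>= 10).
#' @param n_boot,seed Passed to [dip_test()].
#' @return List as from [dip_test()].
#' @export
detect_multimodality <- function(scores, n_boot = 500, seed = 0L) {
  dip_test(scores, n_boot = n_boot, seed = seed)
}
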