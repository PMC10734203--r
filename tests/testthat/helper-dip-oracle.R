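# Exact small-n oracle for the dip statistic, by linear programming.
#
# A cdf in the closure of the unimodal class is convex up to some index B and
# concave from some index A <= B (the overlap being the linear modal
# stretch). For distinct sorted data, dip = (1 + 2*sigma*)/(2n) where sigma*
# is the smallest half-width of deviation bands around the midpoint ecdf
# c_i = i - 1/2 admitting such a shape-constrained monotone function.
dip_lp_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  stopifnot(!anyDuplicated(x))
  c_mid <- seq_len(n) - 0.5
  best <- Inf
  for (A in 1:n) for (B in A:n) {
    nv <- n + 1 # v_1..v_n, sigma
    A2 <- NULL; b2 <- NULL
    for (i in 1:n) {
      r1 <- rep(0, nv); r1[i] <- 1; r1[nv] <- 1
      r2 <- rep(0, nv); r2[i] <- -1; r2[nv] <- 1
      A2 <- rbind(A2, r1, r2); b2 <- c(b2, c_mid[i], -c_mid[i])
    }
    for (i in 1:(n - 1)) {
      r <- rep(0, nv); r[i] <- -1; r[i + 1] <- 1
      A2 <- rbind(A2, r); b2 <- c(b2, 0)
    }
    if (B >= 3) for (i in 1:(B - 2)) {
      d1 <- x[i + 1] - x[i]; d2 <- x[i + 2] - x[i + 1]
      r <- rep(0, nv); r[i] <- d2; r[i + 1] <- -(d1 + d2); r[i + 2] <- d1
      A2 <- rbind(A2, r); b2 <- c(b2, 0)
    }
    if (A <= n - 2) for (i in A:(n - 2)) {
      d1 <- x[i + 1] - x[i]; d2 <- x[i + 2] - x[i + 1]
      r <- rep(0, nv); r[i] <- -d2; r[i + 1] <- (d1 + d2); r[i + 2] <- -d1
      A2 <- rbind(A2, r); b2 <- c(b2, 0)
    }
    sol <- try(boot::simplex(a = c(rep(0, n), 1),
                             A1 = cbind(diag(n), 0), b1 = rep(n, n),
                             A2 = A2, b2 = b2, maxi = FALSE), silent = TRUE)
    if (!inherits(sol, "try-error") && sol$solved == 1) {
      best <- min(best, sol$value)
    }
  }
  (1 + 2 * best) / (2 * n)
}
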