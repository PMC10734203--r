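#' The ten expression-similarity measures
#'
#' Neighbour search uses ten measures of agreement between a query cell's and
#' a reference cell's expression over the shared genes: Pearson, Spearman,
#' cosine, Manhattan, Canberra, Euclidean, the proportionality measures
#' \eqn{\rho_p} and \eqn{\phi_s}, a weighted rank correlation, and the
#' Jaccard index of expression supports. Each measure has a *kind* that
#' drives post-processing: distances are transformed by [to_similarity()] so
#' higher always means more similar, and signed correlation-like measures
#' have negative neighbour similarities clamped to zero during prediction.
#'
#' @return Named character vector mapping measure name to kind
#'   (`"correlation"`, `"distance"` or `"overlap"`).
#' @export
similarity_measures <- function() {
  c(pearson = "correlation", spearman = "correlation", cosine = "correlation",
    manhattan = "distance", canberra = "distance", euclidean = "distance",
    rho_p = "correlation", phi_s = "distance",
    weighted_rank = "correlation", jaccard = "overlap")
}

measure_kind <- function(measure) {
  kinds <- similarity_measures()
  if (!measure %in% names(kinds)) {
    stop("unknown similarity measure: ", measure)
  }
  unname(kinds[[measure]])
}

#' Transform a distance into a similarity
#'
#' \eqn{s = 1 / (1 + d)}: strictly decreasing in the distance, equal to 1 at
#' distance zero.
#'
#' @param d Non-negative distance(s).
#' @return Similarity value(s) in `(0, 1]`.
#' @export
to_similarity <- function(d) {
  if (any(d < 0)) stop("distances must be non-negative")
  1 / (1 + d)
}

row_rank <- function(m) t(apply(m, 1, rank, ties.method = "average"))

#' Pairwise similarity between the rows of two matrices
#'
#' Entry `(i, j)` of the result is `measure` applied to row `i` of `A` and
#' row `j` of `B`, which must share the same gene columns in the same order.
#' Distance-kind measures are returned already transformed by
#' [to_similarity()], so higher always means more similar. Rows that are
#' degenerate for a correlation-kind measure (zero variance, or zero norm
#' for cosine) yield similarity 0 with a warning, so degenerate cells never
#' become preferential neighbours.
#'
#' @param A,B Numeric matrices with identical column count (`>= 2`).
#' @param measure Measure name, see [similarity_measures()].
#' @return `nrow(A)` by `nrow(B)` similarity matrix.
#' @export
pairwise_similarity <- function(A, B, measure = names(similarity_measures())) {
  measure <- match.arg(measure)
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("A and B must share the same gene columns")
  if (ncol(A) < 2) stop("at least two genes are required")
  switch(measure,
    pearson = cor_cross(A, B),
    spearman = cor_cross(row_rank(A), row_rank(B)),
    cosine = cosine_cross(A, B),
    euclidean = to_similarity(euclidean_cross(A, B)),
    manhattan = to_similarity(.manhattan_cross(A, B)),
    canberra = to_similarity(.canberra_cross(A, B)),
    rho_p = rho_p_cross(A, B),
    phi_s = to_similarity(phi_s_cross(A, B)),
    weighted_rank = .weighted_rank_cross(row_rank(A), row_rank(B)),
    jaccard = jaccard_cross(A, B)
  )
}

cor_cross <- function(A, B) {
  suppressWarnings(C <- stats::cor(t(A), t(B)))
  if (anyNA(C)) {
    warning("zero-variance rows under a correlation measure; similarity set to 0")
    C[is.na(C)] <- 0
  }
  C
}

cosine_cross <- function(A, B) {
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  S <- tcrossprod(A, B) / outer(na, nb)
  if (anyNA(S) || any(is.infinite(S))) {
    warning("zero-norm rows under cosine; similarity set to 0")
    S[!is.finite(S)] <- 0
  }
  S
}

euclidean_cross <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

# centered covariance and variances shared by the proportionality measures
prop_parts <- function(A, B) {
  g <- ncol(A)
  Ac <- A - rowMeans(A); Bc <- B - rowMeans(B)
  list(
    cab = tcrossprod(Ac, Bc) / (g - 1),
    va = rowSums(Ac^2) / (g - 1),
    vb = rowSums(Bc^2) / (g - 1)
  )
}

# rho_p(x, y) = 2 cov(x, y) / (var(x) + var(y)); 1 iff y = x + const
rho_p_cross <- function(A, B) {
  p <- prop_parts(A, B)
  den <- outer(p$va, p$vb, "+")
  S <- 2 * p$cab / den
  if (any(den == 0)) {
    warning("zero-variance rows under rho_p; similarity set to 0")
    S[!is.finite(S)] <- 0
  }
  S
}

# phi_s(x, y) = var(x - y) / var(x + y); 0 iff y = x + const (distance kind)
phi_s_cross <- function(A, B) {
  p <- prop_parts(A, B)
  sv <- outer(p$va, p$vb, "+")
  num <- sv - 2 * p$cab
  den <- sv + 2 * p$cab
  D <- num / den
  if (any(den <= 0)) {
    warning("degenerate var(x + y) under phi_s; distance set to +Inf")
    D[den <= 0] <- Inf
  }
  pmax(D, 0)
}

# Jaccard index of supports (> 0); two empty supports give 0
jaccard_cross <- function(A, B) {
  A0 <- (A > 0) * 1; B0 <- (B > 0) * 1
  inter <- tcrossprod(A0, B0)
  uni <- outer(rowSums(A0), rowSums(B0), "+") - inter
  S <- inter / uni
  S[uni == 0] <- 0
  S
}

#' Support of an expression vector for the Jaccard measure
#'
#' Indices at which the vector is strictly positive.
#'
#' @param x Numeric vector.
#' @return Integer vector of 1-based indices.
#' @export
expression_support <- function(x) which(x > 0)
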