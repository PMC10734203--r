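#' Spatial weight matrix with self-loops
#'
#' Builds a k-nearest-neighbour graph on the cell coordinates, symmetrizes
#' it by union, and balances it so that each row's neighbour weights sum to
#' 0.5 while the diagonal (the self-loop) is 0.5 — so every row of the full
#' operator sums to 1. Balancing alternates row normalization with
#' symmetrization (a Sinkhorn-style iteration), which keeps the matrix
#' exactly symmetric and drives row sums to 0.5 within `tol` on typical
#' spatial lattices. The self-loop is what makes the derived spatial
#' cross-correlation reward two genes that agree in the *same* cells, not
#' only in neighbouring ones.
#'
#' @param coords Cells x 2 coordinate matrix.
#' @param k_spatial Number of spatial nearest neighbours.
#' @param tol Row-sum tolerance for the balancing iteration.
#' @param max_iter Iteration cap.
#' @return Object of class `spatial_weights`: list with `W` (sparse
#'   symmetric cells x cells matrix including the 0.5 diagonal) and
#'   `k_spatial`.
#' @export
build_spatial_weights <- function(coords, k_spatial = 6, tol = 1e-9,
                                  max_iter = 200) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k_spatial >= n) stop("k_spatial must be smaller than the number of cells")
  nn <- FNN::get.knn(coords, k = k_spatial)$nn.index
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(n), k_spatial), j = as.vector(nn), x = 1,
    dims = c(n, n)
  )
  A <- ((A + Matrix::t(A)) > 0) * 1 # union symmetrization
  W <- A
  for (it in seq_len(max_iter)) {
    rs <- Matrix::rowSums(W)
    if (max(abs(rs - 0.5)) < tol && it > 1) break
    W <- Matrix::Diagonal(x = 0.5 / rs) %*% W
    W <- (W + Matrix::t(W)) / 2
  }
  W <- W + Matrix::Diagonal(n, 0.5)
  if (!is.null(rownames(coords))) dimnames(W) <- list(rownames(coords), rownames(coords))
  structure(list(W = W, k_spatial = k_spatial), class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("<spatial_weights> ", nrow(x$W), " cells, k = ", x$k_spatial,
      ", 0.5 self-loops\n", sep = "")
  invisible(x)
}

# strip the self-loop: Moran's I uses the neighbour part only
offdiag <- function(sw) {
  W <- sw$W
  W - Matrix::Diagonal(nrow(W), Matrix::diag(W))
}

#' Moran's I for one expression vector
#'
#' \deqn{I = \frac{n}{\sum_{ij} w_{ij}} \frac{\sum_{ij} w_{ij}(x_i - \bar x)
#' (x_j - \bar x)}{\sum_i (x_i - \bar x)^2}} computed on the neighbour
#' (off-diagonal) part of the spatial weights, with a one-sided p-value for
#' positive autocorrelation from the normal approximation under
#' randomization.
#'
#' @param x Per-cell expression vector.
#' @param sw A [build_spatial_weights()] object.
#' @return List with `I`, `expected`, `sd`, `p`.
#' @export
morans_i <- function(x, sw) {
  if (stats::sd(x) == 0) stop("Moran's I is undefined for constant input")
  res <- morans_test(matrix(x, ncol = 1, dimnames = list(NULL, "x")), sw)
  list(I = unname(res$I[1]), expected = unname(res$expected[1]),
       sd = unname(res$sd[1]), p = unname(res$p[1]))
}

#' Moran's I for every gene of an expression matrix
#'
#' Vectorized version of [morans_i()] over the columns of `expr`, with
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param expr Cells x genes matrix.
#' @param sw A [build_spatial_weights()] object.
#' @return Tibble with columns `gene_id`, `I`, `expected`, `sd`, `p`,
#'   `p_adj`; constant genes get `NA` statistics.
#' @export
morans_test <- function(expr, sw) {
  W0 <- offdiag(sw)
  n <- nrow(expr)
  if (n != nrow(W0)) stop("expression and weights disagree on cell count")
  S0 <- sum(W0)
  # symmetric W: S1 = 0.5 * sum((w_ij + w_ji)^2), S2 = sum((row + col)^2)
  S1 <- 2 * sum(W0@x^2)
  rs <- Matrix::rowSums(W0)
  S2 <- sum((2 * rs)^2)
  Xc <- sweep(expr, 2, colMeans(expr))
  ss <- colSums(Xc^2)
  num <- colSums(Xc * as.matrix(W0 %*% Xc))
  I <- (n / S0) * num / ss
  EI <- -1 / (n - 1)
  b2 <- n * colSums(Xc^4) / ss^2
  varI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
           b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  sdI <- sqrt(pmax(varI, 0))
  p <- stats::pnorm((I - EI) / sdI, lower.tail = FALSE)
  const <- ss == 0
  I[const] <- NA_real_; p[const] <- NA_real_
  tibble::tibble(
    gene_id = colnames(expr) %||% paste0("g", seq_along(I)),
    I = I, expected = EI, sd = sdI, p = p,
    p_adj = stats::p.adjust(p, method = "BH")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select spatially variable genes
#'
#' Genes with Benjamini-Hochberg adjusted Moran's I p-value below `alpha`
#' that are expressed (value > 0) in at least `min_frac` of the cells.
#'
#' @param expr Cells x genes expression matrix.
#' @param sw A [build_spatial_weights()] object.
#' @param alpha Adjusted p-value threshold.
#' @param min_frac Minimum expressed fraction.
#' @return Character vector of retained gene ids.
#' @export
filter_spatial_genes <- function(expr, sw, alpha = 0.05, min_frac = 0.05) {
  mt <- morans_test(expr, sw)
  frac <- colMeans(expr > 0)
  keep <- !is.na(mt$p_adj) & mt$p_adj < alpha & frac >= min_frac
  mt$gene_id[keep]
}

#' Spatial cross-correlation index (SCI) of two vectors
#'
#' \deqn{SCI(x, y) = \frac{n}{\sum_{ij} w_{ij}} \frac{\sum_{ij} w_{ij}
#' (x_i - \bar x)(y_j - \bar y)}{\sqrt{\sum_i (x_i-\bar x)^2}
#' \sqrt{\sum_i (y_i-\bar y)^2}}} using the FULL weight matrix including the
#' 0.5 self-loops, so that agreement of the two genes within the same cell
#' raises the score (the departure from the classical cross-correlation,
#' which drops self-pairs).
#'
#' @param x,y Per-cell vectors.
#' @param sw A [build_spatial_weights()] object.
#' @return Scalar SCI.
#' @export
sci <- function(x, y, sw) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("SCI is undefined for constant input")
  }
  sci_matrix(cbind(x = x), sw, cbind(y = y))[1, 1]
}

#' SCI between all column pairs of one or two matrices
#'
#' @param X Cells x genes matrix.
#' @param sw A [build_spatial_weights()] object.
#' @param Y Optional second matrix (defaults to `X`).
#' @return Genes(X) x genes(Y) SCI matrix (symmetric when `Y` is `X`).
#' @export
sci_matrix <- function(X, sw, Y = NULL) {
  W <- sw$W
  n <- nrow(X)
  if (is.null(Y)) Y <- X
  stopifnot(nrow(Y) == n, nrow(W) == n)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  nx <- sqrt(colSums(Xc^2)); ny <- sqrt(colSums(Yc^2))
  S <- (n / sum(W)) * crossprod(Xc, as.matrix(W %*% Yc)) / outer(nx, ny)
  S
}
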