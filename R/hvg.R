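#' Standardized per-gene dispersion
#'
#' Variance of (log-normalized) expression standardized by a mean-binned
#' expected variance: genes are grouped into `n_bins` equal-frequency bins of
#' mean expression, and each gene's variance is divided by the median
#' variance of its bin. This removes the mean-variance trend so that highly
#' variable genes can be ranked across the expression range.
#'
#' @param m Log-normalized expression matrix.
#' @param n_bins Number of mean-expression bins.
#' @return Tibble with columns `gene_id`, `mean`, `variance`, `dispersion`,
#'   sorted by decreasing dispersion.
#' @export
gene_dispersion <- function(m, n_bins = 20) {
  mu <- colMeans(m)
  v <- matrixStats_colVars(m)
  # keep ~20 genes per bin so a bin cannot be filled by variable genes alone
  n_bins <- max(1L, min(n_bins, floor(ncol(m) / 20)))
  if (n_bins == 1L || length(unique(mu)) < 2L) {
    bins <- rep(1L, ncol(m))
  } else {
    breaks <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
    bins <- cut(mu, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  }
  expected <- stats::ave(v, bins, FUN = function(z) {
    md <- stats::median(z[z > 0])
    if (!is.finite(md) || md == 0) md <- 1
    md
  })
  disp <- v / expected
  tibble::tibble(
    gene_id = colnames(m),
    mean = mu,
    variance = v,
    dispersion = disp
  )[order(disp, decreasing = TRUE), ]
}

# column variances without an extra dependency
matrixStats_colVars <- function(m) {
  n <- nrow(m)
  if (n < 2) return(rep(0, ncol(m)))
  mu <- colMeans(m)
  (colSums(m^2) - n * mu^2) / (n - 1)
}

#' Top highly variable genes of one matrix
#'
#' @param m Log-normalized expression matrix.
#' @param n Number of genes to select; when it exceeds the gene count all
#'   genes are returned with a warning.
#' @param n_bins Bins for [gene_dispersion()].
#' @return Character vector of gene ids ranked by dispersion.
#' @export
select_hvg <- function(m, n = 2000, n_bins = 20) {
  d <- gene_dispersion(m, n_bins = n_bins)
  if (n > nrow(d)) {
    warning("requested ", n, " HVGs but only ", nrow(d), " genes present; using all")
    n <- nrow(d)
  }
  d$gene_id[seq_len(n)]
}

#' Union of per-reference highly variable genes
#'
#' Each reference contributes its top `n_per_ref` genes by standardized
#' dispersion; the union across references (optionally minus the query's
#' measured panel) defines the default prediction targets.
#'
#' @param refs List of log-normalized reference matrices.
#' @param n_per_ref Genes per reference.
#' @param exclude Character vector of genes to drop from the union (typically
#'   the query's measured panel).
#' @param n_bins Bins for [gene_dispersion()].
#' @return Character vector of gene ids (sorted).
#' @export
select_hvg_union <- function(refs, n_per_ref = 2000, exclude = NULL, n_bins = 20) {
  if (!is.list(refs)) refs <- list(refs)
  hv <- unlist(lapply(refs, select_hvg, n = n_per_ref, n_bins = n_bins))
  out <- sort(unique(hv))
  if (!is.null(exclude)) out <- setdiff(out, exclude)
  out
}
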