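#' Construct a validated expression matrix
#'
#' The package's universal carrier for expression data is a plain numeric
#' matrix with cells in rows and genes in columns, unique `rownames` (cell
#' ids), unique `colnames` (gene ids), and a `"normalized"` attribute that
#' records whether the values are log-normalized (`TRUE`) or raw counts
#' (`FALSE`).
#'
#' @param values Numeric cells-by-genes matrix (or object coercible to one,
#'   including sparse `Matrix` classes). Values must be finite and
#'   non-negative.
#' @param cell_ids,gene_ids Optional character vectors overriding the
#'   dimnames of `values`.
#' @param normalized Logical flag; `TRUE` when values are already
#'   log-normalized.
#' @return The validated matrix with dimnames and the `normalized` attribute
#'   set.
#' @export
expression_matrix <- function(values, cell_ids = NULL, gene_ids = NULL,
                              normalized = FALSE) {
  if (inherits(values, "Matrix")) values <- as.matrix(values)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(cell_ids)) rownames(values) <- cell_ids
  if (!is.null(gene_ids)) colnames(values) <- gene_ids
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("cell", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("gene", seq_len(ncol(values)))
  }
  validate_expression_matrix(values)
  attr(values, "normalized") <- isTRUE(normalized)
  values
}

validate_expression_matrix <- function(m) {
  if (anyDuplicated(rownames(m)) > 0) {
    stop("duplicate cell ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(m)) > 0) {
    stop("duplicate gene ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  if (!all(is.finite(m))) stop("expression values must be finite")
  invisible(m)
}

is_normalized <- function(m) isTRUE(attr(m, "normalized"))

#' Log-normalize raw counts
#'
#' Per-cell library-size normalization followed by `log1p`: each cell's
#' counts are divided by that cell's total, multiplied by `scale`, then
#' transformed with `log(1 + x)`. This is the conventional "LogNormalize"
#' scheme; the scale factor defaults to `1e4`.
#'
#' Cell totals can optionally be computed on a subset of genes
#' (`size_factor_genes`) while the transform is applied to all genes; this
#' keeps query and reference on a comparable per-cell scale when the two
#' share only part of their panels.
#'
#' @param m Expression matrix of raw counts (`normalized` attribute `FALSE`).
#' @param scale Positive scale factor applied after division by cell totals.
#' @param size_factor_genes Optional character vector of gene ids used to
#'   compute cell totals; defaults to all genes.
#' @return Log-normalized expression matrix with the `normalized` flag set.
#' @export
log_normalize <- function(m, scale = 1e4, size_factor_genes = NULL) {
  if (is_normalized(m)) stop("matrix is already log-normalized")
  stopifnot(scale > 0)
  if (any(m < 0)) stop("raw counts must be non-negative")
  genes <- if (is.null(size_factor_genes)) colnames(m) else size_factor_genes
  missing <- setdiff(genes, colnames(m))
  if (length(missing) > 0) {
    stop("size_factor_genes absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  totals <- rowSums(m[, genes, drop = FALSE])
  if (any(totals == 0)) {
    stop("cells with zero total counts: ",
         paste(utils::head(rownames(m)[totals == 0], 5), collapse = ", "))
  }
  out <- log1p(m / totals * scale)
  attr(out, "normalized") <- TRUE
  out
}

#' Genes shared by a query and every reference
#'
#' Intersection of the query's genes with the genes present in all
#' references, returned in canonical (lexicographic) order. All cross-matrix
#' alignment in the package goes through gene-id joins in this order.
#'
#' @param query Expression matrix of the spatial query.
#' @param refs List of reference expression matrices.
#' @return Character vector of shared gene ids, sorted.
#' @export
shared_genes <- function(query, refs) {
  if (!is.list(refs)) refs <- list(refs)
  if (length(refs) == 0) stop("at least one reference is required")
  common <- colnames(query)
  for (r in refs) common <- intersect(common, colnames(r))
  if (length(common) == 0) stop("query and references share no genes")
  sort(common)
}

#' Per-gene sparsity
#'
#' Fraction of cells in which each gene has expression exactly zero.
#'
#' @param m Expression matrix.
#' @return Tibble with columns `gene_id` and `sparsity` (in `[0, 1]`).
#' @export
gene_sparsity <- function(m) {
  tibble::tibble(
    gene_id = colnames(m),
    sparsity = unname(colMeans(m == 0))
  )
}

#' Construct a spatial query (expression + coordinates)
#'
#' @param expr Expression matrix.
#' @param coords Cells-by-2 numeric matrix (or data frame) of spatial
#'   coordinates; rownames must match the expression matrix cell ids (rows
#'   are matched by id when named, by position otherwise).
#' @return List with elements `expr` and `coords`, class `spatial_query`.
#' @export
spatial_query <- function(expr, coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2) stop("coords must have exactly two columns")
  if (nrow(coords) != nrow(expr)) {
    stop("coords rows (", nrow(coords), ") must match cells (", nrow(expr), ")")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (!is.null(rownames(coords))) {
    if (!setequal(rownames(coords), rownames(expr))) {
      stop("coords rownames do not match expression cell ids")
    }
    coords <- coords[rownames(expr), , drop = FALSE]
  } else {
    rownames(coords) <- rownames(expr)
  }
  colnames(coords) <- c("x", "y")
  structure(list(expr = expr, coords = coords), class = "spatial_query")
}

#' @export
print.spatial_query <- function(x, ...) {
  cat("<spatial_query> ", nrow(x$expr), " cells x ", ncol(x$expr),
      " genes, 2-D coordinates\n", sep = "")
  invisible(x)
}

#' Split a sub-reference into shared and unique gene blocks
#'
#' @param ref Reference expression matrix (one partition).
#' @param shared Character vector of shared genes, in canonical order.
#' @param origin Label of the source reference.
#' @param index Integer index of the sub-reference.
#' @return List with `shared` and `unique` blocks (identical cell order),
#'   class `sub_reference`.
#' @keywords internal
sub_reference <- function(ref, shared, origin = "ref", index = 1L) {
  miss <- setdiff(shared, colnames(ref))
  if (length(miss) > 0) {
    stop("reference lacks shared genes: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  uniq <- setdiff(colnames(ref), shared)
  structure(list(
    shared = ref[, shared, drop = FALSE],
    unique = ref[, uniq, drop = FALSE],
    origin = origin,
    index = as.integer(index)
  ), class = "sub_reference")
}
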