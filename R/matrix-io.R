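#' Read an expression matrix from disk
#'
#' Three on-disk layouts are supported, all cells-by-genes unless
#' `orientation = "genes_by_cells"`:
#'
#' * `"csv"` — comma-separated, header row of gene ids, first column of cell
#'   ids;
#' * `"mtx"` — MatrixMarket triplet file with sidecar `genes.tsv` and
#'   `barcodes.tsv` id files (1-based indices per the MTX standard);
#' * `"h5"` — HDF5 annotated-matrix container in the h5ad layout (`X` dense
#'   or CSR/CSC sparse, `obs/_index` cell ids, `var/_index` gene ids).
#'
#' @param path File path. For `"mtx"`, the `.mtx` file; gene and barcode
#'   files are looked up beside it (or passed explicitly).
#' @param format One of `"csv"`, `"mtx"`, `"h5"`; guessed from the file
#'   extension when missing.
#' @param genes_file,cells_file Sidecar id files for `"mtx"`.
#' @param orientation `"cells_by_genes"` (default) or `"genes_by_cells"` for
#'   transposed dumps.
#' @param normalized Logical; sets the `normalized` attribute of the result.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("guess", "csv", "mtx", "h5"),
                            genes_file = NULL, cells_file = NULL,
                            orientation = c("cells_by_genes", "genes_by_cells"),
                            normalized = FALSE) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "guess") {
    format <- switch(tolower(tools::file_ext(path)),
      "csv" = "csv", "mtx" = "mtx",
      "h5" = "h5", "h5ad" = "h5", "hdf5" = "h5",
      stop("cannot guess format from extension of ", path)
    )
  }
  m <- switch(format,
    csv = read_expr_csv(path),
    mtx = read_expr_mtx(path, genes_file, cells_file),
    h5 = read_expr_h5(path)
  )
  if (orientation == "genes_by_cells") m <- t(m)
  expression_matrix(m, normalized = normalized)
}

read_expr_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, header = TRUE, row.names = 1, check.names = FALSE),
    error = function(e) stop("malformed CSV at ", path, ": ", conditionMessage(e))
  )
  as.matrix(df)
}

read_expr_mtx <- function(path, genes_file, cells_file) {
  if (is.null(genes_file)) genes_file <- file.path(dirname(path), "genes.tsv")
  if (is.null(cells_file)) cells_file <- file.path(dirname(path), "barcodes.tsv")
  for (f in c(genes_file, cells_file)) {
    if (!file.exists(f)) stop("missing MTX sidecar file: ", f)
  }
  m <- as.matrix(Matrix::readMM(path))
  genes <- readLines(genes_file)
  cells <- readLines(cells_file)
  if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
    stop("MTX dimensions ", nrow(m), "x", ncol(m),
         " do not match id files (", length(cells), " cells, ",
         length(genes), " genes)")
  }
  dimnames(m) <- list(cells, genes)
  m
}

read_expr_h5 <- function(path) {
  on.exit(rhdf5::H5close(), add = TRUE)
  cells <- as.character(rhdf5::h5read(path, "obs/_index"))
  genes <- as.character(rhdf5::h5read(path, "var/_index"))
  ls <- rhdf5::h5ls(path)
  x_entries <- ls$name[ls$group == "/X"]
  if (length(x_entries) == 0) {
    m <- rhdf5::h5read(path, "X")
    # h5ad stores X as n_obs x n_var; HDF5 is row-major so R reads it
    # transposed relative to the python convention when written natively.
    if (nrow(m) == length(genes) && ncol(m) == length(cells)) m <- t(m)
  } else {
    data <- as.numeric(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    enc <- tryCatch(rhdf5::h5readAttributes(path, "X")$`encoding-type`,
                    error = function(e) NULL)
    if (is.null(enc)) enc <- "csr_matrix"
    if (grepl("csr", enc)) {
      sm <- Matrix::sparseMatrix(
        j = indices + 1L, p = indptr, x = data,
        dims = c(length(cells), length(genes))
      )
    } else {
      sm <- Matrix::sparseMatrix(
        i = indices + 1L, p = indptr, x = data,
        dims = c(length(cells), length(genes))
      )
    }
    m <- as.matrix(sm)
  }
  dimnames(m) <- list(cells, genes)
  m
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression()]; the same three formats are supported and
#' round-trip to value-identical matrices.
#'
#' @param m Expression matrix.
#' @param path Output path.
#' @param format One of `"csv"`, `"mtx"`, `"h5"`; guessed from extension.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, format = c("guess", "csv", "mtx", "h5")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- switch(tolower(tools::file_ext(path)),
      "csv" = "csv", "mtx" = "mtx",
      "h5" = "h5", "h5ad" = "h5", "hdf5" = "h5",
      stop("cannot guess format from extension of ", path)
    )
  }
  switch(format,
    csv = utils::write.csv(as.data.frame(as.matrix(m)), path, row.names = TRUE),
    mtx = {
      Matrix::writeMM(Matrix::Matrix(as.matrix(m), sparse = TRUE), path)
      writeLines(colnames(m), file.path(dirname(path), "genes.tsv"))
      writeLines(rownames(m), file.path(dirname(path), "barcodes.tsv"))
    },
    h5 = {
      if (file.exists(path)) file.remove(path)
      rhdf5::h5createFile(path)
      # store transposed so python-convention readers see n_obs x n_var
      rhdf5::h5write(t(as.matrix(m)), path, "X")
      rhdf5::h5createGroup(path, "obs")
      rhdf5::h5createGroup(path, "var")
      rhdf5::h5write(rownames(m), path, "obs/_index")
      rhdf5::h5write(colnames(m), path, "var/_index")
      rhdf5::H5close()
    }
  )
  invisible(path)
}

#' Read per-cell spatial coordinates
#'
#' Two-column CSV keyed by cell id (first column cell ids, then `x`, `y`).
#'
#' @param path CSV path.
#' @param cell_ids Optional character vector used to order rows.
#' @return Numeric matrix with columns `x`, `y` and cell-id rownames.
#' @export
read_coords <- function(path, cell_ids = NULL) {
  df <- utils::read.csv(path, header = TRUE, row.names = 1, check.names = FALSE)
  if (ncol(df) < 2) stop("coordinate file must have two value columns")
  coords <- as.matrix(df[, 1:2])
  colnames(coords) <- c("x", "y")
  if (!is.null(cell_ids)) {
    miss <- setdiff(cell_ids, rownames(coords))
    if (length(miss) > 0) {
      stop("coordinates missing for cells: ",
           paste(utils::head(miss, 5), collapse = ", "))
    }
    coords <- coords[cell_ids, , drop = FALSE]
  }
  coords
}

#' Write per-cell coordinates as CSV
#' @param coords Matrix with cell-id rownames and columns `x`, `y`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_coords <- function(coords, path) {
  utils::write.csv(as.data.frame(coords), path, row.names = TRUE)
  invisible(path)
}
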