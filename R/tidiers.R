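#' Tidy an imputation fit
#'
#' One row per sub-reference with its predictive power and ensemble weight.
#'
#' @param x An `st_imputation` object.
#' @param ... Unused.
#' @return Tibble with columns `sub_reference`, `origin`, `n_cells`, `s`,
#'   `omega`.
#' @export
tidy.st_imputation <- function(x, ...) x$weights

#' One-row summary of an imputation fit
#'
#' @param x An `st_imputation` object.
#' @param ... Unused.
#' @return Tibble with cell/gene counts and the weight spread.
#' @export
glance.st_imputation <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$prediction),
    n_targets = ncol(x$prediction),
    n_shared = length(x$shared_genes),
    n_sub_references = nrow(x$weights),
    omega_min = min(x$weights$omega),
    omega_max = max(x$weights$omega)
  )
}

#' Tidy cross-validation results
#'
#' @param x An `st_cv` tibble.
#' @param ... Unused.
#' @return The per-gene metric tibble (gene_id, pcc, scc, rmse, fold).
#' @export
tidy.st_cv <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of cross-validation results
#'
#' @param x An `st_cv` tibble.
#' @param ... Unused.
#' @return Tibble with mean/median PCC and SCC, mean RMSE, gene counts.
#' @export
glance.st_cv <- function(x, ...) {
  tibble::tibble(
    n_genes = length(unique(x$gene_id)),
    n_folds = attr(x, "scheme")$n_folds,
    mean_pcc = mean(x$pcc, na.rm = TRUE),
    median_pcc = stats::median(x$pcc, na.rm = TRUE),
    mean_scc = mean(x$scc, na.rm = TRUE),
    mean_rmse = mean(x$rmse, na.rm = TRUE),
    n_zero_variance = sum(x$zero_variance)
  )
}

#' Tidy a pattern set
#'
#' @param x An `st_patterns` object.
#' @param ... Unused.
#' @return The membership tibble.
#' @export
tidy.st_patterns <- function(x, ...) x$membership

#' One-row-per-pattern summary of a pattern set
#'
#' @param x An `st_patterns` object.
#' @param ... Unused.
#' @return Tibble with pattern ids and member counts.
#' @export
glance.st_patterns <- function(x, ...) {
  dplyr::count(x$membership, .data$pattern, name = "n_genes")
}
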