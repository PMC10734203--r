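#' Split genes into cross-validation folds
#'
#' `N` disjoint subsets of sizes differing by at most one, assigned by a
#' seeded random permutation. Leave-one-out is `mode = "loo"` (one fold per
#' gene).
#'
#' @param genes Character vector of gene ids.
#' @param n_folds Number of folds (ignored for `"loo"`).
#' @param mode `"kfold"` or `"loo"`.
#' @param seed Integer seed.
#' @return List of character vectors partitioning `genes`.
#' @export
make_folds <- function(genes, n_folds = 5, mode = c("kfold", "loo"), seed = 0L) {
  mode <- match.arg(mode)
  g <- length(genes)
  if (mode == "loo") n_folds <- g
  n_folds <- as.integer(n_folds)
  if (n_folds < 2 || n_folds > g) {
    stop("n_folds must be between 2 and the number of genes (", g, ")")
  }
  perm <- withr::with_seed(seed, sample(genes))
  sizes <- rep(floor(g / n_folds), n_folds)
  rem <- g - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(n_folds), function(i) perm[starts[i]:ends[i]])
}

#' Per-gene prediction accuracy metrics
#'
#' Pearson correlation (PCC), Spearman correlation (SCC) and root mean
#' square error between measured and predicted expression, per gene across
#' cells. Genes with zero variance in the measured values get `NA`
#' correlations (undefined) and are flagged.
#'
#' @param predicted,measured Cells x genes matrices with identical dimnames.
#' @return Tibble with columns `gene_id`, `pcc`, `scc`, `rmse`,
#'   `zero_variance`.
#' @export
gene_metrics <- function(predicted, measured) {
  stopifnot(all(dim(predicted) == dim(measured)))
  genes <- colnames(measured)
  pcc <- scc <- rmse <- numeric(length(genes))
  zv <- logical(length(genes))
  for (j in seq_along(genes)) {
    p <- predicted[, j]; o <- measured[, j]
    rmse[j] <- sqrt(mean((p - o)^2))
    if (stats::sd(o) == 0 || stats::sd(p) == 0) {
      zv[j] <- TRUE
      pcc[j] <- NA_real_; scc[j] <- NA_real_
    } else {
      pcc[j] <- stats::cor(p, o)
      scc[j] <- stats::cor(p, o, method = "spearman")
    }
  }
  tibble::tibble(gene_id = genes, pcc = pcc, scc = scc, rmse = rmse,
                 zero_variance = zv)
}

#' Cross-validation on spatially measured genes
#'
#' The shared genes are split into folds; in each iteration one fold is held
#' out, the remaining shared genes act as the common panel, the held-out
#' genes are predicted by [impute_expression()], and per-gene PCC/SCC/RMSE
#' against the measured values are recorded.
#'
#' @param query Query expression matrix.
#' @param refs List of reference expression matrices.
#' @param n_folds Number of folds.
#' @param mode `"kfold"` or `"loo"`.
#' @param config An [impute_config()].
#' @param normalize Passed to [impute_expression()]. When `TRUE` the metrics
#'   compare against the log-normalized measured values.
#' @param seed Seed for the fold assignment.
#' @return Object of class `st_cv`: tibble of per-gene metrics with a `fold`
#'   column, plus attributes `scheme` and `weights` (per-fold weight tables).
#' @export
cross_validate <- function(query, refs, n_folds = 5, mode = c("kfold", "loo"),
                           config = impute_config(), normalize = TRUE,
                           seed = 0L) {
  mode <- match.arg(mode)
  if (!is.list(refs)) refs <- list(refs)
  shared_all <- shared_genes(query, refs)
  folds <- make_folds(shared_all, n_folds = n_folds, mode = mode, seed = seed)
  measured <- query[, shared_all, drop = FALSE]
  if (normalize) {
    measured <- log_normalize(query, size_factor_genes = shared_all)[, shared_all, drop = FALSE]
  }
  out <- list()
  wts <- list()
  for (f in seq_along(folds)) {
    held <- folds[[f]]
    common <- setdiff(shared_all, held)
    if (length(common) < 2) {
      stop("fold ", f, " leaves fewer than two common genes")
    }
    fit <- impute_expression(query, refs, targets = held, config = config,
                             normalize = normalize, shared = common)
    met <- gene_metrics(fit$prediction[, held, drop = FALSE],
                        measured[, held, drop = FALSE])
    met$fold <- f
    out[[f]] <- met
    wts[[f]] <- fit$weights
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("st_cv", class(res))
  attr(res, "scheme") <- list(n_folds = length(folds), mode = mode, seed = seed)
  attr(res, "weights") <- wts
  res
}

#' Accuracy ratio between two methods
#'
#' Number of genes on which method A is strictly better divided by the
#' number on which it is strictly worse; ties count in neither. A ratio
#' above 1 means A wins on more genes. With zero losses the ratio is `Inf`
#' (reported with the counts).
#'
#' @param metric_a,metric_b Per-gene metric values for the two methods, same
#'   gene order.
#' @param higher_better `TRUE` for PCC/SCC, `FALSE` for RMSE.
#' @return List with `ar`, `n_better`, `n_worse`, `n_ties`.
#' @export
accuracy_ratio <- function(metric_a, metric_b, higher_better = TRUE) {
  stopifnot(length(metric_a) == length(metric_b))
  keep <- !is.na(metric_a) & !is.na(metric_b)
  a <- metric_a[keep]; b <- metric_b[keep]
  better <- if (higher_better) sum(a > b) else sum(a < b)
  worse <- if (higher_better) sum(a < b) else sum(a > b)
  list(
    ar = if (worse == 0) Inf else better / worse,
    n_better = better, n_worse = worse,
    n_ties = sum(a == b)
  )
}

#' Compare per-gene metric distributions of two methods
#'
#' Convenience Wilcoxon rank-sum test used for reporting; not part of the
#' prediction method itself.
#'
#' @param metric_a,metric_b Per-gene metric values.
#' @param alternative Passed to [stats::wilcox.test()].
#' @return The `htest` object.
#' @export
compare_methods <- function(metric_a, metric_b, alternative = "two.sided") {
  stats::wilcox.test(metric_a, metric_b, alternative = alternative,
                     exact = FALSE)
}
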