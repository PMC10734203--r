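#' Configuration for ensemble imputation
#'
#' Defaults follow the method's standard settings: sub-references of at most
#' `n0 = 8000` cells, neighbourhood sizes `k = {20, 30, 40, 50}`, all ten
#' similarity measures, and sub-reference weights mapped linearly onto
#' `[0.1, 0.9]`.
#'
#' @param n0 Maximum number of cells per sub-reference.
#' @param k_values Integer vector of neighbourhood sizes.
#' @param measures Character vector of similarity measure names.
#' @param seed Integer seed controlling reference partitioning.
#' @param weight_range Length-2 numeric, the range of sub-reference weights.
#' @param weight_map `"minmax"` rescales the observed predictive powers onto
#'   `weight_range`; `"fixed"` maps the interval `[0, 1]` affinely onto it.
#' @return A list of validated settings, class `impute_config`.
#' @export
impute_config <- function(n0 = 8000, k_values = c(20L, 30L, 40L, 50L),
                          measures = names(similarity_measures()),
                          seed = 0L, weight_range = c(0.1, 0.9),
                          weight_map = c("minmax", "fixed")) {
  weight_map <- match.arg(weight_map)
  k_values <- sort(unique(as.integer(k_values)))
  if (any(k_values < 1)) stop("k_values must all be >= 1")
  if (n0 < max(k_values)) stop("n0 must be at least max(k_values)")
  bad <- setdiff(measures, names(similarity_measures()))
  if (length(bad) > 0) stop("unknown measures: ", paste(bad, collapse = ", "))
  if (length(weight_range) != 2 || weight_range[1] >= weight_range[2] ||
      any(weight_range <= 0) || any(weight_range >= 1)) {
    stop("weight_range must be (low, high) with 0 < low < high < 1")
  }
  structure(list(
    n0 = as.integer(n0), k_values = k_values, measures = measures,
    seed = as.integer(seed), weight_range = weight_range,
    weight_map = weight_map
  ), class = "impute_config")
}

#' Randomly partition a reference into equal-sized sub-references
#'
#' A reference of `n` cells is split into `ceiling(n / n0)` disjoint parts
#' whose sizes differ by at most one, by a seeded random permutation.
#'
#' @param ref Reference expression matrix.
#' @param n0 Maximum cells per part.
#' @param seed Integer seed for the permutation.
#' @return List of expression matrices (row subsets of `ref`).
#' @export
partition_reference <- function(ref, n0 = 8000, seed = 0L) {
  n <- nrow(ref)
  stopifnot(n >= 1)
  n_parts <- ceiling(n / n0)
  sizes <- rep(floor(n / n_parts), n_parts)
  rem <- n - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  perm <- withr::with_seed(seed, sample.int(n))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(n_parts), function(p) {
    # original row order within each part; one part is the identity partition
    ref[sort(perm[starts[p]:ends[p]]), , drop = FALSE]
  })
}

#' k nearest neighbours of one similarity row
#'
#' Indices of the `k` largest similarities; ties broken by ascending index.
#'
#' @param sim_row Numeric vector of similarities to all reference cells.
#' @param k Neighbourhood size (`<= length(sim_row)`).
#' @return Integer vector of `k` reference-cell indices.
#' @export
knn_neighbors <- function(sim_row, k) {
  n <- length(sim_row)
  if (k > n) stop("k (", k, ") exceeds the number of reference cells (", n, ")")
  order(-sim_row, seq_len(n))[seq_len(k)]
}

#' Clamp negative neighbour similarities to zero
#'
#' Signed correlation-like measures can assign negative similarity to a
#' neighbour; such weights are set to 0. Distance- and overlap-kind measures
#' are already non-negative and pass through unchanged.
#'
#' @param sims Numeric similarities of the selected neighbours.
#' @param measure Measure name.
#' @return Non-negative weights.
#' @export
clamp_negatives <- function(sims, measure) {
  if (measure_kind(measure) == "correlation") pmax(sims, 0) else sims
}

# Shared worker: neighbour weights for all query cells at one (measure, k),
# given the full similarity matrix. Returns a sparse m x n weight matrix.
# All-zero rows (possible after clamping) fall back to unweighted means.
neighbor_weights <- function(sim, ord, k, measure) {
  m <- nrow(sim)
  idx <- ord[, seq_len(k), drop = FALSE]
  w <- matrix(sim[cbind(rep(seq_len(m), k), as.vector(idx))], nrow = m)
  if (measure_kind(measure) == "correlation") w <- pmax(w, 0)
  zero <- rowSums(w) == 0
  if (any(zero)) w[zero, ] <- 1 # unweighted mean of the k neighbours
  w <- w / rowSums(w)
  Matrix::sparseMatrix(
    i = rep(seq_len(m), k), j = as.vector(idx), x = as.vector(w),
    dims = c(m, ncol(sim))
  )
}

#' One k-NN regression prediction
#'
#' Predicts expression for the query cells as the similarity-weighted average
#' of their `k` nearest reference cells, with neighbours found on the shared
#' genes and values taken from `target` (the unique- or shared-gene block of
#' the sub-reference).
#'
#' @param ref_shared Sub-reference shared-gene block (cells x shared genes).
#' @param target Sub-reference value block (cells x target genes).
#' @param query_shared Query shared-gene block, same gene order as
#'   `ref_shared`.
#' @param measure Similarity measure name.
#' @param k Neighbourhood size.
#' @param sim Optional precomputed similarity matrix
#'   (`pairwise_similarity(query_shared, ref_shared, measure)`).
#' @return Matrix of predictions, query cells x target genes.
#' @export
knn_predict <- function(ref_shared, target, query_shared, measure, k,
                        sim = NULL) {
  if (k > nrow(ref_shared)) {
    stop("k (", k, ") exceeds sub-reference size (", nrow(ref_shared), ")")
  }
  if (is.null(sim)) sim <- pairwise_similarity(query_shared, ref_shared, measure)
  ord <- t(apply(sim, 1, function(s) order(-s, seq_along(s))))[, seq_len(k), drop = FALSE]
  W <- neighbor_weights(sim, ord, k, measure)
  out <- as.matrix(W %*% target)
  dimnames(out) <- list(rownames(query_shared), colnames(target))
  out
}

#' Full stack of base predictions
#'
#' One prediction per (sub-reference, measure, k) triple; mainly useful for
#' inspection and for checking the vectorized path against a direct
#' implementation.
#'
#' @param subrefs List of `sub_reference` objects.
#' @param query_shared Query shared-gene block.
#' @param measures,k_values Measure names and neighbourhood sizes.
#' @param target_kind `"unique"` predicts the unique-gene block, `"shared"`
#'   the shared-gene block (used for predictive power).
#' @return Nested list `stack[[r]][[measure]][[as.character(k)]]`.
#' @export
base_prediction_stack <- function(subrefs, query_shared, measures, k_values,
                                  target_kind = c("unique", "shared")) {
  target_kind <- match.arg(target_kind)
  lapply(subrefs, function(sr) {
    target <- if (target_kind == "unique") sr$unique else sr$shared
    out_t <- lapply(measures, function(t) {
      sim <- pairwise_similarity(query_shared, sr$shared, t)
      out_k <- lapply(k_values, function(k) {
        knn_predict(sr$shared, target, query_shared, t, k, sim = sim)
      })
      names(out_k) <- as.character(k_values)
      out_k
    })
    names(out_t) <- measures
    out_t
  })
}

#' Consensus shared-gene prediction of one sub-reference
#'
#' Plain average over measures and k of the shared-gene base predictions.
#'
#' @param stack Output of [base_prediction_stack()] with
#'   `target_kind = "shared"`.
#' @param r Sub-reference index.
#' @return Matrix, query cells x shared genes.
#' @export
consensus_shared <- function(stack, r) {
  entries <- stack[[r]]
  mats <- unlist(entries, recursive = FALSE)
  if (length(mats) == 0 || any(vapply(mats, is.null, logical(1)))) {
    stop("prediction stack incomplete for sub-reference ", r)
  }
  Reduce(`+`, mats) / length(mats)
}

#' Predictive power of a sub-reference
#'
#' Squared Pearson correlation between the consensus prediction of the
#' shared genes and their measured values, with all cell-by-gene entries
#' pooled.
#'
#' @param pred,observed Matrices of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
predictive_power <- function(pred, observed) {
  stopifnot(all(dim(pred) == dim(observed)))
  p <- as.vector(pred); o <- as.vector(observed)
  if (stats::sd(p) == 0 || stats::sd(o) == 0) {
    warning("zero variance in flattened matrix; predictive power set to 0")
    return(0)
  }
  stats::cor(p, o)^2
}

#' Map predictive powers to ensemble weights
#'
#' The default min-max map sends the smallest observed power to
#' `range[1]` and the largest to `range[2]`; when all powers are equal
#' (including a single sub-reference) every weight is the midpoint. The
#' `"fixed"` alternative maps the interval `[0, 1]` affinely onto `range`
#' irrespective of the observed spread.
#'
#' @param s Numeric vector of predictive powers in `[0, 1]`.
#' @param range Target weight range.
#' @param method `"minmax"` or `"fixed"`.
#' @return Numeric weights, same length as `s`.
#' @export
map_weights <- function(s, range = c(0.1, 0.9), method = c("minmax", "fixed")) {
  method <- match.arg(method)
  stopifnot(length(s) >= 1)
  if (method == "fixed") return(range[1] + s * (range[2] - range[1]))
  if (length(s) == 1 || diff(range(s)) == 0) {
    return(rep(mean(range), length(s)))
  }
  range[1] + (s - min(s)) / (max(s) - min(s)) * (range[2] - range[1])
}

#' Combine a stack of base predictions with sub-reference weights
#'
#' Entry-wise weighted average \eqn{\sum_r \sum_t \sum_k \omega_r
#' \hat Y^{(rtk)} / (|T||K| \sum_r \omega_r)}; the weight depends only on the
#' sub-reference, never on the measure or k.
#'
#' @param stack Output of [base_prediction_stack()] (`"unique"` kind).
#' @param omega Numeric vector, one weight per sub-reference.
#' @return Matrix of ensemble predictions.
#' @export
ensemble_combine <- function(stack, omega) {
  stopifnot(length(stack) == length(omega))
  acc <- NULL
  n_tk <- NULL
  for (r in seq_along(stack)) {
    mats <- unlist(stack[[r]], recursive = FALSE)
    if (is.null(n_tk)) n_tk <- length(mats)
    if (length(mats) != n_tk) stop("ragged prediction stack")
    for (m in mats) {
      if (!is.null(acc) && !all(dim(m) == dim(acc))) {
        stop("prediction shape mismatch in stack")
      }
      acc <- if (is.null(acc)) omega[r] * m else acc + omega[r] * m
    }
  }
  acc / (n_tk * sum(omega))
}

#' Ensemble k-NN imputation of unmeasured genes
#'
#' The full pipeline: log-normalization on the shared panel, reference
#' partitioning into sub-references, base k-NN predictions for every
#' (sub-reference, measure, k) triple, per-sub-reference predictive power
#' estimated on the shared genes, a linear map of powers to weights, and the
#' weighted-average ensemble. With a single sub-reference overall the
#' weighting step is bypassed and base predictions are plainly averaged.
#' References with different gene panels are supported: each target gene is
#' ensembled over the sub-references that contain it, renormalizing by the
#' weights of those present.
#'
#' @param query Query expression matrix (cells x measured genes).
#' @param refs List of reference expression matrices (named if you want
#'   origin labels in the output).
#' @param targets Character vector of genes to predict. Default: all genes
#'   present in at least one reference but absent from the query.
#' @param config An [impute_config()].
#' @param normalize Log-normalize inputs first (`TRUE` for raw counts). When
#'   `FALSE` the inputs are used as given (they should be on a comparable
#'   log scale).
#' @param shared Optional character vector overriding the shared-gene panel
#'   (used by cross-validation to hold genes out).
#' @param return_stack Also return every base prediction (one matrix per
#'   (sub-reference, measure, k) triple) and the per-sub-reference mean base
#'   predictions; costs memory, mainly for inspection and testing.
#' @return Object of class `st_imputation`: list with `prediction` (cells x
#'   targets matrix), `weights` (tibble of per-sub-reference predictive power
#'   and weight), `shared_genes`, `targets`, `config`, and when
#'   `return_stack` also `stack` and `sub_predictions`.
#' @export
impute_expression <- function(query, refs, targets = NULL,
                              config = impute_config(), normalize = TRUE,
                              shared = NULL, return_stack = FALSE) {
  if (!is.list(refs)) refs <- list(refs)
  if (is.null(names(refs)) || any(names(refs) == "")) {
    names(refs) <- paste0("ref", seq_along(refs))
  }
  if (is.null(shared)) shared <- shared_genes(query, refs)
  shared <- sort(shared)
  miss <- setdiff(shared, colnames(query))
  if (length(miss) > 0) {
    stop("shared genes absent from query: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  ref_gene_union <- sort(unique(unlist(lapply(refs, colnames))))
  if (is.null(targets)) targets <- setdiff(setdiff(ref_gene_union, colnames(query)), shared)
  targets <- sort(unique(targets))
  absent <- setdiff(targets, ref_gene_union)
  if (length(absent) > 0) {
    stop("target genes absent from every reference: ",
         paste(utils::head(absent, 10), collapse = ", "))
  }
  overlap <- intersect(targets, shared)
  if (length(overlap) > 0) {
    stop("targets overlap the shared panel: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  }
  if (length(targets) == 0) stop("no target genes to predict")
  if (length(shared) < 2) stop("need at least two shared genes")

  Yq <- query[, shared, drop = FALSE]
  if (normalize) {
    Yq <- log_normalize(query, size_factor_genes = shared)[, shared, drop = FALSE]
  }

  # partition each (normalized) reference, then split shared/unique blocks
  subrefs <- list()
  for (i in seq_along(refs)) {
    ref <- refs[[i]]
    keep <- union(shared, intersect(targets, colnames(ref)))
    ref <- ref[, intersect(colnames(ref), keep), drop = FALSE]
    if (normalize) {
      attr(ref, "normalized") <- attr(refs[[i]], "normalized")
      ref <- log_normalize(ref, size_factor_genes = shared)
    }
    parts <- partition_reference(ref, config$n0, seed = config$seed + i - 1L)
    for (p in seq_along(parts)) {
      subrefs[[length(subrefs) + 1L]] <-
        sub_reference(parts[[p]], shared, origin = names(refs)[i],
                      index = length(subrefs) + 1L)
    }
  }

  m <- nrow(Yq)
  n_tk <- length(config$measures) * length(config$k_values)
  R <- length(subrefs)

  # per-sub-reference mean base predictions (unique targets + shared block)
  mean_unique <- vector("list", R)
  stack <- if (return_stack) vector("list", R) else NULL
  s_r <- numeric(R)
  for (r in seq_len(R)) {
    sr <- subrefs[[r]]
    n_r <- nrow(sr$shared)
    ks <- pmin(config$k_values, n_r)
    if (any(config$k_values > n_r)) {
      warning("k values clipped to sub-reference size ", n_r)
    }
    tgt_here <- intersect(targets, colnames(sr$unique))
    acc_u <- matrix(0, m, length(tgt_here),
                    dimnames = list(rownames(Yq), tgt_here))
    acc_s <- matrix(0, m, length(shared))
    for (t in config$measures) {
      sim <- pairwise_similarity(Yq, sr$shared, t)
      ord <- t(apply(sim, 1, function(s) order(-s, seq_along(s))))[, seq_len(max(ks)), drop = FALSE]
      for (ki in seq_along(ks)) {
        k <- ks[ki]
        W <- neighbor_weights(sim, ord, k, t)
        if (length(tgt_here) > 0) {
          base_u <- as.matrix(W %*% sr$unique[, tgt_here, drop = FALSE])
          acc_u <- acc_u + base_u
          if (return_stack) {
            rownames(base_u) <- rownames(Yq)
            stack[[r]][[t]][[as.character(config$k_values[ki])]] <- base_u
          }
        }
        acc_s <- acc_s + as.matrix(W %*% sr$shared)
      }
    }
    mean_unique[[r]] <- acc_u / n_tk
    s_r[r] <- suppressWarnings(predictive_power(acc_s / n_tk, Yq))
  }

  omega <- map_weights(s_r, range = config$weight_range,
                       method = config$weight_map)
  if (R == 1) omega <- mean(config$weight_range)

  # per-gene ensemble over the sub-references containing each target
  pred <- matrix(NA_real_, m, length(targets),
                 dimnames = list(rownames(Yq), targets))
  wsum <- stats::setNames(numeric(length(targets)), targets)
  acc <- matrix(0, m, length(targets), dimnames = dimnames(pred))
  for (r in seq_len(R)) {
    g <- colnames(mean_unique[[r]])
    if (length(g) == 0) next
    acc[, g] <- acc[, g] + omega[r] * mean_unique[[r]]
    wsum[g] <- wsum[g] + omega[r]
  }
  uncovered <- names(wsum)[wsum == 0]
  if (length(uncovered) > 0) {
    stop("target genes not covered by any sub-reference: ",
         paste(utils::head(uncovered, 10), collapse = ", "))
  }
  pred <- sweep(acc, 2, wsum, "/")

  weights <- tibble::tibble(
    sub_reference = seq_len(R),
    origin = vapply(subrefs, function(s) s$origin, character(1)),
    n_cells = vapply(subrefs, function(s) nrow(s$shared), integer(1)),
    s = s_r,
    omega = omega
  )
  out <- list(
    prediction = pred,
    weights = weights,
    shared_genes = shared,
    targets = targets,
    config = config
  )
  if (return_stack) {
    out$stack <- stack
    out$sub_predictions <- mean_unique
  }
  structure(out, class = "st_imputation")
}

#' @export
print.st_imputation <- function(x, ...) {
  cat("<st_imputation> ", nrow(x$prediction), " cells x ",
      ncol(x$prediction), " predicted genes\n", sep = "")
  cat("  ", length(x$shared_genes), " shared genes, ",
      nrow(x$weights), " sub-reference(s)\n", sep = "")
  print(x$weights)
  invisible(x)
}
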