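#' Threshold an SCI matrix into a weighted gene network
#'
#' Off-diagonal values at or above the `percentile`-th percentile are
#' retained with their weights; the rest, and the diagonal, are set to zero.
#' The threshold is inclusive so a degenerate all-equal matrix keeps every
#' edge.
#'
#' @param sci_mat Symmetric genes x genes SCI matrix.
#' @param percentile Percentile (0-100) below which edges are dropped.
#' @return Symmetric weighted adjacency matrix with zero diagonal.
#' @export
gene_network <- function(sci_mat, percentile = 10) {
  sci_mat <- as.matrix(sci_mat)
  if (nrow(sci_mat) != ncol(sci_mat)) stop("SCI matrix must be square")
  off <- sci_mat[upper.tri(sci_mat) | lower.tri(sci_mat)]
  thr <- stats::quantile(off, probs = percentile / 100, names = FALSE)
  net <- sci_mat
  net[net < thr] <- 0
  diag(net) <- 0
  (net + t(net)) / 2 # exact numerical symmetry
}

make_patterns <- function(membership, expr, kind) {
  ids <- sort(unique(membership))
  profiles <- vapply(ids, function(p) {
    rowMeans(expr[, names(membership)[membership == p], drop = FALSE])
  }, numeric(nrow(expr)))
  colnames(profiles) <- paste0(substr(kind, 1, 1), ids)
  structure(list(
    membership = tibble::tibble(
      gene_id = names(membership),
      pattern = paste0(substr(kind, 1, 1), membership)
    ),
    profiles = profiles,
    kind = kind
  ), class = "st_patterns")
}

#' @export
print.st_patterns <- function(x, ...) {
  sizes <- table(x$membership$pattern)
  cat("<st_patterns> ", length(sizes), " ", x$kind, " pattern(s): ",
      paste(names(sizes), "(", as.integer(sizes), ")",
            sep = "", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Cluster genes of a network into spatial patterns
#'
#' Louvain community detection on the weighted gene network at the given
#' resolution (seeded for determinism). Each community becomes a pattern
#' whose profile is the per-cell mean expression of its member genes.
#' Negative retained edges are clamped to zero for the modularity
#' computation, which requires non-negative weights.
#'
#' @param net Weighted adjacency from [gene_network()].
#' @param expr Cells x genes matrix covering the network's genes.
#' @param resolution Louvain resolution parameter.
#' @param seed Integer seed.
#' @param kind Label stored on the result (`"known"` or `"novel"`).
#' @return An `st_patterns` object.
#' @export
cluster_genes <- function(net, expr, resolution = 1, seed = 0L,
                          kind = "known") {
  stopifnot(nrow(net) >= 1)
  genes <- colnames(net) %||% colnames(expr)[seq_len(ncol(net))]
  dimnames(net) <- list(genes, genes)
  g <- igraph::graph_from_adjacency_matrix(pmax(net, 0), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  cl <- withr::with_seed(seed, igraph::cluster_louvain(
    g, resolution = resolution))
  membership <- igraph::membership(cl)
  names(membership) <- genes
  make_patterns(membership, expr[, genes, drop = FALSE], kind)
}

#' Drop patterns with a single member gene
#'
#' @param patterns An `st_patterns` object.
#' @return The object without single-gene patterns (warning if none remain).
#' @export
filter_singleton_patterns <- function(patterns) {
  sizes <- table(patterns$membership$pattern)
  keep <- names(sizes)[sizes >= 2]
  if (length(keep) == 0) {
    warning("all patterns are singletons; returning an empty pattern set")
  }
  patterns$membership <- patterns$membership[
    patterns$membership$pattern %in% keep, , drop = FALSE]
  patterns$profiles <- patterns$profiles[, keep, drop = FALSE]
  patterns
}

#' Known spatial patterns from measured genes
#'
#' Spatially variable genes (Moran's I, BH-adjusted p < `alpha`, expressed in
#' at least `min_frac` of cells) are connected by their pairwise SCI, the
#' network is thresholded at the 10th percentile, and Louvain clustering at
#' resolution 1 partitions the genes into patterns. Panels with many genes
#' typically also drop single-gene patterns (`drop_singletons`).
#'
#' @param expr Cells x measured-genes matrix (normalized).
#' @param sw A [build_spatial_weights()] object.
#' @param resolution Louvain resolution.
#' @param alpha,min_frac Spatial-gene filter settings.
#' @param percentile Network threshold percentile.
#' @param drop_singletons Remove single-gene patterns.
#' @param seed Integer seed.
#' @return An `st_patterns` object of kind `"known"`.
#' @export
find_known_patterns <- function(expr, sw, resolution = 1, alpha = 0.05,
                                min_frac = 0.05, percentile = 10,
                                drop_singletons = TRUE, seed = 0L) {
  genes <- filter_spatial_genes(expr, sw, alpha = alpha, min_frac = min_frac)
  if (length(genes) < 2) stop("fewer than two spatially variable genes")
  S <- sci_matrix(expr[, genes, drop = FALSE], sw)
  net <- gene_network(S, percentile = percentile)
  pat <- cluster_genes(net, expr, resolution = resolution, seed = seed,
                       kind = "known")
  if (drop_singletons) pat <- filter_singleton_patterns(pat)
  pat
}

#' Likelihood of predicted genes under the known patterns
#'
#' Each gene's likelihood score is its highest SCI against any known-pattern
#' profile; a high score means the gene reproduces a known pattern, a low
#' score means it matches none.
#'
#' @param pred_expr Cells x predicted-genes matrix.
#' @param patterns Known `st_patterns`.
#' @param sw A [build_spatial_weights()] object.
#' @return Tibble with `gene_id`, `score`, `best_pattern`.
#' @export
likelihood_scores <- function(pred_expr, patterns, sw) {
  if (ncol(patterns$profiles) == 0) stop("no known patterns")
  S <- sci_matrix(pred_expr, sw, patterns$profiles)
  best <- max.col(S, ties.method = "first")
  tibble::tibble(
    gene_id = colnames(pred_expr),
    score = S[cbind(seq_len(nrow(S)), best)],
    best_pattern = colnames(patterns$profiles)[best]
  )
}

#' Classify predicted genes by their likelihood scores
#'
#' A Gaussian kernel density estimate (Silverman bandwidth, 512 grid points
#' — the stats::density defaults) of the scores is searched for its two
#' tallest local maxima; the score at the density minimum between them is
#' the split point `s`. Genes with score above `s + delta` are associated
#' with known patterns, below `s - delta` are novel-pattern candidates, and
#' the rest are weakly associated.
#'
#' @param scores Tibble from [likelihood_scores()] (or a numeric vector).
#' @param delta Half-width of the weak band around the split point.
#' @return List with `classification` (tibble with a `group` column),
#'   `s_split`, `density`.
#' @export
classify_by_likelihood <- function(scores, delta = 0.05) {
  tb <- if (is.numeric(scores)) {
    tibble::tibble(gene_id = paste0("g", seq_along(scores)), score = scores)
  } else scores
  d <- stats::density(tb$score)
  y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  peaks <- which(is_max)
  if (length(peaks) < 2) {
    stop("likelihood density has fewer than two local maxima; ",
         "treat as no novel patterns")
  }
  # the two high peaks = the two most *prominent* local maxima, so ragged
  # sub-bumps of one mode are not mistaken for the second mode
  prominence <- vapply(peaks, function(p) {
    taller_l <- peaks[peaks < p & y[peaks] > y[p]]
    taller_r <- peaks[peaks > p & y[peaks] > y[p]]
    saddles <- c(
      if (length(taller_l) > 0) min(y[max(taller_l):p]),
      if (length(taller_r) > 0) min(y[p:min(taller_r)])
    )
    if (length(saddles) == 0) y[p] else y[p] - max(saddles)
  }, numeric(1))
  top2 <- sort(peaks[order(prominence, decreasing = TRUE)][1:2])
  valley <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1L
  s_split <- d$x[valley]
  group <- dplyr::case_when(
    tb$score > s_split + delta ~ "known-associated",
    tb$score < s_split - delta ~ "novel-candidate",
    TRUE ~ "weak"
  )
  tb$group <- group
  list(classification = tb, s_split = s_split, density = d)
}

#' Assign known-associated genes to their closest known pattern
#'
#' Each gene joins the known pattern whose profile maximizes its SCI (ties
#' broken by the lowest pattern id). The original profiles are retained for
#' scoring; profiles including the assigned genes are reported separately.
#'
#' @param gene_ids Character vector of genes to assign.
#' @param pred_expr Cells x predicted-genes matrix containing them.
#' @param patterns Known `st_patterns`.
#' @param sw A [build_spatial_weights()] object.
#' @return `patterns` with `membership` extended (new rows flagged by
#'   `source = "assigned"`) and an extra `profiles_augmented` matrix.
#' @export
assign_to_known <- function(gene_ids, pred_expr, patterns, sw) {
  pat <- patterns
  if (!"source" %in% names(pat$membership)) {
    pat$membership$source <- "measured"
  }
  if (length(gene_ids) == 0) {
    pat$profiles_augmented <- pat$profiles
    return(pat)
  }
  S <- sci_matrix(pred_expr[, gene_ids, drop = FALSE], sw, pat$profiles)
  best <- max.col(S, ties.method = "first") # first = lowest pattern id on ties
  add <- tibble::tibble(
    gene_id = gene_ids,
    pattern = colnames(pat$profiles)[best],
    source = "assigned"
  )
  pat$membership <- dplyr::bind_rows(pat$membership, add)
  prof_aug <- pat$profiles
  for (p in colnames(pat$profiles)) {
    extra <- add$gene_id[add$pattern == p]
    if (length(extra) == 0) next
    members_new <- pred_expr[, extra, drop = FALSE]
    k_old <- sum(patterns$membership$pattern == p)
    prof_aug[, p] <- (pat$profiles[, p] * k_old + rowSums(members_new)) /
      (k_old + length(extra))
  }
  pat$profiles_augmented <- prof_aug
  pat
}

#' Discover novel spatial patterns among candidate genes
#'
#' The meticulous three-step refinement of the novel-candidate genes:
#' (1) drop the lowest decile of genes by mean expression, then the lowest
#' decile by standardized dispersion; (2) build the SCI network and cluster
#' with Louvain at a low resolution (0.6) to avoid many small clusters;
#' (3) keep only clusters whose mean within-cluster SCI exceeds the mean of
#' all pairwise SCI scores by three standard deviations, and within kept
#' clusters iteratively remove genes with fewer than `min_connections`
#' retained-network edges to other members until stable.
#'
#' @param cand_expr Cells x candidate-genes matrix.
#' @param sw A [build_spatial_weights()] object.
#' @param resolution Louvain resolution.
#' @param percentile Network threshold percentile.
#' @param min_connections Minimum within-cluster degree kept by pruning.
#' @param sd_rule Number of standard deviations above the mean pairwise SCI
#'   a cluster's mean within-cluster SCI must reach.
#' @param seed Integer seed.
#' @return An `st_patterns` object of kind `"novel"` (possibly empty).
#' @export
discover_novel_patterns <- function(cand_expr, sw, resolution = 0.6,
                                    percentile = 10, min_connections = 10,
                                    sd_rule = 3, seed = 0L) {
  empty <- structure(list(
    membership = tibble::tibble(gene_id = character(), pattern = character()),
    profiles = matrix(numeric(), nrow(cand_expr), 0),
    kind = "novel"
  ), class = "st_patterns")
  if (ncol(cand_expr) < 20) {
    warning("fewer than 20 novel-candidate genes; skipping novel-pattern search")
    return(empty)
  }
  # step 1: low-signal filters (lowest decile mean, then lowest decile dispersion)
  mu <- colMeans(cand_expr)
  keep <- colnames(cand_expr)[
    rank(mu, ties.method = "first") > floor(0.10 * length(mu))]
  disp <- gene_dispersion(cand_expr[, keep, drop = FALSE])
  dr <- disp$dispersion[match(keep, disp$gene_id)]
  keep <- keep[rank(dr, ties.method = "first") > floor(0.10 * length(dr))]
  expr <- cand_expr[, keep, drop = FALSE]
  if (ncol(expr) < 3) return(empty)

  # step 2: SCI network + low-resolution Louvain
  S <- sci_matrix(expr, sw)
  net <- gene_network(S, percentile = percentile)
  pat <- cluster_genes(net, expr, resolution = resolution, seed = seed,
                       kind = "novel")

  # step 3a: three-standard-deviation cluster rule on mean within-cluster SCI
  off <- S[upper.tri(S)]
  thr <- mean(off) + sd_rule * stats::sd(off)
  members <- split(pat$membership$gene_id, pat$membership$pattern)
  kept <- list()
  for (p in names(members)) {
    gs <- members[[p]]
    if (length(gs) < 2) next
    sub <- S[gs, gs]
    z <- mean(sub[upper.tri(sub)])
    if (z > thr) kept[[p]] <- gs
  }
  # step 3b: iterative degree pruning inside each kept cluster
  pruned <- list()
  for (p in names(kept)) {
    gs <- kept[[p]]
    repeat {
      if (length(gs) == 0) break
      deg <- rowSums(net[gs, gs, drop = FALSE] > 0)
      drop <- names(deg)[deg < min_connections]
      if (length(drop) == 0) break
      gs <- setdiff(gs, drop)
    }
    if (length(gs) > 0) pruned[[p]] <- gs
  }
  if (length(pruned) == 0) return(empty)
  membership <- stats::setNames(
    rep(seq_along(pruned), lengths(pruned)),
    unlist(pruned)
  )
  make_patterns(membership, expr[, names(membership), drop = FALSE], "novel")
}

#' Representative genes of a pattern
#'
#' The member genes whose SCI against the pattern's own profile is highest.
#'
#' @param patterns An `st_patterns` object.
#' @param pattern Pattern id (column of `patterns$profiles`).
#' @param expr Cells x genes matrix containing the member genes.
#' @param sw A [build_spatial_weights()] object.
#' @param top_n Number of genes to return.
#' @return Character vector of gene ids, best first.
#' @export
representative_genes <- function(patterns, pattern, expr, sw, top_n = 3) {
  gs <- patterns$membership$gene_id[patterns$membership$pattern == pattern]
  if (length(gs) == 0) stop("unknown or empty pattern: ", pattern)
  S <- sci_matrix(expr[, gs, drop = FALSE], sw,
                  patterns$profiles[, pattern, drop = FALSE])
  gs[order(S[, 1], decreasing = TRUE)][seq_len(min(top_n, length(gs)))]
}

#' Full novel-pattern discovery pipeline
#'
#' Chains the spatial-gene filter, likelihood scoring against the known
#' patterns, the dip-test multimodality gate, the three-way classification,
#' assignment of known-associated genes, and the novel-pattern refinement.
#'
#' @param pred_expr Cells x predicted-genes matrix.
#' @param known Known `st_patterns` (from [find_known_patterns()]).
#' @param sw A [build_spatial_weights()] object.
#' @param alpha,min_frac Spatial filter settings.
#' @param dip_alpha Multimodality threshold for the dip test p-value.
#' @param delta Weak-band half width.
#' @param resolution Louvain resolution for the novel clustering.
#' @param n_boot Dip-test null replicates.
#' @param seed Integer seed.
#' @return List with `scores`, `dip`, `classification` (NULL when unimodal),
#'   `augmented_known`, `novel` (`st_patterns`, possibly empty),
#'   `spatial_genes`.
#' @export
discover_patterns <- function(pred_expr, known, sw, alpha = 0.05,
                              min_frac = 0.05, dip_alpha = 0.05,
                              delta = 0.05, resolution = 0.6, n_boot = 500,
                              seed = 0L) {
  genes <- filter_spatial_genes(pred_expr, sw, alpha = alpha,
                                min_frac = min_frac)
  empty_novel <- structure(list(
    membership = tibble::tibble(gene_id = character(), pattern = character()),
    profiles = matrix(numeric(), nrow(pred_expr), 0),
    kind = "novel"
  ), class = "st_patterns")
  if (length(genes) < 10) {
    warning("fewer than 10 spatially variable predicted genes; ",
            "no novel-pattern search")
    return(list(scores = NULL, dip = NULL, classification = NULL,
                augmented_known = known, novel = empty_novel,
                spatial_genes = genes))
  }
  pe <- pred_expr[, genes, drop = FALSE]
  sc <- likelihood_scores(pe, known, sw)
  dp <- detect_multimodality(sc$score, n_boot = n_boot, seed = seed)
  if (dp$p_value >= dip_alpha) {
    return(list(scores = sc, dip = dp, classification = NULL,
                augmented_known = known, novel = empty_novel,
                spatial_genes = genes))
  }
  cls <- tryCatch(classify_by_likelihood(sc, delta = delta),
                  error = function(e) NULL)
  if (is.null(cls)) {
    return(list(scores = sc, dip = dp, classification = NULL,
                augmented_known = known, novel = empty_novel,
                spatial_genes = genes))
  }
  known_assoc <- cls$classification$gene_id[
    cls$classification$group == "known-associated"]
  aug <- assign_to_known(known_assoc, pe, known, sw)
  cand <- cls$classification$gene_id[
    cls$classification$group == "novel-candidate"]
  novel <- if (length(cand) >= 20) {
    discover_novel_patterns(pe[, cand, drop = FALSE], sw,
                            resolution = resolution, seed = seed)
  } else {
    if (length(cand) > 0) {
      warning("fewer than 20 novel-candidate genes; none reported")
    }
    empty_novel
  }
  list(scores = sc, dip = dp, classification = cls, augmented_known = aug,
       novel = novel, spatial_genes = genes)
}
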