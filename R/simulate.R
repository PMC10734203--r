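#' Specification for a synthetic spatial dataset
#'
#' Describes the simulated tissue: cells on a jittered 2-D grid; known
#' spatial programs (layered bands across the tissue and/or scattered
#' hotspots) carried by part of the measured panel; novel programs placed
#' only among the unmeasured genes; remaining genes spatially unstructured.
#' References resample cells from the same expression manifold and are
#' corrupted per reference by multiplicative batch factors, additive noise
#' scaled by `ref_quality`, and Bernoulli dropout — emulating several
#' scRNA-seq references of heterogeneous quality.
#'
#' Default magnitudes are chosen to look like log-normalized single-cell
#' data: profiles peak near 2-3 log units, additive noise of 0.3, 20%
#' dropout, and reference corruption multipliers spanning a 4-fold range.
#'
#' @param n_cells Number of query cells.
#' @param n_genes_measured,n_genes_unmeasured Panel sizes.
#' @param n_patterns_known,n_patterns_novel Number of spatial programs.
#' @param layout `"layered"`, `"scattered"` or `"mixed"` for known programs
#'   (novel programs are scattered unless layout is `"layered"`).
#' @param noise_sd Additive Gaussian noise (log scale) in the query.
#' @param dropout_rate Bernoulli dropout probability in references.
#' @param n_refs Number of references.
#' @param ref_quality Per-reference corruption multipliers (noise and
#'   dropout); defaults to a graded `0.5 * 2^(0:(n_refs-1))`.
#' @param ref_n_cells Cells per reference.
#' @param batch_scale_sd Log-sd of per-gene multiplicative batch factors.
#' @param measured_pattern_frac Fraction of measured genes carrying known
#'   programs.
#' @param unmeasured_known_frac,unmeasured_novel_frac Fractions of the
#'   unmeasured pool carrying known / novel programs.
#' @param unmeasured_singleton_frac Fraction of the unmeasured pool given
#'   idiosyncratic weak spatial structure: each gene is an independent
#'   short-range smoothed random field (spatially autocorrelated, so it
#'   passes a Moran filter) that belongs to no recurring program and shares
#'   no localized structure with any other gene — the background against
#'   which novel program clusters must stand out.
#' @param seed Integer seed; generators are pure functions of the spec.
#' @return List of settings, class `sim_spec`.
#' @export
sim_spec <- function(n_cells = 1000, n_genes_measured = 80,
                     n_genes_unmeasured = 120, n_patterns_known = 4,
                     n_patterns_novel = 2,
                     layout = c("mixed", "layered", "scattered"),
                     noise_sd = 0.3, dropout_rate = 0.2, n_refs = 3,
                     ref_quality = NULL, ref_n_cells = 1000,
                     batch_scale_sd = 0.1, measured_pattern_frac = 0.6,
                     unmeasured_known_frac = 0.4,
                     unmeasured_novel_frac = 0.2,
                     unmeasured_singleton_frac = 0.25, seed = 0L) {
  layout <- match.arg(layout)
  if (is.null(ref_quality)) ref_quality <- 0.5 * 2^(seq_len(n_refs) - 1)
  stopifnot(
    n_cells > 0, n_genes_measured > 0, n_genes_unmeasured > 0,
    n_patterns_known >= 1, n_patterns_novel >= 0,
    noise_sd >= 0, dropout_rate >= 0, dropout_rate <= 1,
    n_refs >= 1, length(ref_quality) == n_refs, all(ref_quality >= 0),
    ref_n_cells > 0, measured_pattern_frac >= 0, measured_pattern_frac <= 1,
    unmeasured_known_frac + unmeasured_novel_frac +
      unmeasured_singleton_frac <= 1
  )
  structure(as.list(environment()), class = "sim_spec")
}

# smooth band across y, or a handful of gaussian hotspots; max-normalized
make_profile <- function(coords, type, idx, n_of_type) {
  y <- coords[, 2]; x <- coords[, 1]
  if (type == "layered") {
    centers <- seq(min(y), max(y), length.out = n_of_type + 2)[-c(1, n_of_type + 2)]
    width <- diff(range(y)) / (2.5 * n_of_type)
    pr <- exp(-(y - centers[idx])^2 / (2 * width^2))
  } else {
    n_hot <- if (type == "singleton") 1 else 3
    cx <- stats::runif(n_hot, min(x), max(x))
    cy <- stats::runif(n_hot, min(y), max(y))
    r <- diff(range(x)) / 10
    pr <- rep(0, length(x))
    for (h in seq_len(n_hot)) {
      pr <- pr + exp(-((x - cx[h])^2 + (y - cy[h])^2) / (2 * r^2))
    }
  }
  pr / max(pr)
}

#' Generate the spatial ground truth and the query dataset
#'
#' @param spec A [sim_spec()].
#' @return List with `query` (a [spatial_query()], measured genes with noise
#'   applied, log-scale) and `truth`: `true_expr` (noiseless cells x
#'   all-genes matrix), `profiles` (cells x patterns), `gene_table`
#'   (tibble: gene, pattern or NA, measured flag), `measured_genes`,
#'   `unmeasured_genes`.
#' @export
generate_spatial_truth <- function(spec) {
  withr::with_seed(spec$seed, {
    side <- ceiling(sqrt(spec$n_cells))
    grid <- expand.grid(x = seq_len(side), y = seq_len(side))[seq_len(spec$n_cells), ]
    coords <- as.matrix(grid) + matrix(stats::runif(2 * spec$n_cells, -0.3, 0.3),
                                       ncol = 2)
    rownames(coords) <- paste0("cell", seq_len(spec$n_cells))

    n_pat <- spec$n_patterns_known + spec$n_patterns_novel
    # known programs: bands (cortex-like stratification) and/or hotspots;
    # novel programs are always scattered so they stay distinct from the
    # measured stratification
    types <- switch(spec$layout,
      layered = c(rep("layered", spec$n_patterns_known),
                  rep("scattered", spec$n_patterns_novel)),
      scattered = rep("scattered", n_pat),
      mixed = c(
        rep_len(c("layered", "scattered"), spec$n_patterns_known),
        rep("scattered", spec$n_patterns_novel)
      )
    )
    # distinct profiles: re-draw scattered hotspots until correlations < 0.5
    n_layer <- sum(types == "layered")
    profiles <- matrix(0, spec$n_cells, n_pat)
    li <- 0
    for (p in seq_len(n_pat)) {
      if (types[p] == "layered") {
        li <- li + 1
        profiles[, p] <- make_profile(coords, "layered", li, n_layer)
      } else {
        for (try in 1:200) {
          pr <- make_profile(coords, "scattered", 1, 1)
          ok <- p == 1 ||
            all(abs(stats::cor(pr, profiles[, seq_len(p - 1), drop = FALSE])) < 0.15)
          if (ok) break
        }
        profiles[, p] <- pr
      }
    }
    colnames(profiles) <- c(paste0("known", seq_len(spec$n_patterns_known)),
                            if (spec$n_patterns_novel > 0)
                              paste0("novel", seq_len(spec$n_patterns_novel)))

    # gene table: measured panel enriched for known programs; novel programs
    # only among unmeasured genes
    gm <- paste0("m", sprintf("%03d", seq_len(spec$n_genes_measured)))
    gu <- paste0("u", sprintf("%03d", seq_len(spec$n_genes_unmeasured)))
    n_mp <- round(spec$measured_pattern_frac * spec$n_genes_measured)
    pat_m <- c(rep_len(paste0("known", seq_len(spec$n_patterns_known)), n_mp),
               rep(NA_character_, spec$n_genes_measured - n_mp))
    n_uk <- round(spec$unmeasured_known_frac * spec$n_genes_unmeasured)
    n_un <- round(spec$unmeasured_novel_frac * spec$n_genes_unmeasured)
    if (spec$n_patterns_novel == 0) n_un <- 0
    n_us <- round(spec$unmeasured_singleton_frac * spec$n_genes_unmeasured)
    pat_u <- c(rep_len(paste0("known", seq_len(spec$n_patterns_known)), n_uk),
               if (n_un > 0)
                 rep_len(paste0("novel", seq_len(spec$n_patterns_novel)), n_un),
               rep("singleton", n_us),
               rep(NA_character_, spec$n_genes_unmeasured - n_uk - n_un - n_us))
    gene_table <- tibble::tibble(
      gene_id = c(gm, gu),
      pattern = c(pat_m, pat_u),
      measured = rep(c(TRUE, FALSE), c(length(gm), length(gu)))
    )
    gene_table$type <- dplyr::case_when(
      is.na(gene_table$pattern) ~ "noise",
      gene_table$pattern == "singleton" ~ "singleton",
      grepl("^novel", gene_table$pattern) ~ "novel",
      TRUE ~ "known"
    )
    gene_table$pattern[gene_table$pattern == "singleton"] <- NA_character_

    # noiseless expression: amplitude * profile for patterned genes,
    # spatially unstructured positive values otherwise
    all_genes <- gene_table$gene_id
    true_expr <- matrix(0, spec$n_cells, length(all_genes),
                        dimnames = list(rownames(coords), all_genes))
    # per-gene target mean abundance, independent of the spatial shape (as
    # in real panels, where abundance and pattern are unrelated)
    abundance <- stats::runif(length(all_genes), 0.25, 0.6)
    # idiosyncratic background fields: each gene a short-range smoothed
    # random field plus a weak shared long-range component (a diffuse
    # tissue-wide gradient), so the background coheres into its own weak
    # community instead of adhering to the strong program cliques
    n_sing <- sum(gene_table$type == "singleton")
    if (n_sing > 0) {
      d2 <- as.matrix(stats::dist(coords))^2
      rng <- diff(range(coords[, 1]))
      K <- exp(-d2 / (2 * (rng / 20)^2)); K <- K / rowSums(K)
      K0 <- exp(-d2 / (2 * (rng / 5)^2)); K0 <- K0 / rowSums(K0)
      std <- function(v) (v - mean(v)) / stats::sd(v)
      F0 <- as.vector(K0 %*% stats::rnorm(spec$n_cells))
      # keep the diffuse gradient orthogonal to every program profile
      F0 <- std(stats::residuals(stats::lm(F0 ~ profiles)))
      Z <- K %*% matrix(stats::rnorm(spec$n_cells * n_sing), ncol = n_sing)
      Z <- 0.5 * F0 + 0.866 * apply(Z, 2, std)
      Z <- apply(Z, 2, function(v) (v - min(v)) / (max(v) - min(v)))
    }
    si <- 0
    for (j in seq_along(all_genes)) {
      p <- gene_table$pattern[j]
      shape <- if (gene_table$type[j] == "singleton") {
        si <- si + 1
        Z[, si]
      } else if (is.na(p)) {
        abs(stats::rnorm(spec$n_cells, 0.8, 0.4))
      } else {
        profiles[, p]
      }
      true_expr[, j] <- abundance[j] * shape / mean(shape)
    }

    noisy <- true_expr[, gm, drop = FALSE] +
      matrix(stats::rnorm(spec$n_cells * length(gm), 0, spec$noise_sd),
             ncol = length(gm))
    noisy <- pmax(noisy, 0)
    expr <- expression_matrix(noisy, normalized = TRUE)

    list(
      query = spatial_query(expr, coords),
      truth = list(
        true_expr = true_expr,
        profiles = profiles,
        gene_table = gene_table,
        measured_genes = gm,
        unmeasured_genes = gu,
        ref_quality_rank = order(spec$ref_quality)
      )
    )
  })
}

#' Generate reference datasets from the ground truth
#'
#' Each reference resamples cells (with replacement) from the ground-truth
#' expression manifold, then applies per-gene multiplicative batch factors,
#' additive Gaussian noise scaled by its `ref_quality` multiplier, and
#' Bernoulli dropout, all on the log scale.
#'
#' @param truth The `truth` element of [generate_spatial_truth()].
#' @param spec The same [sim_spec()].
#' @param gene_subsets Optional list (length `n_refs`) of gene id vectors
#'   restricting each reference's panel (for partial-coverage scenarios).
#' @return List of `n_refs` expression matrices (log scale, `normalized`
#'   flag set).
#' @export
generate_references <- function(truth, spec, gene_subsets = NULL) {
  lapply(seq_len(spec$n_refs), function(r) {
    withr::with_seed(spec$seed + 1000L + r, {
      idx <- sample.int(nrow(truth$true_expr), spec$ref_n_cells, replace = TRUE)
      genes <- colnames(truth$true_expr)
      if (!is.null(gene_subsets)) genes <- intersect(genes, gene_subsets[[r]])
      ex <- truth$true_expr[idx, genes, drop = FALSE]
      batch <- exp(stats::rnorm(length(genes), 0, spec$batch_scale_sd))
      ex <- sweep(ex, 2, batch, "*")
      q <- spec$ref_quality[r]
      ex <- ex + matrix(stats::rnorm(length(ex), 0, spec$noise_sd * q),
                        nrow = nrow(ex))
      ex <- pmax(ex, 0)
      p_drop <- min(1, spec$dropout_rate * q)
      if (p_drop > 0) {
        ex[matrix(stats::runif(length(ex)) < p_drop, nrow = nrow(ex))] <- 0
      }
      rownames(ex) <- paste0("r", r, "c", seq_len(nrow(ex)))
      expression_matrix(ex, normalized = TRUE)
    })
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: ground truth, query and references in one call.
#'
#' @param spec A [sim_spec()].
#' @param gene_subsets Passed to [generate_references()].
#' @return List with `query`, `refs`, `truth`, `spec`.
#' @export
simulate_dataset <- function(spec = sim_spec(), gene_subsets = NULL) {
  st <- generate_spatial_truth(spec)
  refs <- generate_references(st$truth, spec, gene_subsets = gene_subsets)
  names(refs) <- paste0("ref", seq_along(refs))
  list(query = st$query, refs = refs, truth = st$truth, spec = spec)
}
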