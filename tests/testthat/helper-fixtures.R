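# Fixtures and independent oracles shared across the suite.

# small counts matrix with ids
toy_counts <- function(m = 3, g = 2, seed = 1) {
  withr::with_seed(seed, {
    expression_matrix(matrix(rpois(m * g, 5), m, g,
                             dimnames = list(paste0("c", 1:m), paste0("g", 1:g))))
  })
}

# regular jittered lattice coordinates
lattice_coords <- function(side = 10, jitter = 0, seed = 1) {
  grid <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side)))
  if (jitter > 0) {
    grid <- grid + withr::with_seed(seed, matrix(runif(2 * side^2, -jitter, jitter),
                                                 ncol = 2))
  }
  rownames(grid) <- paste0("cell", seq_len(side^2))
  grid
}

# plain-definition similarity between two vectors: the brute-force oracle
brute_similarity <- function(a, b, measure) {
  g <- length(a)
  switch(measure,
    pearson = stats::cor(a, b),
    spearman = stats::cor(rank(a), rank(b)),
    cosine = sum(a * b) / sqrt(sum(a^2) * sum(b^2)),
    manhattan = 1 / (1 + sum(abs(a - b))),
    euclidean = 1 / (1 + sqrt(sum((a - b)^2))),
    canberra = {
      den <- abs(a) + abs(b)
      terms <- ifelse(den > 0, abs(a - b) / den, 0)
      1 / (1 + sum(terms))
    },
    rho_p = 2 * stats::cov(a, b) / (stats::var(a) + stats::var(b)),
    phi_s = 1 / (1 + stats::var(a - b) / stats::var(a + b)),
    weighted_rank = {
      ra <- rank(a); rb <- rank(b)
      w <- ra + rb
      mx <- sum(w * ra) / sum(w); my <- sum(w * rb) / sum(w)
      sum(w * (ra - mx) * (rb - my)) /
        sqrt(sum(w * (ra - mx)^2) * sum(w * (rb - my)^2))
    },
    jaccard = {
      sa <- which(a > 0); sb <- which(b > 0)
      u <- length(union(sa, sb))
      if (u == 0) 0 else length(intersect(sa, sb)) / u
    }
  )
}

brute_similarity_matrix <- function(A, B, measure) {
  out <- matrix(NA_real_, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      out[i, j] <- brute_similarity(A[i, ], B[j, ], measure)
    }
  }
  out
}

# naive k-NN regression: full sort per query cell, same tie rule
naive_knn_predict <- function(ref_shared, target, query_shared, measure, k) {
  m <- nrow(query_shared)
  out <- matrix(NA_real_, m, ncol(target))
  for (i in seq_len(m)) {
    sims <- vapply(seq_len(nrow(ref_shared)), function(j) {
      brute_similarity(query_shared[i, ], ref_shared[j, ], measure)
    }, numeric(1))
    nb <- order(-sims, seq_along(sims))[seq_len(k)]
    w <- sims[nb]
    if (measure_kind(measure) == "correlation") w <- pmax(w, 0)
    if (sum(w) == 0) w <- rep(1, k)
    out[i, ] <- colSums(target[nb, , drop = FALSE] * w) / sum(w)
  }
  dimnames(out) <- list(rownames(query_shared), colnames(target))
  out
}

# brute-force Moran's I (double loop)
brute_morans_i <- function(x, W0) {
  n <- length(x)
  xc <- unname(x - mean(x))
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W0[i, j] * xc[i] * xc[j]
  (n / sum(W0)) * num / sum(xc^2)
}

# adjusted Rand index between two label vectors
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  s <- sum(choose(tab, 2))
  sr <- sum(choose(rowSums(tab), 2))
  sc <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  ex <- sr * sc / n2
  (s - ex) / ((sr + sc) / 2 - ex)
}

jaccard_sets <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# candidate pool for the novel-pattern refinement: one tight planted
# program plus a diffuse structured background, abundances independent of
# shape (mirrors the synthetic generator's study conditions)
novel_candidate_fixture <- function(side = 25, n_planted = 30, n_bg = 200,
                                    seed = 66) {
  withr::with_seed(seed, {
    co <- as.matrix(expand.grid(x = 1:side, y = 1:side))
    rownames(co) <- paste0("cell", seq_len(side^2))
    n <- nrow(co); rng <- side - 1
    hotspot <- exp(-((co[, 1] - 6)^2 + (co[, 2] - 18)^2) / (2 * (rng / 10)^2))
    ab <- function() runif(1, 0.25, 0.6)
    planted <- sapply(seq_len(n_planted), function(i) {
      s <- pmax(hotspot + rnorm(n, 0, 0.08), 0)
      ab() * s / mean(s)
    })
    colnames(planted) <- paste0("p", seq_len(n_planted))
    d2 <- as.matrix(stats::dist(co))^2
    K <- exp(-d2 / (2 * (rng / 20)^2)); K <- K / rowSums(K)
    K0 <- exp(-d2 / (2 * (rng / 5)^2)); K0 <- K0 / rowSums(K0)
    std <- function(v) (v - mean(v)) / sd(v)
    F0 <- std(stats::resid(stats::lm(as.vector(K0 %*% rnorm(n)) ~ hotspot)))
    B <- K %*% matrix(rnorm(n * n_bg), ncol = n_bg)
    B <- 0.5 * F0 + 0.866 * apply(B, 2, std)
    B <- apply(B, 2, function(v) { v <- v - min(v); ab() * v / mean(v) })
    colnames(B) <- paste0("bg", seq_len(n_bg))
    list(coords = co, planted = planted, bg = B,
         cand = cbind(planted, B))
  })
}

# noiseless world where one reference holds the full truth
exact_world <- function(n_cells = 80, n_shared = 12, n_targets = 6, seed = 1) {
  withr::with_seed(seed, {
    all_g <- c(sprintf("s%02d", 1:n_shared), sprintf("t%02d", 1:n_targets))
    truth <- matrix(runif(n_cells * length(all_g), 0, 3), n_cells,
                    dimnames = list(paste0("c", 1:n_cells), all_g))
    query <- expression_matrix(truth[, 1:n_shared], normalized = TRUE)
    ref <- expression_matrix(truth, normalized = TRUE)
    rownames(ref) <- paste0("r", 1:n_cells)
    list(query = query, ref = ref, truth = truth,
         targets = sprintf("t%02d", 1:n_targets))
  })
}
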