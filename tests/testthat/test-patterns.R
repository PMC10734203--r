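test_that("gene_network thresholds at the percentile, inclusively", {
  withr::with_seed(61, {
    S <- matrix(rnorm(11 * 11), 11); S <- (S + t(S)) / 2; diag(S) <- 1
    # values strictly below the 10th-percentile threshold are zeroed,
    # the rest (inclusive) are retained
    net <- gene_network(S, percentile = 10)
    off <- S[upper.tri(S) | lower.tri(S)]
    thr <- quantile(off, 0.10, names = FALSE)
    expect_equal(sum(net[upper.tri(net)] == 0), sum(S[upper.tri(S)] < thr))
    expect_true(all(net[net != 0] >= thr))
    expect_true(all(diag(net) == 0))
    expect_equal(net, t(net))
    # degenerate all-equal matrix keeps every edge
    E <- matrix(0.4, 5, 5)
    net2 <- gene_network(E, 10)
    expect_true(all(net2[upper.tri(net2)] == 0.4))
  })
})

test_that("cluster_genes separates disconnected cliques deterministically", {
  genes <- paste0("g", 1:6)
  net <- matrix(0, 6, 6, dimnames = list(genes, genes))
  net[1:3, 1:3] <- 0.8; net[4:6, 4:6] <- 0.8; diag(net) <- 0
  expr <- matrix(runif(60), 10, 6, dimnames = list(NULL, genes))
  pat <- cluster_genes(net, expr, resolution = 1, seed = 3)
  expect_equal(length(unique(pat$membership$pattern)), 2)
  expect_equal(length(unique(pat$membership$pattern[1:3])), 1)
  pat2 <- cluster_genes(net, expr, resolution = 1, seed = 3)
  expect_identical(pat$membership, pat2$membership)
  # profile is the member mean
  p1 <- pat$membership$pattern[1]
  expect_equal(pat$profiles[, p1], rowMeans(expr[, 1:3]))
})

test_that("planted spatial programs are recovered with high ARI", {
  withr::with_seed(62, {
    sim <- simulate_dataset(sim_spec(n_cells = 400, n_genes_measured = 48,
                                     n_genes_unmeasured = 10,
                                     n_patterns_known = 4, n_patterns_novel = 0,
                                     layout = "layered",
                                     measured_pattern_frac = 1,
                                     unmeasured_singleton_frac = 0,
                                     unmeasured_novel_frac = 0,
                                     n_refs = 1, ref_n_cells = 50, seed = 10))
    sw <- build_spatial_weights(sim$query$coords)
    known <- find_known_patterns(sim$query$expr, sw, seed = 1)
    gt <- sim$truth$gene_table
    m <- merge(known$membership, gt, by = "gene_id")
    expect_gte(rand_index_adj(m$pattern.x, m$pattern.y), 0.9)
  })
})

test_that("singleton patterns are dropped only when asked", {
  genes <- paste0("g", 1:9)
  membership <- c(rep(1, 5), rep(2, 3), 3)
  names(membership) <- genes
  expr <- matrix(runif(90), 10, 9, dimnames = list(NULL, genes))
  pat <- stens:::make_patterns(membership, expr, "known")
  kept <- filter_singleton_patterns(pat)
  expect_equal(sort(unique(kept$membership$pattern)), c("k1", "k2"))
  expect_equal(ncol(kept$profiles), 2)
  allsing <- stens:::make_patterns(stats::setNames(1:3, genes[1:3]),
                                   expr[, 1:3], "known")
  expect_warning(out <- filter_singleton_patterns(allsing), "singleton")
  expect_equal(nrow(out$membership), 0)
})

test_that("likelihood scores are maximal for profile copies and translation-invariant", {
  withr::with_seed(63, {
    co <- lattice_coords(10)
    sw <- build_spatial_weights(co)
    n <- nrow(co)
    prof <- cbind(k1 = co[, 2] / 10, k2 = pmax(1 - abs(co[, 1] - 5) / 3, 0))
    members <- cbind(a1 = prof[, 1] + rnorm(n, 0, 0.05),
                     a2 = prof[, 1] + rnorm(n, 0, 0.05),
                     b1 = prof[, 2] + rnorm(n, 0, 0.05),
                     b2 = prof[, 2] + rnorm(n, 0, 0.05))
    pat <- stens:::make_patterns(stats::setNames(c(1, 1, 2, 2), colnames(members)),
                                 members, "known")
    pe <- cbind(copy1 = pat$profiles[, 1], shifted = pat$profiles[, 1] + 2,
                shuf = sample(prof[, 1]))
    sc <- likelihood_scores(pe, pat, sw)
    expect_equal(sc$best_pattern[1], "k1")
    expect_equal(sc$score[1], sci(pat$profiles[, 1], pat$profiles[, 1], sw))
    expect_equal(sc$score[2], sc$score[1], tolerance = 1e-12)
    expect_lt(sc$score[3], 0.5 * sc$score[1])
  })
})

test_that("likelihood classification splits a clear bimodal mixture", {
  withr::with_seed(64, {
    scores <- c(rnorm(150, 0.2, 0.04), rnorm(150, 0.8, 0.04))
    cls <- classify_by_likelihood(scores)
    expect_gt(cls$s_split, 0.35)
    expect_lt(cls$s_split, 0.65)
    tab <- table(cls$classification$group,
                 rep(c("low", "high"), each = 150))
    expect_gte(tab["novel-candidate", "low"], 145)
    expect_gte(tab["known-associated", "high"], 145)
    # the weak band rule
    s <- cls$s_split
    probe <- classify_by_likelihood(c(scores, s + 0.01))$classification
    expect_equal(probe$group[nrow(probe)], "weak")
    # a crisp unimodal sample has no second mode to split on
    expect_error(classify_by_likelihood(qnorm(ppoints(200), 0.5, 0.05)),
                 "local maxima")
  })
})

test_that("known-associated genes join their closest pattern with stable ties", {
  withr::with_seed(65, {
    co <- lattice_coords(8)
    sw <- build_spatial_weights(co)
    n <- nrow(co)
    members <- cbind(a1 = co[, 2] + rnorm(n, 0, 0.1),
                     a2 = co[, 2] + rnorm(n, 0, 0.1),
                     b1 = co[, 1] + rnorm(n, 0, 0.1),
                     b2 = co[, 1] + rnorm(n, 0, 0.1))
    pat <- stens:::make_patterns(stats::setNames(c(1, 1, 2, 2), colnames(members)),
                                 members, "known")
    pe <- cbind(x1 = pat$profiles[, 2] + rnorm(n, 0, 0.01))
    aug <- assign_to_known("x1", pe, pat, sw)
    expect_equal(aug$membership$pattern[aug$membership$gene_id == "x1"], "k2")
    expect_equal(sum(aug$membership$source == "assigned"), 1)
    # originals retained for scoring; augmented profile reported separately
    expect_equal(aug$profiles, pat$profiles)
    expect_false(isTRUE(all.equal(aug$profiles_augmented[, "k2"],
                                  pat$profiles[, "k2"])))
    # empty input is a no-op
    same <- assign_to_known(character(), pe, pat, sw)
    expect_equal(same$profiles_augmented, pat$profiles)
  })
})

test_that("novel-pattern refinement recovers a planted program and prunes", {
  fx <- novel_candidate_fixture(seed = 66)
  sw <- build_spatial_weights(fx$coords)
  nv <- discover_novel_patterns(fx$cand, sw, seed = 2)
  expect_equal(length(unique(nv$membership$pattern)), 1)
  expect_gte(jaccard_sets(nv$membership$gene_id, colnames(fx$planted)), 0.8)

  # all-background candidates yield nothing
  nv0 <- discover_novel_patterns(fx$bg, sw, seed = 2)
  expect_equal(nrow(nv0$membership), 0)

  # too few candidates short-circuit with a warning
  expect_warning(discover_novel_patterns(fx$cand[, 1:10], sw, seed = 2),
                 "fewer than 20")
})

test_that("surviving novel-pattern genes keep at least ten positive links", {
  fx <- novel_candidate_fixture(seed = 67)
  sw <- build_spatial_weights(fx$coords)
  nv <- discover_novel_patterns(fx$cand, sw, seed = 2)
  gs <- nv$membership$gene_id
  expect_gt(length(gs), 10)
  S <- sci_matrix(fx$cand[, gs, drop = FALSE], sw)
  deg <- rowSums(S > 0) - 1
  expect_true(all(deg >= 10))
})

test_that("representative genes maximize SCI to the pattern profile", {
  withr::with_seed(68, {
    co <- lattice_coords(8)
    sw <- build_spatial_weights(co)
    n <- nrow(co)
    members <- cbind(good = co[, 2], noisy1 = co[, 2] + rnorm(n, 0, 1),
                     noisy2 = co[, 2] + rnorm(n, 0, 1.5))
    pat <- stens:::make_patterns(stats::setNames(rep(1, 3), colnames(members)),
                                 members, "novel")
    # brute-force ranking over members
    S <- sapply(colnames(members), function(g) sci(members[, g], pat$profiles[, 1], sw))
    want <- names(sort(S, decreasing = TRUE))
    expect_equal(representative_genes(pat, "n1", members, sw, top_n = 3), want)
    expect_equal(representative_genes(pat, "n1", members, sw, top_n = 1), want[1])
    expect_error(representative_genes(pat, "zz", members, sw), "empty")
  })
})
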