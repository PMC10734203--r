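test_that("partition_reference yields seeded equal-sized disjoint parts", {
  ref <- expression_matrix(matrix(runif(200 * 3), 200, 3))
  p <- partition_reference(ref, n0 = 80, seed = 5)
  expect_length(p, 3)
  sizes <- vapply(p, nrow, integer(1))
  expect_lte(diff(range(sizes)), 1)
  expect_setequal(unlist(lapply(p, rownames)), rownames(ref))
  # ceiling arithmetic of the spec example
  sizes2 <- vapply(partition_reference(
    expression_matrix(matrix(0, 20000, 1)), 8000, 0), nrow, integer(1))
  expect_equal(sort(sizes2, decreasing = TRUE), c(6667, 6667, 6666))
  # determinism contract
  p2 <- partition_reference(ref, n0 = 80, seed = 5)
  expect_identical(lapply(p, rownames), lapply(p2, rownames))
  p3 <- partition_reference(ref, n0 = 80, seed = 6)
  expect_false(identical(lapply(p, rownames), lapply(p3, rownames)))
  # single part is the identity partition
  expect_identical(rownames(partition_reference(ref, 500, 0)[[1]]), rownames(ref))
})

test_that("knn_neighbors picks the largest similarities, ties by index", {
  expect_equal(knn_neighbors(c(0.9, 0.5, 0.1), 2), c(1L, 2L))
  expect_equal(knn_neighbors(c(0.1, 0.2, 0.3), 3), c(3L, 2L, 1L))
  expect_error(knn_neighbors(c(1, 2), 3), "exceeds")
  # tie straddling the k boundary matches a full-sort oracle
  withr::with_seed(21, {
    for (i in 1:20) {
      s <- sample(c(0.2, 0.5, 0.5, 0.5, 0.9))
      k <- 2
      oracle <- order(-s, seq_along(s))[1:k]
      expect_equal(knn_neighbors(s, k), oracle)
    }
  })
})

test_that("clamp_negatives gates on measure kind", {
  expect_equal(clamp_negatives(c(0.4, -0.2), "pearson"), c(0.4, 0))
  expect_equal(clamp_negatives(c(0.4, 0.2), "euclidean"), c(0.4, 0.2))
  expect_equal(clamp_negatives(c(-1, -0.5), "spearman"), c(0, 0))
})

test_that("knn_predict reproduces hand-worked weighted averages", {
  ref_shared <- rbind(c(5, 1), c(0, 1), c(9, 9))
  target <- cbind(val = c(10, 0, 50))
  # k = 1: prediction equals the nearest neighbour exactly
  q <- rbind(c(5, 1))
  p1 <- knn_predict(ref_shared, target, q, "euclidean", k = 1)
  expect_equal(unname(p1[1, 1]), 10)
  # supplied similarities: weights (0.8, 0.2) on values (10, 0) -> 8
  sim <- rbind(c(0.8, 0.2, 0))
  p2 <- knn_predict(ref_shared, target, q, "euclidean", k = 2, sim = sim)
  expect_equal(unname(p2[1, 1]), 8)
  # equal weights -> arithmetic mean
  sim3 <- rbind(c(0.5, 0.5, 0))
  p3 <- knn_predict(ref_shared, target, q, "euclidean", k = 2, sim = sim3)
  expect_equal(unname(p3[1, 1]), 5)
  # all-negative correlation weights fall back to the unweighted mean
  simn <- rbind(c(-0.2, -0.7, -0.9))
  p4 <- knn_predict(ref_shared, target, q, "pearson", k = 2, sim = simn)
  expect_equal(unname(p4[1, 1]), 5)
})

test_that("self-match recovers the matched cell's unique genes", {
  withr::with_seed(22, {
    w <- exact_world(n_cells = 30, n_shared = 8, n_targets = 4)
    sr <- sub_reference(w$ref, sort(colnames(w$query)))
    p <- knn_predict(sr$shared, sr$unique, w$query[, sort(colnames(w$query))],
                     "pearson", k = 1)
    expect_equal(unname(p), unname(w$truth[, colnames(sr$unique)]),
                 tolerance = 1e-12)
  })
})

test_that("consensus_shared averages the stack and flags gaps", {
  m1 <- matrix(1, 2, 2); m3 <- matrix(3, 2, 2)
  stack <- list(list(pearson = list("5" = m1, "10" = m3)))
  expect_equal(consensus_shared(stack, 1), matrix(2, 2, 2))
  single <- list(list(pearson = list("5" = m1)))
  expect_equal(consensus_shared(single, 1), m1)
  broken <- list(list(pearson = list("5" = m1, "10" = NULL)))
  expect_error(consensus_shared(broken, 1), "incomplete")
})

test_that("predictive_power is a flattened squared correlation", {
  withr::with_seed(23, {
    obs <- matrix(rnorm(40), 8, 5)
    expect_equal(predictive_power(obs, obs), 1)
    expect_equal(predictive_power(-obs + 2, obs), 1) # sign removed by squaring
    noise <- matrix(rnorm(100 * 100), 100, 100)
    obs2 <- matrix(rnorm(100 * 100), 100, 100)
    expect_lt(predictive_power(noise, obs2), 0.05)
    expect_warning(s0 <- predictive_power(matrix(1, 2, 2), matrix(1:4, 2, 2)),
                   "zero variance")
    expect_equal(s0, 0)
  })
})

test_that("map_weights is the min-max map with a degenerate midpoint rule", {
  expect_equal(map_weights(c(0.2, 0.8)), c(0.1, 0.9))
  expect_equal(map_weights(c(0.1, 0.5, 0.9)), c(0.1, 0.5, 0.9))
  expect_equal(map_weights(c(0.4, 0.4)), c(0.5, 0.5))
  expect_equal(map_weights(0.7), 0.5)
  # fixed alternative maps [0,1] affinely
  expect_equal(map_weights(c(0, 1), method = "fixed"), c(0.1, 0.9))
  expect_equal(map_weights(0.5, method = "fixed"), 0.5)
})

test_that("ensemble_combine implements the weighted average identity cases", {
  b0 <- matrix(0, 2, 2); b1 <- matrix(1, 2, 2)
  stack <- list(list(m = list("1" = b1)), list(m = list("1" = b0)))
  expect_equal(ensemble_combine(stack, c(0.9, 0.1)), matrix(0.9, 2, 2))
  # equal weights reduce to the grand mean
  expect_equal(ensemble_combine(stack, c(0.5, 0.5)), matrix(0.5, 2, 2))
  expect_equal(ensemble_combine(stack[1], 0.3), b1)
  bad <- list(list(m = list("1" = b1)), list(m = list("1" = matrix(0, 3, 3))))
  expect_error(ensemble_combine(bad, c(1, 1)), "mismatch")
})

test_that("full pipeline is invariant to reference order and deterministic", {
  withr::with_seed(24, {
    sim <- simulate_dataset(sim_spec(n_cells = 150, n_genes_measured = 20,
                                     n_genes_unmeasured = 15, n_refs = 2,
                                     ref_n_cells = 120, seed = 7))
    cfg <- impute_config(n0 = 120, k_values = c(3, 5),
                         measures = c("pearson", "euclidean"), seed = 2)
    f1 <- impute_expression(sim$query$expr, sim$refs, config = cfg,
                            normalize = FALSE)
    f2 <- impute_expression(sim$query$expr, rev(sim$refs), config = cfg,
                            normalize = FALSE)
    expect_equal(f1$prediction, f2$prediction, tolerance = 1e-12)
    f3 <- impute_expression(sim$query$expr, sim$refs, config = cfg,
                            normalize = FALSE)
    expect_identical(f1$prediction, f3$prediction)
    # weights bounded, convexity of predictions
    expect_true(all(f1$weights$omega >= 0.1 & f1$weights$omega <= 0.9))
    lo <- min(vapply(sim$refs, min, numeric(1)))
    hi <- max(vapply(sim$refs, max, numeric(1)))
    expect_true(all(f1$prediction >= lo - 1e-9 & f1$prediction <= hi + 1e-9))
  })
})

test_that("targets absent everywhere and shared-overlap are rejected", {
  w <- exact_world()
  expect_error(
    impute_expression(w$query, list(w$ref), targets = "missing_gene",
                      normalize = FALSE),
    "absent from every reference"
  )
  expect_error(
    impute_expression(w$query, list(w$ref), targets = colnames(w$query)[1],
                      config = impute_config(k_values = 1), normalize = FALSE),
    "overlap"
  )
})

test_that("partial gene coverage renormalizes over covering references", {
  withr::with_seed(25, {
    w <- exact_world(n_cells = 60, n_shared = 10, n_targets = 4)
    ref_full <- w$ref
    ref_partial <- w$ref[, setdiff(colnames(w$ref), w$targets[1]), drop = FALSE]
    ref_partial <- expression_matrix(ref_partial, normalized = TRUE)
    rownames(ref_partial) <- paste0("p", seq_len(nrow(ref_partial)))
    cfg <- impute_config(n0 = 100, k_values = 2, measures = "pearson")
    fit <- impute_expression(w$query, list(a = ref_full, b = ref_partial),
                             targets = w$targets, config = cfg,
                             normalize = FALSE)
    expect_equal(sort(colnames(fit$prediction)), sort(w$targets))
    expect_false(anyNA(fit$prediction))
  })
})
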