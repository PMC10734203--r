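test_that("expression_matrix validates identifiers and values", {
  m <- toy_counts()
  expect_equal(dim(m), c(3, 2))
  expect_false(is_normalized <- isTRUE(attr(m, "normalized")) && FALSE)
  expect_error(
    expression_matrix(matrix(1, 2, 2), cell_ids = c("a", "a"),
                      gene_ids = c("g1", "g2")),
    "duplicate cell ids"
  )
  expect_error(
    expression_matrix(matrix(c(1, NA, 1, 1), 2, 2)),
    "finite"
  )
})

test_that("read/write round-trips preserve values across formats", {
  m <- toy_counts(m = 5, g = 4)
  tmp <- withr::local_tempdir()

  csv <- file.path(tmp, "m.csv")
  write_expression(m, csv)
  expect_equal(unclass(read_expression(csv))[, ],
               unclass(m)[, ], tolerance = 1e-12)

  mtx <- file.path(tmp, "m.mtx")
  write_expression(m, mtx)
  r2 <- read_expression(mtx)
  expect_equal(r2[, ], m[, ], ignore_attr = TRUE)
  expect_equal(dimnames(r2), dimnames(m))

  h5 <- file.path(tmp, "m.h5")
  write_expression(m, h5)
  r3 <- read_expression(h5)
  expect_equal(r3[, ], m[, ], ignore_attr = TRUE)
  expect_equal(dimnames(r3), dimnames(m))

  # MTX equals CSV of the same data entry-for-entry
  expect_identical(unname(read_expression(mtx)[, ]), unname(read_expression(csv)[, ]))
})

test_that("reading rejects malformed and inconsistent files", {
  tmp <- withr::local_tempdir()
  bad <- file.path(tmp, "bad.mtx")
  writeLines("not a matrix market file", bad)
  writeLines("g1", file.path(tmp, "genes.tsv"))
  writeLines("c1", file.path(tmp, "barcodes.tsv"))
  expect_error(read_expression(bad))
  expect_error(read_expression(file.path(tmp, "missing.csv")), "exist")
})

test_that("log_normalize matches the direct formula and its invariances", {
  m <- expression_matrix(matrix(c(10, 0), 1, 2,
                                dimnames = list("c1", c("g1", "g2"))))
  n <- log_normalize(m)
  expect_equal(unname(n[1, ]), c(log1p(1e4), 0))
  expect_true(isTRUE(attr(n, "normalized")))

  # all-equal counts in a cell stay all-equal
  eq <- expression_matrix(matrix(c(4, 4, 4), 1, 3))
  expect_true(all(log_normalize(eq)[1, ] == log_normalize(eq * 1)[1, 1]))

  # doubling a cell's counts leaves its normalized vector unchanged
  a <- toy_counts(m = 4, g = 5, seed = 3) + 1
  b <- expression_matrix(unclass(a) * 2)
  expect_equal(log_normalize(a)[, ], log_normalize(b)[, ], tolerance = 1e-12)

  # guard rails
  expect_error(log_normalize(n), "already")
  zero <- expression_matrix(matrix(c(0, 1, 0, 1), 2, 2,
                                   dimnames = list(c("dead", "ok"), c("g1", "g2"))))
  expect_error(log_normalize(zero), "dead")
})

test_that("shared_genes intersects across all references in sorted order", {
  q <- expression_matrix(matrix(1, 2, 3), gene_ids = c("C", "A", "B"))
  r1 <- expression_matrix(matrix(1, 2, 3), gene_ids = c("B", "C", "D"))
  expect_equal(shared_genes(q, list(r1)), c("B", "C"))
  expect_equal(shared_genes(q, list(q)), c("A", "B", "C"))
  r2 <- expression_matrix(matrix(1, 2, 2), gene_ids = c("X", "Y"))
  expect_error(shared_genes(q, list(r2)), "no genes")
})

test_that("gene_sparsity counts zero fractions exactly", {
  vals <- matrix(0, 10, 3, dimnames = list(paste0("c", 1:10), c("a", "b", "c")))
  vals[1:3, 1] <- 1   # 7/10 zeros
  vals[, 2] <- 1      # never zero
  m <- expression_matrix(vals)
  sp <- gene_sparsity(m)
  expect_equal(sp$sparsity, c(0.7, 0, 1))

  # brute-force check on a random sparse fixture
  rnd <- withr::with_seed(9, matrix(rbinom(200, 1, 0.3) * runif(200), 20, 10))
  m2 <- expression_matrix(rnd)
  expect_equal(gene_sparsity(m2)$sparsity,
               unname(apply(rnd, 2, function(v) mean(v == 0))))
})

test_that("HVG union ranks by dispersion and respects exclusions", {
  withr::with_seed(4, {
    base <- matrix(rnorm(300 * 60, 1, 0.2), 300, 60)
    hv_idx <- 1:10
    base[, hv_idx] <- matrix(rnorm(300 * 10, 1, 1.5), 300, 10) # 10x variance
    base <- pmax(base, 0)
    colnames(base) <- sprintf("g%02d", 1:60)
    rownames(base) <- paste0("c", 1:300)
    m <- expression_matrix(base, normalized = TRUE)
    top <- select_hvg(m, n = 10)
    expect_setequal(top, sprintf("g%02d", hv_idx))

    # union over two refs with identical content
    u <- select_hvg_union(list(m, m), n_per_ref = 10)
    expect_setequal(u, top)
    u2 <- select_hvg_union(list(m), n_per_ref = 10, exclude = top[1:3])
    expect_equal(length(u2), 7)
    expect_warning(select_hvg(m, n = 100), "only")
  })
})

test_that("coordinate IO round-trips and aligns by cell id", {
  co <- lattice_coords(3)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_coords(co, tmp)
  back <- read_coords(tmp, cell_ids = rev(rownames(co)))
  expect_equal(back, co[rev(rownames(co)), ])
  expect_error(read_coords(tmp, cell_ids = "nope"), "missing")
})
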