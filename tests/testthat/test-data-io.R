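# h5ad reading/writing and obs-based cell filtering.

test_that("h5ad round-trip preserves counts, identifiers and obs", {
  genome <- simulate_genome(n_chromosomes = 3, genes_per_chromosome = 20)
  ds <- simulate_counts(genome, n_cells = 40, seed = 5)
  path <- withr::local_tempfile(fileext = ".h5ad")
  write_h5ad(ds, path)
  rt <- read_h5ad(path)
  expect_identical(dim(rt), dim(ds))
  expect_identical(gene_ids(rt), gene_ids(ds))
  expect_identical(cell_ids(rt), cell_ids(ds))
  expect_true(all(rt$counts == ds$counts))
  expect_identical(rt$obs$cell_type, ds$obs$cell_type)
  expect_identical(rt$obs$regime, ds$obs$regime)
})

test_that("an integral counts layer is preferred over a processed main matrix", {
  genome <- simulate_genome(n_chromosomes = 2, genes_per_chromosome = 10)
  ds <- simulate_counts(genome, n_cells = 15, seed = 6)
  path <- withr::local_tempfile(fileext = ".h5ad")
  write_h5ad(ds, path)
  # make the main matrix log-normalized and stash raw counts in layers/counts
  raw_x <- rhdf5::h5read(path, "X/data")
  rhdf5::h5createGroup(path, "layers")
  rhdf5::h5createGroup(path, "layers/counts")
  rhdf5::h5write(raw_x, path, "layers/counts/data")
  rhdf5::h5write(rhdf5::h5read(path, "X/indices"), path, "layers/counts/indices")
  rhdf5::h5write(rhdf5::h5read(path, "X/indptr"), path, "layers/counts/indptr")
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, "layers/counts")
  rhdf5::h5writeAttribute("csr_matrix", gid, "encoding-type",
                          variableLengthString = TRUE, asScalar = TRUE)
  rhdf5::h5writeAttribute(dim(ds$counts), gid, "shape")
  rhdf5::H5Gclose(gid); rhdf5::H5Fclose(fid); rhdf5::h5closeAll()
  rhdf5::h5write(log1p(raw_x), path, "X/data")
  rhdf5::h5closeAll()

  rt <- read_h5ad(path)
  expect_true(all(rt$counts == ds$counts)) # layer, not the log values
  expect_true(all(rt$counts@x == round(rt$counts@x)))
  # explicit override goes to the requested source
  rt_x <- expect_error(read_h5ad(path, layer = "X"), "integer-valued")
})

test_that("a file with no integral matrix is rejected, naming what was checked", {
  genome <- simulate_genome(n_chromosomes = 2, genes_per_chromosome = 10)
  ds <- simulate_counts(genome, n_cells = 12, seed = 7)
  path <- withr::local_tempfile(fileext = ".h5ad")
  write_h5ad(ds, path)
  rhdf5::h5write(rhdf5::h5read(path, "X/data") + 0.5, path, "X/data")
  rhdf5::h5closeAll()
  expect_error(read_h5ad(path), "No integer-valued count matrix.*X")
})

test_that("reading a missing file is an I/O error", {
  expect_error(read_h5ad("/nonexistent/file.h5ad"), "not found")
})

test_that("filter_cells selects by exact conjunctive criteria", {
  m <- tiny_counts(100, 8)
  obs <- data.frame(
    cell_type = rep(c("A", "B"), c(60, 40)),
    disease = rep(c("normal", "dcm", "normal", "dcm"), c(30, 30, 20, 20))
  )
  ds <- expr_dataset(m, obs)
  expect_equal(nrow(filter_cells(ds, cell_type = "A")$counts), 60)
  # conjunction on a 2x2 design equals the enumerated intersection
  both <- filter_cells(ds, cell_type = "A", disease = "normal")
  expect_equal(nrow(both$counts),
               sum(obs$cell_type == "A" & obs$disease == "normal"))
  # multiple allowed values
  expect_equal(nrow(filter_cells(ds, disease = c("normal", "dcm"))$counts), 100)
})

test_that("unknown filter keys name the available obs columns", {
  ds <- expr_dataset(tiny_counts(10, 4), data.frame(cell_type = rep("A", 10)))
  expect_error(filter_cells(ds, celltype = "A"), "cell_type")
  expect_error(filter_cells(ds, cell_type = "Z"), "No cells match")
})

test_that("filtering is idempotent and an all-pass filter is the identity", {
  ds <- expr_dataset(tiny_counts(50, 6),
                     data.frame(cell_type = rep(c("A", "B"), 25)))
  once <- filter_cells(ds, cell_type = "A")
  twice <- filter_cells(once, cell_type = "A")
  expect_identical(once, twice)
  allpass <- filter_cells(ds, cell_type = c("A", "B"))
  expect_identical(allpass, ds)
})

test_that("per-gene totals of a filtered dataset match a brute-force row scan", {
  m <- tiny_counts(80, 10, seed = 3)
  obs <- data.frame(grp = rep(c("x", "y", "z"), length.out = 80))
  ds <- expr_dataset(m, obs)
  f <- filter_cells(ds, grp = "y")
  brute <- colSums(m[obs$grp == "y", , drop = FALSE])
  expect_equal(as.numeric(Matrix::colSums(f$counts)), unname(brute))
})

test_that("zero-count cells are dropped with a warning after filtering", {
  m <- tiny_counts(20, 5)
  m[3, ] <- 0
  ds <- expr_dataset(m, data.frame(cell_type = rep("A", 20)))
  expect_warning(f <- filter_cells(ds, cell_type = "A"), "zero total count")
  expect_equal(nrow(f$counts), 19)
  expect_false("c003" %in% cell_ids(f))
})

test_that("non-integral or negative counts are rejected at construction", {
  m <- tiny_counts(5, 3)
  m2 <- m; m2[1, 1] <- 0.5
  expect_error(expr_dataset(m2), "integer")
  m3 <- m; m3[1, 1] <- -1
  expect_error(expr_dataset(m3), "non-negative")
})
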