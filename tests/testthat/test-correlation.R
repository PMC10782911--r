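# Correlation profiles, p-values, Bonferroni adjustment and top-K selection.

# Small dataset + search space over a known annotation, for profile tests.
profile_fixture <- function(n_cells = 60, genes_per_chrom = c("1" = 8, "2" = 6),
                            seed = 21) {
  ann <- make_ann(genes_per_chrom)
  m <- tiny_counts(n_cells, nrow(ann), mu = 3, seed = seed)
  colnames(m) <- ann$gene
  ds <- expr_dataset(m)
  ss <- build_search_space(rank_genes(ds, NULL), ann, n_top = nrow(ann))
  list(ds = ds, ann = ann, ss = ss)
}

test_that("perfectly linear pairs give r = +/-1 with p_adj at the floor", {
  ann <- make_ann(c("1" = 3))
  m <- cbind(gA = c(1, 2, 3, 4), gB = c(2, 4, 6, 8), gC = c(4, 3, 2, 1))
  colnames(m) <- ann$gene[1:3]
  rownames(m) <- paste0("c", 1:4)
  ds <- expr_dataset(m)
  ss <- build_search_space(rank_genes(ds, NULL), ann, n_top = 3)
  prof <- correlate_marker(ds, ann$gene[1], ss)
  expect_equal(prof$r[prof$gene == ann$gene[2]], 1)
  expect_equal(prof$r[prof$gene == ann$gene[3]], -1)
  expect_equal(prof$p_adj[prof$gene == ann$gene[2]], 0)
})

test_that("Pearson p-values follow the t transform (cor.test as oracle)", {
  fx <- profile_fixture()
  prof <- correlate_marker(fx$ds, fx$ss$gene[1], fx$ss)
  for (g in sample(prof$gene, 5)) {
    ct <- cor.test(as.numeric(fx$ds$counts[, fx$ss$gene[1]]),
                   as.numeric(fx$ds$counts[, g]))
    expect_equal(prof$r[prof$gene == g], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(prof$p[prof$gene == g], ct$p.value, tolerance = 1e-12)
  }
})

test_that("Bonferroni adjustment uses the designed family size", {
  fx <- profile_fixture()
  prof <- correlate_marker(fx$ds, fx$ss$gene[3], fx$ss)
  m <- nrow(fx$ss) - 1
  expect_equal(attr(prof, "m"), m)
  expect_equal(prof$p_adj, pmin(1, m * prof$p))
  expect_true(all(prof$p_adj >= prof$p))
  expect_true(all(prof$p_adj[m * prof$p >= 1] == 1))
  # self-entry excluded
  expect_false(fx$ss$gene[3] %in% prof$gene)
  expect_equal(nrow(prof) + attr(prof, "n_dropped"), m)
})

test_that("sparse and dense Pearson paths agree to 1e-10", {
  m <- tiny_counts(80, 30, mu = 1, seed = 22)
  sp <- methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix")
  blk <- brooklynr:::pearson_r_block(sp, 1:5, 1:30)
  dense <- cor(m)[1:5, 1:30]
  expect_equal(unname(blk$r), unname(dense), tolerance = 1e-10)
})

test_that("Pearson r is symmetric between profiles on the same cells", {
  fx <- profile_fixture()
  a <- fx$ss$gene[2]; b <- fx$ss$gene[9]
  pa <- correlate_marker(fx$ds, a, fx$ss)
  pb <- correlate_marker(fx$ds, b, fx$ss)
  expect_equal(pa$r[pa$gene == b], pb$r[pb$gene == a], tolerance = 1e-12)
})

test_that("a zero-variance marker is rejected", {
  fx <- profile_fixture()
  m <- as.matrix(fx$ds$counts)
  m[, 1] <- 2L
  ds <- expr_dataset(m)
  expect_error(correlate_marker(ds, colnames(m)[1], fx$ss), "zero variance")
})

test_that("Kendall tau is 1 for concordant sequences and rank-invariant", {
  x <- c(1, 3, 4, 7, 10)
  y <- c(2, 5, 9, 11, 20)
  expect_equal(brooklynr:::.kendall_tau(x, matrix(y, ncol = 1))[1], 1)
  # any strictly increasing transform leaves tau unchanged
  withr::with_seed(34, {
    a <- rnbinom(50, size = 1, mu = 4)
    b <- rnbinom(50, size = 1, mu = 4)
    t0 <- brooklynr:::.kendall_tau(a, matrix(b, ncol = 1))[1]
    t1 <- brooklynr:::.kendall_tau(a, matrix(exp(b / 3), ncol = 1))[1]
    t2 <- brooklynr:::.kendall_tau(a^2 + 1, matrix(b, ncol = 1))[1]
    expect_equal(t1, t0, tolerance = 1e-12)
    expect_equal(t2, t0, tolerance = 1e-12)
  })
})

test_that("top_k ranks by adjusted p, matching a |r| sort for fixed n", {
  withr::with_seed(35, {
    for (i in 1:10) {
      n_entries <- sample(20:60, 1)
      prof <- structure(
        tibble::tibble(
          gene = sprintf("g%03d", seq_len(n_entries)),
          chrom = "1",
          start = seq_len(n_entries) * 1e5,
          r = runif(n_entries, -1, 1)
        ),
        marker = "mk", marker_chrom = "1", marker_start = 1,
        n_cells = 40, method = "pearson", m = n_entries,
        chromosome_set = "1",
        class = c("correlation_profile", class(tibble::tibble()))
      )
      prof$p <- brooklynr:::cor_p_value(prof$r, 40, "pearson")
      prof$p_adj <- pmin(1, n_entries * prof$p)
      tk <- top_k(prof, k = 10)
      oracle <- prof$gene[order(-abs(prof$r), prof$start)]
      expect_equal(tk$gene, head(oracle, 10))
    }
  })
})

test_that("top_k truncates short profiles with a warning and breaks ties genomically", {
  fx <- profile_fixture(genes_per_chrom = c("1" = 4))
  prof <- correlate_marker(fx$ds, fx$ss$gene[1], fx$ss)
  expect_warning(tk <- top_k(prof, k = 50), "only")
  expect_equal(nrow(tk), nrow(prof))
  # duplicated gene columns have identical r: earlier genomic position wins
  ann <- make_ann(c("1" = 2, "2" = 2))
  m <- tiny_counts(30, 4, mu = 3, seed = 36)
  colnames(m) <- ann$gene
  m[, 3] <- m[, 2] # same vector on chr 2 as on chr 1
  m[, 4] <- m[, 1] + m[, 2] # filler
  ds <- expr_dataset(m)
  ss <- build_search_space(rank_genes(ds, NULL), ann, n_top = 4)
  prof2 <- correlate_marker(ds, ann$gene[1], ss)
  dup <- prof2[prof2$gene %in% c(ann$gene[2], ann$gene[3]), ]
  expect_equal(dup$r[1], dup$r[2], tolerance = 1e-12)
  tk2 <- top_k(prof2, k = 3)
  pos <- match(c(ann$gene[2], ann$gene[3]), tk2$gene)
  expect_true(pos[1] < pos[2]) # chr1 gene before its chr2 duplicate
})

test_that("positive_only restricts ranking to positive correlations", {
  fx <- profile_fixture(seed = 37)
  prof <- correlate_marker(fx$ds, fx$ss$gene[5], fx$ss)
  tk <- suppressWarnings(top_k(prof, k = 50, positive_only = TRUE))
  expect_true(all(tk$r > 0))
})

test_that("best-p exceedance of the Bonferroni cut is calibrated on iid noise", {
  # fraction of profiles with min(p) < alpha/m approximates 1-(1-alpha/m)^m
  alpha <- 0.2
  m_genes <- 50
  n_prof <- 400
  withr::with_seed(38, {
    hits <- vapply(seq_len(n_prof), function(i) {
      x <- rnorm(30)
      Y <- matrix(rnorm(30 * m_genes), 30, m_genes)
      r <- suppressWarnings(as.numeric(cor(x, Y)))
      min(brooklynr:::cor_p_value(r, 30, "pearson")) < alpha / m_genes
    }, logical(1))
    expected <- 1 - (1 - alpha / m_genes)^m_genes
    tol <- 3 * sqrt(expected * (1 - expected) / n_prof)
    expect_lt(abs(mean(hits) - expected), tol)
  })
})
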