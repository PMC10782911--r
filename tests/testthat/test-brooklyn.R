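# The per-marker statistic, genome-wide assembly and locality profiles.

test_that("same-chromosome percentages follow the counting rule", {
  # 10 of 50 partners on the marker's chromosome -> 20%
  tk <- make_topk(rep(c("3", "7"), c(10, 40)), marker_chrom = "3")
  expect_equal(same_chromosome_percent(tk), 20)
  # all partners on the marker's chromosome -> 100%
  expect_equal(same_chromosome_percent(make_topk(rep("1", 50), "1")), 100)
  # k = 25 with 7 matches -> 28%
  expect_equal(same_chromosome_percent(make_topk(rep(c("2", "4"), c(7, 18)), "2")), 28)
})

test_that("percentages can be re-derived from an annotation, which must cover the genes", {
  tk <- make_topk(rep(c("1", "2"), c(3, 2)), marker_chrom = "1")
  ann <- as_annotation(data.frame(
    gene = tk$gene, chromosome = tk$chrom, start = tk$start
  ), chromosome_set = c("1", "2"))
  expect_equal(same_chromosome_percent(tk, ann), 60)
  expect_error(same_chromosome_percent(tk, make_ann(c("1" = 2))), "missing")
})

test_that("assembly computes unweighted means and cumulative coordinates", {
  ann <- make_ann(c("1" = 10, "2" = 10))
  mk <- make_marker_set(ann, ann$gene[c(1, 5, 11, 15)])
  bl <- chromosome_baseline(ann)
  res <- assemble_brooklyn(mk, c(0, 20, 40, 100), bl, ann, k_used = 50)
  expect_equal(res$global_percent, 40)
  expect_equal(res$markers$cum_pos, sort(res$markers$cum_pos))
  # chromosome 2 markers are offset by chromosome 1's span
  span1 <- max(ann$start[ann$chrom == "1"])
  expect_equal(res$markers$cum_pos[3], ann$start[11] + span1)
  expect_equal(res$markers$expected_pct, rep(50, 4))
})

test_that("single-chromosome results collapse per-chromosome means onto the global", {
  ann <- make_ann(c("1" = 10))
  mk <- make_marker_set(ann, ann$gene[c(2, 6)])
  bl <- chromosome_baseline(ann)
  res <- assemble_brooklyn(mk, c(30, 50), bl, ann, k_used = 10)
  expect_equal(nrow(res$per_chromosome), 1)
  expect_equal(res$per_chromosome$mean_percent, res$global_percent)
})

test_that("global percent is invariant to marker processing order", {
  genome <- simulate_genome(n_chromosomes = 3, genes_per_chromosome = 30)
  ds <- simulate_counts(genome, n_cells = 120, fold_change = 4,
                        domain_width_genes = 10, seed = 41)
  ss_genes <- build_search_space(rank_genes(ds, NULL), genome, n_top = 90)$gene
  pick <- ss_genes[c(5, 20, 40, 70)]
  r1 <- brooklyn(ds, genome, n_top = 90, markers = pick, k = 10)
  r2 <- brooklyn(ds, genome, n_top = 90, markers = rev(pick), k = 10)
  expect_equal(r1$global_percent, r2$global_percent)
  expect_equal(r1$markers, r2$markers)
})

test_that("every row percentage is a multiple of 100 / k_used", {
  genome <- simulate_genome(n_chromosomes = 4, genes_per_chromosome = 25)
  ds <- simulate_counts(genome, n_cells = 100, seed = 42)
  res <- brooklyn(ds, genome, n_top = 100, stride = 10, k = 20)
  mult <- res$markers$percent * res$markers$k_used / 100
  expect_equal(mult, round(mult))
  expect_equal(res$global_percent, mean(res$markers$percent))
})

test_that("tidy and glance expose the rows and the summary", {
  genome <- simulate_genome(n_chromosomes = 2, genes_per_chromosome = 20)
  ds <- simulate_counts(genome, n_cells = 60, seed = 43)
  res <- brooklyn(ds, genome, n_top = 40, stride = 5, k = 10)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("gene", "chrom", "start", "cum_pos", "percent",
                     "expected_pct", "k_used"))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$global_percent, res$global_percent)
  expect_equal(gl$method, "pearson")
})

test_that("locality profiles bin same-chromosome partners and smooth correctly", {
  ann <- make_ann(c("1" = 30))
  # point mass: 10 genes in one bin
  tk <- make_topk(rep("1", 10), marker_chrom = "1", marker_start = 5e6)
  tk$start <- rep(3.2e6, 10) + seq(0, 9) * 1e4
  prof <- locality_profile(tk, ann, bin_width_bp = 1e6, window_bins = 1)
  expect_equal(sum(prof$count), 10)
  expect_equal(max(prof$count), 10)
  expect_equal(prof$bin[which.max(prof$count)], 4) # bin covering 3-4 Mb
  # uniform placement smooths to a flat profile
  tk2 <- make_topk(rep("1", 10), marker_chrom = "1")
  tk2$start <- (0:9) * 3e6 + 1.5e6 # one gene per 3 Mb bin
  prof2 <- locality_profile(tk2, ann, bin_width_bp = 3e6, window_bins = 3)
  expect_true(all(abs(prof2$smoothed - 1) < 1e-12))
  # no same-chromosome partners: all-zero profile, not an error
  tk3 <- make_topk(rep("2", 5), marker_chrom = "1")
  prof3 <- locality_profile(tk3, ann, bin_width_bp = 1e6)
  expect_true(all(prof3$count == 0))
  expect_true(all(prof3$smoothed == 0))
})

test_that("the analytic chance level is the mean leave-self-out chromosome share", {
  genome <- simulate_genome(n_chromosomes = 5, genes_per_chromosome = 40)
  ds <- simulate_counts(genome, n_cells = 50, seed = 44)
  ss <- build_search_space(rank_genes(ds, NULL), genome, n_top = 200)
  expect_equal(search_space_chance(ss), 100 * 39 / 199)
  mk <- select_markers(ss, stride = 7)
  expect_equal(search_space_chance(ss, mk), 100 * 39 / 199)
})
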