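# Median-gap statistic, resampling null, clustering test and max-gap
# detection.

test_that("median_gap sorts, differences and takes the median of gaps", {
  ann <- make_annotation(c(0, 100, 300, 10, 20, 1000), chrom_length = 1e6)
  expect_equal(median_gap(c("g001", "g002", "g003"), ann), 150)
  expect_equal(median_gap(c("g001", "g002"), ann), 100)
  # odd gap count: starts {0, 10, 20, 1000} -> gaps {10, 10, 980} -> 10
  ann2 <- make_annotation(c(0, 10, 20, 1000), chrom_length = 1e6)
  expect_equal(median_gap(sprintf("g%03d", 1:4), ann2), 10)
  # permutation invariance and translation invariance
  expect_equal(median_gap(c("g003", "g001", "g002"), ann),
               median_gap(c("g001", "g002", "g003"), ann))
  ann3 <- make_annotation(c(0, 100, 300) + 5000, chrom_length = 1e6)
  expect_equal(median_gap(sprintf("g%03d", 1:3), ann3), 150)
  expect_error(median_gap("g001", ann), "at least 2")
  mixed <- gene_annotation(
    data.frame(gene_id = c("a", "b"), chrom = c("chr1", "chr2"),
               start = c(0, 0), end = c(10, 10)),
    chrom_lengths = c(chr1 = 100, chr2 = 100))
  expect_error(median_gap(c("a", "b"), mixed), "multiple chromosomes")
})

test_that("resample_null draws distinct genes, is seeded, and is unbiased", {
  set.seed(17)
  ann <- make_annotation(sort(sample(1e7, 60)), chrom_length = 1.1e7)
  expect_identical(resample_null(ann, "chrX", 10, 50, seed = 1),
                   resample_null(ann, "chrX", 10, 50, seed = 1))
  # k = all genes: every iterate is the full-set median
  full <- median_gap(ann$gene_id, ann)
  expect_true(all(resample_null(ann, "chrX", 60, 20, seed = 2) == full))
  expect_error(resample_null(ann, "chrX", 61, 10, seed = 1), "exceeds")
  # mean within 3 se of a large independent oracle run
  oracle <- with(list(starts = ann$start), {
    set.seed(99)
    replicate(20000, median(diff(sort(sample(starts, 12)))))
  })
  null <- resample_null(ann, "chrX", 12, 2000, seed = 3)
  se <- sd(null) / sqrt(length(null)) + sd(oracle) / sqrt(length(oracle))
  expect_lt(abs(mean(null) - mean(oracle)), 3 * se)
})

test_that("cluster_test flags a planted tight cluster and bounds p from below", {
  set.seed(41)
  starts <- sort(c(round(runif(490, 0, 100e6)),
                   5e6 + round(seq(0, 50e3, length.out = 10))))
  ann <- make_annotation(starts, chrom_length = 101e6)
  tight <- ann$gene_id[ann$start >= 5e6 & ann$start <= 5e6 + 50e3]
  expect_gte(length(tight), 10)
  ct <- cluster_test(tight, ann, "chrX", n_iter = 1000, seed = 7)
  expect_equal(ct$p_empirical, 1 / 1001)
  expect_lt(ct$p_parametric, 1e-3)
  expect_lt(ct$observed_median_bp, ct$null_mean_bp)
  expect_equal(length(ct$null_medians), 1000)
  expect_gte(ct$p_empirical, 1 / (ct$n_iter + 1))
  expect_error(cluster_test(tight, ann, "chrX", n_iter = 0, seed = 1),
               "n_iter")
})

test_that("max-gap chaining builds the clusters the rule implies", {
  ann <- make_annotation(c(0, 50e3, 2e6), chrom_length = 3e6)
  det <- detect_clusters(ann$gene_id, ann, max_gap_bp = 500e3)
  expect_equal(nrow(det$clusters), 1)
  expect_equal(det$clusters$n_genes, 2)
  expect_equal(det$fraction_clustered, 2 / 3)
  # all gaps above threshold: nothing
  far <- make_annotation(c(0, 1e6, 2e6), chrom_length = 3e6)
  expect_equal(nrow(detect_clusters(far$gene_id, far, 500e3)$clusters), 0)
  # chain construction by hand: {0,100k,200k} and {900k,950k} at 300k
  ann2 <- make_annotation(c(0, 100e3, 200e3, 900e3, 950e3),
                          chrom_length = 2e6)
  det2 <- detect_clusters(ann2$gene_id, ann2, max_gap_bp = 300e3)
  expect_equal(det2$clusters$n_genes, c(3, 2))
  expect_equal(det2$fraction_clustered, 1)
  # spans disjoint and ordered; members within the called set
  expect_true(all(diff(det2$clusters$start) > 0))
  expect_true(all(det2$clusters$end[-nrow(det2$clusters)] <
                    det2$clusters$start[-1]))
  # empty input: no clusters, fraction 0
  det0 <- detect_clusters(character(0), ann)
  expect_equal(nrow(det0$clusters), 0)
  expect_equal(det0$fraction_clustered, 0)
})

test_that("null-drawn gene sets yield calibrated empirical p-values", {
  # the called set is drawn by the null sampler itself, so p_empirical must
  # be uniform on its discrete support
  set.seed(55)
  ann <- make_annotation(sort(sample(5e7, 200)), chrom_length = 5.1e7)
  n_rep <- 200
  n_iter <- 199
  pvals <- vapply(seq_len(n_rep), function(i) {
    called <- sample(ann$gene_id, 15)
    cluster_test(called, ann, "chrX", n_iter = n_iter,
                 seed = 1000 + i)$p_empirical
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(pvals >= 1 / (n_iter + 1)))
})

test_that("planted clusters are recovered from the affected gene set", {
  cfg <- sim_config(seed = 12)
  gen <- generate_genome(cfg)
  aff <- gen$truth$gene_id[gen$truth$affected]
  det <- detect_clusters(aff, gen$annotation, max_gap_bp = 500e3)
  rec <- cluster_recovery(det, gen$truth)
  expect_gte(min(rec$jaccard), 0.9)
  ct <- cluster_test(aff, gen$annotation, cfg$chrom, n_iter = 1000, seed = 5)
  expect_lte(ct$p_empirical, 0.001)
})
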