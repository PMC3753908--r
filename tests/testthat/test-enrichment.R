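# Overlap counting, candidate filtering, matched-region sampling and the
# rank-sum enrichment test.

simple_repeats <- function() {
  repeat_annotation(data.frame(
    family = c("famA", "famA", "famB"),
    chrom = "chrX",
    start = c(50, 200, 90),
    end = c(60, 210, 110)))
}

test_that("count_family applies the any-overlap rule on half-open regions", {
  r <- simple_repeats()
  expect_equal(count_family(r, "chrX", 0, 100, "famA"), 1)
  expect_equal(count_family(r, "chrX", 0, 100, "famC"), 0)
  # element straddling the region boundary counts
  expect_equal(count_family(r, "chrX", 0, 100, "famB"), 1)
  expect_equal(count_family(r, "chrX", 100, 200, "famB"), 1)
  # midpoint mode partitions exactly; overlap mode counts straddlers twice
  part_starts <- c(0, 100)
  part_ends <- c(100, 300)
  ov <- sum(count_family(r, rep("chrX", 2), part_starts, part_ends, "famB"))
  mid <- sum(count_family(r, rep("chrX", 2), part_starts, part_ends, "famB",
                          mode = "midpoint"))
  expect_gte(ov, 1)
  expect_equal(mid, 1)
  set.seed(31)
  st <- sort(sample(1e5, 200))
  big <- repeat_annotation(data.frame(
    family = "f", chrom = "chrX", start = st, end = st + 150))
  cuts <- seq(0, 110e3, by = 10e3)
  ov_tot <- sum(count_family(big, rep("chrX", 11), cuts[-12], cuts[-1], "f"))
  mid_tot <- sum(count_family(big, rep("chrX", 11), cuts[-12], cuts[-1], "f",
                              mode = "midpoint"))
  expect_gte(ov_tot, 200)
  expect_equal(mid_tot, 200)
})

test_that("candidate families must occur in every cluster", {
  clusters <- structure(list(clusters = data.frame(
    cluster = 1:3, chrom = "chrX", start = c(0, 1000, 2000),
    end = c(500, 1500, 2500), n_genes = 2,
    members = c("a,b", "c,d", "e,f"))), class = "gene_clusters")
  reps <- repeat_annotation(data.frame(
    family = c(rep("everywhere", 3), rep("partial", 2)),
    chrom = "chrX",
    start = c(10, 1010, 2010, 20, 1020),
    end = c(20, 1020, 2020, 30, 1030)))
  expect_equal(candidate_families(clusters, reps), "everywhere")
  empty <- structure(list(clusters = data.frame()), class = "gene_clusters")
  expect_error(candidate_families(empty, reps), "cluster")
  none <- repeat_annotation(data.frame(family = character(0),
                                       chrom = character(0),
                                       start = numeric(0), end = numeric(0)))
  expect_equal(length(candidate_families(clusters, none)), 0)
})

test_that("matched regions are size-exact, in range, seeded and uniform", {
  reg <- sample_matched_regions(1e6, c(1000, 5000), n_iter = 50, seed = 4)
  expect_equal(nrow(reg), 100)
  expect_true(all(reg$end - reg$start == rep(c(1000, 5000), 50)))
  expect_true(all(reg$start >= 0))
  expect_true(all(reg$end <= 1e6))
  expect_identical(reg, sample_matched_regions(1e6, c(1000, 5000), 50, seed = 4))
  # forced placement when the region is the whole chromosome
  whole <- sample_matched_regions(1e6, 1e6, n_iter = 5, seed = 1)
  expect_true(all(whole$start == 0))
  expect_error(sample_matched_regions(1e6, 2e6, 10, 1), "exceeds")
  # uniform-mean oracle
  many <- sample_matched_regions(1e6, 1000, n_iter = 10000, seed = 9)
  se <- (1e6 - 1000) / sqrt(12) / sqrt(10000)
  expect_lt(abs(mean(many$start) - (1e6 - 999) / 2), 3 * se)
})

test_that("exact rank-sum p matches full enumeration for n1+n2 <= 10", {
  # spec-style separable case: all 3 observed above all 3 null -> 1/20
  r <- rank_sum_greater(c(5, 6, 7), c(1, 2, 3))
  expect_equal(r$p, 1 / 20)
  expect_equal(r$method, "exact")
  # identical multisets: p near 0.5 by rank symmetry
  same <- rank_sum_greater(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p, 0.4)
  # random small cases, with and without ties, vs the recursive oracle
  set.seed(13)
  for (i in 1:30) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(0:4, n1, replace = TRUE)
    y <- sample(0:4, n2, replace = TRUE)
    expect_equal(rank_sum_greater(x, y)$p, rank_sum_oracle(x, y),
                 info = paste(c(x, "|", y), collapse = " "))
  }
  # tie-free cases also agree with the reference exact distribution
  for (i in 1:10) {
    x <- sample(1000, 4); y <- sample(2000, 5) + 0.5
    expect_equal(rank_sum_greater(x, y)$p,
                 wilcox.test(x, y, alternative = "greater",
                             exact = TRUE)$p.value)
  }
  # large samples switch to the tie-corrected normal approximation
  big <- rank_sum_greater(rpois(30, 5), rpois(40, 5))
  expect_equal(big$method, "normal")
  ref <- wilcox.test(rpois(30, 5), rpois(40, 5), alternative = "greater",
                     exact = FALSE)
  expect_true(big$p > 0 && big$p <= 1)
})

test_that("enrichment screen recovers planted families and reports all candidates", {
  cfg <- sim_config(seed = 14)
  gen <- generate_genome(cfg)
  reps <- generate_repeats(gen$annotation, gen$truth, cfg)
  aff <- gen$truth$gene_id[gen$truth$affected]
  clusters <- detect_clusters(aff, gen$annotation, 500e3)
  screen <- enrichment_screen(clusters, reps, cfg$chrom_length_bp,
                              n_iter = 400, seed = 14, alpha = 1e-3)
  expect_setequal(screen$family[screen$enriched], cfg$enriched_families)
  # every candidate family is reported with a p-value
  cands <- candidate_families(clusters, reps)
  expect_setequal(screen$family, cands)
  expect_true(all(screen$p > 0 & screen$p <= 1))
})

test_that("an unknown family or empty cluster set is refused", {
  cl <- structure(list(clusters = data.frame(
    cluster = 1L, chrom = "chrX", start = 0, end = 1000, n_genes = 2,
    members = "a,b")), class = "gene_clusters")
  expect_error(enrichment_test(cl, simple_repeats(), "nope", 1e6, 10, 1),
               "not present")
})
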