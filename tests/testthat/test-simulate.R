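# Synthetic-data generators: determinism, planted-truth audit, and the
# statistical contracts the downstream tests rely on.

test_that("generators are pure functions of the config seed", {
  cfg <- sim_config(seed = 5, n_genes_x = 120, chrom_length_bp = 40e6,
                    n_clusters = 3)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1, g2)
  e1 <- generate_expression(g1$annotation, g1$truth, cfg)
  e2 <- generate_expression(g2$annotation, g2$truth, cfg)
  expect_identical(e1, e2)
  r1 <- generate_repeats(g1$annotation, g1$truth, cfg)
  expect_identical(r1, generate_repeats(g1$annotation, g1$truth, cfg))
  m1 <- generate_methylation(seed = 5)
  expect_identical(m1, generate_methylation(seed = 5))
  # a different seed moves the draws
  expect_false(identical(g1, generate_genome(sim_config(seed = 6,
    n_genes_x = 120, chrom_length_bp = 40e6, n_clusters = 3))))
})

test_that("planted truth matches what was injected", {
  cfg <- sim_config(seed = 2)
  gen <- generate_genome(cfg)
  truth <- gen$truth
  expect_equal(nrow(gen$annotation), 569)
  expect_equal(sum(truth$affected), 57)        # round(0.10 * 569)
  expect_true(all(truth$fold[truth$affected] >= 1.2))
  expect_true(all(truth$fold[truth$affected] <= 2))
  cl <- attr(truth, "clusters")
  expect_true(all(cl$n_genes >= 2 & cl$n_genes <= 12))
  expect_true(all(cl$end - cl$start <= 1.5e6))
  # planted members really lie inside their recorded span
  for (i in seq_len(nrow(cl))) {
    members <- truth$gene_id[!is.na(truth$cluster) & truth$cluster == i]
    g <- gen$annotation[gen$annotation$gene_id %in% members, ]
    expect_gte(min(g$start), cl$start[i])
    expect_lte(max(g$end), cl$end[i])
  }
  expect_setequal(attr(truth, "enriched_families")$family[
    attr(truth, "enriched_families")$enriched], c("B2_Mm1a", "ID4"))
})

test_that("degenerate genome configs behave as specified", {
  empty <- generate_genome(sim_config(n_genes_x = 0))
  expect_equal(nrow(empty$annotation), 0)
  expect_equal(nrow(empty$truth), 0)
  expect_error(generate_genome(sim_config(n_genes_x = 500,
                                          chrom_length_bp = 2e6,
                                          n_clusters = 9)),
               "infeasible")
  expect_error(sim_config(affected_fraction = 1.3), "affected_fraction")
  expect_error(sim_config(fold_range = c(0.5, 2)), "fold_range")
})

test_that("expression shifts equal log2 fold exactly in the noiseless limit", {
  cfg <- sim_config(seed = 9, n_genes_x = 60, chrom_length_bp = 30e6,
                    n_clusters = 2, noise_sd = 0, multi_map_fraction = 0)
  gen <- generate_genome(cfg)
  expr <- generate_expression(gen$annotation, gen$truth, cfg)
  wt <- expr$samples$sample_id[expr$samples$group == "wt"]
  mut <- expr$samples$sample_id[expr$samples$group == "mutant"]
  diffs <- rowMeans(expr$values[, mut]) - rowMeans(expr$values[, wt])
  gene <- expr$probe_map$gene_id[match(rownames(expr$values),
                                       expr$probe_map$probe_id)]
  tt <- gen$truth[match(gene, gen$truth$gene_id), ]
  expected <- ifelse(tt$affected, log2(tt$fold), 0)
  expect_equal(unname(diffs), expected, tolerance = 1e-12)
})

test_that("multi-mapping probe count is a deterministic rounded fraction", {
  cfg <- sim_config(seed = 4, n_genes_x = 100, chrom_length_bp = 40e6,
                    n_clusters = 2, probes_per_gene_range = c(1L, 1L),
                    multi_map_fraction = 0.4)
  gen <- generate_genome(cfg)
  expr <- generate_expression(gen$annotation, gen$truth, cfg)
  n_targets <- table(expr$probe_map$probe_id)
  expect_equal(sum(n_targets == 2), 40)       # round(0.4 * 100)
  expect_equal(length(n_targets), 100)
})

test_that("null expression config produces group differences of pure noise", {
  cfg <- sim_config(seed = 8, n_genes_x = 200, chrom_length_bp = 60e6,
                    affected_fraction = 0, n_clusters = 0)
  gen <- generate_genome(cfg)
  expect_equal(sum(gen$truth$affected), 0)
  expr <- generate_expression(gen$annotation, gen$truth, cfg)
  wt <- expr$samples$sample_id[expr$samples$group == "wt"]
  mut <- expr$samples$sample_id[expr$samples$group == "mutant"]
  diffs <- rowMeans(expr$values[, mut]) - rowMeans(expr$values[, wt])
  # mean difference ~ N(0, noise_sd * sqrt(2/3) / sqrt(n_probes))
  se <- cfg$noise_sd * sqrt(2 / 3) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 4 * se)
})

test_that("repeat generator plants enrichment only where configured", {
  cfg <- sim_config(seed = 3, n_genes_x = 120, chrom_length_bp = 50e6,
                    n_clusters = 3)
  gen <- generate_genome(cfg)
  cl <- attr(gen$truth, "clusters")

  # background_density = 0: enriched elements appear only inside clusters
  cfg0 <- cfg; cfg0$background_repeat_density <- 0
  reps0 <- generate_repeats(gen$annotation, gen$truth, cfg0)
  expect_true(all(reps0$family %in% cfg$enriched_families))
  inside <- rep(FALSE, nrow(reps0))
  for (i in seq_len(nrow(cl))) {
    inside <- inside | (reps0$start >= cl$start[i] & reps0$end <= cl$end[i])
  }
  expect_true(all(inside))
  # every planted cluster holds every enriched family at least once
  for (f in cfg$enriched_families) {
    counts <- count_family(reps0, cl$chrom, cl$start, cl$end, f)
    expect_true(all(counts >= 1))
  }

  # factor = 1: enriched and background families have equal expected counts
  cfg1 <- cfg; cfg1$enrichment_factor <- 1
  reps1 <- generate_repeats(gen$annotation, gen$truth, cfg1)
  tab <- table(reps1$family)
  expected <- cfg$background_repeat_density * cfg$chrom_length_bp / 1e6
  expect_true(all(abs(tab - expected) < 5 * sqrt(expected)))
})

test_that("methylation generator honours the panel and produces valid clones", {
  # deterministic extreme: wt mean 100, sd 0
  panel <- data.frame(amplicon_id = "a", n_units = 4L, wt_mean = 100,
                      mut_mean = 0, sd = 0)
  m <- generate_methylation(panel, default_methylation_groups(2), seed = 1)
  expect_true(all(m$table$pct[m$table$group == "wt"] == 100))
  expect_true(all(m$table$pct[m$table$group == "mutant"] == 0))
  expect_error(generate_methylation(
    data.frame(amplicon_id = "a", n_units = 2L, wt_mean = 120, mut_mean = 0,
               sd = 1)), "\\[0, 100\\]")

  # clones at p = 0 read all-T at CpGs after conversion
  ref <- random_amplicon(5, 60, seed = 2)
  cl0 <- generate_clones(ref, 10, 0, seed = 3)
  calls <- call_clones(ref, cl0)
  expect_true(all(vapply(calls, function(x) all(x$calls == "U"), logical(1))))

  # binomial sampling bound at p = 0.5, one CpG, 1000 clones
  ref1 <- random_amplicon(1, 30, seed = 4)
  cl5 <- generate_clones(ref1, 1000, 0.5, seed = 5)
  frac <- mean(substr(cl5, find_cpg(ref1), find_cpg(ref1)) == "C")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("write_simulation emits a readable, consistent text dataset", {
  dir <- file.path(tempdir(), "simout")
  cfg <- sim_config(seed = 6, n_genes_x = 80, chrom_length_bp = 40e6,
                    n_clusters = 2)
  paths <- write_simulation(cfg, dir)
  obj <- attr(paths, "objects")
  ann <- read_gene_annotation(paths$genes, "bed", paths$chrom_sizes)
  expect_equal(as.data.frame(ann), as.data.frame(obj$annotation))
  reps <- read_repeat_annotation(paths$repeats, "rmsk")
  expect_equal(nrow(reps), nrow(obj$repeats))
  vals <- read_expression(paths$expression)
  expect_equal(vals, obj$expression$values)
  fa <- read_clone_fasta(paths$clones)
  expect_equal(fa$reference, obj$methylation$clones$reference)
  expect_true(file.exists(paths$truth))
})
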