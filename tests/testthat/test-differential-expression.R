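# Moderated t-statistics, BH adjustment, probe classification and gene
# aggregation.

two_group_matrix <- function(wt, mut, probe = "p1") {
  m <- matrix(c(wt, mut), nrow = 1,
              dimnames = list(probe, c(sprintf("w%d", seq_along(wt)),
                                       sprintf("m%d", seq_along(mut)))))
  samples <- data.frame(sample_id = colnames(m),
                        group = rep(c("wt", "mutant"),
                                    c(length(wt), length(mut))))
  list(values = m, samples = samples)
}

test_that("unshrunk moderated_t equals the textbook pooled t", {
  d <- two_group_matrix(c(1, 2, 3), c(2, 3, 4))
  st <- moderated_t(d$values, d$samples, shrinkage = FALSE)
  expect_equal(st$log2fc, 1)
  expect_equal(st$t, 1.224745, tolerance = 1e-6)
  expect_equal(st$df, 4)
  # identical groups: t = 0, p = 1
  d0 <- two_group_matrix(c(1, 5, 2), c(1, 5, 2))
  st0 <- moderated_t(d0$values, d0$samples, shrinkage = FALSE)
  expect_equal(st0$t, 0)
  expect_equal(st0$p, 1)
  # random matrices against the closed-form oracle, tolerance 1e-12
  set.seed(21)
  m <- matrix(rnorm(50 * 8), nrow = 50,
              dimnames = list(sprintf("p%02d", 1:50),
                              c(paste0("w", 1:4), paste0("m", 1:4))))
  samples <- data.frame(sample_id = colnames(m),
                        group = rep(c("wt", "mutant"), each = 4))
  st <- moderated_t(m, samples, shrinkage = FALSE)
  for (i in c(1, 13, 50)) {
    o <- pooled_t_oracle(m[i, 1:4], m[i, 5:8])
    expect_equal(st$t[i], o$t, tolerance = 1e-12)
    expect_equal(st$p[i], o$p, tolerance = 1e-12)
  }
  # zero-variance, nonzero difference: p = 0 with a warning
  dz <- two_group_matrix(c(1, 1, 1), c(2, 2, 2))
  expect_warning(stz <- moderated_t(dz$values, dz$samples, shrinkage = FALSE),
                 "zero")
  expect_equal(stz$p, 0)
  expect_error(moderated_t(dz$values[, c(1, 4), drop = FALSE],
                           data.frame(sample_id = c("w1", "m1"),
                                      group = c("wt", "mutant"))),
               "at least 2")
})

test_that("the infinite-prior limit pins the posterior variance at the prior", {
  d <- two_group_matrix(c(1, 1, 1), c(2, 2, 2))
  st <- moderated_t(d$values, d$samples, shrinkage = TRUE,
                    prior_df = Inf, prior_var = 1)
  expect_equal(st$t, 1 / sqrt(2 / 3), tolerance = 1e-12)
})

test_that("empirical-Bayes moderation matches an independent implementation", {
  set.seed(33)
  n_probe <- 400
  m <- matrix(rnorm(n_probe * 6, sd = rep(sqrt(rchisq(n_probe, 4) / 4), 6)),
              nrow = n_probe,
              dimnames = list(sprintf("p%03d", 1:n_probe),
                              c(paste0("w", 1:3), paste0("m", 1:3))))
  m[1:40, 4:6] <- m[1:40, 4:6] + 1
  samples <- data.frame(sample_id = colnames(m),
                        group = rep(c("wt", "mutant"), each = 3))
  st <- moderated_t(m, samples, shrinkage = TRUE)

  design <- cbind(1, rep(c(0, 1), each = 3))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(attr(st, "prior_df"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(st, "prior_var"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(st$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(st$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("bh_adjust reproduces the brute-force step-up on all permutations", {
  base_sets <- list(c(0.01, 0.02, 0.03, 0.04),
                    c(0.5, 0.001),
                    c(0.04, 0.01, 0.3, 0.9, 0.005, 0.2))
  for (p in base_sets) {
    for (perm in all_permutations(p)) {
      expect_equal(bh_adjust(perm), bh_oracle(perm))
    }
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.5, 0.001)), c(0.5, 0.002))
  expect_equal(bh_adjust(0.37), 0.37)
  # monotone nondecreasing in sorted order, bounded by 1
  set.seed(2)
  for (i in 1:20) {
    p <- runif(15)
    q <- bh_adjust(p)
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    expect_true(all(q <= 1 & q >= p - 1e-15))
    expect_equal(q, bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("probes are classified by FDR category, strict direction and percent", {
  st <- make_stats(c("a", "b", "c", "d"),
                   actual_change = c(1.25, 0.8, 1.9, 1),
                   fdr = c(0.2, 0.05, 0.31, 0.1))
  cl <- classify_probes(st)
  expect_equal(cl$category, c("relaxed", "stringent", "none", "stringent"))
  expect_equal(cl$direction, c("up", "down", "none", "none"))
  expect_equal(cl$pct_change[1], 25)       # actual change 1.25 = 25% up
  expect_error(classify_probes(st, fdr_stringent = 0.3, fdr_relaxed = 0.1),
               "fdr_relaxed")
})

test_that("gene aggregation matches the exhaustive truth-table oracle", {
  dirs <- c("up", "down", "none")
  for (k in 1:3) {
    combos <- expand.grid(rep(list(dirs), k), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(combos))) {
      dd <- unlist(combos[i, ], use.names = FALSE)
      ac <- ifelse(dd == "up", 1.5, ifelse(dd == "down", 0.7, 1.05))
      fdr <- ifelse(dd == "none", 0.9, 0.2)
      st <- classify_probes(make_stats(sprintf("p%d", seq_len(k)), ac, fdr))
      map <- make_unique_map(sprintf("p%d", seq_len(k)), rep("g1", k))
      call <- aggregate_genes(st, map)
      expect_equal(call$status, gene_call_oracle(dd),
                   info = paste(dd, collapse = "/"))
    }
  }
})

test_that("gene expression values average supporting probes; strays are skipped", {
  st <- classify_probes(make_stats(c("p1", "p2", "p3"),
                                   actual_change = c(1.2, 1.6, 1.4),
                                   fdr = c(0.2, 0.2, 0.2)))
  map <- make_unique_map(c("p1", "p2"), c("gA", "gA"))
  call <- aggregate_genes(st, map)          # p3 not in map -> skipped
  expect_equal(call$status, "upregulated")
  expect_equal(call$expression_value, 1.4)  # mean(1.2, 1.6)
  expect_equal(attr(call, "n_skipped"), 1)
  # conflicted genes are not upregulated
  st2 <- classify_probes(make_stats(c("q1", "q2"), c(1.5, 0.7), c(0.1, 0.1)))
  call2 <- aggregate_genes(st2, make_unique_map(c("q1", "q2"), c("gB", "gB")))
  expect_equal(call2$status, "conflicted")
  # a non-filtered map is refused
  multi <- probe_gene_map(data.frame(probe_id = c("p", "p"),
                                     gene_id = c("g1", "g2")))
  expect_error(aggregate_genes(st, multi), "uniqueness-filtered")
})

test_that("qPCR relative expression normalizes to housekeeping and tests groups", {
  samples <- data.frame(sample_id = c("w1", "w2", "w3", "m1", "m2", "m3"),
                        group = rep(c("wt", "mutant"), each = 3))
  # target Ct == housekeeping Ct everywhere -> relative expression 1
  ct <- cbind(tgt = rep(20, 6), hk1 = rep(20, 6), hk2 = rep(20, 6))
  rownames(ct) <- samples$sample_id
  res <- qpcr_relative_expression(ct, c("hk1", "hk2"), samples)
  expect_true(all(res$relative[, "tgt"] == 1))
  expect_equal(res$comparison$t, 0)
  expect_equal(res$comparison$p, 1)
  # mutant Ct uniformly one cycle lower -> fold change 2
  ct2 <- ct
  ct2[4:6, "tgt"] <- 19
  expect_warning(res2 <- qpcr_relative_expression(ct2, c("hk1", "hk2"),
                                                  samples),
                 "zero pooled variance")   # exact doubling has no variance
  expect_equal(res2$comparison$fold_change, 2)
  expect_error(qpcr_relative_expression(ct, c("hk1", "nope"), samples),
               "housekeeping")
})
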