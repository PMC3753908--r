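# Independent oracles and small fixture builders shared across the suite.
# Each oracle is written from the defining formula, independently of the
# implementation path it checks.

# Step-up FDR adjustment straight from the definition: sort ascending,
# q(i) = min over j >= i of p(j) * m / j, clip at 1, return in input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# All permutations of a vector (small n only).
all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) {
      out[[length(out) + 1]] <- c(x[i], rest)
    }
  }
  out
}

# Classic pooled-variance two-sample t from the textbook formula.
pooled_t_oracle <- function(x_ref, x_test) {
  n1 <- length(x_ref); n2 <- length(x_test)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(x_ref) + (n2 - 1) * var(x_test)) / df
  t <- (mean(x_test) - mean(x_ref)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# One-sided (greater) rank-sum p by exhaustive recursive subset enumeration,
# a code path distinct from the implementation's combn-based split.
rank_sum_oracle <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)])
  count <- 0L
  total <- 0L
  recurse <- function(next_i, chosen, w) {
    if (chosen == n1) {
      total <<- total + 1L
      if (w >= w_obs - 1e-9) count <<- count + 1L
      return(invisible())
    }
    if (length(pooled) - next_i + 1 < n1 - chosen) return(invisible())
    for (i in next_i:length(pooled)) {
      recurse(i + 1, chosen + 1, w + r[i])
    }
  }
  recurse(1, 0L, 0)
  count / total
}

# Gene-call truth table applied literally to one gene's probe directions.
gene_call_oracle <- function(directions) {
  n_up <- sum(directions == "up")
  n_down <- sum(directions == "down")
  if (n_up > 0 && n_down == 0) "upregulated"
  else if (n_down > 0 && n_up == 0) "downregulated"
  else if (n_up > 0 && n_down > 0) "conflicted"
  else "no_change"
}

# Minimal annotation fixture: genes at given starts on one chromosome.
make_annotation <- function(starts, chrom = "chrX", width = 1000,
                            chrom_length = max(starts) + width + 1000) {
  gene_annotation(
    data.frame(gene_id = sprintf("g%03d", seq_along(starts)), chrom = chrom,
               start = starts, end = starts + width, strand = "+"),
    chrom_lengths = stats::setNames(chrom_length, chrom))
}

# Build a probe_stats data frame directly (bypassing moderated_t) so the
# classification and aggregation rules can be driven explicitly.
make_stats <- function(probe_id, actual_change, fdr) {
  out <- data.frame(probe_id = probe_id, log2fc = log2(actual_change),
                    actual_change = actual_change,
                    t = NA_real_, df = NA_real_, p = fdr, fdr = fdr,
                    stringsAsFactors = FALSE)
  class(out) <- c("probe_stats", "data.frame")
  out
}

make_unique_map <- function(probe_id, gene_id) {
  probe_gene_map(data.frame(probe_id = probe_id, gene_id = gene_id))
}
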