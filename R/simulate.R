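# Synthetic-data generators.
#
# The generators emulate the statistical structure the downstream analysis
# assumes: a chromosome on which ~10% of genes shift from monoallelic to
# biallelic expression (1.2-2 fold), most of them packed into planted clusters
# of 2-12 genes spanning 65 kb - 1.5 Mb; repeat families enriched inside those
# clusters; and uniparental-type (~30-50%) methylation panels that lose
# methylation in the mutant.  Every generator is a pure function of its
# configuration, including the seed, and records ground truth for recovery
# tests.

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline is designed around:
#' 569 X-linked genes on a 166 Mb chromosome, 10\% of them affected with
#' non-log fold changes uniform in [1.2, 2] (a monoallelic-to-biallelic shift
#' can at most double output), nine planted clusters of 2-12 genes spanning
#' 65 kb - 1.5 Mb holding ~70\% of affected genes, three samples per genotype
#' group, and two repeat families enriched inside the planted clusters.
#'
#' @param seed integer root seed.
#' @param n_genes_x number of genes on the simulated X-like chromosome.
#' @param chrom_length_bp chromosome length in bp.
#' @param chrom chromosome name.
#' @param n_clusters number of planted clusters.
#' @param cluster_gene_range integer (min, max) genes per planted cluster.
#' @param cluster_span_range numeric (min, max) cluster span in bp.
#' @param clustered_fraction fraction of affected genes assigned to planted
#'   clusters (the rest are scattered away from them).
#' @param affected_fraction fraction of X genes upregulated in the mutant.
#' @param fold_range (low, high) non-log fold change, low >= 1.
#' @param n_samples_per_group samples per genotype group.
#' @param noise_sd i.i.d. Gaussian noise, log2 units.
#' @param probes_per_gene_range integer (min, max) probe sets per gene.
#' @param multi_map_fraction fraction of probe sets mapped to two genes
#'   (these are nonspecific and must be discarded by the mapping filter).
#' @param enriched_families repeat families planted at elevated density inside
#'   clusters.
#' @param background_families repeat families present only at background
#'   density.
#' @param enrichment_factor relative element density inside planted cluster
#'   spans for enriched families (>= 1; 1 means no enrichment).
#' @param background_repeat_density background elements per Mb per family.
#' @param n_genes_auto optional autosomal gene count (0 = X-only run); when
#'   positive, a second chromosome carries a few bidirectional (up and down)
#'   planted changes to exercise the downregulation path.
#' @param auto_chrom_length_bp length of the optional autosome.
#' @return object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes_x = 569L,
                       chrom_length_bp = 166e6,
                       chrom = "chrX",
                       n_clusters = 9L,
                       cluster_gene_range = c(2L, 12L),
                       cluster_span_range = c(65e3, 1.5e6),
                       clustered_fraction = 0.7,
                       affected_fraction = 0.10,
                       fold_range = c(1.2, 2),
                       n_samples_per_group = 3L,
                       noise_sd = 0.25,
                       probes_per_gene_range = c(1L, 3L),
                       multi_map_fraction = 0.10,
                       enriched_families = c("B2_Mm1a", "ID4"),
                       background_families = c("B1_Mus1", "B3A", "B4",
                                               "L1Md_F", "L1Md_T", "MIR",
                                               "RLTR10C", "MTA_Mm"),
                       enrichment_factor = 8,
                       background_repeat_density = 20,
                       n_genes_auto = 0L,
                       auto_chrom_length_bp = 100e6) {
  cfg <- list(seed = as.integer(seed), n_genes_x = as.integer(n_genes_x),
              chrom_length_bp = chrom_length_bp, chrom = chrom,
              n_clusters = as.integer(n_clusters),
              cluster_gene_range = as.integer(cluster_gene_range),
              cluster_span_range = cluster_span_range,
              clustered_fraction = clustered_fraction,
              affected_fraction = affected_fraction,
              fold_range = fold_range,
              n_samples_per_group = as.integer(n_samples_per_group),
              noise_sd = noise_sd,
              probes_per_gene_range = as.integer(probes_per_gene_range),
              multi_map_fraction = multi_map_fraction,
              enriched_families = enriched_families,
              background_families = background_families,
              enrichment_factor = enrichment_factor,
              background_repeat_density = background_repeat_density,
              n_genes_auto = as.integer(n_genes_auto),
              auto_chrom_length_bp = auto_chrom_length_bp)
  if (cfg$affected_fraction < 0 || cfg$affected_fraction > 1) {
    stop("affected_fraction must lie in [0, 1]")
  }
  if (cfg$fold_range[1] < 1) stop("fold_range low bound must be >= 1")
  if (cfg$enrichment_factor < 1) stop("enrichment_factor must be >= 1")
  if (any(c(cfg$n_genes_x, cfg$n_clusters, cfg$n_samples_per_group,
            cfg$n_genes_auto) < 0)) {
    stop("counts must be >= 0")
  }
  if (cfg$multi_map_fraction < 0 || cfg$multi_map_fraction > 1) {
    stop("multi_map_fraction must lie in [0, 1]")
  }
  if (diff(cfg$cluster_gene_range) < 0 || cfg$cluster_gene_range[1] < 2) {
    stop("cluster_gene_range must be (min >= 2, max >= min)")
  }
  structure(cfg, class = "sim_config")
}

# Largest intra-cluster start-to-start gap the generator will plant.  Kept
# below the default chaining gap (500 kb) so that a planted cluster is a
# cluster under the default detection rule: members megabases apart would not
# be a cluster under any chaining threshold.
.max_planted_gap <- 450e3
# Minimum clearance between a planted span and anything labelled unclustered.
.scatter_clearance <- 600e3

#' Generate a synthetic gene annotation with planted clusters
#'
#' Affected genes are assigned to planted clusters first; cluster spans are
#' placed in well-separated blocks along the chromosome, member gene starts
#' are spread over the span with every successive gap below the default
#' detection threshold, remaining affected genes are scattered away from the
#' planted spans, and unaffected genes are placed uniformly (they may fall
#' inside cluster spans: not every gene in a real cluster is derepressed).
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with elements \code{annotation} (a
#'   \code{\link{gene_annotation}}) and \code{truth} (data frame gene_id,
#'   chrom, affected, direction, fold, cluster; attribute \code{clusters} holds
#'   the planted spans and attribute \code{enriched_families} the planted
#'   repeat enrichment flags).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config$seed, "genome"), generate_genome_impl(config))
}

generate_genome_impl <- function(config) {
  lens <- stats::setNames(config$chrom_length_bp, config$chrom)
  if (config$n_genes_auto > 0) {
    lens <- c(lens, stats::setNames(config$auto_chrom_length_bp, "chrA"))
  }
  empty_truth <- data.frame(gene_id = character(0), chrom = character(0),
                            affected = logical(0), direction = character(0),
                            fold = numeric(0), cluster = integer(0))
  if (config$n_genes_x == 0) {
    ann <- gene_annotation(
      data.frame(gene_id = character(0), chrom = character(0),
                 start = numeric(0), end = numeric(0), strand = character(0)),
      chrom_lengths = lens)
    truth <- empty_truth
    attr(truth, "clusters") <- data.frame(
      cluster = integer(0), chrom = character(0), start = numeric(0),
      end = numeric(0), n_genes = integer(0))
    attr(truth, "enriched_families") <- data.frame(
      family = c(config$enriched_families, config$background_families),
      enriched = rep(c(TRUE, FALSE), c(length(config$enriched_families),
                                       length(config$background_families))))
    return(list(annotation = ann, truth = truth))
  }

  n_affected <- round_half_up(config$affected_fraction * config$n_genes_x, 0)
  target_clustered <- round_half_up(config$clustered_fraction * n_affected, 0)

  # Cluster sizes: fill n_clusters with draws from cluster_gene_range until
  # the clustered-gene budget is spent.  Sizes are drawn with probability
  # proportional to 1/size: gene-cluster size distributions are right-skewed
  # (many pairs and triplets, few large runs), and it lets the requested
  # number of clusters fit inside the clustered-gene budget.
  size_range <- seq(config$cluster_gene_range[1], config$cluster_gene_range[2])
  sizes <- integer(0)
  budget <- target_clustered
  for (i in seq_len(config$n_clusters)) {
    if (budget < config$cluster_gene_range[1]) break
    s <- sample(size_range, 1, prob = 1 / size_range)
    s <- min(s, budget)
    if (s < config$cluster_gene_range[1]) break
    sizes <- c(sizes, s)
    budget <- budget - s
  }
  n_clusters <- length(sizes)
  n_clustered <- sum(sizes)
  n_scattered <- n_affected - n_clustered

  # Place each cluster inside its own block so spans are well separated.
  block <- config$chrom_length_bp / max(n_clusters, 1)
  max_span <- min(config$cluster_span_range[2], block / 3)
  if (n_clusters > 0 &&
      (max_span < config$cluster_span_range[1] || block < 3e6)) {
    stop("infeasible packing: chromosome too short for ", n_clusters,
         " clusters of the requested span")
  }

  gene_rows <- list()
  cluster_rows <- list()
  gid <- 0
  next_id <- function() sprintf("gene%04d", gid)
  for (ci in seq_len(n_clusters)) {
    k <- sizes[ci]
    span_cap <- min(max_span, (k - 1) * .max_planted_gap)
    span <- stats::runif(1, min(config$cluster_span_range[1], span_cap), span_cap)
    w <- stats::runif(k - 1, 0.5, 1.5)
    gaps <- span * w / sum(w)
    if (max(gaps) > .max_planted_gap) {           # rescale: keep gaps chainable
      gaps <- gaps * .max_planted_gap / max(gaps)
      span <- sum(gaps)
    }
    lo <- (ci - 1) * block + block / 10
    hi <- ci * block - block / 10 - span
    start0 <- stats::runif(1, lo, hi)
    starts <- round(start0 + c(0, cumsum(gaps)))
    lengths <- round(stats::runif(k, 1e3, 10e3))
    for (j in seq_len(k)) {
      gid <- gid + 1
      gene_rows[[gid]] <- data.frame(
        gene_id = next_id(), chrom = config$chrom, start = starts[j],
        end = starts[j] + lengths[j],
        strand = sample(c("+", "-"), 1),
        affected = TRUE, direction = "up", cluster = ci)
    }
    cluster_rows[[ci]] <- data.frame(
      cluster = ci, chrom = config$chrom, start = starts[1],
      end = starts[k] + lengths[k], n_genes = k)
  }
  clusters <- if (n_clusters > 0) do.call(rbind, cluster_rows) else
    data.frame(cluster = integer(0), chrom = character(0), start = numeric(0),
               end = numeric(0), n_genes = integer(0))

  near_cluster <- function(pos) {
    if (nrow(clusters) == 0) return(rep(FALSE, length(pos)))
    out <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(clusters))) {
      out <- out | (pos > clusters$start[i] - .scatter_clearance &
                    pos < clusters$end[i] + .scatter_clearance)
    }
    out
  }
  draw_positions <- function(n, avoid_clusters) {
    if (n == 0) return(numeric(0))
    pos <- numeric(0)
    tries <- 0
    while (length(pos) < n) {
      cand <- stats::runif(n - length(pos), 0, config$chrom_length_bp - 20e3)
      if (avoid_clusters) cand <- cand[!near_cluster(cand)]
      pos <- c(pos, cand)
      tries <- tries + 1
      if (tries > 1000) stop("infeasible packing: cannot place genes")
    }
    round(pos)
  }

  scat <- draw_positions(n_scattered, avoid_clusters = TRUE)
  for (p in scat) {
    gid <- gid + 1
    gene_rows[[gid]] <- data.frame(
      gene_id = next_id(), chrom = config$chrom, start = p,
      end = p + round(stats::runif(1, 1e3, 10e3)),
      strand = sample(c("+", "-"), 1),
      affected = TRUE, direction = "up", cluster = NA_integer_)
  }
  bg <- draw_positions(config$n_genes_x - n_affected, avoid_clusters = FALSE)
  for (p in bg) {
    gid <- gid + 1
    gene_rows[[gid]] <- data.frame(
      gene_id = next_id(), chrom = config$chrom, start = p,
      end = p + round(stats::runif(1, 1e3, 10e3)),
      strand = sample(c("+", "-"), 1),
      affected = FALSE, direction = "none", cluster = NA_integer_)
  }

  # Optional autosome with a few bidirectional planted changes.
  if (config$n_genes_auto > 0) {
    n_auto_aff <- round_half_up(config$affected_fraction * config$n_genes_auto, 0)
    pos <- round(stats::runif(config$n_genes_auto, 0,
                              config$auto_chrom_length_bp - 20e3))
    dirs <- rep("none", config$n_genes_auto)
    if (n_auto_aff > 0) {
      dirs[seq_len(n_auto_aff)] <- rep(c("up", "down"), length.out = n_auto_aff)
    }
    for (j in seq_len(config$n_genes_auto)) {
      gid <- gid + 1
      gene_rows[[gid]] <- data.frame(
        gene_id = next_id(), chrom = "chrA", start = pos[j],
        end = pos[j] + round(stats::runif(1, 1e3, 10e3)),
        strand = sample(c("+", "-"), 1),
        affected = dirs[j] != "none", direction = dirs[j],
        cluster = NA_integer_)
    }
  }

  df <- do.call(rbind, gene_rows)
  n_aff_total <- sum(df$affected)
  folds <- rep(NA_real_, nrow(df))
  folds[df$affected] <- stats::runif(n_aff_total, config$fold_range[1],
                                     config$fold_range[2])
  truth <- data.frame(gene_id = df$gene_id, chrom = df$chrom,
                      affected = df$affected, direction = df$direction,
                      fold = folds, cluster = df$cluster,
                      stringsAsFactors = FALSE)
  ann <- gene_annotation(df[, c("gene_id", "chrom", "start", "end", "strand")],
                         chrom_lengths = lens)

  # Self-audit: the truth table must match what was injected.
  stopifnot(sum(truth$affected & truth$chrom == config$chrom) == n_affected,
            all(truth$fold[truth$affected] >= config$fold_range[1]),
            all(truth$fold[truth$affected] <= config$fold_range[2]),
            all(truth$gene_id %in% ann$gene_id))
  for (ci in seq_len(nrow(clusters))) {
    members <- truth$gene_id[!is.na(truth$cluster) & truth$cluster == ci]
    g <- ann[ann$gene_id %in% members, ]
    stopifnot(length(members) == clusters$n_genes[ci],
              max(diff(sort(g$start))) <= .max_planted_gap)
  }

  attr(truth, "clusters") <- clusters
  attr(truth, "enriched_families") <- data.frame(
    family = c(config$enriched_families, config$background_families),
    enriched = rep(c(TRUE, FALSE), c(length(config$enriched_families),
                                     length(config$background_families))),
    stringsAsFactors = FALSE)
  list(annotation = ann, truth = truth)
}

#' Generate a synthetic log2 expression matrix and probe map
#'
#' Per gene, a baseline log2 mean is drawn from Normal(6, 2) truncated at 0
#' (dynamic range realism; the statistics only see differences); each of its
#' probe sets adds a fixed affinity offset.  Mutant samples of affected genes
#' are shifted by \code{+log2(fold)} for upregulated and \code{-log2(fold)}
#' for downregulated genes, with i.i.d. Gaussian noise of sd \code{noise_sd}
#' on every measurement.  A fixed fraction of probe sets maps to a second gene
#' (nonspecific), exercising the uniqueness filter.
#'
#' @param annotation,truth output of \code{\link{generate_genome}}.
#' @param config the same \code{\link{sim_config}}.
#' @return list with \code{values} (probe x sample matrix of log2
#'   intensities), \code{samples} (sample sheet: sample_id, group, sex) and
#'   \code{probe_map} (data frame probe_id, gene_id; one row per relation).
#' @export
generate_expression <- function(annotation, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(truth$gene_id %in% annotation$gene_id)) {
    stop("truth table does not match annotation")
  }
  with_seed(stage_seed(config$seed, "expression"),
            generate_expression_impl(annotation, truth, config))
}

generate_expression_impl <- function(annotation, truth, config) {
  n_genes <- nrow(annotation)
  n <- config$n_samples_per_group
  samples <- data.frame(
    sample_id = c(sprintf("wt_%d", seq_len(n)), sprintf("mut_%d", seq_len(n))),
    group = rep(c("wt", "mutant"), each = n),
    sex = "F", stringsAsFactors = FALSE)
  if (n_genes == 0) {
    return(list(values = matrix(numeric(0), nrow = 0, ncol = 2 * n,
                                dimnames = list(NULL, samples$sample_id)),
                samples = samples,
                probe_map = data.frame(probe_id = character(0),
                                       gene_id = character(0))))
  }
  n_probes_per_gene <- sample(seq(config$probes_per_gene_range[1],
                                  config$probes_per_gene_range[2]),
                              n_genes, replace = TRUE)
  probe_gene <- rep(annotation$gene_id, n_probes_per_gene)
  probe_id <- sprintf("ps%05d_at", seq_along(probe_gene))
  n_probes <- length(probe_id)

  # Nonspecific probes: a fixed, deterministic count maps to a second gene.
  n_multi <- round_half_up(config$multi_map_fraction * n_probes, 0)
  map <- data.frame(probe_id = probe_id, gene_id = probe_gene,
                    stringsAsFactors = FALSE)
  if (n_multi > 0 && n_genes > 1) {
    multi_idx <- sample(n_probes, n_multi)
    second <- vapply(probe_gene[multi_idx], function(g) {
      sample(setdiff(annotation$gene_id, g), 1)
    }, character(1))
    map <- rbind(map, data.frame(probe_id = probe_id[multi_idx],
                                 gene_id = second, stringsAsFactors = FALSE))
  }

  baseline <- stats::setNames(rtruncnorm(n_genes, 6, 2, lower = 0),
                              annotation$gene_id)
  affinity <- stats::rnorm(n_probes, 0, 0.5)
  tt <- truth[match(probe_gene, truth$gene_id), ]
  shift <- ifelse(tt$affected & tt$direction == "up", log2(tt$fold),
                  ifelse(tt$affected & tt$direction == "down",
                         -log2(tt$fold), 0))
  shift[is.na(shift)] <- 0
  mu <- baseline[probe_gene] + affinity
  values <- matrix(0, nrow = n_probes, ncol = 2 * n,
                   dimnames = list(probe_id, samples$sample_id))
  for (s in seq_len(2 * n)) {
    grp_shift <- if (samples$group[s] == "mutant") shift else 0
    values[, s] <- mu + grp_shift + stats::rnorm(n_probes, 0, config$noise_sd)
  }
  list(values = values, samples = samples, probe_map = map)
}

#' Generate a synthetic repeat annotation
#'
#' Every family is placed as a homogeneous Poisson process at
#' \code{background_repeat_density} elements/Mb across each chromosome.
#' Enriched families receive additional elements inside planted cluster spans
#' at \code{(enrichment_factor - 1)} times the background density, so the
#' total in-cluster density is \code{enrichment_factor} times background, and
#' when \code{enrichment_factor > 1} every planted cluster is guaranteed at
#' least one element of each enriched family (the candidate-family screen
#' requires presence in every cluster).
#'
#' @param annotation,truth output of \code{\link{generate_genome}}.
#' @param config the same \code{\link{sim_config}}.
#' @return a \code{\link{repeat_annotation}}.
#' @export
generate_repeats <- function(annotation, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config$seed, "repeats"),
            generate_repeats_impl(annotation, truth, config))
}

generate_repeats_impl <- function(annotation, truth, config) {
  lens <- chrom_lengths(annotation)
  clusters <- attr(truth, "clusters")
  fams <- c(config$enriched_families, config$background_families)
  rows <- list()
  elem_len <- function(n) round(stats::runif(n, 100, 300))
  for (fam in fams) {
    for (chrom in names(lens)) {
      n_bg <- stats::rpois(1, config$background_repeat_density *
                              lens[[chrom]] / 1e6)
      if (n_bg > 0) {
        st <- round(stats::runif(n_bg, 0, lens[[chrom]] - 300))
        rows[[length(rows) + 1]] <- data.frame(
          family = fam, chrom = chrom, start = st, end = st + elem_len(n_bg))
      }
    }
    if (fam %in% config$enriched_families && config$enrichment_factor > 1 &&
        nrow(clusters) > 0) {
      for (i in seq_len(nrow(clusters))) {
        span <- clusters$end[i] - clusters$start[i]
        n_extra <- stats::rpois(1, (config$enrichment_factor - 1) *
                                   config$background_repeat_density * span / 1e6)
        n_extra <- max(n_extra, 1L)   # every cluster sees the enriched family
        st <- round(stats::runif(n_extra, clusters$start[i],
                                 clusters$end[i] - 300))
        rows[[length(rows) + 1]] <- data.frame(
          family = fam, chrom = clusters$chrom[i], start = st,
          end = st + elem_len(n_extra))
      }
    }
  }
  if (length(rows) == 0) {
    return(repeat_annotation(data.frame(
      family = character(0), chrom = character(0),
      start = numeric(0), end = numeric(0))))
  }
  repeat_annotation(do.call(rbind, rows))
}

#' Default methylation amplicon panel
#'
#' Four uniparental-type amplicons (wild-type means 30-40\%, consistent with
#' one methylated parental allele) planted to lose 20 percentage points in the
#' mutant, one germ-line control that is unaffected (~50\%), and one
#' unmethylated control.  The per-unit between-embryo sd defaults to 5
#' percentage points.
#'
#' @return data frame with columns amplicon_id, n_units, wt_mean, mut_mean, sd.
#' @export
default_methylation_panel <- function() {
  data.frame(
    amplicon_id = c("dmr_a", "dmr_b", "dmr_c", "dmr_d",
                    "germline_dmr", "unmeth_ctrl"),
    n_units = c(8L, 8L, 6L, 8L, 8L, 6L),
    wt_mean = c(35, 40, 30, 35, 50, 5),
    mut_mean = c(15, 20, 10, 15, 50, 5),
    sd = c(5, 5, 5, 5, 5, 3),
    stringsAsFactors = FALSE)
}

#' Default methylation sample design
#' @param n_per_group embryos per genotype group.
#' @return data frame sample_id, group, sex, tissue.
#' @export
default_methylation_groups <- function(n_per_group = 3L) {
  data.frame(
    sample_id = c(sprintf("wt_%d", seq_len(n_per_group)),
                  sprintf("mut_%d", seq_len(n_per_group))),
    group = rep(c("wt", "mutant"), each = n_per_group),
    sex = rep_len(c("F", "M"), 2 * n_per_group),
    tissue = "embryo", stringsAsFactors = FALSE)
}

#' Generate a synthetic percent-methylation table (and optional clone FASTA)
#'
#' Per sample and CpG unit, percent methylation is drawn from a Gaussian with
#' the group mean of the amplicon and the panel sd, truncated to [0, 100].
#' If \code{clone_amplicon} is given, bisulfite clone sequences are also
#' generated for that amplicon: a random reference amplicon is built, and each
#' clone methylates every CpG independently with the group-mean probability
#' while all non-CpG cytosines convert to T.
#'
#' @param panel amplicon specification, see
#'   \code{\link{default_methylation_panel}}.
#' @param groups sample design, see \code{\link{default_methylation_groups}}.
#' @param seed integer seed.
#' @param clone_amplicon optional amplicon_id for which to emit clones.
#' @param n_clones_per_group clones per genotype group.
#' @return list with \code{table} (long data frame: amplicon_id, sample_id,
#'   group, sex, tissue, unit_index, pct), \code{panel} (echo), and, when
#'   requested, \code{clones} (list with \code{reference} and named character
#'   vector \code{sequences}).
#' @export
generate_methylation <- function(panel = default_methylation_panel(),
                                 groups = default_methylation_groups(),
                                 seed = 1L, clone_amplicon = NULL,
                                 n_clones_per_group = 10L) {
  if (any(panel$wt_mean < 0 | panel$wt_mean > 100 |
          panel$mut_mean < 0 | panel$mut_mean > 100)) {
    stop("amplicon means must lie in [0, 100]")
  }
  with_seed(stage_seed(seed, "methylation"), {
    rows <- list()
    for (a in seq_len(nrow(panel))) {
      for (s in seq_len(nrow(groups))) {
        mu <- if (groups$group[s] == "wt") panel$wt_mean[a] else panel$mut_mean[a]
        pct <- rtruncnorm(panel$n_units[a], mu, panel$sd[a], 0, 100)
        rows[[length(rows) + 1]] <- data.frame(
          amplicon_id = panel$amplicon_id[a], sample_id = groups$sample_id[s],
          group = groups$group[s], sex = groups$sex[s],
          tissue = groups$tissue[s], unit_index = seq_len(panel$n_units[a]),
          pct = pct, stringsAsFactors = FALSE)
      }
    }
    out <- list(table = do.call(rbind, rows), panel = panel)
    if (!is.null(clone_amplicon)) {
      a <- match(clone_amplicon, panel$amplicon_id)
      if (is.na(a)) stop("unknown amplicon: ", clone_amplicon)
      ref <- random_amplicon(n_cpg = max(panel$n_units[a], 4), length = 180)
      seqs <- character(0)
      for (grp in unique(groups$group)) {
        p <- (if (grp == "wt") panel$wt_mean[a] else panel$mut_mean[a]) / 100
        cl <- generate_clones(ref, n_clones_per_group, p)
        names(cl) <- sprintf("%s_%s_clone%02d", clone_amplicon, grp,
                             seq_along(cl))
        seqs <- c(seqs, cl)
      }
      out$clones <- list(reference = ref, sequences = seqs)
    }
    out
  })
}

#' Random reference amplicon sequence with a fixed number of CpGs
#'
#' Builds a CpG-free random backbone and plants \code{n_cpg} CG dinucleotides
#' at evenly spread positions, so the CpG count is exact.
#'
#' @param n_cpg number of CpG sites.
#' @param length total sequence length (>= 6 * n_cpg).
#' @param seed optional seed (NULL = use current RNG state).
#' @return uppercase DNA string.
#' @export
random_amplicon <- function(n_cpg, length = 200, seed = NULL) {
  stopifnot(length >= 6 * n_cpg)
  with_seed(seed, {
    repeat {
      backbone <- sample(c("A", "C", "T"), length, replace = TRUE,
                         prob = c(0.4, 0.25, 0.35))
      seq <- paste(backbone, collapse = "")
      pos <- round(seq(10, length - 10, length.out = n_cpg))
      v <- strsplit(seq, "")[[1]]
      for (p in pos) { v[p] <- "C"; v[p + 1] <- "G" }
      # the backbone has no G, so planted CGs are the only CpGs
      out <- paste(v, collapse = "")
      if (length(find_cpg(out)) == n_cpg) return(out)
    }
  })
}

#' Generate bisulfite-converted clone sequences
#'
#' Each CpG cytosine stays C with probability \code{p} (methylated) and reads
#' T otherwise; all non-CpG cytosines convert to T (complete conversion).
#'
#' @param reference uppercase ACGT amplicon sequence.
#' @param n number of clones.
#' @param p per-CpG methylation probability.
#' @param seed optional seed.
#' @return character vector of clone sequences, same length as the reference.
#' @export
generate_clones <- function(reference, n, p, seed = NULL) {
  stopifnot(p >= 0, p <= 1)
  cpg <- find_cpg(reference)
  v0 <- strsplit(reference, "")[[1]]
  c_pos <- which(v0 == "C")
  non_cpg_c <- setdiff(c_pos, cpg)
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      v <- v0
      v[non_cpg_c] <- "T"
      meth <- stats::runif(length(cpg)) < p
      v[cpg[!meth]] <- "T"
      paste(v, collapse = "")
    }, character(1))
  })
}

#' Write a full synthetic dataset to disk
#'
#' Emits the plain-text inputs the pipeline stages consume: gene BED,
#' chrom.sizes, rmsk-style repeat TSV, expression TSV, sample sheet TSV,
#' probe-map TSV, methylation TSV, clone FASTA, and a YAML ground-truth file
#' echoing the configuration.
#'
#' @param config a \code{\link{sim_config}}.
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly; the generated objects as
#'   attribute \code{"objects"}.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_genome(config)
  expr <- generate_expression(gen$annotation, gen$truth, config)
  reps <- generate_repeats(gen$annotation, gen$truth, config)
  meth <- generate_methylation(seed = config$seed, clone_amplicon = "dmr_a")
  paths <- list(
    genes = file.path(dir, "genes.bed"),
    chrom_sizes = file.path(dir, "chrom.sizes"),
    repeats = file.path(dir, "repeats.tsv"),
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.tsv"),
    probe_map = file.path(dir, "probe_map.tsv"),
    methylation = file.path(dir, "methylation.tsv"),
    clones = file.path(dir, "clones.fa"),
    truth = file.path(dir, "truth.yaml"))
  write_gene_annotation(gen$annotation, paths$genes)
  lens <- chrom_lengths(gen$annotation)
  utils::write.table(
    data.frame(names(lens), format(lens, scientific = FALSE, trim = TRUE)),
    paths$chrom_sizes, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  write_repeat_annotation(reps, paths$repeats)
  utils::write.table(
    data.frame(probe_id = rownames(expr$values), expr$values,
               check.names = FALSE),
    paths$expression, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$samples, paths$samples, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(expr$probe_map, paths$probe_map, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(meth$table, paths$methylation, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  seqs <- Biostrings::DNAStringSet(c(reference = meth$clones$reference,
                                     meth$clones$sequences))
  Biostrings::writeXStringSet(seqs, paths$clones)
  truth_list <- list(
    config = unclass(config),
    genes = gen$truth,
    clusters = attr(gen$truth, "clusters"),
    enriched_families = attr(gen$truth, "enriched_families"))
  yaml::write_yaml(lapply(truth_list, function(x)
    if (is.data.frame(x)) as.list(x) else x), paths$truth)
  out <- paths
  attr(out, "objects") <- list(annotation = gen$annotation, truth = gen$truth,
                               expression = expr, repeats = reps,
                               methylation = meth)
  invisible(out)
}
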