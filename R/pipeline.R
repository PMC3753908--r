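# End-to-end orchestration: synthetic (or user-supplied) inputs -> probe
# filtering -> differential expression -> positional clustering -> repeat
# enrichment -> methylation comparison, under one root seed with per-stage
# substreams and a machine-readable run report.

#' Pipeline configuration
#'
#' @param synthetic a \code{\link{sim_config}} for a fully synthetic run, or
#'   NULL when \code{inputs} provides file paths.
#' @param inputs named list of input paths for a user-data run: \code{genes}
#'   (BED), \code{chrom_sizes}, \code{expression} (TSV), \code{samples}
#'   (TSV), \code{probe_map} (TSV), \code{repeats} (rmsk TSV), optionally
#'   \code{methylation} (TSV).
#' @param fdr_stringent,fdr_relaxed probe FDR categories (defaults 0.10 and
#'   0.30).
#' @param max_gap_bp cluster chaining threshold (default 500 kb).
#' @param alpha significance level for the enrichment flag (default 1e-3) and
#'   cluster-test headline.
#' @param n_iter resampling iterates for both resampling tests (default
#'   1000).
#' @param seed root seed; every stage derives its own substream from it by a
#'   stable label, so adding a stage never perturbs earlier stages' draws.
#' @param outdir output directory.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(synthetic = sim_config(), inputs = NULL,
                            fdr_stringent = 0.10, fdr_relaxed = 0.30,
                            max_gap_bp = 500e3, alpha = 1e-3,
                            n_iter = 1000, seed = 1L, outdir = tempfile("run")) {
  structure(list(synthetic = synthetic, inputs = inputs,
                 fdr_stringent = fdr_stringent, fdr_relaxed = fdr_relaxed,
                 max_gap_bp = max_gap_bp, alpha = alpha,
                 n_iter = as.integer(n_iter), seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys mirror the \code{\link{pipeline_config}}
#'   arguments, with \code{synthetic} holding \code{\link{sim_config}}
#'   arguments.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- if (!is.null(y$synthetic)) do.call(sim_config, y$synthetic)
         else if (is.null(y$inputs)) sim_config() else NULL
  args <- y[setdiff(names(y), "synthetic")]
  args$synthetic <- syn
  do.call(pipeline_config, args)
}

#' Validate a pipeline configuration
#'
#' Structural and range checks; fatal findings abort \code{run_pipeline}
#' before any stage runs, warnings are echoed into the report.
#'
#' @param config a \code{pipeline_config}.
#' @return data frame with columns \code{level} (\code{"fatal"} or
#'   \code{"warning"}) and \code{message}; zero rows when clean.
#' @export
validate_config <- function(config) {
  findings <- list()
  add <- function(level, msg) {
    findings[[length(findings) + 1]] <<- data.frame(
      level = level, message = msg, stringsAsFactors = FALSE)
  }
  thresholds <- c(fdr_stringent = config$fdr_stringent,
                  fdr_relaxed = config$fdr_relaxed, alpha = config$alpha)
  for (nm in names(thresholds)) {
    if (is.null(thresholds[[nm]]) || thresholds[[nm]] <= 0 ||
        thresholds[[nm]] > 1) {
      add("fatal", paste0(nm, " must lie in (0, 1]"))
    }
  }
  if (!is.null(config$fdr_relaxed) && !is.null(config$fdr_stringent) &&
      config$fdr_relaxed < config$fdr_stringent) {
    add("fatal", "fdr_relaxed must be >= fdr_stringent")
  }
  if (config$n_iter < 1) add("fatal", "n_iter must be >= 1")
  if (config$max_gap_bp <= 0) add("fatal", "max_gap_bp must be positive")
  if (is.null(config$synthetic) && is.null(config$inputs)) {
    add("fatal", "either synthetic config or input paths required")
  }
  if (!is.null(config$inputs)) {
    need <- c("genes", "expression", "samples", "probe_map", "repeats")
    for (nm in need) {
      if (is.null(config$inputs[[nm]])) {
        add("fatal", paste0("missing input path: ", nm))
      } else if (!file.exists(config$inputs[[nm]])) {
        add("fatal", paste0("input file not found: ", config$inputs[[nm]]))
      }
    }
    if (is.null(config$inputs$chrom_sizes)) {
      add("fatal",
          "chrom.sizes required: resampling needs true chromosome lengths")
    }
  }
  if (length(findings) == 0) {
    return(data.frame(level = character(0), message = character(0)))
  }
  do.call(rbind, c(findings, list(make.row.names = FALSE)))
}

#' Run the full pipeline
#'
#' Stages run in dependency order; every intermediate table is written under
#' \code{config$outdir} and the per-stage summaries are collected into a run
#' report (written as both JSON and a YAML config echo).  Identical config and
#' seed give byte-identical reports.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param verbose print one line per stage.
#' @return object of class \code{run_report} (invisible); see the files under
#'   \code{config$outdir} for full outputs.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  findings <- validate_config(config)
  if (any(findings$level == "fatal")) {
    stop("invalid pipeline config:\n  ",
         paste(findings$message[findings$level == "fatal"], collapse = "\n  "))
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  report <- list(package_version = as.character(utils::packageVersion("derepress")),
                 seed = config$seed,
                 mode = if (is.null(config$inputs)) "synthetic" else "files",
                 warnings = findings$message[findings$level == "warning"],
                 stages = list())

  # --- stage: inputs --------------------------------------------------------
  if (is.null(config$inputs)) {
    syn <- config$synthetic
    syn$seed <- config$seed   # pipeline root seed governs the generators
    gen <- generate_genome(syn)
    annotation <- gen$annotation; truth <- gen$truth
    expr <- generate_expression(annotation, truth, syn)
    repeats <- generate_repeats(annotation, truth, syn)
    meth_tab <- generate_methylation(seed = config$seed)$table
    write_gene_annotation(annotation, file.path(config$outdir, "genes.bed"))
    write_repeat_annotation(repeats, file.path(config$outdir, "repeats.tsv"))
    utils::write.table(expr$samples, file.path(config$outdir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pmap <- probe_gene_map(expr$probe_map,
                           n_probes_total = length(unique(expr$probe_map$probe_id)),
                           n_genes_universe = nrow(annotation))
    values <- expr$values
    samples <- expr$samples
  } else {
    annotation <- read_gene_annotation(config$inputs$genes, "bed",
                                       config$inputs$chrom_sizes)
    repeats <- read_repeat_annotation(config$inputs$repeats, "rmsk")
    values <- read_expression(config$inputs$expression)
    samples <- read_sample_sheet(config$inputs$samples)
    pmap <- read_probe_map(config$inputs$probe_map,
                           n_genes_universe = nrow(annotation))
    meth_tab <- if (!is.null(config$inputs$methylation)) {
      read_methylation(config$inputs$methylation)
    } else NULL
    truth <- NULL
  }
  report$stages$inputs <- list(
    n_genes = nrow(annotation), n_repeat_elements = nrow(repeats),
    n_probes = nrow(values), n_samples = nrow(samples))
  say("inputs", "%d genes, %d probes, %d samples", nrow(annotation),
      nrow(values), nrow(samples))

  # --- stage: probe mapping -------------------------------------------------
  filt <- filter_unique(pmap)
  report$stages$probe_mapping <- unclass(filt$summary)
  say("probe_mapping", "%d unique of %d probes", filt$summary$n_probes_unique,
      filt$summary$n_probes_total)

  # --- stage: differential expression --------------------------------------
  stats <- moderated_t(values, samples)
  stats <- classify_probes(stats, config$fdr_stringent, config$fdr_relaxed)
  calls <- aggregate_genes(stats, filt$map)
  utils::write.table(stats, file.path(config$outdir, "probe_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(calls, file.path(config$outdir, "gene_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$stages$differential_expression <- list(
    n_probes_tested = nrow(stats),
    n_stringent = sum(stats$category == "stringent"),
    n_relaxed = sum(stats$category == "relaxed"),
    n_up_probes = sum(stats$direction == "up"),
    n_down_probes = sum(stats$direction == "down"),
    n_genes_upregulated = sum(calls$status == "upregulated"),
    n_genes_downregulated = sum(calls$status == "downregulated"),
    n_genes_conflicted = sum(calls$status == "conflicted"),
    n_genes_no_change = sum(calls$status == "no_change"))
  say("differential_expression", "%d up / %d down probes",
      sum(stats$direction == "up"), sum(stats$direction == "down"))

  # --- stage: clustering ----------------------------------------------------
  lens <- chrom_lengths(annotation)
  test_chrom <- names(lens)[1]
  up_genes <- calls$gene_id[calls$status == "upregulated"]
  up_genes <- up_genes[annotation$chrom[match(up_genes, annotation$gene_id)] ==
                         test_chrom]
  if (length(up_genes) >= 2) {
    ctest <- cluster_test(up_genes, annotation, test_chrom, config$n_iter,
                          stage_seed(config$seed, "cluster_test"))
    clusters <- detect_clusters(up_genes, annotation, config$max_gap_bp)
    write_clusters(clusters, file.path(config$outdir, "clusters.bed"))
    utils::write.table(data.frame(null_median_bp = ctest$null_medians),
                       file.path(config$outdir, "cluster_null.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$cluster_analysis <- list(
      chrom = test_chrom, k = ctest$k,
      observed_median_bp = ctest$observed_median_bp,
      null_mean_bp = ctest$null_mean_bp,
      null_ci95 = ctest$null_ci95,
      p_empirical = ctest$p_empirical, p_parametric = ctest$p_parametric,
      clustered_significant = ctest$p_empirical <= config$alpha,
      n_clusters = nrow(clusters$clusters),
      fraction_clustered = clusters$fraction_clustered)
  } else {
    ctest <- NULL
    clusters <- detect_clusters(character(0), annotation, config$max_gap_bp)
    report$stages$cluster_analysis <- list(
      chrom = test_chrom, k = length(up_genes), skipped = TRUE,
      n_clusters = 0, fraction_clustered = 0)
  }
  say("cluster_analysis", "%d clusters, p_empirical %s",
      nrow(clusters$clusters),
      if (is.null(ctest)) "NA" else format(ctest$p_empirical))

  # --- stage: repeat enrichment --------------------------------------------
  if (nrow(clusters$clusters) > 0) {
    screen <- enrichment_screen(clusters, repeats, lens[[test_chrom]],
                                config$n_iter,
                                stage_seed(config$seed, "enrichment"),
                                config$alpha)
    utils::write.table(screen, file.path(config$outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$feature_enrichment <- list(
      n_candidate_families = nrow(screen),
      n_enriched = sum(screen$enriched),
      enriched_families = screen$family[screen$enriched],
      p_values = stats::setNames(screen$p, screen$family))
  } else {
    report$stages$feature_enrichment <- list(
      n_candidate_families = 0, n_enriched = 0,
      enriched_families = character(0))
  }
  say("feature_enrichment", "%d enriched families",
      report$stages$feature_enrichment$n_enriched)

  # --- stage: methylation ---------------------------------------------------
  if (!is.null(meth_tab)) {
    utils::write.table(meth_tab, file.path(config$outdir, "methylation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    comp <- compare_groups(meth_tab)
    utils::write.table(comp, file.path(config$outdir,
                                       "methylation_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$methylation <- list(
      n_amplicons = nrow(comp),
      n_significant = sum(comp$significant),
      significant_amplicons = comp$amplicon_id[comp$significant])
    say("methylation", "%d of %d amplicons significant",
        sum(comp$significant), nrow(comp))
  }

  report$config <- config_echo(config)
  report <- structure(report, class = "run_report")
  write_report(report, config$outdir)
  invisible(report)
}

config_echo <- function(config) {
  out <- unclass(config)
  out$synthetic <- if (!is.null(out$synthetic)) unclass(out$synthetic)
  out$outdir <- NULL   # path varies between runs; keep reports comparable
  out
}

write_report <- function(report, outdir) {
  jsonlite::write_json(unclass(report),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  yaml::write_yaml(report$config, file.path(outdir, "config_echo.yaml"))
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (", x$mode, " mode, seed ", x$seed, ")\n", sep = "")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    keys <- names(st)[vapply(st, function(v)
      is.numeric(v) && length(v) == 1, logical(1))]
    cat("  ", nm, ": ",
        paste(keys, vapply(st[keys], function(v) format(signif(v, 4)),
                           character(1)), sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
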