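# Probe-set to gene mapping and the uniqueness filter.

#' Construct a probe-set to gene map
#'
#' @param relations data frame with columns \code{probe_id}, \code{gene_id}
#'   (one row per relation; a probe mapping to k genes has k rows; a probe
#'   mapping to no gene may appear with an empty/NA gene_id).
#' @param n_probes_total total probe sets on the array (the universe); default
#'   the number of distinct probe ids seen.  The reported unique-mapping
#'   percentage is taken over this full array universe, not over the mapped
#'   subset.
#' @param n_genes_universe total genes in the annotation universe; default the
#'   number of distinct gene ids seen.
#' @return object of class \code{probe_gene_map}: list with \code{relations}
#'   (named list probe_id -> character vector of gene ids),
#'   \code{n_probes_total} and \code{n_genes_universe}.
#' @export
probe_gene_map <- function(relations, n_probes_total = NULL,
                           n_genes_universe = NULL) {
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_id") %in% names(relations))) {
    stop("relations need columns probe_id, gene_id")
  }
  relations$probe_id <- as.character(relations$probe_id)
  relations$gene_id <- as.character(relations$gene_id)
  ok <- !is.na(relations$gene_id) & nzchar(relations$gene_id)
  rel <- lapply(split(relations$gene_id[ok], relations$probe_id[ok]), unique)
  # probes present only with empty gene ids map to zero genes
  unmapped <- setdiff(unique(relations$probe_id), names(rel))
  rel[unmapped] <- list(character(0))
  n_seen <- length(rel)
  structure(list(
    relations = rel,
    n_probes_total = as.numeric(n_probes_total %||% n_seen),
    n_genes_universe = as.numeric(
      n_genes_universe %||% length(unique(relations$gene_id[ok])))),
    class = "probe_gene_map")
}

#' Read a probe-map TSV (columns probe_id, gene_id)
#' @param path input TSV with header.
#' @param n_probes_total,n_genes_universe see \code{\link{probe_gene_map}}.
#' @return a \code{probe_gene_map}.
#' @export
read_probe_map <- function(path, n_probes_total = NULL,
                           n_genes_universe = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  probe_gene_map(df, n_probes_total, n_genes_universe)
}

#' @export
print.probe_gene_map <- function(x, ...) {
  cat("Probe-gene map: ", length(x$relations), " probe sets seen (universe ",
      x$n_probes_total, "), gene universe ", x$n_genes_universe, "\n", sep = "")
  invisible(x)
}

#' Discard nonspecific probe sets
#'
#' A probe set mapped to more than one gene is nonspecific and is discarded;
#' probe sets mapped to no gene are also dropped but tallied separately.  The
#' unique percentage is taken over the full array universe.
#'
#' @param map a \code{\link{probe_gene_map}}.
#' @return list with \code{map} (the filtered \code{probe_gene_map}, exactly
#'   the probes with one target gene) and \code{summary} (class
#'   \code{mapping_summary}: counts and percentages, percentages rounded
#'   half-up to 2 decimals for reporting).
#' @export
filter_unique <- function(map) {
  stopifnot(inherits(map, "probe_gene_map"))
  n_targets <- lengths(map$relations)
  keep <- names(map$relations)[n_targets == 1]
  filtered <- structure(list(
    relations = map$relations[keep],
    n_probes_total = map$n_probes_total,
    n_genes_universe = map$n_genes_universe), class = "probe_gene_map")
  covered <- genes_covered(filtered)
  summary <- structure(list(
    n_probes_total = map$n_probes_total,
    n_probes_unique = length(keep),
    n_probes_multi = sum(n_targets > 1),
    n_probes_unmapped = sum(n_targets == 0),
    pct_probes_unique = round_half_up(100 * length(keep) / map$n_probes_total),
    n_genes_covered = covered$count,
    pct_genes_covered = round_half_up(covered$pct)),
    class = "mapping_summary")
  list(map = filtered, summary = summary)
}

#' Genes covered by uniquely mapping probe sets
#'
#' @param map a \code{\link{probe_gene_map}} (apply
#'   \code{\link{filter_unique}} first to restrict to specific probes).
#' @return list with \code{count} (distinct genes with at least one probe) and
#'   \code{pct} (percent of the gene universe, full precision).
#' @export
genes_covered <- function(map) {
  stopifnot(inherits(map, "probe_gene_map"))
  if (map$n_genes_universe <= 0) {
    stop("invalid input: gene universe must be positive")
  }
  single <- map$relations[lengths(map$relations) == 1]
  count <- length(unique(unlist(single, use.names = FALSE)))
  list(count = count, pct = 100 * count / map$n_genes_universe)
}

#' @export
print.mapping_summary <- function(x, ...) {
  cat(sprintf(
    "%d of %d probe sets (%.2f%%) map to unique locations, covering %d genes (%.2f%%);\n%d multi-mapping and %d unmapped probe sets discarded\n",
    x$n_probes_unique, as.integer(x$n_probes_total), x$pct_probes_unique,
    x$n_genes_covered, x$pct_genes_covered, x$n_probes_multi,
    x$n_probes_unmapped))
  invisible(x)
}

#' @export
format.mapping_summary <- function(x, ...) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE)
}
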