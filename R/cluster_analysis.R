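# Positional clustering of a called gene set along one chromosome: the
# median inter-gene-distance statistic, its resampling null (random same-size
# gene sets from the same chromosome), and max-gap cluster detection.

#' Median successive-gap distance of a gene set
#'
#' Genes are sorted by start coordinate; the statistic is the median of the
#' successive start-to-start differences (midpoint of the two central values
#' for an even number of gaps).  Start coordinates anchor the distances; the
#' statistic behaves as a local packing measure.
#'
#' @param gene_ids character vector (>= 2 genes, all on one chromosome).
#' @param annotation a \code{\link{gene_annotation}}.
#' @return median gap in bp.
#' @export
median_gap <- function(gene_ids, annotation) {
  gene_ids <- unique(as.character(gene_ids))
  idx <- match(gene_ids, annotation$gene_id)
  if (anyNA(idx)) stop("unknown gene_id: ", gene_ids[which(is.na(idx))[1]])
  if (length(idx) < 2) stop("need at least 2 genes")
  if (length(unique(annotation$chrom[idx])) > 1) {
    stop("genes span multiple chromosomes")
  }
  starts <- sort(annotation$start[idx])
  stats::median(diff(starts))
}

#' Resampling null for the median-gap statistic
#'
#' Each iterate draws \code{k} distinct genes uniformly without replacement
#' from the chromosome's annotated genes and records their median gap.  The
#' sampling universe is the annotated gene set handed in, so restricting the
#' null to array-represented genes is done by subsetting the annotation.
#'
#' @param annotation a \code{\link{gene_annotation}}.
#' @param chrom chromosome to sample from.
#' @param k genes per resampled set.
#' @param n_iter number of iterates.
#' @param seed integer seed (NULL = use current RNG state).
#' @return numeric vector of \code{n_iter} null median gaps.
#' @export
resample_null <- function(annotation, chrom, k, n_iter = 1000, seed = NULL) {
  pool <- annotation$start[annotation$chrom == chrom]
  if (k > length(pool)) {
    stop("k = ", k, " exceeds the ", length(pool), " genes on ", chrom)
  }
  if (k < 2) stop("need k >= 2")
  if (n_iter < 1) stop("need n_iter >= 1")
  with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      stats::median(diff(sort(sample(pool, k))))
    }, numeric(1))
  })
}

#' Positional-clustering resampling test
#'
#' Tests whether the called genes sit closer together along the chromosome
#' than random same-size gene sets: the observed median successive-gap
#' distance is compared with \code{n_iter} resampled sets.  Two p-values are
#' reported: the empirical lower-tail p
#' \code{(1 + #\{null <= observed\}) / (n_iter + 1)} (the assumption-free
#' headline) and a parametric lower-tail probability under a normal fit to the
#' null medians (the null is close to normal for desk-scale gene counts).
#'
#' @param called_genes character vector of called gene ids (>= 2, one
#'   chromosome).
#' @param annotation a \code{\link{gene_annotation}} (the null universe).
#' @param chrom chromosome tested.
#' @param n_iter resamples (default 1000).
#' @param seed integer seed.
#' @return object of class \code{cluster_test}: list with
#'   \code{observed_median_bp}, \code{null_medians}, \code{null_mean_bp},
#'   \code{null_sd_bp}, \code{null_ci95} (normal-theory CI of the null mean),
#'   \code{p_parametric}, \code{p_empirical}, \code{k}, \code{n_iter}.
#' @export
cluster_test <- function(called_genes, annotation, chrom, n_iter = 1000,
                         seed = NULL) {
  observed <- median_gap(called_genes, annotation)
  k <- length(unique(called_genes))
  null <- resample_null(annotation, chrom, k, n_iter, seed)
  m <- mean(null); s <- stats::sd(null)
  structure(list(
    observed_median_bp = observed,
    null_medians = null,
    null_mean_bp = m,
    null_sd_bp = s,
    null_ci95 = c(m - 1.96 * s / sqrt(n_iter), m + 1.96 * s / sqrt(n_iter)),
    p_parametric = if (s > 0) stats::pnorm(observed, m, s) else
      as.numeric(observed <= m),
    p_empirical = (1 + sum(null <= observed)) / (n_iter + 1),
    k = k, n_iter = n_iter), class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat("Positional-clustering resampling test\n")
  cat(sprintf("  observed median gap: %s bp (k = %d genes)\n",
              format(round(x$observed_median_bp), big.mark = ","), x$k))
  cat(sprintf("  null mean of median gaps: %s bp (95%% CI %s - %s), %d resamples\n",
              format(round(x$null_mean_bp), big.mark = ","),
              format(round(x$null_ci95[1]), big.mark = ","),
              format(round(x$null_ci95[2]), big.mark = ","), x$n_iter))
  cat(sprintf("  empirical p = %.4g (headline); parametric p = %.4g\n",
              x$p_empirical, x$p_parametric))
  invisible(x)
}

#' Detect clusters of called genes by max-gap chaining
#'
#' Called genes are sorted by start; successive genes are chained while the
#' start-to-start gap is at most \code{max_gap_bp}; maximal chains with at
#' least \code{min_genes} members become clusters.  The cluster span runs from
#' the first member's start to the last member's end.
#'
#' @param called_genes character vector of called gene ids (one chromosome).
#' @param annotation a \code{\link{gene_annotation}}.
#' @param max_gap_bp chaining threshold (default 500 kb).
#' @param min_genes minimum cluster size (default 2).
#' @return object of class \code{gene_clusters}: list with \code{clusters}
#'   (data frame cluster, chrom, start, end, n_genes, members
#'   (comma-separated, position-ordered)) and \code{fraction_clustered}
#'   (clustered called genes / all called genes; 0 for empty input).
#' @export
detect_clusters <- function(called_genes, annotation, max_gap_bp = 500e3,
                            min_genes = 2) {
  called_genes <- unique(as.character(called_genes))
  empty <- data.frame(cluster = integer(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_genes = integer(0), members = character(0))
  if (length(called_genes) == 0) {
    return(structure(list(clusters = empty, fraction_clustered = 0,
                          n_called = 0L), class = "gene_clusters"))
  }
  idx <- match(called_genes, annotation$gene_id)
  if (anyNA(idx)) {
    stop("unknown gene_id: ", called_genes[which(is.na(idx))[1]])
  }
  g <- annotation[idx, , drop = FALSE]
  if (length(unique(g$chrom)) > 1) stop("called genes span multiple chromosomes")
  ord <- order(g$start)
  g <- g[ord, , drop = FALSE]
  gaps <- diff(g$start)
  chain <- cumsum(c(1, as.integer(gaps > max_gap_bp)))
  rows <- lapply(split(seq_len(nrow(g)), chain), function(ii) {
    if (length(ii) < min_genes) return(NULL)
    data.frame(chrom = g$chrom[ii[1]], start = g$start[ii[1]],
               end = max(g$end[ii]), n_genes = length(ii),
               members = paste(g$gene_id[ii], collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  clusters <- if (length(rows) > 0) {
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    cbind(cluster = seq_len(nrow(out)), out)
  } else empty
  n_in <- sum(clusters$n_genes)
  structure(list(clusters = clusters,
                 fraction_clustered = n_in / length(called_genes),
                 n_called = length(called_genes)),
            class = "gene_clusters")
}

#' @export
print.gene_clusters <- function(x, ...) {
  cat(sprintf("%d cluster(s) over %d called genes (%.0f%% clustered)\n",
              nrow(x$clusters), x$n_called, 100 * x$fraction_clustered))
  if (nrow(x$clusters) > 0) {
    print(x$clusters[, c("cluster", "chrom", "start", "end", "n_genes")])
  }
  invisible(x)
}

#' Write detected clusters as BED
#' @param clusters a \code{gene_clusters} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  df <- clusters$clusters
  out <- data.frame(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
                    format(df$end, scientific = FALSE, trim = TRUE),
                    sprintf("cluster_%d", df$cluster), df$n_genes, ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-planted-cluster recovery of detected clusters
#'
#' For each planted cluster in a simulation truth table, reports the best
#' membership Jaccard index over the detected clusters.
#'
#' @param detected a \code{gene_clusters} object.
#' @param truth truth table from \code{\link{generate_genome}}.
#' @return data frame planted cluster id, n_genes, best Jaccard.
#' @export
cluster_recovery <- function(detected, truth) {
  planted <- split(truth$gene_id[!is.na(truth$cluster)],
                   truth$cluster[!is.na(truth$cluster)])
  det <- lapply(strsplit(detected$clusters$members, ","), unique)
  jacc <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  rows <- lapply(names(planted), function(ci) {
    best <- if (length(det) == 0) 0 else
      max(vapply(det, jacc, numeric(1), a = planted[[ci]]))
    data.frame(cluster = as.integer(ci), n_genes = length(planted[[ci]]),
               jaccard = best)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
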