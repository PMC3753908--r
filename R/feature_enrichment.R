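# Repeat-family enrichment inside detected clusters, tested against
# size-matched random regions from the same chromosome with a one-sided
# Wilcoxon rank-sum test.

repeats_granges <- function(repeats, family = NULL) {
  df <- as.data.frame(repeats)
  if (!is.null(family)) df <- df[df$family == family, , drop = FALSE]
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' Count repeat elements of a family overlapping a region
#'
#' Any-overlap rule with half-open semantics: an element straddling a region
#' boundary counts.  With \code{mode = "midpoint"} an element counts in the
#' single region containing its midpoint, so counts over a partition of the
#' chromosome sum exactly to the family total (audit mode).
#'
#' @param repeats a \code{\link{repeat_annotation}}.
#' @param chrom,start,end region (0-based half-open); vectors give one count
#'   per region.
#' @param family repeat family name.
#' @param mode \code{"overlap"} (default) or \code{"midpoint"}.
#' @return integer vector of counts.
#' @export
count_family <- function(repeats, chrom, start, end, family,
                         mode = c("overlap", "midpoint")) {
  mode <- match.arg(mode)
  el <- as.data.frame(repeats)
  el <- el[el$family == family, , drop = FALSE]
  if (nrow(el) == 0) return(integer(length(chrom)))
  if (mode == "midpoint") {
    mid <- floor((el$start + el$end) / 2)
    el_gr <- GenomicRanges::GRanges(el$chrom,
                                    IRanges::IRanges(mid + 1, width = 1))
  } else {
    el_gr <- GenomicRanges::GRanges(el$chrom,
                                    IRanges::IRanges(el$start + 1, el$end))
  }
  reg <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  GenomicRanges::countOverlaps(reg, el_gr)
}

#' Families present at least once in every cluster
#'
#' The candidate filter for the enrichment screen: a feature associated with
#' susceptibility would have to occur in every cluster, so only families with
#' a nonzero count in each cluster span are tested.
#'
#' @param clusters a \code{gene_clusters} object (>= 1 cluster).
#' @param repeats a \code{\link{repeat_annotation}}.
#' @return character vector of family names.
#' @export
candidate_families <- function(clusters, repeats) {
  cl <- clusters$clusters
  if (nrow(cl) == 0) stop("need at least one cluster")
  fams <- unique(repeats$family)
  keep <- vapply(fams, function(f) {
    all(count_family(repeats, cl$chrom, cl$start, cl$end, f) >= 1)
  }, logical(1))
  fams[keep]
}

#' Sample size-matched random regions
#'
#' Per iterate, one region per requested size with its start uniform on
#' \code{[0, chrom_length - size]}; regions may overlap each other and any
#' annotation (no exclusion mask).
#'
#' @param chrom_length chromosome length in bp.
#' @param sizes region sizes in bp (the cluster spans).
#' @param n_iter iterates.
#' @param seed integer seed (NULL = current RNG state).
#' @return data frame iter, region (index within iterate), start, end.
#' @export
sample_matched_regions <- function(chrom_length, sizes, n_iter = 1000,
                                   seed = NULL) {
  if (any(sizes > chrom_length)) stop("region size exceeds chromosome length")
  if (any(sizes <= 0)) stop("region sizes must be positive")
  with_seed(seed, {
    n <- length(sizes)
    starts <- floor(stats::runif(n_iter * n, 0,
                                 rep(chrom_length - sizes + 1, n_iter)))
    data.frame(iter = rep(seq_len(n_iter), each = n),
               region = rep(seq_len(n), n_iter),
               start = starts, end = starts + rep(sizes, n_iter))
  })
}

#' One-sided Wilcoxon rank-sum test (greater)
#'
#' Exact p by full enumeration of rank splits when both samples have at most
#' \code{exact_max} observations (ties handled through midranks, enumerating
#' the actual pooled values), otherwise the normal approximation with tie
#' correction and continuity correction.  The enumeration additionally guards
#' against combinatorial blow-up (at most 2e5 splits).
#'
#' @param x,y numeric samples; tests whether \code{x} is stochastically
#'   greater than \code{y}.
#' @param exact_max exact-path sample-size bound (default 12).
#' @return list with \code{W} (rank-sum of \code{x} minus its minimum, the
#'   Mann-Whitney U), \code{p}, and \code{method}.
#' @export
rank_sum_greater <- function(x, y, exact_max = 12) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  if (n1 <= exact_max && n2 <= exact_max &&
      choose(n1 + n2, n1) <= 2e5) {
    splits <- utils::combn(n1 + n2, n1)
    w_all <- colSums(matrix(r[splits], nrow = n1))
    p <- sum(w_all >= w_obs - 1e-9) / ncol(splits)
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- n1 * (n + 1) / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    z <- (w_obs - mu - 0.5) / sqrt(sigma2)
    p <- stats::pnorm(z, lower.tail = FALSE)
    method <- "normal"
  }
  list(W = w_obs - n1 * (n1 + 1) / 2, p = max(p, .Machine$double.xmin),
       method = method)
}

#' Repeat-family enrichment test against size-matched random regions
#'
#' The observed sample is the per-cluster element count of the family; the
#' null sample pools the per-region counts of all iterates of size-matched
#' random regions.  Significance is a one-sided Wilcoxon rank-sum test
#' (observed greater than null); counts are compared raw because each null
#' region matches a cluster's size exactly.
#'
#' @param clusters a \code{gene_clusters} object.
#' @param repeats a \code{\link{repeat_annotation}}.
#' @param family family to test (must be present in the annotation).
#' @param chrom_length length of the sampled chromosome in bp.
#' @param n_iter null iterates (default 1000).
#' @param seed integer seed.
#' @param alpha significance level for the flag (default 1e-3).
#' @param stratified if TRUE, compare each cluster only with its own
#'   size-matched regions (per-cluster-stratified Wilcoxon on pooled evidence
#'   is not defined; the stratified mode simply restricts the null sample of
#'   each cluster's count to regions of its own size and pools ranks within
#'   strata).  Default FALSE (pooled).
#' @return object of class \code{enrichment_result}: list with \code{family},
#'   \code{cluster_counts}, \code{null_counts}, \code{null_mean},
#'   \code{p_wilcoxon}, \code{enriched}, \code{n_iter}, \code{method}.
#' @export
enrichment_test <- function(clusters, repeats, family, chrom_length,
                            n_iter = 1000, seed = NULL, alpha = 1e-3,
                            stratified = FALSE) {
  cl <- clusters$clusters
  if (nrow(cl) == 0) stop("need at least one cluster")
  if (!family %in% repeats$family) {
    stop("family not present in repeat annotation: ", family)
  }
  chrom <- cl$chrom[1]
  sizes <- cl$end - cl$start
  obs <- count_family(repeats, cl$chrom, cl$start, cl$end, family)
  reg <- sample_matched_regions(chrom_length, sizes, n_iter, seed)
  null_counts <- count_family(repeats, rep(chrom, nrow(reg)), reg$start,
                              reg$end, family)
  if (stratified) {
    # rank within strata of identical region size, then pool the evidence
    p_strata <- vapply(seq_along(sizes), function(i) {
      rank_sum_greater(obs[i], null_counts[reg$region == i])$p
    }, numeric(1))
    # Fisher combination of per-cluster one-sided p-values
    stat <- -2 * sum(log(p_strata))
    p <- stats::pchisq(stat, df = 2 * length(p_strata), lower.tail = FALSE)
    test <- list(p = p, method = "stratified-fisher")
  } else {
    test <- rank_sum_greater(obs, null_counts)
  }
  structure(list(family = family, cluster_counts = obs,
                 null_counts = null_counts, null_mean = mean(null_counts),
                 p_wilcoxon = test$p, enriched = test$p <= alpha,
                 alpha = alpha, n_iter = n_iter, method = test$method),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Family %s: cluster counts [%s], null mean %.2f, one-sided p = %.3g (%s)%s\n",
    x$family, paste(x$cluster_counts, collapse = ", "), x$null_mean,
    x$p_wilcoxon, x$method,
    if (x$enriched) sprintf(" *enriched at alpha = %g*", x$alpha) else ""))
  invisible(x)
}

#' Screen every candidate family for cluster enrichment
#'
#' Runs \code{\link{candidate_families}} then \code{\link{enrichment_test}}
#' per family; every candidate's p-value is reported (no silent filtering) and
#' no multiple-testing correction is applied by default (raw rank-sum
#' p-values; set \code{bh = TRUE} for a BH-adjusted column).
#'
#' @param clusters a \code{gene_clusters} object.
#' @param repeats a \code{\link{repeat_annotation}}.
#' @param chrom_length length of the sampled chromosome in bp.
#' @param n_iter null iterates per family.
#' @param seed integer seed (per-family seeds are derived from it).
#' @param alpha flag threshold (default 1e-3).
#' @param bh add BH-adjusted p-values and flag on those instead.
#' @return data frame: family, min/max cluster count, null_mean, p, (fdr),
#'   enriched; attribute \code{results} holds the full
#'   \code{enrichment_result} objects.
#' @export
enrichment_screen <- function(clusters, repeats, chrom_length, n_iter = 1000,
                              seed = NULL, alpha = 1e-3, bh = FALSE) {
  fams <- tryCatch(candidate_families(clusters, repeats),
                   error = function(e) character(0))
  if (length(fams) == 0) {
    out <- data.frame(family = character(0), min_count = integer(0),
                      max_count = integer(0), null_mean = numeric(0),
                      p = numeric(0), enriched = logical(0))
    attr(out, "results") <- list()
    return(out)
  }
  results <- lapply(fams, function(f) {
    s <- if (is.null(seed)) NULL else stage_seed(seed, paste0("enrich:", f))
    enrichment_test(clusters, repeats, f, chrom_length, n_iter, s, alpha)
  })
  out <- data.frame(
    family = fams,
    min_count = vapply(results, function(r) min(r$cluster_counts), numeric(1)),
    max_count = vapply(results, function(r) max(r$cluster_counts), numeric(1)),
    null_mean = vapply(results, function(r) r$null_mean, numeric(1)),
    p = vapply(results, function(r) r$p_wilcoxon, numeric(1)),
    stringsAsFactors = FALSE)
  if (bh) {
    out$fdr <- bh_adjust(out$p)
    out$enriched <- out$fdr <= alpha
  } else {
    out$enriched <- out$p <= alpha
  }
  attr(out, "results") <- results
  out
}
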