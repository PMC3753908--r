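# Two-group differential expression on a log2 matrix: moderated t-statistics
# with empirical-Bayes variance shrinkage, BH FDR control, the probe
# classification rules (stringent FDR <= 0.10, relaxed 0.10 < FDR <= 0.30,
# direction by non-log actual change vs 1), and aggregation to gene calls.

#' Read a log2 expression matrix (TSV, first column probe_id)
#' @param path TSV with header; remaining columns are samples.
#' @return numeric matrix, probes x samples.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("expression matrix contains missing values")
  m
}

#' Read a sample sheet (TSV: sample_id, group, sex)
#' @param path TSV with header.
#' @return data frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("sample sheet needs columns sample_id, group")
  }
  df
}

# Invert the trigamma function by Newton iteration on 1/x scale
# (monotone, well conditioned; used for the prior df fit).
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    y <- 0.5 + 1 / xi
    for (i in 1:60) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif) / y < 1e-10) break
    }
    y
  }, numeric(1))
}

# Method-of-moments fit of a scaled inverse chi-square prior to the sample
# variances, on the log scale: log(s^2) for s^2 ~ s0^2 * chisq_d/d * F prior
# has known digamma/trigamma moments.  Returns prior df d0 (possibly Inf) and
# prior variance s0^2.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) stop("need at least two positive sample variances")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  evar <- sum((e - ebar)^2) / (length(e) - 1)
  rhs <- evar - trigamma(df / 2)
  if (rhs <= 0) {
    d0 <- Inf
    s0 <- exp(ebar)
  } else {
    d0 <- 2 * trigamma_inverse(rhs)
    s0 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  list(prior_df = d0, prior_var = s0)
}

#' Moderated two-sample t-statistics per probe set
#'
#' Computes per-probe log2 fold changes (mean mutant minus mean wild type) and
#' two-sided p-values from a pooled-variance two-sample t-statistic.  With
#' \code{shrinkage = TRUE} (the default) per-probe variances are shrunk toward
#' a common prior fitted across all probes by method of moments on the log
#' sample variances (scaled inverse chi-square prior with df \code{d0} and
#' scale \code{s0^2}); the posterior variance is
#' \code{(d0 s0^2 + d s^2) / (d0 + d)} and the t reference distribution gains
#' the prior degrees of freedom.  With \code{shrinkage = FALSE} the classic
#' pooled t with \code{df = n1 + n2 - 2} is returned (closed-form oracle for
#' testing).
#'
#' @param values probes x samples numeric matrix of log2 intensities.
#' @param samples sample sheet data frame (\code{sample_id}, \code{group}).
#' @param group_test,group_ref group labels contrasted as test minus
#'   reference.
#' @param shrinkage logical; empirical-Bayes variance moderation.
#' @param prior_df,prior_var optional prior overrides (bypass the fit);
#'   \code{prior_df = Inf} pins every posterior variance at \code{prior_var}.
#' @return data frame of class \code{probe_stats}: probe_id, log2fc,
#'   actual_change (= 2^log2fc), t, df, p, plus attributes \code{prior_df} and
#'   \code{prior_var} when shrinkage is on.
#' @export
moderated_t <- function(values, samples, group_test = "mutant",
                        group_ref = "wt", shrinkage = TRUE,
                        prior_df = NULL, prior_var = NULL) {
  stopifnot(is.matrix(values))
  idx_t <- samples$sample_id[samples$group == group_test]
  idx_r <- samples$sample_id[samples$group == group_ref]
  if (!all(c(idx_t, idx_r) %in% colnames(values))) {
    stop("sample sheet does not match matrix columns")
  }
  n1 <- length(idx_r); n2 <- length(idx_t)
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per group")
  xr <- values[, idx_r, drop = FALSE]
  xt <- values[, idx_t, drop = FALSE]
  mr <- rowMeans(xr); mt <- rowMeans(xt)
  log2fc <- mt - mr
  d <- n1 + n2 - 2
  ssr <- rowSums((xr - mr)^2)
  sst <- rowSums((xt - mt)^2)
  s2 <- (ssr + sst) / d
  scale2 <- 1 / n1 + 1 / n2

  if (shrinkage) {
    if (is.null(prior_df) || is.null(prior_var)) {
      prior <- fit_variance_prior(s2, d)
      prior_df <- prior_df %||% prior$prior_df
      prior_var <- prior_var %||% prior$prior_var
    }
    if (is.infinite(prior_df)) {
      s2_post <- rep(prior_var, length(s2))
      df_post <- rep(Inf, length(s2))
    } else {
      s2_post <- (prior_df * prior_var + d * s2) / (prior_df + d)
      df_post <- rep(prior_df + d, length(s2))
    }
    t <- log2fc / sqrt(s2_post * scale2)
    p <- 2 * stats::pt(-abs(t), df_post)
  } else {
    zero <- s2 == 0
    t <- log2fc / sqrt(s2 * scale2)
    t[zero & log2fc == 0] <- 0
    p <- 2 * stats::pt(-abs(t), d)
    p[zero & log2fc == 0] <- 1
    if (any(zero & log2fc != 0)) {
      warning(sum(zero & log2fc != 0),
              " probe(s) with zero within-group variance: p reported as 0")
      p[zero & log2fc != 0] <- 0
    }
    df_post <- rep(d, length(s2))
  }
  out <- data.frame(probe_id = rownames(values) %||%
                      sprintf("probe%05d", seq_along(log2fc)),
                    log2fc = log2fc, actual_change = 2^log2fc,
                    t = t, df = df_post, p = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (shrinkage) {
    attr(out, "prior_df") <- prior_df
    attr(out, "prior_var") <- prior_var
  }
  class(out) <- c("probe_stats", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' \code{q(i) = min over j >= i of p(j) * m / j}, clipped to 1, returned in
#' the original input order (delegates to \code{stats::p.adjust}).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Classify probe sets by FDR category and direction
#'
#' Adds BH-adjusted FDR (if absent), the category (\code{stringent} for
#' FDR <= \code{fdr_stringent}, \code{relaxed} for FDR in
#' (\code{fdr_stringent}, \code{fdr_relaxed}], else \code{none}) and the
#' direction: among probes at FDR <= \code{fdr_relaxed}, upregulated means a
#' non-log actual change > 1 and downregulated < 1 (strict inequalities; an
#' actual change of exactly 1 has no direction).  \code{pct_change} reports
#' \code{(actual_change - 1) * 100}, e.g. an actual change of 1.25 is 25\%
#' upregulation.
#'
#' @param stats a \code{probe_stats} data frame from
#'   \code{\link{moderated_t}}.
#' @param fdr_stringent,fdr_relaxed FDR thresholds (defaults 0.10 and 0.30).
#' @return the input with columns \code{fdr}, \code{category},
#'   \code{direction}, \code{pct_change} added.
#' @export
classify_probes <- function(stats, fdr_stringent = 0.10, fdr_relaxed = 0.30) {
  if (fdr_relaxed < fdr_stringent) {
    stop("fdr_relaxed must be >= fdr_stringent")
  }
  if (is.null(stats$fdr)) stats$fdr <- bh_adjust(stats$p)
  stats$category <- ifelse(stats$fdr <= fdr_stringent, "stringent",
                           ifelse(stats$fdr <= fdr_relaxed, "relaxed", "none"))
  sig <- stats$fdr <= fdr_relaxed
  stats$direction <- ifelse(sig & stats$actual_change > 1, "up",
                            ifelse(sig & stats$actual_change < 1, "down",
                                   "none"))
  stats$pct_change <- (stats$actual_change - 1) * 100
  stats
}

#' Aggregate probe-set calls to gene calls
#'
#' A gene is upregulated iff it has at least one upregulated probe set and no
#' downregulated probe set (at the relaxed FDR), downregulated symmetrically,
#' conflicted if it has both, and no_change if none of its probe sets is
#' significant.  The expression value of an up/downregulated gene is the
#' arithmetic mean of the non-log actual changes of its same-direction
#' significant probe sets.
#'
#' @param stats classified \code{probe_stats} (see
#'   \code{\link{classify_probes}}).
#' @param map a uniqueness-filtered \code{\link{probe_gene_map}} (each probe
#'   maps to exactly one gene).  Probes in \code{stats} absent from the map
#'   are skipped (count reported as attribute \code{n_skipped}).
#' @return data frame gene_id, status, expression_value, n_probes, n_up,
#'   n_down.
#' @export
aggregate_genes <- function(stats, map) {
  stopifnot(inherits(map, "probe_gene_map"))
  if (any(lengths(map$relations) != 1)) {
    stop("map must be uniqueness-filtered (see filter_unique)")
  }
  gene_of <- vapply(map$relations, `[`, character(1), 1)
  known <- stats$probe_id %in% names(gene_of)
  n_skipped <- sum(!known)
  st <- stats[known, , drop = FALSE]
  st$gene_id <- gene_of[st$probe_id]
  agg <- lapply(split(st, st$gene_id), function(g) {
    n_up <- sum(g$direction == "up")
    n_down <- sum(g$direction == "down")
    status <- if (n_up > 0 && n_down == 0) "upregulated"
      else if (n_down > 0 && n_up == 0) "downregulated"
      else if (n_up > 0 && n_down > 0) "conflicted"
      else "no_change"
    value <- switch(status,
      upregulated = mean(g$actual_change[g$direction == "up"]),
      downregulated = mean(g$actual_change[g$direction == "down"]),
      NA_real_)
    data.frame(gene_id = g$gene_id[1], status = status,
               expression_value = value, n_probes = nrow(g),
               n_up = n_up, n_down = n_down, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), status = character(0),
                      expression_value = numeric(0), n_probes = integer(0),
                      n_up = integer(0), n_down = integer(0))
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Relative expression from qPCR Ct values with a housekeeping panel
#'
#' Per sample, a target's relative expression is
#' \code{2^-(Ct_target - mean(Ct_housekeeping))} (arithmetic mean of
#' housekeeping Ct, i.e. geometric mean of linear abundances).  Group pairs
#' are compared by a two-sided unpaired pooled-variance (Student) t-test on
#' relative expression, flagged significant at p <= 0.05.
#'
#' @param ct matrix or data frame of Ct values, samples x targets (row names
#'   are sample ids); NA Ct drops that sample for that target with a warning.
#' @param housekeeping character vector of housekeeping target names (all
#'   must be present for every sample).
#' @param samples sample sheet (\code{sample_id}, \code{group}).
#' @param group_test,group_ref the compared groups.
#' @return list with \code{relative} (samples x targets matrix) and
#'   \code{comparison} (data frame: target, mean and sd per group, fold_change
#'   of group means, t, p, significant).
#' @export
qpcr_relative_expression <- function(ct, housekeeping, samples,
                                     group_test = "mutant",
                                     group_ref = "wt") {
  ct <- as.matrix(ct)
  if (!all(housekeeping %in% colnames(ct))) {
    stop("housekeeping target(s) missing from Ct table")
  }
  if (anyNA(ct[, housekeeping])) {
    stop("housekeeping Ct must be present for every sample")
  }
  hk <- rowMeans(ct[, housekeeping, drop = FALSE])
  targets <- setdiff(colnames(ct), housekeeping)
  rel <- 2^-(ct[, targets, drop = FALSE] - hk)
  grp <- samples$group[match(rownames(ct), samples$sample_id)]
  rows <- lapply(targets, function(tg) {
    x <- rel[grp == group_test, tg]
    y <- rel[grp == group_ref, tg]
    if (anyNA(c(x, y))) {
      warning("missing Ct for ", tg, ": affected sample(s) dropped")
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
    }
    ht <- pooled_t_test(x, y)
    data.frame(target = tg,
               mean_ref = mean(y), sd_ref = stats::sd(y),
               mean_test = mean(x), sd_test = stats::sd(x),
               fold_change = mean(x) / mean(y),
               t = ht$t, p = ht$p, significant = ht$p <= 0.05,
               stringsAsFactors = FALSE)
  })
  list(relative = rel, comparison = do.call(rbind, rows))
}

# Two-sided unpaired pooled-variance t with explicit handling of the
# zero-variance degenerate cases.
pooled_t_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) return(list(t = NA_real_, p = NA_real_, df = NA_real_))
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  delta <- mean(x) - mean(y)
  if (sp2 == 0) {
    if (delta == 0) return(list(t = 0, p = 1, df = df))
    warning("zero pooled variance with distinct means: p reported as 0")
    return(list(t = sign(delta) * Inf, p = 0, df = df))
  }
  t <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}
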