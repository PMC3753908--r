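# Group-wise comparison of percent-methylation tables (per CpG unit, per
# sample, as produced by mass-spectrometry bisulfite assays) and conventional
# bisulfite clone calling with conversion QC.
#
# String positions in this module are 1-based (R convention); genomic
# intervals elsewhere in the package remain 0-based half-open.

#' Read a percent-methylation table
#'
#' Long TSV with columns amplicon_id, sample_id, group, sex, tissue,
#' unit_index, pct (percent methylation in [0, 100]; missing units NA).
#'
#' @param path input TSV with header.
#' @return the validated data frame.
#' @export
read_methylation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("amplicon_id", "sample_id", "group", "unit_index", "pct")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("methylation table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- !is.na(df$pct) & (df$pct < 0 | df$pct > 100)
  if (any(bad)) stop("pct outside [0, 100] at row ", which(bad)[1])
  df
}

#' Per-sample amplicon mean methylation
#'
#' Mean over non-missing CpG units (mass-spec dropouts are excluded pairwise,
#' never imputed).
#'
#' @param table methylation table (see \code{\link{read_methylation}}).
#' @param sample_id sample.
#' @param amplicon_id amplicon.
#' @return mean percent methylation; NA with a warning when every unit is
#'   missing.
#' @export
amplicon_mean <- function(table, sample_id, amplicon_id) {
  sel <- table$sample_id == sample_id & table$amplicon_id == amplicon_id
  if (!any(sel)) stop("no rows for sample ", sample_id, ", amplicon ",
                      amplicon_id)
  v <- table$pct[sel]
  if (all(is.na(v))) {
    warning("all units missing for sample ", sample_id, ", amplicon ",
            amplicon_id, "; sample excluded")
    return(NA_real_)
  }
  mean(v, na.rm = TRUE)
}

#' Compare methylation between two groups, per amplicon
#'
#' Per sample the amplicon mean is taken over CpG units first; groups are then
#' compared by a two-sided unpaired pooled-variance (Student) t-test on those
#' per-sample means (Welch available via \code{welch = TRUE}).  Amplicons with
#' fewer than two usable samples in either group are marked not testable.
#'
#' @param table methylation table.
#' @param group_a,group_b group labels (defaults \code{"wt"},
#'   \code{"mutant"}).
#' @param welch use Welch's t instead of the pooled-variance t.
#' @return data frame of class \code{methylation_comparison}: amplicon_id,
#'   n per group, mean and sd per group, delta (a - b), t, p, significant
#'   (p <= 0.05), testable.
#' @export
compare_groups <- function(table, group_a = "wt", group_b = "mutant",
                           welch = FALSE) {
  amps <- unique(table$amplicon_id)
  rows <- lapply(amps, function(a) {
    sub <- table[table$amplicon_id == a, , drop = FALSE]
    per_sample <- function(grp) {
      ids <- unique(sub$sample_id[sub$group == grp])
      v <- suppressWarnings(
        vapply(ids, function(s) amplicon_mean(sub, s, a), numeric(1)))
      v[!is.na(v)]
    }
    xa <- per_sample(group_a); xb <- per_sample(group_b)
    testable <- length(xa) >= 2 && length(xb) >= 2
    if (!testable) {
      ht <- list(t = NA_real_, p = NA_real_)
    } else if (welch) {
      if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
        ht <- pooled_t_test(xa, xb)
      } else {
        wt <- stats::t.test(xa, xb)
        ht <- list(t = unname(wt$statistic), p = wt$p.value)
      }
    } else {
      ht <- pooled_t_test(xa, xb)
    }
    data.frame(amplicon_id = a, n_a = length(xa), n_b = length(xb),
               mean_a = if (length(xa)) mean(xa) else NA_real_,
               sd_a = if (length(xa) > 1) stats::sd(xa) else NA_real_,
               mean_b = if (length(xb)) mean(xb) else NA_real_,
               sd_b = if (length(xb) > 1) stats::sd(xb) else NA_real_,
               delta = mean(xa) - mean(xb),
               t = ht$t, p = ht$p,
               significant = !is.na(ht$p) & ht$p <= 0.05,
               testable = testable, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("methylation_comparison", "data.frame")
  out
}

#' Find CpG positions in an uppercase DNA string
#' @param seq uppercase ACGT string.
#' @return integer vector of 1-based positions of the C of each CpG.
#' @export
find_cpg <- function(seq) {
  check_dna(seq)
  m <- gregexpr("CG", seq, fixed = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

check_dna <- function(seq) {
  if (grepl("[^ACGT]", seq)) {
    stop("sequence contains non-ACGT character(s)")
  }
  invisible(TRUE)
}

#' Bisulfite conversion map of a reference amplicon
#'
#' CpG positions are the methylation-informative sites; every other reference
#' cytosine is a conversion-QC position (must read T in a fully converted
#' clone).  The expected fully unmethylated conversion replaces every C with
#' T.
#'
#' @param seq uppercase ACGT reference sequence.
#' @return list with \code{cpg_positions}, \code{qc_positions} (1-based
#'   positions of non-CpG Cs) and \code{converted_unmethylated} (string).
#' @export
convert_reference <- function(seq) {
  check_dna(seq)
  cpg <- find_cpg(seq)
  v <- strsplit(seq, "")[[1]]
  c_pos <- which(v == "C")
  v[c_pos] <- "T"
  list(cpg_positions = cpg,
       qc_positions = setdiff(c_pos, cpg),
       converted_unmethylated = paste(v, collapse = ""))
}

#' Call per-CpG methylation of one bisulfite clone
#'
#' The clone must be pre-aligned and equal in length to the reference.  At
#' each reference CpG cytosine: C reads methylated (M), T unmethylated (U),
#' anything else ambiguous.  The conversion rate is the fraction of non-CpG
#' reference cytosines read as T; clones below \code{min_conversion} are
#' flagged rejected (incomplete conversion inflates apparent methylation).
#'
#' @param reference,clone equal-length uppercase ACGT strings.
#' @param min_conversion QC threshold (default 0.97).
#' @return object of class \code{bisulfite_clone}: list with \code{calls}
#'   (character vector M/U/ambiguous, one per reference CpG),
#'   \code{pct_methylation} (100 * M / (M + U)), \code{conversion_rate},
#'   \code{rejected}.
#' @export
call_clone <- function(reference, clone, min_conversion = 0.97) {
  check_dna(reference); check_dna(clone)
  if (nchar(reference) != nchar(clone)) {
    stop("clone length differs from reference")
  }
  conv <- convert_reference(reference)
  vc <- strsplit(clone, "")[[1]]
  calls <- vapply(conv$cpg_positions, function(p) {
    switch(vc[p], C = "M", T = "U", "ambiguous")
  }, character(1))
  qc <- vc[conv$qc_positions]
  conversion <- if (length(qc) == 0) 1 else mean(qc == "T")
  n_m <- sum(calls == "M"); n_u <- sum(calls == "U")
  structure(list(
    calls = calls,
    pct_methylation = if (n_m + n_u > 0) 100 * n_m / (n_m + n_u) else NA_real_,
    conversion_rate = conversion,
    rejected = conversion < min_conversion), class = "bisulfite_clone")
}

#' @export
print.bisulfite_clone <- function(x, ...) {
  lolli <- paste(ifelse(x$calls == "M", "●",
                        ifelse(x$calls == "U", "○", "?")), collapse = " ")
  cat(sprintf("%s  %.0f%% methylated, conversion %.2f%s\n", lolli,
              x$pct_methylation, x$conversion_rate,
              if (x$rejected) " [REJECTED]" else ""))
  invisible(x)
}

#' Call a set of clones against one reference
#' @param reference uppercase ACGT reference.
#' @param clones named character vector of clone sequences.
#' @param min_conversion QC threshold.
#' @return named list of \code{bisulfite_clone} objects.
#' @export
call_clones <- function(reference, clones, min_conversion = 0.97) {
  lapply(clones, call_clone, reference = reference,
         min_conversion = min_conversion)
}

#' Summarise accepted clones per CpG
#'
#' Per CpG site, percent methylation is M / (M + U) over accepted
#' (conversion-passing) clones; ambiguous calls are excluded from both
#' numerator and denominator.
#'
#' @param clones list of \code{bisulfite_clone} objects.
#' @return list with \code{status} (\code{"ok"} or
#'   \code{"no_accepted_clones"}), \code{n_accepted}, \code{n_rejected},
#'   \code{per_cpg_pct} and \code{overall_pct} (NA when no clone passed QC).
#' @export
clone_summary <- function(clones) {
  stopifnot(length(clones) >= 1)
  accepted <- Filter(function(cl) !cl$rejected, clones)
  if (length(accepted) == 0) {
    return(list(status = "no_accepted_clones", n_accepted = 0L,
                n_rejected = length(clones), per_cpg_pct = NA_real_,
                overall_pct = NA_real_))
  }
  mat <- do.call(rbind, lapply(accepted, function(cl) cl$calls))
  per_cpg <- apply(mat, 2, function(col) {
    m <- sum(col == "M"); u <- sum(col == "U")
    if (m + u == 0) NA_real_ else 100 * m / (m + u)
  })
  m_tot <- sum(mat == "M"); u_tot <- sum(mat == "U")
  list(status = "ok", n_accepted = length(accepted),
       n_rejected = length(clones) - length(accepted),
       per_cpg_pct = per_cpg,
       overall_pct = if (m_tot + u_tot > 0) 100 * m_tot / (m_tot + u_tot)
                     else NA_real_)
}

#' Read clone sequences from FASTA
#' @param path FASTA file; a record named \code{reference} (if present) is
#'   returned separately.
#' @return list with \code{reference} (or NULL) and \code{clones} (named
#'   character vector).
#' @export
read_clone_fasta <- function(path) {
  seqs <- as.character(Biostrings::readDNAStringSet(path))
  ref <- if ("reference" %in% names(seqs)) unname(seqs[["reference"]]) else NULL
  list(reference = ref, clones = seqs[setdiff(names(seqs), "reference")])
}
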