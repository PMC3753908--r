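# Genomic interval containers and annotation I/O.
#
# All internal coordinates are 0-based half-open [start, end); conversions to
# and from 1-based formats (GFF3, GRanges) happen only at the I/O boundary.
# Strand is carried but ignored by every statistic in the package.

#' Construct a gene annotation set
#'
#' A gene annotation set is a data frame of named, stranded genomic intervals
#' (0-based half-open) with an attached table of chromosome lengths.  It is the
#' coordinate substrate for the clustering and density operations.
#'
#' @param genes data frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end} and optionally \code{strand} (\code{+}, \code{-}
#'   or \code{.}).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.  If
#'   \code{NULL}, lengths are inferred as the maximum \code{end} per chromosome
#'   and a warning is issued: inferred lengths are unsafe for any sampling
#'   operation.
#' @return object of class \code{gene_annotation} (a data frame with a
#'   \code{chrom_lengths} attribute).
#' @export
gene_annotation <- function(genes, chrom_lengths = NULL) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  required <- c("gene_id", "chrom", "start", "end")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    stop("gene annotation is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"strand" %in% names(genes)) genes$strand <- "."
  genes <- genes[, c("gene_id", "chrom", "start", "end", "strand")]
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  validate_intervals(genes$chrom, genes$start, genes$end)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id: ", genes$gene_id[duplicated(genes$gene_id)][1])
  }
  if (is.null(chrom_lengths)) {
    if (nrow(genes) > 0) {
      chrom_lengths <- tapply(genes$end, genes$chrom, max)
      chrom_lengths <- stats::setNames(as.numeric(chrom_lengths), names(chrom_lengths))
      warning("chrom_lengths inferred from max gene end per chromosome; ",
              "supply a chrom.sizes file before any sampling operation")
    } else {
      chrom_lengths <- stats::setNames(numeric(0), character(0))
    }
  }
  bad <- genes$end > chrom_lengths[genes$chrom]
  if (any(bad, na.rm = TRUE)) {
    stop("gene(s) extend beyond chromosome length: ",
         paste(utils::head(genes$gene_id[which(bad)], 3), collapse = ", "))
  }
  rownames(genes) <- NULL
  structure(genes, chrom_lengths = chrom_lengths,
            class = c("gene_annotation", "data.frame"))
}

validate_intervals <- function(chrom, start, end) {
  if (length(chrom) == 0) return(invisible(TRUE))
  if (any(is.na(chrom) | !nzchar(chrom))) stop("empty chromosome name")
  if (any(is.na(start) | is.na(end))) stop("missing interval coordinate")
  bad <- which(start < 0 | start >= end)
  if (length(bad) > 0) {
    stop("invalid interval (need 0 <= start < end) at row ", bad[1],
         ": [", start[bad[1]], ", ", end[bad[1]], ")")
  }
  invisible(TRUE)
}

#' @export
print.gene_annotation <- function(x, ...) {
  cl <- attr(x, "chrom_lengths")
  cat("Gene annotation set: ", nrow(x), " genes on ",
      length(unique(x$chrom)), " chromosome(s)\n", sep = "")
  cat("Chromosome lengths: ",
      paste(names(cl), format(cl, big.mark = ","), sep = "=", collapse = "; "),
      "\n", sep = "")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Chromosome lengths of an annotation set
#' @param x a \code{gene_annotation} object.
#' @return named numeric vector of lengths in bp.
#' @export
chrom_lengths <- function(x) attr(x, "chrom_lengths")

# Cheap structural pre-scan so parse failures name the offending line.
scan_tabular <- function(path, min_fields, comment_prefixes = c("#")) {
  lines <- readLines(path, warn = FALSE)
  keep <- rep(TRUE, length(lines))
  for (p in comment_prefixes) keep <- keep & !startsWith(lines, p)
  keep <- keep & nzchar(trimws(lines))
  idx <- which(keep)
  for (i in idx) {
    nf <- length(strsplit(lines[i], "\t| +")[[1]])
    if (nf < min_fields) {
      stop("parse error at line ", i, " of ", path,
           ": expected >= ", min_fields, " fields, found ", nf)
    }
  }
  idx
}

#' Read a chrom.sizes file
#'
#' @param path two-column TSV (chromosome, length in bp).
#' @return named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  stats::setNames(df$length, df$chrom)
}

#' Read gene annotation from BED or GFF3
#'
#' BED coordinates are taken as-is (already 0-based half-open); GFF3 is
#' converted from 1-based inclusive.  Parsing is delegated to
#' \code{rtracklayer::import}; a structural pre-scan reports malformed lines by
#' line number first.
#'
#' @param path annotation file.
#' @param format \code{"bed"} or \code{"gff3"}.
#' @param chrom_sizes optional path to a chrom.sizes file; if absent, lengths
#'   are inferred with a warning (see \code{\link{gene_annotation}}).
#' @return a \code{\link{gene_annotation}} object.
#' @export
read_gene_annotation <- function(path, format = c("bed", "gff3"),
                                 chrom_sizes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lens <- if (!is.null(chrom_sizes)) read_chrom_sizes(chrom_sizes) else NULL
  n_data <- length(scan_tabular(path, if (format == "bed") 3 else 9))
  if (n_data == 0) {
    return(gene_annotation(
      data.frame(gene_id = character(0), chrom = character(0),
                 start = numeric(0), end = numeric(0), strand = character(0)),
      chrom_lengths = lens %||% stats::setNames(numeric(0), character(0))))
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,   # GRanges is 1-based inclusive
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "."
  meta <- as.data.frame(GenomicRanges::mcols(gr))
  ids <- if ("name" %in% names(meta)) as.character(meta$name)
         else if ("ID" %in% names(meta)) as.character(meta$ID)
         else if ("Name" %in% names(meta)) as.character(meta$Name)
         else NA_character_
  df$gene_id <- ids
  na_id <- is.na(df$gene_id) | !nzchar(df$gene_id)
  df$gene_id[na_id] <- sprintf("feature_%d", which(na_id))
  gene_annotation(df[, c("gene_id", "chrom", "start", "end", "strand")], lens)
}

#' Write gene annotation as BED
#'
#' Six-column BED (score 0).  Coordinates are written as stored (0-based
#' half-open), so \code{read_gene_annotation(write_gene_annotation(x))} is an
#' exact round trip.
#'
#' @param annotation a \code{gene_annotation}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gene_annotation <- function(annotation, path) {
  df <- as.data.frame(annotation)
  strand <- ifelse(df$strand %in% c("+", "-"), df$strand, ".")
  out <- data.frame(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
                    format(df$end, scientific = FALSE, trim = TRUE),
                    df$gene_id, 0L, strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a repeat annotation set
#'
#' @param elements data frame with columns \code{family}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open) and optional \code{strand}.
#' @return object of class \code{repeat_annotation}.
#' @export
repeat_annotation <- function(elements) {
  elements <- as.data.frame(elements, stringsAsFactors = FALSE)
  required <- c("family", "chrom", "start", "end")
  missing_cols <- setdiff(required, names(elements))
  if (length(missing_cols) > 0) {
    stop("repeat annotation is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"strand" %in% names(elements)) {
    elements$strand <- rep(".", nrow(elements))
  }
  elements <- elements[, c("family", "chrom", "start", "end", "strand")]
  elements$family <- as.character(elements$family)
  elements$chrom <- as.character(elements$chrom)
  if (nrow(elements) > 0 && any(!nzchar(elements$family))) {
    stop("empty repeat family name")
  }
  validate_intervals(elements$chrom, elements$start, elements$end)
  rownames(elements) <- NULL
  structure(elements, class = c("repeat_annotation", "data.frame"))
}

#' @export
print.repeat_annotation <- function(x, ...) {
  cat("Repeat annotation set: ", nrow(x), " elements, ",
      length(unique(x$family)), " families\n", sep = "")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Read repeat annotation (UCSC rmsk TSV or BED with name column)
#'
#' The rmsk dialect is a headered TSV whose columns include \code{genoName},
#' \code{genoStart}, \code{genoEnd} and \code{repName} (coordinates 0-based
#' half-open, as served by the UCSC table browser).  In the BED dialect the
#' name column carries the family.  One element per row; no merging.
#'
#' @param path input file.
#' @param format \code{"rmsk"} or \code{"bed"}.
#' @return a \code{\link{repeat_annotation}}.
#' @export
read_repeat_annotation <- function(path, format = c("rmsk", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "rmsk") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "")
    need <- c("genoName", "genoStart", "genoEnd", "repName")
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols) > 0) {
      stop("rmsk table is missing required column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    strand <- if ("strand" %in% names(df)) df$strand else "."
    repeat_annotation(data.frame(
      family = df$repName, chrom = df$genoName,
      start = df$genoStart, end = df$genoEnd, strand = strand,
      stringsAsFactors = FALSE))
  } else {
    scan_tabular(path, 4)
    gr <- rtracklayer::import(path, format = "BED")
    repeat_annotation(data.frame(
      family = as.character(GenomicRanges::mcols(gr)$name),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,
      end = GenomicRanges::end(gr),
      strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
      stringsAsFactors = FALSE))
  }
}

#' Write repeat annotation as a headered rmsk-style TSV
#' @param repeats a \code{repeat_annotation}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_repeat_annotation <- function(repeats, path) {
  df <- data.frame(genoName = repeats$chrom, genoStart = repeats$start,
                   genoEnd = repeats$end, repName = repeats$family,
                   strand = repeats$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Do two intervals overlap?
#'
#' Half-open semantics: \code{[0,10)} and \code{[10,20)} abut but do not
#' overlap.  Vectorised over both intervals; intervals on different
#' chromosomes never overlap.
#'
#' @param chrom_a,start_a,end_a first interval(s).
#' @param chrom_b,start_b,end_b second interval(s).
#' @return logical vector.
#' @export
interval_overlaps <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  chrom_a == chrom_b & start_a < end_b & start_b < end_a
}

#' Gene density along a chromosome
#'
#' Tiles the chromosome with half-open windows \code{[0,w), [w,2w), ...} and
#' counts each gene in the window containing its start (a start exactly at a
#' boundary falls in the following window).
#'
#' @param annotation a \code{gene_annotation}.
#' @param chrom chromosome name (must have a known length).
#' @param window_bp window size in bp (> 0).
#' @return data frame with columns \code{start}, \code{end}, \code{count}.
#' @export
gene_density <- function(annotation, chrom, window_bp) {
  stopifnot(window_bp > 0)
  lens <- chrom_lengths(annotation)
  if (!chrom %in% names(lens)) stop("unknown chromosome: ", chrom)
  len <- lens[[chrom]]
  n_win <- ceiling(len / window_bp)
  starts <- (seq_len(n_win) - 1) * window_bp
  ends <- pmin(starts + window_bp, len)
  g <- annotation[annotation$chrom == chrom, , drop = FALSE]
  counts <- tabulate(floor(g$start / window_bp) + 1, nbins = n_win)
  data.frame(start = starts, end = ends, count = counts)
}
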