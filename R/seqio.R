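# Sequence, annotation and tabular input/output; coordinate and strand
# conventions.
#
# Conventions used throughout the package:
#  - files use 1-based inclusive intervals (GFF-style);
#  - all thermodynamics operate on transcript-oriented (5'->3') sequences;
#  - start-codon-relative positions: the first nt of the start codon is +1,
#    the nt immediately 5' of it is -1; there is no position 0.

#' Read a (multi-)FASTA file of nucleotide sequences
#'
#' DNA is transparently converted to RNA (T to U) and case-folded to upper
#' case. IUPAC ambiguity codes are rejected by default because they have no
#' defined pairing energy; with `allow_ambiguity = TRUE` they are kept (such
#' positions can never pair).
#'
#' @param path path to a FASTA file.
#' @param allow_ambiguity keep IUPAC ambiguity codes instead of erroring.
#' @return a named character vector of RNA sequences (names from headers).
#' @export
read_fasta <- function(path, allow_ambiguity = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines) | grepl("^>", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1])
    stop("FASTA parse error at line ", lineno[1], ": expected '>' header")
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  if (any(ids == "")) {
    bad <- lineno[hdr][ids == ""][1]
    stop("FASTA parse error at line ", bad, ": malformed (empty) header")
  }
  rec <- cumsum(hdr)
  out <- character(sum(hdr))
  names(out) <- ids
  for (r in seq_along(out)) {
    body <- lines[rec == r & !hdr]
    if (length(body) == 0) {
      bad <- lineno[hdr][r]
      stop("FASTA parse error at line ", bad, ": empty record '", ids[r], "'")
    }
    s <- toupper(paste(body, collapse = ""))
    s <- chartr("T", "U", s)
    ok_alpha <- if (allow_ambiguity) "ACGURYSWKMBDHVN" else "ACGU"
    bad_pos <- regexpr(paste0("[^", ok_alpha, "]"), s)
    if (bad_pos > 0) {
      # locate the offending line
      off <- 0L
      for (b in which(rec == r & !hdr)) {
        off <- off + nchar(lines[b])
        if (bad_pos <= off) {
          stop("FASTA parse error at line ", lineno[b],
               ": invalid character '", substr(s, bad_pos, bad_pos),
               "' in record '", ids[r], "'")
        }
      }
    }
    out[r] <- s
  }
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

ANNOT_COLS <- c("gene_id", "contig", "start", "end", "strand", "start_codon",
                "tss", "operon_id", "operon_rank")

#' Read gene annotations (TSV dialect or GFF3)
#'
#' The TSV dialect has a header line with columns `gene_id`, `contig`,
#' `start`, `end`, `strand`, `start_codon`, `tss`, `operon_id`,
#' `operon_rank` (the last four may be `NA`). GFF3 input (via rtracklayer)
#' uses rows of any feature type carrying the same fields as attributes
#' (`gene_id` falls back to `ID`). Coordinates are 1-based inclusive genomic;
#' minus-strand genes keep genomic coordinates (orientation is resolved when
#' transcripts are built).
#'
#' @param path path to the annotation file.
#' @param format `"tsv"` or `"gff3"` (guessed from the extension by default).
#' @return a data.frame of validated annotations (class `gene_annotation`).
#' @export
read_annotations <- function(path, format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
              else "tsv"
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    missing_cols <- setdiff(setdiff(ANNOT_COLS, c("tss", "operon_id",
                                                  "operon_rank")), names(df))
    if (length(missing_cols))
      stop("annotation TSV lacks columns: ",
           paste(missing_cols, collapse = ", "))
    for (cc in c("tss", "operon_id", "operon_rank"))
      if (is.null(df[[cc]])) df[[cc]] <- NA
  } else {
    gr <- rtracklayer::import(path)
    md <- S4Vectors::mcols(gr)
    gid <- if (!is.null(md$gene_id)) md$gene_id else md$ID
    getm <- function(nm) if (!is.null(md[[nm]])) md[[nm]] else NA
    df <- data.frame(gene_id = as.character(gid),
                     contig = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     start_codon = as.integer(getm("start_codon")),
                     tss = as.integer(getm("tss")),
                     operon_id = as.character(getm("operon_id")),
                     operon_rank = as.integer(getm("operon_rank")),
                     stringsAsFactors = FALSE)
  }
  validate_annotations(df)
}

validate_annotations <- function(df) {
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$start_codon <- as.integer(df$start_codon)
  df$tss <- suppressWarnings(as.integer(df$tss))
  df$operon_rank <- suppressWarnings(as.integer(df$operon_rank))
  if (any(is.na(df$gene_id) | df$gene_id == ""))
    stop("annotation with missing gene_id")
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in annotations: ",
         df$gene_id[duplicated(df$gene_id)][1])
  if (any(df$end < df$start)) stop("annotation span is empty (end < start)")
  bad <- !df$strand %in% c("+", "-")
  if (any(bad))
    stop("strand required ('+' or '-') for gene ", df$gene_id[bad][1])
  out <- df$start_codon < df$start | df$start_codon > df$end |
    is.na(df$start_codon)
  if (any(out))
    stop("start_codon outside span for gene ", df$gene_id[out][1])
  # TSS must lie upstream of the start codon in transcript orientation
  has_tss <- !is.na(df$tss)
  up_ok <- ifelse(df$strand == "+", df$tss <= df$start_codon,
                  df$tss >= df$start_codon)
  if (any(has_tss & !up_ok))
    stop("tss downstream of start_codon for gene ",
         df$gene_id[has_tss & !up_ok][1])
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Write annotations in the package TSV dialect
#' @param annotations a data.frame as returned by [read_annotations()].
#' @param path output path.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations[, ANNOT_COLS[ANNOT_COLS %in%
                                                colnames(annotations)]],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a transcript model from an annotation and a genome
#'
#' Extracts the transcript-oriented (5'->3') sequence for a gene. If the TSS
#' is annotated, the transcript starts at the TSS and the 5'UTR length is
#' known; otherwise `utr_fallback` nt upstream of the annotated translation
#' start are used and the UTR length is flagged unknown (`NA`), following the
#' screen's search-region convention. The transcript extends to the annotated
#' gene end (or TSS-to-end for minus-strand genes, reverse-complemented).
#'
#' @param annotation a single-row annotation (or a row of the data.frame).
#' @param genome named character vector of contig sequences (RNA or DNA).
#' @param utr_fallback nt of upstream sequence when the TSS is unknown.
#' @return an object of class `transcript_model`: list with `gene_id`,
#'   `seq`, `utr_length` (NA if unknown), `start_codon_offset`, `strand`.
#' @examples
#' g <- c(chr = paste(rep("ACGU", 100), collapse = ""))
#' @export
build_transcript <- function(annotation, genome, utr_fallback = 200L) {
  a <- as.list(annotation[1, , drop = FALSE])
  if (!a$contig %in% names(genome))
    stop("contig ", a$contig, " not present in genome")
  contig <- chartr("Tt", "Uu", toupper(genome[[a$contig]]))
  clen <- nchar(contig)
  if (a$end > clen || a$start < 1) stop("span exceeds contig bounds")
  plus <- a$strand == "+"
  if (!is.na(a$tss)) {
    five <- a$tss
    utr <- abs(a$start_codon - a$tss)
  } else {
    five <- if (plus) a$start_codon - utr_fallback
            else a$start_codon + utr_fallback
    utr <- NA_integer_
    clipped <- if (plus) five < 1 else five > clen
    if (clipped) {
      warning("upstream region truncated at contig edge for gene ", a$gene_id)
      five <- if (plus) 1L else clen
    }
  }
  if (plus) {
    seq <- substr(contig, five, a$end)
    offset <- a$start_codon - five + 1L
  } else {
    seq <- revcomp_rna(substr(contig, a$start, five))
    offset <- five - a$start_codon + 1L
  }
  transcript_model(a$gene_id, seq, utr_length = utr,
                   start_codon_offset = offset, strand = a$strand)
}

#' Construct a transcript model directly
#'
#' @param gene_id gene identifier.
#' @param seq transcript-oriented RNA sequence.
#' @param utr_length 5'UTR length in nt, or `NA` when unknown.
#' @param start_codon_offset transcript-local position of the first
#'   start-codon nt (`utr_length + 1` when the UTR is known).
#' @param strand source strand (informational).
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, seq, utr_length = NA,
                             start_codon_offset = NULL, strand = "+") {
  if (is.null(start_codon_offset)) {
    if (is.na(utr_length)) stop("start_codon_offset required")
    start_codon_offset <- utr_length + 1L
  }
  if (!is.na(utr_length) && start_codon_offset != utr_length + 1L)
    stop("start_codon_offset must equal utr_length + 1 when the UTR is known")
  if (nchar(seq) < start_codon_offset)
    stop("transcript shorter than start_codon_offset")
  out <- list(gene_id = gene_id, seq = seq,
              utr_length = if (is.na(utr_length)) NA_integer_
                           else as.integer(utr_length),
              start_codon_offset = as.integer(start_codon_offset),
              strand = strand)
  class(out) <- "transcript_model"
  out
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model>", x$gene_id, "(", nchar(x$seq), "nt )",
      if (is.na(x$utr_length)) "UTR unknown"
      else paste0("UTR ", x$utr_length, " nt"),
      "; start codon at", x$start_codon_offset, "\n")
  invisible(x)
}

revcomp_rna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(
    chartr("T", "U", toupper(x)))))
}

# start-codon-relative coordinates: +1 is the first nt of the start codon,
# -1 the nt immediately 5' of it; there is no 0.
rel_from_local <- function(pos, offset) {
  ifelse(pos >= offset, pos - offset + 1L, pos - offset)
}
local_from_rel <- function(rel, offset) {
  stopifnot(all(rel != 0))
  ifelse(rel > 0, offset + rel - 1L, offset + rel)
}

#' Read a per-gene expression fold-change table
#'
#' TSV with columns `gene_id` and `fold_change` (ratio scale, mutant over
#' wild type) or, with `log2 = TRUE`, a signed `log2_fold_change` column.
#' The regulation direction is derived from the ratio (`down` for ratios
#' below 1).
#'
#' @param path path to the TSV file.
#' @param log2 interpret the value column as signed log2 fold change.
#' @return a data.frame with columns `gene_id`, `fold_change`, `direction`.
#' @export
read_expression <- function(path, log2 = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (is.null(df$gene_id)) stop("expression table lacks a gene_id column")
  if (log2) {
    if (is.null(df$log2_fold_change))
      stop("expression table lacks a log2_fold_change column")
    fc <- 2^df$log2_fold_change
  } else {
    if (is.null(df$fold_change))
      stop("expression table lacks a fold_change column")
    fc <- df$fold_change
  }
  expression_records(df$gene_id, fc)
}

expression_records <- function(gene_id, fold_change) {
  if (any(!is.finite(fold_change) | fold_change <= 0))
    stop("fold changes must be positive and finite")
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id in expression table: ",
         gene_id[duplicated(gene_id)][1])
  data.frame(gene_id = as.character(gene_id),
             fold_change = as.numeric(fold_change),
             direction = ifelse(fold_change >= 1, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Write a table with provenance comments
#'
#' Writes a TSV with a header line, preceded by `#`-prefixed comment lines.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param comments character vector of provenance comments.
#' @export
write_report <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
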