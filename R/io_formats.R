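## Readers/writers for the plain-text formats the pipeline touches.
## Internal convention: all coordinates are 0-based half-open; conversion to
## 1-based inclusive (GFF3, BLAST tabular) happens only at file boundaries.

#' Read a FASTA file
#'
#' Sequences are upper-cased; record order is preserved.  Duplicate ids and
#' empty files are errors, matching the strict-dialect policy of the package.
#'
#' @param path path to an (optionally gzipped) FASTA file.
#' @return named character vector of sequences (names = record ids) with a
#'   `descriptions` attribute carrying the remainder of each header line.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) .stopf("FASTA file is empty: %s", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    .stopf("duplicate FASTA id(s): %s", paste(unique(dup), collapse = ", "))
  out <- toupper(as.character(set))
  names(out) <- ids
  attr(out, "descriptions") <- setNames(desc, ids)
  out
}

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a FASTQ file (sequences only)
#' @param path path to a FASTQ file.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) .stopf("FASTQ file not found: %s", path)
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write reads to FASTQ with a constant quality character
#' @param reads named character vector of read sequences.
#' @param path output file path.
#' @param quality_char single character used for every base quality.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  stopifnot(is.character(reads), !is.null(names(reads)))
  set <- Biostrings::DNAStringSet(reads)
  quals <- Biostrings::BStringSet(vapply(
    nchar(reads), function(n) strrep(quality_char, n), character(1)))
  Biostrings::writeXStringSet(set, path, format = "fastq", qualities = quals)
  invisible(path)
}

## ---- gene features (GFF3) --------------------------------------------------

#' Construct a validated gene feature table
#'
#' The table is the package's internal representation of GFF3 content:
#' one row per feature, 0-based half-open coordinates.
#'
#' @param genome_id,gene_id,start,end,strand,product_label,type equal-length
#'   vectors; `type` defaults to `"gene"` (island spans use
#'   `"mobile_genetic_element"`).
#' @return data.frame with class `fgi_features`.
#' @export
gene_features <- function(genome_id, gene_id, start, end,
                          strand = "+", product_label = "hp",
                          type = "gene") {
  df <- data.frame(genome_id = as.character(genome_id),
                   gene_id = as.character(gene_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   product_label = as.character(product_label),
                   type = as.character(type),
                   stringsAsFactors = FALSE)
  if (any(df$start < 0L) || any(df$start >= df$end))
    .stopf("gene features require 0 <= start < end")
  if (!all(df$strand %in% c("+", "-")))
    .stopf("strand must be '+' or '-'")
  dup <- df[duplicated(df[, c("genome_id", "gene_id")]), "gene_id"]
  if (length(dup) > 0L)
    .stopf("duplicate gene id(s) within a genome: %s",
           paste(unique(dup), collapse = ", "))
  class(df) <- c("fgi_features", "data.frame")
  df
}

#' Write gene features to GFF3
#' @param features an `fgi_features` data.frame (see [gene_features()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = features$genome_id,
    ranges = IRanges::IRanges(start = features$start + 1L,
                              end = features$end),
    strand = features$strand)
  S4Vectors::mcols(gr)$source <- "flexgi"
  S4Vectors::mcols(gr)$type <- features$type
  S4Vectors::mcols(gr)$ID <- features$gene_id
  S4Vectors::mcols(gr)$product <- features$product_label
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene features from GFF3
#' @param path path to a GFF3 file.
#' @return an `fgi_features` data.frame (0-based half-open coordinates).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) .stopf("GFF3 file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  gene_features(
    genome_id = as.character(GenomicRanges::seqnames(gr)),
    gene_id = as.character(mc$ID),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand,
    product_label = as.character(mc$product %||% rep("hp", length(gr))),
    type = as.character(mc$type))
}

## ---- BLAST tabular ---------------------------------------------------------

.blast_cols <- c("read_id", "genome_id", "percent_identity", "align_length",
                 "mismatches", "gap_opens", "read_start", "read_end",
                 "genome_start", "genome_end", "evalue", "bitscore")

#' Read 12-column BLAST tabular alignments (outfmt 6)
#'
#' The dialect is fixed to exactly 12 tab-separated columns; lines with any
#' other column count raise an error naming the line.  An empty file yields
#' an empty table with a warning.
#'
#' @param path path to the tabular file.
#' @return data.frame with the standard outfmt-6 columns (1-based
#'   coordinates, as in the file).
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) .stopf("alignment file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    .warnf("empty alignment file: %s", path)
    df <- as.data.frame(setNames(rep(list(character(0)), 12), .blast_cols))
    return(.type_blast(df))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield != 12L)
  if (length(bad) > 0L)
    .stopf("line %d has %d columns (expected 12)", bad[1L], nfield[bad[1L]])
  mat <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- .blast_cols
  .type_blast(df)
}

.type_blast <- function(df) {
  num <- c("percent_identity", "evalue", "bitscore")
  int <- c("align_length", "mismatches", "gap_opens", "read_start",
           "read_end", "genome_start", "genome_end")
  for (cn in num) df[[cn]] <- suppressWarnings(as.numeric(df[[cn]]))
  for (cn in int) df[[cn]] <- suppressWarnings(as.integer(df[[cn]]))
  if (nrow(df) > 0L) {
    if (anyNA(df$percent_identity) || anyNA(df$align_length))
      .stopf("non-numeric identity or length field in alignment table")
    if (any(df$percent_identity < 0 | df$percent_identity > 100))
      .stopf("percent identity outside [0, 100]")
    if (any(df$align_length < 1L)) .stopf("alignment length < 1")
  }
  df
}

#' Write alignments in 12-column BLAST tabular format
#' @param alignments data.frame as returned by [read_blast_tab()] or
#'   [map_reads()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(alignments, path) {
  stopifnot(all(.blast_cols %in% names(alignments)))
  df <- alignments[, .blast_cols]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, na = "NA")
  invisible(path)
}

## ---- BED6 ------------------------------------------------------------------

#' Write island calls as BED6
#'
#' Columns: genome id, 0-based start, end, island label, score (mean
#' depletion, 0-1), strand `"."`.
#'
#' @param islands data.frame with columns `genome_id`, `start`, `end`,
#'   `locus_label` and optionally `depletion_score`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(islands, path) {
  if (nrow(islands) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  if (any(islands$start < 0L)) .stopf("negative BED start coordinate")
  if (any(islands$start >= islands$end)) .stopf("BED requires start < end")
  score <- islands$depletion_score %||% rep(0, nrow(islands))
  df <- data.frame(islands$genome_id, islands$start, islands$end,
                   islands$locus_label, signif(score, 4), ".")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file written by [write_bed()]
#' @param path path to the BED file.
#' @return data.frame with columns `genome_id`, `start`, `end`,
#'   `locus_label`, `depletion_score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) .stopf("BED file not found: %s", path)
  if (file.size(path) == 0L)
    return(data.frame(genome_id = character(0), start = integer(0),
                      end = integer(0), locus_label = character(0),
                      depletion_score = numeric(0), strand = character(0)))
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("genome_id", "start", "end", "locus_label",
                 "depletion_score", "strand")
  df
}

## ---- TSV -------------------------------------------------------------------

#' Write a table as TSV (header row, `"."` for missing values)
#' @param df data.frame or matrix.
#' @param path output file path.
#' @param row_names write row names as a leading `id` column.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, row_names = FALSE) {
  df <- as.data.frame(df)
  if (row_names) df <- cbind(id = rownames(df), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = ".")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path path to the TSV file.
#' @return data.frame (`"."` read back as `NA`).
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) .stopf("TSV file not found: %s", path)
  read.delim(path, stringsAsFactors = FALSE, na.strings = ".",
             check.names = FALSE)
}

## ---- controlled product vocabulary ----------------------------------------

#' Controlled vocabulary of gene product labels
#'
#' Closed set of labels used by the island version signatures; free-text
#' annotations are mapped onto it with [normalize_product_labels()].
#'
#' @return character vector of valid product labels.
#' @export
product_vocabulary <- function() {
  c("pstS", "pstC", "pstA", "pstB", "phoU", "phoR", "phoB", "phoX_ALP",
    "ppk", "ppx_gppA", "sixA", "wzb", "glpF", "dgk", "lpxH", "rfaG",
    "glycosyltransferase", "set_mtase",
    "phnC", "phnD", "phnE", "phnG", "phnH", "phnI", "phnJ", "phnK",
    "phnL", "phnM", "had_hydrolase", "tp", "nucleotidase_5p", "pit", "hp")
}

#' Alias table from common free-text products to controlled labels
#' @return named character vector: names are lower-cased free-text keys,
#'   values are controlled labels.
#' @export
product_alias_table <- function() {
  c("phosphate abc transporter substrate-binding protein" = "pstS",
    "phosphate abc transporter permease pstc" = "pstC",
    "phosphate abc transporter permease psta" = "pstA",
    "phosphate abc transporter atp-binding protein" = "pstB",
    "phosphate transport system regulatory protein phou" = "phoU",
    "phosphate regulon sensor histidine kinase" = "phoR",
    "phosphate regulon transcriptional regulator" = "phoB",
    "alkaline phosphatase" = "phoX_ALP",
    "polyphosphate kinase" = "ppk",
    "exopolyphosphatase" = "ppx_gppA",
    "phosphohistidine phosphatase" = "sixA",
    "protein-tyrosine phosphatase" = "wzb",
    "glycerol uptake facilitator protein" = "glpF",
    "diacylglycerol kinase" = "dgk",
    "udp-2,3-diacylglucosamine hydrolase" = "lpxH",
    "lipopolysaccharide core biosynthesis protein" = "rfaG",
    "glycosyl transferase" = "glycosyltransferase",
    "set domain methyltransferase" = "set_mtase",
    "methyltransferase" = "set_mtase",
    "phosphonate import atp-binding protein" = "phnC",
    "phosphonate-binding periplasmic protein" = "phnD",
    "phosphonate transport permease" = "phnE",
    "haloacid dehalogenase" = "had_hydrolase",
    "transmembrane protein" = "tp",
    "5'-nucleotidase" = "nucleotidase_5p",
    "low-affinity inorganic phosphate transporter" = "pit",
    "hypothetical protein" = "hp")
}

#' Map free-text product annotations onto the controlled vocabulary
#'
#' Labels already in the vocabulary pass through; other strings are looked up
#' (case-insensitively) in [product_alias_table()]; anything unresolvable
#' becomes `NA` with a warning.
#'
#' @param x character vector of product strings.
#' @return character vector of controlled labels (or `NA`).
#' @export
normalize_product_labels <- function(x) {
  vocab <- product_vocabulary()
  alias <- product_alias_table()
  out <- ifelse(x %in% vocab, x, unname(alias[tolower(trimws(x))]))
  if (anyNA(out))
    .warnf("unmapped product label(s): %s",
           paste(unique(x[is.na(out)]), collapse = ", "))
  out
}
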