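## Read recruitment against reference genomes: internal ungapped mapper,
## dual identity-tier filtering, RPKG, breadth, and presence calls.

#' Map reads against a genome with the internal seed-and-extend mapper
#'
#' Exact k-mer seeds are located on both strands via a genome index; each
#' candidate offset is evaluated by full-read ungapped comparison.  Identity
#' is `matches / read length * 100` (the full read is the denominator - the
#' simulator emits no indels, so ungapped identity is exact).  One best hit
#' per read is reported: highest identity, ties broken toward the lowest
#' genome coordinate, then the forward strand.  Hits below `min_identity`
#' are discarded.  Real-data users can substitute 12-column BLAST tabular
#' input via [read_blast_tab()].
#'
#' @param reads named character vector of read sequences.
#' @param genome single genome sequence (character) or a one-element named
#'   character vector.
#' @param k exact seed length (must not exceed the shortest read).
#' @param min_identity minimum percent identity to report.
#' @param genome_id id used in the output table.
#' @param both_strands also search the reverse complement of each read.
#' @return data.frame in 12-column BLAST tabular layout (1-based
#'   coordinates; `genome_start > genome_end` on minus-strand hits; `evalue`
#'   is `NA` - the internal mapper does not compute one).
#' @export
map_reads <- function(reads, genome, k = 15L, min_identity = 70,
                      genome_id = names(genome) %||% "genome",
                      both_strands = TRUE) {
  stopifnot(is.character(reads), length(genome) == 1L)
  if (length(reads) == 0L) return(.empty_alignments())
  if (k > min(nchar(reads))) .stopf("seed length k exceeds a read length")
  hits <- map_reads_cpp(toupper(as.character(genome)),
                        toupper(unname(reads)), as.integer(k),
                        min_identity, both_strands)
  n <- length(hits$read_index)
  if (n == 0L) return(.empty_alignments())
  len <- hits$read_length
  minus <- hits$strand == "-"
  sstart <- ifelse(minus, hits$pos0 + len, hits$pos0 + 1L)
  send <- ifelse(minus, hits$pos0 + 1L, hits$pos0 + len)
  ids <- names(reads) %||% as.character(seq_along(reads))
  data.frame(
    read_id = ids[hits$read_index],
    genome_id = genome_id,
    percent_identity = 100 * hits$matches / len,
    align_length = len,
    mismatches = len - hits$matches,
    gap_opens = 0L,
    read_start = 1L, read_end = len,
    genome_start = as.integer(sstart), genome_end = as.integer(send),
    evalue = NA_real_, bitscore = 2 * hits$matches,
    stringsAsFactors = FALSE)
}

.empty_alignments <- function() {
  data.frame(read_id = character(0), genome_id = character(0),
             percent_identity = numeric(0), align_length = integer(0),
             mismatches = integer(0), gap_opens = integer(0),
             read_start = integer(0), read_end = integer(0),
             genome_start = integer(0), genome_end = integer(0),
             evalue = numeric(0), bitscore = numeric(0),
             stringsAsFactors = FALSE)
}

#' Filter alignments at one of the two identity tiers
#'
#' The species tier keeps alignments with length at least 50 nt and
#' identity at least 98% (and e-value at most 1e-5 where the e-value field
#' is populated); the permissive tier keeps length at least 50 nt and
#' identity at least 70%.  All thresholds are inclusive.
#'
#' @param alignments BLAST-tabular-style data.frame.
#' @param tier `"species"` or `"permissive"`.
#' @return filtered data.frame.
#' @export
filter_alignments <- function(alignments, tier = c("species", "permissive")) {
  tier <- match.arg(tier)
  keep <- alignments$align_length >= 50L
  if (tier == "species") {
    keep <- keep & alignments$percent_identity >= 98 &
      (is.na(alignments$evalue) | alignments$evalue <= 1e-5)
  } else {
    keep <- keep & alignments$percent_identity >= 70
  }
  alignments[keep, , drop = FALSE]
}

#' RPKG: reads per kb of genome per Gb of metagenome
#' @param n_reads species-tier recruited read count.
#' @param genome_length genome length in nt (> 0).
#' @param metagenome_size metagenome size in bp - the total bases of the
#'   read set, not the read count (> 0).
#' @return RPKG value.
#' @export
compute_rpkg <- function(n_reads, genome_length, metagenome_size) {
  .check_scalar_number(n_reads, "n_reads", min = 0)
  .check_scalar_number(genome_length, "genome_length", min = 0,
                       strict_min = TRUE)
  .check_scalar_number(metagenome_size, "metagenome_size", min = 0,
                       strict_min = TRUE)
  n_reads / (genome_length / 1e3) / (metagenome_size / 1e9)
}

#' Per-position depth and breadth from filtered alignments
#'
#' @param alignments alignments already filtered to a single tier.
#' @param genome_length genome length in nt.
#' @return list with `depth` (integer vector of length `genome_length`) and
#'   `breadth` (fraction of positions with depth >= 1).  Alignments
#'   extending beyond the genome end are an error.
#' @export
coverage_profile <- function(alignments, genome_length) {
  s <- pmin(alignments$genome_start, alignments$genome_end) - 1L
  e <- pmax(alignments$genome_start, alignments$genome_end)
  depth <- interval_depth_cpp(as.integer(s), as.integer(e),
                              as.integer(genome_length))
  list(depth = depth, breadth = mean(depth > 0L))
}

#' Full recruitment profile of one genome in one metagenome
#'
#' Maps (or ingests) alignments, filters at both identity tiers, and
#' assembles per-position depth at the species (>= 98%) and permissive
#' (>= 70%) tiers, the species-tier read count, RPKG, and breadth.
#'
#' @param reads named character vector of reads, or `NULL` when
#'   `alignments` is supplied.
#' @param genome genome sequence (required when mapping internally; for
#'   precomputed alignments `genome_length` suffices).
#' @param genome_id,sample_id identifiers recorded in the profile.
#' @param metagenome_size total bp of the metagenome; defaults to
#'   `sum(nchar(reads))`.
#' @param alignments optional precomputed 12-column tabular alignments
#'   (bypasses the internal mapper).
#' @param genome_length required with `alignments`; otherwise
#'   `nchar(genome)`.
#' @param k seed length of the internal mapper.
#' @return list of class `fgi_recruitment_profile`.
#' @export
recruitment_profile <- function(reads = NULL, genome = NULL,
                                genome_id = "genome", sample_id = "sample",
                                metagenome_size = NULL, alignments = NULL,
                                genome_length = NULL, k = 15L) {
  if (is.null(alignments)) {
    stopifnot(!is.null(reads), !is.null(genome))
    genome_length <- nchar(genome)
    alignments <- map_reads(reads, genome, k = k, min_identity = 70,
                            genome_id = genome_id)
    metagenome_size <- metagenome_size %||% sum(nchar(reads))
  } else {
    if (is.null(genome_length))
      genome_length <- if (!is.null(genome)) nchar(genome) else
        .stopf("genome_length required with precomputed alignments")
    if (is.null(metagenome_size))
      .stopf("metagenome_size required with precomputed alignments")
  }
  sp <- filter_alignments(alignments, "species")
  pm <- filter_alignments(alignments, "permissive")
  cov98 <- coverage_profile(sp, genome_length)
  cov70 <- coverage_profile(pm, genome_length)
  structure(list(
    genome_id = genome_id, sample_id = sample_id,
    genome_length = genome_length,
    depth98 = cov98$depth, depth70 = cov70$depth,
    n_reads98 = nrow(sp),
    rpkg = compute_rpkg(nrow(sp), genome_length, metagenome_size),
    breadth98 = cov98$breadth, breadth70 = cov70$breadth,
    metagenome_size = metagenome_size),
    class = "fgi_recruitment_profile")
}

#' @export
print.fgi_recruitment_profile <- function(x, ...) {
  cat(sprintf(
    "<recruitment profile> %s in %s: %d reads (98%% tier), RPKG %.2f, breadth %.3f\n",
    x$genome_id, x$sample_id, x$n_reads98, x$rpkg, x$breadth98))
  invisible(x)
}

#' Presence call for a genome in a metagenome
#'
#' A genome is present when RPKG is at least `min_rpkg` and species-tier
#' breadth at least `min_breadth` (both inclusive).  Breadth - the fraction of positions
#' covered by at least one read - is the operational reading of "genome
#' coverage" here.
#'
#' @param profile an `fgi_recruitment_profile`.
#' @param min_rpkg,min_breadth presence thresholds.
#' @return list with `genome_id`, `sample_id`, `present`, `rpkg`,
#'   `breadth98`.
#' @export
call_presence <- function(profile, min_rpkg = 10, min_breadth = 0.60) {
  stopifnot(inherits(profile, "fgi_recruitment_profile"))
  list(genome_id = profile$genome_id, sample_id = profile$sample_id,
       present = profile$rpkg >= min_rpkg &&
         profile$breadth98 >= min_breadth,
       rpkg = profile$rpkg, breadth98 = profile$breadth98)
}
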