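## Gene-content typing of flexible genomic islands, marker-protein
## clustering, and island-versus-genome AAI.

PST_CORE <- c("pstS", "pstC", "pstA", "pstB", "phoU")

# full inventory of the longest phosphate island version (19 genes)
FGIP_FULL <- c(PST_CORE, "phoR", "phoB", "phoX_ALP", "ppk", "ppx_gppA",
               "sixA", "glpF", "dgk", "glycosyltransferase", "lpxH", "rfaG",
               "set_mtase", "wzb", "hp")

CP_LYASE <- c("phnG", "phnH", "phnI", "phnJ", "phnK", "phnL", "phnM")
PHN_TRANSPORTER <- c("phnC", "phnD", "phnE")

#' Built-in island version signatures
#'
#' Gene-content signatures for the phosphate island versions (fGIp A-H) and
#' phosphonate island versions (fGIphn A-D).  Each signature has a set of
#' required product labels and a (possibly empty) set of forbidden labels
#' that disqualify the assignment.  Every fGIp signature contains the pst
#' operon core (pstSCAB-phoU); every fGIphn signature contains the C-P lyase
#' genes it retains.  The table can be overridden by passing a custom list
#' to [assign_version()].
#'
#' @param island_class `"fGIp"` or `"fGIphn"`.
#' @return named list of signatures; each element is a list with `label`,
#'   `required` and `forbidden` character vectors.
#' @export
fgi_signatures <- function(island_class = c("fGIp", "fGIphn")) {
  island_class <- match.arg(island_class)
  sig <- function(label, required, forbidden = character(0)) {
    list(label = label, required = required, forbidden = forbidden)
  }
  if (island_class == "fGIp") {
    sigs <- list(
      A = sig("A", c(PST_CORE, "set_mtase"), forbidden = c("phoR", "phoB")),
      B = sig("B", c(PST_CORE, "wzb", "phoR", "phoB"),
              forbidden = "set_mtase"),
      C = sig("C", FGIP_FULL),
      D = sig("D", setdiff(FGIP_FULL, c("phoX_ALP", "hp")),
              forbidden = "phoX_ALP"),
      E = sig("E", setdiff(FGIP_FULL, c("glpF", "hp")), forbidden = "glpF"),
      F = sig("F", c(PST_CORE, "phoR", "phoB")),
      G = sig("G", c(PST_CORE, "phoR", "phoB", "glycosyltransferase")),
      H = sig("H", setdiff(FGIP_FULL, c("set_mtase", "dgk", "phoX_ALP")),
              forbidden = c("set_mtase", "dgk", "phoX_ALP")))
  } else {
    sigs <- list(
      A = sig("A", c(CP_LYASE, PHN_TRANSPORTER, "set_mtase",
                     "had_hydrolase", "tp", "nucleotidase_5p")),
      B = sig("B", c(setdiff(CP_LYASE, "phnG"), PHN_TRANSPORTER),
              forbidden = "phnG"),
      C = sig("C", c(CP_LYASE, PHN_TRANSPORTER)),
      D = sig("D", CP_LYASE, forbidden = PHN_TRANSPORTER))
  }
  for (s in sigs) {
    if (length(intersect(s$required, s$forbidden)) > 0L)
      .stopf("signature %s: required and forbidden sets overlap", s$label)
  }
  sigs
}

# genes that must be present for an island to count as a complete
# (typeable) member of the class
.class_core <- function(island_class) {
  if (island_class == "fGIp") PST_CORE else setdiff(CP_LYASE, "phnG")
}

#' Genes of an island
#'
#' Returns the gene features whose span overlaps the island interval by at
#' least half of the gene length.
#'
#' @param island one-row data.frame (or list) with `genome_id`, `start`,
#'   `end` (0-based half-open).
#' @param features an `fgi_features` table (see [gene_features()]).
#' @return subset of `features`.
#' @export
extract_island_genes <- function(island, features) {
  f <- features[features$genome_id == island$genome_id &
                  features$type == "gene", , drop = FALSE]
  if (nrow(f) == 0L) return(f)
  ov <- pmin(f$end, island$end) - pmax(f$start, island$start)
  f[ov >= 0.5 * (f$end - f$start), , drop = FALSE]
}

#' Assign an observed island to a version signature
#'
#' Each signature is scored as the fraction of its required genes present in
#' the island; any forbidden gene disqualifies the signature.  The winner is
#' the highest-scoring signature, ties broken toward the larger required
#' set.  Islands whose best score falls below `min_score`, or that lack the
#' class core (pst operon for fGIp, C-P lyase for fGIphn), are labelled
#' `"unassigned"` - this accommodates partial islands from incomplete
#' single-amplified genomes.
#'
#' @param genes character vector of controlled product labels observed in
#'   the island (or an `fgi_features` subset, from which `product_label` is
#'   taken).
#' @param island_class `"fGIp"` or `"fGIphn"`.
#' @param signatures signature list, defaulting to
#'   [fgi_signatures()]`(island_class)`.
#' @param min_score minimum winning score for a confident label.
#' @return list with `label`, `score`, and the per-signature `scores`.
#' @export
assign_version <- function(genes, island_class = c("fGIp", "fGIphn"),
                           signatures = NULL, min_score = 0.8) {
  island_class <- match.arg(island_class)
  if (is.data.frame(genes)) genes <- genes$product_label
  genes <- unique(as.character(genes))
  signatures <- signatures %||% fgi_signatures(island_class)
  scores <- vapply(signatures, function(s) {
    if (length(intersect(genes, s$forbidden)) > 0L) return(0)
    length(intersect(genes, s$required)) / length(s$required)
  }, numeric(1))
  sizes <- vapply(signatures, function(s) length(s$required), integer(1))
  best <- which(scores == max(scores))
  if (length(best) > 1L) best <- best[which.max(sizes[best])]
  label <- signatures[[best]]$label
  core_ok <- all(.class_core(island_class) %in% genes)
  if (scores[best] < min_score || !core_ok) label <- "unassigned"
  list(label = label, score = unname(scores[best]), scores = scores)
}

#' Diagnostic genes per version signature
#'
#' A gene is diagnostic for a version when it is required by that version
#' and absent from the required set of every other version of the class.
#' Versions without any diagnostic gene fall back to their full island
#' sequence for abundance quantification.
#'
#' @param signatures signature list (see [fgi_signatures()]).
#' @return named list of character vectors (possibly empty).
#' @export
diagnostic_genes <- function(signatures) {
  labs <- names(signatures)
  out <- lapply(labs, function(l) {
    others <- unlist(lapply(signatures[setdiff(labs, l)],
                            function(s) s$required))
    setdiff(signatures[[l]]$required, others)
  })
  names(out) <- labs
  out
}

## ---- protein comparison ----------------------------------------------------

# identity-style substitution matrix over the amino-acid alphabet
.aa_submat <- function(match = 2, mismatch = -1) {
  letters <- c(Biostrings::AA_ALPHABET, "*")
  letters <- unique(letters)
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  m
}

# global-alignment identity and shorter-sequence coverage of one query
# against a set of subjects
.align_stats <- function(query, subjects, submat) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(subjects),
    subject = Biostrings::AAString(query),
    type = "global", substitutionMatrix = submat,
    gapOpening = 10, gapExtension = 0.5)
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  cols <- nm + nmm
  minlen <- pmin(nchar(subjects), nchar(query))
  list(identity = ifelse(cols > 0, 100 * nm / cols, 0),
       coverage = ifelse(minlen > 0, cols / minlen, 0))
}

#' Average amino-acid identity between two protein sets
#'
#' All-versus-all global alignment; pairs qualify at identity >= 30% and
#' coverage of the shorter sequence >= 70%; AAI is the mean identity over
#' bidirectional best-hit (BBH) pairs.
#'
#' @param set_a,set_b named character vectors of amino-acid sequences.
#' @param set_a_id,set_b_id identifiers used in the result.
#' @param min_identity,min_coverage qualification thresholds.
#' @return list with `set_a_id`, `set_b_id`, `aai` (NA if no BBH pair),
#'   `n_bbh`, and the BBH `pairs` data.frame.
#' @export
compute_aai <- function(set_a, set_b, set_a_id = "A", set_b_id = "B",
                        min_identity = 30, min_coverage = 0.7) {
  if (length(set_a) == 0L || length(set_b) == 0L)
    .stopf("protein sets must be non-empty")
  submat <- .aa_submat()
  na <- length(set_a); nb <- length(set_b)
  ident <- matrix(0, na, nb)
  cover <- matrix(0, na, nb)
  for (i in seq_len(na)) {
    st <- .align_stats(set_a[[i]], set_b, submat)
    ident[i, ] <- st$identity
    cover[i, ] <- st$coverage
  }
  qual <- ident >= min_identity & cover >= min_coverage
  score <- ifelse(qual, ident, -Inf)
  best_ab <- apply(score, 1L, function(r) if (all(r == -Inf)) NA_integer_ else which.max(r))
  best_ba <- apply(score, 2L, function(cl) if (all(cl == -Inf)) NA_integer_ else which.max(cl))
  pa <- integer(0); pb <- integer(0)
  for (i in seq_len(na)) {
    j <- best_ab[i]
    if (!is.na(j) && !is.na(best_ba[j]) && best_ba[j] == i) {
      pa <- c(pa, i); pb <- c(pb, j)
    }
  }
  if (length(pa) == 0L) {
    return(list(set_a_id = set_a_id, set_b_id = set_b_id, aai = NA_real_,
                n_bbh = 0L, pairs = NULL))
  }
  pairs <- data.frame(protein_a = names(set_a)[pa] %||% pa,
                      protein_b = names(set_b)[pb] %||% pb,
                      identity = ident[cbind(pa, pb)])
  list(set_a_id = set_a_id, set_b_id = set_b_id,
       aai = mean(pairs$identity), n_bbh = nrow(pairs), pairs = pairs)
}

#' Cluster concatenated PstSCA marker proteins
#'
#' Concatenates the PstS, PstC and PstA subunits (in that fixed order) per
#' genome, deduplicates at 100% identity, computes pairwise p-distances from
#' global alignments, emits a neighbor-joining tree (newick) and flat
#' clusters by complete linkage at `cut`.
#'
#' @param proteins named list; each element is a named character vector that
#'   must contain entries `pstS`, `pstC`, `pstA` (genomes missing a subunit
#'   are skipped with a warning).
#' @param cut complete-linkage distance cut for flat clusters.
#' @return list with `identity_clusters` (members per unique sequence),
#'   `flat_clusters` (named integer vector), `tree_newick`, `distances`.
#' @export
cluster_marker_sequences <- function(proteins, cut = 0.05) {
  subunits <- c("pstS", "pstC", "pstA")
  keep <- vapply(proteins, function(p) all(subunits %in% names(p)),
                 logical(1))
  if (any(!keep))
    .warnf("genomes missing a PstSCA subunit skipped: %s",
           paste(names(proteins)[!keep], collapse = ", "))
  proteins <- proteins[keep]
  if (length(proteins) == 0L) .stopf("no genome with all PstSCA subunits")
  for (p in proteins) {
    if (any(nchar(p[subunits]) == 0L))
      .stopf("length-zero marker sequence")
  }
  concat <- vapply(proteins, function(p)
    paste(p[subunits], collapse = ""), character(1))

  uniq <- unique(concat)
  rep_ids <- names(concat)[match(uniq, concat)]
  identity_clusters <- lapply(uniq, function(u) names(concat)[concat == u])
  names(identity_clusters) <- rep_ids

  n <- length(uniq)
  D <- matrix(0, n, n, dimnames = list(rep_ids, rep_ids))
  if (n > 1L) {
    submat <- .aa_submat()
    for (i in seq_len(n - 1L)) {
      st <- .align_stats(uniq[i], uniq[(i + 1L):n], submat)
      pd <- 1 - st$identity / 100
      D[i, (i + 1L):n] <- pd
      D[(i + 1L):n, i] <- pd
    }
  }
  tree_newick <- if (n == 1L) {
    paste0("(", rep_ids, ");")
  } else if (n == 2L) {
    d <- D[1, 2] / 2
    sprintf("(%s:%g,%s:%g);", rep_ids[1], d, rep_ids[2], d)
  } else {
    ape::write.tree(ape::nj(stats::as.dist(D)))
  }
  flat <- if (n == 1L) setNames(1L, rep_ids) else {
    hc <- stats::hclust(stats::as.dist(D), method = "complete")
    stats::cutree(hc, h = cut)
  }
  # propagate flat cluster ids to all genomes through the dedup map
  flat_all <- setNames(flat[match(concat, uniq)], names(concat))
  list(identity_clusters = identity_clusters, flat_clusters = flat_all,
       tree_newick = tree_newick, distances = D)
}

#' Paired island-versus-genome AAI table
#'
#' Assembles the per-version pairs of (island AAI, genome AAI) that feed the
#' Wilcoxon signed-rank test of island conservation against genome-wide
#' divergence.
#'
#' @param versions character vector of version labels.
#' @param island_aai,genome_aai numeric vectors of the same length.
#' @return data.frame with columns `version`, `island_aai`, `genome_aai`.
#' @export
island_vs_genome_aai <- function(versions, island_aai, genome_aai) {
  n <- length(versions)
  if (n < 2L) .stopf("need at least 2 version pairs")
  if (length(island_aai) != n || length(genome_aai) != n)
    .stopf("versions, island_aai and genome_aai must have equal length")
  if (n < 5L)
    .warnf("fewer than 5 version pairs; signed-rank test will be weak")
  data.frame(version = versions, island_aai = island_aai,
             genome_aai = genome_aai, stringsAsFactors = FALSE)
}
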