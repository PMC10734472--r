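## Fragment-based ANI, greedy dereplication, and genomospecies assignment
## from ANI clusters plus sample-distribution patterns.

#' Fragment-based average nucleotide identity
#'
#' The query is cut into consecutive non-overlapping fragments of
#' `fragment_length` nt (a trailing partial fragment is dropped); each
#' fragment is placed on the subject with the internal ungapped mapper at
#' permissive settings; identity and aligned fraction are taken over the
#' best local segment of the placement (the part a gapped aligner would
#' report), so fragments that are only partially homologous - e.g.
#' straddling an island boundary - fail the coverage filter just as they
#' would under BLAST.  A fragment is accepted when its segment identity is
#' at least `min_identity` percent and the segment covers at least
#' `min_aligned` of the fragment.  ANI is the mean identity of accepted
#' fragments; `NA` if none is accepted.
#'
#' @param query,subject genome sequences (single character strings or
#'   one-element named vectors).
#' @param fragment_length fragment size in nt (ANIb convention: 1020).
#' @param min_identity,min_aligned fragment acceptance thresholds.
#' @param k seed length of the internal mapper.
#' @param query_id,subject_id identifiers in the result.
#' @return list with `query_id`, `subject_id`, `ani`, `aligned_fraction`,
#'   `n_fragments`.
#' @export
compute_ani <- function(query, subject, fragment_length = 1020L,
                        min_identity = 30, min_aligned = 0.7, k = 15L,
                        query_id = names(query) %||% "query",
                        subject_id = names(subject) %||% "subject") {
  query <- as.character(query); subject <- as.character(subject)
  if (nchar(query) < fragment_length || nchar(subject) < fragment_length)
    .stopf("both genomes must be at least one fragment (%d nt) long",
           fragment_length)
  starts <- seq.int(1L, nchar(query) - fragment_length + 1L,
                    by = fragment_length)
  frags <- substring(query, starts, starts + fragment_length - 1L)
  hits <- map_reads_cpp(toupper(subject), toupper(frags), as.integer(k),
                        0, TRUE)
  ident <- 100 * hits$segment_matches / pmax(1L, hits$segment_length)
  frac <- hits$segment_length / hits$read_length
  accepted <- ident[ident >= min_identity & frac >= min_aligned]
  list(query_id = query_id, subject_id = subject_id,
       ani = if (length(accepted) == 0L) NA_real_ else mean(accepted),
       aligned_fraction = length(accepted) / length(frags),
       n_fragments = length(frags))
}

#' Symmetric pairwise ANI matrix
#'
#' Computes ANI in both directions for every pair and averages them
#' (directional ANI differs slightly through fragment phasing); the
#' diagonal is exactly 100.
#'
#' @param genomes named character vector of genome sequences.
#' @param ... passed to [compute_ani()].
#' @return numeric matrix with genome ids as dimnames; unalignable pairs
#'   are `NA`.
#' @export
ani_matrix <- function(genomes, ...) {
  ids <- names(genomes)
  n <- length(ids)
  M <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(M) <- 100
  if (n < 2L) return(M)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- compute_ani(genomes[[i]], genomes[[j]],
                     query_id = ids[i], subject_id = ids[j], ...)$ani
    b <- compute_ani(genomes[[j]], genomes[[i]],
                     query_id = ids[j], subject_id = ids[i], ...)$ani
    M[i, j] <- M[j, i] <- mean(c(a, b), na.rm = TRUE)
  }
  M[is.nan(M)] <- NA_real_
  M
}

# single-linkage components from a similarity matrix at >= / > threshold
.similarity_components <- function(M, threshold, strict = FALSE) {
  n <- nrow(M)
  edges <- which(if (strict) M > threshold else M >= threshold,
                 arr.ind = TRUE)
  edges <- edges[edges[, 1L] < edges[, 2L], , drop = FALSE]
  .union_find(n, edges)
}

#' Dereplicate genomes at an ANI threshold
#'
#' Single-linkage components at ANI strictly above `ani_threshold`; the
#' representative of each component is the member with the greatest
#' ungapped length (completeness proxy), ties broken toward the
#' lexicographically smallest id.
#'
#' @param genomes named character vector of genome sequences.
#' @param ani_threshold clustering threshold (default 99; strict `>`).
#' @param ani optional precomputed symmetric ANI matrix.
#' @return list with `representatives` (character vector of ids) and
#'   `membership` (named character vector mapping every genome to its
#'   representative).
#' @export
dereplicate <- function(genomes, ani_threshold = 99, ani = NULL) {
  ids <- names(genomes)
  if (is.null(ani)) ani <- ani_matrix(genomes)
  ani <- ani[ids, ids, drop = FALSE]
  ani[is.na(ani)] <- -Inf
  comp <- .similarity_components(ani, ani_threshold, strict = TRUE)
  ungapped <- vapply(genomes, function(g)
    nchar(gsub("[-N]", "", g)), integer(1))
  reps <- character(length(ids))
  for (cid in unique(comp)) {
    members <- ids[comp == cid]
    best <- members[order(-ungapped[members], members)][1L]
    reps[comp == cid] <- best
  }
  list(representatives = sort(unique(reps)),
       membership = setNames(reps, ids))
}

#' Assign genomes to genomospecies (ecogenomic units)
#'
#' Species clusters are single-linkage components at ANI >=
#' `species_threshold`.  Within each cluster, genomes are grouped by their
#' ecological distribution: complete-linkage clustering on
#' `1 - Spearman correlation` of RPKG profiles across samples, cut so that
#' every within-group correlation is at least `cor_threshold`.  Each
#' (species cluster, distribution group) pair is one genomospecies,
#' labelled `GS<cluster>.<letter>`.  Genomes present in no sample are
#' labelled `"unclassified"` - without recruitment there is no
#' distribution to type.
#'
#' @param ani symmetric ANI matrix over the genomes.
#' @param rpkg genomes x samples RPKG matrix.
#' @param presence optional logical genomes x samples presence matrix;
#'   defaults to `rpkg > 0`.
#' @param species_threshold ANI species boundary (default 95, inclusive).
#' @param cor_threshold minimum within-group Spearman correlation.
#' @return data.frame with `genome_id`, `species_cluster`,
#'   `genomospecies`.
#' @export
assign_genomospecies <- function(ani, rpkg, presence = NULL,
                                 species_threshold = 95,
                                 cor_threshold = 0.7) {
  if (is.null(rpkg) || length(rpkg) == 0L) .stopf("empty RPKG matrix")
  ids <- rownames(ani)
  rpkg <- rpkg[ids, , drop = FALSE]
  presence <- presence %||% (rpkg > 0)
  ani2 <- ani; ani2[is.na(ani2)] <- -Inf
  comp <- .similarity_components(ani2, species_threshold, strict = FALSE)
  classified <- rowSums(presence) > 0L

  species_cluster <- paste0("GS", comp)
  genomosp <- rep("unclassified", length(ids))
  for (cid in unique(comp)) {
    members <- which(comp == cid & classified)
    if (length(members) == 0L) next
    if (length(members) == 1L || ncol(rpkg) < 3L) {
      genomosp[members] <- paste0("GS", cid, ".A")
      next
    }
    cm <- suppressWarnings(
      cor(t(rpkg[members, , drop = FALSE]), method = "spearman"))
    cm[is.na(cm)] <- 0
    d <- stats::as.dist(1 - cm)
    if (length(members) == 2L) {
      grp <- if (cm[1L, 2L] >= cor_threshold) c(1L, 1L) else c(1L, 2L)
    } else {
      hc <- stats::hclust(d, method = "complete")
      grp <- stats::cutree(hc, h = 1 - cor_threshold)
    }
    genomosp[members] <- paste0("GS", cid, ".", LETTERS[grp])
  }
  data.frame(genome_id = ids, species_cluster = species_cluster,
             genomospecies = genomosp, stringsAsFactors = FALSE)
}
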