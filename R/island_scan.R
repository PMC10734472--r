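## Metagenomic island delimitation from dual-tier recruitment profiles and
## conserved-vs-variable classification across samples.

#' Island scan parameters
#'
#' Operational parameters for coverage-depletion island detection.  The
#' source method delimits islands visually from recruitment plots; these
#' six parameters make that call reproducible: windows of `window` nt every
#' `step` nt are flagged when their mean species-tier depth falls below
#' `depletion_alpha` times the genome-wide median window depth, flagged
#' windows are merged across gaps up to `bridge_gap` nt, merged intervals
#' shorter than `min_island_length` are dropped, and `presence_beta` is the
#' fraction of the median depth above which a non-flagged sample counts as
#' carrying the island region in its population.
#'
#' @param window,step sliding-window size and step (nt; `step <= window`).
#' @param depletion_alpha depletion threshold as a fraction of the median.
#' @param bridge_gap maximum unflagged gap bridged when merging (nt).
#' @param min_island_length minimum reported island length (nt).
#' @param presence_beta population-presence threshold
#'   (`0 < depletion_alpha < presence_beta <= 1`).
#' @return validated list of class `fgi_scan_params`.
#' @export
scan_params <- function(window = 1000L, step = 500L, depletion_alpha = 0.2,
                        bridge_gap = 2000L, min_island_length = 5000L,
                        presence_beta = 0.5) {
  p <- list(window = as.integer(window), step = as.integer(step),
            depletion_alpha = depletion_alpha,
            bridge_gap = as.integer(bridge_gap),
            min_island_length = as.integer(min_island_length),
            presence_beta = presence_beta)
  if (p$step > p$window) .stopf("step must be <= window")
  if (!(p$depletion_alpha > 0 && p$depletion_alpha < p$presence_beta &&
        p$presence_beta <= 1))
    .stopf("need 0 < depletion_alpha < presence_beta <= 1")
  class(p) <- c("fgi_scan_params", "list")
  p
}

# mean depth per sliding window via cumulative sums
.window_means <- function(depth, window, step) {
  L <- length(depth)
  starts <- seq.int(0L, max(0L, L - window), by = step)
  cs <- c(0, cumsum(as.numeric(depth)))
  means <- (cs[starts + window + 1L] - cs[starts + 1L]) / window
  data.frame(start = starts, end = starts + window, mean_depth = means)
}

#' Detect coverage-depletion islands in one recruitment profile
#'
#' Flags sliding windows whose mean species-tier depth is below
#' `depletion_alpha` times the median window depth, merges them (bridging
#' gaps up to `bridge_gap`), and drops merged intervals shorter than
#' `min_island_length`.  The genome must be present in the sample per
#' [call_presence()] - islands are depletions relative to a well-recruited
#' genome, not absolute coverage gaps.
#'
#' @param profile an `fgi_recruitment_profile`.
#' @param params an `fgi_scan_params` list.
#' @return data.frame of candidate intervals with `start`, `end` (0-based
#'   half-open), `depletion_score` (`1 - mean island depth / median window
#'   depth`, clamped to `[0, 1]`), `mean_depth98`, `mean_depth70`.
#' @export
detect_islands <- function(profile, params = scan_params()) {
  stopifnot(inherits(profile, "fgi_recruitment_profile"),
            inherits(params, "fgi_scan_params"))
  if (!call_presence(profile)$present)
    .stopf("genome %s is absent from sample %s; skip island detection",
           profile$genome_id, profile$sample_id)
  wm <- .window_means(profile$depth98, params$window, params$step)
  m <- median(wm$mean_depth)
  flagged <- wm[wm$mean_depth < params$depletion_alpha * m, , drop = FALSE]
  merged <- .merge_intervals(flagged$start, flagged$end,
                             bridge = params$bridge_gap)
  merged <- merged[merged$end - merged$start >= params$min_island_length, ,
                   drop = FALSE]
  if (nrow(merged) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      depletion_score = numeric(0),
                      mean_depth98 = numeric(0), mean_depth70 = numeric(0)))
  }
  merged$mean_depth98 <- vapply(seq_len(nrow(merged)), function(i)
    mean(profile$depth98[(merged$start[i] + 1L):merged$end[i]]), numeric(1))
  merged$mean_depth70 <- vapply(seq_len(nrow(merged)), function(i)
    mean(profile$depth70[(merged$start[i] + 1L):merged$end[i]]), numeric(1))
  merged$depletion_score <- pmin(1, pmax(0, 1 - merged$mean_depth98 / m))
  rownames(merged) <- NULL
  merged[, c("start", "end", "depletion_score", "mean_depth98",
             "mean_depth70")]
}

# reciprocal overlap fraction of two 0-based half-open intervals
.reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- max(0L, min(e1, e2) - max(s1, s2))
  min(ov / (e1 - s1), ov / (e2 - s2))
}

#' Unify per-sample candidates into island loci and classify them
#'
#' Candidate intervals overlapping reciprocally by at least 50% across
#' samples are unified into one locus.  A locus is flagged in a sample when
#' a candidate overlaps it there; it is `conserved` when flagged in every
#' sample where the genome is present and `variable` otherwise.  For
#' variable loci, a non-flagged present sample additionally reports whether
#' the island region recruits at least `presence_beta` times the median
#' window depth (`population_presence`), distinguishing "region present in
#' the population" from intermediate depletion.
#'
#' @param candidates named list (by sample id) of [detect_islands()]
#'   tables; samples where the genome is absent should carry `NULL`.
#' @param profiles named list (by sample id) of `fgi_recruitment_profile`s
#'   for the same genome.
#' @param params an `fgi_scan_params` list.
#' @return data.frame of class `fgi_island_calls` with one row per locus
#'   (`genome_id`, `start`, `end`, `locus_label`, `category`,
#'   `depletion_score`) plus attributes `per_sample_flag` (matrix of
#'   `"flagged"` / `"not-flagged"` / `"genome-absent"`) and
#'   `population_presence` (logical matrix).
#' @export
classify_islands <- function(candidates, profiles, params = scan_params()) {
  samples <- names(profiles)
  present <- vapply(profiles, function(p) call_presence(p)$present,
                    logical(1))
  if (!any(present)) .stopf("genome present in no sample")
  genome_id <- profiles[[1L]]$genome_id

  pool <- list()
  for (s in samples[present]) {
    cand <- candidates[[s]]
    if (is.null(cand) || nrow(cand) == 0L) next
    for (i in seq_len(nrow(cand)))
      pool[[length(pool) + 1L]] <- list(sample = s, start = cand$start[i],
                                        end = cand$end[i],
                                        score = cand$depletion_score[i])
  }
  if (length(pool) == 0L) {
    out <- data.frame(genome_id = character(0), start = integer(0),
                      end = integer(0), locus_label = character(0),
                      category = character(0), depletion_score = numeric(0))
    class(out) <- c("fgi_island_calls", "data.frame")
    return(out)
  }
  n <- length(pool)
  edges <- matrix(integer(0), ncol = 2L)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (.reciprocal_overlap(pool[[i]]$start, pool[[i]]$end,
                            pool[[j]]$start, pool[[j]]$end) >= 0.5)
      edges <- rbind(edges, c(i, j))
  }
  comp <- .union_find(n, edges)
  loci <- lapply(sort(unique(comp)), function(cid) {
    members <- pool[comp == cid]
    list(start = min(vapply(members, `[[`, numeric(1), "start")),
         end = max(vapply(members, `[[`, numeric(1), "end")),
         score = mean(vapply(members, `[[`, numeric(1), "score")),
         samples = unique(vapply(members, `[[`, character(1), "sample")))
  })
  # enforce non-overlapping, sorted loci: merge any that still overlap
  o <- order(vapply(loci, `[[`, numeric(1), "start"))
  loci <- loci[o]
  i <- 1L
  while (i < length(loci)) {
    if (loci[[i + 1L]]$start < loci[[i]]$end) {
      loci[[i]]$end <- max(loci[[i]]$end, loci[[i + 1L]]$end)
      loci[[i]]$samples <- unique(c(loci[[i]]$samples,
                                    loci[[i + 1L]]$samples))
      loci[[i]]$score <- mean(c(loci[[i]]$score, loci[[i + 1L]]$score))
      loci <- loci[-(i + 1L)]
    } else i <- i + 1L
  }

  nl <- length(loci)
  flag <- matrix("genome-absent", nl, length(samples),
                 dimnames = list(NULL, samples))
  pop <- matrix(NA, nl, length(samples), dimnames = list(NULL, samples))
  category <- character(nl)
  for (li in seq_len(nl)) {
    loc <- loci[[li]]
    for (s in samples[present]) {
      flag[li, s] <- if (s %in% loc$samples) "flagged" else "not-flagged"
      if (flag[li, s] == "not-flagged") {
        prof <- profiles[[s]]
        wm <- .window_means(prof$depth98, params$window, params$step)
        m <- median(wm$mean_depth)
        isl_mean <- mean(prof$depth98[(loc$start + 1L):loc$end])
        pop[li, s] <- isl_mean >= params$presence_beta * m
      }
    }
    category[li] <- if (all(flag[li, samples[present]] == "flagged"))
      "conserved" else "variable"
  }
  out <- data.frame(
    genome_id = genome_id,
    start = vapply(loci, `[[`, numeric(1), "start"),
    end = vapply(loci, `[[`, numeric(1), "end"),
    locus_label = sprintf("MGI-%d", seq_len(nl)),
    category = category,
    depletion_score = vapply(loci, `[[`, numeric(1), "score"),
    stringsAsFactors = FALSE)
  attr(out, "per_sample_flag") <- flag
  attr(out, "population_presence") <- pop
  class(out) <- c("fgi_island_calls", "data.frame")
  out
}

#' Snap island boundaries to the nearest gene edges
#'
#' Window-based detection places boundaries on the window grid; border
#' genes of flexible islands are conserved, so boundaries are refined to
#' the nearest gene boundary within `search` nt: the start to the closest
#' gene end (so a partially overlapped border gene is excluded), the end to
#' the closest gene start.  Boundaries with no gene edge within range are
#' left unchanged.
#'
#' @param islands island table with `genome_id`, `start`, `end` (any extra
#'   columns are preserved).
#' @param features an `fgi_features` table.
#' @param search maximum snap distance (nt).
#' @return `islands` with refined coordinates.
#' @export
refine_boundaries <- function(islands, features, search = 2000L) {
  if (nrow(islands) == 0L) return(islands)
  for (i in seq_len(nrow(islands))) {
    f <- features[features$genome_id == islands$genome_id[i] &
                    features$type == "gene", , drop = FALSE]
    if (nrow(f) == 0L) next
    s <- islands$start[i]; e <- islands$end[i]
    cand_e <- f$end[abs(f$end - s) <= search & f$end < e]
    if (length(cand_e) > 0L) s <- cand_e[which.min(abs(cand_e - s))]
    cand_s <- f$start[abs(f$start - e) <= search & f$start > s]
    if (length(cand_s) > 0L) e <- cand_s[which.min(abs(cand_s - e))]
    if (s < e) {
      islands$start[i] <- s
      islands$end[i] <- e
    }
  }
  islands
}
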