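## Exact and nonparametric statistics tying island variants to environment:
## Wilcoxon signed-rank (exact for small n), Spearman rank correlation,
## Kruskal-Wallis with tie correction, and version-abundance profiles.

#' Wilcoxon signed-rank test (exact for small n)
#'
#' Zero differences are dropped (Wilcoxon's original prescription); ranks
#' of the absolute differences use average ranks on ties.  The statistic is
#' `T = min(W+, W-)`.  For `n_effective <= exact_limit` the two-sided
#' p-value is exact over all `2^n` sign assignments (computed by
#' convolution over the realized rank multiset, which enumerates the sign
#' distribution without materializing it); otherwise a normal approximation
#' with continuity and tie correction is used.
#'
#' @param x,y paired numeric vectors (or `x` a vector of differences when
#'   `y` is `NULL`).
#' @param exact_limit largest `n_effective` for exact enumeration.
#' @return list with `statistic` (T), `p_value`, `n_effective`, `method`,
#'   and `status` (`"ok"` or an explanation when the test is undefined).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 25L) {
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) .stopf("paired vectors of unequal length")
    x - y
  }
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, p_value = NA_real_, n_effective = 0L,
                method = "none", status = "all differences zero"))
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  T_stat <- min(w_pos, w_neg)
  if (n <= exact_limit) {
    # integer DP over doubled ranks (average ranks can be half-integers)
    r2 <- as.integer(round(2 * r))
    S2 <- sum(r2)
    f <- numeric(S2 + 1L)
    f[1L] <- 1
    for (rk in r2) {
      f[(rk + 1L):(S2 + 1L)] <- f[(rk + 1L):(S2 + 1L)] + f[1L:(S2 + 1L - rk)]
    }
    t2 <- as.integer(round(2 * T_stat))
    p <- min(1, 2 * sum(f[1L:(t2 + 1L)]) / 2^n)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (T_stat - mu + 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(z))
    method <- "normal-approximation"
  }
  list(statistic = T_stat, p_value = p, n_effective = n, method = method,
       status = "ok")
}

# all permutations of 1..n as an (n! x n) matrix, built incrementally
.permutations <- function(n) {
  P <- matrix(1L, 1L, 1L)
  for (k in 2L:n) {
    m <- nrow(P)
    out <- matrix(0L, m * k, k)
    row <- 1L
    for (pos in seq_len(k)) {
      idx <- row:(row + m - 1L)
      if (pos > 1L) out[idx, seq_len(pos - 1L)] <- P[, seq_len(pos - 1L)]
      out[idx, pos] <- k
      if (pos < k) out[idx, (pos + 1L):k] <- P[, pos:(k - 1L), drop = FALSE]
      row <- row + m
    }
    P <- out
  }
  P
}

#' Spearman rank correlation with an exact small-n p-value
#'
#' `rho` is the Pearson correlation of average ranks.  For `n <=
#' exact_limit` the two-sided p-value is computed by full enumeration of
#' all `n!` permutations of one variable; otherwise by the t-approximation
#' with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param exact_limit largest n for permutation enumeration.
#' @return list with `rho`, `p_value`, `n`, `method`, `status`.
#' @export
spearman_correlation <- function(x, y, exact_limit = 9L) {
  if (length(x) != length(y)) .stopf("vectors of unequal length")
  n <- length(x)
  if (n < 3L) .stopf("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "none", status = "zero variance"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= exact_limit) {
    P <- .permutations(n)
    cx <- rx - mean(rx)
    ryp <- matrix(ry[P], nrow(P), n)
    num <- as.vector(ryp %*% cx)
    den <- sqrt(sum(cx^2)) * sqrt(sum((ry - mean(ry))^2))
    rho_perm <- num / den
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact-permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(t_stat), n - 2)
    }
    method <- "t-approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method, status = "ok")
}

#' Kruskal-Wallis H test with tie correction
#'
#' @param groups list of numeric vectors (at least 2 groups, each
#'   non-empty, at least 3 observations in total).
#' @return list with `statistic` (H), `p_value` (chi-square, k-1 df),
#'   `df`, `status` (`"ok"`, or `"degenerate"` with `NA` statistics when
#'   all values are tied).
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    .stopf("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes == 0L)) .stopf("every group must have >= 1 observation")
  values <- unlist(groups)
  N <- length(values)
  if (N < 3L) .stopf("need at least 3 observations in total")
  r <- rank(values)
  ties <- table(values)
  D <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (D == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                df = length(groups) - 1L, status = "degenerate"))
  }
  idx <- rep(seq_along(groups), sizes)
  rank_sums <- tapply(r, idx, sum)
  H <- (12 / (N * (N + 1)) * sum(rank_sums^2 / sizes) - 3 * (N + 1)) / D
  k <- length(groups)
  list(statistic = H, p_value = pchisq(H, k - 1L, lower.tail = FALSE),
       df = k - 1L, status = "ok")
}

#' Percentage of genomes carrying an island
#' @param n_islands number of genomes with the island.
#' @param n_genomes total genomes considered.
#' @return prevalence in percent.
#' @export
island_prevalence <- function(n_islands, n_genomes) {
  .check_scalar_number(n_islands, "n_islands", min = 0)
  .check_scalar_number(n_genomes, "n_genomes", min = 0, strict_min = TRUE)
  if (n_islands > n_genomes) .stopf("n_islands exceeds n_genomes")
  100 * n_islands / n_genomes
}

#' Version abundance matrix from read recruitment
#'
#' Recruits each sample's reads at the species tier against per-version
#' diagnostic sequences and reports RPKG over each concatenation.  A
#' version's diagnostic sequence should be the concatenation of the genes
#' unique to its signature, or the full island sequence as a fallback when
#' no gene is unique (see [diagnostic_genes()]).
#'
#' @param reads_by_sample named list: sample id -> named character vector
#'   of reads.
#' @param version_sequences named character vector: version label ->
#'   diagnostic nucleotide sequence.
#' @param metagenome_size named numeric vector of per-sample metagenome bp;
#'   defaults to the total bases of each read set.
#' @param phosphate_uM optional named numeric vector of per-sample
#'   phosphate concentrations, attached to the result.
#' @param relative divide each column by its sum (all-zero columns stay 0).
#' @param k seed length of the internal mapper.
#' @return versions x samples matrix of class `fgi_version_abundance`
#'   with attribute `phosphate_uM`.
#' @export
version_abundance <- function(reads_by_sample, version_sequences,
                              metagenome_size = NULL, phosphate_uM = NULL,
                              relative = FALSE, k = 15L) {
  if (length(version_sequences) == 0L ||
      any(!nzchar(version_sequences)))
    .stopf("every version needs a non-empty diagnostic sequence")
  samples <- names(reads_by_sample)
  versions <- names(version_sequences)
  metagenome_size <- metagenome_size %||%
    vapply(reads_by_sample, function(r) sum(nchar(r)), numeric(1))
  M <- matrix(0, length(versions), length(samples),
              dimnames = list(versions, samples))
  for (s in samples) {
    reads <- reads_by_sample[[s]]
    if (length(reads) == 0L) next
    for (v in versions) {
      aln <- map_reads(reads, version_sequences[[v]], k = k,
                       min_identity = 70, genome_id = v)
      n <- nrow(filter_alignments(aln, "species"))
      M[v, s] <- compute_rpkg(n, nchar(version_sequences[[v]]),
                              metagenome_size[[s]])
    }
  }
  if (relative) {
    cs <- colSums(M)
    nz <- cs > 0
    M[, nz] <- sweep(M[, nz, drop = FALSE], 2L, cs[nz], "/")
  }
  attr(M, "phosphate_uM") <- phosphate_uM
  class(M) <- c("fgi_version_abundance", class(M))
  M
}

#' Correlate island version abundances with environmental phosphate
#'
#' Per version: Spearman correlation of its abundance profile with
#' phosphate across all samples (versions detected in fewer than 2 samples
#' report `NA`).  Across versions: Kruskal-Wallis on the phosphate values
#' of the samples where each version is detected (abundance > 0).
#'
#' @param abundance versions x samples matrix (e.g. from
#'   [version_abundance()]).
#' @param phosphate_uM named numeric vector of per-sample phosphate;
#'   defaults to the matrix's `phosphate_uM` attribute.
#' @return list with `per_version` (data.frame: `version`, `n_detected`,
#'   `rho`, `p_value`) and `kruskal` (the [kruskal_wallis()] result over
#'   detected-sample phosphate groups, or `NULL` if fewer than 2 versions
#'   are detected).
#' @export
correlate_versions_with_environment <- function(abundance,
                                                phosphate_uM = NULL) {
  phosphate_uM <- phosphate_uM %||% attr(abundance, "phosphate_uM")
  if (is.null(phosphate_uM)) .stopf("phosphate_uM required")
  samples <- colnames(abundance)
  phos <- phosphate_uM[samples]
  if (sum(!is.na(phos)) < 3L)
    .stopf("need phosphate values for at least 3 samples")
  if (all(abundance == 0)) .stopf("no version detected in any sample")
  per <- lapply(rownames(abundance), function(v) {
    ab <- abundance[v, ]
    n_det <- sum(ab > 0)
    if (n_det < 2L) {
      return(data.frame(version = v, n_detected = n_det, rho = NA_real_,
                        p_value = NA_real_))
    }
    sc <- spearman_correlation(ab, phos)
    data.frame(version = v, n_detected = n_det, rho = sc$rho,
               p_value = sc$p_value)
  })
  per <- do.call(rbind, per)
  groups <- lapply(rownames(abundance), function(v)
    phos[abundance[v, ] > 0])
  names(groups) <- rownames(abundance)
  groups <- groups[lengths(groups) > 0L]
  kw <- if (length(groups) >= 2L) kruskal_wallis(groups) else NULL
  list(per_version = per, kruskal = kw)
}
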