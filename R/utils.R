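#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.check_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    .stopf("'%s' must be a single number", name)
  if (strict_min && x <= min) .stopf("'%s' must be > %g", name, min)
  if (!strict_min && x < min) .stopf("'%s' must be >= %g", name, min)
  invisible(x)
}

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement nucleotide strings
#' @param x character vector of A/C/G/T sequences.
#' @return character vector of the same length.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Apply i.i.d. substitutions to a nucleotide sequence
#'
#' Each position is substituted independently with probability `rate`; a
#' substituted base is replaced by one of the three other bases chosen
#' uniformly.  Substitution-only (no indels) so coordinates are preserved.
#' The realized number of substitutions is attached as attribute
#' `n_substitutions` so callers can use the applied count as an oracle for
#' identity computations.
#'
#' @param seq single character string over A/C/G/T.
#' @param rate per-base substitution probability in `[0, 1)`.
#' @return mutated string with attribute `n_substitutions`.
#' @export
mutate_sequence <- function(seq, rate) {
  stopifnot(is.character(seq), length(seq) == 1L)
  .check_scalar_number(rate, "rate", min = 0)
  if (rate >= 1) .stopf("'rate' must be < 1")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
  }
  out <- paste(chars, collapse = "")
  attr(out, "n_substitutions") <- length(hit)
  out
}

# union-find over 1..n
.union_find <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1L]); b <- find(edges[k, 2L])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# merge possibly-overlapping 0-based half-open intervals, optionally bridging
# gaps <= bridge
.merge_intervals <- function(start, end, bridge = 0L) {
  if (length(start) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start)[-1L]) {
    if (start[i] - me <= bridge) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

# md5 checksums of a set of files, named by relative path
.file_checksums <- function(paths, root) {
  sums <- tools::md5sum(paths)
  names(sums) <- sub(paste0("^", root, "/?"), "", names(sums))
  as.list(sums)
}
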