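# Independent oracles and shared fixtures for the test suite.  Everything
# here is deliberately naive (literal enumeration, hand arithmetic) and
# independent of the package's own code paths.

# literal 2^n enumeration of the Wilcoxon signed-rank null: two-sided p for
# the observed T = min(W+, W-)
brute_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 12)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * mean(w_all <= w_obs))
}

# literal n! enumeration of the Spearman permutation null
brute_spearman_p <- function(x, y) {
  n <- length(x)
  stopifnot(n <= 7)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  rhos <- vapply(perms(ry), function(p) cor(rx, p), numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

mutate_protein <- function(p, rate) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ch <- strsplit(p, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(aa, ch[i]), 1)
  paste(ch, collapse = "")
}

# small shared simulation: one species, two fGIp versions, three samples;
# memoized so multiple test files can reuse it
.sim_cache <- new.env(parent = emptyenv())
small_population <- function() {
  if (is.null(.sim_cache$pop)) {
    cfg <- simulation_config(
      seed = 11, core_length = 3e4,
      island_loci = list(island_locus("fGIp-1", 1.5e4, c("A", "E"), "fGIp")),
      samples = data.frame(sample_id = c("S1", "S2", "S3"),
                           phosphate_uM = c(1, 0.05, 0.002)),
      depth_per_strain = 20)
    .sim_cache$pop <- build_population(cfg)
    .sim_cache$sim <- simulate_reads(.sim_cache$pop)
  }
  list(pop = .sim_cache$pop, sim = .sim_cache$sim)
}

# a hand-built recruitment profile with a prescribed depth array, for
# exercising the island scan without any mapping
fake_profile <- function(depth98, depth70 = depth98, genome_id = "g",
                         sample_id = "s", rpkg = 100, breadth98 = 1) {
  structure(list(genome_id = genome_id, sample_id = sample_id,
                 genome_length = length(depth98),
                 depth98 = as.integer(depth98),
                 depth70 = as.integer(depth70),
                 n_reads98 = sum(depth98 > 0), rpkg = rpkg,
                 breadth98 = breadth98, breadth70 = mean(depth70 > 0),
                 metagenome_size = 1e7),
            class = "fgi_recruitment_profile")
}
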