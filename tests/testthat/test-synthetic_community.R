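test_that("configuration invariants are validated", {
  expect_error(simulation_config(within_species_divergence = 0.1,
                                 between_species_divergence = 0.05),
               "within")
  expect_error(simulation_config(
    island_loci = list(island_locus("x", 1e9, "A", "fGIp"))), "outside")
  expect_error(simulation_config(
    island_loci = list(island_locus("x", 4e4, "Z", "fGIp"))), "unknown")
  expect_error(simulation_config(
    samples = data.frame(sample_id = "S1", phosphate_uM = 0)), "phosphate")
  expect_error(simulation_config(gene_length = 901L), "multiple of 3")
})

test_that("same seed gives byte-identical genomes and reads", {
  cfg <- simulation_config(seed = 5, core_length = 1e4,
                           island_loci = list(
                             island_locus("L", 5e3, c("A", "B"), "fGIp")),
                           samples = data.frame(sample_id = "S1",
                                                phosphate_uM = 0.05),
                           depth_per_strain = 5)
  p1 <- build_population(cfg); p2 <- build_population(cfg)
  expect_identical(p1$genomes, p2$genomes)
  r1 <- simulate_reads(p1); r2 <- simulate_reads(p2)
  expect_identical(r1$reads, r2$reads)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fastq(r1$reads$S1, f1); write_fastq(r2$reads$S1, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("within-species ANI matches the configured pairwise divergence", {
  sp <- small_population()
  ids <- names(sp$pop$genomes)
  ani <- compute_ani(sp$pop$genomes[[1]], sp$pop$genomes[[2]],
                     query_id = ids[1], subject_id = ids[2])$ani
  expect_equal(ani, 100 * (1 - sp$pop$config$within_species_divergence),
               tolerance = 0.2 / 99.5)
})

test_that("strains differ only by substitutions and island content", {
  sp <- small_population()
  tr <- sp$pop$truth
  # outside the island loci the two strains are equal-length mutated copies
  isl <- tr$islands
  g1 <- sp$pop$genomes[["sp1_s1"]]; g2 <- sp$pop$genomes[["sp1_s2"]]
  pre1 <- substr(g1, 1, isl$start[isl$strain_id == "sp1_s1"])
  pre2 <- substr(g2, 1, isl$start[isl$strain_id == "sp1_s2"])
  expect_equal(nchar(pre1), nchar(pre2))
  mism <- sum(strsplit(pre1, "")[[1]] != strsplit(pre2, "")[[1]])
  expect_equal(mism / nchar(pre1), sp$pop$config$within_species_divergence,
               tolerance = 0.4)
  # island content differs per signature
  v1 <- tr$strains[tr$strains$strain_id == "sp1_s1", "fGIp-1"]
  v2 <- tr$strains[tr$strains$strain_id == "sp1_s2", "fGIp-1"]
  expect_false(v1 == v2)
})

test_that("truth island coordinates exactly match GFF3 border genes", {
  sp <- small_population()
  f <- sp$pop$features
  for (i in seq_len(nrow(sp$pop$truth$islands))) {
    isl <- sp$pop$truth$islands[i, ]
    genes <- f[f$genome_id == isl$strain_id & f$type == "gene", ]
    expect_true(isl$start %in% genes$end)    # upstream border gene end
    expect_true(isl$end %in% genes$start)    # downstream border gene start
    span <- f[f$genome_id == isl$strain_id &
                f$type == "mobile_genetic_element", ]
    expect_equal(span$start, isl$start)
    expect_equal(span$end, isl$end)
  }
})

test_that("abundance model orders versions by phosphate and gene count", {
  w_high <- abundance_model(1.0, c("A", "E"), "fGIp")
  expect_gt(w_high[["A"]], w_high[["E"]])
  w_low <- abundance_model(0.001, c("A", "E"), "fGIp")
  expect_gt(w_low[["E"]], w_low[["A"]])
  # D and E both have 17 required genes: equal rank, equal weights
  w_tie <- abundance_model(0.7, c("D", "E"), "fGIp")
  expect_equal(unname(w_tie[1]), unname(w_tie[2]))
  expect_equal(sum(w_high), 1)
  expect_error(abundance_model(0, "A", "fGIp"), "phosphate")
})

test_that("read counts are computed, not sampled", {
  cfg <- simulation_config(seed = 2, core_length = 1e5,
                           island_loci = list(),
                           samples = data.frame(sample_id = "S1",
                                                phosphate_uM = 0.05),
                           depth_per_strain = 10, per_base_error = 0)
  # no island loci: single strain carrying nothing
  cfg$strains_per_species <- 1L
  pop <- build_population(cfg)
  expect_equal(length(pop$genomes), 1L)
  sim <- simulate_reads(pop)
  L <- nchar(pop$genomes[[1]])
  expect_equal(length(sim$reads$S1), round(L * 10 / 150))
})

test_that("error-free reads are exact substrings; error rate is realized", {
  cfg <- simulation_config(seed = 3, core_length = 1e4,
                           island_loci = list(
                             island_locus("L", 5e3, "A", "fGIp")),
                           samples = data.frame(sample_id = "S1",
                                                phosphate_uM = 0.05),
                           depth_per_strain = 3, per_base_error = 0)
  pop <- build_population(cfg)
  sim <- simulate_reads(pop)
  g <- pop$genomes[[1]]
  for (r in sim$reads$S1[1:20]) {
    hit <- grepl(r, g, fixed = TRUE) ||
      grepl(as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(r))), g,
        fixed = TRUE)
    expect_true(hit)
  }
  # with errors: mean identity to source = 100 * (1 - e) within 0.1 points
  cfg2 <- simulation_config(seed = 3, core_length = 3e4,
                            island_loci = list(
                              island_locus("L", 15e3, "A", "fGIp")),
                            samples = data.frame(sample_id = "S1",
                                                 phosphate_uM = 0.05),
                            depth_per_strain = 10, per_base_error = 0.005)
  pop2 <- build_population(cfg2)
  sim2 <- simulate_reads(pop2)
  info <- strsplit(names(sim2$reads$S1), "|", fixed = TRUE)
  start0 <- as.integer(vapply(info, `[[`, character(1), 4))
  strand <- vapply(info, `[[`, character(1), 5)
  rd <- sim2$reads$S1
  rd[strand == "-"] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rd[strand == "-"])))
  src <- substring(pop2$genomes[[1]], start0 + 1, start0 + 150)
  ident <- vapply(seq_along(rd), function(i)
    mean(strsplit(rd[i], "")[[1]] == strsplit(src[i], "")[[1]]),
    numeric(1))
  expect_equal(100 * mean(ident), 100 * (1 - 0.005), tolerance = 0.001)
})

test_that("per-strain read shares follow the abundance vector", {
  sp <- small_population()
  ab <- sp$pop$truth$abundances
  lens <- nchar(sp$pop$genomes)
  for (s in colnames(ab)) {
    prov <- sp$sim$provenance
    prov <- prov[prov$sample_id == s, ]
    counts <- setNames(prov$n_reads, prov$strain_id)[rownames(ab)]
    counts[is.na(counts)] <- 0
    expected <- ab[, s] * lens
    expect_equal(unname(counts / sum(counts)),
                 unname(expected / sum(expected)), tolerance = 0.01)
  }
})

test_that("read_length larger than a genome is an error", {
  sp <- small_population()
  pop <- sp$pop
  pop$config$read_length <- 1e6L
  expect_error(simulate_reads(pop), "read_length")
})
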