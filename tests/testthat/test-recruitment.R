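test_that("mapper places exact and mismatched reads correctly", {
  set.seed(4)
  g <- random_dna(5000)
  r <- substr(g, 1001, 1150)
  aln <- map_reads(c(x = r), g, genome_id = "g1")
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$percent_identity, 100)
  expect_equal(aln$genome_start, 1001L)
  expect_equal(aln$genome_end, 1150L)

  # 3 mismatches in 150 -> identity 98.0 (denominator = full read length)
  rr <- strsplit(r, "")[[1]]
  for (p in c(10, 75, 140)) rr[p] <- setdiff(c("A", "C", "G", "T"), rr[p])[1]
  aln3 <- map_reads(c(x = paste(rr, collapse = "")), g)
  expect_equal(aln3$percent_identity, 98.0)
  expect_equal(aln3$mismatches, 3L)

  # reverse-complement read is found on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
  alnm <- map_reads(c(x = rc), g)
  expect_equal(min(alnm$genome_start, alnm$genome_end), 1001L)
  expect_gt(alnm$genome_start, alnm$genome_end)

  # random reads do not hit
  set.seed(5)
  expect_equal(nrow(map_reads(c(x = random_dna(150)), g)), 0L)

  expect_error(map_reads(c(x = "ACGT"), g, k = 15), "seed length")
  expect_error(map_reads(c(x = r), substr(g, 1, 10), k = 15), "shorter")
})

test_that("identity-tier filters use inclusive thresholds", {
  aln <- data.frame(percent_identity = c(98.0, 97.9, 99, 70, 69.9),
                    align_length = c(50L, 500L, 49L, 100L, 100L),
                    evalue = NA_real_)
  sp <- filter_alignments(aln, "species")
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$percent_identity, 98.0)
  pm <- filter_alignments(aln, "permissive")
  expect_setequal(pm$percent_identity, c(98.0, 97.9, 70))
  expect_error(filter_alignments(aln, "strict"), "arg")
  # populated e-value gates the species tier
  aln$evalue <- c(1e-6, 1e-6, 1e-6, 1e-6, 1e-6)
  aln$evalue[1] <- 1e-3
  expect_equal(nrow(filter_alignments(aln, "species")), 0L)
})

test_that("species-tier alignments are a subset of permissive-tier", {
  sp <- small_population()
  aln <- map_reads(sp$sim$reads$S1, sp$pop$genomes[[1]])
  s <- filter_alignments(aln, "species")
  p <- filter_alignments(aln, "permissive")
  expect_true(all(rownames(s) %in% rownames(p)))
})

test_that("RPKG definition, hand arithmetic and linearity", {
  expect_equal(compute_rpkg(1000, 1e6, 1e9), 1.0)
  expect_equal(compute_rpkg(0, 1e6, 1e9), 0.0)
  expect_equal(compute_rpkg(652, 2e6, 1e7), 32.6)  # 652/2000/0.01
  expect_error(compute_rpkg(10, 0, 1e9), "genome_length")
  expect_error(compute_rpkg(10, 1e6, 0), "metagenome_size")
  # linearity properties
  set.seed(6)
  for (i in 1:20) {
    n <- sample(1:1e4, 1); gl <- sample(1e4:1e6, 1); ms <- sample(1e6:1e9, 1)
    base <- compute_rpkg(n, gl, ms)
    expect_equal(compute_rpkg(n, gl, 2 * ms), base / 2)
    expect_equal(compute_rpkg(2 * n, gl, ms), base * 2)
  }
})

test_that("presence call boundary behavior is inclusive", {
  p <- fake_profile(rep(5L, 1000), rpkg = 10.0, breadth98 = 0.60)
  expect_true(call_presence(p)$present)
  p$rpkg <- 9.99; p$breadth98 <- 0.99
  expect_false(call_presence(p)$present)
  p$rpkg <- 100; p$breadth98 <- 0.59
  expect_false(call_presence(p)$present)
})

test_that("coverage profile counts overlapping alignments", {
  aln <- data.frame(genome_start = c(1L, 51L), genome_end = c(100L, 150L))
  cov <- coverage_profile(aln, 1000L)
  expect_equal(cov$breadth, 0.15)
  expect_equal(cov$depth[60], 2L)
  expect_equal(cov$depth[40], 1L)
  expect_equal(cov$depth[200], 0L)
  expect_equal(coverage_profile(aln[0, ], 1000L)$breadth, 0)
  expect_error(coverage_profile(
    data.frame(genome_start = 990L, genome_end = 1100L), 1000L), "bounds")
})

test_that("mapper recovers error-free simulated reads at their origin", {
  cfg <- simulation_config(seed = 9, core_length = 2e4,
                           island_loci = list(),
                           samples = data.frame(sample_id = "S1",
                                                phosphate_uM = 0.05),
                           depth_per_strain = 5, per_base_error = 0,
                           strains_per_species = 1L)
  pop <- build_population(cfg)
  sim <- simulate_reads(pop)
  aln <- map_reads(sim$reads$S1, pop$genomes[[1]])
  expect_gte(nrow(aln) / length(sim$reads$S1), 0.999)
  expect_true(all(aln$percent_identity == 100))
  truth0 <- as.integer(vapply(strsplit(aln$read_id, "|", fixed = TRUE),
                              `[[`, character(1), 4))
  expect_true(all(pmin(aln$genome_start, aln$genome_end) - 1L == truth0))
})

test_that("recruitment profile assembles both tiers coherently", {
  sp <- small_population()
  prof <- recruitment_profile(sp$sim$reads$S1, sp$pop$genomes[["sp1_s1"]],
                              genome_id = "sp1_s1", sample_id = "S1",
                              metagenome_size = sp$sim$metagenome_size[["S1"]])
  expect_equal(length(prof$depth98), nchar(sp$pop$genomes[["sp1_s1"]]))
  expect_true(all(prof$depth98 <= prof$depth70 |
                    prof$depth70 == 0))  # permissive covers species tier
  expect_gte(prof$breadth70, prof$breadth98)
  expect_gt(prof$rpkg, 10)
  expect_true(prof$breadth98 >= 0 && prof$breadth98 <= 1)
})
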