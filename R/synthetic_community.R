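## Synthetic clonal community: core genomes with flexible islands at fixed
## loci, and shotgun metagenomes along a phosphate gradient, with full
## ground truth.

# the 61 sense codons of the standard genetic code
.sense_codons <- function() {
  bases <- DNA_BASES
  all3 <- as.vector(outer(as.vector(outer(bases, bases, paste0)),
                          bases, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

.random_gene <- function(gene_length) {
  stopifnot(gene_length %% 3 == 0)
  paste(sample(.sense_codons(), gene_length / 3, replace = TRUE),
        collapse = "")
}

.random_spacer <- function(n) {
  if (n == 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Define an island locus for the simulator
#' @param locus_name label for the locus (e.g. `"fGIp-1"`).
#' @param insertion_position approximate core coordinate (nt) where the
#'   island is inserted; snapped to the nearest gene boundary.
#' @param version_pool character vector of version labels drawn from the
#'   class signature table.
#' @param island_class `"fGIp"` or `"fGIphn"`.
#' @return list describing the locus.
#' @export
island_locus <- function(locus_name, insertion_position, version_pool,
                         island_class = c("fGIp", "fGIphn")) {
  island_class <- match.arg(island_class)
  list(locus_name = locus_name,
       insertion_position = as.integer(insertion_position),
       version_pool = as.character(version_pool),
       island_class = island_class)
}

#' Simulation configuration
#'
#' Collects every tunable of the synthetic community in one validated list.
#' Defaults are the desk-scale world: 100 kb cores (a paper-scale 1.4 Mb
#' core is just `core_length = 1.4e6`), 900 nt genes with 3 nt intergenic
#' spacers, 0.5% pairwise within-species divergence, 8% between-species
#' divergence, 150 nt reads with 0.5% per-base substitution error.
#'
#' @param seed integer seed; all randomness in the simulator flows from it.
#' @param core_length target core genome length (nt); rounded to a whole
#'   number of gene+spacer units.
#' @param gene_length gene length in nt (multiple of 3).
#' @param intergenic intergenic spacer length in nt.
#' @param n_species number of species.
#' @param within_species_divergence expected pairwise substitution rate
#'   between strains of one species.
#' @param between_species_divergence expected pairwise substitution rate
#'   between species.
#' @param island_loci list of loci from [island_locus()].
#' @param read_length,per_base_error,depth_per_strain read simulation
#'   parameters; `depth_per_strain` is the fold-coverage a strain at
#'   relative abundance 1 would receive.
#' @param samples data.frame with columns `sample_id`, `phosphate_uM`.
#' @param abundance_steepness,abundance_midpoint_uM parameters of the
#'   logistic abundance model (see [abundance_model()]).
#' @param strains_per_species strains per species; defaults to the largest
#'   version pool so every version is carried by some strain.
#' @return validated list of class `fgi_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              core_length = 1e5,
                              gene_length = 900L,
                              intergenic = 3L,
                              n_species = 1L,
                              within_species_divergence = 0.005,
                              between_species_divergence = 0.08,
                              island_loci = list(
                                island_locus("fGIp-1", 4e4, c("A", "E"),
                                             "fGIp")),
                              read_length = 150L,
                              per_base_error = 0.005,
                              depth_per_strain = 30,
                              samples = data.frame(
                                sample_id = c("S1", "S2", "S3", "S4", "S5"),
                                phosphate_uM = c(1.0, 0.3, 0.05, 0.01,
                                                 0.002)),
                              abundance_steepness = 4,
                              abundance_midpoint_uM = 0.05,
                              strains_per_species = NULL) {
  cfg <- list(seed = as.integer(seed), core_length = core_length,
              gene_length = as.integer(gene_length),
              intergenic = as.integer(intergenic),
              n_species = as.integer(n_species),
              within_species_divergence = within_species_divergence,
              between_species_divergence = between_species_divergence,
              island_loci = island_loci,
              read_length = as.integer(read_length),
              per_base_error = per_base_error,
              depth_per_strain = depth_per_strain,
              samples = samples,
              abundance_steepness = abundance_steepness,
              abundance_midpoint_uM = abundance_midpoint_uM,
              strains_per_species = strains_per_species)
  .check_scalar_number(cfg$core_length, "core_length", min = 3 * cfg$gene_length)
  if (cfg$gene_length %% 3L != 0L) .stopf("gene_length must be a multiple of 3")
  if (!(cfg$within_species_divergence > 0 &&
        cfg$within_species_divergence < cfg$between_species_divergence))
    .stopf("need 0 < within_species_divergence < between_species_divergence")
  if (!all(c("sample_id", "phosphate_uM") %in% names(samples)))
    .stopf("samples needs columns sample_id and phosphate_uM")
  if (any(samples$phosphate_uM <= 0)) .stopf("phosphate_uM must be > 0")
  unit <- cfg$gene_length + cfg$intergenic
  n_core <- max(3L, as.integer(round(cfg$core_length / unit)))
  cfg$n_core_genes <- n_core
  cfg$actual_core_length <- n_core * unit
  for (loc in island_loci) {
    if (loc$insertion_position <= 0 ||
        loc$insertion_position >= cfg$actual_core_length)
      .stopf("insertion position of %s outside the core", loc$locus_name)
    sigs <- fgi_signatures(loc$island_class)
    unknown <- setdiff(loc$version_pool, names(sigs))
    if (length(unknown) > 0L)
      .stopf("unknown %s version(s): %s", loc$island_class,
             paste(unknown, collapse = ", "))
  }
  class(cfg) <- c("fgi_sim_config", "list")
  cfg
}

#' Logistic abundance weights of island versions along a phosphate gradient
#'
#' Each version gets a rank in `[-1, 1]` from its required-gene count
#' (gene-poorest = +1, gene-richest = -1; equal counts share a rank); its
#' weight is `plogis(steepness * rank * (log10(P) - log10(midpoint)))`,
#' normalized over the pool.  Gene-poor versions therefore increase with
#' phosphate and gene-rich versions decrease, with equal weights at the
#' midpoint concentration.
#'
#' @param phosphate_uM phosphate concentration in micromolar (> 0).
#' @param versions character vector of version labels (the pool).
#' @param island_class `"fGIp"` or `"fGIphn"`.
#' @param steepness logistic slope per log10 unit of phosphate.
#' @param midpoint_uM concentration at which all versions weigh equally.
#' @param signatures optional signature override.
#' @return named numeric vector of weights summing to 1.
#' @export
abundance_model <- function(phosphate_uM, versions,
                            island_class = c("fGIp", "fGIphn"),
                            steepness = 4, midpoint_uM = 0.05,
                            signatures = NULL) {
  .check_scalar_number(phosphate_uM, "phosphate_uM", min = 0,
                       strict_min = TRUE)
  island_class <- match.arg(island_class)
  signatures <- signatures %||% fgi_signatures(island_class)
  counts <- vapply(versions, function(v) length(signatures[[v]]$required),
                   integer(1))
  rng <- range(counts)
  rank <- if (rng[1] == rng[2]) rep(0, length(counts)) else
    2 * (rng[2] - counts) / (rng[2] - rng[1]) - 1
  w <- stats::plogis(steepness * rank *
                       (log10(phosphate_uM) - log10(midpoint_uM)))
  w <- w / sum(w)
  setNames(w, versions)
}

# build one island cassette: required genes in signature order, each
# followed by the intergenic spacer
.build_cassette <- function(gene_seqs, labels, intergenic) {
  parts <- character(0)
  for (lab in labels) {
    parts <- c(parts, gene_seqs[[lab]], .random_spacer(intergenic))
  }
  paste(parts, collapse = "")
}

#' Build the synthetic clonal population
#'
#' Draws (in a documented order, all from one generator seeded by
#' `config$seed`): ancestral island gene sequences per locus, per-version
#' island genes, the root core, per-species cores, and per-strain cores.
#' Each strain is its species core mutated at half the pairwise
#' within-species divergence, with one island version inserted per locus
#' between two conserved border genes.  Island cassettes are copied
#' verbatim across strains carrying the same version (recent horizontal
#' exchange), so island identity within a version is 100% while cores
#' diverge.
#'
#' @param config an `fgi_sim_config` from [simulation_config()].
#' @return list of class `fgi_population` with elements `genomes` (named
#'   character), `features` ([gene_features()] table covering every strain),
#'   `truth` (strain table, island coordinate table, version sequences,
#'   per-sample abundance matrix, samples), and `config`.
#' @export
build_population <- function(config) {
  stopifnot(inherits(config, "fgi_sim_config"))
  set.seed(config$seed)
  unit <- config$gene_length + config$intergenic
  loci <- config$island_loci

  ## 1. per-version island gene sequences.  Versions are modelled as
  ## independently acquired cassettes (horizontal transfer from divergent
  ## donors): gene sequences are drawn independently per version, so reads
  ## from one version neither recruit to another at the species tier nor
  ## contaminate core ANI, while gene CONTENT still follows the signature
  ## tables.  Within a version the cassette is verbatim across carriers.
  version_sequences <- list()
  cassettes <- list()
  for (loc in loci) {
    sigs <- fgi_signatures(loc$island_class)
    vs <- list(); cs <- list()
    for (v in loc$version_pool) {
      req <- sigs[[v]]$required
      genes <- setNames(lapply(req, function(l)
        .random_gene(config$gene_length)), req)
      vs[[v]] <- unlist(genes)
      cs[[v]] <- .build_cassette(genes, req, config$intergenic)
    }
    version_sequences[[loc$locus_name]] <- vs
    cassettes[[loc$locus_name]] <- cs
  }

  ## 2. root and species cores (tiled codon-clean genes + spacers)
  core_genes <- vapply(seq_len(config$n_core_genes), function(i)
    .random_gene(config$gene_length), character(1))
  spacers <- vapply(seq_len(config$n_core_genes), function(i)
    .random_spacer(config$intergenic), character(1))
  root_core <- paste(paste0(core_genes, spacers), collapse = "")
  species_cores <- character(config$n_species)
  for (s in seq_len(config$n_species)) {
    species_cores[s] <- as.character(
      mutate_sequence(root_core, config$between_species_divergence / 2))
  }

  ## 3. strain table: one strain per version of the largest pool, cycling
  ##    smaller pools
  pool_sizes <- vapply(loci, function(l) length(l$version_pool), integer(1))
  n_strains <- config$strains_per_species %||% max(1L, pool_sizes)
  strain_rows <- list()
  for (s in seq_len(config$n_species)) {
    for (j in seq_len(n_strains)) {
      versions <- vapply(loci, function(l)
        l$version_pool[(j - 1L) %% length(l$version_pool) + 1L],
        character(1))
      strain_rows[[length(strain_rows) + 1L]] <- c(
        strain_id = sprintf("sp%d_s%d", s, j), species_id = sprintf("sp%d", s),
        setNames(versions, vapply(loci, `[[`, character(1), "locus_name")))
    }
  }
  strains <- as.data.frame(do.call(rbind, strain_rows),
                           stringsAsFactors = FALSE)

  ## 4. assemble strain genomes + features + island truth
  # snap insertion positions to gene boundaries of the core
  loci_pos <- vapply(loci, function(l) {
    k <- max(1L, min(config$n_core_genes - 1L,
                     as.integer(round(l$insertion_position / unit))))
    k * unit
  }, numeric(1))
  ord <- order(loci_pos)  # insert left-to-right, tracking the offset

  genomes <- character(0)
  feats <- list()
  island_rows <- list()
  for (r in seq_len(nrow(strains))) {
    sid <- strains$strain_id[r]
    sp <- as.integer(sub("^sp", "", strains$species_id[r]))
    core <- as.character(
      mutate_sequence(species_cores[sp],
                      config$within_species_divergence / 2))
    # insert cassettes left to right; offset accumulates
    segs <- character(0)
    prev <- 0L
    offset <- 0L
    ins <- list()
    for (li in ord) {
      loc <- loci[[li]]
      v <- strains[[loc$locus_name]][r]
      cass <- cassettes[[loc$locus_name]][[v]]
      b <- as.integer(loci_pos[li])
      segs <- c(segs, substring(core, prev + 1L, b), cass)
      ins[[length(ins) + 1L]] <- list(locus = loc, version = v,
                                      core_pos = b, shifted_pos = b + offset,
                                      length = nchar(cass))
      offset <- offset + nchar(cass)
      prev <- b
    }
    segs <- c(segs, substring(core, prev + 1L, nchar(core)))
    genome <- paste(segs, collapse = "")
    genomes[sid] <- genome

    # core gene features with insertion shifts
    gstart <- (seq_len(config$n_core_genes) - 1L) * unit
    shift <- rep(0L, config$n_core_genes)
    for (iv in ins) {
      shift[gstart >= iv$core_pos] <- shift[gstart >= iv$core_pos] + iv$length
    }
    feats[[length(feats) + 1L]] <- gene_features(
      genome_id = sid,
      gene_id = sprintf("%s_core%04d", sid, seq_len(config$n_core_genes)),
      start = gstart + shift, end = gstart + shift + config$gene_length,
      strand = "+", product_label = "hp", type = "gene")

    # island gene features + island span (border-gene-to-border-gene)
    for (iv in ins) {
      req <- fgi_signatures(iv$locus$island_class)[[iv$version]]$required
      is_start <- iv$shifted_pos
      g0 <- is_start + (seq_along(req) - 1L) * unit
      feats[[length(feats) + 1L]] <- gene_features(
        genome_id = sid,
        gene_id = sprintf("%s_%s_%02d", sid, iv$locus$locus_name,
                          seq_along(req)),
        start = g0, end = g0 + config$gene_length,
        strand = "+", product_label = req, type = "gene")
      # truth span: end of upstream border gene to start of downstream one
      span_start <- is_start - config$intergenic
      span_end <- is_start + iv$length
      feats[[length(feats) + 1L]] <- gene_features(
        genome_id = sid, gene_id = sprintf("%s_%s", sid, iv$locus$locus_name),
        start = span_start, end = span_end, strand = "+",
        product_label = "hp", type = "mobile_genetic_element")
      island_rows[[length(island_rows) + 1L]] <- data.frame(
        strain_id = sid, locus_name = iv$locus$locus_name,
        island_class = iv$locus$island_class, version = iv$version,
        start = span_start, end = span_end, stringsAsFactors = FALSE)
    }
  }
  features <- do.call(rbind, feats)
  class(features) <- c("fgi_features", "data.frame")
  islands <- do.call(rbind, island_rows)

  ## 5. per-sample strain abundances from the ecology locus (first locus);
  ##    uniform when the population carries no island
  ab <- matrix(1 / nrow(strains), nrow(strains), nrow(config$samples),
               dimnames = list(strains$strain_id, config$samples$sample_id))
  if (length(loci) > 0L) {
    eco <- loci[[1L]]
    for (j in seq_len(nrow(config$samples))) {
      w <- abundance_model(config$samples$phosphate_uM[j],
                           versions = strains[[eco$locus_name]],
                           island_class = eco$island_class,
                           steepness = config$abundance_steepness,
                           midpoint_uM = config$abundance_midpoint_uM)
      ab[, j] <- w / sum(w)
    }
  }

  structure(list(
    genomes = genomes, features = features,
    truth = list(strains = strains, islands = islands,
                 version_sequences = version_sequences,
                 cassettes = cassettes, abundances = ab,
                 samples = config$samples),
    config = config), class = "fgi_population")
}

#' Simulate shotgun metagenomes from a population
#'
#' Reads are drawn uniformly along each strain; the per-strain read count is
#' computed (not sampled) as `round(abundance * depth_per_strain *
#' genome_length / read_length)`.  Substitution errors are i.i.d. at
#' `per_base_error` (an erroneous base is always changed).  Read ids encode
#' provenance as `sample|strain|serial|start0|strand`.  Randomness is drawn
#' from a generator seeded with `config$seed + 1` so genome construction and
#' read simulation have disjoint, documented streams.
#'
#' @param population an `fgi_population` from [build_population()].
#' @return list with `reads` (named list: sample id -> named character
#'   vector), `metagenome_size` (named numeric, total bases per sample) and
#'   `provenance` (data.frame).
#' @export
simulate_reads <- function(population) {
  stopifnot(inherits(population, "fgi_population"))
  config <- population$config
  rl <- config$read_length
  if (rl > min(nchar(population$genomes)))
    .stopf("read_length exceeds the shortest genome")
  set.seed(config$seed + 1L)
  ab <- population$truth$abundances
  reads_by_sample <- list()
  prov <- list()
  for (j in seq_len(ncol(ab))) {
    sample_id <- colnames(ab)[j]
    all_reads <- character(0)
    for (sid in rownames(ab)) {
      g <- population$genomes[[sid]]
      L <- nchar(g)
      n <- round(ab[sid, j] * config$depth_per_strain * L / rl)
      if (n < 1L) next
      start0 <- sample.int(L - rl + 1L, n, replace = TRUE) - 1L
      strand <- sample(c("+", "-"), n, replace = TRUE)
      rd <- substring(g, start0 + 1L, start0 + rl)
      if (any(strand == "-")) rd[strand == "-"] <- revcomp(rd[strand == "-"])
      nerr <- rbinom(n, rl, config$per_base_error)
      for (i in which(nerr > 0L)) {
        pos <- sample.int(rl, nerr[i])
        ch <- strsplit(rd[i], "", fixed = TRUE)[[1L]]
        for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
        rd[i] <- paste(ch, collapse = "")
      }
      ids <- sprintf("%s|%s|%06d|%d|%s", sample_id, sid, seq_len(n),
                     start0, strand)
      names(rd) <- ids
      all_reads <- c(all_reads, rd)
      prov[[length(prov) + 1L]] <- data.frame(
        sample_id = sample_id, strain_id = sid, n_reads = n,
        stringsAsFactors = FALSE)
    }
    reads_by_sample[[sample_id]] <- all_reads
  }
  list(reads = reads_by_sample,
       metagenome_size = vapply(reads_by_sample,
                                function(r) sum(nchar(r)), numeric(1)),
       provenance = do.call(rbind, prov))
}

#' Write the full synthetic data set to a directory
#'
#' Emits `genomes.fasta`, `genes.gff3`, `reads/<sample>.fastq`,
#' `samples.tsv`, and truth tables (`truth_strains.tsv`,
#' `truth_islands.tsv`, `truth_abundances.tsv`).
#'
#' @param population an `fgi_population`.
#' @param sim result of [simulate_reads()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, sim, dir) {
  dir.create(file.path(dir, "reads"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(population$genomes, file.path(dir, "genomes.fasta"))
  write_gff3(population$features, file.path(dir, "genes.gff3"))
  for (s in names(sim$reads))
    write_fastq(sim$reads[[s]], file.path(dir, "reads", paste0(s, ".fastq")))
  write_tsv(population$truth$samples, file.path(dir, "samples.tsv"))
  write_tsv(population$truth$strains, file.path(dir, "truth_strains.tsv"))
  write_tsv(population$truth$islands, file.path(dir, "truth_islands.tsv"))
  write_tsv(as.data.frame(population$truth$abundances),
            file.path(dir, "truth_abundances.tsv"), row_names = TRUE)
  invisible(dir)
}

#' Translate annotated genes of a strain to proteins
#'
#' @param population an `fgi_population`.
#' @param strain_id strain to translate.
#' @param gene_ids optional subset of gene ids.
#' @return named character vector of amino-acid sequences.
#' @export
gene_proteins <- function(population, strain_id, gene_ids = NULL) {
  f <- population$features
  f <- f[f$genome_id == strain_id & f$type == "gene", , drop = FALSE]
  if (!is.null(gene_ids)) f <- f[f$gene_id %in% gene_ids, , drop = FALSE]
  g <- population$genomes[[strain_id]]
  dna <- Biostrings::DNAStringSet(substring(g, f$start + 1L, f$end))
  aa <- as.character(suppressWarnings(
    Biostrings::translate(dna, if.fuzzy.codon = "solve")))
  setNames(aa, f$gene_id)
}
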