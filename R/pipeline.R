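## Orchestration: simulate -> recruit -> islands -> ani/genomospecies ->
## type-islands -> stats, with one config, one seed, and a manifest.

#' Pipeline configuration
#'
#' Bundles the simulator configuration, scan parameters and thresholds for
#' a full run.  Alternatively a run can ingest external files: when
#' `genomes_fasta`, `reads_dir` and `metadata_tsv` are all supplied the
#' simulate stage is skipped and inputs are read from disk.  Referenced
#' paths are validated here, before any stage runs.
#'
#' @param simulation an `fgi_sim_config` (see [simulation_config()]).
#' @param scan an `fgi_scan_params` (see [scan_params()]).
#' @param thresholds named list of recruitment/ANI/typing cutoffs.
#' @param seed optional override of `simulation$seed`.
#' @param references optional character vector of reference genome ids
#'   (default: all genomes).
#' @param genomes_fasta,reads_dir,metadata_tsv,annotations_gff optional
#'   external inputs; either all of the first three are given or none.
#' @param log_level `"info"` or `"quiet"`.
#' @return validated list of class `fgi_pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            scan = scan_params(),
                            thresholds = list(),
                            seed = NULL, references = NULL,
                            genomes_fasta = NULL, reads_dir = NULL,
                            metadata_tsv = NULL, annotations_gff = NULL,
                            log_level = c("info", "quiet")) {
  defaults <- list(min_rpkg = 10, min_breadth = 0.60, ani_species = 95,
                   ani_derep = 99, cor_threshold = 0.7, min_score = 0.8,
                   k = 15L)
  thresholds <- utils::modifyList(defaults, thresholds)
  if (!is.null(seed)) simulation$seed <- as.integer(seed)
  ext <- c(genomes_fasta, reads_dir, metadata_tsv)
  external <- length(ext) > 0L
  if (external) {
    if (is.null(genomes_fasta) || is.null(reads_dir) ||
        is.null(metadata_tsv))
      .stopf("external input needs genomes_fasta, reads_dir and metadata_tsv")
    for (p in c(genomes_fasta, reads_dir, metadata_tsv, annotations_gff)) {
      if (!file.exists(p)) .stopf("input path does not exist: %s", p)
    }
  }
  structure(list(simulation = simulation, scan = scan,
                 thresholds = thresholds, references = references,
                 genomes_fasta = genomes_fasta, reads_dir = reads_dir,
                 metadata_tsv = metadata_tsv,
                 annotations_gff = annotations_gff,
                 external = external,
                 log_level = match.arg(log_level)),
            class = "fgi_pipeline_config")
}

.log <- function(config, fmt, ...) {
  if (config$log_level != "quiet") message(sprintf(fmt, ...))
}

.stage <- function(config, name, expr) {
  .log(config, "[flexgi] stage %s", name)
  tryCatch(expr, error = function(e)
    .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order and writes every stage output as
#' a plain file under `outdir`, plus a `manifest.json` recording the
#' configuration, seed, package version and md5 checksums of all outputs.
#' Reruns with an identical configuration are byte-identical for the
#' deterministic stages (everything except the manifest timestamp).
#'
#' @param config an `fgi_pipeline_config`.
#' @param outdir output directory (created if needed).
#' @return invisible list with the in-memory stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "fgi_pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds

  ## stage 1: inputs (simulate or ingest)
  if (!config$external) {
    population <- .stage(config, "simulate",
                         build_population(config$simulation))
    sim <- .stage(config, "simulate-reads", simulate_reads(population))
    write_population(population, sim, outdir)
    genomes <- population$genomes
    features <- population$features
    reads <- sim$reads
    meta_sizes <- sim$metagenome_size
    samples <- population$truth$samples
  } else {
    population <- NULL
    genomes <- .stage(config, "ingest", read_fasta(config$genomes_fasta))
    features <- if (!is.null(config$annotations_gff))
      read_gff3(config$annotations_gff) else NULL
    samples <- read_tsv(config$metadata_tsv)
    reads <- lapply(samples$sample_id, function(s) {
      p <- file.path(config$reads_dir, paste0(s, ".fastq"))
      if (!file.exists(p)) .stopf("missing reads file: %s", p)
      read_fastq(p)
    })
    names(reads) <- samples$sample_id
    meta_sizes <- vapply(reads, function(r) sum(nchar(r)), numeric(1))
  }
  refs <- config$references %||% names(genomes)

  ## stage 2: recruitment
  profiles <- .stage(config, "recruit", {
    out <- list()
    for (g in refs) {
      out[[g]] <- lapply(names(reads), function(s)
        recruitment_profile(reads[[s]], genomes[[g]], genome_id = g,
                            sample_id = s,
                            metagenome_size = meta_sizes[[s]],
                            k = th$k))
      names(out[[g]]) <- names(reads)
    }
    out
  })
  recr <- do.call(rbind, lapply(refs, function(g)
    do.call(rbind, lapply(names(reads), function(s) {
      p <- profiles[[g]][[s]]
      pc <- call_presence(p, th$min_rpkg, th$min_breadth)
      data.frame(genome_id = g, sample_id = s, n_reads98 = p$n_reads98,
                 rpkg = p$rpkg, breadth98 = p$breadth98,
                 present = pc$present)
    }))))
  write_tsv(recr, file.path(outdir, "recruitment.tsv"))
  rpkg_mat <- matrix(recr$rpkg, nrow = length(refs), byrow = TRUE,
                     dimnames = list(refs, names(reads)))
  presence_mat <- matrix(recr$present, nrow = length(refs), byrow = TRUE,
                         dimnames = list(refs, names(reads)))

  ## stage 3: island scan
  islands <- .stage(config, "islands", {
    calls <- list()
    for (g in refs) {
      pres <- vapply(profiles[[g]], function(p)
        call_presence(p, th$min_rpkg, th$min_breadth)$present, logical(1))
      if (!any(pres)) next
      cand <- lapply(names(reads), function(s) {
        if (!pres[[s]]) return(NULL)
        detect_islands(profiles[[g]][[s]], config$scan)
      })
      names(cand) <- names(reads)
      cl <- classify_islands(cand, profiles[[g]], config$scan)
      if (!is.null(features) && nrow(cl) > 0L)
        cl <- refine_boundaries(cl, features)
      calls[[g]] <- cl
    }
    if (length(calls) == 0L) NULL else {
      flag_list <- lapply(calls, attr, "per_sample_flag")
      out <- do.call(rbind, lapply(calls, as.data.frame))
      rownames(out) <- NULL
      attr(out, "per_sample_flag") <- do.call(rbind, flag_list)
      out
    }
  })
  if (!is.null(islands)) {
    write_bed(islands, file.path(outdir, "islands.bed"))
    isl_tsv <- islands
    flags <- attr(islands, "per_sample_flag")
    if (!is.null(flags))
      isl_tsv <- cbind(isl_tsv, as.data.frame(flags))
    write_tsv(isl_tsv, file.path(outdir, "islands.tsv"))
  } else {
    write_bed(data.frame(genome_id = character(0), start = integer(0),
                         end = integer(0), locus_label = character(0)),
              file.path(outdir, "islands.bed"))
  }

  ## stage 4: ANI, dereplication, genomospecies
  taxo <- .stage(config, "genomospecies", {
    ani <- ani_matrix(genomes, k = th$k)
    derep <- dereplicate(genomes, ani_threshold = th$ani_derep, ani = ani)
    gs <- assign_genomospecies(ani, rpkg_mat[names(genomes),
                                             , drop = FALSE],
                               presence_mat[names(genomes), , drop = FALSE],
                               species_threshold = th$ani_species,
                               cor_threshold = th$cor_threshold)
    list(ani = ani, derep = derep, genomospecies = gs)
  })
  ani_long <- do.call(rbind, lapply(rownames(taxo$ani), function(a)
    data.frame(query_id = a, subject_id = colnames(taxo$ani),
               ani = taxo$ani[a, ])))
  write_tsv(ani_long, file.path(outdir, "ani.tsv"))
  gs_out <- taxo$genomospecies
  gs_out$representative <-
    gs_out$genome_id %in% taxo$derep$representatives
  write_tsv(gs_out, file.path(outdir, "genomospecies.tsv"))

  ## stage 5: island typing
  typing <- .stage(config, "type-islands", {
    if (is.null(islands) || is.null(features) || nrow(islands) == 0L)
      NULL
    else {
      rows <- lapply(seq_len(nrow(islands)), function(i) {
        genes <- extract_island_genes(islands[i, ], features)
        cand <- lapply(c("fGIp", "fGIphn"), function(cl)
          assign_version(genes, cl, min_score = th$min_score))
        names(cand) <- c("fGIp", "fGIphn")
        scores <- vapply(cand, `[[`, numeric(1), "score")
        labels <- vapply(cand, `[[`, character(1), "label")
        assigned <- labels != "unassigned"
        pick <- if (any(assigned)) {
          names(which.max(scores[assigned]))
        } else names(which.max(scores))
        data.frame(genome_id = islands$genome_id[i],
                   locus_label = islands$locus_label[i],
                   start = islands$start[i], end = islands$end[i],
                   island_class = pick, version = labels[[pick]],
                   score = scores[[pick]])
      })
      do.call(rbind, rows)
    }
  })
  if (!is.null(typing))
    write_tsv(typing, file.path(outdir, "island_versions.tsv"))

  ## stage 6: environment statistics (simulated runs only: needs version
  ## diagnostic sequences and phosphate metadata)
  stats_out <- .stage(config, "stats", {
    if (config$external || is.null(population)) NULL else {
      loc <- config$simulation$island_loci[[1L]]
      diag_seqs <- .version_diagnostic_sequences(population, loc)
      phos <- setNames(samples$phosphate_uM, samples$sample_id)
      ab <- version_abundance(reads, diag_seqs,
                              metagenome_size = meta_sizes,
                              phosphate_uM = phos, k = th$k)
      corr <- correlate_versions_with_environment(ab)
      write_tsv(as.data.frame(unclass(ab)),
                file.path(outdir, "version_abundance.tsv"),
                row_names = TRUE)
      stats_df <- corr$per_version
      if (!is.null(corr$kruskal)) {
        stats_df <- rbind(stats_df, data.frame(
          version = "ALL(Kruskal-Wallis H)",
          n_detected = NA, rho = corr$kruskal$statistic,
          p_value = corr$kruskal$p_value))
      }
      write_tsv(stats_df, file.path(outdir, "stats.tsv"))
      list(abundance = ab, correlation = corr)
    }
  })

  ## manifest
  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "flexgi",
    version = as.character(utils::packageVersion("flexgi")),
    seed = config$simulation$seed,
    thresholds = config$thresholds,
    scan = unclass(config$scan),
    simulation = .serializable_config(config$simulation),
    checksums = .file_checksums(files, normalizePath(outdir)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(population = population, profiles = profiles,
                 islands = islands, taxonomy = taxo, typing = typing,
                 stats = stats_out, manifest = manifest))
}

# per-version diagnostic sequences for one locus: unique signature genes,
# falling back to the full island cassette when no gene is unique
.version_diagnostic_sequences <- function(population, locus) {
  sigs <- fgi_signatures(locus$island_class)
  diag <- diagnostic_genes(sigs)
  vs <- population$truth$version_sequences[[locus$locus_name]]
  out <- vapply(locus$version_pool, function(v) {
    dg <- intersect(diag[[v]], names(vs[[v]]))
    if (length(dg) > 0L) paste(vs[[v]][dg], collapse = "") else
      population$truth$cassettes[[locus$locus_name]][[v]]
  }, character(1))
  setNames(out, locus$version_pool)
}

.serializable_config <- function(sim) {
  cfg <- unclass(sim)
  cfg$samples <- as.list(as.data.frame(cfg$samples))
  cfg
}
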