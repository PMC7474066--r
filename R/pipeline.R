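#' End-to-end run configuration
#'
#' Bundles the per-module configurations. In `synthetic` mode everything is
#' generated; `replication` mode instead loads an external reference FASTA,
#' an exon BED and per-individual VCFs through the same readers and runs the
#' identical downstream stages.
#'
#' @param mode `"synthetic"` or `"replication"`.
#' @param genome A [synthetic_genome_config()] (synthetic mode).
#' @param population A [population_config()].
#' @param read_lengths Read lengths to simulate.
#' @param mapper A [mapper_config()].
#' @param seed Master seed; module seeds derive from it.
#' @param reference_fasta,exon_bed,vcf_dir External inputs (replication
#'   mode; all required there).
#' @return A `camo_run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "replication"),
                       genome = synthetic_genome_config(),
                       population = population_config(),
                       read_lengths = c(70L, 100L, 150L, 250L),
                       mapper = mapper_config(),
                       seed = 1L,
                       reference_fasta = NULL,
                       exon_bed = NULL,
                       vcf_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "replication" &&
      (is.null(reference_fasta) || is.null(exon_bed))) {
    abort("replication mode requires reference_fasta and exon_bed paths")
  }
  stopifnot(all(read_lengths >= 20L))
  structure(
    list(mode = mode, genome = genome, population = population,
         read_lengths = as.integer(read_lengths), mapper = mapper,
         seed = as.integer(seed), reference_fasta = reference_fasta,
         exon_bed = exon_bed, vcf_dir = vcf_dir),
    class = "camo_run_config"
  )
}

#' Load replication-mode inputs
#'
#' Reads an external reference FASTA and exon BED (with a `name` column of
#' the form `gene` or `gene_exonN`) into the same genome structure the
#' synthetic generator produces; `camo_truth` is empty since no planted
#' truth exists for external data.
#'
#' @param config A replication-mode [run_config()].
#' @return A genome list (`reference`, `panel`, empty `camo_truth`).
#' @export
load_replication_inputs <- function(config) {
  stopifnot(config$mode == "replication")
  ref <- read_fasta(config$reference_fasta)
  bed <- read_bed(config$exon_bed)
  gene <- sub("_ex[0-9]+$", "", bed$name)
  exons <- tibble(contig = bed$contig, start = bed$start, end = bed$end,
                  gene = gene, name = bed$name)
  genes <- summarise(group_by(exons, .data$gene),
                     contig = first(.data$contig),
                     start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
  pn <- panel(genes, exons, buffer = config$genome$buffer %||% 70L,
              flank = config$genome$flank %||% 2000L)
  list(
    reference = ref, panel = pn,
    camo_truth = tibble(gene = character(), contig = character(),
                        gene_tract_start = integer(),
                        gene_tract_end = integer(),
                        pseudo_start = integer(), pseudo_end = integer(),
                        tract_length = integer(), identity = double(),
                        profile = character())
  )
}

#' Flag potentially problematic panel genes
#'
#' Composes the homology stage: k-mer mappability, per-exon means,
#' homology search over buffered exons, the mismatch/length filter, and the
#' union flagging rule.
#'
#' @param genome A [make_reference()] result.
#' @param k Mappability word length (default 75).
#' @param word_size Homology seed word (default 11).
#' @param max_mismatch,max_len_diff Hit filter thresholds (default 10/10).
#' @param out_dir Optional directory for TSV artifacts.
#' @return List: `exon_mappability`, `hits`, `filtered_hits`, `flags`.
#' @export
run_flag <- function(genome, k = 75L, word_size = 11L, max_mismatch = 10L,
                     max_len_diff = 10L, out_dir = NULL) {
  lens <- reference_lengths(genome$reference)
  track <- compute_mappability(genome$reference, k)
  bex <- buffered_exons(genome$panel, lens)
  em <- exon_mean_mappability(track, bex)
  hits <- panel_homology_hits(genome, word_size = word_size)
  fh <- filter_hits(hits, max_mismatch = max_mismatch,
                    max_len_diff = max_len_diff)
  flags <- flag_panel(genome$panel, em, fh)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(em, file.path(out_dir, "exon_mappability.tsv"))
    readr::write_tsv(select(hits, -dplyr::any_of("alt_locations")),
                     file.path(out_dir, "homology_hits.tsv"))
    readr::write_tsv(flags, file.path(out_dir, "flagged_genes.tsv"))
  }
  list(exon_mappability = em, hits = hits, filtered_hits = fh, flags = flags)
}

#' Simulate, map and evaluate one read set
#'
#' @param genome A [make_reference()] result.
#' @param vcf Single-sample VCF records (or `NULL` for a reference-identical
#'   individual).
#' @param read_length Read length (bp).
#' @param seed Simulation seed.
#' @param mapper A [mapper_config()].
#' @param index Optional pre-built index.
#' @param individual Label recorded in read names.
#' @param coverage Per-haplotype coverage (default 20; 40X combined).
#' @return List: `classified` alignments, `summary`, `depth` (MQ >= 20
#'   track over gene bodies), `camo` regions.
#' @export
simeval_one <- function(genome, vcf = NULL, read_length = 150L, seed = 1L,
                        mapper = mapper_config(), index = NULL,
                        individual = "ind1", coverage = 20) {
  ref <- genome$reference
  lens <- reference_lengths(ref)
  cons <- if (is.null(vcf) || nrow(vcf) == 0L) ref else build_consensus(ref, vcf)
  haps <- split_haplotypes(cons)
  cfg <- simulation_config(read_length = read_length,
                           per_haplotype_coverage = coverage, seed = seed)
  regs <- simulation_regions(genome$panel, lens)
  reads <- simulate_reads(haps$hap1, haps$hap2,
                          regs[, c("contig", "start", "end")], cfg,
                          individual = individual)
  idx <- index %||% build_index(ref, mapper$seed_length)
  frag_mean <- 2 * cfg$read_length + cfg$inner_distance_mean
  aln <- map_read_pairs(idx, reads, frag_mean, cfg$inner_distance_sd, mapper)
  cls <- classify_reads(aln)
  genes <- genome$panel$genes[, c("contig", "start", "end", "gene")]
  d20 <- depth_track(aln, genes, lens, mq_min = 20L)
  camo <- call_camo_regions(d20, genome$panel, aln)
  list(
    classified = cls,
    summary = summarize_classification(cls),
    depth = d20,
    camo = camo
  )
}

#' Simulate and evaluate mapping across read lengths
#'
#' Runs the simulate/map/evaluate stage for one individual at each read
#' length, calls camo regions (depth < 20 at MQ >= 20, merged within
#' 50 bp over gene bodies), and classifies genes by read-length rescue.
#'
#' @param genome A [make_reference()] result.
#' @param vcf Optional single-sample VCF records.
#' @param read_lengths Read lengths (default 70/100/150/250).
#' @param seed Simulation seed.
#' @param mapper A [mapper_config()].
#' @param out_dir Optional directory for camo BED artifacts.
#' @param keep_alignments Keep classified alignments per read length?
#' @return List: `accuracy` (tibble per read length), `camo` (list per read
#'   length), `depth`, `rescue` table.
#' @export
run_simeval <- function(genome, vcf = NULL,
                        read_lengths = c(70L, 100L, 150L, 250L),
                        seed = 1L, mapper = mapper_config(), out_dir = NULL,
                        keep_alignments = FALSE) {
  idx <- build_index(genome$reference, mapper$seed_length)
  camo <- list()
  depth <- list()
  acc <- list()
  cls_all <- list()
  for (rl in read_lengths) {
    res <- simeval_one(genome, vcf, read_length = rl, seed = seed,
                       mapper = mapper, index = idx)
    key <- as.character(rl)
    camo[[key]] <- res$camo
    depth[[key]] <- res$depth
    acc[[key]] <- mutate(res$summary, read_length = rl)
    if (keep_alignments) cls_all[[key]] <- res$classified
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_camo_bed(res$camo, file.path(out_dir, paste0("camo_", rl, "bp")))
    }
  }
  rescue <- if (length(read_lengths) >= 2L) {
    read_length_rescue_table(camo, genome$panel)
  } else {
    NULL
  }
  out <- list(accuracy = bind_rows(acc), camo = camo, depth = depth,
              rescue = rescue)
  if (keep_alignments) out$classified <- cls_all
  out
}

#' Per-population mapping evaluation
#'
#' Simulates one individual per population at a single read length,
#' summarises mapping accuracy by population, and returns per-population
#' depth tracks for the differentiation-versus-coverage analysis.
#'
#' @param genome A [make_reference()] result.
#' @param popsim A [simulate_population_genotypes()] result.
#' @param read_length Read length (150 bp default, the standard panel
#'   read length).
#' @param seed Simulation seed base (per-population seeds derive from it).
#' @param mapper A [mapper_config()].
#' @param coverage Per-haplotype coverage.
#' @return List: `accuracy` by population, `depth` (named list of
#'   [depth_track()]s at MQ >= 10 over gene bodies).
#' @export
run_population_eval <- function(genome, popsim, read_length = 150L,
                                seed = 1L, mapper = mapper_config(),
                                coverage = 20) {
  idx <- build_index(genome$reference, mapper$seed_length)
  lens <- reference_lengths(genome$reference)
  genes <- genome$panel$genes[, c("contig", "start", "end", "gene")]
  pops <- unique(popsim$individuals$population)
  acc <- list()
  depth <- list()
  for (i in seq_along(pops)) {
    ind <- popsim$individuals$individual[popsim$individuals$population ==
                                           pops[i]][1]
    vcf <- genotype_vcf(popsim, ind)
    res <- simeval_one(genome, vcf, read_length = read_length,
                       seed = seed + i, mapper = mapper, index = idx,
                       individual = ind, coverage = coverage)
    acc[[i]] <- mutate(res$summary, population = pops[i])
    depth[[pops[i]]] <- depth_track(res$classified, genes, lens, mq_min = 10L)
  }
  list(accuracy = bind_rows(acc), depth = depth)
}

#' Run the variant-rescue strategy comparison
#'
#' @param genome A [make_reference()] result.
#' @param gene Target gene (default: the camo gene with the isolated
#'   divergence profile, the converting-variant host).
#' @param n_variants Scenario-library size per gene (default 11).
#' @param strategies Subset of [strategy_names()].
#' @param mapper A [mapper_config()].
#' @param sim_seed Seed for scenario simulations.
#' @return Verdict tibble from [run_scenarios()].
#' @export
run_rescue <- function(genome, gene = NULL, n_variants = 11L,
                       strategies = strategy_names(),
                       mapper = mapper_config(), sim_seed = 7L) {
  if (is.null(gene)) {
    ct <- genome$camo_truth
    gene <- if (any(ct$profile == "isolated")) {
      ct$gene[ct$profile == "isolated"][1]
    } else if (nrow(ct) > 0L) {
      ct$gene[1]
    } else {
      abort("no camo gene available for the rescue experiment")
    }
  }
  scenarios <- make_scenarios(genome, gene, n_variants = n_variants,
                              sim_seed = sim_seed)
  run_scenarios(scenarios, strategies = strategies, mapper = mapper)
}

#' Run the full pipeline
#'
#' Generates (or loads) the genome, flags the panel, runs the read-length
#' evaluation, the population analyses and the rescue strategies.
#'
#' @param config A [run_config()].
#' @param out_dir Optional artifact directory.
#' @return List with `genome`, `flag`, `simeval`, `popsim`, `popeval`,
#'   `fst`, `rescue`.
#' @export
run_all <- function(config = run_config(), out_dir = NULL) {
  genome <- if (config$mode == "synthetic") {
    make_reference(config$genome)
  } else {
    load_replication_inputs(config)
  }
  flag <- run_flag(genome, out_dir = out_dir)
  popsim <- simulate_population_genotypes(genome$panel, config$population,
                                          ref = genome$reference)
  simeval <- run_simeval(genome, vcf = genotype_vcf(
    popsim, popsim$individuals$individual[1]
  ), read_lengths = config$read_lengths, seed = config$seed,
  mapper = config$mapper, out_dir = out_dir)
  fst <- wc_fst(popsim$genotypes, popsim$individuals$population)
  rescue <- if (nrow(genome$camo_truth) > 0L) {
    run_rescue(genome, mapper = config$mapper)
  } else {
    NULL
  }
  list(genome = genome, flag = flag, simeval = simeval, popsim = popsim,
       fst = fst, rescue = rescue)
}
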