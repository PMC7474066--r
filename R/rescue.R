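#' Build a variant-calling scenario
#'
#' A scenario bundles a genome, a target gene, one planted variant and the
#' simulation settings under which the four calling strategies are compared.
#'
#' @param genome A [make_reference()] result.
#' @param gene Target gene.
#' @param converting,zygosity,exon,seed Passed to [plant_variant()].
#' @param sim_config Base [simulation_config()] (150 bp reads, inner
#'   distance 50 by default).
#' @param id Scenario label.
#' @return A `camo_scenario` list.
#' @export
make_scenario <- function(genome, gene, converting = TRUE, zygosity = "hom",
                          exon = NULL, seed = 7L,
                          sim_config = simulation_config(seed = seed),
                          id = NULL) {
  planted <- plant_variant(genome, gene, converting = converting,
                           zygosity = zygosity, exon = exon, seed = seed)
  structure(
    list(
      genome = genome, gene = gene, planted = planted,
      sim_config = sim_config,
      id = id %||% sprintf("%s_%s_%s", gene,
                           if (converting) "conv" else "nonconv", zygosity)
    ),
    class = "camo_scenario"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scenario library for a camo gene
#'
#' Plants `n_variants` variants in the gene: the converting variant (hom and
#' het, when the gene has a pseudogene copy with divergent sites) plus
#' non-converting variants spread across exons clear of the homologous
#' tract, alternating hom/het — eleven simulated pathogenic variants per
#' gene by default.
#'
#' @param genome A [make_reference()] result.
#' @param gene Gene name.
#' @param n_variants Number of scenarios (default 11).
#' @param sim_seed Seed for the simulation configs.
#' @return List of [make_scenario()] objects.
#' @export
make_scenarios <- function(genome, gene, n_variants = 11L, sim_seed = 7L) {
  has_pseudo <- gene %in% genome$camo_truth$gene
  out <- list()
  if (has_pseudo) {
    out <- c(out, list(
      make_scenario(genome, gene, converting = TRUE, zygosity = "hom",
                    seed = sim_seed),
      make_scenario(genome, gene, converting = TRUE, zygosity = "het",
                    seed = sim_seed + 1L)
    ))
  }
  exons <- genome$panel$exons[genome$panel$exons$gene == gene, ]
  ct <- genome$camo_truth[genome$camo_truth$gene == gene, ]
  free <- seq_len(nrow(exons))
  if (nrow(ct) == 1L) {
    free <- free[!(exons$start < ct$gene_tract_end &
                     exons$end > ct$gene_tract_start)]
  }
  if (length(free) == 0L) free <- seq_len(nrow(exons))
  k <- length(out)
  i <- 0L
  while (k < n_variants) {
    ex <- free[(i %% length(free)) + 1L]
    zyg <- if (i %% 2L == 0L) "hom" else "het"
    sc <- make_scenario(genome, gene, converting = FALSE, zygosity = zyg,
                        exon = ex, seed = sim_seed + 10L + i,
                        id = sprintf("%s_nonconv_%s_ex%d_%d", gene, zyg, ex, i))
    out <- c(out, list(sc))
    k <- k + 1L
    i <- i + 1L
  }
  out
}

#' Names of the implemented calling strategies
#' @return Character vector.
#' @export
strategy_names <- function() {
  c("standard", "lowered_mq", "long_inner_distance", "masked_ploidy4")
}

masked_reference_for <- function(genome, gene, flank = 2000L) {
  ct <- genome$camo_truth[genome$camo_truth$gene == gene, ]
  if (nrow(ct) != 1L) {
    abort(paste0("gene ", gene, " has no pseudogene copy to mask"))
  }
  mask_reference(
    genome$reference,
    tibble(contig = ct$contig, start = ct$pseudo_start, end = ct$pseudo_end),
    flank = flank
  )
}

#' Run one calling strategy on a scenario
#'
#' Strategies (all at 150 bp paired-end reads, 40X combined coverage):
#' * `standard` — inner distance 50, ploidy 2, pileup MAPQ cutoff 20;
#' * `lowered_mq` — as standard but MAPQ cutoff 10;
#' * `long_inner_distance` — inner distance elongated to 255 so mates are
#'   sequenced outside the homologous region and rescue their pairs;
#' * `masked_ploidy4` — reads simulated from both the gene and its
#'   pseudogene (residual capture of the pseudogene occurs even when the
#'   gene is targeted), mapped to a reference with the pseudogene masked
#'   (plus 2 kb flanks), and genotyped at ploidy 4.
#'
#' @param scenario A [make_scenario()].
#' @param strategy One of [strategy_names()].
#' @param mapper A [mapper_config()].
#' @param index Optional pre-built index of the scenario reference.
#' @param masked_index Optional pre-built index of the masked reference.
#' @param keep_alignments Return the alignment tibble (for depth analyses)?
#' @return List with `verdict` (one-row tibble), `call`, `extra_calls`
#'   (ploidy-4 strategy only; [discriminate_calls()] applied), and
#'   optionally `alignments`.
#' @export
run_strategy <- function(scenario, strategy, mapper = mapper_config(),
                         index = NULL, masked_index = NULL,
                         keep_alignments = FALSE) {
  if (!strategy %in% strategy_names()) {
    abort(paste0("unknown strategy: ", strategy))
  }
  genome <- scenario$genome
  ref <- genome$reference
  panel <- genome$panel
  v <- scenario$planted$variant
  cfg <- scenario$sim_config
  if (strategy == "long_inner_distance") {
    cfg$inner_distance_mean <- 255
  }

  regs <- simulation_regions(panel, reference_lengths(ref))
  regions <- regs[regs$gene == scenario$gene, c("contig", "start", "end")]
  if (strategy == "masked_ploidy4") {
    ct <- genome$camo_truth[genome$camo_truth$gene == scenario$gene, ]
    if (nrow(ct) != 1L) abort("masked_ploidy4 requires a pseudogene copy")
    lens <- reference_lengths(ref)
    pseudo_region <- tibble(
      contig = ct$contig,
      start = pmax(0L, ct$pseudo_start - panel$flank),
      end = pmin(as.integer(lens[ct$contig]), ct$pseudo_end + panel$flank)
    )
    regions <- bind_rows(regions, pseudo_region)
  }

  reads <- make_variant_readset(ref, panel, scenario$planted, cfg,
                                regions = regions)
  idx <- if (strategy == "masked_ploidy4") {
    masked_index %||% build_index(masked_reference_for(genome, scenario$gene),
                                  mapper$seed_length)
  } else {
    index %||% build_index(ref, mapper$seed_length)
  }
  frag_mean <- 2 * cfg$read_length + cfg$inner_distance_mean
  aln <- map_read_pairs(idx, reads, frag_mean, cfg$inner_distance_sd, mapper)

  ccfg <- switch(
    strategy,
    standard = caller_config(ploidy = 2L, mq_min = 20L),
    lowered_mq = caller_config(ploidy = 2L, mq_min = 10L),
    long_inner_distance = caller_config(ploidy = 2L, mq_min = 20L),
    masked_ploidy4 = caller_config(ploidy = 4L, mq_min = 20L)
  )
  call <- call_site(aln, ref, v$contig, v$pos, alt = v$alt, config = ccfg)

  extra <- NULL
  if (strategy == "masked_ploidy4") {
    ct <- genome$camo_truth[genome$camo_truth$gene == scenario$gene, ]
    sc <- scan_variants(aln, ref, ct$contig, ct$gene_tract_start,
                        ct$gene_tract_end, config = ccfg)
    sc <- sc[sc$pos != v$pos, , drop = FALSE]
    extra <- discriminate_calls(sc, ploidy = 4L)
  }

  scenario_id <- scenario$id
  scenario_gene <- scenario$gene
  verdict <- tibble(
    scenario = scenario_id,
    gene = scenario_gene,
    converting = v$converting,
    zygosity = v$zygosity,
    strategy = strategy,
    called = isTRUE(call$called) && call$dosage > 0L,
    genotype = call$genotype,
    gq = call$gq,
    site_depth = call$n_ref + call$n_alt,
    n_extra_calls = if (is.null(extra)) NA_integer_ else nrow(extra)
  )
  out <- list(verdict = verdict, call = call, extra_calls = extra)
  if (keep_alignments) out$alignments <- aln
  out
}

#' Run all strategies over a scenario set
#'
#' Indexes are built once and shared across scenarios and strategies.
#'
#' @param scenarios List of [make_scenario()] objects (one gene).
#' @param strategies Subset of [strategy_names()].
#' @param mapper A [mapper_config()].
#' @return Tibble of verdicts (one row per scenario x strategy), with the
#'   per-run detail in the `detail` attribute.
#' @export
run_scenarios <- function(scenarios, strategies = strategy_names(),
                          mapper = mapper_config()) {
  stopifnot(length(scenarios) > 0L)
  genome <- scenarios[[1]]$genome
  gene <- scenarios[[1]]$gene
  idx <- build_index(genome$reference, mapper$seed_length)
  midx <- if ("masked_ploidy4" %in% strategies &&
              gene %in% genome$camo_truth$gene) {
    build_index(masked_reference_for(genome, gene), mapper$seed_length)
  } else {
    NULL
  }
  detail <- list()
  verdicts <- list()
  for (sc in scenarios) {
    for (st in strategies) {
      if (st == "masked_ploidy4" && is.null(midx)) next
      res <- run_strategy(sc, st, mapper = mapper, index = idx,
                          masked_index = midx)
      verdicts[[length(verdicts) + 1L]] <- res$verdict
      detail[[paste(sc$id, st, sep = ".")]] <- res
    }
  }
  out <- bind_rows(verdicts)
  attr(out, "detail") <- detail
  out
}
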