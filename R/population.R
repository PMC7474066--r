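#' Configuration for multi-population genotype simulation
#'
#' Population allele frequencies follow the Balding–Nichols model: each site
#' draws an ancestral frequency `p` uniformly from `ancestral_freq_range`,
#' and population k draws its frequency from
#' `Beta(p (1 - F_k) / F_k, (1 - p) (1 - F_k) / F_k)` (the ancestral `p`
#' itself when `F_k = 0`). Individual genotypes are `Binomial(2, freq)`.
#'
#' `differentiation_F` may be a single value or one value per population;
#' the expected pairwise Weir–Cockerham FST between populations i and j is
#' approximately `(F_i + F_j) / 2`. The defaults (five populations labelled
#' with 1000 Genomes super-population codes, one clearly more
#' differentiated than the rest) place every expected pairwise estimate
#' inside the 0.047–0.165 band typical of global human differentiation
#' across such panels.
#'
#' @param n_populations Number of populations.
#' @param n_per_population Diploid individuals per population.
#' @param n_sites_per_gene Variant sites placed uniformly within each gene.
#' @param differentiation_F Drift parameter(s) in `[0, 1)`.
#' @param ancestral_freq_range Range for the ancestral allele frequency.
#' @param population_names Optional population labels.
#' @param seed Integer seed.
#' @return A `population_config` list.
#' @export
population_config <- function(n_populations = 5L,
                              n_per_population = 10L,
                              n_sites_per_gene = 20L,
                              differentiation_F = c(CHS = 0.08, GIH = 0.07,
                                                    GWD = 0.17, FIN = 0.09,
                                                    CLM = 0.07),
                              ancestral_freq_range = c(0.1, 0.9),
                              population_names = NULL,
                              seed = 1L) {
  stopifnot(
    n_populations >= 1L, n_per_population >= 1L, n_sites_per_gene >= 1L,
    all(differentiation_F >= 0), all(differentiation_F < 1),
    length(ancestral_freq_range) == 2L,
    ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
    ancestral_freq_range[1] <= ancestral_freq_range[2]
  )
  if (is.null(population_names)) {
    population_names <- if (!is.null(names(differentiation_F)) &&
                            length(differentiation_F) == n_populations) {
      names(differentiation_F)
    } else {
      sprintf("POP%d", seq_len(n_populations))
    }
  }
  stopifnot(length(population_names) == n_populations)
  F <- rep_len(unname(differentiation_F), n_populations)
  structure(
    list(
      n_populations = as.integer(n_populations),
      n_per_population = as.integer(n_per_population),
      n_sites_per_gene = as.integer(n_sites_per_gene),
      differentiation_F = setNames(F, population_names),
      ancestral_freq_range = ancestral_freq_range,
      population_names = population_names,
      seed = as.integer(seed)
    ),
    class = "population_config"
  )
}

#' Simulate multi-population diploid genotypes over a panel
#'
#' Sites are placed uniformly within gene bodies; genotypes are drawn under
#' the Balding–Nichols model described in [population_config()]. Only
#' autosomal-style diploid genotypes are produced (the emulated design
#' uses female samples only, so no sex contigs exist).
#'
#' @param panel A [panel()].
#' @param config A [population_config()].
#' @param ref Optional [reference()]; when given, site REF alleles are read
#'   from it and ALT alleles drawn among the other bases.
#' @return A list of class `camo_popsim`: `genotypes` (individuals x sites
#'   matrix of alt-allele dosages 0/1/2), `sites` (tibble: contig, pos, ref,
#'   alt), `individuals` (tibble: individual, population).
#' @export
simulate_population_genotypes <- function(panel, config, ref = NULL) {
  stopifnot(inherits(panel, "camo_panel"), inherits(config, "population_config"))
  with_seed(config$seed, {
    genes <- panel$genes
    sites <- lapply(seq_len(nrow(genes)), function(i) {
      width <- genes$end[i] - genes$start[i]
      k <- min(config$n_sites_per_gene, width)
      pos <- genes$start[i] + sort(sample.int(width, k)) - 1L
      tibble(contig = genes$contig[i], pos = pos, gene = genes$gene[i])
    })
    sites <- bind_rows(sites)
    n_sites <- nrow(sites)
    if (!is.null(ref)) {
      sites$ref <- vapply(seq_len(n_sites), function(i) {
        ref_seq(ref, sites$contig[i], sites$pos[i], sites$pos[i] + 1L)
      }, "")
    } else {
      sites$ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
    }
    sites$alt <- vapply(sites$ref, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, "")

    Fv <- config$differentiation_F
    npop <- config$n_populations
    nind <- config$n_per_population
    p_anc <- runif(n_sites, config$ancestral_freq_range[1],
                   config$ancestral_freq_range[2])
    geno <- matrix(0L, nrow = npop * nind, ncol = n_sites)
    individuals <- tibble(
      individual = sprintf("%s_%02d", rep(config$population_names, each = nind),
                           rep(seq_len(nind), npop)),
      population = rep(config$population_names, each = nind)
    )
    for (k in seq_len(npop)) {
      F <- Fv[k]
      q <- if (F == 0) p_anc else {
        rbeta(n_sites, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
      }
      rows <- (k - 1L) * nind + seq_len(nind)
      draws <- matrix(rbinom(nind * n_sites, 2L, rep(q, each = nind)),
                      nrow = nind)
      geno[rows, ] <- draws
    }
    rownames(geno) <- individuals$individual
    structure(
      list(genotypes = geno, sites = select(sites, -"gene"),
           site_genes = sites$gene, individuals = individuals),
      class = "camo_popsim"
    )
  })
}

#' @export
print.camo_popsim <- function(x, ...) {
  cat("<camo_popsim> ", nrow(x$genotypes), " individuals x ",
      ncol(x$genotypes), " sites, ",
      length(unique(x$individuals$population)), " populations\n", sep = "")
  invisible(x)
}

#' Per-individual VCF records from a population simulation
#'
#' @param popsim A [simulate_population_genotypes()] result.
#' @param individual Individual identifier.
#' @return VCF record tibble (as from [read_vcf()]) with the individual's
#'   genotypes; hom-ref sites are omitted.
#' @export
genotype_vcf <- function(popsim, individual) {
  stopifnot(inherits(popsim, "camo_popsim"))
  i <- match(individual, popsim$individuals$individual)
  if (is.na(i)) abort(paste0("unknown individual: ", individual))
  g <- popsim$genotypes[i, ]
  keep <- g > 0L
  rec <- popsim$sites[keep, ]
  out <- tibble(
    contig = rec$contig, pos = rec$pos, id = NA_character_,
    ref = rec$ref, alt = rec$alt, qual = NA_character_,
    filter = "PASS", info = NA_character_
  )
  out[[paste0("gt_", individual)]] <- c("0/1", "1/1")[g[keep]]
  attr(out, "samples") <- individual
  out
}

#' Write per-individual VCFs and a population manifest
#'
#' @param popsim A [simulate_population_genotypes()] result.
#' @param dir Output directory.
#' @param contig_lengths Named integer vector for VCF headers.
#' @return Tibble of written paths, invisibly.
#' @export
write_population_vcfs <- function(popsim, dir, contig_lengths = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(popsim$individuals$individual, function(ind) {
    p <- file.path(dir, paste0(ind, ".vcf"))
    write_vcf(genotype_vcf(popsim, ind), p, contig_lengths)
    p
  }, "")
  readr::write_tsv(popsim$individuals, file.path(dir, "individuals.tsv"))
  invisible(tibble(individual = popsim$individuals$individual, path = paths))
}

#' Plant a pathogenic-style variant in a panel gene
#'
#' Converting variants are placed at a position where the gene and its
#' pseudogene copy differ, with the alternate allele set to the pseudogene
#' base, so the variant locally converts the gene toward the pseudogene
#' sequence; the most isolated divergent site (largest distance to its
#' nearest neighbouring divergent site, preferring exonic positions) is
#' chosen. Non-converting variants are placed mid-exon outside any
#' homologous tract.
#'
#' @param genome A [make_reference()] result.
#' @param gene Gene name.
#' @param converting Should the alternate allele equal the pseudogene base at
#'   the aligned position?
#' @param zygosity `"hom"` or `"het"`.
#' @param exon Exon index used for non-converting placements (default: first
#'   exon clear of the tract).
#' @param seed Seed for the alternate-allele draw.
#' @return List with `variant` (tibble: contig, pos, ref, alt, zygosity,
#'   converting) and `vcf` (single-sample VCF record tibble).
#' @export
plant_variant <- function(genome, gene, converting = TRUE, zygosity = "hom",
                          exon = NULL, seed = 7L) {
  stopifnot(zygosity %in% c("hom", "het"))
  panel <- genome$panel
  if (!gene %in% panel$genes$gene) abort(paste0("unknown gene: ", gene))
  ct <- genome$camo_truth
  row <- ct[ct$gene == gene, ]
  exons <- panel$exons[panel$exons$gene == gene, ]

  if (converting) {
    if (nrow(row) != 1L) {
      abort(paste0("gene ", gene, " has no pseudogene copy; ",
                   "a converting variant requires one"))
    }
    offs <- camo_divergent_sites(genome, gene)
    if (length(offs) == 0L) {
      abort("gene and pseudogene are identical: no divergent position exists")
    }
    pos_all <- row$gene_tract_start + offs
    exonic <- vapply(pos_all, function(p) {
      any(exons$start <= p & p < exons$end)
    }, logical(1))
    cand <- if (any(exonic)) pos_all[exonic] else pos_all
    isolation <- vapply(cand, function(p) {
      others <- setdiff(pos_all, p)
      if (length(others) == 0L) Inf else min(abs(others - p))
    }, numeric(1))
    pos <- cand[which.max(isolation)]
    off <- pos - row$gene_tract_start
    ref_base <- ref_seq(genome$reference, row$contig, pos, pos + 1L)
    alt_base <- ref_seq(genome$reference, row$contig, row$pseudo_start + off,
                        row$pseudo_start + off + 1L)
  } else {
    in_tract <- function(s, e) {
      nrow(row) == 1L && s < row$gene_tract_end && e > row$gene_tract_start
    }
    free <- which(!vapply(seq_len(nrow(exons)), function(i) {
      in_tract(exons$start[i], exons$end[i])
    }, logical(1)))
    if (!is.null(exon)) free <- intersect(exon, seq_len(nrow(exons)))
    if (length(free) == 0L) abort("no exon clear of the homologous tract")
    e <- exons[free[1], ]
    pos <- e$start + (e$end - e$start) %/% 2L
    ref_base <- ref_seq(genome$reference, e$contig, pos, pos + 1L)
    alt_base <- with_seed(seed, sample(setdiff(c("A", "C", "G", "T"), ref_base), 1L))
  }
  if (ref_base == alt_base) abort("variant ref and alt alleles coincide")

  contig <- panel$genes$contig[panel$genes$gene == gene]
  variant <- tibble(
    contig = contig, pos = as.integer(pos), ref = ref_base, alt = alt_base,
    zygosity = zygosity, converting = converting, gene = gene
  )
  vcf <- tibble(
    contig = contig, pos = as.integer(pos), id = NA_character_,
    ref = ref_base, alt = alt_base, qual = NA_character_, filter = "PASS",
    info = NA_character_,
    gt_sample = if (zygosity == "hom") "1/1" else "0/1"
  )
  attr(vcf, "samples") <- "sample"
  list(variant = variant, vcf = vcf)
}
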