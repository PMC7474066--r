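test_that("zero differentiation gives near-zero FST and shared frequencies", {
  g <- small_genome()
  cfg <- population_config(n_populations = 4L, n_per_population = 15L,
                           n_sites_per_gene = 60L, differentiation_F = 0,
                           seed = 3L)
  ps <- simulate_population_genotypes(g$panel, cfg)
  est <- wc_fst(ps$genotypes, ps$individuals$population)$fst
  expect_lt(abs(est), 0.01)
})

test_that("the Balding-Nichols F parameter is recovered by the estimator", {
  g <- small_genome()
  base <- population_config(n_populations = 5L, n_per_population = 10L,
                            n_sites_per_gene = 250L,
                            differentiation_F = 0.1, seed = 101L)
  ps <- simulate_population_genotypes(g$panel, base)
  est <- wc_fst(ps$genotypes, ps$individuals$population)$fst
  # Monte-Carlo CI from independent re-simulations under the same model
  reps <- vapply(1:8, function(k) {
    cfg <- population_config(n_populations = 5L, n_per_population = 10L,
                             n_sites_per_gene = 250L,
                             differentiation_F = 0.1, seed = 1000L + k)
    p <- simulate_population_genotypes(g$panel, cfg)
    wc_fst(p$genotypes, p$individuals$population)$fst
  }, numeric(1))
  halfwidth <- 4 * sd(reps)
  expect_lt(abs(est - 0.1), max(halfwidth, 0.02))
  expect_lt(abs(mean(reps) - 0.1), 3 * sd(reps) / sqrt(length(reps)) + 0.01)
})

test_that("genotype tables and per-individual VCFs are mutually consistent", {
  g <- small_genome()
  ps <- simulate_population_genotypes(
    g$panel,
    population_config(n_populations = 2L, n_per_population = 3L,
                      n_sites_per_gene = 30L, seed = 8L),
    ref = g$reference
  )
  ind <- ps$individuals$individual[4]
  vcf <- genotype_vcf(ps, ind)
  dose <- ps$genotypes[ind, ]
  # VCF carries exactly the non-ref sites with matching genotype strings
  expect_equal(nrow(vcf), sum(dose > 0))
  key <- paste(ps$sites$contig, ps$sites$pos)
  vkey <- paste(vcf$contig, vcf$pos)
  expect_true(all(vkey %in% key))
  gts <- vcf[[paste0("gt_", ind)]]
  expect_equal(gts, c("0/1", "1/1")[dose[match(vkey, key)]])
  # REF alleles match the reference sequence
  refbases <- vapply(seq_len(nrow(vcf)), function(i) {
    ref_seq(g$reference, vcf$contig[i], vcf$pos[i], vcf$pos[i] + 1L)
  }, "")
  expect_equal(refbases, vcf$ref)
  # round-trip through disk
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vcf, p)
  expect_equal(read_vcf(p)$pos, vcf$pos)
})

test_that("fixed seeds give identical population simulations", {
  g <- small_genome()
  cfg <- population_config(seed = 77L, n_sites_per_gene = 10L)
  a <- simulate_population_genotypes(g$panel, cfg)
  b <- simulate_population_genotypes(g$panel, cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$sites, b$sites)
})

test_that("converting variants equalise the local gene/pseudogene window", {
  g <- small_genome()
  gene <- g$camo_truth$gene[2]  # 3 kb tract
  pv <- plant_variant(g, gene, converting = TRUE, zygosity = "hom")
  v <- pv$variant
  ct <- g$camo_truth[g$camo_truth$gene == gene, ]
  off <- v$pos - ct$gene_tract_start
  # alt allele equals the pseudogene base at the aligned position
  pb <- ref_seq(g$reference, ct$contig, ct$pseudo_start + off,
                ct$pseudo_start + off + 1L)
  expect_equal(v$alt, pb)
  expect_true(v$ref != v$alt)
  # after applying the variant, a 2x-read-length window around the site is
  # identical between gene and pseudogene
  cons <- build_consensus(g$reference, pv$vcf)
  w <- 150L
  lo <- max(off - w, 0L)
  hi <- min(off + w, ct$tract_length)
  gwin <- substr(cons[[ct$contig]], ct$gene_tract_start + lo + 1L,
                 ct$gene_tract_start + hi)
  pwin <- ref_seq(g$reference, ct$contig, ct$pseudo_start + lo,
                  ct$pseudo_start + hi)
  n_diff_before <- sum(strsplit(ref_seq(g$reference, ct$contig,
                                        ct$gene_tract_start + lo,
                                        ct$gene_tract_start + hi), "")[[1]] !=
                         strsplit(pwin, "")[[1]])
  expect_equal(sum(strsplit(gwin, "")[[1]] != strsplit(pwin, "")[[1]]),
               n_diff_before - 1L)
})

test_that("variant planting encodes zygosity and rejects impossible requests", {
  g <- small_genome()
  gene <- g$camo_truth$gene[1]
  het <- plant_variant(g, gene, converting = FALSE, zygosity = "het")
  expect_equal(het$vcf$gt_sample, "0/1")
  hom <- plant_variant(g, gene, converting = FALSE, zygosity = "hom")
  expect_equal(hom$vcf$gt_sample, "1/1")
  clean <- setdiff(g$panel$genes$gene, g$camo_truth$gene)[1]
  expect_error(plant_variant(g, clean, converting = TRUE),
               "converting|pseudogene")
  # identical copies leave no divergent site to convert
  ident <- make_reference(synthetic_genome_config(
    n_genes = 3L, n_camo_genes = 1L,
    camo_tracts = tibble::tibble(tract_length = 500L, identity = 1,
                                 profile = "uniform", core = NA_integer_),
    seed = 2L
  ))
  expect_error(plant_variant(ident, ident$camo_truth$gene[1],
                             converting = TRUE), "no divergent|identical")
})

test_that("non-converting variants leave cross-genome k-mer sharing unchanged", {
  g <- small_genome()
  clean <- setdiff(g$panel$genes$gene, g$camo_truth$gene)[1]
  pv <- plant_variant(g, clean, converting = FALSE, zygosity = "hom")
  cons <- build_consensus(g$reference, pv$vcf)
  k <- 31L
  v <- pv$variant
  window <- function(seqs) {
    s <- substr(seqs[[v$contig]], v$pos - k + 2L, v$pos + k)
    n <- nchar(s) - k + 1L
    substring(s, seq_len(n), seq_len(n) + k - 1L)
  }
  idx <- build_index(g$reference, k)
  before <- window(g$reference)
  after <- window(cons)
  # every k-mer across the variant site was unique before and is absent
  # from the (unmutated) genome after - no homolog shares it
  expect_true(all(vapply(before, function(km) nrow(index_lookup(idx, km)),
                         integer(1)) == 1L))
  expect_true(all(vapply(after, function(km) nrow(index_lookup(idx, km)),
                         integer(1)) == 0L))
})
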