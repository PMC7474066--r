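sim_fixture <- function(len = 100000L, read_length = 150L, seed = 1L,
                        error_rate = 0.0024, coverage = 20) {
  hap <- c(chr = random_seq(len, seed = 99L))
  regions <- tibble::tibble(contig = "chr", start = 0L, end = len)
  cfg <- simulation_config(read_length = read_length, error_rate = error_rate,
                           per_haplotype_coverage = coverage, seed = seed)
  list(hap = hap, regions = regions, cfg = cfg,
       reads = simulate_reads(hap, hap, regions, cfg))
}

source_window <- function(hap, contig, pos, len) {
  substr(hap[[contig]], pos + 1L, pos + len)
}

test_that("error-free reads are exact substrings at their truth coordinates", {
  fx <- sim_fixture(len = 20000L, error_rate = 0, coverage = 5)
  r <- fx$reads
  rl <- fx$cfg$read_length
  s1 <- ifelse(r$strand1 == "+",
               substring(fx$hap[["chr"]], r$pos1 + 1L, r$pos1 + rl),
               revcomp(substring(fx$hap[["chr"]], r$pos1 + 1L, r$pos1 + rl)))
  s2 <- ifelse(r$strand1 == "+",
               revcomp(substring(fx$hap[["chr"]], r$pos2 + 1L, r$pos2 + rl)),
               substring(fx$hap[["chr"]], r$pos2 + 1L, r$pos2 + rl))
  expect_identical(r$seq1, s1)
  expect_identical(r$seq2, s2)
})

test_that("combined two-haplotype depth is within 2% of 40X", {
  fx <- sim_fixture(len = 100000L)
  r <- fx$reads
  rl <- fx$cfg$read_length
  total_bases <- 2 * rl * nrow(r)
  expect_lt(abs(total_bases / 100000 - 40) / 40, 0.02)
  # truth-coordinate pileup confirms near-uniform coverage in the interior
  d <- integer(100001L)
  for (pos in list(r$pos1, r$pos2)) {
    d <- d + tabulate(pos + 1L, nbins = 100001L) -
      tabulate(pos + rl + 1L, nbins = 100001L)
  }
  dep <- cumsum(d)[1:100000]
  interior <- dep[2000:98000]
  expect_lt(abs(mean(interior) - 40) / 40, 0.02)
  # per-1kb-window coefficient of variation under 10%
  wins <- matrix(interior[1:96000], nrow = 1000)
  wmeans <- colMeans(wins)
  expect_lt(sd(wmeans) / mean(wmeans), 0.10)
})

test_that("the empirical substitution rate matches the configured 0.0024", {
  fx <- sim_fixture(len = 100000L)  # ~13 k pairs x 300 bases = 4 M bases
  r <- fx$reads
  rl <- fx$cfg$read_length
  exp1 <- ifelse(r$strand1 == "+",
                 substring(fx$hap[["chr"]], r$pos1 + 1L, r$pos1 + rl),
                 revcomp(substring(fx$hap[["chr"]], r$pos1 + 1L, r$pos1 + rl)))
  exp2 <- ifelse(r$strand1 == "+",
                 revcomp(substring(fx$hap[["chr"]], r$pos2 + 1L, r$pos2 + rl)),
                 substring(fx$hap[["chr"]], r$pos2 + 1L, r$pos2 + rl))
  mm <- function(a, b) {
    sum(vapply(seq_along(a), function(i) {
      sum(utf8ToInt(a[i]) != utf8ToInt(b[i]))
    }, numeric(1)))
  }
  n_bases <- 2 * rl * nrow(r)
  expect_gt(n_bases, 1e6)
  rate <- (mm(r$seq1, exp1) + mm(r$seq2, exp2)) / n_bases
  expect_lt(abs(rate - 0.0024) / 0.0024, 0.10)
})

test_that("inner distances follow the 50 +/- 10 model", {
  fx <- sim_fixture(len = 120000L)
  r <- fx$reads
  rl <- fx$cfg$read_length
  inner <- abs(r$pos2 - r$pos1) - rl
  expect_gt(nrow(r), 1e4)
  expect_lt(abs(mean(inner) - 50) / 50, 0.02)
  expect_lt(abs(sd(inner) - 10) / 10, 0.05)
  expect_true(all(inner >= 0))
})

test_that("truth names round-trip losslessly", {
  camoseq:::with_seed(10, {
    n <- 1e5
    truth <- tibble::tibble(
      individual = sample(c("ind1", "GWD_02", "s"), n, replace = TRUE),
      hap = sample(1:2, n, replace = TRUE),
      contig = sample(c("chrS", "ctg_9"), n, replace = TRUE),
      pos1 = sample.int(1e8, n) - 1L,
      pos2 = sample.int(1e8, n) - 1L,
      strand1 = sample(c("+", "-"), n, replace = TRUE),
      serial = seq_len(n)
    )
    ids <- encode_truth(truth$individual, truth$hap, truth$contig,
                        truth$pos1, truth$pos2, truth$strand1, truth$serial)
    back <- parse_truth(ids)
    expect_equal(as.data.frame(back), as.data.frame(truth))
  })
  expect_error(parse_truth("garbage"), "unparseable")
  expect_error(encode_truth("a|b", 1, "c", 1, 2, "+", 1), "must not contain")
})

test_that("fixed seeds give identical read sets", {
  a <- sim_fixture(len = 20000L, seed = 5L)$reads
  b <- sim_fixture(len = 20000L, seed = 5L)$reads
  expect_identical(a, b)
  c <- sim_fixture(len = 20000L, seed = 6L)$reads
  expect_false(identical(a$seq1, c$seq1))
})

test_that("reads exceeding the N limit are redrawn", {
  hap <- c(chr = random_seq(30000, seed = 42L))
  # hard-mask a 120 bp patch mid-region
  substr(hap[["chr"]], 15001, 15120) <- strrep("N", 120)
  regions <- tibble::tibble(contig = "chr", start = 0L, end = 30000L)
  cfg <- simulation_config(read_length = 150L, error_rate = 0,
                           per_haplotype_coverage = 10, seed = 2L,
                           max_n_per_read = 5L)
  reads <- simulate_reads(hap, hap, regions, cfg)
  nmax <- max(camoseq:::count_n(reads$seq1), camoseq:::count_n(reads$seq2))
  expect_lte(nmax, 5L)
})

test_that("short regions are skipped with a warning", {
  hap <- c(chr = random_seq(5000, seed = 1L))
  regions <- tibble::tibble(contig = "chr", start = c(0L, 4000L),
                            end = c(3000L, 4200L))
  cfg <- simulation_config(read_length = 150L, seed = 1L)
  expect_warning(r <- simulate_reads(hap, hap, regions, cfg), "skipped")
  expect_true(all(r$pos1 < 3000L))
})

test_that("variant read sets carry the planted allele at the expected rate", {
  g <- small_genome()
  gene <- setdiff(g$panel$genes$gene, g$camo_truth$gene)[1]
  pv <- plant_variant(g, gene, converting = FALSE, zygosity = "het")
  cfg <- simulation_config(read_length = 150L, error_rate = 0, seed = 3L)
  reads <- make_variant_readset(g$reference, g$panel, pv, cfg)
  v <- pv$variant
  alt_frac <- function(reads) {
    bases <- character()
    for (m in 1:2) {
      pos <- if (m == 1) reads$pos1 else reads$pos2
      seq <- if (m == 1) reads$seq1 else reads$seq2
      strand <- if (m == 1) reads$strand1 else
        ifelse(reads$strand1 == "+", "-", "+")
      ov <- which(pos <= v$pos & v$pos < pos + 150L)
      for (i in ov) {
        s <- if (strand[i] == "-") revcomp(seq[i]) else seq[i]
        bases <- c(bases, substr(s, v$pos - pos[i] + 1L, v$pos - pos[i] + 1L))
      }
    }
    mean(bases == v$alt)
  }
  f_het <- alt_frac(reads)
  expect_gt(f_het, 0.35)
  expect_lt(f_het, 0.65)
  pv_hom <- plant_variant(g, gene, converting = FALSE, zygosity = "hom")
  reads_hom <- make_variant_readset(g$reference, g$panel, pv_hom, cfg)
  expect_equal(alt_frac(reads_hom), 1)
  # variant outside the simulated regions is rejected
  far <- pv
  far$variant$pos <- 0L
  far$vcf$pos <- 0L
  expect_error(
    make_variant_readset(g$reference, g$panel, far, cfg,
                         regions = tibble::tibble(contig = "chrS",
                                                  start = 50000L,
                                                  end = 60000L)),
    "outside"
  )
})
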