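test_that("the seed index resolves unique, duplicated and N-containing k-mers", {
  ref <- dup_reference(dup_len = 500L)
  idx <- build_index(ref, 19L)
  # a k-mer inside the duplicated tract occurs twice
  dup_kmer <- ref_seq(ref, "ctgA", 2200, 2219)
  expect_equal(nrow(index_lookup(idx, dup_kmer)), 2L)
  # a k-mer outside occurs once
  uniq_kmer <- ref_seq(ref, "ctgA", 100, 119)
  expect_equal(nrow(index_lookup(idx, uniq_kmer)), 1L)
  # k-mers containing N are absent
  refN <- ref
  substr(refN[["ctgA"]], 101, 101) <- "N"
  idxN <- build_index(refN, 19L)
  expect_equal(nrow(index_lookup(idxN, uniq_kmer)), 0L)
})

test_that("unique reads map to their origin at the MAPQ cap", {
  ref <- dup_reference()
  idx <- build_index(ref, 19L)
  read <- ref_seq(ref, "ctgA", 4000, 4150)
  a <- map_reads(idx, tibble::tibble(id = "r", seq = read))
  expect_equal(a$contig, "ctgA")
  expect_equal(a$pos, 4000L)
  expect_equal(a$strand, "+")
  expect_equal(a$mapq, 60L)
  expect_equal(a$n_cand, 1L)
  # reverse-strand read maps back to the same locus
  b <- map_reads(idx, tibble::tibble(id = "r", seq = revcomp(read)))
  expect_equal(b$pos, 4000L)
  expect_equal(b$strand, "-")
  expect_equal(b$mapq, 60L)
})

test_that("reads inside an identical duplication tie at MAPQ 0", {
  ref <- dup_reference(dup_len = 500L)
  idx <- build_index(ref, 19L)
  read <- ref_seq(ref, "ctgA", 2100, 2250)  # wholly inside the copy
  a <- map_reads(idx, tibble::tibble(id = "r", seq = read))
  expect_equal(a$mapq, 0L)
  expect_equal(a$n_cand, 2L)
  expect_equal(a$score, a$score2)
  # deterministic tie-break: lowest (contig order, coordinate)
  expect_equal(a$contig, "ctgA")
  expect_equal(a$pos, 2100L)
  expect_equal(a$alt_contig, "ctgB")
})

test_that("reads with no seed hit are reported unmapped", {
  ref <- dup_reference()
  idx <- build_index(ref, 19L)
  a <- map_reads(idx, tibble::tibble(id = "r", seq = strrep("A", 50)))
  if (a$mapped) skip("poly-A present in random fixture")
  expect_false(a$mapped)
  expect_equal(a$mapq, 0L)
})

test_that("best loci agree with an exhaustive all-position oracle", {
  ref <- dup_reference(dup_len = 500L)  # 10 kb total
  idx <- build_index(ref, 19L)
  camoseq:::with_seed(21, {
    starts <- c(
      sample(0:5850, 6),            # anywhere on ctgA
      seq(1951, 2049, by = 24),     # straddling the tract boundary
      sample(0:3850, 4)             # ctgB
    )
    contigs <- rep(c("ctgA", "ctgA", "ctgB"), c(6, 5, 4))
    for (i in seq_along(starts)) {
      read <- ref_seq(ref, contigs[i], starts[i], starts[i] + 150)
      # inject up to 2 errors
      nerr <- sample(0:2, 1)
      if (nerr > 0) {
        ch <- strsplit(read, "")[[1]]
        at <- sample(150, nerr)
        ch[at] <- vapply(ch[at], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, "")
        read <- paste(ch, collapse = "")
      }
      a <- map_reads(idx, tibble::tibble(id = "r", seq = read))
      o <- oracle_best_locus(ref, read)
      expect_equal(a$score, o$score)
      if (a$mapq > 0L) {
        expect_equal(a$contig, o$contig)
        expect_equal(a$pos, o$pos)
        expect_equal(a$strand, o$strand)
      }
    }
  })
})

test_that("MAPQ grows monotonically with the score margin", {
  # progressively diverge the second copy: a read from copy A then leads
  # copy B by 5 score units per mismatch, and MAPQ = min(60, 6 x margin)
  base <- dup_reference(dup_len = 500L)
  read <- ref_seq(base, "ctgA", 2100, 2250)
  mapqs <- vapply(0:3, function(k) {
    ref <- base
    if (k > 0) {
      # the read's window on copy B is 1-based [1101, 1250]
      camoseq:::with_seed(50 + k, {
        for (at in sample(1110:1240, k)) {
          cur <- substr(ref[["ctgB"]], at, at)
          substr(ref[["ctgB"]], at, at) <-
            sample(setdiff(c("A", "C", "G", "T"), cur), 1)
        }
      })
    }
    idx <- build_index(ref, 19L)
    map_reads(idx, tibble::tibble(id = "r", seq = read))$mapq
  }, integer(1))
  expect_equal(mapqs[1], 0L)
  expect_true(all(diff(mapqs) >= 0L))
  expect_equal(mapqs[3:4], c(60L, 60L))
  expect_equal(mapqs[2], 30L)
})

test_that("a uniquely mapped mate rescues its tied partner", {
  ref <- dup_reference(dup_len = 500L)
  idx <- build_index(ref, 19L)
  # read1 unique (left of the tract on ctgA), read2 inside the identical copy
  r1 <- ref_seq(ref, "ctgA", 1800, 1950)
  r2 <- revcomp(ref_seq(ref, "ctgA", 2150, 2300))
  pairs <- tibble::tibble(qname = "p", seq1 = r1, seq2 = r2)
  aln <- map_read_pairs(idx, pairs, fragment_mean = 500, fragment_sd = 10)
  m2 <- aln[aln$mate == 2L, ]
  expect_equal(m2$contig, "ctgA")
  expect_equal(m2$pos, 2150L)
  expect_gt(m2$mapq, 0L)
  expect_true(all(aln$proper))
  expect_equal(abs(aln$tlen), c(500L, 500L))
  # both mates inside the identical copy: no rescue possible
  both <- tibble::tibble(
    qname = "q",
    seq1 = ref_seq(ref, "ctgA", 2020, 2170),
    seq2 = revcomp(ref_seq(ref, "ctgA", 2320, 2470))
  )
  aln2 <- map_read_pairs(idx, both, fragment_mean = 450, fragment_sd = 10)
  expect_equal(aln2$mapq, c(0L, 0L))
  # tie broken to the lowest coordinate (ctgA copy)
  expect_equal(aln2$contig, c("ctgA", "ctgA"))
})

test_that("a longer inner distance rescues where a short one cannot", {
  # construct: identical 700 bp duplication; pair with read2 inside it;
  # with inner 50 the mate also falls inside (no anchor), with inner 255
  # the mate lands outside the tract and anchors the pair
  camoseq:::with_seed(31, {
    a <- random_seq(6000)
    dup <- substr(a, 3001, 3700)
    b <- random_seq(3000)
    substr(b, 1001, 1700) <- dup
    ref <- reference(c(ctgA = a, ctgB = b))
  })
  idx <- build_index(ref, 19L)
  rl <- 150L
  # read1 at the left end of the tract region, read2 to its right
  short_r1 <- ref_seq(ref, "ctgA", 3100, 3100 + rl)
  short_r2 <- revcomp(ref_seq(ref, "ctgA", 3400, 3400 + rl))  # inner 150... still inside
  pairs_short <- tibble::tibble(qname = "s", seq1 = short_r1,
                                seq2 = short_r2)
  aln_s <- map_read_pairs(idx, pairs_short, fragment_mean = 450,
                          fragment_sd = 10)
  expect_equal(aln_s$mapq, c(0L, 0L))
  long_r2 <- revcomp(ref_seq(ref, "ctgA", 3655, 3655 + rl))  # leaves tract
  pairs_long <- tibble::tibble(qname = "l", seq1 = short_r1, seq2 = long_r2)
  aln_l <- map_read_pairs(idx, pairs_long, fragment_mean = 705,
                          fragment_sd = 10)
  m1 <- aln_l[aln_l$mate == 1L, ]
  expect_equal(m1$pos, 3100L)
  expect_gt(m1$mapq, 0L)
})

test_that("paired mapping is deterministic down to SAM bytes", {
  g <- small_genome()
  cfg <- simulation_config(read_length = 100L, per_haplotype_coverage = 2,
                           seed = 12L)
  regs <- simulation_regions(g$panel, reference_lengths(g$reference))
  reads <- simulate_reads(g$reference, g$reference,
                          regs[1:3, c("contig", "start", "end")], cfg)
  idx <- build_index(g$reference, 19L)
  a1 <- map_read_pairs(idx, reads, 250, 10)
  a2 <- map_read_pairs(idx, reads, 250, 10)
  p1 <- withr::local_tempfile(fileext = ".sam")
  p2 <- withr::local_tempfile(fileext = ".sam")
  write_sam(a1, reference_lengths(g$reference), p1)
  write_sam(a2, reference_lengths(g$reference), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("reads from unique sequence always map correctly with MAPQ >= 10", {
  g <- small_genome()
  camo <- g$camo_truth
  cfg <- simulation_config(read_length = 150L, per_haplotype_coverage = 1,
                           seed = 9L, error_rate = 0)
  regs <- simulation_regions(g$panel, reference_lengths(g$reference))
  clean_regs <- regs[!regs$gene %in% camo$gene, c("contig", "start", "end")]
  reads <- simulate_reads(g$reference, g$reference, clean_regs, cfg)
  idx <- build_index(g$reference, 19L)
  aln <- map_read_pairs(idx, reads, 350, 10)
  cls <- classify_reads(aln)
  expect_true(all(cls$class == "correct"))
  expect_true(all(cls$mapq >= 10L))
})
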