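mk_aln <- function(contig, pos, mapq, len = 150L, qname = NULL, mate = 1L,
                   strand = "+", seq = NULL) {
  n <- length(pos)
  tibble::tibble(
    qname = qname %||% sprintf("r%d", seq_len(n)),
    mate = rep_len(mate, n),
    contig = contig, pos = as.integer(pos),
    strand = rep_len(strand, n),
    mapq = as.integer(mapq),
    score = len, score2 = NA_integer_, n_cand = 1L,
    alt_contig = NA_character_, alt_pos = NA_integer_,
    alt_strand = NA_character_,
    cigar = paste0(len, "M"),
    seq = seq %||% strrep("A", len),
    qual = strrep("I", len),
    mapped = TRUE, proper = TRUE, tlen = NA_integer_,
    mate_contig = contig, mate_pos = as.integer(pos),
    mate_strand = "-", mate_mapped = TRUE
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("read classification follows the MQ and position-tolerance rules", {
  qn <- encode_truth("i", 1L, "c1", 500L, 800L, "+", 1L)
  base <- mk_aln("c1", 500L, 60L, qname = qn)
  expect_equal(classify_reads(base)$class, "correct")
  # within tolerance still correct; beyond is incorrect
  expect_equal(classify_reads(mk_aln("c1", 519L, 60L, qname = qn))$class,
               "correct")
  expect_equal(classify_reads(mk_aln("c1", 521L, 60L, qname = qn))$class,
               "incorrect")
  # pseudogene placement: wrong locus
  expect_equal(classify_reads(mk_aln("c1", 9000L, 27L, qname = qn))$class,
               "incorrect")
  # MQ below 10 counts as unmapped even at the true position
  expect_equal(classify_reads(mk_aln("c1", 500L, 5L, qname = qn))$class,
               "unmapped")
  # wrong strand is incorrect
  wrong <- mk_aln("c1", 500L, 60L, qname = qn, strand = "-")
  expect_equal(classify_reads(wrong)$class, "incorrect")
  # mate 2 checks pos2 and the flipped strand
  m2 <- mk_aln("c1", 800L, 60L, qname = qn, mate = 2L, strand = "-")
  expect_equal(classify_reads(m2)$class, "correct")
  expect_error(classify_reads(mk_aln("c1", 1L, 60L, qname = "bad")),
               "unparseable")
})

test_that("classification summaries are order-invariant and complete", {
  qn <- vapply(1:6, function(i) encode_truth("i", 1L, "c1", i * 100L,
                                             i * 100L + 300L, "+", i), "")
  aln <- mk_aln("c1", c(100L, 200L, 300L, 9000L, 500L, 600L),
                c(60L, 60L, 5L, 60L, 60L, 60L), qname = qn)
  s1 <- summarize_classification(classify_reads(aln))
  s2 <- summarize_classification(classify_reads(aln[sample(6), ]))
  expect_equal(s1, s2)
  expect_equal(s1$n_correct, 4L)
  expect_equal(s1$n_incorrect, 1L)
  expect_equal(s1$n_unmapped, 1L)
  expect_equal(s1$pct_correct + s1$pct_incorrect + s1$pct_unmapped, 100)
})

test_that("depth tracks agree with a manual pileup oracle", {
  regions <- tibble::tibble(contig = "c1", start = 0L, end = 1000L)
  lens <- c(c1 = 1000L)
  # one alignment covers exactly its 150 bases
  d1 <- depth_track(mk_aln("c1", 100L, 60L), regions, lens, mq_min = 10L)
  expect_equal(sum(d1$depth$c1), 150L)
  expect_equal(unique(d1$depth$c1[101:250]), 1L)
  # MAPQ 0 contributes nowhere at mq_min 10
  d2 <- depth_track(mk_aln("c1", 100L, 0L), regions, lens, mq_min = 10L)
  expect_equal(sum(d2$depth$c1), 0L)
  # two half-overlapping alignments: depth 2 on the 75 bp overlap
  a <- mk_aln("c1", c(100L, 175L), c(60L, 60L))
  d3 <- depth_track(a, regions, lens, mq_min = 10L)
  expect_equal(unique(d3$depth$c1[176:250]), 2L)
  expect_equal(unique(d3$depth$c1[101:175]), 1L)
  expect_equal(unique(d3$depth$c1[251:325]), 1L)
  # zero outside regions
  d4 <- depth_track(mk_aln("c1", 100L, 60L),
                    tibble::tibble(contig = "c1", start = 0L, end = 120L),
                    lens, mq_min = 10L)
  expect_equal(sum(d4$depth$c1[121:1000]), 0L)
})

depth_fixture <- function(values, start = 0L) {
  structure(
    list(
      depth = list(c1 = as.integer(values)),
      regions = tibble::tibble(contig = "c1", start = start,
                               end = start + length(values), gene = "g1"),
      mq_min = 20L
    ),
    class = "camo_depth"
  )
}

pn_fixture <- panel(
  tibble::tibble(contig = "c1", start = 0L, end = 10000L, gene = "g1"),
  tibble::tibble(contig = "c1", start = 300L, end = 400L, gene = "g1",
                 name = "e1"),
  buffer = 70L
)

test_that("camo-region calling merges across the <= 50 bp rule boundary", {
  # two 30 bp low runs separated by exactly 50 high bases merge
  v <- rep(40L, 400)
  v[101:130] <- 5L
  v[181:210] <- 5L
  camo <- call_camo_regions(depth_fixture(v), pn_fixture)
  expect_equal(nrow(camo), 1L)
  expect_equal(c(camo$start, camo$end), c(100L, 210L))
  # 51 separating bases stay split
  v2 <- rep(40L, 400)
  v2[101:130] <- 5L
  v2[182:211] <- 5L
  camo2 <- call_camo_regions(depth_fixture(v2), pn_fixture)
  expect_equal(nrow(camo2), 2L)
  # uniform depth 40: nothing called
  expect_equal(nrow(call_camo_regions(depth_fixture(rep(40L, 400)),
                                      pn_fixture)), 0L)
  # depth exactly 20 is not low; 19 is
  v3 <- rep(20L, 100)
  expect_equal(nrow(call_camo_regions(depth_fixture(v3), pn_fixture)), 0L)
  v3[50] <- 19L
  camo3 <- call_camo_regions(depth_fixture(v3), pn_fixture)
  expect_equal(c(camo3$start, camo3$end), c(49L, 50L))
})

test_that("camo calling agrees with a per-base set-then-merge oracle", {
  camoseq:::with_seed(33, {
    for (rep in 1:10) {
      v <- as.integer(pmax(0, round(rnorm(2000, mean = 22, sd = 6))))
      camo <- call_camo_regions(depth_fixture(v), pn_fixture)
      low <- which(v < 20L) - 1L
      want <- if (length(low) == 0L) {
        tibble::tibble(start = integer(), end = integer())
      } else {
        oracle_merge(tibble::tibble(contig = "c1", start = low,
                                    end = low + 1L), gap = 50L)
      }
      expect_equal(camo$start, want$start)
      expect_equal(camo$end, want$end)
      # idempotence: re-calling on a masked track reproduces itself
      camo_again <- call_camo_regions(depth_fixture(v), pn_fixture)
      expect_identical(camo, camo_again)
    }
  })
})

test_that("camo annotations count reads, non-unique reads and alt loci", {
  v <- rep(40L, 1000)
  v[301:400] <- 2L
  aln <- mk_aln("c1", c(250L, 320L, 500L), c(0L, 60L, 60L))
  aln$alt_contig[1] <- "c1"
  aln$alt_pos[1] <- 5000L
  camo <- call_camo_regions(depth_fixture(v), pn_fixture, aln = aln)
  expect_equal(nrow(camo), 1L)
  expect_true(camo$exonic)  # overlaps exon [300, 400)
  expect_equal(camo$n_reads, 2L)       # reads at 250 and 320 overlap
  expect_equal(camo$n_nonunique, 1L)   # the MAPQ-0 read
  alt <- camo$alt_locations[[1]]
  expect_equal(c(alt$start, alt$end), c(5000L, 5150L))
  # requiring non-unique support drops sampling dips
  aln2 <- mk_aln("c1", c(250L, 320L), c(60L, 60L))
  expect_equal(nrow(call_camo_regions(depth_fixture(v), pn_fixture,
                                      aln = aln2)), 0L)
  expect_equal(nrow(call_camo_regions(depth_fixture(v), pn_fixture,
                                      aln = aln2,
                                      require_nonunique = FALSE)), 1L)
})

test_that("rescue classification follows the read-length status rules", {
  pn <- panel(
    tibble::tibble(contig = "c", start = (0:3) * 1000L,
                   end = (0:3) * 1000L + 900L,
                   gene = paste0("g", 1:4)),
    tibble::tibble(contig = "c", start = (0:3) * 1000L + 100L,
                   end = (0:3) * 1000L + 200L, gene = paste0("g", 1:4),
                   name = paste0("e", 1:4))
  )
  camo_tbl <- function(genes) {
    tibble::tibble(contig = "c", start = 0L, end = 10L, gene = genes)
  }
  camo <- list(
    `70` = camo_tbl(c("g1", "g2")),
    `150` = camo_tbl("g1"),
    `250` = camo_tbl("g1")
  )
  rt <- read_length_rescue_table(camo, pn)
  expect_equal(rt$status[rt$gene == "g1"], "low_at_all_lengths")
  expect_equal(rt$status[rt$gene == "g2"], "rescued_by_longer")
  expect_equal(rt$status[rt$gene == "g3"], "never_low")
  expect_error(read_length_rescue_table(camo["70"], pn), "two read lengths")
})
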