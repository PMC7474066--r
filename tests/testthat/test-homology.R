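test_that("mappability agrees with a brute-force k-mer count oracle", {
  # exact duplication fixture (10 kb) checked against full enumeration
  ref <- dup_reference(dup_len = 500L)
  refN <- ref
  substr(refN[["ctgA"]], 151, 151) <- "N"
  for (k in c(15L, 75L)) {
    track <- compute_mappability(refN, k)
    want <- oracle_kmer_counts(refN, k)
    for (ctg in names(refN)) {
      expect_equal(track$values[[ctg]],
                   ifelse(want[[ctg]] > 0, 1 / want[[ctg]], 0))
    }
  }
  expect_error(compute_mappability(ref, 20L), "odd")
})

test_that("mappability reflects copy number: 1, 1/2, 1/3", {
  camoseq:::with_seed(13, {
    a <- random_seq(4000)
    tract <- substr(a, 1001, 1500)
    b <- paste0(random_seq(800), tract, random_seq(800))
    c <- paste0(random_seq(500), tract, random_seq(500))
    ref2 <- reference(c(x = a, y = b))
    ref3 <- reference(c(x = a, y = b, z = c))
  })
  t1 <- compute_mappability(ref2, 75L)
  # interior positions of the duplicated tract score 1/2
  expect_equal(unique(t1$values[["x"]][1001:1426]), 0.5)
  expect_equal(unique(t1$values[["x"]][1:900]), 1)
  t2 <- compute_mappability(ref3, 75L)
  expect_equal(unique(t2$values[["x"]][1001:1426]), 1 / 3)
})

test_that("exon means follow the <= 0.5 flag rule, including boundaries", {
  camoseq:::with_seed(14, {
    a <- random_seq(6000)
    tract <- substr(a, 2001, 3000)
    ref <- reference(c(x = paste0(a, tract, random_seq(500))))
  })
  track <- compute_mappability(ref, 75L)
  exon_in <- tibble::tibble(contig = "x", start = 2200L, end = 2500L,
                            gene = "g", name = "in")
  exon_out <- tibble::tibble(contig = "x", start = 500L, end = 800L,
                             gene = "g", name = "out")
  # half in the 2-copy tract, half unique
  exon_half <- tibble::tibble(contig = "x", start = 1780L, end = 2380L,
                              gene = "g", name = "half")
  em <- exon_mean_mappability(track, rbind(exon_in, exon_out, exon_half))
  expect_equal(em$mean_mappability[1], 0.5)
  expect_true(em$flagged[1])           # exactly 0.5 flags (inclusive rule)
  expect_equal(em$mean_mappability[2], 1)
  expect_false(em$flagged[2])
  expect_gt(em$mean_mappability[3], 0.5)
  expect_false(em$flagged[3])
})

test_that("homology search finds planted copies and excludes the self-hit", {
  camoseq:::with_seed(15, {
    a <- random_seq(8000)
    exon <- substr(a, 3001, 3200)  # 200 bp query
    mutated <- strsplit(exon, "")[[1]]
    at <- sort(sample(20:180, 4))
    for (i in at) mutated[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                               mutated[i]), 1)
    b <- paste0(random_seq(1000), paste(mutated, collapse = ""),
                random_seq(1000))
    ref <- reference(c(x = a, y = b))
  })
  widx <- build_index(ref, 11L)
  origin <- tibble::tibble(contig = "x", start = 3000L, end = 3200L)
  hits <- homology_search(widx, exon, origin = origin)
  real <- hits[hits$alignment_length >= 190, ]
  expect_equal(nrow(real), 1L)
  expect_equal(real$contig, "y")
  expect_equal(real$mismatches, 4L)
  expect_equal(real$strand, "+")
  # without a planted copy, only the (excluded) self-hit exists
  widx_a <- build_index(reference(ref["x"]), 11L)
  solo <- homology_search(widx_a, exon, origin = origin)
  expect_equal(nrow(solo[solo$alignment_length >= 190, ]), 0L)
  # self-hit present when origin is not declared
  noex <- homology_search(widx_a, exon)
  self <- noex[noex$alignment_length == 200, ]
  expect_equal(nrow(self), 1L)
  expect_equal(self$sstart, 3000L)
  expect_equal(self$mismatches, 0L)
})

test_that("the mismatch/length filter keeps inclusive boundaries", {
  mk <- function(mm, len, ql = 300L) {
    tibble::tibble(contig = "x", sstart = 0L, send = len, qstart = 0L,
                   qend = len, alignment_length = len, mismatches = mm,
                   gaps = 0L, strand = "+", query_length = ql)
  }
  expect_equal(nrow(filter_hits(mk(10L, 290L))), 1L)  # mm=10, diff=10 kept
  expect_equal(nrow(filter_hits(mk(11L, 300L))), 0L)  # mm=11 dropped
  expect_equal(nrow(filter_hits(mk(0L, 289L))), 0L)   # diff=11 dropped
  expect_equal(nrow(filter_hits(mk(0L, 310L))), 1L)   # longer by 10 kept
  expect_error(filter_hits(dplyr::select(mk(0L, 300L), -query_length)),
               "query length")
})

test_that("a copy with 11 mismatches is found but fails the filter", {
  camoseq:::with_seed(16, {
    a <- random_seq(6000)
    exon <- substr(a, 2001, 2300)
    mutated <- strsplit(exon, "")[[1]]
    for (i in sample(seq(25, 275, by = 22), 11)) {
      mutated[i] <- sample(setdiff(c("A", "C", "G", "T"), mutated[i]), 1)
    }
    ref <- reference(c(
      x = a, y = paste0(random_seq(600), paste(mutated, collapse = ""),
                        random_seq(600))
    ))
  })
  widx <- build_index(ref, 11L)
  hits <- homology_search(widx, exon,
                          origin = tibble::tibble(contig = "x",
                                                  start = 2000L, end = 2300L))
  hits$query_length <- 300L
  real <- hits[hits$contig == "y" & hits$alignment_length >= 280, ]
  expect_equal(nrow(real), 1L)
  expect_gte(real$mismatches, 11L)
  expect_equal(nrow(filter_hits(real)), 0L)
})

test_that("gene flagging uses union semantics and is monotone", {
  pn <- panel(
    tibble::tibble(contig = "c", start = c(0L, 1000L), end = c(900L, 1900L),
                   gene = c("g1", "g2")),
    tibble::tibble(contig = "c", start = c(100L, 1100L),
                   end = c(200L, 1200L), gene = c("g1", "g2"),
                   name = c("e1", "e2"))
  )
  em <- tibble::tibble(gene = c("g1", "g2"), flagged = c(TRUE, FALSE))
  no_hits <- tibble::tibble(gene = character())
  f1 <- flag_panel(pn, em, no_hits)
  expect_equal(f1$flagged, c(TRUE, FALSE))
  hits <- tibble::tibble(gene = "g2")
  f2 <- flag_panel(pn, em, hits)
  expect_equal(f2$flagged, c(TRUE, TRUE))
  # monotone: adding hits never unflags
  expect_true(all(f2$flagged >= f1$flagged))
})

test_that("short queries warn and yield no hits", {
  ref <- dup_reference()
  widx <- build_index(ref, 11L)
  expect_warning(h <- homology_search(widx, "ACGTACG"), "shorter")
  expect_equal(nrow(h), 0L)
})
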