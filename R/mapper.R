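#' Mapper configuration
#'
#' Scoring uses the conventional short-read penalty set — mismatch 4, gap
#' open 6, gap extend 1 (`-B 4 -O 6 -E 1` in common mapper notation) — with
#' the implicit match bonus of 1. Candidate loci come from exact seed
#' hits on both strands; each candidate is scored over the full read
#' (match +1, mismatch -4; no indels exist in the simulated data, so gapped
#' and ungapped extension coincide — the gap penalties are retained in the
#' configuration for the record). MAPQ is `min(cap, 6 x (S1 - S2))` with the
#' second-best score taken as 0 for single-candidate reads and MAPQ 0 on
#' ties. A mate whose candidates tie is rescued when the other mate maps
#' uniquely: candidates forming a proper pair within the fragment window
#' (mean +/- `pair_window_sd` x sd) receive `pair_bonus` (default 17, the
#' conventional unpaired penalty), lifting the rescued mate's MAPQ above
#' the MQ 10 and MQ 20 working thresholds. The bonus exceeds the score
#' differential of a single substitution (match + mismatch = 5), so a
#' properly paired placement with one mismatch still beats an unpaired
#' perfect match elsewhere — the geometry a converting variant creates.
#'
#' @param seed_length Exact-match seed length (bp).
#' @param match,mismatch_penalty,gap_open,gap_extend Alignment scores.
#' @param mapq_cap Maximum MAPQ.
#' @param pair_window_sd Mate-rescue window half-width in fragment-length
#'   standard deviations.
#' @param pair_bonus Score bonus for properly paired candidates.
#' @return A `mapper_config` list.
#' @export
mapper_config <- function(seed_length = 19L, match = 1L, mismatch_penalty = 4L,
                          gap_open = 6L, gap_extend = 1L, mapq_cap = 60L,
                          pair_window_sd = 4, pair_bonus = 17L) {
  stopifnot(seed_length >= 8L, mismatch_penalty >= 0L, gap_open >= 0L,
            gap_extend >= 0L, mapq_cap > 0L, pair_window_sd > 0,
            pair_bonus >= 0L)
  structure(
    list(seed_length = as.integer(seed_length), match = as.integer(match),
         mismatch_penalty = as.integer(mismatch_penalty),
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         mapq_cap = as.integer(mapq_cap), pair_window_sd = pair_window_sd,
         pair_bonus = as.integer(pair_bonus)),
    class = "mapper_config"
  )
}

#' Build a seed index over a reference
#'
#' Indexes every `seed_length`-mer of the forward strand (reverse-strand
#' hits are found by looking up the reverse complement of the read); k-mers
#' containing `N` are excluded, so masked regions cannot anchor seeds.
#'
#' @param ref A [reference()].
#' @param seed_length Seed length (<= 31).
#' @return A `camo_index` object.
#' @export
build_index <- function(ref, seed_length = 19L) {
  ref <- reference(ref)
  structure(
    list(ptr = cpp_build_index(ref, seed_length),
         contigs = names(ref),
         lengths = reference_lengths(ref),
         seed_length = as.integer(seed_length)),
    class = "camo_index"
  )
}

#' @export
print.camo_index <- function(x, ...) {
  cat("<camo_index> ", length(x$contigs), " contig(s), ",
      sum(x$lengths), " bp, seed length ", x$seed_length, "\n", sep = "")
  invisible(x)
}

#' Look up a seed k-mer in the index
#' @param index A [build_index()] result.
#' @param kmer Character scalar of length `seed_length`.
#' @return Tibble of (contig, pos) forward-strand occurrences.
#' @export
index_lookup <- function(index, kmer) {
  hits <- cpp_index_lookup(index$ptr, kmer)
  tibble(contig = index$contigs[hits$contig], pos = hits$pos)
}

mate_tibble <- function(m, index, ids, seqs, quals, mate_no) {
  strand <- c("+", "-")[m$strand + 1L]
  mapped <- m$contig > 0L
  seq_out <- ifelse(mapped & strand == "-", revcomp(seqs), seqs)
  tibble(
    qname = ids,
    mate = mate_no,
    contig = ifelse(mapped, index$contigs[pmax(m$contig, 1L)], NA_character_),
    pos = m$pos,
    strand = ifelse(mapped, strand, NA_character_),
    mapq = m$mapq,
    score = m$score,
    score2 = m$score2,
    n_cand = m$n_cand,
    alt_contig = ifelse(m$alt_contig > 0L,
                        index$contigs[pmax(m$alt_contig, 1L)], NA_character_),
    alt_pos = m$alt_pos,
    alt_strand = ifelse(m$alt_contig > 0L, c("+", "-")[m$alt_strand + 1L],
                        NA_character_),
    cigar = paste0(nchar(seqs), "M"),
    seq = seq_out,
    qual = quals,
    mapped = mapped
  )
}

#' Map single-end reads
#'
#' @param index A [build_index()] result.
#' @param reads Tibble with columns `id` and `seq` (optionally `qual`).
#' @param config A [mapper_config()].
#' @return Alignment tibble, one row per read; `mapped = FALSE` rows record
#'   reads with no seed hit anywhere.
#' @export
map_reads <- function(index, reads, config = mapper_config()) {
  stopifnot(inherits(index, "camo_index"))
  if (index$seed_length != config$seed_length) {
    abort("index and config disagree on seed length")
  }
  qual <- if ("qual" %in% names(reads)) reads$qual else
    strrep("I", nchar(reads$seq))
  m <- cpp_map_single(index$ptr, reads$seq, config$mismatch_penalty,
                      config$mapq_cap)
  aln <- mate_tibble(m, index, reads$id, reads$seq, qual, 1L)
  aln$proper <- FALSE
  aln$tlen <- NA_integer_
  aln$mate_contig <- NA_character_
  aln$mate_pos <- NA_integer_
  aln$mate_strand <- NA_character_
  aln$mate_mapped <- FALSE
  aln
}

#' Map paired-end reads with proper-pair rescue
#'
#' @param index A [build_index()] result.
#' @param pairs Read-pair tibble from [simulate_reads()] (columns `qname`,
#'   `seq1`, `seq2`, optionally `qual1`/`qual2`).
#' @param fragment_mean,fragment_sd Fragment-length model (total fragment:
#'   `2 x read_length + inner distance`).
#' @param config A [mapper_config()].
#' @return Alignment tibble with two rows per pair (`mate` 1 and 2),
#'   including mate fields, `proper` flag and signed `tlen`.
#' @export
map_read_pairs <- function(index, pairs, fragment_mean, fragment_sd,
                           config = mapper_config()) {
  stopifnot(inherits(index, "camo_index"))
  if (index$seed_length != config$seed_length) {
    abort("index and config disagree on seed length")
  }
  window <- config$pair_window_sd * fragment_sd
  res <- cpp_map_pairs(index$ptr, pairs$seq1, pairs$seq2, fragment_mean,
                       window, config$pair_bonus, config$mismatch_penalty,
                       config$mapq_cap)
  q1 <- if ("qual1" %in% names(pairs)) pairs$qual1 else
    strrep("I", nchar(pairs$seq1))
  q2 <- if ("qual2" %in% names(pairs)) pairs$qual2 else
    strrep("I", nchar(pairs$seq2))
  a1 <- mate_tibble(res$mate1, index, pairs$qname, pairs$seq1, q1, 1L)
  a2 <- mate_tibble(res$mate2, index, pairs$qname, pairs$seq2, q2, 2L)
  cross <- function(x, y) {
    x$proper <- res$proper
    x$mate_contig <- y$contig
    x$mate_pos <- y$pos
    x$mate_strand <- y$strand
    x$mate_mapped <- y$mapped
    x
  }
  a1 <- cross(a1, a2)
  a2 <- cross(a2, a1)
  # signed template length: positive for the leftmost mate
  tl <- res$tlen
  sign1 <- if_else(!is.na(tl) & a1$pos <= a2$pos, 1L, -1L)
  a1$tlen <- tl * sign1
  a2$tlen <- -a1$tlen
  bind_rows(a1, a2)
}
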