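#' Compute a k-mer mappability (alignability) track
#'
#' For every position admitting a full k-mer, the value is the reciprocal of
#' the number of exact occurrences of that k-mer in the genome, counting both
#' strands — 1 for unique k-mers, 0.5 for two copies, and so on. Positions
#' whose k-mer contains `N` score 0. Exact matching is used (the track this
#' emulates tolerates small edit distance; at the >=97% identities studied
#' here, exact 75-mer sharing still occurs throughout homologous tracts).
#'
#' @param ref A [reference()].
#' @param k Word length (default 75).
#' @return A `camo_mappability` object: per-contig numeric vectors in
#'   `[0, 1]` of length `contig length - k + 1` (empty for contigs shorter
#'   than `k`).
#' @export
compute_mappability <- function(ref, k = 75L) {
  stopifnot(k >= 1L)
  if (k %% 2L == 0L) {
    # odd k rules out reverse-complement palindromes (which would double count)
    abort("k must be odd")
  }
  counts <- cpp_kmer_counts(reference(ref), k)
  values <- lapply(counts, function(v) ifelse(v > 0L, 1 / v, 0))
  structure(list(values = setNames(values, names(ref)), k = as.integer(k)),
            class = "camo_mappability")
}

#' @export
print.camo_mappability <- function(x, ...) {
  cat("<camo_mappability> k = ", x$k, ", ", length(x$values),
      " contig(s)\n", sep = "")
  invisible(x)
}

#' Mean mappability per buffered exon
#'
#' Averages the track over each buffered exon and flags exons whose mean is
#' at or below the threshold — the conservative reading of the "include all
#' genes that may have regions of poor alignability" rule. Exons with no
#' position admitting a full k-mer get an undefined mean and are flagged.
#'
#' @param track A [compute_mappability()] result.
#' @param exons Buffered-exon tibble from [buffered_exons()].
#' @param threshold Flag when mean mappability `<=` this value (default 0.5).
#' @return `exons` with `mean_mappability` and `flagged` columns.
#' @export
exon_mean_mappability <- function(track, exons, threshold = 0.5) {
  stopifnot(inherits(track, "camo_mappability"))
  validate_intervals(exons)
  means <- vapply(seq_len(nrow(exons)), function(i) {
    v <- track$values[[exons$contig[i]]]
    if (is.null(v)) abort(paste0("no track for contig ", exons$contig[i]))
    lo <- exons$start[i] + 1L
    hi <- min(exons$end[i], length(v))
    if (lo > hi) return(NA_real_)
    mean(v[lo:hi])
  }, numeric(1))
  exons$mean_mappability <- means
  exons$flagged <- is.na(means) | means <= threshold
  exons
}

#' Search a query sequence against the genome
#'
#' Word-seeded (default word size 11), ungapped X-drop extension with the
#' mapper's match/mismatch scores, on both strands. The self-hit (a subject
#' interval identical to the query's own coordinates) is excluded when the
#' query origin is supplied.
#'
#' @param index A word index from [build_index()] (use
#'   `build_index(ref, word_size)`).
#' @param query Query sequence (typically a buffered exon).
#' @param origin Optional one-row interval tibble giving the query's own
#'   coordinates, used to drop the self-hit.
#' @param xdrop Extension termination threshold (score units).
#' @param config A [mapper_config()] providing match/mismatch scores.
#' @return Hit tibble: `contig`, `sstart`, `send` (subject, 0-based
#'   half-open, forward strand), `qstart`, `qend`, `alignment_length`,
#'   `mismatches`, `gaps` (always 0: extension is ungapped), `strand`.
#' @export
homology_search <- function(index, query, origin = NULL, xdrop = 50L,
                            config = mapper_config()) {
  stopifnot(inherits(index, "camo_index"))
  if (nchar(query) < index$seed_length) {
    warn("query shorter than the word size; no hits possible")
    return(empty_hits())
  }
  h <- cpp_homology_search(index$ptr, query, config$match,
                           config$mismatch_penalty, as.integer(xdrop))
  out <- tibble(
    contig = index$contigs[h$contig],
    sstart = h$sstart, send = h$send,
    qstart = h$qstart, qend = h$qend,
    alignment_length = h$send - h$sstart,
    mismatches = h$mismatches,
    gaps = 0L,
    strand = h$strand
  )
  if (!is.null(origin) && nrow(out) > 0L) {
    self <- out$contig == origin$contig & out$sstart == origin$start &
      out$send == origin$end & out$strand == "+"
    out <- out[!self, , drop = FALSE]
  }
  arrange(out, .data$contig, .data$sstart)
}

empty_hits <- function() {
  tibble(contig = character(), sstart = integer(), send = integer(),
         qstart = integer(), qend = integer(), alignment_length = integer(),
         mismatches = integer(), gaps = integer(), strand = character())
}

#' Homology hits for every buffered exon of a panel
#'
#' Runs [homology_search()] with each buffered exon as query and annotates
#' hits with the query exon. When `camo_truth` is given, hits are classified
#' by subject: `pseudogene` (overlapping a planted pseudogene copy),
#' `other_gene`, or `intergenic`.
#'
#' @param genome A [make_reference()] result (or a list with `reference`,
#'   `panel`, optionally `camo_truth`).
#' @param word_size Seed word length (default 11).
#' @param xdrop,config Passed to [homology_search()].
#' @return Hit tibble with `gene`, `query_length` and (optionally)
#'   `subject_class` columns.
#' @export
panel_homology_hits <- function(genome, word_size = 11L, xdrop = 50L,
                                config = mapper_config()) {
  ref <- genome$reference
  widx <- build_index(ref, word_size)
  widx$seed_length <- as.integer(word_size)
  bex <- buffered_exons(genome$panel, reference_lengths(ref))
  hits <- lapply(seq_len(nrow(bex)), function(i) {
    q <- ref_seq(ref, bex$contig[i], bex$start[i], bex$end[i])
    h <- homology_search(widx, q, origin = bex[i, ], xdrop = xdrop,
                         config = config)
    if (nrow(h) == 0L) return(NULL)
    h$gene <- bex$gene[i]
    h$query_length <- nchar(q)
    h$query_start <- bex$start[i]
    h$query_end <- bex$end[i]
    h
  })
  hits <- bind_rows(hits)
  if (nrow(hits) == 0L) {
    out <- empty_hits()
    out$gene <- character()
    out$query_length <- integer()
    return(out)
  }
  if (!is.null(genome$camo_truth) && nrow(genome$camo_truth) > 0L) {
    ct <- genome$camo_truth
    genes <- genome$panel$genes
    hits$subject_class <- vapply(seq_len(nrow(hits)), function(i) {
      ps <- ct$contig == hits$contig[i] & ct$pseudo_start < hits$send[i] &
        ct$pseudo_end > hits$sstart[i]
      if (any(ps)) return("pseudogene")
      g <- genes$contig == hits$contig[i] & genes$start < hits$send[i] &
        genes$end > hits$sstart[i] & genes$gene != hits$gene[i]
      if (any(g)) "other_gene" else "intergenic"
    }, "")
  }
  hits
}

#' Filter homology hits by mismatch and alignment-length thresholds
#'
#' Keeps hits with at most `max_mismatch` mismatches and an alignment length
#' within `max_len_diff` of the query length (both bounds inclusive).
#'
#' @param hits Hit tibble from [panel_homology_hits()] (needs
#'   `query_length`) or [homology_search()] plus an explicit `query_length`.
#' @param query_length Query length override (scalar), if `hits` lacks the
#'   column.
#' @param max_mismatch Maximum mismatches (default 10).
#' @param max_len_diff Maximum |alignment length - query length| (default 10).
#' @return Filtered hit tibble.
#' @export
filter_hits <- function(hits, query_length = NULL, max_mismatch = 10L,
                        max_len_diff = 10L) {
  ql <- if (!is.null(query_length)) {
    query_length
  } else if ("query_length" %in% names(hits)) {
    hits$query_length
  } else {
    abort("query length is required to filter hits")
  }
  keep <- hits$mismatches <= max_mismatch &
    abs(hits$alignment_length - ql) <= max_len_diff
  hits[keep, , drop = FALSE]
}

#' Flag panel genes with potential mapping problems
#'
#' Union rule: a gene is flagged iff any of its exons is mappability-flagged
#' or has at least one surviving homology hit.
#'
#' @param panel A [panel()].
#' @param exon_mappability Output of [exon_mean_mappability()].
#' @param filtered_hits Output of [filter_hits()].
#' @return Tibble with one row per gene: `gene`, `mappability_flagged`,
#'   `homology_flagged`, `flagged`.
#' @export
flag_panel <- function(panel, exon_mappability, filtered_hits) {
  genes <- unique(panel$genes$gene)
  mflag <- vapply(genes, function(g) {
    any(exon_mappability$flagged[exon_mappability$gene == g])
  }, logical(1))
  hflag <- vapply(genes, function(g) {
    any(filtered_hits$gene == g)
  }, logical(1))
  tibble(gene = genes, mappability_flagged = unname(mflag),
         homology_flagged = unname(hflag),
         flagged = unname(mflag | hflag))
}
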