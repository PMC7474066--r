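#' Genotype-caller configuration
#'
#' A pileup genotyper with configurable ploidy. At ploidy 4 it implements
#' the pseudogene-masking rescue: the gene and its masked pseudogene are
#' genotyped as one tetraploid locus, so gene-borne homozygous variants
#' appear at full dosage (`1/1/1/1`) while pseudogene-divergence sites
#' appear at half dosage (`0/0/1/1`).
#'
#' @param ploidy Number of allele copies modelled (default 2).
#' @param mq_min Minimum MAPQ for a read to enter the pileup (default 20;
#'   10 is the common relaxed alternative).
#' @param base_error Per-base error rate used in the likelihood (default
#'   matches the simulator's 0.0024).
#' @param min_depth Minimum covering reads for a call (default 4).
#' @param min_call_qual Minimum Phred-scaled likelihood margin (default 30).
#' @return A `caller_config` list.
#' @export
caller_config <- function(ploidy = 2L, mq_min = 20L, base_error = 0.0024,
                          min_depth = 4L, min_call_qual = 30) {
  stopifnot(ploidy >= 1L, mq_min >= 0L, base_error >= 0, base_error < 1,
            min_depth >= 0L, min_call_qual >= 0)
  structure(
    list(ploidy = as.integer(ploidy), mq_min = as.integer(mq_min),
         base_error = base_error, min_depth = as.integer(min_depth),
         min_call_qual = min_call_qual),
    class = "caller_config"
  )
}

#' Pileup base counts at a site
#'
#' Counts A/C/G/T over alignments with MAPQ at or above `mq_min` whose
#' aligned span covers the site.
#'
#' @param aln Alignment tibble.
#' @param contig,pos Site (0-based).
#' @param mq_min Minimum MAPQ.
#' @return Named integer vector of counts for A, C, G, T.
#' @export
pileup <- function(aln, contig, pos, mq_min = 20L) {
  a <- aln[aln$mapped & aln$contig == contig, ]
  if (nrow(a) == 0L) return(setNames(integer(4L), c("A", "C", "G", "T")))
  m <- cpp_pileup_counts(a$pos, a$seq, a$mapq, as.integer(pos),
                         as.integer(pos) + 1L, as.integer(mq_min))
  setNames(as.integer(m[, 1L]), c("A", "C", "G", "T"))
}

#' Pileup base-count matrix over an interval
#'
#' @param aln Alignment tibble.
#' @param contig,start,end Interval (0-based half-open).
#' @param mq_min Minimum MAPQ.
#' @return 4 x width integer matrix (rows A, C, G, T).
#' @export
pileup_matrix <- function(aln, contig, start, end, mq_min = 20L) {
  a <- aln[aln$mapped & aln$contig == contig, ]
  m <- cpp_pileup_counts(a$pos, a$seq, a$mapq, as.integer(start),
                         as.integer(end), as.integer(mq_min))
  rownames(m) <- c("A", "C", "G", "T")
  m
}

#' Call a genotype from a biallelic pileup
#'
#' For each dosage `d` in `0..ploidy`, the likelihood multiplies, over
#' reads, `(d/ploidy)(1-e) + (1-d/ploidy)(e/3)` for alt reads and the
#' complement for ref reads (`e` = base error rate), under a flat prior.
#' No-call when covering reads fall below `min_depth` or the Phred margin
#' between the best and second-best dosage falls below `min_call_qual`.
#'
#' @param n_ref,n_alt Ref and alt read counts at the site.
#' @param config A [caller_config()].
#' @return One-row tibble: `called`, `dosage`, `genotype` (slashed string),
#'   `gq`, `depth`, `reason` (for no-calls).
#' @export
call_genotype <- function(n_ref, n_alt, config = caller_config()) {
  P <- config$ploidy
  e <- config$base_error
  depth <- n_ref + n_alt
  no_call <- function(reason) {
    tibble(called = FALSE, dosage = NA_integer_, genotype = NA_character_,
           gq = NA_real_, depth = depth, reason = reason)
  }
  if (depth == 0L) return(no_call("no coverage"))
  if (depth < config$min_depth) return(no_call("below minimum depth"))
  d <- 0:P
  p_alt <- (d / P) * (1 - e) + (1 - d / P) * (e / 3)
  p_ref <- (1 - d / P) * (1 - e) + (d / P) * (e / 3)
  ll <- n_alt * log(p_alt) + n_ref * log(p_ref)
  ord <- order(ll, decreasing = TRUE)
  gq <- 10 * (ll[ord[1]] - ll[ord[2]]) / log(10)
  if (gq < config$min_call_qual) return(no_call("below call quality"))
  dose <- d[ord[1]]
  tibble(
    called = TRUE, dosage = dose,
    genotype = paste(c(rep("0", P - dose), rep("1", dose)), collapse = "/"),
    gq = gq, depth = depth, reason = NA_character_
  )
}

#' Call a genotype at a reference site from alignments
#'
#' Convenience wrapper: pileup at the site, take the reference base as REF
#' and the most frequent other base as ALT, then [call_genotype()].
#'
#' @param aln Alignment tibble.
#' @param ref A [reference()].
#' @param contig,pos Site (0-based).
#' @param alt Optional fixed alternate base.
#' @param config A [caller_config()].
#' @return One-row tibble as [call_genotype()], plus `contig`, `pos`,
#'   `ref`, `alt` and the raw counts.
#' @export
call_site <- function(aln, ref, contig, pos, alt = NULL,
                      config = caller_config()) {
  counts <- pileup(aln, contig, pos, config$mq_min)
  rb <- ref_seq(ref, contig, pos, pos + 1L)
  others <- counts[setdiff(names(counts), rb)]
  ab <- if (!is.null(alt)) alt else names(others)[which.max(others)]
  res <- call_genotype(counts[[rb]], counts[[ab]], config)
  bind_cols(
    tibble(contig = contig, pos = as.integer(pos), ref = rb, alt = ab,
           n_ref = counts[[rb]], n_alt = counts[[ab]]),
    res
  )
}

#' Scan an interval for non-reference calls
#'
#' Examines every position whose pileup shows at least `min_alt_reads`
#' non-reference reads and at least 10% non-reference fraction, and calls a
#' genotype there. Used to enumerate the extra (pseudogene-origin) variants
#' the masking strategy produces.
#'
#' @param aln Alignment tibble.
#' @param ref A [reference()].
#' @param contig,start,end Interval (0-based half-open).
#' @param config A [caller_config()].
#' @param min_alt_reads Screening threshold (default 3).
#' @return Tibble of called non-reference sites (possibly empty).
#' @export
scan_variants <- function(aln, ref, contig, start, end,
                          config = caller_config(), min_alt_reads = 3L) {
  m <- pileup_matrix(aln, contig, start, end, config$mq_min)
  refbases <- strsplit(ref_seq(ref, contig, start, end), "")[[1]]
  width <- end - start
  out <- list()
  for (i in seq_len(width)) {
    rb <- refbases[i]
    if (!rb %in% rownames(m)) next
    tot <- sum(m[, i])
    altc <- m[setdiff(rownames(m), rb), i]
    ab <- names(altc)[which.max(altc)]
    na <- max(altc)
    if (na < min_alt_reads || tot == 0L || na / tot < 0.1) next
    res <- call_genotype(m[rb, i], na, config)
    if (isTRUE(res$called) && res$dosage > 0L) {
      out[[length(out) + 1L]] <- bind_cols(
        tibble(contig = contig, pos = start + i - 1L, ref = rb, alt = ab,
               n_ref = m[rb, i], n_alt = na),
        res
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble(contig = character(), pos = integer(), ref = character(),
                  alt = character(), n_ref = integer(), n_alt = integer(),
                  called = logical(), dosage = integer(),
                  genotype = character(), gq = numeric(), depth = integer(),
                  reason = character()))
  }
  bind_rows(out)
}

#' Mask reference intervals with N
#'
#' Replaces the bases of the given intervals (each optionally extended by
#' `flank`) with `N`, so no seed can anchor there.
#'
#' @param ref A [reference()].
#' @param intervals Interval tibble.
#' @param flank Extra bases masked on each side (the pseudogene-masking
#'   strategy uses 2 kb).
#' @return The masked [reference()].
#' @export
mask_reference <- function(ref, intervals, flank = 0L) {
  if (nrow(intervals) == 0L) return(ref)
  iv <- intervals
  iv$start <- pmax(0L, iv$start - as.integer(flank))
  iv$end <- iv$end + as.integer(flank)
  iv <- clip_intervals(iv, reference_lengths(ref))
  iv <- merge_intervals(iv)
  for (i in seq_len(nrow(iv))) {
    ctg <- iv$contig[i]
    substr(ref[[ctg]], iv$start[i] + 1L, iv$end[i]) <-
      strrep("N", iv$end[i] - iv$start[i])
  }
  ref
}

#' Partition ploidy-4 calls into target and pseudogene-origin variants
#'
#' Full-dosage calls (all copies alternate) are variants carried by the
#' target gene itself; half-dosage calls are divergence sites of the masked
#' pseudogene copy; anything else is ambiguous (interpretation of such call
#' sets can be difficult when many additional variants appear).
#'
#' @param calls Call tibble (from [scan_variants()] or [call_site()]) made
#'   at even ploidy >= 4.
#' @param ploidy The calling ploidy (default 4).
#' @return `calls` with an `origin` column: `target`, `pseudogene`,
#'   `ambiguous`.
#' @export
discriminate_calls <- function(calls, ploidy = 4L) {
  if (ploidy %% 2L != 0L) abort("discrimination requires an even ploidy")
  calls$origin <- dplyr::case_when(
    calls$dosage == ploidy ~ "target",
    calls$dosage == ploidy / 2L ~ "pseudogene",
    TRUE ~ "ambiguous"
  )
  if (any(calls$origin == "ambiguous")) {
    warn("ambiguous-dosage calls present; interpretation may be difficult")
  }
  calls
}
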