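IUPAC_HET <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' Build an IUPAC consensus sequence from a VCF
#'
#' Hom-alt sites are replaced by the alternate base; het sites by the IUPAC
#' ambiguity code for the ref/alt pair. Only biallelic SNVs are supported.
#'
#' @param ref A [reference()].
#' @param vcf VCF record tibble (single sample) as from [read_vcf()].
#' @return Named character vector of consensus sequences (may contain IUPAC
#'   ambiguity codes).
#' @export
build_consensus <- function(ref, vcf) {
  gt_col <- grep("^gt_", names(vcf), value = TRUE)
  if (length(gt_col) != 1L) abort("consensus requires a single-sample VCF")
  out <- ref
  if (nrow(vcf) == 0L) return(out)
  if (any(nchar(vcf$ref) != 1L | nchar(vcf$alt) != 1L)) {
    abort("only SNV records are supported")
  }
  for (ctg in unique(vcf$contig)) {
    rec <- vcf[vcf$contig == ctg, ]
    seq <- out[[ctg]]
    have <- substring(seq, rec$pos + 1L, rec$pos + 1L)
    bad <- which(have != rec$ref)
    if (length(bad) > 0L) {
      abort(paste0("VCF REF mismatch at ", ctg, ":", rec$pos[bad[1]] + 1L,
                   " (reference has ", have[bad[1]], ", VCF says ",
                   rec$ref[bad[1]], ")"))
    }
    gt <- rec[[gt_col]]
    is_hom <- gt %in% c("1/1", "1|1")
    is_het <- gt %in% c("0/1", "1/0", "0|1", "1|0")
    if (any(!is_hom & !is_het)) {
      abort(paste0("unsupported genotype: ", gt[which(!is_hom & !is_het)[1]]))
    }
    new <- character(nrow(rec))
    new[is_hom] <- rec$alt[is_hom]
    if (any(is_het)) {
      pair <- vapply(which(is_het), function(i) {
        paste(sort(c(rec$ref[i], rec$alt[i])), collapse = "")
      }, "")
      new[is_het] <- IUPAC_HET[pair]
    }
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    chars[rec$pos + 1L] <- new
    out[[ctg]] <- paste(chars, collapse = "")
  }
  out
}

#' Split an IUPAC consensus into two haplotypes
#'
#' Each biallelic ambiguity code resolves deterministically: the
#' alphabetically first base goes to haplotype 1. Three- and four-fold
#' ambiguity codes are rejected (the pipeline is restricted to biallelic
#' SNVs); `N` passes through unchanged as a hard-masked base.
#'
#' @param consensus Named character vector from [build_consensus()].
#' @return List with elements `hap1` and `hap2`.
#' @export
split_haplotypes <- function(consensus) {
  bad <- grepl("[BDHVbdhv]", consensus)
  if (any(bad)) {
    abort("3/4-fold ambiguity codes are not biallelic; cannot split")
  }
  list(
    hap1 = toupper(chartr("MRWSYKmrwsyk", "AAACCGAAACCG", consensus)),
    hap2 = toupper(chartr("MRWSYKmrwsyk", "CGTGTTCGTGTT", consensus))
  )
}

#' Read-simulation configuration
#'
#' Defaults are the package's reference simulation conditions: paired-end
#' reads with
#' an inner distance of 50 +/- 10 bp, 20X coverage per haplotype (40X
#' combined), a 0.0024 per-base substitution error rate, no indels, at most
#' 5 `N` bases per read, and a 2 kb simulation flank around each gene.
#'
#' @param read_length Read length in bp (70, 100, 150 or 250 in the
#'   default evaluation).
#' @param inner_distance_mean,inner_distance_sd Gaussian inner-distance model
#'   (gap between the inner ends of a pair), truncated at 0.
#' @param per_haplotype_coverage Expected fold-coverage simulated from each
#'   haplotype.
#' @param error_rate Per-base substitution error probability.
#' @param max_n_per_read Reads with more `N` bases are discarded and redrawn.
#' @param flank Simulation flank (bp) around each gene.
#' @param seed Integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(read_length = 150L,
                              inner_distance_mean = 50,
                              inner_distance_sd = 10,
                              per_haplotype_coverage = 20,
                              error_rate = 0.0024,
                              max_n_per_read = 5L,
                              flank = 2000L,
                              seed = 1L) {
  stopifnot(
    read_length >= 20L, inner_distance_mean >= 0, inner_distance_sd >= 0,
    per_haplotype_coverage > 0, error_rate >= 0, error_rate < 1,
    max_n_per_read >= 0L, flank >= 0L
  )
  structure(
    list(
      read_length = as.integer(read_length),
      inner_distance_mean = inner_distance_mean,
      inner_distance_sd = inner_distance_sd,
      per_haplotype_coverage = per_haplotype_coverage,
      error_rate = error_rate,
      max_n_per_read = as.integer(max_n_per_read),
      flank = as.integer(flank),
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Encode and parse truth-read names
#'
#' The read-name grammar `sim|<indiv>|<hap>|<contig>|<pos1>|<pos2>|<strand1>|<serial>`
#' losslessly records each simulated pair's origin: individual, haplotype,
#' contig, the true 0-based leftmost positions of read 1 and read 2, read 1's
#' strand, and a serial number.
#'
#' @param individual,hap,contig,pos1,pos2,strand1,serial Truth fields
#'   (vectors of equal length). Identifiers must not contain `|`.
#' @return `encode_truth()` a character vector; `parse_truth()` a tibble.
#' @export
encode_truth <- function(individual, hap, contig, pos1, pos2, strand1, serial) {
  if (any(grepl("|", c(individual, contig), fixed = TRUE))) {
    abort("identifiers must not contain '|'")
  }
  paste("sim", individual, hap, contig, pos1, pos2, strand1, serial, sep = "|")
}

#' @rdname encode_truth
#' @param ids Character vector of encoded truth names.
#' @export
parse_truth <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  ok <- lengths(parts) == 8L & vapply(parts, `[[`, "", 1L) == "sim"
  if (any(!ok)) {
    abort(paste0("unparseable truth read name: ", ids[which(!ok)[1]]))
  }
  f <- function(i) vapply(parts, `[[`, "", i)
  tibble(
    individual = f(2L),
    hap = as.integer(f(3L)),
    contig = f(4L),
    pos1 = as.integer(f(5L)),
    pos2 = as.integer(f(6L)),
    strand1 = f(7L),
    serial = as.integer(f(8L))
  )
}

inject_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  rl <- nchar(seqs[1])
  n_err <- rbinom(length(seqs), rl, error_rate)
  idx <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    at <- sample.int(rl, n_err[i])
    for (p in at) {
      cur <- chars[p]
      if (cur %in% bases) chars[p] <- sample(setdiff(bases, cur), 1L)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

count_n <- function(x) nchar(x) - nchar(gsub("N", "", x, fixed = TRUE))

draw_pairs_region <- function(hapseq, contig, rs, re, n, cfg) {
  rl <- cfg$read_length
  inner <- pmax(0, round(rnorm(n, cfg$inner_distance_mean,
                               cfg$inner_distance_sd)))
  frag <- 2L * rl + as.integer(inner)
  frag <- pmin(frag, re - rs)  # guarded by caller: region >= max fragment
  fs <- rs + floor(runif(n) * (re - rs - frag + 1))
  fe <- fs + frag
  strand1 <- ifelse(runif(n) < 0.5, "+", "-")
  left <- substring(hapseq, fs + 1L, fs + rl)
  right <- substring(hapseq, fe - rl + 1L, fe)
  fwd1 <- strand1 == "+"
  tibble(
    contig = contig,
    pos1 = as.integer(ifelse(fwd1, fs, fe - rl)),
    pos2 = as.integer(ifelse(fwd1, fe - rl, fs)),
    strand1 = strand1,
    seq1 = ifelse(fwd1, left, revcomp(right)),
    seq2 = ifelse(fwd1, revcomp(right), left)
  )
}

#' Simulate truth-labelled paired-end reads from a diploid genome
#'
#' Fragments are drawn per haplotype until the expected per-haplotype depth
#' reaches `per_haplotype_coverage` over each region (number of pairs =
#' coverage x region length / (2 x read length)); fragment length is
#' `2 x read_length` plus a truncated-Gaussian inner distance; fragment
#' starts are uniform within the region; read 1's strand is a fair coin;
#' substitution errors are i.i.d. per base with the erroneous base uniform
#' over the three alternatives. Reads exceeding the `N` limit are redrawn.
#' Both haplotype read sets are returned combined.
#'
#' @param hap1,hap2 Haplotype sequences (named character vectors sharing the
#'   reference's contigs), e.g. from [split_haplotypes()].
#' @param regions Interval tibble of simulation regions (genes + flank).
#' @param config A [simulation_config()].
#' @param individual Individual label recorded in read names.
#' @return Tibble with columns `qname`, `seq1`, `qual1`, `seq2`, `qual2` and
#'   the truth fields (`contig`, `pos1`, `pos2`, `strand1`, `hap`, `serial`).
#' @export
simulate_reads <- function(hap1, hap2, regions, config,
                           individual = "ind1") {
  stopifnot(inherits(config, "simulation_config"))
  validate_intervals(regions)
  with_seed(config$seed, {
    rl <- config$read_length
    max_frag <- 2L * rl +
      as.integer(ceiling(config$inner_distance_mean +
                           6 * config$inner_distance_sd))
    keep <- regions$end - regions$start >= max_frag
    if (any(!keep)) {
      warn(paste0(sum(!keep), " region(s) shorter than the maximum fragment",
                  " were skipped"))
      regions <- regions[keep, , drop = FALSE]
    }
    out <- vector("list", 2L * nrow(regions))
    k <- 0L
    for (h in 1:2) {
      hap <- if (h == 1L) hap1 else hap2
      for (i in seq_len(nrow(regions))) {
        ctg <- regions$contig[i]
        rs <- regions$start[i]
        re <- regions$end[i]
        n <- max(1L, round(config$per_haplotype_coverage * (re - rs) /
                             (2 * rl)))
        pairs <- draw_pairs_region(hap[[ctg]], ctg, rs, re, n, config)
        pairs$seq1 <- inject_errors(pairs$seq1, config$error_rate)
        pairs$seq2 <- inject_errors(pairs$seq2, config$error_rate)
        # redraw reads violating the N limit
        for (iter in 1:50) {
          bad <- count_n(pairs$seq1) > config$max_n_per_read |
            count_n(pairs$seq2) > config$max_n_per_read
          if (!any(bad)) break
          redo <- draw_pairs_region(hap[[ctg]], ctg, rs, re, sum(bad), config)
          redo$seq1 <- inject_errors(redo$seq1, config$error_rate)
          redo$seq2 <- inject_errors(redo$seq2, config$error_rate)
          pairs[bad, ] <- redo
        }
        pairs$hap <- h
        k <- k + 1L
        out[[k]] <- pairs
      }
    }
    reads <- bind_rows(out[seq_len(k)])
    reads$serial <- seq_len(nrow(reads))
    reads$qname <- encode_truth(individual, reads$hap, reads$contig,
                                reads$pos1, reads$pos2, reads$strand1,
                                reads$serial)
    q <- strrep("I", rl)  # constant Q40
    reads$qual1 <- q
    reads$qual2 <- q
    select(reads, "qname", "seq1", "qual1", "seq2", "qual2", "contig",
           "pos1", "pos2", "strand1", "hap", "serial")
  })
}

#' Simulate reads for a sample carrying one planted variant
#'
#' Applies the variant VCF to the reference, splits haplotypes (so a het
#' variant is carried by exactly one haplotype and ~50% of overlapping
#' reads), and simulates each haplotype at half the total coverage.
#'
#' @param ref A [reference()].
#' @param panel A [panel()] (defines simulation regions).
#' @param planted A [plant_variant()] result.
#' @param config A [simulation_config()].
#' @param regions Optional interval tibble overriding the default region
#'   (the variant's gene plus flank).
#' @return Read tibble as from [simulate_reads()].
#' @export
make_variant_readset <- function(ref, panel, planted, config, regions = NULL) {
  v <- planted$variant
  if (is.null(regions)) {
    regs <- simulation_regions(panel, reference_lengths(ref))
    regions <- regs[regs$gene == v$gene, c("contig", "start", "end")]
  }
  inside <- any(regions$contig == v$contig & regions$start <= v$pos &
                  v$pos < regions$end)
  if (!inside) abort("planted variant lies outside the simulated regions")
  cons <- build_consensus(ref, planted$vcf)
  haps <- split_haplotypes(cons)
  simulate_reads(haps$hap1, haps$hap2, regions, config,
                 individual = "sample")
}

#' Write a simulated read set as paired FASTQ plus a truth table
#'
#' @param reads Tibble from [simulate_reads()].
#' @param prefix Output path prefix; writes `<prefix>_R1.fastq`,
#'   `<prefix>_R2.fastq` and `<prefix>_truth.tsv`.
#' @return The three paths, invisibly.
#' @export
write_read_fastqs <- function(reads, prefix) {
  p1 <- paste0(prefix, "_R1.fastq")
  p2 <- paste0(prefix, "_R2.fastq")
  pt <- paste0(prefix, "_truth.tsv")
  write_fastq(tibble(id = reads$qname, seq = reads$seq1, qual = reads$qual1), p1)
  write_fastq(tibble(id = reads$qname, seq = reads$seq2, qual = reads$qual2), p2)
  readr::write_tsv(select(reads, "qname", "contig", "pos1", "pos2",
                          "strand1", "hap", "serial"), pt)
  invisible(c(p1, p2, pt))
}
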