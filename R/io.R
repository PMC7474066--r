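#' Reference sequence container
#'
#' A reference is a named character vector of uppercase sequences over
#' `{A, C, G, T, N}`. Soft-masked (lowercase) input is uppercased on load;
#' only `N` is treated as hard-masked.
#'
#' @param seqs Named character vector of sequences.
#' @return The validated, uppercased reference.
#' @export
reference <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    abort("reference contigs must be named")
  }
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0("contig ", names(seqs)[bad][1],
                 " contains characters outside {A,C,G,T,N}"))
  }
  seqs
}

#' Contig lengths of a reference
#' @param ref A [reference()].
#' @return Named integer vector.
#' @export
reference_lengths <- function(ref) {
  setNames(nchar(ref), names(ref))
}

#' Extract a reference subsequence (0-based, half-open)
#' @param ref A [reference()].
#' @param contig Contig name.
#' @param start,end 0-based half-open coordinates.
#' @return Character scalar.
#' @export
ref_seq <- function(ref, contig, start, end) {
  if (!contig %in% names(ref)) abort(paste0("unknown contig: ", contig))
  len <- nchar(ref[[contig]])
  if (start < 0 || end > len || start >= end) {
    abort(paste0("interval [", start, ",", end, ") out of bounds for contig ",
                 contig, " (length ", len, ")"))
  }
  substr(ref[[contig]], start + 1L, end)
}

#' Reverse complement of character sequences
#' @param x Character vector of DNA sequences.
#' @return Character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# --- FASTA --------------------------------------------------------------

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings; sequences are uppercased on read and written
#' with 60-column wrapping. Names are truncated at the first whitespace.
#'
#' @param path File path.
#' @return `read_fasta()` returns a [reference()].
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  reference(setNames(as.character(x), names(x)))
}

#' @rdname read_fasta
#' @param ref A [reference()].
#' @export
write_fasta <- function(ref, path) {
  x <- Biostrings::DNAStringSet(ref)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

# --- FASTQ --------------------------------------------------------------

#' Read and write FASTQ (Phred+33)
#'
#' @param path File path.
#' @return `read_fastq()` returns a tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities)
  )
}

#' @rdname read_fastq
#' @param reads Tibble with columns `id`, `seq`, `qual`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual)
  )
  invisible(path)
}

# --- BED ----------------------------------------------------------------

#' Read and write BED (BED3/BED6)
#'
#' BED is 0-based half-open, matching the internal convention, so coordinates
#' pass through unchanged.
#'
#' @param path File path.
#' @return `read_bed()` returns an interval tibble.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(contig = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort(paste0("malformed BED record at line ", which(nf < 3L)[1]))
  }
  starts <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(starts) || anyNA(ends)) {
    abort(paste0("non-numeric BED coordinate at line ",
                 which(is.na(starts) | is.na(ends))[1]))
  }
  out <- tibble(
    contig = vapply(fields, `[[`, "", 1L),
    start = starts,
    end = ends,
    name = ifelse(nf >= 4L, vapply(fields, function(f) {
      if (length(f) >= 4L) f[[4L]] else NA_character_
    }, ""), NA_character_),
    score = ifelse(nf >= 5L, vapply(fields, function(f) {
      if (length(f) >= 5L) f[[5L]] else NA_character_
    }, ""), NA_character_),
    strand = ifelse(nf >= 6L, vapply(fields, function(f) {
      if (length(f) >= 6L) f[[6L]] else "*"
    }, ""), "*")
  )
  validate_intervals(out)
  out
}

#' @rdname read_bed
#' @param x Interval tibble; columns beyond `contig`, `start`, `end` are
#'   written as BED name/score/strand when present.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- list(x$contig, x$start, x$end)
  if ("name" %in% names(x)) {
    cols <- c(cols, list(ifelse(is.na(x$name), ".", x$name)))
    if ("score" %in% names(x)) {
      cols <- c(cols, list(ifelse(is.na(x$score), "0", as.character(x$score))))
      if ("strand" %in% names(x)) cols <- c(cols, list(x$strand))
    }
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

# --- VCF (SNVs only) ----------------------------------------------------

#' Read and write a minimal SNV VCF (v4.2)
#'
#' Only biallelic SNV records with a GT FORMAT field are supported, which is
#' all the pipeline produces and consumes. Positions are converted between
#' the file's 1-based convention and the internal 0-based convention.
#'
#' @param path File path.
#' @return `read_vcf()` returns a tibble with columns `contig`, `pos`
#'   (0-based), `id`, `ref`, `alt`, `qual`, `filter`, `info`, and one `gt_*`
#'   column per sample; sample names are stored in the `samples` attribute.
#' @export
read_vcf <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- which(startsWith(lines, "#CHROM"))
  if (length(hdr) != 1L) abort("VCF lacks a single #CHROM header line")
  header <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  samples <- if (length(header) > 9L) header[-(1:9)] else character()
  body_idx <- seq_along(lines) > hdr & nzchar(lines)
  body <- lines[body_idx]
  lineno <- which(body_idx)
  if (length(body) == 0L) {
    out <- tibble(
      contig = character(), pos = integer(), id = character(),
      ref = character(), alt = character(), qual = character(),
      filter = character(), info = character()
    )
    for (s in samples) out[[paste0("gt_", s)]] <- character()
    attr(out, "samples") <- samples
    return(out)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  need <- 8L + (length(samples) > 0L) * (1L + length(samples))
  bad <- which(lengths(fields) < need)
  if (length(bad) > 0L) {
    abort(paste0("malformed VCF record at line ", lineno[bad[1]]))
  }
  pos1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  if (anyNA(pos1)) {
    abort(paste0("non-numeric POS at line ", lineno[which(is.na(pos1))[1]]))
  }
  out <- tibble(
    contig = vapply(fields, `[[`, "", 1L),
    pos = pos1 - 1L,
    id = vapply(fields, `[[`, "", 3L),
    ref = vapply(fields, `[[`, "", 4L),
    alt = vapply(fields, `[[`, "", 5L),
    qual = vapply(fields, `[[`, "", 6L),
    filter = vapply(fields, `[[`, "", 7L),
    info = vapply(fields, `[[`, "", 8L)
  )
  if (length(samples) > 0L) {
    fmt <- vapply(fields, `[[`, "", 9L)
    gt_at <- vapply(strsplit(fmt, ":", fixed = TRUE), function(f) {
      match("GT", f)
    }, integer(1))
    if (anyNA(gt_at)) {
      abort(paste0("FORMAT without GT at line ", lineno[which(is.na(gt_at))[1]]))
    }
    for (si in seq_along(samples)) {
      raw <- vapply(fields, `[[`, "", 9L + si)
      out[[paste0("gt_", samples[si])]] <- vapply(seq_along(raw), function(i) {
        strsplit(raw[i], ":", fixed = TRUE)[[1]][gt_at[i]]
      }, "")
    }
  }
  attr(out, "samples") <- samples
  out
}

#' @rdname read_vcf
#' @param records Tibble as returned by `read_vcf()`.
#' @param contig_lengths Named integer vector used for `##contig` header
#'   lines.
#' @export
write_vcf <- function(records, path, contig_lengths = NULL) {
  samples <- sub("^gt_", "", grep("^gt_", names(records), value = TRUE))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=camoseq",
    if (!is.null(contig_lengths)) {
      paste0("##contig=<ID=", names(contig_lengths), ",length=",
             contig_lengths, ">")
    },
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t")
  )
  body <- character()
  if (nrow(records) > 0L) {
    cols <- list(
      records$contig, records$pos + 1L,
      ifelse(is.na(records$id), ".", records$id),
      records$ref, records$alt,
      ifelse(is.na(records$qual), ".", as.character(records$qual)),
      ifelse(is.na(records$filter), ".", records$filter),
      ifelse(is.na(records$info), ".", records$info)
    )
    if (length(samples) > 0L) {
      cols <- c(cols, list("GT"),
                lapply(samples, function(s) records[[paste0("gt_", s)]]))
    }
    body <- do.call(paste, c(cols, sep = "\t"))
  }
  readr::write_lines(c(header, body), path)
  invisible(path)
}

# --- SAM ----------------------------------------------------------------

sam_flag <- function(aln) {
  flag <- rep(1L, nrow(aln))  # paired
  flag <- flag + if_else(aln$proper & aln$mapped, 2L, 0L)
  flag <- flag + if_else(!aln$mapped, 4L, 0L)
  flag <- flag + if_else(!aln$mate_mapped, 8L, 0L)
  flag <- flag + if_else(aln$mapped & aln$strand == "-", 16L, 0L)
  flag <- flag + if_else(aln$mate_mapped & aln$mate_strand == "-", 32L, 0L)
  flag <- flag + if_else(aln$mate == 1L, 64L, 128L)
  flag
}

#' Write alignments as SAM v1.6
#'
#' Internal 0-based positions are converted to the 1-based SAM convention.
#'
#' @param aln Alignment tibble as produced by [map_read_pairs()].
#' @param contig_lengths Named integer vector for `@SQ` header lines.
#' @param path File path.
#' @param pg Optional program-line description recorded as `@PG`.
#' @export
write_sam <- function(aln, contig_lengths, path, pg = "camoseq") {
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    paste0("@SQ\tSN:", names(contig_lengths), "\tLN:", contig_lengths),
    paste0("@PG\tID:camoseq\tPN:camoseq\tCL:", pg)
  )
  flag <- sam_flag(aln)
  rnext <- dplyr::case_when(
    !aln$mate_mapped ~ "*",
    aln$mate_contig == aln$contig & aln$mapped ~ "=",
    TRUE ~ aln$mate_contig
  )
  body <- paste(
    aln$qname, flag,
    if_else(aln$mapped, aln$contig, "*"),
    if_else(aln$mapped, aln$pos + 1L, 0L),
    aln$mapq,
    if_else(aln$mapped, aln$cigar, "*"),
    rnext,
    if_else(aln$mate_mapped, aln$mate_pos + 1L, 0L),
    if_else(aln$mapped & aln$mate_mapped & !is.na(aln$tlen), aln$tlen, 0L),
    aln$seq, aln$qual,
    sep = "\t"
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read SAM alignments written by [write_sam()]
#'
#' @param path File path.
#' @return Alignment tibble (0-based positions).
#' @export
read_sam <- function(path) {
  lines <- readr::read_lines(path)
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(body) == 0L) abort("SAM file contains no alignment records")
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 11L)
  if (length(bad) > 0L) {
    abort(paste0("malformed SAM record at line ", bad[1]))
  }
  f <- function(i) vapply(fields, `[[`, "", i)
  flag <- as.integer(f(2L))
  tibble(
    qname = f(1L),
    mate = if_else(bitwAnd(flag, 64L) > 0L, 1L, 2L),
    contig = ifelse(f(3L) == "*", NA_character_, f(3L)),
    pos = as.integer(f(4L)) - 1L,
    strand = if_else(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mapq = as.integer(f(5L)),
    cigar = f(6L),
    seq = f(10L),
    qual = f(11L),
    tlen = as.integer(f(9L)),
    mapped = bitwAnd(flag, 4L) == 0L,
    proper = bitwAnd(flag, 2L) > 0L
  )
}
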