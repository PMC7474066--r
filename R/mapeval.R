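#' Classify mapped reads against simulation truth
#'
#' A read is `unmapped` when it has no alignment or MAPQ below
#' `mq_unmapped` (low-MAPQ reads "would typically be filtered out");
#' otherwise `correct` iff it aligned to the true contig and strand within
#' `pos_tolerance` bases of its true start, else `incorrect`.
#'
#' @param aln Alignment tibble from [map_read_pairs()] with truth-encoded
#'   read names.
#' @param mq_unmapped MAPQ threshold below which a read counts as unmapped
#'   (default 10).
#' @param pos_tolerance Positional tolerance in bp (default 20).
#' @return `aln` with `true_contig`, `true_pos`, `true_strand` and `class`
#'   columns.
#' @export
classify_reads <- function(aln, mq_unmapped = 10L, pos_tolerance = 20L) {
  truth <- parse_truth(aln$qname)
  true_pos <- if_else(aln$mate == 1L, truth$pos1, truth$pos2)
  true_strand1 <- truth$strand1
  true_strand <- if_else(aln$mate == 1L, true_strand1,
                         if_else(true_strand1 == "+", "-", "+"))
  cls <- dplyr::case_when(
    !aln$mapped | aln$mapq < mq_unmapped ~ "unmapped",
    aln$contig == truth$contig & aln$strand == true_strand &
      abs(aln$pos - true_pos) <= pos_tolerance ~ "correct",
    TRUE ~ "incorrect"
  )
  aln$true_contig <- truth$contig
  aln$true_pos <- true_pos
  aln$true_strand <- true_strand
  aln$individual <- truth$individual
  aln$class <- cls
  aln
}

#' Summarise read classification counts and percentages
#'
#' @param classified Output of [classify_reads()].
#' @param ... Grouping columns (e.g. `population`, `read_length`) present in
#'   `classified`.
#' @return Tibble of counts and percentages per class and group.
#' @export
summarize_classification <- function(classified, ...) {
  classified$class <- factor(classified$class,
                             levels = c("correct", "incorrect", "unmapped"))
  grouped <- group_by(classified, ..., .data$class, .drop = FALSE)
  counts <- summarise(grouped, n = n(), .groups = "drop_last")
  out <- mutate(counts, pct = 100 * .data$n / sum(.data$n))
  tidyr::pivot_wider(
    ungroup(out),
    names_from = "class", values_from = c("n", "pct"),
    values_fill = list(n = 0L, pct = 0)
  )
}

#' Per-base depth of coverage over evaluated regions
#'
#' Counts, for every base of the given regions, alignments with MAPQ at or
#' above `mq_min` whose span covers the base; every region base is reported,
#' zeros included, and depth is zero outside the regions.
#'
#' @param aln Alignment tibble.
#' @param regions Interval tibble of evaluated regions.
#' @param contig_lengths Named integer vector of contig lengths.
#' @param mq_min Minimum MAPQ for an alignment to contribute (default 10).
#' @return A `camo_depth` object with per-contig depth vectors.
#' @export
depth_track <- function(aln, regions, contig_lengths, mq_min = 10L) {
  validate_intervals(regions)
  keep <- aln$mapped & aln$mapq >= mq_min
  a <- aln[keep, c("contig", "pos", "seq")]
  a$len <- nchar(a$seq)
  depth <- lapply(names(contig_lengths), function(ctg) {
    L <- contig_lengths[[ctg]]
    d <- integer(L + 1L)
    ai <- a[a$contig == ctg, ]
    if (nrow(ai) > 0L) {
      starts <- ai$pos + 1L
      ends <- pmin(ai$pos + ai$len, L) + 1L
      d <- d + tabulate(starts, nbins = L + 1L) - tabulate(ends, nbins = L + 1L)
      d <- cumsum(d)
    }
    d <- d[seq_len(L)]
    mask <- logical(L)
    ri <- regions[regions$contig == ctg, ]
    for (i in seq_len(nrow(ri))) {
      mask[(ri$start[i] + 1L):ri$end[i]] <- TRUE
    }
    d[!mask] <- 0L
    as.integer(d)
  })
  structure(
    list(depth = setNames(depth, names(contig_lengths)), regions = regions,
         mq_min = as.integer(mq_min)),
    class = "camo_depth"
  )
}

#' @export
print.camo_depth <- function(x, ...) {
  cat("<camo_depth> ", length(x$depth), " contig(s), ", nrow(x$regions),
      " region(s), MQ >= ", x$mq_min, "\n", sep = "")
  invisible(x)
}

#' Mean depth over an interval
#' @param depth A [depth_track()] result.
#' @param contig,start,end Interval (0-based half-open).
#' @return Numeric scalar.
#' @export
depth_mean <- function(depth, contig, start, end) {
  mean(depth$depth[[contig]][(start + 1L):end])
}

#' Call camouflaged (low-depth) regions
#'
#' Finds maximal runs of bases with depth below `depth_threshold` inside the
#' evaluated regions, merges runs separated by at most `merge_distance`
#' bases, and annotates each region with its mean depth, overlap with panel
#' exons, read counts and the alternate placements of its non-uniquely
#' mapped reads.
#'
#' @param depth A [depth_track()] result (typically at MQ >= 20).
#' @param panel A [panel()] (for gene/exon annotation).
#' @param aln Optional alignment tibble used for the read-count and
#'   alternate-location annotations.
#' @param depth_threshold Bases with depth strictly below this are low
#'   (default 20).
#' @param merge_distance Merge runs separated by at most this many bases
#'   (default 50).
#' @param mq_nonunique Reads below this MAPQ count as non-unique
#'   (default 10).
#' @param require_nonunique When alignments are supplied, keep only regions
#'   containing at least one non-uniquely mapped read (default TRUE). A
#'   camouflaged region is by definition one where reads cannot be placed
#'   uniquely; requiring non-unique support separates genuine camouflage
#'   from shallow sampling dips in unique sequence, whose reads all map at
#'   full MAPQ.
#' @return Tibble of camo regions: `contig`, `start`, `end`, `gene`,
#'   `mean_depth`, `exonic`, `n_reads`, `n_nonunique`, `alt_locations`
#'   (list-column of interval tibbles).
#' @export
call_camo_regions <- function(depth, panel, aln = NULL, depth_threshold = 20L,
                              merge_distance = 50L, mq_nonunique = 10L,
                              require_nonunique = TRUE) {
  stopifnot(inherits(depth, "camo_depth"))
  regions <- depth$regions
  runs <- list()
  for (i in seq_len(nrow(regions))) {
    ctg <- regions$contig[i]
    d <- depth$depth[[ctg]][(regions$start[i] + 1L):regions$end[i]]
    low <- d < depth_threshold
    if (!any(low)) next
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    li <- which(r$values)
    runs[[length(runs) + 1L]] <- tibble(
      contig = ctg,
      start = regions$start[i] + starts[li] - 1L,
      end = regions$start[i] + ends[li],
      gene = if ("gene" %in% names(regions)) regions$gene[i] else NA_character_
    )
  }
  if (length(runs) == 0L) return(empty_camo())
  out <- bind_rows(runs)
  merged <- lapply(split(out, paste(out$contig, out$gene)), function(x) {
    m <- merge_intervals(x, gap = merge_distance)
    m$gene <- x$gene[1]
    m
  })
  out <- arrange(bind_rows(merged), .data$contig, .data$start)

  out$mean_depth <- vapply(seq_len(nrow(out)), function(i) {
    depth_mean(depth, out$contig[i], out$start[i], out$end[i])
  }, numeric(1))
  out$exonic <- intervals_overlap_any(out, panel$exons)

  if (!is.null(aln)) {
    a <- aln[aln$mapped, ]
    alen <- nchar(a$seq)
    ann <- lapply(seq_len(nrow(out)), function(i) {
      ov <- a$contig == out$contig[i] & a$pos < out$end[i] &
        a$pos + alen > out$start[i]
      sub <- a[ov, ]
      nu <- sub$mapq < mq_nonunique
      alt <- sub[nu & !is.na(sub$alt_contig), c("alt_contig", "alt_pos")]
      alt_iv <- if (nrow(alt) > 0L) {
        merge_intervals(tibble(
          contig = alt$alt_contig, start = alt$alt_pos,
          end = alt$alt_pos + nchar(sub$seq[nu & !is.na(sub$alt_contig)])
        ), gap = 50L)
      } else {
        tibble(contig = character(), start = integer(), end = integer())
      }
      list(n_reads = nrow(sub), n_nonunique = sum(nu), alt = alt_iv)
    })
    out$n_reads <- vapply(ann, `[[`, integer(1), "n_reads")
    out$n_nonunique <- vapply(ann, `[[`, integer(1), "n_nonunique")
    out$alt_locations <- lapply(ann, `[[`, "alt")
    if (require_nonunique) {
      out <- out[out$n_nonunique > 0L, , drop = FALSE]
    }
  } else {
    out$n_reads <- NA_integer_
    out$n_nonunique <- NA_integer_
    out$alt_locations <- rep(list(tibble(contig = character(),
                                         start = integer(),
                                         end = integer())), nrow(out))
  }
  out
}

empty_camo <- function() {
  tibble(contig = character(), start = integer(), end = integer(),
         gene = character(), mean_depth = numeric(), exonic = logical(),
         n_reads = integer(), n_nonunique = integer(),
         alt_locations = list())
}

#' Write camo regions as BED6 plus a TSV sidecar
#'
#' The BED name column carries the gene and the score column the mean depth
#' times ten, rounded; the sidecar records read counts, the non-unique read
#' count, alternate mapping locations and the exonic flag.
#'
#' @param camo Tibble from [call_camo_regions()].
#' @param prefix Output prefix; writes `<prefix>.bed` and `<prefix>.tsv`.
#' @return The two paths, invisibly.
#' @export
write_camo_bed <- function(camo, prefix) {
  bed <- tibble(
    contig = camo$contig, start = camo$start, end = camo$end,
    name = camo$gene, score = as.character(round(camo$mean_depth * 10)),
    strand = "*"
  )
  pb <- paste0(prefix, ".bed")
  pt <- paste0(prefix, ".tsv")
  write_bed(bed, pb)
  side <- mutate(
    select(camo, -"alt_locations"),
    alt_locations = vapply(camo$alt_locations, function(x) {
      if (nrow(x) == 0L) return(".")
      paste(sprintf("%s:%d-%d", x$contig, x$start, x$end), collapse = ",")
    }, "")
  )
  readr::write_tsv(side, pt)
  invisible(c(pb, pt))
}

#' Classify genes by read-length rescue behaviour
#'
#' @param camo_by_length Named list of [call_camo_regions()] tibbles, one
#'   per read length (names are the read lengths, ascending order assumed
#'   by value).
#' @param panel A [panel()].
#' @return Tibble with one row per gene: logical `low_<length>` columns and
#'   a `status` of `never_low`, `rescued_by_longer`, `low_at_all_lengths`,
#'   or `other`.
#' @export
read_length_rescue_table <- function(camo_by_length, panel) {
  if (length(camo_by_length) < 2L) {
    abort("rescue classification requires at least two read lengths")
  }
  lens <- as.integer(names(camo_by_length))
  if (anyNA(lens)) abort("camo_by_length must be named by read length")
  ord <- order(lens)
  lens <- lens[ord]
  camo_by_length <- camo_by_length[ord]
  genes <- unique(panel$genes$gene)
  low <- vapply(camo_by_length, function(camo) {
    genes %in% camo$gene
  }, logical(length(genes)))
  low <- matrix(low, nrow = length(genes),
                dimnames = list(genes, paste0("low_", lens)))
  longest <- ncol(low)
  status <- vapply(seq_along(genes), function(i) {
    l <- low[i, ]
    if (!any(l)) return("never_low")
    if (all(l)) return("low_at_all_lengths")
    if (any(l[-longest]) && !l[longest]) return("rescued_by_longer")
    "other"
  }, "")
  out <- as_tibble(low)
  out$gene <- genes
  out$status <- status
  select(out, "gene", everything())
}
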