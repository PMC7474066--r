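#' Genomic interval tibbles
#'
#' camoseq represents genomic intervals as plain tibbles with columns
#' `contig`, `start`, `end` (0-based, half-open) and optionally `name` and
#' `strand`. All internal coordinates are 0-based half-open; conversion to the
#' 1-based conventions of SAM/VCF happens only in the readers and writers.
#'
#' @param contig Character vector of contig identifiers.
#' @param start,end Integer vectors; 0-based half-open (`0 <= start < end`).
#' @param name Optional labels.
#' @param strand Optional strand, one of `"+"`, `"-"`, `"*"`.
#' @return A tibble with one row per interval.
#' @export
#' @examples
#' genomic_intervals("chr1", 9, 20, name = "ex1")
genomic_intervals <- function(contig, start, end, name = NA_character_,
                              strand = "*") {
  x <- tibble(
    contig = as.character(contig),
    start = as.integer(start),
    end = as.integer(end),
    name = as.character(name),
    strand = as.character(strand)
  )
  validate_intervals(x)
  x
}

validate_intervals <- function(x) {
  stopifnot(all(c("contig", "start", "end") %in% names(x)))
  if (any(is.na(x$contig) | !nzchar(x$contig))) {
    abort("interval contigs must be non-empty")
  }
  if (any(x$start < 0L) || any(x$start >= x$end)) {
    abort("intervals require 0 <= start < end")
  }
  invisible(x)
}

#' Merge intervals into their union
#'
#' Intervals on the same contig are combined when they overlap, touch, or are
#' separated by at most `gap` bases. With `gap = 50` this reproduces the
#' low-depth region merge rule (runs separated by <= 50 bases are joined).
#'
#' @param x Interval tibble.
#' @param gap Maximum separation (bases between `end` of one interval and
#'   `start` of the next) for two intervals to be merged.
#' @return Interval tibble sorted by `(contig, start)`.
#' @export
merge_intervals <- function(x, gap = 0L) {
  validate_intervals(x)
  if (nrow(x) == 0L) {
    return(tibble(contig = character(), start = integer(), end = integer()))
  }
  x <- arrange(x, .data$contig, .data$start, .data$end)
  out <- vector("list", nrow(x))
  k <- 0L
  cur <- x[1, c("contig", "start", "end")]
  if (nrow(x) > 1L) {
    for (i in 2:nrow(x)) {
      same <- x$contig[i] == cur$contig
      if (same && x$start[i] <= cur$end + gap) {
        cur$end <- max(cur$end, x$end[i])
      } else {
        k <- k + 1L
        out[[k]] <- cur
        cur <- x[i, c("contig", "start", "end")]
      }
    }
  }
  k <- k + 1L
  out[[k]] <- cur
  bind_rows(out[seq_len(k)])
}

#' Clip intervals to contig bounds
#'
#' @param x Interval tibble.
#' @param contig_lengths Named integer vector of contig lengths.
#' @return `x` with `start` floored at 0 and `end` capped at the contig
#'   length. Errors if an interval lies on an unknown contig.
#' @export
clip_intervals <- function(x, contig_lengths) {
  validate_intervals(x)
  unknown <- setdiff(unique(x$contig), names(contig_lengths))
  if (length(unknown) > 0) {
    abort(paste0("unknown contig(s): ", paste(unknown, collapse = ", ")))
  }
  x$start <- pmax(0L, x$start)
  x$end <- pmin(as.integer(contig_lengths[x$contig]), x$end)
  x[x$start < x$end, , drop = FALSE]
}

#' Intersect two interval sets
#'
#' @param x,y Interval tibbles.
#' @return The per-base intersection of the two unions, as an interval tibble.
#' @export
intersect_intervals <- function(x, y) {
  x <- merge_intervals(x)
  y <- merge_intervals(y)
  out <- list()
  for (ctg in intersect(unique(x$contig), unique(y$contig))) {
    xi <- x[x$contig == ctg, ]
    yi <- y[y$contig == ctg, ]
    for (i in seq_len(nrow(xi))) {
      s <- pmax(xi$start[i], yi$start)
      e <- pmin(xi$end[i], yi$end)
      keep <- s < e
      if (any(keep)) {
        out[[length(out) + 1L]] <-
          tibble(contig = ctg, start = s[keep], end = e[keep])
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(contig = character(), start = integer(), end = integer()))
  }
  arrange(bind_rows(out), .data$contig, .data$start)
}

#' Do intervals overlap any interval of a second set?
#'
#' @param x,y Interval tibbles.
#' @return Logical vector, one element per row of `x`.
#' @export
intervals_overlap_any <- function(x, y) {
  vapply(seq_len(nrow(x)), function(i) {
    any(y$contig == x$contig[i] & y$start < x$end[i] & y$end > x$start[i])
  }, logical(1))
}

#' Gene panel container
#'
#' A panel is a set of genes, each with sorted non-overlapping exons, plus the
#' exon buffer (added up- and downstream of each exon before homology and
#' mappability analysis) and the simulation flank (added around each gene when
#' reads are simulated).
#'
#' @param genes Tibble with columns `gene`, `contig`, `start`, `end`.
#' @param exons Tibble with columns `gene`, `contig`, `start`, `end`.
#' @param buffer Bases added on each side of every exon (default 70).
#' @param flank Bases added on each side of every gene for read simulation
#'   (default 2000).
#' @return An object of class `camo_panel`.
#' @export
panel <- function(genes, exons, buffer = 70L, flank = 2000L) {
  validate_intervals(genes)
  validate_intervals(exons)
  stopifnot(all(exons$gene %in% genes$gene), buffer >= 0L, flank >= 0L)
  for (g in unique(exons$gene)) {
    e <- exons[exons$gene == g, ]
    e <- arrange(e, .data$start)
    if (nrow(e) > 1L && any(e$start[-1] < e$end[-nrow(e)])) {
      abort(paste0("exons of gene ", g, " overlap"))
    }
  }
  structure(
    list(
      genes = arrange(genes, .data$contig, .data$start),
      exons = arrange(exons, .data$contig, .data$start),
      buffer = as.integer(buffer),
      flank = as.integer(flank)
    ),
    class = "camo_panel"
  )
}

#' @export
print.camo_panel <- function(x, ...) {
  cat("<camo_panel> ", nrow(x$genes), " genes, ", nrow(x$exons),
      " exons, buffer ", x$buffer, " bp, flank ", x$flank, " bp\n", sep = "")
  invisible(x)
}

#' Buffered exons of a panel
#'
#' Expands every exon by the panel buffer on both sides, clips the result to
#' contig bounds, and merges expanded exons that overlap within a gene.
#'
#' @param panel A [panel()].
#' @param contig_lengths Named integer vector of contig lengths.
#' @return Interval tibble with a `gene` column.
#' @export
buffered_exons <- function(panel, contig_lengths) {
  stopifnot(inherits(panel, "camo_panel"))
  ex <- panel$exons
  ex$start <- ex$start - panel$buffer
  ex$end <- ex$end + panel$buffer
  ex$start <- pmax(0L, ex$start)
  ex <- clip_intervals(ex, contig_lengths)
  out <- lapply(split(ex, ex$gene), function(e) {
    m <- merge_intervals(e)
    m$gene <- e$gene[1]
    m
  })
  arrange(bind_rows(out), .data$contig, .data$start)
}

#' Read-simulation regions of a panel
#'
#' Each gene expanded by the simulation flank, clipped to contig bounds.
#' Regions are kept per gene (panel geometry guarantees they do not overlap).
#'
#' @inheritParams buffered_exons
#' @return Interval tibble with a `gene` column.
#' @export
simulation_regions <- function(panel, contig_lengths) {
  stopifnot(inherits(panel, "camo_panel"))
  g <- panel$genes
  tibble(
    contig = g$contig,
    start = pmax(0L, g$start - panel$flank),
    end = pmin(as.integer(contig_lengths[g$contig]), g$end + panel$flank),
    gene = g$gene
  )
}
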