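#' Configuration for the synthetic panel genome
#'
#' The generator emulates a clinical screening panel on a single synthetic
#' contig: `n_genes` genes separated by intergenic spacers, a subset of which
#' ("camo genes") carry a tract that has been copied into downstream
#' intergenic sequence and mutated to a controlled identity — the synthetic
#' analogue of a pseudogene or paralog.
#'
#' Tract divergence supports three spatial profiles. Real gene/pseudogene
#' alignments concentrate their divergence in clusters and indel scars,
#' leaving long identical stretches; a purely uniform (i.i.d.) profile cannot
#' reproduce that geometry, so each tract chooses one of:
#' * `"uniform"` — i.i.d. per-site divergence at rate `1 - identity`;
#' * `"core"` — an identical core of `core` bases centred on the tract
#'   midpoint, with all divergence pushed into the tract margins (overall
#'   identity preserved);
#' * `"isolated"` — an identical window of `core` bases centred on the tract
#'   midpoint containing exactly one divergent site at its centre, uniform
#'   divergence elsewhere. This hosts the converting-variant scenario: the
#'   single central difference is the only anchor distinguishing gene from
#'   pseudogene locally.
#'
#' The default panel has 158 genes (the size of the newborn-screening panel
#' this emulates) and four camo genes spanning the qualitative regimes:
#' 400 bp @ 99.5% (rescued by moderate read lengths), 3 kb @ 97.7% with a
#' 600 bp identical core (rescued only by the longest reads), 6 kb @ 99.9%
#' uniform (never rescued — no read or fragment spans it), and 3 kb @ 97.7%
#' with an isolated divergent site (the converting-variant host). High-
#' homology tracts total under 1% of simulated-region bases.
#'
#' @param n_genes Number of genes in the panel.
#' @param gene_length Gene length in bp (camo genes are extended when their
#'   tract would not fit).
#' @param exons_per_gene Number of exons per gene.
#' @param exon_length Exon length in bp.
#' @param n_camo_genes Number of genes given a homologous tract.
#' @param camo_tracts Tibble with one row per camo gene: `tract_length` (bp),
#'   `identity` (fraction), `profile` (`"uniform"`, `"core"`, `"isolated"`),
#'   `core` (bp of identical core/window; `NA` for uniform).
#' @param intergenic_spacer Baseline spacer between genes (bp); spacers
#'   hosting a pseudogene copy are widened so the copy stays clear of the
#'   2 kb simulation flanks.
#' @param base_composition Probabilities for A, C, G, T.
#' @param buffer,flank Passed to [panel()].
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A `synthetic_genome_config` list.
#' @export
synthetic_genome_config <- function(n_genes = 158L,
                                    gene_length = 5000L,
                                    exons_per_gene = 5L,
                                    exon_length = 160L,
                                    n_camo_genes = 4L,
                                    camo_tracts = default_camo_tracts(n_camo_genes),
                                    intergenic_spacer = 4500L,
                                    base_composition = c(A = 0.25, C = 0.25,
                                                         G = 0.25, T = 0.25),
                                    buffer = 70L,
                                    flank = 2000L,
                                    seed = 42L) {
  stopifnot(
    n_genes >= 1L, n_camo_genes <= n_genes, n_camo_genes >= 0L,
    exons_per_gene >= 1L, exon_length >= 1L,
    exons_per_gene * exon_length < gene_length,
    abs(sum(base_composition) - 1) < 1e-8
  )
  if (n_camo_genes > 0L) {
    stopifnot(
      nrow(camo_tracts) == n_camo_genes,
      all(camo_tracts$identity > 0), all(camo_tracts$identity <= 1),
      all(camo_tracts$profile %in% c("uniform", "core", "isolated"))
    )
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      gene_length = as.integer(gene_length),
      exons_per_gene = as.integer(exons_per_gene),
      exon_length = as.integer(exon_length),
      n_camo_genes = as.integer(n_camo_genes),
      camo_tracts = camo_tracts,
      intergenic_spacer = as.integer(intergenic_spacer),
      base_composition = base_composition,
      buffer = as.integer(buffer),
      flank = as.integer(flank),
      seed = as.integer(seed)
    ),
    class = "synthetic_genome_config"
  )
}

#' Default camo-tract geometry
#' @param n Number of tracts (the first `n` rows of the default table).
#' @return Tibble of tract descriptions.
#' @export
default_camo_tracts <- function(n = 4L) {
  tracts <- tibble(
    tract_length = c(400L, 3000L, 6000L, 3000L),
    identity = c(0.995, 0.977, 0.999, 0.977),
    profile = c("core", "core", "uniform", "isolated"),
    core = c(340L, 600L, NA_integer_, 700L)
  )
  if (n > nrow(tracts)) abort("no default geometry for that many camo genes")
  tracts[seq_len(n), , drop = FALSE]
}

random_sequence <- function(n, base_composition) {
  paste(sample(names(base_composition), n, replace = TRUE,
               prob = base_composition), collapse = "")
}

# mutate `positions` (1-based offsets within seq) to a random different base
mutate_positions <- function(seq, positions) {
  if (length(positions) == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in positions) {
    chars[p] <- sample(setdiff(bases, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# divergent-site offsets (1-based) for one tract, by profile
draw_divergent_sites <- function(tract_length, identity, profile, core) {
  rate <- 1 - identity
  n_target <- rbinom(1L, tract_length, rate)
  if (profile == "uniform") {
    return(sort(sample.int(tract_length, min(n_target, tract_length))))
  }
  mid <- floor(tract_length / 2)
  win <- c(mid - floor(core / 2) + 1L, mid + ceiling(core / 2))
  margin <- setdiff(seq_len(tract_length), seq(win[1], win[2]))
  if (profile == "core") {
    return(sort(sample(margin, min(n_target, length(margin)))))
  }
  # isolated: exactly one divergent site at the window centre
  centre <- mid + 1L
  extra <- sort(sample(margin, min(max(n_target - 1L, 0L), length(margin))))
  sort(unique(c(centre, extra)))
}

#' Generate a synthetic panel reference
#'
#' Builds the reference sequence, the gene panel and the camo truth table
#' from a [synthetic_genome_config()]. For each camo gene the designated
#' tract (centred on the gene's middle exon) is copied into the following
#' intergenic spacer and mutated according to its divergence profile;
#' `camo_truth` records the exact gene-to-pseudogene coordinate pairing.
#'
#' @param config A [synthetic_genome_config()].
#' @return A list with elements `reference` ([reference()]), `panel`
#'   ([panel()]) and `camo_truth` (tibble: gene, contig, tract coordinates on
#'   gene and pseudogene copy, identity, profile).
#' @export
make_reference <- function(config) {
  stopifnot(inherits(config, "synthetic_genome_config"))
  with_seed(config$seed, make_reference_impl(config))
}

make_reference_impl <- function(config) {
  n <- config$n_genes
  ncamo <- config$n_camo_genes
  camo_idx <- if (ncamo > 0L) {
    unique(round(seq(1L, n, length.out = ncamo + 2L)))[2:(ncamo + 1L)]
  } else integer()
  tracts <- config$camo_tracts
  margin <- config$flank + 250L  # keeps pseudogene clear of simulation flanks

  gene_len <- rep(config$gene_length, n)
  if (ncamo > 0L) {
    gene_len[camo_idx] <- pmax(config$gene_length,
                               tracts$tract_length + 400L)
    if (any(tracts$tract_length > gene_len[camo_idx])) {
      abort("pseudogene tract longer than its gene")
    }
  }

  # exon offsets within a gene: evenly spaced, middle exon centred mid-gene
  exon_offsets <- function(glen) {
    k <- config$exons_per_gene
    gap <- (glen - k * config$exon_length) / (k + 1)
    starts <- round(gap * seq_len(k) + config$exon_length * (seq_len(k) - 1))
    as.integer(starts)
  }

  pieces <- character(0)
  cursor <- 0L
  genes <- list()
  exons <- list()
  truth <- list()
  pending_pseudo <- NULL  # sequence to embed in the next spacer

  add_spacer <- function(len, pseudo = NULL, pseudo_at = NULL) {
    s <- random_sequence(len, config$base_composition)
    if (!is.null(pseudo)) {
      substr(s, pseudo_at + 1L, pseudo_at + nchar(pseudo)) <- pseudo
    }
    s
  }

  for (i in seq_len(n)) {
    # spacer before gene i; embeds the pseudogene of gene i-1 when present
    spacer_len <- config$intergenic_spacer
    pseudo_seq <- NULL
    pseudo_at <- NULL
    if (!is.null(pending_pseudo)) {
      spacer_len <- max(spacer_len, nchar(pending_pseudo$seq) + 2L * margin)
      pseudo_at <- margin
      pseudo_seq <- pending_pseudo$seq
    }
    sp <- add_spacer(spacer_len, pseudo_seq, pseudo_at)
    if (!is.null(pending_pseudo)) {
      truth[[length(truth) + 1L]] <- mutate(
        pending_pseudo$row,
        pseudo_start = cursor + pseudo_at,
        pseudo_end = cursor + pseudo_at + .data$tract_length
      )
      pending_pseudo <- NULL
    }
    pieces <- c(pieces, sp)
    cursor <- cursor + spacer_len

    glen <- gene_len[i]
    gseq <- random_sequence(glen, config$base_composition)
    gname <- sprintf("gene%03d", i)
    genes[[i]] <- tibble(contig = "chrS", start = cursor,
                         end = cursor + glen, gene = gname)
    offs <- exon_offsets(glen)
    exons[[i]] <- tibble(
      contig = "chrS",
      start = cursor + offs,
      end = cursor + offs + config$exon_length,
      gene = gname,
      name = sprintf("%s_ex%d", gname, seq_along(offs))
    )
    if (i %in% camo_idx) {
      t <- tracts[match(i, camo_idx), ]
      mid_exon <- offs[ceiling(config$exons_per_gene / 2)] +
        config$exon_length %/% 2L
      ts <- min(max(0L, mid_exon - t$tract_length %/% 2L),
                glen - t$tract_length)
      tract <- substr(gseq, ts + 1L, ts + t$tract_length)
      sites <- draw_divergent_sites(t$tract_length, t$identity, t$profile,
                                    t$core)
      pending_pseudo <- list(
        seq = mutate_positions(tract, sites),
        row = tibble(
          gene = gname, contig = "chrS",
          gene_tract_start = cursor + ts,
          gene_tract_end = cursor + ts + t$tract_length,
          tract_length = t$tract_length,
          identity = t$identity,
          profile = t$profile
        )
      )
    }
    pieces <- c(pieces, gseq)
    cursor <- cursor + glen
  }
  # closing spacer (embeds the last pseudogene if the last gene is camo)
  spacer_len <- config$intergenic_spacer
  pseudo_seq <- NULL
  pseudo_at <- NULL
  if (!is.null(pending_pseudo)) {
    spacer_len <- max(spacer_len, nchar(pending_pseudo$seq) + 2L * margin)
    pseudo_at <- margin
    pseudo_seq <- pending_pseudo$seq
  }
  pieces <- c(pieces, add_spacer(spacer_len, pseudo_seq, pseudo_at))
  if (!is.null(pending_pseudo)) {
    truth[[length(truth) + 1L]] <- mutate(
      pending_pseudo$row,
      pseudo_start = cursor + pseudo_at,
      pseudo_end = cursor + pseudo_at + .data$tract_length
    )
  }

  ref <- reference(c(chrS = paste(pieces, collapse = "")))
  pn <- panel(bind_rows(genes), bind_rows(exons),
              buffer = config$buffer, flank = config$flank)
  ct <- if (length(truth) > 0L) {
    select(bind_rows(truth), "gene", "contig", "gene_tract_start",
           "gene_tract_end", "pseudo_start", "pseudo_end", "tract_length",
           "identity", "profile")
  } else {
    tibble(gene = character(), contig = character(),
           gene_tract_start = integer(), gene_tract_end = integer(),
           pseudo_start = integer(), pseudo_end = integer(),
           tract_length = integer(), identity = double(),
           profile = character())
  }
  list(reference = ref, panel = pn, camo_truth = ct)
}

#' Divergent sites of a camo tract
#'
#' Compares the gene tract to its pseudogene copy and returns the 0-based
#' offsets (within the tract) where they differ.
#'
#' @param genome A genome list from [make_reference()].
#' @param gene Gene name (must appear in `camo_truth`).
#' @return Integer vector of 0-based tract offsets.
#' @export
camo_divergent_sites <- function(genome, gene) {
  ct <- genome$camo_truth
  row <- ct[ct$gene == gene, ]
  if (nrow(row) != 1L) abort(paste0(gene, " has no camo tract"))
  g <- ref_seq(genome$reference, row$contig, row$gene_tract_start,
               row$gene_tract_end)
  p <- ref_seq(genome$reference, row$contig, row$pseudo_start, row$pseudo_end)
  which(strsplit(g, "")[[1]] != strsplit(p, "")[[1]]) - 1L
}

# run expr under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
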