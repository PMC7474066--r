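# Shared fixtures and independent oracles. Heavy objects (the default-panel
# genome and its four-read-length evaluation) are computed once per test run
# and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small panel: 8 genes, the three classic camo tracts, ~91 kb genome
small_genome <- function() {
  cached("small_genome", {
    make_reference(synthetic_genome_config(
      n_genes = 8L, n_camo_genes = 3L,
      camo_tracts = default_camo_tracts(3L), seed = 11L
    ))
  })
}

default_genome <- function() {
  cached("default_genome", make_reference(synthetic_genome_config()))
}

default_simeval <- function() {
  cached("default_simeval", {
    run_simeval(default_genome(), read_lengths = c(70L, 100L, 150L, 250L),
                seed = 3L)
  })
}

default_flag <- function() {
  cached("default_flag", run_flag(default_genome()))
}

default_popsim <- function() {
  cached("default_popsim", {
    g <- default_genome()
    simulate_population_genotypes(g$panel, population_config(),
                                  ref = g$reference)
  })
}

# a tiny two-contig reference with an exact duplicated tract, for oracle
# tests (deterministic)
dup_reference <- function(dup_len = 500L, seed = 3L) {
  camoseq:::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    a <- paste(sample(bases, 6000, replace = TRUE), collapse = "")
    dup <- substr(a, 2001, 2000 + dup_len)
    b <- paste(sample(bases, 4000, replace = TRUE), collapse = "")
    substr(b, 1001, 1000 + dup_len) <- dup
    reference(c(ctgA = a, ctgB = b))
  })
}

# --- oracles -------------------------------------------------------------

# per-base set oracle for interval union with a merge gap
oracle_merge <- function(x, gap = 0L) {
  out <- list()
  for (ctg in sort(unique(x$contig))) {
    xi <- x[x$contig == ctg, ]
    max_end <- max(xi$end)
    covered <- logical(max_end + gap + 2L)
    for (i in seq_len(nrow(xi))) {
      covered[(xi$start[i] + 1L):xi$end[i]] <- TRUE
    }
    # close gaps of length <= gap
    r <- rle(covered)
    pos <- cumsum(r$lengths)
    for (j in seq_along(r$values)) {
      if (!r$values[j] && j > 1L && j < length(r$values) &&
          r$lengths[j] <= gap) {
        covered[(pos[j] - r$lengths[j] + 1L):pos[j]] <- TRUE
      }
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (length(keep)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        contig = ctg, start = as.integer(starts[keep] - 1L),
        end = as.integer(ends[keep])
      )
    }
  }
  dplyr::bind_rows(out)
}

# brute-force k-mer occurrence counts (both strands) for small references
oracle_kmer_counts <- function(ref, k) {
  all_kmers <- unlist(lapply(ref, function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1L) return(character())
    substring(s, seq_len(n), seq_len(n) + k - 1L)
  }), use.names = FALSE)
  tab <- table(all_kmers)
  lapply(ref, function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1L) return(numeric())
    km <- substring(s, seq_len(n), seq_len(n) + k - 1L)
    rc <- revcomp(km)
    cnt <- as.integer(tab[km])
    cnt[is.na(cnt)] <- 0L
    cnt2 <- as.integer(tab[rc])
    cnt2[is.na(cnt2)] <- 0L
    has_n <- grepl("N", km, fixed = TRUE)
    ifelse(has_n, 0, cnt + cnt2)
  })
}

# exhaustive all-position ungapped alignment of a read over a small genome;
# returns the best (contig, pos, strand, score) with the mapper's tie order
oracle_best_locus <- function(ref, read, mismatch_pen = 4L) {
  best <- NULL
  ints <- lapply(ref, function(s) utf8ToInt(s))
  for (strand in c("+", "-")) {
    rs <- if (strand == "+") read else revcomp(read)
    ri <- utf8ToInt(rs)
    L <- length(ri)
    for (ci in seq_along(ints)) {
      g <- ints[[ci]]
      if (length(g) < L) next
      for (p in 0:(length(g) - L)) {
        mm <- sum(g[(p + 1L):(p + L)] != ri)
        sc <- L - (1L + mismatch_pen) * mm
        cand <- list(contig = names(ref)[ci], pos = p, strand = strand,
                     score = sc)
        if (is.null(best) || sc > best$score) best <- cand
      }
    }
  }
  best
}

# literal per-site transcription of the Weir & Cockerham (1984) a, b, c
# components, computed with explicit loops
oracle_wc <- function(geno, pops) {
  upops <- unique(pops)
  r <- length(upops)
  n_sites <- ncol(geno)
  a <- b <- cc <- numeric(n_sites)
  for (s in seq_len(n_sites)) {
    n_i <- p_i <- h_i <- numeric(r)
    for (k in seq_len(r)) {
      gk <- geno[pops == upops[k], s]
      n_i[k] <- length(gk)
      p_i[k] <- mean(gk) / 2
      h_i[k] <- mean(gk == 1)
    }
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n_i * p_i) / (r * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    a[s] <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) *
         (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b[s] <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
         ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc[s] <- hbar / 2
  }
  list(a = a, b = b, c = cc)
}

# dosage-enumeration genotype oracle with explicit per-read products
oracle_genotype <- function(n_ref, n_alt, ploidy, e) {
  lik <- vapply(0:ploidy, function(d) {
    pa <- (d / ploidy) * (1 - e) + (1 - d / ploidy) * (e / 3)
    pr <- (1 - d / ploidy) * (1 - e) + (d / ploidy) * (e / 3)
    l <- 1
    for (i in seq_len(n_alt)) l <- l * pa
    for (i in seq_len(n_ref)) l <- l * pr
    l
  }, numeric(1))
  ord <- order(lik, decreasing = TRUE)
  list(dosage = (0:ploidy)[ord[1]],
       gq = 10 * (log10(lik[ord[1]]) - log10(lik[ord[2]])))
}

random_seq <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else camoseq:::with_seed(seed, draw())
}

# Converting-variant rescue fixture on the default panel: all four
# strategies for the hom scenario, standard with alignments kept, plus a
# no-variant baseline over the same region (for the coverage-collapse
# comparison).
default_rescue <- function() {
  cached("default_rescue", {
    g <- default_genome()
    gene <- g$camo_truth$gene[g$camo_truth$profile == "isolated"][1]
    idx <- build_index(g$reference, 19L)
    midx <- build_index(camoseq:::masked_reference_for(g, gene), 19L)
    sc_hom <- make_scenario(g, gene, converting = TRUE, zygosity = "hom")
    sc_het <- make_scenario(g, gene, converting = TRUE, zygosity = "het")
    # the ploidy-4 scan may emit its ambiguous-dosage warning here; that
    # behaviour has its own test in test-caller.R
    runs_hom <- suppressWarnings(
      lapply(stats::setNames(nm = strategy_names()), function(st) {
        run_strategy(sc_hom, st, index = idx, masked_index = midx,
                     keep_alignments = (st == "standard"))
      })
    )
    het_std <- run_strategy(sc_het, "standard", index = idx,
                            masked_index = midx, keep_alignments = TRUE)
    # no-variant baseline under the same simulation settings
    cfg <- sc_hom$sim_config
    regs <- simulation_regions(g$panel, reference_lengths(g$reference))
    region <- regs[regs$gene == gene, c("contig", "start", "end")]
    reads0 <- simulate_reads(g$reference, g$reference, region, cfg,
                             individual = "baseline")
    aln0 <- map_read_pairs(idx, reads0,
                           2 * cfg$read_length + cfg$inner_distance_mean,
                           cfg$inner_distance_sd)
    list(genome = g, gene = gene, scenario_hom = sc_hom,
         runs_hom = runs_hom, het_std = het_std, baseline_aln = aln0,
         index = idx, masked_index = midx)
  })
}
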