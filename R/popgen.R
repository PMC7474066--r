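#' Principal component analysis of genotypes
#'
#' Monomorphic sites are dropped; genotypes are standardised per site by
#' their mean `2p` and binomial scale `sqrt(2p(1-p))`; the eigendecomposition
#' of the individual-by-individual covariance matrix gives the coordinates
#' (eigenvectors scaled by the square root of their eigenvalues).
#'
#' @param genotypes Individuals x sites matrix of alt-allele dosages
#'   (0/1/2), e.g. from [simulate_population_genotypes()].
#' @param populations Population label per individual.
#' @param n_pcs Number of components to keep.
#' @return A `camo_pca` object with `scores` (tibble) and
#'   `explained_variance`.
#' @export
genotype_pca <- function(genotypes, populations = NULL, n_pcs = 10L) {
  if (nrow(genotypes) < 2L) abort("PCA requires at least two individuals")
  p <- colMeans(genotypes) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) abort("all sites are monomorphic")
  g <- genotypes[, keep, drop = FALSE]
  p <- p[keep]
  z <- sweep(g, 2L, 2 * p, "-")
  z <- sweep(z, 2L, sqrt(2 * p * (1 - p)), "/")
  cv <- tcrossprod(z) / ncol(z)
  eg <- eigen(cv, symmetric = TRUE)
  m <- min(n_pcs, nrow(genotypes) - 1L)
  vals <- pmax(eg$values, 0)
  coords <- eg$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(m)]), m)
  colnames(coords) <- paste0("PC", seq_len(m))
  scores <- as_tibble(coords)
  scores$individual <- if (!is.null(rownames(genotypes))) {
    rownames(genotypes)
  } else {
    sprintf("ind%03d", seq_len(nrow(genotypes)))
  }
  scores$population <- if (!is.null(populations)) {
    populations
  } else {
    NA_character_
  }
  structure(
    list(scores = select(scores, "individual", "population", everything()),
         explained_variance = vals[seq_len(m)] / sum(vals),
         n_sites = ncol(g)),
    class = "camo_pca"
  )
}

#' @export
print.camo_pca <- function(x, ...) {
  cat("<camo_pca> ", nrow(x$scores), " individuals, ", x$n_sites,
      " polymorphic sites; PC1 explains ",
      sprintf("%.1f%%", 100 * x$explained_variance[1]), "\n", sep = "")
  invisible(x)
}

# Weir & Cockerham (1984) per-site variance components a, b, c for diploids
wc_components <- function(genotypes, populations) {
  pops <- unique(populations)
  r <- length(pops)
  if (r < 2L) abort("FST requires at least two populations")
  n_i <- vapply(pops, function(p) sum(populations == p), numeric(1))
  if (any(n_i < 2L)) abort("each population needs at least two individuals")
  p_i <- vapply(pops, function(p) {
    colMeans(genotypes[populations == p, , drop = FALSE]) / 2
  }, numeric(ncol(genotypes)))
  h_i <- vapply(pops, function(p) {
    colMeans(genotypes[populations == p, , drop = FALSE] == 1L)
  }, numeric(ncol(genotypes)))
  p_i <- matrix(p_i, ncol = r)
  h_i <- matrix(h_i, ncol = r)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- as.vector(p_i %*% n_i) / (r * nbar)
  hbar <- as.vector(h_i %*% n_i) / (r * nbar)
  s2 <- as.vector(((p_i - pbar)^2) %*% n_i) / ((r - 1) * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c <- hbar / 2
  tibble(a = a, b = b, c = c)
}

#' Weir-Cockerham FST estimates
#'
#' Computes the Weir & Cockerham (1984) variance-component estimator from
#' diploid genotypes: per site `a / (a + b + c)`, and for multi-site
#' estimates the ratio of sums `sum(a) / sum(a + b + c)`.
#'
#' @param genotypes Individuals x sites dosage matrix.
#' @param populations Population label per individual (>= 2 populations with
#'   >= 2 individuals each).
#' @param by `"global"` (one estimate), `"site"` (per site), or `"window"`
#'   (per stepping window; requires `sites` and `windows`).
#' @param sites Tibble (`contig`, `pos`) aligned with genotype columns.
#' @param windows Interval tibble of stepping windows (see
#'   [fst_windows()]).
#' @return A tibble: global — `fst`, `n_sites`; site — one row per site;
#'   window — one row per window (`fst` is `NA` for windows without sites).
#' @export
wc_fst <- function(genotypes, populations, by = c("global", "site", "window"),
                   sites = NULL, windows = NULL) {
  by <- match.arg(by)
  comp <- wc_components(genotypes, populations)
  denom <- comp$a + comp$b + comp$c
  if (by == "global") {
    return(tibble(fst = sum(comp$a) / sum(denom), n_sites = nrow(comp)))
  }
  if (by == "site") {
    out <- tibble(fst = if_else(denom != 0, comp$a / denom, NA_real_),
                  a = comp$a, b = comp$b, c = comp$c)
    if (!is.null(sites)) out <- bind_cols(sites[, c("contig", "pos")], out)
    return(out)
  }
  if (is.null(sites) || is.null(windows)) {
    abort("windowed FST requires site coordinates and windows")
  }
  stopifnot(nrow(sites) == nrow(comp))
  res <- vapply(seq_len(nrow(windows)), function(i) {
    inw <- sites$contig == windows$contig[i] &
      sites$pos >= windows$start[i] & sites$pos < windows$end[i]
    if (!any(inw)) return(c(NA_real_, 0))
    c(sum(comp$a[inw]) / sum(denom[inw]), sum(inw))
  }, numeric(2))
  out <- windows
  out$fst <- res[1, ]
  out$n_sites <- as.integer(res[2, ])
  structure(out, class = c("camo_fst_windows", class(out)))
}

#' Stepping windows tiling panel genes
#'
#' Non-overlapping windows of `size` bases tiling each gene body (final
#' partial windows kept).
#'
#' @param panel A [panel()].
#' @param size Window size in bp (1 kb default; 150 bp is the common
#'   fine-scale alternative).
#' @return Interval tibble with a `gene` column.
#' @export
fst_windows <- function(panel, size = 1000L) {
  g <- panel$genes
  out <- lapply(seq_len(nrow(g)), function(i) {
    starts <- seq(g$start[i], g$end[i] - 1L, by = size)
    tibble(contig = g$contig[i], start = as.integer(starts),
           end = as.integer(pmin(starts + size, g$end[i])),
           gene = g$gene[i])
  })
  bind_rows(out)
}

#' Correlation between windowed FST and population depth differences
#'
#' Pairs each window's FST with the absolute difference of the two
#' populations' mean depth in that window and reports a Spearman rank
#' correlation over windows with both values present.
#'
#' @param fst_win Windowed [wc_fst()] output.
#' @param depth_a,depth_b [depth_track()] results for the two populations.
#' @return Tibble with `rho`, `p_value`, `n_windows`, `degenerate` (TRUE
#'   when all depth differences tie, in which case `rho` is reported as 0).
#' @export
depth_fst_correlation <- function(fst_win, depth_a, depth_b) {
  diffs <- vapply(seq_len(nrow(fst_win)), function(i) {
    abs(depth_mean(depth_a, fst_win$contig[i], fst_win$start[i],
                   fst_win$end[i]) -
          depth_mean(depth_b, fst_win$contig[i], fst_win$start[i],
                     fst_win$end[i]))
  }, numeric(1))
  ok <- !is.na(fst_win$fst) & !is.na(diffs)
  if (sum(ok) < 3L) abort("fewer than 3 complete windows")
  x <- fst_win$fst[ok]
  y <- diffs[ok]
  if (length(unique(y)) == 1L || length(unique(x)) == 1L) {
    return(tibble(rho = 0, p_value = NA_real_, n_windows = sum(ok),
                  degenerate = TRUE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value,
         n_windows = sum(ok), degenerate = FALSE)
}
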