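#' @export
tidy.camo_pca <- function(x, ...) {
  x$scores
}

#' @export
glance.camo_pca <- function(x, ...) {
  tibble(
    n_individuals = nrow(x$scores),
    n_sites = x$n_sites,
    pc1_variance = x$explained_variance[1],
    pc2_variance = x$explained_variance[2]
  )
}

#' @export
tidy.camo_depth <- function(x, ...) {
  out <- lapply(seq_len(nrow(x$regions)), function(i) {
    r <- x$regions[i, ]
    tibble(
      contig = r$contig,
      pos = seq(r$start, r$end - 1L),
      depth = x$depth[[r$contig]][(r$start + 1L):r$end],
      gene = if (!is.null(r$gene)) r$gene else NA_character_
    )
  })
  bind_rows(out)
}

#' @export
glance.camo_depth <- function(x, ...) {
  d <- tidy(x)
  tibble(
    mean_depth = mean(d$depth),
    sd_depth = sd(d$depth),
    frac_below_20 = mean(d$depth < 20),
    mq_min = x$mq_min
  )
}

#' Plot genotype PCA coordinates
#'
#' @param object A [genotype_pca()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.camo_pca <- function(object, ...) {
  s <- object$scores
  pct <- function(i) sprintf("PC%d (%.1f%%)", i,
                             100 * object$explained_variance[i])
  ggplot2::ggplot(s, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                  colour = .data$population)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = pct(1), y = pct(2), colour = "Population") +
    ggplot2::theme_minimal()
}

#' Plot depth of coverage along a gene
#'
#' @param object A [depth_track()] result.
#' @param gene Optional gene to restrict to.
#' @param depth_threshold Horizontal guide (default 20).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.camo_depth <- function(object, gene = NULL, depth_threshold = 20, ...) {
  d <- tidy(object)
  if (!is.null(gene)) d <- d[d$gene %in% gene, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = depth_threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::facet_wrap(~gene, scales = "free_x") +
    ggplot2::labs(x = "Position (bp)", y = "Depth") +
    ggplot2::theme_minimal()
}

#' Plot windowed FST along the panel
#'
#' @param object A windowed [wc_fst()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.camo_fst_windows <- function(object, ...) {
  d <- object[!is.na(object$fst), ]
  d$mid <- (d$start + d$end) / 2
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$fst)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(x = "Window midpoint (bp)", y = expression(F[ST])) +
    ggplot2::theme_minimal()
}

#' Plot per-gene camo status across read lengths
#'
#' @param rescue A [read_length_rescue_table()] result.
#' @return A ggplot tile map of low-depth status (camo genes only).
#' @export
plot_rescue_table <- function(rescue) {
  d <- rescue[rescue$status != "never_low", ]
  long <- tidyr::pivot_longer(d, dplyr::starts_with("low_"),
                              names_to = "read_length", values_to = "low")
  long$read_length <- as.integer(sub("low_", "", long$read_length))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$read_length),
                                     y = .data$gene, fill = .data$low)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey85",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Read length (bp)", y = NULL,
                  fill = "Low depth") +
    ggplot2::theme_minimal()
}
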