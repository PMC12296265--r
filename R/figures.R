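# Figure builders for the result bundle. Each is a pure function of the
# tables it is given, so regenerating from the saved CSVs reproduces the
# figures.

#' @import ggplot2
NULL

#' Regional cross-correlation heatmap
#'
#' @param corr a \code{\link{CorrelationMatrix-class}} or a square
#'   correlation data.frame/matrix with region dimnames.
#' @param title plot title.
#' @return a ggplot object.
#' @export
figHeatmap <- function(corr, title = "Regional cross-correlation") {
  r <- if (is(corr, "CorrelationMatrix")) corValues(corr) else as.matrix(corr)
  regions <- rownames(r)
  df <- data.frame(a = factor(rep(regions, times = ncol(r)), levels = regions),
                   b = factor(rep(regions, each = nrow(r)),
                              levels = rev(regions)),
                   r = as.vector(r))
  ggplot(df, aes(x = .data$a, y = .data$b, fill = .data$r)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                         limits = c(-1, 1), name = "r") +
    labs(title = title, x = NULL, y = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' Functional network diagram
#'
#' Nodes on a deterministic circular layout; edge colour encodes the sign
#' of the correlation and width its magnitude.
#'
#' @param network a \code{\link{FunctionalNetwork-class}}.
#' @param title plot title.
#' @return a ggplot object.
#' @export
figNetwork <- function(network, title = "Functional network") {
  nodes <- networkNodes(network)
  th <- seq(0, 2 * pi, length.out = length(nodes) + 1)[seq_along(nodes)]
  lay <- data.frame(region = nodes, x = cos(th), y = sin(th))
  e <- networkEdges(network)
  p <- ggplot()
  if (nrow(e)) {
    e$x <- lay$x[match(e$region_a, nodes)]
    e$y <- lay$y[match(e$region_a, nodes)]
    e$xend <- lay$x[match(e$region_b, nodes)]
    e$yend <- lay$y[match(e$region_b, nodes)]
    e$sign <- ifelse(e$r >= 0, "correlated", "anti-correlated")
    p <- p + geom_segment(data = e,
                          aes(x = .data$x, y = .data$y, xend = .data$xend,
                              yend = .data$yend, colour = .data$sign,
                              linewidth = abs(.data$r))) +
      scale_colour_manual(values = c(correlated = "#B2182B",
                                     `anti-correlated` = "#2166AC"),
                          limits = c("correlated", "anti-correlated")) +
      scale_linewidth(range = c(0.3, 1.5), guide = "none")
  }
  p + geom_point(data = lay, aes(x = .data$x, y = .data$y), size = 3) +
    geom_text(data = lay, aes(x = .data$x * 1.12, y = .data$y * 1.12,
                              label = .data$region), size = 3) +
    coord_equal() + labs(title = title) + theme_void()
}

#' Volcano plot of permuted correlation differences
#'
#' d = r(group B) - r(group A) against -log10 permutation p, with the
#' significance box |d| > dThresh and p < alpha highlighted.
#'
#' @param pairs data.frame from \code{\link{permPairs}} (columns d, p).
#' @param dThresh absolute correlation-difference threshold (default 1).
#' @param alpha significance threshold (default 0.01).
#' @param title plot title.
#' @return a ggplot object; the highlighted subset is attached as
#'   \code{attr(, "highlighted")}.
#' @export
figVolcano <- function(pairs, dThresh = 1, alpha = 0.01,
                       title = "Correlation differences") {
  pairs <- pairs[!is.na(pairs$d) & !is.na(pairs$p), ]
  pairs$significant <- abs(pairs$d) > dThresh & pairs$p < alpha
  pairs$sigf <- factor(pairs$significant, levels = c(FALSE, TRUE))
  g <- ggplot(pairs, aes(x = .data$d, y = -log10(.data$p),
                         colour = .data$sigf)) +
    geom_point(alpha = 0.7) +
    geom_vline(xintercept = c(-dThresh, dThresh), linetype = "dashed") +
    geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "#B2182B"),
                        limits = c("FALSE", "TRUE"), guide = "none") +
    labs(title = title, x = "correlation difference (B - A)",
         y = "-log10 p") +
    theme_classic()
  attr(g, "highlighted") <- pairs[pairs$significant, , drop = FALSE]
  g
}

#' Parallel-coordinate plot of significantly changed correlations
#'
#' One ribbon per significant pair, from its correlation in group A to its
#' correlation in group B.
#'
#' @param pairs data.frame with columns region_a, region_b, r_a, r_b, d, p.
#' @param dThresh,alpha the significance box (as in \code{\link{figVolcano}}).
#' @param groups axis labels.
#' @param title plot title.
#' @return a ggplot object (one ribbon per significant pair).
#' @export
figParallel <- function(pairs, dThresh = 1, alpha = 0.01,
                        groups = c("A", "B"),
                        title = "Significantly changed correlations") {
  sig <- pairs[!is.na(pairs$d) & !is.na(pairs$p) &
                 abs(pairs$d) > dThresh & pairs$p < alpha, , drop = FALSE]
  df <- if (nrow(sig)) {
    data.frame(pair = rep(paste(sig$region_a, sig$region_b, sep = "-"), 2),
               group = factor(rep(groups, each = nrow(sig)), levels = groups),
               r = c(sig$r_a, sig$r_b),
               direction = factor(rep(ifelse(sig$d > 0, "up", "down"), 2),
                                  levels = c("down", "up")))
  } else {
    data.frame(pair = character(), group = factor(character(), levels = groups),
               r = numeric(),
               direction = factor(character(), levels = c("down", "up")))
  }
  ggplot(df, aes(x = .data$group, y = .data$r, group = .data$pair,
                 colour = .data$direction)) +
    geom_line(linewidth = 0.8, alpha = 0.8) + geom_point() +
    scale_colour_manual(values = c(up = "#B2182B", down = "#2166AC"),
                        limits = c("down", "up")) +
    labs(title = title, x = NULL, y = "Pearson r") +
    ylim(-1.05, 1.05) + theme_classic()
}

#' Per-region correlation distribution comparison
#'
#' Empirical distributions of one region's correlations with all other
#' regions, one curve per group (the view the KS test formalizes).
#'
#' @param valuesA,valuesB the two correlation vectors (see
#'   \code{\link{ksRegionDistributions}}).
#' @param region region acronym for the title.
#' @param groups group labels.
#' @return a ggplot object.
#' @export
figDistribution <- function(valuesA, valuesB, region = "",
                            groups = c("A", "B")) {
  df <- data.frame(r = c(valuesA, valuesB),
                   group = factor(rep(groups, c(length(valuesA),
                                                length(valuesB))),
                                  levels = groups))
  ggplot(df, aes(x = .data$r, colour = .data$group)) +
    stat_ecdf(linewidth = 0.8) +
    labs(title = sprintf("Correlation distribution: %s", region),
         x = "Pearson r", y = "ECDF") +
    xlim(-1.05, 1.05) + theme_classic()
}

saveFigure <- function(plot, pathNoExt, width = 6, height = 5) {
  ggsave(paste0(pathNoExt, ".png"), plot, width = width, height = height,
         dpi = 120)
  if (capabilities("cairo")) {
    try(ggsave(paste0(pathNoExt, ".svg"), plot, width = width,
               height = height, device = grDevices::svg), silent = TRUE)
  }
  invisible(pathNoExt)
}
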