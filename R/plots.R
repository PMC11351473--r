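#' Correlation circle of a PCA
#'
#' Variables drawn as arrows on Dim1/Dim2, scaled by their correlation with
#' the components and coloured by cos2 (explanatory power of the plane).
#'
#' @param pca a "PCAResult" from [pcaFit()].
#' @return a ggplot object.
#' @export
plotCorrelationCircle <- function(pca) {
  lam <- pca$eigenvalues
  corr <- sweep(pca$loadings[, 1:2, drop = FALSE], 2L,
                sqrt(pmax(lam[1:2], 0)), "*")
  df <- data.frame(variable = rownames(corr), x = corr[, 1L], y = corr[, 2L],
                   cos2 = rowSums(pca$cos2))
  th <- seq(0, 2 * pi, length.out = 200)
  circ <- data.frame(x = cos(th), y = sin(th))
  ggplot2::ggplot(df) +
    ggplot2::geom_path(data = circ, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "grey60") +
    ggplot2::geom_segment(ggplot2::aes(x = 0, y = 0, xend = .data$x,
                                       yend = .data$y, colour = .data$cos2),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_text(ggplot2::aes(x = .data$x * 1.08, y = .data$y * 1.08,
                                    label = .data$variable), size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = sprintf("Dim1 (%.1f%%)", pca$varianceFraction[1L]),
      y = sprintf("Dim2 (%.1f%%)", pca$varianceFraction[2L]),
      colour = "cos2") +
    ggplot2::theme_minimal()
}

#' Two-species niche overlay in environmental space
#'
#' Occupancy of both species on the shared Dim1/Dim2 grid with 50% and 100%
#' density contours.
#'
#' @param gridA,gridB [EnvSpaceGrid-class] objects on the same grid.
#' @return a ggplot object.
#' @export
plotNicheOverlap <- function(gridA, gridB) {
  tidy <- function(g, label) {
    cont <- nicheContours(g)
    data.frame(
      x = rep(g@xGrid, times = length(g@yGrid)),
      y = rep(g@yGrid, each = length(g@xGrid)),
      inFull = as.vector(cont$q1),
      inHalf = as.vector(cont$q0.5),
      species = label)
  }
  df <- rbind(tidy(gridA, speciesName(gridA)), tidy(gridB, speciesName(gridB)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_tile(data = df[df$inFull, ],
                       ggplot2::aes(fill = .data$species), alpha = 0.35) +
    ggplot2::geom_tile(data = df[df$inHalf, ],
                       ggplot2::aes(fill = .data$species), alpha = 0.6) +
    ggplot2::labs(x = "Dim1", y = "Dim2", fill = "species") +
    ggplot2::theme_minimal()
}

#' Per-variable occurrence density curves for two species
#'
#' @param vo a "VariableOverlap" from [variableOverlap1d()].
#' @param variable label for the x axis.
#' @return a ggplot object.
#' @export
plotVariableOverlap <- function(vo, variable = "variable") {
  df <- data.frame(
    x = rep(vo$grid, 2L),
    density = c(vo$densityA, vo$densityB),
    species = rep(c("A", "B"), each = length(vo$grid)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$density,
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = variable, y = "density",
                  subtitle = sprintf("D = %.2f", vo$D)) +
    ggplot2::theme_minimal()
}
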