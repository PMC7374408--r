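#' Simplex plot of belief triplets
#'
#' Barycentric plot of `(B(NP), B(OA), U)` in the unit-side triangle whose
#' vertices are the pure beliefs: `B(NP) = 1` bottom-left, `B(OA) = 1`
#' bottom-right, `U = 1` at the apex. The dashed vertical line `x = 0.5` is
#' the decision boundary `B(OA) = B(NP)`.
#'
#' @param triplets data.frame with columns `b_OA`, `b_NP`, `u` and
#'   optionally a grouping column named by `colour`.
#' @param colour optional name of a column used for point colour/shape
#'   (e.g. `"true"` for the cohort label).
#' @return a ggplot object.
#' @export
plotSimplex <- function(triplets, colour = NULL) {
  xy <- as.data.frame(simplexCoordinates(triplets))
  df <- cbind(triplets[setdiff(names(triplets), c("x", "y"))], xy)
  tri <- data.frame(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = tri, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(x = 0.5, y = 0, xend = 0.5, yend = sqrt(3) / 2,
                          linetype = "dashed", colour = "grey40") +
    ggplot2::annotate("text", x = c(-0.03, 1.03, 0.5),
                      y = c(-0.04, -0.04, sqrt(3) / 2 + 0.05),
                      label = c("B(NP)=1", "B(OA)=1", "U=1"), size = 3) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (!is.null(colour) && colour %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]],
                                         shape = .data[[colour]]))
  } else {
    p + ggplot2::geom_point()
  }
}

#' Arrow plot of pre-to-post belief change
#'
#' One arrow per subject from the baseline to the post-operative `B(OA)`,
#' with subjects ordered by decreasing objective recovery (rank 1 = largest
#' reduction in `B(OA)`); worsening subjects sit at the tail.
#'
#' @param ordering data.frame from [arrowOrdering()].
#' @return a ggplot object.
#' @export
plotArrows <- function(ordering) {
  stopifnot(all(c("rank", "baseline_b_OA", "postop_b_OA") %in%
                  names(ordering)))
  ggplot2::ggplot(ordering,
                  ggplot2::aes(x = .data$rank, y = .data$baseline_b_OA)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$rank, yend = .data$postop_b_OA,
                   colour = .data$worsened),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "cm"))) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "steelblue", `TRUE` = "firebrick"),
      labels = c(`FALSE` = "improved", `TRUE` = "worsened"),
      name = NULL) +
    ggplot2::labs(x = "subject (decreasing recovery)", y = "B(OA)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
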