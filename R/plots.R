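# ggplot2 views of simulation results and boxel maps.

#' @importFrom ggplot2 ggplot aes geom_tile geom_histogram geom_vline
#'   facet_wrap scale_fill_viridis_c scale_fill_brewer labs theme_minimal
#'   autoplot coord_equal
#' @importFrom rlang .data
NULL

#' @export
ggplot2::autoplot

#' Histogram of replicate cycle-length estimates
#'
#' @param object A `cycle_sim` from [simulate_cycle_experiment()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cycle_sim <- function(object, ...) {
  p <- attr(object, "params")
  ggplot(object, aes(x = .data$t_c_h)) +
    geom_histogram(bins = 30, fill = "grey35") +
    geom_vline(xintercept = p$cycle_length_h, colour = "red",
               linetype = "dashed") +
    labs(x = "estimated cycle length (h)", y = "replicates",
         title = sprintf("differential exposure estimates (true T_C = %g h)",
                         p$cycle_length_h)) +
    theme_minimal()
}

#' Section-wise map of a boxel quantity
#'
#' One tile per boxel, facetted by boxel layer in z. Censored cycle lengths
#' are shown at the cap value.
#'
#' @param object A `boxel_grid`.
#' @param quantity Column to map (default `"t_c_h"`).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.boxel_grid <- function(object, quantity = "t_c_h", ...) {
  d <- object[object$valid & is.finite(object[[quantity]]), ]
  ggplot(d, aes(x = .data$x_um, y = .data$y_um, fill = .data[[quantity]])) +
    geom_tile() +
    facet_wrap(~bz, labeller = ggplot2::label_both) +
    scale_fill_viridis_c(name = quantity) +
    coord_equal() +
    labs(x = "x (um)", y = "y (um)") +
    theme_minimal()
}

#' Map of cluster membership
#'
#' @param object A `boxel_clusters` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.boxel_clusters <- function(object, ...) {
  d <- object$grid[!is.na(object$grid$cluster), ]
  d$cluster <- factor(d$cluster)
  ggplot(d, aes(x = .data$x_um, y = .data$y_um, fill = .data$cluster)) +
    geom_tile() +
    facet_wrap(~bz, labeller = ggplot2::label_both) +
    scale_fill_brewer(palette = "Set1") +
    coord_equal() +
    labs(x = "x (um)", y = "y (um)") +
    theme_minimal()
}
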