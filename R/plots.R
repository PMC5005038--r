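# ggplot2 displays for designs, similarity structure and searchlight maps.

#' Plot the city layout and a design's sampled vectors
#'
#' Buildings on the triangular-lattice hexagon, with the start-to-target
#' vectors of a trial design overlaid when one is supplied.
#'
#' @param layout A `city_layout`.
#' @param trials Optional trial tibble whose vectors to draw.
#' @return A ggplot object.
#' @export
plot_city_layout <- function(layout, trials = NULL) {
  b <- layout$buildings
  p <- ggplot2::ggplot(b, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$ring, colour = .data$ring),
                        size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (lattice units)", y = "y (lattice units)",
                  title = "Hexagonal building layout") +
    ggplot2::theme_minimal()
  if (!is.null(trials)) {
    seg <- dplyr::distinct(trials, .data$start_id, .data$target_id)
    seg <- mutate(seg,
      x = b$x[.data$start_id], y = b$y[.data$start_id],
      xend = b$x[.data$target_id], yend = b$y[.data$target_id])
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      alpha = 0.3, arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      inherit.aes = FALSE)
  }
  p
}

#' Pairwise similarity matrix ordered by direction
#'
#' Heatmap of the trial-pair Fisher-z similarity with trials sorted by their
#' sampled direction, making one-fold or six-fold structure visible as
#' diagonal banding.
#'
#' @param sim Similarity tibble from [pairwise_similarity()].
#' @param trials The trial tibble (for directions).
#' @return A ggplot object.
#' @export
plot_pair_similarity <- function(sim, trials) {
  ord <- order(trials$direction_deg, trials$trial_id)
  rank_of <- match(seq_len(nrow(trials)), ord)
  df <- bind_rows(
    mutate(sim, a = rank_of[.data$i], b = rank_of[.data$j]),
    mutate(sim, a = rank_of[.data$j], b = rank_of[.data$i])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick",
                                  mid = "white", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "trial (sorted by direction)",
                  y = "trial (sorted by direction)", fill = "z") +
    ggplot2::theme_minimal()
}

#' @method autoplot contrast_result
#' @export
autoplot.contrast_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$mean_z)) +
    ggplot2::geom_col(width = 0.6, fill = c("firebrick", "steelblue")) +
    ggplot2::labs(
      x = "condition", y = "mean Fisher z",
      title = sprintf("%s contrast: difference = %.4f",
                      object$scheme, object$difference)) +
    ggplot2::theme_minimal()
}

#' @method autoplot searchlight_map
#' @export
autoplot.searchlight_map <- function(object, slice = NULL, ...) {
  d <- dim(object$map)
  slice <- slice %||% ceiling(d[3] / 2)
  df <- tidyr::expand_grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- object$map[cbind(df$x, df$y, slice)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick",
                                  mid = "white", midpoint = 0,
                                  na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s searchlight map, slice z = %d",
                                  object$scheme, slice),
                  fill = "contrast") +
    ggplot2::theme_minimal()
}

#' @method autoplot permutation_result
#' @export
autoplot.permutation_result <- function(object, ...) {
  df <- tibble(x = c("observed"), v = object$observed)
  ggplot2::ggplot() +
    ggplot2::geom_vline(xintercept = object$null_mean, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick") +
    ggplot2::annotate("label", x = object$observed, y = 1,
                      label = sprintf("p = %.4g", object$p)) +
    ggplot2::labs(x = "contrast", y = NULL,
                  title = sprintf("Permutation null (%d shuffles)",
                                  object$n_perm)) +
    ggplot2::theme_minimal()
}
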