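#' Plot a read spread function
#'
#' Heatmap of the 2D RSF over mate offsets, with the anti-identity line
#' (equidistant fragmentation) overlaid.
#'
#' @param object An `rsf` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rsf <- function(object, ...) {
  df <- tidyr::expand_grid(dx = object$offsets, dy = object$offsets)
  df$value <- as.vector(t(object$values))
  ggplot2::ggplot(df, ggplot2::aes(.data$dx, .data$dy,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::geom_abline(slope = -1, intercept = 0, linetype = 2,
                         colour = "white", linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c(name = "mass") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "minus-end offset (bp)", y = "plus-end offset (bp)",
                  title = "Read spread function")
}

#' Plot an occupancy track
#'
#' @param object An `occupancy_track` tibble.
#' @param chrom,start,end Optional window to restrict the plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.occupancy_track <- function(object, chrom = NULL, start = NULL,
                                     end = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(chrom)) df <- df[df$chrom == chrom, ]
  if (!is.null(start)) df <- df[df$start >= start, ]
  if (!is.null(end)) df <- df[df$end <= end, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$start, .data$mass)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "occupancy mass",
                  title = "Marginal occupancy")
}

#' Plot the conditional joint profile at one anchor
#'
#' @param field A [conditional_field()].
#' @param anchor_id Anchor index.
#' @param calls Optional `interaction_calls` tibble; called regions for
#'   this anchor are shaded and their `eloc` marked.
#' @return A ggplot object.
#' @export
plot_anchor_profile <- function(field, anchor_id, calls = NULL) {
  prof <- field$profiles[[anchor_id]]
  if (nrow(prof) == 0) stop("anchor has an empty profile")
  p <- ggplot2::ggplot(prof, ggplot2::aes(.data$start, .data$mass)) +
    ggplot2::geom_col(width = field$bin_size, fill = "grey30") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(
      x = "distal position (bp)", y = "conditional joint mass",
      title = paste0("Joint occupancy with ",
                     field$anchors$name[anchor_id])
    )
  if (!is.null(calls)) {
    hits <- calls[calls$anchor_id == anchor_id, ]
    if (nrow(hits) > 0) {
      p <- p +
        ggplot2::geom_rect(
          data = hits,
          ggplot2::aes(xmin = .data$start, xmax = .data$end,
                       ymin = -Inf, ymax = Inf),
          inherit.aes = FALSE, alpha = 0.15, fill = "red"
        ) +
        ggplot2::geom_vline(data = hits,
                            ggplot2::aes(xintercept = .data$eloc),
                            linetype = 3, colour = "red")
    }
  }
  p
}
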