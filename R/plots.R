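# ggplot2 views of scan, classification and bootstrap results.

#' Domain map of scanned proteins
#'
#' Draws each protein as a horizontal line with its called WRKY domains
#' as coloured segments (by zinc-finger class) and signature positions as
#' ticks.
#'
#' @param object A `wrky_domains` tibble from [scan_proteome()].
#' @param records Optional records tibble; when given, full protein
#'   lengths are drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wrky_domains <- function(object, records = NULL, ...) {
  d <- as_tibble(object)
  p <- ggplot2::ggplot(d)
  if (!is.null(records)) {
    backbone <- tibble(protein_id = records$id, len = nchar(records$residues))
    backbone <- backbone[backbone$protein_id %in% d$protein_id, ]
    p <- p + ggplot2::geom_segment(
      data = backbone,
      ggplot2::aes(x = 0, xend = .data$len, y = .data$protein_id,
                   yend = .data$protein_id),
      linewidth = 0.3, colour = "grey60")
  }
  p +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$span_start, xend = .data$span_end,
                   y = .data$protein_id, yend = .data$protein_id,
                   colour = .data$finger_class),
      linewidth = 3) +
    ggplot2::geom_point(
      ggplot2::aes(x = .data$sig_offset, y = .data$protein_id),
      shape = "|", size = 3) +
    ggplot2::labs(x = "residue (0-based)", y = NULL,
                  colour = "zinc finger") +
    ggplot2::theme_minimal()
}

#' Group composition bar chart
#' @param object A `wrky_groups` tibble from [classify_proteome()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wrky_groups <- function(object, ...) {
  d <- as_tibble(object) |> dplyr::count(.data$group)
  d$group <- factor(d$group, levels = GROUP_LEVELS)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$n)) +
    ggplot2::geom_col(fill = "#4477AA") +
    ggplot2::labs(x = NULL, y = "domains") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Bootstrap support distribution
#' @param object A `wrky_boot` object from [bootstrap_support()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wrky_boot <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$support)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0,
                            fill = "#4477AA") +
    ggplot2::labs(x = "bipartition support", y = "count") +
    ggplot2::theme_minimal()
}

#' Architecture token diagram
#'
#' @param arch Architecture tibble from [build_architecture()] (one or
#'   more proteins).
#' @return A ggplot object with one row per protein and labelled domain
#'   boxes.
#' @export
plot_architecture <- function(arch) {
  ggplot2::ggplot(arch) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = as.numeric(factor(.data$protein_id)) - 0.3,
                   ymax = as.numeric(factor(.data$protein_id)) + 0.3,
                   fill = .data$label)) +
    ggplot2::geom_text(
      ggplot2::aes(x = (.data$start + .data$end) / 2,
                   y = as.numeric(factor(.data$protein_id)),
                   label = .data$token), size = 2.5) +
    ggplot2::scale_y_continuous(
      breaks = seq_along(unique(arch$protein_id)),
      labels = sort(unique(arch$protein_id))) +
    ggplot2::labs(x = "residue", y = NULL, fill = "domain") +
    ggplot2::theme_minimal()
}
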