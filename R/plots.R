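#' Plot a 96-channel mutational profile
#'
#' Standard signature barplot: 96 channels grouped and colored by the six
#' substitution classes.
#'
#' @param profile Numeric vector of length 96 (a count vector or a
#'   probability profile), or a single row of a signature matrix.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_signature_profile <- function(profile, title = NULL) {
  stopifnot(length(profile) == 96)
  df <- decode_channel(0:95)
  df$value <- as.numeric(profile)
  df$class <- paste0(df$ref, ">", df$alt)
  df$label <- factor(df$label, levels = sbs96_channels())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$value,
                                   fill = .data$class)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::facet_grid(~class, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "probability / count", title = title) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   legend.position = "none")
}

#' Rainfall-style plot of a segmentation
#'
#' Inter-mutation distance (log10) along the genome, colored by segment,
#' faceted by chromosome; segment boundaries are where the color changes.
#'
#' @param object A `mut_segmentation` (or `mut_clustering`, which colors by
#'   cluster instead).
#' @param catalog The segmented catalog.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mut_segmentation <- function(object, catalog, ...) {
  catalog <- assert_catalog(catalog)
  segs <- tibble::as_tibble(object)
  grp <- rep(NA_integer_, nrow(catalog))
  for (i in seq_len(nrow(segs))) {
    grp[(segs$start_idx[i] + 1L):segs$end_idx[i]] <-
      if ("cluster_id" %in% names(segs)) segs$cluster_id[i] else segs$segment_id[i]
  }
  df <- tibble::as_tibble(catalog)
  df$group <- factor(grp)
  df <- dplyr::mutate(
    dplyr::group_by(df, .data$sample_id, .data$chrom),
    imd = c(NA, diff(.data$pos)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$imd,
                                   color = .data$group)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "inter-mutation distance (bp)",
                  color = if ("cluster_id" %in% names(segs)) "cluster" else "segment") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Signature composition per mutation cluster
#'
#' Stacked per-cluster exposure bars from a fitted assignment.
#'
#' @param object A `mut_assignment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mut_assignment <- function(object, ...) {
  ex <- exposures(object)
  ex$unit <- factor(ifelse(is.na(ex$unit_id), ex$sample_id,
                           as.character(ex$unit_id)))
  ggplot2::ggplot(ex, ggplot2::aes(x = .data$unit, y = .data$exposure,
                                   fill = .data$signature)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~sample_id, scales = "free_x") +
    ggplot2::labs(x = sprintf("%s-level unit", ex$granularity[1] %||% "cluster"),
                  y = "exposure") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
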