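# autoplot() methods for the package's result types. Each returns a
# ggplot the caller can restyle.

#' @describeIn call_peaks plot window z-scores along the genome with the
#'   significance threshold and called peaks.
#' @param object a `peak_calls` object (for `autoplot`).
#' @method autoplot peak_calls
#' @export
autoplot.peak_calls <- function(object, ...) {
  w <- object$windows
  p <- ggplot2::ggplot(w, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                       y = .data$z)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_hline(yintercept = object$config$z_threshold,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "enrichment z")
  if (nrow(object$peaks)) {
    p <- p + ggplot2::geom_segment(
      data = object$peaks,
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$z_max, yend = .data$z_max),
      colour = "firebrick", linewidth = 1.2
    )
  }
  p
}

#' @describeIn insulation_score insulation profile with masked bins
#'   omitted.
#' @param object an `insulation_track` (for `autoplot`).
#' @param ... unused.
#' @method autoplot insulation_track
#' @export
autoplot.insulation_track <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$valid),
                  ggplot2::aes(x = (.data$start + .data$end) / 2,
                               y = .data$score)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "position (bp)", y = "insulation (log2 vs mean)")
}

#' @describeIn contact_matrix contact heat map (log10 counts).
#' @param object a `contact_matrix` (for `autoplot`).
#' @param ... unused.
#' @method autoplot contact_matrix
#' @export
autoplot.contact_matrix <- function(object, ...) {
  n <- ncol(object$matrix)
  df <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n))
  df$count <- object$matrix[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j,
                                   fill = log10(.data$count + 1))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "log10 contacts") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "bin", y = "bin")
}

#' @describeIn metagene_profile metagene profile with flank/body panels.
#' @param object a `metagene_profile` (for `autoplot`).
#' @param ... unused.
#' @method autoplot metagene_profile
#' @export
autoplot.metagene_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$bin, .data$mean_value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(
      xintercept = c(attr(object, "flank_bins") + 0.5,
                     attr(object, "flank_bins") +
                       attr(object, "n_body_bins") + 0.5),
      linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::labs(x = "bin (5' flank | body | 3' flank)",
                  y = "mean coverage")
}

#' @describeIn annotate_peaks peak vs genome-background feature
#'   fractions.
#' @param object a `feature_distribution` (for `autoplot`).
#' @param ... unused.
#' @method autoplot feature_distribution
#' @export
autoplot.feature_distribution <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("category", "fraction", "background_fraction")],
    cols = c("fraction", "background_fraction"),
    names_to = "set", values_to = "value"
  )
  df$set <- ifelse(df$set == "fraction", "peaks", "genome background")
  df$category <- factor(df$category, levels = FEATURE_LEVELS)
  ggplot2::ggplot(df, ggplot2::aes(.data$category, .data$value,
                                   fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "fraction of peaks / probes", fill = NULL)
}
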