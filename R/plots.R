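#' Plot an MDS embedding
#'
#' Scatter of the first two principal coordinates, optionally colored by a
#' grouping vector (e.g. breed).
#'
#' @param object An `mds_result` from [classical_mds()].
#' @param group Optional vector (length = points) used for color.
#' @param dims Two dimension indices to display (default `c(1, 2)`).
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.mds_result <- function(object, group = NULL, dims = c(1, 2), ...) {
  df <- object$coordinates
  xn <- paste0("C", dims[1]); yn <- paste0("C", dims[2])
  ev <- pmax(object$eigenvalues, 0)
  pct <- round(100 * ev[dims] / sum(ev), 1)
  p <- if (is.null(group)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data[[xn]], y = .data[[yn]]))
  } else {
    df$group <- group
    ggplot2::ggplot(df, ggplot2::aes(x = .data[[xn]], y = .data[[yn]],
                                     color = .data$group))
  }
  p + ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(x = paste0(xn, " (", pct[1], "%)"),
                  y = paste0(yn, " (", pct[2], "%)"),
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of a selection scan
#'
#' Per-SNP statistic along the genome with flagged (top-quantile) SNPs
#' highlighted and the retention threshold drawn.
#'
#' @param object A `scan_result` from [select_top()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scan_result <- function(object, ...) {
  stat <- attr(object, "statistic_name")
  df <- tidy(object)
  df <- df[order(chrom_key(df$chrom), df$bp), ]
  offsets <- c(0, cumsum(tapply(df$bp, factor(df$chrom,
                                              levels = unique(df$chrom)),
                                max)))
  df$x <- df$bp + offsets[match(df$chrom, unique(df$chrom))]
  thr <- attr(object, "threshold_value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data[[stat]],
                                   color = .data$selected)) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick"),
                                guide = "none") +
    ggplot2::labs(x = "genome position", y = stat) +
    ggplot2::theme_minimal()
}

#' Plot an effective-population-size trend
#'
#' Ne against generations ago on log-log axes.
#'
#' @param object An `ne_trend` tibble from [ne_trend()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ne_trend <- function(object, ...) {
  df <- object[!object$flagged, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generations_ago,
                                   y = .data$ne)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generations ago", y = "effective population size") +
    ggplot2::theme_minimal()
}

#' Plot ROH-based inbreeding by breed and length class
#'
#' Stacked per-breed mean F_ROH, partitioned into the five ROH length
#' classes.
#'
#' @param froh Tibble from [compute_froh()] (must include `breed`).
#' @return A ggplot object.
#' @export
plot_froh <- function(froh) {
  classes <- c("froh_1_2", "froh_2_4", "froh_4_8", "froh_8_16", "froh_gt16")
  long <- tidyr::pivot_longer(froh, dplyr::all_of(classes),
                              names_to = "class", values_to = "froh")
  agg <- dplyr::summarise(dplyr::group_by(long, .data$breed, .data$class),
                          froh = mean(.data$froh), .groups = "drop")
  agg$class <- factor(agg$class, levels = classes,
                      labels = c("1-2 Mb", "2-4 Mb", "4-8 Mb", "8-16 Mb",
                                 ">16 Mb"))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$breed, y = .data$froh,
                                    fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = expression(F[ROH]), fill = "ROH length") +
    ggplot2::theme_minimal()
}
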