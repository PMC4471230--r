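#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a terminal misincorporation profile
#'
#' One panel per read end, offset on the x axis, one line per substitution
#' type; the ancient DNA signature is the C>T line rising toward offset 0
#' at the 5' end and the G>A line at the 3' end.
#'
#' @param object A [damage_profile()].
#' @param highlight Substitutions drawn in colour (others grey).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot damage_profile
#' @export
autoplot.damage_profile <- function(object, highlight = c("C>T", "G>A"),
                                    ...) {
  df <- tibble::as_tibble(object)
  df$end <- factor(df$end, levels = c("5p", "3p"),
                   labels = c("5' end", "3' end"))
  df$hl <- ifelse(df$sub %in% highlight, df$sub, "other")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$frequency,
                                   group = .data$sub, colour = .data$hl)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~end) +
    ggplot2::scale_colour_manual(
      values = stats::setNames(c(scales_pal(length(highlight)), "grey70"),
                               c(highlight, "other")),
      name = "substitution") +
    ggplot2::labs(x = "offset from read end (nt)",
                  y = "mismatch frequency") +
    ggplot2::theme_minimal()
}

scales_pal <- function(n) {
  c("#D55E00", "#0072B2", "#009E73", "#CC79A7", "#E69F00")[seq_len(n)]
}

#' Plot per-position coverage of an assembly
#'
#' @param object A `mito_assembly` from [assemble()].
#' @param ... Unused.
#' @return A ggplot of evidence depth along the consensus.
#' @method autoplot mito_assembly
#' @export
autoplot.mito_assembly <- function(object, ...) {
  cov <- coverage_stats(object)
  df <- tibble::tibble(pos = seq_along(cov$depth), depth = cov$depth)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_area(fill = "grey60") +
    ggplot2::geom_hline(yintercept = cov$mean_fold_coverage,
                        linetype = "dashed") +
    ggplot2::labs(x = "consensus position (nt)", y = "evidence depth") +
    ggplot2::theme_minimal()
}
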