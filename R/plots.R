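#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_hline
#'   geom_vline facet_wrap labs scale_colour_manual theme_minimal
NULL

bias_palette <- c(paternal = "#1b7837", maternal = "#762a83",
                  unbiased = "grey70")
status_palette <- c(up = "#b2182b", down = "#2166ac", ns = "grey70",
                    hyper = "#b2182b", hypo = "#2166ac", none = "grey80")

#' Plot homoeolog bias calls
#'
#' Log2 paternal:maternal ratio against total informative reads, coloured
#' by classification; the dashed lines mark the ratio gates.
#'
#' @param object An `ase_bias_calls` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ase_bias_calls <- function(object, ...) {
  params <- attr(object, "params")
  df <- as_tibble(object) |>
    mutate(total = .data$pat_total + .data$mat_total,
           log2_ratio = log2((.data$pat_total + 0.5) /
                               (.data$mat_total + 0.5)))
  ggplot(df, aes(x = .data$total, y = .data$log2_ratio,
                 colour = .data$classification)) +
    geom_point(alpha = 0.7) +
    geom_hline(yintercept = log2(c(params$ratio_hi, params$ratio_lo)),
               linetype = "dashed", colour = "grey40") +
    ggplot2::scale_x_log10() +
    scale_colour_manual(values = bias_palette) +
    labs(x = "informative reads (paternal + maternal)",
         y = "log2(paternal / maternal)", colour = "bias") +
    theme_minimal()
}

#' Plot DMR calls as per-context volcano panels
#'
#' Methylation-level difference against -log10(q), faceted by context,
#' with the per-context delta gates as dashed lines.
#'
#' @param object A `dmr_calls` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dmr_calls <- function(object, ...) {
  criteria <- attr(object, "params")$criteria
  df <- as_tibble(object) |>
    filter(.data$tested) |>
    mutate(neg_log10_q = -log10(pmax(.data$q, 1e-300)))
  ggplot(df, aes(x = .data$delta, y = .data$neg_log10_q,
                 colour = .data$status)) +
    geom_point(alpha = 0.6, size = 0.8) +
    geom_vline(data = criteria,
               aes(xintercept = .data$min_delta), linetype = "dashed",
               colour = "grey40") +
    geom_vline(data = criteria,
               aes(xintercept = -.data$min_delta), linetype = "dashed",
               colour = "grey40") +
    facet_wrap(~context) +
    scale_colour_manual(values = status_palette) +
    labs(x = "methylation difference (group A - group B)",
         y = "-log10(q)") +
    theme_minimal()
}

#' Plot DEG calls as an MA-style panel
#'
#' Mean normalised expression against log2 fold change, coloured by status.
#'
#' @param object A `deg_calls` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deg_calls <- function(object, ...) {
  params <- attr(object, "params")
  ggplot(as_tibble(object),
         aes(x = .data$base_mean, y = .data$log2fc,
             colour = .data$status)) +
    geom_point(alpha = 0.6, size = 0.8) +
    geom_hline(yintercept = c(-params$lfc_min, params$lfc_min),
               linetype = "dashed", colour = "grey40") +
    ggplot2::scale_x_log10() +
    scale_colour_manual(values = status_palette) +
    labs(x = "mean expression", y = "log2(hybrid / maternal)") +
    theme_minimal()
}

#' Plot methylation profiles across expression bins
#'
#' Mean region methylation level per expression class, one line per
#' context, faceted by region.
#'
#' @param object A `meth_by_bin` result from [methylation_by_bin()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meth_by_bin <- function(object, ...) {
  ggplot(object$profile,
         aes(x = .data$bin, y = .data$mean_level,
             colour = .data$context, group = .data$context)) +
    geom_line() +
    geom_point() +
    facet_wrap(~region) +
    labs(x = "expression class", y = "mean methylation level") +
    theme_minimal()
}
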