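# broom-style tidiers and ggplot2 convenience plots.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a refined motif into a long per-position tibble
#'
#' @param x A `refined_motif`.
#' @param ... Unused.
#' @return Tibble with columns `position`, `base`, `prob`.
#' @export
tidy.refined_motif <- function(x, ...) {
  tibble::tibble(
    position = rep(seq_len(x$width), times = 4L),
    base = rep(BASES, each = x$width),
    prob = as.vector(x$pwm)
  ) |> dplyr::arrange(.data$position, .data$base)
}

#' One-row summary of a refined motif
#'
#' @param x A `refined_motif`.
#' @param ... Unused.
#' @return One-row tibble: `consensus`, `width`, `x_m`, `map_score`,
#'   `fold`, `zscore`.
#' @export
glance.refined_motif <- function(x, ...) {
  tibble::tibble(consensus = x$consensus, width = x$width, x_m = x$x_m,
                 map_score = x$map_score, fold = x$fold, zscore = x$zscore)
}

#' Tidy a pipeline result into its motif summary table
#'
#' @param x A `motifstep_result`.
#' @param ... Unused.
#' @return The per-motif summary tibble.
#' @export
tidy.motifstep_result <- function(x, ...) {
  x$summary
}

#' One-row summary of a pipeline run
#'
#' @param x A `motifstep_result`.
#' @param ... Unused.
#' @return One-row tibble with motif count and best scores.
#' @export
glance.motifstep_result <- function(x, ...) {
  tibble::tibble(
    n_motifs = length(x$motifs),
    best_map = if (nrow(x$summary)) max(x$summary$map_score) else NA_real_,
    best_consensus = if (nrow(x$summary)) x$summary$consensus[1] else
      NA_character_
  )
}

#' Information-content profile plot of a refined motif
#'
#' A simple sequence-logo-like visualization: per position, stacked bars of
#' each base's share of the positional information content (2 - Shannon
#' entropy in bits).
#'
#' @param object A `refined_motif`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.refined_motif <- function(object, ...) {
  td <- tidy(object)
  ic <- td |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(ic = 2 + sum(.data$prob * log2(.data$prob)))
  td <- dplyr::left_join(td, ic, by = "position")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$position,
                                   y = .data$prob * .data$ic,
                                   fill = .data$base)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::scale_x_continuous(breaks = seq_len(object$width)) +
    ggplot2::labs(x = "position", y = "information (bits)",
                  title = object$consensus) +
    ggplot2::theme_minimal()
}

#' MAP-score ranking plot for a pipeline result
#'
#' @param object A `motifstep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motifstep_result <- function(object, ...) {
  if (nrow(object$summary) == 0) {
    stop("no motifs to plot")
  }
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = stats::reorder(.data$consensus,
                                                  -.data$map_score),
                               y = .data$map_score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "modified MAP score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
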