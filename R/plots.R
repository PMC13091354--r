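#' Waterfall plot of substrate log fold changes
#'
#' Substrates ordered by signed mean LFC, flagged substrates highlighted,
#' with dashed lines at the +/- flag threshold.
#'
#' @param object A `substrate_stats` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.substrate_stats <- function(object, ...) {
  thr <- attr(object, "threshold") %||% 0.2
  d <- as_tibble(object) |>
    arrange(desc(.data$mean_lfc)) |>
    mutate(ord = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ord, y = .data$mean_lfc,
                                  fill = .data$flag)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "red3", `FALSE` = "grey60"),
                               name = paste0("|LFC| >= ", thr)) +
    ggplot2::labs(x = "substrates (waterfall order)",
                  y = "mean log2 fold change",
                  title = attr(object, "contrast"))
}

#' Waterfall plot of upstream kinase scores
#'
#' Kinases ordered by final score (UKA results) or sampling Z (Z-score
#' results), colored by kinome branch.
#'
#' @param object A `uka_result` or `krsa_result` tibble.
#' @param top Show only the `top` kinases by rank (default 30; `Inf` for all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.uka_result <- function(object, top = 30, ...) {
  .kinase_waterfall(object, "final_score", top, "final score")
}

#' @rdname autoplot.uka_result
#' @export
autoplot.krsa_result <- function(object, top = 30, ...) {
  .kinase_waterfall(object, "z", top, "sampling Z-score")
}

.kinase_waterfall <- function(object, col, top, ylab) {
  d <- as_tibble(object) |>
    filter(.data$rank <= top) |>
    arrange(desc(.data[[col]]))
  d$kinase_id <- factor(d$kinase_id, levels = d$kinase_id)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$kinase_id, y = .data[[col]],
                                  fill = .data$family_group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = ylab, fill = "branch") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Target PerMed scores per drug and analysis unit
#'
#' @param object A `trial_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trial_report <- function(object, ...) {
  d <- as_tibble(object$summary)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$drug_id, y = .data$target_permed,
                                  fill = .data$non_responder)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$unit)) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue4",
                                          `TRUE` = "orange3"),
                               name = "non-responder") +
    ggplot2::labs(x = NULL, y = "target PerMed (%)")
}

#' Heat map of a quantified (or row-scaled) matrix
#'
#' Renders the output of [heatmap_matrix()] as tiles, rows in cluster order.
#'
#' @param hm A wide tibble from [heatmap_matrix()].
#' @return A ggplot object.
#' @export
plot_heatmap <- function(hm) {
  long <- hm |>
    mutate(substrate_id = factor(.data$substrate_id,
                                 levels = rev(attr(hm, "row_order")))) |>
    pivot_longer(-c("substrate_id", "chip_type"),
                 names_to = "sample", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$substrate_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "red3") +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = attr(hm, "row_scaling") %||% "value") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
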