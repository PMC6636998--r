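#' @export
autoplot.mi_matrix <- function(object, ...) {
  d <- as_tibble(object)
  d$nmi[d$masked] <- NA_real_
  ggplot2::ggplot(dplyr::bind_rows(d, dplyr::rename(d, i = "j", j = "i")),
                  ggplot2::aes(x = .data$i, y = .data$j, fill = .data$nmi)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "fragment", y = "fragment", fill = "nMI",
                  title = "Fragment coupling network") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hub_table <- function(object, ...) {
  d <- object$pairs[!object$pairs$masked, ]
  d$neglog <- -log10(pmax(if (!is.null(object$p_max)) d$p else d$q, 1e-300))
  thr <- if (!is.null(object$p_max)) object$p_max else object$q_max
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc, y = .data$neglog,
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$lfc_min,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "forestgreen")) +
    ggplot2::labs(
      x = expression(log[2] ~ "fold-change (holo / apo)"),
      y = if (!is.null(object$p_max)) expression(-log[10] ~ p)
          else expression(-log[10] ~ q),
      colour = "hub pair",
      title = sprintf("Difference network: %s vs %s",
                      object$state_holo, object$state_apo)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.substate_set <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$first_block - 0.5, xmax = .data$last_block + 0.5,
      ymin = 0, ymax = 1, fill = factor(.data$substate))) +
    ggplot2::scale_x_continuous(breaks = seq_len(object$n_blocks)) +
    ggplot2::labs(x = "trajectory block", y = NULL, fill = "substate",
                  title = sprintf("Substate segmentation (omega >= %.2f)",
                                  object$omega_threshold)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Positional entropy vs total coupling strength
#'
#' Scatter of per-fragment positional entropy against the fragment's summed
#' nMI, with the least-squares line; flexible fragments are expected to
#' carry more coupling.
#'
#' @param alignment An [sa_alignment()].
#' @param mi An [mi_matrix()] (or `ensemble_network`) on the same fragments.
#' @return A ggplot object.
#' @export
plot_entropy_mi <- function(alignment, mi) {
  d <- dplyr::inner_join(positional_entropy(alignment),
                         fragment_total_mi(mi),
                         by = c("column", "chain", "first_resid"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$entropy, y = .data$total_nmi)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey30", linewidth = 0.5) +
    ggplot2::labs(x = "positional entropy (nats)", y = "total nMI",
                  title = "Backbone flexibility vs coupling strength") +
    ggplot2::theme_minimal()
}
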