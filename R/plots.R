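#' Plot simulated trajectories
#'
#' @param object A `g2m_sim`.
#' @param species Species to draw (default the main mitotic and checkpoint
#'   regulators).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.g2m_sim <- function(object,
                             species = c("CyclinB", "MPF", "Cdc25P",
                                         "Wee1", "APC/CP:Cdc20",
                                         "Mad2:Cdc20P", "ATM/ATR", "p53"),
                             ...) {
  d <- tidy(object)
  d <- d[d$species %in% species, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$value,
                                  colour = .data$species)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "time (h)", y = "concentration (rel. CDK1)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a Plk1-depletion scan
#'
#' Normalized cell cycle period against the depletion level; arrested
#' levels are drawn as open points on the top axis line.
#'
#' @param object A `depletion_scan` (rows from one or both backgrounds).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.depletion_scan <- function(object, ...) {
  d <- tibble::as_tibble(object)
  top <- max(d$normalized_period, na.rm = TRUE) * 1.05
  d$y <- ifelse(d$viable %in% TRUE, d$normalized_period, top)
  ggplot2::ggplot(d, ggplot2::aes(.data$level, .data$y,
                                  colour = .data$background,
                                  shape = .data$viable)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_line(data = d[d$viable %in% TRUE, ]) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                labels = c(`TRUE` = "cycling",
                                           `FALSE` = "arrested")) +
    ggplot2::labs(x = "Plk1 synthesis-rate depletion",
                  y = "normalized period T/T0",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an essentiality matrix
#'
#' Knockout targets against cell-line groups, black = arrest (essential),
#' red = cycling (nonessential), following the dependency-screen heatmap
#' convention.
#'
#' @param object An `essentiality_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.essentiality_matrix <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$target <- factor(d$target, levels = c(unique(d$target[d$target !=
                                                            "control"]),
                                          "control"))
  ggplot2::ggplot(d, ggplot2::aes(.data$group, .data$target,
                                  fill = .data$essential)) +
    ggplot2::geom_tile(colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "red3"),
                               labels = c(`TRUE` = "essential (arrest)",
                                          `FALSE` = "nonessential"),
                               na.value = "grey80") +
    ggplot2::labs(x = "cell-line group (mutated gene)",
                  y = "knocked-out gene", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot logarithmic sensitivity intensities
#'
#' @param object A `sensitivity_report`.
#' @param quantities Rows to show (default the checkpoint-related
#'   regulators).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sensitivity_report <- function(object,
                                        quantities = c("Cdc25", "Plk1",
                                                       "Cdc20", "Cdc20P",
                                                       "APC/CT:Cdh1",
                                                       "ATM/ATR",
                                                       "Mad2:Cdc20P", "p53",
                                                       "CyclinB",
                                                       "APC/CP:Cdc20"),
                                        ...) {
  d <- object$values
  d <- d[d$quantity %in% quantities & !d$excluded, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$parameter, .data$quantity,
                                  fill = .data$S)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(x = NULL, y = NULL, fill = "S",
                  title = object$settings$scenario) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 5))
}

#' Plot PRCC values
#'
#' @param object A `prcc_report`.
#' @param quantities Quantities to show (default the checkpoint-related
#'   regulators).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.prcc_report <- function(object,
                                 quantities = c("Cdc25", "Plk1", "Cdc20",
                                                "ATM/ATR", "Mad2:Cdc20P",
                                                "APC/CP:Cdc20", "p53"),
                                 ...) {
  d <- tidy(object)
  d <- d[d$quantity %in% quantities, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$parameter, .data$quantity,
                                  fill = .data$prcc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "PRCC",
                  title = object$settings$scenario) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 5))
}

#' Plot fuzzy uncertainty bands
#'
#' Maximum uncertainty band against the membership level, one line per
#' perturbed parameter.
#'
#' @param object A `fuzzy_band`.
#' @param quantities Quantities to facet (default the arrest indicator and
#'   checkpoint species).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fuzzy_band <- function(object,
                                quantities = c("Mad2:Cdc20P", "ATM/ATR",
                                               "APC/CP:Cdc20", "Cdc25",
                                               "Cdc20P"),
                                ...) {
  d <- tibble::as_tibble(object)
  d <- d[d$quantity %in% quantities, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$band, .data$alpha,
                                  colour = .data$parameter)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~quantity, scales = "free_x") +
    ggplot2::labs(x = "maximum uncertainty band", y = "alpha-cut level",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
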