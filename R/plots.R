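#' Plot the miRNA-by-stress rank matrix
#'
#' Tile heatmap of Banzhaf importance ranks: darker tiles mark more
#' important miRNAs (rank 1 = most important).
#'
#' @param object A `banzhaf_ranks` object from [rank_all_stresses()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.banzhaf_ranks <- function(object, ...) {
  long <- tidy(object)
  long$player <- factor(long$player, levels = rev(mirna_names))
  long$stress <- factor(long$stress, levels = stress_names)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stress, y = .data$player,
                                     fill = .data$rank)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$rank), size = 3) +
    ggplot2::scale_fill_gradient(low = "#1b7837", high = "#f7f7f7",
                                 name = "rank") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "miRNA importance per stress (Banzhaf rank)") +
    ggplot2::theme_minimal()
}

#' Plot cross-validated R-squared across the model grid
#'
#' Mean pooled out-of-fold R-squared (with a +/- 1 SD ribbon over fold
#' seeds) per kernel and gamma, faceted by model family; kernel-free
#' families (CART, NB) appear as horizontal reference lines.
#'
#' @param object A `cv_grid` from [run_model_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cv_grid <- function(object, ...) {
  tb <- tibble::as_tibble(unclass(object))
  kernelled <- tb[!is.na(tb$kernel), ]
  flat <- tb[is.na(tb$kernel), ]
  p <- ggplot2::ggplot(kernelled,
                       ggplot2::aes(x = .data$gamma, y = .data$r2_mean,
                                    color = .data$kernel)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$r2_mean - .data$r2_sd,
                                          ymax = .data$r2_mean + .data$r2_sd),
                             position = ggplot2::position_dodge(0.004)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~family) +
    ggplot2::labs(x = "kernel parameter gamma",
                  y = "mean pooled 3-fold CV R-squared",
                  title = "Model grid performance") +
    ggplot2::theme_minimal()
  if (nrow(flat) > 0) {
    p <- p + ggplot2::geom_hline(
      data = flat, ggplot2::aes(yintercept = .data$r2_mean,
                                linetype = .data$family),
      color = "grey40")
  }
  p
}

#' Plot concentration profiles across stress severities
#'
#' Mean concentration (fM) of each miRNA against severity level for one
#' stress, with +/- 1 SD error bars; log10 y-scale because the 11
#' miRNAs span roughly two orders of magnitude.
#'
#' @param table An `expression_table`.
#' @param scope One stress type.
#' @return A ggplot object.
#' @export
plot_expression_profiles <- function(table, scope = "drought") {
  if (!scope %in% stress_names) abort(paste0("unknown stress: ", scope))
  tb <- tibble::as_tibble(unclass(table))
  tb <- tb[tb$stress_type %in% c("control", scope), ]
  tb$mirna <- factor(tb$mirna, levels = mirna_names)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$level_index, y = .data$mean_fM,
                                   color = .data$mirna)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = pmax(.data$mean_fM -
                                                        .data$sd_fM, 0.5),
                                          ymax = .data$mean_fM +
                                            .data$sd_fM)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "severity level (0 = control)",
                  y = "concentration (fM, log scale)",
                  title = paste("miRNA concentrations under", scope)) +
    ggplot2::theme_minimal()
}
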