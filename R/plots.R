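#' Plot crossover / short-tract proportions with binomial intervals
#'
#' Bar plot of proportions with Wilson interval error bars, the standard
#' display for recombinant frequencies across timepoint windows.
#'
#' @param estimates A tibble with `estimate`, `conf_low`, `conf_high` and a
#'   grouping column given by `x`.
#' @param x Name of the column for the x axis, default `"window"`.
#' @param fill Optional name of a fill grouping column (e.g. `"genotype"`).
#' @return A ggplot object.
#' @export
plot_proportions <- function(estimates, x = "window", fill = NULL) {
  aes_args <- if (is.null(fill)) {
    ggplot2::aes(x = .data[[x]], y = .data$estimate)
  } else {
    ggplot2::aes(x = .data[[x]], y = .data$estimate, fill = .data[[fill]])
  }
  ggplot2::ggplot(estimates, aes_args) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conf_low, ymax = .data$conf_high),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(y = "proportion (95% binomial CI)") +
    ggplot2::theme_classic()
}

#' Plot conversion tracts along the polymorphism ladder
#'
#' One horizontal line per recombinant spanning its minimum tract, with
#' points at converted (filled) and heteroduplex (open) polymorphisms,
#' ordered smallest to largest tract — the standard tract display.
#'
#' @param tracts Long tract tibble (as read by [read_tracts()] or produced
#'   by [sim_tracts()]).
#' @param ladder Ladder positions.
#' @return A ggplot object.
#' @export
plot_tracts <- function(tracts, ladder = polymorphism_ladder()) {
  scored <- score_tracts(tracts, ladder)
  ord <- scored %>% arrange(.data$min_bp) %>%
    mutate(y = row_number()) %>%
    select("tract_id", "y", "min_bp")
  pts <- tracts %>%
    filter(.data$call %in% c("converted", "heteroduplex")) %>%
    left_join(ord, by = "tract_id")
  spans <- scored %>%
    left_join(ord, by = c("tract_id", "min_bp")) %>%
    left_join(
      tracts %>%
        filter(.data$call %in% c("converted", "heteroduplex")) %>%
        group_by(.data$tract_id) %>%
        summarise(from = min(.data$position), to = max(.data$position),
                  .groups = "drop"),
      by = "tract_id")
  ggplot2::ggplot() +
    ggplot2::geom_vline(xintercept = ladder, colour = "grey85") +
    ggplot2::geom_segment(
      data = spans,
      ggplot2::aes(x = .data$from, xend = .data$to,
                   y = .data$y, yend = .data$y)) +
    ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$position, y = .data$y,
                   shape = .data$call == "heteroduplex"),
      size = 2) +
    ggplot2::scale_shape_manual(
      values = c(`FALSE` = 16, `TRUE` = 21), guide = "none") +
    ggplot2::labs(x = "bp 3' of excision site", y = "recombinant") +
    ggplot2::theme_classic()
}

#' Plot a sliding-window RAD-51 focus profile
#'
#' Mean foci per nucleus (line) with an SEM ribbon along the normalized
#' germline axis, optionally per genotype.
#'
#' @param nuclei Tibble with `norm_position`, `foci` and optionally
#'   `genotype`.
#' @param width,step,span Passed to [sliding_window_profile()].
#' @return A ggplot object.
#' @export
plot_rad51_profile <- function(nuclei, width = 0.1, step = 0.01,
                               span = c(-0.25, 1)) {
  nuclei <- as_tibble(nuclei)
  if (!"genotype" %in% names(nuclei)) nuclei$genotype <- "all"
  prof <- nuclei %>%
    group_by(.data$genotype) %>%
    dplyr::group_modify(~ sliding_window_profile(.x, width, step, span)) %>%
    ungroup()
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$center, y = .data$mean_foci,
                                     colour = .data$genotype,
                                     fill = .data$genotype)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_foci - .data$sem,
                                      ymax = .data$mean_foci + .data$sem),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = stage_bins()$upper, linetype = "dotted",
                        colour = "grey60") +
    ggplot2::labs(x = "normalized germline position (pachytene = 0 to 1)",
                  y = "RAD-51 foci per nucleus (mean ± SEM)") +
    ggplot2::theme_classic()
}

#' Plot posterior gamma estimates
#'
#' Median and credible interval of the radiosensitivity ratio per genotype,
#' faceted by window and dose. A dashed line marks gamma = 1 (no effect of
#' irradiation).
#'
#' @param object A [gamma_posterior()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gamma_estimates
#' @export
autoplot.gamma_estimates <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$genotype, y = .data$median)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf_low,
                                          ymax = .data$conf_high)) +
    ggplot2::facet_grid(ggplot2::vars(.data$window),
                        ggplot2::vars(.data$dose_rads)) +
    ggplot2::labs(y = "gamma (posterior median, 95% CrI)") +
    ggplot2::theme_bw()
}

#' Plot posterior viability estimates of a brood fit
#'
#' @param object A `brood_fit` object.
#' @param ... Unused.
#' @return A ggplot object: posterior median and interval of phi per group.
#' @method autoplot brood_fit
#' @export
autoplot.brood_fit <- function(object, ...) {
  phi <- tidy(object) %>% filter(.data$parameter == "phi")
  ggplot2::ggplot(phi, ggplot2::aes(x = .data$genotype, y = .data$median,
                                    colour = factor(.data$dose_rads))) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$conf_low, ymax = .data$conf_high),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$window)) +
    ggplot2::labs(y = "mean brood viability phi (posterior)",
                  colour = "dose (Rads)") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
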