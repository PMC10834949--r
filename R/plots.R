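# ggplot2 graphics for each result type

#' Plot a sensorgram series
#'
#' @param data Sensorgram tibble (see [sim_sensorgrams()]).
#' @param fit Optional `spr_fit`; fitted curves are overlaid.
#' @return A ggplot.
#' @export
#' @examples
#' sg <- sim_sensorgrams(kinetic_params(), concentrations = c(1e-6, 1e-5),
#'                       t_grid = seq(0, 600, 10), t0 = 300)
#' plot_sensorgrams(sg)
plot_sensorgrams <- function(data, fit = NULL) {
  check_columns(data, c("curve_id", "concentration_M", "time_s",
                        "response"), "data")
  p <- ggplot2::ggplot(data, ggplot2::aes(
    x = .data$time_s, y = .data$response,
    group = .data$curve_id,
    colour = factor(signif(.data$concentration_M * 1e6, 3)))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "Time (s)", y = "Response (RU)",
                  colour = "Conc (µM)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_line(
      data = fitted(fit),
      ggplot2::aes(y = .data$fitted), linewidth = 0.3, colour = "black")
  }
  p
}

#' @rdname plot_sensorgrams
#' @param object An `spr_fit`.
#' @param ... Unused.
#' @export
autoplot.spr_fit <- function(object, ...) {
  plot_sensorgrams(object$data, fit = object)
}

#' Plot a per-residue combined-shift profile
#'
#' Bar profile of combined chemical-shift changes with category glyphs
#' and, optionally, the significance threshold.
#'
#' @param records [csp_match_peaks()] output (optionally classified).
#' @param threshold Optional threshold (ppm) drawn as a dashed line; if
#'   `records` came from [csp_classify()], its stored threshold is used.
#' @return A ggplot.
#' @export
#' @examples
#' tabs <- sim_peak_tables(perturbed = c(27, 28))
#' plot_csp(csp_match_peaks(tabs$reference, tabs$query))
plot_csp <- function(records, threshold = attr(records, "threshold_ppm")) {
  check_columns(records, c("residue_index", "delta_comb", "category"),
                "records")
  p <- ggplot2::ggplot(records, ggplot2::aes(
    x = .data$residue_index, y = .data$delta_comb,
    fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Residue", y = "Combined shift change (ppm)",
                  fill = "Category") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed")
  }
  p
}

#' Plot solvent-PRE profiles
#'
#' @param profiles One PRE profile or several row-bound profiles from
#'   [compute_pre()] (`condition` distinguishes them).
#' @return A ggplot with error bars.
#' @export
#' @examples
#' pr <- tibble::tibble(residue_index = 1:10, pre = runif(10),
#'                      pre_err = 0.05, condition = "apo")
#' plot_pre(pr)
plot_pre <- function(profiles) {
  check_columns(profiles, c("residue_index", "pre", "pre_err"),
                "profiles")
  if (!"condition" %in% names(profiles)) profiles$condition <- "profile"
  ggplot2::ggplot(profiles, ggplot2::aes(
    x = .data$residue_index, y = .data$pre, fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$pre - .data$pre_err,
      ymax = .data$pre + .data$pre_err),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3) +
    ggplot2::labs(x = "Residue", y = expression(PRE ~ (s^-1)),
                  fill = "Condition") +
    ggplot2::theme_minimal()
}

#' @rdname plot_pre
#' @param object A `delta_pre` result; plotted as the per-residue
#'   difference with significance flags.
#' @param ... Unused.
#' @export
autoplot.delta_pre <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(
    x = .data$residue_index, y = .data$delta, fill = .data$flag)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$delta - object$k_sigma * .data$err,
      ymax = .data$delta + object$k_sigma * .data$err), width = 0.3) +
    ggplot2::scale_fill_manual(values = c(decreased = "#2166ac",
                                          increased = "#b2182b",
                                          none = "grey70")) +
    ggplot2::labs(x = "Residue",
                  y = expression(Delta * PRE ~ (s^-1)), fill = "Flag") +
    ggplot2::theme_minimal()
}

#' Plot fibril diameter distributions
#'
#' Jittered per-fibril diameters by condition with the group mean marked,
#' the standard morphometry display.
#'
#' @param data Diameter tibble (`condition`, `diameter_nm`).
#' @return A ggplot.
#' @export
#' @examples
#' plot_diameters(sim_diameters(fibril_diameter_summaries()[c(1, 3), ]))
plot_diameters <- function(data) {
  check_columns(data, c("condition", "diameter_nm"), "data")
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data$condition, y = .data$diameter_nm,
    colour = .data$condition)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, show.legend = FALSE) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "black", linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "Fibril diameter (nm)") +
    ggplot2::theme_minimal()
}
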