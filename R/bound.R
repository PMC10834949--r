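# Bound-fraction estimation from HSQC cross-peak attenuation. Binding to
# slowly tumbling fibrils removes a chaperone molecule from the
# solution-state spectrum, so the uniform attenuation of cross-peak
# intensities upon adding fibrils reports the bound population directly.

#' Per-peak intensity ratios with S/N-propagated errors
#'
#' Computes `intensity_mixed / intensity_free` per cross-peak, with the
#' first-order error propagated in quadrature from the reciprocal
#' signal-to-noise of both members:
#' `err = ratio * sqrt(1/snr_free^2 + 1/snr_mixed^2)`.
#'
#' @param pairs Tibble with columns `peak_id`, `intensity_free`,
#'   `intensity_mixed`, `snr_free`, `snr_mixed`; intensities and S/N must
#'   be positive.
#' @return `pairs` with `ratio` and `ratio_err` columns appended.
#' @export
#' @examples
#' intensity_ratios(tibble::tibble(peak_id = "G25", intensity_free = 100,
#'                  intensity_mixed = 90, snr_free = 50, snr_mixed = 45))
intensity_ratios <- function(pairs) {
  check_columns(pairs, c("peak_id", "intensity_free", "intensity_mixed",
                         "snr_free", "snr_mixed"), "pairs")
  if (nrow(pairs) == 0) abort("`pairs` must be non-empty.")
  check_number(pairs$intensity_free, "intensity_free", lower = 0,
               strict_lower = TRUE)
  check_number(pairs$intensity_mixed, "intensity_mixed", lower = 0,
               strict_lower = TRUE)
  check_number(pairs$snr_free, "snr_free", lower = 0, strict_lower = TRUE)
  check_number(pairs$snr_mixed, "snr_mixed", lower = 0, strict_lower = TRUE)
  dplyr::mutate(pairs,
    ratio = .data$intensity_mixed / .data$intensity_free,
    ratio_err = .data$ratio * sqrt(1 / .data$snr_free^2 +
                                     1 / .data$snr_mixed^2))
}

#' Estimate the bound fraction from intensity ratios
#'
#' The attenuation of solution-state cross-peaks correlates linearly with
#' the population bound to the fibrils, so the bound fraction is one
#' minus the mean intensity ratio. The mean is error-weighted (weights
#' `1/ratio_err^2`); a reduced chi-square of the ratios about the mean
#' (`uniformity_stat`, approximately 1 for uniform attenuation) checks
#' the uniform-attenuation assumption, and the spread across peaks is
#' reported alongside the propagated error.
#'
#' @param ratios Output of [intensity_ratios()] (needs columns `ratio`
#'   and `ratio_err`); at least 3 peaks.
#' @return An object of class `bound_fraction_result`: `mean_ratio`,
#'   `ratio_err` (error of the weighted mean), `ratio_sd` (SD across
#'   peaks), `bound_fraction` (clamped to \[0, 1\]), `n_peaks`,
#'   `uniformity_stat`.
#' @export
#' @examples
#' tibble::tibble(peak_id = letters[1:4], intensity_free = 100,
#'                intensity_mixed = 90, snr_free = 30, snr_mixed = 27) |>
#'   intensity_ratios() |>
#'   bound_fraction()
bound_fraction <- function(ratios) {
  check_columns(ratios, c("ratio", "ratio_err"), "ratios")
  if (nrow(ratios) < 3) abort("At least 3 peaks are required.")
  w <- 1 / ratios$ratio_err^2
  mean_ratio <- sum(w * ratios$ratio) / sum(w)
  ratio_err <- sqrt(1 / sum(w))
  chi2 <- sum(((ratios$ratio - mean_ratio) / ratios$ratio_err)^2) /
    (nrow(ratios) - 1)
  structure(
    list(mean_ratio = mean_ratio,
         ratio_err = ratio_err,
         ratio_sd = sd(ratios$ratio),
         bound_fraction = min(max(1 - mean_ratio, 0), 1),
         n_peaks = nrow(ratios),
         uniformity_stat = chi2),
    class = "bound_fraction_result"
  )
}

#' @export
print.bound_fraction_result <- function(x, ...) {
  cat(sprintf(
    "<bound_fraction_result> %d peaks: mean ratio %.3f +/- %.3f (SD %.3f)\n",
    x$n_peaks, x$mean_ratio, x$ratio_err, x$ratio_sd))
  cat(sprintf("  bound fraction %.3f; uniformity (reduced chi-sq) %.2f\n",
              x$bound_fraction, x$uniformity_stat))
  invisible(x)
}

#' Check bound fraction against the soluble fraction
#'
#' An independent measurement of the soluble (supernatant) fraction after
#' pelleting the fibrils implies a bound fraction of
#' `1 - soluble_fraction`; this check passes when the two estimates agree
#' within `tolerance`.
#'
#' @param bound_fraction Bound-fraction estimate in \[0, 1\] (a number or
#'   a [bound_fraction()] result).
#' @param soluble_fraction Soluble fraction in \[0, 1\].
#' @param tolerance Allowed absolute discrepancy (default 0.06).
#' @return A one-row tibble with `bound_fraction`, `implied_bound`,
#'   `difference`, `tolerance`, `consistent`.
#' @export
#' @examples
#' supernatant_consistency(0.10, 0.95)
supernatant_consistency <- function(bound_fraction, soluble_fraction,
                                    tolerance = 0.06) {
  if (inherits(bound_fraction, "bound_fraction_result")) {
    bound_fraction <- bound_fraction$bound_fraction
  }
  check_number(bound_fraction, "bound_fraction", lower = 0, upper = 1)
  check_number(soluble_fraction, "soluble_fraction", lower = 0, upper = 1)
  check_number(tolerance, "tolerance", lower = 0)
  implied <- 1 - soluble_fraction
  tibble::tibble(
    bound_fraction = bound_fraction,
    implied_bound = implied,
    difference = abs(bound_fraction - implied),
    tolerance = tolerance,
    consistent = abs(bound_fraction - implied) <= tolerance
  )
}

#' Intensity pairs from matched peak tables
#'
#' Joins a fibril-free and a fibril-containing assigned peak table by
#' residue and atom pair, yielding the per-peak intensity pairs consumed
#' by [intensity_ratios()]. The S/N of each member is taken as
#' `intensity / noise`, with `noise` the supplied spectral noise floor.
#'
#' @param free,mixed Peak tibbles (columns `residue_index`, `atom_pair`,
#'   `intensity`), e.g. from [sim_peak_tables()] or [read_sparky()].
#' @param noise_free,noise_mixed Spectral noise floors (intensity units).
#' @return A tibble suitable for [intensity_ratios()].
#' @export
#' @examples
#' tabs <- sim_peak_tables(attenuation = 0.1)
#' intensity_pairs(tabs$reference, tabs$query, 1e4, 1e4) |> head()
intensity_pairs <- function(free, mixed, noise_free, noise_mixed) {
  check_columns(free, c("residue_index", "atom_pair", "intensity"), "free")
  check_columns(mixed, c("residue_index", "atom_pair", "intensity"),
                "mixed")
  check_number(noise_free, "noise_free", lower = 0, strict_lower = TRUE)
  check_number(noise_mixed, "noise_mixed", lower = 0, strict_lower = TRUE)
  dplyr::inner_join(
    dplyr::select(free, "residue_index", "atom_pair",
                  intensity_free = "intensity"),
    dplyr::select(mixed, "residue_index", "atom_pair",
                  intensity_mixed = "intensity"),
    by = c("residue_index", "atom_pair"),
    relationship = "one-to-one") |>
    dplyr::mutate(
      peak_id = paste0("res", .data$residue_index, "_", .data$atom_pair),
      snr_free = .data$intensity_free / noise_free,
      snr_mixed = .data$intensity_mixed / noise_mixed,
      .before = 1)
}
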