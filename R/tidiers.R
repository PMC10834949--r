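# broom-style tidiers for the fitted-result classes

#' Tidy a global kinetic fit
#'
#' @param x An `spr_fit` from [spr_fit_global()].
#' @param ... Unused.
#' @return One row per shared model parameter with `term`, `estimate`,
#'   `std_error`.
#' @export
tidy.spr_fit <- function(x, ...) {
  terms <- c("kon1", "kon2", "koff1", "koff2", "bmax1", "bmax2", "a")
  tibble::tibble(
    term = terms,
    estimate = unlist(x$params[terms]),
    std_error = unname(x$param_errors[terms])
  )
}

#' Glance at a global kinetic fit
#'
#' @param x An `spr_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `kd_strong`, `kd_weak`, `residual_rms`,
#'   `n_curves`, `n_points`, `excluded` and `converged`.
#' @export
glance.spr_fit <- function(x, ...) {
  tibble::tibble(
    kd_strong = x$kd$kd_strong,
    kd_weak = x$kd$kd_weak,
    residual_rms = x$residual_rms,
    n_curves = x$n_curves,
    n_points = x$n_points,
    excluded = length(x$excluded_concentrations),
    converged = x$converged
  )
}

#' Tidy a PRE condition-difference result
#'
#' @param x A `delta_pre` from [delta_pre()].
#' @param ... Unused.
#' @return The per-residue table (`residue_index`, `delta`, `err`,
#'   `flag`).
#' @export
tidy.delta_pre <- function(x, ...) x$table

#' Glance at a PRE condition-difference result
#'
#' @param x A `delta_pre`.
#' @param ... Unused.
#' @return A one-row tibble with residue/segment counts and `k_sigma`.
#' @export
glance.delta_pre <- function(x, ...) {
  tibble::tibble(
    n_residues = nrow(x$table),
    n_flagged = sum(x$table$flag != "none"),
    n_segments = nrow(x$segments),
    k_sigma = x$k_sigma
  )
}

#' Tidy an active-residue set
#'
#' @param x An `active_residue_set` from [csp_select_residues()].
#' @param ... Unused.
#' @return A tibble with one `residue_index` per row.
#' @export
tidy.active_residue_set <- function(x, ...) {
  tibble::tibble(residue_index = x$residues)
}

#' Glance at a bound-fraction estimate
#'
#' @param x A `bound_fraction_result` from [bound_fraction()].
#' @param ... Unused.
#' @return A one-row tibble with all summary fields.
#' @export
glance.bound_fraction_result <- function(x, ...) {
  tibble::as_tibble(x[c("mean_ratio", "ratio_err", "ratio_sd",
                        "bound_fraction", "n_peaks", "uniformity_stat")])
}
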