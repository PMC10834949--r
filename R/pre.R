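# Per-residue 15N R1 fitting from inversion-recovery series, Monte-Carlo
# error propagation, and solvent-PRE / condition-difference profiles.

# three-parameter mono-exponential: I(t) = offset + amplitude * exp(-r1 t)
ir_model <- function(p, t) p[1] + p[2] * exp(-exp(p[3]) * t)

ir_start <- function(delays, intensities) {
  offset0 <- intensities[which.max(delays)]
  amp0 <- intensities[which.min(delays)] - offset0
  if (abs(amp0) < .Machine$double.eps) amp0 <- -1e-6
  # log-linear estimate of the rate from the decaying residual
  resid <- (intensities - offset0) / amp0
  ok <- resid > 1e-3 & delays > 0
  r1_0 <- if (sum(ok) >= 2) {
    max(1e-4, -coef(stats::lm(log(resid[ok]) ~ delays[ok]))[[2]])
  } else {
    1 / max(max(delays), 1e-6)
  }
  c(offset0, amp0, log(r1_0))
}

fit_ir_single <- function(delays, intensities) {
  n <- length(delays)
  if (n < 4) abort("At least 4 points are required for the 3-parameter fit.")
  if (anyDuplicated(delays) > 0 || any(delays < 0)) {
    abort("`delays` must be unique and non-negative.")
  }
  starts <- list(ir_start(delays, intensities))
  span <- max(delays[delays > 0], 1)
  for (r in c(0.1, 1, 5) / span) {
    starts <- c(starts, list(c(starts[[1]][1], starts[[1]][2], log(r))))
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = s, fn = function(p) ir_model(p, delays) - intensities,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) {
      best <- fit
    }
    if (!is.null(best) &&
        best$deviance < (1e-10 * max(abs(intensities), 1))^2 * n) break
  }
  if (is.null(best)) {
    return(list(r1 = NA_real_, amplitude = NA_real_, offset = NA_real_,
                sigma = NA_real_, converged = FALSE))
  }
  p <- best$par
  sigma <- sqrt(best$deviance / max(1, n - 3))
  amp <- p[2]
  # degenerate (flat) series: the rate is unidentifiable
  degenerate <- abs(amp) <= max(4 * sigma,
                                1e-6 * max(abs(intensities), 1))
  list(r1 = exp(p[3]), amplitude = amp, offset = p[1], sigma = sigma,
       converged = best$info %in% 1:4 && !degenerate)
}

#' Fit per-residue longitudinal relaxation rates
#'
#' Fits the three-parameter mono-exponential
#' \eqn{I(t) = \mathrm{offset} + \mathrm{amplitude}\, e^{-R_1 t}} to each
#' residue/condition inversion-recovery series by Levenberg-Marquardt
#' least squares (the parameterization accommodates inversion-recovery
#' data, where the amplitude is negative, as well as saturation-recovery
#' data). Series that are flat within noise are flagged
#' `converged = FALSE` rather than raising an error.
#'
#' @param data Relaxation tibble with columns `residue_index`,
#'   `condition`, `delay_s`, `intensity` (and optionally `noise_sd`, used
#'   by [r1_mc_error()]); as produced by [sim_inversion_recovery()] or
#'   [read_relaxation()]. Each series needs at least 4 unique delays.
#' @return A tibble with one row per (residue, condition): `r1` (per
#'   second), `amplitude`, `offset`, `sigma` (residual SD) and
#'   `converged`.
#' @export
#' @examples
#' r1s <- tibble::tibble(residue_index = 1, condition = "undoped", r1 = 0.5)
#' sim_inversion_recovery(r1s, cfg = synth_config(noise_sd_relaxation = 0)) |>
#'   fit_r1()
fit_r1 <- function(data) {
  check_columns(data, c("residue_index", "condition", "delay_s",
                        "intensity"), "data")
  data |>
    dplyr::group_by(.data$residue_index, .data$condition) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_ir_single(d$delay_s, d$intensity)
      tibble::tibble(r1 = f$r1, amplitude = f$amplitude, offset = f$offset,
                     sigma = f$sigma, converged = f$converged,
                     noise_sd = if ("noise_sd" %in% names(d))
                       d$noise_sd[1] else NA_real_)
    }) |>
    dplyr::ungroup()
}

#' Monte-Carlo errors on fitted relaxation rates
#'
#' Propagates the spectral noise floor into an uncertainty on each fitted
#' `r1` by parametric resampling: `n_sim` synthetic series (best-fit
#' curve plus Gaussian noise at `noise_sd`) are refitted and the SD of
#' the refitted rates is reported.
#'
#' @param data The relaxation tibble used for the fits; must carry a
#'   `noise_sd` column (the per-series spectral noise floor).
#' @param fits Result of [fit_r1()] on `data`; computed if `NULL`.
#' @param n_sim Number of simulations (default 500); must be >= 2.
#' @param seed Seed for the resampling.
#' @return `fits` with an `r1_err` column appended (NA for
#'   non-converged series; exactly 0 when `noise_sd` is 0).
#' @export
#' @examples
#' r1s <- tibble::tibble(residue_index = 1, condition = "undoped", r1 = 0.5)
#' dat <- sim_inversion_recovery(r1s)
#' r1_mc_error(dat, n_sim = 50, seed = 2)
r1_mc_error <- function(data, fits = NULL, n_sim = 500, seed = 1) {
  if (n_sim < 2) abort("`n_sim` must be >= 2.")
  check_columns(data, c("residue_index", "condition", "delay_s",
                        "intensity", "noise_sd"), "data")
  if (is.null(fits)) fits <- fit_r1(data)
  delays_of <- data |>
    dplyr::group_by(.data$residue_index, .data$condition) |>
    dplyr::summarise(delays = list(.data$delay_s),
                     noise_sd = .data$noise_sd[1], .groups = "drop")
  fits <- dplyr::left_join(
    dplyr::select(fits, -dplyr::any_of("noise_sd")), delays_of,
    by = c("residue_index", "condition"))
  withr::with_seed(derive_seed(seed, "r1_mc"), {
    fits$r1_err <- purrr::pmap_dbl(
      fits[c("r1", "amplitude", "offset", "converged", "delays",
             "noise_sd")],
      function(r1, amplitude, offset, converged, delays, noise_sd) {
        if (!converged) return(NA_real_)
        if (noise_sd == 0) return(0)
        clean <- offset + amplitude * exp(-r1 * delays)
        sims <- purrr::map_dbl(seq_len(n_sim), function(i) {
          f <- fit_ir_single(delays, clean + rnorm(length(delays), 0,
                                                   noise_sd))
          if (f$converged) f$r1 else NA_real_
        })
        sd(sims, na.rm = TRUE)
      })
  })
  dplyr::select(fits, -"delays")
}

#' Solvent paramagnetic relaxation enhancement profile
#'
#' The solvent PRE of a residue is the increase of its longitudinal
#' relaxation rate caused by a dissolved paramagnetic dopant:
#' `pre = r1(doped) - r1(undoped)`, with errors combined in quadrature.
#' Solvent-exposed residues show large PREs; buried residues are
#' unaffected. Residues present (and converged) in only one condition are
#' dropped with a message.
#'
#' @param doped,undoped [fit_r1()] / [r1_mc_error()] results for the
#'   doped and undoped sample (columns `residue_index`, `r1`,
#'   `converged`, optionally `r1_err`).
#' @param condition Optional label (e.g. `"apo"`, `"holo"`) attached to
#'   the profile.
#' @return A tibble with columns `residue_index`, `pre`, `pre_err` and
#'   `condition`.
#' @export
#' @examples
#' f <- tibble::tibble(residue_index = 1:3, r1 = c(0.5, 0.6, 0.9),
#'                     r1_err = 0.02, converged = TRUE)
#' g <- dplyr::mutate(f, r1 = r1 + c(0.1, 0.5, 0.05))
#' compute_pre(g, f)
compute_pre <- function(doped, undoped, condition = NA_character_) {
  for (nm in c("doped", "undoped")) {
    check_columns(get(nm), c("residue_index", "r1", "converged"), nm)
  }
  keep <- function(x) {
    x <- dplyr::filter(x, .data$converged)
    if (!"r1_err" %in% names(x)) x$r1_err <- NA_real_
    dplyr::select(x, "residue_index", "r1", "r1_err")
  }
  merged <- dplyr::inner_join(keep(doped), keep(undoped),
                              by = "residue_index",
                              suffix = c("_doped", "_undoped"))
  if (nrow(merged) == 0) {
    abort("No residue is converged in both conditions.")
  }
  dropped <- setdiff(union(doped$residue_index, undoped$residue_index),
                     merged$residue_index)
  if (length(dropped) > 0) {
    rlang::inform(paste("Dropped residues present/converged in only one",
                        "condition:", paste(sort(dropped), collapse = ", ")))
  }
  merged |>
    dplyr::transmute(
      residue_index = .data$residue_index,
      pre = .data$r1_doped - .data$r1_undoped,
      pre_err = sqrt(.data$r1_err_doped^2 + .data$r1_err_undoped^2),
      condition = condition
    ) |>
    dplyr::arrange(.data$residue_index)
}

#' Condition difference of two PRE profiles
#'
#' Per-residue difference `holo - apo` of two solvent-PRE profiles with
#' propagated errors. A residue is flagged `"decreased"` or
#' `"increased"` when the absolute difference strictly exceeds
#' `k_sigma` times its propagated error (default `k_sigma = 2`,
#' i.e. a two-sigma rule); contiguous flagged residues are summarized as
#' segments. Decreased solvent PREs indicate burial of the site by the
#' bound chaperone; increased PREs indicate newly exposed residues.
#'
#' @param apo,holo PRE profiles from [compute_pre()] (columns
#'   `residue_index`, `pre`, `pre_err`).
#' @param k_sigma Significance multiplier (default 2; `Inf` flags
#'   nothing).
#' @return An object of class `delta_pre`: list with `table` (per-residue
#'   tibble: `residue_index`, `delta`, `err`, `flag`), `segments`
#'   (tibble: `start`, `end`, `direction`) and `k_sigma`.
#' @export
#' @examples
#' apo <- tibble::tibble(residue_index = 1:5, pre = 0.5, pre_err = 0.02)
#' holo <- dplyr::mutate(apo, pre = pre - c(0, 0.2, 0.2, 0, 0))
#' delta_pre(apo, holo)
delta_pre <- function(apo, holo, k_sigma = 2) {
  check_columns(apo, c("residue_index", "pre", "pre_err"), "apo")
  check_columns(holo, c("residue_index", "pre", "pre_err"), "holo")
  merged <- dplyr::inner_join(
    dplyr::select(apo, "residue_index", apo_pre = "pre",
                  apo_err = "pre_err"),
    dplyr::select(holo, "residue_index", holo_pre = "pre",
                  holo_err = "pre_err"),
    by = "residue_index")
  if (nrow(merged) == 0) abort("The two profiles share no residues.")
  tab <- merged |>
    dplyr::transmute(
      residue_index = .data$residue_index,
      delta = .data$holo_pre - .data$apo_pre,
      err = sqrt(.data$apo_err^2 + .data$holo_err^2),
      flag = dplyr::case_when(
        .data$delta > k_sigma * .data$err ~ "increased",
        -.data$delta > k_sigma * .data$err ~ "decreased",
        TRUE ~ "none"
      )
    ) |>
    dplyr::arrange(.data$residue_index)

  flagged <- dplyr::filter(tab, .data$flag != "none")
  segments <- if (nrow(flagged) == 0) {
    tibble::tibble(start = integer(), end = integer(),
                   direction = character())
  } else {
    flagged |>
      dplyr::mutate(brk = cumsum(
        c(1, diff(.data$residue_index) != 1 |
            .data$flag[-1] != .data$flag[-dplyr::n()]))) |>
      dplyr::group_by(.data$brk) |>
      dplyr::summarise(start = min(.data$residue_index),
                       end = max(.data$residue_index),
                       direction = .data$flag[1], .groups = "drop") |>
      dplyr::select(-"brk")
  }
  structure(list(table = tab, segments = segments, k_sigma = k_sigma),
            class = "delta_pre")
}

#' @export
print.delta_pre <- function(x, ...) {
  cat(sprintf("<delta_pre> %d residues, k_sigma = %g\n", nrow(x$table),
              x$k_sigma))
  if (nrow(x$segments) == 0) {
    cat("  no significant segments\n")
  } else {
    for (i in seq_len(nrow(x$segments))) {
      s <- x$segments[i, ]
      rng <- if (s$start == s$end) s$start else
        paste0(s$start, "-", s$end)
      cat(sprintf("  residues %s: %s\n", rng, s$direction))
    }
  }
  invisible(x)
}
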