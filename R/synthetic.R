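#' Configuration for the synthetic-data generators
#'
#' Bundles the random seed and per-modality noise levels used by all
#' `sim_*()` generators. The same configuration and arguments always
#' produce bit-identical output (the generators seed a local RNG and
#' restore the global RNG state afterwards).
#'
#' Default noise levels are typical acquisition noise for the respective
#' experiments: sub-RU sensorgram noise, a 2\% spectral noise floor on
#' inversion-recovery intensities, and peak-position scatter well below
#' one line width (0.004 ppm for 1H, 0.02 ppm for 13C/15N).
#'
#' @param seed Integer RNG seed.
#' @param noise_sd_sensorgram Sensorgram noise SD (response units).
#' @param noise_sd_relaxation Relaxation-intensity noise SD, as a fraction
#'   of the equilibrium intensity.
#' @param noise_sd_shift_h 1H peak-position noise SD (ppm).
#' @param noise_sd_shift_hetero Heteronucleus (13C or 15N) peak-position
#'   noise SD (ppm).
#' @param snr_intensity Signal-to-noise ratio of peak intensities
#'   (dimensionless); `Inf` for noise-free intensities.
#' @return An object of class `synth_config`.
#' @export
#' @examples
#' synth_config(seed = 7)
synth_config <- function(seed = 1L,
                         noise_sd_sensorgram = 0.5,
                         noise_sd_relaxation = 0.02,
                         noise_sd_shift_h = 0.004,
                         noise_sd_shift_hetero = 0.02,
                         snr_intensity = 30) {
  check_number(noise_sd_sensorgram, "noise_sd_sensorgram", lower = 0)
  check_number(noise_sd_relaxation, "noise_sd_relaxation", lower = 0)
  check_number(noise_sd_shift_h, "noise_sd_shift_h", lower = 0)
  check_number(noise_sd_shift_hetero, "noise_sd_shift_hetero", lower = 0)
  check_number(snr_intensity, "snr_intensity", lower = 0, strict_lower = TRUE)
  structure(
    list(seed = as.integer(seed),
         noise_sd_sensorgram = noise_sd_sensorgram,
         noise_sd_relaxation = noise_sd_relaxation,
         noise_sd_shift_h = noise_sd_shift_h,
         noise_sd_shift_hetero = noise_sd_shift_hetero,
         snr_intensity = snr_intensity),
    class = "synth_config"
  )
}

#' Standard analyte concentration series
#'
#' Nine two-fold dilutions from 50 uM down to 0.195 uM, the injection
#' series used for the chaperone concentration ladder in the SPR assay.
#'
#' @return Numeric vector of concentrations (molar), decreasing.
#' @export
#' @examples
#' spr_concentration_series() * 1e6
spr_concentration_series <- function() {
  50e-6 * 2^-(0:8)
}

#' Simulate an SPR sensorgram concentration series
#'
#' Generates one noisy sensorgram per concentration (and replicate) from
#' the two-phase kinetic model: association for `t < t0`, biexponential
#' dissociation for `t >= t0`. The dissociation amplitude `R0` is tied to
#' the association response at `t0`, so noiseless traces are continuous
#' at the injection stop.
#'
#' @param params A [kinetic_params()] object (the ground truth).
#' @param concentrations Analyte concentrations (molar), all > 0.
#' @param t_grid Strictly increasing sampling times (seconds) spanning
#'   `t0` (so both phases are sampled).
#' @param t0 Injection-stop time (seconds); must lie strictly inside
#'   `t_grid`'s range.
#' @param cfg A [synth_config()]; `noise_sd_sensorgram` is the i.i.d.
#'   Gaussian noise SD added to every sampled point.
#' @param replicates Number of replicate injections per concentration
#'   (duplicate injections by default mimic the assay protocol).
#' @return A tibble with columns `curve_id`, `concentration_M`,
#'   `replicate`, `t0_s`, `time_s`, `response`.
#' @export
#' @examples
#' sg <- sim_sensorgrams(kinetic_params(), concentrations = c(1e-6, 1e-5),
#'                       t_grid = seq(0, 600, by = 10), t0 = 300)
#' dplyr::count(sg, curve_id)
sim_sensorgrams <- function(params,
                            concentrations = spr_concentration_series(),
                            t_grid = seq(0, 900, by = 3),
                            t0 = 300,
                            cfg = synth_config(),
                            replicates = 2) {
  stopifnot(inherits(params, "kinetic_params"), inherits(cfg, "synth_config"))
  check_number(concentrations, "concentrations", lower = 0,
               strict_lower = TRUE)
  if (any(diff(t_grid) <= 0)) abort("`t_grid` must be strictly increasing.")
  if (t0 <= min(t_grid) || t0 >= max(t_grid)) {
    abort("`t0` must lie strictly inside the range of `t_grid`.")
  }
  grid <- tidyr::expand_grid(
    concentration_M = concentrations,
    replicate = seq_len(replicates)
  )
  withr::with_seed(derive_seed(cfg$seed, "sensorgram"), {
    out <- purrr::pmap(grid, function(concentration_M, replicate) {
      assoc <- t_grid < t0
      r0 <- spr_response_assoc(params, concentration_M, t0)
      response <- numeric(length(t_grid))
      response[assoc] <- spr_response_assoc(params, concentration_M,
                                            t_grid[assoc])
      response[!assoc] <- spr_response_dissoc(params, t_grid[!assoc],
                                              t0 = t0, r0 = r0)
      response <- response + rnorm(length(t_grid), 0,
                                   cfg$noise_sd_sensorgram)
      tibble::tibble(
        concentration_M = concentration_M,
        replicate = replicate,
        t0_s = t0,
        time_s = t_grid,
        response = response
      )
    })
  })
  dplyr::bind_rows(out) |>
    dplyr::mutate(curve_id = sprintf("c%.4g_r%d", .data$concentration_M * 1e6,
                                     .data$replicate),
                  .before = 1)
}

#' Simulate per-residue inversion-recovery series
#'
#' Generates mono-exponential longitudinal relaxation recovery curves
#' \eqn{I(t) = I_0 (1 - 2 e^{-R_1 t})} for each residue/condition in
#' `r1_map`, with additive Gaussian noise.
#'
#' @param r1_map Tibble with columns `residue_index`, `condition` and
#'   `r1` (per second, > 0); one row per series.
#' @param delays Unique non-negative recovery delays (seconds). The
#'   defaults span 0-10 s; pass delays up to 20 s for slowly relaxing
#'   (chaperone-present) samples.
#' @param i0 Equilibrium intensity (arbitrary units).
#' @param cfg A [synth_config()]; noise SD is
#'   `noise_sd_relaxation * i0`.
#' @return A tibble with columns `residue_index`, `condition`, `delay_s`,
#'   `intensity`, `noise_sd`.
#' @export
#' @examples
#' r1s <- tibble::tibble(residue_index = 27, condition = "undoped", r1 = 0.4)
#' sim_inversion_recovery(r1s)
sim_inversion_recovery <- function(r1_map,
                                   delays = c(0, 0.1, 0.25, 0.5, 1, 2, 4,
                                              7, 10),
                                   i0 = 100,
                                   cfg = synth_config()) {
  check_columns(r1_map, c("residue_index", "condition", "r1"), "r1_map")
  if (length(delays) == 0) abort("`delays` must be non-empty.")
  if (any(delays < 0) || anyDuplicated(delays) > 0) {
    abort("`delays` must be unique and non-negative.")
  }
  check_number(r1_map$r1, "r1_map$r1", lower = 0, strict_lower = TRUE)
  noise_sd <- cfg$noise_sd_relaxation * i0
  withr::with_seed(derive_seed(cfg$seed, "inversion_recovery"), {
    out <- purrr::pmap(
      r1_map[c("residue_index", "condition", "r1")],
      function(residue_index, condition, r1) {
        clean <- i0 * (1 - 2 * exp(-r1 * delays))
        tibble::tibble(
          residue_index = residue_index,
          condition = condition,
          delay_s = delays,
          intensity = clean + rnorm(length(delays), 0, noise_sd),
          noise_sd = noise_sd
        )
      })
  })
  dplyr::bind_rows(out)
}

# deterministic, well-separated synthetic peak positions (ppm)
base_peak_positions <- function(res) {
  dplyr::mutate(res,
    atom_pair = "CA-HA",
    w1 = 45 + 0.5 * .data$residue_index,
    w2 = 3.5 + 0.05 * (.data$residue_index %% 11),
    intensity = 1e6 * (1 + 0.1 * sin(.data$residue_index))
  )
}

#' Simulate reference and query assigned peak tables
#'
#' Generates a fibril-alone (reference) and chaperone-present (query)
#' assigned peak list over a sequence. Residues in `perturbed` acquire a
#' chemical-shift perturbation of (`delta_h`, `delta_hetero`) ppm in the
#' query; with `doubling = TRUE` the query keeps the unshifted peak and
#' adds a shifted twin (both environments coexist), otherwise the peak
#' simply moves. All query intensities are scaled by `1 - attenuation`.
#' Gaussian position noise (`cfg`) and intensity noise
#' (`intensity / snr_intensity`) are added to both tables.
#'
#' @param sequence One-letter sequence; defaults to the 42-residue
#'   amyloid-beta peptide.
#' @param perturbed Integer residue indices that sense the bound
#'   chaperone; must lie within the sequence.
#' @param doubling Logical; add shifted twins instead of moving peaks.
#' @param attenuation Fractional intensity loss of the query table, in
#'   \[0, 1\].
#' @param delta_h,delta_hetero Ground-truth shift perturbation (ppm).
#' @param cfg A [synth_config()].
#' @return A list with tibbles `reference` and `query` (columns
#'   `residue_index`, `residue_name`, `atom_pair`, `w1`, `w2`,
#'   `intensity`), plus the ground truth as attributes.
#' @export
#' @examples
#' tabs <- sim_peak_tables(perturbed = c(27, 28), doubling = TRUE)
#' nrow(tabs$query) - nrow(tabs$reference)
sim_peak_tables <- function(sequence = abeta42_sequence(),
                            perturbed = integer(),
                            doubling = TRUE,
                            attenuation = 0,
                            delta_h = 0.06,
                            delta_hetero = 0.4,
                            cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  res <- residue_table(sequence)
  if (length(perturbed) > 0 &&
      !all(perturbed %in% res$residue_index)) {
    abort("`perturbed` residues must lie within the sequence.")
  }
  check_number(attenuation, "attenuation", lower = 0, upper = 1)
  base <- base_peak_positions(res)

  add_noise <- function(tab) {
    n <- nrow(tab)
    dplyr::mutate(tab,
      w1 = .data$w1 + rnorm(n, 0, cfg$noise_sd_shift_hetero),
      w2 = .data$w2 + rnorm(n, 0, cfg$noise_sd_shift_h),
      intensity = .data$intensity +
        rnorm(n, 0, .data$intensity / cfg$snr_intensity)
    )
  }

  withr::with_seed(derive_seed(cfg$seed, "peak_tables"), {
    reference <- add_noise(base)
    query <- base
    shifted <- dplyr::filter(base, .data$residue_index %in% perturbed) |>
      dplyr::mutate(w1 = .data$w1 + delta_hetero,
                    w2 = .data$w2 + delta_h)
    if (doubling) {
      # both environments visible: halve intensities and add the twin
      query <- query |>
        dplyr::mutate(intensity = dplyr::if_else(
          .data$residue_index %in% perturbed,
          .data$intensity / 2, .data$intensity))
      query <- dplyr::bind_rows(
        query, dplyr::mutate(shifted, intensity = .data$intensity / 2))
    } else {
      query <- query |>
        dplyr::rows_update(shifted, by = "residue_index")
    }
    query <- query |>
      dplyr::mutate(intensity = .data$intensity * (1 - attenuation)) |>
      add_noise() |>
      dplyr::arrange(.data$residue_index, .data$w1)
  })
  structure(list(reference = reference, query = query),
            perturbed = sort(unique(perturbed)),
            delta_h = delta_h, delta_hetero = delta_hetero,
            attenuation = attenuation)
}

#' Fibril diameter summaries from negative-stain EM
#'
#' Reported group summaries (mean, SD, n = 100 measurements) of fibril
#' diameters for the mature fibrils, fibrils grown with the chaperone
#' present, and third-generation seeded preparations. These serve both as
#' reference inputs for summary-statistic tests and as generative targets
#' for [sim_diameters()].
#'
#' @return A tibble with columns `figure`, `condition`, `mean_nm`,
#'   `sd_nm`, `n`.
#' @export
#' @examples
#' fibril_diameter_summaries()
fibril_diameter_summaries <- function() {
  tibble::tribble(
    ~figure, ~condition,                        ~mean_nm, ~sd_nm, ~n,
    "fig1",  "ab42",                            13.8,     2.9,    100L,
    "fig1",  "mature_ab42_plus_chaperone",      15.2,     3.2,    100L,
    "fig1",  "chaperone_ab42_coincubated",      8.4,      1.5,    100L,
    "fig2",  "ab42_seeded",                     13.9,     2.0,    100L,
    "fig2",  "ab42_chaperone_seeds",            14.0,     2.5,    100L,
    "fig2",  "ab42_chaperone_coincubated",      7.9,      1.4,    100L
  )
}

#' Simulate fibril diameter samples
#'
#' Draws diameter samples from normal populations truncated at zero
#' (diameters are physically positive; at realistic means and SDs the
#' truncation is negligible).
#'
#' @param populations Tibble with columns `condition`, `mean_nm` (> 0),
#'   `sd_nm` (>= 0) and `n` (>= 2).
#' @param cfg A [synth_config()].
#' @return A tibble with columns `condition` and `diameter_nm`.
#' @export
#' @examples
#' pops <- fibril_diameter_summaries()[c(1, 3), ]
#' sim_diameters(pops) |> dplyr::count(condition)
sim_diameters <- function(populations, cfg = synth_config()) {
  check_columns(populations, c("condition", "mean_nm", "sd_nm", "n"),
                "populations")
  check_number(populations$mean_nm, "mean_nm", lower = 0,
               strict_lower = TRUE)
  check_number(populations$sd_nm, "sd_nm", lower = 0)
  if (any(populations$n < 2)) abort("Each population needs `n` >= 2.")
  withr::with_seed(derive_seed(cfg$seed, "diameters"), {
    out <- purrr::pmap(
      populations[c("condition", "mean_nm", "sd_nm", "n")],
      function(condition, mean_nm, sd_nm, n) {
        x <- rnorm(n, mean_nm, sd_nm)
        while (any(x <= 0)) {               # truncate at 0 by resampling
          bad <- x <= 0
          x[bad] <- rnorm(sum(bad), mean_nm, sd_nm)
        }
        tibble::tibble(condition = condition, diameter_nm = x)
      })
  })
  dplyr::bind_rows(out)
}
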