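# Fibril-diameter morphometry: group summaries, unpaired two-sample
# t-tests (from raw samples or printed summary statistics) and
# cross-section architecture classification.

#' Summarize diameter samples by condition
#'
#' Arithmetic mean, sample SD (n - 1 denominator) and count per
#' condition.
#'
#' @param data Tibble with columns `condition` and `diameter_nm`; each
#'   condition needs at least 2 measurements.
#' @return A tibble with columns `condition`, `mean_nm`, `sd_nm`, `n`.
#' @export
#' @examples
#' tibble::tibble(condition = "a", diameter_nm = c(8, 10, 12)) |>
#'   diameter_summary()
diameter_summary <- function(data) {
  check_columns(data, c("condition", "diameter_nm"), "data")
  check_number(data$diameter_nm, "diameter_nm", lower = 0,
               strict_lower = TRUE)
  out <- data |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean_nm = mean(.data$diameter_nm),
                     sd_nm = sd(.data$diameter_nm),
                     n = dplyr::n(), .groups = "drop")
  if (any(out$n < 2)) abort("Each condition needs at least 2 measurements.")
  out
}

as_group_summary <- function(g, name) {
  if (is.data.frame(g)) {
    check_columns(g, c("mean_nm", "sd_nm", "n"), name)
    if (nrow(g) != 1) abort(sprintf("`%s` must be a single group.", name))
    g <- list(mean = g$mean_nm, sd = g$sd_nm, n = g$n)
  } else if (is.numeric(g) && length(g) == 3) {
    g <- list(mean = g[[1]], sd = g[[2]], n = g[[3]])
  } else if (is.list(g) && all(c("mean", "sd", "n") %in% names(g))) {
    g <- g[c("mean", "sd", "n")]
  } else {
    abort(sprintf(
      "`%s` must be c(mean, sd, n), a named list, or a one-row summary.",
      name))
  }
  if (g$sd < 0 || g$n < 2) abort(sprintf("`%s`: need sd >= 0 and n >= 2.",
                                         name))
  g
}

ttest_one <- function(g1, g2, variant) {
  d <- g1$mean - g2$mean
  if (variant == "student") {
    df <- g1$n + g2$n - 2
    sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df
    se <- sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  } else {
    v1 <- g1$sd^2 / g1$n
    v2 <- g2$sd^2 / g2$n
    se <- sqrt(v1 + v2)
    df <- if (se > 0) {
      (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
    } else {
      g1$n + g2$n - 2
    }
  }
  note <- NA_character_
  if (se == 0) {
    if (d == 0) {
      t_stat <- 0
      p <- 1
    } else {
      t_stat <- sign(d) * Inf
      p <- .Machine$double.xmin     # zero variance, unequal means
      note <- "zero-variance groups; p clamped"
    }
  } else {
    t_stat <- d / se
    p <- 2 * pt(-abs(t_stat), df)
  }
  tibble::tibble(variant = variant, t = t_stat, df = df, p = p,
                 note = note)
}

#' Unpaired two-sample t-test from summary statistics
#'
#' Standard unpaired two-tailed t-test computed from (mean, SD, n)
#' summaries, as used to compare fibril diameter distributions whose raw
#' measurements are reported only as group summaries. `"student"` pools
#' the variances (classical unpaired t, the default of common analysis
#' software); `"welch"` uses the Satterthwaite degrees of freedom;
#' `"both"` reports the two variants.
#'
#' @param g1,g2 Group summaries: `c(mean, sd, n)`, a named list, or a
#'   one-row tibble with `mean_nm`, `sd_nm`, `n`. Both need `n >= 2`.
#' @param variant `"student"` (default), `"welch"`, or `"both"`.
#' @return A tibble with one row per variant: `variant`, `t`, `df`, `p`
#'   (two-sided), `note`.
#' @export
#' @examples
#' ttest_from_summary(c(13.8, 2.9, 100), c(8.4, 1.5, 100),
#'                    variant = "both")
ttest_from_summary <- function(g1, g2,
                               variant = c("student", "welch", "both")) {
  variant <- match.arg(variant)
  g1 <- as_group_summary(g1, "g1")
  g2 <- as_group_summary(g2, "g2")
  variants <- if (variant == "both") c("student", "welch") else variant
  dplyr::bind_rows(purrr::map(variants, function(v) ttest_one(g1, g2, v)))
}

#' Unpaired two-sample t-test from raw samples
#'
#' Summarizes each sample and delegates to [ttest_from_summary()], so
#' sample-mode and summary-mode calls on the same data agree exactly.
#'
#' @param a,b Numeric vectors of measurements (each length >= 2).
#' @param variant `"student"` (default), `"welch"`, or `"both"`.
#' @return As [ttest_from_summary()].
#' @export
#' @examples
#' ttest_from_samples(c(8, 10, 12, 9), c(12, 14, 13, 15))
ttest_from_samples <- function(a, b,
                               variant = c("student", "welch", "both")) {
  variant <- match.arg(variant)
  for (x in list(a, b)) {
    if (!is.numeric(x) || length(x) < 2 || anyNA(x)) {
      abort("`a` and `b` must be numeric vectors of length >= 2.")
    }
  }
  ttest_from_summary(list(mean = mean(a), sd = sd(a), n = length(a)),
                     list(mean = mean(b), sd = sd(b), n = length(b)),
                     variant = variant)
}

#' Classify fibril cross-section architecture from the mean diameter
#'
#' Thin fibrils (single filament, dimeric cross-section) and thick
#' fibrils (two filaments, tetrameric cross-section) are separated by a
#' diameter boundary; the default of 11 nm is the midpoint of the 8.4 nm
#' and 13.8 nm class means. A mean exactly at the boundary is
#' `"unclassified"`.
#'
#' @param mean_diameter Mean diameter(s) in nm, > 0; vectorized.
#' @param boundary Class boundary in nm (default 11).
#' @return Character vector with levels
#'   `"single-filament (dimer)"`, `"two-filament (tetramer)"`,
#'   `"unclassified"`.
#' @export
#' @examples
#' cross_section_class(c(8.4, 13.8, 11))
cross_section_class <- function(mean_diameter, boundary = 11) {
  check_number(mean_diameter, "mean_diameter", lower = 0,
               strict_lower = TRUE)
  check_number(boundary, "boundary", lower = 0, strict_lower = TRUE)
  dplyr::case_when(
    mean_diameter > boundary ~ "two-filament (tetramer)",
    mean_diameter < boundary ~ "single-filament (dimer)",
    TRUE ~ "unclassified"
  )
}
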