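#' Combined chemical-shift change
#'
#' Combines a proton and a heteronucleus shift difference into one
#' per-residue perturbation magnitude,
#' \deqn{|\delta_{comb}| = \sqrt{(\delta_{het}/s)^2 + \delta_H^2},}
#' with the heteronucleus scale factor `s = 2` by default (written for
#' 13C; applied identically to 15N unless overridden).
#'
#' @param delta_h Proton shift difference (ppm); vectorized.
#' @param delta_hetero Heteronucleus shift difference (ppm); vectorized.
#' @param hetero_scale Heteronucleus scale factor (default 2).
#' @return Combined shift (ppm), always >= 0.
#' @export
#' @examples
#' csp_combined_shift(0.03, 0.4)
csp_combined_shift <- function(delta_h, delta_hetero, hetero_scale = 2) {
  if (anyNA(c(hetero_scale)) || hetero_scale <= 0) {
    abort("`hetero_scale` must be a positive number.")
  }
  sqrt((delta_hetero / hetero_scale)^2 + delta_h^2)
}

#' Match assigned peaks between two conditions
#'
#' Matches each reference (fibril-alone) peak to the query
#' (chaperone-present) peaks carrying the same residue assignment and
#' atom pair, computes per-residue shift differences and classifies every
#' residue:
#'
#' * `unique` - exactly one query peak (shifted or not);
#' * `doubled` - two query peaks, one at the reference position (within
#'   `radius_hetero` x `radius_h`) and one shifted; the shift difference
#'   is taken from the shifted member;
#' * `overlapped` - the reference peak lies within the matching radii of
#'   another reference peak, so shifts cannot be attributed;
#' * `ambiguous` - conflicting query candidates (two shifted peaks, or
#'   more than two peaks);
#' * `missing` - no query peak for the residue.
#'
#' @param reference,query Peak tibbles with columns `residue_index`,
#'   `atom_pair`, `w1` (heteronucleus, ppm), `w2` (1H, ppm); optional
#'   `residue_name`, `intensity`. Duplicate (`residue_index`,
#'   `atom_pair`) rows in `reference` are an error.
#' @param radius_h,radius_hetero "Same position" radii in ppm for 1H and
#'   the heteronucleus (defaults 0.05 and 0.2).
#' @param hetero_scale Scale factor passed to [csp_combined_shift()].
#' @return A tibble of per-residue records: `residue_index`,
#'   `residue_name`, `atom_pair`, `delta_h`, `delta_hetero`,
#'   `delta_comb`, `category`.
#' @export
#' @examples
#' tabs <- sim_peak_tables(perturbed = 28,
#'                         cfg = synth_config(noise_sd_shift_h = 0,
#'                                            noise_sd_shift_hetero = 0))
#' csp_match_peaks(tabs$reference, tabs$query) |>
#'   dplyr::filter(residue_index == 28)
csp_match_peaks <- function(reference, query, radius_h = 0.05,
                            radius_hetero = 0.2, hetero_scale = 2) {
  check_columns(reference, c("residue_index", "atom_pair", "w1", "w2"),
                "reference")
  check_columns(query, c("residue_index", "atom_pair", "w1", "w2"), "query")
  check_number(radius_h, "radius_h", lower = 0, strict_lower = TRUE)
  check_number(radius_hetero, "radius_hetero", lower = 0,
               strict_lower = TRUE)
  if (anyDuplicated(reference[c("residue_index", "atom_pair")]) > 0) {
    abort("`reference` contains duplicate (residue_index, atom_pair) rows.")
  }
  if (!"residue_name" %in% names(reference)) {
    reference$residue_name <- NA_character_
  }
  ref <- dplyr::arrange(reference, .data$residue_index)

  # reference peaks that cannot be told apart in the spectrum
  overlapped_idx <- unique(unlist(purrr::map(
    split(ref, ref$atom_pair), function(g) {
      if (nrow(g) < 2) return(integer())
      pairs <- which(
        outer(g$w1, g$w1, function(x, y) abs(x - y) <= radius_hetero) &
          outer(g$w2, g$w2, function(x, y) abs(x - y) <= radius_h) &
          outer(seq_len(nrow(g)), seq_len(nrow(g)), `!=`),
        arr.ind = TRUE)
      g$residue_index[unique(as.vector(pairs))]
    })))

  records <- purrr::pmap(ref, function(residue_index, residue_name,
                                       atom_pair, w1, w2, ...) {
    qs <- query[query$residue_index == residue_index &
                  query$atom_pair == atom_pair, ]
    rec <- tibble::tibble(
      residue_index = residue_index, residue_name = residue_name,
      atom_pair = atom_pair, delta_h = NA_real_, delta_hetero = NA_real_,
      delta_comb = NA_real_, category = "missing")
    if (nrow(qs) == 0) return(rec)
    d_het <- qs$w1 - w1
    d_h <- qs$w2 - w2
    at_ref <- abs(d_het) <= radius_hetero & abs(d_h) <= radius_h
    if (nrow(qs) == 1) {
      rec$category <- "unique"
      pick <- 1L
    } else if (nrow(qs) == 2 && sum(at_ref) == 1) {
      rec$category <- "doubled"
      pick <- which(!at_ref)
    } else {
      rec$category <- "ambiguous"
      pick <- which.max(csp_combined_shift(d_h, d_het, hetero_scale))
    }
    rec$delta_h <- d_h[pick]
    rec$delta_hetero <- d_het[pick]
    rec$delta_comb <- csp_combined_shift(d_h[pick], d_het[pick],
                                         hetero_scale)
    rec
  })
  out <- dplyr::bind_rows(records)
  dplyr::mutate(out, category = dplyr::if_else(
    .data$residue_index %in% overlapped_idx, "overlapped", .data$category))
}

csp_threshold <- function(records, rule, k, threshold) {
  assessable <- !(records$category %in% c("overlapped", "missing")) &
    !is.na(records$delta_comb)
  if (!any(assessable)) {
    abort("No assessable residues (all overlapped or missing).")
  }
  thr <- if (rule == "absolute") {
    check_number(threshold, "threshold", lower = 0)
    threshold
  } else {
    x <- records$delta_comb[assessable]
    mean(x) + k * sd(x)
  }
  list(assessable = assessable, threshold = thr)
}

#' Flag residues with significant shift changes
#'
#' Flags residues whose combined shift change strictly exceeds a
#' threshold: either an absolute value in ppm (`rule = "absolute"`) or
#' `mean + k * SD` of the combined shifts over assessable residues
#' (`rule = "mean_sd"`, the default with `k = 1`). Overlapped and missing
#' residues enter neither the statistics nor the flags.
#'
#' @param records Output of [csp_match_peaks()].
#' @param rule `"mean_sd"` or `"absolute"`.
#' @param k Multiplier for the SD under `"mean_sd"`.
#' @param threshold Absolute threshold in ppm under `"absolute"`.
#' @return `records` with a logical `significant` column; the numeric
#'   threshold used is stored in the `"threshold_ppm"` attribute.
#' @export
#' @examples
#' tabs <- sim_peak_tables(perturbed = c(27, 28))
#' csp_match_peaks(tabs$reference, tabs$query) |>
#'   csp_classify() |>
#'   dplyr::filter(significant)
csp_classify <- function(records, rule = c("mean_sd", "absolute"), k = 1,
                         threshold = NULL) {
  rule <- match.arg(rule)
  check_columns(records, c("residue_index", "delta_comb", "category"),
                "records")
  th <- csp_threshold(records, rule, k, threshold)
  out <- dplyr::mutate(records, significant = th$assessable &
                         !is.na(.data$delta_comb) &
                         .data$delta_comb > th$threshold)
  attr(out, "threshold_ppm") <- th$threshold
  out
}

#' Select interacting residues for docking restraints
#'
#' Returns the sorted unique set of residues flagged by [csp_classify()],
#' the residue set used as active restraints when docking the chaperone
#' onto the fibril. Residues whose assignment is ambiguous are included
#' only on request.
#'
#' @inheritParams csp_classify
#' @param include_ambiguous Include residues of category `"ambiguous"`
#'   (default `FALSE`).
#' @return An object of class `active_residue_set`: list with `residues`
#'   (sorted integer vector), `threshold_ppm` and `rule`.
#' @export
#' @examples
#' tabs <- sim_peak_tables(perturbed = c(27, 28, 30:32, 40:42))
#' csp_match_peaks(tabs$reference, tabs$query) |>
#'   csp_select_residues()
csp_select_residues <- function(records, rule = c("mean_sd", "absolute"),
                                k = 1, threshold = NULL,
                                include_ambiguous = FALSE) {
  rule <- match.arg(rule)
  classified <- csp_classify(records, rule = rule, k = k,
                             threshold = threshold)
  keep <- classified$significant &
    (include_ambiguous | classified$category != "ambiguous")
  rule_desc <- if (rule == "absolute") {
    sprintf("delta_comb > %.4g ppm (absolute)", attr(classified,
                                                     "threshold_ppm"))
  } else {
    sprintf("delta_comb > mean + %g*SD (= %.4g ppm)", k,
            attr(classified, "threshold_ppm"))
  }
  structure(
    list(residues = sort(unique(classified$residue_index[keep])),
         threshold_ppm = attr(classified, "threshold_ppm"),
         rule = rule_desc),
    class = "active_residue_set"
  )
}

#' @export
print.active_residue_set <- function(x, ...) {
  cat("<active_residue_set>", length(x$residues), "residues:",
      paste(x$residues, collapse = ", "), "\n")
  cat("  rule:", x$rule, "\n")
  invisible(x)
}

#' Export docking restraint table
#'
#' Expands the fibril-side active residues over the central fibril
#' subunits (the binding epitope repeats along the fibril axis, so the
#' docking site is restrained to `n_subunits` consecutive chains in the
#' middle of the fibril) and appends the chaperone-side active residues,
#' producing a table suitable for transfer into docking software.
#'
#' @param fibril_set,partner_set [csp_select_residues()] results or plain
#'   integer residue vectors; both must be non-empty.
#' @param n_subunits Number of central fibril chains the site is
#'   replicated over (default 3).
#' @return A tibble with columns `molecule` (`"fibril"`/`"partner"`),
#'   `chain` and `residue_index`.
#' @export
#' @examples
#' csp_export_restraints(c(27, 28), c(115, 130), n_subunits = 3)
csp_export_restraints <- function(fibril_set, partner_set, n_subunits = 3) {
  as_res <- function(x) {
    if (inherits(x, "active_residue_set")) x$residues else
      sort(unique(as.integer(x)))
  }
  fr <- as_res(fibril_set)
  pr <- as_res(partner_set)
  if (length(fr) == 0 || length(pr) == 0) {
    abort("Both residue sets must be non-empty.")
  }
  if (n_subunits < 1) abort("`n_subunits` must be >= 1.")
  dplyr::bind_rows(
    tidyr::expand_grid(chain = LETTERS[seq_len(n_subunits)],
                       residue_index = fr) |>
      dplyr::mutate(molecule = "fibril", .before = 1),
    tibble::tibble(molecule = "partner", chain = "P", residue_index = pr)
  )
}

#' Bri2 chaperone-side restraint residues
#'
#' Residues of the Bri2 chaperone-like domain lining face A (within 5
#' angstrom of its natural amyloidogenic client peptide), used as the
#' partner-side active restraints in docking.
#'
#' @return Integer vector of residue indices in full-precursor numbering.
#' @export
#' @examples
#' bri2_active_residues()
bri2_active_residues <- function() {
  c(115L, 130L, 132L, 139:143, 145L, 156:158)
}
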