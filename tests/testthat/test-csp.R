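test_that("combined shift matches its closed form and scaling properties", {
  expect_equal(csp_combined_shift(0, 0), 0)
  expect_equal(csp_combined_shift(0, 2), 1)       # reduces to delta_C / 2
  expect_equal(csp_combined_shift(0.03, 0.4), sqrt(0.2^2 + 0.03^2),
               tolerance = 1e-12)
  # sign symmetry and first-order homogeneity
  x <- c(0.02, -0.05, 0.1)
  y <- c(-0.3, 0.6, 0.2)
  expect_equal(csp_combined_shift(x, y), csp_combined_shift(-x, y))
  expect_equal(csp_combined_shift(x, y), csp_combined_shift(x, -y))
  expect_equal(csp_combined_shift(3 * x, 3 * y),
               3 * csp_combined_shift(x, y), tolerance = 1e-12)
  expect_error(csp_combined_shift(1, 1, hetero_scale = 0), "positive")
})

test_that("peak matching classifies unique, doubled, overlapped and missing", {
  tabs <- sim_peak_tables(perturbed = c(27, 28), doubling = TRUE,
                          cfg = quiet_cfg())
  rec <- csp_match_peaks(tabs$reference, tabs$query)
  expect_equal(rec$category[rec$residue_index %in% c(27, 28)],
               c("doubled", "doubled"))
  expect_equal(rec$delta_comb[rec$residue_index == 28],
               csp_combined_shift(0.06, 0.4), tolerance = 1e-10)
  expect_true(all(rec$category[!rec$residue_index %in% c(27, 28)] ==
                    "unique"))
  expect_equal(rec$delta_comb[rec$category == "unique"],
               rep(0, 40), tolerance = 1e-12)

  # shifted-without-doubling residues stay unique with nonzero delta
  tabs_m <- sim_peak_tables(perturbed = 30, doubling = FALSE,
                            cfg = quiet_cfg())
  rec_m <- csp_match_peaks(tabs_m$reference, tabs_m$query)
  expect_equal(rec_m$category[rec_m$residue_index == 30], "unique")
  expect_gt(rec_m$delta_comb[rec_m$residue_index == 30], 0.1)

  # missing when the query lost the peak
  rec_miss <- csp_match_peaks(
    tabs$reference, dplyr::filter(tabs$query, residue_index != 5))
  expect_equal(rec_miss$category[rec_miss$residue_index == 5], "missing")
  expect_true(is.na(rec_miss$delta_comb[rec_miss$residue_index == 5]))

  # two reference peaks within both radii are overlapped
  ref <- tibble::tibble(residue_index = 1:3,
                        residue_name = c("A", "G", "V"),
                        atom_pair = "CA-HA",
                        w1 = c(50, 50.1, 60), w2 = c(4.0, 4.02, 4.5),
                        intensity = 1)
  rec_ov <- csp_match_peaks(ref, ref)
  expect_equal(rec_ov$category, c("overlapped", "overlapped", "unique"))

  # duplicate reference assignments are rejected
  expect_error(csp_match_peaks(ref[c(1, 1, 2), ], ref), "duplicate")
})

test_that("peak matching is invariant to input row order", {
  tabs <- sim_peak_tables(perturbed = c(27, 40),
                          cfg = synth_config(seed = 9))
  rec1 <- csp_match_peaks(tabs$reference, tabs$query)
  shuffle <- withr::with_seed(1, sample(nrow(tabs$query)))
  rec2 <- csp_match_peaks(tabs$reference[rev(seq_len(42)), ],
                          tabs$query[shuffle, ])
  expect_equal(dplyr::arrange(rec1, residue_index),
               dplyr::arrange(rec2, residue_index))
})

test_that("significance classification follows the mean + k*SD and absolute rules", {
  toy <- tibble::tibble(
    residue_index = 1:5, residue_name = "A", atom_pair = "CA-HA",
    delta_h = 0, delta_hetero = 0,
    delta_comb = c(0.01, 0.02, 0.01, 0.02, 0.50),
    category = "unique")
  # hand computation: mean 0.112, sd ~0.2169 -> threshold ~0.329
  thr <- mean(toy$delta_comb) + sd(toy$delta_comb)
  cl <- csp_classify(toy)
  expect_equal(attr(cl, "threshold_ppm"), thr)
  expect_equal(which(cl$significant), 5L)

  # equal shifts: SD = 0, strict inequality flags nothing
  toy_eq <- dplyr::mutate(toy, delta_comb = 0.1)
  expect_false(any(csp_classify(toy_eq)$significant))

  # absolute threshold 0 flags any nonzero shift
  cl0 <- csp_classify(toy, rule = "absolute", threshold = 0)
  expect_true(all(cl0$significant))

  # overlapped/missing rows enter neither statistics nor flags
  toy_mix <- dplyr::mutate(toy, category = c("unique", "overlapped",
                                             "unique", "missing",
                                             "unique"))
  cl_mix <- csp_classify(toy_mix, rule = "absolute", threshold = 0)
  expect_equal(cl_mix$significant, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_error(csp_classify(dplyr::mutate(toy, category = "missing")),
               "assessable")
})

test_that("interacting-residue selection recovers the perturbed set exactly", {
  perturbed <- c(27, 28, 30:32, 40:42)
  tabs <- sim_peak_tables(perturbed = perturbed,
                          cfg = synth_config(seed = 21))
  rec <- csp_match_peaks(tabs$reference, tabs$query)
  set <- csp_select_residues(rec)
  expect_equal(set$residues, perturbed)

  # empty flag set gives an empty selection
  tabs0 <- sim_peak_tables(cfg = quiet_cfg())
  rec0 <- csp_match_peaks(tabs0$reference, tabs0$query)
  expect_equal(
    csp_select_residues(rec0, rule = "absolute", threshold = 1)$residues,
    integer(0))

  # ambiguous residues excluded unless requested
  rec_amb <- dplyr::mutate(rec, category = dplyr::if_else(
    residue_index == 27, "ambiguous", category))
  expect_false(27 %in% csp_select_residues(rec_amb)$residues)
  expect_true(27 %in% csp_select_residues(
    rec_amb, include_ambiguous = TRUE)$residues)
})

test_that("restraint export replicates fibril residues over the central chains", {
  r <- csp_export_restraints(c(27, 28), c(115, 130), n_subunits = 3)
  fib <- dplyr::filter(r, molecule == "fibril")
  expect_equal(nrow(fib), 6)
  expect_equal(sort(unique(fib$chain)), c("A", "B", "C"))
  # chaperone-side list from face A spans 12 residues
  r2 <- csp_export_restraints(c(27, 28), bri2_active_residues())
  expect_equal(nrow(dplyr::filter(r2, molecule == "partner")), 12)
  # single subunit: row count equals residue count
  r1 <- csp_export_restraints(c(27, 28, 30), 115, n_subunits = 1)
  expect_equal(nrow(dplyr::filter(r1, molecule == "fibril")), 3)
  expect_error(csp_export_restraints(integer(), 115), "non-empty")
})
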