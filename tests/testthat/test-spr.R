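test_that("association model matches the printed closed form", {
  params <- kinetic_params(kon1 = 1e5, koff1 = 1e-3, kon2 = 1e3,
                           koff2 = 1e-2, bmax1 = 100, bmax2 = 50)
  expect_equal(spr_response_assoc(params, 1e-6, 0), 0)
  expect_equal(spr_response_assoc(params, 1e-6, 50),
               oracle_assoc(1e5, 1e3, 1e-3, 1e-2, 100, 50, 1e-6, 50),
               tolerance = 1e-12)
  expect_error(spr_response_assoc(params, 1e-6, -5), "t")

  # second phase annihilated: plateau is kon1*c*B1/(kon1*c + koff2)
  p1 <- kinetic_params(bmax2 = 0)
  plateau <- p1$kon1 * 1e-6 * p1$bmax1 / (p1$kon1 * 1e-6 + p1$koff2)
  expect_equal(spr_response_assoc(p1, 1e-6, 1e6), plateau,
               tolerance = 1e-9)

  # paired pairing couples each phase with its own off-rate
  pp <- kinetic_params(pairing = "paired")
  k1 <- 1e-6 * pp$kon1 + pp$koff1
  expect_equal(spr_response_assoc(pp, 1e-6, 30),
               pp$kon1 * 1e-6 * pp$bmax1 / k1 * (1 - exp(-k1 * 30)) +
                 pp$kon2 * 1e-6 * pp$bmax2 /
                 (1e-6 * pp$kon2 + pp$koff2) *
                 (1 - exp(-(1e-6 * pp$kon2 + pp$koff2) * 30)),
               tolerance = 1e-12)
})

test_that("association response is monotone in t and saturates at bmax1 + bmax2", {
  params <- kinetic_params()
  for (conc in c(1e-7, 1e-6, 1e-5)) {
    r <- spr_response_assoc(params, conc, seq(0, 2000, 10))
    expect_true(all(diff(r) >= -1e-12))
  }
  expect_equal(spr_response_assoc(params, 1, 1e7),
               params$bmax1 + params$bmax2, tolerance = 1e-4)
})

test_that("dissociation model honors its boundary and degenerate cases", {
  params <- kinetic_params()
  expect_equal(spr_response_dissoc(params, t = 300, t0 = 300, r0 = 77), 77)
  expect_error(spr_response_dissoc(params, t = 299, t0 = 300, r0 = 77),
               "t0")
  pa <- kinetic_params(a = 1)
  expect_equal(spr_response_dissoc(pa, t = 400, t0 = 300, r0 = 50),
               50 * exp(-pa$koff1 * 100), tolerance = 1e-12)
  # equal off-rates make the decay independent of a
  pk <- function(a) kinetic_params(koff1 = 5e-3, koff2 = 5e-3, a = a)
  expect_equal(spr_response_dissoc(pk(0.2), t = 450, t0 = 300, r0 = 50),
               spr_response_dissoc(pk(0.9), t = 450, t0 = 300, r0 = 50),
               tolerance = 1e-12)
})

test_that("reference subtraction removes the blank response", {
  tgrid <- seq(0, 100, 10)
  sample <- tibble::tibble(time_s = tgrid, response = 5 + 0.3 * tgrid)
  expect_equal(spr_subtract_reference(sample, sample)$response,
               rep(0, length(tgrid)))
  blank0 <- tibble::tibble(time_s = tgrid, response = 0)
  expect_equal(spr_subtract_reference(sample, blank0)$response,
               sample$response)
  # a linear-drift blank de-drifts the trace analytically
  drift <- tibble::tibble(time_s = tgrid, response = 0.3 * tgrid)
  expect_equal(spr_subtract_reference(sample, drift)$response,
               rep(5, length(tgrid)), tolerance = 1e-12)
  # mismatched grids need explicit interpolation
  blank2 <- tibble::tibble(time_s = seq(0, 100, 5),
                           response = 0.3 * seq(0, 100, 5))
  expect_error(spr_subtract_reference(sample, blank2), "interpolate")
  expect_equal(spr_subtract_reference(sample, blank2,
                                      interpolate = TRUE)$response,
               rep(5, length(tgrid)), tolerance = 1e-12)
})

test_that("equilibrium constants divide off- by on-rates and order strong/weak", {
  p <- kinetic_params(kon1 = 1e5, koff1 = 1e-3)
  expect_equal(spr_kd(p)$kd_strong, 1e-8)
  # symmetric rates collapse the two constants
  ps <- kinetic_params(kon1 = 1e4, kon2 = 1e4, koff1 = 1e-3,
                       koff2 = 1e-3)
  expect_equal(spr_kd(ps)$kd_strong, spr_kd(ps)$kd_weak)
  # swapping phase labels swaps strong/weak assignment, not the value set
  pa <- kinetic_params(kon1 = 1e5, kon2 = 1e3, koff1 = 1e-3,
                       koff2 = 1e-2)
  pb <- kinetic_params(kon1 = 1e3, kon2 = 1e5, koff1 = 1e-2,
                       koff2 = 1e-3)
  expect_equal(spr_kd(pa), spr_kd(pb))
  pz <- kinetic_params()
  pz$koff1 <- 0
  expect_error(spr_kd(pz), "> 0")
})

test_that("global fit recovers noiseless synthetic series exactly under both pairings", {
  for (pairing in c("crossed", "paired")) {
    truth <- kinetic_params(pairing = pairing)
    sg <- sim_sensorgrams(truth, t_grid = seq(0, 900, 10), t0 = 300,
                          cfg = quiet_cfg(2), replicates = 1)
    fit <- spr_fit_global(sg, exclude_lowest = 2, pairing = pairing,
                          seed = 1)
    expect_true(fit$converged)
    expect_lt(fit$residual_rms, 1e-6)
    for (nm in c("kon1", "kon2", "koff1", "koff2", "bmax1", "bmax2",
                 "a")) {
      expect_lt(abs(fit$params[[nm]] - truth[[nm]]) /
                  max(truth[[nm]], 1e-12), 1e-4)
    }
  }
})

test_that("the protocol exclusion drops exactly the lowest concentrations", {
  sg <- sim_sensorgrams(kinetic_params(), t_grid = seq(0, 900, 15),
                        t0 = 300, cfg = quiet_cfg(4), replicates = 2)
  fit <- spr_fit_global(sg, exclude_lowest = 2, seed = 1)
  concs <- sort(unique(sg$concentration_M))
  expect_equal(sort(fit$excluded_concentrations), concs[1:2])
  expect_equal(length(unique(fit$data$concentration_M)), 7)
  expect_equal(fit$n_curves, 14)
  expect_error(spr_fit_global(sg, exclude_lowest = 9), "drop every")
  expect_error(spr_fit_global(sg, exclude_lowest = 7), "At least 3")
})

test_that("the fit is invariant to a global rescaling of response units", {
  truth <- kinetic_params()
  sg <- sim_sensorgrams(truth, concentrations = 50e-6 * 2^-(0:4),
                        t_grid = seq(0, 900, 10), t0 = 300,
                        cfg = synth_config(seed = 6,
                                           noise_sd_sensorgram = 0.5),
                        replicates = 1)
  fit1 <- spr_fit_global(sg, exclude_lowest = 0, seed = 3)
  sg_scaled <- dplyr::mutate(sg, response = response * 100)
  fit2 <- spr_fit_global(sg_scaled, exclude_lowest = 0, seed = 3)
  for (nm in c("kon1", "kon2", "koff1", "koff2", "a")) {
    expect_equal(fit2$params[[nm]], fit1$params[[nm]], tolerance = 1e-2)
  }
  expect_equal(fit2$params$bmax1 / fit1$params$bmax1, 100,
               tolerance = 1e-2)
  expect_equal(fit2$kd$kd_strong, fit1$kd$kd_strong, tolerance = 1e-2)
})

test_that("tidy and glance expose the fitted parameters and constants", {
  sg <- sim_sensorgrams(kinetic_params(),
                        concentrations = 50e-6 * 2^-(0:3),
                        t_grid = seq(0, 900, 15), t0 = 300,
                        cfg = quiet_cfg(8), replicates = 1)
  fit <- spr_fit_global(sg, exclude_lowest = 0, seed = 1)
  td <- tidy(fit)
  expect_equal(td$term, c("kon1", "kon2", "koff1", "koff2", "bmax1",
                          "bmax2", "a"))
  expect_true(all(c("estimate", "std_error") %in% names(td)))
  gl <- glance(fit)
  expect_lte(gl$kd_strong, gl$kd_weak)
  expect_equal(gl$n_curves, 4)
})
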