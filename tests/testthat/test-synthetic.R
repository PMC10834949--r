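test_that("noiseless sensorgrams follow the closed forms and are continuous at t0", {
  params <- kinetic_params(kon1 = 1e5, koff1 = 1e-3, kon2 = 1e3,
                           koff2 = 1e-2, bmax1 = 100, bmax2 = 50)
  sg <- sim_sensorgrams(params, concentrations = 1e-6,
                        t_grid = c(0, 10, 50, 299.999, 300, 600, 3000),
                        t0 = 300, cfg = quiet_cfg(), replicates = 1)
  # zero at injection start
  expect_equal(sg$response[sg$time_s == 0], 0)
  # association samples match the independent arithmetic oracle
  for (tt in c(10, 50)) {
    expect_equal(sg$response[sg$time_s == tt],
                 oracle_assoc(1e5, 1e3, 1e-3, 1e-2, 100, 50, 1e-6, tt),
                 tolerance = 1e-12)
  }
  # continuity at the injection stop
  expect_equal(sg$response[sg$time_s == 300],
               sg$response[sg$time_s == 299.999], tolerance = 1e-4)
  # the long-time dissociation decays toward zero from R0
  r0 <- oracle_assoc(1e5, 1e3, 1e-3, 1e-2, 100, 50, 1e-6, 300)
  expect_equal(sg$response[sg$time_s == 600],
               r0 * (0.7 * exp(-1e-3 * 300) + 0.3 * exp(-1e-2 * 300)),
               tolerance = 1e-12)
})

test_that("degenerate parameter choices reduce to single exponentials", {
  params <- kinetic_params(bmax2 = 0, a = 1)
  conc <- 2e-6
  t <- c(5, 20, 80)
  k1 <- conc * params$kon1 + params$koff2
  amp <- params$kon1 * conc * params$bmax1 / k1
  expect_equal(spr_response_assoc(params, conc, t),
               amp * (1 - exp(-k1 * t)), tolerance = 1e-12)
  expect_equal(spr_response_dissoc(params, t = 300 + t, t0 = 300, r0 = 50),
               50 * exp(-params$koff1 * t), tolerance = 1e-12)
})

test_that("sensorgram generation is seed-deterministic and validates input", {
  cfg <- synth_config(seed = 7)
  args <- list(kinetic_params(), concentrations = c(1e-6, 1e-5),
               t_grid = seq(0, 600, 20), t0 = 300, cfg = cfg)
  expect_identical(do.call(sim_sensorgrams, args),
                   do.call(sim_sensorgrams, args))
  expect_error(sim_sensorgrams(kinetic_params(), concentrations = -1e-6,
                               t_grid = seq(0, 600, 20), t0 = 300),
               "concentrations")
  expect_error(sim_sensorgrams(kinetic_params(), concentrations = 1e-6,
                               t_grid = seq(400, 600, 20), t0 = 300),
               "t0")
  expect_error(kinetic_params(kon1 = -1), "kon1")
})

test_that("inversion-recovery generator matches its model and supports long delays", {
  r1s <- tibble::tibble(residue_index = 1, condition = "undoped", r1 = 0.5)
  d <- sim_inversion_recovery(r1s, delays = c(0, 2, 4, 8),
                              cfg = quiet_cfg())
  expect_equal(d$intensity, 100 * (1 - 2 * exp(-0.5 * c(0, 2, 4, 8))),
               tolerance = 1e-12)
  # slow-relaxing samples are sampled out to 20 s
  d20 <- sim_inversion_recovery(r1s, delays = seq(0, 20, length.out = 9),
                                cfg = quiet_cfg())
  expect_equal(max(d20$delay_s), 20)
  cfg <- synth_config(seed = 3)
  expect_identical(sim_inversion_recovery(r1s, cfg = cfg),
                   sim_inversion_recovery(r1s, cfg = cfg))
  expect_error(sim_inversion_recovery(r1s, delays = numeric()), "delays")
  expect_error(sim_inversion_recovery(r1s, delays = c(0, 1, 1)), "delays")
})

test_that("peak tables carry the sequence, perturbations and doubling", {
  # the 42-residue amyloid-beta sequence holds exactly two serines
  tabs <- sim_peak_tables(cfg = quiet_cfg())
  expect_equal(sum(tabs$reference$residue_name == "S"), 2)
  expect_equal(tabs$reference$residue_index[
    tabs$reference$residue_name == "S"], c(8, 26))

  # no perturbation, no noise: query equals reference up to attenuation
  tabs0 <- sim_peak_tables(attenuation = 0.2, cfg = quiet_cfg())
  expect_equal(tabs0$query$w1, tabs0$reference$w1)
  expect_equal(tabs0$query$intensity, 0.8 * tabs0$reference$intensity)

  # a doubled residue yields two rows at the configured separation
  tabs28 <- sim_peak_tables(perturbed = 28, doubling = TRUE,
                            delta_h = 0.06, delta_hetero = 0.4,
                            cfg = quiet_cfg())
  rows <- dplyr::filter(tabs28$query, residue_index == 28)
  expect_equal(nrow(rows), 2)
  expect_equal(diff(sort(rows$w1)), 0.4, tolerance = 1e-12)
  expect_equal(diff(sort(rows$w2)), 0.06, tolerance = 1e-12)

  expect_error(sim_peak_tables(perturbed = 99), "sequence")
})

test_that("diameter samples honor their generative populations", {
  pops <- tibble::tibble(condition = c("a", "b"),
                         mean_nm = c(13.8, 8.4), sd_nm = c(2.9, 1.5),
                         n = c(100L, 100L))
  d <- sim_diameters(pops, cfg = synth_config(seed = 11))
  s <- diameter_summary(d)
  expect_equal(s$n, c(100L, 100L))
  expect_lt(abs(s$mean_nm[1] - 13.8), 3 * 2.9 / 10)
  expect_lt(abs(s$mean_nm[2] - 8.4), 3 * 1.5 / 10)
  expect_true(all(d$diameter_nm > 0))

  # SD 0 degenerates to the mean
  d0 <- sim_diameters(tibble::tibble(condition = "c", mean_nm = 10,
                                     sd_nm = 0, n = 5L))
  expect_equal(d0$diameter_nm, rep(10, 5))

  # law of large numbers on the sample SD
  dl <- sim_diameters(tibble::tibble(condition = "d", mean_nm = 10,
                                     sd_nm = 2, n = 10000L),
                      cfg = synth_config(seed = 5))
  expect_lt(abs(sd(dl$diameter_nm) - 2) / 2, 0.05)

  expect_error(sim_diameters(tibble::tibble(condition = "e", mean_nm = -1,
                                            sd_nm = 1, n = 10L)))
})
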