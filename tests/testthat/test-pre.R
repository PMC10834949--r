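test_that("mono-exponential fits recover rates from clean and noisy recovery data", {
  r1s <- tibble::tibble(residue_index = 1, condition = "undoped",
                        r1 = 0.5)
  clean <- sim_inversion_recovery(r1s, cfg = quiet_cfg())
  f <- fit_r1(clean)
  expect_true(f$converged)
  expect_lt(abs(f$r1 - 0.5) / 0.5, 1e-6)
  expect_equal(f$offset, 100, tolerance = 1e-5)
  expect_equal(f$amplitude, -200, tolerance = 1e-4)

  # flat series: rate unidentifiable, flagged rather than thrown
  flat <- tibble::tibble(residue_index = 1, condition = "undoped",
                         delay_s = c(0, 1, 2, 4), intensity = 50)
  expect_false(fit_r1(flat)$converged)

  expect_error(fit_r1(tibble::tibble(residue_index = 1, condition = "u",
                                     delay_s = c(0, 1, 2),
                                     intensity = c(1, 2, 3))),
               "4 points")

  # median recovery over noisy replicates stays within 5%
  r1t <- tibble::tibble(residue_index = 1, condition = "undoped",
                        r1 = 0.4)
  est <- purrr::map_dbl(1:40, function(s) {
    fit_r1(sim_inversion_recovery(r1t,
                                  cfg = synth_config(seed = 300 + s)))$r1
  })
  expect_lt(abs(median(est) - 0.4) / 0.4, 0.05)
})

test_that("Monte-Carlo rate errors are deterministic and vanish with the noise", {
  r1s <- tibble::tibble(residue_index = 1, condition = "undoped", r1 = 0.5)
  d <- sim_inversion_recovery(r1s, cfg = synth_config(seed = 4))
  e1 <- r1_mc_error(d, n_sim = 50, seed = 5)
  e2 <- r1_mc_error(d, n_sim = 50, seed = 5)
  expect_identical(e1$r1_err, e2$r1_err)
  expect_gt(e1$r1_err, 0)

  d0 <- dplyr::mutate(d, noise_sd = 0)
  expect_equal(r1_mc_error(d0, n_sim = 10, seed = 1)$r1_err, 0)
  expect_error(r1_mc_error(d, n_sim = 1), "n_sim")
})

test_that("Monte-Carlo errors are invariant under intensity rescaling", {
  r1s <- tibble::tibble(residue_index = 1, condition = "undoped", r1 = 0.6)
  d <- sim_inversion_recovery(r1s, cfg = synth_config(seed = 8))
  e <- r1_mc_error(d, n_sim = 200, seed = 3)
  d_scaled <- dplyr::mutate(d, intensity = intensity * 1000,
                            noise_sd = noise_sd * 1000)
  e_scaled <- r1_mc_error(d_scaled, n_sim = 200, seed = 3)
  expect_equal(e_scaled$r1_err, e$r1_err, tolerance = 1e-6)
})

test_that("PRE profiles difference doped minus undoped with quadrature errors", {
  doped <- tibble::tibble(residue_index = 1:4, r1 = c(1.0, 0.5, 0.8, 0.6),
                          r1_err = 0.02, converged = TRUE)
  undoped <- tibble::tibble(residue_index = 1:4, r1 = 0.5,
                            r1_err = 0.02, converged = TRUE)
  pre <- compute_pre(doped, undoped)
  expect_equal(pre$pre, c(0.5, 0, 0.3, 0.1))
  expect_equal(pre$pre_err, rep(sqrt(2) * 0.02, 4), tolerance = 1e-12)
  expect_equal(pre$pre_err[1], 0.0283, tolerance = 1e-3)

  # identical conditions give an all-zero profile
  expect_equal(compute_pre(undoped, undoped)$pre, rep(0, 4))
  # antisymmetry under swapping the conditions
  expect_equal(compute_pre(undoped, doped)$pre, -pre$pre)

  # non-overlapping or unconverged residues are dropped, empty is an error
  doped_part <- dplyr::mutate(doped, converged = c(TRUE, FALSE, TRUE,
                                                   TRUE))
  expect_message(pre_part <- compute_pre(doped_part, undoped), "Dropped")
  expect_equal(pre_part$residue_index, c(1, 3, 4))
  expect_error(compute_pre(dplyr::mutate(doped, converged = FALSE),
                           undoped), "converged")
})

test_that("PRE recovery through the full fit chain matches the ground truth", {
  # residue 27 carries a true solvent PRE of 0.3 /s
  maps <- dplyr::bind_rows(
    tibble::tibble(residue_index = 27, condition = "undoped", r1 = 0.4),
    tibble::tibble(residue_index = 27, condition = "doped", r1 = 0.7))
  d <- sim_inversion_recovery(maps, cfg = synth_config(seed = 14))
  fits <- r1_mc_error(d, n_sim = 200, seed = 2)
  pre <- compute_pre(dplyr::filter(fits, condition == "doped"),
                     dplyr::filter(fits, condition == "undoped"))
  expect_lt(abs(pre$pre - 0.3), 2 * pre$pre_err)
})

test_that("condition differences flag exactly the built-in segments", {
  apo <- make_pre_profile(1:42, pre = rep(0.5, 42))
  holo_pre <- rep(0.5, 42)
  holo_pre[26:29] <- 0.1          # buried by the bound chaperone
  holo_pre[42] <- 1.0             # newly exposed C-terminus
  holo <- make_pre_profile(1:42, pre = holo_pre, condition = "holo")
  dp <- delta_pre(apo, holo, k_sigma = 2)
  expect_equal(dp$segments,
               tibble::tibble(start = c(26L, 42L), end = c(29L, 42L),
                              direction = c("decreased", "increased")))
  expect_equal(sum(dp$table$flag != "none"), 5)

  # identical profiles: nothing flagged
  dp0 <- delta_pre(apo, apo)
  expect_equal(nrow(dp0$segments), 0)
  expect_true(all(dp0$table$flag == "none"))

  # an infinite multiplier silences every flag
  dp_inf <- delta_pre(apo, holo, k_sigma = Inf)
  expect_true(all(dp_inf$table$flag == "none"))

  expect_error(delta_pre(apo, make_pre_profile(100:110, pre = 0.1)),
               "share no residues")
})

test_that("two-sigma flagging is calibrated on truly null residues", {
  n <- 1500
  sigma <- 0.05
  withr::with_seed(99, {
    apo <- make_pre_profile(1:n, pre = 0.5 + rnorm(n, 0, sigma),
                            err = sigma)
    holo <- make_pre_profile(1:n, pre = 0.5 + rnorm(n, 0, sigma),
                             err = sigma, condition = "holo")
  })
  dp <- delta_pre(apo, holo, k_sigma = 2)
  rate <- mean(dp$table$flag != "none")
  expect_gt(rate, 0.026)
  expect_lt(rate, 0.066)
})
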