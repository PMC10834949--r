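# Global Levenberg-Marquardt fit of the two-phase kinetic model across a
# sensorgram concentration series. Rates and amplitudes are shared across
# curves; R0 is per-curve. Rates/amplitudes are fitted in log space (and
# `a` on the logit scale) so positivity and the [0,1] bound hold by
# construction.

theta_pack <- function(kon1, kon2, koff1, koff2, bmax1, bmax2, a, r0) {
  c(log(c(kon1, kon2, koff1, koff2, bmax1, bmax2)),
    qlogis(pmin(pmax(a, 1e-6), 1 - 1e-6)),
    log(pmax(r0, 1e-9)))
}

theta_unpack <- function(theta, n_curves, pairing) {
  p <- exp(theta[1:6])
  list(params = kinetic_params(kon1 = p[1], kon2 = p[2], koff1 = p[3],
                               koff2 = p[4], bmax1 = p[5], bmax2 = p[6],
                               a = plogis(theta[7]), pairing = pairing),
       r0 = exp(theta[7 + seq_len(n_curves)]))
}

fit_residuals <- function(theta, curves, pairing) {
  up <- theta_unpack(theta, length(curves), pairing)
  unlist(purrr::imap(curves, function(cv, i) {
    assoc <- cv$time_s < cv$t0
    pred <- numeric(length(cv$time_s))
    pred[assoc] <- spr_response_assoc(up$params, cv$conc, cv$time_s[assoc])
    pred[!assoc] <- spr_response_dissoc(up$params, cv$time_s[!assoc],
                                        t0 = cv$t0, r0 = up$r0[i])
    pred - cv$response
  }), use.names = FALSE)
}

# canonical phase labelling: phase 1 dissociates more slowly (koff1 <=
# koff2). The model is exactly invariant under the full label swap
# (kon1<->kon2, koff1<->koff2, bmax1<->bmax2, a<->1-a), so a fit can
# return either labelling; we report one deterministically.
canonicalize_phases <- function(params, se = NULL) {
  if (params$koff1 <= params$koff2) return(list(params = params, se = se))
  swapped <- kinetic_params(
    kon1 = params$kon2, kon2 = params$kon1,
    koff1 = params$koff2, koff2 = params$koff1,
    bmax1 = params$bmax2, bmax2 = params$bmax1,
    a = 1 - params$a, pairing = params$pairing)
  if (!is.null(se)) {
    se <- se[c("kon2", "kon1", "koff2", "koff1", "bmax2", "bmax1", "a")]
    names(se) <- c("kon1", "kon2", "koff1", "koff2", "bmax1", "bmax2", "a")
  }
  list(params = swapped, se = se)
}

#' Globally fit a sensorgram concentration series
#'
#' Fits the two-phase association/dissociation model (see
#' [kinetic_params()]) simultaneously to all curves of a concentration
#' series: one shared set of rate constants, amplitudes and `a`, plus a
#' per-curve dissociation amplitude `R0` (initialized from the observed
#' response at the injection stop). Following the assay protocol, the
#' lowest `exclude_lowest` concentrations are excluded from the global
#' objective. Optimization is unweighted least squares over the
#' concatenated association and dissociation residuals, by
#' Levenberg-Marquardt with multistart initialization (one data-driven
#' start plus log-uniform random draws over `rate_bounds`); starts stop
#' early once additional starts no longer improve the objective.
#'
#' Phase labels are reported canonically with `koff1 <= koff2` (the model
#' is invariant under swapping the two phases). Parameter standard errors
#' come from the Jacobian-based covariance at the optimum.
#'
#' @param data Sensorgram tibble with columns `curve_id`,
#'   `concentration_M`, `t0_s`, `time_s`, `response` (as produced by
#'   [sim_sensorgrams()] or [read_sensorgrams()]). Every curve must
#'   sample both phases.
#' @param exclude_lowest Number of lowest concentrations excluded from
#'   the fit (default 2, matching the assay protocol); at least 3
#'   concentrations must remain.
#' @param pairing Observed-rate convention, `"crossed"` (default) or
#'   `"paired"`; see [kinetic_params()].
#' @param n_starts Maximum number of multistart initializations
#'   (default 16).
#' @param seed Seed for the random starts.
#' @param rate_bounds List with elements `kon` and `koff`, each a length-2
#'   range for the log-uniform random starts.
#' @param patience Stop after this many consecutive non-improving starts
#'   (default 3, once at least 4 starts have run).
#' @return An object of class `spr_fit`; see also [tidy()] and
#'   [glance()] methods. Components include `params`
#'   (canonical [kinetic_params()]), `param_errors`, `r0`, `kd` (tibble
#'   with `kd_strong`/`kd_weak`, paired convention), `residual_rms`,
#'   `excluded_concentrations` and `converged`.
#' @export
#' @examples
#' cfg <- synth_config(seed = 3, noise_sd_sensorgram = 0)
#' sg <- sim_sensorgrams(kinetic_params(), concentrations = c(2e-7, 1e-6,
#'                       5e-6, 2e-5), t_grid = seq(0, 600, 10), t0 = 300,
#'                       cfg = cfg, replicates = 1)
#' fit <- spr_fit_global(sg, exclude_lowest = 0, n_starts = 2)
#' glance(fit)
spr_fit_global <- function(data, exclude_lowest = 2,
                           pairing = c("crossed", "paired"),
                           n_starts = 16, seed = 1,
                           rate_bounds = list(kon = c(1e2, 1e7),
                                              koff = c(1e-5, 1e-1)),
                           patience = 3) {
  pairing <- match.arg(pairing)
  check_columns(data, c("curve_id", "concentration_M", "t0_s", "time_s",
                        "response"), "data")
  concs <- sort(unique(data$concentration_M))
  if (exclude_lowest >= length(concs)) {
    abort("`exclude_lowest` would drop every concentration.")
  }
  excluded <- if (exclude_lowest > 0) concs[seq_len(exclude_lowest)] else
    numeric()
  retained <- dplyr::filter(data, !.data$concentration_M %in% excluded)
  if (length(unique(retained$concentration_M)) < 3) {
    abort("At least 3 retained concentrations are required for a global fit.")
  }

  curves <- retained |>
    dplyr::group_by(.data$curve_id) |>
    dplyr::group_map(function(d, key) {
      if (!any(d$time_s < d$t0_s[1]) || !any(d$time_s >= d$t0_s[1])) {
        abort(sprintf("Curve %s does not sample both phases.",
                      key$curve_id))
      }
      list(curve_id = key$curve_id, conc = d$concentration_M[1],
           t0 = d$t0_s[1], time_s = d$time_s, response = d$response,
           r0_obs = d$response[which.min(abs(d$time_s - d$t0_s[1]))])
    })
  n_curves <- length(curves)
  max_r <- max(abs(retained$response))
  r0_obs <- pmax(purrr::map_dbl(curves, "r0_obs"), 1e-6 * max_r)

  starts <- withr::with_seed(derive_seed(seed, "spr_multistart"), {
    heuristic <- theta_pack(1e5, 1e3, 1e-3, 1e-2, 0.75 * max_r,
                            0.25 * max_r, 0.5, r0_obs)
    random <- purrr::map(seq_len(max(0, n_starts - 1)), function(i) {
      lo <- function(b) exp(stats::runif(1, log(b[1]), log(b[2])))
      ko <- sort(c(lo(rate_bounds$koff), lo(rate_bounds$koff)))
      theta_pack(lo(rate_bounds$kon), lo(rate_bounds$kon),
                 ko[1], ko[2],
                 max_r * stats::runif(1, 0.2, 1.5),
                 max_r * stats::runif(1, 0.05, 1),
                 stats::runif(1, 0.1, 0.9), r0_obs)
    })
    c(list(heuristic), random)
  })

  best <- NULL
  since_improve <- 0L
  for (i in seq_along(starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[[i]], fn = fit_residuals, curves = curves,
        pairing = pairing,
        control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      if (is.null(best) || fit$deviance < best$deviance * (1 - 1e-3)) {
        best <- fit
        since_improve <- 0L
      } else {
        since_improve <- since_improve + 1L
      }
      # essentially-perfect fit: no further starts needed
      if (sqrt(best$deviance / length(best$fvec)) < 1e-7 * max_r) break
      if (i >= 4 && since_improve >= patience) break
    }
  }
  if (is.null(best)) {
    abort("All multistart optimizations failed to evaluate.")
  }

  converged <- best$info %in% 1:4
  up <- theta_unpack(best$par, n_curves, pairing)
  n_res <- length(best$fvec)
  n_par <- length(best$par)
  sigma2 <- best$deviance / max(1, n_res - n_par)
  se_nat <- rep(NA_real_, n_par)
  cov_log <- tryCatch(sigma2 * solve(best$hessian), error = function(e) NULL)
  if (!is.null(cov_log)) {
    se_theta <- sqrt(pmax(diag(cov_log), 0))
    # delta method back to the natural scale
    nat <- c(unlist(up$params[c("kon1", "kon2", "koff1", "koff2",
                                "bmax1", "bmax2")]),
             up$params$a * (1 - up$params$a), up$r0)
    se_nat <- se_theta * nat
  }
  se <- setNames(se_nat[1:7], c("kon1", "kon2", "koff1", "koff2",
                                "bmax1", "bmax2", "a"))
  canon <- canonicalize_phases(up$params, se)

  structure(
    list(params = canon$params,
         param_errors = canon$se,
         r0 = setNames(up$r0, purrr::map_chr(curves, "curve_id")),
         r0_errors = setNames(se_nat[7 + seq_len(n_curves)],
                              purrr::map_chr(curves, "curve_id")),
         kd = spr_kd(canon$params),
         residual_rms = sqrt(best$deviance / n_res),
         excluded_concentrations = excluded,
         n_curves = n_curves,
         n_points = n_res,
         converged = converged,
         pairing = pairing,
         data = retained),
    class = "spr_fit"
  )
}

#' @export
print.spr_fit <- function(x, ...) {
  cat(sprintf(
    "<spr_fit> global two-phase fit (%s pairing): %d curves, %d points\n",
    x$pairing, x$n_curves, x$n_points))
  print(x$params)
  cat(sprintf("  Kd(strong) = %.3g M, Kd(weak) = %.3g M\n",
              x$kd$kd_strong, x$kd$kd_weak))
  cat(sprintf("  residual RMS = %.4g RU; converged: %s\n",
              x$residual_rms, x$converged))
  if (length(x$excluded_concentrations) > 0) {
    cat("  excluded concentrations (M):",
        paste(signif(x$excluded_concentrations, 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predicted response of a fitted model
#'
#' @param object An `spr_fit`.
#' @param ... Unused.
#' @return The fitted data with a `fitted` column appended.
#' @export
fitted.spr_fit <- function(object, ...) {
  r0 <- object$r0
  object$data |>
    dplyr::group_by(.data$curve_id) |>
    dplyr::group_modify(function(d, key) {
      assoc <- d$time_s < d$t0_s[1]
      pred <- numeric(nrow(d))
      pred[assoc] <- spr_response_assoc(object$params,
                                        d$concentration_M[1],
                                        d$time_s[assoc])
      pred[!assoc] <- spr_response_dissoc(object$params, d$time_s[!assoc],
                                          t0 = d$t0_s[1],
                                          r0 = r0[[key$curve_id]])
      dplyr::mutate(d, fitted = pred)
    }) |>
    dplyr::ungroup()
}
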