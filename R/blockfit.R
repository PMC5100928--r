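#' Woodhull-type block model parameters
#'
#' Parameters of the permeant-blocker model in which a blocking ion (Ba2+)
#' enters the pore from the outside (rate constant k1), can leave back
#' outside (k-1) or pass through to the cytoplasm (k2), with the binding site
#' an electrical distance `delta` into the membrane field and the entry
#' barrier halfway between the outside and the site:
#' \deqn{K_{D}(V) = \frac{k_{-1}}{k_1} e^{\delta z F V / RT}
#'       + \frac{k_2}{k_1} e^{(\delta - 1/2) z F V / RT}}
#' Only the rate ratios are identifiable: `K_out = k-1/k1` and
#' `K_through = k2/k1`, both in mM. At V = 0, `K_D(0) = K_out + K_through`.
#' Fractional block at concentration C follows the Hill equation
#' `1 / (1 + (C / K_D(V))^n)`.
#'
#' @param K_out_mM Rate ratio k-1/k1 (mM), exit to the outside.
#' @param K_through_mM Rate ratio k2/k1 (mM), permeation to the inside.
#' @param delta Electrical distance of the binding site, in `[0, 1]`.
#' @param z Blocker valence (2 for Ba2+).
#' @param hill_n Hill coefficient (> 0); values below 1 arise when surface
#'   charge concentrates the blocker near the mouth of the pore.
#' @param temperature_K Absolute temperature.
#' @return An object of class `block_model_params`.
#' @examples
#' block_model_params(0.3, 0.3, 0.5, z = 2, hill_n = 0.6)
#' @export
block_model_params <- function(K_out_mM, K_through_mM, delta, z = 2,
                               hill_n = 1, temperature_K = 298.15) {
  stopifnot(K_out_mM > 0, K_through_mM > 0,
            delta >= 0, delta <= 1, hill_n > 0, z != 0,
            temperature_K > 0)
  structure(list(K_out_mM = K_out_mM, K_through_mM = K_through_mM,
                 delta = delta, z = z, hill_n = hill_n,
                 temperature_K = temperature_K),
            class = "block_model_params")
}

#' @export
print.block_model_params <- function(x, ...) {
  cat(sprintf(
    "block model: K_out %.4g mM, K_through %.4g mM (K_D(0) = %.4g mM), delta %.3f, z %g, n %.3g\n",
    x$K_out_mM, x$K_through_mM, x$K_out_mM + x$K_through_mM,
    x$delta, x$z, x$hill_n))
  invisible(x)
}

#' Voltage-dependent dissociation constant of a permeant blocker
#'
#' Evaluates the two-barrier Woodhull expression (see
#' [block_model_params()]). The second exponent is `(delta - 1/2)` because
#' the entry barrier is assumed halfway between the outside and the binding
#' site; with `delta = 0.5` the through-pathway term is voltage independent,
#' which is why the K_D changes little at negative potentials.
#'
#' @param params A [block_model_params()].
#' @param V_mV Membrane potential(s), mV.
#' @return K_D at each voltage, mM.
#' @examples
#' p <- block_model_params(0.3, 0.3, 0.5, z = 2)
#' kd_of_voltage(p, 0)      # 0.6 mM
#' kd_of_voltage(p, -25.7)  # 0.3*exp(-1) + 0.3
#' @export
kd_of_voltage <- function(params, V_mV) {
  stopifnot(inherits(params, "block_model_params"))
  rt_f <- physical_constants(params$temperature_K)$RT_over_F_mV
  params$K_out_mM * exp(params$delta * params$z * V_mV / rt_f) +
    params$K_through_mM * exp((params$delta - 0.5) * params$z * V_mV / rt_f)
}

#' Unblocked current fraction under Hill block
#'
#' `1 / (1 + (C / K_D(V))^n)` with the voltage-dependent K_D of
#' [kd_of_voltage()].
#'
#' @param C_mM Blocker concentration (mM), >= 0.
#' @param params A [block_model_params()].
#' @param V_mV Membrane potential(s), mV.
#' @return Fraction of unblocked current in (0, 1].
#' @examples
#' p <- block_model_params(0.3, 0.3, 0.5, z = 2, hill_n = 0.6)
#' hill_block_fraction(0, p, -80)                    # 1
#' hill_block_fraction(kd_of_voltage(p, -80), p, -80)  # 0.5
#' @export
hill_block_fraction <- function(C_mM, params, V_mV) {
  stopifnot(all(C_mM >= 0))
  1 / (1 + (C_mM / kd_of_voltage(params, V_mV))^params$hill_n)
}

# Predicted normalized I-V curve for one concentration: the unblocked
# conductance cancels under normalization at the highest voltage.
predict_norm_curve <- function(params, C_mM, voltages_mV, v_norm, reversal_mV) {
  u <- hill_block_fraction(C_mM, params, voltages_mV)
  u_norm <- hill_block_fraction(C_mM, params, v_norm)
  ((voltages_mV - reversal_mV) * u) / ((v_norm - reversal_mV) * u_norm)
}

#' Fit the voltage-dependent block model to a multi-concentration family
#'
#' Global least-squares fit of `(K_out, K_through, delta, hill_n)` jointly
#' across all normalized current-voltage curves of a [simulate_block_dataset()]
#' (or equivalently structured) dataset. Rate ratios and the Hill coefficient
#' are optimized in log space; `delta` is constrained to `[0, 1]`. Several
#' starting points are tried and the best local optimum kept.
#'
#' @param dataset A `block_dataset` (data frame with `concentration_mM`,
#'   `voltage_mV`, `norm_current` and a `normalization_voltage_mV`
#'   attribute).
#' @param z Blocker valence.
#' @param temperature_K Absolute temperature.
#' @return An object of class `block_fit`: list with `params` (fitted
#'   [block_model_params()]), `se` (standard errors for K_out, K_through,
#'   delta, hill_n on the natural scale), `KD0_mM` and `KD0_se_mM`,
#'   `rss`, `n_obs`, `fitted` (data frame of predicted curves).
#' @examples
#' truth <- fixture_registry("Ba-WT")
#' ds <- simulate_block_dataset(truth, 5000, c(0.3, 1, 3, 10, 30))
#' fit <- fit_block_model(ds, z = 2)
#' fit$KD0_mM
#' @export
fit_block_model <- function(dataset, z = 2, temperature_K = 298.15) {
  stopifnot(is.data.frame(dataset),
            all(c("concentration_mM", "voltage_mV", "norm_current") %in%
                  names(dataset)))
  conc <- sort(unique(dataset$concentration_mM))
  if (sum(conc > 0) < 2) {
    stop("under-determined: need at least two nonzero blocker concentrations")
  }
  if (length(unique(dataset$voltage_mV)) < 10) {
    stop("need at least 10 voltages per curve")
  }
  v_norm <- attr(dataset, "normalization_voltage_mV")
  if (is.null(v_norm)) v_norm <- max(dataset$voltage_mV)
  reversal <- attr(dataset, "reversal_mV")
  if (is.null(reversal)) reversal <- 0

  resid_fun <- function(theta) {
    p <- block_model_params(exp(theta[1]), exp(theta[2]),
                            delta = theta[3], z = z,
                            hill_n = exp(theta[4]),
                            temperature_K = temperature_K)
    pred <- predict_norm_curve(p, dataset$concentration_mM,
                               dataset$voltage_mV, v_norm, reversal)
    dataset$norm_current - pred
  }

  kd_guess <- stats::median(conc[conc > 0])
  starts <- list(
    c(log(kd_guess / 2), log(kd_guess / 2), 0.5, log(0.7)),
    c(log(kd_guess / 2), log(kd_guess / 2), 0.25, log(1)),
    c(log(kd_guess / 4), log(kd_guess), 0.75, log(0.5)),
    c(log(kd_guess), log(kd_guess / 4), 0.5, log(1.2))
  )
  lower <- c(-Inf, -Inf, 0, log(1e-3))
  upper <- c(Inf, Inf, 1, log(1e3))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    stop("block-model fit did not converge from any starting point")
  }
  theta <- best$par
  params <- block_model_params(exp(theta[1]), exp(theta[2]), theta[3],
                               z = z, hill_n = exp(theta[4]),
                               temperature_K = temperature_K)
  # delta-method standard errors on the natural scale
  se_nat <- rep(NA_real_, 4)
  kd0_se <- NA_real_
  vc <- tryCatch({
    dof <- length(resid_fun(theta)) - 4
    s2 <- best$deviance / dof
    jtj <- best$hessian
    s2 * solve(jtj)
  }, error = function(e) NULL)
  if (!is.null(vc)) {
    grad_nat <- c(exp(theta[1]), exp(theta[2]), 1, exp(theta[4]))
    se_nat <- sqrt(pmax(diag(vc), 0)) * grad_nat
    g <- c(exp(theta[1]), exp(theta[2]), 0, 0)
    kd0_se <- sqrt(max(0, drop(t(g) %*% vc %*% g)))
  }
  fitted <- dataset[c("concentration_mM", "voltage_mV")]
  fitted$predicted <- predict_norm_curve(params, fitted$concentration_mM,
                                         fitted$voltage_mV, v_norm, reversal)
  structure(list(params = params,
                 se = stats::setNames(se_nat,
                                      c("K_out_mM", "K_through_mM",
                                        "delta", "hill_n")),
                 KD0_mM = params$K_out_mM + params$K_through_mM,
                 KD0_se_mM = kd0_se,
                 rss = best$deviance,
                 n_obs = nrow(dataset),
                 converged = best$info %in% 1:4,
                 fitted = fitted),
            class = "block_fit")
}

#' @export
print.block_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  K_D(0 mV) = %.4g mM (SE %.3g), RSS %.4g over %d points\n",
              x$KD0_mM, x$KD0_se_mM, x$rss, x$n_obs))
  invisible(x)
}

#' Fit a Hill dose-response curve to block data
#'
#' Fits `fraction unblocked = 1 / (1 + (C / K_D)^n)` to measured unblocked
#' fractions at a fixed voltage, as used for pore blockers such as ruthenium
#' red and Gd3+.
#'
#' @param concentration Blocker concentrations (> 0, any unit).
#' @param fraction_unblocked Fractions of unblocked current in `[0, 1]`.
#' @return An object of class `dose_response_fit`: list with `K_D` (in the
#'   unit of `concentration`), `hill_n`, `se` (named standard errors),
#'   `fitted`, and `flagged` (TRUE when the data carry no block signal so
#'   K_D is unbounded).
#' @examples
#' p <- function(C) 1 / (1 + (C / 1)^0.54)
#' fit_dose_response(c(0.1, 0.3, 1, 3, 10), p(c(0.1, 0.3, 1, 3, 10)))
#' @export
fit_dose_response <- function(concentration, fraction_unblocked) {
  stopifnot(length(concentration) == length(fraction_unblocked),
            all(concentration > 0))
  if (length(concentration) < 3) {
    stop("need at least 3 concentrations")
  }
  ord <- order(concentration)
  if (any(diff(fraction_unblocked[ord]) > 0.05)) {
    warning("fraction unblocked is non-monotone in concentration beyond noise")
  }
  if (all(fraction_unblocked > 0.95)) {
    return(structure(list(K_D = Inf, hill_n = NA_real_,
                          se = c(K_D = NA_real_, hill_n = NA_real_),
                          fitted = rep(1, length(concentration)),
                          flagged = TRUE),
                     class = "dose_response_fit"))
  }
  resid_fun <- function(theta) {
    fraction_unblocked - 1 / (1 + (concentration / exp(theta[1]))^exp(theta[2]))
  }
  # start near the concentration giving half block
  kd0 <- concentration[which.min(abs(fraction_unblocked - 0.5))]
  fit <- minpack.lm::nls.lm(par = c(log(kd0), log(1)), fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  theta <- fit$par
  se <- c(K_D = NA_real_, hill_n = NA_real_)
  vc <- tryCatch({
    dof <- max(1, length(concentration) - 2)
    (fit$deviance / dof) * solve(fit$hessian)
  }, error = function(e) NULL)
  if (!is.null(vc)) {
    se <- c(K_D = sqrt(max(0, vc[1, 1])) * exp(theta[1]),
            hill_n = sqrt(max(0, vc[2, 2])) * exp(theta[2]))
  }
  structure(list(K_D = exp(theta[1]), hill_n = exp(theta[2]), se = se,
                 fitted = 1 / (1 + (concentration / exp(theta[1]))^exp(theta[2])),
                 flagged = FALSE),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$flagged) {
    cat("dose-response fit: no block detected; K_D unbounded\n")
  } else {
    cat(sprintf("dose-response fit: K_D = %.4g, hill n = %.3g\n",
                x$K_D, x$hill_n))
  }
  invisible(x)
}
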