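#' Gating fixture: generator truth for one recording condition
#'
#' A fixture bundles everything the synthetic generator needs to emulate a
#' patch recorded under one experimental condition: the two open-channel
#' conductance levels, the probability that an opening enters the smaller
#' level, simple two-state gating rates, reversal potential, seal leak and
#' recording noise. Rectifying mutants additionally carry branch-specific
#' conductances (separate negative- and positive-branch values) used when
#' rendering voltage ramps, because their current-voltage relation is not a
#' single slope.
#'
#' @param name Condition label, e.g. `"WT-150"`.
#' @param gamma_large_pS,gamma_small_pS Large and small open-level
#'   conductances (pS); `gamma_small_pS < gamma_large_pS`.
#' @param p_small Probability that an opening enters the smaller level.
#' @param open_rate_Hz,close_rate_Hz Two-state gating rates (1/s).
#' @param reversal_mV Reversal potential (0 mV in symmetrical solutions).
#' @param leak_pS Ohmic seal-leak conductance (pS).
#' @param noise_rms_pA RMS of the recording noise after filtering (pA).
#' @param branch_conductances Optional named vector
#'   `c(negative = , positive = )` of large-level slope conductances (pS)
#'   used for ramp rendering in rectifying conditions; the small level is
#'   scaled by `gamma_small_pS / gamma_large_pS`.
#' @return An object of class `gating_fixture`.
#' @export
gating_fixture <- function(name, gamma_large_pS, gamma_small_pS,
                           p_small = 0.3, open_rate_Hz = 50,
                           close_rate_Hz = 50, reversal_mV = 0,
                           leak_pS = 20, noise_rms_pA = 1,
                           branch_conductances = NULL) {
  stopifnot(p_small >= 0, p_small <= 1,
            gamma_small_pS < gamma_large_pS,
            gamma_large_pS >= 0, gamma_small_pS >= 0, leak_pS >= 0,
            noise_rms_pA > 0,
            open_rate_Hz >= 0, close_rate_Hz > 0)
  if (!is.null(branch_conductances)) {
    stopifnot(all(c("negative", "positive") %in% names(branch_conductances)),
              all(branch_conductances >= 0))
  }
  structure(list(name = name,
                 gamma_large_pS = gamma_large_pS,
                 gamma_small_pS = gamma_small_pS,
                 p_small = p_small,
                 open_rate_Hz = open_rate_Hz,
                 close_rate_Hz = close_rate_Hz,
                 reversal_mV = reversal_mV,
                 leak_pS = leak_pS,
                 noise_rms_pA = noise_rms_pA,
                 branch_conductances = branch_conductances),
            class = "gating_fixture")
}

#' @export
print.gating_fixture <- function(x, ...) {
  cat(sprintf("gating fixture '%s': %g / %g pS (p_small %.2f), leak %g pS, noise %g pA\n",
              x$name, x$gamma_large_pS, x$gamma_small_pS, x$p_small,
              x$leak_pS, x$noise_rms_pA))
  if (!is.null(x$branch_conductances)) {
    cat(sprintf("  ramp branches: %g pS (negative), %g pS (positive)\n",
                x$branch_conductances[["negative"]],
                x$branch_conductances[["positive"]]))
  }
  invisible(x)
}

#' Registry of packaged recording-condition fixtures
#'
#' Returns the named generator truths used throughout the analyses. The
#' single-channel conductance levels are the values measured at -60 mV in
#' outside-out patches:
#' \itemize{
#'   \item `WT-150`: wild type in 150 mM symmetrical Cs+, 251 / 170 pS.
#'   \item `WT-500`: wild type in 500 mM Cs+, 345 / 215 pS.
#'   \item `WT-150-Ba100`: 150 mM Cs+ with 100 uM Ba2+, 161 / 89 pS.
#'   \item `E920A-150`: E920A in 150 mM Cs+, 172 / 99 pS; ramp branches at
#'     54% (negative) and 85% (positive) of wild type, reflecting the loss
#'     of the ion-collecting vestibule charge at negative potentials.
#'   \item `E920A-500`: in 500 mM Cs+ screening makes E920A and wild type
#'     indistinguishable at negative voltages (negative branch 95% of
#'     `WT-500`).
#'   \item `D915E-150`: conserved charge, bulkier side chain; 63% / 62% of
#'     wild type on the negative / positive branches.
#'   \item `D915A-500`: charge neutralized at the constriction; strongly
#'     rectifying, 10% / 50% of `WT-500` on the negative / positive branches.
#' }
#' The block-model truths (see [block_model_params()]) place the wild-type
#' Ba2+ dissociation constant at 0.6 mM at 0 mV with electrical distance 0.5,
#' and scale mutant affinities by the reported fold changes (E920A 3x lower,
#' D915A 10x lower, D915E 3x higher).
#'
#' @param name Fixture name; omit to get the full named list.
#' @return A `gating_fixture` (or list of them) for gating conditions; a
#'   `block_model_params` for names starting with `"Ba-"`.
#' @examples
#' fixture_registry("WT-150")$gamma_large_pS  # 251
#' names(fixture_registry())
#' @export
fixture_registry <- function(name = NULL) {
  wt150 <- gating_fixture("WT-150", 251, 170)
  wt500 <- gating_fixture("WT-500", 345, 215)
  reg <- list(
    "WT-150" = wt150,
    "WT-500" = wt500,
    "WT-150-Ba100" = gating_fixture("WT-150-Ba100", 161, 89),
    "E920A-150" = gating_fixture(
      "E920A-150", 172, 99,
      branch_conductances = c(negative = 0.54 * wt150$gamma_large_pS,
                              positive = 0.85 * wt150$gamma_large_pS)),
    "E920A-500" = gating_fixture(
      "E920A-500", 328, 204,
      branch_conductances = c(negative = 0.95 * wt500$gamma_large_pS,
                              positive = 0.85 * wt500$gamma_large_pS)),
    "D915E-150" = gating_fixture(
      "D915E-150", 158, 107,
      branch_conductances = c(negative = 0.63 * wt150$gamma_large_pS,
                              positive = 0.62 * wt150$gamma_large_pS)),
    "D915A-500" = gating_fixture(
      "D915A-500", 173, 117,
      branch_conductances = c(negative = 0.10 * wt500$gamma_large_pS,
                              positive = 0.50 * wt500$gamma_large_pS)),
    "Ba-WT" = block_model_params(K_out_mM = 0.3, K_through_mM = 0.3,
                                 delta = 0.5, z = 2, hill_n = 0.6),
    "Ba-E920A" = block_model_params(K_out_mM = 0.9, K_through_mM = 0.9,
                                    delta = 0.5, z = 2, hill_n = 0.95),
    "Ba-D915A" = block_model_params(K_out_mM = 3, K_through_mM = 3,
                                    delta = 0.5, z = 2, hill_n = 0.9),
    "Ba-D915E" = block_model_params(K_out_mM = 0.1, K_through_mM = 0.1,
                                    delta = 0.5, z = 2, hill_n = 0.6)
  )
  if (is.null(name)) return(reg)
  if (!name %in% names(reg)) {
    stop(sprintf("unknown fixture '%s'; available: %s",
                 name, paste(names(reg), collapse = ", ")))
  }
  reg[[name]]
}
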