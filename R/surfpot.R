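#' Surface-potential change from a blocker-affinity ratio
#'
#' A fixed charge near a blocker binding site changes the local blocker
#' concentration by a Boltzmann factor, so a charge-neutralizing mutation
#' shifts the apparent dissociation constant. The potential change is
#' recovered from the ratio of dissociation constants:
#' \deqn{\Delta\varphi = (RT/zF)\,\ln(K_{D,mut}/K_{D,wt})}
#' Positive values mean the mutation made the local surface potential less
#' negative (the usual case when an acidic residue is neutralized, which
#' raises the blocker's K_D).
#'
#' @param kd_mut,kd_wt Dissociation constants of mutant and wild type, any
#'   common concentration unit.
#' @param z Blocker valence (nonzero; 2 for Ba2+, 3 for Gd3+, 6 for
#'   ruthenium red).
#' @param constants A [physical_constants()] object.
#' @return Surface-potential change in mV.
#' @examples
#' # three-fold affinity loss for a divalent blocker
#' delta_phi_from_kd_ratio(1.8, 0.6, z = 2)  # ~14.1 mV
#' @export
delta_phi_from_kd_ratio <- function(kd_mut, kd_wt, z,
                                    constants = physical_constants()) {
  stopifnot(kd_mut > 0, kd_wt > 0)
  if (any(z == 0)) stop("blocker valence z must be nonzero")
  (constants$RT_over_F_mV / z) * log(kd_mut / kd_wt)
}

#' Local ion concentration at a site held at potential phi
#'
#' Boltzmann equilibrium between the bulk solution and a site at
#' electrostatic potential `phi`: `[I] = [I]_b exp(-zF phi / RT)`. Negative
#' potentials concentrate cations.
#'
#' @param bulk Bulk concentration (any unit; the same unit is returned).
#' @param phi_mV Local electrostatic potential in mV.
#' @param z Ion valence.
#' @param constants A [physical_constants()] object.
#' @return Local concentration in the unit of `bulk`.
#' @examples
#' boltzmann_concentration(150, -25.7, z = 1)  # ~ e * 150
#' @export
boltzmann_concentration <- function(bulk, phi_mV, z,
                                    constants = physical_constants()) {
  stopifnot(all(bulk >= 0))
  bulk * exp(-z * phi_mV / constants$RT_over_F_mV)
}

#' Surface-potential change from a conductance ratio
#'
#' If single-channel conductance is proportional to the permeant-ion
#' concentration at the mouth of the pore, a conductance ratio between mutant
#' and wild type reports the same Boltzmann factor as a blocker K_D ratio:
#' \deqn{\Delta\varphi = (RT/zF)\,\ln(g_{wt}/g_{mut})}
#'
#' @param g_mut,g_wt Single-channel (branch) conductances in pS.
#' @param z Permeant-ion valence (1 for Cs+).
#' @param constants A [physical_constants()] object.
#' @return Surface-potential change in mV (positive when the mutant
#'   conducts less, i.e. the mutation made the vestibule less attractive
#'   for cations).
#' @examples
#' # mutant negative-branch conductance at 54% of wild type
#' delta_phi_from_conductance_ratio(0.54, 1, z = 1)  # ~15.8 mV
#' @export
delta_phi_from_conductance_ratio <- function(g_mut, g_wt, z,
                                             constants = physical_constants()) {
  stopifnot(g_mut > 0, g_wt > 0)
  if (any(z == 0)) stop("permeant valence z must be nonzero")
  (constants$RT_over_F_mV / z) * log(g_wt / g_mut)
}

#' Debye screening length of an electrolyte
#'
#' \deqn{\kappa^{-1} = \sqrt{\varepsilon\varepsilon_0 RT / (2 F^2 I)}}
#' with the ionic strength I in molar units. Around 150 mM monovalent salt
#' this is ~8 Angstroms, the distance scale over which fixed charges in the
#' outer vestibule are screened.
#'
#' @param ionic_strength_mM Ionic strength in mM (treated as a 1:1 salt).
#' @param constants A [physical_constants()] object.
#' @return Debye length in Angstroms.
#' @examples
#' debye_length(150)  # ~7.9 A
#' @export
debye_length <- function(ionic_strength_mM, constants = physical_constants()) {
  stopifnot(all(ionic_strength_mM > 0))
  I_molar_m3 <- ionic_strength_mM            # mM == mol/m^3
  lambda_m <- sqrt(constants$epsilon * constants$epsilon0 * constants$R *
                     constants$temperature_K /
                     (2 * constants$F^2 * I_molar_m3))
  lambda_m * 1e10
}

#' Charge geometry for screened-Coulomb potential evaluation
#'
#' Describes a set of fixed point charges around an evaluation point in the
#' outer vestibule, either by direct distances or by 3-D positions.
#'
#' @param z Integer valences of the charges (e.g. -1 for a carboxylate).
#' @param r_A Distances from the evaluation point in Angstroms. Supply either
#'   `r_A` or both `positions` and `eval_point`.
#' @param positions Optional n x 3 matrix of charge coordinates (Angstroms).
#' @param eval_point Optional length-3 evaluation point (Angstroms).
#' @param debye_length_A Debye screening length in Angstroms.
#' @param prefactor_mV_A Screened-Coulomb prefactor q/(4 pi eps0 eps) in
#'   mV*Angstrom; 180 for water at room temperature.
#' @param interface_doubling 1 for a charge fully in electrolyte; 2 for a
#'   charge at an electrolyte/low-dielectric interface, where the potential
#'   approximately doubles because water cannot neutralize it on one side.
#' @return An object of class `charge_geometry`.
#' @export
charge_geometry <- function(z, r_A = NULL, positions = NULL, eval_point = NULL,
                            debye_length_A = 8, prefactor_mV_A = 180,
                            interface_doubling = 1) {
  if (is.null(r_A)) {
    stopifnot(!is.null(positions), !is.null(eval_point))
    positions <- as.matrix(positions)
    stopifnot(ncol(positions) == 3, length(eval_point) == 3)
    r_A <- sqrt(rowSums(sweep(positions, 2, eval_point)^2))
  }
  stopifnot(length(z) == length(r_A), debye_length_A > 0, prefactor_mV_A > 0,
            interface_doubling %in% c(1, 2))
  if (any(r_A <= 0)) stop("all charge distances must be > 0")
  structure(list(z = z, r_A = r_A, debye_length_A = debye_length_A,
                 prefactor_mV_A = prefactor_mV_A,
                 interface_doubling = interface_doubling),
            class = "charge_geometry")
}

#' Screened-Coulomb (Debye-Hueckel) potential from fixed charges
#'
#' Linear superposition of screened point-charge potentials at the
#' evaluation point:
#' \deqn{\varphi = d \sum_i z_i \, A \, e^{-r_i/\lambda} / r_i}
#' where A is the prefactor (180 mV*Angstrom in water), lambda the Debye
#' length and d an optional interface-doubling factor.
#'
#' @param geometry A [charge_geometry()] object.
#' @return Potential in mV (signed; negative for acidic side chains).
#' @examples
#' # one carboxylate one Debye length away
#' debye_huckel_potential(charge_geometry(z = -1, r_A = 8))  # ~ -8.3 mV
#' # four ring charges 11 A from the pore axis
#' debye_huckel_potential(charge_geometry(z = rep(-1, 4), r_A = rep(11, 4)))
#' @export
debye_huckel_potential <- function(geometry) {
  stopifnot(inherits(geometry, "charge_geometry"))
  geometry$interface_doubling *
    sum(geometry$z * geometry$prefactor_mV_A *
          exp(-geometry$r_A / geometry$debye_length_A) / geometry$r_A)
}
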