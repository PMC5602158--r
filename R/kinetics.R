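# Local biochemical network of the CCL19/CCL21/CCR7/ACKR4/ECM system:
# right-hand sides for the well-mixed ODEs, and the closed-form steady
# states used both inside the PDE solver (as the local closure for the
# immobile species) and as independent oracles in tests.
#
# Species (volumetric, nM): C19, C21u, C21b, Mfree, R, R19, Rdes, Rint,
# R21u, R21b. Surface species (molecules/um^2): A, A19, A21, Aint.
#
# Reaction wiring: CCL21u binds ECM reversibly (k1/k2) to give CCL21b.
# CCR7 binds all three ligands at lambda_on/lambda_off; only the CCL19
# complex desensitizes (lambda_des), internalizes (lambda_int, where the
# ligand is degraded) and recycles (lambda_up). A matrix site stays
# attributed to its CCL21 molecule while that molecule is receptor-bound,
# so Mfree + C21b + R21b = Mtot. ACKR4 on the ceiling binds CCL19/CCL21u
# competitively (eta_on/eta_off), internalizes bound ligand (eta_in,
# ligand degraded) and resurfaces (eta_up).

LOCAL_SPECIES <- c("C19", "C21u", "C21b", "Mfree", "R", "R19", "Rdes",
                   "Rint", "R21u", "R21b")

#' Kinetic and transport rate constants
#'
#' All binding, trafficking and transport rate constants of the network,
#' with measured literature defaults: matrix binding `k1` = 9.3e-5
#' nM^-1 s^-1, `k2` = 1.2e-4 s^-1; CCR7 `lambda_on` = 1e-3 nM^-1 s^-1,
#' `lambda_off` = 5e-3 s^-1 (Kd 5 nM), desensitization 3e-3 s^-1,
#' internalization 5e-4 s^-1, recycling 3.75e-4 s^-1; ACKR4
#' `eta_on` = 0.5 nM^-1 s^-1, `eta_off` = 2.25 s^-1 (Kd 4.5 nM),
#' internalization 1 s^-1, resurfacing 2e-3 s^-1 (resurfacing-limited
#' scavenging). Effective diffusivities and the vascular permeability are
#' transport-side constants carried alongside.
#'
#' @param k1,k2 ECM on/off rates (nM^-1 s^-1, s^-1).
#' @param lambda_on,lambda_off CCR7 on/off rates.
#' @param lambda_des,lambda_int,lambda_up CCR7 desensitization,
#'   internalization and recycling rates (s^-1).
#' @param eta_on,eta_off,eta_in,eta_up ACKR4 rates.
#' @param D_eff_19,D_eff_21 effective diffusivities (um^2/s).
#' @param P_vasc vascular permeability for chemokine loss to blood (cm/s).
#' @param sv_vessel vessel surface density S/V per porous region (um^-1).
#' @return object of class `ln_kinetics` (a validated list) with derived
#'   dissociation constants `Kd_CCR7` and `Kd_ACKR4`.
#' @export
kinetic_params <- function(k1 = 9.3e-5, k2 = 1.2e-4,
                           lambda_on = 1e-3, lambda_off = 5e-3,
                           lambda_des = 3e-3, lambda_int = 5e-4,
                           lambda_up = 3.75e-4,
                           eta_on = 0.5, eta_off = 2.25,
                           eta_in = 1.0, eta_up = 2e-3,
                           D_eff_19 = 35, D_eff_21 = 12,
                           P_vasc = 5e-7,
                           sv_vessel = c(BFOLLICLE = 0.015,
                                         TCELL_AREA = 0.02,
                                         MEDULLA = 0.03)) {
  p <- list(k1 = k1, k2 = k2, lambda_on = lambda_on, lambda_off = lambda_off,
            lambda_des = lambda_des, lambda_int = lambda_int,
            lambda_up = lambda_up, eta_on = eta_on, eta_off = eta_off,
            eta_in = eta_in, eta_up = eta_up,
            D_eff_19 = D_eff_19, D_eff_21 = D_eff_21,
            P_vasc = P_vasc, sv_vessel = sv_vessel)
  if (any(unlist(p) < 0)) stop("kinetic_params: all rates must be >= 0")
  p$Kd_CCR7  <- lambda_off / lambda_on
  p$Kd_ACKR4 <- eta_off / eta_on
  class(p) <- "ln_kinetics"
  p
}

#' Reaction right-hand side for the local (well-mixed) network
#'
#' Time derivatives of all ten local species under mass-action kinetics,
#' with no transport terms. Conservation is exact by construction:
#' `d/dt (R + R19 + Rdes + Rint + R21u + R21b) = 0` and
#' `d/dt (Mfree + C21b + R21b) = 0`. CCL19 is destroyed at receptor
#' internalization; CCL21 is never destroyed by CCR7.
#'
#' @param state named numeric vector (or list) of the ten species, nM;
#'   vectors are accepted for vectorized evaluation.
#' @param params an `ln_kinetics` object.
#' @return named list of derivatives (nM/s), same shapes as the inputs.
#' @export
local_rhs <- function(state, params) {
  s <- state
  if (any(unlist(s) < 0)) stop("local_rhs: negative concentrations")
  p <- params
  v_on19  <- p$lambda_on * s$C19 * s$R
  v_off19 <- p$lambda_off * s$R19
  v_des   <- p$lambda_des * s$R19
  v_int   <- p$lambda_int * s$Rdes
  v_up    <- p$lambda_up * s$Rint
  v_on21u <- p$lambda_on * s$C21u * s$R
  v_off21u <- p$lambda_off * s$R21u
  v_on21b <- p$lambda_on * s$C21b * s$R
  v_off21b <- p$lambda_off * s$R21b
  v_m_on  <- p$k1 * s$C21u * s$Mfree
  v_m_off <- p$k2 * s$C21b
  list(
    C19  = -v_on19 + v_off19,
    C21u = -v_m_on + v_m_off - v_on21u + v_off21u,
    C21b = v_m_on - v_m_off - v_on21b + v_off21b,
    Mfree = -v_m_on + v_m_off,
    R    = -v_on19 + v_off19 + v_up - v_on21u + v_off21u - v_on21b + v_off21b,
    R19  = v_on19 - v_off19 - v_des,
    Rdes = v_des - v_int,
    Rint = v_int - v_up,
    R21u = v_on21u - v_off21u,
    R21b = v_on21b - v_off21b
  )
}

# Effective per-nM weight of the CCL19 branch in the receptor conservation
# sum at steady state: R19 + Rdes + Rint = alpha19 * C19 * R.
ccr7_alpha19 <- function(p) {
  (p$lambda_on / (p$lambda_off + p$lambda_des)) *
    (1 + p$lambda_des / p$lambda_int + p$lambda_des / p$lambda_up)
}

#' Closed-form CCR7 occupancy at fixed ligand concentrations
#'
#' Steady state of the receptor subsystem under competitive binding of
#' CCL19, free CCL21 and matrix-bound CCL21, with the CCL19-driven
#' desensitization/internalization/recycling cycle. Serves as the
#' well-mixed oracle for the PDE solver and for occupancy summaries.
#'
#' @param C19,C21u,C21b ligand concentrations (nM), vectorized.
#' @param Rtot total CCR7 (nM), vectorized.
#' @param params an `ln_kinetics`.
#' @return named list of receptor-state concentrations (nM): `R`, `R19`,
#'   `Rdes`, `Rint`, `R21u`, `R21b`.
#' @export
ccr7_occupancy_equilibrium <- function(C19, C21u, C21b, Rtot, params) {
  p <- params
  Kd <- p$Kd_CCR7
  a19 <- ccr7_alpha19(p)
  denom <- 1 + a19 * C19 + (C21u + C21b) / Kd
  R <- Rtot / denom
  R19 <- p$lambda_on * C19 * R / (p$lambda_off + p$lambda_des)
  list(R = R, R19 = R19,
       Rdes = (p$lambda_des / p$lambda_int) * R19,
       Rint = (p$lambda_des / p$lambda_up) * R19,
       R21u = C21u * R / Kd,
       R21b = C21b * R / Kd)
}

#' Coupled local steady state of all immobile species
#'
#' Given the mobile concentrations `C19` and `C21u` and the regional totals
#' `Rtot` and `Mtot`, solves the coupled matrix-site / receptor closure:
#' `C21b = (k1/k2) * C21u * Mfree` with `Mfree = Mtot - C21b - R21b` and
#' the receptor occupancy of [ccr7_occupancy_equilibrium()]. The two-field
#' fixed point (in `R` and `C21b`) is contractive and solved by damped
#' iteration, vectorized over cells.
#'
#' @inheritParams ccr7_occupancy_equilibrium
#' @param Mtot total matrix binding sites (nM), vectorized.
#' @param tol relative fixed-point tolerance.
#' @param max_iter iteration cap.
#' @return named list with all immobile species plus `C21b` and `Mfree`.
#' @export
local_equilibrium <- function(C19, C21u, Rtot, Mtot, params,
                              tol = 1e-12, max_iter = 200) {
  p <- params
  KM <- p$k1 / p$k2
  Kd <- p$Kd_CCR7
  a19 <- ccr7_alpha19(p)
  g <- KM * C21u
  C21b <- g * Mtot / (1 + g)      # site-only first guess
  R <- Rtot / (1 + a19 * C19 + (C21u + C21b) / Kd)
  for (it in seq_len(max_iter)) {
    C21b_new <- g * Mtot / (1 + g * (1 + R / Kd))
    R_new <- Rtot / (1 + a19 * C19 + (C21u + C21b_new) / Kd)
    dC <- max(abs(C21b_new - C21b) / pmax(C21b_new, 1e-12),
              abs(R_new - R) / pmax(R_new, 1e-12))
    C21b <- C21b_new; R <- R_new
    if (dC < tol) break
  }
  occ <- ccr7_occupancy_equilibrium(C19, C21u, C21b, Rtot, params)
  occ$C21b <- C21b
  occ$Mfree <- Mtot - C21b - occ$R21b
  occ
}

#' ACKR4 surface scavenging: steady state and consumption fluxes
#'
#' Steady state of the four-state surface receptor model (free, bound to
#' CCL19, bound to CCL21u, internalized) under competitive binding,
#' internalization of bound receptor and resurfacing of internalized
#' receptor. The per-area consumption flux for each ligand is
#' `eta_in * A_bound`. With saturating ligand the total flux tends to the
#' resurfacing-limited ceiling `eta_up * Atot / (1 + eta_up/eta_in)`
#' (~`eta_up * Atot` since resurfacing is much slower than
#' internalization). `Atot = 0` gives zero flux (receptor knockout).
#'
#' @param C19,C21u ligand concentrations at the wall (nM), vectorized.
#' @param Atot total surface receptor (molecules/um^2), vectorized.
#' @param params an `ln_kinetics`.
#' @return named list: `flux19`, `flux21` (molecules/um^2/s), and the
#'   surface state `A`, `A19`, `A21`, `Aint` (molecules/um^2).
#' @export
ackr4_scavenging_flux <- function(C19, C21u, Atot, params) {
  p <- params
  if (any(Atot < 0)) stop("ackr4_scavenging_flux: Atot must be >= 0")
  bind <- p$eta_on / (p$eta_off + p$eta_in)   # bound fraction per nM free A
  b19 <- bind * C19
  b21 <- bind * C21u
  m <- 1 + p$eta_in / p$eta_up                # internalized amplification
  A <- Atot / (1 + (b19 + b21) * m)
  A19 <- b19 * A
  A21 <- b21 * A
  list(flux19 = p$eta_in * A19, flux21 = p$eta_in * A21,
       A = A, A19 = A19, A21 = A21, Aint = (p$eta_in / p$eta_up) * (A19 + A21))
}

# ODE right-hand side of the ACKR4 surface model at fixed ligand
# concentrations (oracle use).
ackr4_rhs <- function(state, C19, C21u, params) {
  p <- params
  v_on19 <- p$eta_on * C19 * state$A
  v_on21 <- p$eta_on * C21u * state$A
  list(A = -v_on19 - v_on21 + p$eta_off * (state$A19 + state$A21) +
         p$eta_up * state$Aint,
       A19 = v_on19 - (p$eta_off + p$eta_in) * state$A19,
       A21 = v_on21 - (p$eta_off + p$eta_in) * state$A21,
       Aint = p$eta_in * (state$A19 + state$A21) - p$eta_up * state$Aint)
}
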