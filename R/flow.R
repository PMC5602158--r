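# Steady lymph flow through the node. The full viscous problem is reduced
# to a single linear pressure equation: every region carries a Darcy
# permeability, with the free-flow channels represented by their
# Poiseuille-equivalent permeabilities (h^2/12 for the thin sinus slot,
# a^2/8 for the vessel lumina). Inertia is dropped (Re << 1), which makes
# the operator linear: rescaling the afferent flow rescales the whole
# velocity field exactly. Transvascular fluid loss follows the Starling
# relation with fixed driving pressures, giving a constant volumetric sink
# per porous region that is also exported to the transport solver as the
# convective clearance.

#' Lymph-flow parameters
#'
#' @param afferent_flow_ul_h afferent lymph flow into the whole node
#'   (uL/h). The default is a frozen calibration chosen so the sinus-floor
#'   wall shear spans the reported >5 dyn/cm^2 (near the afferent vessel)
#'   to <1 dyn/cm^2 (near the medulla) range.
#' @param viscosity_Pa_s lymph dynamic viscosity (Pa s).
#' @param k_parenchyma,k_medulla Darcy permeabilities (um^2) of the
#'   cortical parenchyma (follicles + T-cell area) and the medullary
#'   sinuses.
#' @param starling list of Starling parameters: `LpS_per_V` (1/(Pa s)),
#'   lymph-side and capillary hydrostatic pressures `P_lymph_Pa`,
#'   `P_cap_Pa`, osmotic pressures `pi_lymph_Pa`, `pi_cap_Pa`, reflection
#'   coefficient `sigma`, and `medulla_factor` scaling the exchange-vessel
#'   density in the medulla.
#' @param outlet_pressure_Pa efferent outlet pressure (Pa).
#' @return object of class `ln_flow_params`.
#' @export
flow_params <- function(afferent_flow_ul_h = 10,
                        viscosity_Pa_s = 1.5e-3,
                        k_parenchyma = 0.01, k_medulla = 0.5,
                        starling = list(LpS_per_V = 8.6e-7,
                                        P_lymph_Pa = 600, P_cap_Pa = 2000,
                                        pi_lymph_Pa = 1100, pi_cap_Pa = 3300,
                                        sigma = 0.9, medulla_factor = 2),
                        outlet_pressure_Pa = 0) {
  if (afferent_flow_ul_h < 0) stop("flow_params: afferent flow must be >= 0")
  if (k_parenchyma <= 0 || k_medulla <= 0)
    stop("flow_params: permeabilities must be positive")
  if (starling$sigma < 0 || starling$sigma > 1)
    stop("flow_params: sigma must lie in [0,1]")
  structure(list(afferent_flow_ul_h = afferent_flow_ul_h,
                 viscosity_Pa_s = viscosity_Pa_s,
                 k_parenchyma = k_parenchyma, k_medulla = k_medulla,
                 starling = starling,
                 outlet_pressure_Pa = outlet_pressure_Pa),
            class = "ln_flow_params")
}

# Starling volumetric loss J_v (1/s) per region, from fixed driving
# pressures: J_v = LpS/V * [(P_l - P_c) - sigma*(pi_l - pi_c)], clamped at
# zero (no reverse filtration into lymph under baseline parameters).
starling_jv <- function(fp) {
  s <- fp$starling
  dp <- (s$P_lymph_Pa - s$P_cap_Pa) - s$sigma * (s$pi_lymph_Pa - s$pi_cap_Pa)
  jv <- max(0, s$LpS_per_V * dp)
  c(AFFERENT_VESSEL = 0, SCS = 0, BFOLLICLE = jv, TCELL_AREA = jv,
    MEDULLA = jv * s$medulla_factor, EFFERENT_VESSEL = 0)
}

# region permeabilities (um^2)
region_permeability <- function(mesh, fp) {
  g <- mesh$params
  c(AFFERENT_VESSEL = g$afferent_radius^2 / 8,
    SCS = g$scs_thickness^2 / 12,
    BFOLLICLE = fp$k_parenchyma,
    TCELL_AREA = fp$k_parenchyma,
    MEDULLA = fp$k_medulla,
    EFFERENT_VESSEL = g$efferent_radius^2 / 8)
}

#' Solve the steady lymph-flow field
#'
#' Assembles and solves the finite-volume Darcy pressure equation with a
#' prescribed volumetric inflow at the afferent inlet, fixed pressure at
#' the efferent outlet, no flux through the capsule, vessel walls and
#' symmetry planes, and the Starling fluid sink in the porous regions.
#' Velocities are reconstructed from the conservative face fluxes, so the
#' discrete mass balance (inflow = outflow + total transvascular loss)
#' holds to solver precision.
#'
#' @param mesh an `ln_mesh`.
#' @param params an `ln_flow_params`.
#' @return object of class `ln_flow`: cell pressures (Pa), cell velocity
#'   components in the spherical basis and Cartesian (um/s), signed face
#'   fluxes (um^3/s, owner -> neighbour / outward), per-cell `Jv` (1/s),
#'   and the mass-balance summary.
#' @export
solve_flow <- function(mesh, params = flow_params()) {
  stopifnot(inherits(mesh, "ln_mesh"))
  fp <- params
  n <- mesh$n
  f <- mesh$faces
  mu <- fp$viscosity_Pa_s
  Kreg <- region_permeability(mesh, fp)
  Kc <- Kreg[mesh$cell$region]
  jv_reg <- starling_jv(fp)
  jv <- jv_reg[mesh$cell$region]
  Q_quarter <- ul_per_h_to_um3_per_s(fp$afferent_flow_ul_h) / 4

  int <- f$patch == PATCHES[["INTERIOR"]]
  o <- f$owner[int]; nb <- f$neigh[int]
  # harmonic-mean face permeability
  Kf <- 2 / (1 / Kc[o] + 1 / Kc[nb])
  Tf <- Kf * f$area[int] / (mu * f$dist[int])     # um^3 / (Pa s)

  out_faces <- which(f$patch == PATCHES[["EFFERENT_OUTLET"]])
  ob <- f$owner[out_faces]
  Tb <- Kc[ob] * f$area[out_faces] / (mu * f$dist[out_faces])

  in_faces <- which(f$patch == PATCHES[["AFFERENT_INLET"]])
  A_in <- sum(f$area[in_faces])
  if (A_in <= 0) stop("solve_flow: no afferent inlet faces")
  qin_face <- Q_quarter * f$area[in_faces] / A_in  # um^3/s per face

  A <- Matrix::sparseMatrix(
    i = c(o, nb, o, nb, ob),
    j = c(o, nb, nb, o, ob),
    x = c(Tf, Tf, -Tf, -Tf, Tb),
    dims = c(n, n))
  b <- numeric(n)
  b[f$owner[in_faces]] <- b[f$owner[in_faces]] + qin_face
  b <- b - jv * mesh$cell$vol
  b[ob] <- b[ob] + Tb * fp$outlet_pressure_Pa

  # SPD system: supernodal Cholesky
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE, super = TRUE)
  p <- as.numeric(Matrix::solve(ch, b, system = "A"))

  # conservative face fluxes, positive owner -> neighbour (or outward)
  flux <- numeric(length(f$owner))
  flux[int] <- Tf * (p[o] - p[nb])
  flux[out_faces] <- Tb * (p[ob] - fp$outlet_pressure_Pa)
  flux[in_faces] <- -qin_face                     # inward

  # velocity reconstruction: average of face-flux velocities per axis,
  # signed + outward along +axis direction
  u_ax <- matrix(0, n, 3)
  w_ax <- matrix(0, n, 3)
  uf <- flux / pmax(f$area, 1e-12)
  for (ax in 1:3) {
    sel <- f$axis == ax & f$area > 1e-9
    ow <- f$owner[sel]; ng <- f$neigh[sel]; v <- uf[sel]; ar <- f$area[sel]
    u_ax[, ax] <- u_ax[, ax] +
      as.numeric(tapply_add(ow, v * ar, n)) +
      as.numeric(tapply_add(ng[!is.na(ng)], (v * ar)[!is.na(ng)], n))
    w_ax[, ax] <- w_ax[, ax] +
      as.numeric(tapply_add(ow, ar, n)) +
      as.numeric(tapply_add(ng[!is.na(ng)], ar[!is.na(ng)], n))
  }
  u_ax <- u_ax / pmax(w_ax, 1e-12)

  th <- mesh$cell$th; ph <- mesh$cell$ph
  ur <- u_ax[, 1]; ut <- u_ax[, 2]; up <- u_ax[, 3]
  ux <- ur * sin(th) * cos(ph) + ut * cos(th) * cos(ph) - up * sin(ph)
  uy <- ur * sin(th) * sin(ph) + ut * cos(th) * sin(ph) + up * cos(ph)
  uz <- ur * cos(th) - ut * sin(th)

  Q_out <- sum(flux[out_faces])
  Q_jv <- sum(jv * mesh$cell$vol)
  imbalance <- (Q_quarter - Q_out - Q_jv) / max(Q_quarter, 1e-300)

  structure(list(
    params = fp, pressure = p,
    u_sph = u_ax, u_xyz = cbind(x = ux, y = uy, z = uz),
    speed = sqrt(ur^2 + ut^2 + up^2),
    face_flux = flux, Jv = jv, Q_quarter = Q_quarter,
    mass_balance = list(inflow = Q_quarter, outflow = Q_out,
                        starling_loss = Q_jv, rel_imbalance = imbalance),
    flow_scale = 1
  ), class = "ln_flow")
}

# fast grouped sum (base R)
tapply_add <- function(idx, val, n) {
  out <- numeric(n)
  if (length(idx)) {
    s <- rowsum(val, group = idx, reorder = FALSE)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Rescale a solved flow field
#'
#' The Stokes/Darcy operator is linear, so a change of afferent flow by a
#' factor simply rescales pressures (relative to the outlet), velocities,
#' face fluxes and the Starling sink. Used by the low-flow scenarios.
#'
#' @param flow an `ln_flow`.
#' @param factor multiplicative flow factor (e.g. 0.01).
#' @return rescaled `ln_flow`.
#' @export
scale_flow <- function(flow, factor) {
  stopifnot(inherits(flow, "ln_flow"), factor >= 0)
  p0 <- flow$params$outlet_pressure_Pa
  flow$pressure <- p0 + factor * (flow$pressure - p0)
  flow$u_sph <- flow$u_sph * factor
  flow$u_xyz <- flow$u_xyz * factor
  flow$speed <- flow$speed * factor
  flow$face_flux <- flow$face_flux * factor
  flow$Jv <- flow$Jv * factor
  flow$Q_quarter <- flow$Q_quarter * factor
  flow$mass_balance <- lapply(flow$mass_balance, function(v) v * factor)
  flow$mass_balance$rel_imbalance <- flow$mass_balance$rel_imbalance / max(factor, 1e-300)
  flow$flow_scale <- flow$flow_scale * factor
  flow
}

#' Wall shear stress along the sinus floor
#'
#' The sinus is a thin slot of height h; with the local mean tangential
#' speed U in the slot the plane-Poiseuille closure gives the floor shear
#' `tau = 6 mu U / h` (exact for fully developed channel flow). Returned
#' per floor face in dyn/cm^2, ordered by polar angle (arc length from the
#' afferent pole).
#'
#' @param flow an `ln_flow`.
#' @param mesh the `ln_mesh` the flow was solved on.
#' @return data.frame with `theta` (rad), `arc_um` (arc length along the
#'   floor from the afferent pole), `tau_dyn_cm2`, and `region` of the
#'   parenchyma side.
#' @export
wall_shear <- function(flow, mesh) {
  g <- mesh$params
  f <- mesh$faces
  ff <- mesh$floor_faces
  if (!length(ff)) stop("wall_shear: mesh has no sinus floor faces")
  shell_cells <- f$neigh[ff]             # SCS side (outer)
  # mean tangential speed over the shell column above each floor face
  jj <- mesh$cell$j[shell_cells]; kk <- mesh$cell$k[shell_cells]
  i_shell <- which(mesh$r_c > g$R_floor & mesh$r_c <= g$R_out)
  U <- numeric(length(ff))
  for (m in seq_along(ff)) {
    ids <- mesh$id3[i_shell, jj[m], kk[m]]
    ids <- ids[!is.na(ids)]
    U[m] <- mean(sqrt(flow$u_sph[ids, 2]^2 + flow$u_sph[ids, 3]^2))
  }
  tau_Pa <- 6 * flow$params$viscosity_Pa_s * (U * 1e-6) / (g$scs_thickness * 1e-6)
  th <- mesh$cell$th[shell_cells]
  ord <- order(th)
  data.frame(theta = th[ord], arc_um = g$R_floor * th[ord],
             tau_dyn_cm2 = (tau_Pa * ln_units$pa_to_dyn_cm2)[ord],
             region = names(REGIONS)[mesh$cell$region[f$owner[ff]]][ord])
}

#' Plane-Poiseuille wall shear (closed form)
#'
#' For a channel of height `h_um` carrying mean speed `U_um_s`,
#' `tau = 6 mu U / h`. Used as the sinus closure and as its verification
#' identity.
#'
#' @param mu_Pa_s viscosity, `U_um_s` mean speed (um/s), `h_um` height (um).
#' @param U_um_s,h_um see above.
#' @return shear stress in dyn/cm^2.
#' @export
poiseuille_wall_shear <- function(mu_Pa_s, U_um_s, h_um) {
  6 * mu_Pa_s * (U_um_s * 1e-6) / (h_um * 1e-6) * ln_units$pa_to_dyn_cm2
}

#' @export
print.ln_flow <- function(x, ...) {
  mb <- x$mass_balance
  cat("Lymph flow field (Darcy / lubrication closure)\n")
  cat(sprintf("  afferent inflow (quarter): %.4g um^3/s (scale %.3g)\n",
              x$Q_quarter, x$flow_scale))
  cat(sprintf("  outflow %.4g, Starling loss %.4g um^3/s (%.1f%% of inflow)\n",
              mb$outflow, mb$starling_loss,
              100 * mb$starling_loss / max(mb$inflow, 1e-300)))
  cat(sprintf("  relative mass imbalance: %.3g\n", mb$rel_imbalance))
  invisible(x)
}
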