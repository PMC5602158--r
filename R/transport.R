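# Steady-state coupled chemokine transport. The two mobile species (CCL19
# and free CCL21) satisfy finite-volume advection-diffusion equations with
# first-order upwind advection on the conservative flow fluxes, regional
# production, blood clearance (convective Starling drag + vascular
# permeability), a CCR7-mediated degradation sink for CCL19, and an
# ACKR4 scavenging flux on the capsule ceiling. All immobile species
# (matrix-bound CCL21 and the receptor states) are slaved to the mobile
# fields through the closed-form local equilibrium. The bilinear reaction
# terms are Picard-linearized: each outer iteration freezes the free-CCR7
# field and the ACKR4 mass-transfer coefficients, solves the two sparse
# linear systems, and updates the closures until the fields stop changing.

#' Transport problem definition
#'
#' Bundles everything the steady solver needs. Inlet concentrations are
#' zero by default (clean afferent lymph); the ACKR4 ceiling flux can be
#' disabled (receptor knockout) and the flow field rescaled (low-flow
#' scenarios) without re-solving the flow.
#'
#' @param mesh an `ln_mesh`.
#' @param flow an `ln_flow` solved on `mesh`.
#' @param maps an `ln_fields` from [build_field_maps()].
#' @param params an `ln_kinetics`.
#' @param C_in_19,C_in_21 afferent inlet concentrations (nM).
#' @param ackr4 logical; scavenging at the ceiling active?
#' @param flow_scale multiplicative factor applied to the flow field.
#' @return object of class `ln_problem`.
#' @export
transport_problem <- function(mesh, flow, maps, params = kinetic_params(),
                              C_in_19 = 0, C_in_21 = 0, ackr4 = TRUE,
                              flow_scale = 1) {
  stopifnot(inherits(mesh, "ln_mesh"), inherits(flow, "ln_flow"),
            inherits(maps, "ln_fields"))
  if (length(flow$pressure) != mesh$n)
    stop("transport_problem: flow and mesh sizes differ")
  if (C_in_19 < 0 || C_in_21 < 0)
    stop("transport_problem: inlet concentrations must be >= 0")
  if (flow_scale != 1) flow <- scale_flow(flow, flow_scale)
  structure(list(mesh = mesh, flow = flow, maps = maps, params = params,
                 C_in_19 = C_in_19, C_in_21 = C_in_21, ackr4 = ackr4,
                 flow_scale = flow_scale),
            class = "ln_problem")
}

# Assemble the constant (species-specific) operator pieces. Returns sparse
# matrices/vectors reused across Picard iterations:
#   A_diff  diffusion + inlet-Dirichlet diffusive part
#   A_adv   upwind advection incl. outlet outflow and inlet advective part
#   A_perm  vascular-permeability clearance diagonal
#   b0      production + inlet contributions
assemble_transport <- function(prob, species = c("C19", "C21u")) {
  species <- match.arg(species)
  mesh <- prob$mesh; f <- mesh$faces; n <- mesh$n
  p <- prob$params
  D <- if (species == "C19") p$D_eff_19 else p$D_eff_21
  q <- if (species == "C19") prob$maps$cell$q19 else prob$maps$cell$q21
  C_in <- if (species == "C19") prob$C_in_19 else prob$C_in_21
  flux <- prob$flow$face_flux

  int <- f$patch == PATCHES[["INTERIOR"]]
  o <- f$owner[int]; nb <- f$neigh[int]
  TD <- D * f$area[int] / f$dist[int]
  Fint <- flux[int]
  Fp <- pmax(Fint, 0); Fm <- pmin(Fint, 0)

  in_faces <- which(f$patch == PATCHES[["AFFERENT_INLET"]])
  oin <- f$owner[in_faces]
  TD_in <- D * f$area[in_faces] / f$dist[in_faces]
  F_in <- -flux[in_faces]                     # positive inflow magnitude

  out_faces <- which(f$patch == PATCHES[["EFFERENT_OUTLET"]])
  oout <- f$owner[out_faces]
  F_out <- flux[out_faces]                    # positive outflow

  A_diff <- Matrix::sparseMatrix(
    i = c(o, nb, o, nb, oin),
    j = c(o, nb, nb, o, oin),
    x = c(TD, TD, -TD, -TD, TD_in),
    dims = c(n, n))
  # upwind advection: owner row gets +F+ * C_o + F- * C_n, neighbour row
  # the negatives; outlet faces advect the upwind (owner) value out
  A_adv <- Matrix::sparseMatrix(
    i = c(o, o, nb, nb, oout),
    j = c(o, nb, nb, o, oout),
    x = c(Fp, Fm, -Fm, -Fp, pmax(F_out, 0)),
    dims = c(n, n))

  reg_names <- names(REGIONS)[mesh$cell$region]
  sv <- ifelse(reg_names %in% names(p$sv_vessel), p$sv_vessel[reg_names], 0)
  k_perm <- (p$P_vasc * 1e4) * sv             # cm/s -> um/s, times S/V
  A_perm <- Matrix::Diagonal(n, x = k_perm * mesh$cell$vol)
  # convective (Starling) drag to blood: J_v * C, no solute reflection.
  # This also restores the conservative balance of the upwind operator on a
  # flux field with distributed fluid loss (div u = -J_v).
  A_conv <- Matrix::Diagonal(n, x = prob$flow$Jv * mesh$cell$vol)

  b0 <- q * mesh$cell$vol
  b0 <- b0 + tapply_add(oin, (TD_in + F_in) * C_in, n)

  list(A_diff = A_diff, A_adv = A_adv, A_perm = A_perm, A_conv = A_conv,
       b0 = b0, in_faces = in_faces, out_faces = out_faces, C_in = C_in,
       F_in = F_in, F_out = F_out, TD_in = TD_in)
}

# ceiling face info for the ACKR4 Robin condition
ceiling_faces <- function(mesh) {
  f <- mesh$faces
  which(f$patch %in% PATCHES[c("CAPSULE_CEILING_SCS", "CAPSULE_CEILING_MEDULLA")])
}

#' Solve the steady coupled transport problem
#'
#' Picard (frozen-coefficient) outer iteration over the two mobile-species
#' linear systems. Convergence requires both the relative linear residual
#' and the maximum relative field change to fall below `tol`. The returned
#' state carries every immobile species from the local closure, the ACKR4
#' surface state per ceiling face, and convergence metadata. A transport
#' problem with no sink for a produced species has no steady state; the
#' singular system is detected and reported as an error.
#'
#' @param prob an `ln_problem`.
#' @param tol outer-iteration tolerance (relative).
#' @param max_iter maximum outer iterations.
#' @param quiet suppress the per-iteration residual trace.
#' @return object of class `ln_state`.
#' @export
solve_steady <- function(prob, tol = 1e-8, max_iter = 60, quiet = TRUE) {
  stopifnot(inherits(prob, "ln_problem"))
  mesh <- prob$mesh; n <- mesh$n
  p <- prob$params
  maps <- prob$maps
  f <- mesh$faces

  op19 <- assemble_transport(prob, "C19")
  op21 <- assemble_transport(prob, "C21u")
  ceil <- ceiling_faces(mesh)
  ceil_cells <- f$owner[ceil]
  ceil_area <- f$area[ceil]
  # surface uptake acts in series with diffusion across the half cell
  # between the cell centre and the wall
  ceil_gdiff19 <- p$D_eff_19 / f$dist[ceil]
  ceil_gdiff21 <- p$D_eff_21 / f$dist[ceil]
  in_series <- function(k, g) ifelse(k > 0, 1 / (1 / k + 1 / g), 0)
  Atot <- if (prob$ackr4) maps$Atot else 0

  C19 <- numeric(n); C21u <- numeric(n)
  # initial linearization at zero concentration; wall concentrations are
  # tracked per ceiling face so the surface saturation is evaluated at the
  # wall, not at the cell mean
  eq <- local_equilibrium(C19, C21u, maps$cell$Rtot, maps$cell$Mtot, p)
  kA19 <- kA21 <- rep(ackr4_linear_coeff(0, 0, Atot, p), length(ceil))
  Cw19 <- Cw21 <- numeric(length(ceil))

  # fixed operator parts; the Picard updates only touch diagonal entries,
  # so the LU factorization is reused via defect correction and only
  # refreshed when the diagonal has drifted too far
  base19 <- op19$A_diff + op19$A_adv + op19$A_perm + op19$A_conv
  base21 <- op21$A_diff + op21$A_adv + op21$A_perm + op21$A_conv
  fac19 <- list(lu = NULL, A = NULL)
  fac21 <- list(lu = NULL, A = NULL)

  hist <- numeric(0)
  converged <- FALSE
  y_prev <- NULL; d_prev <- NULL
  dmax <- 1
  for (it in seq_len(max_iter)) {
    # CCL19 consumption coefficient: lambda_on*lambda_des/(lambda_off+lambda_des) * R_free
    k19 <- p$lambda_on * p$lambda_des / (p$lambda_off + p$lambda_des) * eq$R
    A19m <- base19 + Matrix::Diagonal(n, x = k19 * mesh$cell$vol) +
      robin_matrix(n, ceil_cells, in_series(kA19, ceil_gdiff19) * ceil_area)
    A21m <- base21 + robin_matrix(n, ceil_cells,
                                  in_series(kA21, ceil_gdiff21) * ceil_area)

    inner_tol <- max(1e-11, min(1e-4, 1e-3 * dmax))
    s19 <- solve_reuse(A19m, op19$b0, C19, fac19, "CCL19", inner_tol)
    fac19 <- s19$fac; C19_new <- s19$x
    s21 <- solve_reuse(A21m, op21$b0, C21u, fac21, "CCL21u", inner_tol)
    fac21 <- s21$fac; C21_new <- s21$x

    dmax <- max(rel_change(C19_new, C19), rel_change(C21_new, C21u))
    if (min(C19_new, C21_new) < -1e-6 * max(C19_new, C21_new, 1e-12))
      stop("solve_steady: negative concentrations beyond tolerance; refine the mesh")

    # Aitken (one-point secant) acceleration of the linearly convergent
    # Picard map, applied once per three plain steps and clamped to keep
    # fields nonnegative
    y <- c(C19_new, C21_new)
    if (!is.null(y_prev)) {
      d_cur <- y - y_prev
      if (!is.null(d_prev)) {
        denom <- sum(d_prev * d_prev)
        rho <- if (denom > 0) sum(d_cur * d_prev) / denom else 0
        if (is.finite(rho) && rho > 0.05 && rho < 0.95)
          y <- y + (rho / (1 - rho)) * d_cur
        d_prev <- NULL; y_prev <- NULL      # restart the secant history
      } else {
        d_prev <- d_cur
        y_prev <- c(C19_new, C21_new)
      }
    } else {
      y_prev <- c(C19_new, C21_new)
    }
    y[y < 0] <- 0
    C19 <- y[seq_len(n)]; C21u <- y[n + seq_len(n)]

    eq <- local_equilibrium(C19, C21u, maps$cell$Rtot, maps$cell$Mtot, p)
    # update wall concentrations from the series fluxes, then relinearize
    # the surface model at the wall
    f19 <- in_series(kA19, ceil_gdiff19) * C19[ceil_cells]
    f21 <- in_series(kA21, ceil_gdiff21) * C21u[ceil_cells]
    Cw19 <- pmax(0, C19[ceil_cells] - f19 / ceil_gdiff19)
    Cw21 <- pmax(0, C21u[ceil_cells] - f21 / ceil_gdiff21)
    kA19 <- ackr4_linear_coeff(Cw19, Cw21, Atot, p, "flux19")
    kA21 <- ackr4_linear_coeff(Cw19, Cw21, Atot, p, "flux21")

    hist <- c(hist, dmax)
    if (!quiet) message(sprintf("  outer %d: max rel change %.3e", it, dmax))
    if (dmax < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("solve_steady: no convergence after %d iterations (last change %.3g); residual history: %s",
                 max_iter, tail(hist, 1),
                 paste(signif(tail(hist, 5), 3), collapse = ", ")))

  # discrete boundary fluxes (consistent with the assembled Robin terms)
  # and the surface state at the wall concentrations
  f19 <- in_series(kA19, ceil_gdiff19) * C19[ceil_cells]
  f21 <- in_series(kA21, ceil_gdiff21) * C21u[ceil_cells]
  ack <- ackr4_scavenging_flux(Cw19, Cw21, rep(Atot, length(ceil)), p)
  ack$flux19 <- f19 * ln_units$molec_per_um3_per_nM
  ack$flux21 <- f21 * ln_units$molec_per_um3_per_nM
  structure(list(
    problem = prob,
    C19 = C19, C21u = C21u, C21b = eq$C21b, Mfree = eq$Mfree,
    R = eq$R, R19 = eq$R19, Rdes = eq$Rdes, Rint = eq$Rint,
    R21u = eq$R21u, R21b = eq$R21b,
    ackr4 = c(list(face = ceil, cell = ceil_cells, area = ceil_area), ack),
    iterations = length(hist), residuals = hist,
    operators = list(C19 = op19, C21u = op21)
  ), class = "ln_state")
}

# effective linear mass-transfer coefficient (um/s) of the ACKR4 flux at
# the current wall concentration: flux = k * C, with the zero-concentration
# limit used where C ~ 0
ackr4_linear_coeff <- function(C19, C21u, Atot, p,
                               which = c("flux19", "flux21")) {
  which <- match.arg(which)
  if (all(Atot == 0)) return(rep(0, max(length(C19), 1)))
  fl <- ackr4_scavenging_flux(C19, C21u, Atot, p)
  C <- if (which == "flux19") C19 else C21u
  k0 <- p$eta_in * p$eta_on / (p$eta_off + p$eta_in) * Atot /
    ln_units$molec_per_um3_per_nM  # limit slope, molecules-flux per nM -> um/s
  k <- ifelse(C > 1e-12, molec_flux_to_nM_um(fl[[which]]) / C, k0)
  # guard against the other ligand's competition at C ~ 0
  comp <- 1 + p$eta_on / (p$eta_off + p$eta_in) *
    (1 + p$eta_in / p$eta_up) * (C19 + C21u)
  ifelse(C > 1e-12, k, k0 / comp)
}

robin_matrix <- function(n, cells, coeff) {
  if (!length(cells)) return(Matrix::Diagonal(n, x = 0))
  Matrix::sparseMatrix(i = cells, j = cells, x = coeff, dims = c(n, n))
}

solve_sparse_checked <- function(A, b, label) {
  x <- tryCatch(as.numeric(Matrix::solve(A, b)),
                error = function(e)
                  stop("solve_steady: singular steady problem for ", label,
                       " (produced species with no sink has no steady state): ",
                       conditionMessage(e)))
  if (any(!is.finite(x)))
    stop("solve_steady: non-finite solution for ", label,
         " (no sink balances production; no steady state exists)")
  x
}

# Solve A x = b reusing a previous LU of a nearby matrix (same sparsity,
# diagonal drift only) by defect correction; refactorizes when the
# correction stalls.
solve_reuse <- function(A, b, x0, fac, label, inner_tol = 1e-12,
                        max_inner = 15) {
  if (is.null(fac$lu)) {
    lu <- tryCatch(Matrix::lu(A), error = function(e)
      stop("solve_steady: singular steady problem for ", label,
           " (produced species with no sink has no steady state): ",
           conditionMessage(e)))
    x <- as.numeric(Matrix::solve(lu, b))
    if (any(!is.finite(x)))
      stop("solve_steady: non-finite solution for ", label,
           " (no sink balances production; no steady state exists)")
    return(list(x = x, fac = list(lu = lu, A = A)))
  }
  x <- x0
  bn <- max(abs(b), 1e-300)
  relres <- Inf
  for (m in seq_len(max_inner)) {
    r <- b - as.numeric(A %*% x)
    relres <- max(abs(r)) / bn
    if (relres < inner_tol) return(list(x = x, fac = fac))
    dx <- as.numeric(Matrix::solve(fac$lu, r))
    if (any(!is.finite(dx))) break
    x <- x + dx
    # increment at the rounding floor: the correction is converged
    if (max(abs(dx)) < 1e-13 * max(abs(x), 1e-300))
      return(list(x = x, fac = fac))
  }
  if (is.finite(relres) && relres < max(1e-7, 100 * inner_tol))
    return(list(x = x, fac = fac))
  # stalled: refresh the factorization
  refac <- getOption("lnchemosim.refac_count", NULL)
  if (!is.null(refac)) options(lnchemosim.refac_count = refac + 1L)
  solve_reuse(A, b, x0, list(lu = NULL, A = NULL), label,
              inner_tol, max_inner)
}

rel_change <- function(a, b) {
  sc <- max(abs(a), 1e-12)
  max(abs(a - b)) / sc
}

#' Per-species steady-state mass ledger
#'
#' Integrates every production and removal pathway from the assembled
#' discrete operators, so the ledger closes to solver precision by
#' construction: production + afferent import = CCR7 degradation (CCL19
#' only; exactly zero for CCL21) + blood clearance (convective + vascular
#' permeability) + ACKR4 scavenging + efferent export. All entries in
#' nmol/s equivalents (nM um^3/s), whole quarter.
#'
#' @param state an `ln_state` from [solve_steady()].
#' @return data.frame, one row per chemokine (total CCL19; total CCL21
#'   counting CCL21u transport), with columns for each pathway and the
#'   relative closure error.
#' @export
mass_balance_report <- function(state) {
  prob <- state$problem
  mesh <- prob$mesh
  p <- prob$params
  ledger_for <- function(species) {
    op <- state$operators[[species]]
    C <- state[[species]]
    production <- sum(op$b0) -
      sum((op$TD_in + op$F_in) * op$C_in)          # q only
    import <- sum((op$TD_in + op$F_in) * op$C_in) -
      sum(op$TD_in * C[mesh$faces$owner[op$in_faces]])
    export <- sum(op$F_out * C[mesh$faces$owner[op$out_faces]])
    perm <- sum(as.numeric(op$A_perm %*% C))
    convective <- sum(as.numeric(op$A_conv %*% C))
    ack <- state$ackr4
    if (species == "C19") {
      ccr7 <- sum(p$lambda_des * state$R19 * mesh$cell$vol)
      scav <- sum(molec_flux_to_nM_um(ack$flux19) * ack$area)
    } else {
      ccr7 <- 0
      scav <- sum(molec_flux_to_nM_um(ack$flux21) * ack$area)
    }
    sinks <- ccr7 + perm + convective + scav + export
    data.frame(species = if (species == "C19") "CCL19" else "CCL21",
               production = production, import = import,
               ccr7_degradation = ccr7, blood_convective = convective,
               blood_permeability = perm, ackr4_scavenging = scav,
               efferent_export = export,
               closure_rel = (production + import - sinks) /
                 max(production + import, 1e-300))
  }
  rbind(ledger_for("C19"), ledger_for("C21u"))
}

#' @export
print.ln_state <- function(x, ...) {
  cat("Steady chemokine state\n")
  cat(sprintf("  outer iterations: %d (final change %.3g)\n",
              x$iterations, tail(x$residuals, 1)))
  cat(sprintf("  max CCL19 %.4g nM, CCL21u %.4g nM, CCL21b %.4g nM\n",
              max(x$C19), max(x$C21u), max(x$C21b)))
  invisible(x)
}
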