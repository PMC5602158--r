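# Probe-line profile extraction and gradient analysis: concentration
# profiles along the radial probe arrows, zero-phase low-pass filtering,
# central-difference gradients, across-cell concentration differences for
# 9/18/36 um cells, and the scalar gradient/content summaries used by the
# scenario comparisons and the sensitivity analysis.

PROFILE_SPECIES <- c("C19", "C21u", "C21b")

# trilinear interpolation of a cell field at spherical points.
# Fields are cell-centred on the structured (r, theta, phi) grid; outside
# the centred hull the nearest-cell value is used (constant extrapolation
# over the half-cell skin).
interp_field <- function(mesh, field, r, th, ph) {
  ax_interp <- function(centers, xq) {
    nctr <- length(centers)
    i0 <- findInterval(xq, centers, all.inside = TRUE)
    w <- (xq - centers[i0]) / (centers[pmin(i0 + 1, nctr)] - centers[i0])
    w[!is.finite(w)] <- 0
    w <- pmin(pmax(w, 0), 1)
    list(i0 = i0, w = w)
  }
  # restrict to the in-capsule radial range (stub cells are vessel lumen)
  ri <- ax_interp(mesh$r_c[seq_len(mesh$i_Rout)], r)
  ti <- ax_interp(mesh$th_c, th)
  pi_ <- ax_interp(mesh$ph_c, ph)
  val <- numeric(length(r))
  # gather the 8 corners; missing (inactive) corners fall back to the cell
  # on the other side of the same axis
  get3 <- function(i, j, k) {
    id <- mesh$id3[cbind(i, j, k)]
    field[ifelse(is.na(id), NA, id)]
  }
  acc <- numeric(length(r)); wacc <- numeric(length(r))
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    i <- pmin(ri$i0 + di, mesh$i_Rout)
    j <- pmin(ti$i0 + dj, mesh$dims[["nth"]])
    k <- pmin(pi_$i0 + dk, mesh$dims[["nph"]])
    v <- get3(i, j, k)
    w <- (if (di == 1) ri$w else 1 - ri$w) *
         (if (dj == 1) ti$w else 1 - ti$w) *
         (if (dk == 1) pi_$w else 1 - pi_$w)
    ok <- !is.na(v)
    acc[ok] <- acc[ok] + (w * v)[ok]
    wacc[ok] <- wacc[ok] + w[ok]
  }
  ifelse(wacc > 0, acc / pmax(wacc, 1e-300), NA_real_)
}

# zero-phase symmetric moving average; window must be odd. Ends use a
# shrinking symmetric window, so constants are preserved exactly.
lowpass_ma <- function(x, window = 5) {
  if (window %% 2 != 1) stop("lowpass_ma: window must be odd")
  half <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1, n - i)
    mean(x[(i - h):(i + h)])
  }, 0)
}

#' Sample a concentration profile along a probe line
#'
#' Interpolates the cell-centred fields at `spacing` resolution along the
#' radial probe, applies the zero-phase moving-average low-pass filter
#' (window given in samples; the 5-point default spans +-9 um), and
#' computes the central-difference gradient of the filtered series.
#' Positions are arc length from the capsule ceiling, increasing inward.
#'
#' @param state an `ln_state` (or a named list of per-cell fields).
#' @param line an `ln_probe` from [probe_lines()].
#' @param species which fields to sample (default CCL19, CCL21u, CCL21b).
#' @param window low-pass window in samples (odd; default 5).
#' @param mesh required if `state` is a bare field list.
#' @return object of class `ln_profile`: data.frame with `s_um`, raw,
#'   filtered and gradient columns per species, plus probe metadata.
#' @export
sample_profile <- function(state, line, species = PROFILE_SPECIES,
                           window = 5, mesh = NULL) {
  if (inherits(state, "ln_state")) mesh <- state$problem$mesh
  if (is.null(mesh)) stop("sample_profile: mesh required")
  s <- seq(0, line$length, by = line$spacing)
  r <- line$r_start - s
  keep <- r >= 0
  if (!all(keep)) {
    warning("sample_profile: probe exits the mesh; truncating")
    s <- s[keep]; r <- r[keep]
  }
  out <- data.frame(s_um = s)
  for (sp in species) {
    v <- interp_field(mesh, state[[sp]], r, rep(line$theta, length(r)),
                      rep(line$phi, length(r)))
    filt <- lowpass_ma(v, window)
    grad <- central_gradient(filt, line$spacing)
    out[[sp]] <- v
    out[[paste0(sp, "_filt")]] <- filt
    out[[paste0(sp, "_grad")]] <- grad
  }
  structure(list(data = out, probe = line, window = window,
                 species = species), class = "ln_profile")
}

# central differences; one-sided at the ends
central_gradient <- function(x, h) {
  n <- length(x)
  if (n < 2) return(rep(NA_real_, n))
  g <- numeric(n)
  g[1] <- (x[2] - x[1]) / h
  g[n] <- (x[n] - x[n - 1]) / h
  if (n > 2) g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * h)
  g
}

#' Concentration differences across a cell
#'
#' For a cell of the given diameter with its leading edge pointing inward
#' (away from the sinus), the difference is `C(x + d) - C(x)` on the
#' filtered profile, and the percentage difference normalizes by the
#' trailing-edge concentration `C(x)`. The diameter must be a multiple of
#' the sample spacing (9, 18 and 36 um all are at the 4.5 um default).
#'
#' @param profile an `ln_profile`.
#' @param diameter_um cell diameter (um).
#' @param species which species column to difference.
#' @return data.frame with `s_um`, `delta_nM` and `pct` (NA where the
#'   trailing-edge concentration is zero); empty if the diameter exceeds
#'   the profile length.
#' @export
cell_differences <- function(profile, diameter_um, species = "C21b") {
  stopifnot(inherits(profile, "ln_profile"))
  h <- profile$probe$spacing
  steps <- diameter_um / h
  if (abs(steps - round(steps)) > 1e-9)
    stop("cell_differences: diameter must be a multiple of the spacing")
  steps <- as.integer(round(steps))
  x <- profile$data[[paste0(species, "_filt")]]
  n <- length(x)
  if (steps >= n)
    return(data.frame(s_um = numeric(0), delta_nM = numeric(0), pct = numeric(0)))
  i <- seq_len(n - steps)
  delta <- x[i + steps] - x[i]
  pct <- ifelse(x[i] > 0, 100 * delta / x[i], NA_real_)
  data.frame(s_um = profile$data$s_um[i], delta_nM = delta, pct = pct)
}

# least-squares slope of y over a window of s centred at s0 with half-width
# hw; NA when fewer than 3 samples fall in the window
window_slope <- function(s, y, s0, hw) {
  sel <- s >= s0 - hw & s <= s0 + hw & is.finite(y)
  if (sum(sel) < 3) return(NA_real_)
  fit <- stats::lm.fit(cbind(1, s[sel]), y[sel])
  unname(fit$coefficients[2])
}

#' Scalar gradient and content summaries
#'
#' Computes the headline outputs used for scenario comparison and
#' sensitivity analysis: per species, the peak gradient magnitude in the
#' interfollicular region within `ifr_window_um` below the sinus floor
#' (IFR probe); the least-squares slope over a 25 um window straddling the
#' follicle/T-zone border, and the peak gradient magnitude near that
#' border (BFTC probe); the total whole-node content (volume integral, in
#' fmol); and the flow-weighted efferent outlet concentration (nM).
#'
#' @param state an `ln_state`.
#' @param lines probe lines from [probe_lines()] (defaults to the mesh's).
#' @param ifr_window_um window below the sinus floor for the IFR slope.
#' @param border_window_um full width of the border slope window.
#' @param window low-pass filter window (samples).
#' @return named list of scalars; see Details in the vignette.
#' @export
summary_gradients <- function(state, lines = NULL, ifr_window_um = 20,
                              border_window_um = 25, window = 5) {
  stopifnot(inherits(state, "ln_state"))
  mesh <- state$problem$mesh
  if (is.null(lines)) lines <- probe_lines(mesh)
  out <- list()

  ifr <- sample_profile(state, lines$IFR_ARROW, window = window)
  d <- ifr$data
  floor_s <- lines$IFR_ARROW$scs_floor_s
  sel <- d$s_um >= floor_s & d$s_um <= floor_s + ifr_window_um
  # slopes are signed: positive means concentration increasing inward
  # (away from the sinus); the reported value is the extremal gradient
  signed_peak <- function(g) {
    g <- g[is.finite(g)]
    if (!length(g)) return(NA_real_)
    g[which.max(abs(g))]
  }
  for (sp in PROFILE_SPECIES)
    out[[paste0("ifr_slope_", sp)]] <- signed_peak(d[[paste0(sp, "_grad")]][sel])

  if (!is.null(lines$BFTC_ARROW)) {
    bftc <- sample_profile(state, lines$BFTC_ARROW, window = window)
    db <- bftc$data
    border_s <- lines$BFTC_ARROW$border_s
    for (sp in PROFILE_SPECIES) {
      out[[paste0("bftc_slope_", sp)]] <-
        window_slope(db$s_um, db[[paste0(sp, "_filt")]],
                     border_s, border_window_um / 2)
      near <- abs(db$s_um - border_s) <= border_window_um
      out[[paste0("bftc_peak_grad_", sp)]] <-
        signed_peak(db[[paste0(sp, "_grad")]][near])
    }
  }

  vol <- mesh$cell$vol
  to_fmol <- function(C) sum(C * vol) * 4 / ln_units$um3_per_L * 1e-9 * 1e15
  # extracellular pools only: total CCL21 = unbound + matrix-bound
  out$total_CCL19_fmol <- to_fmol(state$C19)
  out$total_CCL21u_fmol <- to_fmol(state$C21u)
  out$total_CCL21b_fmol <- to_fmol(state$C21b)
  out$total_CCL21_fmol <- out$total_CCL21u_fmol + out$total_CCL21b_fmol

  op <- state$operators
  eff_conc <- function(species) {
    o <- op[[species]]
    Fw <- o$F_out
    if (sum(Fw) <= 0) return(0)
    Co <- state[[species]][mesh$faces$owner[o$out_faces]]
    sum(Fw * Co) / sum(Fw)
  }
  out$efferent_CCL19_nM <- eff_conc("C19")
  out$efferent_CCL21_nM <- eff_conc("C21u")
  out
}

#' Receptor-occupancy summaries near the follicle border and T-zone core
#'
#' Peak concentrations of the CCL21u-CCR7 and CCL19-CCR7 complexes on the
#' follicle side of the follicle/T-zone border (sampled along the BFTC
#' probe), and the percentage of T-zone-core CCR7 not occupied by
#' matrix-bound CCL21 (hence available to free CCL21 or CCL19), with its
#' equilibrium cross-check `Kd/(Kd + C21b)`.
#'
#' @param state an `ln_state`.
#' @param lines probe lines (defaults to the mesh's).
#' @param core_r_um radius of the "core" T-zone sphere.
#' @return named list: `R21u_peak_BF`, `R19_peak_BF` (nM),
#'   `pct_ccr7_available_TC`, `pct_free_ccr7_equilibrium`.
#' @export
receptor_summaries <- function(state, lines = NULL, core_r_um = 250) {
  stopifnot(inherits(state, "ln_state"))
  mesh <- state$problem$mesh
  if (is.null(lines)) lines <- probe_lines(mesh)
  out <- list(R21u_peak_BF = NA_real_, R19_peak_BF = NA_real_)
  if (!is.null(lines$BFTC_ARROW)) {
    bf <- lines$BFTC_ARROW
    s <- seq(0, bf$length, by = bf$spacing)
    r <- bf$r_start - s
    th <- rep(bf$theta, length(s)); ph <- rep(bf$phi, length(s))
    fol <- s <= bf$border_s + bf$spacing
    out$R21u_peak_BF <- max(interp_field(mesh, state$R21u, r, th, ph)[fol],
                            na.rm = TRUE)
    out$R19_peak_BF <- max(interp_field(mesh, state$R19, r, th, ph)[fol],
                           na.rm = TRUE)
  }
  tc <- mesh$cell$region == REGIONS[["TCELL_AREA"]] & mesh$cell$r < core_r_um
  Rtot <- state$problem$maps$cell$Rtot[tc]
  out$pct_ccr7_available_TC <- mean(100 * (Rtot - state$R21b[tc]) / Rtot)
  Kd <- state$problem$params$Kd_CCR7
  out$pct_free_ccr7_equilibrium <- mean(100 * Kd / (Kd + state$C21b[tc]))
  out
}

#' @export
print.ln_profile <- function(x, ...) {
  cat(sprintf("profile along %s: %d samples at %g um\n",
              x$probe$name, nrow(x$data), x$probe$spacing))
  invisible(x)
}
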