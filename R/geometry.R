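# Idealized quarter-symmetric popliteal lymph node geometry on a structured
# spherical-coordinate grid (r, theta, phi). The polar axis carries the
# afferent (theta = 0) and efferent (theta = pi) vessels; the quarter is
# phi in [0, pi/2] with symmetry planes at phi = 0 (y = 0) and phi = pi/2
# (x = 0). The subcapsular sinus (SCS) is the shell R_floor < r <= R_out,
# resolved by two grid layers so the sinus channel is always conforming.

#' Region identifiers
#'
#' Integer codes for the anatomical regions carried by every mesh cell.
#' @export
REGIONS <- c(AFFERENT_VESSEL = 1L, SCS = 2L, BFOLLICLE = 3L,
             TCELL_AREA = 4L, MEDULLA = 5L, EFFERENT_VESSEL = 6L)

#' Boundary patch identifiers
#'
#' Integer codes for named boundary face sets. Code 0 marks interior faces.
#' @export
PATCHES <- c(INTERIOR = 0L, AFFERENT_INLET = 1L, EFFERENT_OUTLET = 2L,
             CAPSULE_CEILING_SCS = 3L, CAPSULE_CEILING_MEDULLA = 4L,
             SYMMETRY_Y = 5L, SYMMETRY_X = 6L, VESSEL_WALL = 7L)

#' Geometry parameters for the idealized lymph node
#'
#' Constructs and validates the geometric description of the quarter node.
#' All lengths are in micrometres. Defaults describe a ~1 mm diameter node
#' with a 10 um subcapsular sinus and the B-follicle/T-cell-area border at
#' 188 um below the sinus floor. Follicles are spherical caps abutting the
#' sinus floor; their radius is half the border depth so that a radial probe
#' through a follicle centre crosses the border exactly at the stated depth.
#'
#' @param node_diameter outer capsule diameter (um).
#' @param scs_thickness sinus height between capsule ceiling and floor (um).
#' @param bf_tc_border_depth depth of the follicle/T-zone border below the
#'   sinus floor along a radial line through a follicle centre (um).
#' @param n_follicles_per_quarter number of follicles in the quarter.
#' @param follicle_polar_deg polar angle of follicle centres (degrees from
#'   the afferent pole).
#' @param follicle_azimuth_deg azimuths of follicle centres (degrees);
#'   default spreads them evenly so an interfollicular gap straddles 45 deg.
#' @param afferent_radius,efferent_radius vessel radii (um).
#' @param vessel_length length of the vessel stubs outside the capsule (um).
#' @param medulla_depth the medulla occupies z < -medulla_depth (um).
#' @return object of class `ln_geometry`.
#' @export
geometry_params <- function(node_diameter = 1000, scs_thickness = 10,
                            bf_tc_border_depth = 188,
                            n_follicles_per_quarter = 2,
                            follicle_polar_deg = 50,
                            follicle_azimuth_deg = NULL,
                            afferent_radius = 25, efferent_radius = 35,
                            vessel_length = 20, medulla_depth = 250) {
  if (node_diameter <= 0) stop("geometry: node_diameter must be positive")
  if (scs_thickness <= 0 || scs_thickness >= node_diameter / 10)
    stop("geometry: scs_thickness must lie in (0, node_diameter/10)")
  if (bf_tc_border_depth <= 0 || bf_tc_border_depth >= node_diameter / 2)
    stop("geometry: bf_tc_border_depth must lie in (0, node_diameter/2)")
  n_f <- as.integer(n_follicles_per_quarter)
  if (n_f < 0) stop("geometry: n_follicles_per_quarter must be >= 0")
  if (is.null(follicle_azimuth_deg) && n_f > 0)
    follicle_azimuth_deg <- (90 / (2 * n_f)) * (2 * seq_len(n_f) - 1)
  if (n_f > 0 && length(follicle_azimuth_deg) != n_f)
    stop("geometry: need one azimuth per follicle")

  R_out   <- node_diameter / 2
  R_floor <- R_out - scs_thickness
  rho_f   <- bf_tc_border_depth / 2           # follicle ball radius
  c_f     <- R_floor - rho_f                  # follicle centre radius
  th_f    <- follicle_polar_deg * pi / 180
  th_af   <- asin(afferent_radius / R_out)
  th_ef   <- asin(efferent_radius / R_out)

  if (n_f > 0) {
    half_ang <- asin(min(1, rho_f / c_f))
    if (th_f - half_ang <= 2.5 * th_af)
      stop("geometry: follicles overlap the afferent vessel cone")
    if (pi - th_f - half_ang <= 2.5 * th_ef)
      stop("geometry: follicles overlap the efferent vessel cone")
    if (c_f * cos(th_f) - rho_f <= -medulla_depth)
      stop("geometry: follicles intrude into the medulla")
  }
  if (medulla_depth >= R_floor)
    stop("geometry: medulla_depth exceeds the parenchyma radius")

  structure(list(
    node_diameter = node_diameter, scs_thickness = scs_thickness,
    bf_tc_border_depth = bf_tc_border_depth,
    n_follicles_per_quarter = n_f,
    follicle_polar_deg = follicle_polar_deg,
    follicle_azimuth_deg = follicle_azimuth_deg,
    afferent_radius = afferent_radius, efferent_radius = efferent_radius,
    vessel_length = vessel_length, medulla_depth = medulla_depth,
    R_out = R_out, R_floor = R_floor, r_border = R_floor - bf_tc_border_depth,
    rho_follicle = rho_f, c_follicle = c_f,
    theta_af = th_af, theta_ef = th_ef
  ), class = "ln_geometry")
}

# follicle centres in Cartesian coordinates (um)
follicle_centers <- function(geom) {
  if (geom$n_follicles_per_quarter == 0)
    return(matrix(numeric(0), ncol = 3))
  th <- geom$follicle_polar_deg * pi / 180
  ph <- geom$follicle_azimuth_deg * pi / 180
  cbind(x = geom$c_follicle * sin(th) * cos(ph),
        y = geom$c_follicle * sin(th) * sin(ph),
        z = geom$c_follicle * cos(th) + 0 * ph)
}

#' Build the quarter-node finite-volume mesh
#'
#' Discretizes the quarter node on a structured spherical grid, tags every
#' cell with a region, and classifies boundary faces into named patches.
#' The radial grid is graded: coarse in the deep paracortex, fine through
#' the cortex so the follicle border is well resolved, and exactly two
#' layers across the sinus. The polar grid is refined around both vessel
#' cones so the vessel openings align with grid faces.
#'
#' @param params an `ln_geometry` object from [geometry_params()].
#' @param resolution target cells per 100 um (>= 2); controls all grid
#'   spacings jointly.
#' @return an object of class `ln_mesh` with cell arrays (centroids,
#'   volumes, region tags), a face table (owner/neighbour, area, centroid
#'   distance, patch), and precomputed region volumes.
#' @export
build_mesh <- function(params = geometry_params(), resolution = 6) {
  stopifnot(inherits(params, "ln_geometry"))
  if (resolution < 2) stop("build_mesh: resolution must be >= 2")
  g <- params
  h <- 100 / resolution
  R_out <- g$R_out; R_floor <- g$R_floor; r_border <- g$r_border
  stub_out <- R_out + g$vessel_length

  ## --- 1-D grids -----------------------------------------------------
  n_core <- max(4L, ceiling(r_border / (1.8 * h)))
  n_ctx  <- max(6L, ceiling((R_floor - r_border) / (0.8 * h)))
  r_breaks <- c(seq(0, r_border, length.out = n_core + 1),
                seq(r_border, R_floor, length.out = n_ctx + 1)[-1],
                seq(R_floor, R_out, length.out = 3)[-1],
                seq(R_out, stub_out, length.out = 5)[-1])
  i_Rout <- n_core + n_ctx + 2L                # last r index inside capsule
  nr <- length(r_breaks) - 1L

  th_af <- g$theta_af; th_ef <- g$theta_ef
  mid_lo <- 2.5 * th_af; mid_hi <- pi - 2.5 * th_ef
  n_mid <- max(8L, ceiling((mid_hi - mid_lo) / (1.4 * h / R_out)))
  th_breaks <- c(c(0, 0.5, 1, 1.7) * th_af,
                 seq(mid_lo, mid_hi, length.out = n_mid + 1),
                 pi - c(1.7, 1, 0.5, 0) * th_ef)
  nth <- length(th_breaks) - 1L

  nph <- max(4L, 4L * ceiling((pi / 2) * R_out / (1.8 * h) / 4))
  ph_breaks <- seq(0, pi / 2, length.out = nph + 1)

  r_c  <- (head(r_breaks, -1) + tail(r_breaks, -1)) / 2
  th_c <- (head(th_breaks, -1) + tail(th_breaks, -1)) / 2
  ph_c <- (head(ph_breaks, -1) + tail(ph_breaks, -1)) / 2

  ## --- active cells ---------------------------------------------------
  # full grid indices
  idx <- expand.grid(i = seq_len(nr), j = seq_len(nth), k = seq_len(nph))
  ri <- r_c[idx$i]; thj <- th_c[idx$j]; phk <- ph_c[idx$k]
  in_af_cone <- thj < th_af
  in_ef_cone <- thj > pi - th_ef
  active <- idx$i <= i_Rout | in_af_cone | in_ef_cone
  idx <- idx[active, ]
  ri <- ri[active]; thj <- thj[active]; phk <- phk[active]
  n <- nrow(idx)
  id3 <- array(NA_integer_, dim = c(nr, nth, nph))
  id3[cbind(idx$i, idx$j, idx$k)] <- seq_len(n)

  x <- ri * sin(thj) * cos(phk)
  y <- ri * sin(thj) * sin(phk)
  z <- ri * cos(thj)

  ## --- region tags ----------------------------------------------------
  # the sinus shell ends where the medulla begins: over the medulla the
  # capsule is backed by medullary sinuses, not the thin SCS slot
  th_med <- acos(-g$medulla_depth / R_floor)
  region <- integer(n)
  shell   <- ri > R_floor & ri <= R_out
  stub    <- ri > R_out
  in_af   <- thj < th_af
  in_ef   <- thj > pi - th_ef
  region[shell | stub] <- REGIONS[["SCS"]]
  region[shell & thj > th_med] <- REGIONS[["MEDULLA"]]
  region[(shell | stub) & in_af] <- REGIONS[["AFFERENT_VESSEL"]]
  region[(shell | stub) & in_ef] <- REGIONS[["EFFERENT_VESSEL"]]
  paren <- ri <= R_floor
  region[paren] <- REGIONS[["TCELL_AREA"]]
  region[paren & z < -g$medulla_depth] <- REGIONS[["MEDULLA"]]
  fc <- follicle_centers(g)
  if (nrow(fc) > 0) {
    for (m in seq_len(nrow(fc))) {
      d2 <- (x - fc[m, 1])^2 + (y - fc[m, 2])^2 + (z - fc[m, 3])^2
      region[paren & d2 <= g$rho_follicle^2] <- REGIONS[["BFOLLICLE"]]
    }
  }

  ## --- volumes --------------------------------------------------------
  dr3 <- (tail(r_breaks, -1)^3 - head(r_breaks, -1)^3) / 3
  dcs <- cos(head(th_breaks, -1)) - cos(tail(th_breaks, -1))
  dph <- diff(ph_breaks)
  vol <- dr3[idx$i] * dcs[idx$j] * dph[idx$k]

  ## --- faces ----------------------------------------------------------
  fo <- integer(0); fn <- integer(0); fax <- integer(0)
  far <- numeric(0); fd <- numeric(0); fp <- integer(0)

  add_faces <- function(o, nb, ax, area, d, patch) {
    m <- length(o)
    fo  <<- c(fo, o);  fn <<- c(fn, nb); fax <<- c(fax, rep_len(ax, m))
    far <<- c(far, area); fd <<- c(fd, d); fp <<- c(fp, rep_len(patch, m))
  }

  ii <- idx$i; jj <- idx$j; kk <- idx$k
  # radial faces (axis 1): between (i) and (i+1)
  nb_r <- ifelse(ii < nr, id3[cbind(pmin(ii + 1L, nr), jj, kk)], NA_integer_)
  nb_r[ii == nr] <- NA_integer_
  int_r <- !is.na(nb_r)
  rf <- r_breaks[ii + 1L]
  area_r <- rf^2 * dcs[jj] * dph[kk]
  add_faces(which(int_r), nb_r[int_r], 1L,
            area_r[int_r], (r_c[pmin(ii + 1L, nr)] - r_c[ii])[int_r],
            rep(PATCHES[["INTERIOR"]], sum(int_r)))
  # outer radial boundary faces
  bnd_r <- is.na(nb_r) & ii >= i_Rout        # at capsule or stub top
  w <- which(bnd_r)
  if (length(w)) {
    at_stub <- ii[w] == nr & (thj[w] < th_af | thj[w] > pi - th_ef)
    patch <- integer(length(w))
    patch[at_stub & thj[w] < th_af] <- PATCHES[["AFFERENT_INLET"]]
    patch[at_stub & thj[w] > pi - th_ef] <- PATCHES[["EFFERENT_OUTLET"]]
    at_caps <- !at_stub
    patch[at_caps & thj[w] <= th_med] <- PATCHES[["CAPSULE_CEILING_SCS"]]
    patch[at_caps & thj[w] > th_med]  <- PATCHES[["CAPSULE_CEILING_MEDULLA"]]
    add_faces(w, rep(NA_integer_, length(w)), 1L, area_r[w],
              (r_breaks[ii + 1L] - r_c[ii])[w], patch)
  }

  # polar faces (axis 2): between (j) and (j+1); theta=0/pi have zero area
  nb_t <- ifelse(jj < nth, id3[cbind(ii, pmin(jj + 1L, nth), kk)], NA_integer_)
  nb_t[jj == nth] <- NA_integer_
  thf <- th_breaks[jj + 1L]
  area_t <- sin(thf) * (r_breaks[ii + 1L]^2 - r_breaks[ii]^2) / 2 * dph[kk]
  int_t <- !is.na(nb_t) & jj < nth
  add_faces(which(int_t), nb_t[int_t], 2L, area_t[int_t],
            (ri * (th_c[pmin(jj + 1L, nth)] - th_c[jj]))[int_t],
            rep(PATCHES[["INTERIOR"]], sum(int_t)))
  # vessel stub side walls: active cell with inactive polar neighbour
  wall_t <- is.na(nb_t) & jj < nth
  w <- which(wall_t)
  if (length(w))
    add_faces(w, rep(NA_integer_, length(w)), 2L, area_t[w],
              (ri * (th_breaks[jj + 1L] - th_c[jj]))[w],
              rep(PATCHES[["VESSEL_WALL"]], length(w)))
  # (faces towards j-1 with inactive neighbour: mirrored walls)
  nb_tm <- ifelse(jj > 1L, id3[cbind(ii, pmax(jj - 1L, 1L), kk)], NA_integer_)
  nb_tm[jj == 1L] <- NA_integer_
  wall_tm <- is.na(nb_tm) & jj > 1L
  w <- which(wall_tm)
  if (length(w)) {
    thf_m <- th_breaks[jj[w]]
    area_m <- sin(thf_m) * (r_breaks[ii[w] + 1L]^2 - r_breaks[ii[w]]^2) / 2 * dph[kk[w]]
    add_faces(w, rep(NA_integer_, length(w)), 2L, area_m,
              ri[w] * (th_c[jj[w]] - thf_m),
              rep(PATCHES[["VESSEL_WALL"]], length(w)))
  }

  # azimuthal faces (axis 3): between (k) and (k+1); k=0 and k=nph are the
  # symmetry planes y=0 and x=0
  nb_p <- ifelse(kk < nph, id3[cbind(ii, jj, pmin(kk + 1L, nph))], NA_integer_)
  nb_p[kk == nph] <- NA_integer_
  area_p <- (r_breaks[ii + 1L]^2 - r_breaks[ii]^2) / 2 * diff(th_breaks)[jj]
  int_p <- !is.na(nb_p)
  add_faces(which(int_p), nb_p[int_p], 3L, area_p[int_p],
            (ri * sin(thj) * (ph_c[pmin(kk + 1L, nph)] - ph_c[kk]))[int_p],
            rep(PATCHES[["INTERIOR"]], sum(int_p)))
  w <- which(kk == nph)
  add_faces(w, rep(NA_integer_, length(w)), 3L, area_p[w],
            (ri * sin(thj) * (ph_breaks[nph + 1L] - ph_c[kk]))[w],
            rep(PATCHES[["SYMMETRY_X"]], length(w)))
  w <- which(kk == 1L)
  area_p0 <- area_p[w]
  add_faces(w, rep(NA_integer_, length(w)), 3L, area_p0,
            (ri * sin(thj) * (ph_c[kk] - 0))[w],
            rep(PATCHES[["SYMMETRY_Y"]], length(w)))

  faces <- list(owner = fo, neigh = fn, axis = fax, area = far,
                dist = pmax(fd, 1e-9), patch = fp)

  # sinus floor faces (for wall shear): radial interior faces at R_floor
  # between the shell and the parenchyma
  is_floor <- faces$axis == 1L & faces$patch == PATCHES[["INTERIOR"]]
  if (any(is_floor)) {
    ro <- ri[faces$owner]; rn <- ri[pmax(faces$neigh, 1L)]
    rgn <- region[pmax(faces$neigh, 1L)]
    is_floor <- is_floor & ro < R_floor & rn > R_floor &
      rgn == REGIONS[["SCS"]]
  }

  region_vol <- vapply(REGIONS, function(rg) sum(vol[region == rg]), 0)

  mesh <- structure(list(
    params = g, resolution = resolution,
    r_breaks = r_breaks, th_breaks = th_breaks, ph_breaks = ph_breaks,
    r_c = r_c, th_c = th_c, ph_c = ph_c,
    dims = c(nr = nr, nth = nth, nph = nph), i_Rout = i_Rout,
    n = n, id3 = id3,
    cell = list(i = ii, j = jj, k = kk, r = ri, th = thj, ph = phk,
                x = x, y = y, z = z, vol = vol, region = region),
    faces = faces, floor_faces = which(is_floor),
    region_vol = region_vol, theta_med = th_med
  ), class = "ln_mesh")
  mesh
}

#' @export
print.ln_mesh <- function(x, ...) {
  cat("Idealized lymph-node mesh (quarter node, spherical grid)\n")
  cat(sprintf("  cells: %d  (%d x %d x %d grid, resolution %.3g/100um)\n",
              x$n, x$dims[1], x$dims[2], x$dims[3], x$resolution))
  cat(sprintf("  faces: %d (%d boundary)\n", length(x$faces$owner),
              sum(x$faces$patch != 0L)))
  rv <- x$region_vol / 1e6
  cat("  region volumes (1e6 um^3):\n")
  for (nm in names(rv)) cat(sprintf("    %-16s %10.3f\n", nm, rv[[nm]]))
  invisible(x)
}

#' Probe lines for concentration profiles
#'
#' Returns the two radial probe lines along which gradients are measured:
#' `IFR_ARROW` descends from the sinus ceiling through the interfollicular
#' gap into the T-cell area; `BFTC_ARROW` descends through the centre of
#' the first follicle and crosses the follicle/T-zone border. Both start on
#' the capsule ceiling and point radially inward.
#'
#' @param mesh an `ln_mesh`.
#' @param length_um probe length (default 450).
#' @param spacing_um sample spacing (default 4.5).
#' @return list of `ln_probe` objects (named `IFR_ARROW`, `BFTC_ARROW`).
#' @export
probe_lines <- function(mesh, length_um = 450, spacing_um = 4.5) {
  g <- mesh$params
  th_f <- g$follicle_polar_deg * pi / 180
  mk <- function(name, th, ph) {
    structure(list(name = name, theta = th, phi = ph,
                   r_start = g$R_out, length = length_um,
                   spacing = spacing_um,
                   scs_floor_s = g$scs_thickness,
                   border_s = g$scs_thickness + g$bf_tc_border_depth),
              class = "ln_probe")
  }
  out <- list(IFR_ARROW = mk("IFR_ARROW", th_f, pi / 4))
  if (g$n_follicles_per_quarter >= 1) {
    out$BFTC_ARROW <- mk("BFTC_ARROW", th_f,
                         g$follicle_azimuth_deg[1] * pi / 180)
  } else {
    warning("probe_lines: mesh has no follicles; BFTC_ARROW is absent")
  }
  out
}

#' @export
print.ln_probe <- function(x, ...) {
  cat(sprintf("probe %s: theta=%.1f deg, phi=%.1f deg, length %g um, spacing %g um\n",
              x$name, x$theta * 180 / pi, x$phi * 180 / pi, x$length, x$spacing))
  invisible(x)
}

# Breadth-first search over face adjacency; returns TRUE if some cell owning
# a face in `from_patch` connects to a cell owning a face in `to_patch`.
mesh_connected <- function(mesh, from_patch, to_patch) {
  f <- mesh$faces
  from_cells <- unique(f$owner[f$patch == PATCHES[[from_patch]]])
  to_cells   <- unique(f$owner[f$patch == PATCHES[[to_patch]]])
  if (!length(from_cells) || !length(to_cells)) return(FALSE)
  int <- f$patch == PATCHES[["INTERIOR"]]
  adj_o <- f$owner[int]; adj_n <- f$neigh[int]
  visited <- logical(mesh$n)
  frontier <- from_cells
  visited[frontier] <- TRUE
  while (length(frontier)) {
    nb <- c(adj_n[adj_o %in% frontier], adj_o[adj_n %in% frontier])
    nb <- unique(nb[!visited[nb]])
    visited[nb] <- TRUE
    frontier <- nb
  }
  any(visited[to_cells])
}
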