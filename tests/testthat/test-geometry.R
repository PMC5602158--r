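# Mesh construction: tagged volumes against an independent Monte-Carlo
# CSG oracle, border placement, adjacency invariants, probe lines and
# connectivity.

# Monte-Carlo region volumes from the constructive-solid-geometry
# definition, written independently of the mesher's tagging code.
mc_region_volumes <- function(geom, n = 2e5, seed = 7) {
  set.seed(seed)
  R <- geom$R_out
  # rejection-sample the quarter ball
  x <- runif(3 * n, 0, R); y <- runif(3 * n, 0, R); z <- runif(3 * n, -R, R)
  keep <- x^2 + y^2 + z^2 <= R^2
  x <- x[keep][1:n]; y <- y[keep][1:n]; z <- z[keep][1:n]
  r <- sqrt(x^2 + y^2 + z^2)
  th <- acos(z / r)
  region <- character(n)
  shell <- r > geom$R_floor
  th_med <- acos(-geom$medulla_depth / geom$R_floor)
  region[shell] <- ifelse(th[shell] > th_med, "MEDULLA", "SCS")
  region[shell & th < geom$theta_af] <- "AFFERENT_VESSEL"
  region[shell & th > pi - geom$theta_ef] <- "EFFERENT_VESSEL"
  region[!shell] <- ifelse(z[!shell] < -geom$medulla_depth, "MEDULLA",
                           "TCELL_AREA")
  fc <- lnchemosim:::follicle_centers(geom)
  for (m in seq_len(nrow(fc))) {
    d2 <- (x - fc[m, 1])^2 + (y - fc[m, 2])^2 + (z - fc[m, 3])^2
    region[!shell & d2 <= geom$rho_follicle^2] <- "BFOLLICLE"
  }
  vol_quarter <- (4 / 3) * pi * R^3 / 4
  tab <- table(factor(region, levels = names(REGIONS)))
  as.numeric(tab) / n * vol_quarter
}

test_that("tagged region volumes match the Monte-Carlo CSG oracle", {
  mesh <- coarse_mesh()
  g <- mesh$params
  mc <- mc_region_volumes(g)
  names(mc) <- names(REGIONS)
  tagged <- mesh$region_vol
  # vessel stubs extend outside the ball; compare in-ball regions
  for (rg in c("SCS", "BFOLLICLE", "TCELL_AREA", "MEDULLA")) {
    expect_lt(abs(tagged[[rg]] - mc[[rg]]) / mc[[rg]], 0.06, label = rg)
  }
  # total in-ball volume is exact
  inball <- mesh$cell$r <= g$R_out
  expect_equal(sum(mesh$cell$vol[inball]), (4 / 3) * pi * g$R_out^3 / 4,
               tolerance = 1e-12)
})

test_that("sinus shell volume matches the analytic spherical-shell value", {
  mesh <- coarse_mesh()
  g <- mesh$params
  th_med <- acos(-g$medulla_depth / g$R_floor)
  frac <- (cos(g$theta_af) - cos(th_med)) / 2    # polar coverage of the SCS
  shell_full <- (4 / 3) * pi * (g$R_out^3 - g$R_floor^3)
  expect_equal(mesh$region_vol[["SCS"]], shell_full / 4 * frac,
               tolerance = 0.05)
})

test_that("region volumes converge under refinement", {
  v3 <- coarse_mesh()$region_vol
  v6 <- fixture("mesh6vol", function() build_mesh(resolution = 6)$region_vol)
  for (rg in c("SCS", "BFOLLICLE", "TCELL_AREA", "MEDULLA"))
    expect_lt(abs(v3[[rg]] - v6[[rg]]) / v6[[rg]], 0.05, label = rg)
})

test_that("the follicle border sits at the configured depth on the probe", {
  mesh <- coarse_mesh()
  g <- mesh$params
  lines <- probe_lines(mesh)
  bf <- lines$BFTC_ARROW
  expect_equal(bf$border_s, g$scs_thickness + g$bf_tc_border_depth)
  # region transition along the follicle axis happens within a cell of the
  # analytic border radius
  s <- seq(0, bf$length, by = 1)
  rg <- region_at(mesh, g$R_out - s, rep(bf$theta, length(s)),
                  rep(bf$phi, length(s)))
  in_bf <- which(rg == REGIONS[["BFOLLICLE"]])
  expect_gt(length(in_bf), 0)
  deepest_bf <- max(s[in_bf])
  dr_cortex <- diff(mesh$r_breaks)[findInterval(g$r_border + 1, mesh$r_breaks)]
  expect_lt(abs(deepest_bf - bf$border_s), dr_cortex + 1)
})

test_that("follicle cells touch only sinus or T-cell area", {
  mesh <- coarse_mesh()
  f <- mesh$faces
  int <- f$patch == PATCHES[["INTERIOR"]]
  ro <- mesh$cell$region[f$owner[int]]
  rn <- mesh$cell$region[f$neigh[int]]
  bf_pairs <- ro == REGIONS[["BFOLLICLE"]] | rn == REGIONS[["BFOLLICLE"]]
  others <- ifelse(ro[bf_pairs] == REGIONS[["BFOLLICLE"]], rn[bf_pairs],
                   ro[bf_pairs])
  expect_true(all(others %in% REGIONS[c("BFOLLICLE", "SCS", "TCELL_AREA")]))
})

test_that("mesh is conforming and connected from inlet to outlet", {
  mesh <- coarse_mesh()
  f <- mesh$faces
  int <- f$patch == PATCHES[["INTERIOR"]]
  expect_true(all(!is.na(f$neigh[int])))
  expect_true(all(is.na(f$neigh[!int])))
  expect_true(all(f$area >= 0))
  expect_true(mesh_connected(mesh, "AFFERENT_INLET", "EFFERENT_OUTLET"))
})

test_that("probe lines start in the sinus and cross one follicle border", {
  mesh <- coarse_mesh()
  lines <- probe_lines(mesh)
  for (ln in lines) {
    expect_gte(ln$length, 400)
    s <- seq(1, mesh$params$scs_thickness - 1, by = 1)
    rg <- region_at(mesh, mesh$params$R_out - s,
                    rep(ln$theta, length(s)), rep(ln$phi, length(s)))
    expect_true(all(rg == REGIONS[["SCS"]]), label = ln$name)
  }
  # BFTC arrow: exactly one BF -> TC transition going inward
  bf <- lines$BFTC_ARROW
  s <- seq(0, bf$length, by = 2)
  rg <- region_at(mesh, mesh$params$R_out - s,
                  rep(bf$theta, length(s)), rep(bf$phi, length(s)))
  rg <- rg[!is.na(rg)]
  trans <- sum(head(rg, -1) == REGIONS[["BFOLLICLE"]] &
                 tail(rg, -1) == REGIONS[["TCELL_AREA"]])
  expect_equal(trans, 1)
  # IFR arrow never enters a follicle
  ifr <- lines$IFR_ARROW
  rg2 <- region_at(mesh, mesh$params$R_out - s,
                   rep(ifr$theta, length(s)), rep(ifr$phi, length(s)))
  expect_false(any(rg2 == REGIONS[["BFOLLICLE"]], na.rm = TRUE))
})

test_that("a follicle-free mesh warns and drops the follicle probe", {
  m0 <- build_mesh(geometry_params(n_follicles_per_quarter = 0),
                   resolution = 2)
  expect_equal(m0$region_vol[["BFOLLICLE"]], 0)
  expect_warning(lines <- probe_lines(m0), "no follicles")
  expect_null(lines$BFTC_ARROW)
})

test_that("infeasible geometries are rejected with informative errors", {
  expect_error(geometry_params(scs_thickness = 200), "scs_thickness")
  expect_error(geometry_params(bf_tc_border_depth = 600), "border_depth")
  expect_error(geometry_params(follicle_polar_deg = 3), "afferent")
  expect_error(geometry_params(medulla_depth = 500), "medulla")
  expect_error(build_mesh(resolution = 1), "resolution")
})
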