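# Shared fixtures, built once per test session. Coarse meshes keep the
# suite fast; the physics being checked (conservation, closures, scenario
# logic) is resolution-independent.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

coarse_mesh <- function() fixture("mesh3", function() build_mesh(resolution = 3))
coarse_flow <- function() fixture("flow3", function() solve_flow(coarse_mesh()))
coarse_maps <- function() fixture("maps3", function() build_field_maps(coarse_mesh()))

coarse_baseline <- function() fixture("base3", function() {
  solve_steady(transport_problem(coarse_mesh(), coarse_flow(), coarse_maps()))
})

# extra-coarse mesh for ensemble-style tests
tiny_mesh <- function() fixture("mesh2", function() build_mesh(resolution = 2.5))
tiny_flow <- function() fixture("flow2", function() solve_flow(tiny_mesh()))
tiny_maps <- function() fixture("maps2", function() build_field_maps(tiny_mesh()))

# field maps with selected components overridden (uniform-value helpers)
maps_with <- function(maps, q19 = NULL, q21 = NULL, Rtot = NULL, Mtot = NULL,
                      Atot = NULL) {
  set <- function(fld, val) {
    if (!is.null(val)) {
      maps$region[[fld]][] <<- val
      maps$cell[[fld]][] <<- val
    }
  }
  set("q19", q19); set("q21", q21); set("Rtot", Rtot); set("Mtot", Mtot)
  if (!is.null(Atot)) maps$Atot <- Atot
  maps
}

# nearest-cell region lookup at spherical coordinates (independent of the
# package's trilinear interpolation)
region_at <- function(mesh, r, th, ph) {
  i <- findInterval(r, mesh$r_breaks, all.inside = TRUE)
  j <- findInterval(th, mesh$th_breaks, all.inside = TRUE)
  k <- findInterval(ph, mesh$ph_breaks, all.inside = TRUE)
  id <- mesh$id3[cbind(i, j, k)]
  ifelse(is.na(id), NA_integer_, mesh$cell$region[id])
}

# random admissible local state honouring the conservation totals
random_local_state <- function(Rtot = 80, Mtot = 400) {
  rs <- runif(6); rs <- rs / sum(rs) * Rtot
  c21b_pool <- runif(2); c21b_pool <- c21b_pool / sum(c21b_pool)
  sites_used <- runif(1, 0, Mtot - rs[6])
  list(C19 = runif(1, 0, 5), C21u = runif(1, 0, 10),
       C21b = sites_used, Mfree = Mtot - sites_used - rs[6],
       R = rs[1], R19 = rs[2], Rdes = rs[3], Rint = rs[4],
       R21u = rs[5], R21b = rs[6])
}
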