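# Local kinetics: conservation, closed-form equilibria, and agreement with
# brute-force ODE integration (deSolve) as the independent oracle.

p_default <- kinetic_params()

test_that("derived dissociation constants follow from the on/off rates", {
  expect_equal(p_default$Kd_CCR7, 5)
  expect_equal(p_default$Kd_ACKR4, 4.5)
})

test_that("reaction RHS conserves receptor and matrix-site totals exactly", {
  set.seed(42)
  for (rep in 1:20) {
    s <- random_local_state()
    d <- local_rhs(s, p_default)
    expect_equal(d$R + d$R19 + d$Rdes + d$Rint + d$R21u + d$R21b, 0,
                 tolerance = 1e-14)
    expect_equal(d$Mfree + d$C21b + d$R21b, 0, tolerance = 1e-14)
  }
})

test_that("zero state has zero derivatives and negative input is rejected", {
  zero <- as.list(setNames(rep(0, 10), names(random_local_state())))
  expect_true(all(abs(unlist(local_rhs(zero, p_default))) == 0))
  bad <- random_local_state(); bad$C19 <- -1
  expect_error(local_rhs(bad, p_default), "negative")
})

test_that("without desensitization the CCL19 complex reaches Kd equilibrium", {
  p <- kinetic_params(lambda_des = 0)
  C19 <- 3.7
  occ <- ccr7_occupancy_equilibrium(C19, 0, 0, Rtot = 100, p)
  expect_equal(occ$R19 / occ$R, C19 / p$Kd_CCR7, tolerance = 1e-12)
  expect_equal(occ$Rdes, 0)
  expect_equal(occ$Rint, 0)
})

test_that("receptor occupancy matches brute-force ODE integration", {
  skip_if_not_installed("deSolve")
  p <- p_default
  lig <- list(C19 = 0.8, C21u = 4.1, C21b = 250)
  Rtot <- 75
  rhs <- function(t, y, parms) {
    s <- c(lig, as.list(setNames(y, c("R", "R19", "Rdes", "Rint",
                                      "R21u", "R21b"))),
           list(Mfree = 0))
    d <- local_rhs(s, p)
    list(c(d$R, d$R19, d$Rdes, d$Rint, d$R21u, d$R21b))
  }
  y0 <- c(Rtot, 0, 0, 0, 0, 0)
  sol <- deSolve::ode(y0, times = c(0, 5e5), rhs, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  num <- sol[nrow(sol), -1]
  occ <- ccr7_occupancy_equilibrium(lig$C19, lig$C21u, lig$C21b, Rtot, p)
  expect_equal(unname(num),
               unname(unlist(occ[c("R", "R19", "Rdes", "Rint", "R21u", "R21b")])),
               tolerance = 1e-6)
})

test_that("coupled local equilibrium zeroes the immobile-species derivatives", {
  p <- p_default
  eq <- local_equilibrium(C19 = 0.6, C21u = 5, Rtot = 70, Mtot = 450, p)
  s <- c(list(C19 = 0.6, C21u = 5), eq[c("C21b", "Mfree", "R", "R19",
                                         "Rdes", "Rint", "R21u", "R21b")])
  d <- local_rhs(s, p)
  scale <- max(unlist(s))
  for (f in c("C21b", "R", "R19", "Rdes", "Rint", "R21u", "R21b", "Mfree"))
    expect_lt(abs(d[[f]]) / scale, 1e-10)
  # conservation identities of the closure
  expect_equal(eq$R + eq$R19 + eq$Rdes + eq$Rint + eq$R21u + eq$R21b, 70,
               tolerance = 1e-10)
  expect_equal(eq$Mfree + eq$C21b + eq$R21b, 450, tolerance = 1e-8)
})

test_that("abundant matrix-bound CCL21 leaves ~2% of CCR7 free", {
  occ <- ccr7_occupancy_equilibrium(0, 0, C21b = 306, Rtot = 100, p_default)
  expect_equal(occ$R / 100, 5 / (5 + 306), tolerance = 1e-12)
  expect_lt(occ$R / 100, 0.02)
})

test_that("ACKR4 flux: knockout, saturation ceiling, and competition bound", {
  p <- p_default
  ko <- ackr4_scavenging_flux(5, 5, Atot = 0, p)
  expect_equal(ko$flux19, 0)
  expect_equal(ko$flux21, 0)
  Atot <- 61
  sat <- ackr4_scavenging_flux(1e7, 0, Atot, p)
  ceiling_flux <- p$eta_up * Atot / (1 + p$eta_up / p$eta_in)
  expect_equal(sat$flux19, ceiling_flux, tolerance = 1e-5)
  # monotone in ligand and receptor; competing fluxes never exceed ceiling
  C <- 10^seq(-3, 3, length.out = 25)
  f <- ackr4_scavenging_flux(C, 0, Atot, p)$flux19
  expect_true(all(diff(f) > 0))
  f2 <- ackr4_scavenging_flux(1, 1, c(10, 20, 40), p)
  expect_true(all(diff(f2$flux19 + f2$flux21) > 0))
  comp <- ackr4_scavenging_flux(500, 500, Atot, p)
  expect_lt(comp$flux19 + comp$flux21, p$eta_up * Atot)
})

test_that("ACKR4 steady state matches ODE integration, incl. half-max point", {
  skip_if_not_installed("deSolve")
  p <- p_default
  Atot <- 61
  ode_flux <- function(C19, C21u) {
    rhs <- function(t, y, parms) {
      s <- as.list(setNames(y, c("A", "A19", "A21", "Aint")))
      list(unlist(ackr4_rhs(s, C19, C21u, p)))
    }
    sol <- deSolve::ode(c(Atot, 0, 0, 0), c(0, 5e4), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
    y <- sol[nrow(sol), -1]
    p$eta_in * y[2]
  }
  cf <- ackr4_scavenging_flux(0.5, 0.2, Atot, p)
  expect_equal(unname(ode_flux(0.5, 0.2)), cf$flux19, tolerance = 1e-6)
  # resurfacing-limited half-max: the internalized pool shifts the
  # half-maximal concentration far below the binding Kd
  C_half <- (p$eta_off + p$eta_in) / (p$eta_on * (1 + p$eta_in / p$eta_up))
  sat <- p$eta_in * Atot / (1 + p$eta_in / p$eta_up)
  expect_equal(unname(ode_flux(C_half, 0)), sat / 2, tolerance = 1e-5)
})
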