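# Steady transport: trivial limits, well-mixed oracle, positivity/maximum
# principle, linearity without receptors, conservation closures and the
# mass ledger.

test_that("zero production and clean inlet give the zero solution", {
  maps0 <- maps_with(tiny_maps(), q19 = 0, q21 = 0)
  st <- solve_steady(transport_problem(tiny_mesh(), tiny_flow(), maps0))
  expect_equal(max(abs(st$C19)), 0, tolerance = 1e-12)
  expect_equal(max(abs(st$C21u)), 0, tolerance = 1e-12)
  expect_equal(max(abs(st$C21b)), 0, tolerance = 1e-12)
})

test_that("a produced species with no sink has no steady state", {
  mesh <- tiny_mesh()
  fp <- flow_params(afferent_flow_ul_h = 0,
                    starling = list(LpS_per_V = 0, P_lymph_Pa = 0,
                                    P_cap_Pa = 0, pi_lymph_Pa = 0,
                                    pi_cap_Pa = 0, sigma = 0,
                                    medulla_factor = 1))
  fl0 <- solve_flow(mesh, fp)
  maps <- maps_with(tiny_maps(), q19 = 1e-3, q21 = 1e-3,
                    Rtot = 0, Mtot = 0)
  kin <- kinetic_params(D_eff_19 = 0, D_eff_21 = 0, P_vasc = 0)
  expect_error(
    solve_steady(transport_problem(mesh, fl0, maps, kin, ackr4 = FALSE)),
    "no steady state|singular")
})

test_that("well-mixed limit matches the zero-dimensional closure", {
  # uniform production balanced by a uniform CCR7 sink: the 0-D fixed
  # point (from the local-kinetics oracle) is an exact steady state of
  # the transport problem when the inlet carries the same concentration
  mesh <- tiny_mesh()
  fp <- flow_params(afferent_flow_ul_h = 0,
                    starling = list(LpS_per_V = 0, P_lymph_Pa = 0,
                                    P_cap_Pa = 0, pi_lymph_Pa = 0,
                                    pi_cap_Pa = 0, sigma = 0,
                                    medulla_factor = 1))
  fl0 <- solve_flow(mesh, fp)
  q <- 2e-3
  Rtot <- 50
  maps <- maps_with(tiny_maps(), q19 = q, q21 = 0, Rtot = Rtot, Mtot = 0)
  kin <- kinetic_params(D_eff_19 = 500, D_eff_21 = 500, P_vasc = 0)
  # 0-D: q = lambda_des * R19(C0)
  resid <- function(C) {
    eq <- local_equilibrium(C, 0, Rtot, 0, kin)
    q - kin$lambda_des * eq$R19
  }
  C0 <- uniroot(resid, c(1e-9, 1e3), tol = 1e-14)$root
  st <- solve_steady(transport_problem(mesh, fl0, maps, kin,
                                       C_in_19 = C0, ackr4 = FALSE))
  V <- sum(mesh$cell$vol)
  Cbar <- sum(st$C19 * mesh$cell$vol) / V
  expect_equal(Cbar, C0, tolerance = 0.01)
  expect_lt(max(abs(st$C19 - C0)) / C0, 0.01)
  # with a clean inlet the boundary can only lower the average
  st2 <- solve_steady(transport_problem(mesh, fl0, maps, kin,
                                        C_in_19 = 0, ackr4 = FALSE))
  expect_lt(sum(st2$C19 * mesh$cell$vol) / V, C0)
})

test_that("advection-diffusion obeys the discrete maximum principle", {
  mesh <- tiny_mesh()
  maps <- maps_with(tiny_maps(), q19 = 0, q21 = 0, Rtot = 0, Mtot = 0)
  kin <- kinetic_params(P_vasc = 0)
  st <- solve_steady(transport_problem(mesh, tiny_flow(), maps, kin,
                                       C_in_19 = 5, C_in_21 = 5,
                                       ackr4 = FALSE))
  expect_gte(min(st$C19), -1e-10)
  expect_lte(max(st$C19), 5 + 1e-8)
  expect_gte(min(st$C21u), -1e-10)
  expect_lte(max(st$C21u), 5 + 1e-8)
})

test_that("without receptors and matrix the response is exactly linear", {
  mesh <- tiny_mesh()
  maps1 <- maps_with(tiny_maps(), Rtot = 0, Mtot = 0)
  maps2 <- maps_with(tiny_maps(), Rtot = 0, Mtot = 0)
  maps2$cell$q19 <- maps2$cell$q19 * 2
  maps2$cell$q21 <- maps2$cell$q21 * 2
  # the ceiling scavenger saturates, so it is switched off here
  s1 <- solve_steady(transport_problem(mesh, tiny_flow(), maps1,
                                       ackr4 = FALSE))
  s2 <- solve_steady(transport_problem(mesh, tiny_flow(), maps2,
                                       ackr4 = FALSE))
  expect_equal(s2$C19, 2 * s1$C19, tolerance = 1e-8)
  expect_equal(s2$C21u, 2 * s1$C21u, tolerance = 1e-8)
})

test_that("baseline solution is nonnegative with conserved local totals", {
  st <- coarse_baseline()
  maps <- coarse_maps()
  expect_gte(min(st$C19), 0)
  expect_gte(min(st$C21u), 0)
  Rsum <- st$R + st$R19 + st$Rdes + st$Rint + st$R21u + st$R21b
  expect_equal(Rsum, maps$cell$Rtot, tolerance = 1e-8)
  Msum <- st$Mfree + st$C21b + st$R21b
  expect_equal(Msum, maps$cell$Mtot, tolerance = 1e-8)
})

test_that("highest concentrations sit in the T-cell area core", {
  st <- coarse_baseline()
  mesh <- coarse_mesh()
  for (sp in c("C19", "C21u", "C21b")) {
    i <- which.max(st[[sp]])
    expect_equal(mesh$cell$region[i], REGIONS[["TCELL_AREA"]], label = sp)
    expect_lt(mesh$cell$r[i], 302, label = sp)
  }
})

test_that("the steady-state ledger closes and CCR7 never destroys CCL21", {
  led <- mass_balance_report(coarse_baseline())
  expect_lt(max(abs(led$closure_rel)), 0.005)
  expect_equal(led$ccr7_degradation[led$species == "CCL21"], 0)
  expect_gt(led$ccr7_degradation[led$species == "CCL19"], 0)
  # every sink is nonnegative
  expect_true(all(led$blood_convective >= 0))
  expect_true(all(led$ackr4_scavenging >= 0))
  expect_true(all(led$efferent_export >= 0))
})

test_that("disabling ACKR4 at baseline raises efferent export", {
  mesh <- coarse_mesh()
  st_ko <- fixture("ko3", function()
    solve_steady(transport_problem(mesh, coarse_flow(), coarse_maps(),
                                   ackr4 = FALSE)))
  led_wt <- mass_balance_report(coarse_baseline())
  led_ko <- mass_balance_report(st_ko)
  for (sp in c("CCL19", "CCL21"))
    expect_gt(led_ko$efferent_export[led_ko$species == sp],
              led_wt$efferent_export[led_wt$species == sp])
})

test_that("low flow causes chemokine accumulation in sinus and medulla", {
  mesh <- coarse_mesh()
  st_lf <- fixture("lowflow3", function()
    solve_steady(transport_problem(mesh, coarse_flow(), coarse_maps(),
                                   flow_scale = 0.01)))
  st <- coarse_baseline()
  scs <- mesh$cell$region == REGIONS[["SCS"]]
  med <- mesh$cell$region == REGIONS[["MEDULLA"]]
  expect_gt(mean(st_lf$C21u[scs]), mean(st$C21u[scs]))
  expect_gt(mean(st_lf$C21b[med]), mean(st$C21b[med]))
  expect_gt(mean(st_lf$C19[med]), mean(st$C19[med]))
})
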