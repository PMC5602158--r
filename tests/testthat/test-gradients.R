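# Profile sampling, filtering, gradients and across-cell differences:
# analytic fields with known slopes are the oracles.

fake_state <- function(mesh, f) {
  # a bare field list accepted by sample_profile(mesh=)
  list(C19 = f, C21u = f, C21b = f)
}

test_that("a uniform field samples flat with exactly zero gradient", {
  mesh <- tiny_mesh()
  lines <- probe_lines(mesh)
  st <- fake_state(mesh, rep(3.5, mesh$n))
  pr <- sample_profile(st, lines$IFR_ARROW, mesh = mesh)
  expect_true(all(abs(pr$data$C19 - 3.5) < 1e-12))
  expect_true(all(abs(pr$data$C19_filt - 3.5) < 1e-12))
  expect_true(all(abs(pr$data$C19_grad) < 1e-12))
})

test_that("a linear radial field recovers its slope", {
  mesh <- tiny_mesh()
  lines <- probe_lines(mesh)
  slope <- 0.02
  f <- slope * (mesh$params$R_out - mesh$cell$r)   # linear in depth
  pr <- sample_profile(fake_state(mesh, f), lines$IFR_ARROW, mesh = mesh)
  g <- pr$data$C19_grad
  interior <- seq(5, length(g) - 5)
  expect_lt(max(abs(g[interior] - slope)), slope * 0.05)
})

test_that("cell differences scale linearly with cell diameter", {
  mesh <- tiny_mesh()
  lines <- probe_lines(mesh)
  slope <- 0.05
  f <- slope * (mesh$params$R_out - mesh$cell$r)
  pr <- sample_profile(fake_state(mesh, f), lines$IFR_ARROW, mesh = mesh)
  d9 <- cell_differences(pr, 9, "C19")
  d18 <- cell_differences(pr, 18, "C19")
  d36 <- cell_differences(pr, 36, "C19")
  mid <- 30:60
  expect_equal(d9$delta_nM[mid], rep(slope * 9, length(mid)), tolerance = 0.02)
  expect_equal(d18$delta_nM[mid], 2 * d9$delta_nM[mid], tolerance = 0.02)
  expect_equal(d36$delta_nM[mid], 4 * d9$delta_nM[mid], tolerance = 0.02)
  # diameters not on the sample grid are rejected
  expect_error(cell_differences(pr, 10, "C19"), "multiple")
})

test_that("percentage difference across a cell depends only on alpha*d for
          an exponential profile", {
  # construct a synthetic profile object directly
  s <- seq(0, 450, by = 4.5)
  alpha <- 0.01
  prof <- structure(list(
    data = data.frame(s_um = s, C19 = exp(alpha * s),
                      C19_filt = lnchemosim:::lowpass_ma(exp(alpha * s), 5)),
    probe = list(spacing = 4.5), window = 5), class = "ln_profile")
  d18 <- cell_differences(prof, 18, "C19")
  mid <- 10:80
  # the moving average rescales an exponential by a constant, so the
  # percentage difference is exactly position-independent
  expect_lt(diff(range(d18$pct[mid])), 1e-9)
  expect_equal(d18$pct[20], 100 * (exp(alpha * 18) - 1), tolerance = 1e-6)
})

test_that("the low-pass filter is linear and preserves constants", {
  x <- sin(seq(0, 4, by = 0.1)); y <- cos(seq(0, 4, by = 0.1))
  lp <- lnchemosim:::lowpass_ma
  expect_equal(lp(2 * x + 3 * y, 5), 2 * lp(x, 5) + 3 * lp(y, 5),
               tolerance = 1e-14)
  expect_equal(lp(rep(7, 50), 5), rep(7, 50), tolerance = 1e-14)
})

test_that("summary gradients vanish for a zero state and totals decompose", {
  st <- coarse_baseline()
  sg <- summary_gradients(st)
  expect_equal(sg$total_CCL21_fmol,
               sg$total_CCL21u_fmol + sg$total_CCL21b_fmol,
               tolerance = 1e-12)
  # zero fields: fake a state with zero concentrations
  z <- st
  for (f in c("C19", "C21u", "C21b")) z[[f]] <- rep(0, length(st[[f]]))
  sgz <- summary_gradients(z)
  expect_equal(sgz$ifr_slope_C19, 0)
  expect_equal(sgz$bftc_slope_C21b, 0)
  expect_equal(sgz$total_CCL19_fmol, 0)
  expect_equal(sgz$efferent_CCL19_nM, 0)
})

test_that("probe truncation warns when the line exits the mesh", {
  mesh <- tiny_mesh()
  long <- probe_lines(mesh, length_um = 600)$IFR_ARROW
  expect_warning(
    sample_profile(fake_state(mesh, rep(1, mesh$n)), long, mesh = mesh),
    "truncat")
})
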