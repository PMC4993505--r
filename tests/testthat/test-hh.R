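test_that("Nernst potentials match the closed form at 6.3 C", {
  cn <- physical_constants()
  vt <- 1000 * cn$R_gas * cn$temperature / cn$faraday   # independent
  expect_equal(nernst_potential(155, 155, 1), 0)
  expect_equal(nernst_potential(155, 4, 1), vt * log(4 / 155),
               tolerance = 1e-12)
  expect_equal(nernst_potential(155, 4, 1), -88.06, tolerance = 1e-3)
  expect_equal(nernst_potential(12, 145, 1), 60.01, tolerance = 1e-2)
  expect_error(nernst_potential(0, 4, 1), "positive")
})

test_that("gating rates are positive with monotone steady states", {
  V <- seq(-100, 60, by = 2)
  r <- gating_rates(V)
  for (x in c("m", "h", "n")) {
    expect_true(all(r[[x]]$alpha >= 0))
    expect_true(all(r[[x]]$beta >= 0))
  }
  s <- gating_steady(V)
  for (x in c("m", "h", "n"))
    expect_true(all(s$inf[[x]] > 0 & s$inf[[x]] < 1))
  expect_true(all(diff(s$inf$m) >= 0))
  expect_true(all(diff(s$inf$h) <= 0))
  expect_true(all(diff(s$inf$n) >= 0))
})

test_that("removable singularities evaluate to the analytic limit", {
  # alpha_m pole sits at v = -40 relative to the canonical rest
  r <- gating_rates(-40)
  expect_false(any(vapply(r, function(x)
    any(!is.finite(c(x$alpha, x$beta))), TRUE)))
  # series-expansion oracle: x/(1 - exp(-x/10)) -> 10 + x/2 + O(x^2)
  eps <- 1e-9
  r_eps <- gating_rates(-40 + eps)
  expect_equal(r$m$alpha, 0.1 * 10, tolerance = 1e-7)
  expect_equal(r_eps$m$alpha, r$m$alpha, tolerance = 1e-7)
  expect_equal(gating_rates(-55)$n$alpha, 0.01 * 10, tolerance = 1e-7)
})

test_that("exact exponential gating update stays bounded and composes", {
  st <- gating_state(-65)
  big <- advance_gating(st, 20, 1e6)
  s <- gating_steady(20)
  for (x in c("m", "h", "n")) expect_equal(big[[x]], s$inf[[x]])
  # semigroup: two half steps equal one full step at frozen V
  one <- advance_gating(st, -20, 0.4)
  two <- advance_gating(advance_gating(st, -20, 0.2), -20, 0.2)
  for (x in c("m", "h", "n")) expect_equal(one[[x]], two[[x]],
                                           tolerance = 1e-12)
  # never leaves [0,1] along an arbitrary V trajectory
  set.seed(7)
  cur <- st
  for (V in runif(200, -120, 80)) {
    cur <- advance_gating(cur, V, runif(1, 1e-4, 0.5))
    expect_true(all(unlist(cur[c("m", "h", "n")]) >= 0))
    expect_true(all(unlist(cur[c("m", "h", "n")]) <= 1))
  }
})

test_that("gating update matches a fine-step ODE oracle at frozen V", {
  skip_if_not_installed("deSolve")
  V <- -30
  r <- gating_rates(V)
  st <- gating_state(-65)
  rhs <- function(t, y, p) {
    list(c(r$m$alpha * (1 - y[1]) - r$m$beta * y[1],
           r$h$alpha * (1 - y[2]) - r$h$beta * y[2],
           r$n$alpha * (1 - y[3]) - r$n$beta * y[3]))
  }
  out <- deSolve::ode(c(st$m, st$h, st$n), c(0, 1), rhs, NULL,
                      method = "ode45", atol = 1e-10, rtol = 1e-10)
  mine <- advance_gating(st, V, 1)
  expect_equal(unname(out[2, 2:4]), c(mine$m, mine$h, mine$n),
               tolerance = 1e-6)
})

test_that("current-to-flux conversion matches the unit oracle", {
  # 36 mS/cm2 at 100 mV driving force -> 3.6 mA/cm2 -> I/F mol m-2 s-1
  st <- gating_state(-65)
  st$n <- 1
  ch <- channel_set(gbar_kv = 36, g_kl = 0, gbar_nav = 0, g_nal = 0)
  fl <- transmembrane_flux(V_m = 100, st, E_K = 0, E_Na = 0, channels = ch)
  expect_equal(fl$I[["K"]], 3.6, tolerance = 1e-12)
  f_SI <- 3.6 * 10 / 96485                 # mol m-2 s-1, independent
  expect_equal(f_SI, 3.73e-4, tolerance = 1e-2)
  expect_equal(fl$flux[["K"]], f_SI * 1e3, tolerance = 1e-12)  # internal units
  # zero driving force
  fl0 <- transmembrane_flux(V_m = -88, st, E_K = -88, E_Na = 60,
                            channels = channel_set(g_nal = 0, gbar_nav = 0))
  expect_equal(fl0$flux[["K"]], 0)
})

test_that("stimulus gate is a clean rectangle", {
  ch <- channel_set(stim_amplitude = 1, stim_duration = 0.5)
  expect_equal(stimulus_flux(0.6, ch), 0)
  expect_gt(stimulus_flux(0.25, ch), 0)
  # integral = magnitude * duration (rectangle)
  tt <- seq(0, 1, by = 1e-4)
  f <- stimulus_flux(tt, ch)
  expect_equal(sum(f) * 1e-4, stimulus_flux(0, ch) * 0.5, tolerance = 1e-3)
})

test_that("leak-balanced rest is in the physiological corridor", {
  vr <- resting_potential()
  expect_gt(vr, -80)
  expect_lt(vr, -60)
})

test_that("charge bookkeeping ties current to moles moved", {
  st <- gating_state(-65)
  fl <- transmembrane_flux(-20, st, E_K = -88, E_Na = 60)
  cn <- physical_constants()
  # f (mM um/ms) * z * F must reproduce the current in internal charge units
  for (sp in c("K", "Na")) {
    I_SI <- fl$I[[sp]] * 10                      # A m-2
    f_SI <- fl$flux[[sp]] * 1e-3                 # mol m-2 s-1
    expect_equal(I_SI, f_SI * cn$faraday, tolerance = 1e-12)
  }
})
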