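test_that("balanced inputs are a fixed point: BG stays constant over 6 h", {
  p <- fx_params
  gf <- 65
  si <- 4.5e-4
  iq <- eq_insulin(3, p)
  G0 <- ((gf / 60 + p[["EGP"]] - p[["CNS"]]) / p[["V_G"]]) /
    (p[["p_G"]] + si * iq[["Q"]] / (1 + p[["alpha_G"]] * iq[["Q"]]))
  st <- icing_state(G0, iq[["I"]], iq[["Q"]],
                    (gf / 60) / p[["d1"]], (gf / 60) / p[["d2"]])
  sched <- input_schedule(insulin_rates = data.frame(time_h = 0, rate_U_h = 3),
                          enteral = data.frame(time_h = 0, pct_gf = 100),
                          goal_feed = gf)
  sim <- simulate_icing(st, p, rep(si, 6), sched, 6)
  expect_lt(max(abs(sim$G - G0)), 1e-5)
  expect_equal(as.numeric(bg_at_hours(sim, 0:6)), rep(G0, 7), tolerance = 1e-5)
})

test_that("trajectory matches an independent adaptive-solver reference", {
  skip_if_not_installed("deSolve")
  p <- fx_params
  gf <- 65
  si <- c(4e-4, 8e-4, 6e-4)
  st <- init_state(9, gf, p)
  sched <- input_schedule(insulin_boluses = data.frame(time_h = 0:2, units = 3),
                          enteral = data.frame(time_h = 0, pct_gf = 100),
                          goal_feed = gf)
  sim <- simulate_icing(st, p, si, sched, 3)

  deriv <- function(t, y, parms) {
    with(as.list(c(y, parms)), {
      P2out <- min(d2 * P2, P_max)
      dG <- -p_G * G - si_h * G * Q / (1 + alpha_G * Q) +
        (P2out + EGP - CNS) / V_G
      dI <- -n_K * I - n_L * I / (1 + alpha_I * I) - n_I * (I - Q) +
        (1 - x_L) * u_en / V_I
      dQ <- n_I * (I - Q) - n_C * Q / (1 + alpha_G * Q)
      list(c(dG, dI, dQ, -d1 * P1 + feed, d1 * P1 - P2out))
    })
  }
  y <- st$y
  ref <- numeric(3)
  for (h in 1:3) {
    y["I"] <- y["I"] + 3 * 1000 / p[["V_I"]]
    parms <- c(as.list(p), feed = gf / 60, si_h = si[h])
    seg <- deSolve::ode(y, c(0, 60), deriv, parms, method = "lsoda",
                        rtol = 1e-10, atol = 1e-10)
    y <- seg[nrow(seg), 2:6]
    ref[h] <- y[["G"]]
  }
  expect_lt(max(abs(as.numeric(bg_at_hours(sim, 1:3)) - ref)), 1e-6)
})

test_that("BG is monotone non-increasing in SI when insulin is present", {
  p <- fx_params
  st <- init_state(8, 65, p)
  sched <- input_schedule(insulin_boluses = data.frame(time_h = 0:5, units = 4),
                          enteral = data.frame(time_h = 0, pct_gf = 100),
                          goal_feed = 65)
  lo <- simulate_icing(st, p, rep(3e-4, 6), sched, 6)
  hi <- simulate_icing(st, p, rep(9e-4, 6), sched, 6)
  expect_true(all(hi$G <= lo$G + 1e-12))
  expect_lt(hi$G[nrow(hi)], lo$G[nrow(lo)])   # strictly lower eventually
})

test_that("no insulin input and no history keeps interstitial insulin at zero", {
  p <- fx_params
  st <- init_state(8, 65, p)
  sched <- input_schedule(enteral = data.frame(time_h = 0, pct_gf = 100),
                          goal_feed = 65)
  sim <- simulate_icing(st, p, rep(5e-4, 6), sched, 6)
  expect_identical(max(sim$Q), 0)
  expect_identical(max(sim$I), 0)
  # with Q identically zero the insulin-mediated uptake term is exactly 0,
  # so BG cannot depend on SI
  sim2 <- simulate_icing(st, p, rep(5e-3, 6), sched, 6)
  expect_identical(sim$G, sim2$G)
})

test_that("doubling a dextrose bolus never decreases any subsequent BG", {
  p <- fx_params
  st <- init_state(7, 65, p)
  base <- input_schedule(insulin_boluses = data.frame(time_h = 0:3, units = 2),
                         enteral = data.frame(time_h = 0, pct_gf = 80),
                         dextrose = data.frame(time_h = 1, mmol = 10),
                         goal_feed = 65)
  dbl <- input_schedule(insulin_boluses = data.frame(time_h = 0:3, units = 2),
                        enteral = data.frame(time_h = 0, pct_gf = 80),
                        dextrose = data.frame(time_h = 1, mmol = 20),
                        goal_feed = 65)
  s1 <- simulate_icing(st, p, rep(5e-4, 4), base, 4)
  s2 <- simulate_icing(st, p, rep(5e-4, 4), dbl, 4)
  expect_true(all(s2$G >= s1$G - 1e-12))
})

test_that("halving the integration step changes end BG below tolerance", {
  p <- fx_params
  st <- init_state(10, 65, p)
  sched <- input_schedule(insulin_boluses = data.frame(time_h = 0:5, units = 5),
                          enteral = data.frame(time_h = 0, pct_gf = 100),
                          goal_feed = 65)
  a <- simulate_icing(st, p, rep(6e-4, 6), sched, 6, step_min = 0.5)
  b <- simulate_icing(st, p, rep(6e-4, 6), sched, 6, step_min = 0.25)
  expect_lt(abs(a$G[nrow(a)] - b$G[nrow(b)]), 1e-6)
})

test_that("bg_at_hours returns exact solver values and range-checks", {
  p <- fx_params
  st <- init_state(8, 65, p)
  sched <- input_schedule(enteral = data.frame(time_h = 0, pct_gf = 100),
                          goal_feed = 65)
  sim <- simulate_icing(st, p, rep(5e-4, 4), sched, 4)
  h <- bg_at_hours(sim, 0:4)
  idx <- match(0:4, sim$time_h)
  expect_identical(as.numeric(h), sim$G[idx])   # bit-identical, no interpolation
  expect_error(bg_at_hours(sim, 5), "outside")
  expect_error(bg_at_hours(sim, -1), "outside")
})

test_that("an unstable parameterisation raises an integration failure naming the time", {
  p <- icing_params(n_I = 1e7)   # pathological transport rate blows up RK4
  st <- init_state(8, 65, p)
  sched <- input_schedule(insulin_boluses = data.frame(time_h = 0, units = 5),
                          enteral = data.frame(time_h = 0, pct_gf = 100),
                          goal_feed = 65)
  expect_error(simulate_icing(st, p, rep(5e-4, 2), sched, 2),
               "non-finite.*t = ")
})

test_that("input validation rejects malformed states, schedules and traces", {
  expect_error(icing_state(-1), "finite and >= 0")
  expect_error(input_schedule(enteral = data.frame(time_h = 0, pct_gf = 120)),
               "100")
  expect_error(input_schedule(insulin_boluses = data.frame(time_h = 0, units = -1)),
               "negative")
  st <- init_state(8, 65, fx_params)
  sched <- input_schedule(goal_feed = 65)
  expect_error(simulate_icing(st, fx_params, rep(5e-4, 2), sched, 4),
               "does not cover")
  expect_error(simulate_icing(st, fx_params, c(-1e-4, 5e-4), sched, 2),
               "non-negative")
})

test_that("parameter files round-trip and overrides apply", {
  p <- icing_params(EGP = 1.3)
  expect_equal(p[["EGP"]], 1.3)
  tmp <- tempfile(fileext = ".txt")
  write_icing_params(p, tmp)
  p2 <- icing_params(file = tmp)
  expect_equal(as.numeric(p2), as.numeric(p))
  expect_error(icing_params(nonsense = 2), "unknown")
  expect_error(icing_params(V_G = -1), "strictly positive")
})
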