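test_that("candidate grids honour caps, steps and floors", {
  cfg <- star_config(max_interval = 3)
  # maximum 2 U/h increase from any prior intervention, capped at 6 U/h
  c1 <- candidate_treatments(star_treatment(4, 100), cfg)
  expect_equal(max(c1$insulin), 6)
  c2 <- candidate_treatments(star_treatment(5.5, 100), cfg)
  expect_equal(max(c2$insulin), 6)   # insulin_max binds before +2
  # maximum decrease of 30 %GF over successive treatments
  expect_equal(min(c1$nutrition), 70)
  # the 30 %GF floor binds
  c3 <- candidate_treatments(star_treatment(2, 40, 1), cfg)
  expect_equal(min(c3$nutrition), 30)
  expect_equal(max(c3$nutrition), 100)
  # intervals 1..max_interval, list never empty, previous insulin legal
  expect_setequal(unique(c1$interval), 1:3)
  expect_true(4 %in% c1$insulin)
  expect_gt(nrow(c3), 0)
})

test_that("config validation enforces the printed constant ordering", {
  expect_error(star_config(band_lo = 9), "band_lo < band_hi")
  expect_error(star_config(max_interval = 7), "1..6")
  expect_silent(star_config(insulin_max = 8))
})

test_that("degenerate identity models collapse the BG band to the deterministic path", {
  p <- fx_params
  ms <- identity_models()
  st <- init_state(6.2, 65, p)
  iq <- eq_insulin(3, p)
  st$y[["I"]] <- iq[["I"]]; st$y[["Q"]] <- iq[["Q"]]
  trt <- star_treatment(3, 100, 3L)
  band <- predict_band(6.5e-4, trt, st, ms, p, 65)
  expect_lt(band$bg_high - band$bg_low, 0.2)
  # deterministic reference: constant-SI simulation under the same dosing
  sched <- input_schedule(insulin_boluses = data.frame(time_h = 0:2, units = 3),
                          enteral = data.frame(time_h = 0, pct_gf = 100),
                          goal_feed = 65)
  ref <- simulate_icing(st, p, rep(6.5e-4, 3), sched, 3)
  expect_lt(abs(band$bg_low - ref$G[nrow(ref)]), 0.2)
  expect_lt(abs(band$bg_high - ref$G[nrow(ref)]), 0.2)
})

test_that("with no predicted risk the longest interval is selected mid-band", {
  p <- fx_params
  ms <- identity_models()
  iq <- eq_insulin(2, p)
  st <- init_state(6.0, 65, p)
  st$y[["I"]] <- iq[["I"]]; st$y[["Q"]] <- iq[["Q"]]
  for (mi in c(3L, 6L)) {
    cfg <- star_config(max_interval = mi)
    sel <- select_treatment(6.5e-4, st, star_treatment(2, 100), ms, cfg, p, 65)
    expect_false(sel$fallback)
    expect_equal(sel$treatment$interval, mi)
    # the chosen treatment keeps the (collapsed) predicted band in band
    expect_gte(sel$band$bg_low, cfg$band_lo)
    expect_lte(sel$band$bg_high, cfg$band_hi + 0.1)
  }
})

test_that("band endpoints equal independent end-to-end re-simulation", {
  p <- fx_params
  w <- small_world()
  st <- init_state(8.5, 60, p)
  trt <- star_treatment(2.5, 85, 4L)
  band <- predict_band(6e-4, trt, st, w$models, p, 60)
  for (path in list(c("si_low_path", "bg_hourly_hi"),
                    c("si_high_path", "bg_hourly_lo"))) {
    sched <- input_schedule(
      insulin_boluses = data.frame(time_h = 0:3, units = 2.5),
      enteral = data.frame(time_h = 0, pct_gf = 85), goal_feed = 60)
    sim <- simulate_icing(st, p, band[[path[1]]], sched, 4)
    expect_equal(as.numeric(bg_at_hours(sim, 1:4)),
                 band[[path[2]]], tolerance = 1e-10)
  }
  expect_lte(band$bg_low, band$bg_high)
})

test_that("widening any horizon's percentile spread never narrows the BG band", {
  p <- fx_params
  w <- small_world()
  st <- init_state(8, 60, p)
  trt <- star_treatment(3, 90, 3L)
  band <- predict_band(6e-4, trt, st, w$models, p, 60)
  wider <- lapply(w$models, function(m) { m$sy <- m$sy * 2; m })
  band2 <- predict_band(6e-4, trt, st, wider, p, 60)
  expect_lte(band2$bg_low, band$bg_low + 1e-9)
  expect_gte(band2$bg_high, band$bg_high - 1e-9)
})

test_that("selection equals exhaustive enumeration with the documented objective", {
  p <- fx_params
  w <- small_world()
  cfg <- star_config(insulin_grid_step = 3, nutrition_grid_step = 35,
                     nutrition_step_down_max = 70, max_interval = 3)
  prev <- star_treatment(6, 100)
  st <- init_state(9, 65, p)
  iq <- eq_insulin(2, p)
  st$y[["I"]] <- iq[["I"]]; st$y[["Q"]] <- iq[["Q"]]
  si_now <- 6e-4

  sel <- select_treatment(si_now, st, prev, w$models, cfg, p, 65)

  # independent brute force over the 3 insulin x 3 nutrition x 3 interval
  # grid, reimplementing the documented admissibility and objective
  grid <- expand.grid(insulin = c(0, 3, 6), nutrition = c(30, 65, 100))
  found <- NULL
  for (L in 3:1) {
    cand <- NULL
    for (i in seq_len(nrow(grid))) {
      b <- predict_band(si_now, star_treatment(grid$insulin[i],
                                               grid$nutrition[i], L),
                        st, w$models, p, 65)
      ok <- all(b$bg_hourly_lo >= cfg$band_lo) &&
        (L == 1 || b$bg_high <= cfg$band_hi + cfg$avail_slack)
      if (!ok) next
      wdt <- b$bg_high - b$bg_low
      inter <- max(0, min(b$bg_high, cfg$band_hi) - max(b$bg_low, cfg$band_lo))
      ov <- if (wdt > 1e-9) inter / wdt
            else as.numeric((b$bg_low + b$bg_high) / 2 >= cfg$band_lo &&
                            (b$bg_low + b$bg_high) / 2 <= cfg$band_hi)
      dist <- max(0, cfg$band_lo - b$bg_high) + max(0, b$bg_low - cfg$band_hi)
      cand <- rbind(cand, data.frame(i = i, ov = ov, dist = dist,
                                     nut = grid$nutrition[i],
                                     ins = grid$insulin[i]))
    }
    if (!is.null(cand)) {
      cand <- cand[cand$nut == max(cand$nut), ]
      cand <- cand[order(-cand$ov, cand$dist, cand$ins), ]
      found <- list(insulin = cand$ins[1], nutrition = cand$nut[1],
                    interval = L)
      break
    }
  }
  expect_false(sel$fallback)
  expect_equal(sel$treatment$insulin, found$insulin)
  expect_equal(sel$treatment$nutrition, found$nutrition)
  expect_equal(sel$treatment$interval, found$interval)
})

test_that("ULC is a restriction: never a longer interval, never more nutrition", {
  p <- fx_params
  w <- small_world()
  iq <- eq_insulin(2, p)
  for (bg in c(7.5, 9, 11)) {
    st <- init_state(bg, 65, p)
    st$y[["I"]] <- iq[["I"]]; st$y[["Q"]] <- iq[["Q"]]
    prev <- star_treatment(2, 100)
    s_std <- select_treatment(7e-4, st, prev, w$models,
                              star_config(max_interval = 6), p, 65)
    s_ulc <- select_treatment(7e-4, st, prev, w$models,
                              star_config(max_interval = 6, ulc = TRUE), p, 65)
    expect_lte(s_ulc$treatment$interval, s_std$treatment$interval)
    expect_lte(s_ulc$treatment$nutrition, s_std$treatment$nutrition)
    if (!s_ulc$relaxed && !s_ulc$fallback)
      expect_lt(s_ulc$band$bg_high, 8.5)
  }
})

test_that("imminent predicted hypoglycaemia triggers the flagged safety fallback", {
  p <- fx_params
  w <- small_world()
  iq <- eq_insulin(4, p)
  st <- init_state(4.3, 65, p)     # below band floor, insulin on board
  st$y[["I"]] <- iq[["I"]]; st$y[["Q"]] <- iq[["Q"]]
  sel <- select_treatment(2e-3, st, star_treatment(4, 60), w$models,
                          star_config(max_interval = 3), p, 65)
  expect_true(sel$fallback)
  expect_equal(sel$treatment$interval, 1L)
  expect_gte(sel$treatment$nutrition, 60)      # feed raised toward 100 %GF
  expect_true(sel$treatment$insulin %in% c(0, 4))
})

test_that("a missing horizon model is a configuration error", {
  p <- fx_params
  w <- small_world()
  ms <- w$models[c("1", "2")]
  st <- init_state(8, 65, p)
  expect_error(predict_band(6e-4, star_treatment(2, 100, 3L), st, ms, p, 65),
               "horizon 3")
})
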