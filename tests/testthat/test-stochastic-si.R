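test_that("pair construction counts, flag exclusion and episode boundaries", {
  pr <- si_profile(rep(5e-4, 10), "A")
  expect_equal(nrow(make_si_pairs(pr, 1)), 9)
  expect_equal(nrow(make_si_pairs(pr, 6)), 4)

  flags <- rep("ok", 10); flags[6] <- "nonidentifiable"   # hour index 5
  prf <- si_profile(seq(4e-4, 8e-4, length.out = 10), "B", flags)
  p1 <- make_si_pairs(prf, 1)
  # pairs (4,5) and (5,6) are both absent: the flagged hour appears in
  # neither slot (profile values are distinct by construction)
  expect_equal(nrow(p1), 7)
  expect_false(prf$si[6] %in% p1$si_now)
  expect_false(prf$si[6] %in% p1$si_future)

  # never across episodes: two profiles give (n1-1) + (n2-1) pairs
  two <- list(si_profile(rep(5e-4, 5), "A"), si_profile(rep(6e-4, 5), "B"))
  expect_equal(nrow(make_si_pairs(two, 1)), 8)

  expect_error(make_si_pairs(si_profile(rep(5e-4, 3), "A"), 6),
               "horizon 6")
})

test_that("degenerate data concentrate the conditional at the data point", {
  cc <- 5e-4
  pairs <- data.frame(si_now = rep(cc, 200), si_future = rep(cc, 200),
                      horizon = 1, patient_id = "d")
  m <- fit_si_transition(pairs, min_pairs = 100)
  expect_true(all(m$sx == m$sigma_min))   # bandwidth floor engages on ties
  q <- conditional_percentiles(m, cc, c(5, 95))
  expect_true(all(abs(log(q) - log(cc)) <= m$sigma_min * qnorm(0.95) + 1e-9))
})

test_that("the conditional density integrates to one for every current SI", {
  m <- fit_si_transition(synth_pairs(800, seed = 2), min_pairs = 500)
  xs <- exp(seq(log(m$si_range[1]), log(m$si_range[2]), length.out = 50))
  ints <- vapply(xs, function(x) kde_cond_integral(m, x), 0)
  expect_lt(max(abs(ints - 1)), 1e-6)
})

test_that("density equals the direct double-loop kernel sum to machine precision", {
  m <- fit_si_transition(synth_pairs(300, seed = 3), min_pairs = 200)
  ys <- exp(seq(log(m$si_range[1] / 2), log(m$si_range[2] * 2),
                length.out = 40))
  for (x in c(3e-4, 6.5e-4, 1.1e-3)) {
    got <- conditional_density(m, x, ys)
    want <- kde_oracle_conditional(m, x, ys)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("percentiles match a large Monte-Carlo sample from the conditional", {
  m <- fit_si_transition(synth_pairs(1000, seed = 5), min_pairs = 500)
  for (x in c(3e-4, 6.5e-4, 1.2e-3)) {
    q <- conditional_percentiles(m, x, c(5, 95))
    draws <- simulate(m, 1e6, seed = 99, si_now = x)
    mc <- quantile(draws, c(0.05, 0.95), names = FALSE)
    expect_true(all(abs(q - mc) / mc < 0.005))
  }
})

test_that("percentiles are strictly increasing and flag extrapolation", {
  m <- fit_si_transition(synth_pairs(600, seed = 6), min_pairs = 500)
  q <- conditional_percentiles(m, 6e-4, c(5, 25, 50, 75, 95))
  expect_true(all(diff(q) > 0))
  far <- conditional_percentiles(m, m$si_range[2] * 50, c(5, 95))
  expect_true(isTRUE(attr(far, "extrapolation")))
  expect_true(all(is.finite(far)))
  expect_null(attr(conditional_percentiles(m, 6e-4, c(5, 95)), "extrapolation"))
  expect_error(conditional_percentiles(m, 6e-4, c(0, 95)), "0, 100")
})

test_that("a log-symmetric model centred on the identity line has median ~ si_now", {
  set.seed(8)
  x <- exp(rnorm(400, log(6e-4), 0.25))
  eps <- abs(rnorm(400, 0, 0.1))
  pairs <- data.frame(si_now = rep(x, 2),
                      si_future = c(x * exp(eps), x * exp(-eps)),
                      horizon = 1, patient_id = "s")
  m <- fit_si_transition(pairs, min_pairs = 500)
  med <- conditional_percentiles(m, 6e-4, 50)
  expect_lt(abs(log(med) - log(6e-4)), 0.02)
})

test_that("fitting is order-independent and refuses undersized training sets", {
  pairs <- synth_pairs(600, seed = 7)
  m1 <- fit_si_transition(pairs, min_pairs = 500)
  m2 <- fit_si_transition(pairs[sample(nrow(pairs)), ], min_pairs = 500)
  q1 <- conditional_percentiles(m1, 5e-4, c(5, 50, 95))
  q2 <- conditional_percentiles(m2, 5e-4, c(5, 50, 95))
  expect_equal(q1, q2, tolerance = 1e-10)
  expect_error(fit_si_transition(synth_pairs(100), min_pairs = 500),
               "at least 500")
})

test_that("percentile band width grows with horizon and its increments shrink", {
  # random-walk traces: variance grows linearly in the horizon, so the
  # 5th-95th band widens while consecutive-horizon increments converge
  set.seed(12)
  profiles <- lapply(1:40, function(i)
    si_profile(exp(cumsum(c(log(6.5e-4) + rnorm(1, 0, 0.1),
                            rnorm(39, 0, 0.12)))), sprintf("P%02d", i)))
  widths <- vapply(1:6, function(h) {
    m <- fit_si_transition(make_si_pairs(profiles, h), min_pairs = 200)
    xs <- exp(seq(log(4e-4), log(1e-3), length.out = 20))
    median(vapply(xs, function(x) {
      q <- conditional_percentiles(m, x, c(5, 95))
      log(q[2]) - log(q[1])
    }, 0))
  }, 0)
  expect_true(all(diff(widths) > -1e-9))        # non-decreasing in horizon
  expect_lt(widths[6] - widths[5], widths[2] - widths[1])  # converging
})

test_that("cross-validation folds partition patients and never leak", {
  profiles <- lapply(1:100, function(i)
    si_profile(exp(log(6.5e-4) + cumsum(rnorm(20, 0, 0.1))),
               sprintf("P%03d", i)))
  set <- fit_si_transitions(profiles, horizons = 1:2, folds = 5, seed = 9,
                            min_pairs = 50)
  test_sets <- lapply(set$folds, `[[`, "test_patients")
  expect_true(all(lengths(test_sets) == 20))
  for (f in set$folds) {
    expect_length(intersect(f$train_patients, f$test_patients), 0)
    expect_length(f$train_patients, 80)
    expect_false(any(vapply(f$models, is.null, TRUE)))
  }
  all_test <- unlist(test_sets)
  expect_length(all_test, 100)
  expect_false(any(duplicated(all_test)))
  # fold/horizon named error on insufficient data
  expect_error(fit_si_transitions(profiles[1:5], horizons = 1, folds = 5,
                                  min_pairs = 500),
               "fold 1, horizon 1")
})

test_that("model archives reload bit-exactly", {
  m <- fit_si_transition(synth_pairs(600, seed = 10), min_pairs = 500)
  tmp <- tempfile(fileext = ".json")
  save_transition_models(m, tmp)
  m2 <- load_transition_models(tmp)
  for (f in c("cx", "cy", "sx", "sy", "px", "py", "grid", "si_range"))
    expect_identical(m2[[f]], m[[f]])
  expect_identical(conditional_percentiles(m2, 6e-4, c(5, 95)),
                   conditional_percentiles(m, 6e-4, c(5, 95)))
})
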