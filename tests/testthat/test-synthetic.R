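test_that("default design matches the 8-sensor, 12-class experiment shape", {
  cfg <- default_design()
  ds <- generate_features(cfg)
  expect_equal(n_measurements(ds), 240)
  expect_equal(n_sensors(ds), 8)
  expect_equal(n_classes(ds), 12)
  expect_equal(sum(!ds$irrelevant), 180)
  expect_equal(sum(ds$irrelevant), 60)

  ds1 <- generate_features(default_design(reps_per_class = 1))
  expect_equal(n_measurements(ds1), 12)
})

test_that("default profiles keep sensors 1-2 small and 3-8 class-varying", {
  cfg <- default_design()
  sig <- t(sapply(cfg$trained_profiles, `[[`, "mean_signature"))
  expect_lt(max(sig[, 1:2]), 0.5)
  expect_gt(min(apply(sig[, 3:8], 2, function(v) diff(range(v)))), 0.3)
  # physically plausible scale: below the 5 V supply at the defaults
  expect_lt(max(sig), 5)
})

test_that("time series follow the first-order rise with seeded noise", {
  p <- class_profile(c(2, 3), c(0, 0), c(0.5, 0.5), tau = 10)
  s <- generate_time_series(p, duration = 100, rate = 5, seed = 1)
  expect_equal(as.numeric(s[nrow(s), ]), p$mean_signature, tolerance = 0.01)

  s2 <- generate_time_series(p, duration = 10, rate = 100, seed = 1)
  i <- which.min(abs(attr(s2, "time") - 10))  # t = tau
  frac <- unname((s2[i, 1] - 0.5) / (2 - 0.5))
  expect_equal(frac, 1 - exp(-1), tolerance = 1e-3)

  pn <- class_profile(c(2, 3), c(0.1, 0.1), c(0.5, 0.5), tau = 10)
  expect_identical(generate_time_series(pn, 5, 10, seed = 42),
                   generate_time_series(pn, 5, 10, seed = 42))
  expect_error(generate_time_series(p, -1, 10), "duration")
  expect_error(generate_time_series(p, 10, 0), "rate")
})

test_that("steady-state features average the trailing window", {
  const <- matrix(3.3, 50, 4)
  expect_equal(steady_state_features(const, 0.2), rep(3.3, 4))

  s <- matrix(seq_len(10), 10, 1)
  expect_equal(unname(steady_state_features(s, 1)), mean(1:10))

  # noise-free exponential, duration 10 tau: windowed mean vs closed form
  p <- class_profile(c(2, 4), c(0, 0), c(0.2, 0.4), tau = 5)
  s3 <- generate_time_series(p, duration = 50, rate = 20, seed = 1)
  f <- steady_state_features(s3, 0.2)
  tt <- attr(s3, "time")
  keep <- tail(seq_along(tt), ceiling(0.2 * length(tt)))
  expected <- p$baseline + (p$mean_signature - p$baseline) *
    mean(1 - exp(-tt[keep] / p$tau))
  expect_equal(as.numeric(f), expected, tolerance = 1e-12)
  expect_equal(as.numeric(f), p$mean_signature, tolerance = 0.005)

  expect_error(steady_state_features(matrix(numeric(0), 0, 2)), "empty")
})

test_that("feature generation is a pure, correctly dispersed function of the config", {
  cfg <- default_design(seed = 5)
  expect_identical(generate_features(cfg), generate_features(cfg))

  # zero dispersion collapses every row onto its class mean
  prof0 <- lapply(default_design()$trained_profiles[1:3], function(p) {
    p$dispersion <- rep(0, 8); p
  })
  cfg0 <- generator_config(prof0, reps_per_class = 4, seed = 2)
  ds0 <- generate_features(cfg0)
  for (m in 1:3)
    expect_equal(max(abs(sweep(ds0$features[ds0$labels == m, ], 2,
                               prof0[[m]]$mean_signature))), 0)

  # law of large numbers: class sample means near the signature at reps 1000
  cfg_big <- default_design(reps_per_class = 1000, seed = 3)
  ds_big <- generate_features(cfg_big)
  for (m in c(1, 5, 9)) {
    p <- cfg_big$trained_profiles[[m]]
    se <- p$dispersion / sqrt(1000)
    mu_hat <- colMeans(ds_big$features[ds_big$labels == m, ])
    expect_true(all(abs(mu_hat - p$mean_signature) < 3 * se + 1e-12))
  }
})

test_that("enforce_separation pushes every irrelevant sample outside every box", {
  fx <- make_openset_fixture(seed = 1, margin = 3)
  Q <- fx$boxes$Q; V <- fx$boxes$V
  for (r in seq_len(nrow(fx$irrelevant_X)))
    expect_false(inside_any_box(fx$irrelevant_X[r, ], Q, V))
  expect_equal(nrow(fx$irrelevant_X), 60)
})

test_that("separation margin is monotone and margin 0 is refused", {
  cfg <- default_design(seed = 2)
  ds0 <- generate_features(cfg)
  trained0 <- ds_subset(ds0, which(!ds0$irrelevant))
  boxes <- fit_mmm(trained0)
  min_dist <- sapply(c(1, 2, 3), function(margin) {
    cfg2 <- enforce_separation(cfg, boxes, margin = margin)
    ds <- generate_features(cfg2)
    irr <- ds$features[ds$irrelevant, , drop = FALSE]
    # min over rows of (min over classes of the largest sensor exceedance)
    min(apply(irr, 1, function(x)
      min(sapply(seq_len(nrow(boxes$Q)), function(m)
        max(pmax(boxes$V[m, ] - x, x - boxes$Q[m, ]))))))
  })
  expect_true(all(diff(min_dist) > 0))
  expect_error(enforce_separation(cfg, boxes, margin = 0), "separation error")
})
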