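test_that("canonical HRF peaks at the requested time with unit maximum", {
  h <- canonical_hrf(20, fs = 10, peak_s = 6)
  expect_equal(max(h), 1)
  expect_lt(abs((which.max(h) - 1) / 10 - 6), 0.1 + 1e-9)  # within 1 sample
  expect_true(all(canonical_hrf(20, 10, 6, undershoot_ratio = 0) >= 0))
  expect_lt(h[length(h)], 0.05)  # decays toward 0
  expect_error(canonical_hrf(4, 10, peak_s = 5), "duration")
})

test_that("canonical HRF integral matches a quadrature oracle", {
  fs <- 10
  h <- canonical_hrf(30, fs = fs)  # defaults: peak 5 s, undershoot 1/6
  disc <- (sum(h) - (h[1] + h[length(h)]) / 2) / fs  # trapezoid
  # oracle: adaptive quadrature of the closed-form curve at 10x resolution
  hi_fs <- 10 * fs
  grid <- seq(0, 30, by = 1 / hi_fs)
  raw <- function(t) dgamma(t, shape = 6, rate = 1) -
    (1 / 6) * dgamma(t, shape = 16, rate = 1)
  peak <- max(raw(grid))
  oracle <- integrate(function(t) raw(t) / peak, 0, 30, rel.tol = 1e-10)$value
  expect_lt(abs(disc - oracle) / oracle, 1e-3)
})

test_that("the generator is deterministic and respects its seed", {
  ep <- epoch_definition(2, 12, 10, fs = 4)
  spec <- simulation_spec(n_per_cell = 2, epoch = ep, n_channels = 4,
                          n_trials = 2, seed = 11)
  s1 <- simulate_dataset(spec)
  s2 <- simulate_dataset(spec)
  expect_identical(s1$recordings[[1]]$hbo, s2$recordings[[1]]$hbo)
  expect_identical(s1$recordings[[8]]$hbo, s2$recordings[[8]]$hbo)
  spec2 <- simulation_spec(n_per_cell = 2, epoch = ep, n_channels = 4,
                           n_trials = 2, seed = 12)
  expect_false(identical(simulate_dataset(spec2)$recordings[[1]]$hbo,
                         s1$recordings[[1]]$hbo))
})

test_that("growing the design keeps existing subjects' substreams", {
  ep <- epoch_definition(2, 12, 10, fs = 4)
  small <- simulate_dataset(simulation_spec(n_per_cell = 1, epoch = ep,
                                            n_channels = 4, n_trials = 2,
                                            seed = 5))
  big <- simulate_dataset(simulation_spec(n_per_cell = 2, epoch = ep,
                                          n_channels = 4, n_trials = 2,
                                          seed = 5))
  expect_identical(small$recordings[[1]]$hbo, big$recordings[[1]]$hbo)
})

test_that("a noiseless planted main effect reproduces its amplitude", {
  ep <- epoch_definition(2, 12, 6, fs = 10)
  eff <- effect_spec("main_a", channels = c("ch02", "ch03"),
                     window_s = c(4, 8), amplitude_delta = 2)
  spec <- simulation_spec(n_per_cell = 2, epoch = ep, n_channels = 4,
                          n_trials = 3, effects = list(eff), noise_sd = 0,
                          drift_amp = 0, seed = 2)
  sim <- simulate_dataset(spec)
  hrfs <- unlist(lapply(sim$recordings, build_hrf, epoch = ep,
                        design = sim$design), recursive = FALSE)
  la <- vapply(hrfs, `[[`, "", "level_a")
  mean_a1 <- Reduce(`+`, lapply(hrfs[la == "a1"], `[[`, "hrf")) / sum(la == "a1")
  mean_a2 <- Reduce(`+`, lapply(hrfs[la == "a2"], `[[`, "hrf")) / sum(la == "a2")
  diff <- mean_a1 - mean_a2
  # peak difference equals amplitude_delta in planted channels
  expect_equal(max(diff[, "ch02"]), 2, tolerance = 1e-10)
  expect_equal(max(diff[, "ch03"]), 2, tolerance = 1e-10)
  # peak sits at the window center
  expect_equal(ep$times[which.max(diff[, "ch02"])], 6, tolerance = 0.11)
  # zero difference in unplanted channels
  expect_lt(max(abs(diff[, c("ch01", "ch04")])), 1e-10)
})

test_that("planting an effect moves signal only into the named channels", {
  ep <- epoch_definition(2, 12, 6, fs = 4)
  base <- simulation_spec(n_per_cell = 1, epoch = ep, n_channels = 4,
                          n_trials = 2, seed = 9)
  effA <- simulation_spec(n_per_cell = 1, epoch = ep, n_channels = 4,
                          n_trials = 2, seed = 9,
                          effects = list(effect_spec("main_a", "ch01",
                                                     c(3, 7), 1)))
  effB <- simulation_spec(n_per_cell = 1, epoch = ep, n_channels = 4,
                          n_trials = 2, seed = 9,
                          effects = list(effect_spec("main_a", "ch03",
                                                     c(3, 7), 1)))
  h0 <- simulate_dataset(base)$recordings[[1]]$hbo
  hA <- simulate_dataset(effA)$recordings[[1]]$hbo
  hB <- simulate_dataset(effB)$recordings[[1]]$hbo
  expect_identical(hA[2:4, ], h0[2:4, ])
  expect_identical(hB[c(1, 2, 4), ], h0[c(1, 2, 4), ])
  expect_equal(hA[1, ] - h0[1, ], hB[3, ] - h0[3, ], tolerance = 1e-12)
})

test_that("effect specs are validated against channels and windows", {
  ep <- epoch_definition(2, 12, 6, fs = 4)
  expect_error(simulation_spec(epoch = ep, n_channels = 4,
                               effects = list(effect_spec("main_a", "ch09",
                                                          c(3, 7), 1))),
               "nonexistent")
  expect_error(simulation_spec(epoch = ep, n_channels = 4,
                               effects = list(effect_spec("main_a", "ch01",
                                                          c(3, 14), 1))),
               "stimulus period")
  expect_error(effect_spec("interaction", "ch01", c(3, 7), 1,
                           cell_pattern = matrix(c(1, 1, 1, 1), 2)),
               "non-additive")
})

test_that("a mixed design presents within-levels in blocks", {
  ep <- epoch_definition(2, 12, 6, fs = 4)
  sim <- simulate_dataset(simulation_spec(n_per_cell = 2, epoch = ep,
                                          n_channels = 4, n_trials = 6,
                                          scope_a = "within", seed = 4))
  expect_length(sim$recordings, 4L)
  on <- sim$recordings[[1]]$trial_onsets
  expect_equal(on$level_a, rep(c("a1", "a2"), each = 3))
  expect_equal(length(unique(on$level_b)), 1L)
})
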