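test_that("analytic occupancies follow the closed form and sum to 1", {
  cfg <- markov_config(deltaH = 31000, deltaS = 108, pi_I = 0.6)
  # K = 1 exactly at T = deltaH/deltaS: symmetric split of the bonded mass
  Tsym <- 31000 / 108
  o <- analytic_occupancies(Tsym, cfg)
  expect_equal(unname(o["W"]), unname(o["Y"]))
  expect_equal(unname(o["W"]), (1 - 0.6) / 2, tolerance = 1e-12)
  expect_equal(sum(o), 1, tolerance = 1e-15)

  # direct evaluation against independent arithmetic at 240 K
  K <- exp(-31000 / (8.314462618 * 240) + 108 / 8.314462618)
  o240 <- analytic_occupancies(240, cfg)
  expect_equal(unname(o240["W"]), 0.4 / (1 + K), tolerance = 1e-12)
  expect_equal(unname(o240["Y"] / o240["W"]), K, tolerance = 1e-12)

  # strongly Y-favouring limit: almost all non-intermediate mass on Y
  cfg2 <- markov_config(deltaH = 0, deltaS = 500, pi_I = 0.01)
  oY <- analytic_occupancies(300, cfg2)
  expect_gt(unname(oY["Y"]), 0.98)
})

test_that("the stationary distribution is the transition-matrix eigenvector", {
  for (tt in c(245, 293, 323)) {
    cfg <- markov_config(temperature = tt)
    P <- transition_matrix(cfg)
    expect_equal(rowSums(P), c(W = 1, I = 1, Y = 1), tolerance = 1e-15)
    expect_equal(P["W", "Y"], 0)
    expect_equal(P["Y", "W"], 0)
    ev <- eigen(t(P))
    i <- which.min(abs(ev$values - 1))
    stat <- Re(ev$vectors[, i]); stat <- stat / sum(stat)
    expect_equal(unname(analytic_occupancies(tt, cfg)), stat,
                 tolerance = 1e-10)
  }
  expect_error(transition_matrix(markov_config(pi_I = 0.001,
                                               mean_dwell_ns = 0.15)),
               "infeasible")
  expect_error(markov_config(pi_I = 1), "pi_I")
})

test_that("the same seed reproduces structures and trajectories bit-identically", {
  a <- generate_structure_series(fixture_config(seed = 3))
  b <- generate_structure_series(fixture_config(seed = 3))
  expect_identical(lapply(a, write_pdb), lapply(b, write_pdb))
  s1 <- simulate_three_state_markov(markov_config(seed = 9,
                                                  n_frames = 5000))
  s2 <- simulate_three_state_markov(markov_config(seed = 9,
                                                  n_frames = 5000))
  expect_identical(s1$traceW$values, s2$traceW$values)
  expect_identical(s1$states, s2$states)
})

test_that("empirical occupancies converge to the stationary distribution", {
  # short dwell keeps the autocorrelation time tau ~ 10 frames, so the
  # correlation-corrected sd sqrt(pi (1-pi) 2 tau / n) is tight
  cfg <- markov_config(temperature = 293, mean_dwell_ns = 1,
                       frame_interval_ns = 0.1, n_frames = 5e4, seed = 8)
  sim <- simulate_three_state_markov(cfg)
  pi <- sim$stationary
  emp <- as.numeric(table(sim$states)) / cfg$n_frames
  tau <- cfg$mean_dwell_ns / cfg$frame_interval_ns
  for (k in 1:3) {
    sd_k <- sqrt(pi[k] * (1 - pi[k]) * 2 * tau / cfg$n_frames)
    expect_lt(abs(emp[k] - pi[k]), 3 * sd_k)
  }
})

test_that("detailed balance holds for the simulated chain", {
  cfg <- markov_config(temperature = 280, mean_dwell_ns = 1,
                       frame_interval_ns = 0.1, n_frames = 5e4, seed = 13)
  sim <- simulate_three_state_markov(cfg)
  s <- as.character(sim$states)
  from <- s[-length(s)]; to <- s[-1]
  n_wi <- sum(from == "W" & to == "I")
  n_iw <- sum(from == "I" & to == "W")
  expect_lt(abs(n_wi - n_iw), 3 * sqrt(n_wi + n_iw))
  n_yi <- sum(from == "Y" & to == "I")
  n_iy <- sum(from == "I" & to == "Y")
  expect_lt(abs(n_yi - n_iy), 3 * sqrt(n_yi + n_iy))
  expect_equal(sum(from == "W" & to == "Y"), 0)  # no direct W-Y hops
})

test_that("generated structures pass cleanly through the full pipeline", {
  ms <- fixture_series_cached()
  expect_equal(length(ms), 12)
  # every model re-parses with zero warnings
  expect_no_warning({
    reparsed <- lapply(ms, function(m) {
      parse_pdb(write_pdb(m), temperature = m$temperature)
    })
  })
  # programmed features, measured by the analysis modules
  hb <- detect_hbonds(reparsed[[1]])
  d <- hb$distance[(hb$donor_resseq == 19 & hb$acceptor_resseq == 37) |
                     (hb$donor_resseq == 37 & hb$acceptor_resseq == 19)]
  expect_equal(d, 2.88, tolerance = 1e-9)
  zn <- coordination_stats(reparsed[[1]], list(resseq = 90, name = "ZN"),
                           list(name = "SG"))
  expect_equal(round(zn$mean, 2), 2.34)
  expect_equal(water_count(reparsed[[1]]),
               fixture_water_count(100, fixture_config()))
  # no clashes by construction
  cfg <- fixture_config()
  for (m in ms[c(1, 12)]) {
    expect_gte(rdtherm:::.min_nonbonded_distance(m), 1.0)
  }
})

test_that("fixture files and manifest round trip through disk", {
  dir <- withr::local_tempdir()
  cfg <- fixture_config(temperatures = c(100, 260, 393))
  ms <- generate_structure_series(cfg)
  write_fixture_series(ms, dir, cfg)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_fixture_series(file.path(dir, "manifest.json"))
  expect_equal(length(back), 3)
  expect_equal(vapply(back, `[[`, 0, "temperature"), c(100, 260, 393),
               ignore_attr = TRUE)
  expect_equal(nrow(back[[1]]$atoms), nrow(ms[[1]]$atoms))
})

test_that("the programmed volume series encodes the coherent slope pair", {
  s <- generate_volume_series(fixture_config())
  expect_equal(nrow(s), 12)
  fit <- expansion_fit(s)
  expect_equal(fit$slope, 0.48, tolerance = 1e-12)
  expect_equal(fit$relative_slope_pct_per_100K, 0.6, tolerance = 1e-9)
})
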