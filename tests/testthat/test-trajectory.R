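test_that("distance traces are extracted from frames and tables", {
  f1 <- bare_model(rbind(c(0, 0, 0), c(3, 0, 0)), c("NE1", "OH"),
                   resname = c("TRP", "TYR"), resseq = c(37, 11),
                   element = c("N", "O"), temperature = 253)
  f2 <- f1
  f2$atoms$x[2] <- 5
  tr <- extract_distance_trace(list(f1, f2), list(resseq = 37),
                               list(resseq = 11))
  expect_equal(tr$values, c(3, 5))
  expect_equal(tr$temperature, 253)

  tab <- data.frame(frame = 1:3, distance = c(2.9, 3.1, 6.0))
  expect_equal(extract_distance_trace(tab, temperature = 253)$values,
               c(2.9, 3.1, 6.0))
})

test_that("a carboxylate oxygen pair is reduced by the minimum rule", {
  f <- bare_model(rbind(c(2.9, 0, 0), c(-4.5, 0, 0), c(0, 0, 0)),
                  c("OD1", "OD2", "NE1"),
                  resname = c("ASP", "ASP", "TRP"),
                  resseq = c(19, 19, 37), element = c("O", "O", "N"))
  tr <- extract_distance_trace(list(f), list(resseq = 19, name = "OD*"),
                               list(resseq = 37))
  expect_equal(tr$values, 2.9)
  # any other multi-atom selection is ambiguous
  f2 <- bare_model(rbind(c(0, 0, 0), c(1, 0, 0), c(5, 0, 0)),
                   c("OG", "OG", "NE1"), resname = c("SER", "SER", "TRP"),
                   resseq = c(1, 2, 37), element = c("O", "O", "N"))
  expect_error(extract_distance_trace(list(f2), list(name = "OG"),
                                      list(resseq = 37)), "ambiguous")
})

test_that("three-state classification follows the cutoff rules", {
  mk <- function(w, y) classify_three_state(
    distance_trace(w, 253), distance_trace(y, 253))
  expect_equal(as.character(mk(2.9, 7)$states), "W")
  expect_equal(as.character(mk(7, 2.9)$states), "Y")
  expect_equal(as.character(mk(7, 7)$states), "I")
  # both within cutoff: closer partner wins, flagged ambiguous
  amb <- mk(3.0, 2.8)
  expect_equal(as.character(amb$states), "Y")
  expect_equal(amb$n_ambiguous, 1)

  dW <- c(2.9, 2.9, 7, 7, 7, 2.9, 7, 7, 2.9, 7)
  dY <- c(7, 7, 2.9, 7, 7, 7, 2.9, 7, 7, 2.9)
  s <- mk(dW, dY)
  expect_equal(unname(s$occupancies), c(4, 3, 3) / 10)
  expect_equal(sum(s$occupancies), 1)
  expect_error(mk(c(2.9, 2.9), 2.9), "mismatched")
})

test_that("the occupancy ratio is the two-state Y/W fraction", {
  s <- list(occupancies = c(W = 0.07, I = 0.64, Y = 0.29),
            temperature = 293)
  class(s) <- "state_series"
  expect_equal(occupancy_ratio(s), 0.29 / 0.07)
  s$occupancies <- c(W = 0.2, I = 0.6, Y = 0.2)
  expect_equal(occupancy_ratio(s), 1)
  s$occupancies <- c(W = 0.4, I = 0.6, Y = 0)
  expect_equal(occupancy_ratio(s), 0)
  s$occupancies <- c(W = 0, I = 0.6, Y = 0.4)
  expect_error(occupancy_ratio(s), "zero")
})

test_that("the van't Hoff estimator inverts analytic occupancies exactly", {
  temps <- c(245, 260, 275, 293, 308, 323)
  cfg <- markov_config(deltaH = 31000, deltaS = 108)
  K <- sapply(temps, function(tt) {
    o <- analytic_occupancies(tt, cfg)
    o["Y"] / o["W"]
  })
  fit <- vant_hoff_fit(data.frame(temperature = temps, K = K))
  expect_equal(fit$deltaH, 31000, tolerance = 1e-9)
  expect_equal(fit$deltaS, 108, tolerance = 1e-9)
  expect_lt(max(abs(fit$residuals)), 1e-12)

  flat <- vant_hoff_fit(data.frame(temperature = temps, K = rep(2, 6)))
  expect_equal(flat$deltaH, 0, tolerance = 1e-9)
  expect_error(vant_hoff_fit(data.frame(temperature = c(250, 300),
                                        K = c(1, 2))), "at least 3")
  expect_warning(
    fit2 <- vant_hoff_fit(data.frame(temperature = c(temps, 340),
                                     K = c(K, 0))), "K <= 0")
  expect_equal(fit2$deltaH, 31000, tolerance = 1e-9)
})

test_that("dwell times average maximal runs and flag censoring", {
  s <- structure(list(states = factor(c("W", "W", "W", "Y", "Y", "Y"),
                                      levels = c("W", "I", "Y")),
                      interval_ns = 1), class = "state_series")
  d <- dwell_times(s)
  expect_equal(d$mean_dwell_ns[d$state == "W"], 3)
  expect_equal(d$mean_dwell_ns[d$state == "Y"], 3)
  expect_equal(d$n_censored, c(1, 1))

  one <- structure(list(states = factor(rep("I", 5),
                                        levels = c("W", "I", "Y")),
                        interval_ns = 0.1), class = "state_series")
  d1 <- dwell_times(one)
  expect_equal(d1$n_runs, 1)
  expect_equal(d1$n_censored, 1)
})

test_that("simulated dwell times match the generating exit rate", {
  cfg <- markov_config(temperature = 293, mean_dwell_ns = 2,
                       frame_interval_ns = 0.1, n_frames = 4e4, seed = 5)
  sim <- simulate_three_state_markov(cfg)
  s <- classify_three_state(sim$traceW, sim$traceY)
  # classification recovers the simulated states essentially perfectly,
  # so dwell in the bonded states estimates the geometric mean dwell
  d <- dwell_times(s)
  for (st in c("W", "Y")) {
    row <- d[d$state == st, ]
    runs <- rle(as.character(s$states))
    lens <- runs$lengths[runs$values == st]
    se <- sd(lens) / sqrt(length(lens)) * cfg$frame_interval_ns
    expect_lt(abs(row$mean_dwell_ns - 2), 3 * se + 1e-9)
  }
})

test_that("RMSF separates a fluctuating atom after superposition", {
  set.seed(41)
  base <- matrix(rnorm(30, sd = 4), 10, 3)
  frames <- list(base, base, base)
  p <- rmsf_profile(frames)
  expect_equal(p$rmsf, rep(0, 10), tolerance = 1e-10)

  # atom 1 oscillating +/-1 A along x: after mean-centring the fit, the
  # moving atom keeps (n-1)/n of the motion and the rest absorb 1/n;
  # placing atom 1 at the centroid of the rest removes any rotational
  # absorption, so the translation-only closed form is exact
  base[1, ] <- colMeans(base[-1, ])
  osc <- lapply(c(1, -1, 1, -1), function(s) {
    f <- base
    f[1, 1] <- f[1, 1] + s
    f
  })
  n <- 10
  p2 <- rmsf_profile(osc)
  expect_equal(p2$rmsf[1], (n - 1) / n, tolerance = 0.02)
  expect_equal(p2$rmsf[-1], rep(1 / n, n - 1), tolerance = 0.02)

  # a global rigid motion of every frame changes nothing
  R <- random_rotation()
  moved <- lapply(osc, function(f) sweep(f %*% t(R), 2, c(9, -3, 4), `+`))
  expect_equal(rmsf_profile(moved)$rmsf, p2$rmsf, tolerance = 1e-8)

  # rigid-body-moved copies of one frame are flat after superposition
  copies <- lapply(1:3, function(i) {
    sweep(base %*% t(random_rotation()), 2, rnorm(3, sd = 5), `+`)
  })
  expect_lt(max(rmsf_profile(copies)$rmsf), 1e-8)
})
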