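#' Configuration for the three-state Markov trajectory generator
#'
#' Ground-truth model for synthetic partner-exchange trajectories: a
#' discrete-time Markov chain on the states W (W37-bonded), I (both bonds
#' broken) and Y (Y11-bonded), with transitions only through the
#' intermediate (no direct W-Y exchange: the carboxylate must break one
#' H-bond before forming the other). The stationary distribution puts mass
#' `pi_I` on the intermediate — the scatter-plot analyses motivating this
#' generator show roughly 50-70% broken-bond frames, hence the 0.6
#' default — and splits the remainder between Y and W according to the
#' van't Hoff law `pi_Y / pi_W = exp(-deltaH/(R T) + deltaS/R)`.
#'
#' Emission model: the distance to the bonded partner is drawn from a
#' normal with mean 2.9 and sd 0.15 angstrom truncated below at 2.4; a
#' broken-partner distance from a normal with mean 6.5 and sd 1.0
#' truncated below at 4.0.
#'
#' @param temperature kelvin.
#' @param deltaH enthalpy difference, J/mol (default 31000).
#' @param deltaS entropy difference, J/K/mol (default 108).
#' @param pi_I stationary intermediate fraction in (0, 1) (default 0.6).
#' @param mean_dwell_ns mean dwell time of the bonded states (default 100).
#' @param frame_interval_ns frame spacing (default 0.1).
#' @param n_frames frames to simulate (default 1e5).
#' @param emission list with `bonded_mean`, `bonded_sd`, `bonded_min`,
#'   `unbonded_mean`, `unbonded_sd`, `unbonded_min` (angstrom).
#' @param seed integer seed.
#' @return a list of class `markov_config`.
#' @export
markov_config <- function(temperature = 293, deltaH = 31000, deltaS = 108,
                          pi_I = 0.6, mean_dwell_ns = 100,
                          frame_interval_ns = 0.1, n_frames = 1e5,
                          emission = list(bonded_mean = 2.9,
                                          bonded_sd = 0.15,
                                          bonded_min = 2.4,
                                          unbonded_mean = 6.5,
                                          unbonded_sd = 1.0,
                                          unbonded_min = 4.0),
                          seed = 1) {
  if (!(pi_I > 0 && pi_I < 1)) stop("pi_I must lie strictly in (0, 1)")
  stopifnot(temperature > 0, mean_dwell_ns > 0, frame_interval_ns > 0,
            n_frames >= 1)
  structure(list(temperature = temperature, deltaH = deltaH,
                 deltaS = deltaS, pi_I = pi_I,
                 mean_dwell_ns = mean_dwell_ns,
                 frame_interval_ns = frame_interval_ns,
                 n_frames = as.integer(n_frames), emission = emission,
                 seed = seed), class = "markov_config")
}

#' Analytic three-state occupancies under the van't Hoff law
#'
#' Closed form for the generator's stationary occupancies:
#' `pi_I` is the configured intermediate fraction and, with
#' `K = exp(-deltaH/(R T) + deltaS/R)`,
#' `pi_Y = (1 - pi_I) K / (1 + K)` and `pi_W = (1 - pi_I) / (1 + K)`.
#' Sums to 1 exactly.
#'
#' @param temperature kelvin.
#' @param config a [markov_config()] (its `temperature` field is ignored in
#'   favour of the argument).
#' @return named numeric vector `c(W=, I=, Y=)`.
#' @export
analytic_occupancies <- function(temperature, config = markov_config()) {
  K <- exp(-config$deltaH / (R_GAS * temperature) + config$deltaS / R_GAS)
  w <- (1 - config$pi_I) / (1 + K)
  c(W = w, I = config$pi_I, Y = w * K)
}

#' Transition matrix of the three-state chain
#'
#' Per-frame transition probabilities on (W, I, Y). The bonded states exit
#' to I with probability `q = frame_interval / mean_dwell`; the
#' intermediate's exits are set by detailed balance against the stationary
#' distribution, `P(I->W) = pi_W q / pi_I` and `P(I->Y) = pi_Y q / pi_I`.
#' There is no direct W-Y element.
#'
#' @param config a [markov_config()].
#' @return 3x3 row-stochastic matrix with dimnames (W, I, Y).
#' @export
transition_matrix <- function(config) {
  stopifnot(inherits(config, "markov_config"))
  pi <- analytic_occupancies(config$temperature, config)
  q <- config$frame_interval_ns / config$mean_dwell_ns
  if (q >= 1) stop("frame interval must be smaller than the mean dwell")
  b <- unname(pi["W"]) * q / config$pi_I
  cc <- unname(pi["Y"]) * q / config$pi_I
  if (b + cc >= 1) {
    stop("infeasible: intermediate exit probabilities exceed 1; ",
         "increase pi_I or mean_dwell_ns")
  }
  P <- matrix(c(1 - q, q, 0,
                b, 1 - b - cc, cc,
                0, q, 1 - q), nrow = 3, byrow = TRUE,
              dimnames = list(c("W", "I", "Y"), c("W", "I", "Y")))
  P
}

# inverse-cdf truncated normal draws (lower truncation only)
.rtnorm <- function(n, mean, sd, lower) {
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, p0, 1), mean, sd)
}

# sample per-frame (d_W, d_Y) given a state vector
.emit_distances <- function(states, em) {
  n <- length(states)
  dW <- .rtnorm(n, em$unbonded_mean, em$unbonded_sd, em$unbonded_min)
  dY <- .rtnorm(n, em$unbonded_mean, em$unbonded_sd, em$unbonded_min)
  w <- states == "W"; y <- states == "Y"
  dW[w] <- .rtnorm(sum(w), em$bonded_mean, em$bonded_sd, em$bonded_min)
  dY[y] <- .rtnorm(sum(y), em$bonded_mean, em$bonded_sd, em$bonded_min)
  list(dW = dW, dY = dY)
}

#' Simulate a three-state Markov distance trajectory
#'
#' Draws the initial state from the stationary distribution, simulates the
#' W-I-Y chain of [transition_matrix()] by alternating geometric dwell
#' segments, and emits per-frame (d_W, d_Y) distances from the
#' state-conditional emission model. Bit-reproducible given the seed.
#'
#' @param config a [markov_config()].
#' @return list with `states` (factor, per frame), `traceW`, `traceY`
#'   ([distance_trace()] objects), `config`, and `stationary` (the analytic
#'   occupancies).
#' @export
simulate_three_state_markov <- function(config = markov_config()) {
  stopifnot(inherits(config, "markov_config"))
  set.seed(config$seed)
  P <- transition_matrix(config)
  pi <- analytic_occupancies(config$temperature, config)
  n <- config$n_frames
  lab <- c("W", "I", "Y")

  st <- character(0)
  cur <- sample(lab, 1, prob = pi)
  total <- 0L
  while (total < n) {
    exit_p <- 1 - P[cur, cur]
    dwell <- stats::rgeom(1, exit_p) + 1L
    dwell <- min(dwell, n - total)
    st <- c(st, rep(cur, dwell))
    total <- total + dwell
    if (total >= n) break
    nxt <- P[cur, ]; nxt[cur] <- 0
    cur <- sample(lab, 1, prob = nxt)
  }
  states <- factor(st[seq_len(n)], levels = lab)
  em <- .emit_distances(states, config$emission)
  list(states = states,
       traceW = distance_trace(em$dW, config$temperature, "dW",
                               config$frame_interval_ns),
       traceY = distance_trace(em$dY, config$temperature, "dY",
                               config$frame_interval_ns),
       config = config, stationary = pi)
}

#' Simulate an i.i.d. state scatter with fixed occupancies
#'
#' Generates (d_W, d_Y) frames whose states are drawn independently from
#' the given fractions — the synthetic counterpart of a scatter-plot panel
#' whose occupancy percentages are known — using the same state-conditional
#' emission model as the Markov simulator.
#'
#' @param n_frames frames to draw.
#' @param fractions named fractions `c(W=, I=, Y=)` summing to 1.
#' @param temperature kelvin label for the traces.
#' @param emission emission model list (see [markov_config()]).
#' @param frame_interval_ns frame spacing.
#' @param seed integer seed.
#' @return list with `states`, `traceW`, `traceY`.
#' @export
simulate_state_scatter <- function(n_frames, fractions, temperature,
                                   emission = markov_config()$emission,
                                   frame_interval_ns = 0.1, seed = 1) {
  stopifnot(all(c("W", "I", "Y") %in% names(fractions)),
            abs(sum(fractions) - 1) < 1e-9)
  set.seed(seed)
  states <- factor(sample(c("W", "I", "Y"), n_frames, replace = TRUE,
                          prob = fractions[c("W", "I", "Y")]),
                   levels = c("W", "I", "Y"))
  em <- .emit_distances(states, emission)
  list(states = states,
       traceW = distance_trace(em$dW, temperature, "dW", frame_interval_ns),
       traceY = distance_trace(em$dY, temperature, "dY", frame_interval_ns))
}

#' Write a simulated trajectory as a distance TSV
#'
#' Columns: `frame`, `time_ns`, `d_W_A`, `d_Y_A`.
#'
#' @param sim output of [simulate_three_state_markov()] or
#'   [simulate_state_scatter()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_trajectory_tsv <- function(sim, path) {
  n <- length(sim$traceW$values)
  dt <- sim$traceW$interval_ns
  write_tsv(data.frame(frame = seq_len(n), time_ns = (seq_len(n) - 1) * dt,
                       d_W_A = sim$traceW$values,
                       d_Y_A = sim$traceY$values), path)
}
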