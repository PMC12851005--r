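#' Gas constant
#'
#' Molar gas constant, 8.314462618 J mol^-1 K^-1 (CODATA), used by every
#' thermodynamic expression in the package.
#' @export
R_GAS <- 8.314462618

#' Construct a distance trace
#'
#' A per-frame time series of one labeled atom-pair distance at one
#' temperature, the reduced form in which trajectories enter the analysis.
#'
#' @param values per-frame distances (angstrom), all > 0.
#' @param temperature kelvin.
#' @param label pair label, e.g. `"D19:Oc-W37:Ne"`.
#' @param interval_ns frame interval in nanoseconds.
#' @return object of class `distance_trace`.
#' @export
distance_trace <- function(values, temperature, label = "",
                           interval_ns = 0.1) {
  stopifnot(length(values) >= 1, all(is.finite(values)), all(values > 0),
            temperature > 0, interval_ns > 0)
  structure(list(values = as.numeric(values), temperature = temperature,
                 label = label, interval_ns = interval_ns),
            class = "distance_trace")
}

#' Extract a distance trace from coordinate frames or a distance table
#'
#' Two input forms are accepted. A data.frame with a distance column passes
#' through unchanged (a trajectory already reduced to distances). A list of
#' `structure_model` frames is reduced by resolving both selections in every
#' frame and recording the per-frame Euclidean distance. A selection
#' resolving to the two oxygens of one carboxylate (OD1/OD2 or OE1/OE2 of a
#' single residue) is legal and reduced by the minimum rule: the recorded
#' distance is the smaller of the two oxygen distances in each frame,
#' because a rotating carboxylate exchanges its oxygens without changing
#' the H-bond partner. Any other multi-atom selection is an error.
#'
#' @param frames list of `structure_model`, or a data.frame with a
#'   `distance` column (optionally `time_ns`).
#' @param pairA,pairB selection lists (see [select_atoms()]); ignored for
#'   table input.
#' @param temperature,label,interval_ns trace metadata (table input).
#' @return a `distance_trace`.
#' @export
extract_distance_trace <- function(frames, pairA = NULL, pairB = NULL,
                                   temperature = NULL, label = "",
                                   interval_ns = 0.1) {
  if (is.data.frame(frames)) {
    if (!"distance" %in% names(frames)) {
      stop("distance table must have a 'distance' column")
    }
    return(distance_trace(frames$distance,
                          temperature = temperature %||% 298,
                          label = label, interval_ns = interval_ns))
  }
  stopifnot(is.list(frames), length(frames) >= 1)
  carboxylate_ok <- function(sel) {
    nrow(sel) == 2 && length(unique(sel$resseq)) == 1 &&
      all(sort(sel$name) %in% list(c("OD1", "OD2"), c("OE1", "OE2")) [[
        if (all(sort(sel$name) == c("OD1", "OD2"))) 1 else 2]])
  }
  vals <- vapply(frames, function(m) {
    A <- do.call(select_atoms, c(list(m), pairA))
    B <- do.call(select_atoms, c(list(m), pairB))
    for (sel in list(A, B)) {
      if (nrow(sel) == 0) stop("pair selection resolves to no atoms")
      if (nrow(sel) > 1 && !carboxylate_ok(sel)) {
        stop("ambiguous selection (", nrow(sel),
             " atoms) is only allowed for one carboxylate oxygen pair")
      }
    }
    d <- sqrt(outer(seq_len(nrow(A)), seq_len(nrow(B)),
                    Vectorize(function(i, j) {
                      sum((as.numeric(.coords(A[i, ])) -
                           as.numeric(.coords(B[j, ])))^2)
                    })))
    min(d)
  }, 0)
  tt <- temperature %||% frames[[1]]$temperature
  distance_trace(vals, temperature = tt, label = label,
                 interval_ns = interval_ns)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify frames into W-bonded / intermediate / Y-bonded states
#'
#' Per-frame three-state classification from the two competing partner
#' distances: `W` when only the W-partner distance is within the cutoff,
#' `Y` when only the Y-partner distance is, `I` (intermediate, both H-bonds
#' broken) when neither is. Frames where both distances fall within the
#' cutoff are assigned to the closer partner and counted as ambiguous.
#'
#' @param traceW,traceY `distance_trace` objects at the same temperature
#'   with equal frame counts (e.g. D19 carboxylate-O to W37 NE1 and to
#'   Y11 OH).
#' @param cutoff classification cutoff in angstrom (default 3.5, matching
#'   the H-bond detection cutoff).
#' @return object of class `state_series`: list with `states` (factor with
#'   levels W, I, Y), `occupancies` (named fractions summing to 1),
#'   `n_frames`, `n_ambiguous`, `temperature`, `interval_ns`.
#' @export
classify_three_state <- function(traceW, traceY, cutoff = 3.5) {
  stopifnot(inherits(traceW, "distance_trace"),
            inherits(traceY, "distance_trace"))
  if (length(traceW$values) != length(traceY$values)) {
    stop("traces have mismatched frame counts")
  }
  if (!isTRUE(all.equal(traceW$temperature, traceY$temperature))) {
    stop("traces have different temperatures")
  }
  dW <- traceW$values; dY <- traceY$values
  st <- rep("I", length(dW))
  st[dW <= cutoff & dY > cutoff] <- "W"
  st[dY <= cutoff & dW > cutoff] <- "Y"
  both <- dW <= cutoff & dY <= cutoff
  st[both] <- ifelse(dW[both] <= dY[both], "W", "Y")
  states <- factor(st, levels = c("W", "I", "Y"))
  occ <- as.numeric(table(states)) / length(states)
  names(occ) <- c("W", "I", "Y")
  structure(list(states = states, occupancies = occ,
                 n_frames = length(states), n_ambiguous = sum(both),
                 temperature = traceW$temperature,
                 interval_ns = traceW$interval_ns),
            class = "state_series")
}

#' @export
print.state_series <- function(x, ...) {
  cat(sprintf(paste0("state_series at %g K: %d frames, ",
                     "W %.1f%% / I %.1f%% / Y %.1f%% (%d ambiguous)\n"),
              x$temperature, x$n_frames, 100 * x$occupancies["W"],
              100 * x$occupancies["I"], 100 * x$occupancies["Y"],
              x$n_ambiguous))
  invisible(x)
}

#' Two-state equilibrium constant from occupancies
#'
#' `K = pi_Y / pi_W`, the ratio of Y-bonded to W-bonded occupancy.
#' Intermediate (both-broken) frames do not enter the ratio: the constant
#' describes the pure partner-exchange equilibrium between the two bonded
#' conformations.
#'
#' @param series a `state_series`.
#' @return dimensionless K.
#' @export
occupancy_ratio <- function(series) {
  stopifnot(inherits(series, "state_series"))
  if (series$occupancies["W"] == 0) {
    stop("W-state occupancy is zero: K undefined at ",
         series$temperature, " K")
  }
  unname(series$occupancies["Y"] / series$occupancies["W"])
}

# integrated autocorrelation time (frames) of a 0/1 indicator, by the
# initial-positive-sequence rule; acf computed in O(n log n) via FFT
.iact <- function(ind, lag_max = NULL) {
  n <- length(ind)
  if (stats::var(ind) == 0) return(1)
  lag_max <- lag_max %||% min(n - 1, 10000L)
  x <- ind - mean(ind)
  m <- stats::nextn(2L * n, 2)
  f <- stats::fft(c(x, rep(0, m - n)))
  ac <- Re(stats::fft(Mod(f)^2, inverse = TRUE))[seq_len(lag_max + 1)]
  ac <- ac / ac[1]
  ac <- ac[-1]
  neg <- which(ac <= 0)
  if (length(neg)) ac <- ac[seq_len(neg[1] - 1)]
  1 + 2 * sum(ac)
}

#' van't Hoff fit of an equilibrium across temperatures
#'
#' Fits `ln K = -dH/(R T) + dS/R` by ordinary least squares of `ln K` on
#' `1/T`, so the enthalpy difference is `-slope * R` and the entropy
#' difference `intercept * R`. Points with `K <= 0` are excluded with a
#' warning (a state never visited carries no ratio information); at least 3
#' usable temperatures are required.
#'
#' Uncertainties come from the regression standard errors and, when the
#' frame-level state series are supplied, from a moving-block bootstrap:
#' each replicate resamples contiguous blocks of every temperature's state
#' sequence (block length 10x the integrated autocorrelation time of the
#' Y-state indicator, so resampled blocks are effectively independent),
#' recomputes each K and refits. This respects the strong serial
#' correlation of slowly switching trajectories, which a frame-level
#' resample would ignore.
#'
#' @param points data.frame with columns `temperature` (kelvin) and `K`.
#' @param series_list optional list of `state_series` matching `points`
#'   rows, enabling the block bootstrap.
#' @param n_boot bootstrap replicates (default 200).
#' @param seed optional seed for the bootstrap resampling.
#' @return object of class `vant_hoff_fit`: list with `deltaH` (J/mol),
#'   `deltaS` (J/K/mol), `se_deltaH`, `se_deltaS` (regression),
#'   `boot_se_deltaH`, `boot_se_deltaS` (`NA` without series), `points`
#'   (the included temperatures with K and ln K), `residuals`, and `R`.
#' @export
vant_hoff_fit <- function(points, series_list = NULL, n_boot = 200,
                          seed = NULL) {
  stopifnot(is.data.frame(points), all(c("temperature", "K") %in%
                                         names(points)))
  bad <- !(points$K > 0) | !is.finite(points$K)
  if (any(bad)) {
    warning(sprintf("excluding %d point(s) with K <= 0 (T = %s K)",
                    sum(bad),
                    paste(points$temperature[bad], collapse = ", ")))
  }
  pts <- points[!bad, , drop = FALSE]
  if (!is.null(series_list)) series_list <- series_list[!bad]
  if (nrow(pts) < 3) stop("need at least 3 temperatures with K > 0")
  x <- 1 / pts$temperature
  y <- log(pts$K)
  fit <- stats::lm(y ~ x)
  # plain OLS standard errors (avoids summary.lm's perfect-fit warning on
  # exact analytic input)
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  s2 <- sum(stats::resid(fit)^2) / (n - 2)
  se_slope <- sqrt(s2 / sxx)
  se_int <- sqrt(s2 * (1 / n + mean(x)^2 / sxx))
  out <- list(
    deltaH = -unname(stats::coef(fit)[2]) * R_GAS,
    deltaS = unname(stats::coef(fit)[1]) * R_GAS,
    se_deltaH = se_slope * R_GAS,
    se_deltaS = se_int * R_GAS,
    boot_se_deltaH = NA_real_, boot_se_deltaS = NA_real_,
    points = data.frame(temperature = pts$temperature, K = pts$K,
                        lnK = y),
    residuals = unname(stats::resid(fit)), R = R_GAS)

  if (!is.null(series_list)) {
    stopifnot(length(series_list) == nrow(pts))
    if (!is.null(seed)) set.seed(seed)
    prep <- lapply(series_list, function(s) {
      ind_y <- as.integer(s$states == "Y")
      ind_w <- as.integer(s$states == "W")
      L <- max(1L, min(round(10 * .iact(ind_y)), floor(s$n_frames / 2)))
      # cumulative counts allow O(1) per-block tallies of W and Y frames
      list(cy = cumsum(ind_y), cw = cumsum(ind_w), L = L, n = s$n_frames)
    })
    bh <- bs <- numeric(n_boot)
    keep <- 0L
    for (b in seq_len(n_boot)) {
      Kb <- vapply(prep, function(p) {
        nb <- ceiling(p$n / p$L)
        starts <- sample.int(p$n - p$L + 1L, nb, replace = TRUE)
        ends <- starts + p$L - 1L
        ny <- sum(p$cy[ends] - ifelse(starts > 1, p$cy[starts - 1L], 0))
        nw <- sum(p$cw[ends] - ifelse(starts > 1, p$cw[starts - 1L], 0))
        if (nw == 0) return(NA_real_)
        ny / nw
      }, 0)
      ok <- is.finite(Kb) & Kb > 0
      if (sum(ok) < 3) next
      fb <- stats::lm(log(Kb[ok]) ~ x[ok])
      keep <- keep + 1L
      bh[keep] <- -unname(stats::coef(fb)[2]) * R_GAS
      bs[keep] <- unname(stats::coef(fb)[1]) * R_GAS
    }
    if (keep >= 2) {
      out$boot_se_deltaH <- stats::sd(bh[seq_len(keep)])
      out$boot_se_deltaS <- stats::sd(bs[seq_len(keep)])
    }
  }
  class(out) <- "vant_hoff_fit"
  out
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf("van't Hoff fit over %d temperatures:\n", nrow(x$points)))
  cat(sprintf("  dH = %.2f kJ/mol (se %.2f%s)\n", x$deltaH / 1000,
              x$se_deltaH / 1000,
              if (is.finite(x$boot_se_deltaH))
                sprintf(", boot se %.2f", x$boot_se_deltaH / 1000) else ""))
  cat(sprintf("  dS = %.2f J/K/mol (se %.2f%s)\n", x$deltaS, x$se_deltaS,
              if (is.finite(x$boot_se_deltaS))
                sprintf(", boot se %.2f", x$boot_se_deltaS) else ""))
  invisible(x)
}

#' Mean dwell times per state
#'
#' Mean length of maximal same-state runs, converted to nanoseconds with
#' the frame interval. Runs truncated by the start or end of the series are
#' censored: they are counted, but their number is reported so that heavily
#' censored estimates can be discounted. Dwell estimates depend on frame
#' order (unlike occupancies).
#'
#' @param series a `state_series`.
#' @return data.frame with one row per observed state: `state`,
#'   `mean_dwell_ns`, `n_runs`, `n_censored`.
#' @export
dwell_times <- function(series) {
  stopifnot(inherits(series, "state_series"))
  r <- rle(as.character(series$states))
  k <- length(r$lengths)
  censored <- logical(k)
  censored[1] <- TRUE; censored[k] <- TRUE
  states <- sort(unique(r$values))
  out <- do.call(rbind, lapply(states, function(s) {
    sel <- r$values == s
    data.frame(state = s,
               mean_dwell_ns = mean(r$lengths[sel]) * series$interval_ns,
               n_runs = sum(sel), n_censored = sum(sel & censored))
  }))
  rownames(out) <- NULL
  out
}

#' Per-residue RMSF over trajectory frames
#'
#' Root-mean-square fluctuation of each selected atom about its mean
#' position, after removing rigid-body motion: every frame is superposed
#' (Kabsch) onto the mean structure, the mean is recomputed from the fitted
#' frames, and frames are superposed once more onto the updated mean before
#' the per-atom RMS deviation is taken.
#'
#' @param frames list of `structure_model` with identical atom ordering, or
#'   a list of nx3 coordinate matrices.
#' @param chain,resseq,name selection applied to every frame (default all
#'   C-alpha atoms).
#' @return object of class `rmsf_profile`: data.frame with columns `resseq`
#'   and `rmsf` (angstrom).
#' @export
rmsf_profile <- function(frames, chain = "*", resseq = "*", name = "CA") {
  stopifnot(length(frames) >= 2)
  if (is.matrix(frames[[1]])) {
    mats <- frames
    rs <- seq_len(nrow(mats[[1]]))
  } else {
    sels <- lapply(frames, select_atoms, chain = chain, resseq = resseq,
                   name = name)
    rs <- sels[[1]]$resseq
    key <- paste(sels[[1]]$chain, sels[[1]]$resseq, sels[[1]]$name)
    for (s in sels) {
      if (!identical(paste(s$chain, s$resseq, s$name), key)) {
        stop("frames do not share a common atom correspondence")
      }
    }
    mats <- lapply(sels, .coords)
  }
  n <- nrow(mats[[1]])
  if (any(vapply(mats, nrow, 0L) != n)) {
    stop("frames do not share a common atom correspondence")
  }
  fit_all <- function(mats, ref) {
    lapply(mats, function(m) {
      f <- superpose_kabsch(m, ref)
      apply_transform(m, f)
    })
  }
  mean_mat <- function(ms) Reduce(`+`, ms) / length(ms)
  fitted <- fit_all(mats, mats[[1]])
  fitted <- fit_all(mats, mean_mat(fitted))
  mu <- mean_mat(fitted)
  dev2 <- Reduce(`+`, lapply(fitted, function(m) rowSums((m - mu)^2)))
  out <- data.frame(resseq = rs, rmsf = sqrt(dev2 / length(fitted)))
  rownames(out) <- NULL
  class(out) <- c("rmsf_profile", "data.frame")
  out
}
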