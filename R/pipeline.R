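#' Run configuration for the full analysis report
#'
#' Exactly one input source must be given: `files` (a data.frame with
#' columns `path` and `temperature`, one crystal structure per row) or
#' `fixture` (a [fixture_config()]; the structure series is generated).
#' Trajectory analysis always runs on simulated three-state trajectories at
#' the configured van't Hoff protocol temperatures.
#'
#' @param files optional data.frame of (path, temperature).
#' @param fixture optional [fixture_config()].
#' @param out_dir output directory.
#' @param cutoff H-bond/classification distance cutoff, angstrom.
#' @param vant_hoff_temperatures protocol temperatures for the trajectory
#'   stage (default `c(245, 260, 275, 293, 308, 323)`, spanning the
#'   245-323 K fitting range).
#' @param markov base [markov_config()] for the trajectory stage (its
#'   `temperature` is replaced per protocol point, its `seed` offset per
#'   temperature).
#' @param seed master seed; all stage seeds derive from it.
#' @return a list of class `run_config`.
#' @export
run_config <- function(files = NULL, fixture = NULL, out_dir = "rdtherm_out",
                       cutoff = 3.5,
                       vant_hoff_temperatures = c(245, 260, 275, 293, 308,
                                                  323),
                       markov = markov_config(), seed = 1) {
  if (is.null(files) == is.null(fixture)) {
    stop("exactly one of 'files' or 'fixture' must be given")
  }
  if (!is.null(files)) {
    stopifnot(is.data.frame(files),
              all(c("path", "temperature") %in% names(files)))
    missing <- !file.exists(files$path)
    if (any(missing)) {
      stop("input file(s) not found: ",
           paste(files$path[missing], collapse = ", "))
    }
  }
  structure(list(files = files, fixture = fixture, out_dir = out_dir,
                 cutoff = cutoff,
                 vant_hoff_temperatures = vant_hoff_temperatures,
                 markov = markov, seed = seed), class = "run_config")
}

.log_line <- function(con, ...) {
  msg <- sprintf(...)
  message(msg)
  writeLines(msg, con)
}

#' Run the full temperature-series analysis and write a report bundle
#'
#' Stages, each written to the output directory as TSV/JSON:
#' \describe{
#'   \item{partner_table.tsv}{D19 partner-switch table across the series.}
#'   \item{bfactor_raw.tsv / bfactor_normalized.tsv}{per-residue C-alpha
#'     B-factor profiles, raw and z-score normalized, long format.}
#'   \item{series_waters.tsv, series_cell_volume.tsv,
#'     series_protein_volume.tsv}{thermal series of the three metrics.}
#'   \item{trend_fits.json}{expansion fits for both volume series and the
#'     changepoint fit of the water series.}
#'   \item{occupancy.tsv / dwell.tsv}{state occupancies, equilibrium
#'     constants and dwell times of the simulated trajectories.}
#'   \item{vant_hoff.json}{the van't Hoff fit with bootstrap errors.}
#'   \item{run_log.txt}{package version, seed, parameters, stage outcomes.}
#' }
#'
#' @param config a [run_config()].
#' @return invisibly, a named list of the computed objects.
#' @export
run_full_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(config$out_dir, "run_log.txt"), "w")
  on.exit(close(logf))
  .log_line(logf, "rdtherm %s | seed %d | cutoff %.2f A",
            as.character(utils::packageVersion("rdtherm")), config$seed,
            config$cutoff)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .log_line(logf, "FAILED stage %s: %s", name, conditionMessage(e))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  models <- stage("load_structures", {
    if (!is.null(config$fixture)) {
      .log_line(logf, "generating fixture series (%d temperatures)",
                length(config$fixture$temperatures))
      generate_structure_series(config$fixture)
    } else {
      .log_line(logf, "reading %d structure file(s)", nrow(config$files))
      Map(read_pdb, config$files$path, temperature = config$files$temperature)
    }
  })

  out <- list()
  out$partner_table <- stage("hbond", {
    pt <- partner_switch_table(models, cutoff = config$cutoff)
    write_tsv(pt, file.path(config$out_dir, "partner_table.tsv"))
    pt
  })

  out$bfactors <- stage("bfactor", {
    prof <- lapply(models, bfactor_profile)
    long <- function(ps) do.call(rbind, lapply(ps, function(p) {
      data.frame(temperature_K = attr(p, "temperature"),
                 resseq = p$resseq, bfactor = p$bfactor)
    }))
    write_tsv(long(prof), file.path(config$out_dir, "bfactor_raw.tsv"))
    nprof <- lapply(prof, normalize_bfactors)
    write_tsv(long(nprof), file.path(config$out_dir,
                                     "bfactor_normalized.tsv"))
    list(raw = prof, normalized = nprof)
  })

  out$trends <- stage("trends", {
    sw <- collect_series(models, "waters")
    sc <- collect_series(models, "cell_volume")
    sp <- if (!is.null(config$fixture)) generate_volume_series(config$fixture)
          else collect_series(models, "protein_volume")
    write_tsv(sw, file.path(config$out_dir, "series_waters.tsv"))
    write_tsv(sc, file.path(config$out_dir, "series_cell_volume.tsv"))
    write_tsv(sp, file.path(config$out_dir, "series_protein_volume.tsv"))
    fits <- list(
      cell_volume = unclass(expansion_fit(sc)),
      protein_volume = unclass(expansion_fit(sp)),
      water_changepoint = unclass(changepoint_fit(sw)))
    jsonlite::write_json(fits, file.path(config$out_dir, "trend_fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .log_line(logf,
              "trends: cell %+.2f%% endpoints, water breakpoint %g K",
              fits$cell_volume$endpoint_pct_change,
              fits$water_changepoint$breakpoint)
    fits
  })

  out$trajectory <- stage("trajectory", {
    mk <- config$markov
    sims <- lapply(seq_along(config$vant_hoff_temperatures), function(k) {
      tt <- config$vant_hoff_temperatures[k]
      ck <- mk
      ck$temperature <- tt
      ck$seed <- config$seed * 1000L + k
      simulate_three_state_markov(ck)
    })
    series <- lapply(sims, function(s) {
      classify_three_state(s$traceW, s$traceY, cutoff = config$cutoff)
    })
    occ <- do.call(rbind, lapply(series, function(s) {
      data.frame(temperature_K = s$temperature,
                 pi_W = s$occupancies["W"], pi_I = s$occupancies["I"],
                 pi_Y = s$occupancies["Y"],
                 K = if (s$occupancies["W"] > 0)
                       s$occupancies["Y"] / s$occupancies["W"] else NA,
                 n_frames = s$n_frames, row.names = NULL)
    }))
    write_tsv(occ, file.path(config$out_dir, "occupancy.tsv"))
    dw <- do.call(rbind, lapply(series, function(s) {
      cbind(temperature_K = s$temperature, dwell_times(s))
    }))
    write_tsv(dw, file.path(config$out_dir, "dwell.tsv"))
    vh <- vant_hoff_fit(data.frame(temperature = occ$temperature_K,
                                   K = occ$K),
                        series_list = series,
                        seed = config$seed * 1000L + 999L)
    jsonlite::write_json(
      list(deltaH_J_mol = vh$deltaH, deltaS_J_K_mol = vh$deltaS,
           se_deltaH = vh$se_deltaH, se_deltaS = vh$se_deltaS,
           boot_se_deltaH = vh$boot_se_deltaH,
           boot_se_deltaS = vh$boot_se_deltaS, points = vh$points),
      file.path(config$out_dir, "vant_hoff.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .log_line(logf, "van't Hoff: dH %.1f kJ/mol, dS %.1f J/K/mol",
              vh$deltaH / 1000, vh$deltaS)
    list(occupancy = occ, dwell = dw, fit = vh)
  })

  .log_line(logf, "report complete: %s", normalizePath(config$out_dir))
  invisible(out)
}
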