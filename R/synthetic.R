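#' Configuration for the synthetic structure-series generator
#'
#' Bundles every programmed feature of the schematic rubredoxin-like
#' fixture series: the temperature grid, the H-bond partner-switch
#' temperature, the key bond lengths, the B-factor model, the ordered-water
#' count model, and the unit-cell expansion. Defaults realize the
#' temperature-dependent observations the package is built to measure: a
#' D19 carboxylate H-bonded to the W37 indole nitrogen at 2.88 angstrom
#' below the switch temperature and directly to the Y11 hydroxyl at or
#' above it, two- and one-water Y11 bridges at two intermediate
#' temperatures, a tetrahedral Zn(S-Cys)4 site with 2.34 angstrom Zn-S
#' bonds, a conserved E15 polar network at every temperature, B-factors
#' rising with temperature (faster in the loops), an ordered-water count
#' with a sharp kink at 240 K, and a unit cell whose volume grows linearly
#' to +2.8% at the top of the range.
#'
#' @param temperatures kelvin grid (default the 12-point series
#'   100-393 K).
#' @param switch_temperature kelvin; D19 partner switches from W37 to Y11
#'   at/above it (default 300).
#' @param bonded_distance angstrom for the programmed direct H-bonds
#'   (default 2.88).
#' @param zn_s_distance angstrom for the four Zn-S bonds (default 2.34).
#' @param two_water_T,one_water_T temperatures carrying the 2-water and
#'   1-water D19-Y11 bridges (defaults 100 and 260 K).
#' @param b_base,b_slope named vectors (`core`, `loop`) giving the
#'   B-factor at 100 K (square angstrom) and its growth per kelvin.
#' @param water_count_model list: `low` (count at the lowest temperature),
#'   `high` (count at the highest), `transition` (kelvin, default 240),
#'   `width` (kelvin; 0 = sharp kink, > 0 logistic-smooths it), and
#'   `pre_slope` (count per kelvin lost below the transition).
#' @param cell0 a [unit_cell()] for the lowest temperature.
#' @param cell_expansion fractional volume increase per kelvin (default
#'   0.028/293, i.e. +2.8% over 100-393 K).
#' @param volume_slope protein-volume slope in cubic angstrom per kelvin
#'   for [generate_volume_series()] (default 0.48).
#' @param volume_rel_slope relative protein-volume slope in percent per
#'   100 K (default 0.6); with `volume_slope` this fixes the 100 K volume
#'   at `100 * volume_slope * 100 / volume_rel_slope` cubic angstrom.
#' @param seed integer seed (used only for clash-resolution jitter; the
#'   construction itself is deterministic).
#' @return a list of class `fixture_config`.
#' @export
fixture_config <- function(
    temperatures = c(100, 140, 180, 220, 240, 260, 293, 323, 353, 363, 383,
                     393),
    switch_temperature = 300,
    bonded_distance = 2.88,
    zn_s_distance = 2.34,
    two_water_T = 100,
    one_water_T = 260,
    b_base = c(core = 8, loop = 12),
    b_slope = c(core = 0.03, loop = 0.08),
    water_count_model = list(low = 80, high = 20, transition = 240,
                             width = 0, pre_slope = -0.06),
    cell0 = unit_cell(34.5, 35.5, 44.5),
    cell_expansion = 0.028 / 293,
    volume_slope = 0.48,
    volume_rel_slope = 0.6,
    seed = 1) {
  if (anyDuplicated(temperatures)) stop("temperatures must be distinct")
  stopifnot(bonded_distance > 0, zn_s_distance > 0,
            all(c("core", "loop") %in% names(b_base)),
            all(c("core", "loop") %in% names(b_slope)))
  structure(list(
    temperatures = sort(temperatures),
    switch_temperature = switch_temperature,
    bonded_distance = bonded_distance, zn_s_distance = zn_s_distance,
    two_water_T = two_water_T, one_water_T = one_water_T,
    b_base = b_base, b_slope = b_slope,
    water_count_model = water_count_model,
    cell0 = cell0, cell_expansion = cell_expansion,
    volume_slope = volume_slope, volume_rel_slope = volume_rel_slope,
    seed = seed), class = "fixture_config")
}

# residue types at the positions the analyses select on; ALA elsewhere
.fixture_resnames <- function() {
  rn <- rep("ALA", 54)
  rn[c(1, 4, 37)] <- c("MET", "TRP", "TRP")
  rn[c(6, 9, 39, 42)] <- "CYS"
  rn[c(11, 13)] <- "TYR"
  rn[15] <- "GLU"
  rn[19] <- "ASP"
  rn[c(30, 49)] <- "PHE"
  rn
}

# loop A (16-27) and loop B (30-38) residues carry the larger B model
.fixture_loop_residues <- function() c(16:27, 30:38)

#' Ordered-water count model of the fixture
#'
#' Piecewise-linear count: a shallow loss below the transition temperature
#' and a steep loss above it, meeting in a kink at the transition — the
#' generator's emulation of the drop in crystallographically ordered waters
#' at the protein dynamical transition near 240 K. A positive `width`
#' replaces the sharp kink by a logistic blend of the two branches.
#'
#' @param temperature kelvin (vectorized).
#' @param config a [fixture_config()].
#' @return water count(s), rounded to integer.
#' @export
fixture_water_count <- function(temperature, config = fixture_config()) {
  wm <- config$water_count_model
  tmin <- min(config$temperatures); tmax <- max(config$temperatures)
  n_at_kink <- wm$low + wm$pre_slope * (wm$transition - tmin)
  post_slope <- (wm$high - n_at_kink) / (tmax - wm$transition)
  lo <- wm$low + wm$pre_slope * (temperature - tmin)
  hi <- n_at_kink + post_slope * (temperature - wm$transition)
  if (wm$width > 0) {
    w <- 1 / (1 + exp((temperature - wm$transition) / wm$width))
    n <- w * lo + (1 - w) * hi
  } else {
    n <- ifelse(temperature <= wm$transition, lo, hi)
  }
  pmax(0L, as.integer(round(n)))
}

.element_from_name <- function(name) {
  ifelse(name %in% c("ZN"), "ZN", substr(name, 1, 1))
}

# one atom row
.atom_row <- function(serial, name, resname, chain, resseq, xyz, b,
                      record = "ATOM") {
  data.frame(serial = serial, name = name, altloc = "", resname = resname,
             chain = chain, resseq = resseq, x = xyz[1], y = xyz[2],
             z = xyz[3], occupancy = 1, bfactor = b,
             element = .element_from_name(name), record = record,
             stringsAsFactors = FALSE)
}

# deterministic geometric construction of one fixture model; jitter is a
# small displacement applied on clash-resolution retries
.build_fixture_model <- function(temperature, config, jitter = NULL) {
  resnames <- .fixture_resnames()
  loops <- .fixture_loop_residues()
  bclass <- ifelse(seq_len(54) %in% loops, "loop", "core")
  bval <- config$b_base[bclass] +
    config$b_slope[bclass] * (temperature - min(config$temperatures))

  rows <- list()
  add <- function(name, resname, resseq, xyz, b, record = "ATOM") {
    rows[[length(rows) + 1]] <<- .atom_row(length(rows) + 1L, name, resname,
                                           "A", resseq, xyz, b, record)
  }

  # serpentine-free backbone: four left-to-right rows of 14/14/14/12
  # residues, CA every 3.8 A; main chain N, C, O at fixed local offsets
  ca_pos <- function(i) {
    r <- (i - 1) %/% 14
    c(((i - 1) %% 14) * 3.8, 5.5 * r, 0)
  }
  feature_atoms <- list()  # resseq -> list(name=xyz) appended after mainchain

  # -- D19 partner cluster (z = 8 plane, clear of the backbone) --
  OD1 <- c(11.0, 5.0, 8.0)
  OD2 <- c(9.6, 6.6, 8.0)
  d <- config$bonded_distance
  low_T <- temperature < config$switch_temperature
  NE1_37 <- if (low_T) OD1 + c(d, 0, 0) else OD1 + c(6, 0, 0)
  bridge_waters <- list()
  if (isTRUE(all.equal(temperature, config$two_water_T))) {
    bridge_waters <- list(OD2 + c(0, 2.8, 0), OD2 + c(0, 5.6, 0))
    OH_11 <- OD2 + c(0, 8.4, 0)
  } else if (isTRUE(all.equal(temperature, config$one_water_T))) {
    bridge_waters <- list(OD2 + c(0, 2.8, 0))
    OH_11 <- OD2 + c(0, 5.6, 0)
  } else if (low_T) {
    OH_11 <- OD2 + c(0, 8.4, 0)
  } else {
    OH_11 <- OD2 + c(0, d, 0)  # rotated carboxylate: direct D19-Y11 bond
  }

  # -- E15 conserved network: E15 N wired to A2 O; OE1/OE2 to W4 NE1 and
  # F30 N; identical at every temperature --
  O_A2 <- ca_pos(2) + c(1.2, 0.9, 1.75)
  u <- (ca_pos(15) - O_A2); u <- u / sqrt(sum(u^2))
  N_E15 <- O_A2 + 2.9 * u
  N_F30 <- ca_pos(30) + c(-1.2, -0.5, 0.6)
  OE2 <- N_F30 + c(0, 0, 2.9)
  OE1 <- OE2 + c(0, -2.2, 0)
  NE1_4 <- OE1 + c(0, -2.9, 0)

  # -- tetrahedral Zn(S-Cys)4 site above the feature plane --
  zn <- c(30, 8, 14)
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
    sqrt(3)
  sg <- sweep(tet * config$zn_s_distance, 2, zn, `+`)

  feature_atoms <- list(
    `19` = list(OD1 = OD1, OD2 = OD2),
    `37` = list(NE1 = NE1_37),
    `11` = list(OH = OH_11),
    `15` = list(OE1 = OE1, OE2 = OE2),
    `4` = list(NE1 = NE1_4),
    `6` = list(SG = sg[1, ]), `9` = list(SG = sg[2, ]),
    `39` = list(SG = sg[3, ]), `42` = list(SG = sg[4, ]))

  for (i in 1:54) {
    ca <- ca_pos(i)
    N <- ca + c(-1.2, -0.5, 0.6)
    if (i == 15) N <- N_E15
    C <- ca + c(1.2, 0.5, 0.6)
    O <- C + c(0, 0.4, 1.15)
    add("N", resnames[i], i, N, bval[i])
    add("CA", resnames[i], i, ca, bval[i])
    add("C", resnames[i], i, C, bval[i])
    add("O", resnames[i], i, O, bval[i])
    fa <- feature_atoms[[as.character(i)]]
    if (!is.null(fa)) {
      for (nm in names(fa)) add(nm, resnames[i], i, fa[[nm]], bval[i])
    }
  }
  add("ZN", "ZN", 90, zn, 15, record = "HETATM")

  # waters: bridge waters first, then a bulk grid well below the protein,
  # topping the total up to the programmed count
  n_total <- fixture_water_count(temperature, config)
  wseq <- 100L
  wb <- 30
  for (bw in bridge_waters) {
    wseq <- wseq + 1L
    add("O", "HOH", wseq, bw, wb, record = "HETATM")
  }
  n_bulk <- max(0L, n_total - length(bridge_waters))
  if (n_bulk > 0) {
    gx <- seq(0, by = 4, length.out = 12)
    gy <- seq(-36, by = 4, length.out = 10)
    grid <- as.matrix(expand.grid(x = gx, y = gy))[seq_len(n_bulk), ,
                                                   drop = FALSE]
    for (k in seq_len(n_bulk)) {
      wseq <- wseq + 1L
      add("O", "HOH", wseq, c(grid[k, 1], grid[k, 2], -8), wb,
          record = "HETATM")
    }
  }

  atoms <- do.call(rbind, rows)
  if (!is.null(jitter)) {
    atoms$x <- atoms$x + jitter[, 1]
    atoms$y <- atoms$y + jitter[, 2]
    atoms$z <- atoms$z + jitter[, 3]
  }
  atoms$serial <- seq_len(nrow(atoms))

  # expand the cell so volume grows linearly with T
  f <- (1 + config$cell_expansion *
          (temperature - min(config$temperatures)))^(1 / 3)
  c0 <- config$cell0
  cell <- unit_cell(c0$a * f, c0$b * f, c0$c * f, c0$alpha, c0$beta,
                    c0$gamma)

  structure(list(atoms = atoms, cell = cell, temperature = temperature,
                 label = sprintf("fixture_%gK", temperature)),
            class = "structure_model")
}

# smallest distance between heavy atoms not covalently linked by
# construction (same residue, or sequence neighbours, or the Zn site)
.min_nonbonded_distance <- function(model) {
  a <- model$atoms
  d <- as.matrix(stats::dist(.coords(a)))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  bonded <- (a$chain[i] == a$chain[j] & a$record[i] == a$record[j] &
               abs(a$resseq[i] - a$resseq[j]) <= 1) |
    (a$name[i] == "ZN" | a$name[j] == "ZN")
  min(d[cbind(i, j)][!bonded])
}

#' Generate the synthetic rubredoxin-like structure series
#'
#' Builds one schematic 54-residue structure per configured temperature:
#' full main chain, the side-chain atoms the analyses select on, a
#' tetrahedral Zn(S-Cys)4 site, the programmed D19 partner switch with its
#' water bridges, the conserved E15 network, the B-factor and water-count
#' models, and a linearly expanding unit cell. Construction is
#' deterministic; if a build ever places two non-bonded heavy atoms closer
#' than 1 angstrom it is retried with a small seeded jitter, and fails
#' after 10 attempts.
#'
#' The geometry is schematic: local distances of the programmed features
#' are exact, but the fold is a flat serpentine and side-chain atoms float
#' free of their backbone. These structures exercise the analysis code with
#' known ground truth; they are not a model of a real rubredoxin fold.
#'
#' @param config a [fixture_config()].
#' @return list of `structure_model`, one per temperature, in increasing
#'   temperature order.
#' @export
generate_structure_series <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(config$seed)
  lapply(config$temperatures, function(tt) {
    jitter <- NULL
    for (attempt in 1:10) {
      m <- .build_fixture_model(tt, config, jitter)
      if (.min_nonbonded_distance(m) >= 1.0) return(m)
      jitter <- matrix(stats::runif(3 * nrow(m$atoms), -0.2, 0.2), ncol = 3)
    }
    stop(sprintf("clash in fixture construction at %g K after 10 attempts",
                 tt))
  })
}

#' Noiseless protein-volume series of the fixture
#'
#' The fixture's programmed protein-volume trend: an exactly linear series
#' `V(T) = V(Tmin) + slope * (T - Tmin)` over the configured temperatures,
#' with `V(Tmin)` fixed by the configured absolute slope (cubic angstrom
#' per kelvin) and relative slope (percent per 100 K) so the two cohere:
#' `V(Tmin) = 100 * slope * 100 / rel_slope`. Grid volumes of the schematic
#' fixture atoms are deliberately not tuned to this series; the programmed
#' trend is emitted directly.
#'
#' @param config a [fixture_config()].
#' @return a `thermal_series` of protein volumes (cubic angstrom).
#' @export
generate_volume_series <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  tmin <- min(config$temperatures)
  v0 <- 100 * config$volume_slope * 100 / config$volume_rel_slope
  thermal_series(config$temperatures,
                 v0 + config$volume_slope * (config$temperatures - tmin),
                 metric = "protein_volume", units = "A^3")
}

#' Write a fixture series as PDB files plus a manifest
#'
#' One PDB file per temperature plus `manifest.json` mapping each file to
#' its temperature and recording the generator truth parameters.
#'
#' @param models output of [generate_structure_series()].
#' @param dir output directory (created if needed).
#' @param config the [fixture_config()] used (recorded in the manifest).
#' @return invisibly, the manifest path.
#' @export
write_fixture_series <- function(models, dir, config = fixture_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(models, function(m) {
    fn <- sprintf("fixture_%03dK.pdb", as.integer(round(m$temperature)))
    write_pdb(m, file.path(dir, fn))
    fn
  }, "")
  manifest <- list(
    files = data.frame(file = files,
                       temperature = vapply(models, `[[`, 0, "temperature")),
    seed = config$seed,
    truth = list(switch_temperature = config$switch_temperature,
                 bonded_distance = config$bonded_distance,
                 zn_s_distance = config$zn_s_distance,
                 water_transition = config$water_count_model$transition,
                 cell_expansion = config$cell_expansion,
                 volume_slope = config$volume_slope,
                 volume_rel_slope = config$volume_rel_slope))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a fixture manifest and its structures
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [write_fixture_series()].
#' @return list of `structure_model`.
#' @export
read_fixture_series <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  Map(function(f, tt) read_pdb(file.path(dir, f), temperature = tt),
      man$files$file, man$files$temperature)
}
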