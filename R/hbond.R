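#' Table of polar (H-bond capable) heavy atoms
#'
#' Reads the packaged per-residue polar-atom table
#' (`inst/extdata/polar_atoms.tsv`): main-chain N/O/OXT for every residue
#' plus side-chain donors/acceptors of the 20 amino acids and the water
#' oxygen. Both carboxylate oxygens of Asp and Glu are listed; the
#' carboxylate can rotate between them, so partner identity rather than
#' oxygen identity defines an interaction. The table is a plain TSV and can
#' be replaced via `path` for non-standard chemistry.
#'
#' @param path optional path to an alternative table (columns `resname`,
#'   `atom`; resname `*` matches any residue).
#' @return data.frame with columns `resname` and `atom`.
#' @export
polar_atom_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "polar_atoms.tsv", package = "rdtherm",
                        mustWork = TRUE)
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# rows of `atoms` that are polar per the table; hydrogens excluded
.polar_atoms <- function(model, table) {
  a <- model$atoms
  any_res <- table$atom[table$resname == "*"]
  spec <- table[table$resname != "*", , drop = FALSE]
  polar <- (a$record == "ATOM" & a$name %in% any_res) |
    paste(a$resname, a$name) %in% paste(spec$resname, spec$atom)
  polar <- polar & toupper(a$element) != "H"
  a[polar, , drop = FALSE]
}

.atom_id <- function(atoms) {
  sprintf("%s:%s%d:%s", atoms$chain, atoms$resname, atoms$resseq, atoms$name)
}

#' Detect direct hydrogen bonds by heavy-atom distance
#'
#' Enumerates all pairs of polar heavy atoms within the distance cutoff.
#' The criterion is distance-only (no donor-H-acceptor angle): the X-ray
#' models this package targets carry no hydrogens, so H-bonds are reported
#' by donor-acceptor heavy-atom separations, e.g. a 2.88 angstrom
#' carboxylate-O to indole-N contact. Pairs within one residue, and the
#' main-chain N-O pair of one peptide bond (O of residue i with N of residue
#' i+1 on the same chain), are excluded as covalent-geometry artifacts.
#'
#' @param model a `structure_model`.
#' @param cutoff heavy-atom distance cutoff in angstrom (default 3.5).
#' @param polar_table polar-atom table, see [polar_atom_table()].
#' @return data.frame of class `hbond_table`, sorted by distance: columns
#'   `donor`, `acceptor` (atom identifiers `chain:RES#:name`), per-atom
#'   fields, `distance` (angstrom), `kind` (`"direct"`).
#' @export
detect_hbonds <- function(model, cutoff = 3.5, polar_table = polar_atom_table()) {
  stopifnot(inherits(model, "structure_model"), cutoff > 0)
  p <- .polar_atoms(model, polar_table)
  empty <- data.frame(donor = character(0), acceptor = character(0),
                      distance = numeric(0), kind = character(0))
  if (nrow(p) < 2) return(structure(empty, class = c("hbond_table", "data.frame")))
  # stable order, independent of file order
  p <- p[order(p$chain, p$resseq, p$name), , drop = FALSE]
  xyz <- .coords(p)
  d <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (!nrow(idx)) return(structure(empty, class = c("hbond_table", "data.frame")))
  i <- idx[, 1]; j <- idx[, 2]
  same_residue <- p$chain[i] == p$chain[j] & p$resseq[i] == p$resseq[j] &
    p$record[i] == p$record[j]
  peptide <- p$chain[i] == p$chain[j] & p$record[i] == "ATOM" &
    p$record[j] == "ATOM" &
    ((p$name[i] == "O" & p$name[j] == "N" & p$resseq[j] == p$resseq[i] + 1) |
     (p$name[j] == "O" & p$name[i] == "N" & p$resseq[i] == p$resseq[j] + 1))
  keep <- !(same_residue | peptide)
  i <- i[keep]; j <- j[keep]
  if (!length(i)) return(structure(empty, class = c("hbond_table", "data.frame")))
  out <- data.frame(
    donor = .atom_id(p[i, ]), acceptor = .atom_id(p[j, ]),
    donor_chain = p$chain[i], donor_resseq = p$resseq[i],
    donor_name = p$name[i], acceptor_chain = p$chain[j],
    acceptor_resseq = p$resseq[j], acceptor_name = p$name[j],
    distance = d[cbind(i, j)], kind = "direct",
    stringsAsFactors = FALSE
  )
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("hbond_table", "data.frame"))
}

#' Water-mediated hydrogen-bond bridges between two endpoints
#'
#' Breadth-first search over the contact graph whose nodes are the endpoint
#' atoms and all water oxygens, with edges between nodes within the cutoff.
#' Returns every simple path from an A endpoint to a B endpoint with at most
#' `max_waters` (0-2) intermediate waters, ordered by number of waters then
#' total path length — so a direct contact, a single-water link, and a
#' two-water bridge are all reported in that preference order.
#'
#' @param model a `structure_model`.
#' @param endpointA,endpointB selection lists `list(chain=, resseq=, name=)`.
#' @param max_waters maximum bridging waters, 0, 1 or 2.
#' @param cutoff per-leg heavy-atom distance cutoff (angstrom).
#' @return list of class `bridge_list`; each element has `endpoints`
#'   (atom ids), `waters` (atom ids of bridging water oxygens, in path
#'   order), `n_waters`, `leg_distances`, and `total_length`.
#' @export
water_bridges <- function(model, endpointA, endpointB, max_waters = 2,
                          cutoff = 3.5) {
  stopifnot(inherits(model, "structure_model"))
  if (!is.numeric(max_waters) || length(max_waters) != 1 ||
      !(max_waters %in% 0:2)) {
    stop("max_waters must be 0, 1, or 2")
  }
  A <- do.call(select_atoms, c(list(model), endpointA))
  B <- do.call(select_atoms, c(list(model), endpointB))
  if (!nrow(A) || !nrow(B)) stop("endpoint selection resolves to no atoms")
  wa <- model$atoms
  W <- wa[wa$record == "HETATM" & wa$resname == "HOH" & wa$name == "O", ,
          drop = FALSE]
  dAB <- function(p, q) sqrt(sum((as.numeric(p) - as.numeric(q))^2))
  cA <- .coords(A); cB <- .coords(B); cW <- .coords(W)

  paths <- list()
  add <- function(ia, ib, iw, legs) {
    paths[[length(paths) + 1]] <<- list(
      endpoints = c(.atom_id(A[ia, ]), .atom_id(B[ib, ])),
      waters = if (length(iw)) .atom_id(W[iw, , drop = FALSE]) else character(0),
      n_waters = length(iw), leg_distances = unname(legs),
      total_length = sum(legs))
  }
  for (ia in seq_len(nrow(A))) for (ib in seq_len(nrow(B))) {
    d0 <- dAB(cA[ia, ], cB[ib, ])
    if (d0 <= cutoff) add(ia, ib, integer(0), d0)
    if (max_waters >= 1 && nrow(W)) {
      dAw <- sqrt(colSums((t(cW) - cA[ia, ])^2))
      dBw <- sqrt(colSums((t(cW) - cB[ib, ])^2))
      for (w in which(dAw <= cutoff & dBw <= cutoff)) {
        add(ia, ib, w, c(dAw[w], dBw[w]))
      }
      if (max_waters >= 2 && nrow(W) >= 2) {
        for (w1 in which(dAw <= cutoff)) for (w2 in which(dBw <= cutoff)) {
          if (w1 == w2) next
          dww <- dAB(cW[w1, ], cW[w2, ])
          if (dww <= cutoff) add(ia, ib, c(w1, w2), c(dAw[w1], dww, dBw[w2]))
        }
      }
    }
  }
  ord <- order(vapply(paths, `[[`, 0, "n_waters"),
               vapply(paths, `[[`, 0, "total_length"))
  structure(paths[ord], class = "bridge_list")
}

#' @export
print.bridge_list <- function(x, ...) {
  cat(sprintf("bridge_list: %d path(s)\n", length(x)))
  for (p in x) {
    cat(sprintf("  %s -[%d water(s)]- %s  total %.2f A\n", p$endpoints[1],
                p$n_waters, p$endpoints[2], p$total_length))
  }
  invisible(x)
}

#' Tabulate H-bond partner assignments across a temperature series
#'
#' For each structure in the series and each candidate partner, classifies
#' the donor-partner interaction as `direct` (heavy-atom contact within the
#' cutoff), `1-water` or `2-water` (water-mediated bridge), or `none`, and
#' returns one row per (temperature, partner), sorted by temperature. This
#' is the table behind a partner-switch analysis such as the Asp-19
#' carboxylate exchanging the Trp-37 indole nitrogen for the Tyr-11 hydroxyl
#' as temperature rises. When several kinds coexist the most direct one is
#' reported (direct before 1-water before 2-water); if two partners are both
#' direct-bonded at one temperature both rows say so — the table reports,
#' it does not adjudicate.
#'
#' @param models list of `structure_model`, each with a distinct temperature.
#' @param donor selection list for the donor atoms (default the Asp-19
#'   carboxylate oxygens, `list(chain="A", resseq=19, name="OD*")`).
#' @param partners named list of selection lists (default W37 indole N and
#'   Y11 hydroxyl O).
#' @param max_waters,cutoff passed to [water_bridges()].
#' @return data.frame of class `partner_table`: columns `temperature_K`,
#'   `partner`, `kind` (`direct`/`1-water`/`2-water`/`none`),
#'   `min_distance_A` (total path length; `NA` when `none`), `n_waters`.
#' @export
partner_switch_table <- function(models,
    donor = list(chain = "A", resseq = 19, name = "OD*"),
    partners = list(W37 = list(chain = "A", resseq = 37, name = "NE1"),
                    Y11 = list(chain = "A", resseq = 11, name = "OH")),
    max_waters = 2, cutoff = 3.5) {
  stopifnot(length(models) >= 1)
  temps <- vapply(models, `[[`, 0, "temperature")
  if (anyDuplicated(temps)) {
    stop("duplicate temperatures in series: ",
         paste(temps[duplicated(temps)], collapse = ", "))
  }
  rows <- list()
  for (m in models) for (pn in names(partners)) {
    br <- water_bridges(m, donor, partners[[pn]], max_waters = max_waters,
                        cutoff = cutoff)
    if (length(br)) {
      best <- br[[1]]
      kind <- c("direct", "1-water", "2-water")[best$n_waters + 1]
      rows[[length(rows) + 1]] <- data.frame(
        temperature_K = m$temperature, partner = pn, kind = kind,
        min_distance_A = best$total_length, n_waters = best$n_waters,
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        temperature_K = m$temperature, partner = pn, kind = "none",
        min_distance_A = NA_real_, n_waters = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$temperature_K, out$partner), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("partner_table", "data.frame"))
}
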