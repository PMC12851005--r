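# van der Waals radii (angstrom) for the grid volume; C is also the
# fallback for unknown elements.
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, ZN = 1.39, FE = 1.47)
.vdw_default <- 1.70

#' Kabsch least-squares superposition
#'
#' Optimal rigid-body superposition of a mobile structure onto a reference
#' over a common atom selection, by the Kabsch algorithm: centre both point
#' sets, take the SVD of the covariance matrix, and correct the sign of the
#' smallest singular direction so the result is a proper rotation
#' (determinant +1), never a reflection.
#'
#' @param mobile,reference `structure_model` objects, or nx3 coordinate
#'   matrices in atom correspondence.
#' @param chain,resseq,name atom selection (see [select_atoms()]) applied to
#'   both models; it must resolve to the same ordered correspondence in each.
#'   Ignored when coordinate matrices are given. Default: all main-chain
#'   atoms are a common choice, but the default selection is all atoms.
#' @return an object of class `superposition_result`: list with `rmsd`
#'   (angstrom, after fitting), `rotation` (3x3 proper rotation applied to
#'   the centred mobile coordinates), `translation` (so that
#'   `mobile %*% t(R) + translation` superposes onto the reference), and
#'   `n_atoms`.
#' @examples
#' m <- matrix(rnorm(15), 5, 3)
#' superpose_kabsch(m, m)$rmsd
#' @export
superpose_kabsch <- function(mobile, reference, chain = "*", resseq = "*",
                             name = "*") {
  P <- if (is.matrix(mobile)) mobile else
    .coords(select_atoms(mobile, chain, resseq, name))
  Q <- if (is.matrix(reference)) reference else
    .coords(select_atoms(reference, chain, resseq, name))
  if (nrow(P) != nrow(Q)) {
    stop(sprintf("selection yields %d mobile vs %d reference atoms",
                 nrow(P), nrow(Q)))
  }
  n <- nrow(P)
  if (n < 3) stop("need at least 3 atoms to superpose")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  # collinear (or coincident) point sets have no unique rotation
  if (any(svd(Pc)$d[2] < 1e-10, svd(Qc)$d[2] < 1e-10)) {
    stop("degenerate (collinear) point set: superposition is not unique")
  }
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  fitted <- Pc %*% t(R)
  rmsd <- sqrt(sum((fitted - Qc)^2) / n)
  structure(list(rmsd = rmsd, rotation = R,
                 translation = as.numeric(cq - cp %*% t(R)),
                 n_atoms = n),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition: %d atoms, rmsd %.4f A\n", x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#'
#' @param coords nx3 matrix.
#' @param fit a `superposition_result`.
#' @return transformed nx3 matrix.
#' @export
apply_transform <- function(coords, fit) {
  sweep(coords %*% t(fit$rotation), 2, fit$translation, `+`)
}

#' Coordination distances around a central atom
#'
#' Euclidean distances from one central atom (e.g. the Zn of a Zn(S-Cys)4
#' site) to each ligand atom, and their arithmetic mean.
#'
#' @param model a `structure_model`.
#' @param center selection list `list(chain=, resseq=, name=)` resolving to
#'   exactly one atom.
#' @param ligands selection list resolving to one or more atoms.
#' @return list with `mean` (angstrom), `distances` (named per-ligand), and
#'   `n_ligands`.
#' @export
coordination_stats <- function(model, center, ligands) {
  ca <- do.call(select_atoms, c(list(model), center))
  if (nrow(ca) != 1) {
    stop(sprintf("center selection resolves to %d atoms (need exactly 1)",
                 nrow(ca)))
  }
  la <- do.call(select_atoms, c(list(model), ligands))
  if (nrow(la) < 1) stop("ligand selection resolves to no atoms")
  d <- sqrt(rowSums(sweep(.coords(la), 2, as.numeric(.coords(ca)))^2))
  names(d) <- sprintf("%s%d:%s", la$resname, la$resseq, la$name)
  list(mean = mean(d), distances = d, n_ligands = nrow(la))
}

#' Triclinic unit-cell volume
#'
#' `V = abc * sqrt(1 - cos^2(alpha) - cos^2(beta) - cos^2(gamma)
#'  + 2 cos(alpha) cos(beta) cos(gamma))`, the general triclinic formula;
#' for right angles it reduces to `abc`.
#'
#' @param cell a [unit_cell()].
#' @return volume in cubic angstroms.
#' @export
unit_cell_volume <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  rad <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (rad <= 0) stop("invalid angle combination: non-positive cell volume radicand")
  cell$a * cell$b * cell$c * sqrt(rad)
}

#' Grid-based van der Waals protein volume
#'
#' Volume of the union of van der Waals spheres of all non-water,
#' non-hydrogen atoms, computed by grid occupancy: a cubic grid of the given
#' spacing is laid over the bounding box and points falling inside any atom
#' sphere are counted. Radii (angstrom): C 1.70, N 1.55, O 1.52, S 1.80,
#' Zn 1.39, Fe 1.47, default 1.70. Deterministic; accuracy is limited by the
#' grid (about 1% at the 0.5 angstrom default for protein-sized objects).
#'
#' Absolute values depend on the radius set and exclude solvent-excluded
#' cavities; temperature trends and relative expansion are the intended use,
#' not comparison of absolute volumes between methods.
#'
#' @param model a `structure_model`.
#' @param spacing grid spacing in angstrom (default 0.5).
#' @return volume in cubic angstroms.
#' @export
protein_volume <- function(model, spacing = 0.5) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  a <- a[!(a$record == "HETATM" & a$resname == "HOH"), , drop = FALSE]
  a <- a[toupper(a$element) != "H", , drop = FALSE]
  if (!nrow(a)) stop("no non-water heavy atoms in model")
  el <- toupper(a$element)
  r <- unname(.vdw_radii[el])
  r[is.na(r)] <- .vdw_default
  rmax <- max(r)
  xyz <- .coords(a)

  gx <- seq(min(xyz[, 1]) - rmax, max(xyz[, 1]) + rmax, by = spacing)
  gy <- seq(min(xyz[, 2]) - rmax, max(xyz[, 2]) + rmax, by = spacing)
  gz <- seq(min(xyz[, 3]) - rmax, max(xyz[, 3]) + rmax, by = spacing)
  occ <- array(FALSE, dim = c(length(gx), length(gy), length(gz)))
  for (i in seq_len(nrow(a))) {
    ix <- which(abs(gx - xyz[i, 1]) <= r[i])
    iy <- which(abs(gy - xyz[i, 2]) <= r[i])
    iz <- which(abs(gz - xyz[i, 3]) <= r[i])
    if (!length(ix) || !length(iy) || !length(iz)) next
    sub <- expand.grid(x = gx[ix], y = gy[iy], z = gz[iz])
    d2 <- (sub$x - xyz[i, 1])^2 + (sub$y - xyz[i, 2])^2 + (sub$z - xyz[i, 3])^2
    inside <- array(d2 <= r[i]^2, dim = c(length(ix), length(iy), length(iz)))
    occ[ix, iy, iz] <- occ[ix, iy, iz] | inside
  }
  sum(occ) * spacing^3
}

#' Per-residue C-alpha B-factor profile
#'
#' Extracts the B-factor of each residue's C-alpha atom, in residue order.
#' Residues without a C-alpha (e.g. ligands) are skipped with a warning.
#'
#' @param model a `structure_model`.
#' @return an object of class `bfactor_profile`: data.frame with columns
#'   `resseq` and `bfactor` (square angstrom), attribute `temperature`.
#' @seealso [normalize_bfactors()]
#' @export
bfactor_profile <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  prot <- model$atoms[model$atoms$record == "ATOM", , drop = FALSE]
  if (!nrow(prot)) stop("model has no ATOM records")
  res <- unique(prot[, c("chain", "resseq")])
  ca <- prot[prot$name == "CA", , drop = FALSE]
  if (!nrow(ca)) stop("model has no C-alpha atoms")
  missing <- nrow(res) - nrow(unique(ca[, c("chain", "resseq")]))
  if (missing > 0) {
    warning(sprintf("%d residue(s) lack a C-alpha atom and were skipped",
                    missing))
  }
  ca <- ca[!duplicated(paste(ca$chain, ca$resseq)), , drop = FALSE]
  out <- data.frame(resseq = ca$resseq, bfactor = ca$bfactor)
  out <- out[order(out$resseq), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "temperature") <- model$temperature
  class(out) <- c("bfactor_profile", "data.frame")
  out
}

#' Normalize a B-factor profile to per-structure z-scores
#'
#' Standardizes a C-alpha B-factor profile within one structure:
#' `(B - mean(B)) / sd(B)` over the profile's residues, giving a
#' dimensionless profile with mean 0 and standard deviation 1. This makes
#' the spatial pattern of disorder comparable across structures collected at
#' different temperatures, whose absolute B scales differ.
#'
#' @param profile a `bfactor_profile` with at least 2 residues and nonzero
#'   spread.
#' @return a `bfactor_profile` with `bfactor` replaced by its z-score.
#' @export
normalize_bfactors <- function(profile) {
  stopifnot(inherits(profile, "bfactor_profile"))
  if (nrow(profile) < 2) stop("profile needs at least 2 residues")
  s <- stats::sd(profile$bfactor)
  if (!is.finite(s) || s == 0) stop("zero spread: profile cannot be normalized")
  profile$bfactor <- (profile$bfactor - mean(profile$bfactor)) / s
  profile
}

#' Convert between B-factor and isotropic mean-square displacement
#'
#' Isotropic relation `B = 8 pi^2 <u^2> / 3` for mean-square displacement
#' `<u^2>` (square angstrom). Provided as a documented conversion; headline
#' profile outputs stay in B units.
#'
#' @param b B-factor(s), square angstrom.
#' @param msd mean-square displacement(s), square angstrom.
#' @return the converted quantity.
#' @export
b_to_msd <- function(b) 3 * b / (8 * pi^2)

#' @rdname b_to_msd
#' @export
msd_to_b <- function(msd) 8 * pi^2 * msd / 3
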