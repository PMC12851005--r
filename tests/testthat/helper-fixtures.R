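# shared in-code fixtures: tiny PDB texts and bare structure models

pdb_atom_line <- function(serial, name, resname, chain, resseq, x, y, z,
                          occ = 1, b = 10, element = substr(name, 1, 1),
                          record = "ATOM", altloc = " ") {
  sprintf("%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial,
          if (nchar(name) == 4) name else sprintf(" %-3s", name),
          altloc, resname, chain, resseq, x, y, z, occ, b, element)
}

# hand-written mixed fixture: 5 protein atoms, 3 waters, cubic cell
mixed_fixture_text <- function() {
  c("CRYST1   10.000   10.000   10.000  90.00  90.00  90.00 P 1",
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0, element = "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.5, 0, 0, element = "C"),
    pdb_atom_line(3, "C", "ALA", "A", 1, 2.5, 1, 0, element = "C"),
    pdb_atom_line(4, "O", "ALA", "A", 1, 2.5, 2.2, 0, element = "O"),
    pdb_atom_line(5, "CA", "GLY", "A", 2, 5.0, 0, 0, element = "C"),
    pdb_atom_line(6, "O", "HOH", "A", 101, 8, 8, 8, record = "HETATM",
                  element = "O"),
    pdb_atom_line(7, "O", "HOH", "A", 102, 8, 8, 5, record = "HETATM",
                  element = "O"),
    pdb_atom_line(8, "O", "HOH", "A", 103, 8, 5, 8, record = "HETATM",
                  element = "O"),
    "END")
}

# build a structure_model directly from coordinate/name vectors
bare_model <- function(xyz, name, resname = "ALA", resseq = seq_len(nrow(xyz)),
                       chain = "A", record = "ATOM", b = 10,
                       element = substr(name, 1, 1), cell = NULL,
                       temperature = 298, label = "toy") {
  n <- nrow(xyz)
  atoms <- data.frame(serial = seq_len(n), name = name, altloc = "",
                      resname = rep_len(resname, n),
                      chain = rep_len(chain, n),
                      resseq = rep_len(resseq, n),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      occupancy = 1, bfactor = rep_len(b, n),
                      element = rep_len(element, n),
                      record = rep_len(record, n), stringsAsFactors = FALSE)
  structure(list(atoms = atoms, cell = cell, temperature = temperature,
                 label = label), class = "structure_model")
}

random_rotation <- function() {
  # QR of a random matrix, sign-corrected to a proper rotation
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(model, R, t) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  model$atoms$x <- xyz[, 1] + t[1]
  model$atoms$y <- xyz[, 2] + t[2]
  model$atoms$z <- xyz[, 3] + t[3]
  model
}

# small default fixture series, built once per test run
fixture_series_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_structure_series(fixture_config())
    cache
  }
})
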