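#' @keywords internal
"_PACKAGE"

# Fixed PDB columns (1-based, inclusive) shared by parser and writer.
.pdb_cols <- list(
  record = c(1L, 6L), serial = c(7L, 11L), name = c(13L, 16L),
  altloc = c(17L, 17L), resname = c(18L, 20L), chain = c(22L, 22L),
  resseq = c(23L, 26L), x = c(31L, 38L), y = c(39L, 46L), z = c(47L, 54L),
  occupancy = c(55L, 60L), bfactor = c(61L, 66L), element = c(77L, 78L)
)

.field <- function(lines, col) trimws(substr(lines, col[1], col[2]))

.num_field <- function(lines, col, what, lineno) {
  v <- suppressWarnings(as.numeric(.field(lines, col)))
  bad <- is.na(v)
  if (any(bad)) {
    stop(sprintf("malformed %s field on line %d: '%s'",
                 what, lineno[bad][1],
                 substr(lines[bad][1], col[1], col[2])), call. = FALSE)
  }
  v
}

#' Parse a PDB-format string into a structure model
#'
#' Reads `ATOM`/`HETATM` records using fixed PDB columns (serial 7-11, atom
#' name 13-16, altLoc 17, residue name 18-20, chain 22, residue number 23-26,
#' coordinates 31-54, occupancy 55-60, B-factor 61-66, element 77-78) and the
#' `CRYST1` record, when present, into unit-cell parameters. Waters are
#' `HETATM` records with residue name `HOH`. Only blank or `'A'` alternate
#' locations are kept: the structures this package targets are refined with a
#' single conformation per residue.
#'
#' The crystallization/data-collection temperature is supplied by the caller
#' (REMARK dialects vary too much to parse reliably) and travels with the
#' model so that downstream series operations can sort and label by it.
#'
#' @param text a single string, or character vector of lines, in PDB format.
#' @param temperature temperature label in kelvin (> 0).
#' @param label free-text label for the model.
#' @return an object of class `structure_model`: a list with elements
#'   `atoms` (data.frame with columns serial, name, altloc, resname, chain,
#'   resseq, x, y, z, occupancy, bfactor, element, record, in file order),
#'   `cell` (a [unit_cell()] or `NULL` when no CRYST1 record is present),
#'   `temperature`, and `label`.
#' @seealso [write_pdb()], [select_atoms()], [water_count()]
#' @examples
#' txt <- paste0("ATOM      1  CA  ALA A   1       1.000   2.000   3.000",
#'               "  1.00 10.00           C")
#' m <- parse_pdb(txt, temperature = 100)
#' m$atoms$x
#' @export
parse_pdb <- function(text, temperature = 298, label = "") {
  stopifnot(is.character(text), length(text) >= 1)
  if (length(text) == 1 && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0) {
    stop("temperature must be a single positive number (kelvin)")
  }
  rec <- .field(text, .pdb_cols$record)
  is_atom <- rec %in% c("ATOM", "HETATM")
  if (!any(is_atom)) stop("no ATOM or HETATM records found")
  lineno <- which(is_atom)
  lines <- text[is_atom]

  atoms <- data.frame(
    serial = as.integer(.num_field(lines, .pdb_cols$serial, "serial", lineno)),
    name = .field(lines, .pdb_cols$name),
    altloc = .field(lines, .pdb_cols$altloc),
    resname = .field(lines, .pdb_cols$resname),
    chain = .field(lines, .pdb_cols$chain),
    resseq = as.integer(.num_field(lines, .pdb_cols$resseq, "resseq", lineno)),
    x = .num_field(lines, .pdb_cols$x, "x", lineno),
    y = .num_field(lines, .pdb_cols$y, "y", lineno),
    z = .num_field(lines, .pdb_cols$z, "z", lineno),
    occupancy = .num_field(lines, .pdb_cols$occupancy, "occupancy", lineno),
    bfactor = .num_field(lines, .pdb_cols$bfactor, "bfactor", lineno),
    element = .field(lines, .pdb_cols$element),
    record = .field(lines, .pdb_cols$record),
    stringsAsFactors = FALSE
  )
  atoms <- atoms[atoms$altloc %in% c("", "A"), , drop = FALSE]
  rownames(atoms) <- NULL

  cell <- NULL
  cl <- text[startsWith(text, "CRYST1")]
  if (length(cl) >= 1) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(substr(cl[1], 7, 54)),
                                              "[[:space:]]+")[[1]]))
    if (length(f) < 6 || anyNA(f[1:6])) {
      stop("malformed CRYST1 record: ", cl[1])
    }
    cell <- unit_cell(f[1], f[2], f[3], f[4], f[5], f[6])
  }

  structure(list(atoms = atoms, cell = cell,
                 temperature = temperature, label = label),
            class = "structure_model")
}

#' Read a PDB file from disk
#'
#' @inheritParams parse_pdb
#' @param path path to a PDB file.
#' @return a `structure_model`; see [parse_pdb()].
#' @export
read_pdb <- function(path, temperature = 298, label = basename(path)) {
  parse_pdb(readLines(path, warn = FALSE), temperature = temperature,
            label = label)
}

#' Unit-cell parameters
#'
#' Crystallographic unit cell with edge lengths in angstroms and angles in
#' degrees, as carried by a PDB `CRYST1` record.
#'
#' @param a,b,c cell edges (angstrom), all > 0.
#' @param alpha,beta,gamma cell angles (degrees), all in (0, 180).
#' @return an object of class `unit_cell`.
#' @seealso [unit_cell_volume()]
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  v <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(v))) stop("unit cell parameters must be finite")
  if (any(v[1:3] <= 0)) stop("unit cell lengths must be positive")
  if (any(v[4:6] <= 0 | v[4:6] >= 180)) {
    stop("unit cell angles must lie in (0, 180) degrees")
  }
  structure(as.list(v), class = "unit_cell")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d waters, T = %g K%s\n",
              nrow(x$atoms), water_count(x), x$temperature,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  if (!is.null(x$cell)) {
    cat(sprintf("  cell: %.3f %.3f %.3f  %.2f %.2f %.2f\n", x$cell$a,
                x$cell$b, x$cell$c, x$cell$alpha, x$cell$beta, x$cell$gamma))
  }
  invisible(x)
}

# PDB atom-name field: element symbol right-justified in cols 13-14, so
# names shorter than 4 characters start in column 14.
.format_atom_name <- function(name) {
  n <- nchar(name)
  if (any(n > 4)) {
    stop("atom name longer than 4 characters: ", name[n > 4][1])
  }
  ifelse(n == 4, name, sprintf(" %-3s", name))
}

#' Write a structure model as a PDB-format string
#'
#' Inverse of [parse_pdb()]: coordinates are written to 3 decimals,
#' occupancy and B-factor to 2, and the cell (when present) as a `CRYST1`
#' record, so that a parse/write/parse round trip is the identity at that
#' precision.
#'
#' @param model a `structure_model`.
#' @param path optional file path; when given the text is also written there.
#' @return invisibly, a character vector of PDB lines.
#' @export
write_pdb <- function(model, path = NULL) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  lines <- character(0)
  if (!is.null(model$cell)) {
    cl <- model$cell
    lines <- sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma)
  }
  if (nrow(a)) {
    lines <- c(lines, sprintf(
      "%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$record, a$serial, .format_atom_name(a$name), substr(a$altloc, 1, 1),
      a$resname, a$chain, a$resseq, a$x, a$y, a$z, a$occupancy, a$bfactor,
      a$element))
  }
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

.match_field <- function(values, pattern) {
  if (identical(pattern, "*") || is.null(pattern)) return(rep(TRUE, length(values)))
  if (grepl("[*?]", pattern)) {
    grepl(utils::glob2rx(pattern), values)
  } else {
    values == as.character(pattern)
  }
}

#' Select atoms by chain, residue number, and atom name
#'
#' Matches all three fields against the model's atoms, in file order. Each
#' field accepts an exact value or a glob pattern (`*`, `?`), e.g.
#' `name = "OD*"` selects the Asp carboxylate oxygens OD1 and OD2. An empty
#' selection is valid and returns a zero-row data frame.
#'
#' @param model a `structure_model`.
#' @param chain chain identifier or pattern (default `"*"`).
#' @param resseq residue number or pattern (default `"*"`).
#' @param name atom-name or pattern (default `"*"`).
#' @return the matching rows of `model$atoms`, in file order.
#' @export
select_atoms <- function(model, chain = "*", resseq = "*", name = "*") {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  keep <- .match_field(a$chain, chain) &
    .match_field(as.character(a$resseq), as.character(resseq)) &
    .match_field(a$name, name)
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count crystallographically ordered waters
#'
#' Waters are `HETATM` records with residue name `HOH`; the count is over
#' distinct (chain, residue number) pairs, so multi-atom water models are
#' not double-counted.
#'
#' @param model a `structure_model`.
#' @return integer water count.
#' @export
water_count <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  w <- a[a$record == "HETATM" & a$resname == "HOH", , drop = FALSE]
  if (!nrow(w)) return(0L)
  length(unique(paste(w$chain, w$resseq)))
}

# nx3 coordinate matrix for an atom data.frame
.coords <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}
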