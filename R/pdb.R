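# Protein structure container and PDB I/O. Structures are stored as a
# flat atom table (one row per atom) with class "protein_structure";
# file parsing and writing delegate to bio3d.

#' Bondi van der Waals radii (Angstroms)
#' @export
BONDI_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                 P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)

.vdw_radius <- function(elements) {
  r <- BONDI_RADII[elements]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Construct a protein structure from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid` (3-letter
#'   residue name), `elety` (PDB atom name), `elesy` (element symbol),
#'   `x`, `y`, `z` (Angstroms) and optionally `o` (occupancy).
#' @param source free-text provenance identifier.
#' @return object of class `protein_structure`.
#' @export
protein_structure <- function(atoms, source = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (!"o" %in% names(atoms)) atoms$o <- 1.0
  need <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, atom name) triple: ",
         key[which(duplicated(key))[1L]])
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source = source), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat(sprintf("<protein_structure%s: %d atoms, %d residues, chains %s>\n",
              if (nzchar(x$source)) paste0(" ", x$source) else "",
              nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain", "resno")])),
              paste(ch, collapse = ",")))
  invisible(x)
}

#' Coordinates of a structure (or subset) as an n x 3 matrix
#' @param s a `protein_structure`.
#' @param sel optional logical or integer row selection.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(s, sel = NULL) {
  a <- s$atoms
  if (!is.null(sel)) a <- a[sel, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Read a protein structure from a PDB file
#'
#' ATOM/HETATM records are parsed with bio3d; alternate locations other
#' than blank or 'A' are dropped. Records with unparsable coordinates
#' raise a format error naming the offending line.
#'
#' @param path path to a PDB file.
#' @return a `protein_structure`.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (k in which(rec)) {
    ln <- lines[k]
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop("PDB format error at line ", k, ": unparsable coordinates in '",
           ln, "'")
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  keep <- is.na(a$alt) | a$alt %in% c("", "A")
  a <- a[keep, , drop = FALSE]
  elesy <- a$elesy
  blank <- is.na(elesy) | !nzchar(trimws(elesy))
  elesy[blank] <- substr(gsub("[^A-Za-z]", "", a$elety[blank]), 1, 1)
  atoms <- data.frame(chain = ifelse(is.na(a$chain), "A", a$chain),
                      resno = a$resno, resid = a$resid,
                      elety = a$elety, elesy = trimws(elesy),
                      x = a$x, y = a$y, z = a$z,
                      o = ifelse(is.na(a$o), 1.0, a$o),
                      stringsAsFactors = FALSE)
  protein_structure(atoms, source = basename(path))
}

#' Write a protein structure to a PDB file
#'
#' Round-tripping through [read_pdb()] preserves coordinates to 3
#' decimals and residue ordering.
#' @param s a `protein_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  a <- s$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, o = a$o, b = rep(0, nrow(a)),
                   elesy = a$elesy)
  invisible(path)
}

# Resolve a selection spec into atom row indices. Selections are
# character strings: "B" (whole chain), "A:10-12" (residue range) or
# "A:15" (single residue).
.resolve_selection <- function(s, selection) {
  rows <- integer()
  for (sel in selection) {
    parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
    if (length(parts) == 1L) {
      hit <- which(s$atoms$chain == parts[1])
    } else {
      rng <- strsplit(parts[2], "-", fixed = TRUE)[[1]]
      lo <- as.integer(rng[1])
      hi <- if (length(rng) > 1L) as.integer(rng[2]) else lo
      hit <- which(s$atoms$chain == parts[1] &
                   s$atoms$resno >= lo & s$atoms$resno <= hi)
    }
    if (!length(hit)) stop("selection '", sel, "' matches no residues")
    rows <- union(rows, hit)
  }
  rows
}

#' Delete chains or residue ranges from a structure
#'
#' Used, e.g., to remove a chaperone peptide and linker from a template
#' complex before docking. All remaining atoms are untouched.
#'
#' @param s a `protein_structure`.
#' @param selection character vector of selections: `"B"` (whole chain),
#'   `"A:10-12"` (residue range) or `"A:15"` (single residue).
#' @return the structure without the selected residues.
#' @export
delete_components <- function(s, selection) {
  rows <- .resolve_selection(s, selection)
  out <- s
  out$atoms <- s$atoms[-rows, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

#' Extract atoms of a selection as a structure
#' @param s a `protein_structure`.
#' @param selection selection strings as in [delete_components()].
#' @return a `protein_structure` containing only the selected atoms.
#' @export
extract_components <- function(s, selection) {
  rows <- .resolve_selection(s, selection)
  out <- s
  out$atoms <- s$atoms[rows, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

#' Find steric clashes between two coordinate sets
#'
#' A pair of atoms clashes when its distance falls below the sum of the
#' Bondi van der Waals radii minus a tolerance. The scan is exhaustive
#' over all cross pairs and order-independent.
#'
#' @param coordsA,coordsB n x 3 coordinate matrices.
#' @param tolerance clash tolerance in Angstroms (default 0.4, the common
#'   crystallographic convention).
#' @param elementsA,elementsB element symbols per atom (default carbon).
#' @return data.frame with columns `i` (row in A), `j` (row in B),
#'   `dist`, `threshold`.
#' @export
find_clashes <- function(coordsA, coordsB, tolerance = 0.4,
                         elementsA = NULL, elementsB = NULL) {
  coordsA <- rbind(coordsA); coordsB <- rbind(coordsB)
  if (!nrow(coordsA) || !nrow(coordsB)) stop("both coordinate sets must be non-empty")
  rA <- .vdw_radius(if (is.null(elementsA)) rep("C", nrow(coordsA)) else elementsA)
  rB <- .vdw_radius(if (is.null(elementsB)) rep("C", nrow(coordsB)) else elementsB)
  d2 <- .cross_dist2(coordsA, coordsB)
  thr <- outer(rA, rB, "+") - tolerance
  hit <- which(d2 < thr^2, arr.ind = TRUE)
  data.frame(i = hit[, 1], j = hit[, 2],
             dist = sqrt(d2[hit]), threshold = thr[hit])
}

# Squared cross-distance matrix between two n x 3 coordinate sets.
.cross_dist2 <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  d2
}

#' Define a binding/degradation site from tagged residues
#'
#' @param s a `protein_structure`.
#' @param residues character vector of `"chain:resno"` residue tags.
#' @param radius site radius in Angstroms (default 8).
#' @return object of class `site_definition` with the residue list, the
#'   centroid of all their atoms, and the radius.
#' @export
define_site <- function(s, residues, radius = 8) {
  if (radius <= 0) stop("site radius must be positive")
  rows <- integer()
  for (r in residues) {
    parts <- strsplit(r, ":", fixed = TRUE)[[1]]
    hit <- which(s$atoms$chain == parts[1] & s$atoms$resno == as.integer(parts[2]))
    if (!length(hit)) stop("site residue '", r, "' not found in structure")
    rows <- c(rows, hit)
  }
  xyz <- coords(s, rows)
  structure(list(residues = residues, atom_rows = rows,
                 centroid = colMeans(xyz), radius = radius),
            class = "site_definition")
}

#' Minimum distance from a ligand to a site's residues
#'
#' Minimum over all (ligand heavy atom, site residue atom) Euclidean
#' distances; used by the degradation-site proximity filter.
#'
#' @param ligand_xyz n x 3 heavy-atom coordinates of the ligand.
#' @param s a `protein_structure`.
#' @param site a `site_definition` built from `s`.
#' @return minimum distance in Angstroms.
#' @export
min_site_distance <- function(ligand_xyz, s, site) {
  ligand_xyz <- rbind(ligand_xyz)
  if (!nrow(ligand_xyz)) stop("ligand must have at least one heavy atom")
  if (any(site$atom_rows > nrow(s$atoms)))
    stop("site residues absent from structure")
  site_xyz <- coords(s, site$atom_rows)
  sqrt(min(.cross_dist2(ligand_xyz, site_xyz)))
}
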