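# Virtual point mutagenesis: side chains are rebuilt from idealized
# internal-coordinate templates superposed on the existing backbone
# (N, CA, CB), one canonical rotamer per residue type. Backbone atoms
# are never moved.

AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", I = "ILE", L = "LEU",
            K = "LYS", M = "MET", F = "PHE", S = "SER", T = "THR",
            V = "VAL")
AA3TO1 <- stats::setNames(names(AA1TO3), AA1TO3)

#' Place an atom by internal coordinates (NeRF)
#'
#' Returns the position of atom d given reference positions a, b, c, the
#' bond length c-d, the angle b-c-d (degrees) and the torsion a-b-c-d
#' (degrees).
#' @param a,b,c reference coordinates (length-3 numeric).
#' @param bond,angle,torsion internal coordinates (Angstrom, degrees).
#' @return length-3 coordinate vector.
#' @keywords internal
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  mm <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * mm + d2[3] * n
}

# Side-chain templates beyond CB as internal coordinates. Each entry:
# atom name, element, reference atom names (a, b, c), bond, angle,
# torsion. References may be backbone (N, CA, CB) or earlier template
# atoms. Single canonical rotamer (chi angles trans where free).
.SIDECHAIN_TEMPLATES <- list(
  ALA = list(),
  VAL = list(
    list("CG1", "C", c("N", "CA", "CB"), 1.521, 110.5, 180),
    list("CG2", "C", c("N", "CA", "CB"), 1.521, 110.5, -60)
  ),
  LEU = list(
    list("CG", "C", c("N", "CA", "CB"), 1.530, 114.1, 180),
    list("CD1", "C", c("CA", "CB", "CG"), 1.521, 110.7, 180),
    list("CD2", "C", c("CA", "CB", "CG"), 1.521, 110.7, 60)
  ),
  ILE = list(
    list("CG1", "C", c("N", "CA", "CB"), 1.530, 110.4, 180),
    list("CG2", "C", c("N", "CA", "CB"), 1.521, 110.5, -60),
    list("CD1", "C", c("CA", "CB", "CG1"), 1.513, 113.8, 180)
  ),
  PHE = list(
    list("CG", "C", c("N", "CA", "CB"), 1.502, 113.8, 180),
    list("CD1", "C", c("CA", "CB", "CG"), 1.390, 120.0, 90),
    list("CD2", "C", c("CA", "CB", "CG"), 1.390, 120.0, -90),
    list("CE1", "C", c("CB", "CG", "CD1"), 1.390, 120.0, 180),
    list("CE2", "C", c("CB", "CG", "CD2"), 1.390, 120.0, 180),
    list("CZ", "C", c("CG", "CD1", "CE1"), 1.390, 120.0, 0)
  ),
  TYR = list(
    list("CG", "C", c("N", "CA", "CB"), 1.512, 113.9, 180),
    list("CD1", "C", c("CA", "CB", "CG"), 1.390, 120.0, 90),
    list("CD2", "C", c("CA", "CB", "CG"), 1.390, 120.0, -90),
    list("CE1", "C", c("CB", "CG", "CD1"), 1.390, 120.0, 180),
    list("CE2", "C", c("CB", "CG", "CD2"), 1.390, 120.0, 180),
    list("CZ", "C", c("CG", "CD1", "CE1"), 1.390, 120.0, 0),
    list("OH", "O", c("CD1", "CE1", "CZ"), 1.376, 120.0, 180)
  ),
  LYS = list(
    list("CG", "C", c("N", "CA", "CB"), 1.520, 114.1, 180),
    list("CD", "C", c("CA", "CB", "CG"), 1.520, 111.3, 180),
    list("CE", "C", c("CB", "CG", "CD"), 1.520, 111.3, 180),
    list("NZ", "N", c("CG", "CD", "CE"), 1.489, 111.9, 180)
  ),
  ARG = list(
    list("CG", "C", c("N", "CA", "CB"), 1.520, 114.1, 180),
    list("CD", "C", c("CA", "CB", "CG"), 1.520, 111.3, 180),
    list("NE", "N", c("CB", "CG", "CD"), 1.461, 112.0, 180),
    list("CZ", "C", c("CG", "CD", "NE"), 1.329, 124.2, 180),
    list("NH1", "N", c("CD", "NE", "CZ"), 1.326, 120.0, 0),
    list("NH2", "N", c("CD", "NE", "CZ"), 1.326, 120.0, 180)
  ),
  SER = list(
    list("OG", "O", c("N", "CA", "CB"), 1.417, 110.8, 180)
  ),
  THR = list(
    list("OG1", "O", c("N", "CA", "CB"), 1.433, 109.6, 180),
    list("CG2", "C", c("N", "CA", "CB"), 1.521, 110.5, -60)
  ),
  CYS = list(
    list("SG", "S", c("N", "CA", "CB"), 1.808, 113.8, 180)
  ),
  MET = list(
    list("CG", "C", c("N", "CA", "CB"), 1.520, 114.1, 180),
    list("SD", "S", c("CA", "CB", "CG"), 1.803, 112.7, 180),
    list("CE", "C", c("CB", "CG", "SD"), 1.791, 100.9, 180)
  ),
  ASP = list(
    list("CG", "C", c("N", "CA", "CB"), 1.516, 112.6, 180),
    list("OD1", "O", c("CA", "CB", "CG"), 1.250, 118.5, 0),
    list("OD2", "O", c("CA", "CB", "CG"), 1.250, 118.5, 180)
  ),
  ASN = list(
    list("CG", "C", c("N", "CA", "CB"), 1.516, 112.6, 180),
    list("OD1", "O", c("CA", "CB", "CG"), 1.231, 120.8, 0),
    list("ND2", "N", c("CA", "CB", "CG"), 1.328, 116.4, 180)
  ),
  GLU = list(
    list("CG", "C", c("N", "CA", "CB"), 1.520, 114.1, 180),
    list("CD", "C", c("CA", "CB", "CG"), 1.516, 112.6, 180),
    list("OE1", "O", c("CB", "CG", "CD"), 1.250, 118.5, 0),
    list("OE2", "O", c("CB", "CG", "CD"), 1.250, 118.5, 180)
  ),
  GLN = list(
    list("CG", "C", c("N", "CA", "CB"), 1.520, 114.1, 180),
    list("CD", "C", c("CA", "CB", "CG"), 1.516, 112.6, 180),
    list("OE1", "O", c("CB", "CG", "CD"), 1.231, 120.8, 0),
    list("NE2", "N", c("CB", "CG", "CD"), 1.328, 116.4, 180)
  ),
  GLY = list()
)

#' Specify point mutations
#'
#' @param chain chain identifier(s).
#' @param position PDB residue number(s) in the structure's own numbering.
#' @param from,to 1-letter codes of the current and the target residue.
#' @return data.frame of class `mutation_spec`.
#' @examples
#' mutation_spec("A", c(71, 72, 74, 81), c("V", "A", "L", "R"),
#'               c("A", "V", "F", "K"))
#' @export
mutation_spec <- function(chain, position, from, to) {
  if (!all(from %in% names(AA1TO3)) || !all(to %in% names(AA1TO3)))
    stop("mutation residues must be supported 1-letter amino acid codes (",
         paste(names(AA1TO3), collapse = ""), ")")
  df <- data.frame(chain = chain, position = as.integer(position),
                   from = from, to = to, stringsAsFactors = FALSE)
  class(df) <- c("mutation_spec", "data.frame")
  df
}

#' Apply point mutations to a structure
#'
#' For each mutation the backbone atoms (N, CA, C, O and CB where the
#' target residue has one) keep their coordinates bit-identically; the
#' side chain beyond CB is rebuilt from an idealized internal-coordinate
#' template anchored on the residue's own N/CA/CB frame, and the residue
#' is renamed. Truncating mutations (e.g. V to A) reduce to atom
#' deletion.
#'
#' @param s a `protein_structure`.
#' @param specs a `mutation_spec` (see [mutation_spec()]).
#' @return the mutated structure.
#' @export
apply_mutations <- function(s, specs) {
  a <- s$atoms
  for (k in seq_len(nrow(specs))) {
    ch <- specs$chain[k]; pos <- specs$position[k]
    rows <- which(a$chain == ch & a$resno == pos)
    if (!length(rows))
      stop("mutation ", specs$from[k], pos, specs$to[k],
           ": no residue at ", ch, ":", pos)
    cur3 <- unique(a$resid[rows])
    if (length(cur3) != 1L || is.na(AA3TO1[cur3]) ||
        AA3TO1[[cur3]] != specs$from[k])
      stop("mutation ", specs$from[k], pos, specs$to[k], ": residue at ",
           ch, ":", pos, " is ", paste(cur3, collapse = "/"), ", not ",
           AA1TO3[[specs$from[k]]])
    to3 <- AA1TO3[[specs$to[k]]]
    tmpl <- .SIDECHAIN_TEMPLATES[[to3]]
    if (is.null(tmpl))
      stop("no side-chain template for target residue ", to3)
    keep_names <- c("N", "CA", "C", "O", "OXT")
    if (to3 != "GLY") keep_names <- c(keep_names, "CB")
    keep <- rows[a$elety[rows] %in% keep_names]
    drop <- setdiff(rows, keep)
    # anchor frame
    getxyz <- function(name) {
      r <- rows[a$elety[rows] == name]
      if (!length(r)) return(NULL)
      as.numeric(a[r[1], c("x", "y", "z")])
    }
    anchors <- list(N = getxyz("N"), CA = getxyz("CA"), CB = getxyz("CB"),
                    C = getxyz("C"))
    if (is.null(anchors$N) || is.null(anchors$CA))
      stop("residue ", ch, ":", pos, " lacks backbone N/CA; cannot rebuild")
    if (to3 != "GLY" && is.null(anchors$CB)) {
      if (is.null(anchors$C))
        stop("residue ", ch, ":", pos, " lacks CB and C; cannot place CB")
      cb <- nerf_place(anchors$C, anchors$N, anchors$CA, 1.530, 110.5, -122)
      newrow <- a[rows[1], , drop = FALSE]
      newrow$elety <- "CB"; newrow$elesy <- "C"
      newrow[c("x", "y", "z")] <- as.list(cb)
      a <- rbind(a, newrow)
      keep <- c(keep, nrow(a))
      anchors$CB <- cb
    }
    placed <- anchors
    newrows <- list()
    for (t in tmpl) {
      refs <- lapply(t[[3]], function(nm) placed[[nm]])
      if (any(vapply(refs, is.null, TRUE)))
        stop("internal template reference missing for ", to3)
      p <- nerf_place(refs[[1]], refs[[2]], refs[[3]], t[[4]], t[[5]], t[[6]])
      placed[[t[[1]]]] <- p
      nr <- a[rows[1], , drop = FALSE]
      nr$elety <- t[[1]]; nr$elesy <- t[[2]]
      nr$x <- p[1]; nr$y <- p[2]; nr$z <- p[3]
      newrows[[length(newrows) + 1L]] <- nr
    }
    a$resid[keep] <- to3
    if (length(drop)) a <- a[-drop, , drop = FALSE]
    if (length(newrows)) {
      nr <- do.call(rbind, newrows)
      nr$resid <- to3
      # insert after the kept atoms of this residue to preserve ordering
      last <- max(which(a$chain == ch & a$resno == pos))
      a <- rbind(a[seq_len(last), , drop = FALSE], nr,
                 a[-seq_len(last), , drop = FALSE][
                   seq_len(nrow(a) - last), , drop = FALSE])
    }
    rownames(a) <- NULL
  }
  protein_structure(a, source = s$source)
}

#' Build a synthetic peptide with idealized geometry
#'
#' Constructs an extended-conformation peptide (phi = -120, psi = 120,
#' omega = 180) from a 1-letter sequence, with side chains from the same
#' idealized templates used by [apply_mutations()]. Intended for fixtures
#' and tests: the result is a valid full-atom `protein_structure`.
#'
#' @param sequence 1-letter amino acid string.
#' @param chain chain id.
#' @param start_resno residue number of the first residue.
#' @param origin coordinates of the first N atom.
#' @return a `protein_structure`.
#' @export
make_synthetic_peptide <- function(sequence, chain = "A", start_resno = 1L,
                                   origin = c(0, 0, 0)) {
  aa <- strsplit(sequence, "")[[1]]
  if (!all(aa %in% names(AA1TO3)))
    stop("unsupported residue(s): ",
         paste(setdiff(aa, names(AA1TO3)), collapse = ","))
  rows <- list()
  # backbone internal coordinates
  prevC <- NULL; prevCA <- NULL; prevN <- NULL
  for (i in seq_along(aa)) {
    res3 <- AA1TO3[[aa[i]]]
    resno <- start_resno + i - 1L
    if (i == 1L) {
      N <- origin
      CA <- N + c(1.458, 0, 0)
      C <- nerf_place(N + c(0, 1, 0), N, CA, 1.525, 111.0, -120)
    } else {
      N <- nerf_place(prevN, prevCA, prevC, 1.329, 116.2, 120)   # psi
      CA <- nerf_place(prevCA, prevC, N, 1.458, 121.7, 180)      # omega
      C <- nerf_place(prevC, N, CA, 1.525, 111.0, -120)          # phi
    }
    O <- nerf_place(N, CA, C, 1.231, 120.8, -60)
    add <- function(name, el, p) {
      rows[[length(rows) + 1L]] <<- data.frame(
        chain = chain, resno = resno, resid = res3, elety = name,
        elesy = el, x = p[1], y = p[2], z = p[3], o = 1.0,
        stringsAsFactors = FALSE)
    }
    add("N", "N", N); add("CA", "C", CA); add("C", "C", C); add("O", "O", O)
    placed <- list(N = N, CA = CA, C = C)
    if (res3 != "GLY") {
      CB <- nerf_place(C, N, CA, 1.530, 110.5, -122)
      add("CB", "C", CB)
      placed$CB <- CB
      for (t in .SIDECHAIN_TEMPLATES[[res3]]) {
        p <- nerf_place(placed[[t[[3]][1]]], placed[[t[[3]][2]]],
                        placed[[t[[3]][3]]], t[[4]], t[[5]], t[[6]])
        placed[[t[[1]]]] <- p
        add(t[[1]], t[[2]], p)
      }
    }
    prevN <- N; prevCA <- CA; prevC <- C
  }
  protein_structure(do.call(rbind, rows), source = "synthetic-peptide")
}
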