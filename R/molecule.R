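# Molecular graph model: atoms carry element, formal charge, implicit H
# count and an aromatic flag; bonds carry 0-based... no: 1-based atom
# indices and an order code (1, 2, 3, or 4 for aromatic, as in SDF V2000).

#' Standard atomic weights (IUPAC 2021, 3 decimals)
#' @keywords internal
ATOMIC_WEIGHTS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904
)

# Default valences of the SMILES organic subset; charge shifts them
# (N+ gets 4, O- gets 1, carbanion/carbocation lose one).
.default_valence <- list(
  B = 3, C = 4, N = 3, O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

#' Construct a molecule from atom and bond tables
#'
#' @param atoms data.frame with columns `element`, `charge`, `nH`
#'   (implicit hydrogen count) and `aromatic` (logical).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices)
#'   and `order` (1, 2, 3, or 4 = aromatic).
#' @param name molecule name.
#' @param conformers optional list of conformers (see [embed_conformers()]).
#' @return An object of class `molecule`.
#' @export
molecule <- function(atoms, bonds, name = "", conformers = list()) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms) == 0L) {
    atoms <- data.frame(element = character(), charge = integer(),
                        nH = integer(), aromatic = logical())
  }
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  } else {
    bonds <- as.data.frame(bonds)
  }
  m <- structure(list(atoms = atoms, bonds = bonds, name = name,
                      conformers = conformers),
                 class = "molecule")
  validate_molecule(m)
  m
}

#' Validate molecule invariants
#'
#' Checks bond index validity, absence of self- and duplicate bonds, and
#' that aromatic flags only occur on ring atoms.
#' @param m a `molecule`.
#' @return `m`, invisibly; stops on violation.
#' @export
validate_molecule <- function(m) {
  n <- nrow(m$atoms)
  b <- m$bonds
  if (nrow(b) > 0L) {
    if (any(b$i < 1L | b$i > n | b$j < 1L | b$j > n))
      stop("bond references atom index outside 1..", n)
    if (any(b$i == b$j)) stop("self-bond (i == j) not allowed")
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    if (anyDuplicated(key)) stop("duplicate bond between the same atom pair")
    if (!all(b$order %in% c(1L, 2L, 3L, 4L)))
      stop("bond order must be 1, 2, 3 or 4 (aromatic)")
  }
  if (any(m$atoms$aromatic)) {
    ring <- ring_atoms(m)
    bad <- which(m$atoms$aromatic & !ring)
    if (length(bad))
      stop("aromatic flag on non-ring atom(s): ", paste(bad, collapse = ", "))
  }
  invisible(m)
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule%s: %d atoms, %d bonds, %d conformer(s)>\n",
              if (nzchar(x$name)) paste0(" ", x$name) else "",
              nrow(x$atoms), nrow(x$bonds), length(x$conformers)))
  invisible(x)
}

# Adjacency list (neighbors per atom) as list of integer vectors.
.adjacency <- function(m) {
  n <- nrow(m$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(m$bonds))) {
    i <- m$bonds$i[k]; j <- m$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# Bond lookup: order of the bond between a and b, or 0L.
.bond_order <- function(m, a, b) {
  hit <- (m$bonds$i == a & m$bonds$j == b) | (m$bonds$i == b & m$bonds$j == a)
  if (any(hit)) m$bonds$order[which(hit)[1L]] else 0L
}

#' Which atoms lie in a ring?
#'
#' An atom is a ring atom iff it is not removed by iteratively pruning
#' degree-<=1 vertices.
#' @param m a `molecule`.
#' @return logical vector over atoms.
#' @keywords internal
ring_atoms <- function(m) {
  n <- nrow(m$atoms)
  deg <- integer(n)
  alive <- rep(TRUE, n)
  adj <- .adjacency(m)
  deg <- vapply(adj, length, 1L)
  repeat {
    leaf <- which(alive & deg <= 1L)
    if (!length(leaf)) break
    for (v in leaf) {
      alive[v] <- FALSE
      for (w in adj[[v]]) if (alive[w]) deg[w] <- deg[w] - 1L
      deg[v] <- 0L
    }
  }
  alive
}

# Smallest set of smallest rings, approximated by BFS shortest cycles
# through each ring bond (adequate for drug-like fused ring systems).
.find_rings <- function(m, max_size = 8L) {
  nb <- nrow(m$bonds)
  adj <- .adjacency(m)
  rings <- list()
  seen <- character()
  for (k in seq_len(nb)) {
    a <- m$bonds$i[k]; b <- m$bonds$j[k]
    # shortest path a->b avoiding the direct bond
    n <- nrow(m$atoms)
    prev <- rep(NA_integer_, n)
    dist <- rep(NA_integer_, n)
    dist[a] <- 0L
    queue <- a
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (v == a && w == b) next
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          prev[w] <- v
          queue <- c(queue, w)
        }
      }
      if (!is.na(dist[b])) break
    }
    if (is.na(dist[b]) || dist[b] + 1L > max_size) next
    path <- b
    while (path[1L] != a) path <- c(prev[path[1L]], path)
    key <- paste(sort(path), collapse = "-")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- path
    }
  }
  rings
}

# Sum of bond orders at an atom, aromatic bonds counting 1.5.
.bond_order_sum <- function(m) {
  n <- nrow(m$atoms)
  s <- numeric(n)
  for (k in seq_len(nrow(m$bonds))) {
    o <- m$bonds$order[k]
    v <- if (o == 4L) 1.5 else as.numeric(o)
    s[m$bonds$i[k]] <- s[m$bonds$i[k]] + v
    s[m$bonds$j[k]] <- s[m$bonds$j[k]] + v
  }
  s
}

# Implicit hydrogen count for organic-subset atoms from standard valence.
.implicit_h <- function(element, charge, bosum) {
  vals <- .default_valence[[element]]
  if (is.null(vals)) return(0L)
  if (element %in% c("N", "P", "B", "O", "S")) vals <- vals + charge
  else vals <- vals - abs(charge)
  need <- ceiling(bosum - 1e-9)
  v <- vals[vals >= need]
  if (!length(v)) return(0L)
  max(0L, as.integer(min(v)) - as.integer(need))
}

#' Molecular formula (Hill order)
#' @param m a `molecule`.
#' @return character scalar such as `"C28H35N3O3"`.
#' @export
molecular_formula <- function(m) {
  if (nrow(m$atoms) == 0L) return("")
  counts <- table(m$atoms$element)
  nh <- sum(m$atoms$nH)
  els <- names(counts)
  hill <- c(intersect("C", els), if (nh > 0) "H", sort(setdiff(els, c("C", "H"))))
  parts <- vapply(hill, function(e) {
    k <- if (e == "H") nh + sum(counts[names(counts) == "H"]) else counts[[e]]
    if (k == 1L) e else paste0(e, k)
  }, "")
  paste(parts, collapse = "")
}

#' Parse a SMILES string into a molecule
#'
#' Supports the Daylight organic subset (B, C, N, O, P, S, F, Cl, Br, I),
#' aromatic lowercase atoms, branches, ring-closure digits (and `%nn`),
#' bond symbols `-`, `=`, `#`, `:` (stereo bond marks `/` and `\` are read
#' as single bonds), and bracket atoms with charge and explicit H count.
#' Aromaticity of Kekule-form rings is perceived with a simple smallest-ring
#' Hueckel (4n+2) rule; implicit hydrogens are filled to standard valence.
#'
#' @param text a single SMILES string.
#' @param name optional molecule name.
#' @return a `molecule`.
#' @examples
#' benzene <- parse_smiles("c1ccccc1")
#' sum(benzene$atoms$nH)  # 6
#' @export
parse_smiles <- function(text, name = "") {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("SMILES input must be a single non-empty string")
  chars <- strsplit(text, "")[[1]]
  np <- length(chars)
  atoms <- list()
  bonds <- list()
  prev_stack <- integer()   # branch stack
  prev <- NA_integer_
  pending <- NA_integer_    # explicit bond order before next atom
  ring_open <- list()       # closure id -> list(atom, order)
  pos <- 1L

  add_atom <- function(element, aromatic, charge = 0L, hcount = NA_integer_,
                       bracket = FALSE) {
    atoms[[length(atoms) + 1L]] <<- list(element = element, charge = charge,
                                         nH = hcount, aromatic = aromatic,
                                         bracket = bracket)
    idx <- length(atoms)
    if (!is.na(prev)) {
      o <- pending
      if (is.na(o)) {
        o <- if (aromatic && atoms[[prev]]$aromatic) 4L else 1L
      }
      bonds[[length(bonds) + 1L]] <<- list(i = prev, j = idx, order = o)
    }
    prev <<- idx
    pending <<- NA_integer_
    idx
  }
  close_ring <- function(id) {
    if (!is.null(ring_open[[id]])) {
      op <- ring_open[[id]]
      o <- pending
      if (is.na(o)) o <- op$order
      if (is.na(o)) {
        o <- if (atoms[[op$atom]]$aromatic && atoms[[prev]]$aromatic) 4L else 1L
      }
      bonds[[length(bonds) + 1L]] <<- list(i = op$atom, j = prev, order = o)
      ring_open[[id]] <<- NULL
      pending <<- NA_integer_
    } else {
      ring_open[[id]] <<- list(atom = prev, order = pending)
      pending <<- NA_integer_
    }
  }

  while (pos <= np) {
    ch <- chars[pos]
    if (ch %in% c("-", "/", "\\")) { pending <- 1L; pos <- pos + 1L }
    else if (ch == "=") { pending <- 2L; pos <- pos + 1L }
    else if (ch == "#") { pending <- 3L; pos <- pos + 1L }
    else if (ch == ":") { pending <- 4L; pos <- pos + 1L }
    else if (ch == "(") {
      if (is.na(prev)) stop("SMILES parse error at position ", pos,
                            ": branch before any atom")
      prev_stack <- c(prev_stack, prev); pos <- pos + 1L
    }
    else if (ch == ")") {
      if (!length(prev_stack)) stop("SMILES parse error at position ", pos,
                                    ": unmatched ')'")
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      pos <- pos + 1L
    }
    else if (grepl("[0-9]", ch)) { close_ring(ch); pos <- pos + 1L }
    else if (ch == "%") {
      if (pos + 2L > np) stop("SMILES parse error at position ", pos,
                              ": truncated %nn ring closure")
      close_ring(paste0(chars[pos + 1L], chars[pos + 2L]))
      pos <- pos + 3L
    }
    else if (ch == "[") {
      close_br <- pos
      while (close_br <= np && chars[close_br] != "]") close_br <- close_br + 1L
      if (close_br > np) stop("SMILES parse error at position ", pos,
                              ": unterminated bracket atom")
      inner <- paste(chars[(pos + 1L):(close_br - 1L)], collapse = "")
      mt <- regmatches(inner,
        regexec("^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H([0-9]*))?([+-][0-9]*|[+]+|[-]+)?$",
                inner))[[1]]
      if (!length(mt)) stop("SMILES parse error at position ", pos,
                            ": cannot parse bracket atom [", inner, "]")
      sym <- mt[3]
      aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
      element <- if (aromatic) toupper(sym) else sym
      if (!(element %in% names(ATOMIC_WEIGHTS)) || element == "H")
        stop("unsupported element '", element, "' in SMILES at position ", pos)
      hc <- 0L
      if (nzchar(mt[5])) hc <- if (nzchar(mt[6])) as.integer(mt[6]) else 1L
      chg <- 0L
      cs <- mt[7]
      if (nzchar(cs)) {
        if (grepl("^[+-][0-9]+$", cs)) {
          chg <- as.integer(substring(cs, 2))
          if (substring(cs, 1, 1) == "-") chg <- -chg
        } else {
          chg <- nchar(cs) * (if (substring(cs, 1, 1) == "+") 1L else -1L)
        }
      }
      add_atom(element, aromatic, charge = chg, hcount = hc, bracket = TRUE)
      pos <- close_br + 1L
    }
    else if (grepl("[A-Za-z]", ch)) {
      two <- if (pos < np) paste0(ch, chars[pos + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE); pos <- pos + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(ch, FALSE); pos <- pos + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        add_atom(toupper(ch), TRUE); pos <- pos + 1L
      } else {
        stop("unsupported element or symbol '", ch,
             "' in SMILES at position ", pos)
      }
    }
    else stop("SMILES parse error at position ", pos,
              ": unexpected character '", ch, "'")
  }
  if (length(prev_stack)) stop("SMILES parse error: unclosed '(' branch")
  open_ids <- names(ring_open)[!vapply(ring_open, is.null, TRUE)]
  if (length(open_ids))
    stop("SMILES parse error: unclosed ring bond(s) ",
         paste(open_ids, collapse = ", "))
  if (!length(atoms)) stop("SMILES parse error: no atoms parsed")

  at <- data.frame(
    element = vapply(atoms, `[[`, "", "element"),
    charge = vapply(atoms, `[[`, 0L, "charge"),
    nH = vapply(atoms, `[[`, NA_integer_, "nH"),
    aromatic = vapply(atoms, `[[`, FALSE, "aromatic"),
    stringsAsFactors = FALSE
  )
  bd <- data.frame(
    i = vapply(bonds, `[[`, 0L, "i"),
    j = vapply(bonds, `[[`, 0L, "j"),
    order = vapply(bonds, `[[`, 0L, "order")
  )
  m <- structure(list(atoms = at, bonds = bd, name = name,
                      conformers = list()), class = "molecule")
  m <- perceive_aromaticity(m)
  m <- fill_implicit_h(m, bracket = vapply(atoms, `[[`, FALSE, "bracket"))
  validate_molecule(m)
  m
}

#' Perceive aromaticity of Kekule-form rings
#'
#' Marks smallest rings as aromatic when every ring atom is sp2-consistent
#' and the Hueckel pi-electron count is 4n+2: atoms in an in-ring double
#' bond contribute one electron each and heteroatoms (N, O, S) with only
#' single bonds contribute a lone pair (two electrons). Ring bonds of
#' aromatized rings are rewritten to the aromatic order code.
#'
#' @param m a `molecule`.
#' @return the molecule with updated aromatic flags and bond orders.
#' @export
perceive_aromaticity <- function(m) {
  rings <- .find_rings(m, max_size = 7L)
  if (!length(rings)) return(m)
  for (ring in rings) {
    nr <- length(ring)
    if (nr < 5L || nr > 7L) next
    pi_e <- 0L
    ok <- TRUE
    already <- all(m$atoms$aromatic[ring])
    for (idx in seq_along(ring)) {
      a <- ring[idx]
      nxt <- ring[if (idx == nr) 1L else idx + 1L]
      prv <- ring[if (idx == 1L) nr else idx - 1L]
      o1 <- .bond_order(m, a, nxt); o2 <- .bond_order(m, a, prv)
      el <- m$atoms$element[a]
      if (o1 == 4L || o2 == 4L) { pi_e <- pi_e + 1L; next }
      if (o1 == 2L || o2 == 2L) { pi_e <- pi_e + 1L }
      else if (el %in% c("N", "O", "S")) { pi_e <- pi_e + 2L }
      else { ok <- FALSE; break }
    }
    if (already) next
    if (ok && pi_e >= 6L && (pi_e - 2L) %% 4L == 0L) {
      m$atoms$aromatic[ring] <- TRUE
      for (idx in seq_along(ring)) {
        a <- ring[idx]; b <- ring[if (idx == nr) 1L else idx + 1L]
        hit <- (m$bonds$i == a & m$bonds$j == b) |
               (m$bonds$i == b & m$bonds$j == a)
        m$bonds$order[hit] <- 4L
      }
    }
  }
  m
}

#' Fill implicit hydrogen counts to standard valence
#'
#' @param m a `molecule`.
#' @param bracket logical per atom: bracket atoms keep their explicit H
#'   count (default none).
#' @return the molecule with the `nH` column completed.
#' @export
fill_implicit_h <- function(m, bracket = rep(FALSE, nrow(m$atoms))) {
  bosum <- .bond_order_sum(m)
  for (a in seq_len(nrow(m$atoms))) {
    if (bracket[a]) {
      if (is.na(m$atoms$nH[a])) m$atoms$nH[a] <- 0L
      next
    }
    if (is.na(m$atoms$nH[a])) {
      m$atoms$nH[a] <- .implicit_h(m$atoms$element[a], m$atoms$charge[a],
                                   bosum[a])
    }
  }
  m
}

#' Heavy-atom degree of every atom
#' @param m a `molecule`.
#' @return integer vector of heavy-atom neighbor counts.
#' @keywords internal
heavy_degree <- function(m) {
  vapply(.adjacency(m), length, 1L)
}
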