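# SwissADME-style drug-likeness panel: Ertl fragment TPSA, Wildman-Crippen
# atomic logP, Delaney ESOL logS, Lipinski rule-of-five and the Abbott
# (Martin 2005) bioavailability score.

#' Radar axis ranges for the bioavailability radar
#'
#' SwissADME default "drug-like space" per axis: LIPO = logP, SIZE =
#' molecular weight (g/mol), POLAR = TPSA (A^2), INSOLU = ESOL logS,
#' INSATU = fraction of sp3 carbons, FLEX = rotatable bonds.
#' @export
RADAR_RANGES <- list(
  LIPO  = c(-0.7, 5.0),
  SIZE  = c(150, 500),
  POLAR = c(20, 130),
  INSOLU = c(-6, 0),
  INSATU = c(0.25, 1.0),
  FLEX  = c(0, 9)
)

#' Molecular weight
#'
#' Sum of standard atomic weights over heavy atoms plus implicit
#' hydrogens (IUPAC 2021 table, 3 decimals).
#' @param m a `molecule`.
#' @return weight in g/mol (0 for an empty molecule).
#' @export
molecular_weight <- function(m) {
  if (nrow(m$atoms) == 0L) return(0)
  w <- sum(ATOMIC_WEIGHTS[m$atoms$element]) +
    sum(m$atoms$nH) * ATOMIC_WEIGHTS[["H"]]
  unname(w)
}

# Per-atom environment summary used by the descriptor rules.
.atom_env <- function(m) {
  n <- nrow(m$atoms)
  adj <- .adjacency(m)
  env <- vector("list", n)
  for (a in seq_len(n)) {
    nb <- adj[[a]]
    orders <- vapply(nb, function(b) .bond_order(m, a, b), 0L)
    env[[a]] <- list(
      nb = nb,
      orders = orders,
      n_single = sum(orders == 1L),
      n_double = sum(orders == 2L),
      n_triple = sum(orders == 3L),
      n_arom = sum(orders == 4L),
      elements = m$atoms$element[nb]
    )
  }
  env
}

# Is atom a part of a 3-membered ring?
.in_three_ring <- function(m) {
  rings <- .find_rings(m, max_size = 3L)
  out <- rep(FALSE, nrow(m$atoms))
  for (r in rings) if (length(r) == 3L) out[r] <- TRUE
  out
}

# Carbonyl carbons: non-aromatic C with a double bond to O.
.is_carbonyl_c <- function(m, env = .atom_env(m)) {
  vapply(seq_len(nrow(m$atoms)), function(a) {
    m$atoms$element[a] == "C" && !m$atoms$aromatic[a] &&
      any(env[[a]]$orders == 2L & env[[a]]$elements == "O")
  }, TRUE)
}

#' Ertl topological polar surface area
#'
#' Fragment-contribution sum over nitrogen, oxygen, sulfur and phosphorus
#' environments (Ertl 2000 published contributions). An N/O environment
#' missing from the table falls back to the generic three-single-bond N
#' (3.24) or ether O (9.23) contribution with a warning.
#'
#' @param m a `molecule`.
#' @return TPSA in square Angstroms.
#' @export
tpsa <- function(m) {
  if (nrow(m$atoms) == 0L) return(0)
  env <- .atom_env(m)
  three <- .in_three_ring(m)
  total <- 0
  for (a in seq_len(nrow(m$atoms))) {
    el <- m$atoms$element[a]
    if (!(el %in% c("N", "O", "S", "P"))) next
    e <- env[[a]]
    h <- m$atoms$nH[a]
    q <- m$atoms$charge[a]
    arom <- m$atoms$aromatic[a]
    s <- e$n_single; d <- e$n_double; t <- e$n_triple; ar <- e$n_arom
    contrib <- NA_real_
    if (el == "N") {
      if (arom) {
        if (q > 0) {
          if (h >= 1L) contrib <- 14.14
          else if (s >= 1L) contrib <- 3.88
          else contrib <- 4.10
        } else if (h >= 1L) contrib <- 15.79
        else if (ar >= 3L) contrib <- 4.41
        else if (s == 1L) contrib <- 4.93
        else if (d == 1L) contrib <- 8.39
        else if (ar == 2L) contrib <- 12.89
      } else if (q > 0) {
        if (h == 0L && s == 4L) contrib <- 0.00
        else if (h == 0L && s == 2L && d == 1L) contrib <- 3.01
        else if (h == 0L && s == 1L && t == 1L) contrib <- 4.36
        else if (h == 1L && s == 3L) contrib <- 4.44
        else if (h == 1L && s == 1L && d == 1L) contrib <- 13.97
        else if (h == 2L && s == 2L) contrib <- 16.61
        else if (h == 2L && d == 1L) contrib <- 25.59
        else if (h == 3L && s == 1L) contrib <- 27.64
      } else {
        if (h == 0L && s == 3L) contrib <- if (three[a]) 3.01 else 3.24
        else if (h == 0L && s == 1L && d == 1L) contrib <- 12.36
        else if (h == 0L && t == 1L && s == 0L) contrib <- 23.79
        else if (h == 0L && s == 1L && d == 2L) contrib <- 11.68
        else if (h == 0L && d == 1L && t == 1L) contrib <- 13.60
        else if (h == 1L && s == 2L) contrib <- if (three[a]) 21.94 else 12.03
        else if (h == 1L && d == 1L && s == 0L) contrib <- 23.85
        else if (h == 2L && s == 1L) contrib <- 26.02
      }
      if (is.na(contrib)) {
        warning("no TPSA contribution for N environment at atom ", a,
                "; using generic 3.24")
        contrib <- 3.24
      }
    } else if (el == "O") {
      if (arom) contrib <- 13.14
      else if (q < 0) contrib <- if (s == 1L) 23.06 else NA_real_
      else if (h >= 2L) contrib <- 31.50     # water-like OH2
      else if (h >= 1L) contrib <- 20.23
      else if (d == 1L) contrib <- 17.07
      else if (s == 2L) contrib <- if (three[a]) 12.53 else 9.23
      if (is.na(contrib)) {
        warning("no TPSA contribution for O environment at atom ", a,
                "; using generic 9.23")
        contrib <- 9.23
      }
    } else if (el == "S") {
      if (arom) contrib <- if (d >= 1L) 21.70 else 28.24
      else if (h >= 1L) contrib <- 38.80
      else if (s == 2L && d == 2L) contrib <- 8.38
      else if (s == 2L && d == 1L) contrib <- 19.21
      else if (d == 1L && s == 0L) contrib <- 32.09
      else if (s == 2L) contrib <- 25.30
      else contrib <- 0
    } else if (el == "P") {
      if (s == 3L && d == 1L) contrib <- 9.81
      else if (s == 3L) contrib <- 13.59
      else if (s == 1L && d == 1L) contrib <- 34.14
      else if (h == 1L && s == 2L && d == 1L) contrib <- 23.47
      else contrib <- 0
    }
    total <- total + contrib
  }
  total
}

#' Hydrogen-bond donor count
#'
#' Number of nitrogen or oxygen atoms bearing at least one hydrogen.
#' @param m a `molecule`.
#' @return integer count.
#' @export
count_h_bond_donors <- function(m) {
  sum(m$atoms$element %in% c("N", "O") & m$atoms$nH > 0L)
}

#' Hydrogen-bond acceptor count
#'
#' All oxygen atoms, plus nitrogen atoms that are neither amide/imide
#' nitrogens (single-bonded to a carbonyl carbon) nor pyrrole-type aromatic
#' nitrogens (aromatic N with three connections or an attached hydrogen;
#' pyridine-type N with two ring connections does count).
#' @param m a `molecule`.
#' @return integer count.
#' @export
count_h_bond_acceptors <- function(m) {
  if (nrow(m$atoms) == 0L) return(0L)
  env <- .atom_env(m)
  carbonyl <- .is_carbonyl_c(m, env)
  n_ok <- vapply(seq_len(nrow(m$atoms)), function(a) {
    if (m$atoms$element[a] != "N") return(FALSE)
    e <- env[[a]]
    if (m$atoms$aromatic[a]) {
      # pyrrole-type: 3 connections or N-H in the aromatic ring
      return(length(e$nb) + m$atoms$nH[a] <= 2L && m$atoms$nH[a] == 0L)
    }
    amide <- any(e$orders == 1L & carbonyl[e$nb])
    !amide
  }, TRUE)
  sum(m$atoms$element == "O") + sum(n_ok)
}

# Wildman-Crippen atom typing. Returns the per-atom logP contribution
# including the atom's implicit hydrogens (H typed by their heavy partner).
.crippen_atom <- function(m, a, env, carbonyl) {
  el <- m$atoms$element[a]
  e <- env[[a]]
  h <- m$atoms$nH[a]
  arom <- m$atoms$aromatic[a]
  nb_el <- e$elements
  nb_arom <- m$atoms$aromatic[e$nb]
  het <- c("N", "O", "P", "S", "F", "Cl", "Br", "I")

  h_contrib <- function(owner) {
    per <- switch(owner,
      C = 0.1230,
      N = 0.2142,
      O_acid = 0.2980,
      O = -0.2677,
      S = -0.2677,
      0.1125)
    per * h
  }

  if (el == "C") {
    hc <- h_contrib("C")
    if (arom) {
      ext <- which(e$orders != 4L)
      if (h >= 1L && !length(ext)) return(0.1581 + hc)          # C18 [cH]
      if (!length(ext)) return(0.2955 + hc)                     # C19 fused
      b <- e$nb[ext[1L]]; o <- e$orders[ext[1L]]
      belem <- m$atoms$element[b]
      if (o == 2L) return(-0.8186 + hc)                         # C25 =X
      if (m$atoms$aromatic[b]) return(0.2713 + hc)              # C20 biaryl
      if (belem == "C") return(0.1360 + hc)                     # C21
      if (belem == "N") return(0.4619 + hc)                     # C22
      if (belem == "O") return(0.5437 + hc)                     # C23
      if (belem == "S") return(0.1893 + hc)                     # C24
      if (belem == "F") return(0.0000 + hc)                     # C14
      if (belem == "Cl") return(0.2450 + hc)                    # C15
      if (belem == "Br") return(0.1980 + hc)                    # C16
      if (belem == "I") return(0.0000 + hc)                     # C17
      return(-0.5443 + hc)                                      # C13
    }
    if (e$n_triple >= 1L || (e$n_double >= 2L)) return(0.0017 + h_contrib("C"))
    if (e$n_double >= 1L) {
      dpos <- which(e$orders == 2L)
      delem <- nb_el[dpos]
      if (any(delem != "C")) return(-0.2783 + hc)               # C5 C=X
      if (any(nb_arom)) return(0.2640 + hc)                     # C26 vinyl-aryl
      return(0.1551 + hc)                                       # C6 C=C
    }
    # sp3 carbon
    if (any(nb_arom)) {
      if (h >= 3L) {
        aromnb <- e$nb[nb_arom][1L]
        if (m$atoms$element[aromnb] == "C") return(0.08452 + hc) # C8 CH3-c
        return(-0.1444 + hc)                                     # C9 CH3-a
      }
      if (h == 2L) return(-0.0516 + hc)                          # C10
      if (h == 1L) return(0.1193 + hc)                           # C11
      return(-0.0967 + hc)                                       # C12
    }
    if (any(nb_el %in% het)) {
      if (h >= 2L) return(-0.2035 + hc)                          # C3
      return(-0.2051 + hc)                                       # C4
    }
    if (h >= 2L || length(e$nb) + h == 4L && h >= 2L) return(0.1441 + hc)
    if (h >= 2L) return(0.1441 + hc)
    if (length(e$nb) <= 2L && h >= 2L) return(0.1441 + hc)
    if (h == 1L && length(e$nb) == 3L) return(0.0000 + hc)       # C2 CH(C)3
    if (h == 0L && length(e$nb) == 4L) return(0.0000 + hc)       # C2 quat
    return(0.1441 + hc)                                          # C1
  }
  if (el == "N") {
    hc <- h_contrib("N")
    if (arom) return((if (m$atoms$charge[a] > 0) -1.1190 else -0.3239) + hc)
    if (m$atoms$charge[a] > 0) {
      if (h >= 1L) return(-1.9500 + hc)                          # N10
      return(-0.3396 + hc)                                       # N13
    }
    if (e$n_triple >= 1L) return(0.01508 + hc)                   # N9 nitrile
    if (e$n_double >= 1L) {
      if (h >= 1L) return(0.08387 + hc)                          # N5
      return(0.1836 + hc)                                        # N6
    }
    if (h >= 2L) return((if (any(nb_arom)) -1.0270 else -1.0190) + hc)
    if (h == 1L) return((if (any(nb_arom)) -0.5188 else -0.7096) + hc)
    if (length(e$nb) == 3L)
      return((if (any(nb_arom)) -0.4458 else -0.3187) + hc)
    return(-0.4806 + hc)                                         # NS
  }
  if (el == "O") {
    if (arom) return(0.1552)
    if (m$atoms$charge[a] < 0) {
      if (any(carbonyl[e$nb])) return(-1.3260)                   # O12
      if (any(nb_el == "N")) return(0.0335)                      # O5 N-oxide
      if (any(nb_el == "S")) return(-0.3339)                     # O6
      return(-1.1890)                                            # O7
    }
    if (h >= 1L) {
      owner <- if (any(carbonyl[e$nb])) "O_acid" else "O"
      return(-0.2893 + h_contrib(owner))                         # O2 + H
    }
    if (e$n_double >= 1L) {
      b <- e$nb[which(e$orders == 2L)[1L]]
      belem <- m$atoms$element[b]
      if (belem == "C" && m$atoms$aromatic[b]) return(0.1788)    # O8
      if (belem %in% c("N", "O")) return(0.0335)                 # O5
      if (belem == "S") return(-0.3339)                          # O6
      if (belem == "C") {
        cnb <- env[[b]]$nb
        cnb <- cnb[cnb != a]
        cel <- m$atoms$element[cnb]
        carom <- m$atoms$aromatic[cnb]
        n_het <- sum(!(cel == "C"))
        if (n_het >= 2L) return(0.4833)                          # O11
        if (any(carom)) return(0.1129)                           # O10
        return(-0.1526)                                          # O9
      }
      return(-0.1188)
    }
    if (any(nb_arom)) return(-0.4195)                            # O4
    return(-0.0684)                                              # O3 ether
  }
  if (el == "S") {
    if (arom) return(0.6237)
    if (m$atoms$charge[a] != 0 || any(e$orders == 2L & nb_el %in% c("N", "O")))
      return(-0.0024)
    return(0.6482 + h_contrib("S"))
  }
  if (el == "P") return(0.8612)
  if (el == "F") return(if (m$atoms$charge[a] == 0) 0.4202 else -2.996)
  if (el == "Cl") return(if (m$atoms$charge[a] == 0) 0.6895 else -2.996)
  if (el == "Br") return(if (m$atoms$charge[a] == 0) 0.8456 else -2.996)
  if (el == "I") return(if (m$atoms$charge[a] == 0) 0.8857 else -2.996)
  if (el == "B") return(-0.3808)
  0.0
}

#' Wildman-Crippen logP
#'
#' Atomic-contribution octanol/water partition coefficient using the
#' published Wildman-Crippen parameter set mapped onto this package's
#' molecular graph (one model, not a multi-model consensus).
#' @param m a `molecule`.
#' @return logP (unitless).
#' @export
crippen_logp <- function(m) {
  if (nrow(m$atoms) == 0L) return(0)
  env <- .atom_env(m)
  carbonyl <- .is_carbonyl_c(m, env)
  sum(vapply(seq_len(nrow(m$atoms)),
             function(a) .crippen_atom(m, a, env, carbonyl), 0))
}

#' Rotatable bond count
#'
#' Non-ring single bonds between heavy atoms that each have at least two
#' heavy neighbors, excluding amide C-N bonds.
#' @param m a `molecule`.
#' @return integer count.
#' @export
count_rotatable_bonds <- function(m) {
  if (nrow(m$bonds) == 0L) return(0L)
  deg <- heavy_degree(m)
  env <- .atom_env(m)
  carbonyl <- .is_carbonyl_c(m, env)
  rings <- .find_rings(m, max_size = 12L)
  ring_bond <- rep(FALSE, nrow(m$bonds))
  for (r in rings) {
    nr <- length(r)
    for (idx in seq_len(nr)) {
      a <- r[idx]; b <- r[if (idx == nr) 1L else idx + 1L]
      hit <- (m$bonds$i == a & m$bonds$j == b) |
             (m$bonds$i == b & m$bonds$j == a)
      ring_bond[hit] <- TRUE
    }
  }
  n <- 0L
  for (k in seq_len(nrow(m$bonds))) {
    if (m$bonds$order[k] != 1L || ring_bond[k]) next
    i <- m$bonds$i[k]; j <- m$bonds$j[k]
    if (deg[i] < 2L || deg[j] < 2L) next
    amide <- (m$atoms$element[i] == "N" && carbonyl[j]) ||
             (m$atoms$element[j] == "N" && carbonyl[i])
    if (amide) next
    n <- n + 1L
  }
  n
}

#' ESOL aqueous solubility estimate
#'
#' Delaney's ESOL model: `logS = 0.16 - 0.63 logP - 0.0062 MW +
#' 0.066 RB - 0.74 AP` with AP the aromatic proportion of heavy atoms.
#' @param m a `molecule`.
#' @return estimated log of aqueous solubility (mol/L).
#' @export
esol_logs <- function(m) {
  if (nrow(m$atoms) == 0L) return(0)
  ap <- mean(m$atoms$aromatic)
  0.16 - 0.63 * crippen_logp(m) - 0.0062 * molecular_weight(m) +
    0.066 * count_rotatable_bonds(m) - 0.74 * ap
}

#' Lipinski rule-of-five violation count
#'
#' Violations of MW <= 500, logP <= 5, HBD <= 5, HBA <= 10.
#' @param m a `molecule`.
#' @return integer in 0..4.
#' @export
lipinski_violations <- function(m) {
  sum(molecular_weight(m) > 500,
      crippen_logp(m) > 5,
      count_h_bond_donors(m) > 5,
      count_h_bond_acceptors(m) > 10)
}

# Is the molecule anionic at pH ~7? Formal negative charge, or a
# carboxylic / sulfonic / phosphoric acid group assumed deprotonated.
.is_anionic <- function(m) {
  if (any(m$atoms$charge < 0)) return(TRUE)
  env <- .atom_env(m)
  carbonyl <- .is_carbonyl_c(m, env)
  for (a in seq_len(nrow(m$atoms))) {
    if (m$atoms$element[a] == "O" && m$atoms$nH[a] >= 1L) {
      nb <- env[[a]]$nb
      if (any(carbonyl[nb])) return(TRUE)                 # -C(=O)OH
      acid_sp <- vapply(nb, function(b) {
        m$atoms$element[b] %in% c("S", "P") &&
          any(env[[b]]$orders == 2L & env[[b]]$elements == "O")
      }, TRUE)
      if (any(acid_sp)) return(TRUE)
    }
  }
  FALSE
}

#' Abbott bioavailability score
#'
#' Martin (2005) rule table: anionic compounds at pH 7 are bucketed by
#' TPSA (> 150 -> 0.11; 75-150 -> 0.56; < 75 -> 0.85); all other
#' compounds score 0.55 with at most one Lipinski violation and 0.17
#' otherwise.
#' @param m a `molecule`.
#' @return one of 0.11, 0.17, 0.55, 0.56, 0.85.
#' @export
bioavailability_score <- function(m) {
  if (.is_anionic(m)) {
    t <- tpsa(m)
    if (t > 150) return(0.11)
    if (t >= 75) return(0.56)
    return(0.85)
  }
  if (lipinski_violations(m) <= 1L) 0.55 else 0.17
}

#' Fraction of sp3-hybridized carbons
#' @param m a `molecule`.
#' @return fraction in \[0, 1\] (0 if the molecule has no carbon).
#' @export
fraction_csp3 <- function(m) {
  idx <- which(m$atoms$element == "C")
  if (!length(idx)) return(0)
  env <- .atom_env(m)
  sp3 <- vapply(idx, function(a) {
    !m$atoms$aromatic[a] && all(env[[a]]$orders == 1L)
  }, TRUE)
  mean(sp3)
}

#' Full drug-likeness descriptor panel
#'
#' Computes every panel entry: molecular weight, Ertl TPSA, H-bond
#' donors/acceptors, Wildman-Crippen logP, ESOL logS, rotatable bonds,
#' Lipinski violations, the Abbott bioavailability score, a drug-likeness
#' flag (at most one Lipinski violation) and the six bioavailability
#' radar axes (LIPO, SIZE, POLAR, INSOLU, INSATU, FLEX).
#'
#' @param m a `molecule`.
#' @return an object of class `descriptor_set` (named list).
#' @examples
#' descriptor_panel(parse_smiles("CCO"))
#' @export
descriptor_panel <- function(m) {
  lp <- crippen_logp(m)
  viol <- lipinski_violations(m)
  radar <- c(
    LIPO = lp,
    SIZE = molecular_weight(m),
    POLAR = tpsa(m),
    INSOLU = esol_logs(m),
    INSATU = fraction_csp3(m),
    FLEX = as.numeric(count_rotatable_bonds(m))
  )
  out <- list(
    name = m$name,
    molecular_weight = molecular_weight(m),
    tpsa = tpsa(m),
    hbd = count_h_bond_donors(m),
    hba = count_h_bond_acceptors(m),
    logp = lp,
    logs_esol = esol_logs(m),
    rotatable_bonds = count_rotatable_bonds(m),
    lipinski_violations = viol,
    bioavailability_score = bioavailability_score(m),
    drug_like = viol <= 1L,
    radar = radar
  )
  class(out) <- "descriptor_set"
  out
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("Descriptor panel%s\n",
              if (nzchar(x$name)) paste0(" for ", x$name) else ""))
  cat(sprintf("  MW %.1f g/mol | TPSA %.2f A^2 | HBD %d | HBA %d\n",
              x$molecular_weight, x$tpsa, x$hbd, x$hba))
  cat(sprintf("  logP %.2f | ESOL logS %.2f | rotatable bonds %d\n",
              x$logp, x$logs_esol, x$rotatable_bonds))
  cat(sprintf("  Lipinski violations %d | bioavailability score %.2f | drug-like %s\n",
              x$lipinski_violations, x$bioavailability_score,
              if (x$drug_like) "yes" else "no"))
  invisible(x)
}

#' Write descriptor panels as a TSV table
#'
#' @param panels list of `descriptor_set` objects.
#' @param path output file path.
#' @return the data.frame written, invisibly.
#' @export
write_descriptor_tsv <- function(panels, path) {
  df <- do.call(rbind, lapply(panels, function(p) {
    data.frame(name = p$name,
               molecular_weight = round(p$molecular_weight, 1),
               tpsa = round(p$tpsa, 2),
               hbd = p$hbd, hba = p$hba,
               logp = round(p$logp, 2),
               logs_esol = round(p$logs_esol, 2),
               rotatable_bonds = p$rotatable_bonds,
               lipinski_violations = p$lipinski_violations,
               bioavailability_score = p$bioavailability_score,
               drug_like = p$drug_like)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
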