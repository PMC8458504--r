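# 3D conformer generation: spanning-tree layout with idealized bond
# lengths/angles, staggered torsion sampling over rotatable bonds, then
# minimization under a Dreiding-style objective (harmonic bonds, 1-3
# distance restraints standing in for angle terms, 12-6 nonbonded).

# Covalent radii (Angstroms) for ideal bond lengths.
.COVALENT_RADII <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
                     F = 0.57, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20,
                     I = 1.39)

.ideal_bond <- function(el1, el2, order) {
  r <- .COVALENT_RADII[[el1]] + .COVALENT_RADII[[el2]]
  f <- switch(as.character(order), `1` = 1.0, `2` = 0.87, `3` = 0.78,
              `4` = 0.93, 1.0)
  r * f
}

# Run expr with a private RNG seeded by `seed`, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Hybridization code per atom: 3 = sp3, 2 = sp2/aromatic, 1 = sp.
.hybridization <- function(m) {
  env <- .atom_env(m)
  vapply(seq_len(nrow(m$atoms)), function(a) {
    e <- env[[a]]
    if (e$n_triple >= 1L || e$n_double >= 2L) return(1L)
    if (e$n_double >= 1L || m$atoms$aromatic[a]) return(2L)
    3L
  }, 1L)
}

# Rotatable tree bonds: non-ring single bonds with both ends of heavy
# degree >= 2 (the torsions worth sampling).
.rotatable_bonds <- function(m) {
  if (nrow(m$bonds) == 0L) return(integer())
  deg <- heavy_degree(m)
  ring <- rep(FALSE, nrow(m$bonds))
  for (r in .find_rings(m, max_size = 12L)) {
    nr <- length(r)
    for (idx in seq_len(nr)) {
      a <- r[idx]; b <- r[if (idx == nr) 1L else idx + 1L]
      hit <- (m$bonds$i == a & m$bonds$j == b) |
             (m$bonds$i == b & m$bonds$j == a)
      ring[hit] <- TRUE
    }
  }
  which(m$bonds$order == 1L & !ring & deg[m$bonds$i] >= 2L &
          deg[m$bonds$j] >= 2L)
}

# Lay out heavy-atom 3D coordinates along a BFS spanning tree with NeRF.
# `torsions` is a named numeric vector: torsion value (degrees) per
# rotatable bond index (names = bond row indices as character).
.layout_coords <- function(m, torsions = numeric()) {
  n <- nrow(m$atoms)
  xyz <- matrix(NA_real_, n, 3)
  if (n == 0L) return(xyz)
  adj <- .adjacency(m)
  hyb <- .hybridization(m)
  ring <- ring_atoms(m)
  parent <- rep(NA_integer_, n)
  depth <- rep(0L, n)
  order <- integer()
  visited <- rep(FALSE, n)
  queue <- 1L; visited[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (w in adj[[v]]) if (!visited[w]) {
      visited[w] <- TRUE
      parent[w] <- v
      depth[w] <- depth[v] + 1L
      queue <- c(queue, w)
    }
  }
  if (!all(visited)) stop("disconnected molecular graph; cannot embed")
  bond_key <- function(a, b) {
    which((m$bonds$i == a & m$bonds$j == b) | (m$bonds$i == b & m$bonds$j == a))[1L]
  }
  child_rank <- integer(n)  # how many children of each parent placed so far
  for (v in order) {
    p <- parent[v]
    if (is.na(p)) { xyz[v, ] <- c(0, 0, 0); next }
    bl <- .ideal_bond(m$atoms$element[p], m$atoms$element[v],
                      m$bonds$order[bond_key(p, v)])
    g <- parent[p]
    if (is.na(g)) {
      # second shell: place along x then branch in xy-plane
      k <- child_rank[p]; child_rank[p] <- k + 1L
      ang <- switch(hyb[p], 180, 120, 109.47)
      if (k == 0L) xyz[v, ] <- xyz[p, ] + c(bl, 0, 0)
      else {
        theta <- (ang) * pi / 180
        phi <- (k - 1L) * 2 * pi / 3
        dir <- c(cos(pi - theta), sin(pi - theta) * cos(phi),
                 sin(pi - theta) * sin(phi))
        xyz[v, ] <- xyz[p, ] + bl * dir
      }
      next
    }
    gg <- parent[g]
    aref <- if (is.na(gg)) xyz[g, ] + c(0, 1.0, 0.3) else xyz[gg, ]
    ang <- switch(hyb[p], 179, 120, 109.47)
    bk <- bond_key(g, p)
    base <- if (as.character(bk) %in% names(torsions)) {
      torsions[[as.character(bk)]]
    } else if (ring[v] && ring[p] && ring[g]) {
      if (hyb[p] == 2L && hyb[v] == 2L) 0 else 55 * (-1)^depth[v]
    } else 180
    k <- child_rank[p]; child_rank[p] <- k + 1L
    offset <- if (hyb[p] == 2L) k * 180 else k * 120
    xyz[v, ] <- nerf_place(aref, xyz[g, ], xyz[p, ], bl, ang, base + offset)
  }
  xyz
}

# Precompute the energy-term pair lists for a molecule.
.ff_terms <- function(m) {
  n <- nrow(m$atoms)
  adj <- .adjacency(m)
  # graph distances by BFS (small molecules)
  gd <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (dist[w] > dist[v] + 1) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
    gd[s, ] <- dist
  }
  bonds <- cbind(m$bonds$i, m$bonds$j)
  r0 <- vapply(seq_len(nrow(m$bonds)), function(k)
    .ideal_bond(m$atoms$element[m$bonds$i[k]], m$atoms$element[m$bonds$j[k]],
                m$bonds$order[k]), 0)
  hyb <- .hybridization(m)
  # 1-3 restraints via law of cosines at the central atom
  ang_i <- integer(); ang_j <- integer(); ang_d0 <- numeric()
  for (c in seq_len(n)) {
    nb <- adj[[c]]
    if (length(nb) < 2L) next
    th <- switch(hyb[c], 179, 120, 109.47) * pi / 180
    for (p in seq_len(length(nb) - 1L)) for (q in seq(p + 1L, length(nb))) {
      i <- nb[p]; j <- nb[q]
      ri <- .ideal_bond(m$atoms$element[c], m$atoms$element[i],
                        .bond_order(m, c, i))
      rj <- .ideal_bond(m$atoms$element[c], m$atoms$element[j],
                        .bond_order(m, c, j))
      ang_i <- c(ang_i, i); ang_j <- c(ang_j, j)
      ang_d0 <- c(ang_d0, sqrt(ri^2 + rj^2 - 2 * ri * rj * cos(th)))
    }
  }
  # cross-ring restraints keep aromatic 6-rings planar-hexagonal
  flat_i <- integer(); flat_j <- integer(); flat_d0 <- numeric()
  for (r in .find_rings(m, max_size = 7L)) {
    if (length(r) == 6L && all(m$atoms$aromatic[r])) {
      for (idx in 1:3) {
        a <- r[idx]; b <- r[idx + 3L]
        bl <- .ideal_bond(m$atoms$element[a], m$atoms$element[b], 4L)
        flat_i <- c(flat_i, a); flat_j <- c(flat_j, b)
        flat_d0 <- c(flat_d0, 2 * bl)
      }
    }
  }
  # nonbonded pairs: graph distance >= 3
  nb_i <- integer(); nb_j <- integer()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      if (gd[i, j] >= 3) { nb_i <- c(nb_i, i); nb_j <- c(nb_j, j) }
    }
  }
  nb_rmin <- 0.85 * (.vdw_radius(m$atoms$element[nb_i]) +
                     .vdw_radius(m$atoms$element[nb_j]))
  # stack all harmonic distance terms into flat arrays
  h_i <- c(bonds[, 1], ang_i, flat_i)
  h_j <- c(bonds[, 2], ang_j, flat_j)
  h_d0 <- c(r0, ang_d0, flat_d0)
  h_k <- c(rep(300, nrow(bonds)), rep(60, length(ang_i)),
           rep(30, length(flat_i)))
  list(h_i = h_i, h_j = h_j, h_d0 = h_d0, h_k = h_k,
       nb_i = nb_i, nb_j = nb_j, nb_rmin = nb_rmin, eps = 0.1)
}

# Accumulate per-pair force contributions into per-atom rows (indices
# may repeat, so plain subassignment would drop duplicates).
.acc_rows <- function(G, idx, M) {
  rs <- rowsum(M, idx)
  rows <- as.integer(rownames(rs))
  G[rows, ] <- G[rows, ] + rs
  G
}

# Energy and gradient of the conformer objective.
.ff_energy <- function(xyz, terms, grad = FALSE) {
  E <- 0
  G <- if (grad) matrix(0, nrow(xyz), 3) else NULL
  if (length(terms$h_i)) {
    i <- terms$h_i; j <- terms$h_j
    d <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
    r <- pmax(sqrt(rowSums(d^2)), 1e-8)
    dev <- r - terms$h_d0
    E <- E + sum(terms$h_k * dev^2)
    if (grad) {
      f <- 2 * terms$h_k * dev / r
      G <- .acc_rows(G, i, d * f)
      G <- .acc_rows(G, j, -d * f)
    }
  }
  if (length(terms$nb_i)) {
    i <- terms$nb_i; j <- terms$nb_j
    d <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
    r <- pmax(sqrt(rowSums(d^2)), 1e-8)
    s <- terms$nb_rmin / r
    E <- E + sum(terms$eps * (s^12 - 2 * s^6))
    if (grad) {
      f <- terms$eps * (-12 * s^12 + 12 * s^6) / r / r
      G <- .acc_rows(G, i, d * f)
      G <- .acc_rows(G, j, -d * f)
    }
  }
  if (grad) list(E = E, G = G) else E
}

#' Minimize a conformer's geometry
#'
#' Gradient-based minimization (limited-memory BFGS with an analytic
#' gradient) of a Dreiding-style objective: harmonic bond terms, 1-3
#' distance restraints standing in for angle bending, planarity
#' restraints for aromatic six-rings, and 12-6 nonbonded terms between
#' atoms three or more bonds apart. The returned energy never exceeds
#' the input energy (the input conformer is returned unchanged if the
#' optimizer fails to improve it); iteration stops on the step budget or
#' at gradient convergence.
#'
#' @param m the parent `molecule`.
#' @param conf a conformer: `list(xyz = matrix, energy = numeric)`.
#' @param max_steps iteration budget.
#' @param tol convergence tolerance on the projected gradient.
#' @return the minimized conformer with its final `energy`.
#' @export
minimize_conformer <- function(m, conf, max_steps = 300L, tol = 1e-6) {
  terms <- .ff_terms(m)
  xyz <- conf$xyz
  n <- nrow(xyz)
  E0 <- .ff_energy(xyz, terms)
  if (!is.finite(E0)) stop("non-finite energy at step 0")
  fn <- function(p) {
    e <- .ff_energy(matrix(p, n, 3), terms)
    if (!is.finite(e)) stop("non-finite energy during minimization")
    e
  }
  gr <- function(p) as.numeric(.ff_energy(matrix(p, n, 3), terms,
                                          grad = TRUE)$G)
  res <- tryCatch(
    stats::optim(as.numeric(xyz), fn, gr, method = "L-BFGS-B",
                 control = list(maxit = max_steps, pgtol = tol)),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$value) || res$value > E0)
    return(list(xyz = xyz, energy = E0))
  list(xyz = matrix(res$par, n, 3), energy = res$value)
}

#' Optimal-superposition RMSD between two conformations (Kabsch)
#'
#' @param A,B n x 3 coordinate matrices with matching atom order.
#' @param superpose superpose with the Kabsch rotation first (default);
#'   set `FALSE` for RMSD in a common frame.
#' @return RMSD in Angstroms.
#' @export
conformer_rmsd <- function(A, B, superpose = TRUE) {
  A <- rbind(A); B <- rbind(B)
  if (nrow(A) != nrow(B)) stop("coordinate sets differ in atom count")
  if (superpose) {
    Ac <- sweep(A, 2, colMeans(A))
    Bc <- sweep(B, 2, colMeans(B))
    H <- t(Ac) %*% Bc
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    Ar <- Ac %*% t(R)
    sqrt(mean(rowSums((Ar - Bc)^2)))
  } else {
    sqrt(mean(rowSums((A - B)^2)))
  }
}

#' Prune conformers by pairwise RMSD
#'
#' Greedy keep-lowest-energy-first: a conformer is discarded when its
#' superposition RMSD to an already kept conformer is below `threshold`.
#'
#' @param conformers list of conformers.
#' @param threshold RMSD threshold in Angstroms (default 0.5).
#' @return the kept subset, lowest energy first.
#' @export
prune_by_rmsd <- function(conformers, threshold = 0.5) {
  if (!length(conformers)) stop("need at least one conformer")
  en <- vapply(conformers, function(cf)
    if (is.null(cf$energy) || is.na(cf$energy)) Inf else cf$energy, 0)
  ord <- order(en)
  kept <- list()
  for (k in ord) {
    cf <- conformers[[k]]
    dup <- any(vapply(kept, function(kc)
      conformer_rmsd(kc$xyz, cf$xyz) < threshold, TRUE))
    if (!dup) kept[[length(kept) + 1L]] <- cf
  }
  kept
}

#' Generate up to N minimized 3D conformers
#'
#' Heavy-atom conformers are laid out along a spanning tree with ideal
#' bond lengths and angles; rotatable-bond torsions are drawn from the
#' staggered set (180, +60, -60 degrees), the first conformer being the
#' all-trans extended form. Each candidate is minimized and the set is
#' pruned by superposition RMSD. Deterministic for a fixed seed.
#'
#' @param m a `molecule` with at least one atom.
#' @param max_n conformer cap (default 10, the screening default).
#' @param seed RNG seed.
#' @param prune_threshold RMSD dedupe threshold (Angstroms).
#' @return the molecule with its `conformers` list populated (each
#'   `list(xyz, energy)`), at most `max_n` entries, lowest energy first.
#' @export
embed_conformers <- function(m, max_n = 10L, seed = 1L,
                             prune_threshold = 0.5) {
  if (nrow(m$atoms) == 0L) stop("cannot embed an empty molecule")
  rot <- .rotatable_bonds(m)
  staggered <- c(180, 60, -60)
  n_states <- 3^length(rot)
  assignments <- list(rep(180, length(rot)))
  if (length(rot) && n_states <= 3 * max_n) {
    grid <- expand.grid(rep(list(staggered), length(rot)))
    assignments <- lapply(seq_len(nrow(grid)), function(r) as.numeric(grid[r, ]))
  } else if (length(rot)) {
    assignments <- with_seed(seed, {
      out <- list(rep(180, length(rot)))
      seen <- paste(out[[1]], collapse = ",")
      tries <- 0L
      while (length(out) < 3L * max_n && tries < 50L * max_n) {
        cand <- sample(staggered, length(rot), replace = TRUE)
        key <- paste(cand, collapse = ",")
        if (!(key %in% seen)) {
          out[[length(out) + 1L]] <- cand
          seen <- c(seen, key)
        }
        tries <- tries + 1L
      }
      out
    })
  }
  confs <- list()
  for (ai in seq_along(assignments)) {
    asg <- assignments[[ai]]
    tors <- stats::setNames(asg, as.character(rot))
    xyz0 <- tryCatch(.layout_coords(m, tors), error = function(e) NULL)
    if (is.null(xyz0)) next
    cf <- NULL
    for (jit in 0:2) {   # jitter restarts break symmetric saddle traps
      xyz <- if (jit == 0L) xyz0 else
        xyz0 + with_seed(seed + 1000L * jit + ai,
                         matrix(stats::rnorm(length(xyz0), 0, 0.3),
                                nrow(xyz0), 3))
      out <- tryCatch({
        o <- minimize_conformer(m, list(xyz = xyz), max_steps = 400L)
        tries <- 0L
        while (!.bond_lengths_ok(m, o$xyz) && tries < 3L) {
          o <- minimize_conformer(m, o, max_steps = 800L)
          tries <- tries + 1L
        }
        o
      }, error = function(e) NULL)
      if (!is.null(out) && .bond_lengths_ok(m, out$xyz)) { cf <- out; break }
    }
    if (!is.null(cf)) confs[[length(confs) + 1L]] <- cf
  }
  if (!length(confs))
    stop("embedding failed for molecule '", m$name, "'")
  kept <- prune_by_rmsd(confs, prune_threshold)
  m$conformers <- kept[seq_len(min(length(kept), max_n))]
  m
}

# Bonded atoms must sit within 0.9-1.9 A after minimization (2.1 A
# upper bound for bonds to the heavy halogens Br/I, whose equilibrium
# lengths exceed 1.9 A).
.bond_lengths_ok <- function(m, xyz) {
  if (nrow(m$bonds) == 0L) return(TRUE)
  d <- sqrt(rowSums((xyz[m$bonds$i, , drop = FALSE] -
                     xyz[m$bonds$j, , drop = FALSE])^2))
  heavy_hal <- m$atoms$element[m$bonds$i] %in% c("Br", "I") |
    m$atoms$element[m$bonds$j] %in% c("Br", "I")
  all(d >= 0.9 & d <= ifelse(heavy_hal, 2.1, 1.9))
}
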