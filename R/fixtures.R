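# Deterministic synthetic benchmark generators: pseudo-atom receptors
# with one concave pocket flanked by two tagged "degradation-site"
# lysines, planted cognate complexes (positives), decoy ligand
# libraries, and a train/test screen benchmark. Everything is seeded
# and reproducible byte-for-byte.

# Derive a child seed from a master seed (stays below 2^31).
.child_seed <- function(master, k) {
  ((as.numeric(master) %% 65536) * 31259 + k * 7919) %% 2147483399 + 1
}

#' Construct a docking site around a point
#'
#' A `site_definition` that is not tied to tagged residues: used to
#' direct pose sampling at a pocket center.
#' @param centroid length-3 coordinates (Angstroms).
#' @param radius site radius (> 0).
#' @return a `site_definition` with an empty residue list.
#' @export
site_from_point <- function(centroid, radius) {
  stopifnot(radius > 0, length(centroid) == 3)
  structure(list(residues = character(), atom_rows = integer(),
                 centroid = as.numeric(centroid), radius = radius),
            class = "site_definition")
}

#' Generate a toy receptor with a concave pocket
#'
#' Pseudo-atoms (one CA per pseudo-residue) fill a spherical shell
#' around a cavity of radius `pocket_radius`; a cylindrical opening
#' toward +z makes the cavity a solvent-accessible concave pocket. Two
#' wall residues at the pocket rim are tagged as degradation-site
#' lysines with residue numbers 76 and 81 (emulating the ubiquitylation
#' lysines flanking the targeted surface). Atom positions are jittered
#' with seeded Gaussian noise; a fixed seed gives identical structures.
#'
#' @param pocket_radius cavity radius in Angstroms.
#' @param seed RNG seed.
#' @param noise_sd coordinate jitter (Angstroms, default 0.15).
#' @param wall_thickness shell thickness beyond the cavity (Angstroms).
#' @param spacing pseudo-atom lattice spacing (Angstroms).
#' @return `list(structure, pocket_center, site_residues, pocket_radius)`.
#' @export
make_toy_receptor <- function(pocket_radius, seed = 1L, noise_sd = 0.15,
                              wall_thickness = 4.5, spacing = 2.6) {
  if (pocket_radius <= spacing)
    stop("infeasible geometry: pocket radius must exceed lattice spacing")
  p0 <- c(0, 0, 0)
  rmax <- pocket_radius + wall_thickness
  n <- ceiling(rmax / spacing)
  g <- as.matrix(expand.grid(x = -n:n, y = -n:n, z = -n:n)) * spacing
  r <- sqrt(rowSums(g^2))
  keep <- r >= pocket_radius & r <= rmax
  # opening: remove a cylinder toward +z
  rho <- sqrt(g[, 1]^2 + g[, 2]^2)
  keep <- keep & !(g[, 3] > 0.25 * pocket_radius & rho < 0.8 * pocket_radius)
  g <- g[keep, , drop = FALSE]
  g <- with_seed(seed, g + matrix(stats::rnorm(length(g), 0, noise_sd),
                                  nrow(g), 3))
  # tag the two rim atoms (highest z among near-cavity wall atoms)
  rr <- sqrt(rowSums(g^2))
  near_wall <- rr <= pocket_radius + 0.6 * 2.6
  cand <- which(near_wall)
  cand <- cand[order(-g[cand, 3])]
  if (length(cand) < 2L) stop("infeasible geometry: no rim atoms for site tags")
  tag <- cand[1:2]
  resno <- seq_len(nrow(g)) + 100L
  resid <- rep("GLY", nrow(g))
  resno[tag] <- c(76L, 81L)
  resid[tag] <- "LYS"
  atoms <- data.frame(chain = "A", resno = resno, resid = resid,
                      elety = "CA", elesy = "C",
                      x = g[, 1], y = g[, 2], z = g[, 3], o = 1.0,
                      stringsAsFactors = FALSE)
  s <- protein_structure(atoms, source = sprintf("toy-receptor-seed%d", seed))
  list(structure = s, pocket_center = p0,
       site_residues = c("A:76", "A:81"), pocket_radius = pocket_radius)
}

#' Plant a cognate ligand into a toy receptor pocket (positive example)
#'
#' Searches seeded random orientations and small centroid jitters for a
#' placement of the ligand's first conformer with at least
#' `min_contacts` contacts in the 3.0-4.5 A shell and zero clashes.
#'
#' @param receptor result of [make_toy_receptor()].
#' @param ligand a conformer-embedded `molecule`.
#' @param seed RNG seed.
#' @param min_contacts required contact count (default 5).
#' @param max_tries orientation attempts before giving up.
#' @return a scored pose (the planted position).
#' @export
plant_cognate_ligand <- function(receptor, ligand, seed = 1L,
                                 min_contacts = 5L, max_tries = 150L) {
  if (!length(ligand$conformers))
    stop("ligand has no conformers; embed first")
  s <- receptor$structure
  rec_xyz <- coords(s)
  rec_el <- s$atoms$elesy
  lig <- ligand$conformers[[1L]]$xyz
  lig <- sweep(lig, 2, colMeans(lig))
  found <- with_seed(seed, {
    best <- NULL
    for (t in seq_len(max_tries)) {
      q <- .random_quaternion()
      jit <- stats::rnorm(3, 0, 0.5)
      pose <- list(conformer = 1L, quaternion = q,
                   translation = receptor$pocket_center + jit,
                   xyz = sweep(lig %*% t(.quat_to_matrix(q)), 2,
                               receptor$pocket_center + jit, "+"),
                   elements = ligand$atoms$element)
      pose <- score_pose(rec_xyz, rec_el, pose)
      if (pose$clashes == 0L && pose$contacts >= min_contacts) {
        best <- pose
        break
      }
      if (is.null(best) || pose$score > best$score) best <- pose
    }
    best
  })
  if (is.null(found) || found$clashes > 0L || found$contacts < min_contacts)
    stop("could not plant ligand '", ligand$name,
         "' with ", min_contacts, " contacts and no clashes in ",
         max_tries, " tries")
  found
}

# Fragment grammar for drug-like decoy SMILES. Cores use ring digits
# 1-2, substituents 8-9, so composition never collides.
.DECOY_CORES <- c(
  "c1ccc(%A)cc1", "c1ccc(%A)c(%B)c1", "c1cc(%A)ccc1%B", "c1ccncc1",
  "c1ccc(%A)nc1", "C1CCN(%A)CC1", "C1CCOC1%A", "c1csc(%A)c1",
  "C1CCC(%A)CC1", "c1cnc(%A)nc1", "c1ccc2ccccc2c1"
)
.DECOY_SUBS <- c(
  "C", "CC", "CCC", "C(C)C", "OC", "OCC", "N", "NC", "N(C)C", "O",
  "F", "Cl", "Br", "C#N", "C(=O)OC", "C(=O)NC", "C(=O)N", "CO", "CCO",
  "CN", "C(F)(F)F", "c8ccccc8", "Cc8ccccc8", "OCc8ccccc8", "N8CCOCC8",
  "N8CCNCC8", "CC(=O)N", "S(C)", "CNC"
)

#' Generate a library of random drug-like decoy molecules
#'
#' Decoy SMILES are assembled from a fragment grammar (aromatic and
#' saturated cores with drug-like substituents), parsed and validated;
#' every molecule passes the descriptor panel and the set is seeded and
#' reproducible.
#'
#' @param n library size.
#' @param seed RNG seed.
#' @param min_heavy,max_heavy heavy-atom bounds per molecule.
#' @return list of `molecule` objects named `DEC00001`, ...
#' @export
make_decoy_library <- function(n, seed = 1L, min_heavy = 6L,
                               max_heavy = 18L) {
  stopifnot(n >= 1L)
  with_seed(seed, {
    out <- vector("list", n)
    seen <- character()
    k <- 0L; guard <- 0L
    while (k < n && guard < 200L * n) {
      guard <- guard + 1L
      core <- sample(.DECOY_CORES, 1L)
      smi <- core
      for (slot in c("%A", "%B")) {
        if (grepl(slot, smi, fixed = TRUE)) {
          smi <- sub(slot, sample(.DECOY_SUBS, 1L), smi, fixed = TRUE)
        }
      }
      if (smi %in% seen) next
      m <- tryCatch(parse_smiles(smi), error = function(e) NULL)
      if (is.null(m)) next
      if (nrow(m$atoms) < min_heavy || nrow(m$atoms) > max_heavy) next
      ok <- tryCatch({ descriptor_panel(m); TRUE },
                     error = function(e) FALSE)
      if (!ok) next
      seen <- c(seen, smi)
      k <- k + 1L
      m$name <- sprintf("DEC%05d", k)
      out[[k]] <- m
    }
    if (k < n) stop("decoy grammar exhausted before reaching ", n,
                    " molecules")
    out
  })
}

#' Generate a random acyclic branched ligand
#'
#' Grows a random atom tree (C/N/O, valence-respecting) and emits its
#' SMILES. Acyclic branched ligands have strongly asymmetric shapes, so
#' a shape-complementary pocket pins their docked orientation; they are
#' used as the cognate ligands of the synthetic benchmark. Regenerated
#' until the molecule has at least `min_polar` N/O atoms.
#'
#' @param n_heavy heavy-atom count.
#' @param seed RNG seed.
#' @param min_polar,max_polar bounds on the number of N/O atoms.
#' @return a `molecule`.
#' @export
make_branched_ligand <- function(n_heavy, seed = 1L, min_polar = 2L,
                                 max_polar = 4L) {
  stopifnot(n_heavy >= 4L)
  with_seed(seed, {
    for (attempt in 1:80) {
      elems <- c("C", sample(c("C", "N", "O"), n_heavy - 1L,
                             replace = TRUE, prob = c(0.72, 0.14, 0.14)))
      max_children <- c(C = 3L, N = 2L, O = 1L)
      parent <- rep(NA_integer_, n_heavy)
      nchild <- integer(n_heavy)
      ok <- TRUE
      for (i in seq(2L, n_heavy)) {
        open <- which(seq_len(i - 1L) > 0 &
                        nchild[seq_len(i - 1L)] <
                        max_children[elems[seq_len(i - 1L)]])
        if (!length(open)) { ok <- FALSE; break }
        p <- if (length(open) == 1L) open else sample(open, 1L)
        parent[i] <- p
        nchild[p] <- nchild[p] + 1L
      }
      if (!ok) next
      np <- sum(elems %in% c("N", "O"))
      if (np < min_polar || np > max_polar) next
      # require a genuinely branched (shape-asymmetric) skeleton
      if (sum(nchild >= 2L) < 2L) next
      children <- lapply(seq_len(n_heavy), function(i) which(parent == i))
      emit <- function(i) {
        kids <- children[[i]]
        out <- elems[i]
        if (length(kids) > 1L) {
          for (k in kids[-length(kids)])
            out <- paste0(out, "(", emit(k), ")")
        }
        if (length(kids)) out <- paste0(out, emit(kids[length(kids)]))
        out
      }
      smi <- emit(1L)
      m <- tryCatch(parse_smiles(smi), error = function(e) NULL)
      if (!is.null(m) && nrow(m$atoms) == n_heavy) return(m)
    }
    stop("failed to grow a branched ligand with ", n_heavy, " atoms")
  })
}

#' Benchmark specification for the synthetic screen
#'
#' @param n_train,n_test cognate complexes for training and held-out
#'   evaluation (receptors are disjoint between splits).
#' @param n_decoys decoy molecules screened alongside the planted binder.
#' @param noise_sd receptor coordinate jitter (Angstroms).
#' @param conformer_max conformers per screened molecule.
#' @param n_orientations docking rotations per grid point.
#' @param n_trees forest size.
#' @param dock_radius translation-grid radius around the pocket center.
#' @param master_seed master seed; all child seeds derive from it.
#' @param library_seed seed of the decoy compound library. The library
#'   plays the role of a fixed external screening collection, so it
#'   does not vary with the master seed.
#' @return a `benchmark_spec` list.
#' @export
benchmark_spec <- function(n_train = 11L, n_test = 8L, n_decoys = 99L,
                           noise_sd = 0.03, conformer_max = 1L,
                           n_orientations = 24L, n_trees = 500L,
                           dock_radius = 2.0, master_seed = 1L,
                           library_seed = 420L) {
  stopifnot(n_train >= 2L, n_test >= 2L, n_decoys >= 1L)
  structure(list(n_train = n_train, n_test = n_test, n_decoys = n_decoys,
                 noise_sd = noise_sd, conformer_max = conformer_max,
                 n_orientations = n_orientations, n_trees = n_trees,
                 dock_radius = dock_radius, master_seed = master_seed,
                 library_seed = library_seed),
            class = "benchmark_spec")
}

#' Build a receptor shaped around a ligand pose
#'
#' Constructs a shape-complementary pocket: pseudo-atom walls are
#' sampled at contact distance (3.4-4.2 A) from each ligand heavy atom
#' in random outward directions, rejecting positions that would clash
#' with the ligand (< 3.2 A) or crowd other wall atoms (< 2.4 A), and
#' leaving a solvent opening toward +z. The two rim atoms with the
#' highest z are tagged as degradation-site lysines 76 and 81.
#'
#' @param pose_xyz ligand heavy-atom coordinates the pocket should wrap
#'   (centroid near the origin).
#' @param seed RNG seed.
#' @param per_atom wall atoms attempted per ligand atom.
#' @param noise_sd extra jitter applied to wall positions (Angstroms).
#' @param contact_min,contact_max wall distance range from the anchor
#'   ligand atom (Angstroms).
#' @param clearance minimum wall distance from every other ligand atom.
#' @param opening upper bound on the +z direction component of wall
#'   placements (larger = smaller solvent opening).
#' @param elements optional ligand element symbols: when given, walls
#'   anchored near ligand N/O atoms become polar (N or O) partners
#'   placed at hydrogen-bond distance (3.2-3.45 A), emulating the
#'   favorable polar contacts of a cognate complex.
#' @return `list(structure, pocket_center, site_residues)` as in
#'   [make_toy_receptor()].
#' @export
make_complementary_receptor <- function(pose_xyz, seed = 1L, per_atom = 4L,
                                        noise_sd = 0.1, contact_min = 3.7,
                                        contact_max = 4.3,
                                        clearance = 3.5, opening = 0.55,
                                        elements = NULL) {
  pose_xyz <- rbind(pose_xyz)
  polar_anchor <- if (is.null(elements)) rep(FALSE, nrow(pose_xyz))
                  else elements %in% c("N", "O")
  built <- with_seed(seed, {
    out <- matrix(numeric(0), 0, 3)
    wel <- character()
    for (i in seq_len(nrow(pose_xyz))) {
      placed <- 0L
      for (try in seq_len(12L * per_atom)) {
        if (placed >= per_atom) break
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        if (u[3] > opening) next   # keep the opening clear
        polar <- polar_anchor[i] && placed < 2L
        dist <- stats::runif(1, contact_min, contact_max)
        w <- pose_xyz[i, ] + dist * u + stats::rnorm(3, 0, noise_sd)
        dmin <- sqrt(rowSums(sweep(pose_xyz, 2, w)^2))
        dmin[i] <- Inf
        if (min(dmin) < clearance) next
        if (nrow(out) && min(sqrt(rowSums(sweep(out, 2, w)^2))) < 2.4) next
        out <- rbind(out, w)
        wel <- c(wel, if (polar) sample(c("N", "O"), 1L) else "C")
        placed <- placed + 1L
      }
    }
    list(xyz = out, el = wel)
  })
  walls <- built$xyz
  wel <- built$el
  if (nrow(walls) < 6L)
    stop("could not build a complementary wall around the pose")
  tag <- order(-walls[, 3])[1:2]
  resno <- seq_len(nrow(walls)) + 100L
  resid <- rep("GLY", nrow(walls))
  resno[tag] <- c(76L, 81L)
  resid[tag] <- "LYS"
  elety <- ifelse(wel == "C", "CA", ifelse(wel == "N", "N", "O"))
  atoms <- data.frame(chain = "A", resno = resno, resid = resid,
                      elety = elety, elesy = wel,
                      x = walls[, 1], y = walls[, 2], z = walls[, 3],
                      o = 1.0, stringsAsFactors = FALSE)
  s <- protein_structure(atoms,
                         source = sprintf("complementary-receptor-seed%d",
                                          seed))
  list(structure = s, pocket_center = colMeans(pose_xyz),
       site_residues = c("A:76", "A:81"))
}

# Build one cognate complex: a snug receptor shaped around a random
# planted orientation of the ligand, plus the two site objects.
.make_cognate_complex <- function(ligand, seed, noise_sd, dock_radius) {
  lig <- ligand$conformers[[1L]]$xyz
  lig <- sweep(lig, 2, colMeans(lig))
  for (try in 0:4) {
    pose_xyz <- with_seed(seed + 17L * try, {
      lig %*% t(.quat_to_matrix(.random_quaternion()))
    })
    rec <- make_complementary_receptor(pose_xyz, seed = seed + 17L * try + 1L,
                                       noise_sd = noise_sd, per_atom = 8L,
                                       contact_min = 3.1, contact_max = 3.35,
                                       clearance = 3.02, opening = 0.8,
                                       elements = ligand$atoms$element)
    planted <- score_pose(coords(rec$structure), rec$structure$atoms$elesy,
                          list(conformer = 1L, quaternion = c(0, 0, 0, 1),
                               translation = c(0, 0, 0), xyz = pose_xyz,
                               elements = ligand$atoms$element))
    if (planted$clashes == 0L && planted$contacts >= 5L) {
      return(list(receptor = rec$structure,
                  site = site_from_point(rec$pocket_center, dock_radius),
                  filter_site = define_site(rec$structure,
                                            rec$site_residues),
                  ligand = ligand, planted = planted, meta = rec))
    }
  }
  stop("could not build a clash-free cognate complex for ", ligand$name)
}

#' Build the synthetic screen benchmark
#'
#' Generates disjoint training and held-out cognate complexes (each a
#' receptor whose pocket is sized to its own ligand, with the ligand
#' planted at >= 5 contacts and 0 clashes), plus a screening task: the
#' first held-out receptor with its cognate ligand as the planted binder
#' among `n_decoys` decoys.
#'
#' @param spec a [benchmark_spec()].
#' @return `list(train, test, screen, spec)`; `screen` holds the
#'   receptor, docking and filter sites, the binder molecule (named
#'   `BINDER`) and the decoy list.
#' @export
make_screen_benchmark <- function(spec = benchmark_spec()) {
  ms <- spec$master_seed
  n_cognate <- spec$n_train + spec$n_test
  # cognate ligands: acyclic branched molecules with asymmetric shapes
  # and a few polar atoms, sizes spread evenly over 9-16 heavy atoms
  sizes <- round(seq(9L, 16L, length.out = n_cognate))
  cognates <- lapply(seq_len(n_cognate), function(i) {
    m <- make_branched_ligand(sizes[i], seed = .child_seed(ms, 50 + i))
    m$name <- sprintf("COG%03d", i)
    embed_conformers(m, max_n = spec$conformer_max,
                     seed = .child_seed(ms, 100 + i))
  })
  complexes <- lapply(seq_along(cognates), function(i) {
    .make_cognate_complex(cognates[[i]], seed = .child_seed(ms, 200 + i),
                          noise_sd = spec$noise_sd,
                          dock_radius = spec$dock_radius)
  })
  # alternate assignment by size so both splits span the size range
  lab <- character(n_cognate)
  tr_need <- spec$n_train; te_need <- spec$n_test
  take_train <- TRUE
  for (i in seq_len(n_cognate)) {
    if ((take_train && tr_need > 0L) || te_need == 0L) {
      lab[i] <- "train"; tr_need <- tr_need - 1L
    } else {
      lab[i] <- "test"; te_need <- te_need - 1L
    }
    take_train <- !take_train
  }
  train <- complexes[lab == "train"]
  test <- complexes[lab == "test"]
  screen_cx <- test[[1L]]
  binder <- screen_cx$ligand
  binder$name <- "BINDER"
  decoys <- make_decoy_library(spec$n_decoys, seed = spec$library_seed,
                               min_heavy = 6L, max_heavy = 16L)
  list(train = train, test = test,
       screen = list(receptor = screen_cx$receptor,
                     site = screen_cx$site,
                     filter_site = screen_cx$filter_site,
                     binder = binder, decoys = decoys),
       spec = spec)
}

#' Write a benchmark to a fixture directory
#'
#' Serializes every receptor as PDB, the ligand library as SDF, the
#' train/test labels as TSV and a manifest as JSON.
#'
#' @param bench result of [make_screen_benchmark()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (split in c("train", "test")) {
    for (i in seq_along(bench[[split]])) {
      cx <- bench[[split]][[i]]
      write_pdb(cx$receptor,
                file.path(dir, sprintf("%s_receptor_%02d.pdb", split, i)))
    }
  }
  ligs <- c(lapply(bench$train, `[[`, "ligand"),
            lapply(bench$test, `[[`, "ligand"))
  write_sdf(ligs, file.path(dir, "cognate_ligands.sdf"))
  write_sdf(bench$screen$decoys, file.path(dir, "decoys.sdf"))
  labels <- data.frame(
    split = c(rep("train", length(bench$train)),
              rep("test", length(bench$test))),
    ligand = vapply(ligs, `[[`, "", "name"))
  utils::write.table(labels, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(format = "wasscreen-benchmark", version = 1L,
                            spec = unclass(bench$spec)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
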