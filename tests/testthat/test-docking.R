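# Rigid pose sampling, geometric scoring, clustering and refinement.

test_that("single-atom ligand translations lie on the site lattice", {
  # site radius 2 A: exactly the 33 integer lattice points with
  # x^2+y^2+z^2 <= 4
  rec <- make_toy_receptor(pocket_radius = 6, seed = 2)
  site <- site_from_point(c(0, 0, 0), 2)
  conf <- list(list(xyz = matrix(0, 1, 3), energy = 0))
  poses <- suppressWarnings(
    sample_poses(rec$structure, site, conf, "C", n_orientations = 1L,
                 seed = 1L))
  lattice <- expand.grid(x = -2:2, y = -2:2, z = -2:2)
  lattice <- lattice[rowSums(lattice^2) <= 4, ]
  expect_equal(length(poses), nrow(lattice))  # 33
  got <- t(vapply(poses, function(p) as.numeric(p$xyz), numeric(3)))
  expect_setequal(apply(round(got, 9), 1, paste, collapse = ","),
                  apply(lattice, 1, paste, collapse = ","))
})

test_that("pose sampling is deterministic for a fixed seed", {
  rec <- make_toy_receptor(pocket_radius = 6, seed = 2)
  site <- site_from_point(c(0, 0, 0), 2)
  lig <- recovery_ligand()
  p1 <- sample_poses(rec$structure, site, lig$conformers,
                     lig$atoms$element, n_orientations = 4L, seed = 11L)
  p2 <- sample_poses(rec$structure, site, lig$conformers,
                     lig$atoms$element, n_orientations = 4L, seed = 11L)
  expect_identical(p1, p2)
})

test_that("pose scoring counts shell contacts and vdW clashes", {
  # one ligand atom 3.5 A from a single receptor atom: 1 contact
  pose <- list(xyz = matrix(c(3.5, 0, 0), 1), elements = "C",
               conformer = 1L)
  sc <- score_pose(matrix(0, 1, 3), "C", pose)
  expect_equal(sc$contacts, 1L)
  expect_equal(sc$clashes, 0L)
  expect_equal(sc$score, 1.0)
  # overlapping pair at 1.0 A: clash dominates
  sc2 <- score_pose(matrix(0, 1, 3), "C",
                    list(xyz = matrix(c(1, 0, 0), 1), elements = "C"))
  expect_gte(sc2$clashes, 1L)
  expect_lte(sc2$score, -5 + sc2$contacts)
  # random 15-atom ligand vs 50-atom pocket equals brute force
  set.seed(13)
  for (rep in 1:5) {
    rxyz <- matrix(runif(150, 0, 10), 50)
    rel <- sample(c("C", "N", "O", "S"), 50, replace = TRUE)
    lxyz <- matrix(runif(45, 0, 10), 15)
    lel <- sample(c("C", "N", "O"), 15, replace = TRUE)
    got <- score_pose(rxyz, rel, list(xyz = lxyz, elements = lel))
    contacts <- 0L; clashes <- 0L
    for (i in 1:50) for (j in 1:15) {
      d <- sqrt(sum((rxyz[i, ] - lxyz[j, ])^2))
      if (d >= 3.0 && d <= 4.5) contacts <- contacts + 1L
      if (d < BONDI_RADII[[rel[i]]] + BONDI_RADII[[lel[j]]] - 0.4)
        clashes <- clashes + 1L
    }
    expect_equal(got$contacts, contacts)
    expect_equal(got$clashes, clashes)
    expect_equal(got$score, contacts - 5 * clashes)
  }
})

test_that("pose scores are invariant under a joint rigid transform", {
  set.seed(4)
  rxyz <- matrix(runif(90, 0, 8), 30)
  lxyz <- matrix(runif(30, 2, 6), 10)
  s0 <- score_pose(rxyz, rep("C", 30), list(xyz = lxyz,
                                            elements = rep("C", 10)))
  th <- 0.9
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  shift <- c(-4, 2, 9)
  s1 <- score_pose(rxyz %*% t(R) + matrix(shift, 30, 3, byrow = TRUE),
                   rep("C", 30),
                   list(xyz = lxyz %*% t(R) +
                          matrix(shift, 10, 3, byrow = TRUE),
                        elements = rep("C", 10)))
  expect_equal(s1$contacts, s0$contacts)
  expect_equal(s1$clashes, s0$clashes)
})

test_that("greedy clustering merges near poses and splits far ones", {
  base <- list(conformer = 1L, xyz = matrix(rnorm(30), 10),
               elements = rep("C", 10), contacts = 5L, clashes = 0L,
               score = 5)
  same <- rep(list(base), 5)
  res <- cluster_poses(same)
  expect_length(res$poses, 1L)
  expect_equal(res$sizes, 5L)
  far <- base
  far$xyz <- base$xyz + 10
  far$score <- 3
  res2 <- cluster_poses(list(base, far))
  expect_length(res2$poses, 2L)
  expect_equal(res2$best$score, 5)
  # 50 jittered copies of 3 seeds separated by > 4 A give 3 clusters
  set.seed(17)
  seeds <- list(base$xyz, base$xyz + c(12, 0, 0), base$xyz + c(0, 12, 0))
  jittered <- list()
  for (k in 1:50) {
    s <- seeds[[(k %% 3) + 1L]]
    p <- base
    p$xyz <- s + matrix(rnorm(30, 0, 0.3), 10)
    p$score <- runif(1, 0, 10)
    jittered[[k]] <- p
  }
  expect_length(cluster_poses(jittered, 4.0)$poses, 3L)
  # ordering is non-increasing in score
  sc <- vapply(cluster_poses(jittered, 4.0)$poses, `[[`, 0, "score")
  expect_true(all(diff(sc) <= 0))
})

test_that("refinement resolves a mild clash and respects the site bound", {
  lig <- recovery_ligand()
  lxyz <- sweep(lig$conformers[[1]]$xyz, 2,
                colMeans(lig$conformers[[1]]$xyz))
  pose_xyz <- with_seed(31, lxyz %*% t(.quat_to_matrix(.random_quaternion())))
  rec <- make_complementary_receptor(pose_xyz, seed = 32)
  site <- site_from_point(rec$pocket_center, 2)
  # push the planted pose 0.8 A off register: creates close approaches
  off <- pose_xyz + matrix(c(0.8, 0, 0), nrow(pose_xyz), 3, byrow = TRUE)
  pose <- score_pose(coords(rec$structure), rec$structure$atoms$elesy,
                     list(conformer = 1L, xyz = off,
                          elements = lig$atoms$element))
  ref <- refine_pose(rec$structure, site, pose)
  expect_gte(ref$score, pose$score)
  # ligand centroid never leaves the site sphere plus margin
  expect_lte(sqrt(sum((colMeans(ref$xyz) - site$centroid)^2)),
             site$radius + 2 + 1e-6)
})

test_that("a planted complementary cavity is recovered by docking", {
  # stochastic enrichment property: top-ranked cluster within 2 A of
  # the planted pose in >= 8/10 docking seeds
  lig <- recovery_ligand()
  lxyz <- sweep(lig$conformers[[1]]$xyz, 2,
                colMeans(lig$conformers[[1]]$xyz))
  pose_xyz <- with_seed(31, lxyz %*% t(.quat_to_matrix(.random_quaternion())))
  rec <- make_complementary_receptor(pose_xyz, seed = 32, per_atom = 6L,
                                     contact_min = 3.5, contact_max = 3.7,
                                     clearance = 3.4, noise_sd = 0.05,
                                     opening = 0.95)
  site <- site_from_point(rec$pocket_center, 2)
  hits <- 0L
  for (sd in 1:10) {
    res <- tryCatch(suppressWarnings(
      dock_molecule(rec$structure, site, lig, n_orientations = 80L,
                    seed = sd, refine = TRUE, refine_top = 15L)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (conformer_rmsd(res$best$xyz, pose_xyz, superpose = FALSE) <= 2.0)
      hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})
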