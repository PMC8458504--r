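# Deterministic generators: toy receptors, planted complexes, decoys.

test_that("toy receptors have a concave tagged pocket and reproduce", {
  rec <- make_toy_receptor(pocket_radius = 6, seed = 3)
  s <- rec$structure
  tags <- s$atoms[s$atoms$resid == "LYS", ]
  expect_equal(sort(tags$resno), c(76L, 81L))
  # concavity: many receptor atoms near the pocket centroid
  d <- sqrt(rowSums(sweep(coords(s), 2, rec$pocket_center)^2))
  expect_gte(sum(d <= 8), 10L)
  # no atom intrudes into the cavity
  expect_true(all(d >= rec$pocket_radius - 3 * 0.15 - 1e-9))
  # byte-identical PDB for the same seed
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(make_toy_receptor(6, seed = 3)$structure, p1)
  write_pdb(make_toy_receptor(6, seed = 3)$structure, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_error(make_toy_receptor(pocket_radius = 1), "infeasible")
})

test_that("planted cognate ligands satisfy the contact/clash contract", {
  lig <- recovery_ligand()
  rec <- make_toy_receptor(pocket_radius = 5.5, seed = 5)
  pose <- plant_cognate_ligand(rec, lig, seed = 8)
  expect_gte(pose$contacts, 5L)
  expect_equal(pose$clashes, 0L)
  # site-proximal: within the filter cutoff of the tagged lysines
  site <- define_site(rec$structure, rec$site_residues)
  expect_lte(min_site_distance(pose$xyz, rec$structure, site), 5.0)
  # reproducible placement
  pose2 <- plant_cognate_ligand(rec, lig, seed = 8)
  expect_identical(pose$xyz, pose2$xyz)
})

test_that("complementary receptors wrap the pose without clashing", {
  lig <- recovery_ligand()
  lxyz <- sweep(lig$conformers[[1]]$xyz, 2,
                colMeans(lig$conformers[[1]]$xyz))
  rec <- make_complementary_receptor(lxyz, seed = 12,
                                     elements = lig$atoms$element)
  pose <- score_pose(coords(rec$structure), rec$structure$atoms$elesy,
                     list(xyz = lxyz, elements = lig$atoms$element))
  expect_equal(pose$clashes, 0L)
  expect_gte(pose$contacts, 5L)
  expect_equal(sort(rec$structure$atoms$resno[
    rec$structure$atoms$resid == "LYS"]), c(76L, 81L))
})

test_that("decoy libraries are valid, diverse and reproducible", {
  lib <- make_decoy_library(100, seed = 1)
  expect_length(lib, 100L)
  # all parse and pass the descriptor panel; >= 80% Lipinski-compliant
  panels <- lapply(lib, descriptor_panel)
  expect_gte(mean(vapply(panels, function(p) p$lipinski_violations, 0) <= 1),
             0.8)
  # duplicate rate < 5%
  keys <- vapply(lib, function(m)
    paste(molecular_formula(m), nrow(m$bonds),
          round(tpsa(m), 2), round(crippen_logp(m), 2)), "")
  expect_lt(mean(duplicated(keys)), 0.05)
  lib2 <- make_decoy_library(100, seed = 1)
  expect_identical(lapply(lib, `[[`, "atoms"), lapply(lib2, `[[`, "atoms"))
})

test_that("branched cognate ligands are acyclic, polar and sized", {
  for (k in 1:5) {
    m <- make_branched_ligand(10L, seed = k)
    expect_equal(nrow(m$atoms), 10L)
    expect_equal(nrow(m$bonds), 9L)     # tree: n-1 edges
    expect_gte(sum(m$atoms$element %in% c("N", "O")), 2L)
  }
  expect_identical(make_branched_ligand(12L, seed = 4L),
                   make_branched_ligand(12L, seed = 4L))
})

test_that("benchmark splits are sized, disjoint and reproducible", {
  spec <- benchmark_spec(n_train = 3L, n_test = 2L, n_decoys = 5L,
                         master_seed = 11L)
  b <- make_screen_benchmark(spec)
  expect_length(b$train, 3L)
  expect_length(b$test, 2L)
  expect_length(b$screen$decoys, 5L)
  # no ligand appears in both splits
  tr_names <- vapply(b$train, function(cx) cx$ligand$name, "")
  te_names <- vapply(b$test, function(cx) cx$ligand$name, "")
  expect_length(intersect(tr_names, te_names), 0L)
  b2 <- make_screen_benchmark(spec)
  expect_identical(lapply(b$train, function(cx) cx$receptor$atoms),
                   lapply(b2$train, function(cx) cx$receptor$atoms))
})

test_that("generated artifacts round-trip through PDB and SDF", {
  spec <- benchmark_spec(n_train = 2L, n_test = 2L, n_decoys = 3L,
                         master_seed = 21L)
  b <- make_screen_benchmark(spec)
  dir <- withr::local_tempdir()
  write_benchmark(b, dir)
  expect_true(file.exists(file.path(dir, "train_receptor_01.pdb")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_pdb(file.path(dir, "train_receptor_01.pdb"))
  expect_equal(coords(back), round(coords(b$train[[1]]$receptor), 3),
               ignore_attr = TRUE)
  ligs <- read_sdf(file.path(dir, "cognate_ligands.sdf"))
  expect_length(ligs, 4L)
  expect_equal(nrow(ligs[[1]]$atoms), nrow(b$train[[1]]$ligand$atoms))
})
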