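# PDB I/O, component deletion, virtual mutagenesis, clash and
# site-distance utilities. All fixtures are built in code.

test_that("PDB write/read round-trips coordinates and ordering", {
  s <- two_chain_fixture()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, path)
  back <- read_pdb(path)
  expect_equal(nrow(back$atoms), nrow(s$atoms))
  expect_equal(back$atoms$chain, s$atoms$chain)
  expect_equal(back$atoms$resno, s$atoms$resno)
  expect_equal(back$atoms$elety, s$atoms$elety)
  expect_equal(coords(back), round(coords(s), 3), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("unparsable PDB records raise line-numbered format errors", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       1.000   xxx     0.000  1.00  0.00           C",
    "END"), path)
  expect_error(read_pdb(path), "line 2")
})

test_that("delete/extract components resolve chains and residue ranges", {
  s <- two_chain_fixture()
  nB <- sum(s$atoms$chain == "B")
  onlyA <- delete_components(s, "B")
  expect_equal(unique(onlyA$atoms$chain), "A")
  expect_equal(nrow(onlyA$atoms), nrow(s$atoms) - nB)
  # untouched atoms are bit-identical
  expect_identical(onlyA$atoms$x, s$atoms$x[s$atoms$chain == "A"])
  # residue range deletion drops exactly those residues
  del <- delete_components(s, "A:2-3")
  expect_false(any(del$atoms$chain == "A" & del$atoms$resno %in% 2:3))
  expect_equal(nrow(unique(del$atoms[del$atoms$chain == "A",
                                     c("chain", "resno")])), 2L)
  expect_error(delete_components(s, "Z"), "no residues")
  ext <- extract_components(s, "B")
  expect_equal(nrow(ext$atoms), nB)
})

test_that("the surrogate mutation set changes 4 residues and no backbone", {
  pep <- mutation_fixture()
  specs <- mutation_spec("A", c(71, 72, 74, 81),
                         c("V", "A", "L", "R"), c("A", "V", "F", "K"))
  mut <- apply_mutations(pep, specs)
  # exactly the four targets renamed
  changed <- merge(unique(pep$atoms[, c("resno", "resid")]),
                   unique(mut$atoms[, c("resno", "resid")]), by = "resno")
  expect_equal(sort(changed$resno[changed$resid.x != changed$resid.y]),
               c(71, 72, 74, 81))
  expect_equal(unname(AA3TO1[unique(mut$atoms$resid[mut$atoms$resno == 71])]), "A")
  expect_equal(unname(AA3TO1[unique(mut$atoms$resid[mut$atoms$resno == 81])]), "K")
  # backbone (and CB) coordinates unchanged at every mutated position
  bb <- c("N", "CA", "C", "O", "CB")
  for (rn in c(71, 72, 74, 81)) {
    a0 <- pep$atoms[pep$atoms$resno == rn & pep$atoms$elety %in% bb, ]
    a1 <- mut$atoms[mut$atoms$resno == rn & mut$atoms$elety %in% bb, ]
    a1 <- a1[match(a0$elety, a1$elety), ]
    expect_equal(as.matrix(a1[, c("x", "y", "z")]),
                 as.matrix(a0[, c("x", "y", "z")]), ignore_attr = TRUE)
  }
})

test_that("V->A truncation deletes the branched side chain only", {
  pep <- mutation_fixture()
  mut <- apply_mutations(pep, mutation_spec("A", 71, "V", "A"))
  at71 <- mut$atoms[mut$atoms$resno == 71, ]
  expect_setequal(at71$elety, c("N", "CA", "C", "O", "CB"))
})

test_that("R->K rebuild produces lysine atoms with ideal bond lengths", {
  pep <- mutation_fixture()
  mut <- apply_mutations(pep, mutation_spec("A", 81, "R", "K"))
  k <- mut$atoms[mut$atoms$resno == 81, ]
  expect_setequal(k$elety, c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"))
  g <- function(nm) as.numeric(k[k$elety == nm, c("x", "y", "z")])
  blen <- function(a, b) sqrt(sum((g(a) - g(b))^2))
  expect_close(blen("CB", "CG"), 1.520, 0.02)
  expect_close(blen("CG", "CD"), 1.520, 0.02)
  expect_close(blen("CD", "CE"), 1.520, 0.02)
  expect_close(blen("CE", "NZ"), 1.489, 0.02)
})

test_that("mutation validation catches mismatched source residues", {
  pep <- mutation_fixture()
  expect_error(apply_mutations(pep, mutation_spec("A", 71, "L", "F")),
               "A:71")
  expect_error(apply_mutations(pep, mutation_spec("A", 999, "V", "A")),
               "no residue")
})

test_that("mutation then reverse mutation restores names and backbone", {
  pep <- mutation_fixture()
  fwd <- apply_mutations(pep, mutation_spec("A", 74, "L", "F"))
  back <- apply_mutations(fwd, mutation_spec("A", 74, "F", "L"))
  expect_equal(unique(back$atoms$resid[back$atoms$resno == 74]), "LEU")
  bb <- c("N", "CA", "C", "O", "CB")
  a0 <- pep$atoms[pep$atoms$elety %in% bb, ]
  a1 <- back$atoms[back$atoms$elety %in% bb, ]
  a1 <- a1[order(a1$resno, match(a1$elety, bb)), ]
  a0 <- a0[order(a0$resno, match(a0$elety, bb)), ]
  expect_equal(as.matrix(a1[, c("x", "y", "z")]),
               as.matrix(a0[, c("x", "y", "z")]), ignore_attr = TRUE)
})

test_that("clash detection follows the Bondi rule and is symmetric", {
  # two carbons: threshold 1.7 + 1.7 - 0.4 = 3.0
  a <- matrix(c(0, 0, 0), 1)
  expect_equal(nrow(find_clashes(a, matrix(c(2.9, 0, 0), 1))), 1L)
  expect_equal(nrow(find_clashes(a, matrix(c(3.1, 0, 0), 1))), 0L)
  # random sets match a brute-force double loop and are order-independent
  set.seed(5)
  for (rep in 1:5) {
    A <- matrix(runif(60, 0, 8), 20)
    B <- matrix(runif(60, 0, 8), 20)
    elA <- sample(c("C", "N", "O", "S"), 20, replace = TRUE)
    elB <- sample(c("C", "N", "O", "H"), 20, replace = TRUE)
    got <- find_clashes(A, B, elementsA = elA, elementsB = elB)
    brute <- list()
    for (i in 1:20) for (j in 1:20) {
      d <- sqrt(sum((A[i, ] - B[j, ])^2))
      thr <- BONDI_RADII[[elA[i]]] + BONDI_RADII[[elB[j]]] - 0.4
      if (d < thr) brute[[length(brute) + 1L]] <- c(i, j)
    }
    expect_equal(nrow(got), length(brute))
    if (nrow(got)) {
      expect_setequal(paste(got$i, got$j),
                      vapply(brute, function(p) paste(p[1], p[2]), ""))
    }
    rev <- find_clashes(B, A, elementsA = elB, elementsB = elA)
    expect_setequal(paste(got$i, got$j), paste(rev$j, rev$i))
  }
})

test_that("site definition and minimum site distance are geometric", {
  s <- two_chain_fixture()
  site <- define_site(s, c("A:2", "A:3"), radius = 8)
  rows <- s$atoms$chain == "A" & s$atoms$resno %in% 2:3
  expect_equal(site$centroid, colMeans(coords(s, rows)), ignore_attr = TRUE)
  expect_error(define_site(s, "A:99"), "not found")
  expect_error(define_site(s, "A:2", radius = -1), "positive")
  # coincident atom -> 0; single atom at 4.9 -> 4.9
  p0 <- coords(s, which(rows))[1, , drop = FALSE]
  expect_close(min_site_distance(p0, s, site), 0, 1e-12)
  off <- p0 + c(4.9, 0, 0)
  d_direct <- sqrt(min(colSums((t(coords(s, which(rows))) - as.numeric(off))^2)))
  expect_close(min_site_distance(off, s, site), d_direct, 1e-9)
  # 30-atom ligand equals an exhaustive pairwise minimum
  set.seed(7)
  lig <- matrix(rnorm(90, sd = 6), 30)
  brute <- min(sqrt(.cross_dist2(lig, coords(s, which(rows)))))
  expect_close(min_site_distance(lig, s, site), brute, 1e-9)
})

test_that("min site distance is invariant under joint rigid motion", {
  s <- two_chain_fixture()
  site <- define_site(s, c("A:2", "A:3"))
  set.seed(3)
  lig <- matrix(rnorm(30, sd = 5), 10)
  d0 <- min_site_distance(lig, s, site)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  shift <- c(5, -3, 2)
  s2 <- s
  s2$atoms[, c("x", "y", "z")] <- coords(s) %*% t(R) +
    matrix(shift, nrow(s$atoms), 3, byrow = TRUE)
  site2 <- define_site(s2, c("A:2", "A:3"))
  lig2 <- lig %*% t(R) + matrix(shift, nrow(lig), 3, byrow = TRUE)
  expect_close(min_site_distance(lig2, s2, site2), d0, 1e-9)
})
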