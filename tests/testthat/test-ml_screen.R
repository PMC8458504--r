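# Interaction featurization and the random-forest binder classifier.

test_that("feature vector has fixed names, order and finite entries", {
  fn <- feature_names()
  expect_length(fn, 65L)
  expect_equal(fn[1], "ct_C_C_1")
  expect_true(all(c("hbond_pairs", "hydrophobic_cc", "buried_fraction",
                    "composite_score", "ligand_heavy_atoms") %in% fn))
  rec <- make_toy_receptor(pocket_radius = 6, seed = 2)
  pose <- list(xyz = matrix(c(0, 0, 0), 1), elements = "C", score = 0)
  v <- featurize_pose(rec$structure, pose)
  expect_equal(names(v), fn)
  expect_true(all(is.finite(v)))
})

test_that("a far-away ligand featurizes to zero contacts", {
  rec <- make_toy_receptor(pocket_radius = 6, seed = 2)
  pose <- list(xyz = matrix(c(500, 500, 500), 1), elements = "C",
               score = 0)
  v <- featurize_pose(rec$structure, pose)
  expect_equal(sum(v[grepl("^ct_", names(v))]), 0)
  expect_equal(unname(v["buried_fraction"]), 0)
  expect_equal(unname(v["hbond_pairs"]), 0)
})

test_that("a single C-O pair at 3.0 A fills exactly one contact bin", {
  s <- protein_structure(data.frame(
    chain = "A", resno = 1L, resid = "GLY", elety = "O", elesy = "O",
    x = 0, y = 0, z = 0, o = 1))
  pose <- list(xyz = matrix(c(3.0, 0, 0), 1), elements = "C", score = 1)
  v <- featurize_pose(s, pose)
  ct <- v[grepl("^ct_", names(v))]
  expect_equal(sum(ct), 1)
  expect_equal(unname(v["ct_O_C_2"]), 1)  # [2.5, 3.5) shell
})

test_that("contact bins equal brute-force per-bin counts", {
  set.seed(23)
  for (rep in 1:5) {
    n <- 40; m <- 12
    rxyz <- matrix(runif(3 * n, 0, 10), n)
    rel <- sample(c("C", "N", "O", "S", "P"), n, replace = TRUE)
    s <- protein_structure(data.frame(
      chain = "A", resno = seq_len(n), resid = "GLY", elety = "CA",
      elesy = rel, x = rxyz[, 1], y = rxyz[, 2], z = rxyz[, 3], o = 1))
    lxyz <- matrix(runif(3 * m, 0, 10), m)
    lel <- sample(c("C", "N", "O", "F"), m, replace = TRUE)
    pose <- list(xyz = lxyz, elements = lel, score = 2.5)
    v <- featurize_pose(s, pose)
    bins <- c(0, 2.5, 3.5, 4.5)
    pc <- ifelse(rel %in% c("C", "N", "O", "S"), rel, "other")
    lc <- ifelse(lel %in% c("C", "N", "O"), lel, "other")
    brute <- stats::setNames(numeric(length(feature_names())),
                             feature_names())
    hb <- 0; cc <- 0; buried <- logical(m)
    for (i in seq_len(n)) for (j in seq_len(m)) {
      d <- sqrt(sum((rxyz[i, ] - lxyz[j, ])^2))
      if (d < 4.5) {
        b <- findInterval(d, bins)
        key <- sprintf("ct_%s_%s_%d", pc[i], lc[j], b)
        brute[key] <- brute[key] + 1
      }
      if (d <= 3.5 && rel[i] %in% c("N", "O") && lel[j] %in% c("N", "O"))
        hb <- hb + 1
      if (d <= 4.5 && rel[i] == "C" && lel[j] == "C") cc <- cc + 1
      if (d <= 4.5) buried[j] <- TRUE
    }
    brute["hbond_pairs"] <- hb
    brute["hydrophobic_cc"] <- cc
    brute["buried_fraction"] <- mean(buried)
    brute["composite_score"] <- 2.5
    brute["ligand_heavy_atoms"] <- m
    expect_equal(v, brute)
  }
})

test_that("training pairs form a seeded derangement with balance", {
  spec <- benchmark_spec(n_train = 4L, n_test = 2L, n_decoys = 1L,
                         master_seed = 3L)
  bench <- make_screen_benchmark(spec)
  ts <- build_training_set(bench$train, seed = 5L, n_orientations = 20L)
  expect_equal(sum(ts$labels == 1L), 4L)
  expect_equal(sum(ts$labels == 0L), 4L)
  neg <- ts$pairs[ts$pairs$label == 0L, ]
  expect_true(all(neg$receptor != neg$ligand))  # no fixed point
  expect_setequal(neg$ligand, 1:4)              # a permutation
  ts2 <- build_training_set(bench$train, seed = 5L, n_orientations = 20L)
  expect_identical(ts$pairs, ts2$pairs)
  expect_error(build_training_set(bench$train[1], seed = 1L),
               "at least two")
})

test_that("forest training honors size, determinism and class checks", {
  set.seed(31)
  X <- matrix(rnorm(40 * 6), 40)
  colnames(X) <- paste0("f", 1:6)
  y <- as.integer(X[, 2] > 0)
  fo <- train_forest(X, y, n_trees = 25L, seed = 4L)
  expect_length(fo$trees, 25L)
  expect_equal(fo$n_trees, 25L)
  fo2 <- train_forest(X, y, n_trees = 25L, seed = 4L)
  expect_equal(classify(fo, X), classify(fo2, X))
  expect_error(train_forest(X, rep(1L, 40)), "single class")
  # two-point linearly separable set trains to perfect accuracy
  X2 <- matrix(c(0, 1, 0, 1), 4)
  colnames(X2) <- c("a")
  X2 <- cbind(X2, b = c(0, 0, 1, 1))
  y2 <- c(0L, 1L, 0L, 1L)
  fo3 <- train_forest(X2, y2, n_trees = 50L, seed = 1L)
  expect_equal(as.integer(classify(fo3, X2) >= 0.5), y2)
})

test_that("default forest size is 500 trees", {
  expect_equal(formals(train_forest)$n_trees, 500L)
})

test_that("classification is a vote fraction matching a hand tally", {
  set.seed(77)
  X <- matrix(rnorm(30 * 5), 30)
  colnames(X) <- paste0("f", 1:5)
  y <- as.integer(X[, 1] + 0.3 * X[, 3] > 0)
  fo <- train_forest(X, y, n_trees = 5L, seed = 9L)
  for (k in 1:10) {
    v <- stats::setNames(rnorm(5), colnames(X))
    votes <- vapply(fo$trees, function(tr)
      as.numeric(.tree_predict(tr, v) >= 0.5), 0)
    expect_equal(classify(fo, v), mean(votes))
    expect_gte(classify(fo, v), 0)
    expect_lte(classify(fo, v), 1)
  }
  bad <- stats::setNames(rnorm(5), paste0("g", 1:5))
  expect_error(classify(fo, bad), "schema")
})

test_that("forest predictions agree with an independent implementation", {
  skip_if_not_installed("randomForest")
  set.seed(42)
  X <- matrix(rnorm(60 * 8), 60)
  colnames(X) <- paste0("f", 1:8)
  y <- as.integer(X[, 3] - X[, 5] > 0)
  Xt <- matrix(rnorm(200 * 8), 200)
  colnames(Xt) <- colnames(X)
  yt <- as.integer(Xt[, 3] - Xt[, 5] > 0)
  mine <- train_forest(X, y, n_trees = 200L, seed = 1L)
  ref <- randomForest::randomForest(x = X, y = factor(y), ntree = 200)
  auc_mine <- roc_auc(classify(mine, Xt), yt)
  auc_ref <- roc_auc(predict(ref, Xt, type = "prob")[, 2], yt)
  expect_gt(auc_mine, 0.85)
  expect_lt(abs(auc_mine - auc_ref), 0.1)
})

test_that("serialization round-trips to identical predictions", {
  set.seed(13)
  X <- matrix(rnorm(20 * 4), 20)
  colnames(X) <- paste0("f", 1:4)
  y <- as.integer(X[, 1] > 0)
  fo <- train_forest(X, y, n_trees = 10L, seed = 2L)
  path <- withr::local_tempfile(fileext = ".json")
  write_forest(fo, path)
  back <- read_forest(path)
  expect_equal(classify(back, X), classify(fo, X))
  expect_equal(back$feature_names, fo$feature_names)
})

test_that("permuting training rows barely moves out-of-bag accuracy", {
  set.seed(55)
  X <- matrix(rnorm(60 * 6), 60)
  colnames(X) <- paste0("f", 1:6)
  y <- as.integer(X[, 1] > 0)
  a <- train_forest(X, y, n_trees = 150L, seed = 3L)$oob_accuracy
  perm <- sample(60)
  b <- train_forest(X[perm, ], y[perm], n_trees = 150L,
                    seed = 3L)$oob_accuracy
  expect_lte(abs(a - b), 0.05 + 1e-9)
})
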