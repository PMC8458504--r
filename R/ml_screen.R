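# Interaction-fingerprint featurization of docking models and a seeded
# bagged-CART random-forest binder classifier (Gini impurity, sqrt(F)
# candidate features per split, trees grown to purity), scoring 0-1 as
# the fraction of trees voting "binder".

.PROT_CLASSES <- c("C", "N", "O", "S", "other")
.LIG_CLASSES <- c("C", "N", "O", "other")
.DIST_BINS <- c(0, 2.5, 3.5, 4.5)

#' Names of the interaction feature vector, in fixed order
#'
#' 60 contact-count bins (receptor atom class x ligand atom class x
#' distance shell) followed by five pose/ligand summaries: H-bond pair
#' count, hydrophobic C-C contact count, buried-ligand fraction, docking
#' composite score and ligand heavy-atom count.
#' @return character vector of feature names.
#' @export
feature_names <- function() {
  bins <- character()
  for (p in .PROT_CLASSES) for (l in .LIG_CLASSES)
    for (b in seq_len(length(.DIST_BINS) - 1L))
      bins <- c(bins, sprintf("ct_%s_%s_%d", p, l, b))
  c(bins, "hbond_pairs", "hydrophobic_cc", "buried_fraction",
    "composite_score", "ligand_heavy_atoms")
}

.atom_class <- function(elements, classes) {
  out <- ifelse(elements %in% classes, elements, "other")
  factor(out, levels = classes)
}

#' Featurize a docking pose
#'
#' Deterministic fixed-length interaction fingerprint of one docking
#' model: per-bin contact counts over receptor atom class {C,N,O,S,other}
#' x ligand atom class {C,N,O,other} x distance shell {[0,2.5), [2.5,3.5),
#' [3.5,4.5)}, plus H-bond donor/acceptor heavy-atom pairs (N/O vs N/O
#' within 3.5 A), hydrophobic C-C contacts within 4.5 A, the fraction of
#' ligand atoms with any receptor atom within 4.5 A, the pose composite
#' score, and the ligand heavy-atom count.
#'
#' @param s receptor `protein_structure`.
#' @param pose a scored pose.
#' @return named numeric vector (see [feature_names()]).
#' @export
featurize_pose <- function(s, pose) {
  rec_xyz <- coords(s)
  d <- sqrt(.cross_dist2(rec_xyz, pose$xyz))
  pc <- .atom_class(s$atoms$elesy, .PROT_CLASSES)
  lc <- .atom_class(pose$elements, .LIG_CLASSES)
  v <- stats::setNames(numeric(length(feature_names())), feature_names())
  within <- d < .DIST_BINS[length(.DIST_BINS)]
  hit <- which(within, arr.ind = TRUE)
  if (nrow(hit)) {
    db <- cut(d[hit], breaks = .DIST_BINS, right = FALSE, labels = FALSE)
    keys <- sprintf("ct_%s_%s_%d", pc[hit[, 1]], lc[hit[, 2]], db)
    tab <- table(keys)
    v[names(tab)] <- as.numeric(tab)
  }
  no_r <- s$atoms$elesy %in% c("N", "O")
  no_l <- pose$elements %in% c("N", "O")
  v["hbond_pairs"] <- sum(d[no_r, no_l, drop = FALSE] <= 3.5)
  c_r <- s$atoms$elesy == "C"
  c_l <- pose$elements == "C"
  v["hydrophobic_cc"] <- sum(d[c_r, c_l, drop = FALSE] <= 4.5)
  v["buried_fraction"] <- mean(apply(d <= 4.5, 2, any))
  v["composite_score"] <- if (is.null(pose$score)) 0 else pose$score
  v["ligand_heavy_atoms"] <- length(pose$elements)
  v
}

#' Build a labeled training set from cognate complexes
#'
#' Positive examples are the interaction features of the redocked
#' cognate (receptor, ligand) pairs; negative examples come from docking
#' a seeded derangement of the same ligands against non-cognate
#' receptors, giving exact class balance. Each complex must supply the
#' receptor, its docking site and a conformer-embedded ligand.
#'
#' @param complexes list of `list(receptor, site, ligand, name)`.
#' @param seed RNG seed for the derangement and docking.
#' @param n_orientations docking orientations per grid point.
#' @param refine rigid-refine the best poses (default TRUE).
#' @return `list(features, labels, pairs)`: feature matrix (rows =
#'   samples), 0/1 labels, and the receptor/ligand pairing table.
#' @export
build_training_set <- function(complexes, seed = 1L, n_orientations = 30L,
                               refine = TRUE) {
  n <- length(complexes)
  if (n < 2L) stop("need at least two distinct receptors for a derangement")
  perm <- with_seed(seed, {
    repeat {
      p <- sample(n)
      if (!any(p == seq_len(n))) break
    }
    p
  })
  feats <- list(); labels <- integer(); pairs <- list()
  for (k in seq_len(n)) {
    cx <- complexes[[k]]
    res <- suppressWarnings(
      dock_molecule(cx$receptor, cx$site, cx$ligand,
                    n_orientations = n_orientations,
                    seed = seed + k, refine = refine, refine_top = 8L))
    if (is.null(res)) stop("redocking failed for cognate complex ", k)
    feats[[length(feats) + 1L]] <- featurize_pose(cx$receptor, res$best)
    labels <- c(labels, 1L)
    pairs[[length(pairs) + 1L]] <- data.frame(receptor = k, ligand = k,
                                              label = 1L)
  }
  for (k in seq_len(n)) {
    cx <- complexes[[k]]
    lig <- complexes[[perm[k]]]$ligand
    res <- tryCatch(suppressWarnings(
      dock_molecule(cx$receptor, cx$site, lig,
                    n_orientations = n_orientations,
                    seed = seed + n + k, refine = refine,
                    refine_top = 8L)), error = function(e) NULL)
    f <- if (is.null(res)) {
      # fully clashing non-cognate pair: all-zero contact features
      v <- stats::setNames(numeric(length(feature_names())), feature_names())
      v["ligand_heavy_atoms"] <- nrow(lig$atoms)
      v
    } else featurize_pose(cx$receptor, res$best)
    feats[[length(feats) + 1L]] <- f
    labels <- c(labels, 0L)
    pairs[[length(pairs) + 1L]] <- data.frame(receptor = k, ligand = perm[k],
                                              label = 0L)
  }
  list(features = do.call(rbind, feats), labels = labels,
       pairs = do.call(rbind, pairs))
}

# Grow one CART tree on (X, y) rows `idx`, Gini impurity, `mtry`
# candidate features per split, grown to purity (min leaf 1). Returns a
# flat-list tree: each node is list(feature, threshold, left, right) or
# list(leaf = positive fraction).
.grow_tree <- function(X, y, idx, mtry) {
  build <- function(rows) {
    ys <- y[rows]
    if (length(unique(ys)) == 1L || length(rows) == 1L)
      return(list(leaf = mean(ys)))
    feats <- sample.int(ncol(X), mtry)
    best <- NULL; best_gini <- Inf
    for (f in feats) {
      xv <- X[rows, f]
      ux <- sort(unique(xv))
      if (length(ux) < 2L) next
      cuts <- (ux[-1] + ux[-length(ux)]) / 2
      for (cut in cuts) {
        l <- xv < cut
        nl <- sum(l); nr <- length(rows) - nl
        if (nl == 0L || nr == 0L) next
        pl <- mean(ys[l]); pr <- mean(ys[!l])
        g <- nl * 2 * pl * (1 - pl) + nr * 2 * pr * (1 - pr)
        if (g < best_gini - 1e-12) {
          best_gini <- g
          best <- list(feature = f, threshold = cut, left_rows = rows[l],
                       right_rows = rows[!l])
        }
      }
    }
    if (is.null(best)) return(list(leaf = mean(ys)))
    list(feature = best$feature, threshold = best$threshold,
         left = build(best$left_rows), right = build(best$right_rows))
  }
  build(idx)
}

.tree_predict <- function(tree, x) {
  node <- tree
  while (is.null(node$leaf)) {
    node <- if (x[node$feature] < node$threshold) node$left else node$right
  }
  node$leaf
}

#' Train a random-forest binder classifier
#'
#' Bagged CART trees: each tree is grown on a bootstrap sample with Gini
#' impurity, `ceiling(sqrt(F))` candidate features per split and
#' expansion to purity (minimum leaf size 1). Training is deterministic
#' for a fixed seed. Out-of-bag accuracy is recorded.
#'
#' @param features numeric feature matrix (rows = samples); column names
#'   become the model's feature schema.
#' @param labels 0/1 integer labels (both classes must be present).
#' @param n_trees forest size (default 500, the screening default).
#' @param seed RNG seed.
#' @return object of class `trained_forest`.
#' @export
train_forest <- function(features, labels, n_trees = 500L, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("training labels contain a single class")
  if (min(table(labels)) < 2L)
    stop("need at least two samples per class")
  n <- nrow(features)
  mtry <- ceiling(sqrt(ncol(features)))
  forest <- with_seed(seed, {
    lapply(seq_len(n_trees), function(t) {
      boot <- sample.int(n, n, replace = TRUE)
      list(tree = .grow_tree(features, labels, boot, mtry),
           oob = setdiff(seq_len(n), unique(boot)))
    })
  })
  # out-of-bag accuracy
  votes <- matrix(NA_real_, n, n_trees)
  for (t in seq_len(n_trees)) {
    for (i in forest[[t]]$oob)
      votes[i, t] <- as.numeric(.tree_predict(forest[[t]]$tree,
                                              features[i, ]) >= 0.5)
  }
  oob_pred <- rowMeans(votes, na.rm = TRUE)
  have <- !is.nan(oob_pred)
  oob_acc <- if (any(have))
    mean((oob_pred[have] >= 0.5) == (labels[have] == 1L)) else NA_real_
  structure(list(trees = lapply(forest, `[[`, "tree"),
                 n_trees = n_trees,
                 feature_names = colnames(features),
                 seed = seed, oob_accuracy = oob_acc),
            class = "trained_forest")
}

#' @export
print.trained_forest <- function(x, ...) {
  cat(sprintf("<trained_forest: %d trees, %d features, OOB accuracy %s>\n",
              x$n_trees, length(x$feature_names),
              if (is.na(x$oob_accuracy)) "NA"
              else sprintf("%.2f", x$oob_accuracy)))
  invisible(x)
}

#' Classify a feature vector with a trained forest
#'
#' @param forest a `trained_forest`.
#' @param v named feature vector (names must match the training schema)
#'   or a matrix of such rows.
#' @return binder score(s) in \[0, 1\]: the fraction of trees voting the
#'   positive class.
#' @export
classify <- function(forest, v) {
  if (is.matrix(v)) return(apply(v, 1, function(r) classify(forest, r)))
  if (!is.null(names(v)) && !is.null(forest$feature_names)) {
    if (!all(forest$feature_names %in% names(v)))
      stop("feature names do not match the training schema")
    v <- v[forest$feature_names]
  } else if (length(v) != length(forest$feature_names)) {
    stop("feature vector length does not match the training schema")
  }
  votes <- vapply(forest$trees, function(tr)
    as.numeric(.tree_predict(tr, v) >= 0.5), 0)
  mean(votes)
}

#' Serialize a trained forest to versioned JSON
#' @param forest a `trained_forest`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_forest <- function(forest, path) {
  payload <- list(format = "wasscreen-forest", version = 1L,
                  n_trees = forest$n_trees,
                  feature_names = forest$feature_names,
                  seed = forest$seed, oob_accuracy = forest$oob_accuracy,
                  trees = forest$trees)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a trained forest from JSON
#' @param path path written by [write_forest()].
#' @return a `trained_forest` with identical predictions.
#' @export
read_forest <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(payload$format) || payload$format != "wasscreen-forest")
    stop("not a serialized forest model: ", path)
  fix_tree <- function(node) {
    if (!is.null(node$leaf)) return(list(leaf = as.numeric(node$leaf)))
    list(feature = as.integer(node$feature),
         threshold = as.numeric(node$threshold),
         left = fix_tree(node$left), right = fix_tree(node$right))
  }
  structure(list(trees = lapply(payload$trees, fix_tree),
                 n_trees = as.integer(payload$n_trees),
                 feature_names = unlist(payload$feature_names),
                 seed = payload$seed,
                 oob_accuracy = as.numeric(payload$oob_accuracy)),
            class = "trained_forest")
}

#' Area under the ROC curve (rank statistic)
#' @param scores numeric predictions.
#' @param labels 0/1 truth.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) stop("need both classes for AUC")
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}
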