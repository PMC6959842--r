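#' Fit a binary classification tree on H-bond features
#'
#' Greedy recursive partitioning on binary presence/absence features using
#' the Gini diversity index: at each node the split "feature == 1" minimizing
#' the frame-weighted child impurity over all features is taken (ties broken
#' by lowest feature index).  Growth stops at pure nodes, when no split
#' reduces impurity, or at `max_depth`.  The tree is fitted on all frames
#' (resubstitution): its purpose is to uncover which residue-residue hydrogen
#' bonds distinguish the damage classes, not to generalize, so no held-out
#' validation set is used.
#'
#' Leaf class probabilities are the empirical count ratio: the number of
#' frames of a class reaching the leaf divided by the total number of frames
#' reaching it.
#'
#' @param fm a [feature_matrix()] with class labels.
#' @param max_depth optional cap on tree depth (levels; root = level 1).
#' @return an object of class `"damage_tree"` with fields `root` (nested node
#'   list), `classes`, `features`, `depth`, `n`.
#' @export
fit_tree <- function(fm, max_depth = Inf) {
  stopifnot(inherits(fm, "feature_matrix"))
  X <- fm$data
  if (ncol(X) < 1) stopf("need at least one feature")
  classes <- sort(unique(fm$labels))
  y <- match(fm$labels, classes)
  if (length(classes) < 2)
    warning("single-class input: returning a degenerate one-leaf tree",
            call. = FALSE)
  Y <- matrix(0L, nrow(X), length(classes))
  Y[cbind(seq_along(y), y)] <- 1L

  make_leaf <- function(counts) {
    prob <- counts / sum(counts)
    list(type = "leaf", counts = counts, prob = prob,
         class = classes[which.max(prob)])
  }
  gini <- function(counts, n) 1 - sum((counts / n)^2)

  build <- function(rows, level) {
    counts <- colSums(Y[rows, , drop = FALSE])
    names(counts) <- classes
    n <- length(rows)
    parent_imp <- gini(counts, n)
    # `level` = number of splits already taken on this path
    if (parent_imp <= 0 || level >= max_depth || ncol(X) == 0)
      return(make_leaf(counts))
    # per-feature class counts on the feature == 1 side, via one crossprod
    n1c <- crossprod(X[rows, , drop = FALSE], Y[rows, , drop = FALSE])
    n1 <- rowSums(n1c)
    n0c <- matrix(counts, ncol(X), length(classes), byrow = TRUE) - n1c
    n0 <- n - n1
    g1 <- 1 - rowSums((n1c / pmax(n1, 1))^2)
    g0 <- 1 - rowSums((n0c / pmax(n0, 1))^2)
    w <- (n1 * g1 + n0 * g0) / n
    w[n1 == 0 | n0 == 0] <- Inf          # no actual split
    j <- which.min(w)
    if (!is.finite(w[j]) || w[j] >= parent_imp - 1e-12)
      return(make_leaf(counts))
    on <- rows[X[rows, j] == 1L]
    off <- rows[X[rows, j] == 0L]
    list(type = "split", feature = unname(j),
         counts = counts,
         yes = build(on, level + 1),     # feature present
         no = build(off, level + 1))     # feature absent
  }

  root <- build(seq_len(nrow(X)), 0L)
  structure(list(root = root, classes = classes, features = fm$features,
                 depth = tree_depth(root), n = nrow(X)),
            class = "damage_tree")
}

# depth counts SPLIT levels: a single-leaf tree has depth 0, and a tree
# "pruned to two levels" retains two levels of decision nodes (up to three
# split features), matching how pruning levels are reported for these trees
tree_depth <- function(node) {
  if (node$type == "leaf") 0L
  else 1L + max(tree_depth(node$yes), tree_depth(node$no))
}

#' @export
print.damage_tree <- function(x, ...) {
  cat(sprintf("classification tree: %d levels, %d leaves, %d training frames, classes: %s\n",
              x$depth, n_leaves(x$root), x$n, paste(x$classes, collapse = ", ")))
  invisible(x)
}

n_leaves <- function(node) {
  if (node$type == "leaf") 1L else n_leaves(node$yes) + n_leaves(node$no)
}

#' Per-leaf class probability table
#'
#' One row per leaf: the frame counts per class and the estimated class
#' probabilities, computed as count(class, leaf) / total frames at the leaf.
#'
#' @param tree a fitted [fit_tree()] object.
#' @return data frame with columns `leaf`, `path`, `n`, `class`, one count
#'   column per class and one probability column (`p_<class>`) per class.
#' @export
leaf_probabilities <- function(tree) {
  rows <- list()
  walk <- function(node, path) {
    if (node$type == "leaf") {
      if (sum(node$counts) == 0)
        stopf("undefined probability: leaf with zero frames")
      rows[[length(rows) + 1]] <<- data.frame(
        path = if (nzchar(path)) path else "(root)",
        n = sum(node$counts), class = node$class,
        t(node$counts), t(stats::setNames(node$prob, paste0("p_", names(node$counts)))),
        check.names = FALSE)
    } else {
      f <- tree$features[node$feature]
      walk(node$yes, paste0(path, if (nzchar(path)) " & ", f))
      walk(node$no, paste0(path, if (nzchar(path)) " & ", "!", f))
    }
  }
  walk(tree$root, "")
  out <- do.call(rbind, rows)
  out <- cbind(leaf = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Prune a tree by removing bottom levels
#'
#' Collapses every split node deeper than `depth - levels_removed` split
#' levels into a leaf carrying the merged class counts of its subtree; the
#' collapsed leaf predicts the subtree majority class, the collapse that
#' misclassifies the fewest training frames.  Pruning by `depth` levels
#' leaves the root leaf predicting the global majority class.
#'
#' @param tree a fitted [fit_tree()] object.
#' @param levels_removed number of maximum-depth split levels to remove
#'   (`0 <= levels_removed <= depth`).
#' @return the pruned `damage_tree`.
#' @export
prune_tree <- function(tree, levels_removed) {
  levels_removed <- as.integer(levels_removed)
  if (levels_removed < 0 || levels_removed > tree$depth)
    stopf("levels_removed must lie in [0, %d]", tree$depth)
  if (levels_removed == 0) return(tree)
  keep_depth <- tree$depth - levels_removed
  clip <- function(node, level) {
    if (node$type == "leaf") return(node)
    if (level >= keep_depth) {
      counts <- node$counts
      prob <- counts / sum(counts)
      return(list(type = "leaf", counts = counts, prob = prob,
                  class = names(counts)[which.max(prob)]))
    }
    node$yes <- clip(node$yes, level + 1)
    node$no <- clip(node$no, level + 1)
    node
  }
  tree$root <- clip(tree$root, 0L)
  tree$depth <- tree_depth(tree$root)
  tree
}

# route frames down the tree, returning the leaf node index for each row
route <- function(tree, X) {
  leaf_of <- integer(nrow(X))
  counter <- 0L
  walk <- function(node, rows) {
    if (node$type == "leaf") {
      counter <<- counter + 1L
      if (length(rows)) leaf_of[rows] <<- counter
    } else {
      on <- if (length(rows)) X[rows, node$feature] == 1L else logical(0)
      walk(node$yes, rows[on])
      walk(node$no, rows[!on])
    }
  }
  walk(tree$root, seq_len(nrow(X)))
  leaf_of
}

collect_leaves <- function(node, acc = list()) {
  if (node$type == "leaf") return(c(acc, list(node)))
  acc <- collect_leaves(node$yes, acc)
  collect_leaves(node$no, acc)
}

#' Predict damage classes for frames
#'
#' Follows the fitted splits to a leaf and returns that leaf's predicted
#' class and estimated class probabilities.
#'
#' @param object a `damage_tree`.
#' @param fm a [feature_matrix()] (or bare 0/1 matrix / vector) whose columns
#'   match the tree's feature schema.
#' @param ... unused.
#' @return list with `class` (character vector) and `prob`
#'   (frames x classes matrix).
#' @export
predict.damage_tree <- function(object, fm, ...) {
  X <- if (inherits(fm, "feature_matrix")) fm$data
       else if (is.matrix(fm)) fm
       else matrix(as.integer(fm), nrow = 1)
  if (ncol(X) != length(object$features))
    stopf("schema error: %d features supplied, tree expects %d",
          ncol(X), length(object$features))
  if (!is.null(colnames(X)) && !identical(colnames(X), object$features))
    stopf("schema error: feature descriptors do not match the tree's")
  leaves <- collect_leaves(object$root)
  idx <- route(object, X)
  prob <- do.call(rbind, lapply(leaves, `[[`, "prob"))[idx, , drop = FALSE]
  colnames(prob) <- object$classes
  list(class = vapply(leaves, `[[`, "", "class")[idx], prob = prob)
}

#' Resubstitution loss of a tree
#'
#' Fraction of frames whose predicted class differs from their label.
#'
#' @param tree a `damage_tree`.
#' @param fm a [feature_matrix()] with labels.
#' @return misclassified fraction in \[0, 1\].
#' @export
tree_loss <- function(tree, fm) {
  mean(predict(tree, fm)$class != fm$labels)
}

#' Loss as a function of pruning level
#'
#' @param tree a fitted `damage_tree`.
#' @param fm the [feature_matrix()] to evaluate on (typically the training
#'   data, mirroring resubstitution pruning curves).
#' @return data frame with columns `levels_removed`, `depth`, `loss`; row 0
#'   is the full tree, the last row the root-leaf majority baseline.
#' @export
prune_curve <- function(tree, fm) {
  lv <- 0:tree$depth
  do.call(rbind, lapply(lv, function(k) {
    pt <- prune_tree(tree, k)
    data.frame(levels_removed = k, depth = pt$depth, loss = tree_loss(pt, fm))
  }))
}

#' Export / import a tree as JSON
#'
#' The JSON document carries the full node structure (split feature
#' descriptors, per-leaf class counts and probabilities) and round-trips
#' losslessly: `export_tree(import_tree(export_tree(t)))` is byte-identical.
#'
#' @param tree a `damage_tree`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
export_tree <- function(tree, path = NULL) {
  ser <- function(node) {
    if (node$type == "leaf") {
      list(type = "leaf", counts = as.list(node$counts),
           prob = as.list(node$prob), class = node$class)
    } else {
      list(type = "split", feature = tree$features[node$feature],
           counts = as.list(node$counts),
           yes = ser(node$yes), no = ser(node$no))
    }
  }
  doc <- list(classes = tree$classes, features = tree$features,
              depth = tree$depth, n = tree$n, root = ser(tree$root))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(as.character(js))) }
  as.character(js)
}

#' @rdname export_tree
#' @param json JSON string or file path produced by `export_tree`.
#' @export
import_tree <- function(json) {
  if (length(json) == 1 && file.exists(json)) json <- paste(readLines(json), collapse = "\n")
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  classes <- unlist(doc$classes)
  features <- unlist(doc$features)
  de <- function(nd) {
    if (nd$type == "leaf") {
      counts <- unlist(nd$counts)
      list(type = "leaf", counts = counts, prob = unlist(nd$prob),
           class = nd$class)
    } else {
      list(type = "split", feature = match(nd$feature, features),
           counts = unlist(nd$counts),
           yes = de(nd$yes), no = de(nd$no))
    }
  }
  root <- de(doc$root)
  structure(list(root = root, classes = classes, features = features,
                 depth = doc$depth, n = doc$n),
            class = "damage_tree")
}
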