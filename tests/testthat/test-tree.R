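# classification-tree fitting, leaf probabilities, pruning, loss, round trips

fm_from <- function(X, y) feature_matrix(X, sprintf("b%02d", seq_len(ncol(X))), y)

test_that("a perfect single separator is found and gives zero loss", {
  X <- cbind(c(1, 1, 0, 0), c(0, 1, 0, 1))
  fm <- fm_from(X, c("A", "A", "B", "B"))
  tr <- fit_tree(fm)
  expect_equal(tr$root$feature, 1)
  expect_equal(tree_loss(tr, fm), 0)
  expect_equal(tr$depth, 1)
})

test_that("constant features yield a single majority leaf", {
  fm <- fm_from(matrix(1, 6, 3), c("A", "A", "A", "A", "B", "C"))
  tr <- fit_tree(fm)
  expect_equal(tr$depth, 0)
  expect_equal(tr$root$type, "leaf")
  expect_equal(tr$root$class, "A")
  expect_equal(tree_loss(tr, fm), 2 / 6)
  expect_warning(fit_tree(fm_from(matrix(0:1, 4, 2), rep("A", 4))), "single-class")
})

test_that("the root split matches exhaustive Gini enumeration (and rpart)", {
  withr::with_seed(17, {
    for (i in 1:25) {
      n <- sample(20:200, 1)
      p <- sample(2:8, 1)
      X <- matrix(rbinom(n * p, 1, stats::runif(p, 0.2, 0.8)[rep(1:p, each = n)]), n, p)
      y <- sample(c("A", "B", "C"), n, replace = TRUE)
      if (length(unique(y)) < 2) next
      fm <- fm_from(X, y)
      tr <- fit_tree(fm)
      oracle <- best_gini_split(X, y)
      if (tr$root$type == "leaf") {
        # no impurity-reducing split existed
        base <- 1 - sum((table(y) / n)^2)
        expect_gte(oracle$impurity + 1e-12, base)
      } else {
        expect_equal(tr$root$feature, oracle$feature)
      }
    }
    # independent library cross-check on one dataset with a strong signal
    X <- cbind(rbinom(300, 1, 0.5), rbinom(300, 1, 0.5))
    y <- ifelse(X[, 2] == 1, "A", ifelse(rbinom(300, 1, 0.8) == 1, "B", "A"))
    tr <- fit_tree(fm_from(X, y))
    rp <- rpart::rpart(y ~ ., data = data.frame(X, y = factor(y)),
                       method = "class",
                       control = rpart::rpart.control(maxdepth = 1, cp = 0,
                                                      minsplit = 2, minbucket = 1))
    expect_equal(paste0("X", tr$root$feature),
                 as.character(rp$frame$var[1]))
  })
})

test_that("leaf probabilities are exactly the count ratios", {
  # single constant feature forces a root leaf with known counts (71, 3, 1)
  y <- rep(c("Cis", "FdU", "Carbo"), c(71, 3, 1))
  fm <- fm_from(matrix(0L, 75, 1), y)
  tr <- suppressWarnings(fit_tree(fm))
  lp <- leaf_probabilities(tr)
  expect_identical(lp$p_Cis, 71 / 75)
  expect_identical(lp$p_FdU, 3 / 75)
  expect_identical(lp$p_Carbo, 1 / 75)
  expect_equal(lp$p_Cis, 0.9467, tolerance = 1e-4)
  # every leaf of a real tree: probabilities == counts / total, summing to 1
  fm2 <- gen_hbond_matrix(hbond_plant_spec(n_frames = 300, n_features = 10, seed = 5))
  tr2 <- fit_tree(fm2)
  lp2 <- leaf_probabilities(tr2)
  cnt <- as.matrix(lp2[, tr2$classes])
  prb <- as.matrix(lp2[, paste0("p_", tr2$classes)])
  expect_identical(unname(prb), unname(cnt / rowSums(cnt)))
  expect_equal(unname(rowSums(prb)), rep(1, nrow(prb)))
  # leaf counts over all leaves sum to the training frame count
  expect_equal(sum(cnt), tr2$n)
})

test_that("pruning collapses bottom split levels into merged-count leaves", {
  # hand-constructed separable data -> known depth-2 structure
  X <- cbind(c(1, 1, 1, 1, 0, 0, 0, 0), c(1, 1, 0, 0, 1, 1, 0, 0))
  y <- c("A", "A", "B", "B", "C", "C", "C", "B")
  fm <- fm_from(X, y)
  tr <- fit_tree(fm)
  expect_identical(prune_tree(tr, 0), tr)
  p1 <- prune_tree(tr, tr$depth - 1)
  expect_equal(p1$depth, 1)
  # children of the root are leaves whose counts are the subtree sums
  expect_equal(sum(p1$root$yes$counts), 4)
  expect_equal(sum(p1$root$no$counts), 4)
  expect_equal(unname(p1$root$yes$counts + p1$root$no$counts),
               unname(tr$root$counts))
  # full prune -> root leaf predicting the global majority
  p0 <- prune_tree(tr, tr$depth)
  expect_equal(p0$depth, 0)
  expect_equal(p0$root$class, names(which.max(table(y))))
  expect_equal(tree_loss(p0, fm), 1 - max(table(y)) / length(y))
  expect_error(prune_tree(tr, tr$depth + 1), "levels_removed")
  expect_error(prune_tree(tr, -1), "levels_removed")
})

test_that("prune-curve loss is non-decreasing with majority baseline at the end", {
  for (seed in 1:5) {
    fm <- gen_hbond_matrix(hbond_plant_spec(n_frames = 400, n_features = 20,
                                            seed = seed))
    tr <- fit_tree(fm)
    curve <- prune_curve(tr, fm)
    expect_equal(nrow(curve), tr$depth + 1)
    expect_equal(curve$loss[1], tree_loss(tr, fm))
    expect_true(all(diff(curve$loss) >= -1e-12))
    expect_equal(curve$loss[nrow(curve)],
                 1 - max(table(fm$labels)) / length(fm$labels))
  }
})

test_that("weighted child impurity never exceeds the parent at a chosen split", {
  fm <- gen_hbond_matrix(hbond_plant_spec(n_frames = 500, n_features = 15, seed = 9))
  tr <- fit_tree(fm)
  gini <- function(cnt) 1 - sum((cnt / sum(cnt))^2)
  walk <- function(node) {
    if (node$type == "leaf") return(invisible())
    n <- sum(node$counts)
    child <- (sum(node$yes$counts) * gini(node$yes$counts) +
              sum(node$no$counts) * gini(node$no$counts)) / n
    expect_lte(child, gini(node$counts) + 1e-12)
    walk(node$yes); walk(node$no)
  }
  walk(tr$root)
})

test_that("prediction follows splits and validates its schema", {
  fm <- gen_hbond_matrix(hbond_plant_spec(n_frames = 200, n_features = 8,
                                          planted = 1:2, seed = 3))
  tr <- fit_tree(fm)
  pr <- predict(tr, fm)
  expect_equal(length(pr$class), nrow(fm$data))
  expect_equal(unname(rowSums(pr$prob)), rep(1, nrow(fm$data)))
  # resubstitution consistency: predictions reproduce the stated loss
  expect_equal(mean(pr$class != fm$labels), tree_loss(tr, fm))
  expect_error(predict(tr, matrix(0L, 1, 3)), "schema")
})

test_that("a frame with both planted bonds present is labeled their class", {
  # two-level tree on strongly planted data: presence of both signature bonds
  # routes to the leaf dominated by the class whose bonds they are
  fm <- gen_hbond_matrix(hbond_plant_spec(n_frames = 2000, seed = 21))
  tr <- prune_tree(fit_tree(fm), fit_tree(fm)$depth - 2)
  splits <- tree_splits(tr)
  expect_setequal(splits, c("SYN:HB001", "SYN:HB002"))
  v <- integer(length(tr$features))
  v[1] <- 1L  # planted bond of class Carbo
  expect_equal(predict(tr, v)$class, "Carbo")
})

test_that("JSON export round-trips byte-identically", {
  fm <- gen_hbond_matrix(hbond_plant_spec(n_frames = 150, n_features = 6, seed = 4))
  tr <- fit_tree(fm)
  js <- export_tree(tr)
  tr2 <- import_tree(js)
  expect_identical(export_tree(tr2), js)
  expect_equal(predict(tr2, fm)$class, predict(tr, fm)$class)
  path <- tempfile(fileext = ".json")
  export_tree(tr, path)
  expect_identical(export_tree(import_tree(path)), js)
})
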