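#' Extract per-frame coordinate feature vectors
#'
#' Row f of the returned matrix is the concatenated (x, y, z) coordinates of
#' the selected heavy atoms in frame f -- the input representation for
#' conformational clustering.  Distance-based residue selections ("any atom
#' within `within` Angstrom of the target") are evaluated on a single
#' reference frame so the feature schema is fixed across frames.
#'
#' @param traj a [trajectory()].
#' @param selection atom selection passed to [select_atoms()], or the string
#'   `"near"` to use the distance rule below.
#' @param near target selection for the distance rule (e.g. `"nucleic"`):
#'   residues with any atom within `within` Angstrom of any target atom (on
#'   `ref_frame`) contribute their heavy atoms.
#' @param within distance cutoff, Angstrom.
#' @param ref_frame frame on which distance-based selections are evaluated.
#' @param heavy_only keep heavy atoms only (default `TRUE`).
#' @return matrix `frames x (3 * n_selected)` of class `"frame_features"`,
#'   with attributes `atoms` (indices), `labels` (per-frame system labels) and
#'   column names `<segid:resname+resno:name>.<axis>`.
#' @export
extract_features <- function(traj, selection = "heavy", near = NULL,
                             within = 10, ref_frame = 1, heavy_only = TRUE) {
  top <- traj$topology
  if (!is.null(near)) {
    target <- select_atoms(top, near)
    ref <- traj$coords[ref_frame, , , drop = TRUE]
    d2 <- outer(rowSums(ref^2), rowSums(ref[target, , drop = FALSE]^2), "+") -
      2 * tcrossprod(ref, ref[target, , drop = FALSE])
    close_atom <- sqrt(pmax(apply(d2, 1, min), 0)) <= within
    rk <- residue_key(top)
    idx <- which(rk %in% unique(rk[close_atom]))
  } else {
    idx <- select_atoms(top, selection)
  }
  if (heavy_only) idx <- idx[top$heavy[idx]]
  if (length(idx) == 0) stopf("empty selection for feature extraction")
  X <- coords_to_xyz(traj$coords[, idx, , drop = FALSE])
  colnames(X) <- paste0(rep(atom_key(top)[idx], each = 3), ".", c("x", "y", "z"))
  structure(X, atoms = idx, labels = traj$label, class = c("frame_features", "matrix"))
}

minkowski_center <- function(x, p) {
  if (abs(p - 2) < 1e-12) return(mean(x))
  if (abs(p - 1) < 1e-12) return(stats::median(x))
  stats::optimize(function(c) sum(abs(x - c)^p), range(x))$minimum
}

# weighted Minkowski distance^p of rows of X to a center, given weights w
wmink <- function(X, center, w, p) {
  abs(sweep(X, 2, center))^p %*% (w^p)
}

# per-feature Minkowski centers of the rows of X (colMeans fast path at p = 2)
mink_centers <- function(X, p) {
  if (abs(p - 2) < 1e-12) colMeans(X)
  else apply(X, 2, minkowski_center, p = p)
}

#' Intelligent Minkowski-weighted K-means
#'
#' The first stage of Amorim-Hennig clustering.  Anomalous-pattern
#' initialization repeatedly extracts the point farthest from the grand
#' center, grows a tentative cluster around it by weighted-distance
#' assignment until stable, and removes it; tentative clusters of size
#' `<= theta` are discarded and the surviving count fixes K.  The main loop
#' then alternates (i) assignment minimizing
#' `sum_v w_kv^p |x_v - c_kv|^p`, (ii) per-feature Minkowski-center centroid
#' updates (the mean when `p = 2`), and (iii) the closed-form weight update
#' `w_kv = 1 / sum_u (D_kv / D_ku)^{1/(p-1)}` with `D_kv` the within-cluster
#' dispersion of feature v, to a fixed point.  The objective is non-increasing
#' at every iteration and is recorded in `$objective_trace`.
#'
#' @param X numeric matrix (frames x features), e.g. [extract_features()].
#' @param p Minkowski exponent, > 1 (default 2, Euclidean).
#' @param theta anomalous-cluster discard threshold: tentative clusters with
#'   `<= theta` members are dropped (default 1, discarding singletons).
#' @param max_iter iteration cap for the main loop.
#' @param eps_frac zero-dispersion guard: `D_kv = 0` is replaced by
#'   `eps_frac * mean(D)` before the weight update.
#' @param standardize centre each feature and scale it by its range before
#'   clustering (default `TRUE`, the source algorithm's preprocessing: range
#'   scaling deflates unimodal noise features relative to cluster-structured
#'   ones, unlike variance scaling).  The transform is stored in the model
#'   (`$center`, `$scale`) and reapplied by [rescale_and_kmeans()]; centroids
#'   are reported in the standardized space.
#' @return an object of class `"cluster_model"`: `K`, `p`, `weights`
#'   (K x features, rows summing to 1), `centroids` (K x features), `labels`
#'   (1-based), `objective`, `objective_trace`.
#' @references de Amorim & Mirkin (2012) Pattern Recognition 45:1061;
#'   Amorim & Hennig (2015) Information Sciences 324:126.
#' @export
imwk_fit <- function(X, p = 2, theta = 1, max_iter = 100, eps_frac = 1e-12,
                     standardize = TRUE) {
  X <- unclass(as.matrix(X))
  n <- nrow(X); V <- ncol(X)
  if (n < 2 || nrow(unique(X)) < 2)
    stopf("degenerate input: need at least two distinct rows")
  if (p <= 1) stopf("Minkowski exponent must be > 1")
  if (standardize) {
    ctr <- colMeans(X)
    rng <- apply(X, 2, function(v) diff(range(v)))
    rng[rng == 0] <- 1
  } else {
    ctr <- rep(0, V); rng <- rep(1, V)
  }
  X <- sweep(sweep(X, 2, ctr), 2, rng, "/")

  grand <- mink_centers(X, p)
  w0 <- rep(1 / V, V)
  remaining <- seq_len(n)
  seeds <- list()
  while (length(remaining) > 0) {
    Xr <- X[remaining, , drop = FALSE]
    d_grand <- wmink(Xr, grand, w0, p)
    ct <- Xr[which.max(d_grand), ]
    w <- w0
    members <- NULL
    # weighted reallocation can cycle on ties; cap the refinement loop
    for (ap_it in seq_len(50)) {
      d_t <- wmink(Xr, ct, w, p)
      d_g <- wmink(Xr, grand, w, p)
      new_members <- which(d_t < d_g)
      if (length(new_members) == 0) new_members <- which.max(d_grand)
      if (identical(new_members, members)) break
      members <- new_members
      ct <- mink_centers(Xr[members, , drop = FALSE], p)
      D <- colSums(abs(sweep(Xr[members, , drop = FALSE], 2, ct))^p)
      w <- dispersion_weights(matrix(D, 1), eps_frac, p)[1, ]
    }
    seeds[[length(seeds) + 1]] <- list(center = ct, size = length(members), w = w)
    remaining <- remaining[-members]
  }
  keep <- vapply(seeds, function(s) s$size > theta, TRUE)
  if (!any(keep)) keep[which.max(vapply(seeds, `[[`, 0, "size"))] <- TRUE
  centroids <- do.call(rbind, lapply(seeds[keep], `[[`, "center"))
  K <- nrow(centroids)
  # surviving anomalous clusters seed the main loop's centroids AND weights
  W <- do.call(rbind, lapply(seeds[keep], `[[`, "w"))

  obj_trace <- numeric(0)
  labels <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    D_all <- vapply(seq_len(K), function(k) wmink(X, centroids[k, ], W[k, ], p),
                    numeric(n))
    new_labels <- max.col(-D_all, ties.method = "first")
    occupied <- sort(unique(new_labels))
    if (length(occupied) < K) {           # drop emptied clusters
      centroids <- centroids[occupied, , drop = FALSE]
      W <- W[occupied, , drop = FALSE]
      new_labels <- match(new_labels, occupied)
      K <- length(occupied)
    }
    for (k in seq_len(K))
      centroids[k, ] <- mink_centers(X[new_labels == k, , drop = FALSE], p)
    Dmat <- t(vapply(seq_len(K), function(k)
      colSums(abs(sweep(X[new_labels == k, , drop = FALSE], 2, centroids[k, ]))^p),
      numeric(V)))
    W <- dispersion_weights(Dmat, eps_frac, p)
    obj <- sum(W^p * Dmat)
    obj_trace <- c(obj_trace, obj)
    converged <- identical(new_labels, labels)
    labels <- new_labels
    if (converged) break
  }
  structure(list(K = K, p = p, weights = W, centroids = centroids,
                 labels = labels, objective = obj_trace[length(obj_trace)],
                 objective_trace = obj_trace, center = ctr, scale = rng,
                 stage = "imwk"),
            class = "cluster_model")
}

# w_kv = 1 / sum_u (D_kv / D_ku)^(1/(p-1)), with a zero-dispersion guard
dispersion_weights <- function(Dmat, eps_frac = 1e-12, p = 2) {
  md <- mean(Dmat)
  if (md == 0) return(matrix(1 / ncol(Dmat), nrow(Dmat), ncol(Dmat)))
  Dmat[Dmat == 0] <- eps_frac * md
  t(apply(Dmat, 1, function(D) {
    w <- 1 / vapply(D, function(dv) sum((dv / D)^(1 / (p - 1))), 0)
    w / sum(w)
  }))
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model (%s): K = %d, p = %g, objective = %.6g, sizes: %s\n",
              x$stage, x$K, x$p, x$objective,
              paste(tabulate(x$labels, x$K), collapse = ", ")))
  invisible(x)
}

#' Explicit rescaling followed by K-means
#'
#' The second stage of Amorim-Hennig clustering: the per-cluster feature
#' weights learned by [imwk_fit()] are aggregated (averaged over clusters) to
#' a single per-feature weight vector, the features are multiplied by those
#' weights, and a standard K-means (Lloyd) with K fixed and centroids seeded
#' from the rescaled iMWK centroids is run to convergence in the rescaled
#' space.
#'
#' @param X the feature matrix used for [imwk_fit()].
#' @param model the intermediate `cluster_model` from [imwk_fit()].
#' @param aggregate how to collapse per-cluster weights to one vector:
#'   `"mean"` (default) or `"max"`.
#' @return a `cluster_model` (stage `"rescaled_kmeans"`) with labels and
#'   centroids from the rescaled K-means run; `weights` holds the aggregated
#'   per-feature weight vector replicated per cluster.
#' @export
rescale_and_kmeans <- function(X, model, aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  X <- unclass(as.matrix(X))
  X <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  w <- switch(aggregate, mean = colMeans(model$weights),
              max = apply(model$weights, 2, max))
  Xs <- sweep(X, 2, w, "*")
  centers <- sweep(model$centroids, 2, w, "*")
  km <- suppressWarnings(stats::kmeans(Xs, centers = centers,
                                       iter.max = 100, algorithm = "Lloyd"))
  structure(list(K = nrow(km$centers), p = model$p,
                 weights = matrix(w, nrow(km$centers), length(w), byrow = TRUE),
                 centroids = km$centers, labels = km$cluster,
                 objective = km$tot.withinss,
                 objective_trace = model$objective_trace,
                 center = model$center, scale = model$scale,
                 stage = "rescaled_kmeans"),
            class = "cluster_model")
}

#' Amorim-Hennig clustering
#'
#' Convenience wrapper: [imwk_fit()] followed by [rescale_and_kmeans()].
#'
#' @inheritParams imwk_fit
#' @inheritParams rescale_and_kmeans
#' @return a `cluster_model`.
#' @export
amorim_hennig <- function(X, p = 2, theta = 1, max_iter = 100,
                          aggregate = "mean") {
  rescale_and_kmeans(X, imwk_fit(X, p = p, theta = theta, max_iter = max_iter),
                     aggregate = aggregate)
}

#' Per-system cluster occupancy table
#'
#' Percentage of each system's frames falling in each cluster; every row
#' sums to 100.
#'
#' @param labels cluster labels (integer).
#' @param systems per-frame system labels, same length.
#' @return matrix systems x clusters of percentages.
#' @export
occupancy_table <- function(labels, systems) {
  if (length(labels) != length(systems))
    stopf("labels and systems must have equal length")
  if (length(labels) == 0) stopf("empty label vector")
  tab <- table(systems, labels)
  out <- 100 * sweep(unclass(tab), 1, rowSums(tab), "/")
  dimnames(out) <- list(system = rownames(tab),
                        cluster = paste0("cluster_", colnames(tab)))
  out
}

#' Representative frame of a cluster
#'
#' The member frame with the smallest RMSD from the coordinate-wise mean
#' structure of the cluster; ties are broken by lowest frame index.
#'
#' @param X frame-feature matrix (frames x 3N coordinates).
#' @param labels cluster labels.
#' @param cluster cluster id to summarize.
#' @return frame index (into the rows of `X`).
#' @export
representative_frame <- function(X, labels, cluster) {
  members <- which(labels == cluster)
  if (length(members) == 0) stopf("cluster %s is empty", cluster)
  Xm <- unclass(as.matrix(X))[members, , drop = FALSE]
  mu <- colMeans(Xm)
  rmsd <- sqrt(rowSums(sweep(Xm, 2, mu)^2) / (ncol(Xm) / 3))
  members[which.min(rmsd)]
}
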