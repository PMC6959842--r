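#' Root mean square fluctuation per atom
#'
#' `RMSF_i = sqrt( (1/N) * sum_j |r_i(t_j) - rbar_i|^2 )` with `rbar_i` the
#' time-average position of atom i.  The trajectory should be superposed
#' first so fluctuations measure internal motion, not global drift.
#'
#' @param traj a superposed [trajectory()].
#' @param subset atom selection (default `"calpha"`, the backbone alpha
#'   carbons whose flexibility profiles are usually reported).
#' @return data frame with columns `atom`, `residue`, `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, subset = "calpha") {
  if (n_frames(traj) < 2) stopf("RMSF needs at least two frames")
  idx <- select_atoms(traj$topology, subset)
  X <- coords_to_xyz(traj$coords[, idx, , drop = FALSE])
  mu <- colMeans(X)
  msf3 <- colMeans(sweep(X, 2, mu)^2)                   # per coordinate
  vals <- sqrt(colSums(matrix(msf3, nrow = 3)))         # per atom
  data.frame(atom = idx, residue = residue_key(traj$topology)[idx], rmsf = vals)
}

#' Dynamic cross-correlation matrix
#'
#' Pearson normalized covariance of atomic displacement vectors:
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)` with `dr` the
#' displacement from the time-average position.  Symmetric, unit diagonal,
#' entries in \[-1, 1\]; +1 marks perfectly correlated motion, -1 perfectly
#' anti-correlated.
#'
#' @param traj a superposed [trajectory()].
#' @param subset atom selection (default alpha carbons).
#' @param zero_variance `"error"` (default) or `"na"`: handling of atoms
#'   that never move.
#' @return `n x n` correlation matrix with residue keys as dimnames.
#' @export
dccm <- function(traj, subset = "calpha", zero_variance = c("error", "na")) {
  zero_variance <- match.arg(zero_variance)
  if (n_frames(traj) < 2) stopf("DCCM needs at least two frames")
  idx <- select_atoms(traj$topology, subset)
  nf <- n_frames(traj)
  num <- 0
  comp <- list()
  for (ax in 1:3) {
    A <- traj$coords[, idx, ax, drop = TRUE]
    if (length(idx) == 1) A <- matrix(A, ncol = 1)
    A <- sweep(A, 2, colMeans(A))
    comp[[ax]] <- A
    num <- num + crossprod(A) / nf
  }
  v <- diag(num)
  if (any(v == 0)) {
    if (zero_variance == "error") stopf("zero-variance atom in DCCM subset")
    v[v == 0] <- NA_real_
  }
  C <- num / sqrt(outer(v, v))
  C <- pmin(pmax(C, -1), 1)
  dimnames(C) <- rep(list(residue_key(traj$topology)[idx]), 2)
  C
}

#' Principal component analysis of coordinate fluctuations
#'
#' Eigendecomposition of the `3N x 3N` covariance matrix of the selected
#' atoms' coordinates (all frames must be superposed to one common reference
#' so that a shared, meaningful basis results).  Components are sorted by
#' eigenvalue; the sum of all eigenvalues equals the total coordinate
#' variance.
#'
#' @param X a `frames x 3N` coordinate matrix ([extract_features()]), or a
#'   [trajectory()] combined with `subset`.
#' @param subset atom selection when `X` is a trajectory.
#' @return an object of class `"pca_basis"`: `mean` (3N), `rotation`
#'   (3N x m orthonormal columns), `eigenvalues` (descending),
#'   `var_explained` (fractions summing to 1).
#' @export
pca_basis <- function(X, subset = "calpha") {
  if (inherits(X, "trajectory")) X <- extract_features(X, subset, heavy_only = FALSE)
  X <- unclass(as.matrix(X))
  if (nrow(X) < 2) stopf("PCA needs at least two frames")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(mean = pc$center, rotation = pc$rotation, eigenvalues = ev,
                 var_explained = ev / sum(ev)),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf("pca_basis: %d coordinates, %d components; PC1+PC2 explain %.1f%% of variance\n",
              nrow(x$rotation), ncol(x$rotation),
              100 * sum(x$var_explained[1:min(2, length(x$var_explained))])))
  invisible(x)
}

#' Project coordinates onto a PCA basis
#'
#' @param basis a [pca_basis()].
#' @param X `frames x 3N` coordinate matrix (or a trajectory plus `subset`)
#'   over the same atoms the basis was built from.
#' @param n_components number of components to keep.
#' @param subset atom selection when `X` is a trajectory.
#' @return `frames x n_components` score matrix.
#' @export
pca_project <- function(basis, X, n_components = 2, subset = "calpha") {
  if (inherits(X, "trajectory")) X <- extract_features(X, subset, heavy_only = FALSE)
  X <- unclass(as.matrix(X))
  if (ncol(X) != length(basis$mean))
    stopf("atom mismatch: %d coordinates supplied, basis has %d",
          ncol(X), length(basis$mean))
  sweep(X, 2, basis$mean) %*% basis$rotation[, seq_len(n_components), drop = FALSE]
}

.kB_kcal <- 0.0019872  # Boltzmann constant, kcal / (mol K)

#' Free-energy landscape over two principal components
#'
#' Projects frames onto PC1/PC2, bins the projections in a 2D histogram and
#' converts populations to free energies with `dG = -kT ln(P / P0)`, where
#' `P0` is the population of the most-populated bin (whose `dG` is therefore
#' exactly 0).  Unvisited bins are unbounded and reported as `NA` (masked),
#' never as a large finite number.
#'
#' @param scores `frames x >=2` projection matrix from [pca_project()], or a
#'   trajectory plus `basis`.
#' @param basis needed when `scores` is a trajectory.
#' @param bins number of bins per axis (default 100).
#' @param temperature temperature in Kelvin (default 300).
#' @param subset atom selection when `scores` is a trajectory.
#' @param edges optional list(x, y) of bin edges to reuse a common grid.
#' @return an object of class `"fes"`: `dG` (bins x bins, kcal/mol, `NA` for
#'   empty bins), `counts`, `xedges`, `yedges`, `temperature`, `kT`.
#' @export
project_fes <- function(scores, basis = NULL, bins = 100, temperature = 300,
                        subset = "calpha", edges = NULL) {
  if (inherits(scores, "trajectory")) {
    if (is.null(basis)) stopf("a pca_basis is required to project a trajectory")
    scores <- pca_project(basis, scores, 2, subset)
  }
  scores <- as.matrix(scores)
  if (nrow(scores) < 1) stopf("empty trajectory")
  if (ncol(scores) < 2) stopf("need at least two components")
  if (bins < 2) stopf("bins must be >= 2")
  xe <- edges$x %||% seq(min(scores[, 1]), max(scores[, 1]), length.out = bins + 1)
  ye <- edges$y %||% seq(min(scores[, 2]), max(scores[, 2]), length.out = bins + 1)
  bx <- findInterval(scores[, 1], xe, rightmost.closed = TRUE, all.inside = TRUE)
  by <- findInterval(scores[, 2], ye, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, length(xe) - 1, length(ye) - 1)
  for (i in seq_along(bx)) counts[bx[i], by[i]] <- counts[bx[i], by[i]] + 1L
  kT <- .kB_kcal * temperature
  P0 <- max(counts)
  dG <- -kT * log(counts / P0) + 0   # + 0 normalizes IEEE negative zero
  dG[counts == 0] <- NA_real_
  structure(list(dG = dG, counts = counts, xedges = xe, yedges = ye,
                 temperature = temperature, kT = kT),
            class = "fes")
}

#' @export
print.fes <- function(x, ...) {
  cat(sprintf("free-energy landscape: %d x %d bins, T = %g K, max finite dG = %.3f kcal/mol, %d empty bins\n",
              nrow(x$dG), ncol(x$dG), x$temperature,
              max(x$dG, na.rm = TRUE), sum(is.na(x$dG))))
  invisible(x)
}

#' Mark a reference structure on a landscape
#'
#' Projects a reference structure (e.g. the crystal structure) onto the
#' first two components of a basis, giving the (PC1, PC2) coordinates at
#' which to mark it on a free-energy landscape.
#'
#' @param basis a [pca_basis()].
#' @param reference coordinates of the reference over the basis atoms:
#'   a length-3N vector, an `atoms x 3` matrix, or a 1-frame trajectory.
#' @param subset atom selection when `reference` is a trajectory.
#' @return numeric length-2 vector `(PC1, PC2)`.
#' @export
mark_reference <- function(basis, reference, subset = "calpha") {
  if (inherits(reference, "trajectory"))
    reference <- extract_features(reference, subset, heavy_only = FALSE)[1, ]
  if (is.matrix(reference) && ncol(reference) == 3)
    reference <- as.vector(t(reference))
  reference <- as.numeric(reference)
  if (length(reference) != length(basis$mean))
    stopf("atom mismatch: reference has %d coordinates, basis has %d",
          length(reference), length(basis$mean))
  drop((reference - basis$mean) %*% basis$rotation[, 1:2, drop = FALSE])
}

#' Write a free-energy landscape as CSV
#'
#' Long-format grid: bin centers on both axes, population and `dG` (empty
#' bins have an empty `dG` field).
#'
#' @param fes a [project_fes()] result.
#' @param path output CSV path.
#' @export
write_fes <- function(fes, path) {
  xc <- (head(fes$xedges, -1) + tail(fes$xedges, -1)) / 2
  yc <- (head(fes$yedges, -1) + tail(fes$yedges, -1)) / 2
  df <- expand.grid(pc1 = xc, pc2 = yc)
  df$count <- as.vector(fes$counts)
  df$dG_kcal_mol <- as.vector(fes$dG)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
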