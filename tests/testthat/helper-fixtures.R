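# shared fixture builders -- everything is generated in code at test time

# n CA atoms, one residue each
ca_topology <- function(n, segid = "A") {
  topology(rep("CA", n), "GLY", seq_len(n), segid, element = rep("C", n))
}

# trajectory from a list of atoms x 3 frame matrices
traj_from_frames <- function(frames, top = NULL, label = "A") {
  na <- nrow(frames[[1]])
  if (is.null(top)) top <- ca_topology(na)
  co <- array(0, dim = c(length(frames), na, 3))
  for (i in seq_along(frames)) co[i, , ] <- frames[[i]]
  trajectory(top, co, label = label)
}

random_rotation <- function() {
  q <- svd(matrix(stats::rnorm(9), 3, 3))
  R <- q$u %*% t(q$v)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# mixed-molecule topology for pair-filter tests: two protein segments,
# a DNA strand, an ADP and a water
mixed_topology <- function() {
  topology(
    name = c("N", "CA", "O", "N", "CA", "O", "N1", "N3", "N6", "O1B", "O2B", "OH2"),
    resname = c("THR", "THR", "THR", "ALA", "ALA", "ALA", "CYT", "CYT", "ADE", "ADP", "ADP", "HOH"),
    resno = c(781, 781, 781, 517, 517, 517, 4, 4, 9, 1, 1, 3001),
    segid = c("MSH6", "MSH6", "MSH6", "MSH2", "MSH2", "MSH2", "DNAA", "DNAA", "DNAA", "ADP1", "ADP1", "WAT"),
    element = c("N", "C", "O", "N", "C", "O", "N", "N", "N", "O", "O", "O"))
}

# brute-force O(donors x hydrogens x acceptors) H-bond oracle, independent of
# the vectorized detector
brute_force_hbonds <- function(traj, criteria = hbond_criteria()) {
  top <- traj$topology
  rkey <- paste0(top$segid, ":", top$resname, top$resno)
  polar <- which(top$heavy & top$element %in% c("N", "O"))
  hyd <- which(top$element == "H")
  ref <- traj$coords[1, , , drop = TRUE]
  pairs <- list()
  for (h in hyd) {
    best <- NA_integer_; bd <- Inf
    for (p in polar) {
      d <- sqrt(sum((ref[p, ] - ref[h, ])^2))
      if (d < bd) { bd <- d; best <- p }
    }
    if (bd < 1.2) pairs[[length(pairs) + 1]] <- c(best, h)
  }
  out <- list()
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$coords[f, , , drop = TRUE]
    for (dh in pairs) {
      d <- dh[1]; h <- dh[2]
      for (a in polar) {
        if (a == d || rkey[a] == rkey[d]) next
        dist <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
        if (dist > criteria$max_dist) next
        v1 <- xyz[d, ] - xyz[h, ]; v2 <- xyz[a, ] - xyz[h, ]
        ang <- acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang >= criteria$min_angle - 1e-9)
          out[[length(out) + 1]] <- data.frame(frame = f, donor = d,
                                               hydrogen = h, acceptor = a)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(frame = integer(), donor = integer(),
                      hydrogen = integer(), acceptor = integer()))
  do.call(rbind, out)
}

# exhaustive weighted-Gini split search over all binary features
best_gini_split <- function(X, y) {
  classes <- sort(unique(y))
  n <- length(y)
  gini <- function(lab) {
    if (length(lab) == 0) return(0)
    1 - sum((table(factor(lab, classes)) / length(lab))^2)
  }
  w <- vapply(seq_len(ncol(X)), function(j) {
    on <- X[, j] == 1
    if (!any(on) || all(on)) return(Inf)
    (sum(on) * gini(y[on]) + sum(!on) * gini(y[!on])) / n
  }, 0)
  list(feature = which(w <= min(w) + 1e-12)[1], impurity = min(w))
}

# 3-cluster Gaussian mixture with informative and uniform-noise features,
# the planted-recovery design for clustering tests
gaussian_mixture_fixture <- function(seed, n_per = 100, sep = 8,
                                     n_inform = 5, n_noise = 5) {
  withr::with_seed(seed, {
    # informative features separate cluster means by `sep` within-cluster
    # standard deviations (unit sd); all pairwise center distances >= sep
    centers <- rbind(rep(0, n_inform),
                     rep(sep, n_inform),
                     rep(c(sep, 0), length.out = n_inform) + sep / 2)
    X <- do.call(rbind, lapply(1:3, function(k)
      matrix(stats::rnorm(n_per * n_inform), n_per) +
        matrix(centers[k, ], n_per, n_inform, byrow = TRUE)))
    span <- max(X) - min(X)
    noise <- matrix(stats::runif(3 * n_per * n_noise, min(X), max(X)),
                    3 * n_per, n_noise)
    list(X = cbind(X, noise), truth = rep(1:3, each = n_per),
         informative = seq_len(n_inform),
         noisy = n_inform + seq_len(n_noise))
  })
}

# frames x atoms x 3 -> frames x 3N matrix in bio3d xyz ordering
coords_to_xyz_test <- function(coords) {
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  out <- matrix(0, nf, 3 * na)
  for (a in seq_len(na)) out[, 3 * a - 2:0] <- coords[, a, ]
  out
}
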