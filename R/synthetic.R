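#' Specification for a planted hydrogen-bond feature matrix
#'
#' Describes per-class Bernoulli occupancies for a panel of binary H-bond
#' features: a small set of planted class-discriminative bonds (high occupancy
#' in one class, near-absent elsewhere) hidden among uninformative background
#' bonds with identical occupancy in every class.  The defaults mirror the
#' study design this generator emulates: 3 damage classes x 5000 frames
#' (15,000 concatenated frames), 50 background bonds at occupancy 0.3 and two
#' planted bonds at 0.9 in their signature class versus 0.05 elsewhere.
#'
#' @param classes class (system) names.
#' @param n_frames frames per class (scalar or one per class).
#' @param n_features total number of H-bond features.
#' @param planted indices of the discriminative features.
#' @param planted_class signature class of each planted feature.
#' @param p_on occupancy of a planted feature in its signature class.
#' @param p_off occupancy of a planted feature in the other classes.
#' @param background occupancy of every non-planted feature (all classes).
#' @param prob optional full `classes x n_features` probability matrix,
#'   overriding the planted/background construction.
#' @param seed RNG seed for [gen_hbond_matrix()].
#' @return an object of class `"hbond_plant_spec"`.
#' @export
hbond_plant_spec <- function(classes = c("Carbo", "Cis", "FdU"),
                             n_frames = 5000, n_features = 52,
                             planted = c(1L, 2L),
                             planted_class = classes[seq_along(planted)],
                             p_on = 0.9, p_off = 0.05, background = 0.3,
                             prob = NULL, seed = 1) {
  n_frames <- rep_len(as.integer(n_frames), length(classes))
  if (any(n_frames < 1)) stopf("n_frames must be >= 1")
  if (is.null(prob)) {
    if (any(planted > n_features)) stopf("planted index exceeds n_features")
    prob <- matrix(background, length(classes), n_features,
                   dimnames = list(classes, NULL))
    for (i in seq_along(planted)) {
      prob[, planted[i]] <- p_off
      prob[planted_class[i], planted[i]] <- p_on
    }
  }
  if (nrow(prob) != length(classes) || ncol(prob) != n_features)
    stopf("prob must be %d x %d", length(classes), n_features)
  if (any(prob < 0 | prob > 1)) stopf("occupancy probabilities must lie in [0, 1]")
  structure(list(classes = classes, n_frames = n_frames,
                 n_features = as.integer(n_features),
                 planted = as.integer(planted), prob = prob, seed = seed),
            class = "hbond_plant_spec")
}

#' Generate a binary H-bond feature matrix with planted discriminative bonds
#'
#' Every entry is drawn independently as Bernoulli(p\[class, feature\]) under a
#' local seeded RNG stream; the same spec (and seed) regenerates the matrix
#' bit-identically.
#'
#' @param spec an [hbond_plant_spec()].
#' @return a [feature_matrix()] whose labels are the generating classes.
#' @export
gen_hbond_matrix <- function(spec) {
  stopifnot(inherits(spec, "hbond_plant_spec"))
  feats <- sprintf("SYN:HB%03d", seq_len(spec$n_features))
  local_seed(spec$seed, {
    blocks <- lapply(seq_along(spec$classes), function(ci) {
      n <- spec$n_frames[ci]
      u <- matrix(stats::runif(n * spec$n_features), n, spec$n_features)
      (u < matrix(spec$prob[ci, ], n, spec$n_features, byrow = TRUE)) + 0L
    })
    feature_matrix(do.call(rbind, blocks),
                   features = feats,
                   labels = rep(spec$classes, spec$n_frames))
  })
}

#' Specification for a planted-structure synthetic trajectory
#'
#' Describes a mixture of Gaussian conformational wells with class-dependent
#' well occupancy, plus planted high-fluctuation ("flexible") atoms, planted
#' cross-atom displacement couplings, and donor-hydrogen-acceptor triads whose
#' geometry toggles between bonded and broken with a per-class probability.
#' Used to give every coordinate-based stage (clustering, RMSF, DCCM, PCA/FES,
#' H-bond detection) a parameter-recovery fixture with known ground truth.
#'
#' @param n_atoms number of atoms.
#' @param classes class (system) names.
#' @param n_frames frames per class.
#' @param K number of conformational wells (ignored if `centers` given).
#' @param well_sep radius (Angstrom) of the circle on which default well
#'   centers sit; wells displace a block of "moving" atoms, so consecutive
#'   centers are `2 * well_sep * sin(pi / K)` apart per moving coordinate.
#' @param centers optional list of `n_atoms x 3` well-center matrices.
#' @param occupancy `classes x K` well-occupancy matrix; rows sum to 1.
#'   Default concentrates class i in well i (0.8) with the remainder spread
#'   evenly.
#' @param spread isotropic Gaussian displacement sd per coordinate (Angstrom).
#' @param flexible indices of atoms given `flex_scale`-fold displacement sd.
#' @param flex_scale fluctuation inflation factor for flexible atoms.
#' @param coupled data frame with columns `a`, `b`, `rho`: atom `b`'s
#'   displacement is built from atom `a`'s via a shared latent Gaussian factor
#'   so their per-coordinate Pearson correlation is exactly `rho` in
#'   expectation (and identically `rho = 1` realizations share displacements).
#' @param triads data frame with columns `d`, `h`, `a` (atom indices) defining
#'   donor-hydrogen-acceptor triads.
#' @param p_bond per-class probability that a triad frame satisfies the
#'   H-bond geometry (recycled over classes).
#' @param dt frame spacing, ps.
#' @param seed RNG seed for [gen_trajectory()].
#' @return an object of class `"conformer_plant_spec"`.
#' @export
conformer_plant_spec <- function(n_atoms = 30,
                                 classes = c("Carbo", "Cis", "FdU"),
                                 n_frames = 500, K = 3, well_sep = 10,
                                 centers = NULL, occupancy = NULL,
                                 spread = 0.5, flexible = integer(),
                                 flex_scale = 4,
                                 coupled = NULL, triads = NULL,
                                 p_bond = 0.9, dt = 100, seed = 1) {
  n_frames <- rep_len(as.integer(n_frames), length(classes))
  if (is.null(centers)) {
    # wells displace a contiguous block of "moving" atoms; centers sit on a
    # circle of radius well_sep in the x-y plane so the wells are in general
    # position (none coincides with the ensemble grand mean)
    moving <- seq_len(max(1L, n_atoms %/% 3))
    base <- matrix(stats::qnorm(seq(0.05, 0.95, length.out = n_atoms * 3)) * 3,
                   n_atoms, 3)  # fixed, seed-independent scaffold
    centers <- lapply(seq_len(K), function(k) {
      m <- base
      ang <- 2 * pi * (k - 1) / max(K, 1)
      m[moving, 1] <- m[moving, 1] + well_sep * cos(ang)
      m[moving, 2] <- m[moving, 2] + well_sep * sin(ang)
      m
    })
  }
  K <- length(centers)
  if (is.null(occupancy)) {
    occupancy <- matrix(ifelse(K > 1, 0.2 / (K - 1), 0), length(classes), K)
    for (i in seq_along(classes)) occupancy[i, 1 + (i - 1) %% K] <- if (K > 1) 0.8 else 1
  }
  occupancy <- matrix(occupancy, length(classes), K)
  if (any(abs(rowSums(occupancy) - 1) > 1e-8))
    stopf("well occupancies must sum to 1 within each class")
  if (any(spread <= 0)) stopf("spread must be > 0")
  if (!is.null(coupled)) {
    if (any(abs(coupled$rho) > 1)) stopf("coupling must lie in [-1, 1]")
    if (anyDuplicated(coupled$b))
      stopf("singular coupling structure: atom %d is the target of multiple couplings",
            coupled$b[anyDuplicated(coupled$b)])
    if (any(coupled$a == coupled$b)) stopf("coupling an atom to itself")
  }
  p_bond <- rep_len(p_bond, length(classes))
  if (any(p_bond < 0 | p_bond > 1)) stopf("p_bond must lie in [0, 1]")
  structure(list(n_atoms = as.integer(n_atoms), classes = classes,
                 n_frames = n_frames, centers = centers, occupancy = occupancy,
                 spread = spread, flexible = as.integer(flexible),
                 flex_scale = flex_scale, coupled = coupled, triads = triads,
                 p_bond = p_bond, dt = dt, seed = seed),
            class = "conformer_plant_spec")
}

synthetic_topology <- function(spec) {
  n <- spec$n_atoms
  name <- rep("CA", n); element <- rep("C", n)
  if (!is.null(spec$triads)) {
    name[spec$triads$d] <- "N";  element[spec$triads$d] <- "N"
    name[spec$triads$h] <- "HN"; element[spec$triads$h] <- "H"
    name[spec$triads$a] <- "O";  element[spec$triads$a] <- "O"
  }
  topology(name, "GLY", seq_len(n), "SYN", element = element)
}

#' Generate a synthetic trajectory with planted conformational structure
#'
#' Each frame samples a well from the class occupancy distribution, adds
#' isotropic Gaussian displacements (inflated for flexible atoms), rewrites
#' coupled atoms' displacements through shared latent factors, and places each
#' donor-hydrogen-acceptor triad in bonded geometry (D-A 2.9 A, D-H-A 180
#' degrees) or broken geometry (D-A 5 A) according to the per-class bond
#' probability.  Ground truth is attached to the returned trajectory:
#' `$well` (frame well membership) and `$bonded` (frames x triads logical).
#'
#' @param spec a [conformer_plant_spec()].
#' @return a [trajectory()] with extra fields `well` and `bonded`.
#' @export
gen_trajectory <- function(spec) {
  stopifnot(inherits(spec, "conformer_plant_spec"))
  top <- synthetic_topology(spec)
  n <- spec$n_atoms
  sds <- rep(spec$spread, n)
  sds[spec$flexible] <- spec$spread * spec$flex_scale
  nf_total <- sum(spec$n_frames)
  ntr <- if (is.null(spec$triads)) 0L else nrow(spec$triads)
  local_seed(spec$seed, {
    coords <- array(0, dim = c(nf_total, n, 3))
    well <- integer(nf_total)
    bonded <- matrix(FALSE, nf_total, max(ntr, 1))
    f <- 0L
    for (ci in seq_along(spec$classes)) {
      for (j in seq_len(spec$n_frames[ci])) {
        f <- f + 1L
        w <- sample.int(ncol(spec$occupancy), 1, prob = spec$occupancy[ci, ])
        well[f] <- w
        disp <- matrix(stats::rnorm(n * 3), n, 3) * sds
        if (!is.null(spec$coupled)) {
          for (r in seq_len(nrow(spec$coupled))) {
            a <- spec$coupled$a[r]; b <- spec$coupled$b[r]
            rho <- spec$coupled$rho[r]
            disp[b, ] <- rho * (sds[b] / sds[a]) * disp[a, ] +
              sqrt(1 - rho^2) * disp[b, ]
          }
        }
        fr <- spec$centers[[w]] + disp
        if (ntr > 0) {
          for (r in seq_len(ntr)) {
            d <- spec$triads$d[r]; h <- spec$triads$h[r]; a <- spec$triads$a[r]
            u <- stats::rnorm(3); u <- u / vec_norm(u)
            on <- stats::runif(1) < spec$p_bond[ci]
            bonded[f, r] <- on
            fr[h, ] <- fr[d, ] + 1.0 * u
            fr[a, ] <- fr[d, ] + (if (on) 2.9 else 5.0) * u
          }
        }
        coords[f, , ] <- fr
      }
    }
    out <- trajectory(top, coords, dt = spec$dt,
                      label = rep(spec$classes, spec$n_frames))
    out$well <- well
    if (ntr > 0) out$bonded <- bonded
    out
  })
}

hexagon_ring <- function(radius = 1.4) {
  ang <- (0:5) * pi / 3
  cbind(radius * cos(ang), radius * sin(ang), 0)
}

rotation_matrix <- function(axis, theta) {
  a <- axis / vec_norm(axis)
  ct <- cos(theta); st <- sin(theta)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * tcrossprod(a)
}

#' Generate a stacked or unstacked pair of six-membered rings
#'
#' Fixture geometry for the aromatic-stacking classifier.  `stacked` places
#' two parallel rings with centroid separation 3.5 Angstrom and aligned
#' normals; `unstacked` draws (by seed) either a distance violation (centroid
#' separation >= 8 Angstrom) or an angle violation (normals tilted >= 60
#' degrees at stacking distance).
#'
#' @param state `"stacked"` or `"unstacked"`.
#' @param seed RNG seed; the same seed reproduces the same coordinates.
#' @return list with `ring1`, `ring2` (6 x 3 coordinate matrices) and `state`.
#' @export
gen_ring_pair <- function(state = c("stacked", "unstacked"), seed = 1) {
  state <- match.arg(state)
  r1 <- hexagon_ring()
  local_seed(seed, {
    if (state == "stacked") {
      r2 <- sweep(hexagon_ring(), 2, c(0, 0, 3.5), "+")
    } else if (stats::runif(1) < 0.5) {  # distance branch
      d <- stats::runif(1, 8, 12)
      dir <- stats::rnorm(3); dir <- dir / vec_norm(dir)
      tilt <- rotation_matrix(c(1, 0, 0), stats::runif(1, 0, 10) * pi / 180)
      r2 <- sweep(hexagon_ring() %*% tilt, 2, d * dir, "+")
    } else {                             # angle branch
      tilt <- rotation_matrix(c(1, 0, 0), stats::runif(1, 60, 90) * pi / 180)
      r2 <- sweep(hexagon_ring() %*% tilt, 2, c(0, 0, 3.5), "+")
    }
    list(ring1 = r1, ring2 = r2, state = state)
  })
}

#' Generate a synthetic stacking trajectory
#'
#' Builds an 18-atom system (a phenylalanine-like probe ring and two base
#' rings, "damaged" and "complement") in which each frame places the probe in
#' one of three planted states: stacked on the damaged base, stacked on the
#' complementary base, or unstacked.  State probabilities are per class.
#'
#' @param classes class names.
#' @param n_frames frames per class.
#' @param p_state `classes x 3` matrix of state probabilities in the order
#'   (stacked_damaged, stacked_complement, none); rows sum to 1.
#' @param jitter coordinate noise sd (Angstrom), kept well inside the
#'   classification margins.
#' @param seed RNG seed.
#' @return a [trajectory()] with extra field `state` (planted per-frame state).
#' @export
gen_stacking_trajectory <- function(classes = c("Carbo", "Cis", "FdU"),
                                    n_frames = 500,
                                    p_state = NULL, jitter = 0.05, seed = 1) {
  if (is.null(p_state))
    p_state <- rbind(c(0.05, 0.9, 0.05), c(0.05, 0.9, 0.05), c(0.6, 0.1, 0.3))
  p_state <- matrix(p_state, length(classes), 3)
  if (any(abs(rowSums(p_state) - 1) > 1e-8)) stopf("state probabilities must sum to 1")
  n_frames <- rep_len(as.integer(n_frames), length(classes))
  states <- c("stacked_damaged", "stacked_complement", "none")
  ring_names <- list(
    probe = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
    damaged = c("N1", "C2", "N3", "C4", "C5", "C6"),
    complement = c("N1", "C2", "N3", "C4", "C5", "C6"))
  top <- topology(unlist(ring_names),
                  resname = rep(c("PHE", "GUA", "CYT"), each = 6),
                  resno = rep(c(71L, 4L, 104L), each = 6),
                  segid = rep(c("MSH6", "DNAA", "DNAB"), each = 6),
                  element = substr(unlist(ring_names), 1, 1))
  dam_c <- c(0, 0, 0); comp_c <- c(14, 0, 0)      # base centroids 14 A apart
  dam <- sweep(hexagon_ring(), 2, dam_c, "+")
  comp <- sweep(hexagon_ring(), 2, comp_c, "+")
  nf_total <- sum(n_frames)
  local_seed(seed, {
    coords <- array(0, dim = c(nf_total, 18, 3))
    state <- character(nf_total)
    f <- 0L
    for (ci in seq_along(classes)) {
      for (j in seq_len(n_frames[ci])) {
        f <- f + 1L
        s <- sample.int(3, 1, prob = p_state[ci, ])
        state[f] <- states[s]
        probe <- switch(s,
          sweep(hexagon_ring(), 2, dam_c + c(0, 0, 3.5), "+"),
          sweep(hexagon_ring(), 2, comp_c + c(0, 0, 3.5), "+"),
          sweep(hexagon_ring() %*% rotation_matrix(c(1, 0, 0), pi / 2),
                2, c(7, 8, 6), "+"))
        fr <- rbind(probe, dam, comp)
        coords[f, , ] <- fr + matrix(stats::rnorm(18 * 3, sd = jitter), 18, 3)
      }
    }
    out <- trajectory(top, coords, dt = 100, label = rep(classes, n_frames))
    out$state <- state
    out
  })
}
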