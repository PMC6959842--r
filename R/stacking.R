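#' Geometric aromatic-stacking criteria
#'
#' Two rings are "stacked" when their centroid separation, the angle between
#' their best-fit plane normals, and the lateral (in-plane) centroid offset
#' are all within the thresholds.  Defaults (5.0 Angstrom separation, 30
#' degree tilt, 2.0 Angstrom offset) capture face-to-face pi-stacking while
#' rejecting T-shaped and displaced contacts.
#'
#' @param max_dist maximum ring-centroid separation, Angstrom.
#' @param max_angle maximum angle between ring normals, degrees.
#' @param max_offset maximum lateral centroid offset, Angstrom; `NULL`
#'   disables the offset test.
#' @return an object of class `"stacking_criteria"`.
#' @export
stacking_criteria <- function(max_dist = 5.0, max_angle = 30, max_offset = 2.0) {
  if (max_dist <= 0 || max_angle <= 0 || (!is.null(max_offset) && max_offset <= 0))
    stopf("stacking thresholds must be > 0")
  structure(list(max_dist = max_dist, max_angle = max_angle,
                 max_offset = max_offset),
            class = "stacking_criteria")
}

# centroid + unit normal of the least-squares plane through ring atoms
ring_plane <- function(ring) {
  ring <- as.matrix(ring)
  if (nrow(ring) < 3) stopf("degenerate ring: need >= 3 atoms")
  ctr <- colMeans(ring)
  sv <- svd(sweep(ring, 2, ctr))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stopf("degenerate ring: atoms are collinear")
  list(centroid = ctr, normal = sv$v[, 3])
}

ring_pair_geometry <- function(ring1, ring2) {
  p1 <- ring_plane(ring1); p2 <- ring_plane(ring2)
  d <- p2$centroid - p1$centroid
  sep <- vec_norm(d)
  # normals are sign-ambiguous: fold the angle into [0, 90]
  ang <- deg(acos(pmin(1, abs(sum(p1$normal * p2$normal)))))
  vert <- abs(sum(d * p1$normal))
  lateral <- sqrt(max(sep^2 - vert^2, 0))
  list(separation = sep, angle = ang, offset = lateral)
}

is_stacked <- function(geom, criteria) {
  geom$separation <= criteria$max_dist && geom$angle <= criteria$max_angle &&
    (is.null(criteria$max_offset) || geom$offset <= criteria$max_offset)
}

#' Classify the stacking state of a probe ring in one frame
#'
#' Computes centroid and best-fit plane for the probe and each candidate
#' ring; a candidate passes when separation, normal angle and lateral offset
#' all meet the criteria.  If both candidates pass, the one with the smaller
#' centroid separation wins.
#'
#' @param probe `>=3 x 3` coordinate matrix of the probe ring
#'   (phenylalanine-like side chain).
#' @param damaged,complement coordinate matrices of the two candidate base
#'   rings.
#' @param criteria a [stacking_criteria()].
#' @return one of `"stacked_damaged"`, `"stacked_complement"`, `"none"`.
#' @export
classify_stacking <- function(probe, damaged, complement,
                              criteria = stacking_criteria()) {
  gd <- ring_pair_geometry(probe, damaged)
  gc_ <- ring_pair_geometry(probe, complement)
  sd_ok <- is_stacked(gd, criteria)
  sc_ok <- is_stacked(gc_, criteria)
  if (sd_ok && sc_ok)
    return(if (gd$separation <= gc_$separation) "stacked_damaged" else "stacked_complement")
  if (sd_ok) return("stacked_damaged")
  if (sc_ok) return("stacked_complement")
  "none"
}

# resolve a residue descriptor "SEG:RESNAME+RESNO" (or atom indices) to the
# ring atoms used for plane fitting
resolve_ring <- function(top, ring) {
  if (is.numeric(ring)) return(as.integer(ring))
  rk <- residue_key(top)
  idx <- which(rk == ring & top$heavy)
  if (length(idx) == 0) stopf("cannot resolve residue '%s' in topology", ring)
  ring_names <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ",       # Phe/Tyr
                  "N1", "C2", "N3", "C4", "C5", "C6")           # pyrimidine-type
  sel <- idx[top$name[idx] %in% ring_names]
  if (length(sel) < 3) sel <- idx
  if (length(sel) < 3) stopf("residue '%s' has fewer than 3 ring atoms", ring)
  sel
}

#' Per-frame stacking states and per-system fractions
#'
#' Classifies every frame of a trajectory and tabulates, per system label,
#' the fraction of frames in each of the three states; fractions sum to 1
#' within each system.
#'
#' @param traj a [trajectory()].
#' @param probe,damaged,complement ring definitions: residue descriptors
#'   (`"MSH6:PHE71"`) or integer atom-index vectors.
#' @param criteria a [stacking_criteria()].
#' @return list with `states` (per-frame character vector) and `fractions`
#'   (systems x 3 matrix over stacked_damaged / stacked_complement / none).
#' @export
stacking_fractions <- function(traj, probe, damaged, complement,
                               criteria = stacking_criteria()) {
  top <- traj$topology
  ip <- resolve_ring(top, probe)
  id <- resolve_ring(top, damaged)
  ic <- resolve_ring(top, complement)
  states <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- traj$coords[f, , , drop = TRUE]
    classify_stacking(xyz[ip, , drop = FALSE], xyz[id, , drop = FALSE],
                      xyz[ic, , drop = FALSE], criteria)
  }, "")
  lv <- c("stacked_damaged", "stacked_complement", "none")
  tab <- table(factor(traj$label, unique(traj$label)), factor(states, lv))
  frac <- sweep(unclass(tab), 1, rowSums(tab), "/")
  dimnames(frac) <- list(system = rownames(tab), state = lv)
  list(states = states, fractions = frac)
}
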