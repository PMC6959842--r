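#' Geometric hydrogen-bond criteria
#'
#' A donor-hydrogen-acceptor triple counts as a hydrogen bond when the
#' heavy-atom (donor-acceptor) distance is at most `max_dist` and the
#' donor-hydrogen-acceptor angle is at least `min_angle`.  The defaults
#' (3.2 Angstrom, 120 degrees) select intermediate-strength hydrogen bonds;
#' the angle is applied as a minimum because strong hydrogen bonds approach
#' 180 degrees and 120 degrees is the conventional lower cutoff of detection
#' tools.
#'
#' @param max_dist maximum donor-acceptor heavy-atom distance, Angstrom.
#' @param min_angle minimum D-H-A angle, degrees.
#' @return an object of class `"hbond_criteria"`.
#' @export
hbond_criteria <- function(max_dist = 3.2, min_angle = 120) {
  if (max_dist <= 0) stopf("max_dist must be > 0")
  if (min_angle <= 0 || min_angle > 180) stopf("min_angle must lie in (0, 180]")
  structure(list(max_dist = max_dist, min_angle = min_angle),
            class = "hbond_criteria")
}

# donor table: heavy N/O atoms paired with each covalently bonded hydrogen.
# Bonds are inferred from the reference frame: an H belongs to the nearest
# polar heavy atom within bond_cut (1.2 A), the usual fallback when the
# topology carries no connectivity.
find_donors <- function(top, ref_coords, bond_cut = 1.2) {
  polar <- which(top$heavy & top$element %in% c("N", "O"))
  hyd <- which(top$element == "H")
  if (length(polar) == 0 || length(hyd) == 0)
    return(data.frame(donor = integer(), hydrogen = integer()))
  d2 <- outer(rowSums(ref_coords[polar, , drop = FALSE]^2),
              rowSums(ref_coords[hyd, , drop = FALSE]^2), "+") -
    2 * tcrossprod(ref_coords[polar, , drop = FALSE],
                   ref_coords[hyd, , drop = FALSE])
  nearest <- apply(d2, 2, which.min)
  ok <- sqrt(pmax(d2[cbind(nearest, seq_along(hyd))], 0)) < bond_cut
  data.frame(donor = polar[nearest[ok]], hydrogen = hyd[ok])
}

#' Detect hydrogen bonds in every frame of a trajectory
#'
#' Donors are polar heavy atoms (N, O) with at least one covalently bonded
#' hydrogen; acceptors are polar heavy atoms.  A directional event
#' (donor, hydrogen, acceptor) is emitted for every triple passing both
#' geometric tests of `criteria` in a frame.
#'
#' @param traj a [trajectory()].
#' @param criteria an [hbond_criteria()].
#' @param exclude_same_residue drop donor-acceptor pairs within one residue
#'   (default `TRUE`; intra-residue contacts are not interaction features).
#' @return data frame of events with columns `frame`, `donor`, `hydrogen`,
#'   `acceptor` (atom indices), `distance` (Angstrom), `angle` (degrees).
#' @export
detect_hbonds <- function(traj, criteria = hbond_criteria(),
                          exclude_same_residue = TRUE) {
  top <- traj$topology
  don <- find_donors(top, traj$coords[1, , , drop = TRUE])
  acc <- which(top$heavy & top$element %in% c("N", "O"))
  if (nrow(don) == 0 || length(acc) == 0)
    stopf("empty selection: no polar donor/acceptor atoms in topology")
  rkey <- residue_key(top)
  out <- vector("list", n_frames(traj))
  cosmin <- cos(criteria$min_angle * pi / 180)
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$coords[f, , , drop = TRUE]
    dmat <- outer(rowSums(xyz[don$donor, , drop = FALSE]^2),
                  rowSums(xyz[acc, , drop = FALSE]^2), "+") -
      2 * tcrossprod(xyz[don$donor, , drop = FALSE], xyz[acc, , drop = FALSE])
    dmat <- sqrt(pmax(dmat, 0))
    hit <- which(dmat <= criteria$max_dist, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    di <- don$donor[hit[, 1]]; hi <- don$hydrogen[hit[, 1]]; ai <- acc[hit[, 2]]
    keep <- di != ai
    if (exclude_same_residue) keep <- keep & rkey[di] != rkey[ai]
    if (!any(keep)) next
    di <- di[keep]; hi <- hi[keep]; ai <- ai[keep]
    dd <- dmat[hit[keep, , drop = FALSE]]
    v1 <- xyz[di, , drop = FALSE] - xyz[hi, , drop = FALSE]
    v2 <- xyz[ai, , drop = FALSE] - xyz[hi, , drop = FALSE]
    cosang <- rowSums(v1 * v2) /
      (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    cosang <- pmin(1, pmax(-1, cosang))
    # angle >= min_angle  <=>  cos(angle) <= cos(min_angle)
    ok <- cosang <= cosmin + 1e-12
    if (!any(ok)) next
    out[[f]] <- data.frame(frame = f, donor = di[ok], hydrogen = hi[ok],
                           acceptor = ai[ok], distance = dd[ok],
                           angle = deg(acos(cosang[ok])))
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(frame = integer(), donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(), angle = numeric())
  rownames(res) <- NULL
  res
}

#' Build a residue-pair filter for feature construction
#'
#' Reproduces the contact subsets used for motif mining:
#' `protein_nucleic` keeps protein vs (DNA or nucleotide-cofactor, e.g. ADP)
#' pairs; `inter_monomer` keeps protein-protein pairs spanning the two named
#' monomer segments (e.g. MSH2 vs MSH6); `protein_any` keeps any pair with at
#' least one protein residue.
#'
#' @param top a [topology()].
#' @param mode one of `"protein_nucleic"`, `"inter_monomer"`, `"protein_any"`.
#' @param monomers the two segment names spanned by `inter_monomer`.
#' @return a predicate `function(atom_i, atom_j)` vectorized over atom index
#'   pairs, carrying attribute `"mode"`.
#' @export
select_pairs <- function(top, mode = c("protein_nucleic", "inter_monomer",
                                       "protein_any"),
                         monomers = NULL) {
  mode <- match.arg(mode)
  mc <- top$molclass
  seg <- top$segid
  if (mode == "inter_monomer") {
    if (is.null(monomers)) {
      monomers <- unique(seg[mc == "protein"])
      if (length(monomers) != 2)
        stopf("configuration error: inter_monomer needs exactly two protein segments, found [%s]",
              paste(monomers, collapse = ", "))
    }
    if (!all(monomers %in% seg))
      stopf("configuration error: unknown segment '%s'",
            monomers[!monomers %in% seg][1])
  }
  f <- switch(mode,
    protein_nucleic = function(i, j) {
      (mc[i] == "protein" & mc[j] %in% c("nucleic", "cofactor")) |
      (mc[j] == "protein" & mc[i] %in% c("nucleic", "cofactor"))
    },
    inter_monomer = function(i, j) {
      mc[i] == "protein" & mc[j] == "protein" &
        ((seg[i] == monomers[1] & seg[j] == monomers[2]) |
         (seg[i] == monomers[2] & seg[j] == monomers[1]))
    },
    protein_any = function(i, j) mc[i] == "protein" | mc[j] == "protein")
  attr(f, "mode") <- mode
  f
}

#' Construct a binary feature matrix
#'
#' @param data 0/1 matrix, frames in rows, features in columns.
#' @param features feature descriptors (unordered residue-pair names), one
#'   per column, unique.
#' @param labels per-frame class labels.
#' @return an object of class `"feature_matrix"`.
#' @export
feature_matrix <- function(data, features = colnames(data), labels) {
  data <- as.matrix(data)
  storage.mode(data) <- "integer"
  if (length(data) && !all(data %in% c(0L, 1L)))
    stopf("feature matrix entries must be 0 or 1")
  if (is.null(features)) features <- sprintf("f%03d", seq_len(ncol(data)))
  if (anyDuplicated(features)) stopf("feature descriptors must be unique")
  if (length(labels) != nrow(data))
    stopf("label count (%d) must equal frame count (%d)", length(labels), nrow(data))
  colnames(data) <- features
  structure(list(data = data, features = as.character(features),
                 labels = as.character(labels)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d frames x %d binary features, classes: %s\n",
              nrow(x$data), ncol(x$data),
              paste(unique(x$labels), collapse = ", ")))
  invisible(x)
}

#' Collapse atom-level H-bond events into a binary residue-pair matrix
#'
#' One column per unordered residue pair that passes `pairs` and occurs at
#' least once; entry (frame, pair) is 1 iff any atom-level event between the
#' two residues (either donation direction) exists in that frame.
#'
#' @param events event data frame from [detect_hbonds()].
#' @param traj the trajectory the events came from (supplies the topology,
#'   frame count and class labels).
#' @param pairs optional residue-pair predicate from [select_pairs()];
#'   `NULL` keeps all pairs.
#' @return a [feature_matrix()].
#' @export
binarize <- function(events, traj, pairs = NULL) {
  top <- traj$topology
  nf <- n_frames(traj)
  if (nrow(events) && max(events$frame) > nf)
    stopf("event frame index exceeds trajectory frame count")
  keep <- if (nrow(events) == 0) logical(0)
          else if (is.null(pairs)) rep(TRUE, nrow(events))
          else pairs(events$donor, events$acceptor)
  ev <- events[keep, , drop = FALSE]
  if (nrow(ev) == 0)
    return(feature_matrix(matrix(0L, nf, 0), character(0), traj$label))
  rkey <- residue_key(top)
  a <- rkey[ev$donor]; b <- rkey[ev$acceptor]
  lo <- pmin(a, b); hi <- pmax(a, b)
  pair <- paste0(lo, "--", hi)
  feats <- sort(unique(pair))
  m <- matrix(0L, nf, length(feats), dimnames = list(NULL, feats))
  m[cbind(ev$frame, match(pair, feats))] <- 1L
  feature_matrix(m, feats, traj$label)
}

#' Write / read a feature matrix as CSV
#'
#' CSV dialect: first column `frame`, second column `label`, remaining
#' columns one per residue-pair descriptor with 0/1 values.  The round trip
#' `read_matrix(write_matrix(fm))` is lossless.
#'
#' @param fm a [feature_matrix()].
#' @param path CSV file path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` returns a
#'   [feature_matrix()].
#' @export
write_matrix <- function(fm, path) {
  df <- data.frame(frame = seq_len(nrow(fm$data)), label = fm$labels,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(fm$data, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stopf("I/O error: cannot read '%s'", path)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE, colClasses = NA),
                 error = function(e) stopf("parse error in '%s': %s", path,
                                           conditionMessage(e)))
  if (ncol(df) < 2 || !identical(names(df)[1:2], c("frame", "label")))
    stopf("parse error in '%s' line 1: expected header 'frame,label,...'", path)
  dat <- df[, -(1:2), drop = FALSE]
  for (j in seq_along(dat)) {
    v <- dat[[j]]
    bad <- which(!(v %in% c(0, 1)))
    if (length(bad))
      stopf("parse error in '%s' line %d: non-binary value '%s' in column '%s'",
            path, bad[1] + 1L, v[bad[1]], names(dat)[j])
  }
  feature_matrix(as.matrix(dat), names(dat), as.character(df$label))
}
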