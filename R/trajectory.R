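#' Construct an in-memory trajectory
#'
#' The central container: a topology plus a `frames x atoms x 3` coordinate
#' array in Angstrom, a frame spacing in picoseconds, and a per-frame system
#' label (the damage-class name downstream stages classify on).
#'
#' @param top a [topology()].
#' @param coords numeric array `frames x atoms x 3` (Angstrom).  A single
#'   `atoms x 3` matrix is promoted to one frame.
#' @param dt frame spacing in ps.
#' @param label per-frame system label; a scalar is recycled.
#' @return an object of class `"trajectory"` with fields `topology`, `coords`,
#'   `dt`, `label`.
#' @export
trajectory <- function(top, coords, dt = 100, label = "system") {
  if (is.matrix(coords)) coords <- array(coords, dim = c(1, dim(coords)))
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    stopf("coords must be a frames x atoms x 3 array")
  if (dim(coords)[2] != nrow(top))
    stopf("structural error: coordinates carry %d atoms but topology has %d",
          dim(coords)[2], nrow(top))
  if (dim(coords)[1] < 1) stopf("trajectory needs at least one frame")
  if (!all(is.finite(coords))) stopf("non-finite coordinates")
  label <- rep_len(as.character(label), dim(coords)[1])
  structure(list(topology = top, coords = coords, dt = dt, label = label),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, dt = %g ps, systems: %s\n",
              n_frames(x), n_atoms(x), x$dt,
              paste(unique(x$label), collapse = ", ")))
  invisible(x)
}

#' @rdname trajectory
#' @param traj a trajectory.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

topology_from_pdb <- function(pdb, ...) {
  ele <- tryCatch(suppressWarnings(bio3d::atom2ele(pdb)), error = function(e) NULL)
  if (is.null(ele) || anyNA(ele)) ele <- guess_element(pdb$atom$elety)
  seg <- pdb$atom$segid
  if (is.null(seg) || all(is.na(seg) | seg == "")) seg <- pdb$atom$chain
  seg[is.na(seg) | seg == ""] <- "A"
  topology(pdb$atom$elety, pdb$atom$resid, pdb$atom$resno, seg,
           element = toupper(ele), ...)
}

#' Load a trajectory from files
#'
#' Reads a PDB topology and DCD (or multi-model PDB) coordinates, keeping
#' every `stride`-th frame.  The conventional workflow resamples production
#' trajectories by keeping every tenth frame, so `stride = 10` turns 10 ps
#' frames into 100 ps frames; `dt` is the spacing in the coordinate file and
#' is multiplied by `stride` in the returned trajectory.
#'
#' @param topology_file path to a PDB file defining the atoms.
#' @param coords_file path to a DCD file or a (multi-model) PDB file.
#' @param stride keep frames `1, 1+stride, 1+2*stride, ...` (>= 1).
#' @param label system label applied to every frame.
#' @param dt frame spacing of the coordinate file, ps.
#' @inheritParams topology
#' @return a [trajectory()].
#' @export
load_trajectory <- function(topology_file, coords_file, stride = 1,
                            label = "system", dt = 10,
                            solvent_extra = character(), ion_extra = character()) {
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1) stopf("stride must be a positive integer")
  for (f in c(topology_file, coords_file))
    if (!file.exists(f)) stopf("I/O error: cannot read '%s'", f)
  pdb <- tryCatch(bio3d::read.pdb(topology_file, verbose = FALSE),
                  error = function(e) stopf("I/O error: cannot read '%s': %s",
                                            topology_file, conditionMessage(e)))
  top <- topology_from_pdb(pdb, solvent_extra = solvent_extra, ion_extra = ion_extra)
  ext <- tolower(tools::file_ext(coords_file))
  xyz <- if (ext == "dcd") {
    tryCatch(bio3d::read.dcd(coords_file, verbose = FALSE),
             error = function(e) stopf("I/O error: cannot read '%s': %s",
                                       coords_file, conditionMessage(e)))
  } else if (ext %in% c("pdb", "ent")) {
    m <- tryCatch(bio3d::read.pdb(coords_file, multi = TRUE, verbose = FALSE),
                  error = function(e) stopf("I/O error: cannot read '%s': %s",
                                            coords_file, conditionMessage(e)))
    m$xyz
  } else stopf("unsupported coordinate format '.%s' (use DCD or PDB)", ext)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 * nrow(top))
    stopf("structural error: topology has %d atoms but coordinates have %d",
          nrow(top), ncol(xyz) / 3)
  keep <- seq(1, nrow(xyz), by = stride)
  trajectory(top, xyz_to_coords(xyz[keep, , drop = FALSE]),
             dt = dt * stride, label = label)
}

#' Remove solvent and counter-ions
#'
#' Drops every atom classed `solvent` or `ion` and reindexes the topology
#' contiguously; analysis stages then see only the protein-DNA-cofactor
#' complex.
#'
#' @param traj a [trajectory()].
#' @return the stripped trajectory.
#' @export
strip_solvent <- function(traj) {
  keep <- !(traj$topology$molclass %in% c("solvent", "ion"))
  if (!any(keep)) stopf("empty selection: stripping solvent removes every atom")
  if (all(keep)) return(traj)
  top <- traj$topology[keep, , drop = FALSE]
  rownames(top) <- NULL
  class(top) <- c("topology", "data.frame")
  trajectory(top, traj$coords[, keep, , drop = FALSE], dt = traj$dt,
             label = traj$label)
}

#' Superpose all frames onto a reference frame
#'
#' Rigid-body least-squares fit (Kabsch): each frame is rotated (proper
#' rotation, determinant +1 -- reflections are never applied) and translated
#' to minimize the RMSD of `fit_selection` to the same atoms in the reference
#' frame.  Default selection is the protein alpha carbons.
#'
#' @param traj a [trajectory()].
#' @param fit_selection selection passed to [select_atoms()]; needs >= 3
#'   non-collinear atoms.
#' @param reference reference frame index (default 1, the first frame).
#' @return the superposed trajectory.
#' @export
superpose <- function(traj, fit_selection = "calpha", reference = 1) {
  idx <- select_atoms(traj$topology, fit_selection)
  if (length(idx) < 3) stopf("degenerate fit: need >= 3 fit atoms")
  ref <- traj$coords[reference, idx, , drop = TRUE]
  sv <- svd(sweep(ref, 2, colMeans(ref)))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stopf("degenerate fit: fit selection is collinear")
  out <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    fit <- kabsch(ref, traj$coords[f, idx, , drop = TRUE])
    out[f, , ] <- sweep(traj$coords[f, , , drop = TRUE] %*% fit$R, 2, fit$t, "+")
  }
  traj$coords <- out
  traj
}

#' Frame-wise RMSD of a selection to a reference frame
#'
#' @inheritParams superpose
#' @param selection atoms over which the RMSD is computed.
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
frame_rmsd <- function(traj, selection = "calpha", reference = 1) {
  idx <- select_atoms(traj$topology, selection)
  ref <- traj$coords[reference, idx, , drop = TRUE]
  vapply(seq_len(n_frames(traj)), function(f) {
    d <- traj$coords[f, idx, , drop = TRUE] - ref
    sqrt(sum(d^2) / length(idx))
  }, numeric(1))
}

#' Concatenate trajectories over their common atoms
#'
#' Appends frames in input order, preserving per-frame system labels, after
#' matching atoms across inputs by identity (segment, residue name and number,
#' atom name).
#'
#' @param trajs list of [trajectory()] objects.
#' @param common_atoms `"identity"` requires all inputs to carry exactly the
#'   same atoms (first mismatch is reported); `"intersect"` subsets every
#'   input to the atoms present in all of them.
#' @return the concatenated trajectory (`dt` taken from the first input).
#' @export
concatenate <- function(trajs, common_atoms = c("identity", "intersect")) {
  common_atoms <- match.arg(common_atoms)
  if (length(trajs) < 1) stopf("need at least one trajectory")
  if (length(trajs) == 1) return(trajs[[1]])
  keys <- lapply(trajs, function(t) atom_key(t$topology))
  if (common_atoms == "identity") {
    for (i in seq_along(trajs)[-1]) {
      if (length(keys[[i]]) != length(keys[[1]])) {
        stopf("incompatible trajectories: input 1 has %d atoms, input %d has %d",
              length(keys[[1]]), i, length(keys[[i]]))
      }
      bad <- which(keys[[i]] != keys[[1]])
      if (length(bad))
        stopf("incompatible trajectories: atom %d is '%s' in input 1 but '%s' in input %d",
              bad[1], keys[[1]][bad[1]], keys[[i]][bad[1]], i)
    }
    sel <- lapply(trajs, function(t) seq_len(n_atoms(t)))
  } else {
    shared <- Reduce(intersect, keys)
    if (length(shared) == 0) stopf("incompatible trajectories: no common atoms")
    sel <- lapply(keys, function(k) match(shared, k))
  }
  top <- trajs[[1]]$topology[sel[[1]], , drop = FALSE]
  rownames(top) <- NULL
  class(top) <- c("topology", "data.frame")
  coords <- do.call(abind_frames, lapply(seq_along(trajs), function(i)
    trajs[[i]]$coords[, sel[[i]], , drop = FALSE]))
  trajectory(top, coords, dt = trajs[[1]]$dt,
             label = unlist(lapply(trajs, `[[`, "label"), use.names = FALSE))
}

# bind frames x atoms x 3 arrays along dimension 1
abind_frames <- function(...) {
  parts <- list(...)
  na <- dim(parts[[1]])[2]
  out <- array(0, dim = c(sum(vapply(parts, function(p) dim(p)[1], 0L)), na, 3))
  at <- 0
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Write a trajectory as PDB plus CHARMM-format DCD
#'
#' `write_pdb_topology()` writes the topology with first-frame coordinates;
#' `write_dcd()` writes all frames as a single-precision CHARMM DCD that
#' standard readers accept.
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(payload_writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4)
    payload_writer()
    writeBin(as.integer(nbytes), con, size = 4)
  }
  nf <- n_frames(traj); na <- n_atoms(traj)
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L  # CHARMM version stamp; marks 4-byte format fields
  rec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(icntrl, con, size = 4)
  }, 84)
  title <- sprintf("%-80s", "written by mdmotifs")
  rec(function() {
    writeBin(1L, con, size = 4)
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(na), con, size = 4), 4)
  for (f in seq_len(nf)) {
    for (ax in 1:3)
      rec(function() writeBin(as.numeric(traj$coords[f, , ax]), con, size = 4),
          4 * na)
  }
  invisible(path)
}

#' @rdname write_dcd
#' @param frame which frame's coordinates to place in the PDB.
#' @export
write_pdb_topology <- function(traj, path, frame = 1) {
  top <- traj$topology
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(traj$coords[frame, , , drop = TRUE])),
                   resno = top$resno, resid = top$resname,
                   eleno = seq_len(nrow(top)), elety = top$name,
                   chain = substr(top$segid, 1, 1), segid = top$segid,
                   elesy = top$element)
  invisible(path)
}

#' Export a per-frame scalar series as CSV
#'
#' @param x numeric vector (one value per frame).
#' @param traj the trajectory the series was computed from (for time stamps).
#' @param path output CSV path.
#' @param name column name for the series.
#' @export
write_series <- function(x, traj, path, name = "value") {
  df <- data.frame(frame = seq_along(x), time_ps = (seq_along(x) - 1) * traj$dt,
                   label = traj$label, value = x)
  names(df)[4] <- name
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
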