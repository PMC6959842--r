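# trajectory reading, resampling, stripping, superposition, concatenation

make_dcd_fixture <- function(n_frames = 150, n_atoms = 7, seed = 11) {
  withr::with_seed(seed, {
    co <- array(stats::rnorm(n_frames * n_atoms * 3, sd = 3),
                dim = c(n_frames, n_atoms, 3))
    traj <- trajectory(ca_topology(n_atoms), co, dt = 10, label = "Cis")
    pdb <- tempfile(fileext = ".pdb")
    dcd <- tempfile(fileext = ".dcd")
    write_pdb_topology(traj, pdb)
    write_dcd(traj, dcd)
    list(traj = traj, pdb = pdb, dcd = dcd)
  })
}

test_that("load_trajectory resamples every stride-th frame and scales dt", {
  fx <- make_dcd_fixture(150)
  lt <- load_trajectory(fx$pdb, fx$dcd, stride = 10, label = "Cis", dt = 10)
  expect_equal(n_frames(lt), 15)
  expect_equal(lt$dt, 100)
  expect_true(all(lt$label == "Cis"))
  # stride 1 keeps every frame; stride-10 frames are an exact subset of them
  l1 <- load_trajectory(fx$pdb, fx$dcd, stride = 1, dt = 10)
  expect_equal(n_frames(l1), 150)
  expect_identical(lt$coords, l1$coords[seq(1, 150, 10), , , drop = FALSE])
  # float32 storage: agreement with the source within single precision
  expect_lt(max(abs(l1$coords - fx$traj$coords)), 1e-4)
})

test_that("atom-count mismatch between topology and coordinates is an error", {
  fx <- make_dcd_fixture(5, n_atoms = 12)
  small <- make_dcd_fixture(5, n_atoms = 10)
  expect_error(load_trajectory(small$pdb, fx$dcd), "structural error")
  expect_error(load_trajectory(fx$pdb, tempfile(fileext = ".dcd")), "cannot read")
})

test_that("strip_solvent removes water/ions, keeps everything else intact", {
  top <- topology(c(rep("CA", 4), rep("OH2", 6), "SOD"),
                  resname = c(rep("GLY", 4), rep("TIP3", 6), "SOD"),
                  resno = c(1:4, 5:10, 11),
                  element = c(rep("C", 4), rep("O", 6), "NA"))
  co <- array(stats::rnorm(2 * 11 * 3), dim = c(2, 11, 3))
  traj <- trajectory(top, co, label = "A")
  st <- strip_solvent(traj)
  expect_equal(n_atoms(st), 4)
  expect_identical(st$coords, traj$coords[, 1:4, , drop = FALSE])
  # no solvent present -> identity
  dry <- trajectory(ca_topology(4), co[, 1:4, , drop = FALSE])
  expect_identical(strip_solvent(dry), dry)
  # solvent-only -> empty-selection error
  wet <- trajectory(top[5:11, ], co[, 5:11, , drop = FALSE])
  expect_error(strip_solvent(wet), "empty selection")
})

test_that("superpose undoes a planted rigid-body motion (Kabsch oracle)", {
  withr::with_seed(4, {
    f1 <- matrix(stats::rnorm(18, sd = 2), 6, 3)
    Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)  # 90 deg about z
    f2 <- sweep(f1 %*% Rz, 2, c(5, 0, 0), "+")
    traj <- traj_from_frames(list(f1, f2))
    fitted <- superpose(traj, "all")
    expect_lt(frame_rmsd(fitted, "all")[2], 1e-8)
    # independent oracle: bio3d's least-squares fit reaches the same coordinates
    fx <- bio3d::fit.xyz(fixed = as.vector(t(f1)), mobile = as.vector(t(f2)),
                         fixed.inds = 1:18, mobile.inds = 1:18)
    expect_lt(max(abs(matrix(fx, 6, 3, byrow = TRUE) - fitted$coords[2, , ])), 1e-8)
  })
})

test_that("reflections are never used to fit a mirror image", {
  withr::with_seed(5, {
    f1 <- matrix(stats::rnorm(18, sd = 2), 6, 3)
    mirror <- f1 %*% diag(c(-1, 1, 1))
    fitted <- superpose(traj_from_frames(list(f1, mirror)), "all")
    expect_gt(frame_rmsd(fitted, "all")[2], 1e-3)
  })
})

test_that("superpose is idempotent and preserves interatomic distances", {
  withr::with_seed(6, {
    frames <- replicate(4, matrix(stats::rnorm(24, sd = 3), 8, 3), simplify = FALSE)
    traj <- traj_from_frames(frames)
    s1 <- superpose(traj, "all")
    s2 <- superpose(s1, "all")
    expect_lt(max(abs(s2$coords - s1$coords)), 1e-10)
    for (f in 1:4) {
      d_before <- dist(traj$coords[f, , ])
      d_after <- dist(s1$coords[f, , ])
      expect_lt(max(abs(d_before - d_after)), 1e-10)
    }
    # identical frames -> zero RMSD everywhere
    same <- superpose(traj_from_frames(list(frames[[1]], frames[[1]])), "all")
    expect_lt(max(frame_rmsd(same, "all")), 1e-10)
  })
})

test_that("degenerate fit selections are rejected", {
  line <- cbind(1:5, 0, 0)
  traj <- traj_from_frames(list(line, line))
  expect_error(superpose(traj, "all"), "collinear")
  expect_error(superpose(traj_from_frames(list(line[1:2, ], line[1:2, ])), "all"),
               ">= 3")
})

test_that("concatenate appends frames and preserves system labels", {
  withr::with_seed(7, {
    co <- function() array(stats::rnorm(5 * 4 * 3), dim = c(5, 4, 3))
    a <- trajectory(ca_topology(4), co(), label = "A")
    b <- trajectory(ca_topology(4), co(), label = "B")
    cc <- concatenate(list(a, b))
    expect_equal(n_frames(cc), 10)
    expect_equal(cc$label, rep(c("A", "B"), each = 5))
    expect_identical(cc$coords[1:5, , ], a$coords[, , ])
    expect_identical(concatenate(list(a)), a)
    # disjoint residue numbering under the strict selection -> error naming it
    top2 <- ca_topology(4); top2$resno <- 11:14
    d <- trajectory(top2, co(), label = "D")
    expect_error(concatenate(list(a, d)), "incompatible.*atom 1")
    # intersect mode recovers the shared atoms instead
    top3 <- ca_topology(5)
    e <- trajectory(top3, array(stats::rnorm(5 * 5 * 3), dim = c(5, 5, 3)), label = "E")
    ce <- concatenate(list(a, e), "intersect")
    expect_equal(n_atoms(ce), 4)
  })
})

test_that("load -> strip -> concatenate at stride 1 preserves coordinates bit-for-bit", {
  fx1 <- make_dcd_fixture(6, n_atoms = 5, seed = 21)
  fx2 <- make_dcd_fixture(4, n_atoms = 5, seed = 22)
  t1 <- strip_solvent(load_trajectory(fx1$pdb, fx1$dcd, stride = 1, label = "A"))
  t2 <- strip_solvent(load_trajectory(fx2$pdb, fx2$dcd, stride = 1, label = "B"))
  cc <- concatenate(list(t1, t2))
  expect_identical(cc$coords[1:6, , ], t1$coords[, , ])
  expect_identical(cc$coords[7:10, , ], t2$coords[, , ])
})
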