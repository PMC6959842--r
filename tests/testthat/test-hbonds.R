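# geometric H-bond detection and feature-matrix construction

# minimal donor/hydrogen/acceptor system; acceptor position is configurable
triad_trajectory <- function(acceptor_pos, hydrogen_pos = c(1, 0, 0)) {
  top <- topology(c("N", "HN", "O"), c("ASN", "ASN", "SER"), c(1, 1, 2), "A",
                  element = c("N", "H", "O"))
  co <- array(0, dim = c(1, 3, 3))
  co[1, 2, ] <- hydrogen_pos
  co[1, 3, ] <- acceptor_pos
  trajectory(top, co, label = "A")
}

test_that("distance and angle cutoffs act as stated", {
  # collinear D-H-A at 2.9 A: distance passes, angle is 180 degrees
  ev <- detect_hbonds(triad_trajectory(c(2.9, 0, 0)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$distance, 2.9, tolerance = 1e-12)
  expect_equal(ev$angle, 180, tolerance = 1e-9)
  # 3.5 A exceeds the 3.2 A heavy-atom cutoff
  expect_equal(nrow(detect_hbonds(triad_trajectory(c(3.5, 0, 0)))), 0)
  # D-H-A angle of 90 degrees fails the 120-degree minimum
  expect_equal(nrow(detect_hbonds(triad_trajectory(c(1, 2.5, 0)))), 0)
  # exactly at the distance threshold: detected (cutoff is inclusive)
  expect_equal(nrow(detect_hbonds(triad_trajectory(c(3.2, 0, 0)))), 1)
  expect_error(detect_hbonds(trajectory(ca_topology(3), array(0, c(1, 3, 3)))),
               "empty selection")
})

test_that("detector matches the brute-force double-loop oracle", {
  # many random triad geometries per frame spanning detected/undetected cases
  withr::with_seed(31, {
    n_tri <- 40
    top <- topology(rep(c("N", "HN", "O"), n_tri),
                    rep(c("ASN", "ASN", "SER"), n_tri),
                    # donor+H share residue 2t-1, acceptor sits in residue 2t
                    rep(1:(2 * n_tri), times = rep(c(2, 1), n_tri)),
                    "A", element = rep(c("N", "H", "O"), n_tri))
    for (rep_i in 1:3) {
      co <- array(0, dim = c(1, 3 * n_tri, 3))
      for (t in seq_len(n_tri)) {
        base <- stats::runif(3, 0, 50)           # spread triads apart
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        co[1, 3 * t - 2, ] <- base
        co[1, 3 * t - 1, ] <- base + u           # H at 1 A
        v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
        co[1, 3 * t, ] <- base + stats::runif(1, 1.5, 4.5) *
          (if (stats::runif(1) < 0.5) u else v)  # acceptor: varied dist/angle
      }
      traj <- trajectory(top, co, label = "A")
      got <- detect_hbonds(traj)
      want <- brute_force_hbonds(traj)
      key <- function(d) sort(paste(d$frame, d$donor, d$hydrogen, d$acceptor))
      expect_identical(key(got), key(want))
    }
  })
})

test_that("detection is invariant under global rotation and translation", {
  withr::with_seed(32, {
    s <- conformer_plant_spec(n_atoms = 9, classes = "A", n_frames = 10, K = 1,
                              triads = data.frame(d = c(4, 7), h = c(5, 8),
                                                  a = c(6, 9)),
                              p_bond = 0.5, seed = 12)
    traj <- gen_trajectory(s)
    ev1 <- detect_hbonds(traj)
    R <- random_rotation(); shift <- c(10, -5, 3)
    rot <- traj
    for (f in 1:n_frames(traj))
      rot$coords[f, , ] <- sweep(traj$coords[f, , ] %*% R, 2, shift, "+")
    ev2 <- detect_hbonds(rot)
    expect_identical(ev1[c("frame", "donor", "hydrogen", "acceptor")],
                     ev2[c("frame", "donor", "hydrogen", "acceptor")])
    expect_equal(ev1$distance, ev2$distance, tolerance = 1e-9)
  })
})

test_that("pair filters implement the three contact subsets", {
  top <- mixed_topology()
  pn <- select_pairs(top, "protein_nucleic")
  im <- select_pairs(top, "inter_monomer", monomers = c("MSH2", "MSH6"))
  pa <- select_pairs(top, "protein_any")
  thr_n <- 1; ala_n <- 4; cyt_n1 <- 7; ade <- 9; adp_o <- 10
  expect_true(pn(thr_n, adp_o))     # protein vs ADP kept (Thr781-ADP style)
  expect_true(pn(ala_n, cyt_n1))    # protein vs DNA kept (Ala517-Cyt style)
  expect_false(pn(thr_n, ala_n))    # protein-protein excluded here
  expect_true(im(thr_n, ala_n))     # spans MSH6-MSH2
  expect_false(im(thr_n, 2))        # same monomer excluded
  expect_false(im(thr_n, cyt_n1))   # protein-DNA excluded
  expect_true(pa(thr_n, cyt_n1))
  expect_false(pa(cyt_n1, ade))     # no protein member
  expect_error(select_pairs(top, "inter_monomer", monomers = c("MSH2", "NOPE")),
               "unknown segment")
})

test_that("binarize OR-collapses atom events into unordered residue-pair columns", {
  top <- mixed_topology()
  co <- array(0, dim = c(5, nrow(top), 3))
  traj <- trajectory(top, co, label = "A")
  # two atom-level events between the same residue pair in frame 1, opposite
  # donation directions between the same pair in frame 4, a lone event frame 4
  ev <- data.frame(frame = c(1, 1, 4, 4, 4),
                   donor = c(1, 1, 1, 10, 4),
                   hydrogen = c(2, 2, 2, 11, 5),
                   acceptor = c(10, 11, 10, 1, 7),
                   distance = 3, angle = 170)
  fm <- binarize(ev, traj)
  expect_equal(ncol(fm$data), 2)
  expect_true(all(fm$data %in% 0:1))
  thr_adp <- grep("THR781", fm$features, value = TRUE)
  expect_length(thr_adp, 1)                       # one unordered pair column
  expect_equal(unname(fm$data[, thr_adp]), c(1L, 0L, 0L, 1L, 0L))
  ala_cyt <- setdiff(fm$features, thr_adp)
  expect_equal(unname(fm$data[, ala_cyt]), c(0L, 0L, 0L, 1L, 0L))
  # every column has at least one nonzero entry
  expect_true(all(colSums(fm$data) >= 1))
  # filters drop events before collapsing
  fm_pn <- binarize(ev, traj, select_pairs(top, "protein_nucleic"))
  expect_equal(ncol(fm_pn$data), 2)
  fm_im <- binarize(ev, traj, select_pairs(top, "inter_monomer",
                                           monomers = c("MSH2", "MSH6")))
  expect_equal(ncol(fm_im$data), 0)
})

test_that("CSV round trip is lossless and malformed cells are located", {
  fm <- gen_hbond_matrix(hbond_plant_spec(n_frames = 7, n_features = 4, seed = 2))
  path <- tempfile(fileext = ".csv")
  write_matrix(fm, path)
  back <- read_matrix(path)
  expect_identical(back$data, fm$data)
  expect_identical(back$features, fm$features)
  expect_identical(back$labels, fm$labels)
  # header line preserved verbatim
  expect_match(readLines(path, n = 1), '^"frame","label"')
  # a non-binary cell is reported with its line number
  lines <- readLines(path)
  lines[3] <- sub(",0,", ",2,", lines[3])
  if (identical(lines[3], readLines(path)[3])) lines[3] <- sub(",1,", ",2,", lines[3])
  writeLines(lines, path)
  expect_error(read_matrix(path), "line 3")
})
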