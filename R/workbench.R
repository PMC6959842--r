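#' Demo pipeline configuration
#'
#' A self-contained synthetic configuration exercising every stage: a planted
#' H-bond matrix (3 damage classes, two discriminative bonds among background
#' bonds), a planted-well coordinate trajectory (flexible atoms, coupled
#' pairs, H-bond triads) and a planted stacking trajectory.  Sizes are kept
#' modest so the full pipeline runs in well under five minutes.
#'
#' @param seed master seed; every stochastic stage derives from it.
#' @param out_dir output directory.
#' @return a config list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 1, out_dir = tempfile("mdmotifs_demo_")) {
  list(
    seed = seed,
    out_dir = out_dir,
    synthetic = list(
      hbond = list(n_frames = 1500),
      trajectory = list(n_atoms = 24, n_frames = 300, K = 3,
                        flexible = 22:24, flex_scale = 4,
                        coupled = data.frame(a = 20, b = 21, rho = 1),
                        triads = data.frame(d = 16, h = 17, a = 18),
                        p_bond = c(0.9, 0.1, 0.1)),
      stacking = list(n_frames = 300)),
    stages = list(
      tree = list(prune_to = 2),
      clustering = list(p = 2, theta = 1, selection = "heavy"),
      kinetics = list(rmsf = TRUE, dccm = TRUE, fes_bins = 40,
                      temperature = 300),
      stacking = list(probe = "MSH6:PHE71", damaged = "DNAA:GUA4",
                      complement = "DNAB:CYT104")))
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stopf("config file '%s' not found", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a list or a YAML file path")
  config$seed <- config$seed %||% 1
  config$stages <- config$stages %||% list()
  config
}

config_hash <- function(config) {
  config$out_dir <- NULL  # hash the analysis parameters, not the run location
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  tf <- tempfile()
  writeLines(as.character(js), tf)
  h <- unname(tools::md5sum(tf))
  unlink(tf)
  h
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order -- input assembly
#' (synthetic generation or file loading with stride/strip/superpose), then
#' hydrogen bonds and decision tree, conformational clustering, kinetics
#' (RMSF, DCCM, PCA, free-energy landscape) and stacking analysis -- writing
#' every artifact (CSV tables, JSON models, a plain-text log) into the output
#' directory.  Identical config and seed produce byte-identical outputs.
#'
#' @param config a config list (see [demo_config()]) or path to a YAML file.
#'   Recognized top-level fields: `seed`, `out_dir`, `synthetic`
#'   (`hbond`, `trajectory`, `stacking` generator arguments), `inputs`
#'   (list of `topology`/`coords`/`stride`/`label` declarations), `stages`
#'   (`hbonds`, `tree`, `clustering`, `kinetics`, `stacking`).
#' @return a bundle: list of in-memory results plus `files` (paths) and `log`
#'   (character vector), invisibly usable by [summarize_bundle()].
#' @export
run_pipeline <- function(config) {
  config <- read_config(config)
  out <- config$out_dir %||% tempfile("mdmotifs_run_")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message("[mdmotifs] ", msg)
  }
  fail <- function(stage, e) stopf("stage '%s' failed: %s", stage, conditionMessage(e))
  bundle <- list(files = character(0))
  add_file <- function(p) bundle$files <<- c(bundle$files, p)
  say("run: seed %d, config hash %s", seed, config_hash(config))

  # ---- inputs ---------------------------------------------------------------
  traj <- NULL
  if (!is.null(config$synthetic$trajectory)) {
    args <- config$synthetic$trajectory
    if (!is.null(args$coupled)) args$coupled <- as.data.frame(args$coupled)
    if (!is.null(args$triads)) args$triads <- as.data.frame(args$triads)
    args$seed <- args$seed %||% (seed + 1)
    traj <- tryCatch(gen_trajectory(do.call(conformer_plant_spec, args)),
                     error = function(e) fail("synthetic trajectory", e))
    say("synthetic trajectory: %d frames x %d atoms", n_frames(traj), n_atoms(traj))
  } else if (!is.null(config$inputs)) {
    trajs <- lapply(config$inputs, function(inp) tryCatch({
      t <- load_trajectory(inp$topology, inp$coords, stride = inp$stride %||% 1,
                           label = inp$label %||% "system", dt = inp$dt %||% 10)
      t <- strip_solvent(t)
      superpose(t, inp$fit %||% "calpha")
    }, error = function(e) fail("trajectory_io", e)))
    traj <- tryCatch(concatenate(trajs, config$common_atoms %||% "identity"),
                     error = function(e) fail("concatenate", e))
    say("loaded %d trajectories: %d frames x %d atoms",
        length(trajs), n_frames(traj), n_atoms(traj))
  }

  # ---- hydrogen bonds + feature matrix -------------------------------------
  fm <- NULL
  if (!is.null(config$synthetic$hbond)) {
    args <- config$synthetic$hbond
    args$seed <- args$seed %||% seed
    fm <- tryCatch(gen_hbond_matrix(do.call(hbond_plant_spec, args)),
                   error = function(e) fail("synthetic hbond matrix", e))
    say("synthetic H-bond matrix: %d frames x %d features", nrow(fm$data), ncol(fm$data))
  } else if (!is.null(traj) && !is.null(config$stages$hbonds)) {
    st <- config$stages$hbonds
    crit <- hbond_criteria(st$max_dist %||% 3.2, st$min_angle %||% 120)
    ev <- tryCatch(detect_hbonds(traj, crit), error = function(e) fail("hbonds", e))
    filt <- if (!is.null(st$subset)) select_pairs(traj$topology, st$subset) else NULL
    fm <- tryCatch(binarize(ev, traj, filt), error = function(e) fail("hbonds", e))
    say("detected %d H-bond events -> %d residue-pair features", nrow(ev), ncol(fm$data))
  }
  if (!is.null(fm)) {
    write_matrix(fm, file.path(out, "feature_matrix.csv"))
    add_file(file.path(out, "feature_matrix.csv"))
    bundle$feature_matrix <- fm
  }

  # ---- decision tree --------------------------------------------------------
  if (!is.null(fm) && !is.null(config$stages$tree)) {
    st <- config$stages$tree
    tree <- tryCatch(fit_tree(fm), error = function(e) fail("tree", e))
    say("fitted tree: depth %d, loss %.4f", tree$depth, tree_loss(tree, fm))
    curve <- prune_curve(tree, fm)
    utils::write.csv(curve, file.path(out, "prune_curve.csv"), row.names = FALSE,
                     quote = FALSE)
    add_file(file.path(out, "prune_curve.csv"))
    export_tree(tree, file.path(out, "tree_full.json"))
    add_file(file.path(out, "tree_full.json"))
    pruned <- tree
    if (!is.null(st$prune_to) && st$prune_to < tree$depth) {
      pruned <- prune_tree(tree, tree$depth - st$prune_to)
      say("pruned to %d levels: loss %.4f, splits on [%s]",
          pruned$depth, tree_loss(pruned, fm),
          paste(tree_splits(pruned), collapse = ", "))
      export_tree(pruned, file.path(out, "tree_pruned.json"))
      add_file(file.path(out, "tree_pruned.json"))
    }
    bundle$tree <- tree; bundle$pruned <- pruned; bundle$prune_curve <- curve
  }

  # ---- conformational clustering -------------------------------------------
  if (!is.null(traj) && !is.null(config$stages$clustering)) {
    st <- config$stages$clustering
    X <- tryCatch(extract_features(traj, st$selection %||% "heavy",
                                   near = st$near, within = st$within %||% 10),
                  error = function(e) fail("clustering", e))
    model <- tryCatch(amorim_hennig(X, p = st$p %||% 2, theta = st$theta %||% 1),
                      error = function(e) fail("clustering", e))
    occ <- occupancy_table(model$labels, traj$label)
    say("Amorim-Hennig clustering: K = %d", model$K)
    utils::write.csv(as.data.frame.matrix(occ), file.path(out, "occupancy.csv"),
                     quote = FALSE)
    add_file(file.path(out, "occupancy.csv"))
    utils::write.csv(data.frame(frame = seq_along(model$labels),
                                system = traj$label, cluster = model$labels),
                     file.path(out, "cluster_labels.csv"), row.names = FALSE,
                     quote = FALSE)
    add_file(file.path(out, "cluster_labels.csv"))
    reps <- vapply(seq_len(model$K), function(k)
      representative_frame(X, model$labels, k), 0L)
    bundle$cluster_model <- model; bundle$occupancy <- occ
    bundle$representatives <- reps
  }

  # ---- kinetics -------------------------------------------------------------
  if (!is.null(traj) && !is.null(config$stages$kinetics)) {
    st <- config$stages$kinetics
    sub <- st$subset %||% "heavy"
    if (isTRUE(st$rmsf)) {
      prof <- tryCatch(rmsf(traj, sub), error = function(e) fail("kinetics", e))
      utils::write.csv(prof, file.path(out, "rmsf.csv"), row.names = FALSE,
                       quote = FALSE)
      add_file(file.path(out, "rmsf.csv"))
      bundle$rmsf <- prof
      say("RMSF: min %.3f, max %.3f A", min(prof$rmsf), max(prof$rmsf))
    }
    if (isTRUE(st$dccm)) {
      C <- tryCatch(dccm(traj, sub), error = function(e) fail("kinetics", e))
      utils::write.csv(as.data.frame(C), file.path(out, "dccm.csv"), quote = FALSE)
      add_file(file.path(out, "dccm.csv"))
      bundle$dccm <- C
    }
    if (!isFALSE(st$pca)) {
    basis <- tryCatch(pca_basis(traj, sub), error = function(e) fail("kinetics", e))
    utils::write.csv(data.frame(component = seq_along(basis$eigenvalues),
                                eigenvalue = basis$eigenvalues,
                                var_explained = basis$var_explained),
                     file.path(out, "pca_eigenvalues.csv"), row.names = FALSE,
                     quote = FALSE)
    add_file(file.path(out, "pca_eigenvalues.csv"))
    fes <- project_fes(pca_project(basis, traj, 2, sub),
                       bins = st$fes_bins %||% 100,
                       temperature = st$temperature %||% 300)
    write_fes(fes, file.path(out, "fes.csv"))
    add_file(file.path(out, "fes.csv"))
    bundle$pca <- basis; bundle$fes <- fes
    say("PCA: PC1+PC2 explain %.1f%% of variance",
        100 * sum(basis$var_explained[1:2]))
    }
  }

  # ---- stacking -------------------------------------------------------------
  if (!is.null(config$stages$stacking)) {
    st <- config$stages$stacking
    straj <- if (!is.null(config$synthetic$stacking)) {
      args <- config$synthetic$stacking
      args$seed <- args$seed %||% (seed + 2)
      tryCatch(do.call(gen_stacking_trajectory, args),
               error = function(e) fail("synthetic stacking", e))
    } else traj
    if (!is.null(straj)) {
      res <- tryCatch(
        stacking_fractions(straj, st$probe, st$damaged, st$complement,
                           stacking_criteria(st$max_dist %||% 5,
                                             st$max_angle %||% 30,
                                             st$max_offset %||% 2)),
        error = function(e) fail("stacking", e))
      utils::write.csv(as.data.frame.matrix(res$fractions),
                       file.path(out, "stacking_fractions.csv"), quote = FALSE)
      add_file(file.path(out, "stacking_fractions.csv"))
      bundle$stacking <- res
      if (!is.null(straj$state)) bundle$stacking_truth <- straj$state
    }
  }

  writeLines(log, file.path(out, "run.log"))
  add_file(file.path(out, "run.log"))
  bundle$log <- log
  bundle$out_dir <- out
  bundle$seed <- seed
  invisible(bundle)
}

#' Distinct split features of a tree, in pre-order
#'
#' @param tree a `damage_tree`.
#' @return character vector of split feature descriptors.
#' @export
tree_splits <- function(tree) {
  acc <- character(0)
  walk <- function(node) {
    if (node$type == "split") {
      acc <<- c(acc, tree$features[node$feature])
      walk(node$yes); walk(node$no)
    }
  }
  walk(tree$root)
  unique(acc)
}

#' Plain-text report of a pipeline bundle
#'
#' Renders the decision-tree flow (split residue pairs and leaf class
#' probabilities), the prune curve, per-system cluster occupancies, RMSF
#' extrema and stacking fractions as a readable report; missing tables
#' produce warnings rather than errors.
#'
#' @param bundle the result of [run_pipeline()].
#' @return character vector of report lines (also printed).
#' @export
summarize_bundle <- function(bundle) {
  lines <- c("mdmotifs pipeline report", strrep("=", 24),
             sprintf("seed: %s", bundle$seed %||% "?"))
  warn <- function(what) sprintf("warning: %s not present in bundle", what)
  if (!is.null(bundle$pruned)) {
    lines <- c(lines, "", "decision tree (pruned):",
               sprintf("  splits on: %s",
                       paste(tree_splits(bundle$pruned), collapse = ", ")))
    lp <- leaf_probabilities(bundle$pruned)
    pcols <- grep("^p_", names(lp), value = TRUE)
    for (i in seq_len(nrow(lp)))
      lines <- c(lines, sprintf("  leaf %d [%s] -> %s (%s)",
        lp$leaf[i], lp$path[i], lp$class[i],
        paste(sprintf("%s %.1f%%", sub("^p_", "", pcols),
                      100 * unlist(lp[i, pcols])), collapse = ", ")))
  } else lines <- c(lines, warn("decision tree"))
  if (!is.null(bundle$prune_curve)) {
    lines <- c(lines, "", "prune curve (levels removed -> loss):",
               sprintf("  %d -> %.4f", bundle$prune_curve$levels_removed,
                       bundle$prune_curve$loss))
  }
  if (!is.null(bundle$occupancy)) {
    occ <- bundle$occupancy
    lines <- c(lines, "", "cluster occupancy (% of system frames):")
    for (s in rownames(occ)) {
      nz <- which(occ[s, ] > 0)
      lines <- c(lines, sprintf("  %s: %s", s,
        paste(sprintf("%s (%.2f%%)", sub("cluster_", "cluster ", colnames(occ)[nz]),
                      occ[s, nz]), collapse = ", ")))
    }
  } else lines <- c(lines, warn("cluster occupancy"))
  if (!is.null(bundle$rmsf)) {
    pk <- bundle$rmsf[which.max(bundle$rmsf$rmsf), ]
    lines <- c(lines, "", sprintf("RMSF: peak %.3f A at %s; median %.3f A",
                                  pk$rmsf, pk$residue, stats::median(bundle$rmsf$rmsf)))
  } else lines <- c(lines, warn("RMSF"))
  if (!is.null(bundle$stacking)) {
    fr <- bundle$stacking$fractions
    lines <- c(lines, "", "stacking-state fractions:")
    for (s in rownames(fr))
      lines <- c(lines, sprintf("  %s: %s", s,
        paste(sprintf("%s %.2f%%", colnames(fr), 100 * fr[s, ]), collapse = ", ")))
  } else lines <- c(lines, warn("stacking"))
  cat(lines, sep = "\n")
  invisible(lines)
}
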