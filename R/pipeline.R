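# One-config orchestration of the full analysis: generate (or load) the
# three liganded states, compute force tables, difference networks, stress
# and convergence, entropies, order parameters, collective motions and
# distance classification, and write everything under a run directory with a
# provenance manifest.

# tiny FNV-1a string hash for the manifest (no external digest dependency)
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256                       # xor touches the low byte only
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  # format as 8 hex digits without requiring integer range
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

#' Read and validate a pipeline run configuration
#'
#' YAML configuration with explicit unit suffixes in field names
#' (`temperature_K`, `cutoffs_pN`, `window_ps`, ...). Either a `model` block
#' (synthetic dimer generation) or a `states` block with trajectory file
#' paths must be present; all referenced paths must exist at validation time.
#'
#' @param path YAML config path
#' @return validated config list (class `run_config`)
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$config_text <- paste(readLines(path), collapse = "\n")
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a config list (as from yaml)
#' @export
validate_run_config <- function(cfg) {
  need <- function(x, name) if (is.null(x)) stop("config missing field: ", name)
  need(cfg$seed, "seed")
  need(cfg$temperature_K, "temperature_K")
  if (cfg$temperature_K <= 0) stop("temperature_K must be positive")
  if (is.null(cfg$model) && is.null(cfg$states)) {
    stop("config needs a `model` (synthetic) or `states` (trajectory paths) block")
  }
  if (!is.null(cfg$states)) {
    for (st in names(cfg$states)) {
      p <- cfg$states[[st]]$traj
      need(p, paste0("states$", st, "$traj"))
      if (!file.exists(p)) {
        stop("trajectory for state '", st, "' not found: ", p)
      }
    }
    p <- cfg$topology_pdb
    need(p, "topology_pdb")
    if (!file.exists(p)) stop("topology PDB not found: ", p)
  }
  if (!is.null(cfg$model)) {
    need(cfg$model$n_res_per_protomer, "model$n_res_per_protomer")
  }
  need(cfg$sampling$n_replicas, "sampling$n_replicas")
  need(cfg$sampling$n_frames, "sampling$n_frames")
  if (is.null(cfg$analysis$cutoffs_pN)) cfg$analysis$cutoffs_pN <- c(40, 50)
  if (is.null(cfg$analysis$window_ps)) cfg$analysis$window_ps <- 3000
  if (is.null(cfg$analysis$selection)) cfg$analysis$selection <- "mainchain"
  class(cfg) <- c("run_config", "list")
  cfg
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Synthetic mode: builds the apo dimer, adds one ligand (cap1) and its
#' C2-partner ligand (cap2), samples each state, and runs every analysis
#' stage; outputs land under `out_dir` as TSV tables, PDB/PyMOL files, plots
#' and a provenance manifest (config echo + hash, seeds, package version).
#' Reruns with the same config produce byte-identical numeric outputs.
#'
#' @param config a `run_config` (or path to a YAML config)
#' @param out_dir output directory (created; default from the config)
#' @return invisibly, a list of the main result objects
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  if (is.null(out_dir)) out_dir <- if (!is.null(config$output)) config$output else "dynallo_run"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  Tk <- config$temperature_K
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (!is.null(config$model)) {
    mc <- config$model
    res <- stage("generate", {
      apo <- build_enm_dimer(
        n_res_per_protomer = mc$n_res_per_protomer,
        contact_cutoff = mc$contact_cutoff_nm %||% 1.2,
        k_default = mc$k_default %||% 500,
        seed = config$seed,
        nodes_per_residue = mc$nodes_per_residue %||% 4
      )
      n <- apo$n_res_per_protomer
      pocketA <- mc$pocket_residues_A %||% utils::tail(seq_len(n), 3)
      pocketB <- pocketA + n
      klig <- mc$k_ligand %||% 800
      cap1 <- add_ligand(apo, pocketA, k_ligand = klig)
      cap2 <- add_ligand(cap1, pocketB, k_ligand = klig)
      list(apo = apo, cap1 = cap1, cap2 = cap2)
    })
    models <- res
    write_pdb(models$apo, file.path(out_dir, "model_apo.pdb"))
    write_pdb(models$cap2, file.path(out_dir, "model_cap2.pdb"))
    write_model_sidecar(models$cap2, file.path(out_dir, "model_ground_truth.yaml"))

    ensembles <- stage("sample", {
      lapply(seq_along(models), function(i) {
        spec <- ensemble_spec(
          n_replicas = config$sampling$n_replicas,
          n_frames = config$sampling$n_frames,
          temperature = Tk,
          seed = replica_seed(config$seed, 1000 + i),
          dt_ps = config$sampling$dt_ps %||% 20
        )
        sample_ensemble(models[[i]], spec, state = names(models)[i])
      })
    })
    names(ensembles) <- names(models)

    tables <- stage("forces", {
      lapply(names(models), function(st) {
        pf <- pairwise_forces_from_model(models[[st]], ensembles[[st]])
        average_table(residue_pair_forces(pf, include_ligand = FALSE))
      })
    })
    names(tables) <- names(models)

    networks <- stage("networks", {
      pairs <- list(c("apo", "cap1"), c("cap1", "cap2"))
      out <- list()
      for (pr in pairs) {
        d <- force_difference(tables[[pr[1]]], tables[[pr[2]]])
        .write_tsv(d, file.path(out_dir, sprintf("forcediff_%s_%s.tsv",
                                                 pr[2], pr[1])))
        for (co in config$analysis$cutoffs_pN) {
          nw <- threshold_network(d, co, keep = "largest")
          base <- sprintf("network_%s_%s_%gpN", pr[2], pr[1], co)
          write_network(nw, file.path(out_dir, paste0(base, ".tsv")),
                        pml_path = file.path(out_dir, paste0(base, ".pml")),
                        pdb_name = "model_cap2")
          out[[base]] <- nw
        }
      }
      out
    })

    stress <- stage("stress", {
      prof <- lapply(tables, punctual_stress)
      for (st in names(prof)) {
        .write_tsv(prof[[st]], file.path(out_dir, sprintf("stress_%s.tsv", st)))
      }
      conv <- convergence_curve(tables$cap2, seed = config$seed)
      .write_tsv(conv, file.path(out_dir, "convergence_cap2.tsv"))
      grDevices::pdf(file.path(out_dir, "stress_convergence.pdf"), 7, 5)
      graphics::plot(conv$k, conv$mean_abs_diff_pN, type = "b",
                     xlab = "replicas in subset",
                     ylab = "mean |protomer stress difference| (pN)",
                     main = "convergence of the protomer stress difference")
      grDevices::dev.off()
      list(profiles = prof, convergence = conv)
    })

    entropies <- stage("entropy", {
      rows <- list()
      ers <- list()
      for (sel in c("mainchain", "full")) {
        # "full" means the full protein: ligand pseudo-atoms are excluded so
        # states with different ligand counts stay comparable
        sel_atoms <- if (sel == "full") "protein" else sel
        for (st in names(models)) {
          qh <- quasi_harmonic_entropy(ensembles[[st]], selection = sel_atoms,
                                       temperature = Tk)
          fc <- force_covariance_entropy(
            atomic_forces_from_model(models[[st]], ensembles[[st]]),
            selection = sel_atoms,
            temperature = Tk)
          ers[[paste(sel, st, "QH")]] <- qh
          ers[[paste(sel, st, "FC")]] <- fc
        }
        for (pr in list(c("apo", "cap1"), c("cap1", "cap2"), c("apo", "cap2"))) {
          for (est in c("QH", "FC")) {
            dd <- entropy_difference(ers[[paste(sel, pr[1], est)]],
                                     ers[[paste(sel, pr[2], est)]],
                                     temperature = Tk, n_boot = 100,
                                     seed = config$seed)
            rows[[length(rows) + 1]] <- data.frame(
              event = paste0(pr[2], "-", pr[1]), estimator = est,
              selection = sel, minus_TdS_kcal = dd$minus_TdS_kcal,
              se = if (is.null(dd$se)) NA_real_ else dd$se)
          }
        }
      }
      tab <- do.call(rbind, rows)
      .write_tsv(tab, file.path(out_dir, "entropy_table.tsv"))
      tab
    })

    orderp <- stage("order_parameters", {
      out <- list()
      if (!is.null(models$apo$topology$axes)) {
        prof <- lapply(names(models), function(st) {
          methyl_axis_s2(ensembles[[st]],
                         topology = models[[st]]$topology,
                         window_ps = config$analysis$window_ps)
        })
        names(prof) <- names(models)
        for (pr in list(c("apo", "cap1"), c("cap1", "cap2"))) {
          d <- order_parameter_difference(prof[[pr[1]]], prof[[pr[2]]])
          .write_tsv(d, file.path(out_dir,
                                  sprintf("s2axis_diff_%s_%s.tsv", pr[2], pr[1])))
        }
        out$s2 <- prof
      }
      if (!is.null(models$apo$topology$dihedrals)) {
        dop <- lapply(names(models), function(st) {
          dihedral_order_parameters(ensembles[[st]],
                                    topology = models[[st]]$topology)
        })
        names(dop) <- names(models)
        for (pr in list(c("apo", "cap1"), c("cap1", "cap2"))) {
          d <- order_parameter_difference(dop[[pr[1]]], dop[[pr[2]]])
          .write_tsv(d, file.path(out_dir,
                                  sprintf("dihedral_op_diff_%s_%s.tsv", pr[2], pr[1])))
        }
        out$dihedral <- dop
      }
      out
    })

    motions <- stage("motions", {
      eig <- pca_ensemble(ensembles$apo, selection = "mainchain")
      proj <- lapply(ensembles, function(e) project_frames(e, eig, mode = 1))
      df <- do.call(rbind, lapply(names(proj), function(st) {
        data.frame(state = st, projection_nm = proj[[st]])
      }))
      .write_tsv(df, file.path(out_dir, "projection_mode1.tsv"))
      grDevices::pdf(file.path(out_dir, "projection_mode1.pdf"), 7, 5)
      cols <- c(apo = "black", cap1 = "blue", cap2 = "orange")
      dens <- lapply(proj, stats::density)
      graphics::plot(NULL, xlim = range(unlist(proj)),
                     ylim = c(0, max(vapply(dens, function(d) max(d$y), 1))),
                     xlab = "projection on apo mode 1 (nm)", ylab = "density")
      for (st in names(dens)) graphics::lines(dens[[st]], col = cols[[st]])
      graphics::legend("topright", legend = names(dens),
                       col = cols[names(dens)], lty = 1)
      grDevices::dev.off()
      rb <- rmsf_bfactor(ensembles$cap2, selection = "calpha")
      .write_tsv(rb, file.path(out_dir, "rmsf_bfactor_cap2.tsv"))
      list(eig = eig, projections = proj, rmsf = rb)
    })

    metrics <- stage("metrics", {
      mp <- config$analysis$mindist_pair
      if (is.null(mp)) {
        n <- models$apo$n_res_per_protomer
        mp <- c(paste0("A:", max(1, n %/% 2)), paste0("B:", max(1, n %/% 2)))
      }
      dists <- lapply(ensembles, function(e) {
        minimal_distance(e, mp[1], mp[2])
      })
      cls <- tryCatch(
        classify_by_inflections(dists$cap2, dists),
        error = function(e) NULL)
      if (!is.null(cls)) {
        .write_tsv(cls, file.path(out_dir, "mindist_classification.tsv"))
      }
      df <- do.call(rbind, lapply(names(dists), function(st) {
        data.frame(state = st, mindist_A = dists[[st]])
      }))
      .write_tsv(df, file.path(out_dir, "mindist_series.tsv"))
      list(distances = dists, classification = cls)
    })

    results <- list(models = models, ensembles = ensembles, tables = tables,
                    networks = networks, stress = stress,
                    entropies = entropies, order_parameters = orderp,
                    motions = motions, metrics = metrics)
  } else {
    # trajectory-file mode: coordinate-based analyses only
    results <- stage("load", {
      topo <- read_pdb(config$topology_pdb)$topology
      ensembles <- lapply(names(config$states), function(st) {
        e <- read_traj(config$states[[st]]$traj, topology = topo)
        e$state <- st
        e
      })
      names(ensembles) <- names(config$states)
      eig <- pca_ensemble(ensembles[[1]], selection = "mainchain")
      for (st in names(ensembles)) {
        pr <- project_frames(ensembles[[st]], eig, mode = 1)
        .write_tsv(data.frame(state = st, projection_nm = pr),
                   file.path(out_dir, sprintf("projection_%s.tsv", st)))
      }
      list(ensembles = ensembles, eig = eig)
    })
  }

  cfg_text <- config$config_text %||% yaml::as.yaml(unclass(config))
  manifest <- list(
    package = "dynallo",
    version = as.character(utils::packageVersion("dynallo")),
    seed = config$seed,
    config_hash = .fnv1a(cfg_text),
    config = yaml::yaml.load(cfg_text)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
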