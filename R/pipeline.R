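#' Default pipeline configuration
#'
#' Returns the full configuration list with every numeric convention of
#' the comparative analysis as defaults: H-bond criteria (3.5 Angstrom
#' / 30 degrees / polar only), the 10% occupancy filter, the 0.8
#' importance threshold, the 2 kJ/mol per-residue energy threshold, the
#' 1 / 3 Angstrom ordered/disordered RMSF thresholds, and per-analysis
#' frame counts. Any element can be overridden by the user config.
#'
#' @return nested list of defaults
#' @export
default_config <- function() {
  list(
    window = NULL,                      # c(t0, t1) ns; NULL = full span
    frames = list(energy = 100L, ml = NULL, ss = 25L, bridges = 25L),
    hbond = list(d_DA_max = 3.5, angle_max = 30, polar_only = TRUE),
    thresholds = list(occupancy_min_pct = 10, importance = 0.8, ddg = 2,
                      rmsf_ordered = 1, rmsf_disordered = 3),
    ml_iterations = 20L,
    eps_r = 1,
    sasa_n_points = 240L,
    test_directions = list(default = "greater"),
    interfaces = NULL                   # interface ids to score; NULL = all
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Run the full comparative pipeline
#'
#' Executes geometry -> hydrogen bonds -> energetics -> statistics ->
#' ML importance -> residue classification over two or more
#' state-labelled replicate ensembles, writing every stage table under
#' `outdir` and returning a run report. All randomness derives from
#' `seed`; identical config + inputs give byte-identical outputs.
#'
#' States come either from a `synthetic` block (a [synthetic_spec()]
#' argument list; two states generated in memory) or from a `states`
#' list of `label` + `trajectories` (multi-model PDB paths) with a
#' `param_table` and the topology read from the first file. The first
#' state is the reference for every comparison.
#'
#' @param config list or YAML path; see [default_config()] for the
#'   tunable blocks. Must contain `synthetic` or `states` (+
#'   `param_table`), and `domain_map` (path or list) when interfaces
#'   are scored.
#' @param outdir output directory
#' @param seed integer seed for every stochastic stage
#' @return object of class `run_report`: `manifest` (stage -> files),
#'   `summaries` (in-memory key results), `log` (character)
#' @export
run_pipeline <- function(config, outdir, seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- NULL
  emit <- function(stage, file) {
    manifest <<- rbind(manifest, data.frame(stage = stage, file = file,
                                            stringsAsFactors = FALSE))
  }
  stage <- "validate"
  on_fail <- function(e) {
    stop(sprintf("pipeline failed in stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    # ---- validation & input loading -------------------------------------
    say("run_pipeline: seed = %d", seed)
    for (nm in c("d_DA_max", "angle_max")) {
      say("default in effect: hbond %s = %s", nm, cfg$hbond[[nm]])
    }
    for (nm in names(cfg$thresholds)) {
      say("default in effect: threshold %s = %s", nm, cfg$thresholds[[nm]])
    }
    if (!is.null(cfg$synthetic)) {
      spec <- do.call(synthetic_spec, c(cfg$synthetic, list(seed = seed)))
      stage <- "simulate"
      gen <- generate_ensembles(spec)
      ensembles <- list(gen$ensemble_a, gen$ensemble_b)
      topology <- gen$topology
      ref_coords <- gen$ref_coords
      say("generated synthetic ensembles: %s vs %s",
          gen$ensemble_a$state_label, gen$ensemble_b$state_label)
    } else {
      if (is.null(cfg$states)) stop("config needs 'synthetic' or 'states'")
      paths <- unlist(lapply(cfg$states, `[[`, "trajectories"))
      missing <- paths[!file.exists(paths)]
      if (length(missing)) stop("missing trajectory file(s): ",
                                paste(missing, collapse = ", "))
      if (is.null(cfg$param_table)) {
        stop("config requests energetics but lists no 'param_table'")
      }
      if (!file.exists(cfg$param_table)) {
        stop("missing parameter table: ", cfg$param_table)
      }
      stage <- "load"
      first <- read_structure(cfg$states[[1L]]$trajectories[1L])
      topology <- read_param_table(cfg$param_table, first$topology)
      ref_coords <- first$coords
      ensembles <- lapply(cfg$states, function(s) {
        md_ensemble(s$label, lapply(s$trajectories, read_trajectory,
                                    topology = topology))
      })
    }
    dmap <- if (!is.null(cfg$domain_map)) load_domain_map(cfg$domain_map) else NULL
    omask <- if (!is.null(dmap)) order_mask(dmap, topology) else NULL
    labels <- vapply(ensembles, `[[`, "", "state_label")
    ref_label <- labels[1L]
    windowed <- lapply(ensembles, function(e) {
      lapply(e$replicates, function(tr) {
        if (is.null(cfg$window)) tr else {
          window_frames(tr, cfg$window,
                        sum(tr$times >= cfg$window[1] & tr$times <= cfg$window[2]))
        }
      })
    })
    summaries <- list()

    # ---- geometry: RMSF profiles and flexible regions -------------------
    stage <- "rmsf"
    ca <- select_atoms(topology, elety = "CA")
    profiles <- lapply(seq_along(ensembles), function(i) {
      cat_traj <- concatenate_trajectories(windowed[[i]])
      rmsf_profile(cat_traj, ref_coords, selection = ca, fit_selection = ca)
    })
    names(profiles) <- labels
    flags <- list()
    for (i in seq_along(ensembles)[-1L]) {
      fl <- flag_flexible_regions(profiles[[1L]], profiles[[i]], omask,
                                  thresholds = c(ordered = cfg$thresholds$rmsf_ordered,
                                                 disordered = cfg$thresholds$rmsf_disordered))
      flags[[labels[i]]] <- fl
      f <- file.path(outdir, sprintf("rmsf_%s_vs_%s.csv", ref_label, labels[i]))
      write_flex_profile(fl, f)
      emit("rmsf", f)
      say("rmsf: %s vs %s, %d flagged residue(s)", ref_label, labels[i],
          sum(fl$flag))
    }
    summaries$rmsf <- flags

    # ---- secondary structure fractions ----------------------------------
    stage <- "ss"
    for (i in seq_along(ensembles)) {
      cat_traj <- concatenate_trajectories(windowed[[i]])
      n_ss <- min(cfg$frames$ss %||% n_frames(cat_traj), n_frames(cat_traj))
      samp <- window_frames(cat_traj, range(cat_traj$times) + c(-1e-9, 1e-9), n_ss)
      ssf <- ss_fractions(samp)
      f <- file.path(outdir, sprintf("ss_fractions_%s.csv", labels[i]))
      utils::write.csv(as.data.frame(ssf), f, row.names = FALSE)
      emit("ss", f)
      say("ss: %s over %d frames", labels[i], n_ss)
    }

    # ---- hydrogen-bond occupancy ---------------------------------------
    stage <- "hbonds"
    crit <- hbond_criteria(cfg$hbond$d_DA_max, cfg$hbond$angle_max,
                           cfg$hbond$polar_only)
    occ_tables <- list()
    for (i in seq_along(ensembles)) {
      for (r in seq_along(windowed[[i]])) {
        occ_tables[[sprintf("%s_rep%d", labels[i], r)]] <-
          hbond_occupancy(windowed[[i]][[r]], crit)
      }
    }
    filt <- filter_occupancy(occ_tables, cfg$thresholds$occupancy_min_pct)
    f <- file.path(outdir, "hbond_occupancy.csv")
    utils::write.csv(as.data.frame(filt), f, row.names = FALSE)
    emit("hbonds", f)
    say("hbonds: %d row(s) pass the %s%% filter", nrow(filt),
        cfg$thresholds$occupancy_min_pct)
    summaries$hbonds <- filt

    # ---- binding energetics --------------------------------------------
    stage <- "energy"
    part_a <- select_atoms(topology, chain = cfg$partition$a_chain %||% "A")
    part_b <- select_atoms(topology, chain = cfg$partition$b_chain %||% "B")
    bfe_values <- lapply(seq_along(ensembles), function(i) {
      vapply(windowed[[i]], function(tr) {
        n_e <- min(cfg$frames$energy %||% n_frames(tr), n_frames(tr))
        samp <- window_frames(tr, range(tr$times) + c(-1e-9, 1e-9), n_e)
        suppressMessages(
          binding_energy(samp, part_a, part_b, eps_r = cfg$eps_r,
                         sasa_n_points = cfg$sasa_n_points))$mean
      }, numeric(1))
    })
    names(bfe_values) <- labels
    bfe_sum <- summarize_bfe(bfe_values)
    tests <- NULL
    for (i in seq_along(ensembles)[-1L]) {
      dir_i <- cfg$test_directions[[labels[i]]] %||% cfg$test_directions$default
      tt <- mann_whitney_exact(bfe_values[[1L]], bfe_values[[i]],
                               alternative = dir_i)
      tests <- rbind(tests, data.frame(
        comparison = sprintf("%s vs %s", ref_label, labels[i]),
        direction = dir_i, U = unname(tt$statistic), p = tt$p.value,
        method = tt$method, stringsAsFactors = FALSE))
    }
    f <- file.path(outdir, "bfe_summary.csv")
    utils::write.csv(cbind(bfe_sum$states,
                           do.call(rbind, lapply(bfe_values, function(v) {
                             stats::setNames(as.data.frame(t(v)),
                                             paste0("rep", seq_along(v)))
                           }))), f, row.names = FALSE)
    emit("energy", f)
    f <- file.path(outdir, "bfe_tests.csv")
    utils::write.csv(tests, f, row.names = FALSE)
    emit("energy", f)
    say("energy: state means %s", paste(sprintf("%s %.1f", bfe_sum$states$state,
                                                bfe_sum$states$mean),
                                        collapse = ", "))
    summaries$bfe <- list(summary = bfe_sum, tests = tests,
                          values = bfe_values)

    # ---- per-residue decomposition & deltas -----------------------------
    stage <- "decompose"
    decomps <- lapply(seq_along(ensembles), function(i) {
      tr <- concatenate_trajectories(windowed[[i]])
      n_e <- min(cfg$frames$energy %||% n_frames(tr), n_frames(tr))
      samp <- window_frames(tr, range(tr$times) + c(-1e-9, 1e-9), n_e)
      suppressMessages(
        per_residue_decomposition(samp, part_a, part_b, eps_r = cfg$eps_r,
                                  sasa_n_points = cfg$sasa_n_points))
    })
    names(decomps) <- labels
    ddg_tables <- list()
    for (i in seq_along(ensembles)[-1L]) {
      dd <- residue_delta_bfe(decomps[[1L]], decomps[[i]])
      ddg_tables[[labels[i]]] <- dd
      f <- file.path(outdir, sprintf("ddg_%s_vs_%s.csv", ref_label, labels[i]))
      utils::write.csv(dd, f, row.names = FALSE)
      emit("decompose", f)
    }
    summaries$ddg <- ddg_tables

    # ---- ML importance & categories -------------------------------------
    if (!is.null(dmap) && !is.null(dmap$interfaces) && length(ensembles) >= 2L) {
      stage <- "ml-importance"
      ids <- cfg$interfaces %||% dmap$interfaces$id
      for (i in seq_along(ensembles)[-1L]) {
        for (id in ids) {
          feats <- extract_pair_features(ensembles[[1L]], ensembles[[i]], dmap,
                                         id,
                                         frames_per_replicate = cfg$frames$ml,
                                         window = cfg$window)
          imp <- residue_importance(feats, n_iter = cfg$ml_iterations,
                                    seed = seed)
          f <- file.path(outdir, sprintf("importance_if%s_%s.csv", id, labels[i]))
          utils::write.csv(as.data.frame(imp), f, row.names = FALSE)
          emit("ml-importance", f)
          stage <- "categorize"
          cats <- classify_categories(imp, ddg_tables[[labels[i]]],
                                      flags[[labels[i]]],
                                      ml_threshold = cfg$thresholds$importance,
                                      ddg_threshold = cfg$thresholds$ddg)
          f <- file.path(outdir, sprintf("categories_if%s_%s.csv", id, labels[i]))
          utils::write.csv(cats, f, row.names = FALSE)
          emit("categorize", f)
          say("interface %s (%s): %d category-3 residue(s)", id, labels[i],
              sum(cats$category == "3"))
          summaries$categories[[sprintf("if%s_%s", id, labels[i])]] <- cats
          summaries$importance[[sprintf("if%s_%s", id, labels[i])]] <- imp
          stage <- "ml-importance"
        }
      }
    }

    # ---- report ---------------------------------------------------------
    stage <- "report"
    f <- file.path(outdir, "run_log.txt")
    writeLines(log, f)
    emit("report", f)
    f <- file.path(outdir, "manifest.json")
    jsonlite::write_json(manifest, f, auto_unbox = TRUE)
    emit("report", f)
    structure(list(manifest = manifest, summaries = summaries, log = log),
              class = "run_report")
  }, error = on_fail)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d output file(s) across %d stage(s)\n",
              nrow(x$manifest), length(unique(x$manifest$stage))))
  invisible(x)
}

#' Reproduce replicate summary tables and their exact statistics
#'
#' Takes a replicate table (states in columns, one row per replicate
#' mean binding energy), and reports each state's mean +/- sd, the
#' rounded-mean deltas against the reference state, and the exact
#' one-tailed Mann-Whitney p-value for each configured comparison.
#'
#' @param values CSV path or data.frame; columns are states (first =
#'   reference unless `comparisons` says otherwise), rows replicates
#' @param comparisons data.frame with columns `reference`, `modified`,
#'   `alternative` (`"greater"`/`"less"`); default compares the first
#'   state to each other with `"greater"`
#' @return object of class `table_summary`: `states` (mean, sd,
#'   rounded mean), `deltas` (rounded + raw), `tests` (U, p, direction)
#' @export
reproduce_tables <- function(values, comparisons = NULL) {
  if (is.character(values)) {
    values <- utils::read.csv(values, check.names = FALSE)
  }
  num_ok <- vapply(values, is.numeric, logical(1))
  if (!all(num_ok)) {
    bad <- which(!num_ok)[1L]
    row <- which(is.na(suppressWarnings(as.numeric(values[[bad]]))))[1L]
    stop(sprintf("non-numeric cell at row %s, column '%s'",
                 row %||% "?", names(values)[bad]))
  }
  cols <- as.list(values)
  if (is.null(comparisons)) {
    comparisons <- data.frame(reference = names(cols)[1L],
                              modified = names(cols)[-1L],
                              alternative = "greater",
                              stringsAsFactors = FALSE)
  }
  sums <- lapply(cols, replicate_summary)
  states <- data.frame(state = names(cols),
                       mean = vapply(sums, `[[`, numeric(1), "mean"),
                       sd = vapply(sums, `[[`, numeric(1), "sd"),
                       rounded_mean = vapply(sums, `[[`, numeric(1), "rounded_mean"),
                       n = vapply(sums, `[[`, numeric(1), "n"),
                       stringsAsFactors = FALSE, row.names = NULL)
  deltas <- NULL; tests <- NULL
  for (k in seq_len(nrow(comparisons))) {
    ref <- comparisons$reference[k]; mod <- comparisons$modified[k]
    alt <- comparisons$alternative[k]
    if (!ref %in% names(cols) || !mod %in% names(cols)) {
      stop("comparison references unknown state column")
    }
    deltas <- rbind(deltas, data.frame(
      reference = ref, modified = mod,
      delta_rounded = state_delta(sums[[ref]], sums[[mod]], "rounded"),
      delta_raw = state_delta(sums[[ref]], sums[[mod]], "raw"),
      stringsAsFactors = FALSE))
    tt <- mann_whitney_exact(cols[[ref]], cols[[mod]], alternative = alt)
    tests <- rbind(tests, data.frame(
      reference = ref, modified = mod, alternative = alt,
      U = unname(tt$statistic), p = tt$p.value, p_rounded = tt$p_rounded,
      method = tt$method, stringsAsFactors = FALSE))
  }
  structure(list(states = states, deltas = deltas, tests = tests),
            class = "table_summary")
}

#' @export
print.table_summary <- function(x, ...) {
  cat("Replicate table summary (kJ/mol)\n")
  for (i in seq_len(nrow(x$states))) {
    s <- x$states[i, ]
    cat(sprintf("  %-14s mean %8.1f +/- %5.1f (n = %d)\n",
                s$state, s$mean, s$sd, s$n))
  }
  for (i in seq_len(nrow(x$deltas))) {
    d <- x$deltas[i, ]
    t <- x$tests[i, ]
    cat(sprintf("  Delta %s -> %s: %6.1f   one-tailed exact p = %.3f (%s)\n",
                d$reference, d$modified, d$delta_rounded, t$p, t$alternative))
  }
  invisible(x)
}
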