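## End-to-end study orchestration: build topology -> generate disordered
## tails -> run seeded production simulations -> analyse translocation.
##
## Every random stream is derived from one master seed by a documented
## splitting rule, so a report bundle is a pure function of (config, seed,
## code version).

## deterministic seed splitting (Lehmer-style mixing, kept inside 32-bit
## signed range)
derive_seeds <- function(master, n) {
  vapply(seq_len(n), function(i) {
    as.integer((as.double(master %% 65536L) * 48271 + i * 16807) %% 2147483629)
  }, integer(1))
}

.pipeline_defaults <- function() {
  list(
    mode = "toy",
    toy_spec = list(),
    shadow = list(contact_cutoff = 0.6, shadow_radius = 0.1,
                  min_residue_separation = 3, bonded_radius = 0.05),
    scale_factor = 0.95,
    dihedral_contact_ratio = 0,
    langevin = list(reduced_temperature = 0.582, timestep = 0.002,
                    friction = 1.0, n_steps = 120000L, save_interval = 500L),
    tail_generation = list(high_T = 1.0, restraint_k = 1000,
                           stride = 4500L, equilibration_strides = 2L,
                           interior_only = TRUE),
    n_starting_conformations = 4L,
    runs_per_conformation = 5L,
    analysis = list(formed_factor = 1.5, translocation_threshold = 0.8,
                    contact_scope = "intermolecular_only",
                    histogram_bins = 50L, peak_prominence = 0.005),
    seed = 1L,
    outdir = NULL,
    write_trajectories = FALSE)
}

#' Pipeline configuration
#'
#' Builds a configuration list for [run_pipeline()] from named overrides of
#' the documented defaults (see [validate_config()] for the full surface).
#'
#' @param ... named overrides, e.g. `seed = 7`,
#'   `langevin = list(n_steps = 50000)`.
#' @export
pipeline_config <- function(...) {
  validate_config(list(...))
}

#' Validate and normalise a pipeline configuration
#'
#' Unknown keys are rejected; defaults are filled in (nested blocks merge
#' key-wise); value constraints are checked and all violations are reported
#' together.  Omitting the production temperature fills in the default
#' 0.582 with a logged notice.
#'
#' @param config named list of overrides, or a path to a YAML file.
#' @return normalised configuration of class `pipeline_config`, with a
#'   `notices` attribute.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  defs <- .pipeline_defaults()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  notices <- character()
  nested <- c("toy_spec", "shadow", "langevin", "tail_generation", "analysis")
  for (blk in nested) {
    if (!is.null(config[[blk]])) {
      bad <- setdiff(names(config[[blk]]),
                     union(names(defs[[blk]]),
                           names(formals(toy_shell_spec))))
      if (blk != "toy_spec") bad <- setdiff(names(config[[blk]]),
                                            names(defs[[blk]]))
      if (length(bad) > 0) {
        stop("unknown key(s) in '", blk, "': ", paste(bad, collapse = ", "))
      }
    }
  }
  if (is.null(config$langevin$reduced_temperature)) {
    notices <- c(notices,
                 "production temperature not set; using default 0.582")
  }
  cfg <- defs
  for (nm in names(config)) {
    if (nm %in% nested && is.list(config[[nm]])) {
      for (k in names(config[[nm]])) cfg[[nm]][[k]] <- config[[nm]][[k]]
    } else {
      cfg[[nm]] <- config[[nm]]
    }
  }
  ## value constraints, collected and reported together
  problems <- character()
  chk <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  chk(identical(cfg$mode, "toy") || identical(cfg$mode, "files"),
      "mode must be 'toy' or 'files'")
  chk(cfg$scale_factor > 0 && cfg$scale_factor <= 1,
      "scale_factor must be in (0, 1]")
  chk(cfg$langevin$timestep > 0, "langevin timestep must be > 0")
  chk(cfg$langevin$reduced_temperature >= 0,
      "langevin temperature must be >= 0")
  chk(cfg$langevin$friction >= 0, "langevin friction must be >= 0")
  chk(cfg$langevin$n_steps >= 1, "langevin n_steps must be >= 1")
  chk(cfg$analysis$translocation_threshold > 0 &&
        cfg$analysis$translocation_threshold <= 1,
      "translocation threshold must be in (0, 1]")
  chk(cfg$analysis$formed_factor > 1, "formed_factor must be > 1")
  chk(cfg$n_starting_conformations >= 1,
      "n_starting_conformations must be >= 1")
  chk(cfg$runs_per_conformation >= 1, "runs_per_conformation must be >= 1")
  chk(cfg$tail_generation$high_T >= 0, "tail-generation temperature must be >= 0")
  chk(cfg$tail_generation$restraint_k > 0, "restraint_k must be > 0")
  if (length(problems) > 0) {
    stop("configuration validation failed:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  cfg$n_starting_conformations <- as.integer(cfg$n_starting_conformations)
  cfg$runs_per_conformation <- as.integer(cfg$runs_per_conformation)
  cfg$seed <- as.integer(cfg$seed)
  attr(cfg, "notices") <- notices
  class(cfg) <- "pipeline_config"
  cfg
}

#' Analyse stored trajectories
#'
#' The analysis stage in isolation: given the shell pair, its topology and a
#' list of trajectories, computes per-chain Q traces, Rg traces,
#' translocation events, position-resolved counts, ensemble statistics and
#' Q distributions.  Re-running on the same trajectories yields identical
#' output.
#'
#' @param pair a `toy_shell_pair` (or list with `expanded_reference` and
#'   `annotations`).
#' @param topology the production `ff_topology`.
#' @param trajectories list of [cg_trajectory()] objects.
#' @param run_ids character vector of run identifiers.
#' @param params an [analysis_params()].
#' @return list with `events`, `counts`, `nit_by_run`, `ensemble`,
#'   `distributions`, `rg`, `q_traces`, `equilibration`.
#' @export
analyze_trajectories <- function(pair, topology, trajectories, run_ids,
                                 params = analysis_params()) {
  stopifnot(length(trajectories) == length(run_ids))
  ref <- pair$expanded_reference
  ann <- pair$annotations
  capsomer <- ann$chain_id[!is.na(ann$position_label)]
  labels <- sort(unique(ann$position_label[!is.na(ann$position_label)]))
  cmap <- topology$contacts
  subsets <- lapply(capsomer, function(cid) {
    tail_contact_subset(cmap, ref, cid, params)
  })
  names(subsets) <- capsomer

  events <- list(); q_traces <- list(); rg_tr <- list(); equil <- integer()
  for (r in seq_along(trajectories)) {
    traj <- trajectories[[r]]
    rg <- rg_trace(traj)
    rg_tr[[run_ids[r]]] <- rg
    equil[run_ids[r]] <- equilibration_index(rg$rg)
    for (cid in capsomer) {
      tr <- q_trace(traj, subsets[[cid]], params)
      q_traces[[paste(run_ids[r], cid, sep = ":")]] <- tr
      ev <- detect_translocation(tr, params$translocation_threshold,
                                 run_id = run_ids[r])
      if (!is.null(ev)) events[[length(events) + 1L]] <- ev
    }
  }
  events <- if (length(events) > 0) do.call(rbind, events) else
    data.frame(chain_id = character(), position_label = character(),
               run_id = character(), first_passage_time = numeric(),
               stringsAsFactors = FALSE)

  chains_per_pos <- sum(ann$position_label[!is.na(ann$position_label)] ==
                          labels[1])
  time_grid <- trajectories[[1]]$times
  counts <- count_events_by_position(events, labels, chains_per_pos,
                                     length(trajectories), time_grid)
  ## per-run N_i(t) and ensemble mean +/- SD per position
  nit_by_run <- lapply(labels, function(p) {
    t(vapply(run_ids, function(rid) {
      tp <- events$first_passage_time[events$position_label == p &
                                        events$run_id == rid]
      vapply(time_grid, function(t) sum(tp <= t), numeric(1))
    }, numeric(length(time_grid))))
  })
  names(nit_by_run) <- labels
  ensemble <- if (length(trajectories) >= 2) {
    lapply(nit_by_run, ensemble_statistics)
  } else NULL

  distributions <- lapply(labels, function(p) {
    keys <- names(q_traces)
    sel <- vapply(keys, function(k) {
      identical(q_traces[[k]]$position_label, p)
    }, logical(1))
    eqs <- vapply(strsplit(keys[sel], ":", fixed = TRUE),
                  function(v) equil[[v[1]]], integer(1))
    q_probability_distribution(q_traces[sel], params, equilibration = eqs)
  })
  names(distributions) <- labels

  list(events = events, counts = counts, nit_by_run = nit_by_run,
       ensemble = ensemble, distributions = distributions, rg = rg_tr,
       q_traces = q_traces, equilibration = equil, time_grid = time_grid)
}

#' Run the full pipeline
#'
#' Toy mode: generates the shell pair, builds the mature-reference topology,
#' samples disordered-tail starting conformations by restrained high-T
#' dynamics, runs `n_starting_conformations x runs_per_conformation` seeded
#' Langevin production simulations and analyses them.  When `outdir` is set,
#' event tables (TSV), count curves (TSV), distributions (JSON) and a
#' reproducibility manifest (JSON) are written there.
#'
#' @param config a [pipeline_config()], raw named list or YAML path.
#' @param progress print per-run progress lines.
#' @return report bundle: list with `shell`, `topology`, `analysis`,
#'   `trajectories` (if kept), `config` and `manifest`.
#' @export
run_pipeline <- function(config = list(), progress = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  if (!identical(cfg$mode, "toy")) {
    stop("only toy mode is implemented for the end-to-end pipeline; ",
         "use the module functions directly for file-based studies")
  }
  t0 <- proc.time()[["elapsed"]]
  spec <- do.call(toy_shell_spec, c(cfg$toy_spec, list(seed = cfg$seed)))
  shell <- make_toy_shell(spec)
  topo <- build_topology(shell$expanded_reference,
                         shadow = do.call(shadow_params, cfg$shadow),
                         scale_factor = cfg$scale_factor,
                         param_table = NULL,
                         dihedral_contact_ratio = cfg$dihedral_contact_ratio)
  n_runs <- cfg$n_starting_conformations * cfg$runs_per_conformation
  seeds <- derive_seeds(cfg$seed, n_runs + 1L)
  tg <- cfg$tail_generation
  starts <- generate_disordered_tails(
    shell$compact, topo, n_samples = cfg$n_starting_conformations,
    high_T = tg$high_T, restraint_k = tg$restraint_k,
    seed = seeds[n_runs + 1L], stride = tg$stride,
    equilibration_strides = tg$equilibration_strides,
    interior_only = tg$interior_only)
  if (length(starts) < cfg$n_starting_conformations) {
    stop("tail generation yielded only ", length(starts), " of ",
         cfg$n_starting_conformations, " starting conformations")
  }

  restr <- production_restraints(shell)

  lv <- cfg$langevin
  run_ids <- character(n_runs); trajs <- vector("list", n_runs)
  k <- 0L
  for (ci in seq_along(starts)) {
    for (rj in seq_len(cfg$runs_per_conformation)) {
      k <- k + 1L
      run_ids[k] <- sprintf("c%dr%d", ci, rj)
      st0 <- initialize_velocities(simulation_state(coords(starts[[ci]])),
                                   lv$reduced_temperature, seeds[k])
      pars <- langevin_params(reduced_temperature = lv$reduced_temperature,
                              timestep = lv$timestep, friction = lv$friction,
                              n_steps = lv$n_steps, seed = seeds[k],
                              save_interval = lv$save_interval)
      trajs[[k]] <- run_langevin(topo, st0, pars, restraints = restr)
      if (progress) {
        message(sprintf("run %s done (%.1f s elapsed)", run_ids[k],
                        proc.time()[["elapsed"]] - t0))
      }
    }
  }

  params <- do.call(analysis_params, cfg$analysis)
  analysis <- analyze_trajectories(shell, topo, trajs, run_ids, params)

  manifest <- list(seed = cfg$seed, run_seeds = seeds[seq_len(n_runs)],
                   tail_seed = seeds[n_runs + 1L], run_ids = run_ids,
                   n_runs = n_runs,
                   package_version = as.character(utils::packageVersion("capsidgo")),
                   tail_generation = attr(starts, "manifest"),
                   wall_time_s = proc.time()[["elapsed"]] - t0,
                   notices = attr(cfg, "notices"))

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    write.table(analysis$events, file.path(cfg$outdir, "events.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    counts_df <- data.frame(position = names(analysis$counts$counts),
                            events = as.integer(analysis$counts$counts),
                            denominator = analysis$counts$denominator)
    write.table(counts_df, file.path(cfg$outdir, "counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(analysis$ensemble)) {
      ens <- do.call(rbind, lapply(names(analysis$ensemble), function(p) {
        data.frame(position = p, time = analysis$time_grid,
                   mean = analysis$ensemble[[p]]$mean,
                   sd = analysis$ensemble[[p]]$sd)
      }))
      write.table(ens, file.path(cfg$outdir, "nit_ensemble.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      lapply(analysis$distributions, function(d) {
        list(bin_edges = d$bin_edges, probabilities = d$probabilities,
             peaks = d$peaks)
      }),
      file.path(cfg$outdir, "q_distributions.json"),
      auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    if (isTRUE(cfg$write_trajectories)) {
      for (k in seq_len(n_runs)) {
        write_trajectory(trajs[[k]],
                         file.path(cfg$outdir,
                                   sprintf("traj_%s.xyz", run_ids[k])))
      }
    }
  }

  list(shell = shell, topology = topo, starts = starts,
       trajectories = trajs, run_ids = run_ids, analysis = analysis,
       config = cfg, manifest = manifest)
}

#' Production-run scaffold restraints for a toy shell
#'
#' Cage chains (no position label) are restrained firmly (k = 50) and the
#' shell body (non-tail residues of capsomer chains) weakly (k = 3) to their
#' mature positions.  The cage models the rigid steric environment whose
#' geometry is a controlled parameter; the weak body anchoring fixes the
#' global frame -- the whole-shell rotational diffusion that a
#' million-atom capsid does not exhibit on simulated timescales -- while
#' leaving expansion and local fluctuations contact-driven.  Tail residues
#' are never restrained.
#'
#' @param shell a `toy_shell_pair`.
#' @param k_cage,k_body spring constants, reduced energy / nm^2.
#' @param scale radial scale of the restraint reference (default 0.95, the
#'   contact-minimum scaling: the model's free-energy minimum sits at the
#'   scaled geometry, so the scaffold is anchored there).
#' @return a [restraint_spec()].
#' @export
production_restraints <- function(shell, k_cage = 50, k_body = 3,
                                  scale = 0.95) {
  ann <- shell$annotations
  ref <- coords(shell$expanded_reference) * scale
  cage_ids <- ann$chain_id[is.na(ann$position_label)]
  caps <- ann$chain_id[!is.na(ann$position_label)]
  cage_idx <- if (length(cage_ids) > 0) {
    unlist(lapply(cage_ids, function(cid)
      atom_indices(shell$expanded_reference, cid)))
  } else integer(0)
  body_idx <- unlist(lapply(caps, function(cid) {
    k <- match(cid, ann$chain_id)
    span <- range(shell$expanded_reference$atoms$residue_index[
      shell$expanded_reference$atoms$chain_id == cid])
    atom_indices(shell$expanded_reference, cid,
                 c(ann$tail_end[k] + 1L, span[2]))
  }))
  idx <- c(cage_idx, body_idx)
  restraint_spec(idx, ref[idx, , drop = FALSE],
                 c(rep(k_cage, length(cage_idx)),
                   rep(k_body, length(body_idx))))
}
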