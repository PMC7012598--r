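## Pipeline orchestration from a single YAML (or list) config.
##
## One config drives any subset of the analysis stages; outputs (CSV, DX
## maps, JSON fits) land in the configured output directory together with
## a run record (config + package version + seed), so a run is reproducible
## from its own outputs. Independent stages continue when one fails; the
## failures are collected in the returned summary.

PIPELINE_STAGES <- c("switch_survey", "loop_rmsd", "pocket_volume", "pca",
                     "kinetics", "conservation", "simulate")
GLOBAL_KEYS <- c("seed", "out_dir", "log_level")

STAGE_SCHEMAS <- list(
  simulate = list(.keys = c("switch", "kinetics_decay", "kinetics_panel"),
                  switch = c("n_up", "n_down", "noise_sigma"),
                  kinetics_decay = c("t_half", "noise_frac"),
                  kinetics_panel = c("slope", "intercept", "n_mutants",
                                     "noise_sd")),
  switch_survey = list(.keys = c("in", "chains", "margin", "out")),
  loop_rmsd = list(.keys = c("traj", "ref", "segment", "fit", "backbone",
                             "out")),
  pocket_volume = list(.keys = c("traj", "spheres", "grid_spacing",
                                 "contour", "frame_stride", "out_map",
                                 "out_volumes")),
  pca = list(.keys = c("trajs", "ref", "components", "bin_width", "out",
                       "out_model")),
  kinetics = list(.keys = c("decay", "regress", "efficiency"),
                  decay = c("in", "t_chx", "out"),
                  regress = c("in", "out"),
                  efficiency = c("in", "E_total", "S0", "t", "out")),
  conservation = list(.keys = c("aln", "ref", "patch", "out")))

validate_config <- function(config) {
  check_keys(config, c(GLOBAL_KEYS, PIPELINE_STAGES), "config")
  for (stage in intersect(names(config), PIPELINE_STAGES)) {
    schema <- STAGE_SCHEMAS[[stage]]
    check_keys(config[[stage]], schema$.keys, stage)
    for (sub in setdiff(names(schema), ".keys"))
      if (!is.null(config[[stage]][[sub]]) &&
          is.list(config[[stage]][[sub]]))
        check_keys(config[[stage]][[sub]], schema[[sub]],
                   paste(stage, sub, sep = "/"))
  }
  invisible(config)
}

pipeline_log <- function(level, threshold, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] >= levels[[threshold]])
    message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
}

check_keys <- function(block, allowed, where) {
  bad <- setdiff(names(block), allowed)
  if (length(bad))
    stop("schema error in '", where, "': unknown key(s): ",
         paste(bad, collapse = ", "))
}

#' Run the analysis pipeline from a config
#'
#' The config is a YAML file or an equivalent named list, with global keys
#' `seed`, `out_dir`, `log_level` and one optional block per stage:
#' `simulate`, `switch_survey`, `loop_rmsd`, `pocket_volume`, `pca`,
#' `kinetics`, `conservation`. Unknown keys raise a schema error naming
#' them. Given the same config and seed, every numeric output is
#' reproduced exactly.
#'
#' @param config path to a YAML config file, or a named list.
#' @return (invisibly) a summary list: outputs written per stage, failed
#'   stages with messages, and `ok` (TRUE iff no stage failed). A run
#'   record JSON is written beside the outputs.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  validate_config(config)
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% "."
  log_level <- config$log_level %||% "info"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  outputs <- list(); failed <- list()
  run_stage <- function(name, fun) {
    if (is.null(config[[name]])) return()
    pipeline_log("info", log_level, "stage ", name, " started")
    res <- tryCatch(fun(config[[name]]), error = function(e) e)
    if (inherits(res, "error")) {
      pipeline_log("error", log_level, "stage ", name, " failed: ",
                   conditionMessage(res))
      failed[[name]] <<- conditionMessage(res)
    } else {
      outputs[[name]] <<- res
      pipeline_log("info", log_level, "stage ", name, " done")
    }
  }

  sim_env <- new.env()
  run_stage("simulate", function(blk) {
    check_keys(blk, c("switch", "kinetics_decay", "kinetics_panel"),
               "simulate")
    written <- character()
    if (!is.null(blk$switch)) {
      check_keys(blk$switch, c("n_up", "n_down", "noise_sigma"),
                 "simulate/switch")
      sw <- make_switch_ensemble(blk$switch$n_up, blk$switch$n_down,
                                 blk$switch$noise_sigma %||% 0, seed)
      p <- file.path(out_dir, "simulated_switch_ensemble.pdb")
      write_ensemble(sw$ensemble, p)
      utils::write.csv(data.frame(frame = seq_along(sw$labels),
                                  label = sw$labels),
                       file.path(out_dir, "simulated_switch_labels.csv"),
                       row.names = FALSE, quote = FALSE)
      sim_env$switch <- sw
      written <- c(written, p)
    }
    if (!is.null(blk$kinetics_decay)) {
      check_keys(blk$kinetics_decay, c("t_half", "noise_frac"),
                 "simulate/kinetics_decay")
      sim <- simulate_decay(t_half = blk$kinetics_decay$t_half %||% 3.5,
                            noise_frac = blk$kinetics_decay$noise_frac %||% 0.02,
                            seed = seed)
      p <- file.path(out_dir, "simulated_decay.csv")
      utils::write.csv(sim$table, p, row.names = FALSE, quote = FALSE)
      sim_env$decay <- sim
      written <- c(written, p)
    }
    if (!is.null(blk$kinetics_panel)) {
      check_keys(blk$kinetics_panel, c("slope", "intercept", "n_mutants",
                                       "noise_sd"),
                 "simulate/kinetics_panel")
      sim <- simulate_phosphoswitch_panel(
        slope = blk$kinetics_panel$slope %||% 1.5,
        intercept = blk$kinetics_panel$intercept %||% 1,
        n_mutants = blk$kinetics_panel$n_mutants %||% 8,
        noise_sd = blk$kinetics_panel$noise_sd %||% 0.2, seed = seed)
      p <- file.path(out_dir, "simulated_panel.csv")
      utils::write.csv(sim$table, p, row.names = FALSE, quote = FALSE)
      sim_env$panel <- sim
      written <- c(written, p)
    }
    written
  })

  run_stage("switch_survey", function(blk) {
    check_keys(blk, c("in", "chains", "margin", "out"), "switch_survey")
    margin <- blk$margin %||% 1.0
    x <- if (!is.null(blk[["in"]]) && identical(blk[["in"]], "simulated")) {
      if (is.null(sim_env$switch))
        stop("switch_survey input 'simulated' needs a simulate/switch block")
      sim_env$switch$ensemble
    } else if (length(blk[["in"]]) == 1 &&
               grepl("\\.pdb$", blk[["in"]][1]) &&
               is_multimodel_pdb(blk[["in"]][1])) {
      read_ensemble(blk[["in"]][1])
    } else {
      lapply(blk[["in"]], read_structure)
    }
    survey <- survey_ensemble(x, chains = blk$chains, margin = margin)
    out <- file.path(out_dir, blk$out %||% "survey.csv")
    write_survey_csv(survey, out)
    if (nrow(survey$skipped))
      pipeline_log("warn", log_level, nrow(survey$skipped),
                   " chain(s) skipped (missing probe atoms)")
    out
  })

  run_stage("loop_rmsd", function(blk) {
    check_keys(blk, c("traj", "ref", "segment", "fit", "backbone", "out"),
               "loop_rmsd")
    ens <- read_ensemble(blk$traj)
    ref <- read_structure(blk$ref)
    seg <- as.integer(strsplit(blk$segment %||% "168-175", "-")[[1]])
    bb <- blk$backbone %||% BACKBONE_ATOMS
    rmsd_sel <- atom_selection(res_range = seg, atom_names = bb)
    fit <- blk$fit %||% "segment"
    fit_sel <- if (identical(fit, "segment")) rmsd_sel else {
      core <- as.integer(strsplit(sub("^core:", "", fit), "-")[[1]])
      atom_selection(res_range = core, atom_names = bb)
    }
    tr <- segment_rmsd_trace(ens, ref, fit_sel, rmsd_sel,
                             reference_name = blk$ref)
    out <- file.path(out_dir, blk$out %||% "trace.csv")
    write_trace_csv(tr, out)
    out
  })

  run_stage("pocket_volume", function(blk) {
    check_keys(blk, c("traj", "spheres", "grid_spacing", "contour",
                      "frame_stride", "out_map", "out_volumes"),
               "pocket_volume")
    ens <- strip_nonprotein(read_ensemble(blk$traj))
    spheres <- lapply(blk$spheres, function(s)
      sphere_region(unlist(s$center), s$radius))
    spec <- pocket_spec(spheres, grid_spacing = blk$grid_spacing %||% 1.0,
                        frame_stride = blk$frame_stride %||% 1L)
    res <- ensemble_frequency_map(ens, spec)
    ct <- contour_map(res$map, blk$contour %||% 0.1)
    out_map <- file.path(out_dir, blk$out_map %||% "map.dx")
    write_grid_map(ct, out_map)
    out_vol <- file.path(out_dir, blk$out_volumes %||% "volumes.csv")
    write_volumes_csv(res$volumes, out_vol)
    c(out_map, out_vol)
  })

  run_stage("pca", function(blk) {
    check_keys(blk, c("trajs", "ref", "components", "bin_width", "out",
                      "out_model"), "pca")
    enss <- lapply(blk$trajs, read_ensemble)
    ref <- read_structure(blk$ref)
    model <- fit_pc_model(enss, ref)
    ncomp <- blk$components %||% 2
    tab <- do.call(rbind, lapply(seq_along(enss), function(i)
      do.call(rbind, lapply(seq_len(ncomp), function(pc) {
        pr <- project(enss[[i]], model, pc,
                      system = basename(blk$trajs[[i]]))
        data.frame(system = pr$system, component = pc,
                   frame = seq_along(pr$values), projection_A = pr$values)
      }))))
    out <- file.path(out_dir, blk$out %||% "proj.csv")
    utils::write.csv(tab, out, row.names = FALSE, quote = FALSE)
    out_model <- file.path(out_dir, blk$out_model %||% "pc_model.txt")
    write_pc_model(model, out_model)
    c(out, out_model)
  })

  run_stage("kinetics", function(blk) {
    check_keys(blk, c("decay", "regress", "efficiency"), "kinetics")
    written <- character()
    if (!is.null(blk$decay)) {
      check_keys(blk$decay, c("in", "t_chx", "out"), "kinetics/decay")
      tab <- if (identical(blk$decay[["in"]], "simulated")) {
        if (is.null(sim_env$decay))
          stop("decay input 'simulated' needs a simulate/kinetics_decay block")
        sim_env$decay$table
      } else utils::read.csv(blk$decay[["in"]])
      t_chx <- blk$decay$t_chx %||% 0
      fits <- lapply(split(tab, tab$replicate), function(d)
        fit_one_phase_decay(d$time_hr, d$signal, t_chx))
      hl <- vapply(fits, function(f) f$half_life, numeric(1))
      out <- file.path(out_dir, blk$decay$out %||% "decay_fit.json")
      jsonlite::write_json(list(half_life_hr_mean = mean(hl),
                                half_life_hr_sd = stats::sd(hl),
                                n = length(hl),
                                per_replicate = unname(hl)),
                           out, auto_unbox = TRUE, digits = NA)
      written <- c(written, out)
    }
    if (!is.null(blk$regress)) {
      check_keys(blk$regress, c("in", "out"), "kinetics/regress")
      tab <- if (identical(blk$regress[["in"]], "simulated")) {
        if (is.null(sim_env$panel))
          stop("regress input 'simulated' needs a simulate/kinetics_panel block")
        sim_env$panel$table
      } else utils::read.csv(blk$regress[["in"]])
      fit <- efficiency_halflife_regression(tab$ratio, tab$half_life_hr)
      out <- file.path(out_dir, blk$regress$out %||% "regression_fit.json")
      write_fit_json(fit, out)
      written <- c(written, out)
    }
    if (!is.null(blk$efficiency)) {
      check_keys(blk$efficiency, c("in", "E_total", "S0", "t", "out"),
                 "kinetics/efficiency")
      tab <- utils::read.csv(blk$efficiency[["in"]])
      est <- estimate_efficiency(tab$P, blk$efficiency$E_total,
                                 blk$efficiency$S0, blk$efficiency$t)
      out <- file.path(out_dir, blk$efficiency$out %||% "efficiency.json")
      write_fit_json(est, out)
      written <- c(written, out)
    }
    written
  })

  run_stage("conservation", function(blk) {
    check_keys(blk, c("aln", "ref", "patch", "out"), "conservation")
    aln <- read_alignment(blk$aln)
    patch <- patch_identity(aln, blk$ref, unlist(blk$patch))
    out <- file.path(out_dir, blk$out %||% "identity.csv")
    write_identity_csv(patch, out)
    out
  })

  record <- list(config = config, seed = seed,
                 package_version = as.character(utils::packageVersion("ck1switch")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 failed = failed)
  jsonlite::write_json(record, file.path(out_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (length(failed))
    pipeline_log("error", log_level, length(failed), " stage(s) failed: ",
                 paste(names(failed), collapse = ", "))
  invisible(list(outputs = outputs, failed = failed,
                 ok = length(failed) == 0, out_dir = out_dir))
}

is_multimodel_pdb <- function(path) {
  head <- readLines(path, n = 200)
  any(startsWith(head, "MODEL"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
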