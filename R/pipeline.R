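# End-to-end orchestration: simulate (or read) -> reliability -> fits ->
# power -> bootstrap, with a reproducibility manifest.

#' Run configuration
#'
#' Exactly one input source per run: either paths to volumes/changes files
#' or a simulation preset (the default study design with the built-in
#' parameter presets).
#'
#' @param simulate Logical: generate data from presets instead of reading
#'   files.
#' @param volumes_file,changes_file CSV inputs (when `simulate = FALSE`).
#' @param changes_kind `change_kind` of the changes file.
#' @param exclusions_file Optional scan exclusion list.
#' @param structures Structures to analyse.
#' @param followups Trial follow-up durations in years.
#' @param n_resamples Bootstrap resamples (0 disables the bootstrap
#'   stage).
#' @param bootstrap_model Model whose effect size is bootstrapped
#'   (`"direct"` or `"volume"`).
#' @param bootstrap_followup Follow-up (years) for the bootstrapped effect
#'   size.
#' @param seed Master seed for simulation and resampling.
#' @param design A [study_design()].
#' @param out_dir Output directory for result tables and the manifest.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(simulate = TRUE, volumes_file = NULL,
                       changes_file = NULL, changes_kind = NULL,
                       exclusions_file = NULL,
                       structures = c("brain", "ventricle", "hippo_L",
                                      "hippo_R"),
                       followups = c(0.5, 1, 2), n_resamples = 0L,
                       bootstrap_model = "direct", bootstrap_followup = 1,
                       seed = 1L, design = study_design(),
                       out_dir = tempfile("atrophyrun")) {
  if (simulate && (!is.null(volumes_file) || !is.null(changes_file)))
    stop("exactly one of simulation preset or input files per run")
  if (!simulate && is.null(volumes_file) && is.null(changes_file))
    stop("supply volumes_file and/or changes_file when simulate = FALSE")
  structure(list(simulate = simulate, volumes_file = volumes_file,
                 changes_file = changes_file, changes_kind = changes_kind,
                 exclusions_file = exclusions_file, structures = structures,
                 followups = followups, n_resamples = as.integer(n_resamples),
                 bootstrap_model = bootstrap_model,
                 bootstrap_followup = bootstrap_followup,
                 seed = as.integer(seed), design = design,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; a nested `design` block
#' (fields of [study_design()]) overrides the default design. The
#' round-trip is lossless for all scalar and vector fields.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files")
  y <- yaml::read_yaml(path)
  if (!is.null(y$design)) y$design <- do.call(study_design, y$design)
  do.call(run_config, y)
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config[setdiff(names(config), "out_dir")], tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full evaluation pipeline
#'
#' Executes simulate (or read) -> exclusions -> reliability scorecard ->
#' volume and direct model fits per (structure, group) -> trial power
#' tables -> optional bootstrap effect-size intervals, writing each stage's
#' table under `config$out_dir` together with a reproducibility manifest
#' (seed, package version, config hash, stage log, removal counts). Two
#' runs with the same configuration and seed produce byte-identical
#' tables.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`volumes`,
#'   `changes`, `scorecard`, `fits`, `power`, `bootstrap`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- config$design
  log <- character()
  note <- function(...) log <<- c(log, paste0(format(Sys.time(), "%H:%M:%S"),
                                              " ", ...))

  # --- inputs -------------------------------------------------------------
  if (config$simulate) {
    note("simulating volumes and changes for ",
         paste(config$structures, collapse = ", "))
    volumes <- do.call(rbind, lapply(config$structures, function(s)
      simulate_volume_dataset(design, structure = s, seed = config$seed)))
    changes <- do.call(rbind, lapply(config$structures, function(s)
      simulate_direct_dataset(design, structure = s, seed = config$seed)))
  } else {
    volumes <- if (!is.null(config$volumes_file)) {
      note("reading volumes from ", config$volumes_file)
      read_volumes(config$volumes_file)
    }
    changes <- if (!is.null(config$changes_file)) {
      note("reading changes from ", config$changes_file)
      read_changes(config$changes_file, design,
                   change_kind = config$changes_kind, volumes = volumes)
    }
  }

  removed <- c(scans = 0L, pairs = 0L)
  if (!is.null(config$exclusions_file)) {
    ex <- read_exclusions(config$exclusions_file, design)
    if (!is.null(volumes)) {
      r <- apply_exclusions(volumes, ex)
      volumes <- r$records; removed["scans"] <- r$n_removed
    }
    if (!is.null(changes)) {
      r <- apply_exclusions(changes, ex)
      changes <- r$records; removed["pairs"] <- r$n_removed
    }
    note("exclusions: removed ", removed["scans"], " scan record(s) and ",
         removed["pairs"], " pair record(s)")
  }

  # --- reliability --------------------------------------------------------
  scorecard <- reliability_scorecard(volumes, changes, design)
  write.csv(scorecard, file.path(config$out_dir, "reliability.csv"),
            row.names = FALSE)
  note("reliability scorecard: ", nrow(scorecard), " row(s)")

  # --- model fits and power ----------------------------------------------
  fits <- list(); power <- list()
  for (s in config$structures) {
    for (model in c("volume", "direct")) {
      dat <- if (model == "volume") volumes else
        changes[changes$direction == "forward", , drop = FALSE]
      if (is.null(dat)) next
      dat <- dat[dat$structure == s, , drop = FALSE]
      if (!nrow(dat)) next
      fitfun <- if (model == "volume") fit_volume_model else fit_direct_model
      fit_ad <- fitfun(dat[dat$group == "AD", , drop = FALSE])
      fit_hc <- fitfun(dat[dat$group == "control", , drop = FALSE])
      fits[[paste(s, model, "AD", sep = ".")]] <- fit_ad
      fits[[paste(s, model, "control", sep = ".")]] <- fit_hc
      fit_report(fit_ad, file.path(config$out_dir,
                                   paste0("fit_", s, "_", model, "_AD.json")))
      fit_report(fit_hc, file.path(config$out_dir,
                                   paste0("fit_", s, "_", model, "_control.json")))
      power[[paste(s, model, sep = ".")]] <-
        power_table(fit_ad, fit_hc, config$followups, structure = s,
                    technique = model)
      note("fitted ", model, " model for ", s)
    }
  }
  power_df <- do.call(rbind, power)
  if (!is.null(power_df)) {
    rownames(power_df) <- NULL
    write.csv(power_df, file.path(config$out_dir, "power.csv"),
              row.names = FALSE)
  }

  # --- bootstrap ----------------------------------------------------------
  boot <- NULL
  if (config$n_resamples > 0L) {
    spec <- bootstrap_spec(config$n_resamples, seed = config$seed)
    boot <- list()
    for (s in config$structures) {
      dat <- if (config$bootstrap_model == "volume") volumes else changes
      if (is.null(dat)) next
      dat <- dat[dat$structure == s, , drop = FALSE]
      if (!nrow(dat)) next
      pipe <- es_pipeline(config$bootstrap_model, config$bootstrap_followup)
      boot[[s]] <- bootstrap_effect_size_ci(dat, pipe, spec)
      note("bootstrap (", config$bootstrap_model, ", ",
           config$bootstrap_followup, "y) for ", s, ": ",
           spec$n_resamples, " resamples")
    }
    bt <- do.call(rbind, lapply(names(boot), function(s) {
      b <- boot[[s]]
      data.frame(structure = s, followup_years = config$bootstrap_followup,
                 es = b$es_hat, es_lo = b$es_ci[1], es_hi = b$es_ci[2],
                 n_total = b$n_total_hat, n_lo = b$n_ci[1], n_hi = b$n_ci[2],
                 n_failed = b$n_failed, fallback = b$fallback)
    }))
    write.csv(bt, file.path(config$out_dir, "bootstrap.csv"),
              row.names = FALSE)
  }

  # --- manifest -----------------------------------------------------------
  manifest <- list(seed = config$seed,
                   package_version = as.character(packageVersion("atrophytrials")),
                   config_hash = .config_hash(config),
                   structures = config$structures,
                   followups = config$followups,
                   n_resamples = config$n_resamples,
                   removed_scan_records = unname(removed["scans"]),
                   removed_pair_records = unname(removed["pairs"]),
                   stages = log)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(volumes = volumes, changes = changes, scorecard = scorecard,
                 fits = fits, power = power_df, bootstrap = boot,
                 manifest = manifest, out_dir = config$out_dir))
}
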