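#' Default run configuration
#'
#' The full set of documented defaults for [load_config()] /
#' [run_pipeline()]: nested blocks for the kernel, scenario, sampling,
#' experiment and synthetic stages plus the global seed, output directory
#' and verbosity. Every stochastic stage derives its seed from the global
#' seed.
#'
#' @return A nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L, out_dir = "stratmix-out", verbose = TRUE,
    kernel = list(ws = 2.5, K0 = 3, z0 = 10, z_scale = 1.5, dt = 10,
                  T = 60000, dz = 0.2, n_particles = 10000, n_runs = 100),
    scenario = list(type = "step", length_cm = 100, onset_cm = 50,
                    onset_duration = 5, pre_cm = 20, post_cm = 30,
                    ref_mbsf = 171.30),
    sampling = list(spacing = 2, thickness = 2, n_per_clade = 4,
                    min_run = 2, run_rule = "longest"),
    experiment = list(durations = c(0, 1, 2, 3, 5, 10, 15),
                      sample_sizes = c(5, 10, 20, 50, 100, 500),
                      replicates = 100, ws = 0.5, pre_cm = 20, post_cm = 30),
    synthetic = list(row_spacing_m = 0.02, noise_sd = 2,
                     caco3_noise_sd = 1.5, mask_frac = 0.25,
                     mask_frac_caco3 = 0.05, n_per_sample = 4))
}

# Recursive merge of a user config into defaults; unknown keys are an error
# reported with their full path.
.merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(defaults) || !is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste(paste(c(path, unknown[1]), collapse = "."), collapse = ", "))
  for (nm in names(user))
    defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]], c(path, nm))
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills unset keys with the documented
#' defaults, and rejects unknown keys (reporting the offending key path).
#' An empty or missing-content file yields the full default configuration.
#'
#' @param path Path to a YAML file.
#' @return A validated configuration list (class `stratmix_config`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- .merge_config(default_config(), user)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "stratmix_config"
  cfg
}

#' Run pipeline stages and write their artifacts
#'
#' Executes a prefix of the stage chain kernel -> record -> sample (or the
#' `experiment` branch after `kernel`), writing each stage's tables and a
#' manifest (parameters, seed, output checksums) into the configured output
#' directory. Reruns with an identical configuration produce identical
#' files and checksums.
#'
#' @param config A configuration from [load_config()] or
#'   [default_config()].
#' @param stages Character vector of stages to run, a prefix of
#'   `c("kernel", "record", "sample")` optionally followed by
#'   `"experiment"`.
#' @return Invisibly, the manifest list (also written as `manifest.yml`).
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("kernel", "record", "sample")) {
  valid <- c("kernel", "record", "sample", "experiment")
  if (!all(stages %in% valid))
    stop("unknown stage(s): ", paste(setdiff(stages, valid), collapse = ", "))
  deps <- c(kernel = NA, record = "kernel", sample = "record",
            experiment = "kernel")
  for (s in stages) {
    d <- deps[[s]]
    if (!is.na(d) && !d %in% stages[seq_len(match(s, stages) - 1)])
      stop("stage '", s, "' requires stage '", d, "' to run first")
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (isTRUE(config$verbose)) message(...)
  manifest <- list(seed = config$seed, stages = list())
  artifacts <- list()
  record_file <- function(stage, files) {
    sums <- tools::md5sum(files)
    manifest$stages[[stage]] <<- list(
      outputs = as.list(stats::setNames(unname(sums), basename(files))))
  }
  for (s in stages) {
    if (s == "kernel") {
      p <- do.call(mixing_params,
                   c(config$kernel, list(seed = config$seed)))
      say("kernel: ", p$n_runs, " runs x ", p$n_particles, " particles")
      artifacts$profile <- median_mixing_profile(p)
      f <- file.path(out_dir, "profile.csv")
      write_profile(artifacts$profile, f)
      record_file("kernel", c(f, sub("\\.csv$", ".yml", f)))
    } else if (s == "record") {
      scfg <- config$scenario
      artifacts$scenario <- if (scfg$type == "step")
        step_scenario(scfg$length_cm, scfg$onset_cm,
                      ws = config$kernel$ws, dz = config$kernel$dz,
                      ref_mbsf = scfg$ref_mbsf)
      else
        ramp_scenario(scfg$onset_duration, ws = config$kernel$ws,
                      pre_cm = scfg$pre_cm, post_cm = scfg$post_cm,
                      dz = config$kernel$dz)
      say("record: ", scfg$type, " scenario, ",
          artifacts$scenario$n, " increments")
      artifacts$column <- form_record(artifacts$scenario, artifacts$profile)
      f1 <- file.path(out_dir, "column_long.csv")
      f2 <- file.path(out_dir, "column_summary.csv")
      write_column(artifacts$column, f1, f2)
      record_file("record", c(f1, f2))
    } else if (s == "sample") {
      smp <- config$sampling
      cfg <- sampling_config(smp$spacing, smp$thickness, smp$n_per_clade,
                             smp$min_run, smp$run_rule)
      draws <- draw_individuals(artifacts$column, cfg,
                                seed = config$seed + 1L)
      iso <- artifacts$scenario$iso
      flags <- logical(nrow(draws))
      for (cl in unique(draws$clade)) {
        i <- draws$clade == cl
        flags[i] <- flag_intermediates(draws$d13c[i], iso[[cl]])
      }
      draws$intermediate <- flags
      say("sample: ", nrow(draws), " individuals drawn")
      f <- file.path(out_dir, "draws.csv")
      utils::write.csv(draws, f, row.names = FALSE)
      artifacts$draws <- draws
      record_file("sample", f)
    } else if (s == "experiment") {
      e <- config$experiment
      kern <- do.call(mixing_params,
                      c(config$kernel, list(seed = config$seed)))
      grid <- experiment_grid(
        durations = e$durations, sample_sizes = e$sample_sizes,
        replicates = e$replicates, ws = e$ws, kernel = kern,
        sampling = sampling_config(
          config$sampling$spacing, config$sampling$thickness,
          n_per_clade = 5, min_run = config$sampling$min_run,
          run_rule = config$sampling$run_rule),
        pre_cm = e$pre_cm, post_cm = e$post_cm, seed = config$seed)
      say("experiment: ", length(e$durations), " durations x ",
          length(e$sample_sizes), " sample sizes x ", e$replicates,
          " replicates")
      res <- run_grid(grid)
      f1 <- file.path(out_dir, "experiment_summary.csv")
      f2 <- file.path(out_dir, "experiment_raw.csv")
      write_experiment(res, f1, f2)
      artifacts$experiment <- res
      record_file("experiment", c(f1, f2))
    }
  }
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  invisible(manifest)
}
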