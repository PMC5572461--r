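#' Configuration for the Site-690-like synthetic dataset generator
#'
#' Generates depth-series inputs with the statistical structure the analysis
#' assumes, so that every pipeline stage is testable without the original
#' (request-only) data: two-clade piecewise-constant unmixed abundance
#' histories with highs, lows and depositional gaps and excursion reductions
#' of 80 percent (mixed-layer, Acarinina-like) and 97.5 percent
#' (thermocline, Subbotina-like); carbonate content declining from >85 wt%
#' pre-event to lows near 60 wt%; coarse-fraction and fragmentation
#' covariates satisfying the imputation regressions plus Gaussian noise; and
#' two-cloud single-individual d13C populations.
#'
#' @param depth_top,depth_base Top and base of the modeled interval, mbsf.
#' @param row_spacing_m Sample spacing of the output table, m.
#' @param onset_mbsf Depth of the excursion onset.
#' @param ws Sedimentation rate, cm/kyr.
#' @param kernel [mixing_params()] for the mixing profile.
#' @param acarinina,subbotina Data frames (`from_mbsf`, `to_mbsf`, `level`)
#'   of unmixed relative abundance in `[0, 1]`; `NULL` uses defaults
#'   emulating the published abundance structure.
#' @param scale_aca,scale_sub Sedimentary weight percent corresponding to
#'   relative abundance 1 for each clade.
#' @param caco3_pre,caco3_low,caco3_recovery Carbonate content (wt%) before
#'   the onset, at its post-onset low, and at the top of the interval.
#' @param noise_sd Gaussian noise s.d. (percentage points) on the
#'   coarse-fraction and fragmentation covariates.
#' @param caco3_noise_sd Noise s.d. on CaCO3.
#' @param mask_frac Fraction of coarse/fragmentation cells masked to NA to
#'   exercise the imputation paths.
#' @param mask_frac_caco3 Fraction of CaCO3 cells masked to NA.
#' @param n_per_sample Individuals drawn per clade per row for the
#'   single-specimen d13C table.
#' @param seed Random seed (mandatory).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(depth_top = 170.30, depth_base = 171.45,
                             row_spacing_m = 0.02, onset_mbsf = 170.74,
                             ws = 2.5, kernel = mixing_params(ws = ws),
                             acarinina = NULL, subbotina = NULL,
                             scale_aca = 3.3, scale_sub = 2.6,
                             caco3_pre = 88, caco3_low = 60,
                             caco3_recovery = 70,
                             noise_sd = 2, caco3_noise_sd = 1.5,
                             mask_frac = 0.25, mask_frac_caco3 = 0.05,
                             n_per_sample = 4, seed) {
  if (missing(seed)) stop("a seed is mandatory for the synthetic generator")
  stopifnot(depth_top < onset_mbsf, onset_mbsf < depth_base,
            row_spacing_m > 0, ws > 0, noise_sd >= 0, caco3_noise_sd >= 0,
            mask_frac >= 0, mask_frac < 1, n_per_sample >= 1)
  if (is.null(acarinina))
    acarinina <- data.frame(
      from_mbsf = c(171.45, 171.20, 171.05, 170.92, 170.86, onset_mbsf),
      to_mbsf   = c(171.20, 171.05, 170.92, 170.86, onset_mbsf, depth_top),
      level     = c(1.0, 0.55, 0.9, 0, 1.0, 0.2))
  if (is.null(subbotina))
    subbotina <- data.frame(
      from_mbsf = c(171.45, 171.33, 171.23, 171.00, 170.85, onset_mbsf, 170.64),
      to_mbsf   = c(171.33, 171.23, 171.00, 170.85, onset_mbsf, 170.64, depth_top),
      level     = c(1.0, 0, 0.85, 0.45, 1.0, 0, 0.025))
  kernel$ws <- ws
  structure(list(depth_top = depth_top, depth_base = depth_base,
                 row_spacing_m = row_spacing_m, onset_mbsf = onset_mbsf,
                 ws = ws, kernel = kernel,
                 acarinina = acarinina, subbotina = subbotina,
                 scale_aca = scale_aca, scale_sub = scale_sub,
                 caco3_pre = caco3_pre, caco3_low = caco3_low,
                 caco3_recovery = caco3_recovery,
                 noise_sd = noise_sd, caco3_noise_sd = caco3_noise_sd,
                 mask_frac = mask_frac, mask_frac_caco3 = mask_frac_caco3,
                 n_per_sample = as.integer(n_per_sample),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Piecewise-constant level lookup at heights (cm above the column base).
.levels_at <- function(segments, h, depth_base) {
  lo_h <- (depth_base - segments$from_mbsf) * 100
  hi_h <- (depth_base - segments$to_mbsf) * 100
  out <- numeric(length(h))
  for (k in seq_len(nrow(segments))) {
    sel <- h >= lo_h[k] - 1e-9 & h < hi_h[k] - 1e-9
    out[sel] <- segments$level[k]
  }
  out
}

#' Generate a Site-690-like synthetic dataset
#'
#' Forward-mixes the configured true abundance histories, derives a
#' depth-series table of genus percentages and preservation covariates
#' consistent with the mixed record and the imputation regressions, draws
#' single-individual d13C values from the mixed column, and returns the
#' ground truth for recovery tests. Genus percentages are expressed relative
#' to the whole sediment (the two genera do not close to 100), so the
#' matching downstream convention is `sedimentary_abundance(...,
#' normalize = "over100")`.
#'
#' @param cfg A [synthetic_config()].
#' @param profile Optional precomputed `mixing_profile` (computed from
#'   `cfg$kernel` when missing).
#' @return A list with `table` (the depth-series covariate table),
#'   `individuals` (single-specimen d13C draws, 4 per clade per row by
#'   default), `truth` (true histories, scales, onset depth and isotope
#'   models), `scenario` and `column` (the mixed column the draws came
#'   from).
#' @export
generate_dataset <- function(cfg, profile = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (is.null(profile)) profile <- median_mixing_profile(cfg$kernel)
  dz <- cfg$kernel$dz
  length_cm <- (cfg$depth_base - cfg$depth_top) * 100
  n <- round(length_cm / dz)
  h <- (seq_len(n) - 1) * dz
  onset_h <- (cfg$depth_base - cfg$onset_mbsf) * 100
  ab <- cbind(mixed_layer = .levels_at(cfg$acarinina, h, cfg$depth_base),
              thermocline = .levels_at(cfg$subbotina, h, cfg$depth_base))
  iso <- list(
    mixed_layer = isotope_model("mixed_layer", 3.1, 0, 0.30, onset_h, 0, cfg$ws),
    thermocline = isotope_model("thermocline", 1.6, -0.4, 0.12, onset_h, 0, cfg$ws))
  sc <- new_scenario(ab, iso, dz, cfg$ws, onset_h, ref_mbsf = cfg$depth_base)
  col <- form_record(sc, profile)
  cs <- column_summary(col)

  set.seed(cfg$seed)
  row_h <- seq(0, length_cm - cfg$row_spacing_m * 100,
               by = cfg$row_spacing_m * 100)
  row_bin <- floor(row_h / dz + 1e-9) + 1L
  depth <- cfg$depth_base - row_h / 100
  sed_aca <- cfg$scale_aca * cs$mixed_layer_mass[row_bin]
  sed_sub <- cfg$scale_sub * cs$thermocline_mass[row_bin]

  # carbonate declines across the onset from the pre-event plateau to its
  # low, then recovers toward the top of the interval
  low_h <- onset_h + 10
  caco3 <- ifelse(row_h < onset_h, cfg$caco3_pre,
           ifelse(row_h < low_h,
                  cfg$caco3_pre + (cfg$caco3_low - cfg$caco3_pre) *
                    (row_h - onset_h) / (low_h - onset_h),
                  cfg$caco3_low + (cfg$caco3_recovery - cfg$caco3_low) *
                    (row_h - low_h) / max(length_cm - low_h, 1)))
  caco3 <- pmin(pmax(caco3 + stats::rnorm(length(caco3), 0, cfg$caco3_noise_sd),
                     0), 100)
  coarse <- pmax(0.1361 * caco3 - 5.3177 +
                   stats::rnorm(length(caco3), 0, cfg$noise_sd), 0)
  frag <- pmin(pmax(-0.3219 * caco3 + 40.051 +
                      stats::rnorm(length(caco3), 0, cfg$noise_sd), 0), 100)
  unfrag <- coarse * (100 - frag) / 100
  pct_aca <- ifelse(unfrag > 0, pmin(sed_aca / unfrag * 100, 100), 0)
  pct_sub <- ifelse(unfrag > 0, pmin(sed_sub / unfrag * 100, 100), 0)

  tb <- data.frame(depth_mbsf = depth,
                   pct_subbotina = pct_sub, pct_acarinina = pct_aca,
                   caco3 = caco3, coarse_fraction = coarse,
                   fragmentation = frag)
  mask <- function(x, frac) {
    x[stats::runif(length(x)) < frac] <- NA_real_
    x
  }
  tb$coarse_fraction <- mask(tb$coarse_fraction, cfg$mask_frac)
  tb$fragmentation <- mask(tb$fragmentation, cfg$mask_frac)
  tb$caco3 <- mask(tb$caco3, cfg$mask_frac_caco3)

  smp <- sampling_config(spacing = cfg$row_spacing_m * 100,
                         n_per_clade = cfg$n_per_sample, min_run = 2)
  individuals <- draw_individuals(col, smp, seed = cfg$seed + 1L)

  truth <- list(acarinina = cfg$acarinina, subbotina = cfg$subbotina,
                scale_aca = cfg$scale_aca, scale_sub = cfg$scale_sub,
                onset_mbsf = cfg$onset_mbsf, onset_duration_kyr = 0,
                iso = iso, seed = cfg$seed)
  for (cl in names(iso)) {
    m <- iso[[cl]]
    if (m$mean_pre - 3 * m$sd <= m$mean_cie + 3 * m$sd)
      warning("isotope clouds for ", cl,
              " overlap under the 3-s.d. rule; intermediates undetectable")
  }
  list(table = tb, individuals = individuals, truth = truth,
       scenario = sc, column = col)
}

#' Write a small fixture set of synthetic inputs
#'
#' Writes the generated covariate table, individual d13C table and the
#' truth record (as YAML) into a directory, in the same comma-separated
#' formats the pipeline reads.
#'
#' @param dir Output directory (created if needed).
#' @param cfg A [synthetic_config()].
#' @param profile Optional precomputed profile passed to
#'   [generate_dataset()].
#' @return The directory path, invisibly.
#' @export
make_fixture_set <- function(dir, cfg, profile = NULL) {
  ds <- generate_dataset(cfg, profile)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(ds$table, file.path(dir, "abundance_table.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$individuals, file.path(dir, "individual_d13c.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(
    onset_mbsf = ds$truth$onset_mbsf,
    onset_duration_kyr = ds$truth$onset_duration_kyr,
    scale_aca = ds$truth$scale_aca, scale_sub = ds$truth$scale_sub,
    acarinina = ds$truth$acarinina, subbotina = ds$truth$subbotina,
    seed = ds$truth$seed), file.path(dir, "truth.yml"))
  invisible(dir)
}
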