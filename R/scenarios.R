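#' Isotope model for one clade
#'
#' Describes the carbon-isotope history of a population across an excursion
#' onset: a pre-event mean, an excursion (post-onset) mean, an
#' among-individual standard deviation, and the stratigraphic position and
#' duration of the onset. A zero duration is a step change; a positive
#' duration is a linear ramp of the population mean over the onset interval
#' (thickness `onset_duration * ws` cm of unmixed sediment).
#'
#' @param clade Clade label.
#' @param mean_pre Pre-event mean d13C, permil VPDB.
#' @param mean_cie Excursion mean d13C, permil VPDB.
#' @param sd Among-individual standard deviation, permil (>= 0; zero makes
#'   every individual carry its population mean exactly).
#' @param onset_height Column height (cm, increasing upward) at which the
#'   onset begins.
#' @param onset_duration Onset duration, kyr (0 = step change).
#' @param ws Sedimentation rate, cm/kyr (converts duration to thickness).
#' @return An object of class `isotope_model`.
#' @export
isotope_model <- function(clade, mean_pre, mean_cie, sd,
                          onset_height = 0, onset_duration = 0, ws = 2.5) {
  stopifnot(sd >= 0, onset_duration >= 0, ws > 0)
  structure(list(clade = clade, mean_pre = mean_pre, mean_cie = mean_cie,
                 sd = sd, onset_height = onset_height,
                 onset_duration = onset_duration, ws = ws,
                 ramp_cm = onset_duration * ws),
            class = "isotope_model")
}

#' Population-mean d13C at a given column height
#'
#' @param iso An [isotope_model()].
#' @param h Column height(s), cm (increasing upward; vectorised).
#' @return Mean d13C at each height: `mean_pre` below the onset, `mean_cie`
#'   at and above the top of the ramp, linear in between.
#' @export
isotope_mean_at <- function(iso, h) {
  if (iso$ramp_cm > 0) {
    f <- pmin(pmax((h - iso$onset_height) / iso$ramp_cm, 0), 1)
  } else {
    f <- as.numeric(h >= iso$onset_height)
  }
  iso$mean_pre + (iso$mean_cie - iso$mean_pre) * f
}

# Internal constructor for deposition scenarios: a contiguous column of
# dz-increments with per-clade pre-mixing relative abundance and an isotope
# model per clade. Heights increase upward; `ref_mbsf` is the mbsf of height
# zero, so mbsf = ref_mbsf - height/100.
new_scenario <- function(abundance, iso, dz, ws, onset_height,
                         ref_mbsf = NA_real_) {
  stopifnot(is.matrix(abundance), !is.null(colnames(abundance)),
            all(abundance >= 0), all(abundance <= 1),
            setequal(colnames(abundance), names(iso)))
  structure(list(
    dz = dz, ws = ws, n = nrow(abundance),
    height = (seq_len(nrow(abundance)) - 1L) * dz,
    abundance = abundance, iso = iso,
    onset_height = onset_height, ref_mbsf = ref_mbsf),
    class = "deposition_scenario")
}

#' @export
print.deposition_scenario <- function(x, ...) {
  cat(sprintf(
    "Deposition scenario: %d increments of %g cm (%g cm at w_s = %g cm/kyr)\n",
    x$n, x$dz, x$n * x$dz, x$ws))
  cat(sprintf("  clades: %s; onset at height %g cm%s\n",
              paste(colnames(x$abundance), collapse = ", "), x$onset_height,
              if (is.na(x$ref_mbsf)) "" else
                sprintf(" (%.2f mbsf)", x$ref_mbsf - x$onset_height / 100)))
  invisible(x)
}

#' Simplified step-change scenario
#'
#' The two-clade scenario with a step carbon-isotope excursion and a
#' single-step abundance change coincident with the onset: the mixed-layer
#' clade drops to half its pre-event abundance, the thermocline clade to zero
#' for a gap interval (very low populations approximated by a depositional
#' gap) and to a small fraction of its initial abundance thereafter. Isotope
#' step changes are 3.1 to 0 permil (s.d. 0.30) for the mixed-layer clade and
#' 1.6 to -0.4 permil (s.d. 0.12) for the thermocline clade.
#'
#' @param length_cm Column length, cm.
#' @param onset_cm Height of the onset above the column base, cm; must lie
#'   inside the column.
#' @param ws Sedimentation rate, cm/kyr.
#' @param dz Increment, cm.
#' @param mixed_layer_reduction Post-onset fraction of the pre-event
#'   mixed-layer abundance retained (default 0.5, a 50 percent reduction).
#' @param thermocline_gap_cm Thickness of the post-onset thermocline gap, cm.
#' @param thermocline_level Post-gap thermocline abundance as a fraction of
#'   its initial abundance.
#' @param ref_mbsf Depth (mbsf) of the column base; the default places the
#'   onset at 170.80 mbsf.
#' @return A `deposition_scenario` with clades `mixed_layer` and
#'   `thermocline`.
#' @export
step_scenario <- function(length_cm = 100, onset_cm = 50, ws = 2.5, dz = 0.2,
                          mixed_layer_reduction = 0.5,
                          thermocline_gap_cm = 10, thermocline_level = 0.025,
                          ref_mbsf = 171.30) {
  if (onset_cm <= 0 || onset_cm >= length_cm)
    stop("onset depth lies outside the modeled column")
  n <- round(length_cm / dz)
  h <- (seq_len(n) - 1) * dz
  post <- h >= onset_cm
  ml <- ifelse(post, mixed_layer_reduction, 1)
  th <- ifelse(post,
               ifelse(h < onset_cm + thermocline_gap_cm, 0, thermocline_level),
               1)
  ab <- cbind(mixed_layer = ml, thermocline = th)
  iso <- list(
    mixed_layer = isotope_model("mixed_layer", 3.1, 0, 0.30, onset_cm, 0, ws),
    thermocline = isotope_model("thermocline", 1.6, -0.4, 0.12, onset_cm, 0, ws))
  new_scenario(ab, iso, dz, ws, onset_cm, ref_mbsf)
}

#' Ramped-onset scenario for the mixed-layer clade
#'
#' A single-clade scenario in which the population-mean d13C declines
#' linearly from 3.1 to 0 permil and the abundance declines linearly from 1
#' to 0.5 over the full onset interval (thickness `onset_duration * ws` cm);
#' both are constant outside it and there are no depositional gaps. Used for
#' the onset-duration detection experiments.
#'
#' @param onset_duration Onset duration, kyr (>= 0; 0 is a step change).
#' @param ws Sedimentation rate, cm/kyr (default 0.5, typical of the
#'   earliest excursion interval).
#' @param pre_cm,post_cm Column extent below / above the onset, cm.
#' @param dz Increment, cm.
#' @param sd Among-individual d13C standard deviation, permil.
#' @return A `deposition_scenario` with a single `mixed_layer` clade.
#' @export
ramp_scenario <- function(onset_duration, ws = 0.5, pre_cm = 20, post_cm = 30,
                          dz = 0.2, sd = 0.30) {
  if (onset_duration < 0) stop("onset duration must be >= 0")
  n <- round((pre_cm + post_cm) / dz)
  h <- (seq_len(n) - 1) * dz
  ramp <- onset_duration * ws
  if (ramp >= post_cm)
    stop("onset ramp extends beyond the top of the column; increase post_cm")
  f <- if (ramp > 0) pmin(pmax((h - pre_cm) / ramp, 0), 1) else
    as.numeric(h >= pre_cm)
  ab <- cbind(mixed_layer = 1 - 0.5 * f)
  iso <- list(mixed_layer = isotope_model("mixed_layer", 3.1, 0, sd,
                                          pre_cm, onset_duration, ws))
  new_scenario(ab, iso, dz, ws, pre_cm)
}

#' Bulk-carbonate scenario
#'
#' The bulk record is modeled as the mass-weighted mean of a single carbonate
#' population undergoing an isotopic step from 1.6 to -0.4 permil whose
#' abundance collapses at the onset to below one percent of pre-event levels
#' for a gap interval and recovers to 2.5 percent thereafter.
#'
#' @param length_cm,onset_cm,ws,dz,ref_mbsf As in [step_scenario()].
#' @param low_level Post-onset abundance fraction during the gap interval
#'   (default 0.005, i.e. below the one-percent level).
#' @param gap_cm Thickness of the low interval, cm.
#' @param late_level Abundance fraction after the low interval.
#' @return A `deposition_scenario` with a single `bulk` clade.
#' @export
bulk_scenario <- function(length_cm = 100, onset_cm = 50, ws = 2.5, dz = 0.2,
                          low_level = 0.005, gap_cm = 10, late_level = 0.025,
                          ref_mbsf = 171.30) {
  if (onset_cm <= 0 || onset_cm >= length_cm)
    stop("onset depth lies outside the modeled column")
  n <- round(length_cm / dz)
  h <- (seq_len(n) - 1) * dz
  ab <- ifelse(h < onset_cm, 1,
               ifelse(h < onset_cm + gap_cm, low_level, late_level))
  iso <- list(bulk = isotope_model("bulk", 1.6, -0.4, 0.12, onset_cm, 0, ws))
  new_scenario(cbind(bulk = ab), iso, dz, ws, onset_cm, ref_mbsf)
}
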