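#' Sampling configuration for single-specimen measurements
#'
#' Describes how single individuals are picked from a mixed column: samples
#' are contiguous intervals of `thickness` cm taken every `spacing` cm (the
#' defaults tile the record with 2-cm samples, matching common core-sampling
#' practice), with `n_per_clade` individuals drawn per clade per sample.
#'
#' @param spacing Distance between sample bases, cm (> 0).
#' @param thickness Sample thickness, cm (defaults to `spacing`, i.e.
#'   contiguous samples).
#' @param n_per_clade Individuals drawn per clade per sample (>= 1).
#' @param min_run Minimum number of consecutive intermediate-bearing samples
#'   required for a nonzero observed onset duration. The default 2 treats an
#'   isolated intermediate-bearing sample as defining no interval; set 1 to
#'   count single samples.
#' @param run_rule `"longest"` (default) or `"first"`: which run of
#'   consecutive intermediate-bearing samples measures the observed duration.
#' @return An object of class `sampling_config`.
#' @export
sampling_config <- function(spacing = 2, thickness = spacing,
                            n_per_clade = 4, min_run = 2,
                            run_rule = c("longest", "first")) {
  stopifnot(spacing > 0, thickness > 0, n_per_clade >= 1, min_run >= 1)
  structure(list(spacing = spacing, thickness = thickness,
                 n_per_clade = as.integer(n_per_clade),
                 min_run = as.integer(min_run),
                 run_rule = match.arg(run_rule)),
            class = "sampling_config")
}

#' Draw single-specimen d13C values from a mixed column
#'
#' For each sample interval and clade, `n_per_clade` source horizons are
#' drawn with replacement with probability proportional to their post-mixing
#' mass within the interval (masses are expectations, not enumerable
#' individuals); each individual's d13C is its source-horizon population mean
#' plus Gaussian noise with the clade's among-individual standard deviation.
#' Clades with zero mass in an interval yield no rows for that sample, as in
#' barren core samples.
#'
#' @param column A `mixed_column`.
#' @param cfg A [sampling_config()].
#' @param seed Random seed.
#' @return A data frame with columns `sample`, `height_cm` (sample midpoint),
#'   `depth_mbsf` (when available), `clade`, `individual`, `d13c`,
#'   `source_height_cm`.
#' @export
draw_individuals <- function(column, cfg, seed = 1L,
                             weights = sample_weights(column, cfg)) {
  stopifnot(inherits(column, "mixed_column"), inherits(cfg, "sampling_config"))
  set.seed(seed)
  ref <- column$scenario$ref_mbsf
  out <- vector("list", length(weights$starts) * length(column$clades))
  k <- 0L
  for (s in seq_along(weights$starts)) {
    for (cl in column$clades) {
      wt <- weights$w[[s]][[cl]]
      if (is.null(wt)) next
      pick <- sample.int(length(wt), cfg$n_per_clade, replace = TRUE,
                         prob = wt)
      sd <- column$scenario$iso[[cl]]$sd
      vals <- column$src_mu[[cl]][pick] + stats::rnorm(cfg$n_per_clade, 0, sd)
      k <- k + 1L
      mid <- weights$starts[s] + cfg$thickness / 2
      out[[k]] <- data.frame(
        sample = s, height_cm = mid,
        depth_mbsf = if (is.na(ref)) NA_real_ else ref - mid / 100,
        clade = cl, individual = seq_len(cfg$n_per_clade),
        d13c = vals, source_height_cm = column$src_height[pick])
    }
  }
  do.call(rbind, out[seq_len(k)])
}

#' Precompute per-sample source-horizon weights
#'
#' The per-sample, per-clade source-mass vectors used by
#' [draw_individuals()]; precompute once when drawing many replicates from
#' the same column.
#'
#' @inheritParams draw_individuals
#' @return A list with `starts` (sample base heights, cm) and `w` (per
#'   sample, a named list of per-clade weight vectors over source horizons;
#'   `NULL` where the clade has no mass in the interval).
#' @export
sample_weights <- function(column, cfg) {
  stopifnot(inherits(column, "mixed_column"), inherits(cfg, "sampling_config"))
  w <- column$window
  h <- column$dest_height[w]
  H <- length(h) * column$dz
  starts <- seq(0, H - cfg$thickness + 1e-9, by = cfg$spacing)
  ws <- lapply(starts, function(st) {
    inb <- which(h >= st - 1e-9 & h < st + cfg$thickness - 1e-9)
    out <- lapply(column$clades, function(cl) {
      wt <- colSums(column$mass[[cl]][w[inb], , drop = FALSE])
      if (any(wt < -1e-12)) stop("negative mass encountered in column")
      if (sum(wt) <= 0) NULL else wt
    })
    names(out) <- column$clades
    out
  })
  list(starts = starts, w = ws)
}

#' Flag intermediate-value individuals
#'
#' A value is "intermediate" when it lies more than three standard
#' deviations away from both the pre-event and the excursion population
#' means, i.e. strictly inside the open interval
#' (`mean_cie + 3 sd`, `mean_pre - 3 sd`). When the two 3-s.d. clouds
#' overlap no value can qualify and a configuration warning is raised.
#'
#' @param values Numeric d13C values.
#' @param iso An [isotope_model()] supplying the two means and the s.d.
#' @return A logical vector of flags with attribute `count` (number flagged).
#' @examples
#' iso <- isotope_model("ml", 3.1, 0, 0.30)
#' flag_intermediates(c(1.5, 3.0, 0.9), iso)  # TRUE, FALSE, FALSE
#' @export
flag_intermediates <- function(values, iso) {
  stopifnot(inherits(iso, "isotope_model"))
  # a hair of tolerance keeps the 3-s.d. boundary exclusive under floating
  # point (3 * 0.30 must exclude exactly 0.90)
  eps <- 1e-9
  lo <- min(iso$mean_pre, iso$mean_cie) + 3 * iso$sd + eps
  hi <- max(iso$mean_pre, iso$mean_cie) - 3 * iso$sd - eps
  if (lo >= hi) {
    warning("pre-event and excursion 3-s.d. clouds overlap; ",
            "intermediate values are undetectable under this model")
    flags <- rep(FALSE, length(values))
  } else {
    flags <- values > lo & values < hi
  }
  structure(flags, count = sum(flags))
}

#' Observed onset duration from per-sample intermediate counts
#'
#' The apparent (recorded) onset duration is measured from runs of
#' consecutive samples that each contain at least one intermediate-value
#' individual: the qualifying run's length times the sample spacing,
#' converted to time by the sedimentation rate. Runs shorter than
#' `cfg$min_run` yield zero (by default an isolated intermediate-bearing
#' sample defines no interval); `cfg$run_rule` selects the longest (default)
#' or the first qualifying run.
#'
#' @param counts Integer vector of intermediate counts per sample, ordered
#'   by stratigraphic position.
#' @param cfg A [sampling_config()].
#' @param ws Sedimentation rate, cm/kyr.
#' @return Observed onset duration, kyr (0 when no run qualifies).
#' @examples
#' cfg <- sampling_config(spacing = 2, min_run = 1)
#' observed_onset_duration(c(0, 1, 2, 0), cfg, ws = 0.5)  # 2 * 2 / 0.5 = 8
#' @export
observed_onset_duration <- function(counts, cfg, ws) {
  stopifnot(inherits(cfg, "sampling_config"), ws > 0)
  if (length(counts) == 0 || all(counts == 0)) return(0)
  r <- rle(counts > 0)
  lens <- r$lengths[r$values]
  lens <- lens[lens >= cfg$min_run]
  if (length(lens) == 0) return(0)
  len <- if (cfg$run_rule == "longest") max(lens) else lens[[1]]
  len * cfg$spacing / ws
}

#' Per-sample intermediate counts for a draw table
#'
#' Convenience wrapper: flags every individual in a [draw_individuals()]
#' table against its clade's isotope model and tabulates intermediates per
#' sample.
#'
#' @param draws A data frame from [draw_individuals()].
#' @param iso A named list of [isotope_model()]s (one per clade present).
#' @return A data frame with `sample`, `height_cm` and `n_intermediate`,
#'   ordered by sample; samples with no drawn individuals keep count zero.
#' @export
count_intermediates <- function(draws, iso) {
  if (is.null(draws) || nrow(draws) == 0)
    return(data.frame(sample = integer(), height_cm = numeric(),
                      n_intermediate = integer()))
  flags <- logical(nrow(draws))
  for (cl in unique(draws$clade)) {
    i <- draws$clade == cl
    flags[i] <- flag_intermediates(draws$d13c[i], iso[[cl]])
  }
  agg <- stats::aggregate(flags, by = list(sample = draws$sample), FUN = sum)
  hgt <- stats::aggregate(draws$height_cm, by = list(sample = draws$sample),
                          FUN = function(x) x[[1]])
  data.frame(sample = agg$sample, height_cm = hgt$x,
             n_intermediate = as.integer(agg$x))
}
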