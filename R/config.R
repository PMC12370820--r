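#' Canonical frequency band definitions
#'
#' The five clinical bands used throughout the pipeline: delta (1--4 Hz),
#' theta (4--8 Hz), alpha (8--13 Hz), beta (13--30 Hz) and gamma
#' (30--77.5 Hz). The gamma band carries two excluded sub-intervals,
#' 47.5--52.5 Hz and 57.5--62.5 Hz, which remove both 50 Hz and 60 Hz
#' power-line contamination, and is capped at 77.5 Hz to stay clear of
#' 80 Hz noise present in some recording systems.
#'
#' Band membership of a PSD bin is decided by its centre frequency under a
#' half-open `[lower, upper)` convention, so a shared edge (e.g. 4 Hz)
#' belongs to the higher band only and is never double counted.
#'
#' @return A list of five band definitions, each a list with elements
#'   `name`, `lower`, `upper` (Hz) and `exclusions` (a list of
#'   `c(lower, upper)` sub-intervals excluded from the integral).
#' @examples
#' names(default_bands())
#' default_bands()$gamma$exclusions
#' @export
default_bands <- function() {
  list(
    delta = band_definition("delta", 1, 4),
    theta = band_definition("theta", 4, 8),
    alpha = band_definition("alpha", 8, 13),
    beta  = band_definition("beta", 13, 30),
    gamma = band_definition("gamma", 30, 77.5,
                            exclusions = list(c(47.5, 52.5), c(57.5, 62.5)))
  )
}

#' Construct a frequency band definition
#'
#' @param name Band name.
#' @param lower,upper Band edges in Hz; membership is half-open
#'   `[lower, upper)`.
#' @param exclusions List of `c(lower, upper)` sub-intervals (Hz) excluded
#'   from the band integral; each must nest within `[lower, upper]`.
#' @return A `band_definition` list.
#' @export
band_definition <- function(name, lower, upper, exclusions = list()) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(lower), is.numeric(upper), lower < upper)
  for (ex in exclusions) {
    if (length(ex) != 2L || ex[1] >= ex[2] || ex[1] < lower || ex[2] > upper)
      stop("exclusion [", ex[1], ", ", ex[2], "] not nested within band [",
           lower, ", ", upper, "]")
  }
  structure(list(name = name, lower = lower, upper = upper,
                 exclusions = exclusions),
            class = "band_definition")
}

#' Names of the five canonical bands, in spectral order
#' @return Character vector `c("delta","theta","alpha","beta","gamma")`.
#' @export
band_names <- function() names(default_bands())

#' Subcortical regions excluded from the normative table
#'
#' Pallidum, thalamus and accumbens area, in both hemispheres: regions with
#' no or very low electrode sampling in normative icEEG cohorts. Excluding
#' them reduces the standard 82-region atlas to 76 regions.
#'
#' @return Character vector of six hemisphere-prefixed region names.
#' @export
default_subcortical_exclusions <- function() {
  base <- c("pallidum", "thalamus", "accumbens")
  c(paste0("left_", base), paste0("right_", base))
}

#' Shared pipeline configuration
#'
#' One object holding every tunable constant of the pipeline, with defaults
#' reproducing the standard processing choices: 0.5--80 Hz band-pass,
#' 200 Hz target rate, 2 s Welch window with 1 s overlap, five bands with
#' gamma power-line exclusions, 5 mm maximum contact-to-grey-matter
#' assignment distance, the six subcortical exclusions, mean bilateral
#' collapse, the four candidate fixed-effect structures, 95% confidence
#' level and the 1e-4 variance-ratio singularity threshold.
#'
#' @param bands Band definitions (see [default_bands()]).
#' @param filter_low,filter_high Band-pass corner frequencies, Hz.
#' @param target_fs Target sampling rate after anti-alias resampling, Hz.
#' @param welch_window,welch_overlap Welch window length and overlap, s.
#' @param segment_length Interictal segment length, s.
#' @param min_ictal_gap Minimum distance from any ictal event, s.
#' @param flat_range_uv Channel-screening: minimum peak-to-peak range, uV.
#' @param amplitude_z Channel-screening: robust-z threshold on channel SD.
#' @param line_noise_ratio Channel-screening: line-noise/flank power ratio.
#' @param max_assign_dist Maximum contact-to-voxel distance, mm.
#' @param subcortical_exclusions Region names dropped from the table.
#' @param mirror_rule Bilateral collapse rule: `"mean"`, `"left"` or
#'   `"right"`.
#' @param candidate_models Fixed-effect sets considered in model selection.
#' @param conf_level Confidence level for intervals.
#' @param selection_alpha Significance level used by the LRT in selection.
#' @param singular_tol Variance ratio below which a fit is flagged singular.
#' @param min_roi_n Minimum rows per ROI for a regional fit.
#' @param deviation_threshold |z| above which a deviation is flagged.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(bands = default_bands(),
                            filter_low = 0.5, filter_high = 80,
                            target_fs = 200,
                            welch_window = 2, welch_overlap = 1,
                            segment_length = 70, min_ictal_gap = 7200,
                            flat_range_uv = 1, amplitude_z = 5,
                            line_noise_ratio = 3,
                            max_assign_dist = 5,
                            subcortical_exclusions =
                              default_subcortical_exclusions(),
                            mirror_rule = c("mean", "left", "right"),
                            candidate_models =
                              list(character(0), "age", "sex",
                                   c("age", "sex")),
                            conf_level = 0.95,
                            selection_alpha = 0.05,
                            singular_tol = 1e-4,
                            min_roi_n = 10,
                            deviation_threshold = 2) {
  mirror_rule <- match.arg(mirror_rule)
  stopifnot(filter_low > 0, filter_high > filter_low, target_fs > 0,
            welch_window > 0, welch_overlap >= 0,
            welch_overlap < welch_window,
            conf_level > 0, conf_level < 1)
  structure(list(
    bands = bands, filter_low = filter_low, filter_high = filter_high,
    target_fs = target_fs, welch_window = welch_window,
    welch_overlap = welch_overlap, segment_length = segment_length,
    min_ictal_gap = min_ictal_gap, flat_range_uv = flat_range_uv,
    amplitude_z = amplitude_z, line_noise_ratio = line_noise_ratio,
    max_assign_dist = max_assign_dist,
    subcortical_exclusions = subcortical_exclusions,
    mirror_rule = mirror_rule, candidate_models = candidate_models,
    conf_level = conf_level, selection_alpha = selection_alpha,
    singular_tol = singular_tol, min_roi_n = min_roi_n,
    deviation_threshold = deviation_threshold
  ), class = "pipeline_config")
}
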