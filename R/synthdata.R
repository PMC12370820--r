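#' @importFrom stats rnorm runif rbinom fft
NULL

# Evaluate code under a temporary RNG seed, restoring global RNG state,
# so all generators are pure functions of (params, seed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parameters of the generative multi-hospital cohort model
#'
#' Defines the generative counterpart of the normative mixed model:
#' for each frequency band b,
#' `RBP_b = beta0_b + b_age_b * age + b_sex_b * male + u_hospital_b + eps`,
#' with `u ~ N(0, sigma_u_b^2)` per hospital and `eps ~ N(0, sigma_e_b^2)`
#' per row. Bands are simulated independently and the five values are not
#' constrained to sum to one: the modelling layer treats each band
#' separately and never uses that constraint.
#'
#' Defaults emulate a 15-hospital, ~500-subject multi-centre icEEG cohort
#' with ages 4--66 years: age slopes are on the 1e-4 RBP/year scale
#' (strongly negative in delta, positive in alpha/beta, near zero in
#' theta/gamma), sex offsets are negligible, and the hospital/residual
#' variances are calibrated so the hospital intraclass correlation spans
#' roughly 5--30% across bands while age explains at most ~8% of variance.
#'
#' @param beta0 Per-band intercepts, RBP units (scalar recycled).
#' @param b_age Per-band age slopes, RBP per year.
#' @param b_sex Per-band male-vs-female offsets, RBP units.
#' @param sigma_u Per-band hospital-intercept SD (>= 0).
#' @param sigma_e Per-band residual SD (> 0).
#' @param n_hospitals Number of hospitals H (>= 1).
#' @param n_per_hospital Subjects per hospital (scalar or length-H vector).
#' @param age_range `c(min, max)` ages in years.
#' @param sex_prop Proportion of male subjects in (0, 1).
#' @param rois Data frame with columns `roi` and `prob` (implantation
#'   probability per region); defaults to [default_roi_probs()].
#' @param seed Integer random seed.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(beta0 = c(delta = 0.33, theta = 0.23,
                                        alpha = 0.18, beta = 0.15,
                                        gamma = 0.11),
                              b_age = c(delta = -6.1e-4, theta = -0.8e-4,
                                        alpha = 4.1e-4, beta = 2.9e-4,
                                        gamma = -0.2e-4),
                              b_sex = c(delta = 0, theta = 3e-3,
                                        alpha = 0, beta = 0, gamma = 3e-3),
                              sigma_u = c(delta = 0.0101, theta = 0.0157,
                                          alpha = 0.0055, beta = 0.0080,
                                          gamma = 0.0139),
                              sigma_e = 0.024,
                              n_hospitals = 15,
                              n_per_hospital = 33,
                              age_range = c(4, 66),
                              sex_prop = 0.5,
                              rois = default_roi_probs(),
                              seed = 1L) {
  bn <- band_names()
  expand <- function(v, what) {
    if (length(v) == 1L) v <- stats::setNames(rep(v, 5), bn)
    if (is.null(names(v))) names(v) <- bn
    if (!setequal(names(v), bn))
      stop(what, " must be named by the five bands")
    v[bn]
  }
  beta0 <- expand(beta0, "beta0"); b_age <- expand(b_age, "b_age")
  b_sex <- expand(b_sex, "b_sex"); sigma_u <- expand(sigma_u, "sigma_u")
  sigma_e <- expand(sigma_e, "sigma_e")
  if (any(sigma_u < 0)) stop("sigma_u must be >= 0")
  if (any(sigma_e <= 0)) stop("sigma_e must be > 0")
  stopifnot(n_hospitals >= 1, age_range[1] < age_range[2],
            sex_prop >= 0, sex_prop <= 1)
  rois <- as.data.frame(rois)
  if (nrow(rois) == 0L) stop("ROI list must be non-empty")
  stopifnot(all(c("roi", "prob") %in% names(rois)),
            all(rois$prob >= 0 & rois$prob <= 1))
  if (length(n_per_hospital) == 1L)
    n_per_hospital <- rep(n_per_hospital, n_hospitals)
  stopifnot(length(n_per_hospital) == n_hospitals, all(n_per_hospital >= 1))
  structure(list(beta0 = beta0, b_age = b_age, b_sex = b_sex,
                 sigma_u = sigma_u, sigma_e = sigma_e,
                 n_hospitals = as.integer(n_hospitals),
                 n_per_hospital = as.integer(n_per_hospital),
                 age_range = age_range, sex_prop = sex_prop,
                 rois = rois, seed = as.integer(seed)),
            class = "simulation_params")
}

#' Default regional implantation probabilities
#'
#' Heterogeneous per-region implantation probabilities over the 38
#' mirrored regions of the standard atlas, emulating the clinical bias
#' towards temporal and perisylvian coverage (middle temporal most
#' densely sampled, frontal pole and medial occipital regions sparse).
#'
#' @return Data frame with columns `roi` and `prob`.
#' @export
default_roi_probs <- function() {
  pairs <- standard_region_pairs()
  base <- setdiff(pairs$base,
                  sub("^left_", "", default_subcortical_exclusions()[1:3]))
  p <- rep(0.2, length(base)); names(p) <- base
  p[c("middle_temporal", "superior_temporal", "inferior_temporal",
      "hippocampus", "amygdala", "fusiform")] <-
    c(0.80, 0.70, 0.60, 0.60, 0.55, 0.50)
  p[c("supramarginal", "insula", "parahippocampal", "entorhinal",
      "temporal_pole", "inferior_parietal")] <-
    c(0.45, 0.45, 0.40, 0.35, 0.35, 0.40)
  p[c("superior_frontal", "rostral_middle_frontal", "precentral",
      "postcentral", "lateral_orbitofrontal")] <-
    c(0.35, 0.35, 0.30, 0.30, 0.30)
  p[c("frontal_pole", "pericalcarine", "cuneus", "paracentral",
      "transverse_temporal")] <- c(0.075, 0.10, 0.10, 0.10, 0.12)
  data.frame(roi = names(p), prob = unname(p))
}

#' Simulate a multi-hospital normative cohort with known ground truth
#'
#' Draws hospital intercepts, subject covariates, sparse regional
#' implantation and per-row residuals from the generative model described
#' in [simulation_params()], returning the long-format normative table the
#' modelling layer consumes plus a ground-truth record of every drawn
#' quantity. Deterministic given the seed in `params`.
#'
#' @param params A [simulation_params()] object.
#' @return A list: `table` (tibble with one row per subject x implanted
#'   region: `subject`, `hospital`, `age`, `sex`, `roi` and the five band
#'   columns) and `truth` (list with the parameters and the realised
#'   per-hospital intercepts `u`, an H x 5 matrix per band).
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  bn <- band_names()
  with_seed(params$seed, {
    H <- params$n_hospitals
    u <- sapply(bn, function(b) rnorm(H, 0, params$sigma_u[b]))
    u <- matrix(u, nrow = H, dimnames = list(sprintf("hosp%02d", 1:H), bn))
    n_sub <- sum(params$n_per_hospital)
    hospital <- rep(sprintf("hosp%02d", 1:H), params$n_per_hospital)
    subject <- sprintf("sub%04d", seq_len(n_sub))
    age <- runif(n_sub, params$age_range[1], params$age_range[2])
    male <- rbinom(n_sub, 1, params$sex_prop)
    sex <- ifelse(male == 1, "male", "female")
    # independent Bernoulli implantation per subject x region
    nroi <- nrow(params$rois)
    imp <- matrix(rbinom(n_sub * nroi, 1,
                         rep(params$rois$prob, each = n_sub)) == 1,
                  nrow = n_sub)
    idx <- which(imp, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    si <- idx[, 1]; ri <- idx[, 2]
    tab <- tibble::tibble(subject = subject[si], hospital = hospital[si],
                          age = age[si], sex = sex[si],
                          roi = params$rois$roi[ri])
    hi <- match(tab$hospital, rownames(u))
    for (b in bn) {
      mu <- params$beta0[b] + params$b_age[b] * tab$age +
        params$b_sex[b] * (tab$sex == "male") + u[hi, b]
      tab[[b]] <- as.numeric(mu + rnorm(nrow(tab), 0, params$sigma_e[b]))
    }
    list(table = as_normative_table(tab, mirrored = TRUE),
         truth = list(params = params, u = u,
                      subjects = tibble::tibble(subject, hospital, age, sex)))
  })
}

#' Describe a planted spectral model for synthetic recordings
#'
#' A 1/f ("pink") background over 0.5--80 Hz plus one fixed-amplitude
#' sinusoidal oscillation per band, with amplitudes solved so that the
#' analytic absolute band powers are proportional to the requested
#' targets. Optionally adds mains interference at 50/60 Hz.
#'
#' @param targets Named positive vector of target relative band powers
#'   (any scale; only ratios matter). `NULL` plants no oscillations.
#' @param exponent Spectral exponent chi of the `1/f^chi` background.
#' @param osc_freqs Named oscillation centre frequencies, Hz, one per
#'   target band; must lie in 0.5--80 Hz.
#' @param noise_power Total background power over 0.5--80 Hz, uV^2. The
#'   default 100 uV^2 keeps all band powers above 1 uV^2, the regime in
#'   which log10/L1 normalisation preserves the band-power ordering.
#' @param line_amp Amplitude of 50 and 60 Hz mains sinusoids, uV.
#' @return A `planted_spectrum` list.
#' @export
planted_spectrum <- function(targets = c(delta = 0.34, theta = 0.25,
                                         alpha = 0.18, beta = 0.13,
                                         gamma = 0.10),
                             exponent = 1,
                             osc_freqs = c(delta = 2.5, theta = 6,
                                           alpha = 10.5, beta = 21.5,
                                           gamma = 40),
                             noise_power = 100,
                             line_amp = 0) {
  if (!is.null(targets)) {
    stopifnot(all(targets > 0), !is.null(names(targets)))
    if (!all(names(targets) %in% names(osc_freqs)))
      stop("every target band needs an oscillation centre frequency")
    f <- osc_freqs[names(targets)]
    if (any(f < 0.5 | f > 80))
      stop("oscillation centre frequencies must lie in 0.5-80 Hz")
  }
  stopifnot(noise_power >= 0, line_amp >= 0, exponent >= 0)
  structure(list(targets = targets, exponent = exponent,
                 osc_freqs = osc_freqs, noise_power = noise_power,
                 line_amp = line_amp),
            class = "planted_spectrum")
}

# integral of c * f^-chi over [a, b]
pink_integral <- function(a, b, chi) {
  if (b <= a) return(0)
  if (abs(chi - 1) < 1e-12) log(b / a)
  else (b^(1 - chi) - a^(1 - chi)) / (1 - chi)
}

# background power of the 1/f^chi model within a band definition,
# honouring the band's exclusions and the 0.5-80 Hz support
pink_band_power <- function(band, chi, c0, support = c(0.5, 80)) {
  lo <- max(band$lower, support[1]); hi <- min(band$upper, support[2])
  p <- pink_integral(lo, hi, chi)
  for (ex in band$exclusions)
    p <- p - pink_integral(max(ex[1], lo), min(ex[2], hi), chi)
  c0 * p
}

#' Analytic band powers of a planted spectrum
#'
#' Closed-form absolute band powers of the planted model: the exact
#' integral of the 1/f background over each band (minus exclusions) plus
#' `A^2/2` for each in-band oscillation. Serves as the independent oracle
#' for the DSP chain.
#'
#' @param spectrum A [planted_spectrum()].
#' @param bands Band definitions (default [default_bands()]).
#' @return Named numeric vector of absolute band powers, uV^2.
#' @export
planted_band_powers <- function(spectrum, bands = default_bands()) {
  chi <- spectrum$exponent
  c0 <- if (spectrum$noise_power > 0)
    spectrum$noise_power / pink_integral(0.5, 80, chi) else 0
  bg <- vapply(bands, pink_band_power, 0, chi = chi, c0 = c0)
  osc <- osc_amplitudes(spectrum, bands)
  total <- bg
  for (b in names(osc$amp)) total[b] <- total[b] + osc$amp[b]^2 / 2
  total
}

# solve oscillation amplitudes so total band powers are proportional to
# the targets: the band with the largest background-to-target ratio gets
# amplitude zero and fixes the overall scale
osc_amplitudes <- function(spectrum, bands = default_bands()) {
  if (is.null(spectrum$targets))
    return(list(amp = numeric(0), freq = numeric(0)))
  chi <- spectrum$exponent
  c0 <- if (spectrum$noise_power > 0)
    spectrum$noise_power / pink_integral(0.5, 80, chi) else 0
  tb <- names(spectrum$targets)
  bg <- vapply(bands[tb], pink_band_power, 0, chi = chi, c0 = c0)
  r <- spectrum$targets / sum(spectrum$targets)
  total <- if (c0 > 0) max(bg / r) else sum(spectrum$targets)
  amp <- sqrt(pmax(2 * (r * total - bg), 0))
  list(amp = amp, freq = spectrum$osc_freqs[tb])
}

#' Simulate a multichannel recording with a planted spectrum
#'
#' Each channel is an independent realisation of spectrally shaped
#' Gaussian noise (frequency-domain synthesis of the 1/f^chi background,
#' band-limited to 0.5--80 Hz) plus fixed-amplitude sinusoids with a
#' random phase per channel, scaled so analytic band-power ratios match
#' the planted targets (see [planted_band_powers()]). Deterministic given
#' the seed.
#'
#' @param spectrum A [planted_spectrum()].
#' @param n_channels Number of channels.
#' @param fs Sampling rate, Hz (>= 200).
#' @param duration Duration, s (70 s typical).
#' @param seed Integer seed.
#' @param subject Optional subject id attached to the segment.
#' @return A [ts_segment()]; the analytic band powers are attached as
#'   attribute `"planted_band_powers"`.
#' @export
simulate_recording <- function(spectrum, n_channels, fs, duration,
                               seed = 1L, subject = NA_character_) {
  stopifnot(inherits(spectrum, "planted_spectrum"),
            n_channels >= 1, fs >= 200, duration > 0)
  osc <- osc_amplitudes(spectrum)
  if (length(osc$freq) && any(osc$freq >= fs / 2))
    stop("oscillation frequency at or above Nyquist (", fs / 2, " Hz)")
  n <- round(duration * fs)
  nf <- n %/% 2 + 1
  freq <- seq(0, nf - 1) * fs / n
  chi <- spectrum$exponent
  c0 <- if (spectrum$noise_power > 0)
    spectrum$noise_power / pink_integral(0.5, 80, chi) else 0
  S <- ifelse(freq >= 0.5 & freq <= 80, c0 * pmax(freq, 0.5)^(-chi), 0)
  S[1] <- 0
  amp_spec <- sqrt(S * fs * n / 2)
  tgrid <- seq_len(n) / fs
  with_seed(seed, {
    x <- matrix(0, n_channels, n)
    for (ch in seq_len(n_channels)) {
      if (c0 > 0) {
        z <- complex(real = rnorm(nf), imaginary = rnorm(nf)) / sqrt(2)
        X <- amp_spec * z
        X[1] <- 0
        if (n %% 2 == 0) X[nf] <- 0
        full <- c(X, Conj(rev(X[2:(nf - 1)])))
        x[ch, ] <- Re(fft(full, inverse = TRUE)) / n
      }
      if (length(osc$amp)) {
        ph <- runif(length(osc$amp), 0, 2 * pi)
        for (j in seq_along(osc$amp))
          x[ch, ] <- x[ch, ] +
            osc$amp[j] * sin(2 * pi * osc$freq[j] * tgrid + ph[j])
      }
      if (spectrum$line_amp > 0) {
        for (f0 in c(50, 60))
          if (f0 < fs / 2)
            x[ch, ] <- x[ch, ] +
              spectrum$line_amp * sin(2 * pi * f0 * tgrid + runif(1, 0, 2 * pi))
      }
    }
    seg <- ts_segment(x, fs, subject = subject)
    attr(seg, "planted_band_powers") <- planted_band_powers(spectrum)
    seg
  })
}

#' The 41 homologous region pairs of the standard atlas fixture
#'
#' Base names of the 41 left/right region pairs (82 regions) used by the
#' synthetic parcellation at standard scale: 34 cortical parcels plus 7
#' subcortical structures per hemisphere. Pallidum, thalamus and
#' accumbens are the subcortical structures later excluded from the
#' normative table.
#'
#' @return Data frame with columns `base` and `subcortical`.
#' @export
standard_region_pairs <- function() {
  cortical <- c(
    "lateral_orbitofrontal", "medial_orbitofrontal", "pars_opercularis",
    "pars_orbitalis", "pars_triangularis", "rostral_middle_frontal",
    "caudal_middle_frontal", "superior_frontal", "frontal_pole",
    "precentral", "paracentral", "postcentral", "supramarginal",
    "superior_parietal", "inferior_parietal", "precuneus", "cuneus",
    "pericalcarine", "lateral_occipital", "lingual", "fusiform",
    "parahippocampal", "entorhinal", "temporal_pole", "inferior_temporal",
    "middle_temporal", "superior_temporal", "transverse_temporal",
    "bankssts", "insula", "rostral_anterior_cingulate",
    "caudal_anterior_cingulate", "posterior_cingulate", "isthmus_cingulate")
  subcortical <- c("hippocampus", "amygdala", "caudate", "putamen",
                   "thalamus", "pallidum", "accumbens")
  data.frame(base = c(cortical, subcortical),
             subcortical = rep(c(FALSE, TRUE),
                               c(length(cortical), length(subcortical))))
}

#' Simulate a volumetric parcellation of paired hemispheric regions
#'
#' Generates `2 * n_region_pairs` regions named with `left_`/`right_`
#' prefixes forming homologous pairs. Each right-hemisphere region is a
#' compact spherical blob of grey-matter voxel centres (mm) on a regular
#' grid; the left homologue is its mirror image across the sagittal
#' plane. Deterministic given the seed.
#'
#' @param n_region_pairs Number of homologous pairs (>= 1). 41 gives an
#'   82-region standard-scale fixture.
#' @param voxel_spacing Voxel grid spacing, mm.
#' @param seed Integer seed.
#' @param pair_names Optional data frame like [standard_region_pairs()];
#'   defaults to the standard names when `n_region_pairs` is 41, else
#'   generic `region_k` names.
#' @return A `parcellation`: list with `regions` (tibble: `region_id`,
#'   `name`, `base`, `hemisphere`, `subcortical`), `voxels` (tibble:
#'   `region_id`, `voxel_idx`, `x`, `y`, `z`) and `pairs` (tibble:
#'   `left_id`, `right_id`).
#' @export
simulate_parcellation <- function(n_region_pairs, voxel_spacing = 2,
                                  seed = 1L, pair_names = NULL) {
  stopifnot(n_region_pairs >= 1, voxel_spacing > 0)
  if (is.null(pair_names)) {
    pair_names <- if (n_region_pairs == 41) standard_region_pairs()
    else data.frame(base = sprintf("region_%02d", seq_len(n_region_pairs)),
                    subcortical = FALSE)
  }
  stopifnot(nrow(pair_names) == n_region_pairs)
  with_seed(seed, {
    vox <- list(); regs <- list()
    rid <- 0L
    pairs <- data.frame(left_id = integer(n_region_pairs),
                        right_id = integer(n_region_pairs))
    for (i in seq_len(n_region_pairs)) {
      centre <- c(runif(1, 15, 60), runif(1, -80, 55), runif(1, -45, 65))
      radius <- runif(1, 4, 9)
      g <- seq(-radius, radius, by = voxel_spacing)
      grid <- as.matrix(expand.grid(x = g, y = g, z = g))
      grid <- grid[rowSums(grid^2) <= radius^2, , drop = FALSE]
      if (nrow(grid) == 0L) grid <- matrix(0, 1, 3,
                                           dimnames = list(NULL, c("x", "y", "z")))
      for (hemi in c("left", "right")) {
        rid <- rid + 1L
        sgn <- if (hemi == "left") -1 else 1
        vox[[rid]] <- tibble::tibble(region_id = rid,
                                     voxel_idx = seq_len(nrow(grid)),
                                     x = sgn * (grid[, 1] + centre[1]),
                                     y = grid[, 2] + centre[2],
                                     z = grid[, 3] + centre[3])
        regs[[rid]] <- tibble::tibble(
          region_id = rid,
          name = paste0(hemi, "_", pair_names$base[i]),
          base = pair_names$base[i], hemisphere = hemi,
          subcortical = pair_names$subcortical[i])
        if (hemi == "left") pairs$left_id[i] <- rid
        else pairs$right_id[i] <- rid
      }
    }
    structure(list(regions = do.call(rbind, regs),
                   voxels = do.call(rbind, vox),
                   pairs = tibble::as_tibble(pairs)),
              class = "parcellation")
  })
}
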