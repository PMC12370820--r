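#' Locate the earliest valid interictal window
#'
#' Scans candidate window onsets on a 1 s grid and returns the earliest
#' window of the requested length whose every time point lies at least
#' `min_gap` seconds from the nearest edge of every annotated ictal
#' interval (the clearance is measured to the interval's closest edge, so
#' a window may precede or follow a seizure).
#'
#' @param ictal_annotations List of `c(start, end)` ictal intervals, s.
#' @param total_duration Total recording duration, s.
#' @param segment_length Window length, s (default 70).
#' @param min_gap Minimum distance from any ictal interval, s (default
#'   7200, i.e. two hours).
#' @return `c(start, end)` of the selected window, s.
#' @examples
#' select_segment(list(c(0, 60)), total_duration = 4 * 3600)
#' @export
select_segment <- function(ictal_annotations, total_duration,
                           segment_length = 70, min_gap = 7200) {
  stopifnot(total_duration > 0, segment_length > 0, min_gap >= 0)
  for (iv in ictal_annotations) {
    if (length(iv) != 2L || iv[1] > iv[2] || iv[1] < 0 ||
        iv[2] > total_duration)
      stop("ictal annotation [", iv[1], ", ", iv[2],
           "] outside [0, ", total_duration, "]")
  }
  if (total_duration < segment_length)
    stop("no interictal window: recording shorter than segment length")
  starts <- seq(0, total_duration - segment_length, by = 1)
  ok <- rep(TRUE, length(starts))
  for (iv in ictal_annotations) {
    # window [s, s+L] clears interval iff it ends min_gap before the
    # interval starts or begins min_gap after it ends
    ok <- ok & (starts + segment_length <= iv[1] - min_gap |
                  starts >= iv[2] + min_gap)
  }
  if (!any(ok)) stop("no interictal window clears the ", min_gap,
                     " s gap from all ictal events")
  s <- starts[which(ok)[1]]
  c(start = s, end = s + segment_length)
}

#' Screen channels for flat lines, amplitude outliers and line noise
#'
#' Heuristic automated channel quality control applied before any
#' filtering: flags channels whose peak-to-peak range falls below
#' `flat_range_uv` ("flat"), whose per-channel standard deviation is a
#' robust-z outlier against the other channels ("amplitude_outlier"), and
#' whose Welch power density around 50 or 60 Hz exceeds
#' `line_noise_ratio` times the density in the flanking +-2.5--7.5 Hz
#' bands ("line_noise"). Thresholds come from the shared
#' [pipeline_config()] and are returned alongside the decision so every
#' run logs the criteria it applied.
#'
#' @param segment A [ts_segment()] with at least 2 channels.
#' @param config A [pipeline_config()].
#' @return A list: `keep` (logical mask per channel), `reasons` (list of
#'   character vectors per channel, empty when clean), `thresholds`.
#' @export
screen_channels <- function(segment, config = pipeline_config()) {
  x <- segment$samples
  if (nrow(x) < 2L) stop("channel screening needs at least 2 channels")
  nch <- nrow(x)
  reasons <- rep(list(character(0)), nch)

  rng <- apply(x, 1, function(v) diff(range(v)))
  flat <- rng < config$flat_range_uv
  for (i in which(flat)) reasons[[i]] <- c(reasons[[i]], "flat")

  sds <- apply(x, 1, stats::sd)
  live <- !flat
  if (sum(live) >= 3L) {
    med <- stats::median(sds[live])
    scale <- stats::mad(sds[live])
    if (scale > 1e-12) {
      z <- abs(sds - med) / scale
      out <- live & z > config$amplitude_z
      for (i in which(out))
        reasons[[i]] <- c(reasons[[i]], "amplitude_outlier")
    }
  }

  # line-noise ratio at 50 and 60 Hz, where resolvable below Nyquist
  mains <- c(50, 60)
  mains <- mains[mains + 7.5 < segment$fs / 2]
  if (length(mains) > 0L && ncol(x) >= round(2 * segment$fs)) {
    psd <- welch_psd(segment, window = 2, overlap = 1)
    for (f0 in mains) {
      centre <- psd$freq >= f0 - 2.5 & psd$freq <= f0 + 2.5
      flank <- (psd$freq >= f0 - 7.5 & psd$freq < f0 - 2.5) |
        (psd$freq > f0 + 2.5 & psd$freq <= f0 + 7.5)
      pc <- rowMeans(psd$density[, centre, drop = FALSE])
      pf <- rowMeans(psd$density[, flank, drop = FALSE])
      noisy <- pf > 0 & pc / pf > config$line_noise_ratio
      for (i in which(noisy & !flat))
        reasons[[i]] <- c(reasons[[i]], paste0("line_noise_", f0))
    }
  }
  keep <- vapply(reasons, length, 1L) == 0L
  if (!any(keep))
    stop("all ", nch, " channels flagged; nothing to analyse")
  list(keep = keep, reasons = reasons,
       thresholds = list(flat_range_uv = config$flat_range_uv,
                         amplitude_z = config$amplitude_z,
                         line_noise_ratio = config$line_noise_ratio))
}

#' Zero-phase Butterworth band-pass filter
#'
#' A 4th-order Butterworth band-pass (8 poles) applied forward and
#' backward with [signal::filtfilt()], giving zero phase distortion and
#' an effective 16-pole magnitude response. Passband gain is ~1; DC and
#' content beyond the corners is strongly attenuated. Length preserved.
#'
#' @param segment A [ts_segment()].
#' @param low,high Corner frequencies, Hz (defaults 0.5 and 80).
#' @return Filtered [ts_segment()] at the same sampling rate.
#' @export
bandpass_filter <- function(segment, low = 0.5, high = 80) {
  fs <- segment$fs
  if (fs <= 2 * high)
    stop("sampling rate ", fs, " Hz too low for a ", high, " Hz corner")
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  n <- ncol(segment$samples)
  # odd-reflection padding keeps the forward-backward start-up transient
  # of the low corner (time constant ~ 1/(2 pi low)) out of the data
  pad <- min(n - 1L, ceiling(6 * fs / low))
  out <- t(apply(segment$samples, 1, function(v) {
    ext <- c(2 * v[1] - v[(pad + 1L):2],
             v,
             2 * v[n] - v[(n - 1L):(n - pad)])
    signal::filtfilt(bf, ext)[(pad + 1L):(pad + n)]
  }))
  ts_segment(out, fs, segment$labels, segment$subject)
}

#' Anti-aliased resampling to a target rate
#'
#' Rational-rate polyphase FIR resampling (upfirdn): the signal is
#' zero-stuffed by the interpolation factor, passed through a linear
#' phase FIR low-pass cutting at the smaller of the two Nyquist
#' frequencies (the anti-alias filter; 20 taps per polyphase branch,
#' Hamming design via [signal::fir1()], group delay compensated), and
#' decimated. Passband content below ~0.9 of the new Nyquist is
#' preserved to well within 2%. Refuses to upsample. An input already at
#' the target rate is returned unchanged.
#'
#' @param segment A [ts_segment()].
#' @param target_fs Target sampling rate, Hz (default 200).
#' @return Resampled [ts_segment()] at `target_fs`.
#' @export
downsample <- function(segment, target_fs = 200) {
  fs <- segment$fs
  if (fs < target_fs)
    stop("refusing to upsample: fs ", fs, " < target ", target_fs)
  if (isTRUE(all.equal(fs, target_fs))) return(segment)
  k <- 1000  # tolerate rates specified to 1 mHz
  a <- round(target_fs * k); b <- round(fs * k)
  g <- gcd_int(a, b)
  p <- a / g; q <- b / g
  out <- t(apply(segment$samples, 1, resample_upfirdn, p = p, q = q))
  ts_segment(out, target_fs, segment$labels, segment$subject)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# zero-stuff by p, FIR low-pass at min Nyquist, decimate by q; the FIR is
# long enough (20 taps per branch) that passband droop is negligible
resample_upfirdn <- function(x, p, q) {
  m <- max(p, q)
  L <- 20L * m + 1L                       # odd length, exact group delay
  h <- p * signal::fir1(L - 1L, 1 / m)
  delay <- (L - 1L) %/% 2L
  n_out <- ceiling(length(x) * p / q)
  up <- numeric(length(x) * p + delay)
  up[seq(1L, by = p, length.out = length(x))] <- x
  y <- signal::fftfilt(h, up)
  y <- y[(delay + 1L):length(y)]
  y[seq(1L, by = q, length.out = n_out)]
}

#' Common average reference
#'
#' Subtracts the across-channel mean from every sample, so the output's
#' across-channel mean is exactly zero at each time point. Apply after
#' channel screening so bad channels do not contaminate the reference.
#'
#' @param segment A [ts_segment()] with at least 2 channels.
#' @return Re-referenced [ts_segment()].
#' @export
common_average_reference <- function(segment) {
  if (nrow(segment$samples) < 2L)
    stop("common average reference needs at least 2 channels")
  out <- sweep(segment$samples, 2, colMeans(segment$samples))
  ts_segment(out, segment$fs, segment$labels, segment$subject)
}

#' Welch power spectral density estimate
#'
#' Hann-windowed, overlap-averaged periodogram with density scaling
#' (uV^2/Hz): with the default 2 s window the frequency grid has 0.5 Hz
#' spacing and integrating the density over the full grid recovers the
#' signal variance (Parseval consistency).
#'
#' @param segment A [ts_segment()].
#' @param window Window length, s (default 2).
#' @param overlap Overlap between consecutive windows, s (default 1).
#' @return A `psd_estimate`: `freq` (Hz, 0..fs/2), `density`
#'   (channels x frequency matrix, uV^2/Hz), `window`, `overlap`, `fs`.
#' @export
welch_psd <- function(segment, window = 2, overlap = 1) {
  fs <- segment$fs
  nwin <- round(window * fs)
  step <- round((window - overlap) * fs)
  stopifnot(nwin > 1, step >= 1)
  n <- ncol(segment$samples)
  if (n < nwin)
    stop("segment (", n, " samples) shorter than the ", window,
         " s window (", nwin, " samples)")
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nwin - 1) / (nwin - 1))  # Hann
  starts <- seq(1, n - nwin + 1, by = step)
  nfreq <- nwin %/% 2 + 1
  scale <- 1 / (fs * sum(w^2) * length(starts))
  dens <- matrix(0, nrow(segment$samples), nfreq)
  for (s in starts) {
    seg <- segment$samples[, s:(s + nwin - 1), drop = FALSE]
    seg <- seg - rowMeans(seg)  # per-window detrend (constant)
    X <- t(apply(seg * rep(w, each = nrow(seg)), 1, stats::fft))
    dens <- dens + Mod(X[, seq_len(nfreq), drop = FALSE])^2 * scale
  }
  # one-sided: double everything except DC and (for even nwin) Nyquist
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (nwin %% 2 == 0) dbl[nfreq] <- 1
  dens <- sweep(dens, 2, dbl, `*`)
  rownames(dens) <- segment$labels
  structure(list(freq = seq(0, nfreq - 1) * fs / nwin, density = dens,
                 window = window, overlap = overlap, fs = fs),
            class = "psd_estimate")
}

#' Integrated band power from a PSD estimate
#'
#' Rectangle-rule integral of the density over the band's frequency
#' support: a grid bin contributes iff its centre frequency falls in the
#' half-open interval `[lower, upper)` and in none of the band's excluded
#' sub-intervals (same half-open rule), so shared band edges are counted
#' exactly once. For the gamma band the 47.5--52.5 and 57.5--62.5 Hz
#' power-line windows are excluded.
#'
#' @param psd A `psd_estimate` from [welch_psd()].
#' @param band A [band_definition()].
#' @return Named numeric vector of band power per channel, uV^2.
#' @export
band_power <- function(psd, band) {
  if (band$lower < min(psd$freq) || band$upper > max(psd$freq) + 1e-9)
    stop("band [", band$lower, ", ", band$upper,
         ") outside the PSD grid [", min(psd$freq), ", ", max(psd$freq), "]")
  df <- psd$freq[2] - psd$freq[1]
  inb <- psd$freq >= band$lower & psd$freq < band$upper
  for (ex in band$exclusions)
    inb <- inb & !(psd$freq >= ex[1] & psd$freq < ex[2])
  rowSums(psd$density[, inb, drop = FALSE]) * df
}

#' Relative band power: log10-transformed, L1-normalised band powers
#'
#' For each channel, the five band powers are log10 transformed and the
#' logs divided by their sum, yielding five components that sum to one:
#' the relative band power vector RBP. The normalisation is only convex
#' (all components positive) when the five logs share one sign, which
#' holds when all band powers sit on the same side of 1 uV^2; typical
#' referential icEEG in uV gives band powers well above 1, so the logs
#' are positive and a band with more power receives a larger component.
#' Mixed-sign logs raise an error asking the caller to rescale units
#' rather than silently producing non-convex weights.
#'
#' @param psd A `psd_estimate` from [welch_psd()].
#' @param bands Five band definitions (default [default_bands()]).
#' @return Matrix, channels x 5 bands, rows summing to 1.
#' @export
relative_band_power <- function(psd, bands = default_bands()) {
  bp <- vapply(bands, function(b) band_power(psd, b),
               numeric(nrow(psd$density)))
  if (nrow(psd$density) == 1L) bp <- matrix(bp, nrow = 1L,
                                            dimnames = list(NULL, names(bands)))
  if (any(bp <= 0))
    stop("zero band power encountered; raw band powers must be strictly ",
         "positive (consider an epsilon floor on the PSD)")
  lg <- log10(bp)
  sgn <- sign(lg)
  bad <- apply(sgn, 1, function(s) any(s > 0) && any(s < 0))
  if (any(bad))
    stop("log10 band powers have mixed signs on ", sum(bad), " channel(s); ",
         "rescale the input units so all band powers lie on one side of 1")
  out <- lg / rowSums(lg)
  rownames(out) <- rownames(psd$density)
  out
}

#' Full signal chain: raw referential segment to RBP per retained contact
#'
#' Runs channel screening, 0.5--80 Hz zero-phase band-pass, anti-aliased
#' resampling to 200 Hz, common average referencing, Welch PSD (2 s / 1 s)
#' and log10/L1 relative band power, with all constants taken from the
#' shared [pipeline_config()].
#'
#' @param segment A raw [ts_segment()].
#' @param config A [pipeline_config()].
#' @return A [tibble::tibble()] with one row per retained channel:
#'   `subject`, `channel`, and one column per band. The screening report
#'   is attached as attribute `"screening"`.
#' @export
extract_rbp <- function(segment, config = pipeline_config()) {
  scr <- screen_channels(segment, config)
  kept <- ts_segment(segment$samples[scr$keep, , drop = FALSE], segment$fs,
                     segment$labels[scr$keep], segment$subject)
  if (nrow(kept$samples) < 2L)
    stop("fewer than 2 channels survive screening")
  kept <- bandpass_filter(kept, config$filter_low, config$filter_high)
  kept <- downsample(kept, config$target_fs)
  kept <- common_average_reference(kept)
  psd <- welch_psd(kept, config$welch_window, config$welch_overlap)
  rbp <- relative_band_power(psd, config$bands)
  out <- tibble::tibble(subject = kept$subject, channel = kept$labels)
  for (b in colnames(rbp)) out[[b]] <- rbp[, b]
  attr(out, "screening") <- scr
  out
}
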