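#' Construct a multichannel time-series segment
#'
#' The unit of work of the signal-processing chain: a channels-by-time
#' matrix of referential voltages (uV) with its sampling rate.
#'
#' @param samples Numeric matrix, channels x time, uV.
#' @param fs Sampling rate, Hz.
#' @param labels Optional channel labels (default `ch001`, `ch002`, ...).
#' @param subject Optional subject identifier.
#' @return An object of class `ts_segment`.
#' @export
ts_segment <- function(samples, fs, labels = NULL, subject = NA_character_) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1L)
  stopifnot(is.numeric(samples), is.numeric(fs), length(fs) == 1L, fs > 0)
  if (!all(is.finite(samples))) stop("segment contains non-finite samples")
  if (is.null(labels))
    labels <- sprintf("ch%03d", seq_len(nrow(samples)))
  if (length(labels) != nrow(samples))
    stop("need one label per channel: ", nrow(samples), " channels, ",
         length(labels), " labels")
  structure(list(samples = samples, fs = fs, labels = labels,
                 subject = subject),
            class = "ts_segment")
}

#' @export
print.ts_segment <- function(x, ...) {
  cat(sprintf("<ts_segment> %d channels x %d samples @ %g Hz (%.1f s)%s\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs,
              if (is.na(x$subject)) "" else paste0(" subject ", x$subject)))
  invisible(x)
}

#' @export
dim.ts_segment <- function(x) dim(x$samples)

n_channels <- function(seg) nrow(seg$samples)
n_samples <- function(seg) ncol(seg$samples)
seg_duration <- function(seg) ncol(seg$samples) / seg$fs
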