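# Denoising of fused skeleton streams (median + zero-phase Butterworth
# low-pass) and per-channel signal-to-noise computation.

#' Filter specification
#'
#' The pipeline order is median-then-Butterworth.  A 30 Hz cutoff is
#' only meaningful above 60 Hz sampling; at lower rates the cutoff defaults
#' to `0.45 * sample_rate` (see the methods vignette).
#'
#' @param sample_rate Sampling rate (Hz).
#' @param median_window Odd window length (samples) of the median stage.
#' @param butter_order Butterworth order.
#' @param cutoff Low-pass cutoff (Hz); default `min(30, 0.45 * sample_rate)`.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(sample_rate, median_window = 5, butter_order = 6,
                        cutoff = min(30, 0.45 * sample_rate)) {
  if (median_window %% 2 != 1 || median_window < 3)
    stop("filter_spec: median_window must be odd and >= 3")
  if (cutoff <= 0 || cutoff >= sample_rate / 2)
    stop(sprintf(
      "filter_spec: cutoff %.3g Hz not in (0, Nyquist) for sample rate %.3g Hz (Nyquist %.3g Hz)",
      cutoff, sample_rate, sample_rate / 2))
  structure(list(sample_rate = sample_rate, median_window = median_window,
                 butter_order = butter_order, cutoff = cutoff),
            class = "filter_spec")
}

#' Median filter with reflected edges
#'
#' Running median of odd window length; the series is padded by reflection so
#' the output has the input's length and constant series pass unchanged.
#' Eliminates isolated outlier samples (occlusion spikes).
#'
#' @param x Numeric series.
#' @param window Odd window length, `<= length(x)`.
#' @return Filtered series, same length as `x`.
#' @export
median_filter <- function(x, window = 5) {
  if (window %% 2 != 1) stop("median_filter: window must be odd")
  if (window > length(x)) stop("median_filter: window exceeds series length")
  if (window < 3) return(x)
  h <- (window - 1) / 2
  xp <- c(x[(h + 1):2], x, x[(length(x) - 1):(length(x) - h)])
  y <- stats::runmed(xp, window, endrule = "keep")
  y[(h + 1):(h + length(x))]
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies the Butterworth design forward and backward
#' (`signal::filtfilt`) so filtered landmarks are not shifted in time;
#' DC gain is 1.
#'
#' @param x Numeric series.
#' @param spec A [filter_spec()].
#' @return Filtered series, same length as `x`.
#' @export
lowpass_filter <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  bf <- signal::butter(spec$butter_order,
                       spec$cutoff / (spec$sample_rate / 2), type = "low")
  n <- length(x)
  # odd-reflection padding keeps the start/end transients out of the data
  pad <- min(n - 1, max(3 * (spec$butter_order + 1),
                        spec$butter_order *
                          ceiling(2 * spec$sample_rate / spec$cutoff)))
  pre <- 2 * x[1] - x[(pad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- as.numeric(signal::filtfilt(bf, c(pre, x, post)))
  y[(pad + 1):(pad + n)]
}

#' Denoise every joint-axis channel of a stream
#'
#' Median filter followed by the zero-phase Butterworth low-pass, applied
#' independently to each joint's x/y/z series.  Confidences and timestamps
#' are carried over.
#'
#' @param stream A `skeleton_stream`.
#' @param spec A [filter_spec()]; default derived from the stream's median
#'   frame interval.
#' @return Filtered `skeleton_stream`.
#' @export
preprocess_stream <- function(stream, spec = NULL) {
  if (is.null(spec)) {
    fs <- 1 / stats::median(diff(stream$timestamps))
    spec <- filter_spec(fs)
  }
  xyz <- stream$xyz
  for (j in seq_along(stream$joints)) {
    ok <- stream$conf[, j] > 0
    for (d in 1:3) {
      s <- xyz[, j, d]
      # bridge occlusion sentinels so they cannot contaminate the filters;
      # the confidence-0 marks are kept, so downstream model fitting still
      # treats these samples as unobserved
      if (any(!ok) && sum(ok) >= 2)
        s <- stats::approx(which(ok), s[ok], xout = seq_along(s),
                           rule = 2)$y
      if (length(s) > spec$median_window)
        s <- median_filter(s, spec$median_window)
      if (length(s) > 3 * (spec$butter_order + 1))
        s <- lowpass_filter(s, spec)
      xyz[, j, d] <- s
    }
  }
  skeleton_stream(stream$timestamps, stream$joints, xyz, stream$conf)
}

#' Signal-to-noise ratio in decibels
#'
#' Treats `reference` as the signal and `raw - reference` as noise:
#' `10 * log10(var(reference) / var(raw - reference))`.  Returns `Inf` when
#' the two series are identical (zero noise variance).
#'
#' @param raw,reference Equal-length numeric series.
#' @return SNR in dB.
#' @export
snr_db <- function(raw, reference) {
  stopifnot(length(raw) == length(reference))
  nv <- stats::var(raw - reference)
  if (!is.finite(nv) || nv == 0) return(Inf)
  10 * log10(stats::var(reference) / nv)
}

#' Per-channel SNR table for two streams
#'
#' @param raw,clean `skeleton_stream` objects over the same joints, with the
#'   clean stream as reference.
#' @return `data.frame` with columns `joint`, `axis`, `snr_db`.
#' @export
snr_table <- function(raw, clean) {
  stopifnot(identical(raw$joints, clean$joints),
            n_frames(raw) == n_frames(clean))
  ax <- c("x", "y", "z")
  out <- expand.grid(joint = raw$joints, axis = ax,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(match(out$joint, raw$joints)), ]
  out$snr_db <- mapply(function(j, d) {
    snr_db(raw$xyz[, match(j, raw$joints), match(d, ax)],
           clean$xyz[, match(j, clean$joints), match(d, ax)])
  }, out$joint, out$axis)
  rownames(out) <- NULL
  out
}
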