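#' Notch out power-line interference
#'
#' Zero-phase second-order Butterworth band-stop centered on the line
#' frequency (applied forward-backward), attenuating the line component by
#' well over 20 dB while leaving broadband power essentially unchanged.
#'
#' @param rec An \code{\link{ieeg_recording}}.
#' @param line_freq Line frequency in Hz, 50 or 60 in practice; must be
#'   below Nyquist.
#' @param half_width Half-width of the stop band in Hz (default 2).
#' @return Filtered recording of identical length.
#' @export
notch <- function(rec, line_freq, half_width = 2) {
  ny <- rec$sample_rate / 2
  if (line_freq >= ny) stop("`line_freq` must be below Nyquist")
  flt <- signal::butter(2, c(line_freq - half_width, line_freq + half_width) / ny,
                        type = "stop")
  rec$samples <- t(apply(rec$samples, 1, function(x) signal::filtfilt(flt, x)))
  rec
}

#' Anti-alias low-pass and resample to the standard rate
#'
#' Applies a zero-phase FIR low-pass with the given passband edge, then
#' resamples to \code{target_rate} (polyphase for rational ratios).
#' Upsampling requests are rejected: the standardized dataset is only ever
#' produced by downsampling.
#'
#' @param rec An \code{\link{ieeg_recording}}.
#' @param target_rate Output rate in Hz (default 400).
#' @param passband_edge Low-pass passband edge in Hz (default 180).
#' @param order FIR order for the anti-aliasing filter (default 128).
#' @return Recording at \code{target_rate}, onset index rescaled.
#' @export
antialias_resample <- function(rec, target_rate = 400, passband_edge = 180,
                               order = 128) {
  fs <- rec$sample_rate
  if (fs < target_rate) stop("upsampling is not supported; original rate below target")
  ny <- fs / 2
  h <- signal::fir1(order, min(passband_edge, 0.99 * ny) / ny, type = "low")
  low <- t(apply(rec$samples, 1, function(x) signal::filtfilt(h, x)))
  if (fs == target_rate) {
    rec$samples <- low
    return(rec)
  }
  frac <- gcd_ratio(target_rate, fs)
  out <- t(apply(low, 1, function(x) signal::resample(x, frac[1], frac[2])))
  rec$samples <- rbind(out)
  rec$onset_sample <- as.integer(floor((rec$onset_sample - 1) * target_rate / fs)) + 1L
  rec$sample_rate <- target_rate
  rec
}

gcd_ratio <- function(p, q) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(p, q)
  c(p / d, q / d)
}

#' Zero-phase FIR high-pass (DC and drift removal)
#'
#' Hamming-window FIR high-pass applied forward-backward, so pure tones in
#' the passband keep zero group delay. The default order gives a narrow
#' enough transition to remove sub-Hz drift while passing 1 Hz upward.
#'
#' @param rec An \code{\link{ieeg_recording}}.
#' @param passband_edge Passband edge in Hz (default 1).
#' @param order FIR order; even (default 1600 at 400 Hz, i.e. a 4 s kernel).
#' @return Filtered recording.
#' @export
highpass_fir <- function(rec, passband_edge = 1, order = 1600) {
  ny <- rec$sample_rate / 2
  h <- signal::fir1(order, passband_edge / ny, type = "high")
  rec$samples <- t(apply(rec$samples, 1, function(x) fir_zerophase(h, x)))
  rec
}

# linear-phase FIR applied with exact group-delay (order/2) compensation,
# via FFT convolution; zero phase for even-order symmetric kernels
fir_zerophase <- function(h, x) {
  d <- (length(h) - 1L) %/% 2L
  y <- signal::fftfilt(h, c(x, numeric(d)))
  y[(d + 1L):(d + length(x))]
}

#' Crop a recording to the standardized window around seizure onset
#'
#' Produces a \code{total}-second recording with onset aligned
#' \code{onset_at} seconds in (default: 2 minutes with onset at 1 minute).
#' Recordings without enough context on either side of onset are rejected.
#'
#' @param rec An \code{\link{ieeg_recording}}.
#' @param total Output duration in seconds (default 120).
#' @param onset_at Onset position within the output in seconds (default 60).
#' @return Cropped recording; idempotent on already-standardized input.
#' @export
crop_align <- function(rec, total = 120, onset_at = 60) {
  fs <- rec$sample_rate
  n_total <- round(total * fs)
  n_pre <- round(onset_at * fs)
  start <- rec$onset_sample - n_pre
  stop_ <- start + n_total - 1L
  if (start < 1 || stop_ > ncol(rec$samples)) {
    stop("insufficient context around onset for the requested crop")
  }
  rec$samples <- rec$samples[, start:stop_, drop = FALSE]
  rec$onset_sample <- as.integer(n_pre + 1L)
  rec
}

#' Re-reference a recording
#'
#' \code{"common-average"} subtracts the instantaneous channel mean (the
#' montage of the canine contest data); \code{"common-reference"} leaves
#' samples as recorded.
#'
#' @param rec An \code{\link{ieeg_recording}}.
#' @param montage Target montage tag.
#' @return Re-referenced recording with updated \code{montage_tag}.
#' @export
rereference <- function(rec, montage = c("common-reference", "common-average")) {
  montage <- match.arg(montage)
  if (montage == "common-average") {
    rec$samples <- sweep(rec$samples, 2, colMeans(rec$samples))
  }
  rec$montage_tag <- montage
  rec
}

#' Cut a recording into labeled 1 s single-channel epochs
#'
#' Half-open windows \code{[t, t + window)}: the epoch whose start
#' coincides with onset is the first ictal epoch, so every sample at or
#' after onset is labeled ictal (1) and everything before it preictal (0).
#' Non-overlapping mode tiles the recording exactly; 50%-overlap mode is
#' the sliding-window augmentation used at deployment.
#'
#' @param rec An \code{\link{ieeg_recording}} at the standard rate.
#' @param window Epoch length in seconds (default 1).
#' @param overlap Fractional overlap, 0 or 0.5.
#' @return An \code{epoch_set}: list with \code{samples} (epochs x
#'   samples-per-epoch matrix) and \code{index} (data.frame of subject_id,
#'   channel_id, offset seconds relative to onset, label).
#' @export
epoch_and_label <- function(rec, window = 1, overlap = 0) {
  stopifnot(overlap %in% c(0, 0.5))
  fs <- rec$sample_rate
  len <- round(window * fs)
  step <- round(len * (1 - overlap))
  starts <- seq(1L, ncol(rec$samples) - len + 1L, by = step)
  rows <- vector("list", length(starts) * nrow(rec$samples))
  idx <- vector("list", length(rows))
  k <- 0L
  for (ci in seq_len(nrow(rec$samples))) {
    for (s in starts) {
      k <- k + 1L
      rows[[k]] <- rec$samples[ci, s:(s + len - 1L)]
      off <- (s - rec$onset_sample) / fs
      idx[[k]] <- data.frame(subject_id = rec$subject_id,
                             channel_id = rec$channel_ids[ci],
                             offset = off,
                             label = as.integer(off >= 0),
                             stringsAsFactors = FALSE)
    }
  }
  structure(list(samples = do.call(rbind, rows),
                 index = do.call(rbind, idx),
                 sample_rate = fs),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch_set: %d epochs x %d samples (%d ictal, %d preictal), %d subject(s)\n",
              nrow(x$samples), ncol(x$samples), sum(x$index$label == 1),
              sum(x$index$label == 0), length(unique(x$index$subject_id))))
  invisible(x)
}

#' Combine epoch sets from several recordings
#'
#' @param sets List of \code{epoch_set} objects at a common sample rate.
#' @return A single \code{epoch_set}.
#' @export
bind_epoch_sets <- function(sets) {
  stopifnot(length(unique(vapply(sets, `[[`, numeric(1), "sample_rate"))) == 1)
  structure(list(samples = do.call(rbind, lapply(sets, `[[`, "samples")),
                 index = do.call(rbind, lapply(sets, `[[`, "index")),
                 sample_rate = sets[[1]]$sample_rate),
            class = "epoch_set")
}

#' Standard preprocessing chain for a dataset of recordings
#'
#' Notch (optional), anti-alias resample to 400 Hz, zero-phase 1 Hz FIR
#' high-pass, crop to the 2-minute onset-aligned window, then epoch and
#' label.
#'
#' @param recordings List of \code{\link{ieeg_recording}} objects.
#' @param line_freq Line frequency to notch, or \code{NULL} to skip.
#' @param overlap Epoching overlap (0 or 0.5).
#' @param crop If \code{TRUE} (default), crop-align to 120 s around onset.
#' @return A combined \code{epoch_set}.
#' @export
preprocess_dataset <- function(recordings, line_freq = NULL, overlap = 0,
                               crop = TRUE) {
  sets <- lapply(recordings, function(r) {
    if (!is.null(line_freq)) r <- notch(r, line_freq)
    if (r$sample_rate != 400) r <- antialias_resample(r)
    r <- highpass_fir(r)
    if (crop) r <- crop_align(r)
    epoch_and_label(r, overlap = overlap)
  })
  bind_epoch_sets(sets)
}
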