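#' Configuration for the synthetic iEEG generator
#'
#' Defines the study conditions the generator emulates: 2-minute,
#' 400 Hz multi-subject recordings with seizure onset aligned at 60 s, a
#' preictal 1/f background with subject-specific alpha/theta rhythms, and
#' an ictal half with elevated beta / low-gamma / high-gamma power plus
#' rhythmic discharges that ramp up after onset.
#'
#' @param n_subjects Number of subjects.
#' @param channels_per_subject Channels recorded per subject.
#' @param sample_rate Sample rate in Hz (default 400).
#' @param duration Recording length in seconds (default 120).
#' @param onset_time Seizure onset in seconds, strictly inside
#'   \code{(0, duration)} (default 60, the midpoint).
#' @param seed Integer seed; recordings are deterministic given
#'   \code{(seed, subject_index)}.
#' @param ictal_band_gain Named list of multiplicative power gains applied
#'   to bands during the ictal half (names from \code{\link{eeg_bands}}).
#' @param discharge_rate Rate (Hz) of the rhythmic ictal discharge train.
#' @param subject_variability Relative spread of per-subject parameters
#'   (0 makes all subjects identical).
#' @param line_noise_hz Optional sinusoidal line-noise frequency (e.g. 60);
#'   \code{NULL} disables it.
#' @return A \code{synthetic_config} list.
#' @export
synthetic_config <- function(n_subjects = 10, channels_per_subject = 2,
                             sample_rate = 400, duration = 120,
                             onset_time = 60, seed = 1,
                             ictal_band_gain = list(low_gamma = 8,
                                                    high_gamma = 6),
                             discharge_rate = 3,
                             subject_variability = 0.1,
                             line_noise_hz = NULL) {
  cfg <- list(n_subjects = n_subjects, channels_per_subject = channels_per_subject,
              sample_rate = sample_rate, duration = duration,
              onset_time = onset_time, seed = seed,
              ictal_band_gain = ictal_band_gain, discharge_rate = discharge_rate,
              subject_variability = subject_variability,
              line_noise_hz = line_noise_hz)
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1, cfg$channels_per_subject >= 1)
  if (cfg$onset_time <= 0 || cfg$onset_time >= cfg$duration) {
    stop("`onset_time` must lie strictly inside (0, duration)")
  }
  top <- max(vapply(eeg_bands(), `[`, numeric(1), 2))
  if (cfg$sample_rate <= 2 * top) {
    stop(sprintf("sample_rate must exceed twice the highest band edge (%g Hz)", top))
  }
  if (length(cfg$ictal_band_gain)) {
    if (is.null(names(cfg$ictal_band_gain)) ||
        !all(names(cfg$ictal_band_gain) %in% names(eeg_bands()))) {
      stop("ictal_band_gain names must be canonical band names")
    }
    if (any(unlist(cfg$ictal_band_gain) <= 0)) stop("band gains must be > 0")
  }
  if (cfg$subject_variability < 0) stop("subject_variability must be >= 0")
  invisible(cfg)
}

#' Construct an iEEG recording object
#'
#' @param samples channels x time numeric matrix (microvolt-scale units).
#' @param sample_rate Sample rate in Hz.
#' @param onset_sample 1-based index of the first ictal sample.
#' @param subject_id,channel_ids Identifiers.
#' @param montage_tag "common-reference" or "common-average".
#' @return An \code{ieeg_recording}.
#' @export
ieeg_recording <- function(samples, sample_rate, onset_sample, subject_id,
                           channel_ids = NULL,
                           montage_tag = "common-reference") {
  samples <- rbind(samples)
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(nrow(samples)))
  stopifnot(all(is.finite(samples)),
            onset_sample >= 1, onset_sample <= ncol(samples),
            length(channel_ids) == nrow(samples))
  structure(list(samples = samples, sample_rate = sample_rate,
                 onset_sample = as.integer(onset_sample),
                 subject_id = subject_id, channel_ids = channel_ids,
                 montage_tag = montage_tag),
            class = "ieeg_recording")
}

#' @export
print.ieeg_recording <- function(x, ...) {
  cat(sprintf("iEEG recording: subject %s, %d channel(s), %.1f s @ %g Hz, onset at %.1f s (%s)\n",
              x$subject_id, nrow(x$samples), ncol(x$samples) / x$sample_rate,
              x$sample_rate, (x$onset_sample - 1) / x$sample_rate, x$montage_tag))
  invisible(x)
}

# evaluate expr under a derived RNG substream, restoring global RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% (.Machine$integer.max - 1L)))
  expr
}

# per-subject rhythm/amplitude parameters, drawn deterministically
subject_params <- function(cfg, subject_index) {
  with_seed(cfg$seed * 1009L + subject_index, {
    v <- cfg$subject_variability
    jit <- function(center, spread) center * (1 + v * spread * stats::runif(1, -1, 1))
    list(
      alpha_freq = jit(10, 0.4),      # 8-12 Hz subject rhythm
      theta_freq = jit(6, 0.5),       # 4-8 Hz
      alpha_amp = jit(12, 0.5),
      theta_amp = jit(8, 0.5),
      bg_amp = jit(20, 0.5),
      discharge_rate = min(4, max(2, jit(cfg$discharge_rate, 0.5)))
    )
  })
}

# 1/f^beta colored noise via spectral shaping of white noise
one_over_f_noise <- function(n, beta = 1) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)             # symmetric frequency index
  X <- X / f^(beta / 2)
  X[1] <- 0
  Re(stats::fft(X, inverse = TRUE) / n)
}

# band-limited oscillation matching a target time-domain power
band_oscillation <- function(n, fs, band, target_power, phase_jitter = TRUE) {
  t <- (seq_len(n) - 1) / fs
  f0 <- stats::runif(1, band[1], min(band[2], fs / 2 - 1))
  ph <- if (phase_jitter) stats::runif(1, 0, 2 * pi) else 0
  sqrt(2 * target_power) * sin(2 * pi * f0 * t + ph)
}

#' Generate one synthetic iEEG recording
#'
#' The preictal half is 1/f background plus the subject's alpha and theta
#' rhythms. The ictal half keeps the background and adds (i) band-limited
#' oscillations whose power equals the configured gain times the measured
#' preictal power of that band and (ii) a 2-4 Hz train of sharp biphasic
#' discharges with an amplitude ramp after onset, whose rhythm also
#' amplitude-modulates the injected high-gamma component so that
#' phase-amplitude coupling (and hence PLHG) rises ictally.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @param subject_index Subject number (1-based); output is deterministic
#'   given \code{(config$seed, subject_index)}.
#' @return An \code{\link{ieeg_recording}} with
#'   \code{channels_per_subject} rows.
#' @export
generate_recording <- function(config, subject_index = 1) {
  validate_synthetic_config(config)
  sp <- subject_params(config, subject_index)
  fs <- config$sample_rate
  n <- round(config$duration * fs)
  onset <- round(config$onset_time * fs) + 1L
  t <- (seq_len(n) - 1) / fs
  ictal <- seq_len(n) >= onset

  ch <- with_seed(config$seed * 7907L + subject_index * 131L,
                  lapply(seq_len(config$channels_per_subject), function(ci) {
    bg <- sp$bg_amp * one_over_f_noise(n)
    x <- bg +
      sp$alpha_amp * sin(2 * pi * sp$alpha_freq * t + stats::runif(1, 0, 2 * pi)) +
      sp$theta_amp * sin(2 * pi * sp$theta_freq * t + stats::runif(1, 0, 2 * pi))

    # measured preictal band powers set the scale of the ictal components
    pre <- x[!ictal]
    bp <- welch_band_powers(pre, fs = fs, seg_length = 4 * fs)
    ramp <- pmin(1, pmax(0, (t - config$onset_time) / 5))  # 5 s onset ramp
    fd <- sp$discharge_rate
    for (bname in names(config$ictal_band_gain)) {
      g <- config$ictal_band_gain[[bname]]
      osc <- band_oscillation(n, fs, eeg_bands()[[bname]],
                              target_power = g * bp[[bname]])
      if (bname == "high_gamma") {
        # phase-lock high-gamma bursts to the discharge rhythm
        osc <- osc * (0.5 + 0.5 * cos(2 * pi * fd * t))
        osc <- osc * sqrt(8 / 3)      # restore target power after modulation
      }
      x <- x + ictal * ramp * osc
    }
    # rhythmic sharp discharges: biphasic derivative-of-Gaussian transients
    spike_times <- seq(config$onset_time, config$duration, by = 1 / fd)
    spike <- numeric(n)
    width <- 0.02                     # 20 ms transient
    for (st in spike_times) {
      idx <- which(abs(t - st) < 5 * width)
      u <- (t[idx] - st) / width
      spike[idx] <- spike[idx] - u * exp(-u^2 / 2)
    }
    x <- x + 3 * sp$bg_amp * ramp * spike
    # slow ictal rhythm at the discharge rate carries the LF phase
    x <- x + ictal * ramp * sp$theta_amp * sin(2 * pi * fd * t)
    if (!is.null(config$line_noise_hz)) {
      x <- x + 2 * sin(2 * pi * config$line_noise_hz * t)
    }
    x
  }))
  ieeg_recording(do.call(rbind, ch), fs, onset,
                 subject_id = sprintf("S%02d", subject_index),
                 channel_ids = sprintf("S%02d_ch%d", subject_index,
                                       seq_len(config$channels_per_subject)))
}

#' Generate the full multi-subject synthetic dataset
#'
#' One recording per subject (each holding all of that subject's channels),
#' with subject-level rhythm parameters drawn once per subject so channels
#' within a subject share their rhythms.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @return List of \code{n_subjects} \code{\link{ieeg_recording}} objects.
#' @export
generate_dataset <- function(config) {
  validate_synthetic_config(config)
  lapply(seq_len(config$n_subjects), function(i) generate_recording(config, i))
}

#' Write / read a recording as plain text with a JSON manifest
#'
#' Samples go to a TSV (one row per channel) and recording metadata
#' (subject, sample rate, onset sample, channel ids, montage) to a JSON
#' sidecar, a text-only interchange format that round-trips exactly.
#'
#' @param rec An \code{\link{ieeg_recording}}.
#' @param path Base path without extension; writes \code{<path>.tsv} and
#'   \code{<path>.json}.
#' @return \code{write_recording}: the base path, invisibly.
#'   \code{read_recording}: the reconstructed recording.
#' @export
write_recording <- function(rec, path) {
  utils::write.table(format(rec$samples, digits = 10, trim = TRUE, scientific = TRUE),
                     paste0(path, ".tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- rec[c("sample_rate", "onset_sample", "subject_id", "channel_ids",
                "montage_tag")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  m <- as.matrix(utils::read.table(paste0(path, ".tsv"), sep = "\t"))
  dimnames(m) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ieeg_recording(m, meta$sample_rate, meta$onset_sample, meta$subject_id,
                 meta$channel_ids, meta$montage_tag)
}
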