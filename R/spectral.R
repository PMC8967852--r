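#' Canonical EEG frequency bands (Hz)
#'
#' delta 2-4, theta 4-8, alpha 8-12, beta 12-30, low gamma 30-80,
#' high gamma 80-150. Band membership uses half-open intervals
#' \code{[lo, hi)} so adjacent bands never double-count a bin.
#'
#' @return Named list of \code{c(lo, hi)} pairs.
#' @export
eeg_bands <- function() {
  list(
    delta = c(2, 4), theta = c(4, 8), alpha = c(8, 12),
    beta = c(12, 30), low_gamma = c(30, 80), high_gamma = c(80, 150)
  )
}

#' Welch power spectral density of an epoch
#'
#' Mean of Hann-windowed segment periodograms. The default for a
#' 400-sample epoch is a single full-length segment (a Hann periodogram):
#' one second of signal leaves no room for segment averaging at 2 Hz
#' band-edge resolution.
#'
#' @param x Numeric signal vector.
#' @param fs Sample rate in Hz.
#' @param seg_length Segment length in samples (default: full signal).
#' @param overlap Fractional segment overlap in \[0, 1) (default 0.5,
#'   irrelevant for a single segment).
#' @return List with \code{freq} (Hz) and \code{power} (density per bin),
#'   one-sided including DC.
#' @export
welch_psd <- function(x, fs = 400, seg_length = length(x), overlap = 0.5) {
  n <- length(x)
  seg_length <- min(seg_length, n)
  step <- max(1L, floor(seg_length * (1 - overlap)))
  starts <- seq(1L, n - seg_length + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_length) / (seg_length + 1))
  u <- sum(w^2)
  nfreq <- seg_length %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    # normalized so the spectrum sums to the mean-square signal power
    seg <- x[s:(s + seg_length - 1L)] * w
    p <- Mod(stats::fft(seg))^2 / (u * seg_length)
    acc <- acc + p[seq_len(nfreq)]
  }
  # double interior bins to fold the negative frequencies in
  pw <- acc / length(starts)
  if (seg_length %% 2 == 0) {
    pw[2:(nfreq - 1L)] <- 2 * pw[2:(nfreq - 1L)]
  } else {
    pw[2:nfreq] <- 2 * pw[2:nfreq]
  }
  list(freq = (seq_len(nfreq) - 1) * fs / seg_length, power = pw)
}

#' Absolute band powers of an epoch
#'
#' Integrates the Welch spectrum over the six canonical bands. The DC bin
#' (f = 0) is dropped before computing the total power.
#'
#' @param epoch Numeric epoch samples (400 for a standardized 1 s epoch).
#' @param fs Sample rate in Hz.
#' @param ... Passed to \code{\link{welch_psd}}.
#' @return A \code{band_power_set}: named list of the six band powers and
#'   \code{total_power}.
#' @export
welch_band_powers <- function(epoch, fs = 400, ...) {
  psd <- welch_psd(epoch, fs = fs, ...)
  keep <- psd$freq > 0
  f <- psd$freq[keep]
  p <- psd$power[keep]
  bp <- vapply(eeg_bands(), function(b) sum(p[f >= b[1] & f < b[2]]), numeric(1))
  out <- c(as.list(bp), list(total_power = sum(p)))
  class(out) <- "band_power_set"
  out
}

#' Relative and log absolute band powers
#'
#' Relative powers are the band powers normalized by total (DC-excluded)
#' signal power; log powers are log10 of the absolute band powers, the
#' convention in EEG band-power reporting.
#'
#' @param bp A \code{band_power_set} from \code{\link{welch_band_powers}}.
#' @param base Logarithm base for \code{log_abs_band_powers} (default 10).
#' @return Named numeric vector of six values.
#' @export
relative_band_powers <- function(bp) {
  if (bp$total_power <= 0) stop("degenerate epoch: zero total power")
  v <- unlist(bp[names(eeg_bands())]) / bp$total_power
  names(v) <- paste0("rel_", names(eeg_bands()))
  v
}

#' @rdname relative_band_powers
#' @export
log_abs_band_powers <- function(bp, base = 10) {
  v <- unlist(bp[names(eeg_bands())])
  if (any(v <= 0)) {
    # empty bands map to the log of the smallest positive double rather
    # than -Inf so downstream feature matrices stay finite
    v[v <= 0] <- .Machine$double.xmin
  }
  v <- log(v, base = base)
  names(v) <- paste0("log_", names(eeg_bands()))
  v
}

#' Energy ratio between fast and slow rhythms
#'
#' ER = (P_beta + P_lowgamma + P_highgamma) / (P_theta + P_alpha),
#' computed on relative band powers of a 1 s epoch. Large values flag the
#' shift towards fast activity that characterizes ictal onset.
#'
#' @param rel Named vector of the six relative band powers.
#' @return Nonnegative scalar.
#' @export
energy_ratio <- function(rel) {
  den <- rel[["rel_theta"]] + rel[["rel_alpha"]]
  if (den <= 0) stop("degenerate epoch: theta + alpha power is zero")
  (rel[["rel_beta"]] + rel[["rel_low_gamma"]] + rel[["rel_high_gamma"]]) / den
}

#' Epileptogenicity index of an epoch
#'
#' EI averages the energy ratio over the delay N_d - N_0 from a reference
#' point: EI = ER / (N_d - N_0 + 1). On standardized 1 s epochs every time
#' interval reduces to one (N_d = N_0), so EI equals ER; the generalized
#' delay is retained as optional arguments.
#'
#' @param er Energy ratio of the epoch.
#' @param n_d,n_0 Onset delay and reference sample points (defaults equal).
#' @return Nonnegative scalar.
#' @export
epileptogenicity_index <- function(er, n_d = 0, n_0 = 0) {
  if (n_d < n_0) stop("`n_d` must be >= `n_0`")
  er / (n_d - n_0 + 1)
}

#' Analytic signal via the FFT half-spectrum construction
#'
#' @param x Real numeric vector.
#' @return Complex vector whose modulus is the instantaneous envelope and
#'   whose argument the instantaneous phase.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Zero-phase FIR band-pass of a short signal
#'
#' Hamming-window FIR design (signal::fir1) applied forward-backward.
#' Used to build the low-frequency (4-30 Hz) and high-frequency-oscillation
#' (30-150 Hz) composites for PLHG.
#'
#' @param x Numeric signal.
#' @param band \code{c(lo, hi)} edges in Hz.
#' @param fs Sample rate in Hz.
#' @param order FIR order (default 64, adequate for 400-sample epochs).
#' @return Filtered signal, same length.
#' @export
bandpass_fir <- function(x, band, fs = 400, order = 64) {
  ny <- fs / 2
  if (any(band <= 0) || any(band >= ny)) stop("band edges must lie in (0, Nyquist)")
  h <- signal::fir1(order, band / ny, type = "pass")
  signal::filtfilt(h, x)
}

#' Envelope-weighted phase-locking phasor mean
#'
#' The core of the PLHG statistic:
#' \code{| mean(a * exp(i (phi_lf - phi_hfo))) |}. With a constant phase
#' difference this equals the mean envelope \code{mean(a)}; with
#' uniform-random phase differences and unit envelope its magnitude
#' concentrates around \code{1/sqrt(n)}. It never exceeds \code{max(a)}.
#'
#' @param a Nonnegative instantaneous envelope samples.
#' @param phi_lf,phi_hfo Instantaneous phases in radians.
#' @return Nonnegative scalar.
#' @export
plhg_phasor <- function(a, phi_lf, phi_hfo) {
  Mod(mean(a * exp(1i * (phi_lf - phi_hfo))))
}

#' Phase-locked high gamma of an epoch
#'
#' PLHG = | mean over samples of A_HFO * exp(i (Phi_LF - Phi_HFO)) |.
#' A_HFO is the instantaneous envelope (analytic-signal modulus) of the
#' high-frequency composite (low + high gamma, 30-150 Hz); Phi_LF is the
#' instantaneous phase of the low-frequency composite (theta + alpha +
#' beta, 4-30 Hz); Phi_HFO is the instantaneous phase of the
#' low-frequency component of the HFO envelope, i.e. of A_HFO band-passed
#' to 4-30 Hz — the construction of the phase-locked high-gamma
#' literature, under which the phase difference is constant exactly when
#' high-gamma bursts ride a fixed phase of the slow rhythm. Perfect
#' locking then yields PLHG near the mean envelope, while unrelated
#' phases concentrate the phasor mean near zero (about n^-1/2 for unit
#' envelope).
#'
#' @param epoch Numeric epoch samples.
#' @param fs Sample rate in Hz.
#' @param mode \code{"composite"} (default) uses the single 4-30 and
#'   30-150 Hz composites; \code{"pairs"} averages PLHG over the six
#'   (theta, alpha, beta) x (low gamma, high gamma) band pairs.
#' @return Nonnegative scalar, at most \code{max(A_HFO)}.
#' @export
plhg <- function(epoch, fs = 400, mode = c("composite", "pairs")) {
  mode <- match.arg(mode)
  if (all(epoch == 0)) return(0)
  pair_plhg <- function(lf_band, hf_band) {
    lf <- analytic_signal(bandpass_fir(epoch, lf_band, fs))
    env <- Mod(analytic_signal(bandpass_fir(epoch, hf_band, fs)))
    env_lf <- bandpass_fir(env - mean(env), lf_band, fs)
    plhg_phasor(env, Arg(lf), Arg(analytic_signal(env_lf)))
  }
  if (mode == "composite") {
    pair_plhg(c(4, 30), c(30, 150))
  } else {
    b <- eeg_bands()
    lfs <- b[c("theta", "alpha", "beta")]
    hfs <- b[c("low_gamma", "high_gamma")]
    mean(unlist(lapply(lfs, function(l) vapply(hfs, function(h) pair_plhg(l, h), numeric(1)))))
  }
}

#' Canonical names of the 16 engineered epoch features
#' @return Character vector of length 16 (schema contract).
#' @export
engineered_feature_names <- function() {
  c(paste0("rel_", names(eeg_bands())), paste0("log_", names(eeg_bands())),
    "ei", "plhg", "tdcg", "fdcg")
}

#' The 16-element engineered feature vector of an epoch
#'
#' Six relative band powers, six log10 absolute band powers, the
#' epileptogenicity index, phase-locked high gamma, and the time- and
#' frequency-domain Cho-Gaines distances, in that fixed order.
#'
#' @param epoch Numeric epoch samples (400 for a 1 s epoch at 400 Hz).
#' @param fs Sample rate in Hz.
#' @return Named numeric vector of length 16.
#' @export
engineered_features <- function(epoch, fs = 400) {
  bp <- welch_band_powers(epoch, fs = fs)
  rel <- relative_band_powers(bp)
  lg <- log_abs_band_powers(bp)
  er <- energy_ratio(rel)
  out <- c(rel, lg,
           ei = epileptogenicity_index(er),
           plhg = plhg(epoch, fs = fs),
           tdcg = tdcg(epoch, n = fs),
           fdcg = fdcg(epoch, n = fs))
  names(out) <- engineered_feature_names()
  out
}
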