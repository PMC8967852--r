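#' Leading significant digit of numeric values
#'
#' Extracts the first nonzero decimal digit of \code{abs(x)} element-wise:
#' \code{floor(|x| / 10^floor(log10 |x|))}. Exact zeros have no significant
#' digit and are mapped to 0, outside the Benford support \{1..9\}.
#'
#' @param x Numeric vector of finite values.
#' @return Integer vector of digits in 0..9 (0 only for exact zeros).
#' @export
#' @examples
#' leading_digit(c(345.6, 0.00042, 0, -7.2))
leading_digit <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  if (any(!is.finite(x))) stop("non-finite values have no leading digit")
  d <- integer(length(x))
  nz <- x != 0
  a <- abs(x[nz])
  m <- a / 10^floor(log10(a))
  # log10 rounding near exact powers of ten can put the mantissa one decade
  # off; fold it back into [1, 10)
  m[m >= 10] <- m[m >= 10] / 10
  m[m < 1] <- m[m < 1] * 10
  d[nz] <- as.integer(floor(m))
  d
}

#' First-digit probability distribution
#'
#' Counts digits 1..9 and normalizes to a probability distribution. Zeros
#' (the digit assigned to exact-zero samples) are excluded from the
#' normalization since they lie outside the Benford support.
#'
#' @param digits Integer vector of digits in 0..9.
#' @return A \code{digit_distribution}: named numeric vector of 9
#'   probabilities for digits 1..9.
#' @export
digit_distribution <- function(digits) {
  if (any(digits < 0 | digits > 9)) stop("digits must lie in 0..9")
  digits <- digits[digits != 0]
  if (length(digits) == 0) {
    stop("degenerate epoch: no nonzero values to form a digit distribution")
  }
  p <- tabulate(digits, nbins = 9) / length(digits)
  names(p) <- paste0("d", 1:9)
  class(p) <- c("digit_distribution", "numeric")
  p
}

#' Benford's expected first-digit distribution
#'
#' P(d) = log10((d + 1) / d) for d in 1..9. The nine terms telescope to
#' log10(10) so the distribution sums to 1 exactly.
#'
#' @return A \code{digit_distribution} of the nine Benford probabilities.
#' @export
#' @examples
#' benford_expected()  # P(1) ~ 0.30103
benford_expected <- function() {
  d <- 1:9
  p <- log10((d + 1) / d)
  names(p) <- paste0("d", d)
  class(p) <- c("digit_distribution", "numeric")
  p
}

#' Cho-Gaines distance between two first-digit distributions
#'
#' The sample-size-scaled Euclidean distance
#' \code{D = sqrt(N * sum((e_i - o_i)^2))} between an observed and an
#' expected digit distribution. \code{N} is the EEG sample rate (400 for the
#' standardized 1 s epochs), so the distance grows as \code{sqrt(N)}.
#'
#' @param observed,expected Digit distributions over 1..9 (see
#'   \code{\link{digit_distribution}}).
#' @param n Scale count N (sample rate); must be > 0.
#' @return List with \code{distance} (nonnegative scalar) and \code{n}.
#' @export
cho_gaines <- function(observed, expected = benford_expected(), n = 400) {
  if (length(observed) != 9L || length(expected) != 9L) {
    stop("digit distributions must have support {1..9}")
  }
  if (n <= 0) stop("`n` must be positive")
  D <- sqrt(n * sum((as.numeric(expected) - as.numeric(observed))^2))
  structure(list(distance = D, n = n), class = "cho_gaines_result")
}

#' @export
print.cho_gaines_result <- function(x, ...) {
  cat(sprintf("Cho-Gaines distance: %.6g (N = %d)\n", x$distance, as.integer(x$n)))
  invisible(x)
}

#' Time- and frequency-domain Cho-Gaines epoch features
#'
#' \code{tdcg()} measures Benford conformity of the raw time-domain samples
#' of an epoch; \code{fdcg()} of the one-sided FFT magnitude spectrum with
#' the DC bin dropped (squared magnitude available via \code{power = TRUE}).
#' Both are scaled by the epoch sample rate N.
#'
#' @param epoch Numeric vector of epoch samples (one second of signal).
#' @param n Scale count for the Cho-Gaines distance; defaults to the epoch
#'   length, i.e. the sample rate for a 1 s epoch.
#' @param power If \code{TRUE}, \code{fdcg()} pools digits of the squared
#'   magnitude spectrum instead of the magnitude.
#' @return Nonnegative scalar distance.
#' @export
tdcg <- function(epoch, n = length(epoch)) {
  obs <- digit_distribution(leading_digit(epoch))
  cho_gaines(obs, benford_expected(), n)$distance
}

#' @rdname tdcg
#' @export
fdcg <- function(epoch, n = length(epoch), power = FALSE) {
  mag <- spectrum_magnitude(epoch)
  if (power) mag <- mag^2
  obs <- digit_distribution(leading_digit(mag))
  cho_gaines(obs, benford_expected(), n)$distance
}

#' One-sided FFT magnitude spectrum of an epoch, DC dropped
#'
#' For a 400-sample epoch this returns 200 values (bins 1..200, i.e.
#' 1..200 Hz at 400 Hz sampling), the representation consumed by the
#' frequency-domain encoder and by \code{\link{fdcg}}.
#'
#' @param epoch Numeric vector of epoch samples.
#' @return Numeric vector of length \code{floor(length(epoch) / 2)}.
#' @export
spectrum_magnitude <- function(epoch) {
  n <- length(epoch)
  Mod(stats::fft(epoch))[2:(n %/% 2 + 1)]
}
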