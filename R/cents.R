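#' Convert frequency to cents relative to a reference
#'
#' Pitch is expressed on the logarithmic cents scale, `1200 * log2(f / ref)`,
#' where one octave equals 1200 cents and one equal-tempered semitone equals
#' 100 cents. Sung-melody analyses in this package use a 252 Hz reference (the
#' singing target, ~B3), which places the target at 0 cents and makes traces
#' comparable across voices of different register.
#'
#' @param f0_hz Numeric vector of frequencies in Hz; must be positive.
#' @param ref_hz Reference frequency in Hz (default 252).
#' @return Numeric vector of the same length, in cents.
#' @seealso [cents_to_hz()]
#' @examples
#' hz_to_cents(504)        # one octave above 252 Hz -> 1200
#' hz_to_cents(250, 250)   # 0
#' @export
hz_to_cents <- function(f0_hz, ref_hz = 252) {
  stopifnot(is.numeric(f0_hz), is.numeric(ref_hz), length(ref_hz) == 1L)
  if (any(!is.na(f0_hz) & f0_hz <= 0) || ref_hz <= 0)
    stop("frequencies must be positive")
  1200 * log2(f0_hz / ref_hz)
}

#' Convert cents back to frequency
#'
#' Inverse of [hz_to_cents()]: `ref * 2^(cents / 1200)`.
#'
#' @param cents Numeric vector of pitches in cents.
#' @param ref_hz Reference frequency in Hz (default 252).
#' @return Numeric vector of frequencies in Hz.
#' @export
cents_to_hz <- function(cents, ref_hz = 252) {
  stopifnot(is.numeric(cents), is.numeric(ref_hz), length(ref_hz) == 1L,
            ref_hz > 0)
  ref_hz * 2^(cents / 1200)
}
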