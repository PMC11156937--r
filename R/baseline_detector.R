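# Classical freeze-index baseline: ratio of accelerometer band power in the
# 3-8 Hz "freeze" band to the 0.5-3 Hz locomotor band over a sliding window.
# Training-free, so it gives an end-to-end score series for exercising the
# scoring and agreement stages.

#' Freeze-index configuration
#'
#' @param window_s analysis window length in seconds (default 4; must cover
#'   at least two periods of the locomotor band's lower edge).
#' @param freeze_band,locomotor_band Hz intervals; must be disjoint and
#'   positive.
#' @param axis `"vertical"` (vertical acceleration) or `"norm"` (Euclidean
#'   norm of the three axes).
#' @param fi_max cap applied when locomotor power is numerically zero.
#' @param hop_s spectral estimation stride; `NULL` (default) evaluates the
#'   windowed spectrum at every sample, a positive value evaluates on a
#'   stride grid and linearly interpolates between grid points.
#' @return list of class `freeze_index_config`.
#' @export
freeze_index_config <- function(window_s = 4, freeze_band = c(3, 8),
                                locomotor_band = c(0.5, 3),
                                axis = c("vertical", "norm"),
                                fi_max = 100, hop_s = NULL) {
  axis <- match.arg(axis)
  if (any(freeze_band <= 0) || any(locomotor_band <= 0) ||
      diff(freeze_band) <= 0 || diff(locomotor_band) <= 0)
    stop_validation("bands must be positive, increasing intervals")
  if (!(locomotor_band[2] <= freeze_band[1] || freeze_band[2] <= locomotor_band[1]))
    stop_validation("freeze and locomotor bands must be disjoint")
  if (window_s < 2 / locomotor_band[1])
    stop_validation("window must cover two periods of the locomotor lower edge")
  structure(list(window_s = window_s, freeze_band = freeze_band,
                 locomotor_band = locomotor_band, axis = axis,
                 fi_max = fi_max, hop_s = hop_s),
            class = "freeze_index_config")
}

# one-sided band power of a detrended, Hann-windowed segment by FFT bin
# summation; bins exactly on a band edge count half
band_power_weights <- function(freqs, band) {
  w <- as.numeric(freqs > band[1] + 1e-9 & freqs < band[2] - 1e-9)
  w[abs(freqs - band[1]) <= 1e-9] <- 0.5
  w[abs(freqs - band[2]) <= 1e-9] <- 0.5
  w
}

#' Per-sample freeze index
#'
#' For each sample, the signal in a centered window (reflection-padded at
#' the edges) is mean-detrended, Hann-windowed, and its magnitude-squared
#' FFT summed over the freeze and locomotor bands (boundary bins
#' half-weighted); the freeze index is the power ratio. As a ratio it is
#' invariant to amplitude scaling. Windows whose locomotor power is
#' numerically zero get the configured cap, flagged in the `capped`
#' attribute.
#'
#' @param recording a [fog_recording] (length at least one window).
#' @param config a [freeze_index_config].
#' @return numeric vector of length `recording$n` with attribute `capped`.
#' @export
freeze_index <- function(recording, config = freeze_index_config()) {
  fs <- recording$sampling_rate
  x <- switch(config$axis,
              vertical = recording$acc[, 1],
              norm = sqrt(rowSums(recording$acc^2)))
  n <- length(x)
  w <- max(4L, round(config$window_s * fs))
  if (n < w) stop_validation("recording shorter than the analysis window")
  half_lo <- w %/% 2L
  half_hi <- w - half_lo - 1L
  xp <- c(rev(x[seq_len(half_lo) + 1L]), x, rev(x[n - seq_len(half_hi)]))
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(w) / (w + 1))
  freqs <- (0:(w %/% 2L)) * fs / w
  wf <- band_power_weights(freqs, config$freeze_band)
  wl <- band_power_weights(freqs, config$locomotor_band)
  centers <- if (is.null(config$hop_s)) seq_len(n)
             else unique(c(seq(1L, n, by = max(1L, round(config$hop_s * fs))), n))
  fi <- numeric(length(centers))
  capped <- logical(length(centers))
  nb <- w %/% 2L + 1L
  for (j in seq_along(centers)) {
    i <- centers[j]
    seg <- xp[i:(i + w - 1L)]
    seg <- (seg - mean(seg)) * hann
    pw <- Mod(fft(seg)[seq_len(nb)])^2
    pf <- sum(pw * wf); pl <- sum(pw * wl)
    if (pl <= 1e-12) { fi[j] <- config$fi_max; capped[j] <- TRUE }
    else fi[j] <- min(pf / pl, config$fi_max)
  }
  out <- if (is.null(config$hop_s)) fi
         else approx(centers, fi, xout = seq_len(n), rule = 2)$y
  attr(out, "capped") <- if (is.null(config$hop_s)) capped else any(capped)
  out
}

#' Class-agnostic baseline score series from the freeze index
#'
#' The freeze-index series min-max scaled to `[0, 1]` and replicated across
#' the three class channels: the baseline has no context model, so class
#' attribution is left to downstream thresholding/argmax. A constant index
#' maps to constant 0.5.
#'
#' @inheritParams freeze_index
#' @return N x 3 score matrix (see [fog_scores]).
#' @export
baseline_scores <- function(recording, config = freeze_index_config()) {
  fi <- as.numeric(freeze_index(recording, config))
  rng <- range(fi)
  s <- if (diff(rng) <= 0) rep(0.5, length(fi)) else (fi - rng[1]) / diff(rng)
  fog_scores(matrix(s, ncol = 3, nrow = length(s)))
}
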