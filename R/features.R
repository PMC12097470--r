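#' Welch power spectral density
#'
#' Hann-windowed Welch estimator with 50% overlapping windows and a
#' zero-padded FFT. The default configuration (10-s windows inside a 30-s
#' epoch at 128 Hz, padded to 5120 points) yields a frequency grid with
#' exactly 0.025 Hz spacing. A series shorter than one window is estimated
#' from a single window of its own length (used for the 2.5-s spike-wave
#' segment).
#'
#' @param x Numeric series.
#' @param fs Sampling rate (Hz).
#' @param window_sec Inner window length (s).
#' @param overlap Fractional window overlap in `[0, 1)`.
#' @param nfft FFT length after zero padding; grid spacing is `fs / nfft`.
#' @return List with `freqs` (Hz, from 0 to Nyquist) and `power`
#'   (one-sided density, x-units^2/Hz).
#' @export
welch_psd <- function(x, fs = 128, window_sec = 10, overlap = 0.5,
                      nfft = 5120) {
  n <- length(x)
  if (n < 2) stop("series too short for spectral estimation")
  nw <- min(round(window_sec * fs), n)
  if (nfft < nw) stop("nfft must be >= the window length")
  step <- max(1, round(nw * (1 - overlap)))
  starts <- seq(1, n - nw + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nw - 1) / (nw - 1))  # Hann
  u <- sum(w^2)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nw - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(fft(c(seg, numeric(nfft - nw))))^2
    acc <- acc + sp[seq_len(nfft %/% 2 + 1)]
  }
  pw <- acc / (length(starts) * fs * u)
  pw[2:(length(pw) - 1)] <- 2 * pw[2:(length(pw) - 1)]  # one-sided
  list(freqs = (0:(nfft %/% 2)) * fs / nfft, power = pw)
}

#' Normalized power spectrum on the standard 0.6-10 Hz grid
#'
#' Welch spectra are computed per epoch, averaged across epochs, restricted
#' to the fixed grid over [0.6, 10] Hz with 0.025 Hz spacing, and divided by
#' the trapezoidal area under the curve, so that the relative prominence of
#' each frequency component is comparable across subjects. The returned
#' curve has unit area by construction.
#'
#' @param epochs An [make_epochs()] `epoch_set`, or a numeric matrix
#'   (samples x epochs), or a single numeric series.
#' @param fs Sampling rate (Hz); taken from the `epoch_set` when given.
#' @param fmin,fmax Grid limits (Hz).
#' @param df Grid spacing (Hz); with `fs = 128` forces `nfft = fs/df = 5120`.
#' @return Object of class `spectral_feature`: list with `freqs`, `power`.
#' @export
welch_normalized_psd <- function(epochs, fs = 128, fmin = 0.6, fmax = 10,
                                 df = 0.025) {
  if (inherits(epochs, "epoch_set")) {
    fs <- epochs$fs
    epochs <- epochs$epochs
  }
  if (is.vector(epochs)) epochs <- matrix(epochs, ncol = 1)
  if (ncol(epochs) == 0 || nrow(epochs) == 0) stop("empty epoch set")
  nfft <- round(fs / df)
  if (abs(fs / df - nfft) > 1e-9) stop("fs/df must be an integer FFT length")
  acc <- NULL
  for (j in seq_len(ncol(epochs))) {
    sp <- welch_psd(epochs[, j], fs = fs, nfft = nfft)
    acc <- if (is.null(acc)) sp$power else acc + sp$power
  }
  pw <- acc / ncol(epochs)
  freqs <- (0:(nfft %/% 2)) * df
  keep <- freqs >= fmin - 1e-9 & freqs <= fmax + 1e-9
  f <- freqs[keep]
  p <- pw[keep]
  area <- .trapz(f, p)
  if (area <= 0) stop("degenerate spectrum: zero power in band")
  structure(list(freqs = f, power = p / area), class = "spectral_feature")
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' @export
print.spectral_feature <- function(x, ...) {
  cat(sprintf("<spectral_feature> %d points, %.3g-%.3g Hz, peak at %.3g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              x$freqs[which.max(x$power)]))
  invisible(x)
}

#' Weighted horizontal visibility graph degrees
#'
#' Maps a series to a graph: samples are nodes; nodes `i < j` are linked
#' iff every intermediate sample is strictly lower than both (`x_k <
#' min(x_i, x_j)`; ties block visibility). Each edge carries weight
#' `|atan(slope)|` where the slope is the amplitude difference over the time
#' lag `(j - i)/fs`, computed on the unit-variance-normalized series so the
#' statistic is scale-free. Construction is the O(n) stack algorithm.
#'
#' @param x Numeric series, length >= 2.
#' @param fs Sampling rate (Hz) used in the slope.
#' @param normalize Divide by the series SD before weighting (default TRUE;
#'   skipped automatically for a constant series).
#' @return Object of class `hvg_feature`: `degree` (unweighted integer
#'   degrees), `wdegree` (weighted degrees), `mean_degree`,
#'   `mean_wdegree`.
#' @export
hvg_weighted_degrees <- function(x, fs = 128, normalize = TRUE) {
  if (length(x) < 2) stop("series must have length >= 2")
  s <- sd(x)
  if (normalize && s > 0) x <- x / s
  r <- .hvg_degrees_cpp(as.numeric(x), fs)
  structure(list(degree = r$degree, wdegree = r$wdegree,
                 mean_degree = mean(r$degree),
                 mean_wdegree = mean(r$wdegree)),
            class = "hvg_feature")
}

#' Feature set of a signal: normalized spectrum + HVG degree summary
#'
#' The space in which model output and data are compared. The HVG summary
#' is computed per epoch on the z-scored series and averaged.
#'
#' @param epochs `epoch_set`, matrix (samples x epochs), or numeric series.
#' @param fs Sampling rate (Hz).
#' @param hvg_stat `"mean"` (default) compares mean weighted degree;
#'   `"hist"` retains the weighted-degree histogram as well.
#' @return Object of class `feature_set`: `spectrum` (a
#'   `spectral_feature`), `mean_wdegree`, `fs`, `n_epochs`.
#' @export
feature_set <- function(epochs, fs = 128, hvg_stat = c("mean", "hist")) {
  hvg_stat <- match.arg(hvg_stat)
  if (inherits(epochs, "epoch_set")) {
    fs <- epochs$fs
    epochs <- epochs$epochs
  }
  if (is.vector(epochs)) epochs <- matrix(epochs, ncol = 1)
  spec <- welch_normalized_psd(epochs, fs = fs)
  wd <- numeric(ncol(epochs))
  hists <- NULL
  for (j in seq_len(ncol(epochs))) {
    z <- epochs[, j]
    z <- (z - mean(z)) / ifelse(sd(z) > 0, sd(z), 1)
    h <- hvg_weighted_degrees(z, fs = fs, normalize = FALSE)
    wd[j] <- h$mean_wdegree
    if (hvg_stat == "hist") hists <- c(hists, list(h$wdegree))
  }
  structure(list(spectrum = spec, mean_wdegree = mean(wd), fs = fs,
                 n_epochs = ncol(epochs),
                 wdegree_pool = if (hvg_stat == "hist") unlist(hists)),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d epoch(s) at %g Hz, mean weighted degree %.3f\n",
              x$n_epochs, x$fs, x$mean_wdegree))
  invisible(x)
}

#' Spectral distance between two normalized spectra
#'
#' Euclidean norm of the pointwise difference on the common grid (the
#' spectral objective and the perturbation sensitivity measure); `"l1"`
#' gives the sum of absolute differences instead.
#'
#' @param a,b `spectral_feature` objects on identical grids.
#' @param norm `"l2"` (default) or `"l1"`.
#' @return Non-negative scalar.
#' @export
spectral_distance <- function(a, b, norm = c("l2", "l1")) {
  norm <- match.arg(norm)
  if (length(a$freqs) != length(b$freqs) ||
      max(abs(a$freqs - b$freqs)) > 1e-9) {
    stop("spectral grids do not match")
  }
  d <- a$power - b$power
  if (norm == "l2") sqrt(sum(d^2)) else sum(abs(d))
}

#' Objective pair between a simulated series and a data feature target
#'
#' The simulated EEG is z-scored (removing the unidentifiable gain/offset
#' between model membrane potential and scalp voltage), its features are
#' computed, and the two objectives are returned: `f_spec` = Euclidean
#' distance between normalized spectra; `f_hvg` = absolute difference of
#' mean weighted HVG degrees.
#'
#' @param sim Numeric simulated series (or an `nmm_sim`, whose `eeg` is
#'   used).
#' @param target_feats A [feature_set()] built from the data.
#' @param fs Sampling rate of `sim` (must equal the target's).
#' @return Named numeric vector `c(f_spec = , f_hvg = )`.
#' @export
objective_pair <- function(sim, target_feats, fs = 128) {
  if (inherits(sim, "nmm_sim")) {
    fs <- sim$fs
    sim <- sim$eeg
  }
  stopifnot(inherits(target_feats, "feature_set"))
  if (abs(fs - target_feats$fs) > 1e-9) stop("sampling rates do not match")
  s <- sd(sim)
  z <- if (s > 0) (sim - mean(sim)) / s else sim - mean(sim)
  sf <- feature_set(z, fs = fs)
  c(f_spec = spectral_distance(sf$spectrum, target_feats$spectrum),
    f_hvg = abs(sf$mean_wdegree - target_feats$mean_wdegree))
}
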