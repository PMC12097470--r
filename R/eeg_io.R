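#' Construct an EEG segment
#'
#' A single- or multi-channel voltage time series with sampling metadata,
#' the ingestion container for all downstream preprocessing. Channels with
#' any non-finite sample are rejected at construction.
#'
#' @param samples Numeric matrix, one column per channel (microvolts), or a
#'   vector for a single channel.
#' @param fs Sampling rate (Hz), > 0.
#' @param channel_labels Character vector, one label per column.
#' @param subject_id Subject identifier string.
#' @param group_label One of `"control"`, `"patient_no_seizure"`,
#'   `"patient_seizure"`, `"swd"`, or `NA`.
#' @param t0 Segment start offset in seconds.
#' @return Object of class `eeg_segment`.
#' @export
eeg_segment <- function(samples, fs, channel_labels = NULL,
                        subject_id = NA_character_, group_label = NA_character_,
                        t0 = 0) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  stopifnot(is.matrix(samples), fs > 0)
  if (is.null(channel_labels)) {
    channel_labels <- colnames(samples)
    if (is.null(channel_labels)) {
      channel_labels <- paste0("ch", seq_len(ncol(samples)))
    }
  }
  stopifnot(length(channel_labels) == ncol(samples))
  if (!all(is.finite(samples))) {
    stop("non-finite samples in channel(s): ",
         paste(channel_labels[!apply(is.finite(samples), 2, all)],
               collapse = ", "))
  }
  colnames(samples) <- channel_labels
  ok_groups <- c("control", "patient_no_seizure", "patient_seizure", "swd")
  if (!is.na(group_label) && !group_label %in% ok_groups) {
    stop("group_label must be one of: ", paste(ok_groups, collapse = ", "))
  }
  structure(list(samples = samples, fs = fs, channel_labels = channel_labels,
                 subject_id = subject_id, group_label = group_label, t0 = t0),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %s: %d ch x %.4g s at %g Hz [%s]\n",
              x$subject_id, ncol(x$samples), nrow(x$samples) / x$fs, x$fs,
              paste(x$channel_labels, collapse = ",")))
  invisible(x)
}

# ---- EDF (European Data Format, 16-bit) ----

.edf_pad <- function(x, n) {
  x <- substr(as.character(x), 1, n)
  sprintf(paste0("%-", n, "s"), x)
}

#' Write an EEG segment as a 16-bit EDF file
#'
#' Minimal continuous EDF writer: one data record per second, all channels
#' at the segment's rate, physical dimension uV. The trailing partial second
#' is dropped. Values are quantized to the 16-bit digital range spanning the
#' observed physical range.
#'
#' @param seg An [eeg_segment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(seg, path) {
  stopifnot(inherits(seg, "eeg_segment"))
  fs <- seg$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- ncol(seg$samples)
  n_rec <- floor(nrow(seg$samples) / fs)
  if (n_rec < 1) stop("segment shorter than one EDF record (1 s)")
  x <- seg$samples[seq_len(n_rec * fs), , drop = FALSE]
  pmin_ <- apply(x, 2, min)
  pmax_ <- apply(x, 2, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad(paste("X X X", seg$subject_id), 80),
    .edf_pad("Startdate X X X X", 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (1 + ns), 8), .edf_pad("", 44),
    .edf_pad(n_rec, 8), .edf_pad("1", 8), .edf_pad(ns, 4)
  )
  field <- function(vals, w) paste(vapply(vals, .edf_pad, "", n = w), collapse = "")
  hdr <- paste0(hdr,
    field(seg$channel_labels, 16),
    field(rep("", ns), 80),
    field(rep("uV", ns), 8),
    field(sprintf("%.6g", pmin_), 8),
    field(sprintf("%.6g", pmax_), 8),
    field(rep(dmin, ns), 8),
    field(rep(dmax, ns), 8),
    field(rep("", ns), 80),
    field(rep(fs, ns), 8),
    field(rep("", ns), 32))
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round((x[idx, ch] - pmin_[ch]) / scale[ch]) + dmin)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read channels from an EDF file
#'
#' Reads a continuous 16-bit EDF recording, converts digital values to
#' physical units, and returns the requested channels. Physical dimensions
#' `uV` and `mV` are converted to microvolts.
#'
#' @param path EDF file path.
#' @param channels Character vector of channel labels to read; `NULL` for
#'   all channels.
#' @return An [eeg_segment()] at the file's native sampling rate.
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("cannot read EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    raw <- readChar(con, n, useBytes = TRUE)
    trimws(raw)
  }
  rd(8)                      # version
  patient <- rd(80); rd(80); rd(8); rd(8)
  rd(8)                      # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("unreadable EDF header in ", path)
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  dims <- trimws(vapply(seq_len(ns), function(i) rd(8), ""))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")

  if (is.null(channels)) channels <- labels
  missing_ch <- setdiff(channels, labels)
  if (length(missing_ch)) {
    stop("channel(s) not present in EDF file: ",
         paste(missing_ch, collapse = ", "),
         " (available: ", paste(labels, collapse = ", "), ")")
  }
  if (length(unique(spr)) != 1) stop("mixed per-channel rates not supported")
  fs <- spr[1] / rec_dur

  out <- matrix(NA_real_, nrow = n_rec * spr[1], ncol = ns)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2,
                     endian = "little", signed = TRUE)
      phys <- pmin_[ch] + (dig - dmin[ch]) * (pmax_[ch] - pmin_[ch]) /
        (dmax[ch] - dmin[ch])
      out[((r - 1) * spr[ch] + 1):(r * spr[ch]), ch] <- phys
    }
  }
  mv <- dims %in% c("mV", "mv")
  out[, mv] <- out[, mv] * 1000
  sel <- match(channels, labels)
  subject <- sub("^X X X ?", "", patient)
  eeg_segment(out[, sel, drop = FALSE], fs = fs, channel_labels = channels,
              subject_id = if (nzchar(subject)) subject else NA_character_)
}

# ---- channel operations and filtering ----

#' Average a set of channels into one
#'
#' Samplewise arithmetic mean of the named channels, the standard frontal
#' (F3, F4) averaging step before spectral analysis.
#'
#' @param seg An [eeg_segment()].
#' @param labels Channels to average; must be present in `seg`.
#' @return Single-channel `eeg_segment` labelled `mean(<labels>)`.
#' @export
average_channels <- function(seg, labels = c("F3", "F4")) {
  stopifnot(inherits(seg, "eeg_segment"))
  if (length(labels) == 0) stop("labels must name at least one channel")
  missing_ch <- setdiff(labels, seg$channel_labels)
  if (length(missing_ch)) {
    stop("channel(s) not in segment: ", paste(missing_ch, collapse = ", "))
  }
  m <- rowMeans(seg$samples[, labels, drop = FALSE])
  eeg_segment(m, fs = seg$fs,
              channel_labels = paste0("mean(", paste(labels, collapse = ","), ")"),
              subject_id = seg$subject_id, group_label = seg$group_label,
              t0 = seg$t0)
}

# forward-backward (zero-phase) filtering with odd-extension padding, so
# edge transients decay inside the pad rather than the data; the padded
# extension is a linear map of x, keeping filtering exactly linear
.zero_phase <- function(filt, x) {
  n <- length(x)
  npad <- min(n - 1, 1280)
  xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  y <- signal::filter(filt, xp)
  y <- rev(as.numeric(signal::filter(filt, rev(as.numeric(y)))))
  y[(npad + 1):(npad + n)]
}

.butter_apply <- function(seg, filt) {
  y <- apply(seg$samples, 2, function(ch) .zero_phase(filt, ch))
  if (is.vector(y)) y <- matrix(y, ncol = 1)
  eeg_segment(y, fs = seg$fs, channel_labels = seg$channel_labels,
              subject_id = seg$subject_id, group_label = seg$group_label,
              t0 = seg$t0)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero-phase) application of an `order`-th order
#' Butterworth band-pass; the default 0.3-10 Hz band is the slow-wave-sleep
#' preprocessing band. Length is preserved.
#'
#' @param seg An [eeg_segment()].
#' @param low,high Band edges (Hz), `0 < low < high < fs/2`.
#' @param order Filter order (default 4).
#' @return Filtered `eeg_segment`.
#' @export
bandpass <- function(seg, low = 0.3, high = 10, order = 4) {
  stopifnot(inherits(seg, "eeg_segment"))
  if (!(low > 0 && low < high && high < seg$fs / 2)) {
    stop("band must satisfy 0 < low < high < fs/2")
  }
  filt <- signal::butter(order, c(low, high) / (seg$fs / 2), type = "pass")
  .butter_apply(seg, filt)
}

#' Zero-phase Butterworth high-pass filter
#'
#' Used to remove low-frequency artifacts from the spike-wave-discharge
#' segment before feature computation.
#'
#' @param seg An [eeg_segment()].
#' @param cutoff Cutoff frequency (Hz), `0 < cutoff < fs/2`.
#' @param order Filter order (default 4).
#' @return Filtered `eeg_segment`.
#' @export
highpass <- function(seg, cutoff = 1, order = 4) {
  stopifnot(inherits(seg, "eeg_segment"))
  if (!(cutoff > 0 && cutoff < seg$fs / 2)) {
    stop("cutoff must satisfy 0 < cutoff < fs/2")
  }
  filt <- signal::butter(order, cutoff / (seg$fs / 2), type = "high")
  .butter_apply(seg, filt)
}

#' Resample a segment to a target rate
#'
#' Polyphase resampling via `signal::resample`; identity when the rates
#' already match. All recordings are put on the common 128 Hz grid at
#' ingestion.
#'
#' @param seg An [eeg_segment()].
#' @param fs_target Target rate (Hz).
#' @return Resampled `eeg_segment`.
#' @export
resample_segment <- function(seg, fs_target = 128) {
  stopifnot(inherits(seg, "eeg_segment"))
  if (abs(seg$fs - fs_target) < 1e-9) return(seg)
  frac <- .simplify_ratio(fs_target, seg$fs)
  y <- apply(seg$samples, 2, function(ch) {
    if (frac[1] == 1) {
      signal::decimate(ch, frac[2], ftype = "fir")
    } else {
      signal::resample(ch, p = frac[1], q = frac[2])
    }
  })
  if (is.vector(y)) y <- matrix(y, ncol = 1)
  eeg_segment(y, fs = fs_target, channel_labels = seg$channel_labels,
              subject_id = seg$subject_id, group_label = seg$group_label,
              t0 = seg$t0)
}

.simplify_ratio <- function(p, q) {
  # integer ratio p/q for rational rates (e.g. 128/512)
  k <- 1
  while (abs(p * k - round(p * k)) > 1e-9 || abs(q * k - round(q * k)) > 1e-9) {
    k <- k + 1
    if (k > 1000) stop("cannot express rate ratio as a small rational")
  }
  a <- round(p * k); b <- round(q * k)
  g <- .gcd(a, b)
  c(a / g, b / g)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Split a single-channel segment into non-overlapping epochs
#'
#' Consecutive, non-overlapping epochs of `epoch_length` seconds; a trailing
#' partial epoch is discarded. (Window overlap belongs to the Welch
#' estimator inside an epoch, not to epoching.)
#'
#' @param seg Single-channel [eeg_segment()].
#' @param epoch_length Epoch length (s), default 30.
#' @return Object of class `epoch_set`: list with `epochs` (a
#'   samples-by-epochs matrix), `fs`, `epoch_length`.
#' @export
make_epochs <- function(seg, epoch_length = 30) {
  stopifnot(inherits(seg, "eeg_segment"))
  if (ncol(seg$samples) != 1) {
    stop("make_epochs expects a single-channel segment; average channels first")
  }
  n_per <- round(epoch_length * seg$fs)
  n <- nrow(seg$samples)
  n_ep <- floor(n / n_per)
  if (n_ep < 1) {
    stop(sprintf("segment (%.4g s) shorter than one epoch (%g s)",
                 n / seg$fs, epoch_length))
  }
  ep <- matrix(seg$samples[seq_len(n_ep * n_per), 1], nrow = n_per)
  structure(list(epochs = ep, fs = seg$fs, epoch_length = epoch_length),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs of %g s at %g Hz\n",
              ncol(x$epochs), x$epoch_length, x$fs))
  invisible(x)
}
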