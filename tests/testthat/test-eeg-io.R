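test_that("EDF round-trip preserves samples up to 16-bit quantization", {
  set.seed(1)
  n <- 3 * 128
  x <- cbind(F3 = 50 * sin(2 * pi * 2 * (1:n) / 128) + rnorm(n, 0, 5),
             F4 = 30 * cos(2 * pi * 1 * (1:n) / 128) + rnorm(n, 0, 5))
  seg <- eeg_segment(x, fs = 128, subject_id = "rt01")
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(seg, path)
  back <- read_edf(path)
  expect_equal(back$channel_labels, c("F3", "F4"))
  expect_equal(nrow(back$samples), n)
  # quantization step = physical range / 65535
  for (ch in 1:2) {
    step <- diff(range(x[, ch])) / 65535
    expect_lt(max(abs(back$samples[, ch] - x[, ch])), step)
  }
})

test_that("read_edf selects requested channels and errors on missing ones", {
  seg <- eeg_segment(cbind(F3 = sin(1:256), F4 = cos(1:256)), fs = 128)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(seg, path)
  one <- read_edf(path, channels = "F3")
  expect_equal(ncol(one$samples), 1)
  expect_equal(one$channel_labels, "F3")
  expect_error(read_edf(path, channels = "Cz"), "Cz")
})

test_that("segment construction rejects non-finite samples", {
  expect_error(eeg_segment(c(1, NA, 3), fs = 128), "non-finite")
  expect_error(eeg_segment(c(1, Inf, 3), fs = 128), "non-finite")
})

test_that("average_channels takes the samplewise mean", {
  x <- cbind(F3 = c(1, 2, 3, 4), F4 = c(1, 2, 3, 4))
  seg <- eeg_segment(x, fs = 4)
  expect_equal(average_channels(seg)$samples[, 1], c(1, 2, 3, 4))
  seg2 <- eeg_segment(cbind(F3 = c(1, -2, 3), F4 = c(-1, 2, -3)), fs = 4)
  expect_equal(average_channels(seg2)$samples[, 1], c(0, 0, 0))
  seg3 <- eeg_segment(cbind(F3 = c(5, 6), F4 = c(9, 9)), fs = 4)
  expect_equal(average_channels(seg3, "F3")$samples[, 1], c(5, 6))
  expect_error(average_channels(seg3, character(0)), "at least one")
  expect_error(average_channels(seg3, "Oz"), "Oz")
})

test_that("band-pass keeps in-band tones, removes DC and attenuates 30 Hz", {
  t <- seq(0, 30 - 1 / 128, by = 1 / 128)
  tone5 <- sin(2 * pi * 5 * t)
  seg <- eeg_segment(tone5, fs = 128)
  out <- bandpass(seg)$samples[, 1]
  mid <- 500:3300  # avoid edge transients
  expect_equal(sd(out[mid]) / sd(tone5[mid]), 1, tolerance = 0.01)
  expect_equal(length(out), length(tone5))

  # 30 Hz tone: >= 20 dB attenuation, checked against the filter's own
  # frequency response evaluated independently
  tone30 <- sin(2 * pi * 30 * t)
  out30 <- bandpass(eeg_segment(tone30, fs = 128))$samples[, 1]
  att_db <- 20 * log10(sd(out30[mid]) / sd(tone30[mid]))
  expect_lt(att_db, -20)
  # independent oracle: evaluate the squared filter response at 30 Hz from
  # the transfer-function coefficients directly
  bt <- signal::butter(4, c(0.3, 10) / 64, type = "pass")
  z <- exp(-1i * 2 * pi * 30 / 128)
  hmag <- Mod(sum(bt$b * z^(seq_along(bt$b) - 1)) /
                sum(bt$a * z^(seq_along(bt$a) - 1)))
  expect_lt(40 * log10(hmag), -20)  # squared (forward-backward) response

  dc <- rep(100, length(t))
  expect_lt(abs(mean(bandpass(eeg_segment(dc, fs = 128))$samples[, 1])), 0.01)
  expect_error(bandpass(seg, low = 10, high = 5), "band")
  expect_error(bandpass(seg, low = 0.3, high = 70), "band")
})

test_that("high-pass removes offsets, keeps in-band tones, validates cutoff", {
  t <- seq(0, 10 - 1 / 128, by = 1 / 128)
  seg <- eeg_segment(sin(2 * pi * 6 * t) + 50, fs = 128)
  out <- highpass(seg, cutoff = 0.5)$samples[, 1]
  # offset removed: interior free of edge transients is zero-mean, and the
  # whole segment retains under 2% of the 50 uV offset
  expect_lt(abs(mean(out[400:900])), 0.01)
  expect_lt(abs(mean(out)), 1)
  tone <- sin(2 * pi * 6 * t)
  out_t <- highpass(eeg_segment(tone, fs = 128), cutoff = 0.5)$samples[, 1]
  mid <- 200:1000
  expect_equal(sd(out_t[mid]) / sd(tone[mid]), 1, tolerance = 0.01)
  expect_error(highpass(seg, cutoff = 64), "cutoff")
})

test_that("filtering is linear in amplitude", {
  set.seed(2)
  x <- rnorm(1280)
  a <- 7.3
  f1 <- bandpass(eeg_segment(a * x, fs = 128))$samples[, 1]
  f2 <- a * bandpass(eeg_segment(x, fs = 128))$samples[, 1]
  # the 0.3 Hz edge at fs = 128 puts poles very close to the unit circle,
  # so direct-form recursion noise bounds the achievable agreement
  expect_lt(max(abs(f1 - f2)) / max(abs(f2)), 1e-6)
})

test_that("epoching drops partial tails and errors on short segments", {
  fs <- 128
  seg <- eeg_segment(rnorm(95 * fs), fs = fs)
  ep <- make_epochs(seg, 30)
  expect_equal(ncol(ep$epochs), 3)
  expect_equal(nrow(ep$epochs), 30 * fs)
  expect_equal(ncol(make_epochs(eeg_segment(rnorm(30 * fs), fs = fs))$epochs), 1)
  expect_error(make_epochs(eeg_segment(rnorm(29 * fs), fs = fs)), "shorter")
  # epoch-then-concatenate reproduces the truncated input
  expect_equal(as.vector(ep$epochs), seg$samples[seq_len(3 * 30 * fs), 1])
})

test_that("resampling changes the rate and roughly preserves a slow tone", {
  t <- seq(0, 10 - 1 / 512, by = 1 / 512)
  seg <- eeg_segment(sin(2 * pi * 3 * t), fs = 512)
  out <- resample_segment(seg, 128)
  expect_equal(out$fs, 128)
  expect_equal(nrow(out$samples), 128 * 10)
  mid <- 200:1000
  expect_equal(sd(out$samples[mid, 1]), sd(sin(2 * pi * 3 * t)[mid]),
               tolerance = 0.05)
})
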