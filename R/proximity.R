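#' Spike-wave-discharge fitting target
#'
#' Wraps a 2.5-s single-channel seizure waveform: applies the
#' low-frequency-artifact high-pass filter and computes the feature set
#' (single-window Welch spectrum on the standard padded grid, HVG on the
#' full window) used by [fit_swd()].
#'
#' @param samples Numeric series, 2.5 s long.
#' @param fs Sampling rate (Hz), default 128.
#' @param highpass_cutoff High-pass cutoff (Hz), default 1; `NULL` skips
#'   filtering.
#' @param order High-pass Butterworth order.
#' @return Object of class `swd_target`: `samples` (filtered), `fs`,
#'   `features` (a [feature_set()]).
#' @export
swd_target <- function(samples, fs = 128, highpass_cutoff = 1, order = 4) {
  dur <- length(samples) / fs
  if (abs(dur - 2.5) > 1e-6) {
    stop(sprintf("SWD segment must be 2.5 s (got %.4g s)", dur))
  }
  x <- samples
  if (!is.null(highpass_cutoff)) {
    seg <- eeg_segment(x, fs = fs, channel_labels = "swd",
                       group_label = "swd")
    x <- highpass(seg, cutoff = highpass_cutoff, order = order)$samples[, 1]
  }
  structure(list(samples = x, fs = fs, features = feature_set(x, fs = fs)),
            class = "swd_target")
}

#' @export
print.swd_target <- function(x, ...) {
  cat(sprintf("<swd_target> %.3g s at %g Hz, spectral peak %.3g Hz\n",
              length(x$samples) / x$fs, x$fs,
              x$features$spectrum$freqs[which.max(x$features$spectrum$power)]))
  invisible(x)
}

#' Mean emergent properties across SWD fit repeats
#'
#' Re-simulates each repeat's representative SWD solution and averages the
#' emergent properties; the mean excitatory synaptic current defines "the"
#' seizure-regime current that proximity scores are measured against.
#'
#' @param swd_fits List of `fit_result` from [fit_swd()].
#' @param sim_duration Simulation duration (s), default 2.5 to match the
#'   fitted segment.
#' @param dt_internal,burn_in,seed Simulation settings.
#' @return Named numeric vector of mean emergent properties.
#' @export
swd_properties <- function(swd_fits, sim_duration = 2.5, dt_internal = 2e-4,
                           burn_in = 5, seed = 1L) {
  if (!length(swd_fits)) stop("no SWD fit results")
  props <- vapply(swd_fits, function(fr) {
    sim <- simulate_nmm(fr$best$params, duration = sim_duration,
                        seed = seed + fr$repeat_id,
                        dt_internal = dt_internal, burn_in = burn_in)
    emergent_properties(sim)
  }, numeric(length(emergent_property_names())))
  rowMeans(props)
}

#' Distance of a subject's resting fit to the seizure regime
#'
#' The absolute difference between the subject's mean excitatory synaptic
#' current onto the excitatory population (averaged over fit repeats) and
#' the same current inferred from the SWD fits. Smaller distances mean a
#' smaller current change would move the subject to the seizure rhythm.
#'
#' @param subject_current Subject-level mean `I_exc_e` (from
#'   [subject_summaries()]).
#' @param swd_current SWD-regime mean `I_exc_e` (from [swd_properties()]).
#' @return Non-negative scalar distance.
#' @export
proximity <- function(subject_current, swd_current) {
  abs(subject_current - swd_current)
}

#' Proximity scores for a cohort
#'
#' @param summaries Data frame from [subject_summaries()] (needs columns
#'   `subject_id`, `group`, `I_exc_e`).
#' @param swd_props Named vector from [swd_properties()] (needs
#'   `I_exc_e`), or a scalar SWD current.
#' @param property Which current defines the distance; `"I_exc_e"`
#'   (default, current onto the excitatory population) or
#'   `"I_exc_total"` to sum the excitatory currents onto both populations.
#' @return Data frame: `subject_id`, `group`, `distance`.
#' @export
proximity_scores <- function(summaries, swd_props, property = c("I_exc_e",
                                                                "I_exc_total")) {
  property <- match.arg(property)
  val <- function(x) {
    if (property == "I_exc_e") {
      if (is.null(names(x))) unname(x[1]) else unname(x["I_exc_e"])
    } else {
      unname(x["I_exc_e"] + x["I_exc_i"])
    }
  }
  swd_cur <- if (length(swd_props) == 1 && is.null(names(swd_props))) {
    swd_props
  } else {
    val(swd_props)
  }
  subj_cur <- if (property == "I_exc_e") {
    summaries$I_exc_e
  } else {
    summaries$I_exc_e + summaries$I_exc_i
  }
  data.frame(subject_id = summaries$subject_id, group = summaries$group,
             distance = proximity(subj_cur, swd_cur),
             stringsAsFactors = FALSE)
}
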