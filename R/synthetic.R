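#' Synthetic cohort specification
#'
#' Defines a cohort of model-generated subjects with known ground-truth
#' parameters. Group templates come from [param_template()]; each subject's
#' true parameters are the group template plus truncated-Gaussian jitter
#' (SD = `jitter_frac` of each parameter's bound range, re-drawn until in
#' bounds). Default group sizes mirror a 16-control / 15-patient cohort in
#' which 7 patients had seizures during admission.
#'
#' @param n_control,n_patient_no_seizure,n_patient_seizure Group sizes
#'   (each >= 1).
#' @param jitter_frac Between-subject jitter SD as a fraction of each
#'   parameter's bound range.
#' @param noise_sd Measurement-noise SD as a fraction of the simulated
#'   signal SD.
#' @param n_epochs 30-s epochs generated per subject.
#' @param base_seed Cohort base seed; every subject's draw derives from it.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 16, n_patient_no_seizure = 8,
                        n_patient_seizure = 7, jitter_frac = 0.02,
                        noise_sd = 0.2, n_epochs = 4, base_seed = 1L) {
  stopifnot(n_control >= 1, n_patient_no_seizure >= 1, n_patient_seizure >= 1,
            jitter_frac >= 0, noise_sd >= 0, n_epochs >= 1)
  structure(as.list(environment()), class = "cohort_spec")
}

.jitter_params <- function(template, jitter_frac, max_draws = 100) {
  b <- nmm_bounds()
  p <- unclass(template)[b$name]
  if (jitter_frac == 0) return(structure(p, class = "nmm_params"))
  for (i in seq_along(p)) {
    sd_i <- jitter_frac * (b$upper[i] - b$lower[i])
    ok <- FALSE
    for (k in seq_len(max_draws)) {
      v <- p[[i]] + rnorm(1, 0, sd_i)
      if (v >= b$lower[i] && v <= b$upper[i]) {
        p[[i]] <- v
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("jitter rejected ", max_draws, " times for parameter ", b$name[i])
    }
  }
  structure(p, class = "nmm_params")
}

#' Generate one synthetic subject
#'
#' Draws true parameters around a group template, simulates a continuous
#' slow-wave-sleep-like recording of `n_epochs` x 30 s at 128 Hz, adds
#' white measurement noise, and emits it as two identical channels labelled
#' F3/F4 (so the frontal-averaging ingestion path is exercised).
#'
#' @param template Group template `nmm_params`.
#' @param jitter_frac Jitter SD fraction (see [cohort_spec()]).
#' @param noise_sd Measurement noise SD as a fraction of signal SD.
#' @param n_epochs Number of 30-s epochs.
#' @param seed Subject seed (drives jitter, simulation noise and
#'   measurement noise).
#' @param subject_id,group_label Metadata recorded on the segment.
#' @param dt_internal Simulator step (s).
#' @return List with `segment` (an [eeg_segment()]) and `truth` (the true
#'   `nmm_params`).
#' @export
generate_subject <- function(template, jitter_frac = 0.02, noise_sd = 0.2,
                             n_epochs = 4, seed = 1L,
                             subject_id = "s01", group_label = "control",
                             dt_internal = 1e-4) {
  validate_params(unclass(template))
  set.seed(seed)
  truth <- .jitter_params(template, jitter_frac)
  sim <- simulate_nmm(truth, duration = 30 * n_epochs, seed = seed,
                      dt_internal = dt_internal)
  if (sim$blown_up) stop("synthetic subject simulation blew up: ", subject_id)
  x <- sim$eeg
  if (noise_sd > 0) x <- x + rnorm(length(x), 0, noise_sd * sd(x))
  seg <- eeg_segment(cbind(F3 = x, F4 = x), fs = sim$fs,
                     channel_labels = c("F3", "F4"),
                     subject_id = subject_id, group_label = group_label)
  list(segment = seg, truth = truth)
}

#' Generate a full synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @return List with `segments` (named list of [eeg_segment()]) and
#'   `ground_truth` (named list of true `nmm_params`, one per subject) and
#'   `meta` (data frame: subject_id, group, seed).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  plan <- rbind(
    data.frame(group = "control", template = "control",
               k = seq_len(spec$n_control)),
    data.frame(group = "patient_no_seizure", template = "patient",
               k = seq_len(spec$n_patient_no_seizure)),
    data.frame(group = "patient_seizure", template = "patient_seizure",
               k = seq_len(spec$n_patient_seizure))
  )
  plan$subject_id <- sprintf("%s_%02d", plan$group, plan$k)
  plan$seed <- as.integer(spec$base_seed) + seq_len(nrow(plan)) * 97L
  segments <- list()
  truth <- list()
  for (i in seq_len(nrow(plan))) {
    g <- generate_subject(param_template(plan$template[i]),
                          jitter_frac = spec$jitter_frac,
                          noise_sd = spec$noise_sd,
                          n_epochs = spec$n_epochs,
                          seed = plan$seed[i],
                          subject_id = plan$subject_id[i],
                          group_label = plan$group[i])
    segments[[plan$subject_id[i]]] <- g$segment
    truth[[plan$subject_id[i]]] <- g$truth
  }
  list(segments = segments, ground_truth = truth,
       meta = plan[, c("subject_id", "group", "seed")])
}

#' Generate the spike-wave-discharge fixture
#'
#' A 2.5-s model-generated spike-wave waveform at 128 Hz from the packaged
#' SWD-regime parameters (a deterministic limit cycle in the 2.5-4 Hz band
#' with harmonics), standing in for a recorded seizure segment, plus its
#' ground-truth parameters.
#'
#' @param seed RNG seed (the SWD template is noise-free, so this only
#'   matters if `params` overrides add noise).
#' @param params SWD-regime parameters; default [param_template()]`("swd")`.
#' @param dt_internal Simulator step (s).
#' @return List with `samples` (320-sample series), `fs` (128),
#'   `truth` (the parameters), and `target` (an [swd_target()] ready for
#'   fitting).
#' @export
generate_swd_fixture <- function(seed = 1L, params = param_template("swd"),
                                 dt_internal = 1e-4) {
  sim <- simulate_nmm(params, duration = 2.5, seed = seed,
                      dt_internal = dt_internal)
  if (sim$blown_up) stop("SWD fixture simulation blew up")
  list(samples = sim$eeg, fs = sim$fs, truth = params,
       target = swd_target(sim$eeg, fs = sim$fs))
}
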