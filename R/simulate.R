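#' Population firing-rate sigmoid
#'
#' Mean firing rate of a population as a function of its mean membrane
#' potential: `Q = Qmax / (1 + exp(-C (V - theta) / sigma))` with
#' `C = pi / sqrt(3)`, so that `sigma` is the SD of the underlying
#' threshold distribution.
#'
#' @param V Membrane potential (mV); vectorized.
#' @param Qmax Maximum firing rate (1/s).
#' @param theta Firing threshold (mV).
#' @param sigma Sigmoid slope (mV), > 0.
#' @return Firing rate (1/s), in `[0, Qmax]`.
#' @export
sigmoid_rate <- function(V, Qmax, theta, sigma) {
  stopifnot(sigma > 0)
  Qmax / (1 + exp(-pi / sqrt(3) * (V - theta) / sigma))
}

#' Simulate the cortical neural mass model
#'
#' Integrates the two-population conductance-based model with
#' Euler-Maruyama at a fixed internal step, discards a burn-in transient,
#' and returns all state variables downsampled to `fs_out`. The membrane
#' equations combine excitatory, inhibitory, leak and sodium-dependent
#' potassium (KNa) currents; each synaptic connection is a second-order
#' filter `s'' = gamma^2 (N Q + phi - s) - 2 gamma s'` (stochastic afferent
#' drive `phi` on the two excitatory connections); sodium follows
#' `dNa/dt = (alpha_Na Q_e - pump(Na)) / tau_Na` and gates the KNa current
#' through `w(Na) = 0.37 / (1 + (38.7/Na)^3.5)`.
#'
#' The simulated EEG proxy is the excitatory membrane potential `V_e`
#' (gain/offset are removed downstream by z-scoring). A non-finite state or
#' `|V| > 200` mV aborts integration and returns a result flagged
#' `blown_up = TRUE` rather than raising, so an optimizer can penalize it.
#'
#' @param params `nmm_params` vector (see [nmm_params()]).
#' @param duration Output duration (s) after burn-in; default 30.
#' @param seed Integer RNG seed for the afferent noise; identical seeds give
#'   bit-identical trajectories.
#' @param dt_internal Integration step (s); default 1e-4.
#' @param burn_in Discarded initial transient (s); default 5.
#' @param fs_out Output sampling rate (Hz); default 128.
#' @return List of class `nmm_sim`: `t`, `V_e`, `V_i`, `Q_e`, `Q_i`,
#'   `s_ee`, `s_ei`, `s_ie`, `s_ii`, `Na`, `eeg` (= `V_e`), `blown_up`,
#'   `means` (exact post-burn-in time averages of rates and currents),
#'   `seed`, `dt_internal`, `fs`.
#' @export
simulate_nmm <- function(params, duration = 30, seed = 1L,
                         dt_internal = 1e-4, burn_in = 5, fs_out = 128) {
  stopifnot(duration > 0, dt_internal > 0, burn_in >= 0)
  p <- unclass(params)[nmm_param_names()]
  if (anyNA(p)) stop("params must be a named vector covering all 32 parameters")
  res <- .nmm_simulate_cpp(as.numeric(p), duration, burn_in, dt_internal,
                           as.integer(fs_out), as.numeric(seed))
  n <- length(res$V_e)
  if (res$blown_up) {
    keep <- seq_len(res$n_out_filled)
    for (f in c("V_e", "V_i", "Q_e", "Q_i", "s_ee", "s_ei", "s_ie", "s_ii",
                "Na")) res[[f]] <- res[[f]][keep]
    n <- res$n_out_filled
  }
  structure(list(
    t = seq_len(n) / fs_out - 1 / fs_out,
    V_e = res$V_e, V_i = res$V_i, Q_e = res$Q_e, Q_i = res$Q_i,
    s_ee = res$s_ee, s_ei = res$s_ei, s_ie = res$s_ie, s_ii = res$s_ii,
    Na = res$Na, eeg = res$V_e,
    blown_up = res$blown_up, means = res$means,
    seed = seed, dt_internal = dt_internal, fs = fs_out
  ), class = "nmm_sim")
}

#' @export
print.nmm_sim <- function(x, ...) {
  cat(sprintf("<nmm_sim> %.4g s at %g Hz%s\n", length(x$eeg) / x$fs, x$fs,
              if (x$blown_up) " [BLOWN UP]" else ""))
  invisible(x)
}

#' Emergent properties of a fitted simulation
#'
#' Time-averaged firing rates and synaptic currents per target population,
#' the unit of all group comparisons. Currents are signed with depolarizing
#' positive: `I = -g s (V - E_rev)` for synaptic channels and
#' `I = -g_L (V - E_L)` for leak, so a "larger (more negative)" inhibitory
#' current maps to a more negative `I_inh`. Averages are accumulated over
#' every integration step after burn-in (not from the downsampled traces).
#'
#' @param sim An `nmm_sim` from [simulate_nmm()], not flagged as blown up.
#' @param params The parameter vector used to generate `sim` (unused for the
#'   averages, which the simulator accumulates exactly, but kept so callers
#'   state the pairing explicitly and for the zero-conductance checks).
#' @return Named numeric vector: `mean_Q_e`, `mean_Q_i`, `I_exc_e`,
#'   `I_inh_e`, `I_leak_e`, `I_KNa_e`, `I_exc_i`, `I_inh_i`, `I_leak_i`.
#' @export
emergent_properties <- function(sim, params = NULL) {
  if (isTRUE(sim$blown_up)) {
    stop("simulation blew up; emergent properties undefined")
  }
  m <- sim$means
  out <- as.numeric(m)
  names(out) <- names(m)
  out
}

#' Names of the emergent properties tracked per simulation
#' @return Character vector.
#' @export
emergent_property_names <- function() {
  c("mean_Q_e", "mean_Q_i", "I_exc_e", "I_inh_e", "I_leak_e", "I_KNa_e",
    "I_exc_i", "I_inh_i", "I_leak_i")
}
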