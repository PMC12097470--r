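#' Conductance channels available for in-silico intervention
#' @return Character vector of the four channel names.
#' @export
conductance_channels <- function() c("excitatory", "inhibitory", "leak", "KNa")

#' Perturb one synaptic conductance
#'
#' Adjusts the conductance governing one synaptic channel by a fraction of
#' its bound range, in the direction that emulates treatment: excitatory
#' (`g_AMPA`) and leak (`g_L_e`, `g_L_i`) conductances are decreased;
#' inhibitory (`g_GABA`) and KNa (`g_KNa`) conductances are increased.
#' The result is clipped to the bounds; all other parameters are unchanged.
#'
#' @param params `nmm_params` vector, in bounds.
#' @param channel One of [conductance_channels()].
#' @param fraction Fraction of the bound range (upper - lower) in [0, 1];
#'   the intervention experiment uses 0.4, 0.5, 0.6.
#' @return Perturbed `nmm_params`.
#' @export
perturb_conductance <- function(params, channel, fraction = 0.5) {
  if (!channel %in% conductance_channels()) {
    stop("unknown channel '", channel, "'; must be one of: ",
         paste(conductance_channels(), collapse = ", "))
  }
  stopifnot(fraction >= 0, fraction <= 1)
  b <- nmm_bounds()
  p <- unclass(params)
  adjust <- function(pname, dir) {
    i <- match(pname, b$name)
    delta <- dir * fraction * (b$upper[i] - b$lower[i])
    min(max(p[[pname]] + delta, b$lower[i]), b$upper[i])
  }
  switch(channel,
    excitatory = { p["g_AMPA"] <- adjust("g_AMPA", -1) },
    inhibitory = { p["g_GABA"] <- adjust("g_GABA", +1) },
    leak = {
      p["g_L_e"] <- adjust("g_L_e", -1)
      p["g_L_i"] <- adjust("g_L_i", -1)
    },
    KNa = { p["g_KNa"] <- adjust("g_KNa", +1) }
  )
  structure(p, class = "nmm_params")
}

#' Spectral sensitivity to a perturbation
#'
#' Euclidean norm of the pointwise difference between the baseline and
#' perturbed normalized spectra on their common grid; zero iff the spectra
#' are identical.
#'
#' @param base,pert `spectral_feature` objects on the same grid.
#' @param norm `"l2"` (default) or `"l1"`.
#' @return Non-negative scalar.
#' @export
spectral_sensitivity <- function(base, pert, norm = "l2") {
  spectral_distance(base, pert, norm = norm)
}

# mean normalized spectrum over fresh-seed simulations of one parameter set
.mean_spectrum <- function(params, n_seeds, seed0, duration, dt_internal,
                           burn_in) {
  acc <- NULL
  used <- 0
  for (s in seq_len(n_seeds)) {
    sim <- simulate_nmm(params, duration = duration, seed = seed0 + s,
                        dt_internal = dt_internal, burn_in = burn_in)
    if (sim$blown_up || sd(sim$eeg) == 0) next
    sp <- welch_normalized_psd(sim$eeg, fs = sim$fs)
    acc <- if (is.null(acc)) sp$power else acc + sp$power
    used <- used + 1
    freqs <- sp$freqs
  }
  if (used == 0) return(NULL)
  p <- acc / used
  structure(list(freqs = freqs, power = p / .trapz(freqs, p)),
            class = "spectral_feature")
}

#' In-silico intervention experiment
#'
#' For each subject's representative fitted parameters and each
#' channel x fraction condition, re-simulates with fresh seeds (averaging
#' spectra over `n_seeds` noise realizations), computes the spectral
#' sensitivity to the perturbation, and tests whether the excitatory
#' channel's sensitivities exceed each other channel's (Mann-Whitney,
#' Bonferroni family = 3 per fraction).
#'
#' @param subject_params Named list (by subject id) of `nmm_params` --
#'   typically each subject's representative fit.
#' @param fractions Perturbation fractions (default `c(0.4, 0.5, 0.6)`).
#' @param n_seeds Fresh noise seeds averaged per condition (default 5).
#' @param duration,dt_internal,burn_in Simulation settings.
#' @param seed Base seed for the fresh-seed draws.
#' @param alpha Level for the excitatory-vs-other tests.
#' @return List with `sensitivities` (data frame: subject_id, channel,
#'   fraction, sensitivity) and `tests` (data frame per fraction x
#'   comparison).
#' @export
intervention_experiment <- function(subject_params,
                                    fractions = c(0.4, 0.5, 0.6),
                                    n_seeds = 5, duration = 30,
                                    dt_internal = 2e-4, burn_in = 5,
                                    seed = 1L, alpha = 0.05) {
  if (!length(subject_params)) stop("no fitted subjects supplied")
  stopifnot(!is.null(names(subject_params)))
  rows <- list()
  for (sid in names(subject_params)) {
    p0 <- subject_params[[sid]]
    base <- .mean_spectrum(p0, n_seeds, seed, duration, dt_internal, burn_in)
    if (is.null(base)) next
    for (ch in conductance_channels()) {
      for (fr in fractions) {
        pp <- perturb_conductance(p0, ch, fr)
        pert <- .mean_spectrum(pp, n_seeds, seed + 100L, duration,
                               dt_internal, burn_in)
        sens <- if (is.null(pert)) NA_real_ else spectral_sensitivity(base, pert)
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = sid, channel = ch, fraction = fr,
          sensitivity = sens, stringsAsFactors = FALSE)
      }
    }
  }
  sens <- do.call(rbind, rows)
  tests <- list()
  others <- setdiff(conductance_channels(), "excitatory")
  for (fr in fractions) {
    d <- sens[sens$fraction == fr & is.finite(sens$sensitivity), ]
    exc <- d$sensitivity[d$channel == "excitatory"]
    if (length(exc) < 2) next
    ps <- vapply(others, function(ch) {
      mann_whitney_u(exc, d$sensitivity[d$channel == ch])$p
    }, 0)
    tests[[length(tests) + 1]] <- data.frame(
      fraction = fr, comparison = paste0("excitatory_vs_", others),
      p = unname(ps),
      excitatory_larger = vapply(others, function(ch) {
        median(exc) > median(d$sensitivity[d$channel == ch])
      }, TRUE),
      significant = bonferroni(unname(ps), alpha = alpha, m = length(others)),
      stringsAsFactors = FALSE)
  }
  list(sensitivities = sens,
       tests = if (length(tests)) do.call(rbind, tests) else NULL)
}
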