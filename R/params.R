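#' @useDynLib sleepmass, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median quantile rnorm runif sd wilcox.test approx fft
#' @importFrom utils head read.csv write.csv
NULL

#' Names of the 32 tunable model parameters
#'
#' The search space of the cortical neural mass model: two populations
#' (excitatory `e`, inhibitory `i`) with sigmoidal firing, second-order
#' synaptic filters on the four connections, leak and sodium-dependent
#' potassium (KNa) currents, sodium dynamics, and a stochastic afferent
#' drive on the excitatory synapses.
#'
#' @return Character vector of length 32, in the canonical order used by
#'   [simulate_nmm()] and the optimizer.
#' @export
nmm_param_names <- function() {
  c("Qmax_e", "Qmax_i", "theta_e", "theta_i", "sigma_e", "sigma_i",
    "gamma_e", "gamma_i",
    "N_ee", "N_ei", "N_ie", "N_ii",
    "tau_e", "tau_i", "C_e", "C_i",
    "g_AMPA", "g_GABA", "g_L_e", "g_L_i", "g_KNa",
    "E_AMPA", "E_GABA", "E_L_e", "E_L_i", "E_K",
    "alpha_Na", "tau_Na", "R_pump", "Na_eq",
    "phi_mean", "phi_sd")
}

#' Parameter bounds of the search space
#'
#' Lower/upper bounds for every tunable parameter, with units and a short
#' description. These bounds define the optimizer's search space and the
#' ranges used by conductance perturbations ("fraction of the bound range").
#' The reversal-potential bounds are non-overlapping so that every in-bounds
#' vector satisfies `E_GABA < E_L_e < E_AMPA`.
#'
#' @return A data frame with columns `name`, `lower`, `upper`, `unit`,
#'   `description`, `searched`.
#' @export
nmm_bounds <- function() {
  b <- rbind(
    c("Qmax_e",  20,     40,    "1/s",  "max excitatory firing rate"),
    c("Qmax_i",  40,     80,    "1/s",  "max inhibitory firing rate"),
    c("theta_e", -65,    -52,   "mV",   "excitatory firing threshold"),
    c("theta_i", -65,    -52,   "mV",   "inhibitory firing threshold"),
    c("sigma_e", 2,      8,     "mV",   "excitatory sigmoid slope"),
    c("sigma_i", 2,      8,     "mV",   "inhibitory sigmoid slope"),
    c("gamma_e", 40,     100,   "1/s",  "excitatory synaptic rate constant"),
    c("gamma_i", 20,     90,    "1/s",  "inhibitory synaptic rate constant"),
    c("N_ee",    60,     180,   "",     "e->e mean synapse count"),
    c("N_ei",    30,     120,   "",     "e->i mean synapse count"),
    c("N_ie",    40,     140,   "",     "i->e mean synapse count"),
    c("N_ii",    40,     140,   "",     "i->i mean synapse count"),
    c("tau_e",   0.015,  0.060, "s",    "excitatory membrane time constant"),
    c("tau_i",   0.015,  0.060, "s",    "inhibitory membrane time constant"),
    c("C_e",     0.5,    2,     "muF",  "excitatory capacitance scale"),
    c("C_i",     0.5,    2,     "muF",  "inhibitory capacitance scale"),
    c("g_AMPA",  1e-5,   3e-4,  "mS",   "excitatory synaptic conductance"),
    c("g_GABA",  1e-4,   3e-3,  "mS",   "inhibitory synaptic conductance"),
    c("g_L_e",   0.5,    1.5,   "mS",   "excitatory leak conductance"),
    c("g_L_i",   0.5,    1.5,   "mS",   "inhibitory leak conductance"),
    c("g_KNa",   1,      40,    "mS",   "KNa conductance"),
    c("E_AMPA",  -5,     10,    "mV",   "excitatory synaptic reversal"),
    c("E_GABA",  -75,    -68,   "mV",   "inhibitory synaptic reversal"),
    c("E_L_e",   -67,    -61,   "mV",   "excitatory leak reversal"),
    c("E_L_i",   -67,    -61,   "mV",   "inhibitory leak reversal"),
    c("E_K",     -105,   -90,   "mV",   "potassium reversal"),
    c("alpha_Na",0.05,   2.5,   "mM",   "Na influx per spike"),
    c("tau_Na",  0.2,    2,     "s",    "Na dynamics time scale"),
    c("R_pump",  5,      100,   "mM/s", "Na pump strength"),
    c("Na_eq",   8,      11,    "mM",   "baseline Na concentration"),
    c("phi_mean",0,      200,   "1/s",  "afferent drive mean"),
    c("phi_sd",  0,      30,    "1/s",  "afferent drive noise SD")
  )
  out <- data.frame(
    name = b[, 1],
    lower = as.numeric(b[, 2]),
    upper = as.numeric(b[, 3]),
    unit = b[, 4],
    description = b[, 5],
    searched = TRUE,
    stringsAsFactors = FALSE
  )
  stopifnot(identical(out$name, nmm_param_names()))
  out
}

#' Construct and validate a model parameter vector
#'
#' @param ... Named scalar overrides of the defaults (the slow-wave control
#'   template, see [param_template()]).
#' @param base Named numeric vector of length 32 to start from.
#' @param check If `TRUE`, error when a value lies outside its bound.
#' @return Named numeric vector of length 32, class `nmm_params`.
#' @export
nmm_params <- function(..., base = param_template("control"), check = TRUE) {
  p <- unclass(base)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), nmm_param_names())
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           "; valid names are: ", paste(nmm_param_names(), collapse = ", "))
    }
    p[names(over)] <- unlist(over)
  }
  p <- p[nmm_param_names()]
  if (check) validate_params(p)
  structure(p, class = "nmm_params")
}

#' @rdname nmm_params
#' @param p Named numeric vector of length 32.
#' @export
validate_params <- function(p) {
  b <- nmm_bounds()
  p <- p[b$name]
  if (anyNA(p)) stop("parameter vector is missing names or contains NA")
  out_lo <- p < b$lower - 1e-12
  out_hi <- p > b$upper + 1e-12
  if (any(out_lo | out_hi)) {
    bad <- b$name[out_lo | out_hi]
    stop("parameter(s) out of bounds: ", paste(bad, collapse = ", "))
  }
  if (!(p[["E_GABA"]] < p[["E_L_e"]] && p[["E_L_e"]] < p[["E_AMPA"]])) {
    stop("reversal potentials must satisfy E_GABA < E_L_e < E_AMPA")
  }
  invisible(TRUE)
}

#' Group parameter templates
#'
#' Canonical parameter sets used by the synthetic-cohort generator and as
#' optimizer test points:
#' * `"control"` -- slow-oscillation regime with a delta-dominant
#'   (< 4 Hz) normalized spectrum, the healthy slow-wave-sleep baseline.
#' * `"patient"` -- the control set with a lowered excitatory firing
#'   threshold `theta_e`, raised excitatory connectivity (`N_ee`, `N_ei`),
#'   shifted synaptic rate constants (`gamma_e`, `gamma_i`) and a slightly
#'   raised excitatory reversal `E_AMPA`: a mildly hyperexcitable cortex.
#' * `"patient_seizure"` -- the same shifts, roughly doubled; emulates
#'   patients with a seizure during admission.
#' * `"swd"` -- strongly hyperexcitable regime producing a 2.5-4 Hz
#'   spike-wave limit cycle (nonsinusoidal, with harmonics), the archetypal
#'   seizure rhythm target.
#'
#' @param which One of `"control"`, `"patient"`, `"patient_seizure"`, `"swd"`.
#' @return Named numeric vector of length 32, class `nmm_params`.
#' @export
param_template <- function(which = c("control", "patient", "patient_seizure",
                                     "swd")) {
  which <- match.arg(which)
  ctrl <- c(
    Qmax_e = 30, Qmax_i = 60, theta_e = -58.5, theta_i = -58.5,
    sigma_e = 6, sigma_i = 6, gamma_e = 70, gamma_i = 58.6,
    N_ee = 120, N_ei = 72, N_ie = 90, N_ii = 90,
    tau_e = 0.030, tau_i = 0.030, C_e = 1, C_i = 1,
    g_AMPA = 2.0e-4, g_GABA = 6e-4, g_L_e = 1, g_L_i = 1, g_KNa = 15,
    E_AMPA = 0, E_GABA = -70, E_L_e = -64, E_L_i = -64, E_K = -100,
    alpha_Na = 0.6, tau_Na = 1, R_pump = 40, Na_eq = 9.5,
    phi_mean = 60, phi_sd = 5
  )
  shift <- c(theta_e = -0.3, N_ee = 2, N_ei = 1, gamma_e = -12,
             gamma_i = -8, E_AMPA = 0.2)
  p <- ctrl
  if (which == "patient") {
    p[names(shift)] <- p[names(shift)] + shift
  } else if (which == "patient_seizure") {
    p[names(shift)] <- p[names(shift)] + 2 * shift
  } else if (which == "swd") {
    p[c("theta_e", "g_AMPA", "gamma_i", "tau_Na", "alpha_Na", "R_pump",
        "g_KNa", "N_ee", "sigma_e", "phi_sd")] <-
      c(-59, 2.4e-4, 30, 0.25, 2.0, 80, 22, 160, 4.5, 0)
  }
  structure(p[nmm_param_names()], class = "nmm_params")
}

#' @export
print.nmm_params <- function(x, ...) {
  cat("<nmm_params> 32 neural mass model parameters\n")
  print(unclass(x), ...)
  invisible(x)
}
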