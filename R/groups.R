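#' Mann-Whitney U test
#'
#' Two-sided nonparametric comparison of two samples. Uses the exact
#' distribution (full enumeration) when the combined sample size is at most
#' 20 and there are no ties, and the normal approximation with continuity
#' and tie correction otherwise.
#'
#' @param a,b Numeric samples, both non-empty.
#' @return List with `U` (the U statistic of `a`) and `p` (two-sided).
#' @export
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b)) <= 20 && !ties
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Bonferroni significance flags
#'
#' Flags `p_i < alpha / m` for a family of `m` comparisons (e.g. `m = 4`
#' when the four synaptic current types are compared).
#'
#' @param pvals Numeric p-values.
#' @param alpha Family-wise level in (0, 1).
#' @param m Family size; defaults to `length(pvals)`.
#' @return Logical vector of significance flags.
#' @export
bonferroni <- function(pvals, alpha = 0.05, m = length(pvals)) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  pvals < alpha / m
}

#' Jensen-Shannon divergence between two samples
#'
#' Both samples are histogrammed on a shared grid of `bins` equal-width
#' bins spanning `bounds`; the JSD between the two normalized histograms is
#' returned in bits (base-2 logarithm), with additive smoothing `eps`.
#' Bounded in [0, 1]: 0 for identical histograms, 1 bit for disjoint
#' supports.
#'
#' @param sample_a,sample_b Numeric samples within `bounds`.
#' @param bounds Length-2 numeric `c(lower, upper)`, `lower < upper`.
#' @param bins Number of histogram bins (default 20).
#' @param eps Additive smoothing mass per bin.
#' @return Scalar in [0, 1] (bits).
#' @export
js_divergence <- function(sample_a, sample_b, bounds, bins = 20,
                          eps = 1e-12) {
  if (bounds[2] <= bounds[1]) stop("degenerate bounds")
  brk <- seq(bounds[1], bounds[2], length.out = bins + 1)
  h <- function(x) {
    x <- pmin(pmax(x, bounds[1]), bounds[2])
    cnt <- tabulate(findInterval(x, brk, rightmost.closed = TRUE), nbins = bins)
    p <- cnt + eps
    p / sum(p)
  }
  p <- h(sample_a); q <- h(sample_b)
  m <- (p + q) / 2
  kl <- function(x, y) sum(ifelse(x > 0, x * log2(x / y), 0))
  (kl(p, m) + kl(q, m)) / 2
}

#' Rank model parameters by between-group divergence
#'
#' Pools each group's per-repeat representative parameter values and ranks
#' all searched parameters by decreasing Jensen-Shannon divergence between
#' the two groups, each parameter histogrammed over its own search bounds.
#' Identifies which synaptic mechanism most separates the groups.
#'
#' @param fits_a,fits_b Lists of per-subject fit-result lists (as returned
#'   by [fit_subject()]) for the two groups, or flat lists of
#'   `fit_result`.
#' @param bins Histogram bins passed to [js_divergence()].
#' @return Data frame with columns `param`, `jsd`, sorted by decreasing
#'   `jsd`.
#' @export
rank_parameters_by_divergence <- function(fits_a, fits_b, bins = 20) {
  flatten <- function(f) {
    if (!length(f)) stop("each group needs at least one fit result")
    if (inherits(f[[1]], "fit_result")) f else do.call(c, f)
  }
  fa <- flatten(fits_a); fb <- flatten(fits_b)
  b <- nmm_bounds()
  searched <- b$name[b$searched]
  jsd <- vapply(searched, function(pn) {
    bb <- c(b$lower[b$name == pn], b$upper[b$name == pn])
    js_divergence(pooled_distribution(fa, pn), pooled_distribution(fb, pn),
                  bounds = bb, bins = bins)
  }, 0)
  out <- data.frame(param = searched, jsd = unname(jsd))
  out[order(-out$jsd), , drop = FALSE]
}

#' Subject-level summary of emergent properties
#'
#' One row per subject: the arithmetic mean over optimization repeats of
#' each emergent property of the repeat's representative simulation (each
#' violin-plot point in the group figures is such a subject mean).
#'
#' @param fits Named list (by subject id) of fit-result lists.
#' @param groups Named character vector mapping subject id to group label.
#' @param sim_duration,dt_internal,burn_in Simulation settings used to
#'   re-simulate each representative solution.
#' @param seed Noise seed offset for the re-simulations.
#' @param solutions `"best"` re-simulates each repeat's single
#'   representative solution; `"front"` averages over the spectrum-proximal
#'   Pareto members of each repeat (those with `f_spec` within
#'   `front_fspec_ratio` of the front minimum), a variance-reduced
#'   estimator of the same quantity that averages many near-equivalent
#'   fits per repeat.
#' @param front_fspec_ratio Inclusion ratio for `solutions = "front"`.
#' @return Data frame: `subject_id`, `group`, one column per emergent
#'   property (see [emergent_property_names()]).
#' @export
subject_summaries <- function(fits, groups, sim_duration = 30,
                              dt_internal = 2e-4, burn_in = 5, seed = 1L,
                              solutions = c("best", "front"),
                              front_fspec_ratio = 1.25) {
  solutions <- match.arg(solutions)
  stopifnot(length(fits) > 0, !is.null(names(fits)))
  np <- length(emergent_property_names())
  repeat_props <- function(fr) {
    if (solutions == "best") {
      sets <- list(fr$best$params)
    } else {
      keep <- which(fr$pareto_objectives[, "f_spec"] <=
                      front_fspec_ratio * min(fr$pareto_objectives[, "f_spec"]))
      sets <- lapply(keep, function(i)
        structure(fr$pareto_params[i, ], class = "nmm_params"))
    }
    acc <- numeric(np)
    used <- 0
    for (k in seq_along(sets)) {
      sim <- simulate_nmm(sets[[k]], duration = sim_duration,
                          seed = seed + fr$repeat_id * 131L + k,
                          dt_internal = dt_internal, burn_in = burn_in)
      if (sim$blown_up) next
      acc <- acc + emergent_properties(sim)
      used <- used + 1
    }
    if (used == 0) rep(NA_real_, np) else acc / used
  }
  rows <- lapply(names(fits), function(sid) {
    props <- vapply(fits[[sid]], repeat_props, numeric(np))
    data.frame(subject_id = sid, group = unname(groups[sid]),
               t(rowMeans(props, na.rm = TRUE)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise group comparisons of emergent properties
#'
#' For each property, compares the control group against each patient
#' group (patients pooled, patients with seizures, patients without
#' seizures) with two-sided Mann-Whitney U tests on subject-level means,
#' Bonferroni-corrected with family size = number of properties tested.
#'
#' @param summaries Data frame from [subject_summaries()].
#' @param properties Character vector of property columns to test.
#' @param alpha Family-wise level.
#' @return Data frame: one row per property x comparison, with `U`, `p`,
#'   `direction` (sign of patient-group median minus control median) and
#'   `significant` (Bonferroni flag).
#' @export
compare_groups <- function(summaries,
                           properties = c("mean_Q_e", "mean_Q_i", "I_exc_e",
                                          "I_inh_e"),
                           alpha = 0.05) {
  stopifnot(all(properties %in% names(summaries)))
  g <- summaries$group
  if (length(unique(g)) < 2) stop("need at least two groups")
  ctrl <- summaries[g == "control", , drop = FALSE]
  if (nrow(ctrl) < 2) stop("control group needs at least 2 subjects")
  sets <- list(
    patient_all = summaries[g %in% c("patient_no_seizure", "patient_seizure"), ],
    patient_seizure = summaries[g == "patient_seizure", ],
    patient_no_seizure = summaries[g == "patient_no_seizure", ]
  )
  sets <- Filter(function(d) nrow(d) >= 2, sets)
  if (!length(sets)) stop("no patient group with at least 2 subjects")
  rows <- list()
  for (prop in properties) {
    for (cmp in names(sets)) {
      mw <- mann_whitney_u(sets[[cmp]][[prop]], ctrl[[prop]])
      rows[[length(rows) + 1]] <- data.frame(
        property = prop, comparison = paste0(cmp, "_vs_control"),
        U = mw$U, p = mw$p,
        direction = sign(median(sets[[cmp]][[prop]]) - median(ctrl[[prop]])),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- bonferroni(out$p, alpha = alpha, m = length(properties))
  out
}
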