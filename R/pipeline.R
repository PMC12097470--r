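#' End-to-end pipeline configuration
#'
#' Serializable configuration for [run_pipeline()]. Every random draw in a
#' run derives from `base_seed` plus a fixed per-stage offset and the
#' subject index, so a rerun with the same configuration reproduces all
#' outputs.
#'
#' @param cohort A [cohort_spec()].
#' @param fit A [fit_config()].
#' @param band Preprocessing band-pass edges (Hz).
#' @param filter_order Butterworth order.
#' @param epoch_length Epoch length (s).
#' @param fractions Perturbation fractions.
#' @param alpha Significance level.
#' @param swd_highpass SWD high-pass cutoff (Hz).
#' @param stages Stage names to run, in dependency order; any subset of
#'   `c("synth", "features", "fit", "emergent", "compare", "perturb",
#'   "proximity")`. Later stages require earlier outputs on disk.
#' @param base_seed Global base seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), fit = fit_config(),
                            band = c(0.3, 10), filter_order = 4,
                            epoch_length = 30,
                            fractions = c(0.4, 0.5, 0.6), alpha = 0.05,
                            swd_highpass = 1,
                            stages = c("synth", "features", "fit", "emergent",
                                       "compare", "perturb", "proximity"),
                            base_seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Write/read a pipeline configuration as YAML
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a `pipeline_config`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  x <- lapply(config, function(v) if (is.list(v)) unclass(v) else v)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in names(x)) {
    v <- x[[nm]]
    if (nm == "cohort") v <- do.call(cohort_spec, v)
    if (nm == "fit") v <- do.call(fit_config, v)
    if (nm %in% c("band", "fractions", "stages")) v <- unlist(v)
    cfg[[nm]] <- v
  }
  cfg
}

.stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(..., collapse = " ")))
}

#' Run the staged analysis pipeline
#'
#' Executes the configured stages in dependency order with plain-file
#' handoff under `out_dir`:
#' * `synth`: generate the synthetic cohort (EDF per subject,
#'   `cohort.csv`, `ground_truth.json`) and the SWD fixture
#'   (`swd.csv`).
#' * `features`: ingest each EDF (average F3/F4, band-pass, epoch) and
#'   cache feature sets (`features/<id>.json`).
#' * `fit`: NSGA-II fits per subject (`fits/<id>.json`) and for the SWD
#'   target (`fits/swd.json`).
#' * `emergent`: subject-level emergent-property summaries
#'   (`summaries.csv`).
#' * `compare`: group comparisons (`comparisons.csv`) and parameter
#'   divergence ranking (`divergence.csv`).
#' * `perturb`: conductance-intervention sensitivities
#'   (`sensitivities.csv`, `perturb_tests.csv`).
#' * `proximity`: seizure-proximity scores (`proximity.csv`).
#'
#' Stages are re-entrant: each reads only earlier stages' files and
#' rewrites its own.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fdir <- file.path(out_dir, "features")
  gdir <- file.path(out_dir, "fits")
  stages <- config$stages

  if ("synth" %in% stages) {
    .stage_msg("synth", "generating cohort")
    spec <- config$cohort
    spec$base_seed <- as.integer(config$base_seed)
    coh <- generate_cohort(spec)
    for (sid in names(coh$segments)) {
      write_edf(coh$segments[[sid]], file.path(out_dir, paste0(sid, ".edf")))
    }
    write.csv(coh$meta, file.path(out_dir, "cohort.csv"), row.names = FALSE)
    jsonlite::write_json(lapply(coh$ground_truth, function(p)
      as.list(unclass(p))), file.path(out_dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA)
    swd <- generate_swd_fixture(seed = as.integer(config$base_seed) + 7777L)
    write.csv(data.frame(t = seq_along(swd$samples) / swd$fs,
                         uV = swd$samples),
              file.path(out_dir, "swd.csv"), row.names = FALSE)
  }

  meta <- read.csv(file.path(out_dir, "cohort.csv"), stringsAsFactors = FALSE)

  if ("features" %in% stages) {
    .stage_msg("features", "computing feature targets")
    dir.create(fdir, showWarnings = FALSE)
    for (sid in meta$subject_id) {
      seg <- read_edf(file.path(out_dir, paste0(sid, ".edf")),
                      channels = c("F3", "F4"))
      seg <- average_channels(seg, c("F3", "F4"))
      seg <- bandpass(seg, config$band[1], config$band[2],
                      order = config$filter_order)
      eps <- make_epochs(seg, epoch_length = config$epoch_length)
      fs <- feature_set(eps)
      jsonlite::write_json(list(freqs = fs$spectrum$freqs,
                                power = fs$spectrum$power,
                                mean_wdegree = fs$mean_wdegree,
                                fs = fs$fs, n_epochs = fs$n_epochs),
                           file.path(fdir, paste0(sid, ".json")),
                           digits = NA, auto_unbox = TRUE)
    }
  }

  read_feats <- function(sid) {
    x <- jsonlite::read_json(file.path(fdir, paste0(sid, ".json")),
                             simplifyVector = TRUE)
    structure(list(
      spectrum = structure(list(freqs = x$freqs, power = x$power),
                           class = "spectral_feature"),
      mean_wdegree = x$mean_wdegree, fs = x$fs, n_epochs = x$n_epochs),
      class = "feature_set")
  }

  if ("fit" %in% stages) {
    dir.create(gdir, showWarnings = FALSE)
    fitc <- config$fit
    for (i in seq_along(meta$subject_id)) {
      sid <- meta$subject_id[i]
      .stage_msg("fit", sid)
      fitc$base_seed <- as.integer(config$base_seed) + 1000L * i
      res <- fit_subject(read_feats(sid), fitc)
      .write_fits_json(res, file.path(gdir, paste0(sid, ".json")))
    }
    .stage_msg("fit", "swd")
    swd_df <- read.csv(file.path(out_dir, "swd.csv"))
    tgt <- swd_target(swd_df$uV, fs = 128,
                      highpass_cutoff = config$swd_highpass)
    fitc$base_seed <- as.integer(config$base_seed) + 999000L
    .write_fits_json(fit_swd(tgt, fitc), file.path(gdir, "swd.json"))
  }

  if ("emergent" %in% stages) {
    .stage_msg("emergent", "subject summaries")
    fits <- lapply(meta$subject_id, function(sid)
      .read_fits_json(file.path(gdir, paste0(sid, ".json"))))
    names(fits) <- meta$subject_id
    groups <- structure(meta$group, names = meta$subject_id)
    summ <- subject_summaries(fits, groups,
                              dt_internal = config$fit$dt_internal,
                              seed = as.integer(config$base_seed) + 5L)
    write.csv(summ, file.path(out_dir, "summaries.csv"), row.names = FALSE)
  }

  if ("compare" %in% stages) {
    .stage_msg("compare", "group statistics")
    summ <- read.csv(file.path(out_dir, "summaries.csv"),
                     stringsAsFactors = FALSE)
    cmp <- compare_groups(summ, alpha = config$alpha)
    write.csv(cmp, file.path(out_dir, "comparisons.csv"), row.names = FALSE)
    fits <- lapply(meta$subject_id, function(sid)
      .read_fits_json(file.path(gdir, paste0(sid, ".json"))))
    names(fits) <- meta$subject_id
    is_pat <- meta$group %in% c("patient_no_seizure", "patient_seizure")
    if (any(is_pat) && any(meta$group == "control")) {
      rk <- rank_parameters_by_divergence(fits[meta$group == "control"],
                                          fits[is_pat])
      write.csv(rk, file.path(out_dir, "divergence.csv"), row.names = FALSE)
    }
  }

  if ("perturb" %in% stages) {
    .stage_msg("perturb", "conductance interventions")
    is_pat <- meta$group %in% c("patient_no_seizure", "patient_seizure")
    pats <- meta$subject_id[is_pat]
    sp <- lapply(pats, function(sid) {
      fits <- .read_fits_json(file.path(gdir, paste0(sid, ".json")))
      fits[[1]]$best$params
    })
    names(sp) <- pats
    res <- intervention_experiment(sp, fractions = config$fractions,
                                   dt_internal = config$fit$dt_internal,
                                   seed = as.integer(config$base_seed) + 11L,
                                   alpha = config$alpha)
    write.csv(res$sensitivities, file.path(out_dir, "sensitivities.csv"),
              row.names = FALSE)
    if (!is.null(res$tests)) {
      write.csv(res$tests, file.path(out_dir, "perturb_tests.csv"),
                row.names = FALSE)
    }
  }

  if ("proximity" %in% stages) {
    .stage_msg("proximity", "distance to seizure regime")
    summ <- read.csv(file.path(out_dir, "summaries.csv"),
                     stringsAsFactors = FALSE)
    swd_fits <- .read_fits_json(file.path(gdir, "swd.json"))
    props <- swd_properties(swd_fits, dt_internal = config$fit$dt_internal,
                            seed = as.integer(config$base_seed) + 13L)
    px <- proximity_scores(summ, props)
    write.csv(px, file.path(out_dir, "proximity.csv"), row.names = FALSE)
  }

  invisible(out_dir)
}

.write_fits_json <- function(results, path) {
  jsonlite::write_json(lapply(results, function(r) list(
    repeat_id = r$repeat_id,
    pareto_params = r$pareto_params,
    pareto_objectives = r$pareto_objectives,
    best_params = as.list(unclass(r$best$params)),
    best_objectives = as.list(r$best$objectives),
    seed = r$seed, trace = r$trace
  )), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

.read_fits_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(x)), function(i) {
    bp <- unlist(x$best_params[i, ])
    structure(list(
      repeat_id = x$repeat_id[i],
      pareto_params = x$pareto_params[[i]],
      pareto_objectives = x$pareto_objectives[[i]],
      best = list(params = structure(bp[nmm_param_names()],
                                     class = "nmm_params"),
                  objectives = unlist(x$best_objectives[i, ])),
      seed = x$seed[i], trace = x$trace[[i]]
    ), class = "fit_result")
  })
}
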