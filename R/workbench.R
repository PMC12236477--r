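#' Validated end-to-end run configuration
#'
#' Bundles the simulation settings and every analysis parameter of a full
#' pipeline run. Unknown keys are rejected so that silently misspelled
#' options cannot change an analysis.
#'
#' @param sim a [sim_config()] (the dataset to generate), or `NULL` when
#'   `dataset` will be supplied to [run_pipeline()] directly.
#' @param n_perm permutation count for reactivation scoring (>= 100).
#' @param seed master analysis seed (governs all stochastic stages).
#' @param lag_s hemodynamic shift for pattern extraction.
#' @param q_threshold searchlight significance threshold.
#' @param screen_p ISC screen selection threshold.
#' @param test `"paired"` or `"independent"` remembered-vs-forgotten
#'   variant.
#' @param dmn_networks collapsed network names treated as the default-mode
#'   correction set.
#' @param extra named list of additional options; must be empty (reserved).
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), n_perm = 1000, seed = 1,
                       lag_s = 0, q_threshold = 0.1, screen_p = 0.05,
                       test = c("paired", "independent"),
                       dmn_networks = "Default", extra = list()) {
  test <- match.arg(test)
  if (length(extra) > 0) {
    abort(sprintf("unknown config keys: %s",
                  paste(names(extra), collapse = ", ")))
  }
  if (n_perm < 100) abort("`n_perm` must be >= 100")
  assert_scalar_number(lag_s, "lag_s")
  assert_scalar_number(q_threshold, "q_threshold", positive = TRUE)
  assert_scalar_number(screen_p, "screen_p", positive = TRUE)
  structure(list(sim = sim, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), lag_s = lag_s,
                 q_threshold = q_threshold, screen_p = screen_p,
                 test = test, dmn_networks = dmn_networks),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; the `sim` block
#' mirrors [sim_config()] (with `scenes` given via the [sim_scene_table()]
#' arguments under a `scene_layout` key). Unknown keys error.
#'
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$scene_layout)) {
    sim_args$scenes <- do.call(sim_scene_table, sim_args$scene_layout)
    sim_args$scene_layout <- NULL
  }
  unknown <- setdiff(names(sim_args), names(formals(sim_config)))
  if (length(unknown) > 0) {
    abort(sprintf("unknown sim keys: %s", paste(unknown, collapse = ", ")))
  }
  top <- y[setdiff(names(y), "sim")]
  unknown <- setdiff(names(top), names(formals(run_config)))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config keys: %s",
                  paste(unknown, collapse = ", ")))
  }
  do.call(run_config, c(list(sim = do.call(sim_config, sim_args)), top))
}

#' Run the full replication pipeline
#'
#' Executes every stage in order on a synthetic dataset: generation,
#' pattern extraction, cross-group reactivation scoring, subsequent-memory
#' searchlight over the default-mode correction set, spatial ISC in both
#' conditions, the ISC subsequent-memory screen and sequential
#' residualization, the residual re-analysis, the no-music control
#' pipeline, and the three condition contrasts. Interpretive choices that
#' the method text leaves open (shuffle unit, pair aggregation, test
#' variant) are logged once per run.
#'
#' @param config a [run_config()].
#' @param dataset optionally, a pre-generated `sim_dataset` (otherwise
#'   `config$sim` is generated).
#' @param out_dir optional directory; when given, stage outputs are written
#'   as TSV/JSON with a provenance block (config, seed, package version).
#' @return named list with every stage's result.
#' @export
run_pipeline <- function(config = run_config(), dataset = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  inform(c("interpretive choices for this run:",
           "*" = "null shuffle permutes earlier-scene identities among all repeated-music scenes, within participant and parcel",
           "*" = "pair-level z values are averaged per cued earlier scene",
           "*" = sprintf("remembered-vs-forgotten tests are %s", config$test)))
  dataset <- dataset %||% simulate_dataset(config$sim)
  meta <- dataset$parcel_meta
  dmn <- meta$parcel_id[meta$network %in% config$dmn_networks]
  recall <- dataset$recall

  pp <- pool_patterns(dataset, lag_s = config$lag_s)
  react <- reactivation_scores(pp, n_perm = config$n_perm,
                               seed = config$seed, mode = "cross_group")
  memory <- searchlight_memory(react, recall, correction_set = dmn,
                               q_threshold = config$q_threshold,
                               test = config$test)
  isc <- spatial_isc(pp, condition = "both")
  isc_effects_pooled <- searchlight_memory(isc, recall, value = "r",
                                           test = config$test)
  screen <- isc_memory_screen(isc[isc$condition == "music", ], recall,
                              p_threshold = config$screen_p,
                              test = config$test)
  residual <- residual_memory(react, recall,
                              isc[isc$condition == "music", ], screen,
                              correction_set = dmn,
                              q_threshold = config$q_threshold,
                              test = config$test)
  control <- reactivation_scores(pp, n_perm = config$n_perm,
                                 seed = config$seed,
                                 mode = "nomusic_control")
  control_memory <- searchlight_memory(control, recall,
                                       correction_set = dmn,
                                       q_threshold = config$q_threshold,
                                       test = config$test)
  zmap <- condition_zmap(react, control, recall, test = config$test)
  contrast_dmn <- parcelwise_condition_contrast(
    zmap[zmap$parcel_id %in% dmn, ])
  contrast_participants <- participant_reliability_contrast(
    react, control, recall, parcel_set = dmn)
  contrast_networks <- network_contrast(zmap, meta)

  result <- list(
    config = config, dataset = dataset,
    reactivation = react, memory = memory,
    isc = isc, isc_effects_pooled = isc_effects_pooled,
    isc_screen = screen, residual = residual,
    control = control, control_memory = control_memory,
    zmap = zmap, contrast_dmn = contrast_dmn,
    contrast_participants = contrast_participants,
    contrast_networks = contrast_networks
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# Serialize the tabular stage outputs plus a provenance sidecar.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- list(reactivation = result$reactivation,
               memory = result$memory,
               isc = result$isc,
               residual_memory = result$residual$effects,
               control_memory = result$control_memory,
               condition_zmap = result$zmap,
               network_contrast = result$contrast_networks)
  for (nm in names(tabs)) {
    readr::write_tsv(tabs[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  cfg <- result$config
  prov <- list(
    package_version = as.character(utils::packageVersion("reverie")),
    seed = cfg$seed, n_perm = cfg$n_perm, lag_s = cfg$lag_s,
    q_threshold = cfg$q_threshold, screen_p = cfg$screen_p,
    test = cfg$test, config_hash = rlang::hash(cfg),
    isc_screen_regions = result$isc_screen$regions,
    contrast_dmn = as.list(result$contrast_dmn[, c("t", "p", "df")]),
    contrast_participants = as.list(
      result$contrast_participants[, c("t", "p", "df")])
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
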