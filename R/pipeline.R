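#' Configuration for an end-to-end pipeline run
#'
#' Collects the stage toggles and per-stage parameters for [run_pipeline()].
#' With `simulate = TRUE` all inputs are generated by the synthetic module;
#' otherwise `tiles` and `clinical` must be paths to CSV files with the same
#' schemas the generator writes.
#'
#' @param out_dir output directory (created if absent).
#' @param seed master seed recorded in the manifest and used by every stage.
#' @param simulate generate inputs with [simulate_cohort()].
#' @param synthetic a [synthetic_config()] used when `simulate = TRUE`.
#' @param tiles,clinical,ratings,signatures optional input CSV paths used
#'   when the corresponding stage runs without simulation.
#' @param stages character vector of stages to run, any of `"cluster"`,
#'   `"compose"`, `"subtype"`, `"survive"`, `"agree"`, `"associate"`.
#' @param subsample,knn_k,resolutions,target_clusters clustering settings
#'   (see [fit_hpc_model()]).
#' @param assign_m neighbours for [assign_remaining()].
#' @param min_tiles,presence_threshold composition settings.
#' @param folds cross-validation folds for subtype and survival.
#' @param horizon_months Kaplan-Meier display horizon.
#' @param association_method,association_mode,association_alpha settings for
#'   [correlate()] and [filter_and_adjust()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = TRUE,
                            synthetic = synthetic_config(seed = seed),
                            tiles = NULL, clinical = NULL, ratings = NULL,
                            signatures = NULL,
                            stages = c("cluster", "compose", "subtype",
                                       "survive"),
                            subsample = 5000L, knn_k = 15L,
                            resolutions = c(0.5, 1, 1.5, 2),
                            target_clusters = NULL,
                            assign_m = 25L, min_tiles = 100L,
                            presence_threshold = 0.01, folds = 5L,
                            horizon_months = 60,
                            association_method = "pearson",
                            association_mode = "raw_threshold",
                            association_alpha = NULL) {
  cfg <- as.list(environment())
  known <- c("cluster", "compose", "subtype", "survive", "agree", "associate")
  if (length(stages) && !all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

write_stage_csv <- function(df, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".csv"))
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the HPC analysis pipeline end to end
#'
#' Executes the enabled stages in order — simulate, cluster, compose,
#' subtype, survive, agree, associate — writing each stage's tables as CSV
#' into `out_dir` together with a JSON manifest (package version, seed,
#' configuration fingerprint, stage outputs). Reruns with an identical
#' configuration reproduce the outputs byte-for-byte. A stage failure aborts
#' the run with the stage name in the error message.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of in-memory stage results plus `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  # validate referenced files before any compute
  for (input in c("tiles", "clinical", "ratings", "signatures")) {
    p <- config[[input]]
    if (!is.null(p) && !file.exists(p)) {
      stop("input file for '", input, "' not found: ", p)
    }
  }
  needs_clinical <- any(c("subtype", "survive") %in% config$stages)
  if (needs_clinical && !config$simulate && is.null(config$clinical)) {
    stop("stages subtype/survive need a clinical table (or simulate = TRUE)")
  }
  if (any(c("cluster", "compose") %in% config$stages) &&
      !config$simulate && is.null(config$tiles)) {
    stop("stages cluster/compose need a tile table (or simulate = TRUE)")
  }

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  result <- list()
  outputs <- list()

  truth <- NULL
  if (config$simulate) {
    sim <- run_stage("simulate", simulate_cohort(config$synthetic))
    tiles <- sim$tiles
    clinical <- sim$patients
    truth <- sim$truth
    outputs$tiles <- write_stage_csv(tiles, config$out_dir, "tiles")
    outputs$clinical <- write_stage_csv(clinical, config$out_dir, "clinical")
    result$truth <- truth
  } else {
    tiles <- if (!is.null(config$tiles)) read.csv(config$tiles) else NULL
    clinical <- if (!is.null(config$clinical)) read.csv(config$clinical) else NULL
  }

  assignment <- NULL
  if ("cluster" %in% config$stages) {
    run <- run_stage("cluster", {
      model <- fit_hpc_model(tiles, subsample = config$subsample,
                             k = config$knn_k,
                             resolutions = config$resolutions,
                             target_clusters = config$target_clusters,
                             seed = config$seed)
      emb <- as.matrix(tiles[grep("^e[0-9]+$", names(tiles))])
      rownames(emb) <- tiles$tile_id
      hpc <- assign_remaining(model, emb, m = config$assign_m)
      list(model = model, assignment = data.frame(
        tile_id = tiles$tile_id, slide_id = tiles$slide_id,
        patient_id = tiles$patient_id, hpc = unname(hpc)))
    })
    result$model <- run$model
    assignment <- run$assignment
    outputs$assignments <- write_stage_csv(assignment, config$out_dir,
                                           "assignments")
    outputs$resolution_sweep <- write_stage_csv(run$model$sweep,
                                                config$out_dir,
                                                "resolution_sweep")
  }

  if ("compose" %in% config$stages) {
    run <- run_stage("compose", {
      if (is.null(assignment)) stop("compose requires the cluster stage")
      c <- result$model$n_clusters
      slide <- compute_composition(assignment, "slide", c,
                                   min_tiles = config$min_tiles)
      patient <- compute_composition(assignment, "patient", c,
                                     min_tiles = config$min_tiles)
      list(slide = slide, patient = patient,
           prevalence = presence_prevalence(patient, config$presence_threshold),
           clr_slide = composition_clr(slide),
           clr_patient = composition_clr(patient))
    })
    result$composition <- run
    outputs$composition_patient <- write_stage_csv(
      data.frame(sample_id = rownames(run$patient$proportions),
                 n_tiles = unname(run$patient$n_tiles),
                 run$patient$proportions, check.names = FALSE),
      config$out_dir, "composition_patient")
    outputs$clr_patient <- write_stage_csv(
      data.frame(sample_id = rownames(run$clr_patient), run$clr_patient,
                 check.names = FALSE),
      config$out_dir, "clr_patient")
    outputs$prevalence <- write_stage_csv(run$prevalence, config$out_dir,
                                          "prevalence")
  }

  clr_patient <- if (!is.null(result$composition)) {
    result$composition$clr_patient
  } else NULL

  if ("subtype" %in% config$stages) {
    run <- run_stage("subtype", {
      if (is.null(clr_patient)) stop("subtype requires the compose stage")
      idx <- match(rownames(clr_patient), clinical$patient_id)
      y <- binarize_subtype(clinical[idx, ])
      cv <- cross_validate_subtype(clr_patient, y, folds = config$folds,
                                   seed = config$seed)
      fit <- fit_subtype(clr_patient, y)
      list(cv = cv, fit = fit)
    })
    result$subtype <- run
    outputs$subtype_metrics <- write_stage_csv(run$cv$per_fold,
                                               config$out_dir,
                                               "subtype_metrics")
    outputs$subtype_coefficients <- write_stage_csv(run$fit$coef_table,
                                                    config$out_dir,
                                                    "subtype_coefficients")
  }

  if ("survive" %in% config$stages) {
    run <- run_stage("survive", {
      if (is.null(clr_patient)) stop("survive requires the compose stage")
      idx <- match(rownames(clr_patient), clinical$patient_id)
      time <- clinical$time_months[idx]
      event <- clinical$event[idx]
      cv <- cross_validate_cox(clr_patient, time, event,
                               folds = config$folds, seed = config$seed)
      fit <- fit_cox(clr_patient, time, event)
      km <- km_logrank(cv$held_out$group, cv$held_out$time,
                       cv$held_out$event,
                       horizon_months = config$horizon_months)
      list(cv = cv, fit = fit, km = km)
    })
    result$survival <- run
    outputs$cox_coefficients <- write_stage_csv(run$fit$coef_table,
                                                config$out_dir,
                                                "cox_coefficients")
    outputs$risk_groups <- write_stage_csv(run$cv$held_out, config$out_dir,
                                           "risk_groups")
    outputs$cindex <- write_stage_csv(run$cv$per_fold, config$out_dir,
                                      "cindex")
  }

  if ("agree" %in% config$stages) {
    run <- run_stage("agree", {
      tab <- if (!is.null(config$ratings)) {
        as.matrix(read.csv(config$ratings, row.names = 1))
      } else {
        simulate_ratings(47L, 3L, 3L, config$synthetic$agreement_level,
                         seed = config$seed)
      }
      list(consensus = majority_consensus(tab), kappa = fleiss_kappa(tab))
    })
    result$agreement <- run
    outputs$consensus <- write_stage_csv(run$consensus, config$out_dir,
                                         "consensus")
    outputs$kappa <- write_stage_csv(
      data.frame(kappa = run$kappa$kappa, P_bar = run$kappa$P_bar,
                 Pe_bar = run$kappa$Pe_bar, n_items = run$kappa$n_items,
                 n_raters = run$kappa$n_raters),
      config$out_dir, "kappa")
  }

  if ("associate" %in% config$stages) {
    run <- run_stage("associate", {
      if (is.null(clr_patient)) stop("associate requires the compose stage")
      sig <- if (!is.null(config$signatures)) {
        as.matrix(read.csv(config$signatures, row.names = 1))
      } else {
        if (is.null(truth)) stop("associate needs a signature file or simulate = TRUE")
        simulate_signatures(clinical, truth, n_signatures = 10L,
                            linked = data.frame(signature = 1L, hpc = 0L,
                                                rho = 0.6),
                            seed = config$seed)
      }
      res <- correlate(clr_patient, sig, method = config$association_method)
      filter_and_adjust(res, config$association_mode,
                        config$association_alpha)
    })
    result$association <- run
    outputs$associations <- write_stage_csv(run, config$out_dir,
                                            "associations")
  }

  cfg_plain <- config[setdiff(names(config), "synthetic")]
  cfg_plain$synthetic <- unclass(config$synthetic)
  # fingerprint the analysis parameters, not the output location
  cfg_json <- jsonlite::toJSON(cfg_plain[setdiff(names(cfg_plain), "out_dir")],
                               auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(
    package = "hplearn",
    version = as.character(utils::packageVersion("hplearn")),
    seed = config$seed,
    config = cfg_plain,
    config_hash = fnv1a(as.character(cfg_json)),
    stages = config$stages,
    outputs = outputs
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  result$manifest <- manifest
  invisible(result)
}
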