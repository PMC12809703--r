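pipeline_known_keys <- c("seed", "stages", "synth", "inputs", "ees",
                         "penalty", "optimize", "consensus", "predict")

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON file path")
  unknown <- setdiff(names(config), pipeline_known_keys)
  if (length(unknown)) {
    stop("unknown config key '", unknown[1], "' (known: ",
         paste(pipeline_known_keys, collapse = ", "), ")")
  }
  config
}

take <- function(lst, defaults) {
  if (is.null(lst)) return(defaults)
  unknown <- setdiff(names(lst), names(defaults))
  if (length(unknown)) stop("unknown config key '", unknown[1], "'")
  modifyList(defaults, lst)
}

#' Run the full prediction pipeline from a config
#'
#' Executes the requested stages in order: `synth` (or loading of provided
#' input CSVs), `compute_ees`, `penalty`, `optimize`, `rank`, `consensus`,
#' `predict`. Each stage writes its artifacts under `out_dir`, and a run
#' manifest (`manifest.json`) records the config snapshot, seeds, input file
#' digests, artifact paths and a timestamp. Failures stop the pipeline with
#' a stage-labeled error. Identical configs and seeds reproduce identical
#' artifacts (the manifest differs only in its timestamp).
#'
#' @param config A named list or path to a YAML/JSON file. Keys: `seed`;
#'   `stages` (character vector, default inferred); `synth` (fixture
#'   settings, see [fixture_config()]); `inputs` (`descriptors`,
#'   `chromatograms` CSV paths, alternative to `synth`); `ees` (overrides
#'   for [ees_params()]); `penalty` (`candidates`, `target_rate`);
#'   `optimize` (`population`, `iterations`, `runs`, `max_epochs`,
#'   `patience`, `learning_rate`, `w`, `p_overfit`); `consensus` (`top_k`,
#'   `rank_subset`); `predict` (`descriptors` CSV path, or `"self"` to
#'   predict the training compounds).
#' @param out_dir Artifact directory (created).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  config <- read_config(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  say <- function(...) if (!quiet) message("[ees-profile] ", ...)

  # parse and validate every config section before touching the filesystem
  params <- do.call(ees_params, take(config$ees, formals_defaults(ees_params)))
  scfg <- do.call(fixture_config,
                  take(config$synth, formals_defaults(fixture_config)))
  if (is.null(config$synth$seed)) scfg$seed <- seed
  pcfg <- take(config$penalty, list(candidates = 1:100, target_rate = 0.02))
  ocfg <- take(config$optimize,
               list(population = 250L, iterations = 500L, runs = 70L,
                    max_epochs = 500L, patience = 20L, learning_rate = 0.02,
                    w = 0.5, p_overfit = 2))
  ccfg <- take(config$consensus, list(top_k = 5L, rank_subset = "all"))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  input_digests <- list()
  add_artifact <- function(p) artifacts <<- c(artifacts, p)

  stages <- config$stages
  if (is.null(stages)) {
    stages <- c(if (is.null(config$inputs)) "synth",
                "compute_ees",
                if (!is.null(config$penalty)) "penalty",
                if (!is.null(config$optimize)) c("optimize", "rank",
                                                "consensus"),
                if (!is.null(config$predict)) "predict")
  }

  descriptors <- NULL; records <- NULL; target <- NULL
  archive <- NULL; ranking <- NULL; cmodel <- NULL

  run_stage <- function(stage, expr) {
    say("stage: ", stage)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if ("synth" %in% stages) {
    run_stage("synth", {
      ds <- generate_dataset(scfg, params, dir = file.path(out_dir, "fixtures"))
      descriptors <- ds$descriptors
      records <- ds$chromatograms
      add_artifact(file.path(out_dir, "fixtures",
                             c("descriptors.csv", "chromatograms.csv",
                               "target.csv", "ground_truth.json")))
    })
  } else if (!is.null(config$inputs)) {
    run_stage("load_inputs", {
      for (p in unlist(config$inputs)) {
        if (!file.exists(p)) stop("input file not found: ", p)
        input_digests[[p]] <- unname(tools::md5sum(p))
      }
      descriptors <- read_matrix(config$inputs$descriptors, "descriptor")
      records <- read_matrix(config$inputs$chromatograms, "chromatogram")
    })
  }

  if ("compute_ees" %in% stages) {
    run_stage("compute_ees", {
      if (is.null(records)) stop("no chromatographic records available")
      target <- build_target_matrix(records, params)
      p <- file.path(out_dir, "target.csv")
      write_matrix(target, p, "target")
      add_artifact(p)
    })
  }

  if ("penalty" %in% stages) {
    run_stage("penalty", {
      rep45 <- simulate_false_positive_rate(params$p, params, "enumerate")
      chosen <- select_penalty_factor(pcfg$candidates, pcfg$target_rate,
                                      params)
      p <- file.path(out_dir, "penalty.json")
      jsonlite::write_json(
        list(configured_p = params$p,
             rate_percent_at_configured_p = rep45$rate_percent,
             selected_p = chosen, target_rate_percent = pcfg$target_rate),
        p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      add_artifact(p)
    })
  }

  if ("optimize" %in% stages) {
    run_stage("optimize", {
      if (is.null(target)) stop("no target matrix available")
      archive <- run_batch(
        descriptors, target, n_runs = ocfg$runs, base_seed = seed,
        cfg = optimizer_config(population = ocfg$population,
                               iterations = ocfg$iterations, seed = seed),
        train_cfg = training_config(max_epochs = ocfg$max_epochs,
                                    patience = ocfg$patience,
                                    learning_rate = ocfg$learning_rate,
                                    seed = seed),
        weights = objective_weights(w = ocfg$w, p_overfit = ocfg$p_overfit),
        params = params)
      save_archive(archive, file.path(out_dir, "models"))
      add_artifact(file.path(out_dir, "models", "archive.json"))
    })
  }

  if ("rank" %in% stages) {
    run_stage("rank", {
      ranking <- rank_models(archive, subset = ccfg$rank_subset)
      p <- file.path(out_dir, "ranking.csv")
      write.csv(ranking$table, p, row.names = FALSE, quote = FALSE)
      add_artifact(p)
    })
  }

  if ("consensus" %in% stages) {
    run_stage("consensus", {
      cmodel <- build_consensus(ranking, k = ccfg$top_k, params = params)
      p <- file.path(out_dir, "consensus.json")
      jsonlite::write_json(
        list(top_k = ccfg$top_k, rank_subset = ccfg$rank_subset,
             member_model_ids = ranking$table$model_id[seq_len(ccfg$top_k)]),
        p, auto_unbox = TRUE, pretty = TRUE)
      add_artifact(p)
    })
  }

  if ("predict" %in% stages) {
    run_stage("predict", {
      px <- config$predict
      x_new <- if (is.null(px) || identical(px$descriptors, "self")) {
        descriptors
      } else {
        input_digests[[px$descriptors]] <-
          unname(tools::md5sum(px$descriptors))
        read_matrix(px$descriptors, "descriptor")
      }
      profiles <- consensus_predict(cmodel, x_new)
      p <- file.path(out_dir, "profiles.csv")
      write.csv(profiles, p, row.names = FALSE, quote = FALSE)
      add_artifact(p)
    })
  }

  manifest <- list(
    command = "run_pipeline",
    package_version = as.character(utils::packageVersion("eesprofiler")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    stages = stages,
    config = config,
    input_digests = input_digests,
    artifacts = artifacts,
    artifact_digests = as.list(setNames(unname(tools::md5sum(artifacts)),
                                        artifacts))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  say("done: ", out_dir)
  invisible(manifest)
}

formals_defaults <- function(fn) {
  fm <- formals(fn)
  fm <- fm[!vapply(fm, is.symbol, logical(1))]
  lapply(fm, eval, envir = environment(fn))
}
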