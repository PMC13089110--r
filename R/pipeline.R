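# Pipeline orchestration: simulate -> classify -> clocks -> harmonize ->
# comet -> analyze, each stage reading and writing CSV tables in a run
# directory and appending a provenance entry (stage, parameters, seed,
# input/output md5 hashes) to the run manifest.  The manifest carries no
# timestamps, so identical config + seed yields byte-identical run
# directories.

PIPELINE_STAGES <- c("simulate", "classify", "clocks", "harmonize",
                     "comet", "analyze")

#' Pipeline configuration
#'
#' @param synthetic a [synthetic_config()] (or argument list) for the
#'   simulate stage; ignored when `input_dir` points at existing tables.
#' @param input_dir optional directory with pre-existing
#'   `participants.csv`, `roi.csv`, `amyloid.csv`, `methylation.csv` and
#'   `clocks/` instead of simulation.
#' @param thresholds amyloid cutoffs, default
#'   [default_amyloid_thresholds()].
#' @param k SD multiplier for biological age groups (> 0).
#' @param bag_cohort which participants enter the BAG regression:
#'   `"all"` (everyone with methylation, the default) or `"per_cohort"`
#'   (fit separately within CU and symptomatic).
#' @param clock_files optional character vector of clock coefficient CSV
#'   paths; default uses the clocks found in the run directory.
#' @param roi_sets ROI definition.
#' @param seed top-level seed; all stage randomness derives from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            input_dir = NULL,
                            thresholds = default_amyloid_thresholds(),
                            k = 0.5,
                            bag_cohort = c("all", "per_cohort"),
                            clock_files = NULL,
                            roi_sets = default_roi_sets(),
                            seed = 1L) {
  if (!inherits(synthetic, "synthetic_config")) {
    synthetic <- do.call(synthetic_config, as.list(synthetic))
  }
  if (!is.numeric(k) || k <= 0) {
    cb_stop("invalid configuration field `k`", "cometbag_config_error")
  }
  bag_cohort <- match.arg(bag_cohort)
  if (!is.null(clock_files)) {
    absent <- clock_files[!file.exists(clock_files)]
    if (length(absent) > 0) {
      cb_stop(paste("clock file(s) not found:", paste(absent, collapse = ", ")),
              "cometbag_config_error")
    }
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    cb_stop(paste("input_dir not found:", input_dir), "cometbag_config_error")
  }
  structure(list(synthetic = synthetic, input_dir = input_dir,
                 thresholds = thresholds, k = k, bag_cohort = bag_cohort,
                 clock_files = clock_files, roi_sets = roi_sets,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `synthetic` (a mapping of
#' [synthetic_config()] arguments), `thresholds`, `k`, `bag_cohort`,
#' `clock_files`, `roi_sets`, `seed`, `input_dir`.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    cb_stop(paste("config file not found:", path), "cometbag_config_error")
  }
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$synthetic)) args$synthetic <- do.call(synthetic_config, y$synthetic)
  if (!is.null(y$thresholds)) args$thresholds <- unlist(y$thresholds)
  for (f in c("input_dir", "k", "bag_cohort", "clock_files", "seed")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  if (!is.null(y$roi_sets)) args$roi_sets <- lapply(y$roi_sets, as.character)
  do.call(pipeline_config, args)
}

run_path <- function(dir, ...) file.path(dir, ...)

manifest_add <- function(dir, stage, params, seed, inputs, outputs) {
  mpath <- run_path(dir, "manifest.json")
  manifest <- if (file.exists(mpath)) {
    jsonlite::read_json(mpath, simplifyVector = FALSE)
  } else list()
  hash <- function(paths) {
    paths <- paths[file.exists(paths)]
    h <- tools::md5sum(paths)
    # store run-relative paths so run directories are byte-identical
    # across locations
    names(h) <- sub(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", dir),
                           "/?"), "", names(h))
    as.list(h)
  }
  manifest[[stage]] <- list(stage = stage, params = params, seed = seed,
                            inputs = hash(inputs), outputs = hash(outputs))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Run one pipeline stage in a run directory
#'
#' @param stage one of `simulate`, `classify`, `clocks`, `harmonize`,
#'   `comet`, `analyze`.
#' @param dir run directory.
#' @param config a [pipeline_config()].
#' @return Invisibly, the paths written by the stage.
#' @export
run_stage <- function(stage, dir, config = pipeline_config()) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fn <- switch(stage,
    simulate = stage_simulate, classify = stage_classify,
    clocks = stage_clocks, harmonize = stage_harmonize,
    comet = stage_comet, analyze = stage_analyze)
  out <- tryCatch(fn(dir, config), error = function(e) {
    cb_stop(paste0("stage `", stage, "` failed: ", conditionMessage(e)),
            "cometbag_stage_error")
  })
  invisible(out)
}

stage_simulate <- function(dir, config) {
  if (!is.null(config$input_dir)) {
    # copy external inputs into the run directory for provenance
    files <- c("participants.csv", "roi.csv", "amyloid.csv", "methylation.csv")
    for (f in files) {
      src <- file.path(config$input_dir, f)
      if (!file.exists(src)) {
        cb_stop(paste("input table not found:", src), "cometbag_input_error")
      }
      file.copy(src, run_path(dir, f), overwrite = TRUE)
    }
    cdir <- file.path(config$input_dir, "clocks")
    dir.create(run_path(dir, "clocks"), showWarnings = FALSE)
    for (f in list.files(cdir, full.names = TRUE)) {
      file.copy(f, run_path(dir, "clocks", basename(f)), overwrite = TRUE)
    }
    outs <- run_path(dir, files)
  } else {
    scfg <- config$synthetic
    cohort <- generate_cohort(scfg, roi_sets = config$roi_sets)
    clocks <- generate_clock_data(cohort$participants, cohort$truth, scfg)
    write_table(cohort$participants, run_path(dir, "participants.csv"))
    write_table(cohort$roi, run_path(dir, "roi.csv"))
    write_table(cohort$amyloid, run_path(dir, "amyloid.csv"))
    write_methylation(clocks$betas, run_path(dir, "methylation.csv"))
    dir.create(run_path(dir, "clocks"), showWarnings = FALSE)
    for (cl in clocks$clocks) {
      write_clock_model(cl, run_path(dir, "clocks",
                                     paste0("clock_", cl$name, ".csv")))
    }
    write_truth(clocks$truth, run_path(dir, "truth.json"))
    outs <- run_path(dir, c("participants.csv", "roi.csv", "amyloid.csv",
                            "methylation.csv", "truth.json"))
  }
  manifest_add(dir, "simulate", params = unclass(config$synthetic),
               seed = config$seed, inputs = character(0), outputs = outs)
  outs
}

stage_classify <- function(dir, config) {
  participants <- read_table(run_path(dir, "participants.csv"))
  amyloid <- read_table(run_path(dir, "amyloid.csv"))
  stop_on_invalid(list(participants = participants, amyloid = amyloid),
                  config$roi_sets)
  status <- classify_amyloid_table(amyloid, ids = participants$id,
                                   thresholds = config$thresholds)
  labels <- assign_cohort(participants, status)
  labels$age_group <- as.character(age_group(participants$age_at_mri))
  out <- run_path(dir, "cohort_labels.csv")
  write_table(labels, out)
  manifest_add(dir, "classify", params = as.list(config$thresholds),
               seed = config$seed,
               inputs = run_path(dir, c("participants.csv", "amyloid.csv")),
               outputs = out)
  out
}

stage_clocks <- function(dir, config) {
  participants <- read_table(run_path(dir, "participants.csv"))
  betas <- read_methylation(run_path(dir, "methylation.csv"))
  stop_on_invalid(list(participants = participants, methylation = betas),
                  config$roi_sets)
  clock_paths <- config$clock_files %||%
    list.files(run_path(dir, "clocks"), pattern = "\\.csv$", full.names = TRUE)
  if (length(clock_paths) == 0) {
    cb_stop("no clock coefficient files found", "cometbag_input_error")
  }
  clocks <- lapply(clock_paths, read_clock_model)
  ages <- stats::setNames(participants$age_at_mri, participants$id)
  seed <- derive_seed(config$seed, "replicate_selection")
  if (config$bag_cohort == "all") {
    bag <- compute_bag_table(betas, clocks, ages, k = config$k, seed = seed)
  } else {
    labels <- read_table(run_path(dir, "cohort_labels.csv"))
    pid <- sub("_r[0-9]+$", "", rownames(betas))
    coh <- labels$cohort[match(pid, labels$participant_id)]
    parts <- lapply(unique(coh), function(cc) {
      compute_bag_table(betas[coh == cc, , drop = FALSE], clocks, ages,
                        k = config$k, seed = seed)
    })
    bag <- do.call(rbind, parts)
  }
  out <- run_path(dir, "bag.csv")
  write_table(bag, out)
  manifest_add(dir, "clocks",
               params = list(k = config$k, bag_cohort = config$bag_cohort),
               seed = seed,
               inputs = c(run_path(dir, c("participants.csv", "methylation.csv")),
                          clock_paths),
               outputs = out)
  out
}

stage_harmonize <- function(dir, config) {
  participants <- read_table(run_path(dir, "participants.csv"))
  roi <- read_table(run_path(dir, "roi.csv"))
  labels <- read_table(run_path(dir, "cohort_labels.csv"))
  stop_on_invalid(list(participants = participants, roi = roi),
                  config$roi_sets)
  covs <- participants[match(roi$participant_id, participants$id),
                       c("age_at_mri", "sex", "diagnosis")]
  names(covs)[1] <- "age"
  cu_rows <- roi$participant_id %in%
    labels$participant_id[labels$cohort == "CU"]
  if (sum(cu_rows) < 4) {
    cb_stop("too few CU reference rows to fit harmonization",
            "cometbag_fit_error")
  }
  feats <- intersect(roi_all_columns(config$roi_sets), names(roi))
  model <- fit_combat(roi[cu_rows, feats, drop = FALSE],
                      covs[cu_rows, , drop = FALSE],
                      roi$batch[cu_rows])
  harmonized <- roi
  harmonized[, feats] <- apply_combat(model, roi[, feats, drop = FALSE],
                                      covs, roi$batch)
  outs <- run_path(dir, c("roi_harmonized.csv", "combat_model.json"))
  write_table(harmonized, outs[1])
  write_combat_model(model, outs[2])
  manifest_add(dir, "harmonize", params = list(batch = "scanner_field"),
               seed = config$seed,
               inputs = run_path(dir, c("participants.csv", "roi.csv",
                                        "cohort_labels.csv")),
               outputs = outs)
  outs
}

stage_comet <- function(dir, config) {
  participants <- read_table(run_path(dir, "participants.csv"))
  roi <- read_table(run_path(dir, "roi_harmonized.csv"))
  labels <- read_table(run_path(dir, "cohort_labels.csv"))
  covs <- participants[match(roi$participant_id, participants$id),
                       c("age_at_mri", "sex", "icv")]
  names(covs)[1] <- "age"
  cu_rows <- roi$participant_id %in%
    labels$participant_id[labels$cohort == "CU"]
  models <- fit_comet_models(roi[cu_rows, , drop = FALSE],
                             covs[cu_rows, , drop = FALSE],
                             roi_sets = config$roi_sets)
  comet <- compute_comet(roi, covs, models, roi_sets = config$roi_sets)
  out <- run_path(dir, "comet.csv")
  write_table(comet, out)
  manifest_add(dir, "comet", params = list(reference = "CU"),
               seed = config$seed,
               inputs = run_path(dir, c("participants.csv",
                                        "roi_harmonized.csv",
                                        "cohort_labels.csv")),
               outputs = out)
  out
}

stage_analyze <- function(dir, config) {
  participants <- read_table(run_path(dir, "participants.csv"))
  comet <- read_table(run_path(dir, "comet.csv"))
  bag <- read_table(run_path(dir, "bag.csv"))
  labels <- read_table(run_path(dir, "cohort_labels.csv"))
  analysis <- run_primary_analysis(comet, bag, labels, participants)
  descriptives <- describe_cohorts(participants, labels, bag)
  outs <- run_path(dir, c("analysis.csv", "descriptives.csv", "summary.txt"))
  write_table(analysis$table, outs[1])
  write_table(descriptives, outs[2])
  writeLines(format_analysis_summary(analysis), outs[3])
  manifest_add(dir, "analyze", params = list(), seed = config$seed,
               inputs = run_path(dir, c("participants.csv", "comet.csv",
                                        "bag.csv", "cohort_labels.csv")),
               outputs = outs)
  outs
}

#' Run the full pipeline
#'
#' Executes the stages in order in `outdir`.  Any stage error halts the
#' run with a stage-named condition.  Identical config + seed produces a
#' byte-identical run directory.
#'
#' @param config a [pipeline_config()].
#' @param outdir run directory (created if needed).
#' @param stages subset of stages to run, in pipeline order.
#' @return Invisibly, a list with the run directory, the analysis object
#'   (when the analyze stage ran) and the manifest path.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(synthetic_config(n_cu = 40, n_mci = 20,
#'                                         n_dementia = 20, seed = 7))
#' res <- run_pipeline(cfg, outdir = tempfile("run"))
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         stages = PIPELINE_STAGES) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (s in PIPELINE_STAGES[PIPELINE_STAGES %in% stages]) {
    message("stage: ", s)
    run_stage(s, outdir, config)
  }
  analysis <- NULL
  if ("analyze" %in% stages) {
    tab <- read_table(run_path(outdir, "analysis.csv"))
    analysis <- tab
  }
  invisible(list(dir = outdir, analysis = analysis,
                 manifest = run_path(outdir, "manifest.json")))
}
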