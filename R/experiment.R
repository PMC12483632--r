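# Experiment orchestration: one configuration -> split, train, evaluate,
# artifacts on disk, and a machine-readable runs ledger mirroring the
# published experiment-grid columns (model, architecture, optimizer,
# shot, task, accuracy, loss, F1 score).

#' Experiment run configuration
#'
#' Validates and normalizes everything one training/evaluation run needs.
#' Presets resolve to the four tested shot-task configurations; explicit
#' `shotTask` values override the preset.
#'
#' @param bank bank root directory, manifest path, or an
#'   [ImageBank-class].
#' @param outDir output directory for run artifacts.
#' @param regime `"fssl"` or `"maml"`.
#' @param backbone backbone name (default `"standin"`).
#' @param headVariant `"complex"` or `"baseline"`.
#' @param preset shot-task preset name (see [shotTaskPreset()]); default
#'   chosen from the regime.
#' @param shotTask optional explicit [shotTaskConfig()] overriding the
#'   preset.
#' @param optimizer an [optimizerSpec()]; for MAML this is the meta
#'   optimizer.
#' @param earlyStop,lrSchedule training control specs.
#' @param innerLr,innerSteps MAML inner-loop hyperparameters.
#' @param augment logical; online augmentation of training images.
#' @param inputSide stand-in backbone input side.
#' @param maxEpochs epoch cap.
#' @param seed global seed; all derived streams (split, samplers,
#'   initialisation, augmentation) come from it.
#' @return an object of class `RunConfig`.
#' @export
runConfig <- function(bank, outDir, regime = c("fssl", "maml"),
                      backbone = "standin", headVariant = "complex",
                      preset = NULL, shotTask = NULL,
                      optimizer = optimizerSpec("adam", 1e-3),
                      earlyStop = earlyStopSpec(),
                      lrSchedule = lrScheduleSpec(),
                      innerLr = 0.01, innerSteps = 1L,
                      augment = TRUE, inputSide = 64L, maxEpochs = 100L,
                      seed = 1) {
  regime <- match.arg(regime)
  headVariant <- match.arg(headVariant, c("complex", "baseline"))
  backbone <- match.arg(backbone, names(.backboneTable))
  stopifnot(inherits(optimizer, "OptimizerSpec"))
  preset <- preset %||% if (regime == "fssl") "fssl-low" else "maml-low"
  shotTask <- shotTask %||% shotTaskPreset(preset)
  if (regime == "maml" && is.null(shotTask$qQuery)) {
    stop("MAML requires a shot-task configuration with qQuery", call. = FALSE)
  }
  structure(list(bank = bank, outDir = outDir, regime = regime,
                 backbone = backbone, headVariant = headVariant,
                 preset = preset, shotTask = shotTask,
                 optimizer = optimizer, earlyStop = earlyStop,
                 lrSchedule = lrSchedule, innerLr = innerLr,
                 innerSteps = as.integer(innerSteps),
                 augment = isTRUE(augment),
                 inputSide = as.integer(inputSide),
                 maxEpochs = as.integer(maxEpochs),
                 seed = as.integer(seed)),
            class = "RunConfig")
}

runId <- function(config) {
  key <- paste(config$regime, config$backbone, config$headVariant,
               config$preset, config$optimizer$kind,
               config$optimizer$learningRate, config$shotTask$kShot,
               config$shotTask$nTasks, config$maxEpochs, config$augment,
               sep = "|")
  sprintf("%s-%s-%s-seed%d-%s", config$regime, config$backbone,
          config$headVariant, config$seed, hashString(key))
}

#' Execute one experiment run
#'
#' Loads (or accepts) the bank, performs the stratified split, trains
#' under the configured regime, evaluates on the held-out test split, and
#' writes artifacts under `<outDir>/<runId>`: `history.csv`,
#' `report.tsv`, `confusion.csv`, `split.csv`, `checkpoint.rds`, and a row
#' appended to `<outDir>/runs.tsv` (columns model, architecture,
#' optimizer, shot, task, accuracy, loss, F1, plus run id and seed).
#' Identical configuration and seed reproduce identical ledger rows.
#'
#' @param config a [runConfig()].
#' @param verbose print per-epoch progress.
#' @return list with `model`, `history`, `evaluation`, `summary` (the
#'   ledger row) and `dir`.
#' @export
runExperiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  bank <- if (is(config$bank, "ImageBank")) config$bank else
    loadBank(config$bank)
  id <- runId(config)
  dir <- file.path(config$outDir, id)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  splits <- stratifiedSplit(bank, splitSpec(seed = deriveSeed(config$seed, "split")))
  writeSplit(splits, file.path(dir, "split.csv"))
  model <- buildClassifier(config$backbone, config$headVariant,
                           inputSide = config$inputSide,
                           seed = deriveSeed(config$seed, "init"))
  if (config$regime == "fssl") {
    fit <- trainFSSL(model, splits$train, splits$val,
                     shotTask = config$shotTask, optimizer = config$optimizer,
                     earlyStop = config$earlyStop,
                     lrSchedule = config$lrSchedule,
                     augment = config$augment, maxEpochs = config$maxEpochs,
                     seed = config$seed, verbose = verbose)
    ev <- evaluateModel(fit$model, splits$test)
  } else {
    cfg <- mamlConfig(innerLr = config$innerLr,
                      innerSteps = config$innerSteps,
                      metaOptimizer = config$optimizer,
                      shotTask = config$shotTask)
    fit <- trainMAML(model, splits$train, splits$val, config = cfg,
                     earlyStop = config$earlyStop,
                     lrSchedule = config$lrSchedule,
                     augment = config$augment, maxEpochs = config$maxEpochs,
                     seed = config$seed, verbose = verbose)
    ev <- evaluateModel(fit$model, splits$test, adaptBank = splits$train,
                        shotTask = config$shotTask,
                        innerLr = config$innerLr,
                        innerSteps = config$innerSteps,
                        seed = config$seed)
  }
  write.csv(fit$history, file.path(dir, "history.csv"), row.names = FALSE)
  writeLines(renderReport(ev$report, "tsv"), file.path(dir, "report.tsv"))
  writeConfusion(ev$confusion, file.path(dir, "confusion.csv"))
  checkpoint <- list(model = fit$model, config = config, runId = id,
                     classLevels = taxonLevels(),
                     testAccuracy = ev$accuracy)
  saveRDS(checkpoint, file.path(dir, "checkpoint.rds"))
  summary <- data.frame(model = config$backbone,
                        architecture = ifelse(config$headVariant == "baseline",
                                              "simple", "complex"),
                        optimizer = config$optimizer$kind,
                        shot = config$shotTask$kShot,
                        task = config$shotTask$nTasks,
                        accuracy = ev$accuracy, loss = ev$loss,
                        f1 = unname(ev$report@macro["f1"]),
                        regime = config$regime, run_id = id,
                        seed = config$seed, status = "ok",
                        stringsAsFactors = FALSE)
  ledger <- file.path(config$outDir, "runs.tsv")
  utils::write.table(summary, ledger, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !file.exists(ledger),
                     append = file.exists(ledger))
  list(model = fit$model, history = fit$history, evaluation = ev,
       summary = summary, dir = dir)
}

#' Enumerate an experiment grid
#'
#' Cartesian product of configuration axes over a template, mirroring the
#' published experiment grid (e.g. 5 backbones x 3 optimizers x 2 presets
#' x 2 head variants = 60 runs).
#'
#' @param axes named list over a subset of `backbone`, `optimizer`,
#'   `preset`, `headVariant`; each entry a character vector of values.
#' @return data.frame with one row per run and a `run_index` column.
#' @export
gridPlan <- function(axes) {
  allowed <- c("backbone", "optimizer", "preset", "headVariant")
  stopifnot(length(axes) > 0L, all(names(axes) %in% allowed))
  plan <- expand.grid(axes, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  plan$run_index <- seq_len(nrow(plan))
  plan
}

#' Execute an experiment grid sequentially
#'
#' Runs every row of [gridPlan()] applied to a template configuration.
#' Per-run seeds are derived from the template's global seed and the run
#' index. Runs whose id already appears in the ledger are skipped (so a
#' half-completed grid can be resumed), and per-run failures are recorded
#' in the ledger while the grid continues.
#'
#' @param template a [runConfig()] supplying everything the axes do not.
#' @param axes named list of axis values (see [gridPlan()]).
#' @param verbose print progress.
#' @return the runs ledger data.frame.
#' @export
gridRun <- function(template, axes, verbose = FALSE) {
  stopifnot(inherits(template, "RunConfig"))
  plan <- gridPlan(axes)
  ledgerPath <- file.path(template$outDir, "runs.tsv")
  for (i in seq_len(nrow(plan))) {
    cfg <- template
    for (ax in setdiff(names(plan), "run_index")) cfg[[ax]] <- plan[[ax]][i]
    if ("preset" %in% names(plan)) {
      cfg$shotTask <- shotTaskPreset(cfg$preset)
      cfg$regime <- if (startsWith(cfg$preset, "maml")) "maml" else "fssl"
    }
    if ("optimizer" %in% names(plan) && is.character(cfg$optimizer)) {
      cfg$optimizer <- optimizerSpec(cfg$optimizer,
                                     template$optimizer$learningRate)
    }
    cfg$seed <- deriveSeed(template$seed, paste0("grid:", i))
    class(cfg) <- "RunConfig"
    id <- runId(cfg)
    if (file.exists(ledgerPath)) {
      done <- read.delim(ledgerPath, stringsAsFactors = FALSE)
      if (id %in% done$run_id) {
        if (verbose) message("skipping finished run ", id)
        next
      }
    }
    tryCatch(runExperiment(cfg, verbose = verbose), error = function(e) {
      row <- data.frame(model = cfg$backbone, architecture = cfg$headVariant,
                        optimizer = if (is.character(cfg$optimizer))
                          cfg$optimizer else cfg$optimizer$kind,
                        shot = cfg$shotTask$kShot, task = cfg$shotTask$nTasks,
                        accuracy = NA_real_, loss = NA_real_, f1 = NA_real_,
                        regime = cfg$regime, run_id = id, seed = cfg$seed,
                        status = paste0("error: ", conditionMessage(e)),
                        stringsAsFactors = FALSE)
      utils::write.table(row, ledgerPath, sep = "\t", quote = FALSE,
                         row.names = FALSE,
                         col.names = !file.exists(ledgerPath),
                         append = file.exists(ledgerPath))
    })
  }
  read.delim(ledgerPath, stringsAsFactors = FALSE)
}
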