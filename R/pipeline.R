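#' Configuration for an end-to-end enrichment run
#'
#' @param model path to an SBML file, or a [MetabolicModel-class].
#' @param tasks path to a task list file (see [readTaskList()]), or a
#'   character vector of metabolite ids / \code{BBB:<reaction>} directives.
#' @param expression path to a gene expression table (see
#'   [readExpression()]).
#' @param outdir output directory (created if missing).
#' @param mode expression mode, \code{"foldchange"} or \code{"absolute"}.
#' @param mapping optional gene-id mapping file.
#' @param epsilon minimum production flux per task.
#' @param upCutoff,downCutoff,highPct,lowPct regulation thresholds
#'   (mode-dependent; see [regulationSets()]).
#' @param universe \code{"all"} or \code{"valued"}.
#' @param rankBy \code{"up"} or \code{"down"}.
#' @param fdr add Benjamini-Hochberg adjusted columns.
#' @param config an [EnumConfig-class] for the enumeration.
#' @param fva \code{"global"} (default: prune blocked reactions once, over
#'   the whole flux space) or \code{"task"} (re-run FVA with each task's
#'   demand imposed before enumerating that task).
#' @param seed integer seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters only when generated inputs are used).
#' @return a validated run configuration (list).
#' @export
runConfig <- function(model, tasks, expression, outdir,
                      mode = c("foldchange", "absolute"), mapping = NULL,
                      epsilon = 1e-3, upCutoff = NULL, downCutoff = NULL,
                      highPct = NULL, lowPct = NULL,
                      universe = c("all", "valued"),
                      rankBy = c("up", "down"), fdr = FALSE,
                      config = enumConfig(), fva = c("global", "task"),
                      seed = 1L) {
  mode <- match.arg(mode)
  universe <- match.arg(universe)
  rankBy <- match.arg(rankBy)
  fva <- match.arg(fva)
  for (p in c(if (is.character(model)) model,
              if (is.character(tasks) && length(tasks) == 1L &&
                  file.exists(tasks)) tasks,
              expression, mapping))
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  stopifnot(methods::is(config, "EnumConfig"), epsilon > 0)
  list(model = model, tasks = tasks, expression = expression,
       outdir = outdir, mode = mode, mapping = mapping, epsilon = epsilon,
       upCutoff = upCutoff, downCutoff = downCutoff, highPct = highPct,
       lowPct = lowPct, universe = universe, rankBy = rankBy, fdr = fdr,
       config = config, fva = fva, seed = as.integer(seed))
}

#' Run minimal-network enrichment end to end
#'
#' Stages: read the model, flux variability analysis and blocked-reaction
#' pruning, map expression onto reactions and call regulation sets, then per
#' task: add the demand reaction, enumerate alternative minimal networks,
#' score them, and write a ranked tab-delimited report. Per-task failures
#' (unproducible targets, time limits) are logged and recorded in the run
#' summary without aborting the remaining tasks. A machine-readable manifest
#' (JSON: configuration echo, package version, per-task status, wall time)
#' and a \code{run.log} are written alongside.
#'
#' @param cfg a configuration from [runConfig()].
#' @param quiet suppress progress messages to stderr.
#' @return invisibly, a list with \code{status} (per-task data.frame),
#'   \code{reports} (named list of score data.frames) and \code{sets}
#'   (the [RegulationSets-class] used).
#' @export
runEnrichment <- function(cfg, quiet = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(cfg$outdir, "run.log")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon), add = TRUE)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    writeLines(msg, logCon)
    if (!quiet) message(msg)
  }

  model <- if (is.character(cfg$model)) readSBML(cfg$model) else cfg$model
  say("model: %d metabolites, %d reactions", nrow(model@metabolites),
      nrow(model@reactions))
  fvaRes <- runFVA(model)
  pruned <- pruneBlocked(model, fvaRes)
  say("FVA: %d blocked reaction(s) pruned, %d remain",
      sum(fvaRes@blocked), nrow(pruned@reactions))

  profile <- readExpression(cfg$expression, mode = cfg$mode,
                            mapping = cfg$mapping)
  sets <- regulationSets(pruned, profile, upCutoff = cfg$upCutoff,
                         downCutoff = cfg$downCutoff, highPct = cfg$highPct,
                         lowPct = cfg$lowPct, universe = cfg$universe)
  say("regulation sets: N=%d, up/high=%d, down/low=%d",
      length(sets@universe), length(sets@up), length(sets@down))

  taskTab <- if (is.character(cfg$tasks) && length(cfg$tasks) == 1L &&
                 file.exists(cfg$tasks)) readTaskList(cfg$tasks)
             else data.frame(kind = ifelse(startsWith(cfg$tasks, "BBB:"),
                                           "bbb", "metabolite"),
                             id = sub("^BBB:", "", cfg$tasks),
                             stringsAsFactors = FALSE)
  targets <- character()
  for (i in seq_len(nrow(taskTab))) {
    if (taskTab$kind[i] == "bbb")
      targets <- c(targets, extractBBBs(pruned, taskTab$id[i]))
    else targets <- c(targets, taskTab$id[i])
  }
  targets <- unique(targets)
  say("%d task(s): %s", length(targets), paste(targets, collapse = ", "))

  status <- data.frame(task = targets, status = NA_character_,
                       nMins = NA_integer_, sStar = NA_integer_,
                       bestP = NA_real_, stringsAsFactors = FALSE)
  reports <- list()
  for (i in seq_along(targets)) {
    tgt <- targets[i]
    res <- tryCatch({
      base <- pruned
      if (cfg$fva == "task") {
        dt0 <- makeDemandTask(model, tgt, epsilon = cfg$epsilon)
        f <- runFVA(.taskImposed(dt0$model, dt0$task))
        keep <- !f@blocked | f@reaction %in% dt0$model@helpers
        base <- .subsetReactions(dt0$model, keep)
        dt <- makeDemandTask(base, tgt, epsilon = cfg$epsilon)
      } else dt <- makeDemandTask(base, tgt, epsilon = cfg$epsilon)
      mins <- enumerateMins(dt$model, dt$task, cfg$config)
      rep <- scoreMins(mins, sets, rankBy = cfg$rankBy,
                       exclude = dt$model@helpers, fdr = cfg$fdr)
      out <- file.path(cfg$outdir, paste0("task_", .safeName(tgt), ".tsv"))
      writeEnrichment(rep, out)
      list(rep = rep, mins = mins, truncated = attr(mins, "truncated"))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status$status[i] <- conditionMessage(res)
      say("task %s: FAILED (%s)", tgt, conditionMessage(res))
    } else {
      status$status[i] <- if (isTRUE(res$truncated)) "truncated" else "ok"
      status$nMins[i] <- length(res$mins)
      status$sStar[i] <- attr(res$mins, "sStar")
      status$bestP[i] <- if (nrow(res$rep))
        min(if (cfg$rankBy == "up") res$rep$p_up else res$rep$p_down)
        else NA_real_
      reports[[tgt]] <- res$rep
      say("task %s: %d MiN(s), s*=%d, best p=%.4g", tgt, length(res$mins),
          attr(res$mins, "sStar"), status$bestP[i])
    }
  }
  utils::write.table(status, file.path(cfg$outdir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    package = "minnet",
    version = as.character(utils::packageVersion("minnet")),
    config = .manifestConfig(cfg),
    tasks = status,
    wallTimeSec = round(proc.time()[["elapsed"]] - t0, 3),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  say("done in %.2f s", manifest$wallTimeSec)
  invisible(list(status = status, reports = reports, sets = sets))
}

.safeName <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

# model copy with the task's minimum demand imposed (for task-specific FVA)
.taskImposed <- function(model, task) {
  j <- match(task@demand, model@reactions$id)
  model@reactions$lb[j] <- max(model@reactions$lb[j], task@epsilon)
  model
}

.manifestConfig <- function(cfg) {
  ec <- cfg$config
  list(model = if (is.character(cfg$model)) cfg$model else "<in-memory>",
       tasks = if (is.character(cfg$tasks)) paste(cfg$tasks, collapse = ",")
               else "<in-memory>",
       expression = cfg$expression, mode = cfg$mode,
       epsilon = cfg$epsilon, upCutoff = cfg$upCutoff,
       downCutoff = cfg$downCutoff, highPct = cfg$highPct,
       lowPct = cfg$lowPct, universe = cfg$universe, rankBy = cfg$rankBy,
       fdr = cfg$fdr, fva = cfg$fva, seed = cfg$seed,
       enumeration = list(maxAlternatives = ec@maxAlternatives,
                          diverge = ec@diverge, sizeSlack = ec@sizeSlack,
                          timeLimit = ec@timeLimit,
                          activityTol = ec@activityTol, bigM = ec@bigM,
                          cutType = ec@cutType))
}
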