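#' Generate a toy metabolic model with known minimal pathways
#'
#' Builds a model with one substrate uptake (\code{UPT}: nothing -> sub_c),
#' \code{length(routeLengths)} parallel linear routes from the substrate to
#' a common target metabolite \code{tgt_c}, and one secretion (\code{SEC}:
#' tgt_c -> nothing). Route \code{r} has \code{routeLengths[r]} reactions
#' named \code{R<r>_<step>}, each carrying a GPR with its own unique gene
#' \code{g<r>_<step>}. Optionally a dead-end branch (\code{DEAD_1}: sub_c ->
#' dead_c with no consumer, hence blocked) and a fraction of route reactions
#' made reversible.
#'
#' Ground truth: for the task "produce tgt_c", the minimum-size network is
#' (any) shortest route plus the uptake and the demand reaction, so
#' \code{s* = min(routeLengths) + 2}; the number of optimal alternatives is
#' the number of routes attaining the minimum length.
#'
#' The same arguments always produce the same model, and \code{path} written
#' twice gives byte-identical SBML.
#'
#' @param routeLengths integer vector (all >= 1), one entry per route.
#' @param includeDeadEnd add the blocked dead-end branch.
#' @param reversibleFraction fraction of route reactions (deterministically
#'   seeded) whose lower bound is opened to -maxFlux.
#' @param seed integer seed controlling which reactions become reversible.
#' @param maxFlux bound magnitude for all reactions (flux units).
#' @param path optional: also write the model as SBML L3-FBC here.
#' @return a [MetabolicModel-class]; attribute \code{routes} holds the
#'   reaction ids of each route.
#' @export
makeToyModel <- function(routeLengths = c(2L, 3L), includeDeadEnd = FALSE,
                         reversibleFraction = 0, seed = 1L, maxFlux = 10,
                         path = NULL) {
  stopifnot(length(routeLengths) >= 1L, all(routeLengths >= 1L),
            reversibleFraction >= 0, reversibleFraction <= 1)
  mets <- data.frame(id = "sub_c", name = "substrate", compartment = "c",
                     stringsAsFactors = FALSE)
  addMet <- function(id, name) {
    mets <<- rbind(mets, data.frame(id = id, name = name, compartment = "c",
                                    stringsAsFactors = FALSE))
  }
  addMet("tgt_c", "target")
  rxn <- data.frame(id = character(), lb = numeric(), ub = numeric(),
                    gpr = character(), stringsAsFactors = FALSE)
  trip <- list()
  addRxn <- function(id, stoich, lb, ub, gpr = NA_character_) {
    rxn <<- rbind(rxn, data.frame(id = id, lb = lb, ub = ub, gpr = gpr,
                                  stringsAsFactors = FALSE))
    j <- nrow(rxn)
    for (met in names(stoich))
      trip[[length(trip) + 1L]] <<-
        data.frame(met = met, j = j, x = stoich[[met]])
  }
  addRxn("UPT", list(sub_c = 1), 0, maxFlux)
  routes <- list()
  for (r in seq_along(routeLengths)) {
    len <- routeLengths[r]
    prev <- "sub_c"
    ids <- character(len)
    for (s in seq_len(len)) {
      nxt <- if (s == len) "tgt_c" else {
        mid <- sprintf("m%d_%d_c", r, s)
        addMet(mid, sprintf("route %d intermediate %d", r, s))
        mid
      }
      id <- sprintf("R%d_%d", r, s)
      st <- stats::setNames(list(-1, 1), c(prev, nxt))
      addRxn(id, st, 0, maxFlux, gpr = sprintf("g%d_%d", r, s))
      ids[s] <- id
      prev <- nxt
    }
    routes[[r]] <- ids
  }
  addRxn("SEC", list(tgt_c = -1), 0, maxFlux)
  if (includeDeadEnd) {
    addMet("dead_c", "dead end")
    addRxn("DEAD_1", list(sub_c = -1, dead_c = 1), 0, maxFlux)
  }
  if (reversibleFraction > 0) {
    rids <- unlist(routes)
    nRev <- round(reversibleFraction * length(rids))
    if (nRev > 0) {
      old <- globalenv()$.Random.seed
      set.seed(seed)
      rev <- sample(rids, nRev)
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      rxn$lb[rxn$id %in% rev] <- -maxFlux
    }
  }
  tr <- do.call(rbind, trip)
  S <- Matrix::sparseMatrix(i = match(tr$met, mets$id), j = tr$j, x = tr$x,
                            dims = c(nrow(mets), nrow(rxn)))
  model <- MetabolicModel(metabolites = mets, reactions = rxn, S = S)
  attr(model, "routes") <- routes
  if (!is.null(path)) writeSBML(model, path)
  model
}

#' Generate a synthetic expression table for a toy model
#'
#' Genes of the chosen route are drawn from Normal(+2 theta, 0.1), genes of
#' every other route from Normal(-2 theta, 0.1), and any remaining genes
#' from Normal(0, 0.1) — an effect size of twice the calling threshold, so
#' up/down calls at the default theta are essentially deterministic.
#' Deterministic under \code{seed}: the same call writes byte-identical
#' files.
#'
#' @param model a model from [makeToyModel()] (carries the route map).
#' @param upRoute index of the route to up-regulate.
#' @param theta the fold-change calling threshold the effect is scaled to
#'   (log2 units).
#' @param seed integer seed.
#' @param path optional path for a two-column tab-delimited file
#'   (gene_id, value) with header.
#' @return named numeric vector of gene values (invisibly when a file is
#'   written).
#' @export
makeExpression <- function(model, upRoute = 1L, theta = 1, seed = 1L,
                           path = NULL) {
  routes <- attr(model, "routes")
  if (is.null(routes))
    stop("model does not carry a route map (build it with makeToyModel)",
         call. = FALSE)
  if (upRoute < 1L || upRoute > length(routes))
    stop(sprintf("unknown route index %d (model has %d routes)",
                 upRoute, length(routes)), call. = FALSE)
  rules <- gprRules(model)
  geneOf <- function(ids) unique(unlist(lapply(rules[ids], gprGenes)))
  upGenes <- geneOf(routes[[upRoute]])
  downGenes <- setdiff(geneOf(unlist(routes)), upGenes)
  allGenes <- modelGenes(model)
  restGenes <- setdiff(allGenes, c(upGenes, downGenes))
  old <- globalenv()$.Random.seed
  set.seed(seed)
  vals <- c(
    stats::setNames(stats::rnorm(length(upGenes), 2 * theta, 0.1), upGenes),
    stats::setNames(stats::rnorm(length(downGenes), -2 * theta, 0.1),
                    downGenes),
    stats::setNames(stats::rnorm(length(restGenes), 0, 0.1), restGenes))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  vals <- vals[order(names(vals))]
  if (!is.null(path)) {
    writeLines(c("gene_id\tvalue",
                 sprintf("%s\t%.10f", names(vals), vals)), path,
               useBytes = TRUE)
    return(invisible(vals))
  }
  vals
}
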