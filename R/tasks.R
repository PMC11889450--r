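#' Add a demand reaction and define a synthesis task
#'
#' A demand reaction is an artificial sink consuming exactly one unit of the
#' target metabolite (\code{met -> nothing}, bounds [0, uMax]). The returned
#' task requires the demand to carry at least \code{epsilon} flux, which is
#' what "the model can synthesise the target" means operationally. When a
#' demand for the metabolite already exists it is reused, never duplicated.
#'
#' @param model a [MetabolicModel-class] (normally already pruned of blocked
#'   reactions; demands added here are marked as helpers and are never
#'   themselves pruned or counted in enrichment).
#' @param metabolite exact metabolite id (compartment suffix included).
#' @param epsilon minimum production flux (> 0). The default 1e-3 is small
#'   enough not to distort the flux space yet well above solver tolerance.
#' @param uMax upper bound of the demand reaction.
#' @return list with elements \code{model} (with the demand present) and
#'   \code{task} (a [Task-class]).
#' @export
makeDemandTask <- function(model, metabolite, epsilon = 1e-3, uMax = 1000) {
  stopifnot(epsilon > 0)
  mets <- model@metabolites$id
  if (!metabolite %in% mets) {
    near <- utils::head(agrep(metabolite, mets, value = TRUE,
                              max.distance = 0.3), 5L)
    stop(sprintf("unknown metabolite '%s'%s", metabolite,
                 if (length(near))
                   paste0("; near matches: ", paste(near, collapse = ", "))
                 else ""), call. = FALSE)
  }
  # reuse an existing demand: a helper (or DM_-named) column equal to {met: -1}
  mi <- match(metabolite, mets)
  cand <- union(model@helpers,
                intersect(paste0("DM_", metabolite), model@reactions$id))
  for (id in cand) {
    j <- match(id, model@reactions$id)
    col <- model@S[, j]
    if (col[mi] == -1 && sum(col != 0) == 1L) {
      task <- methods::new("Task", target = metabolite, demand = id,
                           epsilon = epsilon)
      return(list(model = model, task = task))
    }
  }
  id <- paste0("DM_", metabolite)
  while (id %in% model@reactions$id) id <- paste0(id, "_dm")
  rxn <- rbind(model@reactions,
               data.frame(id = id, lb = 0, ub = uMax,
                          stringsAsFactors = FALSE))
  S <- cbind(model@S, Matrix::sparseMatrix(i = mi, j = 1L, x = -1,
                                           dims = c(length(mets), 1L)))
  dimnames(S) <- list(mets, rxn$id)
  out <- methods::new("MetabolicModel", metabolites = model@metabolites,
                      reactions = rxn, S = S, gpr = model@gpr,
                      objective = model@objective,
                      helpers = c(model@helpers, id))
  task <- methods::new("Task", target = metabolite, demand = id,
                       epsilon = epsilon)
  list(model = out, task = task)
}

#' Biomass building blocks of a biomass reaction
#'
#' The building blocks (BBBs) are the metabolites the biomass reaction
#' consumes (negative stoichiometric coefficient): amino acids, nucleotides,
#' lipids, cofactors. Each defines a synthesis task. A blacklist can exclude
#' small cofactors (atp, h2o, ...) that are consumed by biomass but are not
#' biosynthetic end points.
#'
#' @param model a [MetabolicModel-class].
#' @param biomassReaction id of the biomass reaction.
#' @param blacklist metabolite ids to exclude (default none).
#' @return character vector of metabolite ids.
#' @export
extractBBBs <- function(model, biomassReaction, blacklist = character()) {
  j <- match(biomassReaction, model@reactions$id)
  if (is.na(j))
    stop(sprintf("unknown reaction '%s'", biomassReaction), call. = FALSE)
  col <- model@S[, j]
  bbb <- model@metabolites$id[col < 0]
  setdiff(bbb, blacklist)
}

#' Read a task list file
#'
#' Plain text, one entry per line: either a metabolite id, or
#' \code{BBB:<biomass_reaction_id>} to expand to that reaction's building
#' blocks. \code{#} starts a comment; blank lines are ignored.
#'
#' @param path file path.
#' @return data.frame with columns \code{kind} (\code{"metabolite"} or
#'   \code{"bbb"}) and \code{id}.
#' @export
readTaskList <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(kind = character(), id = character(),
                      stringsAsFactors = FALSE))
  isBBB <- startsWith(lines, "BBB:")
  data.frame(kind = ifelse(isBBB, "bbb", "metabolite"),
             id = ifelse(isBBB, trimws(sub("^BBB:", "", lines)), lines),
             stringsAsFactors = FALSE)
}
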