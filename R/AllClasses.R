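#' @import methods
#' @importFrom Matrix Matrix sparseMatrix rowSums colSums
#' @importClassesFrom Matrix Matrix
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Constraint-based metabolic model
#'
#' Holds the stoichiometric matrix \code{S} (rows = metabolites, columns =
#' reactions), per-reaction flux bounds, and parsed gene-protein-reaction
#' (GPR) rules. Flux units follow the source model (conventionally
#' mmol/gDW/h). Metabolite ids are opaque strings, compartment suffix
#' included; tasks must name the exact id.
#'
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}.
#' @slot reactions data.frame with columns \code{id}, \code{lb}, \code{ub}.
#' @slot S sparse stoichiometric matrix (\code{dgCMatrix}), dimnames set to
#'   metabolite and reaction ids.
#' @slot gpr named list of GPR rule trees (see [parseGpr()]); entries are
#'   \code{NULL} for reactions without gene association.
#' @slot objective id of the objective reaction, or empty character.
#' @slot helpers ids of artificial reactions added by task preparation
#'   (demand sinks); they carry no GPR and are excluded from enrichment.
#' @export
setClass("MetabolicModel",
  representation(metabolites = "data.frame", reactions = "data.frame",
                 S = "Matrix", gpr = "list", objective = "character",
                 helpers = "character"),
  prototype(objective = character(), helpers = character()))

setValidity("MetabolicModel", function(object) {
  msg <- character()
  met <- object@metabolites; rxn <- object@reactions
  if (!all(c("id", "name", "compartment") %in% names(met)))
    msg <- c(msg, "metabolites must have columns id, name, compartment")
  if (!all(c("id", "lb", "ub") %in% names(rxn)))
    msg <- c(msg, "reactions must have columns id, lb, ub")
  if (anyDuplicated(met$id)) msg <- c(msg, "duplicate metabolite ids")
  if (anyDuplicated(rxn$id)) msg <- c(msg, "duplicate reaction ids")
  if (nrow(object@S) != nrow(met) || ncol(object@S) != nrow(rxn))
    msg <- c(msg, "S dimensions do not match metabolite/reaction tables")
  if (length(msg) == 0L) {
    if (any(rxn$lb > rxn$ub)) msg <- c(msg, "reaction with lb > ub")
    if (ncol(object@S) > 0 && any(Matrix::colSums(object@S != 0) == 0))
      msg <- c(msg, "reaction column of S with no nonzero coefficient")
    bad <- setdiff(names(object@gpr), rxn$id)
    if (length(bad)) msg <- c(msg, "gpr entries for unknown reactions")
    if (length(object@objective) > 1L) msg <- c(msg, "objective must be length <= 1")
    if (length(object@objective) == 1L && !(object@objective %in% rxn$id))
      msg <- c(msg, "objective reaction not in model")
    if (!all(object@helpers %in% rxn$id))
      msg <- c(msg, "helper reaction not in model")
  }
  if (length(msg)) msg else TRUE
})

#' Metabolic task: produce a target metabolite at a minimum rate
#'
#' A task binds a target metabolite to the demand reaction that realises it
#' (\code{target -> nothing}) and the minimum production rate \code{epsilon}
#' (flux units) the minimal networks must sustain.
#'
#' @slot target target metabolite id.
#' @slot demand id of the demand reaction.
#' @slot epsilon minimum demand flux (> 0).
#' @export
setClass("Task",
  representation(target = "character", demand = "character",
                 epsilon = "numeric"))

setValidity("Task", function(object) {
  if (length(object@epsilon) != 1L || !is.finite(object@epsilon) ||
      object@epsilon <= 0) return("epsilon must be a single value > 0")
  TRUE
})

#' Flux variability analysis result
#'
#' Per-reaction flux minima and maxima under steady state and bounds, and the
#' derived blocked flag: a reaction is blocked when it cannot carry flux in
#' either direction (|vMin| and |vMax| below \code{tol}).
#'
#' @slot reaction reaction ids.
#' @slot vMin,vMax flux range per reaction (may be +/-Inf when unbounded).
#' @slot blocked logical blocked flag.
#' @slot tol tolerance used for the blocked call.
#' @export
setClass("FvaResult",
  representation(reaction = "character", vMin = "numeric", vMax = "numeric",
                 blocked = "logical", tol = "numeric"))

setValidity("FvaResult", function(object) {
  n <- length(object@reaction)
  if (length(object@vMin) != n || length(object@vMax) != n ||
      length(object@blocked) != n) return("field lengths differ")
  if (any(object@vMin > object@vMax + 1e-6)) return("vMin > vMax")
  TRUE
})

#' One minimal network (MiN)
#'
#' A minimum-cardinality set of reactions that can jointly carry a
#' steady-state flux producing the task target at the required rate, together
#' with a witnessing flux vector.
#'
#' @slot task task id (target metabolite).
#' @slot reactions active reaction ids.
#' @slot size number of active reactions.
#' @slot flux named flux witness over all model reactions.
#' @slot optimal TRUE when the size equals the proven minimum.
#' @slot proven FALSE when the solver hit its time limit before proving
#'   optimality of this solution.
#' @export
setClass("MinNetwork",
  representation(task = "character", reactions = "character",
                 size = "integer", flux = "numeric", optimal = "logical",
                 proven = "logical"))

setValidity("MinNetwork", function(object) {
  if (object@size != length(object@reactions))
    return("size must equal the number of reactions")
  TRUE
})

#' Enumeration settings for alternative minimal networks
#'
#' @slot maxAlternatives maximum number of MiNs to return (>= 1).
#' @slot diverge D, the minimum number of reactions of each earlier MiN that
#'   every later MiN must omit (>= 1).
#' @slot sizeSlack allowed size excess over the optimum (0 = only
#'   minimum-size alternatives).
#' @slot timeLimit cumulative wall-clock budget in seconds.
#' @slot activityTol |flux| above which a reaction counts as active.
#' @slot bigM cap applied to infinite bounds before binary coupling.
#' @slot cutType \code{"onesided"} (default; later MiNs must omit D reactions
#'   of each earlier active set) or \code{"symmetric"} (symmetric difference
#'   >= D).
#' @export
setClass("EnumConfig",
  representation(maxAlternatives = "integer", diverge = "integer",
                 sizeSlack = "integer", timeLimit = "numeric",
                 activityTol = "numeric", bigM = "numeric",
                 cutType = "character"))

setValidity("EnumConfig", function(object) {
  if (object@maxAlternatives < 1L) return("maxAlternatives must be >= 1")
  if (object@diverge < 1L) return("diverge must be >= 1")
  if (object@sizeSlack < 0L) return("sizeSlack must be >= 0")
  if (object@timeLimit <= 0) return("timeLimit must be > 0")
  if (!object@cutType %in% c("onesided", "symmetric"))
    return("cutType must be 'onesided' or 'symmetric'")
  TRUE
})

#' Gene-level expression profile
#'
#' @slot mode \code{"foldchange"} (relative, log2 units) or
#'   \code{"absolute"} (RPKM/FPKM-like, nonnegative).
#' @slot values named numeric vector, one finite value per gene id.
#' @export
setClass("ExpressionProfile",
  representation(mode = "character", values = "numeric"))

setValidity("ExpressionProfile", function(object) {
  if (!object@mode %in% c("foldchange", "absolute"))
    return("mode must be 'foldchange' or 'absolute'")
  if (anyDuplicated(names(object@values))) return("duplicate gene ids")
  if (length(object@values) && !all(is.finite(object@values)))
    return("non-finite expression values")
  TRUE
})

#' Partition of the reaction universe into regulation sets
#'
#' In relative mode, \code{up}/\code{down} are reactions whose GPR-mapped
#' log2 fold change clears +theta / -theta; in absolute mode they hold the
#' high/low expression tails by percentile. Everything else, including
#' reactions without GPR or without measured genes, is neutral.
#'
#' @slot universe all eligible reaction ids (N).
#' @slot up,down member reaction ids.
#' @slot mode the expression mode the sets were derived from.
#' @slot settings list of the thresholds used.
#' @export
setClass("RegulationSets",
  representation(universe = "character", up = "character", down = "character",
                 mode = "character", settings = "list"))

setValidity("RegulationSets", function(object) {
  if (length(intersect(object@up, object@down)))
    return("up and down sets overlap")
  if (!all(c(object@up, object@down) %in% object@universe))
    return("regulated reaction outside the universe")
  TRUE
})
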