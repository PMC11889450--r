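#' Construct a MetabolicModel
#'
#' Low-level constructor; most users will get models from [readSBML()] or
#' [makeToyModel()].
#'
#' @param metabolites data.frame with columns \code{id} and optionally
#'   \code{name}, \code{compartment}.
#' @param reactions data.frame with columns \code{id}, \code{lb}, \code{ub}
#'   and optionally \code{gpr} (rule text, \code{NA} for none).
#' @param S stoichiometric matrix (metabolites x reactions), dense or sparse.
#' @param objective optional objective reaction id.
#' @param helpers ids of artificial task reactions.
#' @return a [MetabolicModel-class] object.
#' @export
MetabolicModel <- function(metabolites, reactions, S,
                           objective = character(), helpers = character()) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- NA_character_
  gpr <- list()
  if (!is.null(reactions$gpr)) {
    for (i in seq_len(nrow(reactions))) {
      g <- reactions$gpr[i]
      if (!is.na(g) && nzchar(trimws(g)))
        gpr[[reactions$id[i]]] <- parseGpr(g)
    }
    reactions$gpr <- NULL
  }
  S <- Matrix::Matrix(as.matrix(S), sparse = TRUE)
  S <- methods::as(methods::as(S, "generalMatrix"), "CsparseMatrix")
  dimnames(S) <- list(metabolites$id, reactions$id)
  methods::new("MetabolicModel", metabolites = metabolites,
               reactions = reactions, S = S, gpr = gpr,
               objective = as.character(objective),
               helpers = as.character(helpers))
}

#' @rdname MetabolicModel
#' @param object,x a MetabolicModel.
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))
#' @rdname MetabolicModel
#' @export
setMethod("reactionIds", "MetabolicModel", function(object)
  object@reactions$id)

#' @rdname MetabolicModel
#' @export
setGeneric("metaboliteIds", function(object) standardGeneric("metaboliteIds"))
#' @rdname MetabolicModel
#' @export
setMethod("metaboliteIds", "MetabolicModel", function(object)
  object@metabolites$id)

#' @rdname MetabolicModel
#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))
#' @rdname MetabolicModel
#' @export
setMethod("stoichiometry", "MetabolicModel", function(object) object@S)

#' @rdname MetabolicModel
#' @export
setGeneric("bounds", function(object) standardGeneric("bounds"))
#' @rdname MetabolicModel
#' @export
setMethod("bounds", "MetabolicModel", function(object)
  data.frame(id = object@reactions$id, lb = object@reactions$lb,
             ub = object@reactions$ub, stringsAsFactors = FALSE))

#' @rdname MetabolicModel
#' @export
setGeneric("gprRules", function(object) standardGeneric("gprRules"))
#' @rdname MetabolicModel
#' @export
setMethod("gprRules", "MetabolicModel", function(object) {
  out <- stats::setNames(vector("list", nrow(object@reactions)),
                         object@reactions$id)
  for (id in names(object@gpr)) out[[id]] <- object@gpr[[id]]
  out
})

#' @rdname MetabolicModel
#' @export
setGeneric("objectiveReaction", function(object)
  standardGeneric("objectiveReaction"))
#' @rdname MetabolicModel
#' @export
setMethod("objectiveReaction", "MetabolicModel", function(object)
  if (length(object@objective)) object@objective else NA_character_)

#' @rdname MetabolicModel
#' @export
setGeneric("helperReactions", function(object)
  standardGeneric("helperReactions"))
#' @rdname MetabolicModel
#' @export
setMethod("helperReactions", "MetabolicModel", function(object)
  object@helpers)

#' Genes of a model
#'
#' All gene ids referenced by any GPR rule of the model.
#' @param object a [MetabolicModel-class].
#' @return character vector of gene ids.
#' @export
setGeneric("modelGenes", function(object) standardGeneric("modelGenes"))
#' @rdname modelGenes
#' @export
setMethod("modelGenes", "MetabolicModel", function(object)
  sort(unique(unlist(lapply(object@gpr, gprGenes)))))

#' Reversibility of reactions
#'
#' A reaction is reversible when it can carry negative flux (lb < 0).
#' @param object a [MetabolicModel-class].
#' @return named logical vector.
#' @export
setGeneric("reversibilities", function(object)
  standardGeneric("reversibilities"))
#' @rdname reversibilities
#' @export
setMethod("reversibilities", "MetabolicModel", function(object)
  stats::setNames(object@reactions$lb < 0, object@reactions$id))

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel:", nrow(object@metabolites), "metabolites,",
      nrow(object@reactions), "reactions,",
      length(object@gpr), "with GPR\n")
  if (length(object@objective))
    cat("  objective:", object@objective, "\n")
  if (length(object@helpers))
    cat("  helper reactions:", paste(object@helpers, collapse = ", "), "\n")
})

setMethod("show", "Task", function(object) {
  cat(sprintf("Task: produce %s via %s at rate >= %g\n",
              object@target, object@demand, object@epsilon))
})

setMethod("show", "FvaResult", function(object) {
  cat("FvaResult:", length(object@reaction), "reactions,",
      sum(object@blocked), "blocked (tol", object@tol, ")\n")
})

setMethod("show", "MinNetwork", function(object) {
  cat(sprintf("MinNetwork [%s]: %d reactions%s%s\n", object@task,
              object@size,
              if (object@optimal) " (minimum size)" else "",
              if (!object@proven) " [not proven optimal]" else ""))
  cat(" ", paste(object@reactions, collapse = "; "), "\n")
})

setMethod("show", "RegulationSets", function(object) {
  lab <- if (object@mode == "absolute") c("high", "low") else c("up", "down")
  cat(sprintf("RegulationSets (%s): N=%d, %s=%d, %s=%d, neutral=%d\n",
              object@mode, length(object@universe),
              lab[1], length(object@up), lab[2], length(object@down),
              length(object@universe) - length(object@up) -
                length(object@down)))
})

#' @export
#' @describeIn FvaResult-class coerce to a data.frame (columns
#'   \code{reaction}, \code{vMin}, \code{vMax}, \code{blocked}).
#' @param x an FvaResult.
#' @param ... ignored.
as.data.frame.FvaResult <- function(x, ...) {
  data.frame(reaction = x@reaction, vMin = x@vMin, vMax = x@vMax,
             blocked = x@blocked, stringsAsFactors = FALSE)
}

# internal: subset a model to a reaction index vector (logical or integer),
# dropping metabolites whose row becomes all zero
.subsetReactions <- function(model, keep) {
  rxn <- model@reactions[keep, , drop = FALSE]
  S <- model@S[, keep, drop = FALSE]
  nz <- Matrix::rowSums(S != 0) > 0
  S <- S[nz, , drop = FALSE]
  met <- model@metabolites[nz, , drop = FALSE]
  gpr <- model@gpr[intersect(names(model@gpr), rxn$id)]
  obj <- model@objective
  if (length(obj) && !(obj %in% rxn$id)) obj <- character()
  methods::new("MetabolicModel", metabolites = met, reactions = rxn, S = S,
               gpr = gpr, objective = obj,
               helpers = intersect(model@helpers, rxn$id))
}
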