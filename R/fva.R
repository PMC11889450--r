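#' Flux variability analysis
#'
#' For every reaction, minimises and maximises its flux subject to steady
#' state (\code{S v = 0}) and the model bounds, optionally while holding the
#' model objective at a fraction of its optimum. A reaction is flagged
#' blocked when it can carry no flux in either direction (|vMin| and |vMax|
#' below \code{tol}).
#'
#' By default no objective constraint is imposed (\code{fractionOfOptimum =
#' NULL}): blocked-reaction detection must reflect the whole flux space, not
#' just the optimal face.
#'
#' @param model a [MetabolicModel-class].
#' @param fractionOfOptimum \code{NULL}, or a number in [0, 1]: constrain the
#'   objective reaction to at least this fraction of its FBA optimum.
#' @param tol blocked-call tolerance (flux units). The default 1e-9 sits
#'   below the LP feasibility tolerance so numerically zero optima are not
#'   mistaken for activity.
#' @return an [FvaResult-class].
#' @export
runFVA <- function(model, fractionOfOptimum = NULL, tol = 1e-9) {
  ss <- .steadyState(model)
  n <- ncol(ss$A)
  A <- ss$A; sense <- ss$sense; rhs <- ss$rhs
  if (!is.null(fractionOfOptimum)) {
    stopifnot(fractionOfOptimum >= 0, fractionOfOptimum <= 1)
    objId <- objectiveReaction(model)
    if (is.na(objId))
      stop("runFVA: fractionOfOptimum given but the model has no objective",
           call. = FALSE)
    opt <- fba(model, objId, maximize = TRUE)$objective
    row <- as.numeric(model@reactions$id == objId)
    A <- rbind(A, row)
    sense <- c(sense, 1L)                 # objective >= fraction * optimum
    rhs <- c(rhs, fractionOfOptimum * opt)
  }
  vMin <- vMax <- numeric(n)
  ids <- model@reactions$id
  for (i in seq_len(n)) {
    obj <- numeric(n); obj[i] <- 1
    lo <- .lp(obj, A, sense, rhs, ss$lb, ss$ub, maximize = FALSE)
    if (lo$status == 1L)
      stop(sprintf(paste0("runFVA: model infeasible ",
                          "(first failing LP: minimise flux of '%s')"),
                   ids[i]), call. = FALSE)
    hi <- .lp(obj, A, sense, rhs, ss$lb, ss$ub, maximize = TRUE)
    vMin[i] <- if (lo$status == 2L) -Inf else lo$obj
    vMax[i] <- if (hi$status == 2L) Inf else hi$obj
  }
  methods::new("FvaResult", reaction = ids, vMin = vMin, vMax = vMax,
               blocked = abs(vMin) < tol & abs(vMax) < tol, tol = tol)
}

#' Remove blocked reactions from a model
#'
#' Drops every reaction flagged blocked by [runFVA()] and any metabolite left
#' with an all-zero stoichiometric row. Because a blocked reaction carries
#' zero flux in every feasible steady state, the feasible flux space is
#' unchanged: any feasible flux of the pruned model extends by zeros to a
#' feasible flux of the original, and vice versa.
#'
#' @param model a [MetabolicModel-class].
#' @param fva the [FvaResult-class] computed on this model; computed on the
#'   fly when missing.
#' @return the pruned [MetabolicModel-class].
#' @export
pruneBlocked <- function(model, fva = runFVA(model)) {
  if (!setequal(fva@reaction, model@reactions$id))
    stop("pruneBlocked: FVA result does not match the model", call. = FALSE)
  blocked <- fva@blocked[match(model@reactions$id, fva@reaction)]
  .subsetReactions(model, !blocked)
}
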