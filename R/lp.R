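#' @useDynLib minnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Internal linear-programming interface. min c'x s.t. A x (sense) b,
# lb <= x <= ub; sense is -1 '<=', 0 '=', +1 '>=' per row.
# Returns list(status, obj, x); status 0 optimal, 1 infeasible, 2 unbounded.
.lp <- function(obj, A, sense, rhs, lb, ub, maximize = FALSE) {
  A <- as.matrix(A)
  stopifnot(length(obj) == ncol(A), length(rhs) == nrow(A),
            length(sense) == nrow(A))
  cc <- if (maximize) -obj else obj
  r <- .lp_solve_cpp(as.numeric(cc), A, as.integer(sense), as.numeric(rhs),
                     as.numeric(lb), as.numeric(ub))
  if (r$status == 0 && maximize) r$obj <- -r$obj
  r
}

# Internal binary MILP. `binary`: 1-based column indices restricted to {0,1}.
.milp <- function(obj, A, sense, rhs, lb, ub, binary, timeLimit = 1e9,
                  maximize = FALSE, objIntegral = TRUE) {
  A <- as.matrix(A)
  cc <- if (maximize) -obj else obj
  r <- .milp_solve_cpp(as.numeric(cc), A, as.integer(sense), as.numeric(rhs),
                       as.numeric(lb), as.numeric(ub), as.integer(binary),
                       as.numeric(timeLimit), isTRUE(objIntegral))
  if (!is.null(r$obj) && !is.na(r$obj) && maximize) r$obj <- -r$obj
  r
}

# Steady-state LP pieces for a model: S v = 0 with the model's bounds.
.steadyState <- function(model) {
  S <- as.matrix(model@S)
  list(A = S, sense = rep.int(0L, nrow(S)), rhs = rep.int(0, nrow(S)),
       lb = model@reactions$lb, ub = model@reactions$ub)
}

#' Flux balance analysis
#'
#' Maximises (or minimises) the flux of one reaction subject to steady state
#' (\code{S v = 0}) and the model's bounds.
#'
#' @param model a [MetabolicModel-class].
#' @param reaction reaction id to optimise; defaults to the model objective.
#' @param maximize direction of optimisation.
#' @return list with \code{objective} (optimal value), \code{flux} (named
#'   optimal flux vector) and \code{status}.
#' @export
fba <- function(model, reaction = objectiveReaction(model), maximize = TRUE) {
  if (is.na(reaction) || !reaction %in% model@reactions$id)
    stop("fba: no objective reaction available", call. = FALSE)
  ss <- .steadyState(model)
  obj <- as.numeric(model@reactions$id == reaction)
  r <- .lp(obj, ss$A, ss$sense, ss$rhs, ss$lb, ss$ub, maximize = maximize)
  if (r$status == 1L)
    stop("fba: model is infeasible (no steady-state flux satisfies the bounds)",
         call. = FALSE)
  flux <- if (length(r$x)) stats::setNames(r$x, model@reactions$id) else NULL
  list(objective = if (r$status == 0L) r$obj else
         (if (maximize) Inf else -Inf),
       flux = flux, status = r$status)
}
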