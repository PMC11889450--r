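#' Enumeration settings
#'
#' @param maxAlternatives maximum number of alternative MiNs to enumerate.
#' @param diverge D: every later MiN must omit at least D reactions of each
#'   earlier MiN's active set. D = 1 enumerates all distinct alternatives;
#'   larger D spreads the alternatives further apart.
#' @param sizeSlack allowed excess over the minimum size s*; 0 keeps only
#'   minimum-size networks.
#' @param timeLimit cumulative wall-clock budget in seconds for the whole
#'   enumeration.
#' @param activityTol |flux| above which a reaction is counted active.
#' @param bigM finite cap substituted for infinite bounds before the binary
#'   coupling (flux units).
#' @param cutType \code{"onesided"} or \code{"symmetric"}; see
#'   [EnumConfig-class].
#' @return an [EnumConfig-class].
#' @export
enumConfig <- function(maxAlternatives = 10L, diverge = 1L, sizeSlack = 0L,
                       timeLimit = 600, activityTol = 1e-6, bigM = 1000,
                       cutType = c("onesided", "symmetric")) {
  methods::new("EnumConfig",
               maxAlternatives = as.integer(maxAlternatives),
               diverge = as.integer(diverge),
               sizeSlack = as.integer(sizeSlack),
               timeLimit = as.numeric(timeLimit),
               activityTol = as.numeric(activityTol),
               bigM = as.numeric(bigM), cutType = match.arg(cutType))
}

#' Build the minimal-network MILP for a task
#'
#' Variables are the fluxes \code{v} plus one binary \code{y_i} per reaction;
#' \code{y_i = 0} forces \code{v_i = 0} through the coupling
#' \code{l_i y_i <= v_i <= u_i y_i} (a single binary gates both directions of
#' a reversible reaction). The demand flux is bounded below by the task's
#' epsilon and its binary fixed to 1; the objective minimises the number of
#' active reactions \code{sum(y)}. Infinite bounds are capped at
#' \code{+/- bigM} so all coupling coefficients are finite.
#'
#' Two tightenings make the relaxation informative without changing the
#' enumerated networks. First, a selected irreversible reaction must carry
#' at least the activity tolerance (\code{v_i >= activityTol * y_i});
#' "selected but inert" reactions never occur in a minimum-cardinality
#' solution anyway, and activity below the tolerance would be dropped from
#' the reported network regardless. Second, that floor validates
#' producer-cover constraints: when an irreversible reaction consuming a
#' metabolite is active, steady state forces at least one producer of that
#' metabolite to be active too, so \code{sum(y[producers]) >= y_consumer}.
#' These covers propagate the demand requirement backwards through the
#' network and give the LP relaxation shortest-path strength.
#'
#' @param model a pruned [MetabolicModel-class] containing the task's demand
#'   reaction.
#' @param task a [Task-class].
#' @param bigM finite cap for infinite bounds; set to \code{Inf} to forbid
#'   capping (then any gated reaction with an infinite bound is an error).
#' @param activityTol minimum |flux| an irreversible selected reaction must
#'   carry; keep it well below epsilon divided by the largest stoichiometric
#'   ratio of the model.
#' @return an opaque MILP handle consumed by [solveMin()].
#' @export
buildMilp <- function(model, task, bigM = 1000, activityTol = 1e-6) {
  ids <- model@reactions$id
  di <- match(task@demand, ids)
  if (is.na(di))
    stop("buildMilp: task demand reaction not in model", call. = FALSE)
  n <- length(ids)
  S <- as.matrix(model@S)
  m <- nrow(S)
  lb <- model@reactions$lb
  ub <- model@reactions$ub
  inf <- !is.finite(lb) | !is.finite(ub)
  if (any(inf) && !is.finite(bigM))
    stop(paste0("buildMilp: reaction(s) with infinite bounds cannot be ",
                "gated by a binary: ",
                paste(ids[inf], collapse = ", "),
                ". Provide a finite big-M cap (default 1000 flux units)."),
         call. = FALSE)
  lb <- pmax(lb, -bigM)
  ub <- pmin(ub, bigM)
  lb[di] <- max(lb[di], task@epsilon)

  # Tighten the coupling. When every gated reaction's bound interval
  # contains zero, any feasible flux can be scaled down, so fixing the
  # demand to exactly epsilon leaves the set of feasible supports
  # unchanged; a flux variability pass under that normalisation then
  # yields per-reaction coupling coefficients far tighter than the raw
  # bounds, which is what makes the LP relaxation of "minimise the number
  # of active reactions" informative.
  if (all(lb[-di] <= 0 & ub[-di] >= 0)) {
    ub[di] <- lb[di]
    rng <- .rangeFVA(S, lb, ub)
    marg <- 1e-7
    lb <- pmax(lb, rng$vMin - marg)
    ub <- pmin(ub, rng$vMax + marg)
  }

  # irreversible (under the tightened bounds) selected reactions must carry
  # at least the activity tolerance
  irr <- lb >= 0
  cpl <- lb
  cpl[irr] <- pmax(lb[irr], activityTol)
  cpl <- pmin(cpl, ub)                       # never above the upper bound

  # columns: v_1..v_n, y_1..y_n
  Z <- matrix(0, m, n)
  rows <- rbind(cbind(S, Z),                 # S v = 0
                cbind(diag(n), diag(-ub)),   # v_i - u_i y_i <= 0
                cbind(diag(n), diag(-cpl)))  # v_i - max(l_i, tol) y_i >= 0
  sense <- c(rep.int(0L, m), rep.int(-1L, n), rep.int(1L, n))
  rhs <- rep.int(0, m + 2L * n)

  # producer covers: an active irreversible consumer of a metabolite needs
  # an active producer (reactions able to make it under the current bounds)
  canRun <- ub > activityTol | lb < -activityTol
  for (r in which(irr & canRun)) {
    for (mi in which(S[, r] < 0)) {
      P <- which(((S[mi, ] > 0 & ub > activityTol) |
                  (S[mi, ] < 0 & lb < -activityTol)))
      P <- setdiff(P, r)
      row <- numeric(2L * n)
      row[n + P] <- 1
      row[n + r] <- row[n + r] - 1
      rows <- rbind(rows, row)
      sense <- c(sense, 1L)
      rhs <- c(rhs, 0)
    }
  }

  vlb <- c(lb, rep.int(0, n))
  vub <- c(ub, rep.int(1, n))
  vlb[n + di] <- 1                           # demand binary fixed on
  obj <- c(rep.int(0, n), rep.int(1, n))
  structure(list(obj = obj, A = rows, sense = sense, rhs = rhs,
                 lb = vlb, ub = vub, binary = (n + 1L):(2L * n),
                 n = n, ids = ids, demand = di, task = task@target),
            class = "minnetMilp")
}

# plain flux variability over S v = 0 with the given box bounds
.rangeFVA <- function(S, lb, ub) {
  n <- ncol(S)
  sense <- rep.int(0L, nrow(S))
  rhs <- rep.int(0, nrow(S))
  vMin <- vMax <- numeric(n)
  for (i in seq_len(n)) {
    obj <- numeric(n); obj[i] <- 1
    lo <- .lp(obj, S, sense, rhs, lb, ub)
    hi <- .lp(obj, S, sense, rhs, lb, ub, maximize = TRUE)
    if (lo$status == 1L || hi$status == 1L)
      stop("task not producible: no reaction subset sustains the demand",
           call. = FALSE)
    vMin[i] <- if (lo$status == 0L) lo$obj else lb[i]
    vMax[i] <- if (hi$status == 0L) hi$obj else ub[i]
  }
  list(vMin = vMin, vMax = vMax)
}

# append an inequality row over the y block; coef named by reaction id
.milpAddRow <- function(milp, yCoef, sense, rhs) {
  row <- numeric(2L * milp$n)
  j <- match(names(yCoef), milp$ids)
  row[milp$n + j] <- yCoef
  milp$A <- rbind(milp$A, row)
  milp$sense <- c(milp$sense, sense)
  milp$rhs <- c(milp$rhs, rhs)
  milp
}

#' Solve the minimal-network MILP once
#'
#' @param milp handle from [buildMilp()] (possibly carrying integer cuts).
#' @param timeLimit wall-clock limit in seconds for this solve.
#' @param activityTol |flux| above which a selected reaction is kept in the
#'   active set; selected reactions whose witness flux is below it are
#'   dropped after the solve.
#' @return a [MinNetwork-class]. Errors with "task not producible" when the
#'   MILP is infeasible; errors on a time limit hit with no incumbent; a time
#'   limit hit with an incumbent returns the incumbent with
#'   \code{proven = FALSE}.
#' @export
solveMin <- function(milp, timeLimit = 600, activityTol = 1e-6) {
  stopifnot(inherits(milp, "minnetMilp"))
  r <- .milp(milp$obj, milp$A, milp$sense, milp$rhs, milp$lb, milp$ub,
             binary = milp$binary, timeLimit = timeLimit)
  if (r$status == 1L)
    stop("task not producible: no reaction subset sustains the demand",
         call. = FALSE)
  if (r$status == 4L)
    stop("time limit reached before any feasible network was found",
         call. = FALSE)
  v <- r$x[seq_len(milp$n)]
  y <- r$x[milp$binary]
  act <- which(y > 0.5 & abs(v) >= activityTol * (1 - 1e-9))
  methods::new("MinNetwork", task = milp$task,
               reactions = milp$ids[act], size = length(act),
               flux = stats::setNames(v, milp$ids),
               optimal = TRUE, proven = r$status == 0L)
}

#' Enumerate alternative minimal networks
#'
#' Solves the minimal-network MILP repeatedly. After each solution with
#' active set A_k an integer cut is added requiring every later solution to
#' omit at least D (= \code{diverge}) reactions of A_k; after the first
#' solution the size is capped at \code{s* + sizeSlack}. Enumeration stops at
#' \code{maxAlternatives}, at infeasibility (all alternatives exhausted), or
#' when the cumulative time limit is hit (partial results are returned with
#' \code{attr(,"truncated") = TRUE}).
#'
#' @param model pruned [MetabolicModel-class] containing the demand reaction.
#' @param task a [Task-class].
#' @param config an [EnumConfig-class].
#' @return list of [MinNetwork-class] in discovery order, with attributes
#'   \code{sStar} (proven minimum size, counted over selected binaries) and
#'   \code{truncated}.
#' @export
enumerateMins <- function(model, task, config = enumConfig()) {
  milp <- buildMilp(model, task, bigM = config@bigM,
                    activityTol = config@activityTol)
  t0 <- proc.time()[["elapsed"]]
  out <- list()
  sStar <- NA_integer_
  truncated <- FALSE
  for (k in seq_len(config@maxAlternatives)) {
    left <- config@timeLimit - (proc.time()[["elapsed"]] - t0)
    if (left <= 0) { truncated <- TRUE; break }
    mn <- tryCatch(
      solveMin(milp, timeLimit = left, activityTol = config@activityTol),
      error = function(e) e)
    if (inherits(mn, "error")) {
      if (k == 1L) stop(mn)                 # first solve failing is a real error
      if (grepl("time limit", conditionMessage(mn))) truncated <- TRUE
      break                                  # infeasible: alternatives exhausted
    }
    if (!mn@proven) truncated <- TRUE
    if (k == 1L) {
      sStar <- mn@size
      milp <- .milpAddRow(milp,
                          stats::setNames(rep.int(1, milp$n), milp$ids),
                          -1L, sStar + config@sizeSlack)
    }
    mn@optimal <- mn@size <= sStar
    out[[k]] <- mn
    A <- mn@reactions
    if (config@cutType == "onesided") {
      # sum_{i in A} y_i <= |A| - D
      milp <- .milpAddRow(milp, stats::setNames(rep.int(1, length(A)), A),
                          -1L, length(A) - config@diverge)
    } else {
      # symmetric difference >= D:
      # sum_{i in A}(1 - y_i) + sum_{i notin A} y_i >= D
      coef <- stats::setNames(rep.int(1, milp$n), milp$ids)
      coef[A] <- -1
      milp <- .milpAddRow(milp, coef, 1L, config@diverge - length(A))
    }
    if (!mn@proven) break
  }
  structure(out, sStar = sStar, truncated = truncated)
}

#' Check minimality of a network by single-reaction deletion
#'
#' TRUE iff (a) restricting the model to the network's reactions leaves the
#' task feasible, and (b) removing any single reaction of the network makes
#' it infeasible. One LP per reaction.
#'
#' @param model the [MetabolicModel-class] the network was enumerated on
#'   (must contain the demand reaction).
#' @param task a [Task-class].
#' @param min a [MinNetwork-class].
#' @return logical.
#' @export
verifyMinimality <- function(model, task, min) {
  if (length(min@reactions) == 0L) return(FALSE)
  if (!all(min@reactions %in% model@reactions$id)) return(FALSE)
  if (!.taskFeasible(model, task, min@reactions)) return(FALSE)
  for (r in min@reactions)
    if (.taskFeasible(model, task, setdiff(min@reactions, r))) return(FALSE)
  TRUE
}

# LP feasibility of the task when flux is restricted to `keep` reactions
.taskFeasible <- function(model, task, keep) {
  ss <- .steadyState(model)
  ids <- model@reactions$id
  off <- !(ids %in% keep)
  lb <- ss$lb; ub <- ss$ub
  lb[off] <- 0; ub[off] <- 0
  di <- match(task@demand, ids)
  if (is.na(di) || off[di]) return(FALSE)
  lb[di] <- max(lb[di], task@epsilon)
  if (lb[di] > ub[di]) return(FALSE)
  r <- .lp(numeric(length(ids)), ss$A, ss$sense, ss$rhs, lb, ub)
  r$status != 1L
}

#' Exhaustive minimal-network search (reference implementation)
#'
#' Brute-force enumeration for small models: walks reaction subsets in order
#' of increasing cardinality (demand always included), testing task
#' feasibility of each subset by LP, and returns all feasible subsets of the
#' minimum cardinality. Exponential in the reaction count; intended as an
#' independent reference for models with at most ~15 reactions.
#'
#' @param model [MetabolicModel-class] containing the demand reaction.
#' @param task a [Task-class].
#' @param maxSize largest cardinality to try (default: all reactions).
#' @return list of character vectors (sorted reaction id sets), possibly
#'   empty; attribute \code{sStar} carries the minimum cardinality found.
#' @export
enumerateMinsExhaustive <- function(model, task, maxSize = NULL) {
  ids <- model@reactions$id
  others <- setdiff(ids, task@demand)
  if (is.null(maxSize)) maxSize <- length(ids)
  for (k in seq_len(maxSize)) {
    hits <- list()
    for (cmb in .combnList(others, k - 1L)) {
      subset <- c(cmb, task@demand)
      if (.taskFeasible(model, task, subset))
        hits[[length(hits) + 1L]] <- sort(subset)
    }
    if (length(hits)) return(structure(hits, sStar = k))
  }
  structure(list(), sStar = NA_integer_)
}

.combnList <- function(x, k) {
  if (k == 0L) return(list(character()))
  if (k > length(x)) return(list())
  asplit(utils::combn(x, k), 2L)
}

#' Write minimal networks to a tab-delimited file
#'
#' One row per MiN: task id, index, size, optimal flag, semicolon-joined
#' reaction ids.
#'
#' @param mins list of [MinNetwork-class] (as from [enumerateMins()]).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeMins <- function(mins, path) {
  df <- data.frame(
    task_id = vapply(mins, function(m) m@task, character(1)),
    min_index = seq_along(mins),
    size = vapply(mins, function(m) m@size, integer(1)),
    optimal = vapply(mins, function(m) m@optimal, logical(1)),
    reactions = vapply(mins, function(m)
      paste(m@reactions, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  if (!length(mins))
    df <- df[0, , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
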