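# Shared fixtures and independent oracles.

# linear chain with no exit: uptake -> A -> B -> C, C accumulates, so no
# reaction can carry steady-state flux
chainModel <- function() {
  MetabolicModel(
    metabolites = data.frame(id = c("A", "B", "C")),
    reactions = data.frame(id = c("UPT_A", "R_AB", "R_BC"),
                           lb = c(0, 0, 0), ub = c(10, 10, 10)),
    S = matrix(c(1, -1, 0,
                 0, 1, -1,
                 0, 0, 1), nrow = 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), NULL)))
}

# two parallel one-step conversions A -> B with open uptake and secretion
parallelModel <- function() {
  MetabolicModel(
    metabolites = data.frame(id = c("A", "B")),
    reactions = data.frame(id = c("UPT_A", "R1", "R2", "SEC_B"),
                           lb = 0, ub = 10,
                           gpr = c(NA, "gA", "gB", NA)),
    S = matrix(c(1, -1, -1, 0,
                 0, 1, 1, -1), nrow = 2, byrow = TRUE))
}

# independent LP oracle: scipy.optimize.linprog (HiGHS) via the system python
scipyLP <- function(obj, A, sense, rhs, lb, ub, maximize = FALSE) {
  payload <- jsonlite::toJSON(list(
    c = as.numeric(if (maximize) -obj else obj),
    A = unname(as.matrix(A)), sense = as.integer(sense),
    b = as.numeric(rhs), lb = as.numeric(lb), ub = as.numeric(ub)),
    digits = NA, auto_unbox = FALSE)
  script <- '
import sys, json, math
import numpy as np
from scipy.optimize import linprog
d = json.load(sys.stdin)
A = np.array(d["A"], dtype=float); b = np.array(d["b"], dtype=float)
sense = d["sense"]
Aub, bub, Aeq, beq = [], [], [], []
for i, s in enumerate(sense):
    if s == 0: Aeq.append(A[i]); beq.append(b[i])
    elif s < 0: Aub.append(A[i]); bub.append(b[i])
    else: Aub.append(-A[i]); bub.append(-b[i])
bnd = [(l if math.isfinite(l) else None, u if math.isfinite(u) else None)
       for l, u in zip(d["lb"], d["ub"])]
r = linprog(d["c"], A_ub=np.array(Aub) if Aub else None,
            b_ub=np.array(bub) if bub else None,
            A_eq=np.array(Aeq) if Aeq else None,
            b_eq=np.array(beq) if beq else None,
            bounds=bnd, method="highs")
out = {"status": int(r.status), "obj": r.fun if r.status == 0 else None,
       "x": list(r.x) if r.x is not None else None}
print(json.dumps(out))
'
  tf <- tempfile(fileext = ".py")
  writeLines(script, tf)
  res <- system2("python", tf, input = as.character(payload), stdout = TRUE)
  out <- jsonlite::fromJSON(paste(res, collapse = ""))
  if (!is.null(out$obj) && maximize) out$obj <- -out$obj
  out
}

# exhaustive multivariate hypergeometric tail by enumerating labelled subsets
enumPUp <- function(N, Kup, Kdown, n, kup, kdown) {
  lab <- c(rep("u", Kup), rep("d", Kdown), rep("n", N - Kup - Kdown))
  subsets <- utils::combn(N, n)
  hit <- 0L
  for (j in seq_len(ncol(subsets))) {
    s <- lab[subsets[, j]]
    if (sum(s == "u") >= kup && sum(s == "d") <= kdown) hit <- hit + 1L
  }
  hit / ncol(subsets)
}

# Monte-Carlo estimate of the up tail with standard error
mcPUp <- function(N, Kup, Kdown, n, kup, kdown, draws = 1e5) {
  lab <- c(rep("u", Kup), rep("d", Kdown), rep("n", N - Kup - Kdown))
  hit <- 0L
  for (i in seq_len(draws)) {
    s <- lab[sample.int(N, n)]
    if (sum(s == "u") >= kup && sum(s == "d") <= kdown) hit <- hit + 1L
  }
  p <- hit / draws
  list(p = p, se = sqrt(p * (1 - p) / draws))
}

# sorted-set-of-sets comparison
sameSetOfSets <- function(a, b) {
  norm <- function(x) sort(vapply(x, function(s)
    paste(sort(s), collapse = ";"), character(1)))
  identical(norm(a), norm(b))
}

minReactionSets <- function(mins) lapply(mins, function(m) m@reactions)

# a small battery of toy specifications with <= 12 reactions (pre-demand)
smallToySpecs <- function() {
  list(
    list(routeLengths = c(1L), deadEnd = FALSE, revFrac = 0),
    list(routeLengths = c(2L), deadEnd = TRUE, revFrac = 0),
    list(routeLengths = c(3L), deadEnd = FALSE, revFrac = 0.5),
    list(routeLengths = c(1L, 1L), deadEnd = FALSE, revFrac = 0),
    list(routeLengths = c(1L, 2L), deadEnd = TRUE, revFrac = 0),
    list(routeLengths = c(2L, 2L), deadEnd = FALSE, revFrac = 0),
    list(routeLengths = c(2L, 2L), deadEnd = TRUE, revFrac = 0.5),
    list(routeLengths = c(2L, 3L), deadEnd = FALSE, revFrac = 0),
    list(routeLengths = c(2L, 3L), deadEnd = TRUE, revFrac = 0),
    list(routeLengths = c(3L, 3L), deadEnd = FALSE, revFrac = 0),
    list(routeLengths = c(3L, 3L), deadEnd = FALSE, revFrac = 0.5),
    list(routeLengths = c(3L, 4L), deadEnd = TRUE, revFrac = 0),
    list(routeLengths = c(4L, 4L), deadEnd = FALSE, revFrac = 0),
    list(routeLengths = c(4L, 5L), deadEnd = FALSE, revFrac = 0),
    list(routeLengths = c(1L, 1L, 1L), deadEnd = FALSE, revFrac = 0),
    list(routeLengths = c(2L, 2L, 2L), deadEnd = FALSE, revFrac = 0),
    list(routeLengths = c(2L, 2L, 2L), deadEnd = TRUE, revFrac = 0),
    list(routeLengths = c(2L, 2L, 3L), deadEnd = FALSE, revFrac = 0),
    list(routeLengths = c(2L, 3L, 3L), deadEnd = FALSE, revFrac = 0.3),
    list(routeLengths = c(1L, 2L, 3L), deadEnd = TRUE, revFrac = 0),
    list(routeLengths = c(3L, 3L, 3L), deadEnd = FALSE, revFrac = 0),
    list(routeLengths = c(2L, 2L, 2L, 2L), deadEnd = FALSE, revFrac = 0))
}

buildToy <- function(spec, seed = 1L) {
  makeToyModel(routeLengths = spec$routeLengths,
               includeDeadEnd = spec$deadEnd,
               reversibleFraction = spec$revFrac, seed = seed)
}
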