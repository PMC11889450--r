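---
title: "Minimal network enrichment analysis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal network enrichment analysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minnet)
```

## The problem

Genome-scale metabolic models describe a cell's metabolism as a
stoichiometric matrix $S$ (metabolites $\times$ reactions) with flux bounds
$l_i \le v_i \le u_i$ per reaction. Elementary flux modes — minimal sets of
reactions that can operate at steady state — are the natural pathway concept
on such models, but enumerating all of them is intractable at genome scale.
This package works with a tractable surrogate: for one *metabolic task* —
"synthesise metabolite $t$ at rate at least $\varepsilon$" — it enumerates
**minimal networks (MiNs)**, minimum-cardinality reaction sets that can carry
a steady-state flux accomplishing the task. MiNs capture what EFMs are used
for in practice (cofactor balancing, by-product routes, alternative
pathways) while remaining computable by mixed-integer linear programming.
Alternative MiNs for the same task are then ranked by how strongly they are
enriched in up- or down-regulated (or highly/lowly expressed) reactions
derived from a gene-expression experiment, which is what turns a structural
enumeration into a statement about context-specific metabolism.

## The enumeration model

A task is realised by a *demand reaction* $t \to \emptyset$ with flux at
least $\varepsilon$ (default $10^{-3}$ flux units — small enough not to
distort the flux space, three orders of magnitude above the activity
tolerance). The core MILP is

$$
\min \sum_i y_i
\quad \text{s.t.} \quad
S v = 0,\qquad
l_i y_i \le v_i \le u_i y_i,\qquad
v_{\mathrm{demand}} \ge \varepsilon,\qquad
y_i \in \{0, 1\},
$$

with the demand's binary fixed to one. A single binary gates both directions
of a reversible reaction (no direction splitting; this halves the binary
count and was never observed to matter on the fixtures). Infinite bounds are
capped at $\pm 1000$ before coupling so all coefficients are finite; the cap
is configurable.

Two valid tightenings make the LP relaxation informative (without them, the
relaxation's optimum is close to zero because $y_i \ge v_i / u_i$ can be
made arbitrarily small, and branch-and-bound degenerates into subset
enumeration):

1. **Demand normalisation and range reduction.** Whenever every gated
   reaction's bound interval contains zero, any feasible flux can be scaled
   toward zero, so fixing $v_{\mathrm{demand}} = \varepsilon$ leaves the set
   of feasible *supports* unchanged. A flux-variability pass under that
   normalisation then replaces the raw bounds in the coupling constraints by
   the actual attainable ranges.
2. **Activity floors and producer covers.** A selected irreversible
   reaction must carry at least the activity tolerance
   ($v_i \ge \delta y_i$, $\delta = 10^{-6}$): a selected-but-inert reaction
   never occurs in a minimum-cardinality solution, and flux below $\delta$
   would not count as activity anyway. This floor makes the following cover
   constraints valid: if an irreversible reaction consuming metabolite $m$
   is active, steady state forces at least one producer of $m$ to be active,
   i.e. $\sum_{j \in P(m)} y_j \ge y_i$. These covers propagate the demand
   requirement backwards through the network and give the relaxation
   shortest-path strength.

The floor interacts with one numerical convention: a reaction is *active*
(belongs to the reported MiN) when its witness flux exceeds
$\delta = 10^{-6}$ in absolute value. $\delta$ must stay well below
$\varepsilon$ divided by the largest stoichiometric ratio in the model; the
defaults leave three orders of magnitude of headroom.

### Alternatives and divergence

After each solution with active set $A_k$, the integer cut
$\sum_{i \in A_k} y_i \le |A_k| - D$ is added: every later MiN must omit at
least $D$ reactions of $A_k$. This one-sided reading of "differ by $D$
reactions" is the default; a symmetric-difference cut is available
(`cutType = "symmetric"`). With $D = 1$ and `sizeSlack = 0` the enumeration
provably yields exactly the minimum-cardinality feasible supports (checked
against exhaustive subset search on every fixture). Alternatives are capped
at $s^* + \mathrm{sizeSlack}$; the default slack of 0 reflects that the
method is about *minimum-size* networks, so suboptimal alternatives are
opt-in. A cumulative wall-clock limit truncates enumeration gracefully;
truncated results are flagged rather than discarded.

### The solver

No linear or mixed-integer programming library is available to this package
at build time, so it carries its own exact solver (C++, RcppArmadillo): a
bounded-variable revised simplex (Dantzig pricing with a Bland anti-cycling
fallback, dense refactorisation each iteration — appropriate at these
problem sizes) inside a deterministic depth-first branch-and-bound that
branches on the lowest-index fractional binary, explores the 1-branch first,
warm-starts each node from its parent's basis, and prunes with
integer-rounded bounds. Determinism matters: repeated runs return the same
MiNs in the same order, which the pipeline's idempotence contract relies on.
The simplex is cross-checked in the test suite against an independent LP
implementation on random instances, and the branch-and-bound against
exhaustive search.

## Flux variability analysis and pruning

Blocked reactions (those that can carry no flux in any steady state) are
found by per-reaction flux minimisation/maximisation and removed before
enumeration, together with any metabolite row left empty. FVA runs *without*
an objective constraint by default, because blocked-reaction detection must
reflect the whole flux space, not the optimal face; `fractionOfOptimum`
restores the constrained variant. The blocked tolerance ($10^{-9}$) sits
below the LP feasibility tolerance to avoid false positives. Pruning
provably preserves the flux space (blocked reactions are zero in every
feasible flux), which the tests verify by comparing LP optima before and
after. Re-running FVA with each task's demand already imposed blocks more
reactions but costs one FVA per task; both designs are defensible, so this
package prunes once globally by default and offers `fva = "task"` in the
pipeline for the task-specific variant.

## From genes to reaction regulation

Expression is mapped to reactions through the gene–protein–reaction rules:
`and` (complex subunits) takes the minimum of its children, `or`
(isoenzymes) the maximum. This min/max convention is the dominant one in
expression-integration methods and is consistent with complexes being
limited by their scarcest subunit. Genes missing from the profile are
dropped from their parent node; a rule with no measured gene leaves the
reaction neutral.

Two modes are supported. In **relative** mode (log2 fold changes) a reaction
is up-regulated at $\ge +\theta$ and down-regulated at $\le -\theta$, with
$\theta = 1$ (two-fold) by default. In **absolute** mode (RPKM/FPKM-like),
the high/low sets are the $\ge 75$th / $\le 25$th percentile tails of the
valued reactions (linear interpolation, ties included in the extreme set).
No cutoff is canonical in the literature, so all four are exposed as
parameters. Reactions without expression stay in the universe as neutral by
default — they dilute enrichment, which is the conservative choice — and
`universe = "valued"` restricts the universe instead. Relative-mode input is
taken as signed values from which the up/down calls are derived, rather than
as pre-called gene lists; signed input preserves the information needed to
change thresholds without re-importing data.

## The enrichment statistic

Given a universe of $N$ reactions with $K_{up}$ up- and $K_{down}$
down-regulated members, and a MiN occupying $n$ of them with $k_{up}$ and
$k_{down}$ observed, the up-enrichment p-value is the multivariate
hypergeometric tail

$$
p_{up} = \sum_{a \ge k_{up}}\; \sum_{b \le k_{down}}
\frac{\binom{K_{up}}{a}\binom{K_{down}}{b}
      \binom{N-K_{up}-K_{down}}{n-a-b}}{\binom{N}{n}},
$$

small when the network contains many up- and few down-regulated reactions;
$p_{down}$ is the mirror image. The joint tail
$\{a \ge k_{up},\, b \le k_{down}\}$ is the literal reading of "an elevated
number of up-regulated and as few as possible down-regulated reactions"; a
point-mass "as extreme or more" alternative is deliberately not offered.
With $K_{down} = 0$ the statistic reduces to the classical one-tailed
hypergeometric survival function, which the tests verify against `phyper`
to $10^{-12}$; the general case is verified against exhaustive subset
enumeration and a Monte-Carlo oracle. Binomial coefficients are computed in
log space, so universes of genome-scale size are safe.

Demand reactions added during task preparation are excluded from the
universe and from $n$: they carry no GPR and occur in every MiN, so counting
them would only shrink percentages. Records are ranked per task ascending in
the requested tail, ties broken by larger percentage, then smaller network
size, then discovery index. Raw p-values are reported because the method
ranks alternatives within a task rather than testing a family of hypotheses;
an optional Benjamini–Hochberg column (`fdr = TRUE`) is available.

## What the toy generator emulates — and what it does not

`makeToyModel()` builds one substrate uptake, parallel linear routes with
one unique gene per reaction, one secretion, optionally a dead-end branch
and a seeded fraction of reversible reactions. Its value is that the ground
truth is known by construction: the optimal MiN is the shortest route plus
uptake and demand, the number of optimal alternatives is the number of
shortest routes, and the dead end must be flagged blocked.
`makeExpression()` draws the chosen route's genes from
$\mathcal N(+2\theta, 0.1)$, other route genes from
$\mathcal N(-2\theta, 0.1)$ and the rest from $\mathcal N(0, 0.1)$ — an
effect of twice the calling threshold, so regulation calls are essentially
deterministic and tests do not flake.

These fixtures deliberately lack most features of real models: no cofactor
coupling, no by-products, no shared reactions between routes, no isoenzyme
`or`-rules or complex `and`-rules in the generated GPRs, unit stoichiometry
throughout. Passing tests on them demonstrates the correctness of the
machinery (enumeration, statistics, ranking), not that the defaults are
tuned for any particular organism's genome-scale model.

```{r example}
m <- makeToyModel(routeLengths = c(2, 2, 3), includeDeadEnd = TRUE)
pruned <- pruneBlocked(m)
dt <- makeDemandTask(pruned, "tgt_c")
mins <- enumerateMins(dt$model, dt$task, enumConfig(maxAlternatives = 10))
vals <- makeExpression(m, upRoute = 2, seed = 7)
profile <- new("ExpressionProfile", mode = "foldchange", values = vals)
sets <- regulationSets(pruned, profile)
scoreMins(mins, sets, exclude = helperReactions(dt$model))
```

## Numerical choices and limitations

* Tolerances: blocked $10^{-9}$; activity $10^{-6}$; MILP integrality
  $10^{-6}$; simplex pivot floor $10^{-7}$. Witness mass balance is checked
  to $10^{-6}$ in the tests.
* Problem sizes: the test and acceptance fixtures use models of up to 60
  reactions with exhaustive cross-checks up to 12 reactions, 100-seed
  ranking recovery on three-route models, and $10^5$-draw Monte-Carlo
  checks of the statistic. These sizes keep the dense simplex comfortably
  fast while exercising every code path.
* The dense-refactorising simplex is designed for models of this order
  (hundreds of reactions); genuinely genome-scale MILPs (thousands of
  binaries) would need a sparse LP engine with incremental factorisation.
* Degenerate alternative optima of the MILP are resolved deterministically
  but arbitrarily; which of several equally minimal networks appears first
  is not meaningful, only the set of them is.
* Extra linear constraint rows present in a model (for instance
  thermodynamic ones added upstream) ride along unchanged through FVA and
  enumeration; generating such constraints is out of scope.
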