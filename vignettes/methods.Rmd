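---
title: "Detecting reticulate taxa from cytonuclear discordance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting reticulate taxa from cytonuclear discordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model, the three-phase procedure, the tunable parameters and why
their defaults are what they are, what the synthetic benchmark does and
does not emulate, and the numerical choices underneath.

## The problem

Plastid loci are maternally inherited as a single non-recombining linkage
group; nuclear ribosomal ITS evolves biparentally and undergoes concerted
evolution. After hybridization or introgression the two genomes can tell
different stories: a species may carry a captured chloroplast from one
lineage while its (partly or fully homogenized) ITS still tracks another.
On trees, this shows up as *cytonuclear discordance* — strongly supported
splits of the plastid tree that cannot coexist with strongly supported
splits of the ITS tree.

The package treats discordance not as noise but as the object of study:
specimens responsible for hard conflicts are identified, set aside from a
clean "core" phylogeny of presumed direct-descent taxa, and then probed —
one genome at a time — against that core to characterize their parental
affinities.

## Likelihood machinery

Everything rests on standard time-reversible substitution models.  A model
is built from six exchangeabilities $s_{ij}$ and stationary frequencies
$\pi$, $Q_{ij} = s_{ij}\pi_j$, rescaled so one unit of branch length is
one expected substitution per site.  The implemented family is JC, K80,
HKY and GTR, each optionally with discrete-gamma rate heterogeneity
(equal-probability categories, category means; 4 categories by default).
Site likelihoods are computed by Felsenstein pruning with per-node
rescaling, so underflow is impossible by construction rather than
detected after the fact; ambiguity codes enter as indicators over their
compatible states, and `-`, `?`, `N` are uninformative.  Partitioned data
sum region log-likelihoods, each region with its own model and a relative
rate multiplier applied to the shared branch lengths (multipliers are
renormalized to a weighted mean of one, the scale being absorbed by the
branch lengths).

The engine exposes, for any edge, the conditional likelihoods of the two
half-trees on either side ("edge environments").  Branch lengths are then
one-dimensional problems: we use guarded Newton steps on the analytic
first and second derivatives of the log-likelihood in the edge length,
bounded to $[0, 10]$, with backtracking; sweeps alternate a cheap
parallel phase against shared environments with a sequential
fresh-environment phase that is monotone by construction, stopping when a
sweep gains less than $10^{-6}$ log-units.

Model choice per region minimizes AIC ($2k - 2\ln L$) over the candidate
family on a fixed topology.  Parameter counts: JC 0, K80 1, HKY 4
(kappa + 3 empirical frequencies), GTR 8, $+\Gamma$ adds 1; branch
lengths are shared across candidates and excluded from $k$.  Free-rate
and invariant-site components are deliberately out of family: GTR+Γ is
the supremum of the implemented family and the pipeline's conclusions
rest on topology and support, not on fine model identity.

## Phase 1 — conflict scan and specimen attribution

Class trees are inferred by NJ (JC distances; ties in the Q criterion go
to the lowest-index pair, negative lengths are clamped to zero) followed
by best-improvement NNI hill-climbing.  Both alternatives of every
internal edge are scored locally: one pruning pass caches, for each edge,
the four surrounding subtree partials, and any resolution's likelihood is
their product joined by the central branch, whose length alone is
re-optimized (per-pattern scaling constants cancel across the three
resolutions of an edge, so the score differences are exact for the cached
lengths).  The best improving move is accepted only after exact
verification — the candidate's branch lengths are fully re-optimized and
the move is kept only if the true log-likelihood improves — so the search
remains a deterministic ascent.

Two supports annotate each internal edge.  The aBayes posterior is the
softmax of the three NNI resolutions' log-likelihoods (uniform prior),
each alternative scored by the same cached-partial scheme with the
central branch re-optimized — the fast scoring used by the standard
aBayes implementations; the input tree carries fully optimized branch
lengths, so the current resolution is at its optimum and alternatives
are, if anything, slightly under-scored.  Bootstrap supports resample
columns with replacement *within each region* (preserving partition
structure) and re-infer each replicate; by default replicates are
re-inferred by distance NJ, with `refine = TRUE` adding the NNI search
per replicate.  The default is a deliberate design choice: across
hundreds of replicates the NJ re-inference preserves the property that
matters — support rises with signal and stays low on star-like data —
at a small fraction of the cost, and the likelihood-based aBayes support
is always computed on the full search.

A split passes the strong-support rule under `mode = "or"` (either
aBayes ≥ 0.95 or BS ≥ 95; the default, matching the inspection rule
"and/or") or `mode = "and"`.  Two strong splits, one per class tree,
form a hard conflict iff their restrictions to the shared taxa are
non-trivial and all four intersection blocks are non-empty — the
classical pairwise-compatibility criterion, verified in the tests against
exhaustive display over all 945 seven-taxon topologies.

**Attribution** formalizes "testing specimens individually", which the
underlying procedure leaves open.  Candidates are the taxa in a
minimal-size intersection block of at least one conflict (the displaced
group of a conflict is small; its members are the natural suspects).
For each candidate we remove it, re-infer both class trees (warm-started
from the current trees restricted to the kept taxa, with the full-data
models and rates held fixed) and re-detect conflicts.  The candidate's
score is the *net reduction in the number of hard conflicts*; conflicts
whose restriction merely becomes trivial after the removal are not
credited, because removing a bystander that happens to sit in a small
block trivializes splits without resolving the discordance.  Candidates
are evaluated lazily in decreasing order of involvement (the number of
conflicts whose minimal blocks contain them), stopping early when no
unevaluated candidate's involvement bound can beat the best score.  A
candidate that reaches a conflict-free state is accepted outright.  When
no single specimen reaches zero conflicts, whole minimal blocks of two
to four specimens are tested jointly: sister hybrids that share both
donor lineages travel as a block through every conflict, and removing
only one of them resolves nothing — a structural blind spot of strict
one-at-a-time testing that the block step closes.  If nothing scores
positively the remaining conflicts are reported as unattributable; the
procedure never forces a removal.

## Phase 2 — core phylogeny and taxon duplication

The core matrix contains only congruent specimens; before the classes
are combined the zero-conflict invariant is re-verified on the reduced
class trees and a residual conflict is a hard failure — incongruent data
are never silently combined.  Flagged specimens keep their data: each
re-enters as `X_ITS` and `X_PL`, the complementary class coded missing.

Placement holds the core topology and branch lengths fixed: an entry is
attached at the midpoint of every edge with a free pendant branch, the
pendant length alone is optimized, and the per-edge likelihoods (on the
entry's class regions only) are normalized into likelihood weight ratios.
This is the default screen; `expanded_inference()` is the faithful full
re-inference mode over core taxa plus a group's duplicated entries, used
for the phase-3 trees.  Its search can be warm-started from the
individual placements; an NJ start over imputed distances (pairs of
single-class entries from different classes share no columns; their NJ
distance is imputed by the shortest one-intermediate path) is the
fallback.  Specimens are analyzed one at a time — no other flagged
specimen is present during placement — so confounding ITS copies cannot
attract each other.

## Phase 3 — patterns and floating ITS groups

Placements are labelled against named core clades.  A user-supplied map
(e.g. taxonomic sections) is validated against the core tree; otherwise
clades are auto-generated from the strongly supported splits.  The
auto-map keeps *all* strong clades of at most half the taxa (nested
clades allowed, with assignment to the smallest containing clade) rather
than only maximal ones: at a couple dozen taxa the maximal strong clades
collapse onto one or two backbone-scale groups and erase exactly the
distinctions the classification exists to report.  A placement on the
path between named clades is labelled `between(X,Y)` by edge-graph
proximity.

A specimen's discordance pattern is its pair (plastid clade, ITS clade);
pattern equality partitions the flagged specimens into the expanded
datasets.  Floating ITS groups — strongly supported clades consisting
only of duplicated ITS entries (no core taxa, the operational reading of
"little affinity to other clades") whose members' plastid entries attach
to at least two distinct clades — are sought on a joint expanded tree
containing *every* flagged specimen.  This matters: grouping by exact
pattern equality separates shared-ITS/distinct-plastid hybrids into
different expanded datasets, and no per-group tree could ever display
the floating group they jointly form.

## The synthetic benchmark

`sim_config()` defaults define the study conditions used throughout the
tests: 24 taxa on a forward-simulated Yule tree (birth rate 1, stopped at
n tips, rescaled to a root-to-tip depth of 0.3 expected
substitutions/site — a typical Sanger-era divergence), 2 hybrids whose
plastid and ITS donor edges are at least 4 edges apart, four plastid
regions of 500 bp sharing one gene tree (a single non-recombining
plastid) and one 800 bp ITS region with its own gene tree at twice the
plastid rate, GTR+Γ sequences (exchangeabilities 1.5/3/0.5/0.8/2.5/1,
frequencies 0.3/0.2/0.2/0.3, α = 0.8), no missing data.  Region lengths
echo the ~5:1 plastid:ITS character ratio of typical matrices; the
paper-scale option of masking ~10 % of region cells as missing is
available via `missing_frac`.

Hybridization is modeled as clean tip regrafting — the plastid gene tree
prunes the hybrid and regrafts it onto its plastid donor edge
(chloroplast capture), the nuclear gene tree likewise onto the ITS donor
edge; attachment is at the edge midpoint with an ultrametric pendant.
Hybrids sharing a donor attach serially so their gene copies form a
clade, emulating a shared homogenized ITS.  Gene trees therefore differ
from the species tree *exactly* by the recorded regrafts, and the truth
table is unambiguous.  This deliberately omits incomplete lineage
sorting, gene flow gradients, indels and alignment error: passing the
recovery tests shows the procedure detects clean, strongly supported
reticulation signals; it does not show robustness to coalescent
stochasticity or partial homogenization, which real data add on top.

## Numerical choices and limitations

* Branch lengths live in $[0, 10]$; edge optimization tolerance
  $10^{-6}$; pruning is exact to $10^{-8}$ against enumeration on small
  instances; likelihoods are invariant to the traversal root to
  $10^{-9}$.
* Saturated pairwise distances are capped at 5; pairs with no shared
  defined columns are a missing-distance signal (never 0) and are only
  imputed for NJ starting trees.
* Partition files use 1-based inclusive spans externally *and*
  internally — the natural R indexing convention; nothing in the package
  converts index bases.
* Desk-scale defaults: B = 200 bootstrap replicates (raise toward 10⁴
  for publication supports), the +Γ candidate family, benchmark sizes as
  above.  The acceptance checks use 20-replicate experiments at those
  default conditions, which keep the full suite within an interactive
  budget on one CPU.
* The attribution heuristics (minimal blocks, involvement-ordered lazy
  evaluation, block removal) are this package's formalization of a
  procedure that is usually done by expert inspection; reports label the
  flagged set accordingly and always carry the conflict evidence that
  drove each removal.
* The classification is descriptive: a floating ITS group is a pattern,
  not a process claim — hybridization, repeated introgression and
  ancient ILS can all produce it.
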