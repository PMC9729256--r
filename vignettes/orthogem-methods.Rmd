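---
title: "Orthology-guided metabolic model reconstruction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthology-guided metabolic model reconstruction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthogem)
```

## The problem

Building a genome-scale metabolic model (GEM) from scratch takes months of
manual curation. When a well-curated GEM already exists for a close relative,
most of that work can be transferred: each reaction of the reference model
carries a gene-reaction rule (GPR) — a positive Boolean formula over the
reference genome's genes — and comparative genomics tells us which of those
genes have orthologs in a new genome. `orthogem` implements this
semi-automated route for bacterial genomes (its motivating use case is
acetic acid bacteria of the genus *Acetobacter*, where a curated reference
model and a genus-wide orthogroup analysis are available): rule rewriting
over orthogroups, draft assembly, evidence-curated gap filling, constraint-
based simulation, and pan-genome pathway screening.

## Rule transfer over orthogroups

A GPR is monotone: it contains only `and` (complex subunits) and `or`
(isoenzymes), never negation. That makes orthology substitution sound. For a
target genome $t$ and a reference gene $g$ with orthogroup $O(g)$, the leaf
$g$ is rewritten as

* the `or` over all genes of $t$ in $O(g)$ — the *co-ortholog OR assumption*:
  genes of one genome sharing an orthogroup with $g$ are treated as
  interchangeable isofunctional copies;
* logical `FALSE` if $O(g)$ contains no gene of $t$ (the function was lost);
* logical `FALSE` with an `unmapped-no-orthogroup` flag if $g$ occurs in no
  orthogroup at all. This last case is qualitatively different: it usually
  means the reference model and the orthogroup table were built from
  different annotation versions of the reference genome, and silently calling
  the reaction absent would create false negatives. `orthogem` therefore
  flags these reactions into a mandatory side report, and re-adding them is an
  explicit user decision via an allowlist (`build_draft_model(allowlist=)`).

A reaction is called present when the substituted rule is satisfiable over
the target's full gene complement, i.e. did not collapse to `FALSE`.
Reactions without any rule — spontaneous reactions, lumped macromolecular
biosynthesis, the biomass reaction — are transferred as such: their presence
is not gene-conditional.

Two properties make this testable without real genomes. Substitution
*commutes* with evaluation: evaluating the substituted rule over the target
genes equals evaluating the original rule over the reference genes whose
orthogroups retain a target member. And transfer is *monotone*: adding genes
to a genome never removes a reaction. The test suite checks both as
property-style loops over randomly generated rules (500 commutation cases,
exhaustive truth tables for rules of up to five genes), against an oracle
that evaluates the rule text with R's own Boolean operators.

When two `and`-joined reference genes fall into one orthogroup that does
contain target genes, the substitution cannot tell the subunits apart; the
call is still made, but the rule is flagged (`and_shared_orthogroup`) for
manual curation. How such rules should be resolved is genuinely ambiguous,
so the package surfaces them rather than deciding.

## Flux balance analysis and the carbon cap

FBA maximizes the biomass flux $v_{bio}$ subject to steady state $S v = 0$,
reaction bounds $l \le v \le u$ (mmol gCDW$^{-1}$ h$^{-1}$), and the medium.
A medium specification closes every exchange for uptake unless it is named
(with a maximal uptake rate) or belongs to the always-open inorganic set;
secretion is never medium-limited. Signs follow the COBRA convention:
negative exchange flux is uptake.

Defined-medium experiments motivate a cap on *total carbon consumption*
rather than on individual substrates: growth is compared across carbon
sources at a fixed carbon supply of 60 c-mmol gCDW$^{-1}$ h$^{-1}$. Because
consumption is not net exchange (a model may secrete carbon), the cap is
implemented with nonnegative uptake-split variables $u_e \ge 0$,
$u_e \ge -v_e$, and $\sum_e c_e\, u_e \le C$, where $c_e$ is the carbon count
of the exchanged metabolite's formula. Secretion therefore never relaxes the
cap. With glucose (C6) as the sole source and $C = 60$, glucose uptake can
never exceed 10 — a closed-form consequence asserted in the tests.

Parsimonious FBA re-optimizes at the fixed biomass optimum, minimizing
$\sum_r |v_r|$ via the standard flux split $v = v^+ - v^-$. It suppresses
futile cycles that plain FBA leaves undetermined, which matters whenever a
flux *distribution* (not just the optimum) is reported. Flux splits through
alternative pathways can still be non-unique at the pFBA optimum; the
package reports the pFBA value and leaves uniqueness checks to the user
rather than asserting a single answer.

### The LP backend

FBA, pFBA and the gap-filling feasibility probes all reduce to linear
programs with equality rows and bounded variables. `orthogem` ships its own
dense two-phase primal simplex (`lp_solve()`) for these problems:
bounded-variable pivoting with Bland's smallest-index rule, which guarantees
termination on the highly degenerate bases that zero-right-hand-side
steady-state systems produce. Basic variable values are recomputed from the
basis factorization at every iteration, so error does not accumulate across
pivots. Optimality and feasibility use a $10^{-9}$ pivot tolerance; returned
solutions are checked against a $10^{-7}$ steady-state residual. The solver
is deterministic — identical inputs yield identical flux vectors — which the
gap-filling tie-break and the test suite rely on. During development it was
cross-validated against an independent LP implementation on randomized
bounded problems and on FBA/pFBA instances; those checks informed the
implementation but the shipped tests rely on hand-solved networks
(chain, branch, futile cycle) and closed-form properties instead.

Numerical choices worth knowing: the pFBA biomass pin keeps a relative slack
of $10^{-9}$ below the FBA optimum (enough to absorb round-off, small enough
that the reported growth rates are indistinguishable); infeasibility and
unboundedness are reported as statuses, never as silent zeros; a model with
infinite bounds can legitimately return `unbounded`.

## Gap filling and evidence curation

A transferred draft often cannot grow in silico: essential biosynthesis
steps were lost to annotation gaps. Gap filling asks for a
minimum-cardinality set of template-model reactions whose addition restores
growth on the given medium (candidate pool: template reactions absent from
the draft, excluding exchanges unless the medium names them). `orthogem`
solves this exactly and deterministically in three stages:

1. **Feasibility.** If the draft plus the whole pool still fails the growth
   test, the instance is unfillable; the blocked biomass precursors are
   reported.
2. **Forced set.** Adding reactions only enlarges the feasible flux space,
   so growth is monotone in the added set. Hence any candidate whose removal
   from the full pool kills growth must belong to *every* feasible fill.
   One leave-one-out pass finds this forced set; if it alone restores
   growth, it is the certified unique minimum.
3. **Residual search.** Otherwise the residual pool is enumerated in order
   of increasing cardinality, lexicographic within a cardinality — the
   deterministic tie-break among equal-size solutions. The result is
   certified minimal whenever the residual pool is within the candidate cap
   (default 12); beyond the cap a greedy irreducible set is returned with
   `minimal = FALSE`, never silently presented as a minimum.

This search returns exactly what a mixed-integer formulation with binary
indicators would (and the tests compare it against an exhaustive
subset-search oracle); the staged form needs no MILP solver and makes the
certificate explicit.

Gap filling is deliberately not the last word. Each proposed reaction is
*curated* against per-genome annotation evidence (flat TSV: gene, EC
numbers, annotation text, source tag): EC intersection first, exact
normalized name match second, user overrides (`force_include` /
`force_exclude`) last. Only evidence-supported or user-forced reactions
enter the final model; the rest are excluded and listed. This mirrors the
semi-automated practice in which in-silico growth is never bought at the
price of gene-evidence-free reactions — in the motivating study exactly this
step rejected two of seventeen proposed reactions for one strain.

## Pathway screening

Comparative read-outs need only presence/absence, not flux. A screen names a
pathway's member enzymes by EC number (for annotation evidence) or reference
reaction id (for a presence matrix), plus a decision rule. Shipped screens:
glyoxylate cycle (isocitrate lyase EC 4.1.3.1 + malate synthase EC 2.3.3.9,
all-members — both enzymes are required for net C2 assimilation), aerobic
respiratory chain (EC 7.1.1.2, EC 1.6.5.9, EC 7.1.1.3, EC 7.1.1.7,
all-members), and the NAD(P)$^+$ transhydrogenase pair (membrane EC 7.1.1.1
vs soluble EC 1.6.1.1, member-wise). A genome with no evidence rows at all is
`unknown`, never coerced to absent.

Two report operations sit on top: `mutual_exclusivity_report()` classifies
each genome by a member pair (`first-only` / `second-only` / `both` /
`neither`) and counts the `both` exceptions, and
`concordance_with_phenotype()` compares screen verdicts with growth
phenotypes, flagging growth-positive/pathway-absent genomes as candidate
false-positive growth records. The packaged glyoxylate table ships the
published phenotype and presence calls per species; the transhydrogenase
panel fixture is a synthetic reconstruction from narrative statements (and
is named accordingly), not a published table. Weak growth (`w`) defaults to
counting as growth in tallies — the convention under which the packaged
table's "able to grow" count adds up — and is configurable because the
underlying phenotype assays leave it unclassified.

## The synthetic-data generator

Every pipeline stage is tested against generated data with recorded ground
truth rather than downloads. `make_reference_model()` builds a mass-balanced
toy metabolism: per carbon source an exchange, transporter and assimilation
entry; a linear C6 backbone; precursor taps; a biomass reaction draining one
unit of each precursor; a C3 byproduct secretion route; and random
isomerization/cleavage padding. Default dimensions (30 reactions, 2 carbon
sources, 3 precursors, GPR mix 15% orphan / 40% single / 20% OR / 15% AND /
10% nested) are chosen so the model is small enough for exhaustive oracles
yet exercises every rule shape; build-time FBA verifies feasibility, and an
infeasible draw rebuilds with an incremented sub-seed.

`simulate_genome_family()` derives target genomes by independent gene loss
(default 10% per gene, the regime where presence and absence calls are both
common) and co-ortholog duplication (5%), emits the induced one-orthogroup-
per-gene table, the truth reactome (original rules evaluated under retained
genes), and consistent evidence tables. `make_gapfill_scenario()` removes
reactions whose essentiality is verified by blocking them in the draft
merged with the full template — which is what certifies the removed set as
the unique minimum fill — pads the template with inert decoys, and strips
evidence for a chosen subset so curation has planted negatives.

What the generator does *not* emulate: sequence-level artifacts (frameshifts,
split genes, mis-assemblies), orthogroup inference errors, gene fusions
across orthogroups, cofactor/energy metabolism, and realistic phylogenetic
correlation of losses. Passing tests therefore demonstrate the correctness
of the transfer/gap-fill/screen machinery under clean orthology, not the
biological accuracy of any particular reconstruction; on real data the
flagged-case reports and the evidence-curation step are where those
imperfections surface.

All randomness flows through one seed per generator call; sub-seeds are
derived deterministically, identical seeds reproduce byte-identical scenario
bundles, and generator calls restore the caller's RNG state.

## Design choices on open points

* **Dead-end metabolites.** No standard definition exists at the detail
  level needed for counting. `orthogem` calls a metabolite dead-end when its
  direction-resolved producing channels or consuming channels are empty, or
  when it touches exactly one reaction (even a reversible one: production
  and consumption then coincide in a single reaction and no steady-state
  flux can pass). Published dead-end counts computed under other conventions
  may differ slightly; comparisons should state the criterion.
* **Mass-balance exemptions.** Biomass and macromolecular lump reactions are
  exempted by an explicit id list, never by name heuristics.
* **Growth threshold.** In-silico "growth" means biomass flux above
  $10^{-6}$ h$^{-1}$ (configurable) — a numerically safe cutoff well above
  solver noise and well below any biologically meaningful rate.
* **Rule simplification.** Substituted rules only have `FALSE` branches
  pruned; surviving structure is kept verbatim so curators can trace every
  target rule back to its reference original.
* **Certified vs best-found gap fills.** Published gap-fill counts from
  heuristic tools may not be certified minima; `gap_fill()` reports its
  certificate (`minimal`) explicitly so the two are never conflated.

## Problem sizes

The shipped tests run synthetic references of 20–30 reactions, families of
up to 20 genomes, exhaustive truth tables to $2^5$ assignments, 500-case
property loops, and gap-fill pools of about ten candidates with exhaustive
subset oracles — sizes chosen so every oracle is exact and the full suite
completes in well under a minute. The algorithms themselves have no such
limits: transfer is linear in rules × genomes, and the LP solver handles the
few-hundred-variable systems of bacterial GEMs comfortably; certified gap
filling beyond the candidate cap falls back to the documented greedy mode.

## Limitations

Reconstruction quality is bounded by the reference curation and the
orthogroup inference, both treated as upstream inputs. The simplex backend
is dense and single-threaded — adequate for bacterial GEMs, not tuned for
community-scale models. Gap filling against universal reaction databases,
flux variability analysis, and thermodynamic constraints are out of scope.
The deposited-model reproduction harness (`run_reproduce()`) performs no
network access; users supply the archived files themselves.
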