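---
title: "Methods: presence-absence inference for the HIF pathway and sponge hypoxia physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-absence inference for the HIF pathway and sponge hypoxia physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spongehif)
```

`spongehif` asks two questions about early-branching animals. First, a
comparative one: does a lineage carry orthologs of the hypoxia-inducible
factor (HIF) pathway — the HIFa/ARNT bHLH-PAS pair, the EGL9/PHD prolyl
hydroxylase, VHL, FIH — or only more distant homologs, or nothing at
all? Second, a physiological one: how does a sponge's contraction
behaviour and oxygen uptake respond when ambient oxygen is stepped
down? This vignette explains the models behind each stage, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the design choices made where the design was genuinely
open.

## Orthology from gene trees

### The species-overlap rule

Internal nodes of a rooted gene tree are labelled duplication or
speciation by the species-overlap rule: a node is a duplication iff at
least two of its child subtrees share a species. The alternative —
full reconciliation against a species tree — requires committing to a
species topology, which is exactly what is contested for the deepest
animal branches (sponge-sister versus ctenophore-sister). The overlap
rule needs no species tree at all, which is why it is used here; the
presence-absence matrix is rendered under both clade orderings purely
as presentation, and the verdicts are identical by construction.

The known cost of the overlap rule is one-sided: it can *miss* a
duplication (when complementary losses leave the two child subtrees
with disjoint species sets) but, on clean input, it cannot invent one.
The test suite asserts both directions — exact label equality on
loss-free simulations, and inferred-duplication ⊆ true-duplication
with losses.

### Verdicts

Against a reference gene of defined function (e.g. human HIFa), the
relation of a target species is summarized through two sets: O, the
target-species leaves whose most recent common ancestor with the
reference is a speciation (the reference's orthologs there), and R,
the reference-species leaves orthologous to at least one member of O.
The verdict is 1-to-1 (|O| = |R| = 1), 1-to-many (|O| > 1, |R| = 1),
homolog/many-to-many (|R| > 1, or |O| = 0 with the species present —
the gene is related only through positions preceding duplications), or
absent (no leaf of that species). A clade's verdict is the strongest
verdict among its species, and an absence is upgraded to *secondary
loss* only when a configured non-metazoan outgroup clade
(Choanoflagellata, Capsaspora) still carries the component — absence
plus an outgroup homolog implies loss on the lineage rather than
primary absence. Two or more duplication nodes confined to a single
clade raise the lineage-duplication flag (`+M` in the matrix).

Support values are *not* used to collapse nodes by default; an
optional `min_support` collapses weak nodes to polytomies, whose
children the labeller compares pairwise. Unrooted input trees are
rooted on outgroup species when present, otherwise by midpoint.

## Reciprocal best hits

Candidate homologs are selected from 12-column tabular search output
with an inclusive e-value ceiling of 1e-5, multiple HSPs per
query-subject pair collapsed to the best-bitscore record, ties broken
by smaller e-value then lexicographic subject id, and the reciprocal
criterion applied to the two best-hit maps.

The simulator that exercises this module emits bitscores as a strictly
decreasing function of patristic distance on the true gene tree, with
jitter bounded below half the smallest score gap so ranks never
reorder. Each table emulates searching one species' proteins against a
*combined* database holding both proteomes. On an ultrametric tree,
patristic distance is monotone in divergence time, so an in-paralog
(post-speciation duplicate) always outscores every cross-species hit;
reciprocity therefore fails exactly for the 1-to-many and many-to-many
configurations, and the reciprocal-best-hit set coincides with the
true 1:1 ortholog pairs. With cross-species-only databases this
identity would not hold (each 1:many family would contribute one
spurious pair), which is why the combined-database construction was
chosen.

## Domain architectures and the degron scan

Domain calls use envelope coordinates, an e-value ceiling of 0.1 and a
bitscore floor of 10. Overlaps are resolved greedily by bitscore: a
hit overlapping an accepted hit by more than half the shorter one is
dropped. A protein is bHLH-PAS iff it has at least one bHLH-class and
one PAS-class domain with the bHLH N-terminal to the first PAS — the
canonical arrangement; the ordering requirement is relaxable. The
PAS-class vocabulary is {PAS, PAS_3, PAS_11, PAC} and bHLH-class is
{HLH}; both are configurable because profile databases differ in which
models tile a given sensor region. The region scanned for degrons runs
from the end of the last PAS-class domain to the protein end.

The oxygen-dependent degradation degron is matched in two modes: the
strict octamer consensus `L[D/E]x[L/R]AP[F/Y]I`, and the core tetramer
`[L/R]AP[F/Y]`. The two-mode design is deliberate: near-miss
arrangements (e.g. `LAMRAPYI`) match only the core, and keeping the
modes separate keeps the claim auditable — a core match in a
proline-rich tail is weak evidence precisely because composition alone
produces it. Two nulls quantify that: an i.i.d. expectation
`E = (L - k + 1) * prod_p sum(freq[allowed at p])` (the unconstrained
position contributes 1), and a permutation p-value
`(1 + #{shuffles >= observed}) / (n + 1)` from uniform residue
shuffles within the region. The i.i.d. null ignores residue
autocorrelation (P/S/Q runs); the permutation null preserves exact
composition but not runs; both are reported side by side. Coordinates
are 0-based half-open internally and 1-based in reports.

## Oxygen conversions

Percent air saturation is referenced to the equilibrium concentration
of seawater under water-saturated air at 1 atm, computed from the
Garcia–Gordon refit of the Benson–Krause data (combined fit, per-litre
variant) and converted to µM with 44.6596 µmol per cm³ O2. At the
study conditions (26 °C, salinity 32) this gives ≈211.6 µM, and the
conversion is linear in percent. The per-litre variant was chosen over
the per-kilogram one because the experimental values are reported
volumetrically; hydrostatic and altitude corrections are out of scope.
Valid ranges are −2–40 °C and salinity 0–42 (the fit's calibration).

## Imaging and contraction detection

Segmentation is threshold-plus-morphology: optional background
subtraction, a global Otsu threshold, morphological closing (disc
radius 3 px), largest connected component, hole fill. The mask
boundary *is* the detected edge; since the quantity of interest is
projected area rather than the contour, a gradient-based mode is
provided only behind configuration. Frames whose intensity range falls
below a contrast floor (20 of 255 by default), or whose largest
component is under 20 px, return an explicit "no object" result that
propagates as a missing value in the trace — gaps are never silently
interpolated.

Contraction detection works on the normalized area a(t)/baseline(t):
a 5-sample running median removes shot noise, a rolling 90th-percentile
over a 2 h window tracks the expanded-state baseline (robust to the
dips themselves at realistic event rates), events are maximal intervals
below 1 − θ_sub with θ_sub = 0.1, events closer than 5 min are merged,
and an event is a full-body contraction when its trough passes
1 − θ_full with θ_full = 0.5. The θ values are package conventions —
the distinction between full-body and local sub-contractions is not
quantified in the physiological literature this emulates — and both
are exposed in `contraction_config()`.

## The contraction-rate model

Counts per (individual, oxygen level) cell with exposure offsets are
modelled as `log E[count] = log(exposure_days) + α_individual +
β_level`, fitted by iteratively reweighted least squares (tolerance
1e-8 on the coefficient change, at most 100 iterations). Individuals
enter as *fixed* intercepts rather than random effects: with a handful
of sponges sampled repeatedly, fixed intercepts are a standard small-N
approximation that keeps the likelihood exact and testable, avoiding
adaptive quadrature entirely; this is a deliberate design choice. A
likelihood-ratio test compares against the equal-rates null (the
statistic is 2(ℓ_fit − ℓ_null), non-negative by construction), and all
pairwise level contrasts are Wald tests with Holm adjustment — chosen
because Holm is uniformly valid without distributional extras. A level
whose counts are all zero is a boundary case: its observations
contribute zero to the likelihood regardless of the coefficient, so
the level is excluded from the IRLS design and reported with a −∞
rate coefficient (rate ratio 0) rather than failing.

Oxygen uptake is the rolling least-squares slope of O2 against time
(positive when O2 declines), and the contraction-coupling contrast
compares mean uptake inside versus outside detected events against a
null built by circular shifts of the phase labels, which preserves
both the autocorrelation of the uptake series and the run structure of
the labels.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the analyses assume.

*Gene families* evolve by a birth-death duplication–loss process along
a fixed ultrametric species tree (15 species, 10 clades, root depth 1
time unit; both non-metazoan outgroups included). Default rates in the
drivers are 0.1 duplications and 0.05 losses per lineage per unit time
— enough to produce a realistic mix of 1:1, 1:many, many-to-many and
lost lineages without routinely extinguishing families. The simulation
is gene-tree-first: no sequences evolve, so the recorded event history
is an exact oracle for orthology truth. Extinction of every lineage is
a reported outcome, not an error.

*Proteomes* draw domain and linker residues uniformly and tail
residues from a specified composition (default P = 0.2, S = 0.15,
Q = 0.1 — a P/S/Q-rich tail of the kind that makes bHLH-PAS C-termini
hard to align). Planted degrons overwrite the tail at requested
offsets; chance strict-consensus matches elsewhere are scrubbed (a
constrained position outside any planted window is set to N, a residue
no constrained slot accepts), so the truth record lists exactly the
planted strict hits while the composition-driven core background
remains.

*Experiments* sample a 30 s cadence over a stepped %AS schedule
(default 100 → 10 → 5 → 2 over four days). Contraction onsets are a
Poisson process per plateau thinned to a 20 min refractory gap after
each 30 min raised-cosine dip; the default rate is 12 events/day at
and above 4 %AS and 0 below — the cessation pattern the physiology
module is meant to detect. Thinning makes the kept process a renewal
process with inter-event time D + Exp(λ), so tests compare counts
against T/(D + 1/λ), not λT. Full-body amplitudes are drawn from
0.55–0.8 and sub-contraction amplitudes from 0.15–0.4 of baseline area
(conventions; the emulated experiments report no amplitude
distribution). The O2 trace relaxes exponentially (τ = 30 min) toward
each step. Frames render an ellipse (axis ratio 3:2) whose area tracks
the trace at intensity ≈200 on a ≈30 background, emulating a pale body
against black felt; optics, lens distortion and illumination drift are
not modelled.

What passing these tests shows — and what it does not: the suites
demonstrate that each inference stage recovers the truth its generator
defines, under that generator's assumptions (ultrametric divergence,
rank-preserving scores, i.i.d. or composition-driven residues, clean
step schedules). They do not certify performance on real data, where
alignment error, assembly incompleteness (transcriptome-only species
can make a true presence look like absence), non-clocklike evolution
and illumination artefacts all intrude. The presence-absence machinery
deliberately records absence agnostic of assembly completeness.

## Numerical choices and problem sizes

Determinism: every stochastic routine takes an integer seed and
restores the caller's RNG state; identical seeds give byte-identical
outputs. Thresholds are inclusive where the corresponding tool
convention is inclusive (e-value ≤, bitscore ≥, LFC ≥ / ≤ −, adjusted
p strictly <). Best-hit ties break by e-value then lexicographic id;
overlap-resolution ties keep the earlier-starting hit.

The test and driver suites use problem sizes chosen to exercise the
asymptotics while staying desk-scale: 500 duplication-loss families
for verdict recovery (observed recovery is well above the 95%
criterion), 200 loss-free families for exact label equality, 30
families × 3 species pairs for RBH precision/recall, 100 one-day
replicates at 5% baseline noise for detector F1, and 200 replicates
each for the rate model's type-I error (nominal 5%) and power
(rates 10 vs 2 events/day across 8 individuals). Exhaustive k-mer
enumeration backs the motif expectation on reduced alphabets (6
letters for the strict octamer, 4 for the core tetramer).

## Known limitations

- The overlap rule under-counts duplications after complementary
  losses; verdict recovery is correspondingly below 100% (but above
  95%) at the simulated rates.
- The fixed-intercept Poisson model conditions on individuals; it does
  not estimate between-individual variance, and its LRT relies on the
  usual asymptotics (adequate at the simulated counts, as the type-I
  suite shows).
- The i.i.d. motif null ignores residue runs; the permutation null
  ignores them differently (it destroys runs). Agreement between the
  two is itself informative.
- Segmentation assumes a single bright body on a dark background;
  multiple animals, reflections or lighting changes must be handled
  upstream (gaps propagate as missing values).
- No numeric equivalence with any particular MATLAB edge-detection
  output is claimed; the imaging module is validated against its own
  rasterization oracle and internal-consistency properties.
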