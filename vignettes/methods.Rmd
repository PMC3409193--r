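---
title: "Models and methods behind paralogr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind paralogr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogr)
```

`paralogr` reconstructs the history of a multi-paralog gene family —
which genes are orthologs, when the duplications happened relative to
speciations, and where gene conversion has overwritten the record. This
vignette explains the models, the tunable parameters and their defaults,
the numerical choices, what the simulator does and does not emulate, and
the known limitations. Throughout, alignment coordinates are 0-based and
half-open, `N` is treated as missing everywhere (excluded from
distances, similarity and parsimony state sets — a conservative choice
where the convention is not dictated by the method), and region maps are
4-column TSVs (`region`, `start`, `end`, `frame`) with `frame` the
GFF-style phase of coding regions.

## Distances with composite parameter sharing

`pairwise_distance(x, "tn93cl")` implements the defining idea of
maximum-composite-likelihood distances: substitution parameters are
estimated *once* from the whole alignment and shared across pairs,
rather than refit per pair. Concretely, base frequencies are the pooled
empirical frequencies; the two TN93 transition/transversion rate ratios
come from pooled pair counts through the standard TN93 component
estimators; each pair's divergence is then the unique `d` solving
`p(d) = p_obs`, where `p(d)` is the expected difference proportion under
the shared TN93 model (monotone in `d`, solved by `uniroot` to 1e-12)
and `p_obs` is the pair's observed mismatch proportion under pairwise
gap deletion — a column counts for a pair only when neither member holds
a gap or `N`. This is a method-of-moments estimator, not per-pair
maximum likelihood: it captures the parameter-sharing substance with a
tractable, testable form, and the simpler `"p"`, `"jc"` and `"k2p"`
models remain selectable as oracles. Variances use the delta method,
`var(d) = p(1-p) / (n p'(d)^2)`, with `p'` evaluated by a symmetric
difference (step 1e-6). Saturated pairs (observed `p` at or above the
model plateau) and pairs with zero comparable sites are reported `NA`
with a warning, never silently dropped.

Ortholog assignment takes, for each gene and foreign species, the
minimum-distance partner; ties within 1e-9 are *reported as ambiguous*,
with both candidates listed, and two genes claiming one partner are
flagged as conflicts — assignment problems are surfaced, not resolved
arbitrarily, because downstream interpretation leans on the assignments
being unambiguous. The margin to the second-best candidate quantifies
that. Neighbor-joining is delegated to `ape::nj()` (with the closed-form
three-taxon star resolved in-package); for additive matrices the tree
realises the input exactly, which the tests exploit.

Chimeric duplicates — a new paralog whose 5' and 3' portions descend
from two different parents, as produced by unequal crossing-over within
a gene — are diagnosed by `per_region_nearest()`: distances are refit
within each region, and a gene is flagged when its 5' block and 3' block
of regions have different nearest same-species parents, each consistent
over at least two contiguous regions. Regions under 100 sites are marked
low-confidence and excluded from the flag, since per-region distances on
short regions are too noisy to anchor a breakpoint.

## Site classification and degeneracy

`classify_sites()` labels each column with the number of distinct
non-gap states, the parsimony-informative flag (two states each in two
or more sequences), the unconstrained minimum changes (`states - 1`),
and the Fitch count on the supplied topology. A column is *supporting*
when informative and achieving the minimum, *homoplasic* when the tree
demands parallel or reverse changes (steps exceed the minimum).
Homoplasy is always judged against the supplied topology — the
classification is tree-relative by construction. Fitch counting encodes
states as bitmasks and roots the (binary) input arbitrarily; the count
is invariant to rooting, and multifurcations are resolved arbitrarily
before counting (exact only for binary trees, which is what the package
produces and consumes). For coding regions the synonymous flag marks
columns whose observed complete codons all translate identically;
gap-containing codons are excluded — the handling of such codons in exon
analyses is genuinely open, and exclusion is the conservative choice.

Third-position degeneracy is assigned *pairwise*: a site enters the
two-fold set only when both sequences' codons make it two-fold. This
mirrors the pairwise procedure of the underlying counting method and
avoids artifacts where one lineage's codon context has shifted the
degeneracy class. Stop codons warn and are excluded.

## The TREx clock on two-fold sites

Third positions of two-fold degenerate codons toggle between two silent
states (AT-type vs GC-type). With stationary bias `(p1, p2)` the
identity fraction of a pair decays from 1 to the equilibrium identity
`q = p1^2 + p2^2` (0.5008 at the default 0.52/0.48 bias):

```
f2(T) = q + (1 - q) exp(-2 r T / (1 - q))
```

The calibration constant `1/(1-q)` in the exponent is chosen so the
*initial* decay rate of f2 equals `2r` per year — two lineages each
accumulating silent substitutions at the rate constant `r` (default
3.1e-9 substitutions/site/year) — which both keeps the quoted rate
constant in its stated units and makes the model exactly the two-state
Markov chain the simulator draws from. `trex_date()` inverts the decay
in closed form; the tests check agreement with a numeric root-finder to
1e-9 relative error and strict monotonicity. Whether a clock of this
kind reports time since the common ancestor or summed branch time is a
convention that differs between presentations; both are supported
behind `time_scale`, with `"divergence"` (time since the common
ancestor) the default. Confidence intervals propagate the binomial
error of f2 through the monotone inversion; `f2 <= q` is reported as
saturation, not a number.

Reference introns qualify as neutral clocks only after screening:
overlap with long conserved noncoding sequence, distance to the nearest
telomere below 15 Mbp, or high GC content disqualify a locus
(`filter_reference_introns()`). The GC cutoff defaults to 45%: the
screening that motivated it removed loci at 47% and above and retained
38.5%, but printed no threshold, so 45% is this package's documented
default, not a claim about the original choice. Presence in an mRNA
database is retained by default because the screened data showed it does
not imply functional constraint. `place_duplications()` then compares
the paralog divergence mean against each split's ortholog distribution:
verdict `before`/`after` by sign of the difference, `unresolved` when
the difference is inside one pooled standard deviation (a deliberately
blunt rule — with handfuls of loci per split a formal test would
overstate resolution; the Welch statistic is reported alongside for
reference).

## Similarity scan

The scan scores identities 1 and mismatches 0 inside a sliding window
(default 250 nt for intronic data; 150 nt is the exonic convention),
skips sites gapped in the pair, and reports no score when gapped sites
exceed 20% of the window. The score denominator is the window width
minus skipped sites; a final partial window is not scored, keeping the
denominator semantics fixed. The step defaults to 1 nt — the original
calculator's step is not recorded, and a 1-nt step dominates coarser
choices at negligible cost, producing the continuous curves the method
is known for. Candidate regions are maximal runs of consecutive scored
windows strictly above the threshold (default 0.96, stored in
`scan_params()` rather than hard-coded; it sits above the
0.938 ± 0.018 background similarity of orthologous introns that
diverged at the human/macaque split, so super-threshold windows mark
conversion more recent than that speciation). With gaps disallowed the
windowed score equals one minus the window's p-distance, which the
tests use as a cross-module oracle.

## Micro-indels as characters

Maximal gap runs with identical start and length in two or more
sequences are coded as shared binary presence/absence characters;
singletons are retained but flagged uninformative. A sequence whose own
gap strictly engulfs a character's span is scored missing (`.`) — the
smaller indel's presence is unobservable there — and missing leaves are
free in the Fitch count. The "micro" cutoff defaults to 100 nt; the
term has no fixed definition, so the bound is configurable and logged.
Only shared characters enter topology comparison (`shared_indels()`
then `compare_topologies()`), matching the definition of an informative
indel; totals are invariant to leaf order and rerooting, and the
brute-force enumeration oracle pins the counts exactly on small trees.
Homoplasic characters (informative, more than one step) are
co-localised with candidate similarity regions; a region corroborates a
character when they overlap and both members of the region's pair carry
the gap.

## Sawyer-style conversion statistic

Within a species group, polymorphic sites are the columns with two or
more distinct non-gap states. For each pair, the match/mismatch
sequence over those sites is scored +1 per match and `-penalty` per
mismatch; all maximal-scoring segments (Ruzzo–Tompa) are fragments,
filtered by minimum span, polymorphism count and score. The published
parameter set is preserved verbatim as defaults (G-scale 1, minimum
fragment length 1 nt, minimum polymorphisms 2, minimum score 2, at most
one overlapping fragment). The mismatch penalty follows the formulation
where the penalty grows with the group's polymorphism count:
`penalty = 1 + n_poly / g_scale`, infinite at `g_scale = 0` (no
mismatch tolerated). The exact constant in the original program is
version-specific, so it is isolated here, documented, and overridable
via `mismatch_penalty`; score-for-score equality with any particular
external binary is not guaranteed, and the statistic is reimplemented
rather than wrapped precisely so that its behaviour is testable.

P-values come from permuting the order of the group's polymorphic-site
columns — destroying linear clustering while preserving per-site
frequencies — with `p = (1 + #null >= obs) / (1 + B)` and Bonferroni
correction across the group's pairs. Permutation and correction are
within-species: cross-species comparisons would mix divergence scales
and inflate the null. A degenerate null (all observed best scores zero)
reports `p = 1` with a warning. At the default `B = 1000` the smallest
attainable corrected p for a six-pair group is ~0.006, comfortably
below the 0.05 alpha.

Evidence integration is two-tier: a *recent* call is a super-threshold
similarity region with at least one corroborating indicator in the same
region for the same pair (homoplasic indel, significant fragment, or an
imported external-method region via
`read_conversion_annotations()` — external phylogenetic-incompatibility
and bootscan detectors are accepted as annotations, not reimplemented);
a significant fragment without a super-threshold window becomes an
*ancient* call, reported separately because the similarity signal decays
first; super-threshold regions without corroboration are listed as
uncorroborated candidates but not called. Overlapping same-pair calls
merge with union extent and combined evidence.

## The simulator

`simulate_family()` is a forward simulator on a species tree with branch
lengths in years. Substitutions use exact TN93 transition probabilities
over each inter-event interval (so chained intervals compose exactly);
micro-indels arrive as a Poisson process per site-year with geometric
lengths (default mean 4 nt, cap 100 nt), insertions adding columns to
the global alignment and deletions leaving gap columns; duplications
clone a gene — or splice a chimeric fusion of two co-resident parents —
losses remove one; conversions overwrite the recipient's tract with the
donor's current sequence, with geometric tract lengths reflecting the
reported range from a dozen nucleotides to several thousand, the donor
drawn uniformly among co-resident paralogs unless configured. Column
identities persist through insertions, so the emitted alignment *is*
the true alignment and every truth record (conversion tracts, indels,
gene tree with duplication/speciation labels, pairwise divergence
times) carries final alignment coordinates. Emitting the true alignment
is deliberate: it isolates the inference modules from aligner noise,
the same role a manually optimised alignment plays in real analyses.
What the simulator does **not** emulate: alignment error, selection
(dN/dS), rate heterogeneity across sites and lineages, and
population-level (coalescent) variation. Passing tests therefore
demonstrate correctness of the inference machinery under its own model
assumptions — not robustness to misalignment or selection, which real
data add on top.

The presets in `make_family()` define the study regime used throughout
the tests: a three-species tree (two catarrhine-like tips splitting
30 Myr ago, their ancestor splitting from a platyrrhine-like tip
43 Myr ago, a 5 Myr pre-speciation root branch), four paralogs created
at 1–3 Myr on the root branch (rapid succession before the deepest
split), one lineage-specific loss, ~12.5 kb of "intronic" sequence in
eight regions, substitution rate 1.4e-9/site/year with transition bias
2 — chosen so pairwise divergences span ~0.08–0.16, the regime of the
motivating data — and, per preset, a chimeric duplicate, a recent
800-nt conversion tract (planted 5 Myr before present, carrying ~10%
internal polymorphisms), or nothing (the null family). The
`small_family` preset (3 kb, two species) is the fast replicate unit
for permutation-test calibration. These values were fixed once from the
study regime and are not tuning knobs.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` measure: Fitch vs exhaustive
enumeration on 1000 random binary characters over 4–8-leaf trees
(exact); NJ recovery from 20 random additive matrices (exact) and 100
simulated 50-kb five-taxon families at pairwise divergences 0.06–0.18
(≥95% recovery); clock inversion on a 0.55–0.99 f2 grid (1e-9
relative) and divergence-time recovery over 200 simulated pairs of 500
two-fold sites (median within 10%); permutation-test size over 500 null
groups at B = 200 (binomial envelope of alpha = 0.05); and conversion
power over 25 planted 800-nt tracts with B = 300 (recall ≥ 0.8, tract
Jaccard ≥ 0.5), with eight null families checked for zero recent-tier
false calls. These sizes are the package's documented operating points;
larger runs only sharpen the same estimates.

## Known limitations

* The composite TN93 estimator shares parameters but is not per-pair
  ML; distances on heavily saturated pairs go `NA` rather than being
  extrapolated.
* Parsimony (nucleotide and binary) ignores ambiguity codes beyond `N`
  and treats multifurcations by arbitrary resolution.
* The fragment statistic's mismatch penalty is one documented member of
  a family of program-specific variants; p-values are calibrated by
  permutation regardless, but fragment scores need not match any
  specific external program release.
* Conversion calls inherit the similarity threshold's blind spot:
  tracts older than the threshold's calibration horizon surface only
  through the ancient tier, and tracts much shorter than the window
  rarely lift a full window above threshold.
* The worked-example reference tables carry published summary values;
  fields the source never printed (telomere distances of retained loci)
  are synthetic placeholders and are marked as such in the bundled
  file.
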