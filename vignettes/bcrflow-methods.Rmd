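---
title: "Methods: models, thresholds and design choices in bcrflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, thresholds and design choices in bcrflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcrflow)
```

`bcrflow` analyses annotated immunoglobulin heavy-chain rearrangements
sampled longitudinally from blood and gut mucosa. This vignette records
the models it implements, the tunable parameters and their defaults, the
numerical choices, what the synthetic generator does and does not
emulate, and the design decisions taken where the method left room.

## Input model

The unit record is one unique rearrangement observed in one sample: V and
J calls, CDR3 amino acids, a productive flag, a copy number (reads
collapsed upstream), the number of V-gene mutations and the sequenced V
length, and optionally the explicit mutation set (position plus
substitution relative to germline). Upstream read QC and germline
alignment are out of scope: the package consumes their output. V/J calls
are collapsed to gene level (allele suffix stripped) for all grouping —
clone definitions in this ecosystem operate on genes. "Functional" is
taken to mean the productive flag (in-frame, no stop codon).
Rearrangements failing basic invariants (copy number below 1, mutation
count exceeding V length, a mutation set whose cardinality disagrees with
the count) are dropped and tallied rather than silently repaired.

Sample metadata carries patient, tissue, post-operative day (POD),
histological rejection grade, parent-gate event count and chimerism
percentage. Repertoire analyses run on quiescent samples only by default:
grades `none` and `indeterminate` are kept, mild-or-greater cellular
rejection and antibody-mediated rejection are excluded. Indeterminate is
treated as quiescent because the exclusion rule is phrased as "mild or
greater".

## Clonal inference

Two sequences belong to one clone when they share V gene, J gene and CDR3
length and their CDR3 amino-acid identity (matching positions divided by
the common length) is at least 0.85. Within each (V, J, length) bucket
the package applies **single linkage**: clusters are the connected
components of the ≥85% identity graph. Single linkage is the closest
published behaviour for "combine sequences with at least 85% similarity",
it is deterministic, and it is independent of input order; clone ids are
additionally canonicalized by sorting on (V, J, length, smallest member
CDR3, smallest member id) so that reruns and permuted inputs produce
identical tables. Exact partition parity with the original
database-driven clustering is not claimed — the normative surface is the
85% pairwise rule itself, which the test suite checks against a
brute-force all-pairs oracle on hundreds of random buckets. The identity
comparison uses a `1e-9` slack below the threshold so that exact boundary
cases (17/20 = 85%) are included regardless of floating-point
representation.

Vocabulary used throughout: a **unique sequence** is a distinct
`sequence_id` (nucleotide-level collapsing happens upstream); a **unique
instance** is one unique sequence in one sample, and is the unit of clone
size; clone sizes within a time bracket sum instances over all samples in
the bracket. Clone-level mutation summaries are *instance-weighted*
averages, never copy-number-weighted. Boundary inclusivity follows the
printed rules exactly: detectability needs copy number ≥ 2 on a
productive sequence; trunk clones need ≥ 5 mutations each in ≥ 85% of
unique sequences; a "mutated" clone strictly exceeds 2% average mutation
frequency; per-bracket summaries require strictly more than 5 clones;
lineage-mixing eligibility requires ≥ 3 unique sequences and both tissues
sampled.

## Lineage trees

The lineage of a clone is a germline-rooted containment tree over
V-mutation sets. A mutation identifier is (position, germline base,
observed base); two unique sequences with identical sets share one
populated node and pool their tissue labels, because nodes represent
genotypes while instances carry provenance. The parent of a node is the
node with the largest mutation set that is a strict subset of its own;
when two siblings share mutations their parent lacks, an unpopulated
ancestor is inferred at their pairwise intersection, and this is iterated
to a fixed point. Only intersections actually needed are created, which
keeps the tree minimal and stable under permutation of the input; parent
ties are broken by set size then lexicographically, making builds fully
deterministic. Conflicting substitutions at one position within a single
genotype are rejected as contradictory input. CDR3 mutations are not part
of lineage sets (only V-region mutations are annotated upstream). This is
deliberately not a phylogenetic reconstruction — no likelihood model, no
reversions, no isotype awareness — it is the containment structure the
mixing metric needs.

## Clumpiness

Clumpiness quantifies how mixed two tissue labels are within one lineage,
on [0, 1]. The published description pins down the extremes (0 =
separated on different branches, 1 = highly mixed within branches) but
defers the formula to external code; the implementation here is a
re-derivation chosen to satisfy every stated property, and numeric parity
with the original implementation is not claimed. The rule: every instance
of one label at populated node $u$ scores $2^{-d}$ where $d$ is the edge
distance to the nearest populated node carrying the other label ($d = 0$
if $u$ carries both); any path through the germline root scores 0, since
labels meeting only at the root are on different founder clades; the
clumpiness is the mean score over all instances of both labels. Edge
distances count unpopulated inferred nodes. Instances are multiset
entries — a node sampled twice in blood contributes two blood instances.
The metric is symmetric, invariant to labels outside the queried pair,
and undefined (`NA`, distinct from 0) when a label is absent. Per-patient
medians are reported only when more than 5 clones contribute.

## Diversity, evenness, cosine similarity

Diversity uses Hill numbers on clone-size proportions,
$D_q = (\sum_i p_i^q)^{1/(1-q)}$, with the entropy limit
$D_1 = \exp(-\sum_i p_i \ln p_i)$ at $q = 1$ (natural log; the limit is
base-independent). $D_0$ is richness; $D_q$ is non-increasing in $q$ and
scale-invariant. Because $D_q$ has a nonzero derivative in $q$ at 1 for
non-uniform distributions, the continuity of the $q = 1$ branch is tested
with a symmetric evaluation at $1 \pm 10^{-6}$ (averaging cancels the
first-order term), not a one-sided difference. Evenness is $D_1 / D_0$.

Cosine similarity compares clone-size vectors of two slices of the same
patient over the **union** of clone ids, with absent clones as zeros —
the union convention is what makes "no shared clones → 0" hold; whether
the original analysis used union or intersection support is not stated,
and union was chosen for exactly that limiting behaviour. Clone identity
across slices comes from a single clonal-grouping run on the patient's
pooled records; cross-patient cosine is undefined because clones are
never shared between individuals.

## Longitudinal statistics

PODs map to brackets as pre = 0, early = 1–90, mid = 91–365, late > 365.
One published figure describes "early" as POD 0–90; the conflict exists
only at POD 0, where samples are pre-transplant by definition, so the
pre = 0 convention is used everywhere and a pre-transplant sample is
recognized by its day, not a separate flag.

The clone-size **sign test** between two brackets counts clones present
in both that grew (+) or shrank (−), excludes unchanged clones, and
reports the exact two-sided binomial p at one half (doubled smaller tail,
capped at 1). With zero informative clones the result is `NA` with a
classed warning rather than a fabricated value. The **Mann–Whitney U**
comparison is exact (via the U distribution) when the combined sample is
≤ 20 without ties, and a tie-corrected normal approximation otherwise; a
degenerate variance returns p = 1. Both are implemented directly so their
definitions are explicit, and both are cross-checked in the tests against
full enumeration (and `wilcox.test`) — the library route is the oracle,
not the implementation.

**Chimerism AUC** is the trapezoidal area under (POD, percent) within a
bracket divided by the days of measurement (last minus first POD), which
keeps the value on the percent scale and inside the range of the data; no
extrapolation beyond observed points, at least two points required,
points below 40 parent-gate events removed first. **DSA positivity** uses
the printed increments — +2,000 MFI over baseline for serum, +500 for
concentrated supernatants — read inclusively ("exceeded by 2,000" =
reaching the stated increment); this interpretive choice is isolated in
`call_dsa_positive()`.

## Synthetic data: the stated world

The generator emulates the *output* of an upstream QC/alignment/collapse
stack, not sequencing itself. Per clone it draws toy V/J genes and a
14–20 aa CDR3, grows 2–6 genotypes by a branching process that adds
1 + Poisson(`shm_rate` = 2) fresh V mutations per step (sampled without
replacement from positions 80–319 of a 240-nt post-trim V region, so
containment is exact by construction) to a depth cap of 4. Founder clades
alternate between blood and ileum; each genotype is sampled in both
tissues with probability `tissue_mix` and otherwise only in its clade's
tissue — at `tissue_mix = 0` every lineage splits into tissue-pure root
clades (clumpiness exactly 0), at 1 every populated node carries both
labels (exactly 1). Per tissue, early-bracket sizes are the eligible
genotype count plus a Pareto-tailed excess governed by
`clone_size_exponent` (0.7 by default; larger values give heavier tails
and lower evenness), with every eligible genotype sampled at least once
in the early bracket so label coverage is guaranteed; sizes then move
between consecutive brackets by ±(1 + Poisson(0.5)) with growth
probability `growth_bias` (0.5 = no drift). Copy numbers are shifted
geometric with mean 2, so roughly half of instances clear the
detectability bar; 97% of rows are productive. Chimerism follows logistic
replacement curves (midpoint day 60, steepness 0.05/day, asymptote 95%,
±3% bounded noise): donor chimerism in blood falls, recipient chimerism
in the graft rises — the ≥ 80%-replacement-within-a-year regime. The
default scale is 5 patients × 200 clones and runs in seconds; the test
and acceptance suites use the defaults or smaller.

What the generator does **not** emulate: real germline gene databases,
indels, selection, class switching, sequencing error, uneven sampling
depth, or inter-patient sharing of clones. A green test therefore
establishes that the analysis code implements its definitions and
recovers planted structure — not that it would reproduce any particular
cohort's biology.

## Numerical choices and degenerate inputs

Threshold comparisons at printed boundaries use a `1e-9` tolerance in the
inclusive direction only. Undefined quantities are `NA` with classed
conditions (`bcrflow_no_informative_clones`, `bcrflow_auc_undefined`),
never silent zeros, because 0 is a meaningful value for every metric
here. All analysis code is randomness-free; only the generator consumes
the seed, and a seed fully determines its output, so the end-to-end
report is byte-reproducible (checked in the tests) and every report
directory carries a manifest with the thresholds and input digests used.

## Known limitations

Clumpiness and lineage construction are re-derivations against stated
properties, not ports, so single-tree numeric parity with the original
tools is not guaranteed; clonal grouping is gene-level only (no
allele-aware germline inference, no nucleotide-level clone splitting);
diversity is reported without rarefaction or bootstrap intervals; p-values
are unadjusted for multiplicity, matching the source analysis.
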