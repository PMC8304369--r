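---
title: "Classifying TAP families and reconstructing their evolution"
author: "tapfams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying TAP families and reconstructing their evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapfams)
```

## The problem

Transcription-associated proteins (TAPs) — sequence-specific transcription
factors (TF), transcriptional regulators acting through chromatin or core
complexes (TR), and putative TAPs (PT) — are routinely annotated by scanning
a predicted proteome against a library of profile hidden Markov models, one
per diagnostic protein domain. Family membership is not a one-domain-one-family
lookup: a family is defined by the domains its members *must* carry together
with domains whose presence *disqualifies* a protein (multi-domain proteins
would otherwise be claimed by several families at once). `tapfams`
implements this rule-based classification and the comparative machinery
built on top of it: families-by-species count matrices, group statistics,
ordination, and ancestral family-size reconstruction on a species tree.

## From domain hits to family calls

The input is HMMER3 per-domain output (`--domtblout`), read by
`readDomtbl()`. Two filters decide whether a raw domain match counts as
domain *presence*:

* **Gathering (GA) threshold** — the per-profile minimum bit score. The
  comparison is inclusive (`score >= GA`), since GA is by construction the
  *suggested minimum* score. Two tuned values shipped with the demonstration
  library are 9.45 bits for `zf-C2H2` and 14.00 bits for `HLH`; the others
  are ordinary PFAM-style gathering cutoffs supplied per profile.
* **Model coverage** — the fraction of the profile's match states spanned by
  the hit, `(hmm_to - hmm_from + 1) / model_length`. Coverage is measured on
  the model side because the threshold is a property of the profile, not of
  any particular protein. Most profiles carry no coverage cutoff; the short
  bZIP-refinement profiles use 0.75 (`bZIP_AUREO`) and 0.50 (`bZIP_CDD`),
  again inclusively.

The GA filter is applied to the per-domain bit score (not the full-sequence
score): presence of a *domain* is what the rules consume, and the per-domain
score is the quantity HMMER attaches to that claim.

Classification then evaluates, per protein, every family rule over the
surviving hits (`classifyProteome()`):

* a family is a **candidate** iff each of its `should` domains has at least
  one surviving hit and none of its `should not` domains has any;
* a *vetoing* hit must itself survive the filters — a sub-threshold match of
  a forbidden domain is not evidence of that domain;
* competing candidates are resolved by the smallest independent per-domain
  E-value over the family's `should` hits, with exact ties broken
  alphabetically for determinism;
* each protein is assigned to at most one family.

The veto mechanism is what makes multi-domain proteins tractable. The
canonical case: a protein carrying both a PHD finger and an HMG box gets a
stronger E-value from the PHD profile, so E-value resolution alone assigns
PHD. Adding `HMG_box` as a forbidden domain to the PHD, CCAAT_HAP5 and
SWI/SNF_SNF2 rules removes those candidacies, and the protein resolves to
HMG:

```{r hmg}
h <- data.frame(protein_id = "p1", domain = c("PHD", "HMG_box"),
                full_seq_evalue = c(1e-12, 1e-10),
                domain_ievalue = c(1e-12, 1e-10), domain_score = 25,
                hmm_from = 1L, hmm_to = c(52L, 70L),
                ali_from = 1L, ali_to = c(52L, 70L))
classifyProteome(h, demoProfileLibrary(), demoRuleSet(2))$family  # "PHD"
classifyProteome(h, demoProfileLibrary(), demoRuleSet(3))$family  # "HMG"
```

Rule tables are plain text, one semicolon triplet per line
(`family; domain; should`, `family; domain; should not`, plus an optional
`family; TF; class` line). Only these rule kinds exist; anything else is
rejected loudly rather than silently skipped, so a catalogue written for a
richer dialect cannot be half-read.

## Count matrices, group tests and PCA

`genomeTapProfile()` collapses one proteome's assignments to per-family
counts and `buildCountMatrix()` assembles several genomes into a
families-by-species `TAPCountMatrix` (a `SummarizedExperiment`; rows are
families, columns are species codes, missing pairs are zero).

Before ordination the catalogue is restricted to families actually observed
in the clade of interest (`selectFamiliesWithPresence()`: keep a family iff
it has at least one member in at least one focal species).

`compareGroups()` compares one family (or the per-species totals,
`"total"`) between two species groups. Because TAP family sizes are small
counts in handfuls of genomes, the test choice is gated: each group is
screened with a Shapiro–Wilk test, and only if both groups are consistent
with normality (default `alpha_normality = 0.05`) is a two-sample t-test
used; otherwise a two-sided Wilcoxon rank-sum test. For the sample sizes
this package targets (3–6 genomes per group) the Wilcoxon p-value is exact
(no ties, n ≤ 10); with ties or larger groups it falls back to the normal
approximation with tie correction. The gate is applied per group by
default; `pool_groups = TRUE` screens the pooled mean-centred values
instead, for users who read "the data" as one sample. Perfectly constant
data cannot be screened at all and is reported as `p = 1` with a
`degenerate` flag rather than an error, so batch runs over many families
survive all-zero rows.

`runPCA()` treats species as observations and families as variables,
centres columns, and does not scale to unit variance by default — family
size differences are the signal, and unit scaling would let near-constant
families dominate. Scaling is available as a flag. Component signs are
fixed (largest-magnitude loading positive) so that repeated runs and
family reorderings give identical score tables.

## Ancestral family sizes by asymmetric Wagner parsimony

Family sizes on a rooted species tree are reconstructed by minimising total
branch change, where a one-copy increase costs `gain_penalty` (default 1)
and a one-copy decrease costs 1. The default of 1 mirrors the documented
default of the established gene-content parsimony tools; making gains
relatively expensive (`gain_penalty > 1`) biases reconstructions toward
loss-heavy histories, and the flag is exposed everywhere
(`--gain-penalty` on the command line).

The optimum is found by Sankoff-style dynamic programming over the integer
states `0..max_state`, with `max_state` defaulting to the largest observed
count plus two. Bounding is exact, not an approximation: the per-branch
cost is convex and monotone on either side of the leaf range, so no optimal
labeling ever uses a state above the largest observed count (the two slack
states exist only so that a binding bound would be visible). TAP families
are small (tens of copies at most), so the DP is fast at
`O(edges × max_state²)` and no piecewise-linear machinery is needed. An
independent exhaustive enumerator, `bruteForceReconstruct()`, shares the
cost definition but none of the machinery and anchors the test suite.

Among equally parsimonious labelings each node takes the **smallest**
optimal state in a top-down pass. This is deterministic and conservative
about ancestral gene content; its one visible consequence is discussed
below.

Per-branch events are classified mutually exclusively from the parent state
*s* and child state *t*: **gain** (s = 0, t ≥ 1), **loss** (s ≥ 1, t = 0),
**expansion** (t > s ≥ 1), **contraction** (s > t ≥ 1), else none. A
0 → 2 branch is one gain, not a gain plus an expansion; multi-copy changes
count once, by category. `summarizeOverFamilies()` totals events over
families, overall and within named node groups (a branch belongs to its
child node), which is how clade-restricted subtotals such as "events within
the red algae" are produced.

```{r wagner}
tr <- ape::read.tree(text = "((A,B),C);")
fit <- wagnerReconstruct(tr, c(A = 3, B = 1, C = 1))
totalCost(fit)
classifyBranchEvents(fit)
```

## The synthetic generators, and what passing tests mean

Real inputs to this pipeline are produced upstream (hmmsearch, genome
annotation); the package therefore ships generators that emit the same
formats with recorded ground truth.

`generateHits()` plants, per protein, either a clean family signature (one
confident hit per required domain) or a decoy, realised two ways so both
rejection paths are exercised: a sub-GA hit of a required domain (dies at
the filter) and a valid required-domain hit paired with a valid forbidden
hit (dies at the veto). Written `domtblout` files round-trip exactly
through `readDomtbl()` because generated scores and E-values are drawn at
the format's printed precision. What these fixtures deliberately do *not*
model: borderline scores drifting across the GA cutoff, partial/fragmented
domains, or correlated domain architectures — 100% label recovery on them
validates the engine's logic, not the biological error rate of any real
annotation.

`generateHistory()` simulates family-size histories: a random bifurcating
tree, root counts in 0..3 (small families, the realistic TAP regime), and
per-branch events — gains to 1–2 copies from absence, losses to zero, or
one-copy shifts — at low per-branch rates (defaults 0.006/0.003/0.005),
with tip counts capped at 10 copies. The recovery benchmark runs 500
families on 30-leaf trees (the species count of a typical multi-clade
comparative study) in the rare-event regime (`max_events_per_family = 1`).
Recovery of planted events clears 95% but is structurally short of 100%,
for a reason worth knowing: a loss (or contraction) on a branch
incident to the root has an equally parsimonious mirror image — the family
instead absent (or smaller) at the root and gained (or expanded) on the
sibling branch — and the smallest-state tie-break deliberately prefers the
mirror. Events deeper in the tree do not suffer this ambiguity. The same
caveat applies to real data: direction of change at the root is not
identifiable from parsimony alone, which is why outgroups matter.

## Numerical and design choices

* All threshold comparisons (GA, coverage) are inclusive.
* The augmentation planner for rebalancing biased seed alignments caps new
  sequences at `floor(0.25 × seed size)` — the quarter is measured against
  the *original* seed, and flooring never lets the cap round up past a
  quarter. Candidates are tiered so every (taxon group, species) pair is
  represented before any species repeats; only the last, partially fitting
  tier is thinned at random, under a caller-supplied seed, after
  distributing its slots round-robin over groups. Sequence completeness is
  an input flag: it records a curator's judgement, which the tool does not
  try to automate.
* Degenerate inputs err early and loudly: unknown domains at filter time,
  missing GA thresholds, duplicate profile names, malformed rule kinds,
  missing leaf counts.
* Test and benchmark problem sizes (200 oracle instances at ≤ 8 leaves and
  counts ≤ 5; 500-protein proteomes; 500 families on 30-leaf trees) were
  chosen as the smallest scales at which every code path and the documented
  failure modes are visible.

## Limitations

* One family per protein. Proteins legitimately belonging to two families
  are resolved, not duplicated; the veto lists are the instrument for
  steering such cases.
* Parsimony reconstructs a minimal history, not a probable one; no
  birth–death model, no branch-length use, and root-adjacent event
  directions are not identifiable (above).
* The shipped rule catalogue is a demonstration set covering the documented
  rule interactions; production use expects a full curated catalogue via
  `readRules()`.
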