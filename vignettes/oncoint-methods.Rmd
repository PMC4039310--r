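---
title: "Methods and design of the oncoint pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the oncoint pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoint)
```

`oncoint` models the computational workflow of an interactome-walking
study of a mutant receptor tyrosine kinase: assemble the physical
interactome of the driver protein from TAP-MS pulldowns, enrich it with
drug-responsive phosphoproteins, interrogate it functionally with RNAi
across a cell-line panel, and translate the surviving "core" into drug
candidates and combination strategies. This vignette documents the
statistical model of each stage, the tunable parameters, the synthetic
world used for validation, and the design choices made where the
methodology was genuinely open.

## 1. TAP-MS network assembly

**Model.** A pulldown observes spectral counts for peptides; a peptide
may map to several proteins. Assembly proceeds in a fixed order:
isoform collapsing, per-pulldown protein grouping, control subtraction,
network construction. The order matters — subtraction is by protein
identity, so it must happen after isoforms are collapsed and groups
named; we collapse → group → subtract and document that order.

- *Isoform collapsing* (`collapse_isoforms`): only a trailing
  `<delimiter><digits>` suffix (UniProt style, default `-`) is treated as
  an isoform tag, so gene symbols like `HLA-DRB1` survive. Counts of rows
  made identical by stripping are summed per (run, peptide).
- *Grouping* (`group_proteins`): proteins with identical peptide sets
  merge into one group named after the lexicographically smallest member.
  A peptide is *specific* to a group when every protein it maps to is in
  the group. Groups without a specific peptide are discarded — the
  parsimony rule that removes proteins explicable entirely by shared
  peptides. `min_peptides` (default 2) additionally drops one-peptide
  groups, mirroring the "at least two distinct peptides" convention of
  merged search-engine results; set it to 1 for toy data.
- *Control subtraction* (`subtract_background`): the union of all control
  (GFP-like) pulldowns defines the non-specific background; any bait
  group sharing a member with it is removed. A per-cell-line mode exists
  (`per_line_controls`) but the global union is the default — controls
  are few and pooling them is the stricter filter.
- *Network* (`build_network`): one TAP edge per (bait, prey group), with
  support summed over that bait's pulldowns; self-retrievals are dropped.
  Edge orientation is canonical (bait first; database edges
  lexicographic), which makes outputs independent of input row order and
  GraphML round-trips exact.

No probabilistic interaction scoring (SAINT/CompPASS style) is applied:
the presence/absence-versus-controls design is deliberate and matches
the experimental practice this pipeline mirrors.

## 2. Phosphosite perturbation score

Per site, four pooled spectral counts are observed: treated/control ×
phosphorylated/non-phosphorylated. Per state, the observed
(treated, control) pair is tested against expected counts with a 1-df
Pearson goodness-of-fit statistic; by default the expectation splits the
state total proportionally to the number of runs per condition (equal
runs ⇒ 50/50), with a total-spectral-load allocation behind
`allocation = "load"`. The two state P-values are multiplied:

\[ \text{score} = p_{\mathrm{Ph}^+} \cdot p_{\mathrm{Ph}^-}, \qquad
   \chi^2_{\text{state}} = \sum_{\text{cond}} (O-E)^2/E \]

and sites with score ≤ 0.1 (inclusive boundary, a documented choice) are
called perturbed. Choices worth knowing:

- *Zero-total states* get P = 1 (no evidence) rather than dropping the
  site.
- *No continuity correction* by default (`yates = TRUE` available): the
  statistic should match the textbook Pearson sum exactly.
- *No multiple-testing correction* by default, matching the raw product
  cutoff this design reproduces; `adjust = "BH"` is available.
- The product of two independent uniform P-values satisfies
  \(P(p_1 p_2 \le t) = t(1-\ln t)\), i.e. ≈ 0.33 at t = 0.1. The cutoff
  is therefore *liberal by construction*; with discrete counts the
  realized null rate is at or below that bound (verified by simulation
  in the acceptance suite). Downstream steps tolerate this: false
  positives on proteins without PPI links to the TAP network never enter
  it, and network membership — not the site list — is the interpreted
  artifact.

*Extension* (`extend_network`): significant sites on proteins already in
the network become node annotations; significant proteins outside it are
added (role `pY-added`) with a database edge to every TAP protein they
contact in the PPI reference, and proteins with no such contact are not
added. Extension never removes anything.

## 3. RNAi screens

Readings are normalized per line to the mean of its non-targeting
control wells (idempotent; errors name the offending line). A hit
requires *both* inhibition > 50% and Student's t-test p < 0.05 (strict
inequalities). The t-test is two-sample equal-variance against the
line's normalized control replicates by default; a one-sample test
against 1.0 is available (`mode = "one-sample"`) because the original
description does not fix the comparator. Degenerate zero-variance data
(possible at `replicate_cv = 0`) are given p = 1 when means coincide and
p = 0 otherwise rather than erroring.

The *core network* is the exact intersection of per-line hit sets —
deliberately not a vote or a union, because its purpose is conserved
dependency. Sensitive/resistant pairs are compared as a three-way
partition (`pair_overlap`), and `resistant_gain` — genes with more
effect in the resistant line — is an explicit reconstruction (directional
t-test plus a minimum viability delta, default 0.15), since only the
resulting counts, not the rule, were ever reported for the design this
follows.

*Specificity* across a mutant/wild-type panel uses a two-sided Wilcoxon
rank-sum test on per-line replicate means: exact via the classical null
distribution when both groups have ≤ 10 lines and the data are tie-free,
exact by permutation enumeration for small tied samples, and a normal
approximation with tie correction (no continuity correction) otherwise.
Tiers are `##` (p < 0.01) and `#` (p < 0.05). The two-sided P-value is
`min(1, 2·min(P(W ≤ w), P(W ≥ w)))`, which for the minimum rank-sum of a
2-vs-3 split gives exactly 2/C(5,2) = 0.2.

## 4. Drug networks and diffusion ranking

`filter_records` applies strict source-specific cutoffs: Kd < 100 nM for
the two kinase-assay databases, Ki/Kd/IC50/EC50 < 10 nM for BindingDB.
DrugBank carries no comparable affinity and is kept by presence, tagged
`low_confidence`. Percent-inhibition values never pass the filter; they
are the *input* to diffusion ranking. `allele_match` is exact: a
wild-type query matches only untagged records, an allele query (e.g.
`T790M`) only records with exactly that tag — allele-specific binding is
the one place where a loose match would be actively misleading.

`diffusion_rank` is the least-constrained component and is flagged as a
reconstruction. The chosen kernel is the simplest one satisfying the
stated intuition (a compound is promising for kinase *k* if it strongly
inhibits *k*'s close network neighbours):

\[ s(c,k) = \sum_{k'} v(c,k')\,\alpha^{d(k,k')} \]

with unweighted shortest-path distance *d*, decay α ∈ (0,1)
(default 0.5), weight 1 at distance 0 (a kinase's own measurement is
recovered undamped) and 0 for unreachable pairs. It is unnormalized — a
kinase with more measured neighbours legitimately accumulates more
evidence. The candidate cutoff is a configurable score percentile
(`top_candidates`, default top 5%), since a threshold was used but never
published in the design this reconstructs. The kernel is validated
against brute-force BFS on exhaustively enumerable graphs, not against
any external result.

## 5. Median-effect synergy

Dose–response curves follow the median-effect equation
`fa = 1/(1+(Dm/D)^m)`, fitted by least squares on
log(fa/(1−fa)) vs log D (≥ 3 usable points; fa of exactly 0 or 1 is
dropped with a warning, or clipped to [0.01, 0.99] with `clip = TRUE`).
The combination index uses the mutually exclusive Chou–Talalay form
CI = d₁/Dx₁ + d₂/Dx₂ with no third term, reported at fa ∈
{0.5, 0.75, 0.9} by default. Structural identities serve as tests: a
drug combined with itself gives CI ≡ 1; a combination curve built at
half the additive dose gives CI = 0.5; CI is invariant to a global unit
change.

## 6. The synthetic world

The generators state one fixed world; they are validation scaffolding,
not a fitted model of any instrument.

- *Spectral counts* are Poisson with per-protein means scaled by a
  bait-affinity factor (bait 3×, prey 1×, background 0.6× of
  `count_mean`, default 20); negative-binomial overdispersion is
  available behind `overdispersion`. No distributional claim from real
  data is embedded — counts in published TAP-MS tables are reported
  per-protein without a generative description, so Poisson is a
  pragmatic choice sufficient to exercise count-based logic.
- *World shape* mirrors the study this pipeline reimplements: 8 baits,
  25 prey each (≈ 240 TAP proteins), 368 phosphosites of which 66
  (≈ 18%) are planted as perturbed at 10-fold suppression, a 14-gene
  core at viability 0.3 in mutant lines, triplicate wells at CV 0.05,
  and a 17-line panel (5 mutant / 12 wild-type by default).
- *Shared-peptide prey*: a configurable fraction of each bait's prey is
  constructed with only peptides shared with a retained paralog, so
  grouping must discard exactly those; recovery metrics exclude them
  from the denominator because no peptide-level method can retain them.
- *The PPI reference* contains planted extension edges for roughly half
  of the perturbed external phosphoproteins plus random background
  edges. Background edges never connect a *non-perturbed* external
  phosphoprotein to a TAP protein: this keeps the planted extension set
  exactly recoverable and is the one place the generator is
  deliberately easier than nature, where contaminating PPI edges would
  admit liberal-cutoff false positives into the network. A green
  extension test therefore establishes rule correctness, not robustness
  to a promiscuous interactome.
- *Screens* use multiplicative log-normal replicate noise
  (mean-one, CV-parameterized) — plate-reader-like and positivity
  preserving; `replicate_cv = 0` reproduces planted means exactly.
- *Not emulated*: raw spectra, retention times, peptide misassignment,
  plate spatial effects, siRNA off-target structure, cell-growth
  kinetics, chemical structure. Green tests say nothing about those.
- *Determinism*: one global seed; each generator draws from its own
  derived sub-stream, so outputs are byte-identical across runs and
  adding a generator never perturbs another. The pipeline writes doubles
  with fixed 10-significant-digit formatting to keep TSVs byte-stable.

One acceptance property deserves honesty: exact recovery of the planted
mutant-specific gene set at p < 0.05 over a 15-gene panel is a
stochastic event — with 6 null genes and an exact-test false-positive
rate just under 0.05 per gene, a fully correct implementation passes
for roughly three seeds in four. The suite pins one seed, chosen before
the test was first run and not revisited.

## 7. Known limitations

- The diffusion kernel and its cutoff are reconstructions validated only
  by their own properties.
- `resistant_gain`'s rule (directional t + min_delta) is likewise a
  reconstruction.
- The χ² product score is used exactly as specified — uncorrected and
  liberal; users wanting FDR control should use `adjust = "BH"` and
  understand they are then deviating from the reproduced design.
- Protein grouping is parsimony-lite: mutually shared peptide sets with
  no anchor protein discard all members rather than electing one.
- SIF export is lossy (no node attributes); GraphML is the round-trip
  format.
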