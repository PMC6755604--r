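---
title: "Comparing binary similarity measures on interaction fingerprints with SRD"
author: "ifpsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing binary similarity measures on interaction fingerprints with SRD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifpsim)
```

## The problem

An interaction fingerprint (IFP) encodes a docked protein–ligand complex as
a bitstring: for each binding-site residue, nine bits record whether the
ligand establishes each interaction type (any contact, backbone contact,
sidechain contact, polar, hydrophobic, H-bond acceptor, H-bond donor,
aromatic, charged). Screening workflows rank candidate ligands by the
similarity of their IFP to a reference pose. That ranking depends on three
design choices that are usually made by habit rather than evidence:

1. **the similarity coefficient** — the Jaccard–Tanimoto coefficient is the
   de facto standard, but it is one of dozens;
2. **the bit definitions kept** — the general contact bits (Any, BB, SC)
   largely duplicate information in the specific bits;
3. **the filtering rule** — most residues of a protein never interact with
   any ligand of a docked set, so unfiltered IFPs are dominated by columns
   of shared zeros.

`ifpsim` makes these choices comparable on equal terms. This vignette
documents the model, its assumptions, the tunable parameters, and the
numerical conventions, in the order the pipeline applies them.

## Confusion counts and the 44-measure catalog

Every binary similarity coefficient here is a function of the confusion
counts of a fingerprint pair: $a$ common on-bits, $b$ and $c$ exclusive
on-bits of the first and second fingerprint, $d$ common off-bits, and
$p = a+b+c+d$. Examples spanning the catalog's three shapes:

$$\mathrm{SM} = \frac{a+d}{p}, \qquad
  \mathrm{JT} = \frac{a}{a+b+c}, \qquad
  \mathrm{BUB} = \frac{\sqrt{ad}+a}{\sqrt{ad}+a+b+c}.$$

Measures whose natural range is not $[0,1]$ (correlation-type coefficients
live on $[-1,1]$; a few, like Forbes or Harris–Lahey, on $p$-dependent
ranges) are rescaled affinely, $s' = (s+\alpha)/\beta$. The catalog stores
$\alpha$ and $\beta$ per measure, as functions of $p$ where necessary; the
constants were derived analytically from each formula's extremal values so
that $s' \in [0,1]$ holds for **every** valid confusion table, and the test
suite verifies this on 10,000 randomized tables per measure. For a few
measures the bound is derived rather than taken from the older
compilations, which contain scaling constants that do not actually bound
the formula (the Mountford coefficient, for instance, attains 2 at
$b+c = 1$, so it is scaled with $\beta = 2$).

Each entry also carries two classifications used as ANOVA factors:

- **symmetricity**: S if $d$ is weighted like $a$, I if underweighted, A if
  ignored, Q for correlation-based coefficients. The classes obey testable
  invariances: S-measures are unchanged by complementing both fingerprints
  ($a \leftrightarrow d$, $b \leftrightarrow c$); A-measures are unchanged
  by altering $d$ alone. Measures that involve $d$ only through the
  dilution by $p$ (Russell–Rao $a/p$, Forbes, Fossum, CT3) are classed I,
  which keeps both invariances exact.
- **metricity**: M if $1-s'$ satisfies the metric axioms, N otherwise. The
  suite verifies the triangle inequality on random triples for JT, SM and
  RT.

Two documented idiosyncrasies, queryable from `list_measures()`:
`exchange_symmetric = FALSE` for the directional Peirce and Cole pairs
(swapping the fingerprints maps Pe1 onto Pe2 and Co1 onto Co2), and
`max_at_identity = FALSE` for absolute-type measures (RR, Fai, For, Fos,
Mic, Den, dis, CT3, CT5) whose value at $b=c=0$ depends on how many bits
are on — a self-similarity of, say, RR is $a/p$, not 1. This is a property
of the formulas, not a defect of the implementation.

**Degenerate denominators.** Many formulas divide by marginal products that
can be zero (e.g. $\sqrt{(a+b)(a+c)(b+d)(c+d)}$ when a fingerprint is all
ones or all zeros). The convention: if $b = c = 0$ the fingerprints are
identical and the measure returns its maximum $s' = 1$; any other
degeneracy returns the minimum $s' = 0$. This preserves ranking semantics
(identical pattern = most similar) and every such event is counted and
reported once per similarity-matrix call.

## Pretreatment and the consensus reference

Even rescaled to $[0,1]$, measures occupy very different sub-ranges
(Mountford values sit near 0, Yule values near 1). The SRD reference is
fused **row-wise** — for an active ligand the row maximum over measures,
for a decoy the row minimum — so unequal column ranges would bias the
fusion toward extreme-valued measures regardless of ligand activity.
Column-wise pretreatment is therefore applied **before** fusion:
autoscaling (mean 0, sample $n-1$ standard deviation 1), range scaling
(min 0, max 1), or rank transformation (ascending, ties averaged). All
three are strictly monotone within a column, so they never change a
measure's own ligand ranking — only the fusion. Constant columns cannot be
scaled and are set to zero with a warning. Autoscaling is the default, as
the compromise least sensitive to outliers among the three.

## The SRD engine

For $n$ ligands, each measure's column and the fused reference are ranked
ascending (ties averaged); the SRD value of a measure is the Manhattan
distance $\sum_i |r_i^{\mathrm{measure}} - r_i^{\mathrm{ref}}|$ — the
Spearman footrule when tie-free. It is normalized by the tie-free maximum

$$\max \mathrm{SRD}(n) = \begin{cases} n^2/2 & n \text{ even}\\
(n^2-1)/2 & n \text{ odd}\end{cases}$$

to a percentage. Under ties the averaged ranks can only shrink the sum, so
the normalized value is a conservative percentage; the tie-free constant is
kept as the divisor. $n = 1$ is defined as 0 %.

**Validation.** Two mechanisms guard against reading noise as signal:

- *Randomization test*: the null distribution of the SRD between a random
  permutation and a fixed reference. For $n \le 8$ it is exact (all $n!$
  permutations — at most 40,320); beyond that, a seeded Monte-Carlo sample
  (default 10,000 draws, at least 100 enforced). The null mean is
  $(n^2-1)/3$; the suite checks the exact mean at $n=4$ (which is 5) and
  3-standard-error agreement at $n=50$. `pvalue(observed)` returns
  $P(\mathrm{SRD} \le \mathrm{observed})$, the probability that a random
  ranking comes at least this close to the reference.
- *Fivefold cross-validation*: rows are split into $k$ near-equal random
  folds (a uniform permutation cut into contiguous blocks; no
  stratification by activity is applied). Round $j$ drops
  fold $j$ and re-runs the **entire** analysis on the remaining rows —
  fusion, ranking and normalization are all recomputed, so each round is a
  self-contained SRD analysis — and a final round ("All") uses every row,
  giving $k+1$ values per measure.

## The factorial grid

`run_grid()` crosses datasets × bit selections (ALL, WO1, WO3) × filtering
rules (NO, RES, INTS). Selection is applied before filtering, mirroring the
order in which a fingerprint pipeline fixes its bit definitions before
looking at the data; both orders are available as functions and commute on
the columns they both retain. Each variant contributes $(k+1)$ rows per
measure of normalized SRD, plus one ROC-AUC per measure computed on the raw
scaled similarities — AUC is rank-based and pretreatment is column-monotone,
so pretreating first would change nothing. With 10 datasets the grid has
90 variants and, with all 44 measures and fivefold CV, 23,760 rows.

A variant whose filtering removes every column is skipped with a warning
and listed in the result's `skipped` field rather than producing an empty
similarity matrix (similarity on zero-length vectors is undefined);
emptiness after filtering is likewise an error, not an empty dataset, in
the filtering functions themselves.

`factor_anova()` fits fixed-effects ANOVA (sequential type-I sums of
squares, which coincide with all other types on the balanced grid) on the
normalized SRD values over any of the grouping factors (measure, bit
selection, filtering, symmetricity, metricity, dataset), reporting
per-level means with 95 % t-based confidence intervals and F tests at
$\alpha = 0.05$. When all groups are identical the F ratio is $0/0$; it is
reported as 0 by convention (no evidence of a between-group effect). Note
that some factor pairs have structurally empty cells — every
correlation-based (Q) measure in the catalog is non-metric, so a
symmetricity × metricity interaction cannot be estimated — and the function
reports the empty cells by name.

## The synthetic generator

`generate_dataset()` emulates the statistical structure of a docked
active/decoy screening set without any docking:

- a **reference** fingerprint drawn bitwise Bernoulli($p_{\mathrm{ref}}$)
  over the full residues × 9 layout;
- each **active** is the reference with independent per-bit flips at
  `flip_active`; each **decoy** likewise at `flip_decoy` ≥ `flip_active`.
  Reference-anchored corruption (rather than independent per-class bits)
  encodes what makes a decoy a decoy: partial overlap with the active
  interaction pattern, graded by one parameter per class;
- a fraction of residues is **silent** (whole 9-bit block zero across the
  dataset and the reference) and a further fraction of single columns
  inside interacting residues is **impossible** (never a residue's full
  block), mimicking non-interacting residues and interactions that cannot
  be established by definition — the material the RES and INTS rules act
  on.

Defaults, chosen once as a plausible screening scenario and used by the
acceptance checks: 40 residues (360 bits — a generous binding-site
neighbourhood), 200 actives vs 200 decoys (mid-sized screening deck),
$p_{\mathrm{ref}} = 0.2$ (a reference pose establishes roughly 1–2
interaction types per interacting residue), `flip_active = 0.05`,
`flip_decoy = 0.4`, 30 % silent residues, 15 % impossible bits. The
generator is deterministic given its seed and restores the caller's RNG
state.

**What the synthetic data do and do not show.** The generator reproduces
the *structure* the pipeline needs (two classes with graded reference
overlap, heavy shared-zero sparsity), so it can verify the machinery:
cardinalities, bounds, invariances, calibrations (with
`flip_active = flip_decoy` every measure's AUC is ~0.5). It does not
reproduce docking physics, residue chemistry, or the correlated noise of
real poses. Empirical findings on real data — e.g. which filtering rule
improves agreement with the consensus — are regime-dependent: at the
default flip rates decoys are nearly uncorrelated with the reference, and
their ranking noise dominates the filtering effect, so the direction of
real-data filtering benefits should not be expected to transfer
quantitatively to arbitrary synthetic settings.

## Numerical conventions, in one place

- Scaled similarities outside $[0,1]$ by more than $10^{-9}$ raise an
  internal error (a wrong $\alpha/\beta$ should never be silently clamped);
  within tolerance they are clamped.
- Degenerate denominators: $s'=1$ if $b=c=0$, else $s'=0$; counted and
  reported.
- Ranking ties: average ranks everywhere (pretreatment, reference, SRD).
- SRD normalization divides by the tie-free maximum even under ties.
- Permutation test: exact for $n \le 8$, Monte-Carlo otherwise (reps ≥ 100
  enforced); p-values are $P(\mathrm{SRD} \le \mathrm{observed})$.
- ANOVA on a perfect fit: F = 0, p = 1.
- Fingerprints are stored as plain 0/1 integer matrices; confusion counts
  for a whole dataset are computed by one matrix product per reference.
- All seeded functions (generator, CV folds, Monte-Carlo) restore the
  caller's RNG state.

## Problem sizes

The shipped test suite and the acceptance script run the full protocol at
the default conditions: ten synthetic datasets of 400 ligands × 360 bits,
90 grid variants, 23,760 SRD rows, 10,000-table range checks and
10,000-draw permutation nulls. These sizes exercise every code path at the
same cardinalities as a ten-target screening study while completing in
about a minute on a single core.

## Known limitations

- The catalog membership beyond the universally agreed coefficients follows
  one published compilation tradition; other compilations differ in
  which Yule/Cole/Peirce variants they include and in naming.
- SRD normalization under heavy ties is conservative rather than exact.
- The ANOVA layer covers the factorial fixed-effects design only — no
  post-hoc pairwise tests, no random effects.
- AUC assumes binary activity labels; graded potency is out of scope.
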