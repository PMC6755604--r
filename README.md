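# ifpsim

Which binary similarity coefficient should you trust when you compare
protein–ligand **interaction fingerprints**? Interaction fingerprints
(SIFt-style bitstrings) encode, per binding-site residue, which of nine
interaction types (Any contact, backbone, sidechain, polar, hydrophobic,
H-bond acceptor/donor, aromatic, charged) a docked ligand establishes.
Virtual-screening workflows rank ligands by the similarity of their
fingerprint to a reference pose, almost always with the Jaccard–Tanimoto
coefficient — but dozens of alternatives exist, and their behaviour depends
strongly on how the fingerprint is configured (which bit definitions are
kept, and whether never-interacting bits are filtered out).

`ifpsim` implements the complete comparison machinery for this question, for
computational chemists and method developers:

- **Fingerprint handling** — CSV I/O (`ligand_id,active,RES:INT,...`),
  bit-selection schemes **ALL / WO1 / WO3** (all nine types / without "Any
  contact" / additionally without backbone and sidechain contacts), and the
  filtering rules **RES** (drop residues that never interact across the
  dataset) and **INTS** (drop every individual bit that is never set).
- **A catalog of 44 binary similarity measures** built from the confusion
  counts *a* (common on-bits), *b*, *c* (exclusive on-bits), *d* (common
  off-bits), *p* = *a*+*b*+*c*+*d*; e.g. simple matching
  SM = (*a*+*d*)/*p*, Jaccard–Tanimoto JT = *a*/(*a*+*b*+*c*), and
  Baroni–Urbani–Buser BUB = (√(*ad*)+*a*)/(√(*ad*)+*a*+*b*+*c*).
  Measures whose natural range is not [0, 1] are rescaled as
  s′ = (s + α)/β. Every entry carries a symmetricity class
  (S/I/A/Q: *d* weighted like *a* / underweighted / ignored /
  correlation-based) and a metricity flag (M if 1 − s′ is a metric).
- **Sum of ranking differences (SRD)** — ranks the ligands by every measure
  and by a consensus reference fused row-wise from the similarity matrix
  (row maximum for actives, row minimum for decoys), then scores each
  measure by the Manhattan distance between its rank vector and the
  reference ranks, normalized by the theoretical maximum (n²/2 for even n,
  (n²−1)/2 for odd n) to a percentage. Smaller SRD = closer to the ideal
  consensus. Validated by fivefold cross-validation and a permutation
  (randomization) test whose null distribution is exact up to n = 8 and
  Monte-Carlo beyond (null mean (n²−1)/3).
- **Evaluation** — ROC-AUC (Mann–Whitney midrank formulation), the full
  factorial grid over datasets × bit selections × filtering rules, and
  factorial ANOVA with 95 % confidence intervals on the normalized SRD
  values, with column-wise pretreatment (autoscaling, range scaling, rank
  transformation) applied before reference fusion.
- **Synthetic data** — a seeded generator of active/decoy fingerprint sets:
  a Bernoulli reference pattern, actives as mildly bit-flipped copies,
  decoys flipped harder, plus silent residue blocks and "impossible" bits so
  that the filtering rules have realistic work to do.

## Worked example

```r
library(ifpsim)

# a synthetic screening set: 20 residues, 50 actives vs 50 decoys
g   <- generate_dataset(synth_config(n_residues = 20, n_actives = 50,
                                     n_decoys = 50, seed = 42))
# drop the "Any contact" bits, then every never-established interaction
d   <- filter_interactions(select_bits(g$dataset, "WO1"))
ref <- interaction_fp(g$reference$bits[colnames(d$bits)], "reference", TRUE)

sm  <- similarity_matrix(d, ref)        # 100 ligands x 44 measures
roc_auc(sm$JT, sm$active)               # 1 (clean separation by design)

fit <- srd(sm, pretreatment = "auto", folds = 5, perm_reps = 10000, seed = 1)
print(fit)
#> Sum of ranking differences analysis
#>   100 ligands, 44 similarity measures, pretreatment: auto
#>   closest to the consensus reference:
#>     HL   SRD =  8.48%
#>     SS4  SRD =  8.52%
#>     GK   SRD =  8.64%
#>     JT   SRD =  8.64%
#>     Gle  SRD =  8.64%
#>   random-ranking null mean: 66.75%
```

Reading this: after dropping the 20 "Any contact" bits and INTS filtering,
the fingerprints keep 95 of the original 180 bits;
the Harris–Lahey and Sokal–Sneath-4 coefficients rank the 100 ligands most
consistently with the ideal consensus (SRD ≈ 8.5 % of the maximum possible
rank displacement), the standard Tanimoto is essentially tied with them,
and all are far below the ≈ 67 % expected of a random ranking, so none of
them behaves randomly (`summary(fit)` reports the permutation p-values —
here 0 to Monte-Carlo resolution).

The factorial layer runs the whole protocol over every dataset ×
bit-selection × filtering combination:

```r
gens <- lapply(1:10, function(i) generate_dataset(synth_config(seed = 1000 + i)))
grid <- run_grid(lapply(gens, `[[`, "dataset"),
                 lapply(gens, `[[`, "reference"), folds = 5, seed = 1)
grid                      # 90 variants, 23,760 SRD rows
factor_anova(grid, c("filtering", "bit_selection"))
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/ifpsim.R` with `synth`, `sim`, `srd` and `grid` subcommands.

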