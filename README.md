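# stabscan

Rapid prediction of protein stability changes
(ΔΔG, kcal/mol; positive = destabilizing) for single amino-acid
substitutions, from structure alone. The package is aimed at structural
bioinformaticians who want saturation-mutagenesis stability scans of a
protein chain, and at method developers who want a fully testable,
desk-scale implementation of the two-stage representation-plus-regressor
architecture.

## The model

**Stage 1 — self-supervised 3D CNN.** For each residue, all atoms within
9 Å of its Cα — *excluding the residue's own atoms* — are expressed in a
backbone-local frame and binned into an 18³ grid of 1 Å voxels with six
element channels (C, N, O, H, S, P), then Gaussian-blurred. A 3D
convolutional network (16/32/64 filters, conv → batchnorm → leaky ReLU →
max-pool; fully-connected 100 and 20 nodes) is trained to classify the
masked wild-type amino acid. The 100-d layer is the residue
representation.

**Stage 2 — supervised ensemble regressor.** Features for a variant are
the 100-d representation ⊕ one-hot wild type (20) ⊕ one-hot mutant (20) ⊕
background frequencies of both (2). Targets are compressed by the Fermi
(switching) function

    F(ΔΔG) = 1 / (1 + exp(−β (ΔΔG − α))),   β = 0.4 (kcal/mol)⁻¹, α = 3.0 kcal/mol

and a 128/64/16-node network with a sigmoid output is fit by mean
absolute error in Fermi space. The prediction is the median over an
ensemble of 10 seeded replicas, mapped back to kcal/mol by the inverse
transform.

On top sit a saturation-scan pipeline with SASA-based burial annotation
(Shrake–Rupley, Sander–Rost normalization, exposed iff relative SASA ≥
0.2), variant-table joining, allele-frequency binning, bootstrap
difference-of-medians statistics, and seeded generators of toy structures
and synthetic ΔΔG landscapes that make every stage testable without
external data.

## Worked example

Build a toy four-helix bundle, train nothing, and ask structural
questions first:

```r
library(stabscan)

st <- makeToyStructure(42, "compact_bundle", seed = 1, sourceId = "toy")
sa <- computeRelativeSasa(st)
table(classifyBurial(sa$relative_sasa))
#> buried exposed
#>     10      32

fermiTransform(3.0)       # the transform midpoint
#> [1] 0.5
convertRosettaUnits(2.9)  # raw reference score -> kcal/mol
#> [1] 1
```

Then train the two-stage model on synthetic fixtures and scan. The same
study (24 helices for the representation learnability check; 8 + 16
compact bundles for the two-stage recovery study, 13 training / 1
validation / 2 held-out proteins; reduced 6/12/24-filter representation
model and a 3-seed ensemble) is what `scripts/acceptance.R` runs; with
`--seed 1` it prints:

```
representation held-out accuracy: 0.452 (chance 0.05)
ddG recovery on held-out proteins: Pearson 0.974, MAE 0.150 kcal/mol
30-residue scan rows: 600
pathogenic - benign median ddG: 0.507 (CI 0.327..0.665)
bootstrap: first-rep shift estimate 1.000, coverage 50/50
```

Reading those numbers: the self-supervised model recovers masked residue
identities on held-out proteins at nine times the 1/20 chance rate; the
downstream ensemble reconstructs the (noiseless) synthetic ΔΔG rule on
proteins it never saw with Pearson r = 0.97 and MAE 0.15 kcal/mol against
targets carrying 0.2 kcal/mol of added noise; a 30-residue scan yields
exactly 30 × 20 records (one flagged self-substitution per site, ΔΔG = 0);
and in the synthetic clinical-variant table, pathogenic variants are more
destabilizing than benign ones by ~0.5 kcal/mol in the median, with a
bootstrap confidence interval that behaves as advertised on a known shift.

A saturation scan of a real (pre-protonated) PDB chain, given trained
checkpoints, is one call — or one shell command via the thin CLI in
`inst/scripts/stabscan.R`:

```r
st  <- readStructure("protein.pdb", chain = "A")
tab <- saturationScan(st, loadCheckpoint("repr.rds"),
                      loadCheckpoint("ensemble.rds"))
writeScanCsv(tab, "scan.csv")
```

## Scope notes

Inputs are single chains, already protonated/repaired (the reader
validates and warns; it does not fix). Reverse-variant anti-symmetry is
not modelled; predictions at disulfide-bonded cysteines are flagged as
unreliable rather than suppressed. See the methods vignette
(`vignettes/stability-scanning.Rmd`) for the model's assumptions, the
open design choices and what the synthetic fixtures do and do not
demonstrate.
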