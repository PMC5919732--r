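---
title: "Scoring metal-toxicity modifier screens and zinc-stress transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring metal-toxicity modifier screens and zinc-stress transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Arrayed RNAi modifier screens measure, for thousands of dsRNA reagents on
384-well plates, a viability proxy (total ATP by luminescence) under a
stress condition — here toxic ZnCl~2~ or MnCl~2~ supplementation of
Drosophila S2R+ cells — relative to an untreated control screen. Genes
whose knockdown lowers the readout under metal stress are candidate
*sensitizers* (normally protective, e.g. detoxification transporters);
genes whose knockdown raises it are candidate *protectors* (e.g. metal
importers). A matched transcriptomics arm asks which genes change
expression under mild metal supplementation of wild-type and genetically
zinc-sensitized (zinc-exporter knockout) cells.

`metalscreen` implements both analysis chains plus the supporting
machinery: gene-set over-representation, overlap reports,
expression-evidence false-discovery assessment, and seeded simulators
with planted ground truth.

# The screen statistic chain

For wells $w$ on plate $p$ (one physical plate = plate layout x
condition x replicate), the model is multiplicative: luminescence is a
positive, scale-family quantity, so plate effects (reagent batch,
cell-seeding, reader drift) act as factors, not offsets. The chain is:

1. **Plate normalization.** $\tilde{x}_w = x_w / \bar{x}_p$, where
   $\bar{x}_p$ averages the *experimental* wells of plate $p$ only.
   Edge wells (the outermost two rows and columns, kept reagent-free in
   the plate design to limit evaporation and gradient artifacts) and
   other reagent-free wells are excluded from the average and flagged;
   including them would bias $\bar{x}_p$ toward the unperturbed
   baseline. After this step the mean normalized signal of each plate's
   experimental wells is exactly 1.
2. **Replicate averaging.** Per reagent and condition, the mean of
   $\tilde{x}$ over the replicate plates (3 for metal conditions, 2 for
   control). Missing wells are dropped from the mean, never imputed:
   with at most three replicates any imputation rule would dominate the
   estimate.
3. **Z-scores.** Within one condition, $z = (\bar{\tilde{x}} - \mu)/s$
   over *all* reagents of that condition pooled across plates, with the
   sample (n−1) standard deviation. The condition-wide reference
   population (rather than per-plate standardization) is what makes
   scores comparable across plates after step 1 has removed plate
   scale; per-plate standardization would re-introduce sensitivity to
   how many true effects happen to share a plate.
4. **Hit calls.** A reagent is a hit when $|z| \ge 1.5$. The boundary
   is inclusive by choice (the threshold's provenance mixes strict and
   non-strict phrasing); it is a single argument (`z_cutoff`) if a
   different convention is wanted.
5. **Gene tiers.** A gene is **high-confidence** when at least two of
   its designs hit in the same direction *and* no design hits in the
   opposite direction; a single hitting design (none opposite) is
   **low-confidence**; opposite-direction hits cancel to `none`.
   Requiring two independent dsRNA designs is the standard guard
   against off-target effects. The **moderate** tier is never assigned
   by aggregation: it exists only as a promotion of low-confidence hits
   that fall in a significantly enriched gene set
   (`promote_confidence()`), the rationale being that membership in an
   enriched functional group is independent corroborating evidence.
6. **Reported score.** `avg_z` averages the Z-scores of *all* designs
   targeting the gene by default. Averaging only the hitting designs is
   available (`avg_hits_only = TRUE`); with reagent-level data for the
   published screens one could adjudicate which convention reproduces
   the printed per-gene averages, but for two-design high-confidence
   genes the two conventions coincide anyway.

Quality control reports Pearson correlations between replicate plates
matched by layout position: within-condition correlations measure
reproducibility, cross-condition correlations measure how much of the
signal is condition-independent (generic dsRNA toxicity). A healthy
condition-specific screen has the former clearly above the latter.

**A note on the tier/cutoff interaction.** Lowering `z_cutoff` can only
grow the reagent-level hit set, but it can *demote* a gene from
high-confidence to `none` when a previously sub-threshold
opposite-direction design becomes a hit. This is a deliberate
consequence of the direction-conflict rule, and the property tests
assert exactly that: monotone reagent hits, with any gene-tier demotion
attributable to a new opposite-direction hit.

# The expression chain

Inputs are gene x sample FPKM matrices (upstream read mapping and
quantification are out of scope). For each genotype x treatment against
a baseline (default: untreated samples of the same genotype; a
wild-type-untreated baseline is one argument away):

1. Replicate means are computed on raw FPKM.
2. **Flooring:** any mean below 1 FPKM (including 0) is set to 1 before
   forming ratios. This suppresses spurious fold changes between
   negligible expression levels (0.1 vs 0.0001 FPKM) and removes zero
   denominators; flooring after averaging follows from defining the
   floor on the *average* level. The rule is idempotent, and the ratio
   is antisymmetric under swapping numerator and denominator.
3. The reported statistic is $\log_2$ of the floored mean ratio; a gene
   is called when the mean-level ratio exceeds the cutoff (default 1 in
   log2 units, i.e. twofold) **and** every individual experimental
   replicate (floored) also exceeds the cutoff against the floored
   baseline mean in the same direction. The per-replicate clause is the
   interpretation of "twofold change for all replicates" adopted here:
   with two replicates it guards against a single outlier replicate
   carrying the mean; the reported log2 value is always the mean-level
   ratio, which is the unambiguous part of the rule.
4. Calls are intersected across genotypes (`de_overlap()`): genes
   responding in all three zinc-treated genotypes form the
   highest-confidence zinc-responsive core, robust to clonal artifacts
   of any single knockout line (each knockout line passed through
   single-cell cloning, which can itself shift expression). Genes also
   called under manganese, in the same direction, are annotated
   `shared` (`cross_metal_annotation()`) — candidate chloride/generic
   responders rather than zinc-specific ones.

# Enrichment

Over-representation uses the upper-tail hypergeometric probability
$P(X \ge k)$ for an overlap of $k$ between a hit list of size $n$ and a
set with $K$ members in a universe of $N$, computed with `stats::phyper`
and cross-checked in the test suite against exhaustive subset
enumeration for all universes up to $N = 12$. The universe is the
caller's choice; the intended defaults are all genes targeted by the
screened libraries (screen hits) or all genes with FPKM data
(transcriptomics hits). Sets are tested only when their
universe-intersected size lies in `[3, 500]` and the overlap is at
least 1. Multiplicity is handled by Benjamini–Hochberg at
$\alpha = 0.05$ across the tested collection; because the original
significance convention for "enriched group" is not fully specified,
raw-p thresholding is available (`adjust = "none"`).

# False-discovery assessment

Two external consistency checks on screen results:

- **Expression evidence.** A hit with no evidence of expression in the
  assayed cells (maximum condition-mean FPKM below 1 across all
  provided conditions — a gene expressed anywhere counts as expressed)
  cannot produce a knockdown phenotype and is flagged as a probable
  false positive. Percentages are reported per tier, rounded half-up to
  integer percent.
- **Essential genes.** Genes independently known to be essential in
  cultured cells should score down in the control screen; the
  cross-check reports the concordance per tier, optionally through a
  scored ortholog map filtered at score > 2 (best-match convention).
  No formal false-negative rate is estimated: with a handful of
  comparable genes such a rate would be noise.

# What the simulators emulate — and what they do not

`simulate_screen()` generates raw well signals as
$\text{base} \times \text{plate} \times \text{reagent} \times
\text{condition effect} \times \text{noise}$, all factors log-normal.
Defaults (chosen once as the study conditions for all seeded checks):

| parameter | default | rationale |
|---|---|---|
| `n_genes` / designs | 2000, P(1,2,3 designs) = .05/.85/.10 | matches a ~3900-reagent, ~2000-gene library (~2 designs/gene), 18 plates of 240 usable wells |
| `replicates` | control 2, metals 3 | the screened design |
| `plate_effect_sd` | 0.10 (log) | ~10% plate-to-plate scale drift, removed exactly by normalization |
| `well_noise_sd` | 0.12 (log) | ~12% well CV, a typical mid-quality luminescence assay |
| `reagent_effect_sd` | 0.08 (log) | reagent-intrinsic (condition-independent) effects; makes replicate plates correlate within *and*, more weakly, across conditions, as real screens do |
| planted effects | 10 sensitizers ×0.55, 10 protectors ×1.8 per metal condition, on two-design genes | strong modifiers; deviations ≈3.6 and 6.4 within-condition SDs, comfortably past the ≥3 SD regime the recovery checks target |

With these settings the planted deviation divided by the realized
condition SD (which the planted reagents themselves inflate) stays
above 3, planted recovery is essentially complete, and the null
high-confidence rate sits near its analytic value
$2(p_1/2)^2 \approx 0.9\%$ for two-design genes at
$p_1 = 2\Phi(-1.5)$ — the test suite checks a null screen against that
closed form.

`simulate_expression()` draws log-normal baselines (meanlog 1.5, sdlog
1.5, natural log — median ≈ 4.5 FPKM), forces 25% of genes to
near-silent baselines (0.001–0.5 FPKM) to exercise the flooring rule,
adds log2-normal replicate noise (sd 0.15, inside the ≤0.2 regime the
recovery checks target), and plants fourfold (±2 log2) responses: 60 up
and 40 down core genes responsive in all genotypes under zinc, plus 20
genes shared with manganese. Planted genes are drawn from baselines ≥5
FPKM so that the floor cannot mask a planted fourfold drop (a baseline
of 4 halved twice lands exactly on the floor and would be
undetectable by construction, not by failure of the method).

Neither simulator models spatial within-plate gradients, cell-count
confounding of the ATP readout, sequencing-depth or transcript-length
bias in FPKM, or correlated off-target structure among designs.
Passing the recovery suites therefore demonstrates that the statistics
recover what they are defined to recover under clean multiplicative
noise — not that the pipeline is robust to artifact classes it does not
model (spatial correction is explicitly out of scope).

# Numerical choices and degenerate inputs

- A plate whose experimental-well average is zero is an error, as is a
  condition with zero variance at the Z-score step (no reference
  distribution) — both indicate a broken assay, not a statistical
  outcome.
- Correlations over fewer than three shared wells, or against a
  zero-variance vector, are reported as `NA`, not 0.
- Missing signals are excluded from every average; there is no
  imputation anywhere.
- The hypergeometric tail is exact (no normal approximation); BH
  adjustment is `stats::p.adjust`.
- Percentages round half-up (`floor(x + 0.5)`), so 18.6% → 19%, 6.9% → 7%.
- Seeds: every simulator takes an explicit integer seed; identical
  config + seed is byte-identical output.

# Problem sizes in the checks

The bundled test suite runs its property sweeps at reduced scale
(universes ≤ 12 for enumeration, screens of 300–500 genes for
normalization/standardization properties, 1000-draw calibration of the
discrete test against its frozen exact level) and the recovery checks at
the full default scale above; the whole suite completes in about a
minute on one core. `scripts/acceptance.R` re-runs the default-scale
simulations and the bundled reference-table arithmetic from scratch at
the seed given on the command line.

# Known limitations

- The screen statistics assume plate effects are purely multiplicative;
  spatial (row/column/edge-gradient) correction such as B-scoring is
  intentionally not implemented.
- The per-replicate DE clause compares each replicate against the
  *baseline mean*, one of several readings of "all replicates"; the
  replicate-vs-replicate alternative can be emulated by calling
  `call_de()` with swapped roles, but is not a built-in mode.
- The moderate tier depends on the gene-set collection supplied;
  promotion is only as meaningful as the collection is.
- Confidence tiers are heuristics on top of a thresholded statistic;
  they are not posterior probabilities, and no gene-level error rate is
  attached to them.
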