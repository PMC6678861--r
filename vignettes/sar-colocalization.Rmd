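---
title: "Methods: SAR-gene classification and its statistical machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SAR-gene classification and its statistical machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Transcription-factor (TF) perturbation screens and ChIP binding maps
disagree: most genes that respond to a TF knockout are not bound by that
TF. `sarloc` operationalizes one candidate explanation — regulation through
nuclear colocalization. A knockout-affected gene that is not bound may
still sit next to a bound gene in 3D space, where the knocked-out factor
participates in the regulating protein complex. The package classifies such
**spatially adjacent regulated (SAR) genes** and asks, with a permutation
null, whether there are more of them than chance chromosome geometry
predicts.

The analysis takes the 3D contact list as ground truth for spatial
adjacency: no polymer modelling, no embedding. Its assumptions are
therefore those of the contact data — kilobase segments, a hard FDR
call — plus flat-set semantics for annotations (two genes share a process
if they co-occur in at least one term; no ontology propagation).

# Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| binding P cutoff | 0.005 | probability | defines bound sets from ChIP scores, inclusive at the boundary |
| interaction FDR cutoff | 1e-4 | probability | the call threshold of the contact data; applied at load time |
| TSS-segment window | 2500 | bp | gene maps to segments whose interval lies within this distance of its TSS |
| proximity exclusion | 3000 | bp | knockout/bound genes closer than this (TSS-to-TSS, same chromosome) are removed from both sides |
| minimum set size | 20 | genes | TFs need strictly more than this on both sides ("more than 20") |
| intra separation | 60000 | bp | intra-chromosomal contacts closer than this are linear-proximity artifacts |
| permutation replicates | 10000 | — | empirical P resolution 1e-4 |
| bootstrap resamples | 1000 | — | percentile CIs on group medians |
| expression conditions | 112 | — | the combined normal-growth time-course compendium size |

Decisions the input definitions left open, and what the package does:

* **Distance anchors.** "Close to" is measured TSS-to-TSS; gene-segment
  distance is TSS to the nearest interval point (0 inside); intra-pair
  separation is midpoint-to-midpoint (`anchor = "edge"` available). TSS is
  the only coordinate the pipeline requires, and midpoints are symmetric at
  segment resolution.
* **Exclusion semantics.** Both exclusions are computed from the original,
  pre-filter sets simultaneously, making the filter order-independent and
  idempotent (property-tested). The exclusion is symmetric: a bound gene
  proximal to a knockout gene is removed too.
* **Set-size rule.** "More than 20" is read strictly (`> 20`); the
  threshold is configurable.
* **SAR definition.** A knockout gene is SAR when inter- **or**
  intra-colocalized (union), computed after the 60 kb filter; the per-mode
  flags are retained so inter and intra frequencies remain independently
  reproducible. Genes that map to no segment stay in denominators as
  never-colocalized — dropping them would silently shrink the pair counts.
* **Colocalization requires two distinct interacting segments.** Two genes
  sharing a single segment are *not* colocalized; the contact list, not
  co-mapping, defines adjacency.
* **Binding affinity proxy.** The per-event score is `-log10` of the ChIP
  binding P value (a raw-score override exists). The affinity contrast is
  rank-based, so any strictly monotone choice gives the same P.

# The permutation engine

Each replicate replaces every gene set with a chromosome-matched random
set: per chromosome, the same number of genes drawn uniformly **without
replacement** (so random sets are genuine sets; with-replacement draws
would deflate colocalization through duplicates). The actual genes remain
eligible, and no exclusion is imposed between the two randomized sides —
adding one would bias the null. For the colocalization test both sides are
randomized; for the cellular co-component test only the SAR-gene side is,
with the TF side held fixed — the two tests are deliberately asymmetric.

Numerical conventions:

* **Ties count as not exceeding** (strict `>`), so the reported
  `p_empirical` can be 0; it is then reported alongside the resolution
  bound `< 1/n_reps`. A conservative `(k + 1)/(N + 1)` estimator is a
  config switch and is what the calibration checks use.
* **Reproducibility.** Replicate *r* draws from a substream seeded by the
  *r*-th element of a seed vector derived once from the master seed;
  results are bit-identical across runs and independent of evaluation
  order. The pipeline derives one substream per stage, so disabling one
  analysis never changes another's draws.
* **Degenerate contrasts** (an empty group, or all values identical across
  both groups) return an `NA` P with an explanatory note instead of a
  fabricated number.
* **Correlations** use pairwise-complete conditions; pairs with fewer than
  3 shared non-missing conditions are skipped and counted. Expression
  variability is the per-gene SD across conditions (CV available) — the
  metric is a package choice, made explicit because rank tests only need
  an order.
* The Mann-Whitney test delegates to R's `wilcox.test`: exact enumeration
  for tie-free samples with `min(n, m) <= 8`, tie-corrected normal
  approximation (no continuity correction) otherwise. The test suite
  verifies the exact branch against an independent brute-force enumeration
  of all rank assignments.

# What the synthetic generator emulates

`simulate_dataset()` produces all eight inputs self-consistently: genes at
fixed 2 kb spacing on 16 chromosomes, 3 kb segments tiling the genome
(~4000 genome-wide at default scale, matching kilobase contact
resolution), Bernoulli background contacts over all segment pairs,
per-TF bound/knockout sets that already respect the proximity filter,
overlapping CC/BP terms, a 112-condition expression matrix with latent
per-TF block factors, unit-mean occupancy tracks with an additive offset
on planted-SAR promoters, and motif presence lists at two rates.

The planted signal is a contact-probability elevation: eligible
(bound-gene, knockout-gene) segment pairs are drawn at
`min(1, planted_enrichment × background_contact_rate)` **instead of** the
background rate, so `planted_enrichment = 1` is an exact null by
construction. Planting only touches pairs the pipeline's own filters keep
(distinct segments; inter, or intra separated by ≥ 60 kb), which makes the
ground-truth SAR label well-defined and recoverable; background contacts
still cover all separations so the 60 kb filter is exercised. Every
planted contact appears in the emitted interaction table (asserted).

Two density choices matter and were made on realism grounds:

* The default background rate (1.5e-4) puts the default-scale pooled
  inter-chromosomal frequency near 10%, the order observed in real yeast
  data.
* At test scale the genome keeps 125 genes per chromosome so background
  contacts outnumber planted contacts by roughly an order of magnitude, as
  in real data, where called contacts vastly outnumber colocalized
  regulatory pairs. In a sparser draft genome the planted contacts
  themselves inflated the permutation null and masked the very signal they
  plant.

**What the generator does not emulate**, hence what green tests do *not*
show about real data:

* A single contact rate for inter and intra pairs. Real intra contacts are
  strongly distance-dependent and relatively denser; the synthetic intra
  colocalization frequency is therefore much lower than the inter one, and
  the intra permutation test has little planted power at default settings.
* Planting is symmetric in bound and knockout genes, so the bound-side
  direction is enriched whenever the knockout side is. The real data's
  partner-count asymmetry (many knockout partners per bound gene, few
  bound partners per knockout gene) is not reproduced — only the exact
  pair-total symmetry that reconciles the two directions is, and it is
  asserted exactly.
* Cellular-component membership is independent of the contact structure,
  so the co-component permutation test is exercised as a calibrated null,
  not as a power case.
* No centromere clustering, rDNA, chromosome-length heterogeneity or
  chromosome-biased TF regulation; the chromosome-matched null is
  structurally correct but not stressed by real karyotype quirks.

# Problem sizes used by the checks

Calibration uses 200 null datasets at the fixture scale (8 chromosomes ×
125 genes, 8 TFs with 25 bound + 30 knockout genes, 500 replicates each)
and checks the 5% rejection rate against its 99% binomial band; uniformity
of null P values is checked after randomized tie-breaking, the standard
de-discretization for a discrete statistic. Power and recovery use 100
datasets of 20 TFs (30 + 30 genes, 16 chromosomes, five-fold enrichment,
1000 replicates): the test demands P ≤ 0.01 in at least 90% of runs and
at least 90% recall of planted SAR genes. Oracle equivalence compares the
vectorized classifier against a naive double loop on 100 random instances
of up to 50 genes and 100 contacts. These sizes are the package's chosen
trade-off between statistical resolution and a test suite that runs in
minutes.

# Known limitations

* The contact list is binary: contact weights or distance decay are not
  modelled, and the 60 kb cutoff is a hard boundary.
* Annotations are flat gene sets; ontology structure (term specificity,
  propagation) is out of scope by design.
* The co-expression pooling treats every (gene, bound gene) combination as
  one observation; correlated pairs within a TF are not deduplicated
  (per-TF aggregation is available as a configuration).
* With external (non-synthetic) data the package expects the documented
  TSV dialects; raw ChIP intensities, raw sequencing reads and ontology
  files are not parsed.
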