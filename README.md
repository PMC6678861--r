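# sarloc — spatially adjacent regulated genes from chromosomal interaction data

Most genes whose expression changes when a transcription factor (TF) is
knocked out are **not** bound by that factor: in budding yeast only a few
percent of knockout-affected genes overlap the factor's ChIP-defined
targets. One contributing mechanism is nuclear organization. An unbound
knockout-affected gene may sit, in three-dimensional space, next to a gene
the factor *does* bind, and be regulated through the protein complex
assembled there. `sarloc` identifies these **spatially adjacent regulated
(SAR) genes** from a genome-wide chromosomal interaction map and runs the
statistical analyses that characterize this indirect regulatory mode. It is
aimed at regulatory-genomics researchers who have, or can simulate, per-TF
binding and knockout gene lists plus a segment-level 3D contact list.

## The statistic and its null

For each TF *t*, let *K(t)* be its knockout-affected genes and *B(t)* its
bound genes, after two exclusions: genes in both sets, and genes whose TSS
lies within 3 kb of a gene of the other set (same chromosome), are removed
from both sides; only TFs with more than 20 genes in each filtered set are
analyzed. Genes map to interaction segments within 2.5 kb of their TSS.
Two genes are *colocalized* when two distinct segments of theirs form a
contact called at FDR ≤ 1e-4; intra-chromosomal contacts closer than 60 kb
(midpoint to midpoint) are discarded to control for linear proximity. The
pooled colocalization frequency is

```
F = Σ_t |{ k ∈ K(t) : k colocalized with ≥ 1 gene of B(t) }| / Σ_t |K(t)|
```

computed separately for inter- and intra-chromosomal contacts and in both
directions (knockout side and bound side). Significance comes from a
**chromosome-matched permutation test**: each gene set is replaced by a
random set with identical per-chromosome composition (drawn without
replacement within a chromosome), the statistic is recomputed for 10,000
such replicates, and the empirical P value is the fraction of replicates
*strictly* exceeding the observed value (reported as `< 1/n_reps` when none
does). Downstream analyses compare SAR against non-SAR pairs: shared
GO-style cellular components between a SAR TF and the TFs binding its SAR
gene, shared biological processes with bound genes, Pearson co-expression
across 112 conditions, promoter nucleosome occupancy over [-500, -1] from
the TSS, motif presence, binding-TF counts and binding-affinity contrasts,
using Mann-Whitney rank tests with bootstrap confidence intervals on
medians.

Because the published yeast datasets are not redistributable here, the
package ships a first-class synthetic generator (`simulate_dataset()`)
that reproduces the statistical structure of all eight inputs with planted
ground truth, so every claim the package makes is testable end to end.

## Worked example

```r
library(sarloc)

cfg <- run_config(sim = fixture_config(planted_enrichment = 5, seed = 2),
                  n_reps = 1000, n_boot = 200, seed = 42)
res <- run_pipeline(cfg)
s <- res$summary
```

On this reduced synthetic genome (8 chromosomes, 1000 genes, 8 TFs, a
five-fold planted contact excess between bound and knockout genes) the run
prints:

```
analyzable TFs: 8   (TF, KO gene) pairs: 240   SAR pairs: 50
inter-chromosomal colocalization: 46/240 = 19.17%  (P 0.024)
intra-chromosomal colocalization: 5/240 = 2.08%  (P 0.1)
co-expression medians, SAR vs non-SAR: 0.036 vs -0.001  (P = 1.8e-38)
```

Read: 46 of 240 (TF, knockout-gene) pairs are inter-chromosomally
colocalized with a bound gene of the same TF — more than in randomized
gene sets of matched chromosomal composition (empirical P = 0.024 at 1000
replicates; the enrichment strengthens with more TFs or replicates) — and
those SAR genes co-express with the TF's bound genes while non-SAR genes
do not. `res$permutations$inter` holds the full null sample:

```
permutation_result: observed = 0.1917, null mean = 0.1469, P = 0.024 (24/1000 exceed, strict)
```

`run_pipeline(cfg, out_dir = "...")` additionally writes `summary.json`,
per-TF frequency tables, the SAR pair table and partner-count tables.

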