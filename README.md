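# tensorDE

Integrated multi-tissue differential expression analysis by tensor
decomposition, with standard-deviation-optimized probe selection.

## What problem this solves, and for whom

Factorial expression studies that profile the *same* probes across several
tissues — e.g. a diabetic (Goto-Kakizaki) vs control (Wistar-Kyoto) rat
model measured in adipose, muscle and liver at five time points with five
replicates and two treatment arms — are conventionally analysed one tissue
at a time and reconciled afterwards. tensorDE is for analysts who want to
use the whole design at once: it arranges the data as a six-mode tensor

    x[i, j, k, m, s, t]   (probe, time, replicate, treatment, strain, tissue)

and extracts the probes whose expression separates the treatment arms
consistently across tissues. The package also implements the conventional
per-tissue selectors (Welch *t*, a SAM-like permutation statistic, an
empirical-Bayes moderated *t*) and a ComBat-style cross-tissue batch
adjustment, so the integrated analysis can be benchmarked against standard
practice on identical data, plus local hypergeometric gene-set enrichment
on GMT libraries for downstream interpretation.

## The method in brief

1. **Normalize** every sample fiber over probes: mean 0, sum of squares
   *N* (`normalize_tensor()`).
2. **Decompose** by higher-order SVD (`hosvd()`): mode-wise factor
   matrices of singular vectors `u`, plus a core tensor `G` weighting each
   combination,

   x<sub>ijkmst</sub> = Σ G(ℓ₁…ℓ₆) · u<sup>(1)</sup><sub>ℓ₁i</sub> ⋯ u<sup>(6)</sup><sub>ℓ₆t</sub>.

3. **Select singular vectors** per non-probe mode against biological
   criteria (`score_mode_vectors()`): treatment → most *contrast*-like
   (anti-symmetric across arms), tissue/replicate/strain → most constant,
   time → free (fixed by maximal core weight).
4. **Rank probe vectors** by |G| at the chosen indices
   (`rank_probe_vectors()`) and score each probe by the sum of squared
   entries of the retained probe vectors.
5. **Select probes**: the null SD σ of the probe-vector entries is chosen
   so the null p-value distribution is maximally uniform
   (`optimize_sd()`), scores/σ² get upper-tail χ² p-values, BH correction,
   adjusted p < 0.01 (`compute_pvalues()`, all orchestrated by
   `run_td_pipeline()`).

A full synthetic-study generator (`generate_dataset()`,
`write_series_matrices()`) emulates the factorial design with planted
tissue-independent DEGs and ground-truth labels, so every stage is testable
without downloads; GEO-style series-matrix files are parsed with
`parse_series_matrix()` + `extract_design()` + `assemble_tensor()`.

## Worked example

Simulate the default study (2000 probes, 10% planted DEGs with effect 3,
unit noise), normalize, inspect the core-weight profile to decide how many
probe vectors to retain, and run the pipeline:

```r
library(tensorDE)

cfg <- simulation_config(n_probes = 2000, frac_deg = 0.1, effect_size = 3,
                         noise_sd = 1, seed = 7)
sim <- generate_dataset(cfg)
tn  <- normalize_tensor(sim$tensor)

dec <- hosvd(tn)
sel <- score_mode_vectors(dec)
(w <- attr(rank_probe_vectors(dec, sel, n_keep = 5), "weights"))
#> [1] 167.9 127.8   6.8   0.4   0.4

# two comparable leading weights: the planted pattern splits across two
# near-degenerate probe vectors, so retain both (df = 2)
K <- sum(w >= 0.5 * w[1])
res <- run_td_pipeline(tn, n_probe_vectors = K, decomposition = dec)
res
#> tensor-decomposition feature extraction
#>   chosen singular vectors (non-probe modes):
#>     time      kind=free     index 1, constancy 1.000
#>     replicate kind=constant index 1, constancy 1.000
#>     treatment kind=contrast index 2, contrast 1.000
#>     strain    kind=constant index 1, constancy 1.000
#>     tissue    kind=constant index 1, constancy 1.000
#>   probe vectors retained: 4, 1
#>   optimized sigma: 0.016089
#>   selected probes: 209 of 2000 (BH < 0.01)

selection_performance(res$stats$probe_id[res$stats$selected], sim$truth)
#> precision     recall n_selected        fdr
#>     0.952      0.995    209.000      0.048
```

Reading the report: the treatment mode's chosen vector is perfectly
anti-symmetric across arms (contrast 1.000) while tissue, strain and
replicate use near-constant vectors — i.e. the extracted component is a
treatment difference shared by all tissues, which is exactly the planted
signal; 209 probes pass BH < 0.01, recovering 199 of the 200 planted DEGs
with 10 false positives. The per-tissue baselines
(`ttest_select()`, `sam_like_select()`, `moderated_t_select()`) and
`combat_adjust()` accept slices from `extract_tissue_matrix()`, and
`enrich()` / `overlap_report()` handle gene-set enrichment and Venn-style
method comparisons.

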