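# circatissue

Detection of 24-hour rhythmic genes in multi-tissue expression time series,
and quantification of how rhythms differ between tissues.

Peripheral organs (liver, muscle, adipose, lung, ...) keep cell-autonomous
circadian clocks, but the genes they drive, and the peak times and amplitudes
of those genes, are highly tissue specific. Quantifying that inter-tissue
variability from dense time-series expression data takes four ingredients,
all implemented here for analysts working with microarray- or
sequencing-style gene × sample intensity matrices:

1. **Rhythm detection.** A nonparametric cosine-ordering test in the
   JTK_CYCLE family, written from scratch. For each candidate peak time
   &phi;<sub>ref</sub> on an hourly grid, the cosine
   cos(2&pi;(t &minus; &phi;<sub>ref</sub>)/24) is evaluated at the actual
   (possibly unequally spaced) sampling times; exactly tied cosine values are
   merged into rank groups, and the gene's Kendall S — concordant minus
   discordant sample pairs across groups — is referred to its **exact** null
   distribution, computed by dynamic-programming convolution of Mann–Whitney
   null distributions over successive group merges. The minimal one-sided p
   across reference phases is Bonferroni-multiplied by the number of phases;
   Benjamini–Hochberg q-values across genes give the circadian call at
   q < 0.05. Peak time &phi; is the winning reference phase; amplitude A is
   the Hodges–Lehmann median of pairwise slopes of expression against the
   unit cosine.
2. **Normalization.** The two-step scheme used for inter-tissue microarray
   comparisons: each chip scaled to its median (50th percentile → 1), then
   each probe set scaled to its mean across the chips of that tissue, so
   every profile oscillates around 1.
3. **Cross-tissue comparison.** For genes circadian in several tissues:
   circular phase lag &Delta;&phi; = min(|&phi;<sub>i</sub> &minus;
   &phi;<sub>j</sub>|, 24 &minus; |&phi;<sub>i</sub> &minus;
   &phi;<sub>j</sub>|) &isin; [0, 12] h (and its maximum over 3–4 tissues);
   percent amplitude difference &Delta;A = (A<sub>max</sub> &minus;
   A<sub>min</sub>)/A<sub>max</sub> × 100; k-set overlap (Venn) partitions
   with pairwise common counts; Fisher–Lee circular correlation of paired
   peak times; cross-species conservation percentages; and the standard
   binned summaries (2-h lag bins, 20% amplitude bins).
4. **Synthetic truth.** A generator that emulates a dense rat study design —
   18 unequally spaced time points over 24 h (0.25, 1, 2, 4, 6, 8, 10, 11,
   11.75, 12.25, 13, 14, 16, 18, 20, 22, 23, 23.75 h), 3 replicates per
   point — with configurable rhythmic fractions, von Mises or bimodal
   "rush hour" phase distributions, amplitudes, noise, and genes shared
   across tissues with known phase offsets, so every stage is testable
   against ground truth without any downloads.

## Worked example

```r
library(circatissue)

sim <- generate_tissue(rat_design(), n_genes = 40, frac_rhythmic = 0.5,
                       amplitude_range = c(0.3, 0.5), noise_sd = 0.1,
                       seed = 17)
res <- detect_rhythms(sim$matrix, phase_step = 1, fdr = 0.05)
head(res, 3)
#>   gene_id        p_adj            q phase_h amplitude circadian
#> 1  g00001 8.334798e-26 3.333919e-24       4 0.4982974      TRUE
#> 2  g00009 1.828356e-25 3.656713e-24      19 0.4774249      TRUE
#> 3  g00008 2.270177e-23 3.026903e-22       5 0.4293170      TRUE
sum(res$circadian)
#> [1] 20
```

Twenty genes are flagged — exactly the simulated rhythmic half — each with a
Bonferroni-adjusted exact p, a BH q, the estimated peak time in hours
after lights-on, and the cosine amplitude on the normalized scale.

Comparing two synchronized tissues:

```r
mt <- generate_multitissue(
  tissue_specs = list(liver = list(frac_rhythmic = 0.4),
                      lung  = list(frac_rhythmic = 0.4)),
  n_genes = 300,
  shared_config = list(n_shared = 50, offsets = list(liver = 0, lung = 0)),
  seed = 5)
dets <- lapply(mt$matrices, detect_rhythms)
cmp <- compare_tissues(dets)
cmp$phase_hist
#>   [0,2]   (2,4]   (4,6]   (6,8]  (8,10] (10,12]
#>      50       1       0       0       0       0
```

All but one shared circadian gene shows a phase lag of at most 2 h, as
constructed.

The `analysis/` directory holds the five-stage narrative workflow
(simulate → normalize → detect → compare → annotate); run the scripts in
order from the repository root. Each writes its tables under
`results/analysis/`.

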