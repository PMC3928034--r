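# kappa3C

Quantitative viewpoint 3C-seq analysis of the mouse immunoglobulin kappa
(Igκ) light-chain locus.

During B-cell development, recombination of the Igκ locus depends on
long-range chromatin contacts between its ~3.2 Mb Vκ gene region and
three regulatory elements near the Jκ/Cκ end of the locus: the Sis
silencer region, the intronic enhancer iEκ, and the 3′ enhancer 3′Eκ.
Viewpoint 3C-seq measures those contacts as read counts per BglII
restriction fragment, and the scientific question is how pre-B-cell
receptor (pre-BCR) signaling — probed with an ordered series of mouse
genotypes forming a signaling gradient, from *Rag1⁻/⁻* pro-B cells
through *Btk/Slp65* single- and double-deficient pre-B cells to
wild-type pre-B cells — redistributes those contacts toward the Vκ
genes. `kappa3C` is for genomicists who want that analysis as tested,
reusable R functions rather than a one-off script.

## The quantities the package computes

For a viewpoint profile with per-fragment counts $k_f$ and library size
$N$:

* **Normalized frequency** $x_f = 10^6 k_f / N$ (reads per million),
  averaged per fragment across replicates. Fragments under 100 bp and
  fragments in the viewpoint-proximal window are excluded.
* **Regional means** $\bar x_R = \mathrm{mean}\{x_f : f \in R\}$ for the
  upstream / Vκ / downstream partition (mm9 defaults:
  chr6:65,441,978–67,443,029, chr6:67,443,034–70,801,754,
  chr6:70,801,759–73,993,074), and the **inside/outside ratio**
  $\bar x_{V\kappa} / \bar x_{\text{flanks}}$.
* **Group contrasts** (Vκ⁺ vs Vκ⁻ fragments; fragments with vs without
  Ctcf/Ikaros/E2a/H3K4me2-3 sites): two-sided Mann–Whitney U with
  midranks, exact by enumeration for small groups, normal approximation
  with tie and continuity corrections otherwise.
* **Fold classes** between two conditions: *increase* if the frequency
  ratio exceeds 1.5, *decrease* below 1/1.5, *stable* otherwise,
  *no evidence* if averaged raw counts never exceed 25 at any viewpoint.
* **Correlations**: inter-viewpoint R² of per-gene log10 frequencies
  (values below 1 floored to 10⁰), and the usage analysis correlating
  the four repertoire-usage categories (<0.1%, 0.1–0.3%, 0.3–0.5%,
  >0.5%) with category mean frequency.
* **FISH**: per-nucleus 3D inter-probe distances
  $\sqrt{(X_a-X_b)^2+(Y_a-Y_b)^2+(Z_a-Z_b)^2}$, medians per cell type,
  pairwise Mann–Whitney tests.

A seeded synthetic-data generator (`sim_params()`, `simulate_locus()`,
`simulate_viewpoint_counts()`, `simulate_usage()`, `simulate_fish()`)
emulates the locus interaction structure — power-law distance decay,
condition-dependent focusing onto gene fragments, negative-binomial
replicate noise, usage coupled to contact strength, contracted vs
non-contracted FISH distances — so the full pipeline runs and is tested
with no external data. See the methods vignette
(`vignettes/kappa3C-methods.Rmd`) for the model and every numerical
choice.

## Worked example

```r
library(kappa3C)

# an in-silico BglII digest: cuts at A^GATCT
m <- digest_sequence("GGAGATCTGGTTAGATCTAA", chrom = "demo")
fragments(m)
#>       seqnames    ranges   ...  fragment_id     region  excluded
#>   [1]     demo       1-3   ...            1 unassigned     FALSE
#>   [2]     demo      4-13   ...            2 unassigned     FALSE
#>   [3]     demo     14-20   ...            3 unassigned     FALSE

# the full synthetic analysis at the default study conditions
res <- run_pipeline(default_config(seed = 1), outdir = "igk_run")

round(100 * res$fold_classes, 1)   # % of Vk+ fragments, WT vs lowest signaling
#>      increase decrease stable no_evidence
#> Sis      42.6     15.8   28.7        12.9
#> iEk      47.5     13.9   25.7        12.9
#> 3pEk     52.5     14.9   19.8        12.9

subset(res$viewpoint_correlations,
       condition %in% c("WT", "BtkSlp65") & viewpoint_a == "iEk")
#>  condition viewpoint_a viewpoint_b r_squared   n
#>   BtkSlp65         iEk        3pEk 0.3323540 101
#>         WT         iEk        3pEk 0.7884126 101

subset(res$comparisons, contrast == "vk" & viewpoint == "3pEk" &
                        condition %in% c("proB", "WT"))
#>  viewpoint condition    mean_a   mean_b            p stars
#>       3pEk      proB  76.13366 84.97132 7.762773e-01  n.s.
#>       3pEk        WT 908.35644 55.74431 1.301054e-07   ***
```

Reading the output: most Vκ⁺ fragments gain 3′Eκ contacts when
signaling is strong (52.5% increase vs 14.9% decrease); the two
enhancers' per-gene interaction profiles are coordinated in WT pre-B
cells (R² = 0.79) but much less so under low signaling (R² = 0.33); and
the 3′Eκ enhancer shows no preference for Vκ-gene fragments in pro-B
cells (p = 0.78, means 76 vs 85 RPM) but a strong one in WT pre-B cells
(908 vs 56 RPM, p < 0.001) — the planted focusing behaviour the
analysis is designed to detect. `igk_run/` additionally holds the
fragment BED, per-condition bedGraph tracks, 100-kb binned tracks,
TSV tables, FISH centroids, the planted-parameter truth JSON, a figure
report and `results.json`, which is byte-identical across reruns with
the same seed.

Real datasets enter through the same building blocks:
`read_fragment_map()` (BED), `read_features()` (BED per feature kind),
`read_usage_table()` (TSV), per-fragment count profiles, and
`read_fish_table()` (TSV of probe centroids).

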