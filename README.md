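# heataa

Does heat stress induce genes whose proteins look like thermophile
proteins? `heataa` is an R package for relating a gene's transcriptional
response to heat stress to the physico-chemical makeup of the protein it
encodes: amino-acid class composition (charged / polar / hydrophobic),
GC content and intrinsic disorder, with the confound-controlled statistics
needed to make the comparison honest. It is aimed at researchers analysing
temperature-stress expression experiments (microarray or otherwise) who
have probe-level intensities, probe annotations and a proteome in hand.

The central statistic is the heat response of each gene,

    R = log2( E[24h, 37°C] / E[24h, 22°C] ),

computed after probe quality filtering ("well above background" in ≥ 3 of
4 replicates), annotation filtering (E-value ≤ 9.9×10⁻⁶, identity ≥ 98 %,
overlap ≥ 75 % of the probe, multi-gene probes discarded) and two-step
averaging (replicates → probe, probes → gene). Per-protein features come
from the longest isoform: the 20 amino-acid frequencies, class fractions
(charged = R+D+E+K; polar = N+C+Q+H+S+T+W+Y; hydrophobic = the rest), CDS
GC content, and the percent of residues in intrinsically disordered
regions, scored by windowed pairwise-energy estimation (30-residue window,
logistic score, strict > 0.4 call). The statistical battery covers
Spearman and first-order partial Spearman correlations
(ρ_xy·z = (r_xy − r_xz r_yz)/√((1−r_xz²)(1−r_yz²))), Mann–Whitney group
comparisons, one-tailed binomial sign tests across subcellular
compartments, and Benjamini–Hochberg correction within each 20-amino-acid
family.

Because the original data cannot be assumed downloadable, the package
ships a first-class synthetic-data generator whose couplings between
protein features and R are recorded, so every stage is verifiable by
parameter recovery.

## Worked example

Simulate a study-scale dataset with the default (study-like) couplings and
run the full pipeline:

```r
library(heataa)
library(dplyr)

ds  <- simulate_dataset(synthetic_truth(seed = 1, n_genes = 2000))
cfg <- pipeline_config(probes = ds$probe_table, hits = ds$hit_table,
                       proteins = ds$proteins, cds = ds$cds,
                       locations = ds$locations, seed = 1)
run <- run_pipeline(cfg)
run
#> Heat-response analysis run
#>   genes with R: 1952 (induced 945, repressed 1007, zero 0)
#>   strong: R>1 344, R>2 53, R<-2 57
#>   features: 2000 genes; association rows: 96
#>   seed 1, config 663c4cfbabe282d09c274f685ab1802d
```

48 of the 2000 genes lose their expression estimate to the quality and
multi-gene-probe filters, as designed. The class-level associations
(Table-1 shape) recover the injected pattern — induced proteins are richer
in charged residues and disorder, poorer in polar and hydrophobic ones:

```r
tidy(run) |> filter(control == "none", type != "amino_acid")
#> # A tibble: 4 × 8
#>   feature     type        control     rho        p     q     n significant
#>   <chr>       <chr>       <chr>     <dbl>    <dbl> <dbl> <int> <lgl>
#> 1 charged     class_total none     0.238  1.70e-26    NA  1952 TRUE
#> 2 polar       class_total none    -0.0914 5.30e- 5    NA  1952 TRUE
#> 3 hydrophobic class_total none    -0.124  3.92e- 8    NA  1952 TRUE
#> 4 disorder    disorder    none     0.226  5.67e-24    NA  1952 TRUE
```

Stratifying by subcellular compartment and testing whether the correlation
signs depart from the 50 % expected at random:

```r
glance(run$compartments)
#> # A tibble: 4 × 6
#>   feature     n_compartments n_positive n_negative majority_sign binomial_p
#>   <chr>                <int>      <int>      <int> <chr>              <dbl>
#> 1 charged                 10          9          1 positive        0.0107
#> 2 disorder                10         10          0 positive        0.000977
#> 3 hydrophobic             10          3          7 negative        0.172
#> 4 polar                   10          2          8 negative        0.0547
```

A charged-composition correlation positive in 9 of 10 compartments gives
the exact one-tailed binomial p = 0.011. `autoplot()` methods exist for
the association, group-comparison and compartment results, and
`run_pipeline()` writes TSV/JSON result tables (stamped with the seed and
a configuration hash) when given an `out_dir`.

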