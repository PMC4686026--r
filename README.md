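# mthaplostat

Tidy population-genetics tools for mitochondrial haplotype data, built
around the countrywide survey of African lion (*Panthera leo*) 12S–16S
mtDNA in Zambia: 165 individuals from five areas (Luangwa Valley LV,
Corridor CO, Lower Zambezi ZA in the east; Kafue KF, Sioma Ngwezi SI in
the west) carrying eight haplotypes over a 1882-column alignment.

Because mtDNA is maternally inherited, haplotype structure reveals
matrilineal gene flow: in lions, females stay while males disperse, so
strong geographic structure in mtDNA alongside shared haplotypes is the
signature of male-biased dispersal. The package covers the full analysis
chain for this kind of data:

* **Haplotype calling** against a catalog of polymorphic-site profiles
  (1-based alignment columns × states), with the replication rule for
  novel haplotypes: a previously unseen state vector is accepted outright
  when observed two or more times, and flagged for re-sequencing when
  observed once.
* **Molecular diversity indices** — haplotype frequencies
  `f = n_h/n` with sampling s.d. `sqrt(f(1−f)/(n−1))`; unbiased gene
  diversity `h = n(1 − Σp²)/(n − 1)` (the probability that two sampled
  individuals carry different haplotypes) with its sampling variance
  `V = 2/(n(n−1)) · {2(n−2)(Σp³ − (Σp²)²) + Σp² − (Σp²)²}`;
  nucleotide diversity; polymorphic-site counts split into transitions,
  transversions and per-column indels.
* **Pairwise-difference summaries** within and between populations, and
  Nei's corrected (net) distance `d = π_XY − (π_X + π_Y)/2`.
* **One-level AMOVA** with identity or nucleotide-difference distances:
  sums of squares, variance components Va/Vb,
  `Fst = Va/(Va + Vb)`, and a label-permutation test with
  `p = (1 + #{Fst* ≥ Fst})/(R + 1)`.
* **Median-joining haplotype networks** with majority-consensus median
  (Steiner) vectors, exported as edge-list TSV or GraphML.
* **A synthetic-data generator** reproducing the study's sampling design
  cell-for-cell, so the entire pipeline runs and is tested without any
  sequence download.

Every user-facing function takes a data frame first and returns a tibble,
so analyses chain with the pipe; the AMOVA fit supports `tidy()`,
`glance()` and `autoplot()`.

## Worked example

```r
library(mthaplostat)
library(dplyr)

study <- generate_study(seed = 1)              # 165 samples x 1882 columns
calls <- call_haplotypes(study$alignment, study$catalog)
data  <- left_join(tidy(calls), study$metadata, by = "sample_id")

gene_diversity(data)
#> # A tibble: 1 × 6
#>       n n_haplotypes     h     sd sum_p2 sum_p3
#>   <int>        <int> <dbl>  <dbl>  <dbl>  <dbl>
#> 1   165            8 0.732 0.0174  0.273 0.0863

amova(data, group = "region", permutations = 1000, seed = 1)
#> One-level AMOVA (identity distances), 2 populations, N = 165
#>
#>                term  df    SSD variance percent     p_value
#>   Among populations   1 18.966  0.22785    47.5 0.000999001
#>  Within populations 163 41.052  0.25185    52.5 0.000999001
#>               Total 164 60.018  0.47971   100.0          NA
#>
#> Fixation index Fst: 0.47499
#> Permutation p-value: 0.000999 (1000 permutations)
```

A gene diversity of 0.73 says that two lions drawn at random from the
whole country would carry different haplotypes 73% of the time; the Fst
of 0.47 between the eastern and western regions (p < 0.001) indicates
essentially no matrilineal gene flow between them, while the among-area
Fst inside the eastern region,

```r
east <- filter(data, region == "eastern")
D <- pairwise_difference_matrix(calls$catalog)
round(glance(amova(east, group = "area", distances = D))$Fst, 2)
#> [1] 0.05
```

shows free female movement within a region. The median-joining network
summarises the mutational paths between haplotypes:

```r
net <- median_joining_network(lion_haplotype_catalog(), counts = data)
net$edges |> filter(weight == 1) |> head(3)
#> # A tibble: 3 × 3
#>   from  to    weight
#>   <chr> <chr>  <int>
#> 1 H1    Z3         1
#> 2 H10   H11        1
#> 3 H10   Z1         1
```

`run_study_analysis(config)` orchestrates all stages (calling, diversity,
distances, AMOVA, network) into a TSV/JSON report bundle with a checksum
manifest, and `exec/mthaplostat` exposes the same steps as a command-line
tool (`simulate`, `call`, `diversity`, `amova`, `network`, `run`).

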