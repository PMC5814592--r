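# cpmapr

Genetic linkage maps for outbred F1 ("CP", cross-pollinated) mapping
populations genotyped on a wheat SNP array, and identification of
wheat–wild relative chromosome addition/substitution lines.

`cpmapr` targets the analysis situation of mapping a diploid wild wheat
relative (e.g. *Agropyron cristatum*, genome P) by hybridising it to a
high-density wheat array: two heterozygous parents and ~119 F1 progeny,
markers segregating in the CP patterns `hk×hk` (both parents
heterozygous), `lm×ll` (father informative) and `nn×np` (mother
informative), low call rates, genotyping error and segregation
distortion. On top of the maps, alignment hits of marker probes against
the hexaploid wheat genome anchor each linkage group to a wheat
homoeologous group (1–7), reveal collinearity blocks and rearrangements,
and mediate the identification of derivative lines carrying added or
substituted alien chromosomes from heterozygosity and missingness
profiles.

## What it computes

* **Genotype QC** — array performance categories re-expressed at
  genotype level (PolyHighResolution, NoMinorHomozygote, ...), 80%
  call-rate thresholds, CP segregation-pattern classification, and
  chi-square segregation-distortion tests (1:2:1 for `hk×hk`, df = 2;
  1:1 for the testcross patterns, df = 1).
* **Two-point linkage** — maximum-likelihood recombination fractions and
  LOD scores for every pair type: the testcross closed form
  r̂ = min(R, N−R)/N with LOD = R·log₁₀(2r̂) + (N−R)·log₁₀(2(1−r̂));
  the full 3×3 multinomial likelihood maximised over r and parental
  phase for `hk×hk` pairs; and mixed testcross/intercross bridging.
* **Map construction** — single-linkage grouping at LOD > 11 (groups of
  more than 15 markers retained), co-segregation binning into loci,
  seriation plus windowed 2-opt/or-opt ordering, Kosambi distances
  d = 25·ln((1+2r)/(1−2r)) cM, and male, female and integrated maps with
  the usual summaries (length, mean/max gap, "Gap ≤ 5" share).
* **Homoeology & synteny** — e ≤ 1e−05 hit filtering with best hit per
  subgenome, per-LG homoeologous-group proportions with an ambiguity
  flag (the signature of a 4P/2P-style rearrangement), monotone-chain
  collinearity blocks, and 500 Mbp pseudo-physical scaling.
* **Introgression calling** — per-chromosome and 50 Mb/1 Mb
  sliding-window heterozygosity, genome-specific-marker missingness,
  robust (median + 5·MAD) calling of added P chromosomes via their three
  wheat homoeologs, and substitution calling for missing wheat
  chromosomes homoeologous to an added P.
* **Synthetic data** — a first-class simulator for all of the above:
  CP crosses with Poisson crossovers, error/missingness/distortion;
  hit tables with rearrangement and noise; and a 35-line
  addition/substitution panel with known truth.

## Worked example

```r
library(cpmapr)

truth <- sim_map_truth(seed = 1)                    # 7 chromosomes x 100 markers
sim   <- simulate_cp_cross(truth, sim_cross_config(seed = 1))
qc    <- filter_markers(marker_qc(sim$gm))
maps  <- build_maps(sim$gm, qc)
maps$integrated
#> genetic_map (integrated): 7 linkage groups, 617 markers, 879.4 cM
head(map_summary(maps$integrated), 3)
#>    lg n_markers n_loci length_cm mean_gap_cm max_gap_cm frac_gap_le5
#> 1 LG1        93     92  136.2641    1.497407   6.807909    0.9450549
#> 2 LG2        91     90  128.7439    1.446560  10.741509    0.9550562
#> 3 LG3        90     88  119.5569    1.374217   7.923147    0.9540230

hits <- filter_hits(simulate_hit_table(truth, seed = 1))
assign_homoeology(maps$integrated, hits)$assignment[1:3, c("lg", "assigned_p", "proportion", "ambiguous")]
#>    lg assigned_p proportion ambiguous
#> 1 LG1         6P  0.8602151     FALSE
#> 2 LG2         2P  0.9120879     FALSE
#> 3 LG3         5P  0.9000000     FALSE
```

Here 86–91% of each linkage group's filtered hits fall in a single
wheat homoeologous group, which names the corresponding P chromosome.
Further down the same table, the group holding the simulated 4P→group-2
rearrangement carries an ambiguity flag (its hits split between groups
4 and 2); the assignment is never silently overridden — external
evidence is supplied through the `overrides` argument.

Identify a substitution line:

```r
wm  <- default_wheat_marker_map()
lin <- simulate_introgression_lines(
  list(line_spec("cand", "6P", substitutions = data.frame(p = "6P", wheat = "6D"))),
  wm, seed = 1)
rep_ <- batch_report(lin$gm, wm)
rep_$report$label
#> [1] "6P/6D substitution line"
```

The whole pipeline (simulate → QC → maps → homoeology → introgression,
with every artifact persisted and a run manifest) runs as

```r
run_pipeline(pipeline_config(seed = 1), outdir = "run1")
```

or from the shell via the thin wrapper `inst/exec/cpmap`.

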