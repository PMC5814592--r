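---
title: "Two-point CP linkage mapping and alien introgression detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-point CP linkage mapping and alien introgression detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmapr)
```

# The analysis problem

A diploid outbreeding wild relative of wheat (such as *Agropyron
cristatum*, genome P) can be genotyped on a high-density wheat SNP
array. The mapping population is an F1 of two heterozygous parents (a
"CP" cross): every marker segregates in a parent-specific pattern, and a
genetic map must be assembled from two-point recombination evidence
while coping with low call rates, call errors and segregation
distortion. Once linkage groups exist, marker-to-wheat alignment hits
anchor each group to one of the seven wheat homoeologous groups, expose
collinearity and rearrangement, and — through that homoeology table —
let heterozygosity and missingness profiles identify which alien
chromosomes a wheat–wild relative derivative line carries.

`cpmapr` implements this pipeline end to end, together with a
synthetic-data module that generates every input with known ground
truth, so the whole analysis is testable without any external dataset.

# Genotype model and QC

Calls are biallelic (`AA`, `AB`, `BB`, `NC`). Only three CP patterns are
informative for mapping from such calls: `hk×hk` (AB × AB, both meioses
observed through a 1:2:1 progeny ratio), `lm×ll` (father AB, 1:1) and
`nn×np` (mother AB, 1:1). Patterns are read off the parental genotypes;
progeny calls impossible under the pattern are counted and reported, not
fatal. When a parent call is missing, the pattern is inferred only if
the progeny classes force it (all three classes present forces `hk×hk`);
anything else is dropped with reason "parent NoCall" — guessing a
testcross orientation silently would corrupt phase downstream.

Array performance categories are re-expressed at genotype level. The
"at least two examples of the minor allele" rule for PolyHighResolution
is read as *two carrier samples* (a heterozygote counts as one carrier)
— the stricter deterministic reading. The Off-Target Variant category
cannot be derived from calls (it needs probe intensities) and is
accepted only as a pass-through label.

Distortion is tested by chi-square goodness of fit (df 2 or 1). Two
thresholds govern filtering:

* `data_tolerance` (default **p ≥ 0.001**): the distortion cut-off. The
  upstream tool this emulates uses an unprinted default; 0.001 is a
  conservative mapping-community value and is exposed as a flag.
* `missing_limit` (default **0.2** among progeny), consistent with the
  80% variant call-rate regime (`call_rate_threshold = 0.8`, relaxed
  from the array default of 97% because wild-relative DNA hybridises
  poorly).

# Two-point estimation

For a same-parent testcross pair the transmitted parental allele is
observed directly; with \(R\) recombinant of \(N\) informative progeny
under the better phase, \(\hat r = \min(R, N-R)/N\) and
\(\mathrm{LOD} = R\log_{10}2\hat r + (N-R)\log_{10}2(1-\hat r)\).

For an `hk×hk` pair both meioses inform. The 3×3 genotype table is a
multinomial whose class probabilities follow from the two parental
gamete distributions; the likelihood is maximised over \(r\) for each
parental phase combination (`cc`, `cr`, `rr`; `cr` and `rc` give the
same genotype distribution and are reported as `cr`). A shared \(r\) is
assumed for the two meioses — the standard two-point simplification.
Numerically, a 0.001-step grid scan locates the global optimum per
phase and golden-section search refines it far below the 1e-6
requirement; tests verify equality with an independent exhaustive
1e-4-grid oracle to ≤ 1e-3.

For a mixed pair (testcross × `hk×hk`), only the testcross parent's
meiosis carries linkage. A heterozygous call at the `hk×hk` marker is
ambiguous for parental origin and has class probability 1/4 whatever
\(r\), so the maximum-likelihood estimate reduces exactly to the
testcross estimator on the progeny with homozygous `hk×hk` calls — this
is how `hk×hk` markers bridge the two parental maps into the integrated
map. Opposite-parent testcross pairs share no meiosis: LOD is defined as
0 and the pair flagged.

Pairs are computed on pairwise-complete progeny only, and pairs with
fewer than `min_informative = 20` informative progeny are excluded from
grouping and distance estimation.

# Grouping and ordering

Grouping is single-linkage transitive closure over pairs with
LOD > `lod_limit` (default **11**); groups with more than
`min_group_size = 15` markers are retained, numbered by decreasing size
then smallest member id.

Ordering within a linkage group proceeds in stages:

1. **Binning.** Markers with \(\hat r = 0\) and no discordant calls
   collapse into loci; each locus maps to one position.
2. **Locus distances.** Pair estimates are aggregated to locus level by
   informative-count-weighted means. Only short, well-supported
   distances (\(\hat r <\) `r_max` = 0.4, locus-level LOD ≥
   `lod_direct` = 3) are trusted directly, and of those each locus keeps
   only its `knn = 8` nearest neighbours *mutually* — a pair must be
   among the best options of both endpoints. This matters: the
   phase-corrected \(\hat r\) of a weakly linked pair scatters downward,
   and the minimum over many such pairs produces "shortcut" edges that
   fold any embedding built on them. Mutual selection removes them
   because interior loci always have closer genuine neighbours; if the
   graph disconnects (a real map gap), components are re-bridged through
   the candidate edge with the strongest LOD — not the smallest
   \(\hat r\), which is an extreme-value statistic. Long distances are
   then rebuilt additively by all-pairs shortest paths (the Isomap
   construction).
3. **Seriation and polish.** The initial order is the first classical
   MDS coordinate of the completed metric (computed from both the
   mutual-kNN and the denser union-kNN variant). Polish uses 2-opt
   segment reversals and or-opt segment relocations (lengths 1–10,
   optionally reversed), screened by the adjacent-distance delta but
   *accepted* only if a windowed objective improves: the sum of
   distances over rank offsets 1..6, weighted 1/t. Summing over a window
   averages the noise of individual two-point estimates, so a move
   cannot win by exploiting one lucky small distance. A deterministic
   double-bridge iterated local search (eight fixed cut patterns)
   escapes fold-shaped optima that no single reversal or relocation can
   repair. The marker ordering runs `n_iterations = 40` improvement
   rounds per polish with early stopping. Everything is deterministic
   for fixed input: ties break toward the incumbent, and orientation is
   normalised so the smallest marker id sits in the first half.
4. **Positions.** Adjacent-locus \(\hat r\) are corrected for the
   additive inflation that call errors cause (below), transformed by the
   Kosambi map function \(d = 25\ln\frac{1+2r}{1-2r}\), and cumulated
   from 0.

## Two-point error shaving

A per-locus call-error rate \(e_j\) inflates every two-point estimate
involving that locus: \(r_{obs}(a,b) \approx r(a,b) + e_a + e_b\).
Summed over ~100 adjacent intervals, a 1% call-error rate roughly
doubles a chromosome's apparent length. Multipoint HMMs absorb this with
an explicit error parameter; a two-point pipeline can instead estimate
the offsets from flanking triples: for ordered loci \(a<j<b\),

\[(r_{aj} + r_{jb} - r_{ab})/2 \;=\; e_j + r_{aj}^{true}\,r_{jb}^{true},\]

the product term arising from no-interference additivity
(\(r_{ab} = r_{aj} + r_{jb} - 2 r_{aj} r_{jb}\)). A first pass takes
per-locus medians of the raw triple differences; a second pass subtracts
the product of pass-1-corrected fractions, removing the structural term.
Offsets are deliberately not floored at zero (the median fluctuates
symmetrically and truncation would bias every offset upward, shrinking
the map); only the final corrected adjacent \(\hat r\) is floored. The
correction is on by default (`correct_errors = TRUE`) and, on simulated
truth, brings integrated map length within a few percent both with and
without call errors.

# Homoeology, synteny, introgression

Hits are filtered at `e_cutoff = 1e-05`, keeping the best hit per marker
per wheat subgenome and flagging the overall best. Per linkage group,
the homoeologous-group distribution of overall-top hits (leading digit
of the wheat chromosome, A/B/D pooled — an alternative counting all
subgenome top hits is a documented switch) assigns the group; the
corresponding P chromosome is `<group>P`. An ambiguity flag fires when
the runner-up group reaches `ambiguity_ratio = 0.5` of the winner —
the signature of an interchromosomal rearrangement splitting a group's
hits. The assignment is never silently overridden; external evidence
(e.g. verified addition lines) enters through an explicit override
table, recorded as such.

Collinearity blocks are maximal marker chains monotone in both map order
and physical rank, allowing `max_rank_gap = 3` skipped markers, found
greedily by longest-chain dynamic programming (≥ `min_block = 5`
markers). Blocks on a non-assigned group are rearrangements; off-group
markers outside blocks are small-fragment noise. Maps are rescaled to a
fixed 500 Mbp pseudo-length per chromosome for cross-genome drawing.

Derivative lines are profiled per wheat chromosome: heterozygosity ratio
(AB / called) and, on the genome-specific marker subset only, the
missing rate — only genome-specific probes can reveal a physically
missing chromosome, the rest also hybridise to the homoeologous copies.
Windows are 0-based half-open, 50 Mb advancing by 1 Mb, clipped at the
chromosome end (the final clipped window closes at the end so boundary
markers are counted once); windows with fewer than 10 called markers are
flagged uninformative. Calling uses a robust threshold, median +
`het_z_min = 5` × spread across the line's 21 chromosomes, where the
spread is the MAD floored by the binomial standard error of the rates —
a chance low MAD cannot make the threshold tighter than the data
support. Hot chromosomes vote for their homoeologous group; with an
external alien-pair count (from cytology metadata such as "42W + 4P")
exactly that many top groups are called, otherwise groups with at least
two hot homoeologs. A high-missingness chromosome is called substituted
only when homoeologous to a called addition; unexplained missingness is
reported, not called. Labels are composed deterministically
(`"2P addition and 1P/1A substitution line"`).

# The synthetic-data module

The generator defines the study conditions: 7 chromosomes of 120 cM
(the average chromosome length such maps reach) with 100 markers each,
patterns mixed 45% `hk×hk` / 27% `lm×ll` / 28% `nn×np`, 119 progeny, 1%
call error, 15% missingness, 5% of markers distorted. Crossovers are
Poisson(length/100) with uniform positions and no interference — the
simplest process consistent with two-point statistics (it follows the
Haldane map function; at the short distances that dominate map building
Haldane and Kosambi coincide). Distortion is modelled as transmission
skew of the heterozygous parent's allele with strength 0.6
(transmission 0.8:0.2): strong distortion is what the p ≥ 0.001 filter
is meant to remove, and weaker skews are indistinguishable from noise at
n = 119. Parents are simulated without error or missingness so the
pattern truth is part of the output; the QC path for missing parents is
tested directly instead.

Hit tables place each marker on a random subgenome of its true group
with physical position increasing along the chromosome; a default
rearrangement sends the proximal 40% of chromosome 4P to group 2, and
noise sends 15% of markers to uniformly random chromosomes. Wheat
chromosomes default to 600 Mb with uniformly spaced markers, 30% flagged
genome-specific.

Introgression lines elevate AB calls on the three wheat homoeologs of
each added P chromosome (Bernoulli per marker, `homoeolog_het = 0.15`
vs `baseline_het = 0.01`) and no-calls on each substituted wheat
chromosome (`substituted_missing = 0.6` vs `baseline_missing = 0.05`).
This per-marker Bernoulli model is a stand-in for whatever
cross-hybridisation mechanism raises heterozygous calls on homoeologs in
real lines — no per-probe model is claimed. The bundled 35-line panel
mirrors a realistic screen: 26 single disomic additions, three double
additions, five substitutions, and one combined addition + substitution
line.

What passing tests show — and do not show — about real data: the
generator reproduces the statistical structure of a CP array screen
(pattern mix, error, missingness, distortion, rearrangement, noise), but
not probe-level artefacts (cluster geometry, off-target variants,
position-dependent error), linked viability selection, or crossover
interference. Recovery results on it validate the machinery, not any
particular organism's map.

# Determinism and reproducibility

One master seed drives everything; each stage derives its own stream
via a deterministic hash of the seed and a stage label, so adding a
stage never perturbs another stage's draws. Mapping of fixed input uses
no randomness at all. `run_pipeline()` persists every artifact with a
version/parameter-hash header and no timestamps; re-running with the
same configuration is byte-identical, which the tests verify by file
checksums.

# Problem sizes used by the test suite

The full study-condition dataset (7 × 100 markers, 119 progeny) is
mapped once in the acceptance tests (~40 s); estimator-oracle
comparisons use 200 random instances per pair type against 1e-4-grid
maximisation; null calibration uses 2000 markers; homoeology assignment
is repeated over 100 simulated hit tables; chaining is checked against
exhaustive subset enumeration on 500 instances of up to 15 markers; the
introgression panel runs 35 lines × 10 seeds; and the determinism check
reruns a 5 × 50-marker pipeline twice. Unit tests use smaller sizes of
the same generators.

# Known limitations

* Two-point only: ordering accuracy is bounded by pairwise information
  at n = 119; a multipoint likelihood would discriminate orders that
  two-point statistics cannot. Occasional linkage groups order at
  Spearman ~0.91 against truth where the two-point objective genuinely
  prefers the wrong order.
* Grouping at LOD > 11 can split a chromosome at a sparse marker region
  whose best cross-gap pair falls just under the threshold; with real
  data the remedy is marker density, and the threshold is exposed.
* The integrated map assumes equal male and female recombination when
  estimating `hk×hk` pairs with a single shared r.
* Arm-level resolution (short/long arm of a wheat chromosome) is
  reported only through window tracks and bp positions; no centromere
  table is bundled.
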