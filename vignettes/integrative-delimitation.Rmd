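---
title: "Integrative species delimitation for mixed-ploidy complexes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative species delimitation for mixed-ploidy complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyrank)
```

## The problem

Polyploid plant complexes resist the usual species-delimitation toolbox.
Polyploidisation creates reproductively isolated lineages instantly, often
without the morphological, ecological or genetic divergence that delimitation
methods key on, and the multispecies coalescent machinery used for diploids
has no accepted analogue for mixed-ploidy data. `polyrank` implements a
pattern-based alternative: measure differentiation between candidate
morphotaxa on four independent axes — genetic, geographic, ecological and
morphological — test each axis with permutation statistics, and convert the
per-pair evidence pattern into explicit species-vs-subspecies
recommendations through an ordered, auditable rule list (the "Wettstein
tesseract", after von Wettstein's classic morphology–ecology–geography
triad extended by a genetic axis).

Every stage is exercisable on synthetic data with planted truth, so the
whole pipeline can be validated end-to-end without any external downloads.

## Genetic axis

**Distances.** Individual-level allele frequencies (`dosage / ploidy`) make
diploid and tetraploid samples directly comparable. For samples $x, y$ and
the pairwise-complete site set $L$, Nei's (1972) standard distance is

$$J_x = \frac{1}{|L|}\sum_{l}\sum_i x_{li}^2,\quad
  J_{xy} = \frac{1}{|L|}\sum_{l}\sum_i x_{li}y_{li},\quad
  I = \frac{J_{xy}}{\sqrt{J_x J_y}},\quad D = -\ln I.$$

$D$ is capped at 10 (default, recorded in the result) because $-\ln I$
diverges for disjoint allele sets. Missing genotypes are removed pairwise;
pairs sharing fewer than 50 sites (configurable) are flagged rather than
silently trusted. Note that individual-level $D$ does not vanish between
samples drawn from one population — binomial sampling noise keeps it
positive — which is why the no-differentiation limit is checked on
taxon-pooled frequencies (`pool_by_taxon = TRUE`).

**Embedding.** Distances enter a principal coordinate analysis. When the
Gower-centered matrix has negative eigenvalues, the Lingoes correction adds
$2c_1$ (with $c_1 = |\lambda_{\min}|$) to all squared off-diagonal
distances, shifting every non-trivial eigenvalue up by $c_1$; score-space
distances then reproduce the corrected input distances exactly. Clustering
runs on the leading coordinates that explain at least 50% of the variance.

**Consensus clustering.** The weighted ensemble of random-$(k)$ $k$-means
draws, per run, 60% of the features, 80% of the samples and
$k \sim \mathcal U\{2, \dots, 14\}$ (capped at one below the subset size so
the silhouette stays defined), fits $k$-means with $k$-means++ seeding, and
weights the run by

$$w = \frac{s + 1}{2}\; Q\; \Big(\prod_c q_c\Big)^{1/C},$$

where $s$ is the mean silhouette and $Q$, $q_c$ the clustering- and
cluster-level consistencies with the fuzzy must-link / must-not-link
constraints ($Q = 1 -$ violated weight / applicable weight). The published
description of the weight is only qualitative ("non-linearly combined"), so
the product form is isolated in one place and recorded with the results.
Weighted co-assignments accumulate into the consensus matrix
$C_{ij} = M_{ij}/N_{ij}$ over co-sampled pairs.

**Choosing $k$.** Average-linkage clustering of $1 - C$ is cut at each $k$
and scored by the Calinski–Harabasz index and a Bayesian information
criterion. Two design points deserve emphasis:

* The BIC is the hard-assignment spherical-Gaussian (x-means) form,
  $-2\,\mathrm{LL} + p\ln n$ with pooled variance
  $\hat\sigma^2 = SS_w/(d(n-k))$ and $p = (k-1) + dk + 1$ parameters. A
  simpler $n d \ln(SS_w/nd) + k d \ln n$ criterion cannot plateau at the
  true cluster number in low dimension: splitting a genuine Gaussian
  cluster always buys more likelihood than the $d\ln n$ penalty costs, and
  in our planted-recovery simulations it selected $k_{\max}$ on every seed.
  The x-means form recovers the planted $k$ reliably.
* Partitions are *scored* on the full PCo embedding even though the
  ensemble *clusters* in the ≥50%-variance subspace (`X_score` argument).
  Scoring only in the reduced space lets spurious splits exploit those few
  axes; the full embedding penalises them (30/30 vs 27/30 planted-$k$
  recoveries in our calibration).

With random $k$ up to 14, runs with $k$ above the planted cluster number
*must* split true clusters, so within-cluster consensus values average well
below 1 even for perfectly separated data; what identifies the structure is
the contrast (across-cluster consensus ≈ 0) and the cut of the consensus
tree, not the absolute within-cluster value.

## Genealogical axis (allopolyploid parentage)

For a (diploid, diploid, tetraploid) individual triplet, each SNP with both
parents homozygous is classified: parents fixed for different alleles $a
\ne b$ and child fixed for $a$ → category 1, fixed for $b$ → category 2,
carrying exactly $\{a, b\}$ → category 5 (homeo-SNP, the signature of
recent allopolyploidy); any child allele outside $\{a,b\}$ → categories
3+4 (derived; not separable on unphased data). Categories are counted per
individual combination, averaged per child individual and then across
child individuals. A parent scan evaluates every unordered pair of
candidate diploid taxa and ranks pairs by mean category-5 proportion.
Classification with parents fixed for *different* alleles and a novel child
allele is still reported as 3+4 but flagged in a diagnostic column, since
the published category definitions only cover the identical-parent case.

## Ecological axis

Environmental layers are standardized per layer, soil-depth triplets are
averaged first, and a PCA across cells yields three PC rasters. The default
suitability model is a deliberately simple, deterministic multivariate
Gaussian envelope: the Mahalanobis distance of each cell's environment to
the centroid of the occupied cells, mapped through the $\chi^2_d$ survival
function. MaxEnt is not reimplemented — the scientific content here is the
*comparison* of niches, not the niche model itself — but a
presence–background logistic model and a grid adapter for externally
produced suitability surfaces are provided behind the same interface.

Overlap between two suitability surfaces normalized to probability masses
$p, q$: Schoener's $D = 1 - \tfrac12\sum|p - q|$ and Warren's
$I = 1 - \tfrac12\sum(\sqrt p - \sqrt q)^2$, with
$0 \le D \le I \le 1$. The equivalency test pools both taxa's occurrences,
re-splits them at random preserving sample sizes, refits both models and
counts replicates with overlap at or below the observed value (one-tailed:
low observed overlap rejects equivalency). Taxa whose occurrences fall in a
single raster cell (point endemics) raise a typed `NICHE_UNDEFINED`
condition that propagates as "n/a" through all pairwise tables.

## Geographic axis

The realized range is approximated from the suitability surface: binarize
at 0.25, label 8-connected components, and drop components containing no
collection — predicted but unsampled regions separated from the
collections by unsuitable areas are not evidence of presence. Occupied
cells below the threshold are retained (a collection *is* presence). Range
overlap uses $|A \cap B| / \min(|A|, |B|)$ so a narrow endemic nested
inside a widespread taxon scores 1 (parapatry is not allopatry); Jaccard
is available by flag. The sympatry test permutes taxon labels over the
pooled points (400 replicates by default), rebuilds both pruned ranges and
counts replicates with overlap at or below observed.

## Morphological axis

Leaves are straightened before measurement: the mid-vein is resampled at
1-px arc-length steps and every outline vertex maps to (arc length of the
nearest vein point, signed perpendicular offset), which removes drying- and
growth-induced bending while preserving area to within a few percent.
Contours extracted from binary masks use marching squares at level 0.5 with
a 5-vertex circular moving average; without smoothing, pixel staircase
inflates perimeters by ~10% and the dissection index of a circle by ~11%.

The leaf dissection index is $P^2 / 4\pi A$ — 1 for a circle, scale
invariant, growing with both elongation and incision. Shape is captured by
20-harmonic elliptic Fourier descriptors (chord-length parameterization),
normalized so that $A_1 = 1$, $B_1 = C_1 = 0$; the residual half-turn
ambiguity of the first-harmonic phase is resolved by the sign of the first
substantial even-harmonic coefficient, making the 77-vector reproducible to
machine precision across rotated, rescaled and start-shifted copies. The
"ellipse = first harmonic" intuition holds only in the small-eccentricity
limit under chord-length parameterization (residual harmonics scale with
the ellipse parameter $\lambda = (a-b)/(a+b)$), which the tests respect by
using a near-circular ellipse.

Descriptors are decorrelated by centered (not re-standardized) PCA —
normalized EFA coefficients are already commensurate — and the first 15 PCs
enter two tests per taxon pair: a permutation test of the mean cross-taxon
Euclidean distance (5000 permutations) and distance-based NPMANOVA
(Anderson's pseudo-$F$, 100 permutations), which on 1-D Euclidean data
equals the classical ANOVA $F$ exactly. Dissection differences use Welch's
test. Each family of 28 pairwise tests is Bonferroni-corrected with
truncation at 1.

## Rank integration

`build_evidence_matrix()` reduces everything to per-pair flags:
GEN (different consensus clusters at the BIC-optimal $k$), GEO (sympatry
rejected ⇒ allopatry), EcoD/EcoI, and the three morphology tests, each
`sig` / `nonsig` at α = 0.01 on corrected p values, or `na` for
untestable point-endemic pairs. The rule list is ordered and total, and
field knowledge enters only as *explicit named overrides*, never as hidden
heuristics:

1. hybrid-swarm conservatism: genetically distinct, but declared
   introgressive hybrid swarms → subspecies;
2. genetically distinct + any ecological or morphological corroboration →
   distinct species;
3. genetically undifferentiated + allopatric (or untestable endemic) + any
   corroborating axis or a declared edaphic difference → subspecies;
4. all testable axes green → conspecific;
5. genetic signal alone → distinct species;
6. fallback → conspecific.

The hybrid-swarm override outranks rule 2 deliberately: the documented case
it encodes (mixed stands with complete blurring of taxon limits) is exactly
a situation where significant axis-wise differentiation coexists with
ongoing gene flow, and the conservative choice must win. Running the engine
on the published evidence pattern with the two documented overrides yields
five species, two of them polytypic (one with two, one with three
subspecies) — the arrangement of the published taxonomic treatment.

## Synthetic data: what it does and does not show

* `simulate_genotypes()` uses Balding–Nichols-style Beta drift around
  shared ancestral frequencies (single interpretable parameter $F$),
  binomial dosages, allotetraploids as the sum of two parental binomial
  draws and autotetraploids as `Binomial(4, p)`. It has no linkage
  disequilibrium, no post-formation drift of the polyploid, and no
  assembly artefacts; recovery results therefore speak to the statistical
  machinery, not to RADseq data quality.
* `simulate_leaves()` draws outlines $r(\theta) = R\,(1 + a\sin m\theta)$
  stretched by an elongation factor, with log-normal per-leaf jitter,
  optional constant-curvature bending (ground-truth unbent masks are
  retained for straightening validation). Real herbarium leaves have
  asymmetric lobes, petioles and damage that this family does not model.
* `simulate_landscape()` builds gradient-plus-correlated-noise layers,
  Gaussian niches in environment space, and suitability-proportional
  occurrence sampling under sympatric / parapatric / allopatric /
  point-endemic scenarios. Cells are sampled independently; real
  collections cluster along roads and rivers.

Default study conditions used in the validation suite: planted-$k$ recovery
at $F = 0.2$, 4 taxa × 10 samples × 2000 sites with 500 ensemble runs
(the package default of 5000 runs only sharpens the consensus matrix);
parentage recovery at $F = 0.2$, 800 sites, 3 child individuals over 20
seeds; landscape tests on 40 × 40 grids with 25–30 occurrences per taxon,
200 equivalency replicates and 400 sympatry simulations.

## Numerical choices and degenerate inputs

* Permutation p values are always $(1 + \#\{T^* \ge T\}) / (B + 1)$, never
  zero, and bounded below by $1/(B+1)$.
* $k$-means++ centres receive $10^{-9}$ jitter to avoid duplicate-centre
  failures on coincident points; ties in arg-min/arg-max model selection
  resolve toward smaller $k$ (parsimony).
* The Gaussian envelope regularizes the covariance with a
  $10^{-6}\,\overline{\mathrm{diag}}$ ridge so two-cell taxa remain
  fittable.
* Distance matrices must be symmetric to $10^{-9}$; the NEXUS writer
  refuses asymmetry rather than averaging silently.
* Sub-threshold occurrence cells enter the range as singleton components;
  raising the threshold can therefore never enlarge a range.
* The sympatry test orders the pair canonically by taxon label before
  seeding, so results are argument-order invariant.

## Known limitations

* Nei distances use pairwise-complete deletion; with highly structured
  missingness (RADseq dropout correlated with divergence) distances can be
  biased in ways the flag matrix only partially reveals.
* The consensus-weight formula is one defensible choice among several; it
  is pluggable but untested against the original implementation.
* The envelope niche model is unimodal and symmetric in PC space; strongly
  bimodal niches call for the logistic alternative or an external model
  through the grid adapter.
* The rank rule list encodes a published line of reasoning that is
  narrative, not tabular; it is configuration, and should be read (and
  edited) as such.
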