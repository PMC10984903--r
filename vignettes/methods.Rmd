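---
title: "Models and methods in myeloidStates"
author: "myeloidStates authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in myeloidStates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`myeloidStates` analyses single-nucleus RNA-seq of brain myeloid cells
sampled across brain regions that differ systematically in tau and
amyloid-β burden. This vignette documents the statistical models, the
parameter choices and their rationale, what the synthetic cohort generator
does and does not emulate, and the numerical conventions — the things a
reader needs to judge what a passing test suite does and does not show.

# Study design assumptions

The package assumes a crossed design: `nDonors` donors, each assigned to
one of four pathology severity groups, each contributing one sample per
region of an ordered five-region panel (default EC, ITG, PFC, V2, V1 —
ordered by decreasing tau burden). Per donor × region sample there are
four continuous biochemical readouts: the pTau(Thr231)/Total tau ratio
(unitless), aggregated tau (assay units), tau seeding activity from a
biosensor assay (integrated FRET density), and amyloid-β plaque area
fraction (% area). All association statistics treat the *donor*, not the
nucleus, as the biological replicate wherever a readout is involved;
nucleus-level tests (hurdle DE) include donor as a fixed-effect covariate
instead.

# Nucleus QC

Four fixed rules — exonic read count > 100, mitochondrial fraction
< 0.15, detected genes ≥ 800, total UMIs ≥ 800 — followed by an adaptive
per-sample rule keeping nuclei with log(genes) and log(UMIs) inside
median ± 3·MAD of the sample's distribution. Conventions the source
protocol leaves open, fixed here:

- natural log; **unscaled** MAD (no 1.4826 consistency factor), so the
  window is ≈ ±2 standard deviations for roughly normal log-libraries;
- the MAD window is computed **once**, over the nuclei that survive the
  four fixed rules, and is not iterated;
- reject reasons have fixed precedence (exonic → mito → genes → umis →
  mad): a nucleus failing several rules reports the first.

Two consequences worth knowing. First, the adaptive window always trims
the extreme ~4% of a continuous log-library distribution, whatever the
data quality; "all clean nuclei pass QC" is therefore only a property of
the four fixed rules, and that is what the tests assert. Second, the
filter is idempotent only in its fixed part: re-running it on the kept set
recomputes the MAD window on a tighter distribution and may trim further.
The tests check fixed-rule idempotence, fixed-threshold monotonicity and
nestedness of the MAD window in its multiplier — the forms of those
invariants that actually hold.

# Myeloid subsetting

The per-nucleus score is the mean z-score (across nuclei) of
log-normalised expression over the marker panel (P2RY12, P2RY13, ITGAM,
PTPRC, CX3CR1, SPI1, C1QA, C1QB, TMEM119). The original workflow subsets
at cluster level by marker inspection; here a per-nucleus threshold
(default 0.0) makes the step automatic and testable, and cluster-level
subsetting is recovered by averaging scores per cluster. A mean-z
threshold of 0 only separates compartments when the non-myeloid fraction
is substantial — a z-score of an overwhelming majority class centres at
zero — which the default generator respects (see below).

# Clustering

Log-normalisation is `log(1 + 1e4·x/colsum)` (natural log). The top 2,000
variable genes (variance of log-normalised expression) are centred and
scaled; PCA keeps 30 components (`nPCs`); a k-nearest-neighbour graph
(k = 20) is converted to a shared-nearest-neighbour graph with Jaccard
weights (self included, edges pruned below 1/15); Louvain modularity is
run at `resolution` (0.2 for region-level work, 0.4 for the cross-region
object). Determinism: the vertex order is shuffled by the seed before
Louvain and labels are re-ordered 0-based by decreasing size, so equal
seeds give byte-identical labels. Clusters with > 75% of nuclei from one
donor (strict inequality) are flagged donor-specific and excluded from
association statistics.

Donor integration (anchor-based methods in the original workflow) is out
of scope; its statistical intent is preserved by entering donor as a
covariate in every nucleus-level test and, optionally, by per-donor
centring of PCs before graph construction.

# Association statistics

*Binomial enrichment.* For cluster c and group g with x group-g nuclei of
cluster size n and overall group share p₀: one-sided tail
P(X ≥ x), X ~ Bin(n, p₀); BH adjustment across all cluster × group
tests; enriched iff adjusted p < 0.001 **and** x/n ≥ 1.1·p₀. p₀ comes
from all non-donor-specific nuclei of the same dataset. Depletion is
reported descriptively through the observed/expected ratio.

*Proportion correlation.* Per donor, the normalised proportion is (donor's
nuclei in cluster)/(donor's nuclei in dataset); Spearman correlation
against each readout of that donor's sample in the analysed region,
significant at nominal p < 0.05. The p-value is exact — full enumeration
of the permutation null of ρ, cached per n — for n ≤ 9 without ties, and
a t approximation otherwise. Two-sided.

*Binary covariates.* Per cluster, a 2×2 chi-square with continuity
correction on (in/out of cluster) × (covariate +/−), BH across clusters.

*Cell-type annotation.* Cluster mean z of the perivascular-macrophage
panel (LYVE1, MRC1, CD163, F13A1) and of CCR2; PvM wins when its panel is
above threshold (0.5) and at least the CCR2 score (precedence), monocyte
when CCR2 alone clears the threshold, microglia otherwise.

# Pathology bins and the hurdle test

Readouts are cut into five equal-width classes over the observed range
(half-open bins, value on an interior edge → higher bin, last bin
right-closed); bins with < 3 contributing donors are invalid. An
equal-frequency mode exists as an option. Densities are per-bin cluster
fractions (rows sum to 1), compared between adjacent valid bins.

The hurdle DE test has a discrete part — logistic regression of detection
(count > 0) on group + covariates, LRT of the group term — and a
continuous part — Gaussian LRT of the group term on log-normalised
expression among detected nuclei (2n·log ratio of RSS). Combined
χ² = sum of parts, df = sum of dfs; BH across genes. Donors with < 5
nuclei in a comparison are pooled into "other"; a rank check refuses
designs where covariates absorb the group. On quasi-complete separation
the logistic part falls back to ridge-penalised IRLS (penalty λ = 10⁻³·n
applied equally to full and null fits, intercept unpenalised) with a
warning. log2FC is the difference of mean log2-normalised expression —
the convention the downstream |log2FC| filters assume — not a model
coefficient. The contract is calibrated type-I error and planted-effect
recovery, not equality with any particular shrinkage-based
implementation; genes detected in fewer than 2 nuclei per side skip the
continuous part with the df adjusted.

Per-cluster DE tests clusters of ≥ 100 nuclei against the homeostatic
cluster (or the rest), significant at adjusted p < 0.01, |log2FC| > 0.2,
and detection ≥ 10% on the upregulated side.

# Trajectory and phasic genes

A principal tree is the minimum spanning tree over cluster centroids in
PC space. Each nucleus is projected to its nearest point on any tree edge;
pseudotime is the geodesic (along-tree) distance from the root centroid,
which makes it invariant to rigid rotations of the embedding. The named
trajectory comprises nuclei projecting onto the root→target path. This is
a deterministic, desk-scale replacement for learned principal graphs; the
downstream filters are implemented exactly:

- aggregate expression into 100 equal-count pseudotime bins; keep genes
  detected (bin mean > 0) in **more than** 50 bins;
- expressed in **more than** 100 cells (both strict inequalities);
- Moran's I on a symmetrised kNN graph (k = 20) over the trajectory's
  nuclei, z-score under the normality null (E[I] = −1/(n−1)); keep z > 10
  and BH-adjusted one-sided p < 0.001 ("Moran's test statistic" is read
  as the z-score, the convention of graph-based trajectory tools);
- phasic rule: split pseudotime into four rank-based quartiles of equal
  cell counts (sizes differ by ≤ 1); per gene, z-scale expression over
  the trajectory and compute quartile means m₁..m₄; phasic iff the mean
  over Q2 ∪ Q3 exceeds both m₁ and m₄. Width-based quartiles and the
  strict per-quartile rule (m₂ and m₃ each above both ends) are available
  as options; the rank/mean form is the default because it is insensitive
  to the pseudotime scale and to end-of-trajectory crowding.

# Pseudobulk contrasts and gene programs

Pseudobulk is the exact integer sum of nucleus counts per sample. The
region contrast within a pathology group is a log-link negative-binomial
GLM per gene (design: region + sex; offsets: library size × trimmed-mean
normalisation factors, trim 0.3, reference = median-library sample).
Gene-wise dispersions are method-of-moments estimates from Poisson
residuals with a (1 − p/n) degrees-of-freedom correction, shrunk toward
the global median with 10 pseudo-samples; the region coefficient is
tested by a Wald statistic referred to a t distribution on the residual
df (the small-sample guard that brings null type-I at α = 0.01 into the
[0.005, 0.02] band; with a supplied dispersion of 0 the fit and the
normal-reference p reduce exactly to a Poisson GLM). DEGs require nominal
p < 0.01 and |log2FC| > 1.2, read two-sided; a one-sided option exists.
The control filter then removes genes whose group-1 contrast has nominal
p < 0.05, keeping genes absent from the control table with an NA control
p.

Gene programs: per gene, counts are summed per region within a group,
z-scored across the five ordered regions, and clustered by k-means. The
k-means is an own seeded Lloyd implementation (50 restarts, ≤ 15
iterations, empty clusters re-seeded from a random point) because the
per-iteration objective is asserted non-increasing — an invariant of this
package's contract — with `stats::kmeans` serving as an independent
cross-check in the tests. k is chosen over k = 1..10 at the elbow,
defined as the largest positive second difference of the best-WSS curve;
if none is positive, k = 2 with a warning. Transitions between
consecutive groups' clusterings are contingency counts over shared genes
(row sums equal source cluster sizes, exactly), with row percentages and
a Sankey-ready JSON export. Early-reversal genes are flagged when the
Pearson correlation between a gene's group-1 and group-2 z-profiles is
≤ −0.5 — a declared operational convention for "opposite expression
pattern"; cluster-transition evidence is reported alongside.

# Signature comparison

Each side is filtered by its own rule before joining: the cluster DE
table by detection ≥ 5% and adjusted p < 0.05; the public signature by
its configured p-type (adjusted for sc/sn and bulk studies, nominal for
laser-capture studies) and, when present, the same detection filter.
Spearman ρ on the paired log2 fold changes of the overlap; fewer than 10
shared genes yields an insufficient-data flag and no p-value. Averaged
signature expression is the mean z of log-normalised expression over the
deduplicated, detected signature genes, averaged per cluster.
Over-representation is the upper-tail hypergeometric on each GMT term
restricted to the user-supplied universe, BH across terms, with terms
overlapping < 5 genes flagged for display. Note that the exact
hypergeometric p is discrete and conservative (superuniform) at small
term sizes; the calibration tests assert stochastic dominance over
U(0,1) rather than exact uniformity, which a discrete test cannot have.

# The synthetic cohort generator

`simulateReadouts` draws each assay as
base × regionMult × groupMult × ε, with ε unit-mean lognormal
(`exp(rnorm(1, −σ²/2, σ))`), so expectations follow the configured grid
exactly and the σ = 0 limit is deterministic. Defaults: tau assays decay
monotonically along EC > ITG > PFC > V2 > V1 with group multipliers
rising up to 8–10-fold from group 1 to 4 and σ = 0.3–0.4 — the
within-group spread typical of biochemical assays on autopsy tissue; the
amyloid assay peaks in neocortex (ITG/PFC) as plaque burden does.

`simulateCounts` draws gene-wise negative-binomial counts (dispersion
0.5, lognormal library factors, mean library 2,500 UMIs) with:

- six planted states (HOM 0.40, TRANS 0.10, DAM 0.25, RIBO 0.05, PvM
  0.12, Mono 0.08). Per-sample mixing weights are tilted by
  exp(±β·z(readout)) and renormalised — monotone and invertible — with
  DAM positively (β = 1.0) and HOM negatively (β = 0.8) tied to the
  pTau ratio by default;
- marker genes elevated by their log-fold change in their state; the
  subsetting panel genes get a higher baseline weight (their real
  counterparts sit in the top expression tier of myeloid nuclei) and are
  nearly silent (e^−1.5) outside the myeloid compartment;
- a latent homeostatic→disease axis t ∈ [0, 1] carried by microglial
  nuclei (cluster-specific centres 0.1/0.5/0.9, sd 0.1): ramp genes
  follow a logistic in t, hump genes a Gaussian bump at t = 0.5 (sd
  0.12), both with peak log-fold 1.5 — unambiguous truth for
  phasic-detection tests;
- a non-myeloid fraction (default 0.25, carrying neuronal/glial instead
  of myeloid markers). The sorted nuclei in studies of this design are
  only ~24–34% myeloid; a quarter non-myeloid is a deliberately cleaner
  version of that reality and is also what makes a z-score-based
  subsetting threshold of 0 meaningful;
- QC contaminants: high-mito nuclei (mito ~ 0.15 + 0.85·Beta(2, 5);
  clean nuclei draw from 0.15·Beta(2, 10), bounded below the threshold by
  construction), and low-gene/low-UMI nuclei as library shrinkages (×0.10
  and ×0.22).

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: ambient RNA and doublets; donor batch
effects beyond a scalar library factor (so integration is not stressed);
FACS gating composition; realistic gene–gene correlation (genes are
independent given state and t); spliced/unspliced structure; and any
particular real marker amplitude. Recovery rates measured on it are
upper bounds on real-data performance.

# Determinism and problem sizes

Every stochastic step takes a seed (`SimConfig@seed`, `EmbeddingParams@seed`,
explicit arguments elsewhere) and the full pipeline (`runPipeline`) is
byte-identical across reruns with equal seeds — asserted by test and by
the acceptance script. The test suite runs the statistical checks at
deliberately desk-scale sizes chosen to keep each file in seconds while
leaving the Monte-Carlo margins comfortable: 1,000-nucleus QC fixtures;
100 null and 100 planted association simulations at 12 nuclei/sample;
a 2,000-gene × 600-nucleus permuted-label hurdle null plus 100
recovery seeds at 2 × 150 nuclei; 100 trajectory seeds at ~480 nuclei
and 120 genes; 100 pseudobulk seeds at 8 + 8 samples with dispersion
0.3; and a ~3,000-nucleus end-to-end determinism run. The acceptance
script reruns the same computations at slightly reduced seed counts and
reports the measured quantities rather than asserting them.

# Known limitations

- The centroid-MST pseudotime is coarser than a learned principal graph:
  within-cluster geometry only enters through the projection onto
  straight edges, and branching beyond the MST topology is not modelled.
- The hurdle test's continuous part assumes Gaussian residuals of
  log-normalised expression among detected nuclei; for very low detection
  it degrades to the discrete part.
- The NB Wald contrast is calibrated, but it is not numerically identical
  to quasi-likelihood F-tests; p-values on real data will differ in the
  tails.
- Proportion correlations treat donors as independent given region;
  repeated measures across regions are analysed per region, never pooled.
- The per-nucleus subsetting threshold is a convention; with very small
  non-myeloid admixture the z-score geometry degrades and the
  cluster-averaged score should be used instead.
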