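---
title: "Selective-sweep scans on phased haplotype data: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective-sweep scans on phased haplotype data: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

sweepscan detects recent positive selection from phased, multi-population
SNP data, the setting of comparative cattle-genome studies: a test breed
(say, an African taurine population) is contrasted with a reference panel
(other African breeds, or pooled commercial breeds), and the genome is
scanned for windows where the test population shows unusually long
haplotype homozygosity (XP-EHH) or an allele-frequency shift too large for
drift over too wide a region (XP-CLR).  Around the scans sit the standard
supporting statistics — nucleotide diversity, Weir–Cockerham FST, windowed
LD, IBS distances, EIGENSTRAT-style PCA, neighbor-joining trees — and a
breed-specific SNP enrichment test.  This vignette describes the models,
the tunable parameters, and the design choices, in that order.

## The data model

All scans operate on a `haplo_matrix`: a binary matrix of 2N phased
haplotypes by S biallelic SNPs (0 = reference allele, 1 = alternate), with
1-based bp positions strictly increasing within each chromosome, plus a
sample-to-population map.  Phasing is assumed done upstream (BEAGLE-class
tools); variant calling, deduplication and imputation are out of scope.
VCF input is restricted to phased, biallelic SNP records; everything else
is rejected with a count.  Genotype dosages (0/1/2) are derived by summing
each sample's two haplotype rows.

### Hard filtering

Sites are removed when any of three rules fires:

* phred-scaled site quality below 30;
* more than 4 mapping-quality-zero reads **and** quality-by-depth below 5;
* strand-bias FS above 200.

The middle rule is a conjunction by default (that is how the thresholds
are conventionally combined for GATK-called SNPs); a flag switches it to a
disjunction for sensitivity analysis.  Missing annotations pass — minimal
and simulated files may omit INFO keys, and an absent annotation is no
evidence against a site.

## EHH, iHH and XP-EHH

EHH at offset site $x$ from a core site $c$ is the probability that two
haplotypes drawn without replacement from the population are identical at
every SNP from $c$ to $x$ inclusive:

$$\mathrm{EHH}(x) = \sum_g \binom{m_g}{2} \Big/ \binom{n}{2},$$

where $m_g$ are the multiplicities of the distinct haplotype strings over
that span.  The curve starts at 1 at distance 0 and is non-increasing
outward.  One definitional subtlety: the core site's own alleles are
included in the spanning strings, while the integration anchor at distance
zero is fixed at 1; the package computes EHH over the whole population at
each core (the cross-population statistic compares populations, so no
within-population allele partition is needed — an allele-partitioned curve
is available for plotting).

iHH is the trapezoidal integral of the curve over physical distance, left
plus right, truncated when EHH falls below a cutoff (default 0.05) or a
maximum span (default 1 Mb) is reached.  Distances are in bp throughout: no
genetic map is assumed for simulated or arbitrary data.

The raw cross-population score at a site is
$\ln(\mathrm{iHH}_A / \mathrm{iHH}_B)$.  Both curves are truncated over the
*union* of their spans: stepping continues until both populations' EHH has
fallen below the cutoff, the earlier-truncated curve carrying its last
value forward.  Without this rule a population whose curve happens to cross
the cutoff one SNP earlier would lose integral mass it actually has, and
the log-ratio would jitter with the truncation point.  Raw scores are then
standardized genome-wide (mean 0, sd 1, population variance); extreme
positive standardized scores mark sites where the test population carries
an unusually extended, near-fixed haplotype.

## The simplified XP-CLR

XP-CLR asks, per 50-kb window, whether the test population's allele
frequencies around the window midpoint deviate from the reference panel's
in the coordinated, distance-dependent way a hitchhiking event produces —
rather than by independent per-site drift.

**Null model.**  The latent test-population frequency at a site with
reference frequency $p_1$ is
$p_2 \sim \mathrm{Normal}(p_1,\ \omega\, p_1 (1 - p_1))$ truncated to
$(0,1)$, with the clipped tails moved to point masses at the boundaries
(drift to loss or fixation).  The observed alternate count is
$k_2 \sim \mathrm{Binomial}(n_2, p_2)$.  The drift scale $\omega$ is
estimated genome-wide by the method of moments,
$\omega = \mathrm{mean}\big[(p_2 - p_1)^2 / (p_1(1-p_1))\big]$ over sites
with $0.05 < p_1 < 0.95$, and floored at $10^{-6}$.

**Sweep model.**  A sampled lineage at distance $d$ from the sweep site
escapes the sweep by recombination with probability
$c = 1 - e^{-\rho d / s}$, where $\rho$ is the per-bp recombination rate
(default $10^{-8}$, the conventional cattle-scale constant) and $s$ the
sweep-scale parameter.  A non-escaping lineage carries whichever allele
rode the sweep (the alternate with probability $p_1$).  The observed
frequency is therefore the classic hitchhiking transform of the latent one
— $1 - c + c\,p_2$ if the alternate rode, $c\,p_2$ if the reference did —
marginalized over both the latent $p_2$ and the rode-allele identity, with
the same binomial sampling layer.  At $c = 1$ this is exactly the null
(nesting); at $c = 0$ it degenerates to point masses $p_1$ at fixation and
$1 - p_1$ at loss.  The per-lineage formulation matters: a variant that
treats the *population* as all-or-nothing swept (a latent-distribution
mixture with pure boundary masses) assigns zero sweep-model probability to
any site that is *almost* fixed in the sample, and since an implanted sweep
at final frequency 0.95 leaves most nearby sites one haplotype short of
fixation, that variant has essentially no power — the per-lineage escape
model is both the standard derivation and the one that detects partial
sweeps.

The window score is $2(\max_s \ell(s) - \ell(s_0))$ over a logarithmic
grid of 12 values of $s$ plus a pinned near-zero entry $s_0 = 10^{-12}$
that reproduces the null exactly, so the score is non-negative by
construction.  The composite log-likelihood sums over at most 600 SNPs per
window (nearest the midpoint), each weighted by $1/|\text{group}|$ where
groups are the transitive closure of reference-panel pairs with
$r^2 > 0.95$ — near-duplicate SNPs carry shared, not independent,
evidence.  Sites monomorphic in the reference panel are excluded (the
drift model needs $0 < p_1 < 1$).

**Numerics.**  The latent integral uses a fixed 64-node midpoint rule plus
the explicit boundary masses, evaluated in log space (log-sum-exp); the
64-node value is within about $10^{-3}$ of the converged integral, which
is far below the between-window variation the scan ranks on, and the test
suite pins both the converged value (against adaptive quadrature, at
$10^{-6}$) and the default-resolution discretization error.

## The empirical-P outlier pipeline

The genome is tiled into non-overlapping 50-kb windows (terminal partial
windows kept and flagged).  Each window is summarized by the signed
maximum of its SNPs' standardized XP-EHH scores — signed, so a window of
all-negative scores is still summarized, while the positive tail the scan
targets dominates ranking; an absolute-maximum variant is behind a flag.
Windows are binned by SNP count in increments of 500 (1–500, 501–999, and
all windows with ≥ 1000 SNPs pooled — at exactly 1000 the pooling rule
wins), because the null distribution of a windowed maximum depends
strongly on how many SNPs feed it.  Within each bin, the empirical P of
window $i$ is the fraction of the bin's windows with a statistic strictly
greater than window $i$'s; windows with $P < 0.005$ are outliers.  Strict
inequality means ties favour significance, and a bin of all-tied values
degenerates to $P = 0$ everywhere — the pipeline emits a message in that
case, and warns when a bin has fewer than 200 windows (where a 0.005
threshold is vacuous).  The denominator is the full bin size, including
window $i$ itself, matching the plain reading of "fraction of windows".
For XP-CLR the top-0.5% rule is used directly: windows at or above the
$\lceil 0.005 n \rceil$-th largest score, ties included.

Candidate genes are genes whose interval overlaps any outlier window by at
least 1 bp (BED input is converted from 0-based half-open to the package's
1-based inclusive coordinates; GFF3 is taken as-is, `gene` features only).
An optional nearest-gene mode assigns otherwise empty outlier windows to
their closest gene.  Candidate sets from the two scans are intersected by
gene id, keeping each scan's supporting windows.

Standardization happens before window summarization (the standardized
scale is what the window maximum ranks); a different order changes only a
monotone transform within the genome-wide score set, and the empirical-P
machinery is rank-based, so the outlier set is insensitive to this choice.

## Breed-specific SNP enrichment

Per site, a 2 × 3 genotype-count table (focal breed vs all others pooled ×
dosage class) feeds three tests: Fisher's exact test on the dominant
collapse ({1,2} vs {0}) and on the recessive collapse ({2} vs {0,1}), and
the Cochran–Armitage trend test with scores (0, 1, 2) on the co-dominant
table.  Fisher's two-sided p is the sum of hypergeometric probabilities not
exceeding the observed table's (with the customary 1e-7 relative slack for
floating-point ties — the dominant software convention).  The trend
statistic is the score form $T = \sum_j w_j (n r_j - R c_j)$ with null
variance $\frac{R(n-R)}{n}\big[n \sum_j w_j^2 c_j - (\sum_j w_j c_j)^2\big]$
and a two-sided normal p; because the permutation distribution of $T$ is
discrete, the asymptotic p approximates the mid-p and a permutation mode
(`method = "permutation"`) gives the exact inclusive tail for small
counts.  All p values are Bonferroni-corrected over a caller-specified $m$
(defaulting to the number of sites tested; a genome-wide analysis passes
its full test count).  Two site flags are reported: *enriched* (any
adjusted p below alpha) and *private* (alternate allele observed in the
focal breed only), since headline "breed-specific SNP" counts can be built
either way.

## Population structure

PCA follows the EIGENSTRAT normalization: per site, dosages are centred
and scaled by $\sqrt{\hat p (1 - \hat p)}$ with the smoothed frequency
$\hat p = (1 + \sum d_i) / (2 + 2N)$ — the smoothing exists to avoid
division by zero at sites approaching monomorphism (fully monomorphic
sites are dropped).  The sample-by-sample covariance is
eigen-decomposed; axis variance fractions are eigenvalues over the trace,
and coordinates are eigenvectors scaled by the square root of their
eigenvalue.  Axis signs are arbitrary — tests compare magnitudes, never
raw signs.

Neighbor joining runs on the IBS distance matrix
($\mathrm{dist} = 1 - \mathrm{mean}\,\frac{2 - |d_i - d_j|}{2}$) via the
canonical Saitou–Nei agglomeration (ape's implementation); negative branch
lengths, which NJ can produce on non-additive inputs, are clipped to zero
with a message.  Newick output carries branch lengths at 6 significant
digits.

## The synthetic-data generator

Every stage is testable without external data through a founder-mosaic
simulator.  Per contig: SNP positions are drawn uniformly without
replacement; ancestral derived-allele frequencies follow a neutral SFS
(founder count $i$ with weight $1/i$); each population's founder-pool
frequencies are the ancestral ones perturbed on the logit scale with sd
`drift_sigma` (the source of FST), and founder pools are drawn with common
uniform variates across populations, so `drift_sigma = 0` yields literally
identical pools; each haplotype is then a mosaic of its population's
founders with exponential(`switch_rate`) segment lengths, which produces
LD decaying on the scale of `1 / switch_rate`.  Site-quality annotations
mark exactly `round(qual_fail_fraction * n_sites)` sites as failing one of
the three filter rules, the rest passing with margin; a truth ledger
records the flags.

Sweeps are implanted post hoc rather than forward-simulated: a carrier
haplotype is chosen in the target population, and a fraction
`final_frequency` of that population's haplotypes copies the carrier's
allele at each site independently with probability
$e^{-d/\text{decay\_scale}}$.  This gives an analytically controllable
footprint — elevated haplotype homozygosity and allele-frequency
differentiation decaying exponentially around the focal site — which is
exactly the signal pattern the two scans target.

Default study conditions (used by the acceptance checks): 2 populations ×
10 diploids, 20 contigs of 5 Mb with 5,000 SNPs each (~2,000 windows of
50 kb, ~50 SNPs per window), `switch_rate` $10^{-5}$ (mean copied segment
100 kb, giving strong LD to tens of kb as in livestock genomes),
`drift_sigma` 0.5 (genome-wide FST near 0.05–0.1, the African–commercial
cattle range), sweeps at final frequency 0.95 with a 100-kb decay scale,
placed at a window centre.  All randomness flows from a single seed
through fixed-offset child streams, so identical configuration and seed
give bit-identical output, including the emitted VCF.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: mutation/recombination heterogeneity along the
genome, background selection, admixture and gene flow, genotyping error
correlated with depth, reference bias, and realistic demographic histories
(bottlenecks, expansions).  The scans' *calibration* (empirical-P outlier
fraction) is distribution-free by construction, but their *power* numbers
transfer to real data only qualitatively.

## Determinism and degenerate inputs

The full pipeline is a pure function of (inputs, configuration, seed), and
report files are byte-stable.  Degenerate cases have defined behaviour:
zero-SNP windows are excluded and counted; a site where XP-EHH's
denominator iHH is zero is flagged and dropped from standardization;
all-equal raw scores make standardization a labelled error; a Fisher table
with a zero margin returns p = 1 flagged; a trend table with zero variance
likewise; `estimate_omega` on identical frequency vectors clamps to its
floor with a warning; NJ needs at least 3 taxa.

## Known limitations

* XP-CLR is a deliberately simplified reimplementation: the drift model is
  a truncated normal rather than the full Wright–Fisher transition
  density, and $s$ is a scan diagnostic, not an interpretable selection
  coefficient.  Agreement with published XP-CLR *scores* is a non-goal;
  the contract is null calibration plus power on controlled sweeps.
* Distances are physical (bp); with a genetic map the escape probability
  and EHH spans would use centimorgans.
* One-vs-rest comparisons pool the "rest" populations into a single
  reference panel without reweighting for sample-size imbalance.
* The empirical-P criterion identifies outliers of the genome-wide
  distribution; under pervasive selection or strong structure it
  under-detects by construction, and it cannot see selection on standing
  variation that barely shifts haplotype structure.
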