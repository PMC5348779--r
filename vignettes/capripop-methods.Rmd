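---
title: "Methods: multi-breed SNP-array population genomics with capripop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-breed SNP-array population genomics with capripop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(capripop)
```

# Scope

`capripop` implements the analysis chain typically applied to medium-density
(50K) SNP-array genotypes from multiple livestock breeds, with goats as the
motivating system: quality control, within-breed diversity, five inbreeding
estimators, runs of homozygosity (ROH), smoothed-FST selection scans under
breed-contrast scenarios, Reynolds-distance population trees with a
tree-kinship FLK test, and a mixed-model association scan for a breed-coded
phenotype. Because real multi-breed genotype panels are rarely
redistributable, the package ships a Balding–Nichols simulator whose
defaults emulate a nine-breed, 52,088-SNP goat panel, so that every stage
can be exercised — and its statistical guarantees tested — on data with
known ground truth.

# Data model and quality control

Genotypes are held as an individuals × SNPs matrix of allele-B dosages
(0/1/2, `NA` for missing), with a marker map (29 autosomes, 1-based bp,
inclusive ranges, PLINK `.map` convention) and a sample/breed table. Allele
orientation is a free convention: the PLINK-text reader labels the first
allele observed in file order as allele A, and every downstream statistic
is invariant to flipping any marker (asserted in the tests).
`canonicalize_alleles()` puts an in-memory dataset in the reader's
orientation so write-then-read round trips are exact.

QC retains autosomal SNPs with known position, call rate ≥ 0.95 and
MAF ≥ 0.01 (the standard array thresholds, both configurable). A SNP
failing several rules is counted once in the report, at its first failure,
in the order position → call rate → MAF; the order is a bookkeeping choice
only and does not affect the retained set.

# The synthetic study

The simulator draws ancestral frequencies $p_0 \sim U(0.15, 0.85)$ and
breed frequencies $p_b \sim \mathrm{Beta}\!\left(p_0\frac{1-F_b}{F_b},
(1-p_0)\frac{1-F_b}{F_b}\right)$ — the Balding–Nichols drift model, which
links the drift parameter $F_b$ to expected differentiation in closed form,
making simulator and test thresholds mutually interpretable. Genotypes are
Binomial(2, $p_b$) (Hardy–Weinberg within breed); calls are set missing
completely at random at rate 0.01.

Default conditions emulate a worldwide goat panel: nine breeds with sample
sizes 403, 61, 67, 48, 81, 54, 66, 318, 53 (total 1151); 52,088 SNPs placed
at uniform 50 kb spacing over 29 autosomes (50K arrays space markers at
roughly 40–60 kb); per-breed drift $F_b$ spread over 0.05–0.15, the range
of between-breed differentiation such panels show. The ancestral frequency
band $U(0.15, 0.85)$ reflects array ascertainment toward intermediate
frequencies and was chosen once so that expected per-breed heterozygosity
falls in the 0.33–0.41 band reported for goat 50K data; with it, per-breed
$H_E \approx 2\,\overline{p_0 q_0}(1-F_b) \in [0.36, 0.40]$.

What the generator does **not** emulate: linkage disequilibrium (SNPs are
independent given breed frequencies), recombination maps, mutation,
ascertainment by discovery panel, or non-random missingness. Consequently,
passing tests certify the estimators and the scan logic, not robustness to
haplotype structure; in particular regional $r^2$ on simulated data has no
LD signal to find, and sweep signatures are frequency shifts rather than
extended haplotypes.

Ground-truth generators: `inject_sweep()` moves the favoured allele's
frequency $p \to p + s(1-p)$ inside a region for one breed and re-draws
genotypes (preserving Hardy–Weinberg within breed and the missingness
pattern); `plant_roh()` writes a single breed-frequency haplotype
homozygously across a region; `simulate_pedigree()` builds
discrete-generation pedigrees with a controllable fraction of full-sib
matings; `assign_ear_phenotype()` codes ears by breed (0 short, 1 average,
2 long) with an optional additive dosage QTL.

# Diversity metrics

$H_O$ is heterozygotes over non-missing calls; $H_E = 2\hat p(1-\hat p)$
per SNP from within-breed frequencies, without small-sample correction
(the plain estimator is what array studies report, and breed means at
$n \ge 48$ differ from the corrected version by $< 1/(2n)$). SNPs
monomorphic within a breed are included in the breed mean (contributing
0); the proportion of polymorphic SNPs $P_N$ uses within-breed MAF > 0.01.
The pairwise distance is allele-sharing: over co-called loci,
$D_{ST} = (\mathrm{IBS2} + 0.5\,\mathrm{IBS1})/m$ and $D = 1 - D_{ST}$,
computed on dosages (valid for biallelic markers: $D = \overline{|d_1 -
d_2|}/2$).

# Inbreeding estimators

All four genomic estimators take a frequency reference; the default is the
pooled post-QC sample, with `per_breed = TRUE` for within-breed references
(the scale on which per-breed means are reported; used by the analysis
scripts). Missing calls and SNPs monomorphic in the reference are skipped
and the SNP count adjusted, with one deliberate exception below.

* **Excess of homozygosity**: $F_{EH} = \frac1m \sum_i \left[1 -
  \frac{c_i(2-c_i)}{2p_iq_i}\right]$ — 1 for a fully homozygous genome,
  negative for heterozygote excess.
* **VanRaden**: $F_{VR} = \frac{\sum_i (c_i - 2p_i)^2}{2\sum_i p_iq_i} - 1$,
  a ratio of sums. Missing dosages contribute zero to the numerator while
  the denominator runs over all polymorphic reference SNPs — exactly
  equivalent to mean imputation, and the convention that makes
  $F_{VR} = \mathrm{diag}(\mathbf G) - 1$ hold to machine precision
  against the genomic relationship matrix, which imputes the same way.
* **Leutenegger-style**: the mean of $\frac{(c_i-2p_i)^2}{2p_iq_i}$ has
  expectation 1 under Hardy–Weinberg, so the default subtracts 1 to centre
  the estimator at zero — the scale on which breed means are near zero in
  array studies; `literal = TRUE` returns the uncentred mean. When the
  frequency reference is the same sample, the centred mean equals the
  $F_{EH}$ mean identically (the linear terms cancel), a useful
  cross-check visible in the analysis output.
* **ROH-based**: summed segment length over the SNP-covered genome length
  ($\sum_{chr} (\text{last} - \text{first})$ bp).
* **Pedigree**: Wright's $F$ equals half the additive relationship of the
  parents, obtained by Colleau's indirect method — one backward and one
  forward sweep over the pedigree per animal computes the needed column of
  the relationship matrix without ever forming it; animals are processed
  in topological order so each Mendelian-sampling variance is available
  when used. The test suite certifies it against an independent tabular
  (full-matrix) implementation to $10^{-10}$ on random pedigrees. Animals
  with an unknown parent are treated as founders on that side.

# Runs of homozygosity

To control chance ROH, the minimum SNP count is
$l = \lceil \ln(\alpha/(n_s n_i)) / \ln(1 - het) \rceil$ with
$\alpha = 0.05$ and $het$ the dataset's mean SNP heterozygosity (a
per-breed $het$ can be supplied, since per-breed panels differ). The scan
is PLINK-style: sliding 50-SNP windows tolerating 1 heterozygote and 5
missing calls mark qualifying SNPs; maximal qualifying runs — split at
inter-SNP gaps over 1000 kb — become segments when they hold ≥ $l$ SNPs,
span ≥ 1000 kb and average ≤ 50 kb/SNP. These remaining parameters are the
standard PLINK 1.9 defaults, all exposed in `roh_params()`. Segment length
is end − start bp. At 50 kb spacing with $het \approx 0.37$ the binding
constraint is $l$ (~37–45 SNPs ≈ 2 Mb), and a qualifying 50-SNP window
with ≤ 1 heterozygote has probability $\sim 10^{-10}$ per position under
neutrality, so null datasets stay clean — verified over 10 seeds of a
100 × 50K null panel.

# Selection scan

Per SNP and contrast group, FST is the squared deviation of the group
frequency from the unweighted across-group mean, divided by
$\bar p(1-\bar p)$ — the across-group mean is used in the denominator
because it is the quantity the numerator deviates from. Within a group,
frequencies pool individual calls (sample-size weighted); across groups
the mean is unweighted so small breeds are not swamped; both choices are
documented and the grouped scheme is configurable. Three scenarios mirror
common practice: each breed against all others with pairwise values
averaged (scenario 1), intensively selected breed groups, and all breeds
grouped by breeding objective. Monomorphic SNPs score 0 rather than being
dropped, keeping tracks aligned to the map.

Smoothing is a fixed five-SNP centred moving average within chromosome
(two SNPs on each side, truncated at ends) — a fixed window is
reproducible and matches the window size such scans settle on after
comparing 2/5/10-SNP choices. Regions are maximal runs of SNPs whose
smoothed value exceeds the track's mean + $k$ SD ($k = 3$ for called
sweeps, $k = 2$ for suggestive regions; thresholds computed per track,
genome-wide, from the smoothed values). Each region records its peak SNP
and whether it bp-overlaps a region of another group. Regional LD reports
squared Pearson correlations of dosages (composite LD — no phasing on
unphased data), for adjacent and all syntenic pairs, after a within-breed
MAF ≥ 0.05 filter.

# Trees and FLK

Reynolds distances treat population frequencies as known:
$D = \sum_l (p_{al} - p_{bl})^2 / \sum_l (p_{al} + p_{bl} - 2p_{al}p_{bl})$
(no sample-size correction; at 50K SNPs the correction is negligible
relative to drift). Neighbour-joining trees come from `ape`, with negative
branch lengths clamped to zero and the deficit moved to the sibling so
pairwise path lengths are preserved. "Local trees" repeat the computation
on the SNPs of a candidate region; under a sweep the affected breed sits
on the longest terminal branch.

For FLK, the tree is midpoint-rooted and converted to a population
kinship: $K_{ij}$ is the shared root-to-MRCA branch length (diagonal =
root-to-tip distance), which is positive semidefinite by construction. The
per-SNP statistic is the single-SNP (allele-frequency) form:
$p_0 = \frac{\mathbf 1' K^{-1} p}{\mathbf 1' K^{-1} \mathbf 1}$ (clipped
to $(10^{-6}, 1-10^{-6})$), and
$\mathrm{FLK} = (p - p_0\mathbf 1)' [p_0(1-p_0)K]^{-1} (p - p_0\mathbf 1)$,
approximately $\chi^2_{K-1}$ under neutral drift (verified to within 10%
of its mean on matched simulations). The haplotype-cluster (hapFLK) model
is out of scope: it requires an LD model the simulator deliberately lacks.
Instead of multiple-testing correction, p-values follow the empirical
standardization used in livestock scans: the genome-wide statistic is
standardized by its own mean and SD and upper-tail normal p-values are
reported — approximate by design, so calibration is asserted only loosely
(empirical $P(p < 0.05)$ in $[0.02, 0.09]$ under neutrality).

# Mixed-model GWAS

The genomic relationship matrix is VanRaden's: dosages centred by $2\hat
p$, missing imputed to the mean, $\mathbf G = \mathbf{ZZ}'/(2\sum \hat
p\hat q)$. The null model $y = \mu + g + e$, $g \sim N(0, \sigma^2_g
\mathbf G)$, is fitted by REML after an eigendecomposition of the ridged
($10^{-6}$) GRM, profiling the likelihood down to a one-dimensional search
over $\log(\sigma^2_g/\sigma^2_e) \in [-12, 12]$ — deterministic, and
checked against a fine grid. The scan fixes the covariance at the null
estimates (the P3D/EMMAX approximation — the standard tractable choice)
and tests each mean-imputed SNP by GLS with a two-sided $t$ ($n-2$ df);
Benjamini–Hochberg q-values and significance sets at 1% and 5% FDR follow.
The ordinal ear phenotype is analysed as continuous, as single-SNP
regression implies. The breed-coded phenotype is perfectly confounded with
breed; no breed fixed effect is fitted, mirroring the design such studies
use, so the polygenic term absorbs essentially all signal
($\hat h^2 \to 1$) and only a true within-breed QTL can surface — the
analysis scripts show both sides of this.

# Numerical choices and degenerate inputs

Ridges: $10^{-6}$ on the GRM diagonal, $10^{-8}$ on the FLK kinship before
inversion. Zero-variance phenotypes are flagged degenerate rather than
fitted; zero-variance SNPs report effect 0, p = 1; pairs of individuals
with no co-called locus, individuals with no usable SNP, and breeds with
no segment are flagged `NA`, never silently 0. Monomorphic SNPs: excluded
from $F_{EH}$/$F_{LEUT}$ sums (division by zero), contribute zero to both
$F_{VR}$ sums, score 0 in FST/FLK tracks. NJ ties are resolved by `ape`'s
internal order; ties cannot arise on the additive metrics used for
correctness checks. Empty QC results and empty regions are explicit
errors; an empty ROH result is a valid empty table.

# Problem sizes

The analysis scripts run nine breeds × 48 animals × 6,000 SNPs (seconds
per script). The test suite uses 20 × 200 panels for exactness checks
against transcription oracles ($10^{-12}$), 100 × 50K panels for ROH
recovery, nine-breed × 50 × 20K panels over 10 seeds for sweep detection,
and 500 × 20K panels for GWAS calibration — sizes chosen to make the
Monte-Carlo assertions stable, and stated here as the package's own
defaults for reproducing them.

# Known limitations

No LD / haplotype simulation (hence no hapFLK, and regional $r^2$ carries
no signal on synthetic data); no X chromosome; no strand reconciliation
when merging panels; ordinal phenotypes treated as continuous; the
empirical-standardization p-values are approximate by construction; FST
variance denominators use the unweighted group mean, so scenarios with
very unequal group counts weight breeds, not animals.
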