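---
title: "Methods: pseudo-haploid population genetics with adnakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudo-haploid population genetics with adnakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adnakit)
```

## Scope and data model

`adnakit` implements the standard desk workflow for combining a handful of
low-coverage ancient genomes with modern reference panels, as practiced in
ancient-DNA studies of domesticated animals: random-read pseudo-haploid
genotyping, transition masking, panel filtering and merging, outgroup f3
shared-drift statistics and pairwise-mismatch diversity with weighted
block-jackknife errors, projection PCA, runs of homozygosity (ROH), a
drift-based likelihood-ratio test of population continuity, molecular
sexing from X/autosome coverage, and presence/absence genotyping of
insertions from breakpoint-spanning reads.

Everything operates on one container, the `gt_panel`: a matrix of allele-1
dosages over individuals and sites plus a variant table (chromosome,
1-based position, two alleles, optional ancestral state). Diploid panels
carry dosages 0/1/2, pseudo-haploid panels single-allele calls 0/1;
missingness is `NA` everywhere internally, with format codes (`9` in
EIGENSTRAT, `0` in PLINK text) translated at the parser boundary.
Coordinates are 1-based with inclusive endpoints throughout.

## The synthetic-data generator

Real panels of this kind derive from archived sequencing runs and
published SNP-chip data; the package instead ships a generator that
emulates their statistical structure with recorded ground truth, so every
downstream stage can be validated by parameter recovery rather than by
eyeballing.

**Drifted breed frequencies.** Populations sit at the leaves of a
user-specified tree. Each branch applies one Balding–Nichols step: given a
parent frequency $p$ and branch drift $F \in [0, 1)$, the child frequency
is Beta-distributed with mean $p$ and variance $F\,p(1-p)$. We chose this
over explicit Wright–Fisher generations because the closed-form moments
make tests exact, and only the panel structure — not a generative model —
is pinned down by the data the workflow targets. Draws within machine
tolerance of 0/1 are clamped to exact fixation; admixture edges mix node
frequencies linearly; ascertainment keeps sites still polymorphic in the
outgroup, emulating outgroup-ascertained SNP panels. No demographic
calibration to any real species is implied: trees are user-specified.

**Ancient samples.** Per site, read depth is Poisson($\lambda$), each
read draws one of the two chromosomes, and at C/T or G/A sites a read
truly carrying the C (resp. G) allele is flipped with probability
$\delta$ — postmortem deamination. Damage is modelled at the allele
level, not on full read sequences, which suffices because all downstream
consumers work from allele counts and alignment intervals. A per-read
error rate $\varepsilon$ and per-site dropout complete the model.
Transversion-pair sites are structurally untouched by $\delta$, which is
the property the transversion-only analyses rely on.

**Other truths.** Homozygous tracts are planted by drawing one allele per
site from the population frequency inside declared intervals; coverage
profiles draw per-chromosome depths Normal($d$, cv·$d$) with the X mean
halved for males; insertion read sets place reads across a breakpoint and
record clean spans on the matching reference and short noisy overhangs
(0–5 bp with random mismatches) on the other.

Default chromosome lengths mimic a 26-autosome + X karyotype. The
generator does **not** produce linkage disequilibrium beyond block
independence, sequencing quality strings, reference bias, or contamination;
passing tests therefore demonstrate correctness of the estimators under
the stated sampling models, not robustness to every artifact of real
ancient DNA.

## Genotyping and filtering

Pseudo-haploidization draws one read uniformly at random per covered site
(`pseudo_haploidize_pileup()`), or one allele per diploid genotype
(`pseudo_haploidize_diploid()`); both are deterministic given a seed, and
the expected pseudo-haploid frequency equals the diploid frequency — a
property tested by averaging over seeds. Transition masking removes
\{A,G\} and \{C,T\} pairs. Site filtering drops sites by missingness and
minor-allele frequency (defaults 0.01/0.01, the strict panel setting).
Merging intersects on (chromosome, position), flips dosages where allele
labels are reversed, and drops cross-dataset triallelic sites and
duplicated positions/individuals. Strand handling is label matching only:
no reverse-complement flipping is attempted, because transversion-only
analyses leave A/T and C/G pairs as the only ambiguous class — those are
retained and flagged (`ambiguous_sites` attribute) rather than silently
resolved. LD pruning is greedy within 200-SNP windows advanced by 25,
removing the later member of any pair with $r^2 > 0.4$; always removing
the *second* member is a reproducibility-over-optimality tie-break.

## f3, jackknife, and mismatch diversity

The outgroup f3 statistic is the mean over complete-case sites of
$(o-a)(o-b)$ with $o, a, b$ the group allele frequencies; it is symmetric
in the two test groups and used for *ranking* shared drift, so no
finite-sample bias correction is applied by default (a documented
`bias_correct` flag subtracts $h_o/n_o$ for users who want it). Standard
errors use the weighted delete-$m_j$ block jackknife (Busing-style) over
contiguous physical blocks; with equal block weights the formula reduces
exactly to the classical delete-one jackknife, which the tests assert to
machine precision. The default block length is 5 Mb — a conventional
choice, since only the use of block-jackknife errors, not the block size,
is pinned down by the workflow this package reproduces.

Pairwise-mismatch diversity is the mean over within-group pairs of the
per-pair mismatch rate at jointly called sites, computed on pseudo-haploid
calls (diploid members are haploidized first). At Hardy–Weinberg
equilibrium the per-site expectation is $2p(1-p)$, which anchors the
closed-form test. Both an all-pairs and a seeded random-pairs policy are
provided, since published figures of this statistic sometimes subsample
pairs; all-pairs is the default. Restricting to transversions removes the
deamination inflation — the package's tests reproduce this rationale
quantitatively (damage shifts the all-sites estimate by several jackknife
SEs while moving the transversion-only estimate by less than one).

## Projection PCA

PCA standardizes dosages by per-site mean and $\sqrt{\hat p(1-\hat p)}$,
mean-imputes missing dosages at fit time (the standard behavior of
reference-panel PCA tools), and takes the SVD. Signs are fixed so each
component's largest-magnitude loading is positive, making output
deterministic. Low-coverage samples are placed by least squares restricted
to their observed sites; a complete-data panel individual projects exactly
onto its fit-time scores. Out-of-sample projections shrink toward the
origin; `estimate_shrinkage()` calibrates one factor per component by
leave-one-out refits (components matched by loading correlation, factor =
median ratio of fit-score to projected magnitude). This is a calibration
procedure defined by this package: equivalence with any specific external
tool's shrinkage mode is *not* claimed, only the qualitative behavior that
projected samples are rescaled back to the scale of the fit scores.

## Runs of homozygosity

ROH calling follows the windowed algorithm family of plink's `--homozyg`,
with defaults equal to the full published parameter set (window 100 SNPs,
≤1 heterozygote and ≤10 missing per window, hit threshold 0.02, segment
minimums of 100 SNPs / 500 kb, density 50 kb/SNP, gap 1000 kb). Windows
are only formed where 100 consecutive SNPs exist; edge SNPs covered by
fewer windows use the reduced denominator. Candidate runs are trimmed to
homozygous end points and split at physical gaps. Heterozygosity comes
from dosage 1; missing calls are excluded from the het count but count
against the window missing limit. Undocumented tie/edge behaviors of the
original tool are mimicked on a best-effort basis — bit-exact concordance
is not claimed, and the recovery guarantees are stated (and tested)
against planted tracts instead. Optional depth/quality pre-filters can be
applied upstream when diploid calls derive from read data.

## The continuity test

Per polarized site the data are derived-allele counts $d/n$ (modern
chromosomes) and $a/m$ (pseudo-haploid ancient chromosomes, one allele per
individual). The latent ancestral frequency $x$ at the split is uniform a
priori; the modern lineage drifts for variance-scaled time $t_1$ and the
ancient branch for $t_2$, each drift step being the mean/variance-matched
Beta with variance $x(1-x)(1-e^{-t})$. Both binomial sampling layers then
integrate in closed form (beta-binomial), and the Beta's boundary mass
supplies the fixation classes — a spike at 0 would contribute
$\mathbb{1}(k=0)$, and Beta mass below $\kappa$ contributes
$\mathrm{Bin}(k; \cdot, y<\kappa) \approx \mathbb{1}(k=0)$ up to
$O(\mathrm{size}\cdot\kappa)$, so explicit spike masses are not separately
represented. Only $x$ is integrated numerically, by Gauss–Legendre
quadrature of order 64 (configurable); the tests verify agreement with an
independent dense-grid oracle to $10^{-6}$ on the reference configuration.

The likelihood conditions on the modern counts, so polymorphism
ascertainment applied to the modern panel cannot bias the test. At
$t_1=t_2=0$ it reduces to the pooled posterior-predictive (hypergeometric
style) probability of $a$ given $d$. The null of direct continuity pins
$t_2=0$; because that is a boundary point, the LRT reference distribution
is the mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$. Optimization is
bounded (Brent for the null, L-BFGS-B from three deterministic starts for
the alternative). Calibration and power are checked by simulation from the
same generative model (uniform ancestral frequencies, Beta drift, binomial
sampling): with 50 modern diploids, 6 ancient chromosomes and 50,000 sites
the nominal 5% level is held within binomial error and drift $t_2 = 0.2$
is detected essentially always. The coverage-style filters on the ancient
site counts (`min_m`/`max_m`) are configurable and make no claim to match
any specific external tool's defaults.

## Read-level calls

Sexing compares mean X depth to length-weighted mean autosomal depth;
thresholds 0.8 (female) and 0.6 (male) formalize "similar" and "around
half", with an indeterminate band between and the raw ratio always
reported. Insertion genotyping formalizes what is usually a visual
read-inspection call: a read is diagnostic only if it crosses the
breakpoint by ≥10 bp on both sides with ≤1 overhang mismatch — chosen so
that a 3 bp overhang carrying 2 mismatches, the canonical weak read, is
excluded. One qualified read suffices for a call, flagged low-confidence
below 3 supporting reads, since the workflows this package serves operate
at extremely low coverage where demanding more support would mean no calls
at all.

## Reproducibility and problem sizes

Every stochastic operation takes an explicit integer seed, and the
pipeline driver (`run_pipeline()`) derives per-stage seeds from one master
seed during config validation, so a configuration fully determines the
output bundle byte for byte (`hash_bundle()` verifies this). The test and
acceptance workloads use deliberately compact problem sizes chosen to keep
Monte-Carlo error well inside the asserted tolerances: 20,000 SNPs × 100
replicates for f3 ranking, 50,000 sites × 200 replicates for LRT
calibration, 50 individuals for ROH recovery, 100 replicates for PCA
assignment and read-level calls. These sizes are the package's own
choices; the assertions are statements about the estimators under the
generator's sampling models at these sizes.

## Known limitations

- The generator omits LD, reference bias and contamination; claims about
  robustness to those artifacts are out of scope.
- Strand-ambiguous (A/T, C/G) sites are flagged, not resolved, at merge
  time.
- PCA shrinkage is a package-defined calibration, not a re-implementation
  of any external tool's mode.
- ROH calling mimics the plink algorithm family but is validated against
  planted truth, not against plink output bit for bit.
- The continuity model treats sites as independent; linked sites inflate
  the effective information and the test is correspondingly strict, which
  matches how it is used in practice (failure to reject is the
  interesting outcome).
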