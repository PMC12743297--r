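---
title: "Methods: quantifying eco-evolutionary dynamics in perturbed bacterial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying eco-evolutionary dynamics in perturbed bacterial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoevotrack)
```

# The problem

Wild bacterial communities tracked through an environmental perturbation
change along three distinct axes: *ecological sorting* (shifts in the
relative abundance of resident species), *dispersal* (colonisation by taxa
not previously present), and *evolution* (shifts in allele frequencies
within species). `ecoevotrack` implements a coherent set of estimators for
all three from the data types such a study produces — amplicon (ASV or
genus) count tables over a time series of habitat patches, per-genome SNV
frequency tables at two metagenome timepoints, circular-genome coverage
tracks, and plate-reader growth curves from spent-media assays — together
with a synthetic-data generator that produces all of these with known
ground truth, so every estimator is testable end to end without any
sequencing data.

# Community ecology on count tables

Counts are treated compositionally. The centred log-ratio transform for a
sample with counts $c_k$ is

$$\mathrm{clr}(c)_k = \log(c_k + p) - \frac{1}{K}\sum_j \log(c_j + p),$$

with pseudocount $p = 0.5$ by default: half a read perturbs the
composition minimally while keeping zeros finite, and any common
alternative (1, or depth-scaled) is available through the `pseudocount`
argument. CLR vectors sum to zero by construction, which the tests assert
to $10^{-9}$. Shannon diversity is reported in natural-log units (nats);
comparisons between samples are invariant to the base.

**Colonisers.** A taxon is a coloniser of a habitat patch if it is absent
from every sample at or before the baseline week, appears at some later
sampled week, and is present in every sampled week from its first
appearance through the end (`detect_colonisers()`). The baseline is "all
weeks $\le 0$" so that a pre-perturbation observation window (e.g. a week
$-7$ sample) tightens the filter; `baseline_week` is configurable. The
rule is deliberately strict about persistence — a taxon that appears and
then lapses is ambient noise, not an establishment event — and the test
suite checks the implementation against a brute-force oracle over every
presence/absence pattern of a six-week design. Colonisation pressure is
summarised as taxa per week (mean per-patch coloniser count divided by the
duration) and as the coloniser read fraction per sample.

**Connectivity.** Patch-to-patch sharing pools each patch's counts over
all its timepoints and reports the fraction of the two patches' combined
reads that belong to taxa present in both. Pooling is the default because
sharing is read as a measure of long-term connectivity rather than of
instantaneous similarity; a week-matched mode (`per_week = TRUE`) computes
the same quantity per shared sampling week and averages, and neither mode
is claimed to be the only defensible reading. The association between
sharing and geography uses a Mantel permutation test with the Pearson
statistic on upper-triangle entries, simultaneous row/column permutation,
a two-sided criterion $|r^\*| \ge |r|$ and the $+1$ correction
$p = (1 + \#\{|r^\*| \ge |r|\})/(1 + n_\mathrm{perm})$, which keeps the
p-value valid (never anti-conservative) at any permutation count.

# Drift calibration: from polymorphism and frequency change to generation times

The calibration chain converts two observable quantities per genome (MAG)
into an effective population size and a generation time.

1. **Polymorphism → $\theta$.** Watterson's estimator per site,
   $\theta = K / a_n / L$, where $K$ is the number of SNVs segregating at
   the first timepoint, $L$ the genome length, and $n$ the average read
   depth standing in for the number of sampled sequences;
   $a_n = \sum_{k=1}^{n-1} 1/k$. Depth is a real number, so $n$ is rounded
   to the nearest integer (floor 2) before the harmonic number; a
   continuous digamma-based variant ($\psi(n) - \psi(1)$) is available via
   `method = "digamma"` for users who prefer not to round. The difference
   is negligible at metagenome depths.
2. **$\theta$ → $N_e$.** $N_e = \theta / (2m)$ with $m$ the per-nucleotide
   per-generation mutation rate, default $2 \times 10^{-10}$ (the median
   across published estimates for sixteen bacterial species — medians
   because such compilations are right-skewed).
3. **Frequency change → $F$.** For each SNV with frequencies $x, y$ at the
   two timepoints, the standardised variance
   $F = (x - y)^2 / \{x(1 - x)\}$. Sites with $x \in \{0, 1\}$ carry no
   drift information in this standardisation and are excluded (flagged,
   not an error). Only synonymous ("silent") sites enter the aggregate, as
   the closest available approximation to neutrality.
4. **$F$ → generations.** Under pure drift
   $\mathbb{E}[F] = 1 - (1 - \tfrac{1}{2N_e})^t$, so
   $t = -2 N_e \ln(1 - \bar F)$. The aggregation is the **mean** of
   per-SNV $F$ by default, because the expectation above is what the
   inversion assumes; a median mode exists for robustness comparisons. Each
   per-SNV $F$ is capped at `f_cap = 0.95` before aggregation: sites that
   drift to fixation make $\ln(1 - F)$ blow up, and fixation is outside the
   domain of the diffusion-style approximation anyway.
5. **Generations → generation time.** `elapsed_days / t` days per
   generation (with the study design's 56 days between metagenome
   timepoints as the default).

All conventions are "haploid with $2N_e$ allele copies", so the factors of
two in steps 2 and 4 hold verbatim; the synthetic generator uses exactly
the same convention.

## Read-sampling noise in F

Observed frequencies are binomial read draws, not true frequencies. At
depths $d_1, d_2$ this inflates the expected per-SNV $F$ by approximately
$1/d_1 + 1/d_2$ — at depth 200 per timepoint that is $0.01$, which can
*exceed* the drift signal itself (for example $N_e = 5000$ over 56
generations gives $\mathbb{E}[F] \approx 0.0056$) and would roughly triple
the inferred $t$. `calibrate_mag(noise_correction = "binomial")` therefore
subtracts the per-SNV plug-in expectation of the sampling contribution,
$1/d_1 + y(1-y)/\{x(1-x)\,d_2\}$, keeping per-SNV corrected values signed
(flooring each at zero would re-inflate the mean exactly where noise
dominates) and flooring only the aggregate at zero. The default remains
`"none"` — the raw estimator, whose upward bias at low depth is the
documented price of simplicity — but the correction is the appropriate
setting for depth-200-scale data, and the package's own parameter-recovery
validation (below) uses it. A residual upward bias of order 5–10% remains
even corrected, from the nonlinearity of the plug-in denominator.

## Variant classification

A variant is *new* when undetected at the first timepoint
(`x <= presence_eps`, default 0: exactly absent from the call set,
mirroring a caller's detected/not-detected semantics) and detected at the
second; a new variant is *sweeping* when its endpoint frequency exceeds
`sweep_threshold = 0.75`. "Changed above the threshold" could also be read
as $|y - x| > 0.75$; that mode is exposed (`sweep_mode = "delta"`) and for
new variants (where $x = 0$) the two coincide. Sweeping variants are a
subset of new ones by construction, which the tests assert on an
exhaustive $(x, y)$ grid against a brute-force oracle.

## Comparing inter- and intra-specific sorting

`sorting_comparison()` compares the distribution of absolute genome
relative-abundance changes (ecological sorting) against absolute
non-synonymous SNV frequency changes (evolution) with a two-sided Wilcoxon
rank-sum test — magnitudes, because SNV changes are not directional in any
comparable sense — and regresses per-SNV absolute changes on the signed
abundance change of the genome carrying them (and optionally on the change
in log2 PTR). Genome relative abundances are computed from supplied
coverages as each genome's share of the summed coverage per timepoint;
other normalisations are possible and the function accepts any
pre-computed signed changes.

# Growth proxy: peak-to-trough ratio

In growing bacteria, ongoing bidirectional replication makes sequencing
coverage highest near the origin of replication and lowest near the
antipodal terminus; the log2 ratio of the two (log2 PTR) correlates with
growth rate. `estimate_ptr()` implements a deliberately simple estimator:
median depth per analysis window (median, not mean, for robustness to
coverage spikes; zero-depth windows are floored at 0.5 before the log),
then a least-squares fit of log2 depth against the normalised circular
distance to a candidate origin — a symmetric triangle wave — over a grid of
candidate origins, taking the candidate with the smallest residual sum of
squares. Two numerical points matter:

* the triangle model is mirror-symmetric (a candidate and its antipode fit
  identically with the slope sign flipped), so candidates whose fitted
  slope is positive, i.e. that model the *trough*, are discarded; without
  this the winner would be decided by floating-point round-off;
* exact ties are broken toward the lowest candidate index, making results
  deterministic (and therefore *not* rotation-equivariant in the
  measure-zero case of a perfectly symmetric track whose origin falls
  exactly on a window boundary).

The estimator handles a single circular contig. Real MAGs are unordered
multi-contig bins — the reason dedicated read-level tools exist — so
multi-contig input must be concatenated explicitly by the caller, with the
understanding that the resulting coordinate is arbitrary; this estimator
exists for synthetic validation and simple genomes, and no numerical
agreement with read-level PTR tools is claimed.

# Time-shift spent-media assays

Each assay grows community $i$ on fresh medium (area under the OD curve
$x_i$, trapezoidal integration), community $j$ on fresh medium ($x_j$), and
community $i$ on filter-sterilised spent medium conditioned by $j$
($x_{ij}$). The interaction coefficient

$$\alpha_{ij} = (x_{ij} - x_i) / x_j$$

is the effect of $j$'s conditioning on $i$, scaled by how well $j$ grew:
negative means inhibition (resources depleted, inhibitory molecules),
positive stimulation (detoxification, cross-feeding). $x_j = 0$ (community
$j$ failed to grow) leaves the coefficient undefined rather than infinite.

Per patch and focal timepoint $i$, the spent-media source $j$ with the
minimum coefficient is tallied. Exact ties (within $10^{-9}$) go to the
earliest timepoint label — a deterministic convention; ties have measure
zero with real OD data — and are counted in the output. The column sums of
the tally are tested against the null that every assay's strongest
reduction is uniform over the sources, using the *maximum column count* as
statistic: $p = P(\max \ge \text{observed max})$ under the symmetric
multinomial, by exact enumeration of all count configurations up to total
30 and by the Bonferroni-corrected exact binomial tail
$\min(1, k\,P[\mathrm{Bin}(T, 1/k) \ge \max])$ above. This test is defined
here on its own terms — published "multinomial test" p-values rarely pin
down a unique procedure — and is exact-conservative: under the null
$P(p \le \alpha) \le \alpha$, which the test suite checks by simulation.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults encode the
study design the package targets: 17 patches (tree holes) sampled at weeks
0, 1, 2, 4, 8, 12; uneven resident abundances (Dirichlet concentration
0.3, giving dominant-genus shares in the tens of percent); ~11 new taxa
per patch per week each at $2.6 \times 10^{-4}$ relative frequency
(together a few percent of the community by week 12); 50,000 reads per
sample; SNV trajectories with $N_e = 5000$, 1-day generations over 56
days read at depth 200; coverage tracks of 1 Mb at mean depth 100 with
log2 PTR 1; and 3×3 factorial spent-media assays at timepoints
$-7, 0, 8$ weeks. Where the emulated design fixes a value the default is
that value; remaining choices (noise SDs, fresh-growth AUC ~2.5 OD·days)
are ordinary plate-reader magnitudes.

Implementation points:

* **Multinomial sampling with a resident floor.** Every resident taxon's
  expected count per sample is floored at 5 reads (water-filling the
  remaining mass), so that residents essentially never produce the
  absent-then-persistent pattern through sampling zeros and the planted
  coloniser list is the exact truth set. The floor is the generator's
  guarantee, not the detector's: `detect_colonisers()` sees only counts.
* **Wright–Fisher with $2N_e$ alleles.** Trajectories use
  `round(elapsed/generation time)` discrete binomial generations; for
  populations beyond $2^{31}$ allele copies the binomial step switches to
  its gaussian limit (drift there is numerically negligible). Observed
  frequencies are binomial read draws. Across 5,000 SNVs the mean $F$
  matches $1 - (1 - \tfrac{1}{2N})^t$ within 10% for
  $N \in \{100, 1000\}$, $t \in \{10, 56\}$ — an oracle the test suite
  recomputes.
* **Coverage as a log-linear gradient on both arcs** (bidirectional
  replication), normalised so the length-weighted mean equals the target
  depth, with Poisson counts per bin. A single-arc decay was rejected as
  unrealistic and useless for origin inference.
* **Time-shift assays** draw one fresh-growth AUC per timepoint per patch
  (shared between its $x_i$ and $x_j$ roles) and construct
  $x_{ij} = x_i + \alpha^{\mathrm{true}}_{ij} x_j + \varepsilon$, so the
  noiseless inversion is exact to machine precision.
* **One seeded generator per call**, no global state left behind; the
  pipeline derives per-stage seeds by hashing the stage name, so adding a
  stage never shifts another stage's stream.

What the generator does **not** emulate: taxonomic structure or realistic
names, linkage and selection in the drift model, read-level artefacts
(chimeras, mapping error), compositional coupling between patches, or
pH-dependent treatment effects. Passing tests demonstrate correctness of
the estimators under the stated models, not robustness to everything real
data can do.

# Validation scale and known limitations

The package's own validation (test suite and `scripts/acceptance.R`) runs
at desk scale, chosen to keep the full suite under a minute of simulation
time while leaving Monte-Carlo error well inside each tolerance: drift
recovery uses 2,000 SNVs × 20 seeds (median recovered $t$ within 15% of
the 56-generation truth), the closed-form drift check 5,000 SNVs per
condition, PTR recovery a 100-bin track over
$\mathrm{log2\,PTR} \in \{0, 0.5, 1, 1.5\}$ × 20 seeds (median absolute
error well under 0.1), and the null calibrations 200 Mantel datasets at
199 permutations and 500 multinomial draws.

Known limitations, stated plainly:

* $\theta/(2m)$ inherits every caveat of treating read depth as sample
  size and of a literature mutation rate; downstream $N_e$ and generation
  times are order-of-magnitude calibrations, not precision estimates.
  Note also that published figures computed from *rounded* intermediate
  values need not match the chain applied to unrounded ones (e.g. a median
  $\theta$ of $4.5 \times 10^{-6}$ at $m = 2 \times 10^{-10}$ prints as
  $N_e = 11{,}250$, while the per-genome median of $N_e$ computed before
  rounding can differ by a few percent).
* The mean-$F$ inversion assumes unlinked neutral sites; linked selection
  or clonal replacement within a genome bin violates it in ways the
  package does not model.
* The coloniser rule is detection-limited: "absent" means below the
  sampling depth, so colonisation rates are upper bounds on true
  immigration, and the persistence clause makes the rule sensitive to
  drop-outs near the detection limit.
* The PTR estimator requires a known circular coordinate; its use on
  concatenated multi-contig bins is explicitly a compromise.
* The multinomial column test conditions only on the total and the
  maximum; other tally features (diagonal excess, say) need different
  statistics.
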