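---
title: "Methods: recombination mapping and mitotic cluster inference in dysgenic backcrosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recombination mapping and mitotic cluster inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hybrid dysgenesis arises when a paternally inherited set of active
transposable-element (TE) families meets a maternal genome that lacks them
(and lacks the corresponding piRNA defence). In *Drosophila virilis*, F1
daughters of an inducer-strain father (strain 160) and a reactive-strain
mother (strain 9) suffer germline TE activation; the reciprocal cross does
not. Because the two kinds of F1 females are genetically identical, a
backcross of each to strain 9 gives a controlled readout of what TE
activation does to female recombination: every BC1 daughter's genome is a
mosaic of heterozygous (160/9) and homozygous (9/9) blocks, and each block
switch is one crossover (CO) in the F1 mother's germline.

`dysrec` implements this analysis end to end: a cohort simulator with known
truth, ancestry inference from shallow sequencing, CO calling with the
standard exclusion filters, genetic-map construction, detection of
sibling-shared (mitotic) recombination clusters, and a likelihood model of
mitotic cluster formation and transmission.

## The simulator: a stated world

`study_design()` fixes the world the synthetic data comes from. Defaults
are taken from the published experiment where it states them, and are set
once — not tuned — where it does not:

* **Genome.** Five chromosomes of 26–29.5 Mb. Chromosome 6 (the dot) is
  unmappable and excluded throughout.
* **Mothers and cohorts.** 66 low-fecundity dysgenic, 7 high-fecundity
  dysgenic and 20 non-dysgenic F1 mothers. Cohort sizes are Poisson draws
  clipped to published ranges: means 4.7 / 34.6 / 13.8 reflecting the 311,
  242 and 275 sequenced progeny per group. The true distribution of cohort
  sizes is not published; these are configuration defaults, not claims.
* **Meiosis.** 1.46 expected COs per chromosome per gamete (a 732 cM map
  over five chromosomes). Counts are Poisson; positions are uniform with a
  5 Mb minimum separation as a simple interference stand-in (the source
  study reports no generative model; its observed inter-CO distances
  motivate the scale). The spacing constraint is imposed by the exact
  "shrunk interval" construction, so counts keep their Poisson law; counts
  are capped at `floor(L/min_sep)`, an event of probability < 5e-4 at the
  defaults.
* **Mitotic events.** At most one per mother per chromosome. An event
  arises with probability `alpha` (default 0.12 in both conditions) and its
  recombinant chromatid is transmitted to each progeny independently with
  probability `beta` (0.78 dysgenic, 0.11 non-dysgenic). Segregation is X
  (75%) or Z (25%), reflecting the predominance of distortion-type
  clusters in the source data.
* **Sequencing.** Reads per marker are Poisson with mean 2 at the default
  1,000 markers per chromosome, with per-read allele error 0.001 and no
  mapping bias. This is a *reduced-density emulation*: the real study had
  ~136 bp between markers at 0.15X coverage with ~18 kb breakpoint
  intervals; the default here gives ~30 kb intervals — the same order of
  localization error, at ~1/200 of the marker count.

### Segregation modes, concretely

Under **X segregation** the two recombinant chromatids go to different
daughter cells, so the surviving germline cell is homozygous distal to the
exchange. Carrier progeny all show one fixed distal genotype (LOH —
heterozygous if the 160/160 product survived, homozygous otherwise), and a
visible genotype switch only where their proximal meiotic mosaic happens to
differ from it — about half of carriers, matching the published X-linked
cluster where half the cohort shows the breakpoint and the distal region is
extremely distorted. Under **Z segregation** both recombinant products stay
in one cell; every carrier shows the breakpoint, with the two reciprocal
orientations near 1:1. Chromatid-level meiosis inside the mosaic germline
is *not* simulated: carriers take their meiotic mosaic proximally and the
forced product state distally. A green cluster-recovery test therefore
establishes detection of breakpoint sharing at realistic localization
error, not fidelity of within-germline chromatid dynamics.

## Ancestry inference

A two-state HMM (heterozygous 160/9 vs homozygous 9/9 — the backcross
admits no 160/160) is run along each chromosome. Emissions treat reads as
i.i.d.: a het site emits a 160-strain read with probability 0.5, a hom
site only through the error rate. The transition probability across a gap
of d bp is `1 - exp(-r d)` with `r = 4.6e-8` per bp, the euchromatic rate
of 4.6 cM/Mb expressed per base. The forward–backward pass is rescaled at
every marker; underflow is an error, never a warning. Posteriors above
0.95 / below 0.05 define confident genotype blocks; markers in between
belong to transition gaps. These thresholds mirror the genotype-probability
switch rule used to define breakpoint intervals in the source pipeline.

An exhaustive-enumeration oracle (all `2^m` state paths, m ≤ 12) pins the
implementation to 1e-9.

## Crossover calling and the exclusion ledger

Each adjacent pair of opposite-state blocks is one CO; its interval spans
the transition gap and its point estimate is the interval midpoint (the
source data report intervals only; a point is needed for window
assignment).
Filters apply in a fixed order — confidence, double-CO, exclusion zones —
so that zone statistics are computed on cleaned calls (the source does not
state an order):

1. **Confidence.** Calls whose flanking-block support (minimum of the two
   blocks' mean own-state posterior) is below 0.9 are removed. "Flanking
   probability" is not defined precisely in the source; the minimum of the
   two flanking block means is used.
2. **Double COs.** Adjacent calls closer than 750 kb are removed *as a
   pair*, closest pair first, re-joining the genotype — the short segment
   is treated as HMM error, consistent with such pairs being described as
   extremely improbable.
3. **Zones.** Telomeric exclusions of 500 kb (X, 4) and 700 kb (2, 3, 5),
   and proximal exclusions of 3.5 / 1.1 / 1.5 / 2.4 / 2.3 Mb (X, 2, 3, 4,
   5). Samples under 10,000 total reads are dropped before any calling.

Filtering is idempotent and monotone in the exclusion distances; both are
tested as properties.

## Maps and group comparisons

Because whole-gamete CO counts are observed, map length is estimated as
`100 × mean COs per gamete` rather than via a map function
(Haldane/Kosambi would only matter for interval data). Windowed rates
(`cM/Mb`, 250–500 kb windows) partition the map exactly; loess smoothing
uses tricube weights, degree 2, default span 0.3 (unstated in the source;
chosen to track a 26 Mb chromosome at 500 kb windows without erasing the
centromere-proximal decline). CO-count distributions carry bootstrap CIs
from 1,000 resamples of progeny, not of COs. Between-group inter-CO
distances use the two-sided Mann–Whitney U test with mid-rank ties. The
published mixed-model rate comparison is deliberately replaced by a Poisson
likelihood-ratio test (`compare_co_rates()`); mother-level random effects
are not reproduced, and the simplification is part of the package contract.

## Sibling clusters and the mitotic likelihood

A cluster is ≥4 distinct progeny of one mother with COs in a 100 kb span.
The span slides across sorted CO midpoints (the source does not define
window anchoring); overlapping qualifying spans are merged and the
maximal-carrier set kept, at most one cluster per mother-chromosome.
Whether the criterion should use intervals or points is unstated;
midpoints are used.

The by-chance probability of such a cluster (`null_cluster_probability()`)
is defined on the `floor(L/w)` tiling grid: a union bound of
`windows × P(Binomial(N, expected_co·w/L) ≥ 4)`, cross-checked by Monte
Carlo of the same grid event. At cohort 10 and 1.46 COs this is ~6e-5,
below the 1e-4 criterion. **Caveat:** the sliding-span detector is more
sensitive than the fixed grid — simulation puts its false-cluster rate
near 5e-4 per mother-chromosome at cohort 10 — so the grid bound
understates the scan statistic, in this package as in the source analysis.
For the study's actual cohort mix the expected count of spurious clusters
remains well below one.

Per mother and estimation chromosome (X and 3, the only chromosomes where
clusters occurred), the cohort contributes one observation (N, x). The
likelihood multiplies, over mothers,

* no cluster observed: `(1 - alpha) + alpha * P(not sampled)`, with
  `P(not sampled) = sum_{x=0}^{3} C(N,x) beta^x (1-beta)^(N-x)` — exactly 1
  for cohorts of three or fewer;
* cluster observed: `alpha * C(N,x) beta^x (1-beta)^(N-x)`.

The source displays the total likelihood as a sum of the per-mother
factors; the product (sum of logs) is implemented, as the product form of
a likelihood over independent mothers is unambiguous. The observed-cluster
term uses the *untruncated* binomial exactly as displayed, even though
detection requires x ≥ 4; the statistically truncated variant is available
via `model_spec(truncated = TRUE)`. Mothers' X and chromosome-3
observations enter as independent trials; whether the original script did
the same cannot be confirmed from the text, and non-estimation chromosomes
contribute no terms.

Fitting maximizes the log-likelihood with L-BFGS-B from a deterministic
5×5 multi-start grid, parameters boxed to `[1e-6, 1-1e-6]`. With zero
observed clusters the likelihood is non-increasing in alpha for every beta
(and exactly flat at beta = 0); the ridge is resolved deterministically to
the alpha lower boundary. Nested models (2-, two 3- and 4-parameter
sharing patterns across conditions) are compared by likelihood-ratio tests
with one df per extra parameter. Confidence intervals follow the published
procedure — scan one parameter, others fixed at their MLEs, to the
two-log-likelihood-unit drop — which is narrower than a full profile
likelihood; this is documented rather than "fixed".

## Numerical and degenerate-input choices

* HMM underflow stops with an error; posteriors are renormalized per
  marker.
* `p_cluster_not_sampled()` is clipped to [0, 1] against floating-point
  drift; the complement identity is tested to 1e-12.
* Grid/optimizer ties: the first maximal window (sorted by position) and
  the first optimum over the deterministic start grid are kept, making
  every fit reproducible bit-for-bit.
* Fewer than three windows after zero-CO exclusion yields `NA`
  correlations, not an error; a group without multi-CO gametes yields an
  undefined (reported) rank-sum comparison.
* Chromosomes absent from the zone tables get zero-width zones.

## What a green suite does and does not establish

The generator emulates marker sparsity, genotyping noise, cohort imbalance
and cluster penetrance, but not: mapping bias, reference errors,
heterochromatic marker deserts, TE-insertion polymorphism within strains,
or chromatid-level germline dynamics. Tests against the simulator
establish that the pipeline recovers the truth *of this world* at the
published operating points (e.g. cluster recovery ≥95% at beta = 0.78 and
N ≥ 6 at 25 kb localization error); end-to-end sensitivity on real data
also depends on the double-CO filter, which removes a carrier whose
breakpoint falls within 750 kb of one of its own meiotic COs (~8% of
carriers at these rates — visible in full-pipeline simulations as a few
points of sensitivity loss).

The headline data-dependent quantities of the source study (per-chromosome
map lengths, the eight-cluster table, the alpha/beta fits) are reproduced
by this code path only when the study's supplementary crossover tables are
supplied to `read_crossover_table()`; they are not bundled. The package's
own tests compute every number they assert.
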