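---
title: "Demultiplexing hashed single-cell pools: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demultiplexing hashed single-cell pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hashdemux)
```

## The problem

Cell hashing labels each sample in a pooled single-cell experiment with an
antibody conjugate carrying a sample-specific DNA barcode (a hashtag oligo,
HTO). After droplet encapsulation and sequencing, every cell barcode has a
small vector of HTO UMI counts. Three things must be decided per barcode:

* which sample the cell came from (demultiplexing),
* whether the droplet contained cells from more than one sample
  (cross-sample multiplet detection), and
* whether the droplet contained any labelled cell at all (negative calls:
  unstained spike-in cells, failed stains, or ambient material).

Because multiplets from distinct samples become detectable, pools can be
"super-loaded" well beyond the usual droplet occupancy: detected
cross-sample multiplets are simply discarded, and only same-sample
(unresolved) multiplets survive as contamination.

## The classification model

Let $x_i$ be the raw count of a given HTO in cell $i$ and $n$ the number of
cells. Counts are normalized per tag with a centered log-ratio (CLR)
transform,

$$x_i' = \ln\frac{x_i + c}{\left(\prod_{j=1}^{n}(x_j + c)\right)^{1/n}},$$

with pseudocount $c = 1$ by default. The raw formula is undefined whenever
any count is zero, and zeros are ubiquitous in tag data, so the pseudocount
is not optional in practice; it is exposed as a parameter and enters both
the numerator and the geometric mean, preserving the per-tag zero-mean
property that the tests assert to $10^{-9}$.

Classification then proceeds in three stages:

1. **Provisional structure.** All cells are partitioned by seeded k-medoids
   on the CLR matrix with $k = (\text{number of tags}) + 1$ — one cluster
   per tag plus one for cells low in everything. This is only scaffolding:
   it suggests, per tag, which cells are that tag's positive population.
2. **Background fit.** For each tag independently, cells in the cluster
   with the highest mean CLR value for that tag are excluded; of the
   remainder, the highest 0.5% of raw counts are dropped as potential
   outliers (multiplets straddling clusters, doublet debris); a negative
   binomial $\mathrm{NB}(\mu, \theta)$ is fitted to the remaining **raw**
   counts by maximum likelihood. The positivity threshold is the smallest
   integer $t$ with $F_{NB}(t) \ge q$, $q = 0.99$ by default.
3. **Calls.** A cell is positive for a tag when its raw count strictly
   exceeds $t$. Zero positive tags → negative; one → singlet of that
   sample; two or more → multiplet, reported as the two most highly
   expressed tags (by CLR, descending), e.g. `HTO2+HTO7`. The number of
   positive tags is kept alongside, so calls with three or more positives
   lose no information.

The NB is fitted on raw counts, not CLR values: CLR values are real-valued
and cannot follow a count distribution, and the threshold must live on the
count scale where the positivity rule is applied. Fitting uses
`MASS::fitdistr` with a method-of-moments start; when the optimizer fails
the moment estimate itself is used, and when the background is not
overdispersed at all the fit degrades to Poisson ($\theta \to \infty$) with
a warning. An all-equal background is treated as a point mass whose
$q$-quantile is the constant itself — the natural limit, and the only
reading under which a degenerate background at count $c$ yields threshold
$c$.

### Why the threshold is contamination-robust in practice

The background set for tag $t$ still contains some multiplets involving
$t$ that were assigned to other clusters. These inflate the fitted mean and
dispersion, pushing the threshold upward — away from the background bulk
but still far below genuine signal when staining is strong. The outlier
trim bounds this effect. On simulated data with signal mean 100 against
background mean 2 the fitted thresholds land around 20–30 counts, and
singlet assignment accuracy exceeds 98% (the acceptance suite measures
this over ten seeds).

### RNA-UMI gating and rescue

Barcodes with fewer than 200 RNA UMIs are never used for fitting or
first-pass classification. Barcodes with 50–200 RNA UMIs can afterwards be
classified with the *frozen* thresholds (`rescue_low_umi()`): a low-RNA
barcode with one clean positive tag is a real cell worth keeping, while one
negative for everything is ambient material. Applying the rescue rule to
the originally classified set reproduces its calls exactly, which the test
suite asserts barcode-for-barcode; this holds because rescue re-derives CLR
values only to rank tags *within* a barcode, while positivity depends only
on raw counts and frozen thresholds.

If no RNA totals are provided, every barcode is eligible for fitting and
rescue is not meaningful.

## k-medoids: determinism and scale

The partitioning stage wants a deterministic, dependency-light clusterer
whose centers are data points. `kmedoids()` uses exact PAM (`cluster::pam`,
with the classic `pamonce = 2` acceleration) up to 3,000 rows and CLARA
(`cluster::clara`, PAM on seeded subsamples, `pamLike = TRUE`,
`rngR = TRUE`) above that, keeping cost linear in cell number. Both routes
are deterministic given the seed, and every randomized operation in the
package takes and records a seed. Exact PAM at tens of thousands of cells
would need a quadratic dissimilarity matrix, which is why the subsampled
variant exists at all; on well-separated tag data the two give the same
partitions in practice.

One consequence worth knowing: cluster *labels* are arbitrary. Everything
downstream uses only the membership structure (the per-tag top cluster is
found by mean CLR), so relabelling cannot change calls.

## The droplet simulator

`simulate_experiment()` emulates the pooled experiment the classifier is
designed for:

* droplet occupancy $K \sim \mathrm{Poisson}(\lambda)$, zero-truncated for
  matrix emission (empty droplets appear in the ground-truth table only);
* each cell draws a sample label from the pool proportions, or no label
  with probability `unlabeled_fraction` (unstained negative-control cells);
* a droplet holding $m$ cells of sample $t$ receives
  $\mathrm{NB}(m \cdot \mu_s, \theta_s)$ counts for tag $t$ — signal adds
  at the mean level, the simplest model consistent with multiplets having
  higher totals — plus an ambient $\mathrm{NB}(\mu_b, \theta_b)$ draw on
  every tag in every droplet;
* per-cell RNA UMI totals are lognormal and exist solely to exercise the
  200-UMI gate and the 50–200 rescue window.

Defaults are the study conditions: $\lambda = 0.43$ (80% of occupied
droplets are singlets — the super-loading regime in which a run targeting
20,000 singlets carries roughly 5,000 multiplets), eight equal samples,
`unlabeled_fraction = 1/9` (about one sample-equivalent of unstained
spike-in cells), signal mean 100 vs background mean 2, NB sizes 10
(signal, CV ≈ 0.33) and 2 (background, strongly overdispersed ambient
counts), RNA totals lognormal(log 2000, 1). Sizes accept `Inf`, which
recovers Poisson exactly — a testable limit.

`expected_loading_stats()` gives the closed-form companion: conditional on
occupancy ≥ 1, the singlet and multiplet fractions of the truncated
Poisson, with the multiplet mass split into cross-sample and unresolved
using $\sum_k P(K{=}k)\sum_j p_j^k = \sum_j e^{-\lambda}(e^{\lambda p_j} -
1 - \lambda p_j)$. The simulator is checked against this closed form within
binomial error, and the closed form against an independent term-by-term
series summation.

**What the simulator does not model:** ambient-RNA expression profiles,
batch effects in staining efficiency, per-cell staining heterogeneity
(signal means are shared within a sample), barcode-sharing artifacts, or
any transcriptome content beyond a scalar UMI total. Passing tests on
simulated data therefore demonstrate that the procedure recovers the model
it assumes at realistic signal-to-background ratios — not that every real
dataset is this clean. On real data the relevant knobs are `q` (stricter →
fewer positives), the outlier fraction, and the RNA gate.

## Tag counting

`count_tags()` reproduces the standard tag quantification convention: the
cell barcode and UMI are sliced from read 1 (10x 3' v2 spans by default),
the tag from read 2, the tag is assigned to the unique library barcode
within a maximum hamming distance (default 1), and one UMI is counted per
distinct (cell barcode, UMI, tag) triple. Choices worth stating:

* ties at the minimal distance are discarded, never split fractionally;
* `N` bases always count as mismatches; comparison is case-insensitive;
* UMIs are collapsed by exact identity only — no UMI error correction,
  which belongs to upstream RNA processing if anywhere;
* deduplication is per (cell, UMI, tag) triple, so the same cell-UMI pair
  observed with two different (validly assigned) tags counts once for
  each tag; collapsing across tags would silently vote on chimeric reads;
* cell barcodes are never error-corrected here; an optional whitelist
  drops off-list barcodes and tallies them.

Every read pair lands in exactly one tally (counted, duplicate, no-match,
off-whitelist, too-short), a conservation property the tests check, and
the whole pipeline is validated read-for-read against a brute-force
all-pairs matcher on 10,000 synthetic reads.

The tag library loader warns when two barcodes are within
$2 \times$ `max_hamming` of each other, the geometry in which a read can
tie between entries.

## Staining index

For antibody titration, `staining_index()` computes
$\mathrm{SI} = (\mathrm{Pos}_{0.5} - \mathrm{Neg}_{0.5}) / (2 \times
\mathrm{mad}(\mathrm{Neg}))$ where **mad is the MEAN absolute deviation
about the negative median** — not the median absolute deviation, despite
the flow-cytometry abbreviation. This is stated prominently because
`stats::mad` is the other convention and the two differ by a constant
factor on Gaussian data and more on skewed data.

`titration_curve()` pools all condition matrices with the unstained
control and CLR-normalizes them jointly (they come from one pooled,
hash-demultiplexed run; one experiment, one normalization), takes the
negative peak from the control cells, and finds each condition's positive
peak automatically: seeded k-medoids with $k = 2$ on the normalized ADT
matrix, keeping the cluster with the highest mean for the antibody under
test. Graph-based clustering would also work here; k-medoids was chosen to
stay deterministic and dependency-free, at the cost of possible
peak-membership differences when populations barely separate.

Two numerical caveats, both visible in the tests: picking the top cluster
on *unstained* data selects slightly upward, so the zero-concentration SI
is a small positive number rather than exactly zero (the bias shrinks as
the panel widens — with seven markers it is well inside ±0.25); and at very
low background means the CLR median sits on discrete atoms spaced
$\ln\frac{c+2}{c+1}$ apart, so SI comparisons are only meaningful when
background counts are at least in the tens, as ADT backgrounds are.

## Problem sizes and numerical choices

The shipped tests run the full classifier on 20,000-droplet simulations
across ten seeds, check the loading closed form on 50,000 droplets, and
validate tag counting on 10,000 reads — sizes at which every statistical
check has comfortable power while the whole suite stays quick on a laptop.
Other fixed choices: positivity is strict inequality above the integer
threshold; the per-tag top cluster breaks ties toward the lower cluster
index; background fits refuse to run on fewer than 20 cells; thresholds
are non-decreasing in `q` by construction (quantiles of a fixed fit).

## Known limitations

* Same-sample multiplets are invisible by construction; only the Poisson
  arithmetic (`expected_loading_stats`) bounds their rate.
* Severely unbalanced pools shrink some clusters; the k-medoids scaffold
  can then merge a rare sample into background, inflating its threshold.
* The background fit assumes one background population per tag; bimodal
  ambient contamination would violate it.
* A singlet call means "exactly one hashtag detected": a labelled cell
  co-encapsulated with an unstained cell is still called a singlet, which
  is the designed behaviour when unstained controls are spiked in.
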