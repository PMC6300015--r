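# hashdemux

Demultiplexing and doublet detection for hashed single-cell pools.

In cell hashing, every sample in a pooled droplet-based single-cell
experiment is stained with an antibody conjugate carrying a sample-specific
DNA barcode (a hashtag oligo, HTO). After sequencing, each cell barcode has
a small vector of HTO UMI counts, and three questions must be answered per
droplet: which sample did the cell come from, did the droplet hold cells
from more than one sample (a detectable cross-sample multiplet), and did it
hold any labelled cell at all. Answering them makes "super-loading" safe:
pools can be run far above normal droplet occupancy because cross-sample
multiplets are detected and discarded.

`hashdemux` is aimed at people building or validating hashing workflows:
it implements the full path from raw paired reads to per-droplet calls,
plus a ground-truth droplet simulator and staining-index computation for
antibody titration.

## The method

Raw counts `x_i` for each HTO are normalized with a centered log-ratio
(CLR) transform across cells,

```
x_i' = ln( (x_i + 1) / geometric_mean(x + 1) )
```

then all cells are partitioned by seeded k-medoids with `k = tags + 1`.
For each tag, the cluster with the highest mean CLR value (that tag's
positive population) is excluded, the top 0.5% of remaining raw counts are
trimmed, and a negative binomial NB(mu, size) is fitted by maximum
likelihood to the remaining raw counts — the tag's ambient background. The
positivity threshold is the smallest integer count whose fitted CDF
reaches q = 0.99. A barcode positive (count strictly above threshold) for
exactly one tag is a singlet of that sample; for two or more, a multiplet
named by its two most expressed tags (`HTO2+HTO7`); for none, negative.
Barcodes under 200 RNA UMIs are excluded from fitting and can be rescued
afterwards with the frozen thresholds (`rescue_low_umi()`), separating
low-RNA real cells from ambient material.

`expected_loading_stats()` provides the closed-form Poisson loading
arithmetic (singlet/multiplet fractions conditional on occupancy, split
into detectable cross-sample and undetectable same-sample multiplets), and
`simulate_experiment()` generates full experiments with known per-droplet
ground truth. `staining_index()` / `titration_curve()` compute the
flow-style staining index SI = (Pos_0.5 − Neg_0.5) / (2 × mad(Neg)) — mad
here is the *mean* absolute deviation — with automated positive-peak
detection and an unstained control as the negative peak.

See `vignettes/hto-demultiplexing.Rmd` for assumptions, parameter
guidance and design notes.

## Worked example

Simulate a super-loaded pool of 8 equally mixed samples (20,000 droplets
at λ = 0.43 cells/droplet, one sample-equivalent of unstained
negative-control cells) and demultiplex it:

```r
library(hashdemux)

loading <- loading_model(lambda_cells = 0.43,
                         sample_proportions = rep(1/8, 8),
                         n_droplets = 20000, unlabeled_fraction = 1/9)
sim <- simulate_experiment(loading, signal_model(), seed = 1)
res <- demultiplex(sim$counts, seed = 1)
res
#> Hash demultiplexing of 7005 barcodes, 8 tags
#>
#> multiplet  negative   singlet
#>      1027       639      5339
#> per-tag thresholds (count units):
#> HTO1 HTO2 HTO3 HTO4 HTO5 HTO6 HTO7 HTO8
#>   26   21   27   24   19   19   20   22
```

7,005 of the 20,000 droplets were occupied. The fitted per-tag thresholds
(19–27 counts) sit an order of magnitude above the ambient background
(mean 2) and well below genuine signal (mean 100): 5,339 droplets get a
sample assignment, 1,027 are flagged as multiplets for removal, 639 are
negative (mostly the unstained spike-ins). The closed form says what to
expect at this loading rate:

```r
stats <- expected_loading_stats(0.43, rep(1/8, 8))
#> expected: 80.0% singlets, 20.0% multiplets (17.8% detectable cross-sample)
```

and against the simulator's ground truth the singlet assignment accuracy
here is 99.96%. The staining-index worked example:

```r
staining_index(c(9, 9, 9), 1:5)
#> [1] 2.5
```

## Command line

A thin wrapper over the same functions is installed as `exec/hashdemux`:

```sh
hashdemux simulate --config sim.yaml --seed 1 --out simdir/
hashdemux count    --r1 R1.fastq.gz --r2 R2.fastq.gz --tags tags.csv --max-hamming 1 --out counts/
hashdemux demux    --counts counts/ --rna-umi umis.tsv --q 0.99 --seed 1 --out calls/
hashdemux titrate  --manifest manifest.csv --seed 1 --out si.csv
```

Each run writes a `run_metadata.json` with the parameters, seed and
package version next to its outputs.

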