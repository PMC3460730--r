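# hicratio

Chromatin-state segmentation and cluster detection from intra-chromosomal
Hi-C contact maps, for genomicists who want a fast, deterministic
alternative to PCA compartment calling plus a finer, domain-scale
partition of the open genome.

## Method

The analysis has two steps, both at a fixed bin size (100 kb default).

**1. Plus/minus states from the interaction ratio.** Raw bin-pair counts
`IV[m,n]` are normalized by the chromosome-wide mean count at the same bin
distance (`lc` bins per chromosome, `lc - t` pairs at distance `t`):

```
NormIV[m,n] = IV[m,n] / ( Σ_{|p-q|=|m-n|} IV[p,q] / (lc - |m-n|) )
```

so the distance decay drops out, and each bin `i` gets a logged
short/long-range contrast with window `d` (default 10 bins):

```
R[i] = log( Σ_{j=i-d..i+d} NormIV[i,j] / Σ_{k>i+d} NormIV[i,k] )
```

The sign of `R[i]` calls the bin **plus** (open chromatin, enriched in
active genes and TF binding) or **minus** (closed); unassessable bins are
**gap**. The rationale: random short-range contacts are easier to capture
in open chromatin, so the short-range share of a bin's contacts indexes
its openness.

**2. Markov Clustering of plus regions.** Plus bins and the raw counts
between them (pairs closer than 20 kb discarded) form a weighted graph
that a deterministic MCL implementation (expansion 2, inflation 3.0)
partitions into clusters with more contact inside than between them. The
terminal bins of each cluster's contiguous runs are **boundary** bins —
where insulator (CTCF/cohesin) and transcription-machinery binding sites
concentrate in real data — and the interior bins are the control group
for enrichment statistics: exact binomial tails with BH adjustment, a
one-sided rank-sum test of within- vs across-cluster counts, and a
distance-preserving simulated null. A dynamics module compares two
conditions (pair transitions, common vs specific boundaries, Jaccard
cluster similarity vs differential expression), and a seeded synthetic
generator plants known states/clusters/features for validation.

## Worked example

```r
library(hicratio)
plan <- make_plan(c(chr1 = 1000), seed = 3)   # planted genome, 40% open target
maps <- sample_contacts(plan, sim_params(), seed = 4)
tracks <- segment_maps(maps)
clusters <- cluster_genome(maps, tracks)
print(tracks$chr1)
print(clusters)
recovery_metrics(plan, tracks, clusters)
```

prints

```
ratio_track: chr1, 1000 bins (399 plus / 590 minus / 11 gap), d=10, mode=as_printed
cluster_set: 75 cluster(s) over 399 bins (inflation 3.0)
  eligible: 71, with distal bins: 5
$state_accuracy
[1] 0.9838221
$boundary_precision
[1] 0.7866109
$boundary_recall
[1] 0.8708333
$boundary_f1
[1] 0.8265929
```

i.e. roughly 40% of assessable bins are called plus, 98.4% of state calls
match the planted truth, and the MCL boundary bins recover the planted
cluster boundaries at F1 0.83. The gap bins are the trailing bins of the
chromosome, whose one-sided long-range window is empty. The within- vs
across-cluster contrast on this map is strong (`within_across_fold()`
gives fold 279, rank-sum p ~ 0), as expected with planted clusters.

## Command-line use

`inst/scripts/hicratio` wraps the pipeline as subcommands that emit the
tool's three standard files — an interaction-ratio wiggle, a per-bin
state/cluster BED, and a cluster file — plus enrichment and dynamics
reports:

```sh
Rscript inst/scripts/hicratio simulate -o sim --bins 1000 --seed 1
Rscript inst/scripts/hicratio cluster -f sim.contacts.tsv --format triplets \
    --chrom-sizes sim.chrom.sizes -o run
Rscript inst/scripts/hicratio enrich --bed run.bed --peaks sim.peaks.bed \
    --genes sim.genes.tsv --chrom-sizes sim.chrom.sizes -o enr
```

Key flags: `-f` input, `-r` resolution (100000), `-d` short/long window in
bins (10), `-c` minimum pair span before clustering (20000), `--inflation`
(3.0), `--mode` (`as_printed`/`symmetric`), `--gaps`, `--seed`. Every run
writes a `.provenance.json` sidecar (parameters, input md5s, seed) that
suffices to reproduce it.

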