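# radelim

Species delimitation for closely related insect lineages from two
independent lines of evidence: genome-wide RAD-seq locus presence/absence
and a mitochondrial barcode marker. The package was built for the
situation common in ghost moths (*Thitarodes*, the hosts of the caterpillar
fungus) and similar poorly sampled groups: populations from neighbouring
valleys that may or may not be distinct species, a handful of CO1-like
sequences, and reduced-representation genomic data whose most informative
signal is which loci are *missing* where.

## What it computes

**SNP-coverage side.** Restriction-site-associated DNA (RAD) reads are
anchored at enzyme cut sites, so divergence at a cut site makes the whole
locus drop out of a lineage. The package performs a simplified de-novo
assembly with the three classic rules — per-sample read stacks retained at
a minimum depth (default 3 reads), within-sample stack merging at ≤ 2
mismatches, cross-sample catalog merging at ≤ 1 mismatch — and converts
the catalog into a samples × loci presence/absence matrix (0 = missing
locus, indicative of a divergent cut site). Samples are hierarchically
clustered on Jaccard distances between presence profiles, the dendrogram
is cut into *k* groups, and each group's **exclusive shared-locus
fraction** is reported: the fraction of catalog loci present in every
member of the group and absent from every other sample.

**Marker side.** From an aligned marker, pairwise p-distances with
pairwise deletion, the Jukes–Cantor correction
*d* = −(3/4)·ln(1 − 4*p*/3), a neighbor-joining tree (Saitou–Nei
Q-criterion), patristic distances, and single-linkage **threshold
clustering at 0.025** (2.5%, a conventional inter-species cutoff for
mitochondrial barcodes). Clusters of size one are flagged as *orphan
taxa*; occupancy and divergence reports compare within- and
between-cluster divergence against reference landmarks (3.78%
intraspecific, 11.06% congeneric).

`run_delineate()` chains both sides and scores their concordance per
sample and globally (Rand index).

**Synthetic data.** `simulation_config()` / `simulate_genomes()` /
`simulate_rad_reads()` / `simulate_markers()` generate multi-species
genomes on a star tree with exact Jukes–Cantor substitutions, in-silico
EcoRI digestion, Poisson read depth and sequencing errors — so the entire
pipeline is verifiable end to end without external data.

## Worked example

Three simulated species, six individuals each, 100 kb genomes, 10%
between-species and 0.2% within-species divergence:

```r
library(radelim)
cfg <- simulation_config(seed = 11)   # defaults are the above
report <- run_delineate(run_config(simulation = cfg, seed = 11))
print(report)
```

```
Species delineation report
  samples: 18  catalog loci: 159
  matrix groups: 3  marker clusters: 3
  exclusive shared-locus fractions: 1=0.245, 2=0.264, 3=0.208
  concordance: 18 / 18 samples agree (Rand index 1)
```

Both lines of evidence recover the three species: the dendrogram cut at
k = 3 matches the marker clusters for all 18 samples, and each group
privately shares 21–26% of the 159-locus catalog — loci present in all of
its members and in no one else, the signature of a species-specific set
of intact restriction sites. The divergence report confirms the pattern
against the barcode landmarks:

```r
divergence_report(report$marker$distances, report$marker$clusters)$intra
```

```
  cluster size   max_intra within_intraspecific_range
1       1    6 0.002032807                       TRUE
2       2    6 0.004010705                       TRUE
3       3    6 0.002734408                       TRUE
```

Within-cluster divergence (≤ 0.4%) sits far inside the 3.78%
intraspecific range while the smallest between-cluster distance (9.7%)
exceeds it — three distinct species.

A command-line front end mirroring the functions is included:

```sh
Rscript inst/scripts/radelim.R simulate --out sim --seed 3
Rscript inst/scripts/radelim.R delineate --reads sim \
    --alignment sim/markers.fasta --out run --k 3 --seed 3
```

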