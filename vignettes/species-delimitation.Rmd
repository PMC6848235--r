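---
title: "Delimiting species from RAD locus dropout and marker distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting species from RAD locus dropout and marker distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radelim)
```

## The problem and the two signals

Candidate species from neighbouring valleys can be morphologically
indistinguishable and are often known from a single sequence. This
package delimits them from two signals that fail independently:

1. **RAD locus dropout.** RAD-seq reads are anchored at restriction
   cut sites. A substitution inside the recognition motif (or enough
   divergence in the flank to defeat catalog merging) removes the locus
   from a lineage. Presence/absence of catalog loci across samples is
   therefore itself a divergence signal: conspecific samples share intact
   cut sites; heterospecific samples do not. No genotype calling is
   needed — the statistic lives at locus granularity.
2. **Barcode distances.** A fixed threshold (0.025 substitutions/site) on
   patristic or corrected sequence distances groups marker sequences into
   putative species; singletons are orphan taxa, evidence of
   undersampling rather than of diversity.

Agreement of the two partitions — scored per sample and by the Rand
index — is the delimitation evidence; disagreement is reported, not
hidden.

## Models and procedures

### Synthetic data generator

`simulate_genomes()` draws a uniform ancestral genome and evolves it on a
**star species tree**: a stem of length $b/2$ per species and a terminal
branch of $w/2$ per individual, where $b$ and $w$ are the configured
between- and within-species divergences (expected substitutions/site).
Two conspecific genomes are thus separated by $w$, two heterospecific
genomes by $b + w$.

Substitutions are placed per site with the **exact Jukes–Cantor branch
probability** $p(t) = \tfrac34\,(1 - e^{-4t/3})$, choosing one of the
three other bases uniformly. Because JC transition matrices compose,
chaining branches gives exactly the JC process for the total path length:
the expected p-distance between two sequences at divergence $d$ is
$\tfrac34(1 - e^{-4d/3})$ at any $d < 0.75$, and inverting observed $p$
through `jc_distance()` is a consistent estimator of $d$. (A first-order
alternative — substituting with probability $t$ itself — was rejected: at
$d = 0.10$ its compounded mismatch probability is 0.0967 against the JC
value 0.0936, a bias several standard errors wide on a 100 kb genome.)
Divergences at or above 0.75 are rejected as saturated.

Digestion scans the forward strand for every (possibly overlapping)
occurrence of the motif and takes the `flank_length` bases immediately
left and right of it as two loci; flanks truncated by a genome end are
discarded. All coordinates are 0-based half-open. Each locus is stored in
**canonical orientation** — the lexicographic minimum of the sequence and
its reverse complement — because digestion exposes flanks on both strands
and catalog matching needs one deterministic representative.

Read counts are Poisson per locus; errors are iid per-base substitutions.
Single-end reads are generated even though real protocols are typically
150 bp paired-end: the presence/absence statistic needs only one locus
sequence per cut-site flank, so the second mate would double the
bookkeeping without changing anything tested. There is no PCR-duplicate,
coverage-bias, quality-profile, indel or diploidy model; the generator
emulates locus dropout and stack formation, not a sequencer. Passing
tests therefore show that the assembly and clustering rules behave
correctly under clean Poisson sampling and JC divergence — not that they
are robust to allelic dropout from heterozygosity, repeat-induced
paralogy, or batch effects in real libraries.

### Assembly rules

`build_stacks()` groups identical canonically oriented reads, processes
primary stacks in decreasing depth (ties: lexicographic consensus), and
merges each into the earliest retained stack whose founding consensus is
within 2 mismatches; consensus is then the depth-weighted per-column
majority (ties to the alphabetically smallest base) and stacks below
depth 3 are dropped. `build_catalog()` pools per-sample consensuses,
sorts by (depth, consensus, sample) and merges greedily by single linkage
at ≤ 1 mismatch. Two readings deserve note:

* the within-sample "2 bp distance" is taken as Hamming distance ≤ 2 on
  fixed-length reads (the `ustacks -M` convention); indels are out of
  scope;
* cross-sample merging "less than 1 bp" is taken as ≤ 1 mismatch (the
  `cstacks -n 1` convention) rather than the literal "< 1 = 0"; the
  parameter is exposed (`cross_sample_max_dist = 0`) so both readings are
  runnable.

The greedy order (decreasing depth, lexicographic tie-break) is not part
of any published rule; it was fixed so that output is reproducible and an
exhaustive brute-force oracle can replay the identical procedure in the
tests. Read-order permutation invariance is tested.

### Matrix clustering

Rows of the presence/absence matrix are compared by **Jaccard distance**
by default: catalog columns are dominated by shared absence, which a
Jaccard set distance ignores and a Hamming distance would count as
similarity. Agglomeration uses `stats::hclust` with **average linkage**
(UPGMA) as the default — the standard heatmap-ordering choice; rows are
pre-sorted by label so tie-breaking is deterministic. Groups are cut at
an explicit `k` (the number of candidate species is the question being
asked) rather than a height; the height cut, when used, keeps merges
*strictly below* the cut and is computed from the merge table directly to
avoid floating-point ambiguity at the boundary.

`group_shared_fraction()` defaults to the **ALL quantifier**: a locus
counts for a group only when present in every member and absent outside.
This is the conservative reading of "all samples share"; the ANY
quantifier is available for sparser data.

### Marker-side delimitation

`nj_tree()` implements Saitou–Nei neighbor joining with the Q-criterion;
ties are broken toward the lexicographically smallest pair of cluster
labels and negative branch lengths are clamped to zero with the deficit
moved to the sibling edge, so additive matrices are reproduced exactly
(tested to 1e-6 on random additive matrices up to 8 taxa, and
cross-checked against `ape::nj` topologies). NJ stands in for
likelihood-based inference deliberately: distance-threshold clustering
needs only patristic distances, and a user-supplied Newick tree can be
clustered directly for comparability with trees inferred elsewhere.

`threshold_clusters()` defaults to **single linkage** (connected
components of the ≤-threshold graph), the standard semantics in
distance-based species delimitation, where chains of intermediate
haplotypes belong together. Complete linkage — every within-cluster pair
within the threshold — is exposed because cluster counts can differ on
chained data, and which reading a published count used is often
unknowable. The threshold applies inclusively (≤).

The divergence report labels both comparison directions explicitly
(within-cluster maximum vs the 3.78% intraspecific landmark;
between-cluster minimum vs that landmark and the 11.06% congeneric
range) instead of collapsing them into a verdict, because the two
landmarks answer different questions and published prose sometimes swaps
them.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `min_depth` | 3 | reads | below this a stack is indistinguishable from stacked errors |
| `within_sample_max_dist` | 2 | mismatches | allele/error tolerance within an individual |
| `cross_sample_max_dist` | 1 | mismatches | cross-individual merge; tighter than within-sample |
| `threshold` | 0.025 | subst./site | conventional barcode inter-species cutoff (2.5%) |
| `metric` / linkage | jaccard / average | — | presence-set geometry; heatmap convention |
| `depth_mean` | 10 | reads/locus | typical RAD coverage; Poisson(10) leaves ~0.3% of loci under depth 3 |
| `between_species_divergence` | 0.10 | subst./site | design condition: well above the 5% species-level signal |
| `within_species_divergence` | 0.002 | subst./site | free parameter (no field estimate exists for RAD flanks); chosen well inside the <3% conspecific range |

## Numerical and degenerate-input choices

* Distances are proportions throughout; 2.5% ⇔ 0.025. Reports never mix
  the two scales.
* Jaccard distance of two empty presence sets is 0 by convention.
* A pair of sequences with zero comparable sites (all gaps/N) is an
  error naming the pair — silently returning NA would corrupt every
  downstream distance.
* IUPAC ambiguity codes other than N are rejected on input: the pairwise
  deletion rules here define only N and gap handling, and silent
  acceptance would distort comparable-site counts.
* Empty read sets yield empty stack tables; empty catalogs yield
  0-column matrices; both flow through without special-casing.
* All generator outputs are pure functions of (configuration, seed);
  per-individual read streams use deterministic sub-seeds.

## Verification design and problem sizes

Every operation with a closed-form or enumerable answer is tested against
an independent oracle: exhaustive re-derivation of the stacking and
catalog rules (200 random instances), brute-force Jaccard/UPGMA
recomputation, closed-form JC values, random additive matrices for NJ,
and set arithmetic for the exclusive-fraction report. End-to-end checks
run the full pipeline at the design conditions — 3 species × 6
individuals, 100 kb genomes, divergence 0.10/0.002, depth 10 for the SNP
side; 1500 bp markers at 0.08/0.005 for the marker side; 10 replicate
seeds each — and require Rand index 1 recovery in ≥ 9 of 10 replicates.
The locus-dropout curve is measured on two individuals across divergence
0 → 0.20 at saturating depth 30 with zero sequencing error, so that
Poisson coverage dropout (~0.3% of loci per individual at depth 10)
cannot contaminate the restriction-site signal and the shared fraction is
exactly 1 at divergence 0. These sizes keep the whole suite around a
minute while leaving Monte-Carlo standard errors several times smaller
than the effects asserted.

## Known limitations

* Haploid, indel-free, equal-rate (JC) sequence evolution; no rate
  heterogeneity, no transition/transversion bias. Real barcode data
  violate all three; the 0.025 threshold is conventional, not estimated.
* The star species tree makes species exchangeable; nested topologies
  can be supplied as Newick for the marker side but are not simulated.
* Locus presence/absence ignores within-locus variation entirely;
  counts here are locus counts, not SNP counts.
* The greedy assembly is a faithful small-scale re-statement of the
  classic stacking rules, not a re-implementation of any particular
  assembler's code path; absolute locus counts will differ from
  production assemblers even where the partition structure agrees.
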