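---
title: "Methods: pan-genome, phenotype and outer-membrane analysis with cyanopan"
author: "cyanopan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome, phenotype and outer-membrane analysis with cyanopan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanopan)
```

`cyanopan` implements a comparative-genomics workflow for collections of
cyanobacterial genomes whose proteomes have already been clustered into
ortholog groups (CLOGs, CLiques of Orthologous Genes) by an external tool
such as OrthoMCL. The package consumes the cluster table and layers six
analyses on top of it: core/pan-genome classification, rarefaction with a
Heaps-law openness fit, a phenotype similarity index, distance-based trees
with patristic comparison, feature-specific signature-gene mining, and a
consensus categorization of β-barrel outer-membrane proteins. Everything is
testable end-to-end on synthetic data with known truth; no downloads or
external tool runs are required.

## The CLOG model

A CLOG table maps cluster ids to member genes, each member a
(genome, gene) pair, over a declared genome universe of size $G$. The three
classes are purely set-theoretic:

* **core** — the CLOG contains at least one sequence from *every* genome;
* **unique** — all sequences come from a single genome. Singleton genes and
  single-strain multi-gene clusters (putative paralog families) are unified
  in this class;
* **dispensable** — everything in between (2 to $G-1$ genomes).

Classification is a pure function of the presence/absence structure, so the
conservation law `core + dispensable + unique = total` is exact and is
asserted in the tests against a brute-force set-based oracle.

Sequence quality control mirrors standard pre-clustering hygiene: a protein
fails QC when shorter than 10 residues or when its stop-codon (`*`)
frequency exceeds 20% of its length; a CDS/protein pair is accepted when
the nucleotide length is exactly $3L$ or $3(L+1)$ — the source data may or
may not count the stop codon, and both encodings are biologically valid, so
both pass and anything else fails.

## Rarefaction and the openness exponent

For each sample size $n \in 1..G$ we draw `repetitions` uniform random
$n$-genome subsets without replacement and record the core size (CLOGs
covering every sampled genome) and pan size (CLOGs touching any sampled
genome). When fewer than `repetitions` distinct subsets exist at some $n$
(always at $n = G$), all subsets are enumerated once, which makes the means
at those sizes exact rather than Monte-Carlo estimates. A `nested = TRUE`
mode scores prefixes of random genome orderings instead, guaranteeing
monotone core/pan trajectories per replicate; it exists for
accumulation-curve style summaries and for the monotonicity property tests.

Openness is quantified in the Tettelin framework: the mean number of CLOGs
first discovered when the $n$-th genome is added is fitted as
$\mathrm{new}(n) = \kappa\, n^{-\alpha}$ by least squares on
$\log \mathrm{new}(n)$ versus $\log n$ for $n \ge 2$ ($n = 1$ measures
genome size, not discovery, and is excluded by default; the cut is
configurable). Only for $\alpha > 1$ does the pan-genome size approach a
limit, so $\alpha \le 1$ is reported as an *open* pan-genome. The
uncertainty on $\alpha$ is a bootstrap over orderings: orderings are
resampled with replacement, per-$n$ means recomputed and the regression
refitted (default 100 refits). The fit is on means; fitting medians is a
reasonable alternative the package does not implement, because the mean is
what the downstream openness call uses.

The clade enrichment statistic compares a clade's observed core size
(computed on the full table) with the mean core of random subsets of the
same cardinality taken from the rarefaction curve — a ratio of 1 means the
clade shares no more than a random strain sample of its size.

## The Tanimoto-like phenotype index

Phenotypes are encoded per feature as bit strings over ordered
subcategories (e.g. habitat with nine subcategories); a value may also be
the sentinel *unknown*. For a strain pair the index accumulates, per
feature:

* unknown in **both** strains — the feature is skipped entirely;
* unknown in **exactly one** — the denominator grows by 0.5 (a half
  penalty: the comparison is possible in principle but unverifiable);
* known in both — popcount(AND) joins the numerator, popcount(OR) the
  denominator.

Similarity is numerator/denominator and distance its complement. A feature
known in both strains with all-zero bits contributes nothing to either sum;
this falls out of the rule rather than being special-cased, and a test
asserts it. When every feature is unknown in at least one strain of a pair
the index is undefined; matrix construction then fails with the offending
pairs listed unless the caller explicitly substitutes a maximal distance
(`allow_missing = TRUE`). We chose the hard error as default because
silently imputing similarity for information-free pairs would contaminate
downstream trees.

With no unknowns and single-subcategory features the index reduces exactly
to the classical Tanimoto/Jaccard coefficient, which the tests verify
against an independent implementation. "Logically assumed" phenotype values
(unicellular strains cannot form heterocysts, and similar) are applied by
an explicit rule table (`apply_inference_rules`), never hard-coded, and
each applied inference can be logged.

## Trees and their comparison

`neighbor_joining()` is a from-scratch Saitou–Nei implementation: join the
pair minimizing $Q(i,j) = (r-2)\,d(i,j) - R_i - R_j$, with the standard
branch-length estimates. Two behaviours are pinned down that library
implementations leave unspecified:

* **ties** in $Q$ are broken by the lexicographically smallest sorted label
  pair, so output is deterministic under label permutation;
* **negative branch estimates** are clamped to zero with the deficit
  transferred to the sister branch, preserving the pair's path length
  (at the final trifurcation the deficit moves to the longest remaining
  branch).

On additive matrices the implementation reproduces the generating tree's
topology and branch lengths to $10^{-9}$ (patristic round-trip), and on
arbitrary symmetric matrices its topologies match `ape::nj` — the
independent oracle — in randomized tests.

Patristic distances are path sums over branch lengths
(via `ape::dist.nodes`); tree similarity is the Pearson correlation of the
vectorized upper triangles of two patristic matrices over shared leaves.
This makes the statistic invariant to uniform branch scaling and equal to 1
for identical trees, and it ranges over $[-1, 1]$.

AAI (average amino-acid identity) distances are computed over single-copy
core CLOGs: core clusters in which every genome contributes exactly one
sequence. Each pair of member proteins is globally aligned
(Needleman–Wunsch via `Biostrings::pairwiseAlignment`) with
BLOSUM62, gap opening 10 and gap extension 0.5 — a standard protein
scoring; all three sit in `aai_scoring()` and can be changed. Identity is
matches over total alignment columns by default (alternatives: non-gap
columns, shortest-sequence length), and the distance is $1 - \mathrm{AAI}$.
Alignment-based (16S-style) distances use the uncorrected p-distance over a
supplied multiple alignment, skipping columns gapped in either row;
model-corrected distances are deliberately out of scope.

## Signature mining

A feature strain set partitions the universe into positive, negative and
unknown strains; unknown strains count as non-members, so a CLOG touching
an unknown strain is excluded — restricting candidates to confirmed
carriers of the phenotype. *Exact* candidates are CLOGs whose member-genome
set equals the positive set; *relaxed* candidates drop the coverage
requirement (members ⊆ positives) and are bucketed by support. At full
support the relaxed result equals the exact one, which is asserted.

The specificity filter promotes a candidate to *signature gene* when an
outgroup homology search returns no qualifying hit: qualifying means bait
(query) coverage ≥ 0.80 **and** e-value ≤ 1.0e-10, both inclusive. The
boundaries matter and are tested: coverage 0.79 is excluded however strong
the e-value; an e-value of exactly 1.0e-10 qualifies. Because it is
ambiguous whether outgroup evidence should be counted per hit row or per
distinct subject sequence, both counts are reported per query × taxon.

## β-barrel categorization

Four binary criteria feed a decision table:

| criterion | type | rule |
|---|---|---|
| TMBp consensus | major | called β-barrel by **more than one** sequence predictor (≥ 2 votes) |
| pHMM | major | ≥ 1 β-barrel family profile hit |
| Pfam potential | minor | an uncovered stretch **longer than 79** residues (≥ 80) remains after masking non-barrel Pfam domains |
| CLOG detected | minor | the protein passes both majors and **more than 50%** of all sequences of its CLOG do too |

Categories: (a) both majors + both minors; (b) both majors + exactly one
minor; (c) both majors only, retained only with a structure-level
confirmation flag (the in-silico-structure/manual-inspection step is
consumed as an override list, not recomputed); (d) everything else. All
three thresholds are strict readings of their wording and each is asserted
at its boundary (2 votes; uncovered run 79 vs 80; CLOG fraction exactly
0.5 fails). The CLOG vote's denominator counts *all* members of the
cluster; members without an evidence row count as non-passing — the
alternative (denominator = members with evidence) would silently inflate
detection for sparsely annotated clusters. Proteins in a CLOG that fails
the vote keep their Pfam minor and so remain eligible for category (b):
the criteria are independent columns, not a cascade. Family labels come
from the best pHMM hit (lowest e-value, ties by bit score, then name);
this replaces a sequence-stretch clustering step of the original protocol
with a transparent labelling, a documented simplification.

## Functional profiles along clade chains

COG letters are aggregated with dual counting: a gene with two categories
increments both; a gene with more than two collapses to the synthetic
letter X (multi-process) and increments X only. Along a strictly nested
clade chain (universe first), step $i$'s increment is the representative's
clade-core gene set minus all larger clades' cores; increments are
pairwise disjoint and partition the smallest clade's core, which is
asserted exactly. The published valley-based split of category profiles is
underspecified, so the package uses a transparent rule instead: a category
is *core-defined* when more than 2/3 of its profile mass sits at the
whole-universe step, *clade-defined* when more than 2/3 sits at clade
steps, else *mixed*; the threshold is a parameter.

## What the synthetic data emulates — and what it does not

The generators produce every input the pipeline consumes, with truth
retained:

* `gen_pan_genome()` plants core CLOGs (one gene per genome), dispensable
  CLOGs with occupancies drawn from a configurable spectrum (default
  weight ∝ occupancy$^{-2}$, mimicking the strongly right-skewed occupancy
  histograms of real pan-genomes), per-genome unique CLOGs (Poisson), and
  optionally clade-specific cores, exact feature-signature CLOGs and
  adversarial decoys (supersets/subsets of the feature set).
  `calibrated_pan_spec()` freezes the desk-scale study condition —
  $G = 20$, 150 core, 1200 dispensable, 140 unique per genome — whose
  unique rate was calibrated once, by pilot simulation, so the fitted
  openness exponent lands near $\alpha = 0.35$, i.e. in the strongly open
  regime reported for phylum-wide cyanobacterial samples.
* `gen_feature_table()` gives all genomes of a clade the same fingerprint
  and masks entries to unknown independently at a configurable rate
  (default 0.1, matching a feature catalogue in which most but not all
  strain/feature combinations are documented).
* `gen_divergent_proteins()` evolves uniform-random ancestors along a known
  tree with per-site substitution probability $1 - e^{-b\,\rho}$ on a
  branch of length $b$ and uniform replacement among the other 19 residues.
  No indels are simulated, so the gap-free global alignment is optimal and
  identity expectations are analytic (stationary identity 1/20).
* `gen_barrel_evidence()` draws true barrel labels at a prevalence of 0.03
  by default (a realistic outer-membrane share of a proteome) and lets each
  predictor vote with stated sensitivity/specificity; in the noiseless
  limit every true barrel lands in category (a) and every non-barrel
  in (d), which is the generator's acceptance check.

What passing these tests shows is that the *computations* are correct on
data whose truth is known. It does not show that real cyanobacterial data
satisfy the generators' simplifications: real ortholog clusters inherit
errors from the clustering tool, real phenotype fingerprints are correlated
with phylogeny rather than block-constant within clades, real proteins
evolve with indels and rate heterogeneity, and real predictor errors are
correlated between tools rather than independent. Conclusions about real
data require the real inputs, which are consumed through the same readers.

## Orchestrated runs

`run_pipeline()` executes the whole chain from a single YAML configuration
(input paths, output directory, seed, per-stage parameters). The config is
validated in full — unknown keys rejected, every referenced path checked —
before any stage runs, so a typo cannot waste a half-finished run. Each
run writes a manifest recording the parameter echo, seeds, package version
and an MD5 checksum per output; re-running the same configuration
reproduces identical checksums, which is the package's determinism
contract and is tested. The numbered scripts under `analysis/` are thin
narrative drivers over the same exported functions.

## Numerical and design choices

* All randomized operations take an explicit seed, restore the caller's RNG
  state, and are byte-identical under identical seeds (tested).
* Problem sizes in the shipped analyses and checks — 20 genomes, ~4,000
  CLOGs, 200 rarefaction replicates and 200 orderings, 100-seed recovery
  studies at 6 leaves × 8–10 families × 100–120 residues — were chosen as
  the smallest sizes at which every statistic of interest is stable to the
  tolerances the tests assert; all are parameters, and nothing in the
  package caps them.
* The original study's 1000-replicate rarefaction is the package default
  (`repetitions = 1000`); the shipped analyses use 200 because the
  reported means are insensitive to the replicate count well below that
  (the study itself observed identical results at 100 and 10,000).
* Identifiers are case-sensitive throughout. The OrthoMCL member token is
  split at the *first* `|`, so locus tags may contain further pipes.
* Distance matrices must be symmetric with zero diagonal to $10^{-8}$;
  asymmetry, NaN or negative entries are hard errors, not warnings.
* Undefined similarities (empty union of CLOG sets, all-unknown feature
  pairs) are errors naming the pair, with explicit opt-in substitution
  where a matrix is still wanted.

## Limitations

* Ortholog clustering, homology search, alignment computation and β-barrel
  prediction are consumed as tables, never run; their quality bounds
  everything downstream.
* The NJ implementation is quadratic-memory and cubic-time — fine for
  hundreds of taxa, not for thousands.
* Bootstrap support values, maximum-likelihood trees and model-corrected
  distances are out of scope.
* The openness fit assumes a single power law over the whole $n$ range;
  mixed regimes (e.g. a clade-structured collection) will show a lower
  $R^2$ and the exponent then summarizes, rather than decomposes, the
  mixture.
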