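---
title: "Methods: phylogenomic analysis of fungal NRPS families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenomic analysis of fungal NRPS families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Nonribosomal peptide synthetases (NRPSs) are modular megasynthases: each
module minimally comprises an adenylation (A) domain that selects and
activates a substrate, a thiolation/carrier (T) domain, and a condensation
(C) domain; release domains (thioester reductase R, thioesterase) terminate
the chain. Fungal genomes carry from zero to dozens of NRPS genes, ranging
from standalone A domains to eighteen-module synthetases, and the gene
family evolves quickly by module duplication, loss and recombination.

`npsphylome` implements a reusable, tested version of the classic screening
and comparative pipeline for this family:

1. position-specific profiles for the A, T, C and R domain types, built
   from seed alignments and calibrated against a null score distribution;
2. proteome scanning, modular architecture calling (including degenerate
   `dA` domains), and phylogenetic screening of candidates against known
   references and outgroup adenylating enzymes;
3. A-domain phylogenies: maximum-likelihood pairwise distances under
   WAG+Γ(4), neighbor joining, column bootstrap, outgroup rooting;
4. consensus subfamily extraction across three trees, with a
   reduced-dataset rescue rule;
5. Fisher exact tests of subfamily overrepresentation in taxonomic groups;
6. a linear birth–death analysis of gene-count evolution on an ultrametric
   species tree (global rate estimation, Monte-Carlo family p-values,
   Viterbi ancestral counts and per-branch p-values, and a parsimony root
   filter).

A synthetic-data generator with recorded ground truth drives every stage,
so the whole chain can be exercised and validated without any external
downloads.

# Domain profiles and scanning

## Scoring model

A profile is a position-specific score matrix over the 20 amino acids:
column scores are `log2` odds of the observed seed-alignment frequency
(total pseudocount 1, distributed as +0.05 per residue) against the uniform
background 0.05, in bits. Alignment columns with more than 50% gaps are
dropped from the match states. Scanning is local alignment (Smith–Waterman)
of the protein against the profile with affine gaps (defaults: open 11,
extend 1 bit — a gap of length *k* costs `open + k*extend`); sub-optimal
non-overlapping hits are found by masking each reported hit and rescanning.
Coordinates are 0-based half-open throughout.

This is a calibrated position-specific scoring model rather than a full
profile HMM: the pipeline's screening logic (e-value threshold,
architecture calling, candidate phylogeny) is what the package
reimplements, and legacy HMMER2 ASCII profiles can be imported onto the
same score-matrix representation (`read_hmmer2_profile()`) for real-data
runs.

## Null calibration and e-values

Each profile is calibrated by scoring at least 200 random sequences drawn
from the *seed alignment's* residue composition (length-matched to the
profile) and fitting a Gumbel location and scale by the method of moments.
Drawing the null from the seed composition, rather than a uniform
background, matters: a shuffled NRPS protein retains domain-like
composition, and a uniform null underestimates its chance scores.

The e-value of a hit with bit score `S` against a protein of length `L` is

```
E(S) = 20 * (L / L0) * exp(-(S - mu) / scale)
```

with `L0` the calibration length. The anchor is deliberately conservative:
placing `E = 1` at the Gumbel location would mean ~63% of unrelated
proteins yield an `e < 1` hit per scan (the expected chance-hit count at
the location is 1 by construction), and a tenfold inflation still leaves
the expected rate at the screening threshold near 10%. The twentyfold
inflation targets a ~5% chance-hit rate per scan, leaving headroom for the
sampling noise of a 200-draw calibration. Genuine domains score hundreds
of bits above the null, so the screening threshold `e < 1` loses no
sensitivity. E-values decrease strictly as the bit score increases at a
fixed search space.

## Degenerate domains

A hit is flagged degenerate (`dA`) when its bit score falls below half of
the profile's *trusted self score*, defined as the median profile score of
the seed sequences themselves. Two choices here deserve explanation:

* **Anchor.** The sum of per-column score maxima is unattainable for any
  real sequence once the profile mixes subfamilies (no sequence carries
  every subfamily's marker residues), so ratios against it are not
  interpretable. The seed-median is the score a genuine full-length member
  actually achieves — the same idea as a curated profile's trusted cutoff.
* **Threshold 0.5.** A complete A domain at 15% divergence (the upper end
  of what the architecture-accuracy checks cover) scores about 0.65 ± 0.04
  of the trusted score under this scoring model, while a half-length
  degenerate domain scores about 0.33. A threshold of 0.6 would misflag
  roughly one diverged-but-complete domain in ten; 0.5 separates the two
  populations by more than three standard deviations each way. The
  fraction remains a parameter (`degeneracy_fraction`) for profiles or
  divergence regimes where the arithmetic differs.

## Architecture calling and screening

Overlapping hits from all profiles are resolved greedily by bit score (an
overlap counts when it exceeds 30% of the shorter hit; ties break by
earlier start, then by domain-type order A < T < C < R), survivors are
sorted by start, degenerate A domains render as `dA`, and the module count
is the number of A plus dA domains.

Candidate screening is phylogenetic: after rooting the A-domain tree on
the outgroup adenylating enzymes, the accepted queries are the leaves of
the smallest clade that contains all reference (known-function) domains,
excludes every outgroup leaf, and carries bootstrap support of at least 90
on its subtending edge. If the references end up on both sides of the root
no clade qualifies and the screen reports an error.

# Phylogeny construction

## Distances

Pairwise distances are maximum-likelihood under WAG with discrete-gamma
rate heterogeneity (four equal-probability categories, shape `alpha`
defaulting to 1 and user-settable; category rates are the bin means and
average to 1). The WAG exchangeabilities and stationary frequencies are
embedded from the published matrix; supplying observed frequencies gives
the "+F" variant. Sites with a gap or non-standard residue in either
sequence are ignored; a pair with no comparable sites is an error. The
likelihood is maximized over `d` on `[1e-6, 10]`; saturated pairs cap at
10.

Two search modes are used. The full-data tree uses per-pair golden-section
search to tolerance 1e-6. Bootstrap replicate matrices use a shared
48-point log-spaced grid with parabolic refinement: replicate distances
only need to be accurate enough to rank topologies, and sharing the grid's
transition matrices across all pairs makes replicates cheap. Both paths run
in compiled code.

## Neighbor joining and bootstrap

NJ follows the standard agglomeration with two documented contracts: when
two pairs minimize the Q criterion within 1e-12 the lexicographically
smallest label pair is joined (full determinism), and negative intermediate
branch lengths are clamped to zero with the deficit moved to the sister
edge. The result is unrooted, represented with a trifurcating root.

Bootstrap support resamples alignment columns with replacement to the
original length, rebuilds each replicate tree the same way, and annotates
every internal edge of the full-data tree with the rounded percentage of
replicates containing the identical leaf-set bipartition. Supports are
invariant to row order and reproducible per seed. The conventional
replicate count for distance/NJ analyses (200) is the default;
smaller counts are used in the bundled demo for speed. The underlying
scheme — distance bootstrap with ML distances recomputed per replicate —
is one of the two readings of the classic SEQBOOT/NEIGHBOR workflow; it is
the one implemented here and is stated as such rather than assumed
silently.

Outgroup rooting places the root on the edge subtending the smallest clade
containing all outgroup labels, splits that edge at its midpoint, and
re-attaches supports to their bipartitions (the two root children subtend
the same split, so a support present on only one side is mirrored to the
other). When no single edge separates the outgroups, the root goes above
their most recent common ancestor.

# Consensus subfamilies

A subfamily is a clade that (i) reaches the support cutoff (default 70; a
vector gives per-tree cutoffs, covering the lenient reading in which the
distance tree is held to a lower bar), (ii) exists with the identical leaf
set at the cutoff in the other two trees, and (iii) contains at least one
reference. Traversal is preorder from the root and stops descending at a
promoted clade, so calls are maximal ("most internal from the root") and
pairwise disjoint.

One eligibility rule is this package's own: when more than one reference is
supplied, a clade containing *every* reference is not promotable
(`exclude_universal`, default on). With outgroup rooting, the clade of all
candidates is the first clade met in preorder and would otherwise absorb
the whole tree into a single "subfamily"; subfamilies are meant to
partition the reference set, and the all-candidates clade reflects the
rooting, not a finding.

The rescue rule covers borderline clades: a clade that keeps identical
composition across the three full trees but misses the support cutoff is
promoted (flagged `rescued`) when its projection onto the reduced-dataset
taxa is supported at the rescue cutoff (default 80) in every
reduced-dataset tree. Composition identity in the full trees is still
required — reduced-dataset support attests only to the taxa it contains,
so without that requirement any superclade projecting onto the same
representative set would be promoted.

Genes are then assigned to the subfamily holding the majority of their
placed A domains; ties go to the most N-terminal placed domain, and genes
whose domains span several subfamilies are flagged recombinant (there is no
established counting convention for such genes, so the
N-terminal tie rule is declared package behavior). Genes with no placed
domains fall into `Other` — which is also how the packaged count table's
"Other" column is treated: stored verbatim as a subfamily-like column, with
no attempt to decide whether it was a residual or curated category.

# Overrepresentation tests

The gene universe is the whole count matrix (optionally restricted to a
set of groups — analyses of this kind rarely state their comparison
universe, so it is explicit here). For a group and subfamily, the 2×2 table counts genes
in/out of the subfamily and in/out of the group; the one-sided
(overrepresentation) p-value is the exact hypergeometric tail and the
two-sided p sums point probabilities at or below the observed table. The
odds ratio is the sample `ad/bc` with Haldane +0.5 continuity when a cell
is zero. Empty margins return p = 1 with a warning. No multiple-testing
correction is applied by default (raw significance is what the original
analysis reports); Benjamini–Hochberg is available by flag.

# Birth–death analysis of gene counts

## Model

Counts evolve along the ultrametric species tree under a linear
birth–death process with equal per-gene birth and death rate λ (events per
gene per time unit, in the tree's time units); state 0 is absorbing. The
transition probability has the classical closed form: with
`a = λt / (1 + λt)` (also the single-gene extinction probability),

```
P(c | s, t) = sum_{j=0}^{min(s,c)} C(s,j) C(s+c-j-1, s-1) a^(s+c-2j) (1-2a)^j
```

computed stably in log-magnitude/sign form (the `a = 1/2` boundary, where
`(1-2a)` vanishes, is handled explicitly). The state space is truncated at
`c_max` (default twice the maximum observed tip count plus 10) and
transition rows are renormalized; a convergence check in the test suite
confirms the likelihood plateaus as `c_max` grows. The root prior is
uniform on `1..c_max` — zero is excluded because an observed family must
have existed at the root, the same logic as the parsimony exclusion filter
(families whose Sankoff root state under |Δcount| edge costs is 0 are
excluded from fitting, with smallest-state tie-breaking).

## Inference

Family likelihoods use Felsenstein pruning over the truncated state space,
batched across families (the per-branch transition matrix is shared, so
hundreds of families cost little more than one). One global λ is fitted by
bounded scalar search on `[1e-8, 10/tree height]` to tolerance 1e-8 —
fitted once across families, not re-fitted per family, matching the global
model of the classical method.

Family-level significance is Monte-Carlo: simulate families from the root
prior under the fitted λ on the same tree, conditioned on non-extinction
(observable families are non-extinct by construction), and report the
add-one rank of the observed family's log-likelihood among the simulated
ones, so p lies in `[1/(n+1), 1]`. The resample count defaults to 1000.
The per-branch statistic usually goes by the name "viterbi p-value"
without a standard definition; here the ancestral counts are the max-product (joint
Viterbi) assignment with smaller-state tie-breaking, and each edge's
p-value is the exact tail of transitions no more probable than the
observed parent→child transition, with direction `expansion` or
`contraction` by the sign of the change. These definitions are declared
behavior rather than a reconstruction of the original tool's internals,
and the per-family p-values in `bd_analyze()` share one null sample across
families (the null distribution is the same; this is an efficiency choice,
recorded in the report object alongside seed and resample count).

# The synthetic generator

The generator emulates the pipeline's inputs with recorded ground truth:

* **Species trees** are pure-birth (Yule) trees rescaled to an exact
  height, so they are ultrametric to machine precision.
* **Gene counts** evolve by exact Gillespie simulation of the linear
  birth–death process — deliberately a different algorithm from the
  closed-form transition probabilities, so simulation serves as an
  independent Monte-Carlo oracle for them (the generator of the process,
  exponentiated, is a second, deterministic oracle in the tests).
* **Proteomes** are assembled from per-domain-type consensus sequences
  (A 480, T 80, C 430, R 340 residues — realistic sizes so coordinates are
  meaningful) into modular templates (`"A"`, `"A-T-R"`, `"(A-T-C)x3"`,
  `"A-T-C-dA-T-C"`, `"KS-AT-ACP-C-A-T-R"`, with non-NRPS tokens emitted as
  inert linker residues), separated by uniform-random linkers of 10–50
  residues so domains are always separable. Degenerate A domains are the
  N-terminal half of the subfamily consensus (C-terminal half deleted),
  which yields the intended detectable-but-low scores. Each subfamily's
  A-domain consensus substitutes its own disjoint, interleaved block of
  positions in the base consensus, making all subfamily variants (and the
  always-present outgroup variant) exactly equidistant: the deep radiation
  carries no resolving signal, mirroring the unresolved deep relationships
  among the real mono/bi-modular subfamilies, while between-subfamily
  distance always exceeds within-subfamily divergence. This design was
  adopted after observing that overlapping random offsets leave chance
  deep signal that column bootstrap can amplify into spurious
  "super-subfamilies" (the star-tree effect). Interleaving the blocks
  means degenerate half-domains retain half of every subfamily's marker
  positions.
* **Tree triplets** plant clades with controlled per-tree supports in
  three trees that differ by random NNI moves applied while the planted
  clades (and outgroup) are collapsed to placeholder tips, so the moves
  can never break them; zero moves gives three identical trees.
  Non-planted edges, including the outgroup stem, take low background
  support draws so that only the planted clades qualify at typical
  cutoffs.

All generator outputs are pure functions of their parameters and seed.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data: substitution-only divergence (no indels,
so the profile-coordinate stacking of extracted domains is exact and the
masking step sees few gaps), a uniform substitution process (no
amino-acid exchangeability structure or site-rate variation within
domains), no gene-model errors or split annotations (repairing those requires
nucleotide-level rescans of the genome, which are out of scope here), and deep subfamily relationships that are exactly star-like
rather than merely poorly supported.

## The bundled demo

`nps_demo_config()` describes a six-species study (tree height 400 time
units): five subfamilies covering the architecture styles above, one gene
per subfamily per species except an eight-copy expansion of the
`EASlike` family in one species, plus four outgroup adenylating proteins.
Per-instance divergence is 0.08 — comfortably inside the regime where
scanning and tree building are reliable, while far from trivial. The demo
runs the full chain in a few minutes with 50 bootstrap replicates per tree
and 500 birth–death resamples (the conventional 200/1000 defaults are kept
for real runs); these problem sizes are the package's own choice of a
small, reproducible worked example. Identical configs and seeds produce
byte-identical stage outputs, each carrying the config hash and seed in a
header line.

# Numerical and edge-case choices

* Masking removes a column iff its gap fraction strictly exceeds the
  threshold (so exactly 30% gaps survives a 0.30 threshold); masking is
  idempotent and preserves row order; an alignment masked to zero columns
  is an error, as is a threshold of 0.
* Partial A domains shorter than 150 residues are dropped before tree
  building (manual removal of unalignable partial domains is common
  practice; a length filter is the reproducible version).
* Newick parsing validates bracket balance and dangling commas with a
  character offset before handing to the reader; numeric internal labels
  are supports; unrooted trees use a trifurcating root; gap characters
  `.` and `-` both normalize to `-` on alignment input.
* Count-table cells may carry footnote markers (`2^c^`); the integer
  prefix is the count. A row-total column, when present, is validated
  against the cell sums and dropped. The hemiascomycete yeasts appear as
  one aggregate pseudo-species.
* All stochastic operations take explicit seeds and restore the caller's
  RNG state; derived stage seeds stay within 32-bit integer range.

# Limitations

* No native maximum-likelihood tree search: the three-tree consensus is
  met with three configurable distance/NJ builders (different bootstrap
  streams and gamma shapes); external ML programs can substitute via
  newick import, but are not bundled.
* The e-value calibration is empirical (Gumbel moments over 200 draws);
  e-values are comparable within a profile but are not cross-tool
  calibrated.
* The birth–death model is the one-parameter equal-rates process; separate
  birth and death rates, per-branch rates, and family-specific rates are
  out of scope.
* Real-data runs at full scale (hundreds of domains, hand-curated
  alignments, externally dated species trees) are supported as inputs but
  not reproduced in the package's own examples: alignment curation, ML
  tree programs and molecular dating sit outside the package.
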