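---
title: "Mapping gene-duplication bursts on a species phylogeny: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping gene-duplication bursts on a species phylogeny: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylogd)
```

## The problem

Polyploidy leaves a characteristic footprint in gene families: a
whole-genome duplication (WGD) duplicates every gene at once, so gene trees
from many unrelated families show duplication nodes that all map to the same
ancestral species. phylogd implements the phylotranscriptomic workflow that
exploits this footprint: reconcile a large collection of gene trees against
a reference species tree, tally where retained duplications (GDs) fall,
call clustered-GD (CGD) bursts as candidate WGDs, corroborate them with the
synonymous-divergence (Ks) distribution of the implied paralog pairs, and
ask whether GD bursts coincide on the tree with diversification-rate
upshifts or trait transitions more often than random placement would
predict.

The package operates downstream of orthology inference, tree building,
dating, and diversification/ancestral-state analyses: its inputs are newick
trees, aligned in-frame CDS, and node lists; those upstream inferences are
out of scope here.

## Duplication mapping

Each gene-tree node is assigned to the species-tree most recent common
ancestor (MRCA) of the species represented in its clade (LCA mapping).
Tips map to their species; an internal node maps to the species-MRCA of its
children's images, which makes the map monotone along every gene-tree edge.
A node is a **duplication** precisely when its image equals the image of at
least one of its children — the species content of one subclade already
"fills" the node, so the bifurcation cannot be a speciation.

Two conventions matter in practice:

* **Support filter.** A duplication is only retained when both subtending
  subclades are credible: the minimum of the two child-branch supports must
  reach `min_support` (default 50 on the 0–100 bootstrap scale).  Tip
  children count as support 100.  Internal children without a recorded
  support fail the filter by default (`missing_support = "fail"`); treating
  absent support as trustworthy is opt-in, because transcriptome gene trees
  routinely contain unsupported bipartitions.
* **Polytomies** in gene trees are treated as soft: a polytomous node is
  never itself scored as a duplication, while duplications below it are
  detected normally.  This errs on the side of undercounting.

Each retained duplication is classified by its retention pattern.  With
`A` and `B` the two descendant lineages of the mapped species node and
`S1`, `S2` the species sets of the two gene subclades, the event is
**ABAB** when all four intersections `S1∩A`, `S1∩B`, `S2∩A`, `S2∩B` are
nonempty, **tip** when the mapped node is a terminal species
(within-species paralogs), and **partial** otherwise.  ABAB is the pattern
a genuine ancestral duplication leaves when both copies persist across the
subsequent split, so a high ABAB fraction distinguishes an ancestral burst
from pile-up artifacts.

### The "relevant trees" denominator

A GD ratio needs a denominator, and simply dividing by the total number of
gene trees penalizes nodes whose descendant species are poorly sampled.  A
gene tree counts as *relevant* for an internal node when it contains at
least one species from each of the node's descendant lineages — the minimum
taxon occupancy under which a duplication at that node could be observed at
all.  For a terminal node, relevance requires at least two gene copies of
that species, by the same observability logic.  A node with no relevant
trees has an undefined ratio (reported `NA`, never 0) and can never pass
burst calling.  When one tree contains several duplications at the same
node they all add to the node's event count, but the tree counts once in
the ratio numerator.  Whether other reconciliation tools define their
ratio denominator the same way cannot be verified from their outputs alone;
the definition above is recorded in the output metadata.

### Rooting

Gene trees are rooted on a configured outgroup species list: the branch
subtending the smallest clade holding all outgroup tips.  When no rooting
makes the outgroup monophyletic, the bipartition with the highest Jaccard
overlap to the outgroup set is used (ties broken by post-order edge index).
Trees with no outgroup tips are skipped and logged rather than
midpoint-rooted: midpoint rooting systematically relocates duplications on
rate-heterogeneous transcriptome trees.

## Burst calling

A species node is called a CGD burst when, simultaneously (all comparisons
inclusive):

* retained duplication count ≥ `min_gd` (default 600),
* GD ratio ≥ `min_ratio` (default 0.06),
* ABAB fraction ≥ `min_abab` (default 0.30).

The stock thresholds are calibrated to surveys on the order of 45,000 gene
trees.  They are defaults, not constants: `scale_thresholds()` rescales the
count threshold linearly in the survey size (rounding half-up, floor 1), so
the same rule is exercisable on hundreds of simulated families.  The ratio
and ABAB thresholds are proportions and need no rescaling.  Raising any
threshold can only demote nodes, never promote them; the test suite asserts
this monotonicity.

## Ks estimation

Burst calling alone cannot distinguish a WGD from other clustered
duplication processes; the classic corroboration is a common mode in the
paralog Ks distribution.  For each retained duplication and focal species,
one gene is taken from each subclade (the pair with the longest aligned
overlap; ties and absent sequences fall back to lexicographically smallest
gene ids, keeping the choice deterministic).

Ks/Ka are computed with Nei–Gojobori (1986) counting plus Jukes–Cantor
correction.  The method is fixed here deliberately: it is closed-form,
convention-explicit, and checkable against an independent per-codon
pathway-enumeration oracle, which the test suite does to 1e-9.  The
conventions:

* Site counting: at each codon position, the synonymous fraction is the
  number of the 3 possible nucleotide changes preserving the amino acid,
  over 3.  Changes creating a stop codon count as nonsynonymous, so
  `S + N = 3 × codons` exactly.  `S` is averaged over the two sequences.
* Differences: for codons differing at *d* positions, all *d*! single-step
  pathways are enumerated; pathways through stop codons are discarded and
  counts averaged over the rest (if every pathway is blocked, all pathways
  are used with stop-involving steps scored nonsynonymous — a rare corner
  retained for totality).
* Codon columns with a gap, an ambiguous base, or a stop in either sequence
  are excluded pairwise and tallied.
* `Ks = -(3/4)·ln(1 - (4/3)·ps)`; `ps ≥ 3/4` sets a saturation flag instead
  of a negative log.  Saturated pairs are excluded from peak detection but
  counted.

Alignment is **not** performed: inputs must be pre-aligned in frame.  This
keeps codon-alignment heuristics, which have their own failure modes, out
of the quantitative surface; the simulator emits exact alignments by
construction.

The Ks peak is the argmax of a Gaussian kernel density on a 1,000-point
grid over a search range (default 0.01–2).  The default bandwidth is
Silverman's rule of thumb on the values clipped to the range; it is
overridable because WGD cohorts of very different ages can call for wider
or narrower smoothing.  At least 20 in-range values are required — below
that a mode estimate is noise.

## Coincidence testing

Whether GD bursts co-occur with diversification-rate upshifts or trait
transitions is tested by randomized placement.  With feature sets `A` and
`B` (species-tree node sets) the observed coincidence count is `|A ∩ B|`
(at match radius 0); one set is then redrawn uniformly without replacement
from the eligible nodes `n_rand` times (default 1,000), preserving its
cardinality, and

P = (1 + #{null ≥ observed}) / (1 + n_rand).

The add-one estimator never returns 0 and floors at `1/(n_rand+1)`.  Each
test is repeated (default 100 times) to display the Monte-Carlo spread of P
as a distribution, and both null schemes — randomize `A` holding `B`, and
the reverse — are run for every pair, since the two conditionals answer
slightly different questions.  Design choices:

* **Eligible nodes** are the internal nodes including the root: all three
  feature classes are MRCA-anchored, so tips are excluded by default (the
  pool is configurable).
* **Match radius.** Exact node identity is the default.  Because burst
  nodes are sometimes reported "near" rather than at an MRCA, a radius in
  edges is exposed (radius 1 accepts parent/child matches); no radius is
  asserted as the right one.
* **Seeding.** One master seed; per-repeat seeds are drawn from it up
  front, so repeats are independent, reproducible, and identical seeds give
  bit-identical P-value lists.
* **Discreteness.** The coincidence count is integer-valued with few
  attainable values, so the test is conservative: the attainable P-levels
  rarely include one just below a nominal α.  On a 30-internal-node tree
  with two 10-node sets the exact size at α = 0.05 is 0.037, not 0.05.
  Calibration checks on such trees must expect rejection rates at the
  attainable size; this is a property of any permutation test on small
  discrete statistics, not an implementation artifact.

## The simulator

Every quantitative claim above is exercised against simulated ground truth,
so the generator is first-class code.  Gene families evolve along the
species tree as a birth–death process: each lineage duplicates at rate λ
and dies at rate μ (events/lineage/time) within branches, and every lineage
entering a WGD node duplicates with the retention probability `r` before
speciating, so both copies descend into both child lineages.  Losses are
simulated as lineage death, not post-hoc pruning — that is what produces
the partial (non-ABAB) retention patterns and below-node mis-mappings that
make the classifier and the recall checks meaningful.  The simulator
records, per event, the branch where it occurred, whether both copies left
survivors, and the node an LCA reconciliation *should* recover given the
surviving species — the bookkeeping oracle the reconciliation tests compare
against.  Extinct families are retried up to 100 times, then reported as
extinct rather than silently dropped; single-survivor families are kept
(they still inform relevant-tree counts).

Sequences evolve synonymously only: the root is drawn from the 61 stop-free
codons, substitution counts per branch are Poisson(length × rate ×
synonymous sites), and each substitution applies one uniformly chosen
synonymous single-nucleotide change.  Ka on simulated pairs is therefore ≈ 0
by construction (small positive values arise from NG86's pathway averaging
across serially diverged codons, e.g. serine), and the expected pairwise Ks
equals rate × separation time.  Internal-node supports are constant (100)
by default or uniform-integer jitter in a configured range — deliberately
crude, since their only job is to exercise the support filter.

What the simulator does **not** emulate, and hence what green tests do not
establish about real data: incomplete lineage sorting and hybridization
(no coalescent), nonsynonymous substitution and selection, codon-usage
bias, rate heterogeneity across sites and lineages, alignment error, and
assembly artifacts (chimeric transcripts, missing tissues).  Real
transcriptome surveys fail in all of these ways; the package's guarantees
are about the mapping/counting/testing machinery, not about upstream data
quality.

## Study conditions used by the checks

The packaged checks run at desk scale, chosen so every stage has enough
events to measure while the whole suite stays interactive: 300 families on
an 8-species ultrametric tree of depth 1 (λ = 0.05, μ = 0.1, one WGD at
retention 0.6) for burst recovery, with count thresholds rescaled from the
45,722-tree reference via `scale_thresholds()`; 500 paralog pairs of 300
codons at pairwise synonymous distance 0.14 for Ks-peak recovery;
reconciliation verified exhaustively over all 9,535 species-labeled rooted
topologies with ≤ 6 copies of ≤ 4 species; and coincidence calibration with
500 independent-feature tests (two 10-node sets on a 30-internal-node tree,
the size-maximizing configuration under the discreteness analysis above).

## Known limitations

* LCA reconciliation attributes every gene-tree/species-tree conflict to
  duplication; deep coalescence or hybridization inflate GD counts at the
  involved nodes.  The burst criteria (especially the ABAB floor) absorb
  some of this, but the package deliberately implements no ILS-aware
  reconciliation.
* Loss is not inferred, only simulated; reported counts are retained
  duplications, not duplication rates.
* NG86 Ks is downward-robust but saturates quickly; pairs beyond Ks ≈ 2 are
  excluded rather than modeled, and no mixture decomposition of multi-WGD
  Ks distributions is attempted.
* The coincidence test conditions on the observed feature-set sizes and
  treats all eligible nodes as exchangeable; it does not model clade age or
  sampling intensity, which can both correlate features with node depth.
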