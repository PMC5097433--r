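---
title: "Defining a conserved core of developmentally up-regulated genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining a conserved core of developmentally up-regulated genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

dictycore implements, as a tested and reusable pipeline, a comparative
strategy for finding the genes that drive multicellular development across
the social amoebae: *Dictyostelium discoideum* (DD), *D. lacteum* (DL),
*Polysphondylium pallidum* (PP) and *D. fasciculatum* (DF), sampled at five
stages — vegetative growth (t0), early aggregation (t1), mound (t2), early
fruiting (t3) and late fruiting (t4). The strategy rests on a simple idea:
a gene whose up-regulation during development is conserved across species
separated by hundreds of millions of years is much more likely to matter
than one called up-regulated in a single noisy profile. Because no two
methods of calling "developmentally up-regulated" have the same failure
modes, three independent callers are combined and their triple intersection
is taken as the robust core set.

This vignette explains the models and the decisions behind each stage. It
states no empirical result that the package's tests or acceptance script do
not themselves compute.

## The pipeline

1. **Ortholog families.** All-vs-all protein similarity scoring followed by
   Markov clustering (MCL) partitions the union of the four proteomes into
   gene families; one-per-species families provide unambiguous orthology.
2. **Method A — threshold caller.** Per species, a gene is developmentally
   up-regulated when it has at least 20 raw reads in some stage and its
   rpkm at some developmental stage is at least 3-fold the growth value.
   Cross-species groups are formed within families by expression-pattern
   matching, and a DD gene enters the Method A set by the three-of-four
   rule (below).
3. **Method B — species as evolutionary replicates.** For one-per-species
   families, the four species' counts are treated as replicates of one
   unit, and a negative binomial Wald test contrasts each developmental
   stage against growth at 10 % FDR.
4. **Method C — strains as replicates.** The same engine with two
   *D. discoideum* strains (NC4, AX4) as replicates over DD genes.
5. **Core set.** Methods B and C are anchored to DD gene ids; the seven
   exclusive Venn regions of the three sets are reported; the core is the
   triple intersection.
6. **Interpretation.** Hypergeometric GO enrichment (with true-path
   annotation propagation) of the core against the annotated background;
   overlap of a mutant-phenotype catalogue with the full-ortholog set; and
   a Wilcoxon–Mann–Whitney test of whether late-peaking genes are more
   conserved (DD–DF percent identity) than early-peaking ones.

## Ortholog families

Similarity is affine-gap Smith–Waterman (match +2, mismatch −1, gap open
−4, extend −1; a gap of length L costs 4 + (L − 1)), normalised by the
smaller self-score so that weights lie in [0, 1]. Edges below `min_weight
= 0.25` are dropped. A shared-5-mer prefilter plays the role BLAST seeding
plays upstream of OrthoMCL: pairs sharing fewer than 2 distinct 5-mers are
never aligned. The prefilter is a heuristic accelerator — for unrelated
proteins of this length the expected number of shared 5-mers is well below
the cutoff, while genuine orthologs share hundreds — and it can be disabled
(`min_shared_kmers = 0`), which the oracle tests do.

MCL uses the standard iteration: column-stochastic matrix with self-loops
set to each node's maximum incident weight, expansion by squaring,
inflation 2.0 with entry-wise renormalisation, pruning below 1e-5, and
convergence when the maximum entry change falls below 1e-9. Clusters are
connected components of the attractor support. The input is canonically
sorted by gene id, so the procedure is deterministic and invariant to edge
order; the tests check the partition against an independent dense-matrix
implementation on small random graphs.

## The Method A rules

Two thresholds define the caller: at least 20 raw reads in some stage (the read floor is interpreted as
per-stage maximum, tolerating genes silent during growth), and rpkm fold
change of at least 3 versus t0. The t0 denominator is floored at 0.5 rpkm
(`epsilon`) so that genes silent during growth get a finite, large fold
change rather than a division by zero.

Within families lacking one-per-species structure, members are grouped by
greedy agglomeration in descending Pearson correlation of stage-wise
log2(rpkm + 1) profiles (`min_similarity = 0.5`), with a lexicographic
gene-id tie-break and the constraint that a group holds at most one member
per species. A constant profile is given correlation 0 against everything.

**The three-of-four rule.** A DD gene enters the Method A set when it is
called in DD, its matched group spans at least 3 species, and the group
member is called in its own species in at least 3 of them (counting DD).
This reading makes groups restricted to three species require all three
calls, and four-species groups tolerate one missing call — the tolerance
is deliberate, because stage asynchrony quenches fold changes in the
species that develop less synchronously, and demanding all four calls
would discard genes whose up-regulation is real but attenuated in one
profile.

## The negative binomial engine

Counts are modelled as NB with variance `mu + alpha * mu^2`. Library
differences are removed by median-of-ratios size factors. Dispersion per
unit is a method-of-moments estimate pooled across stage conditions, with
a `alpha(mu) = a0 + a1/mu` trend fitted across units by least squares;
the final value is the conservative maximum of the raw and trend values
(floored at 1e-8). The per-stage contrast fits
`mu = s_j * exp(b0 + b1 * x)` by Newton–Raphson (start at the log ratio of
condition means, convergence |Δβ| < 1e-8, at most 50 iterations;
non-convergence is flagged and reported as p = 1) and tests `b1 = 0` with
a two-sided Wald statistic from the observed information. A Wald test was
chosen over the historical conditioned exact test because it is a single
clean contrast per stage that an independent oracle can check; the
suite verifies that null p-values are approximately uniform and that the
type-I error at 0.05 sits in a narrow band around nominal. Benjamini–
Hochberg is applied across all (unit, stage) pairs, and a unit is called
up-regulated when some stage reaches `q <= 0.10` with a positive log2 fold
change. Cross-species CDS-length differences within a family are not
corrected; they are absorbed by the size factors (systematic part) and the
dispersion (residual part) — a documented limitation.

## Enrichment, mutant overlap, conservation

GO annotations are propagated up the is_a DAG (true-path rule) before a
one-sided hypergeometric test per term; the background is the set of genes
with at least one propagated annotation, and terms with fewer than two
study genes are suppressed. Overlap percentages (mutant catalogue versus
ortholog set, and the genome baseline) are reported as integer percentages
rounded half-up. Protein conservation is Needleman–Wunsch global percent
identity (match +1, mismatch −1, linear gap −2; identity = identical
positions over alignment length including gaps; traceback prefers
diagonal, then consuming the first sequence, then the second, making the
reported identity deterministic). The late-versus-early comparison pools
peak stages t3 and t4 against t1 and uses a one-sided Mann–Whitney test
(exact for small untied samples, normal approximation with tie and
continuity correction otherwise); one-sided and pooled were chosen because
the hypothesis is directional — later developmental stages should be
enriched for anciently conserved machinery.

## The synthetic-data generator

The generator is the package's testing ground: every downstream stage is
exercised against planted truth, with no downloads. It emulates:

* **A family landscape** on the fixed species topology `((DF,PP),(DL,DD))`
  with all branch lengths 1. An ancestral protein per family (length
  uniform over 300–3000 nt of CDS in multiples of 3) evolves by
  Poisson-sampled substitutions; each substitution replaces a site by one
  of the 19 other residues uniformly — an intentionally minimal model,
  since percent identity is the only downstream consumer of the
  sequences. Duplication and loss occur per branch per copy (default
  probability 0.05 each). Planted core families are exempt from
  birth–death events: the truth category being recovered is "conserved
  core gene with orthologs in all four species", and a family that lost
  its DD member could never be recovered by a DD-anchored caller, so
  including such families in a recall denominator would measure the
  generator rather than the methods.
* **The conservation gradient.** Families peaking at t3/t4 evolve at
  0.05 substitutions/site/branch, families peaking at t1/t2 and the
  non-developmental background at 0.12. These defaults give DD–DF percent
  identities around 80 % and 60 % respectively — in the range expected for
  orthologs across the two major dictyostelid branches — and leave family
  recovery comfortably above the similarity threshold (the suite checks
  adjusted Rand index 1.0 against truth at default parameters).
* **Expression programs.** Baselines are log-normal (meanlog 3, sdlog 1,
  rpkm scale) drawn per family with small per-member jitter (sdlog 0.25),
  because the species-as-replicates device presumes orthologs keep
  comparable expression levels; fully independent baselines would make
  Method B meaningless by construction. Planted genes rise log-linearly
  from baseline to their peak fold (drawn uniformly from 4–20 per family)
  and decay by half per stage (log scale) afterwards, keeping the peak
  identifiable. Expected values are column-scaled so every stage sums to
  the target library size (2e6 by default), and counts are NB draws with
  dispersion 0.2 by default.
* **Stage asynchrony.** The species that develop less synchronously (DL,
  PP, DF) have their developmental expectations mixed with adjacent
  stages: `(1 - a) * s(t) + a/2 * (s(t-1) + s(t+1))` over t1–t4, edge
  stages mixing with their single neighbour at `a/2`. The growth sample is
  left untouched — it is harvested from suspension culture before
  development starts, so asynchrony cannot contaminate it. The default
  `asynchrony_mix = 0.3` is a free parameter (no measured value exists for
  these species); the tests treat it as a dial and verify that quenching
  monotonically erodes realized fold changes and Method A recall.
* **Annotations and mutants.** A small fixed is_a DAG (root, three branch
  terms, eight leaves including one diamond) with development leaves
  preferentially assigned to planted core genes; and a synthetic mutant
  catalogue mixing a fraction of core genes with background noise, so the
  overlap statistics are computable end to end.

Randomness is consumed in a documented order from streams derived from the
single configuration seed (families and sequences under `seed`, counts
under `seed + 1`, annotations under `seed + 2`), so each stage can be
re-drawn reproducibly without re-running the others.

One consequence of fixed-library column scaling deserves emphasis: rpkm
is compositional. The planted up-regulated mass inflates the peak-stage
library total, so every realized fold change is deflated by the planted
share of the transcriptome. With a realistic planted fraction (a few
percent of genes) the deflation is a few percent; in a toy data set where
most genes are planted with the same peak, the scaling can erase the
signal entirely. The generator's defaults keep the planted fraction
small, and tests that verify planted fold recovery measure it relative to
the flat genes, which cancels the compositional factor the same way
fold changes against stably expressed genes do in practice.

### What the generator does not emulate

Reads and mapping (counts are drawn directly), nucleotide-level evolution
and indels (substitution-only proteins), rate variation within a protein,
expression divergence between orthologs beyond a log-normal jitter, and
the deep family-size skew of real proteomes (the real largest family has
hundreds of members). Passing tests therefore demonstrate that the
algorithms do what they claim under a controlled model — not that the
thresholds are optimal for any particular real data set.

## Problem sizes and numerical choices

The reference fixture used by the acceptance checks is 100 conserved
families plus 20 species-specific genes per species, 10 % planted core,
fold changes 4–20, dispersion 0.2, asynchrony 0.3 — large enough for
stable recall and FDR estimates, small enough that the whole pipeline
(alignment, clustering, three callers, conservation test) runs in well
under a minute. Calibration checks use 2000 null units for the NB test and
100 seeded simulations (40 families each, shortened proteins of 100–300
residues) for the conservation test; these sizes put binomial noise on the
estimated rates well inside the asserted bands.

Ties in the peak-stage argmax resolve toward the later stage (late peaks
are the category of scientific interest); identical correlations in
pattern matching resolve by gene-id order; MCL input is sorted by gene id.
Every tolerance (MCL convergence 1e-9, pruning 1e-5, Newton 1e-8, rpkm
epsilon 0.5) is a package constant exposed as a function argument.

## Known limitations

* The NB engine is a clean-room analogue of a DESeq-style analysis, not a
  numerical reproduction of any released implementation.
* Method B excludes families without exactly one member per species
  rather than resolving membership ambiguity.
* The similarity normalisation is not OrthoMCL's e-value scheme; family
  boundaries on real proteomes would differ in detail.
* Percentages are rounded half-up; a count pair whose printed source used
  a different convention can differ by one point.
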