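# dictycore

Comparative developmental transcriptomics of the social amoebae.

Social amoebae (Dictyostelia) are soil protists that switch, upon
starvation, from unicellular growth to a multicellular developmental
program ending in a fruiting body. Genes whose up-regulation during this
program has been conserved across the whole group — here represented by
*Dictyostelium discoideum* (DD), *D. lacteum* (DL), *Polysphondylium
pallidum* (PP) and *D. fasciculatum* (DF), sampled at growth (t0), early
aggregation (t1), mound (t2), early fruiting (t3) and late fruiting (t4) —
are strong candidates for the ancestral core of multicellular development.
dictycore implements the full strategy for defining that core set from
per-species stage-count matrices and proteomes, plus a seeded
synthetic-data generator with planted ground truth so every stage is
testable offline.

The pipeline combines three independent callers of developmental
up-regulation and takes their intersection as the robust core:

* **Ortholog families** — all-vs-all Smith–Waterman similarity
  (self-score-normalised, `w(a,b) = S(a,b) / min(S(a,a), S(b,b))`)
  clustered with the Markov cluster algorithm (inflation 2).
* **Method A** — per-species threshold caller: ≥ 20 reads in some stage
  and `max_s rpkm(s) / rpkm(t0) >= 3` with
  `rpkm = 1e9 * count / (length_nt * library_size)`; cross-species
  expression-pattern matching inside families; a DD gene is kept when its
  group is called in ≥ 3 of the 4 species (three-of-four rule).
* **Method B** — the four species' ortholog counts treated as
  "evolutionary replicates" in a negative binomial Wald test
  (`Var = mu + alpha * mu^2`, median-of-ratios size factors, trend-shrunken
  dispersion, per-stage contrasts vs t0, Benjamini–Hochberg at 10 % FDR).
* **Method C** — the same engine with two DD strains (NC4/AX4) as
  replicates.

Downstream, the package computes the 7-region Venn partition and the core
set, hypergeometric GO enrichment with true-path annotation propagation,
mutant-catalogue overlap percentages, and a one-sided Mann–Whitney test of
whether late-peaking genes (t3/t4) are more conserved between DD and DF
(global-alignment percent identity) than early-peaking ones (t1).

## Worked example

Everything below is generated; no downloads are needed.

```r
library(dictycore)

cfg <- sim_config(seed = 42, n_families_conserved = 100,
                  n_species_specific_per_species = 20,
                  frac_core_dev = 0.10)
sim    <- simulate_families(cfg)
counts <- simulate_counts(sim$catalogue, sim$truth, cfg)

pl <- run_core_pipeline(sim$catalogue, counts,
                        annotations = simulate_annotations(sim$catalogue, cfg),
                        ontology_edges = sim_ontology())
pl
#> <core_pipeline>
#>   families (>=2 members): 98
#>   method A/B/C DD-anchored: 9 / 9 / 10
#>   union 10, core (A&B&C) 9
#>   conservation late vs early: one-sided p = 0.05
```

Reading: of the ten planted conserved developmental families, the
threshold caller (A) and the species-replicates test (B) each recover
nine as DD-anchored genes, and the strain-replicates test (C) calls ten.
Nine genes survive all three filters (the planted gene outside the core
drew a peak fold of 4.1, the bottom of the 4-20 range, and was quenched
by stage asynchrony in the non-DD species, escaping callers A and B),
and the late-peaking genes in the defined
set are more conserved between DD and DF than the early-peaking ones —
the planted conservation gradient.

```r
glance(pl$report)          # set sizes, union, core
tidy(pl$method_b)          # per-family, per-stage NB results
autoplot(pl$report)        # Venn region bar chart
plot_conservation(pl$conservation)
family_stats(pl$families$families)
```

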