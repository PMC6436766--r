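# eradrank

Invasive mammals — above all cats and rats — are the main driver of
vertebrate extinctions on islands, and eradicating them is one of the few
conservation actions with a long record of success. `eradrank` implements a
global island-prioritization pipeline for conservation planners: given
tables of islands, breeding populations of highly threatened vertebrates
(IUCN Critically Endangered or Endangered), invasive mammal populations,
and impact records, it ranks the islands where eradication would do the
most good and filters them by technical and socio-political feasibility.

## The scoring model

For island *i*, the **Current Conservation Risk** is

```
CCR_i = Σ_s  E_s × I_s × Z_s,i
```

summed over the highly threatened vertebrates *s* breeding on the island:

* **E** — extinction risk from the IUCN category: 0.5 (CR) and 0.05 (EN)
  by default, reflecting the relative risks implied by the Red List
  criteria thresholds; an alternative linear scheme (4 / 3) is available
  for sensitivity comparison.
* **I** — irreplaceability: the reciprocal of the number of islands the
  species breeds on (a single-island endemic scores 1). Continental
  populations are never counted.
* **Z** — severity of impact: the maximum over the invasive mammal
  populations on the island, scored 2 (confirmed), 1 (suspected) or
  0 (none). Missing impact records are imputed from the maximum impact
  recorded for the same invasive against any species of the same
  taxonomic family; explicit records always win.

The **Potential Conservation Risk** (PCR) recomputes the same sum after
setting Z to zero for every population that is technically feasible to
eradicate (per-group thresholds on island area and human population).
The **Eradication Benefit**, `EB = CCR − PCR`, is the primary island
ranking. Islands with `EB > 0` are then assigned an expert-elicited
socio-political timeframe (by 2020, by 2030, never), aggregated by
consensus or, failing that, the most conservative vote; islands without a
usable assessment are reported as a priority data gap. Output names of
sensitive islands (expert-flagged, or < 100 ha with a breeding reptile)
are masked.

## Worked example

The package ships the published eight-island worked example as a fixture:

```r
library(eradrank)
dataset <- table1_fixture()
bundle  <- run_pipeline(list(dataset = dataset))
bundle$scores[, c("rank", "name", "country", "ccr", "pcr", "eb")]
#>  rank              name                                   country ccr pcr  eb
#>     1              Mona                               Puerto Rico 5.0   0 5.0
#>     2             Gough St Helena, Ascension and Tristan da Cunha 4.5   0 4.5
#>     3         Amsterdam               French Southern Territories 3.5   0 3.5
#>     4          Floreana                                   Ecuador 3.0   0 3.0
#>     5           Socorro                                    Mexico 3.0   0 3.0
#>     6          San Jose                                    Mexico 2.0   0 2.0
#>     7 Alejandro Selkirk                                     Chile 1.0   0 1.0
#>     8              Niau                          French Polynesia 1.0   0 1.0

bundle$summaries$by2020
#> <benefit summary: by2020>
#>   24 populations of 23 species on 8 islands in 7 countries
```

Every invasive listed for these islands is feasible, so PCR is 0 and each
island's EB equals its CCR: Mona carries five CR single-island endemics
with confirmed impacts (5 × 0.5 × 1 × 2 = 5.0); Gough's sooty albatross
also breeds on Amsterdam, so it contributes 0.5 × 0.5 × 2 = 0.5 there
instead of 1. Eradications on the eight islands would benefit 24
species-island populations of 23 distinct species (the sooty albatross is
counted on both Gough and Amsterdam).

Synthetic datasets shaped like the global compilations (species-per-island
median 1, invasives median 4, ~69 % of islands uninhabited, cat/rat
dominated) are generated with `generate_dataset(generator_params(seed = 1))`,
and `oracle_scores()` provides an independent brute-force recomputation of
every score for verification.

A command-line front end for shell use lives at `inst/cli/eradrank.R`
(subcommands `validate`, `score`, `rank`, `timeframes`, `summarize`,
`simulate`).

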