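---
title: "Ranking islands for invasive mammal eradication: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking islands for invasive mammal eradication: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eradrank)
```

## The prioritization problem

Islands hold a disproportionate share of the world's most threatened
vertebrates, and invasive mammals are the threat most often amenable to
complete removal. With limited funding and political capital, the
question is *which* islands to clear first. `eradrank` scores every
island in a dataset by how much conservation risk a feasible eradication
would remove, then filters the ranking by whether local experts believe a
project could actually be initiated.

The pipeline takes seven delimited tables (islands, species, breeding
records, invasive populations, impact records, feasibility rules, expert
assessments), validates them, and produces ranked scores, timeframe
sets, benefit summaries and masked output tables.

## The scoring model

Current Conservation Risk for island $i$ is

$$\mathrm{CCR}_i = \sum_s E_s \, I_s \, Z_{s,i}$$

over the highly threatened vertebrates $s$ breeding on $i$. Only
Critically Endangered and Endangered species are in scope — any other
IUCN category in the input is a validation error, not a silently
dropped row. Confirmed, probable and potential breeding records count
equally: for species this close to extinction, a potential breeding
population is worth protecting as much as a confirmed one.

**Extinction risk $E$** is a categorical weight: 0.5 for CR and 0.05 for
EN under the default scheme, mirroring the order-of-magnitude difference
in extinction probability implied by the quantitative Red List criteria.
The linear alternative (4 for CR, 3 for EN) compresses that contrast;
both are exposed via `risk_scheme()` and custom weights are allowed. The
scheme decides how strongly CR species dominate the ranking, but it never
changes *which* islands have a positive benefit — that is decided by
feasibility alone, a property the test suite checks on random datasets.

**Irreplaceability $I$** is $1/n$ for a species breeding on $n$ islands,
regardless of island area; continental populations are ignored because
islands may be the only realistic opportunity to provide invasive-free
habitat. $I$ is computed from the dataset's own breeding table. This
matters when analysing a subset of a larger compilation: a species
breeding on 10 islands globally but 2 in the subset gets $I = 0.5$, not
$0.1$. We chose dataset-self-consistency deliberately — scores, tests and
round-trips remain coherent on any subset — but users comparing against a
global analysis should score the full dataset, not a slice.

**Severity $Z_{s,i}$** is the maximum over the island's contributing
invasive populations of a 2/1/0 impact score (confirmed / suspected /
no evidence or confirmed absence of impact). Candidate interactions are
the full cross product of breeding species and included invasive
populations per island; suspected invasive presence counts the same as
confirmed, and populations under ongoing eradication remain included
because their removal is not yet assured. Entirely domestic or farmed
populations are excluded from scoring but retained in the dataset with an
audit flag.

## Impact imputation

Where a candidate interaction has no explicit impact record, the score is
imputed as the maximum impact recorded anywhere in the dataset for the
same invasive mammal against any species of the same taxonomic family.
The key is (invasive species × native family), pooled across all islands:
the rule is taxonomic, not spatial. If no family evidence exists the
score is 0 with provenance `assumed_zero`. Explicit records — including
an explicit "none" — always beat imputation; the rule only fills
unknowns, and applying it twice changes nothing. Imputation is not
extended across invasive congeners (e.g. from one *Rattus* species to
another): each invasive species carries only its own evidence.

## Technical feasibility

A population is feasible to eradicate when its island is at or below its
invasive group's area and human-population thresholds, both inclusive.
Thresholds are **required configuration**: they should come from
eradication precedent, and a missing rule for a group is an error rather
than a silent default. `default_feasibility_rules()` ships an
illustrative table so examples and synthetic runs work out of the box; it
is documented as non-authoritative and any real analysis must supply its
own. Unbounded thresholds are written with the sentinel `inf` so that
"unbounded" and "absent" can never be confused in a rules file.

Potential Conservation Risk is CCR recomputed with only infeasible
populations contributing to $Z$; all feasible populations on an island
are removed concurrently, and interactions among the removed species
(e.g. mesopredator release) are out of scope at this planning resolution.
The Eradication Benefit $EB = CCR - PCR$ is the primary ranking.
Differences below $10^{-12}$ are snapped to exactly zero so that
floating-point noise cannot place an island in the ranked list.

Ranking ties are broken deterministically: higher CCR first, then more
species with a reduced severity, then island id lexicographically. The
tie-break is our choice (any published ranking at this scale leaves ties
unspecified); it favours islands where more is at stake overall.

## Socio-political timeframes

For islands with $EB > 0$, expert votes (`by2020`, `by2030`, `never`,
`unknown`) are aggregated per island: unanimity among informative votes is
a consensus; otherwise the most conservative (latest) informative vote
wins; `unknown` votes are ignored whenever any informative vote exists,
and an island with no usable vote lands in the data-gap set, excluded
from headline results but reported. Aggregation is order-invariant and
idempotent. Years of experience are recorded as metadata only — votes are
never weighted by seniority.

## Scenario analyses and reporting

* **Rodent scenario.** Rodent surveys are incomplete on many islands, so
  rodent populations can carry an "status unknown" flag. Such populations
  do not contribute to baseline scores; `rodent_scenario()` returns a new
  dataset in which they are treated as confirmed feral presences. We read
  the flag as "presence not established" — re-running with these
  populations included is only informative if the baseline excluded them,
  and the scenario then can only increase CCR (a property the tests
  check). The input dataset is never mutated.
* **Masking.** Island names are replaced by `"unknown"` for islands
  flagged sensitive or smaller than 100 ha (strict) with a breeding
  reptile, limiting information useful to wildlife traffickers. Ids are
  retained internally, so masking never changes a count or score.
* **Low-complexity flags.** Among ranked islands, those under 100 ha
  (strict), uninhabited, and needing only one or two feasible impactful
  invasive species removed are flagged as likely low-cost projects.
* **Percentages** are formatted with half-away-from-zero rounding
  (`round_percent()`), the convention used in conservation reporting;
  base R's round-half-even would print 22.5 % as 22 %.

## The synthetic data generator

`generate_dataset()` produces seed-deterministic datasets whose marginals
emulate global threatened-island compilations: species-per-island counts
drawn as 1 + negative binomial (size 0.22, mean 2, capped at 155), giving
a median of 1 with a heavy right tail; invasive richness 1 + negative
binomial (size 1.5, mean 4, capped at 34) on 58 % of islands, giving a
median of 4; log-normal island areas around a median of 430 ha spanning
rock stacks to very large islands; 69 % of islands uninhabited; and an
invasive pool dominated by cats and rats. The negative-binomial family is
our choice — the published material constrains only medians and ranges.
Where the sources constrain nothing we fixed values a field ecologist
would find unremarkable and did not revisit them: 40 % CR / 60 % EN,
8 % of species also continental, impact classes mixed 8 % confirmed /
12 % suspected / 15 % none / 65 % unrecorded, 5 % domestic and 15 %
unknown feral status, 8 % of rodent populations status-unknown, 75 %
expert response rate with votes 45/30/20/5 across
by2020/by2030/never/unknown.

The generator reproduces marginal distributions, not the real joint
structure: area, human population, invasive richness and species richness
are drawn independently, whereas real large inhabited islands carry more
of both natives and invasives. Passing tests therefore demonstrate the
*mechanics* of scoring, filtering and reporting on realistically shaped
tables — they say nothing about any real island, and the shipped
feasibility defaults must not be mistaken for precedent-derived
thresholds.

`table1_fixture()` encodes the published eight-island worked example:
exactly the printed invasive and benefiting-species lists, every listed
invasive feasible with a confirmed impact on each listed species, all
eight islands assessed feasible by 2020. Island areas, populations and
IUCN categories in the fixture are synthetic placeholders (1000 ha,
uninhabited, CR) chosen only so that every population is feasible and no
name is masked; the fixture encodes what the published table prints and
nothing more.

## Verification strategy and problem sizes

The central correctness property is oracle equivalence:
`oracle_scores()` re-derives CCR/PCR/EB as explicit nested loops over
(island, species, population) in base R, sharing no code with the
vectorized pipeline, including an independent re-derivation of
feasibility and family imputation. The acceptance suite compares pipeline
and oracle on 100 seeded eight-island datasets at $10^{-12}$ tolerance,
alongside invariants (bounds $0 \le PCR \le CCR$, $EB \ge 0$;
monotonicity of CCR under added impacts and PCR under shrinking feasible
sets; partition of the timeframe sets; count-preservation under masking;
CCR monotonicity under the rodent scenario) and byte-identical reruns.
Unit and property tests use 8-30 island datasets and a 500-island run for
the generator's marginal calibration; these sizes keep the full suite
under a minute while exercising every code path.

## Known limitations

* No costs, re-invasion risk, biosecurity, or optimization /
  complementarity — the framework ranks independent opportunities at
  global scale and defers portfolio decisions to regional planning.
* Feasibility is a coarse two-threshold screen; island-scale feasibility
  studies will disagree on individual islands.
* Impact imputation is conservative but coarse: a family-level maximum
  can overstate impacts for atypical family members and understates
  wholly unrecorded interactions (notably mice).
* $I$ from the dataset's own breeding table (above) means subset analyses
  are self-consistent but not comparable across differently scoped
  datasets.
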