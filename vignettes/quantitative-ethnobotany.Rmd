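---
title: "Quantitative ethnobotany with use-report tables: models, indices and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ethnobotany with use-report tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethnosurvey)
```

## The data model

A quantitative ethnobotanical survey asks each of `N` respondents which
plant species they use for each of `NC` predefined use categories. The
atomic datum is the *use report*: one informant citing one species for one
category. `ethnosurvey` models a survey as a **set** of such triples plus
the survey frame (`study_design()`): repeated mentions of the same triple
collapse, because every downstream statistic is defined by counting
*informants*, and an informant cannot agree with themselves twice.

Two frame quantities deliberately live outside the records:

* `N`, the total number of respondents surveyed, is the denominator of
  CI, RFC and CVe even when some respondents contribute no use reports.
  In the bundled Adaklu survey, 258 artisans consented but only 251
  distinct informant identities are needed to carry the records; the
  published index values are `UR/258` and `FC/258`, which is why `N` is a
  design input and not `n_distinct(informant)`.
* `NC`, the number of *designed* categories (six building elements in the
  Adaklu survey), enters CVe regardless of how many categories a
  particular dataset populates.

Identifier normalization (trim, collapse internal whitespace, case-fold)
is applied to species and category names because survey tables are
hand-entered; informant codes are left case-sensitive since coding
schemes often distinguish case. Both choices can be switched off
(`normalize = FALSE`).

## Indices and their interpretation

For species $s$: $CI_s = UR_s/N$, $RFC_s = FC_s/N$,
$RI_s = \tfrac12\left(\frac{RFC_s}{\max RFC} + \frac{NU_s}{\max NU}\right)$,
and $CVe_s = \frac{NU_s}{NC}\cdot RFC_s\cdot CI_s$. The maxima in RI are
taken within the analyzed table, not against an external reference list;
this is the convention under which the Adaklu survey's second-ranked RI
(0.750) belongs to the species with the top citation frequency but only
two uses. For a use category with $Nur$ reports over $Ns$ species, the
Trotter–Logan agreement ratio is $IAR = (Nur - Ns)/(Nur - 1)$, and the
fidelity level of $s$ for $u$ is $FL_{su} = 100\,UR_{su}/FC_s$.

Two definitional points that matter in practice:

* **FL's denominator is FC, not UR.** Only informants citing the species
  at all enter the denominator, so a species' FL values across categories
  sum to $100\,UR_s/FC_s \ge 100$. This is what makes "two categories at
  100.00 and 92.42" possible for a two-use species, and it is the
  convention under which the Adaklu fidelity table inverts to integer
  informant counts that sum exactly to each species' UR.
* **IAR is undefined for $Nur \le 1$.** Agreement among fewer than two
  reports has no meaning; the package reports `NA` with a warning rather
  than forcing 0 or 1.

## Numerical choices

All index arithmetic is full precision; rounding is presentation-only,
applied by `render_table()` as half-even rounding at 3 decimals for
indices and IAR and 2 decimals for FL, matching the conventional printing
of these statistics. Ranked tables break ties deterministically (index
descending, species id ascending). Degenerate inputs are classed errors:
empty tables, unknown species lookups, `fc > n`, `ns > nur` and zero
denominators each raise a distinct condition class so scripts can branch
on them.

## The bundled Adaklu survey and its reconstruction

The package ships the three published summary tables of a 2023 survey of
258 vernacular-building artisans in Ghana's Adaklu district (26 species,
six building elements: main pole, main beam, wall lath, roof lath,
binding material, thatch material). The record-level data behind them is
not redistributed; instead `reconstruct_adaklu_survey()` rebuilds an
exact-margin table: inverting each fidelity level against the species'
citation count gives integer cell counts $UR_{su} =
\mathrm{round}(FL\cdot FC/100)$ which reproduce every published UR, FC,
NU, Nur and Ns — the summaries fully determine the species-by-category
contingency structure. Informant identities are then assigned
deterministically (the anchor category takes all $FC_s$ citing
informants, other categories the first $UR_{su}$ of them). These
identities are synthetic: margins, not respondent-level linkage, are
data. Any analysis that only uses the margins — which is all of the
indices here — is exact; analyses of informant-level co-citation
structure would not be meaningful on the reconstruction.

One labelling wrinkle in the source tables: the fastening element is
called "binding material" in the consensus table and "building rope" in
the fidelity table. The package treats these as one category under the
canonical id `binding material`.

## The synthetic generator

`generate_survey()` simulates the simplest mechanism consistent with the
observed marginal structure: informant $i$ cites species $s$ with
probability $p_s$, independently across informants and species;
conditional on citing, category $u$ is mentioned independently with
probability $w_{su}$, and each species has an anchor category with
$w_{su} = 1$ so that a citing informant always contributes at least one
report (every species in the Adaklu fidelity table has an FL-100
element, which this reproduces by construction). Closed forms follow:
$E[FC_s] = Np_s$, $E[UR_s] = Np_s\sum_u w_{su}$,
$E[Nur_u] = N\sum_s p_s w_{su}$ (`expected_indices()`), which the tests
use for binomial parameter-recovery checks (mean RFC within 2% relative
bias of $p$ over 200 replicates at $N = 1000$; single-draw RFC within 3
Monte-Carlo standard errors at $N = 2000$).

The pseudorandom stream is consumed in a fixed order (citation draws
informant-major, then category draws with category innermost), so a given
seed yields a byte-identical serialized table. `adaklu_survey_params()`
calibrates $p_s = FC_s/258$ and $w_{su} = FL_{su}/100$ to the published
margins — these defaults are the study conditions and are not meant to be
tuned.

What the generator deliberately does *not* model: informant heterogeneity
(knowledgeable informants citing many species at once), snowball-sampling
dependence between respondents, informant covariates, and any correlation
between a species' categories beyond the anchor. Passing tests on
generated data therefore demonstrate correctness of the counting and
index arithmetic under independence, not that real interview data meet
those assumptions.

## Pipeline and reporting

`run_pipeline()` reads a use-report CSV, logs validation diagnostics
(silent informants, single-informant species, uncited designed
categories) to standard error, and writes the species index, consensus
and fidelity tables as CSV and/or markdown plus a JSON manifest (input
checksum, full configuration echo, counts). Outputs are deterministic for
a fixed input and configuration, and the manifest's configuration echo is
sufficient to re-run the pipeline identically. The test suite and the
acceptance script run the complete analysis on the reconstructed
4109-record survey and on randomized tables of up to 10 informants × 5
species × 4 categories against a direct-enumeration oracle; these sizes
keep the whole suite in the tens of seconds while exercising every code
path at full depth.

## Known limitations

* No taxonomic name resolution or fuzzy species matching — identifiers
  are opaque strings after normalization.
* No variance estimates or significance tests for the indices (none are
  conventional for these statistics); no informant-consensus-factor
  variants beyond the Trotter–Logan form.
* XLSX ingestion is not provided; convert spreadsheets to CSV first.
* The IUCN conservation-status column is passthrough metadata only.
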