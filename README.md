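# ethnosurvey

Quantitative ethnobotany for informant use-report surveys.

In a quantitative ethnobotanical survey, the atomic datum is a **use
report**: one informant citing one plant species for one use category.
From a long-format table of such mentions, `ethnosurvey` computes the
standard per-species importance indices, per-category consensus
statistics, and species-by-category fidelity levels, and ships a seeded
synthetic-survey generator so every stage can be tested without field
data. It is aimed at ethnobotanists and biodiversity-survey analysts who
need reproducible, scriptable index tables from interview data.

## The statistics

With `N` the total number of respondents surveyed and `NC` the number of
designed use categories, for each species *s*:

| index | definition | meaning |
| --- | --- | --- |
| UR | number of distinct (informant, category) citations of *s* | use reports |
| FC | number of distinct informants citing *s* for any use | frequency of citation |
| NU | number of distinct categories in which *s* is cited | number of uses |
| CI | UR / N | cultural importance (can exceed 1) |
| RFC | FC / N | relative frequency of citation |
| RI | ((RFC / max RFC) + (NU / max NU)) / 2 | relative importance (maxima over the table) |
| CVe | (NU / NC) × RFC × CI | cultural value |

Per use category *u*, with `Nur` its total use reports and `Ns` the number
of species cited for it, the Trotter–Logan **informant agreement ratio**
is IAR = (Nur − Ns) / (Nur − 1): 1 means complete consensus on a single
species, 0 means every report names a different species. The **fidelity
level** of species *s* for category *u* is FL = 100 × UR_su / FC_s, the
percentage of the informants citing *s* who cite it for *u*.

A use report is a *distinct* triple — repeated mentions by the same
informant collapse — and N and NC come from the survey design, not from
whichever informants and categories happen to appear in the records.

## Worked example

The package ships the published summary tables of a 2023 survey of 258
vernacular-building artisans in Ghana's Adaklu district (26 species, six
building elements, 4109 use reports) and can reconstruct an exact
record-level table from them:

```r
library(ethnosurvey)
tab <- reconstruct_adaklu_survey()
idx <- species_index_table(tab)
cat(render_table(idx[1:5, c("species","ur","ci","fc","nu","rfc","ri","cve")],
                 "markdown", 3))
```

| species | ur | ci | fc | nu | rfc | ri | cve |
| --- | --- | --- | --- | --- | --- | --- | --- |
| bambusa vulgaris | 440 | 1.705 | 162 | 4 | 0.628 | 0.823 | 0.714 |
| borassus aethiopum | 406 | 1.574 | 211 | 2 | 0.818 | 0.670 | 0.429 |
| elaeis guineensis | 397 | 1.539 | 251 | 2 | 0.973 | 0.750 | 0.499 |
| senna siamea | 288 | 1.116 | 107 | 3 | 0.415 | 0.588 | 0.231 |
| azadirachta indica | 265 | 1.027 | 103 | 3 | 0.399 | 0.580 | 0.205 |

Bamboo is the standout: 162 of 258 artisans cite it (RFC 0.628) across
four of the six building elements, giving it the top cultural-importance
(CI 1.705), relative-importance (RI 0.823) and cultural-value (CVe 0.714)
scores. Oil palm is cited by nearly everyone (RFC 0.973) but for only two
elements. Consensus per building element:

```r
cat(render_table(consensus_table(tab), "markdown", 3))
```

| use_category | nur | ns | nur_minus_ns | nur_minus_1 | iar |
| --- | --- | --- | --- | --- | --- |
| main pole | 1183 | 12 | 1171 | 1182 | 0.991 |
| main beam | 730 | 6 | 724 | 729 | 0.993 |
| wall lath | 339 | 2 | 337 | 338 | 0.997 |
| roof lath | 539 | 4 | 535 | 538 | 0.994 |
| binding material | 518 | 4 | 514 | 517 | 0.994 |
| thatch material | 800 | 8 | 792 | 799 | 0.991 |

IAR above 0.99 everywhere: artisans agree strongly on which few species
serve each building element (wall laths use just two species).

For your own data: `read_use_reports("survey.csv")` (columns
`informant,species,use_category`), then `species_index_table()`,
`consensus_table()`, `fidelity_table()`, or the one-shot
`run_pipeline("survey.csv", "out/")`, which writes the three report
tables as CSV and markdown plus a JSON run manifest. A thin command-line
wrapper with `compute`, `simulate` and `validate` subcommands is
installed at `system.file("cli", "ethnosurvey", package = "ethnosurvey")`.
Simulated surveys come from `generate_survey(survey_params(...))`, with
`adaklu_survey_params()` providing a preset calibrated to the study
margins and `expected_indices()` the closed-form expectations.

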