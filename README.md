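# rhizorank

Trait-based prioritization of drought-tolerant rhizobacteria, from raw
in-vitro assay readouts to ranked strains, compatible consortia and
biosafety reports.

Screening programs for plant growth-promoting rhizobacteria (PGPR) test
dozens of candidate strains across a battery of plant-growth-promoting
trait (PGPT) assays — phosphate/potassium solubilization halos,
chrome-azurol-S siderophore assays, Salkowski IAA and Nessler ammonia
colorimetry, gravimetric exopolysaccharides, biofilm morphotyping, and
growth under PEG-6000 osmotic stress. `rhizorank` turns those raw
measurements into a reproducible selection decision:

1. **Quantification** — halo indices
   `PSI% = Ø(colony+halo)/Ø(colony) × 100`, percent units
   `PSU% = (Ar − As)/Ar × 100`, OLS standard-curve inversion for
   concentrations, drought-tolerance classes from OD600 in 24% PEG, and a
   measured PEG → water-potential calibration (0/12/24/32% ↦
   −0.72/−0.98/−1.67/−2.26 MPa, linear in between).
2. **Scoring** — each quantitative trait's observed range is split into
   five equal intervals mapped to scores {0, 0.25, 0.5, 0.75, 1};
   qualitative traits score 0/1; PEG growth uses the fixed 0.51–1.00 OD
   window.
3. **Ranking and selection** — scores are summed within nutritional
   (NH4, KS, PS-plate, PS-broth, SID, NH3) and drought (EPS, BF, IAA, DT)
   categories; strains are ordered by total, then N, then D, then id, and
   the top strains are selected while skipping flagged exclusions.
4. **Consortium design** — maximum-trait-coverage assembly under hard
   pairwise constraints (no antagonistic or limited-growth pair in one
   consortium), with greedy and exact solvers.
5. **Biosafety** — ABRicate-style AMR/virulence hit tables filtered at
   ≥ 80% identity and ≥ 70% coverage (inclusive) and summarized by gene
   family.

A synthetic panel generator with planted ground truth makes the whole
pipeline testable without any external data, and bundled reference tables
transcribe a published screening of 50 drought-tolerant grapevine
rhizosphere isolates (see `inst/extdata/data_quality_notes.md` for known
quirks of those tables).

## Worked example

```r
library(rhizorank)

res <- run_pipeline(pipeline_config())   # bundled reference screening
head(res$ranked[, c("strain_id", "taxonomy", "n_score", "d_score",
                    "total_score", "rank")], 5)
#>  strain_id                       taxonomy n_score d_score total_score rank
#>     UC4449           Pseudomonas glycinis    5.25    3.00        8.25    1
#>     UC4489         Pseudomonas aeruginosa    5.25    1.75        7.00    2
#>     UC4450           Enterobacter ludwigi    5.00    1.75        6.75    3
#>     UC4439 Pseudomonas frederiksbergensis    4.25    2.25        6.50    4
#>     UC4441              Pantoea stewartii    4.25    2.25        6.50    5

res$selection$selected
#> "UC4449" "UC4450" "UC4439" "UC4521" "UC4553" "UC4478" "UC4510" "UC4490" "UC4535"
res$selection$skipped
#>  strain_id             reason rank
#>     UC4489 pathogenic_species    2
#>     UC4441 pathogenic_species    5
#>     UC4444        slow_growth    8
```

The ranking puts *P. glycinis* UC4449 first (total score 8.25 of a
possible 10); *P. aeruginosa* UC4489 and *P. stewartii* UC4441 rank high
but are skipped as known pathogenic species, and *B. velezensis* UC4444
as too slow-growing to scale — leaving the nine selected strains.
Consortium assembly then keeps the antagonist *B. licheniformis* UC4521
away from the four strains it inhibits, and splits the limited-growth
pairs around *P. megaterium* UC4510:

```r
res$consortia
#>  consortium_id                     members coverage_count covered_traits
#>            BC1 UC4439,UC4449,UC4450,UC4478             10 NH4,KS,...,DT
#>            BC2        UC4449,UC4450,UC4478             10 NH4,KS,...,DT
#>            BC3        UC4449,UC4450,UC4490             10 NH4,KS,...,DT
#>            BC4        UC4449,UC4450,UC4535             10 NH4,KS,...,DT
```

Every returned plan covers all ten traits at level 5 and contains no
incompatible pair. A thin command-line wrapper with `run-all`, `simulate`
and `biosafety` subcommands ships in `inst/cli/rhizorank`.

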