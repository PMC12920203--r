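---
title: "Trait-based prioritization of drought-tolerant rhizobacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based prioritization of drought-tolerant rhizobacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizorank)
```

## The problem

Screening programs for plant growth-promoting rhizobacteria (PGPR) produce
large panels of candidate strains, each characterized by a battery of
in-vitro trait assays: phosphate and potassium solubilization, siderophore
and ammonia production, auxin (IAA) synthesis, exopolysaccharide (EPS)
secretion, biofilm formation, and growth under osmotic stress. The
practical question is always the same: which handful of strains should go
into a field-ready consortium? `rhizorank` implements a complete,
deterministic pipeline for that decision: assay quantification, five-level
trait scoring, category-wise ranking, exclusion-aware selection,
compatibility-constrained consortium assembly, and genome-screen biosafety
filtering.

## Assay quantification

Plate solubilization assays are summarized by the halo index

$$\mathrm{PSI}\% = \frac{\varnothing(\mathrm{colony+halo})}{\varnothing(\mathrm{colony})}\times 100,$$

identical in form for phosphate (PSI) and potassium (KSI). The index is
bounded below by 100 (no halo); the implementation rejects non-positive
colony diameters and halos narrower than the colony as invalid
measurements rather than producing quiet nonsense.

Colorimetric broth assays (siderophores by CAS, phosphorus solubilization
by bromophenol-blue acidification) are summarized as percent units

$$\mathrm{PSU}\% = \frac{A_r - A_s}{A_r}\times 100,$$

where $A_r$ is the uninoculated reference absorbance and $A_s$ the sample.
A sample darker than its reference yields a negative value with a quality
flag; we deliberately do not clip at zero, so assay anomalies remain
visible in reports.

Ammonia (Nessler) and IAA (Salkowski) concentrations are inverted through
ordinary least-squares standard curves. Unweighted OLS is used because
calibration standards are measured with equal care across the range; a
fit-quality warning is raised when $R^2 < 0.98$ (there is no community
standard here, so the bar is set where a clean two-reagent colorimetric
calibration normally lands). Inversions below zero are reported as 0 with
a below-detection flag. Replicates (triplicate by default) are averaged
arithmetically before scoring; the SD and replicate count are retained so
standard errors ($SE = SD/\sqrt{n}$) can be reported alongside means.

Osmotic stress is imposed with PEG 6000. The bundled calibration maps
0, 12, 24 and 32 % w/v PEG to measured water potentials of −0.72, −0.98,
−1.67 and −2.26 MPa. Because the relation was measured rather than
modeled, intermediate concentrations are interpolated piecewise-linearly
and extrapolation outside the table is an error. Note that linear
interpolation gives −1.325 MPa at 18 % PEG; quoted values near −1.25 MPa
for that concentration come from instrument fits that are not part of the
calibration table, and the package makes no attempt to reproduce them.
Strains are classed by OD600 after 48 h in 24 % PEG as highly sensitive
(< 0.3), sensitive (0.3 to < 0.4), tolerant (0.4–0.5) or highly tolerant
(> 0.5); the boundaries are half-open so every OD maps to exactly one
class, with 0.5 itself "tolerant" because the top class is strictly above
0.5. Only highly tolerant strains pass the drought pre-screen.

## Scoring and ranking

Each quantitative trait is discretized over the strains being scored: the
observed range $[\min, \max]$ is split into five equal-width intervals
(levels 1–5), mapped to the ratio scale $\{0, 0.25, 0.5, 0.75, 1\}$.
Design choices the source scoring scheme leaves open, fixed here:

* **Bin edges** are left-closed/right-open with a closed last bin, so the
  maximum always reaches level 5 and membership is unambiguous.
* **Zeros anchor the range.** Non-producers are included when computing
  $[\min,\max]$, so they land in level 1 rather than stretching bins.
* **Degenerate ranges** (all strains equal): everyone scores 1 when the
  common value is positive, 0 when it is zero — equal producers should
  not be penalized for lack of contrast.
* **Missing cells** stay missing; they contribute 0 to sums but are
  reported through a completeness warning, never silently zeroed.

Qualitative traits (ammonium plate reaction, biofilm morphotype) score
binary 0/1. Growth in 24 % PEG uses a fixed window: the pre-screened ODs
span 0.51–1.00, split into five levels of width 0.098 (values above 1.00
clamp to level 5; pre-screen survivors marginally below 0.51 floor at
level 1).

Scores are summed within two categories — nutritional
(NH4, KS, PS-plate, PS-broth, SID, NH3) and drought-related
(EPS, BF, IAA, DT) — and the ranking orders strains by total score
descending, with ties broken by N score, then D score, then strain id.
The tie-break sequence is the one consistent with adjacent pairs in the
bundled reference ranking, and it makes the order a deterministic total
order: permuting the input never changes the result. Selection walks the
ranking top-down, skipping strains flagged as excluded (pathogenic
species, strains too slow-growing to scale), until the requested number
(default 9) is reached.

The bundled 50-isolate reference table reproduces this arithmetic
end-to-end; three of its printed rows required minimal reconciliation
between trait cells and their own printed sums, documented
cell-by-cell in `inst/extdata/data_quality_notes.md`.

## Consortium assembly

Consortia are strain sets maximizing *trait coverage*: the number of
traits expressed at the coverage threshold (default score 1, i.e. level 5)
by at least one member. Two constraints and one preference shape the
search:

* **Antagonism** (inhibition halo in co-culture) is a hard exclusion.
* **Limited growth** of one strain in another's presence is treated the
  same way — the reference workflow also distributed such pairs across
  separate consortia. A soft-penalty treatment was considered and
  rejected: with only a handful of candidate strains, a limited-growth
  pair inside a consortium undermines the formulation as thoroughly as
  antagonism does.
* **Shared origin cultivar** adds a small objective bonus (default 0.01
  per shared-origin pair) — a tie-break expressing "potential synergy",
  never worth a covered trait.

The greedy solver grows a candidate set from every seed strain, always
adding the compatible candidate with the best objective gain (ties
lexicographic), and returns the highest-objective grown sets; strains may
appear in several consortia, matching how screening programs reuse strong
strains across formulations. The exact solver enumerates all valid
subsets within the size range and is feasible for pools of roughly a
dozen strains; on random instances with ≤ 8 strains and sizes ≤ 4 it is
tested against an independently written brute-force enumeration, and the
greedy solver is checked empirically against the classical
$(1 - 1/e)$ max-coverage bound. Target consortium size and the number of
consortia are parameters (defaults 2–4 members, 4 consortia) because the
reference workflow fixed neither.

## Biosafety screening

Genome-screen hit tables (ABRicate-style TSV against ResFinder, CARD and
VFDB) are filtered by the standard retention rule: percent identity
≥ 80 and coverage ≥ 70, both inclusive, matching the "≥" wording of the
EFSA-style guideline the rule comes from. Retained hits are categorized
by a prefix-matching gene-family map (efflux, beta-lactamase, motility,
secretion, biofilm, …) shipped as an editable CSV; it is a reporting
convenience, not a claim of completeness. Overlapping ResFinder/CARD hits
for the same locus are retained in duplicate and visible in the per-gene
listing, since no principled deduplication rule exists without
coordinates-level analysis.

## The synthetic panel generator

`generate_panel()` emulates the statistical structure of a bench panel:
uniform colony geometry (3–10 mm colonies, 0–15 mm halo extensions),
fixed-reference absorbance pairs with uniform color-shift fractions,
log-normal IAA (median 15 µg/mL, σ = 0.6), NH3 (median 40 mg/L, σ = 0.8)
and EPS (median 0.2 g/L, σ = 0.8) concentrations — parameters chosen once
so the generated ranges bracket the reference nine-strain measurements —
and a logistic-growth OD600 endpoint scaled down with PEG dose, with
Gaussian read noise (σ = 0.02). Concentration assays are emitted as raw
absorbances next to their standard-curve points, so the full inversion
path is exercised. Planted top performers draw every quantitative trait
from the top decile of its distribution and are positive for every
qualitative trait; the headline recovery property asks that three planted
strains among fifty rank in the top five after the whole pipeline runs.

What the generator does *not* emulate: inter-trait correlation (real
strains have correlated trait syndromes), batch effects, plate-position
effects, or heteroscedastic assay noise beyond the simple proportional
models used. Passing the recovery test therefore shows the pipeline's
arithmetic and ordering are sound under the assumed noise, not that the
assays themselves are informative for field performance.

## Problem sizes and determinism

The shipped tests and the acceptance script use panels of 50 strains with
3 replicates (matching the reference screening's scale), 100-panel
recovery batches, and 100 random instances of ≤ 8 strains for the solver
cross-checks — sizes at which the full suite completes in well under a
minute while keeping the binomial noise on a 95 % recovery criterion
small. All randomness flows through explicit integer seeds; generators
save and restore the caller's random stream, and identical configurations
produce byte-identical output files and manifests.

## Known limitations

* Scoring is relative to the panel being scored: a strain's score changes
  when the cohort changes. This is inherent to range-based discretization
  and is why score matrices, not raw values, are the unit of exchange.
* The drought-growth window (0.51–1.00 OD600) is fixed by the pre-screen
  convention; panels whose survivors exceed OD 1.0 clamp at level 5.
* The consortium objective counts traits covered at level 5 only (by
  default); partial redundancy between members is not rewarded.
* Biosafety categorization is prefix-based and will miscategorize genes
  whose symbols collide across families; the map is editable per study.
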