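# Data-quality notes for the bundled reference tables

The bundled tables transcribe a published in-vitro screening of 50
drought-tolerant grapevine rhizosphere isolates (score table) and of the
nine strains selected from it (quantitative trait table). Known quirks,
kept or reconciled as noted:

## isolate_scores.tsv (50 isolates x 10 trait scores + category sums)

* UC4445 has a blank EPS cell in the source table. It is kept as missing
  (empty field), and its printed category sums are consistent with the
  blank contributing 0.
* Three source rows have per-trait cells that do not add up to their own
  printed N/D/Total sums. Because the ranking and the nine-strain
  selection rest on the sums (which also agree with each row's printed
  rank position), the cells were minimally emended to restore internal
  consistency:
  - UC4439: cells summed to N = 4.5 vs printed N = 4.25 / Tot = 6.5.
    KS emended 0.5 -> 0.25 (any single N cell lowered by 0.25 would
    reconcile the row; KS was chosen arbitrarily).
  - UC4510: the printed triple (N = 3, D = 2.25, Tot = 5.5) violates
    N + D = Tot and the cells summed to D = 2.75. N = 3 and Tot = 5.5 were
    kept, D set to 2.5, and EPS emended 0.75 -> 0.5.
  - UC4535: cells summed to D = 1.5 vs the self-consistent printed triple
    (2.75, 2.5, 5.25). The unique single-cell fix BF 0 -> 1 was applied.
    Note this contradicts the qualitative BF "-" recorded for UC4535 in
    the nine-strain table.

## selected_traits.tsv (9 selected strains, quantitative assays)

* Several PSI values (e.g. 15.5, 32) are below 100 and therefore cannot be
  outputs of the halo-index formula (total/colony x 100 >= 100); several
  strains also show identical PSI and KSI values. These look like
  transcription artifacts in the source; values are stored verbatim and
  are never validated against (or fed through) the halo-index formula.
* BF entries are stored as printed even where the source's prose names a
  different set of biofilm formers.

## compatibility_constraints.tsv

* Antagonism (UC4521 vs UC4450/UC4478/UC4490/UC4439) and limited growth
  (UC4510 vs UC4535/UC4553/UC4449) pairs as reported; all remaining pairs
  of the nine strains were reported mutually compatible and are stored
  explicitly so the matrix is complete.
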