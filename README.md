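# nanoforesight

Horizon-scanning prioritization for nanotechnology-enabled health products
(NHPs).

Regulatory agencies use Horizon Scanning — signal detection, filtration,
prioritization, assessment — to anticipate where guidance will be needed
before innovative products reach evaluation. For NHPs the gap between
innovation and applicable guidelines is a known contributor to the
"valley of death" between development and market. `nanoforesight`
implements the prioritization and assessment stages of such an exercise as
a tested R pipeline, for regulatory scientists and foresight analysts who
start from a curated database of detected signals (literature, patent and
clinical-trial records).

## The method

Each detected signal is one NHP, indexed two ways:

* a **classification signature** `mode.purpose.composition.nanofabrication`
  (e.g. `2.3.2.1`; parentheses mark multivalued, i.e. multifunctional,
  positions, an `s` suffix marks self-assembly, `0` means undefined, and
  `n` in a pattern is a wildcard);
* one or more **design-solution codes** (DSCs, e.g. `B.T.2.3`), the
  attribute by which the product addresses one of six design problems
  (mode-of-action × medical-purpose categories).

With `C` the frequency of a design solution among `T` detected signals,
its novelty score is

```
S = (T − C) / T × 10
```

so ubiquitous solutions score near 0 and unique ones approach 10. On the
cumulative count axis of the descending-frequency spectrum:

* DSCs up to the **first quartile** (Q1 = 0.25·T) are **trends** (weak
  signals);
* DSCs beyond the **third quartile** (Q3 = 0.75·T) are **tentative wild
  cards**.

Because tail scores bunch just below 10, tentative wild cards are ranked
after multiplicative **correction factors**: unspecific (Y/Z) DSCs
annihilate the score (×0); multifunctionality enriches it (1 DSC ×1,
2 ×3/2, >2 ×2); sharing DSCs with trends penalises it (0 shared ×2,
1 ×2/3, >1 ×1/2); sharing a trend NHP signature penalises it (×1 vs ×2).
The raw score of a signal is the novelty of its exact DSC combination.
Final wild cards are the maximal corrected-score cluster. Prioritized
items are then matched against a regulatory-document table
(signature-pattern matching) and flagged when no document applies — for
multifunctional products, when no document covers *all* codes of their
multivalued positions.

A synthetic-data generator (`generate_signals()`) reproduces the
statistical structure of the study conditions — 836 selected signals in
three source strata, trend DSC counts 95/61/61, a Zipf-like singleton-rich
tail, five planted multifunctional wild cards — so the whole pipeline is
testable offline.

## Worked example

```r
library(nanoforesight)

db <- generate_signals(generator_config(seed = 101))
selected_totals(db)
#>         scopus            epo clinicaltrials
#>            102            524            210

spectrum <- build_spectrum(db)
sel <- quartile_selection(spectrum, db)
sel
#> <quartile_selection> 3 trend DSC(s) covering 217 signals; 222 tentative wild-card DSC(s)

round_half_up(novelty_score(spectrum$count[1:3], attr(spectrum, "total")), 2)
#> [1] 8.86 9.27 9.27

fin <- select_final_wildcards(corrected_scores(db, sel))
fin[, c("signal_id", "signature", "raw_score", "combined_factor", "corrected_score")]
#> 1 SIG00832  2.(1.2.3).1.1      9.99               8            79.9
#> ...five multifunctional signals, each a unique triple-DSC combination

report <- gap_report(db, sel, fin, read_regdb())
sum(report$insufficient)
#> [1] 6
```

The three trend DSCs (polymeric nanocarriers, lipid nanocarriers, dental
nanomaterials) cover 217 of the 836 signals with novelty scores
8.86–9.27; the five final wild cards are multifunctional theranostic-style
products whose DSC combinations occur once (raw score 9.99, corrected
79.9); the gap report shows the galenic trends covered by existing
guidance while the dental trend and all multifunctional wild cards have
none.

The same pipeline is laid out as a narrative workflow in `analysis/01` …
`analysis/05`, writing its tables under `results/`.

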