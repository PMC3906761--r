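# pharmaboost

Post-marketing drug-safety signal detection that combines two independent
evidence streams: a spontaneous-report database (FAERS-style quarterly
`DRUG`/`REAC` files) and a biomedical literature corpus. The package is
aimed at pharmacovigilance researchers who want a tested, scriptable
implementation of disproportionality screening plus literature-evidence
signal boosting, and at methodologists who want to study that combination
under controlled synthetic conditions.

## What it computes

**Extraction.** Drug and reaction rows are joined on the report ID. Free-text
drug strings go through dictionary-based NER (leftmost-longest token-boundary
matching; trade names mapped to generic names; no fuzzy matching, so
misspellings yield no entity). Coded event strings are matched whole-string
against a cleaned side-effect lexicon. A report with m recognized drugs and
n recognized events contributes all m × n pairs, once per report.

**Ranking signals.** For each pair, a report-level 2×2 contingency table
(a: drug & event, b: drug only, c: event only, d: neither; N = a+b+c+d) feeds
seven ranking signals:

| signal | definition |
|---|---|
| FREQ | a |
| PRR | [a/(a+b)] / [c/(c+d)] |
| ROR | ad / bc |
| RRR | aN / ((a+b)(a+c)) |
| PhiCorr | (ad − bc) / √((a+b)(c+d)(a+c)(b+d)) |
| IC | log₂ RRR (raw; a shrinkage variant is available) |
| external | score looked up in an OffSides-like table |

PRR and ROR apply the Haldane–Anscombe +0.5 correction when any of b, c, d
is zero; undefined signals are marked and sort last.

**Boosting.** A pair that also co-occurs in the literature — in the same
sentence, or anywhere in the same abstract — has its score replaced by the
*square* of its original signal; all other pairs keep their original score.
Nothing is filtered: the output is a total ranking of every extracted pair.

**Evaluation.** Rankings are compared with 11-point interpolated average
precision against a drug-label gold standard (interpolated precision at
recall levels 0.0, 0.1, …, 1.0; AP is their mean), plus set-level
precision/recall/F1, fold/percent changes, and curated-label
(CAUSE/TREAT/NONE) precision and novelty.

**Synthetic data.** `simulate_faers()` generates the whole input bundle —
reports with planted causal pairs, confounding by indication
(drug–indication pairs misreported as events), Poisson noise, trade-name and
dosage-decorated drug strings, a literature corpus whose sentences co-mention
causal, treatment and background pairs at different rates, lexicons, gold
standard and external scores — deterministically from one seed.

## Worked example

```r
library(pharmaboost)

cfg <- sim_config(n_drugs = 50, n_ses = 100, n_reports = 5000, seed = 42)
sim <- simulate_faers(cfg, tempfile("sim"))

reports <- read_reports(sim$paths$drug_file, sim$paths$reac_file, "tsv")
lex     <- read_lexicons(sim$paths$drug_lexicon, sim$paths$se_lexicon)
pc      <- extract_pairs(reports, lex$drug, lex$se)
pc
#> <pair_counts> 3553 distinct pairs, 50 drugs, 100 side effects, N = 4763 reports

scores <- score_all(pc, "freq")
idx    <- build_index(read_corpus(sim$paths$corpus), lex$drug, lex$se)
ev     <- evidence_for(pc$pairs, idx)
ev
#> <literature_evidence> 127 pairs at sentence level, 406 at abstract level (3553 pairs queried)

gold <- read_gold(sim$paths$gold)
set_metrics(pc$pairs, gold)                        # all extracted pairs
#> <set_metrics> P = 0.056, R = 1.000, F1 = 0.107 (tp 200, fp 3353, fn 0)
set_metrics(evidence_set(ev, "sentence"), gold)    # evidence-restricted pairs
#> <set_metrics> P = 0.646, R = 0.410, F1 = 0.502 (tp 82, fp 45, fn 118)

base    <- interpolated_pr(rank_pairs(scores), gold)
boosted <- interpolated_pr(rank_pairs(scores, ev, "sentence"), gold)
base$average_precision      # 0.546
boosted$average_precision   # 0.659
```

The numbers tell the method's story: extracted pairs alone have high recall
but 5.6% precision; restricting to pairs with same-sentence literature
evidence raises precision to 64.6%; and squaring the frequency signal of
evidence pairs lifts the 11-point AP of the full ranking from 0.546 to
0.659 without dropping a single candidate.

The same flow runs end to end via `run_pipeline()` (see
`?pipeline_config`), or from a shell through the thin CLI at
`inst/cli/pharmaboost.R` (`simulate`, `convert`, `validate`, `ner`,
`extract`, `run`, … — exit codes 0/2/3/4 for success / validation /
format / internal-consistency errors).

## Package layout

- `R/` — IO (`read_reports`, `read_lexicons`, `read_corpus`, pair-list
  readers/writers), NER (`recognize_drugs`, `recognize_ses`,
  `ner_accuracy`), extraction (`extract_pairs`, `contingency`), signals
  (`freq`, `prr`, `rrr`, `ror`, `phi_corr`, `ic`, `score_all`), literature
  evidence (`build_index`, `evidence_for`, `evidence_set`), boosting
  (`boost`, `rank_pairs`), evaluation (`set_metrics`, `interpolated_pr`,
  `precision_at_recall`, `relative_change`, `curation_metrics`), simulator
  (`sim_config`, `simulate_faers`, `expected_counts`), pipeline
  (`run_pipeline`).
- `vignettes/signal-boosting.Rmd` — model, assumptions, parameter choices,
  numerical decisions and known limitations.
- `tests/testthat/` — unit, property and end-to-end tests with independent
  brute-force oracles.
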