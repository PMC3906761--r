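---
title: "Literature-boosted signal detection from spontaneous reports: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Literature-boosted signal detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmaboost)
```

## The problem

Spontaneous-reporting systems collect suspected adverse-event reports, each
listing the drugs a patient took and the coded events they experienced.
Joining the two sides of a report produces drug–side-effect (drug–SE)
candidate pairs, but the m × n expansion (m drugs × n events per report)
makes most candidates spurious: true causal pairs sit alongside
co-medication artifacts, the patient's underlying disease, and — most
systematically — *confounding by indication*, where the disease a drug
treats is itself recorded as an event.

The approach implemented here leans on an independent evidence stream: if a
drug and an event co-occur in the biomedical literature, some semantic
relationship between them probably exists (causal, therapeutic, or other);
if the pair is additionally reported often in an adverse-event database, the
causal reading becomes more likely. Concretely, every extracted pair gets a
base ranking signal from the report database, and pairs that also co-occur
in the literature have that signal **squared**. Pairs never get filtered
out, so recall is preserved; the boost only reorders.

## Extraction model

`read_reports()` outer-joins drug rows and reaction rows on the report ID:
a report may occur in only one file. Drug strings are free text; recognition
is dictionary-based with leftmost-longest matching on token boundaries
(tokens are alphanumeric runs of the NFC-lowercased, whitespace-collapsed
string), and trade names are replaced by their generic names. There is
deliberately no fuzzy matching: a misspelled drug string yields no entity,
mirroring how rare misspelled strings are simply ignored rather than
guessed at. Event strings are dictionary-coded terminology, so side-effect
recognition is exact whole-string matching against the cleaned lexicon —
terms curated out of the lexicon (procedures, lab tests, overly general
terms) never match, terms in it always do.

Counting is report-level: a pair counts at most once per report however
often either member is mentioned, the convention of disproportionality
analysis. The 2×2 universe N comprises only reports with at least one
recognized drug *and* one recognized event. Reports recognized on one side
only are excluded from N and from the marginals; including their marginals
would let a drug margin exceed N and drive the `d` cell negative, so
consistency of every table (`a+b+c+d = N`, all cells ≥ 0) takes precedence.
The per-run statistics record how many reports were excluded and why.

## Ranking signals

All five disproportionality statistics are standard textbook definitions on
the report-level 2×2 table; the package treats "larger = stronger" uniformly.
Raw IC is defined as log₂ RRR, which keeps the identity `ic(t) ==
log2(rrr(t))` exactly testable; a one-parameter shrinkage variant
(`log2((a+0.5)/(E+0.5))`, E the expected count under independence) is
offered for low-count stability, and is the only signal not invariant under
scaling all four cells — a documented, tested exception. PRR and ROR use the
Haldane–Anscombe +0.5-to-all-cells correction, applied only when any of b,
c, d is zero, and flag the affected pairs. A PRR with an empty drug row, a
phi with a zero marginal, and a raw IC at a = 0 are *undefined*, not
numbers: they carry an `NA` marker and sort after every defined signal
(within the undefined block, by co-report count then lexicographically), so
rankings remain total and deterministic.

## Literature evidence

The corpus is indexed per sentence with exactly the same matcher and
normalization as report-string NER, so a pair extracted from reports and a
pair found in text can never disagree by tokenization. Sentence-level
evidence means both terms in one sentence; abstract-level means both terms
anywhere in one document; sentence evidence therefore implies abstract
evidence, an invariant asserted in the tests.

Plain co-occurrence is known to over-count: in "baclofen decreased activity
during a 30-min period", the string "decreased activity" is a verb phrase,
not a side-effect mention. A syntactic filter is out of scope here;
instead, `evidence_for()` accepts a pluggable `sentence_filter(text, drug,
se)` hook through which a parser-based (or any other) filter can be
attached. The default counts every co-occurrence sentence, and that
limitation should be kept in mind when reading sentence-level counts.
Matching of multi-word side-effect terms is contiguous and exact — no gap
or inflection tolerance — so "subacute rashes" is not evidence for "acute
rash"; plural or inflected mentions in real text will be missed, a known
divergence risk on real corpora. Greedy leftmost-longest matching can also
miss a term that overlaps a longer match earlier in the sentence; with
non-overlapping vocabularies (as generated here) the behavior is exact.

## Boosting and ties

Boosting squares the base signal of evidence pairs and leaves the rest
unchanged. For signals below 1 (possible for the ratio statistics) squaring
*demotes* — arguably not the intent of "boosting", but it is what the rule
says, so the package implements it literally, emits a warning when it
happens, and offers an explicitly non-default `boost_floor` mode (squares
`max(value, 1)`) for sensitivity analysis. Note that when all pairs carry
the same method's score and scores are ≥ 1, squaring scores and boosting
rank positions are equivalent; score-squaring is implemented.

Ties break by boosted value, then co-report count, then drug, then
side-effect term, so every ranking — and therefore every evaluation metric —
is reproducible to the byte.

## Evaluation

The 11-point interpolated precision–recall curve takes, at each recall
level r ∈ {0.0, 0.1, …, 1.0}, the maximum precision at any rank whose
recall is ≥ r; average precision is the arithmetic mean of the 11 values.
The default recall denominator is the *reachable* gold — gold pairs present
anywhere in the ranked candidate list — because the gold standard (drug
labels) is used to compare ranking methods on a common universe, not to
estimate absolute recall; a `"full"` denominator is available, in which
levels above the maximum attainable recall score precision 0. A gold
standard disjoint from the candidates gives an undefined (`NA`) curve
rather than an arbitrary number.

`curation_metrics()` covers the second evaluation mode: a manually curated
three-way partition of a candidate subset into CAUSE / TREAT / NONE, with
precision = CAUSE fraction and novelty = the fraction of CAUSE pairs absent
from the gold standard.

## The synthetic generator

`simulate_faers()` exists so every stage — and the boosting benefit — is
testable without multi-gigabyte downloads. Its structure is the minimal one
reproducing the regime the method assumes:

* each drug has `k_causal = 4` causal side effects and `k_indic = 2`
  indications (disjoint); causal pairs are the gold standard, indication
  pairs are the planted confounding;
* a report draws `1 + Poisson(0.4)` drugs (mean 1.4, modest polypharmacy);
  each taken drug reports each causal side effect with probability 0.3 and
  each indication with probability 0.15, plus `Poisson(1)` uniform noise
  events; some reports end up with no events, exercising the outer join;
* drug mentions are written as trade names 30% of the time and decorated
  with dosage tokens, exercising NER; event terms are written verbatim,
  matching coded-terminology behavior;
* drugs are drawn with Zipf(1) popularity weights. This is the
  heavy-tailed shape of real report volumes and it matters structurally:
  under uniform exposure all causal pairs have nearly identical counts and
  the frequency ranking is already near-perfect, leaving boosting nothing
  to improve; under heavy-tailed exposure, causal pairs of rarely-reported
  drugs interleave with confounded pairs of popular drugs, which is
  precisely the ambiguity literature evidence can resolve (a `"uniform"`
  mode is kept, and is the setting in which the closed forms of
  `expected_counts()` are exact);
* literature sentences are templated text containing the pair plus
  distractor sentences and token-boundary traps ("subacute rashes …" for
  the term "acute rash"); causal, treatment and background pairs receive a
  sentence with probability 0.4 / 0.3 / 0.002; sentences are shuffled into
  2–5-sentence documents, which creates abstract-level-only evidence
  naturally.

Each generation stage derives its own RNG substream from the single seed,
so enlarging the report set does not perturb the corpus, and identical
configs give byte-identical files.

What passing tests on this generator do **not** show: real FAERS duplicate
reports, drug-role structure (suspect vs concomitant), MedDRA hierarchy
effects, temporal dynamics, real linguistic variety (inflection, negation,
syntax), or realistic gold-standard incompleteness. The generator's job is
to make the *mechanics* and the *qualitative ordering claims* testable, not
to calibrate absolute performance numbers.

## Problem sizes and numerical choices

The default simulation is 200 drugs × 400 side-effect terms × 50,000
reports, which runs the full pipeline in a few seconds on one CPU and
yields ≈ 40,000 distinct extracted pairs — large enough for stable
average-precision comparisons (the boosted-vs-base AP gap is ≈ 0.1–0.15
across seeds, far above seed noise). Unit and property tests use 15–60
drugs and hundreds of reports; oracle cross-checks (naive per-report
recount, exhaustive 11-point enumeration, brute-force sentence scans) run
at sizes where exhaustive computation is feasible.

Floating-point policy: recall-level membership uses a 1e-12 tolerance;
report output rounds precision/recall/F1 to 3 decimals, fold changes to 1
decimal and percent changes to integers, matching conventional reporting
precision; internal values are never rounded.

## Known limitations

* Sentence-level evidence over-counts non-causal syntactic patterns unless
  a filter hook is supplied (see above).
* Exact-token matching misses inflected side-effect mentions in real text.
* Squaring sub-unit ratio signals demotes them; use `boost_floor` to probe
  sensitivity.
* Report-level counting and the both-sides universe definition are
  conventions; databases with heavy one-sided reporting will see a smaller
  N than their raw report count.
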