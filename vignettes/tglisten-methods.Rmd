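---
title: "Methods: rule-based infoveillance for hypertriglyceridemia consultations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based infoveillance for hypertriglyceridemia consultations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

`tglisten` implements a descriptive surveillance procedure over online
consultation posts about hypertriglyceridemia: keyword retrieval, rule-based
exclusion filtering, attribute extraction, severity/demand classification,
and frequency aggregation. There is no statistical inference anywhere in the
pipeline — every output is a count, a percentage, or a ratio — so the
package's correctness argument rests entirely on oracles: brute-force
recounts for every aggregation, and a synthetic corpus generator whose
ground truth the extraction stage must reproduce exactly.

The pipeline assumes one post = one patient consultation. Attributes
extracted from a proxy consultation ("my father...") describe the *patient*,
not the poster. Posts are independent; nothing links multiple posts by the
same person (a stated limitation of this kind of data — platform users are
pseudonymous).

## Text normalization and matching

All matching operates on a canonical text form: case-folded, full-width
ASCII mapped to half-width, whitespace collapsed. Matching is substring
containment, uniformly — Chinese has no word boundaries, so a tokenizer
would be unfaithful to how keyword search actually behaves on these
platforms, and the same rule is applied to the English lexicon for
consistency. The cost is occasional over-matching of short terms (the
two-letter term "tg" can occur inside other tokens); the lab-value extractor
therefore requires a non-letter before a TG term, and the keyword-frequency
report accepts a stoplist.

## Retrieval

The default strategy is fixed: three single-category clauses (I-a disease,
II-a triglyceride indicators, IV-a fibrates) and eleven pairwise AND
clauses. A pair clause is the AND of two categories, each category an OR
over its terms. Two deliberate consequences:

* category III (diet/food) never appears alone — a diet post without a
  disease or indicator term is not retrievable, by design of the strategy;
* a post mentioning only a IV-b (non-fibrate) drug and "blood lipid" is not
  retrievable either, because no clause combines IV-b with II-b. The
  synthetic advertisement template advertises a fibrate product for exactly
  this reason: contaminant removal should be exercised by the filter stage,
  not silently absorbed by retrieval.

## Exclusion filtering

Rules fire in fixed precedence: duplicate → advertisement → popular science
→ non-topic; the first rule that fires is recorded. Deduplication runs
first so that contamination statistics are per unique post. The two
content rules share one concept, *patient-condition evidence*: an extracted
TG value, a symptom term, or a first/third-person illness pattern
("my/his/her ... is/has/took", "my ... level/value", "i have/had/am/feel").
An advertisement is a promotion marker *without* evidence; a
popular-science post is definitional phrasing ("... are a type of",
"refers to", "popular science:") *without* evidence. The non-topic rule is
numeric: at least one TG value extracted and *all* values < 1.7 mmol/L.
Posts with no extractable value are never non-topic — absence of a lab
value is not evidence of normality.

The original cleaning used trained transformer models; those are replaced
here by the deterministic rules above plus an optional character-trigram
naive Bayes classifier (additive smoothing, ties broken by label order)
that is only ever *compared* against the rule verdicts. This is a
deliberate trade: desk-scale verifiability over model fidelity.

## Extraction

* **Gender/proxy**: relational cues ("my father", "my wife", ...) take
  precedence over direct self-descriptions, because a proxy post describes
  the patient. The relation table (father/husband/brother/son → male,
  mother/wife/sister/daughter → female, parent/spouse/relative → unknown)
  is this package's enumeration; the source procedure gives only the
  "my father → male" example. The earliest relational cue wins when several
  occur.
* **Age**: direct patterns give exact years; indirect band phrases ("in my
  twenties") map to band midpoints via a bundled table (also this package's
  invention — the original "indirect method" is unspecified). With multiple
  direct matches the first is used.
* **TG values**: numbers following a TG term within 60 characters and the
  same sentence; `mg/dL` divided by 88.57 (the standard TG conversion);
  unitless numbers accepted only in [0.1, 100] and assumed mmol/L. Numbers
  denoting ages, gestation weeks or percentages are skipped. All values are
  retained; severity uses the maximum — dates are not parsed, and the
  maximum is the conservative choice for severity.
* **Response word count** is whitespace tokens for English and characters
  for Chinese, because published mean word counts for such corpora are
  character counts; this is a documented convention, not an acceptance
  quantity.

## Classification

Severity bands are left-closed on the maximal TG value: edge [1.7, 2.3),
mild-to-moderate [2.3, 5.6), severe ≥ 5.6 mmol/L. The band *names* come
from the source tables; the numeric cut-points are this package's design
decision, following the Chinese adult dyslipidemia guideline bands those
names refer to, and are configurable. Values below 1.7 raise an error —
they should have been filtered as non-topic, and silently classifying them
would hide a pipeline bug.

The demand taxonomy has 10 labels in priority order; each label carries a
phrase list seeded from the published glosses ("how to treat", "what
drug", ...). A post's demand is the highest-priority matching label — one
primary demand per post. The source tables report demand counts without
stating whether posts could be multi-label; the single-label choice is
deterministic and may undercount relative to a multi-label reading. The
four groups collapse the perception/cognition/recognition wording variants
into one `disease_cognition` group, giving a 1/2/4/3 split of the 10 labels.

## Reporting and rounding

Percentages round **half-up** (not banker's), matching how the printed
tables round; `percent()` exposes this directly. Exclusive-category tables
close to 100 ± 0.2 (rounding slack). In the severity distribution the
pregnant rows are *subsets* of the two main cohorts, not additive — the
printed totals only add up under that reading. Unknown-age records are
excluded from age-stratified tables (denominator = known-age records; the
original denominator convention is unstated). Response rates divide
responses by queries within platform type, rounded to 2 decimals.

The consistency harness re-derives every printed percentage and marginal
total from its raw counts. Two printed values are internally inconsistent
and are flagged `expect_pass: false` in the bundled file: a cohort share
printed as 16.7% whose counts give 26.7%, and a lifestyle row printed as
32.8% whose counts give 32.88% (32.9 under half-up). The harness
demonstrates they fail while all other printed values verify; treating them
as passing would require tuning the arithmetic to the typo.

## The synthetic generator: what a green test establishes

The generator is a stated world, not a dial. Defaults are the published
marginals: platform mix 0.53 Q&A, 43% female, proxy rates 0.276/0.208,
pregnancy 0.158 among females, severity mix 0.193/0.523/0.284, cholesterol
co-elevation 0.267, the demand mix proportional to the published volumes,
drug/lifestyle/factor mention rates from the published denominators,
response-count Poisson means 1.34/1.88, per-severity medication
recommendation rates 0.662/0.778/0.881, and response-suggestion rates from
the published frequencies. Where the source is silent, values were fixed
once: the age mixture (0.05/0.87/0.08 across ≤20/21–60/>60, consistent with
"21–60 over 85%"), a rising-then-falling year weight curve peaking in 2017,
a symptom mention rate of 0.127 with the published head/chest ordering,
TG values uniform on a 0.1-grid within each severity band, 15% two-value
posts, 10% mg/dL posts, 10% indirect-age posts. Contaminants are generated
*in addition to* `n_posts` (rates are per-clean-post binomial expectations),
keeping the clean cohort size exact for recovery arithmetic.

Clean query texts are slot-filled sentence templates, one family per
demand label, with vocabulary chosen to be disjoint across attributes.
This guarantees the oracle relationship: on clean corpora, extraction
reproduces ground truth *exactly*, and the tests assert accuracy 1.0, not
"high". The flip side must be stated plainly: a green extraction test
establishes that the extractors invert the template grammar, not that they
would perform at any particular level on real free-text Chinese posts.
Real posts paraphrase, negate, misspell and mix topics; none of that
variation is modeled. What the synthetic corpus does establish is the
correctness of the pipeline's logic — precedence, thresholds, unit
conversion, joins, aggregation arithmetic — under a distribution with the
right published marginals.

Only the English template family is implemented; `template_language = "zh"`
errors. The Chinese lexicon is bundled and loads through the same
normalization path, so Chinese *matching* is supported; Chinese *generation*
is not.

## Degenerate inputs and numerical choices

Empty corpora produce zero-row (or all-zero) tables rather than errors;
empty response texts get word count 0 and empty suggestion sets;
`percent()` refuses a zero denominator; platform types with no queries are
omitted from response rates with a warning; orphan responses (no matching
record) are an error listing the offending ids. Determinism is end-to-end:
generation runs under an isolated RNG seed (the session RNG stream is left
untouched), serialization is canonical (fixed key order), and identical
seeds yield byte-identical corpus files and reports — asserted by checksum
in the acceptance suite.

## Known limitations

* Substring matching over-matches short terms in adversarial text; the
  vocabularies are curated to avoid this within the package's own corpus.
* The relation table, indirect-age map, demand phrase lists and marker
  lists are English-first enumerations; applying the pipeline to real
  Chinese text requires extending the bundled `zh` lexicon with the
  corresponding rule vocabularies.
* Demographics are generated independently of platform type and year (no
  published cross-tabulations exist to emulate), so cross-strata recovery
  tests only check closure, not dependence.
* The stand-in classifier is a comparison tool, not a cleaning model; no
  claim is made about transformer-level performance.
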