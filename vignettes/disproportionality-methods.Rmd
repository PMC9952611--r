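---
title: "Disproportionality signal detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS collect
voluntary and mandatory reports of suspected drug--adverse-event
associations. They have no denominator: we observe how often a drug and
an event are *reported together*, never how often the drug was used.
Disproportionality analysis works around this by asking whether a
drug--event combination is reported *more often than expected* given the
drug's overall reporting volume and the event's overall frequency in
the database. The unit of counting throughout this package is the
drug--event **pair** (one report naming three drugs and two events
contributes six pairs), which is how large published FAERS screens
count, and the central data structure is the 2x2 pair-level contingency
table:

|                | target event | other events |
|----------------|--------------|--------------|
| target drug    | a            | b            |
| comparators    | c            | d            |

The comparator universe is configurable: all other drugs in the
database, or a restricted list (e.g. the other drugs of the same ATC
class), which asks a sharper question -- is this drug unusual *within its
class*?

## The three indices

`dispro()` computes three standard indices on a table, at full
precision (display rounding, half away from zero to 2 decimals, happens
only in print methods and exported tables):

* **PRR** (proportional reporting ratio): `[a/(a+b)] / [c/(c+d)]`, the
  event's share of the target drug's pairs relative to its share of
  comparator pairs.
* **ROR** (reporting odds ratio): `(a/b)/(c/d)` with a Wald interval on
  the log scale, `SE = sqrt(1/a + 1/b + 1/c + 1/d)`. The interval is
  multiplicatively symmetric about the estimate.
* **IC** (information component of the Bayesian confidence propagation
  neural network): `log2` of the observed-to-expected joint reporting
  probability under a shrinkage posterior. We pin the closed-form
  variant with `Beta(1,1)` marginal priors and the dependence-balancing
  constant `gamma = (N+2)^2 / ((a+b+1)(a+c+1))`, which makes `E(IC)`
  exactly zero under independence and keeps the statistic defined even
  at `a = 0`. The 95% lower credibility bound is
  `IC025 = E(IC) - 1.96 sqrt(V(IC))`. Published screens rarely state
  which BCPNN variant they used; this one reproduces the reference
  values we can verify from printed cells, and we deliberately do not
  chase printed IC bounds that no standard closed form reproduces
  (several such values exist in the bundled reference tables -- we treat
  them as artifacts of the original software and exclude them from our
  checks, asserting sign consistency instead).

The **chi-square with Yates continuity correction**,
`N(|ad-bc| - N/2)^2 / [(a+b)(c+d)(a+c)(b+d)]`, clamped at zero when the
correction overshoots, supports the signal rules. The test suite checks
it against the independent cell-wise `(|O-E|-0.5)^2/E` computation and
against `stats::chisq.test()`.

**Signal criteria** (`evaluate_signals()`): PRR signal when `a >= 3`,
`PRR >= 2` and `chi2 >= 4`; ROR signal when additionally the lower 95%
confidence limit exceeds 1; IC signal when `IC025 > 0`; and a
combination is a *signal* when any of the three fires. Zero cells make
PRR/ROR/chi-square undefined; we return `NA` markers rather than
applying a Haldane-type continuity correction, because the `a >= 3`
frequency rule makes corrected zero-cell estimates irrelevant for
signal status anyway.

## ETL: dialects, versions, exclusions

Quarterly extracts come in two "$"-delimited dialects: the legacy
(pre-2012Q3) schema keys reports by `ISR`/`CASE` (and codes sex as
`GNDR_COD`), the current one by `primaryid`/`caseid`. `parse_quarter()`
is header-driven and case-insensitive, so the difference is invisible
downstream. Malformed rows (wrong field count, missing report id, blank
preferred term, unknown role or outcome code) are routed to a rejects
table, never silently dropped: reject count plus record count equals
the input row count by construction.

Cleaning (`clean_cases()`) applies the standard cascade:

1. **Latest case version**: greatest (quarter, report id) per case id;
   ties within a quarter break by larger numeric id, since ids increase
   over time. Everything else is tallied as superseded.
2. **Deletion list**: an optional plain-text list of case ids flagged
   as erroneous by the database provider; absent list, no-op.
3. **Missing mandatory content**: reports with no valid reaction row or
   no usable (named, non-concomitant) drug row are removed.
4. **Concomitant drugs**: concomitant rows are dropped from surviving
   reports; *interacting* drugs are retained, since only concomitant
   medication is considered background noise.

Ages standardize to years with calendar constants (DEC x10, MON /12,
WK /52.1775, DY /365.25, HR /8766); a missing unit with a value present
is read as years (the dominant convention), and results outside
[0, 150] become missing and are counted. Age groups floor fractional
ages before binning (`18.9 -> <=18`), a choice the source conventions
leave open; bins are `<=18`, `19-64`, `>=65`.

Drug-name standardization is deliberately conservative: exact
dictionary lookup after lowercasing, whitespace collapse and stripping
of trailing dosage tokens ("Zosyn 4.5 g" matches "zosyn"). No substring
or fuzzy matching -- false merges are worse than missed synonyms in a
screen whose denominators are millions of pairs. The packaged
dictionary covers twelve penicillin-class drugs with best-effort
brand/generic synonyms and is an editable YAML resource. Each
electrolyte disorder is queried by exactly two MedDRA preferred terms
(the disorder term and its laboratory counterpart), and each laboratory
"increased/decreased" term belongs to exactly one disorder.

Duplicate *pairs* within one report are collapsed; whether published
screens did the same is unknowable from printed counts, and the choice
cannot affect fixture-level results, which enter as cell counts.

## The synthetic generator

`generate_quarter()` exists because spontaneous-report corpora are too
large and too encumbered to ship: every downstream stage is validated
on synthetic quarters with *planted*, exactly known association
structure. The sampling model is deliberately simple: each report draws
its drugs (weighted, without replacement, via Gumbel-top-k), then its
events with odds multiplied by the maximum over its drugs of a relative
reporting ratio `lambda(drug, event)`; `lambda = 1` everywhere is
exact independence. On top sit the ETL hazards the cleaning stage must
survive: follow-up case versions (higher report id, perturbed age),
concomitant role codes, missing age/sex, and heterogeneous age units.
One random stream, seeded once -- the output is byte-identical for a
given config.

The generator's defaults describe a modest but realistic reporting mix
(eight drugs, eight events, 1-3 drugs and events per report, 5%
follow-up versions, 15% concomitant rows, ~10% missing demographics,
80% of ages reported in years). With one drug and one event per
report, pair-inclusion probabilities have a closed form, which the
tests use as an independent oracle: realized counts must sit within 3
binomial standard deviations of expectation under independence, and
over 200 replicates with `lambda = 3` planted on one pair, the
pipeline's ROR interval covers the population ROR at the nominal 95%
rate. What the generator does **not** emulate: real reporting dynamics
(launch-peaked reporting over time, i.e. the Weber effect),
drug-name misspellings beyond case/whitespace jitter, correlated
event co-reporting, or cross-case duplicates with distinct ids -- so
green tests certify the *machinery*, not robustness to every
real-world pathology.

## Risk-factor stage

For a detected signal, `risk_factor_table()` compares reports with and
without the event among reports that carry both sex and age:
closed-form 2x2 odds ratios against a reference level (male; age
`<=18`) and a mutually adjusted logistic regression with all terms
entered simultaneously (no stepwise selection), fitted by IRLS via
`stats::glm` with a tightened convergence tolerance (`1e-12`, 50
iterations max) so that the single-binary-covariate fit agrees with the
closed form to well below `1e-6` -- an algebraic identity the tests use
as a cross-module oracle. Separation is detected (diverging coefficient
with fitted probabilities at 0/1) and flagged, not silently returned.
Intervals are Wald on the log scale, matching the convention of the
commercial statistics packages used in the published analyses this
mirrors.

Goodness of fit uses the Hosmer--Lemeshow statistic over `g = 10` groups
formed by quantiles of fitted risk, ties kept in one group (assigned
low), statistic `sum (O-E)^2 / (n_k pbar_k (1-pbar_k))` on `g - 2`
degrees of freedom. Published analyses rarely state their grouping
rule; quantile-with-ties-down is the common software default. Under a
correctly specified model the test holds its nominal 5% size (checked
over 400 simulation replicates at n = 50,000) and rejects a grossly
curved truth fitted linearly with power above 0.9.

## Bundled reference tables

Three published pair-level screens -- piperacillin/tazobactam across ten
electrolyte disorders versus all other drugs, and hypokalemia for
twelve penicillins both within-class and versus all drugs (FAERS
2004--2018; pair denominators 64.6 million and 204,403) -- ship as plain
TSV cell counts, plus the sex/age marginal counts of the corresponding
hypokalemia risk-factor analysis. They let the full statistical layer
run and be verified without any report-level data. A handful of printed
statistics in those sources are inconsistent with their own printed
cells (e.g. a confidence bound narrower than its point estimate
implies); the test suite asserts every internally consistent value at
2 decimals and skips the evident misprints rather than tuning formulas
to reproduce them.

## Problem sizes and numerical choices

Simulation-based tests run at sizes chosen to make their statistical
assertions sharp but stable under a fixed seed: independence and
recovery checks at 4,000-20,000 reports, the end-to-end planted-signal
screen at 50,000 reports, interval coverage over 200 generator
replicates, and Hosmer--Lemeshow size over 400 replicates. All
statistics are computed in double precision from raw counts (the
largest products, ~1e27 in the chi-square numerator, are far inside
double range); no intermediate rounding occurs anywhere, and displayed
values round half away from zero.

## Limitations

Signal detection on spontaneous reports is hypothesis-generating only:
reporting is biased, duplicated across reporters, and denominator-free,
so a disproportionality signal is not an incidence estimate and its
absence is not safety evidence. The package implements the mechanical
deduplication rules (latest version, deletion list) but not
probabilistic duplicate detection across distinct case ids, and no
multiplicity adjustment is applied across screened combinations --
matching standard practice for these indices, but worth remembering
when screening many events.
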