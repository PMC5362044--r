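---
title: "Detecting mental-state change in letters: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mental-state change in letters: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stylemark)
```

## The model

`stylemark` asks a simple question of a dated letter corpus: do letters
from two periods of a writer's life differ systematically in style? The
operational answer is predictive: represent each letter by a vector of 29
stylometric features, select the informative ones on training data only,
and test whether a classifier can assign held-out letters to the right
period more accurately than always guessing the larger period (ZeroR).
Prediction above baseline is evidence of a systematic style shift;
failure to beat the baseline (as in seasonal control comparisons) is
evidence of stylistic continuity. A separate stability analysis checks
the premise that style is homogeneous *within* each period.

The design assumes letters are independent samples of the writer's state
in their period — reasonable for political correspondence written days
apart, questionable for replies in a rapid exchange. It also assumes the
two periods differ in *style*, not in topic vocabulary; the features are
deliberately topic-blind (type counts, ratios and information measures,
never word identities).

## Features and their conventions

### Tokens and sentences

Word tokens are maximal alphanumeric runs with internal apostrophes and
hyphens ("Pitt's", "to-morrow"); punctuation is never a token and
numerals are tokens. All *type* counts are case-folded, because
eighteenth-century capitalization is erratic and case-sensitive types
would inflate richness measures; a case-preserving token stream is kept
for parsing. Sentence boundaries are `.` `!` `?` in the default *modern*
dialect; the *historical* dialect adds `;` and `:`, since period
orthography used them as sentence-final marks. The dialect is a
configuration flag (default modern) and feeds both the sentence-based
ratios (MLS, C/S, T/S) and segmentation; the historical dialect can only
increase the sentence count, never decrease it.

### Syntactic complexity (features 1–14)

Fourteen ratios over production-unit counts. A *clause* has a subject and
a finite verb; a *T-unit* is a main clause plus all attached subordinate
material; a *complex T-unit* contains a dependent clause; a *coordinate
phrase* is a phrase immediately before a coordinating conjunction; a
*complex nominal* is a word sequence denoting one concept. The parser is
external by design: the package's contribution is the validated count
container and the tree-pattern queries over Penn-bracketed trees
(`count_trees()`), documented pattern by pattern in `R/parsetree.R`.
Synthetic corpora bypass parsing entirely with ground-truth counts, so
the ratio logic is testable without any parser. Two algebraic identities,
MLS = MLC × C/S and MLT = MLC × C/T, serve as internal self-checks.

A degenerate letter (zero clauses or verb phrases) reports the affected
ratios as 0 with a warning rather than NaN, so one fragmentary letter
cannot poison a feature matrix.

### Textual measures (features 15–29)

Three of the measures — LogTTR, hapax legomena and pair-hapax legomena —
are strongly length-sensitive, so they are computed as *mean segmental*
statistics: the letter is cut into consecutive 10-word blocks, a trailing
partial block is discarded, the statistic is computed per block and
averaged. Ten words is the conventional block size and is configurable.
Letters shorter than one block are rejected rather than silently
extrapolated.

Conventions worth stating explicitly:

* **Brunet's W** is `N^(V^-0.165)`, the standard form: it decreases as
  vocabulary richness rises and lands in the 8–11 range for 60–160-word
  letters, the magnitude reported for corpora of this kind.
* **Simpson's D** uses the without-replacement denominator
  `N(N-1)`, matching its definition as the probability that two distinct
  randomly drawn tokens coincide.
* **Shannon entropy** is normalized by `log2 V`, its maximum for the
  observed vocabulary, putting H in [0, 1] (a single-type letter has
  H = 0 by convention). Raw word entropy of a 100-token letter is about
  6 bits; the normalized form is the only convention consistent with
  reported per-letter values just below 1.
* **Pair-hapax legomena** counts *adjacent* token bigrams unique within
  their block, so its maximum is 9 per 10-word block. Legacy tools that
  report PHL near 10 evidently counted pairs differently; the definition
  here is the one stated above, chosen for reproducibility.
* **Dis legomena over vocabulary** counts types occurring *exactly*
  twice (not "more than once"), the stricter of the two phrasings in
  circulation.
* **Compression ratio** is DEFLATE at zlib level 6 over the UTF-8 bytes,
  via R's `memCompress()` (verified byte-identical to `zlib.compress`
  level 6). Pinning the level and the encoding makes CR reproducible
  across platforms.

## Feature selection

Information Gain needs discrete features, so each feature is discretized
per training fold with the Fayyad–Irani recursive entropy-minimization
procedure under the MDL stopping rule — the standard companion of IG
attribute evaluation. A feature with no accepted cut falls in a single
bin, has IG exactly 0, and is excluded by the strict `IG > 0` rule; an
empty selection is legal and simply means "no feature is individually
informative". Ranking ties are broken by the canonical feature order so
results are deterministic. On shuffled labels the MDL criterion rejects
all cuts in well over 95% of trials, which is what keeps the selection
honest on null data.

Selection runs *inside* every cross-validation training fold, never on
the full corpus — the test fold never influences which features the
classifier sees.

## Classification and evaluation

Gaussian Naive Bayes is the primary classifier: class priors from
training frequencies, one Gaussian per feature and class, variances
floored at 1e-9 times the feature's overall training variance, posterior
ties resolved to the first class in sorted order. Selection bins are used
only for IG; NB sees the raw continuous values. The multilayer perceptron
alternative has one hidden layer of `ceiling((p + k)/2)` sigmoid units,
per-instance gradient descent with learning rate 0.3, momentum 0.2 and
500 epochs (the classical defaults for this architecture), features
standardized on training data, fully deterministic given its seed.

Folds are a seeded shuffle assigned round-robin, giving near-equal sizes
(52 letters split 11/11/10/10/10); stratification is deliberately not
applied, matching a protocol that randomly divides the corpus. Accuracy
is pooled micro-average accuracy over the five test folds. The baseline
reported for a corpus is the majority-class proportion; significance
against ZeroR is a two-sided paired t-test on the five per-fold accuracy
pairs (df = 4), with explicit degenerate handling (all-zero differences
give p = 1, zero-variance nonzero differences are flagged). The paired
interpretation of "per fold" is a design choice; no correction for the
dependence between CV folds is applied, so p-values near 0.05 deserve
caution.

## Stability analysis

One period's letters, date-sorted, are cut into three chronological
epochs (remainder letters go to the earliest epochs), and each of the 29
features is tested with a between-subjects one-way ANOVA. The threshold
is 0.001 — the conventional rounding of 0.05/29. Sphericity corrections
do not arise: the letters in different epochs are different documents,
not repeated measures, so the between-subjects ANOVA is the appropriate
form. A zero-variance feature has no defined F and is reported as not
significant with a `degenerate` flag.

## The synthetic corpus generator

Real letters from the study corpora are published book transcriptions
and cannot be redistributed, so the generator is a first-class module
that emulates what the analysis needs and nothing more:

* **Vocabulary**: `vocab_size` pseudo-words with Zipf(`zipf_s`)
  frequencies; each type carries a fixed coarse POS tag drawn from
  `pos_mix`. The vocabulary is a deterministic function of the
  vocabulary parameters and the corpus seed, shared between the two
  periods when their parameters agree — one writer, one vocabulary. This
  is what makes parameter-identical periods genuinely exchangeable, the
  property every null-calibration test rests on.
* **Repetitiveness**: with probability `rho` a token copies a uniform
  draw from the previous 10 tokens instead of a fresh Zipf draw. Local
  copying (rather than globally inflating top frequencies) is what makes
  repetition visible to compression, block hapax counts and Simpson's D
  simultaneously — the construct of repetitive, patterned manic text.
* **Syntax**: sentences contain Poisson(`lambda_c`) + 1 clauses; a
  non-initial clause is dependent with probability `sigma`; a clause
  contributes a coordinate phrase (and an inserted conjunction token)
  with probability `kappa`; complex nominals and verb phrases arrive at
  fixed per-clause rates. Ground-truth parse counts are accumulated from
  these construction choices.
* **Lengths** are rounded lognormal (sdlog 0.3) around the period's mean.

Default study conditions (the `comparison_preset()`s) use the six
reference class-size/mean-length pairs (21×129.1 vs 31×152.4, and so
on); healthy-period style is rho = 0.05, kappa = 0.2, sigma = 0.25, and
manic-period style rho = 0.35, kappa = 0.35, sigma = 0.18 — a repetition
contrast of Δrho = 0.3 with heavier phrase coordination, the two effect
directions reported for manic-period letters. Zipf exponent 1.05 over
2000 types and lambda_c = 4 put the simulated letters in the observed
range of the richness measures (W ≈ 8.5–10.5, LogTTR ≈ 0.9) and sentence
complexity (C/S ≈ 4–6, MLS ≈ 40–55).

What the generator does **not** emulate: real English syntax (the prose
is pronounceable nonsense), topic drift, addressee effects, scribal and
editorial artifacts, and the long-tailed length distributions of real
correspondence. Tests passing on synthetic corpora therefore validate
the *pipeline's statistical machinery* — calibration, power,
monotonicity, type-I control — not the historical claim itself.

## Numerical choices and degenerate inputs

* Entropies in bits (log base 2) everywhere; IG values below 1e-12 are
  treated as exactly 0 to keep the strict `IG > 0` rule stable under
  floating-point noise.
* NB variance floor 1e-9 × overall variance; MLP weight init uniform
  (−0.5, 0.5) under its own seed, global RNG state never touched
  (`withr::with_seed` throughout — no hidden global state anywhere).
* Zero-verb letters define VV = CVV = 0; zero-lexical-word letters are a
  hard error (such a "letter" is not analyzable text).
* Problem sizes used by the test-suite calibration experiments: 100
  letters per dial level for monotonicity, 20 seeded pipeline runs each
  for null calibration and power, 20 runs for stability type-I control —
  large enough for the monotone orderings to be stable, small enough to
  keep the whole suite comfortably interactive.

## Known limitations

* The rule/lexicon POS tagger is a deliberately simple backend; on real
  historical English its coarse tags are approximate, and any serious
  application should plug in a trained tagger via the backend function
  interface (the synthetic path sidesteps this entirely with ground-truth
  tags).
* The tree patterns implement the production-unit definitions plainly;
  genuinely ambiguous constructions (elliptical clauses, gapping) follow
  the tree as parsed, and parser errors propagate to features 1–14.
* Gaussian NB forced onto the full feature set when selection is empty —
  the standard protocol when selection is empty — systematically *loses*
  to ZeroR under class imbalance, because 29 features' worth of sampling
  noise swamps the prior. That behaviour is inherent to the protocol
  (a null comparison with a 0.81 majority baseline shows the same
  gap) and should be kept in mind when reading "classifier below
  baseline" results on null-like data.
* p-values from CV folds are anti-conservative; treat them as ranking
  evidence, not literal error rates.
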