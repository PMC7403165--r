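---
title: "Methods: mixture weights, entropy and reliability for pseudoword reading responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixture weights, entropy and reliability for pseudoword reading responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcmix)
```

## The problem

When a child reads a pseudoword such as *wact* aloud, the vowel they produce
reveals which print-to-speech regularity they relied on: the simple
grapheme-phoneme correspondence (GPC) *a* → /æ/, or a context-sensitive one
such as *[w]a* → /ɔ/ (onset context, CS_O) or *a[l][C]* → /o:/ (body context,
CS_B). A 4-condition design crosses whether each context cue agrees with the
simple correspondence, so the distribution of a reader's vowel responses
across conditions carries information about how strongly they weight each
correspondence type. `gpcmix` implements the full analysis chain for such
data: preprocessing filters, per-reader weight estimation, entropy measures
of response variability, orthographic-cluster statistics, test-retest
overlap, and a generative simulator for parameter-recovery studies.

## The mixture model

For reader $i$, condition $c$ and response category $k$, the model is

$$
P_i(k \mid c) \;=\; \sum_{j=1}^{3} \beta_{ij}\, P(k \mid \text{rule } j, c),
$$

where $P(k \mid \text{rule } j, c)$ is a language-level conditional
probability (how often rule $j$'s orthographic context yields category $k$ in
the lexicon) supplied as a `corpus_probs` table, and
$\beta_i = (\beta_{i1},\beta_{i2},\beta_{i3})$ are the reader's weights on
the three correspondence types. Two assumptions motivate constraining
$\beta_i$ to the probability simplex ($\beta_{ij} \in [0,1]$,
$\sum_j \beta_{ij} = 1$): the weights are interpreted as the probability of
relying on each correspondence on a given trial, and the three correspondence
types are assumed to exhaust the systematic sources of responses.

`fit_weights()` minimises the equally weighted sum of squared differences
between observed and predicted proportions over all (condition, modelled
category) cells. Observed proportions are computed per reader from non-error
trials (`observed_proportions()`); unmodelled-but-valid responses ("other
vowel") stay in the denominator by default, because they are real responses
the model simply does not predict. The switch `renormalize_modeled = TRUE`
restricts denominators to modelled categories for users who prefer the
alternative reading; the choice is otherwise genuinely open, so the package
makes it explicit and auditable rather than silent.

### Exact solution of the constrained problem

With three weights, the constrained problem is a convex quadratic programme
over the 2-simplex. Rather than iterate a general-purpose solver, the package
solves it exactly: every KKT point lies on a face of the simplex, so the
solver enumerates all seven faces (three vertices, three edges, the
interior), solves each face's equality-constrained least-squares problem in
closed form, discards infeasible candidates, and returns the feasible
minimiser. This is deterministic, needs no starting values or convergence
tolerance beyond the linear-algebra level, and is guaranteed globally optimal
— the test suite nevertheless verifies optimality independently against a
step-0.01 grid over the simplex and against 1,000 random simplex points.

The *relaxed* variant (`constrained = FALSE`) drops the sum-to-one constraint
and both bounds and reduces to ordinary least squares. Dropping all
constraints (rather than only the sum) is deliberate: a relaxed fit should be
free to produce negative weights, which is precisely the diagnostic signal
that a systematic predictor is missing, and it guarantees the relaxed loss
never exceeds the constrained loss.

### Identifiability and degenerate inputs

The weights are identifiable only when the three rule-type prediction
vectors, stacked across conditions and categories, are linearly independent;
`fit_weights()` reports `identifiable = FALSE` when the rank (QR, tolerance
1e-10) is below 3, and `aggregate_weights()` excludes such fits. A condition
in which a reader has no usable trials is dropped from that reader's fit;
fewer than two usable conditions is an error, because a single condition
cannot separate three weights even in the identifiable case. Percentage-scale
inputs are detected (values above 1) and rescaled, so proportions and
percentages give identical weights.

### Model fit

`model_fit_correlation()` pools, within each grade, every fitted reader's
observed and predicted percentages across conditions and modelled categories
and reports the Pearson correlation — one $r$ per grade. Zero variance in
either pooled vector yields `NA`, never a silent 0.

## Entropy measures

Response variability is quantified with Shannon entropy in bits,
$H = -\sum_i p_i \log_2 p_i$ with $0\log 0 = 0$, the plug-in estimator with
no small-sample correction. *Item-level* entropy (over readers' responses to
one pseudoword) indexes disagreement between readers; *participant-level*
entropy (over one reader's responses) indexes within-reader instability.
Trials with consonant errors or non-responses are excluded; in the binary
German-style design all incorrect trials are excluded, so entropies are
bounded by 1 bit. Each distinct transcribed vowel label is its own category —
if a data set collapses miscellaneous vowels into a single `other_vowel`
code, that code is one category; the package deliberately analyses whatever
granularity the transcription provides.

Participant-level entropies (overall plus the four conditions) together with
two reading-ability scores form a 15-correlation screening family, so the
pipeline reports the Bonferroni-adjusted threshold 0.05/15 = 0.003 alongside
those tables.

## Orthographic-cluster statistics

From a pronounced wordlist, `cluster_statistics()` reports, per cluster:
frequency (word count), consistency (share of the modal pronunciation; ties
broken lexicographically and flagged), and pronunciation entropy. Entropy is
computed both type-based and token-weighted because published cluster tables
are not always reconstructible from consistency alone (e.g. a cluster with
consistency 0.89 but entropy 0.15, where the binary type entropy would be
0.50, indicates a token-weighted or multi-category computation); providing
both makes the measure explicit. `derive_corpus_probabilities()` turns the
same wordlist into a `corpus_probs` table via user-supplied context
predicates, which is how language-level conditional probabilities are
obtained for new designs. The bundled `critical_cluster_stats()` table
carries nine reference clusters used by the worked examples; its group means
(shared vs comparison-only clusters) are pure arithmetic on the stored
values.

## Test-retest overlap

`code_overlap()` pairs the two sessions item by item over *all* trials,
codes 1 when the vowel category matches or both sessions are incorrect and 0
otherwise, and `participant_overlap()` averages per child. Overlap of a
session with itself is exactly 1, and the coding is symmetric in session
order. Two different "other vowel" transcriptions count as the same response
only if their labels are identical — the package compares labels as given,
since transcription granularity is a property of the input.

## The simulator

`simulate_study()` generates trial tables under the mechanism the analyses
presuppose: each simulated reader activates a candidate set of
pronunciations — on each trial a rule type is sampled from the reader's
weight vector, then a response from that rule's conditional distribution —
and a *lapse* process replaces the response, with probability `lapse_rate`,
by a uniform draw over the valid categories (modelled plus "other"). This is
the simplest random-error term consistent with that mechanism. Consonant
errors are an independent Bernoulli process (`consonant_error_rate`). Any
residual probability mass in an English-style `corpus_probs` row becomes an
"other vowel" response, so unmodelled responses arise organically.

Defaults are fixed at the study conditions the package emulates: grades 2–4
with 21/20/20 readers, 18 items per condition, consonant-error rate 0.10, and
grade-level weight vectors (0.24, 0.63, 0.13), (0.07, 0.79, 0.14),
(0.23, 0.63, 0.14) for the simple, onset-context and body-context
correspondences. The bundled probability tables are synthetic fixtures —
plausible values with full-rank rule-prediction matrices — because real
corpus-derived conditional probabilities are external inputs, not something
the package can reconstruct. Optional Dirichlet perturbation
(`dirichlet_concentration`) adds individual differences around the grade
weights; it is off by default so recovery checks are exact. Randomness uses
one root seed with per-participant streams derived deterministically, so
enlarging one grade never perturbs other grades' trials.

### What the simulator does and does not emulate

It reproduces the statistical structure the estimators assume: mixture
responding, unsystematic lapses, consonant errors, independent sessions. It
does **not** emulate item-level idiosyncrasy (all items in a condition share
one conditional distribution), lexical-neighbour interference, learning
across sessions, or transcription ambiguity. Passing recovery tests on
synthetic data therefore shows the estimators are correct under the model,
not that the model describes real children; on real data, systematic
mis-specification would surface as the kind of depressed model-fit
correlations the entropy analyses are designed to interrogate.

## Verification at scale

Parameter recovery is checked on a cohort of 100 simulated readers with 50
items per condition: at lapse 0 the across-reader mean weights recover the
generating grade-level weights with mean absolute error well under 0.02.
(Per-reader estimates carry irreducible multinomial noise of roughly 0.05 at
200 trials, so recovery is assessed at the aggregate level, which is also the
level at which weights are reported.) Over a lapse grid {0, 0.1, 0.2, 0.3},
averaged across seeds, the pooled model-fit correlation decreases strictly
and mean item entropy increases strictly — noisy responders degrade the
mixture fit and inflate entropy — and expected two-session overlap decreases
strictly in the lapse rate. These cohort sizes keep the full verification
suite to a couple of minutes while leaving Monte-Carlo error far below the
effects being detected.

## Known limitations

- Corpus conditional probabilities are inputs; the package validates but
  cannot audit them against a lexicon unless one is supplied.
- The plug-in entropy estimator is biased downward at small trial counts;
  comparisons across groups with very different trial counts should use
  equal-sized subsamples or treat small-n entropies with caution.
- The constrained estimator is mildly biased away from the simplex boundary
  when true weights are near 0 or 1 (truncation), visible as a small upward
  bias for near-zero weights at modest trial counts.
- With four conditions and three rule types the design is close to minimal;
  designs whose rule-prediction vectors are nearly collinear will fit but
  with unstable weights, which the `identifiable` flag only catches at exact
  rank deficiency.
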