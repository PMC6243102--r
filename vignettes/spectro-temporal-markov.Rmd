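---
title: "Variable-order Markov analysis of improvised melodies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variable-order Markov analysis of improvised melodies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(improvtp)
```

## The question and the model

Improvising musicians produce melody faster than deliberate reasoning allows;
what they produce is therefore shaped by implicitly learned statistics of
sequences. `improvtp` operationalises "depth of implicit knowledge" as the
order *n* of a Markov model: the transition probability (TP) of the next
element given the preceding *n* elements. A low-order model captures
shallow, easily shared regularities; only a high-order model can expose
long signature patterns specific to one performer. The package computes,
for every piece of a corpus, maximum-likelihood TP tables at orders 1–6 for
four relative encodings of the skyline melody, converts them to information
content and conditional entropy, and compares musicians with PCA, mixed
ANOVA and chronological stepwise regressions.

### Skyline reduction

Every analysis starts from the monophonic line of highest pitches: grace
notes are removed, a slurred group counts as one event (its first note), and
at each distinct onset only the highest pitch *attacked* at that onset
survives. The attack-based rule is a deliberate design choice for the
overlap case the informal "highest pitch playable at a time" description
leaves open: a held lower note never suppresses a new higher attack, and a
new lower attack under a held higher note is kept. It is deterministic,
matches common skyline practice, and makes the reduction idempotent. After
reduction only onsets are used; durations and rests carry no further
information, which is consistent with an onset-based notion of rhythm.

### The four relative encodings

Windows are overlapping (stride 1) runs of consecutive events. All
encodings are *relative*, so transposition and (except for one documented
case) tempo cancel exactly:

| type | window extent | tokens |
|---|---|---|
| `pitch` | n+1 notes | semitone offsets from the window's first pitch (first token 0) |
| `rhythm` | n+2 notes (n+1 IOIs) | IOIs divided by the window's first IOI (first token 1) |
| `pitch_rhythm` | n+1 notes | pitch tokens as above, plus the window's n IOIs |
| `rhythm_pitch` | n+2 notes | IOI-ratio tokens as above, plus all n+2 pitch tokens |

Two conventions deserve comment. First, at order 1 a `pitch_rhythm` window
contains a single IOI, which has no in-window reference; it is expressed as
a ratio to the crotchet (quarter note = 1 beat). This is the one place tempo
does not cancel, and it is why onsets are kept in beats, never seconds — a
tempo change then only rescales this one token type, and metrical input
leaves it unchanged. The rhythm-led joint stream (`rhythm_pitch`) always has
at least two IOIs per window and uses the self-ratio convention at every
order; its printed first-order patterns (`[1, 1] with …`) show the first
token pinned at 1, so no crotchet convention is needed or used there.
Second, rhythm ratios are rounded to **3 decimals before tokenisation**, so
1/3 and 2/6 collide into the token `0.333` by construction; rounding after
division is what makes the collision intentional rather than accidental.

### Estimation, information, entropy

TPs are pure relative frequencies per context — no smoothing. Unobserved
patterns are structural zeros: they never inflate observed probabilities,
and they enter downstream stages explicitly (0 in aligned matrices,
`logit_tp(0)` in the ANOVA). Musician-level tables are means of per-piece
*probabilities* over the union vocabulary (absent = 0), not pooled counts,
so each piece contributes equally regardless of length; such a mean is not
itself a probability table and per-context sums need not be 1.

Information content is −log₂(tp) bits. Conditional entropy is the plug-in
double sum with the context marginal taken as the empirical window
frequency; equivalently (and this identity is tested to 1e-9) the
count-weighted mean information content of the observed windows. Entropy is
computed per piece, because the chronological regressions operate on
per-piece values. No bias correction (Miller–Madow or similar) is applied:
the plug-in form is the quantity of interest, and the validation suite
quantifies its convergence directly.

## Corpus-level statistics

### PCA orientation

The TP matrix has pieces as rows and the lexicographically sorted union
vocabulary as columns. The decomposition is of the **correlation matrix
among pieces**, computed across patterns, so pieces are the standardized
entities: eigenvalues sum to the number of pieces, retention uses the
eigenvalue > 1 rule, and each piece receives a loading (eigenvector scaled
by the square root of its eigenvalue) on each component. This orientation
is what makes the two diagnostic readings possible: a first component on
which all pieces load highly with one sign is a corpus-wide shared style,
and musician separation in the component-1/2 plane is individuality. The
alternative orientation (patterns as standardized variables) was rejected
because with thousands of sparse pattern columns the eigenvalue > 1 rule
loses meaning and pieces no longer receive loadings at all. Components are
sign-oriented so the majority of loadings is non-negative, which makes runs
reproducible; a constant piece profile (possible only in degenerate corpora)
is reported as an error naming the piece.

### Mixed ANOVA

The dependent variables are logit-transformed TPs (clamped at
`eps = 1e-6`, so a structural zero maps to about −13.8 rather than −∞) of
the union of all musicians' top-5 mean-TP patterns, evaluated on every
piece; the union is what makes the design fully crossed. The model is the
classical split-plot: musician between subjects, pattern within, pieces as
subjects, fitted via a multivariate linear model with sum-to-zero contrasts
(treatment contrasts would distort the type-3 within-subject tests).
Sphericity is checked with Mauchly's test; when it fails at p < .05 the
within-effect degrees of freedom are Greenhouse–Geisser corrected — the
fractional-df convention. Effect size is partial η² = SS_effect /
(SS_effect + SS_error). Post-hoc comparisons are pairwise t tests,
Bonferroni-corrected within each family (musicians overall, musicians
within pattern, patterns within musician). A fully constant input returns
F = 0, p = 1 by convention instead of 0/0.

### Stepwise chronological regression

The response is the musician's chronological ordering 1…K (ordinal, but
treated as the numeric regressand, matching the reporting convention of
"predicted chronological order = a + b·TP"); candidates are the top-5
pattern TPs per piece, or the per-piece entropies across orders. Selection
is bidirectional and p-value-based: entry at p ≤ .05, removal at p > .10 —
the common defaults — with two collinearity gates recomputed at every step:
every VIF must stay below 2 and the condition index of the scaled,
intercept-included design matrix below 20. The intercept-included
convention matters: a predictor that barely varies relative to its mean is
nearly collinear with the intercept and is refused entry, which in practice
suppresses most spurious entries among low-variance TP predictors. An empty
model ("no significant regression equation") is a first-class result. Ties
in entry p-values are broken lexicographically on the predictor name, so
selection is order-invariant.

The operating characteristics of this procedure under the package's study
conditions are recomputed by `scripts/acceptance.R`: a single transition
whose probability drifts linearly from 0.20 to 0.47 across seven pieces of
600 notes is recovered with the correct sign in roughly nine out of ten
seeded replicates, while with no drift a non-empty model appears in roughly
one replicate in ten. The null rate is worth a remark: with five candidates
and plain p ≤ .05 entry one would expect about 23% spurious non-empty
models; the condition-index gate prunes near-constant TP candidates to
about 2–3 effective tests, which is what brings the observed rate down to
the vicinity of 10%. Users who need a strictly conservative null should
lower `p_enter` rather than rely on the gates.

## The synthetic-data generator

`musician_spec()` defines a musician as (i) an order-g Markov chain over a
small alphabet of pitch-interval tokens, (ii) an i.i.d. distribution over
IOI tokens on common metrical subdivisions (thirds stored exactly as 1/3 and
2/3 so ratio tokens collide as intended), and (iii) decorations: chords
added below melody notes, flagged grace notes inserted just before them,
per-piece transposition and tempo scaling, and an optional linear
chronological drift of named transitions (the context's remaining mass is
rescaled proportionally). `make_corpus()` derives per-piece RNG substreams
deterministically from the master seed and the musician/piece indices, so
corpora are reproducible and evaluation-order-independent.

The generator emulates the structure of a small jazz-trio study — three
musicians, seven chronologically ordered pieces each — with exact ground
truth: the drifted transition matrices, their stationary context
distributions and conditional entropies are available in closed form
(`spec_tp_table()`, `spec_entropy()`), and a window order of g+1 in the
encoded space corresponds exactly to interval order g conditioning. What it
deliberately does **not** emulate: harmony and voice leading, swing or
expressive timing (IOIs are i.i.d. metrical tokens, so there is no rhythmic
syntax to discover), rests, dynamics, and by-ear transcription noise.
Passing tests therefore demonstrate correctness of the *pipeline* under
known sequential statistics, not musicological claims about real recordings.

Two numerical details. Absolute pitches from a long random interval walk
would leave any playable register, so sampled pitches are octave-folded
into c(24, 108) by default; folding perturbs the handful of windows that
straddle a fold, which is harmless for 2,000-note corpus pieces but is
disabled (`fold = NULL`) in asymptotic recovery studies. The hierarchy
corpus (`hierarchy_specs()`) mixes a shared peaked baseline marginal with
musician-specific deterministic signature maps at weight 0.6 over a
six-interval alphabet: the baseline makes all order-1 TP vectors nearly
identical (one dominant shared component), while the signatures only become
conditionally visible at window order 4.

## Validation sizes and numerical choices

The test suite validates encodings against brute-force window enumeration
on 1,000 random melodies plus exact transposition/tempo invariance checks;
TP estimation against an independent dictionary-count oracle; entropy
against the explicit double sum and the mean-information identity (1e-9);
parameter recovery of an order-2 generator from a 100,000-note sequence
(max TP error < 0.02 on contexts with at least 1% mass, entropy within 0.02
bits); the hierarchy property on a 3 × 7 × 2,000-note corpus (silhouette on
PCA loadings); drift recovery over 200 seeded replicates; and the ANOVA
against hand-computed sums of squares plus a 500-replicate
label-permutation calibration of its null p-values. These sizes were chosen
so each property is measured with comfortable statistical margin while the
whole suite stays convenient to run routinely.

Deterministic conventions used throughout: vocabulary and tie-break order
is lexicographic on the serialised pattern string under C collation;
TSV artifacts serialise doubles as `%.17g` so write/read round trips are
exact; MIDI I/O works in beats (ticks over ticks-per-quarter, 960 by
default) and ignores tempo meta events by design.

## Limitations

* Only adjacent-dependency Markov structure is modelled; no back-off or
  mixture-of-orders (IDyOM-style) prediction, and no harmonic stream.
* The chronological regressions treat an ordinal rank as numeric, as is
  conventional in this analysis style; with seven observations per musician
  they are descriptive, not confirmatory.
* MLE TPs at high orders are sparse; cross-piece comparisons at order 5–6
  rest on structural zeros, which the PCA orientation tolerates but which
  make individual high-order TP values noisy.
* The package analyses symbolic input; transcription from audio, MusicXML
  ingestion and expressive-timing inference are out of scope.
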