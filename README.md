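# improvtp

Spectro-temporal transition-probability analysis of improvised melodies.

`improvtp` is an R package for quantifying the implicit statistical structure
of symbolic music corpora — in particular, for asking *where* a performer's
individuality lives: in shallow, widely shared statistics of melody, or in
deeper sequential dependencies that only higher-order models can see.

## The model

A polyphonic piece is first reduced to its **skyline melody** — the highest
pitch attacked at each moment, with grace notes dropped and slurred groups
counted once. The melody is then re-encoded *relatively*, so that key and
tempo cancel, into four sequence types: pitch intervals (each n-gram window
re-zeroed to its first pitch, semitone steps ±1), inter-onset-interval (IOI)
ratios (each window's IOIs divided by its first IOI), and the two joint
combinations of the two (serialised in the bracketed style
`[0, -1, -2] with [1, 0.5]`).

For each piece, sequence type and Markov order *n* = 1…6, the package
estimates **transition probabilities** by maximum likelihood,

P(e⁽ⁿ⁺¹⁾ | e⁽ⁿ⁾) = count(context, continuation) / count(context),

and summarises each table by **information content** I = −log₂ P (bits) and
the plug-in **conditional entropy**

H(B|A) = −Σᵢ Σⱼ P(aᵢ) P(bⱼ|aᵢ) log₂ P(bⱼ|aᵢ).

Downstream, corpora of several musicians are compared by

* **PCA** of per-piece TP vectors (pieces receive component loadings;
  eigenvalue > 1 retention) — a first component on which every piece loads
  highly is a shared style; musician separation in the component-1/2 plane is
  individuality;
* **mixed ANOVA** on logit-transformed TPs of the musicians' top-5 patterns
  (musician between, pattern within, pieces as subjects, Greenhouse–Geisser
  correction when sphericity fails, Bonferroni post-hocs, partial η²);
* **stepwise chronological regressions** (entry p ≤ .05, removal p > .10,
  VIF < 2 and condition index < 20 as collinearity gates) of each musician's
  piece ordering on pattern TPs or on conditional entropies.

A seeded **synthetic-corpus generator** (`musician_spec()`, `make_corpus()`)
with exact Markov ground truth — including chords, grace notes,
transposition, tempo variation and chronological TP drift — lets every stage
be validated end to end without any copyrighted recordings.

## Worked example

```r
library(improvtp)
library(dplyr)

# three synthetic musicians sharing shallow statistics but carrying
# musician-specific deep (order-3) interval signatures
specs <- hierarchy_specs()
corpus <- make_corpus(specs, pieces_per_musician = 7, length = 2000, seed = 11)

melody <- extract_melody(corpus$notes)

# shallow model: one shared component
pca1 <- tp_pca(align_tp_matrix(estimate_tp(encode_windows(melody, "pitch", 1))))
pca1
#> <tp_pca> 21 pieces x 11 patterns; 1 component(s) with eigenvalue > 1
#>   first two components: 99.4% + 0.2% = 99.6% of variance

# deep model: musicians separate
pca4 <- tp_pca(align_tp_matrix(estimate_tp(encode_windows(melody, "pitch", 4))))
pca4
#> <tp_pca> 21 pieces x 2569 patterns; 3 component(s) with eigenvalue > 1
#>   first two components: 22.1% + 21.7% = 43.8% of variance
autoplot(pca4)   # pieces cluster by musician in the PC1/PC2 plane

# mixed ANOVA on logit TPs of the pooled top-5 patterns
aov4 <- tp_anova(anova_data_topk(estimate_tp(encode_windows(melody, "pitch", 4))))
tidy(aov4)

# entropies and the full artifact tree
run_pipeline(corpus, pipeline_config(orders = 1:4), out_dir = "artifacts")
```

At order 1 the first component carries 99.4% of the variance and every piece
loads above .98 on it — the three generators genuinely share their shallow
pitch statistics. At order 4 the same corpus splits cleanly by musician
(mean silhouette ≈ 0.98 on the first two components), while rhythm streams,
whose generator is shared, never separate. That is the package's headline
property: individuality is carried by deep pitch structure, not by shallow
statistics or rhythm alone.

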