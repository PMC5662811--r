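# HerbTopics

Predicting the therapeutic *function* of a Traditional Chinese Medicine
(TCM) prescription — e.g. "cleaning heat" or "relieving exterior
syndrome" — from its composition is a multilabel problem: a formula is a
set of herbs with dosages, and it may serve several functions at once.
`HerbTopics` implements two complementary prediction routes over a
prescription corpus, plus the herb-pair mining that feeds the first one:

1. **Pair-aware supervised topic model.** Herb-pair compatibility rules
   are mined from prescription co-occurrence: for herbs *h<sub>i</sub>*,
   *h<sub>j</sub>*,

   - support = *p*(*h<sub>i</sub>*, *h<sub>j</sub>*)
   - dependency = *p*(*h<sub>i</sub>*, *h<sub>j</sub>*) /
     (*p*(*h<sub>i</sub>*) *p*(*h<sub>j</sub>*))
   - Cor = *a*·support + *b*·dependency (defaults *a* = *b* = 0.5),

   and the top-*N* pairs by Cor are kept (the universal harmonizer
   *Glycyrrhizae Radix* is stop-listed). A Labeled-LDA-style model —
   prescriptions are documents, herbs are words, the observed function
   labels are the only admissible topics — is then trained by collapsed
   Gibbs sampling, with one extension: when a mined pair occurs in a
   prescription, its two herbs form a single sampling unit that shares
   one function assignment, with conditional weight
   (*n<sub>k</sub><sup>h_i</sup>* + η)(*n<sub>k</sub><sup>h_j</sup>* + η)
   / (*n<sub>k</sub>* + η·V) times the usual document factor. Prediction
   thresholds the raw per-label likelihood product *p*(*k* | **H**) at a
   user-chosen *T*.

2. **Feature-based multilabel classifiers.** Dosages are standardized by
   each herb's pharmacopoeial range, *d\** = *d* / (*d*<sub>max</sub> +
   *d*<sub>min</sub>), normalized within the prescription into weights
   *F*(*h*) and combined with inverse document frequency into TFIDF
   features *F*(*h*)·log(*N*/*F*′(*h*)); the prescription's two
   highest-weight herbs additionally contribute a 134-dimensional
   attribute vector (9 nature & flavor + 12 channel tropism + 46
   efficiency slots per herb, entries 1 or 0.5 for "slightly" terms).
   One-vs-rest SVM (linear, C = 10), AdaBoost (depth-1 stumps) and naive
   Bayes classifiers are trained on the V + 134-dimensional space and
   scored by micro-averaged Precision, Recall and Micro-F1 under
   repeated 4-fold cross-validation.

A synthetic corpus generator with known ground truth (per-label herb
multinomials, planted pairs, label-coherent attributes) makes every
stage testable without external data.

## Worked example

```r
library(HerbTopics)

# a small synthetic corpus with 3 planted pairs and known truth
g  <- generateCorpus(generatorConfig(preset = "small", seed = 1))
g$corpus
#> HerbCorpus with 500 prescriptions, 60 herbs, 5 function labels
#>   synth-00001: 9 herbs, labels {function-04}
#>   synth-00002: 8 herbs, labels {function-03}
#>   synth-00003: 12 herbs, labels {function-05}
#>   ...

# mine compatibility rules
pt <- minePairs(g$corpus, nTop = 100)
head(pairRules(pt), 3)[, c("herb_i", "herb_j", "support", "dependency", "cor")]
#>            herb_i          herb_j support dependency      cor
#> 1 synth-herb-0001 synth-herb-0003   0.080   5.952381 3.016190
#> 2 synth-herb-0031 synth-herb-0034   0.052   5.871725 2.961863
#> 3 synth-herb-0057 synth-herb-0058   0.072   5.681818 2.876909

# fit the pair-aware topic model and check recovery against truth
m <- fitLPH(g$corpus, pt, lphConfig(nIterations = 300, seed = 1))
groundTruthReport(g$trueBeta, m)$meanTV
#> [1] 0.04348555
```

The top-ranked pairs are herbs that the same function draws together
(high dependency), and the mean total-variation distance between the
recovered and generating herb multinomials is ~0.04 — the model has
recovered each function's herb profile. Multilabel prediction for a new
prescription:

```r
sc <- scoreLabels(m, prescriptions(g$corpus)[[2]])
predictLabels(sc, T = 1e-8)
#> [1] "function-03"
```

The classifier track, cross-validated:

```r
cv <- crossValidate(g$corpus, mode = "combined",
                    spec = classifierSpec("svm", C = 10),
                    nFolds = 4, repetitions = 2, seed = 1)
round(c(cv$precision, cv$recall, cv$microF1), 3)
#> [1] 0.840 0.815 0.827
```

## File formats

- **Corpus** (JSON-lines, one prescription per line):
  `{"id":"Ma Huang Tang","herbs":[["Ephedrae Herba",9],["Glycyrrhizae
  Radix",3]],"labels":["relieving exterior syndrome"]}`; an equivalent
  TSV dialect has columns `id`, `herbs` (`Name=dose;...`), `labels`
  (`;`-separated).
- **Herb attribute table** (TSV): `name`, `dose_min`, `dose_max`,
  `nature_flavor`, `channel_tropism`, `efficiency`; attribute terms are
  `;`-separated and a `"slightly "` prefix encodes weight 0.5.
- **Label vocabulary**: plain text, one label per line.
- **Pair table** export/import: TSV edge list `herb_i`, `herb_j`,
  `support`, `dependency`, `cor`.

A command-line front-end over these functions ships in
`inst/scripts/herbtopic` (subcommands `synth`, `mine-pairs`, `fit-lph`,
`predict`).

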