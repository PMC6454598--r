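---
title: "Time-sensitive clinical concept embeddings: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-sensitive clinical concept embeddings: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrembed)
```

## The problem

Coded clinical events — ICD-9 diagnoses (`D`), medications (`M`),
procedures (`P`) — arrive as timestamped visit records, and distributional
embedding methods borrowed from NLP treat the concatenated event stream as
if it were running text. That assumption breaks on longitudinal EHR data:
two events five positions apart may be a day apart or a year apart. A fixed
token window happily declares last winter's pneumonia the "context" of
today's knee replacement. The remedy implemented here is to let calendar
time, not token position, define context: an event's context is every event
occurring within $N$ days of its visit.

Three learners share this context machinery.

## The models

**Skip-gram (SG).** For a target concept $C_t$ in visit $V_t$, the model
maximises $\frac{1}{\varepsilon}\sum_t \sum_{C_k} \log p(C_k \mid C_t)$
over all context events $C_k$ within the time window ($k \neq t$), where
$\varepsilon = \sum_i N_i$ is the patient's total count of distinct
per-visit events and
$p(C_k \mid C_t) = \exp(v'^\top_{C_k} v_{C_t}) / \sum_C \exp(v'^\top_C v_{C_t})$.
Training uses the standard negative-sampling surrogate for this softmax
(5 negatives from the unigram$^{0.75}$ distribution); the exact softmax is
retained as a testable reference scorer (`softmax_prob()`). The per-patient
$1/\varepsilon$ weight is realised implicitly — pairs are streamed
uniformly, so a patient's contribution is proportional to its pair count —
with an explicit `per_patient_weight` option for the literal reading. Input
vectors are the published embeddings.

**PPMI-SVD.** Patient timelines are segmented into tumbling time windows
(one segment per visit at window 0; otherwise a visit joins the open
segment while it is within the segment span of the segment's first visit);
each unordered pair of distinct tokens in a segment increments a symmetric
co-occurrence matrix $C$ by the product of their multiplicities. The PPMI
transform is $M_{ij} = \max(0, \log \frac{p_{ij}}{p_i p_j})$ over the
ordered-pair probability space ($p_{ij} = C_{ij}/2T$, marginals as row
sums), and the embeddings are the rows of $U$ from the rank-$d$ SVD
$M \approx USV^\top$. There is deliberately no token-window or patient-level
PPMI variant: the former is undefined for segment counting, the latter is
meaningless when timelines span decades.

**FastText-style subword model (FT).** Identical to SG except that the
target-side score is $s(C_v, C_t) = \sum_{g \in G(C_v)} z_g^\top v'_{C_t}$:
the target's vector is the *sum* (not average) of its character n-gram
vectors, and the gradient of each pair flows into every one of those n-gram
vectors. N-grams are taken over the rendered token *including* its type
prefix (`D_493.22`), so the shared ICD stem `493` of `493.22` and `493.91`
becomes a literal shared parameter, and an out-of-vocabulary code can be
composed from its n-grams alone (`compose_vector()`). The context side
keeps whole-token vectors.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| embedding dimension | 200 | the published setting |
| time half-window $N$ | 0 (visit) or 15 days | "30-day window" means 15 days before or after the visit; boundary inclusive |
| baseline token window | 5 | the fixed-window comparator (5 concepts each side) |
| negatives / noise | 5, unigram$^{0.75}$ | word2vec convention; the source is silent |
| epochs, learning rate | 5, 0.025 linearly decayed to 0.0025 | word2vec convention; the source is silent |
| n-gram lengths | 3–6, `<`/`>` boundaries, whole token kept | reference FastText convention; the source is silent |
| MCSM $k$ | 40 | the published neighbourhood size |
| vocabulary `min_count` | 1 | no frequency floor is stated |

Day resolution is deliberate: all window arithmetic is in integer days
because every published window is stated in days. Visits carry one date;
events inherit it.

## Evaluation metrics

With a grouping $G$ (ICD prefix, CCS category, or the generator's ground
truth) restricted to the embedding vocabulary:

* $D_{in}$: per group, the mean of $1-\cos$ over all unordered member
  pairs; averaged unweighted over groups (cohesion — smaller is better).
* $D_{out}$: per unordered group pair, the mean of $1-\cos$ over all cross
  pairs; averaged unweighted over group pairs (decoupling — larger is
  better).
* MCSM: for each grouped concept, its $k$ nearest grouped neighbours by
  cosine contribute $1/\log_2(i+1)$ when they share the concept's group;
  averaged over concepts. Ceiling $\sum_{i=1}^k 1/\log_2(i+1)$.

The defining sums are written over concepts $v \in V(G)$ but the inner
terms iterate cluster pairs; we read both distances as group-level averages
(the reading consistent with "average cohesion/decoupling") and expose the
concept-weighted alternative behind `weighting = "concept"`, making no
claim about which the original evaluation used. Since $1-\cos$ is
symmetric, the "2-permutations" normalisation equals unordered-pair
counting; we use unordered pairs. Neighbour ties are broken by token string
so every metric is deterministic.

## The synthetic world

`generate_corpus()` states the world the tests rely on: care arrives in
episodes. Each patient draws $1+\mathrm{Pois}(2)$ episodes; each episode
has one latent group (i.i.d. uniform over 10 groups), $1+\mathrm{Pois}(2)$
visits separated by 1–10 days, and each visit carries $1+\mathrm{Pois}(4)$
events drawn from the episode group's 20 codes (or, with probability 0.1,
from 20 background medication/procedure codes). Episodes are separated by
60–400 quiet days. The constructor *enforces* max intra-gap < min
inter-gap, which yields the separation property the acceptance suite
checks: no two visits of different episodes are within 30 days, so a 30-day
window provably never mixes episodes, while a ±5-token window demonstrably
does (patients mix groups across episodes). Group codes share a 3-character
ICD prefix (`101.01`–`101.20`, ...), so the ICD-prefix grouping recovers
the ground truth and the subword model can exploit the stem.

What the generator does **not** emulate: realistic code frequency (Zipfian
tails), comorbidity structure across groups, progression within an episode,
demographic covariates, or the ~30k-concept vocabulary of a production EHR
database. A green recovery test therefore establishes that the machinery
learns the stated temporal-co-occurrence structure — not that it reproduces
any published table, which required a proprietary 50M-patient database.

## Numerical choices

* The SGD cores (Rcpp) are single-threaded with an internal
  xorshift64* RNG: a seed fixes initialisation, per-epoch pair shuffles and
  negative draws, so identical seeds give bit-identical models. A parallel
  "hogwild" mode would be faster and non-reproducible; reproducibility won.
* Negative draws colliding with the positive context are skipped, the
  word2vec behaviour.
* The SVD uses a dense LAPACK decomposition: desk-scale vocabularies are a
  few hundred tokens, where dense SVD is both faster and better conditioned
  than sparse iterative methods. Singular-vector signs are canonicalised
  (largest-magnitude entry positive), making PPMI-SVD fully deterministic.
* Natural log in PMI; a scale-invariance test confirms the base cannot
  affect the embeddings beyond sign.
* Zero-norm vectors in cosine yield similarity 0 (distance 1) with a
  warning, instead of NaN.
* Degenerate inputs fail loudly: empty pair streams name their likely
  cause, `d > V` SVD requests, baseline-mode PPMI and n-gram configs that
  would leave tokens with no parameters are rejected up front.

## Design choices that were genuinely open

* **PPMI segmentation is tumbling**, anchored at each segment's first
  visit: "segmenting the input sequence" describes a partition, not a
  convolution. A sliding variant would double-count pairs near boundaries.
* **Multiplicity counting** (a code in two visits of one segment counts
  twice against its neighbours) is the default, with `binary = TRUE`
  per-segment counting available; the source does not say which it used.
* **Whether the whole token enters subword space** matters for rare codes;
  we keep it (FastText convention) and expose the frequency threshold `P`
  named by the source (default 0, since its value is unstated).
* **Dimension 200 at desk scale** deserves a caveat: with a ~220-token
  synthetic vocabulary, a rank-200 "truncation" of the PPMI matrix retains
  nearly all noise directions, and PPMI's cohesion margin in the recovery
  test is accordingly thin (skip-gram and FastText, whose dimensionality is
  a free parameterisation rather than a spectral cut, are unaffected). We
  keep the published dimension rather than tune it; at production
  vocabulary sizes ($d/V \approx 0.7\%$) the regime is entirely different.

## Known limitations

* No frequency subsampling of very common tokens (never mentioned by the
  source; omitted rather than shipped as an untested flag).
* No hierarchical softmax; negative sampling is the only training path.
* The baseline linearization shuffles within-visit events per patient with
  a derived seed; a different corpus ordering changes baseline (not time
  mode) results, which is inherent to the method, not to this
  implementation.
* `read_records()` loads the corpus into memory; at 50M patients you would
  stream. Desk-scale corpora are the design point.

## A worked run

```{r pipeline, eval = FALSE}
dir <- tempfile()
paths <- run_simulate(file.path(dir, "sim"),
                      synth_config(n_patients = 400, seed = 1))
run_train(paths$records, file.path(dir, "sg.vec"),
          method = "sg", window = "visit", dim = 100, epochs = 3, seed = 1)
run_evaluate(file.path(dir, "sg.vec"), paths$grouping, k = 10)
run_query(file.path(dir, "sg.vec"), "D_101.01", k = 5)
```

The evaluation prints a one-line row (`d_in`, `d_out`, `MCSM`) of the same
shape as the published comparison tables; the query prints the five
nearest concepts with cosine similarities, which on the synthetic corpus
are dominated by the query's own prefix group.
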