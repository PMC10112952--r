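---
title: "Ontology knowledge injection for relation extraction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology knowledge injection for relation extraction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(kinject)
```

## The problem

Biomedical relation extraction (RE) asks whether, and which, semantic
relation holds between two entities mentioned in one sentence: does
*venlafaxine* cause a *seizure*, is a phenotype linked to a gene, does a
chemical induce a disease. Plain sequence classifiers see only the
sentence; yet much of what makes such a relation plausible lives in
domain ontologies (ChEBI-style chemical hierarchies, disease and
phenotype vocabularies) rather than in the text. `kinject` implements a
knowledge-injection architecture: ontology triples are grafted onto the
sentence as a shallow tree, and a transformer encoder is trained so that
the grafted knowledge can inform the classification without being
allowed to corrupt the sentence's own structure.

## The sentence tree

A sentence is a token sequence $s = \{t_0, t_1, \dots, t_n\}$ in which
the two candidate entities are delimited by `<e>`/`</e>` tags. A
knowledge base $K$ is a collection of triples $e = (t_i, r_j, t_k)$ —
head concept, relation, tail concept — loaded from OBO flat files or
plain TSV triple lists. Injection expands the sentence into a depth-1
sentence tree

$$st = \{t_0, t_1, \dots, t_i\{(r_{i0}, t_{i0}), \dots\}, \dots, t_n\},$$

attaching to some anchor spans a list of branches, each the relation and
tail of one triple whose head matched the anchor. Depth is fixed at one:
no branch grows branches, which keeps the original sentence meaning
recoverable.

Matching is dictionary-based and multi-token. All $n(n+1)/2$ contiguous
spans of a punctuation-free run are candidates (punctuation separates
runs), each span is looked up — once per knowledge source — under a
light normalization (lowercasing, whitespace collapsing, stripping of
surrounding punctuation, deliberately no stemming, since chemical
nomenclature matches exactly or not at all), and among overlapping
matches the longest span wins, with leftmost start and then higher
summed tail information content breaking ties. Two injection modes
exist: **targeted** queries only the two tagged candidate entities;
**contextual** queries every span in the sentence.

When several sources (or a productive anchor) offer more triples than
the per-entity budget `max_entities` (typically 2–5), triples are ranked
by the information content of their tails and the most specific ones are
kept. Because no corpus frequencies are available for arbitrary
ontologies, the package uses intrinsic (descendant-count) IC over the
`is_a` hierarchy,

$$IC(c) = -\log\frac{|\mathrm{desc}(c)| + 1}{N},$$

which is zero for a root subsuming everything and maximal for leaves,
and is anti-monotone along `is_a` edges. `is_a` is used even in
multi-relation sources because it is the one relation that defines the
subsumption hierarchy in all the common biomedical ontologies.

Two tokenization choices deserve a note. Relation labels stay single
tokens (`is_a`). A multi-word tail label ("abnormal nervous system
physiology") also stays a *single* vocabulary token by default — a token
may stand for several words — so every branch contributes exactly two
tokens (relation, tail); `split_tails = TRUE` switches to whitespace
splitting for vocabularies where sharing word pieces across labels
matters.

## Soft positions and the seeing layer

The tree is flattened for the encoder: a `[CLS]` classification token,
then trunk tokens in order, with each anchor's branches inserted
immediately after the anchor's last token. Each token carries two
positions. Its *hard* position is its index in the flattened order; its
*soft* position is its tree position: trunk tokens keep their sentence
indices, a branch continues numbering from its anchor, and distinct
branches of one anchor restart at the same offset. Soft positions index
the position-embedding table, so the encoder perceives the branch as
sitting *at* its anchor, while trunk tokens after the anchor keep their
original positions (duplicated soft positions across trunk and branches
are intended).

The *visible matrix* is the structural firewall. Trunk tokens (and
`[CLS]`) all see each other; a branch token sees only its own branch and
the trunk tokens of its anchor span; everything else is mutually
invisible — including two branches of the same anchor, which are
separate paths of the tree. Classification therefore reads knowledge
only as it is mediated through the anchors. In the attention stack the
matrix becomes an additive mask, 0 where visible and $-10^9$ where not,
applied before the softmax, so invisible positions receive numerically
zero attention. A row masked away from everything falls back to
attending to itself (this can only arise from hand-built masks; padding
rows keep their diagonal).

## Mask-self-attention classifier

The encoder is a standard transformer stack except for the mask:
token + soft-position + segment embeddings with layer normalization,
then `layers` blocks of multi-head scaled dot-product attention (with
the additive visibility mask), residual connections, layer
normalization, and a position-wise feed-forward network, with the
per-label scores read from `[CLS]`. It is written in vectorized base R
over BLAS matrix products with hand-derived backpropagation, which the
test suite validates against numerical differentiation; there is no
external deep-learning runtime behind it. Training uses Adam with
linear warmup over the first tenth of the steps and linear decay after,
class-weighted cross-entropy, and dropout on the embedding and sublayer
outputs.

Two training choices stabilize the noisy end of short from-scratch
runs, and apply identically to every configuration (with and without
knowledge). Query and key projections initialize *tied* (`Wq = Wk`), so
each attention head opens as a Gram-matrix similarity matcher — the
primitive that token-identity and duplicate-detection circuits build
on — and unties freely from the first step. And the weights actually
evaluated are a per-step exponential moving average (Polyak averaging,
decay 0.995); validation selection operates on the averaged weights.

Class weights address the label imbalance endemic to RE corpora
(no-relation candidates dominate). For label counts $n_c$ over $N$
training examples and $L$ labels, $w_c = N/(L\,n_c)$, so a random
training example has expected weight 1 and rare relations are
up-weighted in proportion to their rarity.

Defaults that matter, with the reasoning behind them:

| parameter | default | why |
|---|---|---|
| `hidden` | 64 | desk-scale width; divisible by `heads` |
| `layers` / `heads` | 2 / 2 | two hops let branch information reach `[CLS]` via the anchor |
| `batch_size` | 32 | standard fine-tuning batch for RE corpora |
| `dropout` | 0.1 | regularizes the memorization-prone toy regime |
| `ffn_mult` | 2 | inner FFN width 2× hidden; the classic 4× is one flag away, 2× keeps desk-scale training brisk |
| `lr` | 5e-4 | from-scratch training needs more than fine-tuning rates; stable under warmup/decay at toy widths |
| `max_len` | 64 | accommodates trunk plus injected branches for sentences of a few dozen tokens |
| splits | 60/10/30 | train / validation / test, label-stratified |
| epochs | 20 | with per-epoch model selection on validation weighted F |

Checkpoints are a named tensor manifest (`emb.tok`, `emb.pos`,
`emb.seg`, `layer<l>.attn.Wq` …, `head.W`); loading matches by name and
shape, re-initializes what is absent (e.g. a classification head for a
different label set) from the configuration seed, reports both groups,
and refuses a present-but-misshapen tensor by name. Knowledge plays a
role only at training and prediction time — there is no pretraining
stage anywhere in the package.

## Evaluation and significance

`evaluate()` reports per-label precision, recall, F-measure and support
from the confusion matrix, support-weighted averages of each, and
accuracy; weighted averaging is the honest summary under heavy label
imbalance. `significance()` compares run-level scores of two systems
across repeated seeded runs with Welch's one-tailed t-test (the variance
of two training configurations need not be equal, hence Welch rather
than the pooled-variance test), returning the p-value that the second
system's mean exceeds the first's; the zero-variance corner cases are
defined explicitly (0.5 on equal constants).

## The synthetic benchmark

Real RE corpora and full-size ontologies are external resources, so the
package carries seeded generators that emulate their statistical
structure at desk scale and make every stage — and the
baseline-versus-knowledge contrast — testable offline.

`generate_ontology()` builds a rooted `is_a` DAG: each non-root concept
takes one parent among earlier concepts (respecting a branching-factor
cap), and with probability 0.2 a second parent, so the hierarchy is a
genuine DAG rather than a tree; a chosen fraction of labels are 2–3
pseudowords long to exercise multi-token matching. `generate_corpus()`
plants the relation: two concept labels are embedded, tagged, amid
filler pseudowords, and the gold label says whether the two concepts
share a common `is_a` ancestor within two edges, flipped with
probability $\varepsilon$. Injected branches name each entity's parents,
so the planted relation is — by construction — largely readable off the
injected knowledge, which is the package's stand-in for the premise that
domain ontologies carry information relevant to biomedical relations.

Three dials control how necessary the knowledge is. $\varepsilon$
(default 0.05) bounds every model's ceiling at roughly $1-\varepsilon$.
$\beta$ (default 0.1) controls a spurious surface cue: one filler token
agrees with the gold label with probability $0.5 + \beta/2$, so lexical
features alone recover the label only partially. The default is
deliberately weak: with 40 concepts (the default) and a few thousand
sentences, entity pairs recur between training and test, so a
sufficiently strong surface cue both lets a baseline classifier
memorize its way toward the ceiling and acts as a shortcut that
suppresses learning of the harder ontology circuit, masking the
knowledge effect the benchmark exists to measure. `direct_pos_frac`
(default 0.7) sets what fraction of related pairs share a *direct*
parent (or are parent–child) rather than only a grandparent. Depth-1
triples inject each entity's parents, so direct pairs place literally
overlapping tail tokens in the two entities' branches — evidence the
injected knowledge can express — while grandparent-only pairs require
second-order reasoning about sibling parents that no depth-1 branch
makes explicit. Weighting the planted positives toward expressible
cases is the benchmark's signal-strength dial: the predicate itself is
unchanged, only the mixture of easy and hard positive evidence. About
30% of sentences also mention one to three untagged concepts, which
only contextual injection picks up.

Entity delimiters deserve one remark: the encoder input carries no
marker distinguishing the candidate pair from other mentions
(`keep_markers = FALSE` by default). Retaining delimiter sentinels is
supported, but on this benchmark it mainly sharpens the baseline's
ability to memorize entity pairs, which is not the phenomenon the
contrast is designed to isolate.

What the generator does *not* emulate is worth stating plainly: real
syntax (sentences are bags of pseudowords with planted structure),
entity ambiguity and acronyms, negation and speculation, multi-sentence
context, and annotation biases of curated corpora. A passing contrast
on this benchmark shows that the architecture can route ontology
evidence into its decisions when that evidence is informative; it does
not certify gains on any particular real corpus.

## Numerical and procedural choices

* Invisible attention positions use an additive $-10^9$, the standard
  numerically safe realization of $-\infty$ before a softmax.
* Layer normalization uses $\varepsilon = 10^{-6}$; weights initialize
  from $\mathcal{N}(0, 0.02^2)$ under the configuration seed.
* Overlap ties in span matching resolve by length, then leftmost start,
  then summed tail IC — a total order, so matching is deterministic.
* Branch selection ties resolve by source name, then tail label.
* Truncation to `max_len` is branch-first (whole branches drop in
  ascending tail-IC order) and touches the trunk only as a last resort;
  padding is invisible in both directions.
* Stratified splitting uses largest-remainder rounding per label with a
  global reconciliation pass, so the printed 60/10/30 sizes are exact.
* Every stochastic step — DAG shape, labels, corpus sampling, splits,
  weight init, batch shuffling, dropout — draws from a seed supplied by
  the caller; two runs with one seed are bit-identical, which the suite
  asserts on the whole pipeline.
* With `is_a` cycles the IC computation refuses the source (subsumption
  must be a DAG); triples referencing undefined terms are dropped with a
  warning rather than failing the load.

## Open design points, decided

* **IC on the head or the tail of a competing triple?** The tail: it is
  the token list actually injected, and specificity of what enters the
  sentence is what the cap should protect. Config-exposed via the
  ranking in `select_branches()`.
* **Do identical triples from different sources both inject?** No;
  exact duplicates collapse before ranking.
* **Are synonyms indexed?** Yes by default (`index_synonyms = TRUE`),
  off by one flag, since OBO synonym scopes vary in reliability across
  ontologies.
* **Welch or paired t-test across runs?** Welch, flagged above.
* **Is the entity matched as a whole in targeted mode even when the KB
  lacks the full string?** Yes — targeted injection is defined on the
  tagged span as a unit; a sub-span fallback would silently change what
  "the entity" means.

## Problem sizes used by the test suite

The suite keeps everything at desk scale: ontologies of 20–50 concepts,
corpora of a few dozen to 2,000 sentences, hidden width 16–64, and 2–20
epochs depending on what the test asserts. The knowledge-benefit
contrast uses the generator defaults (2,000 sentences, 40 concepts,
$\beta = 0.1$, $\varepsilon = 0.05$, `direct_pos_frac = 0.7`) with a
2-layer, 2-head, width-64
encoder trained 20 epochs at batch 32, repeated over five model seeds
for both the no-knowledge baseline and contextual injection at
`max_entities = 2`. These sizes are the package's chosen study
conditions for the benchmark, balancing statistical stability of the
contrast against a suite that runs comfortably on one CPU.

## Limitations

The most important one concerns what desk-scale training can show about
knowledge injection. With every concept observed during training, the
injected branches are a deterministic re-representation of information
already present in the entity tokens, so their value is an inductive
bias, not new evidence; and exploiting the strongest planted evidence —
overlapping branch tails at the two entities — requires a set-overlap
computation that, under the visible-matrix and classification-token
conventions, only the final feed-forward block applied to the pooled
classification vector can perform. A two-layer, width-64 encoder
trained from scratch on a thousand-odd sentences does not reliably
discover that circuit: on a diagnostic fixture where an overlap-rule
oracle reaches ~0.95 accuracy, extended training plateaus around 0.68.
The baseline-versus-knowledge contrast the benchmark measures is
therefore small at this scale and sensitive to the training seed —
positive on average across repeated paired runs, but not in every
individual pair. The architectures the method is designed for are
pretrained many-layer encoders whose attention already implements the
matching primitives that injection exploits; the generators and the
paired-run design here measure the direction of the effect honestly at
desk scale rather than guaranteeing its magnitude.

Pretrained biomedical encoders (SciBERT/BioBERT-class) are where
knowledge injection pays off on real corpora; this package trains from
scratch at toy scale and loads checkpoints only through its own tensor
manifest, so transfer from published checkpoints is a best-effort
mapping, not a guarantee. The dictionary matcher is exact after
normalization — no fuzzy matching, abbreviation expansion, or acronym
disambiguation. Sentence-pair (segment B) inputs and masked-language
pretraining are out of scope by design.
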