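---
title: "Extracting and linking medication attributes in discharge summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting and linking medication attributes in discharge summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medlinkr)
```

## The problem

Hospital discharge summaries record prescriptions as free text: "Bisacodyl
5 mg Tablet Sig: 1-2 Tablets PO once a day as needed for constipation."
Turning such text into structured prescriptions requires two steps:

1. **Named-entity recognition (NER):** locate spans of eight types — the
   drug name plus seven attributes (strength, dosage, frequency, duration,
   route, form, reason).
2. **Relation extraction (RE):** link every attribute span to the drug
   span(s) it modifies. An attribute may serve several drugs ("... and
   Benzonatate as needed for *cough*" — one reason, two drugs), and a drug
   may collect attributes across sentence boundaries ("Patient will be on
   Topiramate ... Then increase to *50mg po BID*").

medlinkr implements both steps, their evaluation protocol, and a synthetic
corpus generator so everything is trainable without access to restricted
clinical data.

## The sequence model

The recognizer is a bidirectional LSTM with a linear-chain CRF output
layer. Each token $t$ is mapped to a representation vector $x_t$; a BiLSTM
(300 hidden units per direction) produces contextual states $h_t$, which a
linear layer projects to scores for the 33 BIOES labels (`O` plus
B/I/E/S for each of the eight types). The CRF scores a label path
$y_{1:T}$ as

$$s(y) = \mathrm{start}_{y_1} + \sum_t E_{t,y_t} + \sum_{t>1}
A_{y_{t-1},y_t} + \mathrm{stop}_{y_T},$$

with emissions $E$ and learned transition matrix $A$; training minimizes
$\log Z - s(y^{gold})$ with the forward algorithm in log space, and
decoding uses Viterbi with ties broken toward the lowest label index so
runs are deterministic. Transitions that violate the BIOES grammar are not
hard-masked — the transition matrix learns them, and the span decoder
repairs any residue conservatively (an orphan `I`/`E` run becomes an
entity over its own extent; an unclosed `B I…` run ends at the last
same-type tag).

### Token representations

Four stacks are available through `repr_config(mode = ...)`:

| mode      | composition                              | width          |
|-----------|------------------------------------------|----------------|
| `RIWE`    | randomly initialized word embeddings     | 100            |
| `PWE`     | pretrained word embeddings from a file   | file dim (600) |
| `PWE+CE`  | pretrained ⊕ character-BiLSTM feature    | file dim + 50  |
| `PWE+SFE` | pretrained ⊕ semantic-feature embedding  | file dim + 50  |

The character channel embeds each character (25 dims) and runs a
character-level BiLSTM with 25 hidden units per direction; the token
feature is the concatenation of the two final states (50 dims), which
exposes morphemes — the suffixes of drug names — to the model. Word
lookup is lower-cased; the character channel sees the original surface
because capitalization is informative there.

Semantic-feature embeddings (50 dims, learned jointly) encode a clinical
category per token: Medication, DiseaseDisorder, SignSymptom, Problem
(with a present/absent assertion), Treatment, Temporal, or O. Tags come
either from the built-in lexicon/regex tagger (drug morphemes, problem
word lists, date-time patterns) or from an external pipeline via a
per-token TSV; two tag sequences are merged per token with the precedence
Medication > DiseaseDisorder > SignSymptom > Problem > Treatment >
Temporal — the more specific clinical category wins, and the winner's
assertion is carried.

### Training regime

Plain minibatch SGD, learning rate 0.005, batch size 32 sentences, with
the batch loss being the **sum** of sentence NLLs (the convention of
classic CRF sequence trainers; with a mean-of-batch convention the same
learning rate would take an order of magnitude more epochs). Dropout 0.5
is applied elementwise to the composed token embeddings at training time
only — two inference passes are bit-identical. Early stopping watches
lenient micro-F on a development split (30 documents by default) with
patience 10 and a 100-epoch cap; parameters from the best development
epoch are kept. If the development score reaches 1.0 training stops
immediately, since no further improvement is possible. All randomness
(initialization, the development split, shuffling, dropout) derives from
one integer seed, so training is reproducible end to end.

## Relation extraction

Two methods share the same interface.

**Rules.** A sentence with one drug donates all its attributes to that
drug. A sentence with several drugs is segmented at each drug's start
offset; attributes belong to their segment's anchor, and attributes
before the first drug attach to the first drug (the segment definition
would otherwise leave the prefix unassigned). A sentence with attributes
but no drug looks back up to two sentences and links everything to the
closest preceding drug, measured from attribute start to drug end. The
known blind spot is deliberate: a reason shared by two drugs in one
sentence gets only the nearer link, because segmentation assigns each
span to exactly one segment. The test suite documents this limitation
explicitly.

**Context-aware LSTM.** Every (attribute, drug) pair whose drug lies in
the attribute's sentence or the two preceding sentences is a candidate —
the same window as the rule method, so both methods see the same search
space. Scope tokens are encoded as word embedding ⊕ a 10-dimensional
marker embedding (target drug / target attribute / other drug / other),
run through a unidirectional LSTM (300 hidden units), and the final state
represents the pair. The mean of the other candidates' representations in
the same scope is concatenated as context (zero vector when there is
none), and an affine map plus two-way softmax yields p(related); the
relation type is the attribute's type, which determines it uniquely.
Unrelated candidates dominate, so the cross-entropy is weighted by
inverse class frequency. Gradients flow through both the target and the
context encodings.

A practical note on this architecture: when two candidates share exactly
the same scope tokens and differ only in marker placement, the
class-separating gradient component is small and plain SGD separates them
slowly. On realistic data candidates almost always differ lexically
(different scopes, distances and segment structure), which is what the
model exploits; the overfit test in the suite therefore uses a toy whose
two patterns differ in scope length, not markers alone.

## Evaluation protocol

Strict matching requires identical (type, start, end); lenient matching
requires the same type and any character overlap. Matching is one-to-one:
true positives are the size of a **maximum** bipartite matching between
gold and predicted spans (computed by augmenting paths and verified
against brute force in the tests), so `tp + fn = |gold|` and
`tp + fp = |pred|` always hold. Greedy largest-overlap pairing was
rejected because it is provably suboptimal on crossing-overlap
configurations. A predicted relation is correct iff a gold relation of
the same type has both endpoints matching under the active mode, again
one-to-one.

Micro scores pool counts over all documents; macro scores average
per-document micro metrics, and a document with neither gold nor
predicted instances contributes (1, 1, 1) — a convention, stated here
because corpora with empty documents exist. End-to-end evaluation applies
the relation contract to relations built on *predicted* entities, so
recognition errors compound visibly. Per-document micro-F vectors feed
`paired_ttest()` (two-tailed, n−1 degrees of freedom); zero-variance
differences are reported as degenerate rather than raising an error.
Token-level confusion matrices (gold type × predicted type, BIOES
collapsed) support error analysis.

## The synthetic corpus

`generate_corpus()` emulates the annotation structure of medication
corpora: prescription list lines ("Drug 325 mg Tablet Sig: 1-2 Tablet PO
BID as needed for pain."), narrative sentences, two-drug segmented
sentences, shared-reason sentences, and attribute-only continuations
("Then increase to 50mg po BID for seven days.") that exercise the
lookback rule. Drug names are novel stem+suffix compositions
(-olol, -mycin, -pril, ...), so the character channel must generalize
rather than memorize. Surface noise mirrors phenomena seen in clinical
text: abbreviations (QHS, q8h, od), parenthesized numerals ("One (1)"),
occasional misspellings, and glued tokens ("Aspirin325 mg").

Defaults encode the corpus structure the package assumes: 300 documents
of 4–7 content sentences; entity-type proportions with drugs about a
third of all entities and durations rare; 17% of reasons shared between
two drugs; 18% of eligible sentences being lookback continuations. Slot
probabilities are derived from the configured type mix (attribute share /
drug share) with a fixed calibration factor that corrects for template
dilution — continuation lines carry attributes but no drug, shared-reason
lines carry two drugs but few attributes — so realized corpus shares
track the configured mix within a few percent. Gold relations are derived
from the generating templates, never from the rule linker, so the rules
can be scored honestly: they recover lookback and segment links but
provably miss the second link of every shared reason.

What passing on synthetic data does **not** show: real discharge
summaries have richer narrative, annotation inconsistency, ambiguous
attribute boundaries and rare formats; scores on the synthetic fixture
are near ceiling and should be read as correctness checks of the
machinery, not as clinical performance estimates.

## Numerical and design choices

- Offsets are 0-based half-open everywhere, including standoff files.
- The tokenizer splits punctuation and letter/digit boundaries and is
  offset-faithful; any external tokenizer producing exact offsets can be
  substituted. List markers ("1.") stay attached to their line during
  sentence splitting.
- Entities misaligned with token boundaries claim every overlapped token;
  overlapping entities resolve longest-span-first (ties: earlier start),
  and dropped entities are logged.
- Discontinuous standoff spans are collapsed to their envelope and
  flagged in the load report.
- LSTM forget-gate biases start at 1; other weights are Glorot-uniform;
  embeddings are uniform(−0.25, 0.25); all under the run seed. The
  forward/backward passes are verified against finite differences, and
  the CRF forward/Viterbi against exhaustive path enumeration.
- Checkpoints are single serialized files whose save/load round trip is
  exact.

## Problem sizes used by the test suite

The shipped experiments are sized for a single CPU: the end-to-end
fixture trains the RIWE recognizer on 210+30 synthetic documents with a
30-epoch cap and evaluates on 30 held-out documents; the embedding-mode
checks train on 16 documents with 600-dimensional synthetic pretrained
vectors for 3 epochs; the relation model trains on 40 documents with a
15-epoch cap. These sizes are the package's chosen defaults for its own
regression experiments; the model code itself has no such limits.

## Known limitations

- The rule linker attaches lookback attributes to a single closest drug;
  gold links to several drugs across sentences are not produced.
- The relation classifier's binary softmax (type inherited from the
  attribute) cannot represent typed disagreement; an 8-way variant is a
  possible extension.
- The built-in semantic tagger is a lexicon stand-in for full clinical
  pipelines; its tags are deterministic and shallow. External taggers can
  be supplied via TSV.
- Contextual (transformer) embeddings are out of scope.
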