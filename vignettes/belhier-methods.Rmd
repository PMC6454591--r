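---
title: "Hierarchical sequence labeling for BEL statement extraction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical sequence labeling for BEL statement extraction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(belhier)
```

## The problem

A BEL (Biological Expression Language) statement records a causal finding as
`subject-term relation object-term`, e.g.

```
cat(p(HGNC:IL2)) increases complex(p(HGNC:LYN), p(HGNC:IL2RB))
```

Corpora for this task annotate statements at the *sentence* level: a sentence
is paired with its statements, but nothing says which words express which
node.  That blocks ordinary supervised sequence labeling, which needs
token-level tags.  `belhier` closes the gap in three stages:

1. **Parallel corpus.** Each statement set is normalized, unified into one
   tree, and serialized to a preorder node sequence with arity markers
   (`decreases@2 CHEM_1 complex@2 GENE_1 GENE_2`).  The sentence is
   anonymized (entities replaced by typed placeholders) and reduced to the
   minimal dependency subtree containing all entities.
2. **Word alignment.** An IBM Model 1 EM aligner treats the simplified
   sentence as the source language and the node sequence as the target
   language, producing word-to-node links from which layered BIESO tags are
   generated.
3. **Stacked labeling.** One linear-chain CRF per tree layer is trained;
   layer *k* consumes the tags of layers 1..k-1 as features (gold at
   training, predicted at test time).  Predicted layers are decoded back
   into trees, split at `or` nodes, and rendered as statements.

Everything below documents the concrete modelling choices, their defaults,
and what the bundled synthetic corpus does and does not establish.

## BEL trees and normalization

A statement is parsed into a tree whose root is the relation
(`increases`, `decreases`, `directlyIncreases`, `directlyDecreases`) with its
two arguments, recursively, as ordered children.  Nested relations
(a statement as argument of another) are rejected explicitly rather than
guessed at; they do not occur in the supported task setting.

Modification functions written inside an entity term are *elevated* so
functions always sit above entities:

```{r}
t <- parse_statement("p(HGNC:AKT1, pmod(P, S, 21)) increases p(HGNC:GSK3B)")
render_statement(normalize_statement(t))
```

The elevated set is `pmod`, `sub`, `trunc`, plus `fus` handled identically;
these are the modification functions of the BEL 1.0 protein-abundance term.
Normalization is idempotent, and rendering reverses the elevation.
Duplicate statements attached to one sentence are collapsed by exact tree
equality after normalization — the simplest consistent reading of
"identical".

Serialization writes each internal node as `label@n` (`n` = child count),
which makes preorder sequences uniquely invertible.  Entity leaves become
typed placeholders `GENE_k`/`CHEM_k`/`BP_k`/`DIS_k`, numbered per type in
first-mention order; namespaces map to types as HGNC/MGI/EGID → GENE,
CHEBI → CHEM, GOBP → BP, MESHD → DIS.  Rendering emits no space after
commas; `canonical_bel_text()` strips whitespace variation before string
comparison because gold files vary in dialect.

## Tokenization and anonymization

Tokenization is whitespace splitting plus exactly three domain rules (it is
deliberately *not* a general biomedical tokenizer):

* a sentence-final comma (comma followed by space) becomes its own token,
  while a comma directly followed by a letter or digit stays attached
  (`1,204` survives);
* hyphenated compounds ending in *-ed*/*-ing* split at the hyphen
  (`progesterone-induced` → `progesterone - induced`), because the
  participle usually carries the relation; the hyphen is kept as a token so
  character offsets remain recoverable;
* amino-acid residue abbreviations fused with numbers split
  (`Ser727` → `Ser 727`), feeding `pmod()` parameters.  The rule fires only
  when the letter part is a one/three-letter amino-acid code, so `p53` is
  not shredded.

Stems are computed once, by a compact deterministic suffix stripper
(plurals, *-ed*/*-ing*, *-ation*/*-ization*); any deterministic stemmer
satisfies the feature contract, so no external stemming dependency is used.
Anonymization collapses each mention span to one placeholder token and keeps
the original tokens in a mapping, making it exactly invertible.

## Entity grounding

Statement entities carry identifiers but not positions, so each entity is
located by a cascade: precomputed NER-hook mentions (the package never
shells out to external recognizers), identifier renormalization
(genes/proteins pass through, chemicals map to CHEBI via a user-supplied
name table, OMIM-linked diseases are discarded), then dictionary search.

Dictionary search scans every contiguous window of at most `max_span = 6`
tokens (enough for multiword GO process names at bounded cost) and minimizes
the character-level Levenshtein distance — the spec leaves the variant open
and character-level is implemented — normalized by the longer string,
case-insensitively (gene-symbol casing is inconsistent in text).  A match is
accepted at distance ≤ 0.2, which admits minor morphological variants
without grabbing arbitrary text.  Ties break deterministically: smaller
distance, then longer window (favoring full names), then leftmost.  An
entity with no acceptable window is ABSENT, and a pair with any ABSENT
entity is filtered out of the parallel corpus.

## Sentence simplification

Sentences are reduced to the words of the minimal dependency subtree
containing all entity placeholders (the union of paths to their lowest
common ancestor), in original order.  Parsing is external: trees arrive
pre-parsed in CoNLL-U and any parser can be used.  With Stanford-style basic
dependencies, prepositions sit on the path between content words, so
connectors like "of" survive while determiners, conjunctions and modifier
phrases fall away — which is exactly how the worked example behaves under
the hand-constructed fixture parse shipped in
`inst/extdata/simplify_example_parse.conllu` (a synthetic parse: the
original parse behind the example is not published, so token-for-token
agreement is pinned only for this fixture).  A sentence with no available
parse passes through whole, with a warning, keeping the pipeline total.

## Word alignment

Direction: the simplified sentence is the **source** and the node sequence
the **target**, so each sentence word links to at most one node — the
orientation the alignment examples require (the surrounding prose states it
both ways; the specific description wins).  The aligner is IBM Model 1 with
a NULL target, trained by EM: uniform initialization over each target's
co-occurring sources, expected-count E-step, normalizing M-step.  Iteration
order is fixed by `pair_id` sort and no random numbers are drawn, so
retraining is bit-identical; the corpus log-likelihood is non-decreasing by
construction.  Ten iterations are ample for these short sequences.

Two refinements matter in practice:

* **Pseudo-parallel pairs.** `copies = 50` single-token pairs
  (`GENE_1 → GENE_1`) per placeholder dominate the placeholder rows of the
  translation table, and extraction additionally forces placeholder links,
  giving entity links precision 1 whenever both sides share the
  placeholder.
* **NULL weight.** Model 1 has no fertility model, so frequent function
  words garbage-link to co-occurring content nodes (the classic failure
  mode).  The NULL target therefore receives an alignment-prior weight of
  `null_weight = 2` — equivalent to two NULL tokens per sentence, the
  standard remedy for Model 1 — which leaves words like "of"/"to"/"with"
  unaligned, as a full alignment toolchain would.

Extraction links each source word to its maximum-probability target (ties to
the leftmost) unless weighted NULL wins; several words may share one target
node (a function's span covers several words), but a word never links to two
nodes.

## Layered tags

Leaves sit at layer 1 and every internal node at one plus its highest
child, so the root carries the maximal layer L.  A node's span is the
minimal contiguous token interval covering its own aligned word(s) and all
tokens covered by its descendants; tokens inside a span that belong to no
lower node are tagged `I` (contiguous spans, no `O` gaps).  Layer-1
parameter leaves are tagged by class — `P` (modification type), `AA`
(residue), `NUM` (position) — per "entities and other parameters at the
lowest level".  Tag labels carry no arity marker; fragmenting the label
space by arity would starve the labeler, and arity is recomputed from the
recognized children at reconstruction.

A training instance is rejected (with a typed condition and a logged
reason) when a function or relation node has no aligned word of its own, or
when same-layer spans overlap; this mirrors the attrition real corpora show
between pair filtering and instance generation.  A non-strict mode recovers
unaligned internal spans from the descendants alone, for prediction-side
tooling.

Reconstruction is top-down: spans are extracted per layer with the standard
deterministic BIESO repair (orphan `I`/`E` opens a block, unterminated `B`
closes at the last contiguous token), each layer-k span adopts the
not-yet-claimed lower items nested in its interval in left-to-right order,
and the highest surviving span becomes the root.  Orphan spans outside
every higher span are dropped with a warning; all-`O` predictions yield no
statement.  Relation argument order is surface order — the left span is the
first argument as serialized.  That rule is a documented choice: when an
object precedes its trigger in text the original order is not recoverable
from tags alone, which is a known limitation of this representation (the
bundled generator produces subject-first clauses, so the rule is exact
there, as the inverse-identity tests quantify).

## The stacked CRFs

Each layer is a linear-chain conditional random field over string features:
a bias, word identity and stem at offsets −2..+2 (window 5), plus — for
layer k > 1 — the lower layers' tags at the same offsets; label bigrams are
the CRF transition weights.  Out-of-range offsets yield `_BOS_`/`_EOS_`
sentinels.  Training maximizes the L2-penalized conditional log-likelihood
(`c2 = 1.0`, the conventional default where none is reported) with L-BFGS-B
on the exact forward-backward gradient, computed in compiled code; no CRF
engine ships in the environment, so the engine is implemented in-package
behind the same deterministic-training contract.  Weights start at zero and
the feature/label dictionaries are sorted, so training is exactly
reproducible; the recorded `seed` is provenance metadata, not a source of
randomness.  Lower-layer label features use gold tags during training
(teacher forcing, exactly the stacked training algorithm) and predicted
tags at test time.  Instances shallower than L are padded with all-`O`
upper layers so layer indexing is consistent.

## Evaluation

Scoring is per-sentence, multiset-aware precision/recall/F1 at six levels,
under the task equivalences applied to every canonical key:
`directlyIncreases ≡ increases`, `directlyDecreases ≡ decreases`, and the
activity family (`act, cat, kin, tscript, phos, gtp, pep, ribo, tport,
chap`) mapped to `act()`.  The projections:

| level | one item per | key |
|---|---|---|
| term | entity leaf | rendered term, e.g. `p(HGNC:X)` |
| function | function node | function with full inner term |
| function_secondary | (function, entity beneath it) | act-mapped name + entity term |
| relation_secondary | (relation, single argument) | collapsed type + rendered argument |
| relation | relation node | type + both arguments, ordered |
| statement | statement | full normalized string |

The secondary levels are not restated by the source task description, so the
projections above are this package's documented interpretation, isolated
behind `canonicalize()` so they can be revised without touching the
scoring arithmetic.  `F1 = 2PR/(P+R)`, zero when `P+R = 0`; empty
predictions give precision 0 by convention.

## The synthetic corpus

Real corpora for this task are not redistributable, so the package ships a
seeded generator whose pairs have *known* gold trees, parses, alignments and
tags, making every stage — and the end-to-end pipeline — testable.
Sentences come from a template grammar shaped like the task's worked
examples: an optional unaligned subject phrase ("Preincubation with …",
probability 0.3), a relation trigger drawn from a motif lexicon
("prevented" → `decreases`, "elevated" → `increases`, …), optionally a
function layer (`complex` on the object with a varying connector to/with/and,
or unary `cat`/`deg` on the subject), off-path filler modifiers, and — when
`p_or > 0` — a coordinated second clause unified under `or`.  Dependency
trees are built from the same grammar in Stanford-basic style, so
simplification provably removes the fillers and keeps the connectors.

Defaults are fixed once as the emulated conditions: `p_function = 0.5`
(roughly the "more than a third of statements contain functions" regime),
`p_or = 0.1`, `p_distractor = 0.3`, `p_noise = 0.05` (a trigger word
corrupted, emulating statement/sentence mismatch), entity vocabularies of
30/12/8/4 per type.  The *low-noise study configuration*
(`synth_config_low_noise()`) used by the parameter-recovery tests and the
acceptance script sets `p_or = 0` (three layers) and `p_noise = 0.02`, with
2,000 training pairs (seed 7 in the tests; the acceptance script derives
both corpus seeds from its `--seed`) and 200 held-out pairs from an
independent seed.  These sizes keep the full run within minutes on one CPU
while leaving every estimate comfortably stable.

What passing on this corpus shows: the pipeline's machinery — alignment,
tag generation, stacking, reconstruction, scoring — is correct and
recovers planted structure under realistic attrition.  What it does not
show: performance on real biomedical text, whose vocabulary, sentence
length, parse errors and annotation noise are far harsher; the headline
numbers reported for real corpora are roughly an order of magnitude lower
than synthetic recovery rates, and nothing here should be read as a claim
about them.

## Numerical and degenerate-input choices

* Edit distance 0 ties: longer window, then leftmost (deterministic).
* EM: probabilities are exact ratios of finite sums; no smoothing is
  applied, and unseen (target, source) pairs have probability 0 at
  extraction.
* CRF optimization: `optim` L-BFGS-B, `factr = 1e7`, `maxit = 150` per
  layer; forward-backward in log space with max-shifted log-sum-exp.
* Empty inputs: empty statement lists refuse to unify; empty token lists
  predict empty layers; an empty training corpus is an error; all-`O`
  predictions extract nothing rather than something.
* The generator restores the session RNG state after use, and all seeds are
  plain 32-bit integers.

## Known limitations

* Argument order is surface order (see above); reentrant (graph-shaped)
  statements and discontinuous spans are out of scope.
* `translocation` coordinates and other full-grammar BEL constructs beyond
  the task subset are not parsed.
* The secondary evaluation levels are an interpretation, flagged as such.
* Dictionary search is O(sentence × span) per entity and intended for
  desk-scale corpora, not whole-literature sweeps.
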