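---
title: "Context-vector augmented ABC discovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-vector augmented ABC discovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abcontext)
```

## The problem and the model

Swanson's ABC model infers an undiscovered relationship between concepts A
and C when the literature reports A–B and B–C relationships but no direct
A–C link. Applied to drug repositioning, A is a drug, C a disease, and the
bridge B a gene: a drug that modulates a gene which is itself associated
with a disease is a candidate therapy for that disease. The classical
frequency-based ABC model scores a candidate (A, C) pair by summing, over
all bridge genes, the product of the two interaction frequencies
`freq(A–B) × freq(B–C)`. Its well-known weakness is a flood of false
positives: frequent but unrelated co-occurrences dominate the ranking.

This package implements a context-aware refinement. Every interaction is
assigned a *context vector*: the average, over the abstracts supporting the
interaction, of the abstract-level counts of all other tagged biomedical
entities ("context terms"). The working hypothesis is that a genuine
A–B–C chain discusses A–B and B–C in similar biological contexts, so the
similarity between the two context vectors separates meaningful bridges
from coincidental ones.

A bridge is *meaningful* when its context similarity strictly exceeds a
threshold $\tau$. Four scores per candidate pair:

* **baseline** — $\sum_{B} f_{AB} f_{BC}$ over all bridges (frequency ABC model);
* **sum** — $\sum_{B\,:\,s_B > \tau} s_B$, the summed similarity of meaningful bridges;
* **max** — $\max_{B\,:\,s_B > \tau} s_B$ (0 when no bridge is meaningful);
* **hybrid** — $\sum_{B\,:\,s_B > \tau} f_{AB} f_{BC}$, frequency mass restricted to meaningful bridges.

Candidates with no meaningful bridge are retained with similarity scores of
0 rather than dropped, so all four rankings range over the same candidate
universe and precision@k comparisons are like-for-like.

## Pipeline stages

1. **Dictionaries.** Multi-level (gene/drug/disease/symptom) term →
   accession dictionaries, loaded from TSV. An *interaction* dictionary
   drives pair extraction; a *context* dictionary drives context counting.
   Terms are normalised by lowercasing and whitespace collapsing; a term
   may map to several accessions and levels, and synonyms share an
   accession.
2. **Corpus.** Abstracts from PubMed-style XML (title and abstract
   concatenated) or JSONL. Sentences come from a deterministic rule-based
   splitter: terminal `.`/`!`/`?` followed by whitespace and an
   uppercase letter or digit ends a sentence, except after a small
   abbreviation list ("Dr.", "Fig.", "et al.", ...). The method does not
   depend on the splitter's identity, so a statistical splitter could be
   substituted behind the same interface.
3. **Tagging.** Dictionary matching constrained to token boundaries (so
   "ache" never fires inside "headache"), with both term and text tokenised
   on non-alphanumeric characters (hyphen/space synonym variants match).
   Within a sentence the tagger is greedy left-to-right and takes the
   longest term starting at each position; matched tokens are consumed,
   which keeps same-role mentions non-overlapping. A term ambiguous across
   accessions or levels emits one mention per mapping.
4. **Interactions.** Sentence-level co-occurrence restricted to the
   drug–gene and gene–disease patterns. Frequency counts one incidence per
   sentence containing both members, regardless of mention multiplicity —
   extraction is defined at sentence granularity, and multiplying repeated
   mentions would double-count.
5. **Context vectors.** Context counting is abstract-level: all
   context-role mentions of an abstract, keyed by accession (synonyms
   collapse). The vector of an interaction averages these counts over its
   supporting abstracts; supporting abstracts with no context mentions
   still enter the denominator. An interaction's own members are excluded
   from its vector by default (they would trivially inflate
   self-similarity); `include_self_terms = TRUE` reverses this.
6. **Similarity, inference, evaluation.** Cosine or Spearman similarity
   between bridge vectors, the ABC join, the four scores, deterministic
   ranking, and precision@k against a gold-standard pair set.

## Numerical and design choices

* **Spearman definition.** The standard tie-corrected Spearman coefficient
  is used: vectors are densified over the global context vocabulary so that
  zero-valued terms participate in ties, then fractional ranks are
  correlated (Pearson on ranks, equal to $1 - 6\sum d_i^2 / (n(n^2-1))$
  when untied). Degenerate inputs — a vocabulary smaller than two terms, or
  a vector constant over the vocabulary — return `NA` with a warning, and
  an `NA` similarity is never meaningful. Cosine operates on the sparse
  form directly; the two representations are equivalent because absent
  terms are zeros.
* **Thresholds.** Reference values are exposed by
  `default_similarity_threshold()`: cosine 0.945 / 0.95 and Spearman
  0.999999999 / 0.999999998 for the two reference evaluation settings. The
  extremely tight Spearman values reflect rank correlations over a large,
  mostly-zero vocabulary, where massive zero ties push all correlations
  close to 1. "Meaningful" uses a strict `>`.
* **Tie-breaking.** Ranking is descending by score with ties broken
  ascending by (drug accession, disease accession); reruns are
  byte-identical, and precision@k is insensitive to permutations below the
  cutoff.
* **Precision denominator.** `precision_at_k()` always divides by `k`,
  even when fewer than `k` candidates exist, penalising short rankings
  consistently.
* **Overlap resolution in tagging.** Longest-match-wins with leftmost
  preference is the standard dictionary-NER convention; the greedy
  left-to-right scan implements it, and the test suite checks equivalence
  against a brute-force enumerate-then-resolve oracle.
* **Open choices resolved here.** Matching is case-insensitive (the
  minimal robust choice for dictionary NER); context counting includes
  titles (title and abstract are concatenated before tagging); context
  term identity is the accession, so synonym mentions pool; the "sum"
  score sums similarities, not frequency-weighted similarities; candidate
  pairs that also co-occur directly in the corpus are kept by default
  (`exclude_direct = TRUE` gives classical open-discovery filtering).

## The synthetic world generator

Real inputs at literature scale (tens of thousands of abstracts, full
terminology releases) are neither necessary nor practical for validating
the method's logic. `generate_world()` builds a self-contained test world
whose statistical structure mirrors what the method assumes: chains whose
two interactions share a context distribution, embedded among chains that
do not.

Each planted chain A–B–C uses a distinct drug, gene and disease, and each
of its two interactions is realised as a set of templated abstracts with
exactly three sentences: a title mentioning one member, one interaction
sentence containing both members (the single co-occurrence sentence, so
planted frequency equals abstract count), and a sentence of context terms.
Entity surfaces alternate between two synonyms per accession, exercising
synonym collapsing, and the context dictionary spans symptom terms plus
the gene and disease vocabularies, exercising multi-level context and the
member-exclusion rule.

*Coherent* chains draw context terms, with probability `coherence`, from
one shared 3-term signature distribution for both interactions (uniform
background otherwise); their (A, C) pairs form the gold standard. *Decoy*
chains use two disjoint signatures and inflate their abstract counts by
`decoy_frequency_multiplier`, so they dominate the frequency-only
baseline ranking while failing the similarity filter. Under the default
conditions (coherence 0.95, multiplier 5, 10 + 10 chains, 3 abstracts per
coherent interaction, 6 context draws per abstract over a 40-term
vocabulary) the hybrid ranking recovers coherent chains at the top while
the baseline ranks decoys first; with coherence 0 and multiplier 1 the
two rankings are statistically indistinguishable. These problem sizes were
chosen as a desk-scale analogue that keeps the full property suite fast
while leaving clear headroom between signal and noise.

What passing these tests shows — and does not show. The generator
validates the pipeline's mechanics and the planted-signal behaviour of the
scoring functions. It does not model linguistic variation, real MEDLINE
term distributions, negation, or cross-ontology ambiguity, so performance
numbers on synthetic worlds say nothing quantitative about precision on
real literature.

## Degenerate inputs and edge behaviour

Zero-norm context vectors have cosine 0 by convention. Interactions whose
only context mentions are their own members get an (empty) zero vector,
not an error; an interaction with an empty support set is a construction
error. Empty dictionaries cannot tag; empty gold files and empty rankings
evaluate to precision 0 with warnings. Malformed dictionary/gold rows are
skipped and counted in a warning rather than aborting a long run.

## Known limitations

* Dictionary matching is exact after normalisation: no fuzzy matching,
  abbreviation expansion or disambiguation beyond longest-match.
* Interactions are undirected co-occurrences; negation and relation type
  are out of scope, as are chains longer than A–B–C.
* Accession namespaces of predictions and gold standard must match; no
  cross-ontology identifier mapping is attempted.
* Spearman over a small vocabulary is dominated by zero ties and is best
  used with the large vocabularies it was intended for.
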