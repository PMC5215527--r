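---
title: "Mining and ranking gene-disease evidence: models and design choices"
author: "genevidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and ranking gene-disease evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genevidence)
```

## The problem

A sentence such as *"up-regulation of GSK-3 may contribute to cytoskeletal
pathology in AD"* is evidence that a gene participates in a disease
*through a biological event*. `genevidence` operates downstream of
named-entity and event recognition: its inputs are sentences already
annotated with gene mentions, disease mentions and events, and its job is
to (i) decide how credible each candidate evidence sentence is, (ii) turn
sentence-level evidence into per-disease gene rankings, and (iii) use
those rankings for disease-level analyses — reference-database comparison,
disease-disease relationships in a protein-interaction network, and
event-type profiles of diseases.

Entity recognition, event extraction and disease-name normalization are
explicitly out of scope: they are consumed as annotations in a JSON-Lines
corpus format. A lexicon-based `annotateSentence()` exists purely so that
toy corpora can be built in code; it is a dictionary matcher
(case-insensitive, token-boundary-aware, longest-match-first), not an NER
system.

## Evidence triples

An evidence sentence supports one *(gene, disease, event type)* triple
when the gene is the theme of an event of that type and the disease is
mentioned in the same sentence. Design decisions worth stating:

* **Offsets** are 0-based, half-open and character-based; validity methods
  enforce that every mention's span reproduces its surface text.
* **A sentence with several diseases** supports one triple per distinct
  disease id (Cartesian pairing with the theme-bearing events). Whether a
  production index should do this is genuinely open; pairing is the
  permissive choice and duplicates collapse within the sentence, so the
  gene ranker — which counts *sentences*, not events — is unaffected.
* **Event vocabulary** is closed at 15 types: seven core event types
  (gene expression, transcription, regulation, binding, localization,
  phosphorylation, protein catabolism), seven
  epigenetics/post-translational-modification types in which a reaction
  and its reverse are merged (direction does not matter for gene
  ranking), and mutation.
* The MeSH-style disease vocabulary is a flat TSV; only tree-number
  prefixes drive the mapping to top-level categories, and the
  animal-disease category (C22) is excluded from analyses.

## The evidence classifier

Candidates are scored by a discrete naive Bayes model. For a feature
vector $f_1,\dots,f_k$,

$$\mathrm{raw} \;=\; \log\frac{P(+)\,\prod_j P(f_j\mid +)}
{P(-)\,\prod_j P(f_j\mid -)},
\qquad \mathrm{norm} = \frac{1}{1+e^{-\mathrm{raw}}}.$$

The sigmoid-normalized score lies strictly in $(0,1)$ and preserves the
raw ranking; it equals the naive-Bayes posterior $P(+\mid f)$, so either
reading of "the score" is consistent. Conditionals use Laplace smoothing
$(n_{y,c}+\alpha)/(n_y+\alpha K)$ with $\alpha = 1$ by default; a category
never seen in training is scored as smoothed-unseen rather than erroring,
because at Medline scale unseen bins are routine.

The feature set deserves honesty: the two keyword-count features
(disease keywords, hallmark keywords) are the substantive,
disease-independent part — their lists are produced by embedding analogy
(below) rather than hand curation. The remaining features (token distance
from gene and disease mentions to the event trigger, event type, negation
cues, gene-mention count, sentence position) are a documented default of
plausible surface features; the exact production inventory of such systems
is typically tuned on annotated data we do not ship. Token distances count
whitespace-delimited tokens between nearest span boundaries; the negation
cue list is a deliberately small fixture-scale default
(`negationCues()`). Sentence position needs the document length, which a
lone sentence does not carry, so `extractFeatures()` takes an optional
`nSentences`; without it the bin is "first"/"middle" only.

Evaluation uses AUC (pairwise concordance with ties at 0.5 — the
Mann-Whitney statistic) and F at a fixed 0.5 threshold on the normalized
score.

## Keyword expansion by embedding analogy

Given seed pairs like ("cancer", "proliferation") and a target disease,
the query point is

$$q = v(\text{source}) - v(\text{related term}) + v(\text{disease}),$$

and the vocabulary is ranked by cosine similarity to $q$. Two analogy
orientations are defensible (the king/queen analogy is usually written
the other way round); the formula above is the default and
`reverse = TRUE` gives $v(\text{related}) - v(\text{source}) +
v(\text{disease})$. We deliberately expose both rather than guessing a
single intent. Candidates are merged across seed pairs by their maximum
score — one strong analogy suffices for keyword membership — and all seed
words and the disease word are excluded from the output. Zero-norm
vectors score 0 by convention. Embedding training is out of scope; the
module consumes the word2vec text format.

## Gene ranking

Per disease, evidence is aggregated per gene with sentence identity
$(\text{doc\_id}, \text{sid})$ and abstract identity $\text{doc\_id}$;
several triples for one gene in one sentence count that sentence once
(scored by the max of its triples). The five measures are the number of
abstracts, number of sentences, highest normalized score, sum and mean of
normalized scores. Ties on the measure value are broken by sentence count
then gene id, and tied values share the minimum rank — an arbitrary but
reproducible convention. Threshold filtering keeps evidence with
$\mathrm{norm} \ge t$; since scores are strictly inside $(0,1)$, $t=0$ is
the identity and $t=1$ empties the list.

## Reference comparison

Reference sets are read from GMT. The top-$K$ overlap ratio is pooled
($\sum_d |top_d \cap ref_d| / \sum_d \min(K, |list_d|)$) by default with a
macro-averaged variant, because published overlap figures rarely say
which; we provide both and default to pooled. Overlap significance is the
one-sided hypergeometric upper tail (Fisher test) — the natural choice
when only "p < 0.05" is specified — with the universe defaulting to the
union of all genes seen, overridable since the honest universe (all genes
mentionable in Medline) is not knowable from the inputs. Coverage bins
are quartiles of recall with 0.75 belonging to the top bin, matching the
"75–100%" phrasing such figures use.

## Disease-disease relationships

For gene sets $A, B$: overlap coefficient $C = |A\cap B|/\min(|A|,|B|)$,
Jaccard $J = |A\cap B|/|A\cup B|$, and the four-way classification
(identical / complete subset / partial overlap / complete separation).
Network separation follows the nearest-neighbour convention:

$$\langle d_{AB}\rangle = \frac{\sum_{a\in A}\min_b d(a,b) +
\sum_{b\in B}\min_a d(a,b)}{|A|+|B|},\qquad
S_{AB} = \langle d_{AB}\rangle - \tfrac{1}{2}(\langle d_{AA}\rangle +
\langle d_{BB}\rangle),$$

with unweighted shortest paths, shared genes contributing 0, singleton
within-set distance 0, genes absent from the network dropped (and
counted) and unreachable pairs excluded from means (and counted). The
alternatives — imputing a large constant for unreachable pairs, or
averaging over all pairs instead of nearest neighbours — change absolute
values but not the qualitative ordering the analyses rest on; the counts
`n_dropped` / `n_unreachable` keep the convention auditable.

GO similarity needs no ontology traversal: $S_{GO}(a,b) = 2/\min_i n_i$
over shared terms, where $n_i$ is the number of genes annotated to term
$i$ — the smallest shared term is the most specific one, provided the
annotations are pre-propagated by their producer, which we assume.
Disease-level similarity is the mean over all $|A|\cdot|B|$ cross pairs.

## Event statistics

Per-disease event distributions count deduplicated sentences
$(\text{doc\_id},\text{sid},\text{etype},\text{disease})$; sentence-level
rather than triple-level counting was chosen because the enrichment rule
is phrased over evidence *sentences*. A disease is enriched for an event
type when its ratio exceeds $\mu + 1\sigma$ across diseases. $\sigma$ is
the population standard deviation by default ($\mu+1\sigma$ describes the
observed set of diseases, not a sample from a larger one), with a
`sampleSd` flag. Group comparisons use a two-sided Mann-Whitney test for
real attributes (e.g. network degree) and Fisher's exact test for binary
flags (e.g. transcription-factor membership); the tests are our choice —
analyses of this kind rarely name them — and are recorded in the output.
All-tied input returns p = 1 with a warning rather than erroring.

## The synthetic-data generators

Every generator is a pure function of its configuration: the same seed
yields byte-identical output, and the caller's RNG stream is left
untouched. The standing study conditions (`generatorConfig()` defaults): a
60-gene, 6-disease universe, 150 abstracts, 12 planted associations with a
strict 12..1 intensity gradient, 90 decoy sentences (gene-only,
disease-only, no-event — 30 each) and 25 random background associations.
Labeled classifier data are drawn from explicit per-class categorical
distributions over the evidence feature space
(`evidenceFeatureDistributions()`); the module-structured network study
(`simulateDiseaseModules()`) uses a 6-module stochastic block model
(module size 12, within-module edge probability 0.4, between 0.02) with
two diseases of 8 genes sharing 75% planted per module and GO terms
planted per module.

What the generators emulate is the *combinatorial structure* of the
problem — planted associations under decoys, class-separated feature
distributions, modular interactomes with module-aligned function. What
they do not emulate: real Medline token statistics, realistic NER/event
noise, correlated features, hub-dominated interactome topology, or the
GO DAG. Passing tests therefore demonstrate that the statistics recover
planted structure under controlled noise — not that production
performance on Medline would match any published figure, which would
require the real corpus and curated catalogs.

## Numerical choices and problem sizes

Distances are integer BFS shortest paths; separation values are exact.
The classifier works in log space throughout, so products of small
probabilities cannot underflow at realistic feature counts. Cosine
similarity defines 0 for zero-norm vectors. Test problem sizes were
chosen to make every stochastic assertion stable at its fixed seed while
keeping the default suite under a minute: 2000 labeled instances for AUC
assertions, 200 random graphs of up to 30 nodes for the separation
oracle, permutation enumeration up to group size 8, and exhaustive
hypergeometric enumeration up to a universe of 12.

## Known limitations

* The feature inventory beyond the two keyword-count features is a
  default, not a reconstruction of any production system's supplement.
* `annotateSentence()` is a dictionary matcher; real gene/disease NER
  (and normalization) is out of scope by design.
* $S_{GO}$ ignores the GO hierarchy; it is only as good as the
  pre-propagated annotations it is given.
* The pooled-vs-macro choice for overlap ratios, the universe for
  hypergeometric tests, and the analogy direction are all exposed
  switches because the conventions are genuinely underdetermined;
  defaults are documented above.
* Cross-disease score calibration is a non-goal: normalized scores are
  comparable within a disease's evidence list, not across diseases.
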