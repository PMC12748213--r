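---
title: "Self-correcting agentic retrieval over a clinical property graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-correcting agentic retrieval over a clinical property graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphragent)
```

## The problem and the approach

Clinical question answering with a plain language model is unreliable: the
model hallucinates, and a retrieval step over unstructured text retrieves
isolated passages with no guarantee that the evidence suffices. This
package implements a different architecture: answers are grounded in an
attribute-rich *property graph* of clinical knowledge, and retrieval is
controlled by an *agentic loop* that judges whether the retrieved subgraph
can actually answer the question and, when it cannot, deterministically
refines the retrieval strategy before answering.

The pipeline for one question is:

1. **Entity linking.** Mentions in the question are resolved against a
   terminology dictionary in stages: exact match on casefolded names and
   synonyms; then Levenshtein fuzzy matching,
   $S_\text{fuzzy} = 1 - \text{edit}(s_1, s_2) / \max(|s_1|, |s_2|)$,
   keeping candidates with $S_\text{fuzzy} > 0.8$ (strict, since the
   threshold is phrased as "exceeds"); then embedding cosine ranking with
   the composite $0.5\,S_\text{fuzzy} + 0.5\,\max(0, \cos\theta)$.
   When the top two composites differ by less than 0.05 the candidate
   whose category matches the question's intent keywords wins.
2. **Query planning.** A keyword intent label (fact / diagnosis / symptom
   / causal / multi-hop / ambiguous) selects the search strategy:
   breadth-first with depth $k = 2$ for shallow lookups, depth-first with
   $k = 3$ (causal) or $k = 4$ (multi-hop) for chain exploration. Two
   generator providers independently emit a structured query; agreement of
   their canonical signatures gives consistency $C_\text{cypher} = 1$,
   divergence $0.5$ with the primary's query kept. The query is validated
   against the schema's directed relation map before execution, with one
   rewrite attempt (invert direction, else drop incompatible relation
   types).
3. **Retrieval.** BFS returns the hop-bounded neighborhood
   $\{e : \text{dist}(V_0, e) \le k\}$, truncated by (distance, insertion
   order); DFS enumerates simple directed paths of length $\le k$,
   truncated in lexicographic node-id order. Both truncations are
   tie-broken deterministically because the paper-level contract is
   byte-reproducible runs.
4. **Sufficiency decision.** Two judge models each cast 3 independent
   votes; each judge's internal consistency is
   $C_\text{internal} = \max(N_\text{suff}, N_\text{insuff}) / N_\text{total}$.
   Objective metrics are computed in parallel — coverage of the linked
   entities, node count, mean attributes per node, and the cosine between
   question and serialized context — and combined as
   $\text{Score} = 0.4\,S_\text{sem} + 0.3\,\text{Norm}(N) + 0.3\,\text{Norm}(D)$.
   If the judges agree, their verdict stands; if they disagree, the score
   arbitrates against thresholds $\tau_\text{high} = 0.70$ and
   $\tau_\text{low} = 0.40$, with the in-between region resolved
   *insufficient* — in a clinical setting the cost of answering from thin
   evidence exceeds the cost of one more retrieval round.
5. **Refinement.** On an insufficient verdict a rule tree edits the
   strategy object (never the query): low coverage raises the depth, low
   semantic relevance switches BFS/DFS once then doubles the node limit,
   low density doubles the node limit. Exactly one rule — the first that
   triggers — fires per iteration, so every change is attributable in the
   trace. The loop runs at most 3 times.
6. **Synthesis.** One generator call fuses the serialized facts into an
   answer with inline `[Fn]` citations; anchors not present in the context
   are stripped. The final confidence is
   $C = 0.3\,C_\text{cypher} + 0.3\,C_\text{decision} + 0.2\,S_\text{coverage} + 0.2\,C_\text{entity} - (k-1) \times 0.05$,
   clipped to $[0, 1]$. If no graph evidence survives, the agent answers
   from parametric knowledge alone with a mandatory not-graph-verified
   warning and all graph components zeroed.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `linker$threshold` | 0.8 | fuzzy candidate cut-off (strict `>`) |
| `linker$w_fuzzy`, `w_semantic` | 0.5 / 0.5 | composite weights |
| `linker$disambiguation_margin` | 0.05 | near-tie margin for the category tie-break |
| `decision$w_sem/w_cov/w_den` | 0.4 / 0.3 / 0.3 | overall-score weights (sum to 1) |
| `decision$tau_high`, `tau_low` | 0.70 / 0.40 | arbitration thresholds |
| `decision$tau_coverage/semantic/density` | 0.5 / 0.5 / 0.4 | optimizer triggers |
| `decision$ref_nodes`, `ref_density` | 20 / 5 | `Norm(x) = min(x/ref, 1)` references |
| `decision$n_votes` | 3 | self-consistency votes per judge |
| `confidence$w_*` | 0.3 / 0.3 / 0.2 / 0.2 | final-confidence weights |
| `confidence$iteration_penalty` | 0.05 | per extra retrieval iteration |
| `workflow$max_iterations` | 3 | refinement loop bound |
| `workflow$temperature` | 0.1 | real-generator sampling (mocks ignore it) |

The score weights, the depth mapping, the vote count, the loop bound, the
0.8 threshold, and the 0.05 iteration penalty are fixed properties of the
method. The arbitration thresholds, optimizer triggers, normalization
references, composite linker weights, disambiguation margin, and
final-confidence weights are design choices of this implementation: the
method defines the *roles* of these constants but not their values, so
they live in one configuration block (`default_config()`, overridable via
YAML with `read_config()`) and the defaults were chosen once on the
principle of mid-scale neutrality (0.5-type defaults) and clinical
conservatism (the in-between arbitration region resolves insufficient).

## Numerical and structural choices

* **Simple paths only.** The DFS path definition does not by itself forbid
  node revisits; on cyclic graphs (disease-progression loops) unrestricted
  enumeration does not terminate, so paths never revisit a node.
* **Deterministic tie-breaks.** BFS truncation keeps discovery order
  (distance, then edge insertion order); DFS truncation sorts paths
  lexicographically by node id. Both are documented contracts, tested by
  byte-identity.
* **Directedness.** The graph is directed following the schema's arrow
  conventions; traversal follows outgoing edges by default, with `"in"`
  and `"both"` modes because several natural questions (e.g. which disease
  a drug is recommended for) read the arrows backwards. The planner picks
  `"both"` whenever an anchor is not a Disease or Drug.
* **Signature comparison, not string comparison.** The dual-generation
  consistency check compares canonical tuples (sorted anchors, sorted
  relation filter, direction, intent), so cosmetic differences in rendered
  query text cannot fail it; rendered openCypher is kept for audit.
* **Normalization** of node count and density uses fixed-reference
  clipping rather than batch min–max, so a score is a property of one
  retrieval, not of whichever batch it happened to be evaluated in.
* **Degenerate inputs.** Empty context → all-zero metrics and a valid
  empty score; no linked entities → coverage defined as 1 (logged) but the
  workflow has already fallen back by then; zero-norm embeddings score 0
  with a warning; an answer with zero extractable statements is an error
  record excluded from metric aggregates.
* **Attribute conflicts** at entity merge resolve first-seen-wins with a
  conflict log; relation fusion averages `weight` arithmetically and takes
  the strongest `recommendation_strength` on the ordinal scale
  strong > conditional > weak > expert-opinion (configurable).

## What the synthetic fixtures do and do not show

`generate_fixture_kg()` builds a 40-entity / 47-relation hepatology-like
graph covering all 8 entity categories and all 11 relation types, with
evidence attributes on drug recommendations and multi-hop progression
chains (viral hepatitis → cirrhosis → hepatocellular carcinoma / liver
failure). `generate_question_set()` derives 30 questions from it — 10
one-hop factual, 10 requiring a verified 2-hop chain, 10
colloquial/ambiguous with deterministic out-of-dictionary misspellings —
each with a graph-derivable gold answer and gold entity links for the
linker precision/recall harness. Entity wiring is clinically plausible but
*invented*; the fixture exists to exercise every code path
deterministically.

Passing the fixture suite therefore demonstrates: schema enforcement,
traversal correctness against brute-force oracles, determinism of the
whole loop under seeded mock providers, loop boundedness, citation
soundness, and the algebra of every score. It does **not** demonstrate
answer quality on real clinical guidelines: the mock judge is a
token-overlap rule, the mock embedder is a hashed bag of tokens, and the
mock generator is a template — real-provider behavior (LLM judgment
quality, embedding geometry) is exactly what the provider contracts leave
open. Metric values computed on the fixture are fixture-dependent and are
not comparable to published benchmark scores.

## Scale of the shipped checks

The property tests compare BFS against all-pairs shortest-path distances
on random directed graphs of up to 30 nodes, and DFS against exhaustive
simple-path enumeration on up to 15 nodes — sizes at which the independent
oracles are unconditionally trustworthy and the whole suite stays in the
tens of seconds. The end-to-end check runs the complete 30-question
fixture through the agent twice and asserts byte-identical answers and
citation soundness.

## Known limitations

* Span detection is dictionary-driven longest-match over token n-grams
  (n ≤ 5); mentions absent from the dictionary (and farther than one fuzzy
  edit band) are invisible to the linker.
* The disambiguation tie-break uses surface intent keywords, a stand-in
  for a context model; it is deliberately simple and deterministic.
* The openCypher export and rendered queries are interop artifacts; the
  package executes its own traversals and does not parse or execute
  arbitrary Cypher.
* One refinement rule per iteration and at most 3 iterations bound
  worst-case latency but also bound how far a badly-initialized strategy
  can travel; with all-insufficient judges the agent still answers (from
  the final context, or the tagged fallback).
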