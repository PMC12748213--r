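# graphragent

Self-correcting agentic graph retrieval-augmented generation over clinical
knowledge graphs, in R.

## What problem this solves

Answering clinical questions ("what drugs are recommended for chronic
hepatitis B?", "for which etiologies of cirrhosis is transplantation
recommended?") with a bare language model risks hallucination; answering
with one-shot text retrieval risks answering from insufficient evidence.
`graphragent` grounds every answer in an attribute-rich **property graph**
(8 clinical entity categories, 11 directed relation types carrying
evidence levels, dosing regimens and confidence weights) and wraps
retrieval in an **agentic control loop** that judges whether the retrieved
subgraph suffices and deterministically refines the search strategy when
it does not. It is aimed at builders of clinical decision-support and
knowledge-graph QA systems who need every step — linking, planning,
retrieval, judging, refinement, synthesis — reproducible and auditable
offline.

## The method in brief

For a question *Q* against graph *G*:

* **Link**: exact dictionary match → Levenshtein fuzzy match
  `S_fuzzy = 1 − edit(s₁,s₂)/max(|s₁|,|s₂|)` with candidates kept when
  `S_fuzzy > 0.8` → embedding cosine ranking, composite
  `0.5·S_fuzzy + 0.5·max(0, cos θ)`.
* **Plan**: keyword intent → strategy (fact/diagnosis/symptom: BFS, k = 2;
  causal: DFS, k = 3; multi-hop: DFS, k = 4). Two generators emit the
  structured query independently; signature agreement gives
  `C_cypher = 1.0`, divergence `0.5`. The query is validated against the
  schema's directed relation map before execution (one rewrite attempt).
* **Retrieve**: BFS neighborhood `{e : dist(V₀, e) ≤ k}` or simple-path
  DFS enumeration `P(V₀, k)`, both with deterministic truncation.
* **Judge**: each of two judges casts 3 self-consistency votes,
  `C_internal = max(N_suff, N_insuff)/N_total`; objective score
  `Score = 0.4·S_sem + 0.3·Norm(N_nodes) + 0.3·Norm(D_avg)` arbitrates
  disagreements against `τ_high = 0.70` / `τ_low = 0.40`.
* **Refine** (≤ 3 iterations): first triggered rule only — low coverage →
  depth + 1; low semantic relevance → switch BFS↔DFS once, then double the
  node limit; low density → double the node limit.
* **Answer**: single synthesis call with inline `[Fn]` citations resolved
  to relation provenance, and final confidence
  `C_final = 0.3·C_cypher + 0.3·C_decision + 0.2·S_coverage + 0.2·C_entity − (k−1)×0.05`,
  clipped to [0, 1]. Without graph evidence the agent falls back to
  parametric knowledge with a mandatory warning.

Everything runs offline: generation, judging and embedding sit behind
provider contracts with seeded deterministic mocks (`make_provider_set()`),
so identical inputs give byte-identical answers and traces.

## Worked example

```r
library(graphragent)

kg   <- generate_fixture_kg(fixture_spec(seed = 7))  # synthetic hepatology-like graph
dict <- fixture_dictionary(kg)
providers <- make_provider_set()                     # deterministic mocks

ans <- run_agent("What are the symptoms of cirrhosis?", kg, dict, providers)
print(ans)
#> Q: What are the symptoms of cirrhosis?
#> Based on the knowledge graph: cirrhosis HAS_SYMPTOM jaundice (weight=0.93). [F1] cirrhosis HAS_SYMPTOM ascites (weight=0.57). [F2] cirrhosis HAS_SYMPTOM variceal bleeding (weight=0.86). [F3]
#> [confidence 1.000]
```

The answer cites three graph facts (`[F1]`–`[F3]`, each resolvable to a
relation id and its source chunks); confidence 1.000 decomposes as query
consistency 1.0 (both mock generators agreed), decision confidence 1.0
(unanimous sufficient votes from both judges), full coverage of the linked
entity, full linking confidence, and zero iteration penalty (answered in
the first round).

A misspelled mention resolves through the fuzzy stage:

```r
link_entities("How to treat cirrosis?", dict, kg)[[1]]
#> $query_span  : "cirrosis"
#> $canonical   : "cirrhosis"     # S_fuzzy = 1 - 1/9 ≈ 0.889 > 0.8
#> $entity_id   : "E003"
#> $confidence  : 0.444
#> $match_stage : "fuzzy"
```

A shell front end wraps the same functions:

```sh
Rscript inst/cli/graphragent.R make-fixtures --seed 7 --out fixtures/
Rscript inst/cli/graphragent.R ask --question "How to treat cirrosis?" \
    --kg fixtures/ --dict fixtures/dictionary.tsv
Rscript inst/cli/graphragent.R evaluate --kg fixtures/ \
    --questions fixtures/questions.jsonl --dict fixtures/dictionary.tsv --out eval/
```

`evaluate` scores each answered question with the three built-in metrics —
faithfulness `|V|/|S|` (verified over total answer statements), context
recall (gold sentences attributable to the context), and answer relevancy
(mean cosine between the question and questions regenerated from the
answer) — and writes `report.json` / `report.csv`.

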