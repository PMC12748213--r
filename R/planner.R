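#' Classify question intent
#'
#' Maps a question to one of six intent labels driving strategy selection:
#' `fact`, `diagnosis`, `symptom`, `causal`, `multi_hop`, `ambiguous`.
#' With the mock backend (and as the offline default) classification is a
#' deterministic keyword rule; a provider-backed judge may override it in
#' a real deployment, and any provider failure falls back to `fact` with
#' a warning.
#'
#' @param question Non-empty string.
#' @param judge Optional provider whose `classify(question)` returns a
#'   label; ignored when absent.
#' @return A single intent label string.
#' @export
classify_intent <- function(question, judge = NULL) {
  stopifnot(nzchar(question))
  if (!is.null(judge) && is.function(judge$classify)) {
    lab <- tryCatch(judge$classify(question), error = function(e) NULL)
    if (!is.null(lab) && lab %in% intent_labels()) return(lab)
    warning("intent provider failed; defaulting to 'fact'", call. = FALSE)
    return("fact")
  }
  q <- tolower(question)
  if (grepl("for which|which .* for ", q)) return("multi_hop")
  if (grepl("\\bwhy\\b|\\bcause[sd]?\\b|caused by|lead[s]? to|progress|result in", q))
    return("causal")
  if (grepl("symptom|sign\\b|manifest|present with", q)) return("symptom")
  if (grepl("diagnos|criteri|which test|what test", q)) return("diagnosis")
  if (grepl("feel|something wrong|bloated|not sure|stuff|gunk", q))
    return("ambiguous")
  "fact"
}

intent_labels <- function() {
  c("fact", "diagnosis", "symptom", "causal", "multi_hop", "ambiguous")
}

#' Construct a search strategy
#'
#' @param method `"BFS"` or `"DFS"`.
#' @param k Traversal depth (>= 1, capped at `k_max`).
#' @param node_limit Result-size cap (capped at `limit_max`).
#' @param k_max,limit_max Hard bounds (defaults 4 and 200).
#' @param switched_flag Whether a BFS/DFS method switch already happened.
#' @return A `search_strategy` list.
#' @export
search_strategy <- function(method, k, node_limit = 50L, k_max = 4L,
                            limit_max = 200L, switched_flag = FALSE) {
  stopifnot(method %in% c("BFS", "DFS"), k >= 1, node_limit >= 1)
  structure(list(method = method, k = min(as.integer(k), as.integer(k_max)),
                 node_limit = min(as.integer(node_limit),
                                  as.integer(limit_max)),
                 k_max = as.integer(k_max), limit_max = as.integer(limit_max),
                 switched_flag = switched_flag),
            class = "search_strategy")
}

#' Intent-to-strategy mapping
#'
#' The deterministic policy table: shallow breadth-first retrieval
#' (`k = 2`) for fact/diagnosis/symptom questions, deeper depth-first
#' path exploration for causal (`k = 3`) and multi-hop (`k = 4`)
#' questions; ambiguous questions get the shallow BFS default.
#'
#' @param intent An intent label.
#' @param node_limit Default node limit for the strategy.
#' @return A [search_strategy()].
#' @export
intent_to_strategy <- function(intent, node_limit = 50L) {
  stopifnot(intent %in% intent_labels())
  switch(intent,
         fact      = search_strategy("BFS", 2L, node_limit),
         diagnosis = search_strategy("BFS", 2L, node_limit),
         symptom   = search_strategy("BFS", 2L, node_limit),
         causal    = search_strategy("DFS", 3L, node_limit),
         multi_hop = search_strategy("DFS", 4L, node_limit),
         ambiguous = search_strategy("BFS", 2L, node_limit))
}

# Relation-type hint per intent, for the structured query payload.
intent_relation_hint <- function(intent, question = "") {
  q <- tolower(question)
  base <- switch(intent,
                 symptom   = c("HAS_SYMPTOM"),
                 diagnosis = c("IS_DIAGNOSED_BY", "REQUIRES_CRITERIA"),
                 causal    = c("IS_CAUSED_BY", "PROGRESSES_TO"),
                 character(0))
  if (length(base) == 0 && grepl("treat|drug|medicine|therapy", q) &&
      intent == "fact") {
    base <- c("RECOMMENDS_DRUG", "RECOMMENDS_TREATMENT")
  }
  base
}

query_signature <- function(anchors, relations, direction, intent) {
  paste(paste(sort(anchors), collapse = ","),
        paste(sort(relations), collapse = ","),
        direction, intent, sep = "|")
}

#' Dual-model graph-query generation with consistency check
#'
#' Both generators independently emit a structured query payload (the
#' Text-to-Cypher analogue); the payloads' canonical structural
#' signatures — sorted anchors, sorted relation filter, direction,
#' intent — are compared. Agreement yields consistency `C_cypher = 1.0`;
#' divergence yields 0.5 and the primary model's query is used. Comparing
#' signatures rather than rendered query strings makes the check robust
#' to cosmetic formatting differences.
#'
#' @param question The question.
#' @param linked_entities Non-empty list from [link_entities()].
#' @param generator_primary,generator_secondary Generator contracts.
#' @param intent Optional precomputed intent label.
#' @return List with `query` (a `graph_query`: `anchors`,
#'   `relation_filter`, `direction`, `intent`, `signature`) and `c_cypher`.
#' @export
generate_graph_query <- function(question, linked_entities,
                                 generator_primary = mock_generator("primary"),
                                 generator_secondary = mock_generator("secondary"),
                                 intent = NULL) {
  if (length(linked_entities) == 0) {
    stop("planning error: no linked entities to anchor the query",
         call. = FALSE)
  }
  if (is.null(intent)) intent <- classify_intent(question)
  anchors <- vapply(linked_entities, function(l) {
    if (!is.na(l$entity_id)) l$entity_id else l$concept_id
  }, "")
  anchor_cats <- vapply(linked_entities, function(l) l$category, "")
  # traverse outgoing arrows from Disease anchors; anything else needs the
  # incoming side too (the schema's arrows mostly originate at Disease)
  direction <- if (all(anchor_cats %in% c("Disease", "Drug"))) "out" else "both"
  req <- list(task = "plan_query", question = question, intent = intent,
              anchors = as.list(anchors),
              relation_hint = as.list(intent_relation_hint(intent, question)),
              direction = direction)
  prompt <- as.character(jsonlite::toJSON(req, auto_unbox = TRUE))
  parse_payload <- function(txt) {
    tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
             error = function(e) NULL)
  }
  p1 <- parse_payload(generator_primary$generate(prompt))
  p2 <- parse_payload(generator_secondary$generate(prompt))
  if (is.null(p1) && is.null(p2)) {
    stop("planning error: no provider returned a parseable query payload",
         call. = FALSE)
  }
  if (is.null(p1)) p1 <- p2
  sig <- function(p) query_signature(as.character(unlist(p$anchors)),
                                     as.character(unlist(p$relations)),
                                     p$direction %||% "out",
                                     p$intent %||% "fact")
  c_cypher <- if (!is.null(p2) && identical(sig(p1), sig(p2))) 1.0 else 0.5
  query <- structure(list(
    anchors = as.character(unlist(p1$anchors)),
    relation_filter = as.character(unlist(p1$relations)),
    direction = p1$direction %||% "out",
    intent = p1$intent %||% intent,
    signature = sig(p1)
  ), class = "graph_query")
  list(query = query, c_cypher = c_cypher)
}

#' Pre-execution semantic validation
#'
#' Checks every (anchor category, relation type, direction) combination in
#' the query against the schema's directed relation map, so that
#' syntactically well-formed but semantically impossible queries ("does a
#' disease treat a disease?") are intercepted before execution. An empty
#' relation filter is an unconstrained traversal and always validates.
#'
#' @param query A `graph_query`.
#' @param schema A `kg_schema`.
#' @param kg Optional graph used to look up anchor categories; anchors
#'   missing from the graph are skipped (the executor returns an empty
#'   context for them).
#' @return A `validation_result`: `ok` flag and `violations` (list of
#'   `list(relation =, reason =)`).
#' @export
validate_semantics <- function(query, schema, kg = NULL) {
  violations <- list()
  if (length(query$relation_filter) > 0) {
    for (rt in query$relation_filter) {
      if (is.null(schema$relation_types[[rt]])) {
        violations[[length(violations) + 1L]] <-
          list(relation = rt, reason = "unknown relation type")
        next
      }
      if (is.null(kg)) next
      cats <- unique(stats::na.omit(vapply(query$anchors, function(a) {
        e <- kg$entities[[a]]
        if (is.null(e)) NA_character_ else e$category
      }, "")))
      if (length(cats) == 0) next
      ok_any <- any(vapply(cats, function(cat)
        schema_compatible(schema, cat, rt, query$direction), logical(1)))
      if (!ok_any) {
        violations[[length(violations) + 1L]] <- list(
          relation = rt,
          reason = paste0("no anchor category can be the ",
                          if (query$direction == "in") "target" else "source",
                          " of ", rt))
      }
    }
  }
  structure(list(ok = length(violations) == 0, violations = violations),
            class = "validation_result")
}

#' Validate a query, rewriting once on failure
#'
#' On a semantic violation the planner attempts exactly one rewrite:
#' invert the traversal direction if that alone repairs every violation,
#' otherwise drop the incompatible relation types; then re-validate. An
#' unrepairable query raises a validation error (the workflow routes it to
#' the fallback path).
#'
#' @inheritParams validate_semantics
#' @return List with the (possibly rewritten) `query`, the final
#'   `validation` result, and `rewritten` flag.
#' @export
validate_and_rewrite <- function(query, schema, kg = NULL) {
  v <- validate_semantics(query, schema, kg)
  if (v$ok) return(list(query = query, validation = v, rewritten = FALSE))
  inverted <- query
  inverted$direction <- if (query$direction == "out") "in" else "out"
  vi <- validate_semantics(inverted, schema, kg)
  if (vi$ok) {
    inverted$signature <- query_signature(inverted$anchors,
                                          inverted$relation_filter,
                                          inverted$direction, inverted$intent)
    return(list(query = inverted, validation = vi, rewritten = TRUE))
  }
  bad <- vapply(v$violations, function(x) x$relation, "")
  repaired <- query
  repaired$relation_filter <- setdiff(query$relation_filter, bad)
  if (length(repaired$relation_filter) == 0 &&
      length(query$relation_filter) > 0) {
    stop("validation error: no schema-compatible relation types remain",
         call. = FALSE)
  }
  repaired$signature <- query_signature(repaired$anchors,
                                        repaired$relation_filter,
                                        repaired$direction, repaired$intent)
  v2 <- validate_semantics(repaired, schema, kg)
  if (!v2$ok) {
    stop("validation error: query unrepairable after one rewrite",
         call. = FALSE)
  }
  list(query = repaired, validation = v2, rewritten = TRUE)
}

#' Render a validated query as openCypher text
#'
#' Deterministic rendering for interop and audit: a MATCH with a
#' variable-length pattern bounded by the strategy depth and a LIMIT from
#' the node limit. The same query and strategy always render to
#' byte-identical text.
#'
#' @param query A `graph_query` (anchors should be graph entity ids; names
#'   are taken from `kg` when supplied, else anchors are used verbatim).
#' @param strategy A [search_strategy()].
#' @param kg Optional `property_graph` for anchor display names.
#' @return A single openCypher string.
#' @export
render_cypher <- function(query, strategy, kg = NULL) {
  names <- vapply(query$anchors, function(a) {
    if (!is.null(kg) && !is.null(kg$entities[[a]])) kg$entities[[a]]$name
    else a
  }, "")
  rel <- if (length(query$relation_filter) > 0) {
    paste0(":", paste(query$relation_filter, collapse = "|"))
  } else ""
  arrow_l <- if (query$direction == "in") "<-" else "-"
  arrow_r <- if (query$direction == "out") "->" else "-"
  where <- if (length(names) == 1) {
    paste0("WHERE n.name = ", cypher_quote(names))
  } else {
    paste0("WHERE n.name IN [",
           paste(vapply(sort(names), cypher_quote, ""), collapse = ", "), "]")
  }
  sprintf("MATCH p = (n)%s[r%s*..%d]%s(m) %s RETURN p LIMIT %d",
          arrow_l, rel, strategy$k, arrow_r, where, strategy$node_limit)
}
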