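#' Execute a validated graph query
#'
#' Runs the traversal the strategy prescribes — BFS neighborhood for
#' breadth-first strategies, simple-path DFS enumeration for depth-first
#' ones — from the query anchors, and assembles a retrieved context with
#' full provenance. Anchors absent from the graph are skipped; if none
#' remain, the context is empty (a valid state the decision module scores
#' as zero).
#'
#' @param kg A `property_graph`.
#' @param query A `graph_query`.
#' @param strategy A [search_strategy()].
#' @return A `retrieved_context`: `node_ids`, `relations` (relation ids),
#'   `paths` (for DFS), `node_attr_counts`, `text` (serialized facts with
#'   `[Fn]` anchors), `anchors` (named character, anchor token -> relation
#'   id), `provenance`.
#' @export
execute_query <- function(kg, query, strategy) {
  seeds <- intersect(query$anchors, names(kg$entities))
  if (length(seeds) == 0) {
    return(empty_context())
  }
  if (strategy$method == "BFS") {
    sg <- bfs_neighborhood(kg, seeds, strategy$k, strategy$node_limit,
                           direction = query$direction,
                           relation_filter = query$relation_filter)
    node_ids <- sg$node_ids
    rids <- sg$relations
    paths <- list()
  } else {
    ps <- dfs_paths(kg, seeds, strategy$k,
                    relation_filter = query$relation_filter,
                    path_limit = strategy$node_limit,
                    direction = query$direction)
    paths <- ps$paths
    node_ids <- unique(c(seeds, unlist(lapply(paths, function(p) p$nodes))))
    rids <- unique(unlist(lapply(paths, function(p) p$rids)))
    if (is.null(rids)) rids <- character(0)
  }
  build_context(kg, node_ids, rids, paths)
}

empty_context <- function() {
  structure(list(node_ids = character(0), relations = character(0),
                 paths = list(), node_attr_counts = list(),
                 text = "", anchors = character(0),
                 provenance = list()),
            class = "retrieved_context")
}

build_context <- function(kg, node_ids, rids, paths = list()) {
  attr_counts <- lapply(node_ids, function(id)
    length(kg$entities[[id]]$attributes))
  names(attr_counts) <- node_ids
  ser <- integrate_context_facts(kg, rids)
  structure(list(node_ids = node_ids, relations = ser$order,
                 paths = paths, node_attr_counts = attr_counts,
                 text = ser$text, anchors = ser$anchors,
                 provenance = lapply(ser$order,
                                     function(r) kg$relations[[r]]$provenance)),
            class = "retrieved_context")
}

# Deterministic fact serialization: relations ordered by (type, source id,
# target id); each fact line gets an [Fn] anchor mapping to its relation id.
integrate_context_facts <- function(kg, rids) {
  if (length(rids) == 0) {
    return(list(text = "", anchors = character(0), order = character(0)))
  }
  keys <- vapply(rids, function(r) {
    rel <- kg$relations[[r]]
    paste(rel$type, rel$source_id, rel$target_id, sep = "\x1f")
  }, "")
  rids <- rids[order(keys, method = "radix")]
  lines <- character(length(rids))
  anchors <- character(length(rids))
  for (i in seq_along(rids)) {
    rel <- kg$relations[[rids[i]]]
    src <- kg$entities[[rel$source_id]]
    tgt <- kg$entities[[rel$target_id]]
    attrs <- ""
    if (length(rel$attributes) > 0) {
      attrs <- paste0(" (", paste(vapply(names(rel$attributes), function(a)
        paste0(a, "=", format(rel$attributes[[a]])), ""),
        collapse = "; "), ")")
    }
    lines[i] <- sprintf("[F%d] %s %s %s%s.", i, src$name, rel$type,
                        tgt$name, attrs)
    anchors[i] <- rids[i]
  }
  names(anchors) <- sprintf("F%d", seq_along(rids))
  list(text = paste(lines, collapse = "\n"), anchors = anchors, order = rids)
}

#' Serialize a retrieved context
#'
#' Returns the deterministic textual form of a context: one fact line per
#' relation (ordered by relation type, then source id) carrying an `[Fn]`
#' citation anchor that maps back to the relation's provenance.
#'
#' @param context A `retrieved_context`.
#' @return A single string (empty for an empty context).
#' @export
integrate_context <- function(context) {
  context$text
}

#' Confidence breakdown for a final answer
#'
#' The final confidence combines the dual-model query-generation
#' consistency, the decision confidence, the retrieval coverage, and the
#' mean entity-linking confidence, minus an iteration penalty
#' `(k - 1) * 0.05` that discounts answers needing many refinement
#' rounds. The result is clipped to `[0, 1]`; default weights are
#' 0.3 / 0.3 / 0.2 / 0.2.
#'
#' @param c_cypher,c_decision,s_coverage,c_entity Components in `[0, 1]`.
#' @param k Iteration count at answer time (>= 1).
#' @param config `confidence` config block.
#' @return A `confidence_breakdown`: the four components, `weights`,
#'   `p_iteration`, `c_final`.
#' @export
final_confidence <- function(c_cypher, c_decision, s_coverage, c_entity,
                             k = 1L, config = default_config()$confidence) {
  w <- c(config$w_cypher, config$w_decision, config$w_coverage,
         config$w_entity)
  if (abs(sum(w) - 1) > 1e-9) {
    stop("configuration error: confidence weights must sum to 1",
         call. = FALSE)
  }
  stopifnot(k >= 1)
  p_iteration <- (k - 1) * config$iteration_penalty
  raw <- config$w_cypher * c_cypher + config$w_decision * c_decision +
    config$w_coverage * s_coverage + config$w_entity * c_entity -
    p_iteration
  structure(list(c_cypher = c_cypher, c_decision = c_decision,
                 s_coverage = s_coverage, c_entity = c_entity,
                 weights = w, k = k, p_iteration = p_iteration,
                 c_final = min(1, max(0, raw))),
            class = "confidence_breakdown")
}

#' Synthesize an answer from retrieved context
#'
#' One generator call fuses the serialized graph facts into a fluent
#' answer with inline `[Fn]` citations. Citation anchors in the returned
#' text that do not exist in the context are stripped (and logged as a
#' warning): an answer may only cite facts it was given.
#'
#' @param question The question.
#' @param context A non-empty `retrieved_context`.
#' @param generator A generator contract.
#' @param temperature Sampling temperature for real backends.
#' @return List with `text` and `stripped` (unknown anchors removed).
#' @export
synthesize_answer <- function(question, context, generator,
                              temperature = 0.1) {
  if (!nzchar(context$text)) {
    stop("cannot synthesize from an empty context", call. = FALSE)
  }
  prompt <- as.character(jsonlite::toJSON(list(
    task = "synthesize", question = question,
    fact_lines = as.list(strsplit(context$text, "\n", fixed = TRUE)[[1]])),
    auto_unbox = TRUE))
  text <- generator$generate(prompt, temperature = temperature)
  found <- unique(unlist(regmatches(text, gregexpr("\\[F[0-9]+\\]", text))))
  known <- paste0("[", names(context$anchors), "]")
  unknown <- setdiff(found, known)
  for (u in unknown) text <- gsub(u, "", text, fixed = TRUE)
  if (length(unknown) > 0) {
    warning("stripped unknown citation anchors: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  list(text = text, stripped = unknown)
}

#' Fallback answer from parametric knowledge
#'
#' Last-resort path when no graph evidence is available (linking failure,
#' unrepairable query, or empty context after the refinement loop): a
#' single generator call with no graph context, mandatorily tagged with a
#' warning that the answer is not verified against the knowledge graph.
#' All graph-evidence confidence components are 0.
#'
#' @param question The question.
#' @param generator A generator contract.
#' @param k Iteration count reached before falling back.
#' @param config Full configuration list.
#' @return A `final_answer` with `is_fallback = TRUE`.
#' @export
fallback_answer <- function(question, generator, k = 1L,
                            config = default_config()) {
  text <- tryCatch(
    generator$generate(paste0("{\"task\": \"fallback\", \"question\": ",
                              jsonlite::toJSON(question, auto_unbox = TRUE),
                              "}")),
    error = function(e) "No verified answer is available for this question.")
  warning_text <- paste(
    "WARNING: this answer was generated from the model's general knowledge",
    "and is NOT verified against the knowledge graph.")
  conf <- final_confidence(0, 0, 0, 0, k = k, config = config$confidence)
  final_answer(text = paste0(text, "\n\n", warning_text),
               confidence = conf, is_fallback = TRUE,
               warning = warning_text, citations = character(0))
}

final_answer <- function(text, confidence, is_fallback, warning = "",
                         citations = character(0), trace = list(),
                         context_text = "") {
  if (is_fallback && !nzchar(warning)) {
    stop("fallback answers must carry a warning", call. = FALSE)
  }
  structure(list(text = text, confidence = confidence,
                 is_fallback = is_fallback, warning = warning,
                 citations = citations, context_text = context_text,
                 trace = trace),
            class = "final_answer")
}

#' @export
print.final_answer <- function(x, ...) {
  cat(x$text, "\n", sep = "")
  cat(sprintf("[confidence %.3f%s]\n", x$confidence$c_final,
              if (x$is_fallback) ", FALLBACK" else ""))
  invisible(x)
}

#' Run the agentic question-answering workflow
#'
#' The full iterative loop: (1) link entities in the question against the
#' dictionary and graph; (2) generate the structured graph query with the
#' dual-generator consistency check and validate it semantically
#' (one rewrite allowed); (3) execute the retrieval; then for up to
#' `max_iterations` rounds, (4) judge context sufficiency by dual-model
#' self-consistency voting plus objective metrics, answering immediately
#' on a sufficient verdict, otherwise applying one deterministic
#' strategy-optimizer rule and re-executing the *original validated
#' query* with the updated strategy. When the loop exhausts, the agent
#' answers from the current context if non-empty, else falls back to
#' parametric knowledge with a warning. Hard failures in linking or
#' planning are routed to the fallback, never raised.
#'
#' @param question The clinical question.
#' @param kg A `property_graph`.
#' @param dictionary A `kg_dictionary`.
#' @param providers A [make_provider_set()] result.
#' @param config Configuration list ([default_config()] shape).
#' @return A `final_answer`; its `trace` element is the list of state
#'   transitions (linking, planning, per-iteration decisions, optimizer
#'   traces).
#' @export
run_agent <- function(question, kg, dictionary,
                      providers = make_provider_set(),
                      config = default_config()) {
  trace <- list()
  note <- function(stage, ...) {
    trace[[length(trace) + 1L]] <<- c(list(stage = stage), list(...))
  }
  lk <- config$linker
  linked <- tryCatch(
    link_entities(question, dictionary, kg, providers$embedder,
                  threshold = lk$threshold, w_fuzzy = lk$w_fuzzy,
                  w_semantic = lk$w_semantic,
                  disambiguation_margin = lk$disambiguation_margin),
    error = function(e) list())
  note("link", n_linked = length(linked),
       spans = vapply(linked, function(l) l$query_span, ""))
  if (length(linked) == 0) {
    note("fallback", reason = "linking failure")
    ans <- fallback_answer(question, providers$generator_primary,
                           k = 1L, config = config)
    ans$trace <- trace
    return(ans)
  }
  c_entity <- mean(vapply(linked, function(l) l$confidence, numeric(1)))
  intent <- classify_intent(question)
  plan <- tryCatch({
    gq <- generate_graph_query(question, linked,
                               providers$generator_primary,
                               providers$generator_secondary,
                               intent = intent)
    vr <- validate_and_rewrite(gq$query, kg$schema, kg)
    list(query = vr$query, c_cypher = gq$c_cypher,
         rewritten = vr$rewritten)
  }, error = function(e) e)
  if (inherits(plan, "error")) {
    note("fallback", reason = conditionMessage(plan))
    ans <- fallback_answer(question, providers$generator_primary,
                           k = 1L, config = config)
    ans$trace <- trace
    return(ans)
  }
  note("plan", intent = intent, c_cypher = plan$c_cypher,
       rewritten = plan$rewritten, signature = plan$query$signature)
  strategy <- intent_to_strategy(intent)
  context <- execute_query(kg, plan$query, strategy)
  note("retrieve", iteration = 1L, method = strategy$method,
       k = strategy$k, nodes = length(context$node_ids))
  n_votes <- config$decision$n_votes
  max_iter <- config$workflow$max_iterations
  k_used <- 1L
  decision <- NULL
  answered <- FALSE
  for (t in seq_len(max_iter)) {
    k_used <- t
    v1 <- run_votes(question, context$text, providers$judge_primary,
                    n = n_votes, seed = 100L * t)
    v2 <- run_votes(question, context$text, providers$judge_secondary,
                    n = n_votes, seed = 100L * t + 50L)
    metrics <- compute_metrics(question, context, linked,
                               providers$embedder, config$decision)
    score <- overall_score(metrics, config$decision)
    decision <- adjudicate(v1, v2, score, config$decision)
    note("evaluate", iteration = t, decision = decision$decision,
         action = decision$action, score = score,
         c_decision = decision$c_decision)
    if (decision$action == "USE_CURRENT") {
      answered <- TRUE
      break
    }
    opt <- optimize_strategy(strategy, metrics, config$decision,
                             iteration = t)
    strategy <- opt$strategy
    note("optimize", iteration = t, rule = opt$trace$rule,
         field = opt$trace$field, old = opt$trace$old, new = opt$trace$new)
    context <- execute_query(kg, plan$query, strategy)
    note("retrieve", iteration = t + 1L, method = strategy$method,
         k = strategy$k, nodes = length(context$node_ids))
  }
  if (!nzchar(context$text)) {
    note("fallback", reason = if (answered) "sufficient verdict on factless context"
         else "loop exhausted with empty context")
    ans <- fallback_answer(question, providers$generator_primary,
                           k = k_used, config = config)
    ans$trace <- trace
    return(ans)
  }
  metrics <- compute_metrics(question, context, linked,
                             providers$embedder, config$decision)
  syn <- synthesize_answer(question, context, providers$generator_primary,
                           temperature = config$workflow$temperature)
  conf <- final_confidence(plan$c_cypher,
                           if (is.null(decision)) 0 else decision$c_decision,
                           metrics$coverage, c_entity,
                           k = k_used, config = config$confidence)
  note("answer", k = k_used, c_final = conf$c_final)
  cited <- unique(unlist(regmatches(syn$text,
                                    gregexpr("\\[F[0-9]+\\]", syn$text))))
  final_answer(text = syn$text, confidence = conf, is_fallback = FALSE,
               citations = gsub("\\[|\\]", "", cited), trace = trace,
               context_text = context$text)
}

#' Write a workflow trace as JSONL
#'
#' @param answer A `final_answer` from [run_agent()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(answer, path) {
  lines <- vapply(answer$trace, function(tr)
    as.character(jsonlite::toJSON(tr, auto_unbox = TRUE, null = "null")), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
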