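test_that("execute_query assembles contexts with provenance", {
  kg <- clinic_graph()
  q <- structure(list(anchors = "d_hep", relation_filter = character(0),
                      direction = "out", intent = "fact", signature = "x"),
                 class = "graph_query")
  ctx <- execute_query(kg, q, search_strategy("BFS", 2L))
  # d_hep -> {entecavir, cirrhosis} -> {jaundice, hcc, transplant}
  expect_setequal(ctx$node_ids,
                  c("d_hep", "dr_ete", "d_cirr", "s_jau", "d_hcc", "t_tx"))
  expect_true(all(nzchar(ctx$anchors)))
  # DFS with a relation filter keeps only progression paths
  qf <- q; qf$relation_filter <- "PROGRESSES_TO"
  ctxd <- execute_query(kg, qf, search_strategy("DFS", 3L))
  types <- unlist(lapply(ctxd$paths, function(p) p$types))
  expect_true(all(types == "PROGRESSES_TO"))
  # re-execution with the same strategy is identical
  expect_identical(execute_query(kg, q, search_strategy("BFS", 2L)), ctx)
  # anchors absent from the graph give a valid empty context
  qm <- q; qm$anchors <- "missing"
  expect_length(execute_query(kg, qm, search_strategy("BFS", 2L))$node_ids, 0L)
})

test_that("context integration is deterministic with anchored fact lines", {
  kg <- clinic_graph()
  q <- structure(list(anchors = "d_cirr", relation_filter = character(0),
                      direction = "out", intent = "fact", signature = "x"),
                 class = "graph_query")
  ctx <- execute_query(kg, q, search_strategy("BFS", 1L))
  lines <- strsplit(integrate_context(ctx), "\n")[[1]]
  expect_identical(length(lines), length(ctx$anchors))
  expect_true(all(grepl("^\\[F[0-9]+\\]", lines)))
  # byte-identical across calls
  ctx2 <- execute_query(kg, q, search_strategy("BFS", 1L))
  expect_identical(integrate_context(ctx2), integrate_context(ctx))
  # relation attributes (dosing) are rendered on the fact line
  qh <- q; qh$anchors <- "d_hep"
  ctxh <- execute_query(kg, qh, search_strategy("BFS", 1L))
  expect_match(integrate_context(ctxh), "dosage=0.5 mg")
})

test_that("synthesized answers cite only known anchors", {
  kg <- clinic_graph()
  q <- structure(list(anchors = "d_cirr", relation_filter = character(0),
                      direction = "out", intent = "fact", signature = "x"),
                 class = "graph_query")
  ctx <- execute_query(kg, q, search_strategy("BFS", 1L))
  syn <- synthesize_answer("What about cirrhosis?", ctx, mock_generator())
  cited <- unlist(regmatches(syn$text, gregexpr("\\[F[0-9]+\\]", syn$text)))
  expect_setequal(unique(cited), paste0("[", names(ctx$anchors), "]"))
  # a generator hallucinating an unknown anchor gets it stripped
  bad_gen <- list(kind = "mock_generator", model_id = "bad",
                  generate = function(prompt, temperature = 0.1, seed = 0L)
                    "Claim one [F1]. Hallucinated claim [F9].")
  expect_warning(
    syn2 <- synthesize_answer("q", ctx, bad_gen),
    "F9")
  expect_false(grepl("[F9]", syn2$text, fixed = TRUE))
  # empty context violates the precondition
  expect_error(synthesize_answer("q", empty_ctx <- execute_query(
    kg, {qq <- q; qq$anchors <- "missing"; qq}, search_strategy("BFS", 1L)),
    mock_generator()), "empty context")
})

test_that("final confidence implements the weighted sum with penalty", {
  c1 <- final_confidence(1, 1, 1, 1, k = 1)
  expect_equal(c1$c_final, 1.0)
  expect_equal(c1$p_iteration, 0)
  c3 <- final_confidence(1, 1, 1, 1, k = 3)
  expect_equal(c3$p_iteration, 0.10)
  expect_equal(c3$c_final, 0.90)
  c2 <- final_confidence(0.5, 0.5, 0.5, 0.5, k = 2)
  expect_equal(c2$p_iteration, 0.05)
  expect_equal(c2$c_final, 0.45)
  # clipped at zero
  expect_equal(final_confidence(0, 0, 0, 0, k = 3)$c_final, 0)
  # weight misconfiguration is rejected
  bad <- default_config()$confidence; bad$w_cypher <- 0.9
  expect_error(final_confidence(1, 1, 1, 1, config = bad),
               "configuration error")
})

test_that("final confidence is monotone in k and in each component", {
  for (k in 1:3) {
    expect_gte(final_confidence(0.8, 0.8, 0.8, 0.8, k = k)$c_final,
               final_confidence(0.8, 0.8, 0.8, 0.8, k = k + 1)$c_final)
  }
  base <- final_confidence(0.5, 0.5, 0.5, 0.5, k = 2)$c_final
  for (i in 1:4) {
    comps <- rep(0.5, 4); comps[i] <- 0.9
    expect_gte(final_confidence(comps[1], comps[2], comps[3], comps[4],
                                k = 2)$c_final, base)
  }
})

test_that("a sufficient verdict answers in one iteration", {
  kg <- clinic_graph()
  dict <- clinic_dictionary()
  prov <- make_provider_set(list(judge_mode = "sufficient"))
  ans <- run_agent("What are the symptoms of cirrhosis?", kg, dict, prov)
  expect_false(ans$is_fallback)
  expect_equal(ans$confidence$p_iteration, 0)
  evals <- Filter(function(t) t$stage == "evaluate", ans$trace)
  expect_length(evals, 1L)
  expect_match(ans$text, "jaundice")
  expect_gte(length(ans$citations), 1L)
})

test_that("an always-insufficient judge triggers exactly three refinements", {
  kg <- clinic_graph()
  dict <- clinic_dictionary()
  prov <- make_provider_set(list(judge_mode = "insufficient"))
  ans <- run_agent("What are the symptoms of cirrhosis?", kg, dict, prov)
  opts <- Filter(function(t) t$stage == "optimize", ans$trace)
  expect_length(opts, 3L)
  # non-empty context at loop exhaustion: answer from current context
  expect_false(ans$is_fallback)
  expect_equal(ans$confidence$p_iteration, (3 - 1) * 0.05)
})

test_that("unlinkable questions fall back with a warning", {
  kg <- clinic_graph()
  dict <- clinic_dictionary()
  ans <- run_agent("What is 'liver gunk'?", kg, dict, make_provider_set())
  expect_true(ans$is_fallback)
  expect_match(ans$warning, "NOT verified")
  expect_match(ans$text, "WARNING")
  expect_length(ans$citations, 0L)
  # graph-evidence confidence components are all zero
  expect_equal(ans$confidence$c_cypher, 0)
  expect_equal(ans$confidence$c_entity, 0)
  # empty KG: everything falls back
  ans2 <- run_agent("What are the symptoms of cirrhosis?", property_graph(),
                    clinic_dictionary(), make_provider_set())
  expect_true(ans2$is_fallback)
  expect_true(nzchar(ans2$warning))
  # fallback confidence never exceeds a sufficient graph-grounded answer
  good <- run_agent("What are the symptoms of cirrhosis?", kg, dict,
                    make_provider_set(list(judge_mode = "sufficient")))
  expect_lte(ans$confidence$c_final, good$confidence$c_final)
})

test_that("the workflow is fully deterministic under mock providers", {
  kg <- clinic_graph()
  dict <- clinic_dictionary()
  a1 <- run_agent("How to treat cirrosis?", kg, dict, make_provider_set())
  a2 <- run_agent("How to treat cirrosis?", kg, dict, make_provider_set())
  expect_identical(a1$text, a2$text)
  expect_identical(a1$confidence, a2$confidence)
  expect_identical(a1$trace, a2$trace)
  # trace serializes as JSONL
  tf <- withr::local_tempfile(fileext = ".jsonl")
  write_trace(a1, tf)
  expect_gte(length(readLines(tf)), 3L)
})
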