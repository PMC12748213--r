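test_that("faithfulness is the verified-statement fraction", {
  ctx <- "cirrhosis manifests with jaundice. cirrhosis progresses to carcinoma."
  # every sentence supported
  f1 <- faithfulness("cirrhosis manifests with jaundice.", ctx)
  expect_equal(f1$f, 1.0)
  # one of two statements unsupported
  f2 <- faithfulness(
    "cirrhosis manifests with jaundice. unrelated quantum chromodynamics claim.",
    ctx)
  expect_equal(f2$f, 0.5)
  expect_identical(f2$n_statements, 2L)
  # empty answer -> error record, not a crash
  f3 <- faithfulness("", ctx)
  expect_true(is.na(f3$f))
  expect_match(f3$error, "no statements")
})

test_that("context recall attributes gold sentences to the context", {
  ctx <- "cirrhosis manifests with jaundice. entecavir is recommended."
  expect_equal(context_recall("cirrhosis manifests with jaundice.", ctx)$cr,
               1.0)
  expect_equal(context_recall(
    "totally unrelated alpha. second unrelated beta. third unrelated gamma.",
    ctx)$cr, 0.0)
  cr <- context_recall(paste(
    "cirrhosis manifests with jaundice.",
    "entecavir is recommended.",
    "unrelated delta claim.",
    "unrelated epsilon claim."), ctx)
  expect_equal(cr$cr, 0.5)
  expect_identical(cr$n_sentences, 4L)
})

test_that("answer relevancy is the mean question-embedding cosine", {
  emb <- mock_embedder()
  # generator echoing the original question n times -> AR = 1
  echo_gen <- list(kind = "mock_generator", model_id = "echo",
                   generate = function(prompt, temperature = 0.1, seed = 0L) {
                     req <- jsonlite::fromJSON(prompt)
                     jsonlite::toJSON(rep("what about cirrhosis?",
                                          req$n))
                   })
  ar1 <- answer_relevancy("what about cirrhosis?", "some answer.",
                          echo_gen, emb)
  expect_equal(ar1$ar, 1.0)
  # token-disjoint questions under the hash embedder -> near zero
  ortho_gen <- list(kind = "mock_generator", model_id = "ortho",
                    generate = function(prompt, temperature = 0.1, seed = 0L)
                      jsonlite::toJSON(c("zzyx qqfw pplm", "mnbv ccxz aass")))
  ar0 <- answer_relevancy("what about cirrhosis?", "some answer.",
                          ortho_gen, emb, n = 2)
  expect_lte(abs(ar0$ar), 0.15)
  # n = 1 equals the single-pair cosine
  one_gen <- list(kind = "mock_generator", model_id = "one",
                  generate = function(prompt, temperature = 0.1, seed = 0L)
                    jsonlite::toJSON("cirrhosis question"))
  ar <- answer_relevancy("what about cirrhosis?", "x.", one_gen, emb, n = 1)
  expect_equal(ar$ar, cosine_similarity(emb$embed("what about cirrhosis?"),
                                        emb$embed("cirrhosis question")))
})

test_that("the fixture graph is deterministic, schema-valid, multi-hop", {
  g1 <- generate_fixture_kg(fixture_spec(seed = 7))
  g2 <- generate_fixture_kg(fixture_spec(seed = 7))
  e1 <- withr::local_tempfile(); r1 <- withr::local_tempfile()
  e2 <- withr::local_tempfile(); r2 <- withr::local_tempfile()
  write_graph_jsonl(g1, e1, r1); write_graph_jsonl(g2, e2, r2)
  expect_identical(readLines(e1), readLines(e2))
  expect_identical(readLines(r1), readLines(r2))
  # schema validity is enforced at construction; spot-check the report
  rep <- qc_report(g1)
  expect_identical(rep$dangling_reference_count, 0L)
  expect_length(rep$relations_per_type, 11L)  # all relation types wired
  expect_length(rep$entities_per_type, 8L)
  # at least one 2-hop chain exists so multi-hop questions are answerable
  dz <- names(Filter(function(e) e$category == "Disease", g1$entities))
  long_paths <- unlist(lapply(dz, function(id)
    lapply(dfs_paths(g1, id, k = 2)$paths, function(p) length(p$nodes))))
  expect_true(any(long_paths >= 3))
})

test_that("the question set has the designed composition and gold support", {
  g <- generate_fixture_kg()
  dict <- fixture_dictionary(g)
  qs <- generate_question_set(g, dictionary = dict)
  expect_length(qs, 30L)
  cats <- vapply(qs, function(r) r$category, "")
  expect_identical(as.integer(table(cats)[c("factual", "multi_hop",
                                            "ambiguous")]),
                   c(10L, 10L, 10L))
  # every ambiguous question contains a surface form absent from the dictionary
  for (r in Filter(function(r) r$category == "ambiguous", qs)) {
    expect_false(normalize_name(r$surface) %in% names(dict$exact_index))
    expect_true(grepl(r$surface, r$question, fixed = TRUE))
  }
  # every multi-hop gold path exists in the graph
  for (r in Filter(function(r) r$category == "multi_hop", qs)) {
    ps <- dfs_paths(g, r$path[[1]], k = 2, path_limit = 10000L)
    keys <- vapply(ps$paths, function(p) paste(p$nodes, collapse = "|"), "")
    expect_true(paste(unlist(r$path), collapse = "|") %in% keys)
  }
  # gold links support the linker P/R/F1 harness
  emb <- mock_embedder()
  factual <- Filter(function(r) r$category == "factual", qs)
  preds <- lapply(factual, function(r)
    link_entities(r$question, dict, g, emb))
  prf <- linker_prf(preds, lapply(factual, function(r) r$gold_links))
  expect_gte(unname(prf["recall"]), 0.9)
})

test_that("batch evaluation aggregates per-record metrics", {
  recs <- list(
    list(question = "q one about cirrhosis jaundice",
         category = "factual",
         gold = "cirrhosis manifests with jaundice.",
         answer = "cirrhosis manifests with jaundice.",
         context_text = "cirrhosis manifests with jaundice."),
    list(question = "q two about entecavir hepatitis",
         category = "factual",
         gold = "entecavir is recommended for hepatitis.",
         answer = "entecavir is recommended for hepatitis.",
         context_text = "entecavir is recommended for hepatitis.")
  )
  rep <- evaluate_run(recs)
  expect_identical(nrow(rep$per_record), 2L)
  expect_equal(rep$aggregate$faithfulness, 1.0)
  expect_equal(rep$aggregate$context_recall, 1.0)
  expect_equal(rep$aggregate$faithfulness,
               mean(rep$per_record$faithfulness))
  expect_equal(rep$aggregate$answer_relevancy,
               mean(rep$per_record$answer_relevancy))
  # report writes both formats
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, jp, cp)
  expect_identical(nrow(utils::read.csv(cp)), 2L)
  expect_no_error(jsonlite::read_json(jp))
})
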