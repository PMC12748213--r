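# independent sentence splitter used as the reconstruction oracle
oracle_sentences <- function(text) {
  regmatches(text, gregexpr("[^.!?]*[.!?]+\\s*", text))[[1]]
}

test_that("chunking covers the document and respects the overlap", {
  sents <- sprintf("Sentence number %d is here.", 1:10)
  doc <- paste(sents, collapse = " ")
  chunks <- chunk_text(doc, max_units = 4, overlap = 1)
  for (s in sents) {
    expect_true(any(vapply(chunks, function(ch)
      grepl(s, ch$text, fixed = TRUE), logical(1))), label = s)
  }
  # consecutive chunks share exactly `overlap` sentences
  for (i in seq_len(length(chunks) - 1)) {
    expect_identical(chunks[[i + 1]]$start, chunks[[i]]$end)
  }
})

test_that("short documents yield a single chunk equal to the input", {
  doc <- "Only one sentence here."
  ch <- chunk_text(doc, max_units = 5, overlap = 1)
  expect_length(ch, 1L)
  expect_identical(ch[[1]]$text, doc)
  expect_length(chunk_text("", 5, 1), 0L)
})

test_that("chunks reassemble to the original document", {
  set.seed(42)
  sents <- sprintf("Synthetic sentence %d mentions topic %s.", 1:100,
                   sample(letters, 100, replace = TRUE))
  doc <- paste(sents, collapse = " ")
  for (ov in c(0, 1, 2)) {
    chunks <- chunk_text(doc, max_units = 7, overlap = ov)
    rebuilt <- chunks[[1]]$text
    for (i in seq_along(chunks)[-1]) {
      pieces <- oracle_sentences(chunks[[i]]$text)
      rebuilt <- paste0(rebuilt,
                        paste(utils::tail(pieces, length(pieces) - ov),
                              collapse = ""))
    }
    expect_identical(rebuilt, doc)
  }
})

test_that("extraction payloads are validated record by record", {
  payload <- jsonlite::toJSON(list(
    entities = list(
      list(surface = "cirrhosis", category = "Disease"),
      list(surface = "entecavir", category = "Drug"),
      list(surface = "weirdness", category = "NotAType")
    ),
    relations = list(
      list(source = "cirrhosis", target = "entecavir",
           type = "RECOMMENDS_DRUG"),
      list(source = "entecavir", target = "cirrhosis",
           type = "RECOMMENDS_DRUG")  # direction violation
    )), auto_unbox = TRUE)
  ext <- parse_extraction(as.character(payload))
  expect_length(ext$entities, 2L)
  expect_length(ext$relations, 1L)
  expect_length(ext$rejected, 2L)
  reasons <- vapply(ext$rejected, function(r) r$reason, "")
  expect_true(any(grepl("unknown entity category", reasons)))
  expect_true(any(grepl("incompatible", reasons)))

  # empty object -> empty extraction; garbage -> recoverable parse error
  expect_length(parse_extraction("{}")$entities, 0L)
  bad <- parse_extraction("not json {")
  expect_length(bad$entities, 0L)
  expect_match(bad$errors, "not valid JSON")
})

test_that("deduplication is CUI-first with normalized-name fallback", {
  recs <- list(
    list(surface = "fatty liver", category = "Disease", cui = "C0015695"),
    list(surface = "hepatic steatosis", category = "Disease",
         cui = "C0015695"),
    list(surface = "Cirrhosis ", category = "Disease"),
    list(surface = "cirrhosis", category = "Disease"),
    list(surface = "thing", category = "Disease", cui = "C0000001"),
    list(surface = "thing", category = "Disease", cui = "C0000002")
  )
  dd <- dedup_entities(recs)
  expect_length(dd$entities, 4L)  # fatty-liver pair, cirrhosis pair, 2 CUIs
  # same-CUI pair merged despite different names
  cuis <- vapply(dd$entities, function(e) e$cui %||% "", "")
  expect_identical(sum(cuis == "C0015695"), 1L)
  # distinct CUIs with identical names stay distinct (CUI outranks name)
  expect_identical(sum(vapply(dd$entities, function(e)
    normalize_name(e$name) == "thing", logical(1))), 2L)
})

test_that("deduplication is idempotent", {
  recs <- list(
    list(surface = "A Disease", category = "Disease", cui = "C1"),
    list(surface = "a  disease", category = "Disease"),
    list(surface = "Other", category = "Disease")
  )
  dd1 <- dedup_entities(recs)
  again <- lapply(dd1$entities, function(e)
    list(surface = e$raw_name, category = e$category, cui = e$cui))
  dd2 <- dedup_entities(again)
  expect_identical(length(dd2$entities), length(dd1$entities))
  expect_identical(vapply(dd2$entities, function(e) e$name, ""),
                   vapply(dd1$entities, function(e) e$name, ""))
})

test_that("relation fusion averages weights and takes strongest strength", {
  recs <- list(
    list(surface = "cirrhosis", category = "Disease"),
    list(surface = "propranolol", category = "Drug")
  )
  dd <- dedup_entities(recs)
  rels <- list(
    list(source = "cirrhosis", target = "propranolol",
         type = "RECOMMENDS_DRUG",
         attributes = list(weight = 0.8, recommendation_strength = "conditional"),
         chunk_id = "chunk-001"),
    list(source = "cirrhosis", target = "propranolol",
         type = "RECOMMENDS_DRUG",
         attributes = list(weight = 0.6, recommendation_strength = "strong"),
         chunk_id = "chunk-002")
  )
  fused <- fuse_relations(rels, dd$merge_map)
  expect_length(fused, 1L)
  expect_equal(fused[[1]]$attributes$weight, 0.7)
  expect_identical(fused[[1]]$attributes$recommendation_strength, "strong")
  expect_setequal(fused[[1]]$provenance, c("chunk-001", "chunk-002"))

  # single relation passes through unchanged
  single <- fuse_relations(rels[1], dd$merge_map)
  expect_equal(single[[1]]$attributes$weight, 0.8)

  # unknown strength label is a fusion error naming the label
  bad <- rels
  bad[[1]]$attributes$recommendation_strength <- "platinum"
  expect_error(fuse_relations(bad, dd$merge_map), "platinum")
})

test_that("fused weights stay within member bounds on random groups", {
  set.seed(7)
  for (rep in 1:20) {
    k <- sample(1:5, 1)
    ws <- round(runif(k), 3)
    recs <- list(list(surface = "a disease", category = "Disease"),
                 list(surface = "b drug", category = "Drug"))
    dd <- dedup_entities(recs)
    rels <- lapply(ws, function(w)
      list(source = "a disease", target = "b drug",
           type = "RECOMMENDS_DRUG", attributes = list(weight = w)))
    fused <- fuse_relations(rels, dd$merge_map)
    expect_length(fused, 1L)
    w <- fused[[1]]$attributes$weight
    expect_gte(w, min(ws)); expect_lte(w, max(ws))
  }
})

test_that("review ledger applies exact set algebra", {
  mk <- function(id) entity(id, paste("disease", id), "Disease")
  extracted <- lapply(c("a", "b", "c"), mk)
  out <- apply_review(extracted, list(remove = "b", add = list(mk("d"))))
  expect_setequal(vapply(out, function(e) e$id, ""), c("a", "c", "d"))
  # empty ledger is the identity
  out2 <- apply_review(extracted, list())
  expect_identical(vapply(out2, function(e) e$id, ""), c("a", "b", "c"))
  # adding an existing entity keeps set semantics
  out3 <- apply_review(extracted, list(add = list(mk("a"))))
  expect_identical(sum(vapply(out3, function(e) e$id, "") == "a"), 1L)
  # removal of an absent key warns but does not fail
  expect_warning(apply_review(extracted, list(remove = "zz")), "absent")
  # overlapping remove/add violates the ledger invariant
  expect_error(apply_review(extracted, list(remove = "a",
                                            add = list(mk("a")))),
               "overlap")
})

test_that("review matches a brute-force set-algebra oracle", {
  mk <- function(id) entity(id, paste("disease", id), "Disease")
  set.seed(31)
  for (rep in 1:25) {
    universe <- letters[1:10]
    ellm <- sample(universe, sample(3:8, 1))
    erem <- sample(ellm, sample(0:2, 1))
    eadd <- sample(setdiff(universe, erem), sample(0:3, 1))
    got <- suppressWarnings(apply_review(
      lapply(ellm, mk), list(remove = erem, add = lapply(eadd, mk))))
    want <- union(setdiff(ellm, erem), eadd)
    expect_setequal(vapply(got, function(e) e$id, ""), want)
  }
})

test_that("qc reports count the graph faithfully", {
  g <- clinic_graph()
  rep <- qc_report(g)
  expect_identical(rep$entity_count, length(g$entities))
  expect_identical(rep$relation_count, length(g$relations))
  expect_identical(rep$dangling_reference_count, 0L)
  # the one RECOMMENDS_DRUG has evidence_level but no
  # recommendation_strength, weight or approval_status
  comp <- rep$attribute_completeness$RECOMMENDS_DRUG
  expect_equal(unname(comp["evidence_level"]), 1)
  expect_equal(unname(comp["recommendation_strength"]), 0)
  expect_equal(unname(comp["weight"]), 1)
  # empty graph -> all-zero report, still JSON-serializable
  rep0 <- qc_report(property_graph())
  expect_identical(rep0$entity_count, 0L)
  expect_identical(rep0$relation_count, 0L)
  expect_no_error(jsonlite::toJSON(unclass(rep0), auto_unbox = TRUE))
})

test_that("the build pipeline is deterministic to the byte", {
  payload <- as.character(jsonlite::toJSON(list(
    entities = list(
      list(surface = "cirrhosis", category = "Disease", cui = "C0023890"),
      list(surface = "Cirrhosis", category = "Disease"),
      list(surface = "propranolol", category = "Drug")
    ),
    relations = list(
      list(source = "cirrhosis", target = "propranolol",
           type = "RECOMMENDS_DRUG", attributes = list(weight = 0.8)),
      list(source = "Cirrhosis", target = "propranolol",
           type = "RECOMMENDS_DRUG", attributes = list(weight = 0.6))
    )), auto_unbox = TRUE))
  files <- replicate(2, {
    built <- build_kg(c(payload, payload))
    ep <- tempfile(fileext = ".jsonl"); rp <- tempfile(fileext = ".jsonl")
    write_graph_jsonl(built$graph, ep, rp)
    c(ep, rp)
  })
  expect_identical(readLines(files[1, 1]), readLines(files[1, 2]))
  expect_identical(readLines(files[2, 1]), readLines(files[2, 2]))
  built <- build_kg(c(payload, payload))
  # dedup by CUI/name and fusion by triple leave one entity pair + one edge
  expect_identical(unname(graph_size(built$graph)), c(2L, 1L))
  rel <- built$graph$relations[[1]]
  expect_equal(rel$attributes$weight, 0.7)
})
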