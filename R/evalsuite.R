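#' @name evalsuite
#' @title RAGAS-style evaluation metrics and synthetic fixtures
#'
#' @description
#' Three automated answer-quality metrics — faithfulness, context recall,
#' answer relevancy — plus a seeded generator for a synthetic
#' hepatology-like knowledge graph, its terminology dictionary, and a
#' 30-question evaluation set (10 factual / 10 multi-hop / 10 ambiguous).
#' The fixture is synthetic throughout: entity wiring is clinically
#' plausible but invented, and exists to exercise every relation type and
#' workflow branch deterministically, not to encode real guideline
#' content.
NULL

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

strip_anchors <- function(text) {
  trimws(gsub("\\s*\\[F[0-9]+\\]", "", text))
}

#' Faithfulness of an answer to its retrieved context
#'
#' Splits the answer into statements (generator-backed; the mock splits on
#' sentence boundaries), verifies each against the context with the judge
#' (the mock uses its token-overlap rule), and returns the fraction of
#' verified statements `|V| / |S|`. An answer yielding zero statements is
#' undefined: the record carries `f = NA` and an error message, and is
#' excluded from aggregates.
#'
#' @param answer Generated answer text.
#' @param context_text Serialized retrieved context.
#' @param generator,judge Provider contracts.
#' @return List: `f`, `n_statements`, `n_verified`, `statements`,
#'   `verified` (logical), `error` (`NULL` when defined).
#' @export
faithfulness <- function(answer, context_text,
                         generator = mock_generator(),
                         judge = mock_judge()) {
  clean <- strip_anchors(answer)
  stmts <- tryCatch({
    out <- generator$generate(as.character(jsonlite::toJSON(
      list(task = "extract_statements", answer = clean), auto_unbox = TRUE)))
    as.character(unlist(jsonlite::fromJSON(out, simplifyVector = FALSE)))
  }, error = function(e) character(0))
  stmts <- stmts[nzchar(trimws(stmts))]
  if (length(stmts) == 0) {
    return(list(f = NA_real_, n_statements = 0L, n_verified = 0L,
                statements = character(0), verified = logical(0),
                error = "no statements extracted from answer"))
  }
  verified <- vapply(stmts, function(s)
    identical(judge$vote(s, context_text), "sufficient"), logical(1))
  list(f = sum(verified) / length(stmts), n_statements = length(stmts),
       n_verified = sum(verified), statements = stmts, verified = verified,
       error = NULL)
}

#' Context recall of the retrieval
#'
#' Fraction of gold-answer sentences attributable to the retrieved
#' context, judged sentence by sentence (the mock judge attributes a
#' sentence when enough of its content tokens occur in the context).
#'
#' @param gold_answer Gold-standard answer text (non-empty).
#' @param context_text Serialized retrieved context.
#' @param judge Judge contract.
#' @return List: `cr`, `n_sentences`, `n_attributed`, `attributed`.
#' @export
context_recall <- function(gold_answer, context_text, judge = mock_judge()) {
  stopifnot(nzchar(gold_answer))
  sents <- trimws(split_sentences(gold_answer))
  sents <- sents[nzchar(sents)]
  attributed <- vapply(sents, function(s)
    identical(judge$vote(s, context_text), "sufficient"), logical(1))
  list(cr = if (length(sents) == 0) 0 else sum(attributed) / length(sents),
       n_sentences = length(sents), n_attributed = sum(attributed),
       attributed = attributed)
}

#' Answer relevancy to the original question
#'
#' Generates `n` candidate questions from the answer (generator-backed;
#' the mock applies fixed question templates to the answer's leading
#' content tokens) and returns the mean embedding cosine between each
#' candidate and the original question.
#'
#' @param question Original question.
#' @param answer Generated answer (non-empty).
#' @param generator,embedder Provider contracts.
#' @param n Number of regenerated questions (default 3).
#' @return List: `ar`, `questions`, `similarities`, `error`.
#' @export
answer_relevancy <- function(question, answer,
                             generator = mock_generator(),
                             embedder = mock_embedder(), n = 3L) {
  stopifnot(nzchar(answer), n >= 1)
  qs <- tryCatch({
    out <- generator$generate(as.character(jsonlite::toJSON(
      list(task = "regenerate_questions", answer = strip_anchors(answer),
           n = n), auto_unbox = TRUE)))
    as.character(unlist(jsonlite::fromJSON(out, simplifyVector = FALSE)))
  }, error = function(e) character(0))
  if (length(qs) == 0) {
    return(list(ar = NA_real_, questions = character(0),
                similarities = numeric(0),
                error = "generator returned no questions"))
  }
  vq <- embedder$embed(question)
  sims <- vapply(qs, function(q2) cosine_similarity(vq, embedder$embed(q2)),
                 numeric(1))
  list(ar = mean(sims), questions = qs, similarities = unname(sims),
       error = NULL)
}

#' Fixture specification
#'
#' @param seed Seed for all random attribute draws.
#' @param questions Named integer vector of question counts per category.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 7L,
                         questions = c(factual = 10L, multi_hop = 10L,
                                       ambiguous = 10L)) {
  stopifnot(all(c("factual", "multi_hop", "ambiguous") %in% names(questions)))
  structure(list(seed = as.integer(seed), questions = questions),
            class = "fixture_spec")
}

fixture_roster <- function() {
  list(
    Disease = c("hepatitis b", "hepatitis c", "cirrhosis",
                "hepatocellular carcinoma", "fatty liver",
                "alcoholic hepatitis", "liver failure",
                "autoimmune hepatitis"),
    Drug = c("entecavir", "tenofovir", "sofosbuvir", "ribavirin",
             "prednisolone", "propranolol"),
    Gene = c("tp53", "hfe", "pnpla3", "ifnl4"),
    `Symptom/Sign` = c("jaundice", "ascites", "fatigue", "abdominal pain",
                       "pruritus", "variceal bleeding"),
    `Examination/Test` = c("liver biopsy", "abdominal ultrasound",
                           "alanine aminotransferase test",
                           "transient elastography"),
    Treatment = c("liver transplantation", "lifestyle modification",
                  "paracentesis", "endoscopic band ligation"),
    `Etiology/Risk Factor` = c("hepatitis b virus", "hepatitis c virus",
                               "chronic alcohol use", "obesity",
                               "aflatoxin exposure"),
    `Clinical Criteria` = c("child-pugh score", "meld score",
                            "milan criteria")
  )
}

fixture_wiring <- function() {
  # (type, source name, target name); every one of the 11 types appears
  rbindlist <- function(...) do.call(rbind, list(...))
  m <- rbindlist(
    c("RECOMMENDS_DRUG", "hepatitis b", "entecavir"),
    c("RECOMMENDS_DRUG", "hepatitis b", "tenofovir"),
    c("RECOMMENDS_DRUG", "hepatitis c", "sofosbuvir"),
    c("RECOMMENDS_DRUG", "hepatitis c", "ribavirin"),
    c("RECOMMENDS_DRUG", "autoimmune hepatitis", "prednisolone"),
    c("RECOMMENDS_DRUG", "cirrhosis", "propranolol"),
    c("HAS_ADVERSE_EFFECT", "ribavirin", "fatigue"),
    c("HAS_ADVERSE_EFFECT", "prednisolone", "abdominal pain"),
    c("HAS_ADVERSE_EFFECT", "propranolol", "fatigue"),
    c("ASSOCIATED_WITH_GENE", "hepatocellular carcinoma", "tp53"),
    c("ASSOCIATED_WITH_GENE", "fatty liver", "pnpla3"),
    c("ASSOCIATED_WITH_GENE", "hepatitis c", "ifnl4"),
    c("TARGETS_GENE", "sofosbuvir", "ifnl4"),
    c("TARGETS_GENE", "tenofovir", "hfe"),
    c("IS_CONTRAINDICATED_FOR", "ribavirin", "liver failure"),
    c("IS_CONTRAINDICATED_FOR", "propranolol", "liver failure"),
    c("REQUIRES_CRITERIA", "cirrhosis", "child-pugh score"),
    c("REQUIRES_CRITERIA", "liver failure", "meld score"),
    c("REQUIRES_CRITERIA", "hepatocellular carcinoma", "milan criteria"),
    c("HAS_SYMPTOM", "cirrhosis", "jaundice"),
    c("HAS_SYMPTOM", "cirrhosis", "ascites"),
    c("HAS_SYMPTOM", "cirrhosis", "variceal bleeding"),
    c("HAS_SYMPTOM", "hepatitis b", "fatigue"),
    c("HAS_SYMPTOM", "autoimmune hepatitis", "pruritus"),
    c("HAS_SYMPTOM", "liver failure", "jaundice"),
    c("IS_DIAGNOSED_BY", "cirrhosis", "liver biopsy"),
    c("IS_DIAGNOSED_BY", "cirrhosis", "transient elastography"),
    c("IS_DIAGNOSED_BY", "hepatocellular carcinoma", "abdominal ultrasound"),
    c("IS_DIAGNOSED_BY", "hepatitis b", "alanine aminotransferase test"),
    c("IS_CAUSED_BY", "hepatitis b", "hepatitis b virus"),
    c("IS_CAUSED_BY", "hepatitis c", "hepatitis c virus"),
    c("IS_CAUSED_BY", "cirrhosis", "chronic alcohol use"),
    c("IS_CAUSED_BY", "fatty liver", "obesity"),
    c("IS_CAUSED_BY", "hepatocellular carcinoma", "aflatoxin exposure"),
    c("IS_CAUSED_BY", "alcoholic hepatitis", "chronic alcohol use"),
    c("RECOMMENDS_TREATMENT", "cirrhosis", "liver transplantation"),
    c("RECOMMENDS_TREATMENT", "liver failure", "liver transplantation"),
    c("RECOMMENDS_TREATMENT", "fatty liver", "lifestyle modification"),
    c("RECOMMENDS_TREATMENT", "cirrhosis", "paracentesis"),
    c("RECOMMENDS_TREATMENT", "cirrhosis", "endoscopic band ligation"),
    c("PROGRESSES_TO", "hepatitis b", "cirrhosis"),
    c("PROGRESSES_TO", "hepatitis c", "cirrhosis"),
    c("PROGRESSES_TO", "fatty liver", "cirrhosis"),
    c("PROGRESSES_TO", "alcoholic hepatitis", "cirrhosis"),
    c("PROGRESSES_TO", "cirrhosis", "hepatocellular carcinoma"),
    c("PROGRESSES_TO", "cirrhosis", "liver failure")
  )
  colnames(m) <- c("type", "source", "target")
  m
}

#' Generate the synthetic fixture knowledge graph
#'
#' Builds a schema-valid hepatology-like property graph: 40 entities over
#' all 8 categories, 47 relations covering all 11 relation types,
#' synthetic CUIs, evidence attributes on drug recommendations (seeded
#' weights, evidence levels, dosing), and multi-hop progression chains
#' (e.g. viral hepatitis -> cirrhosis -> hepatocellular carcinoma) so
#' multi-hop questions are answerable. Same seed, same graph.
#'
#' @param spec A [fixture_spec()].
#' @return A `property_graph`.
#' @export
generate_fixture_kg <- function(spec = fixture_spec()) {
  with_seed(spec$seed, {
    g <- property_graph(default_schema())
    roster <- fixture_roster()
    name_to_id <- character(0)
    idx <- 0L
    for (cat in names(roster)) {
      for (nm in roster[[cat]]) {
        idx <- idx + 1L
        id <- sprintf("E%03d", idx)
        name_to_id[nm] <- id
        add_entity(g, entity(
          id = id, name = nm, category = cat,
          cui = sprintf("C%07d", 1000000L + idx),
          attributes = list(source = "synthetic-fixture",
                            prevalence_class = sample(c("common", "uncommon",
                                                        "rare"), 1))))
      }
    }
    wiring <- fixture_wiring()
    levels <- c("A", "B", "C")
    strengths <- c("strong", "conditional", "weak")
    for (i in seq_len(nrow(wiring))) {
      type <- wiring[i, "type"]
      attrs <- list(weight = round(stats::runif(1, 0.55, 0.95), 2))
      if (type == "RECOMMENDS_DRUG") {
        attrs$evidence_level <- sample(levels, 1)
        attrs$recommendation_strength <- sample(strengths, 1)
        attrs$approval_status <- "approved"
        attrs$dosage <- paste0(sample(c(5, 10, 25, 50, 100, 300), 1), " mg")
        attrs$route <- "oral"
        attrs$frequency <- "once daily"
      } else if (type %in% c("RECOMMENDS_TREATMENT", "IS_CAUSED_BY")) {
        attrs$evidence_level <- sample(levels, 1)
      }
      add_relation(g, relation(
        source_id = name_to_id[[wiring[i, "source"]]],
        target_id = name_to_id[[wiring[i, "target"]]],
        type = type, attributes = attrs,
        provenance = sprintf("chunk-%03d", ((i - 1L) %% 12L) + 1L)))
    }
    g
  })
}

#' Build the fixture terminology dictionary
#'
#' One entry per fixture graph entity (concept id = CUI), with the
#' synonym table the ambiguous questions and abbreviation linking draw
#' from (e.g. "HCC" and "liver cancer" for hepatocellular carcinoma,
#' "hepatic steatosis" and "liver fat" for fatty liver).
#'
#' @param graph Fixture graph from [generate_fixture_kg()].
#' @return A `kg_dictionary`.
#' @export
fixture_dictionary <- function(graph) {
  synonyms <- list(
    "hepatocellular carcinoma" = c("hcc", "liver cancer"),
    "fatty liver" = c("hepatic steatosis", "liver fat"),
    "cirrhosis" = c("liver cirrhosis"),
    "hepatitis b" = c("hbv infection", "chronic hepatitis b"),
    "hepatitis c" = c("hcv infection"),
    "jaundice" = c("yellow skin"),
    "ascites" = c("fluid in the abdomen"),
    "liver transplantation" = c("liver transplant"),
    "alanine aminotransferase test" = c("alt test"),
    "transient elastography" = c("fibroscan"),
    "liver failure" = c("hepatic failure")
  )
  entries <- lapply(graph$entity_order, function(id) {
    e <- graph$entities[[id]]
    list(concept_id = e$cui, canonical = e$name,
         synonyms = synonyms[[e$name]] %||% character(0),
         category = e$category)
  })
  build_dictionary(entries)
}

fact_templates <- function() {
  list(
    RECOMMENDS_DRUG = list(q = "What drugs are recommended to manage %s?",
                           a = "%s is recommended for %s."),
    HAS_SYMPTOM = list(q = "What are the symptoms of %s?",
                       a = "%s manifests with %s."),
    IS_DIAGNOSED_BY = list(q = "What test is used to diagnose %s?",
                           a = "%s is diagnosed by %s."),
    RECOMMENDS_TREATMENT = list(q = "What treatment is recommended to manage %s?",
                                a = "%s is recommended for %s."),
    REQUIRES_CRITERIA = list(q = "What criteria apply to %s?",
                             a = "%s requires %s.")
  )
}

# Deterministic misspelling: drop the middle character of the longest word.
misspell <- function(name) {
  words <- strsplit(name, " ", fixed = TRUE)[[1]]
  wi <- which.max(nchar(words))
  w <- words[wi]
  pos <- max(2L, nchar(w) %/% 2L)
  words[wi] <- paste0(substring(w, 1, pos - 1), substring(w, pos + 1))
  paste(words, collapse = " ")
}

#' Generate the evaluation question set
#'
#' Builds, from the fixture graph, the default 30-question evaluation set:
#' 10 simple factual questions (answerable over one relation), 10
#' multi-hop reasoning questions (gold answer requires a length-2
#' progression/etiology chain verified to exist in the graph), and 10
#' ambiguous/colloquial questions whose surface form is a deterministic
#' misspelling absent from the dictionary. Each record carries the gold
#' answer, the gold entity links (concept ids) for the linker
#' precision/recall harness, and its category.
#'
#' @param graph Fixture graph.
#' @param spec A [fixture_spec()] (question counts).
#' @param dictionary Fixture dictionary (used to guarantee ambiguous
#'   surfaces are out-of-dictionary).
#' @return List of eval records: `question`, `category`, `gold`,
#'   `gold_links` (character vector of concept ids), `anchor_entity`.
#' @export
generate_question_set <- function(graph, spec = fixture_spec(),
                                  dictionary = fixture_dictionary(graph)) {
  records <- list()
  tmpl <- fact_templates()
  # --- factual: one per eligible relation, in relation order
  n_fact <- spec$questions[["factual"]]
  for (rid in graph$relation_order) {
    if (length(records) >= n_fact) break
    rel <- graph$relations[[rid]]
    t <- tmpl[[rel$type]]
    if (is.null(t)) next
    src <- graph$entities[[rel$source_id]]
    tgt <- graph$entities[[rel$target_id]]
    gold <- if (rel$type %in% c("RECOMMENDS_DRUG", "RECOMMENDS_TREATMENT")) {
      sprintf(t$a, tgt$name, src$name)
    } else {
      sprintf(t$a, src$name, tgt$name)
    }
    records[[length(records) + 1L]] <- list(
      question = sprintf(t$q, src$name), category = "factual",
      gold = gold, gold_links = src$cui, anchor_entity = src$id)
  }
  if (length(records) < n_fact) {
    stop("generation error: graph too small for ", n_fact,
         " factual questions", call. = FALSE)
  }
  # --- multi-hop: from length-2 directed chains
  n_multi <- spec$questions[["multi_hop"]]
  count <- 0L
  seen <- character(0)
  for (id in graph$entity_order) {
    if (count >= n_multi) break
    if (!identical(graph$entities[[id]]$category, "Disease")) next
    ps <- dfs_paths(graph, id, k = 2L, path_limit = 50L)
    for (p in ps$paths) {
      if (count >= n_multi) break
      if (length(p$nodes) != 3) next
      key <- paste(p$nodes, collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      e0 <- graph$entities[[p$nodes[1]]]
      e1 <- graph$entities[[p$nodes[2]]]
      e2 <- graph$entities[[p$nodes[3]]]
      q <- sprintf(
        "Through %s, what can %s eventually lead to, and for which is %s relevant?",
        e1$name, e0$name, e2$name)
      gold <- sprintf("%s can progress through %s. %s is linked to %s.",
                      e0$name, e1$name, e1$name, e2$name)
      count <- count + 1L
      records[[length(records) + 1L]] <- list(
        question = q, category = "multi_hop", gold = gold,
        gold_links = e0$cui, anchor_entity = e0$id,
        path = p$nodes)
    }
  }
  if (count < n_multi) {
    stop("generation error: graph has fewer than ", n_multi,
         " distinct 2-hop chains", call. = FALSE)
  }
  # --- ambiguous: colloquial surface with an injected misspelling
  n_amb <- spec$questions[["ambiguous"]]
  colloquial <- c(
    "My liver feels off and I think it could be %s, what should I do?",
    "I'm worried about %s, is that bad?",
    "Someone told me about %s, what medicine should I take?",
    "Could this be %s or something like it?",
    "Is %s something a doctor should check?")
  amb <- 0L
  for (id in graph$entity_order) {
    if (amb >= n_amb) break
    e <- graph$entities[[id]]
    if (!(e$category %in% c("Disease", "Symptom/Sign"))) next
    bad <- misspell(e$name)
    if (normalize_name(bad) %in% names(dictionary$exact_index)) next
    amb <- amb + 1L
    q <- sprintf(colloquial[((amb - 1L) %% length(colloquial)) + 1L], bad)
    records[[length(records) + 1L]] <- list(
      question = q, category = "ambiguous",
      gold = sprintf("The question refers to %s.", e$name),
      gold_links = e$cui, anchor_entity = e$id, surface = bad)
  }
  if (amb < n_amb) {
    stop("generation error: not enough entities for ", n_amb,
         " ambiguous questions", call. = FALSE)
  }
  records
}

#' Write a question set to JSONL
#' @param records From [generate_question_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_questions_jsonl <- function(records, path) {
  lines <- vapply(records, function(r)
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE)), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a question set from JSONL
#' @param path JSONL path.
#' @return List of eval records.
#' @export
read_questions_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lapply(lines[nzchar(lines)], function(ln)
    jsonlite::fromJSON(ln, simplifyVector = FALSE))
}

#' Batch evaluation of answered records
#'
#' Computes the three metrics for every record (each must carry
#' `question`, `category`, `gold`, `answer`, `context_text`), aggregates
#' per category and overall over the valid (non-error) records, and
#' returns a report that serializes to JSON and a per-record data frame.
#'
#' @param records List of completed eval records.
#' @param providers A provider set.
#' @param n_relevancy Questions regenerated per record for relevancy.
#' @return A `metric_report`: `per_record` (data.frame), `aggregate`
#'   (named list of means), `by_category` (list of per-category means),
#'   `errors` (character log).
#' @export
evaluate_run <- function(records, providers = make_provider_set(),
                         n_relevancy = 3L) {
  n <- length(records)
  per <- data.frame(question = character(n), category = character(n),
                    faithfulness = numeric(n), context_recall = numeric(n),
                    answer_relevancy = numeric(n),
                    stringsAsFactors = FALSE)
  errors <- character(0)
  for (i in seq_len(n)) {
    r <- records[[i]]
    per$question[i] <- r$question
    per$category[i] <- r$category
    f <- faithfulness(r$answer, r$context_text,
                      providers$generator_primary, providers$judge_primary)
    if (!is.null(f$error)) {
      errors <- c(errors, sprintf("record %d: %s", i, f$error))
    }
    per$faithfulness[i] <- f$f
    cr <- context_recall(r$gold, r$context_text, providers$judge_primary)
    per$context_recall[i] <- cr$cr
    ar <- answer_relevancy(r$question, r$answer,
                           providers$generator_primary, providers$embedder,
                           n = n_relevancy)
    if (!is.null(ar$error)) {
      errors <- c(errors, sprintf("record %d: %s", i, ar$error))
    }
    per$answer_relevancy[i] <- ar$ar
  }
  agg <- list(faithfulness = mean(per$faithfulness, na.rm = TRUE),
              context_recall = mean(per$context_recall, na.rm = TRUE),
              answer_relevancy = mean(per$answer_relevancy, na.rm = TRUE))
  by_cat <- lapply(split(per, per$category), function(d)
    list(faithfulness = mean(d$faithfulness, na.rm = TRUE),
         context_recall = mean(d$context_recall, na.rm = TRUE),
         answer_relevancy = mean(d$answer_relevancy, na.rm = TRUE)))
  structure(list(per_record = per, aggregate = agg, by_category = by_cat,
                 errors = errors),
            class = "metric_report")
}

#' Write a metric report
#'
#' @param report A `metric_report`.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(report$per_record, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(aggregate = report$aggregate,
                              by_category = report$by_category,
                              errors = report$errors),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(json = json_path, csv = csv_path))
}

#' Answer every question in a set with the agent
#'
#' Convenience driver for end-to-end evaluation: runs [run_agent()] on
#' each record and attaches `answer`, `context_text` (reconstructed from
#' the non-fallback answer's citations), and `is_fallback`.
#'
#' @param records Question records ([generate_question_set()]).
#' @param kg,dictionary,providers,config As in [run_agent()].
#' @return The records, completed.
#' @export
answer_question_set <- function(records, kg, dictionary,
                                providers = make_provider_set(),
                                config = default_config()) {
  for (i in seq_along(records)) {
    ans <- run_agent(records[[i]]$question, kg, dictionary, providers,
                     config)
    records[[i]]$answer <- ans$text
    records[[i]]$is_fallback <- ans$is_fallback
    records[[i]]$confidence <- ans$confidence$c_final
    records[[i]]$citations <- ans$citations
    records[[i]]$context_text <- ans$context_text
  }
  records
}
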