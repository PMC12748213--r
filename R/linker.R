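#' Load a terminology dictionary
#'
#' The dictionary stands in for a licensed terminology metathesaurus: a
#' TSV with columns `concept_id`, `canonical`, `synonyms`
#' (pipe-separated, may be empty), `category`. An exact-match index over
#' casefolded names and synonyms is built on load.
#'
#' @param path TSV path (no header row required; a header row whose first
#'   field is `concept_id` is skipped).
#' @return A `kg_dictionary`: `entries` (list with `concept_id`,
#'   `canonical`, `synonyms`, `category`) and `exact_index` (named integer,
#'   casefolded surface -> entry position).
#' @export
read_dictionary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  entries <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (identical(f[1], "concept_id")) next
    if (length(f) < 4) {
      stop("dictionary error: expected 4 tab-separated fields, got '",
           ln, "'", call. = FALSE)
    }
    syn <- if (nzchar(f[3])) strsplit(f[3], "|", fixed = TRUE)[[1]]
           else character(0)
    entries[[length(entries) + 1L]] <-
      list(concept_id = f[1], canonical = f[2], synonyms = syn,
           category = f[4])
  }
  build_dictionary(entries)
}

#' Build a dictionary from entry records
#'
#' @param entries List of `list(concept_id, canonical, synonyms, category)`.
#' @return A `kg_dictionary` (see [read_dictionary()]).
#' @export
build_dictionary <- function(entries) {
  ids <- vapply(entries, function(e) e$concept_id, "")
  if (anyDuplicated(ids)) {
    stop("dictionary error: duplicate concept_id '",
         ids[duplicated(ids)][1], "'", call. = FALSE)
  }
  exact_index <- integer(0)
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    for (surf in c(e$canonical, e$synonyms)) {
      key <- normalize_name(surf)
      if (!(key %in% names(exact_index))) exact_index[key] <- i
    }
  }
  structure(list(entries = entries, exact_index = exact_index),
            class = "kg_dictionary")
}

#' Write a dictionary to TSV
#' @param dictionary A `kg_dictionary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dictionary, path) {
  lines <- vapply(dictionary$entries, function(e) {
    paste(e$concept_id, e$canonical, paste(e$synonyms, collapse = "|"),
          e$category, sep = "\t")
  }, "")
  writeLines(c("concept_id\tcanonical\tsynonyms\tcategory", lines), path,
             useBytes = TRUE)
  invisible(path)
}

#' Normalized Levenshtein similarity
#'
#' `1 - editdist(s1, s2) / max(nchar(s1), nchar(s2))` on casefolded
#' strings: 1 for identical strings, 0 when every position differs.
#' Symmetric and bounded in `[0, 1]`.
#'
#' @param s1,s2 Non-empty strings.
#' @return Similarity in `[0, 1]`.
#' @examples
#' fuzzy_similarity("cirrosis", "cirrhosis")  # 1 - 1/9
#' @export
fuzzy_similarity <- function(s1, s2) {
  if (!nzchar(s1) || !nzchar(s2)) {
    stop("fuzzy_similarity is undefined for empty strings", call. = FALSE)
  }
  a <- tolower(s1); b <- tolower(s2)
  d <- utils::adist(a, b)[1, 1]
  1 - d / max(nchar(a), nchar(b))
}

#' Fuzzy dictionary lookup
#'
#' Scores a query span against every dictionary surface (canonical names
#' and synonyms) with [fuzzy_similarity()] and returns candidates whose
#' score strictly exceeds `threshold`, sorted by descending score. An
#' empty result is valid and triggers the linking-failure path downstream.
#'
#' @param span Query span (non-empty string).
#' @param dictionary A `kg_dictionary`.
#' @param threshold Candidate cut-off (default 0.8, strict `>`).
#' @return List of `link_candidate` records: `query_span`, `entry_index`,
#'   `concept_id`, `canonical`, `matched_surface`, `category`, `s_fuzzy`,
#'   `match_stage`.
#' @export
fuzzy_match <- function(span, dictionary, threshold = 0.8) {
  out <- list()
  for (i in seq_along(dictionary$entries)) {
    e <- dictionary$entries[[i]]
    best <- -Inf; best_surface <- NULL
    for (surf in c(e$canonical, e$synonyms)) {
      s <- fuzzy_similarity(span, surf)
      if (s > best) { best <- s; best_surface <- surf }
    }
    if (best > threshold) {
      out[[length(out) + 1L]] <- list(
        query_span = span, entry_index = i, concept_id = e$concept_id,
        canonical = e$canonical, matched_surface = best_surface,
        category = e$category, s_fuzzy = best,
        match_stage = if (best >= 1) "exact" else "fuzzy")
    }
  }
  if (length(out) > 1) {
    out <- out[order(-vapply(out, function(c) c$s_fuzzy, numeric(1)))]
  }
  out
}

#' Embedding-based candidate ranking
#'
#' Annotates candidates with the cosine similarity between the query
#' embedding and each candidate's canonical-name embedding, computes the
#' composite score `w_f * s_fuzzy + w_s * max(0, s_semantic)` (negative
#' cosines are clamped so the composite stays in `[0, 1]`), and reorders
#' by descending composite.
#'
#' @param query Query span.
#' @param candidates Candidate list from [fuzzy_match()].
#' @param embedder An embedder contract.
#' @param w_fuzzy,w_semantic Composite weights (defaults 0.5 / 0.5).
#' @return Candidates with `s_semantic` and `composite`, sorted.
#' @export
semantic_rank <- function(query, candidates, embedder,
                          w_fuzzy = 0.5, w_semantic = 0.5) {
  if (length(candidates) == 0) return(candidates)
  vq <- embedder$embed(query)
  for (i in seq_along(candidates)) {
    vc <- embedder$embed(candidates[[i]]$canonical)
    s <- cosine_similarity(vq, vc)
    candidates[[i]]$s_semantic <- s
    candidates[[i]]$composite <-
      w_fuzzy * candidates[[i]]$s_fuzzy + w_semantic * max(0, s)
  }
  candidates[order(-vapply(candidates, function(c) c$composite, numeric(1)))]
}

# Categories compatible with a question's surface intent keywords; used as
# the tie-break in disambiguation when top candidates are nearly equal.
intent_compatible_categories <- function(question) {
  q <- tolower(question)
  cats <- character(0)
  if (grepl("symptom|sign|feel|manifest", q)) cats <- c(cats, "Symptom/Sign")
  if (grepl("diagnos|test|exam|criteri", q))
    cats <- c(cats, "Examination/Test", "Clinical Criteria")
  if (grepl("drug|medicine|medication|dose|treat", q))
    cats <- c(cats, "Drug", "Treatment", "Disease")
  if (grepl("cause|why|risk|etiolog", q))
    cats <- c(cats, "Etiology/Risk Factor", "Disease")
  if (grepl("gene|mutation|target", q)) cats <- c(cats, "Gene")
  unique(cats)
}

#' Multi-stage entity linking
#'
#' Detects entity mentions in a question by a dictionary-driven
#' longest-match scan over casefolded token n-grams (n <= 5, greedy
#' left-to-right, consumed tokens not reused), then resolves each span by
#' the staged strategy: exact dictionary match first; failing that,
#' Levenshtein fuzzy matching above the 0.8 threshold; surviving
#' candidates are ranked by the composite of fuzzy and embedding-cosine
#' scores. When the top two composites differ by less than
#' `disambiguation_margin`, the candidate whose category is compatible
#' with the question's intent keywords is preferred. Resolved concepts
#' are mapped onto graph entities by CUI, then by normalized name.
#'
#' @param question Natural-language question (non-empty).
#' @param dictionary A `kg_dictionary`.
#' @param kg Optional `property_graph` to resolve concepts against.
#' @param embedder Embedder contract (default: seeded mock).
#' @param threshold Fuzzy threshold (default 0.8).
#' @param w_fuzzy,w_semantic Composite weights.
#' @param disambiguation_margin Near-tie margin (default 0.05).
#' @return List of `linked_entity` records: `query_span`, `concept_id`,
#'   `canonical`, `category`, `entity_id` (graph id or `NA`), `confidence`
#'   (the winning composite, feeding the final-confidence entity term),
#'   `match_stage`. Empty list when nothing links.
#' @export
link_entities <- function(question, dictionary, kg = NULL,
                          embedder = mock_embedder(),
                          threshold = 0.8, w_fuzzy = 0.5, w_semantic = 0.5,
                          disambiguation_margin = 0.05) {
  stopifnot(nzchar(question))
  toks_raw <- unlist(strsplit(question, "[^[:alnum:]]+"))
  toks_raw <- toks_raw[nzchar(toks_raw)]
  n <- length(toks_raw)
  linked <- list()
  i <- 1L
  preferred <- intent_compatible_categories(question)
  while (i <= n) {
    hit <- NULL
    for (len in seq(min(5L, n - i + 1L), 1L)) {
      span <- paste(toks_raw[i:(i + len - 1L)], collapse = " ")
      key <- normalize_name(span)
      # exact stage
      idx <- dictionary$exact_index[key]
      if (!is.na(idx)) {
        e <- dictionary$entries[[idx]]
        hit <- list(candidate = list(
          query_span = span, entry_index = unname(idx),
          concept_id = e$concept_id, canonical = e$canonical,
          matched_surface = span, category = e$category,
          s_fuzzy = 1, match_stage = "exact"), len = len)
        break
      }
      # fuzzy stage (skip very short spans: initialisms must match exactly)
      if (nchar(key) >= 4) {
        cands <- fuzzy_match(span, dictionary, threshold)
        if (length(cands) > 0) {
          cands <- semantic_rank(span, cands, embedder, w_fuzzy, w_semantic)
          top <- cands[[1]]
          if (length(cands) > 1 &&
              cands[[1]]$composite - cands[[2]]$composite <
                disambiguation_margin &&
              !(cands[[1]]$category %in% preferred) &&
              cands[[2]]$category %in% preferred) {
            top <- cands[[2]]
          }
          hit <- list(candidate = top, len = len)
          break
        }
      }
    }
    if (is.null(hit)) { i <- i + 1L; next }
    cand <- hit$candidate
    if (is.null(cand$s_semantic)) {
      # exact hits skip the embedding stage; composite from s_fuzzy alone
      vq <- embedder$embed(cand$query_span)
      vc <- embedder$embed(cand$canonical)
      cand$s_semantic <- cosine_similarity(vq, vc)
      cand$composite <- w_fuzzy * cand$s_fuzzy +
        w_semantic * max(0, cand$s_semantic)
    }
    entity_id <- NA_character_
    if (!is.null(kg)) {
      for (id in kg$entity_order) {
        e <- kg$entities[[id]]
        if (!is.null(e$cui) && identical(e$cui, cand$concept_id)) {
          entity_id <- id; break
        }
      }
      if (is.na(entity_id)) {
        for (id in kg$entity_order) {
          if (identical(normalize_name(kg$entities[[id]]$name),
                        normalize_name(cand$canonical))) {
            entity_id <- id; break
          }
        }
      }
    }
    linked[[length(linked) + 1L]] <- list(
      query_span = cand$query_span, concept_id = cand$concept_id,
      canonical = cand$canonical, category = cand$category,
      entity_id = entity_id, confidence = cand$composite,
      match_stage = cand$match_stage)
    i <- i + hit$len
  }
  linked
}

#' Linker precision / recall / F1 harness
#'
#' Scores predicted links against gold links per question: a prediction is
#' a true positive when its concept id appears in the question's gold set.
#' Precision = TP / predictions, recall = TP / gold, F1 their harmonic
#' mean (0 when both are 0).
#'
#' @param predictions List (per question) of linked-entity lists from
#'   [link_entities()].
#' @param gold List (per question) of character vectors of gold concept
#'   ids.
#' @return Named numeric: `precision`, `recall`, `f1`, `tp`, `fp`, `fn`.
#' @export
linker_prf <- function(predictions, gold) {
  stopifnot(length(predictions) == length(gold))
  tp <- fp <- fn <- 0L
  for (i in seq_along(predictions)) {
    pred_ids <- vapply(predictions[[i]], function(l) l$concept_id, "")
    g <- unique(as.character(gold[[i]]))
    tp <- tp + sum(unique(pred_ids) %in% g)
    fp <- fp + sum(!(unique(pred_ids) %in% g))
    fn <- fn + sum(!(g %in% pred_ids))
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(precision = precision, recall = recall, f1 = f1,
    tp = tp, fp = fp, fn = fn)
}
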