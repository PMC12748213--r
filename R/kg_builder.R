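#' Split a document into overlapping sentence chunks
#'
#' Documents are segmented into chunks of at most `max_units` sentences,
#' with `overlap` sentences shared between consecutive chunks, so that an
#' extraction model sees bounded, semantically coherent windows without
#' losing cross-boundary statements. Sentence boundaries are detected at
#' `.`, `!`, `?` followed by whitespace; the sentence pieces concatenate
#' exactly back to the input, so chunks are verbatim substrings.
#'
#' @param document A single string (UTF-8).
#' @param max_units Maximum sentences per chunk (> overlap).
#' @param overlap Sentences shared between consecutive chunks (>= 0).
#' @return A list of chunk records: `list(chunk_id =, text =, start =,
#'   end =)` with `start`/`end` sentence indices; empty list for an empty
#'   document.
#' @export
chunk_text <- function(document, max_units = 8L, overlap = 1L) {
  stopifnot(max_units > overlap, overlap >= 0)
  if (is.null(document) || !nzchar(trimws(document))) return(list())
  pieces <- split_sentences(document)
  n <- length(pieces)
  step <- max_units - overlap
  chunks <- list()
  s <- 1L
  repeat {
    e <- min(s + max_units - 1L, n)
    chunks[[length(chunks) + 1L]] <-
      list(chunk_id = sprintf("chunk-%03d", length(chunks) + 1L),
           text = paste(pieces[s:e], collapse = ""),
           start = s, end = e)
    if (e == n) break
    s <- s + step
  }
  chunks
}

# Split keeping every byte: each piece ends after a sentence terminator and
# its trailing whitespace, so paste(pieces, collapse = "") == document.
split_sentences <- function(document) {
  m <- gregexpr("[.!?]+[\\s]*", document, perl = TRUE)[[1]]
  if (m[1] == -1) return(document)
  ends <- m + attr(m, "match.length") - 1L
  starts <- c(1L, utils::head(ends, -1) + 1L)
  pieces <- substring(document, starts, ends)
  last_end <- ends[length(ends)]
  if (last_end < nchar(document)) {
    pieces <- c(pieces, substring(document, last_end + 1L, nchar(document)))
  }
  pieces[nzchar(pieces)]
}

#' Parse and validate an extraction payload
#'
#' Extraction models return one strict-JSON payload per chunk with
#' `entities` (surface, category, optional cui, attributes) and
#' `relations` (source, target, type, attributes). Every record is checked
#' against the schema; invalid records are kept in `$rejected` with a
#' reason, never silently dropped. A payload that is not JSON at all
#' yields an empty extraction with the parse error logged.
#'
#' @param json_payload Payload string.
#' @param schema A `kg_schema`.
#' @param chunk_id Identifier stored with the extraction (provenance).
#' @return A `chunk_extraction`: `entities`, `relations` (valid records),
#'   `rejected` (list of `list(record =, reason =)`), `errors` (parse-level
#'   messages).
#' @export
parse_extraction <- function(json_payload, schema = default_schema(),
                             chunk_id = "chunk-001") {
  stopifnot(is.character(json_payload), length(json_payload) == 1L)
  out <- list(chunk_id = chunk_id, entities = list(), relations = list(),
              rejected = list(), errors = character(0))
  class(out) <- "chunk_extraction"
  payload <- tryCatch(jsonlite::fromJSON(json_payload, simplifyVector = FALSE),
                      error = function(e) e)
  if (inherits(payload, "error")) {
    out$errors <- paste("payload is not valid JSON:",
                        conditionMessage(payload))
    return(out)
  }
  cat_by_surface <- list()
  for (rec in payload$entities) {
    if (is.null(rec$surface) || !nzchar(rec$surface)) {
      out$rejected[[length(out$rejected) + 1L]] <-
        list(record = rec, reason = "entity missing surface form")
      next
    }
    if (is.null(rec$category) || !(rec$category %in% schema$entity_types)) {
      out$rejected[[length(out$rejected) + 1L]] <-
        list(record = rec, reason = paste0("unknown entity category '",
                                           rec$category, "'"))
      next
    }
    rec$chunk_id <- chunk_id
    out$entities[[length(out$entities) + 1L]] <- rec
    cat_by_surface[[normalize_name(rec$surface)]] <- rec$category
  }
  for (rec in payload$relations) {
    rt <- schema$relation_types[[rec$type %||% ""]]
    if (is.null(rt)) {
      out$rejected[[length(out$rejected) + 1L]] <-
        list(record = rec, reason = paste0("unknown relation type '",
                                           rec$type, "'"))
      next
    }
    src_cat <- cat_by_surface[[normalize_name(rec$source %||% "")]]
    tgt_cat <- cat_by_surface[[normalize_name(rec$target %||% "")]]
    if (is.null(src_cat) || is.null(tgt_cat)) {
      out$rejected[[length(out$rejected) + 1L]] <-
        list(record = rec, reason = "relation endpoint not among extracted entities")
      next
    }
    if (!identical(src_cat, rt$source) || !identical(tgt_cat, rt$target)) {
      out$rejected[[length(out$rejected) + 1L]] <-
        list(record = rec,
             reason = paste0("endpoint categories ", src_cat, " -> ", tgt_cat,
                             " incompatible with ", rec$type))
      next
    }
    rec$chunk_id <- chunk_id
    out$relations[[length(out$relations) + 1L]] <- rec
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize an entity name
#'
#' Casefold, trim, and collapse internal whitespace. This is the fallback
#' deduplication key when no CUI is available; no stemming is applied
#' (surface variants are the linker's job).
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_name <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Hierarchical entity deduplication
#'
#' Groups raw entity records by CUI when present, falling back to the
#' normalized name, and to the raw surface form as a last resort. One
#' entity survives per group; attribute conflicts resolve first-seen-wins
#' and are logged. The returned merge map lets relation records re-point
#' their endpoints to the merged entity ids.
#'
#' @param records List of raw entity records (`surface`, `category`,
#'   optional `cui`, optional `attributes`, optional `chunk_id`).
#' @return List with `entities` (list of [entity()] records with generated
#'   ids), `merge_map` (named character: normalized surface -> entity id),
#'   and `conflicts` (character log of attribute conflicts).
#' @export
dedup_entities <- function(records) {
  groups <- list()     # group key -> merged record
  order_keys <- character(0)
  name_index <- character(0)  # normalized name -> group key (first seen)
  merge_map <- character(0)
  conflicts <- character(0)
  for (rec in records) {
    has_cui <- !is.null(rec$cui) && nzchar(rec$cui)
    norm <- normalize_name(rec$surface)
    key <- if (has_cui) {
      paste0("cui:", rec$cui)
    } else if (nzchar(norm)) {
      # name fallback: join an existing group already known under this
      # normalized name (possibly a CUI group), else open a name group
      if (norm %in% names(name_index)) name_index[[norm]]
      else paste0("name:", norm)
    } else {
      paste0("raw:", rec$surface)
    }
    if (nzchar(norm) && !(norm %in% names(name_index))) {
      name_index[norm] <- key
    }
    if (is.null(groups[[key]])) {
      groups[[key]] <- list(cui = if (has_cui) rec$cui else NULL,
                            name = if (nzchar(norm)) norm else rec$surface,
                            raw_name = rec$surface,
                            category = rec$category,
                            attributes = rec$attributes %||% list(),
                            chunks = as.character(rec$chunk_id %||% character(0)))
      order_keys <- c(order_keys, key)
    } else {
      g <- groups[[key]]
      for (a in names(rec$attributes %||% list())) {
        if (is.null(g$attributes[[a]])) {
          g$attributes[[a]] <- rec$attributes[[a]]
        } else if (!identical(g$attributes[[a]], rec$attributes[[a]])) {
          conflicts <- c(conflicts, sprintf(
            "entity '%s': attribute '%s' kept first-seen value", g$name, a))
        }
      }
      g$chunks <- unique(c(g$chunks, as.character(rec$chunk_id %||% character(0))))
      groups[[key]] <- g
    }
    if (!(norm %in% names(merge_map))) merge_map[norm] <- key
  }
  entities <- list()
  key_to_id <- character(0)
  for (i in seq_along(order_keys)) {
    g <- groups[[order_keys[i]]]
    id <- sprintf("E%03d", i)
    key_to_id[order_keys[i]] <- id
    entities[[i]] <- entity(id = id, name = g$name, category = g$category,
                            cui = g$cui, raw_name = g$raw_name,
                            attributes = g$attributes)
  }
  merge_map <- stats::setNames(key_to_id[merge_map], names(merge_map))
  list(entities = entities, merge_map = merge_map, conflicts = conflicts)
}

#' Evidence-weighted relation fusion
#'
#' Relations extracted from multiple chunks for the same
#' (source, target, type) triple are fused into one: the `weight`
#' attribute becomes the arithmetic mean of the member weights, the
#' `recommendation_strength` becomes the strongest label on the ordinal
#' scale, and provenance chunk ids are unioned.
#'
#' @param records List of raw relation records (`source`, `target`,
#'   `type`, optional `attributes`, optional `chunk_id`).
#' @param merge_map Named character from [dedup_entities()] re-pointing
#'   normalized surfaces to merged entity ids.
#' @param strength_scale Ordinal scale, strongest first.
#' @return List of [relation()] records (endpoints are merged entity ids).
#' @export
fuse_relations <- function(records, merge_map,
                           strength_scale = c("strong", "conditional",
                                              "weak", "expert-opinion")) {
  groups <- list()
  order_keys <- character(0)
  for (rec in records) {
    src <- merge_map[[normalize_name(rec$source %||% "")]]
    tgt <- merge_map[[normalize_name(rec$target %||% "")]]
    if (is.null(src) || is.null(tgt)) next  # endpoint filtered upstream
    key <- paste(src, tgt, rec$type, sep = "\x1f")
    member <- list(attributes = rec$attributes %||% list(),
                   chunk_id = as.character(rec$chunk_id %||% character(0)))
    if (is.null(groups[[key]])) {
      groups[[key]] <- list(source = src, target = tgt, type = rec$type,
                            members = list(member))
      order_keys <- c(order_keys, key)
    } else {
      groups[[key]]$members <- c(groups[[key]]$members, list(member))
    }
  }
  fused <- list()
  for (key in order_keys) {
    g <- groups[[key]]
    weights <- unlist(lapply(g$members, function(m) m$attributes$weight))
    strengths <- unlist(lapply(g$members,
                               function(m) m$attributes$recommendation_strength))
    attrs <- g$members[[1]]$attributes
    for (m in g$members[-1]) {       # first-seen wins for other attributes
      for (a in names(m$attributes)) {
        if (is.null(attrs[[a]])) attrs[[a]] <- m$attributes[[a]]
      }
    }
    if (length(weights) > 0) attrs$weight <- mean(weights)
    if (length(strengths) > 0) {
      unknown <- setdiff(strengths, strength_scale)
      if (length(unknown) > 0) {
        stop("fusion error: unknown recommendation strength '", unknown[1],
             "'", call. = FALSE)
      }
      attrs$recommendation_strength <-
        strength_scale[min(match(strengths, strength_scale))]
    }
    prov <- unique(unlist(lapply(g$members, function(m) m$chunk_id)))
    fused[[length(fused) + 1L]] <-
      relation(g$source, g$target, g$type, attributes = attrs,
               provenance = prov)
  }
  fused
}

#' Apply an expert review ledger
#'
#' Expert review is exact set algebra over the extracted entity set:
#' `final = (extracted \ remove) + add`, with set semantics (an added
#' entity already present appears once). A removal key absent from the
#' extracted set is a warning, not a failure.
#'
#' @param extracted List of [entity()] records (keyed by `id`).
#' @param ledger List with `remove` (character vector of entity ids) and
#'   `add` (list of [entity()] records). `remove` and the ids of `add`
#'   must be disjoint.
#' @return List of [entity()] records after review.
#' @export
apply_review <- function(extracted, ledger) {
  remove <- as.character(ledger$remove %||% character(0))
  add <- ledger$add %||% list()
  add_ids <- vapply(add, function(e) e$id, "")
  if (length(intersect(remove, add_ids)) > 0) {
    stop("review ledger invalid: remove and add sets overlap", call. = FALSE)
  }
  ids <- vapply(extracted, function(e) e$id, "")
  absent <- setdiff(remove, ids)
  if (length(absent) > 0) {
    warning("review ledger removes absent entities: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  kept <- extracted[!(ids %in% remove)]
  kept_ids <- vapply(kept, function(e) e$id, "")
  for (e in add) {
    if (!(e$id %in% kept_ids)) {
      kept <- c(kept, list(e))
      kept_ids <- c(kept_ids, e$id)
    }
  }
  kept
}

#' Quality-control report for a property graph
#'
#' Quantitative summary of a built graph: entity/relation totals, per-type
#' counts, dangling references (always 0 for graphs built through
#' [add_relation()], reported for audit), duplicate candidates (entities
#' sharing a normalized name), and per-relation-type attribute
#' completeness fractions for the schema's required attributes.
#'
#' @param graph A `property_graph`.
#' @return A `qc_report` list, serializable with [jsonlite::toJSON()].
#' @export
qc_report <- function(graph) {
  ents <- graph$entities
  rels <- graph$relations
  per_entity_type <- table(vapply(ents, function(e) e$category, ""))
  per_relation_type <- table(vapply(rels, function(r) r$type, ""))
  dangling <- sum(vapply(rels, function(r) {
    !(r$source_id %in% names(ents)) || !(r$target_id %in% names(ents))
  }, logical(1)))
  norm_names <- vapply(ents, function(e) normalize_name(e$name), "")
  dup_candidates <- if (length(norm_names) > 0) {
    sum(table(norm_names) > 1)
  } else 0L
  completeness <- list()
  for (rt in names(graph$schema$required_attributes)) {
    req <- graph$schema$required_attributes[[rt]]
    of_type <- Filter(function(r) identical(r$type, rt), rels)
    if (length(of_type) == 0) next
    completeness[[rt]] <- stats::setNames(vapply(req, function(a) {
      mean(vapply(of_type, function(r) !is.null(r$attributes[[a]]),
                  logical(1)))
    }, numeric(1)), req)
  }
  structure(list(
    entity_count = length(ents),
    relation_count = length(rels),
    entities_per_type = as.list(per_entity_type),
    relations_per_type = as.list(per_relation_type),
    dangling_reference_count = as.integer(dangling),
    duplicate_candidate_count = as.integer(dup_candidates),
    attribute_completeness = completeness
  ), class = "qc_report")
}

#' Build a knowledge graph from extraction payloads
#'
#' End-to-end construction: parse each payload, deduplicate entities
#' (CUI-first), fuse relations with evidence weighting, apply the expert
#' review ledger, and assemble a schema-validated graph.
#'
#' @param payloads Character vector of JSON extraction payloads (one per
#'   chunk).
#' @param schema A `kg_schema`.
#' @param ledger Optional review ledger (see [apply_review()]).
#' @return List with `graph` (a `property_graph`), `report` (a
#'   [qc_report()]), and `log` (rejected-record and conflict messages).
#' @export
build_kg <- function(payloads, schema = default_schema(), ledger = NULL) {
  ent_records <- list()
  rel_records <- list()
  log <- character(0)
  for (i in seq_along(payloads)) {
    ext <- parse_extraction(payloads[i], schema,
                            chunk_id = sprintf("chunk-%03d", i))
    ent_records <- c(ent_records, ext$entities)
    rel_records <- c(rel_records, ext$relations)
    log <- c(log, ext$errors,
             vapply(ext$rejected, function(r) r$reason, ""))
  }
  dd <- dedup_entities(ent_records)
  log <- c(log, dd$conflicts)
  entities <- dd$entities
  relations <- fuse_relations(rel_records, dd$merge_map)
  if (!is.null(ledger)) {
    entities <- apply_review(entities, ledger)
    if (!is.null(ledger$relations_remove) || !is.null(ledger$relations_add)) {
      rel_key <- function(r) paste(r$source_id, r$target_id, r$type,
                                   sep = "\x1f")
      keys <- vapply(relations, rel_key, "")
      drop <- vapply(ledger$relations_remove %||% list(), function(r)
        paste(r$source_id, r$target_id, r$type, sep = "\x1f"), "")
      relations <- relations[!(keys %in% drop)]
      for (r in ledger$relations_add %||% list()) {
        relations <- c(relations, list(r))
      }
    }
  }
  g <- property_graph(schema)
  for (e in entities) add_entity(g, e)
  kept_ids <- names(g$entities)
  for (r in relations) {
    if (r$source_id %in% kept_ids && r$target_id %in% kept_ids) {
      add_relation(g, r)
    } else {
      log <- c(log, sprintf("relation %s -> %s (%s) dropped: endpoint removed in review",
                            r$source_id, r$target_id, r$type))
    }
  }
  list(graph = g, report = qc_report(g), log = log)
}
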