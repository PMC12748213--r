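#' Read a property graph from JSONL files
#'
#' Entities and relations are stored one JSON record per line (UTF-8).
#' Entity records carry `id`, `name`, `category` and optionally `cui`,
#' `raw_name`, `attributes`; relation records carry `source_id`,
#' `target_id`, `type` and optionally `attributes`, `provenance`.
#' Records are validated against the schema as they are added; an invalid
#' record aborts with its line number.
#'
#' @param entities_path,relations_path Paths to the JSONL files.
#' @param schema A `kg_schema` (default: packaged clinical schema).
#' @return A `property_graph`.
#' @export
read_graph_jsonl <- function(entities_path, relations_path,
                             schema = default_schema()) {
  g <- property_graph(schema)
  ent_lines <- readLines(entities_path, encoding = "UTF-8", warn = FALSE)
  for (i in seq_along(ent_lines)) {
    if (!nzchar(trimws(ent_lines[i]))) next
    rec <- tryCatch(jsonlite::fromJSON(ent_lines[i], simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(rec)) {
      stop("invalid entity record at ", entities_path, ":", i, call. = FALSE)
    }
    ok <- tryCatch({
      add_entity(g, entity(
        id = rec$id, name = rec$name, category = rec$category,
        cui = rec$cui,
        raw_name = if (is.null(rec$raw_name)) rec$name else rec$raw_name,
        attributes = if (is.null(rec$attributes)) list() else rec$attributes))
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      stop("invalid entity record at ", entities_path, ":", i, " (",
           conditionMessage(ok), ")", call. = FALSE)
    }
  }
  rel_lines <- readLines(relations_path, encoding = "UTF-8", warn = FALSE)
  for (i in seq_along(rel_lines)) {
    if (!nzchar(trimws(rel_lines[i]))) next
    rec <- tryCatch(jsonlite::fromJSON(rel_lines[i], simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(rec)) {
      stop("invalid relation record at ", relations_path, ":", i,
           call. = FALSE)
    }
    ok <- tryCatch({
      add_relation(g, relation(
        source_id = rec$source_id, target_id = rec$target_id,
        type = rec$type,
        attributes = if (is.null(rec$attributes)) list() else rec$attributes,
        provenance = as.character(unlist(rec$provenance))))
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      stop("invalid relation record at ", relations_path, ":", i, " (",
           conditionMessage(ok), ")", call. = FALSE)
    }
  }
  g
}

#' Write a property graph to JSONL files
#'
#' Inverse of [read_graph_jsonl()]: `read(write(g))` preserves the
#' entity/relation multiset. Output is byte-deterministic for a given
#' graph (fixed key order, fixed entity/relation order).
#'
#' @param graph A `property_graph`.
#' @param entities_path,relations_path Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_graph_jsonl <- function(graph, entities_path, relations_path) {
  ent_lines <- vapply(graph$entity_order, function(id) {
    e <- graph$entities[[id]]
    rec <- list(id = e$id, name = e$name, category = e$category)
    if (!is.null(e$cui)) rec$cui <- e$cui
    if (!identical(e$raw_name, e$name)) rec$raw_name <- e$raw_name
    if (length(e$attributes) > 0) rec$attributes <- e$attributes
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  }, "")
  rel_lines <- vapply(graph$relation_order, function(rid) {
    r <- graph$relations[[rid]]
    rec <- list(source_id = r$source_id, target_id = r$target_id,
                type = r$type)
    if (length(r$attributes) > 0) rec$attributes <- r$attributes
    if (length(r$provenance) > 0) rec$provenance <- as.list(r$provenance)
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(ent_lines, entities_path, useBytes = TRUE)
  writeLines(rel_lines, relations_path, useBytes = TRUE)
  invisible(list(entities = entities_path, relations = relations_path))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Export a property graph to GraphML
#'
#' Nodes carry `name`, `category` and `cui`; edges carry `type` plus
#' every relation attribute, serialized as strings. The output is plain
#' GraphML readable by igraph, Gephi or yEd.
#'
#' @param graph A `property_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(graph, path) {
  edge_attr_names <- unique(unlist(lapply(graph$relations,
                                          function(r) names(r$attributes))))
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "  <key id=\"name\" for=\"node\" attr.name=\"name\" attr.type=\"string\"/>",
    "  <key id=\"category\" for=\"node\" attr.name=\"category\" attr.type=\"string\"/>",
    "  <key id=\"cui\" for=\"node\" attr.name=\"cui\" attr.type=\"string\"/>",
    "  <key id=\"type\" for=\"edge\" attr.name=\"type\" attr.type=\"string\"/>",
    vapply(edge_attr_names, function(a) sprintf(
      "  <key id=\"e_%s\" for=\"edge\" attr.name=\"%s\" attr.type=\"string\"/>",
      xml_escape(a), xml_escape(a)), ""),
    "  <graph id=\"G\" edgedefault=\"directed\">"
  )
  for (id in graph$entity_order) {
    e <- graph$entities[[id]]
    lines <- c(lines,
      sprintf("    <node id=\"%s\">", xml_escape(id)),
      sprintf("      <data key=\"name\">%s</data>", xml_escape(e$name)),
      sprintf("      <data key=\"category\">%s</data>", xml_escape(e$category)),
      if (!is.null(e$cui))
        sprintf("      <data key=\"cui\">%s</data>", xml_escape(e$cui)),
      "    </node>")
  }
  for (rid in graph$relation_order) {
    r <- graph$relations[[rid]]
    lines <- c(lines,
      sprintf("    <edge source=\"%s\" target=\"%s\">",
              xml_escape(r$source_id), xml_escape(r$target_id)),
      sprintf("      <data key=\"type\">%s</data>", xml_escape(r$type)),
      vapply(names(r$attributes), function(a) sprintf(
        "      <data key=\"e_%s\">%s</data>", xml_escape(a),
        xml_escape(format(r$attributes[[a]]))), ""),
      "    </edge>")
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

cypher_quote <- function(x) {
  paste0("\"", gsub("\"", "\\\\\"", gsub("\\\\", "\\\\\\\\", x)), "\"")
}

cypher_label <- function(category) {
  gsub("[^A-Za-z0-9]", "", gsub("/", " ", category))
}

cypher_props <- function(lst) {
  if (length(lst) == 0) return("")
  parts <- vapply(names(lst), function(k) {
    v <- lst[[k]]
    key <- gsub("[^A-Za-z0-9_]", "_", k)
    val <- if (is.numeric(v)) format(v, digits = 15) else cypher_quote(as.character(v))
    paste0(key, ": ", val)
  }, "")
  paste0("{", paste(parts, collapse = ", "), "}")
}

#' Export a property graph as an openCypher CREATE script
#'
#' Produces a CREATE statement per entity and per relation so the graph
#' can be loaded into any openCypher-compatible store (e.g. Neo4j).
#' Entity categories become node labels; all attributes, including the
#' evidence `weight`, are emitted as properties.
#'
#' @param graph A `property_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_cypher_script <- function(graph, path) {
  lines <- character(0)
  for (id in graph$entity_order) {
    e <- graph$entities[[id]]
    props <- c(list(id = e$id, name = e$name), e$attributes)
    if (!is.null(e$cui)) props$cui <- e$cui
    lines <- c(lines, sprintf("CREATE (`%s`:%s %s);", id,
                              cypher_label(e$category), cypher_props(props)))
  }
  for (rid in graph$relation_order) {
    r <- graph$relations[[rid]]
    props <- cypher_props(r$attributes)
    lines <- c(lines, sprintf(
      "MATCH (a {id: %s}), (b {id: %s}) CREATE (a)-[:%s %s]->(b);",
      cypher_quote(r$source_id), cypher_quote(r$target_id), r$type,
      if (nzchar(props)) props else "{}"))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
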