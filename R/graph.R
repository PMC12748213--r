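#' Create an empty property graph
#'
#' A `property_graph` is an environment-backed container (reference
#' semantics, so `add_entity()`/`add_relation()` mutate in place) holding
#' attribute-rich entities and typed, directed relations validated against
#' a [kg_schema][load_schema]. It is the factual anchor every retrieval
#' and answer in the package is grounded in.
#'
#' @param schema A `kg_schema`; defaults to the packaged clinical schema.
#' @return A `property_graph` object.
#' @examples
#' g <- property_graph()
#' add_entity(g, entity("d1", "cirrhosis", "Disease"))
#' add_entity(g, entity("s1", "jaundice", "Symptom/Sign"))
#' add_relation(g, relation("d1", "s1", "HAS_SYMPTOM"))
#' graph_size(g)
#' @export
property_graph <- function(schema = default_schema()) {
  g <- new.env(parent = emptyenv())
  g$schema <- schema
  g$entities <- list()        # id -> entity
  g$entity_order <- character(0)
  g$relations <- list()       # relation id -> relation
  g$relation_order <- character(0)
  g$adj_out <- list()         # entity id -> character vector of relation ids
  g$adj_in <- list()
  g$next_rel <- 1L
  class(g) <- "property_graph"
  g
}

#' @export
print.property_graph <- function(x, ...) {
  cat("<property_graph> ", length(x$entities), " entities, ",
      length(x$relations), " relations\n", sep = "")
  invisible(x)
}

#' Construct an entity record
#'
#' @param id Unique entity key (caller-supplied string).
#' @param name Normalized name (non-empty).
#' @param category One of the schema's entity categories.
#' @param cui Optional concept unique identifier (terminology key).
#' @param raw_name Original surface form; defaults to `name`.
#' @param attributes Named list of scalar attributes.
#' @return An `kg_entity` list.
#' @export
entity <- function(id, name, category, cui = NULL, raw_name = name,
                   attributes = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("entity name must be a non-empty string", call. = FALSE)
  }
  structure(list(id = id, cui = cui, name = name, raw_name = raw_name,
                 category = category, attributes = attributes),
            class = "kg_entity")
}

#' Construct a relation record
#'
#' @param source_id,target_id Entity keys.
#' @param type One of the schema's relation types.
#' @param attributes Named list; an optional `weight` must lie in `[0, 1]`.
#' @param provenance Character vector of source-chunk identifiers.
#' @return A `kg_relation` list.
#' @export
relation <- function(source_id, target_id, type, attributes = list(),
                     provenance = character(0)) {
  structure(list(source_id = source_id, target_id = target_id, type = type,
                 attributes = attributes, provenance = provenance),
            class = "kg_relation")
}

#' Add an entity to a graph
#'
#' @param graph A `property_graph`.
#' @param ent A [entity()] record.
#' @return The entity id, invisibly usable.
#' @export
add_entity <- function(graph, ent) {
  stopifnot(inherits(graph, "property_graph"), inherits(ent, "kg_entity"))
  if (!(ent$category %in% graph$schema$entity_types)) {
    stop("schema violation: unknown entity category '", ent$category, "'",
         call. = FALSE)
  }
  if (ent$id %in% names(graph$entities)) {
    stop("integrity error: duplicate entity id '", ent$id, "'", call. = FALSE)
  }
  graph$entities[[ent$id]] <- ent
  graph$entity_order <- c(graph$entity_order, ent$id)
  graph$adj_out[[ent$id]] <- character(0)
  graph$adj_in[[ent$id]] <- character(0)
  ent$id
}

#' Add a relation to a graph
#'
#' Endpoint categories must match the schema mapping for the relation type
#' (e.g. `RECOMMENDS_DRUG` requires a Disease source and a Drug target),
#' and any `weight` attribute must lie in `[0, 1]`.
#'
#' @param graph A `property_graph`.
#' @param rel A [relation()] record.
#' @return The relation id (internal, used for provenance anchors).
#' @export
add_relation <- function(graph, rel) {
  stopifnot(inherits(graph, "property_graph"), inherits(rel, "kg_relation"))
  rt <- graph$schema$relation_types[[rel$type]]
  if (is.null(rt)) {
    stop("schema violation: unknown relation type '", rel$type, "'",
         call. = FALSE)
  }
  src <- graph$entities[[rel$source_id]]
  tgt <- graph$entities[[rel$target_id]]
  if (is.null(src) || is.null(tgt)) {
    stop("integrity error: relation endpoint '",
         if (is.null(src)) rel$source_id else rel$target_id,
         "' not present in graph", call. = FALSE)
  }
  if (!identical(src$category, rt$source) || !identical(tgt$category, rt$target)) {
    stop("schema violation: ", rel$type, " requires ", rt$source, " -> ",
         rt$target, ", got ", src$category, " -> ", tgt$category,
         call. = FALSE)
  }
  w <- rel$attributes$weight
  if (!is.null(w) && (!is.numeric(w) || w < 0 || w > 1)) {
    stop("schema violation: relation weight must lie in [0, 1]", call. = FALSE)
  }
  rid <- sprintf("R%d", graph$next_rel)
  graph$next_rel <- graph$next_rel + 1L
  rel$rid <- rid
  graph$relations[[rid]] <- rel
  graph$relation_order <- c(graph$relation_order, rid)
  graph$adj_out[[rel$source_id]] <- c(graph$adj_out[[rel$source_id]], rid)
  graph$adj_in[[rel$target_id]] <- c(graph$adj_in[[rel$target_id]], rid)
  rid
}

#' Graph size
#'
#' @param graph A `property_graph`.
#' @return Named integer vector with `entities` and `relations` counts.
#' @export
graph_size <- function(graph) {
  c(entities = length(graph$entities), relations = length(graph$relations))
}

# Neighbors of `id` reachable over one relation, honoring direction and an
# optional relation-type filter. Returns a data-frame-like list in edge
# insertion order (the deterministic expansion order for traversals).
neighbor_steps <- function(graph, id, direction = "out",
                           relation_filter = character(0)) {
  rids <- switch(direction,
                 out  = graph$adj_out[[id]],
                 "in" = graph$adj_in[[id]],
                 both = {
                   # insertion order across both directions
                   r <- c(graph$adj_out[[id]], graph$adj_in[[id]])
                   r[order(as.integer(substring(r, 2)))]
                 })
  if (is.null(rids)) rids <- character(0)
  steps <- list()
  for (rid in rids) {
    rel <- graph$relations[[rid]]
    if (length(relation_filter) > 0 && !(rel$type %in% relation_filter)) next
    other <- if (identical(rel$source_id, id)) rel$target_id else rel$source_id
    # under direction "out"/"in" only the matching endpoint is used
    if (direction == "out" && !identical(rel$source_id, id)) next
    if (direction == "in" && !identical(rel$target_id, id)) next
    steps[[length(steps) + 1L]] <- list(node = other, rid = rid,
                                        type = rel$type)
  }
  steps
}

#' Depth-bounded BFS neighborhood
#'
#' Returns the set of entities whose hop distance from any seed is at most
#' `k`, i.e. the breadth-first neighborhood `{e : dist(seeds, e) <= k}`.
#' Seeds are included at distance 0. When the neighborhood exceeds
#' `node_limit`, nodes are kept in (distance, insertion-order) priority;
#' truncation is therefore deterministic.
#'
#' @param graph A `property_graph`.
#' @param seeds Character vector of entity ids (must exist).
#' @param k Maximum hop distance (`>= 0`).
#' @param node_limit Maximum number of nodes returned (`>= 1`).
#' @param direction Edge traversal direction: `"out"` (default, follows the
#'   schema's arrows), `"in"`, or `"both"` (undirected distances).
#' @param relation_filter Optional character vector of relation types to
#'   traverse; empty means all types.
#' @return A `kg_subgraph`: `node_ids` (ordered), `relations` (induced
#'   relation ids between included nodes), `distances` (named integer).
#' @export
bfs_neighborhood <- function(graph, seeds, k, node_limit = 200L,
                             direction = "out",
                             relation_filter = character(0)) {
  stopifnot(k >= 0, node_limit >= 1)
  missing_seeds <- setdiff(seeds, names(graph$entities))
  if (length(missing_seeds) > 0) {
    stop("linking failure: unknown seed entity '", missing_seeds[1], "'",
         call. = FALSE)
  }
  dist <- stats::setNames(integer(0), character(0))
  order_found <- character(0)
  queue <- unique(seeds)
  for (s in queue) dist[s] <- 0L
  order_found <- queue
  head <- 1L
  while (head <= length(queue)) {
    cur <- queue[head]; head <- head + 1L
    d <- dist[[cur]]
    if (d >= k) next
    for (st in neighbor_steps(graph, cur, direction, relation_filter)) {
      if (!(st$node %in% names(dist))) {
        dist[st$node] <- d + 1L
        queue <- c(queue, st$node)
        order_found <- c(order_found, st$node)
      }
    }
  }
  # BFS discovery order is already (distance, insertion order)
  keep <- utils::head(order_found, node_limit)
  induced <- character(0)
  for (rid in graph$relation_order) {
    rel <- graph$relations[[rid]]
    if (length(relation_filter) > 0 && !(rel$type %in% relation_filter)) next
    if (rel$source_id %in% keep && rel$target_id %in% keep) {
      induced <- c(induced, rid)
    }
  }
  structure(list(node_ids = keep,
                 relations = induced,
                 distances = dist[keep],
                 k = k),
            class = "kg_subgraph")
}

#' Depth-bounded simple-path enumeration (DFS)
#'
#' Enumerates all simple directed paths of length 1..`k` starting at a
#' seed, optionally restricted to a set of relation types. Paths never
#' revisit a node, which guarantees termination on cyclic graphs (disease
#' progression loops, for instance). When more than `path_limit` paths
#' exist, paths are kept in lexicographic node-id order.
#'
#' @param graph A `property_graph`.
#' @param seeds Character vector of entity ids.
#' @param k Maximum path length in edges (`>= 1`).
#' @param relation_filter Character vector of relation types; empty = all.
#' @param path_limit Maximum number of paths returned.
#' @param direction Traversal direction (see [bfs_neighborhood()]).
#' @return A `kg_pathset`: `paths` is a list of `list(nodes =, rids =,
#'   types =)`, `max_depth = k`.
#' @export
dfs_paths <- function(graph, seeds, k, relation_filter = character(0),
                      path_limit = 200L, direction = "out") {
  stopifnot(k >= 1, path_limit >= 1)
  missing_seeds <- setdiff(seeds, names(graph$entities))
  if (length(missing_seeds) > 0) {
    stop("linking failure: unknown seed entity '", missing_seeds[1], "'",
         call. = FALSE)
  }
  paths <- list()
  walk <- function(nodes, rids, types) {
    cur <- nodes[length(nodes)]
    for (st in neighbor_steps(graph, cur, direction, relation_filter)) {
      if (st$node %in% nodes) next  # simple paths only
      nn <- c(nodes, st$node); rr <- c(rids, st$rid); tt <- c(types, st$type)
      paths[[length(paths) + 1L]] <<- list(nodes = nn, rids = rr, types = tt)
      if (length(rr) < k) walk(nn, rr, tt)
    }
  }
  for (s in unique(seeds)) walk(s, character(0), character(0))
  if (length(paths) > 1) {
    keys <- vapply(paths, function(p) paste(p$nodes, collapse = "\x1f"), "")
    paths <- paths[order(keys, method = "radix")]
  }
  paths <- utils::head(paths, path_limit)
  structure(list(paths = paths, max_depth = k), class = "kg_pathset")
}

#' @export
print.kg_subgraph <- function(x, ...) {
  cat("<kg_subgraph> ", length(x$node_ids), " nodes / ",
      length(x$relations), " relations (k = ", x$k, ")\n", sep = "")
  invisible(x)
}

#' @export
print.kg_pathset <- function(x, ...) {
  cat("<kg_pathset> ", length(x$paths), " paths (max depth ", x$max_depth,
      ")\n", sep = "")
  invisible(x)
}
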