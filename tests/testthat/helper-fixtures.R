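# Shared toy graphs and random-graph builders for the test suite.

# A directed path a -> b -> c -> d over Disease nodes (PROGRESSES_TO).
path_graph <- function(n = 4L) {
  g <- property_graph()
  ids <- letters[seq_len(n)]
  for (id in ids) add_entity(g, entity(id, paste0("disease ", id), "Disease"))
  for (i in seq_len(n - 1L)) {
    add_relation(g, relation(ids[i], ids[i + 1L], "PROGRESSES_TO"))
  }
  g
}

# Star: center disease with `n_leaves` progression targets.
star_graph <- function(n_leaves = 5L) {
  g <- property_graph()
  add_entity(g, entity("center", "center disease", "Disease"))
  for (i in seq_len(n_leaves)) {
    id <- paste0("leaf", i)
    add_entity(g, entity(id, paste0("leaf disease ", i), "Disease"))
    add_relation(g, relation("center", id, "PROGRESSES_TO"))
  }
  g
}

# Random directed Disease-only graph (PROGRESSES_TO edges), for oracle
# comparisons against igraph.
random_disease_graph <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  g <- property_graph()
  ids <- sprintf("n%02d", seq_len(n_nodes))
  for (id in ids) add_entity(g, entity(id, paste0("disease ", id), "Disease"))
  pairs <- unique(cbind(sample(ids, n_edges * 3, replace = TRUE),
                        sample(ids, n_edges * 3, replace = TRUE)))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  pairs <- utils::head(pairs, n_edges)
  for (i in seq_len(nrow(pairs))) {
    add_relation(g, relation(pairs[i, 1], pairs[i, 2], "PROGRESSES_TO"))
  }
  list(graph = g, edges = pairs, ids = ids)
}

as_igraph <- function(rg) {
  igraph::graph_from_data_frame(
    as.data.frame(rg$edges, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = rg$ids, stringsAsFactors = FALSE))
}

# Tiny clinical graph used across linker/planner/workflow tests.
clinic_graph <- function() {
  g <- property_graph()
  add_entity(g, entity("d_cirr", "cirrhosis", "Disease", cui = "C0023890"))
  add_entity(g, entity("d_hcc", "hepatocellular carcinoma", "Disease",
                       cui = "C2239176"))
  add_entity(g, entity("d_fat", "fatty liver", "Disease", cui = "C0015695"))
  add_entity(g, entity("d_hep", "hepatitis b", "Disease", cui = "C0019163"))
  add_entity(g, entity("dr_ete", "entecavir", "Drug", cui = "C0754659"))
  add_entity(g, entity("s_jau", "jaundice", "Symptom/Sign", cui = "C0022346"))
  add_entity(g, entity("t_tx", "liver transplantation", "Treatment",
                       cui = "C0023911"))
  add_relation(g, relation("d_hep", "dr_ete", "RECOMMENDS_DRUG",
                           attributes = list(weight = 0.9,
                                             evidence_level = "A",
                                             dosage = "0.5 mg",
                                             route = "oral",
                                             frequency = "once daily")))
  add_relation(g, relation("d_cirr", "s_jau", "HAS_SYMPTOM"))
  add_relation(g, relation("d_hep", "d_cirr", "PROGRESSES_TO"))
  add_relation(g, relation("d_cirr", "d_hcc", "PROGRESSES_TO"))
  add_relation(g, relation("d_fat", "d_cirr", "PROGRESSES_TO"))
  add_relation(g, relation("d_cirr", "t_tx", "RECOMMENDS_TREATMENT"))
  g
}

clinic_dictionary <- function() {
  build_dictionary(list(
    list(concept_id = "C0023890", canonical = "cirrhosis",
         synonyms = c("liver cirrhosis"), category = "Disease"),
    list(concept_id = "C2239176", canonical = "hepatocellular carcinoma",
         synonyms = c("hcc", "liver cancer"), category = "Disease"),
    list(concept_id = "C0015695", canonical = "fatty liver",
         synonyms = c("hepatic steatosis", "liver fat"),
         category = "Disease"),
    list(concept_id = "C0019163", canonical = "hepatitis b",
         synonyms = character(0), category = "Disease"),
    list(concept_id = "C0754659", canonical = "entecavir",
         synonyms = character(0), category = "Drug"),
    list(concept_id = "C0022346", canonical = "jaundice",
         synonyms = c("yellow skin"), category = "Symptom/Sign"),
    list(concept_id = "C0023911", canonical = "liver transplantation",
         synonyms = c("liver transplant"), category = "Treatment")
  ))
}
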