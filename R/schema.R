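#' Clinical knowledge-graph schema
#'
#' A schema fixes the vocabulary of a property graph: the set of entity
#' categories, the set of typed relations, and for each relation type the
#' unique (source category, target category) pair it is allowed to connect.
#' The packaged default is the clinical-guideline ontology used throughout
#' the package: 8 entity categories and 11 directed relation types, with
#' the drug-recommendation relation carrying an evidence/dosing attribute
#' block and a confidence `weight`.
#'
#' @param path Optional path to a YAML schema definition. When `NULL`
#'   (default) the packaged clinical schema is returned.
#' @return An object of class `kg_schema` with elements `entity_types`
#'   (character vector), `relation_types` (named list; each element has
#'   `$source` and `$target` categories), and `required_attributes`
#'   (named list of per-relation-type attribute names).
#' @examples
#' sch <- load_schema()
#' length(sch$entity_types)   # 8
#' length(sch$relation_types) # 11
#' sch$relation_types$RECOMMENDS_DRUG
#' @export
load_schema <- function(path = NULL) {
  if (is.null(path)) {
    return(default_schema())
  }
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("schema error: cannot parse '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(raw$entity_types) || !is.character(unlist(raw$entity_types))) {
    stop("schema error: field 'entity_types' missing or not a character list",
         call. = FALSE)
  }
  entity_types <- as.character(unlist(raw$entity_types))
  relation_types <- list()
  if (!is.null(raw$relation_types)) {
    for (nm in names(raw$relation_types)) {
      rt <- raw$relation_types[[nm]]
      if (is.null(rt$source) || is.null(rt$target)) {
        stop("schema error: relation type '", nm,
             "' must define 'source' and 'target'", call. = FALSE)
      }
      if (!(rt$source %in% entity_types)) {
        stop("schema error: relation '", nm, "' source category '",
             rt$source, "' not in entity_types", call. = FALSE)
      }
      if (!(rt$target %in% entity_types)) {
        stop("schema error: relation '", nm, "' target category '",
             rt$target, "' not in entity_types", call. = FALSE)
      }
      relation_types[[nm]] <- list(source = rt$source, target = rt$target)
    }
  }
  required_attributes <- raw$required_attributes
  if (is.null(required_attributes)) required_attributes <- list()
  new_schema(entity_types, relation_types, required_attributes)
}

new_schema <- function(entity_types, relation_types, required_attributes) {
  structure(
    list(entity_types = entity_types,
         relation_types = relation_types,
         required_attributes = required_attributes),
    class = "kg_schema"
  )
}

#' Packaged clinical schema
#'
#' Eight entity categories (Disease, Drug, Gene, Symptom/Sign,
#' Examination/Test, Treatment, Etiology/Risk Factor, Clinical Criteria)
#' and eleven directed relation types. Relation directions are asymmetric:
#' e.g. `RECOMMENDS_DRUG` runs Disease -> Drug while
#' `IS_CONTRAINDICATED_FOR` runs Drug -> Disease.
#'
#' @return A `kg_schema` object.
#' @export
default_schema <- function() {
  entity_types <- c("Disease", "Drug", "Gene", "Symptom/Sign",
                    "Examination/Test", "Treatment", "Etiology/Risk Factor",
                    "Clinical Criteria")
  rel <- function(source, target) list(source = source, target = target)
  relation_types <- list(
    RECOMMENDS_DRUG        = rel("Disease", "Drug"),
    HAS_ADVERSE_EFFECT     = rel("Drug", "Symptom/Sign"),
    ASSOCIATED_WITH_GENE   = rel("Disease", "Gene"),
    TARGETS_GENE           = rel("Drug", "Gene"),
    IS_CONTRAINDICATED_FOR = rel("Drug", "Disease"),
    REQUIRES_CRITERIA      = rel("Disease", "Clinical Criteria"),
    HAS_SYMPTOM            = rel("Disease", "Symptom/Sign"),
    IS_DIAGNOSED_BY        = rel("Disease", "Examination/Test"),
    IS_CAUSED_BY           = rel("Disease", "Etiology/Risk Factor"),
    RECOMMENDS_TREATMENT   = rel("Disease", "Treatment"),
    PROGRESSES_TO          = rel("Disease", "Disease")
  )
  required_attributes <- list(
    RECOMMENDS_DRUG = c("evidence_level", "recommendation_strength",
                        "approval_status", "dosage", "route", "frequency",
                        "weight")
  )
  new_schema(entity_types, relation_types, required_attributes)
}

#' @export
print.kg_schema <- function(x, ...) {
  cat("<kg_schema> ", length(x$entity_types), " entity types, ",
      length(x$relation_types), " relation types\n", sep = "")
  invisible(x)
}

#' Write a schema to YAML
#'
#' @param schema A `kg_schema`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "kg_schema"))
  yaml::write_yaml(
    list(entity_types = as.list(schema$entity_types),
         relation_types = schema$relation_types,
         required_attributes = lapply(schema$required_attributes, as.list)),
    path
  )
  invisible(path)
}

# Does (category, relation type, direction) have a schema-compatible reading?
# direction: "out" means category is the source, "in" the target,
# "both" accepts either.
schema_compatible <- function(schema, category, rel_type, direction = "out") {
  rt <- schema$relation_types[[rel_type]]
  if (is.null(rt)) return(FALSE)
  switch(direction,
         out  = identical(rt$source, category),
         "in" = identical(rt$target, category),
         both = identical(rt$source, category) || identical(rt$target, category),
         FALSE)
}
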