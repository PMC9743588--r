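# Use-case refinements applied to a derived graph model: absorbing a
# one-attribute entity into its host (optionally as subtype labels), merging a
# child entity into its parent as a self-referencing hierarchy, and promoting
# key-value dynamic fields either into host attributes or into shared entities.

find_relationship <- function(m, name, a = NULL, b = NULL) {
  hits <- which(vapply(m$relationships, function(r) {
    r$name == name &&
      (is.null(a) || r$a %in% c(a, b)) &&
      (is.null(b) || r$b %in% c(a, b))
  }, logical(1)))
  hits
}

#' Absorb a one-attribute entity into a host entity
#'
#' The absorbed entity must carry exactly one non-identifying attribute. In
#' `mode = "attribute"` that attribute moves onto the host (resolved by an FK
#' lookup at migration time); in `mode = "subtype_labels"` each distinct value
#' of the attribute becomes an extra node label of the host (e.g. an analysis
#' typed `ArrayCGH` gains the label `ArrayCGHAnalysis`). The absorbed entity
#' and the connecting relationship are removed in both modes.
#'
#' @param m a `graph_model`.
#' @param absorbed label of the entity to absorb.
#' @param host label of the receiving entity.
#' @param via name of the relationship connecting them.
#' @param mode `"attribute"` or `"subtype_labels"`.
#' @return the refined model.
#' @export
absorb_entity <- function(m, absorbed, host, via, mode = c("subtype_labels", "attribute")) {
  mode <- match.arg(mode)
  if (is.null(m$entities[[absorbed]])) stop2("entity %s not in model", absorbed)
  if (is.null(m$entities[[host]])) stop2("entity %s not in model", host)
  ae <- m$entities[[absorbed]]
  if (length(ae$origins) != 1L) stop2("cannot absorb multi-origin entity %s", absorbed)
  ao <- ae$origins[[1]]
  extra <- ao$props[!ao$props$is_key, , drop = FALSE]
  if (nrow(extra) != 1L) {
    stop2("entity %s has %d non-identifying attributes; absorb_entity requires exactly 1",
          absorbed, nrow(extra))
  }
  hits <- find_relationship(m, via, absorbed, host)
  hits <- hits[vapply(m$relationships[hits], function(r) {
    setequal(c(r$a, r$b), c(absorbed, host)) ||
      (absorbed == host && r$a == r$b)
  }, logical(1))]
  if (length(hits) != 1L) {
    stop2("need exactly one relationship '%s' between %s and %s (found %d)",
          via, absorbed, host, length(hits))
  }
  rel <- m$relationships[[hits]]
  if (rel$origin$kind != "fk") {
    stop2("absorb_entity requires an FK-derived relationship (got %s)", via)
  }
  fk_cols <- paste(rel$origin$fk$columns, collapse = "+")
  hostent <- m$entities[[host]]
  if (mode == "subtype_labels") {
    hostent$subtype <- list(
      fk_relation = rel$origin$relation, fk_columns = fk_cols,
      lookup_relation = ao$relation,
      lookup_key = paste(ao$key_attrs, collapse = "+"),
      label_attr = extra$name, suffix = host)
  } else {
    hostent$origins[[1]]$props <- rbind(
      hostent$origins[[1]]$props,
      entity_prop_row(extra$name, extra$type, ao$relation, extra$origin_attribute,
                      optional = TRUE, lookup_relation = ao$relation,
                      lookup_fk_columns = fk_cols))
  }
  m$entities[[host]] <- hostent
  m$entities[[absorbed]] <- NULL
  m$relationships[[hits]] <- NULL
  if (!is.null(m$schema)) m$ledger <- build_ledger(m, m$schema)
  validate_graph_model(m)
  m
}

#' Merge a child entity into its parent as a self-referencing hierarchy
#'
#' The child's non-identifying attributes become optional properties of the
#' parent, the child-to-parent relationship becomes a self-relationship named
#' `self_rel_name` on the parent, other relationships touching the child are
#' rewired to the parent, and the child entity is removed. Rows of the child's
#' origin relation then migrate as parent-labeled nodes.
#'
#' @param m a `graph_model`.
#' @param child label of the entity to merge away.
#' @param parent label of the receiving entity.
#' @param self_rel_name name for the resulting self-relationship.
#' @return the refined model.
#' @export
merge_hierarchy <- function(m, child, parent, self_rel_name) {
  if (is.null(m$entities[[child]])) stop2("entity %s not in model", child)
  if (is.null(m$entities[[parent]])) stop2("entity %s not in model", parent)
  links <- which(vapply(m$relationships, function(r) {
    setequal(c(r$a, r$b), c(child, parent))
  }, logical(1)))
  if (length(links) != 1L) {
    stop2("need exactly one relationship between %s and %s (found %d): ambiguous merge",
          child, parent, length(links))
  }
  link <- m$relationships[[links]]
  if (link$origin$kind != "fk" || link$origin$relation != m$entities[[child]]$origins[[1]]$relation) {
    stop2("the %s-%s link must be the FK of the child relation", child, parent)
  }
  co <- m$entities[[child]]$origins[[1]]
  co$props$optional[!co$props$is_key] <- TRUE
  co$self_fk <- list(columns = link$origin$fk$columns, rel_name = self_rel_name)
  pe <- m$entities[[parent]]
  pe$origins[[length(pe$origins) + 1L]] <- co
  m$entities[[parent]] <- pe
  m$relationships[[links]] <- list(
    name = self_rel_name, a = parent, b = parent,
    origin = c(link$origin, list(self = TRUE)), props = link$props)
  for (i in seq_along(m$relationships)) {
    if (m$relationships[[i]]$a == child) m$relationships[[i]]$a <- parent
    if (m$relationships[[i]]$b == child) m$relationships[[i]]$b <- parent
  }
  m$entities[[child]] <- NULL
  if (!is.null(m$schema)) m$ledger <- build_ledger(m, m$schema)
  validate_graph_model(m)
  m
}

#' Promote a dynamic key-value field out of the placeholder entity
#'
#' Dynamic-field rows whose key matches `field_key` stop migrating as
#' placeholder nodes. With `mode = "attribute"` the value is stored as a
#' property named `field_key` on the owning analysis (suitable for numeric
#' measurements with large domains). With `mode = "entity"` each distinct
#' (canonicalized) value becomes one shared node of a new entity type (e.g.
#' `Fusion`), linked from the owning analysis by `rel_name`, so equal values
#' map to the same node across patients and analysis types.
#'
#' @param m a `graph_model`.
#' @param field_key the dynamic-field key (matched against the field's stored
#'   `name`).
#' @param mode `"entity"` or `"attribute"`.
#' @param entity_name label of the shared entity (mode `"entity"`).
#' @param rel_name relationship type from the host to the shared entity.
#' @param dyn_entity label of the dynamic-field placeholder entity.
#' @param key_attr,value_attr attributes of the placeholder holding the
#'   semantic key and the value.
#' @return the refined model.
#' @export
promote_dynamic_field <- function(m, field_key, mode = c("entity", "attribute"),
                                  entity_name = NULL, rel_name = NULL,
                                  dyn_entity = "DynamicField",
                                  key_attr = "name", value_attr = "value") {
  mode <- match.arg(mode)
  if (is.null(m$entities[[dyn_entity]])) {
    stop2("dynamic-field entity %s not in model", dyn_entity)
  }
  prior <- m$promotions[[field_key]]
  if (!is.null(prior)) {
    stop2("field key '%s' already promoted (mode %s); conflicting promotion",
          field_key, prior$mode)
  }
  links <- which(vapply(m$relationships, function(r) {
    (r$a == dyn_entity || r$b == dyn_entity) && r$a != r$b
  }, logical(1)))
  if (length(links) != 1L) {
    stop2("%s must have exactly one relationship to its host (found %d)",
          dyn_entity, length(links))
  }
  link <- m$relationships[[links]]
  host <- if (link$a == dyn_entity) link$b else link$a
  promo <- list(key = field_key, mode = mode, dyn_entity = dyn_entity,
                host = host, key_attr = key_attr, value_attr = value_attr)
  if (mode == "entity") {
    if (is.null(entity_name) || is.null(rel_name)) {
      stop2("mode 'entity' requires entity_name and rel_name")
    }
    promo$entity <- entity_name
    promo$rel <- rel_name
    if (is.null(m$entities[[entity_name]])) {
      m$entities[[entity_name]] <- list(
        label = entity_name, subtype = NULL,
        origins = list(list(
          relation = NA_character_, key_attrs = "name",
          props = rbind(
            entity_prop_row("name", "text", NA_character_, NA_character_,
                            is_key = TRUE, promoted = TRUE),
            entity_prop_row("other_names", "text", NA_character_, NA_character_,
                            optional = TRUE, promoted = TRUE)),
          consumed_fk = character(0), self_fk = NULL, promoted_from = dyn_entity)))
    }
    if (!length(find_relationship(m, rel_name, host, entity_name))) {
      m$relationships[[length(m$relationships) + 1L]] <- list(
        name = rel_name, a = host, b = entity_name,
        origin = list(kind = "promoted", relation = dyn_entity, key = field_key),
        props = empty_rel_props())
    }
  } else {
    he <- m$entities[[host]]
    he$origins[[1]]$props <- rbind(
      he$origins[[1]]$props,
      entity_prop_row(field_key, "text", NA_character_, NA_character_,
                      optional = TRUE, promoted = TRUE))
    m$entities[[host]] <- he
  }
  m$promotions[[field_key]] <- promo
  if (!is.null(m$schema)) m$ledger <- build_ledger(m, m$schema)
  validate_graph_model(m)
  m
}

#' Apply a list of refinement rules to a graph model
#'
#' Rules are the structured-config form of [absorb_entity()],
#' [merge_hierarchy()], and [promote_dynamic_field()] (kinds `absorb_entity`,
#' `merge_hierarchy`, `promote_field_entity`, `promote_field_attribute`).
#'
#' @param m a `graph_model`.
#' @param rules list of rule specifications (each a named list with `kind`).
#' @return the refined model.
#' @export
apply_refinements <- function(m, rules) {
  for (rule in rules) {
    m <- switch(rule$kind,
      absorb_entity = absorb_entity(m, rule$absorbed, rule$host, rule$via,
                                    rule$mode %||% "subtype_labels"),
      merge_hierarchy = merge_hierarchy(m, rule$child, rule$parent,
                                        rule$self_rel_name),
      promote_field_entity = promote_dynamic_field(
        m, rule$key, "entity", entity_name = rule$entity, rel_name = rule$rel,
        dyn_entity = rule$dyn_entity %||% "DynamicField"),
      promote_field_attribute = promote_dynamic_field(
        m, rule$key, "attribute",
        dyn_entity = rule$dyn_entity %||% "DynamicField"),
      stop2("unknown refinement kind '%s'", rule$kind)
    )
  }
  m
}

#' Read a pipeline configuration document
#'
#' A YAML document with `name_map`, `refinements` and `analytics` sections; the
#' shipped default reproduces the refined ALL diagnostics model.
#'
#' @param path configuration file; defaults to the shipped configuration.
#' @return list with elements `name_map`, `refinements`, `analytics`.
#' @export
read_config <- function(path = default_config_path()) {
  cfg <- yaml::read_yaml(path)
  list(name_map = cfg$name_map %||% list(),
       refinements = cfg$refinements %||% list(),
       analytics = cfg$analytics %||% list())
}

#' Path to the shipped default pipeline configuration
#'
#' @return file path of the YAML configuration.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "rel2graph",
              mustWork = TRUE)
}

#' Compute the node label for a subtyped value
#'
#' Strips non-alphanumeric characters from the type value and appends the host
#' label, so an analysis of type `Array-CGH` hosted by `Analysis` gets the
#' extra label `ArrayCGHAnalysis`.
#'
#' @param value the type value from the absorbed master relation.
#' @param suffix the host entity label.
#' @return a label string.
#' @export
subtype_label <- function(value, suffix) {
  paste0(gsub("[^A-Za-z0-9]", "", value), suffix)
}
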