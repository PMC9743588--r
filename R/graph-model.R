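# The derived labeled-property-graph model: entity types (with optional
# subtype labeling), relationship types with properties, and an
# attribute-placement ledger accounting for every attribute of the source
# schema exactly once.

entity_prop_row <- function(name, type, origin_relation, origin_attribute,
                            is_key = FALSE, optional = FALSE,
                            lookup_relation = NA_character_,
                            lookup_fk_columns = NA_character_,
                            promoted = FALSE) {
  data.frame(name = name, type = type, origin_relation = origin_relation,
             origin_attribute = origin_attribute, is_key = is_key,
             optional = optional, lookup_relation = lookup_relation,
             lookup_fk_columns = lookup_fk_columns, promoted = promoted,
             stringsAsFactors = FALSE)
}

# Default relationship name when the name map has no entry: associative
# relation name for source-derived edges, Has<TargetRelation> for FK-derived
# edges, Has<NewEntity> for edges created together with a new entity.
default_rel_name <- function(r) {
  if (r$origin$kind == "source") {
    r$origin$relation
  } else if (isTRUE(r$origin$via_new_entity)) {
    paste0("Has", r$a)
  } else {
    paste0("Has", r$origin$fk$ref_table)
  }
}

rel_name_key <- function(r) {
  if (r$origin$kind == "source") r$origin$relation
  else paste0(r$origin$relation, ".", paste(r$origin$fk$columns, collapse = "+"))
}

finalize_schema_graph <- function(g) {
  # Promote leftover PK nodes (isolated relations, n-ary associations,
  # unreferenced relations) to entities, absorbing their merged sink if it
  # hangs only off them, then resolve any FK structure that became resolvable.
  repeat {
    changed <- FALSE
    for (pid in lex_sort(names(g$nodes))) {
      n <- g$nodes[[pid]]
      if (is.null(n) || n$kind != "pk") next
      targets <- g$edges$to[g$edges$from == pid]
      sinks <- targets[vapply(targets, function(t) {
        !is.null(g$nodes[[t]]) && g$nodes[[t]]$kind == "sink" && sg_indeg(g, t) == 1L
      }, logical(1))]
      carried <- n$carried
      for (s in sinks) carried <- rbind(carried, g$nodes[[s]]$carried)
      ent <- n$relation
      g$nodes[[ent]] <- sg_node(ent, n$relation, "entity", carried,
                                key_attrs = carried$attribute[carried$is_pk])
      g <- sg_rewire(g, c(pid, sinks), ent)
      g$nodes[setdiff(c(pid, sinks), ent)] <- NULL
      g$notes <- c(g$notes, sprintf(
        "node %s not resolved by the merge steps; kept as entity %s", pid, ent))
      changed <- TRUE
    }
    if (!changed) break
    g <- resolve_fk_hubs(g)
  }
  # Remaining direct FK edges between entities (e.g. the legs of an n-ary
  # association promoted to an entity) become relationships.
  fk_left <- g$edges[g$edges$kind == "fk", , drop = FALSE]
  for (i in seq_len(nrow(fk_left))) {
    from <- fk_left$from[i]; to <- fk_left$to[i]
    if (is.null(g$nodes[[from]]) || is.null(g$nodes[[to]])) next
    if (g$nodes[[from]]$kind != "entity" || g$nodes[[to]]$kind != "entity") next
    fk <- g$schema[[fk_left$rel[i]]]$fks[[fk_left$fk_id[i]]]
    g$relationships[[length(g$relationships) + 1L]] <- list(
      name = NA_character_, a = from, b = to,
      origin = list(kind = "fk", relation = fk_left$rel[i],
                    fk = list(columns = fk$columns, ref_table = fk$ref_table,
                              optional = fk$optional)),
      props = empty_rel_props())
    g$edges <- g$edges[!(g$edges$from == from & g$edges$to == to &
                           g$edges$kind == "fk" &
                           g$edges$rel == fk_left$rel[i] &
                           (is.na(g$edges$fk_id) | g$edges$fk_id == fk_left$fk_id[i])), ,
                       drop = FALSE]
  }
  left <- names(g$nodes)[vapply(g$nodes, function(n) n$kind != "entity", logical(1))]
  if (length(left)) {
    g$notes <- c(g$notes, sprintf("unclassifiable node left in graph: %s",
                                  paste(left, collapse = ", ")))
  }
  g
}

build_ledger <- function(model, schema) {
  rows <- list()
  put <- function(relation, attribute, placement, detail) {
    rows[[length(rows) + 1L]] <<- data.frame(
      relation = relation, attribute = attribute, placement = placement,
      detail = detail, stringsAsFactors = FALSE)
  }
  for (e in model$entities) {
    for (o in e$origins) {
      p <- o$props
      for (i in seq_len(nrow(p))) {
        if (p$promoted[i]) next  # promoted properties have no schema attribute
        put(p$origin_relation[i], p$origin_attribute[i],
            if (p$is_key[i]) "entity_key" else "entity_property",
            sprintf("%s.%s", e$label, p$name[i]))
        if (!is.na(p$lookup_relation[i])) {
          for (a in strsplit(p$lookup_fk_columns[i], "+", fixed = TRUE)[[1]]) {
            put(o$relation, a, "relationship_fk",
                sprintf("lookup FK absorbed into %s.%s", e$label, p$name[i]))
          }
          if (!is.null(schema[[p$lookup_relation[i]]])) {
            for (a in schema[[p$lookup_relation[i]]]$pk) {
              put(p$lookup_relation[i], a, "consumed_lookup_key",
                  sprintf("identity of absorbed %s", p$lookup_relation[i]))
            }
          }
        }
      }
      if (!is.null(o$consumed_fk) && length(o$consumed_fk)) {
        for (a in o$consumed_fk) {
          put(o$relation, a, "relationship_fk",
              sprintf("edge endpoint of entity %s", e$label))
        }
      }
      if (!is.null(o$self_fk)) {
        for (a in o$self_fk$columns) {
          put(o$relation, a, "relationship_fk",
              sprintf("self-relationship %s on %s", o$self_fk$rel_name, e$label))
        }
      }
    }
    if (!is.null(e$subtype)) {
      put(e$subtype$lookup_relation, e$subtype$label_attr, "subtype_source",
          sprintf("subtype labels of %s", e$label))
      for (a in strsplit(e$subtype$lookup_key, "+", fixed = TRUE)[[1]]) {
        put(e$subtype$lookup_relation, a, "consumed_lookup_key",
            sprintf("identity of absorbed %s", e$subtype$lookup_relation))
      }
      for (a in strsplit(e$subtype$fk_columns, "+", fixed = TRUE)[[1]]) {
        put(e$subtype$fk_relation, a, "relationship_fk",
            sprintf("absorbed into subtype labels of %s", e$label))
      }
    }
  }
  # FK attributes that stay part of an entity's identity key (n-ary
  # associations kept as entities) are accounted as entity keys, not again as
  # relationship endpoints
  entity_keys <- character(0)
  for (e in model$entities) {
    for (o in e$origins) {
      p <- o$props
      entity_keys <- c(entity_keys,
                       paste(p$origin_relation[p$is_key], p$origin_attribute[p$is_key]))
    }
  }
  for (r in model$relationships) {
    o <- r$origin
    if (o$kind == "source") {
      for (a in o$fk_a$columns) put(o$relation, a, "relationship_fk",
                                    sprintf("endpoint %s of %s", r$a, r$name))
      for (a in o$fk_b$columns) put(o$relation, a, "relationship_fk",
                                    sprintf("endpoint %s of %s", r$b, r$name))
    } else if (o$kind == "fk") {
      for (a in o$fk$columns) {
        if (paste(o$relation, a) %in% entity_keys) next
        put(o$relation, a, "relationship_fk", sprintf("edge %s", r$name))
      }
    }
    p <- r$props
    for (i in seq_len(nrow(p))) {
      put(p$origin_relation[i], p$origin_attribute[i], "relationship_property",
          sprintf("%s.%s", r$name, p$name[i]))
      if (!is.na(p$lookup_relation[i])) {
        for (a in strsplit(p$lookup_key[i], "+", fixed = TRUE)[[1]]) {
          put(p$lookup_relation[i], a, "consumed_lookup_key",
              sprintf("identity of %s consumed into %s", p$lookup_relation[i],
                      r$name))
        }
        for (a in strsplit(p$lookup_fk_columns[i], "+", fixed = TRUE)[[1]]) {
          put(o$relation, a, "relationship_fk",
              sprintf("lookup FK consumed into %s", r$name))
        }
      }
    }
  }
  ledger <- if (length(rows)) {
    led <- do.call(rbind, rows)
    led[!duplicated(led[c("relation", "attribute", "placement")]), , drop = FALSE]
  } else
    data.frame(relation = character(0), attribute = character(0),
               placement = character(0), detail = character(0),
               stringsAsFactors = FALSE)
  all_attrs <- do.call(rbind, lapply(schema, function(r) {
    data.frame(relation = r$name, attribute = r$attributes$name,
               stringsAsFactors = FALSE)
  }))
  have <- paste(ledger$relation, ledger$attribute)
  miss <- all_attrs[!paste(all_attrs$relation, all_attrs$attribute) %in% have, ,
                    drop = FALSE]
  if (nrow(miss)) {
    ledger <- rbind(ledger, data.frame(relation = miss$relation,
                                       attribute = miss$attribute,
                                       placement = "unaccounted", detail = "",
                                       stringsAsFactors = FALSE))
  }
  rownames(ledger) <- NULL
  ledger
}

#' Derive the property-graph model from a relational schema
#'
#' Runs the full transformation pipeline: schema-graph construction, sink
#' merging, entity fusion, source resolution and FK-hub resolution, then turns
#' the remaining entity nodes into entity types and the undirected edges into
#' relationship types. Relationship names come from `name_map` (keyed by
#' associative relation name, or `"Relation.fkcolumn"` for FK-derived edges),
#' with `Has<Target>` / association-name fallbacks.
#'
#' @param schema a validated [relational_schema()].
#' @param name_map named list mapping origin keys to relationship names.
#' @return an object of class `graph_model`.
#' @export
derive_graph_model <- function(schema, name_map = list()) {
  g <- build_schema_graph(schema)
  g <- merge_sinks(g)
  g <- merge_entities(g)
  g <- resolve_sources(g)
  g <- resolve_fk_hubs(g)
  g <- finalize_schema_graph(g)

  entities <- list()
  for (id in lex_sort(names(g$nodes))) {
    n <- g$nodes[[id]]
    if (n$kind != "entity") next
    keep <- !(n$carried$attribute %in% n$consumed_fk &
                n$carried$relation == n$relation)
    props <- do.call(rbind, lapply(which(keep), function(i) {
      entity_prop_row(n$carried$attribute[i], n$carried$type[i],
                      n$carried$relation[i], n$carried$attribute[i],
                      is_key = n$carried$is_pk[i])
    }))
    entities[[id]] <- list(
      label = id, subtype = NULL,
      origins = list(list(relation = n$relation, key_attrs = n$key_attrs,
                          props = props, consumed_fk = n$consumed_fk,
                          self_fk = NULL)))
  }
  rels <- g$relationships
  for (i in seq_along(rels)) {
    key <- rel_name_key(rels[[i]])
    rels[[i]]$name <- as.character(name_map[[key]] %||% default_rel_name(rels[[i]]))
  }
  ord <- order(vapply(rels, function(r) r$name, character(1)), method = "radix")
  model <- structure(
    list(entities = entities, relationships = rels[ord], promotions = list(),
         name_map = name_map, notes = g$notes, schema = schema),
    class = "graph_model")
  model$ledger <- build_ledger(model, schema)
  validate_graph_model(model)
  model
}

#' Validate internal consistency of a graph model
#'
#' Checks that every relationship endpoint resolves to a declared entity and
#' that property names are unique per entity. Called after every refinement
#' rule.
#'
#' @param m a `graph_model`.
#' @return `m`, invisibly; errors on inconsistency.
#' @export
validate_graph_model <- function(m) {
  labs <- names(m$entities)
  for (r in m$relationships) {
    if (!r$a %in% labs || !r$b %in% labs) {
      stop2("relationship %s has unresolved endpoint (%s, %s)", r$name, r$a, r$b)
    }
  }
  for (e in m$entities) {
    nms <- unlist(lapply(e$origins, function(o) o$props$name))
    dup <- nms[duplicated(nms)]
    # the same property may be contributed by several origins (e.g. a shared
    # id key after a hierarchy merge), but within one origin names are unique
    for (o in e$origins) {
      if (anyDuplicated(o$props$name)) {
        stop2("entity %s: duplicate property '%s'",
              e$label, o$props$name[duplicated(o$props$name)][1])
      }
    }
  }
  invisible(m)
}

#' @export
print.graph_model <- function(x, ...) {
  cat(sprintf("<graph_model> %d entities, %d relationships\n",
              length(x$entities), length(x$relationships)))
  for (e in x$entities) {
    sub <- if (!is.null(e$subtype)) sprintf(" [subtyped by %s.%s]",
                                            e$subtype$lookup_relation,
                                            e$subtype$label_attr) else ""
    props <- unlist(lapply(e$origins, function(o) o$props$name))
    cat(sprintf("  (%s)%s {%s}\n", e$label, sub, paste(unique(props), collapse = ", ")))
  }
  for (r in x$relationships) {
    pr <- if (nrow(r$props)) sprintf(" {%s}", paste(r$props$name, collapse = ", ")) else ""
    cat(sprintf("  (%s)-[%s%s]->(%s)\n", r$a, r$name, pr, r$b))
  }
  if (length(x$promotions)) {
    cat(sprintf("  promotions: %s\n", paste(names(x$promotions), collapse = ", ")))
  }
  invisible(x)
}

#' Audit attribute conservation of a derived model
#'
#' Verifies that every (relation, attribute) pair of the source schema appears
#' exactly once in the model's placement ledger (entity property/key,
#' relationship property, relationship endpoint FK, consumed lookup key).
#'
#' @param model a `graph_model`.
#' @param schema the source schema (defaults to the model's own).
#' @return data frame of offending attributes (zero rows when conservation
#'   holds), with a `problem` column (`"unaccounted"` or `"duplicated"`).
#' @export
model_audit <- function(model, schema = model$schema) {
  led <- model$ledger
  keys <- paste(led$relation, led$attribute)
  dup <- unique(keys[duplicated(keys)])
  out <- list()
  if (length(dup)) {
    parts <- do.call(rbind, strsplit(dup, " ", fixed = TRUE))
    out[[1]] <- data.frame(relation = parts[, 1], attribute = parts[, 2],
                           problem = "duplicated", stringsAsFactors = FALSE)
  }
  un <- led[led$placement == "unaccounted", , drop = FALSE]
  if (nrow(un)) {
    out[[length(out) + 1L]] <- data.frame(relation = un$relation,
                                          attribute = un$attribute,
                                          problem = "unaccounted",
                                          stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(relation = character(0), attribute = character(0),
                      problem = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Serialize a graph model to a YAML document
#'
#' Lists entities (with properties and origins), relationships, promotions and
#' the attribute-placement ledger. Round-trips through [read_graph_model()].
#'
#' @param model a `graph_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graph_model <- function(model, path) {
  df_to_list <- function(df) lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, , drop = FALSE])
    lapply(row, function(v) if (is.na(v)) NULL else unname(v))
  })
  doc <- list(
    entities = lapply(unname(model$entities), function(e) {
      list(label = e$label, subtype = e$subtype,
           origins = lapply(e$origins, function(o) {
             list(relation = o$relation, key_attrs = as.list(o$key_attrs),
                  consumed_fk = as.list(o$consumed_fk %||% character(0)),
                  self_fk = o$self_fk, props = df_to_list(o$props))
           }))
    }),
    relationships = lapply(model$relationships, function(r) {
      list(name = r$name, a = r$a, b = r$b, origin = r$origin,
           props = df_to_list(r$props))
    }),
    promotions = model$promotions,
    name_map = model$name_map,
    notes = as.list(model$notes),
    ledger = df_to_list(model$ledger)
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

list_to_df <- function(rows, template) {
  if (!length(rows)) return(template)
  out <- do.call(rbind, lapply(rows, function(row) {
    vals <- lapply(names(template), function(nm) {
      v <- row[[nm]]
      if (is.null(v)) {
        if (is.logical(template[[nm]])) NA else NA_character_
      } else v
    })
    names(vals) <- names(template)
    as.data.frame(vals, stringsAsFactors = FALSE)
  }))
  for (nm in names(template)) {
    if (is.logical(template[[nm]])) out[[nm]] <- as.logical(out[[nm]])
  }
  rownames(out) <- NULL
  out
}

#' Read a serialized graph model
#'
#' @param path a YAML document written by [write_graph_model()].
#' @return a `graph_model` (without the source-schema reference).
#' @export
read_graph_model <- function(path) {
  doc <- yaml::read_yaml(path)
  entities <- list()
  for (e in doc$entities) {
    entities[[e$label]] <- list(
      label = e$label, subtype = e$subtype,
      origins = lapply(e$origins, function(o) {
        list(relation = o$relation, key_attrs = unlist(o$key_attrs),
             consumed_fk = as.character(unlist(o$consumed_fk)),
             self_fk = o$self_fk,
             props = list_to_df(o$props,
                                entity_prop_row("x", "text", "r", "a")[0, ]))
      }))
  }
  rels <- lapply(doc$relationships, function(r) {
    r$origin$fk$columns <- unlist(r$origin$fk$columns)
    r$origin$fk_a$columns <- unlist(r$origin$fk_a$columns)
    r$origin$fk_b$columns <- unlist(r$origin$fk_b$columns)
    list(name = r$name, a = r$a, b = r$b, origin = r$origin,
         props = list_to_df(r$props, empty_rel_props()))
  })
  model <- structure(
    list(entities = entities, relationships = rels,
         promotions = doc$promotions %||% list(),
         name_map = doc$name_map %||% list(),
         notes = as.character(unlist(doc$notes)),
         schema = NULL,
         ledger = list_to_df(doc$ledger,
           data.frame(relation = character(0), attribute = character(0),
                      placement = character(0), detail = character(0),
                      stringsAsFactors = FALSE))),
    class = "graph_model")
  validate_graph_model(model)
  model
}
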