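# Intermediate schema graph: one node per relational attribute (composite PKs
# merged into a single PK node, composite FKs into a single FK node), directed
# edges PK -> non-key attribute and FK -> referenced PK. The merge/resolution
# steps rewrite this graph into entity nodes and undirected relationship edges.

sg_node <- function(id, relation, kind, carried, fk = NULL, key_attrs = NULL,
                    consumed_fk = character(0)) {
  list(id = id, relation = relation, kind = kind, carried = carried, fk = fk,
       key_attrs = key_attrs, consumed_fk = consumed_fk)
}

carried_df <- function(relation, attributes, types, is_pk) {
  data.frame(relation = relation, attribute = attributes, type = types,
             is_pk = is_pk, stringsAsFactors = FALSE)
}

empty_edges <- function() {
  data.frame(from = character(0), to = character(0), kind = character(0),
             rel = character(0), fk_id = integer(0), stringsAsFactors = FALSE)
}

pk_node_id <- function(schema, relname) {
  pk <- schema[[relname]]$pk
  if (length(pk) == 1L) paste0(relname, ".", pk) else paste0(relname, ".PK")
}

#' Build the schema graph from a relational schema
#'
#' Creates one node per attribute, merges composite-PK attributes into a single
#' PK node (and composite FKs into a single FK node), then adds directed edges
#' from each PK node to the non-key attribute nodes of its relation and from
#' each FK node to the referenced PK node. FKs whose source attributes are part
#' of the primary key emit their edge directly from the PK node.
#'
#' @param schema a validated [relational_schema()].
#' @return an object of class `schema_graph`.
#' @export
build_schema_graph <- function(schema) {
  nodes <- list()
  edges <- list()
  add_edge <- function(from, to, kind, rel = NA_character_, fk_id = NA_integer_) {
    edges[[length(edges) + 1L]] <<- data.frame(
      from = from, to = to, kind = kind, rel = rel, fk_id = fk_id,
      stringsAsFactors = FALSE)
  }
  for (nm in lex_sort(names(schema))) {
    r <- schema[[nm]]
    pk <- r$pk
    types <- stats::setNames(r$attributes$type, r$attributes$name)
    pknode <- pk_node_id(schema, nm)
    nodes[[pknode]] <- sg_node(pknode, nm, "pk",
                               carried_df(nm, pk, unname(types[pk]), TRUE))
    in_fk <- character(0)
    for (i in seq_along(r$fks)) {
      fk <- r$fks[[i]]
      target <- pk_node_id(schema, fk$ref_table)
      if (all(fk$columns %in% pk)) {
        add_edge(pknode, target, "fk", nm, i)
      } else if (any(fk$columns %in% pk)) {
        stop2("relation %s: FK (%s) mixes PK and non-PK attributes; unsupported",
              nm, paste(fk$columns, collapse = ","))
      } else {
        fid <- paste0(nm, ".", paste(fk$columns, collapse = "_"))
        nodes[[fid]] <- sg_node(fid, nm, "fk",
                                carried_df(nm, fk$columns,
                                           unname(types[fk$columns]), FALSE),
                                fk = fk)
        add_edge(pknode, fid, "attr", nm)
        add_edge(fid, target, "fk", nm, i)
        in_fk <- c(in_fk, fk$columns)
      }
    }
    plain <- setdiff(r$attributes$name, c(pk, in_fk))
    for (a in plain) {
      aid <- paste0(nm, ".", a)
      nodes[[aid]] <- sg_node(aid, nm, "attr", carried_df(nm, a, unname(types[a]), FALSE))
      add_edge(pknode, aid, "attr", nm)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else empty_edges()
  structure(list(nodes = nodes, edges = edges, relationships = list(),
                 schema = schema, notes = character(0)),
            class = "schema_graph")
}

#' @export
print.schema_graph <- function(x, ...) {
  kinds <- table(vapply(x$nodes, function(n) n$kind, character(1)))
  cat(sprintf("<schema_graph> %d nodes (%s), %d directed edges, %d relationships\n",
              length(x$nodes),
              paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", "),
              nrow(x$edges), length(x$relationships)))
  invisible(x)
}

sg_indeg <- function(g, id) sum(g$edges$to == id)
sg_outdeg <- function(g, id) sum(g$edges$from == id)

#' Classify a schema-graph node as sink, source, hub or isolated
#'
#' Computed from the current directed edges only: a sink has no outgoing edges,
#' a source no incoming, a hub both, an isolated node neither.
#'
#' @param g a `schema_graph`.
#' @param id node identifier (its label).
#' @return one of `"sink"`, `"source"`, `"hub"`, `"isolated"`.
#' @export
classify <- function(g, id) {
  if (is.null(g$nodes[[id]])) stop2("unknown node '%s'", id)
  i <- sg_indeg(g, id)
  o <- sg_outdeg(g, id)
  if (i > 0 && o > 0) "hub"
  else if (o == 0 && i > 0) "sink"
  else if (i == 0 && o > 0) "source"
  else "isolated"
}

# Drop nodes (and their edges) from the graph.
sg_drop <- function(g, ids) {
  g$nodes[ids] <- NULL
  g$edges <- g$edges[!(g$edges$from %in% ids | g$edges$to %in% ids), , drop = FALSE]
  g
}

# Rename node old -> new in the edge table, dropping attr self-loops created
# by a merge and collapsing duplicate edges.
sg_rewire <- function(g, old, new) {
  g$edges$from[g$edges$from %in% old] <- new
  g$edges$to[g$edges$to %in% old] <- new
  g$edges <- g$edges[!(g$edges$from == new & g$edges$to == new &
                         g$edges$kind == "attr"), , drop = FALSE]
  g$edges <- unique(g$edges)
  rownames(g$edges) <- NULL
  g
}

#' Merge sink attribute nodes under their PK node (step 5)
#'
#' All plain-attribute sinks that hang off the same PK node with exactly one
#' incoming edge are merged into a single node labeled `R.attributes` carrying
#' the union of their attributes. A single qualifying sink is relabeled (a
#' merge of one). Sinks with more than one incoming edge are untouched.
#'
#' @param g a `schema_graph`.
#' @return the rewritten graph.
#' @export
merge_sinks <- function(g) {
  ids <- lex_sort(names(g$nodes))
  cand <- ids[vapply(ids, function(i) {
    n <- g$nodes[[i]]
    n$kind == "attr" && sg_outdeg(g, i) == 0 && sg_indeg(g, i) == 1
  }, logical(1))]
  if (!length(cand)) return(g)
  parent_of <- vapply(cand, function(i) g$edges$from[g$edges$to == i], character(1))
  keep <- vapply(parent_of, function(p) {
    !is.null(g$nodes[[p]]) && g$nodes[[p]]$kind == "pk"
  }, logical(1))
  cand <- cand[keep]
  parent_of <- parent_of[keep]
  for (p in lex_sort(unique(parent_of))) {
    children <- lex_sort(cand[parent_of == p])
    rel <- g$nodes[[p]]$relation
    new_id <- paste0(rel, ".attributes")
    carried <- do.call(rbind, lapply(children, function(i) g$nodes[[i]]$carried))
    g <- sg_drop(g, children)
    g$nodes[[new_id]] <- sg_node(new_id, rel, "sink", carried)
    g$edges <- rbind(g$edges, data.frame(from = p, to = new_id, kind = "attr",
                                         rel = rel, fk_id = NA_integer_,
                                         stringsAsFactors = FALSE))
  }
  g
}

#' Fuse PK hubs with their merged sink into entity nodes (step 6)
#'
#' A PK node with incoming edges (a hub) and exactly one outgoing edge leading
#' to a merged sink is fused with that sink into an entity node labeled with
#' the relation name, carrying the union of hub and sink attributes. All other
#' edges are rewired onto the entity node. A hub whose merged sink has further
#' incoming edges is left untouched and reported.
#'
#' @param g a `schema_graph`.
#' @return the rewritten graph.
#' @export
merge_entities <- function(g) {
  for (p in lex_sort(names(g$nodes))) {
    n <- g$nodes[[p]]
    if (is.null(n) || n$kind != "pk") next
    if (sg_indeg(g, p) == 0) next   # not a hub; sources are handled later
    targets <- g$edges$to[g$edges$from == p]
    sinks <- targets[vapply(targets, function(t) {
      !is.null(g$nodes[[t]]) && g$nodes[[t]]$kind == "sink"
    }, logical(1))]
    if (length(sinks) != 1L) next
    s <- sinks[[1]]
    if (sg_indeg(g, s) != 1L) {
      g$notes <- c(g$notes, sprintf(
        "unclassifiable: merged sink %s of PK hub %s has other incoming edges", s, p))
      next
    }
    ent <- n$relation
    carried <- rbind(n$carried, g$nodes[[s]]$carried)
    key_attrs <- carried$attribute[carried$is_pk]
    g$nodes[[ent]] <- sg_node(ent, n$relation, "entity", carried,
                              key_attrs = key_attrs)
    g <- sg_rewire(g, c(p, s), ent)
    if (!identical(p, ent)) g$nodes[[p]] <- NULL
    if (!identical(s, ent)) g$nodes[[s]] <- NULL
  }
  g
}

empty_rel_props <- function() {
  data.frame(name = character(0), type = character(0),
             origin_relation = character(0), origin_attribute = character(0),
             lookup_relation = character(0), lookup_fk_columns = character(0),
             lookup_key = character(0), stringsAsFactors = FALSE)
}

rel_prop_row <- function(name, type, origin_relation, origin_attribute,
                         lookup_relation = NA_character_,
                         lookup_fk_columns = NA_character_,
                         lookup_key = NA_character_) {
  data.frame(name = name, type = type, origin_relation = origin_relation,
             origin_attribute = origin_attribute,
             lookup_relation = lookup_relation,
             lookup_fk_columns = lookup_fk_columns, lookup_key = lookup_key,
             stringsAsFactors = FALSE)
}

#' Resolve source nodes into relationship edges (step 7)
#'
#' Every source connected by FK edges to exactly two entity nodes becomes an
#' undirected relationship edge between them. A further edge to a merged sink
#' contributes the sink's attributes as relationship properties; a further edge
#' to an FK hub whose only other edge reaches an otherwise unreferenced entity
#' with a single non-identifying attribute pulls that attribute in as a
#' relationship property and removes hub and entity. Sources matching neither
#' pattern (e.g. ternary associations) are left untouched.
#'
#' @param g a `schema_graph`.
#' @return the rewritten graph.
#' @export
resolve_sources <- function(g) {
  for (sid in lex_sort(names(g$nodes))) {
    n <- g$nodes[[sid]]
    if (is.null(n) || n$kind == "entity" || n$kind == "sink") next
    if (sg_indeg(g, sid) != 0 || sg_outdeg(g, sid) == 0) next
    oe <- g$edges[g$edges$from == sid, , drop = FALSE]
    is_fk_ent <- oe$kind == "fk" & vapply(oe$to, function(t) {
      !is.null(g$nodes[[t]]) && g$nodes[[t]]$kind == "entity"
    }, logical(1))
    if (sum(is_fk_ent) != 2L) next
    fe <- oe[is_fk_ent, , drop = FALSE]
    fe <- fe[order(fe$fk_id), , drop = FALSE]
    others <- oe[!is_fk_ent, , drop = FALSE]
    props <- empty_rel_props()
    consumed <- character(0)
    ok <- TRUE
    for (t in lex_sort(others$to)) {
      tn <- g$nodes[[t]]
      if (!is.null(tn) && tn$kind == "sink" && sg_indeg(g, t) == 1L) {
        props <- rbind(props, do.call(rbind, lapply(seq_len(nrow(tn$carried)),
          function(i) rel_prop_row(tn$carried$attribute[i], tn$carried$type[i],
                                   tn$carried$relation[i], tn$carried$attribute[i]))))
        consumed <- c(consumed, t)
      } else if (!is.null(tn) && tn$kind == "fk" &&
                 sg_indeg(g, t) == 1L && sg_outdeg(g, t) == 1L) {
        rid <- g$edges$to[g$edges$from == t]
        rn <- g$nodes[[rid]]
        if (is.null(rn) || rn$kind != "entity" ||
            sg_indeg(g, rid) != 1L || sg_outdeg(g, rid) != 0L) { ok <- FALSE; break }
        extra <- rn$carried[!rn$carried$is_pk, , drop = FALSE]
        if (nrow(extra) != 1L) { ok <- FALSE; break }
        props <- rbind(props, rel_prop_row(
          extra$attribute, extra$type, extra$relation, extra$attribute,
          lookup_relation = rn$relation,
          lookup_fk_columns = paste(tn$fk$columns, collapse = "+"),
          lookup_key = paste(g$schema[[rn$relation]]$pk, collapse = "+")))
        consumed <- c(consumed, t, rid)
      } else { ok <- FALSE; break }
    }
    if (!ok) next
    fka <- g$schema[[n$relation]]$fks[[fe$fk_id[1]]]
    fkb <- g$schema[[n$relation]]$fks[[fe$fk_id[2]]]
    g$relationships[[length(g$relationships) + 1L]] <- list(
      name = NA_character_, a = fe$to[1], b = fe$to[2],
      origin = list(kind = "source", relation = n$relation,
                    fk_a = list(columns = fka$columns, ref_table = fka$ref_table),
                    fk_b = list(columns = fkb$columns, ref_table = fkb$ref_table)),
      props = props)
    g <- sg_drop(g, unique(c(sid, consumed)))
  }
  g
}

#' Resolve remaining FK nodes into relationship edges (step 8)
#'
#' Case 1: an FK node with exactly one incoming edge from an entity (its owner)
#' and one outgoing edge to an entity (its target) is replaced by an undirected
#' relationship between the two. Case 2: a source PK node with one FK edge to
#' an entity and one edge to its merged sink is first fused with the sink into
#' a new entity (the FK attribute is consumed), which is then connected to the
#' other entity by a relationship. Applied until a fixpoint is reached.
#'
#' @param g a `schema_graph`.
#' @return the rewritten graph.
#' @export
resolve_fk_hubs <- function(g) {
  repeat {
    changed <- FALSE
    for (hid in lex_sort(names(g$nodes))) {
      n <- g$nodes[[hid]]
      if (is.null(n)) next
      if (n$kind == "fk" && sg_indeg(g, hid) == 1L && sg_outdeg(g, hid) == 1L) {
        src <- g$edges$from[g$edges$to == hid]
        oe <- g$edges[g$edges$from == hid, , drop = FALSE]
        if (oe$kind != "fk") next
        tgt <- oe$to
        if (is.null(g$nodes[[src]]) || g$nodes[[src]]$kind != "entity") next
        if (is.null(g$nodes[[tgt]]) || g$nodes[[tgt]]$kind != "entity") next
        g$relationships[[length(g$relationships) + 1L]] <- list(
          name = NA_character_, a = src, b = tgt,
          origin = list(kind = "fk", relation = n$relation,
                        fk = list(columns = n$fk$columns,
                                  ref_table = n$fk$ref_table,
                                  optional = n$fk$optional)),
          props = empty_rel_props())
        g <- sg_drop(g, hid)
        changed <- TRUE
      } else if (n$kind == "pk" && sg_indeg(g, hid) == 0L) {
        oe <- g$edges[g$edges$from == hid, , drop = FALSE]
        if (nrow(oe) != 2L) next
        fk_e <- oe[oe$kind == "fk", , drop = FALSE]
        at_e <- oe[oe$kind == "attr", , drop = FALSE]
        if (nrow(fk_e) != 1L || nrow(at_e) != 1L) next
        m <- fk_e$to
        o <- at_e$to
        if (is.null(g$nodes[[m]]) || g$nodes[[m]]$kind != "entity") next
        if (is.null(g$nodes[[o]]) || g$nodes[[o]]$kind != "sink" ||
            sg_indeg(g, o) != 1L) next
        fk <- g$schema[[n$relation]]$fks[[fk_e$fk_id]]
        carried <- rbind(n$carried, g$nodes[[o]]$carried)
        ent <- n$relation
        g$nodes[[ent]] <- sg_node(ent, n$relation, "entity", carried,
                                  key_attrs = carried$attribute[carried$is_pk],
                                  consumed_fk = fk$columns)
        g$relationships[[length(g$relationships) + 1L]] <- list(
          name = NA_character_, a = ent, b = m,
          origin = list(kind = "fk", relation = n$relation,
                        fk = list(columns = fk$columns, ref_table = fk$ref_table,
                                  optional = fk$optional),
                        via_new_entity = TRUE),
          props = empty_rel_props())
        g <- sg_drop(g, c(hid, o))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  g
}
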