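# Migration of a relational instance into a labeled property graph conforming
# to a (refined) graph model, plus migration validation and duplicate-free
# pattern queries.

node_id_for <- function(label, keys) paste0(label, ":", gsub("\x1f", "|", keys))

# The entity (label + origin spec) whose origin list contains `rel`.
entity_for_relation <- function(model, rel) {
  for (e in model$entities) {
    for (o in e$origins) {
      if (identical(o$relation, rel)) return(list(label = e$label, origin = o))
    }
  }
  NULL
}

canonical_fusion <- function(catalog, values) {
  if (is.null(catalog)) return(toupper(trimws(values)))
  vapply(values, function(v) resolve_fusion(catalog, v), character(1),
         USE.NAMES = FALSE)
}

empty_edge_df <- function() {
  data.frame(type = character(0), src = character(0), dst = character(0),
             stringsAsFactors = FALSE)
}

#' Migrate a relational instance into a property graph
#'
#' Creates one node per row of each entity-origin relation (merge semantics on
#' the identity key `label:PK`, so migration is idempotent), one edge per row
#' of each relationship-origin relation or per non-null FK value, relationship
#' properties populated from consumed attributes (including FK-lookup
#' properties such as a diagnosis-addition description), and promoted
#' dynamic-field values either stored on the host node or deduplicated into
#' shared nodes (one node per distinct canonicalized value). Null properties
#' are omitted.
#'
#' @param inst a `relational_instance`.
#' @param model a (refined) `graph_model`.
#' @param catalog optional [fusion_catalog()] used to canonicalize
#'   entity-promoted values; without it values are uppercased and trimmed.
#' @param check_integrity run [check_referential_integrity()] first.
#' @param skip_violations drop offending rows instead of failing.
#' @return list with elements `graph` (a `property_graph`) and `report` (a
#'   `migration_report`).
#' @export
migrate <- function(inst, model, catalog = NULL, check_integrity = TRUE,
                    skip_violations = FALSE) {
  tables <- inst$tables
  skipped <- data.frame(relation = character(0), rows = integer(0),
                        stringsAsFactors = FALSE)
  if (check_integrity) {
    viol <- check_referential_integrity(inst)
    if (nrow(viol) && !skip_violations) {
      stop2("referential integrity violated (%d rows, first: %s row %d); %s",
            nrow(viol), viol$relation[1], viol$row[1],
            "use skip_violations = TRUE to drop offending rows")
    }
    # dropping a row can orphan its dependents, so cascade until stable
    while (nrow(viol)) {
      for (nm in unique(viol$relation)) {
        bad <- unique(viol$row[viol$relation == nm])
        tables[[nm]] <- tables[[nm]][-bad, , drop = FALSE]
        skipped <- rbind(skipped, data.frame(relation = nm, rows = length(bad),
                                             stringsAsFactors = FALSE))
      }
      tmp <- inst
      tmp$tables <- tables
      viol <- check_referential_integrity(tmp)
    }
  }

  promos <- model$promotions
  dyn_rel <- NULL
  promoted_mask <- NULL
  if (length(promos)) {
    dyn_label <- promos[[1]]$dyn_entity
    dyn_rel <- model$entities[[dyn_label]]$origins[[1]]$relation
    dtbl <- tables[[dyn_rel]]
    key_attr <- promos[[1]]$key_attr
    promoted_mask <- dtbl[[key_attr]] %in% vapply(promos, `[[`, "", "key")
  }
  dyn_keep <- function(rel, tbl) {
    if (!is.null(dyn_rel) && identical(rel, dyn_rel)) {
      tbl[!promoted_mask, , drop = FALSE]
    } else tbl
  }

  nodes <- new.env(parent = emptyenv())
  put_node <- function(id, labels, props) {
    old <- nodes[[id]]
    if (is.null(old)) {
      nodes[[id]] <- list(id = id, labels = labels, props = props)
    } else {
      same <- intersect(names(old$props), names(props))
      conflict <- same[vapply(same, function(k) {
        !identical(format_value(old$props[[k]]), format_value(props[[k]]))
      }, logical(1))]
      if (length(conflict)) {
        stop2("identity collision on %s: conflicting property '%s'",
              id, conflict[1])
      }
      nodes[[id]] <- list(id = id, labels = unique(c(old$labels, labels)),
                          props = utils::modifyList(old$props, props))
    }
  }

  # --- entity nodes ----------------------------------------------------------
  for (lab in lex_sort(names(model$entities))) {
    e <- model$entities[[lab]]
    for (o in e$origins) {
      if (is.na(o$relation)) next        # promoted shared entities come later
      tbl <- dyn_keep(o$relation, tables[[o$relation]])
      if (is.null(tbl) || !nrow(tbl)) next
      ids <- node_id_for(lab, key_string(tbl, o$key_attrs))
      labsets <- rep(list(lab), nrow(tbl))
      if (!is.null(e$subtype) && identical(e$subtype$fk_relation, o$relation)) {
        st <- e$subtype
        fkc <- strsplit(st$fk_columns, "+", fixed = TRUE)[[1]]
        master <- tables[[st$lookup_relation]]
        mk <- strsplit(st$lookup_key, "+", fixed = TRUE)[[1]]
        idx <- match(key_string(tbl, fkc), key_string(master, mk))
        tv <- master[[st$label_attr]][idx]
        labsets <- lapply(seq_len(nrow(tbl)), function(i) {
          if (is.na(tv[i])) lab else c(lab, subtype_label(tv[i], st$suffix))
        })
      }
      pr <- o$props[!o$props$promoted, , drop = FALSE]
      vals <- lapply(seq_len(nrow(pr)), function(i) {
        if (is.na(pr$lookup_relation[i])) {
          tbl[[pr$origin_attribute[i]]]
        } else {
          fkc <- strsplit(pr$lookup_fk_columns[i], "+", fixed = TRUE)[[1]]
          ref <- tables[[pr$lookup_relation[i]]]
          rpk <- model$schema[[pr$lookup_relation[i]]]$pk %||% names(ref)[1]
          ref[[pr$origin_attribute[i]]][match(key_string(tbl, fkc),
                                              key_string(ref, rpk))]
        }
      })
      names(vals) <- pr$name
      for (i in seq_len(nrow(tbl))) {
        p <- lapply(vals, function(v) v[[i]])
        put_node(ids[i], labsets[[i]], p[!vapply(p, is.na, logical(1))])
      }
    }
  }

  edges_acc <- list()
  add_edges <- function(type, src, dst, props = NULL) {
    if (!length(src)) return(invisible())
    df <- data.frame(type = type, src = src, dst = dst, stringsAsFactors = FALSE)
    df$props <- props %||% rep(list(list()), nrow(df))
    edges_acc[[length(edges_acc) + 1L]] <<- df
  }

  # --- promoted dynamic fields ----------------------------------------------
  promo_pairs <- list()
  if (length(promos)) {
    dtbl <- tables[[dyn_rel]]
    link <- Filter(function(r) identical(r$origin$relation, dyn_rel) &&
                     r$origin$kind == "fk", model$relationships)
    host_fk <- if (length(link)) link[[1]]$origin$fk$columns else
      stop2("cannot locate the dynamic-field host FK in the model")
    for (p in promos) {
      rows <- dtbl[dtbl[[p$key_attr]] == p$key, , drop = FALSE]
      if (!nrow(rows)) next
      host_lab <- p$host
      host_key <- key_string(rows, host_fk)
      host_ids <- node_id_for(host_lab, host_key)
      if (p$mode == "attribute") {
        for (i in seq_len(nrow(rows))) {
          v <- rows[[p$value_attr]][i]
          if (!is.na(v)) {
            put_node(host_ids[i], host_lab, stats::setNames(list(v), p$key))
          }
        }
      } else {
        canon <- canonical_fusion(catalog, rows[[p$value_attr]])
        keep <- !is.na(canon)
        for (cv in unique(canon[keep])) {
          props <- list(name = cv)
          if (!is.null(catalog) && !is.null(catalog$aliases[[cv]])) {
            oth <- setdiff(catalog$aliases[[cv]], cv)
            if (length(oth)) props$other_names <- paste(oth, collapse = "; ")
          }
          put_node(node_id_for(p$entity, cv), p$entity, props)
        }
        pair <- unique(data.frame(type = p$rel, src = host_ids[keep],
                                  dst = node_id_for(p$entity, canon[keep]),
                                  stringsAsFactors = FALSE))
        promo_pairs[[length(promo_pairs) + 1L]] <- pair
        add_edges(p$rel, pair$src, pair$dst)
      }
    }
  }

  # --- relationship edges ----------------------------------------------------
  for (r in model$relationships) {
    o <- r$origin
    if (o$kind == "promoted") next
    tbl <- dyn_keep(o$relation, tables[[o$relation]])
    if (is.null(tbl) || !nrow(tbl)) next
    if (o$kind == "source") {
      la <- entity_for_relation(model, o$fk_a$ref_table)
      lb <- entity_for_relation(model, o$fk_b$ref_table)
      src <- node_id_for(la$label, key_string(tbl, o$fk_a$columns))
      dst <- node_id_for(lb$label, key_string(tbl, o$fk_b$columns))
      props <- rep(list(list()), nrow(tbl))
      for (i in seq_len(nrow(r$props))) {
        p <- r$props[i, ]
        v <- if (is.na(p$lookup_relation)) {
          tbl[[p$origin_attribute]]
        } else {
          fkc <- strsplit(p$lookup_fk_columns, "+", fixed = TRUE)[[1]]
          ref <- tables[[p$lookup_relation]]
          rpk <- strsplit(p$lookup_key, "+", fixed = TRUE)[[1]]
          ref[[p$origin_attribute]][match(key_string(tbl, fkc),
                                          key_string(ref, rpk))]
        }
        for (j in seq_len(nrow(tbl))) {
          if (!is.na(v[[j]])) props[[j]][[p$name]] <- v[[j]]
        }
      }
      add_edges(r$name, src, dst, props)
    } else {  # fk-derived (including self-relationships and 8.2 edges)
      owner <- entity_for_relation(model, o$relation)
      fkc <- o$fk$columns
      nn <- !Reduce(`|`, lapply(fkc, function(a) is.na(tbl[[a]])))
      if (!any(nn)) next
      sub <- tbl[nn, , drop = FALSE]
      src <- node_id_for(owner$label, key_string(sub, owner$origin$key_attrs))
      tgt <- entity_for_relation(model, o$fk$ref_table)
      dst <- node_id_for(tgt$label, key_string(sub, fkc))
      add_edges(r$name, src, dst)
    }
  }

  edges <- if (length(edges_acc)) do.call(rbind, edges_acc) else {
    df <- empty_edge_df(); df$props <- list(); df
  }
  if (nrow(edges)) {
    ek <- paste(edges$type, edges$src, edges$dst,
                vapply(edges$props, function(p) {
                  paste(names(p), vapply(p, format_value, character(1)),
                        collapse = ";")
                }, character(1)), sep = "\x1f")
    edges <- edges[!duplicated(ek), , drop = FALSE]
    rownames(edges) <- NULL
  }
  node_list <- as.list(nodes)
  node_list <- node_list[lex_sort(names(node_list))]
  # dangling edge endpoints would indicate a model/ETL bug
  if (nrow(edges)) {
    miss <- setdiff(c(edges$src, edges$dst), names(node_list))
    if (length(miss)) stop2("edge references missing node %s", miss[1])
  }
  pg <- structure(list(nodes = node_list, edges = edges, model = model),
                  class = "property_graph")

  prim <- vapply(node_list, function(n) n$labels[1], character(1))
  report <- structure(list(
    node_counts = table(prim),
    edge_counts = if (nrow(edges)) table(edges$type) else table(character(0)),
    skipped = skipped,
    ledger = model$ledger), class = "migration_report")
  list(graph = pg, report = report)
}

#' @export
print.property_graph <- function(x, ...) {
  cat(sprintf("<property_graph> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  prim <- vapply(x$nodes, function(n) n$labels[1], character(1))
  tb <- sort(table(prim), decreasing = TRUE)
  cat("  nodes:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  if (nrow(x$edges)) {
    te <- sort(table(x$edges$type), decreasing = TRUE)
    cat("  edges:", paste(sprintf("%s=%d", names(te), te), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.migration_report <- function(x, ...) {
  cat("<migration_report>\n  nodes per label:\n")
  for (nm in names(x$node_counts)) cat(sprintf("    %s: %d\n", nm, x$node_counts[[nm]]))
  cat("  edges per type:\n")
  for (nm in names(x$edge_counts)) cat(sprintf("    %s: %d\n", nm, x$edge_counts[[nm]]))
  if (nrow(x$skipped)) {
    cat("  skipped rows:\n")
    for (i in seq_len(nrow(x$skipped))) {
      cat(sprintf("    %s: %d\n", x$skipped$relation[i], x$skipped$rows[i]))
    }
  }
  invisible(x)
}

#' Validate a migration against its source instance
#'
#' Asserts that the node count of every entity equals the row count of its
#' origin relation(s) (distinct canonicalized values for promoted entities),
#' that edge counts match source rows / non-null FK values, and that every
#' associative table can be reconstructed set-exactly from the edges. All
#' mismatches are report items, not errors.
#'
#' @param inst the migrated `relational_instance`.
#' @param pg the resulting `property_graph`.
#' @param model the governing `graph_model`.
#' @param catalog catalog used during migration (for promoted-value counts).
#' @return data frame with columns `check`, `expected`, `actual`, `ok`.
#' @export
validate_migration <- function(inst, pg, model, catalog = NULL) {
  tables <- inst$tables
  promos <- model$promotions
  dyn_rel <- NULL; promoted_mask <- NULL
  if (length(promos)) {
    dyn_rel <- model$entities[[promos[[1]]$dyn_entity]]$origins[[1]]$relation
    dtbl <- tables[[dyn_rel]]
    promoted_mask <- dtbl[[promos[[1]]$key_attr]] %in%
      vapply(promos, `[[`, "", "key")
  }
  rows_of <- function(rel) {
    tbl <- tables[[rel]]
    if (is.null(tbl)) return(0L)
    if (identical(rel, dyn_rel)) sum(!promoted_mask) else nrow(tbl)
  }
  prim <- vapply(pg$nodes, function(n) n$labels[1], character(1))
  checks <- list()
  add <- function(check, expected, actual) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, expected = expected, actual = actual,
      ok = isTRUE(all.equal(expected, actual)), stringsAsFactors = FALSE)
  }
  for (lab in names(model$entities)) {
    e <- model$entities[[lab]]
    exp_n <- 0L
    for (o in e$origins) {
      if (is.na(o$relation)) {
        vals <- unlist(lapply(promos, function(p) {
          if (p$mode != "entity" || !identical(p$entity, lab)) return(character(0))
          dtbl <- tables[[dyn_rel]]
          v <- dtbl[[p$value_attr]][dtbl[[p$key_attr]] == p$key]
          canonical_fusion(catalog, v[!is.na(v)])
        }))
        exp_n <- exp_n + length(unique(vals))
      } else {
        exp_n <- exp_n + rows_of(o$relation)
      }
    }
    add(sprintf("nodes(%s)", lab), exp_n, sum(prim == lab))
  }
  exp_edges <- stats::setNames(
    integer(length(model$relationships)),
    vapply(model$relationships, `[[`, "", "name"))
  for (r in model$relationships) {
    o <- r$origin
    n <- if (o$kind == "promoted") {
      p <- Filter(function(pp) pp$mode == "entity" && identical(pp$rel, r$name),
                  promos)
      link <- Filter(function(rr) identical(rr$origin$relation, dyn_rel) &&
                       rr$origin$kind == "fk", model$relationships)
      host_fk <- link[[1]]$origin$fk$columns
      pairs <- unique(do.call(rbind, lapply(p, function(pp) {
        dtbl <- tables[[dyn_rel]]
        sel <- dtbl[dtbl[[pp$key_attr]] == pp$key & !is.na(dtbl[[pp$value_attr]]), ,
                    drop = FALSE]
        if (!nrow(sel)) return(NULL)
        data.frame(h = key_string(sel, host_fk),
                   v = canonical_fusion(catalog, sel[[pp$value_attr]]),
                   stringsAsFactors = FALSE)
      })))
      if (is.null(pairs)) 0L else nrow(pairs)
    } else if (o$kind == "source") {
      rows_of(o$relation)
    } else {
      tbl <- tables[[o$relation]]
      if (is.null(tbl) || !nrow(tbl)) 0L else {
        if (identical(o$relation, dyn_rel)) tbl <- tbl[!promoted_mask, , drop = FALSE]
        sum(!Reduce(`|`, lapply(o$fk$columns, function(a) is.na(tbl[[a]]))))
      }
    }
    exp_edges[r$name] <- exp_edges[r$name] + n
  }
  for (nm in unique(names(exp_edges))) {
    add(sprintf("edges(%s)", nm), unname(exp_edges[nm]),
        sum(pg$edges$type == nm))
  }
  # associative reconstruction
  strip <- function(ids, label) sub(paste0("^", label, ":"), "", ids)
  for (r in model$relationships) {
    if (r$origin$kind != "source") next
    o <- r$origin
    tbl <- tables[[o$relation]]
    orig <- sort(paste(key_string(tbl, o$fk_a$columns),
                       key_string(tbl, o$fk_b$columns), sep = "\x1f"))
    sel <- pg$edges[pg$edges$type == r$name, , drop = FALSE]
    la <- entity_for_relation(model, o$fk_a$ref_table)$label
    lb <- entity_for_relation(model, o$fk_b$ref_table)$label
    got <- sort(paste(gsub("\\|", "\x1f", strip(sel$src, la)),
                      gsub("\\|", "\x1f", strip(sel$dst, lb)), sep = "\x1f"))
    add(sprintf("reconstruct(%s)", o$relation),
        length(orig), if (identical(orig, got)) length(got) else -1L)
  }
  out <- do.call(rbind, checks)
  rownames(out) <- NULL
  out
}

#' Duplicate-free path-pattern query
#'
#' Matches an alternating label/relationship-type path pattern (e.g.
#' `c("Patient", "HasOrder", "Order", "HasAnalysis", "Analysis")`) against the
#' graph, treating edges as undirected, and returns the union subgraph of all
#' full matches. Each node and edge appears exactly once regardless of how
#' many matching paths traverse it — the graph-side counterpart of a
#' relational join that would repeat a patient row once per combination.
#'
#' @param pg a `property_graph`.
#' @param pattern character vector of odd length alternating node labels and
#'   relationship types.
#' @return a `property_graph` restricted to the matched nodes and edges.
#' @export
dedup_query <- function(pg, pattern) {
  if (length(pattern) %% 2 != 1L) {
    stop2("pattern must alternate label, type, label, ... (odd length)")
  }
  labels <- pattern[seq(1, length(pattern), by = 2)]
  types <- if (length(pattern) > 1) pattern[seq(2, length(pattern), by = 2)] else character(0)
  known_labels <- c(names(pg$model$entities),
                    unlist(lapply(pg$nodes, function(n) n$labels)))
  known_types <- vapply(pg$model$relationships, `[[`, "", "name")
  known_types <- unique(c(known_types, pg$edges$type))
  for (l in labels) if (!l %in% known_labels) stop2("unknown label '%s'", l)
  for (t in types) if (!t %in% known_types) stop2("unknown relationship type '%s'", t)

  has_label <- function(ids, lab) {
    ids[vapply(pg$nodes[ids], function(n) lab %in% n$labels, logical(1))]
  }
  sets <- vector("list", length(labels))
  sets[[1]] <- has_label(names(pg$nodes), labels[1])
  step_edges <- vector("list", length(types))
  for (i in seq_along(types)) {
    e <- pg$edges[pg$edges$type == types[i], , drop = FALSE]
    fwd <- e[e$src %in% sets[[i]], , drop = FALSE]
    bwd <- e[e$dst %in% sets[[i]], , drop = FALSE]
    nxt <- unique(c(fwd$dst, bwd$src))
    sets[[i + 1]] <- has_label(nxt, labels[i + 1])
    keep <- (e$src %in% sets[[i]] & e$dst %in% sets[[i + 1]]) |
      (e$dst %in% sets[[i]] & e$src %in% sets[[i + 1]])
    step_edges[[i]] <- e[keep, , drop = FALSE]
  }
  # backward prune so only nodes/edges on full matches remain
  for (i in rev(seq_along(types))) {
    e <- step_edges[[i]]
    keep <- (e$src %in% sets[[i]] & e$dst %in% sets[[i + 1]]) |
      (e$dst %in% sets[[i]] & e$src %in% sets[[i + 1]])
    e <- e[keep, , drop = FALSE]
    prev <- unique(c(e$src[e$dst %in% sets[[i + 1]]],
                     e$dst[e$src %in% sets[[i + 1]]]))
    sets[[i]] <- intersect(sets[[i]], prev)
    step_edges[[i]] <- e
  }
  if (length(types)) {
    for (i in seq_along(types)) {
      e <- step_edges[[i]]
      keep <- (e$src %in% sets[[i]] & e$dst %in% sets[[i + 1]]) |
        (e$dst %in% sets[[i]] & e$src %in% sets[[i + 1]])
      step_edges[[i]] <- e[keep, , drop = FALSE]
    }
  }
  node_ids <- unique(unlist(sets))
  edges <- do.call(rbind, c(list(empty_edge_df_with_props()), step_edges))
  edges <- edges[!duplicated(paste(edges$type, edges$src, edges$dst,
                                   sep = "\x1f")), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = pg$nodes[lex_sort(node_ids)], edges = edges,
                 model = pg$model), class = "property_graph")
}

empty_edge_df_with_props <- function() {
  df <- empty_edge_df()
  df$props <- list()
  df
}
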