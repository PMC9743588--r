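# Export of a property graph to standard interchange formats: GraphML, an
# idempotent Cypher MERGE script, and bulk-import CSV (one node file per label
# set, one edge file per relationship type).

#' Export a property graph
#'
#' @param pg a `property_graph`.
#' @param format `"graphml"`, `"cypher_script"` or `"bulk_csv"`.
#' @param path output file (`graphml`, `cypher_script`) or directory
#'   (`bulk_csv`).
#' @return the written path(s), invisibly.
#' @export
export_graph <- function(pg, format = c("graphml", "cypher_script", "bulk_csv"),
                         path) {
  format <- match.arg(format)
  switch(format,
         graphml = write_graphml(pg, path),
         cypher_script = write_cypher(pg, path),
         bulk_csv = write_bulk_csv(pg, path))
}

check_encodable <- function(pg) {
  for (n in pg$nodes) {
    bad <- names(n$props)[!vapply(n$props, function(v) {
      is.atomic(v) && length(v) == 1L
    }, logical(1))]
    if (length(bad)) stop2("unencodable value type in node %s property %s",
                           n$id, bad[1])
  }
  invisible(TRUE)
}

#' Write a property graph as GraphML
#'
#' Standard GraphML: labels are stored in a `labels` node attribute
#' (semicolon-joined) and every property becomes a data key. Round-trips
#' through [read_graphml()].
#'
#' @param pg a `property_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(pg, path) {
  check_encodable(pg)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    x <- gsub("\"", "&quot;", x, fixed = TRUE)
    gsub("'", "&apos;", x, fixed = TRUE)
  }
  node_keys <- lex_sort(unique(unlist(lapply(pg$nodes, function(n) names(n$props)))))
  edge_keys <- lex_sort(unique(unlist(lapply(pg$edges$props, names))))
  key_line <- function(id, dom, name) sprintf(
    '  <key id="%s" for="%s" attr.name="%s" attr.type="string"/>',
    esc(id), dom, esc(name))
  data_line <- function(key, value) sprintf('    <data key="%s">%s</data>',
                                            esc(key), esc(value))
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
             key_line("labels", "node", "labels"),
             vapply(node_keys, function(k) key_line(paste0("n_", k), "node", k),
                    character(1)),
             key_line("reltype", "edge", "reltype"),
             vapply(edge_keys, function(k) key_line(paste0("e_", k), "edge", k),
                    character(1)),
             '  <graph id="G" edgedefault="directed">')
  node_chunks <- vapply(pg$nodes, function(n) {
    paste(c(sprintf('  <node id="%s">', esc(n$id)),
            data_line("labels", paste(n$labels, collapse = ";")),
            vapply(names(n$props), function(k)
              data_line(paste0("n_", k), format_value(n$props[[k]])),
              character(1)),
            "  </node>"), collapse = "\n")
  }, character(1))
  edge_chunks <- if (nrow(pg$edges)) vapply(seq_len(nrow(pg$edges)), function(i) {
    p <- pg$edges$props[[i]]
    paste(c(sprintf('  <edge source="%s" target="%s">',
                    esc(pg$edges$src[i]), esc(pg$edges$dst[i])),
            data_line("reltype", pg$edges$type[i]),
            vapply(names(p), function(k)
              data_line(paste0("e_", k), format_value(p[[k]])), character(1)),
            "  </edge>"), collapse = "\n")
  }, character(1)) else character(0)
  writeLines(c(lines, node_chunks, edge_chunks, "  </graph>", "</graphml>"),
             path, useBytes = FALSE)
  invisible(path)
}

#' Read a GraphML file written by [write_graphml()]
#'
#' Properties come back as character values; labels are restored from the
#' `labels` attribute.
#'
#' @param path GraphML file.
#' @return a `property_graph` (with a `NULL` model reference).
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  keymap <- list()
  for (k in xml2::xml_find_all(doc, ".//g:key", ns)) {
    keymap[[xml2::xml_attr(k, "id")]] <- xml2::xml_attr(k, "attr.name")
  }
  nodes <- list()
  for (nd in xml2::xml_find_all(doc, ".//g:graph/g:node", ns)) {
    id <- xml2::xml_attr(nd, "id")
    props <- list(); labels <- character(0)
    for (d in xml2::xml_find_all(nd, "./g:data", ns)) {
      key <- xml2::xml_attr(d, "key")
      val <- xml2::xml_text(d)
      if (identical(key, "labels")) labels <- strsplit(val, ";", fixed = TRUE)[[1]]
      else props[[keymap[[key]] %||% key]] <- val
    }
    nodes[[id]] <- list(id = id, labels = labels, props = props)
  }
  eds <- xml2::xml_find_all(doc, ".//g:graph/g:edge", ns)
  edges <- data.frame(type = character(length(eds)),
                      src = character(length(eds)),
                      dst = character(length(eds)), stringsAsFactors = FALSE)
  eprops <- vector("list", length(eds))
  for (i in seq_along(eds)) {
    edges$src[i] <- xml2::xml_attr(eds[[i]], "source")
    edges$dst[i] <- xml2::xml_attr(eds[[i]], "target")
    props <- list()
    for (d in xml2::xml_find_all(eds[[i]], "./g:data", ns)) {
      key <- xml2::xml_attr(d, "key")
      val <- xml2::xml_text(d)
      if (identical(key, "reltype")) edges$type[i] <- val
      else props[[keymap[[key]] %||% key]] <- val
    }
    eprops[[i]] <- props
  }
  edges$props <- eprops
  structure(list(nodes = nodes, edges = edges, model = NULL),
            class = "property_graph")
}

cypher_quote <- function(v) {
  paste0("'", gsub("'", "\\\\'", gsub("\\\\", "\\\\\\\\", format_value(v))), "'")
}

cypher_props <- function(p) {
  if (!length(p)) return("")
  paste(sprintf("n.`%s` = %s", names(p),
                vapply(p, cypher_quote, character(1))), collapse = ", ")
}

#' Write a property graph as an idempotent Cypher script
#'
#' Nodes are `MERGE`d on a synthetic `_key` identity property (the entity
#' label plus origin PK value), then labeled and populated with `SET`; edges
#' are `MERGE`d between `MATCH`ed endpoints. Replaying the script any number
#' of times yields the same node and edge counts.
#'
#' @param pg a `property_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cypher <- function(pg, path) {
  check_encodable(pg)
  lines <- character(0)
  for (n in pg$nodes) {
    l <- sprintf("MERGE (n:`%s` {`_key`: %s})",
                 paste(n$labels, collapse = "`:`"), cypher_quote(n$id))
    ps <- cypher_props(n$props)
    if (nzchar(ps)) l <- paste0(l, " SET ", ps)
    lines <- c(lines, paste0(l, ";"))
  }
  for (i in seq_len(nrow(pg$edges))) {
    p <- pg$edges$props[[i]]
    pstr <- if (length(p)) {
      sprintf(" {%s}", paste(sprintf("`%s`: %s", names(p),
                                     vapply(p, cypher_quote, character(1))),
                             collapse = ", "))
    } else ""
    lines <- c(lines, sprintf(
      "MATCH (a {`_key`: %s}), (b {`_key`: %s}) MERGE (a)-[:`%s`%s]->(b);",
      cypher_quote(pg$edges$src[i]), cypher_quote(pg$edges$dst[i]),
      pg$edges$type[i], pstr))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write bulk-import CSV files for a property graph
#'
#' One node file per label set with header `id:ID`, `:LABEL` and property
#' columns; one edge file per relationship type with `:START_ID`, `:END_ID`,
#' `:TYPE` and property columns.
#'
#' @param pg a `property_graph`.
#' @param dir output directory (created if needed).
#' @return character vector of written files, invisibly.
#' @export
write_bulk_csv <- function(pg, dir) {
  check_encodable(pg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  labsets <- vapply(pg$nodes, function(n) paste(n$labels, collapse = ":"),
                    character(1))
  for (ls in lex_sort(unique(labsets))) {
    sel <- pg$nodes[labsets == ls]
    keys <- lex_sort(unique(unlist(lapply(sel, function(n) names(n$props)))))
    df <- data.frame(`id:ID` = vapply(sel, `[[`, "", "id"),
                     `:LABEL` = ls, check.names = FALSE,
                     stringsAsFactors = FALSE)
    for (k in keys) {
      df[[k]] <- vapply(sel, function(n) {
        v <- n$props[[k]]
        if (is.null(v)) NA_character_ else format_value(v)
      }, character(1))
    }
    f <- file.path(dir, paste0("nodes_", gsub("[^A-Za-z0-9]", "_", ls), ".csv"))
    utils::write.csv(df, f, row.names = FALSE, na = "")
    written <- c(written, f)
  }
  for (tp in lex_sort(unique(pg$edges$type))) {
    sel <- pg$edges[pg$edges$type == tp, , drop = FALSE]
    keys <- lex_sort(unique(unlist(lapply(sel$props, names))))
    df <- data.frame(`:START_ID` = sel$src, `:END_ID` = sel$dst, `:TYPE` = tp,
                     check.names = FALSE, stringsAsFactors = FALSE)
    for (k in keys) {
      df[[k]] <- vapply(sel$props, function(p) {
        if (is.null(p[[k]])) NA_character_ else format_value(p[[k]])
      }, character(1))
    }
    f <- file.path(dir, paste0("edges_", gsub("[^A-Za-z0-9]", "_", tp), ".csv"))
    utils::write.csv(df, f, row.names = FALSE, na = "")
    written <- c(written, f)
  }
  invisible(written)
}

#' Replay a Cypher MERGE script against an in-memory store
#'
#' A minimal interpreter for the script dialect emitted by [write_cypher()],
#' used to demonstrate idempotence: nodes merge on `_key`, edges on
#' (type, endpoints, properties).
#'
#' @param lines character vector of script lines (or a file path).
#' @param store optional store from a previous replay.
#' @return list with `nodes` (named list) and `edges` (character keys).
#' @export
cypher_replay <- function(lines, store = NULL) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  store <- store %||% list(nodes = list(), edges = character(0))
  for (l in lines) {
    if (grepl("^MERGE \\(n:", l)) {
      key <- sub("^MERGE \\(n:.*\\{`_key`: '((?:[^'\\\\]|\\\\.)*)'\\}.*$", "\\1", l)
      store$nodes[[key]] <- TRUE
    } else if (grepl("^MATCH \\(a ", l)) {
      ek <- sub("^MATCH ", "", l)
      if (!ek %in% store$edges) store$edges <- c(store$edges, ek)
    }
  }
  store
}
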