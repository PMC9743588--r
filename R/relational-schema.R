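#' Construct a foreign-key constraint
#'
#' @param columns character vector of source attribute names (ordered).
#' @param ref_table name of the referenced relation.
#' @param ref_columns character vector of referenced attribute names; must be
#'   the primary key of `ref_table`.
#' @param optional logical; if `TRUE`, null source values are permitted and are
#'   not referential-integrity violations. Default mandatory.
#' @return an object of class `foreign_key`.
#' @export
foreign_key <- function(columns, ref_table, ref_columns, optional = FALSE) {
  columns <- as.character(columns)
  ref_columns <- as.character(ref_columns)
  if (length(columns) < 1L || length(columns) != length(ref_columns)) {
    stop2("foreign key must map >= 1 column onto the same number of referenced columns")
  }
  structure(
    list(columns = columns, ref_table = as.character(ref_table),
         ref_columns = ref_columns, optional = isTRUE(optional)),
    class = "foreign_key"
  )
}

#' Construct a relation schema
#'
#' @param name relation name (unique within a schema).
#' @param attributes named character vector mapping attribute name to declared
#'   type (`text`, `integer`, `date`, `boolean`); order is preserved.
#' @param pk character vector of primary-key attribute names.
#' @param fks list of [foreign_key()] constraints.
#' @return an object of class `relation`.
#' @export
relation <- function(name, attributes, pk, fks = list()) {
  if (is.null(names(attributes)) || any(names(attributes) == "")) {
    stop2("relation %s: attributes must be a named vector (name = type)", name)
  }
  attrs <- data.frame(name = names(attributes), type = unname(as.character(attributes)),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(attrs$name)) {
    stop2("relation %s: duplicate attribute name '%s'",
          name, attrs$name[duplicated(attrs$name)][1])
  }
  bad <- setdiff(attrs$type, REL2GRAPH_TYPES)
  if (length(bad)) stop2("relation %s: unknown declared type '%s'", name, bad[1])
  pk <- as.character(pk)
  if (length(pk) == 0L) stop2("relation %s: empty primary key", name)
  if (!all(pk %in% attrs$name)) {
    stop2("relation %s: PK attribute '%s' is not an attribute of the relation",
          name, setdiff(pk, attrs$name)[1])
  }
  fks <- lapply(fks, function(fk) {
    if (!inherits(fk, "foreign_key")) fk <- do.call(foreign_key, fk)
    if (!all(fk$columns %in% attrs$name)) {
      stop2("relation %s: FK source attribute '%s' does not exist",
            name, setdiff(fk$columns, attrs$name)[1])
    }
    fk
  })
  structure(list(name = as.character(name), attributes = attrs, pk = pk, fks = fks),
            class = "relation")
}

#' Construct and validate a relational schema
#'
#' Validates the foreign-key closure: every FK target relation must exist and
#' every FK must reference the full primary key of its target.
#'
#' @param relations list of [relation()] objects.
#' @return an object of class `relational_schema` (named list of relations).
#' @export
relational_schema <- function(relations = list()) {
  nms <- vapply(relations, function(r) r$name, character(1))
  if (anyDuplicated(nms)) {
    stop2("duplicate relation name '%s'", nms[duplicated(nms)][1])
  }
  names(relations) <- nms
  for (r in relations) {
    for (fk in r$fks) {
      if (!fk$ref_table %in% nms) {
        stop2("dangling FK target: %s(%s) references missing relation %s",
              r$name, paste(fk$columns, collapse = ","), fk$ref_table)
      }
      tpk <- relations[[fk$ref_table]]$pk
      if (!identical(sort(fk$ref_columns), sort(tpk))) {
        stop2("FK %s(%s) must reference the primary key of %s (%s)",
              r$name, paste(fk$columns, collapse = ","), fk$ref_table,
              paste(tpk, collapse = ","))
      }
    }
  }
  structure(relations, class = "relational_schema")
}

#' @export
print.relational_schema <- function(x, ...) {
  cat(sprintf("<relational_schema> %d relations\n", length(x)))
  for (nm in lex_sort(names(x))) {
    r <- x[[nm]]
    cat(sprintf("  %s(%s) PK{%s}%s\n", nm,
                paste(r$attributes$name, collapse = ", "),
                paste(r$pk, collapse = ","),
                if (length(r$fks)) sprintf(" [%d FK]", length(r$fks)) else ""))
  }
  invisible(x)
}

#' Read a relational schema from a YAML/JSON document
#'
#' The document has a top-level `relations:` mapping; each relation has
#' `attributes` (ordered name -> type mapping), `pk` (list of names) and
#' optionally `fks` (each with `columns`, `ref_table`, `ref_columns`,
#' `optional`).
#'
#' @param path path to the schema document.
#' @return a validated [relational_schema()].
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop2("schema file not found: %s", path)
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop2("parse failure in %s: %s", path,
                                            conditionMessage(e)))
  rels <- doc$relations %||% list()
  out <- lapply(names(rels), function(nm) {
    spec <- rels[[nm]]
    attrs <- unlist(spec$attributes)
    fks <- lapply(spec$fks %||% list(), function(fk) {
      foreign_key(unlist(fk$columns), fk$ref_table, unlist(fk$ref_columns),
                  isTRUE(fk$optional))
    })
    relation(nm, attrs, unlist(spec$pk), fks)
  })
  relational_schema(out)
}

#' Write a relational schema to a YAML document
#'
#' Inverse of [read_schema()].
#'
#' @param schema a [relational_schema()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  rels <- lapply(schema, function(r) {
    attrs <- as.list(stats::setNames(r$attributes$type, r$attributes$name))
    spec <- list(attributes = attrs, pk = as.list(r$pk))
    if (length(r$fks)) {
      spec$fks <- lapply(r$fks, function(fk) {
        list(columns = as.list(fk$columns), ref_table = fk$ref_table,
             ref_columns = as.list(fk$ref_columns), optional = fk$optional)
      })
    }
    spec
  })
  yaml::write_yaml(list(relations = rels), path)
  invisible(path)
}

empty_table <- function(rel) {
  cols <- lapply(seq_len(nrow(rel$attributes)), function(i) {
    switch(rel$attributes$type[i],
           integer = integer(0),
           date = as.Date(character(0)),
           boolean = logical(0),
           character(0))
  })
  names(cols) <- rel$attributes$name
  as.data.frame(cols, stringsAsFactors = FALSE)
}

validate_table <- function(df, rel) {
  unknown <- setdiff(names(df), rel$attributes$name)
  if (length(unknown)) {
    stop2("relation %s: unknown column '%s'", rel$name, unknown[1])
  }
  missing <- setdiff(rel$attributes$name, names(df))
  if (length(missing)) {
    stop2("relation %s: missing column '%s'", rel$name, missing[1])
  }
  df <- df[, rel$attributes$name, drop = FALSE]
  for (i in seq_len(nrow(rel$attributes))) {
    a <- rel$attributes$name[i]
    df[[a]] <- coerce_type(df[[a]], rel$attributes$type[i],
                           paste0(rel$name, ".", a))
  }
  keys <- key_string(df, rel$pk)
  if (any(!is.na(keys) & duplicated(keys))) {
    stop2("relation %s: duplicate primary key value (%s)",
          rel$name, keys[duplicated(keys)][1])
  }
  if (nrow(df)) {
    null_pk <- Reduce(`|`, lapply(rel$pk, function(a) is.na(df[[a]])))
    if (any(null_pk)) stop2("relation %s: null primary key in row %d",
                            rel$name, which(null_pk)[1])
  }
  rownames(df) <- NULL
  df
}

#' Construct a relational instance from data frames
#'
#' @param tables named list of data frames, one per relation (missing relations
#'   become empty tables). Character columns are coerced to declared types.
#' @param schema the governing [relational_schema()].
#' @return an object of class `relational_instance`.
#' @export
relational_instance <- function(tables, schema) {
  unknown <- setdiff(names(tables), names(schema))
  if (length(unknown)) stop2("instance table '%s' has no relation in the schema",
                             unknown[1])
  out <- lapply(names(schema), function(nm) {
    df <- tables[[nm]]
    if (is.null(df)) return(empty_table(schema[[nm]]))
    df[] <- lapply(df, function(col) {
      if (inherits(col, "Date")) format(col, "%Y-%m-%d") else as.character(col)
    })
    validate_table(df, schema[[nm]])
  })
  names(out) <- names(schema)
  structure(list(tables = out, schema = schema), class = "relational_instance")
}

#' @export
print.relational_instance <- function(x, ...) {
  n <- vapply(x$tables, nrow, integer(1))
  cat(sprintf("<relational_instance> %d relations, %d rows total\n",
              length(n), sum(n)))
  for (nm in lex_sort(names(n))) cat(sprintf("  %s: %d rows\n", nm, n[[nm]]))
  invisible(x)
}

#' Read relational instance data from a directory of CSV files
#'
#' Expects one `<RelationName>.csv` per relation (RFC 4180, header row,
#' UTF-8); a missing file yields an empty table. Empty cells are nulls; values
#' are coerced to the declared attribute types.
#'
#' @param dir directory containing the CSV files.
#' @param schema the governing [relational_schema()].
#' @return a `relational_instance`.
#' @export
read_instance <- function(dir, schema) {
  if (!dir.exists(dir)) stop2("instance directory not found: %s", dir)
  tables <- lapply(names(schema), function(nm) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f)) return(NULL)
    utils::read.csv(f, colClasses = "character", check.names = FALSE,
                    fileEncoding = "UTF-8")
  })
  names(tables) <- names(schema)
  relational_instance(Filter(Negate(is.null), tables), schema)
}

#' Write a relational instance as one CSV file per relation
#'
#' Nulls become empty cells; dates are ISO-8601. Round-trips through
#' [read_instance()].
#'
#' @param inst a `relational_instance`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_instance <- function(inst, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(inst$tables)) {
    utils::write.csv(inst$tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  }
  invisible(dir)
}

#' Check referential integrity of an instance
#'
#' Scans every foreign key of every relation and reports each row whose FK
#' value has no matching target row. Null FK values are violations unless the
#' FK is flagged `optional`. An empty report means integrity holds.
#'
#' @param inst a `relational_instance`.
#' @param schema the governing schema (defaults to the instance's own).
#' @return data frame with columns `relation`, `fk`, `row`, `value`, `reason`.
#' @export
check_referential_integrity <- function(inst, schema = inst$schema) {
  viol <- list()
  for (nm in names(schema)) {
    rel <- schema[[nm]]
    df <- inst$tables[[nm]]
    if (is.null(df) || !nrow(df)) next
    for (fk in rel$fks) {
      fid <- sprintf("%s(%s)->%s", nm, paste(fk$columns, collapse = ","), fk$ref_table)
      src <- key_string(df, fk$columns)
      has_null <- Reduce(`|`, lapply(fk$columns, function(a) is.na(df[[a]])))
      tgt <- inst$tables[[fk$ref_table]]
      tkeys <- if (is.null(tgt) || !nrow(tgt)) character(0) else {
        key_string(tgt, fk$ref_columns)
      }
      miss <- !has_null & !(src %in% tkeys)
      if (!fk$optional && any(has_null)) {
        viol[[length(viol) + 1L]] <- data.frame(
          relation = nm, fk = fid, row = which(has_null),
          value = NA_character_, reason = "null value in mandatory FK",
          stringsAsFactors = FALSE)
      }
      if (any(miss)) {
        viol[[length(viol) + 1L]] <- data.frame(
          relation = nm, fk = fid, row = which(miss),
          value = gsub("\x1f", ",", src[miss]), reason = "no matching target row",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(viol)) {
    return(data.frame(relation = character(0), fk = character(0),
                      row = integer(0), value = character(0),
                      reason = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, viol)
  rownames(out) <- NULL
  out
}

#' Path to the shipped ALL diagnostics fixture schema
#'
#' A schema with the shape of a pediatric-ALL diagnostics database: patients,
#' families, projects, orders, diagnoses (with optional additions), typed
#' analyses via a master table, key-value dynamic fields, a two-level material
#' hierarchy and aggregated results, plus the associative relations linking
#' them.
#'
#' @return file path of the YAML schema document.
#' @export
all_schema_path <- function() {
  system.file("extdata", "all_schema.yaml", package = "rel2graph", mustWork = TRUE)
}
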