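`%||%` <- function(x, y) if (is.null(x)) y else x

stop2 <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Declared attribute types accepted in schema documents.
REL2GRAPH_TYPES <- c("text", "integer", "date", "boolean")

#' Coerce a character column to its declared relational type
#'
#' Empty strings are treated as nulls (the CSV null convention); dates must be
#' ISO-8601. Used by [read_instance()] and the instance constructors.
#'
#' @param x character vector as read from CSV.
#' @param type one of `"text"`, `"integer"`, `"date"`, `"boolean"`.
#' @param context label used in error messages (relation.attribute).
#' @return vector of the target type with `NA` for nulls.
#' @keywords internal
coerce_type <- function(x, type, context = "value") {
  x <- as.character(x)
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  ok <- !is.na(x)
  out <- switch(type,
    text = x,
    integer = {
      v <- suppressWarnings(as.integer(x))
      if (any(ok & is.na(v))) {
        stop2("type coercion failure in %s: %s is not an integer",
              context, x[ok & is.na(v)][1])
      }
      v
    },
    date = {
      v <- as.Date(rep(NA_character_, length(x)))
      if (any(ok)) {
        parsed <- suppressWarnings(as.Date(x[ok], format = "%Y-%m-%d"))
        if (any(is.na(parsed))) {
          stop2("type coercion failure in %s: %s is not an ISO-8601 date",
                context, x[ok][is.na(parsed)][1])
        }
        v[ok] <- parsed
      }
      v
    },
    boolean = {
      lo <- tolower(x)
      bad <- ok & !lo %in% c("true", "false", "t", "f", "1", "0")
      if (any(bad)) {
        stop2("type coercion failure in %s: %s is not a boolean", context, x[bad][1])
      }
      v <- rep(NA, length(x))
      v[ok] <- lo[ok] %in% c("true", "t", "1")
      v
    },
    stop2("unknown declared type '%s' in %s", type, context)
  )
  out
}

# Collapse key values into a single identity string (used for PK checks,
# FK matching and property-graph node ids).  "\x1f" is the ASCII unit
# separator and cannot occur in sane data values.
key_string <- function(df, cols) {
  if (length(cols) == 1L) {
    as.character(df[[cols]])
  } else {
    do.call(paste, c(lapply(cols, function(cl) as.character(df[[cl]])), sep = "\x1f"))
  }
}

# Format an atomic value for display/serialization (dates as ISO-8601).
format_value <- function(v) {
  if (inherits(v, "Date")) format(v, "%Y-%m-%d") else as.character(v)
}

# A stable lexicographic sort independent of the session locale.
lex_sort <- function(x) {
  if (!length(x)) return(character(0))
  x[order(x, method = "radix")]
}
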