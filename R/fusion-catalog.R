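# Catalog of gene fusions (and aneuploidies treated as fusion-like features)
# with their alias spellings, backing alias resolution, shared-node identity
# and the generator's prevalence defaults.

#' Construct a fusion catalog
#'
#' @param entries named list: canonical name -> list with `aliases` (character
#'   vector) and optionally `prevalence` (cohort carrier probability used by
#'   the synthetic generator). Canonical names are their own alias; alias sets
#'   must be disjoint across canonical names.
#' @return an object of class `fusion_catalog` with fields `canonical`,
#'   `aliases` (canonical -> all spellings), `alias_to_canonical`,
#'   `prevalence`.
#' @export
fusion_catalog <- function(entries) {
  canonical <- names(entries)
  if (is.null(canonical) || anyDuplicated(toupper(canonical))) {
    stop2("catalog entries must be uniquely named by canonical fusion name")
  }
  aliases <- lapply(canonical, function(cn) {
    unique(c(cn, as.character(unlist(entries[[cn]]$aliases))))
  })
  names(aliases) <- canonical
  lookup <- list()
  for (cn in canonical) {
    for (a in toupper(trimws(aliases[[cn]]))) {
      if (!is.null(lookup[[a]]) && lookup[[a]] != cn) {
        stop2("ambiguous alias '%s' maps to both %s and %s", a, lookup[[a]], cn)
      }
      lookup[[a]] <- cn
    }
  }
  prevalence <- vapply(canonical, function(cn) {
    as.numeric(entries[[cn]]$prevalence %||% NA_real_)
  }, numeric(1))
  structure(list(canonical = canonical, aliases = aliases,
                 alias_to_canonical = lookup, prevalence = prevalence),
            class = "fusion_catalog")
}

#' Read a fusion catalog from YAML
#'
#' @param path YAML document with a top-level `fusions:` mapping; defaults to
#'   the shipped catalog.
#' @return a [fusion_catalog()].
#' @export
read_fusion_catalog <- function(path = fusion_catalog_path()) {
  fusion_catalog(yaml::read_yaml(path)$fusions)
}

#' Path to the shipped fusion/aneuploidy catalog
#' @return file path of the YAML catalog.
#' @export
fusion_catalog_path <- function() {
  system.file("extdata", "fusion_catalog.yaml", package = "rel2graph",
              mustWork = TRUE)
}

#' @export
print.fusion_catalog <- function(x, ...) {
  cat(sprintf("<fusion_catalog> %d canonical names, %d aliases\n",
              length(x$canonical), length(x$alias_to_canonical)))
  invisible(x)
}

#' Resolve a fusion name to its canonical form
#'
#' Case-insensitive, whitespace-trimmed lookup over the catalog's alias table.
#' Unknown names are returned canonicalized (uppercased, trimmed) with
#' attribute `matched = FALSE`.
#'
#' @param catalog a [fusion_catalog()].
#' @param name fusion or aneuploidy spelling.
#' @return canonical name (character scalar) with a logical `matched`
#'   attribute.
#' @export
resolve_fusion <- function(catalog, name) {
  key <- toupper(trimws(name))
  hit <- catalog$alias_to_canonical[[key]]
  if (is.null(hit)) structure(key, matched = FALSE)
  else structure(hit, matched = TRUE)
}
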