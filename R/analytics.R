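# Cohort analytics over the migrated property graph: grouped distributions,
# fusion-subgroup selection, per-patient feature sets, Jaccard similarity and
# neighborhood subgraphs. These reproduce the computational content of the
# dashboard views (the rendering itself is out of scope).

node_prop <- function(pg, ids, prop) {
  vapply(ids, function(i) {
    v <- pg$nodes[[i]]$props[[prop]]
    if (is.null(v)) NA_character_ else format_value(v)
  }, character(1), USE.NAMES = FALSE)
}

nodes_with_label <- function(pg, label) {
  names(pg$nodes)[vapply(pg$nodes, function(n) label %in% n$labels, logical(1))]
}

# Undirected one-step hop: map each id in `ids` to its neighbors over edges of
# `type`. Returns a data frame (from, to).
hop <- function(pg, ids, type) {
  e <- pg$edges[pg$edges$type == type, , drop = FALSE]
  out <- rbind(
    data.frame(from = e$src, to = e$dst, stringsAsFactors = FALSE),
    data.frame(from = e$dst, to = e$src, stringsAsFactors = FALSE))
  out[out$from %in% ids, , drop = FALSE]
}

# patient node id -> analysis node ids, via Patient-HasOrder-Order-HasAnalysis.
patient_analysis_map <- function(pg) {
  po <- hop(pg, nodes_with_label(pg, "Patient"), "HasOrder")
  if (!nrow(po)) return(data.frame(patient = character(0),
                                   analysis = character(0),
                                   stringsAsFactors = FALSE))
  oa <- hop(pg, unique(po$to), "HasAnalysis")
  m <- merge(po, oa, by.x = "to", by.y = "from")
  unique(data.frame(patient = m$from, analysis = m$to.y, stringsAsFactors = FALSE))
}

# Completed years between two dates (calendar age).
age_years <- function(dob, ref) {
  dob <- as.POSIXlt(dob); ref <- as.POSIXlt(ref)
  y <- ref$year - dob$year
  before <- ref$mon < dob$mon | (ref$mon == dob$mon & ref$mday < dob$mday)
  as.integer(y - before)
}

patient_id_of <- function(ids) sub("^Patient:", "", ids)

# Per-patient values for a distribution selector; returns a data frame
# (patient, value) with possibly several rows per patient and `numeric`
# attribute marking binnable axes.
resolve_selector <- function(pg, selector, reference_date = NULL) {
  patients <- nodes_with_label(pg, "Patient")
  out <- switch(selector,
    gender = data.frame(patient = patients,
                        value = node_prop(pg, patients, "gender"),
                        stringsAsFactors = FALSE),
    current_age = {
      if (is.null(reference_date)) stop2("selector current_age needs reference_date")
      dob <- node_prop(pg, patients, "dob")
      data.frame(patient = patients,
                 value = age_years(as.Date(dob), as.Date(reference_date)),
                 stringsAsFactors = FALSE)
    },
    age_at_diagnosis = {
      e <- pg$edges[pg$edges$type == "HasDiagnosis", , drop = FALSE]
      date <- vapply(e$props, function(p) {
        if (is.null(p$date)) NA_character_ else format_value(p$date)
      }, character(1))
      pat <- ifelse(e$src %in% patients, e$src, e$dst)
      dob <- node_prop(pg, pat, "dob")
      data.frame(patient = pat,
                 value = age_years(as.Date(dob), as.Date(date)),
                 stringsAsFactors = FALSE)
    },
    diagnosis = {
      e <- hop(pg, patients, "HasDiagnosis")
      data.frame(patient = e$from, value = node_prop(pg, e$to, "name"),
                 stringsAsFactors = FALSE)
    },
    material_type = {
      e <- hop(pg, patients, "HasMaterial")
      data.frame(patient = e$from, value = node_prop(pg, e$to, "type"),
                 stringsAsFactors = FALSE)
    },
    fusion = {
      pa <- patient_analysis_map(pg)
      af <- hop(pg, unique(pa$analysis), "HasFusion")
      m <- merge(pa, af, by.x = "analysis", by.y = "from")
      data.frame(patient = m$patient, value = node_prop(pg, m$to, "name"),
                 stringsAsFactors = FALSE)
    },
    mrd = {
      pa <- patient_analysis_map(pg)
      df <- hop(pg, unique(pa$analysis), "HasDynamicField")
      keep <- node_prop(pg, df$to, "name") == "mrd"
      m <- merge(pa, df[keep, , drop = FALSE], by.x = "analysis", by.y = "from")
      data.frame(patient = m$patient, value = node_prop(pg, m$to, "value"),
                 stringsAsFactors = FALSE)
    },
    stop2("unknown selector '%s'", selector)
  )
  out <- unique(out[!is.na(out$value), , drop = FALSE])
  attr(out, "numeric") <- selector %in% c("current_age", "age_at_diagnosis")
  out
}

#' Grouped distribution over the cohort
#'
#' The computational core of the cohort-view bar plots: a complete cross-tab
#' of an x-axis selector (e.g. `current_age`, `age_at_diagnosis`, `diagnosis`)
#' by an optional grouping selector (e.g. `gender`, `mrd`, `material_type`),
#' with zero cells included. Age axes are binned in whole years of width
#' `bin_width` (bin label = lower bound). `measure = "frequency"` normalizes
#' the counts to sum 1 over the table.
#'
#' @param pg a `property_graph`.
#' @param x x-axis selector name.
#' @param group optional grouping selector name.
#' @param measure `"count"` or `"frequency"`.
#' @param bin_width positive integer bin width in years for age axes.
#' @param reference_date date against which current age is computed.
#' @return data frame with columns `x_bin`, `group`, `value`.
#' @export
distribution <- function(pg, x, group = NULL, measure = c("count", "frequency"),
                         bin_width = 1, reference_date = NULL) {
  measure <- match.arg(measure)
  if (bin_width < 1) stop2("bin_width must be >= 1")
  xv <- resolve_selector(pg, x, reference_date)
  if (isTRUE(attr(xv, "numeric"))) {
    v <- as.integer(xv$value)
    xv$value <- as.character(floor(v / bin_width) * bin_width)
    xlev <- as.character(sort(unique(floor(v / bin_width) * bin_width)))
  } else {
    xlev <- lex_sort(unique(xv$value))
  }
  if (!nrow(xv)) {
    return(data.frame(x_bin = character(0), group = character(0),
                      value = numeric(0), stringsAsFactors = FALSE))
  }
  if (is.null(group)) {
    gv <- data.frame(patient = unique(xv$patient), value = "all",
                     stringsAsFactors = FALSE)
  } else {
    gv <- resolve_selector(pg, group, reference_date)
  }
  glev <- lex_sort(unique(gv$value))
  m <- merge(xv, gv, by = "patient")
  m <- unique(m[, c("patient", "value.x", "value.y")])
  tab <- table(factor(m$value.x, levels = xlev),
               factor(m$value.y, levels = glev))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("x_bin", "group", "value")
  if (measure == "frequency") {
    tot <- sum(out$value)
    out$value <- if (tot > 0) out$value / tot else out$value
  }
  out
}

#' Per-patient feature set for similarity search
#'
#' The union of canonical fusion names detected by any of the patient's
#' analyses (aneuploidy markers are encoded in the same namespace as
#' `ANEUPLOIDY:<TYPE>` tokens) and the patient's diagnosis ICD codes.
#' Duplicate detections collapse (set semantics).
#'
#' @param pg a `property_graph`.
#' @param patient_id patient identifier (the PK value, not the node id).
#' @return an object of class `feature_set` (fields `patient_id`, `features`).
#' @export
feature_set <- function(pg, patient_id) {
  nid <- paste0("Patient:", patient_id)
  if (is.null(pg$nodes[[nid]])) stop2("unknown patient '%s'", patient_id)
  all_fs <- feature_sets(pg)
  all_fs[[as.character(patient_id)]] %||%
    structure(list(patient_id = as.character(patient_id), features = character(0)),
              class = "feature_set")
}

#' Feature sets of every patient in the graph
#'
#' @param pg a `property_graph`.
#' @return named list of `feature_set` objects keyed by patient id.
#' @export
feature_sets <- function(pg) {
  patients <- nodes_with_label(pg, "Patient")
  pa <- patient_analysis_map(pg)
  fus <- if (nrow(pa)) {
    af <- hop(pg, unique(pa$analysis), "HasFusion")
    m <- merge(pa, af, by.x = "analysis", by.y = "from")
    data.frame(patient = m$patient, feature = node_prop(pg, m$to, "name"),
               stringsAsFactors = FALSE)
  } else data.frame(patient = character(0), feature = character(0))
  dg <- hop(pg, patients, "HasDiagnosis")
  icd <- data.frame(patient = dg$from, feature = node_prop(pg, dg$to, "icd"),
                    stringsAsFactors = FALSE)
  feats <- rbind(fus, icd)
  feats <- feats[!is.na(feats$feature), , drop = FALSE]
  out <- lapply(patients, function(p) {
    structure(list(patient_id = patient_id_of(p),
                   features = lex_sort(unique(feats$feature[feats$patient == p]))),
              class = "feature_set")
  })
  names(out) <- patient_id_of(patients)
  out
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> patient %s: {%s}\n", x$patient_id,
              paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Jaccard similarity between two feature sets
#'
#' `|A intersect B| / |A union B|`: 1 for identical non-empty sets, 0 for
#' disjoint sets. Two empty sets score 0 by convention (absence of features is
#' not evidence of similarity).
#'
#' @param a,b `feature_set` objects or character vectors of features.
#' @return similarity score in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  fa <- if (inherits(a, "feature_set")) a$features else unique(as.character(a))
  fb <- if (inherits(b, "feature_set")) b$features else unique(as.character(b))
  u <- length(union(fa, fb))
  if (u == 0) return(0)
  length(intersect(fa, fb)) / u
}

#' Thresholded patient-similarity star graph
#'
#' Scores every other patient against the target by Jaccard similarity of the
#' feature sets and keeps candidates whose score strictly exceeds the
#' threshold ("exceeding"), so renderers can scale edge width/color by score.
#'
#' @param pg a `property_graph`.
#' @param target_patient patient identifier of the target.
#' @param threshold similarity threshold in `[0, 1]`; strict comparison.
#' @param features optional precomputed [feature_sets()] result (avoids
#'   recomputation when scoring many targets).
#' @return data frame of class `similarity_graph` with columns `patient_a`
#'   (target), `patient_b`, `score`, sorted by decreasing score.
#' @export
similarity_graph <- function(pg, target_patient, threshold = 0.2,
                             features = NULL) {
  if (threshold < 0 || threshold > 1) stop2("threshold must be in [0, 1]")
  fs <- features %||% feature_sets(pg)
  target_patient <- as.character(target_patient)
  if (is.null(fs[[target_patient]])) stop2("unknown target patient '%s'", target_patient)
  tf <- fs[[target_patient]]$features
  others <- setdiff(names(fs), target_patient)
  score <- vapply(others, function(p) jaccard(tf, fs[[p]]$features), numeric(1))
  keep <- score > threshold
  out <- data.frame(patient_a = rep(target_patient, sum(keep)),
                    patient_b = others[keep],
                    score = unname(score[keep]), stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$patient_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("similarity_graph", "data.frame")
  out
}

#' Fusion/aneuploidy subgroup view
#'
#' Selects the patients connected to a fusion node (alias spellings are
#' resolved through the catalog first) and returns a per-patient table (id,
#' gender, age, karyotype-related values where measured) plus a relationship
#' subgraph connecting the patients to the subgroup node, optionally expanded
#' by additional node types (e.g. `Material`).
#'
#' @param pg a `property_graph`.
#' @param name fusion or aneuploidy name (canonical or alias).
#' @param catalog a [fusion_catalog()] for alias resolution.
#' @param expand character vector of extra node labels to pull into the
#'   subgraph.
#' @param reference_date date for the age column.
#' @return list of class `subgroup_view` with `canonical`, `table`, `subgraph`.
#' @export
subgroup <- function(pg, name, catalog = NULL, expand = character(0),
                     reference_date = NULL) {
  matched <- FALSE
  canonical <- if (is.null(catalog)) toupper(trimws(name)) else {
    res <- resolve_fusion(catalog, name)
    matched <- attr(res, "matched")
    as.character(res)
  }
  fid <- paste0("Fusion:", canonical)
  if (is.null(pg$nodes[[fid]])) {
    if (!matched) stop2("unknown subgroup '%s'", canonical)
    # catalog-known subgroup with no detections: empty table, one-node subgraph
    edges <- empty_edge_df_with_props()
    sg <- structure(list(
      nodes = stats::setNames(list(list(id = fid, labels = "Fusion",
                                        props = list(name = canonical))), fid),
      edges = edges, model = pg$model), class = "property_graph")
    return(structure(list(
      canonical = canonical,
      table = data.frame(patient_id = character(0), name = character(0),
                         gender = character(0), stringsAsFactors = FALSE),
      subgraph = sg), class = "subgroup_view"))
  }
  pa <- patient_analysis_map(pg)
  af <- hop(pg, unique(pa$analysis), "HasFusion")
  af <- af[af$to == fid, , drop = FALSE]
  m <- merge(pa, af, by.x = "analysis", by.y = "from")
  patients <- lex_sort(unique(m$patient))
  dyn <- function(key) {
    d <- hop(pg, unique(pa$analysis[pa$patient %in% patients]), "HasDynamicField")
    keep <- node_prop(pg, d$to, "name") == key
    dd <- merge(pa, d[keep, , drop = FALSE], by.x = "analysis", by.y = "from")
    vals <- node_prop(pg, dd$to, "value")
    stats::setNames(vals, dd$patient)[patients]
  }
  tab <- data.frame(
    patient_id = patient_id_of(patients),
    name = node_prop(pg, patients, "name"),
    gender = node_prop(pg, patients, "gender"),
    stringsAsFactors = FALSE)
  if (!is.null(reference_date)) {
    tab$age <- age_years(as.Date(node_prop(pg, patients, "dob")),
                         as.Date(reference_date))
  }
  tab$karyotype <- unname(dyn("karyotype"))
  tab$chromosomes <- unname(dyn("chromosomes"))
  edges <- data.frame(type = "HasFusion", src = patients, dst = fid,
                      stringsAsFactors = FALSE)
  edges$props <- rep(list(list()), nrow(edges))
  node_ids <- c(patients, fid)
  for (lab in expand) {
    ex <- hop(pg, patients, paste0("Has", lab))
    keep <- vapply(ex$to, function(i) lab %in% pg$nodes[[i]]$labels, logical(1))
    ex <- ex[keep, , drop = FALSE]
    if (nrow(ex)) {
      more <- data.frame(type = paste0("Has", lab), src = ex$from, dst = ex$to,
                         stringsAsFactors = FALSE)
      more$props <- rep(list(list()), nrow(more))
      edges <- rbind(edges, more)
      node_ids <- c(node_ids, ex$to)
    }
  }
  sg <- structure(list(nodes = pg$nodes[lex_sort(unique(node_ids))],
                       edges = edges, model = pg$model),
                  class = "property_graph")
  structure(list(canonical = canonical, table = tab, subgraph = sg),
            class = "subgroup_view")
}

#' @export
print.subgroup_view <- function(x, ...) {
  cat(sprintf("<subgroup_view> %s: %d patients\n", x$canonical, nrow(x$table)))
  print(utils::head(x$table, 10))
  invisible(x)
}

# Which attribute may be displayed on nodes of each label (the dashboard's
# per-label display alternatives).
DISPLAY_ATTRS <- list(
  Patient = c("id", "name", "gender", "dob"),
  Diagnosis = c("name", "icd"),
  Material = c("id", "type", "sub_type", "sub_number"),
  Order = c("id", "type"),
  Analysis = c("id", "result"),
  Fusion = c("name", "other_names"),
  DynamicField = c("field", "name", "value"),
  Project = c("id", "name"),
  Family = c("id", "name"),
  Result = c("id", "description", "value")
)

#' Neighborhood subgraph of an individual patient
#'
#' Breadth-first expansion from the patient through nodes whose labels are in
#' `node_types` (edges are treated as undirected), annotating every node with
#' a chosen display attribute. `node_types = character(0)` yields the single
#' patient node. Nodes shared across the cohort (fusions, diagnoses, projects,
#' families) are included but never expanded through, so the view stays
#' restricted to the individual's own records.
#'
#' @param pg a `property_graph`.
#' @param patient_id patient identifier.
#' @param node_types labels the neighborhood may expand to.
#' @param display named list label -> attribute to display; validated against
#'   the per-label alternatives.
#' @param leaf_types labels treated as expansion leaves (defaults to the
#'   cohort-shared entity types).
#' @return list of class `patient_view` with `nodes` (data frame `id`,
#'   `labels`, `display`) and `edges`.
#' @export
patient_subgraph <- function(pg, patient_id, node_types = character(0),
                             display = list(),
                             leaf_types = c("Fusion", "Diagnosis", "Project",
                                            "Family")) {
  nid <- paste0("Patient:", patient_id)
  if (is.null(pg$nodes[[nid]])) stop2("unknown patient '%s'", patient_id)
  for (lab in names(display)) {
    allowed <- DISPLAY_ATTRS[[lab]]
    if (!is.null(allowed) && !display[[lab]] %in% allowed) {
      stop2("display attribute '%s' not allowed for label %s (one of: %s)",
            display[[lab]], lab, paste(allowed, collapse = ", "))
    }
  }
  allow <- function(ids) {
    ids[vapply(ids, function(i) {
      any(pg$nodes[[i]]$labels %in% node_types)
    }, logical(1))]
  }
  visited <- nid
  frontier <- nid
  adj <- rbind(
    data.frame(from = pg$edges$src, to = pg$edges$dst, stringsAsFactors = FALSE),
    data.frame(from = pg$edges$dst, to = pg$edges$src, stringsAsFactors = FALSE))
  while (length(frontier)) {
    step <- adj[adj$from %in% frontier, , drop = FALSE]
    nxt <- allow(setdiff(unique(step$to), visited))
    visited <- c(visited, nxt)
    frontier <- nxt[!vapply(nxt, function(i) {
      any(pg$nodes[[i]]$labels %in% leaf_types)
    }, logical(1))]
  }
  # induced subgraph on the visited neighborhood
  keep_edges <- pg$edges[pg$edges$src %in% visited &
                           pg$edges$dst %in% visited, , drop = FALSE]
  rownames(keep_edges) <- NULL
  disp <- vapply(visited, function(i) {
    n <- pg$nodes[[i]]
    lab <- intersect(names(display), n$labels)
    if (length(lab)) {
      v <- n$props[[display[[lab[1]]]]]
      if (is.null(v)) n$labels[1] else format_value(v)
    } else n$labels[1]
  }, character(1))
  nodes <- data.frame(
    id = visited,
    labels = vapply(pg$nodes[visited], function(n) paste(n$labels, collapse = ";"),
                    character(1)),
    display = unname(disp), stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = keep_edges), class = "patient_view")
}

#' @export
print.patient_view <- function(x, ...) {
  cat(sprintf("<patient_view> %d nodes, %d edges\n", nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}
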