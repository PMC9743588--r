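# Shared fixtures, memoized so expensive objects are built once per test run.

.fx <- new.env(parent = emptyenv())

fx_schema <- function() {
  if (is.null(.fx$schema)) .fx$schema <- read_schema(all_schema_path())
  .fx$schema
}

fx_config <- function() {
  if (is.null(.fx$config)) .fx$config <- read_config()
  .fx$config
}

fx_catalog <- function() {
  if (is.null(.fx$catalog)) .fx$catalog <- read_fusion_catalog()
  .fx$catalog
}

# model before use-case refinements (Figs 3-5 stage)
fx_model_raw <- function() {
  if (is.null(.fx$model_raw)) {
    .fx$model_raw <- derive_graph_model(fx_schema(), fx_config()$name_map)
  }
  .fx$model_raw
}

# refined model (final dashboard model)
fx_model <- function() {
  if (is.null(.fx$model)) .fx$model <- build_model(fx_schema(), fx_config())
  .fx$model
}

fx_cohort <- function(n = 100, seed = 42) {
  key <- paste0("cohort_", n, "_", seed)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- generate_cohort(cohort_params(n_patients = n, seed = seed))
  }
  .fx[[key]]
}

fx_graph <- function(n = 100, seed = 42) {
  key <- paste0("graph_", n, "_", seed)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- migrate(fx_cohort(n, seed)$instance, fx_model(),
                          catalog = fx_catalog())$graph
  }
  .fx[[key]]
}

# A hand-built toy instance: 3 patients; patient 1 has two RNA-seq analyses
# both detecting CRLF2-P2RY8 (one via alias) plus PAX5; patient 2 shares
# CRLF2-P2RY8; patient 3 has no orders and no diagnosis. Patient 1's single
# analysis chain fans out into 3 analyses with 2 results each for the
# duplicate-elimination oracle.
toy_instance <- function() {
  if (!is.null(.fx$toy)) return(.fx$toy)
  schema <- fx_schema()
  tables <- list(
    Patient = data.frame(id = 1:3, name = c("Ada Abel", "Bo Bauer", "Cy Conrad"),
                         gender = c("F", "M", "F"),
                         dob = as.Date(c("2010-04-02", "2012-11-20", "2015-06-30"))),
    Project = data.frame(id = 12345L, name = "Leukemia Research"),
    Family = data.frame(id = 1L, name = "Family 1"),
    Order = data.frame(id = 1:2, type = c("diagnostic", "diagnostic")),
    Diagnosis = data.frame(id = 1L, name = "Acute lymphoblastic leukemia",
                           icd = "C91.0"),
    DiagnosisAddition = data.frame(id = 1L, description = "first relapse"),
    AnalysisMaster = data.frame(id = 1:3, type = c("RNASeq", "Panel", "ArrayCGH")),
    Material = data.frame(id = 1:2, type = c("Blood", "DNA")),
    MaterialNumber = data.frame(id = 501:502, master_id = c(1L, 2L),
                                sub_type = c("Preparation", "Extraction"),
                                sub_number = c(1L, 1L)),
    Analysis = data.frame(id = 1:3, order_id = c(1L, 1L, 2L),
                          master_id = c(1L, 1L, 1L),
                          material_id = c(501L, 501L, 502L),
                          result = c("completed", NA, "completed")),
    DynamicField = data.frame(
      analysis_id = c(1L, 1L, 2L, 3L),
      field = c("f1", "f2", "f1", "f1"),
      name = c("fusion", "fusion", "fusion", "fusion"),
      value = c("CRLF2-P2RY8", "PAX5", "p2ry8-crlf2", "CRLF2-P2RY8")),
    Result = data.frame(id = 1:6,
                        description = rep("Aggregated result", 6),
                        value = rep(c("normal", "abnormal"), 3)),
    ProjectPatient = data.frame(patient_id = 1:2, project_id = 12345L),
    FamilyPatient = data.frame(patient_id = 1:3, family_id = 1L),
    DiagnosisPatient = data.frame(patient_id = 1:2, diagnosis_id = 1L,
                                  date = as.Date(c("2019-05-10", "2020-01-15")),
                                  addition = c(1L, NA)),
    OrderPatient = data.frame(patient_id = 1:2, order_id = 1:2,
                              order_date = as.Date(c("2019-05-12", "2020-01-20"))),
    MaterialPatient = data.frame(patient_id = 1:2, material_id = 1:2),
    ResultAnalysis = data.frame(analysis_id = rep(1:3, each = 2), result_id = 1:6))
  .fx$toy <- relational_instance(tables, schema)
  .fx$toy
}

toy_graph <- function() {
  if (is.null(.fx$toy_graph)) {
    .fx$toy_graph <- migrate(toy_instance(), fx_model(),
                             catalog = fx_catalog())$graph
  }
  .fx$toy_graph
}

# Independent nested-loop referential-integrity oracle.
oracle_integrity_ok <- function(inst, schema) {
  for (nm in names(schema)) {
    rel <- schema[[nm]]
    df <- inst$tables[[nm]]
    if (!nrow(df)) next
    for (fk in rel$fks) {
      tgt <- inst$tables[[fk$ref_table]]
      for (i in seq_len(nrow(df))) {
        vals <- unlist(lapply(fk$columns, function(a) df[[a]][i]))
        if (any(is.na(vals))) {
          if (!fk$optional) return(FALSE)
          next
        }
        hit <- FALSE
        for (j in seq_len(nrow(tgt))) {
          tv <- unlist(lapply(fk$ref_columns, function(a) tgt[[a]][j]))
          if (all(as.character(tv) == as.character(vals))) { hit <- TRUE; break }
        }
        if (!hit) return(FALSE)
      }
    }
  }
  TRUE
}

# Random small schema in the shapes the transformation supports: entity
# relations (id + 1..3 plain attributes), plain FK attributes between
# entities, and binary associative relations.
random_schema <- function(seed) {
  set.seed(seed)
  n_ent <- sample(2:5, 1)
  rels <- list()
  ent_names <- paste0("E", seq_len(n_ent))
  for (i in seq_len(n_ent)) {
    attrs <- c(id = "integer")
    for (k in seq_len(sample(1:3, 1))) {
      attrs[paste0("a", k)] <- sample(c("text", "integer", "date"), 1)
    }
    fks <- list()
    if (i > 1 && stats::runif(1) < 0.5) {
      tgt <- ent_names[sample(i - 1, 1)]
      attrs[paste0(tolower(tgt), "_id")] <- "integer"
      fks <- list(foreign_key(paste0(tolower(tgt), "_id"), tgt, "id"))
    }
    rels[[i]] <- relation(ent_names[i], attrs, "id", fks)
  }
  n_assoc <- sample(0:3, 1)
  for (k in seq_len(n_assoc)) {
    pair <- sample(ent_names, 2)
    nm <- paste0("A", k, pair[1], pair[2])
    attrs <- c(x_id = "integer", y_id = "integer")
    if (stats::runif(1) < 0.5) attrs["w"] <- "text"
    rels[[length(rels) + 1L]] <- relation(
      nm, attrs, c("x_id", "y_id"),
      list(foreign_key("x_id", pair[1], "id"),
           foreign_key("y_id", pair[2], "id")))
  }
  relational_schema(rels)
}

# Compact signature of a schema graph for idempotence comparisons.
sg_signature <- function(g) {
  list(nodes = lex_sort(names(g$nodes)),
       edges = g$edges[order(g$edges$from, g$edges$to, g$edges$kind), 1:3],
       nrel = length(g$relationships))
}
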