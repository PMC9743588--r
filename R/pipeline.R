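#' Derive and refine the graph model in one step
#'
#' Convenience wrapper: [derive_graph_model()] with the configuration's name
#' map followed by [apply_refinements()] with its refinement rules. With the
#' shipped default configuration and fixture schema this produces the final
#' dashboard model (analysis subtype labels, merged material hierarchy,
#' shared fusion nodes).
#'
#' @param schema a [relational_schema()].
#' @param config a configuration list from [read_config()].
#' @return a refined `graph_model`.
#' @export
build_model <- function(schema, config = read_config()) {
  m <- derive_graph_model(schema, config$name_map)
  apply_refinements(m, config$refinements)
}

#' Run the full migration pipeline on a directory of instance CSVs
#'
#' Reads schema and instance, derives and refines the model, migrates, and
#' returns graph plus report.
#'
#' @param schema_path schema YAML document.
#' @param instance_dir directory of per-relation CSV files.
#' @param config configuration list from [read_config()].
#' @param catalog a [fusion_catalog()] for value canonicalization.
#' @param skip_violations drop referentially broken rows instead of failing.
#' @return list with `schema`, `model`, `instance`, `graph`, `report`.
#' @export
run_pipeline <- function(schema_path = all_schema_path(), instance_dir,
                         config = read_config(),
                         catalog = read_fusion_catalog(),
                         skip_violations = FALSE) {
  schema <- read_schema(schema_path)
  inst <- read_instance(instance_dir, schema)
  model <- build_model(schema, config)
  mg <- migrate(inst, model, catalog = catalog,
                skip_violations = skip_violations)
  list(schema = schema, model = model, instance = inst,
       graph = mg$graph, report = mg$report)
}
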