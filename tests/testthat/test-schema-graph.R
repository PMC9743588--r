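test_that("schema graph construction creates attribute nodes and PK/FK edges", {
  g <- build_schema_graph(fx_schema())
  # single-attribute PK relation: one node per attribute
  expect_true(all(c("Patient.id", "Patient.name", "Patient.gender",
                    "Patient.dob") %in% names(g$nodes)))
  pe <- g$edges[g$edges$from == "Patient.id", ]
  expect_setequal(pe$to, c("Patient.name", "Patient.gender", "Patient.dob"))
  # composite PK merged into one node, FK edges from the PK node
  expect_true("OrderPatient.PK" %in% names(g$nodes))
  expect_false("OrderPatient.patient_id" %in% names(g$nodes))
  oe <- g$edges[g$edges$from == "OrderPatient.PK", ]
  expect_setequal(oe$to, c("Patient.id", "Order.id", "OrderPatient.order_date"))
  # non-key FK attribute gets its own node with an FK edge
  ae <- g$edges[g$edges$from == "Analysis.order_id", ]
  expect_identical(ae$to, "Order.id")
  expect_identical(ae$kind, "fk")
})

test_that("an empty schema yields an empty graph", {
  g <- build_schema_graph(relational_schema(list()))
  expect_length(g$nodes, 0)
  expect_identical(nrow(g$edges), 0L)
})

test_that("node classification follows in/out degree", {
  g <- build_schema_graph(fx_schema())
  expect_identical(classify(g, "Patient.name"), "sink")
  expect_identical(classify(g, "ProjectPatient.PK"), "source")
  expect_identical(classify(g, "Patient.id"), "hub")
  expect_error(classify(g, "Nope.x"), "unknown node")
  lone <- build_schema_graph(relational_schema(list(
    relation("K", c(id = "integer"), "id"))))
  expect_identical(classify(lone, "K.id"), "isolated")
})

test_that("sink merging unions single-parent sinks and leaves shared PK sinks alone", {
  g <- merge_sinks(build_schema_graph(fx_schema()))
  expect_true("Patient.attributes" %in% names(g$nodes))
  expect_false("Patient.name" %in% names(g$nodes))
  carried <- g$nodes[["Patient.attributes"]]$carried
  expect_setequal(carried$attribute, c("name", "gender", "dob"))
  # merge of one: the lone non-key attribute is relabeled
  expect_true("Project.attributes" %in% names(g$nodes))
  # PK nodes that are sinks in the degree sense (referenced, no non-key
  # attributes) must not be folded into anything
  s2 <- relational_schema(list(
    relation("A", c(id = "integer"), "id"),
    relation("B", c(id = "integer", a_id = "integer"), "id",
             list(foreign_key("a_id", "A", "id")))))
  g2 <- merge_sinks(build_schema_graph(s2))
  expect_true("A.id" %in% names(g2$nodes))
})

test_that("entity fusion requires a PK hub with exactly one merged sink", {
  g <- merge_entities(merge_sinks(build_schema_graph(fx_schema())))
  for (ent in c("Patient", "Project", "Family", "Order", "Diagnosis",
                "DiagnosisAddition", "AnalysisMaster", "Analysis",
                "Material", "MaterialNumber", "Result")) {
    expect_true(ent %in% names(g$nodes), info = ent)
    expect_true(g$nodes[[ent]]$kind == "entity", info = ent)
  }
  expect_setequal(g$nodes$Analysis$carried$attribute, c("id", "result"))
  # the associative PK source is not an entity yet
  expect_identical(g$nodes[["DynamicField.PK"]]$kind, "pk")
  # without prior sink merging there is nothing to fuse
  g0 <- build_schema_graph(fx_schema())
  expect_identical(sg_signature(merge_entities(g0)), sg_signature(g0))
})

test_that("a PK hub whose merged sink has other incoming edges is reported, not merged", {
  g <- merge_sinks(build_schema_graph(fx_schema()))
  g$edges <- rbind(g$edges, data.frame(from = "Order.id", to = "Patient.attributes",
                                       kind = "attr", rel = "Order",
                                       fk_id = NA_integer_))
  g2 <- merge_entities(g)
  expect_false("Patient" %in% names(g2$nodes))
  expect_match(paste(g2$notes, collapse = " "), "other incoming")
})

test_that("source resolution covers plain, attributed and lookup-attributed associations", {
  g <- resolve_sources(merge_entities(merge_sinks(build_schema_graph(fx_schema()))))
  rels <- g$relationships
  origin <- vapply(rels, function(r) r$origin$relation, character(1))
  # plain association
  ip <- rels[[which(origin == "ProjectPatient")]]
  expect_identical(c(ip$a, ip$b), c("Patient", "Project"))
  expect_identical(nrow(ip$props), 0L)
  # association with its own attribute as edge property
  ho <- rels[[which(origin == "OrderPatient")]]
  expect_identical(ho$props$name, "order_date")
  # association pulling a one-attribute entity in through an FK lookup
  hd <- rels[[which(origin == "DiagnosisPatient")]]
  expect_setequal(hd$props$name, c("date", "description"))
  expect_identical(hd$props$lookup_relation[hd$props$name == "description"],
                   "DiagnosisAddition")
  expect_false("DiagnosisAddition" %in% names(g$nodes))
  # a source touching only one entity is untouched
  expect_true("DynamicField.PK" %in% names(g$nodes))
})

test_that("FK hub resolution replaces hubs by edges and builds new entities", {
  g <- resolve_sources(merge_entities(merge_sinks(build_schema_graph(fx_schema()))))
  g <- resolve_fk_hubs(g)
  expect_false("Analysis.order_id" %in% names(g$nodes))
  keys <- vapply(g$relationships, rel_name_key, character(1))
  expect_true("Analysis.order_id" %in% keys)
  expect_true("MaterialNumber.master_id" %in% keys)
  # 8.2: placeholder PK source fuses with its sink into a new entity
  expect_true("DynamicField" %in% names(g$nodes))
  expect_identical(g$nodes$DynamicField$kind, "entity")
  expect_setequal(g$nodes$DynamicField$consumed_fk, "analysis_id")
  dfr <- g$relationships[[which(keys == "DynamicField.analysis_id")]]
  expect_identical(c(dfr$a, dfr$b), c("DynamicField", "Analysis"))
})

test_that("each rewrite step is a fixpoint on its own output", {
  g <- build_schema_graph(fx_schema())
  g1 <- merge_sinks(g)
  expect_identical(sg_signature(merge_sinks(g1)), sg_signature(g1))
  g2 <- merge_entities(g1)
  expect_identical(sg_signature(merge_entities(g2)), sg_signature(g2))
  g3 <- resolve_sources(g2)
  expect_identical(sg_signature(resolve_sources(g3)), sg_signature(g3))
  g4 <- resolve_fk_hubs(g3)
  expect_identical(sg_signature(resolve_fk_hubs(g4)), sg_signature(g4))
})

test_that("the derived model is independent of declaration order", {
  schema <- fx_schema()
  shuffled <- relational_schema(rev(unclass(schema)))
  m1 <- derive_graph_model(schema, fx_config()$name_map)
  m2 <- derive_graph_model(shuffled, fx_config()$name_map)
  expect_identical(names(m1$entities), names(m2$entities))
  expect_identical(vapply(m1$relationships, `[[`, "", "name"),
                   vapply(m2$relationships, `[[`, "", "name"))
  led1 <- m1$ledger[order(m1$ledger$relation, m1$ledger$attribute), ]
  led2 <- m2$ledger[order(m2$ledger$relation, m2$ledger$attribute), ]
  rownames(led1) <- rownames(led2) <- NULL
  expect_identical(led1, led2)
})

test_that("two entities plus one associative relation give two entities and one edge", {
  s <- relational_schema(list(
    relation("A", c(id = "integer", x = "text"), "id"),
    relation("B", c(id = "integer", y = "text"), "id"),
    relation("AB", c(a_id = "integer", b_id = "integer"), c("a_id", "b_id"),
             list(foreign_key("a_id", "A", "id"),
                  foreign_key("b_id", "B", "id")))))
  m <- derive_graph_model(s)
  expect_setequal(names(m$entities), c("A", "B"))
  expect_length(m$relationships, 1)
  expect_identical(m$relationships[[1]]$name, "AB")
  expect_identical(nrow(model_audit(m)), 0L)
})

test_that("a single relation without FKs becomes one entity and no relationships", {
  s <- relational_schema(list(
    relation("Solo", c(id = "integer", x = "text", y = "date"), "id")))
  m <- derive_graph_model(s)
  expect_identical(names(m$entities), "Solo")
  expect_length(m$relationships, 0)
  expect_identical(nrow(model_audit(m)), 0L)
})

test_that("ternary associations are kept as entities with one edge per FK", {
  s <- relational_schema(list(
    relation("A", c(id = "integer", x = "text"), "id"),
    relation("B", c(id = "integer", x = "text"), "id"),
    relation("C", c(id = "integer", x = "text"), "id"),
    relation("ABC", c(a_id = "integer", b_id = "integer", c_id = "integer"),
             c("a_id", "b_id", "c_id"),
             list(foreign_key("a_id", "A", "id"),
                  foreign_key("b_id", "B", "id"),
                  foreign_key("c_id", "C", "id")))))
  m <- derive_graph_model(s)
  expect_setequal(names(m$entities), c("A", "B", "C", "ABC"))
  ends <- vapply(m$relationships, function(r) paste(sort(c(r$a, r$b)),
                                                    collapse = "-"), "")
  expect_setequal(ends, c("A-ABC", "ABC-B", "ABC-C"))
  expect_identical(nrow(model_audit(m)), 0L)
})

test_that("every attribute of random schemas is placed exactly once", {
  for (seed in 1:10) {
    s <- random_schema(seed)
    m <- derive_graph_model(s)
    expect_identical(nrow(model_audit(m)), 0L,
                     info = sprintf("seed %d", seed))
  }
})
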