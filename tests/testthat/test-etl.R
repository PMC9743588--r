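test_that("migration creates one node per row with typed, null-free properties", {
  pg <- toy_graph()
  prj <- pg$nodes[["Project:12345"]]
  expect_identical(prj$labels, "Project")
  expect_identical(prj$props$id, 12345L)
  expect_identical(prj$props$name, "Leukemia Research")
  # a material owned by a patient: node plus ownership edge
  expect_false(is.null(pg$nodes[["Material:1"]]))
  hm <- pg$edges[pg$edges$type == "HasMaterial", ]
  expect_true(any(hm$src == "Patient:1" & hm$dst == "Material:1"))
  # null property omitted (analysis 2 has no result)
  expect_null(pg$nodes[["Analysis:2"]]$props$result)
  # relationship properties, including the FK-lookup description
  hd <- pg$edges[pg$edges$type == "HasDiagnosis", ]
  p1 <- hd$props[[which(hd$src == "Patient:1")]]
  expect_identical(p1$date, as.Date("2019-05-10"))
  expect_identical(p1$description, "first relapse")
  p2 <- hd$props[[which(hd$src == "Patient:2")]]
  expect_null(p2$description)
})

test_that("sub-materials become parent-labeled nodes in a CreatedFrom hierarchy", {
  pg <- toy_graph()
  sub <- pg$nodes[["Material:501"]]
  expect_identical(sub$labels, "Material")
  expect_identical(sub$props$sub_number, 1L)
  cf <- pg$edges[pg$edges$type == "CreatedFrom", ]
  expect_true(any(cf$src == "Material:501" & cf$dst == "Material:1"))
})

test_that("fusion detections deduplicate into shared nodes, aliases included", {
  pg <- toy_graph()
  fus <- names(pg$nodes)[vapply(pg$nodes, function(n) "Fusion" %in% n$labels,
                                logical(1))]
  expect_setequal(fus, c("Fusion:CRLF2-P2RY8", "Fusion:PAX5"))
  hf <- pg$edges[pg$edges$type == "HasFusion", ]
  # analyses 1-3 all detect CRLF2-P2RY8 (analysis 2 via alias spelling)
  expect_setequal(hf$src[hf$dst == "Fusion:CRLF2-P2RY8"],
                  c("Analysis:1", "Analysis:2", "Analysis:3"))
  expect_identical(hf$src[hf$dst == "Fusion:PAX5"], "Analysis:1")
  expect_identical(pg$nodes[["Fusion:CRLF2-P2RY8"]]$props$name, "CRLF2-P2RY8")
})

test_that("an empty instance migrates to an empty graph", {
  inst <- relational_instance(list(), fx_schema())
  mg <- migrate(inst, fx_model(), catalog = fx_catalog())
  expect_length(mg$graph$nodes, 0)
  expect_identical(nrow(mg$graph$edges), 0L)
  expect_identical(sum(mg$report$node_counts), 0L)
})

test_that("migration is idempotent: re-running yields the identical graph", {
  m1 <- migrate(toy_instance(), fx_model(), catalog = fx_catalog())$graph
  m2 <- migrate(toy_instance(), fx_model(), catalog = fx_catalog())$graph
  expect_identical(names(m1$nodes), names(m2$nodes))
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$edges[1:3], m2$edges[1:3])
})

test_that("migration fails on broken references unless rows may be skipped", {
  tables <- toy_instance()$tables
  tables$Analysis$order_id[3] <- 77L
  broken <- relational_instance(tables, fx_schema())
  expect_error(migrate(broken, fx_model(), catalog = fx_catalog()),
               "referential integrity violated")
  mg <- migrate(broken, fx_model(), catalog = fx_catalog(),
                skip_violations = TRUE)
  # the drop cascades to rows depending on the skipped analysis
  expect_setequal(mg$report$skipped$relation,
                  c("Analysis", "DynamicField", "ResultAnalysis"))
  expect_false("Analysis:3" %in% names(mg$graph$nodes))
})

test_that("migration validation passes on generated cohorts and flags tampering", {
  co <- fx_cohort(100, 42)
  pg <- fx_graph(100, 42)
  v <- validate_migration(co$instance, pg, fx_model(), fx_catalog())
  expect_true(all(v$ok))
  # node and edge counts mirror the relational row counts
  expect_equal(v$actual[v$check == "nodes(Patient)"], 100)
  tampered <- pg
  drop <- names(tampered$nodes)[match("Result", vapply(tampered$nodes, function(n)
    n$labels[1], character(1)))]
  tampered$nodes[[drop]] <- NULL
  v2 <- validate_migration(co$instance, tampered, fx_model(), fx_catalog())
  expect_false(v2$ok[v2$check == "nodes(Result)"])
})

test_that("GraphML export round-trips counts, labels and property values", {
  pg <- toy_graph()
  f <- withr::local_tempfile(fileext = ".graphml")
  export_graph(pg, "graphml", f)
  back <- read_graphml(f)
  expect_identical(length(back$nodes), length(pg$nodes))
  expect_identical(nrow(back$edges), nrow(pg$edges))
  expect_identical(back$nodes[["Analysis:1"]]$labels,
                   pg$nodes[["Analysis:1"]]$labels)
  # values come back as their serialized text form
  expect_identical(back$nodes[["Patient:1"]]$props$dob, "2010-04-02")
  expect_identical(back$nodes[["Project:12345"]]$props$name, "Leukemia Research")
  ho <- back$edges[back$edges$type == "HasOrder", ]
  expect_identical(ho$props[[which(ho$src == "Patient:1")]]$order_date,
                   "2019-05-12")
})

test_that("the Cypher script replays idempotently", {
  pg <- toy_graph()
  f <- withr::local_tempfile(fileext = ".cypher")
  export_graph(pg, "cypher_script", f)
  lines <- readLines(f)
  expect_true(all(grepl("^(MERGE|MATCH)", lines)))
  once <- cypher_replay(f)
  twice <- cypher_replay(f, once)
  expect_identical(length(once$nodes), length(pg$nodes))
  expect_identical(length(once$edges), nrow(pg$edges))
  expect_identical(length(twice$nodes), length(once$nodes))
  expect_identical(length(twice$edges), length(once$edges))
})

test_that("bulk CSV export follows the import header conventions", {
  pg <- toy_graph()
  dir <- withr::local_tempdir()
  files <- export_graph(pg, "bulk_csv", dir)
  nodes <- utils::read.csv(file.path(dir, "nodes_Patient.csv"),
                           check.names = FALSE)
  expect_true(all(c("id:ID", ":LABEL") %in% names(nodes)))
  expect_identical(nrow(nodes), 3L)
  edges <- utils::read.csv(file.path(dir, "edges_HasOrder.csv"),
                           check.names = FALSE)
  expect_true(all(c(":START_ID", ":END_ID", ":TYPE") %in% names(edges)))
  expect_true("order_date" %in% names(edges))
})

test_that("pattern queries return each node once where the join repeats rows", {
  pg <- toy_graph()
  inst <- toy_instance()
  sub <- dedup_query(pg, c("Patient", "HasOrder", "Order", "HasAnalysis",
                           "Analysis", "HasResult", "Result"))
  pat_nodes <- names(sub$nodes)[vapply(sub$nodes, function(n)
    "Patient" %in% n$labels, logical(1))]
  # join-table oracle: one row per (patient, analysis, result) combination
  join <- merge(merge(merge(inst$tables$OrderPatient,
                            inst$tables$Analysis, by.x = "order_id",
                            by.y = "order_id"),
                      inst$tables$ResultAnalysis,
                      by.x = "id", by.y = "analysis_id"),
                inst$tables$Result, by.x = "result_id", by.y = "id")
  expect_identical(length(pat_nodes), length(unique(join$patient_id)))
  expect_gt(nrow(join), length(pat_nodes))  # the join repeats each patient
  expect_setequal(sub("Patient:", "", pat_nodes),
                  as.character(unique(join$patient_id)))
})

test_that("pattern queries handle shared nodes and report unknown pattern parts", {
  pg <- toy_graph()
  sub <- dedup_query(pg, c("Patient", "HasOrder", "Order", "HasAnalysis",
                           "Analysis", "HasFusion", "Fusion"))
  fus <- names(sub$nodes)[vapply(sub$nodes, function(n) "Fusion" %in% n$labels,
                                 logical(1))]
  # two patients share one fusion node
  expect_true("Fusion:CRLF2-P2RY8" %in% fus)
  hf <- sub$edges[sub$edges$type == "HasFusion" &
                    sub$edges$dst == "Fusion:CRLF2-P2RY8", ]
  expect_identical(nrow(hf), 3L)
  pats <- names(sub$nodes)[vapply(sub$nodes, function(n) "Patient" %in% n$labels,
                                  logical(1))]
  expect_setequal(pats, c("Patient:1", "Patient:2"))
  # no matches -> empty subgraph
  none <- dedup_query(pg, c("Project", "HasFusion", "Fusion"))
  expect_length(none$nodes, 0)
  expect_identical(nrow(none$edges), 0L)
  expect_error(dedup_query(pg, c("Klingon", "HasOrder", "Order")),
               "unknown label")
  expect_error(dedup_query(pg, c("Patient", "Teleports", "Order")),
               "unknown relationship type")
})
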