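test_that("the fixture schema reads with all relations and a valid FK closure", {
  schema <- fx_schema()
  core <- c("Patient", "Project", "Family", "Order", "Diagnosis",
            "DiagnosisAddition", "AnalysisMaster", "Analysis", "DynamicField",
            "Material", "MaterialNumber", "Result")
  expect_true(all(core %in% names(schema)))
  expect_length(schema, 18)
  expect_identical(schema$Patient$pk, "id")
  expect_identical(schema$DynamicField$pk, c("analysis_id", "field"))
  opt <- vapply(schema$DiagnosisPatient$fks, function(f) f$optional, logical(1))
  expect_identical(sum(opt), 1L)  # only the diagnosis addition is optional
})

test_that("an empty schema document yields an empty schema without error", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("relations: {}", f)
  expect_length(read_schema(f), 0)
})

test_that("schema validation reports dangling FKs and duplicate names", {
  expect_error(
    relational_schema(list(
      relation("A", c(id = "integer", b_id = "integer"), "id",
               list(foreign_key("b_id", "B", "id"))))),
    "dangling FK target.*A\\(b_id\\).*B")
  expect_error(
    relational_schema(list(relation("A", c(id = "integer"), "id"),
                           relation("A", c(id = "integer"), "id"))),
    "duplicate relation name")
  expect_error(relation("A", c(id = "integer", id = "text"), "id"),
               "duplicate attribute")
  expect_error(
    relational_schema(list(
      relation("A", c(id = "integer", name = "text"), "id"),
      relation("B", c(id = "integer", a_name = "text"), "id",
               list(foreign_key("a_name", "A", "name"))))),
    "must reference the primary key")
})

test_that("instance reading types rows, handles missing files and round-trips", {
  schema <- fx_schema()
  dir <- withr::local_tempdir()
  writeLines(c("id,name", '12345,"Leukemia Research"'),
             file.path(dir, "Project.csv"))
  inst <- read_instance(dir, schema)
  prj <- inst$tables$Project
  expect_identical(prj$id, 12345L)
  expect_identical(prj$name[prj$id == 12345L], "Leukemia Research")
  expect_true(all(vapply(inst$tables[names(inst$tables) != "Project"], nrow,
                         integer(1)) == 0))

  co <- fx_cohort(50, 11)
  out <- withr::local_tempdir()
  write_instance(co$instance, out)
  back <- read_instance(out, schema)
  for (nm in names(schema)) {
    expect_identical(back$tables[[nm]], co$instance$tables[[nm]], info = nm)
  }
})

test_that("instance validation rejects bad tables with located errors", {
  schema <- fx_schema()
  expect_error(
    relational_instance(list(Patient = data.frame(
      id = c(1L, 1L), name = c("A", "B"), gender = c("F", "M"),
      dob = c("2010-01-01", "2011-01-01"))), schema),
    "Patient: duplicate primary key")
  expect_error(
    relational_instance(list(Patient = data.frame(
      id = "x", name = "A", gender = "F", dob = "2010-01-01")), schema),
    "type coercion failure in Patient.id")
  expect_error(
    relational_instance(list(Project = data.frame(id = 1L, nom = "x")), schema),
    "unknown column 'nom'")
  expect_error(
    relational_instance(list(Patient = data.frame(
      id = 1L, name = "A", gender = "F", dob = "someday")), schema),
    "not an ISO-8601 date")
})

test_that("referential integrity scan agrees with a nested-loop oracle", {
  schema <- fx_schema()
  co <- fx_cohort(25, 5)
  expect_identical(nrow(check_referential_integrity(co$instance)), 0L)
  expect_true(oracle_integrity_ok(co$instance, schema))

  broken <- co$instance
  broken$tables$Analysis$order_id[1] <- 999999L
  rep <- check_referential_integrity(broken)
  expect_identical(nrow(rep), 1L)
  expect_match(rep$fk, "Analysis\\(order_id\\)->Order")
  expect_false(oracle_integrity_ok(broken, schema))
})

test_that("null optional FKs pass while null mandatory FKs are violations", {
  schema <- fx_schema()
  inst <- toy_instance()
  expect_true(is.na(inst$tables$DiagnosisPatient$addition[2]))
  expect_identical(nrow(check_referential_integrity(inst)), 0L)

  tables <- inst$tables
  tables$Analysis$order_id[1] <- NA_integer_
  broken <- relational_instance(tables, schema)
  rep <- check_referential_integrity(broken)
  expect_identical(rep$reason, "null value in mandatory FK")
})
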