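test_that("distribution counts equal the generator's ground-truth tallies", {
  co <- fx_cohort(100, 42)
  pg <- fx_graph(100, 42)
  gt <- co$ground_truth$patients
  d <- distribution(pg, "gender")
  expect_identical(nrow(d), 2L)
  expect_equal(d$value[d$x_bin == "F"], sum(gt$gender == "F"))
  expect_equal(d$value[d$x_bin == "M"], sum(gt$gender == "M"))
  # diagnosis distribution grouped by gender, zero cells included
  dd <- distribution(pg, "diagnosis", "gender")
  expect_identical(nrow(dd), length(unique(dd$x_bin)) * 2L)
  oracle <- table(DIAGNOSES$name[gt$diagnosis_id], gt$gender)
  for (i in seq_len(nrow(dd))) {
    exp <- tryCatch(oracle[dd$x_bin[i], dd$group[i]], error = function(e) 0L)
    expect_equal(dd$value[i], as.numeric(exp),
                 info = paste(dd$x_bin[i], dd$group[i]))
  }
})

test_that("age selectors bin whole years against the chosen reference date", {
  co <- fx_cohort(100, 42)
  pg <- fx_graph(100, 42)
  ref <- as.Date("2021-12-31")
  d <- distribution(pg, "current_age", "gender", reference_date = ref)
  expect_equal(sum(d$value), 100)
  gt <- co$ground_truth$patients
  # independent calendar-age oracle via date formatting
  cal_age <- function(dob, ref) {
    as.integer(format(ref, "%Y")) - as.integer(format(dob, "%Y")) -
      (format(ref, "%m%d") < format(dob, "%m%d"))
  }
  oracle_age <- cal_age(as.Date(gt$dob), ref)
  # spot-check the aggregate: identical age histogram
  got <- stats::aggregate(value ~ x_bin, d, sum)
  oracle_tab <- table(oracle_age)
  for (i in seq_len(nrow(got))) {
    expect_equal(got$value[i], as.numeric(oracle_tab[[got$x_bin[i]]]),
                 info = got$x_bin[i])
  }
  # age at diagnosis uses the HasDiagnosis edge date
  dad <- distribution(pg, "age_at_diagnosis", reference_date = ref)
  diag_date <- as.Date(co$instance$tables$DiagnosisPatient$date)
  dob <- as.Date(gt$dob)[co$instance$tables$DiagnosisPatient$patient_id]
  oracle_dad <- cal_age(dob, diag_date)
  expect_equal(sum(dad$value), length(oracle_dad))
  expect_setequal(dad$x_bin[dad$value > 0], as.character(sort(unique(oracle_dad))))
  expect_error(distribution(pg, "current_age"), "reference_date")
  expect_error(distribution(pg, "shoe_size"), "unknown selector")
})

test_that("frequency measure normalizes the table to sum one", {
  pg <- fx_graph(100, 42)
  for (sel in c("gender", "diagnosis", "material_type")) {
    d <- distribution(pg, sel, "gender", measure = "frequency")
    expect_equal(sum(d$value), 1, tolerance = 1e-9, info = sel)
  }
})

test_that("an empty graph yields an empty distribution table", {
  inst <- relational_instance(list(), fx_schema())
  pg <- migrate(inst, fx_model(), catalog = fx_catalog())$graph
  d <- distribution(pg, "gender")
  expect_identical(nrow(d), 0L)
})

test_that("fusion names resolve through the alias table case-insensitively", {
  cat <- fx_catalog()
  r <- resolve_fusion(cat, "crlf2-p2ry8")
  expect_identical(as.character(r), "CRLF2-P2RY8")
  expect_true(attr(r, "matched"))
  expect_identical(as.character(resolve_fusion(cat, "CRLF2-P2RY8")),
                   "CRLF2-P2RY8")
  expect_identical(as.character(resolve_fusion(cat, " tel-aml1 ")), "ETV6-RUNX1")
  expect_identical(as.character(resolve_fusion(cat, "Hyperdiploidy")),
                   "ANEUPLOIDY:HYPERDIPLOIDY")
  unk <- resolve_fusion(cat, "zz-unknown")
  expect_identical(as.character(unk), "ZZ-UNKNOWN")
  expect_false(attr(unk, "matched"))
  expect_error(fusion_catalog(list(A = list(aliases = "X"),
                                   B = list(aliases = "x"))),
               "ambiguous alias")
})

test_that("subgroup selection returns the ground-truth carriers", {
  co <- fx_cohort(100, 42)
  pg <- fx_graph(100, 42)
  gt <- co$ground_truth$fusions
  sub <- subgroup(pg, "P2RY8-CRLF2", fx_catalog(), reference_date = "2021-12-31")
  expect_identical(sub$canonical, "CRLF2-P2RY8")
  carriers <- gt$patient_id[gt$canonical == "CRLF2-P2RY8"]
  expect_setequal(sub$table$patient_id, as.character(carriers))
  expect_true(all(!is.na(sub$table$age)))
  # alias input and canonical input agree
  sub2 <- subgroup(pg, "CRLF2-P2RY8", fx_catalog())
  expect_identical(sub2$table$patient_id, sub$table$patient_id)
})

test_that("subgroup expansion stays edge-closed around the returned patients", {
  pg <- fx_graph(100, 42)
  sub <- subgroup(pg, "ETV6-RUNX1", fx_catalog(), expand = "Material")
  mats <- names(sub$subgraph$nodes)[vapply(sub$subgraph$nodes, function(n)
    "Material" %in% n$labels, logical(1))]
  pats <- paste0("Patient:", sub$table$patient_id)
  hm <- sub$subgraph$edges[sub$subgraph$edges$type == "HasMaterial", ]
  expect_true(all(mats %in% hm$dst))
  expect_true(all(hm$src %in% pats))
})

test_that("a catalog-known subgroup with no detections yields an empty view", {
  pg <- toy_graph()
  sub <- subgroup(pg, "BCR-ABL", fx_catalog())
  expect_identical(sub$canonical, "BCR-ABL1")
  expect_identical(nrow(sub$table), 0L)
  expect_length(sub$subgraph$nodes, 1)
  expect_error(subgroup(pg, "NOT-A-FUSION", fx_catalog()), "unknown subgroup")
})

test_that("feature sets union fusions, aneuploidies and diagnosis codes", {
  pg <- toy_graph()
  fs1 <- feature_set(pg, 1)
  expect_setequal(fs1$features, c("PAX5", "CRLF2-P2RY8", "C91.0"))
  # the same fusion detected by two analyses collapses to one feature
  fs2 <- feature_set(pg, 2)
  expect_setequal(fs2$features, c("CRLF2-P2RY8", "C91.0"))
  # no analyses, no diagnosis -> empty set
  fs3 <- feature_set(pg, 3)
  expect_length(fs3$features, 0)
  expect_error(feature_set(pg, 99), "unknown patient")
})

test_that("jaccard matches its definition and conventions", {
  expect_identical(jaccard(c("A", "B"), c("A", "B")), 1)
  expect_identical(jaccard("A", c("B", "C")), 0)
  expect_identical(jaccard(c("PAX5", "CRLF2-P2RY8"), "PAX5"), 0.5)
  expect_identical(jaccard(character(0), character(0)), 0)
  # symmetry and bounds over random feature sets
  set.seed(1)
  pool <- LETTERS[1:8]
  for (i in 1:25) {
    a <- sample(pool, sample(0:5, 1))
    b <- sample(pool, sample(0:5, 1))
    expect_identical(jaccard(a, b), jaccard(b, a))
    expect_gte(jaccard(a, b), 0)
    expect_lte(jaccard(a, b), 1)
    if (length(a)) expect_identical(jaccard(a, a), 1)
    if (jaccard(a, b) == 1 && length(a)) expect_setequal(a, b)
  }
})

test_that("the similarity graph thresholds strictly and shrinks as it rises", {
  pg <- toy_graph()
  # patient 1 vs 2 share 2 of 3 features; patient 3 is featureless
  sg <- similarity_graph(pg, 1, threshold = 0)
  expect_identical(sg$patient_b, "2")
  expect_equal(sg$score, 2 / 3)
  expect_identical(nrow(similarity_graph(pg, 1, threshold = 0.7)), 0L)
  pg100 <- fx_graph(100, 42)
  fs <- feature_sets(pg100)
  e_lo <- similarity_graph(pg100, 5, 0.2, features = fs)
  e_hi <- similarity_graph(pg100, 5, 0.6, features = fs)
  expect_true(all(e_hi$patient_b %in% e_lo$patient_b))
  expect_error(similarity_graph(pg100, "nope"), "unknown target")
  expect_error(similarity_graph(pg100, 5, threshold = 2), "threshold")
})

test_that("the patient view restricts to requested types and display attributes", {
  pg <- toy_graph()
  pv <- patient_subgraph(pg, 1, c("Order", "Analysis", "Fusion"),
                         display = list(Patient = "gender", Fusion = "name"))
  expect_identical(pv$nodes$display[pv$nodes$id == "Patient:1"], "F")
  expect_true("Fusion:PAX5" %in% pv$nodes$id)
  expect_false(any(grepl("^Material:", pv$nodes$id)))
  # shared fusion nodes are leaves: patient 2's records stay out
  expect_false("Analysis:3" %in% pv$nodes$id)
  # empty type set -> single node
  solo <- patient_subgraph(pg, 1)
  expect_identical(solo$nodes$id, "Patient:1")
  expect_identical(nrow(solo$edges), 0L)
  expect_error(patient_subgraph(pg, 1, display = list(Fusion = "karyotype")),
               "not allowed for label Fusion")
})
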