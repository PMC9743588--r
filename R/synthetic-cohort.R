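# Seeded generator for synthetic relational instances with the structure of a
# pediatric-ALL diagnostics database: patients with gender and date of birth,
# family/project memberships, ALL and non-ALL diagnoses, orders, typed
# analyses (RNA-seq, panel, array-CGH) with key-value dynamic fields carrying
# fusion/aneuploidy detections (sometimes via alias spellings), a two-level
# material hierarchy, and aggregated results. Ground truth records every
# sampled assignment so that analytics can be tested against known tallies.

GIVEN_NAMES <- c("Alex", "Ben", "Clara", "Dana", "Emil", "Fiona", "Georg",
                 "Hana", "Ivo", "Julia", "Karl", "Lena", "Mia", "Nils",
                 "Olga", "Paul", "Rosa", "Sven", "Tara", "Ute")
FAMILY_NAMES <- c("Abel", "Bauer", "Conrad", "Dietz", "Ebert", "Falk",
                  "Graf", "Hoffmann", "Ibsen", "Jung", "Keller", "Lang",
                  "Maier", "Neumann", "Otto", "Peters", "Quandt", "Richter",
                  "Schmidt", "Thiel")

DIAGNOSES <- data.frame(
  id = 1:4,
  name = c("Acute lymphoblastic leukemia", "Acute myeloid leukemia",
           "Myelodysplastic syndrome", "Trisomy 21"),
  icd = c("C91.0", "C92.0", "D46", "Q90.9"),
  stringsAsFactors = FALSE)

ANALYSIS_TYPES <- data.frame(id = 1:3,
                             type = c("RNASeq", "Panel", "ArrayCGH"),
                             stringsAsFactors = FALSE)

#' Parameters of the synthetic cohort generator
#'
#' Defaults describe a small pediatric-ALL cohort: an even gender split, a
#' small non-ALL comorbidity fraction (AML, MDS, Trisomy 21), per-fusion
#' carrier prevalences taken from the shipped catalog, roughly 1.3 orders and
#' 2-3 analyses per patient with an RNA-seq/panel/array-CGH mix, one or two
#' materials per patient each with at least one sub-material, and pediatric
#' birth dates. All sampling happens in one seeded stream; entity ids are
#' deterministic sequences per relation.
#'
#' @param n_patients cohort size.
#' @param gender_split probability of gender `"F"`.
#' @param non_all_fraction fraction of patients with a non-ALL diagnosis.
#' @param catalog [fusion_catalog()] providing names, aliases and prevalences.
#' @param alias_fraction fraction of detections written with an alias spelling
#'   rather than the canonical name.
#' @param analysis_type_mix sampling proportions over RNASeq/Panel/ArrayCGH.
#' @param orders_extra,analyses_extra,materials_extra,sub_materials_extra
#'   Poisson means for counts beyond the guaranteed first order / analysis /
#'   material / sub-material.
#' @param family_mean_size mean number of patients per family.
#' @param project_count number of research projects.
#' @param extra_project_prob probability of a second project membership.
#' @param addition_prob probability that a diagnosis carries an addition.
#' @param q_prob probability that an RNA-seq analysis records the numeric
#'   measurement field `q`.
#' @param birth_range,date_max ISO dates bounding births and clinical dates.
#' @param seed integer seed for the generator stream.
#' @return a list of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 100, gender_split = 0.5,
                          non_all_fraction = 0.1,
                          catalog = read_fusion_catalog(),
                          alias_fraction = 0.3,
                          analysis_type_mix = c(RNASeq = 0.5, Panel = 0.3,
                                                ArrayCGH = 0.2),
                          orders_extra = 0.3, analyses_extra = 0.8,
                          materials_extra = 0.5, sub_materials_extra = 0.6,
                          family_mean_size = 2.5, project_count = 3,
                          extra_project_prob = 0.3, addition_prob = 0.3,
                          q_prob = 0.5,
                          birth_range = c("2004-01-01", "2020-12-31"),
                          date_max = "2021-12-31", seed = 1L) {
  stopifnot(n_patients >= 0, gender_split >= 0, gender_split <= 1,
            non_all_fraction >= 0, non_all_fraction <= 1,
            alias_fraction >= 0, alias_fraction <= 1,
            all(analysis_type_mix >= 0), project_count >= 1)
  if (as.Date(birth_range[1]) > as.Date(birth_range[2])) {
    stop2("birth_range must be ordered")
  }
  p <- catalog$prevalence
  if (any(!is.na(p) & (p < 0 | p > 1))) stop2("prevalences must lie in [0, 1]")
  structure(as.list(environment()), class = "cohort_params")
}

sample_dates <- function(n, from, to) {
  from <- as.Date(from); to <- as.Date(to)
  from + sample.int(as.integer(to - from) + 1L, n, replace = TRUE) - 1L
}

#' Generate a synthetic cohort instance with ground truth
#'
#' @param params a [cohort_params()] list.
#' @return list of class `synthetic_cohort` with `instance` (a
#'   `relational_instance` over the shipped schema), `ground_truth` (sampled
#'   assignments and tallies) and `params`.
#' @export
generate_cohort <- function(params = cohort_params()) {
  if (!inherits(params, "cohort_params")) stop2("params must be cohort_params()")
  schema <- read_schema(all_schema_path())
  set.seed(params$seed)
  n <- params$n_patients
  cat_prev <- params$catalog$prevalence
  cat_prev <- cat_prev[!is.na(cat_prev)]

  if (n == 0) {
    inst <- relational_instance(list(), schema)
    gt <- structure(list(seed = params$seed, n_patients = 0L,
                         patients = data.frame(), fusions = data.frame(
                           patient_id = integer(0), canonical = character(0),
                           stringsAsFactors = FALSE),
                         fusion_carriers = stats::setNames(integer(length(cat_prev)),
                                                           names(cat_prev)),
                         prevalence = cat_prev),
                    class = "cohort_ground_truth")
    return(structure(list(instance = inst, ground_truth = gt, params = params),
                     class = "synthetic_cohort"))
  }

  # --- patients, families, projects ----------------------------------------
  gender <- ifelse(stats::runif(n) < params$gender_split, "F", "M")
  dob <- sample_dates(n, params$birth_range[1], params$birth_range[2])
  pname <- paste(sample(GIVEN_NAMES, n, TRUE), sample(FAMILY_NAMES, n, TRUE))
  patient <- data.frame(id = seq_len(n), name = pname, gender = gender,
                        dob = dob, stringsAsFactors = FALSE)

  fam_n <- max(1L, round(n / params$family_mean_size))
  fam_of <- sample.int(fam_n, n, replace = TRUE)
  family <- data.frame(id = seq_len(fam_n),
                       name = paste("Family", seq_len(fam_n)),
                       stringsAsFactors = FALSE)
  family_patient <- data.frame(patient_id = seq_len(n), family_id = fam_of,
                               stringsAsFactors = FALSE)

  proj_names <- c("Leukemia Research", "Genomic Diagnostics", "ALL Registry")
  pc <- params$project_count
  project <- data.frame(id = seq_len(pc) + 12344L,
                        name = if (pc <= 3) proj_names[seq_len(pc)] else
                          c(proj_names, paste("Project", 4:pc)),
                        stringsAsFactors = FALSE)
  pp <- data.frame(patient_id = seq_len(n), project_id = project$id[1],
                   stringsAsFactors = FALSE)
  if (pc > 1) {
    extra <- which(stats::runif(n) < params$extra_project_prob)
    if (length(extra)) {
      pp <- rbind(pp, data.frame(
        patient_id = extra,
        project_id = sample(project$id[-1], length(extra), replace = TRUE),
        stringsAsFactors = FALSE))
    }
  }

  # --- diagnoses ------------------------------------------------------------
  non_all <- stats::runif(n) < params$non_all_fraction
  diag_id <- ifelse(non_all, sample(2:4, n, replace = TRUE), 1L)
  diag_date <- pmin(dob + sample(180:5500, n, replace = TRUE),
                    as.Date(params$date_max))
  addition <- ifelse(stats::runif(n) < params$addition_prob,
                     sample.int(3L, n, replace = TRUE), NA_integer_)
  diagnosis_addition <- data.frame(
    id = 1:3,
    description = c("first relapse", "remission after induction",
                    "secondary malignancy"),
    stringsAsFactors = FALSE)
  diagnosis_patient <- data.frame(patient_id = seq_len(n), diagnosis_id = diag_id,
                                  date = diag_date, addition = addition,
                                  stringsAsFactors = FALSE)

  # --- fusion / aneuploidy carriers ----------------------------------------
  carrier <- lapply(names(cat_prev), function(cn) {
    which(stats::runif(n) < cat_prev[[cn]])
  })
  names(carrier) <- names(cat_prev)
  fus_gt <- do.call(rbind, c(list(data.frame(patient_id = integer(0),
                                             canonical = character(0),
                                             stringsAsFactors = FALSE)),
    lapply(names(carrier), function(cn) {
      if (!length(carrier[[cn]])) return(NULL)
      data.frame(patient_id = carrier[[cn]], canonical = cn,
                 stringsAsFactors = FALSE)
    })))
  is_aneu <- grepl("^ANEUPLOIDY:", fus_gt$canonical)
  gene_carriers <- unique(fus_gt$patient_id[!is_aneu])
  aneu_carriers <- unique(fus_gt$patient_id[is_aneu])

  # --- orders ---------------------------------------------------------------
  n_orders <- 1L + stats::rpois(n, params$orders_extra)
  ord_pat <- rep(seq_len(n), n_orders)
  n_ord <- length(ord_pat)
  order_tbl <- data.frame(id = seq_len(n_ord),
                          type = sample(c("diagnostic", "follow-up"), n_ord,
                                        replace = TRUE, prob = c(0.7, 0.3)),
                          stringsAsFactors = FALSE)
  order_patient <- data.frame(
    patient_id = ord_pat, order_id = order_tbl$id,
    order_date = pmin(diag_date[ord_pat] + sample(0:60, n_ord, replace = TRUE),
                      as.Date(params$date_max)),
    stringsAsFactors = FALSE)

  # --- materials ------------------------------------------------------------
  n_mat <- 1L + stats::rpois(n, params$materials_extra)
  mat_pat <- rep(seq_len(n), n_mat)
  n_material <- length(mat_pat)
  material <- data.frame(id = seq_len(n_material),
                         type = sample(c("Blood", "Bone marrow", "DNA", "RNA"),
                                       n_material, replace = TRUE),
                         stringsAsFactors = FALSE)
  material_patient <- data.frame(patient_id = mat_pat, material_id = material$id,
                                 stringsAsFactors = FALSE)
  n_sub <- 1L + stats::rpois(n_material, params$sub_materials_extra)
  sub_master <- rep(material$id, n_sub)
  material_number <- data.frame(
    id = 500000L + seq_along(sub_master),
    master_id = sub_master,
    sub_type = sample(c("Preparation", "Cultivation", "Extraction"),
                      length(sub_master), replace = TRUE),
    sub_number = unlist(lapply(n_sub, seq_len)),
    stringsAsFactors = FALSE)
  subs_by_patient <- split(material_number$id, mat_pat[match(sub_master, material$id)])

  # --- analyses -------------------------------------------------------------
  n_an_per_order <- 1L + stats::rpois(n_ord, params$analyses_extra)
  an_order <- rep(order_tbl$id, n_an_per_order)
  an_pat <- ord_pat[an_order]
  mix <- params$analysis_type_mix / sum(params$analysis_type_mix)
  an_type <- sample(names(mix), length(an_order), replace = TRUE, prob = mix)
  # guarantee a detecting assay for every carrier
  for (p in gene_carriers) {
    idx <- which(an_pat == p)
    if (!any(an_type[idx] == "RNASeq")) an_type[idx[1]] <- "RNASeq"
  }
  for (p in aneu_carriers) {
    idx <- which(an_pat == p)
    if (!any(an_type[idx] == "ArrayCGH")) {
      free <- idx[an_type[idx] != "RNASeq"]
      if (length(free)) an_type[free[length(free)]] <- "ArrayCGH"
      else {
        an_order <- c(an_order, an_order[idx[1]])
        an_pat <- c(an_pat, p)
        an_type <- c(an_type, "ArrayCGH")
      }
    }
  }
  n_an <- length(an_order)
  an_material <- vapply(seq_len(n_an), function(i) {
    pool <- subs_by_patient[[as.character(an_pat[i])]]
    pool[sample.int(length(pool), 1L)]
  }, integer(1))
  analysis <- data.frame(
    id = seq_len(n_an), order_id = an_order,
    master_id = ANALYSIS_TYPES$id[match(an_type, ANALYSIS_TYPES$type)],
    material_id = an_material,
    result = sample(c("completed", "see report", NA), n_an, replace = TRUE,
                    prob = c(0.5, 0.3, 0.2)),
    stringsAsFactors = FALSE)

  # --- dynamic fields -------------------------------------------------------
  pick_spelling <- function(canonical) {
    vapply(canonical, function(cn) {
      al <- setdiff(params$catalog$aliases[[cn]], cn)
      if (length(al) && stats::runif(1) < params$alias_fraction) {
        al[sample.int(length(al), 1L)]
      } else cn
    }, character(1), USE.NAMES = FALSE)
  }
  dyn <- list()
  add_dyn <- function(analysis_id, name, value) {
    if (!length(analysis_id)) return(invisible())
    dyn[[length(dyn) + 1L]] <<- data.frame(
      analysis_id = analysis_id, name = name, value = value,
      stringsAsFactors = FALSE)
  }
  gene_gt <- fus_gt[!is_aneu, , drop = FALSE]
  rna <- analysis$id[an_type == "RNASeq"]
  if (nrow(gene_gt) && length(rna)) {
    det <- merge(data.frame(analysis_id = rna, patient_id = an_pat[an_type == "RNASeq"],
                            stringsAsFactors = FALSE), gene_gt, by = "patient_id")
    add_dyn(det$analysis_id, "fusion", pick_spelling(det$canonical))
  }
  aneu_gt <- fus_gt[is_aneu, , drop = FALSE]
  cgh <- analysis$id[an_type == "ArrayCGH"]
  if (length(cgh)) {
    cgh_pat <- an_pat[an_type == "ArrayCGH"]
    if (nrow(aneu_gt)) {
      det <- merge(data.frame(analysis_id = cgh, patient_id = cgh_pat,
                              stringsAsFactors = FALSE), aneu_gt, by = "patient_id")
      add_dyn(det$analysis_id, "aneuploidy", pick_spelling(det$canonical))
    }
    hyper <- cgh_pat %in% aneu_gt$patient_id[aneu_gt$canonical == "ANEUPLOIDY:HYPERDIPLOIDY"]
    hypo <- cgh_pat %in% aneu_gt$patient_id[aneu_gt$canonical == "ANEUPLOIDY:HYPODIPLOIDY"]
    sex <- ifelse(gender[cgh_pat] == "F", "X", "Y")
    karyo <- ifelse(hyper, paste0("54,X", sex, ",+4,+6,+10,+14,+17,+18,+21,+21"),
                    ifelse(hypo, paste0("45,X", sex, ",-7"),
                           paste0("46,X", sex)))
    add_dyn(cgh, "karyotype", karyo)
    add_dyn(cgh, "chromosomes", ifelse(hyper, "54", ifelse(hypo, "45", "46")))
  }
  panel <- analysis$id[an_type == "Panel"]
  if (length(panel)) {
    add_dyn(panel, "mrd", sample(c("positive", "negative"), length(panel),
                                 replace = TRUE, prob = c(0.3, 0.7)))
  }
  q_sel <- rna[stats::runif(length(rna)) < params$q_prob]
  add_dyn(q_sel, "q", as.character(round(stats::runif(length(q_sel), 0, 100), 2)))
  dynamic_field <- do.call(rbind, c(list(data.frame(
    analysis_id = integer(0), name = character(0), value = character(0),
    stringsAsFactors = FALSE)), dyn))
  if (nrow(dynamic_field)) {
    dynamic_field <- dynamic_field[order(dynamic_field$analysis_id), , drop = FALSE]
    slot <- stats::ave(rep(1L, nrow(dynamic_field)), dynamic_field$analysis_id,
                       FUN = seq_along)
    dynamic_field <- data.frame(analysis_id = dynamic_field$analysis_id,
                                field = paste0("f", slot),
                                name = dynamic_field$name,
                                value = dynamic_field$value,
                                stringsAsFactors = FALSE)
  } else {
    dynamic_field <- data.frame(analysis_id = integer(0), field = character(0),
                                name = character(0), value = character(0),
                                stringsAsFactors = FALSE)
  }

  # --- aggregated results ---------------------------------------------------
  n_res <- stats::rbinom(n_an, 2L, 0.4)
  res_an <- rep(analysis$id, n_res)
  result <- data.frame(
    id = seq_along(res_an),
    description = sample(c("Aggregated result", "QC summary"),
                         length(res_an), replace = TRUE),
    value = sample(c("normal", "abnormal", "inconclusive"),
                   length(res_an), replace = TRUE),
    stringsAsFactors = FALSE)
  result_analysis <- data.frame(analysis_id = res_an, result_id = result$id,
                                stringsAsFactors = FALSE)

  inst <- relational_instance(list(
    Patient = patient, Project = project, Family = family, Order = order_tbl,
    Diagnosis = DIAGNOSES, DiagnosisAddition = diagnosis_addition,
    AnalysisMaster = ANALYSIS_TYPES, Analysis = analysis,
    DynamicField = dynamic_field, Material = material,
    MaterialNumber = material_number, Result = result,
    ProjectPatient = pp, FamilyPatient = family_patient,
    DiagnosisPatient = diagnosis_patient, OrderPatient = order_patient,
    MaterialPatient = material_patient, ResultAnalysis = result_analysis),
    schema)

  fus_gt <- fus_gt[order(fus_gt$patient_id, fus_gt$canonical), , drop = FALSE]
  rownames(fus_gt) <- NULL
  gt <- structure(list(
    seed = params$seed, n_patients = n,
    patients = data.frame(id = patient$id, gender = gender,
                          dob = format(dob, "%Y-%m-%d"),
                          diagnosis_id = diag_id,
                          icd = DIAGNOSES$icd[diag_id],
                          family_id = fam_of, stringsAsFactors = FALSE),
    fusions = fus_gt,
    fusion_carriers = vapply(names(cat_prev), function(cn)
      length(carrier[[cn]]), integer(1)),
    analyses_per_patient = as.integer(table(factor(an_pat, levels = seq_len(n)))),
    prevalence = cat_prev), class = "cohort_ground_truth")

  structure(list(instance = inst, ground_truth = gt, params = params),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients (seed %d)\n",
              x$ground_truth$n_patients, x$ground_truth$seed))
  print(x$instance)
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' One CSV per relation (re-readable with [read_instance()]) plus
#' `ground_truth.json`, which is consumed only by tests, never by the
#' pipeline.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  write_instance(cohort$instance, dir)
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(seed = gt$seed, n_patients = gt$n_patients, patients = gt$patients,
         fusions = gt$fusions, fusion_carriers = as.list(gt$fusion_carriers),
         prevalence = as.list(gt$prevalence)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
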