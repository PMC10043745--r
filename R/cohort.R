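# Cohort and episode-of-care construction from claims.
#
# The study design anchors each patient on her earliest screening mammogram
# in the index year, follows her for up to 365 days (ending early at the
# first breast-cancer diagnosis claim), and tabulates subsequent diagnostic
# breast services and out-of-pocket costs within that window.

#' Procedure and diagnosis code configuration
#'
#' Code sets used to recognise screening mammograms, the subsequent-service
#' categories, and breast-cancer diagnoses (prefix semantics; dots retained).
#' The biopsy set is a configurable placeholder of common percutaneous breast
#' biopsy codes.
#'
#' @param screening_codes CPT codes identifying screening mammograms.
#' @param diagnostic_mammo_codes,ultrasound_codes,mri_codes,biopsy_codes CPT
#'   code sets per subsequent-service category.
#' @param cancer_dx_prefixes ICD prefixes (ICD-9 174., ICD-10 C50.) matched
#'   against any diagnosis on a claim.
#' @return list of class \code{code_config}.
#' @export
code_config <- function(screening_codes = c("G0202", "77057", "77063"),
                        diagnostic_mammo_codes = c("G0204", "G0206"),
                        ultrasound_codes = c("76641", "76642"),
                        mri_codes = "77059",
                        biopsy_codes = c("19081", "19083", "19085"),
                        cancer_dx_prefixes = c("174.", "C50.")) {
  sets <- list(screening_codes = screening_codes,
               diagnostic_mammo_codes = diagnostic_mammo_codes,
               ultrasound_codes = ultrasound_codes,
               mri_codes = mri_codes,
               biopsy_codes = biopsy_codes)
  if (any(vapply(sets, length, 1L) == 0L) || length(cancer_dx_prefixes) == 0L)
    stop_invalid("invalid config: all code sets must be non-empty")
  all_codes <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_codes))
    stop_invalid("invalid config: CPT code sets must be pairwise disjoint")
  structure(c(sets, list(cancer_dx_prefixes = cancer_dx_prefixes)),
            class = "code_config")
}

# TRUE where any semicolon-separated diagnosis on the claim starts with one
# of the prefixes.
match_dx_prefix <- function(icd_codes, prefixes) {
  pat <- paste0("(^|;)(", paste(gsub("([.\\\\])", "\\\\\\1", prefixes),
                                collapse = "|"), ")")
  grepl(pat, icd_codes)
}

#' Identify index screening mammograms
#'
#' One index event per patient: the earliest claim in \code{index_year} whose
#' CPT is a screening-mammography code.  Patients with no qualifying claim do
#' not appear.
#'
#' @param claims claims table (standard schema).
#' @param codes a \code{\link{code_config}}.
#' @param index_year calendar year of the index event.
#' @return data.frame with \code{patient_id} and \code{index_date}.
#' @export
identify_index_events <- function(claims, codes = code_config(),
                                  index_year = 2016) {
  sel <- claims$cpt_code %in% codes$screening_codes &
    format(claims$service_date, "%Y") == as.character(index_year)
  if (!any(sel)) {
    return(data.frame(patient_id = character(), index_date = as.Date(character()),
                      stringsAsFactors = FALSE))
  }
  cl <- claims[sel, c("enrollee_id", "service_date")]
  first <- tapply(as.integer(cl$service_date), cl$enrollee_id, min)
  data.frame(patient_id = names(first),
             index_date = as.Date(as.vector(first), origin = "1970-01-01"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply the study inclusion and exclusion criteria
#'
#' Retains patients who are female, at least 40 years old at the start of the
#' study period, continuously enrolled in a single plan across the whole
#' period, alive at its end (a \code{death_date} column is honoured when
#' present, otherwise patients are assumed alive), have an index screening
#' mammogram, and have no claim carrying a breast-cancer diagnosis in the 365
#' days before the index date.  Records with missing sex or birth year are
#' rejected with a reason code.
#'
#' @param enrollment enrollment table (standard schema).
#' @param claims claims table.
#' @param index_map output of \code{\link{identify_index_events}}.
#' @param codes a \code{\link{code_config}}.
#' @param study_start,study_end study period boundaries.
#' @return cohort data.frame (\code{patient_id}, \code{plan_id},
#'   \code{index_date}, \code{birth_year}, demographics where available);
#'   an exclusion log data.frame is attached as attribute
#'   \code{"exclusions"} (\code{patient_id}, \code{reason}).
#' @export
apply_inclusion_criteria <- function(enrollment, claims, index_map,
                                     codes = code_config(),
                                     study_start = as.Date("2015-01-01"),
                                     study_end = as.Date("2017-12-31")) {
  multi <- unique(enrollment$enrollee_id[duplicated(enrollment$enrollee_id)])
  e <- enrollment[match(index_map$patient_id, enrollment$enrollee_id), ,
                  drop = FALSE]
  reason <- rep(NA_character_, nrow(index_map))

  start_year <- as.integer(format(study_start, "%Y"))
  no_enroll <- is.na(e$enrollee_id)
  reason[no_enroll] <- "no_enrollment_record"
  bad_sex <- !no_enroll & (is.na(e$sex) | e$sex == "")
  reason[bad_sex & is.na(reason)] <- "missing_sex"
  bad_by <- !no_enroll & is.na(e$birth_year)
  reason[bad_by & is.na(reason)] <- "missing_birth_year"
  not_f <- !no_enroll & !is.na(e$sex) & e$sex != "F"
  reason[not_f & is.na(reason)] <- "not_female"
  under <- !no_enroll & !is.na(e$birth_year) &
    (start_year - e$birth_year) < 40
  reason[under & is.na(reason)] <- "under_40_at_study_start"
  multi_plan <- index_map$patient_id %in% multi
  reason[multi_plan & is.na(reason)] <- "multiple_plans"
  not_cont <- !no_enroll & (e$enroll_start > study_start | e$enroll_end < study_end)
  reason[not_cont & is.na(reason)] <- "not_continuously_enrolled"
  if ("death_date" %in% names(e)) {
    died <- !no_enroll & !is.na(e$death_date) & e$death_date <= study_end
    reason[died & is.na(reason)] <- "died_during_study"
  }

  # breast-cancer diagnosis in the 12 months preceding the index event
  ca <- claims[match_dx_prefix(claims$icd_codes, codes$cancer_dx_prefixes),
               c("enrollee_id", "service_date"), drop = FALSE]
  if (nrow(ca)) {
    idx_date <- index_map$index_date[match(ca$enrollee_id, index_map$patient_id)]
    pre <- !is.na(idx_date) & ca$service_date >= idx_date - 365 &
      ca$service_date < idx_date
    prior <- unique(ca$enrollee_id[pre])
    reason[index_map$patient_id %in% prior & is.na(reason)] <- "prior_breast_cancer"
  }

  keep <- is.na(reason)
  cohort <- data.frame(patient_id = index_map$patient_id[keep],
                       plan_id = e$plan_id[keep],
                       index_date = index_map$index_date[keep],
                       birth_year = e$birth_year[keep],
                       stringsAsFactors = FALSE)
  for (col in c("race_ethnicity", "region")) {
    if (col %in% names(e)) cohort[[col]] <- e[[col]][keep]
  }
  cohort$age_group <- as.character(
    cut(as.integer(format(cohort$index_date, "%Y")) - cohort$birth_year,
        breaks = c(39, 64, 74, 84, Inf),
        labels = c("40-64", "65-74", "75-84", "85+")))
  attr(cohort, "exclusions") <- data.frame(
    patient_id = index_map$patient_id[!keep],
    reason = reason[!keep], stringsAsFactors = FALSE)
  cohort
}

#' Build episodes of care
#'
#' For each cohort patient, the episode runs from the index screening
#' mammogram to \code{min(index + 365 days, first post-index breast-cancer
#' diagnosis claim)}.  Subsequent services are counted per category over the
#' half-open window \code{(index, end]} — the index claim itself never counts.
#' Biopsies are counted over the same window.  Out-of-pocket cost fields are
#' annual totals for the index year via \code{\link{compute_annual_oopc}}.
#'
#' @param cohort output of \code{\link{apply_inclusion_criteria}}.
#' @param claims claims table.
#' @param codes a \code{\link{code_config}}.
#' @param dedup if TRUE, same-day claims with the same CPT for a patient
#'   count once; default counts every claim line.
#' @return data.frame of episodes, one row per patient, with per-category
#'   counts, \code{any_subsequent}, termination data and OOPC totals.
#' @export
build_episodes <- function(cohort, claims, codes = code_config(),
                           dedup = FALSE) {
  cl <- claims[claims$enrollee_id %in% cohort$patient_id, , drop = FALSE]
  pid <- match(cl$enrollee_id, cohort$patient_id)
  idx <- cohort$index_date[pid]

  # episode end: first post-index cancer-dx claim within 365 d, else 365 d
  is_ca <- match_dx_prefix(cl$icd_codes, codes$cancer_dx_prefixes) &
    cl$service_date > idx & cl$service_date <= idx + 365
  end_int <- rep(NA_integer_, nrow(cohort))
  if (any(is_ca)) {
    first_ca <- tapply(as.integer(cl$service_date[is_ca]), pid[is_ca], min)
    end_int[as.integer(names(first_ca))] <- as.integer(first_ca)
  }
  window_end <- as.integer(cohort$index_date) + 365L
  termination <- ifelse(!is.na(end_int) & end_int <= window_end,
                        "cancer_dx", "window_365d")
  end_date <- as.Date(ifelse(termination == "cancer_dx", end_int, window_end),
                      origin = "1970-01-01")

  if (dedup) {
    cl_key <- paste(cl$enrollee_id, cl$service_date, cl$cpt_code)
    keep <- !duplicated(cl_key)
  } else keep <- rep(TRUE, nrow(cl))
  in_win <- keep & cl$service_date > idx & cl$service_date <= end_date[pid]

  count_cat <- function(code_set) {
    m <- in_win & cl$cpt_code %in% code_set
    out <- integer(nrow(cohort))
    if (any(m)) {
      tb <- table(pid[m])
      out[as.integer(names(tb))] <- as.integer(tb)
    }
    out
  }
  dm <- count_cat(codes$diagnostic_mammo_codes)
  us <- count_cat(codes$ultrasound_codes)
  mri <- count_cat(codes$mri_codes)
  bx <- count_cat(codes$biopsy_codes)

  index_year <- as.integer(format(cohort$index_date, "%Y"))
  oopc <- compute_annual_oopc(claims, cohort$patient_id, unique(index_year)[1],
                              codes = codes)

  data.frame(patient_id = cohort$patient_id,
             plan_id = cohort$plan_id,
             index_date = cohort$index_date,
             end_date = end_date,
             termination_reason = termination,
             diagnostic_mammo = dm, ultrasound = us, mri = mri, biopsy = bx,
             any_subsequent = (dm + us + mri + bx) > 0,
             oopc_all_medical = oopc$oopc_all_medical[match(cohort$patient_id,
                                                            oopc$patient_id)],
             oopc_breast_imaging = oopc$oopc_breast_imaging[match(cohort$patient_id,
                                                                  oopc$patient_id)],
             stringsAsFactors = FALSE)
}

#' Annual out-of-pocket cost totals per patient
#'
#' Sums copay + coinsurance + deductible over a patient's claims in a
#' calendar year; \code{oopc_breast_imaging} restricts to claims whose CPT is
#' in any breast-imaging or biopsy code set.
#'
#' @param claims claims table.
#' @param patient_ids patients to tabulate (zero totals when no claims).
#' @param year calendar year.
#' @param codes a \code{\link{code_config}}.
#' @return data.frame \code{patient_id}, \code{oopc_all_medical},
#'   \code{oopc_breast_imaging}.
#' @export
compute_annual_oopc <- function(claims, patient_ids, year,
                                codes = code_config()) {
  share <- claims$copay + claims$coinsurance + claims$deductible
  if (any(claims$copay < 0 | claims$coinsurance < 0 | claims$deductible < 0))
    stop_invalid("data quality: negative cost-share field")
  sel <- claims$enrollee_id %in% patient_ids &
    format(claims$service_date, "%Y") == as.character(year)
  breast_codes <- c(codes$screening_codes, codes$diagnostic_mammo_codes,
                    codes$ultrasound_codes, codes$mri_codes, codes$biopsy_codes)
  all_med <- tapply(share[sel], claims$enrollee_id[sel], sum)
  bsel <- sel & claims$cpt_code %in% breast_codes
  breast <- tapply(share[bsel], claims$enrollee_id[bsel], sum)
  out <- data.frame(patient_id = patient_ids, stringsAsFactors = FALSE)
  out$oopc_all_medical <- as.vector(all_med[out$patient_id])
  out$oopc_breast_imaging <- as.vector(breast[out$patient_id])
  out$oopc_all_medical[is.na(out$oopc_all_medical)] <- 0
  out$oopc_breast_imaging[is.na(out$oopc_breast_imaging)] <- 0
  out
}

#' Default Charlson condition map (ICD-10 prefixes, original weights)
#'
#' Standard Charlson categories keyed by ICD-10 code prefixes with the
#' classical weights (1 for most chronic conditions; 2 for hemiplegia,
#' moderate/severe renal disease, diabetes with complications, malignancy;
#' 3 for moderate/severe liver disease; 6 for metastatic solid tumour and
#' AIDS).  Ships as a sensible default; any prefix-to-weight map of the same
#' shape can be substituted.
#'
#' @return data.frame with \code{condition}, \code{prefix}, \code{weight}.
#' @export
charlson_default_map <- function() {
  spec <- list(
    myocardial_infarction = list(c("I21.", "I22.", "I25.2"), 1),
    congestive_heart_failure = list(c("I50."), 1),
    peripheral_vascular = list(c("I70.", "I71."), 1),
    cerebrovascular = list(c("I60.", "I61.", "I62.", "I63.", "I64",
                             "I65.", "I66.", "I67.", "G45.", "G46."), 1),
    dementia = list(c("F00.", "F01.", "F02.", "F03", "G30."), 1),
    chronic_pulmonary = list(c("J40", "J41.", "J42", "J43.", "J44.",
                               "J45.", "J46", "J47"), 1),
    rheumatic = list(c("M05.", "M06.", "M32.", "M33.", "M34."), 1),
    peptic_ulcer = list(c("K25.", "K26.", "K27.", "K28."), 1),
    mild_liver = list(c("K70.", "K73.", "K74.", "B18."), 1),
    diabetes = list(c("E10.", "E11.", "E13."), 1),
    diabetes_complications = list(c("E10.2", "E10.3", "E10.4", "E10.5",
                                    "E11.2", "E11.3", "E11.4", "E11.5"), 2),
    hemiplegia = list(c("G81.", "G82."), 2),
    renal = list(c("N18.", "N19", "N03.", "N05."), 2),
    malignancy = list(c("C0", "C1", "C2", "C3", "C4", "C5", "C6",
                        "C81.", "C82.", "C83.", "C84.", "C85.", "C91.",
                        "C92.", "C93.", "C94.", "C95.", "C96."), 2),
    moderate_severe_liver = list(c("K72.", "K76.6", "K76.7", "I85."), 3),
    metastatic = list(c("C77.", "C78.", "C79.", "C80."), 6),
    aids = list(c("B20", "B21", "B22", "B24"), 6))
  data.frame(
    condition = rep(names(spec), vapply(spec, function(s) length(s[[1]]), 1L)),
    prefix = unlist(lapply(spec, `[[`, 1), use.names = FALSE),
    weight = rep(vapply(spec, `[[`, numeric(1), 2),
                 vapply(spec, function(s) length(s[[1]]), 1L)),
    stringsAsFactors = FALSE)
}

#' Prospective Charlson comorbidity score from claims
#'
#' Scores each patient from diagnosis codes on claims in the lookback window
#' before (and excluding) the index date.  Each condition counts once however
#' many claims carry it; within a condition the maximum weight applies (so
#' e.g. complicated diabetes supersedes uncomplicated).  Scores are binned
#' into the conventional 0 / 1 / 2 / 3+ categories.
#'
#' @param claims claims table.
#' @param index_map data.frame \code{patient_id}, \code{index_date}.
#' @param lookback_days lookback window length (default 365).
#' @param map prefix-to-weight map as from \code{\link{charlson_default_map}}.
#' @return data.frame \code{patient_id}, \code{cci_score},
#'   \code{cci_category}.
#' @export
compute_charlson <- function(claims, index_map, lookback_days = 365,
                             map = charlson_default_map()) {
  if (is.null(map) || nrow(map) == 0L)
    stop_invalid("invalid config: empty Charlson code map")
  idx <- index_map$index_date[match(claims$enrollee_id, index_map$patient_id)]
  in_lb <- !is.na(idx) & claims$service_date < idx &
    claims$service_date >= idx - lookback_days
  cl <- claims[in_lb, c("enrollee_id", "icd_codes"), drop = FALSE]

  score <- stats::setNames(numeric(nrow(index_map)), index_map$patient_id)
  if (nrow(cl)) {
    # long format: one row per (claim, dx code)
    parts <- strsplit(cl$icd_codes, ";", fixed = TRUE)
    pid <- rep(cl$enrollee_id, lengths(parts))
    dx <- unlist(parts, use.names = FALSE)
    conds <- unique(map$condition)
    hits <- matrix(FALSE, nrow(index_map), length(conds),
                   dimnames = list(index_map$patient_id, conds))
    for (cond in conds) {
      sub <- map[map$condition == cond, , drop = FALSE]
      pat <- paste0("^(", paste(gsub("([.\\\\])", "\\\\\\1", sub$prefix),
                                collapse = "|"), ")")
      hit <- grepl(pat, dx)
      if (any(hit)) hits[unique(pid[hit]), cond] <- TRUE
    }
    # severity hierarchy: the severe form supersedes the mild one
    hier <- c(diabetes_complications = "diabetes",
              moderate_severe_liver = "mild_liver",
              metastatic = "malignancy")
    for (severe in intersect(names(hier), conds)) {
      mild <- hier[[severe]]
      if (mild %in% conds) hits[hits[, severe], mild] <- FALSE
    }
    w <- vapply(conds, function(cond)
      max(map$weight[map$condition == cond]), numeric(1))
    score[] <- as.vector(hits %*% w)
  }
  data.frame(patient_id = index_map$patient_id,
             cci_score = as.vector(score),
             cci_category = as.character(cci_bin(as.vector(score))),
             stringsAsFactors = FALSE)
}
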