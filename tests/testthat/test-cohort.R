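# Cohort construction: index events, inclusion rules, episode windows,
# Charlson scoring, OOPC tabulation.

test_that("index event is the earliest qualifying screening claim", {
  cl <- rbind(
    make_claims("A", service_date = c("2016-09-01", "2016-02-01"),
                cpt_code = "77057"),
    make_claims("B", service_date = "2015-06-01", cpt_code = "77057"),
    make_claims("C", service_date = "2016-05-01", cpt_code = "99213"))
  idx <- identify_index_events(cl)
  expect_equal(idx$patient_id, "A")
  expect_equal(idx$index_date, as.Date("2016-02-01"))
})

test_that("inclusion criteria exclude the specified patients", {
  en <- rbind(
    make_enrollment("ok"),
    make_enrollment("prior_ca"),
    make_enrollment("gap", enroll_end = "2017-06-30"),
    make_enrollment("young", birth_year = 1976),  # 39 at study start, 40 at index
    make_enrollment("male", sex = "M"),
    make_enrollment("nosex", sex = NA),
    make_enrollment("dead", death_date = "2017-10-01"))
  scr <- make_claims(en$enrollee_id, service_date = "2016-06-01",
                     cpt_code = "77057")
  ca <- make_claims("prior_ca", service_date = "2016-02-22",  # 100 d pre-index
                    icd_codes = "C50.1")
  idx <- identify_index_events(rbind(scr, ca))
  cohort <- apply_inclusion_criteria(en, rbind(scr, ca), idx)
  expect_equal(cohort$patient_id, "ok")
  ex <- attr(cohort, "exclusions")
  expect_setequal(ex$patient_id,
                  c("prior_ca", "gap", "young", "male", "nosex", "dead"))
  expect_equal(ex$reason[ex$patient_id == "prior_ca"], "prior_breast_cancer")
  expect_equal(ex$reason[ex$patient_id == "young"], "under_40_at_study_start")
  expect_equal(ex$reason[ex$patient_id == "nosex"], "missing_sex")
  expect_equal(ex$reason[ex$patient_id == "gap"], "not_continuously_enrolled")
})

test_that("a breast-cancer claim more than 12 months before index does not exclude", {
  en <- make_enrollment("A")
  cl <- rbind(make_claims("A", service_date = "2016-06-01", cpt_code = "77057"),
              make_claims("A", service_date = "2015-05-01", icd_codes = "C50.9"))
  idx <- identify_index_events(cl)
  cohort <- apply_inclusion_criteria(en, cl, idx)
  expect_equal(cohort$patient_id, "A")
})

test_that("episodes honour the 365-day window and cancer termination", {
  en <- rbind(make_enrollment("A"), make_enrollment("B"))
  cl <- rbind(
    make_claims("A", service_date = "2016-03-01", cpt_code = "77057"),
    make_claims("A", service_date = "2016-04-01", cpt_code = "G0204"),
    make_claims("A", service_date = "2016-05-01", cpt_code = "76641"),
    make_claims("A", service_date = "2016-06-01", icd_codes = "C50.911"),
    make_claims("A", service_date = "2016-07-01", cpt_code = "76641"),  # after dx
    make_claims("B", service_date = "2016-01-10", cpt_code = "77057"),
    make_claims("B", service_date = "2017-01-14", cpt_code = "76641"))  # day 370
  idx <- identify_index_events(cl)
  cohort <- apply_inclusion_criteria(en, cl, idx)
  ep <- build_episodes(cohort, cl)
  a <- ep[ep$patient_id == "A", ]
  expect_equal(a$end_date, as.Date("2016-06-01"))
  expect_equal(a$termination_reason, "cancer_dx")
  expect_equal(c(a$diagnostic_mammo, a$ultrasound, a$mri, a$biopsy),
               c(1L, 1L, 0L, 0L))
  expect_true(a$any_subsequent)
  b <- ep[ep$patient_id == "B", ]
  expect_equal(b$end_date, as.Date("2016-01-10") + 365)
  expect_equal(b$termination_reason, "window_365d")
  expect_false(b$any_subsequent)   # ultrasound at day 370 is out of window
})

test_that("the index claim itself never counts as a subsequent service", {
  # a diagnostic mammogram on the index date is outside the half-open window
  en <- make_enrollment("A")
  cl <- rbind(
    make_claims("A", service_date = "2016-03-01", cpt_code = "77057"),
    make_claims("A", service_date = "2016-03-01", cpt_code = "G0204"))
  cohort <- apply_inclusion_criteria(en, cl, identify_index_events(cl))
  ep <- build_episodes(cohort, cl)
  expect_equal(ep$diagnostic_mammo, 0L)
  expect_false(ep$any_subsequent)
})

test_that("episode construction is idempotent and window-monotone", {
  sim <- simulate_study(n_plans = 60, seed = 9)
  idx <- identify_index_events(sim$claims)
  cohort <- apply_inclusion_criteria(sim$enrollment, sim$claims, idx)
  ep1 <- build_episodes(cohort, sim$claims)
  ep2 <- build_episodes(cohort, sim$claims)
  expect_identical(ep1, ep2)
  expect_equal(ep1$any_subsequent,
               (ep1$diagnostic_mammo + ep1$ultrasound + ep1$mri + ep1$biopsy) > 0)
  expect_true(all(as.integer(ep1$end_date - ep1$index_date) <= 365))

  # shrinking the window by faking an earlier cancer claim can only reduce counts
  midx <- match(sim$claims$enrollee_id, cohort$patient_id)
  keep <- is.na(midx) | sim$claims$service_date <= cohort$index_date[midx] + 180
  ep_half <- build_episodes(cohort, sim$claims[keep, ])
  m <- match(ep_half$patient_id, ep1$patient_id)
  for (col in c("diagnostic_mammo", "ultrasound", "mri", "biopsy"))
    expect_true(all(ep_half[[col]] <= ep1[[col]][m]))
})

test_that("Charlson scoring counts distinct conditions once and bins correctly", {
  idx <- data.frame(patient_id = c("A", "B", "C"),
                    index_date = as.Date("2016-06-01"))
  cl <- rbind(
    # A: one weight-1 condition coded on 3 claims
    make_claims("A", service_date = c("2016-01-01", "2016-02-01", "2016-03-01"),
                icd_codes = "E11.9"),
    # B: weight 1 (COPD) + weight 2 (renal) = 3
    make_claims("B", service_date = c("2016-01-15", "2016-02-15"),
                icd_codes = c("J44.9", "N18.3")),
    # C: nothing in lookback (claim 2 years before)
    make_claims("C", service_date = "2014-05-01", icd_codes = "E11.9"))
  cci <- compute_charlson(cl, idx)
  expect_equal(cci$cci_score, c(1, 3, 0))
  expect_equal(cci$cci_category, c("1", "3+", "0"))
  expect_error(compute_charlson(cl, idx, map = NULL), "empty")
})

test_that("severe Charlson conditions supersede their mild form", {
  idx <- data.frame(patient_id = "A", index_date = as.Date("2016-06-01"))
  cl <- make_claims("A", service_date = "2016-01-01",
                    icd_codes = "E11.2;E11.9")   # complicated + plain diabetes
  expect_equal(compute_charlson(cl, idx)$cci_score, 2)
})

test_that("annual OOPC sums cost-share fields and flags negative values", {
  cl <- rbind(
    make_claims("A", service_date = "2016-02-01", copay = 20),
    make_claims("A", service_date = "2016-03-01", coinsurance = 30,
                deductible = 100),
    make_claims("A", service_date = "2017-03-01", copay = 999),  # other year
    make_claims("B", service_date = "2016-04-01", copay = 10))
  oopc <- compute_annual_oopc(cl, c("A", "B"), 2016)
  expect_equal(oopc$oopc_all_medical, c(150, 10))
  expect_equal(oopc$oopc_breast_imaging, c(0, 0))
  bad <- make_claims("A", service_date = "2016-01-01", copay = -5)
  expect_error(compute_annual_oopc(bad, "A", 2016), "negative")
})

test_that("synthetic cohort reproduces the ground-truth sidecar", {
  sim <- simulate_study(n_plans = 100, seed = 4)
  idx <- identify_index_events(sim$claims)
  cohort <- apply_inclusion_criteria(sim$enrollment, sim$claims, idx)
  expect_equal(nrow(cohort), sim$truth$n_eligible_cohort)
  expect_setequal(cohort$patient_id, sim$truth$cohort$patient_id)
  ep <- build_episodes(cohort, sim$claims)
  m <- match(ep$patient_id, sim$truth$cohort$patient_id)
  expect_equal(ep$diagnostic_mammo + ep$ultrasound + ep$mri + ep$biopsy,
               sim$truth$cohort$n_services[m])
  # testers' breast-imaging OOPC exceeds screening-only patients' (who pay 0)
  expect_gt(mean(ep$oopc_breast_imaging[ep$any_subsequent]),
            mean(ep$oopc_breast_imaging[!ep$any_subsequent]))
})
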