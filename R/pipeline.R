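# End-to-end pipeline: simulate -> build-cohort -> infer-plans -> fit-hurdle
# -> report, with one master seed, plain CSV/JSON intermediates and a hashed
# run manifest for provenance.

#' Pipeline run configuration
#'
#' Validates and fills a configuration for \code{\link{run_pipeline}}.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed; every stage derives a named substream from it.
#' @param n_plans,mixture,separation,mean_enrollees,params passed to
#'   \code{\link{simulate_study}} (ignored when \code{claims_path} is given).
#' @param claims_path,enrollment_path optional paths to existing claims /
#'   enrollment CSVs; when given, the simulate stage is skipped.
#' @param index_year index calendar year.
#' @param orientation k-means scaling orientation.
#' @param outcomes outcome columns to fit hurdle models for; any of
#'   \code{"all_imaging"}, \code{"diagnostic_mammo"}, \code{"ultrasound"},
#'   \code{"mri"}, \code{"biopsy"}.
#' @param smearing apply Duan smearing in marginal effects?
#' @param codes a \code{\link{code_config}}.
#' @return validated list of class \code{costshare_config}.
#' @export
pipeline_config <- function(out_dir, seed = 1, n_plans = 400,
                            mixture = plan_type_mixture(),
                            separation = 2,
                            mean_enrollees = c(balanced = 5.2, copay = 1.26,
                                               coinsurance = 8.3, deductible = 20),
                            params = default_outcome_params(),
                            claims_path = NULL, enrollment_path = NULL,
                            index_year = 2016,
                            orientation = c("as_printed", "standard"),
                            outcomes = "all_imaging",
                            smearing = TRUE,
                            codes = code_config()) {
  orientation <- match.arg(orientation)
  valid_out <- c("all_imaging", "diagnostic_mammo", "ultrasound", "mri", "biopsy")
  if (!all(outcomes %in% valid_out))
    stop_invalid("invalid config: unknown outcome(s): %s",
                 paste(setdiff(outcomes, valid_out), collapse = ", "))
  if (!is.null(claims_path) && !file.exists(claims_path))
    stop_invalid("invalid config: claims_path does not exist: %s", claims_path)
  if (!is.null(enrollment_path) && !file.exists(enrollment_path))
    stop_invalid("invalid config: enrollment_path does not exist: %s",
                 enrollment_path)
  if (xor(is.null(claims_path), is.null(enrollment_path)))
    stop_invalid("invalid config: claims_path and enrollment_path go together")
  structure(list(out_dir = out_dir, seed = seed, n_plans = n_plans,
                 mixture = mixture, separation = separation,
                 mean_enrollees = mean_enrollees, params = params,
                 claims_path = claims_path, enrollment_path = enrollment_path,
                 index_year = index_year, orientation = orientation,
                 outcomes = outcomes, smearing = smearing, codes = codes),
            class = "costshare_config")
}

read_claims_csv <- function(path) {
  cl <- utils::read.csv(path, colClasses = c(
    enrollee_id = "character", plan_id = "character", cpt_code = "character",
    icd_codes = "character"))
  cl$service_date <- as.Date(cl$service_date)
  cl
}

read_enrollment_csv <- function(path) {
  en <- utils::read.csv(path, colClasses = c(enrollee_id = "character",
                                             plan_id = "character"))
  en$enroll_start <- as.Date(en$enroll_start)
  en$enroll_end <- as.Date(en$enroll_end)
  if ("death_date" %in% names(en)) en$death_date <- as.Date(en$death_date)
  en
}

outcome_count <- function(episodes, outcome) {
  switch(outcome,
         all_imaging = episodes$diagnostic_mammo + episodes$ultrasound +
           episodes$mri + episodes$biopsy,
         episodes[[outcome]])
}

# Assemble the per-patient analysis table: episode outcome counts joined
# with covariates; plan_type levels ordered by OOPC rank so the reference is
# the lowest-OOPC type.
build_analysis_table <- function(episodes, cohort, cci, assignments,
                                 type_stats) {
  d <- episodes
  d$plan_type <- assignments$plan_type[match(d$plan_id, assignments$plan_id)]
  d$age_group <- cohort$age_group[match(d$patient_id, cohort$patient_id)]
  if ("race_ethnicity" %in% names(cohort))
    d$race_ethnicity <- cohort$race_ethnicity[match(d$patient_id,
                                                    cohort$patient_id)]
  if ("region" %in% names(cohort))
    d$region <- cohort$region[match(d$patient_id, cohort$patient_id)]
  d$cci_category <- cci$cci_category[match(d$patient_id, cci$patient_id)]
  type_order <- type_stats$plan_type[order(type_stats$oopc_rank)]
  d$plan_type <- factor(d$plan_type, levels = type_order)
  # regression uses collapsed age (40-64 / 65-74 / 75+); tables keep 4 groups
  d$age_group <- collapse_age_groups(d$age_group)
  if ("race_ethnicity" %in% names(d))
    d$race_ethnicity <- factor(d$race_ethnicity,
                               levels = .covariate_levels$race_ethnicity)
  d$cci_category <- factor(d$cci_category,
                           levels = .covariate_levels$cci_category)
  if ("region" %in% names(d)) d$region <- factor(d$region)
  d
}

# Pool factor levels with too few positive outcomes into the reference
# level: thin adjustment cells cannot support their own indicator in the
# count part and would make the observed information singular.
lump_sparse_levels <- function(f, pos, min_pos = 5) {
  f <- factor(f)
  npos <- table(f[pos])
  keep <- names(npos)[npos >= min_pos]
  ref <- levels(f)[1]
  out <- as.character(f)
  out[!out %in% keep] <- ref
  factor(out, levels = intersect(levels(f), unique(c(ref, keep))))
}

hurdle_formula <- function(d) {
  covs <- intersect(c("plan_type", "age_group", "race_ethnicity",
                      "cci_category", "region"), names(d))
  # drop covariates without at least two observed levels
  covs <- covs[vapply(covs, function(v)
    length(unique(d[[v]][!is.na(d[[v]])])) > 1, TRUE)]
  stats::as.formula(paste("outcome ~", paste(covs, collapse = " + ")))
}

stage_files <- function(out_dir, files) {
  data.frame(file = files,
             md5 = as.vector(tools::md5sum(file.path(out_dir, files))),
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate (unless claims are supplied),
#' build-cohort, infer-plans, fit-hurdle, report — writing each stage's
#' outputs as CSV/JSON under \code{config$out_dir} together with a manifest
#' (stage, outputs, md5 hashes, timings, seed).  Any stage failure halts
#' with the stage name in the error.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return the manifest, invisibly; also written as \code{manifest.json}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "costshare_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  results <- list()

  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    files <- tryCatch(fn(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest[[length(manifest) + 1]] <<- list(
      stage = name, seed = config$seed,
      outputs = stage_files(config$out_dir, files),
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
    invisible(NULL)
  }

  run_stage("simulate", function() {
    if (!is.null(config$claims_path)) {
      results$claims <<- read_claims_csv(config$claims_path)
      results$enrollment <<- read_enrollment_csv(config$enrollment_path)
      return(character())
    }
    sim <- simulate_study(n_plans = config$n_plans, mixture = config$mixture,
                          separation = config$separation,
                          mean_enrollees = config$mean_enrollees,
                          params = config$params,
                          index_year = config$index_year, seed = config$seed)
    results$claims <<- sim$claims
    results$enrollment <<- sim$enrollment
    results$truth <<- sim$truth
    utils::write.csv(sim$claims, file.path(config$out_dir, "claims.csv"),
                     row.names = FALSE)
    utils::write.csv(sim$enrollment, file.path(config$out_dir, "enrollment.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed,
           plans = sim$truth$plans,
           outcome_params = list(
             beta_logit = as.list(sim$truth$params$beta_logit),
             beta_count = as.list(sim$truth$params$beta_count),
             alpha = sim$truth$params$alpha),
           n_eligible_cohort = sim$truth$n_eligible_cohort),
      file.path(config$out_dir, "ground_truth.json"), auto_unbox = TRUE,
      digits = NA)
    c("claims.csv", "enrollment.csv", "ground_truth.json")
  })

  run_stage("build-cohort", function() {
    need <- c("enrollee_id", "plan_id", "service_date", "cpt_code",
              "icd_codes", "allowed_amount", "copay", "coinsurance",
              "deductible")
    miss <- setdiff(need, names(results$claims))
    if (length(miss))
      stop_invalid("claims table is missing column(s): %s",
                   paste(miss, collapse = ", "))
    idx <- identify_index_events(results$claims, config$codes,
                                 config$index_year)
    cohort <- apply_inclusion_criteria(
      results$enrollment, results$claims, idx, config$codes,
      study_start = as.Date(sprintf("%d-01-01", config$index_year - 1)),
      study_end = as.Date(sprintf("%d-12-31", config$index_year + 1)))
    episodes <- build_episodes(cohort, results$claims, config$codes)
    cci <- compute_charlson(results$claims,
                            cohort[, c("patient_id", "index_date")])
    results$cohort <<- cohort
    results$episodes <<- episodes
    results$cci <<- cci
    utils::write.csv(cohort, file.path(config$out_dir, "cohort.csv"),
                     row.names = FALSE)
    utils::write.csv(episodes, file.path(config$out_dir, "episodes.csv"),
                     row.names = FALSE)
    utils::write.csv(attr(cohort, "exclusions"),
                     file.path(config$out_dir, "exclusions.csv"),
                     row.names = FALSE)
    utils::write.csv(cci, file.path(config$out_dir, "charlson.csv"),
                     row.names = FALSE)
    c("cohort.csv", "episodes.csv", "exclusions.csv", "charlson.csv")
  })

  run_stage("infer-plans", function() {
    inf <- classify_plans(results$claims, results$enrollment,
                          seed = config$seed, orientation = config$orientation)
    results$inference <<- inf
    utils::write.csv(inf$triplets, file.path(config$out_dir, "plan_triplets.csv"),
                     row.names = FALSE)
    utils::write.csv(inf$assignments,
                     file.path(config$out_dir, "plan_assignments.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(centers = inf$model$centers, seed = inf$model$seed,
           iterations = inf$model$iterations,
           orientation = config$orientation,
           type_stats = inf$type_stats),
      file.path(config$out_dir, "cluster_model.json"), auto_unbox = TRUE,
      digits = NA)
    c("plan_triplets.csv", "plan_assignments.csv", "cluster_model.json")
  })

  run_stage("fit-hurdle", function() {
    d <- build_analysis_table(results$episodes, results$cohort, results$cci,
                              results$inference$assignments,
                              results$inference$type_stats)
    files <- character()
    results$fits <<- list()
    for (oc in config$outcomes) {
      d$outcome <- outcome_count(results$episodes, oc)
      for (v in intersect(c("age_group", "race_ethnicity", "cci_category",
                            "region"), names(d)))
        d[[v]] <- lump_sparse_levels(d[[v]], d$outcome > 0)
      fit <- hurdle_fit(hurdle_formula(d), d)
      ame <- marginal_effects(fit, "plan_type", smearing = config$smearing)
      results$fits[[oc]] <<- list(fit = fit, ame = ame)
      s <- summary(fit)
      co <- rbind(
        data.frame(part = "binary", term = rownames(s$part1), s$part1,
                   check.names = FALSE, row.names = NULL),
        data.frame(part = "count", term = rownames(s$part2), s$part2,
                   check.names = FALSE, row.names = NULL))
      f1 <- sprintf("hurdle_%s_coefficients.csv", oc)
      f2 <- sprintf("hurdle_%s_marginal_effects.csv", oc)
      f3 <- sprintf("hurdle_%s_fit.json", oc)
      utils::write.csv(co, file.path(config$out_dir, f1), row.names = FALSE)
      utils::write.csv(as.data.frame(ame), file.path(config$out_dir, f2),
                       row.names = FALSE)
      jsonlite::write_json(
        list(outcome = oc, n = fit$n, n_positive = fit$part2$n,
             loglik_part1 = fit$part1$loglik, loglik_part2 = fit$part2$loglik,
             alpha = fit$part2$alpha,
             converged = fit$part2$converged, seed = config$seed),
        file.path(config$out_dir, f3), auto_unbox = TRUE, digits = NA)
      files <- c(files, f1, f2, f3)
    }
    files
  })

  run_stage("report", function() {
    co <- results$cohort
    co$cci_category <- results$cci$cci_category[match(co$patient_id,
                                                      results$cci$patient_id)]
    t1 <- cohort_table(co, results$episodes)
    t2 <- plan_type_table(results$inference$assignments, results$episodes)
    t3 <- oopc_by_type_table(results$episodes, results$inference$assignments)
    t4 <- utilization_table(results$episodes, results$inference$assignments)
    write_table_csv(t1, file.path(config$out_dir, "table1_cohort.csv"))
    write_table_csv(t2, file.path(config$out_dir, "table2_plans.csv"))
    write_table_csv(t3, file.path(config$out_dir, "table3_oopc.csv"))
    write_table_csv(t4, file.path(config$out_dir, "table4_utilization.csv"))
    c("table1_cohort_counts.csv", "table1_cohort_oopc.csv",
      "table2_plans.csv", "table3_oopc.csv", "table4_utilization.csv")
  })

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out <- list(manifest = manifest, results = results)
  class(out) <- "costshare_run"
  invisible(out)
}

#' @export
print.costshare_run <- function(x, ...) {
  cat("Pipeline run:", length(x$manifest), "stages\n")
  for (m in x$manifest)
    cat(sprintf("  %-12s %5.1fs  %d output file(s)\n", m$stage, m$elapsed_s,
                nrow(m$outputs)))
  invisible(x)
}
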