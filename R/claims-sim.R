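# Synthetic administrative-claims generator with known ground truth.
#
# Real claims extracts of the kind this package analyses are proprietary, so
# every downstream stage (cohort construction, mechanism inference, hurdle
# modelling) is exercised against data simulated here, where plan designs,
# cohort membership and outcome parameters are all known exactly.

#' Default plan-type mixture
#'
#' Per-type plan fractions derived from the plan universe the synthetic data
#' emulate: 4736 balanced, 13310 copay-dominant, 1881 coinsurance-dominant
#' and 2901 deductible-dominant plans out of 22828.  Expressed as exact count
#' ratios so the fractions sum to 1 to machine precision (the same shares
#' quoted to three decimals, 0.207/0.583/0.082/0.127, sum to 0.999 and would
#' fail validation).
#'
#' @return named numeric vector of four fractions summing to 1.
#' @export
plan_type_mixture <- function() {
  c(balanced = 4736, copay = 13310, coinsurance = 1881,
    deductible = 2901) / 22828
}

#' Generate a universe of synthetic insurance plans
#'
#' Each plan has a true cost-sharing type and a triplet of mechanism-design
#' parameters (per-visit copay, coinsurance rate, annual deductible).  Plans
#' of a given type have the corresponding component dominant; "balanced"
#' plans have all three components non-trivial at intermediate levels.  The
#' \code{separation} factor shrinks the non-dominant (background) components,
#' so that at \code{separation >= 2} the plan types form well-separated
#' clusters in scaled triplet space.
#'
#' @param n_plans number of plans (at least 4).
#' @param mixture named fractions per type, summing to 1, in the order
#'   balanced, copay, coinsurance, deductible.  Counts are apportioned by
#'   largest remainder, so the realised per-type counts match the mixture up
#'   to rounding.
#' @param separation scale factor \eqn{\ge 1} dividing background component
#'   magnitudes; larger values separate the plan types more cleanly.
#' @param mean_enrollees mean number of enrollees per plan; a scalar or a
#'   named per-type vector.  Realised counts are \code{1 + Poisson(mean - 1)}.
#' @param seed integer seed.
#' @return data.frame with columns \code{plan_id}, \code{true_type},
#'   \code{copay_amount}, \code{coinsurance_rate}, \code{annual_deductible},
#'   \code{n_enrollees}.
#' @export
generate_plans <- function(n_plans,
                           mixture = plan_type_mixture(),
                           separation = 2,
                           mean_enrollees = 4,
                           seed = 1) {
  if (n_plans < 4) stop_invalid("n_plans must be at least 4 (one per type)")
  if (abs(sum(mixture) - 1) > 1e-9)
    stop_invalid("invalid config: mixture fractions must sum to 1 (got %.12f)",
                 sum(mixture))
  if (separation < 1) stop_invalid("invalid config: separation must be >= 1")
  if (is.null(names(mixture))) names(mixture) <- plan_type_levels
  mixture <- mixture[plan_type_levels]
  if (anyNA(mixture)) stop_invalid("mixture must be named by plan type")

  # largest-remainder apportionment; deterministic tie-break by type order
  raw <- n_plans * mixture
  cnt <- floor(raw)
  short <- n_plans - sum(cnt)
  if (short > 0) {
    ord <- order(-(raw - cnt), seq_along(raw))
    cnt[ord[seq_len(short)]] <- cnt[ord[seq_len(short)]] + 1
  }

  set.seed(substream_seed(seed, "plans"))
  types <- rep(plan_type_levels, times = cnt)
  n <- length(types)

  # Dominant components sit in a narrow high band, balanced plans in a
  # middle band, background components near zero (shrunk by `separation`).
  # Annual deductibles are set low enough that typical annual spending
  # exhausts them, so the cap is observable from claims.
  copay <- ifelse(types == "copay", runif(n, 55, 65),
            ifelse(types == "balanced", runif(n, 8, 12),
                   runif(n, 0, 8) / separation))
  coins <- ifelse(types == "coinsurance", runif(n, 0.20, 0.28),
            ifelse(types == "balanced", runif(n, 0.05, 0.08),
                   runif(n, 0, 0.04) / separation))
  deduct <- ifelse(types == "deductible", runif(n, 1000, 1400),
             ifelse(types == "balanced", runif(n, 280, 380),
                    runif(n, 0, 200) / separation))

  if (length(mean_enrollees) == 1L) {
    mu_enr <- rep(mean_enrollees, n)
  } else {
    mu_enr <- mean_enrollees[types]
    if (anyNA(mu_enr)) stop_invalid("mean_enrollees must be named by plan type")
  }
  n_enr <- 1L + stats::rpois(n, pmax(mu_enr - 1, 0))

  data.frame(plan_id = sprintf("P%05d", seq_len(n)),
             true_type = types,
             copay_amount = round(copay, 2),
             coinsurance_rate = round(coins, 4),
             annual_deductible = round(deduct, 2),
             n_enrollees = n_enr,
             stringsAsFactors = FALSE)
}

#' Apply each plan's cost-sharing mechanism to a claims skeleton
#'
#' Claims are processed in service-date order per enrollee with an annual
#' deductible accumulator (the deductible resets each calendar year):
#' deductible portion = min(remaining deductible, allowed amount);
#' coinsurance = rate x (allowed - deductible portion); copay = min(copay
#' amount, allowed - deductible - coinsurance).  Hence copay + coinsurance +
#' deductible never exceeds the allowed amount.  Screening mammogram claims
#' carry zero patient cost-sharing and do not advance the accumulator.
#'
#' @param claims data.frame with \code{enrollee_id}, \code{plan_id},
#'   \code{service_date}, \code{cpt_code}, \code{allowed_amount}.
#' @param plans plan table as from \code{\link{generate_plans}}.
#' @param screening_codes CPT codes exempt from cost-sharing.
#' @return the claims sorted by enrollee and date with \code{copay},
#'   \code{coinsurance}, \code{deductible} columns filled in.
#' @export
apply_cost_sharing <- function(claims, plans,
                               screening_codes = c("G0202", "77057", "77063")) {
  ord <- order(claims$enrollee_id, claims$service_date)
  cl <- claims[ord, , drop = FALSE]
  idx <- match(cl$plan_id, plans$plan_id)
  if (anyNA(idx)) stop_invalid("claim references unknown plan_id")
  cap <- plans$annual_deductible[idx]
  rate <- plans$coinsurance_rate[idx]
  cpay <- plans$copay_amount[idx]

  scr <- cl$cpt_code %in% screening_codes
  yr <- as.integer(format(cl$service_date, "%Y"))
  key <- paste(cl$enrollee_id, yr)

  allowed_acc <- ifelse(scr, 0, cl$allowed_amount)
  cum <- stats::ave(allowed_acc, key, FUN = cumsum)
  before <- cum - allowed_acc
  ded <- pmin(allowed_acc, pmax(0, cap - before))
  coins <- rate * (cl$allowed_amount - ded)
  copay <- pmin(cpay, cl$allowed_amount - ded - coins)
  copay <- pmax(copay, 0)

  cl$deductible <- round(ifelse(scr, 0, ded), 2)
  cl$coinsurance <- round(ifelse(scr, 0, coins), 2)
  cl$copay <- round(ifelse(scr, 0, copay), 2)
  rownames(cl) <- NULL
  cl
}

# Background (non-breast) CPT and benign diagnosis codes used for filler
# claims.  Deliberately outside every breast-imaging code set and outside the
# Charlson prefix map.
.background_cpt <- c("99213", "99214", "99203", "80053", "36415", "71046")
.benign_icd <- c("Z00.00", "M54.5", "J06.9", "K21.9", "I10", "E78.5")

#' Generate enrollment and background medical claims for a plan universe
#'
#' Creates one enrollment row per enrollee (continuously enrolled across the
#' study years) and a stream of routine medical claims whose out-of-pocket
#' decomposition follows each plan's true mechanism via an annual deductible
#' accumulator.  Allowed amounts are drawn log-normal (claims costs are
#' right-skewed).
#'
#' @param plans data.frame from \code{\link{generate_plans}}.
#' @param lambda_claims mean background claims per enrollee per year.
#' @param years calendar years covered.
#' @param allowed_meanlog,allowed_sdlog log-normal parameters of allowed
#'   amounts.
#' @param seed integer seed.
#' @return list with \code{claims} and \code{enrollment} data.frames using
#'   the package's standard schemas.
#' @export
generate_claims <- function(plans, lambda_claims = 8, years = 2015:2017,
                            allowed_meanlog = log(150), allowed_sdlog = 0.8,
                            seed = 1) {
  if (nrow(plans) == 0L) stop_invalid("plans must be non-empty")
  set.seed(substream_seed(seed, "claims"))

  n_enr <- plans$n_enrollees
  enrollment <- data.frame(
    enrollee_id = sprintf("E%07d", seq_len(sum(n_enr))),
    plan_id = rep(plans$plan_id, times = n_enr),
    sex = "F",
    birth_year = sample(1951:1974, sum(n_enr), replace = TRUE),
    enroll_start = as.Date(sprintf("%d-01-01", min(years))),
    enroll_end = as.Date(sprintf("%d-12-31", max(years))),
    race_ethnicity = "Unknown",
    region = paste0("R", sample.int(5, sum(n_enr), replace = TRUE)),
    death_date = as.Date(NA),
    stringsAsFactors = FALSE)

  ey <- expand.grid(enrollee_id = enrollment$enrollee_id, year = years,
                    stringsAsFactors = FALSE)
  n_cl <- stats::rpois(nrow(ey), lambda_claims)
  rows <- rep(seq_len(nrow(ey)), times = n_cl)
  ntot <- length(rows)
  day <- sample.int(365, ntot, replace = TRUE)
  claims <- data.frame(
    enrollee_id = ey$enrollee_id[rows],
    plan_id = enrollment$plan_id[match(ey$enrollee_id[rows],
                                       enrollment$enrollee_id)],
    service_date = as.Date(sprintf("%d-01-01", ey$year[rows])) + (day - 1L),
    cpt_code = sample(.background_cpt, ntot, replace = TRUE),
    icd_codes = sample(.benign_icd, ntot, replace = TRUE),
    allowed_amount = round(stats::rlnorm(ntot, allowed_meanlog,
                                         allowed_sdlog), 2),
    stringsAsFactors = FALSE)
  claims <- apply_cost_sharing(claims, plans)
  list(claims = claims, enrollment = enrollment)
}

#' Draw from a zero-truncated negative binomial (NB2) distribution
#'
#' Inverse-CDF sampling: a uniform draw on \eqn{(F(0), 1)} is passed through
#' the untruncated NB quantile function, so every draw is \eqn{\ge 1}.
#'
#' @param n number of draws.
#' @param mu untruncated NB mean (recycled).
#' @param alpha NB2 dispersion (> 0), variance \eqn{\mu + \alpha \mu^2}.
#' @export
rztnb <- function(n, mu, alpha) {
  if (any(alpha <= 0)) stop_invalid("invalid config: alpha must be > 0")
  size <- 1 / alpha
  f0 <- stats::pnbinom(0, size = size, mu = mu)
  u <- stats::runif(n, f0, 1)
  stats::qnbinom(pmin(u, 1 - 1e-16), size = size, mu = mu)
}

#' Default outcome-generating parameters for the synthetic study
#'
#' Houses the data-generating parameters of the two-part hurdle process:
#' part-1 logit coefficients for whether any subsequent test occurs, part-2
#' log-mean coefficients for the number of services among testers, and the
#' NB2 dispersion.  Defaults emulate the study conditions: a subsequent
#' testing rate around 11% (highest in the reference coinsurance-dominant
#' plans), a mean of roughly 1.9 services among testers, and small negative
#' plan-type effects on the count scale.
#'
#' @param n_regions number of region levels (default 5).
#' @return list with \code{formula}, \code{beta_logit}, \code{beta_count},
#'   \code{alpha}.
#' @export
default_outcome_params <- function(n_regions = 5) {
  regions <- paste0("R", seq_len(n_regions))
  reg_eff <- rep_len(c(0.05, -0.05, 0.02, -0.02), n_regions - 1)
  names(reg_eff) <- paste0("region", regions[-1])
  beta_logit <- c(
    "(Intercept)" = stats::qlogis(0.121),
    plan_typebalanced = -0.16, plan_typecopay = -0.098,
    plan_typedeductible = -0.108,
    `age_group65-74` = -0.25, `age_group75-84` = -0.25, `age_group85+` = -0.25,
    race_ethnicityAsian = 0.03, race_ethnicityBlack = 0.00,
    race_ethnicityHispanic = 0.14, race_ethnicityUnknown = 0.07,
    cci_category1 = -0.06, cci_category2 = -0.05, `cci_category3+` = 0.00,
    reg_eff)
  beta_count <- c(
    "(Intercept)" = log(1.45),
    plan_typebalanced = -0.0064, plan_typecopay = -0.0219,
    plan_typedeductible = -0.0146,
    `age_group65-74` = -0.02, `age_group75-84` = -0.03, `age_group85+` = -0.03,
    race_ethnicityAsian = 0.01, race_ethnicityBlack = 0.00,
    race_ethnicityHispanic = 0.02, race_ethnicityUnknown = 0.00,
    cci_category1 = 0.01, cci_category2 = 0.02, `cci_category3+` = 0.02,
    0.2 * reg_eff)
  list(formula = ~ plan_type + age_group + race_ethnicity + cci_category + region,
       beta_logit = beta_logit, beta_count = beta_count, alpha = 0.1)
}

# Factor levels used throughout; reference level first.
.covariate_levels <- list(
  plan_type = c("coinsurance", "balanced", "copay", "deductible"),
  age_group = c("40-64", "65-74", "75-84", "85+"),
  race_ethnicity = c("White", "Asian", "Black", "Hispanic", "Unknown"),
  cci_category = c("0", "1", "2", "3+"))

#' Collapse age groups for regression use
#'
#' Descriptive tables stratify age as 40-64 / 65-74 / 75-84 / 85+, but the
#' two oldest strata are far too thin to support separate indicators in a
#' screening population (almost everyone is 40-64), so the regression
#' adjustment uses 40-64 / 65-74 / 75+.
#'
#' @param x character or factor of four-level age groups.
#' @return factor with levels \code{40-64}, \code{65-74}, \code{75+}.
#' @export
collapse_age_groups <- function(x) {
  x <- as.character(x)
  x[x %in% c("75-84", "85+")] <- "75+"
  factor(x, levels = c("40-64", "65-74", "75+"))
}

# Coerce covariate columns of a cohort table to the canonical factor levels.
as_design_factors <- function(cohort, n_regions = NULL) {
  for (nm in names(.covariate_levels)) {
    if (nm %in% names(cohort))
      cohort[[nm]] <- factor(as.character(cohort[[nm]]),
                             levels = .covariate_levels[[nm]])
  }
  if ("region" %in% names(cohort)) {
    lev <- if (is.null(n_regions)) sort(unique(as.character(cohort$region)))
           else paste0("R", seq_len(n_regions))
    cohort$region <- factor(as.character(cohort$region), levels = lev)
  }
  cohort
}

#' Generate hurdle-process outcomes for a cohort with known parameters
#'
#' Draws, for each patient, an indicator of any subsequent test from a
#' Bernoulli with logit-linear probability, then a positive service count
#' from a zero-truncated NB2 with log-linear mean.  Counts are \eqn{\ge 1}
#' exactly when the indicator is 1.
#'
#' @param cohort data.frame with the covariate columns referenced by
#'   \code{params$formula}.
#' @param params list as from \code{\link{default_outcome_params}}.
#' @param seed integer seed.
#' @return \code{cohort} with \code{any_test} (0/1) and \code{n_services}
#'   columns appended.
#' @export
generate_outcomes <- function(cohort, params = default_outcome_params(),
                              seed = 1) {
  if (params$alpha <= 0) stop_invalid("invalid config: alpha must be > 0")
  cohort <- as_design_factors(cohort)
  X <- stats::model.matrix(params$formula, cohort)
  # unobserved factor levels give all-zero columns; they contribute nothing
  # to the linear predictor, so rank is checked on the populated columns
  pop <- colSums(abs(X)) > 0
  if (qr(X[, pop, drop = FALSE])$rank < sum(pop))
    stop_invalid("design matrix is rank deficient")
  miss <- setdiff(colnames(X), names(params$beta_logit))
  if (length(miss))
    stop_invalid("beta_logit missing coefficients: %s",
                 paste(miss, collapse = ", "))
  bl <- params$beta_logit[colnames(X)]
  bc <- params$beta_count[colnames(X)]
  if (anyNA(bc)) stop_invalid("beta_count does not cover the design columns")

  set.seed(substream_seed(seed, "outcomes"))
  p <- stats::plogis(drop(X %*% bl))
  ind <- stats::rbinom(nrow(X), 1, p)
  mu <- exp(drop(X %*% bc))
  y <- integer(nrow(X))
  pos <- ind == 1L
  y[pos] <- rztnb(sum(pos), mu[pos], params$alpha)
  cohort$any_test <- ind
  cohort$n_services <- y
  cohort
}

# Charlson conditions planted in synthetic patients: (icd code, weight,
# per-patient probability).  Codes chosen to hit distinct categories of the
# default Charlson map.
.planted_conditions <- data.frame(
  icd = c("E11.9", "J44.9", "I50.9", "K70.3", "N18.3"),
  weight = c(1, 1, 1, 1, 2),
  prob = c(0.07, 0.04, 0.008, 0.008, 0.012),
  stringsAsFactors = FALSE)

cci_bin <- function(score) {
  cut(score, breaks = c(-Inf, 0, 1, 2, Inf), labels = c("0", "1", "2", "3+"))
}

#' Simulate a complete synthetic screening-mammography study
#'
#' End-to-end generator: a plan universe, enrollment, background medical
#' claims, screening mammograms in the index year (with zero patient
#' cost-sharing), planted comorbidity claims in the year before each index,
#' prior and post-index breast-cancer diagnoses, and subsequent diagnostic
#' services (diagnostic mammography, ultrasound, MRI, biopsy) drawn from the
#' two-part hurdle process.  A ground-truth sidecar records the plan specs,
#' outcome parameters, expected cohort and per-patient true counts, so every
#' downstream stage can be checked exactly.
#'
#' @param n_plans number of plans.
#' @param mixture plan-type mixture (see \code{\link{generate_plans}}).
#' @param separation plan-type separation factor.
#' @param mean_enrollees named per-type mean enrollees per plan; the default
#'   reproduces the skew by which deductible-dominant plans hold about half
#'   of all patients while copay-dominant plans are numerous but tiny.
#' @param params outcome parameters (see \code{\link{default_outcome_params}}).
#' @param screen_prob probability an eligible woman has a screening mammogram
#'   in the index year.
#' @param index_year index calendar year (study period is the year before
#'   through the year after).
#' @param p_prior_cancer probability a screened woman has a breast-cancer
#'   diagnosis claim in the 12 months before her index (excluded downstream).
#' @param p_post_cancer probability of a post-index breast-cancer diagnosis
#'   terminating the episode early.
#' @param category_probs multinomial split of subsequent services over
#'   diagnostic mammography, ultrasound, MRI, biopsy.
#' @param lambda_claims background claims per enrollee-year.
#' @param seed master seed; all stages derive named substreams from it.
#' @return list with \code{claims}, \code{enrollment}, and a \code{truth}
#'   sidecar list.
#' @export
simulate_study <- function(n_plans = 400,
                           mixture = plan_type_mixture(),
                           separation = 2,
                           mean_enrollees = c(balanced = 5.2, copay = 1.26,
                                              coinsurance = 8.3, deductible = 20),
                           params = default_outcome_params(),
                           screen_prob = 0.7,
                           index_year = 2016,
                           p_prior_cancer = 0.01,
                           p_post_cancer = 0.015,
                           category_probs = c(diagnostic_mammo = 0.45,
                                              ultrasound = 0.46,
                                              mri = 0.05, biopsy = 0.04),
                           lambda_claims = 8,
                           seed = 1) {
  plans <- generate_plans(n_plans, mixture, separation, mean_enrollees,
                          seed = substream_seed(seed, "study-plans"))
  base <- generate_claims(plans, lambda_claims = lambda_claims,
                          years = (index_year - 1):(index_year + 1),
                          seed = substream_seed(seed, "study-claims"))
  enrollment <- base$enrollment
  n <- nrow(enrollment)
  study_start <- as.Date(sprintf("%d-01-01", index_year - 1))
  study_end <- as.Date(sprintf("%d-12-31", index_year + 1))

  set.seed(substream_seed(seed, "study-people"))
  # demographics: age-group shares reflect a commercially insured screening
  # population dominated by ages 40-64
  ag <- sample(.covariate_levels$age_group, n, replace = TRUE,
               prob = c(0.953, 0.045, 0.0019, 0.0001))
  birth_lo <- c(`40-64` = index_year - 1 - 64, `65-74` = index_year - 1 - 74,
                `75-84` = index_year - 1 - 84, `85+` = index_year - 1 - 95)
  birth_hi <- c(`40-64` = index_year - 1 - 40, `65-74` = index_year - 1 - 65,
                `75-84` = index_year - 1 - 75, `85+` = index_year - 1 - 85)
  by <- birth_lo[ag] + floor(stats::runif(n) * (birth_hi[ag] - birth_lo[ag] + 1))
  enrollment$birth_year <- as.integer(by)
  enrollment$race_ethnicity <- sample(.covariate_levels$race_ethnicity, n,
                                      replace = TRUE,
                                      prob = c(0.713, 0.036, 0.073, 0.071, 0.107))

  # small planted fractions that the inclusion rules must remove
  male <- stats::runif(n) < 0.01
  enrollment$sex[male] <- "M"
  young <- !male & stats::runif(n) < 0.01
  enrollment$birth_year[young] <- index_year - 1 - 35   # under 40 at study start
  gap <- stats::runif(n) < 0.005
  enrollment$enroll_end[gap] <- as.Date(sprintf("%d-12-31", index_year))
  dead <- !gap & stats::runif(n) < 0.005
  enrollment$death_date[dead] <- as.Date(sprintf("%d-06-15", index_year + 1))

  eligible <- enrollment$sex == "F" &
    (as.integer(format(study_start, "%Y")) - enrollment$birth_year) >= 40 &
    enrollment$enroll_start <= study_start & enrollment$enroll_end >= study_end &
    (is.na(enrollment$death_date) | enrollment$death_date > study_end)

  screened <- enrollment$sex == "F" & stats::runif(n) < screen_prob
  idx_day <- sample.int(364, n, replace = TRUE)
  index_date <- as.Date(sprintf("%d-01-01", index_year)) + (idx_day - 1L)

  scr_ids <- which(screened)
  dup <- scr_ids[stats::runif(length(scr_ids)) < 0.05 &
                 index_date[scr_ids] < as.Date(sprintf("%d-11-30", index_year))]
  screening_claims <- data.frame(
    enrollee_id = c(enrollment$enrollee_id[scr_ids], enrollment$enrollee_id[dup]),
    plan_id = c(enrollment$plan_id[scr_ids], enrollment$plan_id[dup]),
    service_date = c(index_date[scr_ids], index_date[dup] + 30L),
    cpt_code = "77057",
    icd_codes = "Z12.31",
    allowed_amount = round(stats::rlnorm(length(scr_ids) + length(dup),
                                         log(140), 0.2), 2),
    stringsAsFactors = FALSE)

  prior_ca <- screened & stats::runif(n) < p_prior_cancer
  pc_ids <- which(prior_ca)
  prior_claims <- if (length(pc_ids)) data.frame(
    enrollee_id = enrollment$enrollee_id[pc_ids],
    plan_id = enrollment$plan_id[pc_ids],
    service_date = index_date[pc_ids] - sample(30:300, length(pc_ids),
                                               replace = TRUE),
    cpt_code = "99214", icd_codes = "C50.911",
    allowed_amount = round(stats::rlnorm(length(pc_ids), log(200), 0.4), 2),
    stringsAsFactors = FALSE) else NULL

  in_cohort <- screened & eligible & !prior_ca
  co_ids <- which(in_cohort)
  nc <- length(co_ids)

  # planted Charlson conditions, coded once in the pre-index lookback year
  set.seed(substream_seed(seed, "study-cci"))
  cond_draw <- matrix(stats::runif(nc * nrow(.planted_conditions)), nrow = nc) <
    matrix(.planted_conditions$prob, nc, nrow(.planted_conditions), byrow = TRUE)
  cci_score <- as.vector(cond_draw %*% .planted_conditions$weight)
  cond_rows <- which(cond_draw, arr.ind = TRUE)
  cond_claims <- if (nrow(cond_rows)) data.frame(
    enrollee_id = enrollment$enrollee_id[co_ids[cond_rows[, 1]]],
    plan_id = enrollment$plan_id[co_ids[cond_rows[, 1]]],
    service_date = index_date[co_ids[cond_rows[, 1]]] -
      sample(10:360, nrow(cond_rows), replace = TRUE),
    cpt_code = "99214",
    icd_codes = .planted_conditions$icd[cond_rows[, 2]],
    allowed_amount = round(stats::rlnorm(nrow(cond_rows), log(180), 0.4), 2),
    stringsAsFactors = FALSE) else NULL

  cohort <- data.frame(
    patient_id = enrollment$enrollee_id[co_ids],
    plan_id = enrollment$plan_id[co_ids],
    plan_type = plans$true_type[match(enrollment$plan_id[co_ids], plans$plan_id)],
    index_date = index_date[co_ids],
    age_group = as.character(cut(index_year - enrollment$birth_year[co_ids],
                                 breaks = c(39, 64, 74, 84, Inf),
                                 labels = .covariate_levels$age_group)),
    race_ethnicity = enrollment$race_ethnicity[co_ids],
    cci_category = as.character(cci_bin(cci_score)),
    region = enrollment$region[co_ids],
    stringsAsFactors = FALSE)
  cohort <- generate_outcomes(cohort, params,
                              seed = substream_seed(seed, "study-outcomes"))

  # post-index cancer terminates the episode; subsequent services are placed
  # before the cancer date so planted counts remain the episode counts
  set.seed(substream_seed(seed, "study-services"))
  post_ca <- stats::runif(nc) < p_post_cancer
  cancer_day <- ifelse(post_ca, sample(60:364, nc, replace = TRUE), NA)
  cohort$cancer_date <- cohort$index_date + cancer_day

  svc_n <- cohort$n_services
  svc_rows <- rep(seq_len(nc), times = svc_n)
  ntot <- length(svc_rows)
  svc_claims <- NULL
  if (ntot) {
    cat_names <- names(category_probs)
    cat_idx <- sample.int(length(category_probs), ntot, replace = TRUE,
                          prob = category_probs)
    last_day <- ifelse(is.na(cancer_day), 365, pmax(cancer_day - 1, 1))
    day_off <- 1L + floor(stats::runif(ntot) * last_day[svc_rows])
    cpt_by_cat <- list(diagnostic_mammo = c("G0204", "G0206"),
                       ultrasound = c("76641", "76642"),
                       mri = "77059",
                       biopsy = c("19081", "19083", "19085"))
    amt_meanlog <- c(diagnostic_mammo = log(250), ultrasound = log(150),
                     mri = log(900), biopsy = log(700))
    cpt <- character(ntot)
    for (k in seq_along(cat_names)) {
      m <- cat_idx == k
      cpt[m] <- sample(cpt_by_cat[[cat_names[k]]], sum(m), replace = TRUE)
    }
    svc_claims <- data.frame(
      enrollee_id = cohort$patient_id[svc_rows],
      plan_id = cohort$plan_id[svc_rows],
      service_date = cohort$index_date[svc_rows] + day_off,
      cpt_code = cpt,
      icd_codes = "R92.8",
      allowed_amount = round(stats::rlnorm(ntot,
                                           amt_meanlog[cat_names[cat_idx]],
                                           0.4), 2),
      stringsAsFactors = FALSE)
    truth_counts <- matrix(tabulate((cat_idx - 1L) * nc + svc_rows,
                                    nbins = nc * length(category_probs)),
                           nrow = nc)
  } else {
    truth_counts <- matrix(0L, nc, length(category_probs))
  }
  colnames(truth_counts) <- names(category_probs)

  ca_ids <- which(post_ca)
  cancer_claims <- if (length(ca_ids)) data.frame(
    enrollee_id = cohort$patient_id[ca_ids],
    plan_id = cohort$plan_id[ca_ids],
    service_date = cohort$cancer_date[ca_ids],
    cpt_code = "99214", icd_codes = "C50.911",
    allowed_amount = round(stats::rlnorm(length(ca_ids), log(250), 0.4), 2),
    stringsAsFactors = FALSE) else NULL

  skeleton <- rbind(base$claims[, c("enrollee_id", "plan_id", "service_date",
                                    "cpt_code", "icd_codes", "allowed_amount")],
                    screening_claims, prior_claims, cond_claims, svc_claims,
                    cancer_claims)
  claims <- apply_cost_sharing(skeleton, plans)

  truth <- list(
    plans = plans, params = params, seed = seed,
    cohort = cbind(cohort, as.data.frame(truth_counts)),
    n_eligible_cohort = nc,
    excluded = data.frame(
      enrollee_id = enrollment$enrollee_id[screened & (!eligible | prior_ca)],
      reason = ifelse(prior_ca[screened & (!eligible | prior_ca)],
                      "prior_cancer", "ineligible"),
      stringsAsFactors = FALSE))
  list(claims = claims, enrollment = enrollment, truth = truth)
}
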