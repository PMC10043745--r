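# Synthetic claims generator: plan universe, cost-sharing decomposition,
# hurdle outcome draws.

test_that("plan mixture is apportioned by largest remainder", {
  p <- generate_plans(100, mixture = c(balanced = .25, copay = .25,
                                       coinsurance = .25, deductible = .25),
                      seed = 1)
  expect_equal(unname(as.integer(table(p$true_type))), rep(25L, 4))

  p2 <- generate_plans(100, seed = 1)   # default: study plan-type shares
  cnt <- table(p2$true_type)
  expect_equal(as.integer(cnt[c("balanced", "copay", "coinsurance",
                                "deductible")]), c(21L, 58L, 8L, 13L))

  expect_error(generate_plans(100, mixture = c(.207, .583, .082, .127)),
               "sum to 1")
  expect_error(generate_plans(3), "at least 4")
})

test_that("high separation yields pairwise well-separated scaled triplets", {
  p <- generate_plans(4, mixture = c(.25, .25, .25, .25), separation = 10,
                      seed = 5)
  # scale the plan design parameters themselves
  tr <- data.frame(plan_id = p$plan_id, mode_copay = p$copay_amount,
                   mode_coinsurance_rate = p$coinsurance_rate,
                   max_deductible = p$annual_deductible)
  sc <- scale_triplets(tr, "standard")
  m <- as.matrix(sc[, -1])
  d <- as.matrix(stats::dist(m))
  expect_true(all(d[upper.tri(d)] > 0.5))
})

test_that("cost decomposition respects the deductible accumulator", {
  plans <- data.frame(plan_id = "P1", true_type = "deductible",
                      copay_amount = 0, coinsurance_rate = 0.2,
                      annual_deductible = 500, n_enrollees = 1)
  cl <- make_claims("E1", "P1",
                    c("2016-01-10", "2016-02-10", "2016-03-10", "2017-01-05"),
                    allowed_amount = c(300, 300, 150, 100))
  out <- apply_cost_sharing(cl, plans)
  # first claim: all 300 to deductible, 200 remaining
  expect_equal(out$deductible, c(300, 200, 0, 100))
  # coinsurance applies to the remainder after the deductible portion
  expect_equal(out$coinsurance, 0.2 * (out$allowed_amount - out$deductible))
  # accumulator resets in the new calendar year
  expect_equal(out$deductible[out$service_date == as.Date("2017-01-05")], 100)
})

test_that("coinsurance applies in full once the deductible is met", {
  plans <- data.frame(plan_id = "P1", true_type = "coinsurance",
                      copay_amount = 0, coinsurance_rate = 0.2,
                      annual_deductible = 0, n_enrollees = 1)
  out <- apply_cost_sharing(make_claims("E1", "P1", "2016-05-01",
                                        allowed_amount = 150), plans)
  expect_equal(out$coinsurance, 30)
  expect_equal(out$deductible, 0)
})

test_that("screening mammogram claims carry zero cost-sharing", {
  plans <- data.frame(plan_id = "P1", true_type = "deductible",
                      copay_amount = 25, coinsurance_rate = 0.2,
                      annual_deductible = 1000, n_enrollees = 1)
  cl <- make_claims("E1", "P1", c("2016-03-01", "2016-04-01"),
                    cpt_code = c("77057", "99213"), allowed_amount = 140)
  out <- apply_cost_sharing(cl, plans)
  scr <- out$cpt_code == "77057"
  expect_equal(out$copay[scr] + out$coinsurance[scr] + out$deductible[scr], 0)
  # and the screening claim does not advance the accumulator
  expect_equal(out$deductible[!scr], 140)
})

test_that("generated claims satisfy the cost-decomposition invariants", {
  plans <- generate_plans(40, seed = 3)
  g <- generate_claims(plans, seed = 3)
  cl <- g$claims
  expect_true(all(cl$copay + cl$coinsurance + cl$deductible <=
                    cl$allowed_amount + 0.02))
  expect_true(all(cl$copay >= 0 & cl$coinsurance >= 0 & cl$deductible >= 0))
  ann <- tapply(cl$deductible,
                paste(cl$enrollee_id, format(cl$service_date, "%Y")), sum)
  cap <- plans$annual_deductible[match(
    g$enrollment$plan_id[match(sub(" .*", "", names(ann)),
                               g$enrollment$enrollee_id)], plans$plan_id)]
  expect_true(all(ann <= cap + 0.02))
})

test_that("hurdle outcome generation matches its analytic targets", {
  co <- data.frame(plan_type = rep("coinsurance", 40000),
                   age_group = "40-64", race_ethnicity = "White",
                   cci_category = "0", region = "R1")
  base <- list(formula = ~ 1, alpha = 0.5,
               beta_logit = c("(Intercept)" = 0),
               beta_count = c("(Intercept)" = log(2)))
  out <- generate_outcomes(co, base, seed = 4)
  # logit^-1(0) = 0.5
  expect_lt(abs(mean(out$any_test) - 0.5), 3 * sqrt(0.25 / 40000))

  rate <- list(formula = ~ 1, alpha = 0.5,
               beta_logit = c("(Intercept)" = stats::qlogis(0.109)),
               beta_count = c("(Intercept)" = log(2)))
  out2 <- generate_outcomes(co, rate, seed = 5)
  expect_lt(abs(mean(out2$any_test) - 0.109),
            3 * sqrt(0.109 * 0.891 / 40000))

  # alpha -> 0: zero-truncated Poisson mean mu/(1 - exp(-mu))
  zp <- list(formula = ~ 1, alpha = 1e-8,
             beta_logit = c("(Intercept)" = 5),
             beta_count = c("(Intercept)" = log(2)))
  out3 <- generate_outcomes(co, zp, seed = 6)
  target <- 2 / (1 - exp(-2))
  pos <- out3$n_services[out3$any_test == 1]
  expect_lt(abs(mean(pos) - target), 3 * stats::sd(pos) / sqrt(length(pos)))

  # counts >= 1 exactly when the indicator is 1
  expect_true(all((out$n_services >= 1) == (out$any_test == 1)))
  expect_error(generate_outcomes(co, modifyList(base, list(alpha = -1))),
               "alpha")
})

test_that("the full study simulation is internally consistent", {
  sim <- simulate_study(n_plans = 120, seed = 2)
  tr <- sim$truth$cohort
  expect_equal(nrow(tr), sim$truth$n_eligible_cohort)
  # planted per-category counts sum to the planted hurdle count
  expect_equal(tr$diagnostic_mammo + tr$ultrasound + tr$mri + tr$biopsy,
               tr$n_services)
  # identical seed reproduces byte-identical claims
  sim2 <- simulate_study(n_plans = 120, seed = 2)
  expect_identical(sim$claims, sim2$claims)
})
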