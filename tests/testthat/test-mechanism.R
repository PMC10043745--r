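# Mechanism inference: triplets, scaling, origin-seeded k-means, labelling,
# OOPC ranking.

test_that("plan triplets take modes and per-enrollee annual deductible maxima", {
  cl <- rbind(
    make_claims("E1", "P1", c("2016-01-01", "2016-02-01", "2016-03-01"),
                allowed_amount = c(100, 150, 100),
                copay = c(25, 25, 10),
                coinsurance = c(20, 30, 10)),
    # enrollee A pays 300 + 200 deductible in one year, B pays 400
    make_claims("E1", "P1", c("2016-04-01", "2016-05-01"),
                deductible = c(300, 200)),
    make_claims("E2", "P1", "2016-06-01", deductible = 400))
  tr <- compute_plan_triplets(cl)
  # the three cost-bearing claims give copay mode 25 and ratio mode .20;
  # over all six claims the zero-cost deductible claims dominate the modes
  tr2 <- compute_plan_triplets(cl[1:3, ])
  expect_equal(tr2$mode_copay, 25)
  expect_equal(tr2$mode_coinsurance_rate, 0.20)
  expect_equal(tr$mode_copay, 0)
  expect_equal(tr$max_deductible, 500)
  expect_equal(tr$n_claims, 6L)
})

test_that("mode ties break toward the smaller value", {
  cl <- make_claims("E1", "P1", c("2016-01-01", "2016-02-01"),
                    copay = c(10, 25))
  expect_equal(compute_plan_triplets(cl)$mode_copay, 10)
})

test_that("min-max scaling matches both orientations at the endpoints", {
  tr <- data.frame(plan_id = c("a", "b", "c"),
                   mode_copay = c(0, 50, 100),
                   mode_coinsurance_rate = c(0, 0.1, 0.3),
                   max_deductible = c(100, 400, 1000))
  sp <- scale_triplets(tr, "as_printed")
  ss <- scale_triplets(tr, "standard")
  expect_equal(sp$s_copay, c(1, 0.5, 0))    # max scales to 0 as printed
  expect_equal(ss$s_copay, c(0, 0.5, 1))
  expect_equal(sp$s_copay[2], ss$s_copay[2])  # midpoint identical either way
  tr$max_deductible <- 100
  expect_warning(sd <- scale_triplets(tr), "degenerate")
  expect_equal(sd$s_deductible, c(0, 0, 0))
})

test_that("scaling preserves component-wise ordering under monotone transforms", {
  set.seed(11)
  tr <- data.frame(plan_id = paste0("p", 1:30),
                   mode_copay = runif(30, 0, 60),
                   mode_coinsurance_rate = runif(30, 0, .4),
                   max_deductible = runif(30, 0, 2000))
  s1 <- scale_triplets(tr, "standard")
  tr2 <- tr
  tr2$mode_copay <- exp(tr$mode_copay / 20)        # strictly increasing
  s2 <- scale_triplets(tr2, "standard")
  expect_equal(order(s1$s_copay), order(s2$s_copay))
})

test_that("k-means matches the brute-force Lloyd oracle from identical inits", {
  for (s in 1:10) {
    set.seed(1000 + s)
    n <- sample(4:8, 1)
    sc <- data.frame(plan_id = paste0("p", 1:n),
                     s_copay = runif(n), s_coinsurance = runif(n),
                     s_deductible = runif(n))
    init <- kmeans_init(s)
    km <- kmeans_classify(sc, init = init)
    oracle <- brute_lloyd(as.matrix(sc[, -1]), init)
    expect_identical(as.vector(km$cluster), oracle$cluster)
    expect_equal(km$centers, oracle$centers, ignore_attr = TRUE)
  }
})

test_that("within-cluster SSE is non-increasing across Lloyd iterations", {
  for (s in 1:5) {
    set.seed(2000 + s)
    n <- 60
    sc <- data.frame(plan_id = paste0("p", 1:n),
                     s_copay = runif(n), s_coinsurance = runif(n),
                     s_deductible = runif(n))
    km <- kmeans_classify(sc, seed = s)
    expect_true(all(diff(km$sse_path) <= 1e-12))
    expect_true(km$converged)
  }
})

test_that("k-means is deterministic given seed and degenerates gracefully", {
  set.seed(3)
  sc <- data.frame(plan_id = paste0("p", 1:20),
                   s_copay = runif(20), s_coinsurance = runif(20),
                   s_deductible = runif(20))
  k1 <- kmeans_classify(sc, seed = 42)
  k2 <- kmeans_classify(sc, seed = 42)
  expect_identical(k1$cluster, k2$cluster)
  expect_identical(k1$centers, k2$centers)

  same <- data.frame(plan_id = paste0("p", 1:6), s_copay = 0.3,
                     s_coinsurance = 0.3, s_deductible = 0.3)
  ks <- kmeans_classify(same, seed = 1)
  expect_equal(utils::tail(ks$sse_path, 1), 0)
  expect_equal(length(unique(ks$cluster)), 1L)

  expect_error(kmeans_classify(sc[1:3, ], seed = 1), "at least 4")
})

test_that("well-separated blobs are clustered with full purity", {
  set.seed(8)
  centers <- rbind(c(.05, .9, .9), c(.9, .05, .9), c(.9, .9, .05),
                   c(.5, .5, .5))
  X <- do.call(rbind, lapply(1:4, function(k)
    matrix(rep(centers[k, ], each = 25), 25) + matrix(runif(75, -.03, .03), 25)))
  sc <- data.frame(plan_id = paste0("p", 1:100), s_copay = X[, 1],
                   s_coinsurance = X[, 2], s_deductible = X[, 3])
  km <- kmeans_classify(sc, seed = 5)
  purity <- sum(apply(table(rep(1:4, each = 25), km$cluster), 1, max))
  expect_equal(purity, 100)
})

test_that("cluster labelling follows argmax with deterministic conflict resolution", {
  mk <- function(centers) structure(list(centers = centers,
                                         orientation = "standard"),
                                    class = "plan_kmeans")
  # one-hot centres plus a flat one
  lab <- label_clusters(mk(rbind(c(.9, .1, .1), c(.1, .9, .1),
                                 c(.1, .1, .9), c(.4, .4, .4))))
  expect_equal(lab, c("copay", "coinsurance", "deductible", "balanced"))
  # two clusters claim copay: larger coordinate wins, loser takes its
  # next-largest unclaimed dimension
  lab2 <- label_clusters(mk(rbind(c(.9, .1, .1), c(.8, .1, .05),
                                  c(.1, .1, .9), c(.4, .4, .4))))
  expect_equal(lab2[1], "copay")
  expect_equal(lab2[2], "coinsurance")
  # as-printed orientation is undone before labelling
  lab3 <- label_clusters(structure(list(
    centers = rbind(c(.1, .9, .9), c(.9, .1, .9), c(.9, .9, .1),
                    c(.6, .6, .6)), orientation = "as_printed"),
    class = "plan_kmeans"))
  expect_equal(lab3, c("copay", "coinsurance", "deductible", "balanced"))
})

test_that("plan types are ranked by unweighted plan-mean OOPC", {
  assignments <- data.frame(plan_id = c("p1", "p2", "p3", "p4"),
                            plan_type = c("coinsurance", "balanced", "copay",
                                          "deductible"))
  oopc <- data.frame(plan_id = rep(c("p1", "p2", "p3", "p4"), each = 2),
                     enrollee_id = paste0("e", 1:8),
                     annual_oopc = c(900, 990, 1000, 1034, 1040, 1000, 1100, 1272))
  r <- rank_plan_types(assignments, oopc)
  expect_equal(r$type_stats$plan_type,
               c("coinsurance", "balanced", "copay", "deductible"))
  expect_equal(r$type_stats$oopc_rank, 1:4)
  expect_equal(r$type_stats$mean_annual_oopc, c(945, 1017, 1020, 1186))
  # order invariance
  perm <- sample(nrow(oopc))
  r2 <- rank_plan_types(assignments[c(3, 1, 4, 2), ], oopc[perm, ])
  expect_equal(r2$assignments$oopc_rank[match(assignments$plan_id,
                                              r2$assignments$plan_id)],
               r$assignments$oopc_rank)
})

test_that("end-to-end classification recovers planted plan types", {
  plans <- generate_plans(300, separation = 2, seed = 21)
  g <- generate_claims(plans, seed = 21)
  inf <- classify_plans(g$claims, g$enrollment, seed = 21)
  truth <- plans$true_type[match(inf$assignments$plan_id, plans$plan_id)]
  expect_gte(mean(inf$assignments$plan_type == truth), 0.95)
  expect_equal(sort(unique(inf$assignments$oopc_rank)), 1:4)
})
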