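# Independent oracles and small fixture builders shared across tests.

# Brute-force Lloyd k-means written with plain loops, independent of the
# package's vectorised implementation.  Same contract: exact Euclidean
# nearest centre with ties to the lowest index, all centres recomputed as
# assigned-point means, empty clusters re-seeded to the point farthest from
# its nearest live centre, stop when assignments repeat.
brute_lloyd <- function(X, centers, max_iter = 300) {
  n <- nrow(X); k <- nrow(centers)
  cl <- rep(0L, n)
  for (iter in seq_len(max_iter)) {
    new_cl <- integer(n)
    for (i in seq_len(n)) {
      best <- 1L; bestd <- Inf
      for (j in seq_len(k)) {
        d <- sum((X[i, ] - centers[j, ])^2)
        if (d < bestd) { bestd <- d; best <- j }
      }
      new_cl[i] <- best
    }
    repeat {
      empty <- setdiff(seq_len(k), unique(new_cl))
      if (!length(empty)) break
      kk <- empty[1]
      live <- setdiff(seq_len(k), empty)
      fard <- -Inf; far <- 1L
      for (i in seq_len(n)) {
        nd <- Inf
        for (j in live) nd <- min(nd, sum((X[i, ] - centers[j, ])^2))
        if (nd > fard) { fard <- nd; far <- i }
      }
      if (fard <= 0) break
      centers[kk, ] <- X[far, ]
      for (i in seq_len(n)) {
        best <- 1L; bestd <- Inf
        for (j in seq_len(k)) {
          d <- sum((X[i, ] - centers[j, ])^2)
          if (d < bestd) { bestd <- d; best <- j }
        }
        new_cl[i] <- best
      }
    }
    if (identical(new_cl, cl)) break
    cl <- new_cl
    for (j in seq_len(k)) {
      if (any(cl == j)) centers[j, ] <- colMeans(X[cl == j, , drop = FALSE])
    }
  }
  list(cluster = cl, centers = centers,
       sse = sum((X - centers[cl, , drop = FALSE])^2))
}

# Brute-force zero-truncated NB2 log-likelihood: builds the pmf by the
# explicit recursion f(0) = (1+alpha*mu)^(-1/alpha),
# f(y) = f(y-1) * (y-1+1/alpha)/y * (alpha*mu/(1+alpha*mu)), and normalises
# by the explicitly summed positive-tail mass.
brute_ztnb_loglik <- function(beta, alpha, y, X, K = 500) {
  eta <- as.vector(X %*% beta)
  total <- 0
  for (i in seq_along(y)) {
    mu <- exp(eta[i])
    r <- (alpha * mu) / (1 + alpha * mu)
    f <- numeric(max(K, y[i]) + 1)
    f[1] <- (1 + alpha * mu)^(-1 / alpha)
    for (kk in seq_len(length(f) - 1))
      f[kk + 1] <- f[kk] * (kk - 1 + 1 / alpha) / kk * r
    total <- total + log(f[y[i] + 1]) - log(sum(f[-1]))
  }
  total
}

# Closed-form zero-truncated Poisson log-density (the alpha -> 0 limit).
ztpois_logdens <- function(y, mu) {
  stats::dpois(y, mu, log = TRUE) - log(1 - exp(-mu))
}

# Minimal claims-table constructor for handcrafted fixtures.
make_claims <- function(enrollee_id, plan_id = "P1", service_date,
                        cpt_code = "99213", icd_codes = "Z00.00",
                        allowed_amount = 100, copay = 0, coinsurance = 0,
                        deductible = 0) {
  data.frame(enrollee_id = enrollee_id, plan_id = plan_id,
             service_date = as.Date(service_date), cpt_code = cpt_code,
             icd_codes = icd_codes, allowed_amount = allowed_amount,
             copay = copay, coinsurance = coinsurance,
             deductible = deductible, stringsAsFactors = FALSE)
}

make_enrollment <- function(enrollee_id, plan_id = "P1", sex = "F",
                            birth_year = 1960,
                            enroll_start = "2015-01-01",
                            enroll_end = "2017-12-31",
                            death_date = NA) {
  data.frame(enrollee_id = enrollee_id, plan_id = plan_id, sex = sex,
             birth_year = birth_year,
             enroll_start = as.Date(enroll_start),
             enroll_end = as.Date(enroll_end),
             death_date = as.Date(death_date),
             stringsAsFactors = FALSE)
}

# Small covariate table for hurdle simulations.
make_cohort <- function(n, seed = 1, plan_probs = c(.134, .215, .147, .503)) {
  set.seed(seed)
  data.frame(
    plan_type = sample(c("coinsurance", "balanced", "copay", "deductible"),
                       n, TRUE, prob = plan_probs),
    age_group = sample(c("40-64", "65-74", "75-84", "85+"), n, TRUE,
                       prob = c(.953, .045, .0019, .0001)),
    race_ethnicity = sample(c("White", "Asian", "Black", "Hispanic", "Unknown"),
                            n, TRUE, prob = c(.713, .036, .073, .071, .107)),
    cci_category = sample(c("0", "1", "2", "3+"), n, TRUE,
                          prob = c(.874, .104, .018, .005)),
    region = paste0("R", sample.int(5, n, TRUE)),
    stringsAsFactors = FALSE)
}
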