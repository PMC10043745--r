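# Plan cost-sharing mechanism inference.
#
# A plan's mechanism design — the copay amount, coinsurance percentage and
# deductible printed on the insurance card — is not observable in claims
# extracts; it is inferred here from the cost-sharing of all claims of all of
# the plan's enrollees.  Each plan is summarised by the triplet
# (mode copay, mode coinsurance rate, maximum annual deductible paid),
# min-max scaled, and clustered into four types by a Lloyd k-means with
# three random centers plus one deterministic center at the origin.

#' Compute mechanism-design triplets for every plan
#'
#' Per plan: \code{mode_copay} is the most frequent copay value across the
#' plan's claims; \code{mode_coinsurance_rate} is the most frequent value of
#' per-claim coinsurance / allowed amount (claims with zero allowed amount
#' skipped; ratios rounded to 2 decimals before taking the mode, since real
#' coinsurance rates are quoted in whole percents); \code{max_deductible} is
#' the maximum over enrollees of the enrollee's annual sum of deductible
#' payments.  Mode ties break toward the smaller value, so the statistic is
#' deterministic.
#'
#' @param claims claims table (standard schema).
#' @param enrollment enrollment table, used for enrollee counts.
#' @param exclude_zero_cost if TRUE, claims with zero total cost-sharing are
#'   dropped before computing modes.
#' @return data.frame with one row per plan holding the raw triplet plus
#'   \code{n_enrollees} and \code{n_claims}.  Plans with no claims are
#'   absent (attribute \code{"excluded_plans"} lists them).
#' @export
compute_plan_triplets <- function(claims, enrollment = NULL,
                                  exclude_zero_cost = FALSE) {
  cl <- claims
  if (exclude_zero_cost) {
    cl <- cl[cl$copay + cl$coinsurance + cl$deductible > 0, , drop = FALSE]
  }
  if (nrow(cl) == 0L) stop_invalid("no claims to summarise")
  plan <- cl$plan_id

  mode_copay <- tapply(cl$copay, plan, stat_mode)

  ok <- cl$allowed_amount > 0
  ratio <- round(cl$coinsurance[ok] / cl$allowed_amount[ok], 2)
  mode_coins <- tapply(ratio, plan[ok], stat_mode)

  yr <- format(cl$service_date, "%Y")
  ann <- rowsum(cl$deductible, paste(plan, cl$enrollee_id, yr))
  ann_plan <- sub(" .*", "", rownames(ann))
  max_ded <- tapply(ann[, 1], ann_plan, max)

  ids <- sort(unique(plan))
  n_claims <- as.vector(table(plan)[ids])
  n_enr <- if (!is.null(enrollment)) {
    as.vector(table(enrollment$plan_id)[ids])
  } else {
    as.vector(tapply(cl$enrollee_id, plan, function(x) length(unique(x)))[ids])
  }
  out <- data.frame(plan_id = ids,
                    mode_copay = as.vector(mode_copay[ids]),
                    mode_coinsurance_rate = as.vector(mode_coins[ids]),
                    max_deductible = as.vector(max_ded[ids]),
                    n_enrollees = n_enr,
                    n_claims = n_claims,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$mode_coinsurance_rate[is.na(out$mode_coinsurance_rate)] <- 0
  excluded <- if (!is.null(enrollment))
    setdiff(unique(enrollment$plan_id), ids) else character()
  attr(out, "excluded_plans") <- excluded
  out
}

#' Min-max scale plan triplets
#'
#' Component-wise over all plans.  Orientation \code{"as_printed"} uses
#' \code{(max - x) / (max - min)}, so the plan attaining the global maximum
#' of a component scales to 0; \code{"standard"} uses the usual
#' \code{(x - min) / (max - min)}.  A degenerate component (max = min)
#' scales to 0 for all plans, with a warning.
#'
#' @param triplets data.frame from \code{\link{compute_plan_triplets}}.
#' @param orientation \code{"as_printed"} (default) or \code{"standard"}.
#' @return data.frame \code{plan_id}, \code{s_copay}, \code{s_coinsurance},
#'   \code{s_deductible}, each in [0, 1]; the orientation is recorded as an
#'   attribute.
#' @export
scale_triplets <- function(triplets, orientation = c("as_printed", "standard")) {
  orientation <- match.arg(orientation)
  raw <- as.matrix(triplets[, c("mode_copay", "mode_coinsurance_rate",
                                "max_deductible")])
  lo <- apply(raw, 2, min)
  hi <- apply(raw, 2, max)
  rng <- hi - lo
  s <- matrix(0, nrow(raw), 3)
  for (j in 1:3) {
    if (rng[j] <= 0) {
      warning(sprintf("degenerate scale on component %d: all plans share value %g",
                      j, lo[j]))
    } else if (orientation == "as_printed") {
      s[, j] <- (hi[j] - raw[, j]) / rng[j]
    } else {
      s[, j] <- (raw[, j] - lo[j]) / rng[j]
    }
  }
  out <- data.frame(plan_id = triplets$plan_id,
                    s_copay = s[, 1], s_coinsurance = s[, 2],
                    s_deductible = s[, 3], stringsAsFactors = FALSE)
  attr(out, "orientation") <- orientation
  out
}

scaled_matrix <- function(scaled) {
  as.matrix(scaled[, c("s_copay", "s_coinsurance", "s_deductible")])
}

#' Initial cluster centers: one at the origin, three uniform at random
#'
#' @param seed integer seed for the three random centers.
#' @return 4 x 3 matrix; row 1 is the deterministic origin center.
#' @export
kmeans_init <- function(seed) {
  set.seed(substream_seed(seed, "kmeans-init"))
  rbind(origin = c(0, 0, 0),
        matrix(stats::runif(9), 3, 3))
}

#' Classify plans by Lloyd k-means with an origin-seeded cluster
#'
#' Runs Lloyd's iteration with 4 centers in scaled triplet space: one center
#' initialised deterministically at (0, 0, 0) and three uniformly at random
#' in the unit cube.  Every round assigns each plan to its exactly nearest
#' center (Euclidean; ties to the lowest center index), then recomputes all
#' four centers as assigned-point means (the origin center is not pinned
#' unless \code{pin_origin = TRUE}).  A cluster left empty is re-seeded to
#' the point farthest from its nearest center.  Iteration stops when no
#' assignment changes.  A single run per seed; no restarts.
#'
#' @param scaled data.frame from \code{\link{scale_triplets}}.
#' @param seed integer seed (ignored when \code{init} is given).
#' @param max_iter iteration cap (default 300).
#' @param init optional 4 x 3 matrix of initial centers overriding the
#'   seeded initialisation.
#' @param pin_origin if TRUE the origin center is held fixed at (0,0,0).
#' @return object of class \code{plan_kmeans}: \code{centers} (4 x 3),
#'   \code{cluster} (named assignment per plan), \code{iterations},
#'   \code{sse_path} (within-cluster SSE after each assignment step),
#'   \code{converged}, \code{seed}, \code{reseeded} (count of empty-cluster
#'   re-seeds).
#' @export
kmeans_classify <- function(scaled, seed = 1, max_iter = 300, init = NULL,
                            pin_origin = FALSE) {
  X <- scaled_matrix(scaled)
  n <- nrow(X)
  if (n < 4) stop_invalid("invalid input: need at least 4 plans for 4 clusters")
  centers <- if (is.null(init)) kmeans_init(seed) else {
    stopifnot(is.matrix(init), all(dim(init) == c(4, 3)))
    init
  }
  dimnames(centers) <- list(NULL, colnames(X))

  assign_pts <- function(centers) {
    d <- vapply(1:4, function(k)
      rowSums((X - matrix(centers[k, ], n, 3, byrow = TRUE))^2), numeric(n))
    max.col(-d, ties.method = "first")
  }

  cl <- rep(0L, n)
  sse_path <- numeric(0)
  reseeded <- 0L
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    new_cl <- assign_pts(centers)
    # empty-cluster rule: re-seed to the point farthest from its nearest center
    repeat {
      empty <- setdiff(1:4, unique(new_cl))
      if (!length(empty)) break
      k <- empty[1]
      live <- setdiff(1:4, empty)
      d_live <- vapply(live, function(j)
        rowSums((X - matrix(centers[j, ], n, 3, byrow = TRUE))^2), numeric(n))
      nearest <- if (length(live) > 1) apply(d_live, 1, min) else as.vector(d_live)
      # if every point already sits on a live centre (duplicate data),
      # re-seeding cannot populate the cluster; leave it empty
      if (max(nearest) <= 0) break
      centers[k, ] <- X[which.max(nearest), ]
      reseeded <- reseeded + 1L
      new_cl <- assign_pts(centers)
    }
    sse_path <- c(sse_path,
                  sum((X - centers[new_cl, , drop = FALSE])^2))
    if (identical(new_cl, cl)) { converged <- TRUE; break }
    cl <- new_cl
    for (k in 1:4) {
      if (any(cl == k)) centers[k, ] <- colMeans(X[cl == k, , drop = FALSE])
    }
    if (pin_origin) centers[1, ] <- 0
    if (iter >= max_iter) break
  }
  structure(list(centers = centers,
                 cluster = stats::setNames(cl, scaled$plan_id),
                 iterations = iter,
                 sse_path = sse_path,
                 converged = converged,
                 seed = if (is.null(init)) seed else NA_integer_,
                 reseeded = reseeded,
                 orientation = attr(scaled, "orientation") %||% "as_printed"),
            class = "plan_kmeans")
}

#' @export
print.plan_kmeans <- function(x, ...) {
  cat("Plan-type k-means (4 clusters, origin-seeded)\n")
  cat(sprintf("  %d plans, %d iteration(s), converged: %s\n",
              length(x$cluster), x$iterations, x$converged))
  cat(sprintf("  final within-cluster SSE: %.6f\n", utils::tail(x$sse_path, 1)))
  cat("  centers (scaled copay, coinsurance, deductible):\n")
  print(round(x$centers, 3))
  invisible(x)
}

#' Label clusters as balanced / copay / coinsurance / deductible dominant
#'
#' Centers are first re-expressed so that larger means more cost-sharing in
#' every dimension (undoing the \code{as_printed} inversion when needed).
#' The cluster whose re-expressed center has the smallest across-dimension
#' range is labelled \code{balanced}; each remaining cluster takes the label
#' of its center's largest dimension.  If two clusters claim the same
#' dimension the larger coordinate wins and the loser takes its largest
#' unclaimed dimension; the procedure is deterministic.
#'
#' @param model a \code{plan_kmeans} object.
#' @param orientation orientation of the scaled space the model was fitted
#'   in; defaults to the one recorded in the model.
#' @return character vector of length 4 mapping cluster index to plan type.
#' @export
label_clusters <- function(model, orientation = NULL) {
  orientation <- orientation %||% model$orientation
  ctr <- model$centers
  if (orientation == "as_printed") ctr <- 1 - ctr
  dims <- c("copay", "coinsurance", "deductible")
  labels <- rep(NA_character_, 4)
  rng <- apply(ctr, 1, function(r) max(r) - min(r))
  bal <- which.min(rng)
  labels[bal] <- "balanced"

  remaining <- setdiff(1:4, bal)
  unclaimed <- 1:3
  while (length(remaining)) {
    # largest coordinate among unassigned clusters x unclaimed dimensions wins
    sub <- ctr[remaining, unclaimed, drop = FALSE]
    best <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    cl <- remaining[best[1]]
    dim <- unclaimed[best[2]]
    labels[cl] <- dims[dim]
    remaining <- setdiff(remaining, cl)
    unclaimed <- setdiff(unclaimed, dim)
  }
  labels
}

#' Rank plan types by mean annual out-of-pocket cost
#'
#' The type-level statistic is the unweighted mean over plans of the mean
#' over each plan's enrollees of their annual OOPC; ranks ascend with the
#' statistic (rank 1 = lowest cost-sharing).
#'
#' @param assignments data.frame \code{plan_id}, \code{plan_type}.
#' @param enrollee_oopc data.frame \code{plan_id}, \code{enrollee_id},
#'   \code{annual_oopc} (one row per enrollee).
#' @return list: \code{type_stats} (plan type, mean OOPC, rank) and
#'   \code{assignments} with \code{oopc_rank} appended.
#' @export
rank_plan_types <- function(assignments, enrollee_oopc) {
  plan_mean <- tapply(enrollee_oopc$annual_oopc, enrollee_oopc$plan_id, mean)
  pm <- plan_mean[assignments$plan_id]
  if (anyNA(pm)) stop_invalid("every plan needs at least one enrollee with OOPC")
  type_stat <- tapply(as.vector(pm), assignments$plan_type, mean)
  stats_df <- data.frame(plan_type = names(type_stat),
                         mean_annual_oopc = as.vector(type_stat),
                         stringsAsFactors = FALSE)
  stats_df$oopc_rank <- rank(stats_df$mean_annual_oopc, ties.method = "first")
  assignments$oopc_rank <- stats_df$oopc_rank[match(assignments$plan_type,
                                                    stats_df$plan_type)]
  list(type_stats = stats_df[order(stats_df$oopc_rank), ],
       assignments = assignments)
}

#' Annual out-of-pocket totals per enrollee
#'
#' One row per enrollee: the mean over calendar years of the enrollee's
#' annual copay + coinsurance + deductible total.
#'
#' @param claims claims table.
#' @return data.frame \code{plan_id}, \code{enrollee_id}, \code{annual_oopc}.
#' @export
enrollee_annual_oopc <- function(claims) {
  share <- claims$copay + claims$coinsurance + claims$deductible
  yr <- format(claims$service_date, "%Y")
  key <- paste(claims$plan_id, claims$enrollee_id, sep = "\r")
  ann <- rowsum(share, paste(key, yr, sep = "\r"))
  kyr <- rownames(ann)
  ekey <- sub("\r[^\r]*$", "", kyr)
  per_enr <- tapply(ann[, 1], ekey, mean)
  parts <- strsplit(names(per_enr), "\r", fixed = TRUE)
  data.frame(plan_id = vapply(parts, `[`, "", 1),
             enrollee_id = vapply(parts, `[`, "", 2),
             annual_oopc = as.vector(per_enr),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Infer and classify plan cost-sharing types from claims
#'
#' Convenience wrapper running the whole mechanism-inference chain:
#' triplets, min-max scaling, origin-seeded k-means, cluster labelling, and
#' OOPC ranking of the four types.
#'
#' @param claims,enrollment standard tables.
#' @param seed integer seed for the k-means initialisation.
#' @param orientation scaling orientation (see \code{\link{scale_triplets}}).
#' @param exclude_zero_cost passed to \code{\link{compute_plan_triplets}}.
#' @param pin_origin passed to \code{\link{kmeans_classify}}.
#' @return list: \code{assignments} (plan_id, cluster, plan_type, oopc_rank),
#'   \code{type_stats}, \code{model}, \code{triplets}, \code{scaled}.
#' @export
classify_plans <- function(claims, enrollment = NULL, seed = 1,
                           orientation = c("as_printed", "standard"),
                           exclude_zero_cost = FALSE, pin_origin = FALSE) {
  orientation <- match.arg(orientation)
  triplets <- compute_plan_triplets(claims, enrollment,
                                    exclude_zero_cost = exclude_zero_cost)
  scaled <- scale_triplets(triplets, orientation)
  model <- kmeans_classify(scaled, seed = seed, pin_origin = pin_origin)
  labels <- label_clusters(model)
  assignments <- data.frame(plan_id = scaled$plan_id,
                            cluster = as.vector(model$cluster),
                            plan_type = labels[model$cluster],
                            stringsAsFactors = FALSE)
  ranked <- rank_plan_types(assignments, enrollee_annual_oopc(claims))
  list(assignments = ranked$assignments, type_stats = ranked$type_stats,
       model = model, triplets = triplets, scaled = scaled)
}
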