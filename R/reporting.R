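# Summary tables: cohort characteristics, plan-type distribution, OOPC by
# plan type, and downstream-service utilisation.  Percentages are rounded
# half-up to one decimal, and every emitted table is self-checked so that
# each printed percentage recomputes from its own printed counts.

#' Percentage of a count over a denominator, rounded half-up to one decimal
#'
#' @param numerator,denominator non-negative counts with
#'   \code{0 <= numerator <= denominator} and \code{denominator > 0}.
#' @return \code{100 * numerator / denominator}, rounded half-up to 1
#'   decimal.
#' @examples
#' proportion(25073, 230845)  # 10.9
#' @export
proportion <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop_invalid("invalid input: denominator must be > 0")
  if (any(numerator < 0) || any(numerator > denominator))
    stop_invalid("invalid input: need 0 <= numerator <= denominator")
  round_half_up(100 * numerator / denominator, 1)
}

# Every percentage in a table block must recompute from its count and total
# to within 0.05 (rounding slack).  Called on every table emit.
check_percent_consistency <- function(n, pct, total) {
  ok <- abs(pct - 100 * n / total) <= 0.05 + 1e-9
  if (!all(ok))
    stop_invalid("table self-consistency failure: %d percentage(s) do not recompute from counts",
                 sum(!ok))
  invisible(TRUE)
}

mean_sd <- function(x) {
  c(mean = round_half_up(mean(x), 2),
    sd = round_half_up(stats::sd(x), 2))
}

categorical_block <- function(values, split, block, levels_order) {
  f <- factor(values, levels = levels_order)
  out <- do.call(rbind, lapply(levels_order, function(lv) {
    n_full <- sum(f == lv, na.rm = TRUE)
    n_scr <- sum(f == lv & !split, na.rm = TRUE)
    n_sub <- sum(f == lv & split, na.rm = TRUE)
    data.frame(block = block, level = lv,
               full_n = n_full,
               full_pct = proportion(n_full, length(f)),
               screening_n = n_scr,
               screening_pct = if (sum(!split)) proportion(n_scr, sum(!split)) else 0,
               subsequent_n = n_sub,
               subsequent_pct = if (sum(split)) proportion(n_sub, sum(split)) else 0,
               stringsAsFactors = FALSE)
  }))
  out
}

#' Cohort characteristics table (counts, percentages, OOPC means)
#'
#' One row per stratum of race/ethnicity, age group and Charlson category,
#' with counts and column percentages for the full sample and the
#' screening-only / subsequent-testing split, plus mean (SD) annual
#' out-of-pocket costs.  Within each block the screening-only and
#' subsequent-testing counts partition the full-sample count.
#'
#' @param cohort cohort table with \code{race_ethnicity}, \code{age_group},
#'   \code{cci_category}.
#' @param episodes episode table from \code{\link{build_episodes}} (matched
#'   by \code{patient_id}).
#' @return list of class \code{costshare_table}: \code{counts} data.frame and
#'   \code{oopc} data.frame.
#' @export
cohort_table <- function(cohort, episodes) {
  ep <- episodes[match(cohort$patient_id, episodes$patient_id), ]
  sub <- ep$any_subsequent
  counts <- rbind(
    categorical_block(cohort$race_ethnicity, sub, "race_ethnicity",
                      .covariate_levels$race_ethnicity),
    categorical_block(cohort$age_group, sub, "age_group",
                      .covariate_levels$age_group),
    categorical_block(cohort$cci_category, sub, "cci_category",
                      .covariate_levels$cci_category))
  for (blk in unique(counts$block)) {
    b <- counts[counts$block == blk, ]
    stopifnot(sum(b$full_n) == nrow(cohort),
              all(b$screening_n + b$subsequent_n == b$full_n))
    check_percent_consistency(b$full_n, b$full_pct, nrow(cohort))
  }
  oopc <- do.call(rbind, lapply(
    c(all_medical = "oopc_all_medical", breast_imaging = "oopc_breast_imaging"),
    function(col) {
      data.frame(full_mean = mean_sd(ep[[col]])[1],
                 full_sd = mean_sd(ep[[col]])[2],
                 screening_mean = mean_sd(ep[[col]][!sub])[1],
                 screening_sd = mean_sd(ep[[col]][!sub])[2],
                 subsequent_mean = mean_sd(ep[[col]][sub])[1],
                 subsequent_sd = mean_sd(ep[[col]][sub])[2])
    }))
  oopc <- cbind(measure = c("all_medical", "breast_imaging"), oopc)
  rownames(oopc) <- NULL
  structure(list(counts = counts, oopc = oopc,
                 n = nrow(cohort), n_subsequent = sum(sub)),
            class = "costshare_table")
}

#' Plan and patient distribution across plan types
#'
#' Plan counts with percentages of the plan universe, and patient counts
#' with percentages of the cohort, split by screening-only versus
#' subsequent testing.
#'
#' @param assignments plan-type assignments (plan_id, plan_type).
#' @param episodes episode table.
#' @return data.frame of class \code{costshare_table}.
#' @export
plan_type_table <- function(assignments, episodes) {
  ep_type <- assignments$plan_type[match(episodes$plan_id, assignments$plan_id)]
  types <- plan_type_levels
  out <- do.call(rbind, lapply(types, function(tp) {
    np <- sum(assignments$plan_type == tp)
    pat <- ep_type == tp
    data.frame(plan_type = tp,
               plans_n = np,
               plans_pct = proportion(np, nrow(assignments)),
               patients_n = sum(pat),
               patients_pct = proportion(sum(pat), nrow(episodes)),
               screening_n = sum(pat & !episodes$any_subsequent),
               subsequent_n = sum(pat & episodes$any_subsequent),
               stringsAsFactors = FALSE)
  }))
  check_percent_consistency(out$plans_n, out$plans_pct, nrow(assignments))
  check_percent_consistency(out$patients_n, out$patients_pct, nrow(episodes))
  structure(out, class = c("costshare_table", "data.frame"))
}

#' Downstream-service utilisation by plan type
#'
#' Per plan type (ordered from lowest to highest mean OOPC): patient counts
#' and row percentages for the screening-only / subsequent-testing split,
#' per-service recipient counts and percentages among testers, and mean (SD)
#' per-patient service counts among testers.
#'
#' @param episodes episode table.
#' @param assignments plan-type assignments with \code{oopc_rank}.
#' @return data.frame of class \code{costshare_table}, one row per plan
#'   type, ordered by \code{oopc_rank}.
#' @export
utilization_table <- function(episodes, assignments) {
  ep_type <- assignments$plan_type[match(episodes$plan_id, assignments$plan_id)]
  rk <- unique(assignments[, c("plan_type", "oopc_rank")])
  types <- rk$plan_type[order(rk$oopc_rank)]
  svc <- c("diagnostic_mammo", "ultrasound", "mri", "biopsy")
  out <- do.call(rbind, lapply(types, function(tp) {
    e <- episodes[ep_type == tp & !is.na(ep_type), , drop = FALSE]
    testers <- e[e$any_subsequent, , drop = FALSE]
    row <- data.frame(plan_type = tp,
                      screening_n = nrow(e) - nrow(testers),
                      screening_pct = if (nrow(e))
                        proportion(nrow(e) - nrow(testers), nrow(e)) else 0,
                      subsequent_n = nrow(testers),
                      subsequent_pct = if (nrow(e))
                        proportion(nrow(testers), nrow(e)) else 0,
                      stringsAsFactors = FALSE)
    for (s in svc) {
      recip <- sum(testers[[s]] > 0)
      row[[paste0(s, "_n")]] <- recip
      row[[paste0(s, "_pct")]] <- if (nrow(testers)) proportion(recip, nrow(testers)) else 0
      row[[paste0(s, "_mean")]] <- if (nrow(testers)) round_half_up(mean(testers[[s]]), 2) else 0
      row[[paste0(s, "_sd")]] <- if (nrow(testers) > 1) round_half_up(stats::sd(testers[[s]]), 2) else 0
    }
    tot <- rowSums(testers[, svc, drop = FALSE])
    row$all_services_mean <- if (nrow(testers)) round_half_up(mean(tot), 2) else 0
    row$all_services_sd <- if (nrow(testers) > 1) round_half_up(stats::sd(tot), 2) else 0
    row
  }))
  for (i in seq_len(nrow(out))) {
    tot <- out$screening_n[i] + out$subsequent_n[i]
    if (tot > 0)
      check_percent_consistency(c(out$screening_n[i], out$subsequent_n[i]),
                                c(out$screening_pct[i], out$subsequent_pct[i]),
                                tot)
  }
  structure(out, class = c("costshare_table", "data.frame"))
}

#' OOPC distribution by plan type
#'
#' Mean (SD) and median (IQR) of annual all-medical and breast-imaging
#' out-of-pocket costs per plan type plus an overall row.
#'
#' @param episodes episode table.
#' @param assignments plan-type assignments with \code{oopc_rank}.
#' @export
oopc_by_type_table <- function(episodes, assignments) {
  ep_type <- assignments$plan_type[match(episodes$plan_id, assignments$plan_id)]
  rk <- unique(assignments[, c("plan_type", "oopc_rank")])
  types <- rk$plan_type[order(rk$oopc_rank)]
  one <- function(e, label) {
    if (nrow(e) == 0L)
      return(data.frame(plan_type = label, all_medical_mean = 0,
                        all_medical_sd = 0, all_medical_median = 0,
                        all_medical_q1 = 0, all_medical_q3 = 0,
                        breast_imaging_mean = 0, breast_imaging_sd = 0,
                        stringsAsFactors = FALSE))
    q <- stats::quantile(e$oopc_all_medical, c(0.25, 0.5, 0.75))
    data.frame(plan_type = label,
               all_medical_mean = round_half_up(mean(e$oopc_all_medical), 2),
               all_medical_sd = round_half_up(stats::sd(e$oopc_all_medical), 2),
               all_medical_median = round_half_up(q[[2]], 2),
               all_medical_q1 = round_half_up(q[[1]], 2),
               all_medical_q3 = round_half_up(q[[3]], 2),
               breast_imaging_mean = round_half_up(mean(e$oopc_breast_imaging), 2),
               breast_imaging_sd = round_half_up(stats::sd(e$oopc_breast_imaging), 2),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(
    lapply(types, function(tp) one(episodes[ep_type == tp & !is.na(ep_type), ], tp)),
    list(one(episodes, "total"))))
  structure(out, class = c("costshare_table", "data.frame"))
}

#' @export
print.costshare_table <- function(x, ...) {
  if (is.data.frame(x)) {
    print.data.frame(x, row.names = FALSE)
  } else {
    cat(sprintf("Cohort: %d patients (%d with subsequent testing, %s%%)\n",
                x$n, x$n_subsequent, proportion(x$n_subsequent, x$n)))
    print.data.frame(x$counts, row.names = FALSE)
    cat("\nOut-of-pocket costs, mean (SD):\n")
    print.data.frame(x$oopc, row.names = FALSE)
  }
  invisible(x)
}

#' Write a summary table to CSV
#'
#' @param x a \code{costshare_table} (or plain data.frame).
#' @param path output file; for a list-shaped table, \code{_counts} /
#'   \code{_oopc} suffixes are inserted.
#' @export
write_table_csv <- function(x, path) {
  if (is.data.frame(x)) {
    utils::write.csv(x, path, row.names = FALSE)
    return(invisible(path))
  }
  base <- sub("\\.csv$", "", path)
  utils::write.csv(x$counts, paste0(base, "_counts.csv"), row.names = FALSE)
  utils::write.csv(x$oopc, paste0(base, "_oopc.csv"), row.names = FALSE)
  invisible(path)
}
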