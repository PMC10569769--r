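cohort_fingerprint <- function(cohort) {
  list(seed = cohort$config$seed, n_patients = nrow(cohort$patients),
       n_encounters = nrow(cohort$encounters),
       n_weeks = cohort$config$n_weeks)
}

## shared weekly engine: walks the weeks once, assigning new patients
## under the given policy and scoring each specialty-week's unfairness
## from REALIZED encounter counts. For policy "random" with n_reps > 1,
## the weekly value is the mean unfairness over n_reps conditional
## re-draws of that week's new patients around a single committed
## random trajectory.
sim_engine <- function(cohort, table, policy, predictor = NULL,
                       n_weeks = NULL, exact_threshold = 12, n_reps = 1) {
  sp <- cohort$config$specialties
  if (is.null(n_weeks)) n_weeks <- cohort$config$n_weeks
  n_weeks <- min(n_weeks, cohort$config$n_weeks)

  pred <- NULL
  if (policy %in% c("prediction_informed", "future_informed")) {
    if (policy == "prediction_informed") {
      if (is.null(predictor)) {
        stop("prediction_informed policy needs a fitted predictor",
             call. = FALSE)
      }
      if (length(intersect(predictor$train_patients,
                           unique(table$patient_id)))) {
        stop(paste("refusing to simulate: predictor was trained on",
                   "patients present in the simulation table"),
             call. = FALSE)
      }
      pred <- predict(predictor, table)
    } else {
      pred <- table$target_next_week  # oracle: realized workloads
    }
  }
  actual <- table$target_next_week

  series <- matrix(NA_real_, nrow(sp), n_weeks,
                   dimnames = list(sp$specialty_id, NULL))
  state <- assignment_state()
  for (g in seq_len(nrow(sp))) {
    m <- sp$n_navigators[g]
    rows_g <- which(table$specialty_id == sp$specialty_id[g] &
                      table$week < n_weeks)
    by_week <- split(rows_g, factor(table$week[rows_g],
                                    levels = 0:(n_weeks - 1)))
    nav <- integer(0)  # named navigator index per assigned patient
    for (w in seq_len(n_weeks)) {
      r <- by_week[[w]]
      new_r <- r[table$is_new[r]]
      old_r <- setdiff(r, new_r)
      old_nav <- nav[table$patient_id[old_r]]

      if (policy == "random") {
        exist_act <- load_by_nav(actual[old_r], old_nav, m)
        w_act <- actual[new_r]
        n_new <- length(new_r)
        if (n_reps > 1) {
          if (n_new > 0) {
            A <- matrix(sample.int(m, n_reps * n_new, replace = TRUE),
                        n_reps, n_new)
            L <- matrix(rep(exist_act, each = n_reps), n_reps, m)
            for (j in seq_len(m)) {
              L[, j] <- L[, j] + (A == j) %*% w_act
            }
            fair <- (sum(exist_act) + sum(w_act)) / m
            series[g, w] <- mean(rowSums(abs(L - fair)) / m)
          } else {
            series[g, w] <- unfairness(exist_act)
          }
        }
        draw <- if (n_new > 0) sample.int(m, n_new, replace = TRUE)
                else integer(0)
        names(draw) <- table$patient_id[new_r]
        mapping <- draw
      } else {
        exist_pred <- load_by_nav(pred[old_r], old_nav, m)
        prob <- assignment_problem(
          exist_pred,
          stats::setNames(pred[new_r], table$patient_id[new_r]),
          specialty_id = sp$specialty_id[g]
        )
        mapping <- optimal_assignment(prob,
                                      exact_threshold = exact_threshold)
      }
      if (length(mapping)) {
        state <- commit(state, mapping)
        nav[names(mapping)] <- mapping
      }
      if (policy != "random" || n_reps == 1) {
        all_nav <- nav[table$patient_id[r]]
        series[g, w] <- unfairness(load_by_nav(actual[r], all_nav, m))
      }
    }
  }
  structure(
    list(policy = policy, series = series, n_weeks = n_weeks,
         n_reps = n_reps, state = state,
         fingerprint = cohort_fingerprint(cohort)),
    class = "policy_run"
  )
}

load_by_nav <- function(values, nav, m) {
  out <- numeric(m)
  for (g in seq_len(m)) out[g] <- sum(values[nav == g])
  out
}

#' Run one distribution policy over the simulation weeks
#'
#' Walks the weekly timeline: each Monday, predicts (or looks up) the
#' next-week workload of every active patient, distributes the week's
#' new patients under the chosen policy, commits the assignments
#' (patients never move once assigned), and scores each specialty's
#' weekly [unfairness()] from the REALIZED encounter counts of each
#' navigator's panel. All policies therefore score identical realized
#' encounter streams; only who holds each patient differs.
#'
#' @param cohort A `cpn_cohort`.
#' @param policy `"prediction_informed"`, `"random"` (single
#'   trajectory), or `"future_informed"` (oracle: assigns on realized
#'   workloads).
#' @param predictor A fitted [workload_model()] (required for
#'   `prediction_informed`; it must not have been trained on any
#'   simulated patient).
#' @param partition Patient partition to simulate (default `"test"`).
#' @param n_weeks Number of weeks (default: the cohort's).
#' @param exact_threshold Passed to [optimal_assignment()].
#' @param seed Seed for the random policy's draws.
#' @param table Optional pre-built modelling table (from
#'   [build_model_table()]) to avoid rebuilding.
#' @return Object of class `policy_run` with the per-specialty weekly
#'   unfairness `series` (matrix specialties x weeks) and the final
#'   assignment state.
#' @export
run_policy <- function(cohort, policy = c("prediction_informed", "random",
                                          "future_informed"),
                       predictor = NULL, partition = "test",
                       n_weeks = NULL, exact_threshold = 12, seed = 1,
                       table = NULL) {
  policy <- match.arg(policy)
  if (is.null(table)) table <- build_model_table(cohort, partition)
  with_local_seed(seed,
    sim_engine(cohort, table, policy, predictor, n_weeks,
               exact_threshold, n_reps = 1))
}

#' Random-distribution baseline with per-week repetitions
#'
#' Emulates the expected behaviour of rotation-based (effectively
#' random) patient intake: each week, conditional on the committed
#' panel state, the week's new patients are randomly re-distributed
#' `n_reps` times (default 10,000) and the mean of the resulting
#' unfairness values is recorded for that week; a single additional
#' random draw is then committed to evolve the panel state.
#'
#' @inheritParams run_policy
#' @param n_reps Random re-draws per week.
#' @return A `policy_run` whose series holds the per-week mean
#'   unfairness of the repeated random distribution.
#' @export
random_baseline <- function(cohort, partition = "test", n_reps = 10000,
                            n_weeks = NULL, seed = 1, table = NULL) {
  stopifnot(n_reps >= 1)
  if (is.null(table)) table <- build_model_table(cohort, partition)
  with_local_seed(seed,
    sim_engine(cohort, table, "random", n_weeks = n_weeks,
               n_reps = n_reps))
}

#' @export
print.policy_run <- function(x, ...) {
  cat(sprintf("<policy_run> %s: %d specialties x %d weeks%s\n",
              x$policy, nrow(x$series), x$n_weeks,
              if (x$n_reps > 1) sprintf(" (%d reps/week)", x$n_reps)
              else ""))
  invisible(x)
}

#' Compare distribution policies run on the same cohort
#'
#' Builds the per-specialty comparison table: mean, SD, and 95% CI
#' (via [summarize_series()]) of weekly unfairness per policy, the
#' percent reduction of each policy's mean relative to the random
#' baseline, and a flag for CI overlap with the baseline. An
#' `"(all)"` row pools the weekly values across specialties; its
#' percent reduction is the headline aggregate.
#'
#' @param runs Named list of `policy_run` objects over the identical
#'   cohort (same fingerprint); must include a `"random"` element when
#'   reductions are requested.
#' @return Object of class `policy_comparison`: list with `table` (the
#'   comparison data frame) and `runs`.
#' @export
compare_policies <- function(runs) {
  stopifnot(length(runs) >= 2, !is.null(names(runs)))
  fps <- lapply(runs, function(r) r$fingerprint)
  if (!all(vapply(fps, identical, logical(1), fps[[1]]))) {
    stop("policy runs come from different cohorts", call. = FALSE)
  }
  specialties <- rownames(runs[[1]]$series)
  rows <- list()
  for (spc in c(specialties, "(all)")) {
    for (p in names(runs)) {
      vals <- if (spc == "(all)") as.vector(t(runs[[p]]$series))
              else runs[[p]]$series[spc, ]
      s <- summarize_series(vals)
      rows[[length(rows) + 1L]] <- data.frame(
        specialty_id = spc, policy = p, mean = s$mean, sd = s$sd,
        n = s$n, ci_low = s$ci_low, ci_high = s$ci_high)
    }
  }
  tab <- do.call(rbind, rows)
  if ("random" %in% names(runs)) {
    base <- tab[tab$policy == "random", ]
    i <- match(tab$specialty_id, base$specialty_id)
    tab$pct_reduction_vs_random <-
      100 * (base$mean[i] - tab$mean) / base$mean[i]
    tab$ci_overlaps_random <- tab$ci_low <= base$ci_high[i] &
      base$ci_low[i] <= tab$ci_high
  }
  structure(list(table = tab, runs = runs), class = "policy_comparison")
}

#' Aggregate percent reduction in mean unfairness vs. the random baseline
#'
#' @param comparison A `policy_comparison` containing a `"random"` run.
#' @param policy Policy to evaluate (default `"prediction_informed"`).
#' @return Percent reduction pooled across specialties.
#' @export
pct_reduction <- function(comparison, policy = "prediction_informed") {
  tab <- comparison$table
  r <- tab[tab$specialty_id == "(all)" & tab$policy == policy, ]
  if (nrow(r) != 1) stop("policy not found in comparison", call. = FALSE)
  r$pct_reduction_vs_random
}

#' Simulate and compare distribution policies on one cohort
#'
#' Convenience wrapper: builds the modelling table for the chosen
#' partition once, runs the requested policies on identical realized
#' encounter streams (the random policy as a [random_baseline()] with
#' `n_reps` repetitions per week), and returns their
#' [compare_policies()] comparison.
#'
#' @inheritParams run_policy
#' @param policies Policies to run.
#' @param n_reps Repetitions per week for the random baseline.
#' @return A `policy_comparison`.
#' @export
simulate_policies <- function(cohort, predictor = NULL,
                              policies = c("prediction_informed",
                                           "random",
                                           "future_informed"),
                              partition = "test", n_reps = 10000,
                              n_weeks = NULL, exact_threshold = 12,
                              seed = 1) {
  table <- build_model_table(cohort, partition)
  runs <- list()
  for (p in policies) {
    runs[[p]] <- if (p == "random") {
      random_baseline(cohort, n_reps = n_reps, n_weeks = n_weeks,
                      seed = seed, table = table)
    } else {
      run_policy(cohort, p, predictor = predictor, n_weeks = n_weeks,
                 exact_threshold = exact_threshold, seed = seed,
                 table = table)
    }
  }
  compare_policies(runs)
}

#' @export
print.policy_comparison <- function(x, digits = 3, ...) {
  cat("<policy_comparison>\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.policy_comparison <- function(object, ...) {
  tab <- object$table
  agg <- tab[tab$specialty_id == "(all)", ]
  cat("Pooled weekly unfairness by policy:\n")
  print(agg[, c("policy", "mean", "sd", "ci_low", "ci_high",
                intersect("pct_reduction_vs_random", names(agg)))],
        row.names = FALSE)
  invisible(object)
}

#' Bar chart of mean weekly unfairness by specialty and policy
#'
#' @param x A `policy_comparison`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.policy_comparison <- function(x, ...) {
  tab <- x$table[x$table$specialty_id != "(all)", ]
  pol <- unique(tab$policy)
  spc <- unique(tab$specialty_id)
  m <- matrix(tab$mean[order(match(tab$policy, pol),
                             match(tab$specialty_id, spc))],
              nrow = length(pol), byrow = TRUE,
              dimnames = list(pol, spc))
  barplot(m, beside = TRUE, legend.text = pol,
          ylab = "mean weekly unfairness", xlab = "specialty", ...)
  invisible(x)
}
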