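# Shared fixtures and independent oracles used across test files.

# small cohort configs keep unit tests fast; acceptance tests use the
# package defaults
tiny_config <- function(seed = 1, n_weeks = 12, signal = 1) {
  cohort_config(
    n_weeks = n_weeks,
    specialties = data.frame(
      specialty_id = c("alpha", "beta"),
      n_navigators = c(2L, 3L),
      arrival_rate = c(6, 9)
    ),
    feature_signal_strength = signal,
    interaction_log = FALSE,
    seed = seed
  )
}

# independent brute-force minimum-unfairness oracle: tries all m^n
# assignments via expand.grid, no shared code with the package solver
brute_force_assignment <- function(existing, new) {
  m <- length(existing)
  n <- length(new)
  if (n == 0) {
    return(list(unfairness = mean(abs(existing - mean(existing)))))
  }
  grid <- as.matrix(expand.grid(rep(list(seq_len(m)), n)))
  best <- Inf
  best_row <- NULL
  for (i in seq_len(nrow(grid))) {
    loads <- existing
    for (j in seq_len(n)) {
      loads[grid[i, j]] <- loads[grid[i, j]] + new[j]
    }
    u <- mean(abs(loads - mean(loads)))
    if (u < best - 1e-12) {
      best <- u
      best_row <- grid[i, ]
    }
  }
  list(unfairness = best, assignment = best_row)
}

# naive mixed-dissimilarity oracle (plain loops) for k-prototypes checks
naive_mixed_cost <- function(x_num, x_cat, centers, modes, gamma,
                             cluster) {
  total <- 0
  for (i in seq_len(nrow(x_num))) {
    cl <- cluster[i]
    d <- sum((x_num[i, ] - centers[cl, ])^2)
    if (!is.null(x_cat)) {
      for (q in seq_along(x_cat)) {
        d <- d + gamma * (as.character(x_cat[[q]][i]) !=
                            as.character(modes[[q]][cl]))
      }
    }
    total <- total + d
  }
  total
}

naive_assign <- function(x_num, x_cat, centers, modes, gamma) {
  n <- nrow(x_num)
  k <- nrow(centers)
  out <- integer(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (cl in seq_len(k)) {
      d <- sum((x_num[i, ] - centers[cl, ])^2)
      if (!is.null(x_cat)) {
        for (q in seq_along(x_cat)) {
          d <- d + gamma * (as.character(x_cat[[q]][i]) !=
                              as.character(modes[[q]][cl]))
        }
      }
      if (d < best - 1e-12) {
        best <- d
        out[i] <- cl
      }
    }
  }
  out
}

# hand-built two-navigator cohort with fully scripted encounters, for
# exact plumbing checks of the simulation harness
scripted_cohort <- function() {
  cfg <- cohort_config(
    n_weeks = 4,
    specialties = data.frame(specialty_id = "solo", n_navigators = 2L,
                             arrival_rate = 1),
    interaction_log = FALSE,
    seed = 1
  )
  patients <- data.frame(
    patient_id = "P1", specialty_id = "solo", arrival_week = 0L,
    arrival_day = 0L, diagnosis_day = -5L, base_rate = 0.1,
    service_days = 28L, last_interaction_day = 16L,
    active_end_day = 106L, age = 60L, sex = "F", insurance = "Medicare",
    cancer_type = "solo_primary", adi = 50, rucc = 4,
    prior_admissions = 0L, er_visits = 0L,
    historical_navigator = "solo-N1", stringsAsFactors = FALSE
  )
  encounters <- data.frame(
    patient_id = "P1", specialty_id = "solo",
    day = c(1L, 3L, 9L, 16L),  # week 0: 2 encounters, week 1: 1, week 2: 1
    stringsAsFactors = FALSE
  )
  structure(
    list(config = cfg, patients = patients, encounters = encounters,
         interactions = NULL,
         split = list(train = character(0), test = "P1")),
    class = "cpn_cohort"
  )
}
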