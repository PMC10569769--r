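#' Configuration for the synthetic CPN cohort generator
#'
#' Builds the configuration object consumed by [generate_cohort()]. The
#' defaults encode the study conditions the generator is calibrated to:
#' a 150-week observation window; five cancer specialties staffed by 13
#' navigators in total (two specialties with two navigators, three with
#' three); mean weekly arrival rates of 13.4 new patients for
#' two-navigator specialties and 20.1 for three-navigator specialties;
#' a 90-day active tail after the last navigator interaction; and a
#' zero-inflated daily encounter model whose 30-day aggregates reproduce
#' the reference workload-proxy distribution (per-patient monthly
#' encounter counts with median 0, mean ~0.5, SD ~1.1, coefficient of
#' variation ~220%, capped at 15).
#'
#' @param n_weeks Number of simulated weeks (Mondays) of patient
#'   arrivals.
#' @param specialties Data frame with columns `specialty_id`,
#'   `n_navigators` (>= 2) and `arrival_rate` (mean new patients/week).
#' @param active_tail_days Days a patient remains active after the last
#'   interaction.
#' @param encounter_model Parameters of the zero-inflated encounter
#'   process; see Details.
#' @param feature_signal_strength Value in `[0, 1]` controlling how
#'   strongly the static covariates (ADI, RUCC, utilization counts) are
#'   associated with a patient's latent encounter intensity. At 0 the
#'   covariates are pure noise; at 1 (default) they carry the full
#'   designed signal.
#' @param arrival_model `"poisson"` (default) or `"nbinom"` for
#'   overdispersed weekly arrivals.
#' @param arrival_size Negative-binomial size parameter when
#'   `arrival_model = "nbinom"`.
#' @param train_fraction Fraction of patients assigned to the training
#'   partition (patient-level split).
#' @param interaction_log Generate a full EHR-style interaction log
#'   (notes, encounters, other touches with navigator ids) in addition
#'   to the encounter-day table? Needed by [evaluate_proxies()].
#' @param seed Integer seed; the generator is deterministic given the
#'   config.
#'
#' @details
#' The encounter model gives each patient a latent daily encounter
#' probability: with probability `p_zero` the patient is a low-need
#' patient who generates only the intake encounter; otherwise the daily
#' probability is drawn from a Gamma(`shape`, scale = `scale`)
#' distribution capped at `max_daily_p`. Encounters occur as independent
#' daily Bernoulli events (at most one encounter per patient per day, by
#' the definition of the `enct` workload proxy) over a service period of
#' lognormal duration, and each consecutive 30-day block is capped at
#' `monthly_cap` encounters. These defaults were calibrated once, by
#' moment matching, to the reference monthly workload statistics.
#'
#' @return A list of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_weeks = 150,
                          specialties = default_specialties(),
                          active_tail_days = 90,
                          encounter_model = list(),
                          feature_signal_strength = 1,
                          arrival_model = c("poisson", "nbinom"),
                          arrival_size = 5,
                          train_fraction = 0.8,
                          interaction_log = TRUE,
                          seed = 1L) {
  arrival_model <- match.arg(arrival_model)
  em <- utils::modifyList(default_encounter_model(), encounter_model)
  stopifnot(
    is.data.frame(specialties),
    all(c("specialty_id", "n_navigators", "arrival_rate") %in%
          names(specialties)),
    n_weeks >= 1,
    active_tail_days >= 0,
    feature_signal_strength >= 0, feature_signal_strength <= 1,
    train_fraction > 0, train_fraction < 1
  )
  if (nrow(specialties) == 0) {
    stop("at least one specialty is required", call. = FALSE)
  }
  if (any(specialties$n_navigators < 2)) {
    stop("only specialties with >= 2 navigators are in scope",
         call. = FALSE)
  }
  if (any(specialties$arrival_rate <= 0)) {
    stop("arrival_rate must be positive", call. = FALSE)
  }
  if (is.null(seed) || is.na(seed)) stop("a seed is required", call. = FALSE)
  structure(
    list(
      n_weeks = as.integer(n_weeks),
      specialties = specialties,
      active_tail_days = as.integer(active_tail_days),
      encounter_model = em,
      feature_signal_strength = feature_signal_strength,
      arrival_model = arrival_model,
      arrival_size = arrival_size,
      train_fraction = train_fraction,
      interaction_log = isTRUE(interaction_log),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Default specialty roster
#'
#' Two specialties with two navigators and three with three (13
#' navigators in total), with the default arrival rates of 13.4 and
#' 20.1 new patients/week respectively.
#'
#' @return Data frame with `specialty_id`, `n_navigators`,
#'   `arrival_rate`.
#' @export
default_specialties <- function() {
  data.frame(
    specialty_id = c("breast", "gastrointestinal", "thoracic",
                     "genitourinary", "hematology"),
    n_navigators = c(3L, 3L, 3L, 2L, 2L),
    arrival_rate = c(20.1, 20.1, 20.1, 13.4, 13.4),
    stringsAsFactors = FALSE
  )
}

default_encounter_model <- function() {
  list(
    p_zero = 0.66,        # fraction of low-need (intake-only) patients
    shape = 0.6,          # Gamma shape of daily encounter probability
    scale = 0.065,        # Gamma scale of daily encounter probability
    max_daily_p = 0.45,   # cap on the daily encounter probability
    monthly_cap = 15,     # max encounters per 30-day block
    duration_meanlog = log(75),  # lognormal service duration (days)
    duration_sdlog = 0.7,
    duration_min = 7,
    duration_max = 450
  )
}

insurance_categories <- function() {
  c("Medicare", "Medicaid", "Self-pay", "Commercial (non-BC/BS)",
    "Blue Cross/Blue Shield", "Others")
}

#' Generate a synthetic longitudinal CPN cohort
#'
#' Simulates the full data set the distribution pipeline consumes:
#' weekly patient arrivals per specialty, per-patient latent encounter
#' intensities, static demographic/utilization/clinical covariates
#' correlated with intensity, daily encounter days over each patient's
#' service period, and (optionally) an EHR-style interaction log with
#' historical round-robin navigator assignments. Patients are active
#' from their first interaction until `active_tail_days` (default 90)
#' days after their last interaction. The output is deterministic for a
#' fixed config (including its seed).
#'
#' Time is measured in integer days with day 0 a Monday; Mondays are the
#' days divisible by 7, and arrivals are placed on Mondays. An ISO
#' calendar date can be attached via `day + as.Date("2019-01-07")`.
#'
#' @param config A [cohort_config()].
#' @return An object of class `cpn_cohort`: a list with elements
#'   `config`, `patients` (one row per patient: ids, arrival day,
#'   latent intensity, covariates, activity window), `encounters`
#'   (one row per patient per encounter day), `interactions` (EHR-style
#'   event log, or `NULL`), and `split` (train/test patient ids).
#' @examples
#' cfg <- cohort_config(n_weeks = 8, seed = 42)
#' coh <- generate_cohort(cfg)
#' head(coh$patients)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_local_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  sp <- config$specialties
  em <- config$encounter_model
  nw <- config$n_weeks

  ## weekly arrivals per specialty
  arr <- lapply(seq_len(nrow(sp)), function(g) {
    counts <- if (config$arrival_model == "poisson") {
      rpois(nw, sp$arrival_rate[g])
    } else {
      stats::rnbinom(nw, size = config$arrival_size, mu = sp$arrival_rate[g])
    }
    data.frame(
      specialty_id = sp$specialty_id[g],
      arrival_week = rep.int(seq_len(nw) - 1L, counts)
    )
  })
  pat <- do.call(rbind, arr)
  n <- nrow(pat)
  if (n == 0) stop("no patients generated; increase rates or weeks",
                   call. = FALSE)
  pat$patient_id <- sprintf("P%05d", seq_len(n))
  pat$arrival_day <- pat$arrival_week * 7L
  pat$diagnosis_day <- pat$arrival_day -
    pmax(0L, round(rlnorm(n, log(20), 0.8)))

  ## latent intensity: zero-inflated gamma daily encounter probability
  engaged <- runif(n) >= em$p_zero
  lambda <- numeric(n)
  lambda[engaged] <- pmin(
    rgamma(sum(engaged), shape = em$shape, scale = em$scale),
    em$max_daily_p
  )
  pat$base_rate <- lambda
  pat$service_days <- pmin(
    pmax(round(rlnorm(n, em$duration_meanlog, em$duration_sdlog)),
         em$duration_min),
    em$duration_max
  )

  ## daily encounters: guaranteed intake on day 1, then Bernoulli(lambda)
  ## over the service period; <= 1/day by construction (enct proxy)
  reps <- pat$service_days
  pidx <- rep.int(seq_len(n), reps)
  offs <- sequence(reps)  # days 1..D after arrival
  hit <- runif(length(pidx)) < lambda[pidx]
  hit[offs == 1L] <- TRUE  # intake encounter the day after the arrival Monday
  enc <- data.frame(p = pidx[hit], offset = offs[hit])

  ## cap each consecutive 30-day block at monthly_cap encounters
  block <- (enc$offset - 1L) %/% 30L
  o <- order(enc$p, enc$offset)
  enc <- enc[o, ]
  block <- block[o]
  key <- paste(enc$p, block)
  within_block <- sequence(rle(key)$lengths)
  enc <- enc[within_block <= em$monthly_cap, ]

  enc$patient_id <- pat$patient_id[enc$p]
  enc$day <- pat$arrival_day[enc$p] + enc$offset
  last_off <- vapply(split(enc$offset, enc$p), max, numeric(1))
  pat$last_interaction_day <- pat$arrival_day
  pat$last_interaction_day[as.integer(names(last_off))] <-
    pat$arrival_day[as.integer(names(last_off))] + as.integer(last_off)
  pat$active_end_day <- pat$last_interaction_day + config$active_tail_days

  ## static covariates, blended with the latent intensity by the
  ## feature signal strength s: corr(covariate driver, intensity) ~ s
  s <- config$feature_signal_strength
  z <- log1p(lambda * 30)
  z <- (z - mean(z)) / max(sd(z), 1e-9)
  blend <- function() s * z + sqrt(max(0, 1 - s^2)) * rnorm(n)
  pat$adi <- pmin(pmax(round(55 + 20 * blend() + 5 * rnorm(n)), 1), 100)
  pat$rucc <- pmin(pmax(round(4 + 1.8 * blend() + 0.8 * rnorm(n)), 1), 9)
  pat$prior_admissions <- rpois(n, exp(-0.3 + 0.7 * blend()))
  pat$er_visits <- rpois(n, exp(-0.8 + 0.6 * blend()))
  pat$age <- pmin(pmax(round(rnorm(n, 62, 12)), 18), 95)
  pat$sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.6, 0.4))
  pat$insurance <- sample(insurance_categories(), n, replace = TRUE,
                          prob = c(0.42, 0.12, 0.03, 0.20, 0.16, 0.07))
  pat$cancer_type <- paste0(pat$specialty_id, "_",
                            sample(c("primary", "secondary"), n,
                                   replace = TRUE, prob = c(0.8, 0.2)))

  ## historical round-robin navigator (for the interaction log only;
  ## simulated policies assign their own navigators)
  pat$historical_navigator <- NA_character_
  for (g in seq_len(nrow(sp))) {
    i <- which(pat$specialty_id == sp$specialty_id[g])
    i <- i[order(pat$arrival_day[i])]
    pat$historical_navigator[i] <- sprintf(
      "%s-N%d", sp$specialty_id[g],
      ((seq_along(i) - 1L) %% sp$n_navigators[g]) + 1L
    )
  }

  encounters <- data.frame(
    patient_id = enc$patient_id,
    specialty_id = pat$specialty_id[enc$p],
    day = enc$day,
    stringsAsFactors = FALSE
  )
  encounters <- encounters[order(encounters$patient_id, encounters$day), ]
  rownames(encounters) <- NULL

  interactions <- if (config$interaction_log) {
    build_interaction_log(pat, enc)
  }

  split <- split_by_patient(pat$patient_id,
                            train_fraction = config$train_fraction)

  pat <- pat[order(pat$patient_id),
             c("patient_id", "specialty_id", "arrival_week", "arrival_day",
               "diagnosis_day", "base_rate", "service_days",
               "last_interaction_day", "active_end_day", "age", "sex",
               "insurance", "cancer_type", "adi", "rucc",
               "prior_admissions", "er_visits", "historical_navigator")]
  rownames(pat) <- NULL

  structure(
    list(config = config, patients = pat, encounters = encounters,
         interactions = interactions, split = split),
    class = "cpn_cohort"
  )
}

## EHR-style event log: encounters plus note/other events whose volume is
## noisier than encounter volume, so the enct proxy tracks panel size best
build_interaction_log <- function(pat, enc) {
  nav <- pat$historical_navigator[enc$p]
  base <- data.frame(
    patient_id = enc$patient_id, day = enc$day,
    hour = round(runif(nrow(enc), 8, 16), 2),
    kind = "encounter", navigator_id = nav, stringsAsFactors = FALSE
  )
  ## navigator-specific documentation habits decouple note volume from
  ## true encounter volume, degrading the note proxies' correlation
  navs <- unique(nav)
  note_p <- stats::setNames(runif(length(navs), 0.4, 0.95), navs)
  note <- base[runif(nrow(base)) < note_p[base$navigator_id], ]
  if (nrow(note)) {
    note$kind <- "note_create"
    note$hour <- pmin(note$hour + round(runif(nrow(note), 0.2, 2), 2), 19)
  }
  habit <- stats::setNames(rgamma(length(navs), shape = 1.2, scale = 1.2),
                           navs)
  n_edit <- rpois(nrow(base), habit[base$navigator_id])
  edit <- base[rep.int(seq_len(nrow(base)), n_edit), ]
  if (nrow(edit)) {
    edit$kind <- "note_edit"
    edit$day <- edit$day + sample(0:6, nrow(edit), replace = TRUE)
    edit$hour <- round(runif(nrow(edit), 7, 18), 2)
  }
  touch <- base
  touch$kind <- "other_ehr_touch"
  touch$hour <- round(runif(nrow(touch), 7, 18), 2)
  log <- rbind(base, note, edit, touch)
  log <- log[order(log$navigator_id, log$day, log$hour), ]
  rownames(log) <- NULL
  log
}

#' @export
print.cpn_cohort <- function(x, ...) {
  cat(sprintf(
    "<cpn_cohort> %d patients, %d specialties, %d weeks, %d encounter-days\n",
    nrow(x$patients), nrow(x$config$specialties), x$config$n_weeks,
    nrow(x$encounters)
  ))
  cat(sprintf("  train/test patients: %d/%d; seed %d\n",
              length(x$split$train), length(x$split$test), x$config$seed))
  invisible(x)
}

#' Latent weekly encounter intensity of one patient
#'
#' Couples a patient's latent daily encounter probability with a simple
#' service-phase profile: the full rate while the patient is in the
#' active service period, zero afterwards.
#'
#' @param patient_id Identifier.
#' @param base_rate Daily encounter probability, in `[0, 1]`.
#' @param service_weeks Length of the service period in weeks.
#' @return Object of class `latent_intensity`.
#' @seealso [sample_weekly_encounters()]
#' @export
latent_intensity <- function(patient_id, base_rate, service_weeks = 12) {
  stopifnot(base_rate >= 0, base_rate <= 1, service_weeks >= 0)
  structure(list(patient_id = patient_id, base_rate = base_rate,
                 service_weeks = service_weeks),
            class = "latent_intensity")
}

#' Sample one week of encounters for a patient
#'
#' Draws the number of encounter days in one week for a patient with a
#' given latent intensity: seven independent daily Bernoulli events at
#' the phase-adjusted daily rate, so the weekly count never exceeds 7
#' (at most one encounter per patient per day).
#'
#' @param intensity A [latent_intensity()].
#' @param week Week index since enrollment (0-based); the patient must
#'   be active.
#' @return Integer count in `0..7`, drawn from the current RNG stream.
#' @export
sample_weekly_encounters <- function(intensity, week = 0) {
  stopifnot(inherits(intensity, "latent_intensity"), week >= 0)
  phase <- if (week < intensity$service_weeks) 1 else 0
  rbinom(1, 7, min(intensity$base_rate * phase, 1))
}

#' Per-patient monthly (30-day) encounter counts
#'
#' Aggregates each patient's encounter days into consecutive 30-day
#' blocks spanning the patient's active window (first interaction to 90
#' days after the last). Months with no encounters count as zeros.
#'
#' @param cohort A `cpn_cohort`.
#' @return Integer vector of patient-month encounter counts.
#' @export
monthly_counts <- function(cohort) {
  stopifnot(inherits(cohort, "cpn_cohort"))
  pat <- cohort$patients
  n_months <- ceiling((pat$active_end_day - pat$arrival_day) / 30)
  n_months <- pmax(n_months, 1L)
  enc <- cohort$encounters
  pi <- match(enc$patient_id, pat$patient_id)
  month_of <- (enc$day - pat$arrival_day[pi] - 1L) %/% 30L  # 0-based
  offset <- c(0L, cumsum(n_months))[seq_len(nrow(pat))]
  counts <- tabulate(offset[pi] + month_of + 1L, nbins = sum(n_months))
  as.integer(counts)
}

#' Monthly workload distribution statistics
#'
#' Summary statistics of per-patient 30-day encounter counts: mean,
#' sample SD, median, coefficient of variation (100 x SD/mean), maximum,
#' and two skewness measures. `skew` is Pearson's second (median)
#' skewness coefficient, `3 * (mean - median) / SD`, the measure
#' consistent with the reference workload statistics; `skew_moment` is
#' the adjusted Fisher-Pearson moment skewness
#' `g1 * sqrt(n(n-1)) / (n-2)`, reported alongside for completeness.
#'
#' @param x A `cpn_cohort` (monthly counts are computed with
#'   [monthly_counts()]) or a numeric vector of monthly counts.
#' @return A list with `n`, `mean`, `sd`, `median`, `cv_percent`,
#'   `skew`, `skew_moment`, `max`.
#' @examples
#' monthly_workload_stats(c(0, 0, 0, 2))
#' @export
monthly_workload_stats <- function(x) {
  counts <- if (inherits(x, "cpn_cohort")) monthly_counts(x) else as.numeric(x)
  if (length(counts) == 0) stop("empty dataset", call. = FALSE)
  n <- length(counts)
  m <- mean(counts)
  s <- if (n >= 2) sd(counts) else 0
  if (m == 0) {
    stop("mean monthly count is 0: coefficient of variation undefined",
         call. = FALSE)
  }
  med <- median(counts)
  skew_m <- if (s == 0 || n < 3) {
    0  # no variation: moment skewness taken as 0 by convention
  } else {
    g1 <- mean((counts - m)^3) / (mean((counts - m)^2))^1.5
    g1 * sqrt(n * (n - 1)) / (n - 2)
  }
  skew_p <- if (s == 0) 0 else 3 * (m - med) / s
  list(n = n, mean = m, sd = s, median = med,
       cv_percent = 100 * s / m, skew = skew_p, skew_moment = skew_m,
       max = max(counts))
}

## evaluate expr with a temporary RNG state seeded by `seed`
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
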