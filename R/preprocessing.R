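#' Drop features with a high fraction of missing values
#'
#' Removes every column whose fraction of missing values is greater
#' than or equal to `null_fraction_threshold` (default 0.8: a column
#' with 80% or more nulls is removed). Column order is otherwise
#' preserved.
#'
#' @param table A data frame.
#' @param null_fraction_threshold Threshold in `(0, 1]`.
#' @return The data frame without the sparse columns.
#' @export
drop_sparse_features <- function(table, null_fraction_threshold = 0.8) {
  stopifnot(is.data.frame(table),
            null_fraction_threshold > 0, null_fraction_threshold <= 1)
  if (nrow(table) == 0) return(table)
  frac <- vapply(table, function(col) mean(is.na(col)), numeric(1))
  table[, frac < null_fraction_threshold, drop = FALSE]
}

#' Map a raw insurance plan name to one of six categories
#'
#' Collapses free-text plan names into the six insurance categories
#' used for modelling: Medicare, Medicaid, Self-pay, Commercial
#' (non-BC/BS), Blue Cross/Blue Shield, and Others. Missing or
#' unrecognized values map to Others. The keyword table ships with the
#' package (`inst/extdata/insurance_keywords.csv`); Blue Cross/Blue
#' Shield keywords take precedence over generic commercial keywords.
#'
#' @param raw_plan Character vector of raw plan names (may contain NA).
#' @return Character vector of categories.
#' @examples
#' map_insurance(c("MEDICARE PART B", "BCBS PPO", NA, "ACME GOLD"))
#' @export
map_insurance <- function(raw_plan) {
  kw <- insurance_keyword_table()
  up <- toupper(trimws(as.character(raw_plan)))
  out <- rep("Others", length(raw_plan))
  for (i in seq_len(nrow(kw))) {  # first matching rule wins
    hit <- out == "Others" & !is.na(up) & grepl(kw$pattern[i], up)
    out[hit] <- kw$category[i]
  }
  out[is.na(up) | up == ""] <- "Others"
  out
}

insurance_keyword_table <- function() {
  path <- system.file("extdata", "insurance_keywords.csv",
                      package = "navfair")
  if (nzchar(path)) {
    read.csv(path, stringsAsFactors = FALSE)
  } else {  # fallback when running from a source checkout
    read.csv(file.path("inst", "extdata", "insurance_keywords.csv"),
             stringsAsFactors = FALSE)
  }
}

#' Impute numeric columns from training-set means
#'
#' Replaces missing values in the given columns of `apply_table` (and of
#' `train_table`) by the mean of the non-missing TRAINING values only,
#' so no test-set information leaks into the imputation constant.
#'
#' @param train_table Training data frame.
#' @param apply_table Data frame to impute (e.g. the test set).
#' @param columns Character vector of numeric column names (default ADI
#'   and RUCC).
#' @return `apply_table` with the columns imputed.
#' @export
impute_numeric <- function(train_table, apply_table,
                           columns = c("adi", "rucc")) {
  stopifnot(all(columns %in% names(train_table)),
            all(columns %in% names(apply_table)))
  for (cl in columns) {
    tv <- train_table[[cl]]
    if (all(is.na(tv))) {
      stop(sprintf("column '%s' is all-missing in the training set", cl),
           call. = FALSE)
    }
    m <- mean(tv, na.rm = TRUE)
    apply_table[[cl]][is.na(apply_table[[cl]])] <- m
  }
  apply_table
}

#' Average nine-digit-zip ADI values into a five-digit-zip value
#'
#' The Area Deprivation Index is published per nine-digit zip code; when
#' only a five-digit zip is known, the arithmetic mean over its
#' nine-digit constituents is used.
#'
#' @param nine_digit_adis Numeric vector of ADI values.
#' @return Mean ADI, or `NA` for an empty vector (to be imputed
#'   downstream by [impute_numeric()]).
#' @export
average_adi <- function(nine_digit_adis) {
  x <- as.numeric(nine_digit_adis)
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  mean(x)
}

#' Activity window of a patient
#'
#' A patient is active from the first navigator interaction until
#' `tail_days` (default 90) days after the last interaction.
#'
#' @param interaction_days Integer/numeric vector of interaction days
#'   for one patient (at least one).
#' @param tail_days Days of activity after the last interaction.
#' @return Named numeric vector `c(start, end)`.
#' @examples
#' active_window(c(0, 10)) # c(start = 0, end = 100)
#' @export
active_window <- function(interaction_days, tail_days = 90) {
  x <- as.numeric(interaction_days)
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    stop("patient has no interactions and must be excluded", call. = FALSE)
  }
  c(start = min(x), end = max(x) + tail_days)
}

#' Patient-level train/test split
#'
#' Randomly partitions patients into a training and a test set so that
#' all rows of any patient fall on the same side. The training fraction
#' is honoured to within one patient.
#'
#' @param patients Vector of unique patient identifiers (>= 2).
#' @param train_fraction Fraction of patients in the training set.
#' @param seed Optional integer seed; if `NULL` the current RNG stream
#'   is used.
#' @return A list with character vectors `train` and `test`.
#' @export
split_by_patient <- function(patients, train_fraction = 0.8, seed = NULL) {
  patients <- unique(as.character(patients))
  if (length(patients) < 2) stop("need at least 2 patients", call. = FALSE)
  stopifnot(train_fraction > 0, train_fraction < 1)
  do_split <- function() {
    n_train <- round(train_fraction * length(patients))
    n_train <- min(max(n_train, 1L), length(patients) - 1L)
    train <- sort(sample(patients, n_train))
    list(train = train, test = sort(setdiff(patients, train)))
  }
  if (is.null(seed)) do_split() else with_local_seed(seed, do_split())
}

#' Build the weekly (Monday-sampled) modelling table for a cohort
#'
#' Constructs one row per active patient per Monday, carrying the static
#' covariates, date-derived features (days since first interaction,
#' days since last interaction, days since diagnosis), short-term
#' utilization trend features (encounter counts over the trailing 28 and
#' 56 days), and the prediction target: the number of encounter days in
#' the following week, counted over the half-open window
#' `(monday, monday + 7]`.
#'
#' Mondays beyond the cohort's arrival horizon are dropped so that every
#' retained row has a fully populated target.
#'
#' @param cohort A `cpn_cohort`.
#' @param partition `"all"`, `"train"`, or `"test"` — which patient
#'   partition to build rows for.
#' @return Data frame with one row per active patient-week; columns
#'   include `patient_id`, `specialty_id`, `week`, `monday`, `is_new`
#'   (patient arrived on this Monday), the features, and
#'   `target_next_week`.
#' @export
build_model_table <- function(cohort,
                              partition = c("all", "train", "test")) {
  stopifnot(inherits(cohort, "cpn_cohort"))
  partition <- match.arg(partition)
  pat <- cohort$patients
  if (partition != "all") {
    pat <- pat[pat$patient_id %in% cohort$split[[partition]], ]
  }
  n_weeks <- cohort$config$n_weeks

  ## active Mondays per patient, clipped to the simulation horizon
  first_w <- ceiling(pat$arrival_day / 7)
  last_w <- pmin(pat$active_end_day %/% 7, n_weeks - 1L)
  keep <- first_w <= last_w
  pat <- pat[keep, ]
  first_w <- first_w[keep]
  last_w <- last_w[keep]
  counts <- last_w - first_w + 1L
  pidx <- rep.int(seq_len(nrow(pat)), counts)
  week <- unlist(lapply(seq_along(counts),
                        function(i) seq.int(first_w[i], last_w[i])),
                 use.names = FALSE)

  rows <- pat[pidx, c("patient_id", "specialty_id", "age", "sex",
                      "insurance", "cancer_type", "adi", "rucc",
                      "prior_admissions", "er_visits")]
  rows$week <- as.integer(week)
  rows$monday <- rows$week * 7L
  rows$is_new <- pat$arrival_day[pidx] == rows$monday
  rows$days_since_first_interaction <- rows$monday - pat$arrival_day[pidx]
  rows$days_since_diagnosis <- rows$monday - pat$diagnosis_day[pidx]

  ## encounter-derived columns, keyed by (patient, week)
  enc <- cohort$encounters
  enc <- enc[enc$patient_id %in% pat$patient_id, ]
  ei <- match(enc$patient_id, pat$patient_id)
  K <- n_weeks + 64L  # key stride; encounters can extend past the horizon
  rkey <- (match(rows$patient_id, pat$patient_id) - 1L) * K + rows$week

  ## target: encounters in (monday, monday + 7] belong to the Monday
  ## floor((day - 1)/7); the next Monday's encounter goes to that week
  tweek <- (enc$day - 1L) %/% 7L
  tgt <- tapply_sum_int((ei - 1L) * K + tweek)
  rows$target_next_week <- lookup_counts(tgt, rkey)

  ## trailing utilization trends: encounters in (monday - 28, monday]
  ## and (monday - 56, monday]
  trend <- function(days_back) {
    nb <- days_back %/% 7L
    contrib <- rep.int((ei - 1L) * K, nb) +
      as.vector(vapply(seq_len(nb), function(k) tweek + k,
                       integer(length(tweek))))
    counts <- tapply_sum_int(contrib)
    lookup_counts(counts, rkey)
  }
  rows$enc_last_4wk <- trend(28L)
  rows$enc_last_8wk <- trend(56L)

  ## days since last interaction as of the Monday (inclusive); the
  ## arrival day itself counts as the first interaction
  last_seen <- last_day_by_week(enc$day, ei, first_w, last_w,
                                pat$arrival_day)
  rows$days_since_last_interaction <- rows$monday -
    last_seen[cbind(pidx, week - first_w[pidx] + 1L)]
  rows <- rows[order(rows$week, rows$patient_id), ]
  rownames(rows) <- NULL
  rows
}

## sum of ones per integer key, returned as named lookup environment-free
tapply_sum_int <- function(keys) {
  t <- table(keys)
  data.frame(key = as.numeric(names(t)), n = as.integer(t))
}

lookup_counts <- function(counts, keys) {
  i <- match(keys, counts$key)
  out <- counts$n[i]
  out[is.na(out)] <- 0L
  out
}

## for each patient (row) and active week (col), the most recent
## interaction day <= that Monday (the arrival day counts)
last_day_by_week <- function(days, pidx, first_w, last_w, arrival_day) {
  n_pat <- length(arrival_day)
  out <- matrix(NA_real_, n_pat, max(last_w - first_w + 1L))
  sp <- split(days, factor(pidx, levels = seq_len(n_pat)))
  for (i in seq_len(n_pat)) {
    d <- sort(c(arrival_day[i], sp[[i]]))
    wks <- seq.int(first_w[i], last_w[i])
    pos <- pmax(findInterval(wks * 7L, d), 1L)
    out[i, seq_along(wks)] <- d[pos]
  }
  out
}

#' Build weekly rows from a generic daily table
#'
#' Retains only Monday rows (day index divisible by 7, with day 0 a
#' Monday) of a one-row-per-patient-per-day table, and drops trailing
#' Mondays whose 7-day target window extends beyond the table's
#' coverage, so every retained row can carry a populated target.
#'
#' @param daily_table Data frame with columns `patient_id` and `day`.
#' @param coverage_end Last day covered by the encounter log (default:
#'   the maximum day in the table).
#' @return The Monday-filtered data frame.
#' @export
build_weekly_rows <- function(daily_table, coverage_end = NULL) {
  stopifnot(all(c("patient_id", "day") %in% names(daily_table)))
  if (is.null(coverage_end)) coverage_end <- max(daily_table$day)
  out <- daily_table[daily_table$day %% 7 == 0 &
                       daily_table$day + 7 <= coverage_end, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label weekly rows with the next-week encounter target
#'
#' For each Monday row, counts the patient's encounter days in the
#' half-open window `(monday, monday + 7]`. Rows whose window is not
#' fully covered by the encounter log are dropped.
#'
#' @param weekly_rows Data frame with `patient_id` and `day` (a Monday).
#' @param encounter_log Data frame with `patient_id` and `day`, one row
#'   per encounter day.
#' @param coverage_end Last day covered by the log (default: its max).
#' @return `weekly_rows` with a `target_next_week` column.
#' @export
label_target <- function(weekly_rows, encounter_log, coverage_end = NULL) {
  stopifnot(all(c("patient_id", "day") %in% names(weekly_rows)),
            all(c("patient_id", "day") %in% names(encounter_log)))
  if (is.null(coverage_end)) coverage_end <- max(encounter_log$day)
  dropped <- weekly_rows$day + 7 > coverage_end
  if (any(dropped)) {
    message(sprintf("label_target: dropped %d row(s) without full %s",
                    sum(dropped), "7-day target coverage"))
  }
  out <- weekly_rows[!dropped, , drop = FALSE]
  key_r <- paste(out$patient_id, (out$day %/% 7))
  key_e <- paste(encounter_log$patient_id, (encounter_log$day - 1) %/% 7)
  t <- table(key_e)
  cnt <- as.integer(t)[match(key_r, names(t))]
  out$target_next_week <- ifelse(is.na(cnt), 0L, cnt)
  rownames(out) <- NULL
  out
}

#' Evaluate candidate workload-proxy metrics against panel size
#'
#' For each candidate proxy — notes written (`notct`), notes created or
#' edited (`notct2`), encounter days counting at most one encounter per
#' patient per day (`enct`), and the daily first-to-last EHR-touch time
#' span in hours (`dur`) — computes the average daily value per
#' navigator over each 30-day month, pairs it with the navigator's
#' active panel size that month, and reports the Pearson correlation
#' across navigator-months. The proxy that tracks panel size most
#' strongly ranks first.
#'
#' @param log Interaction log: data frame with `patient_id`, `day`,
#'   `hour`, `kind` (one of `note_create`, `note_edit`, `encounter`,
#'   `other_ehr_touch`) and `navigator_id`.
#' @param panels Optional data frame `navigator_id`, `month`,
#'   `panel_size`. If `NULL`, panel sizes are derived from the log: a
#'   patient belongs to a navigator's panel in every month overlapping
#'   the patient's activity window ([active_window()] of their
#'   interaction days).
#' @param tail_days Activity tail used when deriving panels.
#' @return Data frame with one row per metric: `metric`, `pearson_r`,
#'   `rank` (1 = best; `NA` correlation ranks last), sorted by rank.
#' @export
evaluate_proxies <- function(log, panels = NULL, tail_days = 90) {
  needed <- c("patient_id", "day", "kind", "navigator_id")
  stopifnot(all(needed %in% names(log)))
  if (!"hour" %in% names(log)) log$hour <- 12
  log$month <- log$day %/% 30L
  if (max(log$month) - min(log$month) < 1) {
    stop("need at least 2 months of data", call. = FALSE)
  }

  if (is.null(panels)) panels <- derive_panels(log, tail_days)
  key <- function(nav, mo) paste(nav, mo)
  pk <- key(panels$navigator_id, panels$month)

  per_day_avg <- function(sub, value_per_navmonth) {
    v <- value_per_navmonth(sub)
    v$value <- v$value / 30
    v
  }
  count_rows <- function(sub) {
    if (nrow(sub) == 0) {
      return(data.frame(navigator_id = character(0), month = integer(0),
                        value = numeric(0)))
    }
    aggregate(list(value = sub$day), by = list(
      navigator_id = sub$navigator_id, month = sub$month), FUN = length)
  }
  metrics <- list(
    notct = function(l) count_rows(l[l$kind == "note_create", ]),
    notct2 = function(l) count_rows(l[l$kind %in%
                                        c("note_create", "note_edit"), ]),
    enct = function(l) {
      e <- l[l$kind == "encounter", ]
      e <- e[!duplicated(paste(e$patient_id, e$day)), ]  # <= 1/patient/day
      count_rows(e)
    },
    dur = function(l) {
      span <- aggregate(list(lo = l$hour), by = list(
        navigator_id = l$navigator_id, day = l$day, month = l$month),
        FUN = min)
      span$hi <- aggregate(l$hour, by = list(
        l$navigator_id, l$day, l$month), FUN = max)$x
      aggregate(list(value = span$hi - span$lo), by = list(
        navigator_id = span$navigator_id, month = span$month), FUN = sum)
    }
  )
  res <- lapply(names(metrics), function(nm) {
    v <- per_day_avg(log, metrics[[nm]])
    x <- numeric(nrow(panels))
    i <- match(pk, key(v$navigator_id, v$month))
    x <- ifelse(is.na(i), 0, v$value[i])
    r <- if (sd(x) == 0 || sd(panels$panel_size) == 0) {
      NA_real_  # constant series: correlation undefined
    } else {
      cor(x, panels$panel_size)
    }
    data.frame(metric = nm, pearson_r = r)
  })
  out <- do.call(rbind, res)
  out$rank <- rank(-replace(out$pearson_r, is.na(out$pearson_r), -Inf),
                   ties.method = "first")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  out
}

derive_panels <- function(log, tail_days) {
  ## a patient's navigator is the most frequent navigator in their events
  by_pat <- split(log$navigator_id, log$patient_id)
  nav_of <- vapply(by_pat, function(v) names(which.max(table(v))), "")
  win <- t(vapply(split(log$day, log$patient_id),
                  active_window, numeric(2), tail_days = tail_days))
  months <- seq.int(min(log$day) %/% 30L, max(log$day) %/% 30L)
  navs <- sort(unique(log$navigator_id))
  grid <- expand.grid(navigator_id = navs, month = months,
                      stringsAsFactors = FALSE)
  grid$panel_size <- vapply(seq_len(nrow(grid)), function(i) {
    mo_lo <- grid$month[i] * 30
    mo_hi <- mo_lo + 29
    sum(nav_of == grid$navigator_id[i] &
          win[, "start"] <= mo_hi & win[, "end"] >= mo_lo)
  }, numeric(1))
  grid
}
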