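test_that("sparse-feature dropping uses the 80%-or-more rule", {
  n <- 1000
  tab <- data.frame(
    keep = c(rep(NA, 799), rnorm(201)),          # 79.9% null
    drop_exact = c(rep(NA, 800), rnorm(200)),    # exactly 80% null
    drop_all = rep(NA_real_, n),
    full = rnorm(n)
  )
  out <- drop_sparse_features(tab)
  expect_named(out, c("keep", "full"))
})

test_that("insurance mapping hits the six categories with Others as
          fallback", {
  expect_equal(map_insurance("MEDICARE PART B"), "Medicare")
  expect_equal(map_insurance("BCBS PPO"), "Blue Cross/Blue Shield")
  expect_equal(map_insurance("Blue Cross select"),
               "Blue Cross/Blue Shield")
  expect_equal(map_insurance("AETNA PPO GOLD"), "Commercial (non-BC/BS)")
  expect_equal(map_insurance("IL MEDICAID"), "Medicaid")
  expect_equal(map_insurance("SELF-PAY"), "Self-pay")
  expect_equal(map_insurance(NA), "Others")
  expect_equal(map_insurance("MYSTERY PLAN 9"), "Others")
  expect_true(all(map_insurance(c("medicare", "bcbs", "x", NA)) %in%
                    navfair:::insurance_categories()))
})

test_that("numeric imputation uses training means only (no leakage)", {
  train <- data.frame(adi = c(10, 20, NA), rucc = c(1, 2, 3))
  test <- data.frame(adi = NA_real_, rucc = NA_real_)
  out <- impute_numeric(train, test)
  expect_equal(out$adi, 15)
  expect_equal(out$rucc, 2)
  # identity on complete data
  full <- data.frame(adi = c(1, 2), rucc = c(3, 4))
  expect_identical(impute_numeric(train, full), full)
  # mutation test: perturbing test values cannot move the constant
  test2 <- data.frame(adi = c(NA, 999), rucc = c(NA, 999))
  out2 <- impute_numeric(train, test2)
  expect_equal(out2$adi[1], 15)
  expect_error(impute_numeric(data.frame(adi = NA_real_, rucc = 1),
                              test, columns = "adi"), "all-missing")
})

test_that("ADI averaging over nine-digit zips", {
  expect_equal(average_adi(c(40, 60)), 50)
  expect_equal(average_adi(77), 77)
  expect_equal(average_adi(1:4), 2.5)
  expect_true(is.na(average_adi(numeric(0))))
})

test_that("activity window ends 90 days after the last interaction", {
  expect_equal(active_window(5), c(start = 5, end = 95))
  expect_equal(active_window(c(0, 10)), c(start = 0, end = 100))
  # an interaction during the tail extends the tail
  expect_equal(active_window(c(0, 10, 95)), c(start = 0, end = 185))
  expect_error(active_window(numeric(0)), "excluded")
})

test_that("patient-level split partitions patients reproducibly", {
  ids <- sprintf("P%02d", 1:10)
  sp <- split_by_patient(ids, seed = 4)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(sp, split_by_patient(ids, seed = 4))
  expect_error(split_by_patient("P1"), "at least 2")

  # every row of any patient lands on one side
  rows <- data.frame(patient_id = sample(ids, 100, replace = TRUE))
  side <- ifelse(rows$patient_id %in% sp$train, "train", "test")
  expect_true(all(tapply(side, rows$patient_id,
                         function(v) length(unique(v))) == 1))
})

test_that("Monday filtering and target labelling follow the half-open
          week convention", {
  daily <- data.frame(patient_id = "A", day = 0:13)
  expect_equal(build_weekly_rows(daily, coverage_end = Inf)$day, c(0, 7))
  # trailing Monday without 7 days of target follow-up is dropped
  expect_equal(build_weekly_rows(daily)$day, 0)

  weekly <- data.frame(patient_id = "A", day = c(0, 7))
  enc <- data.frame(patient_id = "A", day = c(1, 4, 7, 14))
  lab <- label_target(weekly, enc)
  # Tue & Fri after Monday 0 -> 2; day 7 belongs to week 0's window,
  # day 14 to week 1's window
  expect_equal(lab$target_next_week, c(3, 1))
  # no encounters -> 0
  lab0 <- label_target(weekly,
                       data.frame(patient_id = "B", day = c(1, 20)),
                       coverage_end = 30)
  expect_equal(lab0$target_next_week, c(0, 0))
  # rows without coverage are dropped with a message
  expect_message(
    lab2 <- label_target(data.frame(patient_id = "A", day = c(0, 70)),
                         enc),
    "dropped 1")
  expect_equal(nrow(lab2), 1)
})

test_that("the cohort weekly table is consistent with its encounter log", {
  coh <- generate_cohort(tiny_config(seed = 8))
  tab <- build_model_table(coh)
  # recompute a sample of targets directly from the encounter table
  set.seed(1)
  for (i in sample(nrow(tab), 50)) {
    e <- coh$encounters[coh$encounters$patient_id == tab$patient_id[i], ]
    expect_equal(tab$target_next_week[i],
                 sum(e$day > tab$monday[i] & e$day <= tab$monday[i] + 7))
    expect_equal(tab$enc_last_4wk[i],
                 sum(e$day > tab$monday[i] - 28 & e$day <= tab$monday[i]))
  }
  # one row per active patient per Monday, never off the horizon
  expect_false(any(duplicated(paste(tab$patient_id, tab$week))))
  expect_true(all(tab$week >= 0 & tab$week < coh$config$n_weeks))
  pat <- coh$patients
  i <- match(tab$patient_id, pat$patient_id)
  expect_true(all(tab$monday >= pat$arrival_day[i] &
                    tab$monday <= pat$active_end_day[i]))
})

test_that("proxy evaluation ranks enct first on a constructed log where
          encounters track panels but notes are noise", {
  set.seed(11)
  navs <- c("N1", "N2")
  months <- 0:5
  log <- list()
  pid <- 0
  for (nv in navs) {
    for (mo in months) {
      # panel grows over months for N1, shrinks for N2
      n_pat <- if (nv == "N1") 3 + 2 * mo else 14 - 2 * mo
      for (p in seq_len(n_pat)) {
        pid <- pid + 1
        d <- mo * 30 + sort(sample(0:29, 3))
        log[[length(log) + 1]] <- data.frame(
          patient_id = sprintf("q%04d", pid), day = d,
          hour = runif(3, 8, 16),
          kind = c("encounter", "encounter", "other_ehr_touch"),
          navigator_id = nv)
      }
      # note volume is documentation habit, independent of panel size
      n_note <- rpois(1, 15)
      log[[length(log) + 1]] <- data.frame(
        patient_id = "q0001",
        day = mo * 30 + sample(0:29, n_note, replace = TRUE),
        hour = runif(n_note, 8, 16),
        kind = sample(c("note_create", "note_edit"), n_note,
                      replace = TRUE),
        navigator_id = nv)
    }
  }
  log <- do.call(rbind, log)
  panels <- expand.grid(navigator_id = navs, month = months,
                        stringsAsFactors = FALSE)
  panels$panel_size <- ifelse(panels$navigator_id == "N1",
                              3 + 2 * panels$month, 14 - 2 * panels$month)
  res <- evaluate_proxies(log, panels)
  expect_equal(res$metric[res$rank == 1], "enct")
  r_enct <- res$pearson_r[res$metric == "enct"]
  r_notct2 <- res$pearson_r[res$metric == "notct2"]
  expect_gt(r_enct, r_notct2)

  # duplicate encounters for one patient on one day count once for enct
  dup <- rbind(log, log[log$kind == "encounter", ][1:5, ])
  res_dup <- evaluate_proxies(dup, panels)
  expect_equal(res_dup$pearson_r[res_dup$metric == "enct"], r_enct)

  expect_error(evaluate_proxies(log[log$day < 25, ], panels),
               "2 months")
})

test_that("proxy evaluation ranks enct first on the generated cohort log", {
  coh <- generate_cohort(cohort_config(n_weeks = 25, seed = 7))
  res <- evaluate_proxies(coh$interactions)
  expect_equal(res$metric[res$rank == 1], "enct")
})
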