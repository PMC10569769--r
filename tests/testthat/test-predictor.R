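# labelled table with a learnable deterministic signal, for fast checks
toy_table <- function(n_pat = 60, rows_per = 4, seed = 1) {
  set.seed(seed)
  n <- n_pat * rows_per
  tab <- data.frame(
    patient_id = rep(sprintf("T%03d", seq_len(n_pat)), each = rows_per),
    age = sample(30:80, n, replace = TRUE),
    adi = sample(1:100, n, replace = TRUE),
    rucc = sample(1:9, n, replace = TRUE),
    prior_admissions = rpois(n, 1),
    er_visits = rpois(n, 0.5),
    days_since_first_interaction = sample(0:140, n, replace = TRUE),
    enc_last_4wk = rpois(n, 1),
    enc_last_8wk = rpois(n, 2),
    days_since_last_interaction = sample(0:60, n, replace = TRUE),
    days_since_diagnosis = sample(0:300, n, replace = TRUE),
    sex = sample(c("F", "M"), n, replace = TRUE),
    insurance = sample(c("Medicare", "Others"), n, replace = TRUE),
    cancer_type = "breast_primary",
    cluster_id = sample(c("c1", "c2"), n, replace = TRUE)
  )
  tab$target_next_week <- tab$enc_last_4wk + (tab$adi > 50)
  tab
}

gbt_cfg <- function(nrounds = 150) {
  data.frame(max_depth = 4, eta = 0.2, nrounds = nrounds, subsample = 1,
             colsample_bytree = 1, min_child_weight = 1)
}

test_that("random search respects the sampled-config contract", {
  tab <- toy_table()
  one <- gbt_cfg(20)
  r <- random_search_cv(tab, "gbt", search_space = one, n_samples = 1,
                        folds = 3, seed = 2)
  expect_equal(r$best_config, one)
  expect_length(r$cv_mse, 1)

  # a duplicate of the winner keeps the first sampled as winner
  two <- rbind(one, one)
  expect_warning(
    r2 <- random_search_cv(tab, "gbt", search_space = two, n_samples = 5,
                           folds = 3, seed = 2),
    "distinct configs")
  expect_equal(r2$best_index, 1)
})

test_that("CV folds never split a patient across folds", {
  tab <- toy_table()
  set.seed(3)
  pts <- unique(tab$patient_id)
  fold_of_patient <- sample(rep_len(1:3, length(pts)))
  fold <- fold_of_patient[match(tab$patient_id, pts)]
  expect_true(all(tapply(fold, tab$patient_id,
                         function(v) length(unique(v))) == 1))
})

test_that("tuning improves on an extreme untuned configuration on
          signal-rich data", {
  wins <- 0L
  for (s in 1:5) {
    tab <- toy_table(seed = 400 + s)
    bad <- gbt_cfg(nrounds = 2)  # severely underfit reference
    tuned <- random_search_cv(tab, "gbt", n_samples = 5, folds = 3,
                              seed = 400 + s)
    ref <- random_search_cv(tab, "gbt", search_space = bad, n_samples = 1,
                            folds = 3, seed = 400 + s)
    wins <- wins + (min(tuned$cv_mse) < ref$cv_mse)
  }
  expect_gte(wins, 4)
})

test_that("fit_and_score computes held-out MSE and guards its
          preconditions", {
  tab <- toy_table()
  train <- tab[tab$patient_id <= "T048", ]
  test <- tab[tab$patient_id > "T048", ]
  # constant training target: the model predicts that constant, so the
  # test MSE equals the population mean squared deviation from it
  train_c <- train
  train_c$target_next_week <- 1
  test_c <- test
  test_c$target_next_week <- rep_len(c(0L, 1L, 2L), nrow(test))
  mse <- fit_and_score(train_c, test_c, "gbt", gbt_cfg(300))
  expect_equal(as.numeric(mse),
               mean((1 - test_c$target_next_week)^2), tolerance = 0.02)

  expect_error(fit_and_score(train, train, "gbt", gbt_cfg(10)),
               "overlap")
  expect_error(fit_and_score(train, test[0, ], "gbt", gbt_cfg(10)),
               "empty test")
})

test_that("family selection takes the lowest test MSE with the fixed
          tie order", {
  res <- list(list(family = "gbt", test_mse = 0.103),
              list(family = "rf", test_mse = 0.114),
              list(family = "nn", test_mse = 0.129))
  expect_equal(select_model(res), "gbt")
  expect_equal(select_model(res[2]), "rf")
  tie <- list(list(family = "nn", test_mse = 0.1),
              list(family = "gbt", test_mse = 0.1))
  expect_equal(select_model(tie), "gbt")
  expect_error(select_model(list()), "no results")
})

test_that("the fitted two-stage model predicts nonnegative finite
          workloads and ranks intense patients higher", {
  coh <- generate_cohort(tiny_config(seed = 31, n_weeks = 14))
  tab <- build_model_table(coh, "train")
  m <- workload_model(tab, k = 3, n_samples = 3, seed = 5)
  test_tab <- build_model_table(coh, "test")
  pred <- predict(m, test_tab)
  expect_true(all(is.finite(pred)))
  expect_true(all(pred >= 0))

  rate <- coh$patients$base_rate[match(test_tab$patient_id,
                                       coh$patients$patient_id)]
  hot <- rate > quantile(rate[rate > 0], 0.5)
  expect_gt(mean(pred[hot]), mean(pred[rate == 0]))

  pw <- predict_week(m, test_tab[1:5, ])
  expect_named(pw, c("patient_id", "week", "predicted"))
  expect_equal(nrow(pw), 5)
})

test_that("test rows never influence tuning or the fitted predictor", {
  coh <- generate_cohort(tiny_config(seed = 32, n_weeks = 12))
  tab <- build_model_table(coh, "train")
  m1 <- workload_model(tab, k = 2, n_samples = 2, seed = 6)
  test_tab <- build_model_table(coh, "test")
  mutated <- test_tab
  mutated$target_next_week <- mutated$target_next_week + 100L
  expect_identical(predict(m1, test_tab), predict(m1, mutated))
  # determinism: same seed, same model output
  m2 <- workload_model(tab, k = 2, n_samples = 2, seed = 6)
  expect_identical(predict(m1, test_tab), predict(m2, test_tab))
})
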