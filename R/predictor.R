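## Feature roles. The regressor uses all inputs except days since last
## navigator interaction and days since last cancer diagnosis, plus the
## cluster id; clustering uses all inputs except days since diagnosis.
regression_numeric <- function() {
  c("age", "adi", "rucc", "prior_admissions", "er_visits",
    "days_since_first_interaction", "enc_last_4wk", "enc_last_8wk")
}
regression_categorical <- function() {
  c("sex", "insurance", "cancer_type", "cluster_id")
}
clustering_numeric <- function() {
  c("age", "adi", "rucc", "prior_admissions", "er_visits",
    "days_since_first_interaction", "days_since_last_interaction",
    "enc_last_4wk", "enc_last_8wk")
}
clustering_categorical <- function() c("sex", "insurance", "cancer_type")

take_features <- function(table, num_cols, cat_cols) {
  miss <- setdiff(c(num_cols, cat_cols), names(table))
  if (length(miss)) {
    stop("missing feature columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  list(
    num = as.matrix(table[, num_cols, drop = FALSE]),
    cat = as.data.frame(lapply(table[, cat_cols, drop = FALSE],
                               as.character), stringsAsFactors = FALSE)
  )
}

## one-hot encoder with frozen levels (unseen levels encode as all-zero)
make_encoder <- function(feats) {
  list(num_cols = colnames(feats$num),
       cat_levels = lapply(feats$cat, function(v) sort(unique(v))))
}
encode_features <- function(feats, enc) {
  parts <- list(feats$num)
  for (cl in names(enc$cat_levels)) {
    lv <- enc$cat_levels[[cl]]
    m <- outer(feats$cat[[cl]], lv, "==") * 1
    colnames(m) <- paste0(cl, "=", lv)
    parts[[length(parts) + 1L]] <- m
  }
  do.call(cbind, parts)
}

default_search_space <- function(family) {
  switch(family,
    gbt = function(n) data.frame(
      max_depth = sample(2:8, n, replace = TRUE),
      eta = exp(runif(n, log(0.01), log(0.3))),
      nrounds = sample(seq(50, 300, by = 25), n, replace = TRUE),
      subsample = runif(n, 0.6, 1),
      colsample_bytree = runif(n, 0.6, 1),
      min_child_weight = sample(1:10, n, replace = TRUE)
    ),
    rf = function(n) data.frame(
      ntree = sample(seq(100, 500, by = 50), n, replace = TRUE),
      nodesize = sample(1:8, n, replace = TRUE),
      maxnodes = sample(seq(16, 256, by = 16), n, replace = TRUE)
    ),
    nn = function(n) data.frame(
      size = sample(c(8, 16, 32, 64), n, replace = TRUE),
      decay = exp(runif(n, log(1e-5), log(1e-2))),
      maxit = 200
    ),
    stop("unknown family: ", family, call. = FALSE)
  )
}

fit_family <- function(family, x, y, config, nthread = 1) {
  if (family == "gbt") {
    dtrain <- xgboost::xgb.DMatrix(x, label = y)
    booster <- xgboost::xgb.train(
      params = list(
        objective = "reg:squarederror",
        max_depth = config$max_depth, eta = config$eta,
        subsample = config$subsample,
        colsample_bytree = config$colsample_bytree,
        min_child_weight = config$min_child_weight,
        tree_method = "hist", nthread = nthread
      ),
      data = dtrain, nrounds = config$nrounds, verbose = 0
    )
    list(family = family, fit = booster)
  } else if (family == "rf") {
    if (!requireNamespace("randomForest", quietly = TRUE)) {
      stop("the 'rf' family needs the randomForest package", call. = FALSE)
    }
    fit <- randomForest::randomForest(
      x = x, y = y, ntree = config$ntree,
      nodesize = config$nodesize, maxnodes = config$maxnodes
    )
    list(family = family, fit = fit)
  } else if (family == "nn") {
    if (!requireNamespace("nnet", quietly = TRUE)) {
      stop("the 'nn' family needs the nnet package", call. = FALSE)
    }
    ctr <- colMeans(x); scl <- apply(x, 2, sd); scl[scl == 0] <- 1
    xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
    fit <- nnet::nnet(xs, y, size = config$size, decay = config$decay,
                      maxit = config$maxit, linout = TRUE, trace = FALSE)
    list(family = family, fit = fit, center = ctr, scale = scl)
  } else stop("unknown family: ", family, call. = FALSE)
}

predict_family <- function(fitted, x) {
  out <- if (fitted$family == "gbt") {
    predict(fitted$fit, xgboost::xgb.DMatrix(x))
  } else if (fitted$family == "rf") {
    predict(fitted$fit, x)
  } else {
    xs <- sweep(sweep(x, 2, fitted$center), 2, fitted$scale, "/")
    as.vector(predict(fitted$fit, xs))
  }
  as.numeric(out)
}

#' Random-search hyperparameter tuning with patient-level CV
#'
#' Samples `n_samples` hyperparameter combinations from the family's
#' search space and scores each by mean squared error under
#' `folds`-fold cross-validation, with folds split BY PATIENT so no
#' patient contributes rows to two folds. The combination with the
#' smallest mean fold MSE wins; ties go to the first sampled.
#'
#' @param train_table Labelled modelling table (must contain
#'   `patient_id`, `target_next_week`, the feature columns, and
#'   `cluster_id`).
#' @param family `"gbt"` (gradient-boosted trees, the default),
#'   `"rf"`, or `"nn"`.
#' @param search_space Either `NULL` (the family's default space), or a
#'   data frame of explicit configurations to sample from. If the frame
#'   has fewer distinct rows than `n_samples`, all are used once, with
#'   a warning.
#' @param n_samples Number of sampled combinations (default 15).
#' @param folds Number of CV folds (default 3).
#' @param seed Optional integer seed; fixes the sampled configurations
#'   and fold memberships.
#' @param nthread Threads for the boosted-tree fits.
#' @return Object of class `tuning_result`: list with `family`,
#'   `configs`, `cv_mse`, `best_index`, `best_config`.
#' @export
random_search_cv <- function(train_table, family = "gbt",
                             search_space = NULL, n_samples = 15,
                             folds = 3, seed = NULL, nthread = 1) {
  run <- function() random_search_cv_impl(train_table, family,
                                          search_space, n_samples, folds,
                                          nthread)
  out <- if (is.null(seed)) run() else with_local_seed(seed, run())
  out$seed <- seed
  out
}

random_search_cv_impl <- function(train_table, family, search_space,
                                  n_samples, folds, nthread) {
  stopifnot("target_next_week" %in% names(train_table),
            "patient_id" %in% names(train_table))
  configs <- if (is.data.frame(search_space)) {
    distinct <- unique(search_space)
    if (nrow(distinct) < n_samples) {
      warning(sprintf(
        "search space has %d distinct configs (< %d); using all once",
        nrow(distinct), n_samples))
      distinct
    } else {
      search_space[sample.int(nrow(search_space), n_samples), ,
                   drop = FALSE]
    }
  } else {
    default_search_space(family)(n_samples)
  }
  rownames(configs) <- NULL

  feats <- take_features(train_table, regression_numeric(),
                         regression_categorical())
  enc <- make_encoder(feats)
  x <- encode_features(feats, enc)
  y <- train_table$target_next_week

  pts <- unique(train_table$patient_id)
  fold_of_patient <- sample(rep_len(seq_len(folds), length(pts)))
  fold <- fold_of_patient[match(train_table$patient_id, pts)]

  cv_mse <- vapply(seq_len(nrow(configs)), function(ci) {
    cfg <- configs[ci, , drop = FALSE]
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold != f
      fitted <- fit_family(family, x[tr, , drop = FALSE], y[tr], cfg,
                           nthread)
      mean((predict_family(fitted, x[!tr, , drop = FALSE]) - y[!tr])^2)
    }, numeric(1)))
  }, numeric(1))

  best <- which.min(cv_mse)  # ties: first sampled
  structure(
    list(family = family, configs = configs, cv_mse = cv_mse,
         best_index = best, best_config = configs[best, , drop = FALSE]),
    class = "tuning_result"
  )
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> family %s: %d configs, best CV MSE %.4f\n",
              x$family, nrow(x$configs), x$cv_mse[x$best_index]))
  invisible(x)
}

#' Fit one configuration and score it on a held-out test table
#'
#' Fits the given family/configuration on the training rows and returns
#' the mean squared error between predicted and actual next-week
#' encounter counts over the test rows. Train and test patient sets
#' must be disjoint.
#'
#' @inheritParams random_search_cv
#' @param test_table Held-out labelled table (non-empty).
#' @param config One-row data frame of hyperparameters (default: the
#'   family's defaults, the first draw of a seeded sample).
#' @return Test MSE (single number) with the fitted model attached as
#'   attribute `"model"`.
#' @export
fit_and_score <- function(train_table, test_table, family = "gbt",
                          config = NULL, nthread = 1) {
  if (NROW(test_table) == 0) stop("empty test table", call. = FALSE)
  if (length(intersect(unique(train_table$patient_id),
                       unique(test_table$patient_id)))) {
    stop("train and test patient sets overlap", call. = FALSE)
  }
  if (is.null(config)) {
    config <- with_local_seed(1, default_search_space(family)(1))
  }
  feats <- take_features(train_table, regression_numeric(),
                         regression_categorical())
  enc <- make_encoder(feats)
  fitted <- fit_family(family, encode_features(feats, enc),
                       train_table$target_next_week, config, nthread)
  tf <- take_features(test_table, regression_numeric(),
                      regression_categorical())
  pred <- predict_family(fitted, encode_features(tf, enc))
  mse <- mean((pred - test_table$target_next_week)^2)
  attr(mse, "model") <- fitted
  mse
}

#' Select the model family with the lowest test MSE
#'
#' @param results List of records, each with elements `family` and
#'   `test_mse` (e.g. built from [fit_and_score()] outputs).
#' @return The winning family name. Ties are broken by the fixed family
#'   order gbt, rf, nn.
#' @examples
#' select_model(list(list(family = "gbt", test_mse = 0.103),
#'                   list(family = "rf", test_mse = 0.114),
#'                   list(family = "nn", test_mse = 0.129)))
#' @export
select_model <- function(results) {
  if (length(results) == 0) stop("no results", call. = FALSE)
  fam <- vapply(results, function(r) r$family, "")
  mse <- vapply(results, function(r) as.numeric(r$test_mse), numeric(1))
  ord <- order(mse, match(fam, c("gbt", "rf", "nn")))
  fam[ord[1]]
}

#' Fit the two-stage next-week workload predictor
#'
#' Stage 1 clusters the training patient-weeks with [kprototypes()]
#' (using all inputs except days since last cancer diagnosis); the
#' cluster id is appended as a categorical feature. Stage 2 tunes a
#' regressor by 15-combination random search with 3-fold patient-level
#' cross-validation and refits the best configuration on the full
#' training table. Days since last navigator interaction and days since
#' diagnosis are excluded from the regression features.
#'
#' @param train_table Labelled modelling table from
#'   [build_model_table()] (training partition).
#' @param k Number of clusters (default 7).
#' @param family Regressor family (default `"gbt"`).
#' @param n_samples,folds Random-search budget and CV folds.
#' @param search_space Optional explicit search space (data frame).
#' @param cluster_sample,cv_sample To bound fitting cost, the clustering
#'   stage and the tuning stage run on at most this many training rows
#'   (patient-level subsamples); the final model is refit on all rows.
#' @param seed Integer seed controlling clustering, subsampling, tuning
#'   draws, and fold splits.
#' @param nthread Threads for boosted-tree fits (default 1, fully
#'   reproducible).
#' @return Object of class `workload_model`: the fitted cluster model,
#'   the tuned regressor, the feature encoder, the training-mean
#'   baseline, and the training patient ids.
#' @export
workload_model <- function(train_table, k = 7, family = "gbt",
                           n_samples = 15, folds = 3,
                           search_space = NULL, cluster_sample = 20000,
                           cv_sample = 30000, seed = 1, nthread = 1) {
  with_local_seed(seed, {
    stopifnot("target_next_week" %in% names(train_table))
    n <- nrow(train_table)
    if (n == 0) stop("empty training table", call. = FALSE)

    ## stage 1: k-prototypes on (a patient subsample of) the train rows
    crows <- subsample_patient_rows(train_table, cluster_sample)
    cf <- take_features(train_table[crows, ], clustering_numeric(),
                        clustering_categorical())
    cluster_model <- kprototypes(cf$num, cf$cat, k = k,
                                 n_init = 2, max_iter = 25)
    train_table$cluster_id <- assign_cluster(cluster_model, train_table)

    ## stage 2: random-search tuning on a patient subsample, refit on all
    trows <- subsample_patient_rows(train_table, cv_sample)
    tuning <- random_search_cv(train_table[trows, ], family = family,
                               search_space = search_space,
                               n_samples = n_samples, folds = folds,
                               nthread = nthread)
    feats <- take_features(train_table, regression_numeric(),
                           regression_categorical())
    enc <- make_encoder(feats)
    fitted <- fit_family(family, encode_features(feats, enc),
                         train_table$target_next_week,
                         tuning$best_config, nthread)
    structure(
      list(cluster_model = cluster_model, family = family, fit = fitted,
           encoder = enc, tuning = tuning,
           baseline_mean = mean(train_table$target_next_week),
           train_patients = unique(train_table$patient_id),
           seed = seed),
      class = "workload_model"
    )
  })
}

subsample_patient_rows <- function(table, max_rows) {
  n <- nrow(table)
  if (n <= max_rows) return(seq_len(n))
  pts <- sample(unique(table$patient_id))
  rows_per <- n / length(pts)
  keep <- pts[seq_len(max(1L, floor(max_rows / rows_per)))]
  which(table$patient_id %in% keep)
}

#' Cluster assignment for modelling rows
#'
#' @param model A [kprototypes()] fit (or a `workload_model`, whose
#'   cluster stage is used).
#' @param table Modelling table rows.
#' @return Character vector of cluster labels (`"c1"`..`"ck"`).
#' @export
assign_cluster <- function(model, table) {
  if (inherits(model, "workload_model")) model <- model$cluster_model
  f <- take_features(table, clustering_numeric(),
                     clustering_categorical())
  paste0("c", predict(model, f$num, f$cat))
}

#' @export
print.workload_model <- function(x, ...) {
  cat(sprintf(
    "<workload_model> family %s, k = %d clusters, best CV MSE %.4f\n",
    x$family, x$cluster_model$k, x$tuning$cv_mse[x$tuning$best_index]))
  cat(sprintf("  trained on %d patients; baseline mean %.4f\n",
              length(x$train_patients), x$baseline_mean))
  invisible(x)
}

#' @export
summary.workload_model <- function(object, ...) {
  print(object)
  cat("tuning configurations:\n")
  print(cbind(object$tuning$configs,
              cv_mse = round(object$tuning$cv_mse, 4)))
  invisible(object)
}

#' Predict next-week workload for modelling rows
#'
#' @param object A fitted [workload_model()].
#' @param newdata Modelling table rows ([build_model_table()] schema).
#' @param ... Unused.
#' @return Numeric vector of non-negative predicted next-week encounter
#'   counts (raw negative outputs are clipped to 0).
#' @export
predict.workload_model <- function(object, newdata, ...) {
  newdata$cluster_id <- assign_cluster(object$cluster_model, newdata)
  feats <- take_features(newdata, regression_numeric(),
                         regression_categorical())
  pred <- predict_family(object$fit, encode_features(feats, object$encoder))
  pmax(pred, 0)
}

#' Per-patient predicted workload for one week's active rows
#'
#' Thin wrapper over [predict.workload_model()] returning one
#' prediction per active patient-week row.
#'
#' @inheritParams predict.workload_model
#' @param rows Active patient rows for the week.
#' @return Data frame `patient_id`, `week`, `predicted`.
#' @export
predict_week <- function(object, rows) {
  stopifnot(inherits(object, "workload_model"))
  data.frame(patient_id = rows$patient_id,
             week = if ("week" %in% names(rows)) rows$week else NA_integer_,
             predicted = predict(object, rows))
}
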