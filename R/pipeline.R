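#' Run the full distribution-study pipeline
#'
#' Generate (or accept) a cohort, build the weekly modelling tables,
#' fit the two-stage workload predictor on the training partition, run
#' the policy comparison on the test partition, and write the artifacts
#' (weekly unfairness CSV, summary JSON, config snapshot, optional
#' bar-chart figure) to `out_dir`.
#'
#' Stage seeds are derived deterministically from the cohort config's
#' seed, so a rerun with the same config reproduces the same summary.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing artifacts.
#' @param cohort Optional pre-generated `cpn_cohort` (must match
#'   `config` if both are given).
#' @param k,n_samples,folds Predictor settings (see [workload_model()]).
#' @param policies,n_reps,exact_threshold Simulation settings (see
#'   [simulate_policies()]).
#' @param write_cohort Also write the full patient/encounter tables as
#'   CSV (large; default FALSE).
#' @param make_figure Write a PNG bar chart of the comparison.
#' @return Invisibly, a list with `cohort`, `model`, `comparison`, and
#'   `paths` of written artifacts.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = NULL,
                         cohort = NULL, k = 7, n_samples = 15, folds = 3,
                         policies = c("prediction_informed", "random",
                                      "future_informed"),
                         n_reps = 10000, exact_threshold = 12,
                         write_cohort = FALSE, make_figure = FALSE) {
  if (!inherits(config, "cohort_config")) {
    stop("config must be a cohort_config(); offending argument: config",
         call. = FALSE)
  }
  if (is.null(cohort)) {
    cohort <- generate_cohort(config)
  } else if (!identical(cohort$config, config)) {
    stop("supplied cohort was generated from a different config",
         call. = FALSE)
  }
  train_tab <- build_model_table(cohort, "train")
  model <- workload_model(train_tab, k = k, n_samples = n_samples,
                          folds = folds, seed = config$seed + 1L)
  comparison <- simulate_policies(cohort, model, policies = policies,
                                  n_reps = n_reps,
                                  exact_threshold = exact_threshold,
                                  seed = config$seed + 2L)

  paths <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- write_report(comparison, out_dir, config,
                          make_figure = make_figure)
    if (write_cohort) {
      paths <- c(paths, write_cohort_csv(cohort, out_dir))
    }
  }
  invisible(list(cohort = cohort, model = model, comparison = comparison,
                 paths = paths))
}

write_report <- function(comparison, out_dir, config,
                         make_figure = FALSE) {
  weekly <- do.call(rbind, lapply(names(comparison$runs), function(p) {
    s <- comparison$runs[[p]]$series
    data.frame(policy = p,
               specialty_id = rep(rownames(s), each = ncol(s)),
               week = rep(seq_len(ncol(s)) - 1L, times = nrow(s)),
               unfairness = as.vector(t(s)))
  }))
  p_weekly <- file.path(out_dir, "weekly_unfairness.csv")
  write.csv(weekly, p_weekly, row.names = FALSE)

  p_summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(comparison$table, p_summary, dataframe = "rows",
                       digits = NA, auto_unbox = TRUE)

  p_config <- file.path(out_dir, "config.json")
  snap <- unclass(config)
  jsonlite::write_json(snap, p_config, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE)

  paths <- c(p_weekly, p_summary, p_config)
  if (make_figure) {
    p_fig <- file.path(out_dir, "unfairness_by_policy.png")
    grDevices::png(p_fig, width = 900, height = 500)
    plot(comparison)
    grDevices::dev.off()
    paths <- c(paths, p_fig)
  }
  paths
}

#' Write a cohort to plain CSV files
#'
#' Writes the patient table (one row per patient), the encounter-day
#' table, and the train/test split, with day indices accompanied by ISO
#' dates anchored at Monday 2019-01-07.
#'
#' @param cohort A `cpn_cohort`.
#' @param out_dir Output directory.
#' @return Paths of the written files.
#' @export
write_cohort_csv <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  origin <- as.Date("2019-01-07")
  pat <- cohort$patients
  pat$arrival_date <- origin + pat$arrival_day
  enc <- cohort$encounters
  enc$date <- origin + enc$day
  p1 <- file.path(out_dir, "patients.csv")
  p2 <- file.path(out_dir, "encounters.csv")
  p3 <- file.path(out_dir, "split.csv")
  write.csv(pat, p1, row.names = FALSE)
  write.csv(enc, p2, row.names = FALSE)
  write.csv(
    data.frame(
      patient_id = c(cohort$split$train, cohort$split$test),
      partition = rep(c("train", "test"),
                      c(length(cohort$split$train),
                        length(cohort$split$test)))),
    p3, row.names = FALSE)
  c(p1, p2, p3)
}
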