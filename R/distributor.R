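#' A weekly assignment problem for one specialty
#'
#' @param existing_loads Numeric vector (length m >= 2): per-navigator
#'   predicted (or actual) next-week workload from already-assigned
#'   active patients.
#' @param new_workloads Numeric vector (length n >= 0): predicted (or
#'   actual) next-week workload of the week's new patients, named by
#'   patient id if available.
#' @param specialty_id Optional identifier.
#' @return Object of class `assignment_problem`.
#' @export
assignment_problem <- function(existing_loads, new_workloads = numeric(0),
                               specialty_id = NA_character_) {
  existing_loads <- as.numeric(existing_loads)
  if (length(existing_loads) < 2) {
    stop("a specialty needs at least 2 navigators", call. = FALSE)
  }
  if (any(existing_loads < 0) || any(new_workloads < 0)) {
    stop("workloads cannot be negative", call. = FALSE)
  }
  structure(list(existing_loads = existing_loads,
                 new_workloads = as.numeric(new_workloads),
                 patient_ids = names(new_workloads),
                 specialty_id = specialty_id),
            class = "assignment_problem")
}

#' Minimum-unfairness assignment of new patients to navigators
#'
#' Assigns each new patient to a navigator of the specialty so that the
#' resulting per-navigator loads (existing plus newly assigned
#' workloads) minimize the weekly [unfairness()] metric. Because the
#' fair share is fixed by the week's total workload, this is the
#' integer program minimizing the total absolute deviation of loads
#' from the fair share.
#'
#' For `n <= exact_threshold` new patients the optimum is found exactly
#' by vectorized exhaustive enumeration of all `m^n` assignments (m is
#' the navigator count; specialties in scope have m of 2 or 3). For
#' larger n a greedy longest-processing-time fallback is used: new
#' workloads are sorted in decreasing order and each is given to the
#' currently least-loaded navigator. All ties break deterministically
#' toward the lowest navigator index.
#'
#' @param problem An [assignment_problem()].
#' @param exact_threshold Largest n solved exactly (default 12).
#' @return Integer vector of navigator indices (length n, named by
#'   patient id when available), with attributes `loads` (resulting
#'   per-navigator loads) and `unfairness` (the achieved objective).
#' @examples
#' p <- assignment_problem(c(5, 0), c(a = 2, b = 3))
#' optimal_assignment(p)  # both new patients to navigator 2
#' @export
optimal_assignment <- function(problem, exact_threshold = 12) {
  stopifnot(inherits(problem, "assignment_problem"))
  e <- problem$existing_loads
  w <- problem$new_workloads
  m <- length(e)
  n <- length(w)
  if (n == 0) {
    out <- integer(0)
    attr(out, "loads") <- e
    attr(out, "unfairness") <- unfairness(e)
    return(out)
  }
  assign <- if (n <= exact_threshold) {
    enumerate_best(e, w)
  } else {
    greedy_lpt(e, w)
  }
  loads <- e + as.vector(rowsum_loads(w, assign, m))
  names(assign) <- problem$patient_ids
  attr(assign, "loads") <- loads
  attr(assign, "unfairness") <- unfairness(loads)
  assign
}

## all m^n assignments, vectorized; first (lowest-index) optimum wins
enumerate_best <- function(e, w, chunk = 262144L) {
  m <- length(e)
  n <- length(w)
  total <- m^n
  if (total > 2^31) stop("enumeration space too large", call. = FALSE)
  fair <- (sum(e) + sum(w)) / m
  best_val <- Inf
  best_assign <- NULL
  start <- 0
  while (start < total) {
    size <- min(chunk, total - start)
    idx <- start + seq_len(size) - 1
    ## digit j of idx in base m = navigator of patient j (0-based)
    L <- matrix(rep(e, each = size), size, m)
    for (j in seq_len(n)) {
      d <- (idx %/% m^(j - 1)) %% m
      for (g in seq_len(m)) {
        sel <- d == (g - 1)
        L[sel, g] <- L[sel, g] + w[j]
      }
    }
    unf <- rowSums(abs(L - fair)) / m
    i <- which.min(unf)
    if (unf[i] < best_val - 1e-12) {
      best_val <- unf[i]
      best_assign <- idx[i]
    }
    start <- start + size
  }
  vapply(seq_len(n),
         function(j) as.integer((best_assign %/% m^(j - 1)) %% m) + 1L,
         integer(1))
}

greedy_lpt <- function(e, w) {
  m <- length(e)
  ord <- order(w, decreasing = TRUE)
  assign <- integer(length(w))
  loads <- e
  for (j in ord) {
    g <- which.min(loads)  # ties: lowest navigator index
    assign[j] <- g
    loads[g] <- loads[g] + w[j]
  }
  assign
}

rowsum_loads <- function(w, assign, m) {
  out <- numeric(m)
  for (g in seq_len(m)) out[g] <- sum(w[assign == g])
  out
}

#' Uniformly random assignment of new patients
#'
#' Each new patient is assigned independently and uniformly at random
#' among the specialty's navigators, emulating rotation-based intake.
#' Draws come from the current RNG stream.
#'
#' @inheritParams optimal_assignment
#' @return Integer vector of navigator indices with `loads` and
#'   `unfairness` attributes, as in [optimal_assignment()].
#' @export
random_assignment <- function(problem) {
  stopifnot(inherits(problem, "assignment_problem"))
  e <- problem$existing_loads
  w <- problem$new_workloads
  m <- length(e)
  assign <- if (length(w)) sample.int(m, length(w), replace = TRUE)
            else integer(0)
  loads <- e + rowsum_loads(w, assign, m)
  names(assign) <- problem$patient_ids
  attr(assign, "loads") <- loads
  attr(assign, "unfairness") <- unfairness(loads)
  assign
}

#' Future-informed (oracle) assignment
#'
#' Runs the same solver as [optimal_assignment()], but the problem is
#' expected to carry the REALIZED next-week workloads instead of
#' predictions. Available only in simulation, where the future is
#' known; it serves as an oracle policy whose achieved unfairness
#' lower-bounds what prediction-informed distribution can reach.
#'
#' @inheritParams optimal_assignment
#' @return As [optimal_assignment()].
#' @export
future_informed_assignment <- function(problem, exact_threshold = 12) {
  optimal_assignment(problem, exact_threshold = exact_threshold)
}

#' Persistent patient-to-navigator assignment state
#'
#' Records which navigator holds each patient. The consistency
#' constraint of the distribution model is enforced here: once a
#' patient is assigned, any attempt to reassign is an error, so
#' patients remain with their initially assigned navigator for as long
#' as they are in the panel.
#'
#' @param assignments Named integer vector (names are patient ids,
#'   values navigator indices), usually empty to start.
#' @return Object of class `assignment_state`.
#' @export
assignment_state <- function(assignments = integer(0)) {
  stopifnot(is.numeric(assignments))
  if (length(assignments) && is.null(names(assignments))) {
    stop("assignments must be named by patient id", call. = FALSE)
  }
  structure(list(assignments = assignments), class = "assignment_state")
}

#' Commit a week's assignment mapping into the state
#'
#' @param state An [assignment_state()].
#' @param mapping Named integer vector (patient id -> navigator index)
#'   for newly distributed patients. No patient may already be
#'   assigned. Committing disjoint mappings is order-independent.
#' @return The extended `assignment_state` (the input is unchanged;
#'   state history is immutable).
#' @export
commit <- function(state, mapping) {
  stopifnot(inherits(state, "assignment_state"))
  if (length(mapping) == 0) return(state)
  if (is.null(names(mapping)) || any(!nzchar(names(mapping)))) {
    stop("mapping must be named by patient id", call. = FALSE)
  }
  dup <- intersect(names(mapping), names(state$assignments))
  if (length(dup)) {
    stop("consistency violation: patient(s) already assigned: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  merged <- c(state$assignments, mapping)
  assignment_state(merged[order(names(merged))])
}

#' @export
print.assignment_state <- function(x, ...) {
  cat(sprintf("<assignment_state> %d patients assigned\n",
              length(x$assignments)))
  invisible(x)
}
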