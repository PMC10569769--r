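#' k-prototypes clustering of mixed numeric/categorical data
#'
#' Huang's k-prototypes algorithm: alternating assignment and prototype
#' update with the mixed dissimilarity
#' `d(x, c) = sum_numeric (x - c)^2 + gamma * sum_categorical [x != c]`.
#' Numeric prototypes are cluster means, categorical prototypes are
#' cluster modes. Numeric columns are standardized internally (the
#' stored centering/scaling is reapplied by `predict`). With no
#' categorical columns the method reduces to k-means; with no numeric
#' columns, to k-modes.
#'
#' Initialization draws `k` distinct rows as prototypes; `n_init`
#' restarts are run and the lowest-cost fit is kept. An empty cluster is
#' re-seeded from the point farthest from its assigned prototype. Ties
#' in assignment go to the lowest cluster index, so fits are
#' reproducible for a fixed seed.
#'
#' @param x_num Numeric matrix/data frame of numeric features (may have
#'   0 columns).
#' @param x_cat Data frame of categorical features (may be `NULL` or
#'   have 0 columns).
#' @param k Number of clusters (1 <= k <= n rows).
#' @param gamma Categorical mismatch weight; default (`NULL`) is half
#'   the mean variance of the standardized numeric columns (Huang's
#'   heuristic), or 1 when there are no numeric columns.
#' @param seed Optional integer seed.
#' @param max_iter Maximum alternating iterations per restart.
#' @param n_init Number of random restarts.
#' @param standardize Standardize numeric columns first (default TRUE).
#' @return Object of class `kprototypes` with elements `k`, `centers`
#'   (k x p standardized numeric centroids), `modes` (k x q data frame),
#'   `gamma`, `cost` (total within-cluster mixed dissimilarity),
#'   `cluster` (training assignments), `center_means`, `center_sds`,
#'   `iterations`, `seed`.
#' @examples
#' fit <- kprototypes(matrix(c(rnorm(20), rnorm(20, 6)), ncol = 2),
#'                    data.frame(g = rep(c("a", "b"), each = 10)),
#'                    k = 2, seed = 1)
#' fit$k
#' @export
kprototypes <- function(x_num, x_cat = NULL, k, gamma = NULL, seed = NULL,
                        max_iter = 50, n_init = 5, standardize = TRUE) {
  run <- function() kprototypes_impl(x_num, x_cat, k, gamma, max_iter,
                                     n_init, standardize, seed)
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

kprototypes_impl <- function(x_num, x_cat, k, gamma, max_iter, n_init,
                             standardize, seed) {
  X <- if (is.null(x_num)) matrix(numeric(0), nrow = nrow(x_cat), ncol = 0)
       else as.matrix(x_num)
  storage.mode(X) <- "double"
  C <- if (is.null(x_cat) || NCOL(x_cat) == 0) NULL
       else as.data.frame(lapply(as.data.frame(x_cat), as.character),
                          stringsAsFactors = FALSE)
  n <- if (nrow(X) > 0 || !is.null(C)) max(nrow(X), NROW(C)) else 0
  if (n == 0) stop("no rows to cluster", call. = FALSE)
  if (ncol(X) == 0 && is.null(C)) stop("no features", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > n) stop("k exceeds the number of rows", call. = FALSE)

  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  if (standardize && ncol(X) > 0) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[scl == 0 | is.na(scl)] <- 1
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  if (is.null(gamma)) {
    gamma <- if (ncol(X) > 0) 0.5 * mean(apply(X, 2, var)) else 1
    if (is.na(gamma)) gamma <- 0.5
  }

  best <- NULL
  for (init in seq_len(n_init)) {
    fit <- kproto_once(X, C, k, gamma, max_iter)
    if (is.null(best) || fit$cost < best$cost) best <- fit
  }
  structure(
    list(k = k, centers = best$centers, modes = best$modes, gamma = gamma,
         cost = best$cost, cluster = best$cluster,
         center_means = ctr, center_sds = scl,
         num_names = colnames(x_num), cat_names = names(x_cat),
         iterations = best$iterations, seed = seed),
    class = "kprototypes"
  )
}

kproto_once <- function(X, C, k, gamma, max_iter) {
  n <- max(nrow(X), NROW(C))
  idx <- sample.int(n, k)
  centers <- X[idx, , drop = FALSE]
  modes <- if (!is.null(C)) C[idx, , drop = FALSE]
  assign_old <- rep(0L, n)
  it <- 0L
  repeat {
    it <- it + 1L
    D <- mixed_distance(X, C, centers, modes, gamma)
    cl <- max.col(-D, ties.method = "first")
    ## re-seed any empty cluster from the currently farthest point;
    ## reassignment may empty another cluster, so iterate (bounded)
    tries <- 0L
    repeat {
      empty <- which(tabulate(cl, k) == 0)
      if (length(empty) == 0 || tries >= 3L * k) break
      tries <- tries + 1L
      j <- empty[1]
      far <- which.max(D[cbind(seq_len(n), cl)])
      centers[j, ] <- X[far, , drop = FALSE]
      if (!is.null(modes)) modes[j, ] <- C[far, , drop = FALSE]
      D <- mixed_distance(X, C, centers, modes, gamma)
      cl <- max.col(-D, ties.method = "first")
    }
    if (identical(cl, assign_old) || it >= max_iter) break
    assign_old <- cl
    counts <- tabulate(cl, k)
    present <- which(counts > 0)
    if (ncol(X) > 0) {
      centers[present, ] <- rowsum(X, cl)[as.character(present), ,
                                          drop = FALSE] / counts[present]
    }
    if (!is.null(modes)) {
      for (q in seq_along(modes)) {
        tb <- table(factor(cl, levels = present), C[[q]])
        modes[[q]][present] <- colnames(tb)[max.col(tb,
                                                    ties.method = "first")]
      }
    }
  }
  cost <- sum(D[cbind(seq_len(n), cl)])
  list(centers = centers, modes = modes, cluster = cl, cost = cost,
       iterations = it)
}

mixed_distance <- function(X, C, centers, modes, gamma) {
  k <- max(nrow(centers), NROW(modes))
  n <- max(nrow(X), NROW(C))
  D <- matrix(0, n, k)
  if (ncol(X) > 0) {
    ## ||x||^2 - 2 x.c + ||c||^2
    D <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    D[D < 0] <- 0  # numerical guard
  }
  if (!is.null(C)) {
    for (q in seq_along(C)) {
      D <- D + gamma * outer(C[[q]], unlist(modes[[q]]), "!=")
    }
  }
  D
}

#' @export
print.kprototypes <- function(x, ...) {
  cat(sprintf(
    "<kprototypes> k = %d, %d numeric + %d categorical features,%s\n",
    x$k, ncol(x$centers), length(x$cat_names),
    sprintf(" gamma = %.3f, cost = %.2f (%d iterations)",
            x$gamma, x$cost, x$iterations)
  ))
  invisible(x)
}

#' Assign new rows to fitted k-prototypes clusters
#'
#' @param object A fitted [kprototypes()] model.
#' @param x_num Numeric features of the new rows (same columns as at
#'   fit time; standardization is reapplied from the stored scaling).
#' @param x_cat Categorical features of the new rows.
#' @param ... Unused.
#' @return Integer vector of cluster ids (ties broken toward the lowest
#'   cluster index).
#' @export
predict.kprototypes <- function(object, x_num = NULL, x_cat = NULL, ...) {
  p <- ncol(object$centers)
  q <- length(object$cat_names)
  X <- if (p > 0) as.matrix(x_num) else
    matrix(numeric(0), nrow = NROW(x_cat), ncol = 0)
  if (ncol(X) != p) stop("numeric schema mismatch", call. = FALSE)
  C <- NULL
  if (q > 0) {
    if (is.null(x_cat) || NCOL(x_cat) != q) {
      stop("categorical schema mismatch", call. = FALSE)
    }
    C <- as.data.frame(lapply(as.data.frame(x_cat), as.character),
                       stringsAsFactors = FALSE)
  }
  if (p > 0) {
    storage.mode(X) <- "double"
    X <- sweep(sweep(X, 2, object$center_means), 2, object$center_sds, "/")
  }
  D <- mixed_distance(X, C, object$centers, object$modes, object$gamma)
  max.col(-D, ties.method = "first")
}

#' Choose the number of clusters by the elbow of the cost curve
#'
#' Fits k-prototypes for every k in `k_grid`, then selects the elbow of
#' the cost-versus-k curve by the maximum-distance-to-chord rule (the k
#' whose point lies farthest from the straight line joining the curve's
#' endpoints). If the curve is flat or monotone without a bend, the
#' smallest k is returned with a warning.
#'
#' @param x_num,x_cat Features as in [kprototypes()].
#' @param k_grid Candidate k values (default 2..12).
#' @param seed Optional seed (each k is fitted from a deterministic
#'   sub-seed).
#' @param ... Passed to [kprototypes()].
#' @return The selected k (integer), with the cost curve attached as
#'   attribute `"costs"`.
#' @export
select_k <- function(x_num, x_cat = NULL, k_grid = 2:12, seed = NULL, ...) {
  if (length(k_grid) == 0) stop("k_grid must be non-empty", call. = FALSE)
  k_grid <- sort(unique(as.integer(k_grid)))
  costs <- vapply(seq_along(k_grid), function(i) {
    s <- if (is.null(seed)) NULL else seed + i
    kprototypes(x_num, x_cat, k = k_grid[i], seed = s, ...)$cost
  }, numeric(1))
  if (length(k_grid) == 1) {
    out <- k_grid
  } else {
    ## distance from each point to the chord through the endpoints
    x1 <- k_grid[1]; y1 <- costs[1]
    x2 <- k_grid[length(k_grid)]; y2 <- costs[length(costs)]
    num <- abs((y2 - y1) * k_grid - (x2 - x1) * costs +
                 x2 * y1 - y2 * x1)
    d <- num / sqrt((y2 - y1)^2 + (x2 - x1)^2)
    if (all(d < 1e-9)) {
      warning("cost curve has no elbow; returning the smallest k")
      out <- k_grid[1]
    } else {
      out <- k_grid[which.max(d)]
    }
  }
  structure(out, costs = stats::setNames(costs, k_grid))
}
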