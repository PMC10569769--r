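blob_data <- function(n_per = 20, sep = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * 2), ncol = 2),
             matrix(rnorm(n_per * 2, mean = sep), ncol = 2))
  cat <- data.frame(g = rep(c("a", "b"), each = n_per))
  list(x = x, cat = cat, truth = rep(1:2, each = n_per))
}

test_that("k = 1 yields the column means and modes", {
  d <- blob_data()
  fit <- kprototypes(d$x, d$cat, k = 1, seed = 2, standardize = FALSE)
  expect_equal(as.vector(fit$centers), colMeans(d$x))
  expect_equal(as.character(fit$modes[[1]]),
               names(which.max(table(d$cat$g))))
  expect_true(all(fit$cluster == 1))
})

test_that("well-separated mixed blobs are recovered exactly at k = 2", {
  d <- blob_data(sep = 8)
  fit <- kprototypes(d$x, d$cat, k = 2, seed = 3)
  # partition identical to ground truth up to label switching
  tab <- table(fit$cluster, d$truth)
  expect_equal(sort(diag(tab[, order(max.col(t(tab)))])),
               sort(table(d$truth)), ignore_attr = TRUE)
})

test_that("fitting never ends above the cost of a random prototype
          assignment", {
  d <- blob_data(sep = 4)
  for (s in 1:20) {
    set.seed(200 + s)
    idx <- sample(nrow(d$x), 3)
    gamma <- 0.5
    xs <- scale(d$x)
    init_cl <- naive_assign(xs, d$cat, xs[idx, , drop = FALSE],
                            d$cat[idx, , drop = FALSE], gamma)
    init_cost <- naive_mixed_cost(xs, d$cat, xs[idx, , drop = FALSE],
                                  d$cat[idx, , drop = FALSE], gamma,
                                  init_cl)
    fit <- kprototypes(d$x, d$cat, k = 3, gamma = gamma, seed = 200 + s)
    expect_lte(fit$cost, init_cost + 1e-9)
  }
})

test_that("the fitted cost and assignments agree with a naive
          reimplementation of the mixed dissimilarity", {
  d <- blob_data(n_per = 30, sep = 3, seed = 5)
  fit <- kprototypes(d$x, d$cat, k = 3, seed = 6)
  xs <- sweep(sweep(d$x, 2, fit$center_means), 2, fit$center_sds, "/")
  expect_equal(naive_assign(xs, d$cat, fit$centers, fit$modes,
                            fit$gamma),
               fit$cluster)
  expect_equal(naive_mixed_cost(xs, d$cat, fit$centers, fit$modes,
                                fit$gamma, fit$cluster),
               fit$cost, tolerance = 1e-8)
})

test_that("with no categorical columns the fit matches k-means", {
  d <- blob_data(sep = 8)
  fit <- kprototypes(d$x, NULL, k = 2, seed = 7, standardize = FALSE,
                     n_init = 5)
  km <- kmeans(d$x, 2, nstart = 10)
  expect_equal(fit$cost, km$tot.withinss, tolerance = 1e-6)
  expect_equal(length(unique(paste(fit$cluster, km$cluster))), 2)
})

test_that("with no numeric columns the fit matches k-modes mismatch
          counting", {
  set.seed(8)
  cat <- data.frame(
    a = rep(c("x", "y"), each = 25),
    b = rep(c("u", "v"), each = 25),
    c = sample(c("p", "q"), 50, replace = TRUE)
  )
  fit <- kprototypes(NULL, cat, k = 2, gamma = 1, seed = 9)
  x0 <- matrix(numeric(0), nrow = 50, ncol = 0)
  expect_equal(naive_assign(x0, cat, fit$centers, fit$modes, 1),
               fit$cluster)
  # two clean categorical blocks are separated
  expect_equal(length(unique(fit$cluster[1:25])), 1)
  expect_equal(length(unique(fit$cluster[26:50])), 1)
  expect_false(fit$cluster[1] == fit$cluster[26])
})

test_that("assignment ties break toward the lowest cluster index and
          schema mismatches error", {
  d <- blob_data()
  fit <- kprototypes(d$x, d$cat, k = 2, seed = 10)
  # duplicate centroids: every row is equidistant
  fit$centers[2, ] <- fit$centers[1, ]
  fit$modes[2, ] <- fit$modes[1, ]
  expect_true(all(predict(fit, d$x, d$cat) == 1))
  expect_error(predict(fit, d$x[, 1, drop = FALSE], d$cat),
               "numeric schema")
  expect_error(predict(fit, d$x, NULL), "categorical schema")
  # a row equal to a centroid maps to that cluster
  fit2 <- kprototypes(d$x, d$cat, k = 2, seed = 11)
  raw <- sweep(sweep(fit2$centers, 2, fit2$center_sds, "*"), 2,
               fit2$center_means, "+")
  expect_equal(predict(fit2, raw[2, , drop = FALSE],
                       fit2$modes[2, , drop = FALSE]), 2)
})

test_that("identical seeds give identical models", {
  d <- blob_data(sep = 2)
  expect_identical(kprototypes(d$x, d$cat, k = 4, seed = 12),
                   kprototypes(d$x, d$cat, k = 4, seed = 12))
})

test_that("select_k handles singleton grids and decreasing costs", {
  d <- blob_data(sep = 5)
  expect_equal(as.integer(select_k(d$x, d$cat, k_grid = 3, seed = 1)), 3)
  k <- select_k(d$x, d$cat, k_grid = 2:6, seed = 2, n_init = 3)
  costs <- attr(k, "costs")
  expect_true(all(diff(costs) < 1e-6))  # cost non-increasing in k
})

test_that("select_k finds the elbow near the true number of latent
          groups", {
  # seven latent groups at guaranteed-separated centers
  centers <- 8 * matrix(c(0, 0, 0, 0,  1, 0, 0, 0,  0, 1, 0, 0,
                          0, 0, 1, 0,  0, 0, 0, 1,  1, 1, 0, 0,
                          0, 0, 1, 1), byrow = TRUE, ncol = 4)
  hits <- 0L
  for (s in 1:5) {
    set.seed(300 + s)
    x <- centers[rep(1:7, each = 40), ] + matrix(rnorm(280 * 4, sd = 0.5),
                                                 280, 4)
    cat <- data.frame(g = letters[rep(1:7, each = 40)])
    k <- select_k(x, cat, k_grid = 2:10, seed = 300 + s, n_init = 5)
    hits <- hits + (abs(as.integer(k) - 7) <= 1)
  }
  expect_gte(hits, 4)
})
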