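# FCM engine: closed-form updates, invariants, convergence behaviour.

test_that("pairwise distances reduce to hand-computed Euclidean norms", {
  expect_equal(as.vector(fcm_distances(0, matrix(c(0, 1)))), c(0, 1))
  expect_equal(fcm_distances(matrix(c(3, 4), nrow = 1), matrix(c(0, 0), nrow = 1))[1, 1], 5)
  # coincident point has distance 0 to its centre
  expect_equal(fcm_distances(2.5, matrix(2.5))[1, 1], 0)
  expect_error(fcm_distances(matrix(1, 1, 2), matrix(1, 1, 3)),
               class = "fcmseg_invalid_input")
})

test_that("objective matches hand evaluation and vanishes on crisp perfect fits", {
  # every sample on a centre with crisp membership
  expect_equal(fcm_objective(c(0, 2), diag(2), matrix(c(0, 2)), n = 2), 0)
  # samples {0,2}, single centre 1, memberships all 1: 1^2 + 1^2
  expect_equal(fcm_objective(c(0, 2), matrix(1, 2, 1), matrix(1), n = 2), 2)
  expect_error(fcm_objective(c(0, 2), diag(3), matrix(c(0, 2)), n = 2),
               class = "fcmseg_invalid_input")
})

test_that("centre update is the mu^n-weighted mean", {
  # crisp memberships give plain group means
  mu <- rbind(c(1, 0), c(1, 0), c(0, 1))
  expect_equal(as.vector(fcm_update_centers(c(0, 1, 2), mu, n = 2)), c(0.5, 2))
  # hand evaluation with soft memberships
  mu <- rbind(c(0.8, 0.2), c(0.2, 0.8))
  ctr <- fcm_update_centers(c(0, 2), mu, n = 2)
  expect_equal(as.vector(ctr), c(0.08 / 0.68, 1.28 / 0.68), tolerance = 1e-12)
  # uniform memberships collapse all centres onto one weighted mean
  mu <- matrix(1 / 3, 5, 3)
  ctr <- fcm_update_centers(rnorm(5), mu, n = 2)
  expect_equal(max(ctr) - min(ctr), 0, tolerance = 1e-12)
  # centres stay in the convex hull of the samples
  x <- runif(20, -3, 7)
  mu <- matrix(runif(40), 20); mu <- mu / rowSums(mu)
  ctr <- fcm_update_centers(x, mu, n = 2)
  expect_true(all(ctr >= min(x) & ctr <= max(x)))
  # a dead cluster is a classed error naming the cluster
  err <- tryCatch(fcm_update_centers(c(0, 1), cbind(c(1, 1), c(0, 0)), n = 2),
                  error = identity)
  expect_s3_class(err, "fcmseg_degenerate_cluster")
  expect_equal(err$cluster, 2L)
})

test_that("membership update matches the closed form, including zero-distance limits", {
  expect_equal(as.vector(fcm_update_memberships(matrix(c(1, 1), 1), n = 2)), c(0.5, 0.5))
  expect_equal(as.vector(fcm_update_memberships(matrix(c(0.25, 0.75), 1), n = 2)),
               c(0.9, 0.1), tolerance = 1e-12)
  expect_equal(as.vector(fcm_update_memberships(matrix(c(0, 1), 1), n = 2)), c(1, 0))
  expect_equal(as.vector(fcm_update_memberships(matrix(c(0, 2, 0), 1), n = 2)),
               c(0.5, 0, 0.5))
  expect_error(fcm_update_memberships(matrix(c(-1, 1), 1), n = 2),
               class = "fcmseg_invalid_input")
})

test_that("memberships agree with a brute-force evaluation of the formula", {
  # independent oracle: explicit double loop over the textbook expression
  brute <- function(d, n) {
    mu <- matrix(NA_real_, nrow(d), ncol(d))
    for (z in seq_len(nrow(d))) {
      for (s in seq_len(ncol(d))) {
        mu[z, s] <- 1 / sum((d[z, s] / d[z, ])^(2 / (n - 1)))
      }
    }
    mu
  }
  set.seed(42)
  for (rep in 1:10) {
    d <- matrix(runif(12, 0.1, 5), nrow = 6, ncol = 2)
    n <- sample(c(1.5, 2, 3), 1)
    expect_equal(fcm_update_memberships(d, n), brute(d, n), tolerance = 1e-12)
  }
})

test_that("membership rows always lie on the unit simplex", {
  set.seed(7)
  for (rep in 1:20) {
    d <- matrix(rexp(30), nrow = 10, ncol = 3)
    d[sample(30, 2)] <- 0  # include exact-zero rows
    mu <- fcm_update_memberships(d, n = runif(1, 1.2, 4))
    expect_true(all(mu >= 0 & mu <= 1))
    expect_equal(rowSums(mu), rep(1, 10), tolerance = 1e-9)
  }
})

test_that("initialization is deterministic, normalised, and quantile-seeded", {
  x <- rnorm(10, sd = 3)
  cfg <- fcm_config(Q = 3, seed = 7, init = "random-membership")
  expect_identical(fcm_init(x, cfg), fcm_init(x, cfg))
  mu <- fcm_init(x, cfg)
  expect_equal(rowSums(mu), rep(1, 10), tolerance = 1e-9)
  # quantile mode seeds centres at the (s - 0.5)/Q percentiles
  muq <- fcm_init(1:100, fcm_config(Q = 4))
  ctr <- attr(muq, "centers")
  expect_equal(as.vector(ctr),
               as.vector(quantile(1:100, c(0.125, 0.375, 0.625, 0.875))),
               tolerance = 1e-12)
  expect_equal(as.vector(ctr), c(13, 38, 63, 88), tolerance = 0.5)
  expect_error(fcm_init(1:3, fcm_config(Q = 4)), class = "fcmseg_invalid_input")
})

test_that("config validation rejects degenerate parameters", {
  expect_error(fcm_config(Q = 1), class = "fcmseg_invalid_input")
  expect_error(fcm_config(n = 1), class = "fcmseg_invalid_input")
  expect_error(fcm_config(tol = 0), class = "fcmseg_invalid_input")
  expect_error(fcm_config(max_iter = 0), class = "fcmseg_invalid_input")
})

test_that("fit recovers well-separated Gaussian component means", {
  set.seed(11)
  x <- c(rnorm(200, 0, 0.5), rnorm(200, 10, 0.5))
  fit <- fit_fcm(x, fcm_config(Q = 2))
  expect_true(fit$converged)
  ctr <- sort(fit$centers[, 1])
  expect_lt(abs(ctr[1] - 0), 0.3)
  expect_lt(abs(ctr[2] - 10), 0.3)
  # memberships satisfy the simplex constraints after the fit
  expect_true(all(fit$memberships >= 0 & fit$memberships <= 1))
  expect_equal(rowSums(fit$memberships), rep(1, 400), tolerance = 1e-9)
  expect_true(all(colSums(fit$memberships) > 0))
})

test_that("with w = Q samples the centres interpolate the data", {
  fit <- fit_fcm(c(-4, 0, 5), fcm_config(Q = 3, tol = 1e-9))
  expect_equal(sort(fit$centers[, 1]), c(-4, 0, 5), tolerance = 1e-3)
  expect_lt(tail(fit$objective_trace, 1), 1e-4)
})

test_that("objective trace is non-increasing for random problems", {
  for (s in 1:25) {
    set.seed(s)
    x <- matrix(runif(60 * sample(1:2, 1), -5, 5), nrow = 60)
    fit <- fit_fcm(x, fcm_config(Q = 3, n = runif(1, 1.3, 3),
                                 init = "random-membership", seed = s))
    expect_true(all(diff(fit$objective_trace) <= 1e-8))
  }
})

test_that("a converged fit is a fixed point of the update pair", {
  for (s in c(3, 19)) {
    set.seed(s)
    x <- c(rnorm(80, 0, 1), rnorm(80, 12, 1.5), rnorm(80, 30, 2))
    cfg <- fcm_config(Q = 3, tol = 1e-6)
    fit <- fit_fcm(x, cfg)
    expect_true(fit$converged)
    ctr <- fcm_update_centers(x, fit$memberships, cfg$n)
    mu2 <- fcm_update_memberships(fcm_distances(x, ctr), cfg$n)
    expect_lt(max(abs(mu2 - fit$memberships)), cfg$tol)
  }
})

test_that("permuting samples permutes memberships and preserves centres", {
  set.seed(5)
  x <- c(rnorm(60, 0, 1), rnorm(60, 8, 1))
  perm <- sample(120)
  f1 <- fit_fcm(x, fcm_config(Q = 2))
  f2 <- fit_fcm(x[perm], fcm_config(Q = 2))
  expect_equal(f2$memberships, f1$memberships[perm, ], tolerance = 1e-8)
  expect_equal(sort(f2$centers[, 1]), sort(f1$centers[, 1]), tolerance = 1e-8)
})

test_that("defuzzification takes the argmax with lowest-index tie-breaking", {
  mu <- rbind(c(0.1, 0.7, 0.2), c(0.5, 0.5, 0), c(1, 0, 0))
  expect_identical(defuzzify(mu), c(1L, 0L, 0L))
  crisp <- diag(3)[c(2, 3, 1, 2), ]
  expect_identical(defuzzify(crisp), c(1L, 2L, 0L, 1L))
})

test_that("fit agrees with an independent FCM implementation", {
  skip_if_not_installed("e1071")
  set.seed(23)
  x <- c(rnorm(150, 5, 1), rnorm(150, 20, 2))
  fit <- fit_fcm(x, fcm_config(Q = 2, tol = 1e-8))
  ref <- e1071::cmeans(matrix(x), centers = 2, m = 2)
  expect_equal(sort(fit$centers[, 1]), unname(sort(ref$centers[, 1])),
               tolerance = 1e-2, ignore_attr = TRUE)
})

test_that("fit summaries serialise the essentials", {
  fit <- fit_fcm(c(0, 0.1, 9.9, 10), fcm_config(Q = 2))
  s <- fcm_fit_summary(fit)
  expect_named(s, c("centers", "iterations", "converged", "objective"))
  expect_true(jsonlite::validate(jsonlite::toJSON(s, auto_unbox = TRUE)))
})
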