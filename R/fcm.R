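# Fuzzy C-means engine.
#
# FCM minimises the objective
#     J(mu, B) = sum_z sum_s mu[z,s]^n * ||u_z - b_s||^2
# over memberships mu (w x Q, rows on the unit simplex) and cluster centres
# B (Q x p), by alternating the two closed-form coordinate updates:
#     b_s    = sum_z mu[z,s]^n u_z / sum_z mu[z,s]^n
#     mu[z,s] = 1 / sum_W (d_zs / d_zW)^(2/(n-1))
# where d_zs is the Euclidean distance from sample z to centre s and n > 1 is
# the fuzzifier. n -> 1 recovers hard k-means; larger n softens assignments.

#' FCM configuration
#'
#' Bundles the tuning parameters of [fit_fcm()]. Defaults follow common FCM
#' practice: fuzzifier `n = 2`, convergence on the maximum absolute membership
#' change, and deterministic quantile-based initialization so that repeated
#' runs (and cluster-to-tissue ordering) are reproducible.
#'
#' @param Q Number of clusters (integer, >= 2).
#' @param n Fuzzifier (> 1 strictly; `n = 1` degenerates to hard assignment
#'   and divides by zero in the membership update exponent `2/(n-1)`).
#' @param tol Convergence tolerance on the maximum absolute change of any
#'   membership between successive iterations.
#' @param max_iter Iteration cap.
#' @param seed RNG seed used by `init = "random-membership"`.
#' @param init Either `"quantile-centers"` (centres seeded at the
#'   `(s - 0.5)/Q` quantiles of each feature, memberships derived from them)
#'   or `"random-membership"` (seeded uniform rows, normalised).
#' @return An object of class `fcm_config`.
#' @examples
#' fcm_config(Q = 2)
#' @export
fcm_config <- function(Q = 4L, n = 2, tol = 1e-5, max_iter = 300L,
                       seed = 1L, init = c("quantile-centers", "random-membership")) {
  init <- match.arg(init)
  if (!is.numeric(Q) || length(Q) != 1L || Q < 2) {
    abort_invalid("Q must be a single integer >= 2")
  }
  if (!is.numeric(n) || length(n) != 1L || n <= 1) {
    abort_invalid("fuzzifier n must be > 1 (n = 1 is hard clustering and ill-defined here)")
  }
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0) abort_invalid("tol must be > 0")
  if (!is.numeric(max_iter) || length(max_iter) != 1L || max_iter < 1) {
    abort_invalid("max_iter must be >= 1")
  }
  structure(
    list(Q = as.integer(Q), n = as.numeric(n), tol = as.numeric(tol),
         max_iter = as.integer(max_iter), seed = as.integer(seed), init = init),
    class = "fcm_config"
  )
}

#' @export
print.fcm_config <- function(x, ...) {
  cat(sprintf("FCM config: Q = %d, n = %g, tol = %g, max_iter = %d, init = %s\n",
              x$Q, x$n, x$tol, x$max_iter, x$init))
  invisible(x)
}

as_sample_matrix <- function(x, what = "samples") {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) abort_invalid(sprintf("%s must be finite", what))
  x
}

#' Euclidean distances between samples and cluster centres
#'
#' @param samples Numeric matrix, `w` samples by `p` features (a vector is
#'   taken as `p = 1`).
#' @param centers Numeric matrix, `Q` centres by `p` features.
#' @return A `w x Q` matrix of non-negative Euclidean distances.
#' @examples
#' fcm_distances(c(3, 4), matrix(0))
#' @export
fcm_distances <- function(samples, centers) {
  samples <- as_sample_matrix(samples)
  centers <- as_sample_matrix(centers, "centers")
  if (ncol(samples) != ncol(centers)) {
    abort_invalid(sprintf("feature dimension mismatch: samples have %d, centers have %d",
                          ncol(samples), ncol(centers)))
  }
  d2 <- outer(rowSums(samples^2), rowSums(centers^2), "+") -
    2 * tcrossprod(samples, centers)
  sqrt(pmax(d2, 0))  # clip tiny negative round-off before sqrt
}

#' FCM objective function
#'
#' Membership-weighted sum of squared sample-to-centre distances,
#' `sum_z sum_s mu[z,s]^n d[z,s]^2`.
#'
#' @inheritParams fcm_distances
#' @param mu Membership matrix, `w x Q`, rows summing to 1.
#' @param n Fuzzifier (> 1).
#' @return A single non-negative number.
#' @export
fcm_objective <- function(samples, mu, centers, n = 2) {
  samples <- as_sample_matrix(samples)
  mu <- validate_memberships(mu, w = nrow(samples))
  d <- fcm_distances(samples, centers)
  if (ncol(mu) != ncol(d)) abort_invalid("mu and centers disagree on the number of clusters")
  sum(mu^n * d^2)
}

#' Centre update
#'
#' The closed-form minimiser of the FCM objective in the centres for fixed
#' memberships: each centre is the `mu^n`-weighted mean of all samples, and
#' therefore lies in their convex hull.
#'
#' @inheritParams fcm_objective
#' @return A `Q x p` matrix of centres.
#' @export
fcm_update_centers <- function(samples, mu, n = 2) {
  samples <- as_sample_matrix(samples)
  mu <- validate_memberships(mu, w = nrow(samples))
  w_pow <- mu^n
  totals <- colSums(w_pow)
  if (any(totals == 0)) abort_degenerate_cluster(which(totals == 0)[1L])
  crossprod(w_pow, samples) / totals
}

#' Membership update
#'
#' The closed-form minimiser of the FCM objective in the memberships for
#' fixed centres: `mu[z,s] = 1 / sum_W (d[z,s]/d[z,W])^(2/(n-1))`. A sample at
#' zero distance from one or more centres receives crisp membership split
#' equally among the coincident centres (the analytic limit of the formula);
#' all other distances are floored at `1e-12` to avoid overflow in the ratio.
#'
#' @param distances `w x Q` matrix of non-negative distances.
#' @param n Fuzzifier (> 1).
#' @return A `w x Q` membership matrix with rows summing to 1.
#' @export
fcm_update_memberships <- function(distances, n = 2) {
  d <- as.matrix(distances)
  storage.mode(d) <- "double"
  if (any(!is.finite(d)) || any(d < 0)) abort_invalid("distances must be finite and >= 0")
  if (n <= 1) abort_invalid("fuzzifier n must be > 1")
  zero <- d == 0
  pow <- pmax(d, 1e-12)^(-2 / (n - 1))
  mu <- pow / rowSums(pow)
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    crisp <- zero[hit, , drop = FALSE]
    mu[hit, ] <- crisp / rowSums(crisp)
  }
  mu
}

validate_memberships <- function(mu, w = NULL, tol = 1e-9) {
  mu <- as.matrix(mu)
  storage.mode(mu) <- "double"
  if (!is.null(w) && nrow(mu) != w) abort_invalid("membership row count does not match sample count")
  if (any(!is.finite(mu)) || any(mu < -tol) || any(mu > 1 + tol)) {
    abort_invalid("memberships must lie in [0, 1]")
  }
  if (any(abs(rowSums(mu) - 1) > 1e-6)) abort_invalid("membership rows must sum to 1")
  mu
}

#' Initial membership matrix
#'
#' `quantile-centers` places the initial centres at the `(s - 0.5)/Q`
#' quantiles of each feature (type-7 quantiles) and converts them into
#' memberships via [fcm_update_memberships()]; this is deterministic and puts
#' the clusters in ascending intensity order from the start. If the sample
#' quantiles coincide (heavily discrete data), the quantiles of the distinct
#' values are used instead so that no two clusters are seeded at the same
#' point.
#' `random-membership` draws seeded uniform rows and normalises them.
#'
#' @inheritParams fcm_distances
#' @param config An [fcm_config()].
#' @return A valid membership matrix; for quantile initialization the seeding
#'   centres are attached as attribute `"centers"`.
#' @export
fcm_init <- function(samples, config = fcm_config()) {
  samples <- as_sample_matrix(samples)
  w <- nrow(samples)
  if (w < config$Q) {
    abort_invalid(sprintf("need at least Q = %d samples, got %d", config$Q, w))
  }
  if (config$init == "random-membership") {
    mu <- withr::with_seed(config$seed, {
      m <- matrix(stats::runif(w * config$Q), nrow = w)
      m / rowSums(m)
    })
    return(mu)
  }
  probs <- (seq_len(config$Q) - 0.5) / config$Q
  centers <- apply(samples, 2L, function(col) {
    q <- stats::quantile(col, probs = probs, names = FALSE)
    # heavily discrete data can collapse sample quantiles onto one value,
    # which would seed coincident centres; fall back to quantiles of the
    # distinct values, which are strictly increasing whenever there are at
    # least Q of them
    if (anyDuplicated(q)) q <- stats::quantile(unique(col), probs = probs, names = FALSE)
    q
  })
  centers <- matrix(centers, nrow = config$Q)
  mu <- fcm_update_memberships(fcm_distances(samples, centers), config$n)
  attr(mu, "centers") <- centers
  mu
}

#' Fit fuzzy C-means
#'
#' Alternates the centre and membership updates from the configured
#' initialization until the maximum absolute membership change drops to
#' `tol` or `max_iter` is reached. The recorded objective trace (evaluated
#' after each full update pair) is non-increasing, which is the standard
#' convergence guarantee of alternating optimisation.
#'
#' @inheritParams fcm_init
#' @return An object of class `fcm_fit` with elements `memberships`,
#'   `centers`, `objective_trace`, `iterations`, `converged`, `config`.
#' @examples
#' x <- c(rnorm(50, 0, 0.3), rnorm(50, 10, 0.3))
#' fit <- fit_fcm(x, fcm_config(Q = 2))
#' sort(fit$centers[, 1])
#' @export
fit_fcm <- function(samples, config = fcm_config()) {
  samples <- as_sample_matrix(samples)
  if (!inherits(config, "fcm_config")) abort_invalid("config must be an fcm_config object")
  mu <- fcm_init(samples, config)
  attr(mu, "centers") <- NULL
  trace <- numeric(config$max_iter)
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(config$max_iter)) {
    iter <- it
    centers <- fcm_update_centers(samples, mu, config$n)
    d <- fcm_distances(samples, centers)
    mu_new <- fcm_update_memberships(d, config$n)
    obj <- sum(mu_new^config$n * d^2)
    if (!is.finite(obj)) abort_numerical("objective became non-finite during iteration")
    trace[it] <- obj
    delta <- max(abs(mu_new - mu))
    mu <- mu_new
    if (delta <= config$tol) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(memberships = mu, centers = centers, objective_trace = trace[seq_len(iter)],
         iterations = iter, converged = converged, config = config),
    class = "fcm_fit"
  )
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat(sprintf("FCM fit: %d samples, Q = %d, %d iteration%s (%s), objective %.6g\n",
              nrow(x$memberships), ncol(x$memberships), x$iterations,
              if (x$iterations == 1L) "" else "s",
              if (x$converged) "converged" else "not converged",
              utils::tail(x$objective_trace, 1L)))
  cat("centers (per feature):\n")
  print(x$centers)
  invisible(x)
}

#' Defuzzify memberships into crisp labels
#'
#' Assigns each sample to its maximum-membership cluster; ties go to the
#' lowest cluster index so results are deterministic.
#'
#' @param mu A membership matrix or an `fcm_fit`.
#' @return Integer vector of 0-based cluster labels (`0 .. Q-1`).
#' @export
defuzzify <- function(mu) {
  if (inherits(mu, "fcm_fit")) mu <- mu$memberships
  mu <- validate_memberships(mu)
  max.col(mu, ties.method = "first") - 1L
}

#' Serialise an FCM fit for reports
#'
#' @param fit An `fcm_fit`.
#' @return A list (centres, iterations, convergence flag, final objective)
#'   suitable for `jsonlite::toJSON()`.
#' @export
fcm_fit_summary <- function(fit) {
  if (!inherits(fit, "fcm_fit")) abort_invalid("fit must be an fcm_fit")
  list(
    centers = unname(as.matrix(fit$centers)),
    iterations = fit$iterations,
    converged = fit$converged,
    objective = unname(utils::tail(fit$objective_trace, 1L))
  )
}
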