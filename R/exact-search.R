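#' Candidate-grid configuration
#'
#' Controls the grid of candidate thresholds used by the exact search and the
#' maximal tests. Candidates are taken at observed values of the thresholded
#' predictor inside a central quantile window; extreme candidates are trimmed
#' because reduced fits with almost no observations on one side of the
#' threshold are degenerate.
#'
#' @param max_grid maximum number of candidates (default 500); when the
#'   number of eligible distinct values exceeds it, a deterministic subset is
#'   taken at equally spaced ranks.
#' @param lower_quantile,upper_quantile quantile window restricting the
#'   candidate range, defaults `(0.05, 0.95)`.
#' @return an object of class `grid_config`.
#' @export
grid_config <- function(max_grid = 500L, lower_quantile = 0.05,
                        upper_quantile = 0.95) {
  max_grid <- as.integer(max_grid)
  stopifnot(max_grid >= 2L, lower_quantile > 0, upper_quantile < 1,
            lower_quantile < upper_quantile)
  structure(list(max_grid = max_grid, lower_quantile = lower_quantile,
                 upper_quantile = upper_quantile),
            class = "grid_config")
}

#' Candidate thresholds from observed predictor values
#'
#' Returns the sorted distinct observed values of `x` within the configured
#' quantile window. If more than `max_grid` distinct values are eligible, the
#' subset at equally spaced ranks `r_k = round(k (n_eligible - 1) /
#' (max_grid - 1))`, `k = 0, ..., max_grid - 1`, is taken (deterministic
#' uniform rank subsampling), then deduplicated.
#'
#' @param x numeric predictor vector.
#' @param config a [grid_config()].
#' @return sorted numeric vector of candidate thresholds.
#' @export
candidate_grid <- function(x, config = grid_config()) {
  stopifnot(inherits(config, "grid_config"))
  if (!all(is.finite(x))) {
    stop("non-finite values in thresholded predictor", call. = FALSE)
  }
  qs <- stats::quantile(x, c(config$lower_quantile, config$upper_quantile),
                        names = FALSE)
  eligible <- sort(unique(x[x >= qs[1] & x <= qs[2]]))
  ne <- length(eligible)
  if (ne < 10L) {
    stop("fewer than 10 eligible distinct predictor values; ",
         "threshold is not identifiable", call. = FALSE)
  }
  if (ne <= config$max_grid) return(eligible)
  k <- seq_len(config$max_grid) - 1L
  ranks <- unique(round(k * (ne - 1) / (config$max_grid - 1)) + 1L)
  eligible[ranks]
}

#' Profile log-likelihood over a candidate grid
#'
#' For each candidate threshold the model reduces to an ordinary GLM; this
#' returns the maximized log-likelihood of each reduced fit. Non-converged
#' reduced fits are recorded as `-Inf` with a warning, never dropped, so the
#' returned vector always has the grid's length.
#'
#' @param data validated data frame.
#' @param spec a [threshold_spec()].
#' @param grid numeric vector of candidate thresholds.
#' @return numeric vector of profile log-likelihoods, same length as `grid`.
#' @export
profile_loglik <- function(data, spec, grid) {
  if (!length(grid)) stop("empty candidate grid", call. = FALSE)
  d0 <- build_design(data, spec, grid[1])
  out <- profile_core(d0$y, d0$Z, data[[spec$x]], grid, spec$family, spec$link)
  n_bad <- sum(is.na(out))
  if (n_bad > 0L) {
    warning(n_bad, " candidate threshold(s) had non-converged reduced fits ",
            "(recorded as -Inf)", call. = FALSE)
    out[is.na(out)] <- -Inf
  }
  out
}

# Maximized reduced-model log-likelihood at every candidate (NA marks a
# failed fit). Thin wrapper over the compiled loop; profile_core_r() below
# is the pure-R reference implementation kept for cross-checking.
profile_core <- function(y, Z, x, grid, family, link) {
  XX <- stacked_threshold_columns(x, grid, family)
  out <- profile_core_cpp(y, Z, XX, family$p,
                          as.integer(link == "logistic"))
  out[is.nan(out)] <- NA_real_
  drop(out)
}

profile_core_r <- function(y, Z, x, grid, family, link) {
  n <- length(y)
  k0 <- ncol(Z)
  p <- family$p
  kk <- k0 + p
  des <- cbind(Z, matrix(0, n, p))
  out <- rep(NA_real_, length(grid))
  XX <- stacked_threshold_columns(x, grid, family)

  if (link == "linear") {
    for (m in seq_along(grid)) {
      des[, (k0 + 1L):kk] <- XX[, ((m - 1L) * p + 1L):(m * p)]
      ch <- tryCatch(chol(crossprod(des)), error = function(e) NULL)
      if (is.null(ch)) next
      cf <- backsolve(ch, backsolve(ch, crossprod(des, y), transpose = TRUE))
      rss <- sum((y - des %*% cf)^2)
      out[m] <- if (rss > 0) -n / 2 * (log(2 * pi * rss / n) + 1) else Inf
    }
    return(out)
  }

  start0 <- numeric(kk)
  beta <- start0
  for (m in seq_along(grid)) {
    des[, (k0 + 1L):kk] <- XX[, ((m - 1L) * p + 1L):(m * p)]
    b <- beta
    eta <- drop(des %*% b)
    dev_old <- Inf
    ok <- FALSE
    for (it in seq_len(100L)) {
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      ch <- tryCatch(chol(crossprod(des, w * des)), error = function(e) NULL)
      if (is.null(ch)) break
      b_prev <- b
      b <- drop(backsolve(ch, backsolve(ch, crossprod(des, w * eta + (y - mu)),
                                        transpose = TRUE)))
      eta <- drop(des %*% b)
      dev <- -2 * loglik_logistic(y, eta)
      h <- 0L
      while (!(dev <= dev_old) && h < 30L) {  # step-halving on overshoot
        b <- (b + b_prev) / 2
        eta <- drop(des %*% b)
        dev <- -2 * loglik_logistic(y, eta)
        h <- h + 1L
      }
      relchg <- max(abs(b - b_prev) / (abs(b_prev) + 1e-4))
      if (is.finite(dev) && abs(dev - dev_old) / (abs(dev) + 0.1) < 1e-8 &&
          relchg < 1e-4) {
        ok <- TRUE
        dev_old <- dev
        break
      }
      dev_old <- dev
    }
    if (ok && max(abs(eta)) > 30) ok <- FALSE  # settled but quasi-separated
    if (ok) {
      out[m] <- -dev_old / 2
      beta <- b
    } else {
      beta <- start0
    }
  }
  out
}

#' Exact maximum-likelihood threshold fit by grid search
#'
#' Exhaustive profile-likelihood search: every candidate threshold is fitted
#' as a reduced GLM and the candidate with the highest likelihood is the
#' estimate. This finds the global optimum over the grid; ties are broken
#' toward the smallest candidate.
#'
#' @param data data frame with the spec's columns.
#' @param spec a [threshold_spec()].
#' @param config a [grid_config()].
#' @return an object of class `threshold_fit` with the estimated threshold
#'   `e`, `coefficients` (named vector in design-column order), `loglik`,
#'   the full `profile` trace (data frame of candidate and log-likelihood,
#'   suitable for plotting), the reduced-fit `glm` at the estimate, `spec`,
#'   `method = "exact"`, `config` and `n`.
#' @examples
#' sc <- sim_scenario("hinge", n = 300, seed = 1)
#' d <- gen_data(sc)
#' fit <- fit_exact(d, threshold_spec("y", "x", "z", "hinge", "logistic"))
#' fit$e
#' @export
fit_exact <- function(data, spec, config = grid_config()) {
  data <- validate_data(data, spec)
  grid <- candidate_grid(data[[spec$x]], config)
  prof <- profile_loglik(data, spec, grid)
  if (all(prof == -Inf)) {
    stop("no candidate threshold produced a converged fit", call. = FALSE)
  }
  m_hat <- which.max(prof)  # first maximum = smallest e on the sorted grid
  e_hat <- grid[m_hat]
  if (m_hat == 1L || m_hat == length(grid)) {
    warning("threshold estimate lies at the edge of the candidate grid",
            call. = FALSE)
  }
  des <- build_design(data, spec, e_hat)
  gfit <- fit_glm(des$y, cbind(des$Z, des$X), spec$link)
  new_threshold_fit(
    e = e_hat, glm = gfit, spec = spec, method = "exact",
    profile = data.frame(e = grid, loglik = prof),
    n = nrow(data), config = config
  )
}

new_threshold_fit <- function(e, glm, spec, method, profile, n, config,
                              iterations = NULL, b = NULL) {
  structure(
    list(e = unname(e), coefficients = glm$coefficients, loglik = glm$loglik,
         glm = glm, spec = spec, method = method, profile = profile,
         n = n, config = config, converged = glm$converged,
         iterations = iterations, b = b),
    class = "threshold_fit"
  )
}

#' @export
print.threshold_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Threshold %s regression fit (%s search, %s link), n = %d\n",
              x$spec$family$name, x$method, x$spec$link, x$n))
  cat(sprintf("  threshold e = %s, log-likelihood = %s\n",
              format(x$e, digits = digits), format(x$loglik, digits = digits)))
  cat("  coefficients:\n")
  print(round(x$coefficients, digits))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
coef.threshold_fit <- function(object, ...) {
  c(object$coefficients, e = object$e)
}

#' @export
logLik.threshold_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1L,
            class = "logLik")
}
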