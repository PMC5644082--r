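#' Settings for the smooth-approximation search
#'
#' The smooth search replaces the step indicator by a logistic sigmoid with
#' scale `b`, making the likelihood differentiable in the threshold so that
#' quasi-Newton optimization applies. Larger `b` means a sharper, more
#' faithful approximation; the default `20 / sd(x)` (resolved at fit time)
#' puts about 20 sigmoid half-widths per standard deviation of the
#' predictor.
#'
#' @param b smoothing scale (> 0), or `NULL` to use `20 / sd(x)`.
#' @param tol relative-change stopping tolerance for the alternating
#'   optimization (default `1e-6`).
#' @param max_iter maximum number of alternating iterations (default 100);
#'   `0` returns the starting-value fit.
#' @param bounds optional length-2 box constraint for the threshold; defaults
#'   to the candidate-grid range.
#' @return an object of class `smooth_settings`.
#' @export
smooth_settings <- function(b = NULL, tol = 1e-6, max_iter = 100L,
                            bounds = NULL) {
  if (!is.null(b)) stopifnot(b > 0)
  stopifnot(tol > 0, max_iter >= 0)
  if (!is.null(bounds)) stopifnot(length(bounds) == 2L, bounds[1] < bounds[2])
  structure(list(b = b, tol = tol, max_iter = as.integer(max_iter),
                 bounds = bounds),
            class = "smooth_settings")
}

#' Smooth approximation to the step indicator
#'
#' The sigmoid `1 / (1 + exp(-b (x - e)))`, increasing in `x`, which tends
#' to `I(x > e)` pointwise as `b` grows (and equals exactly 0.5 at
#' `x = e`). Evaluation is overflow-safe for large `|b (x - e)|`.
#'
#' @param x numeric vector.
#' @param e threshold.
#' @param b smoothing scale, > 0.
#' @return numeric vector in (0, 1).
#' @examples
#' smooth_step(0.1, 0, 10)  # 1 / (1 + exp(-1)) = 0.7310586
#' @export
smooth_step <- function(x, e, b) {
  stopifnot(b > 0)
  stats::plogis(pmin(pmax(b * (x - e), -700), 700))
}

#' Smooth approximation to the hinge function
#'
#' The product `(x - e) * smooth_step(x, e, b)`, a differentiable surrogate
#' for `(x - e)+` that tends to it pointwise as `b` grows and is exactly 0
#' at `x = e`.
#'
#' @inheritParams smooth_step
#' @return numeric vector.
#' @export
smooth_hinge <- function(x, e, b) {
  (x - e) * smooth_step(x, e, b)
}

# Smoothed threshold-dependent block, mirroring threshold_columns().
smooth_threshold_columns <- function(x, e, b, family) {
  switch(family$name,
    step = matrix(smooth_step(x, e, b), ncol = 1L,
                  dimnames = list(NULL, "I(x>e)")),
    hinge = ,
    segmented = matrix(smooth_hinge(x, e, b), ncol = 1L,
                       dimnames = list(NULL, "(x-e)+")),
    stegmented = cbind(`(x-e)+` = smooth_hinge(x, e, b),
                       `I(x>e)` = smooth_step(x, e, b))
  )
}

#' Starting value for the smooth search
#'
#' Returns the candidate threshold with the maximal per-candidate score
#' statistic (see [score_process()]), the recommended starting value for the
#' smooth search: the score process is computed from a single null fit, so
#' this costs far less than a profile-likelihood pass.
#'
#' @param data validated data frame.
#' @param spec a [threshold_spec()].
#' @param grid numeric vector of candidate thresholds.
#' @return a single threshold value from `grid`.
#' @export
starting_threshold <- function(data, spec, grid) {
  if (length(grid) == 1L) return(grid)
  dec <- score_process(data, spec, grid)
  dec$grid[which.max(dec$T)]
}

#' Smooth-approximation threshold fit
#'
#' Fast approximate maximum-likelihood estimation: the indicator is replaced
#' by a logistic sigmoid of scale `b` and the smoothed likelihood is
#' maximized by alternating block optimization. Starting from the
#' maximal-score-statistic candidate, each iteration (1) maximizes over the
#' threshold and the coefficients of the threshold-dependent terms (and the
#' linear-`x` slope, when present) with the remaining coefficients held
#' fixed, using L-BFGS-B with the threshold box-constrained to the candidate
#' range, then (2) refits all coefficients at the current threshold. The
#' loop stops when the maximum relative parameter change falls below `tol`.
#' Finally the coefficients are re-estimated with the hard indicator at the
#' estimated threshold so that smooth and exact fits are directly
#' comparable.
#'
#' The smooth search may return a local optimum; [fit_exact()] guarantees
#' the global optimum over its grid at higher cost.
#'
#' @param data data frame with the spec's columns.
#' @param spec a [threshold_spec()].
#' @param settings a [smooth_settings()].
#' @param config a [grid_config()] used for the starting value and the
#'   threshold box constraint.
#' @return a `threshold_fit` with `method = "smooth"`; `profile` holds the
#'   per-iteration trace (threshold and smoothed log-likelihood) and
#'   `iterations` the number of alternating iterations used.
#' @export
fit_smooth <- function(data, spec, settings = smooth_settings(),
                       config = grid_config()) {
  data <- validate_data(data, spec)
  x <- data[[spec$x]]
  grid <- candidate_grid(x, config)
  b <- if (is.null(settings$b)) 20 / stats::sd(x) else settings$b
  bounds <- if (is.null(settings$bounds)) range(grid) else settings$bounds

  e <- starting_threshold(data, spec, grid)
  des <- build_design(data, spec, e)
  y <- des$y
  k_alpha <- 1L + length(spec$z)           # intercept + z block, fixed in step 1
  n_theta <- (ncol(des$Z) - k_alpha) + spec$family$p  # gamma (if any) + beta
  A <- des$Z[, seq_len(k_alpha), drop = FALSE]
  xcol <- if (spec$family$includes_linear_x) cbind(x) else NULL

  hard_fit <- function(e_) {
    d <- build_design(data, spec, e_)
    fit_glm(d$y, cbind(d$Z, d$X), spec$link)
  }
  smooth_design <- function(e_) {
    cbind(A, xcol, smooth_threshold_columns(x, e_, b, spec$family))
  }

  gfit <- fit_glm(y, cbind(des$Z, des$X), spec$link)
  theta_full <- c(e, gfit$coefficients)
  trace_e <- e
  trace_ll <- smoothed_loglik(y, smooth_design(e), gfit$coefficients, spec$link)
  converged <- settings$max_iter == 0L
  iter_used <- 0L

  if (settings$max_iter > 0L) {
    alpha <- gfit$coefficients[seq_len(k_alpha)]
    theta <- gfit$coefficients[-seq_len(k_alpha)]
    for (iter in seq_len(settings$max_iter)) {
      iter_used <- iter
      offset <- drop(A %*% alpha)
      negll <- function(par) {
        Bm <- cbind(xcol, smooth_threshold_columns(x, par[1], b, spec$family))
        eta <- offset + drop(Bm %*% par[-1])
        if (spec$link == "logistic") -loglik_logistic(y, eta)
        else 0.5 * length(y) * log(sum((y - eta)^2))
      }
      opt <- stats::optim(c(e, theta), negll, method = "L-BFGS-B",
                          lower = c(bounds[1], rep(-Inf, n_theta)),
                          upper = c(bounds[2], rep(Inf, n_theta)))
      e <- opt$par[1]
      sfit <- fit_glm(y, smooth_design(e), spec$link)
      alpha <- sfit$coefficients[seq_len(k_alpha)]
      theta <- sfit$coefficients[-seq_len(k_alpha)]
      new_full <- c(e, sfit$coefficients)
      trace_e <- c(trace_e, e)
      trace_ll <- c(trace_ll, sfit$loglik)
      rel <- max(abs(new_full - theta_full) / (abs(theta_full) + 1e-4))
      theta_full <- new_full
      if (rel < settings$tol) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged) {
    warning("smooth search reached max_iter without meeting tolerance",
            call. = FALSE)
  }
  # Local polish on the exact (hard-indicator) likelihood: the sigmoid
  # biases the threshold by O(1/b), so the profile is re-examined at the
  # grid candidates within a few smoothing widths of the smoothed optimum.
  # This removes smoothing bias from e just as the hard refit below removes
  # it from the coefficients, while staying local (unlike fit_exact).
  if (settings$max_iter > 0L) {
    near <- grid[abs(grid - e) <= 4 / b]
    if (length(near)) {
      cand <- unique(c(e, near))
      ll <- vapply(cand, function(e_) {
        f <- tryCatch(hard_fit(e_), error = function(err) NULL)
        if (is.null(f) || !f$converged) -Inf else f$loglik
      }, numeric(1))
      e <- cand[which.max(ll)]
    }
  }
  final <- hard_fit(e)
  final$converged <- final$converged && converged
  new_threshold_fit(
    e = e, glm = final, spec = spec, method = "smooth",
    profile = data.frame(iteration = seq_along(trace_e) - 1L,
                         e = trace_e, smoothed_loglik = trace_ll),
    n = nrow(data), config = config, iterations = iter_used, b = b
  )
}

# Smoothed log-likelihood at explicit coefficients (used for traces and for
# the observed-information confidence intervals of continuous families).
smoothed_loglik <- function(y, design, coefficients, link) {
  eta <- drop(design %*% coefficients)
  if (link == "logistic") {
    loglik_logistic(y, eta)
  } else {
    n <- length(y)
    s2 <- sum((y - eta)^2) / n
    -n / 2 * (log(2 * pi * s2) + 1)
  }
}
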