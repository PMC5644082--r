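#' Score process and efficient information over the candidate grid
#'
#' Fits the null model (no threshold effect: intercept, `z` covariates, and
#' the raw `x` slope for segmented/stegmented families) once, then for every
#' candidate threshold computes the score vector of the threshold-dependent
#' coefficients evaluated at the null fit, the efficient (partial)
#' information for that block with the nuisance coefficients partialled out,
#' and the standardized statistic `T_m = S' I^{-1} S`. The covariance `V` of
#' the stacked scores across candidates is assembled either model-based
#' (from the null-fit IRLS weights; default) or empirically (outer products
#' of per-observation efficient scores), and the correlation matrix
#' `R = J V J` (with `J` block-diagonal in the per-candidate inverse
#' square-root information) drives the Monte Carlo null calibration.
#'
#' Candidates whose information block is numerically singular (for example,
#' almost no observations beyond the candidate) are dropped with a warning.
#'
#' @param data data frame with the spec's columns.
#' @param spec a [threshold_spec()].
#' @param grid numeric vector of candidate thresholds.
#' @param v_type `"model"` for the model-based score covariance under the
#'   null fit, `"empirical"` for per-observation outer products.
#' @return an object of class `score_decomposition`: `grid` (kept
#'   candidates), `T` (per-candidate standardized statistics), `S` (M x p
#'   score matrix), `V`, `R`, `p`, `M`, `null_loglik`, `n_dropped`.
#' @export
score_process <- function(data, spec, grid, v_type = c("model", "empirical")) {
  v_type <- match.arg(v_type)
  data <- validate_data(data, spec, quiet = TRUE)
  if (!length(grid)) stop("empty candidate grid", call. = FALSE)
  d0 <- build_design(data, spec, grid[1])
  y <- d0$y
  Z <- d0$Z
  x <- data[[spec$x]]
  p <- spec$family$p
  M <- length(grid)
  null_fit <- fit_glm(y, Z, spec$link)
  if (!null_fit$converged) stop("null model fit did not converge", call. = FALSE)
  r <- y - null_fit$fitted_mean
  if (spec$link == "logistic") {
    w <- null_fit$irls_weights
    phi <- 1
  } else {
    w <- rep(1, length(y))
    phi <- null_fit$sigma2
  }

  XX <- stacked_threshold_columns(x, grid, spec$family)  # n x pM
  U <- drop(crossprod(XX, r)) / phi
  D <- crossprod(XX, w * Z)
  A_inv <- chol2inv(chol(crossprod(Z, w * Z)))
  if (v_type == "model") {
    V <- (crossprod(XX, w * XX) - D %*% A_inv %*% t(D)) / phi
  } else {
    Xres <- XX - Z %*% (A_inv %*% t(D))
    V <- crossprod(Xres * r) / phi^2
  }

  # per-candidate efficient information blocks, standardized statistics and
  # the correlation matrix R = J V J (J block-diagonal in the inverse
  # square-root information; p = 2 blocks use the closed-form 2x2 root)
  dV <- diag(V)
  scale_ref <- mean(abs(dV)) + 1e-300
  if (p == 1L) {
    keep <- dV > 1e-10 * scale_ref
  } else {
    i1 <- seq(1L, 2L * M, by = 2L)
    i2 <- i1 + 1L
    a <- dV[i1]
    cc <- dV[i2]
    bb <- V[cbind(i1, i2)]
    det2 <- a * cc - bb^2
    keep <- a > 1e-10 * scale_ref & cc > 1e-10 * scale_ref &
      det2 > 1e-12 * a * cc
  }
  if (!any(keep)) stop("no candidate had a non-singular information block",
                       call. = FALSE)
  if (any(!keep)) {
    warning(sum(!keep), " candidate(s) dropped: singular information block",
            call. = FALSE)
  }
  kidx <- which(keep)
  Mk <- length(kidx)
  if (p == 1L) {
    Uk <- U[kidx]
    jd <- 1 / sqrt(dV[kidx])
    Tm <- (Uk * jd)^2
    R <- V[kidx, kidx, drop = FALSE] * tcrossprod(jd)
    Smat <- matrix(Uk, ncol = 1L)
    cols <- kidx
  } else {
    cols <- as.vector(rbind(2L * kidx - 1L, 2L * kidx))
    S1 <- U[2L * kidx - 1L]
    S2 <- U[2L * kidx]
    ak <- a[kidx]; ck <- cc[kidx]; bk <- bb[kidx]; dk <- det2[kidx]
    Tm <- (ck * S1^2 - 2 * bk * S1 * S2 + ak * S2^2) / dk
    # closed-form inverse square root of each 2x2 SPD block,
    # J_i = [[c+s, -b], [-b, a+s]] / (s sqrt(a + c + 2 s)); the block-
    # diagonal action J V J is applied as vectorized row/column combinations
    s <- sqrt(dk)
    denom <- s * sqrt(ak + ck + 2 * s)
    u1 <- (ck + s) / denom
    u2 <- (ak + s) / denom
    v <- -bk / denom
    R <- V[cols, cols, drop = FALSE]
    o <- seq(1L, 2L * Mk, by = 2L)
    RO <- R[o, , drop = FALSE]
    RE <- R[o + 1L, , drop = FALSE]
    R[o, ] <- RO * u1 + RE * v
    R[o + 1L, ] <- RO * v + RE * u2
    CO <- t(R[, o, drop = FALSE])
    CE <- t(R[, o + 1L, drop = FALSE])
    R[, o] <- t(CO * u1 + CE * v)
    R[, o + 1L] <- t(CO * v + CE * u2)
    Smat <- cbind(S1, S2)
  }
  R <- (R + t(R)) / 2
  diag(R) <- 1
  structure(
    list(grid = grid[keep], T = Tm,
         S = Smat,
         V = V[cols, cols, drop = FALSE], R = R, p = p, M = Mk,
         null_loglik = null_fit$loglik, null_fit = null_fit,
         n_dropped = sum(!keep), v_type = v_type),
    class = "score_decomposition"
  )
}

# n x (p*M) matrix of threshold-dependent columns, candidate-major order.
stacked_threshold_columns <- function(x, grid, family) {
  dif <- outer(x, grid, "-")
  ind <- (dif > 0) * 1
  switch(family$name,
    step = ind,
    hinge = ,
    segmented = dif * ind,
    stegmented = {
      n <- length(x); M <- length(grid)
      out <- matrix(0, n, 2L * M)
      out[, seq(1L, 2L * M, by = 2L)] <- dif * ind
      out[, seq(2L, 2L * M, by = 2L)] <- ind
      out
    }
  )
}

#' Per-candidate likelihood-ratio statistics
#'
#' For each candidate threshold, `Q_m = 2 (loglik_alt(e_m) - loglik_null)`,
#' computed by an actual refit of the alternative (threshold) model against
#' the null model — not by the asymptotic score representation. Nesting
#' guarantees `Q_m >= 0`; tiny negative values from finite solver tolerance
#' are clipped at 0. Non-converged alternatives are recorded as `NA` with a
#' warning.
#'
#' @inheritParams score_process
#' @return numeric vector of LR statistics, same length as `grid`, `NA`
#'   where the alternative fit failed.
#' @export
lr_process <- function(data, spec, grid) {
  data <- validate_data(data, spec, quiet = TRUE)
  if (!length(grid)) stop("empty candidate grid", call. = FALSE)
  d0 <- build_design(data, spec, grid[1])
  null_fit <- fit_glm(d0$y, d0$Z, spec$link)
  if (!null_fit$converged) stop("null model fit did not converge", call. = FALSE)
  prof <- profile_core(d0$y, d0$Z, data[[spec$x]], grid, spec$family, spec$link)
  Q <- pmax(0, 2 * (prof - null_fit$loglik))
  if (anyNA(Q)) {
    warning(sum(is.na(Q)), " candidate(s) dropped: alternative fit failed",
            call. = FALSE)
  }
  Q
}

#' Monte Carlo null distribution of the maximal statistic
#'
#' Draws `B` samples of length `pM` from a multivariate normal with mean 0,
#' unit variances, and correlation matrix `R = J V J` from the score
#' decomposition; each draw is partitioned into `M` `p`-tuples, the sum of
#' squares is taken per tuple, and the maximum over tuples is recorded. The
#' resulting `B` maxima estimate the null distribution of the maximal
#' score/LR statistic.
#'
#' A Cholesky factor of `R` is used when it is numerically positive
#' definite; otherwise `R` is repaired by clipping negative eigenvalues at 0
#' (with a warning).
#'
#' @param decomp a [score_process()] result.
#' @param B number of Monte Carlo draws (warning below 100).
#' @param seed integer seed governing the draw stream.
#' @return numeric vector of `B` maximal statistics.
#' @export
mc_null_distribution <- function(decomp, B, seed) {
  stopifnot(inherits(decomp, "score_decomposition"), B >= 1)
  if (B < 100) warning("B < 100: Monte Carlo p-values will be unstable",
                       call. = FALSE)
  R <- decomp$R
  d <- nrow(R)
  L <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(L)) {
    # rounding can leave R indefinite at the 1e-13 level; a jitter of 1e-8
    # on the diagonal is far below Monte Carlo resolution
    L <- tryCatch(chol(R + diag(1e-8, d)), error = function(e) NULL)
  }
  if (is.null(L)) {
    warning("correlation matrix not positive definite; ",
            "repaired by clipping negative eigenvalues", call. = FALSE)
    eg <- eigen(R, symmetric = TRUE)
    L <- diag(sqrt(pmax(eg$values, 0)), d) %*% t(eg$vectors)
  }
  set.seed(seed)
  G <- matrix(stats::rnorm(B * d), B, d) %*% L
  G2 <- G * G
  p <- decomp$p
  if (p == 1L) {
    Qb <- G2
  } else {
    Qb <- G2[, seq(1L, d, by = 2L), drop = FALSE] +
      G2[, seq(2L, d, by = 2L), drop = FALSE]
  }
  Qb[cbind(seq_len(B), max.col(Qb, ties.method = "first"))]
}

#' Maximal score / likelihood-ratio test of the threshold effect
#'
#' Tests the null hypothesis of no threshold effect (`beta1 = 0`, jointly
#' `beta1 = beta2 = 0` for the stegmented family; the linear-`x` slope
#' `gamma` is never part of the null) by maximizing a per-candidate
#' statistic over the candidate grid. Because the threshold is unidentified
#' under the null, the reference distribution of the maximum is obtained by
#' Monte Carlo from the joint normal approximation to the score process
#' ([mc_null_distribution()]).
#'
#' The `"score"` statistic maximizes the squared standardized score and is
#' available only for single-parameter nulls (`p = 1`); the `"lr"` statistic
#' maximizes actual likelihood-ratio refits and applies to all families.
#'
#' @param data data frame with the spec's columns.
#' @param spec a [threshold_spec()].
#' @param type `"lr"` or `"score"`.
#' @param grid candidate thresholds; defaults to [candidate_grid()] under
#'   `config`.
#' @param config a [grid_config()] used when `grid` is `NULL`.
#' @param B number of Monte Carlo draws (default 10000).
#' @param seed integer seed for the Monte Carlo draw stream.
#' @param conservative if `TRUE`, report `(1 + #exceed) / (1 + B)` instead
#'   of the raw exceedance fraction.
#' @param v_type passed to [score_process()].
#' @return an object of class `threshold_test`: `statistic_type`, `Q`
#'   (per-candidate statistics on the kept grid), `stat_max`, `p_value`,
#'   `M`, `B`, `seed`, `grid`.
#' @examples
#' sc <- sim_scenario("step", n = 150, seed = 7)
#' tst <- max_test(gen_data(sc), threshold_spec("y", "x", "z", "step"),
#'                 type = "score", B = 500, seed = 1)
#' tst$p_value
#' @export
max_test <- function(data, spec, type = c("lr", "score"), grid = NULL,
                     config = grid_config(), B = 10000L, seed = 1L,
                     conservative = FALSE, v_type = c("model", "empirical")) {
  type <- match.arg(type)
  data <- validate_data(data, spec)
  if (type == "score" && spec$family$p > 1L) {
    stop("the maximal score test is only available for single-parameter ",
         "nulls (p = 1); use type = 'lr' for the stegmented family",
         call. = FALSE)
  }
  if (is.null(grid)) grid <- candidate_grid(data[[spec$x]], config)
  dec <- score_process(data, spec, grid, v_type = match.arg(v_type))
  Q <- if (type == "score") {
    dec$T
  } else {
    q <- lr_process(data, spec, dec$grid)
    q
  }
  stat_max <- max(Q, na.rm = TRUE)
  draws <- mc_null_distribution(dec, B, seed)
  n_exceed <- sum(draws > stat_max)
  p_value <- if (conservative) (1 + n_exceed) / (1 + B) else n_exceed / B
  structure(
    list(statistic_type = if (type == "score") "maxScore" else "maxLR",
         Q = Q, stat_max = stat_max, p_value = p_value,
         M = dec$M, B = as.integer(B), seed = as.integer(seed),
         grid = dec$grid, decomposition = dec),
    class = "threshold_test"
  )
}

#' @export
print.threshold_test <- function(x, ...) {
  cat(sprintf("%s test over %d candidate thresholds\n", x$statistic_type, x$M))
  cat(sprintf("  max statistic = %.4f, Monte Carlo p-value = %.4g (B = %d)\n",
              x$stat_max, x$p_value, x$B))
  invisible(x)
}
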