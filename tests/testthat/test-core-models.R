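test_that("threshold families carry the right dimensions", {
  expect_equal(threshold_family("step")$p, 1L)
  expect_equal(threshold_family("hinge")$p, 1L)
  expect_equal(threshold_family("segmented")$p, 1L)
  expect_equal(threshold_family("stegmented")$p, 2L)
  expect_false(threshold_family("hinge")$includes_linear_x)
  expect_true(threshold_family("segmented")$includes_linear_x)
  expect_true(threshold_family("stegmented")$includes_linear_x)
})

test_that("threshold columns implement the hinge and indicator definitions", {
  expect_equal(threshold_columns(c(5, 8), 7.4, "hinge"),
               matrix(c(0, 0.6), ncol = 1, dimnames = list(NULL, "(x-e)+")))
  expect_equal(threshold_columns(c(5, 8), 7.4, "step"),
               matrix(c(0, 1), ncol = 1, dimnames = list(NULL, "I(x>e)")))
  expect_equal(unname(threshold_columns(c(5, 8), 7.4, "stegmented")),
               cbind(c(0, 0.6), c(0, 1)))
  # strict indicator: a tie x == e contributes exactly 0
  expect_equal(unname(threshold_columns(c(2, 3), 3, "step")),
               cbind(c(0, 0)))
  expect_equal(unname(threshold_columns(c(2, 3, 4), 3, "hinge")),
               cbind(c(0, 0, 1)))
  expect_error(threshold_columns(c(1, NA), 0, "step"), "non-finite")
  expect_error(threshold_columns(numeric(0), 0, "step"), "non-empty")
})

test_that("threshold columns are translation equivariant", {
  set.seed(1)
  x <- rnorm(40)
  for (fam in c("step", "hinge", "segmented", "stegmented")) {
    for (cc in c(-3, 0.7, 12)) {
      expect_equal(threshold_columns(x + cc, 0.4 + cc, fam),
                   threshold_columns(x, 0.4, fam))
    }
  }
})

test_that("design matrices have the documented blocks and column order", {
  d <- data.frame(y = c(0, 1, 1), z = c(1, 2, 3), x = c(0.5, 1.5, 2.5))
  ds <- build_design(d, spec_for("step"), e = 1)
  expect_equal(ncol(ds$Z), 2L)  # intercept + z
  expect_equal(ncol(ds$X), 1L)
  dseg <- build_design(d, threshold_spec("y", "x", family = "segmented"), e = 1)
  expect_equal(colnames(dseg$Z), c("(Intercept)", "x"))
  expect_equal(unname(dseg$X[, 1]), pmax(d$x - 1, 0))
  dst <- build_design(d, spec_for("stegmented"), e = 1)
  expect_equal(colnames(dst$X), c("(x-e)+", "I(x>e)"))

  expect_error(build_design(d, spec_for("step", z = "missing_col"), 1),
               "missing")
  d2 <- d; d2$x <- 1
  expect_error(build_design(d2, spec_for("step"), 1), "constant")
  expect_error(threshold_spec("y", "y", family = "step"), "distinct")
})

test_that("data validation enforces link and completeness rules", {
  d <- data.frame(y = c(0, 1, 2), z = 1:3, x = c(1, 2, 3))
  expect_error(fit_exact(d, spec_for("step")), "\\{0, 1\\}")
  d$y <- c(0, 1, NA)
  expect_message(
    try(thresholdreg:::validate_data(d, spec_for("step")), silent = TRUE),
    "dropped"
  )
})

test_that("the IRLS fitter matches closed forms and an independent solver", {
  # intercept-only logistic with 50% ones: logit(0.5) = 0
  y <- rep(c(0, 1), 10)
  f <- fit_glm(y, cbind(rep(1, 20)), "logistic")
  expect_equal(unname(f$coefficients), 0, tolerance = 1e-8)
  expect_true(f$converged)

  # linear link on exact data reproduces the interpolating coefficients
  x <- 1:10
  f2 <- fit_glm(2 + 3 * x, cbind(1, x), "linear")
  expect_equal(unname(f2$coefficients), c(2, 3), tolerance = 1e-10)
  expect_equal(f2$deviance, 0, tolerance = 1e-16)

  # 20-row logistic fixture against an independent quasi-Newton
  # maximization of the Bernoulli log-likelihood
  set.seed(7)
  X <- cbind(1, rnorm(20), rnorm(20))
  yb <- rbinom(20, 1, plogis(0.3 + 0.8 * X[, 2]))
  f3 <- fit_glm(yb, X, "logistic")
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(yb * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  }
  opt <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(f3$coefficients), opt$par, tolerance = 1e-5)
  expect_equal(f3$loglik, -opt$value, tolerance = 1e-8)

  # and against stats::glm, coefficients and covariance
  g <- glm(yb ~ X - 1, family = binomial(),
           control = glm.control(epsilon = 1e-12))
  expect_equal(unname(f3$coefficients), unname(coef(g)), tolerance = 1e-8)
  expect_equal(unname(f3$vcov), unname(vcov(g)), tolerance = 1e-6)

  expect_error(fit_glm(yb, cbind(X, X[, 2]), "logistic"), "rank deficient")
  expect_error(fit_glm(yb[1:2], X[1:2, ], "logistic"), "more observations")
})

test_that("compiled and reference profile loops agree on both links", {
  d <- toy_logistic(n = 80, seed = 11)
  for (fam in c("step", "hinge", "segmented", "stegmented")) {
    for (link in c("logistic", "linear")) {
      spec <- spec_for(fam, link = link)
      g <- candidate_grid(d$x, grid_config(max_grid = 30))
      d0 <- build_design(d, spec, g[1])
      a <- thresholdreg:::profile_core(d0$y, d0$Z, d$x, g, spec$family, link)
      b <- thresholdreg:::profile_core_r(d0$y, d0$Z, d$x, g, spec$family, link)
      expect_equal(a, b, tolerance = 1e-9)
    }
  }
})

test_that("profile likelihood at fixed e equals the reduced-model fit", {
  d <- toy_logistic(n = 70, seed = 3)
  spec <- spec_for("hinge")
  e <- median(d$x)
  des <- build_design(d, spec, e)
  mine <- fit_glm(des$y, cbind(des$Z, des$X), "logistic")
  ora <- glm(d$y ~ d$z + pmax(d$x - e, 0), family = binomial(),
             control = glm.control(epsilon = 1e-12))
  expect_equal(mine$loglik, as.numeric(logLik(ora)), tolerance = 1e-8)
  expect_equal(profile_loglik(d, spec, e), mine$loglik, tolerance = 1e-9)
})
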