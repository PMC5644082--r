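test_that("interval width is monotone in the confidence level", {
  sc <- sim_scenario("hinge", n = 400, seed = 91)
  d <- gen_data(sc)
  fit <- suppressWarnings(fit_exact(d, spec_for("hinge")))
  hi <- model_based_ci(fit, d, level = 0.95)$intervals
  lo <- model_based_ci(fit, d, level = 0.80)$intervals
  expect_true(all(hi$upper - hi$lower > lo$upper - lo$lower))
  expect_true(all(hi$lower <= hi$estimate & hi$estimate <= hi$upper))

  sc2 <- sim_scenario("step", n = 400, seed = 92)
  d2 <- gen_data(sc2)
  fit2 <- suppressWarnings(fit_exact(d2, spec_for("step")))
  hi2 <- model_based_ci(fit2, d2, level = 0.95)$intervals
  lo2 <- model_based_ci(fit2, d2, level = 0.80)$intervals
  expect_true(all(hi2$upper - hi2$lower >= lo2$upper - lo2$lower))
})

test_that("discontinuous families get a profile-likelihood set for e", {
  sc <- sim_scenario("step", n = 300, seed = 93)
  d <- gen_data(sc)
  fit <- suppressWarnings(fit_exact(d, spec_for("step")))
  ci <- model_based_ci(fit, d)
  erow <- ci$intervals[ci$intervals$parameter == "e", ]
  expect_lte(erow$lower, fit$e)
  expect_gte(erow$upper, fit$e)
  expect_type(ci$e_profile_contiguous, "logical")
})

test_that("input validation rejects unusable robust-interval requests", {
  sc <- sim_scenario("step", n = 200, seed = 94)
  d <- gen_data(sc)
  fit <- suppressWarnings(fit_exact(d, spec_for("step")))
  expect_error(robust_ci(fit, d), "hinge")
  sc2 <- sim_scenario("hinge", n = 200, seed = 95)
  d2 <- gen_data(sc2)
  fit2 <- suppressWarnings(fit_exact(d2, spec_for("hinge")))
  expect_error(robust_ci(fit2, d2, n_boot = 0), "positive")
})

test_that("bootstrap intervals are deterministic given a seed and well-formed", {
  sc <- sim_scenario("hinge", n = 150, beta1 = -2, seed = 96)
  d <- gen_data(sc)
  fit <- suppressWarnings(fit_exact(d, spec_for("hinge"),
                                    grid_config(max_grid = 40)))
  ci1 <- suppressMessages(robust_ci(fit, d, n_boot = 60, seed = 11))
  ci2 <- suppressMessages(robust_ci(fit, d, n_boot = 60, seed = 11))
  expect_equal(ci1$intervals, ci2$intervals)
  expect_true(all(ci1$intervals$lower <= ci1$intervals$upper))
  expect_equal(nrow(ci1$replicates) + ci1$n_failed, 60)
})

test_that("the e-interval endpoints are equivariant under shifts of x", {
  sc <- sim_scenario("hinge", n = 120, beta1 = -2, seed = 97)
  d <- gen_data(sc)
  cfg <- grid_config(max_grid = 30)
  fit <- suppressWarnings(fit_exact(d, spec_for("hinge"), cfg))
  ci <- suppressMessages(robust_ci(fit, d, n_boot = 40, seed = 5))
  d2 <- d; d2$x <- d$x + 10
  fit2 <- suppressWarnings(fit_exact(d2, spec_for("hinge"), cfg))
  ci2 <- suppressMessages(robust_ci(fit2, d2, n_boot = 40, seed = 5))
  e1 <- ci$intervals[ci$intervals$parameter == "e", ]
  e2 <- ci2$intervals[ci2$intervals$parameter == "e", ]
  expect_equal(e2$lower, e1$lower + 10, tolerance = 1e-9)
  expect_equal(e2$upper, e1$upper + 10, tolerance = 1e-9)
})

test_that("the sandwich variant matches an independent HC0 computation", {
  skip_if_not_installed("sandwich")
  sc <- sim_scenario("hinge", n = 300, seed = 98)
  d <- gen_data(sc)
  fit <- suppressWarnings(fit_exact(d, spec_for("hinge")))
  ci <- robust_ci(fit, d, type = "sandwich")
  h <- pmax(d$x - fit$e, 0)
  g <- glm(y ~ z + h, family = binomial(), data = d,
           control = glm.control(epsilon = 1e-12))
  vc <- sandwich::vcovHC(g, type = "HC0")
  se <- sqrt(diag(vc))
  zq <- qnorm(0.975)
  expect_equal(ci$intervals$lower, unname(coef(g) - zq * se), tolerance = 1e-5)
  expect_equal(ci$intervals$upper, unname(coef(g) + zq * se), tolerance = 1e-5)
})

test_that("model-based coverage for the z coefficient is near nominal", {
  covered <- 0
  reps <- 100
  spec <- spec_for("hinge")
  for (i in seq_len(reps)) {
    sc <- sim_scenario("hinge", n = 400, seed = 2000 + i)
    d <- gen_data(sc)
    fit <- tryCatch(suppressWarnings(fit_exact(d, spec)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    ci <- tryCatch(suppressWarnings(model_based_ci(fit, d)),
                   error = function(e) NULL)
    if (is.null(ci) || ci$method != "wald_model") next
    zrow <- ci$intervals[ci$intervals$parameter == "z", ]
    covered <- covered + (zrow$lower <= 0.5 && 0.5 <= zrow$upper)
  }
  expect_gte(covered / reps, 0.90)
  expect_lte(covered / reps, 0.99)
})
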