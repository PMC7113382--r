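single_mediator_spec <- function() {
  path_model_spec(c("group -> m", "m -> y", "group -> y"))
}

test_that("residualize projects out covariates exactly", {
  n <- 60
  t_idx <- seq_len(n)
  dat <- data.frame(y = sin(2 * pi * t_idx / 10), cov = cos(2 * pi * t_idx / 10))
  out <- residualize(dat, "y", "cov")
  expect_equal(out$y, dat$y - mean(dat$y), tolerance = 1e-10)
  expect_false("cov" %in% names(out))

  dat2 <- data.frame(cov = rnorm(n))
  dat2$y <- 2 * dat2$cov
  out2 <- residualize(dat2, "y", "cov")
  expect_lt(max(abs(out2$y)), 1e-10)
})

test_that("residualize matches the normal-equations solution with factors", {
  set.seed(30)
  n <- 100
  dat <- data.frame(y = rnorm(n), m = rnorm(n), age = rnorm(n, 15),
                    sex = sample(c("M", "F"), n, TRUE))
  out <- residualize(dat, c("y", "m"), c("age", "sex"))
  X <- cbind(1, dat$age, as.integer(dat$sex == "M"))
  expect_equal(out$y, as.vector(dat$y - X %*% oracle_ols(X, dat$y)),
               tolerance = 1e-10)
  expect_equal(out$m, as.vector(dat$m - X %*% oracle_ols(X, dat$m)),
               tolerance = 1e-10)

  dat$age2 <- dat$age * 2
  expect_error(residualize(dat, "y", c("age", "age2")), "rank deficient")
})

test_that("path model specs validate structure and detect cycles", {
  spec <- single_mediator_spec()
  expect_equal(spec$exogenous, "group")
  expect_equal(sort(spec$variables), c("group", "m", "y"))
  expect_error(path_model_spec(c("a -> b", "b -> a")), "cycle")
  expect_error(path_model_spec(c("a -> b", "a -> b")), "duplicate")
  expect_error(path_model_spec(c("a -> a")), "self-loop")
  expect_error(path_model_spec(character(0)), "at least one edge")

  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# mediation model", "group -> m", "m -> y", ""), f)
  spec2 <- read_path_spec(f)
  expect_equal(nrow(spec2$edges), 2)
})

test_that("a saturated recursive model fits exactly with zero df", {
  d <- simulate_single_mediator(300, -0.5, 0.4, -0.3, seed = 31)
  fit <- fit_path_model(single_mediator_spec(), d)
  expect_equal(fit$df, 0)
  expect_lt(fit$chi_square, 1e-8)
  expect_equal(fit$rmsea, 0)
  expect_equal(fit$cfi, 1)
})

test_that("path estimates equal the per-equation OLS regressions", {
  d <- simulate_single_mediator(400, -0.5, 0.4, -0.3, seed = 32)
  fit <- fit_path_model(single_mediator_spec(), d)
  est <- fit$estimates
  lm_m <- lm(m ~ group, d)
  lm_y <- lm(y ~ group + m, d)
  expect_equal(est$estimate[est$from == "group" & est$to == "m"],
               unname(coef(lm_m)["group"]), tolerance = 1e-6)
  expect_equal(est$estimate[est$from == "m" & est$to == "y"],
               unname(coef(lm_y)["m"]), tolerance = 1e-6)
  expect_equal(est$estimate[est$from == "group" & est$to == "y"],
               unname(coef(lm_y)["group"]), tolerance = 1e-6)
  # p-values agree with the regression t-tests
  expect_equal(est$p[est$from == "m" & est$to == "y"],
               summary(lm_y)$coefficients["m", 4], tolerance = 1e-6)
})

test_that("the OLS solution coincides with a direct numerical ML minimization", {
  set.seed(33)
  n <- 250
  d <- data.frame(x = rnorm(n))
  d$m <- -0.4 * d$x + rnorm(n)
  d$y <- 0.5 * d$m + rnorm(n)
  d$z <- 0.3 * d$y - 0.2 * d$x + rnorm(n)
  edges <- data.frame(from = c("x", "m", "y", "x"),
                      to = c("m", "y", "z", "z"))
  spec <- path_model_spec(edges)
  fit <- fit_path_model(spec, d)
  ml <- oracle_ml_path(d, edges, spec$variables)
  expect_equal(fit$estimates$estimate, ml$coefficients, tolerance = 1e-4)
  # and the attained discrepancy is no worse than the numerical optimum
  expect_lte(fit$chi_square / (n - 1), ml$f_ml + 1e-6)
})

test_that("planted path coefficients are recovered at large n", {
  set.seed(34)
  n <- 2000
  d <- data.frame(x = rnorm(n))
  d$m <- -0.5 * d$x + rnorm(n, sd = sqrt(1 - 0.5^2))
  d$y <- 0.4 * d$m + rnorm(n, sd = sqrt(1 - 0.4^2))
  spec <- path_model_spec(c("x -> m", "m -> y", "x -> y"))
  fit <- fit_path_model(spec, d)
  est <- fit$estimates
  expect_lt(abs(est$std[est$from == "x" & est$to == "m"] + 0.5), 0.05)
  expect_lt(abs(est$std[est$from == "m" & est$to == "y"] - 0.4), 0.05)
  expect_lt(abs(est$std[est$from == "x" & est$to == "y"]), 0.05)
  # chi-square is invariant to rescaling the observed variables
  d2 <- data.frame(x = 10 * d$x, m = 0.2 * d$m, y = 3 * d$y)
  fit2 <- fit_path_model(spec, d2)
  expect_equal(fit2$chi_square, fit$chi_square, tolerance = 1e-8)
})

test_that("misfit indices behave: CFI in [0,1], RMSEA zero at or below df", {
  set.seed(35)
  n <- 500
  d <- data.frame(x = rnorm(n))
  d$m <- 0.6 * d$x + rnorm(n)
  d$y <- 0.6 * d$m + rnorm(n) # true model has x -> y only through m
  spec_restricted <- path_model_spec(c("x -> m", "m -> y"))
  fit <- fit_path_model(spec_restricted, d)
  expect_equal(fit$df, 1)
  expect_gte(fit$cfi, 0); expect_lte(fit$cfi, 1)
  expect_gt(fit$cfi, 0.9) # restriction is true, fit should be close
  expect_lt(fit$rmsea, 0.1)
  expect_gt(fit$p_fit, 0.001)
})

test_that("indirect effects are reproducible and the n_boot = 1 edge case holds", {
  d <- simulate_single_mediator(200, -0.5, 0.4, -0.3, seed = 36)
  spec <- single_mediator_spec()
  ie1 <- indirect_effect(spec, d, c("group", "m", "y"), n_boot = 250, seed = 7)
  ie2 <- indirect_effect(spec, d, c("group", "m", "y"), n_boot = 250, seed = 7)
  expect_identical(ie1$boot_estimates, ie2$boot_estimates)
  expect_identical(c(ie1$ci_low, ie1$ci_high), c(ie2$ci_low, ie2$ci_high))
  expect_lte(ie1$ci_low, ie1$point_estimate + 0.05)
  expect_gte(ie1$ci_high, ie1$point_estimate - 0.05)

  one <- indirect_effect(spec, d, c("group", "m", "y"), n_boot = 1, seed = 8)
  expect_equal(one$ci_low, one$ci_high)
  expect_equal(one$ci_low, one$boot_estimates[1])

  expect_error(indirect_effect(spec, d, c("m", "group")), "not an edge")
})

test_that("bootstrap CIs for a null indirect effect cover zero at roughly 95%", {
  covered <- 0
  n_rep <- 60
  for (s in seq_len(n_rep)) {
    d <- simulate_single_mediator(200, a = -0.5, b = 0, c_prime = -0.3,
                                  seed = 400 + s)
    ie <- indirect_effect(single_mediator_spec(), d, c("group", "m", "y"),
                          n_boot = 300, seed = s)
    if (ie$ci_low <= 0 && 0 <= ie$ci_high) covered <- covered + 1
  }
  expect_gte(covered / n_rep, 0.85)
})

test_that("trimming removes null direct paths and increases df monotonically", {
  # strong paths everywhere: nothing to remove
  d <- simulate_single_mediator(1000, -0.6, 0.5, -0.5, seed = 37)
  spec <- single_mediator_spec()
  tr <- trim_model(spec, d)
  expect_equal(nrow(tr$removed), 0)
  expect_equal(nrow(tr$spec$edges), 3)

  # c' = 0: the direct group -> y path should be eliminated, a and b kept
  kept_ab <- 0
  n_rep <- 50
  for (s in seq_len(n_rep)) {
    d0 <- simulate_single_mediator(500, a = -0.5, b = 0.4, c_prime = 0,
                                   seed = 500 + s)
    tr0 <- trim_model(spec, d0)
    e <- tr0$spec$edges
    ok <- !any(e$from == "group" & e$to == "y") &&
      any(e$from == "group" & e$to == "m") &&
      any(e$from == "m" & e$to == "y")
    if (ok) kept_ab <- kept_ab + 1
  }
  expect_gte(kept_ab / n_rep, 0.9)

  # df strictly increases with each removal
  d1 <- simulate_single_mediator(500, a = -0.5, b = 0, c_prime = 0, seed = 38)
  fit_full <- fit_path_model(spec, d1)
  tr1 <- trim_model(spec, d1)
  expect_gt(tr1$fit$df, fit_full$df)
  expect_equal(tr1$fit$df, fit_full$df + nrow(tr1$removed))
})
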