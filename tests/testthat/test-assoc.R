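test_that("linear association recovers a planted standardized effect", {
  set.seed(50)
  n <- 3000
  x <- rnorm(n)
  age <- rnorm(n, 50, 10)
  sex <- sample(c("F", "M"), n, TRUE)
  y <- 0.3 * x + rnorm(n, 0, sqrt(1 - 0.09))
  res <- fit_continuous(y, x, age, sex, "toy", "self_report")
  se <- (res$ci_high - res$ci_low) / (2 * 1.96)
  expect_lt(abs(res$effect - 0.3), 3 * se)
  expect_true(res$ci_low <= res$effect && res$effect <= res$ci_high)
  ## exact self-copy -> beta 1
  res2 <- suppressWarnings(fit_continuous(x, x, age, sex))
  expect_equal(res2$effect, 1, tolerance = 1e-10)
  ## null exposure
  res3 <- fit_continuous(rnorm(n), x, age, sex)
  expect_lt(abs(res3$effect), 0.06)
})

test_that("logistic association reports OR per SD and guards separation", {
  set.seed(51)
  n <- 5000
  x <- rnorm(n)
  age <- rnorm(n, 50, 10)
  sex <- sample(c("F", "M"), n, TRUE)
  pr <- 1 / (1 + exp(-(-0.8 + 0.2 * x)))
  y <- rbinom(n, 1, pr)
  res <- fit_binary(y, x, age, sex, "disease", "episcore")
  log_se <- (log(res$ci_high) - log(res$ci_low)) / (2 * 1.96)
  expect_lt(abs(log(res$effect) - 0.2), 3 * log_se)
  ## independent exposure -> OR near 1
  res2 <- fit_binary(y, rnorm(n), age, sex)
  expect_lt(abs(log(res2$effect)), 0.1)
  ## perfect separation is an error, not a silent estimate
  xs <- c(rnorm(30, -3), rnorm(30, 3))
  ys <- rep(c(0, 1), each = 30)
  expect_error(fit_binary(ys, xs, rnorm(60, 50, 5), rep(c("F", "M"), 30)),
               "separation")
  ## single-class outcome skipped with warning
  expect_warning(out <- fit_binary(rep(1, 50), rnorm(50), rnorm(50, 50),
                                   rep("F", 50)), "single class")
  expect_null(out)
})

test_that("Cox model recovers a planted log hazard ratio", {
  set.seed(52)
  n <- 2000
  x <- rnorm(n)
  age <- rnorm(n, 60, 8)
  sex <- sample(c("F", "M"), n, TRUE)
  t_event <- rexp(n, 0.1 * exp(0.15 * x))
  cens <- runif(n, 0, 15)
  time <- pmin(t_event, cens)
  event <- as.integer(t_event <= cens)
  res <- fit_mortality(time, event, x, age, sex, "episcore")
  log_se <- (log(res$ci_high) - log(res$ci_low)) / (2 * 1.96)
  expect_lt(abs(log(res$effect) - 0.15), 3 * log_se)
  expect_equal(res$model, "cox")
  ## independent exposure -> HR near 1
  res2 <- fit_mortality(time, event, rnorm(n), age, sex)
  expect_lt(abs(log(res2$effect)), 0.1)
  ## all censored -> skipped
  expect_warning(out <- fit_mortality(time, rep(0, n), x, age, sex), "no events")
  expect_null(out)
  expect_error(fit_mortality(-time, event, x, age, sex), "nonnegative")
})

test_that("brain-volume models adjust for intracranial volume", {
  set.seed(53)
  n <- 3000
  x <- rnorm(n)
  age <- rnorm(n, 70, 5)
  sex <- sample(c("F", "M"), n, TRUE)
  icv <- rnorm(n, 1500, 100)
  vol <- -0.2 * x + 0.4 * as.numeric(scale(icv)) + rnorm(n, 0, 0.8)
  res <- fit_brain(vol, x, age, sex, icv, exposure_label = "episcore")
  se <- (res$ci_high - res$ci_low) / (2 * 1.96)
  expect_lt(abs(res$effect - (-0.2 / sd(vol))), 3 * se)
  expect_error(fit_brain(vol, x, age, sex, -icv), "positive")
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.1, NA)), "\\(0, 1\\]")
  set.seed(54)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
  }
})

test_that("per-SD effects are invariant to exposure rescaling", {
  set.seed(55)
  n <- 800
  x <- rnorm(n)
  age <- rnorm(n, 50, 10)
  sex <- sample(c("F", "M"), n, TRUE)
  y_bin <- rbinom(n, 1, 1 / (1 + exp(-(-0.5 + 0.3 * x))))
  t_ev <- rexp(n, 0.1 * exp(0.2 * x)); cens <- runif(n, 0, 12)
  time <- pmin(t_ev, cens); event <- as.integer(t_ev <= cens)
  for (k in c(0.01, 1, 250)) {
    a <- fit_binary(y_bin, k * x, age, sex)
    b <- fit_binary(y_bin, x, age, sex)
    expect_equal(a$effect, b$effect, tolerance = 1e-8)
    expect_equal(a$p, b$p, tolerance = 1e-8)
    a2 <- fit_mortality(time, event, k * x, age, sex)
    b2 <- fit_mortality(time, event, x, age, sex)
    expect_equal(a2$effect, b2$effect, tolerance = 1e-6)
  }
})

test_that("the battery fits both exposures and fills in FDR", {
  sc <- small_cohort(n = 300, p = 40, seed = 56,
                     arch = effect_architecture(0L, 5L, 3L))
  sc <- simulate_outcomes(sc, seed = 56)
  score <- rnorm(300)
  res <- association_battery(sc$outcomes, log_units(sc$cohort$units), score,
                             sc$cohort$age, sc$cohort$sex)
  expect_equal(nrow(res), 8)
  expect_setequal(unique(res$exposure), c("self_report", "episcore"))
  expect_true(all(res$p_fdr >= res$p - 1e-15))
  expect_equal(res$p_fdr, bh_oracle(res$p), tolerance = 1e-12)
})
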