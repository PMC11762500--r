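test_that("precorrection matches a two-step explicit OLS-residual oracle", {
  set.seed(40)
  n <- 100; p <- 10
  mv <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("cg%02d", 1:p)))
  units <- rexp(n, 1 / 9)
  age <- rnorm(n, 50, 10)
  sex <- sample(c("F", "M"), n, TRUE)
  smoking <- rnorm(n)
  batch <- factor(sample(1:3, n, TRUE))
  pre <- precorrect(mv, units, age, sex, smoking, batch)

  xy <- cbind(1, age, as.numeric(factor(sex)) - 1, smoking)
  y_or <- log1p(units) - xy %*% solve(crossprod(xy), crossprod(xy, log1p(units)))
  expect_equal(pre$y_resid, as.numeric(y_or), tolerance = 1e-10)

  bmat <- stats::model.matrix(~ batch)[, -1]
  xx <- cbind(xy, bmat)
  for (j in c(1, 5, 10)) {
    rj <- mv[, j] - xx %*% solve(crossprod(xx), crossprod(xx, mv[, j]))
    expect_equal(pre$X_std[, j], as.numeric(scale(rj)), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  expect_equal(unname(colMeans(pre$X_std)), rep(0, p), tolerance = 1e-10)
  expect_equal(unname(apply(pre$X_std, 2, sd)), rep(1, p), tolerance = 1e-10)

  ## a column equal to a covariate has zero residual variance -> dropped
  mv2 <- cbind(mv, cgdup = age)
  expect_warning(pre2 <- precorrect(mv2, units, age, sex, smoking, batch),
                 "zero variance")
  expect_identical(pre2$dropped, "cgdup")
})

test_that("posterior summaries count mixture memberships correctly", {
  beta <- matrix(c(0.5, 0.4, 0.6, 0,
                   0,   0,   0,   0), nrow = 4,
                 dimnames = list(NULL, c("cgB", "cgA")))
  comp <- matrix(c(1L, 2L, 1L, 0L,
                   0L, 0L, 0L, 0L), nrow = 4,
                 dimnames = list(NULL, c("cgB", "cgA")))
  post <- summarize_posterior(list(beta = beta, comp = comp), used_iterations = 4)
  s <- post$summary
  expect_equal(s$pip[s$cpg == "cgB"], 0.75)
  expect_equal(s$pip[s$cpg == "cgA"], 0)
  expect_equal(s$mean_beta[s$cpg == "cgB"], mean(c(0.5, 0.4, 0.6, 0)))
  expect_equal(s$mean_beta[s$cpg == "cgA"], 0)
  ## occupancy fractions sum to one per CpG
  occ <- as.matrix(s[, grep("^occ_", names(s))])
  expect_equal(unname(rowSums(occ)), rep(1, 2))
  ## variance-explained draws are the per-iteration sum of squared effects
  expect_equal(post$ve_draws, rowSums(beta^2))
  expect_error(summarize_posterior(list(beta = beta[1, , drop = FALSE],
                                        comp = comp[1, , drop = FALSE])),
               "at least 2")
})

test_that("significance calls use a strict PIP threshold and stable ordering", {
  mk_post <- function(pips) {
    s <- data.frame(cpg = sprintf("cg%02d", seq_along(pips)),
                    mean_beta = 0.1, se = 0.01, pip = pips,
                    stringsAsFactors = FALSE)
    structure(list(summary = s, pip_threshold = 0.95), class = "bayesr_posterior")
  }
  hits <- call_significant(mk_post(c(0.96, 0.95, 0.99)))
  expect_equal(hits$cpg, c("cg03", "cg01"))
  expect_equal(nrow(call_significant(mk_post(c(0, 0, 0)))), 0)
  ## threshold 0 returns every CpG with any nonzero occupancy
  expect_equal(nrow(call_significant(mk_post(c(0.2, 0, 0.01)), threshold = 0)), 2)
})

test_that("permuting CpG columns permutes the posterior identically", {
  set.seed(44)
  n <- 60; p <- 8
  x <- scale(matrix(rnorm(n * p), n, p))
  colnames(x) <- sprintf("cg%02d", 1:p)
  y <- x[, 2] * 0.5 + rnorm(n)
  cfg <- bayesr_config(mixture_variances = c(0.01, 0.1), burn_in = 100,
                       draws_retained = 200, thin = 1, used_iterations = 200,
                       seed = 9)
  p1 <- summarize_posterior(gibbs_sample(x, y, cfg))
  perm <- sample(p)
  p2 <- summarize_posterior(gibbs_sample(x[, perm], y, cfg))
  s1 <- p1$summary[order(p1$summary$cpg), ]
  s2 <- p2$summary[order(p2$summary$cpg), ]
  expect_equal(s1, s2, ignore_attr = TRUE)
})

test_that("null phenotype yields small PIPs and variance near zero", {
  set.seed(45)
  n <- 150; p <- 60
  x <- scale(matrix(rnorm(n * p), n, p))
  colnames(x) <- sprintf("cg%03d", 1:p)
  y <- rnorm(n)
  cfg <- bayesr_config(burn_in = 200, draws_retained = 400, thin = 1,
                       used_iterations = 400, seed = 3)
  post <- summarize_posterior(gibbs_sample(x, y, cfg))
  expect_lt(post$ve_mean, 0.1)
  expect_equal(sum(post$summary$pip > 0.95), 0)
  expect_true(all(post$ve_draws >= 0 & post$ve_draws <= 1 + 1e-8))
  expect_error(gibbs_sample(x, c(y[-1], NA), cfg), "non-finite")
})

test_that("the Geweke diagnostic separates stationary and shifted chains", {
  ## equal segments -> z exactly 0
  z0 <- suppressWarnings(geweke(rep(c(1, 2), 100)))
  expect_equal(z0$z, 0, tolerance = 1e-12)
  expect_warning(g <- geweke(rep(3, 100)), "constant")
  expect_equal(g$z, 0)
  ## planted step change of >= 3 segment SDs -> |z| > 3
  set.seed(46)
  shifted <- c(rnorm(1000, 0, 1), rnorm(1000, 3, 1))
  expect_gt(abs(geweke(shifted)$z), 3)
  ## calibration under the null across seeds
  set.seed(47)
  zs <- replicate(60, geweke(rnorm(2000))$z)
  expect_gte(mean(abs(zs) < 1.96), 0.85)
  ## autocorrelation table attached
  expect_named(geweke(rnorm(500))$acf, c("lag", "acf"))
  expect_error(geweke(rnorm(50), frac_first = 0.05), "at least 10")
  expect_error(geweke(rnorm(100), frac_first = 0.6, frac_last = 0.6), "overlap")
})

test_that("config invariants are enforced", {
  expect_error(bayesr_config(mixture_variances = c(0.01, 0.001)), "increasing")
  expect_error(bayesr_config(mixture_variances = c(-1, 0.1)), "increasing")
  expect_error(bayesr_config(thin = 0), "thin")
  expect_error(bayesr_config(pip_threshold = 1), "pip_threshold")
  expect_error(bayesr_config(used_iterations = 5000, draws_retained = 1000,
                             thin = 1), "exceeds")
  cfg <- bayesr_config(draws_retained = 1000, thin = 5, used_iterations = NULL,
                       burn_in = 10)
  expect_equal(cfg$n_store, 200L)
  expect_equal(cfg$used_iterations, 200L)
})
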