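test_that("feature pre-selection respects list order and set arithmetic", {
  m <- matrix(runif(20), 4, 5,
              dimnames = list(paste0("S", 1:4), paste0("cg", 1:5)))
  expect_error(preselect_features(m, c("cgA", "cgB")), "nothing to train on")
  expect_error(preselect_features(m, character(0)), "nonempty")
  expect_identical(suppressMessages(preselect_features(m, colnames(m))), m)
  out <- suppressMessages(preselect_features(m, c("cg4", "cgZ", "cg2")))
  expect_identical(colnames(out), c("cg4", "cg2"))
  expect_warning(suppressMessages(intersect_450k(m, c("cg1", "cg1", "cg3"))),
                 "dedup")
  out2 <- suppressWarnings(suppressMessages(
    intersect_450k(m, c("cg1", "cg1", "cg3"))))
  expect_identical(colnames(out2), c("cg1", "cg3"))
})

test_that("mean imputation fills missing values with per-CpG observed means", {
  m <- matrix(c(0.2, NA, 0.4, 0.1, 0.2, 0.3), 3, 2,
              dimnames = list(NULL, c("cg1", "cg2")))
  out <- impute_missing(m)
  expect_equal(unname(out[2, "cg1"]), 0.3)
  expect_identical(out[-2, ], m[-2, ])
  expect_identical(impute_missing(m[, 2, drop = FALSE]), m[, 2, drop = FALSE])
  ## random missingness leaves column means unchanged
  set.seed(5)
  big <- matrix(runif(2000), 100, 20,
                dimnames = list(NULL, paste0("cg", 1:20)))
  miss <- big
  miss[sample(length(miss), 100)] <- NA
  filled <- impute_missing(miss)
  expect_false(anyNA(filled))
  expect_equal(colMeans(filled), colMeans(miss, na.rm = TRUE), tolerance = 1e-12)
  all_na <- big
  all_na[, 3] <- NA
  expect_error(impute_missing(all_na), "cg3")
})

test_that("elastic net recovers a planted single-feature signal", {
  set.seed(10)
  n <- 500; p <- 10
  x <- matrix(runif(n * p, 0.2, 0.8), n, p,
              dimnames = list(NULL, sprintf("cg%02d", 1:p)))
  z1 <- as.numeric(scale(x[, 1]))
  y <- 3 * z1 + rnorm(n, 0, 0.05)
  model <- train_elastic_net(x, y, seed = 2)
  expect_equal(names(which.max(abs(model$weights))), "cg01")
  expect_lte(model$meta$n_selected, 5)
  ## same inputs, same seed -> identical weights
  model2 <- train_elastic_net(x, y, seed = 2)
  expect_identical(model$weights, model2$weights)
  expect_identical(model$meta$lambda, model2$meta$lambda)
})

test_that("pure-noise response shrinks to a near-null model", {
  set.seed(11)
  n <- 200; p <- 100
  x <- matrix(runif(n * p), n, p, dimnames = list(NULL, sprintf("cg%03d", 1:p)))
  y <- rnorm(n)
  model <- train_elastic_net(x, y, seed = 3)
  expect_lte(model$meta$n_selected, 5)
  expect_error(train_elastic_net(x, rep(1, n)), "constant")
  x2 <- x
  x2[, 7] <- 0.5
  expect_warning(train_elastic_net(x2, y, seed = 3), "zero-variance")
})

test_that("projection is a standardized weighted sum with set-invariance", {
  set.seed(12)
  x <- matrix(runif(200, 0.1, 0.9), 20, 10,
              dimnames = list(paste0("S", 1:20), sprintf("cg%02d", 1:10)))
  w <- c(cg03 = 0.7)
  model <- structure(list(weights = w, intercept = 0,
                          feature_means = c(cg03 = 0.5),
                          feature_sds = c(cg03 = 0.1),
                          meta = list()), class = "episcore_model")
  s <- project(model, x)
  expect_equal(s, 0.7 * as.numeric(scale(x[, "cg03"])),
               ignore_attr = TRUE)
  ## adding non-model columns leaves the projection unchanged
  extra <- cbind(x, cgZZ = runif(20))
  expect_equal(project(model, extra), s)
  ## training-parameter standardization uses stored means/sds
  s_tr <- project(model, x, standardize = "training")
  expect_equal(s_tr, 0.7 * (x[, "cg03"] - 0.5) / 0.1, ignore_attr = TRUE)
  expect_error(project(model, x[, 1:2]), "no model CpGs")
})

test_that("evaluate matches a brute-force least-squares oracle", {
  set.seed(30)
  n <- 30
  score <- rnorm(n)
  units <- rexp(n, 1 / 8)
  age <- runif(n, 20, 80)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  rep <- evaluate(score, units, age, sex)
  y <- log(units + 1)
  sexn <- as.numeric(factor(sex))
  r2 <- function(xmat) {
    fit <- xmat %*% solve(crossprod(xmat), crossprod(xmat, y))
    1 - sum((y - fit)^2) / sum((y - mean(y))^2)
  }
  inc_oracle <- 100 * (r2(cbind(1, age, sexn, score)) - r2(cbind(1, age, sexn)))
  expect_equal(rep$incremental_r2, inc_oracle, tolerance = 1e-10)
  expect_equal(rep$pearson_r, cor(score, y), tolerance = 1e-12)
  expect_equal(rep$n, n)
  expect_error(evaluate(rep(1, n), units, age, sex), "constant")
})

test_that("incremental R2 equals the squared semipartial correlation", {
  set.seed(31)
  for (i in 1:5) {
    n <- 80
    score <- rnorm(n); units <- rexp(n, 0.1)
    age <- rnorm(n, 50, 10); sexn <- rbinom(n, 1, 0.5)
    rep <- evaluate(score, units, age, sexn)
    e_score <- residuals(lm(score ~ age + sexn))
    sr2 <- cor(log1p(units), e_score)^2 * 100
    expect_equal(rep$incremental_r2, sr2, tolerance = 1e-8)
  }
})

test_that("perfect affine predictor attains r = 1 and the full incremental R2", {
  set.seed(32)
  n <- 100
  units <- rexp(n, 1 / 10)
  age <- rnorm(n, 50, 10); sex <- sample(c("F", "M"), n, TRUE)
  score <- 2 * log1p(units) - 3
  rep <- suppressWarnings(evaluate(score, units, age, sex))
  expect_equal(rep$pearson_r, 1, tolerance = 1e-12)
  y <- log1p(units); sexn <- as.numeric(factor(sex))
  r2_cov <- summary(lm(y ~ age + sexn))$r.squared
  expect_equal(rep$incremental_r2, 100 * (1 - r2_cov), tolerance = 1e-8)
})

test_that("training is insulated from the test data (mutation check)", {
  sc <- small_cohort(n = 240, p = 60, seed = 21)
  sp <- split_cohort(sc, seed = 21)
  g1 <- suppressWarnings(design_grid(sp$train, sp$test,
                                     feature_sets = list(all = NULL),
                                     training_subsets = "everyone",
                                     nfolds = 5, seed = 4))
  ## perturb the test set completely; the trained model must be bit-identical
  sp$test$methyl[] <- matrix(runif(length(sp$test$methyl), 0.3, 0.7),
                             nrow(sp$test$methyl))
  g2 <- suppressWarnings(design_grid(sp$train, sp$test,
                                     feature_sets = list(all = NULL),
                                     training_subsets = "everyone",
                                     nfolds = 5, seed = 4))
  expect_identical(g1$models$everyone.all$weights, g2$models$everyone.all$weights)
  expect_identical(g1$models$everyone.all$meta$lambda,
                   g2$models$everyone.all$meta$lambda)
})

test_that("the design grid trains one model per cell and reports all subsets", {
  sc <- small_cohort(n = 400, p = 80, seed = 22,
                     arch = effect_architecture(0L, 0L, 8L, frac_large = 0.04))
  sp <- split_cohort(sc, seed = 22)
  presel <- c(sc$truth$causal, colnames(sc$methyl)[1:5])
  grid <- suppressWarnings(design_grid(
    sp$train, sp$test,
    feature_sets = list(all = NULL, preselected = unique(presel)),
    training_subsets = c("everyone", "normal_week"),
    nfolds = 5, seed = 1))
  expect_length(grid$models, 4)
  expect_setequal(unique(grid$report$feature_set), c("all", "preselected"))
  expect_setequal(unique(grid$report$training_subset),
                  c("everyone", "normal_week"))
  ## every model was evaluated on the full test set
  expect_equal(sum(grid$report$subset_label == "all"), 4)
  expect_true(all(grid$report$n_features >= 0))
})

test_that("sex-specific designs match sample sizes and cross-test correctly", {
  sc <- small_cohort(n = 500, p = 60, seed = 23,
                     arch = effect_architecture(0L, 0L, 5L, frac_large = 0.05))
  sp <- split_cohort(sc, seed = 23)
  n_f <- sum(sp$train$cohort$sex == "F")
  n_m <- sum(sp$train$cohort$sex == "M")
  m <- min(n_f, n_m)
  res <- suppressWarnings(sex_specific_designs(sp$train, sp$test,
                                               nfolds = 5, seed = 2))
  expect_equal(res$models$female$meta$n_train, m)
  expect_equal(res$models$male$meta$n_train, m)
  expect_equal(res$models$agnostic$meta$n_train, floor(m / 2) + ceiling(m / 2))
  expect_equal(nrow(res$report), 6)
  expect_setequal(unique(res$report$mode),
                  c("sex_specific", "opposite_sex", "sex_agnostic"))
  ## one sex absent -> error
  idx_f <- which(sp$train$cohort$sex == "F")
  sp$train$cohort$sex[idx_f] <- "M"
  expect_error(sex_specific_designs(sp$train, sp$test), "both sexes")
})
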