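#' Restrict a methylation matrix to a pre-selected CpG list
#'
#' Feature pre-selection ahead of elastic net: the matrix is restricted to
#' the CpGs in `cpg_list` that are present, preserving the list's order.
#' Pre-filtering to CpGs with prior evidence of association has been shown
#' to improve penalized-regression predictors when p >> n.
#'
#' @param matrix samples-by-CpGs methylation matrix with CpG colnames.
#' @param cpg_list character vector of CpG identifiers; duplicates are
#'   removed with a warning.
#' @return the column-restricted matrix.
#' @export
preselect_features <- function(matrix, cpg_list) {
  if (length(cpg_list) == 0) stop("cpg_list must be nonempty")
  if (anyDuplicated(cpg_list)) {
    warning("duplicated CpG identifiers in list; deduplicating")
    cpg_list <- unique(cpg_list)
  }
  keep <- cpg_list[cpg_list %in% colnames(matrix)]
  if (length(keep) == 0) {
    stop("no CpGs in the list are present in the matrix; nothing to train on")
  }
  message(length(keep), " of ", length(cpg_list), " listed CpGs retained")
  matrix[, keep, drop = FALSE]
}

#' Intersect a methylation matrix with an array probe list
#'
#' Restricts to probes also present on another array platform (e.g. the
#' Illumina 450K array) so a trained score remains applicable across
#' platforms. Same mechanics as [preselect_features()]; the list semantics
#' differ (platform membership rather than prior association evidence).
#'
#' @inheritParams preselect_features
#' @param probe_list character vector of probe identifiers.
#' @return the column-restricted matrix.
#' @export
intersect_450k <- function(matrix, probe_list) {
  preselect_features(matrix, probe_list)
}

#' Mean-impute missing methylation values
#'
#' Missing entries are replaced with the mean of the observed values of the
#' same CpG across all samples; observed entries are unchanged.
#'
#' @param matrix samples-by-CpGs methylation matrix, possibly with `NA`s.
#' @return the matrix with no missing entries.
#' @export
impute_missing <- function(matrix) {
  if (!anyNA(matrix)) return(matrix)
  na_counts <- colSums(is.na(matrix))
  all_missing <- na_counts == nrow(matrix)
  if (any(all_missing)) {
    stop("CpG(s) with no observed values cannot be imputed: ",
         paste(head(colnames(matrix)[all_missing], 5), collapse = ", "))
  }
  means <- colMeans(matrix, na.rm = TRUE)
  idx <- which(is.na(matrix), arr.ind = TRUE)
  matrix[idx] <- means[idx[, 2]]
  matrix
}

#' Train an elastic-net EpiScore
#'
#' CpG values are scaled to mean zero and unit variance in the training set,
#' so the fitted coefficients are standardized effect sizes. An elastic net
#' (`glmnet`, mixing parameter `alpha`, default 0.5) is fitted over a lambda
#' path and the shrinkage parameter minimizing the mean cross-validated
#' squared prediction error is selected (ties broken toward the smallest
#' lambda, i.e. the densest of the tied models). Fold assignment is seeded,
#' so the fit is deterministic given the seed.
#'
#' @param X complete (post-imputation) samples-by-CpGs matrix of beta values.
#' @param y numeric response, log(units + 1).
#' @param alpha elastic-net mixing parameter in \[0, 1\].
#' @param nfolds number of cross-validation folds.
#' @param seed integer seed for fold assignment.
#' @param feature_label,subset_label metadata labels recorded in the model.
#' @return an `episcore_model`: sparse standardized weights with per-feature
#'   training means/sds and metadata.
#' @export
train_elastic_net <- function(X, y, alpha = 0.5, nfolds = 10, seed = 1L,
                              feature_label = "all", subset_label = "everyone") {
  n <- nrow(X)
  if (length(y) != n) stop("X and y dimensions differ")
  if (anyNA(X) || anyNA(y)) stop("X and y must be complete; impute first")
  if (n < nfolds) stop("need at least as many samples as folds")
  if (sd(y) == 0) stop("constant response; nothing to train on")

  cm <- colMeans(X)
  csd <- col_sds(X)
  zero_var <- csd < 1e-12
  if (any(zero_var)) {
    warning("dropping ", sum(zero_var), " zero-variance CpG(s) before standardization")
    X <- X[, !zero_var, drop = FALSE]
    cm <- cm[!zero_var]
    csd <- csd[!zero_var]
  }
  xs <- sweep(sweep(X, 2, cm), 2, csd, "/")

  set.seed(substream_seed(seed, "folds"))
  foldid <- sample(rep_len(seq_len(nfolds), n))
  cv <- glmnet::cv.glmnet(xs, y, alpha = alpha, foldid = foldid,
                          standardize = FALSE)
  lambda <- min(cv$lambda[cv$cvm <= min(cv$cvm) + 1e-12])
  co <- coef(cv, s = lambda)
  w <- as.numeric(co)[-1]
  names(w) <- rownames(co)[-1]
  nz <- w[w != 0]

  structure(list(
    weights = nz,
    intercept = as.numeric(co)[1],
    feature_means = cm[names(nz)],
    feature_sds = csd[names(nz)],
    meta = list(alpha = alpha, lambda = lambda, nfolds = nfolds,
                n_train = n, n_candidates = length(cm) + sum(zero_var),
                n_selected = length(nz),
                feature_label = feature_label, subset_label = subset_label,
                seed = seed)
  ), class = "episcore_model")
}

#' @export
print.episcore_model <- function(x, ...) {
  cat("EpiScore model:", x$meta$n_selected, "of", x$meta$n_candidates,
      "CpGs selected (alpha =", x$meta$alpha,
      ", lambda =", signif(x$meta$lambda, 4), ")\n")
  cat("  trained on n =", x$meta$n_train,
      "| subset:", x$meta$subset_label,
      "| features:", x$meta$feature_label, "\n")
  invisible(x)
}

#' Project an EpiScore into a target methylation matrix
#'
#' Each sample's score is the weighted sum of its (standardized) CpG values
#' over the model CpGs present in the target matrix. By default CpG values
#' are scaled to mean zero and unit variance within the *target* cohort
#' before weighting; `standardize = "training"` instead reuses the training
#' means/sds stored in the model.
#'
#' @param model an `episcore_model`.
#' @param matrix target samples-by-CpGs beta-value matrix.
#' @param standardize `"target"` (default) or `"training"`.
#' @return named numeric score vector, one value per target sample.
#' @export
project <- function(model, matrix, standardize = c("target", "training")) {
  standardize <- match.arg(standardize)
  stopifnot(inherits(model, "episcore_model"))
  if (length(model$weights) == 0) {
    ## empty-support (null) model: the score is constant
    message("model has no nonzero weights; returning a constant score")
    return(setNames(rep(0, nrow(matrix)), rownames(matrix)))
  }
  cpgs <- names(model$weights)
  present <- cpgs[cpgs %in% colnames(matrix)]
  if (length(present) == 0) stop("no model CpGs present in the target matrix")
  n_missing <- length(cpgs) - length(present)
  if (n_missing > 0) {
    message(n_missing, " of ", length(cpgs), " model CpGs absent from target; ",
            "projecting on the remaining ", length(present))
  }
  x <- matrix[, present, drop = FALSE]
  if (standardize == "target") {
    cm <- colMeans(x)
    csd <- col_sds(x)
  } else {
    cm <- model$feature_means[present]
    csd <- model$feature_sds[present]
  }
  dead <- csd < 1e-12
  if (any(dead)) {
    warning(sum(dead), " model CpG(s) have zero variance in the target; ",
            "they contribute 0 to the score")
    csd[dead] <- 1
  }
  z <- sweep(sweep(x, 2, cm), 2, csd, "/")
  if (any(dead)) z[, dead] <- 0
  drop(z %*% model$weights[present])
}

#' Evaluate an EpiScore against self-reported consumption
#'
#' Reports the Pearson correlation of the score with log(units + 1), the
#' incremental R-squared (percentage points) upon adding the score to a
#' linear model adjusting for age and sex, and the two-sided marginal
#' p-value of the score coefficient in that full model. Incomplete cases
#' are dropped.
#'
#' @param score numeric score vector.
#' @param units nonnegative units-per-week vector.
#' @param age,sex covariate vectors.
#' @param subset_label label recorded in the report.
#' @return one-row data.frame: `subset_label`, `n`, `pearson_r`,
#'   `incremental_r2` (percent), `marginal_p`.
#' @export
evaluate <- function(score, units, age, sex, subset_label = "all") {
  keep <- complete.cases(score, units, age, sex)
  score <- score[keep]; units <- units[keep]
  age <- age[keep]; sex <- sex[keep]
  n <- length(score)
  if (n < 4) stop("need at least 4 complete cases")
  y <- log_units(units)
  if (sd(score) == 0 || sd(y) == 0) {
    stop("constant score or outcome; correlation undefined")
  }
  sexn <- as.numeric(factor(sex))
  full <- lm(y ~ age + sexn + score)
  null <- lm(y ~ age + sexn)
  inc <- 100 * (summary(full)$r.squared - summary(null)$r.squared)
  p <- summary(full)$coefficients["score", "Pr(>|t|)"]
  data.frame(subset_label = subset_label, n = n,
             pearson_r = cor(score, y),
             incremental_r2 = inc, marginal_p = p,
             stringsAsFactors = FALSE)
}

## training-subset index helper
training_subset_idx <- function(cohort, label) {
  switch(label,
         everyone = seq_len(nrow(cohort)),
         normal_week = which(cohort$normal_week_flag == "normal"),
         stop("unknown training subset: ", label))
}

#' Run the EpiScore design grid
#'
#' Trains one model per (feature set x training subpopulation) cell and
#' evaluates every model on the full test set and on each normal-week-flag
#' stratum of the test set ("all" keeps unknown-flag samples; the flag
#' strata exclude them). Feature sets are named CpG lists (`NULL` = all
#' CpGs); training subsets are `"everyone"` and/or `"normal_week"`.
#'
#' @param train,test `synthetic_cohort` objects (or lists with `methyl` and
#'   `cohort` elements).
#' @param feature_sets named list of CpG id vectors, `NULL` entries meaning
#'   the full methylome.
#' @param training_subsets character vector of subset labels.
#' @param alpha,nfolds,seed passed to [train_elastic_net()].
#' @return list with `models` (named list of `episcore_model`) and `report`
#'   (data.frame of evaluation rows with feature counts).
#' @export
design_grid <- function(train, test,
                        feature_sets = list(all = NULL),
                        training_subsets = c("everyone", "normal_week"),
                        alpha = 0.5, nfolds = 10, seed = 1L) {
  models <- list()
  rows <- list()
  test_flag <- test$cohort$normal_week_flag
  eval_subsets <- list(
    all = seq_len(nrow(test$cohort)),
    normal = which(test_flag == "normal"),
    more = which(test_flag == "more"),
    less = which(test_flag == "less")
  )
  for (ts in training_subsets) {
    idx <- training_subset_idx(train$cohort, ts)
    if (length(idx) == 0) {
      warning("empty training subset '", ts, "'; skipped")
      next
    }
    for (fs in names(feature_sets)) {
      mat <- train$methyl
      if (!is.null(feature_sets[[fs]])) {
        mat <- suppressMessages(preselect_features(mat, feature_sets[[fs]]))
      }
      model <- train_elastic_net(mat[idx, , drop = FALSE],
                                 log_units(train$cohort$units[idx]),
                                 alpha = alpha, nfolds = nfolds, seed = seed,
                                 feature_label = fs, subset_label = ts)
      key <- paste(ts, fs, sep = ".")
      models[[key]] <- model
      score <- suppressMessages(project(model, test$methyl))
      for (es in names(eval_subsets)) {
        ix <- eval_subsets[[es]]
        if (length(ix) < 4) next
        rep <- tryCatch(
          evaluate(score[ix], test$cohort$units[ix],
                   test$cohort$age[ix], test$cohort$sex[ix],
                   subset_label = es),
          error = function(e) {
            warning("evaluation skipped for cell ", key, "/", es, ": ",
                    conditionMessage(e))
            NULL
          })
        if (is.null(rep)) next
        rep$training_subset <- ts
        rep$feature_set <- fs
        rep$n_features <- model$meta$n_selected
        rows[[length(rows) + 1]] <- rep
      }
    }
  }
  list(models = models, report = do.call(rbind, rows))
}

#' Sex-specific EpiScore designs
#'
#' Trains three models on matched sample sizes (all of size
#' `min(n_female, n_male)`): a female-only model, a male-only model, and a
#' sex-agnostic model with a floor(m/2) + ceiling(m/2) female/male mix. Each
#' is evaluated per test-set sex under three testing modes: sex-specific
#' (same-sex model), opposite-sex, and sex-agnostic.
#'
#' @param train,test `synthetic_cohort` objects.
#' @param feature_set optional CpG id vector to pre-select before training.
#' @param alpha,nfolds passed to [train_elastic_net()].
#' @param seed integer seed (subsampling and folds).
#' @return list with `models` (female, male, agnostic) and `report`
#'   (data.frame with `mode`, `model_label`, `test_sex` and metrics).
#' @export
sex_specific_designs <- function(train, test, feature_set = NULL,
                                 alpha = 0.5, nfolds = 10, seed = 1L) {
  sex <- train$cohort$sex
  idx_f <- which(sex == "F")
  idx_m <- which(sex == "M")
  if (length(idx_f) == 0 || length(idx_m) == 0) {
    stop("both sexes must be present in the training cohort")
  }
  m <- min(length(idx_f), length(idx_m))
  set.seed(substream_seed(seed, "sexdesign"))
  take_f <- if (length(idx_f) == m) idx_f else sample(idx_f, m)
  take_m <- if (length(idx_m) == m) idx_m else sample(idx_m, m)
  take_mix <- c(sample(idx_f, floor(m / 2)), sample(idx_m, ceiling(m / 2)))

  mat <- train$methyl
  if (!is.null(feature_set)) {
    mat <- suppressMessages(preselect_features(mat, feature_set))
  }
  fit1 <- function(idx, label) {
    train_elastic_net(mat[idx, , drop = FALSE],
                      log_units(train$cohort$units[idx]),
                      alpha = alpha, nfolds = nfolds, seed = seed,
                      subset_label = label)
  }
  models <- list(female = fit1(take_f, "female"),
                 male = fit1(take_m, "male"),
                 agnostic = fit1(take_mix, "agnostic"))

  test_sexes <- list(F = which(test$cohort$sex == "F"),
                     M = which(test$cohort$sex == "M"))
  grid <- rbind(
    data.frame(mode = "sex_specific", model_label = c("female", "male"),
               test_sex = c("F", "M"), stringsAsFactors = FALSE),
    data.frame(mode = "opposite_sex", model_label = c("female", "male"),
               test_sex = c("M", "F"), stringsAsFactors = FALSE),
    data.frame(mode = "sex_agnostic", model_label = "agnostic",
               test_sex = c("F", "M"), stringsAsFactors = FALSE)
  )
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ix <- test_sexes[[grid$test_sex[i]]]
    score <- suppressMessages(project(models[[grid$model_label[i]]],
                                      test$methyl[ix, , drop = FALSE]))
    rep <- tryCatch(
      evaluate(score, test$cohort$units[ix], test$cohort$age[ix],
               test$cohort$sex[ix], subset_label = grid$test_sex[i]),
      error = function(e) {
        warning("evaluation skipped for ", grid$mode[i], "/",
                grid$test_sex[i], ": ", conditionMessage(e))
        NULL
      })
    if (is.null(rep)) return(NULL)
    cbind(grid[i, , drop = FALSE], rep, row.names = NULL)
  })
  list(models = models, report = do.call(rbind, rows))
}
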