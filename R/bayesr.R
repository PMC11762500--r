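#' Configuration for the mixture-prior Gibbs sampler
#'
#' The effect-size prior on each standardized CpG is a point mass at zero
#' plus `length(mixture_variances)` Gaussian components whose variances are
#' fractions of phenotypic variance (the phenotype is scaled to unit
#' variance before sampling, making "explaining 0.01%, 0.1% and 1% of the
#' variance" literal for the default tiers). Mixture proportions carry a
#' symmetric Dirichlet prior with concentration 0.5: when a slab variance is
#' small enough that spike and slab are nearly indistinguishable per CpG,
#' a flat Dirichlet(1) leaves the mixture proportions in a marginally
#' stable random walk that mixes very slowly at moderate p, inflating the
#' null variance estimate; the mildly sparsity-favoring concentration adds
#' the drift toward the spike that the likelihood cannot supply. The
#' residual variance carries a weakly-informative scaled-inverse-chi-squared
#' prior (`nu0 = 2`, `s02 = var(y)/2`).
#'
#' Chain accounting: `draws_retained` post-burn-in sweeps are thinned by
#' `thin` (so `draws_retained / thin` draws are stored) and the last
#' `used_iterations` stored draws feed the posterior summaries. The
#' defaults (burn-in 5000, 10,000 retained, thin 5, 1000 used) reproduce
#' the conventional chain settings for this model class; all four knobs are
#' independent because retained/thin and the used count are not forced to
#' agree.
#'
#' @param mixture_variances strictly increasing positive slab variances as
#'   fractions of phenotypic variance.
#' @param burn_in discarded initial sweeps.
#' @param draws_retained post-burn-in sweeps.
#' @param thin thinning interval (>= 1).
#' @param used_iterations stored draws used for summaries (the most recent
#'   ones); `NULL` means all stored draws.
#' @param pip_threshold posterior inclusion probability cutoff for calling
#'   significant CpGs (strict inequality).
#' @param seed integer seed.
#' @param dirichlet_alpha symmetric Dirichlet concentration for mixture
#'   proportions.
#' @param nu0,s02 residual-variance prior degrees of freedom and scale;
#'   `s02 = NULL` means half the variance of the (scaled) phenotype.
#' @param fix_sigma2 optional fixed residual variance (disables its update);
#'   used for closed-form oracle comparisons.
#' @param fix_pi optional fixed mixture proportion vector of length
#'   `length(mixture_variances) + 1` (spike first); disables its update.
#' @return a `bayesr_config` object.
#' @export
bayesr_config <- function(mixture_variances = c(1e-4, 1e-3, 1e-2),
                          burn_in = 5000L, draws_retained = 10000L,
                          thin = 5L, used_iterations = 1000L,
                          pip_threshold = 0.95, seed = 1L,
                          dirichlet_alpha = 0.5, nu0 = 2, s02 = NULL,
                          fix_sigma2 = NULL, fix_pi = NULL) {
  if (any(mixture_variances <= 0) || is.unsorted(mixture_variances, strictly = TRUE)) {
    stop("mixture_variances must be strictly increasing and positive")
  }
  if (thin < 1) stop("thin must be >= 1")
  if (pip_threshold <= 0 || pip_threshold >= 1) {
    stop("pip_threshold must lie in (0, 1)")
  }
  n_store <- draws_retained %/% thin
  if (n_store < 2) stop("draws_retained / thin must be at least 2")
  if (!is.null(used_iterations) && used_iterations > n_store) {
    stop("used_iterations (", used_iterations, ") exceeds stored draws (",
         n_store, " = draws_retained / thin)")
  }
  if (!is.null(fix_pi) && length(fix_pi) != length(mixture_variances) + 1) {
    stop("fix_pi must have length(mixture_variances) + 1 entries (spike first)")
  }
  structure(list(
    mixture_variances = mixture_variances, burn_in = as.integer(burn_in),
    draws_retained = as.integer(draws_retained), thin = as.integer(thin),
    n_store = as.integer(n_store),
    used_iterations = if (is.null(used_iterations)) as.integer(n_store)
                      else as.integer(used_iterations),
    pip_threshold = pip_threshold, seed = as.integer(seed),
    dirichlet_alpha = dirichlet_alpha, nu0 = nu0, s02 = s02,
    fix_sigma2 = fix_sigma2, fix_pi = fix_pi
  ), class = "bayesr_config")
}

#' Pre-correct methylation and phenotype for the EWAS model
#'
#' The phenotype fed to the sampler is the residual of log(units + 1) on
#' age, sex and smoking score; M-values are residualized on age, sex,
#' smoking score and batch, then scaled to mean zero and unit variance.
#' Columns with no residual variance (e.g. a CpG equal to a covariate) are
#' dropped with a warning.
#'
#' @param methyl samples-by-CpGs matrix of M-values.
#' @param units nonnegative units-per-week vector.
#' @param age,sex,smoking covariate vectors.
#' @param batch optional batch factor (applied to M-values only).
#' @return list with `X_std` (standardized residual M-values), `y_resid`
#'   (residual phenotype) and `dropped` (ids of removed CpGs).
#' @export
precorrect <- function(methyl, units, age, sex, smoking, batch = NULL) {
  covs_y <- data.frame(age = age, sex = factor(sex), smoking = smoking)
  y_resid <- residualize(log_units(units), covs_y)

  covs_x <- covs_y
  if (!is.null(batch) && length(unique(batch)) > 1) {
    covs_x$batch <- factor(batch)
  }
  design <- model.matrix(~ ., data = covs_x)
  qx <- qr(design)
  if (qx$rank < ncol(design)) {
    bad <- colnames(design)[qx$pivot[(qx$rank + 1):ncol(design)]]
    stop("covariate design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  x_res <- qr.resid(qx, methyl)
  csd <- col_sds(x_res)
  dead <- csd < 1e-10
  dropped <- colnames(methyl)[dead]
  if (any(dead)) {
    warning("dropping ", sum(dead),
            " CpG(s) with zero variance after residualization")
    x_res <- x_res[, !dead, drop = FALSE]
    csd <- csd[!dead]
  }
  x_std <- sweep(sweep(x_res, 2, colMeans(x_res)), 2, csd, "/")
  list(X_std = x_std, y_resid = y_resid, dropped = dropped)
}

#' Draw from the mixture-prior posterior by Gibbs sampling
#'
#' Fits `y = X beta + e` with the spike-and-slabs effect prior of
#' [bayesr_config()] by single-site conjugate Gibbs updates (O(n) per CpG
#' per sweep through residual-vector maintenance). The phenotype is
#' centered and scaled to unit variance internally, so effect draws are on
#' the standardized-phenotype, standardized-CpG scale and the slab
#' variances are literal fractions of phenotypic variance.
#'
#' Columns are processed in a seeded random update order keyed to the CpG
#' identifiers (columns are sorted by name before sampling), so permuting
#' the input columns permutes the results exactly.
#'
#' @param X standardized samples-by-CpGs matrix (from [precorrect()]).
#' @param y residual phenotype vector.
#' @param config a [bayesr_config()].
#' @return a `bayesr_chain`: thinned stored draws of `beta` (draws x CpGs),
#'   component memberships `comp`, `sigma2` and mixture proportions `pi`,
#'   plus the CpG ids and config.
#' @export
gibbs_sample <- function(X, y, config = bayesr_config()) {
  stopifnot(inherits(config, "bayesr_config"))
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("non-finite values in X or y")
  }
  if (nrow(X) != length(y)) stop("X and y dimensions differ")
  y_s <- y - mean(y)
  sdy <- sd(y_s)
  if (sdy == 0) stop("constant phenotype")
  y_s <- y_s / sdy

  ids <- colnames(X)
  if (!is.null(ids)) {
    ord <- order(ids)
    X <- X[, ord, drop = FALSE]
    ids <- ids[ord]
  } else {
    ids <- sprintf("V%d", seq_len(ncol(X)))
  }

  s02 <- if (is.null(config$s02)) var(y_s) / 2 else config$s02
  set.seed(substream_seed(config$seed, "sampler"))
  out <- bayesr_gibbs_cpp(
    X, y_s, config$mixture_variances,
    config$burn_in, config$n_store, config$thin,
    config$dirichlet_alpha, config$nu0, s02,
    if (is.null(config$fix_sigma2)) -1 else config$fix_sigma2,
    if (is.null(config$fix_pi)) numeric(0) else config$fix_pi
  )
  colnames(out$beta) <- ids
  colnames(out$comp) <- ids
  structure(list(beta = out$beta, comp = out$comp, sigma2 = out$sigma2,
                 pi = out$pi, cpg_ids = ids, var_y = 1,
                 config = config),
            class = "bayesr_chain")
}

#' Summarize a sampler chain into posterior quantities
#'
#' Uses the last `used_iterations` stored draws. Per CpG: posterior mean
#' effect, posterior SD (`se`), posterior inclusion probability (fraction of
#' used draws with a nonzero-component membership) and mixture occupancy
#' fractions. The per-iteration variance explained is the sum of squared
#' standardized effect draws (divided by `var_y` if the phenotype was not
#' pre-scaled); its posterior mean and equal-tailed 95% credible interval
#' are reported.
#'
#' @param chain a `bayesr_chain` (or a hand-built list with at least `beta`
#'   and `comp` draw matrices).
#' @param used_iterations draws to use; defaults to the chain config's
#'   value, else all.
#' @return a `bayesr_posterior` with a per-CpG `summary` data.frame,
#'   `ve_draws`, `ve_mean`, `ve_cri` and diagnostics-ready hyperparameter
#'   draws.
#' @export
summarize_posterior <- function(chain, used_iterations = NULL) {
  beta <- chain$beta
  comp <- chain$comp
  if (is.null(beta) || is.null(comp) || nrow(beta) < 2) {
    stop("chain must contain at least 2 stored draws of beta and comp")
  }
  n_store <- nrow(beta)
  if (is.null(used_iterations)) {
    used_iterations <- if (!is.null(chain$config)) {
      chain$config$used_iterations
    } else {
      n_store
    }
  }
  if (used_iterations < 2) stop("need at least 2 used iterations")
  if (used_iterations > n_store) {
    stop("used_iterations exceeds stored draws (", n_store, ")")
  }
  take <- seq.int(n_store - used_iterations + 1, n_store)
  beta <- beta[take, , drop = FALSE]
  comp <- comp[take, , drop = FALSE]
  var_y <- if (is.null(chain$var_y)) 1 else chain$var_y
  n_comp <- if (!is.null(chain$config)) {
    length(chain$config$mixture_variances)
  } else {
    max(comp, 1)
  }

  ids <- colnames(beta)
  if (is.null(ids)) ids <- sprintf("V%d", seq_len(ncol(beta)))
  mean_beta <- colMeans(beta)
  se <- col_sds(beta)
  pip <- colMeans(comp > 0)
  occ <- vapply(0:n_comp, function(k) colMeans(comp == k),
                numeric(ncol(comp)))
  occ <- matrix(occ, ncol = n_comp + 1,
                dimnames = list(ids, paste0("occ_", 0:n_comp)))

  ve_draws <- rowSums(beta^2) / var_y
  ve_cri <- unname(quantile(ve_draws, c(0.025, 0.975)))

  structure(list(
    summary = data.frame(cpg = ids, mean_beta = mean_beta, se = se,
                         pip = pip, occ, row.names = NULL,
                         stringsAsFactors = FALSE),
    ve_draws = ve_draws, ve_mean = mean(ve_draws), ve_cri = ve_cri,
    sigma2 = if (!is.null(chain$sigma2)) chain$sigma2[take] else NULL,
    pi = if (!is.null(chain$pi)) chain$pi[take, , drop = FALSE] else NULL,
    used_iterations = used_iterations,
    pip_threshold = if (!is.null(chain$config)) chain$config$pip_threshold else 0.95
  ), class = "bayesr_posterior")
}

#' @export
print.bayesr_posterior <- function(x, ...) {
  cat("Mixture-model EWAS posterior:", nrow(x$summary), "CpGs,",
      x$used_iterations, "used iterations\n")
  cat(sprintf("  variance explained: %.1f%% (95%% CrI %.1f%%, %.1f%%)\n",
              100 * x$ve_mean, 100 * x$ve_cri[1], 100 * x$ve_cri[2]))
  n_sig <- sum(x$summary$pip > x$pip_threshold)
  cat("  lead CpGs (PIP >", x$pip_threshold, "):", n_sig, "\n")
  invisible(x)
}

#' Run the full EWAS: pre-correction, sampling, summary
#'
#' Convenience wrapper chaining [precorrect()], [gibbs_sample()] and
#' [summarize_posterior()].
#'
#' @inheritParams precorrect
#' @param config a [bayesr_config()].
#' @return a `bayesr_posterior`.
#' @export
bayesr_ewas <- function(methyl, units, age, sex, smoking, batch = NULL,
                        config = bayesr_config()) {
  pre <- precorrect(methyl, units, age, sex, smoking, batch)
  chain <- gibbs_sample(pre$X_std, pre$y_resid, config)
  summarize_posterior(chain)
}

#' Call epigenome-wide significant CpGs by posterior inclusion probability
#'
#' Returns CpGs whose PIP strictly exceeds the threshold, sorted by
#' decreasing PIP and then by identifier.
#'
#' @param posterior a `bayesr_posterior`.
#' @param threshold PIP cutoff in (0, 1); defaults to the config's value.
#' @return data.frame of lead CpGs (`cpg`, `mean_beta`, `se`, `pip`).
#' @export
call_significant <- function(posterior, threshold = NULL) {
  stopifnot(inherits(posterior, "bayesr_posterior"))
  if (is.null(threshold)) threshold <- posterior$pip_threshold
  if (threshold <= 0 || threshold >= 1) {
    ## threshold 0 admissible for "any nonzero occupancy" queries
    if (threshold != 0) stop("threshold must lie in [0, 1)")
  }
  s <- posterior$summary
  hits <- s[s$pip > threshold, c("cpg", "mean_beta", "se", "pip")]
  hits[order(-hits$pip, hits$cpg), , drop = FALSE]
}

#' Geweke convergence diagnostic
#'
#' Compares the means of an early and a late chain segment, with segment
#' variances of the mean estimated by a batch-means spectral estimator
#' (batch size ~ sqrt of segment length), giving an asymptotically standard
#' normal z under stationarity. A lag-k autocorrelation table of the full
#' chain is attached.
#'
#' @param chain numeric vector of scalar draws.
#' @param frac_first,frac_last fractions of the chain forming the early and
#'   late segments (non-overlapping; each segment must hold at least 10
#'   draws).
#' @param max_lag largest lag in the autocorrelation table.
#' @return a `geweke_test`: `z` and an `acf` data.frame.
#' @export
geweke <- function(chain, frac_first = 0.1, frac_last = 0.5, max_lag = 20) {
  n <- length(chain)
  n1 <- floor(frac_first * n)
  n2 <- floor(frac_last * n)
  if (n1 < 10 || n2 < 10) stop("each segment must contain at least 10 draws")
  if (n1 + n2 > n) stop("segments overlap; reduce frac_first/frac_last")
  a <- chain[seq_len(n1)]
  b <- chain[seq.int(n - n2 + 1, n)]

  spectral_var_of_mean <- function(z) {
    m <- length(z)
    bsize <- max(1L, floor(sqrt(m)))
    nb <- m %/% bsize
    bm <- colMeans(matrix(z[seq_len(nb * bsize)], nrow = bsize))
    if (nb < 2) return(var(z) / m)
    bsize * var(bm) / m
  }
  v1 <- spectral_var_of_mean(a)
  v2 <- spectral_var_of_mean(b)
  denom <- sqrt(v1 + v2)
  if (!is.finite(denom) || denom == 0) {
    warning("constant chain segments; Geweke z defined as 0")
    z <- 0
  } else {
    z <- (mean(a) - mean(b)) / denom
  }
  ac <- acf(chain, lag.max = max_lag, plot = FALSE)
  structure(list(z = z,
                 acf = data.frame(lag = drop(ac$lag), acf = drop(ac$acf))),
            class = "geweke_test")
}

#' @export
print.geweke_test <- function(x, ...) {
  cat("Geweke z =", signif(x$z, 4), "\n")
  invisible(x)
}
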