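#' Effect architecture for planted CpG effects
#'
#' Describes a sparse three-tier effect architecture over CpGs: counts of
#' small, medium and large causal sites and the fraction of phenotypic
#' variance each single site of a tier explains. The default tiers
#' (1e-4, 1e-3, 1e-2) mirror the three effect-size classes the mixture-prior
#' EWAS model assumes (0.01%, 0.1% and 1% of phenotypic variance), so the
#' generator plants effects on the same scale the model's priors expect.
#'
#' @param n_small,n_medium,n_large nonnegative counts of causal CpGs per tier.
#' @param frac_small,frac_medium,frac_large per-CpG variance fractions in
#'   \[0, 1\].
#' @param total_methylome_variance target fraction of phenotypic (log-unit)
#'   variance explained by all CpGs jointly. `NULL` (default) means the sum
#'   of the planted per-CpG fractions; if given, effects are rescaled
#'   proportionally to hit the target.
#' @return an `effect_architecture` object.
#' @export
effect_architecture <- function(n_small = 500L, n_medium = 150L, n_large = 30L,
                                frac_small = 1e-4, frac_medium = 1e-3,
                                frac_large = 1e-2,
                                total_methylome_variance = NULL) {
  counts <- c(small = n_small, medium = n_medium, large = n_large)
  fracs <- c(small = frac_small, medium = frac_medium, large = frac_large)
  if (any(counts < 0)) stop("architecture counts must be nonnegative")
  if (any(fracs < 0 | fracs > 1)) stop("variance fractions must lie in [0, 1]")
  planted <- sum(counts * fracs)
  total <- if (is.null(total_methylome_variance)) planted else total_methylome_variance
  if (total < 0 || total > 1) {
    stop("total_methylome_variance must lie in [0, 1]")
  }
  structure(
    list(counts = counts, fracs = fracs, total = total, planted_sum = planted),
    class = "effect_architecture"
  )
}

#' Reporting model linking habitual and last-week alcohol intake
#'
#' Self-reported units refer to the week before the blood draw; the methylome
#' is assumed to track habitual consumption. Each participant is assigned a
#' reporting state (normal week / more than normal / less than normal /
#' unknown). Deviant reporters' last-week units are a multiplicative
#' perturbation of their habitual units: "more" reporters scale
#' `units + 1` up by `exp(|N(0, deviation_sd)|)`, "less" reporters scale it
#' down by the reciprocal, with the result floored at 0 units. Working on
#' `units + 1` makes the deviation exactly additive on the log(units + 1)
#' modelling scale, so both deviation directions attenuate predictor
#' performance symmetrically. At the default `deviation_sd = 1` a deviant
#' reporter's last-week intake is a median factor of ~2 away from habitual,
#' which makes predictor performance visibly best among normal-week
#' reporters — the designed monotonicity that stratified evaluations rely
#' on.
#'
#' Default state probabilities follow the observed frequencies in a large
#' population cohort (62.8% normal, 22.5% more, 9.7% less, remainder
#' unknown).
#'
#' @param p_normal,p_more,p_less probabilities of the three known reporting
#'   states; the remainder to 1 is the "unknown" state.
#' @param deviation_sd spread of the multiplicative deviation for
#'   more/less reporters; must be nonnegative.
#' @param habitual_drives_methylome if `TRUE` (default) planted CpG effects
#'   act on habitual intake, and last-week (reported) intake is the noisy
#'   derived quantity; if `FALSE` the methylome tracks last-week intake
#'   directly (habitual is then set equal to reported).
#' @return a `reporting_model` object.
#' @export
reporting_model <- function(p_normal = 0.628, p_more = 0.225, p_less = 0.097,
                            deviation_sd = 1,
                            habitual_drives_methylome = TRUE) {
  probs <- c(normal = p_normal, more = p_more, less = p_less)
  if (any(probs < 0) || sum(probs) > 1 + 1e-12) {
    stop("reporting state probabilities must be nonnegative and sum to at most 1")
  }
  if (deviation_sd < 0) stop("deviation_sd must be nonnegative")
  structure(
    list(probs = probs, p_unknown = max(0, 1 - sum(probs)),
         deviation_sd = deviation_sd,
         habitual_drives_methylome = isTRUE(habitual_drives_methylome)),
    class = "reporting_model"
  )
}

#' Simulate a samples-by-CpGs methylation beta-value matrix
#'
#' Each CpG is assigned a methylation state class (low / intermediate /
#' high) and per-sample beta values are drawn from a Beta distribution
#' around the CpG-specific mean. Additive structure — per-batch mean shifts
#' and latent cell-composition-like factors — is applied on the M-value
#' (logit) scale so values remain strictly inside (0, 1). The generator is
#' deterministic for a fixed seed (generator algorithm version 1).
#'
#' The planted batch assignment and per-batch, per-CpG shifts are stored as
#' attributes (`batch`, `batch_shifts`, `states`) so downstream tests can
#' verify their recoverability.
#'
#' Batch and latent-factor structure is expressed relative to each CpG's
#' own base variability on the logit scale: a batch shift has standard
#' deviation `batch_sd` times the CpG's base sd, and latent
#' cell-composition-like factors load on a sparse susceptible subset of
#' CpGs (`latent_frac` of them) with loadings of `latent_sd` times the
#' CpG's base sd. This keeps most CpG pairs near-uncorrelated, with a
#' moderately correlated susceptible subset, matching the correlation
#' structure of population blood methylation data.
#'
#' @param n_samples number of samples (rows), at least 2.
#' @param n_cpgs number of CpGs (columns), at least 1.
#' @param n_batches number of processing batches; batch sizes are balanced.
#' @param seed integer seed.
#' @param batch_sd per-batch M-value shift scale, as a fraction of each
#'   CpG's base logit-scale sd.
#' @param n_latent number of latent cell-composition-like factors.
#' @param latent_frac fraction of CpGs susceptible to the latent factors.
#' @param latent_sd latent factor loading scale for susceptible CpGs, as a
#'   fraction of the CpG's base logit-scale sd.
#' @return numeric matrix of beta values in (0, 1) with sample-id rownames
#'   and CpG-id colnames, plus generator attributes.
#' @export
simulate_methylome <- function(n_samples, n_cpgs, n_batches = 1L, seed = 1L,
                               batch_sd = 0.25, n_latent = 2L,
                               latent_frac = 0.15, latent_sd = 0.5) {
  if (n_samples < 2 || n_cpgs < 1 || n_batches < 1) {
    stop("n_samples must be >= 2, n_cpgs >= 1 and n_batches >= 1")
  }
  n <- as.integer(n_samples)
  p <- as.integer(n_cpgs)
  set.seed(substream_seed(seed, "methylome"))

  states <- sample(c("low", "intermediate", "high"), p, replace = TRUE,
                   prob = c(0.40, 0.25, 0.35))
  mu <- numeric(p)
  mu[states == "low"] <- runif(sum(states == "low"), 0.03, 0.15)
  mu[states == "intermediate"] <- runif(sum(states == "intermediate"), 0.35, 0.65)
  mu[states == "high"] <- runif(sum(states == "high"), 0.85, 0.97)
  precision <- runif(p, 40, 150)

  base <- matrix(
    rbeta(n * p, shape1 = rep(mu * precision, each = n),
          shape2 = rep((1 - mu) * precision, each = n)),
    nrow = n, ncol = p
  )
  base <- pmin(pmax(base, 1e-6), 1 - 1e-6)
  m <- logit(base)
  ## base logit-scale sd of a Beta(mu*phi, (1-mu)*phi) draw, delta-method
  base_sd <- sqrt(1 / (mu * (1 - mu) * (precision + 1)))

  batch <- factor(sample(rep_len(seq_len(n_batches), n)),
                  levels = seq_len(n_batches))
  shifts <- matrix(rnorm(n_batches * p, 0, batch_sd * rep(base_sd, each = n_batches)),
                   nrow = n_batches, ncol = p)
  if (n_batches > 1) m <- m + shifts[as.integer(batch), , drop = FALSE]

  if (n_latent > 0 && latent_frac > 0) {
    susceptible <- sample.int(p, round(latent_frac * p))
    u <- matrix(rnorm(n * n_latent), n, n_latent)
    load <- matrix(0, n_latent, p)
    load[, susceptible] <- rnorm(n_latent * length(susceptible), 0,
                                 latent_sd * rep(base_sd[susceptible],
                                                 each = n_latent))
    m <- m + u %*% load
  }

  beta <- inv_logit(m)
  beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  dimnames(beta) <- list(sprintf("S%05d", seq_len(n)), sprintf("cg%07d", seq_len(p)))
  rownames(shifts) <- levels(batch)
  colnames(shifts) <- colnames(beta)
  attr(beta, "batch") <- batch
  attr(beta, "batch_shifts") <- shifts
  attr(beta, "states") <- states
  attr(beta, "generator_version") <- "1"
  beta
}

#' Simulate the alcohol phenotype and cohort table on top of a methylome
#'
#' Habitual log-intake is built as a linear combination of standardized
#' covariates (age, sex, smoking score), planted CpG effects acting on
#' standardized M-values, and Gaussian noise scaled so the methylome explains
#' the architecture's target fraction of phenotypic variance. Habitual units
#' are `exp(h) - 1` floored at 0, placing log(units + 1) on the planted
#' linear scale; reported ("last week") units are then derived from habitual
#' units through the reporting model. The full ground truth (causal set,
#' effect vector, true methylome score, habitual intake, realized variance
#' explained) is recorded.
#'
#' @param methyl beta-value matrix from [simulate_methylome()].
#' @param arch an [effect_architecture()].
#' @param report a [reporting_model()].
#' @param covariate_effects named numeric vector with elements `age`, `sexM`
#'   and `smoking`: effects of the standardized covariates on the
#'   standardized habitual log-intake scale.
#' @param intake_mean_log,intake_sd_log location and scale of habitual
#'   log(units + 1); defaults give a right-skewed units distribution with
#'   mean near 11 units/week.
#' @param seed integer seed.
#' @return a `synthetic_cohort`: list with elements `methyl`, `cohort`
#'   (data.frame of sample_id, age, sex, batch, smoking, units,
#'   normal_week_flag) and `truth`.
#' @export
simulate_phenotype <- function(methyl, arch = effect_architecture(),
                               report = reporting_model(),
                               covariate_effects = c(age = -0.05, sexM = 0.30,
                                                     smoking = 0.15),
                               intake_mean_log = 2.1, intake_sd_log = 0.9,
                               seed = 1L) {
  stopifnot(inherits(arch, "effect_architecture"),
            inherits(report, "reporting_model"))
  n <- nrow(methyl)
  p <- ncol(methyl)
  k_total <- sum(arch$counts)
  if (k_total > p) stop("architecture plants more causal CpGs than the methylome has")

  cov_var <- sum(covariate_effects^2)
  if (arch$total + cov_var >= 1) {
    stop("infeasible variance target: planted methylome variance (",
         signif(arch$total, 3), ") plus covariate variance (",
         signif(cov_var, 3), ") must be < 1")
  }

  set.seed(substream_seed(seed, "effects"))
  age <- pmin(pmax(rnorm(n, 47.5, 14.9), 18), 99)
  sex <- factor(sample(c("F", "M"), n, replace = TRUE, prob = c(0.584, 0.416)),
                levels = c("F", "M"))
  smoking <- rnorm(n)
  batch <- attr(methyl, "batch")
  if (is.null(batch)) batch <- factor(rep(1L, n))

  z_age <- as.numeric(scale(age))
  z_sex <- as.numeric(scale(as.numeric(sex == "M")))
  z_smk <- as.numeric(scale(smoking))
  cov_part <- covariate_effects[["age"]] * z_age +
    covariate_effects[["sexM"]] * z_sex +
    covariate_effects[["smoking"]] * z_smk

  ## planted effects on standardized M-values
  if (k_total > 0) {
    causal_idx <- sample.int(p, k_total)
    tier <- rep(names(arch$counts), times = arch$counts)
    per_cpg_frac <- arch$fracs[tier]
    rescale <- if (arch$planted_sum > 0) sqrt(arch$total / arch$planted_sum) else 0
    eff <- sqrt(per_cpg_frac) * rescale * sample(c(-1, 1), k_total, replace = TRUE)
    z_m <- scale(m_values(methyl[, causal_idx, drop = FALSE]))
    true_score <- drop(z_m %*% eff)
    causal_ids <- colnames(methyl)[causal_idx]
    names(eff) <- causal_ids
    names(tier) <- causal_ids
  } else {
    true_score <- numeric(n)
    eff <- setNames(numeric(0), character(0))
    tier <- setNames(character(0), character(0))
    causal_ids <- character(0)
  }

  noise_var <- 1 - arch$total - cov_var
  h_std <- cov_part + true_score + rnorm(n, 0, sqrt(noise_var))
  h <- intake_mean_log + intake_sd_log * h_std
  habitual_units <- pmax(expm1(h), 0)
  habitual_log <- log1p(habitual_units)

  set.seed(substream_seed(seed, "reporting"))
  flag <- sample(c("normal", "more", "less", "unknown"), n, replace = TRUE,
                 prob = c(report$probs, report$p_unknown))
  flag <- factor(flag, levels = c("normal", "more", "less", "unknown"))
  mult <- rep(1, n)
  i_more <- which(flag == "more")
  i_less <- which(flag == "less")
  mult[i_more] <- exp(abs(rnorm(length(i_more), 0, report$deviation_sd)))
  mult[i_less] <- exp(-abs(rnorm(length(i_less), 0, report$deviation_sd)))

  if (report$habitual_drives_methylome) {
    units <- pmax((habitual_units + 1) * mult - 1, 0)
  } else {
    ## methylome tracks last-week intake directly
    units <- habitual_units
    habitual_units <- units
    habitual_log <- log1p(units)
  }

  realized_ve <- if (k_total > 0 && var(true_score) > 0) {
    fit <- lm(habitual_log ~ true_score)
    summary(fit)$r.squared
  } else 0

  cohort <- data.frame(
    sample_id = rownames(methyl),
    age = age, sex = sex, batch = batch, smoking = smoking,
    units = units, normal_week_flag = flag,
    stringsAsFactors = FALSE
  )
  rownames(cohort) <- cohort$sample_id

  truth <- list(
    effects = eff, causal = causal_ids, tier = tier,
    true_score = setNames(true_score, rownames(methyl)),
    habitual_units = setNames(habitual_units, rownames(methyl)),
    habitual_log = setNames(habitual_log, rownames(methyl)),
    target_ve = arch$total, realized_ve = realized_ve,
    covariate_effects = covariate_effects,
    intake_mean_log = intake_mean_log, intake_sd_log = intake_sd_log
  )
  structure(list(methyl = methyl, cohort = cohort, truth = truth),
            class = "synthetic_cohort")
}

## row-subset of a synthetic cohort, keeping truth aligned
subset_cohort <- function(sc, idx) {
  keep_attrs <- attributes(sc$methyl)[c("batch", "batch_shifts", "states",
                                        "generator_version")]
  methyl <- sc$methyl[idx, , drop = FALSE]
  if (!is.null(keep_attrs$batch)) keep_attrs$batch <- keep_attrs$batch[idx]
  for (a in names(keep_attrs)) attr(methyl, a) <- keep_attrs[[a]]
  truth <- sc$truth
  for (f in c("true_score", "habitual_units", "habitual_log")) {
    truth[[f]] <- truth[[f]][idx]
  }
  out <- list(methyl = methyl, cohort = sc$cohort[idx, , drop = FALSE],
              truth = truth)
  if (!is.null(sc$outcomes)) out$outcomes <- sc$outcomes[idx, , drop = FALSE]
  structure(out, class = "synthetic_cohort")
}

#' Split a synthetic cohort into training and test sets
#'
#' Produces a disjoint, exhaustive partition of the samples, deterministic
#' per seed. Training size is `round(fraction * n)`. With `stratify_by`, the
#' split is performed within each level of the named cohort column so
#' per-stratum proportions are preserved to within one sample.
#'
#' @param sc a `synthetic_cohort`.
#' @param fractions numeric length-2 vector (train, test) summing to 1.
#' @param stratify_by optional name of a cohort column (e.g.
#'   `"normal_week_flag"`) to stratify on.
#' @param seed integer seed.
#' @return list with `train` and `test` synthetic cohorts.
#' @export
split_cohort <- function(sc, fractions = c(train = 0.52, test = 0.48),
                         stratify_by = NULL, seed = 1L) {
  stopifnot(inherits(sc, "synthetic_cohort"))
  if (length(fractions) != 2 || abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be two numbers summing to 1")
  }
  n <- nrow(sc$cohort)
  set.seed(substream_seed(seed, "split"))
  if (is.null(stratify_by)) {
    n_train <- round(fractions[[1]] * n)
    if (n_train < 1 || n_train >= n) stop("split leaves an empty partition")
    ord <- sample.int(n)
    train_idx <- sort(ord[seq_len(n_train)])
  } else {
    if (!stratify_by %in% names(sc$cohort)) {
      stop("stratify_by column not found: ", stratify_by)
    }
    strata <- split(seq_len(n), sc$cohort[[stratify_by]], drop = TRUE)
    train_idx <- sort(unlist(lapply(strata, function(ix) {
      k <- round(fractions[[1]] * length(ix))
      if (length(ix) == 1) return(if (runif(1) < fractions[[1]]) ix else integer(0))
      sample(ix, k)
    }), use.names = FALSE))
    if (length(train_idx) < 1 || length(train_idx) >= n) {
      stop("split leaves an empty partition")
    }
  }
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = subset_cohort(sc, train_idx), test = subset_cohort(sc, test_idx))
}

#' Simulate downstream health outcomes for the association battery
#'
#' Adds continuous, binary, survival and brain-volume outcomes driven by the
#' standardized habitual log-intake, with age and sex entering each linear
#' predictor. Effects are on the conventional reporting scales: standardized
#' beta for continuous and brain-volume outcomes, log odds ratio per SD for
#' the binary outcome and log hazard ratio per SD for mortality under an
#' exponential baseline hazard with uniform censoring.
#'
#' @param sc a `synthetic_cohort`.
#' @param beta_continuous standardized effect on the continuous outcome.
#' @param log_or log odds ratio per SD of exposure (binary outcome).
#' @param log_hr log hazard ratio per SD of exposure (mortality).
#' @param beta_brain standardized effect on brain volume.
#' @param censor_time administrative censoring horizon (years).
#' @param seed integer seed.
#' @return the cohort with an `outcomes` data.frame added (columns
#'   `outcome_cont`, `disease`, `time`, `event`, `brain_vol`, `icv`).
#' @export
simulate_outcomes <- function(sc, beta_continuous = 0.3, log_or = 0.2,
                              log_hr = 0.15, beta_brain = -0.2,
                              censor_time = 12, seed = 1L) {
  stopifnot(inherits(sc, "synthetic_cohort"))
  n <- nrow(sc$cohort)
  set.seed(substream_seed(seed, "outcomes"))
  expo <- as.numeric(scale(sc$truth$habitual_log))
  z_age <- as.numeric(scale(sc$cohort$age))
  z_sex <- as.numeric(sc$cohort$sex == "M")

  outcome_cont <- beta_continuous * expo + 0.1 * z_age + 0.1 * z_sex +
    rnorm(n, 0, sqrt(max(1 - beta_continuous^2 - 0.02, 0.1)))
  lin_bin <- -1 + log_or * expo + 0.05 * z_age
  disease <- rbinom(n, 1, inv_logit(lin_bin))
  rate <- 0.05 * exp(log_hr * expo + 0.3 * z_age)
  t_event <- rexp(n, rate)
  cens <- runif(n, 0, censor_time)
  time <- pmin(t_event, cens)
  event <- as.integer(t_event <= cens)
  icv <- rnorm(n, 1500, 120)
  brain_vol <- beta_brain * expo - 0.3 * z_age + 0.3 * as.numeric(scale(icv)) +
    rnorm(n, 0, sqrt(max(1 - beta_brain^2 - 0.2, 0.1)))

  sc$outcomes <- data.frame(
    sample_id = sc$cohort$sample_id,
    outcome_cont = outcome_cont, disease = disease,
    time = time, event = event,
    brain_vol = brain_vol, icv = icv,
    stringsAsFactors = FALSE
  )
  rownames(sc$outcomes) <- sc$outcomes$sample_id
  sc
}

#' @importFrom stats rbinom rexp
#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic DNAm cohort:", nrow(x$cohort), "samples x",
      ncol(x$methyl), "CpGs\n")
  cat("  causal CpGs:", length(x$truth$causal),
      "| target methylome variance:", signif(x$truth$target_ve, 3),
      "| realized:", signif(x$truth$realized_ve, 3), "\n")
  cat("  reporting flags:",
      paste(names(table(x$cohort$normal_week_flag)),
            table(x$cohort$normal_week_flag), sep = "=", collapse = ", "), "\n")
  invisible(x)
}
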