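## shared scaffolding for the association battery: every fit reports the
## effect per SD of the exposure with a Wald CI on the conventional scale
assoc_row <- function(outcome_label, exposure_label, model, effect,
                      ci_low, ci_high, p, n) {
  data.frame(outcome = outcome_label, exposure = exposure_label,
             model = model, effect = effect, ci_low = ci_low,
             ci_high = ci_high, p = p, p_fdr = NA_real_, n = n,
             stringsAsFactors = FALSE)
}

std1 <- function(x) as.numeric(scale(x))

#' Linear association of a continuous outcome with an exposure
#'
#' Outcome and exposure are both scaled to unit variance, so the reported
#' effect is a standardized beta, with a Wald 95% CI. Models adjust for age
#' and sex.
#'
#' @param outcome continuous outcome vector.
#' @param exposure exposure vector (self-reported log units or an EpiScore);
#'   standardized internally.
#' @param age,sex covariates.
#' @param outcome_label,exposure_label labels recorded in the result.
#' @return one-row `AssociationResult` data.frame.
#' @export
fit_continuous <- function(outcome, exposure, age, sex,
                           outcome_label = "outcome",
                           exposure_label = "exposure") {
  keep <- complete.cases(outcome, exposure, age, sex)
  if (sum(keep) < 10) {
    warning("fewer than 10 complete cases; association skipped")
    return(NULL)
  }
  d <- data.frame(y = std1(outcome[keep]), x = std1(exposure[keep]),
                  age = age[keep], sex = factor(sex[keep]))
  fit <- lm(y ~ x + age + sex, data = d)
  est <- summary(fit)$coefficients["x", ]
  assoc_row(outcome_label, exposure_label, "linear",
            est["Estimate"],
            est["Estimate"] - 1.96 * est["Std. Error"],
            est["Estimate"] + 1.96 * est["Std. Error"],
            est["Pr(>|t|)"], nrow(d))
}

#' Logistic association of a binary outcome with an exposure
#'
#' Reports the odds ratio per SD of exposure with a Wald 95% CI, adjusting
#' for age and sex. Complete or quasi-complete separation is raised as an
#' error rather than returning a silent boundary estimate.
#'
#' @inheritParams fit_continuous
#' @param outcome binary 0/1 outcome vector.
#' @return one-row `AssociationResult` data.frame.
#' @export
fit_binary <- function(outcome, exposure, age, sex,
                       outcome_label = "outcome",
                       exposure_label = "exposure") {
  keep <- complete.cases(outcome, exposure, age, sex)
  if (sum(keep) < 10) {
    warning("fewer than 10 complete cases; association skipped")
    return(NULL)
  }
  y <- outcome[keep]
  if (length(unique(y)) < 2) {
    warning("outcome has a single class; association skipped")
    return(NULL)
  }
  d <- data.frame(y = y, x = std1(exposure[keep]), age = age[keep],
                  sex = factor(sex[keep]))
  fit <- withCallingHandlers(
    glm(y ~ x + age + sex, data = d, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        stop("logistic model did not converge (separation detected)", call. = FALSE)
      }
      invokeRestart("muffleWarning")
    }
  )
  est <- summary(fit)$coefficients["x", ]
  if (!fit$converged || abs(est["Estimate"]) > 10) {
    stop("logistic model did not converge (separation detected)")
  }
  assoc_row(outcome_label, exposure_label, "logistic",
            exp(est["Estimate"]),
            exp(est["Estimate"] - 1.96 * est["Std. Error"]),
            exp(est["Estimate"] + 1.96 * est["Std. Error"]),
            est["Pr(>|z|)"], nrow(d))
}

#' Cox proportional-hazards association with all-cause mortality
#'
#' Reports the hazard ratio per SD of exposure with a Wald 95% CI from a
#' Cox model of time to death or censoring, adjusting for age and sex.
#'
#' @inheritParams fit_continuous
#' @param time nonnegative follow-up times.
#' @param event binary event indicator (1 = death).
#' @return one-row `AssociationResult` data.frame.
#' @export
fit_mortality <- function(time, event, exposure, age, sex,
                          exposure_label = "exposure") {
  keep <- complete.cases(time, event, exposure, age, sex)
  if (any(time[keep] < 0)) stop("follow-up times must be nonnegative")
  if (!all(event[keep] %in% c(0, 1))) stop("event indicator must be 0/1")
  if (sum(event[keep]) == 0) {
    warning("no events observed; association skipped")
    return(NULL)
  }
  d <- data.frame(time = time[keep], event = event[keep],
                  x = std1(exposure[keep]), age = age[keep],
                  sex = factor(sex[keep]))
  fit <- survival::coxph(survival::Surv(time, event) ~ x + age + sex, data = d)
  est <- summary(fit)$coefficients["x", ]
  assoc_row("mortality", exposure_label, "cox",
            exp(est["coef"]),
            exp(est["coef"] - 1.96 * est["se(coef)"]),
            exp(est["coef"] + 1.96 * est["se(coef)"]),
            est["Pr(>|z|)"], nrow(d))
}

#' Linear association with a brain imaging volume
#'
#' Volumes are scaled to mean zero and unit variance and modelled on the
#' standardized exposure adjusting for age, sex and intracranial volume.
#'
#' @inheritParams fit_continuous
#' @param outcome_volume brain volume vector.
#' @param icv positive intracranial volume vector.
#' @return one-row `AssociationResult` data.frame.
#' @export
fit_brain <- function(outcome_volume, exposure, age, sex, icv,
                      outcome_label = "brain_volume",
                      exposure_label = "exposure") {
  if (any(icv <= 0, na.rm = TRUE)) stop("intracranial volume must be positive")
  keep <- complete.cases(outcome_volume, exposure, age, sex, icv)
  if (sum(keep) < 10) {
    warning("fewer than 10 complete cases; association skipped")
    return(NULL)
  }
  d <- data.frame(y = std1(outcome_volume[keep]), x = std1(exposure[keep]),
                  age = age[keep], sex = factor(sex[keep]), icv = icv[keep])
  fit <- lm(y ~ x + age + sex + icv, data = d)
  est <- summary(fit)$coefficients["x", ]
  assoc_row(outcome_label, exposure_label, "linear",
            est["Estimate"],
            est["Estimate"] - 1.96 * est["Std. Error"],
            est["Estimate"] + 1.96 * est["Std. Error"],
            est["Pr(>|t|)"], nrow(d))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjusted p-values; the FDR family is all outcomes and
#' both exposures within one cohort.
#'
#' @param p_values numeric vector of raw p-values in (0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Run the phenome association battery for both exposures
#'
#' Fits linear, logistic, Cox and brain-volume models for self-reported
#' log units and the EpiScore against the outcomes table, then applies
#' BH-FDR across all rows (the within-cohort family).
#'
#' @param outcomes data.frame with columns `outcome_cont`, `disease`,
#'   `time`, `event`, `brain_vol`, `icv` (as from [simulate_outcomes()]).
#' @param self_report log-units vector.
#' @param episcore EpiScore vector.
#' @param age,sex covariates.
#' @return data.frame of `AssociationResult` rows with `p_fdr` filled in.
#' @export
association_battery <- function(outcomes, self_report, episcore, age, sex) {
  rows <- list()
  for (expo in c("self_report", "episcore")) {
    x <- if (expo == "self_report") self_report else episcore
    rows[[length(rows) + 1]] <-
      fit_continuous(outcomes$outcome_cont, x, age, sex,
                     "continuous_trait", expo)
    rows[[length(rows) + 1]] <-
      fit_binary(outcomes$disease, x, age, sex, "disease", expo)
    rows[[length(rows) + 1]] <-
      fit_mortality(outcomes$time, outcomes$event, x, age, sex, expo)
    rows[[length(rows) + 1]] <-
      fit_brain(outcomes$brain_vol, x, age, sex, outcomes$icv,
                "brain_volume", expo)
  }
  res <- do.call(rbind, rows)
  res$p_fdr <- bh_fdr(res$p)
  res
}
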