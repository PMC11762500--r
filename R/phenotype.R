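#' Log-transform weekly alcohol units
#'
#' The consumption phenotype used throughout is `log(units + 1)` (natural
#' log), so zero units maps to zero and the heavy right tail of weekly units
#' is compressed.
#'
#' @param units nonnegative numeric vector of units per week (one NHS unit =
#'   8 g / 10 ml of pure ethanol).
#' @return numeric vector `log(units + 1)`.
#' @export
log_units <- function(units) {
  if (any(units < 0, na.rm = TRUE)) stop("units must be nonnegative")
  log1p(units)
}

#' Categorize drinkers by weekly units and sex
#'
#' Zero units is "non-drinker"; at or above the sex-specific moderate/heavy
#' threshold (14 units/week for females, 21 for males) is "moderate/heavy";
#' anything in between is "light/moderate". The threshold boundary is
#' inclusive ("14 and over" / "21 and over").
#'
#' @param units nonnegative numeric vector.
#' @param sex character or factor vector of `"F"` / `"M"`, recycled if
#'   length 1.
#' @return factor with levels `non-drinker`, `light/moderate`,
#'   `moderate/heavy`.
#' @export
categorize_drinker <- function(units, sex) {
  if (any(units < 0, na.rm = TRUE)) stop("units must be nonnegative")
  sex <- as.character(sex)
  if (length(sex) == 1) sex <- rep(sex, length(units))
  if (length(sex) != length(units)) stop("units and sex lengths differ")
  if (!all(sex %in% c("F", "M"))) {
    stop("unknown sex code: ", paste(unique(setdiff(sex, c("F", "M"))), collapse = ", "))
  }
  threshold <- ifelse(sex == "F", 14, 21)
  out <- ifelse(units == 0, "non-drinker",
                ifelse(units >= threshold, "moderate/heavy", "light/moderate"))
  factor(out, levels = c("non-drinker", "light/moderate", "moderate/heavy"))
}

#' Residualize a response on covariates
#'
#' Returns `y` minus its least-squares projection onto an intercept plus the
#' covariate columns. Residuals are orthogonal to every covariate column.
#' Rank-deficient designs raise an informative error naming the collinear
#' columns.
#'
#' @param y numeric vector.
#' @param covariates data.frame or matrix of covariates (factors in a
#'   data.frame are expanded to dummies).
#' @return numeric residual vector, same length as `y`.
#' @export
residualize <- function(y, covariates) {
  if (is.data.frame(covariates)) {
    x <- model.matrix(~ ., data = covariates)
  } else {
    x <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  }
  if (nrow(x) != length(y)) stop("y and covariates have different lengths")
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("covariate design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  as.numeric(qr.resid(qx, y))
}
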