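# Random-intercept mixed models on the section table and the Snijders &
# Bosker explained-variance statistic: R2 = 100 * (1 - full total / null
# total), where each total is sigma2 + tau00 of the respective model.
#
# Estimation is by maximum likelihood (not REML): the statistic compares
# variance totals across models with different fixed effects, where ML
# totals are the conventional choice. REML is available behind a flag.

#' Log-transform the fibrosis response
#'
#' Adds a `log_fibrosis` column, `ln(fibrosis_pct + offset)`. Fibrosis
#' percentages are right-skewed with heterogeneous variance; the log
#' transform stabilises both. The small offset keeps zero-fibrosis sections
#' finite and is recorded in the `logOffset` attribute.
#'
#' @param table a section table (`data.frame` with at least `animal_id` and
#'   `fibrosis_pct >= 0`).
#' @param offset additive offset in percentage points (default 0.1).
#' @return The table with a `log_fibrosis` column and `logOffset` attribute.
#' @examples
#' tab <- data.frame(animal_id = "A1", fibrosis_pct = c(0, 57))
#' logFibrosis(tab)$log_fibrosis
#' @export
logFibrosis <- function(table, offset = 0.1) {
  if (any(table$fibrosis_pct < 0))
    stop("fibrosis_pct must be nonnegative", call. = FALSE)
  table$log_fibrosis <- log(table$fibrosis_pct + offset)
  attr(table, "logOffset") <- offset
  table
}

checkSectionTable <- function(table) {
  if (!all(c("animal_id", "fibrosis_pct") %in% names(table)))
    stop("section table needs `animal_id` and `fibrosis_pct` columns",
         call. = FALSE)
  if (length(unique(table$animal_id)) < 2)
    stop("section table needs at least 2 animals", call. = FALSE)
}

# Fit y ~ fixed + (1 | animal_id). When the random-intercept variance
# estimate hits the zero boundary the joint information matrix is not
# positive definite, so the residual and intercept variances are pooled:
# the pooled total is the ML residual variance of the fixed-effects-only
# fit (divisor N) and tau00 is reported as 0.
fitRandomIntercept <- function(table, covariate = NULL, reml = FALSE,
                               boundaryTol = 1e-8) {
  checkSectionTable(table)
  if (!"log_fibrosis" %in% names(table)) table <- logFibrosis(table)
  if (!is.null(covariate)) {
    if (!covariate %in% names(table))
      stop("covariate `", covariate, "` not found", call. = FALSE)
    keep <- !is.na(table[[covariate]])
    if (any(!keep))
      message(sum(!keep), " row(s) with missing `", covariate, "` dropped")
    table <- table[keep, , drop = FALSE]
    if (stats::sd(table[[covariate]]) == 0 || !is.finite(stats::sd(table[[covariate]])))
      stop("covariate `", covariate, "` is constant; slope unidentified",
           call. = FALSE)
    form <- stats::as.formula(paste("log_fibrosis ~", covariate,
                                    "+ (1 | animal_id)"))
  } else {
    form <- log_fibrosis ~ 1 + (1 | animal_id)
  }

  # degenerate likelihood (no within-animal residual variation): closed form
  lmres <- stats::residuals(if (is.null(covariate)) {
    stats::lm(log_fibrosis ~ 1, data = table)
  } else {
    stats::lm(stats::as.formula(paste("log_fibrosis ~", covariate)),
              data = table)
  })
  within <- stats::ave(lmres, table$animal_id)  # animal means
  if (sum((lmres - within)^2) / length(lmres) < 1e-10)
    return(degenerateOneWayFit(table, covariate, boundaryTol))

  fit <- tryCatch(
    lme4::lmer(form, data = table, REML = reml,
               control = lme4::lmerControl(check.conv.singular =
                                             lme4::.makeCC("ignore", tol = 1e-4))),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # numerically degenerate likelihood (e.g. zero within-animal residual
    # variance); fall back on the closed-form one-way ML decomposition
    return(degenerateOneWayFit(table, covariate, boundaryTol))
  }
  conv <- length(fit@optinfo$conv$lme4) == 0 ||
    is.null(fit@optinfo$conv$lme4$code) || fit@optinfo$conv$lme4$code >= 0
  if (!conv)
    stop("mixed model did not converge: ",
         paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "),
         call. = FALSE)

  vc <- as.data.frame(lme4::VarCorr(fit))
  tau00 <- vc$vcov[vc$grp == "animal_id"]
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  boundary <- tau00 < boundaryTol

  if (boundary) {
    # pooled representation (degenerate fit): ML variance about the fixed
    # part alone
    lmfit <- if (is.null(covariate)) {
      stats::lm(log_fibrosis ~ 1, data = table)
    } else {
      stats::lm(stats::as.formula(paste("log_fibrosis ~", covariate)),
                data = table)
    }
    pooledSigma2 <- sum(stats::residuals(lmfit)^2) / nrow(table)
    comps <- VarianceComponents(pooledSigma2, 0, pooled = TRUE)
    beta <- stats::coef(lmfit)
    ll <- as.numeric(stats::logLik(lmfit))
  } else {
    comps <- VarianceComponents(sigma2, tau00, pooled = FALSE)
    beta <- lme4::fixef(fit)
    ll <- as.numeric(stats::logLik(fit))
  }
  new("MixedModelFit", beta = beta, components = comps, logLik = ll,
      converged = TRUE, boundaryFlag = boundary,
      nObs = nrow(table),
      covariate = if (is.null(covariate)) "" else covariate)
}

# Closed-form ML variance decomposition for designs whose likelihood
# degenerates (zero within-animal residual variance): residuals of the
# fixed part are split into within-animal (sigma2, divisor N) and
# between-animal-mean (tau00 = between ML variance minus sigma2 / mean
# group size, floored at 0) components.
degenerateOneWayFit <- function(table, covariate, boundaryTol) {
  lmfit <- if (is.null(covariate)) {
    stats::lm(log_fibrosis ~ 1, data = table)
  } else {
    stats::lm(stats::as.formula(paste("log_fibrosis ~", covariate)),
              data = table)
  }
  r <- stats::residuals(lmfit)
  animal <- factor(table$animal_id)
  m <- tapply(r, animal, mean)
  N <- length(r)
  k <- nlevels(animal)
  sigma2 <- sum((r - m[animal])^2) / N
  tau00 <- max(0, sum(table(animal) * (m - mean(r))^2) / N -
                 sigma2 / (N / k))
  boundary <- tau00 < boundaryTol
  comps <- if (boundary) {
    VarianceComponents(sum(r^2) / N, 0, pooled = TRUE)
  } else {
    VarianceComponents(sigma2, tau00, pooled = FALSE)
  }
  new("MixedModelFit", beta = stats::coef(lmfit), components = comps,
      logLik = NA_real_, converged = TRUE, boundaryFlag = boundary,
      nObs = N, covariate = if (is.null(covariate)) "" else covariate)
}

#' Fit the null (intercept-only) random-intercept model
#'
#' `log_fibrosis = beta0 + u_animal + e`, estimated by maximum likelihood.
#' The residual variance `sigma2` captures within-animal variation and the
#' intercept variance `tau00` between-animal variation; their sum is the
#' null total against which covariates are judged. A zero-boundary intercept
#' variance triggers the pooled representation (see
#' [VarianceComponents-class]).
#'
#' @param table a section table; `log_fibrosis` is computed via
#'   [logFibrosis()] if absent.
#' @param reml use REML instead of ML.
#' @return A [MixedModelFit-class].
#' @export
fitNullModel <- function(table, reml = FALSE) {
  fitRandomIntercept(table, covariate = NULL, reml = reml)
}

#' Fit the full model with one CMR covariate
#'
#' `log_fibrosis = beta0 + beta1 * x + u_animal + e` by maximum likelihood,
#' with the same boundary/pooling contract as [fitNullModel()]. Rows with a
#' missing covariate are dropped with a message.
#'
#' @param table a section table.
#' @param covariate name of the covariate column.
#' @param reml use REML instead of ML.
#' @return A [MixedModelFit-class].
#' @export
fitFullModel <- function(table, covariate, reml = FALSE) {
  fitRandomIntercept(table, covariate = covariate, reml = reml)
}

#' Snijders & Bosker explained variance
#'
#' `R2 = 100 * (1 - (sigma2_full + tau00_full) / (sigma2_null +
#' tau00_null))`, in percent: the share of the null model's total variance
#' removed by adding the covariate. Pooled components contribute their
#' pooled totals. A negative value (full model worse than null) is returned
#' as-is with a warning, not clipped.
#'
#' @param full,null [VarianceComponents-class] (or [MixedModelFit-class])
#'   of the full and null models.
#' @return Explained variance in percent (full precision; display rounding
#'   is left to the caller).
#' @examples
#' r2SnijdersBosker(VarianceComponents(0.62, 0.07),
#'                  VarianceComponents(1.71, 0, pooled = TRUE))
#' @export
r2SnijdersBosker <- function(full, null) {
  if (is(full, "MixedModelFit")) {
    if (!full@converged) stop("full model fit did not converge", call. = FALSE)
    full <- full@components
  }
  if (is(null, "MixedModelFit")) {
    if (!null@converged) stop("null model fit did not converge", call. = FALSE)
    null <- null@components
  }
  nullTotal <- totalVariance(null)
  if (nullTotal <= 0)
    stop("null model total variance must be positive", call. = FALSE)
  r2 <- 100 * (1 - totalVariance(full) / nullTotal)
  if (r2 < 0)
    warning("negative explained variance: full model total exceeds the null")
  r2
}

#' Compare all CMR covariates against histological fibrosis
#'
#' Fits the null model once and a full model per covariate, reporting
#' per-covariate variance components, the pooled flag, and the Snijders &
#' Bosker explained variance (full precision plus integer-percent display
#' rounding). The first row records the null model.
#'
#' @param table a section table.
#' @param covariates character vector of covariate column names (no
#'   duplicates).
#' @param offset log-transform offset, percentage points.
#' @param reml use REML instead of ML.
#' @return A `data.frame` with columns `covariate`, `sigma2`, `tau00`,
#'   `pooled`, `r2_pct`, `r2_display`; attribute `nullTotal` holds the null
#'   model total.
#' @export
compareAll <- function(table, covariates, offset = 0.1, reml = FALSE) {
  if (anyDuplicated(covariates))
    stop("duplicate covariate names", call. = FALSE)
  table <- logFibrosis(table, offset = offset)
  null <- fitNullModel(table, reml = reml)
  rows <- list(data.frame(covariate = "(null)",
                          sigma2 = null@components@sigma2,
                          tau00 = null@components@tau00,
                          pooled = null@components@pooled,
                          r2_pct = 0, r2_display = 0L,
                          stringsAsFactors = FALSE))
  for (cv in covariates) {
    fit <- fitFullModel(table, cv, reml = reml)
    r2 <- r2SnijdersBosker(fit, null)
    rows[[length(rows) + 1]] <- data.frame(
      covariate = cv,
      sigma2 = fit@components@sigma2,
      tau00 = fit@components@tau00,
      pooled = fit@components@pooled,
      r2_pct = r2,
      r2_display = as.integer(round(r2)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "nullTotal") <- totalVariance(null)
  out
}
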