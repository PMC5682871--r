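# Abstract two-level cohort generator on the log-fibrosis scale, used to
# exercise the mixed-model stage with known variance components.

drawCovariate <- function(gen, n) {
  switch(gen$dist,
         normal = stats::rnorm(n, gen$mean %||% 0, gen$sd %||% 1),
         uniform = stats::runif(n, gen$min %||% 0, gen$max %||% 1),
         failField("covariateGenerator", "unknown distribution"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a multi-animal section table with known variance components
#'
#' For animal `i` draws a random intercept `u_i ~ N(0, tau00)`; for each of
#' its sections draws a covariate `x_ij` from the configured generator and a
#' residual `e_ij ~ N(0, sigma2)`, and sets log-fibrosis
#' `y_ij = beta0 + beta1 * x_ij + u_i + e_ij`. The fibrosis percentage is
#' `exp(y_ij)` capped at 100 (fibrosis is an area percentage).
#'
#' @param cspec a [CohortSpec-class].
#' @return A `data.frame` (one row per section) with columns `animal_id`,
#'   `section_id`, `covariate`, `fibrosis_pct`, plus the ground-truth columns
#'   `u_true` (animal intercept) and `log_fibrosis_true`.
#' @examples
#' tab <- generateCohort(CohortSpec(nAnimals = 4, sectionsPerAnimal = 3))
#' head(tab)
#' @export
generateCohort <- function(cspec) {
  validObject(cspec)
  nA <- cspec@nAnimals
  nS <- cspec@sectionsPerAnimal
  withSeed(cspec@seed, {
    u <- stats::rnorm(nA, 0, sqrt(cspec@tau00))
    x <- drawCovariate(cspec@covariateGenerator, nA * nS)
    e <- stats::rnorm(nA * nS, 0, sqrt(cspec@sigma2))
    animal <- rep(seq_len(nA), each = nS)
    y <- cspec@beta0 + cspec@beta1 * x + u[animal] + e
    data.frame(
      animal_id = sprintf("A%02d", animal),
      section_id = sprintf("S%d", rep(seq_len(nS), times = nA)),
      covariate = x,
      fibrosis_pct = pmin(100, exp(y)),
      u_true = u[animal],
      log_fibrosis_true = y,
      stringsAsFactors = FALSE)
  })
}
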