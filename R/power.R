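#' @include AllClasses.R AllGenerics.R simulate.R
NULL

#' Analytic power for IV regression with a continuous outcome
#'
#' Normal-approximation power of the two-sided IV test:
#' `power = Phi(sqrt(n * R2) * |beta| - z_{1-alpha/2})`, where `R2` is
#' the fraction of exposure variance explained by the instrument and
#' `beta` the true causal effect in SD of outcome per SD of exposure.
#' `sqrt(n * R2) * beta` is the expected Wald z of the IV estimate; the
#' formula keeps the upper rejection tail only, so at `beta = 0` it
#' returns `alpha / 2`. Monotone non-decreasing in `n`, `r2` and
#' `|beta|`.
#'
#' @param n Sample size (> 0).
#' @param r2 Instrument R-squared on the exposure, in (0, 1).
#' @param beta True causal effect, SD per SD.
#' @param alpha Two-sided significance level, default 0.05.
#' @return A [PowerResult-class].
#' @examples
#' ivPower(7446, 0.019, 0.30)  # ~0.95
#' ivPower(7446, 0.025, 0.30)  # ~0.98
#' @export
ivPower <- function(n, r2, beta, alpha = 0.05) {
  if (n <= 0) stop("n must be > 0")
  if (r2 <= 0 || r2 >= 1) stop("r2 must lie in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  pw <- stats::pnorm(sqrt(n * r2) * abs(beta) -
                       stats::qnorm(1 - alpha / 2))
  new("PowerResult", power = pw, n = n, r2Instrument = r2,
      betaTrue = beta, alpha = alpha, method = "analytic")
}

#' Power at half the observed effect
#'
#' Sensitivity companion to [ivPower()]: the power to detect an effect
#' half the size of the observed exposure-outcome association, guarding
#' against over-optimism when the true causal effect is weaker than the
#' confounded observational slope.
#'
#' @inheritParams ivPower
#' @param betaObserved The observed association effect whose half is
#'   tested.
#' @return A [PowerResult-class] evaluated at `betaObserved / 2`.
#' @export
halfEffectPower <- function(n, r2, betaObserved, alpha = 0.05) {
  ivPower(n, r2, betaObserved / 2, alpha = alpha)
}

#' Monte-Carlo power of the full IV pipeline
#'
#' Empirical companion to the analytic formula: simulates replicate
#' studies under a structural parameter set, runs the pooled two-stage
#' least squares analysis on each, and reports the fraction of
#' replicates rejecting at `alpha`. Agreement with [ivPower()] within
#' Monte-Carlo error validates the analytic form.
#'
#' @param params A [StructuralParams-class]; its `betaCausal`,
#'   `r2GrsBmi` and total profile `n` define the scenario.
#' @param reps Number of replicate studies (>= 100).
#' @param alpha Two-sided level.
#' @param direction Which causal direction to test, default
#'   `"bmi_to_t"`.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return A [PowerResult-class] with `method = "empirical"` and an
#'   attribute `"mcSe"` (binomial Monte-Carlo standard error).
#' @export
empiricalPower <- function(params, reps = 200, alpha = 0.05,
                           direction = c("bmi_to_t", "t_to_bmi"),
                           seed = params@seed) {
  direction <- match.arg(direction)
  if (reps < 100) stop("reps must be >= 100")
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    p <- params
    p@seed <- as.integer((seed + r) %% .Machine$integer.max)
    study <- simulateStudy(p)
    iv <- pooledAnalysis(study, type = "iv", direction = direction)
    rej[r] <- pValue(iv) < alpha
  }
  pw <- mean(rej)
  r2 <- if (direction == "bmi_to_t") params@r2GrsBmi else params@r2GrsT
  res <- new("PowerResult", power = pw,
             n = sum(params@cohortProfiles$n), r2Instrument = r2,
             betaTrue = params@betaCausal, alpha = alpha,
             method = "empirical")
  attr(res, "mcSe") <- sqrt(pw * (1 - pw) / reps)
  res
}
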