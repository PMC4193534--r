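#' Parameters of the two-test screening model
#'
#' The seven base parameters of the conditionally dependent two-test model:
#' prevalence \code{pi}, per-test sensitivities and specificities, and the
#' conditional covariances between the two test results among the diseased
#' (\code{covDp}) and non-diseased (\code{covDn}). The gold standard used in
#' stage two is assumed perfect by default (\code{seGS = spGS = 1}); the
#' constants are retained for sequential-testing algebra but never sampled.
#'
#' The covariances must lie in their feasibility ranges
#' \code{0 <= covDp <= min(se1, se2) - se1*se2} and
#' \code{0 <= covDn <= min(sp1, sp2) - sp1*sp2}; \code{covDp = covDn = 0}
#' recovers conditional independence.
#'
#' @param pi Prevalence, P(D+).
#' @param se1,se2 Sensitivities P(Ti+ | D+).
#' @param sp1,sp2 Specificities P(Ti- | D-).
#' @param covDp,covDn Conditional covariances given disease / non-disease.
#' @param seGS,spGS Gold-standard sensitivity and specificity constants.
#' @return An object of class \code{model_params} (a named list).
#' @examples
#' model_params(pi = 0.4, se1 = 0.9, sp1 = 0.95, se2 = 0.95, sp2 = 0.90,
#'              covDp = 0.0326917, covDn = 0.0261534)
#' @export
model_params <- function(pi, se1, se2, sp1, sp2, covDp = 0, covDn = 0,
                         seGS = 1, spGS = 1) {
  p <- c(pi = pi, se1 = se1, se2 = se2, sp1 = sp1, sp2 = sp2,
         seGS = seGS, spGS = spGS)
  if (anyNA(c(p, covDp, covDn)))
    stop("model parameters must be non-missing")
  if (any(p < 0 | p > 1))
    stop("invariant violated: ", paste(names(p)[p < 0 | p > 1], collapse = ", "),
         " must lie in [0, 1]")
  bDp <- cov_bound(se1, se2)
  bDn <- cov_bound(sp1, sp2)
  if (covDp < 0 || covDp > bDp + 1e-12)
    stop(sprintf(
      "invariant violated: covDp must satisfy 0 <= covDp <= min(se1,se2) - se1*se2 = %.6g",
      bDp))
  if (covDn < 0 || covDn > bDn + 1e-12)
    stop(sprintf(
      "invariant violated: covDn must satisfy 0 <= covDn <= min(sp1,sp2) - sp1*sp2 = %.6g",
      bDn))
  structure(list(pi = pi, se1 = se1, se2 = se2, sp1 = sp1, sp2 = sp2,
                 covDp = covDp, covDn = covDn, seGS = seGS, spGS = spGS),
            class = "model_params")
}

# upper feasibility bound of the conditional covariance of two Bernoulli
# results with success probabilities p1, p2: min(p1,p2) - p1*p2
cov_bound <- function(p1, p2) pmin(p1, p2) - p1 * p2

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "screening model parameters:\n  pi = %.4g\n  test 1: Se = %.4g, Sp = %.4g\n  test 2: Se = %.4g, Sp = %.4g\n  covDp = %.4g, covDn = %.4g\n",
    x$pi, x$se1, x$sp1, x$se2, x$sp2, x$covDp, x$covDn))
  invisible(x)
}

#' Stage-one multinomial cell probabilities
#'
#' Probabilities of the four stage-one test patterns under the
#' covariance-parameterized conditionally dependent model, mixing the
#' diseased and non-diseased strata by the prevalence:
#' \deqn{Px11 = \pi(Se_1 Se_2 + covDp) + (1-\pi)((1-Sp_1)(1-Sp_2) + covDn)}
#' and analogously for the (+,-), (-,+) and (-,-) cells, with the covariance
#' entering each stratum with sign + for concordant and - for discordant
#' patterns.
#'
#' @param params A \code{\link{model_params}} object.
#' @return Named numeric vector \code{c(px11, px10, px01, px00)} summing
#'   to 1.
#' @examples
#' stage_one_cell_probs(model_params(0.3, 1, 1, 1, 1))
#' @export
stage_one_cell_probs <- function(params) {
  stopifnot(inherits(params, "model_params"))
  with(params, {
    dis <- c(se1 * se2 + covDp,
             se1 * (1 - se2) - covDp,
             (1 - se1) * se2 - covDp,
             (1 - se1) * (1 - se2) + covDp)
    non <- c((1 - sp1) * (1 - sp2) + covDn,
             (1 - sp1) * sp2 - covDn,
             sp1 * (1 - sp2) - covDn,
             sp1 * sp2 + covDn)
    p <- pi * dis + (1 - pi) * non
    names(p) <- c("px11", "px10", "px01", "px00")
    p
  })
}

#' Joint accuracy of simultaneous testing
#'
#' Sensitivity and specificity of the stage-one joint rule that calls a
#' subject positive if either test is positive ("joint either"):
#' \code{seJE = se1 + se2 - (se1*se2 + covDp)} and
#' \code{spJE = sp1*sp2 + covDn}. Positive conditional dependence lowers the
#' sensitivity gain of the combination and raises its joint specificity.
#'
#' @param params A \code{\link{model_params}} object.
#' @return Named numeric vector \code{c(seJE, spJE)}.
#' @examples
#' joint_accuracy(model_params(0.4, 0.9, 0.95, 0.95, 0.90,
#'                             covDp = 0.0326917, covDn = 0.0261534))
#' @export
joint_accuracy <- function(params) {
  stopifnot(inherits(params, "model_params"))
  c(seJE = params$se1 + params$se2 - (params$se1 * params$se2 + params$covDp),
    spJE = params$sp1 * params$sp2 + params$covDn)
}

#' Accuracy of sequential testing with a gold standard
#'
#' The two-stage design is a sequential ("joint both") strategy: a subject
#' is a final positive only if the stage-one joint rule and the stage-two
#' gold standard are both positive. Assuming the gold standard is
#' independent of the screen, \code{seJB = seJE * seGS} and
#' \code{spJB = 1 - (1 - spJE) * (1 - spGS)}.
#'
#' @param seJE,spJE Joint sensitivity and specificity of simultaneous
#'   testing.
#' @param seGS,spGS Gold-standard sensitivity and specificity (default
#'   perfect).
#' @return Named numeric vector \code{c(seJB, spJB)}.
#' @examples
#' sequential_accuracy(0.8, 0.9, seGS = 0.9, spGS = 0.8)
#' @export
sequential_accuracy <- function(seJE, spJE, seGS = 1, spGS = 1) {
  stopifnot(all(c(seJE, spJE, seGS, spGS) >= 0),
            all(c(seJE, spJE, seGS, spGS) <= 1))
  c(seJB = seJE * seGS, spJB = 1 - (1 - spJE) * (1 - spGS))
}

#' Stage-two multinomial cell probabilities
#'
#' Probabilities of the verified-diseased, verified-non-diseased and
#' unverified cells of stage two under a perfect gold standard:
#' \code{pa11 = pi*seJE}, \code{pa10 = (1-pi)*(1-spJE)},
#' \code{pa0 = pi*(1-seJE) + (1-pi)*spJE}. The unverified mass \code{pa0}
#' equals the stage-one double-negative probability \code{px00}.
#'
#' @param params A \code{\link{model_params}} object.
#' @return Named numeric vector \code{c(pa11, pa10, pa0)} summing to 1.
#' @export
stage_two_cell_probs <- function(params) {
  ja <- joint_accuracy(params)
  pi <- params$pi
  c(pa11 = pi * ja[["seJE"]],
    pa10 = (1 - pi) * (1 - ja[["spJE"]]),
    pa0 = pi * (1 - ja[["seJE"]]) + (1 - pi) * ja[["spJE"]])
}

#' PPV of simultaneous testing and conditional correlations
#'
#' The positive predictive value of the stage-one joint rule,
#' \code{ppvJE = pi*seJE / (pi*seJE + (1-pi)*(1-spJE))}, and the conditional
#' correlation coefficients corresponding to the covariances,
#' \code{rhoDp = covDp / sqrt(se1(1-se1) se2(1-se2))} (and analogously
#' \code{rhoDn} from the specificities).
#'
#' A correlation is reported as \code{NaN} when an accuracy sits exactly on
#' the boundary 0 or 1 (the denominator vanishes); this is a value, not an
#' error.
#'
#' @param params A \code{\link{model_params}} object.
#' @return Named numeric vector \code{c(ppvJE, rhoDp, rhoDn)}.
#' @export
ppv_and_correlations <- function(params) {
  ja <- joint_accuracy(params)
  pi <- params$pi
  ppv <- pi * ja[["seJE"]] / (pi * ja[["seJE"]] + (1 - pi) * (1 - ja[["spJE"]]))
  denDp <- sqrt(params$se1 * (1 - params$se1) * params$se2 * (1 - params$se2))
  denDn <- sqrt(params$sp1 * (1 - params$sp1) * params$sp2 * (1 - params$sp2))
  c(ppvJE = ppv,
    rhoDp = if (denDp == 0) NaN else params$covDp / denDp,
    rhoDn = if (denDn == 0) NaN else params$covDn / denDn)
}

#' Observed-data log-likelihood of the two-stage model
#'
#' The default (\code{factorization = "two-multinomial"}) is the model's
#' own formulation: the sum of the stage-one multinomial log-mass of
#' \code{(x11, x10, x01, x00)} and the stage-two multinomial log-mass of
#' \code{(a11, a10, a0)}, each over all \code{n} subjects. Because
#' \code{a0 = x00} and \code{a11 + a10} equals the joint-positive total,
#' the two factors share margin information by construction.
#'
#' \code{factorization = "exact"} is an alternative factorization for
#' sensitivity analysis: the stage-one multinomial times the binomial split
#' of the verified joint positives into diseased and non-diseased with
#' probability \code{pa11 / (pa11 + pa10)}.
#'
#' Multinomial normalizing constants (log factorials) are always included,
#' so deviances are comparable across models on the same data. Cells with a
#' zero probability and a positive count yield \code{-Inf}.
#'
#' @param counts A \code{\link{screening_counts}} object.
#' @param params A \code{\link{model_params}} object.
#' @param factorization Likelihood formulation; see Details.
#' @return A single finite number, or \code{-Inf} when a positively
#'   observed cell has probability zero.
#' @examples
#' log_likelihood(colorectal_counts(),
#'                model_params(0.0065, 0.604, 0.6825, 0.9812, 0.9559,
#'                             covDp = 0.03, covDn = 0.0017))
#' @export
log_likelihood <- function(counts, params,
                           factorization = c("two-multinomial", "exact")) {
  stopifnot(inherits(counts, "screening_counts"),
            inherits(params, "model_params"))
  factorization <- match.arg(factorization)
  px <- stage_one_cell_probs(params)
  pa <- stage_two_cell_probs(params)
  x <- c(counts$x11, counts$x10, counts$x01, counts$x00)
  ll <- multinom_logmass(x, px)
  if (factorization == "two-multinomial") {
    ll <- ll + multinom_logmass(c(counts$a11, counts$a10, counts$a0), pa)
  } else {
    npos <- counts$a11 + counts$a10
    psplit <- pa[["pa11"]] / (pa[["pa11"]] + pa[["pa10"]])
    ll <- ll + stats::dbinom(counts$a11, npos, psplit, log = TRUE)
  }
  ll
}

# multinomial log-mass with constants, tolerating zero cells that have
# zero counts
multinom_logmass <- function(x, p) {
  if (any(p < -1e-12)) return(-Inf)
  p <- pmax(p, 0)
  if (any(x > 0 & p == 0)) return(-Inf)
  pos <- x > 0
  lgamma(sum(x) + 1) - sum(lgamma(x + 1)) + sum(x[pos] * log(p[pos]))
}
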