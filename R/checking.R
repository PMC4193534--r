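#' Deviance summaries: Dbar, pD and DIC
#'
#' The deviance is \code{D(theta) = -2 * log_likelihood}. \code{Dbar} is
#' its posterior mean over the retained draws; the effective number of
#' parameters is \code{pD = Dbar - D(theta_bar)} with \code{theta_bar} the
#' posterior mean of the seven base parameters on their natural scale, and
#' \code{DIC = Dbar + pD}. \code{pD} can be negative under weak
#' identification (a diagnostic signal in its own right: the plug-in mean
#' then sits in a low-density fold of the posterior).
#'
#' @param draws A \code{screening_draws} object carrying per-draw
#'   log-likelihoods.
#' @param counts The observed \code{\link{screening_counts}}; defaults to
#'   the counts stored with the draws.
#' @return Named list with \code{Dbar}, \code{D_at_mean}, \code{pD},
#'   \code{DIC}.
#' @export
deviance_summaries <- function(draws, counts = attr(draws, "counts")) {
  stopifnot(inherits(draws, "screening_draws"),
            inherits(counts, "screening_counts"))
  Dbar <- mean(-2 * draws$loglik)
  mean_params <- model_params(
    pi = mean(draws$pi), se1 = mean(draws$se1), se2 = mean(draws$se2),
    sp1 = mean(draws$sp1), sp2 = mean(draws$sp2),
    covDp = mean(draws$covDp), covDn = mean(draws$covDn))
  D_at_mean <- -2 * log_likelihood(counts, mean_params,
                                   factorization = attr(draws, "factorization"))
  pD <- Dbar - D_at_mean
  list(Dbar = Dbar, D_at_mean = D_at_mean, pD = pD, DIC = Dbar + pD)
}

# cells with observed counts: a0 duplicates x00 and is excluded
known_cells <- function() c("x11", "x10", "x01", "x00", "a11", "a10")

# expected known-cell counts per draw: one row per draw, one column per cell
expected_cells <- function(draws, n) {
  cbind(
    x11 = n * (draws$pi * (draws$se1 * draws$se2 + draws$covDp) +
               (1 - draws$pi) * ((1 - draws$sp1) * (1 - draws$sp2) + draws$covDn)),
    x10 = n * (draws$pi * (draws$se1 * (1 - draws$se2) - draws$covDp) +
               (1 - draws$pi) * ((1 - draws$sp1) * draws$sp2 - draws$covDn)),
    x01 = n * (draws$pi * ((1 - draws$se1) * draws$se2 - draws$covDp) +
               (1 - draws$pi) * (draws$sp1 * (1 - draws$sp2) - draws$covDn)),
    x00 = n * (draws$pi * ((1 - draws$se1) * (1 - draws$se2) + draws$covDp) +
               (1 - draws$pi) * (draws$sp1 * draws$sp2 + draws$covDn)),
    a11 = n * draws$pi * draws$seJE,
    a10 = n * (1 - draws$pi) * (1 - draws$spJE))
}

# one replicated dataset per retained draw, as a draws x cells matrix of
# known-cell counts; sequential conditional binomials vectorized over draws
replicate_cells <- function(draws, n) {
  m <- nrow(draws)
  px <- expected_cells(draws, n)[, c("x11", "x10", "x01", "x00")] / n
  x11 <- stats::rbinom(m, n, px[, 1])
  x10 <- stats::rbinom(m, n - x11, pmin(1, px[, 2] / pmax(1e-300, 1 - px[, 1])))
  x01 <- stats::rbinom(m, n - x11 - x10,
                       pmin(1, px[, 3] / pmax(1e-300, 1 - px[, 1] - px[, 2])))
  x00 <- n - x11 - x10 - x01
  pa11 <- draws$pi * draws$seJE
  pa10 <- (1 - draws$pi) * (1 - draws$spJE)
  a11 <- stats::rbinom(m, n, pa11)
  a10 <- stats::rbinom(m, n - a11, pmin(1, pa10 / pmax(1e-300, 1 - pa11)))
  cbind(x11 = x11, x10 = x10, x01 = x01, x00 = x00, a11 = a11, a10 = a10)
}

chi2_stat <- function(obs, expd) {
  # obs: vector over cells; expd: draws x cells matrix
  keep <- expd > 1e-12
  contrib <- (matrix(obs, nrow(expd), length(obs), byrow = TRUE) - expd)^2 / expd
  contrib[!keep] <- 0
  if (any(!keep))
    warning("expected cell count below 1e-12; its chi-squared term was skipped",
            call. = FALSE)
  rowSums(contrib)
}

#' Local chi-squared posterior-predictive check
#'
#' For each retained draw, computes the chi-squared discrepancy
#' \code{sum((O - E)^2 / E)} over the known cells (\code{x11, x10, x01,
#' x00, a11, a10}; the unverified total duplicates \code{x00} and is
#' excluded) for the observed data and for one replicated dataset drawn
#' from the two-stage model at that draw's parameters. The
#' posterior-predictive p-value is the fraction of draws whose replicated
#' discrepancy exceeds the observed one; values near 0.5 indicate that
#' replicated and actual data look alike, values near 0 or 1 indicate
#' misfit.
#'
#' @param draws A \code{screening_draws} object.
#' @param counts Observed counts (defaults to those stored in
#'   \code{draws}).
#' @param seed Integer seed for the replicate datasets.
#' @return List with \code{chi2_obs_median}, \code{ppp}, and the per-draw
#'   vectors \code{chi2_obs}, \code{chi2_rep}.
#' @export
posterior_predictive_chi2 <- function(draws, counts = attr(draws, "counts"),
                                      seed = 1) {
  stopifnot(inherits(draws, "screening_draws"),
            inherits(counts, "screening_counts"))
  obs <- unlist(counts[known_cells()])
  expd <- expected_cells(draws, counts$n)
  chi2_obs <- chi2_stat(obs, expd)
  set.seed(seed)
  rep_cells <- replicate_cells(draws, counts$n)
  chi2_rep <- chi2_stat_rep(rep_cells, expd)
  list(chi2_obs_median = stats::median(chi2_obs),
       ppp = mean(chi2_rep >= chi2_obs),
       chi2_obs = chi2_obs, chi2_rep = chi2_rep)
}

chi2_stat_rep <- function(rep_cells, expd) {
  keep <- expd > 1e-12
  contrib <- (rep_cells - expd)^2 / expd
  contrib[!keep] <- 0
  rowSums(contrib)
}

#' Cell-wise posterior-predictive intervals
#'
#' Medians and central 95\% intervals of replicated known-cell counts
#' across the retained draws, with a flag for whether each observed count
#' falls inside its interval.
#'
#' @inheritParams posterior_predictive_chi2
#' @return Data frame with one row per known cell: \code{cell},
#'   \code{observed}, \code{median}, \code{lower}, \code{upper},
#'   \code{inside}.
#' @export
cell_predictive_intervals <- function(draws, counts = attr(draws, "counts"),
                                      seed = 1) {
  stopifnot(inherits(draws, "screening_draws"),
            inherits(counts, "screening_counts"))
  set.seed(seed)
  rep_cells <- replicate_cells(draws, counts$n)
  obs <- unlist(counts[known_cells()])
  out <- do.call(rbind, lapply(known_cells(), function(cl) {
    q <- stats::quantile(rep_cells[, cl], c(0.5, 0.025, 0.975), names = FALSE)
    data.frame(cell = cl, observed = obs[[cl]], median = q[1],
               lower = q[2], upper = q[3],
               inside = obs[[cl]] >= q[2] && obs[[cl]] <= q[3])
  }))
  rownames(out) <- NULL
  out
}

#' PPV coverage check
#'
#' The observed positive predictive value of the joint screen,
#' \code{a11 / (a11 + a10)}, is a directly identified quantity; a model
#' that fits should cover it with the 95\% credible interval of the
#' per-draw model-based \code{ppvJE}.
#'
#' @inheritParams posterior_predictive_chi2
#' @return List with \code{ppv_observed}, \code{lower}, \code{upper},
#'   \code{in_bci}.
#' @export
ppv_check <- function(draws, counts = attr(draws, "counts")) {
  stopifnot(inherits(draws, "screening_draws"),
            inherits(counts, "screening_counts"))
  npos <- counts$a11 + counts$a10
  if (npos == 0) stop("PPV check requires at least one joint positive")
  ppv_obs <- counts$a11 / npos
  q <- stats::quantile(draws$ppvJE, c(0.025, 0.975), names = FALSE)
  list(ppv_observed = ppv_obs, lower = q[1], upper = q[2],
       in_bci = ppv_obs >= q[1] && ppv_obs <= q[2])
}

#' Four-criterion model evaluation
#'
#' Combines the checking battery into a verdict: (1) \code{pD} is positive
#' and no larger than the number of sampled unknowns (base parameters plus
#' latent prior bounds; the band is configurable because "reasonable" is a
#' qualitative judgement); (2) the posterior-predictive p-value of the
#' local chi-squared test is far from 0 and 1 (default band
#' \code{[0.05, 0.95]}, with the distance from 0.5 reported); (3) the 95\%
#' credible interval of the model-based PPV covers the observed PPV;
#' (4) at least \code{min_cells_inside} of the six known cells fall inside
#' their predictive intervals (default all but one). The overall verdict
#' passes iff all four criteria pass.
#'
#' @param draws A \code{screening_draws} object.
#' @param counts Observed counts (defaults to those stored with the draws).
#' @param seed Seed for the replicate datasets.
#' @param pd_band Numeric length-2; acceptable \code{(min, max)} for
#'   \code{pD}. \code{NULL} uses \code{c(0, n_unknowns)}.
#' @param ppp_band Numeric length-2 band for the posterior-predictive
#'   p-value.
#' @param min_cells_inside Minimum number of known cells whose observed
#'   count must fall inside its predictive interval.
#' @return An object of class \code{check_report}.
#' @export
evaluate_model <- function(draws, counts = attr(draws, "counts"), seed = 1,
                           pd_band = NULL, ppp_band = c(0.05, 0.95),
                           min_cells_inside = length(known_cells()) - 1L) {
  stopifnot(inherits(draws, "screening_draws"))
  spec <- attr(draws, "prior_spec")
  n_unknowns <- 5L +
    (if (is.null(spec) || spec$dependence) 2L else 0L) +
    sum(vapply(base_param_names(), function(nm)
      inherits(spec[[nm]], "two_step_prior"), logical(1)))
  if (is.null(pd_band)) pd_band <- c(0, n_unknowns)
  dev <- deviance_summaries(draws, counts)
  chi <- posterior_predictive_chi2(draws, counts, seed = seed)
  cells <- cell_predictive_intervals(draws, counts, seed = seed)
  ppv <- ppv_check(draws, counts)
  crit <- c(
    pD_reasonable = dev$pD > pd_band[1] && dev$pD <= pd_band[2],
    ppp_moderate = chi$ppp >= ppp_band[1] && chi$ppp <= ppp_band[2],
    ppv_covered = ppv$in_bci,
    cells_covered = sum(cells$inside) >= min_cells_inside)
  structure(list(pD = dev$pD, DIC = dev$DIC, Dbar = dev$Dbar,
                 chi2_obs_median = chi$chi2_obs_median, ppp = chi$ppp,
                 ppp_distance_from_half = abs(chi$ppp - 0.5),
                 cells = cells, ppv = ppv, criteria = crit,
                 pass = all(crit), n_unknowns = n_unknowns,
                 thresholds = list(pd_band = pd_band, ppp_band = ppp_band,
                                   min_cells_inside = min_cells_inside)),
            class = "check_report")
}

#' @export
print.check_report <- function(x, ...) {
  cat("Model evaluation and checking\n")
  cat(sprintf("  pD = %.2f, DIC = %.2f\n", x$pD, x$DIC))
  cat(sprintf("  local chi-squared: median %.4g, posterior-predictive p = %.3f\n",
              x$chi2_obs_median, x$ppp))
  cat(sprintf("  observed PPV %.4f in 95%% BCI (%.4f, %.4f): %s\n",
              x$ppv$ppv_observed, x$ppv$lower, x$ppv$upper, x$ppv$in_bci))
  cat("  replicated cells: median (95% interval), * = observed outside\n")
  for (i in seq_len(nrow(x$cells)))
    cat(sprintf("    %-4s obs %6d  rep %6.0f (%6.0f, %6.0f)%s\n",
                x$cells$cell[i], x$cells$observed[i], x$cells$median[i],
                x$cells$lower[i], x$cells$upper[i],
                if (x$cells$inside[i]) "" else " *"))
  cat("  criteria:", paste(names(x$criteria)[x$criteria], collapse = ", "),
      "\n  overall:", if (x$pass) "PASS" else "FAIL", "\n")
  invisible(x)
}
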