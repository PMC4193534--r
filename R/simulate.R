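#' Convert conditional correlations to covariances
#'
#' Inverts the conditional-correlation definitions: given target
#' correlations between the two test results among the diseased
#' (\code{rhoDp}) and non-diseased (\code{rhoDn}),
#' \code{covDp = rhoDp * sqrt(se1(1-se1) se2(1-se2))} and analogously for
#' \code{covDn} from the specificities. Errors if the requested correlation
#' exceeds the largest correlation compatible with the feasibility bound,
#' naming that maximum.
#'
#' @param rhoDp,rhoDn Target conditional correlations in [0, 1].
#' @param se1,se2,sp1,sp2 Test accuracies, strictly inside (0, 1).
#' @return Named numeric vector \code{c(covDp, covDn)}.
#' @examples
#' correlations_to_covariances(0.5, 0.4, 0.9, 0.95, 0.95, 0.90)
#' @export
correlations_to_covariances <- function(rhoDp, rhoDn, se1, se2, sp1, sp2) {
  acc <- c(se1, se2, sp1, sp2)
  stopifnot(all(acc > 0), all(acc < 1), rhoDp >= 0, rhoDn >= 0)
  conv <- function(rho, p1, p2, label) {
    den <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
    rho_max <- cov_bound(p1, p2) / den
    if (rho > rho_max + 1e-12)
      stop(sprintf(
        "requested %s = %g is infeasible for these accuracies; maximum feasible correlation is %.6g",
        label, rho, rho_max))
    rho * den
  }
  c(covDp = conv(rhoDp, se1, se2, "rhoDp"),
    covDn = conv(rhoDn, sp1, sp2, "rhoDn"))
}

# probabilities of the latent disease x T1 x T2 table, pattern order
# (11, 10, 01, 00) within each disease stratum
latent_cell_probs <- function(params) {
  with(params, {
    dis <- pi * c(se1 * se2 + covDp,
                  se1 * (1 - se2) - covDp,
                  (1 - se1) * se2 - covDp,
                  (1 - se1) * (1 - se2) + covDp)
    non <- (1 - pi) * c((1 - sp1) * (1 - sp2) + covDn,
                        (1 - sp1) * sp2 - covDn,
                        sp1 * (1 - sp2) - covDn,
                        sp1 * sp2 + covDn)
    c(Dp_11 = dis[1], Dp_10 = dis[2], Dp_01 = dis[3], Dp_00 = dis[4],
      Dn_11 = non[1], Dn_10 = non[2], Dn_01 = non[3], Dn_00 = non[4])
  })
}

#' Simulate counts from the two-stage screening design
#'
#' Draws the latent disease-by-test-pattern table from the eight-cell
#' multinomial with the covariance-structured dependence, then collapses it
#' exactly as the design observes it: the stage-one cells sum over disease
#' status, the verified diseased/non-diseased counts are the diseased and
#' non-diseased joint positives, and the unverified total is the
#' double-negative count (perfect gold standard). All count invariants
#' therefore hold by construction.
#'
#' @param params True \code{\link{model_params}}.
#' @param n Number of screened subjects.
#' @return A \code{\link{screening_counts}}.
#' @examples
#' set.seed(7)
#' simulate_counts(scenario_preset("2.1")$params, n = 200)
#' @export
simulate_counts <- function(params, n) {
  stopifnot(inherits(params, "model_params"), n >= 0)
  p <- latent_cell_probs(params)
  cells <- if (n == 0) rep(0L, 8) else
    as.integer(stats::rmultinom(1, n, p))
  names(cells) <- names(p)
  screening_counts(
    x11 = cells[["Dp_11"]] + cells[["Dn_11"]],
    x10 = cells[["Dp_10"]] + cells[["Dn_10"]],
    x01 = cells[["Dp_01"]] + cells[["Dn_01"]],
    x00 = cells[["Dp_00"]] + cells[["Dn_00"]],
    a11 = cells[["Dp_11"]] + cells[["Dp_10"]] + cells[["Dp_01"]],
    a10 = cells[["Dn_11"]] + cells[["Dn_10"]] + cells[["Dn_01"]])
}

#' Simulation scenario presets
#'
#' The four standard study conditions, all with conditional correlations
#' \code{rhoDp = 0.5} and \code{rhoDn = 0.4}:
#' \describe{
#'   \item{1.1}{low prevalence, large sample, high accuracy:
#'     pi = 0.01, n = 20000, (Se1, Sp1) = (0.90, 0.95),
#'     (Se2, Sp2) = (0.95, 0.90)}
#'   \item{1.2}{low prevalence, large sample, low accuracy:
#'     pi = 0.01, n = 20000, (0.60, 0.70), (0.70, 0.60)}
#'   \item{2.1}{high prevalence, small sample, high accuracy:
#'     pi = 0.40, n = 200, (0.90, 0.95), (0.95, 0.90)}
#'   \item{2.2}{high prevalence, small sample, low accuracy:
#'     pi = 0.40, n = 200, (0.60, 0.70), (0.70, 0.60)}
#'   \item{dep}{moderate values for the dependence-misspecification study:
#'     pi = 0.10, n = 2000, (0.70, 0.80), (0.80, 0.70)}
#' }
#' The \code{"indep"} preset is \code{"dep"} with both correlations 0.
#'
#' @param name One of \code{"1.1"}, \code{"1.2"}, \code{"2.1"},
#'   \code{"2.2"}, \code{"dep"}, \code{"indep"}.
#' @return A list with elements \code{name}, \code{params}
#'   (\code{\link{model_params}} including the implied covariances),
#'   \code{n}, \code{rhoDp}, \code{rhoDn}.
#' @export
scenario_preset <- function(name = c("1.1", "1.2", "2.1", "2.2",
                                     "dep", "indep")) {
  name <- match.arg(name)
  tab <- list(
    `1.1` = list(pi = 0.01, n = 20000, se1 = 0.90, sp1 = 0.95,
                 se2 = 0.95, sp2 = 0.90, rhoDp = 0.5, rhoDn = 0.4),
    `1.2` = list(pi = 0.01, n = 20000, se1 = 0.60, sp1 = 0.70,
                 se2 = 0.70, sp2 = 0.60, rhoDp = 0.5, rhoDn = 0.4),
    `2.1` = list(pi = 0.40, n = 200, se1 = 0.90, sp1 = 0.95,
                 se2 = 0.95, sp2 = 0.90, rhoDp = 0.5, rhoDn = 0.4),
    `2.2` = list(pi = 0.40, n = 200, se1 = 0.60, sp1 = 0.70,
                 se2 = 0.70, sp2 = 0.60, rhoDp = 0.5, rhoDn = 0.4),
    dep = list(pi = 0.10, n = 2000, se1 = 0.70, sp1 = 0.80,
               se2 = 0.80, sp2 = 0.70, rhoDp = 0.5, rhoDn = 0.4),
    indep = list(pi = 0.10, n = 2000, se1 = 0.70, sp1 = 0.80,
                 se2 = 0.80, sp2 = 0.70, rhoDp = 0, rhoDn = 0))
  s <- tab[[name]]
  cv <- correlations_to_covariances(s$rhoDp, s$rhoDn,
                                    s$se1, s$se2, s$sp1, s$sp2)
  list(name = name,
       params = model_params(pi = s$pi, se1 = s$se1, se2 = s$se2,
                             sp1 = s$sp1, sp2 = s$sp2,
                             covDp = cv[["covDp"]], covDn = cv[["covDn"]]),
       n = s$n, rhoDp = s$rhoDp, rhoDn = s$rhoDn)
}

#' Run a simulation scenario
#'
#' Simulates \code{replicates} datasets from a scenario's true parameters,
#' fits the model to each under the requested prior mode and model variant,
#' and reports per-replicate posterior medians, 95\% credible intervals,
#' pD and DIC, plus aggregate coverage of the true values.
#'
#' @param scenario A preset from \code{\link{scenario_preset}}, or any list
#'   with elements \code{params} and \code{n}.
#' @param mcmc An \code{\link{mcmc_config}}; its seed controls both data
#'   simulation and fitting (replicate r uses derived seeds).
#' @param prior_mode Prior mode passed to \code{\link{scenario_priors}}.
#' @param dependence Model variant to fit.
#' @param replicates Number of simulated datasets.
#' @return List with \code{results} (one row per replicate: medians,
#'   interval bounds, pD, DIC, convergence flag), \code{coverage} (named
#'   per-parameter coverage proportions of the true values by the 95\%
#'   intervals), \code{mean_pD}, \code{mean_DIC}, and the scenario.
#' @export
run_scenario <- function(scenario, mcmc = mcmc_config(n_iterations = 20000,
                                                      n_burnin = 2000),
                         prior_mode = "se2step", dependence = TRUE,
                         replicates = 20) {
  stopifnot(replicates >= 1)
  truth <- scenario$params
  spec <- scenario_priors(truth, prior_mode, dependence = dependence)
  pars <- base_param_names()
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    seed_r <- mcmc$seed + 7919L * r
    set.seed(seed_r)
    counts <- simulate_counts(truth, scenario$n)
    cfg <- mcmc_config(n_chains = mcmc$n_chains,
                       n_iterations = mcmc$n_iterations,
                       n_burnin = mcmc$n_burnin,
                       thinning = mcmc$thinning, seed = seed_r)
    fit <- withCallingHandlers(
      fit_screening(counts, spec, cfg),
      warning = function(w) invokeRestart("muffleWarning"))
    sm <- posterior_summary(fit)
    dev <- deviance_summaries(fit, counts)
    row <- data.frame(replicate = r, seed = seed_r)
    for (nm in pars) {
      i <- match(nm, sm$parameter)
      row[[paste0(nm, "_median")]] <- sm$median[i]
      row[[paste0(nm, "_lower")]] <- sm$lower[i]
      row[[paste0(nm, "_upper")]] <- sm$upper[i]
      row[[paste0(nm, "_covered")]] <-
        truth[[nm]] >= sm$lower[i] && truth[[nm]] <= sm$upper[i]
    }
    row$pD <- dev$pD
    row$DIC <- dev$DIC
    row$converged <- is.null(attr(fit, "convergence_warning"))
    rows[[r]] <- row
  }
  results <- do.call(rbind, rows)
  coverage <- vapply(pars, function(nm)
    mean(results[[paste0(nm, "_covered")]]), numeric(1))
  list(scenario = scenario, prior_mode = prior_mode,
       dependence = dependence, results = results, coverage = coverage,
       mean_pD = mean(results$pD), mean_DIC = mean(results$DIC))
}

#' Read a simulation scenario from YAML or JSON
#'
#' A scenario file names the true parameter values, the conditional
#' correlations and the sample size, e.g.
#' \preformatted{
#' pi: 0.4
#' se1: 0.9
#' se2: 0.95
#' sp1: 0.95
#' sp2: 0.90
#' rhoDp: 0.5
#' rhoDn: 0.4
#' n: 200
#' }
#'
#' @param path File path; \code{.json} selects JSON, anything else YAML.
#' @return A scenario list as returned by \code{\link{scenario_preset}}.
#' @export
read_scenario <- function(path) {
  rec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("pi", "se1", "se2", "sp1", "sp2", "n")
  missing <- setdiff(need, names(rec))
  if (length(missing))
    stop("scenario file is missing fields: ", paste(missing, collapse = ", "))
  rhoDp <- if (is.null(rec$rhoDp)) 0 else rec$rhoDp
  rhoDn <- if (is.null(rec$rhoDn)) 0 else rec$rhoDn
  cv <- correlations_to_covariances(rhoDp, rhoDn, rec$se1, rec$se2,
                                    rec$sp1, rec$sp2)
  list(name = if (is.null(rec$name)) basename(path) else rec$name,
       params = model_params(pi = rec$pi, se1 = rec$se1, se2 = rec$se2,
                             sp1 = rec$sp1, sp2 = rec$sp2,
                             covDp = cv[["covDp"]], covDn = cv[["covDn"]]),
       n = rec$n, rhoDp = rhoDp, rhoDn = rhoDn)
}
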