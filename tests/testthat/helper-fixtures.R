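# shared fixtures: random valid parameter draws and a small fit

flat_spec <- function(dependence = TRUE) prior_spec(dependence = dependence)

random_params <- function(n, seed = 42) {
  set.seed(seed)
  sample_prior(flat_spec(), n = n)
}

row_params <- function(d, i) {
  model_params(pi = d$pi[i], se1 = d$se1[i], se2 = d$se2[i],
               sp1 = d$sp1[i], sp2 = d$sp2[i],
               covDp = d$covDp[i], covDn = d$covDn[i])
}

quick_config <- function(seed = 1, n_chains = 2, n_iterations = 8000,
                         n_burnin = 2000) {
  mcmc_config(n_chains = n_chains, n_iterations = n_iterations,
              n_burnin = n_burnin, seed = seed)
}

# synthetic draws object at fixed parameters (point-mass posterior)
point_mass_draws <- function(params, counts, n_rows = 500,
                             spec = flat_spec()) {
  ll <- log_likelihood(counts, params)
  d <- data.frame(chain = 1L, pi = params$pi, se1 = params$se1,
                  se2 = params$se2, sp1 = params$sp1, sp2 = params$sp2,
                  covDp = params$covDp, covDn = params$covDn,
                  b_pi = NA_real_, b_se1 = NA_real_, b_se2 = NA_real_,
                  b_sp1 = NA_real_, b_sp2 = NA_real_,
                  loglik = ll)[rep(1, n_rows), ]
  ja <- joint_accuracy(params)
  pc <- ppv_and_correlations(params)
  d$seJE <- ja[["seJE"]]; d$spJE <- ja[["spJE"]]
  d$ppvJE <- pc[["ppvJE"]]; d$rhoDp <- pc[["rhoDp"]]; d$rhoDn <- pc[["rhoDn"]]
  rownames(d) <- NULL
  class(d) <- c("screening_draws", "data.frame")
  attr(d, "counts") <- counts
  attr(d, "prior_spec") <- spec
  attr(d, "factorization") <- "two-multinomial"
  d
}
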