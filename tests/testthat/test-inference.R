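test_that("identical config and seed give identical draws", {
  counts <- screening_counts(20, 12, 15, 153, 18, 29)
  spec <- flat_spec()
  cfg <- mcmc_config(n_chains = 1, n_iterations = 3000, n_burnin = 500,
                     seed = 5)
  f1 <- fit_screening(counts, spec, cfg)
  f2 <- fit_screening(counts, spec, cfg)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
})

test_that("stored per-draw log-likelihoods match the R evaluation", {
  counts <- colorectal_counts()
  fit <- fit_screening(counts, colorectal_priors(),
                       quick_config(n_chains = 1, n_iterations = 3000,
                                    n_burnin = 1000))
  idx <- seq(1, nrow(fit), length.out = 25)
  for (i in round(idx))
    expect_equal(fit$loglik[i], log_likelihood(counts, row_params(fit, i)),
                 tolerance = 1e-9)
})

test_that("with empty data the posterior reproduces the prior", {
  empty <- screening_counts(0, 0, 0, 0, 0, 0)
  spec <- prior_spec(se1 = two_step_prior(0.5, 0.55, 0.99))
  fit <- fit_screening(empty, spec,
                       mcmc_config(n_chains = 2, n_iterations = 22000,
                                   n_burnin = 2000, seed = 2))
  set.seed(31)
  prior <- sample_prior(spec, n = 40000)
  qs <- seq(0.1, 0.9, by = 0.1)
  for (nm in c("pi", "se1", "sp1", "covDn")) {
    expect_lt(max(abs(stats::quantile(fit[[nm]], qs) -
                      stats::quantile(prior[[nm]], qs))), 0.025)
  }
})

test_that("an identified toy posterior matches a quadrature oracle", {
  # accuracies pinned by near-degenerate priors; only prevalence is free,
  # so the exact posterior is a one-dimensional normalized likelihood
  se0 <- c(0.85, 0.90); sp0 <- c(0.92, 0.88)
  w <- 1e-4
  spec <- prior_spec(pi = uniform_prior(0, 1),
                     se1 = uniform_prior(se0[1] - w, se0[1] + w),
                     se2 = uniform_prior(se0[2] - w, se0[2] + w),
                     sp1 = uniform_prior(sp0[1] - w, sp0[1] + w),
                     sp2 = uniform_prior(sp0[2] - w, sp0[2] + w),
                     dependence = FALSE)
  set.seed(17)
  truth <- model_params(0.3, se0[1], se0[2], sp0[1], sp0[2])
  counts <- simulate_counts(truth, 2000)
  fit <- fit_screening(counts, spec,
                       mcmc_config(n_chains = 2, n_iterations = 32000,
                                   n_burnin = 12000, seed = 4))

  # independent oracle: direct multinomial masses on a prevalence grid
  grid <- seq(1e-6, 1 - 1e-6, length.out = 20000)
  px <- function(pi) cbind(
    pi * se0[1] * se0[2] + (1 - pi) * (1 - sp0[1]) * (1 - sp0[2]),
    pi * se0[1] * (1 - se0[2]) + (1 - pi) * (1 - sp0[1]) * sp0[2],
    pi * (1 - se0[1]) * se0[2] + (1 - pi) * sp0[1] * (1 - sp0[2]),
    pi * (1 - se0[1]) * (1 - se0[2]) + (1 - pi) * sp0[1] * sp0[2])
  seJE <- se0[1] + se0[2] - se0[1] * se0[2]
  spJE <- sp0[1] * sp0[2]
  x <- c(counts$x11, counts$x10, counts$x01, counts$x00)
  a <- c(counts$a11, counts$a10, counts$a0)
  lpx <- log(px(grid))
  lpa <- log(cbind(grid * seJE, (1 - grid) * (1 - spJE),
                   grid * (1 - seJE) + (1 - grid) * spJE))
  ll <- lpx %*% x + lpa %*% a
  post <- exp(ll - max(ll)); post <- post / sum(post)
  cdf <- cumsum(post)
  oracle_q <- function(q) grid[which.max(cdf >= q)]
  for (q in c(0.25, 0.5, 0.75))
    expect_equal(unname(stats::quantile(fit$pi, q)), oracle_q(q),
                 tolerance = 0.01)
})

test_that("summary percentiles agree with direct recomputation and ordering", {
  counts <- screening_counts(20, 12, 15, 153, 18, 29)
  fit <- fit_screening(counts, flat_spec(),
                       quick_config(seed = 3, n_chains = 2,
                                    n_iterations = 5000, n_burnin = 1000))
  sm <- posterior_summary(fit)
  expect_true(all(sm$lower <= sm$median & sm$median <= sm$upper))
  i <- match("seJE", sm$parameter)
  expect_equal(sm$median[i], unname(stats::quantile(fit$seJE, 0.5)))
  expect_equal(sm$lower[i], unname(stats::quantile(fit$seJE, 0.025)))
  expect_equal(sm$upper[i], unname(stats::quantile(fit$seJE, 0.975)))
  # derived quantities are summarized per draw, not recomputed from medians
  j <- match("se1", sm$parameter)
  expect_false(isTRUE(all.equal(
    sm$median[i],
    sm$median[j] + sm$median[match("se2", sm$parameter)] -
      sm$median[j] * sm$median[match("se2", sm$parameter)] -
      sm$median[match("covDp", sm$parameter)])))
})

test_that("diagnostics behave on known chains", {
  # two identical independent-draw chains: potential scale reduction ~ 1
  set.seed(40)
  m <- 5000
  base <- data.frame(chain = 1L, pi = stats::runif(m),
                     se1 = stats::runif(m), se2 = stats::runif(m),
                     sp1 = stats::runif(m), sp2 = stats::runif(m),
                     covDp = stats::runif(m, 0, 0.1),
                     covDn = stats::runif(m, 0, 0.1))
  doubled <- rbind(base, transform(base, chain = 2L))
  class(doubled) <- c("screening_draws", "data.frame")
  attr(doubled, "prior_spec") <- flat_spec()
  diag <- convergence_diagnostics(doubled)
  expect_true(all(abs(diag$rhat - 1) < 0.01))

  # white-noise chains: effective sample size near the chain length
  set.seed(44)
  ess <- dualscreen:::ess_ipse(stats::rnorm(20000))
  expect_gt(ess, 20000 * 0.8)
  expect_lt(ess, 20000 * 1.2)
})

test_that("non-convergence attaches a warning rather than failing", {
  # absurdly short run from dispersed starts on weakly identified data
  counts <- colorectal_counts()
  expect_warning(
    fit <- fit_screening(counts, colorectal_priors(),
                         mcmc_config(n_chains = 3, n_iterations = 60,
                                     n_burnin = 10, seed = 10)),
    "scale reduction")
  expect_true(!is.null(attr(fit, "convergence_warning")))
})
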