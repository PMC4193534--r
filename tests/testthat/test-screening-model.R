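# scenario with rhoD+ = 0.5, rhoD- = 0.4 at high accuracy; the covariances
# below were derived by hand from cov = rho * sqrt(p1(1-p1)p2(1-p2))
sc21_params <- function() {
  model_params(pi = 0.4, se1 = 0.9, se2 = 0.95, sp1 = 0.95, sp2 = 0.90,
               covDp = 0.0326917, covDn = 0.0261534)
}

test_that("stage-one cell probabilities match hand arithmetic", {
  perfect <- model_params(pi = 0.3, se1 = 1, se2 = 1, sp1 = 1, sp2 = 1)
  expect_equal(stage_one_cell_probs(perfect),
               c(px11 = 0.3, px10 = 0, px01 = 0, px00 = 0.7))

  # frozen from the four cell formulas evaluated by hand
  expect_equal(stage_one_cell_probs(sc21_params()),
               c(px11 = 0.37376872, px10 = 0.01623128,
                 px01 = 0.06623128, px00 = 0.54376872),
               tolerance = 1e-10)
})

test_that("covariances outside the feasibility bound are rejected by name", {
  expect_error(model_params(0.3, 0.9, 0.95, 0.95, 0.9, covDp = 0.05),
               "covDp.*min\\(se1,se2\\)")
  expect_error(model_params(0.3, 0.9, 0.95, 0.95, 0.9, covDn = 0.06),
               "covDn.*min\\(sp1,sp2\\)")
})

test_that("cell probability vectors are normalized and nonnegative over random draws", {
  d <- random_params(10000)
  px <- cbind(
    d$pi * (d$se1 * d$se2 + d$covDp) +
      (1 - d$pi) * ((1 - d$sp1) * (1 - d$sp2) + d$covDn),
    d$pi * (d$se1 * (1 - d$se2) - d$covDp) +
      (1 - d$pi) * ((1 - d$sp1) * d$sp2 - d$covDn),
    d$pi * ((1 - d$se1) * d$se2 - d$covDp) +
      (1 - d$pi) * (d$sp1 * (1 - d$sp2) - d$covDn),
    d$pi * ((1 - d$se1) * (1 - d$se2) + d$covDp) +
      (1 - d$pi) * (d$sp1 * d$sp2 + d$covDn))
  expect_true(all(abs(rowSums(px) - 1) < 1e-12))
  expect_true(all(px > -1e-15))
  # spot-check the vectorized oracle against the package on a subsample
  for (i in seq(1, 10000, by = 997)) {
    p <- stage_one_cell_probs(row_params(d, i))
    expect_equal(unname(p), unname(px[i, ]), tolerance = 1e-12)
    pa <- stage_two_cell_probs(row_params(d, i))
    expect_equal(sum(pa), 1, tolerance = 1e-12)
    # the unverified stage-two mass is exactly the double-negative mass
    expect_equal(pa[["pa0"]], p[["px00"]], tolerance = 1e-12)
  }
})

test_that("joint accuracy follows the either-positive formulas", {
  expect_equal(
    joint_accuracy(model_params(0.5, 0.5, 0.5, 0.5, 0.5))[["seJE"]], 0.75)
  expect_equal(joint_accuracy(sc21_params()),
               c(seJE = 0.9623083, spJE = 0.8811534), tolerance = 1e-10)
  # dependence raises seJE less than independence would
  d <- random_params(200, seed = 11)
  seJE <- d$se1 + d$se2 - (d$se1 * d$se2 + d$covDp)
  spJE <- d$sp1 * d$sp2 + d$covDn
  expect_true(all(seJE >= pmax(d$se1, d$se2) - 1e-12))
  expect_true(all(spJE <= pmin(d$sp1, d$sp2) + 1e-12))
})

test_that("sequential accuracy composes the screen with the gold standard", {
  expect_equal(sequential_accuracy(0.8, 0.9), c(seJB = 0.8, spJB = 1.0))
  expect_equal(sequential_accuracy(0.8, 0.9, seGS = 0.9, spGS = 0.8),
               c(seJB = 0.72, spJB = 0.98))
  expect_equal(sequential_accuracy(0.37, 0.4, 1, 1)[["seJB"]], 0.37)
})

test_that("stage-two cell probabilities match hand arithmetic", {
  # params engineered so seJE = 0.8103 and spJE = 0.9405
  p <- model_params(pi = 0.0065, se1 = 0.604, se2 = 0.6825,
                    sp1 = 0.9812, sp2 = 0.9559,
                    covDp = 0.60400 + 0.6825 - 0.604 * 0.6825 - 0.8103,
                    covDn = 0.9405 - 0.9812 * 0.9559)
  expect_equal(stage_two_cell_probs(p),
               c(pa11 = 0.00526695, pa10 = 0.05911325, pa0 = 0.9356198),
               tolerance = 1e-8)
  perfect <- model_params(0.3, 1, 1, 1, 1)
  expect_equal(stage_two_cell_probs(perfect),
               c(pa11 = 0.3, pa10 = 0, pa0 = 0.7))
})

test_that("PPV and conditional correlations behave and round-trip", {
  ind <- model_params(0.2, 0.8, 0.7, 0.9, 0.85)
  expect_equal(unname(ppv_and_correlations(ind)[c("rhoDp", "rhoDn")]),
               c(0, 0))
  # round-trip: the scenario covariances reproduce rho = 0.5 / 0.4
  rho <- ppv_and_correlations(sc21_params())
  expect_equal(rho[["rhoDp"]], 0.5, tolerance = 1e-5)
  expect_equal(rho[["rhoDn"]], 0.4, tolerance = 1e-5)
  # boundary accuracy yields an undefined-marker, not an error
  expect_true(is.nan(
    ppv_and_correlations(model_params(0.3, 1, 0.9, 0.8, 0.8))[["rhoDp"]]))
})

test_that("log-likelihood agrees with an independent multinomial-mass oracle", {
  counts_list <- list(colorectal_counts(),
                      screening_counts(10, 5, 7, 78, 9, 13))
  d <- random_params(100, seed = 3)
  for (counts in counts_list) {
    x <- c(counts$x11, counts$x10, counts$x01, counts$x00)
    a <- c(counts$a11, counts$a10, counts$a0)
    for (i in seq_len(50)) {
      p <- row_params(d, i)
      px <- c(p$pi * (p$se1 * p$se2 + p$covDp) +
                (1 - p$pi) * ((1 - p$sp1) * (1 - p$sp2) + p$covDn),
              p$pi * (p$se1 * (1 - p$se2) - p$covDp) +
                (1 - p$pi) * ((1 - p$sp1) * p$sp2 - p$covDn),
              p$pi * ((1 - p$se1) * p$se2 - p$covDp) +
                (1 - p$pi) * (p$sp1 * (1 - p$sp2) - p$covDn),
              p$pi * ((1 - p$se1) * (1 - p$se2) + p$covDp) +
                (1 - p$pi) * (p$sp1 * p$sp2 + p$covDn))
      seJE <- p$se1 + p$se2 - (p$se1 * p$se2 + p$covDp)
      spJE <- p$sp1 * p$sp2 + p$covDn
      pa <- c(p$pi * seJE, (1 - p$pi) * (1 - spJE),
              p$pi * (1 - seJE) + (1 - p$pi) * spJE)
      # direct log-gamma multinomial masses, written out independently
      oracle <- lgamma(sum(x) + 1) - sum(lgamma(x + 1)) + sum(x * log(px)) +
        lgamma(sum(a) + 1) - sum(lgamma(a + 1)) + sum(a * log(pa))
      expect_equal(log_likelihood(counts, p), oracle, tolerance = 1e-9)
    }
  }
})

test_that("log-likelihood degenerate and nested cases", {
  # all mass in one observed cell with probability ~1 gives ~log(1) = 0
  counts <- screening_counts(0, 0, 0, 100, 0, 0)
  near_perfect <- model_params(1e-12, 0.5, 0.5, 1 - 1e-12, 1 - 1e-12)
  expect_equal(log_likelihood(counts, near_perfect), 0, tolerance = 1e-6)

  # a zero-probability cell with a positive count gives -Inf
  some <- screening_counts(5, 2, 3, 90, 4, 6)
  expect_identical(log_likelihood(some, model_params(0.3, 1, 1, 1, 1)), -Inf)

  # with zero covariances the dependent likelihood equals the
  # independence-model likelihood at the same accuracies
  ind <- model_params(0.13, 0.81, 0.77, 0.92, 0.88)
  dep0 <- model_params(0.13, 0.81, 0.77, 0.92, 0.88, covDp = 0, covDn = 0)
  expect_identical(log_likelihood(some, ind), log_likelihood(some, dep0))
})

test_that("the exact factorization differs only by the stage-two margin", {
  counts <- colorectal_counts()
  p <- model_params(0.0065, 0.604, 0.6825, 0.9812, 0.9559,
                    covDp = 0.03, covDn = 0.002)
  pa <- stage_two_cell_probs(p)
  # two-multinomial = exact + multinomial mass of the (positives, negatives)
  # margin, by the multinomial splitting property
  margin <- lgamma(counts$n + 1) -
    lgamma(counts$a11 + counts$a10 + 1) - lgamma(counts$a0 + 1) +
    (counts$a11 + counts$a10) * log(pa[["pa11"]] + pa[["pa10"]]) +
    counts$a0 * log(pa[["pa0"]])
  expect_equal(log_likelihood(counts, p),
               log_likelihood(counts, p, factorization = "exact") + margin,
               tolerance = 1e-9)
})
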