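#' Uniform and two-step hierarchical uniform priors
#'
#' \code{uniform_prior(lower, upper)} is a flat prior on a fixed interval.
#' \code{two_step_prior(lower, upper_hyper_lower, upper_hyper_upper)} is the
#' hierarchical construction used for sensitivities: the parameter is
#' uniform on \code{(lower, b)} where the upper bound \code{b} is itself
#' uniform on \code{(upper_hyper_lower, upper_hyper_upper)}. A securely
#' known lower bound is stated directly, while the risky choice of an upper
#' bound is diffused over a hyperprior.
#'
#' @param lower Lower bound (securely elicited).
#' @param upper Upper bound of a flat prior.
#' @param upper_hyper_lower,upper_hyper_upper Range of the uniform
#'   hyperprior on the latent upper bound.
#' @return An object of class \code{uniform_prior} or
#'   \code{two_step_prior}.
#' @examples
#' uniform_prior(0, 1)
#' two_step_prior(0.5, 0.55, 0.99)
#' @export
uniform_prior <- function(lower, upper) {
  if (!(lower < upper)) stop("uniform prior requires lower < upper")
  structure(list(lower = lower, upper = upper), class = "uniform_prior")
}

#' @rdname uniform_prior
#' @export
two_step_prior <- function(lower, upper_hyper_lower, upper_hyper_upper) {
  if (!(lower < upper_hyper_lower && upper_hyper_lower < upper_hyper_upper))
    stop("two-step prior requires lower < upper_hyper_lower < upper_hyper_upper")
  if (upper_hyper_upper > 1)
    stop("two-step prior upper hyperbound must be <= 1 for probabilities")
  structure(list(lower = lower,
                 upper_hyper_lower = upper_hyper_lower,
                 upper_hyper_upper = upper_hyper_upper),
            class = "two_step_prior")
}

#' @export
print.uniform_prior <- function(x, ...) {
  cat(sprintf("U(%g, %g)\n", x$lower, x$upper)); invisible(x)
}

#' @export
print.two_step_prior <- function(x, ...) {
  cat(sprintf("U(%g, b), b ~ U(%g, %g)\n",
              x$lower, x$upper_hyper_lower, x$upper_hyper_upper))
  invisible(x)
}

#' Full prior specification of the two-stage model
#'
#' Collects one prior per base parameter (\code{pi}, \code{se1}, \code{se2},
#' \code{sp1}, \code{sp2}), each a \code{\link{uniform_prior}} or
#' \code{\link{two_step_prior}}. Under the dependent model
#' (\code{dependence = TRUE}) the conditional covariances get conditionally
#' uniform priors over their feasibility ranges
#' \code{(0, min(se1,se2) - se1*se2)} and \code{(0, min(sp1,sp2) - sp1*sp2)}
#' given the current accuracies; the independence variant fixes both
#' covariances at 0.
#'
#' @param pi,se1,se2,sp1,sp2 Priors for the base parameters.
#' @param dependence Logical; fit the conditionally dependent model?
#' @return An object of class \code{prior_spec}.
#' @examples
#' colorectal_priors()
#' @export
prior_spec <- function(pi = uniform_prior(0, 1),
                       se1 = uniform_prior(0, 1),
                       se2 = uniform_prior(0, 1),
                       sp1 = uniform_prior(0, 1),
                       sp2 = uniform_prior(0, 1),
                       dependence = TRUE) {
  priors <- list(pi = pi, se1 = se1, se2 = se2, sp1 = sp1, sp2 = sp2)
  ok <- vapply(priors, inherits, logical(1),
               what = c("uniform_prior", "two_step_prior"))
  if (!all(ok))
    stop("each prior must be a uniform_prior or two_step_prior")
  structure(c(priors, list(dependence = isTRUE(dependence))),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("prior specification (",
      if (x$dependence) "dependent" else "independence", " model):\n", sep = "")
  for (nm in base_param_names()) {
    cat("  ", format(nm, width = 4), "~ ")
    print(x[[nm]])
  }
  if (x$dependence)
    cat("  covDp, covDn ~ U(0, feasible bound | accuracies)\n")
  invisible(x)
}

base_param_names <- function() c("pi", "se1", "se2", "sp1", "sp2")

#' Priors used for the colorectal worked example
#'
#' Two-step hierarchical uniform priors on the sensitivities with elicited
#' lower bounds 0.5 (rehydrated Hemoccult) and 0.6 (RPHA-Hemeselect) and
#' diffuse upper-bound hyperpriors, flat U(0,1) priors on the specificities
#' and the prevalence, and conditionally uniform covariance priors.
#'
#' @return A \code{\link{prior_spec}}.
#' @export
colorectal_priors <- function() {
  prior_spec(se1 = two_step_prior(0.5, 0.55, 0.99),
             se2 = two_step_prior(0.6, 0.65, 0.99),
             dependence = TRUE)
}

#' Sample model parameters from the prior
#'
#' Draws each base parameter from its prior (for two-step priors the latent
#' upper bound is drawn first, then the parameter uniformly on
#' \code{(lower, b)}), then draws the covariances uniformly on their
#' feasibility ranges given the drawn accuracies, so every draw satisfies
#' the model constraints by construction.
#'
#' @param spec A \code{\link{prior_spec}}.
#' @param n Number of draws.
#' @return For \code{n = 1} a list with elements \code{params}
#'   (\code{\link{model_params}}) and \code{bounds} (named vector of latent
#'   upper bounds, \code{NA} for parameters without a two-step prior); for
#'   \code{n > 1} a data frame with one row per draw.
#' @examples
#' set.seed(1)
#' sample_prior(colorectal_priors())
#' @export
sample_prior <- function(spec, n = 1) {
  stopifnot(inherits(spec, "prior_spec"), n >= 1)
  draw1 <- function() {
    th <- numeric(5); names(th) <- base_param_names()
    bd <- rep(NA_real_, 5); names(bd) <- base_param_names()
    for (nm in base_param_names()) {
      pr <- spec[[nm]]
      if (inherits(pr, "two_step_prior")) {
        b <- stats::runif(1, pr$upper_hyper_lower, pr$upper_hyper_upper)
        bd[nm] <- b
        th[nm] <- stats::runif(1, pr$lower, b)
      } else {
        th[nm] <- stats::runif(1, pr$lower, pr$upper)
      }
    }
    covDp <- covDn <- 0
    if (spec$dependence) {
      covDp <- stats::runif(1, 0, cov_bound(th["se1"], th["se2"]))
      covDn <- stats::runif(1, 0, cov_bound(th["sp1"], th["sp2"]))
    }
    c(th, covDp = unname(covDp), covDn = unname(covDn), bd)
  }
  if (n == 1) {
    d <- draw1()
    list(params = model_params(pi = d[["pi"]], se1 = d[["se1"]],
                               se2 = d[["se2"]], sp1 = d[["sp1"]],
                               sp2 = d[["sp2"]], covDp = d[["covDp"]],
                               covDn = d[["covDn"]]),
         bounds = d[8:12])
  } else {
    m <- t(vapply(seq_len(n), function(i) draw1(), numeric(12)))
    colnames(m) <- c(base_param_names(), "covDp", "covDn",
                     paste0("b_", base_param_names()))
    as.data.frame(m)
  }
}

#' Joint log prior density
#'
#' Evaluates the log density of the joint prior over the base parameters,
#' their latent upper bounds (for two-step priors) and, under the dependent
#' model, the covariances, whose conditionally uniform priors contribute the
#' range-dependent normalization \code{-log(bound)} at the current
#' accuracies. Returns \code{-Inf} outside the support; out-of-support is a
#' value, not an error.
#'
#' @param params A \code{\link{model_params}}.
#' @param bounds Named vector of latent upper bounds as returned by
#'   \code{\link{sample_prior}} (only entries for two-step priors are used).
#' @param spec A \code{\link{prior_spec}}.
#' @return Log density (finite or \code{-Inf}).
#' @export
log_prior_density <- function(params, bounds = NULL, spec) {
  stopifnot(inherits(params, "model_params"), inherits(spec, "prior_spec"))
  lp <- 0
  for (nm in base_param_names()) {
    pr <- spec[[nm]]
    th <- params[[nm]]
    if (inherits(pr, "two_step_prior")) {
      b <- bounds[[nm]]
      if (is.null(b) || is.na(b))
        stop("two-step prior on ", nm, " requires its latent upper bound")
      if (b <= pr$upper_hyper_lower || b >= pr$upper_hyper_upper ||
          th <= pr$lower || th >= b)
        return(-Inf)
      lp <- lp - log(pr$upper_hyper_upper - pr$upper_hyper_lower) - log(b - pr$lower)
    } else {
      if (th <= pr$lower || th >= pr$upper) return(-Inf)
      lp <- lp - log(pr$upper - pr$lower)
    }
  }
  if (spec$dependence) {
    bDp <- cov_bound(params$se1, params$se2)
    bDn <- cov_bound(params$sp1, params$sp2)
    if (params$covDp < 0 || params$covDp > bDp ||
        params$covDn < 0 || params$covDn > bDn) return(-Inf)
    lp <- lp - log(bDp) - log(bDn)
  } else if (params$covDp != 0 || params$covDn != 0) {
    return(-Inf)
  }
  lp
}

#' Read and write prior specifications
#'
#' Priors are serialized as YAML or JSON, one entry per parameter, e.g.
#' \preformatted{
#' se1: {type: two_step_uniform, lower: 0.5, upper_hyper: [0.55, 0.99]}
#' sp1: {type: uniform, lower: 0, upper: 1}
#' dependence: true
#' }
#'
#' @param path File path; \code{.json} selects JSON, anything else YAML.
#' @return \code{read_prior_spec} returns a \code{\link{prior_spec}};
#'   \code{write_prior_spec} returns \code{path} invisibly.
#' @export
read_prior_spec <- function(path) {
  rec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  parse1 <- function(e, nm) {
    if (is.null(e)) return(uniform_prior(0, 1))
    type <- if (is.null(e$type)) "uniform" else e$type
    if (type == "uniform") {
      uniform_prior(e$lower, e$upper)
    } else if (type == "two_step_uniform") {
      hy <- unlist(e$upper_hyper)
      two_step_prior(e$lower, hy[1], hy[2])
    } else stop("unknown prior type for ", nm, ": ", type)
  }
  prior_spec(pi = parse1(rec$pi, "pi"),
             se1 = parse1(rec$se1, "se1"), se2 = parse1(rec$se2, "se2"),
             sp1 = parse1(rec$sp1, "sp1"), sp2 = parse1(rec$sp2, "sp2"),
             dependence = if (is.null(rec$dependence)) TRUE else rec$dependence)
}

#' @rdname read_prior_spec
#' @param spec A \code{\link{prior_spec}}.
#' @export
write_prior_spec <- function(spec, path) {
  stopifnot(inherits(spec, "prior_spec"))
  enc1 <- function(pr) {
    if (inherits(pr, "two_step_prior")) {
      list(type = "two_step_uniform", lower = pr$lower,
           upper_hyper = c(pr$upper_hyper_lower, pr$upper_hyper_upper))
    } else {
      list(type = "uniform", lower = pr$lower, upper = pr$upper)
    }
  }
  rec <- c(lapply(spec[base_param_names()], enc1),
           list(dependence = spec$dependence))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(rec, path, auto_unbox = TRUE)
  } else {
    yaml::write_yaml(rec, path)
  }
  invisible(path)
}

#' Simulation-study prior modes
#'
#' Builds the prior specification used in the simulation scenarios from the
#' true parameter values and a prior mode: \code{"model"} centers an
#' informative uniform at every true value; \code{"se"} does so for the
#' sensitivities only; \code{"se2step"} gives the sensitivities two-step
#' hierarchical priors anchored at the informative lower bound with a
#' diffuse upper-bound hyperprior; \code{"sp"} centers informative uniforms
#' on the specificities only. Parameters without an informative prior get
#' U(0,1). The informative ranges are keyed to the canonical true values
#' (Se/Sp in 0.6, 0.7, 0.8, 0.9, 0.95; prevalence in 0.4, 0.1, 0.01).
#'
#' @param params True \code{\link{model_params}} of the scenario.
#' @param mode One of \code{"model"}, \code{"se"}, \code{"se2step"},
#'   \code{"sp"}.
#' @param dependence Logical; dependent or independence model variant.
#' @return A \code{\link{prior_spec}}.
#' @examples
#' scenario_priors(scenario_preset("2.1")$params, "se2step")
#' @export
scenario_priors <- function(params, mode = c("model", "se", "se2step", "sp"),
                            dependence = TRUE) {
  stopifnot(inherits(params, "model_params"))
  mode <- match.arg(mode)
  acc_inf <- list(`0.6` = c(0.5, 0.7), `0.7` = c(0.6, 0.8),
                  `0.8` = c(0.7, 0.9), `0.9` = c(0.85, 0.95),
                  `0.95` = c(0.9, 0.99))
  acc_2step <- list(`0.6` = c(0.5, 0.55, 0.99), `0.7` = c(0.6, 0.65, 0.99),
                    `0.8` = c(0.7, 0.75, 0.99), `0.9` = c(0.85, 0.9, 0.99),
                    `0.95` = c(0.9, 0.95, 0.99))
  pi_inf <- list(`0.4` = c(0.3, 0.5), `0.1` = c(0.05, 0.15),
                 `0.01` = c(0.005, 0.015))
  lookup <- function(tab, value, what) {
    key <- as.character(value)
    if (is.null(tab[[key]]))
      stop("no informative prior range tabulated for ", what, " = ", value)
    tab[[key]]
  }
  inf_unif <- function(value, what) {
    r <- lookup(acc_inf, value, what); uniform_prior(r[1], r[2])
  }
  twostep <- function(value, what) {
    r <- lookup(acc_2step, value, what); two_step_prior(r[1], r[2], r[3])
  }
  flat <- uniform_prior(0, 1)
  se_pr <- switch(mode,
    model = , se = list(inf_unif(params$se1, "Se"), inf_unif(params$se2, "Se")),
    se2step = list(twostep(params$se1, "Se"), twostep(params$se2, "Se")),
    sp = list(flat, flat))
  sp_pr <- switch(mode,
    model = , sp = list(inf_unif(params$sp1, "Sp"), inf_unif(params$sp2, "Sp")),
    se = , se2step = list(flat, flat))
  pi_pr <- if (mode == "model") {
    r <- lookup(pi_inf, params$pi, "prevalence"); uniform_prior(r[1], r[2])
  } else flat
  prior_spec(pi = pi_pr, se1 = se_pr[[1]], se2 = se_pr[[2]],
             sp1 = sp_pr[[1]], sp2 = sp_pr[[2]], dependence = dependence)
}
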