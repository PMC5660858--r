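#' Default three-factor, six-indicator measurement model
#'
#' The canonical two-indicators-per-factor, three-factor literacy
#' model used throughout the examples and tests.
#'
#' @return An `mi_model`.
#' @export
default_model <- function() {
  parse_model(c(
    "AlphabetKnowledge =~ Letter_Name + Letter_Sound",
    "PhonologicalAwareness =~ Blending + Elision",
    "Spelling =~ Real_Words + Pseudo_Words"))
}

#' Specify a multi-group simulation design
#'
#' Defines the population of a multi-group common-factor model:
#' per-group intercepts, loadings, factor covariance, error variances
#' and latent means, plus group sizes and a seed.  Defaults emulate
#' the canonical two-group, three-factor, six-indicator setting with
#' group sizes 78 and 174, fully invariant parameters, standardized
#' factors (unit variances, correlation 0.5), marker loadings 1 with
#' secondary loadings 0.8, and error variances 0.5.
#'
#' @param model An `mi_model`; defaults to [default_model()].
#' @param n Integer vector of group sizes.
#' @param lambda_free Value of the non-marker loadings.
#' @param phi Factor covariance matrix (k x k), shared by default.
#' @param psi Error-variance vector (length p) or scalar.
#' @param gamma Intercept vector (length p) or scalar.
#' @param tau List of per-group latent-mean vectors (length k each);
#'   default all zero.
#' @param seed Integer seed driving [simulate_groups].
#' @return An object of class `sim_design`: list with `model`, `n`,
#'   `params` (per-group gamma/lambda/phi/psi/tau) and `seed`.
#' @export
sim_design <- function(model = default_model(), n = c(78, 174),
                       lambda_free = 0.8, phi = NULL, psi = 0.5,
                       gamma = 0, tau = NULL, seed = 1) {
  stopifnot(inherits(model, "mi_model"), all(n > 0))
  m <- length(n)
  pat <- lambda_pattern(model)
  p <- nrow(pat); k <- ncol(pat)
  lambda <- matrix(0, p, k, dimnames = dimnames(pat))
  lambda[pat == 1] <- lambda_free
  lambda[(seq_len(k) - 1) * p + attr(pat, "marker")] <- 1
  if (is.null(phi)) {
    phi <- matrix(0.5, k, k); diag(phi) <- 1
  }
  phi <- as.matrix(phi)
  ev <- eigen((phi + t(phi)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0)
    stop("phi is not positive semidefinite", call. = FALSE)
  psi <- rep_len(psi, p)
  if (any(psi < 0)) stop("psi must be nonnegative", call. = FALSE)
  gamma <- rep_len(gamma, p)
  if (is.null(tau)) tau <- replicate(m, rep(0, k), simplify = FALSE)
  stopifnot(length(tau) == m, all(lengths(tau) == k))
  params <- lapply(seq_len(m), function(j)
    list(gamma = stats::setNames(gamma, model$variables), lambda = lambda,
         phi = phi, psi = stats::setNames(psi, model$variables),
         tau = stats::setNames(tau[[j]], names(model$factors))))
  structure(list(model = model, n = as.integer(n), params = params,
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Generate multi-group data from a simulation design
#'
#' Draws multivariate-normal observations group by group from the
#' design's implied moments, or emits the implied population moments
#' exactly (for noiseless identities).  Fully deterministic given the
#' design's seed.
#'
#' @param design A [sim_design].
#' @param type `"raw"` (data frame with a `group` column),
#'   `"moments"` (list of [group_moments] with unbiased sample
#'   covariances), or `"population"` (list of [group_moments] holding
#'   the exact implied moments, `cov_type = "ml"` so no divisor
#'   rescaling is applied downstream).
#' @return See `type`.
#' @export
simulate_groups <- function(design, type = c("raw", "moments", "population")) {
  type <- match.arg(type)
  stopifnot(inherits(design, "sim_design"))
  m <- length(design$n)
  vars <- design$model$variables
  implied <- lapply(seq_len(m), function(j) implied_moments(design$params, j))
  if (type == "population") {
    return(lapply(seq_len(m), function(j)
      group_moments(paste0("g", j), design$n[j],
                    stats::setNames(implied[[j]]$mu, vars),
                    implied[[j]]$sigma, cov_type = "ml")))
  }
  raw <- withr_seed(design$seed, {
    do.call(rbind, lapply(seq_len(m), function(j) {
      sig <- implied[[j]]$sigma
      ev <- eigen((sig + t(sig)) / 2, symmetric = TRUE)
      rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
      z <- matrix(stats::rnorm(design$n[j] * length(vars)), design$n[j])
      x <- sweep(z %*% rt, 2, implied[[j]]$mu, `+`)
      colnames(x) <- vars
      cbind(as.data.frame(x), group = paste0("g", j))
    }))
  })
  if (type == "raw") raw else moments_from_raw(raw, "group")
}

violation_kinds <- c("loading_shift", "intercept_shift",
                     "specific_mean_shift", "latent_mean_shift")

#' Inject an invariance violation into a design
#'
#' Returns a modified design in which group 2 (and later groups)
#' deviates from group 1 in a single, targeted way:
#' \describe{
#'   \item{loading_shift}{adds `magnitude` to every non-marker loading
#'     of group 2 (breaks metric invariance).}
#'   \item{intercept_shift}{adds `magnitude` to every intercept of
#'     group 2 (breaks scalar invariance).}
#'   \item{specific_mean_shift}{shifts group 2's intercepts along a
#'     unit vector orthogonal to the column space of Lambda, scaled by
#'     `magnitude`: the population latent-mean (kappa) difference
#'     stays 0 while the specific-factor (nu) difference becomes
#'     nonzero.}
#'   \item{latent_mean_shift}{adds `magnitude` to every latent mean of
#'     group 2 (nonzero kappa difference, nu difference unchanged).}
#' }
#'
#' @param design A [sim_design].
#' @param kind One of the kinds above.
#' @param magnitude Shift size; 0 returns the design unchanged.
#' @return A modified [sim_design].
#' @export
make_violation <- function(design, kind, magnitude) {
  stopifnot(inherits(design, "sim_design"))
  kind <- match.arg(kind, violation_kinds)
  if (magnitude == 0) return(design)
  m <- length(design$n)
  if (m < 2) stop("violations need at least 2 groups", call. = FALSE)
  pat <- lambda_pattern(design$model)
  marker <- (seq_len(ncol(pat)) - 1) * nrow(pat) + attr(pat, "marker")
  for (j in 2:m) {
    pj <- design$params[[j]]
    if (kind == "loading_shift") {
      idx <- setdiff(which(pat == 1), marker)
      pj$lambda[idx] <- pj$lambda[idx] + magnitude
    } else if (kind == "intercept_shift") {
      pj$gamma <- pj$gamma + magnitude
    } else if (kind == "specific_mean_shift") {
      q1 <- null_basis(design$params[[1]]$lambda)[, 1]
      pj$gamma <- pj$gamma + magnitude * q1
    } else {
      pj$tau <- pj$tau + magnitude
    }
    design$params[[j]] <- pj
  }
  design
}

#' Calibrate a violation to a target population misfit
#'
#' Finds the shift magnitude at which the population discrepancy
#' (the minimized `F_ml` of the relevant constrained model evaluated
#' at the design's exact population moments) equals `target_fml`:
#' the metric model for `loading_shift`, the scalar model otherwise.
#'
#' @param design A [sim_design].
#' @param kind Violation kind, as in [make_violation].
#' @param target_fml Target population `F_ml` (> 0).
#' @param interval Search interval for the magnitude.
#' @return The calibrated [sim_design], with the magnitude in
#'   `attr(, "magnitude")` and the achieved misfit in
#'   `attr(, "population_fml")`.
#' @export
calibrate_violation <- function(design, kind, target_fml,
                                interval = c(1e-4, 2)) {
  kind <- match.arg(kind, violation_kinds)
  stopifnot(target_fml > 0)
  constraints <- if (kind == "loading_shift") "metric" else "scalar"
  pop_fml <- function(mag) {
    d <- make_violation(design, kind, mag)
    pop <- simulate_groups(d, "population")
    fit_mgcfa(pop, d$model, constraints)$fml
  }
  root <- stats::uniroot(function(mag) pop_fml(mag) - target_fml,
                         interval = interval, tol = 1e-8, extendInt = "upX")
  out <- make_violation(design, kind, root$root)
  attr(out, "magnitude") <- root$root
  attr(out, "population_fml") <- pop_fml(root$root)
  out
}
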