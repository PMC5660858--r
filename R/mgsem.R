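#' Model-implied mean and covariance for one group
#'
#' Computes the implied moments of the common-factor model with mean
#' structure: `mu = gamma + Lambda tau` and
#' `Sigma = Lambda Phi Lambda' + Psi`.
#'
#' @param params An `mi_params` object (see [fit_mgcfa]), or a plain
#'   list of per-group parameter lists each holding `gamma`, `lambda`,
#'   `phi`, `psi` (diagonal vector or matrix), `tau`.
#' @param group Group index.
#' @return List with components `mu` (length p) and `sigma` (p x p,
#'   symmetric).
#' @export
implied_moments <- function(params, group = 1) {
  g <- if (inherits(params, "mi_params")) params$groups[[group]] else params[[group]]
  lambda <- as.matrix(g$lambda)
  phi <- as.matrix(g$phi)
  psi <- if (is.matrix(g$psi)) diag(g$psi) else as.numeric(g$psi)
  sigma <- lambda %*% phi %*% t(lambda)
  diag(sigma) <- diag(sigma) + psi
  sigma <- (sigma + t(sigma)) / 2
  mu <- as.numeric(g$gamma + lambda %*% g$tau)
  names(mu) <- rownames(lambda)
  list(mu = mu, sigma = sigma)
}

# One group's normal-theory ML discrepancy contribution:
#   F_j = log|Sigma| - log|S| + tr(S Sigma^-1) - p + (xbar-mu)' Sigma^-1 (xbar-mu)
# S must already be on the ML (divisor-n) scale. Returns a large finite
# value when Sigma is not positive definite, so optimizers can recover.
fml_group <- function(mu, sigma, xbar, S, logdetS) {
  p <- length(xbar)
  R <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(R)) return(1e12)
  ldet <- 2 * sum(log(diag(R)))
  Sinv <- chol2inv(R)
  d <- xbar - mu
  val <- ldet - logdetS + sum(Sinv * S) - p + drop(crossprod(d, Sinv %*% d))
  if (!is.finite(val)) 1e12 else val
}

#' Multi-group normal-theory ML discrepancy
#'
#' Evaluates `F_ml = sum_j (n_j/N) F_j`, the sample-size-weighted
#' normal-distribution-based discrepancy between the model-implied
#' moments of `params` and the observed moments in `data`.  It is zero
#' exactly when every group's implied moments equal its sample moments.
#'
#' @param params Parameter set as in [implied_moments].
#' @param data List of [group_moments] (one per group).
#' @return Nonnegative scalar.
#' @export
ml_discrepancy <- function(params, data) {
  data <- check_groups(data)
  N <- sum(vapply(data, `[[`, numeric(1), "n"))
  total <- 0
  for (j in seq_along(data)) {
    gm <- data[[j]]
    S <- ml_cov(gm)
    R <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(R))
      stop("sample covariance of group ", j, " is singular", call. = FALSE)
    im <- implied_moments(params, j)
    Fj <- fml_group(im$mu, im$sigma, gm$mean, S, 2 * sum(log(diag(R))))
    if (Fj >= 1e12)
      stop("implied covariance of group ", j, " is singular", call. = FALSE)
    total <- total + gm$n / N * Fj
  }
  total
}

# ---- parameter mapping -----------------------------------------------------
#
# Free parameters are shared across groups according to the constraint
# set; per-group free intercepts with latent means fixed at 0 are
# profiled out analytically (gamma_j = xbar_j), which is exact because
# the mean structure is then saturated.

build_parmap <- function(model, m, cs) {
  pat <- lambda_pattern(model)
  marker <- attr(pat, "marker")
  p <- nrow(pat); k <- ncol(pat)
  free_load <- which(pat == 1)                       # linear indices in p x k
  free_load <- setdiff(free_load, (seq_len(k) - 1) * p + marker)
  ltri <- which(lower.tri(matrix(0, k, k), diag = TRUE))

  nxt <- 0L
  take <- function(n) { idx <- nxt + seq_len(n); nxt <<- nxt + n; idx }

  lam_shared <- "lambda" %in% cs$equal
  phi_shared <- "phi" %in% cs$equal
  psi_shared <- "psi" %in% cs$equal
  gam_shared <- "gamma" %in% cs$equal

  lam_idx <- if (lam_shared) list(take(length(free_load))) else
    lapply(seq_len(m), function(j) take(length(free_load)))
  phi_idx <- if (phi_shared) list(take(length(ltri))) else
    lapply(seq_len(m), function(j) take(length(ltri)))
  psi_idx <- if (psi_shared) list(take(p)) else
    lapply(seq_len(m), function(j) take(p))
  gam_idx <- if (gam_shared) list(take(p)) else NULL   # else profiled
  tau_idx <- if (cs$tau == "free" && m >= 2)
    lapply(seq_len(m - 1), function(j) take(k)) else NULL

  n_profiled <- if (gam_shared) 0L else m * p
  list(model = model, m = m, p = p, k = k, cs = cs, pat = pat,
       marker = marker, free_load = free_load, ltri = ltri,
       lam_idx = lam_idx, phi_idx = phi_idx, psi_idx = psi_idx,
       gam_idx = gam_idx, tau_idx = tau_idx,
       n_free = nxt, n_profiled = n_profiled,
       lam_shared = lam_shared, phi_shared = phi_shared,
       psi_shared = psi_shared, gam_shared = gam_shared)
}

# Materialize per-group parameter matrices from theta (gamma profiled
# groups get NA gammas; filled in by the objective / at the solution).
theta_to_groups <- function(theta, map) {
  p <- map$p; k <- map$k; m <- map$m
  pick <- function(idx, j) idx[[if (length(idx) == 1) 1 else j]]
  lapply(seq_len(m), function(j) {
    lambda <- matrix(0, p, k, dimnames = dimnames(map$pat))
    lambda[(seq_len(k) - 1) * p + map$marker] <- 1
    lambda[map$free_load] <- theta[pick(map$lam_idx, j)]
    phi <- matrix(0, k, k)
    phi[map$ltri] <- theta[pick(map$phi_idx, j)]
    phi <- phi + t(phi) - diag(diag(phi), k)
    psi <- theta[pick(map$psi_idx, j)]
    gamma <- if (map$gam_shared) theta[map$gam_idx[[1]]] else rep(NA_real_, p)
    tau <- rep(0, k)
    if (!is.null(map$tau_idx) && j >= 2) tau <- theta[map$tau_idx[[j - 1]]]
    list(gamma = gamma, lambda = lambda, phi = phi, psi = psi, tau = tau)
  })
}

# Data-driven start values: marker-variable scaling.
default_start <- function(map, data) {
  p <- map$p; k <- map$k; m <- map$m
  theta <- numeric(map$n_free)
  S_list <- lapply(data, ml_cov)
  # per-group raw block starts
  lam_g <- list(); phi_g <- list(); psi_g <- list()
  for (j in seq_len(m)) {
    S <- S_list[[j]]
    phv <- pmax(diag(S)[map$marker] * 0.5, 1e-3)
    lam <- matrix(0, p, k)
    for (f in seq_len(k)) {
      rows <- which(map$pat[, f] == 1)
      lam[rows, f] <- S[rows, map$marker[f]] / phv[f]
      lam[map$marker[f], f] <- 1
    }
    phi <- diag(phv, k)
    for (a in seq_len(k)) for (b in seq_len(k)) if (a != b)
      phi[a, b] <- 0.3 * sqrt(phv[a] * phv[b])
    comm <- rowSums((lam %*% phi) * lam)
    psi <- pmax(diag(S) - comm, 0.1 * diag(S))
    lam_g[[j]] <- lam; phi_g[[j]] <- phi; psi_g[[j]] <- psi
  }
  wavg <- function(xs) Reduce(`+`, xs) / length(xs)
  set_block <- function(idx, per_group_vals) {
    if (length(idx) == 1) theta[idx[[1]]] <<- wavg(per_group_vals)
    else for (j in seq_len(m)) theta[idx[[j]]] <<- per_group_vals[[j]]
  }
  set_block(map$lam_idx, lapply(lam_g, function(L) L[map$free_load]))
  set_block(map$phi_idx, lapply(phi_g, function(P) P[map$ltri]))
  set_block(map$psi_idx, psi_g)
  if (map$gam_shared) {
    ns <- vapply(data, `[[`, numeric(1), "n")
    xb <- Reduce(`+`, Map(function(gm, n) gm$mean * n, data, ns)) / sum(ns)
    theta[map$gam_idx[[1]]] <- xb
  }
  # tau starts at 0 (already)
  theta
}

# Map an existing parameter set onto theta (averaging blocks that the
# new constraint set shares across groups). Used for warm starts.
params_to_theta <- function(params, map) {
  gs <- if (inherits(params, "mi_params")) params$groups else params
  m <- map$m
  theta <- numeric(map$n_free)
  avg <- function(get) Reduce(`+`, lapply(gs, get)) / length(gs)
  if (map$lam_shared) theta[map$lam_idx[[1]]] <- avg(function(g) g$lambda[map$free_load])
  else for (j in seq_len(m)) theta[map$lam_idx[[j]]] <- gs[[j]]$lambda[map$free_load]
  if (map$phi_shared) theta[map$phi_idx[[1]]] <- avg(function(g) as.matrix(g$phi)[map$ltri])
  else for (j in seq_len(m)) theta[map$phi_idx[[j]]] <- as.matrix(gs[[j]]$phi)[map$ltri]
  getpsi <- function(g) if (is.matrix(g$psi)) diag(g$psi) else g$psi
  if (map$psi_shared) theta[map$psi_idx[[1]]] <- avg(getpsi)
  else for (j in seq_len(m)) theta[map$psi_idx[[j]]] <- getpsi(gs[[j]])
  if (map$gam_shared) {
    gam <- avg(function(g) g$gamma)
    if (anyNA(gam)) gam <- avg(function(g) g$mu_fallback %||% g$gamma)
    theta[map$gam_idx[[1]]] <- gam
  }
  if (!is.null(map$tau_idx))
    for (j in 2:m) theta[map$tau_idx[[j - 1]]] <- gs[[j]]$tau
  theta
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count degrees of freedom of a constrained multi-group model
#'
#' Moment-counting: `m * (p + p(p+1)/2)` sample moments minus the
#' number of free parameters under the marker-variable identification
#' (first loading per factor fixed at 1, factor variances free, latent
#' means zero in the baseline group when estimated) and the equality
#' constraints of the named set.
#'
#' @param model An `mi_model`.
#' @param constraints Constraint-set name (see [constraint_set]).
#' @param m Number of groups.
#' @return Integer degrees of freedom.
#' @export
mi_dof <- function(model, constraints = "configural", m = 2) {
  cs <- if (is.list(constraints)) constraints else constraint_set(constraints)
  map <- build_parmap(model, m, cs)
  moments <- m * (map$p + map$p * (map$p + 1) / 2)
  df <- moments - (map$n_free + map$n_profiled)
  if (df < 0)
    stop("model is over-parameterized (df = ", df, ")", call. = FALSE)
  as.integer(df)
}

#' Fit a multi-group factor model under a named constraint set
#'
#' Minimizes the normal-theory ML discrepancy [ml_discrepancy] over the
#' free parameters of the constraint set, by quasi-Newton iteration
#' with deterministic seeded random restarts on non-convergence.
#' Equality constraints are enforced by parameter sharing, not post-hoc
#' averaging.  The reported statistic is `T_ml = (N - m) F_ml`
#' (or `N F_ml` with `tstat = "sum"`).
#'
#' @param data List of [group_moments]; a single group is allowed for
#'   per-group configural fits.
#' @param model An `mi_model`.
#' @param constraints Constraint-set name or a list from
#'   [constraint_set].
#' @param start Optional warm start: an `mi_params` (or per-group
#'   parameter list) whose blocks are mapped (averaging where newly
#'   shared) onto the free-parameter vector.
#' @param tstat `"nm"` for `T = (N - m) F_ml` (default) or `"sum"` for
#'   the `sum n_j F_j = N F_ml` convention.
#' @param restarts Maximum number of seeded random restarts after a
#'   failed convergence check.
#' @param restart_seed Base seed for restart jitter.
#' @return An object of class `mi_fit`: list with `fml`, `tml`, `df`,
#'   `pvalue`, `estimates` (`mi_params`), `converged`, `n_iterations`,
#'   `constraints`, `N`, `m`, `tstat`.
#' @export
fit_mgcfa <- function(data, model, constraints = "configural", start = NULL,
                      tstat = c("nm", "sum"), restarts = 5,
                      restart_seed = 20170) {
  tstat <- match.arg(tstat)
  data <- check_groups(data)
  cs <- if (is.list(constraints)) constraints else constraint_set(constraints)
  m <- length(data)
  map <- build_parmap(model, m, cs)
  p <- map$p
  if (!is.null(names(data[[1]]$mean)) &&
      !identical(names(data[[1]]$mean), model$variables)) {
    ord <- match(model$variables, names(data[[1]]$mean))
    if (anyNA(ord))
      stop("model variables missing from data: ",
           paste(setdiff(model$variables, names(data[[1]]$mean)), collapse = ", "),
           call. = FALSE)
    data <- lapply(data, function(gm)
      group_moments(gm$label, gm$n, gm$mean[ord], gm$cov[ord, ord],
                    cov_type = gm$cov_type))
  }
  ns <- vapply(data, `[[`, numeric(1), "n")
  N <- sum(ns)
  w <- ns / N
  S_list <- lapply(data, ml_cov)
  logdetS <- vapply(S_list, function(S) {
    R <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(R)) stop("singular sample covariance", call. = FALSE)
    2 * sum(log(diag(R)))
  }, numeric(1))
  xbars <- lapply(data, `[[`, "mean")

  objective <- function(theta) {
    gs <- theta_to_groups(theta, map)
    tot <- 0
    for (j in seq_len(m)) {
      g <- gs[[j]]
      sigma <- g$lambda %*% g$phi %*% t(g$lambda)
      diag(sigma) <- diag(sigma) + g$psi
      mu <- if (map$gam_shared)
        as.numeric(theta[map$gam_idx[[1]]] + g$lambda %*% g$tau)
      else xbars[[j]]                       # profiled: mean term vanishes
      Fj <- fml_group(mu, sigma, xbars[[j]], S_list[[j]], logdetS[j])
      if (Fj >= 1e12) return(1e12)
      tot <- tot + w[j] * Fj
    }
    tot
  }

  theta0 <- if (is.null(start)) default_start(map, data)
            else params_to_theta(start, map)
  # a warm start mapped from a less constrained fit (e.g. with Heywood
  # estimates) can land where Sigma is not PD; fall back to data-driven
  # starts rather than optimizing on the guard plateau
  if (objective(theta0) >= 1e11) theta0 <- default_start(map, data)

  run_opt <- function(th) {
    ctrl <- list(eval.max = 4000, iter.max = 1000, rel.tol = 1e-11)
    o <- stats::nlminb(th, objective, control = ctrl)
    # polish: restart once from the solution
    o2 <- stats::nlminb(o$par, objective, control = ctrl)
    if (o2$objective < o$objective) o2 else o
  }
  grad_norm <- function(th) {
    h <- 1e-6 * pmax(abs(th), 1)
    g <- vapply(seq_along(th), function(i) {
      e <- numeric(length(th)); e[i] <- h[i]
      (objective(th + e) - objective(th - e)) / (2 * h[i])
    }, numeric(1))
    max(abs(g))
  }

  # gradient check on the F_ml scale, slightly relaxed for large misfit
  gtol <- function(o) 5e-4 * max(1, o)
  opt <- run_opt(theta0)
  n_iter <- opt$iterations
  converged <- opt$objective < 1e11 && grad_norm(opt$par) < gtol(opt$objective)
  tries <- 0
  while (!converged && tries < restarts) {
    tries <- tries + 1
    jit <- withr_seed(restart_seed + tries, stats::rnorm(map$n_free, 0, 0.1))
    base <- if (tries %% 2 == 0) theta0 else default_start(map, data)
    cand <- run_opt(base * (1 + jit) + 0.01 * jit)
    n_iter <- n_iter + cand$iterations
    if (cand$objective < opt$objective) opt <- cand
    converged <- opt$objective < 1e11 && grad_norm(opt$par) < gtol(opt$objective)
  }

  gs <- theta_to_groups(opt$par, map)
  for (j in seq_len(m)) {
    if (!map$gam_shared)
      gs[[j]]$gamma <- xbars[[j]] - as.numeric(gs[[j]]$lambda %*% gs[[j]]$tau)
    names(gs[[j]]$gamma) <- model$variables
    names(gs[[j]]$psi) <- model$variables
    dimnames(gs[[j]]$phi) <- list(names(model$factors), names(model$factors))
    names(gs[[j]]$tau) <- names(model$factors)
  }
  if (any(vapply(gs, function(g) any(g$psi < 0), logical(1))))
    warning("Heywood case: negative error variance at the solution",
            call. = FALSE)

  fml <- opt$objective
  mult <- if (tstat == "nm") N - m else N
  tml <- max(mult * fml, 0)
  df <- mi_dof(model, cs, m)
  structure(list(
    fml = fml, tml = tml, df = df,
    pvalue = if (df > 0) stats::pchisq(tml, df, lower.tail = FALSE) else NA_real_,
    estimates = structure(list(model = model, groups = gs), class = "mi_params"),
    converged = converged, n_iterations = n_iter,
    constraints = cs$name %||% "custom", N = N, m = m, tstat = tstat,
    group_labels = vapply(data, `[[`, character(1), "label")),
    class = "mi_fit")
}

# evaluate expr under a temporary RNG seed without disturbing the
# caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.mi_fit <- function(x, ...) {
  cat(sprintf("mi_fit [%s]: T = %.3f, df = %d, p = %s, converged = %s\n",
              x$constraints, x$tml, x$df,
              ifelse(is.na(x$pvalue), "NA", sprintf("%.3f", x$pvalue)),
              x$converged))
  invisible(x)
}

#' Chi-square-difference test between nested fits
#'
#' @param child The more constrained fit (an `mi_fit`).
#' @param parent The less constrained fit it nests in.
#' @return List with `tdiff`, `dfdiff`, `pvalue`.  A negative `tdiff`
#'   is reported with a warning, not truncated.
#' @export
chisq_diff <- function(child, parent) {
  stopifnot(inherits(child, "mi_fit"), inherits(parent, "mi_fit"))
  ccs <- mi_constraint_table[[child$constraints]]
  pcs <- mi_constraint_table[[parent$constraints]]
  if (!is.null(ccs) && !is.null(pcs) && !constraints_nested(ccs, pcs))
    stop("models are not nested: ", child$constraints, " does not nest in ",
         parent$constraints, call. = FALSE)
  if (child$df < parent$df)
    stop("child model must have at least as many degrees of freedom as parent",
         call. = FALSE)
  tdiff <- child$tml - parent$tml
  if (tdiff < 0)
    warning("negative chi-square difference (", format(tdiff), ")",
            call. = FALSE)
  dfdiff <- child$df - parent$df
  list(tdiff = tdiff, dfdiff = dfdiff,
       pvalue = if (dfdiff > 0)
         stats::pchisq(max(tdiff, 0), dfdiff, lower.tail = FALSE)
       else NA_real_)
}

#' Likelihood-ratio test of equal population covariance matrices
#'
#' Tests `H_sigma: Sigma^(1) = ... = Sigma^(m)` with saturated means.
#' Under this constraint the ML estimate of the common covariance is
#' the sample-size-weighted pool of the groups' (ML-scale) covariance
#' matrices, so the statistic has the closed form
#' `T = (N - m) * sum_j (n_j/N) (log|S_pool| - log|S_j|)` with
#' `df = (m - 1) p (p + 1) / 2`.
#'
#' @param data List of [group_moments].
#' @param tstat Statistic scale convention, as in [fit_mgcfa].
#' @return An object of class `mi_fit` (with `estimates` holding the
#'   pooled covariance).
#' @export
cov_equality_test <- function(data, tstat = c("nm", "sum")) {
  tstat <- match.arg(tstat)
  data <- check_groups(data)
  m <- length(data)
  if (m < 2) stop("need at least 2 groups", call. = FALSE)
  ns <- vapply(data, `[[`, numeric(1), "n")
  N <- sum(ns)
  w <- ns / N
  S_list <- lapply(data, ml_cov)
  pool <- Reduce(`+`, Map(`*`, S_list, w))
  ld <- function(S) {
    R <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(R)) stop("singular covariance matrix", call. = FALSE)
    2 * sum(log(diag(R)))
  }
  fml <- ld(pool) - sum(w * vapply(S_list, ld, numeric(1)))
  fml <- max(fml, 0)
  p <- length(data[[1]]$mean)
  df <- as.integer((m - 1) * p * (p + 1) / 2)
  mult <- if (tstat == "nm") N - m else N
  tml <- mult * fml
  structure(list(fml = fml, tml = tml, df = df,
                 pvalue = stats::pchisq(tml, df, lower.tail = FALSE),
                 estimates = pool, converged = TRUE, n_iterations = 0L,
                 constraints = "equal.cov", N = N, m = m, tstat = tstat,
                 group_labels = vapply(data, `[[`, character(1), "label")),
            class = "mi_fit")
}

#' Run the full invariance-testing sequence
#'
#' Fits the configural model to each group separately, the joint
#' configural model, and the increasingly constrained models
#' (metric, equal error variances, equal factor covariances, scalar,
#' equal latent means, strict), computing each chi-square-difference
#' statistic against its nesting parent:
#' metric vs the combined configural model; `residuals` and `scalar`
#' vs metric; `varfactor` vs `residuals`; `strong.means` and
#' `strict.residuals` vs `scalar`; `strict.means` vs
#' `strict.residuals`.
#'
#' @param data List of [group_moments] (at least two groups).
#' @param model An `mi_model`.
#' @param scope `"both"` (default) runs the covariance and the mean
#'   branch; `"covariance"` stops after the variance-component steps;
#'   `"mean"` skips the variance-component steps.
#' @param tstat Statistic scale convention, as in [fit_mgcfa].
#' @return An object of class `mi_sequence`: a data frame with columns
#'   `Chisq`, `Df`, `pvalue`, `Chisq.diff`, `Df.diff`, `pvalue.diff`
#'   and the row names `fit.configural.g1`, ..., `fit.strict.means`;
#'   the underlying `mi_fit` objects are kept in `attr(, "fits")`.
#' @export
run_mi_sequence <- function(data, model, scope = c("both", "mean", "covariance"),
                            tstat = c("nm", "sum")) {
  scope <- match.arg(scope)
  tstat <- match.arg(tstat)
  data <- check_groups(data)
  m <- length(data)
  if (m < 2) stop("need at least 2 groups", call. = FALSE)

  fits <- list()
  rows <- list()
  add_row <- function(name, fit, diff = NULL) {
    rows[[name]] <<- data.frame(
      Chisq = fit$tml, Df = fit$df,
      pvalue = if (fit$df > 0) fit$pvalue else NA_real_,
      Chisq.diff = if (is.null(diff)) NA_real_ else diff$tdiff,
      Df.diff = if (is.null(diff)) NA_real_ else diff$dfdiff,
      pvalue.diff = if (is.null(diff)) NA_real_ else diff$pvalue,
      row.names = name)
    fits[[name]] <<- fit
  }

  for (j in seq_len(m)) {
    fj <- fit_mgcfa(data[j], model, "configural", tstat = tstat)
    add_row(paste0("fit.configural.g", j), fj)
  }
  fit_comb <- fit_mgcfa(data, model, "configural", tstat = tstat)
  add_row("fit.combine.groups", fit_comb)
  fit_metric <- fit_mgcfa(data, model, "metric",
                          start = fit_comb$estimates, tstat = tstat)
  add_row("fit.metric", fit_metric, chisq_diff(fit_metric, fit_comb))

  if (scope %in% c("both", "covariance")) {
    fit_res <- fit_mgcfa(data, model, "residuals",
                         start = fit_metric$estimates, tstat = tstat)
    add_row("fit.residuals", fit_res, chisq_diff(fit_res, fit_metric))
    fit_vf <- fit_mgcfa(data, model, "varfactor",
                        start = fit_res$estimates, tstat = tstat)
    add_row("fit.varfactor", fit_vf, chisq_diff(fit_vf, fit_res))
  }
  if (scope %in% c("both", "mean")) {
    fit_scalar <- fit_mgcfa(data, model, "scalar",
                            start = fit_metric$estimates, tstat = tstat)
    add_row("fit.scalar", fit_scalar, chisq_diff(fit_scalar, fit_metric))
    fit_sm <- fit_mgcfa(data, model, "strong.means",
                        start = fit_scalar$estimates, tstat = tstat)
    add_row("fit.strong.means", fit_sm, chisq_diff(fit_sm, fit_scalar))
    fit_sr <- fit_mgcfa(data, model, "strict.residuals",
                        start = fit_scalar$estimates, tstat = tstat)
    add_row("fit.strict.residuals", fit_sr, chisq_diff(fit_sr, fit_scalar))
    fit_stm <- fit_mgcfa(data, model, "strict.means",
                         start = fit_sr$estimates, tstat = tstat)
    add_row("fit.strict.means", fit_stm, chisq_diff(fit_stm, fit_sr))
  }

  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  class(out) <- c("mi_sequence", class(out))
  out
}
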