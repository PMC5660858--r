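#' Project a mean vector onto the common-score space
#'
#' Orthogonally decomposes a manifest mean vector into the component
#' lying in the column space of the loading matrix (the common-score
#' means `mu_kappa = Lambda kappa`) and the orthogonal remainder (the
#' specific-factor means `nu`), so that `xbar = mu_kappa + nu`
#' exactly.  The default metric is Euclidean; a positive-definite
#' weight matrix `W` gives the generalized (GLS-weighted) projection
#' `P = Lambda (Lambda' W Lambda)^-1 Lambda' W`.
#'
#' @param xbar Length-p mean vector.
#' @param lambda_hat p x k loading matrix of full column rank.
#' @param weight Optional p x p positive-definite weight matrix.
#' @return List with `mu_kappa` (p), `nu` (p) and `kappa` (k).
#' @export
project_means <- function(xbar, lambda_hat, weight = NULL) {
  lambda_hat <- as.matrix(lambda_hat)
  p <- nrow(lambda_hat); k <- ncol(lambda_hat)
  stopifnot(length(xbar) == p)
  qrL <- qr(lambda_hat)
  if (qrL$rank < k) {
    dep <- colnames(lambda_hat)[qrL$pivot[(qrL$rank + 1):k]]
    stop("loading matrix is rank deficient; collinear column(s): ",
         paste(if (is.null(dep)) qrL$pivot[(qrL$rank + 1):k] else dep,
               collapse = ", "), call. = FALSE)
  }
  W <- if (is.null(weight)) diag(p) else as.matrix(weight)
  A <- solve(crossprod(lambda_hat, W %*% lambda_hat),
             crossprod(lambda_hat, W))           # k x p: kappa = A xbar
  kappa <- as.numeric(A %*% xbar)
  mu_kappa <- as.numeric(lambda_hat %*% kappa)
  list(mu_kappa = stats::setNames(mu_kappa, rownames(lambda_hat)),
       nu = stats::setNames(as.numeric(xbar) - mu_kappa, rownames(lambda_hat)),
       kappa = stats::setNames(kappa, colnames(lambda_hat)))
}

# Orthonormal basis of the orthogonal complement of col(lambda).
null_basis <- function(lambda) {
  p <- nrow(lambda)
  q <- qr.Q(qr(lambda), complete = TRUE)
  q[, (ncol(lambda) + 1):p, drop = FALSE]
}

#' Projection-method mean comparison with Wald tests
#'
#' Given a common loading matrix (from a metric-invariance fit),
#' decomposes each group's mean vector into common-score and
#' specific-factor components and tests cross-group equality of (a)
#' the manifest means, (b) the common-factor means `kappa`, and (c)
#' the specific-factor means `nu`, each with a Wald statistic whose
#' weight is the inverse asymptotic covariance of the stacked
#' differences from group 1.  The sampling covariance of each group
#' mean is taken as `S_j / n_j`; the loading matrix is treated as
#' fixed (its sampling variability can be captured by
#' [bootstrap_mean_tests]).
#'
#' @param data List of [group_moments] (m >= 2 groups, group 1 is the
#'   baseline).
#' @param lambda_hat Either a p x k loading matrix or an `mi_fit`
#'   from a metric-constrained [fit_mgcfa] (its common loading matrix
#'   is extracted).
#' @param weight Optional projection weight matrix, as in
#'   [project_means].
#' @return An object of class `mi_projection`: per-group `kappa_hat`,
#'   `mu_kappa_hat`, `nu_hat`; per-group-vs-baseline comparison tables
#'   (`latent`, `common`, `specific`, each with estimate, difference,
#'   SE and z columns); `wald_manifest`, `wald_common`,
#'   `wald_specific` (each `statistic`, `df`, `pvalue`); and
#'   `validity` (rho^2_c).
#' @export
wald_mean_tests <- function(data, lambda_hat, weight = NULL) {
  data <- check_groups(data)
  m <- length(data)
  if (m < 2) stop("need at least 2 groups", call. = FALSE)
  if (inherits(lambda_hat, "mi_fit"))
    lambda_hat <- lambda_hat$estimates$groups[[1]]$lambda
  lambda_hat <- as.matrix(lambda_hat)
  p <- nrow(lambda_hat); k <- ncol(lambda_hat)
  if (p - k < 1)
    stop("specific-factor test undefined: p - k = ", p - k, call. = FALSE)
  ns <- vapply(data, `[[`, numeric(1), "n")
  N <- sum(ns)
  xbars <- lapply(data, `[[`, "mean")
  Vx <- lapply(data, function(gm) gm$cov / gm$n)   # Cov(xbar_j)

  proj <- lapply(xbars, project_means, lambda_hat = lambda_hat, weight = weight)
  W <- if (is.null(weight)) diag(p) else as.matrix(weight)
  A <- solve(crossprod(lambda_hat, W %*% lambda_hat),
             crossprod(lambda_hat, W))             # kappa = A xbar
  P <- lambda_hat %*% A                            # projection onto col(Lambda)
  Q <- null_basis(lambda_hat)                      # p x (p-k), orthonormal

  # stacked differences vs group 1 and their joint covariance; the
  # baseline mean is shared, so off-diagonal blocks are B V1 B'
  stack_wald <- function(B) {
    q <- nrow(B)
    d <- unlist(lapply(2:m, function(j) B %*% (xbars[[j]] - xbars[[1]])))
    V <- matrix(0, (m - 1) * q, (m - 1) * q)
    B_V1_B <- B %*% Vx[[1]] %*% t(B)
    for (a in 2:m) for (b in 2:m) {
      blk <- B_V1_B + if (a == b) B %*% Vx[[a]] %*% t(B) else 0
      V[(a - 2) * q + seq_len(q), (b - 2) * q + seq_len(q)] <- blk
    }
    Vi <- tryCatch(solve(V), error = function(e)
      stop("singular difference covariance in Wald test", call. = FALSE))
    list(stat = drop(t(d) %*% Vi %*% d), d = d, V = V)
  }

  w_man <- stack_wald(diag(p))
  w_com <- stack_wald(A)
  w_spe <- stack_wald(t(Q))

  wald <- function(w, df) list(statistic = w$stat, df = as.integer(df),
                               pvalue = stats::pchisq(w$stat, df, lower.tail = FALSE))

  # per-element comparison tables (group j vs baseline), SEs from the
  # diagonal of the propagated covariance
  comp_tables <- lapply(2:m, function(j) {
    Vd <- Vx[[1]] + Vx[[j]]
    tab <- function(B, est1, estj, nm) {
      se <- sqrt(diag(B %*% Vd %*% t(B)))
      d <- as.numeric(B %*% (xbars[[j]] - xbars[[1]]))
      data.frame(est1, estj, diff = d, SE = se, z = d / se, row.names = nm)
    }
    list(latent = tab(A, proj[[1]]$kappa, proj[[j]]$kappa, colnames(lambda_hat)),
         common = tab(P, proj[[1]]$mu_kappa, proj[[j]]$mu_kappa, rownames(lambda_hat)),
         specific = tab(diag(p) - P, proj[[1]]$nu, proj[[j]]$nu, rownames(lambda_hat)))
  })
  names(comp_tables) <- paste0("g", 2:m)

  kappa_diffs <- lapply(2:m, function(j) proj[[j]]$kappa - proj[[1]]$kappa)
  nu_diffs <- lapply(2:m, function(j) proj[[j]]$nu - proj[[1]]$nu)

  structure(list(
    lambda_hat = lambda_hat,
    kappa_hat = lapply(proj, `[[`, "kappa"),
    mu_kappa_hat = lapply(proj, `[[`, "mu_kappa"),
    nu_hat = lapply(proj, `[[`, "nu"),
    comparisons = comp_tables,
    wald_manifest = wald(w_man, (m - 1) * p),
    wald_common = wald(w_com, (m - 1) * k),
    wald_specific = wald(w_spe, (m - 1) * (p - k)),
    validity = validity_index(kappa_diffs, nu_diffs, lambda_hat),
    n_total = N, m = m,
    group_labels = vapply(data, `[[`, character(1), "label")),
    class = "mi_projection")
}

#' @export
print.mi_projection <- function(x, ...) {
  s <- function(w) sprintf("T = %.4f, df = %d, p = %.4f",
                           w$statistic, w$df, w$pvalue)
  cat("Projection-method mean comparison (baseline = group 1)\n")
  cat("  manifest means:  ", s(x$wald_manifest), "\n")
  cat("  common factors:  ", s(x$wald_common), "\n")
  cat("  specific factors:", s(x$wald_specific), "\n")
  cat("  validity index rho^2_c =",
      if (is.na(x$validity)) "undefined" else sprintf("%.7g", x$validity), "\n")
  invisible(x)
}

#' Validity index for mean differences
#'
#' Fraction of the squared manifest-variable mean differences that is
#' attributable to differences in common-factor means:
#' `rho^2_c = |mu_kappa_d|^2 / (|mu_kappa_d|^2 + |nu_d|^2)`, where
#' `mu_kappa_d` stacks `Lambda (kappa^(j) - kappa^(1))` and `nu_d`
#' stacks `nu^(j) - nu^(1)` over groups j = 2..m.
#'
#' @param kappa_diffs List (or single vector) of latent-mean
#'   differences vs the baseline group.
#' @param nu_diffs List (or single vector) of specific-factor mean
#'   differences vs the baseline group.
#' @param lambda_hat p x k loading matrix.
#' @return Value in \[0, 1\], or `NA` (with a message) when both
#'   components are zero and the ratio is undefined.
#' @export
validity_index <- function(kappa_diffs, nu_diffs, lambda_hat) {
  if (!is.list(kappa_diffs)) kappa_diffs <- list(kappa_diffs)
  if (!is.list(nu_diffs)) nu_diffs <- list(nu_diffs)
  mu_d <- unlist(lapply(kappa_diffs, function(kd)
    as.numeric(as.matrix(lambda_hat) %*% kd)))
  nu_d <- unlist(nu_diffs)
  ss_mu <- sum(mu_d^2); ss_nu <- sum(nu_d^2)
  if (ss_mu + ss_nu == 0) {
    message("validity index undefined: no mean differences in either component")
    return(NA_real_)
  }
  ss_mu / (ss_mu + ss_nu)
}

#' Equivalence testing of the projection-method Wald statistics
#'
#' Converts the manifest, common-factor and specific-factor Wald
#' statistics of a [wald_mean_tests] result into T-size epsilon and
#' RMSEA with adjusted cutoffs, using the Wald-statistic convention
#' `delta = N epsilon`.
#'
#' @param proj An `mi_projection` object.
#' @param alpha Significance level.
#' @param stat_family Divisor convention passed to [tsize]; the
#'   default `"wald_projection"` uses N.
#' @return Named list of `mi_equiv` objects: `fit.mvmean`,
#'   `fit.common`, `fit.specific`.
#' @export
equivalence_mean_tests <- function(proj, alpha = 0.05,
                                   stat_family = "wald_projection") {
  stopifnot(inherits(proj, "mi_projection"))
  one <- function(w) tsize(w$statistic, w$df, proj$n_total, proj$m,
                           alpha = alpha, stat_family = stat_family)
  list(fit.mvmean = one(proj$wald_manifest),
       fit.common = one(proj$wald_common),
       fit.specific = one(proj$wald_specific))
}

#' Bootstrap tests of equal common- and specific-factor means
#'
#' Tests the equality across groups of common-factor means and of
#' specific-factor means by a within-group nonparametric bootstrap.
#' Each group's raw data are first recentered to impose the null
#' hypothesis being tested (the corresponding projected component of
#' the observed mean differences is removed); each replicate resamples
#' rows within groups, refits the metric-invariance model (so the
#' uncertainty of the loading matrix is propagated) and recomputes the
#' Wald statistics.  p-values are the proportions of resampled
#' statistics at or above the observed ones.
#'
#' @param table Raw data frame with one group column (moments-only
#'   input cannot be bootstrapped).
#' @param model An `mi_model`.
#' @param group_col Name of the group column.
#' @param B Number of bootstrap replications.
#' @param seed Integer seed; the result is deterministic given `seed`.
#' @return List with `p_common`, `p_specific`, `B`, `observed` (the
#'   observed `mi_projection`).
#' @export
bootstrap_mean_tests <- function(table, model, group_col = "group",
                                 B = 200, seed = 1) {
  if (inherits(table, "group_moments") ||
      (is.list(table) && length(table) && inherits(table[[1]], "group_moments")))
    stop("bootstrap requires raw data; moments-only input cannot be resampled",
         call. = FALSE)
  stopifnot(B >= 1)
  table <- as.data.frame(table)
  data <- moments_from_raw(table, group_col)
  fit_m <- fit_mgcfa(data, model, "metric")
  obs <- wald_mean_tests(data, fit_m)
  lam <- obs$lambda_hat
  P <- lam %*% solve(crossprod(lam), t(lam))
  Q <- diag(nrow(lam)) - P

  g <- as.character(table[[group_col]])
  labels <- unique(g)
  vars <- model$variables
  xb <- lapply(data, `[[`, "mean")
  # per-hypothesis null imposition: remove the tested component of each
  # group's mean difference from the baseline
  shift <- function(Pmat, j) as.numeric(Pmat %*% (xb[[j]] - xb[[1]]))

  stat_pair <- function(tab) {
    d <- moments_from_raw(tab, group_col)
    # resampled refits may hit Heywood cases; that is expected noise here
    fm <- suppressWarnings(fit_mgcfa(d, model, "metric", restarts = 2))
    w <- wald_mean_tests(d, fm)
    c(common = w$wald_common$statistic, specific = w$wald_specific$statistic)
  }

  null_tab <- function(Pmat) {
    out <- table
    for (j in seq_along(labels)) {
      if (j == 1) next
      rows <- g == labels[j]
      out[rows, vars] <- sweep(as.matrix(table[rows, vars]), 2,
                               shift(Pmat, j), `-`)
    }
    out
  }
  tab_k <- null_tab(P)    # null: equal common-score means
  tab_n <- null_tab(Q)    # null: equal specific-factor means

  boot_stats <- withr_seed(seed, {
    res <- matrix(NA_real_, B, 2)
    for (b in seq_len(B)) {
      idx <- unlist(lapply(labels, function(l) {
        rows <- which(g == l); sample(rows, length(rows), replace = TRUE)
      }))
      res[b, 1] <- stat_pair(tab_k[idx, , drop = FALSE])["common"]
      res[b, 2] <- stat_pair(tab_n[idx, , drop = FALSE])["specific"]
    }
    res
  })
  list(p_common = mean(boot_stats[, 1] >= obs$wald_common$statistic),
       p_specific = mean(boot_stats[, 2] >= obs$wald_specific$statistic),
       B = B, observed = obs)
}
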