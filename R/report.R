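#' Full invariance analysis with an eight-part report
#'
#' Runs the complete pipeline on multi-group data: (1) the
#' likelihood-ratio test of equal population covariance matrices, (2)
#' the invariance sequence of chi-square and chi-square-difference
#' tests, (3) equivalence testing of every statistic (T-size epsilon,
#' T-size RMSEA, adjusted cutoffs, fit labels), (4) projection-method
#' Wald tests of manifest, common-factor and specific-factor means
#' with the validity index, (5) equivalence testing of those Wald
#' statistics, and (6-8) per-variable comparison tables of latent,
#' common-score and specific-factor means.
#'
#' @param model An `mi_model` or a model string for [parse_model].
#' @param data Either a list of [group_moments] or a raw data frame
#'   with a group column.
#' @param group_col Group column name when `data` is raw.
#' @param output `"both"`, `"mean"` or `"covariance"`: which branch of
#'   the sequence to run (the covariance scope suppresses the
#'   mean-structure rows and the projection parts).
#' @param equivalence_test Run the equivalence-testing parts.
#' @param adjRMSEA Attach adjusted cutoffs and labels to the
#'   equivalence parts.
#' @param projection Run the projection-method parts.
#' @param bootstrap Also compute bootstrap p-values (raw data only).
#' @param B,seed Bootstrap replications and seed.
#' @param alpha Significance level for equivalence testing.
#' @param quiet If `FALSE` (default), print the report.
#' @param tstat Statistic scale convention, see [fit_mgcfa].
#' @return An object of class `eqmi_result` (list of all parts);
#'   printed as the eight-part report.
#' @export
eqmi_main <- function(model, data, group_col = "group",
                      output = c("both", "mean", "covariance"),
                      equivalence_test = TRUE, adjRMSEA = TRUE,
                      projection = TRUE, bootstrap = FALSE, B = 200,
                      seed = 1, alpha = 0.05, quiet = FALSE,
                      tstat = c("nm", "sum")) {
  output <- match.arg(output)
  tstat <- match.arg(tstat)
  if (is.character(model)) model <- parse_model(model)
  raw <- NULL
  if (is.data.frame(data) || is.matrix(data)) {
    raw <- as.data.frame(data)
    data <- moments_from_raw(raw, group_col)
  }
  data <- check_groups(data)
  if (length(data) < 2) stop("need at least 2 groups", call. = FALSE)
  if (bootstrap && is.null(raw))
    stop("bootstrap requires raw data input", call. = FALSE)
  N <- sum(vapply(data, `[[`, numeric(1), "n"))
  m <- length(data)

  covtest <- cov_equality_test(data, tstat = tstat)
  seq_tab <- run_mi_sequence(data, model, scope = output, tstat = tstat)

  et_tab <- NULL
  if (equivalence_test) {
    rows <- rownames(seq_tab)
    et_rows <- setdiff(rows, "fit.combine.groups")
    stats_in <- c(fit.pop.cov = covtest$tml)
    dfs_in <- c(fit.pop.cov = covtest$df)
    for (r in et_rows) {
      use_diff <- !is.na(seq_tab[r, "Chisq.diff"])
      stats_in[r] <- if (use_diff) seq_tab[r, "Chisq.diff"] else seq_tab[r, "Chisq"]
      dfs_in[r] <- if (use_diff) seq_tab[r, "Df.diff"] else seq_tab[r, "Df"]
    }
    et_tab <- lapply(names(stats_in), function(r)
      tsize(stats_in[[r]], dfs_in[[r]], N, m, alpha = alpha))
    names(et_tab) <- names(stats_in)
  }

  proj <- proj_et <- boot <- NULL
  if (projection && output != "covariance") {
    fit_metric <- attr(seq_tab, "fits")[["fit.metric"]]
    proj <- wald_mean_tests(data, fit_metric)
    if (equivalence_test)
      proj_et <- equivalence_mean_tests(proj, alpha = alpha)
    if (bootstrap)
      boot <- bootstrap_mean_tests(raw, model, group_col, B = B, seed = seed)
  }

  out <- structure(list(covtest = covtest, sequence = seq_tab,
                        equivalence = et_tab, projection = proj,
                        projection_et = proj_et, bootstrap = boot,
                        adjRMSEA = adjRMSEA, alpha = alpha,
                        n_total = N, m = m, output = output),
                   class = "eqmi_result")
  if (!quiet) print(out)
  invisible(out)
}

hr <- function(title) cat(sprintf("---------- %s ----------\n", title))

fmt_num <- function(x, digits) ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))

print_table <- function(df, digits) {
  cells <- as.data.frame(Map(function(col, nm) {
    if (!is.numeric(col)) return(as.character(col))
    if (nm %in% c("Df", "Df.diff")) ifelse(is.na(col), "", sprintf("%d", as.integer(col)))
    else fmt_num(col, digits)
  }, df, names(df)), row.names = rownames(df), check.names = FALSE)
  names(cells) <- names(df)
  print(cells)
}

et_table <- function(et_list, adjRMSEA) {
  tab <- do.call(rbind, lapply(names(et_list), function(r) {
    e <- et_list[[r]]
    base <- data.frame(epsilon_t = e$epsilon_t, RMSEA_t = e$rmsea_t,
                       row.names = r)
    if (adjRMSEA) {
      base <- cbind(base, as.data.frame(as.list(e$cutoffs), row.names = r))
      base$`goodness-of-fit` <- e$label
    }
    base
  }))
  names(tab) <- sub("^cut\\.", "cut.", names(tab))
  tab
}

#' @export
print.eqmi_result <- function(x, ...) {
  hr("Equality of Population Covariance Matrices under NHT")
  print_table(data.frame(Chisq = x$covtest$tml, Df = x$covtest$df,
                         pvalue = x$covtest$pvalue, row.names = "fit.pop.cov"),
              digits = 5)
  cat("\n")
  hr("Chi-Square and Chi-Square-Difference Test under NHT")
  tab2 <- rbind(data.frame(Chisq = x$covtest$tml, Df = x$covtest$df,
                           pvalue = x$covtest$pvalue, Chisq.diff = NA_real_,
                           Df.diff = NA_real_, pvalue.diff = NA_real_,
                           row.names = "fit.pop.cov"),
                as.data.frame(x$sequence))
  tab2["fit.combine.groups", "pvalue"] <- NA_real_
  print_table(tab2, digits = 3)
  cat("\n")
  if (!is.null(x$equivalence)) {
    hr("T-size epsilon, RMSEA, and Adjusted Cutoff Values under ET")
    print_table(et_table(x$equivalence, x$adjRMSEA), digits = 3)
    cat("\n")
  }
  if (!is.null(x$projection)) {
    p <- x$projection
    hr("Means of Latent and Specific Factors by the Projection Method and under NHT")
    print_table(data.frame(
      Chisq = c(p$wald_manifest$statistic, p$wald_common$statistic,
                p$wald_specific$statistic),
      Df = c(p$wald_manifest$df, p$wald_common$df, p$wald_specific$df),
      pvalue = c(p$wald_manifest$pvalue, p$wald_common$pvalue,
                 p$wald_specific$pvalue),
      row.names = c("fit.mvmean", "fit.common", "fit.specific")), digits = 6)
    cat("Validity Index is", format(p$validity, digits = 7), "\n\n")
    if (!is.null(x$projection_et)) {
      hr("Means of Latent and Specific Factors by the Projection Method and under ET")
      print_table(et_table(x$projection_et, x$adjRMSEA), digits = 3)
      cat("\n")
    }
    if (!is.null(x$bootstrap)) {
      hr("Bootstrap p-values for Common and Specific Factor Means")
      cat(sprintf("p_common = %.4f, p_specific = %.4f (B = %d)\n\n",
                  x$bootstrap$p_common, x$bootstrap$p_specific, x$bootstrap$B))
    }
    comp_titles <- c(latent = "Cross-group Comparison of Latent Factor Means",
                     common = "Cross-group Comparison of Common Scores",
                     specific = "Cross-group Comparison of Specific Factors")
    for (what in names(comp_titles)) {
      hr(comp_titles[[what]])
      for (gname in names(p$comparisons)) {
        tab <- p$comparisons[[gname]][[what]]
        j <- sub("^g", "", gname)
        names(tab) <- c(paste0(what, "_1"), paste0(what, "_", j),
                        paste0(what, "_d"), "SE_d", "z_d")
        print_table(tab, digits = 5)
      }
      cat("\n")
    }
  }
  invisible(x)
}

# flatten the result into plain lists for JSON serialization
#' Convert an analysis result to a plain list
#'
#' Flattens an `eqmi_result` into base vectors/lists suitable for
#' `jsonlite::toJSON`.
#'
#' @param x An `eqmi_result`.
#' @return A nested plain list.
#' @export
as_bundle <- function(x) {
  stopifnot(inherits(x, "eqmi_result"))
  df2list <- function(df) c(list(row = rownames(df)),
                            lapply(as.data.frame(df), unname))
  out <- list(
    n_total = x$n_total, m = x$m, alpha = x$alpha, output = x$output,
    covtest = list(chisq = x$covtest$tml, df = x$covtest$df,
                   pvalue = x$covtest$pvalue),
    sequence = df2list(as.data.frame(x$sequence)))
  if (!is.null(x$equivalence))
    out$equivalence <- df2list(et_table(x$equivalence, TRUE))
  if (!is.null(x$projection)) {
    p <- x$projection
    out$projection <- list(
      wald = list(mvmean = p$wald_manifest, common = p$wald_common,
                  specific = p$wald_specific),
      validity = p$validity,
      comparisons = lapply(p$comparisons, function(g) lapply(g, df2list)))
    if (!is.null(x$projection_et))
      out$projection_et <- df2list(et_table(x$projection_et, TRUE))
    if (!is.null(x$bootstrap))
      out$bootstrap <- x$bootstrap[c("p_common", "p_specific", "B")]
  }
  out
}
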