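#' Construct a group's summary moments
#'
#' Bundles one group's sample size, mean vector and covariance matrix.
#' These are the sufficient statistics consumed by every fitting
#' routine in the package.
#'
#' @param label Group label (string).
#' @param n Number of observations (positive integer).
#' @param mean Numeric mean vector of length p, named by variable.
#' @param cov p x p covariance matrix (symmetric, positive
#'   semidefinite), same variable order as `mean`.
#' @param cov_type `"unbiased"` if `cov` uses the n - 1 divisor (the
#'   default for user-supplied moments and raw-data summaries) or
#'   `"ml"` if it is already on the maximum-likelihood (divisor n,
#'   or population) scale.  Unbiased covariances are rescaled by
#'   (n - 1)/n internally before entering the ML discrepancy.
#' @return An object of class `group_moments`.
#' @export
group_moments <- function(label, n, mean, cov,
                          cov_type = c("unbiased", "ml")) {
  cov_type <- match.arg(cov_type)
  if (!(is.numeric(n) && length(n) == 1 && n > 0 && n == round(n)))
    stop("n must be a positive integer", call. = FALSE)
  mean <- as.numeric(stats::setNames(mean, names(mean)))
  cov <- as.matrix(cov)
  p <- length(mean)
  if (!all(dim(cov) == c(p, p)))
    stop("mean length (", p, ") does not match cov dimension (",
         paste(dim(cov), collapse = "x"), ")", call. = FALSE)
  asym <- max(abs(cov - t(cov)))
  scale <- max(abs(cov), 1)
  if (asym > 1e-8 * scale)
    stop("covariance matrix is asymmetric beyond tolerance (max |S - S'| = ",
         format(asym), ")", call. = FALSE)
  cov <- (cov + t(cov)) / 2
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("covariance matrix is not positive semidefinite (min eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  vars <- names(mean)
  if (is.null(vars) && !is.null(rownames(cov))) vars <- rownames(cov)
  if (!is.null(vars)) {
    names(mean) <- vars
    dimnames(cov) <- list(vars, vars)
  }
  structure(list(label = as.character(label), n = as.integer(n),
                 mean = mean, cov = cov, cov_type = cov_type),
            class = "group_moments")
}

#' @export
print.group_moments <- function(x, ...) {
  cat("Group ", sQuote(x$label), ": n = ", x$n, ", p = ", length(x$mean),
      " (", x$cov_type, " covariance)\n", sep = "")
  invisible(x)
}

# Covariance on the ML (divisor-n) scale, the form entering F_ml.
ml_cov <- function(gm) {
  if (gm$cov_type == "unbiased") gm$cov * (gm$n - 1) / gm$n else gm$cov
}

split_fields <- function(line) {
  line <- gsub(",", " ", line, fixed = TRUE)
  strsplit(trimws(line), "[[:space:]]+")[[1]]
}

#' Read a moment file
#'
#' Reads one group's sample means and covariance matrix from a plain
#' text file in the layout: a header row of variable names (a leading
#' blank field before the first name is accepted), a row labeled
#' `mean` holding the mean vector, then p rows of the labeled
#' covariance matrix.  Whitespace- and comma-delimited files are both
#' accepted.  The sample size is not part of the file and is supplied
#' by the caller.
#'
#' @param path Path to the file.
#' @param n Number of observations for this group.
#' @param label Group label; defaults to the file name.
#' @param cov_type Divisor convention of the stored covariance; files
#'   are assumed unbiased (n - 1) by default.
#' @return A [group_moments] object.
#' @export
read_moments <- function(path, n, label = basename(path),
                         cov_type = c("unbiased", "ml")) {
  cov_type <- match.arg(cov_type)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3)
    stop("moment file ", sQuote(path), " is too short", call. = FALSE)
  vars <- split_fields(lines[1])
  p <- length(vars)
  mf <- split_fields(lines[2])
  if (tolower(mf[1]) != "mean")
    stop("moment file format error: second row must be labeled 'mean' (found ",
         sQuote(mf[1]), ")", call. = FALSE)
  if (length(mf) != p + 1)
    stop("mean row has ", length(mf) - 1, " values; expected ", p,
         call. = FALSE)
  mean <- as.numeric(mf[-1])
  if (anyNA(mean)) stop("non-numeric value in mean row", call. = FALSE)
  if (length(lines) != p + 2)
    stop("covariance block is not square: found ", length(lines) - 2,
         " rows for ", p, " variables", call. = FALSE)
  cov <- matrix(NA_real_, p, p, dimnames = list(vars, vars))
  for (i in seq_len(p)) {
    fl <- split_fields(lines[i + 2])
    if (length(fl) != p + 1)
      stop("covariance row ", i, " has ", length(fl) - 1,
           " values; expected ", p, call. = FALSE)
    row <- as.numeric(fl[-1])
    if (anyNA(row))
      stop("non-numeric value in covariance row ", i, call. = FALSE)
    cov[i, ] <- row
  }
  names(mean) <- vars
  group_moments(label, n, mean, cov, cov_type)
}

#' Write a moment file
#'
#' Serializes a [group_moments] object in the dialect read by
#' [read_moments]: header (with the required leading blank field),
#' `mean` row, labeled covariance rows.
#'
#' @param gm A [group_moments] object.
#' @param path Output path.
#' @param digits Significant digits to write.
#' @return `path`, invisibly.
#' @export
write_moments <- function(gm, path, digits = 12) {
  stopifnot(inherits(gm, "group_moments"))
  vars <- names(gm$mean)
  if (is.null(vars)) vars <- paste0("V", seq_along(gm$mean))
  num <- function(x) format(x, digits = digits, trim = TRUE, scientific = FALSE)
  out <- c(paste("", paste(vars, collapse = " ")),
           paste("mean", paste(num(gm$mean), collapse = " ")),
           vapply(seq_along(vars), function(i)
             paste(vars[i], paste(num(gm$cov[i, ]), collapse = " ")),
             character(1)))
  writeLines(out, path)
  invisible(path)
}

#' Per-group moments from a raw data table
#'
#' Splits a raw data table on a group-membership column and computes
#' each group's sample size, mean vector and unbiased (n - 1)
#' covariance matrix.  Groups are ordered by first appearance.
#'
#' @param table A data frame (or matrix coercible to one): rows are
#'   observations, columns are variables, plus one group column.
#' @param group_col Name of the group-membership column.
#' @return A list of [group_moments], one per distinct group label.
#' @export
moments_from_raw <- function(table, group_col = "group") {
  table <- as.data.frame(table)
  if (!group_col %in% names(table))
    stop("group column ", sQuote(group_col), " not found", call. = FALSE)
  g <- table[[group_col]]
  x <- table[setdiff(names(table), group_col)]
  for (j in seq_along(x)) {
    if (!is.numeric(x[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(x[[j]])))))
      stop("non-numeric value in column ", sQuote(names(x)[j]),
           if (length(bad)) paste0(" at row ", bad[1]), call. = FALSE)
    }
  }
  labels <- unique(as.character(g))
  if (length(labels) < 2)
    stop("need at least 2 distinct group labels, found ", length(labels),
         call. = FALSE)
  p <- ncol(x)
  out <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    xi <- as.matrix(x[as.character(g) == labels[i], , drop = FALSE])
    n <- nrow(xi)
    if (n <= p)
      warning("group ", sQuote(labels[i]), " has n = ", n, " <= p = ", p,
              ": covariance is singular", call. = FALSE)
    v <- apply(xi, 2, stats::var)
    if (any(v == 0))
      stop("zero variance within group ", sQuote(labels[i]),
           " for variable(s): ",
           paste(sQuote(colnames(xi)[v == 0]), collapse = ", "),
           call. = FALSE)
    out[[i]] <- group_moments(labels[i], n, colMeans(xi), stats::cov(xi),
                              cov_type = "unbiased")
  }
  names(out) <- labels
  out
}

# Validate a list of group_moments: common variable order, >= 2 groups.
check_groups <- function(data) {
  if (inherits(data, "group_moments")) data <- list(data)
  stopifnot(is.list(data), length(data) >= 1,
            all(vapply(data, inherits, logical(1), "group_moments")))
  vars <- names(data[[1]]$mean)
  for (gm in data[-1]) {
    if (length(gm$mean) != length(data[[1]]$mean))
      stop("groups have different numbers of variables", call. = FALSE)
    if (!is.null(vars) && !is.null(names(gm$mean)) &&
        !identical(names(gm$mean), vars))
      stop("variable order differs across groups", call. = FALSE)
  }
  data
}
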