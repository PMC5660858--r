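#' Parse a measurement-model statement
#'
#' Parses a factor-analysis measurement model written in the usual
#' `factor =~ indicator1 + indicator2` syntax, one factor per line.
#' Blank lines and `#` comments are ignored.  Only measurement (`=~`)
#' lines are supported: regressions (`~`) and residual covariances
#' (`~~`) are out of scope.
#'
#' @param text A single string (possibly multi-line) or a character
#'   vector of lines.
#' @return An object of class `mi_model`: a list with components
#'   `factors` (named list mapping each factor name to its character
#'   vector of indicators, in listing order) and `variables` (character
#'   vector of the distinct indicator names, in first-appearance order).
#'   An indicator listed under two factors is recorded as a
#'   cross-loading.
#' @examples
#' m <- parse_model("
#'   AlphabetKnowledge     =~ Letter_Name + Letter_Sound
#'   PhonologicalAwareness =~ Blending + Elision
#'   Spelling              =~ Real_Words + Pseudo_Words
#' ")
#' m$variables
#' @export
parse_model <- function(text) {
  stopifnot(is.character(text), length(text) >= 1)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    stop("empty model statement", call. = FALSE)

  factors <- list()
  for (ln in lines) {
    if (!grepl("=~", ln, fixed = TRUE))
      stop("model syntax error: no '=~' in line: ", sQuote(ln), call. = FALSE)
    parts <- strsplit(ln, "=~", fixed = TRUE)[[1]]
    if (length(parts) > 2)
      stop("model syntax error: more than one '=~' in line: ", sQuote(ln),
           call. = FALSE)
    if (length(parts) < 2) parts <- c(parts, "")
    fac <- trimws(parts[1])
    if (!grepl("^[A-Za-z.][A-Za-z0-9._]*$", fac))
      stop("invalid factor name: ", sQuote(fac), call. = FALSE)
    inds <- trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
    inds <- inds[nzchar(inds)]
    if (length(inds) == 0)
      stop("factor ", sQuote(fac), " has no indicators", call. = FALSE)
    bad <- inds[!grepl("^[A-Za-z.][A-Za-z0-9._]*$", inds)]
    if (length(bad))
      stop("invalid indicator name(s): ", paste(sQuote(bad), collapse = ", "),
           call. = FALSE)
    if (fac %in% names(factors)) {
      factors[[fac]] <- c(factors[[fac]], inds)
    } else {
      factors[[fac]] <- inds
    }
  }

  variables <- unique(unlist(factors, use.names = FALSE))
  clash <- intersect(names(factors), variables)
  if (length(clash))
    stop("factor name(s) duplicate variable name(s): ",
         paste(sQuote(clash), collapse = ", "), call. = FALSE)
  if (length(variables) < length(factors))
    stop("model has more factors than variables", call. = FALSE)

  structure(list(factors = factors, variables = variables),
            class = "mi_model")
}

#' @export
format.mi_model <- function(x, ...) {
  vapply(names(x$factors), function(f)
    paste(f, "=~", paste(x$factors[[f]], collapse = " + ")),
    character(1), USE.NAMES = FALSE)
}

#' @export
print.mi_model <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Loading-pattern matrix of a model
#'
#' Returns the p x k 0/1 pattern of the loading matrix implied by an
#' `mi_model`, with one column per factor and one nonzero row per
#' indicator.  The first indicator of each factor is the marker
#' (scaling) variable whose loading is fixed at 1 for identification.
#'
#' @param model An `mi_model`.
#' @return A p x k integer matrix with dimnames; attribute `"marker"`
#'   holds the row index of each factor's marker variable.
#' @export
lambda_pattern <- function(model) {
  stopifnot(inherits(model, "mi_model"))
  p <- length(model$variables)
  k <- length(model$factors)
  pat <- matrix(0L, p, k, dimnames = list(model$variables, names(model$factors)))
  marker <- integer(k)
  for (j in seq_len(k)) {
    inds <- model$factors[[j]]
    pat[match(inds, model$variables), j] <- 1L
    marker[j] <- match(inds[1], model$variables)
  }
  attr(pat, "marker") <- marker
  pat
}
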