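# Constraint sets for the invariance sequence.
#
# Each set records which parameter blocks are constrained equal across
# groups, how latent means are handled, and its nesting parent.
# Mean-structure handling ("tau"):
#   "zero" with per-group free intercepts  -> saturated means,
#   "free" (requires equal intercepts)     -> tau^(1) = 0 baseline,
#     other groups' latent means free,
#   "zero" with equal intercepts           -> all latent means equal (0).

mi_constraint_table <- list(
  configural       = list(equal = character(0),               tau = "zero", parent = NA_character_),
  metric           = list(equal = "lambda",                   tau = "zero", parent = "configural"),
  residuals        = list(equal = c("lambda", "psi"),         tau = "zero", parent = "metric"),
  varfactor        = list(equal = c("lambda", "psi", "phi"),  tau = "zero", parent = "residuals"),
  scalar           = list(equal = c("lambda", "gamma"),       tau = "free", parent = "metric"),
  strong.means     = list(equal = c("lambda", "gamma"),       tau = "zero", parent = "scalar"),
  strict.residuals = list(equal = c("lambda", "gamma", "psi"), tau = "free", parent = "scalar"),
  strict.means     = list(equal = c("lambda", "gamma", "psi"), tau = "zero", parent = "strict.residuals")
)

#' Named constraint sets of the invariance sequence
#'
#' Returns the definition of one of the named constraint sets used in
#' the invariance-testing sequence: which parameter blocks (loadings
#' `lambda`, intercepts `gamma`, error variances `psi`, factor
#' covariances `phi`) are held equal across groups, how the latent
#' means are treated, and the set's nesting parent.
#'
#' @param name One of `"configural"`, `"metric"`, `"residuals"`,
#'   `"varfactor"`, `"scalar"`, `"strong.means"`, `"strict.residuals"`,
#'   `"strict.means"`.
#' @return A list with components `name`, `equal`, `tau`, `parent`.
#' @export
constraint_set <- function(name) {
  name <- match.arg(name, names(mi_constraint_table))
  c(list(name = name), mi_constraint_table[[name]])
}

# Restrictiveness level of the mean structure (for nesting checks).
mean_level <- function(cs) {
  if (!"gamma" %in% cs$equal) 0L          # saturated means
  else if (cs$tau == "free")  1L          # equal intercepts, free latent means
  else                        2L          # equal intercepts and latent means
}

# TRUE if `child` is nested within (at least as constrained as) `parent`.
constraints_nested <- function(child, parent) {
  all(parent$equal %in% child$equal) && mean_level(child) >= mean_level(parent)
}
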