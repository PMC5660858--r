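# Shared fixtures, built in code at test time.

fig_model <- default_model()   # 3 factors x 2 indicators

small_model <- parse_model(c("F1 =~ a + b", "F2 =~ c + d"))

# a deterministic PSD moment pair for quick structural tests
fixture_moments <- function(n = c(80, 120), seed = 5, invariant = TRUE,
                            model = fig_model) {
  d <- sim_design(model = model, n = n, seed = seed)
  if (!invariant) d <- make_violation(d, "loading_shift", 0.3)
  simulate_groups(d, "moments")
}

# random loading matrix with marker structure, for projection tests
random_lambda <- function(p = 6, k = 3, seed = 1) {
  set.seed(seed)
  stopifnot(p %% k == 0)
  lam <- matrix(0, p, k)
  for (f in seq_len(k)) {
    rows <- (f - 1) * (p / k) + seq_len(p / k)
    lam[rows, f] <- c(1, runif(length(rows) - 1, 0.5, 1.5))
  }
  lam
}
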